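test_that("SSP source classification covers all four classes", {
  sp <- make_species(2, 1)                 # s01, s02 AMS; s03 non-AMS
  calls <- make_count_calls(c(s01 = 2, s03 = 1))
  g_both <- data.frame(species_id = c("s01", "s03"),
                       gene_id = c("s01_p001", "s03_p001"))
  g_ams <- data.frame(species_id = c("s01", "s02"),
                      gene_id = c("s01_p002", "s02_none"))
  g_non <- data.frame(species_id = "s03", gene_id = "s03_p001")
  g_nossp <- data.frame(species_id = c("s01", "s03"),
                        gene_id = c("s01_x", "s03_x"))
  expect_equal(classify_ssp_source(g_both, calls, sp), "BOTH")
  expect_equal(classify_ssp_source(g_ams, calls, sp), "AMS_ONLY")
  expect_equal(classify_ssp_source(g_non, calls, sp), "NONAMS_ONLY")
  expect_equal(classify_ssp_source(g_nossp, calls, sp), "NO_SSP")
  g_bad <- data.frame(species_id = "mystery", gene_id = "g")
  expect_error(classify_ssp_source(g_bad, calls, sp), "unknown species")
})

test_that("AMS specificity applies the ceiling of the 30% span rule", {
  sp <- make_species(39, 21)
  ams_ids <- sp$species_id[sp$ams_status == "AMS"]
  non_id <- sp$species_id[sp$ams_status == "non-AMS"][1]
  calls <- make_count_calls(setNames(rep(1, 39), ams_ids))
  group_of <- function(ids) data.frame(species_id = ids,
                                       gene_id = sprintf("%s_p001", ids))
  # ceiling(0.3 * 39) = 12: 12 AMS species suffice, 11 do not
  expect_true(is_ams_specific(group_of(ams_ids[1:12]), calls, sp))
  expect_false(is_ams_specific(group_of(ams_ids[1:11]), calls, sp))
  # one non-AMS member disqualifies regardless of AMS span
  with_non <- rbind(group_of(ams_ids[1:20]),
                    data.frame(species_id = non_id, gene_id = "x1"))
  expect_false(is_ams_specific(with_non, calls, sp))
  # a wide span without any SSP member is not specific
  no_ssp <- data.frame(species_id = ams_ids[1:15],
                       gene_id = sprintf("%s_x", ams_ids[1:15]))
  expect_false(is_ams_specific(no_ssp, calls, sp))
  # span can be restricted to SSP-contributing species
  mixed <- rbind(group_of(ams_ids[1:11]),
                 data.frame(species_id = ams_ids[12], gene_id = "notssp"))
  expect_true(is_ams_specific(mixed, calls, sp))                  # members span
  expect_false(is_ams_specific(mixed, calls, sp, span_on = "ssp"))
  expect_error(is_ams_specific(group_of(ams_ids[1:12]), calls, make_species(0, 3)),
               "no AMS species")
})

test_that("specificity is monotone in group membership", {
  sp <- make_species(10, 5)
  ams_ids <- sp$species_id[sp$ams_status == "AMS"]
  calls <- make_count_calls(setNames(rep(1, 10), ams_ids))
  g <- data.frame(species_id = ams_ids[1:4],
                  gene_id = sprintf("%s_p001", ams_ids[1:4]))
  expect_true(is_ams_specific(g, calls, sp))
  # adding a non-AMS member can only flip true -> false
  expect_false(is_ams_specific(
    rbind(g, data.frame(species_id = sp$species_id[11], gene_id = "z")), calls, sp))
  # adding another AMS-species member can only flip false -> true
  g2 <- g[1:2, ]
  expect_false(is_ams_specific(g2, calls, sp))
  expect_true(is_ams_specific(
    rbind(g2, data.frame(species_id = ams_ids[3:4],
                         gene_id = sprintf("%s_p001", ams_ids[3:4]))), calls, sp))
})

test_that("exact Wilcoxon path matches exhaustive enumeration (all pairs <= 8)", {
  set.seed(101)
  for (n in 1:8) for (m in 1:8) {
    x <- sample(10000, n); y <- sample(10000, m)
    while (anyDuplicated(c(x, y))) { x <- sample(10000, n); y <- sample(10000, m) }
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt), wilcox_enum_p(x, y, alt),
                   tolerance = 1e-12,
                   info = sprintf("n=%d m=%d alt=%s", n, m, alt))
    }
  }
  # worked example: 1,2,3 vs 4,5,6 is the single most extreme of C(6,3)=20
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, "less"), 0.05, tolerance = 1e-12)
})

test_that("identical samples give p = 1 two-sided", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two.sided"), 1)
})

test_that("empty samples are rejected", {
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks the exact enumeration at moderate sizes", {
  # one sample of size 11 forces the approximation path of the dispatcher;
  # the enumeration oracle stays exact
  set.seed(202)
  for (m in c(3L, 5L, 8L)) {
    for (rep in 1:5) {
      x <- sample(10000, 11); y <- sample(10000, m)
      while (anyDuplicated(c(x, y))) { x <- sample(10000, 11); y <- sample(10000, m) }
      for (alt in c("two.sided", "less", "greater")) {
        pe <- wilcox_enum_p(x, y, alt)
        pa <- wilcoxon_rank_sum(x, y, alt)
        expect_lt(abs(pa - pe), if (pe <= 0.2) 0.02 else 0.035)
      }
    }
  }
})

test_that("tie-corrected approximation stays close to enumeration under ties", {
  set.seed(303)
  for (rep in 1:10) {
    x <- sample(4, 11, replace = TRUE)   # heavy ties -> approximation path
    y <- sample(4, 6, replace = TRUE)
    pe <- wilcox_enum_p(x, y, "greater")
    pa <- wilcoxon_rank_sum(x, y, "greater")
    expect_lt(abs(pa - pe), 0.05)
  }
})

test_that("preferentiality is flagged under maximal separation and skipped otherwise", {
  sp <- make_species(5, 4)
  ams_ids <- sp$species_id[sp$ams_status == "AMS"]
  non_ids <- sp$species_id[sp$ams_status == "non-AMS"]
  calls <- make_count_calls(setNames(c(rep(5, 5), rep(1, 4)),
                                     c(ams_ids, non_ids)))
  memb <- do.call(rbind, lapply(c(ams_ids, non_ids), function(s) {
    k <- if (s %in% ams_ids) 5 else 1
    data.frame(species_id = s, gene_id = sprintf("%s_p%03d", s, seq_len(k)))
  }))
  res <- is_ams_preferential(memb, calls, sp)
  expect_true(res$preferential)
  expect_lte(res$p, 0.05)
  # a group without SSPs from both classes is not testable
  memb_ams <- memb[memb$species_id %in% ams_ids, ]
  res2 <- is_ams_preferential(memb_ams, calls, sp)
  expect_true(is.na(res2$preferential))
  expect_true(is.na(res2$p))
})

test_that("preferentiality test holds its nominal size under the null", {
  # 1000 groups where AMS and non-AMS per-species SSP counts share one
  # distribution: rejections at alpha = 0.05 should stay near 5%
  set.seed(404)
  rej <- replicate(1000, {
    wilcoxon_rank_sum(rpois(20, 5), rpois(13, 5), "greater") <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("genome-level tests detect gross separation and report direction", {
  sp <- make_species(5, 5, n_prot = 1000L)
  counts <- setNames(c(rep(1000, 5), rep(10, 5)), sp$species_id)
  calls <- make_count_calls(counts)
  res <- genome_level_tests(calls, sp)
  overall <- res[res$stratum == "all", ]
  expect_true(all(overall$p_value <= 0.05))
  expect_true(all(overall$direction == "AMS>non-AMS"))
  # equal proteome sizes make the ratio a rescaled count: identical p-values
  expect_equal(overall$p_value[overall$metric == "SSP_COUNT"],
               overall$p_value[overall$metric == "SSP_RATIO"])
})

test_that("strata with fewer than two species per side are skipped with a note", {
  sp <- make_species(3, 3)
  sp$lineage <- c("dicot", "dicot", "dicot", "dicot", "dicot", "monocot")
  calls <- make_count_calls(setNames(rep(3, 6), sp$species_id))
  res <- genome_level_tests(calls, sp)
  mono <- res[res$stratum == "monocot", ]
  expect_true(all(is.na(mono$p_value)))
  expect_match(mono$note[1], "skipped")
})

test_that("genome-level tests rarely reject under the null", {
  set.seed(505)
  hits <- replicate(40, {
    sp <- make_species(8, 8, n_prot = 1000L)
    counts <- setNames(rpois(16, 50), sp$species_id)
    calls <- make_count_calls(counts)
    res <- genome_level_tests(calls, sp)
    any(res$significant %in% TRUE)
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("classify_groups recovers planted structure on noiseless synthetic data", {
  sim <- simulate_dataset(tiny_cfg(tool_sensitivity = 1, tool_specificity = 1))
  calls <- call_ssp(sim$predictions)
  cls <- classify_groups(sim$orthogroups, calls, sim$species)
  expect_setequal(cls$group_id[cls$ams_specific],
                  sim$truth$planted_specific_groups)
  expect_true(all(sim$truth$planted_preferential_groups %in%
                    cls$group_id[cls$ams_preferential]))
  # source classes partition the SSP-containing groups
  src <- table(cls$ssp_source)
  n_ssp_groups <- sum(src[c("AMS_ONLY", "NONAMS_ONLY", "BOTH")], na.rm = TRUE)
  expect_equal(n_ssp_groups + sum(cls$ssp_source == "NO_SSP"), nrow(cls))
  expect_true(all(cls$ssp_source[cls$ams_specific] == "AMS_ONLY"))
  expect_true(all(cls$ssp_source[cls$ams_preferential] == "BOTH"))
})
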