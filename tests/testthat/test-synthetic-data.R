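test_that("AMS/non-AMS split follows round(n_species * frac_ams)", {
  sp <- simulate_species(sim_config(n_species = 10L, frac_ams = 0.5))
  expect_equal(sum(sp$ams_status == "AMS"), 5)
  expect_equal(sum(sp$ams_status == "non-AMS"), 5)

  sp <- simulate_species(sim_config(n_species = 60L, frac_ams = 0.65))
  expect_equal(sum(sp$ams_status == "AMS"), 39)
  expect_equal(sum(sp$ams_status == "non-AMS"), 21)
  expect_true(all(sp$lineage %in% c("dicot", "monocot", "other")))
  expect_false(anyDuplicated(sp$species_id) > 0)
})

test_that("identical configuration (seed included) reproduces identical data", {
  a <- simulate_dataset(tiny_cfg())
  b <- simulate_dataset(tiny_cfg())
  expect_identical(a, b)
  # stage streams are independent of each other: rerunning one stage alone
  # gives the same result as inside the full dataset
  sp <- simulate_species(tiny_cfg())
  expect_identical(sp, a$species)
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(frac_ams = 1.5), "frac_ams")
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(proteins_per_species = c(500L, 100L)),
               "proteins_per_species")
  expect_error(sim_config(n_orthogroups = 2L), "n_orthogroups")
  expect_error(sim_config(tool_sensitivity = c(a = 0.9)), "tool_sensitivity")
})

test_that("noiseless tools let the consensus caller recover ground truth exactly", {
  sim <- simulate_dataset(tiny_cfg(tool_sensitivity = 1, tool_specificity = 1))
  calls <- call_ssp(sim$predictions)
  expect_setequal(calls$protein_id[calls$is_ssp], sim$truth$true_ssp$protein_id)
})

test_that("caller recovery under tool noise matches the analytic error model", {
  cfg <- tiny_cfg(n_species = 6L, proteins_per_species = c(400L, 400L),
                  n_planted_specific = 0L, n_planted_preferential = 0L,
                  n_planted_up_groups = 0L, n_planted_down_groups = 0L,
                  n_preferential_convergent = 0L, n_planted_modules = 0L)
  sim <- simulate_dataset(cfg)
  calls <- call_ssp(sim$predictions)
  found <- calls$protein_id[calls$is_ssp]
  truth <- sim$truth$true_ssp$protein_id
  tp <- length(intersect(found, truth))
  recall <- tp / length(truth)

  # independent analytic model of the caller's behaviour under per-tool
  # Bernoulli errors: a true SSP is recovered via the NSS branch (for
  # conventionally secreted proteins) or the extracellular branch
  sens <- cfg$tool_sensitivity; spec <- cfg$tool_specificity
  p2of3 <- function(p) p^3 + 3 * p^2 * (1 - p)
  p_no_tm_fp <- spec[["tm"]]^3
  p_nss_branch <- p2of3(sens[["nss"]]) * p_no_tm_fp
  p_loc <- p2of3(sens[["loc"]])
  p_nss_fp <- p2of3(1 - spec[["nss"]]) * p_no_tm_fp
  rec_nss <- 1 - (1 - p_nss_branch) * (1 - p_loc)    # status "nss"
  rec_unconv <- 1 - (1 - p_loc) * (1 - p_nss_fp)     # status "unconv"
  expected_recall <- mean(ifelse(
    sim$truth$status[truth] == "nss", rec_nss, rec_unconv))
  expect_lt(abs(recall - expected_recall), 0.05)
})

test_that("frac_true_ssp = 0 yields an empty ground-truth SSP set", {
  cfg <- tiny_cfg(frac_true_ssp = 0, n_planted_specific = 0L,
                  n_planted_preferential = 0L, n_planted_up_groups = 0L,
                  n_planted_down_groups = 0L, n_preferential_convergent = 0L,
                  n_planted_modules = 0L)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$true_ssp), 0)
})

test_that("protein lengths are truncated to [20, 600] and straddle the 50-250 gate", {
  sim <- simulate_dataset(tiny_cfg())
  len <- sim$predictions$length_aa
  expect_true(all(len >= 20 & len <= 600))
  expect_gt(sum(len < 50), 0)
  expect_gt(sum(len > 250), 0)
  expect_gt(sum(len >= 50 & len <= 250), 0)
})

test_that("planted structures satisfy their defining predicates by direct recount", {
  sim <- simulate_dataset(tiny_cfg())
  og <- sim$orthogroups
  status <- setNames(sim$species$ams_status, sim$species$species_id)
  n_ams <- sum(status == "AMS")
  true_ssp <- sim$truth$true_ssp$protein_id

  for (gid in sim$truth$planted_specific_groups) {
    g <- og[og$group_id == gid, ]
    expect_true(all(status[g$species_id] == "AMS"))
    expect_gte(length(unique(g$species_id)), ceiling(0.3 * n_ams))
    expect_true(all(g$gene_id %in% true_ssp))
  }
  k_exp <- 1 + round(tiny_cfg()$preferential_effect)
  for (gid in sim$truth$planted_preferential_groups) {
    g <- og[og$group_id == gid, ]
    cnt <- table(g$species_id[g$gene_id %in% true_ssp])
    expect_true(all(cnt[names(cnt)[status[names(cnt)] == "AMS"]] == k_exp))
    expect_true(all(cnt[names(cnt)[status[names(cnt)] == "non-AMS"]] == 1))
  }
  conv <- sim$truth$planted_convergent
  expect_true(all(conv$gene_id %in% true_ssp))
  key_og <- paste(og$group_id, og$species_id, og$gene_id)
  expect_true(all(paste(conv$group_id, conv$species_id, conv$gene_id) %in% key_og))
})

test_that("infeasible planting raises a configuration error naming the field", {
  cfg <- tiny_cfg(frac_ams = 0)
  expect_error(simulate_dataset(cfg), "frac_ams")
  expect_error(sim_config(n_de_species = 0L, n_planted_up_groups = 1L),
               "n_de_species")
})

test_that("de_log2fc = 0 plants no differential expression", {
  sim <- simulate_dataset(tiny_cfg(de_log2fc = 0))
  expect_equal(nrow(sim$truth$planted_de), 0)
})

test_that("atlas generation needs at least 3 samples and is deterministic", {
  expect_error(simulate_dataset(tiny_cfg(n_atlas_samples = 2L)),
               "n_atlas_samples")
  a <- simulate_dataset(tiny_cfg())
  expect_identical(a$atlas, simulate_dataset(tiny_cfg())$atlas)
  # module genes live in the atlas species and include the SSP seed
  expect_true(all(unlist(a$truth$planted_modules) %in% rownames(a$atlas)))
  expect_true(all(a$truth$module_seeds %in% a$truth$true_ssp$protein_id))
})

test_that("written simulation round-trips through the readers", {
  sim <- simulate_dataset(tiny_cfg())
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_identical(read_species_table(file.path(dir, "species.tsv")), sim$species)
  expect_identical(read_predictions(file.path(dir, "predictions.tsv")),
                   sim$predictions)
  og <- read_orthogroups(file.path(dir, "Orthogroups.tsv"), sim$species)
  expect_identical(og, sim$orthogroups)
  atlas <- read_expression_matrix(file.path(dir, "atlas.tsv"))
  expect_equal(atlas[rownames(sim$atlas), ], sim$atlas, tolerance = 1e-12)
  fa <- read_protein_fasta(file.path(dir, sprintf("proteins_%s.faa",
                                                  sim$species$species_id[1])))
  ids <- sim$predictions$protein_id[sim$predictions$species_id ==
                                      sim$species$species_id[1]]
  expect_setequal(names(fa), ids)
  expect_identical(unname(fa[ids[1]]), unname(sim$sequences[ids[1]]))
})
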