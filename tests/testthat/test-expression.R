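test_that("genes with identical counts in both conditions are never called", {
  m <- matrix(rep(c(5, 9, 0), 4), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("c1", "c2", "t1", "t2")))
  de <- simple_de(m, c("control", "control", "treatment", "treatment"))
  expect_equal(de$log2fc, c(0, 0, 0))
  expect_true(all(de$direction == "ns"))
  expect_equal(de$padj[de$gene_id == "g3"], 1)   # all-zero gene
})

test_that("the fold-change threshold is a strict inequality", {
  # balanced libraries keep normalization neutral; gene g1 sits exactly at
  # log2fc = 1 (means 3 -> 7 give log2(8/4)), gene g2 mirrors it at -1
  m <- matrix(c(3, 7, 3, 7, 7, 3, 7, 3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "t1", "t2")))
  de <- simple_de(m, c("control", "control", "treatment", "treatment"))
  expect_equal(de$log2fc, c(1, -1))
  expect_lt(max(de$padj), 0.05)      # significance is not the blocker ...
  expect_equal(de$direction, c("ns", "ns"))  # ... the strict |log2fc| > 1 is
})

test_that("replicate and label validation", {
  m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_error(simple_de(m, c("control", "treatment", "treatment")),
               "2 replicates")
  expect_error(simple_de(m, c("control", "ctrl", "treatment")), "ctrl")
})

test_that("planted DE is recovered at the stated effect and replication", {
  # planted log2fc = 3, five replicates, dispersion 0.1
  cfg <- tiny_cfg(n_replicates = 5L, de_log2fc = 3, nb_dispersion = 0.1)
  sim <- simulate_dataset(cfg)
  ct <- sim$counts[[1]]
  de <- simple_de(ct$counts, ct$condition, species_id = ct$species_id,
                  contrast_id = ct$contrast_id)
  planted <- sim$truth$planted_de
  planted <- planted[planted$contrast_id == ct$contrast_id, ]
  called <- de[de$direction != "ns", ]
  hit <- merge(planted, called, by = "gene_id")
  recall <- sum(hit$direction.x == hit$direction.y) / nrow(planted)
  fdr <- if (nrow(called)) mean(!(called$gene_id %in% planted$gene_id)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("Benjamini-Hochberg matches the hand-worked step-up example", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
  # monotone: adjustment preserves the ordering of sorted p-values
  set.seed(1)
  p <- sort(runif(50))
  expect_true(all(diff(benjamini_hochberg(p)) >= 0))
})

test_that("DE/SSP intersection keeps only SSP genes of the same species", {
  calls <- data.frame(protein_id = c("g1", "g2", "g3"),
                      species_id = c("A", "A", "B"),
                      is_ssp = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g3"),
                   species_id = c("A", "A", "A", "A", "B"),
                   contrast_id = "c", log2fc = 2, padj = 0.01,
                   direction = "up", stringsAsFactors = FALSE)
  out <- de_ssp_intersect(de, calls)
  # of the 5 DE records only g1 (SSP in A) and g3-in-B survive; the g3
  # record in species A is excluded because g3 is an SSP only in B
  expect_equal(paste(out$species_id, out$gene_id), c("A g1", "B g3"))
})

test_that("convergence needs the same direction in enough species", {
  og <- data.frame(group_id = "OG1", species_id = c("A", "B"),
                   gene_id = c("a1", "b1"), stringsAsFactors = FALSE)
  de <- function(dirs) data.frame(
    gene_id = c("a1", "b1"), species_id = c("A", "B"), contrast_id = "c",
    log2fc = c(2, ifelse(dirs[2] == "up", 2, -2)), padj = 0.01,
    direction = dirs, stringsAsFactors = FALSE)

  both_up <- detect_convergence(de(c("up", "up")), og)
  expect_equal(nrow(both_up), 1)
  expect_equal(both_up$direction, "up")
  expect_equal(both_up$n_species, 2)
  expect_equal(both_up$species_with_signal, "A,B")

  opposed <- detect_convergence(de(c("up", "down")), og)
  expect_equal(nrow(opposed), 0)

  # a group may appear in both directions when each direction has support
  og2 <- data.frame(group_id = "OG1", species_id = c("A", "B", "C", "D"),
                    gene_id = c("a1", "b1", "c1", "d1"), stringsAsFactors = FALSE)
  de2 <- data.frame(gene_id = c("a1", "b1", "c1", "d1"),
                    species_id = c("A", "B", "C", "D"), contrast_id = "c",
                    log2fc = c(2, 2, -2, -2), padj = 0.01,
                    direction = c("up", "up", "down", "down"),
                    stringsAsFactors = FALSE)
  two_dir <- detect_convergence(de2, og2)
  expect_setequal(two_dir$direction, c("up", "down"))
})

test_that("convergence detection is invariant to row order", {
  set.seed(7)
  og <- data.frame(group_id = rep(c("OG1", "OG2"), each = 3),
                   species_id = rep(c("A", "B", "C"), 2),
                   gene_id = sprintf("g%d", 1:6), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = sprintf("g%d", 1:6),
                   species_id = rep(c("A", "B", "C"), 2),
                   contrast_id = "c", log2fc = 2, padj = 0.01,
                   direction = "up", stringsAsFactors = FALSE)
  ref <- detect_convergence(de, og)
  shuf <- detect_convergence(de[sample(nrow(de)), ], og[sample(nrow(og)), ])
  expect_identical(ref, shuf)
})

test_that("the convergence effect matrix averages member fold changes", {
  og <- data.frame(group_id = "OG1", species_id = c("A", "A", "B"),
                   gene_id = c("a1", "a2", "b1"), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("a1", "a2", "b1"), species_id = c("A", "A", "B"),
                   contrast_id = "c", log2fc = c(2, 4, 5), padj = 0.01,
                   direction = "up", stringsAsFactors = FALSE)
  conv <- detect_convergence(de, og)
  m <- convergence_matrix(conv, de, og, "up")
  expect_equal(m["OG1", "A"], 3)
  expect_equal(m["OG1", "B"], 5)
})
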