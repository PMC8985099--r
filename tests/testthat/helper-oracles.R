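# Independent oracles and shared fixtures. Everything here is coded from the
# scientific definitions, not from the package implementation it checks.

# Exhaustive rank-assignment enumeration of the Wilcoxon rank-sum null:
# every way of labelling n of the n+m observations as "x" is equally likely.
# Handles ties through midranks.
wilcox_enum_p <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  picks <- combn(n + m, n)
  w_perm <- colSums(matrix(r[picks], nrow = n)) - n * (n + 1) / 2
  ge <- mean(w_perm >= w_obs - 1e-9)
  le <- mean(w_perm <= w_obs + 1e-9)
  switch(alternative,
         greater = ge,
         less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

# Truth-table oracle for the consensus caller, written as literal branch
# logic: list 1 = gated, >=2 NSS votes, no TM vote; list 2 = gated, >=2
# localization votes; category follows from list membership.
call_oracle <- function(nss, tm, loc, length_aa, complete_orf) {
  gate <- complete_orf && length_aa >= 50 && length_aa <= 250
  in_list1 <- gate && sum(nss) >= 2 && sum(tm) == 0
  in_list2 <- gate && sum(loc) >= 2
  if (in_list1 && in_list2) "NSS_AND_EXTRA"
  else if (in_list1) "NSS_ONLY"
  else if (in_list2) "EXTRA_ONLY"
  else "NOT_SSP"
}

# Textbook two-pass Pearson correlation with the t-based two-sided p-value.
pcc_twopass <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(pcc = r, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}

# Small-but-complete synthetic world used by structural and IO tests; the
# acceptance suite runs the full default configuration instead.
tiny_cfg <- function(...) {
  args <- list(
    n_species = 10L, frac_ams = 0.6, proteins_per_species = c(150L, 200L),
    frac_true_ssp = 0.25, n_orthogroups = 80L,
    n_planted_specific = 1L, n_planted_preferential = 1L,
    preferential_effect = 3, n_planted_up_groups = 1L,
    n_planted_down_groups = 1L, n_preferential_convergent = 1L,
    n_de_species = 2L, n_replicates = 3L, n_background_de = 10L,
    n_atlas_samples = 12L, planted_module_size = 4L, n_planted_modules = 1L,
    rng_seed = 11L)
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

# minimal species/calls fixtures for the orthology tests
make_species <- function(n_ams, n_nonams, lineage = "dicot", n_prot = 1000L) {
  n <- n_ams + n_nonams
  data.frame(
    species_id = sprintf("s%02d", seq_len(n)),
    ams_status = rep(c("AMS", "non-AMS"), c(n_ams, n_nonams)),
    lineage = rep_len(lineage, n),
    n_proteins_annotated = rep_len(n_prot, n),
    stringsAsFactors = FALSE)
}

# calls table holding `counts[s]` SSPs (and nothing else) for each species
make_count_calls <- function(counts) {
  sp <- rep(names(counts), counts)
  data.frame(
    protein_id = sprintf("%s_p%03d", sp, unlist(lapply(counts, seq_len),
                                                use.names = FALSE)),
    species_id = sp,
    is_ssp = TRUE,
    category = "NSS_ONLY",
    stringsAsFactors = FALSE)
}
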