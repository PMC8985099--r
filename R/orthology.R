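# AMS classification of ortholog groups and genome-level comparisons.

ams_status_map <- function(species) {
  setNames(species$ams_status, species$species_id)
}

# annotate a long membership table with per-member SSP flags from calls
flag_ssp_members <- function(orthogroups, calls) {
  ssp_key <- paste(calls$species_id, calls$protein_id)[calls$is_ssp]
  orthogroups$is_ssp <- paste(orthogroups$species_id, orthogroups$gene_id) %in% ssp_key
  orthogroups
}

#' Source class of an ortholog group's SSPs
#'
#' Classifies one group by which species class (AMS, non-AMS) contributes its
#' SSP members: `AMS_ONLY`, `NONAMS_ONLY`, `BOTH`, or `NO_SSP` when the group
#' has members but none is an SSP.
#'
#' @param group membership data frame of one group (`species_id`, `gene_id`).
#' @param calls consensus calls from [call_ssp()].
#' @param species species table.
#' @return one of `"AMS_ONLY"`, `"NONAMS_ONLY"`, `"BOTH"`, `"NO_SSP"`.
#' @export
classify_ssp_source <- function(group, calls, species) {
  status <- ams_status_map(species)
  unknown <- setdiff(group$species_id, names(status))
  if (length(unknown))
    stop(sprintf("unknown species '%s' in ortholog group", unknown[1]), call. = FALSE)
  g <- flag_ssp_members(group, calls)
  ssp_status <- status[g$species_id[g$is_ssp]]
  if (length(ssp_status) == 0L) return("NO_SSP")
  has_ams <- any(ssp_status == "AMS")
  has_non <- any(ssp_status == "non-AMS")
  if (has_ams && has_non) "BOTH" else if (has_ams) "AMS_ONLY" else "NONAMS_ONLY"
}

#' AMS specificity of an ortholog group
#'
#' A group is AMS-specific when it has no member from any non-AMS species,
#' spans at least `ceiling(min_frac * n_AMS)` distinct AMS species, and
#' contains at least one SSP. Span is counted over all members by default
#' (`span_on = "members"`); set `span_on = "ssp"` to count only species
#' contributing SSP members.
#'
#' @param group membership data frame of one group.
#' @param calls consensus calls.
#' @param species species table (needs at least one AMS species).
#' @param min_frac minimum fraction of AMS species spanned (default 0.30).
#' @param span_on count species span on `"members"` or `"ssp"` members.
#' @return logical.
#' @export
is_ams_specific <- function(group, calls, species, min_frac = 0.30,
                            span_on = c("members", "ssp")) {
  span_on <- match.arg(span_on)
  status <- ams_status_map(species)
  n_ams <- sum(status == "AMS")
  if (n_ams == 0L) stop("no AMS species in the species table", call. = FALSE)
  g <- flag_ssp_members(group, calls)
  if (any(status[g$species_id] == "non-AMS")) return(FALSE)
  span_members <- if (span_on == "ssp") g$species_id[g$is_ssp] else g$species_id
  span <- length(unique(span_members))
  span >= ceiling(min_frac * n_ams) && any(g$is_ssp)
}

#' Wilcoxon rank-sum p-value
#'
#' Dispatches to the exact null distribution when both samples are small
#' (`max(n) <= 10`) and tie-free, and to the normal approximation with tie and
#' continuity correction otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (alternative:
#'   x shifted relative to y).
#' @return the p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  exact <- max(length(x), length(y)) <= 10L && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value
  )
}

# per-species SSP-member counts of one group, over all species (zeros
# included) or only over species present in the group
group_ssp_counts <- function(group, calls, species, include_absent = TRUE) {
  g <- flag_ssp_members(group, calls)
  tab <- table(factor(g$species_id[g$is_ssp], levels = species$species_id))
  counts <- as.numeric(tab)
  names(counts) <- species$species_id
  if (!include_absent) counts <- counts[names(counts) %in% unique(g$species_id)]
  counts
}

#' AMS preferentiality of an ortholog group
#'
#' For a group whose SSPs come from both species classes, tests whether AMS
#' species carry significantly more SSPs than non-AMS species: a one-sided
#' Wilcoxon rank-sum test on per-species SSP counts. By default every species
#' contributes a count (zero when absent from the group); set
#' `include_absent = FALSE` to restrict to species present in the group.
#'
#' @param group membership data frame of one group.
#' @param calls consensus calls.
#' @param species species table.
#' @param alpha significance level (default 0.05).
#' @param include_absent include zero counts for species absent from the
#'   group?
#' @return list with `preferential` (logical; `NA` when not testable) and `p`
#'   (p-value or `NA` when the group's SSP source is not `BOTH`).
#' @export
is_ams_preferential <- function(group, calls, species, alpha = 0.05,
                                include_absent = TRUE) {
  src <- classify_ssp_source(group, calls, species)
  if (src != "BOTH") return(list(preferential = NA, p = NA_real_))
  counts <- group_ssp_counts(group, calls, species, include_absent)
  status <- ams_status_map(species)[names(counts)]
  p <- wilcoxon_rank_sum(counts[status == "AMS"], counts[status == "non-AMS"],
                         alternative = "greater")
  list(preferential = p <= alpha, p = p)
}

#' Classify all ortholog groups
#'
#' Runs [classify_ssp_source()], [is_ams_specific()] and
#' [is_ams_preferential()] over every group of a membership table.
#'
#' @param orthogroups long membership data frame.
#' @param calls consensus calls.
#' @param species species table.
#' @param min_frac AMS-specificity span threshold (default 0.30).
#' @param alpha preferentiality significance level (default 0.05).
#' @param span_on see [is_ams_specific()].
#' @param include_absent see [is_ams_preferential()].
#' @param adjust apply Benjamini-Hochberg correction across the
#'   preferentiality p-values before thresholding (off by default, matching
#'   the published raw `P <= 0.05` rule).
#' @return data frame with one row per group: `group_id`, `ssp_source`,
#'   `ams_specific`, `ams_preferential`, `wilcoxon_p`,
#'   `ams_species_fraction`.
#' @export
classify_groups <- function(orthogroups, calls, species, min_frac = 0.30,
                            alpha = 0.05, span_on = "members",
                            include_absent = TRUE, adjust = FALSE) {
  status <- ams_status_map(species)
  n_ams <- sum(status == "AMS")
  groups <- split(orthogroups, orthogroups$group_id)
  res <- lapply(groups, function(g) {
    src <- classify_ssp_source(g, calls, species)
    spec <- if (src == "AMS_ONLY")
      is_ams_specific(g, calls, species, min_frac, span_on) else FALSE
    pref <- is_ams_preferential(g, calls, species, alpha, include_absent)
    ams_span <- length(unique(g$species_id[status[g$species_id] == "AMS"]))
    data.frame(group_id = g$group_id[1], ssp_source = src,
               ams_specific = spec,
               wilcoxon_p = pref$p,
               ams_species_fraction = if (n_ams > 0) ams_span / n_ams else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p <- out$wilcoxon_p
  if (adjust) p[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  out$ams_preferential <- !is.na(p) & p <= alpha
  out <- out[, c("group_id", "ssp_source", "ams_specific", "ams_preferential",
                 "wilcoxon_p", "ams_species_fraction")]
  reset_rownames(order_by(out, "group_id"))
}

#' Genome-level AMS vs non-AMS comparisons
#'
#' Two-sided Wilcoxon rank-sum tests on per-species SSP counts and SSP ratios
#' (count divided by annotated proteome size), overall and stratified by
#' lineage. Strata with fewer than two species on either side are reported
#' with a `skipped` note instead of a p-value.
#'
#' @param calls consensus calls.
#' @param species species table.
#' @param alpha significance level used for the `significant` flag.
#' @return data frame with columns `metric` (`SSP_COUNT`/`SSP_RATIO`),
#'   `stratum`, `n_ams`, `n_nonams`, `p_value`, `direction`, `significant`,
#'   `note`.
#' @export
genome_level_tests <- function(calls, species, alpha = 0.05) {
  counts <- table(factor(calls$species_id[calls$is_ssp],
                         levels = species$species_id))
  per_species <- data.frame(
    species_id = species$species_id,
    ams_status = species$ams_status,
    lineage = species$lineage,
    ssp_count = as.numeric(counts),
    ssp_ratio = as.numeric(counts) / species$n_proteins_annotated,
    stringsAsFactors = FALSE
  )
  strata <- c("all", sort(unique(species$lineage)))
  rows <- list()
  for (metric in c("SSP_COUNT", "SSP_RATIO")) {
    col <- if (metric == "SSP_COUNT") "ssp_count" else "ssp_ratio"
    for (st in strata) {
      d <- if (st == "all") per_species else per_species[per_species$lineage == st, ]
      x <- d[[col]][d$ams_status == "AMS"]
      y <- d[[col]][d$ams_status == "non-AMS"]
      if (length(x) < 2L || length(y) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, stratum = st, n_ams = length(x), n_nonams = length(y),
          p_value = NA_real_, direction = NA_character_, significant = NA,
          note = "skipped: fewer than 2 species on one side",
          stringsAsFactors = FALSE)
        next
      }
      p <- wilcoxon_rank_sum(x, y, alternative = "two.sided")
      dir <- if (median(x) > median(y)) "AMS>non-AMS"
             else if (median(x) < median(y)) "AMS<non-AMS" else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, stratum = st, n_ams = length(x), n_nonams = length(y),
        p_value = p, direction = dir, significant = p <= alpha, note = "",
        stringsAsFactors = FALSE)
    }
  }
  reset_rownames(do.call(rbind, rows))
}
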