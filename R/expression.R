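# Differential expression, SSP intersection and cross-species convergence.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (wraps [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in \[0, 1\], same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) && (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Simple differential-expression engine
#'
#' A deliberately lightweight substitute for a full count-model DE method:
#' counts are library-size normalized (scaled to the median library size),
#' log2 fold change is `log2((mean_trt + 1) / (mean_ctl + 1))` on normalized
#' counts, the p-value comes from a per-gene Welch t-test on
#' `log2(normalized + 1)`, and adjustment is Benjamini-Hochberg. A gene is
#' `up` when `log2fc > min_abs_log2fc` (strict) and `padj <= alpha`, `down`
#' symmetrically, otherwise `ns`. Externally produced DE tables can be used
#' instead anywhere downstream.
#'
#' @param counts genes x samples count matrix with gene-id rownames.
#' @param condition character/factor of length `ncol(counts)` with values
#'   `"control"` and `"treatment"`; at least two replicates each.
#' @param alpha adjusted-p threshold (default 0.05, boundary inclusive).
#' @param min_abs_log2fc absolute log2-fold-change threshold (default 1,
#'   strict inequality).
#' @param species_id,contrast_id labels copied into the output records.
#' @return DE record data frame: `gene_id`, `species_id`, `contrast_id`,
#'   `log2fc`, `pvalue`, `padj`, `direction`.
#' @export
simple_de <- function(counts, condition, alpha = 0.05, min_abs_log2fc = 1,
                      species_id = NA_character_,
                      contrast_id = "AMF_vs_control") {
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("condition must have one label per sample column", call. = FALSE)
  bad <- setdiff(unique(condition), c("control", "treatment"))
  if (length(bad))
    stop(sprintf("unknown condition label '%s'", bad[1]), call. = FALSE)
  n_ctl <- sum(condition == "control")
  n_trt <- sum(condition == "treatment")
  if (n_ctl < 2L || n_trt < 2L)
    stop("simple_de needs at least 2 replicates per condition", call. = FALSE)

  lib <- colSums(counts)
  scale <- ifelse(lib > 0, median(lib) / lib, 1)
  norm <- sweep(counts, 2, scale, `*`)
  lg <- log2(norm + 1)

  ctl <- condition == "control"
  trt <- condition == "treatment"
  m_ctl <- rowMeans(lg[, ctl, drop = FALSE])
  m_trt <- rowMeans(lg[, trt, drop = FALSE])
  v_ctl <- apply(lg[, ctl, drop = FALSE], 1, var)
  v_trt <- apply(lg[, trt, drop = FALSE], 1, var)

  se2 <- v_ctl / n_ctl + v_trt / n_trt
  tstat <- (m_trt - m_ctl) / sqrt(se2)
  df <- se2^2 / ((v_ctl / n_ctl)^2 / (n_ctl - 1) + (v_trt / n_trt)^2 / (n_trt - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate genes (zero variance in both groups): p = 1 when the means
  # agree (includes all-zero genes), ~0 when they differ deterministically
  degen <- se2 == 0
  p[degen] <- ifelse(m_trt[degen] == m_ctl[degen], 1, .Machine$double.xmin)

  padj <- benjamini_hochberg(p)
  log2fc <- log2((rowMeans(norm[, trt, drop = FALSE]) + 1) /
                 (rowMeans(norm[, ctl, drop = FALSE]) + 1))
  direction <- rep("ns", nrow(counts))
  direction[log2fc > min_abs_log2fc & padj <= alpha] <- "up"
  direction[log2fc < -min_abs_log2fc & padj <= alpha] <- "down"

  data.frame(
    gene_id = rownames(counts),
    species_id = species_id,
    contrast_id = contrast_id,
    log2fc = unname(log2fc),
    pvalue = unname(p),
    padj = unname(padj),
    direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Restrict DE records to SSP genes
#'
#' Keeps DE records whose gene is a consensus-called SSP in the same species.
#'
#' @param de DE record data frame.
#' @param calls consensus calls from [call_ssp()].
#' @return the SSP subset of `de`.
#' @export
de_ssp_intersect <- function(de, calls) {
  ssp_key <- paste(calls$species_id, calls$protein_id)[calls$is_ssp]
  reset_rownames(de[paste(de$species_id, de$gene_id) %in% ssp_key, , drop = FALSE])
}

#' Cross-species convergent AMF-responsive ortholog groups
#'
#' For every ortholog group and direction, collects the species having at
#' least one differentially expressed SSP member with that direction and
#' reports the group when the species count reaches `min_species`. A group can
#' appear in both directions.
#'
#' @param de_ssp DE records restricted to SSPs (see [de_ssp_intersect()]);
#'   only rows with direction `up`/`down` count.
#' @param orthogroups long membership data frame.
#' @param min_species minimum number of species with signal (default 2).
#' @return data frame with `group_id`, `direction`, `n_species`,
#'   `species_with_signal` (comma-separated, sorted), `n_ssp_degs` (DE SSP
#'   members supporting the call).
#' @export
detect_convergence <- function(de_ssp, orthogroups, min_species = 2L) {
  de <- de_ssp[de_ssp$direction %in% c("up", "down"), , drop = FALSE]
  empty <- data.frame(group_id = character(0), direction = character(0),
                      n_species = integer(0), species_with_signal = character(0),
                      n_ssp_degs = integer(0), stringsAsFactors = FALSE)
  if (nrow(de) == 0L) return(empty)
  key_og <- paste(orthogroups$species_id, orthogroups$gene_id)
  key_de <- paste(de$species_id, de$gene_id)
  idx <- match(key_de, key_og)
  hit <- !is.na(idx)
  if (!any(hit)) return(empty)
  d <- data.frame(group_id = orthogroups$group_id[idx[hit]],
                  species_id = de$species_id[hit],
                  direction = de$direction[hit],
                  log2fc = de$log2fc[hit],
                  stringsAsFactors = FALSE)
  parts <- split(d, paste(d$group_id, d$direction, sep = "\r"))
  rows <- lapply(parts, function(g) {
    sp <- sort(unique(g$species_id))
    data.frame(group_id = g$group_id[1], direction = g$direction[1],
               n_species = length(sp),
               species_with_signal = paste(sp, collapse = ","),
               n_ssp_degs = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_species >= min_species, , drop = FALSE]
  reset_rownames(order_by(out, c("group_id", "direction")))
}

#' Group-by-species effect matrix for convergent groups
#'
#' One value per (group, species): the mean log2 fold change of that group's
#' differentially expressed SSP members in that species and direction, as
#' displayed in cross-species convergence heatmaps.
#'
#' @param convergence output of [detect_convergence()].
#' @param de_ssp DE records restricted to SSPs.
#' @param orthogroups long membership data frame.
#' @param direction `"up"` or `"down"`.
#' @return numeric matrix (groups x species) with `NA` where a species shows
#'   no signal.
#' @export
convergence_matrix <- function(convergence, de_ssp, orthogroups,
                               direction = c("up", "down")) {
  direction <- match.arg(direction)
  conv <- convergence[convergence$direction == direction, , drop = FALSE]
  if (nrow(conv) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  de <- de_ssp[de_ssp$direction == direction, , drop = FALSE]
  idx <- match(paste(de$species_id, de$gene_id),
               paste(orthogroups$species_id, orthogroups$gene_id))
  de$group_id <- orthogroups$group_id[idx]
  de <- de[!is.na(de$group_id) & de$group_id %in% conv$group_id, , drop = FALSE]
  species <- sort(unique(de$species_id))
  m <- matrix(NA_real_, nrow = nrow(conv), ncol = length(species),
              dimnames = list(conv$group_id, species))
  agg <- tapply(de$log2fc, list(de$group_id, de$species_id), mean)
  m[rownames(agg), colnames(agg)] <- agg
  m
}
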