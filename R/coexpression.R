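# Thresholded Pearson co-expression network, SSP rank labels and functional
# annotation of subnetwork partners.

#' Pearson correlation with p-value
#'
#' Product-moment correlation of two expression vectors and the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return named numeric vector `c(pcc = ..., p = ...)`.
#' @export
pcc_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant expression vector", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  c(pcc = unname(ct$estimate), p = ct$p.value)
}

# two-sided p-values for a matrix of correlations at n samples
cor_p_matrix <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tstat, n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

#' Build a thresholded co-expression network
#'
#' Computes Pearson correlations between seed genes and all genes of the atlas
#' (or between all pairs with `all_pairs = TRUE`) and retains edges with
#' `|PCC| >= pcc_min` and `p <= alpha`. Self-edges are excluded, edges are
#' canonical (`gene_a < gene_b`) and de-duplicated, and the edge list is a
#' deterministic function of the matrix and thresholds. Genes with constant
#' expression never form edges.
#'
#' @param atlas genes x samples numeric matrix (>= 3 samples) with gene-id
#'   rownames.
#' @param seeds character vector of seed gene ids (typically the SSP genes);
#'   ignored when `all_pairs = TRUE`. An empty seed set yields an empty
#'   network with a warning.
#' @param pcc_min absolute-correlation threshold (default 0.95).
#' @param alpha p-value threshold (default 0.05). Raw p-values by default;
#'   set `adjust = TRUE` for Benjamini-Hochberg across the tested pairs.
#' @param all_pairs build the full all-vs-all network instead of seed-vs-all.
#' @param log_transform apply `log2(x + 1)` to the atlas first.
#' @param adjust BH-adjust the correlation p-values before thresholding.
#' @return edge data frame `gene_a`, `gene_b`, `pcc`, `p_value`, sorted; the
#'   seed set used is attached as attribute `"seeds"`.
#' @export
build_network <- function(atlas, seeds = NULL, pcc_min = 0.95, alpha = 0.05,
                          all_pairs = FALSE, log_transform = FALSE,
                          adjust = FALSE) {
  stopifnot(is.matrix(atlas), !is.null(rownames(atlas)))
  if (ncol(atlas) < 3L) stop("need at least 3 atlas samples", call. = FALSE)
  if (log_transform) atlas <- log2(atlas + 1)
  genes <- rownames(atlas)
  if (all_pairs) seeds <- genes
  seeds <- intersect(unique(seeds), genes)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      pcc = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(seeds) == 0L) {
    warning("empty seed set: returning an empty network")
    attr(empty, "seeds") <- character(0)
    return(empty)
  }
  r <- suppressWarnings(cor(t(atlas[seeds, , drop = FALSE]), t(atlas)))
  p <- cor_p_matrix(r, ncol(atlas))
  keep <- is.finite(r) & abs(r) >= pcc_min & p <= alpha
  idx <- which(keep, arr.ind = TRUE)
  a <- seeds[idx[, 1]]
  b <- genes[idx[, 2]]
  sel <- a != b
  a <- a[sel]; b <- b[sel]
  pcc <- r[keep][sel]; pv <- p[keep][sel]
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- data.frame(gene_a = lo, gene_b = hi, pcc = pcc, p_value = pv,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), , drop = FALSE]
  if (adjust && nrow(edges)) {
    edges$p_value <- benjamini_hochberg(edges$p_value)
    edges <- edges[edges$p_value <= alpha, , drop = FALSE]
  }
  edges <- reset_rownames(order_by(edges, c("gene_a", "gene_b")))
  attr(edges, "seeds") <- seeds
  edges
}

#' Seed degrees in a co-expression network
#'
#' Number of retained partners per seed gene, listing isolated seeds with
#' degree 0.
#'
#' @param edges edge data frame from [build_network()].
#' @param seeds seed gene ids; defaults to the attribute stored on `edges`.
#' @return named integer vector.
#' @export
seed_degrees <- function(edges, seeds = attr(edges, "seeds")) {
  if (is.null(seeds)) stop("no seed set available", call. = FALSE)
  touching <- c(edges$gene_a, edges$gene_b)
  vapply(setNames(seeds, seeds),
         function(s) sum(touching == s), integer(1))
}

#' Assign SSP rank labels
#'
#' Rank 1: SSP genes belonging to ortholog groups that are both
#' AMS-preferential and convergent-DE. Rank 2: SSP genes in the union of
#' AMS-specific, AMS-preferential and convergent-DE groups, minus rank 1.
#' All other genes get `none`.
#'
#' @param calls consensus calls.
#' @param classification output of [classify_groups()].
#' @param convergence output of [detect_convergence()].
#' @param orthogroups long membership data frame.
#' @return data frame `gene_id`, `species_id`, `rank`
#'   (`rank1`/`rank2`/`none`) with one row per SSP gene.
#' @export
assign_ranks <- function(calls, classification, convergence, orthogroups) {
  pref <- classification$group_id[classification$ams_preferential %in% TRUE]
  spec <- classification$group_id[classification$ams_specific %in% TRUE]
  conv <- unique(convergence$group_id)
  rank1_groups <- intersect(pref, conv)
  union_groups <- unique(c(spec, pref, conv))

  ssp <- calls[calls$is_ssp, c("protein_id", "species_id")]
  key_og <- paste(orthogroups$species_id, orthogroups$gene_id)
  in_groups <- function(gids) {
    keys <- key_og[orthogroups$group_id %in% gids]
    paste(ssp$species_id, ssp$protein_id) %in% keys
  }
  r1 <- in_groups(rank1_groups)
  r2 <- in_groups(union_groups) & !r1
  out <- data.frame(gene_id = ssp$protein_id, species_id = ssp$species_id,
                    rank = ifelse(r1, "rank1", ifelse(r2, "rank2", "none")),
                    stringsAsFactors = FALSE)
  reset_rownames(order_by(out, c("species_id", "gene_id")))
}

#' Functional category counts of subnetwork partners
#'
#' For every seed gene, tallies the functional categories of its network
#' partners using an imported annotation table; unannotated partners count as
#' `"unknown"`.
#'
#' @param edges edge data frame from [build_network()].
#' @param annotation data frame with columns `gene_id`, `category` (may be
#'   empty).
#' @param seeds seed gene ids; defaults to the attribute stored on `edges`.
#' @return data frame `seed`, `category`, `n`.
#' @export
annotate_functions <- function(edges, annotation, seeds = attr(edges, "seeds")) {
  if (is.null(seeds)) stop("no seed set available", call. = FALSE)
  cat_map <- if (nrow(annotation)) setNames(annotation$category, annotation$gene_id)
             else setNames(character(0), character(0))
  rows <- list()
  for (s in seeds) {
    partners <- c(edges$gene_b[edges$gene_a == s], edges$gene_a[edges$gene_b == s])
    if (length(partners) == 0L) next
    cats <- unname(cat_map[partners])
    cats[is.na(cats)] <- "unknown"
    tab <- table(cats)
    rows[[s]] <- data.frame(seed = s, category = names(tab),
                            n = as.integer(tab), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = character(0), category = character(0), n = integer(0))
  reset_rownames(order_by(out, c("seed", "category")))
}

#' Export edges as a Cytoscape SIF file
#'
#' One line per edge: `gene_a <tab> pcc <tab> gene_b`.
#'
#' @param edges edge data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- sprintf("%s\tpcc\t%s", edges$gene_a, edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a network edge table
#'
#' @param edges edge data frame.
#' @param path TSV path.
#' @return `path` (writer) or the edge data frame (reader).
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = NULL,
                    colClasses = c("character", "character", "numeric", "numeric"))
  need <- c("gene_a", "gene_b", "pcc", "p_value")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort_format(sprintf("missing column '%s' in %s", missing[1], path))
  reset_rownames(raw[, need])
}
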