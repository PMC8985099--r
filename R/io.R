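# Plain-text readers and writers. All writers emit a deterministic column and
# row order (sorted by id); all readers are strict and never coerce silently.

PREDICTION_COLS <- c("protein_id", "species_id", "length_aa", "complete_orf",
                     "nss_signalp", "nss_phobius", "nss_targetp",
                     "tm_tmhmm", "tm_memsat", "tm_phobius",
                     "loc_apoplastp", "loc_deeploc", "loc_msubp")
BOOL_COLS <- PREDICTION_COLS[4:13]

parse_strict_bool <- function(x, column) {
  s <- trimws(as.character(x))
  bad <- !(s %in% c("0", "1"))
  if (any(bad))
    abort_format(sprintf("column '%s' must be 0/1; offending value '%s'",
                         column, s[bad][1]))
  s == "1"
}

check_no_nan <- function(x, column) {
  if (any(!is.finite(x)))
    abort_format(sprintf("column '%s' contains non-finite values", column))
  x
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             check.names = FALSE, na.strings = NULL)
}

#' Read a unified prediction table
#'
#' The unified TSV is the contract between external secretion predictors and
#' the consensus caller: one row per protein with its length, completeness and
#' nine 0/1 tool votes (three NSS tools, three TM tools, three localization
#' tools). Booleans must be encoded strictly as `0`/`1`.
#'
#' @param path TSV file with columns `protein_id`, `species_id`, `length_aa`,
#'   `complete_orf`, `nss_signalp`, `nss_phobius`, `nss_targetp`, `tm_tmhmm`,
#'   `tm_memsat`, `tm_phobius`, `loc_apoplastp`, `loc_deeploc`, `loc_msubp`.
#' @return a prediction data frame with logical vote columns.
#' @export
read_predictions <- function(path) {
  raw <- read_tsv(path)
  missing <- setdiff(PREDICTION_COLS, names(raw))
  if (length(missing))
    abort_format(sprintf("missing column '%s' in %s", missing[1], path))
  out <- data.frame(protein_id = raw$protein_id, species_id = raw$species_id,
                    stringsAsFactors = FALSE)
  len <- suppressWarnings(as.numeric(raw$length_aa))
  if (nrow(raw) > 0 && (any(is.na(len)) || any(len < 1) || any(len != floor(len))))
    abort_format("column 'length_aa' must hold positive integers")
  out$length_aa <- as.integer(len)
  for (cl in BOOL_COLS) out[[cl]] <- parse_strict_bool(raw[[cl]], cl)
  key <- paste(out$species_id, out$protein_id)
  if (anyDuplicated(key))
    abort_format(sprintf("duplicate (species_id, protein_id): %s",
                         key[duplicated(key)][1]))
  reset_rownames(out[, PREDICTION_COLS])
}

#' Write a unified prediction table
#'
#' @param predictions prediction data frame (see [read_predictions()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(PREDICTION_COLS %in% names(predictions)))
  out <- predictions[, PREDICTION_COLS]
  for (cl in BOOL_COLS) out[[cl]] <- as.integer(out[[cl]])
  out <- order_by(out, c("species_id", "protein_id"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' Expects the OrthoFinder dialect: a header row whose first column names the
#' group-id column and whose remaining columns are species; each cell holds a
#' comma(-space)-separated gene list, with empty cells meaning no members in
#' that species.
#'
#' @param path Orthogroups.tsv path.
#' @param species optional species table ([read_species_table()]); when given,
#'   every species column must be a known `species_id`.
#' @return a long data frame with columns `group_id`, `species_id`, `gene_id`.
#' @export
read_orthogroups <- function(path, species = NULL) {
  raw <- read_tsv(path)
  if (ncol(raw) < 2L)
    abort_format("Orthogroups.tsv needs a group-id column plus species columns")
  sp_cols <- names(raw)[-1]
  if (!is.null(species)) {
    unknown <- setdiff(sp_cols, species$species_id)
    if (length(unknown))
      abort_format(sprintf("unknown species column '%s' in %s", unknown[1], path))
  }
  gid <- trimws(raw[[1]])
  if (any(gid == ""))
    abort_format("empty group id in Orthogroups.tsv")
  rows <- list()
  for (sp in sp_cols) {
    cell <- raw[[sp]]
    has <- !is.na(cell) & trimws(cell) != ""
    if (!any(has)) next
    genes <- strsplit(cell[has], ",[ ]*")
    rows[[sp]] <- data.frame(
      group_id = rep(gid[has], lengths(genes)),
      species_id = sp,
      gene_id = trimws(unlist(genes, use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), species_id = character(0),
               gene_id = character(0))
  reset_rownames(order_by(out, c("group_id", "species_id", "gene_id")))
}

#' Write an OrthoFinder-style Orthogroups.tsv
#'
#' @param orthogroups long membership data frame (`group_id`, `species_id`,
#'   `gene_id`).
#' @param path output path.
#' @param species_order column order for species; defaults to sorted ids
#'   present in the table.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path, species_order = NULL) {
  stopifnot(all(c("group_id", "species_id", "gene_id") %in% names(orthogroups)))
  sp <- species_order %||% sort(unique(orthogroups$species_id))
  gids <- sort(unique(orthogroups$group_id))
  og <- order_by(orthogroups, c("group_id", "species_id", "gene_id"))
  cells <- tapply(og$gene_id, list(factor(og$group_id, gids),
                                   factor(og$species_id, sp)),
                  paste, collapse = ", ")
  cells[is.na(cells)] <- ""
  wide <- data.frame(Orthogroup = gids, cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(wide) <- c("Orthogroup", sp)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the species metadata table
#'
#' Columns: `species_id`, `ams_status` (`AMS`/`non-AMS`), `lineage`
#' (`dicot`/`monocot`/`other`), `n_proteins_annotated`.
#'
#' @param path TSV path.
#' @return species data frame.
#' @export
read_species_table <- function(path) {
  raw <- read_tsv(path)
  need <- c("species_id", "ams_status", "lineage", "n_proteins_annotated")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort_format(sprintf("missing column '%s' in %s", missing[1], path))
  if (anyDuplicated(raw$species_id))
    abort_format("duplicate species_id in species table")
  bad <- !(raw$ams_status %in% c("AMS", "non-AMS"))
  if (any(bad))
    abort_format(sprintf("ams_status must be 'AMS' or 'non-AMS'; got '%s'",
                         raw$ams_status[bad][1]))
  n <- suppressWarnings(as.numeric(raw$n_proteins_annotated))
  if (nrow(raw) > 0 && (any(is.na(n)) || any(n < 0)))
    abort_format("n_proteins_annotated must be a non-negative count")
  out <- data.frame(species_id = raw$species_id, ams_status = raw$ams_status,
                    lineage = raw$lineage, n_proteins_annotated = as.integer(n),
                    stringsAsFactors = FALSE)
  reset_rownames(out)
}

#' @rdname read_species_table
#' @param species species data frame.
#' @export
write_species_table <- function(species, path) {
  out <- order_by(species[, c("species_id", "ams_status", "lineage",
                              "n_proteins_annotated")], "species_id")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a differential-expression table
#'
#' Columns: `gene_id`, `species_id`, `contrast_id`, `log2fc`, `padj`,
#' `direction` (`up`/`down`/`ns`). Non-finite values in the numeric fields are
#' rejected.
#'
#' @param path TSV path.
#' @return DE record data frame.
#' @export
read_de_table <- function(path) {
  raw <- read_tsv(path)
  need <- c("gene_id", "species_id", "contrast_id", "log2fc", "padj", "direction")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort_format(sprintf("missing column '%s' in %s", missing[1], path))
  out <- raw[, need]
  out$log2fc <- check_no_nan(suppressWarnings(as.numeric(raw$log2fc)), "log2fc")
  out$padj <- check_no_nan(suppressWarnings(as.numeric(raw$padj)), "padj")
  if (nrow(out) > 0 && any(!(out$direction %in% c("up", "down", "ns"))))
    abort_format("direction must be one of up/down/ns")
  reset_rownames(out)
}

#' @rdname read_de_table
#' @param de DE record data frame.
#' @export
write_de_table <- function(de, path) {
  cols <- c("gene_id", "species_id", "contrast_id", "log2fc", "padj", "direction")
  out <- order_by(de[, cols], c("species_id", "contrast_id", "gene_id"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression or count matrix
#'
#' TSV with a leading `gene_id` column followed by one column per sample.
#'
#' @param path TSV path.
#' @return numeric matrix with gene-id rownames.
#' @export
read_expression_matrix <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = NULL)
  if (names(raw)[1] != "gene_id")
    abort_format("first column of an expression matrix must be 'gene_id'")
  if (anyDuplicated(raw$gene_id))
    abort_format("duplicate gene_id in expression matrix")
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) > 0 && (!is.numeric(m) || any(!is.finite(m))))
    abort_format("expression matrix contains non-numeric or non-finite cells")
  rownames(m) <- raw$gene_id
  m
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix, genes in rows (rownames are gene ids).
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_protein_fasta
#' @param sequences named character vector of amino-acid sequences.
#' @export
write_protein_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences[order(names(sequences))])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write the planted ground truth as JSON
#'
#' @param path JSON path.
#' @return ground-truth list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_ground_truth
#' @param truth ground-truth list (see [simulate_dataset()]).
#' @export
write_ground_truth <- function(truth, path) {
  truth$status <- NULL  # per-protein latent status is bulky and re-derivable
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
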