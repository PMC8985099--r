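#' Thresholds of the consensus SSP caller
#'
#' The defaults encode the published pipeline: complete ORFs of 50-250 aa
#' (bounds inclusive), a majority decision of at least 2 of 3 signal-peptide
#' (NSS) tools, elimination of candidates with a transmembrane region
#' predicted by any single TM tool, and at least 2 of 3 extracellular
#' localization tools for the unconventional-secretion list. The TM veto
#' applies only to the NSS branch unless `tm_applies_to_extra` is set.
#'
#' @param min_len,max_len inclusive length gate in amino acids.
#' @param nss_min_votes,extra_min_votes minimum agreeing tools (1-3).
#' @param tm_exclusion drop NSS candidates with any TM vote?
#' @param tm_applies_to_extra also veto the extracellular list on any TM vote?
#' @return a list of class `caller_thresholds`.
#' @export
caller_thresholds <- function(min_len = 50L, max_len = 250L,
                              nss_min_votes = 2L, extra_min_votes = 2L,
                              tm_exclusion = TRUE, tm_applies_to_extra = FALSE) {
  check_count(min_len, "min_len")
  check_count(max_len, "max_len")
  if (min_len > max_len) abort_config("min_len", "must be <= max_len")
  for (v in c(nss_min_votes, extra_min_votes))
    if (!is.numeric(v) || v < 1 || v > 3 || v != floor(v))
      abort_config("vote threshold", "must be an integer in 1..3")
  structure(list(min_len = min_len, max_len = max_len,
                 nss_min_votes = as.integer(nss_min_votes),
                 extra_min_votes = as.integer(extra_min_votes),
                 tm_exclusion = isTRUE(tm_exclusion),
                 tm_applies_to_extra = isTRUE(tm_applies_to_extra)),
            class = "caller_thresholds")
}

#' Length/completeness gate
#'
#' A protein enters the small-protein subset iff its ORF is complete and its
#' length lies inside the closed interval \[`min_len`, `max_len`\].
#'
#' @param predictions prediction data frame (or any data frame with
#'   `length_aa` and `complete_orf`).
#' @param thresholds a [caller_thresholds()].
#' @return logical vector, one element per row.
#' @export
passes_length_gate <- function(predictions, thresholds = caller_thresholds()) {
  predictions$complete_orf &
    predictions$length_aa >= thresholds$min_len &
    predictions$length_aa <= thresholds$max_len
}

NSS_VOTE_COLS <- c("nss_signalp", "nss_phobius", "nss_targetp")
TM_VOTE_COLS <- c("tm_tmhmm", "tm_memsat", "tm_phobius")
LOC_VOTE_COLS <- c("loc_apoplastp", "loc_deeploc", "loc_msubp")

#' Majority-decision consensus SSP calls
#'
#' Applies the length/completeness gate, the 2-of-3 consensus on NSS and
#' extracellular votes, and the any-tool transmembrane veto, then assigns each
#' protein to one of the categories `NSS_ONLY`, `EXTRA_ONLY`,
#' `NSS_AND_EXTRA` or `NOT_SSP`. Membership of the two published lists is:
#' list 1 (conventional secretion) = gate & NSS consensus & no TM vote;
#' list 2 (extracellular) = gate & extracellular consensus. A protein is an
#' SSP iff it is on either list.
#'
#' @param predictions prediction data frame (see [read_predictions()]).
#' @param thresholds a [caller_thresholds()].
#' @return data frame with one row per protein: `protein_id`, `species_id`,
#'   `is_ssp`, `category`, `nss_consensus`, `tm_any`, `extra_consensus`,
#'   `length_gate`.
#' @export
call_ssp <- function(predictions, thresholds = caller_thresholds()) {
  nss_sum <- rowSums(predictions[, NSS_VOTE_COLS, drop = FALSE])
  tm_any <- rowSums(predictions[, TM_VOTE_COLS, drop = FALSE]) > 0
  loc_sum <- rowSums(predictions[, LOC_VOTE_COLS, drop = FALSE])
  gate <- passes_length_gate(predictions, thresholds)

  nss_consensus <- nss_sum >= thresholds$nss_min_votes
  extra_consensus <- loc_sum >= thresholds$extra_min_votes
  tm_veto <- if (thresholds$tm_exclusion) tm_any else rep(FALSE, length(tm_any))

  list1 <- gate & nss_consensus & !tm_veto
  list2 <- gate & extra_consensus &
    !(thresholds$tm_applies_to_extra & tm_veto)

  category <- rep("NOT_SSP", nrow(predictions))
  category[list1 & !list2] <- "NSS_ONLY"
  category[!list1 & list2] <- "EXTRA_ONLY"
  category[list1 & list2] <- "NSS_AND_EXTRA"

  data.frame(
    protein_id = predictions$protein_id,
    species_id = predictions$species_id,
    is_ssp = list1 | list2,
    category = category,
    nss_consensus = nss_consensus,
    tm_any = tm_any,
    extra_consensus = extra_consensus,
    length_gate = gate,
    stringsAsFactors = FALSE
  )
}

#' Arithmetic of the three-set SSP partition
#'
#' Given the sizes of the two published lists and of their intersection,
#' derives the remaining partition counts and checks the identities
#' `union = list1 + list2 - intersection`, `nss_only = list1 - intersection`,
#' `extra_only = list2 - intersection`.
#'
#' @param n_list1 size of the NSS list (conventional secretion).
#' @param n_list2 size of the extracellular list.
#' @param n_both size of their intersection.
#' @return a list of class `ssp_partition` with elements `list1`, `list2`,
#'   `intersection`, `union`, `nss_only`, `extra_only`, `nss_and_extra`.
#' @export
ssp_partition <- function(n_list1, n_list2, n_both) {
  check_count(n_list1, "n_list1", min = 0L)
  check_count(n_list2, "n_list2", min = 0L)
  check_count(n_both, "n_both", min = 0L)
  if (n_both > min(n_list1, n_list2))
    abort_config("n_both", "cannot exceed either list size")
  out <- list(
    list1 = n_list1, list2 = n_list2, intersection = n_both,
    union = n_list1 + n_list2 - n_both,
    nss_only = n_list1 - n_both,
    extra_only = n_list2 - n_both,
    nss_and_extra = n_both
  )
  stopifnot(out$union == out$nss_only + out$extra_only + out$nss_and_extra)
  structure(out, class = "ssp_partition")
}

#' Partition report from consensus calls
#'
#' Counts list and category sizes of a call table and verifies the partition
#' identities against the category tally.
#'
#' @param calls output of [call_ssp()].
#' @return an `ssp_partition` (see [ssp_partition()]).
#' @export
partition_counts <- function(calls) {
  n1 <- sum(calls$category %in% c("NSS_ONLY", "NSS_AND_EXTRA"))
  n2 <- sum(calls$category %in% c("EXTRA_ONLY", "NSS_AND_EXTRA"))
  nb <- sum(calls$category == "NSS_AND_EXTRA")
  out <- ssp_partition(n1, n2, nb)
  stopifnot(out$union == sum(calls$is_ssp),
            out$nss_only == sum(calls$category == "NSS_ONLY"),
            out$extra_only == sum(calls$category == "EXTRA_ONLY"))
  out
}

#' Write a consensus call table
#'
#' @param calls output of [call_ssp()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- order_by(calls, c("species_id", "protein_id"))
  for (cl in c("is_ssp", "nss_consensus", "tm_any", "extra_consensus", "length_gate"))
    out[[cl]] <- as.integer(out[[cl]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consensus call table written by [write_calls()]
#'
#' @param path TSV path.
#' @return call data frame.
#' @export
read_calls <- function(path) {
  raw <- read_tsv(path)
  need <- c("protein_id", "species_id", "is_ssp", "category",
            "nss_consensus", "tm_any", "extra_consensus", "length_gate")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort_format(sprintf("missing column '%s' in %s", missing[1], path))
  out <- raw[, need]
  for (cl in c("is_ssp", "nss_consensus", "tm_any", "extra_consensus", "length_gate"))
    out[[cl]] <- parse_strict_bool(raw[[cl]], cl)
  reset_rownames(out)
}
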