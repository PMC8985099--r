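# End-to-end pipeline driver: simulate (optional) -> call -> classify-groups
# -> de -> converge -> coexpress -> ranks, plus a machine-readable run report.

#' Pipeline run configuration
#'
#' Collects every threshold applied by the pipeline next to the input source
#' (a simulation configuration, or paths to externally produced files) and the
#' output directory.
#'
#' @param out_dir directory for all artifacts (created if missing).
#' @param rng_seed integer seed; forwarded to the simulation configuration
#'   when `sim` is left at its default.
#' @param sim a [sim_config()] to generate the inputs, or `NULL` to read them
#'   from `inputs`.
#' @param inputs when `sim` is `NULL`: a list with paths `species`,
#'   `predictions`, `orthogroups`, optionally `de_tables` (character vector of
#'   DE TSVs), `atlas` (matrix TSV) and `annotation` (TSV with `gene_id`,
#'   `category`).
#' @param caller a [caller_thresholds()].
#' @param min_frac AMS-specificity span threshold (default 0.30).
#' @param alpha significance level for group classification (default 0.05).
#' @param de_alpha adjusted-p threshold for differential expression (default
#'   0.05).
#' @param min_abs_log2fc DE fold-change threshold (default 1, strict).
#' @param min_species convergence species threshold (default 2).
#' @param pcc_min,pcc_alpha co-expression thresholds (defaults 0.95 and 0.05).
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir, rng_seed = 1L, sim = sim_config(rng_seed = rng_seed),
                       inputs = NULL, caller = caller_thresholds(),
                       min_frac = 0.30, alpha = 0.05, de_alpha = 0.05,
                       min_abs_log2fc = 1, min_species = 2L,
                       pcc_min = 0.95, pcc_alpha = 0.05) {
  check_fraction(min_frac, "min_frac")
  check_fraction(alpha, "alpha")
  check_fraction(de_alpha, "de_alpha")
  check_fraction(pcc_alpha, "pcc_alpha")
  check_count(min_species, "min_species")
  if (!is.numeric(min_abs_log2fc) || min_abs_log2fc < 0)
    abort_config("min_abs_log2fc", "must be a non-negative real")
  if (!is.numeric(pcc_min) || pcc_min < 0)
    abort_config("pcc_min", "must be a non-negative real")
  if (is.null(sim) && is.null(inputs))
    abort_config("inputs", "must be given when no simulation is configured")
  structure(list(out_dir = out_dir, rng_seed = rng_seed, sim = sim,
                 inputs = inputs, caller = caller, min_frac = min_frac,
                 alpha = alpha, de_alpha = de_alpha,
                 min_abs_log2fc = min_abs_log2fc,
                 min_species = as.integer(min_species),
                 pcc_min = pcc_min, pcc_alpha = pcc_alpha),
            class = "run_config")
}

precision_recall <- function(found, planted) {
  found <- unique(found); planted <- unique(planted)
  tp <- length(intersect(found, planted))
  list(n_found = length(found), n_planted = length(planted), true_positives = tp,
       precision = if (length(found)) tp / length(found) else 1,
       recall = if (length(planted)) tp / length(planted) else 1)
}

#' Run the whole pipeline
#'
#' Executes every stage in order and writes all artifacts plus a JSON run
#' report into `cfg$out_dir`. With a simulation configured the report also
#' scores recovery of every planted structure against the ground truth. The
#' run is deterministic: the same configuration (seed included) rewrites
#' byte-identical artifacts.
#'
#' @param cfg a [run_config()].
#' @return the run report (a list), invisibly; written as `report.json`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  annotation <- data.frame(gene_id = character(0), category = character(0))
  if (!is.null(cfg$sim)) {
    sim <- stage("simulate", simulate_dataset(cfg$sim))
    indir <- file.path(cfg$out_dir, "inputs")
    stage("simulate", write_simulation(sim, indir))
    species <- sim$species; predictions <- sim$predictions
    orthogroups <- sim$orthogroups; counts <- sim$counts
    atlas <- sim$atlas; atlas_species <- sim$atlas_species
    truth <- sim$truth
    de_tables <- NULL
  } else {
    species <- stage("read", read_species_table(cfg$inputs$species))
    predictions <- stage("read", read_predictions(cfg$inputs$predictions))
    orthogroups <- stage("read", read_orthogroups(cfg$inputs$orthogroups, species))
    counts <- NULL
    de_tables <- cfg$inputs$de_tables
    atlas <- if (!is.null(cfg$inputs$atlas))
      stage("read", read_expression_matrix(cfg$inputs$atlas)) else NULL
    atlas_species <- cfg$inputs$atlas_species %||% NA_character_
    if (!is.null(cfg$inputs$annotation))
      annotation <- stage("read", read_tsv(cfg$inputs$annotation))
  }

  calls <- stage("call", call_ssp(predictions, cfg$caller))
  write_calls(calls, file.path(cfg$out_dir, "calls.tsv"))
  partition <- partition_counts(calls)

  classification <- stage("classify-groups",
    classify_groups(orthogroups, calls, species,
                    min_frac = cfg$min_frac, alpha = cfg$alpha))
  write.table(classification, file.path(cfg$out_dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  genome <- stage("classify-groups", genome_level_tests(calls, species))

  de_all <- if (!is.null(counts)) {
    stage("de", do.call(rbind, lapply(counts, function(ct) {
      de <- simple_de(ct$counts, ct$condition, alpha = cfg$de_alpha,
                      min_abs_log2fc = cfg$min_abs_log2fc,
                      species_id = ct$species_id, contrast_id = ct$contrast_id)
      write_de_table(de, file.path(cfg$out_dir, sprintf("de_%s.tsv", ct$contrast_id)))
      de
    })))
  } else if (!is.null(de_tables)) {
    stage("de", do.call(rbind, lapply(de_tables, read_de_table)))
  } else NULL

  convergence <- NULL
  de_ssp <- NULL
  if (!is.null(de_all)) {
    de_ssp <- de_ssp_intersect(de_all, calls)
    convergence <- stage("converge",
      detect_convergence(de_ssp, orthogroups, min_species = cfg$min_species))
    write.table(convergence, file.path(cfg$out_dir, "convergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  edges <- NULL
  ranks <- NULL
  if (!is.null(atlas)) {
    seeds <- calls$protein_id[calls$is_ssp & calls$species_id == atlas_species]
    seeds <- intersect(seeds, rownames(atlas))
    edges <- stage("coexpress", suppressWarnings(
      build_network(atlas, seeds, pcc_min = cfg$pcc_min, alpha = cfg$pcc_alpha)))
    write_edges(edges, file.path(cfg$out_dir, "edges.tsv"))
    write_sif(edges, file.path(cfg$out_dir, "edges.sif"))
    ranks <- stage("ranks", assign_ranks(calls, classification,
                                         convergence %||% data.frame(group_id = character(0), direction = character(0)),
                                         orthogroups))
    write.table(ranks, file.path(cfg$out_dir, "ranks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- build_report(cfg, species, calls, partition, classification, genome,
                         de_all, de_ssp, convergence, edges, ranks, truth)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}

count_by <- function(values, levels) {
  tab <- table(factor(values, levels = levels))
  as.list(setNames(as.integer(tab), levels))
}

build_report <- function(cfg, species, calls, partition, classification, genome,
                         de_all, de_ssp, convergence, edges, ranks, truth) {
  # partition identities are re-checked here so every written report is
  # internally consistent
  stopifnot(partition$union == partition$nss_only + partition$extra_only +
              partition$nss_and_extra,
            partition$union == partition$list1 + partition$list2 -
              partition$intersection)
  src_counts <- count_by(classification$ssp_source,
                         c("AMS_ONLY", "NONAMS_ONLY", "BOTH", "NO_SSP"))
  n_ssp_groups <- src_counts$AMS_ONLY + src_counts$NONAMS_ONLY + src_counts$BOTH
  stopifnot(n_ssp_groups + src_counts$NO_SSP == nrow(classification))

  report <- list(
    package_version = as.character(packageVersion("sspAMS")),
    rng_seed = cfg$rng_seed,
    thresholds = list(
      caller = unclass(cfg$caller), min_frac = cfg$min_frac, alpha = cfg$alpha,
      de_alpha = cfg$de_alpha, min_abs_log2fc = cfg$min_abs_log2fc,
      min_species = cfg$min_species, pcc_min = cfg$pcc_min,
      pcc_alpha = cfg$pcc_alpha),
    species = list(
      n_species = nrow(species),
      n_ams = sum(species$ams_status == "AMS"),
      n_nonams = sum(species$ams_status == "non-AMS")),
    ssp_partition = unclass(partition),
    groups = c(list(n_groups = nrow(classification),
                    n_ssp_groups = n_ssp_groups),
               src_counts,
               list(n_ams_specific = sum(classification$ams_specific),
                    n_ams_preferential = sum(classification$ams_preferential))),
    genome_tests = genome
  )
  if (!is.null(de_all)) {
    per_contrast <- lapply(split(de_all, de_all$contrast_id), function(d) {
      ds <- de_ssp[de_ssp$contrast_id == d$contrast_id[1], , drop = FALSE]
      list(species_id = d$species_id[1],
           n_deg = sum(d$direction != "ns"),
           n_de_ssp = sum(ds$direction != "ns"))
    })
    report$expression <- list(
      contrasts = per_contrast,
      convergent_up = sum(convergence$direction == "up"),
      convergent_down = sum(convergence$direction == "down"))
  }
  if (!is.null(edges)) {
    report$coexpression <- list(
      n_seeds = length(attr(edges, "seeds")),
      n_edges = nrow(edges),
      n_connected_seeds = sum(seed_degrees(edges) > 0),
      ranks = count_by(ranks$rank, c("rank1", "rank2", "none")))
  }
  if (!is.null(truth)) {
    spec_pr <- precision_recall(
      classification$group_id[classification$ams_specific],
      truth$planted_specific_groups)
    pref_pr <- precision_recall(
      classification$group_id[classification$ams_preferential],
      truth$planted_preferential_groups)
    conv_up_pr <- precision_recall(
      convergence$group_id[convergence$direction == "up"],
      unique(truth$planted_convergent$group_id[truth$planted_convergent$direction == "up"]))
    conv_down_pr <- precision_recall(
      convergence$group_id[convergence$direction == "down"],
      unique(truth$planted_convergent$group_id[truth$planted_convergent$direction == "down"]))
    module_pairs <- unlist(lapply(seq_along(truth$planted_modules), function(i) {
      memb <- truth$planted_modules[[i]]
      seed <- truth$module_seeds[i]
      partners <- setdiff(memb, seed)
      paste(pmin(seed, partners), pmax(seed, partners))
    }))
    edge_keys <- paste(edges$gene_a, edges$gene_b)
    report$recovery <- list(
      ams_specific = spec_pr,
      ams_preferential = pref_pr,
      convergent_up = conv_up_pr,
      convergent_down = conv_down_pr,
      module_edge_recall = if (length(module_pairs))
        mean(module_pairs %in% edge_keys) else 1)
  }
  report
}

#' Read a pipeline run configuration from JSON
#'
#' The JSON mirrors [run_config()]: top-level scalar fields plus optional
#' objects `sim` (arguments of [sim_config()]), `caller` (arguments of
#' [caller_thresholds()]) and `inputs`.
#'
#' @param path JSON path.
#' @param out_dir,rng_seed overrides applied after reading (optional).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, rng_seed = NULL) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(out_dir)) js$out_dir <- out_dir
  if (!is.null(rng_seed)) js$rng_seed <- rng_seed
  if (is.null(js$out_dir)) abort_config("out_dir", "is required")
  sim <- if (!is.null(js$sim)) {
    args <- js$sim
    if (is.null(args$rng_seed) && !is.null(js$rng_seed)) args$rng_seed <- js$rng_seed
    do.call(sim_config, args)
  } else NULL
  caller <- if (!is.null(js$caller)) do.call(caller_thresholds, js$caller)
            else caller_thresholds()
  args <- js[setdiff(names(js), c("sim", "caller"))]
  args$sim <- sim
  args$caller <- caller
  do.call(run_config, args)
}
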