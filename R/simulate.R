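#' Configuration of the synthetic AMS/SSP world
#'
#' Builds a validated configuration for [simulate_dataset()] and the
#' stage-level generators. The defaults describe a reduced-scale version of a
#' 60-genome comparative study: about two thirds of the species form
#' arbuscular mycorrhizal symbiosis (AMS), roughly one protein in ten is truly
#' secreted (half conventionally via an N-terminal signal sequence, half
#' unconventionally), prediction tools are imperfect binary classifiers, and a
#' handful of ortholog groups, differential-expression signals and
#' co-expression modules are planted with known ground truth.
#'
#' @param n_species number of plant species.
#' @param frac_ams fraction of species able to form AMS; `round(n_species *
#'   frac_ams)` species are flagged AMS.
#' @param proteins_per_species integer range (length-2 vector) of proteome
#'   sizes; each species draws uniformly from it.
#' @param frac_true_ssp fraction of proteins that are truly secreted (split
#'   evenly between signal-peptide and unconventional routes).
#' @param frac_membrane fraction of proteins that are membrane proteins.
#' @param frac_incomplete fraction of protein models lacking a complete ORF.
#' @param tool_sensitivity,tool_specificity per-tool-class error model, either
#'   a single fraction or a named vector with elements `nss`, `tm`, `loc`.
#'   Each tool's positive call is Bernoulli: probability `sensitivity` when
#'   the protein's latent status is relevant to the tool class, `1 -
#'   specificity` otherwise.
#' @param length_meanlog,length_sdlog log-normal protein-length parameters;
#'   lengths are truncated to \[20, 600\] aa so the 50-250 aa gate is
#'   exercised on both sides.
#' @param n_orthogroups total number of ortholog groups (planted plus
#'   background).
#' @param n_planted_specific number of planted AMS-specific groups (SSP
#'   members in at least `ceiling(0.3 * n_AMS)` AMS species, no non-AMS
#'   member).
#' @param n_planted_preferential number of planted AMS-preferential groups
#'   (SSPs from both classes, AMS species carrying more).
#' @param preferential_effect extra SSP members per AMS species in planted
#'   preferential groups (each AMS species contributes `1 +
#'   round(preferential_effect)` SSPs, each non-AMS species one).
#' @param n_planted_up_groups,n_planted_down_groups planted convergent-DE
#'   groups per direction: each receives one true-SSP gene from every
#'   RNA-Seq AMS species plus non-SSP anchors in two non-AMS species.
#' @param n_preferential_convergent how many planted preferential groups are
#'   additionally convergently up-regulated (one SSP member per RNA-Seq
#'   species receives planted DE), mirroring the observation that some
#'   AMS-preferential groups respond convergently to the fungus.
#' @param n_de_species number of AMS species with an AMF-vs-control RNA-Seq
#'   contrast; one non-AMS control species is always added when available.
#' @param n_replicates replicates per condition in each contrast.
#' @param de_log2fc planted log2 fold change (0 plants nothing).
#' @param n_background_de non-SSP background differentially expressed genes
#'   per contrast.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (`size = 1/nb_dispersion`).
#' @param n_atlas_samples samples in the expression atlas.
#' @param planted_module_size genes per planted co-expression module.
#' @param n_planted_modules number of planted modules; each is seeded on one
#'   true-SSP gene of the atlas species.
#' @param module_pcc expected pairwise Pearson correlation within a planted
#'   module (genes share a latent factor with loading `sqrt(module_pcc)`).
#' @param frac_grouped fraction of non-planted genes assigned to an ortholog
#'   group (the remainder stay ungrouped, as in real orthogroup inference).
#' @param rng_seed integer seed; every stage derives its stream from it by a
#'   fixed offset, so identical configurations give identical data.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_species = 60L,
                       frac_ams = 0.65,
                       proteins_per_species = c(600L, 800L),
                       frac_true_ssp = 0.12,
                       frac_membrane = 0.10,
                       frac_incomplete = 0.05,
                       tool_sensitivity = c(nss = 0.90, tm = 0.90, loc = 0.90),
                       tool_specificity = c(nss = 0.95, tm = 0.95, loc = 0.95),
                       length_meanlog = log(140),
                       length_sdlog = 0.7,
                       n_orthogroups = 1500L,
                       n_planted_specific = 3L,
                       n_planted_preferential = 3L,
                       preferential_effect = 5,
                       n_planted_up_groups = 3L,
                       n_planted_down_groups = 3L,
                       n_preferential_convergent = 2L,
                       n_de_species = 4L,
                       n_replicates = 5L,
                       de_log2fc = 3,
                       n_background_de = 30L,
                       nb_dispersion = 0.1,
                       n_atlas_samples = 20L,
                       planted_module_size = 5L,
                       n_planted_modules = 2L,
                       module_pcc = 0.995,
                       frac_grouped = 0.92,
                       rng_seed = 42L) {
  expand_tool <- function(x, field) {
    if (length(x) == 1L && is.null(names(x))) x <- c(nss = x, tm = x, loc = x)
    if (!all(c("nss", "tm", "loc") %in% names(x)))
      abort_config(field, "must be a single value or named with 'nss', 'tm', 'loc'")
    check_fraction(x, field)
    x[c("nss", "tm", "loc")]
  }
  cfg <- list(
    n_species = check_count(n_species, "n_species"),
    frac_ams = check_fraction(frac_ams, "frac_ams"),
    proteins_per_species = check_count(proteins_per_species, "proteins_per_species"),
    frac_true_ssp = check_fraction(frac_true_ssp, "frac_true_ssp"),
    frac_membrane = check_fraction(frac_membrane, "frac_membrane"),
    frac_incomplete = check_fraction(frac_incomplete, "frac_incomplete"),
    tool_sensitivity = expand_tool(tool_sensitivity, "tool_sensitivity"),
    tool_specificity = expand_tool(tool_specificity, "tool_specificity"),
    length_meanlog = length_meanlog,
    length_sdlog = check_positive(length_sdlog, "length_sdlog"),
    n_orthogroups = check_count(n_orthogroups, "n_orthogroups"),
    n_planted_specific = check_count(n_planted_specific, "n_planted_specific", min = 0L),
    n_planted_preferential = check_count(n_planted_preferential, "n_planted_preferential", min = 0L),
    preferential_effect = preferential_effect,
    n_planted_up_groups = check_count(n_planted_up_groups, "n_planted_up_groups", min = 0L),
    n_planted_down_groups = check_count(n_planted_down_groups, "n_planted_down_groups", min = 0L),
    n_preferential_convergent = check_count(n_preferential_convergent,
                                            "n_preferential_convergent", min = 0L),
    n_de_species = check_count(n_de_species, "n_de_species", min = 0L),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    de_log2fc = de_log2fc,
    n_background_de = check_count(n_background_de, "n_background_de", min = 0L),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    n_atlas_samples = check_count(n_atlas_samples, "n_atlas_samples"),
    planted_module_size = check_count(planted_module_size, "planted_module_size", min = 2L),
    n_planted_modules = check_count(n_planted_modules, "n_planted_modules", min = 0L),
    module_pcc = check_fraction(module_pcc, "module_pcc"),
    frac_grouped = check_fraction(frac_grouped, "frac_grouped"),
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L)
  )
  if (length(cfg$proteins_per_species) != 2L ||
      cfg$proteins_per_species[1] > cfg$proteins_per_species[2])
    abort_config("proteins_per_species", "must be an increasing length-2 range")
  if (!is.numeric(cfg$preferential_effect) || cfg$preferential_effect < 0)
    abort_config("preferential_effect", "must be a non-negative real")
  if (!is.numeric(cfg$de_log2fc) || is.na(cfg$de_log2fc))
    abort_config("de_log2fc", "must be a real number")
  n_planted <- cfg$n_planted_specific + cfg$n_planted_preferential +
    cfg$n_planted_up_groups + cfg$n_planted_down_groups
  if (n_planted > cfg$n_orthogroups)
    abort_config("n_orthogroups", "must be at least the number of planted groups")
  if (cfg$n_preferential_convergent > cfg$n_planted_preferential)
    abort_config("n_preferential_convergent", "cannot exceed n_planted_preferential")
  if ((cfg$n_planted_up_groups + cfg$n_planted_down_groups +
       cfg$n_preferential_convergent) > 0L && cfg$n_de_species < 1L)
    abort_config("n_de_species", "must be >= 1 when convergent-DE structure is planted")
  class(cfg) <- "sim_config"
  cfg
}

seed_stage <- function(cfg, offset) set.seed(cfg$rng_seed + offset)

#' Simulate the species table
#'
#' `round(n_species * frac_ams)` species are flagged AMS; lineages are drawn
#' among dicot/monocot/other with probabilities 33:15:12 (the composition of
#' the emulated 60-genome panel). Proteome sizes are drawn uniformly from
#' `proteins_per_species`.
#'
#' @param cfg a [sim_config()].
#' @return a species data frame with columns `species_id`, `ams_status`
#'   (`"AMS"`/`"non-AMS"`), `lineage`, `n_proteins_annotated`.
#' @export
simulate_species <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_stage(cfg, 1L)
  n <- cfg$n_species
  n_ams <- round(n * cfg$frac_ams)
  status <- rep("non-AMS", n)
  status[sample.int(n, n_ams)] <- "AMS"
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    ams_status = status,
    lineage = sample(c("dicot", "monocot", "other"), n, replace = TRUE,
                     prob = c(33, 15, 12) / 60),
    n_proteins_annotated = sample(seq(cfg$proteins_per_species[1],
                                      cfg$proteins_per_species[2]),
                                  n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate per-tool secretion predictions
#'
#' Each protein draws a latent status (`nss` = conventionally secreted,
#' `unconv` = unconventionally secreted, `membrane`, `other`), a length from a
#' log-normal truncated to \[20, 600\] aa, and a completeness flag. The nine
#' tool votes (three signal-peptide, three transmembrane, three localization
#' tools) are independent Bernoulli draws: a tool fires with probability
#' `sensitivity` when the status is relevant to its class (`nss` for the NSS
#' tools, `membrane` for the TM tools, either secreted status for the
#' localization tools) and `1 - specificity` otherwise. The ground-truth SSP
#' set is every secreted, complete protein of 50-250 aa.
#'
#' @param cfg a [sim_config()].
#' @param species species table from [simulate_species()].
#' @return list with `predictions` (unified prediction data frame),
#'   `sequences` (named character vector of synthetic amino-acid sequences,
#'   start-M when complete) and `truth` (list with `true_ssp` data frame and
#'   `status` per protein).
#' @export
simulate_predictions <- function(cfg, species) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(species) == 0L) stop("species table is empty", call. = FALSE)
  seed_stage(cfg, 2L)

  per_species <- lapply(seq_len(nrow(species)), function(i) {
    sp <- species$species_id[i]
    n <- species$n_proteins_annotated[i]
    f <- cfg$frac_true_ssp
    probs <- c(nss = f / 2, unconv = f / 2, membrane = cfg$frac_membrane)
    probs <- c(probs, other = max(0, 1 - sum(probs)))
    status <- sample(names(probs), n, replace = TRUE, prob = probs)
    # truncated log-normal lengths via inverse-CDF sampling
    lo <- plnorm(20, cfg$length_meanlog, cfg$length_sdlog)
    hi <- plnorm(600, cfg$length_meanlog, cfg$length_sdlog)
    len <- round(qlnorm(runif(n, lo, hi), cfg$length_meanlog, cfg$length_sdlog))
    complete <- runif(n) > cfg$frac_incomplete
    vote <- function(relevant, class) {
      p <- ifelse(relevant, cfg$tool_sensitivity[[class]],
                  1 - cfg$tool_specificity[[class]])
      runif(n) < p
    }
    nss_rel <- status == "nss"
    tm_rel <- status == "membrane"
    loc_rel <- status %in% c("nss", "unconv")
    data.frame(
      protein_id = sprintf("%s_g%04d", sp, seq_len(n)),
      species_id = sp,
      length_aa = as.integer(pmax(len, 20)),
      complete_orf = complete,
      nss_signalp = vote(nss_rel, "nss"),
      nss_phobius = vote(nss_rel, "nss"),
      nss_targetp = vote(nss_rel, "nss"),
      tm_tmhmm = vote(tm_rel, "tm"),
      tm_memsat = vote(tm_rel, "tm"),
      tm_phobius = vote(tm_rel, "tm"),
      loc_apoplastp = vote(loc_rel, "loc"),
      loc_deeploc = vote(loc_rel, "loc"),
      loc_msubp = vote(loc_rel, "loc"),
      .status = status,
      stringsAsFactors = FALSE
    )
  })
  pred <- do.call(rbind, per_species)
  status <- pred$.status
  pred$.status <- NULL

  secreted <- status %in% c("nss", "unconv")
  is_true_ssp <- secreted & pred$complete_orf &
    pred$length_aa >= 50 & pred$length_aa <= 250

  # synthetic sequences: complete models start with M; no realism intended
  letters_pool <- sample(AA20, sum(pred$length_aa), replace = TRUE)
  seqs <- vapply(
    split(letters_pool, rep.int(seq_len(nrow(pred)), pred$length_aa)),
    paste0, character(1), collapse = ""
  )
  seqs <- ifelse(pred$complete_orf, paste0("M", substring(seqs, 2)), seqs)
  names(seqs) <- pred$protein_id

  truth <- list(
    true_ssp = reset_rownames(pred[is_true_ssp, c("protein_id", "species_id")]),
    status = setNames(status, pred$protein_id)
  )
  list(predictions = reset_rownames(pred), sequences = seqs, truth = truth)
}

# draw `k` unused gene ids for species `sp` from pool environment
take_genes <- function(pool, sp, k, what) {
  avail <- pool$genes[[sp]]
  if (length(avail) < k)
    stop(sprintf("infeasible planting: species %s has only %d unused %s genes (%d needed)",
                 sp, length(avail), what, k), call. = FALSE)
  picked <- avail[seq_len(k)]
  pool$genes[[sp]] <- avail[-seq_len(k)]
  picked
}

#' Simulate ortholog groups with planted AMS structure
#'
#' Plants `n_planted_specific` AMS-specific groups (one true-SSP gene from
#' each of at least `ceiling(0.3 * n_AMS)` AMS species, no non-AMS member),
#' `n_planted_preferential` AMS-preferential groups (every species
#' contributes true-SSP genes; AMS species contribute `1 +
#' round(preferential_effect)` each, non-AMS species one each) and the
#' convergent-DE groups used later by [simulate_counts()] (one true-SSP gene
#' per RNA-Seq species plus non-SSP anchors in two non-AMS species, so the
#' groups are neither AMS-specific nor AMS-preferential). Remaining genes are
#' assigned uniformly to background groups with probability `frac_grouped`.
#'
#' @param cfg a [sim_config()].
#' @param species,predictions upstream artifacts.
#' @param truth truth list from [simulate_predictions()].
#' @return list with `orthogroups` (long data frame `group_id`, `species_id`,
#'   `gene_id`) and the updated `truth` (`planted_specific_groups`,
#'   `planted_preferential_groups`, `planted_convergent` data frame).
#' @export
simulate_orthogroups <- function(cfg, species, predictions, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_stage(cfg, 3L)
  ams <- species$species_id[species$ams_status == "AMS"]
  nonams <- species$species_id[species$ams_status == "non-AMS"]
  n_ams <- length(ams)
  n_up <- cfg$n_planted_up_groups
  n_down <- cfg$n_planted_down_groups
  n_planted <- cfg$n_planted_specific + cfg$n_planted_preferential + n_up + n_down
  if (n_planted > 0L && n_ams == 0L)
    abort_config("frac_ams", "gives zero AMS species; planting AMS structure is infeasible")
  if (cfg$n_planted_preferential > 0L && length(nonams) == 0L)
    abort_config("frac_ams", "gives zero non-AMS species; preferential groups need both classes")
  if ((n_up + n_down) > 0L && cfg$n_de_species > n_ams)
    abort_config("n_de_species", "exceeds the number of AMS species")

  true_ssp_ids <- truth$true_ssp$protein_id
  is_ssp <- predictions$protein_id %in% true_ssp_ids
  pool <- new.env(parent = emptyenv())
  pool$genes <- split(predictions$protein_id[is_ssp], predictions$species_id[is_ssp])
  pool$genes <- lapply(pool$genes, sample)  # randomize draw order
  nonssp_pool <- new.env(parent = emptyenv())
  nonssp_pool$genes <- split(predictions$protein_id[!is_ssp],
                             predictions$species_id[!is_ssp])
  nonssp_pool$genes <- lapply(nonssp_pool$genes, sample)

  ids <- sample(sprintf("OG%07d", seq_len(cfg$n_orthogroups)))
  next_id <- local({ i <- 0L; function() { i <<- i + 1L; ids[i] } })
  members <- list()
  add_group <- function(gid, sp_ids, gene_ids) {
    members[[length(members) + 1L]] <<- data.frame(
      group_id = gid, species_id = sp_ids, gene_id = gene_ids,
      stringsAsFactors = FALSE)
  }

  min_span <- ceiling(0.3 * n_ams)
  planted_specific <- character(0)
  for (k in seq_len(cfg$n_planted_specific)) {
    span <- if (min_span >= n_ams) n_ams else sample(seq(min_span, n_ams), 1L)
    chosen <- sample(ams, span)
    genes <- vapply(chosen, function(sp) take_genes(pool, sp, 1L, "true-SSP"),
                    character(1))
    gid <- next_id()
    add_group(gid, chosen, unname(genes))
    planted_specific <- c(planted_specific, gid)
  }

  de_species <- head(ams, cfg$n_de_species)
  k_ams <- 1L + round(cfg$preferential_effect)
  planted_pref <- character(0)
  conv <- list()
  for (k in seq_len(cfg$n_planted_preferential)) {
    gid <- next_id()
    pref_genes <- list()
    for (sp in ams) {
      genes <- take_genes(pool, sp, k_ams, "true-SSP")
      add_group(gid, rep(sp, k_ams), genes)
      pref_genes[[sp]] <- genes
    }
    for (sp in nonams) add_group(gid, sp, take_genes(pool, sp, 1L, "true-SSP"))
    planted_pref <- c(planted_pref, gid)
    # some preferential groups also respond convergently to the fungus:
    # one of their SSP members per RNA-Seq species gets planted (up) DE
    if (k <= cfg$n_preferential_convergent && length(de_species))
      conv[[length(conv) + 1L]] <- data.frame(
        group_id = gid, direction = "up", species_id = de_species,
        gene_id = vapply(pref_genes[de_species], `[`, character(1), 1L),
        stringsAsFactors = FALSE)
  }
  for (dir in c(rep("up", n_up), rep("down", n_down))) {
    gid <- next_id()
    genes <- vapply(de_species, function(sp) take_genes(pool, sp, 1L, "true-SSP"),
                    character(1))
    add_group(gid, de_species, unname(genes))
    conv[[length(conv) + 1L]] <- data.frame(
      group_id = gid, direction = dir, species_id = de_species,
      gene_id = unname(genes), stringsAsFactors = FALSE)
    # non-SSP anchors in non-AMS species keep the group out of the
    # AMS-specific class without making it testably "both"-sourced
    anchors <- head(nonams, 2L)
    for (sp in anchors) add_group(gid, sp, take_genes(nonssp_pool, sp, 1L, "non-SSP"))
  }
  planted_convergent <- if (length(conv)) do.call(rbind, conv) else
    data.frame(group_id = character(0), direction = character(0),
               species_id = character(0), gene_id = character(0))

  # background: unused genes assigned uniformly over the remaining group ids
  used <- unlist(lapply(members, `[[`, "gene_id"), use.names = FALSE)
  rest <- predictions[!(predictions$protein_id %in% used), ]
  bg_ids <- ids[seq(n_planted + 1L, cfg$n_orthogroups)]
  if (length(bg_ids) > 0L && nrow(rest) > 0L) {
    keep <- runif(nrow(rest)) < cfg$frac_grouped
    rest <- rest[keep, ]
    if (nrow(rest) > 0L)
      add_group(sample(bg_ids, nrow(rest), replace = TRUE),
                rest$species_id, rest$protein_id)
  }

  og <- do.call(rbind, members)
  og <- reset_rownames(order_by(og, c("group_id", "species_id", "gene_id")))
  truth$planted_specific_groups <- sort(planted_specific)
  truth$planted_preferential_groups <- sort(planted_pref)
  truth$planted_convergent <- planted_convergent
  list(orthogroups = og, truth = truth)
}

#' Simulate AMF-vs-control count matrices with planted DE
#'
#' One contrast per RNA-Seq AMS species (the first `n_de_species` AMS species)
#' plus one non-AMS control species when available. Counts are negative
#' binomial with gene-level baseline means drawn log-normally and dispersion
#' `nb_dispersion`. Planted differentially expressed genes get treatment mean
#' `mu * 2^(+-de_log2fc)`: the convergent-group SSP genes planted by
#' [simulate_orthogroups()] (direction per group) plus `n_background_de`
#' non-SSP genes per contrast (including the control contrast, mirroring a
#' non-host species with DEGs but no DE SSPs). With `de_log2fc = 0` nothing
#' is planted.
#'
#' @param cfg a [sim_config()].
#' @param species,predictions,orthogroups,truth upstream artifacts.
#' @return list with `counts` (named list of contrasts, each holding
#'   `species_id`, `contrast_id`, `counts` matrix genes x samples and
#'   `condition` label vector) and the updated `truth` (`planted_de` data
#'   frame).
#' @export
simulate_counts <- function(cfg, species, predictions, orthogroups, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_stage(cfg, 4L)
  ams <- species$species_id[species$ams_status == "AMS"]
  nonams <- species$species_id[species$ams_status == "non-AMS"]
  if (cfg$n_de_species > length(ams))
    abort_config("n_de_species", "exceeds the number of AMS species")
  de_species <- head(ams, cfg$n_de_species)
  contrast_species <- c(de_species, head(nonams, 1L))

  plant <- !identical(cfg$de_log2fc, 0) && cfg$de_log2fc != 0
  conv <- truth$planted_convergent
  true_ssp_ids <- truth$true_ssp$protein_id

  planted_rows <- list()
  counts <- list()
  for (sp in contrast_species) {
    genes <- predictions$protein_id[predictions$species_id == sp]
    contrast_id <- paste0(sp, "_AMF_vs_control")
    n_rep <- cfg$n_replicates
    mu <- pmax(rlnorm(length(genes), meanlog = log(200), sdlog = 1), 1)
    lfc <- setNames(rep(0, length(genes)), genes)

    if (plant) {
      if (sp %in% de_species && nrow(conv) > 0L) {
        rows <- conv[conv$species_id == sp, ]
        lfc[rows$gene_id] <- ifelse(rows$direction == "up", 1, -1) * cfg$de_log2fc
      }
      candidates <- setdiff(genes[!(genes %in% true_ssp_ids)], names(lfc)[lfc != 0])
      n_bg <- min(cfg$n_background_de, length(candidates))
      bg <- sample(candidates, n_bg)
      sign_bg <- rep_len(c(1, -1), n_bg)
      lfc[bg] <- sign_bg * cfg$de_log2fc
      planted <- names(lfc)[lfc != 0]
      if (length(planted))
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          contrast_id = contrast_id, species_id = sp, gene_id = planted,
          direction = ifelse(lfc[planted] > 0, "up", "down"),
          is_ssp = planted %in% true_ssp_ids, stringsAsFactors = FALSE)
    }

    size <- 1 / cfg$nb_dispersion
    ctl <- matrix(rnbinom(length(genes) * n_rep, mu = mu, size = size),
                  nrow = length(genes))
    trt <- matrix(rnbinom(length(genes) * n_rep, mu = mu * 2^lfc, size = size),
                  nrow = length(genes))
    m <- cbind(ctl, trt)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("control_%d", seq_len(n_rep)),
                     sprintf("treatment_%d", seq_len(n_rep)))
    counts[[contrast_id]] <- list(
      species_id = sp, contrast_id = contrast_id, counts = m,
      condition = rep(c("control", "treatment"), each = n_rep))
  }
  truth$planted_de <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(contrast_id = character(0), species_id = character(0),
               gene_id = character(0), direction = character(0),
               is_ssp = logical(0))
  truth$planted_de <- reset_rownames(truth$planted_de)
  list(counts = counts, truth = truth)
}

#' Simulate an expression atlas with planted co-expression modules
#'
#' The atlas covers every gene of the first AMS species. Module genes share a
#' latent factor: `x = sqrt(module_pcc) * f + sqrt(1 - module_pcc) * noise`,
#' giving expected pairwise Pearson correlation `module_pcc`; background genes
#' are independent standard normal. Each module is seeded on one true-SSP
#' gene.
#'
#' @param cfg a [sim_config()].
#' @param species,predictions,truth upstream artifacts.
#' @return list with `atlas` (genes x samples matrix), `atlas_species` and the
#'   updated `truth` (`planted_modules` list of gene-id vectors,
#'   `module_seeds`).
#' @export
simulate_atlas <- function(cfg, species, predictions, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_atlas_samples < 3L)
    abort_config("n_atlas_samples", "must be >= 3 (correlation p-value undefined below)")
  seed_stage(cfg, 5L)
  ams <- species$species_id[species$ams_status == "AMS"]
  atlas_sp <- if (length(ams)) ams[1] else species$species_id[1]
  genes <- predictions$protein_id[predictions$species_id == atlas_sp]
  n_s <- cfg$n_atlas_samples
  x <- matrix(rnorm(length(genes) * n_s), nrow = length(genes),
              dimnames = list(genes, sprintf("sample_%02d", seq_len(n_s))))

  ssp_genes <- intersect(genes, truth$true_ssp$protein_id)
  modules <- list()
  seeds <- character(0)
  used <- character(0)
  for (k in seq_len(cfg$n_planted_modules)) {
    seed_pool <- setdiff(ssp_genes, used)
    if (length(seed_pool) == 0L)
      abort_config("n_planted_modules", "exceeds available true-SSP genes in the atlas species")
    seed <- sample(seed_pool, 1L)
    partner_pool <- setdiff(genes, c(used, seed))
    if (length(partner_pool) < cfg$planted_module_size - 1L)
      abort_config("planted_module_size", "exceeds available atlas genes")
    memb <- c(seed, sample(partner_pool, cfg$planted_module_size - 1L))
    f <- rnorm(n_s)
    rho <- cfg$module_pcc
    x[memb, ] <- matrix(rep(sqrt(rho) * f, each = length(memb)),
                        nrow = length(memb)) +
      sqrt(1 - rho) * matrix(rnorm(length(memb) * n_s), nrow = length(memb))
    modules[[k]] <- memb
    seeds <- c(seeds, seed)
    used <- c(used, memb)
  }
  truth$planted_modules <- modules
  truth$module_seeds <- seeds
  list(atlas = x, atlas_species = atlas_sp, truth = truth)
}

#' Simulate the full synthetic dataset
#'
#' Runs every stage generator in order under sub-streams derived from
#' `cfg$rng_seed` by fixed offsets, so the same configuration always yields
#' identical data and each stage is individually reproducible.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `ssp_sim` with elements `config`, `species`,
#'   `predictions`, `sequences`, `orthogroups`, `counts`, `atlas`,
#'   `atlas_species` and `truth` (the planted ground truth).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  species <- simulate_species(cfg)
  p <- simulate_predictions(cfg, species)
  o <- simulate_orthogroups(cfg, species, p$predictions, p$truth)
  ct <- simulate_counts(cfg, species, p$predictions, o$orthogroups, o$truth)
  at <- simulate_atlas(cfg, species, p$predictions, ct$truth)
  structure(list(
    config = cfg, species = species, predictions = p$predictions,
    sequences = p$sequences, orthogroups = o$orthogroups, counts = ct$counts,
    atlas = at$atlas, atlas_species = at$atlas_species, truth = at$truth
  ), class = "ssp_sim")
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits one protein FASTA per species, the unified prediction TSV, an
#' OrthoFinder-dialect `Orthogroups.tsv`, the species metadata TSV, one counts
#' and one design TSV per contrast, the atlas TSV and the ground truth as
#' JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ssp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_species_table(sim$species, file.path(dir, "species.tsv"))
  write_predictions(sim$predictions, file.path(dir, "predictions.tsv"))
  write_orthogroups(sim$orthogroups, file.path(dir, "Orthogroups.tsv"),
                    species_order = sim$species$species_id)
  for (sp in sim$species$species_id) {
    ids <- sim$predictions$protein_id[sim$predictions$species_id == sp]
    write_protein_fasta(sim$sequences[ids],
                        file.path(dir, sprintf("proteins_%s.faa", sp)))
  }
  for (ct in sim$counts) {
    write_expression_matrix(ct$counts,
                            file.path(dir, sprintf("counts_%s.tsv", ct$contrast_id)))
    design <- data.frame(sample = colnames(ct$counts), condition = ct$condition)
    write.table(design, file.path(dir, sprintf("design_%s.tsv", ct$contrast_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_expression_matrix(sim$atlas, file.path(dir, "atlas.tsv"))
  write_ground_truth(sim$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
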