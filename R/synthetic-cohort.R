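#' Configuration for a synthetic paired plaque cohort
#'
#' Defines the generative model for paired plaque / non-plaque log2
#' intensity matrices with planted differential abundance, temporal
#' trajectories, correlated protein blocks, an age-tracking amyloid
#' tracer, contaminant rows and logistic left-censored (MNAR)
#' missingness. The defaults are the study conditions used throughout the
#' package's validation.
#'
#' @param n_proteins Number of protein rows (including contaminants and
#'   the tracer).
#' @param n_pairs_per_age Plaque/non-plaque pairs simulated at each age.
#' @param ages Age labels in months; the first is the baseline age.
#' @param baseline_mean,baseline_sd Mean and SD (log2) of per-protein
#'   baseline abundances.
#' @param noise_sd Residual log2 SD of a single measurement.
#' @param effect_size Planted plaque-minus-control log2 fold change of
#'   differentially abundant proteins (DAPs) at full effect.
#' @param frac_dap Fraction of proteins planted as DAPs.
#' @param frac_late,frac_decline Fractions of the planted DAPs following
#'   the late-accumulation and decline trajectories; the remainder are
#'   early/constant. `frac_late + frac_decline` must be at most 1.
#' @param frac_contaminant Fraction of proteins given contaminant-style
#'   identifiers (`CON_KRT...`, `CON_TRYP...`).
#' @param missing_midpoint Log2 intensity at which detection probability
#'   is 0.5 (detection limit of the instrument).
#' @param missing_slope Logistic steepness of detection per log2 unit;
#'   0 disables intensity-dependent missingness.
#' @param n_blocks,block_size,block_rho Correlated protein blocks: count,
#'   proteins per block, and within-block pairwise correlation in `[0,1)`.
#' @param pair_offset_sd SD of the capture-level offset shared by the two
#'   members of a pair (batch effect giving the paired design its power);
#'   defaults to half of `baseline_sd`.
#' @param tracer_id Identifier of the amyloid tracer protein, whose
#'   plaque signal strictly increases with age.
#' @param model Model label written into the sample metadata.
#' @param seed Integer seed; the single source of randomness.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_proteins = 2000L,
                          n_pairs_per_age = 20L,
                          ages = c(3L, 8L, 14L),
                          baseline_mean = 20,
                          baseline_sd = 2,
                          noise_sd = 0.5,
                          effect_size = 2,
                          frac_dap = 0.05,
                          frac_late = 0.13,
                          frac_decline = 0.05,
                          frac_contaminant = 0.02,
                          missing_midpoint = 16,
                          missing_slope = 1,
                          n_blocks = 5L,
                          block_size = 20L,
                          block_rho = 0.8,
                          pair_offset_sd = baseline_sd / 2,
                          tracer_id = "ABETA_TRACER",
                          model = "5xFAD",
                          seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_pairs_per_age = as.integer(n_pairs_per_age),
              ages = as.integer(ages),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, effect_size = effect_size,
              frac_dap = frac_dap, frac_late = frac_late,
              frac_decline = frac_decline,
              frac_contaminant = frac_contaminant,
              missing_midpoint = missing_midpoint,
              missing_slope = missing_slope,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size), block_rho = block_rho,
              pair_offset_sd = pair_offset_sd,
              tracer_id = tracer_id, model = model, seed = as.integer(seed))
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num) & !is.infinite(num) | is.na(num)))
    stop("non-finite configuration value")
  if (cfg$frac_dap + cfg$frac_contaminant > 1)
    stop("frac_dap + frac_contaminant must be <= 1")
  if (cfg$frac_late + cfg$frac_decline > 1)
    stop("frac_late + frac_decline must be <= 1")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0,1)")
  if (cfg$missing_slope < 0) stop("missing_slope must be >= 0")
  if (cfg$n_blocks * cfg$block_size > cfg$n_proteins)
    stop("n_blocks * block_size exceeds n_proteins")
  class(cfg) <- "cohort_config"
  cfg
}

# temporal effect multipliers by class and age index (1 = baseline)
.temporal_multiplier <- function(class, age_frac) {
  # age_frac in [0,1]: 0 at baseline age, 1 at oldest
  switch(class,
         early_constant = rep(1, length(age_frac)),
         late = c(0, 0.1, 1)[seq_along(age_frac)] ,
         decline = c(1, 0.4, -0.1)[seq_along(age_frac)],
         null = rep(0, length(age_frac)))
}

#' Generate a paired plaque cohort with planted ground truth
#'
#' Simulates `2 * n_pairs_per_age * length(ages)` samples. For each pair,
#' the plaque and non-plaque members share a capture-level offset.
#' Planted DAPs are elevated in plaque samples by `effect_size` modulated
#' by temporal class (early/constant: full effect at all ages; late:
#' none at baseline, full at the oldest age; decline: positive at
#' baseline, at or below zero at the oldest age). Block members share a
#' latent per-sample factor giving pairwise correlation `block_rho`. The
#' tracer's plaque enrichment grows strictly with age. Each latent value
#' is observed with probability
#' `plogis((value - missing_midpoint) * missing_slope)`.
#'
#' @param config A [cohort_config()].
#' @return List with elements `matrix` (an [IntensityMatrix]) and
#'   `truth` (a `planted_truth` list: `dap_table` with per-age true
#'   log2FCs, `temporal_class`, `block_assignment`, `tracer_profile`,
#'   `contaminant_ids`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)  # single RNG stream for every draw below

  P <- cfg$n_proteins
  ages <- cfg$ages
  A <- length(ages)
  npair <- cfg$n_pairs_per_age

  width <- max(4L, nchar(as.character(P)))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(P))

  n_con <- round(cfg$frac_contaminant * P)
  n_dap <- round(cfg$frac_dap * P)

  # layout: [contaminants][daps][blocks][null...]; tracer replaces the last row
  idx <- seq_len(P)
  con_idx <- head(idx, n_con)
  dap_idx <- idx[seq_len(n_dap) + n_con]
  blk_start <- n_con + n_dap
  blk_idx <- lapply(seq_len(cfg$n_blocks), function(b)
    blk_start + (b - 1L) * cfg$block_size + seq_len(cfg$block_size))
  if (length(blk_idx) && max(unlist(blk_idx)) > P - 1L)
    stop("contaminants + DAPs + blocks exceed n_proteins - 1 (tracer row)")
  tracer_idx <- P

  if (n_con) {
    stem <- rep(c("CON_KRT", "CON_TRYP"), length.out = n_con)
    ids[con_idx] <- sprintf("%s%03d", stem, seq_len(n_con))
  }
  ids[tracer_idx] <- cfg$tracer_id

  # temporal classes for planted DAPs
  n_late <- round(cfg$frac_late * n_dap)
  n_dec <- round(cfg$frac_decline * n_dap)
  classes <- rep("early_constant", n_dap)
  if (n_dap) {
    extra <- sample(seq_len(n_dap))
    classes[extra[seq_len(n_late)]] <- "late"
    if (n_dec) classes[extra[n_late + seq_len(n_dec)]] <- "decline"
  }

  # samples
  md <- do.call(rbind, lapply(seq_along(ages), function(ai) {
    a <- ages[ai]
    data.frame(
      sample_id = c(sprintf("S_%s_%02dM_p%02d_plaque", cfg$model, a, seq_len(npair)),
                    sprintf("S_%s_%02dM_p%02d_ctrl", cfg$model, a, seq_len(npair))),
      model = cfg$model, age_months = a,
      region = rep(c("plaque", "nonplaque"), each = npair),
      pair_id = rep(sprintf("pair_%s_%02dM_%02d", cfg$model, a, seq_len(npair)), 2L),
      replicate = rep(seq_len(npair), 2L),
      stringsAsFactors = FALSE)
  }))
  S <- nrow(md)
  is_plaque <- md$region == "plaque"
  age_of <- md$age_months
  age_rank <- match(age_of, ages)

  mu <- stats::rnorm(P, cfg$baseline_mean, cfg$baseline_sd)

  # capture-level pair offsets, shared within pair
  pair_levels <- unique(md$pair_id)
  off <- stats::rnorm(length(pair_levels), 0, cfg$pair_offset_sd)
  sample_off <- off[match(md$pair_id, pair_levels)]

  # block latent factors: one per block per sample
  fac <- if (cfg$n_blocks) matrix(stats::rnorm(cfg$n_blocks * S), cfg$n_blocks, S)
         else matrix(0, 0, S)

  eps <- matrix(stats::rnorm(P * S, 0, cfg$noise_sd), P, S)
  lat <- matrix(mu, P, S) + matrix(sample_off, P, S, byrow = TRUE) + eps

  # block correlation: replace residual with shared + idiosyncratic parts
  for (b in seq_len(cfg$n_blocks)) {
    rows <- blk_idx[[b]]
    shared <- sqrt(cfg$block_rho) * cfg$noise_sd *
      matrix(fac[b, ], length(rows), S, byrow = TRUE)
    lat[rows, ] <- matrix(mu[rows], length(rows), S) +
      matrix(sample_off, length(rows), S, byrow = TRUE) +
      shared + sqrt(1 - cfg$block_rho) * eps[rows, ]
  }

  # planted DAP effects in plaque samples, per temporal class
  age_frac <- if (A > 1) (seq_len(A) - 1) / (A - 1) else 0
  true_fc <- matrix(0, n_dap, A,
                    dimnames = list(ids[dap_idx], paste0("age_", ages)))
  for (j in seq_len(n_dap)) {
    mult <- .temporal_multiplier(classes[j], age_frac)
    true_fc[j, ] <- cfg$effect_size * mult
    lat[dap_idx[j], is_plaque] <- lat[dap_idx[j], is_plaque] +
      true_fc[j, age_rank[is_plaque]]
  }

  # tracer: plaque enrichment strictly increasing with age
  tracer_boost <- cfg$effect_size * (1 + seq(0, 1, length.out = A))
  lat[tracer_idx, is_plaque] <- lat[tracer_idx, is_plaque] +
    tracer_boost[age_rank[is_plaque]]

  # MNAR logistic left-censoring on latent intensity
  if (cfg$missing_slope > 0 && is.finite(cfg$missing_midpoint)) {
    p_det <- stats::plogis((lat - cfg$missing_midpoint) * cfg$missing_slope)
    obs <- matrix(stats::runif(P * S) < p_det, P, S)
  } else {
    obs <- matrix(TRUE, P, S)
  }
  vals <- lat
  vals[!obs] <- NA_real_
  dimnames(vals) <- list(ids, md$sample_id)

  tracer_profile <- cfg$baseline_mean + tracer_boost
  names(tracer_profile) <- paste0("age_", ages)

  blocks <- rep(NA_integer_, P)
  for (b in seq_len(cfg$n_blocks)) blocks[blk_idx[[b]]] <- b
  names(blocks) <- ids

  temporal <- rep("null", P)
  temporal[dap_idx] <- classes
  names(temporal) <- ids

  truth <- structure(list(
    dap_ids = ids[dap_idx],
    dap_table = data.frame(protein_id = ids[dap_idx],
                           temporal_class = classes, true_fc,
                           row.names = NULL, check.names = FALSE),
    temporal_class = temporal,
    block_assignment = blocks,
    tracer_profile = tracer_profile,
    contaminant_ids = ids[con_idx]), class = "planted_truth")

  list(matrix = IntensityMatrix(vals, md), truth = truth)
}

#' Generate independent study rankings sharing a planted core
#'
#' Fixtures for consensus ranking: each study ranks the protein universe
#' with a planted core of consistently top-ranked proteins. Core ranks
#' are perturbed by Gaussian noise on the score scale; non-core scores
#' are uniform over the universe. Each core protein is independently
#' dropped from a study with probability `p_absent`, exercising the
#' missing-dataset policy downstream.
#'
#' @param n_studies Number of studies (at least 1).
#' @param n_proteins Universe size.
#' @param n_core Number of planted core proteins (positive, at most
#'   `n_proteins`).
#' @param noise_sd Rank-scale noise SD applied to core scores; 0 makes
#'   every core protein outrank every non-core protein.
#' @param p_absent Probability a core protein is missing from a study.
#' @param seed Integer seed.
#' @return List with `rankings` (list of data frames
#'   `protein_id, rank` with `dataset_id`/`universe_size` attributes) and
#'   `core_ids`.
#' @export
generate_rank_studies <- function(n_studies, n_proteins, n_core,
                                  noise_sd = 0, p_absent = 0.1, seed = 1L) {
  if (n_core <= 0) stop("n_core must be positive")
  if (n_core > n_proteins) stop("n_core exceeds n_proteins")
  if (n_studies < 1) stop("need at least one study")
  set.seed(as.integer(seed))
  width <- max(4L, nchar(as.character(n_proteins)))
  ids <- sprintf(paste0("G%0", width, "d"), seq_len(n_proteins))
  core <- ids[seq_len(n_core)]
  rankings <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    present <- ids
    if (n_studies > 1) {
      drop <- core[stats::runif(n_core) < p_absent]
      present <- setdiff(ids, drop)
    }
    is_core <- present %in% core
    # scores: core far below non-core at noise 0; noise on the rank scale
    score <- numeric(length(present))
    score[is_core] <- match(present[is_core], core) - n_proteins
    score[!is_core] <- stats::runif(sum(!is_core)) * n_proteins
    score <- score + stats::rnorm(length(present), 0, noise_sd)
    ord <- order(score, present)
    df <- data.frame(protein_id = present[ord],
                     rank = seq_along(present), stringsAsFactors = FALSE)
    attr(df, "dataset_id") <- sprintf("study_%02d", s)
    attr(df, "universe_size") <- nrow(df)
    rankings[[s]] <- df
  }
  list(rankings = rankings, core_ids = core)
}

#' Write a cohort and its planted truth to plain-text files
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [cohort_config()] used, written as `key=value` lines.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "metadata.tsv", "truth.tsv",
                            "config.txt"))
  write_intensity_matrix(cohort$matrix, paths[1], paths[2])
  utils::write.table(cohort$truth$dap_table, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    flat <- vapply(config, function(x) paste(x, collapse = ","), character(1))
    writeLines(paste0(names(flat), "=", flat), paths[4])
  }
  invisible(paths)
}
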