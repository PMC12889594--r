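#' Baseline-normalized temporal profiles
#'
#' For each protein, the mean log2 plaque abundance is computed within
#' each age group and normalized by subtracting the baseline-age mean,
#' giving relative fold changes across ages (the baseline delta is
#' exactly zero). Proteins missing an entire age stratum are excluded
#' with a reason.
#'
#' @param m An [IntensityMatrix]; only plaque samples are used.
#' @param protein_ids Proteins to profile (typically the DAP set).
#' @param baseline_age Baseline age label (default: the smallest age
#'   present).
#' @return Data frame `protein_id, age, mean_abund, delta, excluded,
#'   reason` in long form; deltas at the baseline age are 0.
#' @export
baseline_normalize <- function(m, protein_ids = rownames(m$values),
                               baseline_age = NULL) {
  md <- m$metadata
  keep <- md$region == "plaque"
  v <- m$values[protein_ids, md$sample_id[keep], drop = FALSE]
  ages <- sort(unique(md$age_months[keep]))
  if (is.null(baseline_age)) baseline_age <- ages[1]
  if (!baseline_age %in% ages) stop("baseline age absent from data")
  age_of <- md$age_months[keep][match(colnames(v), md$sample_id[keep])]
  means <- sapply(ages, function(a)
    rowMeans(v[, age_of == a, drop = FALSE], na.rm = TRUE))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(protein_ids, NULL))
  colnames(means) <- as.character(ages)
  excluded <- apply(means, 1L, function(x) any(!is.finite(x)))
  delta <- means - means[, as.character(baseline_age)]
  out <- data.frame(
    protein_id = rep(protein_ids, times = length(ages)),
    age = rep(ages, each = length(protein_ids)),
    mean_abund = as.vector(means),
    delta = as.vector(delta),
    excluded = rep(excluded, times = length(ages)),
    reason = rep(ifelse(excluded, "missing age stratum", ""),
                 times = length(ages)),
    stringsAsFactors = FALSE)
  attr(out, "baseline_age") <- baseline_age
  attr(out, "ages") <- ages
  out
}

# long profile -> wide deltas (one row per protein, Delta per non-baseline age)
.profile_wide <- function(profile) {
  ages <- attr(profile, "ages")
  base <- attr(profile, "baseline_age")
  ids <- unique(profile$protein_id)
  wide <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (a in setdiff(ages, base))
    wide[[paste0("delta_", a, "m")]] <-
      profile$delta[profile$age == a][match(ids, profile$protein_id[profile$age == a])]
  wide$excluded <- profile$excluded[match(ids, profile$protein_id)]
  wide$reason <- profile$reason[match(ids, profile$protein_id)]
  wide
}

#' Exclude proteins with inconsistent fold-change directions
#'
#' Proteins whose deltas at the two post-baseline ages have opposite
#' signs are excluded, unless one of the deltas is within `tol` of zero
#' (noise-level sign flips are kept).
#'
#' @param profile Result of [baseline_normalize()] (3-age design).
#' @param tol Magnitude below which a delta does not count as a
#'   direction (default 0.1 log2 units).
#' @return Wide data frame `protein_id, delta_<mid>m, delta_<late>m,
#'   excluded, reason`.
#' @export
direction_filter <- function(profile, tol = 0.1) {
  wide <- .profile_wide(profile)
  dcols <- grep("^delta_", names(wide), value = TRUE)
  if (length(dcols) != 2)
    stop("direction filter expects a 3-age design (two post-baseline deltas)")
  d8 <- wide[[dcols[1]]]; d14 <- wide[[dcols[2]]]
  flip <- !wide$excluded & sign(d8) != sign(d14) &
    abs(d8) > tol & abs(d14) > tol
  wide$excluded <- wide$excluded | flip
  wide$reason[flip] <- "opposite fold-change directions"
  wide
}

#' Assign temporal clusters to non-excluded proteins
#'
#' Deterministic threshold rule on baseline-normalized deltas:
#' `decline` if the late delta is at most `-tau`; `late` if the late
#' delta is at least `tau` while the mid delta is below `tau`;
#' `early_constant` otherwise.
#'
#' @param wide Result of [direction_filter()].
#' @param tau Classification threshold in log2 units (default 0.5).
#' @return The input with a `cluster` column (`NA` for excluded rows).
#' @export
assign_clusters <- function(wide, tau = 0.5) {
  dcols <- grep("^delta_", names(wide), value = TRUE)
  d8 <- wide[[dcols[1]]]; d14 <- wide[[dcols[2]]]
  cl <- ifelse(d14 <= -tau, "decline",
               ifelse(d14 >= tau & d8 < tau, "late", "early_constant"))
  cl[wide$excluded] <- NA_character_
  wide$cluster <- cl
  wide
}

#' Temporal trajectory classification of DAPs
#'
#' Convenience wrapper: baseline normalization of plaque abundances,
#' direction-consistency filter, and threshold clustering into
#' early/constant, late-accumulation and decline classes.
#'
#' @param m An [IntensityMatrix] spanning the ages of one model.
#' @param dap_ids Proteins to classify (typically the union of DAPs).
#' @param tau Cluster threshold (default 0.5 log2 units).
#' @param tol Direction-filter tolerance (default 0.1).
#' @param baseline_age Baseline age (default: smallest present).
#' @return Wide data frame with deltas, exclusion flags and cluster
#'   labels.
#' @export
classify_trajectories <- function(m, dap_ids, tau = 0.5, tol = 0.1,
                                  baseline_age = NULL) {
  profile <- baseline_normalize(m, dap_ids, baseline_age)
  assign_clusters(direction_filter(profile, tol = tol), tau = tau)
}
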