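#' G-test of detection independence on a 2x2 table
#'
#' Likelihood-ratio (G) test comparing detection rates between two groups,
#' using the number of detected samples as a proxy for abundance when a
#' protein has missing values. `G = 2 * sum(O * ln(O/E))` over the 2x2
#' detected/missing table with expected counts from the marginals; cells
#' with zero observed count contribute zero. The p-value is the upper
#' chi-square tail with 1 df. A degenerate margin (all detected in both
#' groups, or all missing in both) gives `G = 0, p = 1`.
#'
#' All arguments are vectorized.
#'
#' @param k1,n1 Detected count and group size in group 1.
#' @param k2,n2 Detected count and group size in group 2.
#' @return Data frame with columns `G` and `p`.
#' @export
g_test <- function(k1, n1, k2, n2) {
  stopifnot(all(k1 >= 0 & k1 <= n1), all(k2 >= 0 & k2 <= n2),
            all(n1 >= 1), all(n2 >= 1))
  O <- cbind(k1, n1 - k1, k2, n2 - k2)
  n <- n1 + n2
  pk <- (k1 + k2) / n       # marginal detection rate
  E <- cbind(n1 * pk, n1 * (1 - pk), n2 * pk, n2 * (1 - pk))
  term <- O * log(O / E)
  term[O == 0] <- 0
  G <- 2 * rowSums(term)
  G <- pmax(G, 0)           # guard tiny negative round-off
  data.frame(G = G, p = stats::pchisq(G, df = 1L, lower.tail = FALSE))
}

#' Detection-equalizing minimum-value imputation
#'
#' Conditional imputation used when the G-test flags a detection imbalance
#' (`g_p < alpha`): in the group with fewer detections, missing cells are
#' imputed with that sample's observed minimum across all proteins (the
#' per-sample detection floor), in ascending sample-id order, until the
#' two groups' detection counts are equal or no missing cells remain. The
#' better-detected group is never modified, and nothing happens when the
#' gate is closed or detections are already equal.
#'
#' @param values1,values2 Named numeric vectors: the protein's values for
#'   the two groups' samples (names are sample ids; `NA` = missing).
#' @param floor1,floor2 Named numeric vectors of per-sample minima
#'   (observed minimum across all proteins in that sample), aligned with
#'   `values1`/`values2`.
#' @param g_p Detection G-test p-value for this protein.
#' @param alpha Gate threshold (default 0.05).
#' @return List with `values1`, `values2`, `imputed1`, `imputed2`
#'   (logical flags) and `imputed_count`.
#' @export
equalizing_impute <- function(values1, values2, floor1, floor2,
                              g_p, alpha = 0.05) {
  imp1 <- rep(FALSE, length(values1)); names(imp1) <- names(values1)
  imp2 <- rep(FALSE, length(values2)); names(imp2) <- names(values2)
  out <- list(values1 = values1, values2 = values2,
              imputed1 = imp1, imputed2 = imp2, imputed_count = 0L)
  if (is.na(g_p) || g_p >= alpha) return(out)
  d1 <- sum(!is.na(values1)); d2 <- sum(!is.na(values2))
  if (d1 == d2) return(out)
  if (d1 < d2) {
    deficit <- d2 - d1
    miss <- names(values1)[is.na(values1)]
    fill <- head(sort(miss), deficit)
    out$values1[fill] <- floor1[fill]
    out$imputed1[fill] <- TRUE
  } else {
    deficit <- d1 - d2
    miss <- names(values2)[is.na(values2)]
    fill <- head(sort(miss), deficit)
    out$values2[fill] <- floor2[fill]
    out$imputed2[fill] <- TRUE
  }
  out$imputed_count <- length(fill)
  out
}

# Inverse of trigamma by Newton iteration on 1/x (monotone, convex there).
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  out[is.finite(x) & x <= 0] <- Inf
  y <- 0.5 + 1 / x[pos]          # starting value
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[pos] <- y
  out
}

#' Empirical-Bayes fit of the variance prior
#'
#' Method-of-moments fit of a scaled F distribution to per-protein sample
#' variances on the log scale, yielding the prior variance `s2_0` and
#' prior degrees of freedom `d_0` used by [moderated_paired_ttest()].
#' With no excess dispersion in the observed log-variances the prior df
#' is infinite and every posterior variance equals `s2_0`.
#'
#' @param s2 Per-protein sample variances (non-negative).
#' @param df Residual degrees of freedom, scalar or per-protein.
#' @return List with `s2_0` and `d_0`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    return(list(s2_0 = if (any(ok)) mean(s2[ok]) else 1, d_0 = 0))
  z <- log(s2[ok]); d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s20 <- exp(emean)
  }
  list(s2_0 = s20, d_0 = d0)
}

#' Moderated paired t-test across proteins
#'
#' Paired t-test with empirical-Bayes variance moderation: each protein's
#' variance of paired log2 differences is shrunk toward a prior estimated
#' across all proteins, and the t statistic gains the prior degrees of
#' freedom. With `d_0 = 0` this is exactly the classical paired t-test;
#' as `d_0 -> Inf` the posterior variance tends to `s2_0`.
#'
#' @param diffs Matrix of paired log2 differences (proteins x pairs,
#'   `NA` for incomplete pairs) or a list of per-protein difference
#'   vectors.
#' @param min_pairs Minimum complete pairs to test a protein (default 3).
#' @param d_0,s2_0 Optional prior overrides; when `NULL` (default) the
#'   prior is estimated from the data via [fit_variance_prior()].
#' @return Data frame, one row per protein: `protein_id, n_pairs,
#'   mean_diff, s2_g, d_g, s2_0, d_0, t_mod, df_total, p, tested,
#'   reason`.
#' @export
moderated_paired_ttest <- function(diffs, min_pairs = 3L,
                                   d_0 = NULL, s2_0 = NULL) {
  if (is.list(diffs) && !is.data.frame(diffs)) {
    ids <- names(diffs)
    npair <- max(lengths(diffs))
    m <- matrix(NA_real_, length(diffs), npair)
    for (i in seq_along(diffs)) m[i, seq_along(diffs[[i]])] <- diffs[[i]]
    rownames(m) <- ids
    diffs <- m
  }
  stopifnot(is.matrix(diffs))
  ids <- rownames(diffs)
  if (is.null(ids)) ids <- paste0("protein_", seq_len(nrow(diffs)))

  n <- rowSums(!is.na(diffs))
  mean_diff <- rowMeans(diffs, na.rm = TRUE)
  s2 <- apply(diffs, 1L, stats::var, na.rm = TRUE)
  dg <- n - 1
  tested <- n >= min_pairs

  if (is.null(d_0) || is.null(s2_0)) {
    prior <- fit_variance_prior(s2[tested], dg[tested])
    if (!is.finite(prior$s2_0) || prior$s2_0 <= 0) {
      warning("degenerate variance prior; falling back to classical paired t")
      prior <- list(s2_0 = 0, d_0 = 0)
    }
    if (is.null(d_0)) d_0 <- prior$d_0
    if (is.null(s2_0)) s2_0 <- prior$s2_0
  }

  if (is.infinite(d_0)) {
    s2_post <- rep_len(s2_0, length(s2))
    df_total <- rep_len(Inf, length(s2))
  } else {
    s2_post <- (d_0 * s2_0 + dg * s2) / (d_0 + dg)
    df_total <- d_0 + dg
  }
  t_mod <- mean_diff / sqrt(s2_post / n)
  t_mod[s2_post == 0 & mean_diff == 0] <- 0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[!is.na(t_mod) & t_mod == 0] <- 1

  res <- data.frame(protein_id = ids, n_pairs = n, mean_diff = mean_diff,
                    s2_g = s2, d_g = dg, s2_0 = s2_0, d_0 = d_0,
                    t_mod = t_mod, df_total = df_total, p = p,
                    tested = tested,
                    reason = ifelse(tested, "",
                                    sprintf("fewer than %d complete pairs",
                                            min_pairs)),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$t_mod[!tested] <- NA_real_
  res$p[!tested] <- NA_real_
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NaN`/`NA` p-values are excluded from the
#' number of tests and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Standardize log2 fold changes within a comparison
#'
#' The log2FC-z statistic: each protein's log2 fold change standardized
#' by the mean and sample SD (ddof 1) across all tested proteins in one
#' comparison.
#'
#' @param log2fc Numeric vector of per-protein log2 fold changes; at
#'   least two finite values and positive SD required.
#' @return Vector of z-scores.
#' @export
log2fc_zscores <- function(log2fc) {
  fin <- is.finite(log2fc)
  if (sum(fin) < 2) stop("need at least two finite log2 fold changes")
  s <- stats::sd(log2fc[fin])
  if (!is.finite(s) || s == 0) stop("degenerate comparison: zero variance of log2FC")
  (log2fc - mean(log2fc[fin])) / s
}

#' Call differentially abundant proteins
#'
#' A protein is a DAP iff `q < fdr_threshold` and `|z| > z_threshold`;
#' untested proteins are never DAPs. Direction follows the sign of the
#' log2 fold change (plaque minus control).
#'
#' @param records Data frame with columns `protein_id, log2fc, z, p, q`
#'   and logical `tested`.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param z_threshold Absolute log2FC-z cutoff; the conventional values
#'   are 2.5 for mouse and 2.0 for human (see [species_z_threshold()]).
#' @return The input with columns `is_dap` and `direction` added.
#' @export
call_daps <- function(records, fdr_threshold = 0.05, z_threshold = 2.5) {
  records$is_dap <- !is.na(records$q) & !is.na(records$z) &
    records$q < fdr_threshold & abs(records$z) > z_threshold
  if (!is.null(records$tested)) records$is_dap <- records$is_dap & records$tested
  records$direction <- ifelse(records$log2fc >= 0, "up_in_plaque",
                              "down_in_plaque")
  records
}

#' Conventional log2FC-z threshold by species
#'
#' @param model Model label; `"human"` (case-insensitive) gives 2.0,
#'   anything else (mouse models) gives 2.5.
#' @return Numeric threshold.
#' @export
species_z_threshold <- function(model) {
  ifelse(tolower(model) == "human", 2.0, 2.5)
}

#' Full differential abundance analysis of one stratum
#'
#' Runs the five-step procedure on one model-by-age stratum: per-protein
#' detection G-test (plaque vs non-plaque), G-gated detection-equalizing
#' minimum-value imputation, complete-pairs moderated paired t-test,
#' BH FDR, and log2FC-z thresholding.
#'
#' @param m An [IntensityMatrix] restricted to one stratum (see
#'   [subset_stratum()]).
#' @param fdr_threshold,alpha_g FDR cutoff for DAP calls and gate
#'   threshold for the G-test (both default 0.05).
#' @param z_threshold Absolute log2FC-z cutoff; default chosen from the
#'   stratum's model label via [species_z_threshold()].
#' @param min_pairs Minimum complete pairs per protein (default 3).
#' @param d_0,s2_0 Optional moderation prior overrides.
#' @return Data frame of DAP records: `protein_id, stratum, log2fc, z,
#'   p, q, g_p, imputed_count, n_pairs, tested, is_dap, direction`.
#' @export
dap_analysis <- function(m, fdr_threshold = 0.05, alpha_g = 0.05,
                         z_threshold = NULL, min_pairs = 3L,
                         d_0 = NULL, s2_0 = NULL) {
  md <- m$metadata
  stratum <- unique(paste(md$model, md$age_months, sep = ":"))
  if (length(stratum) != 1)
    stop("dap_analysis expects a single model:age stratum; got ",
         paste(stratum, collapse = ", "))
  if (is.null(z_threshold)) z_threshold <- species_z_threshold(md$model[1])

  v <- m$values
  pl_samples <- md$sample_id[md$region == "plaque"]
  np_samples <- md$sample_id[md$region == "nonplaque"]
  # order both groups by pair id so columns align pairwise
  pl_samples <- pl_samples[order(md$pair_id[match(pl_samples, md$sample_id)])]
  np_samples <- np_samples[order(md$pair_id[match(np_samples, md$sample_id)])]
  vp <- v[, pl_samples, drop = FALSE]
  vn <- v[, np_samples, drop = FALSE]
  n1 <- length(pl_samples); n2 <- length(np_samples)

  # detection G-test per protein
  k1 <- rowSums(!is.na(vp)); k2 <- rowSums(!is.na(vn))
  g <- g_test(k1, n1, k2, n2)

  # per-sample detection floors from the full stratum matrix
  floor_pl <- apply(vp, 2L, min, na.rm = TRUE)
  floor_np <- apply(vn, 2L, min, na.rm = TRUE)

  imputed_count <- integer(nrow(v))
  gated <- which(!is.na(g$p) & g$p < alpha_g & k1 != k2)
  for (i in gated) {
    res <- equalizing_impute(vp[i, ], vn[i, ], floor_pl, floor_np,
                             g_p = g$p[i], alpha = alpha_g)
    vp[i, ] <- res$values1
    vn[i, ] <- res$values2
    imputed_count[i] <- res$imputed_count
  }

  diffs <- vp - vn  # columns pair-aligned; NA where either member missing
  tt <- moderated_paired_ttest(diffs, min_pairs = min_pairs,
                               d_0 = d_0, s2_0 = s2_0)

  rec <- data.frame(protein_id = rownames(v),
                    stratum = stratum,
                    log2fc = tt$mean_diff,
                    z = NA_real_,
                    p = tt$p,
                    q = NA_real_,
                    g_p = g$p,
                    imputed_count = imputed_count,
                    n_pairs = tt$n_pairs,
                    tested = tt$tested,
                    stringsAsFactors = FALSE)
  rec$q[rec$tested] <- bh_fdr(rec$p[rec$tested])
  rec$z[rec$tested] <- log2fc_zscores(rec$log2fc[rec$tested])
  rec$log2fc[!rec$tested] <- NA_real_
  call_daps(rec, fdr_threshold = fdr_threshold, z_threshold = z_threshold)
}

#' Differential abundance across all strata of a cohort
#'
#' Applies [dap_analysis()] to each model-by-age stratum separately;
#' q-values and z-scores are computed within stratum.
#'
#' @inheritParams dap_analysis
#' @param m An [IntensityMatrix] possibly spanning several strata.
#' @return Row-bound data frame of per-stratum DAP records.
#' @export
dap_analysis_all <- function(m, fdr_threshold = 0.05, alpha_g = 0.05,
                             min_pairs = 3L) {
  strata <- list_strata(m)
  do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- subset_stratum(m, strata$model[i], strata$age_months[i])
    dap_analysis(sub, fdr_threshold = fdr_threshold, alpha_g = alpha_g,
                 min_pairs = min_pairs)
  }))
}

#' Correlation screen against the amyloid tracer
#'
#' Pearson correlation of every protein with the tracer across plaque
#' samples (all ages pooled), pairwise-complete. Returns all proteins
#' with at least `min_overlap` shared observations, flagging those above
#' the correlation threshold and the top `top_k` by R.
#'
#' @param m An [IntensityMatrix].
#' @param tracer_id Tracer protein id.
#' @param r_threshold Correlation cutoff (default 0.8).
#' @param top_k Number of top correlates to flag (default 20).
#' @param min_overlap Minimum complete observations per protein (default 6).
#' @param plaque_only Restrict to plaque samples (default `TRUE`).
#' @return Data frame `protein_id, r, n_obs, passes_threshold, top_k`,
#'   sorted by decreasing R; proteins with insufficient overlap carry
#'   `r = NA` and a `reason`.
#' @export
tracer_correlation_screen <- function(m, tracer_id, r_threshold = 0.8,
                                      top_k = 20L, min_overlap = 6L,
                                      plaque_only = TRUE) {
  if (!tracer_id %in% rownames(m$values))
    stop("tracer protein not present: ", tracer_id)
  keep <- if (plaque_only) m$metadata$region == "plaque"
          else rep(TRUE, nrow(m$metadata))
  v <- m$values[, m$metadata$sample_id[keep], drop = FALSE]
  tr <- v[tracer_id, ]
  others <- setdiff(rownames(v), tracer_id)
  n_obs <- vapply(others, function(id) sum(!is.na(v[id, ]) & !is.na(tr)),
                  integer(1))
  r <- rep(NA_real_, length(others))
  enough <- n_obs >= min_overlap
  r[enough] <- vapply(others[enough], function(id)
    stats::cor(v[id, ], tr, use = "pairwise.complete.obs"), numeric(1))
  out <- data.frame(protein_id = others, r = r, n_obs = n_obs,
                    reason = ifelse(enough, "", "insufficient overlap"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$protein_id, na.last = TRUE), , drop = FALSE]
  out$passes_threshold <- !is.na(out$r) & out$r > r_threshold
  out$top_k <- seq_len(nrow(out)) <= top_k & !is.na(out$r)
  rownames(out) <- NULL
  out
}
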