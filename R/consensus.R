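#' Normalize a study's ranking
#'
#' Converts a study's ranks to normalized ranks `r = rank / M` in
#' `(0, 1]`, `M` being the study's universe size. Tied proteins receive
#' the average of their positions before normalization.
#'
#' @param ranking Data frame with column `protein_id` and either `rank`
#'   or `score` (ascending scores are better; scores are converted to
#'   average ranks).
#' @param universe_size Universe size `M`; defaults to the
#'   `universe_size` attribute or the number of rows.
#' @return Data frame `protein_id, rank, r`.
#' @export
normalize_ranks <- function(ranking, universe_size = NULL) {
  if (anyDuplicated(ranking$protein_id))
    stop("duplicate protein in one ranking")
  if (is.null(universe_size))
    universe_size <- attr(ranking, "universe_size")
  if (is.null(universe_size)) universe_size <- nrow(ranking)
  stopifnot(universe_size >= 1)
  rk <- if (!is.null(ranking$rank)) {
    rank(ranking$rank, ties.method = "average")
  } else if (!is.null(ranking$score)) {
    rank(ranking$score, ties.method = "average")
  } else stop("ranking needs a 'rank' or 'score' column")
  data.frame(protein_id = ranking$protein_id, rank = rk,
             r = rk / universe_size, stringsAsFactors = FALSE)
}

#' Joint order-statistic probability Q
#'
#' For a protein with sorted normalized ranks `r_1 <= ... <= r_N` across
#' `N` independent studies, `Q` is the probability that the order
#' statistics of `N` independent uniforms all fall at or below the
#' observed ranks: `Q = N! * V_N` with the recursion
#' `V_0 = 1; V_k = sum_{i=1..k} (-1)^(i-1) (V_{k-i} / i!) r_{N-k+1}^i`.
#' Small Q means the protein is consistently top-ranked. The result is
#' clamped to `(0, 1]` to absorb floating-point round-off (stable for
#' `N <= 20`).
#'
#' @param r_sorted Ascending normalized ranks in `(0, 1]`.
#' @return Q in `(0, 1]`.
#' @export
order_statistic_q <- function(r_sorted) {
  r <- as.numeric(r_sorted)
  N <- length(r)
  stopifnot(N >= 1)
  if (any(r <= 0 | r > 1)) stop("normalized ranks must lie in (0, 1]")
  if (is.unsorted(r)) stop("normalized ranks must be sorted ascending")
  V <- numeric(N + 1L)
  V[1L] <- 1
  for (k in seq_len(N)) {
    x <- r[N - k + 1L]
    i <- seq_len(k)
    V[k + 1L] <- sum((-1)^(i - 1) * V[k - i + 1L] / factorial(i) * x^i)
  }
  q <- factorial(N) * V[N + 1L]
  min(max(q, .Machine$double.xmin), 1)
}

#' Aggregate study rankings into a consensus list
#'
#' For every protein present in at least `min_datasets` studies, the
#' joint order-statistic probability Q is computed over its available
#' normalized ranks (N = number of contributing studies) and the
#' consensus list is ordered by Q ascending, ties broken by mean
#' normalized rank then protein id. With the `"worst"` missing-protein
#' policy, absent studies contribute `r = 1` instead of being skipped.
#'
#' @param rankings List of study data frames (see [normalize_ranks()]).
#' @param min_datasets Minimum studies a protein must appear in
#'   (default 3, capped at the number of studies supplied).
#' @param missing_policy `"available"` (default: Q over present studies
#'   only) or `"worst"` (absent studies count as `r = 1`).
#' @return List with `consensus` (data frame `protein_id, n_datasets, Q,
#'   consensus_rank, ranks` with per-study normalized ranks ;-joined)
#'   and `unrankable` (proteins below `min_datasets`).
#' @export
aggregate_rankings <- function(rankings, min_datasets = 3L,
                               missing_policy = c("available", "worst")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(rankings) >= 1L)
  min_datasets <- min(min_datasets, length(rankings))
  norm <- lapply(rankings, normalize_ranks)
  all_ids <- sort(unique(unlist(lapply(norm, `[[`, "protein_id"))))
  rmat <- matrix(NA_real_, length(all_ids), length(norm),
                 dimnames = list(all_ids, NULL))
  for (j in seq_along(norm))
    rmat[norm[[j]]$protein_id, j] <- norm[[j]]$r
  n_avail <- rowSums(!is.na(rmat))
  rankable <- n_avail >= min_datasets
  if (!any(rankable))
    warning("no protein present in at least ", min_datasets, " studies")
  qv <- vapply(which(rankable), function(i) {
    r <- rmat[i, ]
    if (missing_policy == "worst") r[is.na(r)] <- 1
    order_statistic_q(sort(r[!is.na(r)]))
  }, numeric(1))
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  cons <- data.frame(protein_id = all_ids[rankable],
                     n_datasets = n_avail[rankable],
                     Q = qv,
                     mean_r = mean_r[rankable],
                     ranks = apply(rmat[rankable, , drop = FALSE], 1L,
                                   function(x) paste(ifelse(is.na(x), "",
                                     formatC(x, digits = 6, format = "g")),
                                     collapse = ";")),
                     stringsAsFactors = FALSE)
  cons <- cons[order(cons$Q, cons$mean_r, cons$protein_id), , drop = FALSE]
  cons$consensus_rank <- seq_len(nrow(cons))
  rownames(cons) <- NULL
  list(consensus = cons,
       unrankable = data.frame(protein_id = all_ids[!rankable],
                               n_datasets = n_avail[!rankable],
                               stringsAsFactors = FALSE))
}

#' Build a study ranking from a DAP table
#'
#' Ranking metric for this pipeline's own strata: ascending q-value,
#' ties broken by descending absolute log2 fold change.
#'
#' @param records DAP records (see [dap_analysis()]); untested proteins
#'   are dropped.
#' @param dataset_id Label attached to the ranking.
#' @return Data frame `protein_id, rank` with `dataset_id` and
#'   `universe_size` attributes.
#' @export
ranking_from_daps <- function(records, dataset_id = "this_study") {
  rec <- records[records$tested, , drop = FALSE]
  ord <- order(rec$q, -abs(rec$log2fc), rec$protein_id)
  out <- data.frame(protein_id = rec$protein_id[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "universe_size") <- nrow(out)
  out
}
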