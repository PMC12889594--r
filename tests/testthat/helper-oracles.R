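# Independent oracles and fixture builders shared across the suite.
# Every oracle is a deliberately naive implementation kept separate from
# the package's code paths.

# likelihood-ratio statistic for independence on a 2x2 table, written as
# the difference of multinomial log-likelihoods (independent of g_test's
# O*ln(O/E) form)
oracle_lr_2x2 <- function(k1, n1, k2, n2) {
  loglik <- function(k, n, p) {
    if (p <= 0 || p >= 1) {
      ifelse((k == 0 && p <= 0) || (k == n && p >= 1), 0, -Inf)
    } else {
      k * log(p) + (n - k) * log(1 - p)
    }
  }
  ll_sat <- loglik(k1, n1, ifelse(n1 > 0, k1 / n1, 0.5)) +
    loglik(k2, n2, ifelse(n2 > 0, k2 / n2, 0.5))
  p0 <- (k1 + k2) / (n1 + n2)
  ll_null <- loglik(k1, n1, p0) + loglik(k2, n2, p0)
  2 * (ll_sat - ll_null)
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(ps[i:m] * m / (i:m), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# brute-force Pearson correlation on complete cases
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# hypergeometric upper-tail by explicit summation
oracle_hyper_tail <- function(a, k, K, M) {
  upper <- min(k, K)
  if (a > upper) return(0)
  sum(vapply(a:upper, function(x)
    exp(lchoose(K, x) + lchoose(M - K, k - x) - lchoose(M, k)), numeric(1)))
}

# GSEA running-sum enrichment score by explicit loop
oracle_es <- function(stats_sorted_desc, hit) {
  s <- abs(stats_sorted_desc)
  nh <- sum(s[hit])
  nm <- sum(!hit)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) s[i] / nh else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Monte-Carlo estimate of the joint order-statistic probability:
# P(U_(k) <= r_k for all k), using the counting identity
# U_(k) <= r_k  <=>  #{U_i <= r_k} >= k
oracle_q_mc <- function(r, n_draws = 1e5L) {
  N <- length(r)
  U <- matrix(stats::runif(n_draws * N), n_draws, N)
  ok <- rep(TRUE, n_draws)
  for (k in seq_len(N)) ok <- ok & (rowSums(U <= r[k]) >= k)
  mean(ok)
}

# planarity via networkx (python), as an implementation-independent check
oracle_planar_nx <- function(n, from, to) {
  f <- tempfile(fileext = ".txt")
  writeLines(c(as.character(n),
               paste(from, collapse = ","),
               paste(to, collapse = ",")), f)
  code <- paste(
    "import sys, networkx as nx",
    "lines = open(sys.argv[1]).read().split()",
    "n = int(lines[0])",
    "f = [int(x) for x in lines[1].split(',')]",
    "t = [int(x) for x in lines[2].split(',')]",
    "G = nx.Graph(); G.add_nodes_from(range(1, n + 1))",
    "G.add_edges_from(zip(f, t))",
    "print(1 if nx.is_planar(G) else 0)", sep = "; ")
  out <- system2("python", c("-c", shQuote(code), f), stdout = TRUE)
  unlink(f)
  identical(trimws(out[length(out)]), "1")
}

# adjusted Rand index between two labelings (permutation-model form)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small deterministic IntensityMatrix: one stratum, paired design
toy_matrix <- function(values, n_pairs = ncol(values) / 2, model = "5xFAD",
                       age = 3L) {
  stopifnot(ncol(values) == 2 * n_pairs)
  sample_id <- c(sprintf("pl%02d", seq_len(n_pairs)),
                 sprintf("np%02d", seq_len(n_pairs)))
  colnames(values) <- sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("PROT%03d", seq_len(nrow(values)))
  md <- data.frame(sample_id = sample_id, model = model, age_months = age,
                   region = rep(c("plaque", "nonplaque"), each = n_pairs),
                   pair_id = rep(sprintf("pair%02d", seq_len(n_pairs)), 2),
                   replicate = rep(seq_len(n_pairs), 2),
                   stringsAsFactors = FALSE)
  IntensityMatrix(values, md)
}

# shift a block of proteins upward in plaque samples (plants a
# plaque-linked module into an existing cohort matrix)
plant_plaque_module <- function(m, protein_ids, shift = 2) {
  pl <- m$metadata$sample_id[m$metadata$region == "plaque"]
  m$values[protein_ids, pl] <- m$values[protein_ids, pl] + shift
  m
}
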