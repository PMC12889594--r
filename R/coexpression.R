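#' Permutation-screened significant correlations
#'
#' Computes all pairwise Pearson correlations (pairwise-complete) among
#' proteins with less than `max_missing` missingness, after per-sample
#' median centering, and screens them at a permutation-based FDR: the
#' null distribution pools `n_perm` per-protein independent sample
#' permutations across all pairs, and for a threshold `t`,
#' `FDR(t) = mean null count(|rho| >= t) / observed count(|rho| >= t)`.
#' Edges at or above the smallest threshold with `FDR(t) <= fdr` are
#' retained.
#'
#' @param m An [IntensityMatrix] (conditions merged; the network stage
#'   pools all samples).
#' @param n_perm Number of permutations (default 100).
#' @param fdr Permutation FDR threshold (default 0.05).
#' @param max_missing Maximum per-protein missingness fraction
#'   (default 0.5, exclusive).
#' @param min_obs Minimum shared observations for a pair (default 3;
#'   pairs below are skipped).
#' @param seed Seed for the permutation draws.
#' @return Data frame `protein_a, protein_b, rho, q_perm, significant`
#'   (all tested pairs, sorted by decreasing `|rho|`), with the selected
#'   threshold in attribute `rho_threshold`.
#' @export
significant_correlations <- function(m, n_perm = 100L, fdr = 0.05,
                                     max_missing = 0.5, min_obs = 3L,
                                     seed = 1L) {
  v <- m$values
  keep <- rowMeans(is.na(v)) < max_missing
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2) stop("fewer than two proteins pass the missingness filter")
  # per-sample median centering removes capture-level offsets
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  v <- sweep(v, 2L, med, "-")
  x <- t(v)                                   # samples x proteins
  rho <- stats::cor(x, use = "pairwise.complete.obs")
  nobs <- crossprod(!is.na(x))                # shared observations per pair
  ut <- upper.tri(rho)
  ok <- ut & nobs >= min_obs & !is.na(rho)
  idx <- which(ok, arr.ind = TRUE)
  obs <- abs(rho[ok])

  set.seed(as.integer(seed))
  ns <- nrow(x)
  null_abs <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    xp <- apply(x, 2L, function(col) col[sample.int(ns)])
    rp <- stats::cor(xp, use = "pairwise.complete.obs")
    np <- crossprod(!is.na(xp))
    okp <- upper.tri(rp) & np >= min_obs & !is.na(rp)
    null_abs[[b]] <- abs(rp[okp])
  }
  null_abs <- sort(unlist(null_abs))

  # FDR(t) over candidate thresholds = observed |rho| values, descending
  o <- order(obs, decreasing = TRUE)
  t_cand <- obs[o]
  n_obs_ge <- seq_along(t_cand)
  n_null_ge <- length(null_abs) -
    findInterval(t_cand, null_abs, left.open = TRUE)
  fdr_t <- (n_null_ge / n_perm) / n_obs_ge
  fdr_run <- rev(cummin(rev(fdr_t)))          # monotone in t (step-up style)
  pass <- fdr_run <= fdr
  rho_threshold <- if (any(pass)) t_cand[max(which(pass))] else Inf

  out <- data.frame(
    protein_a = rownames(v)[pmin(idx[, 1], idx[, 2])],
    protein_b = rownames(v)[pmax(idx[, 1], idx[, 2])],
    rho = rho[ok],
    q_perm = NA_real_,
    stringsAsFactors = FALSE)
  out$q_perm[o] <- pmin(fdr_run, 1)
  out$significant <- abs(out$rho) >= rho_threshold
  out <- out[order(-abs(out$rho), out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rho_threshold") <- rho_threshold
  attr(out, "n_proteins") <- nrow(v)
  out
}

#' Build the planar filtered network
#'
#' Greedy maximal planar subgraph: significant edges are sorted by
#' descending `|rho|` (ties by lexicographic id pair) and each is added
#' iff the graph stays planar (incremental left-right planarity test),
#' stopping when all edges are exhausted or `3(V - 2)` edges are held.
#'
#' @param edges Data frame `protein_a, protein_b, rho` (typically the
#'   significant rows of [significant_correlations()]).
#' @return An [igraph::igraph] with edge attribute `rho` and weight
#'   `|rho|`; the input edge table with an `in_pfn` flag is attached as
#'   graph attribute `edge_table`.
#' @export
build_pfn <- function(edges) {
  if (!nrow(edges)) stop("edge list is empty")
  ord <- order(-abs(edges$rho), edges$protein_a, edges$protein_b)
  edges <- edges[ord, , drop = FALSE]
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  from <- match(edges$protein_a, nodes)
  to <- match(edges$protein_b, nodes)
  keep <- .build_pfn_cpp(length(nodes), from, to)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$protein_a[keep], to = edges$protein_b[keep],
               rho = edges$rho[keep], weight = abs(edges$rho[keep]),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes)
  edges$in_pfn <- keep
  g <- igraph::set_graph_attr(g, "edge_table", edges)
  g
}

#' Planarity check (left-right algorithm)
#'
#' @param g An [igraph::igraph] (undirected, simple).
#' @return Logical: is the graph planar?
#' @export
is_planar <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  .is_planar_cpp(igraph::vcount(g), as.integer(el[, 1]), as.integer(el[, 2]))
}

# modularity-based split of a (sub)graph with a rewiring null;
# returns NULL if no significant split
.try_split <- function(g, alpha, n_null) {
  if (igraph::vcount(g) < 4 || igraph::ecount(g) < 3) return(NULL)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  if (length(unique(memb)) < 2) return(NULL)
  q_obs <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  w <- igraph::E(g)$weight
  q_null <- vapply(seq_len(n_null), function(b) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = max(10L * igraph::ecount(g), 100L)))
    # rewiring drops edge attributes; re-assign the observed weight
    # multiset in random order (degree-preserving weighted null)
    wr <- sample(w)
    clr <- igraph::cluster_louvain(gr, weights = wr)
    igraph::modularity(gr, igraph::membership(clr), weights = wr)
  }, numeric(1))
  p <- (1 + sum(q_null >= q_obs)) / (n_null + 1)
  if (p >= alpha) return(NULL)
  list(membership = memb, p = p)
}

#' Detect modules on the planar filtered network
#'
#' Hierarchical module detection by recursive partitioning: connected
#' components first, then each (sub)graph is split by maximizing
#' weighted modularity (Louvain); a split is accepted if its modularity
#' exceeds the `1 - alpha` quantile of modularities obtained on `n_null`
#' degree-preserving rewirings of the same subgraph (empirical
#' `p < alpha`). Recursion continues until no accepted split. Modules
#' with fewer than `min_size` nodes or exceeding half the network size
#' are excluded from the report (their parents remain in the
#' hierarchy).
#'
#' @param net PFN from [build_pfn()].
#' @param min_size Minimum reported module size (default 10).
#' @param alpha Split significance level (default 0.05).
#' @param n_null Number of rewirings per split test (default 1000).
#' @param seed Seed for Louvain and the rewiring null.
#' @return List with `modules` (data frame `module_id, parent, size,
#'   significance_p, reported`) and `members` (named list of protein id
#'   vectors, one per module).
#' @export
detect_modules <- function(net, min_size = 10L, alpha = 0.05,
                           n_null = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  n_total <- igraph::vcount(net)
  modules <- list(); members <- list()
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("M%d", counter) }

  comp <- igraph::components(net)
  queue <- list()
  root_members <- igraph::V(net)$name
  # the full network is the root; components are its children when >1
  root <- new_id()
  modules[[root]] <- list(parent = "root", p = NA_real_)
  members[[root]] <- sort(root_members)
  if (comp$no > 1) {
    for (ci in seq_len(comp$no)) {
      ids <- names(comp$membership)[comp$membership == ci]
      cid <- new_id()
      modules[[cid]] <- list(parent = root, p = NA_real_)
      members[[cid]] <- sort(ids)
      queue[[length(queue) + 1L]] <- cid
    }
  } else {
    queue[[1L]] <- root
  }

  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    ids <- members[[cur]]
    sub <- igraph::induced_subgraph(net, ids)
    sp <- .try_split(sub, alpha = alpha, n_null = n_null)
    if (is.null(sp)) next
    for (k in sort(unique(sp$membership))) {
      child_ids <- names(sp$membership)[sp$membership == k]
      cid <- new_id()
      modules[[cid]] <- list(parent = cur, p = sp$p)
      members[[cid]] <- sort(child_ids)
      queue[[length(queue) + 1L]] <- cid
    }
  }

  tab <- data.frame(
    module_id = names(modules),
    parent = vapply(modules, `[[`, character(1), "parent"),
    size = lengths(members)[names(modules)],
    significance_p = vapply(modules, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  tab$reported <- tab$size >= min_size & tab$size <= n_total / 2
  rownames(tab) <- NULL
  list(modules = tab, members = members)
}

#' Identify hub proteins within a module
#'
#' A member's within-module connectivity is its strength: the sum of
#' `|rho|` over its edges to other members. The null re-places the
#' module's weighted edges uniformly at random among member pairs
#' (`n_null` draws); since this null is exchangeable across nodes, all
#' node-slots are pooled into one reference distribution. Hubs are
#' members whose strength exceeds the null at `p < alpha`; p-values are
#' BH-adjusted across the module's members.
#'
#' @param net PFN from [build_pfn()].
#' @param member_ids Protein ids of the module.
#' @param alpha Hub significance level (default 0.05).
#' @param n_null Null draws (default 1000).
#' @param seed Seed for the null draws.
#' @return Data frame `protein_id, strength, degree, p, q, is_hub`
#'   sorted by decreasing strength.
#' @export
find_hubs <- function(net, member_ids, alpha = 0.05, n_null = 1000L,
                      seed = 1L) {
  set.seed(as.integer(seed))
  sub <- igraph::induced_subgraph(net, member_ids)
  nv <- igraph::vcount(sub)
  w <- igraph::E(sub)$weight
  ne <- length(w)
  strength <- igraph::strength(sub, weights = w)
  deg <- igraph::degree(sub)
  if (ne == 0 || nv < 3) {
    out <- data.frame(protein_id = igraph::V(sub)$name, strength = strength,
                      degree = deg, p = 1, q = 1, is_hub = FALSE,
                      stringsAsFactors = FALSE)
    return(out[order(-out$strength, out$protein_id), , drop = FALSE])
  }
  npairs <- nv * (nv - 1L) / 2L
  pair_i <- rep(seq_len(nv - 1L), times = (nv - 1L):1L)
  pair_j <- sequence((nv - 1L):1L) + pair_i
  null_strength <- matrix(0, nv, n_null)
  for (b in seq_len(n_null)) {
    sel <- sample.int(npairs, min(ne, npairs))
    wb <- w[seq_along(sel)]
    s <- numeric(nv)
    ii <- pair_i[sel]; jj <- pair_j[sel]
    for (k in seq_along(sel)) {
      s[ii[k]] <- s[ii[k]] + wb[k]
      s[jj[k]] <- s[jj[k]] + wb[k]
    }
    null_strength[, b] <- s
  }
  pooled <- sort(as.vector(null_strength))
  n_pool <- length(pooled)
  p <- (1 + n_pool - findInterval(strength - 1e-12, pooled)) / (n_pool + 1)
  q <- bh_fdr(p)
  out <- data.frame(protein_id = igraph::V(sub)$name, strength = strength,
                    degree = deg, p = p, q = q,
                    is_hub = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum enrichment score of a member set against a
#' ranked statistic (weight = statistic magnitude, exponent 1): hits
#' advance the running sum proportionally to `|stat|`, misses retreat it
#' by `1/(M - m)`; the ES is the deviation of maximal magnitude.
#'
#' @param stats Named numeric vector of ranking statistics (the
#'   universe); sorted internally in decreasing order.
#' @param members Character vector of member ids (must intersect the
#'   universe).
#' @return The enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(stats, members) {
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  hit <- names(s) %in% members
  if (!any(hit)) stop("member set does not intersect the ranking universe")
  .es_from_hits(abs(s), hit)
}

.es_from_hits <- function(absstat, hit) {
  denom_hit <- sum(absstat[hit])
  n_miss <- sum(!hit)
  if (denom_hit == 0 || n_miss == 0) return(0)
  run <- cumsum(ifelse(hit, absstat / denom_hit, -1 / n_miss))
  unname(run[which.max(abs(run))])
}

#' Module enrichment for differential abundance
#'
#' Tests whether a module's members concentrate at the top of a ranking
#' (proteins ranked by `|log2FC-z|`): weighted KS enrichment score with
#' a permutation p-value from `n_perm` random member sets of the same
#' size drawn from the universe.
#'
#' @param stats Named vector of ranking statistics (e.g. `abs(z)`).
#' @param members Module member ids.
#' @param n_perm Number of random sets (default 10000).
#' @param seed Seed for the draws.
#' @return List with `es`, `p` and `n_members_used`.
#' @export
module_set_enrichment <- function(stats, members, n_perm = 10000L,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  ord <- order(stats, decreasing = TRUE)
  s <- abs(stats[ord])
  hit <- names(stats)[ord] %in% members
  m <- sum(hit)
  if (m == 0) stop("member set does not intersect the ranking universe")
  es_obs <- .es_from_hits(s, hit)
  M <- length(s)
  es_null <- vapply(seq_len(n_perm), function(b) {
    h <- logical(M)
    h[sample.int(M, m)] <- TRUE
    .es_from_hits(s, h)
  }, numeric(1))
  p <- (1 + sum(es_null >= es_obs)) / (n_perm + 1)
  list(es = es_obs, p = p, n_members_used = m)
}

#' Enrichment of every reported module, BH-adjusted
#'
#' @param detection Result of [detect_modules()].
#' @param stats Named ranking statistic vector (e.g. `abs(z)` of one
#'   comparison).
#' @param n_perm Permutations per module (default 10000).
#' @param seed Seed.
#' @return Data frame `module_id, size, es, p, q` for reported modules
#'   intersecting the universe.
#' @export
modules_enrichment <- function(detection, stats, n_perm = 10000L, seed = 1L) {
  rep_ids <- detection$modules$module_id[detection$modules$reported]
  rows <- lapply(rep_ids, function(id) {
    mem <- intersect(detection$members[[id]], names(stats))
    if (!length(mem)) return(NULL)
    r <- module_set_enrichment(stats, mem, n_perm = n_perm, seed = seed)
    data.frame(module_id = id, size = length(detection$members[[id]]),
               es = r$es, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(module_id = character(), size = integer(),
                                      es = numeric(), p = numeric(),
                                      q = numeric()))
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Module eigengene
#'
#' First principal component of the standardized member-by-sample
#' submatrix, as one per-sample summary score. Missing values are
#' mean-imputed per protein before standardization; the sign is oriented
#' so the eigengene correlates non-negatively with the mean member
#' profile; scores are scaled to unit variance.
#'
#' @param m An [IntensityMatrix].
#' @param member_ids Module member ids (those with at most 50%
#'   missingness are used).
#' @return Named numeric vector of per-sample eigengene scores.
#' @export
module_eigengene <- function(m, member_ids) {
  v <- m$values[intersect(member_ids, rownames(m$values)), , drop = FALSE]
  v <- v[rowMeans(is.na(v)) <= 0.5, , drop = FALSE]
  if (!nrow(v)) stop("no usable members for eigengene computation")
  for (i in seq_len(nrow(v))) {
    mu <- mean(v[i, ], na.rm = TRUE)
    v[i, is.na(v[i, ])] <- mu
  }
  sds <- apply(v, 1L, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  if (!nrow(v)) stop("constant member profiles; eigengene undefined")
  z <- t(scale(t(v)))
  sv <- svd(z, nu = 0L, nv = 1L)
  eig <- sv$v[, 1L]
  if (stats::sd(eig) == 0) stop("constant eigengene")
  mean_profile <- colMeans(z)
  if (stats::cor(eig, mean_profile) < 0) eig <- -eig
  eig <- as.vector(scale(eig))
  names(eig) <- colnames(v)
  eig
}

#' Module-trait correlation
#'
#' Correlates each reported module's eigengene with the binary plaque
#' indicator; exact t-based p-values, BH across modules; a module is
#' flagged trait-associated iff `trait_q < fdr` and
#' `|trait_r| >= r_cut`.
#'
#' @param detection Result of [detect_modules()].
#' @param m An [IntensityMatrix] (samples define the trait).
#' @param fdr FDR threshold (default 0.05).
#' @param r_cut Absolute correlation cutoff (default 0.4).
#' @return Data frame `module_id, size, trait_r, trait_p, trait_q,
#'   trait_associated`.
#' @export
module_trait_correlation <- function(detection, m, fdr = 0.05, r_cut = 0.4) {
  trait <- as.numeric(m$metadata$region == "plaque")
  rep_ids <- detection$modules$module_id[detection$modules$reported]
  rows <- lapply(rep_ids, function(id) {
    eig <- tryCatch(module_eigengene(m, detection$members[[id]]),
                    error = function(e) NULL)
    if (is.null(eig)) return(NULL)
    tr <- trait[match(names(eig), m$metadata$sample_id)]
    r <- stats::cor(eig, tr)
    n <- length(eig)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    data.frame(module_id = id, size = length(detection$members[[id]]),
               trait_r = r, trait_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module_id = character(), size = integer(),
                      trait_r = numeric(), trait_p = numeric(),
                      trait_q = numeric(), trait_associated = logical()))
  out$trait_q <- bh_fdr(out$trait_p)
  out$trait_associated <- out$trait_q < fdr & abs(out$trait_r) >= r_cut
  rownames(out) <- NULL
  out
}
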