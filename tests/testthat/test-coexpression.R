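# block cohort tailored for network tests: 5 blocks x 20 proteins,
# complete data, no planted DAPs
block_cohort <- function(seed, n_blocks = 5, block_size = 20, extra = 19,
                         rho = 0.8, n_pairs = 20) {
  cfg <- cohort_config(n_proteins = n_blocks * block_size + extra + 1,
                       n_pairs_per_age = n_pairs,
                       frac_dap = 0, frac_contaminant = 0,
                       missing_midpoint = -Inf, missing_slope = 0,
                       n_blocks = n_blocks, block_size = block_size,
                       block_rho = rho, seed = seed)
  generate_cohort(cfg)
}

test_that("correlation screen retains duplicated profiles and matches the Pearson oracle", {
  co <- block_cohort(seed = 21, n_blocks = 2, block_size = 10, extra = 9,
                     n_pairs = 8)
  m <- co$matrix
  m$values["P0022", ] <- m$values["P0021", ]   # exact duplicate profile
  edges <- significant_correlations(m, n_perm = 50, seed = 1)
  dup <- edges[edges$protein_a == "P0021" & edges$protein_b == "P0022", ]
  expect_equal(dup$rho, 1, tolerance = 1e-12)
  expect_true(dup$significant)
  # oracle check on arbitrary pairs (after per-sample median centering)
  v <- sweep(m$values, 2, apply(m$values, 2, median), "-")
  set.seed(1)
  for (i in 1:10) {
    pick <- edges[sample(nrow(edges), 1), ]
    expect_equal(pick$rho, oracle_pearson(v[pick$protein_a, ],
                                          v[pick$protein_b, ]),
                 tolerance = 1e-12)
  }
})

test_that("edge screen is calibrated on independent noise", {
  counts <- vapply(1:5, function(s) {
    set.seed(300 + s)
    v <- matrix(rnorm(200 * 40, 20, 1), 200, 40,
                dimnames = list(sprintf("N%03d", 1:200), NULL))
    m <- toy_matrix(v, n_pairs = 20)
    edges <- significant_correlations(m, n_perm = 30, seed = s)
    c(sum(edges$significant), nrow(edges))
  }, numeric(2))
  expect_lte(mean(counts[1, ] / counts[2, ]), 0.05 + 0.01)
})

test_that("PFN keeps all of K4, drops exactly one edge of K5, and stays planar", {
  k_edges <- function(n) {
    p <- t(combn(sprintf("V%d", 1:n), 2))
    data.frame(protein_a = p[, 1], protein_b = p[, 2],
               rho = seq(1, 0.5, length.out = nrow(p)),
               stringsAsFactors = FALSE)
  }
  g4 <- build_pfn(k_edges(4))
  expect_equal(igraph::ecount(g4), 6)
  g5 <- build_pfn(k_edges(5))
  expect_equal(igraph::ecount(g5), 9)              # 3(5-2)
  et <- igraph::graph_attr(g5, "edge_table")
  # the one rejected edge is the weakest whose insertion violates planarity
  expect_identical(sum(!et$in_pfn), 1L)
  expect_equal(et$rho[!et$in_pfn], min(et$rho))
  expect_true(is_planar(g5))
})

test_that("PFN construction always yields planar graphs within the edge bound", {
  set.seed(70)
  for (rep in 1:5) {
    n <- 50
    p <- t(combn(sprintf("V%02d", 1:n), 2))
    keep <- sample(nrow(p), 400)
    edges <- data.frame(protein_a = p[keep, 1], protein_b = p[keep, 2],
                        rho = runif(400, -1, 1), stringsAsFactors = FALSE)
    g <- build_pfn(edges)
    expect_lte(igraph::ecount(g), 3 * (igraph::vcount(g) - 2))
    expect_true(is_planar(g))
    el <- igraph::as_edgelist(g, names = FALSE)
    expect_true(oracle_planar_nx(igraph::vcount(g), el[, 1], el[, 2]))
  }
})

test_that("module detection resolves two cliques and hides undersized clusters", {
  clique_edges <- function(ids, rho) {
    p <- t(combn(ids, 2))
    data.frame(protein_a = p[, 1], protein_b = p[, 2], rho = rho,
               stringsAsFactors = FALSE)
  }
  e <- rbind(clique_edges(sprintf("A%02d", 1:12), 0.9),
             clique_edges(sprintf("B%02d", 1:12), 0.85),
             data.frame(protein_a = "A01", protein_b = "B01", rho = 0.5))
  g <- build_pfn(e)
  det <- detect_modules(g, n_null = 200, seed = 3)
  rep_mods <- det$modules[det$modules$reported, ]
  expect_identical(nrow(rep_mods), 2L)
  got <- lapply(rep_mods$module_id, function(id) det$members[[id]])
  expect_setequal(vapply(got, function(x) substr(x[1], 1, 1), character(1)),
                  c("A", "B"))
  # a 5-node satellite cluster is never reported
  e2 <- rbind(e, clique_edges(sprintf("C%02d", 1:5), 0.95))
  det2 <- detect_modules(build_pfn(e2), n_null = 200, seed = 3)
  small <- vapply(det2$modules$module_id, function(id)
    all(startsWith(det2$members[[id]], "C")), logical(1))
  expect_false(any(det2$modules$reported[small]))
})

test_that("planted correlation blocks are recovered as modules", {
  aris <- vapply(1:3, function(s) {
    co <- block_cohort(seed = 400 + s)
    edges <- significant_correlations(co$matrix, n_perm = 50, seed = s)
    g <- build_pfn(edges[edges$significant, ])
    det <- detect_modules(g, n_null = 300, seed = s)
    leaf <- det$modules$module_id[det$modules$reported]
    memb <- unlist(lapply(leaf, function(id)
      setNames(rep(id, length(det$members[[id]])), det$members[[id]])))
    truth <- co$truth$block_assignment
    common <- intersect(names(memb), names(truth)[!is.na(truth)])
    oracle_ari(memb[common], truth[common])
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("hub detection flags a star center and nothing in a regular ring", {
  star <- data.frame(protein_a = "HUB",
                     protein_b = sprintf("L%02d", 1:11),
                     rho = 0.8, stringsAsFactors = FALSE)
  g <- build_pfn(star)
  h <- find_hubs(g, c("HUB", sprintf("L%02d", 1:11)), n_null = 500, seed = 2)
  expect_identical(h$protein_id[h$is_hub], "HUB")
  ring_ids <- sprintf("R%02d", 1:12)
  ring <- data.frame(protein_a = ring_ids,
                     protein_b = ring_ids[c(2:12, 1)],
                     rho = 0.8, stringsAsFactors = FALSE)
  g2 <- build_pfn(ring)
  h2 <- find_hubs(g2, ring_ids, n_null = 500, seed = 2)
  expect_false(any(h2$is_hub))
})

test_that("enrichment score matches a hand-computed running sum and fgsea", {
  stats <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1),
                    sprintf("G%02d", 1:10))
  members <- c("G01", "G02")
  es <- enrichment_score(stats, members)
  hit <- names(sort(stats, decreasing = TRUE)) %in% members
  expect_equal(es, unname(oracle_es(sort(stats, decreasing = TRUE), hit)),
               tolerance = 1e-12)
  # hand value: after two hits running sum = 1 - 0/8
  expect_equal(es, 5 / 9 + 4 / 9, tolerance = 1e-12)
  skip_if_not_installed("fgsea")
  es_fgsea <- fgsea::calcGseaStat(sort(stats, decreasing = TRUE),
                                  selectedStats = which(hit),
                                  gseaParam = 1)
  expect_equal(es, es_fgsea, tolerance = 1e-8)
})

test_that("a top-ranked module attains minimal permutation p and random modules do not", {
  set.seed(80)
  stats <- setNames(sort(rexp(100), decreasing = TRUE), sprintf("G%03d", 1:100))
  top <- names(stats)[1:10]
  r <- module_set_enrichment(stats, top, n_perm = 999, seed = 4)
  expect_lte(r$p, 2 / 999)
  expect_gt(r$es, 0.9)
  rand <- module_set_enrichment(stats, sample(names(stats), 10),
                                n_perm = 499, seed = 4)
  expect_gt(rand$p, 0.01)
})

test_that("module eigengene summarizes a rank-1 module and orients positively", {
  set.seed(90)
  profile <- rnorm(20)
  v <- matrix(rep(profile, each = 8), 8, 20, byrow = FALSE) +
    matrix(rnorm(160, 0, 1e-6), 8, 20)
  rownames(v) <- sprintf("M%02d", 1:8)
  m <- toy_matrix(v + 20, n_pairs = 10)
  eig <- module_eigengene(m, rownames(v))
  expect_equal(abs(cor(eig, profile)), 1, tolerance = 1e-6)
  expect_gt(cor(eig, scale(profile)[, 1]), 0)   # sign orientation
  expect_equal(sd(eig), 1, tolerance = 1e-9)
  # invariant to member ordering
  eig2 <- module_eigengene(m, rev(rownames(v)))
  expect_equal(eig, eig2, tolerance = 1e-9)
})

test_that("module-trait correlation flags the planted plaque-linked module only", {
  co <- block_cohort(seed = 31)
  blocks <- co$truth$block_assignment
  linked <- names(blocks)[!is.na(blocks) & blocks == 1]
  m <- plant_plaque_module(co$matrix, linked, shift = 2)
  edges <- significant_correlations(m, n_perm = 50, seed = 7)
  g <- build_pfn(edges[edges$significant, ])
  det <- detect_modules(g, n_null = 300, seed = 7)
  trait <- module_trait_correlation(det, m)
  flagged <- trait$module_id[trait$trait_associated]
  linked_mods <- vapply(trait$module_id, function(id)
    mean(det$members[[id]] %in% linked) > 0.5, logical(1))
  expect_true(any(linked_mods))
  expect_true(all(flagged %in% trait$module_id[linked_mods]))
  expect_gt(max(abs(trait$trait_r[linked_mods])), 0.4)
  # r below the cutoff is never flagged even at tiny q
  fake <- data.frame(module_id = "X", size = 10, trait_r = 0.39,
                     trait_p = 1e-6)
  fake$trait_q <- fake$trait_p
  fake$trait_associated <- fake$trait_q < 0.05 & abs(fake$trait_r) >= 0.4
  expect_false(fake$trait_associated)
})
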