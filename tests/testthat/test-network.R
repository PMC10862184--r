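# SparCC and network-topology unit tests; the heavier planted/null
# validation at the sizes of the co-occurrence analysis lives in the
# acceptance suite.

sim_compositional <- function(n, k, seed, planted = FALSE) {
  set.seed(seed)
  basis <- matrix(rlnorm(n * k, 0, 1), n, k)
  if (planted) basis[, 2] <- basis[, 1] * exp(rnorm(n, 0, 0.05))
  frac <- basis / rowSums(basis)
  counts <- t(apply(frac, 1, function(p) rmultinom(1, 2000, p)[, 1]))
  dimnames(counts) <- list(sprintf("S%03d", 1:n), sprintf("OTU_%04d", 1:k))
  community_table(counts)
}

test_that("SparCC output is symmetric, unit-diagonal and clamped", {
  tab <- sim_compositional(40, 25, seed = 1)
  fit <- sparcc_correlations(tab, n_iterations = 5, seed = 2)
  expect_true(isSymmetric(fit$rho))
  expect_equal(unname(diag(fit$rho)), rep(1, 25))
  expect_true(all(abs(fit$rho) <= 1))
  expect_error(sparcc_correlations(rand_table(5, 3, seed = 1)), "OTUs")
})

test_that("SparCC recovers a planted correlated pair and controls the null", {
  tab <- sim_compositional(150, 30, seed = 3, planted = TRUE)
  fit <- sparcc_correlations(tab, seed = 4)
  expect_gt(fit$rho[1, 2], 0.8)
  null_tab <- sim_compositional(150, 30, seed = 5)
  fit0 <- sparcc_correlations(null_tab, seed = 4)
  expect_lt(mean(abs(fit0$rho[upper.tri(fit0$rho)])), 0.1)
})

test_that("bootstrap p-values respect the attainable floor", {
  tab <- sim_compositional(60, 20, seed = 6, planted = TRUE)
  fit <- sparcc_correlations(tab, n_iterations = 5, seed = 7)
  pv <- sparcc_pvalues(tab, fit, n_bootstrap = 19, seed = 8)
  expect_true(all(pv[upper.tri(pv)] >= 1 / 20 - 1e-12))
  expect_equal(pv[1, 2], 1 / 20)  # planted pair at the floor
  expect_true(isSymmetric(pv))
})

test_that("network construction filters edges and drops isolated nodes", {
  rho <- diag(4)
  dimnames(rho) <- list(paste0("o", 1:4), paste0("o", 1:4))
  rho["o1", "o2"] <- rho["o2", "o1"] <- 0.6
  rho["o3", "o4"] <- rho["o4", "o3"] <- -0.2
  fit <- structure(list(rho = rho), class = "sparcc_fit")
  net <- build_network(fit, r_threshold = 0.3)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "positive")
  expect_warning(build_network(fit, r_threshold = 0.99), "no edge")
  # edge count equals brute-force threshold count on a random matrix
  set.seed(9)
  k <- 15
  r <- matrix(runif(k * k, -1, 1), k, k); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("o", 1:k), paste0("o", 1:k))
  p <- matrix(runif(k * k), k, k); p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(r)
  net2 <- build_network(structure(list(rho = r), class = "sparcc_fit"),
                        pvalues = p, r_threshold = 0.3, p_threshold = 0.4)
  brute <- sum(abs(r[upper.tri(r)]) > 0.3 & p[upper.tri(p)] < 0.4)
  expect_equal(nrow(net2$edges), brute)
})

test_that("network summary counts classes, signs and centralities correctly", {
  mk_net <- function(edges, nodes) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    structure(list(graph = g, nodes = nodes, edges = edges,
                   r_threshold = 0.3, p_threshold = 0.05),
              class = "cooc_network")
  }
  tri <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                    rho = 0.5, p = 0.01, sign = "positive")
  nodes <- data.frame(id = c("a", "b", "c"), class = "abundant", phylum = "P1")
  s <- summarize_network(mk_net(tri, nodes))
  expect_equal(s$edge_classes$n[s$edge_classes$class_pair == "abundant-abundant" &
                                s$edge_classes$sign == "positive"], 3)
  expect_equal(s$node_stats$degree, c(2, 2, 2))
  expect_equal(s$node_classes$pct[s$node_classes$class == "abundant"], 100)
  # path graph a-b-c: middle node more central
  path <- data.frame(from = c("a", "b"), to = c("b", "c"),
                     rho = c(0.5, -0.4), p = 0.01,
                     sign = c("positive", "negative"))
  nodes2 <- data.frame(id = c("a", "b", "c"),
                       class = c("abundant", "rare", "moderate"), phylum = NA)
  s2 <- summarize_network(mk_net(path, nodes2))
  clo <- setNames(s2$node_stats$closeness, s2$node_stats$id)
  expect_gt(clo["b"], clo["a"])
  expect_equal(clo[["b"]], 1)          # harmonic, normalized by n - 1
  expect_equal(clo[["a"]], (1 + 0.5) / 2)
  # degrees sum to twice the edges; class-pair counts partition the edges
  expect_equal(sum(s2$node_stats$degree), 2 * s2$n_edges)
  expect_equal(sum(s2$edge_classes$n), s2$n_edges)
})

test_that("hub ranking is degree first, closeness tiebreak, then id", {
  star <- data.frame(from = "hub", to = paste0("leaf", 1:5),
                     rho = 0.5, p = 0.01, sign = "positive")
  nodes <- data.frame(id = c("hub", paste0("leaf", 1:5)),
                      class = "moderate", phylum = NA)
  g <- igraph::graph_from_data_frame(star, directed = FALSE, vertices = nodes)
  net <- structure(list(graph = g, nodes = nodes, edges = star,
                        r_threshold = 0.3, p_threshold = 0.05),
                   class = "cooc_network")
  hubs <- find_hubs(net, k = 3)
  expect_equal(hubs$id[1], "hub")
  expect_equal(nrow(find_hubs(net, k = 100)), 6)  # k beyond node count
  # brute-force sort oracle on a random graph
  set.seed(10)
  em <- t(combn(10, 2))[runif(45) < 0.4, ]
  edges <- data.frame(from = paste0("n", em[, 1]), to = paste0("n", em[, 2]),
                      rho = 0.5, p = 0.01, sign = "positive")
  ids <- sort(unique(c(edges$from, edges$to)))
  nodes2 <- data.frame(id = ids, class = "moderate", phylum = NA)
  g2 <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes2)
  net2 <- structure(list(graph = g2, nodes = nodes2, edges = edges,
                         r_threshold = 0.3, p_threshold = 0.05),
                    class = "cooc_network")
  hubs2 <- find_hubs(net2, k = 5)
  st <- summarize_network(net2)$node_stats
  ord <- st[order(-st$degree, -st$closeness, st$id), ]
  expect_equal(hubs2$id, head(ord$id, 5))
})

test_that("prevalence filter keeps OTUs above the occupancy fraction", {
  m <- rbind(s1 = c(a = 1, b = 0, c = 1), s2 = c(a = 1, b = 0, c = 0),
             s3 = c(a = 1, b = 1, c = 0))
  out <- prevalence_filter(community_table(m), min_prevalence = 2/3)
  expect_setequal(colnames(out), "a")
  expect_error(prevalence_filter(community_table(m), 2), "no OTU")
})
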