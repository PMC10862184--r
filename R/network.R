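# SparCC-style compositional correlation inference, bootstrap significance,
# edge filtering, abundance-class-aware topology and hub detection.
#
# SparCC estimates basis (absolute-abundance) correlations from compositional
# counts: with t_ij = var(log(x_i/x_j)) across samples, and assuming most true
# correlations are zero, the basis variances w_i solve the linear system
# sum_{j != i} (w_i + w_j) = sum_{j != i} t_ij, and
# rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)). Strongly correlated pairs
# violate the sparsity assumption and are iteratively excluded from the
# system; the whole estimate is averaged over Dirichlet posterior resamples of
# the fractions.

# one Dirichlet resample of fractions from counts (pseudo-count 1)
.dirichlet_fractions <- function(counts, pseudo = 1) {
  g <- matrix(rgamma(length(counts), shape = counts + pseudo),
              nrow(counts), ncol(counts))
  g / rowSums(g)
}

# variation matrix t_ij = var(log(f_i / f_j)) over samples
.variation_matrix <- function(f) {
  L <- log(f)
  C <- cov(L)
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

# solve basis variances given the variation matrix and an inclusion matrix
# (logical, which pairs participate in the sparse system)
.solve_basis <- function(Tm, incl) {
  k <- nrow(Tm)
  A <- incl * 1
  diag(A) <- rowSums(incl)
  b <- rowSums(Tm * incl)
  w <- tryCatch(solve(A, b), error = function(e) rep(mean(b) / max(1, k), k))
  pmax(w, 1e-10)
}

.rho_from_basis <- function(w, Tm) {
  r <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w, "*")))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

# one full SparCC point estimate from a fraction matrix, with iterative
# exclusion of the strongest pairs
.sparcc_once <- function(f, exclusion_threshold, exclusion_rounds) {
  k <- ncol(f)
  Tm <- .variation_matrix(f)
  incl <- matrix(TRUE, k, k); diag(incl) <- FALSE
  w <- .solve_basis(Tm, incl)
  rho <- .rho_from_basis(w, Tm)
  for (round in seq_len(exclusion_rounds)) {
    cand <- abs(rho)
    cand[!incl] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    w <- .solve_basis(Tm, incl)
    rho <- .rho_from_basis(w, Tm)
  }
  rho
}

#' Prevalence pre-filter before network inference
#'
#' Keeps OTUs present in at least `min_prevalence` of samples. Correlation
#' networks on full amplicon tables are dominated by double-zero rare OTUs;
#' a prevalence rule is the usual guard and its value is recorded on the
#' result.
#'
#' @param table A [community_table()].
#' @param min_prevalence Minimum fraction of samples an OTU must occur in
#'   (default 1/3).
#' @return Filtered [community_table()] with a `"min_prevalence"` attribute.
#' @export
prevalence_filter <- function(table, min_prevalence = 1/3) {
  m <- unclass(table)
  keep <- colMeans(m > 0) >= min_prevalence
  if (!any(keep)) stop("no OTU passes the prevalence filter")
  out <- community_table(m[, keep, drop = FALSE])
  attr(out, "min_prevalence") <- min_prevalence
  out
}

#' SparCC basis correlations from a count table
#'
#' @param table A [community_table()] (samples x OTUs); OTUs should number at
#'   least ~20 for the sparsity approximation to hold.
#' @param n_iterations Dirichlet resamples averaged for the point estimate
#'   (default 20).
#' @param exclusion_threshold Pairs with |rho| above this are iteratively
#'   excluded from the basis-variance system (default 0.1).
#' @param exclusion_rounds Maximum exclusion iterations (default 10).
#' @param pseudo_count Added to counts before fraction conversion (default 1).
#' @param seed Integer seed.
#' @return Object of class `"sparcc_fit"`: `rho` (symmetric, unit diagonal,
#'   clamped to \[-1, 1\]) plus the call parameters.
#' @export
sparcc_correlations <- function(table, n_iterations = 20,
                                exclusion_threshold = 0.1,
                                exclusion_rounds = 10, pseudo_count = 1,
                                seed = 1L) {
  m <- unclass(table)
  if (ncol(m) < 4) stop("SparCC needs more OTUs than this (", ncol(m), ")")
  storage.mode(m) <- "double"
  set.seed(seed)
  acc <- matrix(0, ncol(m), ncol(m))
  for (it in seq_len(n_iterations)) {
    f <- .dirichlet_fractions(m, pseudo_count)
    acc <- acc + .sparcc_once(f, exclusion_threshold, exclusion_rounds)
  }
  rho <- acc / n_iterations
  rho <- pmin(pmax((rho + t(rho)) / 2, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  structure(list(rho = rho, n_iterations = n_iterations,
                 exclusion_threshold = exclusion_threshold,
                 exclusion_rounds = exclusion_rounds,
                 pseudo_count = pseudo_count, seed = seed),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- abs(x$rho[upper.tri(x$rho)])
  cat(sprintf("SparCC fit: %d OTUs, mean |rho| = %.3f, max |rho| = %.3f\n",
              nrow(x$rho), mean(off), max(off)))
  invisible(x)
}

#' Bootstrap p-values for SparCC correlations
#'
#' Permutation-style bootstrap: each replicate shuffles every OTU's counts
#' across samples independently (destroying all true co-variation while
#' keeping marginals) and recomputes the SparCC estimate. Two-sided
#' `p = (1 + #{|rho*| >= |rho|}) / (1 + n_bootstrap)`, so the attainable floor
#' is `1 / (n_bootstrap + 1)`.
#'
#' @param table The same [community_table()] used for the estimate.
#' @param fit A `"sparcc_fit"` from [sparcc_correlations()].
#' @param n_bootstrap Number of permutation replicates (default 100).
#' @param seed Integer seed.
#' @return Symmetric matrix of p-values in `(0, 1]` (diagonal `NA`).
#' @export
sparcc_pvalues <- function(table, fit, n_bootstrap = 100, seed = 1L) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  k <- ncol(m)
  obs <- abs(fit$rho)
  hits <- matrix(0L, k, k)
  for (b in seq_len(n_bootstrap)) {
    set.seed(derive_seed(seed, b))
    mp <- apply(m, 2, sample)
    set.seed(derive_seed(seed, n_bootstrap + b))
    acc <- matrix(0, k, k)
    for (it in seq_len(fit$n_iterations)) {
      f <- .dirichlet_fractions(mp, fit$pseudo_count)
      acc <- acc + .sparcc_once(f, fit$exclusion_threshold,
                                fit$exclusion_rounds)
    }
    hits <- hits + (abs(acc / fit$n_iterations) >= obs - 1e-12)
  }
  p <- (1 + hits) / (1 + n_bootstrap)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(fit$rho)
  p
}

#' Build a co-occurrence network from SparCC results
#'
#' Keeps the edge (i, j) iff `|rho_ij| > r_threshold` and `p_ij <
#' p_threshold`; nodes without any surviving edge are dropped. Edge sign is
#' the sign of the correlation.
#'
#' @param fit A `"sparcc_fit"`.
#' @param pvalues Matrix from [sparcc_pvalues()] (or `NULL` to filter on the
#'   correlation alone).
#' @param classification Optional `abundance_classification` labelling nodes.
#' @param taxonomy Optional taxonomy data frame (phylum recorded per node).
#' @param r_threshold Correlation magnitude threshold (default 0.3).
#' @param p_threshold Significance threshold (default 0.05).
#' @return Object of class `"cooc_network"`: an `igraph` graph (`graph`) with
#'   vertex attributes `class` and `phylum` and edge attributes `rho` and
#'   `sign`, plus `nodes` and `edges` data frames.
#' @export
build_network <- function(fit, pvalues = NULL, classification = NULL,
                          taxonomy = NULL, r_threshold = 0.3,
                          p_threshold = 0.05) {
  rho <- fit$rho
  keep <- abs(rho) > r_threshold
  if (!is.null(pvalues)) keep <- keep & !is.na(pvalues) & pvalues < p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    warning("no edge passes |rho| > ", r_threshold, " and p < ", p_threshold)
  edges <- data.frame(
    from = rownames(rho)[idx[, 1]], to = colnames(rho)[idx[, 2]],
    rho = rho[idx],
    p = if (is.null(pvalues)) rep(NA_real_, nrow(idx)) else pvalues[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  cls <- rep("unclassified", length(node_ids))
  if (!is.null(classification))
    cls <- as.character(classification[node_ids, "class"])
  phyl <- rep(NA_character_, length(node_ids))
  if (!is.null(taxonomy) && "phylum" %in% names(taxonomy))
    phyl <- taxonomy[node_ids, "phylum"]
  nodes <- data.frame(id = node_ids, class = cls, phylum = phyl,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (|rho| > %.2g, p < %.2g)\n",
              nrow(x$nodes), nrow(x$edges), x$r_threshold, x$p_threshold))
  invisible(x)
}

# normalized harmonic closeness: sum of reciprocal shortest-path lengths
# (unit edge weights; unreachable pairs contribute 0), divided by n - 1
.harmonic_closeness <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1) return(setNames(rep(0, n), igraph::V(g)$name))
  sp <- igraph::distances(g, weights = NA)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

#' Topology summary of a co-occurrence network
#'
#' Node counts and percentages per abundance class (percentages rounded
#' half-up to 1 decimal), positive/negative edge counts per unordered class
#' pair, and per-node degree and normalized harmonic closeness centrality.
#'
#' @param network A `"cooc_network"`.
#' @return Object of class `"network_summary"` with elements `n_nodes`,
#'   `n_edges`, `node_classes` (class, n, pct), `edge_classes` (class pair x
#'   sign counts) and `node_stats` (id, class, degree, closeness).
#' @export
summarize_network <- function(network) {
  g <- network$graph
  nodes <- network$nodes
  edges <- network$edges
  cls_tab <- table(factor(nodes$class,
                          levels = union(c("abundant", "moderate", "rare"),
                                         unique(nodes$class))))
  node_classes <- data.frame(
    class = names(cls_tab), n = as.integer(cls_tab),
    pct = round_half_up(100 * as.integer(cls_tab) / max(1, nrow(nodes)), 1),
    stringsAsFactors = FALSE)
  cls_of <- setNames(nodes$class, nodes$id)
  if (nrow(edges)) {
    pair <- apply(cbind(cls_of[edges$from], cls_of[edges$to]), 1,
                  function(z) paste(sort(z), collapse = "-"))
    edge_classes <- as.data.frame(table(class_pair = pair, sign = edges$sign),
                                  stringsAsFactors = FALSE)
    names(edge_classes)[3] <- "n"
  } else {
    edge_classes <- data.frame(class_pair = character(), sign = character(),
                               n = integer(), stringsAsFactors = FALSE)
  }
  deg <- igraph::degree(g)
  clo <- .harmonic_closeness(g)
  node_stats <- data.frame(id = nodes$id, class = nodes$class,
                           degree = as.integer(deg[nodes$id]),
                           closeness = clo[nodes$id],
                           stringsAsFactors = FALSE)
  structure(list(n_nodes = nrow(nodes), n_edges = nrow(edges),
                 node_classes = node_classes, edge_classes = edge_classes,
                 node_stats = node_stats),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  for (i in seq_len(nrow(x$node_classes)))
    with(x$node_classes[i, ], cat(sprintf("  %-12s %5d nodes (%.1f%%)\n",
                                          class, n, pct)))
  if (nrow(x$edge_classes)) {
    cat("  edges by class pair and sign:\n")
    for (i in seq_len(nrow(x$edge_classes)))
      with(x$edge_classes[i, ],
           cat(sprintf("    %-22s %-8s %5d\n", class_pair, sign, n)))
  }
  invisible(x)
}

#' Hub nodes of a co-occurrence network
#'
#' Nodes ranked by degree, ties broken by harmonic closeness centrality, then
#' lexicographic id; the top `k` are returned with their abundance class and
#' phylum.
#'
#' @param network A `"cooc_network"`.
#' @param k Number of hubs (default 10); if larger than the node count all
#'   nodes are returned.
#' @return data.frame of the ranked hubs (`rank`, `id`, `class`, `phylum`,
#'   `degree`, `closeness`).
#' @export
find_hubs <- function(network, k = 10) {
  if (nrow(network$nodes) == 0) stop("empty network")
  st <- summarize_network(network)$node_stats
  st$phylum <- network$nodes$phylum[match(st$id, network$nodes$id)]
  ord <- order(-st$degree, -st$closeness, st$id)
  st <- st[ord, c("id", "class", "phylum", "degree", "closeness")]
  st <- head(st, k)
  st <- data.frame(rank = seq_len(nrow(st)), st, row.names = NULL)
  st
}
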