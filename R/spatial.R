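# Geographic distances, Mantel tests and distance-decay, Levins niche
# breadth, and Kruskal-Wallis + BH differential abundance between groups.

#' Great-circle distances between samples
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param metadata A `sample_metadata` data frame with `latitude`/`longitude`
#'   in decimal degrees.
#' @return Square symmetric matrix of distances in km, labelled by sample id.
#' @export
geographic_distance <- function(metadata) {
  bad <- metadata$sample_id[is.na(metadata$latitude) | is.na(metadata$longitude)]
  if (length(bad))
    stop("missing coordinates for sample(s): ", paste(bad, collapse = ", "))
  pts <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  attr(d, "metric") <- "haversine_km"
  d
}

# upper-triangle vector of a square matrix
.utri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries.
#' Significance by permuting the row/column order of `dy` jointly; the
#' two-sided p-value is `(1 + #{|r*| >= |r|}) / (1 + n_permutations)`.
#'
#' @param dx,dy Square symmetric matrices with matching dimnames (or matching
#'   dimensions when unlabelled).
#' @param n_permutations Number of permutations (default 999). When `n!` is
#'   no larger than `n_permutations + 1` the test enumerates all `n!`
#'   permutations instead and the p-value is exact.
#' @param seed Integer seed (unused in the exact case).
#' @return Object of class `"mantel_result"`: `r`, `p`, `n_permutations`,
#'   `statistic_type`, `method` (`"permutation"` or `"exact"`). A
#'   zero-variance matrix gives `r = NA` with `flag = "zero_variance"`.
#' @export
mantel_test <- function(dx, dy, n_permutations = 999, seed = 1L) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!is.null(rownames(dx)) && !is.null(rownames(dy))) {
    common <- intersect(rownames(dx), rownames(dy))
    if (length(common) < nrow(dx) || length(common) < nrow(dy))
      warning("mantel_test: restricting to ", length(common), " shared samples")
    dx <- dx[common, common]; dy <- dy[common, common]
  }
  n <- nrow(dx)
  if (n < 3) stop("Mantel test needs at least 3 samples")
  if (nrow(dy) != n) stop("matrix dimensions differ")
  x <- .utri(dx); y <- .utri(dy)
  ok <- is.finite(x) & is.finite(y)
  exact <- factorial(n) <= n_permutations + 1
  res <- structure(list(r = NA_real_, p = NA_real_,
                        n_permutations = n_permutations, n = n,
                        statistic_type = "pearson",
                        method = if (exact) "exact" else "permutation",
                        flag = NULL),
                   class = "mantel_result")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    res$flag <- "zero_variance"
    return(res)
  }
  r_obs <- cor(x[ok], y[ok])
  score <- function(p) {
    yp <- .utri(dy[p, p])
    rp <- cor(x[ok], yp[ok])
    !is.na(rp) && abs(rp) >= abs(r_obs) - 1e-12
  }
  if (exact) {
    perms <- .all_permutations(n)
    hits <- sum(vapply(perms, score, logical(1)))  # identity included
    res$p <- hits / factorial(n)
    res$n_permutations <- factorial(n) - 1
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_permutations))
      if (score(sample.int(n))) hits <- hits + 1L
    res$p <- (1 + hits) / (1 + n_permutations)
  }
  res$r <- r_obs
  res
}

# all permutations of 1..n as a list (small n only)
.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    i <- i + 1L
    out[[i]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("Mantel test: undefined (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf("Mantel test (Pearson, %d permutations): r = %.4f, p = %.4g (n = %d)\n",
                x$n_permutations, x$r, x$p, x$n))
  }
  invisible(x)
}

#' Distance decay of community similarity with geographic distance
#'
#' Runs a Mantel test between the community dissimilarity and geographic
#' distance matrices, and fits an ordinary least-squares line of similarity
#' (`1 - dissimilarity`) against distance in km.
#'
#' @param community Square Bray-Curtis (or other) dissimilarity matrix.
#' @param geo Square geographic distance matrix (km).
#' @inheritParams mantel_test
#' @return Object of class `"distance_decay"`: the `mantel` result plus
#'   `slope` and `intercept` of similarity vs km (`NA` with a flag when all
#'   distances are equal).
#' @export
distance_decay <- function(community, geo, n_permutations = 999, seed = 1L) {
  man <- mantel_test(community, geo, n_permutations, seed)
  sim <- 1 - .utri(as.matrix(community))
  km <- .utri(as.matrix(geo))
  ok <- is.finite(sim) & is.finite(km)
  out <- structure(list(mantel = man, slope = NA_real_,
                        intercept = NA_real_, flag = NULL),
                   class = "distance_decay")
  if (sd(km[ok]) == 0) {
    out$flag <- "constant_distance"
    return(out)
  }
  fit <- lm(sim[ok] ~ km[ok])
  out$slope <- unname(coef(fit)[2])
  out$intercept <- unname(coef(fit)[1])
  out
}

#' @export
print.distance_decay <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("Distance decay: undefined (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf("Distance decay: slope = %.3e similarity/km; ", x$slope))
    print(x$mantel)
  }
  invisible(x)
}

#' Levins' niche breadth per OTU
#'
#' For OTU j with across-sample proportions `p_ij = x_ij / sum_i x_ij`,
#' `B_j = 1 / sum_i p_ij^2`: the effective number of samples the OTU occupies
#' evenly, between 1 and the number of samples. OTUs with zero total are
#' excluded with a message.
#'
#' @param table A [community_table()].
#' @return Named numeric vector of B per OTU.
#' @export
levins_breadth <- function(table) {
  m <- unclass(table)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    message("levins_breadth: excluded ", length(zero), " zero-total OTU(s)")
  m <- m[, tot > 0, drop = FALSE]
  p <- sweep(m, 2, colSums(m), "/")
  1 / colSums(p^2)
}

#' Compare niche breadth between abundant and rare OTUs
#'
#' Class means of Levins' B plus a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test between the abundant and rare classes.
#'
#' @param breadth Named vector from [levins_breadth()].
#' @param classification An `abundance_classification` over the same OTUs.
#' @return List of class `"breadth_comparison"`: per-class `n` and `mean_B`,
#'   and `p_value` (NA with `flag = "insufficient"` when either class has
#'   fewer than 2 OTUs).
#' @export
compare_breadth <- function(breadth, classification) {
  cls <- setNames(as.character(classification$class), classification$otu_id)
  cls <- cls[names(breadth)]
  means <- tapply(breadth, cls, mean)
  ns <- tapply(breadth, cls, length)
  a <- breadth[cls == "abundant" & !is.na(cls)]
  r <- breadth[cls == "rare" & !is.na(cls)]
  out <- structure(list(n = ns, mean_B = means, p_value = NA_real_,
                        flag = NULL),
                   class = "breadth_comparison")
  if (length(a) < 2 || length(r) < 2) {
    out$flag <- "insufficient"
    return(out)
  }
  out$p_value <- wilcox.test(a, r, exact = FALSE)$p.value
  out
}

#' @export
print.breadth_comparison <- function(x, ...) {
  cat("Levins niche breadth by abundance class:\n")
  for (cl in names(x$mean_B))
    cat(sprintf("  %-9s n = %4d, mean B = %.3f\n", cl, x$n[[cl]], x$mean_B[[cl]]))
  if (is.null(x$flag))
    cat(sprintf("  abundant vs rare (Mann-Whitney, two-sided): p = %.4g\n",
                x$p_value))
  else cat("  test skipped: ", x$flag, "\n", sep = "")
  invisible(x)
}

#' Differential abundance between groups (Kruskal-Wallis + BH)
#'
#' Per-taxon Kruskal-Wallis H test (tie-corrected) across groups, with
#' Benjamini-Hochberg adjustment across taxa. A taxon constant across all
#' samples gets `p = 1` by convention and is flagged.
#'
#' @param mat samples x taxa numeric matrix (e.g. phylum relative abundances
#'   from [relative_abundance_by_rank()]).
#' @param groups Factor/character of group labels, one per sample.
#' @param alpha Significance threshold on the adjusted q-value (default 0.01).
#' @return data.frame per taxon: group means, `H`, `p`, `q`, `significant`,
#'   `flag`.
#' @export
differential_abundance <- function(mat, groups, alpha = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 samples per group")
  res <- lapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    gm <- tapply(v, groups, mean)
    if (length(unique(v)) == 1) {
      list(H = 0, p = 1, flag = "constant", means = gm)
    } else {
      kw <- kruskal.test(v, groups)
      list(H = unname(kw$statistic), p = kw$p.value, flag = "", means = gm)
    }
  })
  means <- do.call(rbind, lapply(res, `[[`, "means"))
  colnames(means) <- paste0("mean_", levels(groups))
  out <- data.frame(taxon = colnames(mat),
                    means,
                    H = vapply(res, `[[`, numeric(1), "H"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    flag = vapply(res, `[[`, character(1), "flag"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out[order(out$q, out$p), ]
}

#' Per-variable environmental distance matrices
#'
#' Pairwise Euclidean (absolute-difference) distance for each environmental
#' variable, for Mantel tests of community dissimilarity against single
#' factors. Missing values propagate to `NA` pairs, which Mantel excludes
#' pairwise.
#'
#' @param metadata A `sample_metadata` data frame.
#' @return Named list of square matrices, one per environmental variable.
#' @export
environmental_distances <- function(metadata) {
  env <- environment_matrix(metadata)
  out <- lapply(colnames(env), function(v) {
    d <- as.matrix(dist(env[, v]))
    dimnames(d) <- list(rownames(env), rownames(env))
    d
  })
  names(out) <- colnames(env)
  out
}
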