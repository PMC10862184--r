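# Phylogenetic-bin null-model partitioning of community assembly into five
# processes: heterogeneous / homogeneous selection (by beta-NRI), dispersal
# limitation / homogenizing dispersal (by modified Raup-Crick), and drift.
#
# The observed taxa are first divided into bins of phylogenetically close
# OTUs; each sample pair is then scored per bin against taxa-shuffle
# (beta-NRI) and richness/abundance-preserving (Raup-Crick) nulls, classified
# by the fixed |1.96| / |0.95| thresholds, and bin classifications are
# aggregated with bin relative-abundance weights.

BNRI_THRESHOLD <- 1.96
RC_THRESHOLD <- 0.95

#' Divide OTUs into phylogenetic bins
#'
#' Greedy traversal from the root: a clade becomes a bin as soon as its
#' maximum within-clade patristic distance is at most `distance_threshold`.
#' Bins smaller than `min_bin_size` are then merged into the phylogenetically
#' nearest bin (minimum between-member patristic distance); bins formed by
#' forced merging can exceed the distance threshold and are flagged.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param otus OTU ids to bin (default: all tips).
#' @param distance_threshold Maximum within-bin patristic distance, in branch
#'   length units (default 0.5, calibrated for unit-depth trees).
#' @param min_bin_size Minimum OTUs per bin after merging (default 12).
#' @return Object of class `"phylo_bins"`: `bins` (named list of OTU id
#'   vectors), `assignment` (named vector OTU -> bin), `merged` (logical per
#'   bin), and the parameters.
#' @export
phylo_bins <- function(tree, otus = tree$tip.label, distance_threshold = 0.5,
                       min_bin_size = 12) {
  stopifnot(distance_threshold > 0, min_bin_size >= 2)
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing))
    stop("OTU(s) not in tree: ", paste(head(missing, 5), collapse = ", "))
  if (length(otus) < 2) stop("tree too small to form bins")
  if (length(setdiff(tree$tip.label, otus)))
    tree <- ape::keep.tip(tree, otus)
  D <- ape::cophenetic.phylo(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # tips under each node, by recursion
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  bins <- list()
  visit <- function(node) {
    tp <- tips_under(node)
    lab <- tree$tip.label[tp]
    if (length(tp) == 1 || max(D[lab, lab]) <= distance_threshold) {
      bins[[length(bins) + 1L]] <<- lab
    } else {
      for (ch in kids[[as.character(node)]]) visit(ch)
    }
  }
  visit(root)
  merged <- rep(FALSE, length(bins))
  # merge undersized bins into their phylogenetically nearest neighbour
  while (length(bins) > 1 && min(lengths(bins)) < min_bin_size) {
    i <- which.min(lengths(bins))
    d_to <- vapply(seq_along(bins), function(j) {
      if (j == i) return(Inf)
      min(D[bins[[i]], bins[[j]]])
    }, numeric(1))
    j <- which.min(d_to)
    bins[[j]] <- c(bins[[j]], bins[[i]])
    merged[j] <- TRUE
    bins[[i]] <- NULL
    merged <- merged[-i]
  }
  names(bins) <- sprintf("bin%03d", seq_along(bins))
  assignment <- setNames(rep(names(bins), lengths(bins)),
                         unlist(bins, use.names = FALSE))
  structure(list(bins = bins, assignment = assignment[otus], merged = merged,
                 distance_threshold = distance_threshold,
                 min_bin_size = min_bin_size),
            class = "phylo_bins")
}

#' @export
print.phylo_bins <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic bins: %d bins over %d OTUs (median size %d, threshold %.3g)\n",
    length(x$bins), length(x$assignment),
    as.integer(median(lengths(x$bins))), x$distance_threshold))
  if (any(x$merged))
    cat(sprintf("  %d bin(s) formed by forced merging of undersized bins\n",
                sum(x$merged)))
  invisible(x)
}

# n x n matrix of beta-MNTD values for all sample rows of F over distance
# matrix D, under a taxa permutation (identity = observed).
.bmntd_matrix <- function(D, F, perm = seq_len(ncol(F))) {
  .Call("C_bmntd", D, F, as.integer(perm), PACKAGE = "micropart")
}

#' Beta-NRI for an explicit list of sample pairs
#'
#' Computes the taxa-shuffle beta-NRI z-score for each listed sample pair,
#' treating the full OTU set as one bin and sharing the null randomizations
#' across pairs. Intended for calibration studies over many (e.g. disjoint)
#' pairs, where the all-pairs engine would waste work.
#'
#' @param table A [community_table()].
#' @param pairs Two-column matrix (or data.frame) of sample ids or row
#'   indices.
#' @param tree Rooted `phylo` over the table's OTUs (or pass `D`).
#' @param D Optional precomputed patristic distance matrix.
#' @param n_null Null randomizations (default 1000).
#' @param seed Integer seed.
#' @param weighted Abundance-weighted beta-MNTD (default TRUE).
#' @return Numeric vector of z-scores, one per pair (`NA` where degenerate).
#' @export
beta_nri_pairs <- function(table, pairs, tree = NULL, D = NULL,
                           n_null = 1000, seed = 1L, weighted = TRUE) {
  m <- unclass(table)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.character(pairs)) pairs <- matrix(match(pairs, rownames(m)),
                                           ncol = 2)
  ai <- as.integer(pairs[, 1]); bi <- as.integer(pairs[, 2])
  if (anyNA(ai) || anyNA(bi)) stop("unknown sample in pairs")
  if (is.null(D)) D <- ape::cophenetic.phylo(tree)
  D <- D[colnames(m), colnames(m)]
  F <- m
  if (!weighted) F <- (m > 0) * 1
  storage.mode(F) <- "double"
  rs <- rowSums(F)
  nz <- rs > 0
  F[nz, ] <- F[nz, , drop = FALSE] / rs[nz]
  k <- ncol(F)
  pcall <- function(perm) .Call("C_bmntd_pairs", D, F, as.integer(perm),
                                ai, bi, PACKAGE = "micropart")
  obs <- pcall(seq_len(k))
  set.seed(seed)
  s1 <- s2 <- numeric(length(obs))
  for (r in seq_len(n_null)) {
    v <- pcall(sample.int(k))
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax(0, (s2 - n_null * mu^2) / (n_null - 1)))
  z <- (obs - mu) / sdv
  z[sdv < 1e-12] <- NA_real_
  z
}

#' Between-community mean nearest-taxon distance (beta-MNTD)
#'
#' `0.5 * [sum_i f_i d(i, nearest taxon in the other community) + symmetric]`
#' with `f` the relative abundances within each community (presence/absence
#' when `weighted = FALSE`). A taxon present in both communities has nearest
#' distance 0.
#'
#' @param x,y Named abundance vectors over a common OTU set.
#' @param tree Rooted `phylo` containing those OTUs (or pass `D`).
#' @param D Optional precomputed patristic distance matrix.
#' @param weighted Abundance-weighted (default) or presence/absence.
#' @return Single non-negative number; `NA` if either community is empty.
#' @export
beta_mntd <- function(x, y, tree = NULL, D = NULL, weighted = TRUE) {
  stopifnot(!is.null(names(x)), identical(names(x), names(y)))
  if (is.null(D)) D <- ape::cophenetic.phylo(tree)
  D <- D[names(x), names(x)]
  F <- rbind(x, y)
  if (!weighted) F <- (F > 0) * 1
  rs <- rowSums(F)
  if (any(rs == 0)) return(NA_real_)
  F <- F / rs
  .bmntd_matrix(D, F)[1, 2]
}

#' Beta net relatedness index (beta-NRI) for one sample pair
#'
#' Standardizes the observed beta-MNTD against a taxa-shuffle null: OTU labels
#' are permuted across the bin's tips with abundances fixed, and
#' `beta-NRI = (obs - mean_null) / sd_null`.
#'
#' @inheritParams beta_mntd
#' @param n_null Number of null randomizations (default 1000).
#' @param seed Integer seed.
#' @return The z-score; `NA` (degenerate null) when the null has zero spread.
#' @export
beta_nri <- function(x, y, tree = NULL, D = NULL, n_null = 1000, seed = 1L,
                     weighted = TRUE) {
  stopifnot(!is.null(names(x)), identical(names(x), names(y)))
  if (is.null(D)) D <- ape::cophenetic.phylo(tree)
  D <- D[names(x), names(x)]
  F <- rbind(x, y)
  if (!weighted) F <- (F > 0) * 1
  rs <- rowSums(F)
  if (any(rs == 0)) return(NA_real_)
  F <- F / rs
  k <- ncol(F)
  obs <- .bmntd_matrix(D, F)[1, 2]
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(r)
    .bmntd_matrix(D, F, sample.int(k))[1, 2], numeric(1))
  s <- sd(nulls)
  if (!is.finite(s) || s < 1e-12) return(NA_real_)
  (obs - mean(nulls)) / s
}

# Generate one Raup-Crick null assemblage matrix: per sample, keep richness
# and total abundance, draw species by occupancy frequency, fill remaining
# individuals in proportion to regional relative abundance.
.rc_null_matrix <- function(S, N, occ, pa) {
  k <- length(occ)
  M <- matrix(0, length(S), k)
  for (b in seq_along(S)) {
    if (S[b] == 0) next
    sp <- if (S[b] >= k) seq_len(k) else sample.int(k, S[b], prob = occ)
    cnt <- rep(1, length(sp))
    extra <- N[b] - length(sp)
    if (extra > 0) {
      pr <- pa[sp]
      if (sum(pr) <= 0) pr <- rep(1, length(sp))
      cnt <- cnt + rmultinom(1, extra, pr)[, 1]
    }
    M[b, sp] <- cnt
  }
  M
}

# Bray-Curtis on a plain matrix, NA rows excluded -> NA pairs
.bc_matrix <- function(M) {
  ok <- rowSums(M) > 0
  d <- matrix(NA_real_, nrow(M), nrow(M))
  if (sum(ok) >= 2)
    d[ok, ok] <- as.matrix(vegan::vegdist(M[ok, , drop = FALSE], "bray"))
  diag(d) <- 0
  d
}

#' Modified Raup-Crick score (on Bray-Curtis) for one sample pair
#'
#' Null assemblages preserve each sample's within-bin richness and total
#' abundance; species are drawn with probability proportional to their
#' occupancy frequency across the table's samples and the remaining
#' individuals filled in proportion to total relative abundance. The score is
#' `RC = 2 [P(null BC < obs BC) + 0.5 P(null BC = obs BC)] - 1`, in [-1, 1].
#'
#' @param table A [community_table()] providing the occupancy and abundance
#'   references (typically the group's samples over the bin's OTUs).
#' @param s1,s2 Sample ids of the pair.
#' @param otus Optional OTU subset (a bin); default all columns.
#' @param n_null Number of null draws (default 1000).
#' @param seed Integer seed.
#' @return The RC score; `NA` if either sample is empty on `otus`.
#' @export
raup_crick <- function(table, s1, s2, otus = NULL, n_null = 1000, seed = 1L) {
  m <- unclass(table)
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  pair <- sort(c(s1, s2))  # canonical order: symmetric in the two samples
  s1 <- pair[1]; s2 <- pair[2]
  x <- m[s1, ]; y <- m[s2, ]
  if (sum(x) == 0 || sum(y) == 0) return(NA_real_)
  occ <- colSums(m > 0)
  pa <- colSums(m); pa <- pa / sum(pa)
  obs <- .bc_matrix(rbind(x, y))[1, 2]
  S <- c(sum(x > 0), sum(y > 0)); N <- c(sum(x), sum(y))
  set.seed(seed)
  less <- eq <- 0L
  for (r in seq_len(n_null)) {
    bc <- .bc_matrix(.rc_null_matrix(S, N, occ, pa))[1, 2]
    if (is.na(bc)) next
    if (bc < obs - 1e-12) less <- less + 1L
    else if (abs(bc - obs) <= 1e-12) eq <- eq + 1L
  }
  2 * ((less + 0.5 * eq) / n_null) - 1
}

#' Pairwise null-model scores for every sample pair and bin
#'
#' The engine behind [run_assembly_analysis()]: for each bin it computes the
#' observed beta-MNTD of every sample pair, a shared taxa-shuffle null (one
#' permutation per null replicate, applied to all pairs), the resulting
#' beta-NRI z-scores, and modified Raup-Crick scores from
#' richness/abundance-preserving null assemblages. Bin weights are the mean
#' relative abundance of the bin across the two samples of the pair, so
#' weights sum to 1 over bins within each pair.
#'
#' @param table A [community_table()] (the analysis group's samples).
#' @param tree Rooted `phylo` over the table's OTUs (or pass `D`).
#' @param bins A [phylo_bins()] partition of the table's OTUs.
#' @param D Optional precomputed patristic distance matrix.
#' @param n_null Null randomizations for both scores (default 1000).
#' @param seed Integer seed.
#' @param weighted Abundance-weighted beta-MNTD (default TRUE).
#' @param metrics Which scores to compute: `"bnri"`, `"rc"`, or both
#'   (default); the omitted score is returned as `NA`.
#' @return data.frame of class `"pairwise_null_scores"` with columns
#'   `sample1`, `sample2`, `bin`, `bnri`, `rc`, `weight`; attributes record
#'   `n_null` and the thresholds.
#' @export
assembly_scores <- function(table, tree = NULL, bins, D = NULL, n_null = 1000,
                            seed = 1L, weighted = TRUE,
                            metrics = c("bnri", "rc")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  m <- unclass(table)
  # canonical sample order, so scores do not depend on input row order
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(D)) D <- ape::cophenetic.phylo(tree)
  sample_tot <- rowSums(m)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- list()
  for (bi in seq_along(bins$bins)) {
    otus <- intersect(bins$bins[[bi]], colnames(m))
    if (length(otus) < 2) next
    Db <- D[otus, otus]
    X <- m[, otus, drop = FALSE]
    bin_tot <- rowSums(X)
    F <- X
    nz <- bin_tot > 0
    F[nz, ] <- F[nz, , drop = FALSE] / bin_tot[nz]
    if (!weighted) { F <- (X > 0) * 1; F[nz, ] <- F[nz, , drop = FALSE] / rowSums(F[nz, , drop = FALSE]) }
    k <- length(otus)
    bnri <- rc <- matrix(NA_real_, n, n)
    if ("bnri" %in% metrics) {
      # --- beta-NRI: shared taxa-shuffle null across all pairs
      obs <- .bmntd_matrix(Db, F)
      set.seed(derive_seed(seed, 2L * bi))
      s1m <- matrix(0, n, n); s2m <- matrix(0, n, n)
      for (r in seq_len(n_null)) {
        B <- .bmntd_matrix(Db, F, sample.int(k))
        s1m <- s1m + B
        s2m <- s2m + B * B
      }
      mu <- s1m / n_null
      sdv <- sqrt(pmax(0, (s2m - n_null * mu^2) / (n_null - 1)))
      bnri <- (obs - mu) / sdv
      bnri[sdv < 1e-12] <- NA_real_
    }
    if ("rc" %in% metrics) {
      # --- Raup-Crick: shared null assemblages across all pairs
      occ <- colSums(X > 0)
      pa <- colSums(X)
      pa <- if (sum(pa) > 0) pa / sum(pa) else rep(1 / k, k)
      obs_bc <- .bc_matrix(X)
      S <- rowSums(X > 0); N <- rowSums(X)
      set.seed(derive_seed(seed, 2L * bi + 1L))
      less <- matrix(0L, n, n); eq <- matrix(0L, n, n)
      for (r in seq_len(n_null)) {
        bc <- .bc_matrix(.rc_null_matrix(S, N, occ, pa))
        less <- less + (!is.na(bc) & bc < obs_bc - 1e-12)
        eq <- eq + (!is.na(bc) & abs(bc - obs_bc) <= 1e-12)
      }
      rc <- 2 * ((less + 0.5 * eq) / n_null) - 1
      rc[is.na(obs_bc)] <- NA_real_
    }
    # --- bin weight: mean relative abundance of the bin across the pair
    share <- ifelse(sample_tot > 0, bin_tot / sample_tot, 0)
    w <- outer(share, share, "+") / 2
    i <- pair_idx[, 1]; j <- pair_idx[, 2]
    out[[length(out) + 1L]] <- data.frame(
      sample1 = rownames(m)[i], sample2 = rownames(m)[j],
      bin = names(bins$bins)[bi],
      bnri = bnri[cbind(i, j)], rc = rc[cbind(i, j)],
      weight = w[cbind(i, j)], stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable bin")
  res <- do.call(rbind, out)
  attr(res, "n_null") <- n_null
  attr(res, "bnri_threshold") <- BNRI_THRESHOLD
  attr(res, "rc_threshold") <- RC_THRESHOLD
  class(res) <- c("pairwise_null_scores", "data.frame")
  res
}

# classify (bnri, rc) vectors into process labels (NA if undecidable)
.classify_process <- function(bnri, rc, bt = BNRI_THRESHOLD,
                              rt = RC_THRESHOLD) {
  ifelse(is.na(bnri), NA_character_,
  ifelse(bnri < -bt, "homogeneous_selection",
  ifelse(bnri > bt, "heterogeneous_selection",
  ifelse(is.na(rc), NA_character_,
  ifelse(rc < -rt, "homogenizing_dispersal",
  ifelse(rc > rt, "dispersal_limitation", "drift"))))))
}

PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
               "homogenizing_dispersal", "dispersal_limitation", "drift")

#' Partition assembly processes from pairwise null scores
#'
#' Each pair x bin is classified by the fixed thresholds: beta-NRI < -1.96
#' homogeneous selection, > +1.96 heterogeneous selection; otherwise
#' RC < -0.95 homogenizing dispersal, > +0.95 dispersal limitation, and the
#' remainder drift. Within each pair, bin classifications are aggregated with
#' the bin abundance weights (renormalized over scoreable bins), then
#' averaged over pairs; the five fractions sum to 1.
#'
#' @param scores A `pairwise_null_scores` data frame (or any data frame with
#'   `sample1`, `sample2`, `bin`, `bnri`, `rc`, `weight`).
#' @param bnri_threshold,rc_threshold Classification thresholds. These are
#'   the standard |1.96| and |0.95| cutoffs; overriding them is allowed but
#'   warned about.
#' @return Object of class `"assembly_partition"`: `fractions` (named, sums
#'   to 1), `n_pairs`, `n_bins`, `n_scored`.
#' @export
partition_processes <- function(scores, bnri_threshold = BNRI_THRESHOLD,
                                rc_threshold = RC_THRESHOLD) {
  if (bnri_threshold != BNRI_THRESHOLD || rc_threshold != RC_THRESHOLD)
    warning("non-standard significance thresholds: beta-NRI |",
            bnri_threshold, "|, RC |", rc_threshold, "|")
  cls <- .classify_process(scores$bnri, scores$rc, bnri_threshold, rc_threshold)
  ok <- !is.na(cls) & !is.na(scores$weight)
  if (!any(ok)) stop("no scoreable pair x bin")
  pair_id <- paste(scores$sample1, scores$sample2, sep = "\r")
  acc <- matrix(0, length(unique(pair_id[ok])), length(PROCESSES),
                dimnames = list(unique(pair_id[ok]), PROCESSES))
  wsum <- setNames(numeric(nrow(acc)), rownames(acc))
  for (r in which(ok)) {
    acc[pair_id[r], cls[r]] <- acc[pair_id[r], cls[r]] + scores$weight[r]
    wsum[pair_id[r]] <- wsum[pair_id[r]] + scores$weight[r]
  }
  keep <- wsum > 0
  frac <- colMeans(acc[keep, , drop = FALSE] / wsum[keep])
  structure(list(fractions = frac, n_pairs = sum(keep),
                 n_bins = length(unique(scores$bin)), n_scored = sum(ok)),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat(sprintf("Assembly process partition (%d pairs, %d bins):\n",
              x$n_pairs, x$n_bins))
  for (p in names(x$fractions))
    cat(sprintf("  %-24s %6.1f%%\n", p, 100 * x$fractions[[p]]))
  invisible(x)
}

#' Full assembly analysis per group
#'
#' Runs the complete per-group pipeline: restrict the table to each group's
#' samples (and, when a classification is given, to each abundance class's
#' OTUs), bin the OTUs on the tree, score every sample pair per bin with
#' beta-NRI and Raup-Crick nulls, and partition into the five processes.
#' Groups with fewer than 3 samples are skipped with a message.
#'
#' @param table A [community_table()] (typically rarefied).
#' @param tree Rooted `phylo` over the table's OTUs.
#' @param groups Factor/character of group labels per sample (e.g. soil
#'   layer), or `NULL` for a single group.
#' @param classification Optional `abundance_classification`; when given the
#'   analysis is run separately per class in `classes`.
#' @param classes Abundance classes to analyse (default abundant and rare).
#' @param distance_threshold,min_bin_size Binning parameters
#'   (see [phylo_bins()]).
#' @param n_null Null randomizations (default 1000).
#' @param seed Integer master seed.
#' @param weighted Abundance-weighted beta-MNTD (default TRUE).
#' @return Object of class `"assembly_analysis"`: named list `partitions`
#'   (one `assembly_partition` per class x group), `scores` (per-group score
#'   tables) and `bins`.
#' @export
run_assembly_analysis <- function(table, tree, groups = NULL,
                                  classification = NULL,
                                  classes = c("abundant", "rare"),
                                  distance_threshold = 0.5, min_bin_size = 12,
                                  n_null = 1000, seed = 1L, weighted = TRUE) {
  m <- unclass(table)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  groups <- setNames(as.character(groups), rownames(m))
  subsets <- if (is.null(classification)) list(all = table) else
    setNames(lapply(classes, function(cl)
      subset_by_class(table, classification, cl)), classes)
  partitions <- list(); score_tabs <- list(); bin_sets <- list()
  gi <- 0L
  for (cl in names(subsets)) {
    sub <- subsets[[cl]]
    for (g in unique(groups)) {
      gi <- gi + 1L
      key <- if (length(subsets) == 1 && length(unique(groups)) == 1) "all"
             else if (length(subsets) == 1) g
             else if (length(unique(groups)) == 1) cl
             else paste(cl, g, sep = ".")
      samp <- names(groups)[groups == g]
      if (length(samp) < 3) {
        message("run_assembly_analysis: group '", key,
                "' has < 3 samples, skipped")
        next
      }
      tab_g <- unclass(sub)[samp, , drop = FALSE]
      keep_otu <- colSums(tab_g) > 0
      tab_g <- community_table(tab_g[, keep_otu, drop = FALSE])
      tr_g <- ape::keep.tip(tree, colnames(tab_g))
      bn <- phylo_bins(tr_g, distance_threshold = distance_threshold,
                       min_bin_size = min_bin_size)
      sc <- assembly_scores(tab_g, tr_g, bn, n_null = n_null,
                            seed = derive_seed(seed, gi), weighted = weighted)
      partitions[[key]] <- partition_processes(sc)
      score_tabs[[key]] <- sc
      bin_sets[[key]] <- bn
    }
  }
  if (!length(partitions)) stop("no group with at least 3 samples")
  structure(list(partitions = partitions, scores = score_tabs,
                 bins = bin_sets, n_null = n_null, seed = seed),
            class = "assembly_analysis")
}

#' @export
print.assembly_analysis <- function(x, ...) {
  cat(sprintf("Assembly analysis (%d group(s), n_null = %d):\n",
              length(x$partitions), x$n_null))
  for (key in names(x$partitions)) {
    cat("--", key, "--\n")
    print(x$partitions[[key]])
  }
  invisible(x)
}
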