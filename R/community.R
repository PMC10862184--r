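# Descriptive layer: rarefaction, abundant/rare classification, taxonomic
# aggregation, alpha diversity, Faith's PD, Bray-Curtis.

#' Rarefy a community table to an even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`; samples whose total is below `depth` are
#' dropped with a message. One draw per sample, deterministic given `seed`.
#'
#' @param table A [community_table()].
#' @param depth Target reads per sample (e.g. 10000 for 16S, 5000 for ITS).
#' @param seed Integer seed.
#' @return A rarefied [community_table()]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(depth >= 1)
  m <- unclass(table)
  totals <- rowSums(m)
  drop <- totals < depth
  if (all(drop)) stop("all samples are below the rarefaction depth ", depth)
  if (any(drop))
    message(sprintf("rarefy: dropped %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(m)[drop], collapse = ", ")))
  m <- m[!drop, , drop = FALSE]
  set.seed(seed)
  # vegan warns when a table has no small counts (heuristic for non-count
  # data); inputs here are validated integer counts, so silence that one
  r <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  community_table(r)
}

#' Classify OTUs as abundant, moderate or rare
#'
#' Classification is by mean relative abundance across all samples (per-sample
#' proportions averaged): abundant if the mean is strictly above
#' `abundant_threshold` (default 0.1%), rare if strictly below
#' `rare_threshold` (default 0.01%), moderate otherwise. Values exactly at a
#' threshold are moderate.
#'
#' @param table A [community_table()] (typically rarefied).
#' @param abundant_threshold,rare_threshold Fractions with
#'   `0 < rare_threshold < abundant_threshold < 1`.
#' @return A data.frame of class `"abundance_classification"` with columns
#'   `otu_id`, `mean_rel_abund`, `class`; thresholds kept as attributes.
#' @export
classify_abundance <- function(table, abundant_threshold = 0.001,
                               rare_threshold = 1e-4) {
  if (!(rare_threshold > 0 && rare_threshold < abundant_threshold &&
        abundant_threshold < 1))
    stop("need 0 < rare_threshold < abundant_threshold < 1")
  m <- unclass(table)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty community table")
  rel <- m / rowSums(m)
  mra <- colMeans(rel)
  cls <- ifelse(mra > abundant_threshold, "abundant",
                ifelse(mra < rare_threshold, "rare", "moderate"))
  out <- data.frame(otu_id = colnames(m), mean_rel_abund = mra,
                    class = factor(cls, levels = c("abundant", "moderate", "rare")),
                    row.names = colnames(m), stringsAsFactors = FALSE)
  attr(out, "abundant_threshold") <- abundant_threshold
  attr(out, "rare_threshold") <- rare_threshold
  attr(out, "basis") <- "mean_relative_abundance"
  class(out) <- c("abundance_classification", "data.frame")
  out
}

#' @export
print.abundance_classification <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf(
    "Abundance classification (> %.3g%% / < %.3g%% mean relative abundance):\n",
    100 * attr(x, "abundant_threshold"), 100 * attr(x, "rare_threshold")))
  for (cl in names(tab))
    cat(sprintf("  %-9s %6d OTUs\n", cl, tab[[cl]]))
  invisible(x)
}

#' Restrict a table to the OTUs of one abundance class
#'
#' The sample set is unchanged; samples left with zero reads are retained and
#' reported in the `"empty_samples"` attribute.
#'
#' @param table A [community_table()].
#' @param classification An `abundance_classification` for the same OTUs.
#' @param cls `"abundant"`, `"moderate"` or `"rare"`.
#' @return A [community_table()] over the class's OTUs.
#' @export
subset_by_class <- function(table, classification, cls) {
  cls <- match.arg(cls, c("abundant", "moderate", "rare"))
  keep <- classification$otu_id[classification$class == cls]
  keep <- intersect(colnames(table), keep)
  if (length(keep) == 0) stop("no OTU in class '", cls, "'")
  out <- community_table(unclass(table)[, keep, drop = FALSE])
  empty <- rownames(out)[rowSums(out) == 0]
  if (length(empty))
    message(sprintf("subset_by_class(%s): %d sample(s) have zero reads: %s",
                    cls, length(empty), paste(empty, collapse = ", ")))
  attr(out, "empty_samples") <- empty
  out
}

#' Relative abundance aggregated at a taxonomic rank
#'
#' @param table A [community_table()].
#' @param taxonomy Taxonomy data frame ([read_taxonomy()]).
#' @param rank Column name of `taxonomy`, e.g. `"phylum"`.
#' @return samples x taxa matrix of fractions; rows sum to 1. OTUs without a
#'   value at `rank` are pooled as `"Unclassified"`.
#' @export
relative_abundance_by_rank <- function(table, taxonomy, rank) {
  if (!rank %in% names(taxonomy))
    stop("rank '", rank, "' not present in taxonomy")
  m <- unclass(table)
  lab <- taxonomy[colnames(m), rank]
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  agg <- t(rowsum(t(m), lab))
  agg / rowSums(agg)
}

#' Non-phylogenetic alpha diversity
#'
#' Per sample: observed richness, Chao1, ACE (rare-abundance cutoff 10),
#' Shannon entropy (nats) and Simpson (1 - D). Chao1 and ACE follow the
#' standard abundance-based estimators and require integer counts. Empty
#' samples yield `NA` for every index and are listed in the
#' `"empty_samples"` attribute.
#'
#' @param table A [community_table()] of integer counts.
#' @return data.frame, one row per sample.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  empty <- rowSums(m) == 0
  out <- data.frame(sample_id = rownames(m),
                    observed = NA_real_, chao1 = NA_real_, ace = NA_real_,
                    shannon = NA_real_, simpson = NA_real_,
                    row.names = rownames(m), stringsAsFactors = FALSE)
  if (any(!empty)) {
    sub <- m[!empty, , drop = FALSE]
    est <- t(vegan::estimateR(sub))  # S.obs, S.chao1, se, S.ACE, se
    out$observed[!empty] <- est[, "S.obs"]
    out$chao1[!empty] <- est[, "S.chao1"]
    out$ace[!empty] <- est[, "S.ACE"]
    out$shannon[!empty] <- vegan::diversity(sub, index = "shannon")
    out$simpson[!empty] <- vegan::diversity(sub, index = "simpson")
  }
  if (any(empty))
    message("alpha_diversity: empty sample(s): ",
            paste(rownames(m)[empty], collapse = ", "))
  attr(out, "empty_samples") <- rownames(m)[empty]
  out
}

#' Faith's phylogenetic diversity
#'
#' PD of a sample is the total branch length of the minimal subtree that spans
#' the sample's present OTUs and the root (rooted convention, so a
#' single-taxon sample has PD equal to its tip-to-root path length). Set
#' `include_root = FALSE` for the unrooted spanning subtree instead.
#'
#' @param table A [community_table()] whose OTUs are all tips of `tree`.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param include_root Include the path to the root (default `TRUE`).
#' @return Named numeric vector of PD per sample (`NA` for empty samples).
#' @export
faith_pd <- function(table, tree, include_root = TRUE) {
  m <- unclass(table)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("OTU(s) absent from tree: ", paste(head(missing, 5), collapse = ", "))
  ntip <- length(tree$tip.label)
  # edge index on the path from each tip to the root
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  edge_above <- integer(ntip + tree$Nnode)  # edge whose child is this node
  edge_above[child] <- seq_along(child)
  root <- ntip + 1L
  tip_paths <- lapply(seq_len(ntip), function(tp) {
    path <- integer(0)
    node <- tp
    while (node != root) {
      e <- edge_above[node]
      path <- c(path, e)
      node <- parent[e]
    }
    path
  })
  tip_idx <- match(colnames(m), tree$tip.label)
  pd <- vapply(seq_len(nrow(m)), function(i) {
    present <- tip_idx[m[i, ] > 0]
    if (length(present) == 0) return(NA_real_)
    all_edges <- unlist(tip_paths[present])
    used <- unique(all_edges)
    if (!include_root) {
      # drop edges above the MRCA of the present tips
      hits <- tabulate(all_edges, nbins = nrow(tree$edge))
      used <- setdiff(used, which(hits == length(present)))
      if (length(present) == 1) used <- integer(0)
    }
    sum(tree$edge.length[used])
  }, numeric(1))
  names(pd) <- rownames(m)
  pd
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric with zero
#' diagonal, values in `[0, 1]`. Pairs involving an all-zero sample are
#' undefined (`NaN`) and reported in the `"undefined_samples"` attribute.
#'
#' @param table A [community_table()] with at least two samples.
#' @return Square symmetric matrix with a `"metric"` attribute.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least two samples")
  zero <- rownames(m)[rowSums(m) == 0]
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (length(zero)) {
    d[zero, ] <- NaN; d[, zero] <- NaN
    message("bray_curtis: all-zero sample(s), pairs undefined: ",
            paste(zero, collapse = ", "))
  }
  diag(d) <- 0
  attr(d, "metric") <- "bray_curtis"
  attr(d, "undefined_samples") <- zero
  d
}
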