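# Orchestration and the end-of-run summary tables: class counts with
# percentages in the survey's reporting style, and the staged pipeline.

#' Percentage in the survey reporting style
#'
#' `100 * count / total`, rounded half-up; by default to 1 decimal, or 2
#' decimals when the value is below 1% (so 164/26308 prints as 0.62 and
#' 24230/26308 as 92.1).
#'
#' @param count,total Non-negative numbers.
#' @param digits Fixed number of decimals, or `NULL` for the adaptive rule.
#' @return Rounded percentage.
#' @export
format_percentage <- function(count, total, digits = NULL) {
  pct <- 100 * count / total
  if (is.null(digits)) {
    d <- ifelse(pct < 1, 2, 1)
    return(round_half_up(pct, d))
  }
  round_half_up(pct, digits)
}

#' Class summary: OTU counts, percentages, relative-abundance shares
#'
#' For each abundance class: the OTU count, its percentage of all OTUs
#' (adaptive rounding, see [format_percentage()]) and the class's share of
#' total reads. Can be driven by a table + classification, or directly by
#' per-class counts (`n_by_class`, `total`) when only the arithmetic is
#' needed.
#'
#' @param table A [community_table()] (ignored when `n_by_class` given).
#' @param classification An `abundance_classification`.
#' @param n_by_class Optional named integer vector of per-class OTU counts.
#' @param total Total OTUs (defaults to `sum(n_by_class)`).
#' @param reads_by_class Optional named vector of per-class read sums.
#' @param digits Decimals for percentages, or `NULL` for adaptive.
#' @return data.frame of class `"class_summary"`: `class`, `n_otus`,
#'   `pct_otus`, `pct_reads`.
#' @export
summarize_classes <- function(table = NULL, classification = NULL,
                              n_by_class = NULL, total = NULL,
                              reads_by_class = NULL, digits = NULL) {
  if (is.null(n_by_class)) {
    stopifnot(!is.null(table), !is.null(classification))
    n_by_class <- base::table(classification$class)
    n_by_class <- setNames(as.integer(n_by_class), names(n_by_class))
    m <- unclass(table)
    cls <- setNames(as.character(classification$class), classification$otu_id)
    reads_by_class <- tapply(colSums(m)[classification$otu_id],
                             cls[classification$otu_id], sum)
  }
  total <- total %||% sum(n_by_class)
  pct <- vapply(n_by_class, format_percentage, numeric(1), total = total,
                digits = digits)
  pct_reads <- rep(NA_real_, length(n_by_class))
  if (!is.null(reads_by_class)) {
    reads_by_class <- reads_by_class[names(n_by_class)]
    reads_by_class[is.na(reads_by_class)] <- 0  # class with no OTUs
    pct_reads <- vapply(reads_by_class, format_percentage, numeric(1),
                        total = sum(reads_by_class),
                        digits = digits)
  }
  out <- data.frame(class = names(n_by_class),
                    n_otus = as.integer(n_by_class),
                    pct_otus = pct, pct_reads = pct_reads,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("class_summary", "data.frame")
  out
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Abundance class summary:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-9s %6d OTUs (%.6g%%)%s\n", x$class[i], x$n_otus[i],
                x$pct_otus[i],
                if (is.na(x$pct_reads[i])) "" else
                  sprintf(", %.6g%% of reads", x$pct_reads[i])))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: align inputs, rarefy, classify abundance, alpha
#' diversity (+ Faith PD when a tree is present), Bray-Curtis + geographic
#' Mantel/distance-decay + niche breadth, assembly-process partitioning (per
#' layer x abundance class), SparCC network, and the class summary. Optional
#' stages that fail (or lack inputs, e.g. no tree) are skipped with a logged
#' message; completed stage outputs are kept.
#'
#' @param table A [community_table()] (raw counts).
#' @param tree Rooted `phylo`, or `NULL` (assembly and PD stages skipped).
#' @param metadata A `sample_metadata` data frame, or `NULL` (spatial and
#'   group-wise stages skipped).
#' @param taxonomy Optional taxonomy data frame.
#' @param depth Rarefaction depth (default 10000).
#' @param abundant_threshold,rare_threshold Classification thresholds.
#' @param n_null Assembly null randomizations (default 1000).
#' @param n_bootstrap SparCC bootstrap replicates (default 100).
#' @param n_permutations Mantel permutations (default 999).
#' @param min_prevalence Network prevalence pre-filter (default 1/3).
#' @param assembly_classes Abundance classes analysed for assembly.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param outdir Optional directory for TSV outputs with provenance headers.
#' @return List of class `"pipeline_result"` with one element per completed
#'   stage plus a `log` of stage messages.
#' @export
run_pipeline <- function(table, tree = NULL, metadata = NULL, taxonomy = NULL,
                         depth = 10000, abundant_threshold = 0.001,
                         rare_threshold = 1e-4, n_null = 1000,
                         n_bootstrap = 100, n_permutations = 999,
                         min_prevalence = 1/3,
                         assembly_classes = c("abundant", "rare"),
                         seed = 1L, outdir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("pipeline: ", msg)
  }
  res <- list()
  t0 <- Sys.time()
  # --- align
  ws <- align_inputs(table, tree, metadata, taxonomy)
  res$working_set <- ws
  note("align: %d samples x %d OTUs", nrow(ws$table), ncol(ws$table))
  # --- rarefy
  rar <- rarefy(ws$table, depth, seed = derive_seed(seed, 1L))
  res$rarefied <- rar
  note("rarefy: depth %d, %d samples kept", depth, nrow(rar))
  meta <- if (!is.null(metadata))
    metadata[metadata$sample_id %in% rownames(rar), , drop = FALSE]
  # --- classify
  cls <- classify_abundance(rar, abundant_threshold, rare_threshold)
  res$classification <- cls
  res$class_summary <- summarize_classes(rar, cls)
  note("classify: %s",
       paste(sprintf("%s=%d", res$class_summary$class,
                     res$class_summary$n_otus), collapse = ", "))
  # --- diversity
  res$alpha <- alpha_diversity(rar)
  if (!is.null(ws$tree)) {
    tr <- ape::keep.tip(ws$tree, colnames(rar))
    res$faith_pd <- faith_pd(rar, tr)
  } else note("faith_pd: skipped (no tree)")
  # --- spatial
  res$bray_curtis <- bray_curtis(rar)
  if (!is.null(meta) && nrow(meta) >= 3) {
    geo <- geographic_distance(meta)
    res$geographic <- geo
    res$distance_decay <- distance_decay(
      res$bray_curtis[meta$sample_id, meta$sample_id], geo,
      n_permutations, seed = derive_seed(seed, 2L))
    res$niche_breadth <- levins_breadth(rar)
    res$breadth_comparison <- compare_breadth(res$niche_breadth, cls)
    if (!is.null(taxonomy) && "phylum" %in% names(taxonomy) &&
        length(unique(meta$layer)) >= 2) {
      phy <- relative_abundance_by_rank(rar, ws$taxonomy, "phylum")
      res$differential <- tryCatch(
        differential_abundance(phy[meta$sample_id, , drop = FALSE],
                               meta$layer),
        error = function(e) { note("differential: skipped (%s)",
                                   conditionMessage(e)); NULL })
    }
  } else note("spatial: skipped (no metadata)")
  # --- assembly
  if (!is.null(ws$tree)) {
    tr <- ape::keep.tip(ws$tree, colnames(rar))
    groups <- if (!is.null(meta)) meta[rownames(rar), "layer"] else NULL
    res$assembly <- tryCatch(
      run_assembly_analysis(rar, tr, groups = groups, classification = cls,
                            classes = assembly_classes, n_null = n_null,
                            seed = derive_seed(seed, 3L)),
      error = function(e) { note("assembly: failed (%s)",
                                 conditionMessage(e)); NULL })
  } else note("assembly: skipped (no tree)")
  # --- network
  res$network <- tryCatch({
    filt <- prevalence_filter(rar, min_prevalence)
    fit <- sparcc_correlations(filt, seed = derive_seed(seed, 4L))
    pv <- sparcc_pvalues(filt, fit, n_bootstrap, seed = derive_seed(seed, 5L))
    net <- build_network(fit, pv, cls, ws$taxonomy)
    list(fit = fit, pvalues = pv, network = net,
         summary = summarize_network(net), hubs = find_hubs(net))
  }, error = function(e) { note("network: failed (%s)",
                                conditionMessage(e)); NULL })
  note("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  res$log <- log
  res$seed <- seed
  class(res) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir, seed)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result with stages:",
      paste(setdiff(names(x), c("log", "seed")), collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs as provenance-stamped TSV files
#'
#' @param res A `"pipeline_result"`.
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in every header.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(res, outdir, seed = res$seed) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name, ...) {
    p <- file.path(outdir, name)
    write_tsv_provenance(df, p, seed = seed, ...)
    paths <<- c(paths, p)
  }
  if (!is.null(res$alpha)) w(res$alpha, "alpha_diversity.tsv")
  if (!is.null(res$classification))
    w(as.data.frame(res$classification), "classification.tsv")
  if (!is.null(res$class_summary))
    w(as.data.frame(res$class_summary), "class_summary.tsv")
  if (!is.null(res$bray_curtis))
    w(as.data.frame(res$bray_curtis), "bray_curtis.tsv", row_label = "sample_id")
  if (!is.null(res$niche_breadth))
    w(data.frame(otu_id = names(res$niche_breadth), B = res$niche_breadth),
      "niche_breadth.tsv")
  if (!is.null(res$differential)) w(res$differential, "differential_taxa.tsv")
  if (!is.null(res$assembly)) {
    parts <- do.call(rbind, lapply(names(res$assembly$partitions), function(g) {
      p <- res$assembly$partitions[[g]]
      data.frame(group = g, t(p$fractions), n_pairs = p$n_pairs,
                 n_bins = p$n_bins, check.names = FALSE)
    }))
    w(parts, "assembly_partition.tsv")
    scores <- do.call(rbind, lapply(names(res$assembly$scores), function(g)
      data.frame(group = g, res$assembly$scores[[g]])))
    w(scores, "pair_scores.tsv")
  }
  if (!is.null(res$network)) {
    w(res$network$network$edges, "network_edges.tsv")
    w(summarize_network(res$network$network)$node_stats, "network_nodes.tsv")
    w(res$network$summary$node_classes, "network_summary.tsv")
    w(res$network$hubs, "network_hubs.tsv")
  }
  invisible(paths)
}
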