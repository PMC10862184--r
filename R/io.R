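# Readers/writers for the formats the pipeline touches, and the in-memory
# containers every downstream module consumes.
#
# Conventions: on disk an OTU table has OTUs as rows and samples as columns
# (the common exported dialect); in memory it is a samples x OTUs integer
# matrix, the orientation community-ecology distance functions expect.

#' Construct and validate a community table
#'
#' A community table is a non-negative integer matrix with samples as rows and
#' OTUs as columns; row and column names carry the identifiers and must be
#' unique.
#'
#' @param counts Numeric matrix (samples x OTUs) with dimnames.
#' @return The validated integer matrix, classed `"comm_table"`.
#' @export
community_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("community table needs sample (row) and OTU (column) names")
  validate_community_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("comm_table", class(counts))
  counts
}

#' @rdname community_table
#' @export
validate_community_table <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  invisible(TRUE)
}

#' @export
print.comm_table <- function(x, ...) {
  cat(sprintf("Community table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.double(x)), big.mark = ",")))
  invisible(x)
}

#' Read / write an OTU count table
#'
#' Reads the common tab-separated OTU-table dialect: first column OTU ids
#' (header `#OTU ID` or any bare name), remaining columns one per sample.
#' Values are rounded to integers. Leading `#` provenance lines are skipped.
#'
#' @param path File path.
#' @return A [community_table()] (samples x OTUs).
#' @export
read_community_table <- function(path) {
  df <- read_tsv_table(path)
  otu_ids <- as.character(df[[1]])
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id in ", path, ": ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                 otu_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  if (any(is.na(m)))
    stop("missing value in count table ", path)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 otu_ids[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- otu_ids
  community_table(t(round(m)))
}

#' @param x A community table.
#' @param seed Optional seed recorded in the provenance header.
#' @rdname read_community_table
#' @export
write_community_table <- function(x, path, seed = NULL) {
  m <- t(unclass(x))  # OTUs as rows on disk
  write_tsv_provenance(as.data.frame(m, check.names = FALSE), path,
                       seed = seed, row_label = "#OTU ID")
}

#' Read / write a rooted phylogenetic tree (newick)
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce the
#' pipeline's invariants: unique tip labels, non-negative branch lengths
#' (missing lengths become 0), rooted topology.
#'
#' @param path File path to a newick tree.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse newick file ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse newick file ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop("negative branch length in ", path)
  if (!ape::is.rooted(tr)) stop("tree in ", path, " is not rooted")
  tr
}

#' @param tree An `phylo` tree.
#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated, one row per sample. Required columns: `sample_id`,
#' `site_id`, `layer` (one of `"surface"`, `"subsurface"`), `latitude`,
#' `longitude`, `elevation`. Any further numeric columns (pH, TP, TC, ...)
#' are kept as environmental variables.
#'
#' @param path File path.
#' @param layer_aliases Optional named character vector mapping nonstandard
#'   layer labels (e.g. `c("0-15cm" = "surface")`) onto the two canonical ones.
#' @return A `data.frame` classed `"sample_metadata"`.
#' @export
read_metadata <- function(path, layer_aliases = NULL) {
  df <- read_tsv_table(path)
  as_sample_metadata(df, layer_aliases)
}

#' @param df A data frame with the columns listed above.
#' @rdname read_metadata
#' @export
as_sample_metadata <- function(df, layer_aliases = NULL) {
  required <- c("sample_id", "site_id", "layer", "latitude", "longitude",
                "elevation")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required metadata column(s): ", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  if (!is.null(layer_aliases)) {
    hit <- df$layer %in% names(layer_aliases)
    df$layer[hit] <- layer_aliases[df$layer[hit]]
  }
  bad <- setdiff(unique(df$layer), c("surface", "subsurface"))
  if (length(bad))
    stop("layer value(s) outside {surface, subsurface}: ",
         paste(bad, collapse = ", "))
  if (any(!is.na(df$latitude) & abs(df$latitude) > 90))
    stop("latitude outside [-90, 90]")
  if (any(!is.na(df$longitude) & abs(df$longitude) > 180))
    stop("longitude outside [-180, 180]")
  rownames(df) <- df$sample_id
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @param metadata A `sample_metadata` data frame.
#' @param seed Optional seed recorded in the provenance header.
#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path, seed = NULL) {
  write_tsv_provenance(as.data.frame(metadata), path, seed = seed)
}

# names of the non-environment metadata columns
.metadata_core_cols <- c("sample_id", "site_id", "layer", "latitude",
                         "longitude", "elevation")

#' Environmental variables of a metadata table
#'
#' @param metadata A `sample_metadata` data frame.
#' @return Numeric matrix (samples x variables) of the extra columns.
#' @export
environment_matrix <- function(metadata) {
  extra <- setdiff(names(metadata), .metadata_core_cols)
  extra <- extra[vapply(metadata[extra], is.numeric, logical(1))]
  m <- as.matrix(as.data.frame(metadata)[, extra, drop = FALSE])
  rownames(m) <- metadata$sample_id
  m
}

#' Read / write a taxonomy lineage table
#'
#' Tab-separated with a first column of OTU ids and one column per rank
#' (kingdom ... genus); empty cells are missing ranks.
#'
#' @param path File path.
#' @return data.frame with rownames = OTU ids and one column per rank.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_table(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate OTU id in taxonomy")
  df <- df[, -1, drop = FALSE]
  df[] <- lapply(df, as.character)
  rownames(df) <- ids
  df
}

#' @param taxonomy Taxonomy data frame as returned by [read_taxonomy()].
#' @param seed Optional seed recorded in the provenance header.
#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path, seed = NULL) {
  write_tsv_provenance(taxonomy, path, seed = seed, row_label = "otu_id")
}

#' Align a count table, tree, metadata and taxonomy into a working set
#'
#' Restricts OTUs to the intersection of the table's OTUs and the tree's tips
#' (and the taxonomy's keys when given), and samples to those present in the
#' metadata; the tree is pruned to the retained OTUs. Every drop is reported
#' via `message()` and recorded in the returned object.
#'
#' @param table A [community_table()].
#' @param tree A rooted `phylo` tree, or `NULL` to skip tree matching.
#' @param metadata A `sample_metadata` data frame, or `NULL`.
#' @param taxonomy Optional taxonomy data frame.
#' @return A list of class `"working_set"` with elements `table`, `tree`,
#'   `metadata`, `taxonomy`, and `dropped` (lists of dropped OTU/sample ids).
#' @export
align_inputs <- function(table, tree = NULL, metadata = NULL, taxonomy = NULL) {
  otus <- colnames(table)
  keep_otus <- otus
  if (!is.null(tree)) keep_otus <- intersect(keep_otus, tree$tip.label)
  if (length(keep_otus) == 0)
    stop("empty OTU intersection between table and tree")
  samples <- rownames(table)
  keep_samples <- samples
  if (!is.null(metadata)) keep_samples <- intersect(keep_samples, metadata$sample_id)
  if (length(keep_samples) == 0)
    stop("no sample of the table has metadata")
  dropped_otus <- setdiff(otus, keep_otus)
  dropped_samples <- setdiff(samples, keep_samples)
  if (length(dropped_otus))
    message(sprintf("align_inputs: dropped %d OTU(s) absent from tree: %s",
                    length(dropped_otus),
                    paste(head(dropped_otus, 10), collapse = ", ")))
  if (length(dropped_samples))
    message(sprintf("align_inputs: dropped %d sample(s) without metadata: %s",
                    length(dropped_samples),
                    paste(head(dropped_samples, 10), collapse = ", ")))
  tab <- community_table(unclass(table)[keep_samples, keep_otus, drop = FALSE])
  if (!is.null(tree) && length(setdiff(tree$tip.label, keep_otus)))
    tree <- ape::keep.tip(tree, keep_otus)
  if (!is.null(metadata))
    metadata <- metadata[metadata$sample_id %in% keep_samples, , drop = FALSE]
  if (!is.null(taxonomy))
    taxonomy <- taxonomy[intersect(rownames(taxonomy), keep_otus), , drop = FALSE]
  structure(list(table = tab, tree = tree, metadata = metadata,
                 taxonomy = taxonomy,
                 dropped = list(otus = dropped_otus, samples = dropped_samples)),
            class = "working_set")
}

#' @export
print.working_set <- function(x, ...) {
  cat(sprintf("Working set: %d samples x %d OTUs (%d OTUs, %d samples dropped)\n",
              nrow(x$table), ncol(x$table),
              length(x$dropped$otus), length(x$dropped$samples)))
  invisible(x)
}
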