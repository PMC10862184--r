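# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed and a stream counter to a new seed in
#' `[0, 2^31 - 2]`, so that independent stages (samples, pairs, bootstrap
#' replicates) can each seed their own RNG stream without collisions between
#' nearby master seeds.
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer stream index.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, counter = 0L) {
  # Knuth-style multiplicative mix, kept inside 31 bits.
  h <- (as.double(seed) * 2654435761 + as.double(counter) * 40503 + 97) %%
    2147483647
  as.integer(h)
}

# Simple 32-bit FNV-1a hash of a character scalar, as an 8-char hex string.
# Used only to stamp output headers with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

provenance_header <- function(seed = NULL, extra = NULL) {
  parts <- c(
    sprintf("micropart %s", as.character(packageVersion("micropart"))),
    sprintf("date=%s", format(Sys.Date())),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    extra
  )
  paste0("# ", paste(parts, collapse = "; "))
}

# Write a data.frame (or matrix) as TSV with a provenance comment line.
write_tsv_provenance <- function(x, path, seed = NULL, extra = NULL,
                                 row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  if (!is.null(row_label)) {
    x <- data.frame(setNames(list(rownames(x)), row_label), x,
                    check.names = FALSE)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV skipping leading '#' comment lines but keeping a '#'-prefixed
# header row (the "#OTU ID" dialect).
read_tsv_table <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  first_data <- match(FALSE, is_comment)
  if (is.na(first_data)) stop("no data rows in ", path)
  # a leading comment line that contains tabs is a '#OTU ID'-style header row;
  # tab-free comment lines are provenance and dropped
  header_idx <- first_data - 1L
  if (header_idx >= 1L && grepl("\t", lines[header_idx], fixed = TRUE)) {
    lines <- c(sub("^#\\s*", "", lines[header_idx]),
               lines[first_data:length(lines)])
  } else {
    lines <- lines[first_data:length(lines)]
  }
  read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
             check.names = FALSE, stringsAsFactors = FALSE)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
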