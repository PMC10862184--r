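# Shared fixture builders; everything generated in code.

two_tip_tree <- function() ape::read.tree(text = "(A:1,B:1):0;")

# random integer community table, samples x OTUs
rand_table <- function(n, k, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * k, lambda), n, k,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("OTU_%04d", seq_len(k))))
  community_table(m)
}

# minimal valid metadata for n samples at given coordinates
meta_frame <- function(sample_id, lat, lon, layer = "surface",
                       site = sample_id) {
  as_sample_metadata(data.frame(
    sample_id = sample_id, site_id = site, layer = layer,
    latitude = lat, longitude = lon, elevation = 3000,
    stringsAsFactors = FALSE))
}

# brute-force Bray-Curtis double loop
bc_brute <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

# brute-force abundance-weighted beta-MNTD
bmntd_brute <- function(x, y, D) {
  px <- x / sum(x); py <- y / sum(y)
  sx <- names(x)[x > 0]; sy <- names(y)[y > 0]
  t1 <- sum(vapply(sx, function(i) px[i] * min(D[i, sy]), numeric(1)))
  t2 <- sum(vapply(sy, function(j) py[j] * min(D[j, sx]), numeric(1)))
  0.5 * (t1 + t2)
}
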