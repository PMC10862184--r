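test_that("rarefaction is an exact without-replacement subsample", {
  tab <- rand_table(5, 40, seed = 2, lambda = 50)
  r <- rarefy(tab, 1000, seed = 7)
  expect_true(all(rowSums(r) == 1000))
  expect_true(all(unclass(r) <= unclass(tab)))
  # deterministic given seed
  expect_identical(unclass(rarefy(tab, 1000, seed = 7)), unclass(r))
  # a sample already at depth is returned unchanged
  m <- matrix(c(600L, 400L), 1, 2,
              dimnames = list("s1", c("A", "B")))
  expect_identical(unclass(rarefy(community_table(m), 1000, seed = 1)), m)
  # single-OTU sample halves exactly
  m1 <- matrix(20000L, 1, 1, dimnames = list("s1", "A"))
  expect_equal(unname(unclass(rarefy(community_table(m1), 10000, seed = 1))[1, 1]),
               10000)
  # samples below depth are dropped with a message
  expect_message(r2 <- rarefy(tab, sum(tab[1, ]) + 1, seed = 1), "dropped")
  expect_lt(nrow(r2), nrow(tab))
  expect_error(rarefy(tab, 1e9, seed = 1), "below")
})

test_that("rarefied proportions match the hypergeometric expectation", {
  # one sample, two OTUs 30/70, depth 50: mean subsampled count must match
  # n*K/N within 3 SE over 200 seeds
  m <- matrix(c(30L, 70L), 1, 2, dimnames = list("s1", c("A", "B")))
  tab <- community_table(m)
  draws <- vapply(1:200, function(s) unclass(rarefy(tab, 50, seed = s))[1, 1],
                  numeric(1))
  expectation <- 50 * 30 / 100
  se <- sqrt(50 * 0.3 * 0.7 * (100 - 50) / (100 - 1)) / sqrt(200)
  expect_lt(abs(mean(draws) - expectation), 3 * se)
})

test_that("abundance classification uses strict thresholds on mean relative abundance", {
  # A: 50% everywhere -> abundant; B: exactly 0.1% -> moderate (strict >);
  # C: exactly 0.01% -> moderate (strict <); D: 0.001% -> rare
  m2 <- rbind(s1 = c(A = 100000, B = 200, C = 20, D = 2, E = 99778),
              s2 = c(A = 100000, B = 200, C = 20, D = 2, E = 99778))
  cls <- classify_abundance(community_table(m2))
  expect_equal(cls["B", "mean_rel_abund"], 0.001)
  expect_equal(as.character(cls["A", "class"]), "abundant")
  expect_equal(as.character(cls["B", "class"]), "moderate")
  expect_equal(as.character(cls["C", "class"]), "moderate")
  expect_equal(as.character(cls["D", "class"]), "rare")
  expect_error(classify_abundance(community_table(m2), 0.5, 0.6), "rare_threshold")
  # partition property on a random table
  tab <- rand_table(8, 300, seed = 5, lambda = 3)
  cc <- classify_abundance(tab)
  expect_equal(sum(table(cc$class)), ncol(tab))
})

test_that("subset_by_class partitions the OTU set and preserves counts", {
  tab <- rand_table(6, 120, seed = 9, lambda = 2)
  cls <- classify_abundance(tab, abundant_threshold = 0.012,
                            rare_threshold = 0.006)
  parts <- lapply(c("abundant", "moderate", "rare"), function(cl)
    subset_by_class(tab, cls, cl))
  expect_setequal(unlist(lapply(parts, colnames)), colnames(tab))
  for (p in parts)
    expect_equal(unclass(p), unclass(tab)[, colnames(p), drop = FALSE],
                 ignore_attr = TRUE)
  expect_error(subset_by_class(tab, cls, "bogus"))
})

test_that("rank aggregation conserves relative abundance", {
  tab <- rand_table(4, 10, seed = 3)
  tax <- data.frame(phylum = c(rep("P1", 3), rep("P2", 5), NA, ""),
                    row.names = colnames(tab), stringsAsFactors = FALSE)
  ra <- relative_abundance_by_rank(tab, tax, "phylum")
  expect_equal(unname(rowSums(ra)), rep(1, 4), tolerance = 1e-9)
  expect_true("Unclassified" %in% colnames(ra))
  # 30/70 two-phylum split
  m <- rbind(s1 = c(a = 30, b = 70))
  tx <- data.frame(phylum = c("X", "Y"), row.names = c("a", "b"))
  expect_equal(unname(relative_abundance_by_rank(community_table(m), tx, "phylum")[1, ]),
               c(0.3, 0.7))
  expect_error(relative_abundance_by_rank(tab, tax, "genus"), "genus")
})

test_that("alpha diversity matches the textbook estimators", {
  # uniform sample over 10 OTUs
  m <- matrix(100L, 1, 10, dimnames = list("s1", paste0("o", 1:10)))
  a <- alpha_diversity(community_table(m))
  expect_equal(a$shannon, log(10), tolerance = 1e-9)
  expect_equal(a$simpson, 0.9, tolerance = 1e-9)
  expect_equal(a$observed, 10)
  expect_equal(a$chao1, 10)  # no singletons -> Chao1 = Observed
  # worked 5-OTU vector against direct formula evaluation
  x <- c(50L, 12L, 3L, 1L, 1L)
  chao_oracle <- function(v) sum(v > 0) + sum(v == 1) * (sum(v == 1) - 1) /
    (2 * (sum(v == 2) + 1))
  ace_oracle <- function(v) {
    v <- v[v > 0]; rare <- v[v <= 10]
    S_ab <- sum(v > 10); S_r <- length(rare); N_r <- sum(rare)
    F1 <- sum(rare == 1); C <- 1 - F1 / N_r
    Fi <- tabulate(rare, 10)
    g2 <- max((S_r / C) * sum(seq_len(10) * (seq_len(10) - 1) * Fi) /
                (N_r * (N_r - 1)) - 1, 0)
    S_ab + S_r / C + F1 / C * g2
  }
  mm <- matrix(x, 1, 5, dimnames = list("s", paste0("o", 1:5)))
  aa <- alpha_diversity(community_table(mm))
  expect_equal(aa$chao1, chao_oracle(x), tolerance = 1e-9)
  expect_equal(aa$ace, ace_oracle(x), tolerance = 1e-9)
  # 20 random samples: all indices vs independent formulas
  tab <- rand_table(20, 60, seed = 11, lambda = 2)
  av <- alpha_diversity(tab)
  for (i in 1:20) {
    v <- unclass(tab)[i, ]; p <- v[v > 0] / sum(v)
    expect_equal(av$shannon[i], -sum(p * log(p)), tolerance = 1e-9)
    expect_equal(av$simpson[i], 1 - sum(p^2), tolerance = 1e-9)
    expect_equal(av$observed[i], sum(v > 0))
    expect_equal(av$chao1[i], chao_oracle(v), tolerance = 1e-9)
    expect_equal(av$ace[i], ace_oracle(v), tolerance = 1e-6)
    expect_gte(av$chao1[i], av$observed[i])
  }
  # empty sample flagged, not zero
  m0 <- rbind(s1 = c(a = 5L, b = 5L), s2 = c(a = 0L, b = 0L))
  expect_message(a0 <- alpha_diversity(community_table(m0)), "empty")
  expect_true(is.na(a0$shannon[2]))
  expect_equal(attr(a0, "empty_samples"), "s2")
})

test_that("Faith's PD follows the rooted convention and is monotone", {
  tr <- two_tip_tree()
  m <- rbind(s_both = c(A = 1, B = 1), s_a = c(A = 1, B = 0))
  pd <- faith_pd(community_table(m), tr)
  expect_equal(unname(pd["s_both"]), 2)
  expect_equal(unname(pd["s_a"]), 1)  # tip-to-root path
  # monotone non-decreasing as tips are added
  set.seed(20)
  for (rep in 1:20) {
    tr2 <- simulate_tree(15, seed = rep)
    ord <- sample(tr2$tip.label)
    m2 <- matrix(0L, 14, 15, dimnames = list(paste0("s", 1:14), tr2$tip.label))
    for (i in 1:14) m2[i, ord[1:(i + 1)]] <- 1L
    pds <- faith_pd(community_table(m2), tr2)
    expect_true(all(diff(pds) >= -1e-12))
  }
  # agrees with picante on a random table
  tab <- rand_table(6, 15, seed = 2, lambda = 1)
  tr3 <- simulate_tree(15, seed = 5)
  colnames(tab) <- tr3$tip.label
  skip_if_not_installed("picante")
  expect_equal(unname(faith_pd(tab, tr3)),
               picante::pd(unclass(tab), tr3, include.root = TRUE)$PD,
               tolerance = 1e-9)
  bad <- rand_table(2, 3, seed = 1)
  colnames(bad) <- c("X1", "X2", "X3")
  expect_error(faith_pd(bad, tr3), "absent")
})

test_that("Bray-Curtis matches the brute-force double loop", {
  tab <- rand_table(6, 20, seed = 13)
  d <- bray_curtis(tab)
  expect_equal(unclass(d)[seq_len(6), seq_len(6)], bc_brute(unclass(tab)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(d)[1:6, 1:6]))
  m <- rbind(s1 = c(a = 3, b = 0), s2 = c(a = 3, b = 0), s3 = c(a = 0, b = 9))
  d2 <- bray_curtis(community_table(m))
  expect_equal(d2["s1", "s2"], 0)
  expect_equal(d2["s1", "s3"], 1)
  m0 <- rbind(s1 = c(a = 1, b = 1), s2 = c(a = 0, b = 0), s3 = c(a = 2, b = 1))
  expect_message(d3 <- bray_curtis(community_table(m0)), "all-zero")
  expect_true(is.nan(d3["s1", "s2"]))
})
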