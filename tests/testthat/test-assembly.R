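test_that("phylogenetic binning respects the distance threshold and merging", {
  # star tree: every pairwise distance 2 -> one bin at threshold >= 2
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  bn <- phylo_bins(star, distance_threshold = 2.5, min_bin_size = 2)
  expect_length(bn$bins, 1)
  expect_setequal(bn$bins[[1]], c("A", "B", "C", "D"))
  # two deeply separated tight clades -> two bins
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):5,(C:0.1,D:0.1):5):0;")
  bn2 <- phylo_bins(tr, distance_threshold = 1, min_bin_size = 2)
  expect_length(bn2$bins, 2)
  expect_setequal(lapply(bn2$bins, sort), list(c("A", "B"), c("C", "D")))
  # partition + threshold property on simulated trees
  for (s in 1:5) {
    tr3 <- simulate_tree(200, seed = s)
    bn3 <- phylo_bins(tr3, distance_threshold = 0.5, min_bin_size = 12)
    expect_setequal(unlist(bn3$bins), tr3$tip.label)
    expect_true(all(lengths(bn3$bins) >= 12))
    D <- ape::cophenetic.phylo(tr3)
    for (i in seq_along(bn3$bins)) {
      dmax <- max(D[bn3$bins[[i]], bn3$bins[[i]]])
      if (!bn3$merged[i]) expect_lte(dmax, 0.5 + 1e-9)
    }
  }
})

test_that("beta-MNTD matches the brute-force nested loop", {
  tr <- two_tip_tree()
  x <- c(A = 1, B = 0); y <- c(A = 0, B = 1)
  expect_equal(beta_mntd(x, y, tr), 2)                 # patristic distance
  expect_equal(beta_mntd(x, x, tr), 0)                 # identical communities
  set.seed(3)
  for (rep in 1:10) {
    tr2 <- simulate_tree(10, seed = rep)
    D <- ape::cophenetic.phylo(tr2)
    x2 <- setNames(rpois(10, 2), tr2$tip.label)
    y2 <- setNames(rpois(10, 2), tr2$tip.label)
    if (sum(x2) == 0 || sum(y2) == 0) next
    expect_equal(beta_mntd(x2, y2, D = D), bmntd_brute(x2, y2, D),
                 tolerance = 1e-12)
  }
})

test_that("beta-MNTD agrees with picante's comdistnt", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(25, seed = 17)
  D <- ape::cophenetic.phylo(tr)
  set.seed(2)
  x <- setNames(rpois(25, 1.2), tr$tip.label)
  y <- setNames(rpois(25, 1.2), tr$tip.label)
  ours <- beta_mntd(x, y, D = D)
  pic <- as.numeric(picante::comdistnt(rbind(x, y), D, abundance.weighted = TRUE))
  expect_equal(ours, pic, tolerance = 1e-9)
})

test_that("beta-NRI flags degenerate nulls and signs phylogenetic clustering", {
  tr <- two_tip_tree()
  # identical supports: beta-MNTD is 0 under every taxa relabeling -> degenerate
  x <- c(A = 3, B = 1)
  expect_true(is.na(beta_nri(x, x, tr, n_null = 50, seed = 1)))
  # sister-restricted communities on a deep two-clade tree are clustered:
  # observed distance far below the shuffle expectation -> negative z
  tr2 <- ape::read.tree(text = "(((A:0.1,B:0.1):3,(C:0.1,D:0.1):3):0.5,((E:0.1,F:0.1):3,(G:0.1,H:0.1):3):0.5):0;")
  x2 <- setNames(c(1, 0, 0, 0, 0, 0, 0, 0), tr2$tip.label)
  y2 <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0), tr2$tip.label)
  z <- beta_nri(x2, y2, tr2, n_null = 200, seed = 4)
  expect_lt(z, 0)
  # determinism
  expect_equal(z, beta_nri(x2, y2, tr2, n_null = 200, seed = 4))
})

test_that("Raup-Crick hits its bounds and is symmetric", {
  set.seed(6)
  tab <- rand_table(8, 30, seed = 6, lambda = 4)
  # identical pair embedded in a varied table: obs BC = 0 below all nulls -> RC -1
  m <- unclass(tab); m[2, ] <- m[1, ]
  tab2 <- community_table(m)
  expect_equal(raup_crick(tab2, "S01", "S02", n_null = 200, seed = 2), -1)
  # symmetric in the two samples
  r12 <- raup_crick(tab, "S03", "S05", n_null = 200, seed = 9)
  r21 <- raup_crick(tab, "S05", "S03", n_null = 200, seed = 9)
  expect_equal(r12, r21)
  expect_true(abs(r12) <= 1)
  # empty sample on the OTU subset -> NA
  m0 <- unclass(tab); m0[4, 1:5] <- 0L
  expect_true(is.na(raup_crick(community_table(m0), "S04", "S01",
                               otus = colnames(tab)[1:5], n_null = 50, seed = 1)))
})

test_that("process partition applies the quoted thresholds and weights", {
  mk <- function(bnri, rc, w, pair = "p1") data.frame(
    sample1 = pair, sample2 = "x", bin = paste0("b", seq_along(bnri)),
    bnri = bnri, rc = rc, weight = w)
  # all beta-NRI = +3 -> pure heterogeneous selection
  p1 <- partition_processes(mk(c(3, 3), c(0, 0), c(0.5, 0.5)))
  expect_equal(unname(p1$fractions["heterogeneous_selection"]), 1)
  expect_equal(sum(p1$fractions), 1, tolerance = 1e-9)
  # all |bnri| <= 1.96 and rc = 0 -> pure drift
  p2 <- partition_processes(mk(c(1, -1.9), c(0, 0.5), c(0.3, 0.7)))
  expect_equal(unname(p2$fractions["drift"]), 1)
  # boundary values are NOT selection/dispersal (thresholds are strict)
  p3 <- partition_processes(mk(c(1.96, -1.96), c(0.95, -0.95), c(0.5, 0.5)))
  expect_equal(unname(p3$fractions["drift"]), 1)
  # enumeration oracle: 3 pairs x 2 bins, hand-computed weighted average
  sc <- rbind(
    data.frame(sample1 = "a", sample2 = "b", bin = c("b1", "b2"),
               bnri = c(2.5, 0), rc = c(0, 0.99), weight = c(0.6, 0.4)),
    data.frame(sample1 = "a", sample2 = "c", bin = c("b1", "b2"),
               bnri = c(-2.5, -2.5), rc = c(0, 0), weight = c(0.2, 0.8)),
    data.frame(sample1 = "b", sample2 = "c", bin = c("b1", "b2"),
               bnri = c(0, 0), rc = c(-0.99, 0.2), weight = c(0.5, 0.5)))
  p4 <- partition_processes(sc)
  manual <- colMeans(rbind(
    c(HeS = 0.6, HoS = 0, HD = 0, DL = 0.4, drift = 0),
    c(HeS = 0, HoS = 1, HD = 0, DL = 0, drift = 0),
    c(HeS = 0, HoS = 0, HD = 0.5, DL = 0, drift = 0.5)))
  expect_equal(unname(p4$fractions), unname(manual), tolerance = 1e-12)
  # NA scores drop out with weight renormalization
  sc$bnri[1] <- NA
  p5 <- partition_processes(sc)
  expect_equal(sum(p5$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(p5$fractions["dispersal_limitation"]),
               mean(c(1, 0, 0)), tolerance = 1e-12)
})

test_that("assembly scores are invariant to OTU and sample order", {
  st <- simulate_study(simulation_config(seed = 3, n_otus = 60, n_sites = 4))
  tab <- st$table
  tr <- ape::keep.tip(st$tree, colnames(tab))
  bn <- phylo_bins(tr, distance_threshold = 0.8, min_bin_size = 5)
  sc1 <- assembly_scores(tab, tr, bn, n_null = 100, seed = 11)
  set.seed(99)
  perm_o <- sample(ncol(tab)); perm_s <- sample(nrow(tab))
  tab2 <- community_table(unclass(tab)[perm_s, perm_o])
  sc2 <- assembly_scores(tab2, tr, bn, n_null = 100, seed = 11)
  key <- function(d) d[order(d$sample1, d$sample2, d$bin), ]
  expect_equal(key(sc1)$bnri, key(sc2)$bnri, tolerance = 1e-12)
  expect_equal(key(sc1)$rc, key(sc2)$rc, tolerance = 1e-12)
  expect_equal(key(sc1)$weight, key(sc2)$weight, tolerance = 1e-12)
  # weights sum to 1 over bins within each pair
  wsum <- tapply(sc1$weight, paste(sc1$sample1, sc1$sample2), sum)
  expect_equal(as.vector(wsum), rep(1, length(wsum)), tolerance = 1e-9)
})

test_that("run_assembly_analysis orchestrates groups and is deterministic", {
  st <- simulate_study(simulation_config(seed = 5, n_otus = 60, n_sites = 4))
  groups <- st$metadata[rownames(st$table), "layer"]
  a1 <- run_assembly_analysis(st$table, st$tree, groups = groups,
                              distance_threshold = 0.8, min_bin_size = 5,
                              n_null = 80, seed = 2)
  expect_setequal(names(a1$partitions), c("surface", "subsurface"))
  for (p in a1$partitions) expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  a2 <- run_assembly_analysis(st$table, st$tree, groups = groups,
                              distance_threshold = 0.8, min_bin_size = 5,
                              n_null = 80, seed = 2)
  expect_equal(a1$partitions$surface$fractions, a2$partitions$surface$fractions)
  # undersized groups are skipped with a message
  g2 <- c(rep("big", nrow(st$table) - 2), rep("tiny", 2))
  expect_message(
    a3 <- run_assembly_analysis(st$table, st$tree, groups = g2,
                                distance_threshold = 0.8, min_bin_size = 5,
                                n_null = 40, seed = 2),
    "skipped")
  expect_equal(names(a3$partitions), "big")
})
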