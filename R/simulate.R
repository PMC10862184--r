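# Synthetic-community generator: OTU tables, trees and metadata with the
# statistical structure the analysis assumes, under known assembly regimes,
# so every stage is testable without external data.
#
# The emulated design is a mountain-soil survey: 13 sites within a ~500 km
# extent, two grouped soil layers per site, rarefaction-scale read depths
# (10,000 / 5,000), and a lognormal regional abundance distribution in which
# a handful of OTUs are abundant (>0.1% mean relative abundance) and most are
# rare (<0.01%).

#' Simulate a random ultrametric phylogeny
#'
#' Pure-birth tree with tips relabelled `OTU_0001 ...`, branch lengths
#' rescaled so the root-to-tip depth is exactly 1.
#'
#' @param n_otus Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An ultrametric rooted `phylo`.
#' @export
simulate_tree <- function(n_otus, seed = 1L) {
  stopifnot(n_otus >= 3)
  set.seed(seed)
  tr <- ape::rphylo(n_otus, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("OTU_%04d", seq_len(n_otus))
  tr
}

#' Simulate a lognormal regional species pool
#'
#' Normalized lognormal abundances. With the default `sdlog = 2.5` fewer than
#' ~2% of OTUs exceed 0.1% pool abundance and well over half fall below
#' 0.01%, mimicking the skew of soil amplicon surveys.
#'
#' @param n_otus Number of OTUs.
#' @param meanlog,sdlog Lognormal parameters on the log scale.
#' @param seed Integer seed.
#' @return Named numeric vector of pool relative abundances summing to 1.
#' @export
simulate_pool <- function(n_otus, meanlog = 0, sdlog = 2.5, seed = 1L) {
  set.seed(seed)
  a <- if (sdlog == 0) rep(1, n_otus) else rlnorm(n_otus, meanlog, sdlog)
  a <- a / sum(a)
  names(a) <- sprintf("OTU_%04d", seq_len(n_otus))
  a
}

#' Simulate the sampling layout of a two-layer multi-site survey
#'
#' Sites are placed uniformly in a square of side `extent_km`, converted to
#' latitude/longitude around a mountain-belt anchor (38 N, 99 E); each site
#' contributes one sample per soil layer. Environmental covariates (pH, TC,
#' TN, ...) are drawn from plausible soil ranges with a layer offset, and are
#' descriptive only unless a selection regime ties weights to them.
#'
#' @param n_sites Number of sites (default 13).
#' @param layers Layer labels (default surface/subsurface).
#' @param extent_km Side of the square spatial extent in km (default 500,
#'   giving pairwise distances on the order of 10-500 km).
#' @param seed Integer seed.
#' @return A `sample_metadata` data frame, one row per site x layer.
#' @export
simulate_metadata <- function(n_sites = 13, layers = c("surface", "subsurface"),
                              extent_km = 500, seed = 1L) {
  set.seed(seed)
  xy <- matrix(runif(2 * n_sites, 0, extent_km), ncol = 2)
  lat0 <- 38; lon0 <- 99
  km_per_deg <- 6371 * pi / 180
  lat <- lat0 + xy[, 2] / km_per_deg
  lon <- lon0 + xy[, 1] / (km_per_deg * cos(lat0 * pi / 180))
  elev <- runif(n_sites, 2500, 4100)
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  df <- expand.grid(site_id = site_ids, layer = layers,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$site_id, df$layer), ]
  idx <- match(df$site_id, site_ids)
  layer_off <- ifelse(df$layer == "surface", 0, 1)
  df <- data.frame(
    sample_id = paste(df$site_id, df$layer, sep = "_"),
    site_id = df$site_id, layer = df$layer,
    latitude = lat[idx], longitude = lon[idx], elevation = elev[idx],
    pH = round(runif(n_sites, 5.5, 8.5)[idx] + 0.1 * layer_off, 2),
    TC = round(rlnorm(n_sites, 3, 0.4)[idx] * (1 - 0.2 * layer_off), 2),
    TN = round(rlnorm(n_sites, 0.5, 0.4)[idx] * (1 - 0.2 * layer_off), 3),
    MC = round(runif(n_sites, 5, 40)[idx], 1),
    AMT = round(runif(n_sites, -4, 4)[idx], 1),
    stringsAsFactors = FALSE)
  as_sample_metadata(df)
}

# spatially correlated site effects: one MVN draw per OTU over sites with an
# exponential-decay kernel on between-site distance
.spatial_site_effects <- function(site_km, n_otus, range_km) {
  K <- exp(-site_km / range_km)
  # numerical jitter for the Cholesky of near-singular kernels
  L <- chol(K + diag(1e-8, nrow(K)))
  t(L) %*% matrix(rnorm(nrow(K) * n_otus), nrow(K), n_otus)
}

#' Simulate communities under a known assembly regime
#'
#' One sample per metadata row, each a multinomial draw of `reads` individuals
#' whose expected composition depends on the regime:
#' Ecological regimes (all but homogenizing dispersal) first realize each
#' sample as a finite local community of `community_size` individuals drawn
#' from its expected composition — the demographic-drift stage — and then
#' sequence it with a multinomial draw of `reads`. Homogenizing dispersal
#' skips the demographic stage: mixing erases local demographic divergence,
#' which is precisely what distinguishes it from drift.
#' \describe{
#'   \item{drift}{every sample draws independently from the shared regional
#'     pool; composition differences are demographic plus sequencing noise.}
#'   \item{selection}{per-OTU traits evolve by Brownian motion on the tree;
#'     the two layers have contrasting environmental optima (1.5 trait-SD on
#'     each side of the trait mean) and sampling weights are
#'     `pool x exp(-(trait - optimum)^2 / (2 width^2))` with
#'     `width = 1/strength`, inducing heterogeneous selection between the
#'     environments.}
#'   \item{dispersal_limitation}{per-site pools are the regional pool
#'     perturbed by lognormal site effects correlated over `range_km`
#'     (exponential-decay kernel), so nearby sites share perturbations and
#'     similarity decays with distance.}
#'   \item{homogenizing_dispersal}{all samples draw from one shared, finite,
#'     well-mixed local pool: a single multinomial realization of
#'     `strength x reads` individuals from the regional pool, which collapses
#'     the rare tail onto one shared realized species set.}
#'   \item{mixed}{convex combination of the drift and selection weights.}
#' }
#'
#' @param pool Regional pool from [simulate_pool()].
#' @param tree Tree from [simulate_tree()] (needed for selection regimes).
#' @param metadata Layout from [simulate_metadata()].
#' @param regime One of drift, selection, dispersal_limitation,
#'   homogenizing_dispersal, mixed.
#' @param strength Regime strength: selection filter sharpness (default 3),
#'   dispersal lognormal effect scale (default 2), homogenizing-dispersal
#'   local pool size multiplier (default 5), mixed weight (default 0.5).
#' @param reads Reads per sample (default 10000).
#' @param range_km Spatial autocorrelation range for dispersal limitation
#'   (default 150 km).
#' @param trait_rate Brownian-motion rate on the unit-depth tree (default 1).
#' @param community_size Individuals in the local community realized before
#'   sequencing (default 1000); `Inf` disables the demographic stage.
#' @param seed Integer seed.
#' @return List of class `"simulated_communities"`: `table` (a
#'   [community_table()]) and `truth` (regime, traits, optima, site effects,
#'   the generating pool).
#' @export
simulate_communities <- function(pool, tree = NULL, metadata, regime = "drift",
                                 strength = NULL, reads = 10000,
                                 range_km = 150, trait_rate = 1,
                                 community_size = 1000, seed = 1L) {
  regime <- match.arg(regime, c("drift", "selection", "dispersal_limitation",
                                "homogenizing_dispersal", "mixed"))
  n <- nrow(metadata)
  k <- length(pool)
  strength <- strength %||% switch(regime, selection = 5, mixed = 0.5,
                                   dispersal_limitation = 2,
                                   homogenizing_dispersal = 5, drift = 0)
  truth <- list(regime = regime, strength = strength, pool = pool)
  W <- matrix(pool, n, k, byrow = TRUE,
              dimnames = list(metadata$sample_id, names(pool)))
  set.seed(derive_seed(seed, 101L))
  if (regime %in% c("selection", "mixed") && strength > 0) {
    if (is.null(tree)) stop("selection regimes need a tree")
    trait <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_rate))
    trait <- trait[names(pool)]
    # contrasting optima, 1.5 trait-SD on each side of the mean between the
    # two layer groups, so that within most bins the two environments favour
    # opposite trait extremes
    opt <- mean(trait) + ifelse(metadata$layer == metadata$layer[1], 1.5, -1.5) *
      sd(trait)
    # mixed keeps the default filter sharpness and uses strength as the mix
    width <- if (regime == "mixed") 1 / 5 else 1 / strength
    filt <- exp(-(outer(opt, trait, "-"))^2 / (2 * width^2))
    Wsel <- W * filt
    Wsel <- Wsel / rowSums(Wsel)
    W <- if (regime == "selection") Wsel else
      (1 - strength) * W + strength * Wsel
    truth$trait <- trait
    truth$optimum <- setNames(opt, metadata$sample_id)
  } else if (regime == "dispersal_limitation") {
    sites <- unique(metadata$site_id)
    site_meta <- metadata[match(sites, metadata$site_id), ]
    site_km <- geographic_distance(site_meta)
    z <- .spatial_site_effects(site_km, k, range_km)
    eff <- exp(strength * z)  # sites x OTUs
    site_pool <- sweep(matrix(pool, length(sites), k, byrow = TRUE) * eff, 1,
                       rowSums(matrix(pool, length(sites), k, byrow = TRUE) * eff), "/")
    W <- site_pool[match(metadata$site_id, sites), , drop = FALSE]
    dimnames(W) <- list(metadata$sample_id, names(pool))
    truth$site_effects <- z
  } else if (regime == "homogenizing_dispersal") {
    local_n <- max(1, round(strength * reads))
    realized <- rmultinom(1, local_n, pool)[, 1]
    lp <- realized / sum(realized)
    W <- matrix(lp, n, k, byrow = TRUE,
                dimnames = list(metadata$sample_id, names(pool)))
    truth$local_pool <- lp
  }
  demographic <- regime != "homogenizing_dispersal" && is.finite(community_size)
  counts <- matrix(0L, n, k, dimnames = list(metadata$sample_id, names(pool)))
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 1000L + i))
    w <- if (demographic)
      rmultinom(1, community_size, W[i, ])[, 1] / community_size
    else W[i, ]
    counts[i, ] <- rmultinom(1, reads, w)[, 1]
  }
  truth$community_size <- if (demographic) community_size else Inf
  structure(list(table = community_table(counts), truth = truth),
            class = "simulated_communities")
}

#' Default simulation configuration
#'
#' Desk-scale defaults emulating the survey design: 13 sites x 2 layers,
#' 500 OTUs, 10,000 reads per sample, lognormal pool (sdlog 2.5), drift
#' regime.
#'
#' @param ... Overrides for any field.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(...) {
  cfg <- list(n_sites = 13, layers = c("surface", "subsurface"),
              n_otus = 500, reads = 10000, meanlog = 0, sdlog = 2.5,
              regime = "drift", strength = NULL, extent_km = 500,
              range_km = 150, trait_rate = 1, community_size = 1000,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a complete study fixture
#'
#' One call generating tree, pool, metadata, communities and a clade-based
#' pseudo-taxonomy; optionally written to disk in the package's TSV/newick
#' dialects with provenance headers.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, `otu_table.tsv`,
#'   `tree.nwk`, `metadata.tsv` and `taxonomy.tsv` are written there.
#' @return List of class `"simulated_study"`: `table`, `tree`, `metadata`,
#'   `taxonomy`, `truth`, `config`, and `paths` when written.
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL) {
  seed <- config$seed
  tree <- simulate_tree(config$n_otus, seed = derive_seed(seed, 1L))
  pool <- simulate_pool(config$n_otus, config$meanlog, config$sdlog,
                        seed = derive_seed(seed, 2L))
  metadata <- simulate_metadata(config$n_sites, config$layers,
                                config$extent_km,
                                seed = derive_seed(seed, 3L))
  sim <- simulate_communities(pool, tree, metadata, config$regime,
                              config$strength, config$reads,
                              config$range_km, config$trait_rate,
                              config$community_size,
                              seed = derive_seed(seed, 4L))
  taxonomy <- clade_taxonomy(tree)
  out <- list(table = sim$table, tree = tree, metadata = metadata,
              taxonomy = taxonomy, truth = sim$truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(table = file.path(dir, "otu_table.tsv"),
                  tree = file.path(dir, "tree.nwk"),
                  metadata = file.path(dir, "metadata.tsv"),
                  taxonomy = file.path(dir, "taxonomy.tsv"))
    write_community_table(sim$table, paths$table, seed = seed)
    write_tree(tree, paths$tree)
    write_metadata(metadata, paths$metadata, seed = seed)
    write_taxonomy(taxonomy, paths$taxonomy, seed = seed)
    out$paths <- paths
  }
  class(out) <- "simulated_study"
  out
}

#' Clade-based pseudo-taxonomy for a simulated tree
#'
#' Cuts the cophenetic distances into `n_phyla` deep clades and labels them
#' `Phylum_A ...`, giving the aggregation layer something realistic to group.
#'
#' @param tree A `phylo` tree.
#' @param n_phyla Number of pseudo-phyla (default 8).
#' @return Taxonomy data frame (rownames = OTU ids; kingdom, phylum columns).
#' @export
clade_taxonomy <- function(tree, n_phyla = 8) {
  D <- ape::cophenetic.phylo(tree)
  hc <- hclust(as.dist(D), method = "average")
  grp <- cutree(hc, k = min(n_phyla, length(tree$tip.label)))
  df <- data.frame(kingdom = "Bacteria",
                   phylum = paste0("Phylum_", LETTERS[grp]),
                   row.names = names(grp), stringsAsFactors = FALSE)
  df[tree$tip.label, , drop = FALSE]
}
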