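---
title: "Methods: abundance classes, assembly processes and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance classes, assembly processes and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements, the choices that were genuinely open, and what its synthetic
validation does and does not establish.

## Data model

The pipeline operates on four objects: a samples × OTUs integer count
matrix (`community_table()`), a rooted phylogeny with branch lengths whose
tips are OTU ids, per-sample metadata (site, soil layer, coordinates,
elevation, environmental covariates), and an optional ranked taxonomy.
`align_inputs()` restricts everything to the shared OTU and sample sets and
logs every drop; all downstream stages assume an aligned working set. On
disk, tables are plain TSV (OTUs as rows, `#OTU ID` header accepted), trees
are newick, and every output carries a `#`-comment provenance line with the
package version and seed.

## Rarefaction and abundance classes

Rarefaction draws an exact without-replacement subsample (multivariate
hypergeometric, one draw per sample, via `vegan::rrarefy`) to an even depth;
samples below the depth are dropped and logged. The depths used throughout
the synthetic studies, 10,000 (bacteria-like) and 5,000 (fungi-like) reads,
mirror common practice for soil surveys.

An OTU is *abundant* when its mean relative abundance across all retained
samples is strictly above 0.1%, *rare* when strictly below 0.01%, and
*moderate* otherwise. Two decisions here were open and are now fixed:

* **After rarefaction.** Classification happens on the rarefied table, so
  the classes refer to the same library size at which all diversity metrics
  are computed. Users who classify on raw counts can call
  `classify_abundance()` on the unrarefied table.
* **Strict boundaries.** An OTU exactly at a threshold is moderate, which
  follows the strict inequalities in the convention's definition ("above
  0.1%", "below 0.01%").

Reported percentages use half-up rounding, one decimal by default and two
decimals below 1% — the mixed precision in which such surveys print their
class summaries (e.g. 0.62% of OTUs abundant but 92.1% rare).

## Diversity and spatial statistics

Alpha diversity uses the standard estimators (observed richness,
bias-corrected Chao1, ACE with rare-abundance cutoff 10, Shannon in natural
log, Simpson as 1 − D) via vegan. Faith's PD is the total branch length of
the minimal subtree spanning a sample's OTUs *and the root*; the rooted
convention is fixed so a single-taxon sample has its tip-to-root path as PD,
and `include_root = FALSE` switches to the unrooted variant.

Bray-Curtis dissimilarity, geographic great-circle distance (haversine,
radius 6371 km) and per-variable environmental distances feed a Mantel test
whose statistic is the Pearson correlation of upper-triangle entries and
whose p-value is two-sided on |r| under joint row/column permutation,
`p = (1 + #{|r*| ≥ |r|}) / (1 + n_perm)` with 999 permutations by default.
When n! does not exceed the permutation budget (n ≤ 6 at the default), the
test enumerates all permutations and the p-value is exact. Distance decay
reports, alongside the Mantel result, the OLS slope of similarity
(1 − Bray-Curtis) against kilometres. Levins' niche breadth is
`B = 1 / Σ p²` over an OTU's across-sample proportions; classes are
compared with a two-sided Mann-Whitney test. Differential abundance between
groups uses per-taxon Kruskal-Wallis with tie correction and BH adjustment
across taxa; constant taxa get p = 1 by convention and are flagged.

## Assembly-process partitioning

The inferential core follows the phylogenetic-bin null-model framework:

1. **Binning.** A greedy root-to-tip traversal turns a clade into a bin as
   soon as its maximum within-clade patristic distance is at most the
   threshold; bins below the minimum size are merged into the bin at
   minimal patristic distance and flagged. Defaults: threshold 0.5 on
   unit-depth trees and minimum size 12, fixed once by measuring bin sizes
   on default 500-tip simulated trees (median around 20–25 OTUs). Merged
   bins can exceed the distance threshold; they are marked in the result.
2. **βMNTD / βNRI.** For each pair and bin, the abundance-weighted
   between-community mean nearest-taxon distance is standardized against a
   taxa-shuffle null (OTU labels permuted across the bin's tips, abundances
   fixed; 1000 randomizations). This within-bin taxa shuffle is the single
   biggest modelling choice; it conditions on the bin's abundance profile
   and asks only whether the *placement* of abundance on the bin's tips is
   unusual. One null randomization is shared by all sample pairs of a bin
   (the standard vectorization of this engine); the exported per-pair
   functions draw their own nulls. A pair whose communities have identical
   support is degenerate under this null (every relabeling gives the same
   score) and is flagged rather than scored.
3. **Raup-Crick.** Null assemblages preserve each sample's within-bin
   richness and total abundance; species enter with probability
   proportional to their occupancy frequency and remaining individuals are
   filled proportional to total relative abundance.
   `RC = 2[P(null BC < obs) + ½P(null BC = obs)] − 1`, with ties resolved
   at 10⁻¹² tolerance.
4. **Partition.** βNRI < −1.96 → homogeneous selection; > +1.96 →
   heterogeneous selection; else RC < −0.95 → homogenizing dispersal;
   > +0.95 → dispersal limitation; remainder drift. The thresholds are the
   framework's fixed critical values and overriding them triggers a
   warning. Within a pair, bins are weighted by their mean relative
   abundance across the two samples (weights sum to 1 over bins); pairs are
   then averaged unweighted. Undefined scores drop out with weight
   renormalization. Whether a study weights bins by abundance or by pair
   counts is rarely stated; abundance weighting is this package's choice
   and is recorded here.
5. **Groups.** `run_assembly_analysis()` forms pairs within each group
   (abundance class × layer by default); cross-layer pairs are never mixed
   into a group. For regime-recovery experiments on the synthetic
   generator, selection between contrasting environments is diagnosed from
   between-environment pairs — the comparisons where the contrast applies —
   and spatial dispersal limitation from across-site pairs (within-site
   pairs sit at geographic distance zero and carry no spatial turnover
   information).

The βMNTD kernel (per-sample nearest-taxon distances plus the pair
reduction) is implemented in C, since the calibration studies run
hundreds of pairs × 1000 nulls × hundreds of taxa. `beta_nri_pairs()`
exposes a pair-list variant used for calibration over disjoint pairs.

## SparCC networks

Counts gain a pseudo-count of 1 and are converted to fractions by Dirichlet
posterior resampling (20 iterations averaged). For each resample the
log-ratio variance matrix is formed, basis variances are solved from the
sparse-system approximation, and up to 10 rounds of exclusion remove the
strongest pair above |ρ| = 0.1 before re-solving. Significance is a
permutation bootstrap (each replicate independently shuffles every OTU's
counts across samples; two-sided p with a floor of 1/(B+1), B = 100 by
default). Edges require |ρ| > 0.3 and p < 0.05; the significance direction
is implemented as p *below* the threshold. Because full amplicon tables are
dominated by double-zero rare OTUs, a prevalence pre-filter (present in at
least a third of samples by default) is applied before estimation; real
surveys that report network node counts far below their OTU counts have
applied some such unstated filter, and the value used here is explicit and
configurable. Harmonic closeness (sum of reciprocal shortest-path lengths,
normalized by n − 1) is used because co-occurrence networks are routinely
disconnected, where classic closeness is undefined; hubs are ranked by
degree with closeness as tiebreak, then id.

## The synthetic-data generator

`simulate_study()` emulates the survey design the analysis assumes: 13
sites in a ~500 km extent (pairwise distances of tens to hundreds of km),
two grouped soil layers per site, a lognormal regional pool (sdlog 2.5),
and read depths of 10,000/5,000. Desk-scale defaults use 500 OTUs so the
full pipeline runs in minutes; the lognormal class proportions quoted for
real surveys (<1–2% of OTUs abundant, the majority rare) emerge at
survey-scale richness, and the tests check them at 10,000 OTUs, where pool
generation is still instant. At 500 OTUs the same distribution yields a
milder skew; this is a property of normalized lognormal pools, not a knob.

All ecological regimes share a two-stage sampling scheme: each sample is
first realized as a finite local community of `community_size` individuals
(default 1000) drawn from its expected composition — the demographic-drift
stage — and then sequenced as a multinomial of `reads`. Pure
sequencing-depth noise at 10,000 reads makes samples far more similar than
any richness/abundance-preserving null expects (the Raup-Crick score pins
at −1), which is an observation about what ecological drift *is*: finite
community sizes, not sequencer resampling. The default of 1000 individuals
was fixed once, from a sweep, as the scale at which the drift generator
realizes the null model's own stochasticity (RC centred near zero).

* **drift** — every sample draws from the shared regional pool.
* **selection** — OTU traits evolve by Brownian motion (unit rate on the
  unit-depth tree); the two layers get contrasting optima at ±1.5 trait-SD
  and sampling weights are `pool × exp(−(trait − optimum)²/(2 width²))`
  with `width = 1/strength` (default strength 5). The ±1.5 SD contrast
  places the two environments beyond most bins' trait ranges, so each bin's
  two communities concentrate on opposite trait extremes — the
  configuration that makes within-bin heterogeneous selection detectable.
  Strength 0 reduces exactly to drift under the same seed.
* **dispersal_limitation** — per-site pools are the regional pool perturbed
  by lognormal site effects (scale = strength, default 2) correlated over
  an exponential-decay kernel (range 150 km), so nearby sites share
  perturbations and similarity decays with distance.
* **homogenizing_dispersal** — all samples draw from one shared, finite,
  well-mixed local pool: a single multinomial realization of
  `strength × reads` individuals (default strength 5) of the regional pool.
  Mixing erases local demographic divergence (no demographic stage), which
  is exactly what distinguishes homogenization from drift.
* **mixed** — a convex combination of the drift and selection weights.

What passing the regime-recovery tests shows: the scoring and partitioning
machinery ranks the generating process first under each pure regime at
desk scale. What it does not show: that real soil communities at survey
scale would be partitioned with these proportions. The generator has no
sequencing error, no chimeras, no taxonomy misassignment, a single trait
axis, isotropic spatial structure, and independence between pool abundance
and phylogeny.

## Numerical choices and degenerate inputs

* Comparisons against null distributions use a 10⁻¹² tolerance for ties;
  null standard deviations below 10⁻¹² mark a score degenerate (`NA`).
* Scores are computed in a canonical sample order, so results are invariant
  to input row/column order; `raup_crick()` sorts its two samples.
* Seeds: every stage derives independent substreams from one master seed
  via an integer mixing function (`derive_seed`), keeping all derived seeds
  below 2³¹.
* Empty samples, all-zero OTUs, zero-variance matrices and empty networks
  are flagged or messaged, never silently zeroed.

## Problem sizes used by the tests

The test and acceptance runs use desk-scale sizes chosen as the package's
validation design: 26 samples × 500 OTUs with 1000 null randomizations for
regime recovery (pooled over three independent datasets for the
between-environment selection and across-site dispersal contrasts, whose
single-dataset margins are realization-noisy); 500 disjoint pairs of
null-generated 100-OTU samples for βNRI calibration (disjoint so the pair
z-scores are independent and their mean obeys the central limit theorem —
pairs sharing samples carry sample-level random effects that do not average
out within one dataset); 200 samples × 50 OTUs for SparCC validation; and
20 independent layouts for the drift distance-decay control.

## Known limitations

* Bin-level Raup-Crick has limited power to flag dispersal limitation:
  occupancy-weighted null draws that miss a bin-dominant OTU push null
  Bray-Curtis toward 1, giving the null a heavy upper tail that observed
  dissimilarities can rarely exceed. The dispersal-limitation recovery
  margin is therefore small (though consistently positive across seeds);
  whole-community Raup-Crick does not have this problem but is not what the
  bin framework prescribes.
* With abundance weighting, pairs dominated by a shared OTU are nearly
  invariant under the taxa-shuffle null, so homogeneous selection is hard
  to detect between near-identical communities; such pairs resolve to
  drift or are flagged degenerate.
* The greedy binning is a heuristic; forced merging can produce bins wider
  than the distance threshold (flagged), and bin boundaries move with the
  tree's depth scaling. The threshold default assumes unit-depth trees.
* SparCC assumes sparse true correlations; dense correlation structure
  biases the basis-variance solution even with exclusion rounds.
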