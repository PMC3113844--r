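---
title: "Control-region haplotype networks, rho dating and lineage geography with rhonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-region haplotype networks, rho dating and lineage geography with rhonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhonet)
```

## The analysis rhonet implements

Human mitochondrial population studies frequently rest on control-region
sequences alone: the two hypervariable regions (HVR-I, HVR-II) concentrate a
large share of mtDNA variability in a few hundred base pairs and are cheap to
obtain, so literature compilations of HVR haplotypes remain the densest
sampling of many populations. rhonet implements the standard analysis chain
for such data, built around a haplogroup-style panel of sequences encoded as
variants against the rCRS reference:

1. parse and validate variant tables (the printed-table encoding: dots for
   identity, `d` for deletions, `310i`-style insertion columns, blanks for
   missing data), trim them to analysis windows;
2. reconstruct the relationships among haplotypes as a weighted
   median-joining (MJ) network, post-processed by maximum parsimony (MP);
3. date the diversification of a chosen root lineage with the rho statistic
   and its Saillard variance, under genealogical or phylogenetic mutation-rate
   conventions;
4. compare the geographic dispersion of ancestral versus derived lineages
   with great-circle distances and a Mann-Whitney U test;
5. simulate synthetic panels with known truth so every stage is testable
   without external downloads.

## Haplotypes, coverage and distances

A haplotype is a set of variant keys (position, kind, insertion index) with
derived states, plus explicit *coverage intervals*. Coverage matters because
compiled panels mix records sequenced over different windows: a record with
no HVR-II data is not "identical to the reference" there, it is silent. All
pairwise comparisons are therefore restricted to sites covered in *both*
sequences (pairwise-complete, not listwise, deletion of missing data).

Contiguous deleted positions (e.g. the common 290-291 dinucleotide deletion)
are merged into a single mutational event by default, following the
event-counting convention of network software; `merge_deletions = FALSE`
disables this. Each insertion key is one event.

## Site weights and exclusion sets

Control-region sites mutate at wildly heterogeneous rates, and the fastest
sites recur often enough to obscure phylogenetic signal. Two standard
defences are implemented:

* **Down-weighting.** Each site's weight derives from its relative mutation
  rate (1.0 = the average of the site's region). The rule is anchored at
  weight 8 for an average site and weight 6 for a site at twice the average;
  those anchors define the linear rule `w = round(10 - 2r)`, clipped to
  `[1, 10]`. The phrase "inverse proportional" is sometimes used for this
  convention, but a strictly inverse rule (`w = round(8/r)`) would give 4 at
  `r = 2` and break the second anchor; rhonet defaults to the linear rule and
  offers the strict-inverse form behind `method = "inverse"` for sensitivity
  analysis.
* **Exclusion.** Three published exclusion lists ship as built-ins
  (`builtin_exclusions()`): the five HVR-I hypervariable sites ignored in
  network construction; the four extra HVR-II sites plus poly-stretch indels
  ignored in joint HVR-I+II networks; and the 41 fast sites (rates at least
  three times their regional average) excluded, together with all indels,
  from rho under the phylogenetic rate convention. Sites excluded from an
  analysis are removed from distances *and* from haplotype identity: two
  sequences differing only at excluded sites collapse into one node, so
  zero-weight links cannot arise.

## Median-joining networks and maximum parsimony

`build_msn()` computes the minimum-spanning network: identical haplotypes
collapse into multiplicity-weighted nodes, and a link `(u, v)` is retained
when its weighted distance is within `epsilon` of the minimal distance at
which the components of `u` and `v` merge (at `epsilon = 0`, the union of
all minimum spanning trees). `epsilon` defaults to 0, the usual software
default.

`build_mj()` then iteratively proposes median vectors: site-wise majority
consensus haplotypes of triplets connected in the current network. At each
round the candidate that most reduces total network length is added (ties
broken lexicographically by state signature); the loop stops when no
candidate reduces the length. Because integer-weighted length decreases
strictly, termination is guaranteed; a `max_iter` cap guards regardless.
Where the three states at a site all differ no consensus exists and the
triplet is skipped — control-region panels are overwhelmingly biallelic per
site, so quasi-median generation is deliberately not implemented. The
returned network is the minimum-spanning network over the final node set,
augmented with any sampled-MSN link not realized by an equal-weight path
through medians, so the sampled MSN is always contained in the result up to
equal-length rerouting.

`mp_extract()` performs the MP post-processing: it finds *every*
minimum-weighted-length tree connecting the sampled nodes (medians allowed
as Steiner points) by exact search — iteration over median subsets with a
branch-and-bound spanning-tree enumeration pruned against the best length —
and prunes the network to the union of those trees. Exact search is limited
to 25 distinct nodes by default; above the cap a documented heuristic
(iterated heaviest-edge deletion) runs with a warning and reports a single
tree with `n_trees = NA`. Back mutations are counted as excess edge
occurrences per variant key: a key labelling `k` edges of a tree implies
`k - 1` state changes beyond a single origin.

All tie-breaking is lexicographic in node ids and no randomness is used, so
results are deterministic; permuting the input order changes node labels at
most.

## Rho dating

For a rooted tree, `rho_stat()` returns the multiplicity-weighted mean
number of mutations on the path from the root to each sampled sequence.
Computing rho on tree paths (not raw mismatches) lets back mutations count
as events; a `mode = "mismatch"` variant exists for comparison, and the two
agree exactly on recurrence-free data. Sequences identical to the root
haplotype count as tips at distance zero. The sampling variance follows
Saillard's estimator, `sigma^2 = sum_e n_e^2 l_e / n^2`, with `n_e` the
number of sampled sequences below edge `e` and `l_e` its mutation count, so
on a star of `n` unit branches `sigma^2 = 1/n` exactly.

`tmrca()` converts rho to calendar time with an explicit effective sequence
length `L` — never silently inferred from the data:

* genealogical convention: `T = rho / (L * mu * 1e-6)` generations times the
  generation span (default 25 years, settable to 30), with
  `mu = 11.7` mutations/base/million generations and raw (unexcluded)
  counts;
* phylogenetic convention: `T = rho / (L * mu * 1e-6)` years with
  `mu = 9.883e-2` mutations/base/million years, fast sites and indels
  excluded from the counts. Whether `L` is also reduced by the excluded
  sites is configurable (`reduce_L`, default off — the convention in the
  source literature is not stated).

`L` presets: 315 bp for the HVR-I truncation (np 16051-16365). For the
joint window the defined ranges give 360 + 316 = 676 (`L_JOINT`), but
published joint-window ages back-calculate to roughly 625; both presets ship
(`L_JOINT_IMPLIED`), with 676 the documented default. The standard error is
`dT = T * sigma / rho`, so `dT/T = sigma/rho` identically; at `rho = 0` the
age is 0 and `dT` is reported as `NA`.

`date_lineage()` locates the root by a variant motif (erroring with the
candidate list when the motif matches zero or several nodes) and, when a
sub-root of an already-rooted tree is named, restricts the tips to that
node's descendant subtree — the workflow used to date, say, the carriers of
one allele at a polymorphic root position separately.

## Geographic dispersion

`lineage_distances()` pools, per lineage class, the great-circle distances
between all unordered pairs of distinct populations carrying the same
lineage (lineages observed in one population contribute nothing).
Distances use the haversine formula on a sphere of radius 6371.0088 km
(the IUGG mean radius; values from other geodesy conventions differ by
under 0.2%). `mann_whitney()` compares two pooled distance samples: U from
midrank sums; for `n1 + n2 <= 12` the two-sided p comes from complete
enumeration of group assignments (valid under ties), otherwise from the
normal approximation with tie-corrected variance and a 0.5 continuity
correction. Both U statistics are reported, `U` being the smaller. Ties are
expected — identical coordinate pairs recur whenever two lineages share the
same two populations — hence the midrank/tie-correction choices.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure of a compiled
control-region panel; its defaults are fixed study conditions, not tuning
knobs:

* 170 sequences over the joint HVR-II (np 57-372) + HVR-I (np 16024-16383)
  window, with 40% of tips lacking HVR-II coverage — the proportions of a
  typical compilation in which only a subset of sources sequenced HVR-II;
* a star (sudden-expansion) genealogy of root age 300 generations by
  default — the regime in which a founder motif retains many exact carriers
  and rho dating's star assumption is meaningful; a Yule genealogy is
  available for structured scenarios;
* per-site Poisson mutation with intensity `mu * 1e-6 * r_s` per generation
  (`mu = 11.7`), where the relative rates `r_s` come from
  `synthetic_site_rates()`: the published hotspot lists at 3-6 times
  average and all remaining sites at one sub-average value chosen so each
  region's mean rate is exactly 1 — the defining property of a relative
  rate table. Mutation toggles the site between the reference base and its
  transition partner, so repeated hits produce genuine back and parallel
  mutations at hotspots;
* populations as 60 sites drawn uniformly in an Americas-scale bounding box
  (lat -55..55, lon -130..-35), about the number of distinct population
  entries a continent-wide compilation contains; each tip's location is a
  Gaussian displacement from its lineage's centre — dispersal sigma
  2000 km for carriers of the root motif (centre of the box) and 800 km
  (0.4 times) for each derived lineage (random centre) — snapped to the
  nearest population site. Lineage identity for dispersal is the haplotype
  observed in the standard 315-bp HVR-I window, the window in which
  compiled panels are comparable and downstream analyses pool lineages.
* one integer seed governs all randomness; replicate `r` of an experiment
  uses `seed + r`; the generator restores the caller's RNG state.

What the generator does *not* emulate: sequencing error, non-random
literature sampling (real compilations over-sample some regions),
insertion/deletion polymorphism (an indel channel is off by default),
population growth within lineages, and rate heterogeneity beyond the
hotspot-list shape. Passing tests therefore demonstrate the pipeline's
internal correctness and statistical behaviour under the stated model, not
the historical conclusions drawn from any real panel.

`recovery_experiment()` is the dating validation harness: star panels at a
known age (the default experiment uses 100 tips, 400 generations over the
315-bp window) are run end-to-end — simulate, connect to the known founder
motif, rho, Saillard variance, TMRCA — and the fraction of replicates whose
`T_hat +/- 2 dT` interval covers the truth is reported; 200 replicates give
coverage around 0.93, consistent with the nominal 95% of a 2-sigma
interval. Problem sizes throughout the test suite (panels of 5-25 distinct
haplotypes for exact MP work, 100-200 replicates for stochastic checks)
were chosen as the smallest that exercise each property cleanly.

## Numerical and design choices

* Coordinates are 1-based rCRS positions; insertions anchor to the
  preceding position (`310iC` inserts C after np 310); mtDNA circularity is
  not modelled (no analysis window wraps the origin).
* Blank table cells shrink coverage; a run of contiguous blank columns is
  one missing interval spanning the run's positions. A blank under a single
  isolated column is treated as a missing single site, not typographical
  identity.
* `round()` in the weight rule is round-half-up, so the printed anchors are
  met exactly regardless of banker's rounding.
* The exact Mann-Whitney enumeration threshold (12 pooled observations)
  keeps `choose(n, n1)` below 1000.
* The MP size cap (25 nodes) bounds the exact search at roughly 2^12 median
  subsets times spanning-tree enumeration; the tree count is additionally
  capped (default 10000) against tie explosions.

## Known limitations

* The greedy single-median acceptance rule in `build_mj()` can miss pairs
  of jointly beneficial medians. In mutation-saturated regimes (recurrence
  at essentially every site) this occasionally leaves the site-excluded
  network with *more* back mutations than the raw one; in the hotspot-driven
  regime the exclusion lists are designed for, exclusion consistently
  reduces back-mutation counts.
* Exact MP extraction is exponential and refuses panels above the size cap;
  the heuristic fallback reports one tree without optimality or count
  guarantees.
* Phylogenetic-rate TMRCAs published for joint HVR-I+II data cannot be
  reproduced from the stated rate and any stated window length by the
  linear conversion; the conversion convention behind such values is not
  documented, so rhonet reports what the stated formula gives and leaves
  the choice of `L` explicit.
* The Mann-Whitney normal approximation is used above 12 pooled
  observations; for the pooled-distance samples this analysis produces
  (dozens to hundreds of pairs) its error against exact enumeration is well
  under 0.02.
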