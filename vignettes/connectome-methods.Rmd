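---
title: "Methods: graph-theoretical group comparison of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical group comparison of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fcnet implements an end-to-end case-control analysis of resting-state
functional connectomes: from parcellated BOLD time series to group statistics
on network topology. This vignette explains the model behind each stage, the
parameters that matter and their defaults, what the synthetic cohort generator
does and does not emulate, and the numerical conventions adopted where the
methodology leaves a genuine choice.

## Pipeline overview

For each subject, the pairwise Pearson correlation of parcel time courses
defines a weighted, undirected connectivity matrix (`compute_fc()`), variance
stabilized by the Fisher transform z = artanh(r) where matrices are averaged
or compared edgewise (`fisher_z()`). Because absolute connectivity levels
differ across subjects, networks are matched on *density*: at density d the
`round(d * N(N-1)/2)` strongest edges are retained (`proportional_threshold()`),
and all nodal analyses sweep d over 10-40% in 1% steps (`density_grid()`).
The lower bound guards against fragmentation of sparse graphs, the upper
bound is a liberal estimate of plausible cortical connectivity. Per-node
metric curves over the sweep are collapsed into a threshold-free summary by
the trapezoid area under the curve (`auc_over_densities()`), and those AUCs
carry all between-group inference.

Group-level community structure and hub classification run on the
group-averaged connectome: subject matrices are averaged in Fisher-z space,
back-transformed, and thresholded at the top 10% of connections
(`group_average_fc()`).

## Graph metrics and their weighted conventions

All metrics operate on nonnegative weighted networks. The weighted variants
follow the conventions of the standard brain-connectivity toolchain:

* **Path-based metrics** use edge length 1/weight. Characteristic path length
  is the mean shortest-path distance over reachable pairs; a `disconnected`
  attribute flags fragmentation rather than erroring, since thresholded
  subject networks can fragment. Global efficiency averages 1/distance with
  1/Inf = 0, so it is always defined.
* **Clustering** is the Watts-Strogatz triangle fraction on binary graphs and
  the Onnela geometric-mean triangle intensity (weights rescaled by the
  maximum) on weighted graphs; nodes with degree < 2 get 0.
* **Local efficiency** of a node is the global efficiency of the subgraph
  induced on its neighbors.
* **Modularity** is Newman-Girvan Q generalized to weights,
  Q = sum_s (w_ss/W - (s_s/2W)^2), with an optional resolution parameter.
* **Small-worldness** sigma = (CC/`<CC_null>`)/(CPL/`<CPL_null>`) against 100
  Maslov-Sneppen degree-preserving null networks by default, 20 rewiring
  attempts per edge. Whether clustering and path length should be computed on
  the weighted or binarized network inside sigma is not standardized; both
  modes are available (threshold with `mode = "binary"` for the binary
  variant) and weighted is the default, consistent with analyzing weighted
  networks throughout.

The Maslov-Sneppen null (`maslov_sneppen_rewire()`) performs double-edge
swaps that preserve every node's degree exactly; weights travel with their
edges, so the weight multiset is preserved but node strengths are not — the
convention of the cited randomization routines. Graphs with no valid swap
(e.g. a clique) are returned unchanged with a warning rather than looping
forever.

## Community detection and consensus

Louvain modularity maximization (`louvain()`) is implemented in compiled code
with a seed-controlled random node sweep order; modularity is asserted to be
non-decreasing over aggregation passes on every run. Because the algorithm is
greedy and stochastic, the partition used downstream is a consensus
(`consensus_partition()`): Louvain is repeated (1000 runs at study scale),
the node-pair co-assignment frequencies form an agreement matrix, entries
below tau = 0.5 are zeroed, and the agreement matrix is re-clustered
iteratively until all runs coincide. tau and the resolution (default 1) are
exposed as configuration; neither is prescribed by the underlying consensus
method, and 0.5 is the conventional midpoint.

## Hub quantification

Within-module degree z-score (`within_module_zscore()`) standardizes each
node's within-module strength against the other members of its module, using
the sample (n-1) standard deviation — matching the reference toolbox — with
zero-spread modules mapping to 0. The participation coefficient
(`participation_coefficient()`) is 1 - sum_s (k_is/k_i)^2.

Raw PC is known to be contaminated by within-module degree: two nodes with
identical between-module profiles get different PC when their intramodular
degree differs. The normalized variant
(`normalized_participation_coefficient()`) compares each node's PC against
its null distribution over degree-preserving randomizations in which **only
between-module edges are rewired** (within-module connections, and hence
every node's within-module strength, are untouched; swaps that would create a
within-module edge are rejected). The reported value is
clip(pc / median(pc_null), 0, 1): a node whose between-module edges are as
dispersed as chance scores near 1, a concentrated profile scores near 0, and
a node with no between-module strength scores 0. This isolates between-module
dispersion from intramodular degree by construction; the property tests
verify that |cor(PC_norm, within-module strength)| falls well below
|cor(PC, within-module strength)| on hub-heterogeneous planted graphs. The
default of 1000 randomizations is the count reported as sufficient for a
stable estimate. Where the reference implementation of the normalization is
unavailable, this package's form should be cited as its own convention: the
published criteria (thresholds at 0.5) retain their meaning because
at-chance dispersion maps to ~1 and concentration to ~0.

Hub roles use the quadrant rule: connector hub (WMZ > 1, PC_norm > 0.5),
provincial hub (WMZ > 1, PC_norm < 0.5), and the corresponding non-hub roles.
Inequalities are strict; exact boundary values classify conservatively
(non-hub / provincial).

Group-level hub detection runs on the 10%-density group-averaged network,
while the WMZ/PC/PC_norm values entering group statistics are computed per
subject per density under the subject's own consensus partition at that
density. Whether subject-level nodal measures should reuse the group
partition is genuinely open; subject-specific partitions were chosen because
the AUC summary requires per-subject curves that respect each subject's
modular structure at each density.

## Group statistics

**Nodal tests** (`nodal_test_suite()`): for each node and measure, a
two-sample Welch (unequal-variance) t statistic on the AUC values, assessed
by permutation of group labels (20,000 at study scale). Age is removed first:
covariates are demeaned, the values regressed on them, and both the observed
statistic and every permuted statistic computed on the residuals
(Freedman-Lane style randomization — the default of the permutation software
this emulates). P-values include the observed statistic,
p = (1 + #{|t*| >= |t|})/(B + 1), so p >= 1/(B+1). One permutation schedule
is shared across all nodes and measures, and a single Benjamini-Hochberg pass
over the pooled p-vector (nodes x measures jointly) controls the FDR at
q < 0.05. Residual-permutation nuisance handling is approximately exact; when
the nuisance covariate is correlated with the group factor (as age is in an
age-imbalanced case-control design), it errs slightly conservative — the
calibration suites verify that the type-I error never exceeds the nominal
level.

**Network-based statistic** (`nbs()`): edgewise Welch t on Fisher-z
connectivity (same nuisance handling), two one-sided suprathreshold graphs at
t > t_init and t < -t_init, connected components as test statistics (size =
edge count), and a component-level FWE-corrected p-value against the null
distribution of the maximal component size over permutations, pooled across
both directions. The default t_init = 3.9856 reproduces the reference
analysis's initial threshold; it is a required explicit parameter because the
appropriate value depends on the design. Note the stated initial threshold
does not correspond to p < 0.05 two-tailed at the study's degrees of freedom;
it is adopted as printed, not rationalized.

**Behavior associations** (`behavior_correlation_suite()`,
`partial_correlation_perm()`): partial Pearson correlations between a
behavioral score and each nodal AUC, residualizing both on age and group by
least squares, with permutation p-values and the same joint FDR. Subjects
with missing scores are excluded from this analysis only.

**Demographics** (`demographic_tests()`): pooled-variance two-sample t tests
(also available from printed summary statistics via
`pooled_t_from_summary()`) and Pearson chi-square tests without continuity
correction — the conventions that reproduce published participant tables.

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` produce the two-group study the
statistics are validated against: 28 vs 29 subjects, 250 timepoints, five
modules, at a desk-scale 90-node parcellation (scalable to 333). The signal
model is a stationary zero-mean multivariate Gaussian: downstream stages
consume only Pearson correlations, so hemodynamic convolution and temporal
autocorrelation would add realism without exercising any additional code
path. The generator does **not** emulate head motion, physiological
artifacts, scanner drift, or non-Gaussian BOLD features; passing tests
demonstrate correctness of the analysis pipeline under its statistical
assumptions, not robustness to acquisition artifacts.

The correlation template (`build_covariance()`) grades within-module
correlation by circular node distance (decay 0.85 per step, module mean
pinned to `within_r` = 0.5), emulating the spatial autocorrelation of real
parcellated BOLD. This gradation matters: with uniform within-module
correlations, proportional thresholding cuts arbitrarily into hundreds of
identical weights and isolates random nodes, which no real connectome shows.
Planted structure is likewise graded around an anchor in the target module:

* **Hubs** (one per module, default) couple to the next module with peak
  correlation equal to `within_r` — connector-like nodes whose cross-module
  edges survive thresholding and keep the 10% group network in one piece.
* **Effect nodes** (three, default) couple to their next two modules at
  between_r + 0.25; the case group shifts this by effect_delta = -0.15,
  a localized loss of between-module integration expressed in the
  participation coefficient.
* The **behavior node** couples to its next two modules at between_r + 0.22
  with a per-subject jitter (sd 0.10, truncated at ±2 sd to respect the
  correlation bound), so subjects genuinely differ in that node's
  between-module coupling. The behavioral score is built from each subject's
  *realized* nodal coupling — the mean Fisher-z connectivity between the
  behavior node and its target modules, measured from the generated time
  series — mixed with noise to correlate with that nodal metric at
  rho_behavior = 0.6. Anchoring the score to the realized metric (rather
  than the latent jitter) makes rho_behavior the planted value of the
  statistic the analysis estimates; anchoring to the latent parameter would
  attenuate the measurable correlation by the finite-scan sampling noise of
  the connectome itself.

Templates are repaired to the nearest PSD correlation matrix by clipping
negative eigenvalues and renormalizing the diagonal (the planted couplings
make the raw template mildly indefinite; the repair moves entries by at most
~0.02, and specs whose repair would exceed 0.05 are rejected as infeasible).
Ages are Gaussian with the control-like group shifted +1 year, mirroring the
case-control age imbalance that motivates the age covariate.

## Problem sizes used in the packaged simulations

The validation suites run at sizes chosen to make replicate simulations
routine on a laptop: replicate cohorts use the default 90-node cohort with a
4-point density grid (10/20/30/40%), 10 Louvain runs per subject-density
consensus, PC and WMZ as the tested measures, 9,999 permutations for nodal
suites and 19,999 for behavior correlations; the NBS calibration uses
30-node edge-level simulations with 199 permutations. Study-scale settings
(31 densities, 1000 Louvain runs, 1000 PC_norm nulls, 20,000/10,000
permutations) remain the defaults of `pipeline_config()` and are exercised
structurally by the unit tests.

## Numerical conventions and degenerate inputs

* Edge-count rounding is half-away-from-zero; weight ties break by
  lexicographic node order, so thresholding is deterministic.
* Negative correlations may be selected by signed-value ranking but are
  zeroed in the retained network (weighted metrics assume nonnegative
  weights); at densities >= 10% on typical FC almost all retained edges are
  positive. How negative edges should enter proportional thresholding is a
  convention, not a documented choice of the emulated analysis.
* Fisher z clips |r| at 1 - 1e-7 so unit correlations stay finite.
* Zero-variance parcels error by name at FC computation; zero-variance
  groups give t = 0, p = 1; singleton or zero-spread modules give WMZ = 0;
  isolated nodes give PC = 0.
* All randomness flows from one seed through named substreams (a hash of
  seed, stage and unit), so any stage can be re-run in isolation and subject
  order does not affect results.

## Known limitations

* The generator's behavioral score couples to a single node through one
  planted mechanism; real listening scores load on distributed networks.
* PC_norm's normalization is this package's reconstruction of the cited
  idea (null networks that preserve within-module structure); numerical
  values are not interchangeable with other implementations, though the
  classification semantics (0.5 threshold) are preserved.
* Weighted small-worldness inherits the ambiguity of its binary original;
  compare only within one convention.
* The NBS assumes edgewise exchangeability after residualizing the nuisance
  covariates; strong distributional violations would require exchangeability
  blocks, which are out of scope.
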