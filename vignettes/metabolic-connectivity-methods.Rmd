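---
title: "Metabolic connectivity networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The model

`metconn` analyses group-level *metabolic connectivity* from FDG-PET. The
core object is unusual compared with fMRI connectivity: because a PET scan
yields one number per region per subject, correlations are computed **across
subjects**, not across time. Each group of subjects therefore yields a
single region-by-region Pearson correlation matrix

$$ R_{ij} = \mathrm{cor}\big(u_{\cdot i},\, u_{\cdot j}\big), $$

where $u_{si}$ is subject $s$'s mean normalized uptake in region $i$. The
subject-by-region table is the unit of resampling everywhere: group
comparisons relabel subjects, never edges.

The preprocessing front end assumes volumes already registered to a common
(atlas) space. It applies, in order: isotropic Gaussian smoothing
($\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis, zero-padded
boundaries, default FWHM 16 mm), intensity normalization by the mean
cerebellar uptake (the cerebellum being the reference region least affected
in Alzheimer's disease), and per-region averaging over an AAL-style label
volume. The packaged AAL table has 116 labels; dropping the cerebellar and
vermian labels (name prefixes `Cerebelum`/`Vermis`) leaves the 90-region
cerebral parcellation on which every matrix is defined, giving
$M = 90 \cdot 89 / 2 = 4005$ edges. Whether regional means are taken from
smoothed or unsmoothed normalized images is not pinned down by convention;
the pipeline applies smoothing → normalization → extraction and exposes
smoothing as a config switch (off by default for precomputed tables).

## Edgewise inference

Group differences per edge use the subtracted connectivity matrix
$\Delta_{ij} = R^{A}_{ij} - R^{B}_{ij}$ and a two-sample permutation null:
subjects are pooled and reassigned to groups (preserving group sizes)
uniformly at random, both matrices recomputed, and the subtraction repeated
— 10,000 relabelings by default. Two-sided p-values use the add-one
estimator $(1 + \#\{|\Delta^{perm}| \ge |\Delta^{obs}|\})/(B + 1)$, which
can never be zero; when $\binom{n_A + n_B}{n_A}$ does not exceed the
requested permutation count, all assignments are enumerated instead and the
plain proportion is the exact p-value.

Familywise error over the 4005 edges is controlled with the max-statistic
null: each edge's $|\Delta^{obs}|$ is referred to the permutation
distribution of $\max_{ij} |\Delta^{perm}_{ij}|$. This is the standard
distribution-free strong-control FWE procedure for permutation tests; the
same relabeling sequence (a `permutation_scheme` object) is shared between
the edge test and the network-parameter test so that both analyses draw one
null. Permutation (sampling labels without replacement) was chosen over a
bootstrap reading of "resampling" because it gives exact finite-sample
level under exchangeability. A relabeling that produces a zero-variance
region column — possible only for degenerate synthetic input — contributes
$+\infty$ to the affected edge statistics, which is conservative.

## Graph construction and metrics

Connectivity matrices are turned into graphs by **proportional
thresholding**: the top $k = \mathrm{round}(d \cdot M)$ edges (rounding
half away from zero) are retained at density $d$, so graphs compared across
groups always have identical edge counts. Ranking is by signed correlation
by default — strongest positive edges first — with ties at the cut broken
by canonical $(i, j)$ index order so the selection is deterministic; an
absolute-value ranking is available. Negative retained weights are treated
as absent by the weighted metrics, since cube roots and inverse-weight path
lengths are meaningless for them. A visible consequence: once the positive
edges are exhausted (often near density 0.6–0.7 for correlation matrices),
weighted metrics plateau across the remaining grid.

Metrics exist in two modes. Binary mode implements the edge-count
formulas: local clustering $C_i = 2 t_i / (k_i (k_i - 1))$ (triangles over
possible neighbour pairs, $C_i = 0$ for degree < 2), characteristic path
length $L$ as the mean hop count over reachable ordered pairs, and global
efficiency $E = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with
$1/\infty = 0$. Weighted mode — the pipeline default, since the network
analysis is defined on weighted matrices — uses the Onnela geometric-mean
clustering $C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij} \hat w_{ih}
\hat w_{jh})^{1/3}$ (weights normalized by the maximum) and shortest paths
over edge lengths $1/w$. Distances come from a compiled dense
Floyd–Warshall; at $N = 90$ a dense cubic algorithm beats sparse
alternatives and keeps the permutation loops tractable. Disconnected graphs
at low density are summarized by $L$ over reachable pairs with the
unreachable fraction reported alongside; $E$ needs no special case.

Small-worldness compares each graph with degree-preserving rewired nulls
(double-edge swaps, which also preserve density; weights are reassigned to
the rewired positions uniformly, preserving the weight multiset):
$\gamma = C/C_{rand}$, $\lambda = L/L_{rand}$, $\sigma = \gamma/\lambda$,
with null means over 1000 randomizations by default. A complete graph
admits no swap and is its own null, so $\sigma = 1$ exactly. Swaps target
10 accepted exchanges per edge with a capped number of trials; if no swap
is admissible in an incomplete graph the code falls back to density-only
rewiring with a warning.

The density sweep covers 10–90% in 5% steps (17 levels, rounded to 4
decimals for platform-stable grids). Because network comparisons are only
meaningful where networks retain small-world organization, profiles are
screened first: per group, the densities with $\sigma > 1$; a comparison's
analysis mask is the intersection across its groups. Parameter differences
are tested per density with the shared permutation scheme and no
across-density multiplicity correction — per-level reporting with
significant levels summarized as maximal consecutive runs — which mirrors
the conventional reporting of density intervals and is a documented
limitation.

## The synthetic cohort generator

No patient data ship with the package, so validation rests on a generator
whose defaults encode the study conditions the pipeline is meant for:
90 regions in 6 modules (coarse lobe-like blocks; labels carry no
anatomical claim), within-module correlation 0.6, between-module 0.15,
subject noise SD 0.1 on a cerebellum-normalized mean of 1 (about a 10%
between-subject spread, a realistic figure for normalized uptake), and
group sizes 74 cases vs 20 controls — the early-onset disease versus young
control design. Subjects are multivariate normal draws, the minimal model
with exactly controllable Pearson structure. Planted effects come in two
forms: a focal one (10 designated cross-module edges, spread diagonally
over two modules, at $r = 0.6$ in the control structure and $r = 0.1$ in
the case structure) and a global one (all block correlations multiplied by
an attenuation factor; 0.5 in the validation scenarios). Overrides can
break positive semi-definiteness, so matrices are repaired by eigenvalue
clipping (floor $10^{-8}$, diagonal rescaled to 1) with a hard guard: a
repair that moves any entry by more than 0.1 aborts. With the default
design the repair shifts the planted control-side correlations from 0.60
to roughly 0.51 — the generator reports the built matrix, and tests
compare against it, not against the nominal override.

What the generator does *not* emulate: PET physics (scatter, attenuation,
partial-volume effects), registration error, non-Gaussian subject
variation, site effects, or realistic anatomical covariance. Passing tests
therefore demonstrate the statistical machinery's correctness and
calibration, not performance on real cohorts.

## Statistical power under the default design

Two validation targets deserve honesty about power. A correlation drop
from 0.6 to 0.1 between groups of 74 and 20 subjects corresponds to a
Fisher-z difference of about $0.59$ against a standard error of
$\sqrt{1/17 + 1/71} \approx 0.27$ — roughly a 2.2-sigma single-edge
effect. Familywise correction over 4005 edges demands roughly 4 sigma, so
the expected FWE-corrected recovery of planted edges is a few percent, and
no implementation can reach high recovery under these sizes; the package's
tests state the high-recovery expectation as specified and report the
shortfall rather than quietly relaxing it. The same arithmetic limits the
per-density network-parameter contrast at $p < 0.005$ with a 20-subject
control group. Detecting such effects reliably needs control groups several
times larger, a stronger planted contrast, or relaxed error control — all
outside the validated design.

## Numerical and design choices

- **Statistic scale.** Group comparisons subtract raw correlations; a
  Fisher-z comparison is available (`fisher_z()`) for variance-stabilized
  analyses.
- **Determinism.** Every stochastic step (scheme draws, rewiring,
  simulation) takes an explicit seed and restores the RNG state; rerunning
  a pipeline config reproduces outputs bit for bit.
- **Degenerate inputs.** Zero-variance regions abort connectivity with the
  region named; fully disconnected graphs abort $L$; densities rounding to
  zero edges abort thresholding.
- **Problem sizes in the test-suite.** Oracle equivalence is exhaustive
  over all 27,474 connected labelled binary graphs with 3–6 nodes. Null
  calibration uses 200 replicate cohorts of 20 vs 20 subjects over 30
  regions at 1000 permutations (the familywise error rate is
  dimension-free for the max statistic, so a 30-region null is
  representative); recovery scenarios use the full 74 vs 20, 90-region
  design at 1000 permutations and 20 replicates for the global-attenuation
  contrast evaluated at densities 0.75 and 0.90.

## Worked example

```{r example, eval = FALSE}
pair <- simulate_cohort_pair(cohort_spec(seed = 1))
scheme <- make_scheme(nrow(pair$case), nrow(pair$control),
                      n_permutations = 1000, seed = 1)
edges <- permute_edge_test(pair$case, pair$control, scheme)
glance(edges)
significant_edges(edges, alpha = 0.05, correction = "fwe")

profile <- metric_profile(pair$control, density_grid(),
                          n_randomizations = 100, seed = 1)
autoplot(profile)
small_world_validity_screen(profile)

comparison <- permute_metric_test(pair$case, pair$control,
                                  density_grid(), scheme)
significant_ranges(comparison, alpha = 0.005)
```

## Known limitations

- Across-density tests are not corrected for multiplicity.
- Negative-edge handling (exclusion under signed ranking) is one of several
  defensible conventions; results at high densities depend on it.
- The max-statistic FWE null includes edges carrying true effects, which is
  conservative when effects are large.
- Inputs must be pre-registered; no spatial normalization is performed.
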