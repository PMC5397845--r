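---
title: "Pattern recognition under nonspecific synaptic depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern recognition under nonspecific synaptic depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsplast)
```

## The scientific question

Cerebellar Purkinje cells are classically modelled as perceptrons that store
sparse binary input patterns by long-term depression (LTD) of the parallel-fibre
synapses activated together with the climbing-fibre teacher signal.  LTD at
these synapses, however, depends on nitric oxide, a messenger that diffuses
away from the active synapse and depresses neighboring, *inactive* synapses as
well.  This *nonspecific* LTD (nsLTD) is usually considered a defect: it blurs
the stored memory trace.  This package implements a linear-unit model in which
that intuition can be quantified, and in which nsLTD turns out to be an asset
once the recall cues themselves are corrupted by *local* noise — ON bits
displaced to neighboring input lines, as happens when clusters of neighboring
parallel fibres carry variable sensory signals.

## Model

A single linear unit receives `N` binary input lines (one per parallel-fibre
synapse), with weights `w` initialized at 1.  A pattern is a binary vector
with exactly `n_on` ON bits (default sparsity 0.7%).  Storing pattern `j`
updates every weight multiplicatively:

* the weight of each ON synapse is multiplied by the depression factor
  `d = 0.5`;
* under nsLTD, the weight of every synapse at distance `delta` from an ON
  synapse is multiplied by the kernel value:
  * **1D (ring)**: `1 - (1 - d) 2^(-delta)` for `delta` up to a radius of 1-3
    ring steps — the depression amount halves per neighbor step, so nearest
    neighbors are depressed to 0.75, next-nearest to 0.875, third to 0.9375;
  * **3D (Euclidean)**: `1 - (1 - d) exp(-delta^2 / 2 sigma^2)`, a unit-peak
    Gaussian of the distance in micrometers (no density normalization — the
    peak is pinned so that the center receives exactly `d`).

Contributions of all ON bits and patterns combine as products, so storage is
order-invariant and specific LTD yields `w_i = d^(hit count)`.  The response
to a pattern is the inner product `r = sum(w * x)`.  Recognition performance
over a set of `P` stored and `P` novel test patterns is the signal-to-noise
ratio

    s/n = (mu_s - mu_n)^2 / ((var_s + var_n) / 2),

with sample (n-1) variances; the statistic is invariant under a global
rescaling of the weights (both the squared mean difference and the variances
scale by the same factor — which is also why post-hoc weight normalization
cannot change the result).

**Recall noise.**  A fraction `alpha` of each stored pattern's ON bits is
displaced to a neighbor, drawn with probability proportional to the
depression amount the kernel applies at that distance (ring radius 1: 0.5 per
neighbor; radius 2: 1/3 and 1/6; 3D: inverse-CDF sampling of the Gaussian
kernel over the spine list with the center excluded).  Arity is preserved
exactly.  Optionally, `additive_fraction * n_on` extra ON bits are added in
the same neighborhoods.  Specific LTD has no kernel of its own, so it is
paired with the noise kernel of the nonspecific rule it is compared against —
both arms of a comparison see identical noise statistics.

**Homeostatic LTP.**  Each stored pattern may additionally potentiate all
synapses it leaves untouched by the factor
`L = 1 + f * sum(a) / (1 - f * m)`, where `f` is the sparsity, `a` the
per-site depression amounts over the `m` kernel sites.  `L` balances expected
depression against expected potentiation, keeping the mean weight at 1; at
`f = 0.007`, `d = 0.5` it evaluates to 1.0035 (specific), 1.0072, 1.0091 and
1.0101 (radii 1-3).  The balance is first-order in the non-overlap of
neighborhoods: at radius 3 (`f * m` about 5%) the realized mean weight drifts
upward by roughly a further 0.5% over 100 patterns, which the tests account
for.  For the linear unit the added potentiation leaves the s/n essentially
unchanged — a global weight inflation cancels in the statistic, and the
residual per-synapse variation is small.

## Closed-form theory

`analytic_response_moments()` re-derives the response mean and variance for
stored, noisy-stored and novel patterns under the assumption that the number
of times a synapse is hit by the ON bits (and kernel sites) of the stored
patterns is Poisson.  Writing `A = sum(a)` for the summed depression amounts
over all kernel sites and `B` for the analogous sum of `1 - multiplier^2`:

* a synapse exposed to all `P` patterns has `E[w] = exp(-P f A)` and
  `E[w^2] = exp(-P f B)` (novel-pattern readout);
* a synapse conditioned on being an ON bit of the read-out pattern counts
  `P - 1` other exposures, an explicit factor `d`, and a first-order factor
  `exp(-f (A - a_0))` for leakage from the read-out pattern's other ON bits;
* a displaced (or added) bit is read out at the leak-depressed weight of the
  neighbor it lands on, mixing over the kernel's target distribution; its
  same-pattern leakage factor runs over neighbor sites only, because a
  direct hit would have made the target ON, which the displacement rule
  excludes.

`analytic_snr()` evaluates the recognition statistic on these moments.  The
derivation is validated against Monte Carlo: across the noise grid at
`N = 147,400`, radius 1, the simulated s/n (10 repeats) tracks the closed
form within three standard errors, and at `N = 2,000`, `P = 20` the moments
agree with brute-force simulation within three sigma.  Two known limits: the
statistic computed from 100-pattern samples carries a small (~2-4%) upward
finite-sample bias relative to the population ratio, and at extreme noise
(`alpha >= 0.9`) for specific LTD the congestion fallback described below
shifts the tiny residual s/n by more than that — both inside the Monte-Carlo
error at the stated scales, except the specific-LTD curve at `alpha = 0.9`,
which the cross-check therefore does not assert.  The theory covers ring
kernels only; the 3D Gaussian case is studied by simulation.

## What the experiments show

With matched displacement noise on the ring (`N = 147,400`, 1000 ON bits,
100 stored patterns, 10 repeats):

* without noise, specific LTD outperforms radius-1 nsLTD by a factor of
  about 1.6 (analytically 1.57; bounded by 2);
* the specific-LTD curve falls steeply with `alpha` while the nsLTD curves
  are shallower — displaced bits land on synapses that the leaky rule
  depressed at storage time, so they still contribute a below-baseline
  readout; the mean curves cross at 30% noise for radius 1 (40% and 50% for
  radii 2 and 3);
* with combined displacement + additive noise, nsLTD starts winning already
  at 20%.  At higher combined noise the curves cross back: the added ON bits
  push the noisy-stored response *above* the novel mean, and the squared
  difference in the s/n statistic makes specific LTD "recognize" again.
  The persistent-dominance crossover is therefore undefined in this
  experiment, and the reported crossover is the onset (first level at which
  nsLTD wins).  `crossover_noise_level()` exposes both via `persistent=`;
  for displacement-only noise the two coincide.  At `alpha = 1.0` combined
  noise is combinatorially infeasible for a radius-1 kernel (2000 ON bits
  demanded within ~2000 neighbor slots); the sweep records such saturated
  levels as `NA` rather than aborting.

On the spatial model (`N = 14,740` spines, `sigma_LTD = sigma_noise =
0.75 um`), the same qualitative picture holds with a crossover at 50% on the
surrogate morphology (one 10% grid step above the value reported for the
reconstructed cell — see the geometry caveats below), and without noise the
s/n declines monotonically with the leakage width.  Sweeps over loading
(25-400 patterns) and sparsity (0.35-5.6%) preserve the sign pattern:
specific LTD wins at 10% noise, nsLTD at 60%, at every tested value.

## The synthetic data

`generate_pattern_set()` draws patterns uniformly: exactly `n_on` distinct ON
indices per pattern, patterns mutually independent (expected pairwise overlap
`n_on^2 / N`).  This emulates an idealized expansion-recoded granule-cell
population; real parallel-fibre activity is temporally structured and
correlated, so passing tests say nothing about temporal coding or correlated
pattern ensembles.

`build_synthetic_morphology()` provides the spatial synapse arrangement: a
random branched tree of straight 3-um compartments, ten spines per
compartment equally spaced along the axis (1474 x 10 = 14,740 spines,
total dendritic length ~4.4 mm), each spine head offset 1 um from the axis in
a random perpendicular direction (Purkinje spines measure about 1-1.5 um from
shaft to head).  Growth is self-avoiding: candidate directions whose segment
comes within 6 um of a non-adjacent compartment are resampled, emulating the
fact that spiny branchlets in the real arbor do not inter-digitate at
sub-micrometer range — without this, a random tree tangles and unrelated
branches dominate the sub-micrometer distance statistics.  Only these
~1-um-scale distance statistics matter for the Gaussian kernels studied
(sigma 0.25-0.75 um).  The surrogate does not reproduce the reconstructed
cell: compartment lengths are uniform rather than measured, the arbor is not
planar, and branch topology is random.  The 3D crossover level is the result
most sensitive to these choices (the spine spacing sets the local kernel
mass); it lands one grid step above the reconstructed-morphology value.
Real spine coordinates can be substituted via `read_layout()` (SWC or CSV).

## Numerical and design choices

* **Weights in log space.**  Training accumulates hit counts per kernel-site
  class (`tabulate()` on the ring; cached fixed-radius neighbor lists on a
  layout) and applies log-multipliers once — exactly equal to the dense
  product, in O(total ON bits x kernel size).
* **Kernel truncation.**  Gaussian kernels are truncated at `5 sigma`
  (multiplier within 2e-6 of 1 beyond); neighbor lookup uses a grid
  cell-list keyed by the cutoff and cached on the layout.
* **Collision handling in the noise model.**  Displacements operate on a
  working copy: origins are vacated first, a target must be OFF when
  accepted, vacated sites are eligible for later displacements, and clashes
  are resampled.  A congested bit with no eligible OFF neighbor — at high
  noise a bit's ring neighbors are all ON a few times per thousand
  displacements — keeps its position and a replacement ON bit is displaced
  instead, so the displaced count stays exact.  Additive noise falls back to
  sampling the remaining bits without replacement from the explicit set of
  free kernel slots when batch resampling stalls, and errors only at genuine
  saturation.
* **Crossover definition.**  Strict inequality, and by default persistence
  to the top of the grid (ties and single-level flukes do not count); the
  onset variant exists for the re-crossing additive-noise curves.
* **Seeding.**  Every sweep is determined by `master_seed`: per-repeat
  pattern seeds and per-condition noise seeds derive from it by a fixed
  counter scheme (`derive_seed()` in the sources) and are recorded in every
  result row.  Within a repeat, all rules share one stored and one novel set
  (paired comparison); novel patterns are drawn fresh per repeat.
* **Problem sizes.**  Full-scale runs (`N = 147,400`, 10 repeats) take
  seconds to a couple of minutes; the per-module tests use scaled-down
  versions of the same pipelines (`N = 2,000`-14,740, 2-5 repeats) and
  reserve the full scale for the headline checks.

## Limitations

The package deliberately models only the linear read-out unit.  The
conductance-based Purkinje-cell model that motivates it — with its
nonlinear dendritic integration, spike/pause response metric, and greater
benefit of nsLTD at lower noise levels — is out of scope, as are
reaction-diffusion models of the nitric-oxide plume itself, which is
abstracted into a fixed distance kernel.  The analytic module covers 1D ring
kernels; 3D results are simulation-only.  Storage-capacity analysis beyond
the loading sweep is not attempted.
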