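---
title: "Higher-criticism analysis of functional connectomes: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-criticism analysis of functional connectomes: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcfc)
```

## The scientific problem

Group studies of brain functional connectivity (FC) often face a *rare-weak*
situation: a condition alters a small fraction of the tens of thousands of
region-pair connections, and each alteration is individually too weak to
survive multiplicity correction. Edge-wise testing with Benjamini–Hochberg
FDR then reports nothing, even though the connectome as a whole clearly
differs between groups. The Higher Criticism (HC) statistic is designed for
exactly this regime: it asks whether the *collection* of edge-wise p-values
deviates from the uniform distribution expected under the global null,
and it attains (up to log factors) the optimal detection boundary for
rare-weak mixtures.

`hcfc` implements the full analysis chain around this idea: parcel-level
denoising, Fisher-z connectivity, per-edge linear models with nuisance
covariates, a three-level HC hierarchy with Monte-Carlo calibration,
edge-level FDR resolution, an exploratory sliding-window state analysis,
and a synthetic-cohort generator used to validate every stage.

## The Higher Criticism statistic

Given $N$ p-values sorted ascending, $p_{(1)} \le \dots \le p_{(N)}$,

$$\mathrm{HC}_N = \max_{1 \le i \le \lfloor \alpha_0 N \rfloor}
  \sqrt{N}\,\frac{i/N - p_{(i)}}{\sqrt{p_{(i)}\,(1 - p_{(i)})}},$$

with $\alpha_0 = 0.5$ by default (only the smaller half of the p-values
can contribute). `hc_statistic()` implements two variants:

* `"hc2004"` — the definition above, and
* `"hc_plus"` — the same maximum restricted to indices with
  $p_{(i)} > 1/N$, which guards against instability from a single minute
  p-value. If *no* p-value exceeds $1/N$ the restriction would leave an
  empty set, so the implementation falls back to the unrestricted maximum
  (this can only happen for wildly non-null inputs, where any sane statistic
  is enormous anyway).

Numerical choices worth knowing:

* p-values are clipped to $[10^{-10},\, 1 - 10^{-10}]$ before the
  standardization, so a p-value of exactly 0 or 1 cannot produce an
  infinite score; e.g. `hc_statistic(c(0.01, 0.5), "hc2004")` is
  `r round(hc_statistic(c(0.01, 0.5), "hc2004"), 4)`.
* HC has no convenient finite-sample null distribution, so calibration is
  Monte-Carlo: `hc_null_distribution()` draws uniform p-vectors of the same
  length $N$ and `hc_test()` reports the empirical p-value
  $(1 + \#\{\mathrm{HC}^{null} \ge \mathrm{HC}^{obs}\})/(M + 1)$, which can
  never be exactly zero. Replicate studies can share one null per
  $(variant, \alpha_0, N)$ via the `null_cache` argument.

## The three-level hierarchy

`run_hierarchy()` tests at three spatial scales, all computed from the same
per-edge model fits:

1. **Global**: HC over all parcel-pair edge p-values (29,403 edges for the
   default 243-parcel, 10-network atlas).
2. **Network**: within-network HC for each network's own edges, plus a
   between-network HC over the 45 network-pair edges obtained by
   correlating network-mean time series.
3. **Edge**: BH-FDR (q = 0.05) at global, between-network, and
   within-network scope. FDR is run unconditionally — reporting zero
   discoveries next to a significant HC is itself the scientifically
   interesting outcome, not an error state.

## Edge-wise models

For each edge, the Fisher-z connectivity value is regressed on an
intercept, a 0/1 group indicator, a 0/1 sex indicator, age standardized
with the sample (n − 1) standard deviation, and mean framewise
displacement (FD). The group effect is tested two-sided with
$df = n - 5$; partial $\eta^2 = t^2/(t^2 + df)$. All edges share a single
QR decomposition of the design, so fitting the full connectome is one
matrix operation. Degenerate edges (non-finite statistics or essentially
zero residual variation) are flagged rather than silently propagated.
The FD covariate matters: motion differs between clinical groups and
inflates connectivity estimates, so omitting it produces spurious group
effects — the acceptance suite demonstrates this directly.

## Denoising

The parcel-level chain follows common resting-state practice:

* **FD** in the Power convention (backward differences; rotations scaled
  by a 50 mm head radius). **DVARS** standardized by its own median so the
  spike threshold of 3 is scale-free.
* **Confounds**: 6 motion parameters, their backward-difference
  derivatives and both sets squared (24 columns), plus white-matter and
  CSF signals expanded the same way (8 columns).
* **Spikes**: one indicator column per frame with FD > 0.5 mm *or*
  DVARS > 3 (union).
* **Regression then filtering**: nuisance regression first, then an
  order-2 zero-phase Butterworth band-pass at 0.008–0.08 Hz
  (`signal::filtfilt`). Columns are demeaned before filtering — the mean
  is outside the passband anyway, and removing it first avoids large
  forward–backward edge transients.
* **Exclusion** (decided from FD *before* any regression): mean FD
  > 0.3 mm, max FD > 5 mm, or > 20 % of frames above 0.5 mm.

## Dynamic states

`run_dynamic_pipeline()` computes raw-correlation FC in 18-volume windows
with 60 % overlap (step = `round(18 * 0.4)` = 7 volumes; 31 windows at
234 volumes, 45 s per window at TR 2.5 s), pools all subjects' windows,
row-standardizes them (making Euclidean k-means equivalent to correlation
distance), and clusters over k = 2..10 with 20 restarts. The
Calinski–Harabasz index (maximized) selects k; the Davies–Bouldin index
(minimized) is the cross-check, and any disagreement is reported rather
than resolved — CH makes the decision. Per-subject metrics are the number
of transitions (NT), mean dwell time per state (MDT) and fraction of
windows per state (FRC), compared between groups by t-test (NT) and
Mann–Whitney (MDT, FRC).

A non-obvious pitfall this design dodges: correlation distance is
invariant to the *level* of connectivity, so states that differ only in
how strongly the same pairs couple are invisible to it. The synthetic
generator therefore makes its states differ in coupling *pattern* (which
disjoint network pairs are coupled), which is also the scientifically
interesting kind of state difference.

## The synthetic cohort generator

`simulate_cohort()` is the validation instrument, and its defaults are the
study conditions: 39 + 44 subjects, 243 parcels in 10 networks, 234
volumes at TR 2.5 s, within-network correlation 0.3, between-network 0.05.
Group effects are planted by shifting `round(eps * n_edges)` randomly
chosen edges by ±delta on the correlation scale and repairing the matrix
to the nearest positive-definite correlation matrix (`Matrix::nearPD`,
tolerance 1e-8). Covariate effects are additive on the z-scale. Motion is
a random walk matched to a target mean FD. Hidden states, when requested,
follow a Markov chain (default switch probability 0.05 per volume) over
covariance matrices that couple disjoint network pairs at 0.45.

What the generator deliberately does **not** emulate: between-subject
variance in the true connectome beyond sampling noise (every subject in a
group shares one population covariance), spatial autocorrelation within
parcels, hemodynamic lag, scanner drift, or non-Gaussian artifacts. It is
a test bed for the statistics, not a biophysical simulator.

All randomness flows from the single config seed through named substreams
(simulation, null calibration, k-means, covariates, states), each derived
with a fixed offset and kept below $2^{31}$, so every pipeline stage is
independently reproducible.

## Frozen calibrations

Two constants were fixed by pilot simulation *before* the acceptance suite
was written and are never revisited:

* **Rare-weak regime**: `effect_sparsity_eps = 0.06`,
  `effect_size_delta = 0.02`. At 60 parcels and n = 39 + 44 this puts the
  cohort inside the dissociation zone — global HC rejects in ~80 % of
  replicates while edge-wise BH-FDR finds nothing in ~77 % — without being
  so strong that single edges become individually significant.
* **State coupling** 0.45 for the hidden-state covariances, strong enough
  that the pooled window clustering recovers the planted two states.

## Problem sizes used in validation

The acceptance suite runs at desk scale: HC correctness on 1,000 random
p-vectors (N ≤ 50) against a brute-force oracle at 1e-10; level
calibration on 1,000 uniform nulls of N = 1,000 (Monte-Carlo null
M = 10,000), with the rejection count checked against the exact binomial
99 % band; the rare-weak dissociation on 100 replicates at 60 parcels;
edge-model bias on 200 replicates of n = 1,000; state recovery on a
20-subject, 40-parcel cohort; FDR and state metrics against brute-force
oracles exhaustively on small inputs. Full-scale (243-parcel) runs are
supported but take minutes rather than seconds per cohort, dominated by
the `nearPD` repair and the 29,403-edge null calibration.

## Limitations

HC answers a *detection* question ("is anything different?"), not a
*localization* one; when HC rejects and FDR finds nothing, the honest
summary is a distributed, individually sub-threshold effect. The
Monte-Carlo empirical p-value is bounded below by $1/(M+1)$. The linear
edge model assumes homoscedastic Gaussian errors and a common group
covariance; the generator satisfies these by construction, so real-data
robustness (heavy tails, site effects) is untested here. Window-based
state analysis inherits the usual arbitrariness of window length; the
18-volume default trades temporal resolution against correlation
estimability and is exposed as a parameter, not a law.
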