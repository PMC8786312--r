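---
title: "Methods: controlled numerosity stimuli and choice analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: controlled numerosity stimuli and choice analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishnum)
```

`fishnum` exists to make one experimental logic reproducible: if two dot
arrays differ in numerosity while every continuous magnitude is either
equated or deliberately randomized across conditions, then above-chance
choice that does not differ across conditions is evidence for the use of
numerical information. This vignette documents the models, the parameters
that matter, and the design decisions taken where a choice was genuinely
open.

## Stimulus model

A stimulus is a set of filled circular dots inside a circular field
(default radius 30 mm, i.e. a 6 cm outline circle), in continuous
millimetre coordinates with the origin at the field center and y up.
Rasterization samples pixel centers without anti-aliasing: reproducibility
and exact ink-area accounting are worth more here than smooth edges, and the
tests rely on the black-pixel count matching $\sum \pi r^2$ within 2%.

### Geometry controls (exact)

Within-array radii are uniform, and the radii of the second array are solved
in closed form from the first:

* *radius fixed*: both arrays share the sampled base radius;
* *equal total area*: $r' = \sqrt{\sum r^2 / n}$;
* *equal total perimeter*: $r' = \sum r / n$.

These constraints are exact (machine precision), and they fix the signature
of the uncontrolled magnitudes: at equal area the perimeter ratio between
the large and small array is $\sqrt{n_2/n_1}$; at equal perimeter the area
ratio is $n_1/n_2$; at fixed radius both scale with $n_2/n_1$. The property
suite asserts these to $10^{-9}$ relative.

Base radii are drawn uniformly from 3–4 mm. Dot sizes are interpreted as
diameters of 3–12 mm (so radii 1.5–6 mm are permitted); the 3–4 mm sampling
band is the single choice that keeps *every* solved radius inside the
permitted band for all comparisons used (up to 9 dots): the harshest case,
equal perimeter at 3 vs 6, maps 3 mm to 1.5 mm exactly. A solution outside
the permitted band raises an infeasible-condition error rather than
silently clipping. At a 400 mm effective viewing distance (screen 300 mm
above the water; the distance is a config value, not a measured quantity)
the permitted diameters subtend 0.43°–1.72°.

### Spatial controls (tolerance-based)

The spatial constraint equates either the convex-hull area or the mean
nearest-neighbor center distance between the two arrays, to within a
relative tolerance `rel_tol` (default 0.05). Placement is uniform rejection
sampling with a 1 mm minimum edge-to-edge gap (10,000 attempts, then up to
50 full restarts). Adjustment exploits similarity geometry: scaling the
centers about their centroid by $k$ scales mean nearest-neighbor distance
by $k$ and hull area by $k^2$ (exactly, for the centers polygon), so the
update factor is computed in closed form, damped into $[0.5, 2]$, capped by
field containment, and interleaved with overlap repair that rotates
offending dots about the centroid (which preserves their centroid distance
and therefore perturbs the metric only mildly). Both arrays are adjusted
toward the geometric mean of their initial metric values — a symmetric
target is markedly more feasible than forcing one array to match the
other. Infeasible targets (e.g. a hull larger than the field can hold) fail
with an adjustment-failure error after the iteration budget.

Two definitional choices deserve emphasis, because the underlying
quantities have no unique convention:

* **Convex hull over dot outlines, not centers.** The hull of two dot
  *centers* has zero area, yet 2 vs 3 comparisons must support a hull
  control; the hull of the disks (centers buffered by the radius) is well
  defined for every numerosity. It is computed by polygonizing each circle
  with 512 vertices (relative error < 10⁻⁴) and cross-checked in the tests
  against the exact Minkowski-sum closed form and a Monte-Carlo estimate.
* **Inter-distance as mean nearest-neighbor center distance.** This is the
  common spacing statistic in the numerosity literature, but note it is
  *not* the only reading, and the congruency lookup table (below) is a
  fixed coding scheme, not a quantity re-derived from this definition: the
  spatial columns' direction depends on which spacing statistic one adopts,
  whereas the area/perimeter columns follow analytically and are re-derived
  on generated stimuli in the tests.

### Congruency coding

Crossing the three geometry and two spatial controls gives six conditions.
For each, the four magnitude columns (overall area, overall perimeter,
convex hull, inter-distance) are coded congruent (C), incongruent (IC) or
equated (EQ); the congruency level is the number of C entries:

| condition | area | perimeter | hull | inter-dist | level |
|-----------|------|-----------|------|------------|-------|
| P-CH      | IC   | =         | =    | C          | 1a    |
| P-ID      | IC   | =         | C    | =          | 1b    |
| A-CH      | =    | C         | =    | C          | 2a    |
| A-ID      | =    | C         | C    | =          | 2b    |
| RF-CH     | C    | C         | =    | C          | 3a    |
| RF-ID     | C    | C         | C    | =          | 3b    |

Density and sparsity are defined relative to the hull
(density = n / hull area, sparsity its reciprocal per dot), matching the
trade-off that enlarging the hull at fixed numerosity lowers density.

## Spatial-frequency summary

The "total power" of a stimulus image is computed as: 2D FFT, modulus,
DC-centered; radial average over annuli one frequency sample wide
(membership by integer-rounded radius); sum over bins. Two options are
exposed because the verbal description of this statistic in the literature
mixes amplitude and power language:

* `use_power_not_amplitude` — average $|F|^2$ instead of $|F|$ (default
  amplitude);
* `dc_included` — keep the first bin (default excluded: DC encodes mean
  luminance, not pattern; with one-sample bins the first bin is *exactly*
  DC, which also makes the contrast-linearity property exact).

The per-condition index $(TP_2 - TP_1)/(TP_2 + TP_1)$ is therefore reported
under the full 2×2 option grid (`power_index_report()`), and the direction
per condition is treated as an empirical property of the stimulus set
rather than asserted: with amplitude averaging and DC excluded, the
generated sets show more spectral energy in the *more* numerous array under
fixed radius and less under equal perimeter; whether a given published
direction is reproduced depends on normalization conventions that are
rarely stated, which is precisely why the options are surfaced. Spectral
analyses render at 512² by default (the suite's invariance checks use
512², the pipeline default is configurable); Parseval's identity and
shift-invariance are asserted on every fixture.

## Protocol

Training sessions hold 48 trials — 12 each of RF-ID and RF-CH, 6 each of
A-ID, A-CH, P-ID, P-CH — so that in half the trials element size is
uninformative. The target side is balanced 24/24 and then shuffled, rather
than i.i.d. randomized: balancing removes a nuisance side bias at no cost.
The learning criterion is ≥ 75% correct (over responded trials; responding
is an attribute, not an error) on two consecutive sessions, boundary
inclusive. One criterion session alone already beats chance:
`criterion_binomial_p(36, 48)` = 3.6 × 10⁻⁴.

Tests are 24 unrewarded probes, three days of 8 ({2,2,1,1,1,1}). Each test
day interleaves 32 rewarded recall trials of the training comparison; the
recall count is per *session* — the reading that yields integer daily
counts — and configurable. Recall trials reuse the training composition
proportions (2:2:1:1:1:1).

## Choice statistics

* **Exact binomial**: two-sided p by the minimum-likelihood convention (all
  outcomes no more likely than the observed one) — a concrete, documented
  choice, identical to `binom.test`; Clopper–Pearson interval, matching the
  exactness of the test. The suite verifies the p-values against
  brute-force PMF enumeration for every (k, n) with n ≤ 50.
* **Cohen's g** = p̂ − 0.5, banded <0.05 negligible, 0.1–0.15 small,
  0.2–0.25 medium, >0.25 large. The scale leaves gaps; values in a gap go
  to the nearer boundary (ties upward), and banding is applied to the
  *unrounded* g — so 0.255 prints as 0.25 yet is large, while 0.25 exactly
  is medium.
* **GLMM**: binomial logit with a per-fish random intercept, ML with the
  Laplace approximation (`lme4::glmer`); `nAGQ ≥ 9` gives adaptive
  Gauss–Hermite quadrature as an internal cross-check. Trials are
  aggregated to binomial counts per fish × factor cell before fitting —
  identical estimates and standard errors for factor models, far cheaper
  refits. A boundary fit (variance 0) is reported as a legitimate estimate,
  and the zero-variance fit reproduces the plain logistic GLM to 10⁻⁶; the
  intercept-only GLM is exactly the logit of the pooled proportion.
* **Backward elimination** removes one term per step (highest-order first,
  marginality respected), keeping a removal only if the information
  criterion improves, on a single shared aggregation so criteria are
  comparable. The default criterion is **BIC**: with roughly 500–2000
  binary trials, AIC retains a spurious 2-df factor with probability
  ≈ P(χ²₂ > 4) ≈ 13.5%, so a null-data simulation would select the
  intercept-only model too rarely; BIC's log(n) penalty makes the null
  selection consistent. AIC remains available.
* **Tukey contrasts** via `emmeans` on the fitted model; with two levels
  the adjustment is the identity, and adjusted p never falls below
  unadjusted. The "non-parametric" label sometimes attached to such post
  hocs is treated as a terminological slip: the contrasts are model-based.
* **Summary-statistics t test** reconstructs group variances as
  $s^2 = n \cdot SEM^2$; pooled by default (df = n₁ + n₂ − 2), Welch
  optional; at equal n the two statistics coincide.

## Synthetic data: what it emulates, and what it does not

The simulator gives every fish a saturating-exponential learning curve on
the log-odds scale,
$\eta_s = \eta_0 + (\eta_\infty - \eta_0)(1 - e^{-\rho s})$, condition
offsets on the same scale, a response probability (default 0.85, inside
the 70–100% range typical of engaged fish), and per-comparison test
log-odds. Choices are independent Bernoulli draws. The "paper-like"
presets use generating truths of 0.819 (training asymptote) and 0.743
(uniform test probability) for the 3 vs 6 design, 0.755/0.698 for the
2 vs 3 design, and a learning rate of 0.25/session, which puts criterion
around sessions 8–10 (≈ 400–500 trials) — the scale observed in such
training. The study layouts are fixed: eight fish (four rewarded on the
smaller set, four on the larger) with tests 2v3/6v9 (rule-consistent),
the reversed comparison, and novel 5v8; or four fish trained 2v3 on the
larger set with tests 3v4 and 3v6.

What passing the end-to-end suite shows: the analysis pipeline recovers
known generating parameters (intercepts within 3 SE in ≥ 95% of runs,
intercept-only selection under the null in ≥ 90%, pooled proportions
within 3 binomial SD). What it does not show: real fish violate every
simplifying assumption — trial-to-trial dependence, motivation drift, side
biases, session-level variance, learning that is neither exponential nor
monotone. The simulator validates the *statistics*, not the biology; note
also that criterion-selected sessions are an upward-biased estimate of the
asymptote (selection on two consecutive high sessions), which is visible
in simulated training accuracies sitting near, not at, the generating
asymptote.

## Numerical conventions and degenerate inputs

* Determinism: every stochastic entry point takes a `seed` and restores
  the caller's RNG state (`withr::with_seed`); pipelines derive per-item
  substreams from the top-level seed by fixed counters, kept below 2³¹.
* Degenerate inputs fail loudly: single-dot inter-distance is an
  undefined-magnitude error; logit at 0 or 1, a constant vector in the
  Pearson correlation, and a zero/zero power index are domain errors;
  non-square images are rejected rather than resampled.
* Problem sizes in the shipped suites are chosen to keep the default run
  in minutes: 100 pairs × 6 conditions for the constraint round-trip, 200
  parameter-recovery fits, 100 null-selection runs, 1000 protocol seeds;
  spectral fixtures at 128–512².

## Known limitations

* Heterogeneous within-array radii are not generated (uniform radii are
  the simplest scheme consistent with the six-condition design); the
  magnitude and congruency machinery nevertheless handles them.
* The congruency table's spatial columns are a fixed coding, not
  re-derived (see the inter-distance definitional caveat above).
* Spectral results depend on the amplitude/power and DC conventions; both
  are exposed, neither is privileged beyond the documented default.
* No real-data ingestion beyond schema-compatible CSV; confidence
  intervals printed by other analyses of the same designs cannot be
  re-derived without their raw trial counts.
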