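---
title: "Deconvolving amino-acid transporter activities from uptake kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving amino-acid transporter activities from uptake kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aatdeconv)
```

## The problem

A cell monolayer — here, the hCMEC/D3 human brain microvascular
endothelial line used as an in vitro blood–brain barrier model — takes
up L-leucine through several solute carrier (SLC) amino-acid
transporters at once. Each transporter species has its own substrate
affinity and may or may not require extracellular sodium, but a tracer
uptake assay only measures their summed flux. `aatdeconv` solves the
resulting mixture problem: given uptake rates measured across a
concentration range in sodium-containing and sodium-free buffers, it
estimates how much maximal transport capacity each candidate species
contributes.

## The forward model

Each candidate activity $i$ is a plain Michaelis–Menten component with
a fixed literature affinity $K_{m,i}$ (mM) and an unknown maximal rate
$V_{\max,i} \ge 0$:

$$V(S, b) \;=\; \sum_{i} g_i(b)\, \frac{V_{\max,i}\, S}{K_{m,i} + S},$$

where $S$ is the substrate concentration (mM) and $g_i(b) \in \{0,1\}$
gates activity $i$ by buffer $b$: every species is active in sodium
buffer ("total" uptake); only sodium-independent species are active in
sodium-free buffer, where N-methyl-D-glucamine replaces sodium.
Deliberate simplifications: antiporters, symporters and uniporters are
all treated as independent saturable components (no exchanger
trans-substrate coupling, no membrane polarity, no intracellular
compartment), and $V_{\max,i}$ is assumed identical in both buffers —
the buffer contrast comes from gating alone.

The default candidate panel (`default_panel()`) holds eight kinetic
activities over seven genes: B0AT2 (SLC6A15, the only sodium
symporter), the antiporters LAT1, b0,+AT, y+LAT1, y+LAT2 and ASCT2,
and the facilitative uniporter LAT4, which exhibits biphasic leucine
kinetics and therefore enters as two activities (`LAT4_high`, Km
0.103 mM; `LAT4_low`, 3.73 mM). Km values are literature constants and
are **never refit**; the literature Vmax column is reference metadata
only, since those values come from heterologous systems in other
units.

## Units and normalization

Concentrations are handled internally in mM; files on disk declare µM
(the unit assay protocols are written in) and are converted on read.
Raw rates are pmol/(min·cm²) of filter area. Before fitting, the
dataset is normalized by the **sodium-buffer mean rate at the 300 µM
reference concentration**, and that single factor is applied to both
buffers' rows. A shared reference (rather than per-buffer references)
preserves the physical ordering total ≥ sodium-independent at every
concentration; the stored factor lets `denormalize_dataset()` recover
raw units exactly. All fitted $V_{\max,i}$ are therefore dimensionless
"normalized rate units"; multiply by the stored factor to return to
raw units.

The sodium-dependent component is also available descriptively as a
difference curve (`na_dependent_difference()`): total minus
sodium-free per shared concentration, SDs propagated in quadrature.
Negative differences — which arise from replicate noise at
concentrations where sodium-dependent flux is small — are retained and
flagged rather than clipped, because clipping at zero would bias any
curve fitted to the difference upward. Concentrations are matched by
exact value; the assays used shared grids, so no interpolation is
attempted.

## The inverse problem

`fit_species_global()` minimizes the weighted residual sum of squares
over all observations in both buffers simultaneously, with a single
shared $V_{\max}$ vector and bound constraints $V_{\max,i} \ge 0$:

* **Weights.** $1/\mathrm{sd}^2$ per observation when every SD is
  positive, otherwise unweighted; the scheme actually used is recorded
  in the result. Fits operate on replicate-mean observations;
  replicate-level data should be aggregated first.
* **Optimizer.** Levenberg–Marquardt (via `minpack.lm::nls.lm`) from
  16 seeded multi-starts, initial values log-uniform in $[10^{-3},
  10]$ normalized units. Because the model is *linear* in
  $V_{\max}$ once Km is fixed, every LM endpoint is then polished by
  an active-set refinement (ordinary least squares on the positive
  support, dropping negative coefficients and admitting zeroed
  coordinates whose gradient would reduce the residual), which is
  exact for this convex problem. The polish matters in practice:
  projected bound handling alone can stall when $1/\mathrm{sd}^2$
  weights span many orders of magnitude, as they do when a tracer-only
  point (10 nM) with a tiny SD sits alongside millimolar points. Best
  RSS wins; ties go to the smallest parameter norm.
* **Zero activities.** Estimates below $10^{-4} \times$ the largest
  fitted $V_{\max,i}$ are reported in the `zero_activity_set` — the
  model's way of saying a species' activity is not needed to explain
  the data.
* **Fit statistics.** Reduced $\chi^2$ = weighted RSS / DOF, with DOF
  counting only free (non-frozen) $V_{\max}$ parameters — fixed Km
  values are constants, not parameters. Adjusted $R^2 = 1 - (1 -
  R^2)(n - 1)/(n - p - 1)$ against the weighted total sum of squares.
* **Standard errors and conditioning.** SEs come from the
  pseudo-inverse of the weighted normal matrix at the optimum, scaled
  by the reduced $\chi^2$. The 2-norm condition number of the weighted
  design (free columns only) is reported as `jacobian_condition`; fits
  above the conventional condition-index bound of 30 are flagged
  `ill_conditioned` and their SEs marked unreliable.

`fit_species_restricted()` runs the identical procedure with selected
activities frozen at zero and excluded from DOF accounting — e.g.
asking whether the most highly expressed transporters alone explain
the data. `compare_models()` reports the changes in reduced $\chi^2$
and adjusted $R^2$ descriptively; no automatic selection rule (AIC/BIC)
is applied, by design.

### Identifiability

Not every direction of the 8-activity panel is estimable from a
13-concentration, 2-buffer design. Three sodium-dependent activities
have affinities within one doubling of each other (Km 0.160, 0.236 and
0.367 mM), so their basis functions are nearly proportional over the
assayed range, and LAT1 (0.032 mM, sodium-independent) is nearly
degenerate with y+LAT1 (0.0317 mM, sodium-dependent) within the sodium
buffer — only the sodium-free rows separate them. A structure with at
most one high- and one low-affinity activity per sodium class is well
identified: noiseless data generated from such a truth is recovered to
numerical precision, and at 5% replicate noise the median relative
error of each component stays in the single digits. In the full
8-activity fit the collinear trio instead shares flux among itself,
inflating SEs by orders of magnitude — exactly the behavior the
conditioning flag is there to surface. Consumers should treat a
flagged fit's per-species split within a collinear group as
undetermined even when the total fits well.

```{r identifiability, eval = FALSE}
p <- default_panel()
sim <- simulate_uptake(noise_scale = 0.05, seed = 41)
ds <- normalize_dataset(sim$dataset)
# near-collinear sodium-dependent trio: flagged, SEs unreliable
fit_species_restricted(ds, p, keep = c("B0AT2", "y+LAT2", "ASCT2"))
# well-separated structure: not flagged
fit_species_restricted(ds, p, keep = c("B0AT2", "LAT1", "LAT4_low"))
```

## Aggregate curve fits

`fit_aggregate_mm()` fits a single $(V_{\max}, K_m)$ pair to one
pooled curve (total, sodium-independent, or the difference curve) by
the same weighted Levenberg–Marquardt machinery, with SEs from the
local curvature. Degenerate inputs — fewer than three distinct
concentrations, flat or all-zero rates — return a result flagged
non-converged instead of throwing, so batch runs survive bad curves;
an all-zero curve reports $V_{\max} \to 0$ with Km marked
unidentifiable.

## qPCR expression arithmetic

The candidate panel itself is chosen from expression data, so the
package includes the comparative-CT arithmetic used for that step:

* `primer_efficiency()`: ordinary least-squares slope $m$ of CT
  against $\log_{10}$ template input; efficiency $E = 10^{-1/m} - 1$.
  A series must have ≥ 3 points spanning ≥ 1 log10 and a negative
  slope.
* `filter_primers()`: primers with $E \ge 1.6$ are accepted, the bound
  inclusive. Note an internal tension implemented **as specified**:
  under the formula above, perfect per-cycle doubling gives $E = 1$,
  so $E \ge 1.6$ nominally demands super-perfect amplification
  (per-cycle factor ≥ 2.6). Plausibly the intended quantity was the
  amplification factor $10^{-1/m}$ itself, for which 1.6 means 60%
  efficiency — but that is a guess, so the threshold is implemented as
  printed and left configurable rather than silently reinterpreted.
* `relative_expression()`: $\Delta C_T$ = mean target CT − mean
  reference CT (HPRT by default), expression $2^{-\Delta C_T}$.
  Technical replicates are averaged before $\Delta C_T$; replicate
  scatter is carried as metadata, not propagated through the power of
  two, matching how such results are summarized across biological
  samples.
* `fold_change()`: $\Delta\Delta C_T$ against a baseline condition,
  fold $2^{-\Delta\Delta C_T}$; the baseline against itself is exactly
  1. `expression_ratio()` compares two genes within one condition.
* Control reactions (−RT, no-template) must show no amplification:
  `qc_controls()` fails any control row with CT below the configurable
  "undetermined" cutoff (default 40 cycles).

No amplification-curve processing (raw fluorescence → CT) and no
efficiency-corrected quantification are included; the arithmetic
mirrors the comparative-CT method exactly.

## The synthetic-data generator

`simulate_uptake()` emulates the study's assay layout: the 13
assayed concentrations (0.01, 4, 10, 12, 20, 30, 50, 40, 100, 120,
300, 400, 1000 µM — the 10 nM point is the tracer-only condition),
both buffers, and 8 replicate "filters" per point (within the 5–12
used per concentration in practice). Replicate rates are drawn around
the panel forward model; the default noise model is proportional (5%
CV), chosen because uptake error bars grow with the mean — the true
assay scatter is not tabulated anywhere, so this default is a
realistic stand-in exposed in the configuration, not a claim about the
assay. An additive option exists for robustness tests. Negative
replicate draws are truncated at zero and counted. The default
four-activity ground truth (`default_truth()`) places activity on
B0AT2, y+LAT1, LAT1 and LAT4_low and zero on the other four species.

Two conventions keep the generator honest as a test oracle:

* Output is **raw-scale**; the ground-truth sidecar carries both the
  generating $V_{\max}$ vector and its normalized-scale equivalent
  (truth divided by the forward rate at the reference concentration in
  sodium buffer), which is what a fit of the normalized data actually
  recovers. Recovery tests compare on that scale.
* The truth is written to a separate sidecar JSON, never embedded in
  the data file, so fitting code cannot accidentally read it.

`simulate_dilution_series()` and `simulate_ct_table()` provide the
qPCR counterparts: with zero noise, `primer_efficiency()` recovers
`amplification − 1` exactly, and the CT generator encodes a gene's
relative expression as a $\log_2$ cycle offset below the reference
level (18.85 cycles, a typical HPRT level in this cell model), so the
comparative-CT pipeline inverts it exactly. All stochastic output is
fully determined by the configuration and seed.

What the generator does **not** emulate: non-Gaussian outliers,
day/passage batch effects, drift between independent experiments,
inter-filter correlation, or any mechanistic intracellular tracer
accumulation over the 1-minute uptake window (the initial-rate
assumption is taken as given). Tests passing on this generator
therefore demonstrate correctness of the estimation machinery under
the stated noise model, not robustness to every artifact of real
uptake data.

## Numerical choices and degenerate inputs

* Normalizing an already-normalized dataset is an error (an idempotence
  guard against double scaling); `denormalize_dataset()` inverts via
  the stored factor to 1e−12.
* A dataset with a single buffer condition fits with a warning:
  sodium-dependent activities are then structurally unidentifiable
  (their design columns vanish), the conditioning indicator is
  infinite, and only the sodium-independent subset is meaningful.
* Multi-start ties are resolved toward the smallest parameter vector
  norm; `n_starts_converged` counts starts reaching the best RSS
  within a relative 1e−8, so disagreement between starts is visible in
  the result rather than hidden.
* The zero threshold ($10^{-4}$ relative) is deliberately far below
  any biologically meaningful activity share; it distinguishes
  bound-hugging numerical zeros from small real contributions.
* In test suites, the optimizer is cross-checked against two
  independent routes: exhaustive grid search on two-parameter toys and
  a non-negative least-squares solve of the equivalent linear problem.
  The grid comparison is made in the objective's metric (the weighted
  quadratic form of the design): along a correlated valley the lattice
  argmin can sit more than one cell from the continuous optimum in raw
  coordinates while being indistinguishable at the grid's resolution,
  whereas a genuinely stalled optimizer shows an objective gap orders
  of magnitude above the one-cell increment.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at the study's
own scale: 13 concentrations × 2 buffers × 8 replicates per simulated
experiment; 100 seeded repeats for stochastic recovery at 5% CV; 200
Monte-Carlo repeats for the reduced-$\chi^2$ calibration; a 301 × 301
grid (resolution 0.01) for the brute-force comparison. A full
simulate-normalize-fit cycle takes well under a second, so these sizes
were chosen to make Monte-Carlo summaries stable, not to economize.

## Known limitations

* Per-species estimates inside a collinear affinity group are not
  individually meaningful (see Identifiability); the package flags but
  cannot resolve this — resolving it needs different data (inhibitors,
  broader concentration ranges, or knockdowns), not a different
  optimizer.
* $V_{\max,i}$ is assumed buffer-invariant; if sodium substitution
  itself altered a transporter's maximal rate, that effect would be
  misattributed.
* The reported SEs are local-curvature estimates scaled by reduced
  $\chi^2$; with few concentrations they understate uncertainty for
  parameters near the zero bound.
* Uptake is modeled single-compartment; apical and basolateral
  contributions are not distinguished, matching the assay geometry.
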