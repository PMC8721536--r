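# aatdeconv

Deconvolution of SLC amino-acid transporter species activities from
substrate uptake kinetics, with the qPCR expression arithmetic used to
assemble the candidate panel.

## The problem

Cells express several amino-acid transporters (AATs) for the same
substrate at once. An uptake assay — here, L-leucine uptake by the
hCMEC/D3 human blood–brain barrier endothelial model, measured across
a concentration range in sodium-containing (+Na⁺, "total") and
sodium-free (NMDG-substituted, sodium-independent) buffers — only sees
their summed flux. Which species carry that flux, and how much of it?

`aatdeconv` models each candidate activity *i* as a Michaelis–Menten
component with a **fixed literature affinity** K<sub>m,i</sub> and an
unknown maximal rate V<sub>max,i</sub> ≥ 0, gated by sodium
dependence:

> V(S, buffer) = Σᵢ gᵢ(buffer) · V<sub>max,i</sub> · S / (K<sub>m,i</sub> + S)

where gᵢ = 1 in sodium buffer, and 1 in sodium-free buffer only for
sodium-independent species. The per-species V<sub>max,i</sub> vector is
estimated by bounded multi-start global least squares over both buffer
curves simultaneously, with reduced χ² and adjusted R² fit statistics,
a zero-activity set (species whose estimate collapses against the
zero bound), and a collinearity diagnostic for affinity groups the
design cannot separate.

The shipped default panel holds the eight leucine-transporting kinetic
activities over seven genes expressed by this cell model — B0AT2,
LAT1, b0,+AT, y+LAT1, y+LAT2, ASCT2 and the biphasic LAT4
(high/low-affinity components) — with their literature Km values and
sodium flags.

The package also implements the comparative-CT qPCR arithmetic used to
choose candidates (primer efficiency E = 10^(−1/m) − 1 with the E ≥
1.6 acceptance filter, 2^−ΔCT relative expression vs HPRT, 2^−ΔΔCT
fold changes vs a baseline condition), and generators of study-shaped
synthetic uptake and qPCR data with known ground truth.

## Worked example

Simulate a noiseless experiment on the assayed design (13
concentrations from 10 nM to 1 mM, both buffers) from a four-activity
ground truth, normalize to the 300 µM sodium-buffer rate, and fit the
full eight-activity panel:

```r
library(aatdeconv)

panel <- default_panel()
sim <- simulate_uptake(noise_scale = 0, seed = 7)
ds  <- normalize_dataset(sim$dataset)
fit <- fit_species_global(ds, panel, seed = 7)
fit
#> Per-species Vmax fit (8 free of 8 activities; seed 7)
#>                vmax        se  zero frozen
#> B0AT2     2.502e-01 3.060e-14 FALSE  FALSE
#> LAT1      9.306e-02 8.024e-16 FALSE  FALSE
#> b0+AT     1.709e-15 1.041e-14  TRUE  FALSE
#> y+LAT1    2.169e-01 1.487e-15 FALSE  FALSE
#> y+LAT2    0.000e+00 5.475e-14  TRUE  FALSE
#> ASCT2     0.000e+00 2.663e-14  TRUE  FALSE
#> LAT4_high 0.000e+00 2.103e-15  TRUE  FALSE
#> LAT4_low  7.477e+00 1.833e-14 FALSE  FALSE
#> RSS 3.573e-31 on 18 DOF; reduced chi2 1.985e-32; adjusted R2 1.0000 (none weights)
#> Jacobian condition 2.33e+03 [ILL-CONDITIONED: SEs unreliable]; 16/16 starts at the optimum
#> Zero-activity set: b0+AT, y+LAT2, ASCT2, LAT4_high
```

Reading the output: exactly the four generating activities (B0AT2,
y+LAT1, LAT1, LAT4_low) come back with nonzero V<sub>max</sub> — in
normalized rate units, i.e. relative to the total uptake rate at
300 µM — and the other four land in the zero-activity set. The
perfect-fit statistics (reduced χ² ≈ 0, adjusted R² = 1) reflect the
noiseless input. The conditioning flag warns that the full 8-activity
design contains nearly collinear affinity groups (three
sodium-dependent Km within 0.16–0.37 mM; LAT1 vs y+LAT1 at 0.032 vs
0.0317 mM), so per-species SEs inside those groups are not to be
trusted even when the totals fit well — the central caveat of this
kind of deconvolution.

Per-species contribution curves show the crossover from the shared
high-affinity regime to low-affinity LAT4 dominance at high substrate:

```r
curves <- species_contribution_curves(fit)
round(curves[curves$s_mM %in% c(0.1, 1), c("s_mM", "B0AT2", "y+LAT1", "LAT1", "LAT4_low", "total")], 4)
#>     s_mM  B0AT2 y+LAT1   LAT1 LAT4_low  total
#> 21   0.1 0.0962 0.1647 0.0705   0.1952 0.5266
#> 201  1.0 0.2157 0.2103 0.0902   1.5807 2.0968
```

At 0.1 mM — physiological plasma leucine territory — the four
activities contribute comparably; by 1 mM the low-affinity LAT4
component carries ~75% of the flux.

With replicate noise (`noise_scale = 0.05`, the default 5% CV), fits
are weighted 1/sd², a restricted model can be compared descriptively,
and the file-level pipeline (`run_simulate_uptake()`,
`run_fit_species()`, `run_qpcr()`) reads and writes the CSV/JSON
formats documented in the function reference. A thin command-line
dispatcher over the same functions ships at `inst/cli/aatdeconv.R`.

## Package layout

| Piece | Contents |
| --- | --- |
| `R/panel.R` | transporter registry, forward flux model, default Table-of-constants panel |
| `R/uptake.R` | uptake dataset container, normalization, difference curve |
| `R/fit-aggregate.R`, `R/fit-species.R`, `R/fit-stats.R` | aggregate MM fits, global constrained deconvolution, fit statistics |
| `R/qpcr.R` | primer efficiency, ΔCT/ΔΔCT arithmetic, control QC |
| `R/simulate.R` | synthetic uptake, dilution-series and CT-table generators |
| `R/io.R` | CSV/JSON/TSV readers and writers, file-level pipelines |
| `vignettes/transporter-deconvolution.Rmd` | the methods vignette: model, assumptions, numerical choices, limitations |
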