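---
title: "Costing cells and membranes in ATP: models, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing cells and membranes in ATP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellergy)
```

## The problem

Whether a cellular feature — an organelle, a membrane system, a protein
complex — can be favoured or disfavoured by natural selection depends on
what it costs relative to the cell's whole energy budget, and on whether
that relative cost exceeds the noise floor set by genetic drift. `cellergy`
provides the accounting machinery for such questions, in a single currency:
one ATP → ADP hydrolysis. Redox-cofactor oxidations (NADH/NADPH) are
converted at 3 ATP equivalents each.

The motivating application is the energetics of the
prokaryote–eukaryote divide: what internalising bioenergetic membranes into
mitochondria costs a cell, and whether cross-species scaling of budgets,
ribosomes and ATP synthase abundance shows any discontinuity between the
two domains (it does not — the fitted power laws are continuous).

## The models

### Energy budgets versus cell volume

Two cross-species power laws in cell volume $V$ (µm³), fitted over four
orders of magnitude of volume and normalised to 20 °C:

$$C_M = 0.39 \times 10^9 \, V^{0.88} \ \text{ATP/cell/hour}, \qquad
  C_G = 27 \times 10^9 \, V^{0.97} \ \text{ATP/cell},$$

maintenance rate and growth investment respectively, combined over a
division time $t$ (hours) as $C_T = C_G + t\,C_M$. Both exponents carry
standard errors (0.07 and 0.04) that make them statistically consistent
with isometry. The package stores budgets as raw ATP counts, never in
units of $10^9$: unit drift between modules is a classic failure mode, and
formatting belongs in the reporting layer (`run_pipeline()` writes both
full-precision and 2-significant-figure "as printed" values).

### Lipid costs

Glycerophospholipid biosynthesis cost per molecule is linear in mean
fatty-acid chain length $N_L$ and mean unsaturated carbons per chain
$N_U$:

| | total (evolutionary) | reduced (direct) |
|---|---|---|
| bacteria | $320 + 38(N_L-16) + 6N_U$ | $110 + 7(N_L-16) + 6N_U$ |
| eukaryotes | $340 + 40(N_L-16) + 6N_U$ | $120 + 9(N_L-16) + 6N_U$ |

The *total* cost includes the ATP-generating potential lost by diverting
precursors (acetyl-CoA, reducing equivalents); the *reduced* cost counts
only direct ATP hydrolyses. Over the biologically occupied grid
($14 \le N_L \le 22$, $0 \le N_U \le 6$) total costs run 244–616 ATP.
Cardiolipin's four-chain structure is not representable by these two-chain
formulas, so it ships as a predefined species with explicit overrides (640
total / 240 reduced ATP); `species_cost()` always prefers an override when
present. The formulas are accepted down to $N_L = 10$; shorter chains
trigger an extrapolation warning rather than silent nonsense, and a
computed cost ≤ 0 is an error.

### Membranes

A bilayer of area $A$ µm² contains $2A/a_h$ lipids, with head-group area
$a_h = 6.5\times10^{-7}$ µm² per lipid per leaflet (measured head groups
are mostly within 10% of this), i.e. about $3.1\times10^6$ lipids per µm².
Membrane cost is that count times the mean per-lipid cost $\bar c_L$
(mole-fraction weighted, `mean_membrane_cost()`). An optional
`protein_area_fraction` (0–0.5) scales lipid counts down for
protein-crowded membranes; the default 0 reproduces the headline numbers.

Composing this with the mitochondrial membrane area law
$A = 3.0\,V^{0.99}$ µm², the mitochondrial mean lipid cost
$\bar c_L = 440$ ATP, and the growth budget $C_G$ gives the relative cost
of mitochondrial membrane lipids:

```{r}
mito_membrane_relative_cost(1)   # ~15% of a 1 um^3 cell's growth budget
mito_membrane_relative_cost(1000)
```

The explicit composition is ground truth in this package; the rounded
closed form $0.15\,V^{0.02}$ is exposed as `mito_relative_cost_approx()`
and agrees with the composition to under 1% across $V \in [0.2, 10^4]$
(0.15 rounds 4.092/27; the composition's coefficient at the default
head-group area is 0.1504).

### Selection versus drift

`relative_cost()` turns a component cost into $s_c$, the fractional budget
drain, interpretable as a selection coefficient against the trait.
`selection_outcome()` compares the net advantage $s_n = s_a - s_c$ with
the drift threshold $1/N_e$ (haploid) or $1/(2N_e)$ (diploid): below it,
even an expensive trait is effectively neutral.

### Power-law fitting and exponent algebra

`fit_power_law()` is unweighted OLS of $\log_{10} y$ on $\log_{10} x$.
Base-10 logs were chosen so the intercept SE is comparable to published
"on the log scale" values; the exponent is base-invariant. Weighting and
reduced-major-axis regression were deliberately not used — published
cross-species fits of this kind give no indication of either, and
phylogenetic non-independence is out of scope. Non-positive data are
rejected with record indices rather than offset: pseudo-counts silently
bias exponents.

`combine_exponents()` implements the algebra of composed scalings —
exponents add under multiplication of power laws and subtract under
division — with SEs combined in quadrature under an independence
assumption. That assumption is validated against the one published
composite: $V^{0.97}$ (SE 0.04) over a bacterial division time scaling of
$V^{-0.17}$ (SE 0.11) gives biomass accumulation scaling as $V^{1.14}$
with SE $\sqrt{0.04^2+0.11^2} = 0.117 \approx 0.12$, the printed value.

```{r}
combine_exponents(c(0.97, 0.04), "divide", c(-0.17, 0.11))
```

### Geometry, packing, turnover

`cell_geometry()` supports spheres, spherocylinders (rod-shaped bacteria)
and triaxial ellipsoids. Sphere and spherocylinder use closed forms;
ellipsoid surface area is computed by nested quadrature (relative
tolerance 1e-12) over the spherical parameterisation, since the exact
expression needs incomplete elliptic integrals and the quadrature is
accurate far beyond measurement error in any real morphometry.

`total_mito_area()` extrapolates total (inner + outer) mitochondrial
membrane from outer-membrane measurements via an inner:outer ratio,
default 4.6 — the published cross-species average — even though the four
individually printed ratios (5.0, 2.4, 2.5, 5.2) average 3.775. Both are
surfaced (`reference_constants$inner_outer_ratios_measured`) so users can
run the sensitivity analysis; when inner membranes were measured directly,
pass the summed area and skip extrapolation.

`complexes_per_cell()` converts subunit copy numbers to assembled-complex
estimates (copies / stoichiometry per subunit). The summary is the
arithmetic mean — the source data are described only as "several
independent estimates" with no stated combiner — and the min/max are
reported so users can apply the conservative assembled-limit (the
scarcest subunit caps assembly). `occupancy_fraction()` is a pure area
ratio with no steric packing model (optimal packing of these complexes is
an open question); occupancies above 1 warn rather than error.
`required_turnover()` divides a budget among complexes with an
`atp_share` discount, default 0.15: only ~15% of biosynthetic energy
flows through ATP hydrolysis, the rest through NADH/NADPH oxidation
(`atp_hydrolysis_share(1.5)` ≈ 18% for amino acids,
`atp_hydrolysis_share(2.0)` ≈ 14% for lipids).

A note on one reference number: the *E. coli* census (3018 synthases of
64 nm² in 15.8 µm²) evaluates to ~1.2% occupancy, while the prose
accompanying those inputs says ~1.8%. The package computes the ratio its
inputs imply and does not force agreement; the discrepancy presumably
involves unstated inputs.

### Membrane budget apportionment

`membrane_budget_table()` maps named compartment areas to costs, divides
by the growth budget, and reports each compartment's share plus the
internal-membrane summary (everything except the `"plasma"` compartment).
Published per-species apportionments were built from species-specific
lipid costs that live in supplementary material outside this package's
scope; the recompute path therefore defaults to the eukaryotic mean direct
cost of 143 ATP/lipid and labels its output a *generic-cost
approximation*. The published shares themselves ship as
`membrane_budget_reference` and feed `membrane_share_summary()`, which
reproduces the printed splits exactly (e.g. the mammalian cell: 96% of
membrane costs internal, ~29% of the whole budget; plastid membranes are
excluded from the algal rows, following the source table's convention).

## The synthetic-data generator

`generate_species_table()` emulates a cross-species trait survey: volumes
log-uniform over the range (mirroring the orders-of-magnitude span of real
size data), each trait a configured power law in volume or surface area
with multiplicative $10^{\mathcal N(0,\sigma)}$ scatter. Defaults encode
the published fits — ribosomes $7586\,V^{0.82}$, ATP synthases
$113\,S^{1.26}$, mitochondrial area $3.0\,V^{0.99}$, division-time
exponents $-0.17$ (bacteria) and $+0.13$ (eukaryotes). Three generator
parameters have no published value and were fixed once as realistic
choices:

* division-time coefficients 1.0 h (bacteria) and 5.0 h (eukaryotes) at
  $V = 1$ µm³, bracketing typical measured times for cells of that size;
* volume ranges 0.03–20 µm³ (bacteria) and 0.2–2000 µm³ (eukaryotes),
  bracketing the smallest and largest cells in the budget data
  (*Mycoplasma*/*Leptospira* up to large protists and mammalian cells);
* default scatter $\sigma = 0.2$ dex, comparable to the residual spread
  of the published log-log fits.

Noise is lognormal and homoscedastic in log space — exactly the error
model the OLS fitter assumes — and seeds are mandatory, never defaulted,
so every dataset is reproducible. What the generator does **not** emulate:
phylogenetic correlation between pseudo-species, heteroscedastic or
trait-correlated errors, and measurement error in $x$. Passing
parameter-recovery tests on these data therefore shows the pipeline is
correct under its own assumptions, not that real cross-species data meet
those assumptions.

Plasma-membrane area is deterministic (sphere-equivalent,
$(36\pi)^{1/3}V^{2/3}$) rather than noisy, so that surface-predicted
traits have a well-defined truth in recovery tests.

## Numerical and design choices

* **Tolerances.** Mole fractions must sum to 1 within 1e-9; compartment
  shares are tested to the same tolerance. Geometry quadrature runs at
  1e-12 relative tolerance. Noiseless fit recovery is asserted at 1e-10.
* **Degenerate inputs.** A spherocylinder of cylinder length 0 equals a
  sphere; a zero-area membrane inventory returns a zero budget with a
  warning rather than NaN shares; an all-zero complex census is an error
  (no estimate exists).
* **Problem sizes.** The test suite and the pipeline default to 20–60
  pseudo-species per dataset and up to 200 replicate fits in calibration
  checks; these sizes give stable statistics for power-law recovery while
  keeping any run interactive.
* **Reproducibility.** `run_pipeline()` logs seed, constants and package
  version; reruns with the same configuration are byte-identical, and the
  logged seed replays the exact species table.

## Worked example

```{r}
out <- file.path(tempdir(), "demo_run")
res <- run_pipeline(list(seed = 11, n_species = 40, group = "eukaryote"),
                    out)
res$fits[, c("trait", "coefficient", "exponent", "se_exponent", "r_squared")]
res$report$mito_relative_cost_v1
```

## Known limitations

* Per-species proteomic copy-number and lipid-composition tables are out
  of scope; their printed summary constants (mean lipid costs 123/143/155
  ATP, the 3018-complex census, footprints 64/110/570 nm²) are consumed
  as published via `reference_constants`.
* Maintenance costs of mitochondrial lipids are not modelled (unknown in
  the source data); the relative-cost results are growth-budget
  statements.
* No temperature handling: budget constants are taken as already
  normalised to 20 °C.
* Fits are pooled across groups; the package ships no formal test of a
  prokaryote/eukaryote discontinuity because no published test statistic
  exists to reproduce (the continuity argument is by inspection of the
  pooled fit).
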