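---
title: "Plug-flow kinetics and donor mass balance for staged sulfate-reducing reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plug-flow kinetics and donor mass balance for staged sulfate-reducing reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfkin)
```

`sulfkin` analyses steady-state performance data from up-flow anaerobic
packed-bed reactors (UAPBRs) performing biological sulfate reduction. This
vignette is the package's account of the science it implements: the models,
their assumptions, the parameters that matter, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The data model

The unit of observation is a steady state: a reactor held at one dilution
rate D (1/h, the reciprocal of the hydraulic retention time) until sulfate
reduction is consistent, then sampled repeatedly at the outlet of each of
three sequential zones (inlet, middle, effluent; cumulative volumes
0.33/0.66/1.0 L by default) plus the feed. Each (dilution rate, boundary,
analyte) cell carries the replicate mean, SD and count. Transients after a
dilution-rate step that never reached steady state are *carried in the
table* with `excluded = TRUE` and filtered downstream — exclusion is data,
not code.

Concentrations are handled internally in mg/L of the free anion; mM is
accepted and produced only at I/O boundaries, converted with the anion
molar masses (sulfate 96.06, lactate 89.07, propionate 73.07, acetate
59.04, citrate 189.10, HS⁻ 33.07 g/mol). This choice reproduces the
1.0 g/L ↔ 10.41 mM sulfate correspondence exactly. The salt-to-molar
conversions quoted for feed media are mutually inconsistent across common
hydrate forms, so the configuration takes the molar feed explicitly;
defaults are 13.3 mM lactate and 15.3 mM acetate, the bases used in the
downstream arithmetic.

## Plug-flow kinetics

Sulfate removal is modelled as an irreversible empirical rate law
$r = -k\,C^n$ along an ideal plug-flow reactor. Integrating
$dC/d\tau = -k\,C^n$ gives the closed forms

$$C_A = C_0 e^{-k\tau} \;(n=1), \qquad
  C_A = \left[C_0^{1-n} + (n-1)k\tau\right]^{1/(1-n)} \;(n\neq 1),$$

and the observable fitted is the segment-mean volumetric rate
$\bar r = (F/V)(C_0 - C_A)$ at the segment's flow-to-volume ratio. The
assumptions are consequential and worth stating:

* ideal plug flow — no axial dispersion, no residence-time distribution;
* a single effective rate law for the whole bed, i.e. the spatially
  varying community is summarised by (k, n);
* no explicit biomass term — biomass retention is folded into k;
* steady state, so position and residence time are interchangeable.

Each steady state contributes up to three nested rate points (inlet
0.33 L, inlet+middle 0.66 L, whole 1.0 L) with the feed as $C_0$ and
`flow_per_volume` = D·V_working/V_segment. By default the three
cumulative datasets are fitted jointly; a dataset filter supports
per-segment fits where the joint assumption is in doubt.

### Estimation and its numerical choices

(k, n) are strongly correlated: over a finite range of F/V, a higher
order with a suitably smaller rate constant produces a nearly identical
curve. The fitter therefore:

1. screens a coarse start grid — orders 0.5–4 in steps of 0.5 crossed
   with $\log_{10} k \in \{-9,\dots,0\}$, augmented with closed-form k
   seeds inverted from a mid-range data point;
2. polishes at least 8 of the best starts with L-BFGS-B on
   $(\log_{10} k, n)$, bounded to $\log_{10} k \in [-12, 3]$ and
   $n \in [0.2, 6]$;
3. takes the lowest SSE, breaking near-ties (1e-8 relative) toward the
   smaller order — the more parsimonious curve.

Correctness is defined against a brute-force 40×40 grid-search oracle on
the same bounds (the fit's SSE may never exceed the grid minimum), not
against any particular optimiser. Fixed-order fits use 1-D Brent
minimisation in $\log_{10} k$; a single point with fixed order is
interpolated exactly by the closed-form inversion. All-zero rate vectors
are refused as degenerate (k = 0 reported in the condition), and free-order
fits require at least three points.

Goodness of fit follows the standard definitions
SSE = Σ(y − y_fit)², R² = 1 − SSE/Σ(y − ȳ)², dof = N − p, and
SE = √(SSE/dof). The square root is an interpretive commitment: a
rate-unit confidence band requires the root even where the quantity is
sometimes written without it. Confidence bands are fit ± t₀.₉₇₅,dof·SE —
constant half-width in rate units, by construction.

For orders below one the integrated form can reach zero concentration
inside the reactor; the solution is clamped at complete conversion and the
trajectory flagged. The analytic solution is validated against adaptive
numeric integration of the ODE (deSolve) to ≤1e-6 relative over
n ∈ [0.5, 5] and dimensionless extents k·τ·C₀ⁿ⁻¹ up to 20, and the
nth-order form is checked to converge to the exponential at n → 1 ± 1e-6.

## The electron-donor ledger

Zone-wise sulfate removal is attributed to donors in molar units with
fixed stoichiometry and fixed precedence:

1. **Propionate.** Net production ⇒ lactate fermentation
   (3 lactate → 1 acetate + 2 propionate), so fermented lactate is 1.5×
   the net propionate and 0.5× is credited as acetate. Net consumption ⇒
   propionate oxidation (0.75 sulfate, 1 acetate per propionate).
2. **Lactate.** Consumption beyond the fermented share is incomplete
   oxidation to acetate (0.5 sulfate, 1 acetate per lactate), capped at
   the remaining observed removal.
3. **Acetate.** Residual removal is charged 1:1 to the acetate pool:
   zone-inlet acetate plus all credits, plus — in the inlet zone only — a
   fixed 268 mg/L (4.54 mM) credit for acetate from yeast-extract
   degradation, independent of dilution rate.

Complete lactate oxidation is deliberately not a separate pathway:
incomplete oxidation followed by re-oxidation of the produced acetate is
species-for-species identical (per mole lactate: 1.5 sulfate, 3
bicarbonate, 1.5 sulfide) on every species the ledger tracks. The proton
term of the written reactions differs, a bookkeeping artefact of the
bicarbonate/bisulfide conventions; the ledger does not track protons. The
test suite asserts this equivalence numerically on random ledgers.

Citrate (1.16 mM in the feed) is excluded from the sulfidogenic ledger by
default and reported as consumed; an optional configuration flag credits
1 acetate per citrate for sensitivity analysis, since citrate oxidation is
a plausible source of the small unattributed acetate sometimes seen in
inlet zones.

Noise robustness is a design requirement: outlet-above-inlet sulfate,
fermented-exceeds-consumed lactate and donor deficits are flagged in
`deficit_flags`, floored at zero where arithmetic requires it, and never
raised as errors — a noisy table must flow through the pipeline.

The acetate leaving each zone is predicted from the ledger and compared
with observation as 100·|obs − pred|/obs, averaged per zone across
dilution rates (zero-observed points are excluded and flagged). Zone
chaining uses the *observed* upstream composition by default — each zone
is judged on its own measured inputs; a `predicted` chaining mode
propagates the predicted acetate instead, which compounds errors
downstream but tests the model as a whole-reactor simulator. Both are
recorded in the output.

## The synthetic-data generator

The generator exists so that every stage has a testable ground truth. It
emulates:

* the nine-step dilution ladder 0.010–0.042 1/h;
* the zone geometry (three cumulative volumes in a 1.0 L bed);
* a kinetic truth (k, n) driving the sulfate profile through the same
  closed-form plug-flow solution;
* donor profiles constructed by running the attribution rules forward
  (fermentation schedule fixes propionate; lactate, then propionate, then
  acetate pay the sulfate demand; yeast-extract credit in the inlet);
* replicate-level Gaussian measurement noise (default CV 5 %, truncated
  at zero, default 5 replicates) summarised to mean/SD exactly as real
  steady-state tables are;
* excluded transients (0.014/0.016 1/h in the lactate scenario, 0.014 in
  the acetate scenario), flagged but present.

The two named scenarios carry the study-condition truths: the lactate
reactor as first-order with k = 0.06955 1/h, the acetate reactor as
order 2.9 with k = 1.5e-7 mg⁻¹·⁹ L¹·⁹ h⁻¹. The fermentation schedule
defaults to 2.3 mM net propionate, elevated to 4.6/3.9 mM at the
transient rates to mimic the observed upset. The 5 % CV is a stand-in —
replicate noise magnitudes are not published for the study conditions —
and is configurable.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: community dynamics (the fermentation schedule
is an input, not an outcome), biomass growth and retention, sulfide
toxicity, axial dispersion, pH/redox chemistry, and any transient
behaviour — steady states only. In particular, the generator's zone
profiles follow the kinetic truth exactly, whereas real inlet zones
deviate from a single-bed rate law (e.g. through sludge accumulation), so
parameter recovery from synthetic data demonstrates the estimator, not
the adequacy of the rate law for any particular reactor.

Feasibility is checked, not assumed: a scenario whose sulfate demand
exceeds the donor capacity of any zone fails with an error naming the
zone and dilution rate.

## Design choices made where the design was open

* **Joint vs per-segment fitting** — both supported; joint is the
  default on the grounds that a single (k, n) for the whole bed is the
  model being asserted.
* **Observed vs predicted chaining** for acetate prediction — observed by
  default, as per-zone comparisons against measured inputs are the
  sharper diagnostic; both modes are first-class.
* **Residual attribution to acetate oxidation** rather than an explicit
  complete-lactate-oxidation pathway — ledger-equivalent (above) and
  simpler to audit.
* **Sampling basis** — zone boundaries are outlet samples; the feed row
  carries the inlet composition. Rates are reported positive for
  consumption.
* **Biofilm densities** are normalised to the foam-free liquid subzone
  volume (0.167 L × (1 − 0.04) = 160.32 mL per subzone).

## Problem sizes and reproducibility

The default test and validation workloads are sized for interactive use:
noiseless recovery uses the full ladder (21–24 rate points); Monte-Carlo
recovery uses 200 replicates per truth at 5 % CV for truths n ∈ {1, 2, 3};
the sampling-distribution check uses 60 seeded tables. All randomness is
seed-controlled; identical seeds produce byte-identical observation
files. Machine-readable outputs are written at full precision (10
significant digits in observation tables); rounding happens only in the
human-readable report.

## Known limitations

* The empirical rate law has no mechanistic content: k and n summarise a
  spatially organised community and will not extrapolate across feeds,
  temperatures or packing geometries.
* (k, n) are strongly correlated; with noisy data the free-order fit's
  order estimate has wide dispersion even when the median is unbiased,
  and confidence bands on the *curve* should not be read as confidence
  intervals on the parameters.
* The ledger is a steady-state mass balance: it cannot distinguish
  donor pathways that are stoichiometrically equivalent (complete lactate
  oxidation vs incomplete + acetate re-oxidation), and it attributes by
  precedence, not by measured fluxes.
* The yeast-extract acetate credit is a constant; any dilution-rate
  dependence of yeast-extract degradation is absorbed into the residuals.
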