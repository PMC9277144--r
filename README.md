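# sulfkin

Plug-flow kinetics and electron-donor mass balance for sulfate-reducing
bioreactors.

## The problem

Biological sulfate reduction (BSR) treats sulfate-rich wastewater by letting
sulfate-reducing microorganisms (SRM) reduce sulfate to sulfide, coupled to
the oxidation of a supplied electron donor (typically lactate or acetate).
In an up-flow anaerobic packed-bed reactor (UAPBR) the feed moves through a
packed biofilm bed in near plug flow, so sulfate concentration, volumetric
sulfate reduction rate (VSRR) and available electron donors all change with
position. Operators of such reactors face two coupled questions:

1. **Kinetics** — what effective rate law governs sulfate removal along the
   reactor, and how does performance change as the hydraulic retention time
   (HRT) is shortened?
2. **Donor bookkeeping** — which electron donors (supplied lactate, its
   fermentation products propionate and acetate, acetate from yeast-extract
   degradation) actually paid for the observed sulfate reduction in each
   zone?

`sulfkin` implements both analyses for steady-state zone-boundary
concentration tables collected over a ladder of dilution rates, plus a
seeded synthetic-data generator so every stage can be exercised and
validated without reactor data. It is aimed at environmental-biotechnology
researchers analysing staged anaerobic reactors.

## The model

**Kinetics.** Sulfate removal is modelled as an irreversible reaction
r = −k·Cⁿ integrated along an ideal plug-flow reactor. For residence time
τ = V/F the outlet concentration is

    C_A = C_0 · exp(−k·τ)                              (n = 1)
    C_A = [C_0^(1−n) + (n − 1)·k·τ]^(1/(1−n))          (n ≠ 1)

and the segment-mean volumetric rate at a flow-to-volume ratio F/V is
r̄ = (F/V)·(C_0 − C_A). Each non-excluded steady state contributes up to
three nested rate points (inlet 0.33 L, inlet+middle 0.66 L, whole reactor
1.0 L). (k, n) are estimated by multi-start nonlinear least squares; fits
report SSE, R², SE = √(SSE/dof) and a two-tailed 95 % Student-t confidence
band.

**Mass balance.** Observed sulfate removal in each zone is attributed to
donors through fixed stoichiometry (mol/mol): net propionate production ⇒
lactate fermentation (3 lactate → 1 acetate + 2 propionate); propionate
consumption ⇒ propionate oxidation (0.75 sulfate, 1 acetate produced);
remaining lactate consumption ⇒ incomplete lactate oxidation (0.5 sulfate,
1 acetate produced); residual removal ⇒ acetate oxidation (1:1). The inlet
zone receives a fixed 268 mg/L acetate credit from yeast-extract
degradation. The ledger predicts the acetate leaving each zone, compared
with observation as a zone-averaged percent difference.

## Worked example

```r
library(sulfkin)

spec <- scenario_lactate_reactor()        # 5% CV noise, 5 replicates
obs  <- simulate_observations(spec, seed = 42)
pts  <- build_rate_points(obs, spec$config)
fit  <- fit_kinetics(pts, order_fixed = 1)
fit
#> <srk_fit> plug-flow order-1 (fixed) rate-law fit
#>   k = 0.069007 1/h
#>   SSE = 1.7436, R2 = 0.9994, SE = 0.2953 (dof = 20, 21 points)

bal <- run_balance(obs, spec$config)
bal$pct_diff$per_zone
#> # A tibble: 3 × 4
#>   zone     mean_pct_diff n_used n_excluded
#>   <chr>            <dbl>  <int>      <int>
#> 1 inlet             3.91      7          0
#> 2 middle            3.51      7          0
#> 3 effluent          1.81      7          0

theoretical_sulfate_capacity("lactate", 13.3, to_mM(1000, "sulfate"),
                             "LACTATE_INCOMPLETE")
#> [1] 63.8799
```

The fitted `k = 0.069 1/h` recovers the scenario's first-order truth
(0.06955 1/h) from noisy replicates; the mass balance predicts zone-outlet
acetate within a few percent of the (noisy) observations; and 13.3 mM
lactate can pay for at most ~64 % of a 10.41 mM sulfate feed through
incomplete oxidation — the quantitative reason lactate-sparing operation
relies on propionate- and acetate-oxidising SRM downstream.

`autoplot(fit)` draws the observed rates, the fitted curve and its 95 %
band; `plot_acetate_profile(bal$profile)` compares observed and predicted
acetate per zone. A thin command-line wrapper over the same functions is
installed at `inst/cli/sulfkin.R` (subcommands `simulate`, `fit`,
`balance`, `report`).

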