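# retrotox

Physiologically-based toxicokinetic (PBTK) modelling of the pyrrolizidine
alkaloid **retrorsine** in humans, and of the change in its CYP3A4-mediated
bioactivation during co-exposure to the enzyme inducer **rifampicin**.

Retrorsine is a hepatotoxic constituent of herbal teas. It is not toxic as
such: CYP enzymes — about half of the flux through CYP3A4 — dehydrogenate
it to reactive metabolites that form protein and DNA adducts. Any drug that
induces CYP3A4 therefore changes not just retrorsine's exposure but the
amount of toxic metabolite formed. This package provides a mechanistic
simulation framework to quantify that interaction for risk assessment:
who is it for — modellers and risk assessors who need internal-dose metrics
(CYP3A4-metabolite formation in liver and gut) rather than plasma
concentrations alone.

## What is implemented

* **Whole-body PBTK model** (flow-limited tissues; nmol/L/h unit system)
  with an **extended-clearance liver**: sinusoidal active uptake
  CL<sub>act,in</sub> plus passive diffusion PS<sub>diff</sub> into the
  hepatocyte, saturable metabolism (V<sub>max</sub>, K<sub>M</sub>), zero
  efflux/biliary clearance, giving

  CL<sub>liv</sub> = Q·f<sub>u</sub>·CL<sub>act,in</sub> / (Q + f<sub>u</sub>·CL<sub>act,in</sub>)

  in the uptake-limited form; first-order oral absorption, small-intestinal
  metabolism confined to the CYP3A4-expressing cellular fraction, and renal
  excretion by glomerular filtration of unbound drug.
* **CYP3A4 turnover with Emax induction** (E<sub>max</sub> = 9,
  EC<sub>50</sub> = 0.34 µM) and **competitive inhibition**
  (K<sub>i</sub> = 18.5 µM multiplies the CYP3A4-pathway K<sub>M</sub> by
  1 + C/K<sub>i</sub>), driven by two-compartment intracellular rifampicin
  exposure models in liver and small intestine, all solved as one ODE
  system.
* **In-vitro kinetics + IVIVE**: monoexponential medium-loss depletion
  (4 °C vs 37 °C separates passive from active hepatic uptake) and a
  microsomal end-product inhibition model; scaling to whole-organ
  clearances.
* **Bayesian estimation**: adaptive random-walk Metropolis in log space,
  posterior mode + equal-tailed 95% credible intervals, 1000-draw
  Monte-Carlo predictive bands.
* **Scenarios and metrics**: daily herbal-tea dosing (0.019 µg/kg/day,
  5 weeks) with and without a 2-week 600 mg/day rifampicin course; 24-h
  AUC/C<sub>max</sub> per matrix, daily and cumulative pathway-resolved
  metabolite formation, interaction ratios, ±10% local sensitivity
  analysis.
* **Synthetic-data generators** for every measured input (seeded,
  lognormal noise), so the full pipeline runs and is tested without any
  external data.

## Worked example

```r
library(retrotox)

phys <- build_reference_human()      # 73-kg reference man
sub  <- substance_retrorsine()       # canonical kinetic parameter set

extended_liver_clearance(sub, phys)
#> CL_liv: 9.08 mL/min/kg

f <- bioavailability_decomposition(sub, phys)
#> F = 44.5% (Fa 78.3%, Fg 94.5%, Fh 60.1%)

sim <- simulate_pbtk(dose_regimen("retrorsine", 100, 0), sub, phys,
                     t_end = 48, dt_out = 0.05)
biodistribution_report(sim)$route_shares
#> route shares: liver 79%, gut 13%, renal 8%
```

The oral dose is cleared mostly by hepatic metabolism (79%), with smaller
intestinal (13%) and renal (8%) contributions; oral bioavailability is 44%,
limited mainly by hepatic first pass (F_h = 60%). The interaction scenario:

```r
tea  <- scenario_spec("herbal_tea")
both <- scenario_spec("herbal_tea_plus_rifampicin")
sim_tea  <- run_scenario(tea)
sim_both <- run_scenario(both)

ref <- scenario_metrics(sim_tea, tea)       # steady-state reference day
tst <- scenario_metrics(sim_both, both)     # days around the rifampicin course
```

At day 2 after the last rifampicin dose — when inhibition has vanished but
induction is still near maximal — the liver retrorsine AUC<sub>24</sub>
falls to 14% of the rifampicin-free reference, while the cumulative amount
of intestinal CYP3A4 metabolites over five weeks rises to ~270% of
reference; hepatic CYP3A4-metabolite totals stay almost constant because
the stronger gut first pass offsets the induced hepatic share. Maximal
CYP3A4 induction is 9.9-fold (liver) and 9.0-fold (gut).

A configuration-driven end-to-end run (synthetic data → MCMC fits → IVIVE
→ simulation → metrics → sensitivity) is available through
`run_pipeline(default_config(seed = 1))`.

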