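# pedtmdd

Simulation toolkit for asking a pharmacometric question that matters in
pediatric drug development: **when a monoclonal antibody is cleared partly
through its own target, do body-weight-based or fixed doses give children the
same exposure — and the same target occupancy — as adults?**

For antibodies with purely linear clearance, allometric mg/kg scaling works
well. Once target-mediated drug disposition (TMDD) contributes, clearance
becomes concentration- and target-level-dependent, and the answer depends on
how the target itself differs between a 12.8-kg two-year-old and a 70-kg
adult. `pedtmdd` makes that comparison computable.

## The model

The full TMDD model (two-compartment, binding in the central compartment,
1:1 stoichiometry, amounts for drug and concentrations for target, with
C = A1/V1):

    dA1/dt = −kel·A1 − Q·(A1/V1 − A2/V2) − kon·C·R·V1 + koff·DR·V1
    dA2/dt =           Q·(A1/V1 − A2/V2)
    dR/dt  = ksyn − kdeg·R − kon·C·R + koff·DR
    dDR/dt = kon·C·R − (koff + kint)·DR

with baseline target R0 = ksyn/kdeg, occupancy DR/(R + DR), and the
clearance decomposition CL_TOT(C) = kel·V1 + kint·R_TOT·V1/(Km + C).
Its quasi-steady-state (Michaelis-Menten) reduction eliminates the target
states using Vmax = kint·R0 and Km = (koff + kint)/kon; the shipped adult
reference set is constrained to R0 = 1.74 nmol/l, Vmax = 7.6038 nmol/l/day,
Km = 0.403 nmol/l.

Around the models, the package provides:

- **allometric scaling** of clearances (BW^0.75) and volumes (BW^1) from a
  70-kg adult to the age-group weights 12.8/21.3/43.5/66.1 kg;
- **target policies** holding either the target *concentration* or the
  whole-body target *amount* equal across ages (amounts convert through a
  2.8-l adult plasma volume);
- **dose construction** in molar units (mg/kg or fixed mg at 150 kDa);
- **stiff-ODE simulation** (deSolve) of single IV bolus doses;
- **NCA metrics**: AUC to infinity (linear-up/log-down trapezoid +
  best-adjusted-R² terminal slope), Cmax, CL_TOT = Dose/AUC, CL_TMDD =
  CL_TOT − CL_linear, occupancy-above-90% duration;
- a **560-cell hierarchical scenario grid** (2 target policies × 2 dosing
  policies × 5 doses × 7 target levels × 4 ages), each cell run under both
  the full and the reduced model;
- a **synthetic-data module**: virtual cohorts with lognormal body-weight
  variability, proportional-error concentration observations, and
  Michaelis-Menten parameter recovery by weighted least squares.

## Worked example

A 2-year-old (12.8 kg) given 4.5 mg/kg IV with the target concentration held
at the adult 1.74 nmol/l:

```r
library(pedtmdd)

adult <- reference_params()
child <- subject("2y")
pol   <- target_policy("same_concentration", adult_r0 = 1.74)

p_child <- scale_parameters(adult, child) |>
  apply_target_policy(child, pol)
reg <- build_regimen(4.5, "per_kg", child)   # 384 nmol total, 30 nmol/kg

sim <- simulate_tmdd(p_child, reg)
nca_summary(sim)
#> # A tibble: 1 × 13
#>   auc_0_last auc_0_inf extrap_frac  cmax  tmax lambda_z lambda_z_n flag  cl_tot
#>        <dbl>     <dbl>       <dbl> <dbl> <dbl>    <dbl>      <int> <chr>  <dbl>
#> 1      4389.     4389.    8.29e-16   750     0    0.322         75 ok    0.0875
#>   cl_linear cl_tmdd cl_fraction occupancy_days
#>       <dbl>   <dbl>       <dbl>          <dbl>
#> 1    0.0699  0.0176       0.201           39.4
```

Exposure is 4389 nmol·day/l with a 750 nmol/l peak; at this dose the target
route contributes 20% of total clearance, and occupancy stays above 90% for
39 days. `autoplot(sim)` draws the concentration and occupancy profiles.

The grid engine runs any slice of the canonical scenario space and appends
child/adult AUC ratios and MM-vs-full agreement per cell:

```r
tab <- default_grid() |>
  dplyr::filter(target_policy == "same_concentration",
                dose_policy == "per_kg", target_level == 1.74) |>
  run_grid()
plot_auc_ratios(tab)
```

A YAML config (`inst/extdata/config-default.yml` is a commented template)
can override every parameter and axis; `load_config()` validates units and
keys and tracks which constants are anchored versus surrogate. A thin CLI
(`inst/cli/pedtmdd.R`) exposes `simulate`, `grid`, `compare` and `recover`
subcommands.

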