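# soilBONCAT

Most soil microbes are dormant most of the time, which makes it hard to say
how many cells actually produce the CO₂ measured in a bulk respiration
assay. **soilBONCAT** implements the quantification chain that links
substrate-induced respiration (SIR) to counts of *translationally active*
bacteria labeled by BONCAT (bioorthogonal non-canonical amino acid tagging):
soil is amended with a carbon substrate plus the methionine analog HPG,
active cells incorporate HPG and are click-labeled with a FITC-channel dye,
all cells are counterstained with SYTO59 (APC channel), and extracts are run
on a flow cytometer alongside two negative controls. The package is aimed at
soil microbial ecologists who want this chain — gating, enumeration,
respiration calibration, growth kinetics, regression — as reproducible code
rather than a manual FlowJo/spreadsheet workflow.

## What it computes

- **Control-anchored gating.** A forward/side-scatter gate constrains
  particle size; the SYTO⁺ (cell vs. soil particle) threshold is the 0.999
  empirical quantile of the APC signal of a *killed* (autoclaved) control;
  the BONCAT⁺ threshold is the same quantile of the FITC signal of the SYTO⁺
  population of an *HPG-negative* control. Events at a threshold count as
  negative. Per batch, the killed control's SYTO⁺ count and the HPG-negative
  control's BONCAT⁺ count are subtracted as backgrounds, and any sample with
  BONCAT⁺ events ≤ the control's is recorded as zero active cells.
- **Enumeration.** With flow rate *F* (µL min⁻¹) and duration *t* (s), the
  analyzed volume is *V = F·t/60*; corrected events convert to cells per
  gram dry soil as `events / V × dilution × extract_mL × 1000 / dry_g`.
- **Respiration.** A linear OLS calibration maps detector readings to µmol
  CO₂; after ambient subtraction, the rate is
  `µmol / (dry_g × accumulation_h)`. Amendment helpers reproduce the
  MicroResp-style 30 mg glucose g⁻¹ soil water arithmetic.
- **Kinetics.** For consecutive time points, the specific growth rate
  µ = ln(N₂/N₁)/Δt, the doubling time already-active cells would need if
  the increase came from division alone (T_req = Δt·ln2/ln(N₂/N₁)), and the
  fraction of the increase replication at a reference generation time T_gen
  would explain: (2^(Δt/T_gen) − 1)·N₁/(N₂ − N₁). Short T_req and tiny
  attribution mean dormant cells were *activating*, not dividing.
- **Relating the two.** Per-treatment and pooled OLS of respiration rate on
  log₁₀(active cells g⁻¹), with 95% confidence bands.

A synthetic-data generator with known ground truth (Poisson event counts,
log-normal channel intensities, mixed active/inactive/particle populations,
both controls, noisy headspace readings) makes every stage testable end to
end.

## Worked example

```r
library(soilBONCAT)

cfg <- run_config(design = experiment_design(seed = 1, replicates = 6))
res <- run_pipeline(cfg)

subset(res$growth, treatment == "glucose" & t1 == 2,
       c(t1, t2, required_doubling_time, replication_attribution,
         interval_class))
#>   t1 t2 required_doubling_time replication_attribution       interval_class
#> 4  2  6              0.6191099             0.005393736 activation-dominated
```

Between 2 h and 6 h of glucose incubation, active cells rose so fast that
already-active cells would have had to double every **0.62 h** to explain
it by division; replication at a rhizosphere-like 7.2-h generation time
would account for only **0.54%** of the increase — so the interval is
classified activation-dominated: dormant cells were waking up. The
pooled respiration regression for the same run:

```r
subset(res$regressions, group == "all")
#>   group     slope intercept r_squared      p_slope  p_intercept  n n_excluded
#> 4   all 0.4078777 -1.452136 0.6038986 1.015568e-15 3.651452e-10 72          0
```

i.e. each tenfold increase in active cells adds ~0.41 µmol CO₂ g⁻¹ h⁻¹ of
respiration across treatments (r² = 0.60, n = 72). Protocol arithmetic:

```r
substrate_concentration(100, 3, 6, 180.16, 1.2, 1.0)  # 30.03 mg glucose / g soil water
gravimetric_water_content(1.2, 1.0, 100)              # 30 %
fraction_of_awhc(30, 62.2)                            # 48.23 % of AWHC
```

A command-line wrapper for the synthetic pipeline lives in
`inst/scripts/run-pipeline.R` (`run` and `simulate` subcommands).

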