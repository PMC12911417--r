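---
title: "Quantifying active soil bacteria and their respiration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active soil bacteria and their respiration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilBONCAT)
```

## The measurement problem

Bulk soil respiration is easy to measure and hard to interpret: the CO₂
coming off a soil microcosm mixes contributions from a small, shifting
subpopulation of active cells embedded in a large pool of dormant ones.
BONCAT labeling makes the active subpopulation countable — cells that are
translating protein during a short HPG exposure pick up a click-chemistry
dye — but turning cytometer events into "active cells per gram dry soil",
and deciding whether an increase in that number reflects *replication* of
already-active cells or *reactivation* of dormant ones, takes a chain of
small quantitative steps. This package implements that chain and a
synthetic-data generator that exercises all of it with known ground truth.

## Gating model

Soil extracts on a cytometer are a three-part mixture: cells (SYTO59
counterstain, bright in the red/APC channel), the active subset of cells
(BONCAT dye, bright in the green/FITC channel), and soil particles plus
electronic noise (dim in APC). Two negative controls anchor the
classification:

* the **killed control** (autoclaved extract) contains no cells, so the
  upper tail of its APC distribution defines what "particle-bright" looks
  like — the SYTO⁺ threshold;
* the **HPG-negative control** (water instead of HPG) contains cells but no
  BONCAT label, so the upper tail of the FITC distribution of its SYTO⁺
  population defines the BONCAT⁺ threshold.

Bench workflows place these thresholds by eye in FlowJo. For
reproducibility we define the threshold as the nearest-rank empirical
quantile of the relevant control distribution, default `0.999`. The choice
of quantile trades false positives against sensitivity: 0.999 leaves ~0.1%
of control events above the threshold, of the same order as the ~0.2%
false-positive discovery rate such assays tolerate, and the residual false
positives are then removed by the background subtraction anyway.
Nearest-rank (inverse-ECDF, `type = 1`) rather than an interpolating
quantile makes thresholds exact on small integer fixtures and means a
threshold is always an observed intensity. Events exactly **at** a
threshold count as negative — a deterministic tie-break that matters on
integer-valued test fixtures and never in practice on continuous data.

Background subtraction is per batch, because controls are processed with
each batch of tubes: the killed control's SYTO⁺ count is removed from every
sample's SYTO⁺ count, the HPG-negative control's BONCAT⁺ count from every
sample's BONCAT⁺ count. Two asymmetric rules apply. A sample whose BONCAT⁺
count is *less than or equal to* its control's is recorded as **zero active
cells** (flagged `zeroed_active`), a deliberately conservative rule: near
the detection limit we prefer to under-report activity rather than invent
it. Totals are merely clamped at zero (`clamped_total`). A final clamp
enforces `active ≤ total`. The HPG-negative control doubles as the
"counterstain-only" control: both describe the same water-instead-of-HPG,
SYTO-stained replicate.

The scatter gate is quantile-based too (defaults 0.001/0.999 on the
HPG-negative control, the control that actually contains cells). Whether
bench scatter gates are quantile- or landmark-based is generally
unrecorded; the quantile rule is our reproducible stand-in, and with the
default near-total span it discards only extreme debris.

## Enumeration

With flow rate $F$ (µL min⁻¹, measured at the instrument's low-flow
setting, default 22.6) and acquisition time $t$ (s, default 120), the
analyzed volume is $V = Ft/60$ µL (45.2 µL at the defaults). Corrected
events scale to cells per gram dry soil:

$$\mathrm{cells\,g^{-1}} = \frac{\mathrm{events}}{V}\times d \times
  v_\mathrm{extract}\,[\mathrm{mL}] \times 1000 \div m_\mathrm{dry}\,[\mathrm{g}]$$

The dilution factor $d$ deserves honesty: real prep chains (glycerol
addition, washes, resuspensions) are rarely written down completely, so the
package exposes a single per-sample factor plus `compose_dilution()` to
build it from named multiplicative steps, keeping the assumption explicit
and auditable. The result counts *extractable* cells only; no
extraction-efficiency correction is applied, because none is measurable
within the assay — extracts are a subset of the soil community, and
comparisons across treatments of one homogenized soil keep that bias
constant.

## Respiration

The CO₂ calibration is ordinary least squares on standards of known
content; "calibration curve" in bench protocols rarely means more than a
line over the standards' range, and the fit is deliberately unit-agnostic
in the reading (ppm or raw signal, as the standards table dictates). The
rate is $(\mathrm{headspace} - \mathrm{ambient})_{+} / (m_\mathrm{dry}
\cdot h)$ with one ambient reading per measurement session and negative
corrected contents clamped to zero and flagged.

The amendment helpers encode the substrate-induced-respiration convention:
100 µL of a 3 mol C L⁻¹ hexose solution into 1.2 g field-moist / 1.0 g dry
soil delivers 9.01 mg substrate into 0.3 g soil water — 30 mg g⁻¹ soil
water — and brings the gravimetric water content to 30%, which is 48.2% of
a 62.2% available water-holding capacity (we report the unrounded figure;
protocols round it to 50%). Added solutions are taken at density 1 g mL⁻¹.

## Kinetics: replication vs. reactivation

Between consecutive time points with replicate-mean active counts
$N_1, N_2$ over $\Delta t$ hours, treating the increase *as if* it were
exponential growth gives $\mu = \ln(N_2/N_1)/\Delta t$ — an upper bound on
any true division rate, since activation inflates it. Its inversion,
$T_\mathrm{req} = \Delta t \ln 2 / \ln(N_2/N_1)$, is the doubling time
already-active cells would have needed. Comparing $T_\mathrm{req}$ with
literature anchors — an *E. coli* culture (20 min), an active rhizosphere
(7.2 h), bulk forest soil (14.1 d), exposed by `reference_rates()` — turns
the bound into an argument: the attribution fraction
$(2^{\Delta t/T_\mathrm{gen}} - 1)\,N_1/(N_2-N_1)$ says how much of the
observed increase replication at $T_\mathrm{gen}$ could explain, and it
equals 1 exactly when $T_\mathrm{gen} = T_\mathrm{req}$ (a self-consistency
property the tests exploit).

Rates are reported in two forms, because both are in circulation: the
ln-based $\mu$ and the hourly proportional change $2^{1/T}-1$ (under which
the *E. coli* anchor sits at 7.0 h⁻¹). They are deterministic transforms of
each other; emitting both avoids guessing which one a reader wants.

Interval classification defaults: `min_plausible_tgen = 0.5` h is the
theoretical maximum replication rate under optimal soil conditions — a
$T_\mathrm{req}$ below it is physically implausible as pure growth;
`attribution_cutoff = 0.05` is our own choice (configurable) for "too small
to matter". An interval is `activation-dominated` if either test fires,
`replication-plausible` if $T_\mathrm{req}$ is at least the reference
generation time, otherwise `indeterminate`. Intervals with zeroed or
non-increasing counts are flagged and kept, never silently dropped; the SE
of $\mu$ is delta-method propagated from the replicate-mean SEs,
$\mathrm{se}_\mu = \sqrt{(s_1/N_1)^2 + (s_2/N_2)^2}/\Delta t$.

## Regression

Respiration is regressed on $\log_{10}$ active cells (base configurable —
it only rescales the slope) per treatment and pooled, with classical OLS
t-tests and a 95% mean-response band. Samples with zero corrected active
cells have no log and are excluded with a warning and a count; whether
published pooled fits include such samples is usually unstated, so we make
the exclusion loud. The pooled fit includes every treatment's usable
samples.

## The synthetic generator

The generator emulates the structure of deposited soil-cytometry data:
Poisson event counts with mean equal to the enumeration contract (natural
for volumetric sampling of a well-mixed suspension), Bernoulli
active/inactive assignment, log-normal intensities per channel (the
standard positive-valued model for cytometry), log-normal scatter
uncorrelated with fluorescence (present only to exercise the scatter
gate), and particles at a per-µL rate. Controls are derived from the same
truth: the killed control keeps only particles; the HPG-negative control
redraws every cell's FITC from the inactive distribution. Headspace
readings invert a linear detector model with additive Gaussian noise, with
exact standards spanning the range. One master seed drives everything;
per-replicate streams are derived by stable hashing of (seed, condition,
replicate), so reruns are byte-identical and inserting a replicate does not
shift its neighbours' draws.

What it does **not** emulate — and therefore what passing tests do not
demonstrate about real data — includes: spectral spillover and
compensation, doublets, autofluorescence structure, correlated
scatter–fluorescence, filamentous or biofilm biomass that extraction
misses, dead-cell populations, day effects beyond batch-shared controls,
and any nonlinearity in the CO₂ detector. The synthetic recovery tests
certify the *arithmetic chain*, not field performance.

### Demo design

The default `experiment_design()` mirrors a short-term SIR incubation:
glucose / galactose / water × 2, 6, 12, 24 h × 6 replicate tubes, 1 g dry
soil, 5 mL extraction, dilution factor 2 (the prep chain is
under-documented in such protocols; 2 keeps per-tube event counts in the
10⁴–10⁵ range typical of the instrument), 2 h headspace accumulation,
ambient 0.17 µmol (a ~10 mL headspace at ~420 ppm CO₂), detector noise 2
units on a ~500-units-per-µmol response. The built-in truths follow the
qualitative pattern of such experiments: totals near 5×10⁶ cells g⁻¹ at
2 h; active fractions from ~0.1% (water, 2 h) to 27% (glucose, 24 h);
a glucose 2→6 h active-cell fold change of 87.55, which corresponds to a
0.62-h required doubling time and a replication attribution of ~0.5% at
the 7.2-h rhizosphere reference; galactose rising slowly enough
(ratios ≤ ~1.8 per interval) that replication alone remains plausible;
respiration ordered glucose > galactose > water and rising by 24 h. These
values were fixed when the design was written and are not tuning knobs.

```{r demo}
res <- run_pipeline(run_config(design = experiment_design(seed = 1,
                                                          replicates = 6)))
res$growth[res$growth$treatment == "glucose",
           c("t1", "t2", "required_doubling_time",
             "replication_attribution", "interval_class")]
```

## Numerical and degenerate-input choices

* Thresholds: strictly-greater comparisons; nearest-rank quantiles.
* Zero totals give a 0% active fraction with a `degenerate` flag rather
  than NaN; zero starting counts make ratio kinetics `NA` with an
  `undefined` flag.
* Calibration with identical readings raises a singular-fit error;
  regressions need ≥3 positive-count samples and non-constant regressors.
* Corrected CO₂ contents and corrected counts are clamped at zero, always
  with flags, so downstream tables never contain negative masses or counts
  and clamping is never silent.
* Problem sizes in the test-suite simulations (20-seed recovery at ~10⁴
  cell events per table, 1000-replicate null calibration of the slope
  test, 100-table gating-oracle sweeps) were chosen to give stable
  Monte-Carlo verdicts at interactive runtimes.

## Known limitations

BONCAT misses activity in cells with methionine access or protein
reserves; extraction misses filamentous and strongly mineral-adhered
organisms; cells-per-gram values are therefore lower bounds on the soil
community and are best used comparatively across treatments of one soil.
The kinetics deliberately fit no continuous growth curve — intervals are
the unit of inference, matching the categorical time design — and the
package makes no attempt at taxon-resolved rates.
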