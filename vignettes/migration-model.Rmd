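---
title: "Predicting chemical migration into saliva and children's mouthing risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chemical migration into saliva and children's mouthing risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivamigr)
```

## The problem

Children mouth pacifiers, teethers, dolls and other products whose materials
carry non-covalently bound additives — plasticizers, flame retardants,
parabens, fragrance allergens. During mouthing these chemicals can migrate
into saliva and be ingested. Experimental migration rates exist for only a
few dozen chemical–material combinations, so screening the thousands of
marketed combinations requires prediction. `salivamigr` implements two
predictors of the standardized migration rate $R_{mgr}$
(µg/10 cm²/min) — a fully predictive mechanistic model and a
regression-based alternative — together with dataset harmonization,
validation statistics, and conversion of rates into daily mouthing doses
and hazard quotients.

## The mechanistic material–saliva migration model

Saliva in contact with a product behaves like a liquid food in contact with
packaging, so the model treats the product as a one-sided slab of thickness
$d_p$ releasing a chemical with diffusion coefficient $D_p$ (cm²/s) into a
finite saliva volume $V_f$, limited by the product–saliva partition
coefficient $K_{pf}$. Two regimes are joined at a deviation time $t_{dev}$:

* **Short-term Fickian diffusion** ($t \le t_{dev}$):
  $f_{ts} = \frac{2}{d_p}\sqrt{\frac{D_p t}{\pi}}$ — the classic
  $\sqrt{t}$ release law from a semi-infinite slab.
* **Two-exponential saturation** ($t > t_{dev}$): the migrated fraction
  relaxes from $f_{t_{dev}}$ toward the equilibrium plateau
  $\alpha/(1+\alpha)$, where $\alpha = \frac{1}{K_{pf}}\frac{V_f}{V_p}$ is
  the saliva-side capacity ratio, as a mixture of a fast pool (weight $A$,
  rate $B\beta$) and a slow pool (weight $1-A$, rate $C\beta$):
  $$f_{mgr} = f_{t_{dev}} + \Bigl(\tfrac{\alpha}{1+\alpha} - f_{t_{dev}}\Bigr)
  \Bigl[A\bigl(1-e^{-B\beta(t-t_{dev})}\bigr) +
  (1-A)\bigl(1-e^{-C\beta(t-t_{dev})}\bigr)\Bigr].$$

$t_{dev}$ scales exactly as $d_p^2/D_p$ with an empirical dimensionless
prefactor that switches branches at $\alpha = 0.2$; $A$, $B$ and $C$ are
clamped power laws in $\alpha$ (see `deviation_time()` and
`saturation_coefficients()` for the exact constants). The model makes no
attempt to describe uptake across mouth or GI barriers — its output is what
reaches saliva.

The fraction is converted to a rate (`migration_rate()`) via
$R_{mgr} = f_{mgr}\, m_0 / (A_{contact}\, t)$, normalized per 10 cm², the
typical mouthing contact area of a child.

### Numerical and interpretive choices

* **Logarithm base.** The empirical prefactors are written with
  $\log(\alpha)$; we evaluate all of them in base 10. Under base 10 the two
  $t_{dev}$ branches agree within about 6% at $\alpha = 0.2$; natural logs
  give a much larger mismatch, so base 10 is clearly the intended reading.
  The choice is centralized in the model functions and verified by a
  branch-continuity test.
* **Initial mass convention.** $m_0$ is the chemical mass in the one-sided
  slab engaged in migration under the mouthed area,
  $m_0 = C_0\, \rho\, A_{contact}\, d_p$. This makes the per-10 cm² rate
  independent of both total product size and of $A_{contact}$ itself, and
  exactly linear in the initial concentration $C_0$ — consistent with the
  one-sided slab diffusion picture.
* **The $C$ coefficient floor.** The slow-pool coefficient is set to 0.004
  whenever its power law falls below 0.3; the asymmetry between floor value
  and threshold is implemented exactly as the source model prints it and
  isolated in a single named constant (`C_COEF_FLOOR`).
* **Degenerate geometries.** If the equilibrium plateau falls below the
  fraction already migrated at $t_{dev}$ (possible only for physically
  absurd capacity ratios), the fraction is clamped at the plateau and a
  structured warning is attached to the result instead of aborting — a
  screening run over thousands of rows must survive edge rows. Warnings are
  retrieved with `result_warnings()`.
* **Units.** Internal computation uses cm, s, µg; conversion to
  µg/10 cm²/min happens exactly once, in `migration_rate()`.

## QSPR estimation of $D_p$ and $K_{ms}$

The two chemical-in-material inputs are estimated from molar mass, log
$K_{ow}$, material identity and the ethanol equivalency (EtOH-eq) of the
medium:

$$\log_{10} D_p = a_D + b_D \log_{10} MW, \qquad
\log_{10} K_{ms} = a_K + b_K\,\ell - s_K \tfrac{EtOHeq}{100}\max(\ell, 0),
\quad \ell = \min(\log K_{ow}, 11).$$

log $K_{ow}$ is capped at 11, the high-end limit of the partition QSPR's
applicability domain; molar masses outside the diffusion QSPR's domain are
extrapolated with a warning rather than refused. The EtOH-eq term models
the medium: a more ethanol-like (lipophilic) medium competes better with
the material, lowering $K_{ms}$. The package selects EtOH-eq = 20% for
unstimulated in-vitro conditions and 50% for in-vivo or mechanically
agitated experiments (`select_etoh_eq()`); 50% is also the recommended
conservative setting for prospective screening, reflecting transfer from
saliva onward into the flesh of the mouth.

The per-material coefficients are **data, not code**: they ship as an
editable YAML table (`inst/extdata/materials_synthetic_defaults.yaml`,
loaded by `default_material_table()`/`read_material_table()`). The shipped
values are synthetic representative defaults, chosen once to reproduce the
qualitative facts reported for these materials — diffusion coefficients in
wood, silicone and EVA roughly three orders of magnitude above PVC and PP
at equal molar mass, partitioning driven primarily by $K_{ow}$ with weak
material dependence — and realistic magnitudes (e.g. $D_p \sim 10^{-12}$
cm²/s for a 300 g/mol plasticizer in PVC). Users with
experimentally-anchored coefficient sets should substitute their own file;
every prediction function takes the table as an argument.

## The regression alternative

The regression predictor models
$\log_{10} R_{mgr} = \beta_0 + \sum_i \beta_i x_i$ over candidate
predictors $\log_{10} C_0$, $\log_{10} D_p$, $\log K_{ow}$,
$\log_{10} K_{ms}$ and $\log_{10} MW$. The shipped default
(`published_regression_model()`) is the three-predictor fit

$$\log_{10} R_{mgr} = 3.23 + 0.73\log_{10}D_p + 0.92\log_{10}C_0 - 0.06\log K_{ow},$$

with molar mass and $K_{ms}$ excluded by the selection (p = 0.79 and 0.17
on the fitting dataset). `fit_forward_selection()` re-derives such models:
classic forward selection adding, at each step, the candidate with the
smallest partial-t p-value below the entry threshold. The threshold is not
fixed by the source analysis, so we default to `entry_alpha = 0.05` —
standard practice, and it reproduces the exclusion of the two decoy
predictors on data simulated from the published model. Ties are broken by
candidate order, making selection fully deterministic. Predictor units are
frozen inside the model object so a fitted model cannot silently be applied
to inputs in other units. The regression is preferred only for
chemical–material combinations resembling its training data; the
mechanistic model, which fits nothing, is the default for new combinations.

## Dataset harmonization and the synthetic generator

Harmonized datasets use a frozen CSV schema (snake_case columns with units
embedded, e.g. `rate_ug_per_10cm2_min`); `read_migration_dataset()`
validates row-by-row, rejecting bad rows with row-numbered diagnostics
rather than failing the file. `standardize_rate()` converts raw
experimental reports — final saliva concentration × volume, fraction
migrated × initial mass, or migrated mass — to the common
µg/10 cm²/min unit. Chemical identity is keyed on CAS when present, else
on normalized name; replicate observations across studies are kept
distinct, never merged. `import_si_workbook()` maps a user-exported
spreadsheet with arbitrary column names onto the schema.

`generate_synthetic_dataset()` is a first-class module, not a test hack.
Its default configuration emulates the *structure* of the harmonized
literature dataset: 437 observations of 60 chemicals in 6 chemical groups
(phthalates/alternative plasticizers in PVC, parabens in EVA,
polybrominated diphenyl ethers in PP and PVC, methylsiloxanes in silicone,
chlorophenols in wood, fragrance allergens in PP) across 5 materials and
66 chemical–material combinations from 18 studies, with one heavily
replicated plasticizer–PVC combination mirroring the most-studied real
one. True rates are computed by the mechanistic model itself and perturbed
by lognormal noise, `observed = true × 10^{N(0, 0.5)}`; 0.5 log units was
chosen once as a realistic inter-study spread. What the generator does
**not** emulate: real chemical-property correlations within groups,
concentration-saturation effects reported for highly plasticized PVC,
temperature/pH/saliva-composition effects, or reporting bias across
studies. Consequently, tests passing on synthetic data demonstrate
internal consistency of the pipeline (the mechanistic model exactly
reproduces noiseless synthetic rates; the regression recovers a generative
model), not predictive accuracy on real measurements — the latter requires
the published harmonized dataset, which users can import with the mapping
helper.

## Validation statistics

Accuracy is measured on the log10 scale **against the 1:1 line**
(`log_accuracy()`): residuals $r_i = \log_{10} pred_i - \log_{10} obs_i$,
$S_e = \sqrt{\sum r_i^2 / n}$ and $R^2 = 1 - \sum r_i^2 / \sum
(\log_{10} obs_i - \overline{\log_{10} obs})^2$. The divisor is $n$
because the comparison line is fixed rather than estimated; an $n-1$
toggle is provided for re-deriving numbers computed under the other
convention. $R^2$ is not clamped and may be negative for predictors worse
than the observation mean.

`cross_validate()` implements three schemes: leave-chemical-group-out
(error on a chemically new group), leave-study-out (controls for
experimental bias) and a seeded random 10-fold split stratified by
material so no fold loses a material entirely. The mechanistic predictor
fits nothing, so its pooled cross-validated metrics equal its
whole-dataset metrics — a useful invariant test; the regression predictor
is refitted on every training fold, and its out-of-group error degrades
relative to its training error, reproducing the qualitative ranking
between the two models.

## Exposure scenarios and risk

Daily dose follows
$E_{mouthing} = \Delta t_{mouthing} \times (A_{contact}/10\,\text{cm}^2)
\times R_{mgr} / BW$ with four built-in scenarios (two age groups × average
and 99th-percentile mouthing behaviour):

| age group | BW (kg) | pacifier avg | doll avg | pacifier p99 | doll p99 |
|---|---|---|---|---|---|
| 3 to <6 months | 7.4 | 3.4 min/h | 0.5 | 37.3 | 2.5 |
| 2 to <3 years | 13.8 | 1.8 | 0.4 | 46.3 | 2.9 |

The tabulated durations are per hour while the dose equation needs minutes
per day; the conversion factor is exposed as the scenario parameter
`active_hours_per_day`, defaulting to 24 (i.e. the min/h figures are read
as day-averaged rates). Materials map to archetypes by rule — PVC, PP and
wood as dolls; silicone and EVA as pacifiers — with per-record overrides.
Archetype geometry ($d_p$, $V_p$, $V_f$) ships as synthetic representative
defaults in `inst/extdata/archetypes_synthetic_defaults.yaml`, fully
overridable; only $A_{contact} = 10$ cm² is anchored in the exposure
literature.

The hazard quotient $HQ = E_{mouthing}/RfD$ uses user-supplied oral
reference doses (CSV; experimental or QSAR-predicted provenance is
recorded, never computed here). `screen_inventory()` crosses every row
with every scenario, keeps rows lacking RfDs (flagged `no_rfd`), and
classifies each row × age group as `concern` (HQ > 1 already under average
behaviour), `upper_bound_concern_only` (HQ > 1 only at the 99th
percentile) or `below_threshold`. The threshold of 1 is the standard
equi-risk line and is configurable for sensitivity analysis. Only organic
chemicals are in scope: migration models for inorganics (e.g. heavy
metals) are a different problem and are not attempted.

## Problem sizes and test design

The test suite exercises the migration model on 1000-point randomized
parameter grids against an independently coded single-expression oracle
(agreement below $10^{-12}$), property-tests bounds and monotonicity on
hundreds of random draws, and uses synthetic datasets of 40–1000 rows and
a 20-seed × n = 500 replication for forward-selection recovery — sizes
chosen to make every statistical check stable while keeping the whole
suite interactive (tens of seconds).

## Known limitations

* Shipped QSPR coefficients and archetype geometries are synthetic
  representative defaults; quantitative agreement with any particular
  measured dataset requires substituting anchored coefficient tables.
* No temperature dependence; single implied temperature throughout.
* No concentration-saturation correction at very high formulation
  contents.
* Hand-to-mouth transfer and ingestion of scraped-off particles are
  separate pathways, out of scope.
* Textiles and coated surfaces would need adapted partitioning and are not
  covered.
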