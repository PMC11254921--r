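---
title: "Mass-balance accounting of insect-herbivory element fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance accounting of insect-herbivory element fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbflux)
library(dplyr)
```

## The problem

Background (non-outbreak) insect folivory removes a few percent of leaf
area in most broadleaved forests. Because the removed tissue is green —
eaten *before* the tree resorbs nutrients at senescence — it returns to the
soil as frass, cadavers, greenfall and leaf fragments that are far more
labile than leaf litter. Summed over a year and a stand, this flux can
rival atmospheric nutrient deposition. `herbflux` implements the standard
mass-balance accounting that turns two cheap field measurements — litter
mass in traps of known area and visual damage scores on collected leaves —
into per-plot, per-element flux estimates, compares them against labile
reference inputs, and quantifies their climatic drivers with mixed models.

## The accounting model

For each plot and element E (C, N, P, Si):

1. **Litterfall.** Each trap's collections are summed over a year and
   divided by trap area, giving $L_H$ (g m⁻² y⁻¹). Traps are averaged
   within a year, years (1 or 2) averaged unweighted. There is no
   partial-year extrapolation: litterfall is strongly seasonal, so a
   series spanning less than 300 days is an error unless the caller
   asserts it covers the complete leaf-fall season.

2. **Herbivory rate.** Litter leaves are scored into an undamaged class
   and six classes of leaf area removed (0–1, 1–5, 5–25, 25–50, 50–75,
   >75 %). $H$ is estimated by midpoint imputation:
   $H = \sum_k n_k m_k / N$ with $m = (0.5, 3, 15, 37.5, 62.5, 87.5)\,\%$.
   The class bounds are configurable so sensitivity to the midpoint
   choice can be tested. Scans within a year are pooled by summing counts
   (leaf-weighted); years are averaged unweighted. *Incidence* is the
   fraction of leaves in any damage class; an explicit undamaged count is
   required because a 0–1 % class is ambiguous about truly untouched
   leaves.

3. **Foliar production.** Traps only catch what survived folivory, so
   $FP = L_H / (1 - H)$.

4. **Gross flux.** $H_c = FP \times F_E \times H$, with $F_E$ the
   green-leaf mass fraction of E. Under a steady-state assumption the
   same mass reaches the floor annually as insect deposits; this is
   documented metadata, not a computed step.

5. **Resorption.** $RE_E = 1 - (c_\mathrm{litter}/F_E) \times MLCF$,
   where the mass-loss correction factor (senesced:green dry mass) is
   0.78 for predominantly evergreen and 0.784 for predominantly deciduous
   angiosperm stands. RE is computed for C, N, P only (Si is not
   resorbed). Values outside $[0,1]$, possible with noisy chemistry, are
   flagged but never clamped — silent clamping would bias net fluxes.

6. **Net flux.** $H_i = H_c \times RE_E$: the extra input caused by
   interception of green tissue before resorption. Equivalently, with the
   counterfactual litter flux
   $L_E = L_{EH} + FP \cdot H \cdot MLCF \cdot c_\mathrm{litter}$ (the
   consumed foliage, had it senesced, would shrink by MLCF and fall at
   litter concentration), the three-term budget
   $L_{EH} + H_c - L_E$ equals $H_c \cdot RE$ to machine precision. We
   adopt $H_c \cdot RE$ as the implementation because the three-term form
   leaves $L_E$ underdetermined otherwise; zone-level worked examples
   (e.g. boreal $0.082 \times 0.618 \approx 0.05$ g N m⁻² y⁻¹) confirm
   this reading, and the identity is enforced by a property test over
   10⁴ random inputs.

`compute_fluxes()` orchestrates these steps over a dataset bundle and is
tolerant of missing chemistry (row-level `error`, pipeline continues).

## Context and statistics

`zone_summaries()` gives zone means ± SE (sample SD / √n, `NA` for a single
plot) plus a plot-count-weighted global mean; `compare_references()`
expresses zone-mean $H_iN$ and $H_iP$ as percentages of atmospheric N and P
deposition and bedrock-weathered P (ratio of zone means by default — this
matches how such comparisons are conventionally tabulated — with a
per-plot-ratio variant behind `per_plot = TRUE`), and reports the share of
plots strictly exceeding the regional reference.

Zone contrasts use the Kruskal–Wallis rank test (via `stats::kruskal.test`)
followed by Dunn pairwise z tests with tie-corrected variance and Holm
(default) or Bonferroni adjustment; a compact letter display is derived
from maximal cliques of the not-significantly-different graph.

Driver analysis fits Gaussian random-intercept models (`lme4::lmer`, REML)
after a fixed preprocessing order: transform → z-score → VIF screen → fit →
parametric bootstrap. Transforms are assigned by variable type — fluxes,
production and concentrations are log transformed; proportions (H, RE,
incidence) logit transformed (exact 0/1 shifted by ε = 10⁻⁴); climate and
stoichiometry left untransformed unless skewness exceeds 2. All variables
are z-scored so estimates are standardized coefficients. Predictor sets
must pass a VIF < 2 screen. Confidence intervals come from 1000 (default)
parametric-bootstrap simulations (`lme4::bootMer`, percentile intervals —
the interval type is our choice, as none is conventionally fixed); an
effect is significant when its interval excludes zero. Marginal and
conditional R² are computed from the variance components
($R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_g + \sigma^2_e)$, $R^2_c$
adds $\sigma^2_g$ to the numerator). The random structure is a site
intercept by default; use `group = "plot_id"` nesting labels when plots
contribute multiple year-rows. A singular fit is returned with a warning,
zero variance component and $R^2_m = R^2_c$.

## The synthetic network generator

`generate_network()` simulates the whole observation chain so every
estimator can be checked against known truth:

* Sites draw MAT uniformly on −2…27 °C and dryness (PET/MAP) on
  0.21…1.30 — the ranges spanned by global broadleaved forests. Zones are
  assigned by MAT terciles (boreal coldest, tropical warmest): the
  analysis consumes zone labels and MAT, not geography, so latitude is
  synthesized only as a plausible label.
* Plot-level truth: $\mathrm{logit}(H) = a + b\,z(\mathrm{MAT}) +
  \mathrm{site} + \mathrm{plot}$ with defaults $a = \mathrm{logit}(0.04)$,
  $b = 0.4$, site SD 0.3, plot SD 0.1 (global mean H ≈ 4 %, plot range
  roughly 0.5–14 %, a strong standardized MAT effect ≈ 0.7–0.8);
  $\log(FP) = c + d\,z(\mathrm{MAT}) - e\,z(\mathrm{soil~C{:}N}) +
  \mathrm{noise}$ with $c = \log 350$, $d = 0.35$, $e = 0.15$.
* Green chemistry is drawn per zone (foliar N and P lower in the tropics);
  litter chemistry is constructed *exactly* as
  $c_\mathrm{litter} = F_E (1 - RE_\mathrm{true}) / MLCF$, so the
  resorption step recovers the true RE identically — an algebraic anchor
  for the whole net-flux chain.
* Trap masses are mean-one lognormal (SD 0.3) around
  $FP(1-H) \times \mathrm{area}$, split into twelve monthly collections;
  9–25 traps of 0.1–0.5 m² per plot.
* Damage tallies are multinomial over the seven classes. Damaged-leaf
  damage follows a beta distribution (concentration 1.2 — strongly
  right-skewed, as background damage is) whose mean is chosen by moment
  matching so that the class-midpoint estimator is *exactly unbiased* for
  the latent H. This matters: with an unbiased estimator, plot-level
  estimation error scales as $1/\sqrt{n_\mathrm{leaves}}$, which is the
  consistency property the tests verify (error halves when the leaf count
  quadruples). Incidence defaults to 12 × H (capped at 0.95), bracketing
  the observed global pattern of ≈ 49 % incidence at ≈ 4 % herbivory.
* Reference fluxes are fixed zone-level values typical of atmospheric N
  and P deposition and bedrock P weathering.

What the generator does **not** emulate: outbreak dynamics, within-year
temporal autocorrelation, multi-species leaf pools, spatially explicit
layouts, leaching losses, or observer error in damage scoring. Passing
recovery tests therefore show the estimators are correct under the stated
sampling model, not that field data meet that model.

## Numerical and design choices

* Concentrations are mass fractions in $[0,1]$ internally; all CSV I/O is
  in percent. This avoids silent 100× unit errors while matching how
  element panels are printed.
* Zone and phenology are required metadata, never inferred from latitude
  or climate.
* No partial-year litterfall extrapolation (seasonality makes linear
  scaling wrong); deciduous growing-season series must be explicitly
  flagged complete.
* Dunn adjustment defaults to Holm; Bonferroni is available as an option.
* All randomness flows from one integer seed; reruns are bit-identical.
* Problem sizes used in the shipped checks (30 sites × 2 plots, 200
  bootstrap draws, 20 replicate seeds, 400–4000 leaves per scan) are
  desk-scale choices that keep full verification runs in the minutes
  range while leaving comfortable statistical margins.

## Worked example

```{r example, eval = FALSE}
bundle <- generate_network(synthetic_config(n_sites = 20), seed = 1)
fluxes <- compute_fluxes(bundle)
per_plot_n <- dplyr::distinct(
  dplyr::filter(fluxes, element == "N"), plot_id, zone, fp, h, h_c
)
zone_summaries(per_plot_n, fp, h, h_c)
run <- run_all(bundle, out = "results", bootstrap_n = 200, seed = 1)
report_tables(run)
```

## Known limitations

Only folivory is represented (no sap-suckers, root herbivores, or
compensatory growth); herbivore C is not partitioned between biomass and
respiration; leaching and decomposition are out of scope; the zone-level
reference comparison inherits whatever uncertainty the deposition and
weathering reference values carry. The aggregation order for herbivory
(pooled counts per plot, rather than per-trap means) is a documented
choice; both orders agree closely at typical sampling intensities.
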