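# herbflux

Mass-balance accounting of the element fluxes mediated by **background
(non-outbreak) insect folivory** in broadleaved forests.

Insect folivores intercept green foliage before trees resorb its nutrients,
returning labile carbon, nitrogen, phosphorus and silicon to the soil as
frass, cadavers, greenfall and leaf fragments. `herbflux` turns the two
standard field measurements — litter-trap collections and binned visual
leaf-damage scores — into per-plot, per-element flux estimates, compares
them against labile reference inputs (atmospheric deposition, bedrock
weathering), and quantifies their drivers with mixed models. It is aimed at
ecosystem ecologists running litter-trap plot networks.

## The accounting

For each plot and element E:

| Quantity | Definition |
|---|---|
| Litterfall `L_H` | Σ trap leaf dry mass over a year / trap area (g m⁻² y⁻¹) |
| Herbivory rate `H` | Σₖ nₖ·mₖ / N over damage classes, midpoints m = (0.5, 3, 15, 37.5, 62.5, 87.5) % |
| Foliar production `FP` | `L_H / (1 − H)` |
| Gross flux `H_c` | `FP × F_E × H` |
| Resorption `RE_E` | `1 − (c_litter / F_E) × MLCF` (MLCF 0.78 evergreen, 0.784 deciduous; C, N, P only) |
| Net flux `H_i` | `H_c × RE_E`, identical to the litter-budget difference `L_EH + H_c − L_E` |

Zone contrasts use Kruskal–Wallis + Dunn post-hoc tests (Holm-adjusted);
drivers are estimated with random-intercept linear mixed models on
z-scored, log/logit-transformed variables, VIF-screened, with 95%
parametric-bootstrap confidence intervals and marginal/conditional R².
A synthetic plot-network generator with exposed ground truth backs the
parameter-recovery tests.

## Worked example

```r
library(herbflux)

bundle <- generate_network(synthetic_config(n_sites = 20), seed = 1)
fluxes <- compute_fluxes(bundle)
subset(fluxes, plot_id == "S01-P1" & element == "N",
       select = c(l_h, h, fp, h_c, re, h_i))
#> # A tibble: 1 × 6
#>     l_h      h    fp   h_c    re    h_i
#>   <dbl>  <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1  210. 0.0346  218. 0.170 0.558 0.0948
```

Reading: this plot dropped 210 g of leaf litter per m² and year; 3.5% of
leaf area was removed by folivores, so it actually produced 218 g m⁻² y⁻¹
of foliage. Folivores consumed 0.170 g N m⁻² y⁻¹ (`h_c`); since the tree
would have resorbed 56% of that nitrogen at senescence (`re`), the *net*
extra nitrogen input caused by herbivory is 0.095 g N m⁻² y⁻¹ (`h_i`).

Worked example on published-style zone summaries:

```r
zr <- zone_reference_values()
hin <- zr$mean[zr$variable == "h_i_N" & zr$zone == "tropical"]  # 0.26
atm <- zr$mean[zr$variable == "atm_n" & zr$zone == "tropical"]  # 0.38
reference_comparison(hin, atm)
#> [1] 68.42105   # tropical net insect N flux is ~68% of atmospheric N input
```

The full pipeline (`run_all()`) writes `fluxes.csv`, `summaries.csv`,
`comparisons.csv`, `tests.csv`, `models.csv` and a run log; a thin CLI
lives at `inst/cli/herbflux.R` (`simulate`, `validate`, `run-all`).

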