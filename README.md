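# deforisk

Deforestation-risk mapping, rate projection and carbon accounting for
REDD+-style regional planning.

`deforisk` implements the full analysis chain a forest-carbon program needs
to turn remote-sensing change maps into a defensible map of where forest is
most likely to be lost next, how much, and what that means in CO2 terms:

1. **Consensus change detection** — combine forest/non-forest grids from
   several imperfect classifiers; a cell counts as deforested only when every
   source agrees, and cells clouded in any source are excluded rather than
   treated as absences.
2. **Deforestation rates and projection** — annualized rates from the
   logarithmic form `r = ln(A2/A1) / (t2 - t1)` (with the FAO
   compound-interest form `q = (A2/A1)^(1/(t2-t1)) - 1` for comparison), and
   business-as-usual projection `A(t) = A0 e^{rt}`.
3. **Accessibility** — a friction surface built from land-cover travel
   speeds, road/river overrides and a slope penalty; least-cost travel time
   from towns over 8-connected moves (Dijkstra); accessibility index
   `exp(-time/tau)`.
4. **Presence-only maximum-entropy risk model** — a from-scratch Maxent-style
   fit of the Gibbs distribution `q(x) ∝ exp(λ·f(x))` over background cells,
   with linear/quadratic/hinge/categorical features, per-class L1
   regularization, replicate runs with test AUC, and permutation-based
   percent contributions per variable.
5. **Hard classification and carbon** — threshold the soft risk map on a
   0.01-step ladder so the selected area matches the projected loss, then
   convert hectares to Mg C (113 Mg C/ha by default) and Mg CO2 (×44/12).
6. **Validation** — compare predicted risk at centroids of later deforested
   patches (≥ 10 ha) against risk at stable-forest points with a
   Mann-Whitney U test.

Because real classified rasters are rarely shareable, the package includes a
seed-reproducible **synthetic landscape generator** (roads, rivers, towns,
designation zones, slope; contagious accessibility-driven clearing; noisy
classifier views with cloud gaps) so the entire pipeline is testable end to
end. Grids are plain planar rasters read and written as ESRI ASCII grids or
single-band float32 GeoTIFFs.

## Worked example

Rates, projection and carbon from a published-style forest-area record
(areas in ha):

```r
library(deforisk)

r <- puyravaud_rate(4146955, 4109955, 2006, 2009)
#> r = -0.002987417            # 0.30 %/yr loss
proj <- project_forest(4109955, r, 11)
#> proj$loss_ha = 132864.6     # BAU loss by 2020, ha
em <- emissions(proj$loss_ha, carbon_params())
#> em$carbon_mg = 15013701     # Mg C at risk
#> em$co2_mg    = 55050236     # Mg CO2
```

The whole pipeline on a synthetic landscape:

```r
out <- run_pipeline(sim_config(seed = 42), k = 10)
print(out$report)
#> <maxent_report> 10 runs: mean test AUC 0.980 (SD 0.002)
#>   percent contribution:
#>     accessibility                 98.7
#>     land_designation               1.3
print(out$validation)
#> <validation_report> 5 deforested-patch centroids vs 267 no-change points
#>   predicted risk: deforested 49% (SD 19) vs no-change 1% (SD 6)
#>   Mann-Whitney U = 8, two-sided p = 0.000156 (normal)
print(out$hard)
#> <hard_map> p* = 0.14: 1299 ha selected (target 1295.5 ha)
```

Reading the output: the replicate fits discriminate cleared from uncleared
cells almost perfectly (test AUC 0.98) and attribute nearly all explanatory
power to the accessibility index — the variable that drives clearing in the
simulation. Validation against the *later* epoch's consensus change shows
deforested-patch centroids carrying far higher predicted risk (49 %) than
stable forest (1 %), and the hard map selects the 1,296 ha the
business-as-usual rate projects to be lost, achieving 1,299 ha at risk
threshold p* = 0.14.

A thin command-line front end (`inst/cli/deforisk.R`) exposes the stages as
subcommands (`simulate`, `consensus`, `rate`, `access`, `fit`, `predict`,
`harden`, `validate`, `report`); every stochastic subcommand requires
`--seed` and writes a run manifest.

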