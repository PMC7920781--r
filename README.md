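# pollinet

Quantitative analysis of plant–pollinator visitation networks: weighted
bipartite modularity with null-model standardization, strength-based
topological roles, and sampling-completeness estimation — plus a
synthetic-data generator with planted ground truth so the entire pipeline
can be validated end to end.

`pollinet` is aimed at community ecologists who tabulate flower-visitation
records (which insect visited which plant, where, when, how often) and want
to answer, reproducibly and from one tidy table:

* **Is the network modular?** Barber's quantitative bipartite modularity
  `Q = (1/F) Σ_{i,j same module} (A_ij − k_i d_j / F)` is maximized by a
  seeded multi-restart label-propagation optimizer, certified against an
  exhaustive small-network oracle, and standardized against quantitative
  *vaznull* ensembles (total and connectance preserved, cell probabilities
  ∝ marginal products) as `Z_Q = (Q_obs − Q̄_null) / σ_null`, with
  `Z_Q > 2` flagging significant modularity.
* **Which plants hold structural roles?** Weighted among-module
  connectivity `c = 1 − Σ_t (s_t/s)²` and within-module connectivity `z`
  (both computed on species strength, not degree) are compared to 95%
  quantiles of the pooled null `c`/`z` distributions, classifying each
  plant as peripheral, connector, module hub or network hub.
* **How complete was the sampling?** Classic Chao1 asymptotic richness
  (with the `f2 = 0` fallback) and exact individual-based rarefaction, for
  pollinator species and for unique plant–pollinator interactions.

Everything takes a data frame first and returns tibbles; fitted objects
have broom-style `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate a community with four planted modules and one planted connector
plant, sample it through a multi-location, multi-season field design, and
run the full analysis:

```r
library(pollinet)

community <- generate_community(
  n_plants = 12, n_pollinators = 30, n_modules = 4,
  lambda_in = 2, lambda_out = 0.1, connector_count = 1, seed = 1
)
records <- sample_visits(community, sampling_design(), seed = 2)

mat <- build_matrix(records)
fit <- optimize_modules(mat, n_restarts = 20, seed = 3)
nulls <- null_ensemble(mat, n = 100, seed = 4, n_restarts = 20)
modularity_z_score(fit, nulls)
#> Q = 0.5415 vs 100 nulls (0.1893 +/- 0.0109): Z_Q = 32.36, Q_adjusted = 0.3522 (significantly modular)

roles <- assign_roles(role_scores(mat, fit$partition, "plant"),
                      critical_thresholds(nulls, 0.95))
dplyr::count(tibble::as_tibble(roles), role)
#> # A tibble: 3 × 2
#>   role           n
#>   <fct>      <int>
#> 1 peripheral    10
#> 2 connector      1
#> 3 module_hub     1

completeness_report(mat)
#> Pollinator species  : Chao1: S_obs = 30, S_est = 30.0 +/- 0.0 (f1 = 0, f2 = 0); 100% detected
#> Unique interactions : Chao1: S_obs = 189, S_est = 257.9 +/- 23.6 (f1 = 61, f2 = 27); 73% detected
```

The optimizer finds the four planted modules exactly (`Q = 0.54`), the
null comparison marks the structure as highly significant (`Z_Q = 32.4`),
and the planted connector (`plant_09`) is the one plant classified as a
connector. The interaction-level Chao estimate says roughly a quarter of
the distinct plant–pollinator links were still undetected at this sampling
depth — with only 30 evenly common synthetic pollinator species, the
species-level estimate saturates at 100%.

`autoplot(roles)` draws the c–z quadrant plot,
`autoplot(rarefaction_curve(interaction_abundances(mat)))` the
accumulation curve, and `plot_module_matrix(mat, fit)` the module-sorted
heatmap.

For empirical data, `read_records()` reads the standard CSV
(`plant,pollinator,guild,location,year,season,sample_id,floral_abundance,count`),
`subset_records()` / `reduce_by_occurrence()` carve the full record table
into location, consecutive-year, seasonal and reduced networks, and
`run_pipeline(run_config(...))` (or `standard_network_specs()`) runs the
whole battery and writes a network-level report, per-network role tables
and a completeness summary. A thin command-line wrapper with the same
verbs lives at `inst/scripts/pollinet.R`.

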