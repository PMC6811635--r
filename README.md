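# karstbeta

Community-level statistics for terrestrial subterranean fauna sampled
across the three-dimensional matrix of a karst massif.

Deep caves are sometimes presented as harbouring a unique deep terrestrial
fauna, by analogy with the deep sea. The competing view holds that the
whole bedrock is interwoven by a continuous fissure network, so that deep
and shallow communities are random subsamples of one massif-wide species
pool. The two views make opposite predictions about **beta diversity
(BD)** — the among-unit component of regional diversity — and about its
additive components: **turnover** (species replacement between sites) and
**nestedness** (one site's community being a partial subset of another's).
`karstbeta` implements the full pipeline that turns pitfall-trap survey
data into those tests, for ecologists analysing subterranean (or other
spatially stratified) incidence data.

## What it computes

Given seasonal trap counts, sampling-unit metadata (zone, depth stratum,
3D coordinates, trap effort) and species classifications
(obligate/non-obligate):

1. **Preprocessing** — pool seasons; normalize counts to individuals per
   trap per meter of passage (`count / (n_traps × passage_length_m)`);
   restrict to obligate subterranean species; reduce to presence/absence.
2. **Community comparison** — incidence-based Jaccard dissimilarity
   `(b+c)/(a+b+c)`; pairwise ANOSIM between massif zones
   (`R = (r̄_between − r̄_within)/(n(n−1)/4)`, permutation p); UPGMA
   dendrogram with Newick export; Mantel test (Spearman) against 3D
   Euclidean distances.
3. **Beta-diversity partitioning** — pairwise and multiple-site Jaccard
   family: `total = turnover + nestedness`, with
   `turnover = 2Σmin/((ΣSᵢ−S_T)+2Σmin)` built from the per-pair
   unique-species sums.
4. **Null models** — fill-preserving randomization (total number of
   presences held constant, placed uniformly over cells) with two-sided
   add-one p-values for every component, across the vertical
   (shallow-unit × deep-cave combinations, slope zone) and horizontal
   (per depth stratum) comparison sets.
5. **Synthetic scenarios** — a generator reproducing the reference survey
   design (20 units in three zones, 34 obligate species) under four
   assembly hypotheses (`bfn_random`, `deep_turnover`, `nested_central`,
   `slope_distinct`) for calibration and power checks.

## Worked example

```r
library(karstbeta)

# Desk calculation from printed zone figures: shallow upper zone
# (16 obligate species) and deep core (17) share 12 species.
p <- pair_counts_from_richness(16, 17, 12)
shared_percentage(p)        # 57
jaccard_dissimilarity(p)    # 0.4286

# Synthetic massif under the shallow-nested-in-deep hypothesis
dat <- generate_scenario(scenario_spec("nested_central", seed = 7))
sets <- c(build_vertical_sets(dat$units), build_horizontal_sets(dat$units))
battery <- run_fig_battery(dat$incidence, sets, n_null = 999, seed = 8)
subset(battery, setting == "vertical_central")
#>   statistic observed null_mean null_q025 null_q975 p_value stars
#>       total   0.8423    0.8931    0.8783     0.907   0.002    **
#>    turnover   0.8012    0.8659    0.8414     0.886   0.002    **
#>  nestedness   0.0411    0.0272    0.0144     0.045   0.090
```

Vertical BD in the central massif falls significantly **below** its null
(p = 0.002), driven by a deficit of turnover, while the nestedness
component sits above the null mean: shallow communities are subsamples of
the deep ones, so the massif is vertically more homogeneous than random
assembly predicts — the signature of connectivity with gravity-assisted
accumulation, not of an isolated deep fauna. The same data show no zone
separation by ANOSIM:

```r
anosim_pairwise(jaccard_matrix(dat$incidence),
                setNames(dat$units$zone, dat$units$unit_id),
                n_perm = 999, seed = 9)
#>          group1        group2       R p_value n_permutations
#> 1     deep_core shallow_upper  0.1905   0.070            999
#> 2     deep_core         slope -0.0335   0.607            999
#> 3 shallow_upper         slope  0.1360   0.172            999
```

`run_full(pipeline_config(...))` chains every stage (files or synthetic
scenario in, JSON report plus CSV/Newick artifacts out);
`analyze_study_data(dir)` runs the deterministic statistics on a local
copy of a survey deposit arranged as `abundance.csv`, `units.csv`,
`species.csv`. See the vignette in `vignettes/` for the model, parameter
and calibration details.

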