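# espcover

Unsupervised detection of covariates that modify the **effect-size
profile (ESP)** — the joint vector of per-exposure effect sizes linking
many omics variables to one outcome — for biostatisticians and
epidemiologists running omics association studies (metabolomics,
lipidomics, …) who suspect that "one effect size fits all" hides
subpopulations.

## Method in brief

For exposures $X_1,\dots,X_M$, outcome $Y$ and candidate modifier
covariates $Z_1,\dots,Z_J$, each window $W_\ell$ of covariate space gets
a profile $\mathrm{ESP}_\ell = (E_1^{W_\ell},\dots,E_M^{W_\ell})$ from
per-exposure fits of

$$ f(Y) = \beta_0 + \beta_m X_m + \sum_j \alpha_j Z'_j + \epsilon, $$

with $E_m = \beta_m$ (linear) or $E_m = e^{\beta_m}$ (logistic). The
pipeline has three steps:

1. **Cover** — overlapping gliding hyperrectangles span the continuous
   covariates (discrete covariates stratify exactly). Sides are the 95th
   percentile of per-point nearest-neighbour box sides (so a window
   typically holds at least `n_target = 20` observations); steps are the
   minimum side. Underfilled windows are dropped.
2. **Cluster** — per-window profiles, standardized per exposure across
   windows, are clustered by Ward agglomeration. The cluster number is
   the consensus of Calinski-Harabasz, Davies-Bouldin, silhouette and
   the elbow statistic $\delta_k = s_k/s_{k+1}-1$ on the inertia curve,
   then tested against a one-cluster null: $\delta_{k_1}$ must beat the
   elbows of `nref = 2000` matrices with each feature uniform over its
   observed range ($p < \alpha = 10^{-3}$).
3. **Regions** — window clusters map back to covariate space as regions
   with centroid ESP summaries, per-exposure between-region gaps, and
   fuzzy point-level membership (windows overlap, so points split their
   membership).

See the vignette (`vignettes/effect-size-profile-clustering.Rmd`) for
assumptions, parameter guidance and known limitations.

## Worked example

Simulate a two-region benchmark dataset (binary outcome, 30 exposures,
two uniform covariates; region B = both covariates above 0.5 carries
shifted exposure means for cases) and run the full pipeline:

```r
library(espcover)
ds  <- generate_dataset("D2", seed = 99)
fit <- esp_run(ds, confounders = character(0), seed = 99,
               early_stop = TRUE)
fit
#> <esp_fit>
#> <cover_geometry> 25 windows retained of 36 candidates
#>   L:     0.3685, 0.4104
#>   step:  0.172, 0.1732
#>   min_obs:  20
#> <cluster_selection> k_final = 2
#>   votes: calinski_harabasz=2, davies_bouldin=3, silhouette=2, elbow=2
#>   k1 = 2, delta_obs = 1.718, p = 0 (alpha = 0.001)
#> <region_summary> 2 region(s); window counts: 17, 8
#>   top exposure gaps: X12=1.8, X18=1.76, X28=1.69, X14=1.57, X1=1.56
```

Reading this: the automatic geometry chose ~0.37–0.41-wide windows
gliding in ~0.17 steps, keeping 25 of 36 candidate windows with at least
20 observations and both outcome classes. Three of the four indices
voted for two clusters; the observed elbow beat all 2000 uniform
reference elbows (p = 0 < 10⁻³), so two regions are reported — 8 of the
25 windows form the second region, matching the planted corner region,
and the exposures with the largest centroid gaps (X12, X18, …) are among
the planted shifted sets. A point deep in region B belongs to cluster 2
with membership 1:

```r
point_membership(fit$cover, fit$selection$labels, c(Z1 = 0.8, Z2 = 0.8))$fractions
#>  1  2
#>  0  1
```

`esp_run()` also accepts real tables: declare roles with
`column_roles()`, clean with `preprocess_observations()` (20%
missingness filters, kNN imputation with k = 3, log(1+x) +
standardization), and pass `outdir =` to write cover/ESP/selection/region
reports as TSV/JSON.

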