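# synchrec

Links annual recruitment of European anchovy (Age-1 abundance from the
MEDIAS/PELMED acoustic surveys) to an environmental **Synchronicity Index
(SI)**: the percentage bend correlation between monthly chlorophyll-a (CHL)
and mixed layer depth (MLD) over the window running from spawning onset
(April of year *t−1*) to the month preceding the survey (year *t*). The SI
captures how synchronously enrichment and concentration/retention processes
evolve during the first year of life — the idea being that this synchrony,
not any single variable's level, is what transfers across Mediterranean
sub-basins (Strait of Sicily, Gulf of Lions, Adriatic Sea).

The package is for fisheries/ecosystem analysts who want to compute the
index from per-area monthly environmental means and relate it to
recruitment.

## The model

For bend fraction β (default 0.2), the percentage bend correlation of the
window's CHL and MLD values is

ρ_pb = Σ aᵢbᵢ / √(Σ aᵢ² Σ bᵢ²),

where aᵢ, bᵢ are deviations from the percentage bend location, standardized
by the bend scale ω̂ (the ⌊(1−β)n + 0.5⌋-th smallest absolute deviation
from the median) and clipped to [−1, 1]. Its 95% CI comes from a pairs
bootstrap (B = 2999). Recruitment is then modeled pooled across areas:

log(1 + R*) = β₀ + β_SI · SI* + β_SST · SST* + ε,

with R*, SI*, SST* min–max scaled within area, fit by Huber M-estimation
(IRLS, k = 1.345), and per-coefficient Normal / Percentile / BCa intervals
from random-X case resampling (B = 2999).

A seasonal synthetic-data generator (cosine MLD/CHL cycles with a
controllable phase lag that sets the true synchrony, plus recruitment drawn
from the regression model) makes the whole pipeline testable end to end; see
`vignettes/synchrony-methods.Rmd` for the methods account.

## Worked example

```r
library(synchrec)

config <- pipeline_config(simulate = TRUE, n_boot = 2999, seed = 1,
                          out_dir = "synchrec-out")
res <- run_full(config)

subset(res$fit$cis$intervals, coefficient == "si_scaled")
#>   coefficient estimate family     ci_low ci_high significant
#>   si_scaled      0.293 normal      0.121   0.465        TRUE
#>   si_scaled      0.293 percentile  0.130   0.479        TRUE
#>   si_scaled      0.293 bca         0.120   0.466        TRUE

tapply(res$si_table$rho_pb, res$si_table$area_id, mean)
#>    AS   GoL   SoS
#> 0.322 0.559 0.779
```

Reading the output: the SI slope is positive and every interval family
excludes zero — years in which CHL and MLD co-vary strongly over the first
year of life have higher standardized recruitment — while the SST slope
(−0.027 here) straddles zero in all three families, i.e. no detectable
temperature effect. The per-area SI means show the gradient the default
scenario builds in: strong synchrony in SoS, intermediate in GoL, weak in
AS. Outputs land in `out_dir` as `si_table.csv` (one row per area-year),
`fit_table.csv` (3 coefficients × 3 interval families), `diagnostics.csv`
and a `manifest.txt` recording seed and settings; identical config + seed
gives byte-identical files.

A command-line wrapper lives at `inst/scripts/synchrec-cli.R`
(`simulate`, `si`, `fit`, `run`, `recover` subcommands).

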