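# pupsurv

Early-life survival analysis of free-ranging dog cohorts.

Free-ranging dogs scavenge in and around human settlements across South
Asia. Their pups die young, and mostly because of people: beyond road
accidents, poisonings and beatings, pups — male pups preferentially —
are simply carried off. `pupsurv` is an R package for analysing census
data on such birth cohorts (one record per pup, tracked from birth to a
210-day horizon), for demographers, urban ecologists and anyone
managing street-dog populations who needs mortality structure rather
than headcounts.

## What it computes

For a cohort of lifetimes *t* with right-censoring at 210 days:

* **Kaplan–Meier** survival, *S(t) = ∏(1 − dᵢ/nᵢ)*, with Greenwood
  variance, Brookmeyer–Crowley median confidence limits (log(−log)
  transform) and the unweighted two-sample **log-rank** test.
* A fixed-effects **Cox proportional-hazards** model (Efron tie
  correction) for litter size, sex and habitat effects on removal.
* **Competing risks**: Aalen–Johansen cumulative incidence
  *CIF_c(t) = Σ S(tᵢ⁻) d_{c,i}/nᵢ* over the five-way cause taxonomy
  (natural death, taken by human, murdered by human, road accident, no
  information), and **Gray's test** (ρ = 0) for sex differences in
  cause-specific incidence.
* **Demography**: litter-size summaries, a Mann–Whitney sex-ratio
  test, net pup counts by calendar month and the log-linear decline of
  survivor counts with age.
* A **calibrated synthetic census generator** (default: 95 litters,
  litter-size mean 3.98, births October–February, monthly hazards
  reconstructed from the published mortality tables) so every stage is
  testable without field data.
* The **selective-removal projection**: 1000 pups at a 1:1 sex ratio
  pushed through seven monthly classes under male-biased
  taken-by-human hazards and sex-neutral other hazards, quantifying
  the survivor sex-ratio skew that human preference for male pups
  produces.

The methods vignette (`vignettes/pup-mortality-methods.Rmd`) documents
the model, the hazard-schedule reconstruction and its assumptions.

## Worked example

```r
library(pupsurv)

coh <- generate_cohort(generator_config(seed = 1))
coh
#> Free-ranging dog pup cohort
#>   370 pups in 95 litters
#>   sex: 180 female / 190 male / 0 unknown
#>   habitat: 186 urban / 184 suburban
#>   survived to 210 d: 51 (13.8%)

cv <- km_fit(coh$records$exit_age_days, !coh$records$censored)
unlist(km_median_ci(cv)[c("median_days", "lo", "hi")])
#> median_days          lo          hi
#>          67          61          80

fr <- cohort_cox_frame(coh)
cox_fit(fr$duration, fr$event,
        fr[, c("litter_size", "sex_male", "habitat_urban")])
#> Cox proportional-hazards fit (Efron ties): n = 370, events = 319
#>                 coef exp(coef)     se      z      p
#> litter_size   0.0203    1.0205 0.0334 0.6089 0.5426
#> sex_male      0.1801    1.1974 0.1130 1.5935 0.1111
#> habitat_urban 0.0975    1.1024 0.1133 0.8600 0.3898

r <- coh$records[coh$records$sex != "unknown", ]
gray_test(r$exit_age_days, r$exit_code, r$sex, 2)$statistic
#> [1] 25.45  (p = 4.5e-07)

run_cohort_sim(default_sim_scenario())$final_ratio_f_per_m
#> [1] 1.733
```

Half the pups survive past day 67 in this draw (95% CL 61–80); none of
the three Cox covariates reaches significance at this single-cohort
scale, but being taken by humans is overwhelmingly male-biased (Gray
chi-square 25.5), and projecting a balanced cohort under those hazards
leaves about 1.73 surviving females per male at seven months.

The pipeline runs end to end with one call (or via the thin CLI at
`inst/scripts/pupsurv-pipeline.R`):

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

writing per-stage CSV reports, a summary of the headline statistics and
a MANIFEST, each stamped with version, seed and configuration hash.

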