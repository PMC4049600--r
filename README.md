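# nbackica

Group spatial ICA analysis of n-back working-memory fMRI, linking BOLD
activation of ICA-derived functional networks to task performance across age
groups — implemented as a fully tested R pipeline that runs end to end on
synthetic data.

## Who this is for

Researchers studying working-memory load effects in blocked n-back fMRI who
want a reproducible, scriptable version of the classic GIFT-style analysis
chain: temporal-concatenation group spatial ICA with stability analysis,
HRF basis-set temporal regression with an area-under-the-curve activation
statistic, behavioral speed/accuracy cost indices, and the component-level
age x load x performance inference chain. Because the original imaging
cohort is not publicly deposited, the package ships a synthetic-data module
that generates fMRI-like and behavioral data with the statistical structure
the analysis assumes, so every downstream stage is testable without any
download.

## The method

1. **Task model.** Blocked letter n-back: three load conditions (0-back,
   1-back, 2-back), two blocks of 100 trials each, targets in exactly half
   of the trials, TR 2 s (`build_schedule()`).
2. **Group spatial ICA.** Per-subject temporal PCA, concatenation, group
   PCA, infomax ICA (natural gradient, logistic nonlinearity), stability
   analysis over 10 randomized restarts by clustering pooled maps at
   1 − |correlation| (`run_group_ica()`), and GICA back-reconstruction of
   subject maps/time courses through the retained reduction operators. Model
   order by Gaussian-source MDL (`estimate_order()`).
3. **Temporal regression.** Each subject-level component time course is
   regressed on a design of 3 conditions x 3 HRF bases (canonical double
   gamma + temporal and dispersion derivatives), motion parameters and their
   first derivatives, and a constant (46 columns). The three basis
   coefficients per condition collapse into one activation value,

   `AUC = (b_can * sum(h) + b_td * sum(h_td) + b_dd * sum(h_dd)) / sum(h)`,

   and the **BOLD load effect** is `AUC(2-back) − AUC(0-back)` per subject
   and component.
4. **Behavior.** Responses faster than 200 ms or slower than 1500 ms count
   as incorrect; accuracy = correct/total, RT = median over correct valid
   trials; `speed_cost = (RT2 − RT0)/RT0`,
   `accuracy_cost = (acc0 − acc2)/acc0`; below-chance subjects (< 50% in the
   memory conditions) are excluded.
5. **Inference.** Mixed repeated-measures ANOVA (component within, age
   between; interaction dfs `(k−1, (N−2)(k−1))`), pooled-variance post-hoc
   t-tests, age x activation interaction regressions (age effect-coded and
   centered, activation z-scored within group), Spearman correlations, and
   the Fisher r-to-z comparison of independent correlations,
   `z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`.

See `vignettes/nback-ica-methods.Rmd` for assumptions, parameter choices and
limitations.

## Worked example

Desk statistics first — the correlation comparison between age groups (here
with the 2-back accuracy–activation correlations of the two cohorts) and the
group-level cost arithmetic:

```r
library(nbackica)
cc <- compare_correlations(-0.017, 38, 0.534, 37)
cat(sprintf("z = %.3f, p = %.3f\n", cc$z, cc$p))
#> z = -2.545, p = 0.011
round(cost_from_means(rt0 = 589, rt2 = 866, acc0 = .94, acc2 = .73), 3)
#>    speed_cost accuracy_cost
#>         0.470         0.223
```

The negative z says the accuracy–activation correlation is reliably stronger
in the older group; the old group pays a 47% speed cost and a 22% accuracy
cost going from 0-back to 2-back.

The full pipeline on the packaged small simulation (6 subjects per group,
12 x 12 x 8 voxel grid, 8 planted sources, 8 estimated components):

```r
cfg <- read_pipeline_config(system.file("extdata", "config-small.yaml",
                                        package = "nbackica"))
res <- run_pipeline(cfg, out_dir = "demo")
res$decompose
#> group ICA decomposition: 8 components, 12 subjects
#>   stability index range: 0.941 - 0.951
res$stats$anova
#>            effect      F df1 df2       p gg_epsilon   p_gg
#> 1           group 0.0472   1   9 0.83283         NA 0.8328
#> 2       component 3.0197   7  63 0.00843      0.619 0.0261
#> 3 group:component 0.9080   7  63 0.50624      0.619 0.4750
```

All 8 components come back with stability indices above 0.94 (tight ICASSO
clusters). One simulated subject was excluded for below-chance accuracy, so
the interaction degrees of freedom are (7, 63) = (8−1, (11−2)·(8−1)). At
this toy size the age x component interaction is not significant — the
packaged config plants an accuracy–activation coupling, not a group
difference in load effects. The run writes every intermediate table
(`activation.tsv`, `load_effects.tsv`, `anova.tsv`, `correlations.tsv`,
`report.txt`, ...) with a provenance header carrying the config hash and
seed; rerunning the same config reproduces them bit for bit.

A thin CLI wraps the same driver:

```sh
inst/cli/nbackica run --config inst/extdata/config-small.yaml --out demo/
```

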