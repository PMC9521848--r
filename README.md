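# capen — cross approximate entropy connectivity analysis for EEG trials

`capen` is an R package for nonlinear EEG functional-connectivity analysis
of two-arm, pre/post clinical trials, built around **cross approximate
entropy (C-ApEn)** — a delay-embedding statistic of the asynchrony between
two time series. It was developed for studies of the cortical
speech-articulation network in post-stroke apraxia of speech, where
connectivity is read from a fixed 10-site montage of the 10–20 system
(DLPFC at F3/F4, IFG at F7/F8, M1 at C3/C4, SPT at T5/T6, IPL at P3/P4)
during eyes-closed rest and an eyes-closed word-repetition task, before and
after treatment (e.g. anodal tDCS over the left lip region of M1 versus
sham).

## The statistic

For standardized series $u, v$, embedding dimension $m$, delay $\ell$ and
tolerance $r$ (in SD units), each template $u_i^m$ is matched against the
other series under the Chebyshev norm,

$$\Phi^m(r) = \mathrm{mean}_i \, \ln
  \frac{\#\{j: \|u_i^m - v_j^m\|_\infty \le r\}}{N-(m-1)\ell},$$

and the reported value is the direction-symmetrized
$\tfrac12[\Phi^m - \Phi^{m+1}]_{u\to v} +
 \tfrac12[\Phi^m - \Phi^{m+1}]_{v\to u}$.
Higher values = more asynchrony; a task-related increase is read as more
active interconnection between the two sites. The package computes this
with an O(N²) C++ kernel verified against brute-force enumeration, wraps
it in a preprocessing/epoching/artifact-rejection pipeline that produces
per-subject **difference values** (task − rest C-ApEn per electrode pair)
and **change scores** (post − baseline difference value), and adds the
full trial statistics layer: normality-routed two-group and paired
comparisons, pooled-SD Cohen's d, Pearson chi-square on contingency
counts, univariate screening with multivariate linear regression, and
paired-design power via the noncentral t distribution.

Because no raw recordings are released for the emulated study, the package
ships a first-class synthetic-trial generator (`simulate_trial()`):
coupled AR(2) latent-source recordings whose pairwise couplings are
programmable per arm/timepoint/condition, plus clinical covariates and
speech scores drawn from the published per-arm summaries, with an
empirical calibration step (`calibrate_effect_delta()`) that maps coupling
shifts to change-score effect sizes.

## Worked example

```r
library(capen)

# pooled-SD effect size from printed summaries (imitation subtest, change
# scores 5.63 +/- 2.41 vs 1.21 +/- 2.10):
cohens_d_pooled(5.63, 2.41, 1.21, 2.10)
#> [1] 1.955475

# baseline sex distribution, 10/2 vs 9/12 male/female:
chi_square(rbind(c(10, 2), c(9, 3)))
#> Pearson chi-square: statistic = 0.2526, p = 0.6152, d = NA (n = 12/12)

# design power of a paired test at dz = 1, n = 11:
paired_t_power(1.0, 11, 0.05)
#> [1] 0.9244891

# a small synthetic trial through the full pipeline:
design <- trial_design(n_per_arm = 2, duration_rest = 4, duration_task = 4,
                       n_extra_channels = 0)
config <- capen_config(params = capen_params(epoch_len = 500), min_epochs = 2)
trial  <- simulate_trial(design, effect_spec(post_offset = -0.08), seed = 1)
conn   <- connectivity_table(trial, config)
conn[1:3, c("subject", "arm", "pair", "diff_baseline", "diff_post", "change")]
#>   subject  arm  pair diff_baseline diff_post change
#> 1     S01 tDCS F3-F7         0.016     0.070  0.054
#> 2     S01 tDCS F3-P3         0.027     0.038  0.011
#> 3     S01 tDCS F7-C3         0.015     0.080  0.065
summary(conn)
#> Mean difference values and change by arm and pair category:
#>       arm         category diff_baseline diff_post    change
#> 1 control interhemispheric        0.0404    0.0382 -0.002140
#> 2    tDCS interhemispheric        0.0332    0.0406  0.007417
#> 3 control       left-intra        0.0364    0.0374  0.000987
#> 4    tDCS       left-intra        0.0304    0.0556  0.025135
#> 5 control      right-intra        0.0430    0.0419 -0.001034
#> 6    tDCS      right-intra        0.0378    0.0327 -0.005160
```

The decoupling programmed into the active arm's left-hemisphere pairs
(`post_offset = -0.08`) surfaces exactly where it should: the tDCS arm's
left-intra change (0.025) stands out against every other arm × category
cell (|change| ≤ 0.007). `compare_changes(conn)` turns this into the
per-pair between-arm report with p-values and effect sizes;
`run_simulate()` / `run_connectivity()` / `run_stats()` are the same steps
as on-disk, self-describing runs.

## Documentation

The methods vignette (`vignettes/capen-methods.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, the calibration
procedure, numerical conventions (zero-match floor, degenerate epochs,
direction symmetrization, variance budgets), and known limitations.
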