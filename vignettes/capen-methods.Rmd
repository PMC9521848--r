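---
title: "Cross approximate entropy connectivity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross approximate entropy connectivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the statistic it
computes, the pipeline around it, the synthetic trial generator, and the
numerical and design choices that were genuinely open.

## The statistic

Cross approximate entropy (C-ApEn) quantifies the asynchrony of two
equal-length time series $u, v$ by template matching. Both series are
standardized per epoch. With embedding dimension $m$, delay $\ell$ and
tolerance $r$ (in SD units), the delay vectors
$u_i^m = (u_i, u_{i+\ell}, \dots, u_{i+(m-1)\ell})$ are compared under the
Chebyshev (maximum-coordinate) norm, and for each query template the
conditional match fraction against the *other* series is

$$C_i^m(r) = \frac{\#\{j : \|u_i^m - v_j^m\|_\infty \le r\}}{N-(m-1)\ell},
\qquad
\Phi^m(r) = \frac{1}{N-(m-1)\ell} \sum_i \ln C_i^m(r).$$

The directed statistic is $\Phi^m(r) - \Phi^{m+1}(r)$: how much *less*
predictable the second series becomes when templates are extended by one
sample. Electrode pairs are unordered, so the package reports the average
of both directions, which also makes `cross_apen(u, v)` exactly symmetric.
`apen(u)` is the self-comparison special case (`cross_apen(u, u)`), in
which every template has a guaranteed self-match. Higher values mean less
mutual predictability (more asynchrony); in the connectivity literature a
*higher* task-related C-ApEn is read as *more active* interconnection
between the two cortical sites.

Because standardization is internal, the statistic is invariant under
positive affine rescaling of either input — amplifier gain and offset do
not matter — and this is enforced by tests to $10^{-10}$.

### Zero matches, degenerate epochs

Unlike the self-comparison case, cross comparison has no guaranteed match,
so $C_i = 0$ (and $\ln 0$) can occur. Dropping such templates would bias
$\Phi$ asymmetrically between the two directions; the package instead
substitutes the smallest observable probability $1/(N - m\ell)$ and counts
the substitution (`floor_triggered`, `n_floored`). Floored epochs are
reported through the pipeline's `flags` column.

A constant (zero-variance) epoch cannot be standardized. It is perfectly
predictable, so the convention is a value of 0 with a `degenerate` flag
rather than an error; batch runs survive flat channels and the affected
cells remain identifiable.

### Parameter defaults and why

* `m = 2`, `lag = 1`, `epoch_len = 1000` (2 s at 500 Hz): standard choices
  for entropy statistics on EEG. All are config-exposed.
* `r_frac = 0.5`. This deliberately departs from the single-series ApEn
  convention of $0.2\,\mathrm{SD}$. For *cross* comparison at $N \le 1000$
  the 0.2 tolerance leaves most templates with zero matches at dimension
  $m+1$; the floor then dominates both $\Phi$ terms and the statistic
  becomes insensitive to genuine coupling — in measurements it was even
  slightly *increasing* in coupling strength, because stronger shared
  rhythms raise the dimension-$m$ match rate while the floored
  dimension-$m{+}1$ term stays pinned. At $r = 0.5$ match counts are
  sufficient at both dimensions and the statistic decreases monotonically
  with coupling. Users reproducing single-series ApEn conventions can set
  `r_frac = 0.2` explicitly.

The package keeps two implementations: an optimized O($N^2$) kernel in C++
(one pass accumulates both embedding dimensions and both directions, using
the symmetry of the cross-distance matrix), and the plain R operations
(`delay_embed()`, `match_fraction()`, `phi_stat()`) that define the
construction. The test suite holds the kernel to within $10^{-10}$ of an
independent brute-force enumeration written separately in the tests.

## The montage and its pairs

Ten electrodes of the 10–20 system cover five bilateral nodes of the
speech-articulation network: DLPFC (F3/F4), IFG (F7/F8), M1 (C3/C4),
SPT (T5/T6), IPL (P3/P4). The F7/F8 leads sit over the inferior frontal
gyri (the crossing of T3–Fz with F7–Cz and its mirror); this placement is
montage metadata and does not change any computation. Twenty-one pairs are
analyzed: 8 left intra-hemispheric, their 8 right mirrors, and the 5
homologous inter-hemispheric pairs, in a fixed report order. Recordings
with extra channels (a 16-channel session) load unchanged; the pipeline
selects the ten analyzed sites and errors only if one is absent.

## The pipeline

1. **Band-pass 1–45 Hz plus 50 Hz notch**, zero-phase (forward–backward
   Butterworth). The recording hardware band is wider (0.3–100 Hz); the
   analysis band is this package's choice, and 50 Hz is the mains
   frequency where the emulated study ran. Both are config-exposed.
2. **Non-overlapping epochs** of `epoch_len` samples. An epoch is dropped
   for all channels when any analyzed channel's peak amplitude exceeds
   `reject_sd` (default 5) times that channel's whole-recording SD — a
   deliberate, documented simplification standing in for manual
   electromyography screening. If every epoch of a recording is rejected,
   the affected cells are marked missing and the run continues.
3. **Per-epoch standardization** (not whole-recording), so the tolerance
   tracks local variance and slow drifts do not inflate matches.
4. **Per-pair C-ApEn averaged over retained epochs**; cells with fewer
   than `min_epochs` epochs (default 10) become missing values, never
   zeros.
5. **Difference value** = task − rest, per pair and timepoint. The sign
   convention is chosen so that task-elevated asynchrony — the typical
   pattern during overt repetition — is positive. **Change score** =
   post − baseline difference value. Missing inputs propagate.

The resulting table has one row per subject × pair with the full set of
cell values, epoch counts and flags, and is written as delimited text.

## The synthetic trial generator

No raw recordings are distributed with the emulated study, so the
generator is a first-class module: it produces the complete dataset the
pipeline consumes — two arms × two timepoints × two conditions of
multichannel recordings plus clinical covariates and five speech subtest
scores — with the statistical structure the analysis assumes.

**Signals.** Each analyzed pair owns a dedicated resonant AR(2) latent
source (pole radius 0.95, peak 10 Hz — an alpha-band rhythm at 500 Hz
sampling). A channel is the weighted sum of its pairs' sources plus a
white private remainder:
$$x_i = \sum_{p \ni i} \sqrt{c_p}\, s_p +
        \sqrt{1 - \textstyle\sum_{p \ni i} c_p}\;\varepsilon_i
        \; (+ \text{sensor noise}),$$
so a pair's coupling $c_p \in [0,1]$ is exactly the correlation its shared
source contributes, and decoupling a pair shifts both channels toward
broadband noise. That last property is essential: for jointly Gaussian
signals with *identical* spectra, C-ApEn is nearly blind to pure
cross-correlation (measured: a change of only ~0.03 across the whole
coupling range), because both series keep the same pattern vocabulary.
Coupling must move the rhythmic-vs-broadband balance for a
template-matching statistic to see it, which this construction provides
while still realizing the requested pairwise correlations. Feasibility is
a per-channel variance budget ($\sum_{p \ni i} c_p \le 1$); violations
raise an error naming the channel and its pairs, and the per-subject
jitter is proportionally capped so random draws stay feasible.

**Conditions and effects.** Rest couples all pairs at `base_coupling`
(0.15); the task subtracts 0.03 everywhere (slight task decoupling, giving
the small positive baseline difference values seen in such tables); after
treatment the programmed pairs decouple by a further `post_offset`. The
default programmed topology matches the emulated trial's significance
pattern: left-hemisphere pairs F3-F7, F7-C3, P3-F7, T5-P3, T5-F7 for the
active arm, and F8-C4, T6-F8, F3-F4, F7-F8 for the control arm.
Per subject, pair and cell, couplings get independent Gaussian jitter
(SD 0.03), which is the dominant between-subject variance component.

**Calibration.** No closed form links a coupling shift to the
change-score effect size, so `calibrate_effect_delta()` measures the
mapping by seeded simulation through the actual synthesis and analysis
path and solves for the shift giving a target standardized between-arm
difference (default 1.0 SD). Two details matter:

* It calibrates *in montage context*. Pairs sharing an electrode interact
  through that channel's variance budget — four of the five active pairs
  contain F7, and the control topology touches F7 via F7-F8 — so the
  probed quantity is the realized separation between the active-post and
  control-post profiles averaged over the programmed pairs, not an
  isolated-pair lookup.
* The change score combines four cells (two conditions × two timepoints)
  with independent jitter and estimation noise, so its SD is modeled as
  $2\sigma_\text{cell}$ with $\sigma_\text{cell}$ measured at the
  unperturbed task profile (homoscedastic approximation over the
  operating range; verified empirically by the pattern-recovery suite,
  where the realized effect size comes out within a few percent of the
  target).

**Clinical data.** Covariates and speech scores are drawn from truncated
normals whose *latent* means are solved so the realized (truncated) means
equal the published per-arm summaries; categorical variables use the
published frequencies. Baseline and post scores share a Gaussian copula
with latent correlation 0.5 (`rho_scores`, config-exposed; the true
within-subject correlation is unknown and this value is a labelled
stand-in). Scores are rounded to integers and respect their instrument
ranges (counting 0–10, imitation 0–20, alphabet 0–20, mono/di 0–10).
Truncation shrinks SDs below the printed ones — the generator matches
means exactly, SDs only approximately; this is a known, accepted
limitation.

**What the generator does not emulate.** Real EEG nonstationarity,
1/f background, eye-blink and electromyographic artifacts (beyond optional
amplitude spikes for testing the rejection rule), volume conduction,
montage reference effects, and any nonlinear coupling mechanism. Passing
tests therefore demonstrate that the pipeline recovers the structure this
linear-mixture model encodes, not that it would behave identically on
clinical recordings.

## The statistics layer

* **Routing.** Each comparison applies the Shapiro–Wilk test at 0.05 per
  variable (on paired differences for within-group contrasts) and routes
  to the t-test (pooled variance for independent groups) or the
  asymptotic tie-corrected rank test. All p-values are two-tailed;
  all-tied paired samples short-circuit to p = 1.
* **Effect size.** Pooled-SD standardized mean difference
  $d = (m_1 - m_2)\big/\sqrt{(s_1^2+s_2^2)/2}$ — the root mean of the two
  variances, not $n$-weighted pooling and, for pre/post contrasts, not the
  change-score SD. This is the only convention that reproduces all the
  published cells the suite checks (to ±0.001 across four tables);
  reports print the magnitude.
* **Chi-square.** Pearson statistic without continuity correction,
  df = k−1, asymptotic two-sided p. Reproduces the published sex, insula,
  severity and etiology comparisons to ±0.001. The published basal-ganglia
  p (0.572) does not match any Pearson computation on its printed counts
  (which give 0.673) and is not asserted.
* **Regression screen.** Univariate OLS per candidate; candidates with
  p < 0.2 plus the treatment-arm term (always kept) enter one multivariate
  OLS. Standardized coefficients are $B \cdot s_x / s_y$. Aphasia type and
  severity enter as single ordinal codes (Global=0, Mixed=1, Broca=2;
  severity 0/1/2), matching one-coefficient-per-variable reporting. Under
  pure noise the screen retains candidates at the nominal 0.2 rate
  (calibration-checked).
* **Power.** Paired-design power via the noncentral t distribution,
  df = n−1, noncentrality $d_z\sqrt{n}$. The default is **one-sided**:
  that is the convention under which the emulated trial's sample size was
  planned — $d_z = 1.0$, $n = 11$, $\alpha = 0.05$ gives 0.9245, matching
  the published 0.924, whereas the two-sided computation gives 0.848.
  `alternative = "two.sided"` is available and is cross-checked against
  Monte-Carlo simulation in the suite.
* **Multiplicity.** No correction across the 21 pairs by default (the
  emulated analysis applied none); `adjust = "BH"` adds
  Benjamini–Hochberg columns for users who want them.

## Problem sizes used by the stochastic suites

The package defaults mirror the study conditions (12 subjects per arm,
500 Hz, ~5 min rest, 1000-sample epochs, ≥10 epochs per cell). The
stochastic test suites run the same machinery at reduced problem sizes,
chosen once as a package decision: 400-sample epochs, one epoch per
condition cell (`min_epochs = 1`), 10-channel recordings, 200 replicates
for pattern recovery and ~1000 pair comparisons for the null calibration.
The calibration step makes the programmed effect size 1.0 *at that scale*,
so the recovered detection frequency is compared against the theoretical
two-sample t power at d = 1.0, n = 12 per arm (≈0.65). Two interval
conventions were fixed before any measurement: the binomial band for the
detection frequency uses n = 200 replicates (the five programmed pairs
within a replicate share subjects and are not independent trials), and the
screening-calibration band uses n = 1000 replicates.

## Known limitations

* The C-ApEn parameter set of the original analyses is not published;
  the defaults here are field conventions plus the documented cross-series
  tolerance adjustment, not a reproduction.
* Whether the original computation symmetrized comparison directions, or
  averaged epochs versus analyzing whole recordings, is unstated; this
  package symmetrizes and averages epochs.
* Subject-level connectivity results of the emulated trial cannot be
  reproduced without its unreleased recordings; only its printed summary
  statistics are recomputable, and the remaining claims are checked as
  properties of the calibrated synthetic system.
* The amplitude-SD rejection rule is a stand-in for the original studies'
  manual artifact handling.
* EDF input is not implemented; delimited text is the canonical format
  (one column per channel, header row of electrode labels, rate in the
  dataset manifest).
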