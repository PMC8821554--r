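---
title: "Models and methods behind msnacor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msnacor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnacor)
```

# The scientific problem

Sudden, arousing stimuli trigger a defense reaction whose sympathetic arm
differs sharply between people: roughly half of healthy subjects transiently
*inhibit* their muscle sympathetic nerve activity (MSNA) after an unexpected
stimulus, while the rest inhibit weakly or even increase their
vasoconstrictor traffic. These response profiles are stable traits, and they
matter: individuals who do not inhibit show a transient blood-pressure rise
after each stimulus that Inhibitors lack. Because the only direct measurement
is invasive microneurography, there is strong interest in non-invasive
cortical correlates — oscillatory responses measured with MEG and structural
measures such as cortical thickness in the central autonomic network
(rostral anterior cingulate, insula) and the sensorimotor (Rolandic) cortex.

`msnacor` implements the complete analysis chain for this problem —
inhibition quantification, Inhibitor classification, beat-aligned
blood-pressure comparison, LCMV source reconstruction, time–frequency
analysis with cluster-based permutation statistics, and thickness
correlations — together with a synthetic-data generator that emulates the
recordings with controllable ground truth, so every stage is testable
without access to human data.

# The MSNA inhibition statistic

A subject receives 72 stimulus trials. Each trial delivers electric pulses
locked 200 ms after the ECG R-wave: 5 shocks on consecutive cardiac
intervals in the microneurography variant, or 3 pulses on alternating
heartbeats in the MEG variant (leaving a free post-pulse window of roughly
1.5–2 s, depending on heart rate). Burst amplitudes are bookkept per cardiac
interval, with absent bursts entered as zero amplitude. The statistic is the
grand-mean ratio

$$\mathrm{inhibition} = 100 \left(1 -
  \frac{\bar A_\text{post}}{\bar A_\text{base}}\right)\,[\%]$$

where $\bar A_\text{base}$ pools the 8 stimulus-free cardiac intervals
immediately preceding each trial and $\bar A_\text{post}$ pools the
stimulated intervals of each trial. The statistic is capped at $+100\%$ by
construction (an integrated burst cannot be more than absent) and can go
far negative: $-200\%$ corresponds to post-stimulus bursts at three times
the baseline mean. Subjects with inhibition **strictly greater than 30%**
are Inhibitors; the threshold is the symmetric bound covering 95% of
between-subject variability when the same statistic is computed against
*dummy* triggers (R-wave-timed triggers without stimulation), which
`calibrate_dummy()` reproduces as the empirical 95th percentile of absolute
dummy deviations.

Design choices where the field leaves latitude:

* **Grand-mean ratio, not mean of per-trial ratios** (default). Per-trial
  ratios are undefined whenever a single trial has a burst-free control
  window, which happens regularly at realistic burst incidence; the pooled
  form is robust. `compute_inhibition(per_trial = TRUE)` provides the
  alternative.
* **Post-stimulus window**: the cardiac interval carrying each pulse of a
  trial, pooled over the trial's pulses; `pulses =` restricts it (e.g. to
  the first, unexpected pulse).
* **Low-baseline guard**: profiles supported by fewer than 5 baseline
  bursts are flagged `unreliable` — relative change is poorly determined
  when baseline MSNA is very low, the situation that produced the one
  strongly excitatory outlier (−132%) the classifier must still label
  Non-inhibitor.

## Burst detection

Detection on the integrated neurogram is deliberately simple: the baseline
is estimated by morphological opening — a rolling minimum followed by a
rolling maximum over 0.8 s, wide enough to swallow a whole burst — smoothed
with a 10 s running median to absorb drift; the amplitude attributed to a
cardiac interval is the peak of the corrected signal 0.8–1.8 s after its
R-wave (bracketing the typical peroneal reflex latency of ~1.3 s). A plain
running median is *not* used as baseline because bursts occupy more than
half of all samples at high burst incidence, which drags a median baseline
into the bursts themselves. The detection threshold is 4 robust noise SDs
(MAD): each interval's amplitude is a maximum over ~100 samples, and the
expected extreme of Gaussian noise over 100 samples is itself ~3 SD, so a
3 SD cut would register spurious bursts in ~10% of empty intervals while
4 SD keeps that below 0.5% without losing the smallest admissible bursts.

# Blood pressure

`align_beats()` converts per-trial beat series into trial-averaged
change-from-baseline curves, with the pre-stimulus baseline defined as
beats −8..−1 — mirroring the 8-interval MSNA control window; there is no
fixed field convention for this window, so it is exposed as an argument.
`compare_groups()` tests Inhibitors against Non-inhibitors at post-stimulus
cardiac interval 6 (where the pressure effect of a present or absent burst
peaks) with a two-sided Wilcoxon rank-sum test — exact when the combined
sample is ≤ 20 and tie-free, normal approximation with continuity
correction otherwise. `screen_beats()` runs the same test for heart rate
and pulse pressure over beats 1–15; raw p-values are reported and no
multiplicity correction is applied when all are ≥ 0.05 (none is then
needed). `correlate_inhibition_bp()` is the Spearman correlation between
individual inhibition and the beat-6 response.

# Source reconstruction

The LCMV beamformer computes, per 5-mm grid point with leadfield $l$,

$$w = \frac{C^{-1} l}{l^\top C^{-1} l},$$

which passes unit gain ($w^\top l = 1$) at the target location while
minimizing output variance. The covariance $C$ is estimated with **all
conditions combined** (1.5 s baseline before pulse 1 and the 1.5 s windows
after pulses 1–3) so one unbiased filter serves every condition; ±5 ms
around each stimulus is excised against artifacts; $C$ is regularized as
$C + \lambda\,\overline{\mathrm{diag}(C)} I$ with $\lambda = 5\%$ (exposed).
Free-orientation leadfields are reduced to a scalar beamformer along the
max-power orientation (principal eigenvector of $(L^\top C^{-1}L)^{-1}$).
Source power per condition is the mean squared filter output; each pulse
condition is contrasted with baseline as $(P - P_b)/P_b$; within each ROI
only grid points reaching **60% of the ROI's peak contrast** are kept, and
their single-trial outputs are averaged into one ROI time series per trial.
Forward modelling is out of scope: leadfields are inputs, and the package
generates toy leadfields (random unit vectors on a 5 mm grid) that are
synthetic by construction — sufficient for validating the inverse
machinery (unit gain, localization round trips, permutation invariance),
not for anatomical realism.

# Time–frequency analysis and statistics

`tfr_hanning()` decomposes each ROI trial series over 5–40 Hz with a
**7-cycle Hanning-tapered sliding window** shifted in 5 ms steps: the
window at frequency $f$ spans $7/f$ s (0.7 s at 10 Hz), and time points
whose window would cross the data edge yield `NA` rather than silently
zero-padded estimates — with 1.5 s epochs this means low frequencies have
a reduced valid time range, which all downstream statistics respect.
Decomposition is per trial; power is averaged across trials afterwards.
Relative power is $(P - \bar B_f)/\bar B_f$ against the frequency-wise mean
baseline power of the pre-pulse-1 epoch, per subject, making every map
invariant to subject-level signal scaling.

The **cluster-based permutation test** asks where in the time–frequency
plane power correlates with inhibition across subjects while controlling
the family-wise error over the whole map: per-bin Spearman correlations are
converted to t statistics; bins passing a two-sided $p < 0.05$
cluster-forming threshold are clustered by 4-neighbourhood adjacency
separately by sign; cluster mass is the sum of bin statistics; the null
distribution of the maximum absolute mass is built from 1000 permutations
of the inhibition values (pooled over signs, two-sided), and cluster
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm}+1)$, which can
never be zero. For significant clusters the per-subject cluster-averaged
power and its Spearman correlation with inhibition are reported. The
cluster-forming threshold, adjacency rule, frequency spacing (2.5 Hz
default over the stated 5–40 Hz range) and statistic are conventions of the
standard toolboxes for this test and are all configurable. Because
permuting the covariate is exact under the null, the test's family-wise
error is controlled by construction; the acceptance suite verifies this
empirically on 200 null cohorts.

Two deliberately simpler summaries complement the cluster test: the
**generic window correlation** (mean relative power in 13–25 Hz × 0.5–1.2 s
versus inhibition, a window usable as a prior in future studies) and the
**group beta time course** (13–25 Hz band mean ± SEM per group with
uncorrected two-tailed t-test marks, explicitly labelled visual guidance
only).

# Cortical thickness

The bilateral rostral-ACC estimate is the mean of the left and right label
thicknesses (a missing hemisphere is an error, never a silent fallback).
Spearman correlations with inhibition are Bonferroni-corrected over the
three pre-selected ROIs (insula, rostral ACC, Rolandic); the insula is
reported bilaterally and per hemisphere because the electrophysiological
analysis used only the side contralateral to stimulation while the
structural convention is not fixed. Spearman p-values are exact for
n ≤ 10 tie-free data and use the t approximation above.

# The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

* cohort of 20 subjects; resting heart rate 56 ± 7.8 beats/min; resting
  burst incidence 44.3 per 100 heartbeats (cohort characteristics of the
  emulated study);
* 72 trials per session; inter-trial intervals drawn from {30, 45, 60} s
  once per session and shared by all subjects; every pulse 200 ms post-R;
  5 consecutive-interval shocks (microneurography) or 3
  alternating-heartbeat pulses (MEG);
* subject inhibition ~ Normal(30, 35²) %, truncated at +100. The mean sits
  at the classification threshold, reproducing the observed even 10/10
  Inhibitor/Non-inhibitor split in expectation; the SD spans the reported
  empirical range (down to about −130% for the rare excitatory outlier,
  which can also be injected exactly via `outlier_inhibition`);
* burst amplitudes log-normal with CV 1.0. This CV is the calibration
  target of the dummy-trigger analysis: with 72 trials it places the 95%
  bound of null-subject deviations near ±30%, the published basis of the
  Inhibitor threshold. Amplitude distributions themselves are not reported
  anywhere, so this is a stipulation, flagged here;
* beta rebound: post-pulse epochs are 1/f noise plus a ~19 Hz oscillation
  whose envelope dips 0–0.4 s (desynchronization) and overshoots 0.5–1.2 s
  (rebound). The rebound gain is monotone in a subject latent
  $c\,z(\text{inhibition}) + \sqrt{1-c^2}\,\varepsilon$ with
  $c = $ `rebound_coupling` (default 0.8, echoing the strong published
  cluster correlations). The rostral ACC responds only after pulses 2 and
  3; the insula responds but is uncoupled from inhibition; the Rolandic
  region responds to all pulses;
* blood pressure: Non-inhibitor MAP rises by `bp_rise_nonin` (default
  4 mmHg, carried mainly by diastolic pressure) peaking at beat 6;
  Inhibitors stay flat; beat noise 2 mmHg;
* thickness: rostral-ACC thickness decreases with the analogous
  thickness-coupling latent (default coupling 0.6, scale 0.25 mm per unit
  latent, measurement noise 0.05 mm), clipped to the plausible 1.5–4.5 mm
  range; other ROIs vary independently.

Both couplings use the latent-mixture form so that each generated cohort
carries a *realized* ground-truth rank correlation (stored in
`ground_truth`, never read by analysis stages) against which pipeline
recovery can be judged — with coupling 1 and no noise the rank correlation
is exactly ±1, with coupling 0 the quantities are independent.

What the generator does **not** emulate: real ECG morphology (only R-times
exist), realistic MEG forward physics (toy leadfields), skin sympathetic
activity, respiration beyond a no-effect channel, habituation across
trials, and any non-stationarity of the couplings. Passing tests therefore
demonstrate that the *analysis chain* is correct and calibrated under
controlled conditions — not that real recordings satisfy the generator's
assumptions.

# Numerical and reproducibility choices

* Every public generator takes an explicit seed; `gen_cohort()` derives
  per-subject, per-stage sub-seeds from the single spec seed with a fixed
  integer mixing formula, so cohorts are bit-identical under one seed and
  single stages can be regenerated independently.
* Permutation p-values use $(1+k)/(n_\text{perm}+1)$; permutation draws are
  seeded and logged in the result object.
* The per-bin Spearman-to-t conversion clamps $|r|$ away from 1 to avoid
  infinite masses on degenerate maps; constant bins get statistic 0.
* `wilcox.test` switches from exact to asymptotic at combined n > 20 or in
  the presence of ties (mid-ranks, continuity correction).
* Degenerate inputs fail loudly: zero baseline activity is an undefined
  statistic (an error, not a number), all-tied group comparisons return
  p = 1 with a warning, an all-negative-contrast ROI falls back to its
  single peak vertex with a warning, and TFR rows whose window exceeds the
  epoch are `NA` with a warning.

# Problem sizes used by the test and acceptance suites

The unit suite exercises everything on deliberately small cohorts (4–20
subjects, 4–24 trials, reduced frequency grids). Two checks run at larger
scale as the package's chosen validation sizes: the family-wise error of
the cluster test is estimated on 200 null cohorts of 20 subjects with a
10 × 50 bin grid and 1000 permutations each, and generator-coupling
recovery runs the full pipeline on 50 cohorts of 20 subjects at the full
72-trial session length (with 15 s inter-trial intervals — long enough to
hold the 8 stimulus-free control intervals even at slow heart rates — one
ROI and the pulse-2 beta-band TFR). At these sizes the rebound and thickness couplings
are recovered with a median absolute rank-correlation error well inside
±0.15 of each cohort's realized ground truth.

# Known limitations

* Burst detection assumes the generator's burst morphology family;
  real neurograms with pronounced baseline wander or movement artifacts
  would need the opening/threshold parameters revisited.
* The scalar beamformer assumes uncorrelated sources; strongly correlated
  bilateral sources would bias ROI power (the classical LCMV limitation).
* The cluster test controls family-wise error per map (ROI × pulse); no
  correction is applied across maps, matching the original analysis logic
  of pre-selected ROIs.
* With 1.5 s epochs, frequencies below ~9 Hz have no valid estimate in
  parts of the 0.5–1.2 s window of interest; the generic-window summary
  therefore effectively lives in the beta band, which is the intent.
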