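---
title: "Estimating slow performance fluctuations from EEG spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating slow performance fluctuations from EEG spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

perfspec estimates slow, endogenous fluctuations in task performance —
lane-keeping error during monotonous driving, and accuracy, reaction time
(RT) or button-press duration in a rapid serial visual presentation (RSVP)
target-detection task — from the concurrent EEG log power spectrum. The
premise is the classic fatigue/vigilance literature: as alertness wanes over
tens of seconds to minutes, band power (theta, ~4–7 Hz; alpha, ~8–12 Hz;
beta, ~13–30 Hz) drifts together with behavior, so a linear map from the
log-spectrum to a smoothed behavioral metric can track time-on-task
decrements. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic test bed does and does not
establish.

## From raw EEG to the log-PSD time series

Raw multichannel EEG is re-referenced to the average of the two mastoid
leads, decimated to 256 Hz (anti-aliased, integer factors), and band-pass
filtered 0.5–50 Hz. The band-pass is a linear-phase FIR (Hamming-windowed
design) applied with group-delay compensation, so it is zero-phase; the
filter length is chosen so the transition band is no wider than the 0.5 Hz
low corner, and the taps are re-centered so the DC gain is exactly zero.
High-density montages are reduced to the 32-channel BioSemi layout by
averaging each target electrode with its immediate neighbors
(`downselect_montage()`), which damps single-lead noise without spatial
filtering — spatial structure is handled later by PCA.

The spectral estimator (`compute_psd()`) slides a 750-sample (~3 s) epoch
every 500 samples (~2 s). Within an epoch, 125-sample Hann windows advance
by 25 samples (26 windows per epoch); each window is zero-padded to a
256-point FFT, giving a 1 Hz bin grid of which bins 1–40 Hz are kept. A
5th-order median filter across the 26 windows (per frequency bin) suppresses
transient artifacts before the windows are averaged and converted to log10.
Two implementation notes:

* *Median edges.* At the first/last windows the median window shrinks
  symmetrically (order 5 → order 3 → passthrough), keeping the filter
  centered and odd-ordered everywhere.
* *What the median can and cannot reject.* Because the 125-sample windows
  overlap by 100 samples, any transient — however brief — contaminates at
  least five consecutive windows. A 5th-order sliding median therefore
  attenuates bursts substantially (about 4 dB for a 50 ms, 100× burst in the
  suite's measurement) but cannot remove them completely; only modest
  (≲3×) bursts stay within half a decibel of the clean spectrum. The test
  suite asserts the realistic property (strict suppression relative to a
  median-free computation), not total rejection.

Power is the squared magnitude of the one-sided FFT of the Hann-windowed
segment with no density scaling: every later stage (PCA + linear
regression) is invariant to a global scale, so the absolute calibration of
power is immaterial; only log-power *differences* matter.

Both the per-channel log-PSD and every behavioral series are smoothed with
the same centered 90 s mean filter, applied strictly within experimental
blocks. Points whose full ±45 s support lies inside the block keep their
windowed mean; points nearer an edge are padded with the first/last valid
smoothed value. The 90 s constant sets the timescale of "slow" here: it
passes fluctuations with periods of a few minutes (the scale of time-on-task
drift) and removes trial-to-trial noise.

## Behavioral targets

*Driving.* The metric is the absolute lateral deviation from the lane
center, smoothed per block and resampled to the PSD epoch grid by
nearest-time lookup within the block.

*RSVP.* Images appear at 5 Hz; the participant presses a button for targets.
Because mean RT far exceeds the 200 ms image duration, presses are assigned
to images by a window rule (`assign_presses()`): images 300–1000 ms before
the press are candidates (boundaries inclusive); if the window holds
targets, the press is credited to the oldest unclaimed one and RT runs from
that image's onset; a press whose window holds no (unclaimed) target is a
false alarm, attributed to the non-target image nearest to 600 ms before the
press, with no RT recorded. Processing presses in temporal order resolves
double presses deterministically (the earlier press claims the target; the
later one becomes a false alarm).

Two normalizations remove known task-parameter effects so that what remains
is endogenous:

1. *Perceptual difficulty.* The mean accuracy/RT/duration of each target
   image across participants (the grand average) is subtracted and the
   difference re-anchored at nominal values — accuracy 1, RT 600 ms,
   duration 300 ms. Values above nominal mean better-than-average accuracy
   or slower-than-average responses *for that image*.
2. *Target probability.* RT and press duration fall approximately linearly
   with the block's target probability (slopes −262 and −277 ms per unit
   probability); `adjust_for_probability()` subtracts the fitted linear
   effect around the mean block probability (0.06). "Removing the fitted
   effect" is the reading adopted for inverting these slopes; the slope and
   reference are arguments, so other conventions are one call away.

## The regression model

For a channel set $S$ with $k = |S|$ channels, the stacked feature matrix
$X_k$ has one row per epoch and $40k$ columns (40 bins per channel,
channel-major). PCA of the column-centered training features retains every
eigenvector whose eigenvalue explains at least 1% of the total variance
(the trace); if none qualifies, the single largest is kept. Ordinary least
squares (with intercept) then maps the projections onto the retained
eigenvectors to the behavioral series, with zero temporal lag. Estimation
applies the stored training means, eigenvectors and coefficients to new
epochs. Centering before PCA is not optional in this package: the
covariance interpretation requires it, and the training means are stored in
the basis so test data are centered identically. The basis and the means
always come from training blocks only — fitting the eigenbasis on the full
session would leak test-set structure into the model even though the
behavior is never touched.

The *standard* scheme fixes $S = \{Fz, Cz, Pz, Oz\}$ (the midline montage,
$40 \times 4 = 160$ features). The *adaptive* scheme selects $S$ per fold by
sequential forward floating selection (SFFS) over the 32-channel montage,
maximizing the criterion

$$J(X_k) = 1 / \mathrm{RMSE}(y, \hat y(X_k)),$$

with subset sizes 1–12 and a budget of 500 criterion evaluations. The
forward step adds the channel that maximizes $J$; after each addition, the
least significant channel is removed whenever doing so beats the best $J$
recorded at the smaller size, and removals may cascade. Evaluated subsets
are memoized; ties break toward the earlier channel in the canonical
montage order, so the search is deterministic.

*What J is evaluated on.* Training-fit RMSE decreases monotonically with
$k$, which would make the backward (floating) steps vacuous. $J$ is
therefore an out-of-sample error: the regression stage is cross-validated
across the training blocks (each training block predicted by a regression
fit on the others) while the PCA basis is fit once on all training blocks.
The basis is unsupervised — it never sees the held-out behavior — so this
keeps the criterion honest about generalization at a fifth of the cost of
refitting the eigendecomposition inside every inner fold; the fully
refitted variant remains available (`protocol = "inner-cv-refit"`), as does
plain training error (`"train-fit"`).

## Evaluation

Models are scored by leave-one-block-out cross-validation: for each of the
six 10-minute blocks, a model (including SFFS, when adaptive) is built from
the other five and predicts the held-out block; the per-fold predictions
are concatenated into a full-session estimate $\hat y$. Because smoothing
never crosses block boundaries, the training and test sets are temporally
separated by at least the 90 s smoothing window by construction. Reported
statistics are the Pearson correlation $R(y, \hat y)$, the RMSE normalized
by the standard deviation of the actual behavior (so a constant mean
predictor scores ≈1), and a permutation significance test.

*Permutation test.* The estimate's values are randomly permuted, re-smoothed
with the 90 s filter, and correlated with the actual behavior; 1000
permutations give the null mean and variance, from which a Gaussian
threshold at $p < 0.05$ (one-sided by default — a model is only "working"
when $R > 0$) and a p-value are derived; an empirical-quantile threshold is
also reported. Re-smoothing is essential: heavily low-pass-filtered random
series reach spuriously large correlations, and the threshold must reflect
that.

Two calibration caveats, established on the synthetic test bed and worth
knowing when reading results:

* With few blocks, leave-one-block-out predictions inherit *swapped block
  means* (each fold's intercept is the mean of the other blocks), which
  biases the null distribution of the concatenated $R$ negative — about
  −0.15 for two 10-minute blocks with no real coupling. The permutation
  null is centered at zero, so the one-sided test is conservative (measured
  false-positive rates 0.02–0.05 at nominal 0.05 over 200-replicate
  simulations). With six blocks the bias shrinks by roughly a factor of
  five.
* Permuting within blocks instead (to carry block means into the null) was
  evaluated and rejected: re-smoothing collapses the within-block variance
  of a permuted series, producing a degenerate, strongly anti-conservative
  null.

*Cross-task transfer.* The six per-fold models from one task are applied to
the other task's full-session PSD; a least-squares slope-and-offset rescale
maps each estimate onto the new metric's scale (necessary because, e.g.,
lane deviation rises with fatigue while accuracy falls). The rescale cannot
change $|R|$; correlations are reported per model with mean ± SE, signs
retained.

## Spectral weights

To interpret a fitted model, the contribution of each frequency is
$W(f) = \|\beta\|^{-1} \sum_i \bar X(f)\, v_i(f)\, \beta_i$ per channel,
where $\bar X$ is the *uncentered* average training log-power, $v_i$ the
retained eigenvectors and $\beta_i$ the regression coefficients; the norm
division makes profiles comparable across models. Profiles are pooled
across folds and channels (and sessions, when supplied), averaged per
frequency, and tested against zero with a one-sample t-test per frequency
under Benjamini–Hochberg FDR control across the 40 frequencies. The
t-test is a choice (any location test would do); with profiles pooled over
folds the test is a descriptive screen, not a strict inference, which is
also why the FDR mask is reported alongside the mean profile rather than
gating it.

## The synthetic test bed

No recordings ship with the package; every claim is exercised against a
generative model (`simulate_session()`) whose defaults mirror the study
design the pipeline targets: 6 blocks of 10 min, 32 channels at 256 Hz, a
5 Hz RSVP stream with per-block target classes and probabilities
(0.01–0.11), vehicle state at 100 Hz.

* *Latent state.* An Ornstein–Uhlenbeck process (time constant 120 s,
  standardized per session) plus a mild within-block upward drift (0.3 SD)
  models slow alertness fluctuation. The 120 s constant was chosen so most
  latent power survives the 90 s smoother; the drift mimics within-block
  performance decrements.
* *EEG.* Each channel is broadband noise (low-pass autoregressive mixture,
  15 µV SD) plus theta and alpha oscillations (7 and 9 µV). On the four
  informative channels the oscillation amplitude is modulated by
  $1 + g\,\ell(t)$ with $g = -0.35$ for theta on Fz/Cz and $+0.35$ for
  alpha on Pz/Oz — so drowsiness lowers frontal-midline theta and raises
  posterior alpha power in this plant, giving the theta-negative /
  alpha-positive weight signature the recovery tests look for. The signal
  scale keeps mean log10 power positive across 1–40 Hz, which matters
  because the weight decomposition multiplies by the average PSD.
* *Behavior.* Lane offset is a fast mean-reverting wander whose innovation
  scale grows with the latent state; RSVP hits follow a logistic model in
  the latent state and per-image difficulty, RT and duration are linear in
  both with Gaussian noise, and the probability effects are planted with
  the −262/−277 ms slopes so the block-wise adjustment removes them
  exactly in expectation. Image difficulty lives in a library shared
  across simulated participants (five classes with mean effects −1…+1 plus
  image-level scatter), which is precisely the structure the grand-average
  normalization is designed to remove.

What passing tests show: the pipeline recovers a planted linear
latent→spectrum→behavior chain at realistic SNR, the channel search finds
the informative montage, the significance test is approximately calibrated
under the null, and every statistic matches its textbook formula. What they
do not show: robustness to real EEG nuisance structure — eye blinks, EMG,
electrode drift, non-stationary spectra, volume conduction — none of which
the generator emulates beyond brief test bursts; results on recorded data
depend on those factors and on the linearity assumption itself.

## Numerical and engineering choices

* Eigendecompositions use LAPACK's `dsyevr` through a small C wrapper that
  computes only the eigenpairs above the retention bound (total variance is
  the trace, known in advance), falling back to the largest pair for
  degenerate inputs. The user-facing `fit_basis()` keeps R's `eigen()`;
  both paths apply the identical retention rule, and predictions agree to
  numerical precision because they depend only on the retained subspace.
* Repeated fits over channel subsets (SFFS evaluates hundreds) assemble
  covariances from per-block cross-product matrices computed once per
  session, rather than re-touching epoch data.
* The median-filter-and-average across PSD windows runs in C; the test
  suite pins it to a naive two-loop R reference at 1e-9.
* Eigenvector signs are fixed (largest-magnitude loading positive) for
  reproducible serialization; predictions are sign-invariant.
* Degenerate inputs: zero-variance features and constant series are
  explicit errors; a zero criterion RMSE returns a capped J (1e12) with a
  warning; blocks shorter than the smoothing window fall back to
  clipped-window means.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state.

Problem sizes in the test suite (full 32-channel sessions for the recovery
checks, 2–4 channel sessions elsewhere; 200-replicate calibration at two
blocks; 50-instance exhaustive-search comparisons at five channels) were
chosen so the whole suite exercises every claim at desk scale while staying
fast enough to run routinely.
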