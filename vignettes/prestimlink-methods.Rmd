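---
title: "Methods: prestimulus spectra, component rotation, and behaviour linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prestimulus spectra, component rotation, and behaviour linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: what each
stage assumes, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The question the pipeline serves

In an equiprobable auditory Go/NoGo task, tones arrive every 1100 ms and
the participant presses to one tone and withholds to the other.  The EEG
in the 500 ms before each tone carries ongoing narrowband activity whose
amplitude fluctuates; the analysis asks whether individual differences in
these prestimulus components relate to the evoked ERP components and to
performance (error rates, reaction-time statistics).  All associations
are within-group Spearman correlations across subjects; nothing causal is
claimed by the machinery.

## Prestimulus amplitude spectra

Each accepted trial contributes its 256-sample prestimulus segment
(half-open [-500, 0) ms at 512 Hz).  The segment is DC-corrected,
multiplied by a 10% cosine-taper window, zero-padded to 512 points,
Fourier transformed, and converted to single-sided amplitudes with two
blanket corrections: x2 for the padding and the reciprocal of the
window's mean gain (~1.05) for the taper.  Per-trial amplitude spectra
are averaged within subject x channel x condition (amplitudes, not
complex spectra, so phase never cancels).

Numerical choices worth knowing:

* **"10% taper" reading.**  The taper fraction is 0.1 in total (5% per
  end).  This is the unique reading consistent with a printed correction
  of 1.05: the mean gain is 1 - 0.1/2 = 0.95 and 1/0.95 = 1.05.  A
  10%-per-end taper would imply 1.11 and is rejected.  The ramps use
  half-sample-offset Hann lobes so they sum to exactly half their length,
  making the mean gain exactly (n - m)/n.
* **DC correction.**  The *window-weighted* mean is subtracted, so the
  windowed segment is exactly zero-mean and the DC bin is numerically
  zero.  Subtracting the plain mean would leave a small DC residual after
  tapering.  The blanket corrections are applied to all 31 bins including
  DC; with DC ~ 0 the choice is inert.
* **Image-frequency leakage.**  A single window's amplitude estimate at
  bin f carries a phase-dependent contribution from the negative-frequency
  image through the taper's transform (up to ~2.6% at 10 Hz, ~5% at
  2 Hz, antisymmetric in phase).  Trial-mean spectra average over phase,
  so the pipeline's estimator is unbiased; single-segment tests must
  either use a phase ensemble or tolerate the wobble.

## Preprocessing

The stage order is fixed: band-pass filter, linked-ears re-reference
(when an ear channel is present), down-sample to 512 Hz (when faster),
epoch extraction for valid trials, EOG-dropout screen, ocular correction,
spherical interpolation, baseline correction, automatic artifact
rejection, prestimulus-press rejection, Go/NoGo count matching.

* **Filter realisation.**  The 0.1-30 Hz zero-phase band-pass is applied
  as multiplication by the *squared* analog Butterworth magnitude
  response (order 4 per edge, high-pass x low-pass cascade) in the
  frequency domain, with odd-reflection padding.  A forward-backward IIR
  pass has exactly this magnitude response and zero phase; the spectral
  implementation avoids per-sample loops and edge-state handling.  With
  band edges 300x apart the cascade is indistinguishable from a true
  band-pass design.
* **Down-sampling** is Fourier resampling (spectral truncation): exact
  for band-limited signals and inherently anti-aliased; event indices are
  rescaled and rounded.
* **Epoch grid.**  Sample offset k covers time k/fs; epochs span
  k in [-256, 307] at 512 Hz (564 samples, -500.0 to 599.6 ms), so the
  prestimulus segment is exactly 256 samples - the length the 512-point
  zero-padding presupposes.  The baseline window [-100, 0) ms is likewise
  half-open.
* **Ocular correction** follows the regression tradition: blinks are
  detected on the upper vertical EOG at 3 robust SDs (MAD x 1.4826,
  dilated +/-50 ms; the criterion is not fixed by the tradition, so a
  robust default was chosen); condition-wise event-related averages are
  removed before regressing residual EEG on residual EOG, separately for
  blink and non-blink samples; raw epochs are corrected with the fitted
  coefficients.  When vertical EOG channels are nearly collinear the
  individual coefficients split arbitrarily between them while the total
  correction remains right; per-channel coefficient recovery is therefore
  tested with single-channel activation.
* **Manual-inspection surrogate.**  The tradition's two visual passes are
  replaced by an automated screen: trials whose EOG channels flatline
  (< 0.05 uV change in ~100 ms) or hold a clipped plateau (>= 50 ms
  pinned at an extremum beyond 500 uV) are rejected before correction.
  This is a deliberate, documented deviation - a pipeline cannot ship a
  human.
* **Rejection semantics.**  Thresholds are applied to the 19 scalp
  channels only, post-baseline, with strict inequalities exactly as
  printed (a smooth waveform peaking at exactly 150 uV survives).  The
  flatline window slides per channel independently.  Rejection order
  (extreme, jump, flat) fixes the single recorded reason.
* **Count matching** subsamples the surplus condition uniformly under the
  run seed, so accepted Go and NoGo counts are equal for every subject.

## Component decomposition

Both PCAs use the covariance matrix over cases (variables centred, never
standardised; n-1 denominator).  Unrotated loadings are
eigenvector x sqrt(eigenvalue), i.e. microvolts per standardised-score
SD, and scores x loadings' reconstructs the centred data exactly when all
components are retained.  All components are rotated (unrestricted), then
components at or above 1.5% variance are selected.

* **Varimax** uses the simultaneous SVD update with Kaiser normalisation;
  the criterion is checked in the tests against a brute-force rotation-
  angle grid.  Convergence: relative criterion gain < 1e-10, cap 1000
  sweeps with a warning (flat criterion landscapes - many pure-noise
  components - converge slowly; the cap returns the best rotation found).
* **Promax** (kappa = 3, the common ERP-PCA default; configurable) builds
  the sign-preserved |loading|^kappa target and fits the oblique
  transformation *in Kaiser row-normalised space*.  This is the
  toolkit convention for covariance-scale loadings: powering raw
  microvolt loadings lets large components dominate the target and drives
  the transformation towards singularity (observed as pattern variances
  far above 100%).  Factor correlations, pattern, and structure obey
  structure = pattern x Phi to machine precision.
* **Scores** use the regression method; obliquely rotated scores satisfy
  cov(scores) = Phi with unit diagonal.
* **Sign convention.**  Each component is oriented so its scaled loading
  at the peak variable matches the sign of the grand-mean data there
  (positive when that mean is zero).  This makes outputs deterministic
  under case permutation - spectra components come out positive, ERP
  components take the polarity of the underlying deflection.
* **Percent variance** is the scaled-loading sum of squares over total
  variance.  For oblique solutions components overlap, so the percentages
  need not total 100; they are reported per component, not summed.
* **Global mean peak amplitude.**  The exact formula is not fixed by the
  tradition's prose; the package uses standardised score x scaled loading
  at the component's peak variable, averaged over the 19 channels within
  subject, and additionally over Go/NoGo cases for the frequency PCA
  (pooling by mean, not by peak-over-pooled-cases).  This is flagged as an
  inference in the documentation.

## Linkage

Spearman's rho is the Pearson correlation of mid-ranks; p is the t
approximation with n - 2 df, two-tailed; the 95% CI is Fisher-z with the
Bonett-Wright variance (1 + rho^2/2)/(n - 3), chosen because it
reproduces the two printed anchor intervals where the Fieller variant
(1.06/(n - 3), also implemented) does not.  All cross-domain pairs are
computed (EEG x ERP, EEG x behaviour, ERP x behaviour; Go and NoGo ERP
measures count as one domain for pair enumeration, so ERP x ERP pairs are
excluded).  Banding uses closed boundaries (significant p <= 0.05, near
0.05 < p <= 0.10) with no multiple-testing correction, matching the
exploratory framing; a Benjamini-Hochberg column is emitted as
supplementary output only.  The t-based p and z-based CI can disagree
near the boundary; the band follows p, and the tests bound the
disagreement rate on a simulated null.

## The synthetic world

The generator's defaults state one concrete world, chosen once:

* Task: 2 blocks x (75 Go + 75 NoGo), SOA 1100 ms, 512 Hz, the
  19-channel 10-20 montage plus 4 EOG channels.
* Background: 1/f amplitude decline (exponent 1, 2 uV at 1 Hz) plus
  three narrowband oscillators - parietal 2 Hz delta (3 uV), parietal
  9 Hz alpha (6 uV), frontal 18 Hz beta (1.8 uV) - realised as
  narrowband-filtered Gaussian noise (pure tones would make PCA recovery
  degenerate), each with log-normal between-subject gains (sigma 0.4) and
  per-trial amplitude modulation.  Every source is calibrated *through
  the package's own spectral estimator* so the stated microvolt amplitude
  is what the pipeline should recover.
* ERPs: three Gaussian templates (posterior +4 uV at 100 ms, central
  -6 uV at 160 ms, parietal +8 uV at 350 ms with NoGo gain 1.25);
  amplitudes are testability choices, not reproductions of any group
  grand mean, since no microvolt tables exist to copy.
* Artifacts: blinks (8/min, ~200 uV raised cosine) and saccades (4/min)
  with fixed EOG-to-EEG propagation factors.
* Behaviour: child-like base rates (6.3% commissions; 3.1/0.5/9.9%
  omission/fast/slow Go errors; mean RT 389 ms, RT variability 85 ms).
  Links are planted through a Gaussian copula: a target Spearman rho is
  converted to a latent Pearson r = 2 sin(pi rho / 6), and the latent
  propensity is mapped monotonically onto RT parameters or error
  probabilities, so the rank correlation is targeted directly.

What the generator does *not* emulate: volume conduction beyond fixed
topography weights, head geometry, non-stationary fatigue or learning
effects, age-group differences beyond user-set parameters, and
correlated sensor noise.  A green end-to-end test therefore establishes
that the pipeline recovers what it is pointed at - not that real
recordings would behave as cleanly.

Two honest limitations surfaced by the tests:

* Templates that overlap in time (the default 100/160 ms pair) mix under
  rotation: peak latencies stay within two samples, but the early
  component's recovered topography correlates only ~0.85 with the planted
  one.  The single-template recovery property is tested with separated
  templates.
* Subject-level behavioural measures are estimates (an SD from ~100-500
  trials), so recovered link strengths are attenuated a few hundredths
  below the planted rho; the recovery test follows the stated convergence
  with trial count and checks containment in the CI around the planted
  value.

## Seeds and reproducibility

Every stochastic stage derives a child seed from the user seed and a
stage label, so any stage can be re-run in isolation and two runs with
identical configuration and seed produce byte-identical outputs (the
determinism tests compare file checksums).
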