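---
title: "Methods: Hankel DMD gait signatures from plantar pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hankel DMD gait signatures from plantar pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdmd)
```

## The model

A pressure-sensitive walkway samples the plantar pressure field under
each foot as a frames x rows x cols tensor (50 Hz, 5 mm cells in the
default geometry). Integrating the pressure over a footstep's region at
each frame gives that step's vertical force signal $s_n$ in newtons,
re-indexed so initial contact is $n = 0$ and zero-padded to 100 frames.
The stance phase -- heel-strike to toe-off -- occupies roughly 40--50
frames and shows the classic two-bump force profile.

`gaitdmd` models each step as a finite sum of damped complex
exponentials. A Hankel (time-delay) matrix of the scalar series,

$$D_{ij} = s_{i+j},$$

restores the surrogate spatial dimensions that SVD-based dynamic mode
decomposition needs: with $X$ and $Y$ the one-shift snapshot pair taken
from $D$'s columns, the thin SVD $X = W S V^*$ and the reduced operator
$\hat A = W^* Y V S^{-1}$ give eigenpairs $(\mu_k, w_k)$ and exact
dynamic modes $\tilde v_k = \mu_k^{-1} Y V S^{-1} w_k$. Because every
Hankel row is a shifted copy of the same signal, only the first element
$v_k$ of each exact mode enters the scalar reconstruction

$$s_n = \sum_{k=1}^{r} \mu_k^{\,n} \, v_k \, b_k ,$$

with amplitudes $b_k$ obtained by least squares against the first
snapshot column. Each eigenvalue converts to continuous-time features
through the principal logarithm: a decay rate
$\alpha_k = \mathrm{Re}\,\ln\mu_k / \Delta t$ (1/s), a frequency
$f_k = \mathrm{Im}\,\ln\mu_k / (2\pi \Delta t)$ (Hz), and an initial
condition $s_{0,k} = v_k b_k$ (N). Conjugate pairs collapse to one
representative with $f_k \ge 0$, so a rank-12 model of a real signal
yields $K = 6$ triplets $(\alpha_k, f_k, |s_{0,k}|)$ -- the step's gait
feature set, sorted by frequency so that mode ranks correspond across
steps.

One printed formula for the reconstruction divides both $\alpha_k$ and
$\beta_k = 2\pi f_k \Delta t$ by $\Delta t$ inside an exponent already
evaluated at $t = n\Delta t$, which would double-count the sampling
interval; the package consistently uses $s_n = \sum_k \mu_k^n v_k b_k$
(equivalently $e^{(\alpha_k + 2\pi i f_k) n \Delta t}$ per pair), and
converts to physical units only in the feature layer.

## Walker baselines and identification

For one person, foot and speed, the per-step triplets of mode rank $k$
scatter around a well-defined centroid $\langle F_k \rangle$ (their
mean over the $C$ enrolled steps). The spread vector is the reciprocal
sample standard deviation per component,
$S_k = [\tfrac{1}{C-1}\sum_c (F_{k,c} - \langle F_k\rangle)^2]^{-1/2}$.
A probe of $C_s$ steps is scored against candidate $x_i$ by

$$\ell(x_i) = \sum_{k=1}^{K} \frac{1}{C_s} \sum_{c=1}^{C_s}
  S_k(x_i) \cdot \big(F_{k,c} - \langle F_k(x_i)\rangle\big)^2 ,$$

and identified as the argmin over the gallery. Note the literal weight
is the *inverse standard deviation*, not the inverse variance a true
Mahalanobis distance would use; the package implements the literal form
by default and offers `standardized = TRUE` for the
$\sum (d/\sigma)^2$ variant. Ties break by enrollment order.

The Monte-Carlo protocol draws a person uniformly, then 30% of their
steps without replacement, and repeats. Two enrollment conventions are
provided:

* **full baselines** (default): every baseline uses all of a person's
  steps. Probe steps then also sit inside their own baseline; this
  leakage inflates accuracy slightly and is the convention the headline
  accuracies use.
* **balanced holdout** (`holdout = TRUE`): the probe person's baseline
  is recomputed without the probe steps, *and every other candidate's
  baseline is subsampled to the same step count*. Holding out only the
  probe's steps would bias the protocol *below* chance (the probe's
  baseline would be noisier than everyone else's); equalizing the
  enrollment size makes indistinguishable walkers exactly exchangeable,
  so the zero-separation control sits at $1/n_\text{persons}$. This is
  the convention for chance-level controls.

## The synthetic cohort

No public walkway data accompany the method, so the package ships a
generator whose defaults *are* the study conditions every test runs
under:

* **Canonical walker.** Six frozen conjugate-pair triplets (see
  `default_mode_params()`) whose expansion renders a stylized vertical
  ground-reaction-force curve: peak about 680 N, mid-stance valley
  about 80% of peak, stance 45 frames at 50 Hz, non-negative
  throughout, with the two lowest-frequency pairs dominating
  $|s_0|$ and alone carrying the double bump (correlation 0.93 with the
  full curve). The triplets were fixed once by weighted least squares
  of the damped-sinusoid basis against a textbook force curve, fitting
  the two dominant pairs first and the remaining four to the residual.
  Because the ground truth is itself a 6-pair expansion, DMD recovery
  is a parameter-recovery problem, not a model-mismatch one; an
  optional rectification switch clamps the signal at zero for extra
  realism but is off by default because it breaks the linear-model
  oracle.
* **Cohort spread.** Person-level variation scales with a single
  `separation` knob: multiplicative lognormal-like factors on decay
  rates (10% relative sd) and initial-condition moduli (12%), additive
  shifts on frequencies (0.05 Hz) and phases (0.1 rad), all times
  `separation`. At `separation = 0` all walkers are identical -- the
  chance-level null.
* **Step-to-step jitter** is multiplicative Gaussian on $\alpha$ and
  $|s_0|$ (5% each) and additive on $f$ (0.02 Hz); these magnitudes are
  free design choices representing comfortable-pace variability, since
  no quantitative step-variability model accompanies the method.
* **Measurement noise** is additive Gaussian during stance only (the
  instrument writes exact zeros off-contact), default sd 0.05 N on a
  ~680 N signal. The choice is deliberate: the Hankel matrix of a
  smooth decaying force curve is ill-conditioned (singular values span
  ~2.5 orders), so noise beyond ~1 N drowns the weakest true modes'
  singular values and biases the recovered spectra; 0.05 N keeps
  estimation error at the scale of the biological jitter. Real
  instrument noise structure (quantization, spatially correlated cell
  errors, calibration drift) is *not* emulated, so passing tests show
  correctness of the pipeline on well-calibrated data, not robustness
  to heavy sensor noise.
* **Rendering.** Full recordings paint each step as heel, metatarsal
  and toe Gaussian blobs with smooth temporal envelopes, normalized per
  frame so the spatial integral reproduces the 1D force exactly;
  anatomical fidelity is a non-goal, integral fidelity is the contract.
  Passes alternate direction (odd passes stored row- and column-
  flipped, as the instrument records them) and are separated by
  all-zero gaps. The default grid is a reduced 256 x 64 walkway --
  rows along the walking direction, columns lateral, so that the
  left foot lands in the higher columns after direction normalization
  and foot assignment by column centroid is meaningful; the full-size
  instrument grid is available through `walkway_geometry()`.

## Numerical choices

* Singular values below $10^{-12}\sigma_{\max}$ are always discarded
  before any rank rule applies.
* The truncation tolerance rule selects the smallest rank with
  one-step residual $\|Y - AX\|_2 \le \varepsilon$, default
  $\varepsilon = 10^{-6}(\text{rows} + \text{cols})$; on noiseless
  six-pair steps it selects $r = 12$, matching the generator's pair
  count. The search uses bisection, valid because the residual is
  non-increasing in rank.
* **Embedding depth.** The theoretical guidance that the Hankel matrix
  should be much wider than tall conflicts with a 100-frame padded
  signal whose stance alone spans ~45 frames, so no single depth is
  canonical. `hankel_dmd(rows = "auto")` grid-searches
  {stance, stance/2, 25} and keeps the residual-minimizing embedding --
  appropriate for clean signals. The feature pipeline instead uses
  `rows = "stance"` (depth = stance length): under noise the residual
  search rewards shallow, overfitted embeddings (observed: a true
  2.4 Hz mode replaced by a spurious Nyquist mode), while the
  stance-deep matrix is stable.
* The pipeline truncates at a fixed $r = 12$ (so $K = 6$ triplets) by
  default: the tolerance rule reproduces this rank on clean steps but
  returns the full numerical rank on noisy ones, where fixed-rank
  truncation is the robust equivalent.
* Feature sets longer than $K$ keep the $K$ largest-$|s_0|$
  representatives; shorter sets pad with flagged missing rows.
  Frequency ties sort by more-negative decay rate first, then larger
  $|s_0|$.
* Zero within-person variance (possible with jitter-free synthetic
  steps) would make a spread infinite; spreads are capped at $10^6$
  with a warning.
* The "initial condition" axis of the feature space is the modulus
  $|s_{0,k}|$: it is conjugation-invariant, which is what makes one
  representative per pair meaningful. The complex value is retained for
  reconstruction.

## Problem sizes

The shipped tests and the acceptance script run on: 16 walkers x 30
steps per foot (960 DMD fits, ~20 s), a 2000-repeat chance control, a
200-step stability suite, and one rendered 4-pass x 8-step recording
per preprocessing check. These sizes give Monte-Carlo standard errors
comfortably inside the asserted margins while keeping a full run under
two minutes on one core.

## Known limitations

* Features are matched across steps by frequency-sorted rank; walkers
  whose mode frequencies cross under jitter can swap ranks, which
  inflates within-person spread. Frequency is empirically the most
  stable coordinate, but no explicit mode-tracking is attempted.
* The generator's jitter is parameter-space Gaussian; real gait
  variability is structured (speed drifts, fatigue trends) and may
  produce heavier-tailed feature distributions.
* Identification is closed-set: every probe belongs to an enrolled
  walker, and no rejection threshold is provided.
* Spatial pressure information (2D mode shapes, center-of-pressure
  trajectories) is integrated away by design.
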