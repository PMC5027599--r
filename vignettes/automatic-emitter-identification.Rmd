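---
title: "Automatic emitter identification for SMLM: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic emitter identification for SMLM: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmet)
```

## The problem

Single-molecule localization microscopy (SMLM: PALM, STORM, dSTORM) builds a
super-resolved image from the positions of individually blinking
fluorophores, localized frame by frame over thousands of camera frames.
Every analysis pipeline must decide which candidate spots are genuine
single-molecule emissions and which are background fluctuations, and that
decision usually rests on user-chosen thresholds. `smlmet` removes this
choice: *every* locally brightest spot is fitted with a point-spread-function
model, and the resulting photoelectron-count histogram — which is bimodal,
because true emitters contribute far more photoelectrons than background
fluctuations — is split by an unsupervised Bayesian minimum-error threshold.
The only inputs are objective experimental constants: camera offset and
gain, pixel size, magnification, numerical aperture and emission wavelength.

## The per-frame analysis

1. **Conversion.** Raw ADU values become photoelectron counts through the
   camera model \(n(i,j) = (I(i,j) - I_{\mathrm{offset}})/G_{\mathrm{eff}}\).
   Values below the offset stay negative: clipping them would bias the
   background fit.
2. **Candidate detection.** A pixel is a candidate when its photoelectron
   count is \(\ge\) every pixel within one Airy-disk radius
   \(R_{\mathrm{airy}} = 0.61\,\lambda M/(\mathrm{NA}\,\mu)\) pixels
   (a circular neighborhood — the Airy disk is a disk). No other
   pre-selection is applied. Candidates within
   \(h_f = \lceil R_{\mathrm{airy}}\rceil\) of a border are dropped so the
   fit window fits inside the frame.
3. **Background estimation.** The frame is convolved with a unit-sum
   Gaussian kernel of width \(s_0 = 0.21\,\lambda M/(\mathrm{NA}\,\mu)\)
   pixels truncated to a \((2h_f+1)^2\) support; the background at a pixel
   is the minimum of the smoothed image over the \((6h_f+1)^2\) square
   around it. The minimum filter escapes any PSF-sized blob, so emitters do
   not inflate their own background.
4. **PSF fitting.** Each candidate's \((2h_f+1)^2\) window is fitted with
   the fixed-width 2D Gaussian
   \[
     m(x,y) = \frac{n_{\mathrm{psf}}}{2\pi s_0^2}
       \exp\!\Big(-\frac{(x-x_0)^2 + (y-y_0)^2}{2 s_0^2}\Big) + n_b,
   \]
   free in \((x_0, y_0, n_{\mathrm{psf}}, n_b)\) with \(s_0\) held at its
   theoretical value, by unweighted Levenberg–Marquardt least squares.
   Starting values: the peak pixel position, the background image value,
   and \(n_{\mathrm{psf}} = 2\pi s_0^2(\mathrm{peak} - n_b)\) (the value at
   which the model reproduces the observed excess at the peak), floored
   at 1.
5. **Pruning.** When fitted centers lie within \(s_0\) of each other only
   the largest-\(n_{\mathrm{psf}}\) fit survives (greedy, in descending
   brightness order — deterministic and idempotent).

The 0.61 prefactor is the first Airy minimum and 0.21 the least-squares
Gaussian approximation of the in-focus PSF; both are the standard constants
in the localization-microscopy literature. Fits that do not converge, end
with \(n_{\mathrm{psf}} \le 0\), or leave the window are discarded before
thresholding.

## Automatic threshold determination

All retained \(n_{\mathrm{psf}}\) values from the whole movie are pooled and
quantized into \(N\) gray levels \(\{0,\dots,N-1\}\) (by default
\(N = \min(\lceil \max n_{\mathrm{psf}} \rceil, \text{count})\), i.e.
integer rounding). For a candidate threshold \(T\), the false side
\(R_{0T} = \{0..T\}\) and true side \(R_{1T} = \{T{+}1..N{-}1\}\) get prior
masses \(P_{iT}\) (their histogram mass fractions) and fitted class
densities \(f_i(x\,|\,\theta_{iT})\), and the minimum-classification-error
criterion

\[
  J(T) = -\sum_{i\in\{0,1\}} \sum_{x \in R_{iT}} h(x)
     \big[\log P_{iT} + \log f_i(x\,|\,\theta_{iT})\big]
\]

is minimized exhaustively over \(T\). This is the generalized
Kittler–Illingworth criterion; any monotone transform preserves the argmin,
and the log-likelihood form above is used throughout.

Two class-density models are built in:

* **GGDM** (Gaussian–Gaussian): both sides Gaussian, the generic
  central-limit choice; parameters are the weighted mean/standard deviation
  of each side.
* **WLDM** (Weibull–Lognormal): background survivors follow a Weibull
  distribution, true single-molecule photon counts a lognormal — the
  empirical shape of single-fluorophore emission. Weibull parameters come
  from weighted maximum likelihood (Newton iteration on the shape, with a
  method-of-moments fallback after 50 iterations); lognormal parameters are
  the weighted moments of the log levels. Levels are shifted by \(+0.5\)
  before any logarithm so level 0 stays in-support.

The module is characteristic-agnostic: `find_threshold()` accepts any
scalar per-emitter characteristic whose false/true distributions are
distinguishable (e.g. an externally computed wavelet SNR), with any
pluggable `dist_model`. GGDM typically thresholds slightly lower than WLDM
because the Gaussian false model reaches further into the right-skewed
true-emitter flank.

### Numerical choices

* **Candidate validity.** Both sides must hold at least 5 occupied gray
  levels with nonzero spread; invalid candidates are skipped, and if none
  is valid the histogram is reported not-bimodal with an error — the method
  is only meaningful when false and true emitters form distinguishable
  groups.
* **Empty levels.** Zero-count levels contribute nothing to \(J\)
  (\(0\log\cdot = 0\)), so \(J(T)\) only changes when \(T\) crosses an
  occupied level; the implementation evaluates it there and carries the
  trace forward, which is exactly equivalent to the naive loop.
* **Plateau tie-break.** On well-separated histograms \(J\) is constant
  across the empty gap between the modes. All plateau members share one
  fitted mixture, whose minimum-error cut is the crossing of the weighted
  class densities; the reported \(T^\ast\) is the plateau level nearest
  that crossing (still an exact argmin of the trace). The threshold is
  reported as \(T^\ast + 0.5\) in raw units, so "\(n_{\mathrm{psf}} \ge\)
  threshold" selects exactly the true side.
* **Fit tolerances.** The Levenberg–Marquardt iteration uses parameter and
  relative-cost tolerances of 1e-8 with at most 200 iterations — tight
  enough that noiseless model spots are recovered to machine-level
  accuracy on the \(\le 9\times9\) windows involved.
* **Detection ties.** Exact plateaus in a frame keep one candidate (the
  lexicographically first pixel) per connected plateau, and a plateau that
  touches equal-valued pixels dominated by a brighter neighbor is discarded
  entirely — a flat background around a bright spot yields no spurious
  candidate, while a perfectly flat frame yields exactly one.

## Reliability

Because both class densities are estimated, each emitter gets a posterior
probability of being true:
\[
  R(n_{\mathrm{psf}}) = \frac{NT(n_{\mathrm{psf}})}
    {NF(n_{\mathrm{psf}}) + NT(n_{\mathrm{psf}})},
  \qquad NI(x) = \text{total}\cdot P_I \cdot f_I(x),
\]
computed in log space so it is defined even where both expected counts
underflow. A reliability map assigns each rendered pixel the mean \(R\)
over *all* potential emitters falling in it (accepted and rejected — which
is why the full table is exported, the "manual threshold 1" convention),
normalized by the map maximum. Low-reliability regions flag structures
built from emitters that the model cannot confidently separate from
background.

## Rendering and evaluation

Super-resolution images are plain 2D histograms of localization positions
(default 10 nm rendered pixel, half-open bins), with an optional
Gaussian-blob mode for display. Evaluation against a ground-truth table
uses one-to-one matching within a tolerance radius (default: the PSF FWHM,
\(2\sqrt{2\ln 2}\, s_0\) in nm), solved optimally on the within-tolerance
pair graph — maximum cardinality, then minimum total distance, via a
Jonker–Volgenant assignment — per frame by default. Jaccard
\(= TP/(TP{+}FP{+}FN)\), precision, recall and RMSD over matched pairs
follow.

## The synthetic scene

`standard_scene()` is the canonical test fixture: a 128×128-pixel field at
70 nm effective pixel size (the classic EMCCD/TIRF configuration:
16 µm pixels, NA 1.49, 670 nm far-red emission, offset 100 ADU, gain
2 ADU/e⁻), three crossing filaments with 30 emitter sites per µm, 200
frames, per-frame activation probability 0.005 (≈4–5 active emitters per
frame — sparse, as SMLM requires), lognormal photoelectron counts with
median 800 and log-sd 0.35, and 10 background photoelectrons per pixel on
a gentle diagonal ramp (±15%) so the background estimator is actually
exercised. Expected photoelectron images receive pixelwise Poisson noise
and are converted to 16-bit ADU through the camera model. These values
were chosen once as a realistic, moderately easy dSTORM-like regime; the
200-frame, single-scene problem size keeps a full exhaustive analysis
(~40 000 PSF fits) comfortable on one CPU.

What the simulator does *not* emulate: pixel-integrated PSFs (it samples
the Gaussian at pixel centers, exactly the analysis model — so fitting is
model-matched and shows no pixelation bias), EMCCD excess noise, PSF
aberrations or defocus, fluorophore photophysics beyond independent
per-frame activation, and overlapping-emitter crowding at high densities.
Passing end-to-end tests on this scene therefore demonstrates the
correctness and internal consistency of the machinery, not performance on
hard real data, where the false/true overlap is larger and the optimal
Jaccard correspondingly lower.

## Worked example

```{r example, eval = FALSE}
cam <- standard_camera()
movie <- simulate_movie(standard_scene(seed = 1), cam)
analysis <- analyze_movie(movie$frames, cam, model = "wldm")
analysis
report <- match_localizations(movie$ground_truth, analysis$localizations,
                              tolerance_nm = psf_fwhm_nm(cam))
report
plot(analysis$threshold)
```

## Known limitations

* The fit is *unweighted* least squares (no Poisson weighting), matching
  the method's nonlinear-regression formulation. Its localization variance
  therefore carries the classical excess factor over the weighted/maximum-
  likelihood information bound (≈16/9 plus a background term), visible as
  a per-axis mean absolute error a few percent above
  \(0.05\,\mathrm{px}\) at \(n_{\mathrm{psf}} = 1000\) on a background of
  10 e⁻/px. Weighted fitting would localize better but is a different
  estimator.
* Single-emitter fitting only: overlapping emitters within \(s_0\) are
  pruned to the brightest, so dense activations lose localizations.
* The class-density models are tools for threshold placement, not faithful
  descriptions of the true-emitter distribution (which is typically a
  mixture of sub-populations); the reliability index inherits the quality
  of the model fit.
* Thresholding assumes a bimodal characteristic; on data where false and
  true emitters are not distinguishable the method correctly refuses
  (not-bimodal error) rather than returning an arbitrary cut.
* No drift correction, repeated-localization merging, or 3D/astigmatic
  fitting.
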