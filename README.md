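# smlmet

Fully automatic emitter identification for single-molecule localization
microscopy (SMLM), with per-emitter reliability.

## The problem

SMLM techniques (PALM, STORM, dSTORM) reconstruct super-resolved images
from the localizations of sparsely blinking fluorophores across thousands
of camera frames. Deciding which candidate spots are true single-molecule
emissions — rather than background fluctuations — normally requires
user-chosen thresholds, and wrong thresholds create or destroy structure in
the final image. `smlmet` removes that user bias:

1. **Fit everything.** Every locally brightest spot in every frame
   (no pre-selection) is fitted with a fixed-width 2D Gaussian PSF,

   &nbsp;&nbsp;*m*(x, y) = *n*<sub>psf</sub>/(2π s₀²) ·
   exp(−((x−x₀)² + (y−y₀)²)/(2 s₀²)) + *n*<sub>b</sub>,

   where s₀ = 0.21 λM/(NA·μ) pixels is the theoretical Gaussian PSF width.
2. **Threshold automatically.** The pooled histogram *h*(*n*<sub>psf</sub>)
   of fitted photoelectron counts is bimodal — false emitters are dim, true
   emitters bright — and is split by generalized minimum-error thresholding:
   the threshold *T* minimizes

   &nbsp;&nbsp;*J*(*T*) = −Σᵢ Σ<sub>x∈R<sub>iT</sub></sub> *h*(x)
   [log *P*<sub>iT</sub> + log *f*ᵢ(x | θ<sub>iT</sub>)],

   with pluggable false/true class densities: Gaussian–Gaussian (GGDM) or
   Weibull–Lognormal (WLDM).
3. **Quantify confidence.** The fitted class densities give each emitter a
   posterior probability of being true,
   *R*(*n*<sub>psf</sub>) = *NT*/(*NF* + *NT*), from which reliability maps
   of the reconstruction are rendered.

The only required inputs are objective experimental constants (camera
offset and gain, pixel size, magnification, NA, emission wavelength). The
package also provides super-resolution rendering, localization evaluation
(Jaccard/precision/recall/RMSD with an optimal tolerance-radius matcher),
a ground-truthed synthetic SMLM movie simulator, and a command-line
interface (`inst/cli/smlmet`).

## Worked example

Simulate the canonical synthetic scene (three crossing filaments,
128×128 px at 70 nm/px, 200 frames, lognormal photon counts, Poisson
noise), analyze it fully automatically, and score the result against the
ground truth:

```r
library(smlmet)
cam <- standard_camera()
movie <- simulate_movie(standard_scene(seed = 1), cam)
analysis <- analyze_movie(movie$frames, cam, model = "wldm")
analysis
#> <smlm_analysis>
#>   40947 potential emitters in 200 frames
#>   model wldm, automatic threshold 114.5, selection threshold 114.5
#>   804 accepted, 40143 rejected
analysis$threshold
#> <threshold_result> model wldm, threshold 114.5 (gray level 114 + 0.5)
#>   P(false) 0.980, P(true) 0.020
#>   theta_false: shape=2.733, scale=37.53
#>   theta_true:  meanlog=6.688, sdlog=0.3714
report <- match_localizations(movie$ground_truth, analysis$localizations,
                              tolerance_nm = psf_fwhm_nm(cam))
report
#> <match_report> TP 804, FP 0, FN 44 (tolerance 222.365 nm)
#>   Jaccard 0.948, precision 1.000, recall 0.948, RMSD 14.05 nm
```

Reading the numbers: exhaustive fitting finds ~41 000 potential emitters,
~50× the ~850 true activations — most candidates are background
fluctuations, which is exactly why the histogram is bimodal. The automatic
threshold (114.5 photoelectrons) accepts 804 localizations, all of them
true (precision 1.000), recovering 94.8% of the ground truth with a 14 nm
RMS localization error. `plot(analysis$threshold)` shows the histogram with
the fitted class densities and threshold line;
`reliability_curve(analysis$threshold)` and `render_reliability_map()`
turn the rejected-and-accepted table into a reliability map.

Any bimodal scalar characteristic can be thresholded the same way:
`find_threshold(values, wldm())` works on externally computed
characteristics (e.g. a wavelet SNR) just as well as on photoelectron
counts.

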