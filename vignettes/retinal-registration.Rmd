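---
title: "Two-stage registration of low-SNR retinal video sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage registration of low-SNR retinal video sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(retreg)
```

## The problem

A video-ophthalmoscope records the retina continuously under low,
non-mydriatic illumination. The frames are noisy (SNR around 19 dB,
measured as $20\log_{10}(\mu/\sigma)$ in a homogeneous region), and the
retina moves between frames: slow fixational drift, micro-saccades with
excursions of tens of pixels, occasional motion blur, and bright
blink/corneal reflections. Every photometric analysis of such a sequence
— vessel-calibre pulsation, blood-volume changes, frame averaging for
noise suppression — needs the frames registered to a common reference
first. Because the eyeball rotates approximately rigidly over a small
field of view and the scale does not change over a short recording, a
shift-plus-rotation (Euclidean) model per frame is adequate.

`register_sequence()` fits exactly that: one rigid transform
$(t_x, t_y, \varphi)$ per frame, mapping reference coordinates to moving
frame coordinates with rotation about the image centre. The rotation
centre is a reporting convention, not a physical claim — any fixed centre
gives an equivalent parameterisation.

## The model and the pipeline

**Reference selection.** Each frame $g$ is treated as a blurred,
noise-corrupted view of the underlying scene. Blur (and equally a bright
blink reflection) collapses the histogram of the Sobel edge image into a
dominant peak, so the Shannon entropy

$$E = -\sum_{i=1}^{N} p_i \log p_i$$

of the 128-bin edge-image histogram ranks frames by sharpness: the
maximum-entropy frame becomes the reference, and low-entropy frames are
flagged as distorted. We use the natural log — the base only rescales $E$
and the ranking is base-invariant. The histogram range is fixed per
sequence (zero to the sequence-wide maximum edge value) so entropies are
comparable across frames. The distortion threshold is
$\mathrm{median}(E) - k\cdot\mathrm{MAD}(E)$ with $k = 3$ by default; the
original procedure sets this threshold by hand, and the robust default
automates that intent while remaining overridable.

**Preprocessing.** A $3\times3$ median filter (reflection borders, so the
frame margins are not darkened before the FFT) and CLAHE (8×8 tiles,
normalised clip limit 0.01) raise the SNR and vessel contrast on working
copies used for all estimation. The final transform is applied to the
*original* frames, because downstream pulsation analyses need unaltered
photometry.

**Coarse stage.** Windowed phase correlation: both frames are multiplied
by a separable Hanning window (the DFT is periodic), the normalised
cross-power spectrum is inverted, and the integer shift is read off the
global maximum, with peak positions past half the image size wrapping to
negative shifts. No subpixel peak interpolation is attempted — subpixel
accuracy is the fine stage's job. The correlation peak height is kept as
a confidence signal; distorted frames produce markedly weaker peaks.

**Fine stage.** Tracking points live on the vessel tree. The per-pixel
larger eigenvalue of the image Hessian (second derivatives by repeated
Sobel operators) is large and positive along dark vessel valleys; clipped
at zero and min–max normalised it forms a tracking-point probability map
$\bar\lambda$. Across the sequence the map accumulates evidence with
exponential weighting,

$$\bar\lambda_i = q\,\bar\lambda_{i-1} + \lambda_i,$$

renormalised after every update, with $q = 0.9$ — close to 1 so that a
single distorted frame cannot reshape the map, giving a memory of roughly
ten frames. Tracking points are extracted by Kittler–Illingworth
minimum-error thresholding of the map's nonzero histogram, removal of
connected components below 20 px (vessels form long structures), and
Zhang–Suen skeletonisation down to centrelines, capped at 400 points by
uniform subsampling along the skeleton.

Each point is tracked by the basic single-level Lucas–Kanade solve over a
$31\times31$ window — sized to span the thickest vessels (about 21 px)
plus the residual motion left after the coarse stage — giving the 2×2
normal-equation system in the temporal difference $D$ and spatial
gradients $I_x, I_y$ of the moving frame. Points with an ill-conditioned
structure matrix (the aperture problem) or displacements beyond half the
window are dropped. A rigid transform is fitted to the surviving point
motion by the closed-form 2-D orthogonal Procrustes solution — the same
least-squares objective as a linearised Gauss-elimination fit in
$(\cos\varphi, \sin\varphi, t_x, t_y)$, but enforcing a true rotation
(the tests assert the equivalence on clean fixtures). The frame is warped
and the solve repeats until the parameter change is small; each point's
trackability

$$Q = \frac{1}{2M^2}\sum_{(x,y)\in W}(D + I_x\,dx + I_y\,dy)(I_x + I_y)$$

is evaluated at the solved displacement, mapped to a $[0,1]$ score
($1 -$ $|Q|$ / max $|Q|$, so 1 = good), spread spatially by a compact
Gaussian (σ = window/6, truncated within the window half-size), and fed
back multiplicatively: $\bar\lambda \leftarrow \bar\lambda\,(1+Q)$, which
raises only locations already above zero, before the next frame's
eigen-map accumulation.

**Evaluation.** Vessel centrelines are static anatomy, so after
registration the minimum of an intensity profile taken across a vessel
should sit at the same position in every frame. For a cross-section site,
each 3×3-box-smoothed frame contributes a profile; the mean profile and
every per-frame profile are upsampled 4× (cubic spline), and with minimum
positions $X_i$ and $X_{mean}$ on that grid the absolute mean error is

$$AME = \frac{1}{4N}\sum_{i=1}^{N}|X_i - X_{mean}|$$

in pixels of the original grid. Sites are stratified inside/outside the
optic nerve head (brighter disc, higher vessel contrast), a site counting
as inside only when both endpoints fall within the circle.
`auto_propose_sites()` automates the manual site choice so the metric is
testable without an operator: skeleton points with high eigen-map
response, spaced apart, each segment oriented along the across-vessel
Hessian eigenvector with length four times the locally estimated width.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `median_window` | 3 | px | noise suppression that preserves vessel edges |
| `clahe_clip`, `clahe_tiles` | 0.01, 8×8 | – | local vessel contrast without amplifying noise to saturation |
| `entropy_bins` | 128 | – | edge-histogram resolution for the quality score |
| `quality_k` | 3 | MADs | robust automatic stand-in for a manually adjusted threshold |
| `q` | 0.9 | – | map memory ≈ 10 frames; close to 1 to damp distorted frames |
| `window` | 31 | px | LK window spanning the thickest vessels (~21 px) + residual motion |
| `min_area` | 20 | px | vessels form long structures; fragments are noise |
| `max_points` | 400 | – | bounds runtime; accuracy saturates well below this |
| `tol_shift`, `tol_rot` | 0.05, 2 | px, deg | fine-stage stop rule |
| `upsample` | 4 | – | quarter-pixel resolution of the AME metric |

One reading of the stop rule deserves a note: the parameter change
between iterations is expressed *at the tracking points* — the largest
pixel displacement the increment induces on any tracked point — so shift
and rotation changes share a single pixel scale. A rotation increment of
2° moves peripheral points by several pixels and correctly keeps the
iteration alive; measuring raw $(t_x, t_y)$ change alone can stall the
loop while the rotation is still being recovered. Divergence is declared
when the residual point motion (not the increment, which legitimately
grows while a large rotation unwinds) grows by more than 10% over four
consecutive iterations; a frame that exhausts the 20-iteration cap with
median point motion above 1 px, or drifts to an implausible transform,
falls back to its stage-1 shift and is flagged.

Two further numerical choices: the eigen map of a *warped* frame is
zeroed outside the (eroded) validity mask before normalisation — the
artificial edges of zero-filled borders otherwise dominate the min–max
normalisation and swamp the vessel signal; and each frame's fine stage is
warm-started with the previous frame's rotation estimate, since ocular
torsion is temporally persistent and the warm start saves iterations
without changing the fixed point.

## The synthetic generator, and what it does not emulate

`phantom_spec()` + `render_sequence()` produce the test scenes: dark
vessels with Gaussian-valley cross-sections (widths 2–21 px at the
nominal 640×480 geometry, scaled with image width) on a brighter
background with a brighter optic-disc region; per-frame rigid motion;
additive white Gaussian noise scaled to a scripted SNR (19 dB by
default, matching the modelled acquisition; Gaussian is the simplest
model consistent with the mean/σ SNR definition); and scheduled
artefacts — Gaussian blur for saccadic smear, a saturating central disc
for blink reflections. Frames are rendered *analytically* at rigidly
transformed coordinates, so the scripted transforms are exact ground
truth with no interpolation error, and a marked homogeneous patch
supports SNR measurements.

The motion model emulates single-spot fixation: a first-order
autoregressive drift around the fixation point with saccadic jumps
(probability 0.08 per frame), shifts truncated at ±30 px; torsion is
scripted far smaller than translation (sub-degree wander with small
saccadic kicks, bounded at ±3°), as fixational ocular torsion is an
order of magnitude below its translational excursions.

What the phantom does **not** emulate: photoreceptor/nerve-fibre texture,
vignetting and slow illumination drift, vessel pulsation (the phantom's
vessels are rigid), true optical PSFs, and non-rigid residual motion.
Passing tests therefore demonstrate the estimator's correctness and its
noise/artefact robustness under the stated conditions — not clinical
performance on device data, whose published precision (sub-pixel to
~1.4 px AME depending on region) rests on sequences that are not
publicly available.

## Problem sizes used by the tests

The recovery suite registers 20 sequences of 60 frames at 192×256 px
(plus noise-free renders of the same scripts), a size at which the
geometry of the task — vessel widths, window size, shift range relative
to the frame — matches the modelled instrument while keeping the full
suite comfortably reproducible on a single CPU. The windowed
phase-correlation sweep runs on a 64×64 texture over the identifiable
envelope |shift| ≤ 16: with the mandated Hanning window, cyclic shifts
approaching half the image size leave no shared content under the window
and no estimator can recover them.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(c(192, 256))
script <- motion_script(n_frames = 30, max_shift = 30, max_rot = 3,
                        noise_snr_db = 19, seed = 7)
synth <- render_sequence(spec, script)

fit <- register_sequence(synth$sequence)
fit
summary(fit)
plot(fit)           # entropy trace + eye-movement trajectory

# precision via vessel cross-sections
ref_pre <- preprocess_frame(synth$sequence$frames[[fit$reference_index + 1]])
sites <- auto_propose_sites(ref_pre, 18)
evaluate_registration(fitted(fit), sites, excluded = fit$excluded_frames)

# high-quality average of the registered, retained frames
avg <- averaged_image(fit)
```

## Known limitations

* The rigid model cannot represent residual non-rigid retinal motion or
  perspective effects at larger fields of view.
* The coarse stage assumes the true translation is identifiable under
  the Hanning window — frames displaced by more than about a third of
  the frame size relative to the reference degrade gracefully into
  low-confidence estimates rather than failing loudly.
* Kittler thresholding assumes a two-population histogram; on maps with
  negligible vessel signal it falls back to Otsu, and frames without
  usable tracking points keep their stage-1 transform.
* AME measures constancy of profile minima, not absolute anatomical
  accuracy: a systematic bias common to all frames is invisible to it.
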