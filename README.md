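# retreg

Two-stage registration of low-SNR retinal video sequences, with a
vessel-profile precision metric and a synthetic ground-truth generator.

## What problem this solves

Video-ophthalmoscopes record the retina continuously under low,
non-mydriatic illumination. The sequences are noisy (SNR ≈ 19 dB) and the
retina moves between frames — fixational drift, micro-saccades of tens of
pixels, motion blur, bright blink reflections. Analyses of such sequences
(vessel pulsation, blood-volume changes, frame averaging, eye-movement
traces) all require the frames registered to a common reference. Over a
small field of view and a short recording the motion is well described by
a per-frame rigid transform: shift $(t_x, t_y)$ plus rotation $\varphi$
about the image centre.

`retreg` estimates that transform for every frame in two stages:

1. **Reference selection & quality flagging** — each frame is scored by
   the entropy $E = -\sum_i p_i\log p_i$ of its 128-bin Sobel
   edge-image histogram. Blur and blink reflections collapse the edge
   histogram into a dominant peak, so the maximum-entropy frame becomes
   the reference and low-entropy frames are flagged as distorted.
2. **Coarse stage** — windowed phase correlation (separable Hanning
   window, normalised cross-power spectrum, integer peak) removes large
   eye movements.
3. **Fine stage** — tracking points on vessel centrelines, drawn from a
   Hessian-eigenvalue probability map that accumulates across the
   sequence with exponential weighting
   ($\bar\lambda_i = q\,\bar\lambda_{i-1} + \lambda_i$, $q = 0.9$) and a
   per-point trackability feedback
   ($\bar\lambda \leftarrow \bar\lambda\,(1+Q)$), are tracked by
   single-level Lucas–Kanade in 31×31 windows; a rigid transform is
   fitted to the point motion (closed-form 2-D Procrustes) and iterated
   to convergence (0.05 px / 2° tolerances).

Precision is quantified by the **absolute mean error (AME)** of vessel
cross-section profile minima on a 4× upsampled grid,

$$AME = \frac{1}{4N}\sum_{i=1}^{N}\left|X_i - X_{mean}\right|,$$

stratified inside/outside the optic nerve head. A synthetic phantom
generator (vessel tree with Gaussian-valley cross-sections, brighter
disc, scripted fixation-like rigid motion, 19 dB additive noise,
blur/blink artefacts) provides exact ground truth for every stage.

## Worked example

```r
library(retreg)

spec   <- phantom_spec(c(192, 256))
script <- motion_script(n_frames = 20, max_shift = 30, max_rot = 3,
                        noise_snr_db = 19, seed = 7)
synth  <- render_sequence(spec, script)

fit <- register_sequence(synth$sequence)
fit
#> retreg fit: 20 frames registered to frame 11
#>   excluded (distorted): 0   fine-stage failures: 0
#>   |shift| median 5.82 px (max 24.60), |rotation| median 0.203 deg (max 0.821)

head(coef(fit), 4)           # per-frame (tx, ty, phi) vs the reference
#>     tx_px   ty_px phi_deg
#> 0 -11.627 -20.446   0.375
#> 1  -4.795 -24.124   0.649
#> 2   0.791 -24.284   0.821
#> 3  -0.224 -23.575   0.611

summary(fit)                 # entropy range, shift/rotation summaries,
#> ...                       # iteration counts (95% converge in 2-7 here)

ref_pre <- preprocess_frame(synth$sequence$frames[[fit$reference_index + 1]])
sites   <- auto_propose_sites(ref_pre, 18)
evaluate_registration(fitted(fit), sites, excluded = fit$excluded_frames)
#> registration evaluation over 18 sites, 20 frames
#>   inside_onh   absent
#>   outside_onh  n = 18  AME median 0.113 +- 0.223 px  (<1px: 94%, 1-2px: 6%, >2px: 0%)
```

The fitted object's `coef()` matrix is the per-frame motion relative to
the reference — usable directly as an eye-movement trace; `fitted()`
returns the registered frames (the *original* photometry warped, so
pulsation analyses stay valid); `plot()` shows the entropy trace and the
trajectory; `averaged_image()` builds the high-quality mean image over
retained frames. `export_transforms()` / `write_sequence()` persist the
results (CSV; multi-page TIFF or PNG directory — both lossless).

The AME above says: across 18 vessel cross-sections, the per-frame
profile minimum deviates from the sequence-mean minimum by a median of
about a tenth of a pixel — the scripted motion (up to ±30 px, ±3°) has
been removed to subpixel residue.

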