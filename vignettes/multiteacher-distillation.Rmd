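---
title: "Multi-teacher knowledge distillation for vessel segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-teacher knowledge distillation for vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Vessel segmentation labels every pixel of a retinal fundus photograph or a
coronary angiogram as vessel or background. The persistent failure mode of a
single U-Net is the thin vessel: a one-or-two-pixel capillary contributes
almost nothing to an overlap loss dominated by thick trunks, so it is the
first thing the optimizer sacrifices.

`vesselkd` implements a response-based multi-teacher knowledge distillation
(MTKD) scheme that attacks this directly. Three *teacher* U-Nets are trained
on three variants of the same ground truth: the full vasculature (T1), only
the thick vessels (T2), and only the thin vessels (T3). A *student* U-Net is
then trained against two signals at once:

1. **Soft labels.** Each teacher's logit map $z_t$ is softened through a
   temperature-scaled sigmoid, $P_t = \sigma(z_t / T)$, while the student
   keeps the plain sigmoid $P_s = \sigma(z_s)$. Both maps are clamped to
   $[\varepsilon, 1-\varepsilon]$ and compared pixel-wise with the binary
   Kullback-Leibler divergence
   $\mathrm{KL}(P_t \| P_s) = P_t \log(P_t/P_s) + (1-P_t)\log\frac{1-P_t}{1-P_s}$,
   averaged over pixels to one scalar per teacher, then averaged over the
   $M$ teachers.
2. **Hard labels.** A conventional segmentation loss (default DiceBCE)
   against the original binary ground truth.

The total objective is
$L_{\mathrm{student}} = \alpha \, L_{\mathrm{avg\_distill}}
 + (1-\alpha) \, \rho \, L_{\mathrm{hard}}$,
with $\alpha = 0.5$ by default and $\rho \ge 1$ an optional *penalty* on the
hard term (the "loss penalization" variant; $\rho \in \{5,10,15,20\}$ in the
ablation grid).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `temperature` | 3.0 | divisor on teacher logits; larger values flatten the soft labels toward 0.5. 3.0 is the value that consistently balances transfer and learnability in the reference ablations. |
| `alpha` | 0.5 | weight of the distillation term; 0 recovers plain supervised training, 1 pure distillation. |
| `epsilon` | 1e-7 | probability clamp protecting the logarithms. |
| `penalty` | 1 (off) | multiplier on the hard-label term only. Multiplying the *whole* objective would merely rescale the effective learning rate and could not change the optimum, so the hard-term reading is the only one that can produce the reported effect. |
| `hard_loss` | DiceBCELoss | any of the nine losses in the zoo. |
| width threshold | 2 px | calibre cut-off separating thin from thick in the synthetic ground-truth decomposition. |

Design choices where the source material was ambiguous:

* **Temperature on one side only.** The stated softening applies $T$ to the
  teacher logits and leaves the student's sigmoid unscaled; classic
  distillation scales both. We honor the stated form literally and expose
  `scale_student = TRUE` as an escape hatch.
* **No $T^2$ gradient rescaling** is applied anywhere.
* **Pixel reduction** of the KL map is the mean over pixels, making losses
  comparable across image sizes.
* **Validation loss for student checkpointing** is the full penalized total.
* **Frozen-teacher logits are computed once per sample** and reused across
  epochs. With frozen teachers and no augmentation this is bit-identical to
  recomputing them every step, and no soft-label files are written to disk.

## The loss zoo

Only the names of the eight student losses are fixed by the experimental
grid; their formulas and hyperparameters are package decisions: smooth
term 1 for every overlap loss, Tversky $(\alpha,\beta)=(0.7,0.3)$ weighting
false-negative recovery (thin-vessel emphasis), focal $\gamma = 2$ with no
class-balance factor so that $\gamma = 0$ reduces exactly to BCE,
focal-Tversky $\gamma = 0.75$, Combo weight 0.5, and CombinedLoss defined as
unit-weight BCE + Dice to stay distinct from ComboLoss. All are exposed in
`loss_config()` so sweeps can revisit them.

One algebraic subtlety: with an additive smoothing constant $s$ in both
numerator and denominator, the symmetric Tversky loss at
$\alpha=\beta=0.5$ equals the Dice loss *at smoothing $2s$* (multiply
numerator and denominator by two), and the two coincide exactly at $s = 0$.
The test suite asserts the reduction in that exact form rather than
pretending the smoothed versions are identical.

## The synthetic world

Real benchmarks (DRIVE, CHASEDB1, CHUAC, DCA1) need downloads and GPU-scale
training, so the package ships a generator of vascular phantoms:

* **Vessel trees** are correlated random walks that branch recursively;
  calibre is constant per branch, drawn from the thick regime (3-8 px) near
  the root and the thin regime (1-2 px) at deeper levels, so every scene
  with branching depth at least 2 contains both calibre classes. Walks
  reflect at the image border, and sub-pixel calibres are stamped as
  single-pixel strokes so thin vessels render at true 1-px width.
* **Background** is smoothed noise plus a radial illumination falloff
  imitating fundus vignetting; vessels sit `vessel_contrast` above it, and
  optional Gaussian pixel noise is added last.
* **Thin/thick ground truths** — manually annotated in the reference
  datasets — are produced programmatically: skeletonize the mask, read the
  local radius off the exact Euclidean distance transform, label skeleton
  pixels thin when estimated full width $2r \le 2$ px, and give every
  foreground pixel the label of its nearest skeleton pixel (ties to thick,
  keeping the partition deterministic). The partition is exact
  (thin ∧ thick = ∅, thin ∨ thick = gt) and monotone in the threshold.

What the generator does *not* emulate: photorealistic texture, pathology,
inter-observer annotation noise, field-of-view masks, or the resolution of
real fundus images. A green end-to-end test therefore establishes that the
training and distillation machinery works and that multi-teacher transfer
is not harmful at desk scale — it does not establish clinical-grade
segmentation quality.

## The desk-scale benchmark

`run_desk_benchmark()` fixes one world: 64×64 scenes, two trees, branch
depth 3, vessel contrast 0.7, no background noise (the "easy" regime), a
6/2/4 train/val/test split, a base-width-8 depth-2 U-Net, Adam 1e-3, batch
4, 30 epochs. At this scale the full-vasculature teacher reaches validation
F1 well above 0.8 in about half a minute of CPU, and the three-teacher
student can be compared against each single-teacher student. The thin-only
teacher's F1 against its own sparse target is much lower — a handful of
one-pixel capillaries leaves F1 brittle — which is expected and not bound
by any test.

## Numerical choices

* The network engine is plain R over BLAS with two compiled kernels
  (patch-matrix construction for the 3×3 convolutions and its adjoint).
  Weights are double precision; He-normal initialization.
* Normalization layers compute statistics per sample over the spatial
  extent (instance-style) rather than across the minibatch: with
  single-sample processing and minibatches of 4-8 this is deterministic,
  batch-size independent, and keeps the affine scale/shift parameters that
  the parameter accounting counts (2 per channel). Running statistics are
  therefore unnecessary at inference.
* Max-pool ties route gradients to the first maximum in a fixed scan
  order; thin/thick ties go to thick; binarization ties go to foreground.
  Every tie-break is deterministic.
* The clamp inside the KL is treated as pass-through in the gradient,
  giving the classic $(P_s - P_t)/n$ form.
* MAC accounting uses `out_H × out_W × C_in × C_out × kernel_area` per
  convolution *and* transposed convolution (output-pixel convention);
  pooling, normalization and activations are excluded. This convention
  reproduces the published FLOPs figures to about 0.1%, so exact equality
  is asserted only for ratios, and the absolute value at 1%.
* The "Lite" student divides every channel width by 8. The prose
  description of the reference ablation says feature maps are "halved",
  but only the ÷8 schedule reproduces the printed 0.487 M parameters and
  1.95 MB exactly; the printed table wins.
* Padding is appended bottom/right only; `auto16` pads each axis to the
  next multiple of 16. The per-dataset overrides (592×576, 1008×1008,
  320×320, none) follow the published pads, with the bottom/right
  assignment resolved by divisibility by 16.

## Known limitations

* Training is CPU-bound and single-threaded apart from BLAS; the standard
  31 M-parameter network is buildable and countable but not trainable at
  desk scale. Sweeps at realistic resolutions need the original GPU stack.
* Micro-aggregated (pixel-pooled) metrics are the only reporting
  convention; per-image macro-averaging is not offered because the
  reference convention is unstated.
* The synthetic benchmark is deliberately easy; differences between
  single- and multi-teacher students at this scale are small, and the
  packaged test only asserts that the multi-teacher student is not
  meaningfully worse than the best single-teacher student.
* Feature-map distillation, learned per-teacher weights, and alternative
  student encoders are out of scope.
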