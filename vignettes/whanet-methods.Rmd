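---
title: "WHA-Net: model, synthetic data, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WHA-Net: model, synthetic data, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `whanet`: the model
and its assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, the numerical conventions,
and the design choices made where the published description left the
design open.

## The classification problem

Optic disc edema (ODE) — true swelling of the optic nerve head, with
blurred disc margins and possible hemorrhage or exudates — must be
distinguished from pseudopapilledema (PPE), a benign elevation that
mimics it, and from normal discs, using only colour fundus
photographs. WHA-Net is a lightweight hybrid CNN/transformer for this
three-class task, small enough (about 2.15 M parameters, 0.81 G MACs
at 256×256) for desktop fundus cameras and handheld devices.

## Architecture

The network downsamples by 2 at the stem and at four later stages
(cumulative stride 32). The default stage table is:

| stage | block | output channels | notes |
|---|---|---|---|
| stem | 3×3 conv, stride 2 | 16 | BN + SiLU |
| wtc | wavelet convolution | 16 | 2-level Haar, BN + SiLU after |
| s1 | HAIR, stride 1 | 32 | scSE after depthwise |
| s2 | HAIR, stride 2 | 48 | |
| s3 | IR ×2, stride 1 | 48 | |
| s4 | IR ↓2 + Agent-MViT | 64 | d = 96, L = 2 |
| s5 | IR ↓2 + Agent-MViT | 80 | d = 112, L = 4 |
| s6 | IR ↓2 + Agent-MViT | 96 | d = 216, L = 3 |
| head | 1×1 conv → GAP → linear | 384 → 3 | Hard-Swish |

**Wavelet convolution.** The fixed orthonormal Haar bank (entries
±1/2) splits each channel into LL/LH/HL/HH at half resolution;
decomposition recurses on the *unconvolved* LL. Each subband at each
level is filtered by its own learnable depthwise 3×3 kernel, and the
original scale by one more (a config switch `orig_branch_kernel`
selects 1×1 instead). Reconstruction runs bottom-up through the exact
inverse transform, adding each level's output to the convolved LL one
level up. Conventions that matter:

* cross-correlation (no kernel flip) throughout — the high-pass
  filters are orientation-sensitive;
* subband names follow the wavelet-CNN literature ("LH" = the filter
  `½[[1,1],[-1,-1]]`, which responds to vertical intensity variation);
* normalization is the orthonormal ±1/2 (no √2 variant), so the
  transform conserves energy exactly and `idwt2(dwt2(x)) = x` to
  machine precision;
* odd spatial sizes are reflect-padded to a multiple of `2^levels` and
  cropped after reconstruction, preserving perfect reconstruction;
* the block is bias-free, normalization-free and activation-free
  inside — a pure linear operator for fixed kernels, which makes its
  identity-kernel trace (`constant c → 3c` at two levels) testable
  exactly. BN + SiLU follow the block at the model level.

**scSE.** Channel gating (global average pool → C/4 bottleneck with
SiLU → Hard-Sigmoid) in parallel with spatial gating (1×1 conv to one
channel → Hard-Sigmoid), fused by elementwise sum. The sum keeps the
zero-initialization identity: with all gate weights zero both branches
output x/2. Reduction ratio 4 (16 would degenerate at the small
channel counts of a lightweight net).

**Agent attention.** Queries are pooled (adaptive average, on the
token grid) to n = 16 agent tokens per head; attention is two
softmax stages — aggregation `σ(AKᵀ/√d_h + B1)V` then broadcasting
`σ(QAᵀ/√d_h + B2)·` — plus a depthwise 3×3 on V as a feature-diversity
residual. The 1/√d_h scaling is applied in both stages (the reference
softmax attention, Eq-style `σ(QKᵀ/√d_k)V`, sets the convention).
Learnable biases B1/B2 are stored per head on the stage's native token
grid at 256 input (16×16, 8×8, 4×4 per patch group) and bilinearly
interpolated when the runtime grid differs; when the sequence is
shorter than n, the agent grid is clipped. Cost is O(N·n·d) per head —
the package's MAC counters expose the linear-vs-quadratic scaling
directly.

**Agent-MViT.** Depthwise 3×3 (+BN+SiLU) and pointwise C→d for the
local representation; MobileViT unfold with patch size 2 (p² = 4
independent sequences of length HW/4); L pre-norm Agent-Transformers
(MLP ratio 2, SiLU); LayerNorm; fold; pointwise d→C; then a
MobileViTv3-style fusion — concatenate the local representation with
the globalized one, 1×1 conv 2C→C, and add the block input. BN
follows every convolution except inside the transformer, which uses
LayerNorm only; where the published description is silent on the BN/LN
boundary this placement is a design choice.

### Reconstructing the stage widths

The published architecture diagram is not machine-readable; only the
totals (2.147 M parameters, 809.81 M FLOPs, with FLOPs = MACs given
the printed 1.0 G figure for the MobileViTv3-xs baseline) pin it down.
Starting from the MobileViTv3-xs lineage (channels 16/32/48/64/80/96,
head 384, L = 2/4/3) and computing the analytic budget shows the
lineage token dims (96/120/144) land 27% short on parameters while
already close on MACs. Parameters at the 8×8 stage cost only 64 MACs
each, so the reconstruction was calibrated there: token dims
96/112/216 with head width 384 give 2.150 M parameters (+0.14%) and
808.95 M MACs (−0.11%). The ablation deltas retain their signs (+WTC
adds ~1.3 k parameters and ~6 M MACs; +HAIR adds ~10.7 k parameters),
though the published +HAIR delta (0.206 M) suggests the original
applied scSE more widely than the two early stages reconstructed here;
with the totals fixed, both cannot hold at once.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `wtc_levels` | 2 | wavelet decomposition depth |
| `n_agents` | 16 | agent tokens per head (4×4 pooled grid) |
| `heads` | 4 | attention heads |
| `patch` | 2 | MobileViT unfold patch size |
| `expansion` | 4 | IR/HAIR channel expansion |
| `scse_r` | 4 | scSE bottleneck reduction |
| `rho` | 2 | transformer MLP ratio |
| `width_mult` | 1 | scales channels (to multiples of 4) and dims |
| lr / lrf | 5e-4 / 0.2 | AdamW with cosine floor `lrf·lr` |
| weight decay | 0.02 | decoupled (AdamW) |
| batch size | 64 | |
| threshold | 0.95 | low-confidence alert level |

Training hyperparameters follow the published recipe; epochs default
to 100 (unstated in the source; smoke tests use 5–10). The cosine
schedule steps per epoch: `lr(t) = lr0(lrf + (1−lrf)(1+cos(πt/T))/2)`.
Best-epoch selection uses validation macro accuracy, ties to the
earlier epoch.

## The metrics convention

Per-class metrics are one-vs-rest: TP is the diagonal entry, FP the
column remainder, FN the row remainder, TN everything else;
accuracy/precision/recall/specificity follow the usual formulas. The
headline "accuracy" of this task is the **macro** (unweighted mean)
one-vs-rest accuracy, which for K > 2 exceeds the pooled trace/total
accuracy whenever off-diagonal mass exists — on the published test
matrix, 0.9779 macro vs 0.9669 pooled. Both are always reported.
Published tables additionally average per-class values after rounding
to 4 dp; `$macro_printed` reproduces that convention (it differs from
the exact macro only in the last specificity digit, 0.9853 vs
0.98536). Division-by-zero cells are `NA` and flagged; zero-support
classes are excluded from the macro.

## Synthetic data: what it emulates, and what it does not

No public dataset accompanies the task, so the package generates
seeded synthetic fundus images: a dark-red vignetted background with
smooth texture; a bright, slightly elliptical disc whose radius is
0.12–0.22 of the frame and whose center stays in the central 60% (and
fully inside the frame — clinically, images cutting off the disc are
excluded); 4–7 vessels leaving the disc at roughly evenly spaced,
jittered angles as random walks with tapering width and occasional
branching; sensor noise. Class conditioning is concentrated at the
disc margin: rim blur σ ≈ 1 px (Normal), 3 px (PPE), 6 px (ODE) at 256
resolution, scaled with image size; ODE additionally gets a brightness
halo, 1–3 dark-red hemorrhage blobs near the rim, and vessel
attenuation where the swollen rim obscures them.

This makes the three classes separable by design — a two-cutpoint
threshold on rim-gradient energy alone reaches ≥80% — while leaving
enough variation (geometry, vessel layout, texture, noise) that a
classifier must generalize rather than memorize fixed templates. What
the generator does **not** emulate: real photographic artifacts
(flash, blur, uneven illumination), anatomical diversity (tilted or
crowded discs, drusen, myelinated fibers), camera/device variation,
or the actual difficulty of early ODE vs PPE. Passing the synthetic
end-to-end test therefore shows the implementation trains and
generalizes on a task with fundus-like structure; it says nothing
about clinical performance.

Augmentation follows the published bookkeeping: offline expansion adds
exactly three variants per training image (rotation within ±20°,
brightness×contrast jitter in [0.8, 1.2], Gaussian noise σ ∈
[0.01, 0.05]) for a 4× split size — 1209 images become 4836 — and is
refused on non-training splits as a leakage guard. Online augmentation
is a seeded random resized crop (area 0.8–1.0) plus horizontal flip
with probability 1/2; the evaluation path is a plain resize. The exact
magnitudes are unstated in the source and are configurable. The
detector that crops the optic disc in the original pipeline is out of
scope; a brightness-based localizer stands in: median-filter the green
channel, smooth lightly, threshold at 40% of the median-to-max range,
take the connected component containing the global maximum, and crop a
square of three estimated radii. On synthetic images its center error
is below 0.05 disc radii.

## Numerical and training notes

* All layers implement explicit forward/backward passes; gradients are
  verified against central finite differences (worst relative error
  ~1e-8 across layer types, end-to-end through the full model).
* Convolutions run through C++ (im2col + BLAS for grouped/pointwise, a
  direct stencil for depthwise); batch norm and activations are fused
  C++ kernels. Everything else is vectorized R.
* Batch-norm statistics: with batch 64 and a few hundred training
  images there are only ~4 optimizer steps per epoch, and momentum-EMA
  running statistics lag the weights badly enough to collapse
  eval-mode predictions. The training loop therefore recomputes the
  running statistics exactly after every epoch by frozen-weight passes
  over the training set (`recompute_bn_stats()`, the "precise BN"
  scheme). This changes evaluation fidelity only, not the optimization
  recipe.
* Initialization: scaled-uniform `U(±sqrt(1/fan_in))` for convolutions
  and linears (the mainstream framework default), and γ = 0 on
  residual-terminating BN layers so every residual block begins as the
  identity. Both matter in a short-schedule regime: with a scale-free
  adaptive optimizer, the weight scale sets how far a fixed-size step
  rotates the function, so oversized init (e.g. Kaiming-normal with
  sd = sqrt(2/fan_in), ~2.4× larger) visibly slows learning per step,
  while much smaller ViT-style σ = 0.02 linears starve the residual
  branches. Measured on the smoke task, the framework-default scale is
  the difference between ~0.82 and ~0.85 validation macro accuracy at
  ten epochs.
* AdamW applies decoupled weight decay to all parameters (framework
  default).
* Softmax rows are max-shifted before exponentiation; hard gates use
  exact breakpoints at ±3.
* The end-to-end smoke problem size is a 300-image synthetic training
  set plus a 100-image validation set (both at the emulated class
  proportions) at 96×96 with a 0.25-width model, batch 64, 10 epochs —
  the full published recipe at a scale a CPU test suite can afford.
  Note the step budget this implies: five optimizer updates per epoch,
  fifty in total, which is why the initialization details above are
  load-bearing. The suite's end-to-end test trains this configuration
  and checks that the best validation macro accuracy reaches 0.85
  within the ten epochs.

## Known limitations

* The stage-table reconstruction matches the published totals, not
  necessarily the exact internal widths; ablation deltas are
  sign-correct but smaller than printed for HAIR (see above).
* Agent-bias base grids are fixed at the 256-input geometry; other
  input sizes interpolate, which is differentiable but approximate.
* The training loop is CPU-bound R; it is meant for reproducing the
  method's behaviour at reduced scale, not for full-resolution
  training runs.
* The disc localizer assumes the disc is the brightest coherent
  structure — true for the synthetic images and for well-exposed
  fundus photographs, not for pathologies that darken the disc.
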