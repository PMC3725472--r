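---
title: "Simulating the hippocampal place code with hierarchical Slow Feature Analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the hippocampal place code with hierarchical Slow Feature Analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Rats entering a new environment develop, within minutes, a stable spatial
code: place cells that fire at particular locations largely independent of
heading, and head-direction cells tuned to heading largely independent of
location. This package implements a purely visual account of that process:
if the only learning signal is *temporal slowness* — find functions of the
retinal input that vary as slowly as possible over a behaviourally
realistic image stream — then place-like and head-direction-like codes
emerge from the statistics of the rat's own movement, with no reward, no
odometry and no map supervision.

Everything needed for such experiments is simulated: an enclosure of
textured walls, a statistical movement model (or a trained path), a
panoramic renderer standing in for the retina, the hierarchical Slow
Feature Analysis (SFA) network, and the sampling machinery that turns the
trained network into rate maps and tuning curves.

## Slow Feature Analysis

Given a multidimensional time series $\mathbf{x}(t)$, SFA finds functions
$g_i$ minimising the slowness objective
$\Delta(y_i) = \langle \dot y_i^2 \rangle_t$ of the outputs
$y_i(t) = g_i(\mathbf{x}(t))$ under the constraints of zero mean, unit
variance and mutual decorrelation over the training ensemble, with outputs
ordered by increasing $\Delta$. With $g_i$ linear in a quadratic expansion
of the input, the optimum is obtained from a generalized eigenproblem: the
covariance of the expanded signal against the covariance of its temporal
derivative.

Implementation choices that matter numerically:

* **Derivative.** The time derivative is approximated by forward
  differences $y(t{+}1) - y(t)$, leaving $T-1$ difference samples; the
  difference second moments are used uncentred, as the differences of a
  stationary ensemble are already mean-free to first order.
* **Solution path.** The expanded, centred data are whitened by an
  eigendecomposition of their covariance; the difference covariance is
  then diagonalised in the whitened basis and the smallest-eigenvalue
  directions kept. On the training ensemble the constraints then hold
  exactly by construction, which the test suite checks to $10^{-8}$ (mean)
  and $10^{-6}$ (variance, covariance). An independently coded dense
  generalized-eigenproblem solver (Cholesky reduction) in the tests
  confirms the whitening path to $10^{-6}$.
* **Rank control.** Whitening keeps eigenvalues above $10^{-7}$ of the
  largest. Degenerate inputs (uniform textures, collinear pixels)
  otherwise blow up; if the retained rank cannot supply the requested
  outputs, the fit aborts with an error advising regularisation noise.
* **Regularisation noise.** During fitting (never at application time)
  seeded Gaussian noise of standard deviation $10^{-4}$ — relative to
  inputs scaled to $[0,1]$ — is added to every node's input. This is a
  training-ensemble property: the constraint statistics are exact on the
  noisy ensemble (`sfa_training_outputs()` reproduces it) and hold on the
  clean data only up to the noise scale.
* **Sign convention.** Each learned function has its largest-magnitude
  coefficient made positive. The SFA objective is sign-blind; fixing the
  sign makes runs comparable and serialisation stable.

The delta value of a unit-variance sampled sinusoid of period $T$ is
$4\sin^2(\pi/T) \approx (2\pi/T)^2$; the tests pin `delta_value()` to this
closed form.

## The visual front end

The renderer replaces a hardware OpenGL stage with a deterministic
software raycaster using an equidistant-azimuth (cylindrical) projection,
appropriate for the rat's 320° field of view (a 55° "camera" option
supports robot-style experiments). Pixel column $c$ of $W$ looks along
azimuth $\mathrm{heading} + \mathrm{fov}/2 - c\,\mathrm{fov}/(W{-}1)$, so
both edge rays are rendered; one ray per column finds the nearest wall,
whose vertical extent on screen is proportional to $1/\mathrm{distance}$
(walls fill the frame at 2 world units by default, the `wall_scale`
parameter). Texture lookup is nearest-neighbour, tiled along the wall
every 2 world units; sky and floor are fixed grey levels (200, 40) that
give the lowest layer vertical luminance structure without modelling
textured floors. There is no distance shading or lighting model — cheap,
deterministic, and sufficient for slowness learning, but visibly simpler
than a real visual scene.

Default frame size is 320 × 40 grayscale. The resolution is not arbitrary:
it is the unique small frame that the first-layer receptive-field tiling
(below) maps exactly onto the 63 × 9 node grid.

Enclosures are closed loops of textured wall segments: box, circle
(regular polygon) and star-maze presets, plain-text custom floor plans
(`x1 y1 x2 y2 [texture]` per line), and axis-aligned rectangular obstacles
that participate in raycasting and validity checks exactly like walls. A
gap check verifies that segment endpoints pair up within $10^{-6}$ world
units; the `wallcheck` overview renders the plan with a labeled coordinate
raster so waypoint coordinates can be read off. The four star-maze
parameters are interpreted as (arms, arm width, arm length, centre
radius) — a geometric reading consistent with the preset's configurable
radius and arm count.

## The movement model

The rat is never steered directly; a statistical model produces the pose
sequence:

| parameter | default | meaning |
|---|---|---|
| `speed` | 0.2 units/step | base displacement per time step |
| `momentum` | 0.6 | blend weight of the previous direction; 1 = straight |
| `arc` | 60° | hard bound on the per-step turn |
| `min_wall_dist` | 0.2 units | closest approach to any wall |
| `path_noise` | 0.5 units | positional jitter in waypoint mode |

Each step draws a turn $u \sim U(-\mathrm{arc}, +\mathrm{arc})$ and blends
the turned direction vector with the previous one:
$\mathbf{d}' = \mathrm{normalize}\big(m\,\mathbf{d}(h) + (1{-}m)\,\mathbf{d}(h{+}u)\big)$.
This realises "higher momentum, straighter paths" while never exceeding
the arc bound, and the expected turn is zero in open space. If the
proposed position violates the wall margin, candidate headings within the
same $\pm$arc bound are tried at full, half and quarter speed
(displacement never exceeds `speed`); if the rat is fully boxed in it
stays put and rotates by the full arc (counter-clockwise tie-break), which
sweeps the whole circle within a few steps. A run aborts with a
simulation error after 50 consecutive zero-displacement steps — that only
happens on malformed plans or `arc = 0` dead ends.

Waypoint mode steers greedily toward the current target (turn clipped to
the arc), adds Gaussian positional noise, and advances the target within a
capture radius of $2\times$`speed` (preventing orbiting under coarse
steps). After the final waypoint the rat either loops to the first
waypoint or is reset there, matching trained-path experiments such as
corridor running. Movement defaults (momentum 0.6, arc 60°) follow the
standard foraging configuration of this simulation lineage; `speed = 0.2`
in a 10-unit box gives an enclosure crossing every ~50 steps, a realistic
ratio of body speed to enclosure size for foraging.

## The hierarchy

Three SFA layers with overlapping receptive fields that tile their input
*exactly* (the constructor rejects any residue):

* layer 1: 63 × 9 nodes, fields 10 × 8 px, stride 5 × 4 — identities
  $(63{-}1)\cdot 5 + 10 = 320$ and $(9{-}1)\cdot 4 + 8 = 40$;
* layer 2: 8 × 2 nodes, fields 14 × 5 nodes, stride 7 × 4 (tiles 63 × 9);
* layer 3: a single node over all 16 layer-2 nodes;
* optionally an ICA node on the final 32 signals.

The published grid sizes fix the layer shapes but not the field/stride
pairs; the pairs above are the unique small integers that reproduce the
grids with roughly 50% overlap. Every node applies linear SFA down to 16
signals, expands quadratically (152 dims) and extracts its 32 slowest
signals — the hierarchy exists precisely to keep each eigenproblem this
small. A reduced first-class architecture (input 64 × 16, grids 12 × 3 and
3 × 1, same node internals) provides fast end-to-end runs.

**Batch training.** Long recordings are processed in batches (default
10,000 frames). Only second moments and difference second moments are
accumulated, so batching is a memory layout, not an approximation: the
last sample of each batch is carried into the next (differences span
batch boundaries), and sums are always taken over fixed 256-sample chunks
aligned to the absolute frame index, so the floating-point summation order
is independent of the batch size. Accumulated moments are bit-identical
for any batch partition; fitted parameters agree to machine rounding (the
per-batch evaluation of the stage-1 projection is the only remaining
rounding difference), and repeated runs with the same seed are
bit-identical throughout. Training noise is drawn sample-major from a
per-node seeded stream, which keeps the noise, too, independent of the
batch partition.

**Generic training.** The lower layers can be trained once on an arbitrary
image stream with natural-image-like variety and then frozen
(`train_generic()`), after which only the top layer (plus ICA) is fitted
per environment (`train_top()`); `crop_center()` conforms foreign image
sizes. The model keeps no memory across environments: retraining the top
layer in a second enclosure destroys the first place code, which the test
suite demonstrates (median absolute map correlation below 0.5).

## Sparse coding

Raw slow signals are smooth global modes of position, not place fields. An
orthogonal ICA rotation of the (already white) 32 SFA outputs maximises a
tanh negentropy contrast by fixed-point iteration with symmetric
decorrelation (tolerance $10^{-5}$, at most 500 iterations; on
non-convergence the best iterate is returned with a warning and flagged).
Because the input is white the unmixing matrix is a pure rotation and
output variance is preserved. The rotation concentrates each signal's
mass, producing localized fields; its correctness is checked against a
grid-search oracle over rotation angles on rotated Laplacian sources
(recovery within 2°). `add_ica()` attaches the node to an already trained
network without touching the SFA layers.

## Sampling and statistics

`sample_place()` probes every valid grid position (default spacing: 1/20
of the larger enclosure extent — finer grids look smoother but sampling
cost grows quadratically) while looking in 8 compass directions, recording
all 32 signals: 32 × 8 directional maps plus 32 averages, the average
being exactly the pointwise mean of the eight. Invalid cells (outside the
enclosure, inside obstacles, or within the wall margin) are masked.
`sample_head_direction()` averages each signal over seeded random valid
positions per heading. Because the ICA sign is arbitrary, field statistics
and plots flip each signal so its spatial peak is positive; plot colour
scales are per-map min–max normalised, since absolute response units are
meaningless after the rotation.

Two scalar summaries support the classical comparisons:
`directionality_score()` ($1 - \min_d \mathrm{cor}(\text{map}_d,
\text{average})$, clamped to $[0,1]$) quantifies loss of directional
invariance, and `place_field_stats()` labels super-threshold cells (50% of
peak, 4-connected via `EBImage::bwlabel`) to count fields and measure
their area. A localized place field is one connected region under a
quarter of the valid area.

## What the simulation does and does not show

The generator emulates the study conditions this model family was
developed under: closed textured enclosures, random foraging with momentum
and turn limits, stereotyped waypoint running, and a panoramic retina. It
does **not** emulate photoreal optics, moving objects or conspecifics,
vestibular or odometric input, lighting changes, or texture-poor
environments; passing tests therefore show that the slowness principle
extracts positional codes under these idealised visual statistics, not
that the renderer rivals real vision. Known limitations: textures must
carry enough luminance structure for layer 1 (a single uniform texture is
degenerate and only trainable thanks to the regularisation noise), the
raycaster ignores wall height variation, and single-threaded determinism
is chosen over parallel speed.

## Problem sizes used in the shipped checks

The end-to-end checks run the reduced architecture: a 20,000-step random
walk in a 10 × 10 box (batch size 5,000, seed fixed) for place-field
emergence and byte-level pipeline determinism; a 10,000-step two-waypoint
corridor loop in a 12 × 2 box for the loss of directional invariance; and
a 10,000-step fast straight-running regime (speed 1, momentum 0.9, arc
10°) for head-direction tuning. At these sizes at least half of the first
16 ICA outputs form single localized fields — in the shipped runs all 16
do — and the corridor code is strictly more directional than the
open-field control. Module-level tests use 500–2,000-frame streams.
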