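# sfamaze

Simulation of hippocampal place-cell and head-direction-cell formation from
vision alone. A virtual rat forages in a configurable 2-D enclosure; its
wide-field (320°) panoramic visual stream is rendered by a software
raycaster and used to train a three-layer **Slow Feature Analysis** (SFA)
network with a final **ICA sparse-coding** step. Probing the trained
network over the enclosure yields place-field rate maps and head-direction
tuning curves — the simulation analogue of unit recordings — so the effect
of enclosure geometry, visual cues, and movement statistics on the spatial
code can be studied entirely in software.

The package is aimed at computational neuroscientists and students who want
to run place-code experiments (box, circle, and star-maze presets, custom
floor plans, obstacles, waypoint-trained running) without rebuilding the
model stack.

## The model

SFA extracts, from a multidimensional signal **x**(t), the input–output
functions g_i whose outputs y_i(t) = g_i(**x**(t)) vary as slowly as
possible:

    Δ(y_i) = ⟨ ẏ_i² ⟩_t   is minimal,

subject to, over the training ensemble,

    ⟨ y_i ⟩_t = 0          (zero mean)
    ⟨ y_i² ⟩_t = 1         (unit variance)
    ⟨ y_i y_j ⟩_t = 0      (decorrelation, i < j; outputs ordered by Δ)

Each g_i is linear in a (usually quadratic) expansion of the input, so the
problem reduces to a generalized eigenproblem of the covariance matrices of
the expanded signal and of its temporal derivative; the slowest directions
are the smallest eigenvectors. Because a full image frame is far too
high-dimensional for a single solve, nodes with small overlapping receptive
fields are arranged in a hierarchy: a 63 × 9 grid over the 320 × 40 pixel
input, an 8 × 2 grid over those node outputs, and a single integrating top
node (a reduced 64 × 16 / 12 × 3 / 3 × 1 configuration is also built in).
During a random walk the rat's position varies more slowly than any pixel,
so the slowest outputs of the top node encode position — but only as
smooth global modes. A final linear ICA rotation maximizes the
non-Gaussianity (sparseness) of the 32 slowest signals, which localizes
them into discrete place fields. Under stereotyped path running the fields
become direction-dependent, and under fast straight running the slowest
variable is heading, yielding head-direction tuning instead.

## Worked example

A complete open-field experiment in a 10 × 10 box (5,000-step random walk,
reduced architecture):

```r
library(sfamaze)

plan   <- make_box(10, 10)
view   <- view_params(width = 64, height = 16)
traj   <- generate_trajectory(plan, motion_params(), n_steps = 5000, seed = 42)
frames <- render_frames(plan, traj, view)
net    <- train(reduced_architecture(), frames, batch_size = 5000,
                with_ica = TRUE, seed = 42)
net
#> <sfa_network> input 64 x 16, 3 layers + ICA
#>   layer 1: grid 12 x 3 (36 nodes), rf 9 x 8, stride 5 x 4, out 32, trained
#>   layer 2: grid 3 x 1 (3 nodes), rf 6 x 3, stride 3 x 1, out 32, trained
#>   layer 3: grid 1 x 1 (1 nodes), rf 3 x 1, stride 1 x 1, out 32, trained

maps <- sample_place(net, plan, view, spacing = 0.5)
maps
#> <rate_maps> 32 signals x 8 directions (+average) on a 20 x 20 grid (400 valid cells)

place_field_stats(maps, signals = 1:4)
#> # A tibble: 4 × 5
#>   signal n_regions area_frac  peak localized
#>    <int>     <int>     <dbl> <dbl> <lgl>
#> 1      1         1    0.055   2.34 TRUE
#> 2      2         1    0.0225  4.60 TRUE
#> 3      3         1    0.03    3.02 TRUE
#> 4      4         1    0.0725  2.56 TRUE
```

Each of the first ICA outputs fires in a single connected region covering a
few percent of the enclosure — a place field. `autoplot(maps)` draws the
rate maps; `sample_head_direction()` and `tuning_concentration()` do the
same for head-direction tuning; `directionality_score()` quantifies how
direction-dependent a field is. `plot_maps()` writes the labelled PNG plot
tree.

## Command-line pipeline

The same experiment as a four-stage shell pipeline (the `sfamaze` script is
installed under `exec/`):

```sh
sfamaze record limit 100000 color box 10 10 mom 0.6 arc 60 seed 1 out exp
sfamaze convert in exp
sfamaze train in exp arch default batch_size 10000 ICA noise
sfamaze sample - 1 32 all in exp
```

`record` also has a `wallcheck` mode that renders the floor-plan overview
with a labeled coordinate raster for designing waypoint paths, and
`train add_ICA` attaches the sparse-coding node to an already trained
network. Stages only consume the previous stage's files, so a network can
be trained once and sampled many times.

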