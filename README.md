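# invasionquant

Quantification of glioblastoma (GB) invasion into brain organoids from
fluorescence confrontation assays, plus track-based invasion-speed analysis
and a synthetic ground-truth generator.

## The problem

In an organoid confrontation assay a patient-derived GB tumor sphere
(labelled with GFP or another fluorophore) is co-cultured with a brain
organoid until the two merge into a single "snowman"-shaped cluster. Tumor
cells then invade the brain compartment in two distinct modes that this
package quantifies separately:

* **cell competition** — the contiguous main tumor mass replaces brain
  tissue at the junction front;
* **single-cell invasion** — individual cells detach from the core and
  migrate deep into the brain tissue.

Both are normalised to the brain-organoid area. With `R` the pixel set of
the brain-compartment ellipse, `C` the tumor-positive pixels connected to
the core mass, and `S` the tumor-positive pixels detached from it:

```
competition  = |C ∩ R| / |R|
single_cell  = |S ∩ R| / |R|
total        = competition + single_cell        (exact, by construction)
```

The per-image pipeline is: seeded region growing on a reference channel
delineates the merged cluster; the cluster outline is split at its two
concave neck points and one ellipse is fitted per lobe (direct
least-squares ellipse fit), giving the brain and tumor compartments; the
tumor channel is thresholded (Otsu within the cluster, by default) and its
components are classified into the core mass and detached single cells by
8-connected labelling with a size filter. Every ratio is a ratio of pixel
counts on rasterized masks.

A second arm analyses exported time-lapse trajectories: invasion speed as
path length per non-overlapping 40-min window converted to µm/h,
boundary-reversal events (cells that reach the organoid margin and turn
back), and post-mitotic behaviour (daughter cells leaving the division
point in opposite directions).

Because the method's inputs are microscopy recordings, the package ships a
synthetic generator (`render_scene()`, `simulate_walks()`) that produces
confrontation images and track sets with pixel-exact, recomputed ground
truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(invasionquant)

## a synthetic 48-h confrontation: 30% of the brain ellipse replaced by the
## tumor front, 5% covered by 12 detached cells
spec  <- scene_spec(seed = 7, competition_true = 0.30, single_cell_true = 0.05)
scene <- render_scene(spec)
scene$stack
#> <image_stack> 2 channel(s) [GFP, BF], 1 z-plane(s), 256 x 256 px, 1.5 um/px

res <- quantify_scene(scene$stack,
                      brain_hint = spec$brain$center,
                      tumor_hint = spec$tumor$center,
                      config = run_config())
res$pair
#> <ellipse_pair>
#>  brain: <ellipse> center (92.06, 125.99), a = 61.76, b = 53.46, rot = 0.074 rad
#>  tumor: <ellipse> center (192.01, 132.01), a = 47.49, b = 41.58, rot = 2.891 rad
#>  overlap 210 px^2, residuals brain 0.566 / tumor 0.338 px
round(res$metrics[, c("competition_ratio", "single_cell_ratio",
                      "total_invasion", "n_single_cells")], 4)
#>   competition_ratio single_cell_ratio total_invasion n_single_cells
#> 1            0.3007            0.0509         0.3516             12
scene$truth$competition_realized   # pixel-exact generator truth: 0.3000
scene$truth$single_cell_realized   #                              0.0502
```

The recovered ratios differ from the rendered truth by less than 0.001:
the fitted brain ellipse (residual ≈ 0.5 px) and the Otsu tumor mask
reproduce the generator's compartments almost pixel for pixel.

Track analysis on a simulated corpus of 40 cells at a true mean speed of
23.8 µm/h (a fast-invading GB model):

```r
sim <- simulate_walks(walk_spec(speed_true = 23.8, seed = 1), 40)
sp  <- window_speeds_all(sim$tracks)
nrow(sp); mean(sp$speed_um_per_h); sd(sp$speed_um_per_h)
#> 120 windows, mean 23.72 um/h, sd 1.24
```

Each row of `sp` is one cell in one 40-min window — the same unit as one
data point in a per-cell speed plot. `percent_inhibition(treated, control)`
expresses treatment effects the standard way:
`percent_inhibition(0.037, 0.100)` → `63`.

A shell entry point wrapping the same functions is installed at
`inst/cli/invasionquant` (subcommands `quantify`, `trackstats`, `simulate`,
`fixtures`).

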