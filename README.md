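# lilymorph

Quantitative description of three-dimensional water-lily (*Nymphaea*)
floral morphology through a 16-parameter theoretical morphological model —
for botanists, horticultural scientists, and morphometricians who need to
generate, compare, and measure whole-flower forms without landmark-based
homology.

Water-lily flowers have an indefinite number of floral organs arranged in a
spiral, with a gradual transition from outer tepals to inner stamens. The
model composes three rules:

1. **Organ sizes.** Every organ is an ellipse; its transverse (`x`) and
   longitudinal (`y`) semi-axes shrink piecewise-linearly with relative
   position `l_i = i/n`:
   `x_i = x_0 − s_x1·l_i` while `l_i ≤ t_x`, then `x_i = x_t − s_x2·l_i`
   (analogously for `y`). Identity switches from tepal to stamen at
   `N_t = round(n·max(t_x, t_y))`. All lengths are in units of the ovary
   radius `r_b`.
2. **Spiral phyllotaxis.** Azimuths step by 90° three times, then by the
   golden angle 137.5°; heights accumulate as `h_{i+1} = h_i + exp(p·φ_i)`.
3. **Elevation angles.** The four outermost tepals sit at `o_min`, the ramp
   reaches `o_max` at the innermost tepal, and stamens stand vertical (90°).

On top of the generator the package provides theoretical morphospace
sweeps, silhouette projection with the two convex-hull shape descriptors —
solidity `S = A_t/A_c` and convexity `C = L_c/L_t` — and the inverse
problem: estimating `(x_0, y_0, s_x1, s_y1)` from ordered organ
measurements (CSV tables or scanned organ-sheet images) by linear
regression, standardized by the ovary radius. Synthetic generators
(measurement tables, organ sheets, shape-class cohorts) make the whole
pipeline testable without specimen data.

## Worked example

```r
library(lilymorph)

params <- flower_params()          # reference flower: 100 organs
flower <- build_organ_sequence(params)
dplyr::count(flower, identity)
#>   identity     n
#> 1 stamen      80
#> 2 tepal       20

geom <- build_flower_geometry(params)
shape_indices(project_silhouette(geom, "top", resolution = 128))
#>   view    A_t   A_c   L_t   L_c     S     C
#> 1 top    89.2  102.  55.3  36.2 0.873 0.654
```

The reference flower has 20 tepals among its 100 organs. Its top-view
silhouette fills 87% of its convex hull (`S = 0.873`) but the hull
perimeter is only 65% of the silhouette's (`C = 0.654`): the notches
between the narrow tepals cost perimeter, not area.

Estimation inverts the generator. With 5% measurement noise on a synthetic
scan of the same flower:

```r
tab <- synth_measurement_table(params, noise_model(0.05, seed = 1))
fit <- estimate_params(tab, tepal_count = tepal_count(params))
tidy(fit)
#>   parameter estimate axis
#> 1 x_0          1.000 transverse
#> 2 y_0          3.53  longitudinal
#> 3 s_x1         0.709 transverse
#> 4 s_y1         1.48  longitudinal
```

The generating values were `x_0 = 1.00`, `y_0 = 3.50`, `s_x1 = 0.80`,
`s_y1 = 1.40`; the initial lengths are recovered tightly and the
shortening rates within the sampling error of a 20-organ fit.

Morphospace sweeps map the shape indices over two-parameter grids:

```r
res <- sweep_morphospace(sweep_config(preset = "shortening"),
                         views = "top", resolution = 128)
plot_morphospace(res, "solidity", "top")
```

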