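---
title: "The lilymorph model: theory, estimation, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lilymorph model: theory, estimation, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(lilymorph)
```

## The model

Water-lily (*Nymphaea*) flowers combine three structural regularities that
make them tractable for a parametric theoretical model: an indefinite number
of floral organs arranged in a spiral, a gradual transition in organ size
and identity from outer tepals to inner stamens, and an opening state
describable by organ elevation angles. `lilymorph` composes these three
rules into a generative model of the whole flower, then provides the
analysis tools that make the model useful: theoretical morphospace sweeps,
silhouette shape descriptors, and parameter estimation from measured organ
sequences.

### Organ sizes

Each organ is an ellipse with transverse semi-axis $x$ and longitudinal
semi-axis $y$, in units of the ovary radius $r_b$. Along the sequence
$i = 0, \dots, n-1$ (outermost first), with relative position $l_i = i/n$,
both semi-axes follow piecewise-linear gradients:

$$
x_i = \begin{cases} x_0 - s_{x1} l_i & l_i \le t_x \\
x_t - s_{x2} l_i & l_i > t_x \end{cases}
\qquad
y_i = \begin{cases} y_0 - s_{y1} l_i & l_i \le t_y \\
y_t - s_{y2} l_i & l_i > t_y \end{cases}
$$

The first piece describes tepals, the second stamens; $t_x, t_y \in [0,1]$
are the transition thresholds and $s$ the "shortening rates". The two axes
may switch at different organs; organ *identity* follows the later switch,
so the tepal count is $N_t = \mathrm{round}(n \cdot \max(t_x, t_y))$.
Negative sizes (possible for large $s$) are clamped to zero: the organ
vanishes physically but keeps its slot in the sequence. The second piece is
applied exactly as parameterized, with no continuity correction at the
joint, because $x_t$ and $y_t$ are free parameters of the model.

### Spiral phyllotaxis

Azimuths start at $\varphi_0 = 0$ and advance by $90°$ for the first three
steps — placing the four outer tepals in a cross — and by the golden angle
$137.5°$ thereafter. Azimuths accumulate without wrapping. Heights follow
$h_0 = 0$, $h_{i+1} = h_i + e^{p \varphi_i}$: with the default pitch
$p = -0.01$ the gaps shrink rapidly, packing inner organs near a common
height. The unit of $\varphi$ inside the exponent is not fixed by the
model's printed form; `lilymorph` uses degrees by default (`phi_unit`
option), which with $p = -0.01$ yields a compact flower whose first few
organs are vertically separated and whose inner organs plateau — the
behavior the reference renders show. Radians would require a pitch two
orders of magnitude larger for the same morphology. The exponent is capped
at 50 to guard against overflow when exploring large positive pitches.

### Elevation angles

The four outermost tepals take the minimum elevation $o_{\min}$; from the
fifth tepal the elevation increases linearly by
$(o_{\max} - o_{\min})/(N_t - 4)$ per organ so the innermost tepal reaches
$o_{\max}$ exactly; all stamens stand vertical ($90°$). An elevation of
$0°$ is a flat, fully open organ; $90°$ is closed against the floral axis.
The printed form of the increment divides by "$t_{\max} - 4$" with
$t_{\max}$ a fraction in $[0,1]$; subtracting 4 from a fraction is
dimensionally inconsistent, so the denominator is read in organ-count units
($N_t - 4$), which reproduces the stated endpoint behavior. With four or
fewer tepals every tepal takes $o_{\min}$. The ramp's endpoint is the last
tepal (index $N_t - 1$).

### Geometric assembly

Organs are rigid planar ellipses attached to the lateral surface of the
ovary cylinder (radius $r_b$, height $h_b$). The attachment point of an
organ at azimuth $\varphi$ and height $h$ is
$A = (r_b\cos\varphi, r_b\sin\varphi, h)$; the ellipse plane is spanned by
the horizontal tangent and the tilt direction
$\hat d = \cos(o)\,\hat r + \sin(o)\,\hat z$. By default the ellipse touches
the ovary at one end of its longitudinal axis (center at $A + y\,\hat d$),
matching how organs visibly detach from the ovary; `anchor = "center"` is
available for sensitivity checks. Organs are not bent, clipped, or
textured — tip acuteness, waviness, and curling are outside the model.

## Silhouettes and shape indices

Flowers are compared through orthographic silhouettes: the top view projects
onto the X–Y plane, the side view onto Y–Z. The silhouette is the union of
all projected, filled organ ellipses plus the ovary disc (top) or rectangle
(side); no hidden-surface removal is applied. Rasterization uses an exact
point-in-ellipse test per pixel at a default of 256 px per ovary radius
(128 px in large sweeps).

A planar ellipse can project to a segment (a vertical organ seen from
above, or an organ edge-on in the side view). Such degenerate projections
are drawn as ribbons of fixed width $0.02\,r_b$ — a stand-in for the
physical thickness of a real organ — floored at 1.5 px so they rasterize
without gaps. A fixed *world* width (rather than a pixel width) keeps the
silhouette geometry resolution-independent, which matters when comparing
index surfaces computed at different resolutions.

Two dimensionless descriptors summarize a silhouette's global shape, both
computed on the largest connected foreground component:

* **solidity** $S = A_t / A_c$: silhouette area over convex-hull area —
  how fully the flower fills its outline;
* **convexity** $C = L_c / L_t$: hull perimeter over silhouette perimeter —
  sensitive to the depth and frequency of notches between organs.

Numerically, the outer contour is extracted by border following and
simplified with a Douglas–Peucker pass (1 px tolerance) before measuring
$L_t$: the raw 8-connected chain length overestimates oblique straight
edges by up to ~8%, and the simplification brings circle, square, and star
test shapes within 2% of their closed-form perimeters at 256 px/radius.
$A_t$ counts foreground pixels; the hull for $A_c$ is taken over the
contour pixels' corners, which guarantees $S \le 1$, and the hull for $L_c$
over the simplified contour, which guarantees $C \le 1$.

## Morphospaces

`sweep_config()` presets reproduce the four canonical two-parameter
morphospaces: openness ($o_{\max} \times o_{\min}$, $0$–$90°$), transition
thresholds ($t_x \times t_y$, $0$–$1$), tepal shortening rates
($s_{x1}$ $0$–$1$ step $0.04$ $\times$ $s_{y1}$ $0$–$3.5$ step $0.14$), and
initial lengths ($x_0, y_0$ $0.5$–$9$ step $0.5$). Grids are inclusive of
both endpoints; the openness and threshold presets, whose step sizes are
not part of the model's parameter table, default to 7 and 6 values per
axis. All other parameters stay at the reference values ($t_x = t_y = 0.2$,
elevations $45°$) except where swept. Cells are independent and evaluated
deterministically, so repeated sweeps are bit-identical.

The shortening-rate morphospace at 128 px/radius (both views, 676 cells)
takes about five minutes on one CPU; this is the problem size used by the
package's own end-to-end tests. The qualitative structure of the index
surfaces — top-view solidity falling with both shortening rates, side-view
solidity nearly independent of $s_{x1}$, minimum convexity at the
$(s_{x1}, s_{y1}) = (1, 0)$ corner — is stable between 128 and 256
px/radius once the fixed-width ribbon rule above is in place.

## Measurement and estimation

The measurement arm mirrors a flatbed-scanner workflow: detached organs on
a dark background, binarized with a global Otsu threshold (a fixed
threshold is available), connected components above a minimum area
(default 100 px²) taken as organs, and each component summarized by its
equivalent ellipse from second-order image moments (full axis =
$4\sqrt{\lambda}$, with a $1/12$ term because pixels are unit squares, not
point masses). Components are ordered row-major by centroid — rows split
where the centroid-row gap exceeds half the median component height — and
the scale (mm/px) must be supplied explicitly. The ovary radius is measured
externally and supplied per flower.

Estimation inverts the tepal-phase size model by ordinary least squares on
the ordered sequence. With lengths standardized by the ovary radius and
$l_i = i/n$, regressing standardized *semi-axes* on $l_i$ gives the initial
semi-axis as the intercept and the shortening rate as the negated slope —
the exact inverse of the generative model, so noiseless synthetic data are
recovered to machine precision. The alternative
`convention = "full_length"` reproduces the halved-intercept form used in
some scan-based protocols ($x_0 = b_x/2$, $s_{x1} = |a_x|$ from a
full-length regression, the slope left unhalved); on synthetic data that
convention doubles the shortening rates — the two formulas are mutually
inconsistent if both come from one regression — which is why the
self-consistent convention is the default. Whether
stamens enter the fit is controlled by `tepal_count` (fit tepals only when
known; all organs otherwise), and `n_used` is recorded.

## Synthetic data

The fixture generators exist so the whole pipeline can be exercised with no
external data:

* `synth_measurement_table()` emits full lengths
  $2\,x_i\,r_b\,(1+\varepsilon_i)$ with multiplicative Gaussian noise
  $\varepsilon_i \sim N(0, \sigma_{rel})$ — measurement error is assumed to
  scale with organ size, since no empirical error model is available.
  Default $\sigma_{rel}$ in tests is 5%, a plausible figure for manual
  scan-based measurement.
* `synth_organ_sheet()` draws the table as filled ellipses on a grid,
  pairing every image with its ground truth.
* `synth_cohort()` draws per-flower parameters from per-class independent
  Gaussians truncated at zero, seeded with the published class-wise means
  and standard deviations of a 100-specimen horticultural cohort (20
  stellate, 34 cup-like, 8 other, 38 unknown flowers). Real parameters are
  correlated (all pairwise correlations below 0.8); the independence
  assumption is a simplification, so cohort-level tests check means, not
  joint structure. Flowers keep all non-drawn parameters at the reference
  values ($n = 100$, $t = 0.2$, hence 20 tepals per flower).

All randomness flows from explicit seeds; identical seeds give identical
outputs.

What the synthetic data do *not* emulate: scan artifacts (shadows, torn or
touching organs, specular highlights), correlated parameter draws, the real
error structure of hand-arranged organ sequences, and any developmental
mechanism behind the size gradients. Passing round-trip tests therefore
demonstrate the correctness of the estimators under the model's own
assumptions, not their robustness to real scan pathology.

## Worked example

```{r example}
params <- flower_params()
flower <- build_organ_sequence(params)
dplyr::count(flower, identity)

geom <- build_flower_geometry(params)
shape_indices(project_silhouette(geom, "top", resolution = 64))
```

```{r plot, fig.height = 4}
autoplot(geom, view = "top")
```

```{r estimation}
tab <- synth_measurement_table(params, noise_model(0.05, seed = 1))
fit <- estimate_params(tab, tepal_count = tepal_count(params))
tidy(fit)
```

## Known limitations

* Organs are rigid planar ellipses: no curvature, thickness, or tip shape,
  so taxa with strongly textured tepals are outside the model's reach.
* Elevation angles are static; diurnal opening and closing is not modeled.
* The silhouette indices are computed on rasters; below ~64 px per ovary
  radius the discretization error in convexity becomes comparable to
  between-cell differences in flat regions of a morphospace.
* The estimation arm recovers only the four tepal-phase parameters; the
  stamen-phase slopes and offsets, the pitch, and the elevation angles are
  not identifiable from an organ-size sequence alone.
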