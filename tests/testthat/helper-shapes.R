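# Shared fixtures: analytic test shapes and convenience parameter sets.

# Five-pointed star with given outer radius and inner/outer ratio, plus its
# closed-form area/perimeter and those of its convex hull (the outer
# pentagon).
star_fixture <- function(outer = 1, ratio = 0.5) {
  angles <- pi / 2 + (0:9) * pi / 5
  r <- rep(c(outer, outer * ratio), 5)
  x <- r * cos(angles)
  y <- r * sin(angles)
  shoelace <- function(px, py) {
    abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  }
  perim <- function(px, py) {
    sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
  }
  hx <- x[c(TRUE, FALSE)]
  hy <- y[c(TRUE, FALSE)]
  list(x = x, y = y,
       area = shoelace(x, y), perimeter = perim(x, y),
       hull_area = shoelace(hx, hy), hull_perimeter = perim(hx, hy))
}

circle_polygon <- function(r = 1, n = 720) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = r * cos(theta), y = r * sin(theta))
}

# A small all-tepal flower whose size gradient is linear over the whole
# sequence: convenient for estimator tests.
all_tepal_params <- function(n = 20, ...) {
  update_params(flower_params(), n = n, t_x = 1, t_y = 1, ...)
}
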