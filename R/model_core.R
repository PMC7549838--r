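#' Number of tepals implied by the transition thresholds
#'
#' Identity switches from tepal to stamen at the later of the two transition
#' thresholds, so the tepal count is `round(n * max(t_x, t_y))` (half-up
#' rounding). `t = 1` makes every organ a tepal; `t = 0` makes every organ a
#' stamen.
#'
#' @param params A [flower_params()] object.
#' @return Integer tepal count in `[0, n]`.
#' @examples
#' tepal_count(flower_params()) # 20
#' @export
tepal_count <- function(params) {
  stopifnot(inherits(params, "flower_params"))
  t_max <- max(params$t_x, params$t_y)
  as.integer(floor(params$n * t_max + 0.5))
}

#' Classify organs as tepals or stamens
#'
#' @param i Organ index (0-based, vectorized), `0 <= i < n`.
#' @param params A [flower_params()] object.
#' @return Character vector of `"tepal"` / `"stamen"`.
#' @examples
#' classify_identity(0:99, flower_params()) |> table()
#' @export
classify_identity <- function(i, params) {
  stopifnot(inherits(params, "flower_params"))
  if (any(i < 0 | i >= params$n | i != round(i))) {
    stop("organ index out of range [0, n)", call. = FALSE)
  }
  ifelse(i < tepal_count(params), "tepal", "stamen")
}

#' Organ semi-axis lengths along the sequence
#'
#' The transverse (`x`) and longitudinal (`y`) semi-axes shrink as two
#' piecewise-linear functions of the relative position `l_i = i / n`:
#' `x_i = x_0 - s_x1 * l_i` while `l_i <= t_x`, then `x_i = x_t - s_x2 * l_i`
#' (and analogously for `y`). Negative values are clamped to zero — the organ
#' vanishes. Lengths are in ovary-radius units.
#'
#' @param params A [flower_params()] object.
#' @return A tibble with columns `index`, `l`, `x`, `y` (one row per organ,
#'   outermost first).
#' @examples
#' organ_sizes(flower_params())
#' @export
organ_sizes <- function(params) {
  stopifnot(inherits(params, "flower_params"))
  i <- seq_len(params$n) - 1L
  l <- i / params$n
  x <- ifelse(l <= params$t_x,
              params$x_0 - params$s_x1 * l,
              params$x_t - params$s_x2 * l)
  y <- ifelse(l <= params$t_y,
              params$y_0 - params$s_y1 * l,
              params$y_t - params$s_y2 * l)
  tibble::tibble(index = i, l = l, x = pmax(x, 0), y = pmax(y, 0))
}

#' Cumulative azimuths of the spiral phyllotaxis
#'
#' Starting from `phi_0 = 0`, the azimuth advances by 90 degrees for the first
#' three steps (placing the four outer tepals in a whorl-like cross) and by
#' the golden angle, 137.5 degrees, thereafter. The sequence is cumulative and
#' not wrapped modulo 360.
#'
#' @param params A [flower_params()] object.
#' @return Numeric vector of `n` azimuths in degrees.
#' @examples
#' azimuth_sequence(flower_params())[1:6] # 0, 90, 180, 270, 407.5, 545
#' @export
azimuth_sequence <- function(params) {
  stopifnot(inherits(params, "flower_params"))
  n <- params$n
  if (n == 1L) return(0)
  dphi <- c(rep(90, min(3L, n - 1L)), rep(137.5, max(0L, n - 4L)))
  cumsum(c(0, dphi))
}

#' Organ heights along the ovary
#'
#' Heights follow `h_0 = 0`, `h_{i+1} = h_i + exp(p * phi_i)`: with a negative
#' pitch `p` the gap between consecutive organs shrinks as the spiral winds
#' up, packing inner organs tightly. The azimuth enters the exponent in the
#' unit selected by `params$phi_unit` (degrees by default); the exponent is
#' capped at 50 to guard against overflow for extreme positive pitches.
#'
#' @param params A [flower_params()] object.
#' @param azimuths Cumulative azimuths in degrees; defaults to
#'   [azimuth_sequence()] of `params`.
#' @return Numeric non-decreasing vector of `n` heights (ovary-radius units).
#' @examples
#' height_sequence(flower_params())[1:3] # 0, 1, 1 + exp(-0.9)
#' @export
height_sequence <- function(params, azimuths = azimuth_sequence(params)) {
  stopifnot(inherits(params, "flower_params"), length(azimuths) == params$n)
  phi <- if (identical(params$phi_unit, "radians")) azimuths * pi / 180 else azimuths
  increments <- exp(pmin(params$p * phi, 50))
  cumsum(c(0, increments[-params$n]))
}

#' Organ elevation angles
#'
#' The four outermost tepals sit at the minimum elevation `o_min`; from the
#' fifth tepal the elevation climbs linearly so that the innermost tepal
#' reaches `o_max`; all stamens stand vertical at 90 degrees (parallel to the
#' apical-basal axis). With four or fewer tepals every tepal takes `o_min`.
#' An elevation of 0 means the organ lies flat; 90 means closed against the
#' axis.
#'
#' @param params A [flower_params()] object.
#' @return Numeric vector of `n` elevation angles in degrees.
#' @examples
#' elevation_sequence(flower_params(o_min = 0, o_max = 40, n = 10, t_x = 0.8, t_y = 0.8))
#' @export
elevation_sequence <- function(params) {
  stopifnot(inherits(params, "flower_params"))
  n <- params$n
  n_t <- tepal_count(params)
  o <- rep(90, n)
  if (n_t > 0) {
    n_flat <- min(4L, n_t)
    o[seq_len(n_flat)] <- params$o_min
    if (n_t > 4L) {
      step <- (params$o_max - params$o_min) / (n_t - 4L)
      o[5:n_t] <- params$o_min + step * seq_len(n_t - 4L)
    }
  }
  o
}

#' Build the full ordered organ sequence
#'
#' Assembles sizes, identities, azimuths, heights, and elevation angles into
#' one table — the complete state of a theoretical flower before geometric
#' placement. The result is a pure function of the parameters.
#'
#' @param params A [flower_params()] object.
#' @return A tibble with one row per organ (outermost first) and columns
#'   `index` (0-based), `l` (relative position `i/n`), `x`, `y` (semi-axes,
#'   ovary-radius units), `phi_deg` (cumulative azimuth), `h` (height above
#'   the ovary base), `o_deg` (elevation angle), `identity`.
#' @examples
#' flower <- build_organ_sequence(flower_params())
#' dplyr::count(flower, identity)
#' @export
build_organ_sequence <- function(params) {
  stopifnot(inherits(params, "flower_params"))
  sizes <- organ_sizes(params)
  tibble::tibble(
    index = sizes$index,
    l = sizes$l,
    x = sizes$x,
    y = sizes$y,
    phi_deg = azimuth_sequence(params),
    h = height_sequence(params),
    o_deg = elevation_sequence(params),
    identity = classify_identity(sizes$index, params)
  )
}

#' Write an organ sequence to CSV
#'
#' @param organs A tibble from [build_organ_sequence()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_organ_sequence <- function(organs, path) {
  utils::write.csv(organs, path, row.names = FALSE)
  invisible(path)
}
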