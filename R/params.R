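#' Construct a flower parameter set
#'
#' The theoretical morphological model describes one water-lily flower with 16
#' parameters: the number of floral organs, the piecewise-linear size gradient
#' of their transverse and longitudinal semi-axes, the pitch of the spiral
#' phyllotaxis, the range of tepal elevation angles, and the dimensions of the
#' ovary cylinder. All lengths are expressed in units of the ovary radius
#' `r_b`, which is 1 by convention; angles are in degrees.
#'
#' Defaults are the model's reference flower (100 organs, 20 of them tepals,
#' half-open at 45 degrees).
#'
#' @param n Total number of floral organs (positive integer).
#' @param s_x1,s_x2 Shortening rates of the transverse semi-axis in the tepal
#'   and stamen phase, respectively (ovary-radius units per unit relative
#'   position).
#' @param x_0 Initial (outermost organ) transverse semi-axis.
#' @param x_t Transverse semi-axis offset of the first organ past the
#'   transition threshold.
#' @param t_x Transition threshold on the transverse axis, a fraction of the
#'   organ sequence in `[0, 1]`.
#' @param s_y1,s_y2,y_0,y_t,t_y Longitudinal analogues of the five transverse
#'   parameters.
#' @param o_max,o_min Maximum and minimum tepal elevation angles in degrees,
#'   in `[0, 90]`. 0 is a flat (fully open) organ, 90 is vertical (closed).
#' @param p Pitch of the spiral phyllotaxis: the height gained between
#'   consecutive organs is `exp(p * phi)` with `phi` the cumulative azimuth.
#' @param r_b Ovary radius; the model's length unit (1 by convention).
#' @param h_b Ovary height, in ovary-radius units.
#' @param phi_unit Unit in which the cumulative azimuth enters the height
#'   rule, `"degrees"` (default) or `"radians"`.
#'
#' @return An object of class `flower_params`: a named list of the validated
#'   parameters.
#' @examples
#' params <- flower_params()
#' params$n
#' open_flower <- flower_params(o_max = 0, o_min = 0)
#' @export
flower_params <- function(n = 100,
                          s_x1 = 0.80, s_x2 = 0.02, x_0 = 1.00, x_t = 0.20,
                          t_x = 0.20,
                          s_y1 = 1.40, s_y2 = 0.28, y_0 = 3.50, y_t = 1.20,
                          t_y = 0.20,
                          o_max = 45, o_min = 45,
                          p = -0.01, r_b = 1.00, h_b = 0.50,
                          phi_unit = c("degrees", "radians")) {
  phi_unit <- match.arg(phi_unit)
  params <- list(
    n = n, s_x1 = s_x1, s_x2 = s_x2, x_0 = x_0, x_t = x_t, t_x = t_x,
    s_y1 = s_y1, s_y2 = s_y2, y_0 = y_0, y_t = y_t, t_y = t_y,
    o_max = o_max, o_min = o_min, p = p, r_b = r_b, h_b = h_b,
    phi_unit = phi_unit
  )
  validate_flower_params(params)
}

#' @rdname flower_params
#' @param x A list (or `flower_params`) of parameter values to validate.
#' @export
validate_flower_params <- function(x) {
  numeric_fields <- setdiff(names(flower_param_defaults()), "phi_unit")
  for (f in numeric_fields) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (x$n < 1 || x$n != round(x$n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  x$n <- as.integer(x$n)
  for (f in c("t_x", "t_y")) {
    if (x[[f]] < 0 || x[[f]] > 1) {
      stop("'", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  for (f in c("o_max", "o_min")) {
    if (x[[f]] < 0 || x[[f]] > 90) {
      stop("'", f, "' must lie in [0, 90] degrees", call. = FALSE)
    }
  }
  if (x$r_b <= 0) stop("'r_b' must be positive", call. = FALSE)
  if (x$h_b < 0) stop("'h_b' must be non-negative", call. = FALSE)
  if (is.null(x$phi_unit)) x$phi_unit <- "degrees"
  structure(x[names(flower_param_defaults())], class = "flower_params")
}

flower_param_defaults <- function() {
  list(
    n = 100L, s_x1 = 0.80, s_x2 = 0.02, x_0 = 1.00, x_t = 0.20, t_x = 0.20,
    s_y1 = 1.40, s_y2 = 0.28, y_0 = 3.50, y_t = 1.20, t_y = 0.20,
    o_max = 45, o_min = 45, p = -0.01, r_b = 1.00, h_b = 0.50,
    phi_unit = "degrees"
  )
}

#' @export
print.flower_params <- function(x, ...) {
  cat("<flower_params>\n")
  cat(sprintf("  organs: n = %d (%d tepals, %d stamens)\n",
              x$n, tepal_count(x), x$n - tepal_count(x)))
  cat(sprintf("  transverse:   x_0 = %.3g, s_x1 = %.3g | x_t = %.3g, s_x2 = %.3g, t_x = %.3g\n",
              x$x_0, x$s_x1, x$x_t, x$s_x2, x$t_x))
  cat(sprintf("  longitudinal: y_0 = %.3g, s_y1 = %.3g | y_t = %.3g, s_y2 = %.3g, t_y = %.3g\n",
              x$y_0, x$s_y1, x$y_t, x$s_y2, x$t_y))
  cat(sprintf("  elevation: o_min = %g, o_max = %g degrees\n", x$o_min, x$o_max))
  cat(sprintf("  phyllotaxis pitch p = %g (%s); ovary r_b = %g, h_b = %g\n",
              x$p, x$phi_unit, x$r_b, x$h_b))
  invisible(x)
}

#' Update selected parameters of a flower parameter set
#'
#' @param params A `flower_params` object.
#' @param ... Named parameter values to override.
#' @return A validated `flower_params` object.
#' @examples
#' closed <- update_params(flower_params(), o_min = 90, o_max = 90)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "flower_params"))
  changes <- list(...)
  bad <- setdiff(names(changes), names(flower_param_defaults()))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params[names(changes)] <- changes
  validate_flower_params(unclass(params))
}

#' Read or write a flower parameter file
#'
#' Parameter sets are serialized as a flat JSON or YAML mapping using the
#' model's symbol names (`n`, `s_x1`, ..., `h_b`). The packaged file
#' `system.file("extdata", "default_params.json", package = "lilymorph")`
#' holds the reference defaults.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_params()` returns a `flower_params` object;
#'   `write_params()` invisibly returns `path`.
#' @examples
#' p <- read_params(system.file("extdata", "default_params.json",
#'                              package = "lilymorph"))
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- flower_param_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    stop("unknown parameter(s) in file: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(raw)] <- raw
  validate_flower_params(defaults)
}

#' @rdname read_params
#' @param params A `flower_params` object to serialize.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "flower_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
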