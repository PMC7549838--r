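#' Measurement noise model
#'
#' Multiplicative Gaussian noise on organ lengths: a measured length is the
#' true length times `1 + e` with `e ~ N(0, sigma_rel)`. Measurement error is
#' assumed to scale with organ size.
#'
#' @param sigma_rel Relative standard deviation (>= 0).
#' @param seed Optional integer RNG seed; when set, generators using this
#'   model are reproducible call-to-call.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(0.05, seed = 1)
#' @export
noise_model <- function(sigma_rel = 0, seed = NULL) {
  stopifnot(is.numeric(sigma_rel), sigma_rel >= 0)
  structure(list(sigma_rel = sigma_rel, seed = seed), class = "noise_model")
}

with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  expr
}

#' Generate a synthetic measurement table from the model
#'
#' Produces the measurement table a perfect scan of a theoretical flower
#' would yield: organ full lengths are twice the model semi-axes times the
#' ovary radius, ordered from the outermost organ inward, with optional
#' multiplicative Gaussian noise.
#'
#' @param params A [flower_params()] object.
#' @param noise A [noise_model()].
#' @param r_b_mm Ovary radius in mm (scales the dimensionless model lengths
#'   to physical units).
#' @param flower_id,shape_class Metadata columns.
#' @return A measurement-table tibble with columns `flower_id`,
#'   `shape_class`, `r_b_mm`, `organ_index`, `transverse_mm`,
#'   `longitudinal_mm`, `identity`.
#' @examples
#' synth_measurement_table(flower_params(), noise_model(0.05, seed = 7))
#' @export
synth_measurement_table <- function(params, noise = noise_model(0),
                                    r_b_mm = 10,
                                    flower_id = "synthetic-1",
                                    shape_class = "unknown") {
  stopifnot(inherits(params, "flower_params"), inherits(noise, "noise_model"),
            r_b_mm > 0)
  organs <- build_organ_sequence(params)
  with_noise_seed(noise, {
    eps_t <- stats::rnorm(nrow(organs), 0, noise$sigma_rel)
    eps_l <- stats::rnorm(nrow(organs), 0, noise$sigma_rel)
    tibble::tibble(
      flower_id = flower_id,
      shape_class = shape_class,
      r_b_mm = r_b_mm,
      organ_index = organs$index,
      transverse_mm = 2 * organs$x * r_b_mm * (1 + eps_t),
      longitudinal_mm = 2 * organs$y * r_b_mm * (1 + eps_l),
      identity = organs$identity
    )
  })
}

#' Draw a synthetic organ sheet image
#'
#' Renders the organs of a measurement table as filled white ellipses on a
#' black background, laid out row-major in table order on a regular grid —
#' a synthetic stand-in for a flatbed scan of detached organs, paired with
#' its ground truth. Organs are drawn with the longitudinal axis vertical.
#'
#' @param table A measurement table (needs `organ_index`, `transverse_mm`,
#'   `longitudinal_mm`).
#' @param scale mm per pixel.
#' @param layout `c(rows, cols)` grid; default is a near-square grid.
#' @param padding_px Blank border around each grid cell (>= 2).
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth` (the
#'   input table rows actually drawn, with pixel-center columns added).
#'   Zero-length organs are skipped with a warning.
#' @examples
#' tab <- synth_measurement_table(flower_params(n = 10, t_x = 1, t_y = 1))
#' sheet <- synth_organ_sheet(tab, scale = 0.1)
#' dim(sheet$image)
#' @export
synth_organ_sheet <- function(table, scale, layout = NULL, padding_px = 10) {
  stopifnot(scale > 0, padding_px >= 2)
  table <- table[order(table$organ_index), ]
  drawable <- table$transverse_mm > 0 & table$longitudinal_mm > 0
  if (any(!drawable)) {
    warning(sum(!drawable), " zero-length organ(s) skipped")
    table <- table[drawable, ]
  }
  n <- nrow(table)
  if (!n) stop("no drawable organs", call. = FALSE)
  if (is.null(layout)) {
    cols <- ceiling(sqrt(n))
    layout <- c(ceiling(n / cols), cols)
  }
  if (prod(layout) < n) {
    suggested <- ceiling(sqrt(n))
    stop(sprintf("layout %dx%d cannot hold %d organs; try c(%d, %d)",
                 layout[1], layout[2], n, ceiling(n / suggested), suggested),
         call. = FALSE)
  }
  semi_minor_px <- table$transverse_mm / 2 / scale
  semi_major_px <- table$longitudinal_mm / 2 / scale
  cell_w <- ceiling(2 * max(semi_minor_px)) + 2 * padding_px
  cell_h <- ceiling(2 * max(semi_major_px)) + 2 * padding_px
  img <- matrix(0, nrow = cell_h * layout[1], ncol = cell_w * layout[2])
  centers <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    gr <- (k - 1) %/% layout[2]
    gc <- (k - 1) %% layout[2]
    cr <- gr * cell_h + cell_h / 2
    cc <- gc * cell_w + cell_w / 2
    rr <- seq_len(cell_h) + gr * cell_h
    rc <- seq_len(cell_w) + gc * cell_w
    dy <- (rr - cr) / semi_major_px[k]
    dx <- (rc - cc) / semi_minor_px[k]
    cell <- outer(dy^2, dx^2, "+") <= 1
    img[rr, rc][cell] <- 1
    centers[k, ] <- c(cr, cc)
  }
  truth <- table
  truth$center_row <- centers[, 1]
  truth$center_col <- centers[, 2]
  list(image = img, truth = truth)
}

#' Shape-class cohort specification
#'
#' Describes per-class distributions of the four measurable parameters
#' (`x_0`, `y_0`, `s_x1`, `s_y1`), modeled as independent Gaussians truncated
#' at zero. The defaults are the published class-wise means and standard
#' deviations of a 100-specimen horticultural cohort (stellate, cup-like,
#' other, unknown); all other model parameters stay at their reference
#' values.
#'
#' @param classes A tibble with columns `shape_class`, `n_flowers`, and
#'   `mean_`/`sd_` columns for the four parameters; defaults to the built-in
#'   class table.
#' @param organs_per_flower Organs per generated flower.
#' @param noise A [noise_model()] applied to every measured length.
#' @param r_b_mm Ovary radius in mm given to each flower.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec()
#' @export
cohort_spec <- function(classes = default_cohort_classes(),
                        organs_per_flower = 100,
                        noise = noise_model(0),
                        r_b_mm = 10) {
  needed <- c("shape_class", "n_flowers",
              paste0("mean_", c("s_y1", "s_x1", "y_0", "x_0")),
              paste0("sd_", c("s_y1", "s_x1", "y_0", "x_0")))
  stopifnot(all(needed %in% names(classes)),
            all(classes$n_flowers >= 1),
            all(classes[paste0("mean_", c("s_y1", "s_x1", "y_0", "x_0"))] > 0),
            organs_per_flower >= 1)
  structure(list(classes = classes,
                 organs_per_flower = as.integer(organs_per_flower),
                 noise = noise, r_b_mm = r_b_mm),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_classes <- function() {
  tibble::tribble(
    ~shape_class, ~n_flowers, ~mean_s_y1, ~mean_s_x1, ~mean_y_0, ~mean_x_0,
    ~sd_s_y1, ~sd_s_x1, ~sd_y_0, ~sd_x_0,
    "stellate", 20L, 0.919, 0.328, 3.714, 0.986, 0.286, 0.140, 0.531, 0.166,
    "cup-like", 34L, 0.780, 0.430, 3.080, 0.962, 0.236, 0.130, 0.469, 0.151,
    "other",     8L, 0.508, 0.241, 3.194, 0.835, 0.074, 0.081, 0.399, 0.084,
    "unknown",  38L, 0.656, 0.255, 3.110, 0.877, 0.265, 0.111, 0.539, 0.146
  )
}

#' Generate a synthetic cohort of measured flowers
#'
#' For every flower, draws (`x_0`, `y_0`, `s_x1`, `s_y1`) from its class's
#' truncated Gaussian, builds the flower with all other parameters at their
#' reference values, and emits a (possibly noisy) measurement table.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed governing all randomness (parameter draws and
#'   measurement noise).
#' @return A tibble with one row per flower: `flower_id`, `shape_class`, the
#'   true generating parameters (`true_s_y1`, `true_s_x1`, `true_y_0`,
#'   `true_x_0`), `tepal_count`, and a list-column `table` of measurement
#'   tables.
#' @examples
#' small <- cohort_spec(organs_per_flower = 25)
#' small$classes$n_flowers <- c(2L, 2L, 1L, 1L)
#' synth_cohort(small, seed = 1)
#' @export
synth_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- update_params(flower_params(), n = spec$organs_per_flower)
  set.seed(seed)
  rows <- purrr::pmap(spec$classes, function(shape_class, n_flowers, ...) {
    cl <- list(...)
    purrr::map(seq_len(n_flowers), function(j) {
      draw <- function(p) {
        v <- stats::rnorm(1, cl[[paste0("mean_", p)]], cl[[paste0("sd_", p)]])
        while (v <= 0) v <- stats::rnorm(1, cl[[paste0("mean_", p)]],
                                         cl[[paste0("sd_", p)]])
        v
      }
      truth <- c(s_y1 = draw("s_y1"), s_x1 = draw("s_x1"),
                 y_0 = draw("y_0"), x_0 = draw("x_0"))
      params <- update_params(base, s_y1 = truth[["s_y1"]],
                              s_x1 = truth[["s_x1"]],
                              y_0 = truth[["y_0"]], x_0 = truth[["x_0"]])
      id <- sprintf("%s-%02d", shape_class, j)
      noise <- noise_model(spec$noise$sigma_rel)  # seedless: one RNG stream
      tab <- synth_measurement_table(params, noise, r_b_mm = spec$r_b_mm,
                                     flower_id = id,
                                     shape_class = shape_class)
      tibble::tibble(
        flower_id = id, shape_class = shape_class,
        true_s_y1 = truth[["s_y1"]], true_s_x1 = truth[["s_x1"]],
        true_y_0 = truth[["y_0"]], true_x_0 = truth[["x_0"]],
        tepal_count = tepal_count(params),
        table = list(tab)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Estimate parameters for every flower of a cohort
#'
#' Convenience wrapper running [estimate_params()] on each table of a
#' [synth_cohort()] result (fitting the tepal range) and returning one row
#' per flower, ready for [summarize_measurements()].
#'
#' @param cohort A [synth_cohort()] tibble.
#' @param ... Passed to [estimate_params()].
#' @return A tibble with `flower_id`, `shape_class`, and estimated `s_y1`,
#'   `s_x1`, `y_0`, `x_0`.
#' @examples
#' small <- cohort_spec(organs_per_flower = 25)
#' small$classes$n_flowers <- c(2L, 2L, 1L, 1L)
#' estimate_cohort(synth_cohort(small, seed = 1))
#' @export
estimate_cohort <- function(cohort, ...) {
  purrr::pmap_dfr(
    list(cohort$flower_id, cohort$shape_class, cohort$tepal_count,
         cohort$table),
    function(id, cls, n_t, tab) {
      fit <- estimate_params(tab, tepal_count = n_t, ...)
      dplyr::bind_cols(tibble::tibble(flower_id = id, shape_class = cls),
                       fit$estimates[, c("s_y1", "s_x1", "y_0", "x_0")])
    }
  )
}
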