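#' Measure a scanned organ sheet
#'
#' Measures ordered floral organs from a scan of detached organs laid out on
#' a dark background. The image is binarized with a global threshold (Otsu by
#' default), connected components above a minimum area are taken as organs,
#' and each component's equivalent ellipse is computed from its second-order
#' image moments: the full major-axis length is taken as the longitudinal
#' organ length and the full minor axis as the transverse length. Components
#' are ordered row-major by centroid (reading order: left to right within
#' rows, rows top to bottom), matching the convention that organs are laid
#' out in detachment order from the outermost.
#'
#' @param image A numeric matrix in `[0, 1]` (rows = image rows from the top)
#'   or path to a PNG file; RGB images are averaged to grayscale.
#' @param scale Calibration in mm per pixel.
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param threshold_value Gray level in `(0, 1)` used when
#'   `threshold = "fixed"`.
#' @param min_area Minimum component area in pixels; smaller specks are
#'   discarded.
#' @param flower_id,shape_class,r_b_mm Metadata copied into the table;
#'   `r_b_mm` is the externally measured ovary radius in mm (the scan itself
#'   does not contain the ovary).
#' @return A measurement table: a tibble with columns `flower_id`,
#'   `shape_class`, `r_b_mm`, `organ_index` (0-based, reading order),
#'   `transverse_mm`, `longitudinal_mm`, plus diagnostic columns
#'   `centroid_row`, `centroid_col`, `area_px`, `touches_border`.
#' @examples
#' tab <- synth_measurement_table(flower_params(n = 10, t_x = 1, t_y = 1))
#' sheet <- synth_organ_sheet(tab, scale = 0.1)
#' measure_organ_sheet(sheet$image, scale = 0.1)
#' @export
measure_organ_sheet <- function(image, scale,
                                threshold = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_area = 100,
                                flower_id = "sheet-1",
                                shape_class = "unknown",
                                r_b_mm = NA_real_) {
  threshold <- match.arg(threshold)
  stopifnot(is.numeric(scale), scale > 0)
  if (is.character(image)) {
    image <- png::readPNG(image)
  }
  if (length(dim(image)) == 3L) {
    image <- apply(image[, , 1:3, drop = FALSE], c(1, 2), mean)
  }
  thr <- if (threshold == "otsu") {
    EBImage::otsu(EBImage::Image(image))
  } else {
    if (is.null(threshold_value)) {
      stop("threshold_value required for fixed thresholding", call. = FALSE)
    }
    threshold_value
  }
  mask <- image > thr
  lab <- EBImage::bwlabel(mask * 1)
  counts <- tabulate(lab)
  keep <- which(counts >= min_area)
  if (!length(keep)) stop("no organs detected", call. = FALSE)
  feats <- purrr::map_dfr(keep, function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    moments_ellipse(px, nrow(image), ncol(image))
  })
  feats <- order_reading(feats)
  tibble::tibble(
    flower_id = flower_id,
    shape_class = shape_class,
    r_b_mm = r_b_mm,
    organ_index = seq_len(nrow(feats)) - 1L,
    transverse_mm = feats$minor_px * scale,
    longitudinal_mm = feats$major_px * scale,
    centroid_row = feats$centroid_row,
    centroid_col = feats$centroid_col,
    area_px = feats$area_px,
    touches_border = feats$touches_border
  )
}

# Equivalent-ellipse axes from second-order central moments of a pixel set:
# full axis lengths are 4 * sqrt(eigenvalues of the covariance matrix).
moments_ellipse <- function(px, img_nrow, img_ncol) {
  r <- px[, 1]; c <- px[, 2]
  mr <- mean(r); mc <- mean(c)
  # + 1/12: each pixel is a unit square, not a point mass
  vrr <- mean((r - mr)^2) + 1 / 12
  vcc <- mean((c - mc)^2) + 1 / 12
  vrc <- mean((r - mr) * (c - mc))
  tr <- vrr + vcc
  det <- vrr * vcc - vrc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  lambda <- c(tr / 2 + disc, tr / 2 - disc)
  tibble::tibble(
    centroid_row = mr, centroid_col = mc, area_px = nrow(px),
    major_px = 4 * sqrt(lambda[1]), minor_px = 4 * sqrt(max(lambda[2], 0)),
    touches_border = any(r == 1L | r == img_nrow | c == 1L | c == img_ncol)
  )
}

# Reading order: cluster centroids into rows (gap > half the median component
# height starts a new row), then left-to-right within each row.
order_reading <- function(feats) {
  ord <- order(feats$centroid_row)
  feats <- feats[ord, ]
  heights <- sqrt(feats$area_px)
  gap <- diff(feats$centroid_row) > stats::median(heights) / 2
  row_id <- cumsum(c(0, gap))
  feats[order(row_id, feats$centroid_col), ]
}

#' Estimate model parameters from an ordered measurement table
#'
#' Recovers the initial lengths (`x_0`, `y_0`) and tepal-phase shortening
#' rates (`s_x1`, `s_y1`) of the size-gradient model by ordinary least
#' squares. Lengths are standardized by the ovary radius, the relative
#' position of organ `i` is `l_i = i / n` with `n` the total number of organs
#' in the table, and the regression runs over the tepal range (the first
#' `tepal_count` organs) or over all organs when `tepal_count` is `NULL`.
#'
#' With the default `convention = "semiaxis"`, standardized semi-axis lengths
#' (half the measured full lengths over `r_b`) are regressed on `l_i`, so the
#' intercept is the initial semi-axis directly and the shortening rate is the
#' negated slope — the exact inverse of the generative model.
#' `convention = "full_length"` instead regresses standardized full lengths
#' and applies the halved-intercept form (`x_0 = b_x / 2`, `s_x1 = |a_x|`,
#' slope left unhalved), a convention seen in scan-based protocols; note it
#' doubles the shortening rates relative to the generative model.
#'
#' @param table A measurement table (see [measure_organ_sheet()] /
#'   [synth_measurement_table()]): needs `organ_index`, `transverse_mm`,
#'   `longitudinal_mm`, and `r_b_mm` unless `r_b` is given.
#' @param r_b Ovary radius in the same units as the lengths; defaults to the
#'   table's `r_b_mm`.
#' @param tepal_count Number of outer organs to fit (the tepals); `NULL` fits
#'   all organs.
#' @param convention `"semiaxis"` (default) or `"full_length"` (see Details).
#' @return An object of class `lily_fit` with elements `estimates` (tibble
#'   with `x_0`, `y_0`, `s_x1`, `s_y1`), `fit` (per-axis slope, intercept,
#'   r-squared), `n_used`, `n_total`, and `convention`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @examples
#' tab <- synth_measurement_table(flower_params())
#' fit <- estimate_params(tab, tepal_count = 20)
#' tidy(fit)
#' @export
estimate_params <- function(table, r_b = NULL, tepal_count = NULL,
                            convention = c("semiaxis", "full_length")) {
  convention <- match.arg(convention)
  needed <- c("organ_index", "transverse_mm", "longitudinal_mm")
  if (!all(needed %in% names(table))) {
    stop("table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(r_b)) r_b <- table$r_b_mm[1]
  if (!is.numeric(r_b) || !is.finite(r_b) || r_b <= 0) {
    stop("ovary radius must be a positive number", call. = FALSE)
  }
  table <- table[order(table$organ_index), ]
  n <- nrow(table)
  fit_idx <- if (is.null(tepal_count)) seq_len(n) else seq_len(min(tepal_count, n))
  if (length(fit_idx) < 3) {
    stop("need at least 3 organs in the fitted range", call. = FALSE)
  }
  l <- table$organ_index[fit_idx] / n
  if (length(unique(l)) < 2) stop("singular fit: positions identical", call. = FALSE)

  fit_axis <- function(full_lengths) {
    std <- full_lengths[fit_idx] / r_b
    response <- if (convention == "semiaxis") std / 2 else std
    fit <- stats::lm(response ~ l)
    a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
    ss_tot <- sum((response - mean(response))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
    if (convention == "semiaxis") {
      list(slope = a, intercept = b, r2 = r2, init = b, rate = -a)
    } else {
      list(slope = a, intercept = b, r2 = r2, init = b / 2, rate = abs(a))
    }
  }
  fx <- fit_axis(table$transverse_mm)
  fy <- fit_axis(table$longitudinal_mm)
  structure(list(
    estimates = tibble::tibble(x_0 = fx$init, y_0 = fy$init,
                               s_x1 = fx$rate, s_y1 = fy$rate),
    fit = tibble::tibble(axis = c("transverse", "longitudinal"),
                         slope = c(fx$slope, fy$slope),
                         intercept = c(fx$intercept, fy$intercept),
                         r_squared = c(fx$r2, fy$r2)),
    n_used = length(fit_idx), n_total = n, r_b = r_b,
    convention = convention
  ), class = "lily_fit")
}

#' @export
print.lily_fit <- function(x, ...) {
  cat(sprintf("<lily_fit> %s convention, %d of %d organs fitted\n",
              x$convention, x$n_used, x$n_total))
  cat(sprintf("  x_0 = %.4g, s_x1 = %.4g (R2 = %.3f)\n",
              x$estimates$x_0, x$estimates$s_x1, x$fit$r_squared[1]))
  cat(sprintf("  y_0 = %.4g, s_y1 = %.4g (R2 = %.3f)\n",
              x$estimates$y_0, x$estimates$s_y1, x$fit$r_squared[2]))
  invisible(x)
}

#' @rdname estimate_params
#' @param x A `lily_fit` object.
#' @param ... Unused.
#' @export
tidy.lily_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c("x_0", "y_0", "s_x1", "s_y1"),
    estimate = c(x$estimates$x_0, x$estimates$y_0,
                 x$estimates$s_x1, x$estimates$s_y1),
    axis = c("transverse", "longitudinal", "transverse", "longitudinal")
  )
}

#' @rdname estimate_params
#' @export
glance.lily_fit <- function(x, ...) {
  tibble::tibble(
    r2_x = x$fit$r_squared[1], r2_y = x$fit$r_squared[2],
    n_used = x$n_used, n_total = x$n_total, convention = x$convention
  )
}

#' Summarize estimated parameters across flowers
#'
#' Produces the per-shape-class descriptive summary of the four estimated
#' parameters (`s_y1`, `s_x1`, `y_0`, `x_0`): mean, standard deviation,
#' minimum and maximum per class plus a total row, and the Pearson
#' correlation matrix of the four parameters across all flowers.
#'
#' @param estimates A tibble with one row per flower and columns
#'   `shape_class`, `s_y1`, `s_x1`, `y_0`, `x_0` (e.g. bound rows of
#'   `estimate_params()$estimates` plus metadata).
#' @return An object of class `measurement_summary`: list with `by_class`
#'   (tibble with columns `shape_class`, `n`, `statistic`, `s_y1`, `s_x1`,
#'   `y_0`, `x_0`) and `correlations` (4x4 matrix, `NA` where a parameter is
#'   constant).
#' @examples
#' est <- tibble::tibble(shape_class = c("stellate", "stellate", "cup-like"),
#'                       s_y1 = c(0.9, 1.0, 0.8), s_x1 = c(0.3, 0.35, 0.4),
#'                       y_0 = c(3.7, 3.6, 3.1), x_0 = c(1.0, 0.95, 0.96))
#' summarize_measurements(est)
#' @export
summarize_measurements <- function(estimates) {
  cols <- c("s_y1", "s_x1", "y_0", "x_0")
  if (!nrow(estimates)) stop("no estimated flowers to summarize", call. = FALSE)
  if (!all(c("shape_class", cols) %in% names(estimates))) {
    stop("estimates must have columns shape_class, ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  summarize_group <- function(df, label) {
    fns <- list(mean = mean,
                std = function(v) if (length(v) > 1) stats::sd(v) else 0,
                min = min, max = max)
    out <- tibble::tibble(shape_class = label, n = nrow(df),
                          statistic = names(fns))
    for (col in cols) {
      out[[col]] <- unname(purrr::map_dbl(fns, function(f) f(df[[col]])))
    }
    out
  }
  classes <- split(estimates, estimates$shape_class)
  by_class <- dplyr::bind_rows(c(
    purrr::imap(classes, summarize_group),
    list(summarize_group(estimates, "total"))
  ))
  correlations <- suppressWarnings(stats::cor(as.matrix(estimates[cols])))
  structure(list(by_class = by_class, correlations = correlations),
            class = "measurement_summary")
}

#' @export
print.measurement_summary <- function(x, ...) {
  cat("<measurement_summary>\n")
  print(x$by_class, n = nrow(x$by_class))
  cat("\nPearson correlations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' @rdname summarize_measurements
#' @param x A `measurement_summary` object.
#' @param ... Unused.
#' @export
tidy.measurement_summary <- function(x, ...) {
  x$by_class
}

#' Pairs plot of estimated parameters
#'
#' Scatter plots for every pair of the four estimated parameters, colored by
#' shape class — a quick view of how the shape classes occupy parameter
#' space.
#'
#' @inheritParams summarize_measurements
#' @return A ggplot object (faceted by parameter pair).
#' @export
plot_pairs <- function(estimates) {
  cols <- c("s_y1", "s_x1", "y_0", "x_0")
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  df <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      pair = paste(pr[2], "vs", pr[1]),
      x = estimates[[pr[1]]], y = estimates[[pr[2]]],
      shape_class = estimates$shape_class
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$shape_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "shape class") +
    ggplot2::theme_minimal()
}
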