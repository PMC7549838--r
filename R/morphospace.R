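#' Configure a two-parameter morphospace sweep
#'
#' A sweep varies two model parameters over inclusive grids while all others
#' stay at the values of `base`. Four canonical presets cover the classic
#' theoretical morphospaces:
#'
#' * `"openness"`: `o_max` x `o_min`, 0-90 degrees in 7 steps of 15.
#' * `"thresholds"`: `t_x` x `t_y`, 0-1 in 6 steps of 0.2.
#' * `"shortening"`: `s_x1` 0-1.00 (step 0.04) x `s_y1` 0-3.50 (step 0.14).
#' * `"initial"`: `x_0` x `y_0`, 0.50-9.00 in steps of 0.50.
#'
#' Presets keep `t_x = t_y = 0.20` and both elevation angles at 45 degrees
#' except where those are the swept axes.
#'
#' @param axis1,axis2 Parameter names to sweep (columns / rows of the grid).
#' @param values1,values2 Numeric grid values for each axis.
#' @param base A [flower_params()] object supplying all fixed parameters.
#' @param preset Optional preset name; overrides the axis arguments.
#' @return An object of class `sweep_config`.
#' @examples
#' sweep_config(preset = "shortening")
#' sweep_config("x_0", "y_0", seq(1, 3, 1), seq(1, 3, 1))
#' @export
sweep_config <- function(axis1 = NULL, axis2 = NULL,
                         values1 = NULL, values2 = NULL,
                         base = flower_params(),
                         preset = c("none", "openness", "thresholds",
                                    "shortening", "initial")) {
  preset <- match.arg(preset)
  stopifnot(inherits(base, "flower_params"))
  if (preset != "none") {
    grid <- switch(preset,
      openness = list("o_max", "o_min", seq(0, 90, by = 15),
                      seq(0, 90, by = 15)),
      thresholds = list("t_x", "t_y", seq(0, 1, by = 0.2), seq(0, 1, by = 0.2)),
      shortening = list("s_x1", "s_y1", seq(0, 1, by = 0.04),
                        seq(0, 3.5, by = 0.14)),
      initial = list("x_0", "y_0", seq(0.5, 9, by = 0.5), seq(0.5, 9, by = 0.5))
    )
    axis1 <- grid[[1]]; axis2 <- grid[[2]]
    values1 <- grid[[3]]; values2 <- grid[[4]]
  }
  valid <- setdiff(names(flower_param_defaults()), c("phi_unit", "n"))
  if (!is.character(axis1) || !axis1 %in% valid ||
      !is.character(axis2) || !axis2 %in% valid) {
    stop("axis1/axis2 must name numeric flower parameters", call. = FALSE)
  }
  if (!length(values1) || !length(values2)) {
    stop("empty sweep range", call. = FALSE)
  }
  structure(list(axis1 = axis1, axis2 = axis2,
                 values1 = values1, values2 = values2,
                 base = base, preset = preset),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config> %s: %s (%d values) x %s (%d values)\n",
              if (x$preset == "none") "custom" else x$preset,
              x$axis1, length(x$values1), x$axis2, length(x$values2)))
  invisible(x)
}

#' Sweep a theoretical morphospace
#'
#' Builds one flower per grid cell and, for each requested view, projects its
#' silhouette and computes solidity and convexity. Cells are independent and
#' the result is deterministic.
#'
#' @param config A [sweep_config()].
#' @param views Character subset of `c("top", "side")`; use `character(0)`
#'   to sweep parameters only.
#' @param resolution Pixels per ovary-radius unit for the silhouettes.
#' @return A `morphospace` tibble: one row per cell with the two swept
#'   parameter columns, a `params` list-column, and per-view index columns
#'   `solidity_<view>`, `convexity_<view>`. Attributes `axis1`/`axis2` record
#'   the swept parameter names.
#' @examples
#' cfg <- sweep_config("x_0", "y_0", c(1, 2), c(2, 3))
#' sweep_morphospace(cfg, views = "top", resolution = 48)
#' @export
sweep_morphospace <- function(config, views = c("top", "side"),
                              resolution = 128) {
  stopifnot(inherits(config, "sweep_config"))
  views <- intersect(views, c("top", "side"))
  grid <- tidyr::expand_grid(v2 = config$values2, v1 = config$values1)
  cells <- purrr::pmap(grid, function(v1, v2) {
    overrides <- stats::setNames(list(v1, v2), c(config$axis1, config$axis2))
    params <- do.call(update_params, c(list(config$base), overrides))
    organs <- build_organ_sequence(params)
    row <- stats::setNames(list(v1, v2), c(config$axis1, config$axis2))
    row$params <- list(params)
    for (view in views) {
      sil <- flower_silhouette(params, view, resolution, organs = organs)
      idx <- shape_indices(sil)
      row[[paste0("solidity_", view)]] <- idx$S
      row[[paste0("convexity_", view)]] <- idx$C
    }
    tibble::as_tibble(row)
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "axis1") <- config$axis1
  attr(out, "axis2") <- config$axis2
  class(out) <- c("morphospace", class(out))
  out
}

#' Extract an index matrix from a morphospace sweep
#'
#' @param result A [sweep_morphospace()] tibble.
#' @param index `"solidity"` or `"convexity"`.
#' @param view `"top"` or `"side"`.
#' @return A numeric matrix (rows = axis2 values, columns = axis1 values,
#'   with dimnames giving the parameter values).
#' @export
index_matrix <- function(result, index = c("solidity", "convexity"),
                         view = c("top", "side")) {
  index <- match.arg(index)
  view <- match.arg(view)
  col <- paste0(index, "_", view)
  if (!col %in% names(result)) {
    stop("index '", col, "' was not computed in this sweep", call. = FALSE)
  }
  a1 <- attr(result, "axis1"); a2 <- attr(result, "axis2")
  v1 <- sort(unique(result[[a1]])); v2 <- sort(unique(result[[a2]]))
  m <- matrix(NA_real_, nrow = length(v2), ncol = length(v1),
              dimnames = list(format(v2), format(v1)))
  m[cbind(match(result[[a2]], v2), match(result[[a1]], v1))] <- result[[col]]
  m
}

#' Write a morphospace index matrix to CSV
#'
#' Rows are axis2 values, columns axis1 values; the header row and first
#' column carry the parameter values.
#'
#' @inheritParams index_matrix
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_index_matrix <- function(result, path, index = c("solidity", "convexity"),
                               view = c("top", "side")) {
  m <- index_matrix(result, index, view)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- paste0(attr(result, "axis2"), "\\", attr(result, "axis1"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Heatmap of a morphospace index
#'
#' Draws the solidity or convexity surface over the swept grid, optionally
#' overlaying measured flowers (e.g. parameter estimates from
#' [estimate_params()]) as points.
#'
#' @inheritParams index_matrix
#' @param points Optional data frame with columns named after the two swept
#'   parameters, drawn as overlay points.
#' @return A ggplot object.
#' @export
plot_morphospace <- function(result, index = c("solidity", "convexity"),
                             view = c("top", "side"), points = NULL) {
  index <- match.arg(index)
  view <- match.arg(view)
  col <- paste0(index, "_", view)
  if (!col %in% names(result)) {
    stop("index '", col, "' was not computed in this sweep", call. = FALSE)
  }
  a1 <- attr(result, "axis1"); a2 <- attr(result, "axis2")
  p <- ggplot2::ggplot(result,
                       ggplot2::aes(x = .data[[a1]], y = .data[[a2]],
                                    fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = index) +
    ggplot2::labs(x = a1, y = a2,
                  title = sprintf("%s (%s view)", index, view)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, inherit.aes = FALSE,
                                 ggplot2::aes(x = .data[[a1]],
                                              y = .data[[a2]]),
                                 colour = "red", shape = 4, size = 2)
  }
  p
}

#' Render a montage of flower silhouettes over a morphospace grid
#'
#' Recomputes a small silhouette thumbnail for every grid cell and composes
#' them into one raster laid out like the sweep (axis1 along columns
#' increasing rightward, axis2 along rows increasing upward).
#'
#' @param result A [sweep_morphospace()] tibble.
#' @param view `"top"` or `"side"`.
#' @param path Optional output PNG path.
#' @param thumb_resolution Pixels per ovary-radius unit for the thumbnails.
#' @return Invisibly, the composed image matrix (values in `[0, 1]`, row 1 =
#'   top of the image). Writes `path` when given.
#' @export
render_montage <- function(result, view = c("top", "side"), path = NULL,
                           thumb_resolution = 16) {
  view <- match.arg(view)
  if (!nrow(result)) stop("empty morphospace result", call. = FALSE)
  thumbs <- purrr::map(result$params, function(p) {
    flower_silhouette(p, view, thumb_resolution)$pixels
  })
  a1 <- attr(result, "axis1"); a2 <- attr(result, "axis2")
  v1 <- sort(unique(result[[a1]])); v2 <- sort(unique(result[[a2]]))
  cell_h <- max(purrr::map_int(thumbs, nrow)) + 2L
  cell_w <- max(purrr::map_int(thumbs, ncol)) + 2L
  canvas <- matrix(0, nrow = cell_h * length(v2), ncol = cell_w * length(v1))
  for (k in seq_len(nrow(result))) {
    i <- match(result[[a2]][k], v2)  # grid row, bottom-up
    j <- match(result[[a1]][k], v1)
    th <- thumbs[[k]]
    r0 <- (length(v2) - i) * cell_h + (cell_h - nrow(th)) %/% 2L
    c0 <- (j - 1L) * cell_w + (cell_w - ncol(th)) %/% 2L
    block <- th[rev(seq_len(nrow(th))), , drop = FALSE] * 1
    canvas[r0 + seq_len(nrow(th)), c0 + seq_len(ncol(th))] <- block
  }
  if (!is.null(path)) png::writePNG(canvas, path)
  invisible(canvas)
}
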