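#' Project a flower geometry to a binary silhouette
#'
#' Orthographically projects every placed organ ellipse (a planar ellipse
#' projects to an ellipse, possibly degenerate) together with the ovary onto
#' the X-Y plane (`"top"` view) or the Y-Z plane (`"side"` view), fills each
#' shape, and rasterizes their union. No hidden-surface removal is applied:
#' the silhouette is the union of all projections, including stamens. The
#' raster tightly crops the silhouette with a 2-pixel margin.
#'
#' Projected ellipses thinner than the nominal organ thickness (e.g.
#' vertical organs seen from the top, or organs seen edge-on from the side)
#' are widened to a ribbon of 0.02 ovary radii — a stand-in for the physical
#' thickness of a real organ — floored at 1.5 px so thin organs always
#' rasterize without gaps.
#'
#' @param geometry A [build_flower_geometry()] result.
#' @param view `"top"` (X-Y) or `"side"` (Y-Z).
#' @param resolution Pixels per ovary-radius unit (>= 32).
#' @param include_ovary Include the ovary disc (top) / rectangle (side).
#' @return An object of class `silhouette`: a list with `pixels` (logical
#'   matrix; rows index the second view coordinate, columns the first),
#'   `view`, `resolution`, and `origin` (world coordinates of pixel `[1, 1]`).
#' @examples
#' sil <- project_silhouette(build_flower_geometry(flower_params()), "top", 64)
#' sil
#' @export
project_silhouette <- function(geometry, view = c("top", "side"),
                               resolution = 256, include_ovary = TRUE) {
  view <- match.arg(view)
  stopifnot(inherits(geometry, "flower_geometry"), resolution >= 32)
  flower_silhouette(geometry$params, view, resolution,
                    organs = geometry$organs, anchor = geometry$anchor,
                    include_ovary = include_ovary)
}

# Silhouette straight from a parameter set; avoids building organ polylines.
flower_silhouette <- function(params, view, resolution,
                              organs = build_organ_sequence(params),
                              anchor = "base", include_ovary = TRUE) {
  cols2d <- if (view == "top") c(1, 2) else c(2, 3)
  keep <- organs$x > 0 & organs$y > 0
  phi <- organs$phi_deg[keep] * pi / 180
  o <- organs$o_deg[keep] * pi / 180
  x <- organs$x[keep]; y <- organs$y[keep]; h <- organs$h[keep]
  # center = attachment + y * d (base anchor); axes u = x * t, v = y * d
  offset <- if (identical(anchor, "base")) y else 0
  cen3 <- cbind((params$r_b + offset * cos(o)) * cos(phi),
                (params$r_b + offset * cos(o)) * sin(phi),
                h + offset * sin(o))
  u3 <- cbind(-x * sin(phi), x * cos(phi), 0)
  v3 <- cbind(y * cos(o) * cos(phi), y * cos(o) * sin(phi), y * sin(o))
  ellipses <- matrix(numeric(0), ncol = 6)
  # near-edge-on organs project to ribbons of the organ's physical thickness
  # (0.02 ovary radii), floored at 1.5 px so they rasterize without gaps;
  # a fixed world width keeps the silhouette resolution-independent
  min_width <- max(0.02 * params$r_b, 1.5 / resolution)
  for (i in seq_along(phi)) {
    reg <- regularize_ellipse2d(u3[i, cols2d], v3[i, cols2d], min_width)
    if (is.null(reg)) next
    ellipses <- rbind(ellipses, c(cen3[i, cols2d], reg$u, reg$v))
  }
  if (include_ovary && view == "top") {
    ellipses <- rbind(ellipses, c(0, 0, params$r_b, 0, 0, params$r_b))
  }
  bounds <- silhouette_bounds(ellipses, params, view, include_ovary)
  margin <- 2 / resolution
  origin <- c(bounds[1] - margin, bounds[3] - margin)
  ncol <- ceiling((bounds[2] - bounds[1] + 2 * margin) * resolution) + 1L
  nrow <- ceiling((bounds[4] - bounds[3] + 2 * margin) * resolution) + 1L
  pixels <- cpp_fill_ellipses(nrow, ncol, origin[1], origin[2], resolution,
                              ellipses)
  if (include_ovary && view == "side") {
    cc <- pmax(1L, pmin(ncol, round((c(-params$r_b, params$r_b) - origin[1]) * resolution) + 1L))
    rr <- pmax(1L, pmin(nrow, round((c(0, params$h_b) - origin[2]) * resolution) + 1L))
    pixels[rr[1]:rr[2], cc[1]:cc[2]] <- TRUE
  }
  new_silhouette(pixels, view, resolution, origin)
}

new_silhouette <- function(pixels, view, resolution, origin) {
  structure(list(pixels = pixels, view = view, resolution = resolution,
                 origin = origin),
            class = "silhouette")
}

# Replace a projected axis pair whose parallelogram is thinner than min_width
# by a ribbon of that width; NULL if the projection vanishes entirely.
regularize_ellipse2d <- function(u, v, min_width) {
  cross <- u[1] * v[2] - u[2] * v[1]
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  if (max(lu, lv) < min_width) return(NULL)
  if (abs(cross) >= min_width * max(lu, lv)) return(list(u = u, v = v))
  long <- if (lu >= lv) u else v
  perp <- c(-long[2], long[1]) / sqrt(sum(long^2)) * min_width
  if (lu >= lv) list(u = long, v = perp) else list(u = perp, v = long)
}

silhouette_bounds <- function(ellipses, params, view, include_ovary) {
  ex <- if (nrow(ellipses)) sqrt(ellipses[, 3]^2 + ellipses[, 5]^2) else numeric(0)
  ey <- if (nrow(ellipses)) sqrt(ellipses[, 4]^2 + ellipses[, 6]^2) else numeric(0)
  xs <- c(ellipses[, 1] - ex, ellipses[, 1] + ex)
  ys <- c(ellipses[, 2] - ey, ellipses[, 2] + ey)
  if (include_ovary || !length(xs)) {
    if (view == "top") {
      xs <- c(xs, -params$r_b, params$r_b); ys <- c(ys, -params$r_b, params$r_b)
    } else {
      xs <- c(xs, -params$r_b, params$r_b); ys <- c(ys, 0, params$h_b)
    }
  }
  c(min(xs), max(xs), min(ys), max(ys))
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette> %s view, %d x %d px at %g px/radius, %d foreground px\n",
              x$view, nrow(x$pixels), ncol(x$pixels), x$resolution,
              sum(x$pixels)))
  invisible(x)
}

#' @method autoplot silhouette
#' @export
autoplot.silhouette <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$fg <- as.vector(t(object$pixels))  # row-major expand_grid order
  df$u <- object$origin[1] + (df$col - 1) / object$resolution
  df$v <- object$origin[2] + (df$row - 1) / object$resolution
  labs <- if (identical(object$view, "side")) c("Y", "Z") else c("X", "Y")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$fg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white"),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Write a silhouette as a white-on-black PNG
#'
#' @param sil A `silhouette`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_silhouette_png <- function(sil, path) {
  stopifnot(inherits(sil, "silhouette"))
  img <- sil$pixels[rev(seq_len(nrow(sil$pixels))), , drop = FALSE] * 1
  png::writePNG(img, path)
  invisible(path)
}

#' Rasterize a filled polygon into a silhouette
#'
#' Utility mainly used to validate the shape indices against shapes with
#' known analytic area and perimeter (circles, squares, stars). Uses an
#' even-odd (crossing-number) membership test on pixel centers.
#'
#' @param x,y Polygon vertex coordinates (closed implicitly).
#' @param resolution Pixels per unit length.
#' @return A `silhouette` object (`view = "custom"`).
#' @examples
#' sq <- rasterize_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1), 128)
#' shape_indices(sq)
#' @export
rasterize_polygon <- function(x, y, resolution = 256) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  margin <- 2 / resolution
  origin <- c(min(x) - margin, min(y) - margin)
  ncol <- ceiling((max(x) - min(x) + 2 * margin) * resolution) + 1L
  nrow <- ceiling((max(y) - min(y) + 2 * margin) * resolution) + 1L
  pu <- origin[1] + (seq_len(ncol) - 1) / resolution
  pv <- origin[2] + (seq_len(nrow) - 1) / resolution
  grid_u <- matrix(pu, nrow = nrow, ncol = ncol, byrow = TRUE)
  grid_v <- matrix(pv, nrow = nrow, ncol = ncol)
  inside <- matrix(FALSE, nrow, ncol)
  n <- length(x)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > grid_v) != (y[j] > grid_v)) &
      (grid_u < (x[j] - x[i]) * (grid_v - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  new_silhouette(inside, "custom", resolution, origin)
}

#' Convex-hull shape indices of a silhouette
#'
#' Computes the two global feature indices of the largest connected
#' foreground component: solidity `S = A_t / A_c` (object area over convex
#' hull area) and convexity `C = L_c / L_t` (hull perimeter over object
#' perimeter). Both lie in `(0, 1]` and equal 1 for a convex silhouette up to
#' discretization error.
#'
#' The outer contour is extracted by border following, simplified with a
#' Douglas-Peucker pass (1-pixel tolerance) to suppress the staircase bias of
#' chain-code perimeters, and `L_t` is the length of the simplified closed
#' polyline. `L_c` is the perimeter of its convex hull. `A_t` counts
#' foreground pixels; `A_c` is the area of the convex hull of the contour
#' pixels' corners (so that `A_c >= A_t` always). Lengths are reported in
#' world units (pixels / resolution), areas in squared world units.
#'
#' @param sil A `silhouette`.
#' @return A one-row tibble with columns `view`, `A_t`, `A_c`, `L_t`, `L_c`,
#'   `S` (solidity), `C` (convexity).
#' @examples
#' geom <- build_flower_geometry(flower_params())
#' shape_indices(project_silhouette(geom, "top", 64))
#' @export
shape_indices <- function(sil) {
  stopifnot(inherits(sil, "silhouette"))
  if (!any(sil$pixels)) stop("empty silhouette", call. = FALSE)
  lab <- EBImage::bwlabel(sil$pixels * 1)
  counts <- tabulate(lab)
  k <- which.max(counts)
  contour <- EBImage::ocontour(EBImage::Image((lab == k) * 1))[[1]]
  a_t <- counts[k] / sil$resolution^2
  if (nrow(contour) < 3) {
    # single pixel or tiny blob: treat as its own hull
    return(tibble::tibble(view = sil$view, A_t = a_t, A_c = a_t,
                          L_t = 4 / sil$resolution, L_c = 4 / sil$resolution,
                          S = 1, C = 1))
  }
  simplified <- simplify_closed(contour, eps = 1.0)
  l_t <- closed_length(simplified) / sil$resolution
  hull_l <- simplified[grDevices::chull(simplified), , drop = FALSE]
  l_c <- closed_length(hull_l) / sil$resolution
  corners <- rbind(
    sweep(contour, 2, c(-0.5, -0.5)), sweep(contour, 2, c(-0.5, 0.5)),
    sweep(contour, 2, c(0.5, -0.5)), sweep(contour, 2, c(0.5, 0.5))
  )
  hull_a <- corners[grDevices::chull(corners), , drop = FALSE]
  a_c <- polygon_area(hull_a) / sil$resolution^2
  tibble::tibble(view = sil$view, A_t = a_t, A_c = a_c, L_t = l_t, L_c = l_c,
                 S = a_t / a_c, C = min(l_c / l_t, 1))
}

closed_length <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Douglas-Peucker simplification of a closed contour: split at the vertex
# farthest from the start, simplify the two open halves, rejoin.
simplify_closed <- function(pts, eps = 1.0) {
  n <- nrow(pts)
  if (n < 5) return(pts)
  d0 <- rowSums(sweep(pts, 2, pts[1, ])^2)
  j <- which.max(d0)
  half1 <- douglas_peucker(pts[1:j, , drop = FALSE], eps)
  half2 <- douglas_peucker(pts[c(j:n, 1), , drop = FALSE], eps)
  rbind(half1, half2[-c(1, nrow(half2)), , drop = FALSE])
}

douglas_peucker <- function(pts, eps) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    if (len == 0) {
      d <- sqrt(rowSums(sweep(pts[mid, , drop = FALSE], 2, a)^2))
    } else {
      rel <- sweep(pts[mid, , drop = FALSE], 2, a)
      d <- abs(rel[, 1] * ab[2] - rel[, 2] * ab[1]) / len
    }
    if (max(d) > eps) {
      k <- mid[which.max(d)]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k), c(k, j)))
    }
  }
  pts[keep, , drop = FALSE]
}
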