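#' Place one organ as a planar ellipse in 3D
#'
#' Each organ is a rigid planar ellipse attached to the lateral surface of
#' the ovary cylinder. The attachment point is
#' `A = (r_b cos(phi), r_b sin(phi), h)`. The ellipse plane is spanned by the
#' horizontal tangential direction `t = (-sin(phi), cos(phi), 0)` and the
#' tilted radial direction `d = cos(o) r + sin(o) z`, with the radial unit
#' vector pointing outward at azimuth `phi`: at an elevation of 0 degrees the organ lies
#' flat, at 90 degrees it stands vertical against the flower axis. With the
#' default `"base"` anchoring the ellipse touches the ovary at one end of its
#' longitudinal axis, so its center sits at `A + y * d`.
#'
#' @param spec A one-row data frame (or list) with fields `x`, `y`,
#'   `phi_deg`, `h`, `o_deg`, as produced by [build_organ_sequence()].
#' @param params A [flower_params()] object (supplies `r_b`).
#' @param vertices_per_ellipse Number of boundary vertices (>= 8).
#' @param anchor `"base"` (ellipse touches the ovary; default) or `"center"`
#'   (ellipse centered on the attachment point).
#' @return A closed `V x 3` matrix of boundary vertices (first row not
#'   repeated), or `NULL` for a degenerate organ (`x == 0` or `y == 0`).
#' @examples
#' organ <- build_organ_sequence(flower_params())[1, ]
#' place_organ(organ, flower_params())
#' @export
place_organ <- function(spec, params, vertices_per_ellipse = 64L,
                        anchor = c("base", "center")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(params, "flower_params"), vertices_per_ellipse >= 8)
  x <- spec$x; y <- spec$y
  if (x <= 0 || y <= 0) return(NULL)
  frame <- organ_frame(spec, params, anchor)
  theta <- seq(0, 2 * pi, length.out = vertices_per_ellipse + 1L)[-(vertices_per_ellipse + 1L)]
  verts <- matrix(frame$center, nrow = vertices_per_ellipse, ncol = 3,
                  byrow = TRUE) +
    outer(x * cos(theta), frame$u) + outer(y * sin(theta), frame$v)
  colnames(verts) <- c("X", "Y", "Z")
  verts
}

# Orthonormal-in-plane frame of an organ ellipse: center, unit tangential
# direction u (transverse axis) and unit tilt direction v (longitudinal axis).
organ_frame <- function(spec, params, anchor = "base") {
  phi <- spec$phi_deg * pi / 180
  o <- spec$o_deg * pi / 180
  r_hat <- c(cos(phi), sin(phi), 0)
  t_hat <- c(-sin(phi), cos(phi), 0)
  d_hat <- cos(o) * r_hat + c(0, 0, sin(o))
  a <- params$r_b * r_hat + c(0, 0, spec$h)
  center <- if (anchor == "base") a + spec$y * d_hat else a
  list(center = center, u = t_hat, v = d_hat, attachment = a)
}

#' Assemble the full 3D flower geometry
#'
#' Builds the organ sequence from the parameters and places each
#' non-degenerate organ as a planar ellipse around the ovary cylinder
#' (radius `r_b`, height `h_b`, axis = global Z, base at Z = 0).
#'
#' @inheritParams place_organ
#' @return An object of class `flower_geometry`: a list with elements
#'   `params`, `organs` (the [build_organ_sequence()] tibble plus a
#'   list-column `vertices` of `V x 3` matrices, `NULL` where degenerate),
#'   and `ovary` (`r_b`, `h_b`).
#' @examples
#' geom <- build_flower_geometry(flower_params())
#' geom
#' @export
build_flower_geometry <- function(params, vertices_per_ellipse = 64L,
                                  anchor = c("base", "center")) {
  anchor <- match.arg(anchor)
  organs <- build_organ_sequence(params)
  organs$vertices <- purrr::map(seq_len(nrow(organs)), function(i) {
    place_organ(organs[i, ], params, vertices_per_ellipse, anchor)
  })
  structure(
    list(params = params, organs = organs,
         ovary = list(r_b = params$r_b, h_b = params$h_b),
         anchor = anchor),
    class = "flower_geometry"
  )
}

#' @export
print.flower_geometry <- function(x, ...) {
  n_placed <- sum(!purrr::map_lgl(x$organs$vertices, is.null))
  cat(sprintf(
    "<flower_geometry> %d organs (%d placed, %d degenerate), ovary r_b = %g, h_b = %g\n",
    nrow(x$organs), n_placed, nrow(x$organs) - n_placed,
    x$ovary$r_b, x$ovary$h_b))
  invisible(x)
}

#' Plot a flower geometry as a 2D orthographic wireframe
#'
#' Projects every organ outline (and the ovary) onto the top (X-Y) or side
#' (Y-Z) plane and draws the outlines with ggplot2. Useful for quick visual
#' inspection; use [project_silhouette()] for quantitative work.
#'
#' @param object A `flower_geometry`.
#' @param view `"top"` or `"side"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flower_geometry
#' @export
autoplot.flower_geometry <- function(object, view = c("top", "side"), ...) {
  view <- match.arg(view)
  keep <- !purrr::map_lgl(object$organs$vertices, is.null)
  outlines <- purrr::imap_dfr(object$organs$vertices[keep], function(v, i) {
    xy <- project_points(v, view)
    tibble::tibble(organ = i, u = xy[, 1], v = xy[, 2],
                   identity = object$organs$identity[keep][i])
  })
  ovary <- ovary_outline(object, view)
  labs <- if (view == "top") c("X", "Y") else c("Y", "Z")
  ggplot2::ggplot(outlines, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$organ,
                                       colour = .data$identity),
                          fill = NA, linewidth = 0.3) +
    ggplot2::geom_polygon(data = ovary, fill = "grey80", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

project_points <- function(vertices, view) {
  if (view == "top") vertices[, c(1, 2), drop = FALSE]
  else vertices[, c(2, 3), drop = FALSE]
}

ovary_outline <- function(geometry, view) {
  r <- geometry$ovary$r_b
  if (view == "top") {
    theta <- seq(0, 2 * pi, length.out = 97)[-97]
    tibble::tibble(u = r * cos(theta), v = r * sin(theta), organ = 0L)
  } else {
    tibble::tibble(u = c(-r, r, r, -r), v = c(0, 0, geometry$ovary$h_b,
                                              geometry$ovary$h_b), organ = 0L)
  }
}

#' Export a flower geometry as a triangle mesh
#'
#' Writes an ASCII OBJ or PLY file (chosen by the path extension). Each organ
#' ellipse is triangulated as a fan from its center; the ovary is a closed
#' (watertight) cylinder with capped ends. Degenerate organs are skipped.
#'
#' @param geometry A `flower_geometry`.
#' @param path Output path ending in `.obj` or `.ply`.
#' @param cylinder_segments Number of segments around the ovary cylinder.
#' @return Invisibly, a list with the vertex and face counts written.
#' @examples
#' \dontrun{
#' write_mesh(build_flower_geometry(flower_params()), "flower.obj")
#' }
#' @export
write_mesh <- function(geometry, path, cylinder_segments = 48L) {
  stopifnot(inherits(geometry, "flower_geometry"))
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("obj", "ply")) {
    stop("unsupported mesh format '", fmt, "' (use .obj or .ply)", call. = FALSE)
  }
  mesh <- flower_mesh(geometry, cylinder_segments)
  if (fmt == "obj") {
    lines <- c(
      sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3]),
      sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
    )
  } else {
    lines <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(mesh$vertices)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(mesh$faces)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3]),
      sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
              mesh$faces[, 3] - 1L)
    )
  }
  writeLines(lines, path)
  invisible(list(vertices = nrow(mesh$vertices), faces = nrow(mesh$faces)))
}

# Triangulated mesh (1-based faces) of ovary cylinder + organ ellipse fans.
flower_mesh <- function(geometry, cylinder_segments = 48L) {
  verts <- list(); faces <- list(); offset <- 0L
  cyl <- cylinder_mesh(geometry$ovary$r_b, geometry$ovary$h_b,
                       cylinder_segments)
  verts[[1]] <- cyl$vertices; faces[[1]] <- cyl$faces
  offset <- nrow(cyl$vertices)
  keep <- which(!purrr::map_lgl(geometry$organs$vertices, is.null))
  for (i in keep) {
    ring <- geometry$organs$vertices[[i]]
    v <- nrow(ring)
    center <- colMeans(ring)
    verts[[length(verts) + 1L]] <- rbind(center, ring)
    fan <- cbind(offset + 1L,
                 offset + 1L + seq_len(v),
                 offset + 1L + c(seq_len(v)[-1], 1L))
    faces[[length(faces) + 1L]] <- fan
    offset <- offset + v + 1L
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

cylinder_mesh <- function(r, h, segments = 48L) {
  theta <- seq(0, 2 * pi, length.out = segments + 1L)[-(segments + 1L)]
  ring_b <- cbind(r * cos(theta), r * sin(theta), 0)
  ring_t <- cbind(r * cos(theta), r * sin(theta), h)
  vertices <- rbind(ring_b, ring_t, c(0, 0, 0), c(0, 0, h))
  s <- seq_len(segments); s1 <- c(s[-1], 1L)
  side <- rbind(cbind(s, s1, segments + s1),
                cbind(s, segments + s1, segments + s))
  bottom <- cbind(2L * segments + 1L, s1, s)
  top <- cbind(2L * segments + 2L, segments + s, segments + s1)
  list(vertices = vertices, faces = rbind(side, bottom, top))
}
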