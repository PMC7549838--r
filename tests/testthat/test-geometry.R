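test_that("a flat organ at azimuth 0 lands where hand geometry says", {
  p <- flower_params(r_b = 1)
  spec <- list(x = 1, y = 1, phi_deg = 0, h = 0, o_deg = 0)
  verts <- place_organ(spec, p, vertices_per_ellipse = 64)
  expect_equal(dim(verts), c(64, 3))
  expect_equal(colMeans(verts), c(X = 2, Y = 0, Z = 0))
  # tip = attachment + 2y along the tilt direction
  expect_equal(max(verts[, 1]), 3)
  expect_equal(min(verts[, 1]), 1)
  expect_true(all(abs(verts[, 3]) < 1e-12))
})

test_that("placed organs are planar and anchored on the ovary surface", {
  p <- flower_params()
  geom <- build_flower_geometry(p)
  organs <- geom$organs
  for (i in c(1, 5, 21, 60)) {
    v <- organs$vertices[[i]]
    # planarity: vertices lie within 1e-9 of the best-fit plane
    centered <- sweep(v, 2, colMeans(v))
    expect_lt(svd(centered)$d[3], 1e-9)
    # attachment (nearest approach of the long axis) touches the cylinder
    frame <- lilymorph:::organ_frame(organs[i, ], p)
    expect_equal(sqrt(sum(frame$attachment[1:2]^2)), p$r_b)
    expect_gte(frame$attachment[3], 0)
  }
})

test_that("vertical organs stay within the attachment's radial bracket", {
  p <- flower_params()
  spec <- list(x = 0.5, y = 2, phi_deg = 123, h = 0.3, o_deg = 90)
  verts <- place_organ(spec, p)
  radii <- sqrt(verts[, 1]^2 + verts[, 2]^2)
  expect_true(all(radii >= p$r_b - spec$x - 1e-9))
  expect_true(all(radii <= p$r_b + spec$x + 1e-9))
})

test_that("rotating every azimuth rotates the flower rigidly", {
  p <- flower_params(n = 9, t_x = 1, t_y = 1, o_min = 30, o_max = 70)
  geom <- build_flower_geometry(p)
  delta <- 360  # full turn maps each organ onto itself
  for (i in c(1, 4, 9)) {
    spec <- as.list(geom$organs[i, c("x", "y", "phi_deg", "h", "o_deg")])
    spec$phi_deg <- spec$phi_deg + delta
    expect_equal(place_organ(spec, p), geom$organs$vertices[[i]])
  }
  # quarter turn = rigid rotation of the vertex cloud
  theta <- pi / 2
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  spec <- as.list(geom$organs[2, c("x", "y", "phi_deg", "h", "o_deg")])
  spec$phi_deg <- spec$phi_deg + 90
  expect_equal(unname(place_organ(spec, p)),
               unname(geom$organs$vertices[[2]] %*% t(rot)))
})

test_that("top-view radial extent equals r_b + 2 y cos(o)", {
  p <- flower_params()
  geom <- build_flower_geometry(p)
  organs <- geom$organs
  for (i in c(1, 10, 20)) {  # opening tepals: the tip is the farthest point
    v <- organs$vertices[[i]]
    expected <- p$r_b + 2 * organs$y[i] * cos(organs$o_deg[i] * pi / 180)
    expect_equal(max(sqrt(v[, 1]^2 + v[, 2]^2)), expected, tolerance = 1e-9)
  }
  # fully closed flower: radial extent bounded by r_b + x_i
  closed <- build_flower_geometry(update_params(p, o_min = 90, o_max = 90))
  for (i in seq_len(20)) {
    v <- closed$organs$vertices[[i]]
    expect_lte(max(sqrt(v[, 1]^2 + v[, 2]^2)),
               p$r_b + closed$organs$x[i] + 1e-9)
  }
})

test_that("degenerate organs are recorded but not placed or meshed", {
  p <- flower_params(s_y1 = 100, t_y = 1, t_x = 1, n = 10)
  geom <- build_flower_geometry(p)
  degenerate <- geom$organs$y == 0
  expect_true(any(degenerate))
  expect_true(all(purrr::map_lgl(geom$organs$vertices[degenerate], is.null)))
  mesh <- lilymorph:::flower_mesh(geom)
  n_placed <- sum(!degenerate)
  v_per <- 64
  segs <- 48
  expect_equal(nrow(mesh$vertices), (2 * segs + 2) + n_placed * (v_per + 1))
})

test_that("mesh export round-trips through OBJ with fan area ~ pi*x*y", {
  p <- flower_params(n = 1, t_x = 1, t_y = 1, x_0 = 1, y_0 = 1,
                     o_min = 0, o_max = 0)
  geom <- build_flower_geometry(p, vertices_per_ellipse = 64)
  path <- withr::local_tempfile(fileext = ".obj")
  info <- write_mesh(geom, path)
  lines <- readLines(path)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  expect_equal(length(vlines), info$vertices)
  expect_equal(length(flines), info$faces)
  verts <- do.call(rbind, lapply(strsplit(vlines, " "), function(s) {
    as.numeric(s[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(flines, " "), function(s) {
    as.integer(s[2:4])
  }))
  # written coordinates match the source geometry within 1e-6
  ring <- geom$organs$vertices[[1]]
  written_ring <- verts[(nrow(verts) - 63):nrow(verts), ]
  expect_equal(unname(written_ring), unname(ring), tolerance = 1e-6)
  # the 64-triangle organ fan approximates the analytic ellipse area
  organ_faces <- faces[(nrow(faces) - 63):nrow(faces), , drop = FALSE]
  tri_area <- function(a, b, c) {
    sqrt(sum(pracma_cross(b - a, c - a)^2)) / 2
  }
  pracma_cross <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  fan_area <- sum(apply(organ_faces, 1, function(f) {
    tri_area(verts[f[1], ], verts[f[2], ], verts[f[3], ])
  }))
  expect_equal(fan_area, pi * 1 * 1, tolerance = 0.01)
})

test_that("PLY export parses with matching counts and the ovary is watertight", {
  geom <- build_flower_geometry(flower_params(n = 5))
  path <- withr::local_tempfile(fileext = ".ply")
  info <- write_mesh(geom, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("element face", lines, value = TRUE)))
  expect_equal(nv, info$vertices)
  expect_equal(nf, info$faces)
  # cylinder component: every edge shared by exactly two triangles
  cyl <- lilymorph:::cylinder_mesh(1, 0.5, 16)
  edges <- rbind(cyl$faces[, 1:2], cyl$faces[, 2:3], cyl$faces[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(keys) == 2))
})
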