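test_that("noiseless synthetic tables return the generating parameters", {
  params <- list(
    update_params(flower_params(), x_0 = 1.0, s_x1 = 0.8),
    update_params(flower_params(), x_0 = 1.3, y_0 = 2.9, s_x1 = 0.25,
                  s_y1 = 0.6),
    all_tepal_params(n = 30, x_0 = 0.9, y_0 = 4.2, s_x1 = 0.4, s_y1 = 1.2)
  )
  for (p in params) {
    tab <- synth_measurement_table(p, r_b_mm = 12.3)
    fit <- estimate_params(tab, tepal_count = tepal_count(p))
    truth <- c(x_0 = p$x_0, y_0 = p$y_0, s_x1 = p$s_x1, s_y1 = p$s_y1)
    est <- unlist(fit$estimates[, names(truth)])
    expect_equal(est, truth, tolerance = 1e-6)
    expect_equal(fit$fit$r_squared, c(1, 1), tolerance = 1e-9)
  }
})

test_that("constant organ lengths give zero shortening rates", {
  p <- all_tepal_params(n = 10, s_x1 = 0, s_y1 = 0)
  fit <- estimate_params(synth_measurement_table(p))
  expect_equal(fit$estimates$s_x1, 0, tolerance = 1e-12)
  expect_equal(fit$estimates$s_y1, 0, tolerance = 1e-12)
  expect_equal(fit$estimates$x_0, p$x_0)
})

test_that("estimates are invariant to a common length rescaling", {
  p <- all_tepal_params(n = 15, x_0 = 1.1, s_x1 = 0.5)
  tab <- synth_measurement_table(p, r_b_mm = 10)
  scaled <- tab
  scaled$transverse_mm <- scaled$transverse_mm * 7
  scaled$longitudinal_mm <- scaled$longitudinal_mm * 7
  scaled$r_b_mm <- scaled$r_b_mm * 7
  expect_equal(estimate_params(scaled)$estimates,
               estimate_params(tab)$estimates)
})

test_that("the literal halved-intercept convention is available", {
  p <- all_tepal_params(n = 20, x_0 = 1.2, s_x1 = 0.5, y_0 = 3.0, s_y1 = 1.0)
  tab <- synth_measurement_table(p)
  lit <- estimate_params(tab, convention = "full_length")
  # regressing full lengths: intercept is 2 * x_0, slope is -2 * s_x1;
  # the halved intercept recovers x_0, the unhalved |slope| doubles the rate
  expect_equal(lit$estimates$x_0, p$x_0, tolerance = 1e-9)
  expect_equal(lit$estimates$y_0, p$y_0, tolerance = 1e-9)
  expect_equal(lit$estimates$s_x1, 2 * p$s_x1, tolerance = 1e-9)
  expect_equal(lit$estimates$s_y1, 2 * p$s_y1, tolerance = 1e-9)
})

test_that("estimator guards reject unusable tables", {
  tab <- synth_measurement_table(all_tepal_params(n = 10))
  expect_error(estimate_params(tab[1:2, ]), "at least 3")
  expect_error(estimate_params(tab, r_b = -1), "positive")
  tab$r_b_mm <- NA_real_
  expect_error(estimate_params(tab), "positive")
  expect_error(estimate_params(tibble::tibble(a = 1)), "columns")
})

test_that("noisy estimates stay unbiased over Monte-Carlo replicates", {
  p <- all_tepal_params(n = 20)
  truth <- c(x_0 = p$x_0, y_0 = p$y_0, s_x1 = p$s_x1, s_y1 = p$s_y1)
  set.seed(101)
  reps <- purrr::map_dfr(1:200, function(r) {
    tab <- synth_measurement_table(p, noise_model(0.05))
    estimate_params(tab)$estimates
  })
  for (nm in names(truth)) {
    bias <- mean(reps[[nm]]) - truth[[nm]]
    se <- stats::sd(reps[[nm]]) / sqrt(nrow(reps))
    expect_lt(abs(bias), 2 * se + 1e-12)
  }
})

test_that("a drawn circle measures its diameter from image moments", {
  img <- matrix(0, 140, 140)
  rr <- matrix(seq_len(140), 140, 140)
  cc <- t(rr)
  img[(rr - 70)^2 + (cc - 70)^2 <= 50^2] <- 1
  tab <- measure_organ_sheet(img, scale = 0.1, min_area = 50)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$transverse_mm, 10, tolerance = 0.02)
  expect_equal(tab$longitudinal_mm, 10, tolerance = 0.02)
  expect_false(tab$touches_border)
})

test_that("synthetic sheets are measured back within 2%", {
  p <- update_params(flower_params(), n = 10, t_x = 1, t_y = 1)
  truth <- synth_measurement_table(p, r_b_mm = 8)
  sheet <- synth_organ_sheet(truth, scale = 0.08)
  measured <- measure_organ_sheet(sheet$image, scale = 0.08)
  expect_equal(nrow(measured), 10)
  expect_equal(measured$transverse_mm, truth$transverse_mm, tolerance = 0.02)
  expect_equal(measured$longitudinal_mm, truth$longitudinal_mm,
               tolerance = 0.02)
})

test_that("blank images and fixed thresholds behave as documented", {
  blank <- matrix(0, 50, 50)
  expect_error(measure_organ_sheet(blank, scale = 0.1), "no organs")
  img <- matrix(0, 60, 60)
  img[20:40, 20:40] <- 0.6
  tab <- measure_organ_sheet(img, scale = 1, threshold = "fixed",
                             threshold_value = 0.5, min_area = 10)
  expect_equal(nrow(tab), 1)
  expect_error(measure_organ_sheet(img, scale = 1, threshold = "fixed"),
               "threshold_value")
})

test_that("sheets read back identically through PNG files", {
  p <- update_params(flower_params(), n = 4, t_x = 1, t_y = 1)
  sheet <- synth_organ_sheet(synth_measurement_table(p), scale = 0.2)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(sheet$image, path)
  from_file <- measure_organ_sheet(path, scale = 0.2)
  from_matrix <- measure_organ_sheet(sheet$image, scale = 0.2)
  expect_equal(from_file$transverse_mm, from_matrix$transverse_mm)
})

test_that("components are ordered row-major by centroid", {
  img <- matrix(0, 100, 160)
  centers <- list(c(25, 30), c(28, 90), c(22, 140), c(75, 40), c(78, 120))
  for (ct in centers) {
    rr <- matrix(seq_len(100), 100, 160)
    cc <- matrix(seq_len(160), 100, 160, byrow = TRUE)
    img[(rr - ct[1])^2 + (cc - ct[2])^2 <= 8^2] <- 1
  }
  tab <- measure_organ_sheet(img, scale = 1, min_area = 20)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$centroid_col, c(30, 90, 140, 40, 120), tolerance = 0.1)
})

test_that("summaries reproduce per-class descriptive statistics", {
  est <- tibble::tibble(
    shape_class = c("stellate", "stellate", "cup-like"),
    s_y1 = c(0.9, 1.1, 0.8), s_x1 = c(0.3, 0.5, 0.4),
    y_0 = c(3.7, 3.5, 3.1), x_0 = c(1.0, 0.9, 0.96)
  )
  s <- summarize_measurements(est)
  by_class <- s$by_class
  stellate_mean <- by_class[by_class$shape_class == "stellate" &
                              by_class$statistic == "mean", ]
  expect_equal(stellate_mean$s_y1, 1.0)
  expect_equal(stellate_mean$n, 2L)
  total <- by_class[by_class$shape_class == "total", ]
  expect_equal(total$n, rep(3L, 4))
  expect_equal(total$s_x1[total$statistic == "min"], 0.3)
  expect_equal(total$s_x1[total$statistic == "max"], 0.5)
  # single flower: mean = min = max, zero spread
  one <- summarize_measurements(est[3, ])$by_class
  expect_equal(one$y_0[one$statistic == "mean"],
               one$y_0[one$statistic == "max"])
  expect_true(all(one$s_y1[one$statistic == "std"] == 0))
  expect_equal(tidy(s), by_class)
})

test_that("degenerate cohorts give zero spread and NA correlations", {
  est <- tibble::tibble(
    shape_class = "cup-like",
    s_y1 = c(0.8, 0.8), s_x1 = c(0.4, 0.4),
    y_0 = c(3.1, 3.1), x_0 = c(0.96, 0.96)
  )
  s <- summarize_measurements(est)
  expect_true(all(s$by_class$s_y1[s$by_class$statistic == "std"] == 0))
  expect_true(all(is.na(s$correlations[upper.tri(s$correlations)])))
  expect_error(summarize_measurements(est[0, ]), "no estimated")
})

test_that("fit objects expose tidy and glance views and pair plots build", {
  tab <- synth_measurement_table(all_tepal_params(n = 12))
  fit <- estimate_params(tab)
  td <- tidy(fit)
  expect_equal(td$parameter, c("x_0", "y_0", "s_x1", "s_y1"))
  expect_equal(td$estimate[1], fit$estimates$x_0)
  gl <- glance(fit)
  expect_equal(gl$n_used, 12)
  expect_equal(gl$convention, "semiaxis")
  est <- tibble::tibble(shape_class = c("a", "b", "a"),
                        s_y1 = c(1, 2, 1.5), s_x1 = c(0.2, 0.4, 0.3),
                        y_0 = c(3, 3.5, 3.2), x_0 = c(1, 1.1, 0.9))
  expect_s3_class(plot_pairs(est), "ggplot")
})
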