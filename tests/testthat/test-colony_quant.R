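test_that("grid fitting locates spot centers on synthetic plates", {
  set.seed(101)
  d <- matrix(stats::rlnorm(96, log(9000), 0.5), 8, 12)

  # no jitter: centers within 1 px of truth
  p <- render_plate(d, pitch = 40, background = 500, gradient_amplitude = 50,
                    noise_sd = 2, seed = 1)
  g <- fit_grid(p$image, 8, 12)
  tru_x <- matrix(p$centers$x, 8, 12)
  tru_y <- matrix(p$centers$y, 8, 12)
  expect_lt(max(abs(g$x - tru_x)), 1)
  expect_lt(max(abs(g$y - tru_y)), 1)
  expect_equal(g$pitch, 40, tolerance = 0.01)

  # per-spot jitter SD 2 px: centers within 3 px of truth
  pj <- render_plate(d, pitch = 40, background = 500, gradient_amplitude = 50,
                     noise_sd = 2, jitter_sd = 2, seed = 2)
  gj <- fit_grid(pj$image, 8, 12)
  jx <- matrix(pj$centers$x, 8, 12)
  jy <- matrix(pj$centers$y, 8, 12)
  expect_lt(max(abs(gj$x - jx)), 3)
  expect_lt(max(abs(gj$y - jy)), 3)

  # blank image: low-signal error advising an override
  set.seed(102)
  blank <- matrix(500 + stats::rnorm(200 * 300, 0, 2), 200, 300)
  err <- tryCatch(fit_grid(blank, 8, 12), error = function(e) e)
  expect_s3_class(err, "low_signal")
  expect_match(conditionMessage(err), "override")
})

test_that("density measurement is accurate, linear and gradient-robust", {
  # blank plate: all densities clamp to zero
  blank <- render_plate(matrix(0, 8, 12), pitch = 30, background = 500,
                        gradient_amplitude = 0, noise_sd = 0, seed = 1)
  m0 <- measure_density(blank$image, nominal_grid(dim(blank$image), 8, 12))
  expect_true(all(m0$raw_density == 0))

  # single colony without gradient: within 5% of truth
  d <- matrix(0, 8, 12); d[3, 5] <- 20000
  p <- render_plate(d, pitch = 30, background = 500, gradient_amplitude = 0,
                    noise_sd = 0, seed = 1)
  g <- nominal_grid(dim(p$image), 8, 12, pitch = 30)
  m <- measure_density(p$image, g)
  expect_equal(m$raw_density[m$row == 3 & m$col == 5], 20000,
               tolerance = 0.05)

  # with a gradient of 10% of background: within 7% of truth
  pg <- render_plate(d, pitch = 30, background = 500, gradient_amplitude = 50,
                     noise_sd = 0, seed = 1)
  mg <- measure_density(pg$image, g)
  expect_equal(mg$raw_density[mg$row == 3 & mg$col == 5], 20000,
               tolerance = 0.07)

  # intensity scaling: scaling pixels by k scales densities by k
  set.seed(103)
  dd <- matrix(stats::rlnorm(96, log(20000), 0.4), 8, 12)
  pp <- render_plate(dd, pitch = 30, background = 500,
                     gradient_amplitude = 0, noise_sd = 0, seed = 2)
  m1 <- measure_density(pp$image, g)
  m3 <- measure_density(3 * pp$image, g)
  expect_equal(m3$raw_density, 3 * m1$raw_density, tolerance = 1e-8)

  # integer translation of the image changes re-fit densities < 2%
  full <- render_plate(dd, pitch = 30, background = 500,
                       gradient_amplitude = 0, noise_sd = 1, seed = 3)
  img <- full$image
  shifted <- img[c(4:nrow(img), rep(nrow(img), 3)),
                 c(6:ncol(img), rep(ncol(img), 5))]
  ma <- measure_density(img, fit_grid(img, 8, 12))
  mb <- measure_density(shifted, fit_grid(shifted, 8, 12))
  expect_lt(max(abs(mb$raw_density - ma$raw_density) / ma$raw_density), 0.02)
})

test_that("diploid area extraction matches rendered colony geometry", {
  g_expect <- function(im) nominal_grid(dim(im), 8, 12, pitch = 60)

  # blank plate: all areas zero
  blank <- render_plate(matrix(0, 8, 12), pitch = 60, background = 500,
                        gradient_amplitude = 0, noise_sd = 2, seed = 1)
  a0 <- measure_area(blank$image, g_expect(blank$image))
  expect_true(all(a0$area == 0))

  # disc colonies of radius 10: areas within 10% of pi * (10 + edge)^2
  radm <- matrix(10, 8, 12)
  ampm <- matrix(400, 8, 12)
  p <- render_plate(matrix(0, 8, 12), pitch = 60, spot_radius = radm,
                    shoulder_sigma = 2, background = 500,
                    gradient_amplitude = 50, noise_sd = 2,
                    amplitude = ampm, seed = 2)
  a <- measure_area(p$image, fit_grid(p$image, 8, 12))
  r_half <- 10 + 2 * sqrt(2 * log(2))
  expect_lt(max(abs(a$area - pi * r_half^2)) / (pi * r_half^2), 0.10)

  # one missing colony: its area under 5% of the plate median
  radm[4, 7] <- 0
  pm <- render_plate(matrix(0, 8, 12), pitch = 60, spot_radius = radm,
                     shoulder_sigma = 2, background = 500,
                     gradient_amplitude = 50, noise_sd = 2,
                     amplitude = ampm, seed = 3)
  am <- measure_area(pm$image, fit_grid(pm$image, 8, 12))
  expect_lt(am$area[am$row == 4 & am$col == 7], 0.05 * median(am$area))
})

test_that("min-max normalization maps onto [0,1] with documented edges", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(1, 1, 1))
  expect_error(minmax_normalize(numeric(0)), "non-empty")
  set.seed(104)
  for (i in 1:20) {
    v <- stats::rlnorm(50, 5, 1)
    nv <- minmax_normalize(v)
    expect_true(all(nv >= 0 & nv <= 1))
    expect_equal(range(nv), c(0, 1))
  }
})

test_that("density normalization flags failed mating below epsilon", {
  nd <- normalize_densities(c(10, 10, 0), c(0.5, 0, 1), epsilon = 0.05)
  expect_equal(nd$normalized_density, c(20, NA, 0))
  expect_equal(nd$qc_flag, c("ok", "failed_mating", "ok"))
  expect_error(normalize_densities(1:3, 1:2), "misaligned")
})

test_that("measured densities track synthetic truth on a full screen", {
  lay <- make_layout()
  cfg <- synth_screen_config(seed = 21)
  scr <- simulate_screen(cfg, lay, sample_interaction_classes(lay, cfg, 22))
  spots <- quantify_screen(scr$test, scr$diploid, lay)
  tr <- scr$truth
  m <- match(paste(spots$plate, spots$row, spots$col),
             paste(tr$plate, tr$row, tr$col))
  expect_false(anyNA(m))
  expect_gt(stats::cor(spots$raw_density, tr$true_density[m]), 0.99)
})
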