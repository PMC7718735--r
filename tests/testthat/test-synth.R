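test_that("rendered plates integrate to their true densities", {
  # blank plate: constant background only
  blank <- render_plate(matrix(0, 4, 6), pitch = 30, background = 500,
                        gradient_amplitude = 0, noise_sd = 0, seed = 1)
  expect_true(all(blank$image == 500))

  # integrated above-background intensity equals the true density exactly
  d <- matrix(c(1234.5, 0, 98765, 42), 2, 2)
  p <- render_plate(d, pitch = 30, background = 500, gradient_amplitude = 0,
                    noise_sd = 0, seed = 1)
  expect_equal(sum(p$image - 500), sum(d), tolerance = 1e-10)
  # per-spot: integrate quadrants
  img <- p$image - 500
  h <- nrow(img) %/% 2; w <- ncol(img) %/% 2
  expect_equal(sum(img[1:h, 1:w]), d[1, 1], tolerance = 1e-6 * d[1, 1])
  expect_equal(sum(img[(h + 1):nrow(img), (w + 1):ncol(img)]), d[2, 2],
               tolerance = 0.01 * d[2, 2])

  # determinism: same config and seed give bit-identical pixels
  p2 <- render_plate(d, pitch = 30, background = 500, gradient_amplitude = 20,
                     noise_sd = 3, jitter_sd = 1, seed = 7)
  p3 <- render_plate(d, pitch = 30, background = 500, gradient_amplitude = 20,
                     noise_sd = 3, jitter_sd = 1, seed = 7)
  expect_identical(p2$image, p3$image)

  # linearity: doubling all densities doubles the rendered integral
  pd <- render_plate(2 * d, pitch = 30, background = 500,
                     gradient_amplitude = 0, noise_sd = 0, seed = 1)
  expect_equal(sum(pd$image - 500), 2 * sum(p$image - 500), tolerance = 1e-9)

  # a grid that cannot fit is refused
  expect_error(render_plate(d, pitch = 30, margin = 2, seed = 1),
               "exceeds image bounds")
  expect_error(render_plate(matrix(-1, 1, 1), pitch = 30), ">= 0")
})

test_that("simulated screens honor class truth, dropouts and determinism", {
  lay <- make_layout()
  cfg <- synth_screen_config(seed = 42)

  # interactor_fraction 0: every truth density is a negative-class draw
  cfg0 <- synth_screen_config(interactor_fraction = 0, seed = 3)
  bt0 <- sample_interaction_classes(lay, cfg0, seed = 4)
  expect_true(all(bt0 == "negative"))
  scr0 <- simulate_screen(cfg0, lay, bt0)
  expect_true(all(scr0$truth$class == "negative"))

  # interactor count within 3 binomial SDs at fraction 0.1
  lay13 <- make_layout(11)  # 1056 preys >= 1000
  cfg10 <- synth_screen_config(interactor_fraction = 0.1, seed = 5)
  bt10 <- sample_interaction_classes(lay13, cfg10, seed = 6)
  n <- length(bt10)
  expect_lt(abs(sum(bt10 != "negative") - 0.1 * n),
            3 * sqrt(n * 0.1 * 0.9))

  # dropout_rate 1: all diploids absent, every spot flagged
  cfgd <- synth_screen_config(dropout_rate = 1, seed = 8)
  scrd <- simulate_screen(cfgd, lay, sample_interaction_classes(lay, cfgd, 9))
  expect_true(all(scrd$truth$dropout))
  expect_true(all(scrd$truth$true_diploid_area == 0))
  expect_true(all(scrd$truth$true_density == 0))

  # unknown prey in bait_truth is refused
  expect_error(simulate_screen(cfg, lay, c(nosuch = "strong")),
               "absent from the layout")

  # determinism: identical config yields identical screens
  bt <- sample_interaction_classes(lay, cfg, seed = 10)
  s1 <- simulate_screen(cfg, lay, bt)
  s2 <- simulate_screen(cfg, lay, bt)
  expect_identical(s1$test[[1]]$image, s2$test[[1]]$image)
  expect_identical(s1$diploid[[1]]$image, s2$diploid[[1]]$image)
  expect_identical(s1$truth, s2$truth)

  # truth table and images agree on spot count (4 spots per occupied well)
  expect_equal(nrow(s1$truth), 4L * nrow(lay$entries))
})

test_that("labeled calibration colonies follow the class mixture", {
  cfg <- synth_screen_config(seed = 1)
  lab <- simulate_labeled_colonies(cfg, n = 100, seed = 2)
  expect_equal(nrow(lab), 100L)
  expect_setequal(unique(lab$label),
                  c("negative", "weak", "medium", "strong"))
  expect_identical(lab, simulate_labeled_colonies(cfg, n = 100, seed = 2))

  # degenerate zero-scale distributions collapse onto the class medians
  cfg0 <- synth_screen_config(density_classes = list(
    negative = c(meanlog = log(10), sdlog = 0),
    weak = c(meanlog = log(100), sdlog = 0),
    medium = c(meanlog = log(1000), sdlog = 0),
    strong = c(meanlog = log(10000), sdlog = 0)), seed = 1)
  lab0 <- simulate_labeled_colonies(cfg0, n = 50, seed = 3)
  med <- c(negative = 10, weak = 100, medium = 1000, strong = 10000)
  expect_equal(lab0$density, unname(med[lab0$label]), tolerance = 1e-12)
})

test_that("nuclear stacks recover their ground truth by construction", {
  # zero nuclei: pure background
  empty <- render_nuclear_stack(NULL, dim = c(64, 64), background = 100)
  expect_true(all(empty$stack == 100))
  expect_equal(dim(empty$stack)[3], 21L)  # 6.3 um at 0.3 um, inclusive

  # one nucleus, zero noise: sum projection over the truth mask recovers
  # the target mean within 2%, and total intensity within 1%
  one <- render_nuclear_stack(
    data.frame(x = 32, y = 32, radius_um = 1.3, intensity = 500),
    dim = c(65, 65), background = 100, noise_sd = 0)
  sm <- project_stack(one, "sum")
  expect_equal(one$truth$true_mean_intensity, 500 + 100 * 21)
  # recompute the half-max mask from the rendered stack itself
  mx <- project_stack(one, "max") - 100
  mask <- mx >= 0.5 * max(mx)
  expect_equal(mean(sm[mask]), one$truth$true_mean_intensity,
               tolerance = 0.02)
  expect_equal(sum((sm - 100 * 21)[mask]), one$truth$true_total_intensity,
               tolerance = 0.01)
  expect_equal(sum(mask) * 0.01, one$truth$true_area_um2)

  # linearity: doubling the target intensity doubles the signal
  two <- render_nuclear_stack(
    data.frame(x = 32, y = 32, radius_um = 1.3, intensity = 1000),
    dim = c(65, 65), background = 100, noise_sd = 0)
  expect_equal(max(two$stack) - 100, 2 * (max(one$stack) - 100),
               tolerance = 1e-9)

  # overlapping nuclei are refused
  expect_error(render_nuclear_stack(
    data.frame(x = c(30, 34), y = c(32, 32), radius_um = c(1.3, 1.3))),
    "overlap")

  # determinism with noise
  a <- render_nuclear_stack(data.frame(x = 32, y = 32, radius_um = 1.2),
                            dim = c(64, 64), noise_sd = 5, seed = 11)
  b <- render_nuclear_stack(data.frame(x = 32, y = 32, radius_um = 1.2),
                            dim = c(64, 64), noise_sd = 5, seed = 11)
  expect_identical(a$stack, b$stack)
})
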