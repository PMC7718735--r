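#' Configuration for the synthetic MYTH screen generator
#'
#' Bundles the geometry, optics and population parameters used to render
#' synthetic diploid-selection (96-spot) and selective test (384-spot)
#' plates with known per-spot ground truth. Colony "density" throughout is
#' integrated above-background intensity in arbitrary 16-bit-scale units.
#'
#' Class densities are log-normal with ordered medians (colony densities
#' are positive and right-skewed, spanning orders of magnitude between
#' background growth and strong reporter activation). Defaults put the
#' negative class (median 900, barely visible background growth) far below
#' the weak class (median 9000), so the calibrated cutoff (25th percentile
#' of weak) separates the populations.
#'
#' @param n_plates Number of 96-well source plates in the screen.
#' @param pitch_384,pitch_96 Center-to-center spot spacing in pixels.
#' @param spot_radius Flat-top radius of rendered test colonies (px).
#' @param shoulder_sigma Gaussian shoulder width of the colony edge (px).
#' @param diploid_radius_mean,diploid_radius_sd Mean/SD of diploid colony
#'   flat-top radius (px); mating success varies colony size.
#' @param diploid_shoulder_sigma Diploid colony edge width (px).
#' @param diploid_amplitude Above-background peak intensity of diploids.
#' @param background_level Constant plate background intensity.
#' @param gradient_amplitude Peak-to-peak amplitude of the smooth
#'   low-order illumination gradient added to every plate.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param interactor_fraction Probability that a prey is a true
#'   interactor; the default matches the hit fraction observed in
#'   screen-scale MYTH data (377 hits among 1037 library preys).
#' @param class_mix Mixture over `weak`/`medium`/`strong` among interactors.
#' @param density_classes Named list of `c(meanlog, sdlog)` per class;
#'   medians must be ordered negative < weak < medium < strong.
#' @param dropout_rate Probability of mating failure (absent diploid and
#'   zero growth on the test plate).
#' @param center_jitter_sd SD of random spot-center displacement (px).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `synth_screen_config`.
#' @export
synth_screen_config <- function(n_plates = 1L,
                                pitch_384 = 30, pitch_96 = 60,
                                spot_radius = 6, shoulder_sigma = 1.5,
                                diploid_radius_mean = 11,
                                diploid_radius_sd = 1,
                                diploid_shoulder_sigma = 2,
                                diploid_amplitude = 400,
                                background_level = 500,
                                gradient_amplitude = 50,
                                noise_sd = 2,
                                interactor_fraction = 377 / 1037,
                                class_mix = c(weak = 0.25, medium = 0.40,
                                              strong = 0.35),
                                density_classes = list(
                                  negative = c(meanlog = log(900), sdlog = 0.40),
                                  weak = c(meanlog = log(9000), sdlog = 0.35),
                                  medium = c(meanlog = log(36000), sdlog = 0.30),
                                  strong = c(meanlog = log(120000), sdlog = 0.30)),
                                dropout_rate = 0.02,
                                center_jitter_sd = 0,
                                seed = 1L) {
  cfg <- list(n_plates = as.integer(n_plates), pitch_384 = pitch_384,
              pitch_96 = pitch_96, spot_radius = spot_radius,
              shoulder_sigma = shoulder_sigma,
              diploid_radius_mean = diploid_radius_mean,
              diploid_radius_sd = diploid_radius_sd,
              diploid_shoulder_sigma = diploid_shoulder_sigma,
              diploid_amplitude = diploid_amplitude,
              background_level = background_level,
              gradient_amplitude = gradient_amplitude,
              noise_sd = noise_sd,
              interactor_fraction = interactor_fraction,
              class_mix = class_mix / sum(class_mix),
              density_classes = density_classes,
              dropout_rate = dropout_rate,
              center_jitter_sd = center_jitter_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_plates >= 1, cfg$noise_sd >= 0,
            cfg$interactor_fraction >= 0, cfg$interactor_fraction <= 1,
            cfg$dropout_rate >= 0, cfg$dropout_rate <= 1)
  cls <- c("negative", "weak", "medium", "strong")
  if (!all(cls %in% names(density_classes))) {
    stop("density_classes must define negative, weak, medium and strong",
         call. = FALSE)
  }
  med <- vapply(density_classes[cls], function(p) unname(p["meanlog"]), 0)
  if (any(diff(med) <= 0)) {
    stop("class medians must be ordered negative < weak < medium < strong",
         call. = FALSE)
  }
  structure(cfg, class = "synth_screen_config")
}

# Radially symmetric colony profile on an integer pixel lattice:
# flat top of the given radius with a Gaussian shoulder. Returns a square
# matrix; pinned colonies are plateau-like so integrated intensity (the
# screen's density readout) is well-defined and linear in amplitude.
colony_profile <- function(radius, shoulder_sigma, dx = 0, dy = 0) {
  half <- ceiling(radius + 3.5 * shoulder_sigma)
  off <- seq(-half, half)
  d <- sqrt(outer((off - dy)^2, (off - dx)^2, `+`))
  p <- exp(-pmax(d - radius, 0)^2 / (2 * shoulder_sigma^2))
  p[d <= radius] <- 1
  p
}

# Pixel count of the half-maximum support disc of a colony profile --
# the ground-truth "area" a mid-edge threshold recovers.
halfmax_area <- function(radius, shoulder_sigma) {
  if (radius <= 0) return(0L)
  r_half <- radius + shoulder_sigma * sqrt(2 * log(2))
  half <- ceiling(r_half) + 1L
  off <- seq(-half, half)
  sum(outer(off^2, off^2, `+`) <= r_half^2)
}

# Smooth low-order polynomial illumination field spanning [0, amplitude].
illumination_gradient <- function(nr, nc, amplitude) {
  u <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  v <- matrix(seq(0, 1, length.out = nr), nr, nc)
  amplitude * (0.5 * u + 0.3 * v + 0.2 * u * v)
}

#' Render a synthetic plate image
#'
#' Draws an `n_rows x n_cols` array of colonies on a constant background
#' plus a smooth illumination gradient and additive Gaussian noise. Each
#' colony is a flat-top disc with a Gaussian shoulder whose integrated
#' above-background intensity equals its requested true density exactly
#' (before noise); alternatively a per-spot peak `amplitude` can be given
#' (used for diploid plates, where area rather than density is the truth).
#'
#' @param densities Matrix (`n_rows x n_cols`) of true integrated spot
#'   densities (>= 0). Ignored where `amplitude` is supplied.
#' @param pitch Center-to-center spacing in pixels.
#' @param spot_radius Scalar or matrix of flat-top radii (px); radius 0
#'   renders nothing (dropout).
#' @param shoulder_sigma Colony edge width (px).
#' @param background Constant background level.
#' @param gradient_amplitude Illumination-gradient amplitude.
#' @param noise_sd Additive Gaussian noise SD.
#' @param amplitude Optional matrix of peak intensities overriding
#'   density-derived amplitudes.
#' @param margin Border between outermost spot centers and the image edge
#'   (px); defaults to one pitch. Must accommodate the colony footprint.
#' @param jitter_sd SD of random spot-center displacement (px).
#' @param seed Integer seed, or `NULL` to consume the ambient RNG stream.
#' @return A list of class `synth_plate`: `image` (numeric matrix, row =
#'   y), `centers` (data frame `row,col,x,y`, 0-based pixel coordinates),
#'   `pitch`, `background`.
#' @examples
#' p <- render_plate(matrix(c(0, 500, 1000, 0), 2, 2), pitch = 30, seed = 1)
#' dim(p$image)
#' @export
render_plate <- function(densities, pitch, spot_radius = 6,
                         shoulder_sigma = 1.5, background = 500,
                         gradient_amplitude = 0, noise_sd = 0,
                         amplitude = NULL, margin = pitch, jitter_sd = 0,
                         seed = NULL) {
  densities <- as.matrix(densities)
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  nr <- nrow(densities); nc <- ncol(densities)
  if (length(spot_radius) == 1) {
    spot_radius <- matrix(spot_radius, nr, nc)
  }
  support <- max(spot_radius) + 3.5 * shoulder_sigma
  if (margin < support) {
    stop("grid exceeds image bounds: margin smaller than colony footprint",
         call. = FALSE)
  }
  H <- as.integer(2 * margin + (nr - 1) * pitch + 1)
  W <- as.integer(2 * margin + (nc - 1) * pitch + 1)
  render <- function() {
    img <- matrix(background, H, W) +
      illumination_gradient(H, W, gradient_amplitude)
    cy <- margin + (seq_len(nr) - 1) * pitch
    cx <- margin + (seq_len(nc) - 1) * pitch
    centers <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    centers$x <- cx[centers$col]
    centers$y <- cy[centers$row]
    if (jitter_sd > 0) {
      centers$x <- centers$x + stats::rnorm(nrow(centers), 0, jitter_sd)
      centers$y <- centers$y + stats::rnorm(nrow(centers), 0, jitter_sd)
    }
    for (k in seq_len(nrow(centers))) {
      r <- centers$row[k]; c <- centers$col[k]
      rad <- spot_radius[r, c]
      if (rad <= 0) next
      iy <- round(centers$y[k]); ix <- round(centers$x[k])
      prof <- colony_profile(rad, shoulder_sigma,
                             dx = centers$x[k] - ix, dy = centers$y[k] - iy)
      if (is.null(amplitude)) {
        if (densities[r, c] <= 0) next
        amp <- densities[r, c] / sum(prof)
      } else {
        amp <- amplitude[r, c]
        if (amp <= 0) next
      }
      half <- (nrow(prof) - 1) / 2
      ys <- (iy - half):(iy + half) + 1L  # 0-based center -> 1-based index
      xs <- (ix - half):(ix + half) + 1L
      if (min(ys) < 1 || min(xs) < 1 || max(ys) > H || max(xs) > W) {
        stop("grid exceeds image bounds", call. = FALSE)
      }
      img[ys, xs] <- img[ys, xs] + amp * prof
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    }
    list(image = pmax(img, 0), centers = centers)
  }
  out <- if (is.null(seed)) render() else withr::with_seed(seed, render())
  structure(list(image = out$image, centers = out$centers, pitch = pitch,
                 background = background), class = "synth_plate")
}

#' Sample ground-truth interaction classes for a bait
#'
#' Assigns each prey in the layout a class: interactor with probability
#' `interactor_fraction` (class drawn from `class_mix`), otherwise
#' `negative`.
#'
#' @param layout A `library_layout`.
#' @param config A `synth_screen_config`.
#' @param seed Integer seed, or `NULL` for the ambient RNG stream.
#' @return Named character vector, prey -> class.
#' @export
sample_interaction_classes <- function(layout, config, seed = NULL) {
  draw <- function() {
    prey <- layout$entries$prey
    cls <- rep("negative", length(prey))
    hit <- stats::runif(length(prey)) < config$interactor_fraction
    cls[hit] <- sample(names(config$class_mix), sum(hit), replace = TRUE,
                       prob = config$class_mix)
    stats::setNames(cls, prey)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full arrayed MYTH screen with ground truth
#'
#' Generates, for one bait, a diploid-selection plate (96 format) and a
#' selective test plate (384 format, contiguous 2x2 technical
#' quadruplicates) per source plate. Diploid colony radii vary around
#' their mean; mating failures (probability `dropout_rate`) leave no
#' diploid colony and zero growth on the test plate. Each test spot's true
#' density is an independent draw from its prey's class distribution.
#'
#' @param config A `synth_screen_config`.
#' @param layout A `library_layout`; only occupied wells are rendered.
#' @param bait_truth Named character vector prey -> class
#'   (`negative`/`weak`/`medium`/`strong`). Every named prey must exist in
#'   the layout; preys absent from `bait_truth` default to `negative`.
#' @return A list of class `synth_screen`: `diploid` and `test` (lists of
#'   `synth_plate`, one per source plate), `truth` (per-spot data frame
#'   with 384 address, source well, prey, class, dropout flag,
#'   `true_density`, `true_diploid_area` in pixels), and `config`.
#' @export
simulate_screen <- function(config, layout, bait_truth) {
  stopifnot(inherits(config, "synth_screen_config"),
            inherits(layout, "library_layout"))
  unknown <- setdiff(names(bait_truth), layout$entries$prey)
  if (length(unknown)) {
    stop(sprintf("bait_truth names prey absent from the layout: %s",
                 paste(utils::head(unknown, 3), collapse = ", ")),
         call. = FALSE)
  }
  bad_cls <- setdiff(unique(bait_truth), names(config$density_classes))
  if (length(bad_cls)) {
    stop(sprintf("unknown interaction class: %s", bad_cls[1]), call. = FALSE)
  }
  withr::with_seed(config$seed, {
    diploid <- vector("list", config$n_plates)
    test <- vector("list", config$n_plates)
    truth <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      e <- layout$entries[layout$entries$plate == p, , drop = FALSE]
      # per-well draws (96 format)
      wells <- data.frame(row = e$row, col = e$col, prey = e$prey)
      n <- nrow(wells)
      wells$class <- ifelse(wells$prey %in% names(bait_truth),
                            unname(bait_truth[wells$prey]), "negative")
      wells$dropout <- stats::runif(n) < config$dropout_rate
      rad <- stats::rnorm(n, config$diploid_radius_mean,
                          config$diploid_radius_sd)
      rad <- pmax(rad, 0.4 * config$diploid_radius_mean)
      rad[wells$dropout] <- 0
      wells$diploid_radius <- if (n) rad else numeric(0)
      wells$true_diploid_area <- vapply(wells$diploid_radius, halfmax_area,
                                        0L, config$diploid_shoulder_sigma)
      # diploid plate image (amplitude-defined colonies)
      radm <- matrix(0, 8, 12); ampm <- matrix(0, 8, 12)
      idx <- cbind(wells$row, wells$col)
      radm[idx] <- wells$diploid_radius
      ampm[idx] <- ifelse(wells$dropout, 0, config$diploid_amplitude)
      diploid[[p]] <- render_plate(matrix(0, 8, 12), pitch = config$pitch_96,
                                   spot_radius = radm,
                                   shoulder_sigma = config$diploid_shoulder_sigma,
                                   background = config$background_level,
                                   gradient_amplitude = config$gradient_amplitude,
                                   noise_sd = config$noise_sd,
                                   amplitude = ampm,
                                   jitter_sd = config$center_jitter_sd,
                                   seed = NULL)
      # per-spot truth: 4 technical replicates per well
      if (n) {
        a384 <- map_96_to_384(plate_address(p, wells$row, wells$col, 96L))
        sp <- data.frame(plate = p, row = a384$row, col = a384$col,
                         src_row = a384$src_row, src_col = a384$src_col)
        wi <- rep(seq_len(n), each = 4L)
        sp$prey <- wells$prey[wi]
        sp$class <- wells$class[wi]
        sp$dropout <- wells$dropout[wi]
        sp$true_diploid_area <- wells$true_diploid_area[wi]
        par <- config$density_classes
        ml <- vapply(sp$class, function(cl) par[[cl]]["meanlog"], 0)
        sl <- vapply(sp$class, function(cl) par[[cl]]["sdlog"], 0)
        sp$true_density <- stats::rlnorm(nrow(sp), ml, sl)
        sp$true_density[sp$dropout] <- 0
      } else {
        sp <- data.frame(plate = integer(0), row = integer(0),
                         col = integer(0), src_row = integer(0),
                         src_col = integer(0), prey = character(0),
                         class = character(0), dropout = logical(0),
                         true_diploid_area = integer(0),
                         true_density = numeric(0))
      }
      dens <- matrix(0, 16, 24)
      if (nrow(sp)) dens[cbind(sp$row, sp$col)] <- sp$true_density
      test[[p]] <- render_plate(dens, pitch = config$pitch_384,
                                spot_radius = config$spot_radius,
                                shoulder_sigma = config$shoulder_sigma,
                                background = config$background_level,
                                gradient_amplitude = config$gradient_amplitude,
                                noise_sd = config$noise_sd,
                                jitter_sd = config$center_jitter_sd,
                                seed = NULL)
      truth[[p]] <- sp
    }
    structure(list(diploid = diploid, test = test,
                   truth = do.call(rbind, truth), config = config),
              class = "synth_screen")
  })
}

#' Simulate manually labeled calibration colonies
#'
#' Emulates the bench calibration step in which at least one hundred
#' individual colonies are assigned by eye to one of four interaction
#' strength categories. Labels are drawn from `mixture`, densities from
#' the corresponding class distributions in `config`.
#'
#' @param config A `synth_screen_config`.
#' @param n Number of labeled colonies (>= 4).
#' @param seed Integer seed, or `NULL` for the ambient RNG stream.
#' @param mixture Named label mixture over the four categories.
#' @return Data frame with columns `density`, `label`.
#' @export
simulate_labeled_colonies <- function(config, n = 100L, seed = NULL,
                                      mixture = c(negative = 0.4, weak = 0.2,
                                                  medium = 0.2, strong = 0.2)) {
  stopifnot(n >= 4)
  mixture <- mixture / sum(mixture)
  draw <- function() {
    lab <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    par <- config$density_classes
    ml <- vapply(lab, function(cl) par[[cl]]["meanlog"], 0)
    sl <- vapply(lab, function(cl) par[[cl]]["sdlog"], 0)
    data.frame(density = stats::rlnorm(n, ml, sl), label = lab,
               row.names = NULL)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Derive calibration labels from a measured synthetic screen
#'
#' Emulates the bench calibration step on synthetic data: picks colonies
#' spanning the screen (evenly spaced per ground-truth class, so all four
#' categories are represented) and labels their measured normalized
#' densities with the true class. Using measured rather than true
#' densities keeps the calibration on the same scale as the calling step,
#' exactly as manual labeling of real screen colonies does.
#'
#' @param spots Measurement table from [quantify_screen()].
#' @param truth Ground-truth table from [simulate_screen()].
#' @param n_per_class Colonies sampled per class (deterministic,
#'   evenly spaced in plate order).
#' @return Data frame `density,label` for [calibrate_cutoff()].
#' @export
label_colonies_from_truth <- function(spots, truth, n_per_class = 30L) {
  m <- match(paste(spots$plate, spots$row, spots$col),
             paste(truth$plate, truth$row, truth$col))
  if (anyNA(m)) stop("spots and truth tables do not align", call. = FALSE)
  cls <- truth$class[m]
  ok <- spots$qc_flag == "ok"
  out <- lapply(split(which(ok), cls[ok]), function(i) {
    pick <- i[unique(round(seq(1, length(i),
                               length.out = min(n_per_class, length(i)))))]
    data.frame(density = spots$normalized_density[pick],
               label = cls[pick])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
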