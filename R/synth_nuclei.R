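# Lateral footprint geometry for overlap checks: shells are discs around
# their center, rods are thin tubes around their axis (sampled as points
# along the segment). Returns, for every object pair, the gap between
# footprints (negative = overlap).
object_clearance <- function(obj, shell_sigma, pixel_size, extra = 0) {
  n <- nrow(obj)
  pts <- lapply(seq_len(n), function(i) {
    if (identical(obj$shape[i], "rod")) {
      L2 <- obj$length_um[i] / 2 / pixel_size
      th <- if (is.null(obj$angle)) 0 else obj$angle[i]
      s <- seq(-L2, L2, length.out = max(2, ceiling(L2)))
      cbind(obj$x[i] + s * cos(th), obj$y[i] + s * sin(th))
    } else {
      cbind(obj$x[i], obj$y[i])
    }
  })
  lat <- ifelse(obj$shape == "rod", 3 * shell_sigma / pixel_size,
                (obj$radius_um + 3 * shell_sigma) / pixel_size)
  gaps <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(min(outer(pts[[i]][, 1], pts[[j]][, 1], `-`)^2 +
                      outer(pts[[i]][, 2], pts[[j]][, 2], `-`)^2))
      gaps <- c(gaps, d - lat[i] - lat[j] - extra)
    }
  }
  gaps
}

#' Render a synthetic confocal z-stack of nuclear-envelope labeled nuclei
#'
#' Each nucleus is rendered as a spherical shell (envelope-enriched
#' fluorescence): intensity falls off as a Gaussian of width `shell_sigma`
#' around radius `radius_um` from the nucleus center, sampled on an
#' anisotropic voxel grid (`pixel_size` in xy, `z_spacing` axially, with
#' sub-plane averaging to emulate slab integration). A maximum projection
#' of such a shell is a flat-top disc; a sum projection shows the
#' limb-brightened ring characteristic of envelope staining. Elongated
#' distractors (`shape = "rod"`) are Gaussian tubes in the central plane.
#'
#' Ground truth per object uses the half-maximum support convention: the
#' mask is the set of pixels whose noiseless maximum-projection value is at
#' least half that object's peak; `true_area_um2` is its area and
#' `true_mean_intensity` the mean of the noiseless sum projection
#' (including the background term) over it. Object amplitudes are scaled
#' so the mean above-background sum-projection signal over the mask equals
#' the requested `intensity` exactly.
#'
#' The default geometry is 21 planes at 0.3 um spacing, i.e. a 6.3 um
#' axial range read with an inclusive fencepost (6.3/0.3 + 1 slices).
#'
#' @param nuclei Data frame with one row per object: `x`, `y` (0-based
#'   pixel center), `radius_um`; optional `z_um` (axial offset from stack
#'   center, default 0), `intensity` (target mean above-background
#'   sum-projection signal, default 500), `shape` (`"shell"` or `"rod"`),
#'   `length_um`, `angle` (rod axis, radians), `distractor` (logical,
#'   carried into truth).
#' @param dim Image size `c(ny, nx)` in pixels.
#' @param z_planes Number of z planes (default 21).
#' @param z_spacing Axial spacing in um (default 0.3).
#' @param pixel_size Lateral pixel size in um (default 0.1).
#' @param background Constant per-plane background level.
#' @param noise_sd Additive Gaussian noise SD per voxel.
#' @param shell_sigma Radial width of the envelope shell in um.
#' @param seed Integer seed, or `NULL` for the ambient RNG stream.
#' @return List of class `synth_stack`: `stack` (array `ny x nx x nz`),
#'   `truth` (per-object data frame with `true_area_um2`,
#'   `true_mean_intensity`, `true_total_intensity`), plus the geometry
#'   parameters.
#' @export
render_nuclear_stack <- function(nuclei, dim = c(512L, 512L),
                                 z_planes = 21L, z_spacing = 0.3,
                                 pixel_size = 0.1, background = 100,
                                 noise_sd = 0, shell_sigma = 0.2,
                                 seed = NULL) {
  ny <- as.integer(dim[1]); nx <- as.integer(dim[2])
  nz <- as.integer(z_planes)
  stopifnot(nz >= 1, z_spacing > 0, pixel_size > 0, noise_sd >= 0)
  n <- if (is.null(nuclei)) 0L else nrow(nuclei)
  if (n) {
    if (is.null(nuclei$z_um)) nuclei$z_um <- 0
    if (is.null(nuclei$intensity)) nuclei$intensity <- 500
    if (is.null(nuclei$shape)) nuclei$shape <- "shell"
    if (is.null(nuclei$distractor)) nuclei$distractor <- FALSE
    if (n > 1 && any(object_clearance(nuclei, shell_sigma, pixel_size) < 0)) {
      stop("overlapping nuclei requested", call. = FALSE)
    }
  }
  zc <- (seq_len(nz) - (nz + 1) / 2) * z_spacing  # plane z in um
  nsub <- 5L
  zoff <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * z_spacing
  stack <- array(0, c(ny, nx, nz))
  truth <- NULL
  for (i in seq_len(n)) {
    cx <- nuclei$x[i]; cy <- nuclei$y[i]; cz <- nuclei$z_um[i]
    if (identical(nuclei$shape[i], "rod")) {
      half <- ceiling((nuclei$length_um[i] / 2 + 4 * shell_sigma) / pixel_size)
    } else {
      half <- ceiling((nuclei$radius_um[i] + 4 * shell_sigma) / pixel_size)
    }
    ix <- round(cx); iy <- round(cy)
    xs <- (ix - half):(ix + half); ys <- (iy - half):(iy + half)
    if (min(xs) < 0 || min(ys) < 0 || max(xs) >= nx || max(ys) >= ny) {
      stop("nucleus footprint exceeds image bounds", call. = FALSE)
    }
    dx <- (xs - cx) * pixel_size
    dy <- (ys - cy) * pixel_size
    box <- array(0, c(length(ys), length(xs), nz))
    if (identical(nuclei$shape[i], "rod")) {
      th <- if (is.null(nuclei$angle)) 0 else nuclei$angle[i]
      ux <- cos(th); uy <- sin(th)
      gx <- matrix(dx, length(ys), length(xs), byrow = TRUE)
      gy <- matrix(dy, length(ys), length(xs))
      along <- gx * ux + gy * uy
      perp <- -gx * uy + gy * ux
      L2 <- nuclei$length_um[i] / 2
      prof2d <- exp(-pmax(abs(along) - L2, 0)^2 / (2 * shell_sigma^2)) *
        exp(-perp^2 / (2 * shell_sigma^2))
      for (k in seq_len(nz)) {
        zg <- mean(exp(-((zc[k] + zoff) - cz)^2 / (2 * (2 * shell_sigma)^2)))
        box[, , k] <- prof2d * zg
      }
    } else {
      R <- nuclei$radius_um[i]
      d2 <- outer(dy^2, dx^2, `+`)
      for (k in seq_len(nz)) {
        acc <- 0
        for (zo in zoff) {
          r <- sqrt(d2 + ((zc[k] + zo) - cz)^2)
          acc <- acc + exp(-(r - R)^2 / (2 * shell_sigma^2))
        }
        box[, , k] <- acc / nsub
      }
    }
    # half-maximum support mask of the object's own max projection
    mx <- apply(box, c(1, 2), max)
    mask <- mx >= 0.5 * max(mx)
    sm <- apply(box, c(1, 2), sum)
    mean_unit <- mean(sm[mask])
    amp <- nuclei$intensity[i] / mean_unit
    stack[ys + 1L, xs + 1L, ] <- stack[ys + 1L, xs + 1L, ] + amp * box
    truth <- rbind(truth, data.frame(
      x = cx, y = cy, radius_um = nuclei$radius_um[i],
      shape = nuclei$shape[i], distractor = nuclei$distractor[i],
      intensity = nuclei$intensity[i],
      true_area_um2 = sum(mask) * pixel_size^2,
      true_mean_intensity = nuclei$intensity[i] + background * nz,
      true_total_intensity = amp * sum(sm[mask])))
  }
  stack <- stack + background
  add_noise <- function(s) {
    if (noise_sd > 0) {
      s <- s + array(stats::rnorm(length(s), 0, noise_sd), dim(s))
    }
    pmax(s, 0)
  }
  stack <- if (is.null(seed)) add_noise(stack) else {
    withr::with_seed(seed, add_noise(stack))
  }
  if (is.null(truth)) {
    truth <- data.frame(x = numeric(0), y = numeric(0),
                        radius_um = numeric(0), shape = character(0),
                        distractor = logical(0), intensity = numeric(0),
                        true_area_um2 = numeric(0),
                        true_mean_intensity = numeric(0),
                        true_total_intensity = numeric(0))
  }
  structure(list(stack = stack, truth = truth, z_planes = nz,
                 z_spacing = z_spacing, pixel_size = pixel_size,
                 background = background),
            class = "synth_stack")
}

#' Simulate a field of nuclei with in-range and distractor objects
#'
#' Places non-overlapping objects uniformly at random: `n_nuclei`
#' in-range nuclei (projected area uniform in `area_range_um2`),
#' plus small and large shells outside the canonical 4-12 um^2 size gate
#' and low-circularity rods, all flagged `distractor` in the truth table.
#'
#' @param n_nuclei In-range nucleus count.
#' @param n_small,n_large,n_rods Distractor counts.
#' @param dim Image size `c(ny, nx)`.
#' @param area_range_um2 Projected-area range for in-range nuclei.
#' @param intensity_range Range of target mean sum-projection signals.
#' @param seed Integer seed (required: placement is random).
#' @param ... Passed to [render_nuclear_stack()].
#' @return A `synth_stack` (see [render_nuclear_stack()]).
#' @export
simulate_nuclear_field <- function(n_nuclei = 20L, n_small = 2L,
                                   n_large = 2L, n_rods = 1L,
                                   dim = c(512L, 512L),
                                   area_range_um2 = c(4.5, 6.5),
                                   intensity_range = c(400, 600),
                                   seed = 1L, ...) {
  dots <- list(...)
  pixel_size <- if (is.null(dots$pixel_size)) 0.1 else dots$pixel_size
  shell_sigma <- if (is.null(dots$shell_sigma)) 0.2 else dots$shell_sigma
  nuclei <- withr::with_seed(seed, {
    n <- n_nuclei + n_small + n_large + n_rods
    area <- c(stats::runif(n_nuclei, area_range_um2[1], area_range_um2[2]),
              stats::runif(n_small, 0.8, 1.2),
              stats::runif(n_large, 18, 22),
              rep(NA_real_, n_rods))
    obj <- data.frame(
      radius_um = ifelse(is.na(area), 0.0, sqrt(area / pi)),
      shape = rep(c("shell", "shell", "shell", "rod"),
                  c(n_nuclei, n_small, n_large, n_rods)),
      distractor = rep(c(FALSE, TRUE, TRUE, TRUE),
                       c(n_nuclei, n_small, n_large, n_rods)),
      length_um = ifelse(rep(c(FALSE, FALSE, FALSE, TRUE),
                             c(n_nuclei, n_small, n_large, n_rods)), 15, 0),
      angle = stats::runif(n, 0, pi),
      intensity = stats::runif(n, intensity_range[1], intensity_range[2]),
      z_um = 0)
    # bounding half-extent keeps footprints inside the image
    ext <- ifelse(obj$shape == "rod",
                  obj$length_um / 2 / pixel_size + 3 * shell_sigma / pixel_size,
                  (obj$radius_um + 3 * shell_sigma) / pixel_size)
    # rejection placement with a clearance so blur cannot bridge objects
    obj$x <- NA_real_; obj$y <- NA_real_
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        obj$x[i] <- stats::runif(1, ext[i] + 2, dim[2] - ext[i] - 3)
        obj$y[i] <- stats::runif(1, ext[i] + 2, dim[1] - ext[i] - 3)
        sub <- obj[seq_len(i), , drop = FALSE]
        if (i == 1 || all(object_clearance(sub, shell_sigma, pixel_size,
                                           extra = 10) >= 0)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place non-overlapping nuclei; reduce counts",
             call. = FALSE)
      }
    }
    obj
  })
  args <- c(list(nuclei = nuclei, dim = dim), dots)
  if (is.null(args$seed)) args$seed <- seed + 1L
  do.call(render_nuclear_stack, args)
}
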