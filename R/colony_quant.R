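#' Fit a regular spot lattice to a plate image
#'
#' Estimates pitch and origin from detrended row/column intensity
#' projections (peak positions regressed on lattice index, with an offset
#' search so partially populated grids anchor correctly), then refines
#' each spot center by local above-background centroid within a half-pitch
#' window. Spots without detectable signal keep their lattice position.
#'
#' @param image Numeric matrix (row = y, column = x).
#' @param n_rows,n_cols Expected grid dimensions (8 x 12 or 16 x 24).
#' @return A list of class `grid_fit`: `n_rows`, `n_cols`, `x`/`y`
#'   (matrices of refined center coordinates, 0-based pixels), `pitch`,
#'   `fit_residual` (RMS refined-vs-lattice displacement over spots with
#'   signal), `detect_frac` (fraction of spots with detectable signal).
#' @section Errors: If fewer than 10\% of spots carry detectable signal
#'   (e.g. a blank image) a `low_signal` error is raised advising a manual
#'   origin/pitch override.
#' @export
fit_grid <- function(image, n_rows, n_cols) {
  stopifnot(is.matrix(image), n_rows >= 2, n_cols >= 2)
  H <- nrow(image); W <- ncol(image)
  axis_fit <- function(profile, n, guess_pitch) {
    k <- max(3L, round(1.2 * guess_pitch))
    k <- min(k, length(profile))
    if (k %% 2 == 0) k <- k - 1L
    det <- pmax(profile - stats::runmed(profile, k), 0)
    sm <- stats::filter(det, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
    thr <- max(0.15 * max(sm), 1e-12)
    pk <- which(sm >= thr &
                  sm >= c(-Inf, utils::head(sm, -1)) &
                  sm > c(utils::tail(sm, -1), -Inf))
    # collapse plateau/adjacent maxima closer than half a pitch
    if (length(pk) > 1) {
      grp <- cumsum(c(TRUE, diff(pk) > guess_pitch / 2))
      pk <- vapply(split(pk, grp),
                   function(ii) ii[which.max(sm[ii])], 0L)
    }
    if (length(pk) < 2) return(NULL)
    pitch0 <- stats::median(diff(sort(pk)))
    if (!is.finite(pitch0) || pitch0 < 2) return(NULL)
    idx <- round((pk - pk[1]) / pitch0)
    fit <- stats::lm.fit(cbind(1, idx), pk)
    pitch <- fit$coefficients[2]
    a <- fit$coefficients[1]
    if (!is.finite(pitch) || pitch < 2) return(NULL)
    # offset search: which lattice index does the first detected peak hold?
    span <- max(idx)
    score <- function(j) {
      pos <- a + (seq_len(n) - 1 - j) * pitch
      if (min(pos) < 0 || max(pos) > length(profile) - 1) return(-Inf)
      sum(stats::approx(seq_along(profile) - 1, det, xout = pos,
                        rule = 2)$y)
    }
    js <- 0:max(0, n - 1 - span)
    j <- js[which.max(vapply(js, score, 0))]
    list(centers = a + (seq_len(n) - 1 - j) * pitch, pitch = pitch)
  }
  yfit <- axis_fit(rowMeans(image), n_rows, H / (n_rows + 1))
  xfit <- axis_fit(colMeans(image), n_cols, W / (n_cols + 1))
  if (is.null(yfit) || is.null(xfit)) {
    stop(structure(class = c("low_signal", "error", "condition"),
                   list(message = paste("too few detectable spots to fit a",
                                        "grid; supply a manual origin/pitch",
                                        "override"), call = NULL)))
  }
  pitch <- mean(c(yfit$pitch, xfit$pitch))
  half <- floor(pitch / 2)
  xs <- matrix(rep(xfit$centers, each = n_rows), n_rows, n_cols)
  ys <- matrix(rep(yfit$centers, n_cols), n_rows, n_cols)
  # noise floor from horizontal first differences (insensitive to the
  # smooth illumination gradient and to colony plateaus)
  noise <- stats::mad(diff(t(image))) / sqrt(2)
  sm <- box3_smooth(image)
  # refine by local centroid of above-background smoothed mass
  resid <- c()
  n_detect <- 0L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      iy <- round(ys[r, c]); ix <- round(xs[r, c])
      wy <- max(0, iy - half):min(H - 1, iy + half)
      wx <- max(0, ix - half):min(W - 1, ix + half)
      w <- sm[wy + 1, wx + 1, drop = FALSE]
      bg <- stats::median(w)
      if (max(w) - bg > max(5 * noise / 3, 1e-9)) {
        n_detect <- n_detect + 1L
        # guard (3 SD of the smoothed noise) keeps residual gradient and
        # noise mass out of the centroid
        m <- pmax(w - bg - noise, 0)
        tot <- sum(m)
        cy <- sum(rowSums(m) * wy) / tot
        cx <- sum(colSums(m) * wx) / tot
        # bound the refinement to the window center region
        if (abs(cy - ys[r, c]) < half / 2 && abs(cx - xs[r, c]) < half / 2) {
          resid <- c(resid, sqrt((cy - ys[r, c])^2 + (cx - xs[r, c])^2))
          ys[r, c] <- cy
          xs[r, c] <- cx
        }
      }
    }
  }
  frac <- n_detect / (n_rows * n_cols)
  if (frac < 0.10) {
    stop(structure(class = c("low_signal", "error", "condition"),
                   list(message = sprintf(
                     paste("only %.0f%% of spots detectable (<10%%);",
                           "supply a manual origin/pitch override"),
                     100 * frac), call = NULL)))
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, x = xs, y = ys,
                 pitch = pitch,
                 fit_residual = if (length(resid)) sqrt(mean(resid^2)) else 0,
                 detect_frac = frac),
            class = "grid_fit")
}

# 3x3 box smoothing with edge replication (cheap, shift-based).
box3_smooth <- function(img) {
  H <- nrow(img); W <- ncol(img)
  pad <- img[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  acc <- matrix(0, H, W)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + pad[dy + seq_len(H), dx + seq_len(W)]
  }
  acc / 9
}

#' Construct a nominal (evenly spaced, centered) grid for a plate image
#'
#' The manual fallback advised by `fit_grid()`'s low-signal error, and the
#' grid used for plates with nothing to detect (e.g. an all-dropout
#' diploid plate, on which every area is zero regardless of alignment).
#'
#' @param dim Image dimensions `c(ny, nx)`.
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch Spot pitch in pixels; default assumes a one-pitch border.
#' @return A `grid_fit`.
#' @export
nominal_grid <- function(dim, n_rows, n_cols, pitch = NULL) {
  if (is.null(pitch)) {
    pitch <- mean(c(dim[1] / (n_rows + 1), dim[2] / (n_cols + 1)))
  }
  cy <- (dim[1] - 1 - (n_rows - 1) * pitch) / 2 + (seq_len(n_rows) - 1) * pitch
  cx <- (dim[2] - 1 - (n_cols - 1) * pitch) / 2 + (seq_len(n_cols) - 1) * pitch
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 x = matrix(rep(cx, each = n_rows), n_rows, n_cols),
                 y = matrix(rep(cy, n_cols), n_rows, n_cols),
                 pitch = pitch, fit_residual = NA_real_, detect_frac = 0),
            class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("grid_fit: %d x %d, pitch %.2f px, residual %.2f px, %d%% spots detected\n",
              x$n_rows, x$n_cols, x$pitch, x$fit_residual,
              round(100 * x$detect_frac)))
  invisible(x)
}

#' Measure per-spot colony densities
#'
#' For every spot of a fitted grid, estimates the local background as the
#' median of the annulus between the integration disc and the cell
#' boundary (robust to smooth illumination gradients and to shoulder
#' bleed from bright neighbours), subtracts it, and integrates the
#' above-background intensity over the integration disc. Negative
#' integrals are clamped to zero: densities are physically non-negative.
#'
#' @param image Numeric plate image.
#' @param grid A `grid_fit`.
#' @param r_int Integration-disc radius as a fraction of the pitch.
#' @param r_bg Inner radius of the background annulus (fraction of pitch).
#' @return Data frame `row,col,raw_density,background` (one row per spot,
#'   grid order).
#' @export
measure_density <- function(image, grid, r_int = 0.40, r_bg = 0.44) {
  stopifnot(inherits(grid, "grid_fit"), r_bg > r_int)
  H <- nrow(image); W <- ncol(image)
  half <- floor(grid$pitch / 2)
  ri <- r_int * grid$pitch
  rb <- r_bg * grid$pitch
  out <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  out$raw_density <- NA_real_
  out$background <- NA_real_
  for (k in seq_len(nrow(out))) {
    r <- out$row[k]; c <- out$col[k]
    iy <- round(grid$y[r, c]); ix <- round(grid$x[r, c])
    wy <- max(0, iy - half):min(H - 1, iy + half)
    wx <- max(0, ix - half):min(W - 1, ix + half)
    w <- image[wy + 1, wx + 1, drop = FALSE]
    d <- sqrt(outer((wy - grid$y[r, c])^2, (wx - grid$x[r, c])^2, `+`))
    bg <- stats::median(w[d > rb])
    out$raw_density[k] <- max(0, sum(w[d <= ri] - bg))
    out$background[k] <- bg
  }
  out
}

#' Measure per-spot diploid colony areas
#'
#' Binarizes the plate by a single global automatic threshold (Otsu) and
#' counts foreground pixels within each spot's grid cell. If the image
#' shows no appreciable signal above background (e.g. a blank plate) all
#' areas are zero.
#'
#' @param image Numeric plate image (diploid-selection plate, 96 format).
#' @param grid A `grid_fit`.
#' @return Data frame `row,col,area` (pixels).
#' @export
measure_area <- function(image, grid) {
  stopifnot(inherits(grid, "grid_fit"))
  H <- nrow(image); W <- ncol(image)
  half <- floor(grid$pitch / 2)
  out <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  out$area <- 0L
  med <- stats::median(image)
  if (max(image) - med < 8 * max(stats::mad(image), 1e-12)) {
    return(out)  # blank plate: nothing above the noise floor
  }
  rng <- range(image)
  img01 <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  fg <- img01 > thr
  for (k in seq_len(nrow(out))) {
    r <- out$row[k]; c <- out$col[k]
    iy <- round(grid$y[r, c]); ix <- round(grid$x[r, c])
    wy <- max(0, iy - half):min(H - 1, iy + half)
    wx <- max(0, ix - half):min(W - 1, ix + half)
    out$area[k] <- sum(fg[wy + 1, wx + 1])
  }
  out
}

#' Min-max normalize a set of values onto [0, 1]
#'
#' `v -> (v - min) / (max - min)`. A degenerate all-equal input maps to
#' all ones (every colony is as large as the largest).
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6)) # 0, 0.5, 1
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) {
    stop("minmax_normalize requires a non-empty input", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Normalize test colony densities by diploid colony area
#'
#' Divides each raw test-plate density by its well's min-max-normalized
#' diploid area. Spots whose normalized area falls below `epsilon` are
#' flagged `failed_mating` and receive no normalized density: the min-max
#' map sends the smallest colony to exactly 0, where the division is
#' undefined, and a vanishing diploid means mating failed rather than that
#' the interaction is absent.
#'
#' @param raw Numeric vector of raw per-spot densities (>= 0).
#' @param area_norm Numeric vector in `[0, 1]`, aligned with `raw`.
#' @param epsilon Minimum usable normalized area, in (0, 1).
#' @return Data frame `raw_density,area_norm,normalized_density,qc_flag`
#'   with `qc_flag` in `{ok, failed_mating}`.
#' @examples
#' normalize_densities(10, 0.5) # normalized 20
#' @export
normalize_densities <- function(raw, area_norm, epsilon = 0.05) {
  if (length(raw) != length(area_norm)) {
    stop("raw and area_norm tables are misaligned", call. = FALSE)
  }
  stopifnot(epsilon > 0, epsilon < 1)
  ok <- area_norm >= epsilon
  data.frame(raw_density = raw, area_norm = area_norm,
             normalized_density = ifelse(ok, raw / area_norm, NA_real_),
             qc_flag = ifelse(ok, "ok", "failed_mating"))
}

# Accept either a synth_plate or a bare image matrix.
as_plate_image <- function(x) {
  if (inherits(x, "synth_plate")) x$image else as.matrix(x)
}

#' Quantify a screen: per-spot measurements from plate images
#'
#' Composes grid fitting, density extraction (test plates), area
#' extraction (diploid plates), per-screen min-max area normalization
#' (diploid areas of all plates of the screen pooled) and density
#' normalization into the per-spot measurement table.
#'
#' @param test_images List of 384-format test-plate images (matrices or
#'   `synth_plate` objects), one per source plate.
#' @param diploid_images List of matching 96-format diploid-plate images.
#' @param layout A `library_layout`; unoccupied wells are dropped.
#' @param epsilon Failed-mating threshold on normalized area.
#' @param min_area_px Absolute diploid-area floor (pixels): wells below it
#'   are flagged `failed_mating` even when min-max normalization is
#'   degenerate (e.g. every diploid absent).
#' @param per_plate If `TRUE`, min-max normalize diploid areas within each
#'   plate instead of across the screen.
#' @return Data frame with one row per technical-replicate spot:
#'   `plate,row,col,src_row,src_col,prey,raw_density,diploid_area,
#'   area_norm,normalized_density,qc_flag`.
#' @export
quantify_screen <- function(test_images, diploid_images, layout,
                            epsilon = 0.05, min_area_px = 20,
                            per_plate = FALSE) {
  stopifnot(length(test_images) == length(diploid_images))
  n_plates <- length(test_images)
  wells <- vector("list", n_plates)
  spots <- vector("list", n_plates)
  fit_or_nominal <- function(img, nr, nc, what, p) {
    tryCatch(fit_grid(img, nr, nc),
             low_signal = function(e) nominal_grid(dim(img), nr, nc),
             error = function(e) {
               stop(sprintf("%s plate %d, grid fit: %s", what, p,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  for (p in seq_len(n_plates)) {
    dimg <- as_plate_image(diploid_images[[p]])
    timg <- as_plate_image(test_images[[p]])
    dgrid <- fit_or_nominal(dimg, 8, 12, "diploid", p)
    tgrid <- fit_or_nominal(timg, 16, 24, "test", p)
    ar <- measure_area(dimg, dgrid)
    de <- measure_density(timg, tgrid)
    ar$plate <- p
    de$plate <- p
    wells[[p]] <- ar
    spots[[p]] <- de
  }
  wells <- do.call(rbind, wells)
  spots <- do.call(rbind, spots)
  if (per_plate) {
    wells$area_norm <- stats::ave(wells$area, wells$plate,
                                  FUN = minmax_normalize)
  } else {
    wells$area_norm <- minmax_normalize(wells$area)
  }
  spots$src_row <- (spots$row + 1L) %/% 2L
  spots$src_col <- (spots$col + 1L) %/% 2L
  m <- match(paste(spots$plate, spots$src_row, spots$src_col),
             paste(wells$plate, wells$row, wells$col))
  if (anyNA(m)) stop("test and diploid tables are misaligned", call. = FALSE)
  spots$diploid_area <- wells$area[m]
  spots$area_norm <- wells$area_norm[m]
  addr <- plate_address(spots$plate, spots$row, spots$col, 384L)
  spots$prey <- prey_at(layout, addr)
  spots <- spots[!is.na(spots$prey), , drop = FALSE]
  nd <- normalize_densities(spots$raw_density, spots$area_norm, epsilon)
  spots$normalized_density <- nd$normalized_density
  spots$qc_flag <- nd$qc_flag
  small <- spots$diploid_area < min_area_px
  spots$qc_flag[small] <- "failed_mating"
  spots$normalized_density[small] <- NA_real_
  rownames(spots) <- NULL
  spots[, c("plate", "row", "col", "src_row", "src_col", "prey",
            "raw_density", "diploid_area", "area_norm",
            "normalized_density", "qc_flag")]
}
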