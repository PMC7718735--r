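#' Segmentation parameters for nuclear-envelope GFP quantification
#'
#' Defaults follow the canonical confocal recipe: rolling-ball radius 20
#' pixels, nuclei retained when their area lies between 4 and 12 square
#' micrometers with circularity at least 0.3. The Gaussian blur width and
#' lateral pixel size are acquisition-dependent and must be supplied (the
#' synthetic fixtures use 0.1 um/px, making the area gate 400-1200 px).
#'
#' @param rolling_ball_radius Background structuring-element radius (px).
#' @param blur_sigma Gaussian pre-threshold blur SD (px).
#' @param min_area,max_area Particle area gate in um^2.
#' @param min_circularity Minimum circularity `4*pi*area/perimeter^2`.
#' @param pixel_size Lateral pixel size in um/px.
#' @return A validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(rolling_ball_radius = 20, blur_sigma = 2,
                                min_area = 4, max_area = 12,
                                min_circularity = 0.3, pixel_size = 0.1) {
  stopifnot(rolling_ball_radius >= 1, blur_sigma > 0,
            min_area > 0, min_area < max_area,
            min_circularity >= 0, min_circularity <= 1, pixel_size > 0)
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 blur_sigma = blur_sigma, min_area = min_area,
                 max_area = max_area, min_circularity = min_circularity,
                 pixel_size = pixel_size),
            class = "segmentation_params")
}

#' Project a z-stack to 2-D
#'
#' @param stack 3-D numeric array (`ny x nx x nz`) or a `synth_stack`.
#' @param mode `"max"` (per-pixel maximum) or `"sum"` (per-pixel sum).
#' @return 2-D numeric matrix.
#' @export
project_stack <- function(stack, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (inherits(stack, "synth_stack")) stack <- stack$stack
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("projection requires a stack with at least one z-plane",
         call. = FALSE)
  }
  nz <- dim(stack)[3]
  out <- stack[, , 1]
  if (nz > 1) {
    for (k in 2:nz) {
      out <- if (mode == "max") pmax(out, stack[, , k]) else out + stack[, , k]
    }
  }
  out
}

#' Rolling-ball style background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a disc structuring element of the given radius and subtracts
#' it. Flat backgrounds are removed exactly; features smaller than the
#' structuring element are preserved; smooth gradients leave only a small
#' slope-proportional residual. The output is pointwise non-negative and
#' never exceeds the input.
#'
#' @param image 2-D numeric matrix.
#' @param radius Structuring-element radius in pixels (>= 1).
#' @return Background-subtracted image, same dimensions.
#' @export
subtract_background <- function(image, radius = 20) {
  if (radius < 1) stop("rolling-ball radius must be >= 1", call. = FALSE)
  bg <- disc_dilate_erode(disc_dilate_erode(image, radius, erode = TRUE),
                          radius, erode = FALSE)
  pmax(image - bg, 0)
}

# --- grayscale morphology on a flat disc ------------------------------
# Sliding min/max are built with the doubling (sparse-table) trick, and
# the disc is decomposed into horizontal chords; outside the image the
# neutral element is used, so the opening never exceeds the input.

shift_cols <- function(M, d, fill) {
  W <- ncol(M)
  if (d == 0) return(M)
  out <- matrix(fill, nrow(M), W)
  if (d > 0 && d < W) {
    out[, seq_len(W - d)] <- M[, (1 + d):W]
  } else if (d < 0 && -d < W) {
    out[, (1 - d):W] <- M[, seq_len(W + d)]
  }
  out
}

shift_rows <- function(M, d, fill) {
  H <- nrow(M)
  if (d == 0) return(M)
  out <- matrix(fill, H, ncol(M))
  if (d > 0 && d < H) {
    out[seq_len(H - d), ] <- M[(1 + d):H, ]
  } else if (d < 0 && -d < H) {
    out[(1 - d):H, ] <- M[seq_len(H + d), ]
  }
  out
}

# centered sliding min/max of width 2*half+1 along each row
row_window_extreme <- function(M, half, op, fill) {
  w <- 2L * half + 1L
  T <- M
  p <- 1L
  while (2L * p <= w) {
    T <- op(T, shift_cols(T, p, fill))
    p <- 2L * p
  }
  S <- op(T, shift_cols(T, w - p, fill))
  shift_cols(S, -half, fill)
}

disc_dilate_erode <- function(img, radius, erode = TRUE) {
  op <- if (erode) pmin else pmax
  fill <- if (erode) Inf else -Inf
  r <- floor(radius)
  chords <- new.env()
  acc <- NULL
  for (dy in -r:r) {
    lx <- floor(sqrt(radius^2 - dy^2))
    key <- as.character(lx)
    if (is.null(chords[[key]])) {
      chords[[key]] <- row_window_extreme(img, lx, op, fill)
    }
    layer <- shift_rows(chords[[key]], dy, fill)
    acc <- if (is.null(acc)) layer else op(acc, layer)
  }
  acc
}

# Iterative intermeans (IsoData) threshold -- the classic "default"
# automatic threshold. Returns Inf for images with no separable
# foreground (constant input), so downstream masks come out empty.
isodata_threshold <- function(x, tol = 1e-6, max_iter = 200L) {
  x <- as.numeric(x)
  if (max(x) - min(x) < .Machine$double.eps * 100) return(Inf)
  t <- mean(range(x))
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(hi) || !length(lo)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(H - 1), if (shift[2] > 0) seq_len(W - 1) else 2:W]
    b <- lab[2:H, if (shift[2] > 0) 2:W else seq_len(W - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Crack-length perimeter: count 4-neighbour foreground/background edges
# (image border included) and correct by pi/4, which makes digitized
# discs come out at 2*pi*r (anti-bias convention for circularity).
crack_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  cracks <- sum(core & !pad[1:H, 2:(W + 1)]) +
    sum(core & !pad[3:(H + 2), 2:(W + 1)]) +
    sum(core & !pad[2:(H + 1), 1:W]) +
    sum(core & !pad[2:(H + 1), 3:(W + 2)])
  cracks * pi / 4
}

#' Segment nuclei by blur, automatic threshold and particle filtering
#'
#' Gaussian blur, iterative-intermeans (IsoData) automatic threshold,
#' 8-connected components, then retention of particles whose area lies in
#' `[min_area, max_area]` um^2 and whose circularity
#' `4*pi*area/perimeter^2` (crack-length perimeter, clamped to <= 1) is at
#' least `min_circularity`. An empty mask is a valid result. Input is
#' expected to be background-subtracted (see [subtract_background()]), so
#' segmentation is invariant to constant intensity offsets upstream.
#'
#' @param image 2-D numeric matrix (typically a background-subtracted
#'   maximum projection).
#' @param params A `segmentation_params`.
#' @return List of class `nucleus_mask`: `mask` (integer label matrix,
#'   labels 1..k in raster order) and `features` (data frame
#'   `label,area_um2,circularity`).
#' @export
segment_nuclei <- function(image, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  sm <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(image), sigma = params$blur_sigma)))
  thr <- isodata_threshold(sm)
  mask <- sm > thr
  lab <- label_components(mask)
  keep <- integer(0)
  feats <- NULL
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      m <- lab == l
      area_um2 <- sum(m) * params$pixel_size^2
      circ <- min(1, 4 * pi * sum(m) / crack_perimeter(m)^2)
      if (area_um2 >= params$min_area && area_um2 <= params$max_area &&
          circ >= params$min_circularity) {
        keep <- c(keep, l)
        feats <- rbind(feats, data.frame(label = l, area_um2 = area_um2,
                                         circularity = circ))
      }
    }
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    # relabel retained particles 1..k by raster order of first pixel
    first <- vapply(keep, function(l) which(lab == l)[1], 0L)
    ord <- order(first)
    for (j in seq_along(ord)) {
      out[lab == keep[ord[j]]] <- j
    }
    feats <- feats[ord, , drop = FALSE]
    feats$label <- seq_along(ord)
    rownames(feats) <- NULL
  } else {
    feats <- data.frame(label = integer(0), area_um2 = numeric(0),
                        circularity = numeric(0))
  }
  structure(list(mask = out, features = feats, threshold = thr,
                 params = params), class = "nucleus_mask")
}

#' Measure per-nucleus mean intensity under a mask
#'
#' Applies a nuclear label mask to an intensity image (canonically the sum
#' projection of the original stack) and reports the mean intensity per
#' labeled nucleus, carrying over area and circularity from segmentation.
#'
#' @param mask A `nucleus_mask` (or plain integer label matrix).
#' @param image Intensity image with the same dimensions.
#' @return Data frame `label,area_um2,circularity,mean_intensity`.
#' @export
measure_nuclei <- function(mask, image) {
  lab <- if (inherits(mask, "nucleus_mask")) mask$mask else mask
  if (!all(dim(lab) == dim(image))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  feats <- if (inherits(mask, "nucleus_mask")) mask$features else {
    data.frame(label = seq_len(max(lab, 0)), area_um2 = NA_real_,
               circularity = NA_real_)
  }
  feats$mean_intensity <- vapply(feats$label, function(l) {
    mean(image[lab == l])
  }, 0)
  feats
}

#' Full nuclear-envelope GFP quantification pipeline
#'
#' Maximum-projects the stack, subtracts the rolling-ball background,
#' segments nuclei (blur, IsoData threshold, area and circularity gates)
#' and measures each nucleus's mean intensity on the sum projection of
#' the original, unprocessed stack. Deterministic.
#'
#' @param stack 3-D array (`ny x nx x nz`) or `synth_stack`.
#' @param params A `segmentation_params`.
#' @return List of class `nuclei_result`: `measurements` (data frame
#'   `label,area_um2,circularity,mean_intensity`), `segmentation` (the
#'   `nucleus_mask`).
#' @export
nuclei_pipeline <- function(stack, params = segmentation_params()) {
  mx <- project_stack(stack, "max")
  sm <- project_stack(stack, "sum")
  bgsub <- subtract_background(mx, params$rolling_ball_radius)
  seg <- segment_nuclei(bgsub, params)
  structure(list(measurements = measure_nuclei(seg, sm),
                 segmentation = seg), class = "nuclei_result")
}
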