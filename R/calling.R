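#' Calibrate the positive-interaction density cutoff
#'
#' The cutoff is the 25th percentile of the densities labeled `weak` in a
#' manually categorized colony set (categories: negative, weak, medium,
#' strong). The quantile uses linear interpolation between order
#' statistics (`stats::quantile` type 7, the default convention of
#' mainstream statistics environments).
#'
#' @param labels Data frame with columns `density` (>= 0) and `label`.
#' @return The cutoff (scalar, same units as `density`).
#' @examples
#' calibrate_cutoff(data.frame(density = c(4, 8, 12, 16), label = "weak")) # 7
#' @export
calibrate_cutoff <- function(labels) {
  stopifnot(is.data.frame(labels), all(c("density", "label") %in%
                                         names(labels)))
  if (any(labels$density < 0)) {
    stop("labeled densities must be >= 0", call. = FALSE)
  }
  w <- labels$density[labels$label == "weak"]
  if (!length(w)) {
    stop("calibration requires at least one 'weak'-labeled colony",
         call. = FALSE)
  }
  unname(stats::quantile(w, 0.25, type = 7))
}

#' Call positive interactions from replicate spot densities
#'
#' A prey is called positive when at least one-half of its usable
#' technical-replicate spots have a density strictly greater than the
#' cutoff (ties at the cutoff count as below). The reported mean density
#' averages all usable replicates, including sub-cutoff ones. Preys with
#' no usable spot are emitted with status `no_call` rather than dropped:
#' absence of a diploid is not absence of an interaction.
#'
#' @param spots Data frame with columns `prey` and `density`; optional
#'   `usable` (logical, default: density not `NA`) and `bait`.
#' @param cutoff Non-negative density cutoff (see [calibrate_cutoff()]).
#' @param bait Bait identifier used when `spots` has no `bait` column.
#' @return Data frame (one row per bait/prey) with columns
#'   `bait,prey,n_spots,n_above,mean_density,positive,status`.
#' @examples
#' call_interactions(data.frame(prey = "p", density = c(10, 12, 3, 1)), 7)
#' @export
call_interactions <- function(spots, cutoff, bait = "bait") {
  stopifnot(is.data.frame(spots), all(c("prey", "density") %in% names(spots)),
            length(cutoff) == 1, cutoff >= 0)
  if (is.null(spots$bait)) spots$bait <- bait
  if (is.null(spots$usable)) spots$usable <- !is.na(spots$density)
  spots$usable <- spots$usable & !is.na(spots$density)
  key <- interaction(spots$bait, spots$prey, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(spots)), key), function(i) {
    d <- spots$density[i][spots$usable[i]]
    n <- length(d)
    if (n == 0) {
      data.frame(bait = spots$bait[i[1]], prey = spots$prey[i[1]],
                 n_spots = 0L, n_above = 0L, mean_density = NA_real_,
                 positive = NA, status = "no_call")
    } else {
      n_above <- sum(d > cutoff)
      data.frame(bait = spots$bait[i[1]], prey = spots$prey[i[1]],
                 n_spots = n, n_above = n_above, mean_density = mean(d),
                 positive = 2L * n_above >= n, status = "ok")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full screen-quantification and calling pipeline
#'
#' Composes grid fitting, density and area extraction, per-screen min-max
#' area normalization, density normalization, cutoff calibration (when
#' labels rather than a cutoff are given) and majority-rule interaction
#' calling. Deterministic for fixed inputs.
#'
#' @inheritParams quantify_screen
#' @param labels Labeled calibration colonies (data frame
#'   `density,label`), or `NULL` when `cutoff` is supplied. The labeled
#'   densities must be on the same (normalized) scale as the screen.
#' @param cutoff Pre-calibrated cutoff, or `NULL` to calibrate from
#'   `labels`.
#' @param bait Bait identifier attached to the interactome rows.
#' @return List of class `myth_screen`: `interactome` (per-prey calls, see
#'   [call_interactions()]), `spots` (per-spot measurements, see
#'   [quantify_screen()]) and `cutoff`.
#' @export
run_screen <- function(test_images, diploid_images, layout, labels = NULL,
                       cutoff = NULL, epsilon = 0.05, min_area_px = 20,
                       per_plate = FALSE, bait = "bait") {
  if (is.null(cutoff)) {
    if (is.null(labels)) {
      stop("supply either calibration labels or a cutoff", call. = FALSE)
    }
    cutoff <- calibrate_cutoff(labels)
  }
  spots <- quantify_screen(test_images, diploid_images, layout,
                           epsilon = epsilon, min_area_px = min_area_px,
                           per_plate = per_plate)
  calls <- call_interactions(
    data.frame(prey = spots$prey, density = spots$normalized_density,
               usable = spots$qc_flag == "ok"),
    cutoff, bait = bait)
  structure(list(interactome = calls, spots = spots, cutoff = cutoff,
                 bait = bait), class = "myth_screen")
}

#' @export
print.myth_screen <- function(x, ...) {
  pos <- sum(x$interactome$positive, na.rm = TRUE)
  nc <- sum(x$interactome$status == "no_call")
  cat(sprintf("myth_screen '%s': %d prey, %d positive, %d no-call, cutoff %.3g\n",
              x$bait, nrow(x$interactome), pos, nc, x$cutoff))
  invisible(x)
}
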