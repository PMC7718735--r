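#' Read and write plate images and z-stacks as 16-bit grayscale TIFF
#'
#' Images are held in memory as numeric matrices in arbitrary intensity
#' units; on disk they are 16-bit grayscale TIFF (multi-page for stacks).
#' `scale` maps intensity units to the 16-bit range: a pixel value `v` is
#' stored as `round(v) / scale` of full scale, so integer-valued images
#' within range round-trip exactly.
#'
#' @param path File path.
#' @param image Numeric matrix (or `synth_plate`).
#' @param stack 3-D numeric array (or `synth_stack`).
#' @param scale Intensity value mapped to the top of the 16-bit range.
#' @return Readers return a matrix / 3-D array in intensity units;
#'   writers return `path` invisibly.
#' @name plate_io
NULL

#' @rdname plate_io
#' @export
write_plate_image <- function(image, path, scale = 65535) {
  img <- as_plate_image(image)
  tiff::writeTIFF(pmin(pmax(round(img) / scale, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_plate_image <- function(path, scale = 65535) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * scale)
}

#' @rdname plate_io
#' @export
write_stack <- function(stack, path, scale = 65535) {
  if (inherits(stack, "synth_stack")) stack <- stack$stack
  planes <- lapply(seq_len(dim(stack)[3]), function(k) {
    pmin(pmax(round(stack[, , k]) / scale, 0), 1)
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_stack <- function(path, scale = 65535) {
  planes <- tiff::readTIFF(path, all = TRUE)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * scale)
  })
  array(unlist(planes), c(dim(planes[[1]]), length(planes)))
}

#' Read labeled calibration colonies from CSV
#'
#' Expected header: `density,label` with labels among
#' negative/weak/medium/strong.
#'
#' @param path CSV path.
#' @return Data frame `density,label`.
#' @export
read_labels <- function(path) {
  x <- utils::read.csv(path, strip.white = TRUE)
  stopifnot(all(c("density", "label") %in% names(x)))
  x$density <- as.numeric(x$density)
  x
}

#' Read and write per-spot measurement tables (TSV)
#'
#' @param spots Data frame from [quantify_screen()].
#' @param path TSV path.
#' @return `read_spots` returns the data frame; `write_spots` returns
#'   `path` invisibly.
#' @name spots_io
NULL

#' @rdname spots_io
#' @export
write_spots <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname spots_io
#' @export
read_spots <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a prey-to-term annotation table (TSV, `prey<TAB>term` per line)
#'
#' @param path TSV path (no header required; a `prey  term` header line is
#'   accepted).
#' @return Data frame `prey,term`.
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("prey", "term"))
  if (nrow(x) && identical(tolower(x$prey[1]), "prey")) {
    x <- x[-1, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Read or write a synthetic-screen configuration as YAML
#'
#' @param config A `synth_screen_config`.
#' @param path YAML path.
#' @return `read_screen_config` returns a `synth_screen_config`;
#'   `write_screen_config` returns `path` invisibly.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_screen_config <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must become maps or YAML loses the names
  x$class_mix <- as.list(x$class_mix)
  x$density_classes <- lapply(x$density_classes, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$class_mix <- unlist(raw$class_mix)
  raw$density_classes <- lapply(raw$density_classes, unlist)
  do.call(synth_screen_config, raw)
}
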