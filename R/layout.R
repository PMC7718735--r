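#' Plate addresses for arrayed colony screens
#'
#' A plate address locates a well or spot by 1-based (plate, row, column)
#' coordinates in either 96-well (8 x 12) or 384-spot (16 x 24) format.
#' Rows may be given as letters (A-H for 96, A-P for 384) or integers; they
#' are normalized to integers internally. All bench-facing coordinates in
#' this package are 1-based and row-major; pixel coordinates elsewhere are
#' 0-based image offsets -- the boundary between the two conventions is
#' this constructor.
#'
#' @param plate Integer vector of source-plate indices (>= 1).
#' @param row Row labels: letters ("A".."P") or 1-based integers.
#' @param col 1-based column indices.
#' @param format Plate format, `96` or `384` (recycled).
#' @return A data frame of class `plate_address` with integer columns
#'   `plate`, `row`, `col` and `format`.
#' @examples
#' plate_address(1, "A", 1, 96)
#' plate_address(2, 16, 24, 384)
#' @export
plate_address <- function(plate, row, col, format = 96) {
  n <- max(length(plate), length(row), length(col), length(format))
  plate <- rep_len(as.integer(plate), n)
  row <- rep_len(parse_row(row), n)
  col <- rep_len(as.integer(col), n)
  format <- rep_len(as.integer(format), n)
  if (!all(format %in% c(96L, 384L))) {
    stop("plate format must be 96 or 384", call. = FALSE)
  }
  nr <- ifelse(format == 96L, 8L, 16L)
  nc <- ifelse(format == 96L, 12L, 24L)
  bad <- is.na(plate) | plate < 1L | is.na(row) | row < 1L | row > nr |
    is.na(col) | col < 1L | col > nc
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid %d-format address: plate %s, row %s, col %s",
                 format[i], plate[i], row[i], col[i]), call. = FALSE)
  }
  structure(data.frame(plate = plate, row = row, col = col, format = format),
            class = c("plate_address", "data.frame"))
}

# Row labels: letters A-P (case-insensitive) or integerish strings/numbers.
parse_row <- function(row) {
  if (is.numeric(row)) return(as.integer(row))
  row <- toupper(trimws(as.character(row)))
  out <- suppressWarnings(as.integer(row))
  alpha <- is.na(out) & row %in% LETTERS[1:16]
  out[alpha] <- match(row[alpha], LETTERS)
  out
}

#' Load an arrayed prey-library layout from CSV
#'
#' The layout maps 96-well source-plate addresses to prey identifiers. The
#' file must have header columns `plate,row,col,prey`; rows may address any
#' subset of positions (empty wells are allowed), rows starting with `#` are
#' ignored, and row labels may be letters or integers.
#'
#' @param path Path to a layout CSV.
#' @param n_plates Number of source plates; defaults to the largest plate
#'   index present.
#' @return A `library_layout`: a list with `entries` (a `plate_address`
#'   data frame with a `prey` column) and `n_plates`.
#' @seealso [prey_at()], [map_96_to_384()], [write_layout()]
#' @export
load_layout <- function(path, n_plates = NULL) {
  raw <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                         strip.white = TRUE)
  need <- c("plate", "row", "col", "prey")
  if (!all(need %in% names(raw))) {
    stop("layout CSV must have header columns plate,row,col,prey",
         call. = FALSE)
  }
  plate <- suppressWarnings(as.integer(raw$plate))
  row <- parse_row(raw$row)
  col <- suppressWarnings(as.integer(raw$col))
  bad <- which(is.na(plate) | is.na(row) | is.na(col) |
                 row < 1L | row > 8L | col < 1L | col > 12L | plate < 1L)
  if (length(bad)) {
    # +1 for the header line so the message points at the file line
    stop(sprintf("malformed layout row at line %d: plate=%s row=%s col=%s",
                 bad[1] + 1L, raw$plate[bad[1]], raw$row[bad[1]],
                 raw$col[bad[1]]), call. = FALSE)
  }
  if (any(!nzchar(raw$prey))) {
    stop("empty prey identifier in layout", call. = FALSE)
  }
  key <- paste(plate, row, col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate layout address: plate %s, row %s, col %s",
                 strsplit(d, " ")[[1]][1], strsplit(d, " ")[[1]][2],
                 strsplit(d, " ")[[1]][3]), call. = FALSE)
  }
  entries <- plate_address(plate, row, col, 96L)
  entries$prey <- raw$prey
  library_layout(entries, n_plates)
}

#' Construct a library layout from an address table
#'
#' @param entries A `plate_address` data frame (96 format) with a `prey`
#'   column, or a plain data frame with columns `plate,row,col,prey`.
#' @param n_plates Number of source plates (defaults to max plate index).
#' @return A `library_layout` object.
#' @export
library_layout <- function(entries, n_plates = NULL) {
  if (!inherits(entries, "plate_address")) {
    ad <- plate_address(entries$plate, entries$row, entries$col, 96L)
    ad$prey <- as.character(entries$prey)
    entries <- ad
  }
  if (any(entries$format != 96L)) {
    stop("layout entries must use 96-well addresses", call. = FALSE)
  }
  if (is.null(n_plates)) n_plates <- max(entries$plate, 1L)
  if (any(entries$plate > n_plates)) {
    stop("layout entry addresses a plate beyond n_plates", call. = FALSE)
  }
  key <- paste(entries$plate, entries$row, entries$col)
  if (anyDuplicated(key)) stop("duplicate layout address", call. = FALSE)
  structure(list(entries = entries, n_plates = as.integer(n_plates)),
            class = "library_layout")
}

#' @export
print.library_layout <- function(x, ...) {
  cat(sprintf("library_layout: %d prey across %d x 96-well plate(s)\n",
              nrow(x$entries), x$n_plates))
  invisible(x)
}

#' Write a library layout back to CSV
#'
#' Inverse of [load_layout()]: `load_layout(write_layout(x, f))` restores
#' the same entries.
#'
#' @param layout A `library_layout`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  e <- layout$entries
  utils::write.csv(data.frame(plate = e$plate, row = e$row, col = e$col,
                              prey = e$prey),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand 96-well addresses to 384-format technical quadruplicates
#'
#' Replicate pinning expands each 96-well source position into a contiguous
#' 2x2 block on the 384-spot test plate (standard RoToR geometry): source
#' (r, c) maps to rows 2r-1..2r and columns 2c-1..2c. The 96 source wells
#' partition the 384 positions into disjoint blocks.
#'
#' @param addr A `plate_address` in 96 format.
#' @return A `plate_address` in 384 format with 4 rows per input address,
#'   plus `src_row`/`src_col` columns recording the source well.
#' @examples
#' map_96_to_384(plate_address(1, "A", 1))$row # 1 1 2 2
#' @export
map_96_to_384 <- function(addr) {
  if (!inherits(addr, "plate_address") || any(addr$format != 96L)) {
    stop("map_96_to_384 expects 96-format plate addresses", call. = FALSE)
  }
  n <- nrow(addr)
  idx <- rep(seq_len(n), each = 4L)
  dr <- rep(c(0L, 0L, 1L, 1L), n)
  dc <- rep(c(0L, 1L, 0L, 1L), n)
  out <- plate_address(addr$plate[idx],
                       2L * addr$row[idx] - 1L + dr,
                       2L * addr$col[idx] - 1L + dc,
                       384L)
  out$src_row <- addr$row[idx]
  out$src_col <- addr$col[idx]
  out
}

#' Collapse 384-format addresses to their 96-well source position
#'
#' Inverse of the quadrant map: 384 position (r, c) originates from 96 well
#' (ceiling(r/2), ceiling(c/2)).
#'
#' @param addr A `plate_address` in 384 format.
#' @return A `plate_address` in 96 format (one row per input row).
#' @export
map_384_to_96 <- function(addr) {
  if (!inherits(addr, "plate_address") || any(addr$format != 384L)) {
    stop("map_384_to_96 expects 384-format plate addresses", call. = FALSE)
  }
  plate_address(addr$plate, (addr$row + 1L) %/% 2L, (addr$col + 1L) %/% 2L,
                96L)
}

#' Look up the prey at a plate address
#'
#' Addresses in 384 format are first resolved to their source 96 well via
#' the inverse quadrant map, so all four technical-quadruplicate spots
#' return the same prey. Unoccupied wells return `NA_character_` (the empty
#' marker), not an error.
#'
#' @param layout A `library_layout`.
#' @param addr A `plate_address` in 96 or 384 format.
#' @return Character vector of prey identifiers, `NA` where unoccupied.
#' @export
prey_at <- function(layout, addr) {
  stopifnot(inherits(layout, "library_layout"))
  if (!inherits(addr, "plate_address")) {
    stop("prey_at expects a plate_address", call. = FALSE)
  }
  a <- addr
  if (any(a$format == 384L)) {
    i <- a$format == 384L
    a96 <- map_384_to_96(a[i, , drop = FALSE])
    a$row[i] <- a96$row
    a$col[i] <- a96$col
    a$format[i] <- 96L
  }
  e <- layout$entries
  m <- match(paste(a$plate, a$row, a$col), paste(e$plate, e$row, e$col))
  ifelse(is.na(m), NA_character_, e$prey[m])
}
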