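#' @title Well addressing for crystallization and library plates
#'
#' @description
#' Crystallization plates are 96-well sitting-drop plates with three subwell
#' drops per well (MRC-3 style): a well address is a row letter (A-H), a
#' column number (1-12) and a drop letter (a-c), e.g. `"B7c"`. Library
#' source plates are 384-well (rows A-P, columns 1-24) or 1536-well (rows
#' A-Z then AA-AF, columns 1-48). Indices are 0-based internally; display
#' strings use 1-based columns.
#'
#' `parse_crystal_well()` and `parse_library_well()` are vectorized and
#' case-insensitive; `format_crystal_well()` and `format_library_well()`
#' produce the canonical display form (upper-case rows, lower-case drop
#' letter), so `parse` followed by `format` is the identity on every valid
#' address. `enumerate_wells()` lists a source-plate format in row-major
#' order.
#'
#' @param text Character vector of well addresses.
#' @param row,col,drop Integer vectors of 0-based indices.
#' @param format Source-plate format: 384 or 1536.
#' @return `parse_crystal_well()`: a data frame with integer columns `row`,
#'   `col`, `drop`. `parse_library_well()` and `enumerate_wells()`: a data
#'   frame with `row`, `col` and the display string `well`. Formatters
#'   return character vectors.
#' @name well-addressing
#' @examples
#' parse_crystal_well(c("A1a", "H12c"))
#' format_crystal_well(1, 6, 2)   # "B7c"
#' parse_library_well("AF48", 1536)
#' nrow(enumerate_wells(384))
NULL

# Excel-style row letters: 0 -> "A", 25 -> "Z", 26 -> "AA", 31 -> "AF"
.row_letter <- function(idx) {
  ifelse(idx < 26L, LETTERS[idx + 1L],
         paste0(LETTERS[idx %/% 26L], LETTERS[idx %% 26L + 1L]))
}

.row_index <- function(letters_part) {
  chars <- strsplit(toupper(letters_part), "")
  vapply(chars, function(ch) {
    vals <- match(ch, LETTERS)
    if (anyNA(vals)) return(NA_integer_)
    as.integer(sum(vals * 26L^(rev(seq_along(vals)) - 1L)) - 1L)
  }, integer(1))
}

#' @rdname well-addressing
#' @export
parse_crystal_well <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  geom <- plate_geometry()$crystal
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]{1,2})([A-Za-z])$", text))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed crystal well address: '", text[bad][1],
         "' (expected e.g. 'B7c')", call. = FALSE)
  }
  parts <- do.call(rbind, m)
  row <- .row_index(parts[, 2])
  col <- as.integer(parts[, 3]) - 1L
  drop <- match(tolower(parts[, 4]), letters) - 1L
  if (any(row >= geom$rows)) {
    i <- which(row >= geom$rows)[1]
    stop("row '", toupper(parts[i, 2]), "' out of range in '", text[i],
         "' (rows A-", .row_letter(geom$rows - 1L), ")", call. = FALSE)
  }
  if (any(col < 0L | col >= geom$cols)) {
    i <- which(col < 0L | col >= geom$cols)[1]
    stop("column '", parts[i, 3], "' out of range in '", text[i],
         "' (columns 1-", geom$cols, ")", call. = FALSE)
  }
  if (any(drop >= geom$drops)) {
    i <- which(drop >= geom$drops)[1]
    stop("drop '", tolower(parts[i, 4]), "' out of range in '", text[i],
         "' (drops a-", letters[geom$drops], ")", call. = FALSE)
  }
  data.frame(row = row, col = col, drop = drop)
}

#' @rdname well-addressing
#' @export
format_crystal_well <- function(row, col, drop) {
  if (is.data.frame(row)) {
    col <- row$col; drop <- row$drop; row <- row$row
  }
  geom <- plate_geometry()$crystal
  stopifnot(all(row >= 0 & row < geom$rows),
            all(col >= 0 & col < geom$cols),
            all(drop >= 0 & drop < geom$drops))
  paste0(.row_letter(as.integer(row)), as.integer(col) + 1L,
         letters[as.integer(drop) + 1L])
}

.library_geom <- function(format) {
  lib <- plate_geometry()$library
  key <- as.character(as.integer(format))
  if (!key %in% names(lib)) {
    stop("unknown library plate format '", format, "' (supported: ",
         paste(names(lib), collapse = ", "), ")", call. = FALSE)
  }
  lib[[key]]
}

#' @rdname well-addressing
#' @export
parse_library_well <- function(text, format) {
  stopifnot(is.character(text), length(text) >= 1)
  geom <- .library_geom(format)
  m <- regmatches(text, regexec("^([A-Za-z]{1,2})([0-9]{1,2})$", text))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("malformed library well address: '", text[bad][1], "'", call. = FALSE)
  }
  parts <- do.call(rbind, m)
  row <- .row_index(parts[, 2])
  col <- as.integer(parts[, 3]) - 1L
  if (anyNA(row) || any(row >= geom$rows)) {
    i <- which(is.na(row) | row >= geom$rows)[1]
    stop("row '", toupper(parts[i, 2]), "' out of range in '", text[i],
         "' for the ", geom$rows * geom$cols, "-well format (rows A-",
         .row_letter(geom$rows - 1L), ")", call. = FALSE)
  }
  if (any(col < 0L | col >= geom$cols)) {
    i <- which(col < 0L | col >= geom$cols)[1]
    stop("column '", parts[i, 3], "' out of range in '", text[i],
         "' for the ", geom$rows * geom$cols, "-well format (columns 1-",
         geom$cols, ")", call. = FALSE)
  }
  data.frame(row = row, col = col,
             well = paste0(.row_letter(row), col + 1L))
}

#' @rdname well-addressing
#' @export
format_library_well <- function(row, col, format) {
  if (is.data.frame(row)) {
    if (missing(format)) format <- col
    col <- row$col; row <- row$row
  }
  geom <- .library_geom(format)
  stopifnot(all(row >= 0 & row < geom$rows), all(col >= 0 & col < geom$cols))
  paste0(.row_letter(as.integer(row)), as.integer(col) + 1L)
}

#' @rdname well-addressing
#' @export
enumerate_wells <- function(format) {
  geom <- .library_geom(format)
  row <- rep(seq_len(geom$rows) - 1L, each = geom$cols)
  col <- rep(seq_len(geom$cols) - 1L, times = geom$rows)
  data.frame(row = row, col = col,
             well = paste0(.row_letter(row), col + 1L))
}

#' Plate record constructor
#'
#' A barcoded plate registered to a campaign. `kind` is fixed at creation:
#' `"crystal"` for crystallization plates, `"library"` for fragment source
#' plates.
#'
#' @param barcode Non-empty barcode string, unique within a campaign.
#' @param kind `"crystal"` or `"library"`.
#' @param temperature Storage temperature, `"4C"` or `"RT"`.
#' @param campaign Campaign name the plate belongs to.
#' @return A list of class `plate_record`.
#' @export
plate_record <- function(barcode, kind = c("crystal", "library"),
                         temperature = c("RT", "4C"), campaign = "") {
  kind <- match.arg(kind)
  temperature <- match.arg(temperature)
  if (!is.character(barcode) || length(barcode) != 1L || !nzchar(barcode)) {
    stop("plate barcode must be a non-empty string", call. = FALSE)
  }
  structure(list(barcode = barcode, kind = kind, temperature = temperature,
                 campaign = campaign),
            class = "plate_record")
}
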