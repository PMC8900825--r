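#' Convert a clicked image pixel to an in-drop dispense offset
#'
#' Drop targets are picked with a single click on the crystallization-drop
#' image; the click is converted to a millimetre offset from the drop-well
#' centre using the image calibration (`x = (px - cx) * mm_per_px`,
#' `y = (py - cy) * mm_per_px`; image convention, +x right and +y down).
#' Offsets beyond the drop-well half-extent are clamped and flagged.
#'
#' @param px,py Pixel coordinates of the click (vectorized).
#' @param well_centre_px Numeric length-2: pixel coordinates of the drop
#'   centre.
#' @param mm_per_px Image scale, millimetres per pixel (> 0).
#' @param half_extent_mm Maximum |offset| allowed; defaults to the
#'   configured drop half-extent.
#' @return Data frame with `x_mm`, `y_mm` and logical `clamped`.
#' @export
#' @examples
#' pixel_to_offset(150, 80, c(100, 100), 0.01)
pixel_to_offset <- function(px, py, well_centre_px, mm_per_px,
                            half_extent_mm = NULL) {
  stopifnot(is.numeric(px), is.numeric(py), length(well_centre_px) == 2,
            mm_per_px > 0)
  if (is.null(half_extent_mm)) {
    half_extent_mm <- plate_geometry()$crystal$drop_half_extent_mm
  }
  x <- (px - well_centre_px[1]) * mm_per_px
  y <- (py - well_centre_px[2]) * mm_per_px
  clamped <- abs(x) > half_extent_mm | abs(y) > half_extent_mm
  data.frame(x_mm = pmin(pmax(x, -half_extent_mm), half_extent_mm),
             y_mm = pmin(pmax(y, -half_extent_mm), half_extent_mm),
             clamped = clamped)
}

#' Plan fragment soaks into selected drops
#'
#' Pairs selected drop targets with fragments and a transfer volume,
#' producing the planned soak records that the transfer-list builder, soak
#' timer and dispense-report ingest operate on.
#'
#' @param targets Data frame of drop targets: `plate_barcode`, `well`
#'   (crystal well with drop letter, e.g. `"B7c"`), and optionally `x_mm`,
#'   `y_mm` in-drop offsets (default 0).
#' @param fragment_ids Character vector, one fragment per target.
#' @param transfer_nl Transfer volume(s) in nL; must be positive exact
#'   multiples of the droplet quantum (2.5 nL by default).
#' @return A `soak_records` data frame: `plate_barcode`, `well`,
#'   `fragment_id`, `transfer_nl`, `x_mm`, `y_mm`, `status`
#'   (`planned`/`dispensed`/`failed`), `soak_start`, `soak_stop`,
#'   `error_msg`.
#' @export
plan_soaks <- function(targets, fragment_ids, transfer_nl) {
  stopifnot(is.data.frame(targets),
            all(c("plate_barcode", "well") %in% names(targets)))
  n <- nrow(targets)
  if (length(fragment_ids) != n) {
    stop("need one fragment_id per target (", n, " targets, ",
         length(fragment_ids), " fragments)", call. = FALSE)
  }
  transfer_nl <- rep_len(transfer_nl, n)
  .check_quantum(transfer_nl)
  wells <- format_crystal_well(parse_crystal_well(targets$well))
  key <- paste(targets$plate_barcode, wells)
  if (anyDuplicated(key)) {
    stop("duplicate destination drop: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  out <- data.frame(
    plate_barcode = targets$plate_barcode,
    well = wells,
    fragment_id = fragment_ids,
    transfer_nl = transfer_nl,
    x_mm = if ("x_mm" %in% names(targets)) targets$x_mm else 0,
    y_mm = if ("y_mm" %in% names(targets)) targets$y_mm else 0,
    status = "planned",
    soak_start = as.POSIXct(NA),
    soak_stop = as.POSIXct(NA),
    error_msg = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("soak_records", "data.frame")
  out
}

.check_quantum <- function(transfer_nl) {
  q <- droplet_quantum()
  if (any(transfer_nl <= 0)) {
    stop("transfer volume must be positive", call. = FALSE)
  }
  rem <- transfer_nl / q
  bad <- abs(rem - round(rem)) > 1e-9
  if (any(bad)) {
    stop("transfer volume ", transfer_nl[bad][1],
         " nL is not a multiple of the ", q, " nL droplet quantum",
         call. = FALSE)
  }
}

#' Build an acoustic-dispenser transfer list
#'
#' Turns planned soaks into the cherry-pick style picklist the acoustic
#' liquid handler consumes: one row per soak, in input order, with the
#' source well looked up from the fragment library. The destination well
#' column holds the plain 96-well address; the subwell drop is encoded in
#' the destination offsets (the configured drop-centre offset plus the
#' user's in-drop offset), since all three drops share one well footprint.
#'
#' @param soaks A `soak_records` data frame (see [plan_soaks()]), or any
#'   data frame with `plate_barcode`, `well`, `fragment_id`, `transfer_nl`
#'   and optional `x_mm`, `y_mm`.
#' @param library The [fragment_library()] resolving fragment to source
#'   well.
#' @return A `transfer_list` data frame with columns `source_plate`,
#'   `source_well`, `dest_plate`, `dest_well`, `transfer_nl`,
#'   `dest_x_offset`, `dest_y_offset` (offsets in mm, 3 decimals).
#' @export
build_transfer_list <- function(soaks, library) {
  stopifnot(is.data.frame(soaks), inherits(library, "fragment_library"))
  req <- c("plate_barcode", "well", "fragment_id", "transfer_nl")
  missing <- setdiff(req, names(soaks))
  if (length(missing)) {
    stop("soaks table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(soaks)
  if (n == 0) {
    return(.as_transfer_list(data.frame(
      source_plate = character(), source_well = character(),
      dest_plate = character(), dest_well = character(),
      transfer_nl = numeric(), dest_x_offset = numeric(),
      dest_y_offset = numeric(), stringsAsFactors = FALSE)))
  }
  .check_quantum(soaks$transfer_nl)
  idx <- match(soaks$fragment_id, library$fragments$fragment_id)
  if (anyNA(idx)) {
    stop("fragment '", soaks$fragment_id[is.na(idx)][1],
         "' not found in library '", library$name, "'", call. = FALSE)
  }
  addr <- parse_crystal_well(soaks$well)
  key <- paste(soaks$plate_barcode, format_crystal_well(addr))
  if (anyDuplicated(key)) {
    stop("duplicate destination drop: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  geom <- plate_geometry()$crystal
  centres <- do.call(rbind, geom$drop_centre_offset_mm)  # drops x 2
  x_user <- if ("x_mm" %in% names(soaks)) soaks$x_mm else rep(0, n)
  y_user <- if ("y_mm" %in% names(soaks)) soaks$y_mm else rep(0, n)
  .as_transfer_list(data.frame(
    source_plate = library$fragments$source_plate[idx],
    source_well = library$fragments$source_well[idx],
    dest_plate = soaks$plate_barcode,
    dest_well = paste0(.row_letter(addr$row), addr$col + 1L),
    transfer_nl = soaks$transfer_nl,
    dest_x_offset = round(centres[addr$drop + 1L, 1] + x_user, 3),
    dest_y_offset = round(centres[addr$drop + 1L, 2] + y_user, 3),
    stringsAsFactors = FALSE))
}

.as_transfer_list <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("transfer_list", "data.frame")
  df
}

# CSV column headers follow the cherry-pick picklist convention
.transfer_csv_cols <- c("Source Plate Barcode", "Source Well",
                        "Destination Plate Barcode", "Destination Well",
                        "Transfer Volume", "Destination Well X Offset",
                        "Destination Well Y Offset")

#' Write and read a transfer list CSV
#'
#' The picklist CSV uses the cherry-pick column convention (Source Plate
#' Barcode, Source Well, Destination Plate Barcode, Destination Well,
#' Transfer Volume, Destination Well X Offset, Destination Well Y Offset);
#' volumes in nL, offsets in mm with 3 decimals. `read_transfer_list()`
#' inverts `write_transfer_list()` exactly.
#'
#' @param tl A `transfer_list`.
#' @param path CSV path.
#' @return `write_transfer_list()`: `path` invisibly;
#'   `read_transfer_list()`: a `transfer_list`.
#' @export
write_transfer_list <- function(tl, path) {
  stopifnot(inherits(tl, "transfer_list"))
  out <- data.frame(
    a = tl$source_plate, b = tl$source_well, c = tl$dest_plate,
    d = tl$dest_well, e = as.character(tl$transfer_nl),
    f = sprintf("%.3f", tl$dest_x_offset),
    g = sprintf("%.3f", tl$dest_y_offset))
  names(out) <- .transfer_csv_cols
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transfer_list
#' @export
read_transfer_list <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!identical(names(df), .transfer_csv_cols)) {
    stop("not a transfer-list CSV: unexpected columns", call. = FALSE)
  }
  .as_transfer_list(data.frame(
    source_plate = df[[1]], source_well = df[[2]], dest_plate = df[[3]],
    dest_well = df[[4]], transfer_nl = as.numeric(df[[5]]),
    dest_x_offset = round(as.numeric(df[[6]]), 3),
    dest_y_offset = round(as.numeric(df[[7]]), 3),
    stringsAsFactors = FALSE))
}

#' DMSO concentration after an acoustic transfer
#'
#' Final DMSO percentage in the drop when `transfer_nl` of fragment stock in
#' neat DMSO is dispensed into a drop of `drop_nl`:
#' `100 * transfer_nl / (drop_nl + transfer_nl)`. Used when optimizing the
#' soak time / DMSO tolerance of a crystal system before a full-library
#' soak.
#'
#' @param drop_nl Crystallization drop volume, nL (> 0).
#' @param transfer_nl Dispensed volume, nL (> 0).
#' @return DMSO percentage in (0, 100).
#' @export
#' @examples
#' dmso_percent(475, 25)  # 5 %
dmso_percent <- function(drop_nl, transfer_nl) {
  if (any(drop_nl <= 0) || any(transfer_nl <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  100 * transfer_nl / (drop_nl + transfer_nl)
}

#' Start the soak timer on planned records
#'
#' Called when the transfer list is exported to the dispenser; the soak
#' duration then runs until the dispense report stops it.
#'
#' @param records A `soak_records` data frame.
#' @param time Timestamp (POSIXct).
#' @return The updated records.
#' @export
start_soak <- function(records, time = Sys.time()) {
  stopifnot(inherits(records, "soak_records"))
  records$soak_start <- as.POSIXct(time)
  records
}

#' Elapsed soak duration in whole minutes
#'
#' Minutes between the soak start and either the soak stop (set when the
#' dispense report arrived — the timer is frozen thereafter) or `now`,
#' floored to whole minutes to match the per-minute display refresh.
#'
#' @param records A `soak_records` data frame with `soak_start` set.
#' @param now Current time (POSIXct).
#' @return Integer vector of elapsed minutes, one per record.
#' @export
soak_elapsed <- function(records, now = Sys.time()) {
  stopifnot(is.data.frame(records))
  if (any(is.na(records$soak_start))) {
    stop("soak_start is not set for record ",
         which(is.na(records$soak_start))[1], call. = FALSE)
  }
  end <- records$soak_stop
  end[is.na(end)] <- as.POSIXct(now)
  secs <- as.numeric(difftime(end, records$soak_start, units = "secs"))
  if (any(secs < 0)) {
    stop("soak end time precedes soak_start for record ",
         which(secs < 0)[1], call. = FALSE)
  }
  as.integer(floor(secs / 60))
}

#' Ingest an acoustic-dispenser status report
#'
#' Matches report rows to planned soaks on the key (destination plate,
#' destination well + drop); first match wins. Matched records become
#' `dispensed` (status `OK`) or `failed` (message retained) and their soak
#' timer is stopped. Report rows that match no planned soak — or a soak
#' already matched — are returned as discrepancies rather than raising.
#'
#' @param records A `soak_records` data frame.
#' @param report A data frame with columns `dest_barcode`, `dest_well`
#'   (with drop letter), `status`, `message`, or a path to such a CSV.
#' @param time Timestamp recorded as `soak_stop` on matched records.
#' @return List with `records` (updated) and `discrepancies` (unmatched
#'   report rows with a `reason` column).
#' @export
ingest_dispense_report <- function(records, report, time = Sys.time()) {
  stopifnot(inherits(records, "soak_records"))
  if (is.character(report)) {
    report <- utils::read.csv(report, colClasses = "character")
  }
  req <- c("dest_barcode", "dest_well", "status", "message")
  missing <- setdiff(req, names(report))
  if (length(missing)) {
    stop("malformed dispense report: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec_key <- paste(records$plate_barcode, tolower(records$well))
  matched <- logical(nrow(records))
  disc <- report[0, , drop = FALSE]
  disc$reason <- character(0)
  for (i in seq_len(nrow(report))) {
    key <- paste(report$dest_barcode[i], tolower(report$dest_well[i]))
    j <- which(rec_key == key & !matched)[1]
    if (is.na(j)) {
      reason <- if (key %in% rec_key) "duplicate report row" else
        "no planned soak at this drop"
      row <- report[i, , drop = FALSE]
      row$reason <- reason
      disc <- rbind(disc, row)
      next
    }
    matched[j] <- TRUE
    ok <- grepl("^ok$", trimws(report$status[i]), ignore.case = TRUE)
    records$status[j] <- if (ok) "dispensed" else "failed"
    if (!ok) {
      msg <- report$message[i]
      records$error_msg[j] <- if (nzchar(msg)) msg else report$status[i]
    }
    records$soak_stop[j] <- as.POSIXct(time)
  }
  rownames(disc) <- NULL
  list(records = records, discrepancies = disc)
}

#' Plan a DMSO-free (redissolve) soak
#'
#' For crystal systems that do not tolerate DMSO: fragment stock is
#' dispensed onto an empty crystallization plate, air-dried, and redissolved
#' in crystallization buffer before crystals are added. Destination drops
#' are auto-assigned row-major, one fragment per subwell drop, and a
#' tracking sheet records the per-well steps (dispensed, dried,
#' redissolved), all initially pending.
#'
#' @param fragment_ids Fragments to deposit.
#' @param dest_plate Barcode of the empty destination plate.
#' @param library The [fragment_library()].
#' @param transfer_nl Volume per drop, nL (quantum multiple).
#' @return List with `transfers` (a `transfer_list`) and `sheet` (data
#'   frame `well`, `fragment_id`, `dispensed`, `dried`, `redissolved`).
#' @export
plan_redissolve <- function(fragment_ids, dest_plate, library,
                            transfer_nl = 25) {
  stopifnot(inherits(library, "fragment_library"))
  geom <- plate_geometry()$crystal
  capacity <- geom$rows * geom$cols * geom$drops
  n <- length(fragment_ids)
  if (n > capacity) {
    stop("more fragments (", n, ") than destination drops (", capacity, ")",
         call. = FALSE)
  }
  if (n == 0) {
    tl <- build_transfer_list(
      data.frame(plate_barcode = character(), well = character(),
                 fragment_id = character(), transfer_nl = numeric()),
      library)
    sheet <- data.frame(well = character(), fragment_id = character(),
                        dispensed = character(), dried = character(),
                        redissolved = character(), stringsAsFactors = FALSE)
    return(list(transfers = tl, sheet = sheet))
  }
  # row-major with drop fastest: A1a, A1b, A1c, A2a, ...
  k <- seq_len(n) - 1L
  wells <- format_crystal_well(row = k %/% (geom$cols * geom$drops),
                               col = (k %/% geom$drops) %% geom$cols,
                               drop = k %% geom$drops)
  soaks <- plan_soaks(
    data.frame(plate_barcode = dest_plate, well = wells,
               stringsAsFactors = FALSE),
    fragment_ids, transfer_nl)
  sheet <- data.frame(well = wells, fragment_id = fragment_ids,
                      dispensed = "pending", dried = "pending",
                      redissolved = "pending", stringsAsFactors = FALSE)
  list(transfers = build_transfer_list(soaks, library), sheet = sheet)
}
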