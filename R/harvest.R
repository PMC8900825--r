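#' Build the fishing definition for the harvesting station
#'
#' One row per dispensed soak, ordered by destination plate then well, with
#' the columns the harvesting station needs to walk the operator through the
#' drops: plate barcode, well + drop, fragment and soak start time. Failed
#' or still-planned soaks are excluded.
#'
#' @param records A `soak_records` data frame (see [plan_soaks()]).
#' @return Data frame with `plate_barcode`, `well`, `fragment_id`,
#'   `soak_start`.
#' @export
build_fishing_definition <- function(records) {
  stopifnot(is.data.frame(records))
  keep <- records$status == "dispensed"
  if (!any(keep)) {
    stop("no dispensed soaks: nothing to fish", call. = FALSE)
  }
  out <- records[keep, c("plate_barcode", "well", "fragment_id",
                         "soak_start")]
  addr <- parse_crystal_well(out$well)
  ord <- order(out$plate_barcode, addr$row, addr$col, addr$drop)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Merge harvesting results with puck/pin barcode scans
#'
#' The harvesting robot reports, per visited drop, whether a crystal was
#' fished, skipped or failed; the barcode station reports the scanned puck
#' and pin positions in the order crystals were mounted. The k-th fished row
#' is joined to the scan row with sequence k; skipped and failed rows
#' consume no scan. When a pin barcode is present it is cross-checked and a
#' mismatch flagged in the record's comment, not resolved.
#'
#' @param shifter Data frame (or CSV path) of harvesting results:
#'   `plate_barcode`, `well` (with drop letter), `status`
#'   (`fished`/`skipped`/`failed`), `timestamp`, `comment`; optionally
#'   `fragment_id`.
#' @param puck_scan Data frame (or CSV path) of scans: `sequence` (1-based
#'   mount order), `puck`, `pin` (1 to the puck capacity, 16 by default),
#'   optional `pin_barcode`.
#' @return A `fish_records` data frame: `plate_barcode`, `well`,
#'   `fragment_id`, `puck`, `pin`, `pin_barcode`, `fished_at`, `status`,
#'   `comment`.
#' @export
merge_fishing_results <- function(shifter, puck_scan) {
  if (is.character(shifter)) {
    shifter <- utils::read.csv(shifter, colClasses = "character")
  }
  if (is.character(puck_scan)) {
    puck_scan <- utils::read.csv(puck_scan, colClasses = "character")
  }
  req <- c("well", "status", "timestamp")
  missing <- setdiff(req, names(shifter))
  if (length(missing)) {
    stop("shifter results are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(c("sequence", "puck", "pin") %in% names(puck_scan))) {
    stop("puck scan needs columns sequence, puck, pin", call. = FALSE)
  }
  bad <- !shifter$status %in% c("fished", "skipped", "failed")
  if (any(bad)) {
    stop("unknown shifter status '", shifter$status[bad][1], "'",
         call. = FALSE)
  }
  pins <- as.integer(puck_scan$pin)
  max_pins <- plate_geometry()$puck_pins
  if (any(pins < 1 | pins > max_pins)) {
    stop("pin position out of range 1-", max_pins, call. = FALSE)
  }
  if (anyDuplicated(paste(puck_scan$puck, pins))) {
    stop("duplicate (puck, pin) in scan", call. = FALSE)
  }
  fished <- which(shifter$status == "fished")
  scans <- puck_scan[order(as.integer(puck_scan$sequence)), , drop = FALSE]
  if (length(fished) != nrow(scans)) {
    stop("cannot reconcile fished crystals with scans: ", length(fished),
         " fished vs ", nrow(scans), " scanned positions", call. = FALSE)
  }
  n <- nrow(shifter)
  out <- data.frame(
    plate_barcode = if ("plate_barcode" %in% names(shifter))
      shifter$plate_barcode else NA_character_,
    well = format_crystal_well(parse_crystal_well(shifter$well)),
    fragment_id = if ("fragment_id" %in% names(shifter))
      shifter$fragment_id else NA_character_,
    puck = NA_character_, pin = NA_integer_, pin_barcode = NA_character_,
    fished_at = shifter$timestamp,
    status = shifter$status,
    comment = if ("comment" %in% names(shifter)) shifter$comment
      else NA_character_,
    stringsAsFactors = FALSE)
  if (length(fished)) {
    out$puck[fished] <- scans$puck
    out$pin[fished] <- as.integer(scans$pin)
    if ("pin_barcode" %in% names(scans)) {
      out$pin_barcode[fished] <- scans$pin_barcode
    }
  }
  class(out) <- c("fish_records", "data.frame")
  out
}

#' Export the data-collection sample sheet
#'
#' One row per fished crystal, sorted by puck then pin, ready for the
#' beamline sample changer: sample name
#' (`campaign-plate-welldrop`), the fragment's canonical SMILES (resolved
#' from the library so the downstream restraint generator can use it), the
#' chosen processing pipeline and the molecular-replacement model filename.
#'
#' @param records A `fish_records` data frame (see
#'   [merge_fishing_results()]).
#' @param library The [fragment_library()].
#' @param campaign Campaign name used in sample names.
#' @param pipeline Data-processing pipeline to request: one of `"gopy"`,
#'   `"autoPROC"`, `"xia2dials"`.
#' @param mr_model Molecular-replacement model filename.
#' @param path Optional CSV path; when given the sheet is also written out.
#' @return Data frame with `puck`, `pin`, `sample_name`, `fragment_smiles`,
#'   `processing_pipeline`, `mr_model`.
#' @export
export_collection_sheet <- function(records, library, campaign,
                                    pipeline = c("gopy", "autoPROC",
                                                 "xia2dials"),
                                    mr_model = "model.pdb", path = NULL) {
  pipeline <- match.arg(pipeline)
  stopifnot(inherits(library, "fragment_library"), is.data.frame(records))
  recs <- records[records$status == "fished", , drop = FALSE]
  if (nrow(recs) && (anyNA(recs$puck) || anyNA(recs$pin))) {
    stop("fished record without puck/pin assignment (run ",
         "merge_fishing_results first)", call. = FALSE)
  }
  smiles <- vapply(recs$fragment_id, function(id) lookup_smiles(library, id),
                   character(1))
  sheet <- data.frame(
    puck = recs$puck, pin = recs$pin,
    sample_name = paste(campaign, recs$plate_barcode, recs$well, sep = "-"),
    fragment_smiles = unname(smiles),
    processing_pipeline = pipeline,
    mr_model = mr_model,
    stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_name)) {
    stop("sample names are not unique: ",
         sheet$sample_name[duplicated(sheet$sample_name)][1], call. = FALSE)
  }
  sheet <- sheet[order(sheet$puck, sheet$pin), , drop = FALSE]
  rownames(sheet) <- NULL
  if (!is.null(path)) {
    utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  }
  sheet
}

#' Read back a written collection sheet
#'
#' @param path CSV path written by [export_collection_sheet()].
#' @return The sheet data frame with `pin` as integer.
#' @export
read_collection_sheet <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$pin <- as.integer(df$pin)
  df
}
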