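#' Read a fragment library from an SDF file
#'
#' Ingests a fragment/compound library from an SDF (V2000) file. Each record
#' must carry the library catalogue code and its source well as named data
#' fields. SMILES are taken from a SMILES data field when present, otherwise
#' derived from the connection table; either way they are canonicalized at
#' ingest so later lookups are stable across runs.
#'
#' @param path Path to the SDF file.
#' @param id_field Name of the SDF data field holding the fragment catalogue
#'   code (e.g. `"BTB00030"`).
#' @param well_field Name of the SDF data field holding the source well
#'   (e.g. `"A3"`).
#' @param name Library name.
#' @param plate_format Source-plate format: 384 or 1536.
#' @param source_plate Barcode of the source plate; used when the SDF has no
#'   per-record plate field.
#' @param plate_field,smiles_field,conc_field Optional names of SDF data
#'   fields holding the source-plate barcode, a SMILES string, and the stock
#'   concentration (mM in DMSO). When `NULL`, fields named `"SMILES"` and
#'   `"Conc_mM"` are used if present.
#' @return A `fragment_library`: a list with `name`, `plate_format` and
#'   `fragments` (a data frame with columns `fragment_id`, `smiles`,
#'   `source_plate`, `source_well`, `stock_conc`, `name`).
#' @export
#' @examples
#' sdf <- fixture_library_sdf(tempfile(fileext = ".sdf"), n = 4)
#' lib <- read_library_sdf(sdf)
#' lib$fragments[, c("fragment_id", "source_well")]
read_library_sdf <- function(path, id_field = "ID", well_field = "Well",
                             name = sub("\\.sdf$", "", basename(path)),
                             plate_format = 384, source_plate = "LIB-001",
                             plate_field = NULL, smiles_field = NULL,
                             conc_field = NULL) {
  if (!file.exists(path)) {
    stop("SDF file not found: ", path, call. = FALSE)
  }
  sdfset <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok)) {
    stop("unreadable SDF record(s) at index ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  blocks <- ChemmineR::datablock(sdfset)
  get_field <- function(i, field) {
    val <- blocks[[i]][field]
    if (is.null(val) || is.na(val) || !nzchar(val)) {
      stop("SDF record ", i, " is missing the '", field, "' data field",
           call. = FALSE)
    }
    unname(val)
  }
  n <- length(sdfset)
  ids <- vapply(seq_len(n), get_field, character(1), field = id_field)
  wells <- vapply(seq_len(n), get_field, character(1), field = well_field)
  if (anyDuplicated(ids)) {
    stop("duplicate fragment_id in library: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  wells <- parse_library_well(wells, plate_format)$well  # canonical form
  plates <- if (!is.null(plate_field)) {
    vapply(seq_len(n), get_field, character(1), field = plate_field)
  } else {
    rep(source_plate, n)
  }
  key <- paste(plates, wells)
  if (anyDuplicated(key)) {
    stop("duplicate source well in library: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  if (is.null(smiles_field) &&
      all(vapply(blocks, function(b) "SMILES" %in% names(b), logical(1)))) {
    smiles_field <- "SMILES"
  }
  smiles <- if (!is.null(smiles_field)) {
    vapply(seq_len(n), get_field, character(1), field = smiles_field)
  } else {
    as.character(ChemmineR::sdf2smiles(sdfset))
  }
  smiles <- canonical_smiles(smiles, ids)
  if (is.null(conc_field) &&
      all(vapply(blocks, function(b) "Conc_mM" %in% names(b), logical(1)))) {
    conc_field <- "Conc_mM"
  }
  conc <- if (!is.null(conc_field)) {
    as.numeric(vapply(seq_len(n), get_field, character(1), field = conc_field))
  } else {
    rep(NA_real_, n)
  }
  names_fld <- vapply(seq_len(n), function(i) {
    val <- blocks[[i]]["Name"]
    if (is.null(val) || is.na(val)) "" else unname(val)
  }, character(1))
  fragment_library(
    name = name, plate_format = plate_format,
    fragments = data.frame(
      fragment_id = ids, smiles = smiles, source_plate = plates,
      source_well = wells, stock_conc = conc, name = names_fld,
      stringsAsFactors = FALSE))
}

#' Fragment library constructor
#'
#' @param name Library name.
#' @param plate_format 384 or 1536.
#' @param fragments Data frame with columns `fragment_id`, `smiles`,
#'   `source_plate`, `source_well`; optionally `stock_conc` (mM) and `name`.
#' @return A list of class `fragment_library`.
#' @export
fragment_library <- function(name, plate_format, fragments) {
  stopifnot(is.data.frame(fragments))
  required <- c("fragment_id", "smiles", "source_plate", "source_well")
  missing <- setdiff(required, names(fragments))
  if (length(missing)) {
    stop("fragments table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"stock_conc" %in% names(fragments)) fragments$stock_conc <- NA_real_
  if (!"name" %in% names(fragments)) fragments$name <- ""
  if (anyDuplicated(fragments$fragment_id)) {
    stop("fragment_id values must be unique within a library", call. = FALSE)
  }
  key <- paste(fragments$source_plate, fragments$source_well)
  if (anyDuplicated(key)) {
    stop("no two fragments may share a source well: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  if (any(!nzchar(fragments$smiles))) {
    stop("every fragment needs a non-empty SMILES", call. = FALSE)
  }
  .library_geom(plate_format)  # validates the format
  rownames(fragments) <- NULL
  structure(list(name = name, plate_format = as.integer(plate_format),
                 fragments = fragments),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("Fragment library '", x$name, "': ", nrow(x$fragments),
      " fragments on a ", x$plate_format, "-well source plate\n", sep = "")
  print(utils::head(x$fragments[, c("fragment_id", "smiles", "source_well")]))
  if (nrow(x$fragments) > 6) cat("... and", nrow(x$fragments) - 6, "more\n")
  invisible(x)
}

#' @export
length.fragment_library <- function(x) nrow(x$fragments)

#' Look up the canonical SMILES of a library fragment
#'
#' Returns the canonical SMILES stored at ingest, suitable for handing to an
#' external ligand restraint generator. Fragment IDs are case-sensitive.
#'
#' @param library A `fragment_library`.
#' @param fragment_id Catalogue code of the fragment.
#' @return The canonical SMILES string.
#' @export
lookup_smiles <- function(library, fragment_id) {
  stopifnot(inherits(library, "fragment_library"))
  i <- match(fragment_id, library$fragments$fragment_id)
  if (is.na(i)) {
    stop("fragment '", fragment_id, "' not found in library '",
         library$name, "'", call. = FALSE)
  }
  library$fragments$smiles[i]
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to their canonical form. Unparseable input
#' is reported with the offending identifier.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional identifiers used in error messages.
#' @return Character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  tags <- paste0("m", seq_along(smiles))
  input <- paste(paste(smiles, tags), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = input)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]")
  can <- vapply(parts, `[`, character(1), 1)
  got <- vapply(parts, function(p) p[length(p)], character(1))
  res <- can[match(tags, got)]
  if (anyNA(res) || any(!nzchar(res))) {
    bad <- which(is.na(res) | !nzchar(res))[1]
    stop("unparseable SMILES for '", ids[bad], "': ", smiles[bad],
         call. = FALSE)
  }
  res
}

#' Export a fragment library as CSV
#'
#' Writes one row per fragment with columns `fragment_id`, `smiles`,
#' `source_plate`, `source_well`, `stock_conc` for record-keeping.
#'
#' @param library A `fragment_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  stopifnot(inherits(library, "fragment_library"))
  cols <- c("fragment_id", "smiles", "source_plate", "source_well",
            "stock_conc")
  utils::write.csv(library$fragments[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
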