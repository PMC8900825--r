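#' Plate geometry and instrument configuration
#'
#' Reads the packaged geometry configuration: crystallization-plate layout
#' (rows, columns, subwell drops, drop half-extent and per-drop centre
#' offsets), library source-plate formats (384 and 1536), the acoustic
#' droplet quantum and the puck pin count. The result is cached for the
#' session. Pass `path` to use a custom configuration file with the same
#' structure, e.g. to add a plate kind.
#'
#' All well indices in this package are 0-based internally; display strings
#' use 1-based column numbers (so internal `(row 1, col 6)` displays as
#' `"B7"`).
#'
#' @param path Optional path to a YAML geometry file; defaults to the
#'   configuration shipped with the package.
#' @return A named list with elements `crystal`, `library`,
#'   `droplet_quantum_nl` and `puck_pins`.
#' @export
#' @examples
#' geom <- plate_geometry()
#' geom$crystal$rows
#' geom$droplet_quantum_nl
plate_geometry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.geom_cache$default)) {
      return(.geom_cache$default)
    }
    path <- system.file("config", "plate_geometry.yaml",
                        package = "fragcampaign", mustWork = TRUE)
    geom <- .validate_geometry(yaml::read_yaml(path))
    .geom_cache$default <- geom
    return(geom)
  }
  .validate_geometry(yaml::read_yaml(path))
}

.geom_cache <- new.env(parent = emptyenv())

.validate_geometry <- function(geom) {
  for (key in c("crystal", "library", "droplet_quantum_nl", "puck_pins")) {
    if (is.null(geom[[key]])) {
      stop("geometry configuration is missing '", key, "'", call. = FALSE)
    }
  }
  cr <- geom$crystal
  stopifnot(cr$rows >= 1, cr$cols >= 1, cr$drops >= 1,
            cr$drop_half_extent_mm > 0)
  if (length(cr$drop_centre_offset_mm) != cr$drops) {
    stop("crystal plate declares ", cr$drops, " drops but ",
         length(cr$drop_centre_offset_mm), " drop centre offsets", call. = FALSE)
  }
  for (fmt in names(geom$library)) {
    lf <- geom$library[[fmt]]
    if (lf$rows * lf$cols != as.integer(fmt)) {
      stop("library format ", fmt, " geometry (", lf$rows, "x", lf$cols,
           ") does not multiply to ", fmt, call. = FALSE)
    }
  }
  stopifnot(geom$droplet_quantum_nl > 0, geom$puck_pins >= 1)
  geom
}

#' @rdname plate_geometry
#' @export
droplet_quantum <- function() plate_geometry()$droplet_quantum_nl
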