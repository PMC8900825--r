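#' Specification for a synthetic screening campaign
#'
#' Collects the knobs of the synthetic-data generator: campaign size,
#' per-stage outcome rates and the dataset resolution model. The defaults
#' emulate a full-scale academic campaign (two 96x3 crystallization plates
#' soaked from a 384-well library plate) with outcome rates shaped like a
#' realistic funnel: a small harvesting loss, resolutions normally
#' distributed around 1.7 Angstrom (truncated at 0.9), RSCC triage passing
#' a few percent of datasets and most passers verified by inspection.
#'
#' @param seed Integer seed; all draws in [simulate_campaign()] and the
#'   catalogue shuffle in [make_library()] come from it.
#' @param n_fragments Library size (at most the 384-well plate capacity).
#' @param n_plates Number of crystallization plates soaked.
#' @param drops_per_plate Targeted drops per plate (at most 288 on a 96x3
#'   plate); `n_plates * drops_per_plate` crystals are soaked.
#' @param dispense_fail_rate Probability a planned transfer fails at the
#'   dispenser.
#' @param fish_skip_rate Probability a dispensed drop is skipped at
#'   harvesting (no crystal mounted).
#' @param resolution_mean,resolution_sd Dataset resolution model,
#'   Normal(mean, sd) in Angstrom truncated below at 0.9. The tail above
#'   the 2.5 Angstrom cutoff stands in for crystals that yield no usable
#'   dataset.
#' @param rscc_pass_rate Probability a dataset passes the RSCC >= 0.7
#'   triage.
#' @param verify_given_pass_rate Probability an RSCC passer is verified as
#'   a true protein-fragment complex.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_fragments = 96L, n_plates = 2L,
                         drops_per_plate = 96L, dispense_fail_rate = 0,
                         fish_skip_rate = 0.029, resolution_mean = 1.7,
                         resolution_sd = 0.55, rscc_pass_rate = 0.081,
                         verify_given_pass_rate = 0.854) {
  spec <- list(seed = as.integer(seed), n_fragments = as.integer(n_fragments),
               n_plates = as.integer(n_plates),
               drops_per_plate = as.integer(drops_per_plate),
               dispense_fail_rate = dispense_fail_rate,
               fish_skip_rate = fish_skip_rate,
               resolution_mean = resolution_mean,
               resolution_sd = resolution_sd,
               rscc_pass_rate = rscc_pass_rate,
               verify_given_pass_rate = verify_given_pass_rate)
  probs <- c("dispense_fail_rate", "fish_skip_rate", "rscc_pass_rate",
             "verify_given_pass_rate")
  for (p in probs) {
    if (spec[[p]] < 0 || spec[[p]] > 1) {
      stop(p, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  counts <- c("n_fragments", "n_plates", "drops_per_plate")
  for (p in counts) {
    if (spec[[p]] < 1) stop(p, " must be positive", call. = FALSE)
  }
  geom <- plate_geometry()$crystal
  if (spec$drops_per_plate > geom$rows * geom$cols * geom$drops) {
    stop("drops_per_plate exceeds the ", geom$rows * geom$cols * geom$drops,
         "-drop plate capacity", call. = FALSE)
  }
  stopifnot(spec$resolution_sd > 0, spec$resolution_mean > 0)
  structure(spec, class = "fixture_spec")
}

# built-in catalogue of small fragment-like molecules (rule-of-3 scale)
.fragment_catalogue <- c(
  "Oc1ccccc1", "c1ccncc1", "CC(=O)Nc1ccccc1", "c1ccc2[nH]ccc2c1",
  "OC(=O)c1ccccc1", "Nc1ccccc1", "COc1ccccc1", "Cc1ccc(O)cc1",
  "O=C1CCCCC1", "C1CCNCC1", "C1CCOC1", "O=C1CCCN1",
  "c1cc[nH]c1", "c1ccsc1", "c1ccoc1", "Cn1ccnc1",
  "OCc1ccccc1", "NC(=O)c1ccccc1", "Clc1ccccc1", "Fc1ccccc1F",
  "CC(=O)Nc1c(F)cccc1F", "CC1CCC(=O)O1", "N#Cc1ccccc1", "O=Cc1ccc(F)cc1",
  "NS(=O)(=O)c1ccccc1", "Nc1ncccn1", "OC(=O)C1CC1", "C1CNCCN1",
  "C1COCCN1", "Cc1nc2ccccc2[nH]1", "Oc1ccc2ccccc2c1", "Cc1cccc(C)n1",
  "NCc1ccccc1", "CC(=O)c1ccccc1", "OC(=O)c1ccco1", "OC(=O)c1cccs1",
  "Nc1ccc(O)cc1", "COC(=O)c1ccccc1", "CC(=O)N1CCCC1", "O=c1cc[nH]c(=O)[nH]1",
  "OCC(O)CO", "NC(=O)C1CCCCC1", "Clc1ccc(Cl)cc1", "Brc1ccccn1",
  "CN(C)c1ccccc1", "CSc1ccccc1", "OC1CCCCC1", "CC(=O)NC1CC1",
  "Oc1ccccc1O", "Oc1ccccn1", "CNC(=O)c1ccccc1", "NCCO")

# run body with the RNG seeded from `seed`, restoring the caller's RNG state
.with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(body)
}

#' Generate a synthetic fragment library SDF
#'
#' Draws `n_fragments` deterministic SMILES from a built-in catalogue of
#' fragment-like molecules (shuffled under the seed; recycled with distinct
#' IDs when the catalogue is smaller than the request), assigns source
#' wells row-major on a 384-well plate, and writes an SDF whose bytes are a
#' pure function of the spec — the same spec always produces an identical
#' file.
#'
#' @param spec A [fixture_spec()].
#' @param path Output SDF path.
#' @return The [fragment_library()] read back from the written file.
#' @export
make_library <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_fragments
  wells <- enumerate_wells(384)
  if (n > nrow(wells)) {
    stop("library capacity exceeded: ", n, " fragments on a ",
         nrow(wells), "-well plate", call. = FALSE)
  }
  smiles <- .with_seed(spec$seed, {
    idx <- sample.int(length(.fragment_catalogue))
    .fragment_catalogue[rep_len(idx, n)]
  })
  ids <- sprintf("FRAG%04d", seq_len(n))
  names(smiles) <- ids
  sdfset <- ChemmineR::smiles2sdf(smiles)
  ChemmineR::datablock(sdfset) <- lapply(seq_len(n), function(i) {
    c(ID = ids[i], Well = wells$well[i], SMILES = unname(smiles[i]),
      Conc_mM = "100")
  })
  ChemmineR::write.SDF(sdfset, path)
  # normalize the program/timestamp line so identical specs give
  # byte-identical files
  lines <- readLines(path)
  lines <- sub("^ OpenBabel.*$", " fragcampaign 2D", lines)
  writeLines(lines, path)
  read_library_sdf(path, name = "synthetic-library",
                   source_plate = "LIB-SYN-001")
}

#' Convenience: write a small synthetic library SDF
#'
#' Thin wrapper over [make_library()] used in examples and tests.
#'
#' @param path Output SDF path.
#' @param n Number of fragments.
#' @param seed Seed for the catalogue shuffle.
#' @return `path`, invisibly.
#' @export
fixture_library_sdf <- function(path, n = 8, seed = 1L) {
  make_library(fixture_spec(seed = seed, n_fragments = n), path)
  invisible(path)
}

#' Simulate a full screening campaign
#'
#' Runs the generator end to end: synthetic library, drop targets on
#' `n_plates` crystallization plates, planned soaks, a dispenser status
#' report with Bernoulli failures, harvesting results with Bernoulli skips,
#' puck/pin scans in mount order, and per-dataset results (truncated-normal
#' resolutions, RSCC passers at `rscc_pass_rate` drawn in `[0.7, 1]` and
#' non-passers below 0.7, verification among passers). All randomness comes
#' from `spec$seed`. Every file the laboratory stations would exchange is
#' written to `dir` in its standard CSV/SDF format.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param campaign Campaign name used in sample names.
#' @return List with the in-memory objects (`library`, `soaks`, `records`,
#'   `fish`, `results`, `summary`) and `files`, the named paths of
#'   everything written.
#' @export
simulate_campaign <- function(spec, dir = tempfile("campaign"),
                              campaign = "SYN-CAMPAIGN") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(library = "library.sdf", targets = "targets.csv",
             transfers = "transfer_list.csv",
             dispense_report = "dispense_report.csv",
             fishing_definition = "fishing_definition.csv",
             shifter_results = "shifter_results.csv",
             puck_scan = "puck_scan.csv", results = "dataset_results.csv",
             summary = "summary.csv")
  paths <- stats::setNames(file.path(dir, paths), names(paths))
  lib <- make_library(spec, paths[["library"]])

  geom <- plate_geometry()$crystal
  n_soaked <- spec$n_plates * spec$drops_per_plate
  k <- seq_len(spec$drops_per_plate) - 1L
  wells <- format_crystal_well(row = k %/% (geom$cols * geom$drops),
                               col = (k %/% geom$drops) %% geom$cols,
                               drop = k %% geom$drops)
  base_time <- as.POSIXct("2024-01-15 10:00:00", tz = "UTC")

  sim <- .with_seed(spec$seed + 1L, {
    targets <- data.frame(
      plate_barcode = rep(sprintf("XTAL-%03d", seq_len(spec$n_plates)),
                          each = spec$drops_per_plate),
      well = rep(wells, spec$n_plates),
      x_mm = round(stats::runif(n_soaked, -0.5, 0.5), 3),
      y_mm = round(stats::runif(n_soaked, -0.5, 0.5), 3),
      stringsAsFactors = FALSE)
    frag_ids <- rep_len(lib$fragments$fragment_id, n_soaked)
    soaks <- start_soak(plan_soaks(targets, frag_ids, transfer_nl = 25),
                        base_time)

    fail <- stats::runif(n_soaked) < spec$dispense_fail_rate
    report <- data.frame(
      dest_barcode = soaks$plate_barcode, dest_well = soaks$well,
      status = ifelse(fail, "failed", "OK"),
      message = ifelse(fail, "no source volume", ""),
      stringsAsFactors = FALSE)
    records <- ingest_dispense_report(soaks, report,
                                      time = base_time + 3600)$records

    fdef <- build_fishing_definition(records)
    n_disp <- nrow(fdef)
    skip <- stats::runif(n_disp) < spec$fish_skip_rate
    shifter <- data.frame(
      plate_barcode = fdef$plate_barcode, well = fdef$well,
      fragment_id = fdef$fragment_id,
      status = ifelse(skip, "skipped", "fished"),
      timestamp = format(base_time + 7200 + 60 * seq_len(n_disp),
                         "%Y-%m-%dT%H:%M:%S"),
      comment = "", stringsAsFactors = FALSE)
    n_fished <- sum(!skip)
    pins <- plate_geometry()$puck_pins
    scan <- data.frame(
      sequence = seq_len(n_fished),
      puck = sprintf("PUCK-%03d", (seq_len(n_fished) - 1L) %/% pins + 1L),
      pin = (seq_len(n_fished) - 1L) %% pins + 1L,
      pin_barcode = sprintf("PIN-%05d", seq_len(n_fished)),
      stringsAsFactors = FALSE)
    fish <- merge_fishing_results(shifter, scan)

    res <- stats::rnorm(n_fished, spec$resolution_mean, spec$resolution_sd)
    while (any(res < 0.9)) {
      res[res < 0.9] <- stats::rnorm(sum(res < 0.9), spec$resolution_mean,
                                     spec$resolution_sd)
    }
    pass <- stats::runif(n_fished) < spec$rscc_pass_rate
    rscc <- ifelse(pass, stats::runif(n_fished, 0.70, 0.98),
                   stats::runif(n_fished, 0.05, 0.69))
    verified <- pass & stats::runif(n_fished) < spec$verify_given_pass_rate
    fished <- fish[fish$status == "fished", ]
    results <- data.frame(
      sample_name = paste(campaign, fished$plate_barcode, fished$well,
                          sep = "-"),
      resolution = round(res, 2), rscc = round(rscc, 3),
      verified = verified, stringsAsFactors = FALSE)
    list(targets = targets, soaks = soaks, report = report,
         records = records, fdef = fdef, shifter = shifter, scan = scan,
         fish = fish, results = results)
  })

  utils::write.csv(sim$targets, paths[["targets"]], row.names = FALSE,
                   quote = FALSE)
  write_transfer_list(build_transfer_list(sim$soaks, lib),
                      paths[["transfers"]])
  utils::write.csv(sim$report, paths[["dispense_report"]],
                   row.names = FALSE)
  fdef_out <- sim$fdef
  fdef_out$soak_start <- format(fdef_out$soak_start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(fdef_out, paths[["fishing_definition"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$shifter, paths[["shifter_results"]],
                   row.names = FALSE)
  utils::write.csv(sim$scan, paths[["puck_scan"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$results, paths[["results"]], row.names = FALSE,
                   quote = FALSE)

  summ <- summarize_campaign(n_soaked, sum(sim$fish$status == "fished"),
                             sim$results)
  write_summary(summ, paths[["summary"]])
  list(library = lib, targets = sim$targets, soaks = sim$records,
       fish = sim$fish, results = sim$results, summary = summ,
       files = paths)
}
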