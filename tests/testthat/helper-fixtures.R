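# Shared fixture builders. Everything is generated in code at test time.

# a small library built directly from SMILES, no SDF round-trip
toy_library <- function(smiles, ids = sprintf("FT%02d", seq_along(smiles)),
                        plate = "LIB-T-001") {
  wells <- enumerate_wells(384)$well[seq_along(smiles)]
  fragment_library(
    name = "toy", plate_format = 384,
    fragments = data.frame(fragment_id = ids,
                           smiles = canonical_smiles(smiles, ids),
                           source_plate = plate, source_well = wells,
                           stringsAsFactors = FALSE))
}

toy_smiles <- c("Oc1ccccc1", "c1ccncc1", "CC(=O)Nc1ccccc1",
                "OCC(O)CO", "C1CCNCC1", "Clc1ccc(Cl)cc1",
                "O=c1cc[nH]c(=O)[nH]1", "CSc1ccccc1")

# brute-force MaxMin oracle: the subset of size 2 maximizing the pairwise
# distance, from an explicit distance matrix
bruteforce_best_pair <- function(d) {
  best <- NULL
  best_val <- -Inf
  n <- nrow(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > best_val) {
        best_val <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  list(pair = best, dist = best_val)
}

# library of k catalogue molecules relabelled so that one member of the
# brute-force optimal pair carries the lexicographically smallest id (the
# seed-0 MaxMin start)
toy_library_optimal_start <- function(k, seed = 1) {
  set.seed(seed)
  smiles <- sample(toy_smiles, k)
  lib <- toy_library(smiles)
  d <- tanimoto_distances(fragment_fingerprints(lib))
  best <- bruteforce_best_pair(d)$pair
  ids <- sprintf("FT%02d", 50 + seq_len(k))
  ids[best[1]] <- "FT01"
  toy_library(smiles, ids = ids)
}

# planned soaks on one plate, fragments recycled from a library
toy_soaks <- function(lib, n, transfer_nl = 25) {
  geom <- plate_geometry()$crystal
  k <- seq_len(n) - 1L
  wells <- format_crystal_well(row = k %/% (geom$cols * geom$drops),
                               col = (k %/% geom$drops) %% geom$cols,
                               drop = k %% geom$drops)
  plan_soaks(data.frame(plate_barcode = "XT-01", well = wells,
                        stringsAsFactors = FALSE),
             rep_len(lib$fragments$fragment_id, n), transfer_nl)
}
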