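#' Structural fingerprints and Tanimoto distances for a library
#'
#' `fragment_fingerprints()` computes a binary structural fingerprint for
#' every fragment in the library (a 1024-bit path-based fingerprint over the
#' molecular graph). `tanimoto_distances()` turns the fingerprints into a
#' full pairwise distance matrix, `d = 1 - Tanimoto similarity`.
#'
#' @param library A `fragment_library`.
#' @param fp An `FPset` as returned by `fragment_fingerprints()`.
#' @return `fragment_fingerprints()`: an [ChemmineR::FPset-class] with one
#'   row per fragment, named by `fragment_id`. `tanimoto_distances()`: a
#'   symmetric numeric matrix with zero diagonal.
#' @export
fragment_fingerprints <- function(library) {
  stopifnot(inherits(library, "fragment_library"))
  frags <- library$fragments
  smi <- frags$smiles
  names(smi) <- frags$fragment_id
  sdf <- tryCatch(ChemmineR::smiles2sdf(smi),
                  error = function(e) stop("unparseable SMILES encountered: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(sdf) != nrow(frags)) {
    # the converter silently drops molecules it cannot parse
    bad <- setdiff(frags$fragment_id, ChemmineR::sdfid(sdf))
    stop("unparseable SMILES encountered for fragment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  ChemmineR::cid(fp) <- frags$fragment_id
  fp
}

#' @rdname fragment_fingerprints
#' @export
tanimoto_distances <- function(fp) {
  n <- length(ChemmineR::cid(fp))
  d <- vapply(seq_len(n), function(i) {
    1 - ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
  }, numeric(n))
  dimnames(d) <- list(ChemmineR::cid(fp), ChemmineR::cid(fp))
  (d + t(d)) / 2  # enforce exact symmetry against float jitter
}

#' Select a maximally diverse fragment subset (greedy MaxMin)
#'
#' Greedy MaxMin selection over binary structural fingerprints with Tanimoto
#' distance: starting from a seeded initial pick, each step adds the
#' fragment whose minimum distance to the already-selected set is largest.
#' This is the standard diversity-picking procedure used to assemble, e.g.,
#' the most diverse few hundred members of a screening library.
#'
#' The selection is deterministic given `seed`: `seed = 0` starts from the
#' lexicographically smallest `fragment_id`; any other seed picks the start
#' uniformly at random under that seed. Ties in the minimum distance are
#' broken by `fragment_id` order. Because the growth is greedy, the
#' selection for `n = k` is a prefix of the selection for `n = k + 1` under
#' the same seed.
#'
#' @param library A `fragment_library`.
#' @param n Number of fragments to select, `1 <= n <= length(library)`.
#' @param seed Integer controlling the initial pick.
#' @return Character vector of `n` distinct fragment IDs, in pick order.
#' @export
#' @examples
#' sdf <- fixture_library_sdf(tempfile(fileext = ".sdf"), n = 8)
#' lib <- read_library_sdf(sdf)
#' select_diverse(lib, 3)
select_diverse <- function(library, n, seed = 0L) {
  stopifnot(inherits(library, "fragment_library"))
  size <- nrow(library$fragments)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > size) {
    stop("n must be between 1 and the library size (", size, ")",
         call. = FALSE)
  }
  n <- as.integer(n)
  ids <- library$fragments$fragment_id
  fp <- fragment_fingerprints(library)
  start <- if (seed == 0L) {
    which(ids == min(ids))
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(size, 1L)
  }
  selected <- integer(n)
  selected[1L] <- start
  if (n > 1L) {
    # min distance from each candidate to the selected set, updated per pick
    mind <- 1 - ChemmineR::fpSim(fp[start], fp, method = "Tanimoto",
                                 sorted = FALSE)
    mind[start] <- -Inf
    for (k in 2L:n) {
      cand <- which(mind == max(mind))
      pick <- cand[order(ids[cand])][1L]
      selected[k] <- pick
      d_new <- 1 - ChemmineR::fpSim(fp[pick], fp, method = "Tanimoto",
                                    sorted = FALSE)
      mind <- pmin(mind, d_new)
      mind[pick] <- -Inf
    }
  }
  ids[selected]
}
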