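#' Summarize a screening campaign as the outcome funnel
#'
#' Computes the campaign success funnel: crystals soaked, crystals mounted,
#' crystals diffracting to at least the resolution cutoff, datasets passing
#' the real-space correlation (RSCC) triage threshold among those, and
#' human-verified protein-fragment complexes among the RSCC passers. All
#' percentages are relative to the number soaked; crystal-level rows
#' (mounted, diffracting) are printed to whole percent, dataset-level rows
#' (RSCC pass, verified) to one decimal, rounding half away from zero.
#'
#' The RSCC threshold is inclusive (`rscc >= threshold` passes); verified
#' status is an input flag (human judgement on the fitted density), not
#' computed.
#'
#' @param n_soaked Number of crystals soaked.
#' @param mounted Number of crystals mounted, or a vector (e.g. of sample
#'   names) whose length is used.
#' @param results Data frame of per-dataset results with columns
#'   `resolution` (Angstrom, high-resolution cutoff), `rscc` (in `[-1, 1]`,
#'   `NA` when not fitted) and logical `verified`; or `NULL` when building
#'   from pre-tabulated counts (see [campaign_summary()]).
#' @param res_cutoff Resolution cutoff in Angstrom (default 2.5): a crystal
#'   counts as diffracting when `resolution <= res_cutoff`.
#' @param rscc_threshold RSCC triage threshold (default 0.7).
#' @return A `campaign_summary` object; see [campaign_summary()].
#' @export
#' @examples
#' res <- data.frame(resolution = c(1.6, 1.9, 2.8),
#'                   rscc = c(0.82, 0.4, NA),
#'                   verified = c(TRUE, FALSE, FALSE))
#' summarize_campaign(5, 4, res)
summarize_campaign <- function(n_soaked, mounted, results,
                               res_cutoff = 2.5, rscc_threshold = 0.7) {
  n_mounted <- if (length(mounted) == 1L && is.numeric(mounted)) {
    as.integer(mounted)
  } else {
    length(mounted)
  }
  stopifnot(is.data.frame(results),
            all(c("resolution", "rscc", "verified") %in% names(results)))
  if (any(!is.na(results$resolution) & results$resolution <= 0)) {
    stop("resolutions must be positive", call. = FALSE)
  }
  if (any(!is.na(results$rscc) & abs(results$rscc) > 1)) {
    stop("rscc must lie in [-1, 1]", call. = FALSE)
  }
  if (nrow(results) > n_mounted) {
    stop("more datasets (", nrow(results), ") than mounted crystals (",
         n_mounted, ")", call. = FALSE)
  }
  # sequential funnel: resolution gate, then RSCC gate, then verification
  diffracting <- results[!is.na(results$resolution) &
                           results$resolution <= res_cutoff, , drop = FALSE]
  passing <- rscc_filter(diffracting, rscc_threshold)
  verified <- passing[passing$verified %in% TRUE, , drop = FALSE]
  campaign_summary(n_soaked, n_mounted, nrow(diffracting), nrow(passing),
                   nrow(verified), res_cutoff = res_cutoff,
                   rscc_threshold = rscc_threshold)
}

# round half away from zero, to `digits` decimals
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Campaign summary from pre-tabulated funnel counts
#'
#' Builds the summary directly from the five funnel counts, enforcing
#' funnel monotonicity (`soaked >= mounted >= diffracting >= rscc_pass >=
#' verified`) and computing the published-style percentages with
#' `n_soaked` as the denominator throughout.
#'
#' @param n_soaked,n_mounted,n_diffracting,n_rscc_pass,n_verified Funnel
#'   counts.
#' @param res_cutoff,rscc_threshold Thresholds the counts were taken at.
#' @return A list of class `campaign_summary` with the five counts, the
#'   percentages `pct_mounted`, `pct_diffracting` (integer),
#'   `pct_rscc_pass`, `pct_verified` (one decimal; `pct_verified` is the
#'   campaign hit rate) and the thresholds.
#' @export
#' @examples
#' campaign_summary(561, 545, 505, 41, 35)
campaign_summary <- function(n_soaked, n_mounted, n_diffracting,
                             n_rscc_pass, n_verified,
                             res_cutoff = 2.5, rscc_threshold = 0.7) {
  counts <- c(n_soaked, n_mounted, n_diffracting, n_rscc_pass, n_verified)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("funnel counts must be non-negative integers", call. = FALSE)
  }
  if (n_soaked == 0) {
    stop("n_soaked must be positive", call. = FALSE)
  }
  if (any(diff(counts) > 0)) {
    i <- which(diff(counts) > 0)[1]
    labels <- c("soaked", "mounted", "diffracting", "RSCC-pass", "verified")
    stop("funnel is not monotone: ", labels[i + 1], " (", counts[i + 1],
         ") exceeds ", labels[i], " (", counts[i], ")", call. = FALSE)
  }
  structure(list(
    n_soaked = n_soaked, n_mounted = n_mounted,
    n_diffracting = n_diffracting, n_rscc_pass = n_rscc_pass,
    n_verified = n_verified,
    pct_mounted = .round_half_away(100 * n_mounted / n_soaked),
    pct_diffracting = .round_half_away(100 * n_diffracting / n_soaked),
    pct_rscc_pass = .round_half_away(100 * n_rscc_pass / n_soaked, 1),
    pct_verified = .round_half_away(100 * n_verified / n_soaked, 1),
    res_cutoff = res_cutoff, rscc_threshold = rscc_threshold),
    class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  cat("Campaign outcome funnel\n")
  cat(sprintf("  crystals soaked                    %5d (100%%)\n",
              x$n_soaked))
  cat(sprintf("  crystals mounted                   %5d (%d%%)\n",
              x$n_mounted, x$pct_mounted))
  cat(sprintf("  diffracting to <= %.1f A           %5d (%d%%)\n",
              x$res_cutoff, x$n_diffracting, x$pct_diffracting))
  cat(sprintf("  datasets with RSCC >= %.1f         %5d (%.1f%%)\n",
              x$rscc_threshold, x$n_rscc_pass, x$pct_rscc_pass))
  cat(sprintf("  verified complexes (hit rate)      %5d (%.1f%%)\n",
              x$n_verified, x$pct_verified))
  invisible(x)
}

#' @export
as.data.frame.campaign_summary <- function(x, ...) {
  data.frame(
    stage = c("soaked", "mounted", "diffracting", "rscc_pass", "verified"),
    count = c(x$n_soaked, x$n_mounted, x$n_diffracting, x$n_rscc_pass,
              x$n_verified),
    percent = c(100, x$pct_mounted, x$pct_diffracting, x$pct_rscc_pass,
                x$pct_verified))
}

#' Write a campaign summary report
#'
#' @param x A `campaign_summary`.
#' @param path Output path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c("| Stage | Count | % of soaked |", "|---|---|---|",
               sprintf("| %s | %d | %s |", df$stage, df$count,
                       formatC(df$percent, format = "fg")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Filter datasets by the RSCC triage threshold
#'
#' Keeps datasets whose real-space correlation coefficient is at least the
#' threshold (inclusive). Datasets without an RSCC (no fitted ligand) are
#' excluded.
#'
#' @param results Data frame with an `rscc` column.
#' @param threshold RSCC threshold in `[0, 1]` (default 0.7).
#' @return The passing subset of `results`.
#' @export
rscc_filter <- function(results, threshold = 0.7) {
  stopifnot(is.data.frame(results), "rscc" %in% names(results),
            threshold >= 0, threshold <= 1)
  results[!is.na(results$rscc) & results$rscc >= threshold, , drop = FALSE]
}

#' Histogram of dataset resolutions
#'
#' Bins the high-resolution cutoffs into half-open bins `[lo, lo + width)`
#' so a value exactly on an edge falls in the upper bin. Bins span the
#' occupied range only (leading/trailing empty bins omitted; interior empty
#' bins kept with count 0) and counts always sum to the input length.
#'
#' @param resolutions Positive resolutions in Angstrom.
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @return Data frame with `lower` (bin lower edge) and `count`.
#' @export
#' @examples
#' resolution_histogram(c(1.45, 1.52, 1.55))
resolution_histogram <- function(resolutions, bin_width = 0.1) {
  stopifnot(is.numeric(resolutions), bin_width > 0)
  if (length(resolutions) == 0) {
    return(data.frame(lower = numeric(), count = integer()))
  }
  if (any(resolutions <= 0)) {
    stop("resolutions must be positive", call. = FALSE)
  }
  # small epsilon so values sitting exactly on an edge (up to float noise)
  # land in the upper bin
  idx <- floor(resolutions / bin_width + 1e-9)
  rng <- seq.int(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  data.frame(lower = rng * bin_width, count = counts)
}
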