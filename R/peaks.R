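#' Peak-caller parameters
#'
#' Bundles the thresholds and conventions of the dual-threshold peak caller.
#' The defaults are the study conditions of the analysis this package
#' implements: a base is part of a putative peak when its median-normalized
#' IP coverage exceeds 4 while every control (input and mock IP) stays
#' below 3, candidate peaks are screened for the triangular shape of a
#' localized ChIP-seq peak, and binding-site windows are the 60 bp centered
#' on the summit.
#'
#' @param ip_threshold Normalized IP coverage must exceed this (default 4).
#' @param control_threshold Every normalized control must stay below this
#'   (default 3).
#' @param min_width Minimum peak width in bp (default 1).
#' @param merge_gap Qualifying runs separated by at most this many
#'   non-qualifying bases are merged (default 0).
#' @param exclusions data.frame of `(chrom, start, end)` intervals removed
#'   from consideration (0-based half-open), or NULL.
#' @param window_width Width of the summit-centered site window (default 60).
#' @param triangularity_min Minimum triangularity score for a peak to pass
#'   the shape screen (default 0.8); the score is the Pearson correlation
#'   between observed coverage around the summit and an ideal triangle.
#' @param shape_flank Half-width in bp of the window the triangularity is
#'   computed over (default 60). This should span the peak footprint
#'   (roughly fragment length plus spread), not just the site window: over
#'   too narrow a window the blunt top of a fragment pileup dominates, and
#'   over too wide a window flat background does.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(ip_threshold = 4, control_threshold = 3,
                        min_width = 1L, merge_gap = 0L, exclusions = NULL,
                        window_width = 60L, triangularity_min = 0.8,
                        shape_flank = 60L) {
  if (!(ip_threshold > control_threshold && control_threshold >= 0)) {
    stop_sigmascan("need ip_threshold > control_threshold >= 0")
  }
  stopifnot(min_width >= 1, merge_gap >= 0, window_width >= 1,
            shape_flank >= 1)
  structure(
    list(ip_threshold = ip_threshold, control_threshold = control_threshold,
         min_width = as.integer(min_width), merge_gap = as.integer(merge_gap),
         exclusions = exclusions, window_width = as.integer(window_width),
         triangularity_min = triangularity_min,
         shape_flank = as.integer(shape_flank)),
    class = "peak_params"
  )
}

#' Call peaks by dual coverage thresholding
#'
#' A base qualifies iff the normalized IP coverage exceeds
#' `params$ip_threshold` AND every provided control stays below
#' `params$control_threshold` (the strictest reading of "compared to input
#' and mock IP controls"). Maximal runs of qualifying bases — allowing
#' internal gaps of at most `merge_gap` bases — of width at least
#' `min_width` become peaks. The summit is the leftmost position attaining
#' the peak's maximum IP coverage; each peak also carries a
#' [triangularity_score()] over `summit +/- shape_flank` and a
#' `passed_shape` flag against `params$triangularity_min`.
#'
#' Excluded bases never qualify. Peaks whose shape window overruns the
#' chromosome get `triangularity = NA` and `passed_shape = FALSE`.
#'
#' @param ip Normalized IP [coverage_track()].
#' @param controls A list of normalized control [coverage_track()]s (may be
#'   a single track).
#' @param params A [peak_params()].
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `summit`, `max_coverage`, `triangularity`, `passed_shape`,
#'   sorted by `start`; zero rows when nothing qualifies.
#' @export
call_peaks <- function(ip, controls, params = peak_params()) {
  stopifnot(inherits(ip, "coverage_track"), inherits(params, "peak_params"))
  if (inherits(controls, "coverage_track")) controls <- list(controls)
  if (!ip$normalized) stop_sigmascan("IP track must be median-normalized")
  L <- length(ip$values)
  for (ctl in controls) {
    stopifnot(inherits(ctl, "coverage_track"))
    if (!ctl$normalized) stop_sigmascan("control tracks must be median-normalized")
    if (length(ctl$values) != L || ctl$chrom != ip$chrom) {
      stop_sigmascan("IP and control tracks must cover the same chromosome")
    }
  }

  qualifying <- ip$values > params$ip_threshold & !ip$excluded
  for (ctl in controls) {
    qualifying <- qualifying & ctl$values < params$control_threshold & !ctl$excluded
  }

  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), max_coverage = numeric(),
                      triangularity = numeric(), passed_shape = logical())
  pos <- which(qualifying)  # 1-based
  if (length(pos) == 0L) return(empty)

  # merge runs separated by gaps <= merge_gap
  brk <- which(diff(pos) > params$merge_gap + 1L)
  run_start <- pos[c(1L, brk + 1L)]
  run_end <- pos[c(brk, length(pos))]
  keep <- (run_end - run_start + 1L) >= params$min_width
  run_start <- run_start[keep]; run_end <- run_end[keep]
  if (length(run_start) == 0L) return(empty)

  flank <- params$shape_flank
  n_runs <- length(run_start)
  summit <- integer(n_runs)
  max_cov <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    vals <- ip$values[run_start[i]:run_end[i]]
    k <- which.max(vals)  # leftmost tie
    summit[i] <- run_start[i] + k - 1L
    max_cov[i] <- vals[k]
  }
  peaks <- data.frame(chrom = ip$chrom, start = run_start - 1L,
                      end = run_end, summit = summit - 1L,
                      max_coverage = max_cov, triangularity = NA_real_,
                      passed_shape = FALSE)

  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    if (s - flank >= 0 && s + flank < L && flank > 0) {
      sc <- tryCatch(
        triangularity_score(ip, peaks[i, ], flank = flank),
        error = function(e) NA_real_
      )
      peaks$triangularity[i] <- sc
      peaks$passed_shape[i] <- isTRUE(sc >= params$triangularity_min)
    }
  }
  rownames(peaks) <- NULL
  peaks
}

#' Triangularity of a peak
#'
#' Automates the visual screen for the triangular shape of a localized
#' ChIP-seq peak: the Pearson correlation between the observed coverage over
#' `[summit - flank, summit + flank]` and an ideal isoceles triangle peaking
#' at the summit. 1 means a perfect triangle; flat or irregular profiles
#' score lower.
#'
#' @param ip Normalized IP [coverage_track()].
#' @param peak One row of the [call_peaks()] data.frame (needs `summit`).
#' @param flank Half-width of the comparison window in bp.
#' @return A score in \[-1, 1\].
#' @export
triangularity_score <- function(ip, peak, flank) {
  stopifnot(inherits(ip, "coverage_track"), flank >= 1)
  s <- peak$summit[1]
  L <- length(ip$values)
  if (s - flank < 0 || s + flank >= L) {
    stop_sigmascan("summit +/- flank outside the chromosome")
  }
  window <- ip$values[(s - flank + 1L):(s + flank + 1L)]
  if (stats::sd(window) == 0) {
    stop_sigmascan("coverage is constant over the shape window")
  }
  triangle <- flank - abs(seq(-flank, flank))
  stats::cor(window, triangle)
}

#' Extract summit-centered site windows
#'
#' For each peak, takes the `window_width` bases centered on the summit:
#' the window is `[summit - floor(w/2), summit - floor(w/2) + w)` in
#' 0-based half-open coordinates (for even widths, `floor(w/2)` bases lie
#' left of the summit). Windows that would overrun a chromosome end are
#' dropped with a warning; output order follows peak order.
#'
#' @param genome A named character vector or [Biostrings::DNAStringSet] of
#'   reference sequences.
#' @param peaks [call_peaks()] data.frame.
#' @param window_width Window width in bp (default 60).
#' @return Named character vector of window sequences (names
#'   `<chrom>_summit<pos>`).
#' @export
extract_site_windows <- function(genome, peaks, window_width = 60L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome))
  out <- character(0)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome) && length(genome) == 1L) chrom <- names(genome)[1]
    seq <- genome[[chrom]]
    start0 <- peaks$summit[i] - window_width %/% 2L
    end0 <- start0 + window_width
    if (start0 < 0 || end0 > nchar(seq)) {
      warning(sprintf("window [%d,%d) for summit %d overruns %s; dropped",
                      start0, end0, peaks$summit[i], chrom))
      next
    }
    w <- substr(seq, start0 + 1L, end0)
    out[sprintf("%s_summit%d", chrom, peaks$summit[i])] <- w
  }
  out
}

#' Write peaks as BED6 plus a summit/triangularity TSV
#'
#' @param peaks [call_peaks()] data.frame.
#' @param bed_path BED6 output (score = `round(max_coverage * 100)`,
#'   strand ".").
#' @param tsv_path Optional TSV with summit, max_coverage, triangularity,
#'   passed_shape.
#' @return `bed_path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, bed_path, tsv_path = NULL) {
  bed <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = round(peaks$max_coverage * 100), strand = "."
  )
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(
      cbind(name = bed$name, peaks), tsv_path, sep = "\t",
      quote = FALSE, row.names = FALSE
    )
  }
  invisible(bed_path)
}
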