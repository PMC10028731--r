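#' Per-base coverage track
#'
#' A coverage track holds one non-negative value per base of a single
#' reference sequence, together with a `normalized` flag and a logical mask
#' of bases excluded from analysis (e.g. a plasmid-borne interval whose
#' reads contaminate the chromosomal signal).
#'
#' All genomic coordinates in this package are 0-based half-open; bedGraph
#' and BED share that convention, GFF3 I/O converts from 1-based inclusive.
#'
#' @param values Numeric vector of per-base coverage, all values >= 0.
#' @param chrom Reference sequence name.
#' @param normalized Logical; has the track already been divided by its
#'   median per-base coverage?
#' @param excluded Optional logical vector (same length as `values`) marking
#'   bases ignored by normalization and peak calling.
#' @return An object of class `coverage_track`.
#' @seealso [normalize_coverage()], [apply_exclusions()], [call_peaks()]
#' @export
coverage_track <- function(values, chrom = "chr", normalized = FALSE,
                           excluded = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_sigmascan("coverage track must be non-empty")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_sigmascan("coverage values must be finite and >= 0")
  }
  if (is.null(excluded)) excluded <- rep(FALSE, length(values))
  stopifnot(is.logical(excluded), length(excluded) == length(values))
  structure(
    list(chrom = as.character(chrom), values = values,
         normalized = isTRUE(normalized), excluded = excluded),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %s, %d bp, %s, %d bases excluded\n  mean %.3f, median (non-excluded) %.3f\n",
    x$chrom, length(x$values),
    if (x$normalized) "median-normalized" else "raw",
    sum(x$excluded), mean(x$values),
    stats::median(x$values[!x$excluded])
  ))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' Median-normalize a coverage track
#'
#' Divides every per-base value by the median per-base coverage of the
#' track, computed over non-excluded bases only. ChIP coverage has a long
#' right tail at enriched bases, so the median (not the mean) is the robust
#' scale; after normalization the non-excluded median equals 1.
#'
#' Normalizing an already-normalized track is an error, as is a zero
#' median (an empty or failed sample).
#'
#' @param track A [coverage_track()].
#' @return A normalized `coverage_track`.
#' @export
normalize_coverage <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) {
    stop_sigmascan("track is already median-normalized")
  }
  usable <- track$values[!track$excluded]
  if (length(usable) == 0L) {
    stop_sigmascan("no non-excluded bases; cannot compute median")
  }
  med <- stats::median(usable)
  if (med <= 0) {
    stop_sigmascan("median per-base coverage is zero; sample looks empty")
  }
  coverage_track(track$values / med, chrom = track$chrom, normalized = TRUE,
                 excluded = track$excluded)
}

#' Exclude intervals from a coverage track
#'
#' Sets coverage inside the given intervals to zero and flags those bases so
#' they are ignored by median normalization and peak calling. Used to remove
#' signal from plasmid-borne sequence (reads from a plasmid copy of a locus
#' pile up on its chromosomal coordinates and would otherwise bias both the
#' median and the peak list).
#'
#' @param track A [coverage_track()].
#' @param exclusions A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); rows whose `chrom` differs from the track's are
#'   ignored. An empty data.frame (or NULL) is a no-op.
#' @return The track with excluded bases zeroed and flagged.
#' @export
apply_exclusions <- function(track, exclusions) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(track)
  stopifnot(all(c("chrom", "start", "end") %in% names(exclusions)))
  L <- length(track$values)
  excl <- track$excluded
  for (i in seq_len(nrow(exclusions))) {
    if (exclusions$chrom[i] != track$chrom) next
    s <- exclusions$start[i]; e <- exclusions$end[i]
    if (s < 0 || e > L || s >= e) {
      stop_sigmascan(sprintf("exclusion interval [%d,%d) out of bounds for %s (length %d)",
                             s, e, track$chrom, L))
    }
    excl[(s + 1L):e] <- TRUE
  }
  vals <- track$values
  vals[excl] <- 0
  coverage_track(vals, chrom = track$chrom, normalized = track$normalized,
                 excluded = excl)
}

#' Read a bedGraph file as a coverage track
#'
#' Expects the intervals to tile the reference contiguously from 0 (as
#' written by [write_bedgraph_track()], which emits zero-coverage runs
#' explicitly); gaps are filled with zero coverage.
#'
#' @param path bedGraph file.
#' @param normalized Whether the stored values are median-normalized.
#' @return A [coverage_track()].
#' @export
read_bedgraph_track <- function(path, normalized = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop_sigmascan("empty bedGraph: ", path)
  chrom <- as.character(GenomicRanges::seqnames(gr)[1])
  L <- max(GenomicRanges::end(gr))
  vals <- numeric(L)
  starts <- GenomicRanges::start(gr)  # 1-based after import
  ends <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) vals[starts[i]:ends[i]] <- gr$score[i]
  coverage_track(vals, chrom = chrom, normalized = normalized)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed into intervals; zero runs are kept
#' so the file tiles the whole reference and round-trips per-base.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = starts, end = ends),
    score = r$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
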