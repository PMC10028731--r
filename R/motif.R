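#' Motif model (count / probability matrix)
#'
#' A motif is stored as a 4 x w probability matrix (rows A, C, G, T;
#' columns 1..w in the R convention), optionally with the underlying count
#' matrix, the pseudocount used for smoothing, the background letter
#' frequencies, and the set of masked columns (see [mask_motif()]).
#'
#' @param probs 4 x w probability matrix; each column must sum to 1.
#' @param counts Optional 4 x w count matrix.
#' @param pseudocount Pseudocount used to derive `probs` from `counts`.
#' @param background Named background letter frequencies (default uniform).
#' @param masked Integer vector of masked column indices (1-based).
#' @param n_sites Number of contributing sites.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(probs, counts = NULL, pseudocount = 0,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        masked = integer(0), n_sites = NA_integer_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop_sigmascan("probability matrix must have 4 rows (A,C,G,T)")
  rownames(probs) <- DNA_LETTERS
  if (ncol(probs) < 1L) stop_sigmascan("motif width must be >= 1")
  csums <- colSums(probs)
  if (any(probs < 0) || any(abs(csums - 1) > 1e-9)) {
    stop_sigmascan("every probability column must be non-negative and sum to 1")
  }
  background <- validate_probability_vector(background, "background")
  masked <- sort(unique(as.integer(masked)))
  if (length(masked) && (min(masked) < 1L || max(masked) > ncol(probs))) {
    stop_sigmascan("masked positions must lie in 1..width")
  }
  structure(
    list(width = ncol(probs), probs = probs, counts = counts,
         pseudocount = pseudocount, background = background,
         masked = masked, n_sites = n_sites),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: width %d, %s sites, %d masked column(s)\n",
              x$width,
              if (is.na(x$n_sites)) "?" else as.character(x$n_sites),
              length(x$masked)))
  cat("consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus string of a motif (most probable letter per column)
#' @param model A [motif_model()].
#' @return A character scalar of length `width`.
#' @export
consensus_string <- function(model) {
  paste(DNA_LETTERS[apply(model$probs, 2, which.max)], collapse = "")
}

#' Count matrix from aligned site sequences
#'
#' @param sites Character vector (or DNAStringSet) of equal-length
#'   sequences over A/C/G/T; ambiguity codes are rejected.
#' @return 4 x w integer matrix of per-column letter counts; column sums
#'   equal the number of sites.
#' @export
build_count_matrix <- function(sites) {
  if (inherits(sites, "DNAStringSet")) sites <- as.character(sites)
  sites <- toupper(sites)
  if (length(sites) == 0L) stop_sigmascan("need at least one site sequence")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop_sigmascan("site sequences must all have the same length")
  if (any(grepl("[^ACGT]", sites))) {
    stop_sigmascan("site sequences must contain only A/C/G/T")
  }
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))[DNA_LETTERS, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Probability matrix from counts with pseudocount smoothing
#'
#' `p[s, i] = (counts[s, i] + pseudocount) / (n + 4 * pseudocount)` where
#' `n` is the column total. The default pseudocount is 0: the scanning
#' matrix is built from the raw site windows, and numerical smoothing is
#' instead applied when the log-odds matrix is constructed
#' ([log_odds_matrix()]).
#'
#' @param counts 4 x w count matrix (rows A,C,G,T).
#' @param pseudocount Non-negative count added to every cell.
#' @param background Background passed through to the model.
#' @return A [motif_model()].
#' @export
counts_to_probabilities <- function(counts, pseudocount = 0,
                                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_sigmascan("count matrix must have 4 rows (A,C,G,T)")
  if (pseudocount < 0) stop_sigmascan("pseudocount must be >= 0")
  totals <- colSums(counts)
  if (any(totals + 4 * pseudocount <= 0)) {
    stop_sigmascan("zero column total with pseudocount 0")
  }
  probs <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
  motif_model(probs, counts = counts, pseudocount = pseudocount,
              background = background,
              n_sites = as.integer(stats::median(totals)))
}

#' Mononucleotide composition of a query sequence
#'
#' The background frequencies used for masking and log-odds scoring are, by
#' default, the composition of each query sequence itself. Non-ACGT letters
#' are skipped with a warning.
#'
#' @param sequence Character scalar (or DNAString).
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @export
background_composition <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop_sigmascan("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                        letters = DNA_LETTERS)
  skipped <- nchar(sequence) - sum(counts)
  if (skipped > 0) {
    warning(sprintf("%d non-ACGT letter(s) skipped in background composition", skipped))
  }
  if (sum(counts) == 0) stop_sigmascan("sequence contains no A/C/G/T letters")
  stats::setNames(as.numeric(counts) / sum(counts), DNA_LETTERS)
}

#' Per-position information content (R_seq)
#'
#' `R_seq(i) = 2 + sum_s p[s,i] * log2(p[s,i])` bits, with `0 * log2(0) = 0`
#' — i.e. 2 minus the column entropy, the per-position information of a
#' sequence logo under a uniform background. No small-sample correction is
#' applied by default; with few contributing sites the correction is
#' non-negligible (about 0.16 bits at n = 13) and can be requested.
#'
#' @param model A [motif_model()].
#' @param small_sample_correction If TRUE, subtracts the first-order
#'   small-sample bias `3 / (2 * ln(2) * n)` bits using `model$n_sites`.
#' @return Numeric vector of per-column information, in bits.
#' @export
information_content <- function(model, small_sample_correction = FALSE) {
  stopifnot(inherits(model, "motif_model"))
  plogp <- model$probs * log2(model$probs)
  plogp[model$probs == 0] <- 0
  r <- 2 + colSums(plogp)
  if (small_sample_correction) {
    n <- model$n_sites
    if (is.na(n) || n < 1) stop_sigmascan("n_sites needed for the small-sample correction")
    r <- r - 3 / (2 * log(2) * n)
  }
  r
}

#' Mask uninformative motif columns with the background
#'
#' Columns whose information content R_seq is at or below `r_threshold`
#' (default 1 bit) are replaced by the background letter frequencies —
#' typically the composition of the query sequence about to be scanned —
#' so that undersampled, weakly constrained positions contribute no
#' spurious sequence preference. Unmasked columns are left bit-identical.
#'
#' @param model A [motif_model()].
#' @param background Named frequencies replacing masked columns.
#' @param r_threshold Information threshold in bits (default 1).
#' @return A new [motif_model()] with `masked` recording the replaced
#'   columns and `background` set to `background`.
#' @export
mask_motif <- function(model, background, r_threshold = 1) {
  stopifnot(inherits(model, "motif_model"))
  background <- validate_probability_vector(background, "background")
  r <- information_content(model)
  masked <- which(r <= r_threshold)
  probs <- model$probs
  for (i in masked) probs[, i] <- background
  motif_model(probs, counts = model$counts, pseudocount = model$pseudocount,
              background = background, masked = masked,
              n_sites = model$n_sites)
}

#' Write the information profile as TSV
#'
#' @param model A [motif_model()].
#' @param path Output TSV (columns: position, r_seq, masked).
#' @return `path`, invisibly.
#' @export
write_information_profile <- function(model, path) {
  r <- information_content(model)
  df <- data.frame(position = seq_along(r), r_seq = r,
                   masked = seq_along(r) %in% model$masked)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
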