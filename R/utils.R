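DNA_LETTERS <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Encode an ACGT string as integers 1..4; non-ACGT letters become NA.
encode_dna <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_LETTERS)
}

decode_dna <- function(idx) paste(DNA_LETTERS[idx], collapse = "")

# Draw from a Laplace (double-exponential) distribution, location 0.
rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

# Laplace CDF, location 0.
plaplace <- function(q, scale) {
  ifelse(q < 0, 0.5 * exp(q / scale), 1 - 0.5 * exp(-q / scale))
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# NULL seed means "use the current stream".
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stop_sigmascan <- function(...) stop(..., call. = FALSE)

validate_probability_vector <- function(p, what = "probabilities") {
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop_sigmascan(what, " must be 4 non-negative values summing to 1")
  }
  if (is.null(names(p))) names(p) <- DNA_LETTERS
  p[DNA_LETTERS]
}
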