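#' Write a motif in minimal MEME motif format
#'
#' Emits the minimal text format understood by the MEME suite: a version
#' line, `ALPHABET= ACGT`, strand and background-frequency lines, then a
#' `MOTIF` block with a `letter-probability matrix:` header and one
#' probability row per motif column. Rows are written at 6 decimal places
#' with largest-remainder rounding so every written column sums to exactly
#' 1.000000; write/read round trips therefore reproduce probabilities to
#' within 1e-6 (one unit in the last written digit).
#'
#' @param model A [motif_model()].
#' @param path Output file, or NULL to return the text.
#' @param name Motif name written after `MOTIF`.
#' @return `path` invisibly, or the formatted text when `path` is NULL.
#' @export
write_meme_motif <- function(model, path = NULL, name = "MOTIF_1") {
  stopifnot(inherits(model, "motif_model"))
  bg <- model$background
  n <- if (is.na(model$n_sites)) 20L else model$n_sites
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            model$width, n),
    apply(model$probs, 2, function(col) {
      # largest-remainder rounding in units of 1e-6 keeps the column sum
      # exactly 1.000000 on disk
      u <- round(col * 1e6)
      d <- 1e6 - sum(u)
      if (d != 0) {
        resid <- col * 1e6 - u
        adj <- order(sign(d) * resid, decreasing = TRUE)[seq_len(abs(d))]
        u[adj] <- u[adj] + sign(d)
      }
      paste(sprintf("%.6f", u / 1e6), collapse = " ")
    })
  )
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(path)
}

#' Read a motif from minimal MEME motif format
#'
#' Parses the first `MOTIF` block of a minimal MEME motif file: width and
#' nsites from the `letter-probability matrix:` header, one A/C/G/T
#' probability row per column, and the file-level background frequencies if
#' present. Probability rows are renormalized to machine precision so that
#' write/read round trips reproduce columns to 6 decimal places.
#'
#' @param path File path, or the text itself (anything containing a
#'   newline is treated as text).
#' @return A [motif_model()].
#' @export
read_meme_motif <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path)) {
    readLines(path)
  } else {
    strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- trimws(lines)

  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(lines[bg_at[1] + 1L], "\\s+")[[1]]
    if (length(tok) >= 8L) {
      vals <- as.numeric(tok[seq(2, 8, by = 2)])
      names(vals) <- tok[seq(1, 7, by = 2)]
      bg <- validate_probability_vector(vals / sum(vals), "background")
    }
  }

  hdr_at <- grep("^letter-probability matrix:", lines)
  if (!length(hdr_at)) stop_sigmascan("no letter-probability matrix header found")
  hdr <- lines[hdr_at[1]]
  get_field <- function(field) {
    m <- regmatches(hdr, regexec(paste0(field, "=\\s*(\\S+)"), hdr))[[1]]
    if (length(m) < 2L) NA else suppressWarnings(as.numeric(m[2]))
  }
  w <- get_field("w")
  alen <- get_field("alength")
  nsites <- get_field("nsites")
  if (is.na(w) || w < 1) stop_sigmascan("malformed matrix header: missing w=")
  if (!is.na(alen) && alen != 4) stop_sigmascan("only alength= 4 (DNA) is supported")

  rows <- lines[(hdr_at[1] + 1L):length(lines)]
  rows <- rows[nzchar(rows)]
  rows <- rows[grepl("^[0-9.eE+\\-]", rows)]
  if (length(rows) < w) stop_sigmascan("fewer probability rows than the stated width")
  probs <- t(vapply(rows[seq_len(w)], function(r) {
    v <- as.numeric(strsplit(r, "\\s+")[[1]])
    if (length(v) != 4L || any(is.na(v)) || any(v < 0)) {
      stop_sigmascan("malformed probability row: ", r)
    }
    v / sum(v)
  }, numeric(4)))
  motif_model(t(probs), background = bg,
              n_sites = if (is.na(nsites)) NA_integer_ else as.integer(nsites))
}
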