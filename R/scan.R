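#' Log-odds scoring matrix from a motif model
#'
#' `score[s, i] = log2((p[s, i] + eps) / (b[s] + eps))` bits, with the
#' smoothing pseudo-probability `eps` added to both numerator and
#' denominator. Columns equal to the background (e.g. masked columns) score
#' near zero for every letter, so masked positions contribute essentially
#' nothing to any window's score.
#'
#' @param model A [motif_model()].
#' @param background Named background frequencies; defaults to the model's.
#' @param smoothing Pseudo-probability `eps` (default 1e-4). With
#'   `smoothing = 0`, any zero probability (or zero background frequency)
#'   would give an infinite cell and is an error.
#' @return An object of class `scoring_matrix`: list with `width`, `scores`
#'   (4 x w, bits), `background`, `smoothing`, `masked`.
#' @export
log_odds_matrix <- function(model, background = NULL, smoothing = 1e-4) {
  stopifnot(inherits(model, "motif_model"))
  if (is.null(background)) background <- model$background
  background <- validate_probability_vector(background, "background")
  if (smoothing < 0) stop_sigmascan("smoothing must be >= 0")
  scores <- log2(sweep(model$probs + smoothing, 1, background + smoothing, "/"))
  if (any(!is.finite(scores))) {
    stop_sigmascan("non-finite log-odds cell; increase smoothing or fix the background")
  }
  structure(
    list(width = model$width, scores = scores, background = background,
         smoothing = smoothing, masked = model$masked),
    class = "scoring_matrix"
  )
}

#' Exact score distribution under the background model
#'
#' Discretizes every log-odds cell to integer multiples of `step` bits
#' (round-half-even) and convolves the per-position score distributions
#' across the motif under the 0-order background letter model — the
#' dynamic program behind exact PWM p-values. Window scores computed by
#' [scan_sequence()] use the same discretized cells, so the tail
#' probabilities are exact on the discretized score axis; the
#' discretization error on the score itself is at most `width * step / 2`.
#'
#' @param matrix A [log_odds_matrix()].
#' @param background Background letter model for the null distribution;
#'   defaults to the matrix's.
#' @param step Discretization step in bits (default 0.001).
#' @return An object of class `score_distribution`: `step`, `int_scores`
#'   (4 x w integer matrix), `min_sum`, `pmf` and `tail` over the
#'   discretized support (`tail[k] = P(S >= min_sum + k - 1)`).
#' @export
score_distribution <- function(matrix, background = NULL, step = 0.001) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  if (step <= 0) stop_sigmascan("step must be > 0")
  if (is.null(background)) background <- matrix$background
  background <- validate_probability_vector(background, "background")

  int_scores <- round(matrix$scores / step)  # round() is round-half-even
  storage.mode(int_scores) <- "integer"
  w <- matrix$width
  min_sum <- sum(apply(int_scores, 2, min))
  max_sum <- sum(apply(int_scores, 2, max))
  support <- max_sum - min_sum + 1L

  pmf <- numeric(support)
  pmf[1L] <- 1
  covered_min <- 0L  # offset of pmf[1] relative to partial minimum
  part_min <- 0L
  for (i in seq_len(w)) {
    col <- int_scores[, i]
    cmin <- min(col)
    new_min <- part_min + cmin
    new <- numeric(support)
    for (s in 1:4) {
      if (background[s] == 0) next
      shift <- col[s] - cmin
      idx <- which(pmf > 0)
      new[idx + shift] <- new[idx + shift] + pmf[idx] * background[s]
    }
    pmf <- new
    part_min <- new_min
  }
  tail <- rev(cumsum(rev(pmf)))
  structure(
    list(step = step, int_scores = int_scores,
         min_sum = as.integer(min_sum), max_sum = as.integer(max_sum),
         pmf = pmf, tail = tail),
    class = "score_distribution"
  )
}

# P(S >= s_int) for integer-unit scores (vectorized)
tail_pvalue <- function(dist, s_int) {
  idx <- s_int - dist$min_sum + 1L
  idx <- pmax(pmin(idx, length(dist$tail) + 1L), 1L)
  out <- numeric(length(idx))
  inside <- idx <= length(dist$tail)
  out[inside] <- dist$tail[idx[inside]]
  out[!inside] <- 0
  out
}

# reverse-complement a scoring/integer matrix: reverse columns, swap A<->T, C<->G
rc_matrix <- function(m) {
  m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m[c(4L, 3L, 2L, 1L), , drop = FALSE]
}

#' Scan a sequence for motif occurrences
#'
#' Scores every window of the sequence (both strands by default; the minus
#' strand is scored with the reverse-complemented matrix and reported in
#' forward coordinates) and reports windows whose exact p-value is at most
#' `p_threshold`. Windows containing non-ACGT letters are skipped. Scanning
#' is case-insensitive.
#'
#' @param matrix A [log_odds_matrix()].
#' @param dist The matching [score_distribution()].
#' @param sequence Character scalar (or DNAString) to scan.
#' @param p_threshold Report windows with `p_value <= p_threshold`
#'   (default 1e-4, the conventional FIMO cut).
#' @param both_strands Scan the minus strand too (default TRUE).
#' @param seqid Sequence name used in the output.
#' @return A data.frame of hits (`seqid`, `start`, `end` 0-based half-open,
#'   `strand`, `score` in bits, `p_value`, `matched`), sorted by p-value
#'   ascending, with attribute `n_scored` = number of windows scored
#'   (counting strands separately) for FDR accounting.
#' @export
scan_sequence <- function(matrix, dist, sequence, p_threshold = 1e-4,
                          both_strands = TRUE, seqid = "seq") {
  stopifnot(inherits(matrix, "scoring_matrix"),
            inherits(dist, "score_distribution"))
  sequence <- toupper(as.character(sequence))
  w <- matrix$width
  L <- nchar(sequence)
  if (L < w) stop_sigmascan("sequence shorter than the motif")
  enc <- encode_dna(sequence)
  n_win <- L - w + 1L

  window_scores <- function(int_scores) {
    s <- integer(n_win)
    ok <- rep(TRUE, n_win)
    for (k in seq_len(w)) {
      letter <- enc[k:(k + n_win - 1L)]
      bad <- is.na(letter)
      ok <- ok & !bad
      letter[bad] <- 1L
      s <- s + int_scores[cbind(letter, k)]
    }
    list(s = s, ok = ok)
  }

  collect <- function(int_scores, strand) {
    ws <- window_scores(int_scores)
    if (!any(ws$ok)) return(NULL)
    idx <- which(ws$ok)
    p <- tail_pvalue(dist, ws$s[idx])
    keep <- p <= p_threshold
    n_sc <- length(idx)
    if (!any(keep)) return(list(hits = NULL, n = n_sc))
    starts <- idx[keep] - 1L
    list(hits = data.frame(
      seqid = seqid, start = starts, end = starts + w, strand = strand,
      score = ws$s[idx][keep] * dist$step, p_value = p[keep],
      matched = substring(sequence, starts + 1L, starts + w)
    ), n = n_sc)
  }

  plus <- collect(dist$int_scores, "+")
  res <- list(plus$hits)
  n_scored <- if (is.null(plus)) 0L else plus$n
  if (both_strands) {
    minus <- collect(rc_matrix(dist$int_scores), "-")
    if (!is.null(minus)) {
      n_scored <- n_scored + minus$n
      res <- c(res, list(minus$hits))
    }
  }
  hits <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(hits)) {
    hits <- data.frame(seqid = character(), start = integer(),
                       end = integer(), strand = character(),
                       score = numeric(), p_value = numeric(),
                       matched = character())
  } else {
    hits <- hits[order(hits$p_value, hits$start), , drop = FALSE]
    rownames(hits) <- NULL
  }
  attr(hits, "n_scored") <- n_scored
  hits
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over ranks j >= rank(i) of p_(j) * n / j`, capped at 1, in
#' the original input order. `n` may exceed `length(p)` when only the
#' smallest p-values of a larger family are passed (as when hits were
#' pre-filtered at a p-value threshold).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param n Family size for the correction (default `length(p_values)`).
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_qvalues <- function(p_values, n = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_sigmascan("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH", n = max(n, length(p_values)))
}

#' Read CDS records from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default "CDS").
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gff_cds <- function(path, feature_type = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("cds_%d", seq_along(gr))
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Extract promoter sequences upstream of annotated CDS
#'
#' The promoter of a plus-strand CDS starting at `s` (0-based) is the
#' genomic interval `[max(0, s - len), s)` read forward; for a minus-strand
#' CDS ending at `e` it is `[e, min(L, e + len))` reverse-complemented, so
#' the returned sequence always runs 5' to 3' toward the start codon.
#' Records truncated at a contig edge carry `truncated = TRUE`.
#'
#' @param cds data.frame as returned by [read_gff_cds()].
#' @param genome Named character vector or DNAStringSet.
#' @param promoter_len Upstream length in bp (default 100).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (genomic,
#'   0-based half-open), `strand`, `truncated`, `sequence`.
#' @export
extract_promoters <- function(cds, genome, promoter_len = 100L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    chrom <- cds$chrom[i]
    if (!chrom %in% names(genome)) {
      if (length(genome) == 1L) chrom <- names(genome)[1]
      else stop_sigmascan("chromosome not in genome: ", cds$chrom[i])
    }
    L <- nchar(genome[[chrom]])
    if (cds$start[i] < 0 || cds$end[i] > L) {
      stop_sigmascan("CDS outside genome bounds: ", cds$gene_id[i])
    }
    if (cds$strand[i] == "-") {
      s <- cds$end[i]; e <- min(L, cds$end[i] + promoter_len)
      seq <- revcomp(substr(genome[[chrom]], s + 1L, e))
      trunc <- (e - s) < promoter_len
    } else {
      s <- max(0L, cds$start[i] - promoter_len); e <- cds$start[i]
      seq <- substr(genome[[chrom]], s + 1L, e)
      trunc <- (e - s) < promoter_len
    }
    out[[i]] <- data.frame(
      gene_id = cds$gene_id[i], chrom = chrom, start = s, end = e,
      strand = cds$strand[i], truncated = trunc, sequence = seq,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[nchar(res$sequence) > 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank and filter scan hits into a report
#'
#' Attaches BH q-values (family size = total windows scored across all
#' queries), annotates each hit with the promoter/gene it falls in when a
#' promoter table is supplied, and splits the result into the full table
#' and the table filtered at `q <= q_threshold`, both sorted by p-value
#' ascending.
#'
#' @param hits data.frame of hits from [scan_sequence()] (possibly
#'   rbind-ed across queries); the `n_scored` attribute, or the `n_scored`
#'   argument, gives the FDR family size.
#' @param promoters Optional [extract_promoters()] table; hits whose
#'   `seqid` matches a `gene_id` are annotated directly, genomic hits are
#'   annotated by interval overlap.
#' @param q_threshold Reporting cut on the q-value (default 0.6).
#' @param n_scored Family size override.
#' @return list with `full` and `filtered` data.frames (columns of `hits`
#'   plus `q_value` and, with promoters, `gene_id`).
#' @export
scan_report <- function(hits, promoters = NULL, q_threshold = 0.6,
                        n_scored = NULL) {
  if (is.null(n_scored)) n_scored <- attr(hits, "n_scored")
  if (is.null(n_scored)) n_scored <- nrow(hits)
  if (nrow(hits) == 0L) {
    hits$q_value <- numeric(0)
    if (!is.null(promoters)) hits$gene_id <- character(0)
    return(list(full = hits, filtered = hits))
  }
  hits$q_value <- bh_qvalues(hits$p_value, n = n_scored)
  if (!is.null(promoters)) {
    gene <- rep(NA_character_, nrow(hits))
    direct <- match(hits$seqid, promoters$gene_id)
    gene[!is.na(direct)] <- promoters$gene_id[direct[!is.na(direct)]]
    genomic <- which(is.na(gene))
    for (i in genomic) {
      ov <- which(promoters$chrom == hits$seqid[i] &
                    hits$start[i] < promoters$end &
                    hits$end[i] > promoters$start)
      if (length(ov)) gene[i] <- promoters$gene_id[ov[1]]
    }
    hits$gene_id <- gene
  }
  ord <- order(hits$p_value, hits$start)
  full <- hits[ord, , drop = FALSE]
  rownames(full) <- NULL
  filtered <- full[full$q_value <= q_threshold, , drop = FALSE]
  rownames(filtered) <- NULL
  list(full = full, filtered = filtered)
}

#' Write a hit table as TSV (1-based inclusive coordinates) and BED6
#'
#' @param report A table from [scan_report()] (`full` or `filtered`).
#' @param tsv_path TSV output path (columns: sequence, start, end, strand,
#'   score, p-value, q-value, matched sequence, gene).
#' @param bed_path Optional BED6 path.
#' @return `tsv_path`, invisibly.
#' @export
write_hits <- function(report, tsv_path, bed_path = NULL) {
  tsv <- data.frame(
    sequence = report$seqid, start = report$start + 1L, end = report$end,
    strand = report$strand, score = report$score,
    p_value = report$p_value,
    q_value = if ("q_value" %in% names(report)) report$q_value else NA,
    matched = report$matched,
    gene = if ("gene_id" %in% names(report)) report$gene_id else NA
  )
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(report$seqid, report$start, report$end,
                      name = sprintf("hit_%d", seq_len(nrow(report))),
                      score = pmin(1000L, as.integer(round(report$score * 10))),
                      strand = report$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
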