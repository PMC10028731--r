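#' De novo motif discovery by ZOOPS expectation-maximization
#'
#' Fits the "zero or one occurrence per sequence" finite mixture used by
#' MEME-style motif discovery: each input sequence either contains exactly
#' one motif occurrence (prior probability `gamma`, uniform over possible
#' start offsets) or is pure background (0-order model with the aggregate
#' composition of the inputs). EM alternates posterior site-location
#' assignment with probability-matrix and `gamma` re-estimation; the log
#' likelihood is non-decreasing across iterations within a start, and the
#' best of `n_starts` seeded starts is returned.
#'
#' Starts are seeded from the data: every distinct w-mer observed on the
#' forward strand is turned into a candidate probability matrix (its letters
#' at probability 0.7, the rest split evenly), candidates are ranked by
#' their one-step ZOOPS log likelihood at `gamma = 0.5`, and EM is run from
#' the top `n_starts`. Only the forward strand is modelled: the intended
#' inputs are short summit-centered windows.
#'
#' @param sequences Character vector (or DNAStringSet) of site windows,
#'   each at least `width` long; letters outside A/C/G/T are rejected.
#' @param width Motif width (>= 4).
#' @param n_starts Number of seed starts (default 5).
#' @param max_iter EM iteration cap per start (default 200); hitting it
#'   returns the best model so far with a warning.
#' @param tol Convergence threshold on the log-likelihood increase
#'   (default 1e-6).
#' @param seed Optional RNG seed; the algorithm is deterministic, the seed
#'   only pins tie-breaking among equally scoring starts.
#' @param em_pseudocount Count added per letter in the M-step (default 0:
#'   the exact maximizer, which keeps the likelihood non-decreasing;
#'   probabilities are floored at 1e-12 purely to keep logs finite).
#' @param report_pseudocount Count added per letter when forming the
#'   returned probability matrix from the converged expected counts
#'   (default 0.25, a weak Dirichlet posterior mean). With around a dozen
#'   contributing sites the maximum-likelihood matrix contains sampling
#'   zeros that any downstream log-odds scoring would exaggerate; the
#'   posterior-mean estimate fills them at the scale the prior dictates.
#'   Set to 0 for the raw maximum-likelihood matrix.
#' @return A list with elements `model` (a [motif_model()]), `gamma`,
#'   `loglik`, `loglik_trace` (per-iteration, non-decreasing), `posteriors`
#'   (per sequence: `p_site`, the posterior that it contains a site, and
#'   `offset`, the 0-based maximum-posterior start), and `converged`.
#' @export
discover_motif_zoops <- function(sequences, width, n_starts = 5L,
                                 max_iter = 200L, tol = 1e-6, seed = NULL,
                                 em_pseudocount = 0, report_pseudocount = 0.25) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  sequences <- toupper(sequences)
  if (width < 4) stop_sigmascan("motif width must be >= 4")
  if (any(nchar(sequences) < width)) {
    stop_sigmascan("every sequence must be at least `width` long")
  }
  if (any(grepl("[^ACGT]", sequences))) {
    stop_sigmascan("sequences must contain only A/C/G/T")
  }
  n <- length(sequences)
  enc <- lapply(sequences, encode_dna)

  # 0-order background from the aggregate input composition
  all_letters <- unlist(enc)
  bg <- as.numeric(tabulate(all_letters, 4L))
  bg <- pmax(bg, 1) / sum(pmax(bg, 1))
  names(bg) <- DNA_LETTERS
  log_bg_letter <- log(bg)

  # one-hot window matrix: row = a candidate site placement, 4*width cols
  m_i <- nchar(sequences) - width + 1L
  seq_of_window <- rep(seq_len(n), m_i)
  total_w <- sum(m_i)
  window_idx <- matrix(0L, nrow = total_w, ncol = width)
  row <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m_i[i])) {
      row <- row + 1L
      window_idx[row, ] <- enc[[i]][j:(j + width - 1L)]
    }
  }
  # column-major one-hot: X[r, (k-1)*4 + letter] = 1
  X <- matrix(0, nrow = total_w, ncol = 4L * width)
  for (k in seq_len(width)) {
    X[cbind(seq_len(total_w), (k - 1L) * 4L + window_idx[, k])] <- 1
  }
  log_bg_per_seq <- vapply(enc, function(e) sum(log_bg_letter[e]), numeric(1))
  # background log-prob of the letters inside each candidate window
  log_bg_window <- as.numeric(X %*% rep(log_bg_letter, width))
  rows_by_seq <- split(seq_len(total_w), seq_of_window)

  zoops_loglik_parts <- function(log_probs_flat, gamma) {
    # log f_ij - log f_i(bg) for every candidate window
    llr <- as.numeric(X %*% log_probs_flat) - log_bg_window
    ll_i <- numeric(n)
    z <- numeric(total_w)
    for (i in seq_len(n)) {
      rows <- rows_by_seq[[i]]
      a <- log(gamma / m_i[i]) + llr[rows]       # site components
      b <- log(1 - gamma)                        # background component
      mx <- max(a, b)
      denom <- exp(b - mx) + sum(exp(a - mx))
      ll_i[i] <- log_bg_per_seq[i] + mx + log(denom)
      z[rows] <- exp(a - mx) / denom
    }
    list(loglik = sum(ll_i), z = z)
  }

  seed_ppm_flat <- function(word_idx) {
    p <- matrix(0.1, nrow = 4L, ncol = width)
    p[cbind(word_idx, seq_len(width))] <- 0.7
    as.numeric(log(p))
  }

  distinct <- !duplicated(window_idx)
  seeds <- which(distinct)
  seed_scores <- with_seed_or_current(seed, {
    vapply(seeds, function(r) {
      zoops_loglik_parts(seed_ppm_flat(window_idx[r, ]), 0.5)$loglik
    }, numeric(1))
  })
  ord <- order(seed_scores, decreasing = TRUE)
  top <- seeds[ord][seq_len(min(n_starts, length(seeds)))]

  run_em <- function(start_row) {
    log_p <- seed_ppm_flat(window_idx[start_row, ])
    gamma <- 0.5
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- zoops_loglik_parts(log_p, gamma)
      trace <- c(trace, es$loglik)
      # M-step: expected letter counts per motif column
      counts <- crossprod(X, es$z)              # 4*width expected counts
      counts <- matrix(counts, nrow = 4L) + em_pseudocount
      probs <- sweep(counts, 2, colSums(counts), "/")
      probs <- pmax(probs, 1e-12)               # finite logs only
      probs <- sweep(probs, 2, colSums(probs), "/")
      log_p <- as.numeric(log(probs))
      gamma_new <- sum(es$z) / n
      gamma <- min(max(gamma_new, 1e-6), 1 - 1e-6)
      if (es$loglik - prev < tol && it > 1L) { converged <- TRUE; break }
      prev <- es$loglik
    }
    final <- zoops_loglik_parts(log_p, gamma)
    list(probs = matrix(exp(log_p), nrow = 4L), gamma = gamma,
         loglik = final$loglik, trace = c(trace, final$loglik),
         z = final$z, converged = converged)
  }

  fits <- lapply(top, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  if (!best$converged) {
    warning("ZOOPS-EM did not converge within max_iter; returning best fit so far")
  }

  posteriors <- do.call(rbind, lapply(seq_len(n), function(i) {
    zi <- best$z[rows_by_seq[[i]]]
    data.frame(sequence = i, p_site = sum(zi),
               offset = which.max(zi) - 1L)
  }))

  rep_counts <- matrix(crossprod(X, best$z), nrow = 4L) + report_pseudocount
  rep_probs <- sweep(rep_counts, 2, colSums(rep_counts), "/")
  model <- motif_model(rep_probs, counts = matrix(crossprod(X, best$z), nrow = 4L,
                                                  dimnames = list(DNA_LETTERS, NULL)),
                       pseudocount = report_pseudocount, background = bg,
                       n_sites = as.integer(round(best$gamma * n)))
  list(model = model, gamma = best$gamma, loglik = best$loglik,
       loglik_trace = best$trace, posteriors = posteriors,
       converged = best$converged, background = bg)
}
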