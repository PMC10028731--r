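# Fixtures and independent oracles used across the suite.

uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a random probability matrix motif (columns Dirichlet-ish via exponentials)
random_motif <- function(width) {
  p <- matrix(stats::rexp(4 * width), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  motif_model(p)
}

random_background <- function() {
  b <- stats::rexp(4) + 0.05
  stats::setNames(b / sum(b), c("A", "C", "G", "T"))
}

# 13 uniform-random 60 bp windows, the first `n_sites` with a motif-sampled
# site planted (forward strand) at a random offset; returns windows + truth
planted_windows <- function(motif, seed, n_windows = 13L, n_sites = 12L,
                            window_len = 60L) {
  withr::with_seed(seed, {
    w <- vapply(seq_len(n_windows), function(i) {
      paste(sample(c("A", "C", "G", "T"), window_len, replace = TRUE),
            collapse = "")
    }, character(1))
    offsets <- rep(NA_integer_, n_windows)
    for (i in seq_len(n_sites)) {
      off <- sample.int(window_len - motif$width + 1L, 1L) - 1L
      site <- sigmascan:::sample_site_sequence(motif)
      substr(w[i], off + 1L, off + motif$width) <- site
      offsets[i] <- off
    }
    list(windows = w, offsets = offsets)
  })
}

# ---- independent oracles -------------------------------------------------

# literal per-base predicate scan + explicit run merging (peak caller oracle)
oracle_call_peaks <- function(ip_vals, control_list, ip_thr = 4, ctl_thr = 3,
                              min_width = 1L, merge_gap = 0L) {
  ok <- ip_vals > ip_thr
  for (ctl in control_list) ok <- ok & (ctl < ctl_thr)
  pos <- which(ok)
  if (length(pos) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      summit = integer(), max_coverage = numeric()))
  }
  runs <- list()
  cur_start <- pos[1]; cur_end <- pos[1]
  if (length(pos) > 1L) {
    for (p in pos[-1]) {
      if (p - cur_end <= merge_gap + 1L) {
        cur_end <- p
      } else {
        runs[[length(runs) + 1L]] <- c(cur_start, cur_end)
        cur_start <- p; cur_end <- p
      }
    }
  }
  runs[[length(runs) + 1L]] <- c(cur_start, cur_end)
  out <- do.call(rbind, lapply(runs, function(r) {
    if (r[2] - r[1] + 1L < min_width) return(NULL)
    vals <- ip_vals[r[1]:r[2]]
    data.frame(start = r[1] - 1L, end = r[2],
               summit = r[1] - 1L + which.max(vals) - 1L,
               max_coverage = max(vals))
  }))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      summit = integer(), max_coverage = numeric())
  }
  rownames(out) <- NULL
  out
}

# brute-force exact tail probabilities by enumerating all 4^w words on the
# discretized score axis used by the distribution
oracle_tail_probs <- function(dist, background, thresholds) {
  w <- ncol(dist$int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  s_int <- rowSums(vapply(seq_len(w), function(k) {
    dist$int_scores[cbind(words[, k], k)]
  }, numeric(nrow(words))))
  wt <- rep(1, nrow(words))
  for (k in seq_len(w)) wt <- wt * background[words[, k]]
  ord <- order(s_int, decreasing = TRUE)
  s_sorted <- s_int[ord]
  cum <- cumsum(wt[ord])
  vapply(thresholds, function(t0) {
    n_ge <- sum(s_sorted >= t0)
    if (n_ge == 0L) 0 else cum[n_ge]
  }, numeric(1))
}

# closed-form BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
oracle_bh <- function(p, n = length(p)) {
  ord <- order(p)
  m <- length(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * n / seq(i, m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# full-axis brute-force tail table: every achievable discretized score and
# its exact tail probability, by enumerating all 4^w words
oracle_tail_table <- function(dist, background) {
  w <- ncol(dist$int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  s_int <- rowSums(vapply(seq_len(w), function(k) {
    dist$int_scores[cbind(words[, k], k)]
  }, numeric(nrow(words))))
  wt <- rep(1, nrow(words))
  for (k in seq_len(w)) wt <- wt * background[words[, k]]
  mass <- tapply(wt, s_int, sum)
  s <- as.numeric(names(mass))
  ord <- order(s, decreasing = TRUE)
  data.frame(s = s[ord], tail = cumsum(mass[ord]))
}

# vectorized closed-form BH step-up (for large families)
oracle_bh_stepup <- function(p, n = length(p)) {
  ord <- order(p)
  m <- length(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * n / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
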