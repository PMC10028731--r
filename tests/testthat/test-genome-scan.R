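test_that("log-odds cells follow the smoothed log2 ratio", {
  m <- motif_model(cbind(c(1, 0, 0, 0)))
  lom <- log_odds_matrix(m, uniform_bg, smoothing = 1e-4)
  expect_equal(unname(lom$scores["A", 1]), log2(1.0001 / 0.2501))
  expect_equal(unname(lom$scores["C", 1]), log2(0.0001 / 0.2501))

  # a column equal to the background scores exactly 0 with no smoothing
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  m2 <- motif_model(cbind(unname(bg)))
  lom2 <- log_odds_matrix(m2, bg, smoothing = 0)
  expect_equal(unname(lom2$scores[, 1]), rep(0, 4))

  # zero probability with zero smoothing is an error, not -Inf
  expect_error(log_odds_matrix(m, uniform_bg, smoothing = 0), "non-finite")
})

test_that("DP tail probabilities equal exhaustive enumeration", {
  withr::with_seed(17, {
    for (i in 1:10) {
      w <- sample(2:5, 1)
      m <- random_motif(w)
      bg <- random_background()
      lom <- log_odds_matrix(m, bg)
      dist <- score_distribution(lom, bg)
      thresholds <- seq(dist$min_sum, dist$max_sum, length.out = 25)
      got <- sigmascan:::tail_pvalue(dist, round(thresholds))
      want <- oracle_tail_probs(dist, bg, round(thresholds))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
  # full support: P(score >= minimum) = 1
  m <- random_motif(4)
  d <- score_distribution(log_odds_matrix(m, uniform_bg), uniform_bg)
  expect_equal(sigmascan:::tail_pvalue(d, d$min_sum), 1)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
  expect_true(all(diff(d$tail) <= 1e-12))  # non-increasing in the threshold

  # width-1 matrix under uniform background: unique best letter has p 0.25
  m1 <- motif_model(cbind(c(0.7, 0.1, 0.1, 0.1)))
  d1 <- score_distribution(log_odds_matrix(m1, uniform_bg), uniform_bg)
  expect_equal(sigmascan:::tail_pvalue(d1, max(d1$int_scores)), 0.25)

  expect_error(score_distribution(log_odds_matrix(m1, uniform_bg),
                                  uniform_bg, step = 0), "step")
})

test_that("scanning finds a planted consensus at the maximal score", {
  withr::with_seed(23, {
    m <- motif_model(local({
      p <- matrix(0.02, 4, 10)
      idx <- sample(1:4, 10, replace = TRUE)
      p[cbind(idx, 1:10)] <- 0.94
      p
    }))
    cons <- consensus_string(m)
    seq <- random_dna(2000)
    substr(seq, 201, 210) <- cons
  })
  lom <- log_odds_matrix(m, uniform_bg)
  dist <- score_distribution(lom, uniform_bg)
  hits <- scan_sequence(lom, dist, seq, p_threshold = 1e-4)
  best <- hits[1, ]
  expect_identical(best$start, 200L)
  expect_identical(best$strand, "+")
  max_int <- sum(apply(dist$int_scores, 2, max))
  expect_equal(best$score, max_int * dist$step)

  # a stringent threshold on random sequence yields nothing
  none <- scan_sequence(lom, dist, random_dna(500, seed = 4),
                        p_threshold = 1e-12)
  expect_identical(nrow(none), 0L)
  expect_gt(attr(none, "n_scored"), 0L)

  expect_error(scan_sequence(lom, dist, "ACGT"), "shorter")
})

test_that("strand handling is coherent", {
  withr::with_seed(29, {
    m <- random_motif(8)
    bg <- uniform_bg
    seq <- random_dna(600)
  })
  lom <- log_odds_matrix(m, bg)
  dist <- score_distribution(lom, bg)
  fwd <- scan_sequence(lom, dist, seq, p_threshold = 0.05)
  rev <- scan_sequence(lom, dist, revcomp(seq), p_threshold = 0.05)
  # same hits in mirrored coordinates with flipped strands
  L <- nchar(seq)
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  o1 <- order(fwd$start, fwd$strand)
  o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(fwd$start[o1], mirrored$start[o2])
  expect_equal(fwd$strand[o1], mirrored$strand[o2])
  expect_equal(fwd$score[o1], mirrored$score[o2])

  # palindromic matrix: plus and minus hits at each site score equally
  half <- matrix(c(0.9, 0.05, 0.03, 0.02, 0.1, 0.6, 0.2, 0.1), 4, 2)
  pal <- motif_model(cbind(half, sigmascan:::rc_matrix(half)))
  lp <- log_odds_matrix(pal, uniform_bg)
  dp <- score_distribution(lp, uniform_bg)
  h <- scan_sequence(lp, dp, random_dna(300, seed = 5), p_threshold = 1)
  plus <- h[h$strand == "+", ]
  minus <- h[h$strand == "-", ]
  merged <- merge(plus, minus, by = "start")
  expect_gt(nrow(merged), 0)
  expect_equal(merged$score.x, merged$score.y)

  # case-insensitive scanning
  h_low <- scan_sequence(lom, dist, tolower(seq), p_threshold = 0.05)
  expect_equal(h_low$start, fwd$start)

  # windows containing ambiguity codes are skipped
  seq_n <- paste0(substr(seq, 1, 100), "N", substr(seq, 102, 600))
  h_n <- scan_sequence(lom, dist, seq_n, p_threshold = 1)
  expect_false(any(h_n$start > 100 - 8 & h_n$start <= 100))
})

test_that("masked columns contribute only the smoothing bound to scores", {
  withr::with_seed(31, {
    m <- random_motif(10)
    qseq <- random_dna(400)
  })
  bg <- background_composition(qseq)
  masked <- mask_motif(m, bg, r_threshold = 2)  # every column masked
  lom <- log_odds_matrix(masked, bg, smoothing = 1e-4)
  # each cell is log2((b+eps)/(b+eps)) = 0 exactly when p == b
  expect_true(all(abs(lom$scores[, masked$masked]) < 1e-12))
})

test_that("BH q-values match the closed-form step-up formula", {
  expect_equal(bh_qvalues(0.05), 0.05)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  withr::with_seed(37, {
    for (i in 1:5) {
      p <- stats::runif(sample(10:200, 1))^sample(1:3, 1)
      p[p == 0] <- 1e-12
      expect_equal(bh_qvalues(p), oracle_bh(p), tolerance = 1e-12)
      # with an enlarged family size (pre-filtered hit lists)
      expect_equal(bh_qvalues(p, n = 1000), oracle_bh(p, n = 1000),
                   tolerance = 1e-12)
    }
  })
  expect_error(bh_qvalues(c(0.5, 0)), "p-values")
  expect_error(bh_qvalues(c(0.5, 1.2)), "p-values")
})

test_that("promoters are the 100 bp upstream of each CDS, strand-aware", {
  genome <- c(chr = random_dna(10000, seed = 41))
  cds <- data.frame(
    gene_id = c("plus", "edge", "minus"),
    chrom = "chr",
    start = c(500L, 40L, 500L),
    end = c(900L, 200L, 900L),
    strand = c("+", "+", "-")
  )
  pr <- extract_promoters(cds, genome)
  expect_identical(pr$start[pr$gene_id == "plus"], 400L)
  expect_identical(pr$end[pr$gene_id == "plus"], 500L)
  expect_identical(pr$sequence[pr$gene_id == "plus"],
                   substr(genome[["chr"]], 401, 500))
  expect_false(pr$truncated[pr$gene_id == "plus"])

  expect_identical(pr$start[pr$gene_id == "edge"], 0L)
  expect_true(pr$truncated[pr$gene_id == "edge"])
  expect_identical(nchar(pr$sequence[pr$gene_id == "edge"]), 40L)

  expect_identical(pr$sequence[pr$gene_id == "minus"],
                   revcomp(substr(genome[["chr"]], 901, 1000)))

  expect_error(extract_promoters(
    data.frame(gene_id = "x", chrom = "chr", start = 9990L, end = 10010L,
               strand = "+"), genome), "bounds")
})

test_that("scan reports filter at the q threshold and annotate genes", {
  hits <- data.frame(
    seqid = c("gA", "gB", "gC"), start = c(5L, 10L, 15L),
    end = c(15L, 20L, 25L), strand = "+",
    score = c(12, 9, 3), p_value = c(1e-6, 1e-4, 0.5),
    matched = "X"
  )
  attr(hits, "n_scored") <- 1000L
  promoters <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr",
                          start = 0L, end = 100L, strand = "+",
                          truncated = FALSE, sequence = "A")
  rep1 <- scan_report(hits, promoters, q_threshold = 0.6)
  expect_identical(nrow(rep1$full), 3L)
  expect_equal(rep1$full$q_value, oracle_bh(hits$p_value, n = 1000),
               tolerance = 1e-12)
  expect_identical(rep1$filtered$gene_id, c("gA", "gB"))
  expect_true(all(diff(rep1$full$p_value) >= 0))

  # saturating threshold keeps everything; impossible threshold, nothing
  expect_identical(nrow(scan_report(hits, q_threshold = 1)$filtered), 3L)
  expect_identical(nrow(scan_report(hits, q_threshold = 0)$filtered), 0L)

  # empty input stays structured
  empty <- scan_report(hits[0, ], promoters)
  expect_identical(nrow(empty$full), 0L)
})
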