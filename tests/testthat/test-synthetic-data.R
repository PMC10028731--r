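test_that("simulate_genome respects length, composition, and seed", {
  g <- simulate_genome(10, gc_fraction = 0, seed = 3)
  expect_identical(nchar(g), 10L)
  expect_false(grepl("[GC]", g))

  g1 <- simulate_genome(500, 0.5, seed = 7)
  g2 <- simulate_genome(500, 0.5, seed = 7)
  expect_identical(g1, g2)

  # binomial standard-error bound on observed GC at n = 1e5
  g3 <- simulate_genome(100000, 0.5, seed = 1)
  gc <- sum(strsplit(g3, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))

  expect_error(simulate_genome(0, 0.5), "length")
  expect_error(simulate_genome(10, 1.5), "gc_fraction")
})

test_that("site planting overwrites exactly the recorded positions", {
  # deterministic motif: every planted sequence is the consensus (or rc)
  cons <- "ACGTACGTACGTACGTACGT"
  p <- matrix(0, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  p[cbind(match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")), 1:20)] <- 1
  det <- motif_model(p)
  cfg <- regulon_config(genome_length = 5000, n_sites = 3, motif = det,
                        min_separation = 200, n_genes = 3,
                        sites_in_promoters = 0, seed = 5)
  genome <- simulate_genome(5000, 0.5, seed = 5)
  res <- sample_sites_and_plant(cfg, genome)
  expect_identical(nrow(res$truth$sites), 3L)
  for (i in 1:3) {
    s <- res$truth$sites[i, ]
    planted <- substr(res$genome, s$start + 1, s$end)
    expect_identical(planted, if (s$strand == "-") revcomp(cons) else cons)
    # conservation: outside the sites the genome is untouched
  }
  changed <- which(strsplit(res$genome, "")[[1]] != strsplit(genome, "")[[1]])
  in_sites <- unlist(mapply(function(a, b) (a + 1):b,
                            res$truth$sites$start, res$truth$sites$end))
  expect_true(all(changed %in% in_sites))

  # n_sites = 0: genome unchanged, empty truth
  cfg0 <- regulon_config(genome_length = 1000, n_sites = 0, n_genes = 0,
                         sites_in_promoters = 0, seed = 1)
  res0 <- sample_sites_and_plant(cfg0, simulate_genome(1000, 0.5, seed = 1))
  expect_identical(res0$genome, simulate_genome(1000, 0.5, seed = 1))
  expect_identical(nrow(res0$truth$sites), 0L)
})

test_that("planted plus-strand sites follow the motif sampling model", {
  # single near-deterministic column model, many sites, frequency check
  p <- matrix(0.01, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  p[1, ] <- 0.97
  m <- motif_model(p)
  withr::with_seed(11, {
    seqs <- vapply(1:200, function(i) sigmascan:::sample_site_sequence(m),
                   character(1))
  })
  freq_a <- colMeans(do.call(rbind, strsplit(seqs, "")) == "A")
  se <- sqrt(0.97 * 0.03 / 200)
  expect_true(all(abs(freq_a - 0.97) < 3 * se + 1e-12))
})

test_that("simulated coverage has the stated mean and peak structure", {
  # Poisson background oracle: no sites, mean within 3 SE
  cfg <- regulon_config(genome_length = 10000, n_sites = 0, n_genes = 0,
                        sites_in_promoters = 0, background_depth = 10,
                        seed = 2)
  tr <- simulate_chip_coverage(cfg, list(peak_centers = integer(0)))
  se <- sqrt(10 / 10000)
  expect_lt(abs(mean(tr$control$values) - 10), 3 * se)
  expect_lt(abs(mean(tr$ip$values) - 10), 3 * se)

  # null enrichment: IP and control means indistinguishable
  cfg0 <- regulon_config(genome_length = 10000, n_sites = 2,
                         enrichment = 0, n_genes = 0,
                         sites_in_promoters = 0, seed = 3)
  tr0 <- simulate_chip_coverage(cfg0, list(peak_centers = c(3000L, 7000L)))
  pooled_se <- sqrt(2 * 10 / 10000)
  expect_lt(abs(mean(tr0$ip$values) - mean(tr0$control$values)), 3 * pooled_se)

  # one site: averaged over seeds, the coverage argmax sits at the center
  cfg1 <- regulon_config(genome_length = 4000, n_sites = 1, n_genes = 0,
                         sites_in_promoters = 0, enrichment = 200,
                         peak_spread = 25, fragment_length = 50, seed = 1)
  truth1 <- list(peak_centers = 2000L)
  argmaxes <- vapply(1:20, function(s) {
    tr <- simulate_chip_coverage(cfg1, truth1, seed = s)
    which.max(tr$ip$values) - 1L
  }, integer(1))
  expect_lt(abs(stats::median(argmaxes) - 2000), 5)

  # expected center enrichment matches the closed-form overlap probability
  overlap <- sigmascan:::plaplace(25, 25) - sigmascan:::plaplace(-25, 25)
  center_cov <- vapply(1:20, function(s) {
    simulate_chip_coverage(cfg1, truth1, seed = s)$ip$values[2001]
  }, numeric(1))
  expected <- 10 + 200 * overlap
  expect_lt(abs(mean(center_cov) - expected), 4 * sqrt(expected / 20))
})

test_that("with no enrichment IP and control are exchangeable", {
  # rank-based two-sample test fails to reject in >= 95% of seeded runs
  cfg <- regulon_config(genome_length = 2000, n_sites = 3, enrichment = 0,
                        n_genes = 0, sites_in_promoters = 0, seed = 1)
  truth <- list(peak_centers = c(500L, 1000L, 1500L))
  rejections <- vapply(1:100, function(s) {
    tr <- simulate_chip_coverage(cfg, truth, seed = s)
    suppressWarnings(
      stats::wilcox.test(tr$ip$values, tr$control$values)$p.value
    ) < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)
})

test_that("fixture bundles round-trip through the package readers", {
  cfg <- regulon_config(genome_length = 8000, n_sites = 2,
                        min_separation = 500, n_genes = 4,
                        sites_in_promoters = 1, seed = 9)
  sim <- simulate_regulon(cfg)
  out <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, out)

  genome2 <- read_genome_fasta(paths$genome)
  expect_identical(unname(genome2), unname(sim$genome))

  ip2 <- read_bedgraph_track(paths$ip)
  expect_identical(ip2$values, sim$ip$values)
  expect_identical(ip2$chrom, sim$ip$chrom)

  truth2 <- read_truth_manifest(paths$truth)
  expect_identical(truth2$start, sim$truth$sites$start)
  expect_identical(truth2$sequence, sim$truth$sites$sequence)

  cds <- read_gff_cds(paths$genes)
  expect_identical(cds$start, sim$truth$genes$start)
  expect_identical(cds$end, sim$truth$genes$end)
})

test_that("GFF3 round trip converts 1-based inclusive to 0-based half-open", {
  genes <- data.frame(gene_id = "g1", chrom = "c", start = 100L, end = 400L,
                      strand = "+")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff_cds(genes, path)
  raw <- read.table(path, sep = "\t", comment.char = "#")
  expect_identical(raw$V4, 101L)  # 1-based start on disk
  expect_identical(raw$V5, 400L)  # inclusive end on disk
  back <- read_gff_cds(path)
  expect_identical(back$start, 100L)
  expect_identical(back$end, 400L)
})

test_that("simulation is deterministic and placement failures are signalled", {
  cfg <- regulon_config(genome_length = 6000, n_sites = 2, n_genes = 2,
                        min_separation = 300, sites_in_promoters = 1,
                        seed = 4)
  s1 <- simulate_regulon(cfg)
  s2 <- simulate_regulon(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$ip$values, s2$ip$values)
  expect_identical(s1$truth$sites, s2$truth$sites)

  # impossible placement: sites cannot fit with the requested separation
  bad <- regulon_config(genome_length = 500, n_sites = 10, n_genes = 0,
                        sites_in_promoters = 0, min_separation = 400,
                        seed = 1)
  expect_error(sample_sites_and_plant(bad, simulate_genome(500, 0.5, 1)),
               "non-overlapping")
})
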