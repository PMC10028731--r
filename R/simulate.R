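#' Configuration for the synthetic ChIP regulon simulator
#'
#' Describes a synthetic study: a random genome, a set of planted
#' sigma-factor binding sites sampled from a motif, annotated CDS (some
#' placed so a planted site falls in their 100 bp upstream promoter), and
#' IP/control coverage with localized, approximately triangular enrichment
#' peaks over the planted sites atop uniform Poisson background.
#'
#' The defaults describe the simulated study used throughout the test
#' suite: a 100 kb genome at GC 0.5, 12 planted sites of a width-20 motif,
#' mean background depth 10x, and 200 IP fragments of 50 bp per site with
#' Laplace-distributed midpoint displacement (scale 25 bp), which puts the
#' expected normalized coverage at a site center above 8.
#'
#' @param genome_length Genome length in bp.
#' @param gc_fraction GC content in \[0, 1\].
#' @param n_sites Number of planted motif instances.
#' @param motif [motif_model()] the sites are sampled from.
#' @param enrichment Mean IP fragment count per planted site.
#' @param background_depth Mean per-base background coverage (both tracks).
#' @param fragment_length IP fragment length in bp (>= motif width).
#' @param peak_spread Scale (bp) of the Laplace fragment-midpoint
#'   displacement around the site center; smaller = sharper peaks.
#' @param min_separation Minimum distance between planted site starts;
#'   distinct regulon loci are well separated, and separation beyond the
#'   peak footprint keeps one peak per site.
#' @param n_genes Number of annotated CDS.
#' @param sites_in_promoters How many planted sites get a CDS placed so
#'   the site falls in its 100 bp upstream promoter.
#' @param seed Random seed for the whole simulation.
#' @return An object of class `regulon_config`.
#' @export
regulon_config <- function(genome_length = 100000L, gc_fraction = 0.5,
                           n_sites = 12L, motif = example_site_motif(),
                           enrichment = 200, background_depth = 10,
                           fragment_length = 50L, peak_spread = 25,
                           min_separation = 1000L, n_genes = 10L,
                           sites_in_promoters = 3L, seed = 1L) {
  stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_sites >= 0, enrichment >= 0, background_depth >= 0,
            inherits(motif, "motif_model"))
  if (fragment_length < motif$width) {
    stop_sigmascan("fragment_length must be >= motif width")
  }
  stopifnot(sites_in_promoters <= n_sites, sites_in_promoters <= n_genes)
  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction, n_sites = as.integer(n_sites),
         motif = motif, enrichment = enrichment,
         background_depth = background_depth,
         fragment_length = as.integer(fragment_length),
         peak_spread = peak_spread,
         min_separation = as.integer(min_separation),
         n_genes = as.integer(n_genes),
         sites_in_promoters = as.integer(sites_in_promoters),
         seed = as.integer(seed)),
    class = "regulon_config"
  )
}

#' A strong example binding-site motif
#'
#' A width-20 probability matrix with the consensus letter at probability
#' 0.9 per column (the others at 1/30), giving a mean per-column
#' information content of about 1.37 bits — a well-determined
#' sigma-factor-like site used as the simulator default.
#'
#' @param width Motif width (default 20).
#' @param consensus Optional consensus string (overrides `width`).
#' @param strength Probability of the consensus letter per column.
#' @return A [motif_model()].
#' @export
example_site_motif <- function(width = 20L, consensus = NULL, strength = 0.9) {
  if (is.null(consensus)) {
    # fixed, arbitrary consensus; sigma-factor promoters are AT-rich-ish
    base <- "TTGACATAGCTATAATGCTA"
    consensus <- paste(rep(strsplit(base, "")[[1]], length.out = width),
                       collapse = "")
  }
  idx <- encode_dna(consensus)
  p <- matrix((1 - strength) / 3, nrow = 4L, ncol = length(idx))
  p[cbind(idx, seq_along(idx))] <- strength
  motif_model(p, n_sites = NA_integer_)
}

#' Simulate a random genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`. Identical seeds give identical
#' sequences.
#'
#' @param length Genome length in bp (> 0).
#' @param gc_fraction GC content in \[0, 1\].
#' @param seed Random seed (NULL = current RNG stream).
#' @return A character scalar over A/C/G/T.
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  if (length <= 0) stop_sigmascan("genome length must be > 0")
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop_sigmascan("gc_fraction must lie in [0, 1]")
  }
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  with_seed_or_current(seed, {
    paste(sample(DNA_LETTERS, length, replace = TRUE, prob = p),
          collapse = "")
  })
}

# sample one site sequence column-wise from a motif's probability matrix
sample_site_sequence <- function(motif) {
  idx <- vapply(seq_len(motif$width), function(i) {
    sample.int(4L, 1L, prob = motif$probs[, i])
  }, integer(1))
  decode_dna(idx)
}

#' Plant motif-sampled sites into a genome
#'
#' Samples `n_sites` sequences column-independently from the motif's
#' probability matrix and overwrites the genome at non-overlapping
#' positions (uniform rejection sampling with at least
#' `min_separation` bp between site starts, capped at `1000 * n_sites`
#' attempts); each site's strand is chosen uniformly and minus-strand
#' sites are planted as the reverse complement. Sites are kept >= 2 kb
#' from the genome ends so peak windows and downstream CDS always fit.
#'
#' @param config A [regulon_config()].
#' @param genome Genome sequence (character scalar).
#' @param seed Random seed (default `config$seed`).
#' @return list with `genome` (modified sequence) and `truth`, a list with
#'   `sites` (data.frame: site_id, chrom, start, end, strand, sequence —
#'   the sampled, motif-oriented sequence), `peak_centers`, and `genes`
#'   (data.frame: gene_id, chrom, start, end, strand,
#'   has_site_in_promoter); coordinates 0-based half-open.
#' @export
sample_sites_and_plant <- function(config, genome, seed = config$seed) {
  stopifnot(inherits(config, "regulon_config"))
  L <- nchar(genome)
  w <- config$motif$width
  if (w > L) stop_sigmascan("motif wider than the genome")
  chrom <- "synthetic_1"
  empty_sites <- data.frame(site_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), sequence = character(),
                            stringsAsFactors = FALSE)
  if (config$n_sites == 0L) {
    genes <- simulate_gene_records(config, empty_sites, L, chrom)
    return(list(genome = genome,
                truth = list(sites = empty_sites, peak_centers = integer(0),
                             genes = genes, chrom = chrom)))
  }
  with_seed_or_current(seed, {
    margin <- min(2000L, max(0L, (L - config$n_sites * w) %/% 4L))
    starts <- integer(0)
    attempts <- 0L
    while (length(starts) < config$n_sites) {
      attempts <- attempts + 1L
      if (attempts > 1000L * max(config$n_sites, 1L)) {
        stop_sigmascan("could not place ", config$n_sites,
                       " non-overlapping sites; genome too small or min_separation too large")
      }
      cand <- sample.int(L - w - 2L * margin + 1L, 1L) + margin - 1L  # 0-based
      if (all(abs(cand - starts) >= max(config$min_separation, w)) || !length(starts)) {
        starts <- c(starts, cand)
      }
    }
    starts <- sort(starts)

    sites <- NULL
    seqs <- character(0); strands <- character(0)
    g <- genome
    for (i in seq_along(starts)) {
      s <- sample_site_sequence(config$motif)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "-") revcomp(s) else s
      substr(g, starts[i] + 1L, starts[i] + w) <- planted
      seqs <- c(seqs, s); strands <- c(strands, strand)
    }
    sites <- data.frame(
      site_id = sprintf("site_%02d", seq_along(starts)), chrom = chrom,
      start = starts, end = starts + w, strand = strands, sequence = seqs,
      stringsAsFactors = FALSE
    )

    genes <- simulate_gene_records(config, sites, L, chrom)
    truth <- list(sites = sites,
                  peak_centers = as.integer(floor(starts + w / 2)),
                  genes = genes, chrom = chrom)
    list(genome = g, truth = truth)
  })
}

# CDS records: the first `sites_in_promoters` sites each get a plus-strand
# CDS whose 100 bp promoter contains the site; remaining genes are placed
# away from all sites.
simulate_gene_records <- function(config, sites, L, chrom) {
  if (config$n_genes == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), has_site_in_promoter = logical()))
  }
  cds_len <- 600L
  genes <- list()
  k <- config$sites_in_promoters
  if (k > 0L && nrow(sites) > 0L) {
    promoted <- seq_len(min(k, nrow(sites)))
    for (j in promoted) {
      s <- sites$end[j] + 20L  # site sits at [start, end) in [s-100, s)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("gene_site_%02d", j), chrom = chrom,
        start = s, end = min(L, s + cds_len), strand = "+",
        has_site_in_promoter = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  n_bg <- config$n_genes - length(genes)
  occupied <- rbind(
    data.frame(start = sites$start - 500L, end = sites$end + 500L),
    do.call(rbind, lapply(genes, function(gdf) {
      data.frame(start = gdf$start - 200L, end = gdf$end + 200L)
    }))
  )
  attempts <- 0L
  while (n_bg > 0L) {
    attempts <- attempts + 1L
    if (attempts > 1000L * config$n_genes) {
      stop_sigmascan("could not place background genes away from sites")
    }
    st <- sample.int(max(L - cds_len - 200L, 1L), 1L) + 100L - 1L
    en <- st + cds_len
    if (en > L) next
    if (!is.null(occupied) && nrow(occupied) > 0 &&
        any(st < occupied$end & en > occupied$start)) next
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene_bg_%02d", n_bg)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, chrom = chrom, start = st, end = en, strand = strand,
      has_site_in_promoter = FALSE, stringsAsFactors = FALSE
    )
    occupied <- rbind(occupied, data.frame(start = st - 200L, end = en + 200L))
    n_bg <- n_bg - 1L
  }
  out <- do.call(rbind, genes)
  rownames(out) <- NULL
  out
}

#' Simulate IP and control ChIP coverage
#'
#' The control track is uniform Poisson noise at `background_depth`. The
#' IP track is Poisson around a deterministic expected pileup: background
#' plus, for each planted site, `enrichment` fragments of
#' `fragment_length` bp whose midpoints are Laplace-displaced (scale
#' `peak_spread`) from the site center — the expected per-base pileup is
#' `enrichment * P(fragment overlaps the base)`, maximal at the site
#' center and decaying monotonically, giving the sharply peaked,
#' near-triangular local pileups of a localized ChIP-seq peak.
#'
#' @param config A [regulon_config()].
#' @param truth Ground truth from [sample_sites_and_plant()].
#' @param seed Random seed (default `config$seed + 1` so coverage noise is
#'   independent of site placement).
#' @return list with `ip` and `control` [coverage_track()]s (raw counts).
#' @export
simulate_chip_coverage <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "regulon_config"))
  L <- config$genome_length
  lambda <- rep(config$background_depth, L)
  fl <- config$fragment_length
  h <- fl %/% 2L
  if (length(truth$peak_centers) > 0 && config$enrichment > 0) {
    R <- as.integer(ceiling(8 * config$peak_spread + fl))
    offs <- (-R):R
    # P(fragment [m-h, m-h+fl) covers center + off), midpoint m ~ Laplace
    p_cover <- plaplace(offs + h, config$peak_spread) -
      plaplace(offs + h - fl, config$peak_spread)
    for (c0 in truth$peak_centers) {
      pos <- c0 + offs + 1L  # 1-based
      keep <- pos >= 1L & pos <= L
      lambda[pos[keep]] <- lambda[pos[keep]] +
        config$enrichment * p_cover[keep]
    }
  }
  chrom <- if (!is.null(truth$chrom)) truth$chrom else "synthetic_1"
  with_seed_or_current(seed, {
    ip <- stats::rpois(L, lambda)
    ctl <- stats::rpois(L, config$background_depth)
    list(ip = coverage_track(ip, chrom = chrom),
         control = coverage_track(ctl, chrom = chrom))
  })
}

#' Run the whole simulator
#'
#' Genome, planted sites, gene annotations, and IP/control coverage from
#' one config, deterministically from `config$seed`.
#'
#' @param config A [regulon_config()].
#' @return list with `genome` (named character vector), `truth`, `ip`,
#'   `control`.
#' @export
simulate_regulon <- function(config) {
  stopifnot(inherits(config, "regulon_config"))
  genome <- simulate_genome(config$genome_length, config$gc_fraction,
                            seed = config$seed)
  planted <- sample_sites_and_plant(config, genome, seed = config$seed + 10000L)
  tracks <- simulate_chip_coverage(config, planted$truth,
                                   seed = config$seed + 20000L)
  chrom <- planted$truth$chrom
  list(genome = stats::setNames(planted$genome, chrom),
       truth = planted$truth, ip = tracks$ip, control = tracks$control)
}

#' Write a simulated study to disk as standard formats
#'
#' Emits the genome as FASTA, the coverage tracks as bedGraph, the gene
#' records as GFF3 (1-based inclusive CDS features with strand and ID),
#' and the planted-site truth as a TSV manifest; everything round-trips
#' through the package readers per-base/per-letter identically.
#'
#' @param sim Output of [simulate_regulon()] (or a compatible list).
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (the manifest).
#' @export
write_fixture_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    ip = file.path(out_dir, "ip.bedGraph"),
    control = file.path(out_dir, "control.bedGraph"),
    genes = file.path(out_dir, "genes.gff3"),
    truth = file.path(out_dir, "truth.tsv")
  )
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, paths$genome)
  write_bedgraph_track(sim$ip, paths$ip)
  write_bedgraph_track(sim$control, paths$control)
  write_gff_cds(sim$truth$genes, paths$genes)
  utils::write.table(sim$truth$sites, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Write CDS records as GFF3
#'
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open), strand.
#' @param path Output GFF3.
#' @return `path`, invisibly.
#' @export
write_gff_cds <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "sigmascan"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a FASTA genome as a named character vector
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dna)),
                  sub("\\s.*$", "", names(dna)))
}

#' Read a planted-site truth manifest
#' @param path TSV written by [write_fixture_bundle()].
#' @return data.frame of sites.
#' @export
read_truth_manifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
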