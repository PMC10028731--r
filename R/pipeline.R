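#' Default pipeline configuration
#'
#' Returns the fully materialized configuration list for [run_all()], with
#' every analysis default named: `ip_threshold = 4`, `control_threshold =
#' 3` (dual-threshold peak rule), `window = 60` (summit-centered site
#' window), `r_threshold = 1` (information masking cut, bits),
#' `promoter_len = 100` (bp upstream of each CDS), `p_threshold = 1e-4`
#' and `q_threshold = 0.6` (scan reporting cuts).
#'
#' @param out_dir Output directory, or NULL for no file output.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = NULL) {
  list(
    paths = list(genome = NULL, ip = NULL, controls = NULL, gff = NULL,
                 out_dir = out_dir),
    peaks = list(ip_threshold = 4, control_threshold = 3, min_width = 1,
                 merge_gap = 30, window = 60, triangularity_min = 0.8,
                 shape_flank = 60, exclusions = NULL),
    motif = list(mode = "discover", width = 20, n_starts = 5,
                 max_iter = 200, tol = 1e-6, pseudocount = 0,
                 min_windows = 2),
    scan = list(p_threshold = 1e-4, q_threshold = 0.6, smoothing = 1e-4,
                step = 0.001, both_strands = TRUE,
                background = "query", promoter_len = 100),
    simulate = NULL,
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; everything else is materialized so the run
#' manifest records the full effective configuration.
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), user)
}

validate_pipeline_paths <- function(config, need = c("genome", "ip")) {
  for (key in need) {
    p <- config$paths[[key]]
    if (is.null(p)) {
      stop_sigmascan("config error: paths$", key, " is required for this stage")
    }
    for (f in unlist(p)) {
      if (!file.exists(f)) stop_sigmascan("config error: missing input file ", f)
    }
  }
  invisible(TRUE)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_sigmascan(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the peak-calling stage
#'
#' normalize -> exclude -> dual-threshold call -> triangularity screen ->
#' summit-window extraction, with per-step counts returned (and written,
#' with a BED/TSV/FASTA bundle, when `config$paths$out_dir` is set).
#'
#' @param config Pipeline configuration (see
#'   [default_pipeline_config()]).
#' @param ip,controls,genome Optional in-memory inputs (raw
#'   [coverage_track()]s and a named genome vector); read from
#'   `config$paths` when NULL.
#' @return list with `peaks` (all called peaks), `kept` (peaks passing the
#'   shape screen), `windows` (named site-window sequences), and `counts`.
#' @export
run_peaks_stage <- function(config, ip = NULL, controls = NULL,
                            genome = NULL) {
  stage_error("peaks", {
    if (is.null(ip)) {
      validate_pipeline_paths(config, c("genome", "ip", "controls"))
      ip <- read_bedgraph_track(config$paths$ip)
      controls <- lapply(unlist(config$paths$controls), read_bedgraph_track)
      genome <- read_genome_fasta(config$paths$genome)
    }
    if (inherits(controls, "coverage_track")) controls <- list(controls)
    pc <- config$peaks
    excl <- pc$exclusions
    if (!is.null(excl)) excl <- as.data.frame(excl)

    prep <- function(tr) {
      if (!is.null(excl)) tr <- apply_exclusions(tr, excl)
      if (!tr$normalized) tr <- normalize_coverage(tr)
      tr
    }
    ip_n <- prep(ip)
    controls_n <- lapply(controls, prep)

    params <- peak_params(
      ip_threshold = pc$ip_threshold, control_threshold = pc$control_threshold,
      min_width = pc$min_width, merge_gap = pc$merge_gap,
      exclusions = excl, window_width = pc$window,
      triangularity_min = pc$triangularity_min,
      shape_flank = pc$shape_flank
    )
    peaks <- call_peaks(ip_n, controls_n, params)
    kept <- peaks[peaks$passed_shape, , drop = FALSE]
    windows <- if (nrow(kept)) {
      extract_site_windows(genome, kept, pc$window)
    } else character(0)
    counts <- c(peaks_called = nrow(peaks), peaks_passing_shape = nrow(kept),
                windows_extracted = length(windows))
    if (!is.null(config$paths$out_dir)) {
      od <- config$paths$out_dir
      dir.create(od, recursive = TRUE, showWarnings = FALSE)
      write_peaks_bed(kept, file.path(od, "peaks.bed"),
                      file.path(od, "peaks.tsv"))
      if (length(windows)) {
        Biostrings::writeXStringSet(Biostrings::DNAStringSet(windows),
                                    file.path(od, "site_windows.fasta"))
      }
    }
    list(peaks = peaks, kept = kept, windows = windows, counts = counts,
         ip_normalized = ip_n)
  })
}

#' Run the motif stage
#'
#' Either de novo ZOOPS-EM discovery on the site windows
#' (`config$motif$mode = "discover"`) or the direct
#' probability-matrix-from-windows route (`mode = "ppm"`), plus the
#' per-position information profile.
#'
#' @param config Pipeline configuration.
#' @param windows Named character vector of site windows.
#' @return list with `model` ([motif_model()]), `r_seq` (information
#'   profile in bits), `fit` (the EM fit in discover mode), `counts`.
#' @export
run_motif_stage <- function(config, windows) {
  stage_error("motif", {
    mc <- config$motif
    if (length(windows) < mc$min_windows) {
      stop_sigmascan("need at least ", mc$min_windows, " site windows, got ",
                     length(windows))
    }
    fit <- NULL
    if (identical(mc$mode, "ppm")) {
      model <- counts_to_probabilities(build_count_matrix(windows),
                                       pseudocount = mc$pseudocount)
    } else {
      fit <- discover_motif_zoops(windows, width = mc$width,
                                  n_starts = mc$n_starts,
                                  max_iter = mc$max_iter, tol = mc$tol,
                                  seed = config$seed)
      model <- fit$model
    }
    r <- information_content(model)
    if (!is.null(config$paths$out_dir)) {
      od <- config$paths$out_dir
      dir.create(od, recursive = TRUE, showWarnings = FALSE)
      write_meme_motif(model, file.path(od, "motif.meme"))
      write_information_profile(model, file.path(od, "information_profile.tsv"))
    }
    list(model = model, r_seq = r, fit = fit,
         counts = c(windows_used = length(windows),
                    informative_positions = sum(r > 1)))
  })
}

#' Run the scanning stage
#'
#' For each query sequence (the promoters extracted from the annotation,
#' or arbitrary sequences): compute the query's own mononucleotide
#' composition, mask motif columns with information content at or below
#' `r_threshold` with it, build the smoothed log-odds matrix and its exact
#' score distribution under that composition, scan both strands, then
#' attach Benjamini-Hochberg q-values over all windows scored in the run
#' and report hits at `p <= p_threshold`, filtered at `q <= q_threshold`.
#'
#' @param config Pipeline configuration.
#' @param model A [motif_model()] (unmasked; masking is per query).
#' @param genome Named genome vector (required when `cds` is given).
#' @param cds CDS table ([read_gff_cds()]) for promoter extraction, or
#'   NULL to scan `queries`.
#' @param queries Named character vector of sequences to scan when `cds`
#'   is NULL (defaults to the genome).
#' @param r_threshold Masking threshold in bits (default 1).
#' @return list with `report` (full and filtered hit tables), `promoters`
#'   (when extracted), `counts`.
#' @export
run_scan_stage <- function(config, model, genome = NULL, cds = NULL,
                           queries = NULL, r_threshold = 1) {
  stage_error("scan", {
    sc <- config$scan
    promoters <- NULL
    if (!is.null(cds)) {
      promoters <- extract_promoters(cds, genome,
                                     promoter_len = sc$promoter_len)
      queries <- stats::setNames(promoters$sequence, promoters$gene_id)
    } else if (is.null(queries)) {
      queries <- genome
    }
    queries <- queries[nchar(queries) >= model$width]
    if (length(queries) == 0L) stop_sigmascan("no query long enough to scan")

    all_hits <- list()
    n_scored <- 0L
    for (qi in seq_along(queries)) {
      qname <- names(queries)[qi]
      qseq <- queries[[qi]]
      bg <- if (identical(sc$background, "uniform")) {
        c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
      } else {
        background_composition(qseq)
      }
      masked <- mask_motif(model, bg, r_threshold = r_threshold)
      lom <- log_odds_matrix(masked, bg, smoothing = sc$smoothing)
      dist <- score_distribution(lom, bg, step = sc$step)
      hits <- scan_sequence(lom, dist, qseq, p_threshold = sc$p_threshold,
                            both_strands = sc$both_strands, seqid = qname)
      n_scored <- n_scored + attr(hits, "n_scored")
      all_hits[[qi]] <- hits
    }
    hits <- do.call(rbind, all_hits)
    report <- scan_report(hits, promoters = promoters,
                          q_threshold = sc$q_threshold, n_scored = n_scored)
    if (!is.null(config$paths$out_dir)) {
      od <- config$paths$out_dir
      dir.create(od, recursive = TRUE, showWarnings = FALSE)
      write_hits(report$full, file.path(od, "hits_full.tsv"))
      write_hits(report$filtered, file.path(od, "hits_filtered.tsv"),
                 file.path(od, "hits_filtered.bed"))
    }
    list(report = report, promoters = promoters,
         counts = c(queries_scanned = length(queries),
                    windows_scored = n_scored,
                    hits_reported = nrow(report$full),
                    hits_below_q = nrow(report$filtered)))
  })
}

#' Run the whole pipeline
#'
#' Optional simulation, then peaks -> motif -> scan; returns a run
#' manifest with the effective configuration and the per-stage counts the
#' analysis narrates (peaks before/after the shape screen, windows used,
#' hits below the q cut). With `config$simulate` set (a
#' [regulon_config()] or a list of its arguments), the study is simulated
#' in memory; otherwise all inputs come from `config$paths`.
#'
#' @param config Pipeline configuration.
#' @return list with `manifest`, `peaks`, `motif`, `scan`, and (when
#'   simulated) `truth`.
#' @export
run_all <- function(config) {
  full <- modifyList(default_pipeline_config(), config)
  truth <- NULL
  if (!is.null(full$simulate)) {
    simcfg <- full$simulate
    if (!inherits(simcfg, "regulon_config")) {
      simcfg <- do.call(regulon_config, simcfg)
    }
    sim <- simulate_regulon(simcfg)
    truth <- sim$truth
    genome <- sim$genome
    ip <- sim$ip; controls <- list(sim$control)
    cds <- truth$genes
  } else {
    validate_pipeline_paths(full, c("genome", "ip", "controls"))
    genome <- read_genome_fasta(full$paths$genome)
    ip <- read_bedgraph_track(full$paths$ip)
    controls <- lapply(unlist(full$paths$controls), read_bedgraph_track)
    cds <- if (!is.null(full$paths$gff)) read_gff_cds(full$paths$gff) else NULL
  }
  pk <- run_peaks_stage(full, ip = ip, controls = controls, genome = genome)
  mo <- run_motif_stage(full, pk$windows)
  scn <- run_scan_stage(full, mo$model, genome = genome, cds = cds)
  manifest <- list(
    config = full[setdiff(names(full), "simulate")],
    seed = full$seed,
    counts = c(pk$counts, mo$counts, scn$counts),
    consensus = consensus_string(mo$model),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  if (!is.null(full$paths$out_dir)) {
    dir.create(full$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      manifest[c("seed", "counts", "consensus", "timestamp")],
      file.path(full$paths$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  list(manifest = manifest, peaks = pk, motif = mo, scan = scn,
       truth = truth)
}
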