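# End-to-end orchestration: simulate, analyse, validate, calibrate.

#' Deterministic wild-type reference call table
#'
#' The expected wild-type observation of the simulated landscape: each dyad
#' reported at its wild-type baseline level with a fixed pseudo-depth.
#' Used as the matching reference for off-target background selection and
#' CGI classification when no sequenced wild-type sample is available.
#'
#' @param truth A `meth_truth`.
#' @param depth Pseudo-coverage assigned to each dyad.
#' @return A call table (chrom, pos, context, n_meth, n_total, level).
#' @export
wt_reference_calls <- function(truth, depth = 1000L) {
  stopifnot(inherits(truth, "meth_truth"))
  n_meth <- as.integer(round(truth$baseline_wt * depth))
  data.frame(chrom = rep(truth$chrom, length(truth$dyads)),
             pos = truth$dyads, context = rep("CG", length(truth$dyads)),
             n_meth = n_meth, n_total = rep(as.integer(depth), length(truth$dyads)),
             level = n_meth / depth, stringsAsFactors = FALSE)
}

#' Estimate the off-target gain rate from a gain curve
#'
#' Under uniform susceptibility with maintenance and divisions disabled,
#' the per-strand true methylated fraction after `t` days from an
#' unmethylated start is `1 - exp(-r_off * t)`. Observed levels are first
#' corrected for the bisulfite observation floor
#' (`obs = true * protection_rate + (1 - true) * (1 - conversion_rate)`),
#' then `-log(1 - true)` is regressed through the origin on day.
#'
#' @param days Numeric vector of days.
#' @param observed_means Genome-wide observed mean level per day.
#' @param config The [sim_config()] used (for the error rates).
#' @return Estimated rate per strand per day.
#' @export
estimate_r_off <- function(days, observed_means, config) {
  floor_ <- 1 - config$conversion_rate
  top_ <- config$protection_rate
  true_ <- pmin(0.999999, pmax(0, (observed_means - floor_) / (top_ - floor_)))
  y <- -log(1 - true_)
  use <- days > 0
  sum(days[use] * y[use]) / sum(days[use]^2)
}

#' Run a full simulation and write all outputs
#'
#' Generates the genome and landscape, simulates footprinting over `days`,
#' samples reads per day, and writes: genome FASTA, CGI/enhancer/sgRNA BED,
#' per-day call tables (coverage dialect) and read-level TSVs, ground-truth
#' TSV, wild-type reference call table, per-CGI ChIP-like H3K4me3 counts,
#' and a JSON manifest with config, seed and per-file MD5 checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; must not exist or be empty unless
#'   `force`.
#' @param sgrnas Optional protospacer data frame (chrom/start/end/strand).
#' @param days Ascending days starting at 0.
#' @param force Overwrite a non-empty `out_dir`.
#' @return The manifest, invisibly.
#' @export
run_simulation <- function(config, out_dir, sgrnas = NULL, days = c(0, 2, 7),
                           force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop(sprintf("output directory %s is not empty (use force = TRUE)", out_dir),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- generate_genome(config)
  truth0 <- assign_wt_landscape(genome, config)
  series <- simulate_footprinting(truth0, sgrnas, config, days = days)

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                cgi = file.path(out_dir, "cgi.bed"),
                enhancers = file.path(out_dir, "enhancers.bed"),
                truth = file.path(out_dir, "truth.tsv"),
                wt_reference = file.path(out_dir, "wt_reference.cov"),
                chip = file.path(out_dir, "k4_chip_counts.tsv"))
  write_genome_fasta(genome, paths$genome)
  with_chrom <- function(tab) cbind(data.frame(chrom = rep(genome$chrom, nrow(tab)),
                                               stringsAsFactors = FALSE), tab)
  write_bed(with_chrom(genome$cgi), paths$cgi)
  write_bed(with_chrom(genome$enhancers), paths$enhancers)
  if (!is.null(sgrnas)) {
    paths$sgrnas <- file.path(out_dir, "sgrnas.bed")
    write_bed(sgrnas, paths$sgrnas)
  }
  write_call_table(wt_reference_calls(truth0), paths$wt_reference)

  # ChIP-like H3K4me3 counts per CGI: Poisson with mean proportional to
  # k4_density and island length
  set.seed(config$seed + 3L)
  cgi <- truth0$cgi
  if (nrow(cgi)) {
    lam <- cgi$k4_density * (cgi$end - cgi$start) * 0.5
    chip <- data.frame(chrom = rep(genome$chrom, nrow(cgi)), start = cgi$start,
                       end = cgi$end, count = stats::rpois(nrow(cgi), lam))
  } else {
    chip <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), count = integer(0))
  }
  .write_tsv(chip, paths$chip, "chrom\tstart\tend\tcount")

  truth_rows <- list()
  for (d in names(series)) {
    smp <- sample_reads(series[[d]], config,
                        seed = config$seed + 1000L + as.integer(d),
                        sample = paste0("day", d))
    paths[[paste0("calls_day", d)]] <- file.path(out_dir, sprintf("calls_day%s.cov", d))
    paths[[paste0("reads_day", d)]] <- file.path(out_dir, sprintf("reads_day%s.tsv", d))
    write_call_table(smp$calls[smp$calls$context == "CG", , drop = FALSE],
                     paths[[paste0("calls_day", d)]])
    if (any(smp$calls$context == "CA")) {
      paths[[paste0("calls_ca_day", d)]] <-
        file.path(out_dir, sprintf("calls_ca_day%s.cov", d))
      write_call_table(smp$calls[smp$calls$context == "CA", , drop = FALSE],
                       paths[[paste0("calls_ca_day", d)]])
    }
    write_read_table(smp$reads, paths[[paste0("reads_day", d)]])
    truth_rows[[d]] <- truth_fractions(series[[d]])
  }
  write_truth_table(do.call(rbind, truth_rows), paths$truth)

  manifest <- list(tool = "methfootprint",
                   version = as.character(utils::packageVersion("methfootprint")),
                   seed = config$seed,
                   days = as.integer(names(series)),
                   config = unclass(config),
                   files = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the footprint analysis over a simulation directory
#'
#' Sequences the analysis stages over the outputs of [run_simulation()]:
#' per-tile paired tests between day 0 and the last day, per-CGI tests,
#' CGI class summary against the wild-type reference, H3K4me3 scores,
#' 1 kb delta histogram, top-k tile overlap across days, read-level
#' none/some classification over the significant tiles, a smoothed track
#' for the densest CGI neighbourhood, and a context summary when CA calls
#' are present. Writes per-stage TSVs plus `summary.tsv` and logs every
#' threshold applied.
#'
#' @param sim_dir Directory written by [run_simulation()].
#' @param config An [analysis_config()].
#' @param out_dir Output directory (default `file.path(sim_dir,
#'   "analysis")`).
#' @param quiet Suppress progress messages.
#' @return List of per-stage results plus a `summary` data frame,
#'   invisibly.
#' @export
run_footprint_analysis <- function(sim_dir, config = analysis_config(),
                                   out_dir = file.path(sim_dir, "analysis"),
                                   quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- jsonlite::read_json(file.path(sim_dir, "manifest.json"))
  days <- unlist(manifest$days)
  d_last <- max(days)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("thresholds: min_cov_summary=%g min_cov_test=%g min_cpgs=%d tile_width=%d alpha=%g min_delta=%g match_tol=%g top_k=%d",
      config$min_cov_summary, config$min_cov_test, config$min_cpgs,
      config$tile_width, config$alpha, config$min_delta, config$match_tol,
      config$top_k)

  calls <- stage("load_calls", {
    out <- lapply(days, function(d)
      read_call_table(file.path(sim_dir, sprintf("calls_day%d.cov", d)),
                      min_coverage = 1))
    names(out) <- as.character(days)
    out
  })
  wt <- stage("load_wt", read_call_table(file.path(sim_dir, "wt_reference.cov")))
  cgis <- stage("load_cgi", read_bed(file.path(sim_dir, "cgi.bed")))

  tiles <- stage("tile_diff", tile_diff(calls[["0"]], calls[[as.character(d_last)]],
                                        config))
  write_tile_stats(tiles, file.path(out_dir, "tile_diff.tsv"))
  say("tile_diff: %d tiles tested, %d significant", nrow(tiles),
      sum(tiles$significant))

  cgi_stats <- stage("cgi_test", cgi_test(calls[["0"]],
                                          calls[[as.character(d_last)]],
                                          cgis, config))
  write_tile_stats(cgi_stats, file.path(out_dir, "cgi_test.tsv"))

  classes <- stage("cgi_class",
                   cgi_class_summary(wt, calls[[as.character(d_last)]], cgis, config))
  k4 <- stage("k4_score", {
    chip <- read_chip_counts(file.path(sim_dir, "k4_chip_counts.tsv"))
    cgi_k4_score(chip, config)
  })
  dh <- stage("delta_histogram",
              delta_histogram(calls[["0"]], calls[[as.character(d_last)]], config))
  topk <- stage("top_k", top_k_overlap(calls, config))

  sig <- tiles[tiles$significant, c("chrom", "start", "end"), drop = FALSE]
  rl <- stage("read_level", {
    reads <- read_read_table(file.path(sim_dir, sprintf("reads_day%d.tsv", d_last)))
    if (nrow(sig)) hemimethylation_report(reads, sig) else NULL
  })

  smooth <- stage("smooth", {
    cc <- calls[[as.character(d_last)]]
    if (nrow(cc) >= 10) {
      n <- min(nrow(cc), 500)
      loess_smooth(cc$pos[seq_len(n)], cc$level[seq_len(n)], config$loess_span)
    } else NULL
  })
  if (!is.null(smooth))
    write_smoothed_track(smooth, file.path(out_dir, "smoothed_track.tsv"))

  ctx <- NULL
  ca_path <- file.path(sim_dir, sprintf("calls_ca_day%d.cov", d_last))
  if (file.exists(ca_path)) {
    ca <- read_call_table(ca_path)
    ca$context <- "CA"
    both <- rbind(calls[[as.character(d_last)]], ca)
    ctx <- stage("context", context_summary(both, min_cov = config$min_cov_summary))
  }

  global_means <- vapply(calls, function(cc)
    mean(cc$level[cc$n_total >= config$min_cov_summary]), numeric(1))
  summary <- data.frame(
    statistic = c(paste0("global_mean_day", names(calls)),
                  "tiles_tested", "tiles_significant", "sig_tile_fraction",
                  "cgis_tested", "cgis_significant",
                  "frac_some_sig_tiles"),
    value = c(global_means, nrow(tiles), sum(tiles$significant),
              if (nrow(tiles)) sum(tiles$significant) / nrow(tiles) else NA_real_,
              nrow(cgi_stats), sum(cgi_stats$significant),
              if (!is.null(rl)) rl$pooled$frac_some else NA_real_),
    stringsAsFactors = FALSE)
  .write_tsv(data.frame(statistic = summary$statistic,
                        value = sprintf("%.6g", summary$value)),
             file.path(out_dir, "summary.tsv"), "statistic\tvalue")

  invisible(list(tiles = tiles, cgi_stats = cgi_stats, classes = classes,
                 k4 = k4, delta_hist = dh, top_k = topk, read_level = rl,
                 smooth = smooth, context = ctx, summary = summary))
}

#' Validate input files
#'
#' Report-only format and invariant checks for a set of input files.
#'
#' @param paths Character vector of file paths; names give the expected
#'   type per file: `call_table`, `bed`, `sgrna`, `reads`, `truth`, or
#'   `chip`. Unnamed entries are guessed from the file extension.
#' @return Data frame: file, type, ok, message.
#' @export
validate_inputs <- function(paths) {
  types <- names(paths) %||% rep("", length(paths))
  res <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    ty <- types[i]
    if (!nzchar(ty) || ty %in% as.character(seq_along(paths))) {
      ty <- switch(tools::file_ext(p), cov = "call_table", bed = "bed",
                   fa = "fasta", tsv = "tsv", "unknown")
    }
    msg <- "ok"; ok <- TRUE
    out <- tryCatch({
      switch(ty,
             call_table = {
               x <- read_call_table(p)
               if (nrow(x) == 0) msg <- "ok (empty)"
             },
             bed = {
               x <- read_bed(p)
               if (nrow(x) == 0) msg <- "warning: empty BED"
             },
             sgrna = invisible(read_sgrnas(p)),
             reads = invisible(read_read_table(p)),
             truth = invisible(read_truth_table(p)),
             chip = invisible(read_chip_counts(p)),
             fasta = invisible(Biostrings::readDNAStringSet(p)),
             msg <- "skipped: unknown type")
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(out)) { ok <- FALSE; msg <- out }
    data.frame(file = p, type = ty, ok = ok, message = msg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build a time-course table from call-table files
#'
#' @param manifest Data frame with columns clone, day, path.
#' @param min_coverage Passed to [read_call_table()].
#' @return The manifest with a `calls` list-column added.
#' @export
read_time_course <- function(manifest, min_coverage = 1) {
  stopifnot(all(c("clone", "day", "path") %in% names(manifest)))
  if (!0 %in% manifest$day) stop("day 0 must be present", call. = FALSE)
  manifest$calls <- lapply(manifest$path, read_call_table,
                           min_coverage = min_coverage)
  manifest
}
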