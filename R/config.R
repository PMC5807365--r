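`%||%` <- function(a, b) if (is.null(a)) b else a

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, deparse(x)), call. = FALSE)
  as.numeric(x)
}

.check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("`%s` must be a single %s number, got %s", name,
                 if (strict) "positive" else "non-negative", deparse(x)),
         call. = FALSE)
  as.numeric(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic methylome generator. Defaults emulate a
#' methylation-depleted (global mean ~0.04), maintenance-competent embryonic
#' stem cell system expressing an inducible dCas9-methyltransferase fusion:
#' a bimodal wild-type-like landscape (CpG islands low, bulk genome high,
#' a minority of enhancer-like tiles intermediate), H3K4me3 density
#' anti-correlated with island methylation, sgRNA-directed on-target gain
#' with exponential distance decay, and globally distributed off-target gain
#' whose susceptibility tracks the prior (wild-type) methylation state.
#'
#' @param seed Integer seed; mandatory so every run is reproducible.
#' @param genome_length Simulated genome size in bp.
#' @param n_cgis Number of CpG islands.
#' @param cgi_length_range Min/max CGI length in bp.
#' @param cpg_rate_background,cpg_rate_cgi Per-bp probability that a CpG dyad
#'   starts at a position (renewal placement, see [generate_genome()]).
#' @param enhancer_fraction Fraction of non-CGI 200 bp tiles labelled
#'   enhancer-like (intermediate baseline methylation).
#' @param wt_mode `"depleted"` scales the wild-type landscape so the global
#'   mean equals `depleted_mean`; `"wild_type"` keeps it as drawn.
#' @param depleted_mean Target global mean methylation in depleted mode.
#' @param cgi_hyper_fraction Fraction of CGIs forced hypermethylated
#'   (wild-type mean > 0.8) with low H3K4me3.
#' @param r_off Per-strand, per-day off-target methylation gain rate.
#' @param r_on Per-strand, per-day on-target rate at zero distance from the
#'   protospacer.
#' @param spread_lambda Exponential distance-decay constant of the on-target
#'   rate, bp.
#' @param on_target_window Width in bp of the window centred on the
#'   protospacer within which the on-target rate applies.
#' @param k4_protection Multiplier in `[0, 1]`: susceptibility inside a CGI is
#'   scaled by `1 - k4_protection * k4_density`.
#' @param susceptibility_mode `"wt_state"` makes off-target susceptibility
#'   proportional to the wild-type baseline (floored at
#'   `susceptibility_floor`); `"uniform"` sets it to 1 everywhere, the
#'   identifiable regime used for rate calibration.
#' @param susceptibility_floor Lower bound on per-dyad susceptibility in
#'   `wt_state` mode.
#' @param maintenance_fidelity Probability that a hemimethylated dyad is
#'   restored to fully methylated at each division.
#' @param divisions_per_day Cell divisions per simulated day.
#' @param maintenance_on If `FALSE`, the nascent strand is never methylated
#'   at division (maintenance enzyme absent).
#' @param context_mode `"cpg_only"` restricts deposition to CG dyads;
#'   `"cpg_and_cpa"` additionally methylates CA sites at
#'   `cpa_relative_rate` times the local rate.
#' @param cpa_relative_rate Relative deposition rate at CA sites.
#' @param track_ca Track CA-site states and emit CA calls (default: `TRUE`
#'   when `context_mode == "cpg_and_cpa"`). Tracking CA in `cpg_only` mode
#'   measures the bisulfite conversion noise floor.
#' @param n_cells Number of independent cell lineages simulated.
#' @param coverage Mean sequencing depth of the observation layer.
#' @param read_length Read length in bp.
#' @param conversion_rate Probability an unmethylated cytosine is read
#'   unmethylated (bisulfite conversion efficiency).
#' @param protection_rate Probability a methylated cytosine is read
#'   methylated.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       genome_length = 2e6,
                       n_cgis = 40,
                       cgi_length_range = c(500, 2000),
                       cpg_rate_background = 0.01,
                       cpg_rate_cgi = 0.08,
                       enhancer_fraction = 0.05,
                       wt_mode = c("depleted", "wild_type"),
                       depleted_mean = 0.04,
                       cgi_hyper_fraction = 0.10,
                       r_off = 0.10,
                       r_on = 1.0,
                       spread_lambda = 250,
                       on_target_window = 2000,
                       k4_protection = 0.8,
                       susceptibility_mode = c("wt_state", "uniform"),
                       susceptibility_floor = 0.05,
                       maintenance_fidelity = 0.95,
                       divisions_per_day = 1,
                       maintenance_on = TRUE,
                       context_mode = c("cpg_only", "cpg_and_cpa"),
                       cpa_relative_rate = 0.25,
                       track_ca = NULL,
                       n_cells = 200,
                       coverage = 30,
                       read_length = 150,
                       conversion_rate = 0.995,
                       protection_rate = 0.995) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  wt_mode <- match.arg(wt_mode)
  susceptibility_mode <- match.arg(susceptibility_mode)
  context_mode <- match.arg(context_mode)
  if (!is.numeric(genome_length) || genome_length <= 0)
    stop("`genome_length` must be positive", call. = FALSE)
  if (length(cgi_length_range) != 2L || cgi_length_range[1] > cgi_length_range[2] ||
      cgi_length_range[1] <= 0)
    stop("`cgi_length_range` must be increasing positive bounds", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_cgis = as.integer(.check_pos(n_cgis, "n_cgis", strict = FALSE)),
    cgi_length_range = as.integer(cgi_length_range),
    cpg_rate_background = .check_prob(cpg_rate_background, "cpg_rate_background"),
    cpg_rate_cgi = .check_prob(cpg_rate_cgi, "cpg_rate_cgi"),
    enhancer_fraction = .check_prob(enhancer_fraction, "enhancer_fraction"),
    wt_mode = wt_mode,
    depleted_mean = .check_prob(depleted_mean, "depleted_mean"),
    cgi_hyper_fraction = .check_prob(cgi_hyper_fraction, "cgi_hyper_fraction"),
    r_off = .check_pos(r_off, "r_off", strict = FALSE),
    r_on = .check_pos(r_on, "r_on", strict = FALSE),
    spread_lambda = .check_pos(spread_lambda, "spread_lambda"),
    on_target_window = .check_pos(on_target_window, "on_target_window"),
    k4_protection = .check_prob(k4_protection, "k4_protection"),
    susceptibility_mode = susceptibility_mode,
    susceptibility_floor = .check_prob(susceptibility_floor, "susceptibility_floor"),
    maintenance_fidelity = .check_prob(maintenance_fidelity, "maintenance_fidelity"),
    divisions_per_day = as.integer(.check_pos(divisions_per_day, "divisions_per_day",
                                              strict = FALSE)),
    maintenance_on = isTRUE(maintenance_on),
    context_mode = context_mode,
    cpa_relative_rate = .check_prob(cpa_relative_rate, "cpa_relative_rate"),
    track_ca = isTRUE(track_ca %||% (context_mode == "cpg_and_cpa")),
    n_cells = as.integer(.check_pos(n_cells, "n_cells")),
    coverage = .check_pos(coverage, "coverage"),
    read_length = as.integer(.check_pos(read_length, "read_length")),
    conversion_rate = .check_prob(conversion_rate, "conversion_rate"),
    protection_rate = .check_prob(protection_rate, "protection_rate")
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Analysis configuration
#'
#' Every threshold of the analysis pipeline in one place: coverage filters,
#' tile widths, significance cutoffs, background matching tolerance, CGI
#' class boundaries, ChIP scaling quantile and smoothing span.
#'
#' @param min_cov_summary Minimum reads per CpG for descriptive summaries
#'   (tile means, feature means, gain curves).
#' @param min_cov_test Minimum reads per CpG, in both samples, for the paired
#'   tile test.
#' @param min_cpgs Minimum shared CpGs per tile (or CGI) for testing.
#' @param tile_width Width of differential-test tiles, bp.
#' @param delta_tile_width Width of delta-histogram tiles, bp.
#' @param alpha Adjusted-p significance level.
#' @param min_delta Minimum absolute methylation difference for tile
#'   significance (ignored for CGI tests).
#' @param match_tol Wild-type methylation tolerance for matched off-target
#'   background tiles.
#' @param top_k Number of top methylated tiles for overlap comparisons.
#' @param cgi_hyper_cut,cgi_hypo_cut Wild-type mean boundaries classifying
#'   CGIs as hypermethylated (strictly above) or hypomethylated (at or
#'   below).
#' @param chip_top_quantile Quantile of CGI ChIP read densities scaled to a
#'   score of 100 (nearest-rank).
#' @param loess_span Local regression span for smoothed tracks.
#' @param on_target_width Width in bp of the on-target window downstream of a
#'   protospacer.
#' @param read_weighted Weight tile means by coverage instead of averaging
#'   per-CpG levels.
#' @param gain_only Call only methylation gains significant (`delta >
#'   min_delta`) instead of two-sided `|delta| > min_delta`.
#' @param downstream Orientation rule for the on-target window:
#'   `"3prime"` (3' of the protospacer on its own strand) or `"plus"`
#'   (always to the right in genome coordinates).
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(min_cov_summary = 5,
                            min_cov_test = 10,
                            min_cpgs = 3,
                            tile_width = 200,
                            delta_tile_width = 1000,
                            alpha = 0.05,
                            min_delta = 0.10,
                            match_tol = 0.05,
                            top_k = 100,
                            cgi_hyper_cut = 0.8,
                            cgi_hypo_cut = 0.2,
                            chip_top_quantile = 0.99,
                            loess_span = 0.4,
                            on_target_width = 200,
                            read_weighted = FALSE,
                            gain_only = FALSE,
                            downstream = c("3prime", "plus")) {
  downstream <- match.arg(downstream)
  cfg <- list(
    min_cov_summary = .check_pos(min_cov_summary, "min_cov_summary", strict = FALSE),
    min_cov_test = .check_pos(min_cov_test, "min_cov_test", strict = FALSE),
    min_cpgs = as.integer(.check_pos(min_cpgs, "min_cpgs")),
    tile_width = as.integer(.check_pos(tile_width, "tile_width")),
    delta_tile_width = as.integer(.check_pos(delta_tile_width, "delta_tile_width")),
    alpha = .check_prob(alpha, "alpha"),
    min_delta = .check_prob(min_delta, "min_delta"),
    match_tol = .check_prob(match_tol, "match_tol"),
    top_k = as.integer(.check_pos(top_k, "top_k")),
    cgi_hyper_cut = .check_prob(cgi_hyper_cut, "cgi_hyper_cut"),
    cgi_hypo_cut = .check_prob(cgi_hypo_cut, "cgi_hypo_cut"),
    chip_top_quantile = .check_prob(chip_top_quantile, "chip_top_quantile"),
    loess_span = .check_prob(loess_span, "loess_span"),
    on_target_width = as.integer(.check_pos(on_target_width, "on_target_width")),
    read_weighted = isTRUE(read_weighted),
    gain_only = isTRUE(gain_only),
    downstream = downstream
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
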