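# Footprinting dynamics: daily stochastic gain followed by cell division
# with semiconservative strand replacement and maintenance.

.sgrna_rate <- function(pos, sgrnas, config) {
  rate <- numeric(length(pos))
  if (is.null(sgrnas) || nrow(sgrnas) == 0 || config$r_on <= 0) return(rate)
  half <- config$on_target_window / 2
  for (i in seq_len(nrow(sgrnas))) {
    s <- sgrnas$start[i]; e <- sgrnas$end[i]
    d <- pmax(0, pmax(s - pos, pos - e + 1L))
    rate <- rate + config$r_on * exp(-d / config$spread_lambda) * (d <= half)
  }
  rate
}

.gain_step <- function(state, p_gain) {
  # p_gain recycles down rows: one probability per dyad
  state | (matrix(stats::runif(length(state)), nrow = nrow(state)) < p_gain)
}

.division_step <- function(truth, config) {
  k <- truth$n_cells
  pf <- if (config$maintenance_on) config$maintenance_fidelity else 0
  tmpl_plus <- stats::runif(k) < 0.5  # which template strand the followed daughter keeps
  maint <- function(m) matrix(stats::runif(length(m)), nrow = nrow(m)) < pf & m
  if (length(truth$dyads)) {
    newP <- truth$plus; newM <- truth$minus
    mp <- maint(truth$plus); mm <- maint(truth$minus)
    newM[, tmpl_plus] <- mp[, tmpl_plus, drop = FALSE]
    newP[, !tmpl_plus] <- mm[, !tmpl_plus, drop = FALSE]
    truth$plus <- newP; truth$minus <- newM
  }
  if (!is.null(truth$ca)) {
    # CA methylation sits on a single strand and has no maintenance
    # substrate: it survives division only when its strand is the template
    if (nrow(truth$ca$plus)) truth$ca$plus[, !tmpl_plus] <- FALSE
    if (nrow(truth$ca$minus)) truth$ca$minus[, tmpl_plus] <- FALSE
  }
  truth
}

#' Simulate dCas9-methyltransferase footprinting over a time course
#'
#' Starting from a day-0 truth table, each simulated day applies stochastic
#' methylation gain to every unmethylated eligible cytosine, then
#' `divisions_per_day` rounds of cell division. The per-strand, per-day gain
#' hazard at position `x` is
#' `r_off * susceptibility(x) + sum_g r_on * exp(-dist(x, g) / spread_lambda)`
#' with the on-target term restricted to a window of `on_target_window` bp
#' centred on each protospacer `g`; the gain probability over one day is
#' `1 - exp(-hazard)`. At division the followed daughter keeps one template
#' strand (chosen uniformly per cell); the nascent strand is methylated
#' opposite a methylated template with probability `maintenance_fidelity`
#' (0 when `maintenance_on = FALSE`). In `cpg_and_cpa` mode, tracked CA
#' sites gain at `cpa_relative_rate` times the local hazard; CA methylation
#' is strand-borne and not maintained.
#'
#' @param truth_day0 A `meth_truth` at day 0 (see [assign_wt_landscape()]).
#' @param sgrnas `NULL`, or a data frame of protospacers with columns
#'   `chrom`, `start`, `end` (0-based half-open) and `strand`.
#' @param config A [sim_config()]; defaults to the truth's own.
#' @param days Ascending integer days starting at 0.
#' @return Named list of `meth_truth` snapshots, one per requested day.
#' @export
simulate_footprinting <- function(truth_day0, sgrnas = NULL,
                                  config = truth_day0$config,
                                  days = c(0, 2, 7)) {
  stopifnot(inherits(truth_day0, "meth_truth"))
  days <- as.integer(days)
  if (is.unsorted(days, strictly = TRUE) || days[1] != 0)
    stop("`days` must be strictly ascending and start at 0", call. = FALSE)
  if (!is.null(sgrnas) && nrow(sgrnas) > 0) {
    if (!all(c("chrom", "start", "end") %in% names(sgrnas)))
      stop("`sgrnas` needs chrom/start/end columns", call. = FALSE)
    bad <- setdiff(unique(sgrnas$chrom), truth_day0$chrom)
    if (length(bad))
      stop(sprintf("unknown sgRNA chromosome: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  set.seed(config$seed + 2L)

  hazard <- config$r_off * truth_day0$susceptibility +
    .sgrna_rate(truth_day0$dyads, sgrnas, config)
  p_gain <- -expm1(-hazard)
  ca_p_gain <- ca_m_gain <- NULL
  if (!is.null(truth_day0$ca) && config$context_mode == "cpg_and_cpa") {
    ca <- truth_day0$ca
    hz_p <- config$r_off * ca$plus_s + .sgrna_rate(ca$plus_pos, sgrnas, config)
    hz_m <- config$r_off * ca$minus_s + .sgrna_rate(ca$minus_pos, sgrnas, config)
    ca_p_gain <- -expm1(-config$cpa_relative_rate * hz_p)
    ca_m_gain <- -expm1(-config$cpa_relative_rate * hz_m)
  }

  truth <- truth_day0
  out <- vector("list", length(days))
  names(out) <- as.character(days)
  if (days[1] == 0L) out[["0"]] <- truth
  for (day in seq_len(max(days))) {
    truth$plus <- .gain_step(truth$plus, p_gain)
    truth$minus <- .gain_step(truth$minus, p_gain)
    if (!is.null(ca_p_gain)) {
      truth$ca$plus <- .gain_step(truth$ca$plus, ca_p_gain)
      truth$ca$minus <- .gain_step(truth$ca$minus, ca_m_gain)
    }
    for (d in seq_len(config$divisions_per_day))
      truth <- .division_step(truth, config)
    truth$day <- day
    if (day %in% days) out[[as.character(day)]] <- truth
  }
  out
}
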