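# Day-0 methylation landscape and truth-table construction.

.new_truth <- function(fields) structure(fields, class = "meth_truth")

#' Assign the wild-type-like day-0 methylation landscape
#'
#' Draws a per-dyad baseline methylation probability from class-specific
#' distributions: CpG-island dyads low (a configurable minority of islands
#' forced hypermethylated with low H3K4me3), bulk dyads high, enhancer-like
#' dyads intermediate. Per-CGI H3K4me3 density is anti-correlated with
#' island methylation by construction (hypomethylated islands draw from
#' `[0.6, 1]`, hypermethylated from `[0, 0.4]`). In `depleted` mode all
#' baselines are scaled so the global mean equals `depleted_mean`. Each
#' cell's dyads are then initialised symmetrically: fully methylated (`mm`)
#' with the baseline probability, otherwise unmethylated (`uu`).
#'
#' Off-target susceptibility per dyad follows the *wild-type* baseline
#' (floored at `susceptibility_floor`) even in depleted mode — gain potential
#' is defined by the prior methylation state — and is reduced inside CGIs by
#' `1 - k4_protection * k4_density`.
#'
#' @param genome A `meth_genome` from [generate_genome()].
#' @param config A [sim_config()]; defaults to the genome's own.
#' @return A `meth_truth` object at day 0: per-dyad baselines, k4 densities,
#'   susceptibilities, and `n_cells` per-strand state matrices.
#' @export
assign_wt_landscape <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "meth_genome"))
  set.seed(config$seed + 1L)
  n <- length(genome$dyads)
  k <- config$n_cells
  cls <- genome$dyad_class
  cgi <- genome$cgi

  # per-CGI class and H3K4me3 density (disjoint ranges guarantee the
  # hyper/hypo ordering asserted downstream)
  n_cgi <- nrow(cgi)
  cgi$class <- rep("hypo", n_cgi)
  if (n_cgi > 0) {
    n_hyper <- round(config$cgi_hyper_fraction * n_cgi)
    hyper <- if (n_hyper > 0) sample(n_cgi, n_hyper) else integer(0)
    cgi$class[hyper] <- "hyper"
    cgi$k4_density <- 0.6 + 0.4 * stats::rbeta(n_cgi, 2, 2)
    cgi$k4_density[hyper] <- 0.4 * stats::rbeta(length(hyper), 2, 2)
  } else {
    cgi$k4_density <- numeric(0)
  }

  baseline_wt <- numeric(n)
  is_bulk <- cls == "bulk"
  is_enh <- cls == "enhancer"
  is_cgi <- cls == "cgi"
  baseline_wt[is_bulk] <- stats::rbeta(sum(is_bulk), 6, 1.2)
  baseline_wt[is_enh] <- 0.25 + 0.5 * stats::rbeta(sum(is_enh), 2, 2)
  if (any(is_cgi)) {
    cgi_of <- genome$dyad_cgi[is_cgi]
    hyper_dyad <- cgi$class[cgi_of] == "hyper"
    v <- numeric(sum(is_cgi))
    v[!hyper_dyad] <- 0.18 * stats::rbeta(sum(!hyper_dyad), 1, 4)
    v[hyper_dyad] <- 0.82 + 0.18 * stats::rbeta(sum(hyper_dyad), 2, 2)
    baseline_wt[is_cgi] <- v
  }

  k4_dyad <- numeric(n)
  if (any(is_cgi)) k4_dyad[is_cgi] <- cgi$k4_density[genome$dyad_cgi[is_cgi]]

  baseline <- baseline_wt
  if (config$wt_mode == "depleted" && n > 0) {
    gm <- mean(baseline_wt)
    scale <- if (gm > 0) config$depleted_mean / gm else 0
    baseline <- pmin(1, baseline_wt * scale)
  }

  susceptibility <- if (config$susceptibility_mode == "uniform") {
    rep(1, n)
  } else {
    s <- pmax(baseline_wt, config$susceptibility_floor)
    s[is_cgi] <- s[is_cgi] * (1 - config$k4_protection * k4_dyad[is_cgi])
    s
  }

  state <- matrix(stats::runif(n * k) < baseline, nrow = n, ncol = k)
  plus <- state
  minus <- state

  ca <- NULL
  if (config$track_ca) {
    cls_of <- function(pos) {
      out <- rep("bulk", length(pos))
      .hit <- function(tab) {
        if (!nrow(tab) || !length(pos)) return(logical(length(pos)))
        ov <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, pos + 1L),
                                    IRanges::IRanges(tab$start + 1L, tab$end))
        h <- logical(length(pos)); h[S4Vectors::queryHits(ov)] <- TRUE; h
      }
      out[.hit(genome$enhancers)] <- "enhancer"
      out[.hit(genome$cgi)] <- "cgi"
      out
    }
    class_s <- c(bulk = if (any(is_bulk)) mean(susceptibility[is_bulk]) else 1,
                 enhancer = if (any(is_enh)) mean(susceptibility[is_enh]) else 1,
                 cgi = if (any(is_cgi)) mean(susceptibility[is_cgi]) else 1)
    s_plus <- unname(class_s[cls_of(genome$ca_plus)])
    s_minus <- unname(class_s[cls_of(genome$ca_minus)])
    ca <- list(
      plus_pos = genome$ca_plus, minus_pos = genome$ca_minus,
      plus_s = s_plus, minus_s = s_minus,
      plus = matrix(FALSE, length(genome$ca_plus), k),
      minus = matrix(FALSE, length(genome$ca_minus), k))
  }

  .new_truth(list(
    chrom = genome$chrom,
    genome_length = genome$length,
    dyads = genome$dyads,
    dyad_class = cls,
    dyad_cgi = genome$dyad_cgi,
    cgi = cgi,
    baseline_wt = baseline_wt,
    baseline = baseline,
    k4_dyad = k4_dyad,
    susceptibility = susceptibility,
    plus = plus,
    minus = minus,
    ca = ca,
    n_cells = k,
    day = 0,
    config = config
  ))
}

#' Construct a truth table from explicit strand states
#'
#' Low-level constructor used to build bespoke ground-truth scenarios (for
#' example a fully hemimethylated window) without running the landscape
#' sampler.
#'
#' @param dyads 0-based plus-strand C positions (strictly increasing).
#' @param plus,minus Logical state matrices, one row per dyad, one column
#'   per cell.
#' @param config A [sim_config()].
#' @param chrom Chromosome name.
#' @param genome_length Chromosome length in bp.
#' @param day Day label.
#' @return A `meth_truth` object.
#' @export
truth_table <- function(dyads, plus, minus, config,
                        chrom = "chrS",
                        genome_length = max(dyads) + 2L,
                        day = 0) {
  plus <- as.matrix(plus); minus <- as.matrix(minus)
  if (is.unsorted(dyads, strictly = TRUE))
    stop("`dyads` must be strictly increasing", call. = FALSE)
  if (nrow(plus) != length(dyads) || nrow(minus) != length(dyads) ||
      ncol(plus) != ncol(minus))
    stop("state matrices must be dyads x cells and conformable", call. = FALSE)
  n <- length(dyads)
  .new_truth(list(
    chrom = chrom, genome_length = as.integer(genome_length),
    dyads = as.integer(dyads),
    dyad_class = rep("bulk", n),
    dyad_cgi = rep(NA_integer_, n),
    cgi = data.frame(start = integer(0), end = integer(0),
                     class = character(0), k4_density = numeric(0)),
    baseline_wt = rowMeans(plus | minus),
    baseline = rowMeans(plus | minus),
    k4_dyad = numeric(n),
    susceptibility = rep(1, n),
    plus = plus, minus = minus, ca = NULL,
    n_cells = ncol(plus), day = day, config = config
  ))
}

#' Per-dyad true methylation fractions
#'
#' @param truth A `meth_truth`.
#' @return Data frame with chrom, pos, per-strand and dyad-merged true
#'   methylated fractions, and annotation columns.
#' @export
truth_fractions <- function(truth) {
  stopifnot(inherits(truth, "meth_truth"))
  fp <- rowMeans(truth$plus)
  fm <- rowMeans(truth$minus)
  data.frame(
    chrom = rep(truth$chrom, length(truth$dyads)),
    pos = truth$dyads,
    context = rep("CG", length(truth$dyads)),
    day = rep(truth$day, length(truth$dyads)),
    true_frac_plus = fp,
    true_frac_minus = fm,
    true_frac = (fp + fm) / 2,
    is_cgi = truth$dyad_class == "cgi",
    is_enhancer = truth$dyad_class == "enhancer",
    k4_density = truth$k4_dyad,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide true methylation level
#'
#' Fraction of methylated strand-cytosines over all dyads, strands and cells.
#'
#' @param truth A `meth_truth`.
#' @return A single number in `[0, 1]`.
#' @export
truth_global_mean <- function(truth) {
  stopifnot(inherits(truth, "meth_truth"))
  (sum(truth$plus) + sum(truth$minus)) / (2 * length(truth$dyads) * truth$n_cells)
}

#' @export
print.meth_truth <- function(x, ...) {
  cat(sprintf("<meth_truth> day %s: %d dyads x %d cells, global mean %.4f\n",
              format(x$day), length(x$dyads), x$n_cells, truth_global_mean(x)))
  invisible(x)
}
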