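# On-target / off-target quantifications: on-target windows, methylation-
# matched background tiles, time-course contrasts and gain curves, top-k
# tile overlap, CGI class summaries, H3K4me3 density scores, delta
# histograms and dinucleotide-context summaries.

#' On-target window downstream of a protospacer
#'
#' The window of `config$on_target_width` bp immediately downstream of the
#' protospacer: 3' of the protospacer on its own strand (default), i.e.
#' `[end, end + w)` for a plus-strand guide and `[start - w, start)` for a
#' minus-strand guide. With `downstream = "plus"` the window is always
#' `[end, end + w)`. Windows are clipped at chromosome bounds with a
#' warning; a window entirely outside the chromosome is an error.
#'
#' @param sgrna One-row data frame (chrom, start, end, strand).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param config An [analysis_config()].
#' @return One-row data frame: chrom, start, end.
#' @export
on_target_window <- function(sgrna, chrom_sizes, config = analysis_config()) {
  w <- config$on_target_width
  if (!sgrna$strand[1] %in% c("+", "-"))
    stop("sgRNA requires a +/- strand", call. = FALSE)
  L <- chrom_sizes[[sgrna$chrom[1]]]
  if (is.null(L)) stop(sprintf("unknown chromosome %s", sgrna$chrom[1]), call. = FALSE)
  if (config$downstream == "plus" || sgrna$strand[1] == "+") {
    start <- sgrna$end[1]; end <- sgrna$end[1] + w
  } else {
    start <- sgrna$start[1] - w; end <- sgrna$start[1]
  }
  cs <- max(0L, start); ce <- min(as.integer(L), end)
  if (cs >= ce)
    stop("on-target window lies entirely outside the chromosome", call. = FALSE)
  if (cs != start || ce != end)
    warning(sprintf("on-target window clipped to %s:%d-%d", sgrna$chrom[1], cs, ce))
  data.frame(chrom = sgrna$chrom[1], start = cs, end = ce,
             stringsAsFactors = FALSE)
}

#' Methylation-matched off-target background tiles
#'
#' All tiles whose wild-type mean methylation lies within `match_tol` of
#' the on-target window's wild-type mean — tiles with the same potential to
#' become methylated — excluding the tile(s) overlapping the on-target
#' window itself and, optionally, anything within `exclude_radius` bp of a
#' protospacer.
#'
#' @param on_target_wt_mean Wild-type mean of the on-target window.
#' @param wt_tile_means Tile table with chrom/start/end/mean (wild-type).
#' @param on_target On-target window (chrom/start/end) to exclude.
#' @param config An [analysis_config()].
#' @param sgrnas Optional protospacer table for radius exclusion.
#' @param exclude_radius Exclusion radius around protospacers, bp.
#' @return Subset of `wt_tile_means`; empty (with a warning) if nothing
#'   matches.
#' @export
matched_background <- function(on_target_wt_mean, wt_tile_means, on_target,
                               config = analysis_config(),
                               sgrnas = NULL, exclude_radius = 0) {
  keep <- abs(wt_tile_means$mean - on_target_wt_mean) <= config$match_tol
  # drop tiles overlapping the on-target window
  ov <- wt_tile_means$chrom == on_target$chrom[1] &
    wt_tile_means$start < on_target$end[1] &
    wt_tile_means$end > on_target$start[1]
  keep <- keep & !ov
  if (!is.null(sgrnas) && exclude_radius > 0) {
    for (i in seq_len(nrow(sgrnas))) {
      near <- wt_tile_means$chrom == sgrnas$chrom[i] &
        wt_tile_means$start < sgrnas$end[i] + exclude_radius &
        wt_tile_means$end > sgrnas$start[i] - exclude_radius
      keep <- keep & !near
    }
  }
  out <- wt_tile_means[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("matched background is empty")
  rownames(out) <- NULL
  out
}

#' On-target vs matched off-target methylation contrast
#'
#' For each clone's time course, the methylation change of the on-target
#' window between day 0 and day `day` is compared with the change over the
#' methylation-matched background tiles. Background summaries (mean and SD
#' over tiles) are reported per clone, and the per-clone on-target and
#' background-mean deltas are additionally summarised across clones (mean
#' and SD; SD is `NA` for a single clone).
#'
#' @param time_course Data frame: clone, day, and a `calls` list-column of
#'   call tables (or use [read_time_course()] to build one from paths).
#' @param sgrna One-row protospacer data frame (chrom/start/end/strand).
#' @param wt_calls Wild-type call table defining matching means.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param config An [analysis_config()].
#' @param day Contrast day (default: the latest shared day).
#' @param region Optional chrom/start/end data frame restricting the tile
#'   universe (e.g. the captured region); default: all tiles with data.
#' @return List with `per_clone` (clone, on_delta, off_mean, off_sd,
#'   n_background) and `summary` (across-clone mean/SD of the on-target and
#'   background deltas).
#' @export
on_off_contrast <- function(time_course, sgrna, wt_calls, chrom_sizes,
                            config = analysis_config(), day = NULL,
                            region = NULL) {
  clones <- unique(time_course$clone)
  days <- sort(unique(time_course$day))
  if (length(days) < 2) stop("need at least two time points", call. = FALSE)
  if (is.null(day)) day <- max(days)
  if (!0 %in% days) stop("day 0 must be present", call. = FALSE)

  ot <- on_target_window(sgrna, chrom_sizes, config)
  wt_use <- if (is.null(region)) wt_calls else
    wt_calls[wt_calls$chrom == region$chrom[1] & wt_calls$pos >= region$start[1] &
               wt_calls$pos < region$end[1], , drop = FALSE]
  wt_tiles <- tile_means(wt_use, config$tile_width, config$min_cov_summary,
                         config$read_weighted)
  on_wt <- interval_mean(wt_calls, ot$chrom, ot$start, ot$end,
                         config$min_cov_summary, config$read_weighted)
  if (is.na(on_wt)) stop("on-target window has no covered CpGs in WT", call. = FALSE)
  bg <- matched_background(on_wt, wt_tiles, ot, config)

  per_clone <- lapply(clones, function(cl) {
    get_calls <- function(d) {
      i <- which(time_course$clone == cl & time_course$day == d)
      if (!length(i)) return(NULL)
      time_course$calls[[i[1]]]
    }
    c0 <- get_calls(0); cd <- get_calls(day)
    if (is.null(c0) || is.null(cd))
      return(data.frame(clone = cl, on_delta = NA_real_, off_mean = NA_real_,
                        off_sd = NA_real_, n_background = 0L,
                        stringsAsFactors = FALSE))
    on_d <- interval_mean(cd, ot$chrom, ot$start, ot$end,
                          config$min_cov_summary, config$read_weighted) -
      interval_mean(c0, ot$chrom, ot$start, ot$end,
                    config$min_cov_summary, config$read_weighted)
    deltas <- rep(NA_real_, nrow(bg))
    for (i in seq_len(nrow(bg))) {
      m0 <- interval_mean(c0, bg$chrom[i], bg$start[i], bg$end[i],
                          config$min_cov_summary, config$read_weighted)
      md <- interval_mean(cd, bg$chrom[i], bg$start[i], bg$end[i],
                          config$min_cov_summary, config$read_weighted)
      deltas[i] <- md - m0
    }
    deltas <- deltas[!is.na(deltas)]
    data.frame(clone = cl, on_delta = on_d,
               off_mean = if (length(deltas)) mean(deltas) else NA_real_,
               off_sd = if (length(deltas) > 1) stats::sd(deltas) else NA_real_,
               n_background = length(deltas), stringsAsFactors = FALSE)
  })
  per_clone <- do.call(rbind, per_clone)
  summary <- data.frame(
    day = day,
    on_mean = mean(per_clone$on_delta, na.rm = TRUE),
    on_sd = if (sum(!is.na(per_clone$on_delta)) > 1)
      stats::sd(per_clone$on_delta, na.rm = TRUE) else NA_real_,
    off_mean = mean(per_clone$off_mean, na.rm = TRUE),
    off_sd = if (sum(!is.na(per_clone$off_mean)) > 1)
      stats::sd(per_clone$off_mean, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
  list(on_target = ot, per_clone = per_clone, summary = summary,
       n_background = nrow(bg))
}

#' Time-course gain curve over target regions
#'
#' The common CpG set is every dyad inside the regions with at least
#' `min_cov_summary` reads in every sample of every clone; each clone's
#' per-day mean is the unweighted mean over that one set, so days and
#' clones are directly comparable. Reported per day as mean and SD across
#' clones.
#'
#' @param time_course Data frame: clone, day, `calls` list-column.
#' @param regions Data frame of chrom/start/end regions.
#' @param config An [analysis_config()].
#' @return Data frame: day, mean, sd (sd `NA` for one clone), n_cpgs.
#' @export
gain_curve <- function(time_course, regions, config = analysis_config()) {
  clones <- unique(time_course$clone)
  days <- sort(unique(time_course$day))
  in_region <- function(calls) {
    sel <- rep(FALSE, nrow(calls))
    for (i in seq_len(nrow(regions)))
      sel <- sel | (calls$chrom == regions$chrom[i] &
                      calls$pos >= regions$start[i] & calls$pos < regions$end[i])
    calls[sel, , drop = FALSE]
  }
  key_sets <- list()
  for (i in seq_len(nrow(time_course))) {
    cc <- in_region(time_course$calls[[i]])
    cc <- cc[cc$n_total >= config$min_cov_summary, , drop = FALSE]
    key_sets[[i]] <- .key(cc$chrom, cc$pos)
  }
  common <- Reduce(intersect, key_sets)
  if (!length(common)) stop("no CpG is covered in every sample", call. = FALSE)
  res <- lapply(days, function(d) {
    per_clone <- vapply(clones, function(cl) {
      i <- which(time_course$clone == cl & time_course$day == d)[1]
      if (is.na(i)) return(NA_real_)
      cc <- in_region(time_course$calls[[i]])
      cc <- cc[.key(cc$chrom, cc$pos) %in% common, , drop = FALSE]
      mean(cc$n_meth / cc$n_total)
    }, numeric(1))
    data.frame(day = d, mean = mean(per_clone, na.rm = TRUE),
               sd = if (sum(!is.na(per_clone)) > 1) stats::sd(per_clone, na.rm = TRUE)
               else NA_real_,
               n_cpgs = length(common), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Overlap of the top-k most methylated tiles between samples
#'
#' Tiles are eligible only when they have a mean in every sample; each
#' sample's eligible tiles are ranked by mean level descending (ties broken
#' by chrom then start ascending) and the top `k` kept. All pairwise
#' intersection sizes and the full intersection are reported.
#'
#' @param samples Named list of call tables.
#' @param config An [analysis_config()].
#' @param k Number of top tiles; defaults to `config$top_k`.
#' @return List with `top` (named list of tile keys), `pairwise` (matrix of
#'   intersection sizes), and `all` (size of the full intersection).
#' @export
top_k_overlap <- function(samples, config = analysis_config(), k = config$top_k) {
  tms <- lapply(samples, tile_means, width = config$tile_width,
                min_cov = config$min_cov_summary,
                read_weighted = config$read_weighted)
  keys <- lapply(tms, function(tm) .key(tm$chrom, tm$start))
  eligible <- Reduce(intersect, keys)
  if (length(eligible) < k) {
    warning(sprintf("only %d eligible tiles (< k = %d); using all",
                    length(eligible), k))
    k <- length(eligible)
  }
  top <- lapply(tms, function(tm) {
    key <- .key(tm$chrom, tm$start)
    tm <- tm[key %in% eligible, , drop = FALSE]
    key <- .key(tm$chrom, tm$start)
    o <- order(-tm$mean, tm$chrom, tm$start)
    key[o][seq_len(k)]
  })
  nm <- names(samples) %||% paste0("sample", seq_along(samples))
  names(top) <- nm
  pw <- outer(seq_along(top), seq_along(top),
              Vectorize(function(i, j) length(intersect(top[[i]], top[[j]]))))
  dimnames(pw) <- list(nm, nm)
  list(top = top, pairwise = pw, all = length(Reduce(intersect, top)))
}

#' CGI class summary by wild-type methylation
#'
#' Classifies each CpG island by its wild-type mean (hypermethylated:
#' strictly above `cgi_hyper_cut`; hypomethylated: at or below
#' `cgi_hypo_cut`; otherwise intermediate) and reports per-class counts and
#' the per-class mean methylation in the test sample.
#'
#' @param calls_wt Wild-type call table.
#' @param calls_sample Test sample call table.
#' @param cgis CGI intervals.
#' @param config An [analysis_config()].
#' @return List with `per_cgi` (per-island WT/test means and class) and
#'   `per_class` (class, n, mean_wt, mean_sample).
#' @export
cgi_class_summary <- function(calls_wt, calls_sample, cgis,
                              config = analysis_config()) {
  wt_mean <- s_mean <- rep(NA_real_, nrow(cgis))
  for (i in seq_len(nrow(cgis))) {
    wt_mean[i] <- interval_mean(calls_wt, cgis$chrom[i], cgis$start[i],
                                cgis$end[i], config$min_cov_summary,
                                config$read_weighted)
    s_mean[i] <- interval_mean(calls_sample, cgis$chrom[i], cgis$start[i],
                               cgis$end[i], config$min_cov_summary,
                               config$read_weighted)
  }
  class <- ifelse(is.na(wt_mean), NA_character_,
                  ifelse(wt_mean > config$cgi_hyper_cut, "hyper",
                         ifelse(wt_mean <= config$cgi_hypo_cut, "hypo",
                                "intermediate")))
  per_cgi <- cbind(cgis[c("chrom", "start", "end")],
                   data.frame(mean_wt = wt_mean, mean_sample = s_mean,
                              class = class, stringsAsFactors = FALSE))
  classes <- c("hyper", "intermediate", "hypo")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- !is.na(class) & class == cl
    data.frame(class = cl, n = sum(sel),
               mean_wt = if (any(sel)) mean(wt_mean[sel], na.rm = TRUE) else NA_real_,
               mean_sample = if (any(sel)) mean(s_mean[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_cgi = per_cgi, per_class = per_class)
}

#' H3K4me3 density score per CGI
#'
#' ChIP read count divided by island length gives a density; the
#' `chip_top_quantile` (nearest-rank) density is scaled to a score of 100,
#' larger densities are capped at 100 and the rest scaled proportionally.
#'
#' @param chip_counts Data frame: chrom, start, end, count.
#' @param config An [analysis_config()].
#' @return `chip_counts` with added `density` and `score` columns
#'   (scores in `[0, 100]`).
#' @export
cgi_k4_score <- function(chip_counts, config = analysis_config()) {
  len <- chip_counts$end - chip_counts$start
  if (any(len <= 0)) stop("CGI with non-positive length", call. = FALSE)
  density <- chip_counts$count / len
  out <- chip_counts
  out$density <- density
  if (all(density == 0)) {
    out$score <- rep(0, length(density))
    return(out)
  }
  q <- sort(density)[ceiling(config$chip_top_quantile * length(density))]
  out$score <- pmin(100, 100 * density / q)
  out
}

#' Histogram of per-tile methylation differences
#'
#' Tiles of `delta_tile_width` bp with at least `min_cpgs` dyads covered at
#' `min_cov_summary` in both samples; the per-tile delta (`b - a`) is
#' binned at width 0.05 over `[-1, 1]`, bins left-closed right-open (the
#' final bin closed).
#'
#' @param calls_a,calls_b Call tables.
#' @param config An [analysis_config()].
#' @return List with `breaks`, `counts`, and `deltas` (per-tile table).
#' @export
delta_histogram <- function(calls_a, calls_b, config = analysis_config()) {
  w <- config$delta_tile_width
  ta <- tile_means(calls_a, w, config$min_cov_summary, config$read_weighted)
  tb <- tile_means(calls_b, w, config$min_cov_summary, config$read_weighted)
  ta <- ta[ta$n_cpgs >= config$min_cpgs, , drop = FALSE]
  tb <- tb[tb$n_cpgs >= config$min_cpgs, , drop = FALSE]
  ka <- .key(ta$chrom, ta$start)
  kb <- .key(tb$chrom, tb$start)
  i <- match(ka, kb)
  keep <- !is.na(i)
  breaks <- seq(-1, 1, by = 0.05)
  if (!any(keep)) {
    warning("no tile qualifies in both samples")
    return(list(breaks = breaks, counts = integer(length(breaks) - 1L),
                deltas = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), delta = numeric(0))))
  }
  delta <- tb$mean[i[keep]] - ta$mean[keep]
  # left-closed, right-open bins: [b_k, b_{k+1}); last bin closed at 1
  bin <- pmin(length(breaks) - 1L, floor((delta + 1) / 0.05 + 1e-9) + 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts,
       deltas = data.frame(chrom = ta$chrom[keep], start = ta$start[keep],
                           end = ta$end[keep], delta = delta,
                           stringsAsFactors = FALSE))
}

#' Mean methylation level per dinucleotide context
#'
#' @param calls Call table with a `context` column, or one whose contexts
#'   can be derived from `genome`.
#' @param genome Optional `meth_genome` (or named sequence list) used to
#'   derive missing contexts; an unknown chromosome is an error.
#' @param min_cov Minimum reads per site.
#' @return Data frame: context (CG, CA, CC, CT), n_sites, mean (`NA` where
#'   no calls).
#' @export
context_summary <- function(calls, genome = NULL, min_cov = 5) {
  calls <- calls[calls$n_total >= min_cov, , drop = FALSE]
  if (is.null(calls$context) || anyNA(calls$context)) {
    if (is.null(genome))
      stop("calls carry no context and no genome was given", call. = FALSE)
    strand <- calls$strand %||% rep("+", nrow(calls))
    for (ch in unique(calls$chrom)) {
      sel <- calls$chrom == ch
      calls$context[sel] <- cytosine_context(genome, ch, calls$pos[sel], strand[sel])
    }
  }
  lev <- calls$n_meth / calls$n_total
  out <- lapply(c("CG", "CA", "CC", "CT"), function(cx) {
    sel <- calls$context == cx
    data.frame(context = cx, n_sites = sum(sel),
               mean = if (any(sel)) mean(lev[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
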