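# Fixed-width genome tiling and per-tile / per-feature aggregation of
# per-CpG calls.

#' Partition chromosomes into fixed-width tiles
#'
#' Tiles are `[k*width, (k+1)*width)` per chromosome; a trailing partial
#' tile is retained, so tiles are disjoint and cover each chromosome
#' exactly.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param width Tile width in bp.
#' @return Data frame: chrom, start, end (0-based half-open).
#' @export
make_tiles <- function(chrom_sizes, width) {
  if (width <= 0) stop("tile width must be positive", call. = FALSE)
  width <- as.integer(width)
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    n <- ceiling(L / width)
    start <- (seq_len(n) - 1L) * width
    data.frame(chrom = rep(ch, n), start = start,
               end = pmin(start + width, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# chrom:pos keys; paste0 recycles the separator to length 1 on empty input,
# so guard the zero-length case explicitly
.key <- function(chrom, pos) {
  if (!length(pos)) return(character(0))
  paste0(chrom, ":", pos)
}

#' Per-tile mean methylation
#'
#' A dyad belongs to the tile containing its plus-strand C coordinate. The
#' tile mean is by default the unweighted mean of per-CpG levels over member
#' dyads with at least `min_cov` reads; with `read_weighted = TRUE` it is
#' the coverage-weighted mean (total methylated over total reads). Tiles
#' with no qualifying dyad are absent from the result.
#'
#' @param calls Call table from one sample.
#' @param width Tile width in bp.
#' @param min_cov Minimum reads per CpG.
#' @param read_weighted Weight by coverage instead of averaging levels.
#' @return Data frame: chrom, start, end, n_cpgs, mean.
#' @export
tile_means <- function(calls, width = 200, min_cov = 5, read_weighted = FALSE) {
  width <- as.integer(width)
  calls <- calls[calls$n_total >= min_cov, , drop = FALSE]
  if (nrow(calls) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_cpgs = integer(0), mean = numeric(0),
                      stringsAsFactors = FALSE))
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  idx <- calls$pos %/% width
  key <- paste0(calls$chrom, ":", idx)
  f <- factor(key, levels = unique(key))
  lev <- calls$n_meth / calls$n_total
  m <- if (read_weighted) {
    as.numeric(tapply(calls$n_meth, f, sum) / tapply(calls$n_total, f, sum))
  } else {
    as.numeric(tapply(lev, f, mean))
  }
  first <- !duplicated(key)
  data.frame(chrom = calls$chrom[first],
             start = idx[first] * width,
             end = idx[first] * width + width,
             n_cpgs = tabulate(f),
             mean = m, stringsAsFactors = FALSE)
}

#' Mean methylation over one interval
#'
#' @param calls Call table from one sample.
#' @param chrom,start,end Interval (0-based half-open).
#' @param min_cov Minimum reads per CpG.
#' @param read_weighted Weight by coverage.
#' @return Mean level, or `NA` if no dyad qualifies.
#' @export
interval_mean <- function(calls, chrom, start, end, min_cov = 5,
                          read_weighted = FALSE) {
  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos < end &
    calls$n_total >= min_cov
  if (!any(sel)) return(NA_real_)
  if (read_weighted) sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
  else mean(calls$n_meth[sel] / calls$n_total[sel])
}

#' Per-feature-class mean methylation
#'
#' For each feature class (a set of intervals), the unweighted mean of
#' qualifying per-CpG levels over dyads overlapping any interval of the
#' class. A dyad overlapping several intervals of one class is counted
#' once.
#'
#' @param calls Call table from one sample.
#' @param features Named list of interval data frames (chrom/start/end).
#' @param min_cov Minimum reads per CpG.
#' @return Data frame: feature, n_cpgs, mean (`NA` for empty classes).
#' @export
intersect_feature <- function(calls, features, min_cov = 5) {
  calls <- calls[calls$n_total >= min_cov, , drop = FALSE]
  lev <- calls$n_meth / calls$n_total
  q <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  res <- lapply(names(features), function(nm) {
    tab <- features[[nm]]
    if (is.null(tab) || nrow(tab) == 0 || nrow(calls) == 0)
      return(data.frame(feature = nm, n_cpgs = 0L, mean = NA_real_,
                        stringsAsFactors = FALSE))
    s <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$start + 1L, tab$end))
    hit <- unique(S4Vectors::queryHits(suppressWarnings(GenomicRanges::findOverlaps(q, s))))
    data.frame(feature = nm, n_cpgs = length(hit),
               mean = if (length(hit)) mean(lev[hit]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
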