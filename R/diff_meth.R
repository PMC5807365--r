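# Paired per-tile and per-CGI differential methylation testing with
# Benjamini-Hochberg adjustment and the dual significance rule.

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} (p_(j) * n / j)` over the ascending order
#' statistics, capped at 1 and mapped back to input order.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  adj <- numeric(n)
  adj[o] <- pmin(1, adj_sorted)
  adj
}

# paired t over grouped differences: one group per tile/CGI.
# Returns per-group n, means, delta, t, p with the degenerate-sd rule:
# sd = 0 & all d = 0 -> p = 1, t = 0; sd = 0 & mean != 0 -> p = 0, t = +-Inf.
.grouped_paired_t <- function(lev_a, lev_b, group) {
  f <- factor(group, levels = unique(group))
  d <- lev_b - lev_a
  n <- tabulate(f)
  sum_d <- as.numeric(rowsum(d, f, reorder = FALSE))
  sum_d2 <- as.numeric(rowsum(d^2, f, reorder = FALSE))
  mean_d <- sum_d / n
  var_d <- ifelse(n > 1, pmax(0, (sum_d2 - n * mean_d^2) / pmax(1, n - 1)), 0)
  # constant differences give variance 0 up to rounding; snap so the
  # degenerate rule (not a huge finite t) applies
  var_d[var_d <= 1e-12 * pmax(1e-300, sum_d2)] <- 0
  sd_d <- sqrt(var_d)
  t_stat <- ifelse(sd_d > 0, mean_d * sqrt(n) / sd_d,
                   ifelse(mean_d == 0, 0, sign(mean_d) * Inf))
  p <- ifelse(sd_d > 0, 2 * stats::pt(-abs(t_stat), df = n - 1),
              ifelse(mean_d == 0, 1, 0))
  data.frame(group = levels(f), n = n,
             mean_a = as.numeric(rowsum(lev_a, f, reorder = FALSE)) / n,
             mean_b = as.numeric(rowsum(lev_b, f, reorder = FALSE)) / n,
             delta = mean_d, t_stat = t_stat, p_raw = p,
             stringsAsFactors = FALSE)
}

.pair_calls <- function(calls_a, calls_b, min_cov) {
  a <- calls_a[calls_a$n_total >= min_cov, c("chrom", "pos", "n_meth", "n_total")]
  b <- calls_b[calls_b$n_total >= min_cov, c("chrom", "pos", "n_meth", "n_total")]
  key_a <- .key(a$chrom, a$pos)
  key_b <- .key(b$chrom, b$pos)
  i <- match(key_a, key_b)
  keep <- !is.na(i)
  data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
             lev_a = (a$n_meth / a$n_total)[keep],
             lev_b = (b$n_meth / b$n_total)[i[keep]],
             stringsAsFactors = FALSE)
}

#' Apply the dual significance rule
#'
#' A tile is significant when its adjusted p-value is strictly below
#' `alpha` and its absolute methylation difference strictly exceeds
#' `min_delta` (the difference itself with `gain_only = TRUE`).
#'
#' @param p_adj Adjusted p-values.
#' @param delta Methylation differences (sample minus reference).
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
call_significant <- function(p_adj, delta, config = analysis_config()) {
  d <- if (config$gain_only) delta else abs(delta)
  p_adj < config$alpha & d > config$min_delta
}

#' Paired per-tile differential methylation test
#'
#' Pairs dyads present in both samples with at least `min_cov_test` reads in
#' each, tiles the genome at `tile_width`, and for every tile with at least
#' `min_cpgs` shared CpGs performs a two-sided paired t-test on the per-CpG
#' level differences. P-values are Benjamini-Hochberg adjusted over all
#' tested tiles genome-wide, and significance requires both `p_adj < alpha`
#' and `|delta| > min_delta`. Tiles with fewer shared CpGs are excluded
#' (not tested, no p-value emitted).
#'
#' @param calls_a Reference sample call table (e.g. control).
#' @param calls_b Test sample call table.
#' @param config An [analysis_config()].
#' @param width Tile width; defaults to `config$tile_width`.
#' @return Data frame of tile statistics: chrom, start, end, n_shared_cpgs,
#'   mean_a, mean_b, delta, t_stat, p_raw, p_adj, significant.
#' @export
tile_diff <- function(calls_a, calls_b, config = analysis_config(),
                      width = config$tile_width) {
  pr <- .pair_calls(calls_a, calls_b, config$min_cov_test)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_shared_cpgs = integer(0), mean_a = numeric(0),
                      mean_b = numeric(0), delta = numeric(0), t_stat = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (nrow(pr) == 0) return(empty)
  pr <- pr[order(pr$chrom, pr$pos), , drop = FALSE]
  width <- as.integer(width)
  idx <- pr$pos %/% width
  group <- .key(pr$chrom, idx)
  counts <- table(factor(group, levels = unique(group)))
  keep <- group %in% names(counts)[counts >= config$min_cpgs]
  if (!any(keep)) return(empty)
  pr <- pr[keep, , drop = FALSE]
  idx <- idx[keep]; group <- group[keep]
  st <- .grouped_paired_t(pr$lev_a, pr$lev_b, group)
  first <- !duplicated(group)
  st$chrom <- pr$chrom[first]
  st$start <- idx[first] * width
  st$end <- st$start + width
  st$p_adj <- bh_adjust(st$p_raw)
  st$significant <- call_significant(st$p_adj, st$delta, config)
  st$n_shared_cpgs <- st$n
  st[c("chrom", "start", "end", "n_shared_cpgs", "mean_a", "mean_b",
       "delta", "t_stat", "p_raw", "p_adj", "significant")]
}

#' Paired per-CGI differential methylation test
#'
#' The same pairing and paired t-test as [tile_diff()], grouped by CpG
#' island instead of by tile. Significance uses the adjusted p-value alone
#' (no methylation-difference cutoff). Islands with fewer than `min_cpgs`
#' shared CpGs are excluded. Overlapping islands are each tested on their
#' own dyads.
#'
#' @param calls_a,calls_b Call tables (reference, test).
#' @param cgis CGI intervals (chrom/start/end data frame).
#' @param config An [analysis_config()].
#' @return Data frame: chrom, start, end, n_shared_cpgs, mean_a, mean_b,
#'   delta, t_stat, p_raw, p_adj, significant.
#' @export
cgi_test <- function(calls_a, calls_b, cgis, config = analysis_config()) {
  pr <- .pair_calls(calls_a, calls_b, config$min_cov_test)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_shared_cpgs = integer(0), mean_a = numeric(0),
                      mean_b = numeric(0), delta = numeric(0), t_stat = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (nrow(pr) == 0 || nrow(cgis) == 0) return(empty)
  q <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$pos + 1L, pr$pos + 1L))
  s <- GenomicRanges::GRanges(cgis$chrom, IRanges::IRanges(cgis$start + 1L, cgis$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  counts <- table(si)
  ok_cgi <- as.integer(names(counts)[counts >= config$min_cpgs])
  keep <- si %in% ok_cgi
  if (!any(keep)) return(empty)
  qi <- qi[keep]; si <- si[keep]
  o <- order(si, pr$pos[qi])
  qi <- qi[o]; si <- si[o]
  st <- .grouped_paired_t(pr$lev_a[qi], pr$lev_b[qi], si)
  cgi_idx <- as.integer(st$group)
  st$chrom <- cgis$chrom[cgi_idx]
  st$start <- cgis$start[cgi_idx]
  st$end <- cgis$end[cgi_idx]
  st$p_adj <- bh_adjust(st$p_raw)
  st$significant <- st$p_adj < config$alpha
  st$n_shared_cpgs <- st$n
  st[c("chrom", "start", "end", "n_shared_cpgs", "mean_a", "mean_b",
       "delta", "t_stat", "p_raw", "p_adj", "significant")]
}

#' Write tile statistics to TSV
#'
#' @param stats Output of [tile_diff()] or [cgi_test()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tile_stats <- function(stats, path) {
  df <- stats
  df$significant <- as.integer(df$significant)
  num <- c("mean_a", "mean_b", "delta", "t_stat", "p_raw", "p_adj")
  for (cn in num) df[[cn]] <- sprintf("%.6g", df[[cn]])
  .write_tsv(df, path, paste(names(df), collapse = "\t"))
}
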