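# Read-level none/some classification used to detect hemimethylation.

.parse_reads <- function(reads) {
  pos <- strsplit(reads$positions, ",", fixed = TRUE)
  st <- strsplit(reads$states, ",", fixed = TRUE)
  list(pos = lapply(pos, function(p) if (length(p) && nzchar(p[1])) as.integer(p)
                    else integer(0)),
       st = lapply(st, function(s) if (length(s) && nzchar(s[1])) as.integer(s)
                   else integer(0)))
}

#' Classify reads as "none" or "some" per window
#'
#' A read is eligible for a window when at least one of its CpG dyads lies
#' inside it (interval overlap alone is not enough — a read must carry
#' evidence). Eligible reads with no methylated in-window CpG are "none";
#' reads with at least one methylated in-window CpG are "some".
#'
#' @param reads Read-level records (read_id, chrom, positions, states, ...),
#'   as emitted by [sample_reads()] or [read_read_table()].
#' @param windows Data frame of windows (chrom, start, end), e.g. the
#'   significant tiles.
#' @return Data frame per window: chrom, start, end, n_none, n_some,
#'   n_reads, frac_some (`NA` when no eligible read).
#' @export
classify_reads <- function(reads, windows) {
  pr <- .parse_reads(reads)
  nin <- lengths(pr$pos)
  ridx <- rep.int(seq_len(nrow(reads)), nin)
  pos <- unlist(pr$pos, use.names = FALSE)
  st <- unlist(pr$st, use.names = FALSE)
  out <- windows[c("chrom", "start", "end")]
  out$n_none <- out$n_some <- integer(nrow(windows))
  if (length(pos) && nrow(windows)) {
    q <- GenomicRanges::GRanges(reads$chrom[ridx],
                                IRanges::IRanges(pos + 1L, pos + 1L))
    s_gr <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start + 1L, windows$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, s_gr))
    if (length(ov)) {
      wi <- S4Vectors::subjectHits(ov)            # window index
      ri <- ridx[S4Vectors::queryHits(ov)]        # read index
      mi <- st[S4Vectors::queryHits(ov)] == 1L    # methylated dyad?
      key <- paste0(wi, "_", ri)                  # one vote per (window, read)
      some <- tapply(mi, key, any)
      w_of <- as.integer(sub("_.*", "", names(some)))
      n_some <- tabulate(w_of[some], nbins = nrow(windows))
      n_none <- tabulate(w_of[!some], nbins = nrow(windows))
      out$n_some <- n_some
      out$n_none <- n_none
    }
  }
  out$n_reads <- out$n_none + out$n_some
  out$frac_some <- ifelse(out$n_reads > 0, out$n_some / out$n_reads, NA_real_)
  out[c("chrom", "start", "end", "n_none", "n_some", "n_reads", "frac_some")]
}

.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Hemimethylation report: pooled fraction of "some" reads
#'
#' Pools the none/some classification over windows and attaches a 95%
#' Wilson score confidence interval. A pooled fraction near 0.5 at loci
#' that are fully methylated on one strand is the read-level signature of
#' hemimethylated DNA (or of a half-methylated cell population — the two
#' are indistinguishable from bisulfite reads alone).
#'
#' @param reads Read-level records.
#' @param windows Window data frame (chrom/start/end).
#' @param conf Confidence level.
#' @return List with `per_window` (from [classify_reads()]) and `pooled`
#'   (n_reads, n_some, frac_some, ci_lo, ci_hi; `NA`s when no eligible
#'   reads).
#' @export
hemimethylation_report <- function(reads, windows, conf = 0.95) {
  per_window <- classify_reads(reads, windows)
  n <- sum(per_window$n_reads)
  x <- sum(per_window$n_some)
  ci <- .wilson_ci(x, n, conf)
  pooled <- data.frame(n_reads = n, n_some = x,
                       frac_some = if (n > 0) x / n else NA_real_,
                       ci_lo = ci[1], ci_hi = ci[2])
  list(per_window = per_window, pooled = pooled)
}
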