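# Locally weighted polynomial smoothing of per-CpG methylation along
# genomic coordinates, with a standard-deviation band.

.tricube <- function(u) {
  w <- (1 - pmin(1, abs(u))^3)^3
  w[w < 0] <- 0
  w
}

.local_fit <- function(x, y, span, degree) {
  n <- length(x)
  k <- ceiling(span * n)
  k <- max(k, degree + 2L)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    o <- order(d)[seq_len(k)]
    dmax <- d[o[k]]
    w <- if (dmax > 0) .tricube(d[o] / dmax) else rep(1, k)
    if (all(w == 0)) w <- rep(1, k)
    xs <- x[o] - x[i]
    X <- outer(xs, 0:degree, "^")
    # guard against rank deficiency (few distinct coordinates)
    fit <- stats::lm.wfit(X, y[o], w)
    fitted[i] <- fit$coefficients[1]
    if (is.na(fitted[i])) fitted[i] <- sum(w * y[o]) / sum(w)
  }
  fitted
}

#' Local polynomial smoothing of a methylation track
#'
#' At every input position fits a tricube-weighted local polynomial of
#' degree 2 over the `ceiling(span * n)` nearest neighbours by coordinate
#' distance (no robustness iterations). The standard-deviation band is the
#' square root of the same smoother applied to the squared residuals,
#' floored at zero. Smoothing is per region: call once per chromosome or
#' region of interest.
#'
#' @param positions Ascending coordinates (bp).
#' @param levels Methylation levels at the positions.
#' @param span Fraction of points in each local neighbourhood, in `(0, 1]`.
#' @param degree Local polynomial degree (default 2).
#' @return Data frame of class `smoothed_track`: position, fitted, sd.
#' @export
loess_smooth <- function(positions, levels, span = 0.4, degree = 2) {
  n <- length(positions)
  if (length(levels) != n) stop("positions and levels differ in length", call. = FALSE)
  if (n < max(5, degree + 2)) stop(sprintf("need at least %d points", max(5, degree + 2)),
                                   call. = FALSE)
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(positions)) {
    o <- order(positions)
    positions <- positions[o]
    levels <- levels[o]
  }
  fitted <- .local_fit(positions, levels, span, degree)
  res2 <- (levels - fitted)^2
  sd_fit <- .local_fit(positions, res2, span, degree)
  out <- data.frame(position = positions, fitted = fitted,
                    sd = sqrt(pmax(0, sd_fit)))
  class(out) <- c("smoothed_track", class(out))
  out
}

#' Write a smoothed track to TSV
#'
#' @param track A `smoothed_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_smoothed_track <- function(track, path) {
  df <- data.frame(position = track$position,
                   fitted = sprintf("%.6f", track$fitted),
                   sd = sprintf("%.6f", track$sd))
  .write_tsv(df, path, "position\tfitted\tsd")
}
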