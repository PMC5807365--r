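# Bisulfite observation layer: read-level sampling and the equivalent
# per-site binomial shortcut.
#
# Conditional on the truth table, read calls at a site are i.i.d.
# Bernoulli(p_obs) where p_obs averages over cells and strands, so the
# per-site counts from sample_calls() have exactly the marginal law of the
# counts aggregated from sample_reads(); only within-read correlation
# (needed for read-level analysis) differs.

.obs_prob <- function(frac_meth, config) {
  frac_meth * config$protection_rate + (1 - frac_meth) * (1 - config$conversion_rate)
}

.n_reads <- function(config) {
  max(1L, as.integer(round(config$coverage * config$genome_length / config$read_length)))
}

#' Sample bisulfite reads from a truth table
#'
#' Reads pick a start uniformly on the chromosome, a cell uniformly from the
#' simulated population, and a strand uniformly; every CpG dyad whose two
#' bases fall inside the read yields one binary call from the chosen
#' strand's true state, flipped by bisulfite conversion failure
#' (`1 - conversion_rate`) or protection failure (`1 - protection_rate`).
#' Tracked CA sites contribute to the per-site call table (under their own
#' strand) but not to the read-level records, which carry CpG dyads only.
#'
#' @param truth A `meth_truth` snapshot.
#' @param config A [sim_config()]; defaults to the truth's own.
#' @param seed RNG seed for this sampling (independent samplings of the same
#'   truth use different seeds).
#' @param sample Sample label stored in the read records.
#' @return List with `reads` (data frame: read_id, chrom, sample, comma-
#'   separated dyad positions and 0/1 states, strand) and `calls` (per-site
#'   call table: chrom, pos, context, n_meth, n_total, level; dyad-merged
#'   for CpG).
#' @export
sample_reads <- function(truth, config = truth$config,
                         seed = config$seed + 1000L, sample = "sim") {
  stopifnot(inherits(truth, "meth_truth"))
  if (config$coverage <= 0) stop("coverage must be positive", call. = FALSE)
  set.seed(seed)
  L <- truth$genome_length
  rl <- config$read_length
  nr <- .n_reads(config)
  starts <- as.integer(floor(stats::runif(nr, 0, max(1, L - rl + 1))))
  cells <- sample.int(truth$n_cells, nr, replace = TRUE)
  plus_read <- stats::runif(nr) < 0.5

  pos <- truth$dyads
  # dyad covered if [pos, pos+1] within [start, start+rl)
  ilo <- findInterval(starts - 0.5, pos) + 1L
  ihi <- findInterval(starts + rl - 2 + 0.5, pos)
  nin <- pmax(0L, ihi - ilo + 1L)
  ridx <- rep.int(seq_len(nr), nin)
  didx <- sequence(nin, from = ilo)
  state <- ifelse(plus_read[ridx],
                  truth$plus[cbind(didx, cells[ridx])],
                  truth$minus[cbind(didx, cells[ridx])])
  call <- ifelse(state,
                 stats::runif(length(state)) < config$protection_rate,
                 stats::runif(length(state)) < 1 - config$conversion_rate)

  reads <- data.frame(
    read_id = paste0("r", seq_len(nr)),
    chrom = rep(truth$chrom, nr),
    sample = rep(sample, nr),
    positions = rep("", nr),
    states = rep("", nr),
    strand = ifelse(plus_read, "+", "-"),
    stringsAsFactors = FALSE
  )
  if (length(ridx)) {
    pos_s <- vapply(split(pos[didx], ridx), paste, "", collapse = ",")
    st_s <- vapply(split(as.integer(call), ridx), paste, "", collapse = ",")
    got <- as.integer(names(pos_s))
    reads$positions[got] <- pos_s
    reads$states[got] <- st_s
  }

  n_total <- tabulate(didx, nbins = length(pos))
  n_meth <- integer(length(pos))
  if (length(didx)) {
    agg <- rowsum(as.integer(call), didx)
    n_meth[as.integer(rownames(agg))] <- agg[, 1]
  }
  calls <- data.frame(
    chrom = rep(truth$chrom, length(pos)),
    pos = pos,
    context = rep("CG", length(pos)),
    n_meth = n_meth,
    n_total = n_total,
    stringsAsFactors = FALSE
  )

  if (!is.null(truth$ca)) {
    ca_calls <- .sample_ca_calls(truth, config, starts, cells, plus_read)
    calls <- rbind(calls, ca_calls)
    calls <- calls[order(calls$pos), , drop = FALSE]
  }
  calls <- calls[calls$n_total > 0, , drop = FALSE]
  calls$level <- ifelse(calls$n_total > 0, calls$n_meth / calls$n_total, NA_real_)
  rownames(calls) <- NULL
  list(reads = reads, calls = calls)
}

.sample_ca_calls <- function(truth, config, starts, cells, plus_read) {
  out <- list()
  rl <- config$read_length
  for (strand in c("plus", "minus")) {
    pos <- truth$ca[[paste0(strand, "_pos")]]
    on_strand <- if (strand == "plus") plus_read else !plus_read
    st <- which(on_strand)
    if (!length(pos) || !length(st)) {
      out[[strand]] <- data.frame(chrom = character(0), pos = integer(0),
                                  context = character(0), n_meth = integer(0),
                                  n_total = integer(0), stringsAsFactors = FALSE)
      next
    }
    s <- starts[st]
    ilo <- findInterval(s - 0.5, pos) + 1L
    ihi <- findInterval(s + rl - 1 + 0.5, pos)
    nin <- pmax(0L, ihi - ilo + 1L)
    ridx <- rep.int(seq_along(st), nin)
    didx <- sequence(nin, from = ilo)
    state <- truth$ca[[strand]][cbind(didx, cells[st][ridx])]
    call <- ifelse(state,
                   stats::runif(length(state)) < config$protection_rate,
                   stats::runif(length(state)) < 1 - config$conversion_rate)
    n_total <- tabulate(didx, nbins = length(pos))
    n_meth <- integer(length(pos))
    if (length(didx)) {
      agg <- rowsum(as.integer(call), didx)
      n_meth[as.integer(rownames(agg))] <- agg[, 1]
    }
    out[[strand]] <- data.frame(
      chrom = rep(truth$chrom, length(pos)), pos = pos,
      context = rep("CA", length(pos)),
      n_meth = n_meth, n_total = n_total, stringsAsFactors = FALSE)
  }
  rbind(out$plus, out$minus)
}

#' Sample a per-site call table directly (binomial shortcut)
#'
#' Exact marginal equivalent of aggregating [sample_reads()]: per-site depth
#' is binomial over read placements, and each read's call is an independent
#' Bernoulli with success probability averaged over cells and strands. Use
#' this when read-level records are not needed; it is much faster.
#'
#' @inheritParams sample_reads
#' @return A per-site call table (chrom, pos, context, n_meth, n_total,
#'   level).
#' @export
sample_calls <- function(truth, config = truth$config,
                         seed = config$seed + 1000L) {
  stopifnot(inherits(truth, "meth_truth"))
  if (config$coverage <= 0) stop("coverage must be positive", call. = FALSE)
  set.seed(seed)
  L <- truth$genome_length
  rl <- config$read_length
  nr <- .n_reads(config)
  n_starts <- max(1, L - rl + 1)

  .one <- function(pos, frac_by_strand, context, span) {
    if (!length(pos)) return(NULL)
    # reads covering a site: those starting in a window of length span
    p_cov <- pmin(1, span / n_starts)
    depth <- stats::rbinom(length(pos), nr, p_cov)
    p_obs <- .obs_prob(frac_by_strand, config)
    n_meth <- stats::rbinom(length(pos), depth, p_obs)
    data.frame(chrom = rep(truth$chrom, length(pos)), pos = pos,
               context = rep(context, length(pos)),
               n_meth = n_meth, n_total = depth, stringsAsFactors = FALSE)
  }

  fp <- rowMeans(truth$plus); fm <- rowMeans(truth$minus)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      context = character(0), n_meth = integer(0),
                      n_total = integer(0), stringsAsFactors = FALSE)
  calls <- .one(truth$dyads, (fp + fm) / 2, "CG", rl - 1) %||% empty
  if (!is.null(truth$ca)) {
    # a CA read must carry the site's strand: halve effective depth
    fcp <- if (nrow(truth$ca$plus)) rowMeans(truth$ca$plus) else numeric(0)
    fcm <- if (nrow(truth$ca$minus)) rowMeans(truth$ca$minus) else numeric(0)
    cap <- .one(truth$ca$plus_pos, fcp, "CA", rl / 2)
    cam <- .one(truth$ca$minus_pos, fcm, "CA", rl / 2)
    calls <- rbind(calls, cap, cam)
    calls <- calls[order(calls$pos), , drop = FALSE]
  }
  calls <- calls[calls$n_total > 0, , drop = FALSE]
  calls$level <- calls$n_meth / calls$n_total
  rownames(calls) <- NULL
  calls
}
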