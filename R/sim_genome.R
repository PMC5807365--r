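# Synthetic genome: sequence, CpG dyad placement, CGI / enhancer annotation.
#
# Dyads are placed by a renewal process: after a dyad occupying 2 bp, the
# next dyad starts after a further Geometric(rate) gap, so the mean spacing
# within a segment of per-bp rate r is 2 + (1 - r) / r.  This gives sorted
# positions directly and a closed-form count expectation used in tests.

.place_dyads <- function(seg_start, seg_end, rate) {
  # positions are 0-based; dyad at p occupies [p, p+2)
  if (rate <= 0 || seg_end - seg_start < 2L) return(integer(0))
  len <- seg_end - seg_start
  mean_gap <- 2 + (1 - rate) / rate
  n_guess <- ceiling(len / mean_gap + 6 * sqrt(len / mean_gap) + 10)
  pos <- integer(0)
  cur <- seg_start
  repeat {
    gaps <- 2L + stats::rgeom(n_guess, rate)
    # first dyad: distance from segment start has the same geometric law
    # minus the 2 bp footprint of a (virtual) preceding dyad
    if (length(pos) == 0L) gaps[1L] <- gaps[1L] - 2L
    p <- cur + cumsum(as.numeric(gaps))
    keep <- p <= seg_end - 2
    pos <- c(pos, as.integer(p[keep]))
    if (!all(keep) || length(p) == 0L) break
    cur <- p[length(p)]
  }
  pos
}

#' Generate a synthetic genome with CpG dyads and annotations
#'
#' Builds a random single-chromosome genome, places CpG dyads at a
#' background rate and a higher rate inside `n_cgis` disjoint CpG islands,
#' labels a fraction of non-CGI 200 bp tiles as enhancer-like, and removes
#' any accidental CG dinucleotides from the random sequence so that the
#' annotated dyads are exactly the CG sites of the FASTA.
#'
#' CGIs are placed one per equal-width slot at a random offset, which makes
#' them disjoint by construction.
#'
#' @param config A [sim_config()].
#' @return An object of class `meth_genome`: a list with the chromosome name,
#'   length, sequence (single string), 0-based dyad positions, per-dyad
#'   class (`cgi`/`enhancer`/`bulk`), CGI and enhancer interval tables, and
#'   0-based positions of plus- and minus-strand CA sites.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length <= 0) stop("genome_length must be positive", call. = FALSE)
  set.seed(config$seed)
  L <- config$genome_length
  chrom <- "chrS"

  # CGI intervals: one per slot, random offset, lengths uniform in range
  n_cgi <- config$n_cgis
  cgi <- data.frame(start = integer(0), end = integer(0))
  if (n_cgi > 0) {
    slot <- floor(L / n_cgi)
    lens <- pmin(slot, round(stats::runif(n_cgi, config$cgi_length_range[1],
                                          config$cgi_length_range[2])))
    offs <- floor(stats::runif(n_cgi, 0, slot - lens + 1))
    cgi <- data.frame(start = as.integer((seq_len(n_cgi) - 1L) * slot + offs))
    cgi$end <- as.integer(cgi$start + lens)
    cgi <- cgi[cgi$end <= L, , drop = FALSE]
  }

  # dyad placement per segment (alternating background / CGI rates)
  bounds <- sort(unique(c(0L, cgi$start, cgi$end, L)))
  dyads <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    in_cgi <- nrow(cgi) > 0 && any(cgi$start <= s & cgi$end >= e)
    rate <- if (in_cgi) config$cpg_rate_cgi else config$cpg_rate_background
    dyads <- c(dyads, .place_dyads(s, e, rate))
  }
  dyads <- sort(dyads)

  # random sequence; scrub accidental CGs, then plant annotated dyads
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (L >= 2) {
    acc <- which(base[-L] == "C" & base[-1] == "G")
    if (length(acc)) base[acc + 1L] <- "A"
  }
  base[dyads + 1L] <- "C"
  base[dyads + 2L] <- "G"
  # planting cannot create new CGs: a planted C blocks 'CG' ending at it and
  # a planted G is preceded by the planted C of its own dyad

  # CA sites: plus strand "CA" at (p, p+1); minus strand C at plus-coord p
  # wherever the plus strand reads "TG" at (p-1, p)
  ca_plus <- which(base[-L] == "C" & base[-1] == "A") - 1L
  ca_minus <- which(base[-L] == "T" & base[-1] == "G")  # 0-based pos of the G
  ca_plus <- setdiff(ca_plus, dyads)

  # enhancer-like tiles among non-CGI 200 bp tiles
  tile_w <- 200L
  n_tiles <- ceiling(L / tile_w)
  tile_start <- (seq_len(n_tiles) - 1L) * tile_w
  tile_end <- pmin(tile_start + tile_w, L)
  overlaps_cgi <- rep(FALSE, n_tiles)
  if (nrow(cgi)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(tile_start + 1L, tile_end),
      IRanges::IRanges(cgi$start + 1L, cgi$end))
    overlaps_cgi[S4Vectors::queryHits(ov)] <- TRUE
  }
  cand <- which(!overlaps_cgi)
  n_enh <- round(config$enhancer_fraction * length(cand))
  enh_idx <- if (n_enh > 0) sort(sample(cand, n_enh)) else integer(0)
  enhancers <- data.frame(start = tile_start[enh_idx], end = tile_end[enh_idx])

  # per-dyad class
  dyad_class <- rep("bulk", length(dyads))
  .mark <- function(tab) {
    if (!nrow(tab) || !length(dyads)) return(logical(length(dyads)))
    ov <- IRanges::findOverlaps(IRanges::IRanges(dyads + 1L, dyads + 1L),
                                IRanges::IRanges(tab$start + 1L, tab$end))
    out <- logical(length(dyads)); out[S4Vectors::queryHits(ov)] <- TRUE; out
  }
  dyad_class[.mark(enhancers)] <- "enhancer"
  cgi_hit <- .mark(cgi)
  dyad_class[cgi_hit] <- "cgi"
  # CGI index per dyad (NA outside); CGIs are disjoint so at most one hit
  dyad_cgi <- rep(NA_integer_, length(dyads))
  if (nrow(cgi) && length(dyads)) {
    ov <- IRanges::findOverlaps(IRanges::IRanges(dyads + 1L, dyads + 1L),
                                IRanges::IRanges(cgi$start + 1L, cgi$end))
    dyad_cgi[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  }

  structure(list(
    chrom = chrom,
    length = L,
    seq = paste(base, collapse = ""),
    dyads = dyads,
    dyad_class = dyad_class,
    dyad_cgi = dyad_cgi,
    cgi = cgi,
    enhancers = enhancers,
    ca_plus = ca_plus,
    ca_minus = ca_minus,
    config = config
  ), class = "meth_genome")
}

#' @export
print.meth_genome <- function(x, ...) {
  cat(sprintf("<meth_genome> %s: %s bp, %d CpG dyads (%d CGI, %d enhancer), %d CGIs\n",
              x$chrom, format(x$length, big.mark = ","), length(x$dyads),
              sum(x$dyad_class == "cgi"), sum(x$dyad_class == "enhancer"),
              nrow(x$cgi)))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `meth_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "meth_genome"))
  seq <- Biostrings::DNAStringSet(genome$seq)
  names(seq) <- genome$chrom
  Biostrings::writeXStringSet(seq, path, width = 80L)
  invisible(path)
}

#' Dinucleotide context at a cytosine position
#'
#' @param genome A `meth_genome` (or a named list of sequences).
#' @param chrom Chromosome name.
#' @param pos 0-based position of the cytosine on `strand`.
#' @param strand `"+"` or `"-"` (vectorised alongside `pos`).
#' @return Character vector of contexts (`CG`, `CA`, `CC`, `CT`), `NA` where
#'   the base at `pos` is not a cytosine on that strand.
#' @export
cytosine_context <- function(genome, chrom, pos, strand = "+") {
  if (inherits(genome, "meth_genome")) {
    if (!identical(chrom, genome$chrom))
      stop(sprintf("chromosome '%s' not present in genome FASTA", chrom), call. = FALSE)
    seq <- genome$seq
  } else {
    if (is.null(genome[[chrom]]))
      stop(sprintf("chromosome '%s' not present in genome FASTA", chrom), call. = FALSE)
    seq <- as.character(genome[[chrom]])
  }
  strand <- rep_len(strand, length(pos))
  out <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b1 <- substring(seq, pos + 1L, pos + 1L)
  if (any(plus)) {
    nxt <- substring(seq, pos + 2L, pos + 2L)
    ok <- plus & b1 == "C" & nxt != ""
    out[ok] <- paste0("C", nxt[ok])
  }
  if (any(!plus)) {
    prv <- substring(seq, pos, pos)
    ok <- !plus & b1 == "G" & prv != ""
    out[ok] <- paste0("C", unname(comp[prv[ok]]))
  }
  out
}
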