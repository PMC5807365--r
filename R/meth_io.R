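# Readers and writers for call tables (bedGraph-like coverage dialect),
# BED annotations, sgRNA tables, truth tables and read-level records.
# All TSV outputs carry a single '#'-prefixed header line.

.read_tsv <- function(path, col_names, col_classes) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      lapply(col_classes, function(cl) vector(cl, 0)), col_names),
      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(col_names))) {
    bad <- which(nf != length(col_names))[1]
    stop(sprintf("%s: line %d has %d fields, expected %d", path, bad, nf[bad],
                 length(col_names)), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = length(col_names), byrow = TRUE)
  out <- vector("list", length(col_names))
  for (j in seq_along(col_names)) {
    v <- m[, j]
    out[[j]] <- switch(col_classes[j],
                       integer = {
                         x <- suppressWarnings(as.integer(v))
                         if (anyNA(x) && !all(is.na(v)))
                           stop(sprintf("%s: non-integer value in column %s (line %d)",
                                        path, col_names[j],
                                        which(is.na(x))[1]), call. = FALSE)
                         x
                       },
                       numeric = {
                         x <- suppressWarnings(as.numeric(v))
                         if (anyNA(x))
                           stop(sprintf("%s: non-numeric value in column %s (line %d)",
                                        path, col_names[j],
                                        which(is.na(x))[1]), call. = FALSE)
                         x
                       },
                       v)
  }
  names(out) <- col_names
  as.data.frame(out, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0 || !is.null(header)) writeLines(paste0("#", header), con)
  if (nrow(df) > 0)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation call table
#'
#' Parses the six-column coverage dialect (chrom, start, end, fraction,
#' count-methylated, count-unmethylated). The fraction scale (0-1 vs 0-100)
#' is auto-detected per file from its maximum value; every fraction is
#' cross-checked against the counts to within 0.01 and a mismatch is an
#' integrity error. Records below `min_coverage` total reads are dropped.
#'
#' @param path Input file; lines starting `#` are ignored.
#' @param min_coverage Minimum `n_meth + n_unmeth` to retain a record.
#' @return Call table sorted by (chrom, pos): chrom, pos (0-based), context
#'   (`CG` unless the file carries a context column), n_meth, n_total,
#'   level.
#' @export
read_call_table <- function(path, min_coverage = 1) {
  df <- .read_tsv(path, c("chrom", "start", "end", "fraction", "n_meth", "n_unmeth"),
                  c("character", "integer", "integer", "numeric", "integer", "integer"))
  if (nrow(df) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      context = character(0), n_meth = integer(0),
                      n_total = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE))
  if (any(df$n_meth < 0) || any(df$n_unmeth < 0))
    stop(sprintf("%s: negative counts", path), call. = FALSE)
  percent <- max(df$fraction) > 1 + 1e-9
  frac <- if (percent) df$fraction / 100 else df$fraction
  n_total <- df$n_meth + df$n_unmeth
  if (any(n_total == 0))
    stop(sprintf("%s: record with zero total reads (line %d)", path,
                 which(n_total == 0)[1]), call. = FALSE)
  mism <- abs(frac - df$n_meth / n_total) > 0.01
  if (any(mism))
    stop(sprintf("%s: fraction/count mismatch at %s:%d (fraction %.4f vs counts %.4f)",
                 path, df$chrom[mism][1], df$start[mism][1],
                 frac[mism][1], (df$n_meth / n_total)[mism][1]), call. = FALSE)
  if (anyDuplicated(paste(df$chrom, df$start)))
    stop(sprintf("%s: duplicate (chrom, pos) records", path), call. = FALSE)
  out <- data.frame(chrom = df$chrom, pos = df$start,
                    context = rep("CG", nrow(df)),
                    n_meth = df$n_meth, n_total = n_total,
                    stringsAsFactors = FALSE)
  out <- out[out$n_total >= min_coverage, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$level <- out$n_meth / out$n_total
  rownames(out) <- NULL
  out
}

#' Write a per-CpG methylation call table
#'
#' Inverse of [read_call_table()]: emits the six-column coverage dialect
#' with fractions on the 0-1 scale at 6 decimals.
#'
#' @param calls Call table (chrom, pos, n_meth, n_total).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  req <- c("chrom", "pos", "n_meth", "n_total")
  if (!all(req %in% names(calls)))
    stop("calls must have chrom/pos/n_meth/n_total columns", call. = FALSE)
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  frac <- calls$n_meth / calls$n_total
  if (any(!is.finite(frac)) || any(calls$n_meth > calls$n_total) || any(calls$n_meth < 0))
    stop("refusing to write invalid calls (non-finite fraction or bad counts)",
         call. = FALSE)
  df <- data.frame(chrom = calls$chrom, start = calls$pos, end = calls$pos + 1L,
                   fraction = sprintf("%.6f", frac),
                   n_meth = calls$n_meth, n_unmeth = calls$n_total - calls$n_meth,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, "chrom\tstart\tend\tfraction\tn_meth\tn_unmeth")
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3 or BED6 (0-based half-open); validates `0 <= start < end`.
#' Overlapping intervals are allowed and reported with a message.
#'
#' @param path BED file.
#' @return Data frame: chrom, start, end, and name/score/strand when
#'   present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("%s: line %d has %d fields; BED needs at least 3",
                 path, which(nf < 3)[1], min(nf)), call. = FALSE)
  ncol_use <- min(6L, min(nf))
  m <- t(vapply(parts, function(p) p[seq_len(ncol_use)], character(ncol_use)))
  df <- data.frame(chrom = m[, 1],
                   start = suppressWarnings(as.integer(m[, 2])),
                   end = suppressWarnings(as.integer(m[, 3])),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop(sprintf("%s: non-integer coordinates", path), call. = FALSE)
  if (ncol_use >= 4) df$name <- m[, 4]
  if (ncol_use >= 5) df$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol_use >= 6) df$strand <- m[, 6]
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad))
    stop(sprintf("%s: invalid interval %s:%d-%d (need 0 <= start < end)",
                 path, df$chrom[bad][1], df$start[bad][1], df$end[bad][1]),
         call. = FALSE)
  ov <- FALSE
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) ov <- TRUE
  }
  if (ov) message(sprintf("%s: overlapping intervals present", path))
  df
}

#' Write intervals to BED
#'
#' @param intervals Data frame with chrom/start/end and optional name,
#'   score, strand.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  opt <- intersect(c("name", "score", "strand"), names(intervals))
  # emit optional columns only up to the last one present, filling defaults
  n_opt <- max(c(0L, match(opt, c("name", "score", "strand"))))
  df <- intervals[cols]
  if (n_opt >= 1) df$name <- if ("name" %in% opt) intervals$name else "."
  if (n_opt >= 2) df$score <- if ("score" %in% opt) intervals$score else 0
  if (n_opt >= 3) df$strand <- if ("strand" %in% opt) intervals$strand else "."
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sgRNA protospacer intervals
#'
#' Reads BED6 protospacers (strand mandatory). With `one_based = TRUE` the
#' start/end columns are interpreted as 1-based inclusive coordinates, the
#' convention used when protospacers are quoted in free text, and converted
#' to 0-based half-open.
#'
#' @param path BED-like file: chrom, start, end, name, score, strand.
#' @param one_based Input coordinates are 1-based inclusive.
#' @return Data frame: name, chrom, start, end (0-based half-open), strand.
#' @export
read_sgrnas <- function(path, one_based = FALSE) {
  df <- read_bed(path)
  if (!"strand" %in% names(df) || any(!df$strand %in% c("+", "-")))
    stop(sprintf("%s: sgRNA records require a +/- strand column", path),
         call. = FALSE)
  if (one_based) {
    df$start <- df$start - 1L
  }
  if (!"name" %in% names(df)) df$name <- paste0("sgrna", seq_len(nrow(df)))
  data.frame(name = df$name, chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Write simulator ground truth to TSV
#'
#' @param truth_frac Output of [truth_fractions()] (any number of days
#'   row-bound).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth_frac, path) {
  df <- truth_frac[c("chrom", "pos", "context", "day", "true_frac_plus",
                     "true_frac_minus", "is_cgi", "is_enhancer", "k4_density")]
  df$true_frac_plus <- sprintf("%.6f", df$true_frac_plus)
  df$true_frac_minus <- sprintf("%.6f", df$true_frac_minus)
  df$k4_density <- sprintf("%.6f", df$k4_density)
  df$is_cgi <- as.integer(df$is_cgi)
  df$is_enhancer <- as.integer(df$is_enhancer)
  .write_tsv(df, path, paste(names(df), collapse = "\t"))
}

#' Read a simulator ground-truth TSV
#'
#' @param path File written by [write_truth_table()].
#' @return Data frame of per-dyad, per-day true fractions and annotations.
#' @export
read_truth_table <- function(path) {
  df <- .read_tsv(path,
                  c("chrom", "pos", "context", "day", "true_frac_plus",
                    "true_frac_minus", "is_cgi", "is_enhancer", "k4_density"),
                  c("character", "integer", "character", "integer", "numeric",
                    "numeric", "integer", "integer", "numeric"))
  df$is_cgi <- df$is_cgi == 1L
  df$is_enhancer <- df$is_enhancer == 1L
  df
}

#' Write read-level methylation records
#'
#' @param reads Data frame as returned in `sample_reads()$reads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path) {
  df <- reads[c("read_id", "chrom", "sample", "positions", "states", "strand")]
  df$positions[!nzchar(df$positions)] <- "."
  df$states[!nzchar(df$states)] <- "."
  .write_tsv(df, path, paste(names(df), collapse = "\t"))
}

#' Read read-level methylation records
#'
#' @param path File written by [write_read_table()].
#' @return Data frame: read_id, chrom, sample, positions, states, strand;
#'   empty reads have `""` positions/states.
#' @export
read_read_table <- function(path) {
  df <- .read_tsv(path,
                  c("read_id", "chrom", "sample", "positions", "states", "strand"),
                  rep("character", 6))
  df$positions[df$positions == "."] <- ""
  df$states[df$states == "."] <- ""
  ok <- vapply(strsplit(df$positions[nzchar(df$positions)], ","), function(p)
    !is.unsorted(as.integer(p), strictly = TRUE), logical(1))
  if (length(ok) && !all(ok))
    stop(sprintf("%s: read with non-increasing positions", path), call. = FALSE)
  df
}

#' Read per-CGI ChIP read counts
#'
#' @param path TSV: chrom, start, end, count.
#' @return Data frame with non-negative integer counts.
#' @export
read_chip_counts <- function(path) {
  df <- .read_tsv(path, c("chrom", "start", "end", "count"),
                  c("character", "integer", "integer", "integer"))
  if (any(df$count < 0)) stop(sprintf("%s: negative ChIP count", path), call. = FALSE)
  df
}
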