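# Shared fixture builders: small configs and hand-made tables.

quick_cfg <- function(seed = 1, genome_length = 5e4, n_cgis = 4,
                      n_cells = 50, coverage = 30, ...) {
  sim_config(seed = seed, genome_length = genome_length, n_cgis = n_cgis,
             n_cells = n_cells, coverage = coverage, ...)
}

make_calls <- function(pos, n_meth, n_total, chrom = "chr1", context = "CG") {
  data.frame(chrom = rep(chrom, length(pos)), pos = as.integer(pos),
             context = rep_len(context, length(pos)),
             n_meth = as.integer(n_meth), n_total = as.integer(n_total),
             level = n_meth / n_total, stringsAsFactors = FALSE)
}

# call table with every dyad at an exact level via large even depth
calls_at_levels <- function(pos, levels, depth = 100L, chrom = "chr1") {
  make_calls(pos, round(levels * depth), rep(depth, length(pos)), chrom)
}

# truth with every dyad hemimethylated (plus strand carries the methyl);
# dyads span most of a short genome so nearly every read is eligible
hemi_truth <- function(n_dyads = 40, n_cells = 50, spacing = 20L, seed = 1,
                       genome_length = 1000L) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_cells = n_cells)
  dyads <- seq(100L, by = spacing, length.out = n_dyads)
  truth_table(dyads,
              plus = matrix(TRUE, n_dyads, n_cells),
              minus = matrix(FALSE, n_dyads, n_cells),
              config = cfg, genome_length = genome_length)
}

# place a guide so its downstream 200 bp window holds >= min_dyads bulk CpGs
place_guide <- function(g, from = 1e5, min_dyads = 3, width = 200) {
  bulk <- g$dyads[g$dyad_class == "bulk" & g$dyads >= from]
  for (x in bulk) {
    if (sum(g$dyads >= x & g$dyads < x + width) >= min_dyads)
      return(data.frame(chrom = g$chrom, start = as.integer(x - 20L),
                        end = as.integer(x), strand = "+",
                        stringsAsFactors = FALSE))
  }
  stop("no dyad-rich window found")
}

# read records built directly (positions/states as comma strings)
make_reads <- function(positions, states, chrom = "chr1", strand = "+",
                       sample = "s") {
  n <- length(positions)
  data.frame(read_id = paste0("r", seq_len(n)), chrom = rep_len(chrom, n),
             sample = rep_len(sample, n),
             positions = vapply(positions, paste, "", collapse = ","),
             states = vapply(states, paste, "", collapse = ","),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}
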