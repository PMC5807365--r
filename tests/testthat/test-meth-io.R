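test_that("coverage filter drops records below the read threshold", {
  p <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t101\t0.250000\t1\t3",
               "chr1\t200\t201\t0.400000\t2\t3",
               "chr1\t300\t301\t0.500000\t6\t6"), p)
  out <- read_call_table(p, min_coverage = 5)
  expect_identical(out$pos, c(200L, 300L))
  expect_identical(out$n_total, c(5L, 12L))
})

test_that("empty call files read as empty call sets", {
  p <- withr::local_tempfile(fileext = ".cov")
  file.create(p)
  expect_identical(nrow(read_call_table(p)), 0L)
})

test_that("call tables round-trip through write and read", {
  cfg <- quick_cfg(seed = 51, genome_length = 2e4)
  tr <- assign_wt_landscape(generate_genome(cfg))
  calls <- sample_calls(tr, cfg, seed = 107)
  calls <- calls[calls$context == "CG", ]
  p <- withr::local_tempfile(fileext = ".cov")
  write_call_table(calls, p)
  back <- read_call_table(p)
  expect_equal(back[c("chrom", "pos", "n_meth", "n_total")],
               calls[c("chrom", "pos", "n_meth", "n_total")],
               ignore_attr = TRUE)
})

test_that("percent-scale fractions are auto-detected", {
  p <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t101\t25.0\t2\t6", "chr1\t200\t201\t100.0\t8\t0"), p)
  out <- read_call_table(p)
  expect_equal(out$level, c(0.25, 1.0))
})

test_that("fraction/count mismatches are an integrity error with position info", {
  p <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t100\t101\t0.90\t1\t3", p)
  expect_error(read_call_table(p), "mismatch.*chr1:100")
})

test_that("malformed call lines fail with a line number", {
  p <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t101\t0.5\t2\t2", "chr1\t200\t201"), p)
  expect_error(read_call_table(p), "line 2")
})

test_that("writer refuses non-finite fractions and writes empty sets as empty files", {
  bad <- make_calls(10, 1, 2)
  bad$n_total <- 0L
  p <- withr::local_tempfile(fileext = ".cov")
  expect_error(write_call_table(bad, p), "refusing")
  write_call_table(make_calls(integer(0), integer(0), integer(0))[0, ], p)
  expect_identical(length(readLines(p)), 0L)
})

test_that("BED reading validates intervals and flags overlap", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300"), p)
  expect_message(df <- read_bed(p), "overlapping")
  expect_identical(nrow(df), 2L)
  writeLines("chr1\t300\t200", p)
  expect_error(read_bed(p), "invalid interval")
  writeLines("chr1", p)
  expect_error(read_bed(p), "at least 3")
})

test_that("printed 1-based sgRNA coordinates convert to a 20 bp 0-based interval", {
  p <- withr::local_tempfile(fileext = ".bed")
  # protospacer quoted in text as chr17: 50432925-50432944 (1-based inclusive)
  writeLines("chr17\t50432925\t50432944\tDazl\t0\t+", p)
  sg <- read_sgrnas(p, one_based = TRUE)
  expect_identical(sg$start, 50432924L)
  expect_identical(sg$end, 50432944L)
  expect_identical(sg$end - sg$start, 20L)
  writeLines("chr17\t50432925\t50432944\tDazl", p)
  expect_error(read_sgrnas(p), "strand")
})

test_that("read-level records round-trip and reject unsorted positions", {
  reads <- make_reads(list(c(10L, 20L), integer(0)), list(c(1L, 0L), integer(0)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_read_table(reads, p)
  back <- read_read_table(p)
  expect_identical(back$positions, reads$positions)
  expect_identical(back$states, reads$states)
  writeLines(c("#h", "r1\tchr1\ts\t20,10\t1,0\t+"), p)
  expect_error(read_read_table(p), "non-increasing")
})

test_that("truth tables round-trip", {
  cfg <- quick_cfg(seed = 52, genome_length = 2e4)
  tr <- assign_wt_landscape(generate_genome(cfg))
  fr <- truth_fractions(tr)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(fr, p)
  back <- read_truth_table(p)
  expect_identical(back$pos, fr$pos)
  expect_identical(back$is_cgi, fr$is_cgi)
  expect_equal(back$true_frac_plus, fr$true_frac_plus, tolerance = 1e-6)
})
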