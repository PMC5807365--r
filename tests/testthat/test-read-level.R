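test_that("reads classify as none/some by their in-window methylated CpGs", {
  win <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  reads <- make_reads(list(c(10L, 20L, 30L), c(10L, 20L, 30L), c(150L, 160L)),
                      list(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L)))
  out <- classify_reads(reads, win)
  expect_identical(out$n_none, 1L)
  expect_identical(out$n_some, 1L)
  expect_identical(out$n_reads, 2L)  # read 3 has no in-window dyad: excluded
  expect_equal(out$frac_some, 0.5)
})

test_that("a read overlapping the window without an in-window dyad is excluded", {
  win <- data.frame(chrom = "chr1", start = 50L, end = 100L)
  reads <- make_reads(list(c(10L, 150L)), list(c(1L, 1L)))
  out <- classify_reads(reads, win)
  expect_identical(out$n_reads, 0L)
  expect_true(is.na(out$frac_some))
})

test_that("none + some equals the eligible read count over random windows", {
  set.seed(91)
  cfg <- quick_cfg(seed = 92, genome_length = 3e4)
  tr <- assign_wt_landscape(generate_genome(cfg))
  smp <- sample_reads(tr, cfg, seed = 201)
  wins <- data.frame(chrom = tr$chrom,
                     start = as.integer(seq(0, 2.8e4, by = 2000)))
  wins$end <- wins$start + 500L
  out <- classify_reads(smp$reads, wins)
  expect_identical(out$n_reads, out$n_none + out$n_some)
  expect_true(all(out$frac_some >= 0 & out$frac_some <= 1, na.rm = TRUE))
})

test_that("saturated and unmethylated windows hit their closed-form fractions", {
  n_cells <- 50
  cfg <- sim_config(seed = 93, genome_length = 1000, n_cells = n_cells,
                    coverage = 300)
  dyads <- seq(100L, by = 20L, length.out = 40)
  full <- truth_table(dyads, matrix(TRUE, 40, n_cells), matrix(TRUE, 40, n_cells),
                      cfg, genome_length = 1000)
  win <- data.frame(chrom = "chrS", start = 0L, end = 1000L)
  rep_full <- hemimethylation_report(sample_reads(full, cfg, seed = 202)$reads, win)
  expect_gt(rep_full$pooled$frac_some, 0.98)
  none <- truth_table(dyads, matrix(FALSE, 40, n_cells), matrix(FALSE, 40, n_cells),
                      cfg, genome_length = 1000)
  smp <- sample_reads(none, cfg, seed = 203)
  rep_none <- hemimethylation_report(smp$reads, win)
  # noise floor: 1 - conversion_rate^k for k in-window CpGs per read,
  # with a 4-sigma binomial tolerance
  ks <- lengths(strsplit(smp$reads$positions[nzchar(smp$reads$positions)], ","))
  p_read <- 1 - cfg$conversion_rate^ks
  expected <- mean(p_read)
  tol <- 4 * sqrt(mean(p_read * (1 - p_read)) / rep_none$pooled$n_reads)
  expect_lt(abs(rep_none$pooled$frac_some - expected), tol)
})

test_that("fully hemimethylated windows classify half the reads as some", {
  truth <- hemi_truth(n_dyads = 40, n_cells = 100, seed = 94)
  cfg <- truth$config
  cfg$coverage <- 100
  smp <- sample_reads(truth, cfg, seed = 204)
  win <- data.frame(chrom = "chrS", start = 0L, end = 4000L)
  rep <- hemimethylation_report(smp$reads, win)
  expect_gt(rep$pooled$n_reads, 500)
  expect_lt(abs(rep$pooled$frac_some - 0.5), 0.05)
  expect_true(rep$pooled$ci_lo < 0.5 & rep$pooled$ci_hi > 0.5)
})

test_that("empty inputs give NA fractions and zero counts", {
  win <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  reads <- make_reads(list(integer(0)), list(integer(0)))
  rep <- hemimethylation_report(reads, win)
  expect_identical(rep$pooled$n_reads, 0L)
  expect_true(is.na(rep$pooled$frac_some))
})
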