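test_that("null dynamics with perfect maintenance preserve day-0 truth exactly", {
  cfg <- quick_cfg(seed = 31, r_off = 0, r_on = 0, maintenance_fidelity = 1)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 7))
  expect_identical(ser[["7"]]$plus, tr$plus)
  expect_identical(ser[["7"]]$minus, tr$minus)
})

test_that("gain without maintenance or division follows the closed-form survival", {
  # per-strand methylated fraction after t days = 1 - exp(-r_off * t)
  cfg <- quick_cfg(seed = 32, genome_length = 2e5, depleted_mean = 0,
                   r_off = 0.1, maintenance_on = FALSE, divisions_per_day = 0,
                   susceptibility_mode = "uniform", n_cells = 100)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 2))
  expected <- 1 - exp(-0.2)
  n_trials <- 2 * length(tr$dyads) * cfg$n_cells
  tol <- 3 * sqrt(expected * (1 - expected) / n_trials)
  expect_lt(abs(truth_global_mean(ser[["2"]]) - expected), tol)
})

test_that("cpg_only mode never methylates CA sites", {
  cfg <- quick_cfg(seed = 33, genome_length = 3e4, context_mode = "cpg_only",
                   track_ca = TRUE, r_off = 0.3)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 3))
  expect_false(any(ser[["3"]]$ca$plus))
  expect_false(any(ser[["3"]]$ca$minus))
})

test_that("cpg_and_cpa mode methylates CA sites", {
  cfg <- quick_cfg(seed = 34, genome_length = 3e4, context_mode = "cpg_and_cpa",
                   r_off = 0.3)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 3))
  expect_gt(sum(ser[["3"]]$ca$plus) + sum(ser[["3"]]$ca$minus), 0)
})

test_that("genome-wide gain is monotone in day with maintenance on", {
  cfg <- quick_cfg(seed = 35, genome_length = 1e5, r_off = 0.1)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = 0:7)
  gm <- vapply(ser, truth_global_mean, numeric(1))
  expect_true(all(diff(gm) >= 0))
})

test_that("one day of gain without maintenance leaves mostly hemimethylated dyads", {
  cfg <- quick_cfg(seed = 36, genome_length = 1e5, depleted_mean = 0,
                   r_off = 0.1, maintenance_on = FALSE, divisions_per_day = 0,
                   susceptibility_mode = "uniform")
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 1))
  p <- ser[["1"]]$plus; m <- ser[["1"]]$minus
  hemi <- sum(xor(p, m)); full <- sum(p & m)
  # gain probability q ~ 0.095: hemi:full odds = 2(1-q):q ~ 19:1
  expect_gt(hemi / (hemi + full), 0.85)
})

test_that("an sgRNA adds methylation around its protospacer only", {
  cfg <- quick_cfg(seed = 37, genome_length = 1e5, depleted_mean = 0,
                   r_off = 0, r_on = 1, n_cells = 100)
  g <- generate_genome(cfg)
  tr <- assign_wt_landscape(g)
  sg <- data.frame(chrom = g$chrom, start = 50000L, end = 50020L, strand = "+")
  ser <- simulate_footprinting(tr, sg, cfg, days = c(0, 3))
  fr <- truth_fractions(ser[["3"]])
  near <- abs(fr$pos - 50010) <= 500
  far <- abs(fr$pos - 50010) > 2000
  expect_gt(mean(fr$true_frac[near]), 0.5)
  expect_equal(mean(fr$true_frac[far]), 0, tolerance = 1e-12)
})

test_that("unknown sgRNA chromosome and bad day vectors are rejected", {
  cfg <- quick_cfg(seed = 38, genome_length = 2e4)
  tr <- assign_wt_landscape(generate_genome(cfg))
  bad <- data.frame(chrom = "chrX", start = 1L, end = 21L, strand = "+")
  expect_error(simulate_footprinting(tr, bad, cfg, days = c(0, 1)),
               "unknown sgRNA chromosome")
  expect_error(simulate_footprinting(tr, NULL, cfg, days = c(1, 2)), "start at 0")
  expect_error(simulate_footprinting(tr, NULL, cfg, days = c(0, 2, 1)), "ascending")
})
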