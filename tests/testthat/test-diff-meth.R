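# independent brute-force oracles
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i)
    min(1, min((p * n / r)[r >= r[i]])), numeric(1))
}

paired_t_oracle <- function(a, b) {
  d <- b - a
  t <- mean(d) * sqrt(length(d)) / stats::sd(d)
  list(t = t, p = 2 * stats::pt(-abs(t), df = length(d) - 1))
}

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.04, 1.0)), c(0.08, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH adjustment equals the brute-force oracle and p.adjust on random vectors", {
  set.seed(71)
  for (i in 1:50) {
    p <- stats::runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("the paired tile test reproduces a hand-computed example", {
  a <- calls_at_levels(c(10, 20, 30, 40), c(0.1, 0.2, 0.3, 0.4))
  b <- calls_at_levels(c(10, 20, 30, 40), c(0.3, 0.5, 0.4, 0.6))
  cfg <- analysis_config(min_cov_test = 10, min_cpgs = 3)
  st <- tile_diff(a, b, cfg)
  expect_identical(nrow(st), 1L)
  expect_equal(st$delta, 0.2)
  expect_equal(st$t_stat, 4.898979, tolerance = 1e-6)
  expect_equal(st$p_raw, 0.0163, tolerance = 1e-2)
  expect_equal(st$p_raw, paired_t_oracle(c(0.1, 0.2, 0.3, 0.4),
                                         c(0.3, 0.5, 0.4, 0.6))$p,
               tolerance = 1e-12)
})

test_that("tiles need at least min_cpgs shared covered CpGs", {
  a <- calls_at_levels(c(10, 20), c(0.1, 0.2))
  b <- calls_at_levels(c(10, 20), c(0.5, 0.6))
  expect_identical(nrow(tile_diff(a, b, analysis_config())), 0L)
  # under-covered dyads in one sample drop out of the pairing
  a2 <- calls_at_levels(c(10, 20, 30), c(0.1, 0.2, 0.3))
  b2 <- make_calls(c(10, 20, 30), c(5, 6, 1), c(10, 10, 5))
  expect_identical(nrow(tile_diff(a2, b2, analysis_config())), 0L)
})

test_that("identical samples give delta 0 and p 1 under the degenerate rule", {
  a <- calls_at_levels(c(10, 20, 30, 40), c(0.1, 0.2, 0.3, 0.4))
  st <- tile_diff(a, a, analysis_config())
  expect_equal(st$delta, 0)
  expect_equal(st$p_raw, 1)
  expect_equal(st$t_stat, 0)
  expect_false(st$significant)
  # constant non-zero shift: p 0 with signed infinite t
  b <- calls_at_levels(c(10, 20, 30, 40), c(0.3, 0.4, 0.5, 0.6))
  st2 <- tile_diff(a, b, analysis_config())
  expect_equal(st2$p_raw, 0)
  expect_identical(st2$t_stat, Inf)
  st3 <- tile_diff(b, a, analysis_config())
  expect_identical(st3$t_stat, -Inf)
})

test_that("grouped t equals the closed-form oracle on random paired vectors", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    pos <- seq(10, by = 10, length.out = n)
    la <- stats::runif(n)
    lb <- stats::runif(n)
    a <- calls_at_levels(pos, la, depth = 1000L)
    b <- calls_at_levels(pos, lb, depth = 1000L)
    st <- tile_diff(a, b, analysis_config(), width = 10000)
    orc <- paired_t_oracle(round(la * 1000) / 1000, round(lb * 1000) / 1000)
    expect_equal(st$t_stat, orc$t, tolerance = 1e-9)
    expect_equal(st$p_raw, orc$p, tolerance = 1e-9)
  }
})

test_that("the dual significance rule applies both thresholds strictly", {
  cfg <- analysis_config()
  expect_true(call_significant(0.04, 0.15, cfg))
  expect_false(call_significant(0.04, 0.05, cfg))
  expect_false(call_significant(0.05, 0.5, cfg))   # boundary: strict
  expect_false(call_significant(0.04, 0.10, cfg))  # boundary: strict
  expect_true(call_significant(0.01, -0.2, cfg))   # two-sided by default
  expect_false(call_significant(0.01, -0.2, analysis_config(gain_only = TRUE)))
})

test_that("CGI tests use no delta cutoff and exclude islands with < 3 CpGs", {
  cgis <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L))
  pos <- c(10, 20, 30, 40, 1010, 1020)
  la <- c(0.10, 0.20, 0.30, 0.40, 0.1, 0.1)
  lb <- la + c(0.05, 0.04, 0.05, 0.06, 0.5, 0.5)
  st <- cgi_test(calls_at_levels(pos, la), calls_at_levels(pos, lb),
                 cgis, analysis_config())
  # the 2-CpG island is excluded; the small but consistent shift is called
  expect_identical(nrow(st), 1L)
  expect_identical(st$start, 0L)
  expect_lt(st$delta, 0.10)
  expect_true(st$significant)
  # identical samples: not significant
  st2 <- cgi_test(calls_at_levels(pos, la), calls_at_levels(pos, la),
                  cgis, analysis_config())
  expect_false(any(st2$significant))
})

test_that("significance calls are idempotent under recomputation", {
  cfg <- quick_cfg(seed = 73, genome_length = 1e5)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 3))
  a <- sample_calls(ser[["0"]], cfg, seed = 110)
  b <- sample_calls(ser[["3"]], cfg, seed = 111)
  st <- tile_diff(a, b, analysis_config())
  expect_identical(st$significant,
                   call_significant(st$p_adj, st$delta, analysis_config()))
  expect_true(all(st$p_adj >= st$p_raw - 1e-15))
  expect_true(all(st$n_shared_cpgs >= 3))
})
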