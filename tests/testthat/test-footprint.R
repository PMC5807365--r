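test_that("on-target windows sit immediately downstream of the protospacer", {
  cs <- c(chr1 = 100000)
  cfg <- analysis_config()
  sg_plus <- data.frame(chrom = "chr1", start = 10000L, end = 10020L, strand = "+")
  expect_identical(on_target_window(sg_plus, cs, cfg),
                   data.frame(chrom = "chr1", start = 10020L, end = 10220L,
                              stringsAsFactors = FALSE))
  sg_minus <- data.frame(chrom = "chr1", start = 10000L, end = 10020L, strand = "-")
  expect_identical(on_target_window(sg_minus, cs, cfg),
                   data.frame(chrom = "chr1", start = 9800L, end = 10000L,
                              stringsAsFactors = FALSE))
  # clipped at the chromosome end with a warning
  sg_edge <- data.frame(chrom = "chr1", start = 99930L, end = 99950L, strand = "+")
  expect_warning(w <- on_target_window(sg_edge, cs, cfg), "clipped")
  expect_identical(w$end, 100000L)
  sg_out <- data.frame(chrom = "chr1", start = 99980L, end = 100000L, strand = "+")
  expect_error(on_target_window(sg_out, cs, cfg), "outside")
  # plus-rule orientation ignores the strand
  expect_identical(on_target_window(sg_minus, cs,
                                    analysis_config(downstream = "plus"))$start,
                   10020L)
})

test_that("matched background selects tiles within the tolerance, excluding on-target", {
  wt <- data.frame(chrom = "chr1", start = c(0L, 200L, 400L, 600L),
                   end = c(200L, 400L, 600L, 800L), n_cpgs = 5L,
                   mean = c(0.32, 0.36, 0.50, 0.35))
  ot <- data.frame(chrom = "chr1", start = 600L, end = 800L)
  bg <- matched_background(0.35, wt, ot, analysis_config())
  expect_identical(bg$start, c(0L, 200L))  # C out of tolerance, on-target out
  expect_true(all(abs(bg$mean - 0.35) <= 0.05))
  expect_warning(empty <- matched_background(0.9, wt, ot, analysis_config()),
                 "empty")
  expect_identical(nrow(empty), 0L)
  # zero tolerance, no exact match
  cfg0 <- analysis_config(match_tol = 0)
  expect_warning(e2 <- matched_background(0.33, wt, ot, cfg0), "empty")
  expect_identical(nrow(e2), 0L)
})

test_that("top-k overlap handles identical, disjoint and partially shared rankings", {
  cfg <- analysis_config(top_k = 3)
  mk <- function(levels) calls_at_levels(seq(10, by = 200, length.out = length(levels)),
                                         levels)
  s <- mk(c(0.9, 0.8, 0.7, 0.1, 0.2))
  same <- top_k_overlap(list(a = s, b = s, c = s), cfg)
  expect_identical(same$all, 3L)
  expect_true(all(same$pairwise == 3L))
  # disjoint constructed rankings
  s1 <- mk(c(0.9, 0.8, 0.7, 0.0, 0.0, 0.0))
  s2 <- mk(c(0.0, 0.0, 0.0, 0.9, 0.8, 0.7))
  dj <- top_k_overlap(list(a = s1, b = s2), cfg)
  expect_identical(dj$pairwise["a", "b"], 0L)
  # two samples sharing exactly 2 of top-3 (tiles 1,2 shared; 3rd differs)
  s3 <- mk(c(0.9, 0.8, 0.1, 0.7, 0.0))
  s4 <- mk(c(0.9, 0.8, 0.7, 0.1, 0.0))
  pa <- top_k_overlap(list(a = s3, b = s4), cfg)
  expect_identical(pa$pairwise["a", "b"], 2L)
  # order invariance
  expect_identical(top_k_overlap(list(a = s3, b = s4), cfg)$pairwise["a", "b"],
                   top_k_overlap(list(b = s4, a = s3), cfg)$pairwise["a", "b"])
  expect_warning(top_k_overlap(list(a = mk(c(0.5, 0.4))), analysis_config(top_k = 5)),
                 "eligible")
})

test_that("CGI classes use strict > 0.8 and inclusive <= 0.2 boundaries", {
  cgis <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                     end = c(500L, 1500L, 2500L))
  pos <- c(10, 20, 30, 1010, 1020, 1030, 2010, 2020, 2030)
  wt_levels <- c(0.81, 0.81, 0.81, 0.20, 0.20, 0.20, 0.5, 0.5, 0.5)
  wt <- calls_at_levels(pos, wt_levels)
  cs <- cgi_class_summary(wt, wt, cgis, analysis_config())
  expect_identical(cs$per_cgi$class, c("hyper", "hypo", "intermediate"))
  # test sample equal to WT: per-class means agree
  expect_equal(cs$per_class$mean_sample, cs$per_class$mean_wt)
})

test_that("K4 scores follow the nearest-rank top-percentile scaling", {
  counts <- data.frame(chrom = "chr1", start = 0L, end = 1L)[rep(1, 101), ]
  counts$start <- seq(0L, by = 10L, length.out = 101)
  counts$end <- counts$start + 1L
  counts$count <- c(1:100, 99L)
  counts$end[101] <- counts$start[101] + 2L  # density 49.5
  sc <- cgi_k4_score(counts, analysis_config())
  expect_equal(sc$score[101], 50.0)
  expect_equal(sc$score[sc$density == 100], 100)
  expect_true(all(sc$score >= 0 & sc$score <= 100))
  # equal densities all score 100; zero counts all score 0
  eq <- data.frame(chrom = "chr1", start = 0L, end = 100L, count = 5L)[rep(1, 10), ]
  expect_true(all(cgi_k4_score(eq, analysis_config())$score == 100))
  z <- data.frame(chrom = "chr1", start = 0L, end = 100L, count = 0L)[rep(1, 10), ]
  expect_true(all(cgi_k4_score(z, analysis_config())$score == 0))
  # monotone in density
  rnd <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                    count = sample(0:50, 30, replace = TRUE))
  sc2 <- cgi_k4_score(rnd, analysis_config())
  expect_false(is.unsorted(sc2$score[order(sc2$density)]))
})

test_that("delta histograms bin per-tile differences left-closed", {
  pos <- seq(5, 4995, by = 10)
  a <- calls_at_levels(pos, rep(0.2, length(pos)))
  b <- calls_at_levels(pos, rep(0.5, length(pos)))
  h <- delta_histogram(a, b, analysis_config())
  # uniform +0.3 shift: all mass in [0.30, 0.35)
  bin <- which(h$counts > 0)
  expect_length(bin, 1L)
  expect_equal(h$breaks[bin], 0.30)
  expect_identical(sum(h$counts), 5L)
  # identical samples: all mass in the bin containing 0
  h0 <- delta_histogram(a, a, analysis_config())
  expect_equal(h$breaks[which(h0$counts > 0)], 0)
  expect_warning(he <- delta_histogram(a[1:2, ], b[5:6, ], analysis_config()),
                 "no tile")
  expect_identical(sum(he$counts), 0L)
})

test_that("context summary reports per-dinucleotide means and NA for absent contexts", {
  calls <- rbind(make_calls(c(10, 20), c(8, 9), c(10, 10), context = "CG"),
                 make_calls(30, 0, 10, context = "CA"))
  cs <- context_summary(calls, min_cov = 5)
  expect_equal(cs$mean[cs$context == "CG"], 0.85)
  expect_equal(cs$mean[cs$context == "CA"], 0)
  expect_true(is.na(cs$mean[cs$context == "CC"]))
  expect_true(is.na(cs$mean[cs$context == "CT"]))
  # context derivable from the genome; unknown chromosome errors
  cfg <- quick_cfg(seed = 81, genome_length = 2e4)
  g <- generate_genome(cfg)
  calls2 <- make_calls(g$dyads[1:5], rep(1, 5), rep(10, 5), chrom = g$chrom)
  calls2$context <- NULL
  cs2 <- context_summary(calls2, genome = g, min_cov = 5)
  expect_identical(cs2$n_sites[cs2$context == "CG"], 5L)
  calls2$chrom <- "chrZ"
  expect_error(context_summary(calls2, genome = g), "not present")
})

test_that("gain curves use one common CpG set and collapse identical clones to sd 0", {
  cfg <- quick_cfg(seed = 82, genome_length = 5e4)
  tr <- assign_wt_landscape(generate_genome(cfg))
  ser <- simulate_footprinting(tr, NULL, cfg, days = c(0, 2, 4))
  calls <- lapply(names(ser), function(d) sample_calls(ser[[d]], cfg,
                                                       seed = 300 + as.integer(d)))
  tc <- data.frame(clone = rep(c("c1", "c2"), each = 3),
                   day = rep(c(0, 2, 4), 2))
  tc$calls <- c(calls, calls)
  regions <- data.frame(chrom = tr$chrom, start = 0L, end = 5e4L)
  gc <- gain_curve(tc, regions, analysis_config())
  expect_identical(gc$day, c(0, 2, 4))
  expect_true(all(gc$sd == 0))
  expect_identical(length(unique(gc$n_cpgs)), 1L)
  expect_false(is.unsorted(gc$mean))
  # single clone: sd is NA; day-0 only input: single point
  tc1 <- tc[tc$clone == "c1", ]
  expect_true(all(is.na(gain_curve(tc1, regions, analysis_config())$sd)))
  tc0 <- tc1[tc1$day == 0, ]
  expect_identical(nrow(gain_curve(tc0, regions, analysis_config())), 1L)
  # empty common set errors
  far <- data.frame(chrom = "chrZ", start = 0L, end = 100L)
  expect_error(gain_curve(tc, far, analysis_config()), "no CpG")
})
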