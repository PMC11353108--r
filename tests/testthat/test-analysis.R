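test_that("nearest-grid frequency selection reports the grid point used", {
  grid <- default_frequency_grid()
  spec <- conductivity_spectrum(grid, seq(0.1, 1, length.out = 256))
  # exact grid point: unchanged
  pk <- pick_frequencies(spec, analysis_frequencies(3))
  expect_equal(pk$frequency_hz, 3e3)
  expect_equal(pk$sigma, 0.1)
  # brute-force nearest-neighbour oracle at 607 kHz
  oracle <- as.numeric(grid)[order(abs(as.numeric(grid) - 607e3),
                                   as.numeric(grid))][1]
  expect_equal(pick_frequencies(spec, analysis_frequencies(607))$frequency_hz,
               oracle)
  expect_error(pick_frequencies(spec, analysis_frequencies(2)), "outside")
})

test_that("ties between grid neighbours break toward the lower frequency", {
  spec <- conductivity_spectrum(c(3e3, 5e3), c(0.1, 0.2))
  pk <- pick_frequencies(spec, analysis_frequencies(4))
  expect_equal(pk$frequency_hz, 3e3)
  expect_equal(pk$sigma, 0.1)
})

test_that("group summaries use the n-1 SD and omit SD for singletons", {
  grid <- c(3e3, 1e6)
  recs <- lapply(seq_along(c(0.1, 0.2, 0.3)), function(i)
    measurement_record(paste0("P", i), "normal", "in_vivo", "none",
      conductivity_spectrum(grid, rep(c(0.1, 0.2, 0.3)[i], 2))))
  lone <- measurement_record("P4", "tumor", "in_vivo", "HCC",
    conductivity_spectrum(grid, c(0.4, 0.5)))
  s <- summarize_groups(as_cohort(c(recs, list(lone))), analysis_frequencies(3))
  norm <- s[s$tissue_class == "normal", ]
  expect_equal(norm$n, 3)
  expect_equal(norm$mean, 0.2)
  expect_equal(norm$sd, 0.1)
  expect_true(is.na(s$sd[s$tissue_class == "tumor"]))
})

test_that("group summaries are invariant to record order", {
  sim <- generate_cohort(small_config(seed = 19, n_points = 8))
  cal <- calibrate_cohort(sim$records, sim$buffers[["Reference #3"]])
  s1 <- summarize_groups(cal, analysis_frequencies(c(3, 1000)))
  set.seed(20)
  s2 <- summarize_groups(as_cohort(sample(cal)), analysis_frequencies(c(3, 1000)))
  expect_equal(s1, s2)
})

test_that("the non-cirrhotic in vivo normal 1 MHz reference values average to 0.497", {
  g <- reference_patient_1mhz_groups()
  expect_length(g$in_vivo_normal, 15)
  expect_equal(mean(g$in_vivo_normal), 0.4966667, tolerance = 1e-6)
})

test_that("ratios are ratios of group means, with exact chain consistency", {
  s <- reference_summaries()
  rt <- ratio_table(s)
  at <- function(fk, r) rt$value[rt$frequency_khz == fk & rt$ratio == r]
  # chain rule holds exactly pre-rounding
  for (fk in unique(rt$frequency_khz)) {
    expect_equal(at(fk, "Tin/Cin"), at(fk, "Tin/Nin") * at(fk, "Nin/Cin"),
                 tolerance = 1e-12)
    expect_equal(at(fk, "Tex/Cin"), at(fk, "Tex/Nin") * at(fk, "Nin/Cin"),
                 tolerance = 1e-12)
  }
  # identical groups give exactly 1
  s2 <- s
  s2$mean <- 0.3
  expect_true(all(ratio_table(s2)$value == 1))
  # missing group is an error naming the ratio
  expect_error(ratio_table(s[s$tissue_class != "cirrhotic", ]), "Tin/Cin")
})

test_that("rounding for report rendering is half away from zero", {
  s <- reference_summaries()
  rt <- ratio_table(s)
  # 0.27 / 0.09 = 3.0 and 0.78 / 0.49 -> 1.6 at the printed precision
  expect_equal(rt$value_rounded[rt$frequency_khz == 3 & rt$ratio == "Tex/Cin"], 3.0)
  expect_equal(rt$value_rounded[rt$frequency_khz == 1000 & rt$ratio == "Tin/Nin"], 1.6)
})

test_that("Kruskal-Wallis matches the hand-computed two-group case", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$h_statistic, 3), 3.857)
  expect_equal(kw$degrees_freedom, 1)
  expect_equal(kw$p_value, 0.0495, tolerance = 1e-3)
  expect_false(kw$tie_corrected)
})

test_that("Kruskal-Wallis agrees with the independent stats::kruskal.test oracle", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      round(rnorm(sample(3:12, 1), mean = j * runif(1)), sample(0:2, 1)))
    if (length(unique(unlist(groups))) == 1L) next
    kw <- kruskal_wallis(groups)
    oracle <- stats::kruskal.test(groups)
    expect_equal(kw$h_statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, oracle$p.value, tolerance = 1e-12)
    expect_equal(kw$degrees_freedom, unname(oracle$parameter))
  }
})

test_that("Kruskal-Wallis is invariant under strictly increasing transforms", {
  set.seed(42)
  groups <- list(runif(8), runif(6) + 0.3, runif(7) + 0.6)
  a <- kruskal_wallis(groups)
  b <- kruskal_wallis(lapply(groups, function(g) exp(5 * g) - 2))
  expect_equal(a$h_statistic, b$h_statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("ties are mid-ranked and corrected; degenerate data are rejected", {
  kw <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_true(kw$tie_corrected)
  expect_equal(kw$h_statistic, 0)
  expect_gt(kw$p_value, 0.9)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3")
  expect_error(kruskal_wallis(list(c(1, 2))), "two groups")
})

test_that("significance report flags p < alpha per frequency; alpha = 1 flags all", {
  sim <- generate_cohort(small_config(seed = 23, n_points = 16))
  cal <- calibrate_cohort(sim$records, sim$buffers[["Reference #3"]])
  rep05 <- significance_report(cal, analysis_frequencies(c(3, 1000)), alpha = 0.05)
  expect_equal(rep05$significant, rep05$p_value < 0.05)
  rep1 <- significance_report(cal, analysis_frequencies(c(3, 1000)), alpha = 1)
  expect_true(all(rep1$significant))
  expect_error(significance_report(cal, alpha = 0), "alpha")
})
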