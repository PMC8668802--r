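test_that("replicate summaries reproduce printed group statistics", {
  low <- c(1.86, 2.77, 1.96, 1.22)
  s <- replicate_summary(low, sd_mode = "population")
  expect_equal(round(s$mean, 2), 1.95)
  expect_equal(round(s$cv_pct, 1), 28.2)
  s2 <- replicate_summary(c(83.2, 94.2), sd_mode = "sample")
  expect_equal(round(s2$cv_pct, 1), 8.8)
  expect_equal(s2$se, s2$sd / sqrt(2))
  expect_error(replicate_summary(numeric()), "one")
})

test_that("rank-sum test reproduces the cartridge comparison", {
  g <- cartridge_groups()
  r <- rank_sum_test(g$x, g$y)
  expect_equal(r$w, 18)
  expect_equal(r$p_value, 1.000)
  expect_equal(r$method, "exact")
  expect_equal(round(r$shift, 2), 0.27)
})

test_that("exact rank-sum enumeration matches closed cases and the stats oracle", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$w, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 rank assignments are as extreme

  set.seed(5)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:8, 1)), 6); y <- round(rnorm(sample(3:8, 1)), 6)
    ours <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$w, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum is antisymmetric and splits ties", {
  set.seed(8)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(rank_sum_test(x, y)$w + rank_sum_test(y, x)$w, 42)
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value)
  z <- c(1, 2, 2, 3)
  expect_equal(rank_sum_test(z, z)$w, length(z)^2 / 2)
})

test_that("Hodges-Lehmann shift equals the pairwise-difference median", {
  g <- cartridge_groups()
  expect_equal(round(hodges_lehmann_shift(g$x, g$y), 2), 0.27)
  expect_equal(hodges_lehmann_shift(g$x, g$x), 0)
  set.seed(9)
  x <- rnorm(5); y <- rnorm(8)
  # brute-force oracle: full sorted enumeration
  expect_equal(hodges_lehmann_shift(x, y),
               median(sort(as.vector(outer(x, y, "-")))))
  # translation equivariance
  expect_equal(hodges_lehmann_shift(x + 3.5, y),
               hodges_lehmann_shift(x, y) + 3.5)
  # agreement with the stats oracle's HL estimate
  ref <- wilcox.test(x, y, conf.int = TRUE)
  expect_equal(hodges_lehmann_shift(x, y), unname(ref$estimate))
})

test_that("dilution linearity: exact geometric series and OLS oracle", {
  q <- data.frame(dilution_fold = c(1, 0.1, 0.01, 0.001),
                  conc_copies_ul = c(100, 10, 1, 0.1),
                  qc_pass = TRUE, k = 1)
  # lm warns about the numerically perfect fit; that is the point here
  lin <- suppressWarnings(dilution_linearity(q, scale = "log10"))
  expect_equal(lin$slope, 1)
  expect_equal(lin$r2, 1)

  set.seed(12)
  noisy <- q
  noisy$conc_copies_ul <- noisy$conc_copies_ul * rlnorm(4, 0, 0.05)
  lin <- dilution_linearity(noisy, scale = "log10")
  # closed-form OLS oracle on the same numbers
  xv <- log10(noisy$dilution_fold); yv <- log10(noisy$conc_copies_ul)
  b <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
  r2 <- b^2 * sum((xv - mean(xv))^2) / sum((yv - mean(yv))^2)
  expect_equal(lin$slope, b)
  expect_equal(lin$r2, r2)

  expect_error(dilution_linearity(q[q$dilution_fold == 1, , drop = FALSE]),
               "distinct dilution levels")
})

test_that("LOD reproduces the printed decision and handles edge series", {
  q <- quantify_wells(table4())
  lod <- limit_of_detection(q)
  expect_true(lod$lod_reached)
  expect_equal(lod$lod_level, 0.01)
  expect_equal(round(lod$lod_conc, 2), 0.86)
  # every level more concentrated than the LOD also passes
  folds <- as.numeric(names(lod$per_level_pass))
  expect_true(all(lod$per_level_pass[folds >= lod$lod_level]))

  none <- data.frame(dilution_fold = rep(c(1, 0.1), each = 3),
                     k = c(0, 5, 5, 0, 4, 4),
                     conc_copies_ul = 1, qc_pass = TRUE)
  expect_false(limit_of_detection(none)$lod_reached)

  top_only <- data.frame(dilution_fold = rep(c(1, 0.1), each = 3),
                         k = c(9, 9, 9, 2, 9, 9),
                         conc_copies_ul = 1, qc_pass = TRUE)
  expect_equal(limit_of_detection(top_only)$lod_level, 1)
})

test_that("LOD is monotone: extra positive droplets never raise it", {
  base <- data.frame(dilution_fold = rep(c(1, 0.1, 0.01), each = 4),
                     k = c(8, 9, 7, 8, 4, 3, 2, 5, 1, 0, 2, 3),
                     n = 12000, qc_pass = TRUE)
  base$conc_copies_ul <- concentration(base$n, base$k)
  lod0 <- limit_of_detection(base)
  richer <- base
  richer$k <- base$k + 3
  richer$conc_copies_ul <- concentration(richer$n, richer$k)
  expect_lte(limit_of_detection(richer)$lod_level, lod0$lod_level)
})

test_that("qPCR efficiency follows the slope formula", {
  expect_lt(abs(qpcr_efficiency(-3.465) - 94.3), 0.1)
  expect_equal(qpcr_efficiency(-3.3219), 100, tolerance = 1e-3)
  expect_equal(qpcr_efficiency(-6.6439), (10^(1 / 6.6439) - 1) * 100)
  expect_equal(round(qpcr_efficiency(-6.6439), 1), 41.4)
  expect_error(qpcr_efficiency(3.3), "negative")
})
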