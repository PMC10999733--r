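# stats_report: histograms, peaks, group averages, t-tests, report bundle

fake_samples <- function(theta, weight = NULL, k_theta = NULL) {
  d <- data.frame(theta_deg = theta)
  d$weight <- if (is.null(weight)) rep(1, length(theta)) else weight
  if (!is.null(k_theta)) d$k_theta <- k_theta
  d
}

test_that("sample_histograms builds normalized circular histograms", {
  s <- sample_histograms(fake_samples(rep(90, 50)))
  expect_equal(sum(s$theta_hist$density * 4), 1)
  expect_equal(sum(s$theta_hist$density > 0), 1)
  expect_equal(s$theta_peak, 90)          # centre of bin [88, 92)
  expect_error(sample_histograms(fake_samples(numeric(0))), "empty-input")

  # circularity: shifting theta by 180 changes nothing
  set.seed(41)
  th <- stats::runif(500, 0, 180)
  s1 <- sample_histograms(fake_samples(th))
  s2 <- sample_histograms(fake_samples(th + 180))
  expect_equal(s1$theta_hist$density, s2$theta_hist$density)
  expect_equal(s1$theta_peak, s2$theta_peak)
})

test_that("uniform angles flatten as n grows (Monte Carlo)", {
  set.seed(42)
  th <- stats::runif(1e5, 0, 180)
  s <- sample_histograms(fake_samples(th))
  d <- s$theta_hist$density
  expect_lt(max(d) / min(d), 1.15)
})

test_that("a concentrated axial von Mises sample peaks at its mean", {
  set.seed(43)
  th <- rvonmises_axial(2e4, 80, 20)
  s <- sample_histograms(fake_samples(th))
  expect_lte(abs(axial_diff(s$theta_peak, 80)), 4)
})

test_that("peak ties resolve to the circular mean of tied centres", {
  h <- list(mids = c(78, 82, 86, 90), density = c(1, 3, 3, 1) / 32)
  expect_equal(peak_value(h), 84)
  # unique max
  h2 <- list(mids = c(86, 90, 94), density = c(1, 5, 1) / 28)
  expect_equal(peak_value(h2), 90)
  # parabolic refinement moves towards the heavier neighbour
  h3 <- list(mids = c(86, 90, 94), density = c(2, 5, 3) / 40)
  p <- peak_value(h3, refine = TRUE)
  expect_gt(p, 90); expect_lt(p, 92)
  expect_error(peak_value(list(mids = numeric(0), density = numeric(0))),
               "empty histogram")
})

test_that("k_theta histograms clamp into the fixed bin range", {
  s <- sample_histograms(fake_samples(rep(45, 10),
                                      k_theta = c(rep(-2e-3, 9), -5)))
  expect_equal(sum(s$ktheta_hist$density * 2.5e-4), 1, tolerance = 1e-9)
  expect_lt(abs(s$ktheta_peak - (-2e-3)), 2.5e-4 / 2 + 1e-12)  # half a bin
})

test_that("group_average computes per-bin mean and SE across samples", {
  s1 <- sample_histograms(fake_samples(rep(90, 100)), sample_id = "a")
  s2 <- sample_histograms(fake_samples(rep(90, 100)), sample_id = "b")
  ga <- group_average(list(s1, s2))
  expect_equal(ga$se, rep(0, 45))
  # two histograms differing in one bin: SE = d / 2 there
  s3 <- sample_histograms(fake_samples(c(rep(90, 99), 10)), sample_id = "c")
  ga2 <- group_average(list(s1, s3))
  i <- which(s1$theta_hist$density != s3$theta_hist$density)
  d <- abs(s1$theta_hist$density - s3$theta_hist$density)[i]
  expect_equal(ga2$se[i], d / 2)
  # single sample: SE undefined, flagged
  ga1 <- group_average(list(s1))
  expect_false(ga1$se_defined)
  expect_true(all(is.na(ga1$se)))
})

test_that("group SE matches a bootstrap oracle within 20%", {
  set.seed(44)
  sums <- lapply(1:5, function(i) {
    sample_histograms(fake_samples(rvonmises_axial(400, 85 + 3 * i, 15)),
                      sample_id = i)
  })
  ga <- group_average(sums)
  dens <- do.call(rbind, lapply(sums, function(s) s$theta_hist$density))
  boot <- replicate(2000, {
    colMeans(dens[sample(5, replace = TRUE), , drop = FALSE])
  })
  se_boot <- apply(boot, 1, stats::sd)
  busy <- ga$mean > stats::median(ga$mean[ga$mean > 0])
  ratio <- ga$se[busy] / (se_boot[busy] * sqrt(5 / 4))  # bootstrap bias factor
  expect_lt(max(abs(ratio - 1)), 0.2)
})

test_that("group averages shrink like 1/sqrt(n) (Monte Carlo)", {
  set.seed(45)
  mean_se <- vapply(c(5, 20), function(n) {
    sums <- lapply(seq_len(n), function(i) {
      sample_histograms(fake_samples(rvonmises_axial(300, 100, 20)),
                        sample_id = i)
    })
    ga <- group_average(sums)
    mean(ga$se[ga$mean > 0])
  }, numeric(1))
  expect_equal(mean_se[1] / mean_se[2], sqrt(20 / 5), tolerance = 0.35)
})

test_that("one-sample t-test matches the closed form and stats::t.test", {
  peaks <- c(92, 94, 96)
  res <- one_sample_test(peaks, 90)
  # closed form: mean 94, sd 2, n 3 -> t = 4 / (2 / sqrt(3))
  t_cf <- 4 / (2 / sqrt(3))
  expect_equal(res$t, t_cf, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-t_cf, 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  ref <- stats::t.test(peaks, mu = 90)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  # equal peaks: t = 0, p = 1
  res0 <- one_sample_test(c(90, 90, 90), 90)
  expect_equal(res0$t, 0); expect_equal(res0$p, 1)
  expect_error(one_sample_test(95, 90), ">= 2")
  # circular linearization handles the 0/180 wrap (pore reference)
  resc <- one_sample_test(c(179, 1, 178, 2), 180, circular = TRUE)
  expect_lt(abs(resc$t), 1)
})

test_that("two-sample t-test matches the closed form, t.test and a permutation check", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- two_sample_test(a, b)
  t_cf <- -3 / sqrt(1 * (1 / 3 + 1 / 3))   # pooled sd = 1
  expect_equal(res$t, t_cf, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(t_cf, 4), tolerance = 1e-12)
  expect_lt(abs(res$p - 0.0214), 5e-4)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  # permutation reference: same order of magnitude (exact: 0.1 two-sided)
  pool <- c(a, b)
  perm <- utils::combn(6, 3)
  tstat <- apply(perm, 2, function(i) {
    x <- pool[i]; y <- pool[-i]
    sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
    (mean(x) - mean(y)) / sqrt(sp2 * 2 / 3)
  })
  p_perm <- mean(abs(tstat) >= abs(res$t) - 1e-12)
  expect_equal(p_perm, 0.1, tolerance = 1e-9)
  # identical groups -> t = 0, p = 1
  res0 <- two_sample_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(res0$t, 0); expect_equal(res0$p, 1)
  expect_error(two_sample_test(1, c(2, 3)), ">= 2")
  # Welch agrees with stats::t.test default
  aw <- c(1, 2, 3, 9); bw <- c(4, 5, 6)
  rw <- two_sample_test(aw, bw, welch = TRUE)
  refw <- stats::t.test(aw, bw)
  expect_equal(rw$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(rw$p, refw$p.value, tolerance = 1e-8)
})

test_that("significance stars follow the 0.05 / 0.005 / 0.001 levels", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.004, 0.0005)),
               c("n.s.", "*", "**", "***"))
})

test_that("build_report aggregates a drifting time series monotonically", {
  set.seed(46)
  days <- c(4, 7, 11, 16, 23, 32)
  thetas <- seq(110, 80, length.out = 6)
  sums <- list()
  for (i in seq_along(days)) {
    for (s in 1:5) {
      th <- rvonmises_axial(300, rvonmises_axial(1, thetas[i], 60), 25)
      sums[[length(sums) + 1]] <- sample_histograms(
        fake_samples(th), sample_id = sprintf("d%d_s%d", days[i], s),
        surface_type = "bridge", day = days[i], treatment = "WT")
    }
  }
  rep1 <- build_report(sums)
  med <- tapply(rep1$peaks$theta_peak, rep1$peaks$day, stats::median)
  med <- med[order(as.numeric(names(med)))]
  expect_true(all(diff(med) < 2))          # monotone decrease (small slack)
  expect_lt(med[length(med)], med[1] - 20)
  # one-sample tests exist per group with the bridge reference 90
  ot <- rep1$tests[rep1$tests$test == "one_sample_theta", ]
  expect_equal(nrow(ot), 6)
  expect_true(all(ot$reference == 90))

  # determinism: identical CSV bytes on re-run
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1); write_report(build_report(sums), d2)
  for (f in c("peaks.csv", "histograms.csv", "tests.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  # empty input: warning, empty bundle
  expect_warning(rep0 <- build_report(list()), "empty report")
  expect_equal(nrow(rep0$peaks), 0)
})

test_that("two-sample comparisons appear for matched groups", {
  set.seed(47)
  sums <- list()
  for (trt in c("WT", "LAC-ko")) {
    mu <- if (trt == "WT") 85 else 110
    for (s in 1:5) {
      sums[[length(sums) + 1]] <- sample_histograms(
        fake_samples(rvonmises_axial(300, mu, 30)),
        sample_id = paste(trt, s), surface_type = "bridge", day = 32,
        treatment = trt)
    }
  }
  rep1 <- build_report(sums)
  tt <- rep1$tests[rep1$tests$test == "two_sample_theta", ]
  expect_equal(nrow(tt), 1)
  expect_lt(tt$p, 0.001)
})
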