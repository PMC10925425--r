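test_that("kinetic traces validate their invariants", {
  expect_error(kinetic_trace(1:5, rnorm(5)), ">= 10")
  expect_error(kinetic_trace(c(1:9, 9), rnorm(10)), "strictly increasing")
  expect_error(kinetic_trace(1:10, c(rnorm(9), NA)), "finite")
})

test_that("noiseless single-exponential fits recover parameters to 1e-6 relative", {
  for (dir in c("decay", "rise")) {
    tr <- simulate_trace("single_exp", A0 = 2, k = 0.5, baseline = 0.3,
                         sigma = 0, times = seq(0, 12, length.out = 120),
                         direction = dir)
    f <- fit_single_exponential(tr, dir)
    expect_equal(f$k, 0.5, tolerance = 1e-6)
    expect_equal(f$A0, 2, tolerance = 1e-6)
    expect_equal(f$baseline, 0.3, tolerance = 1e-6)
    expect_equal(length(f$residuals), 120L)
    expect_gt(f$r_squared, 0.999999)
  }
})

test_that("noisy single-exponential recovery is unbiased with near-nominal SE coverage", {
  n <- 100
  ks <- covered <- numeric(n)
  for (i in seq_len(n)) {
    tr <- simulate_trace("single_exp", A0 = 1, k = 0.5, sigma = 0.01,
                         times = seq(0, 12, length.out = 150), seed = 400 + i)
    f <- fit_single_exponential(tr, "decay")
    ks[i] <- f$k
    covered[i] <- abs(f$k - 0.5) <= qnorm(0.975) * f$se[["k"]]
  }
  expect_lt(abs(mean(ks) - 0.5) / 0.5, 0.02)
  expect_gt(mean(covered), 0.85)
})

test_that("constant traces are rejected", {
  expect_error(fit_single_exponential(kinetic_trace(1:20, rep(3, 20))),
               "constant")
})

test_that("the two-step model handles the equal-rates limit analytically", {
  t <- seq(0, 10, length.out = 50)
  lim <- two_step_signal(t, A = 1, k1 = 1, k2 = 1)
  near <- two_step_signal(t, A = 1, k1 = 1 + 1e-9, k2 = 1 - 1e-9)
  expect_equal(lim, 1 - (1 + t) * exp(-t), tolerance = 1e-12)
  expect_equal(near, lim, tolerance = 1e-6)
  expect_true(all(is.finite(near)))
})

test_that("lag detection fires on two-step traces and not on single exponentials", {
  hits_two <- hits_one <- logical(30)
  for (i in seq_along(hits_two)) {
    tr2 <- simulate_trace("two_step", A0 = 1, k1 = 5, k2 = 0.5, sigma = 0.01,
                          times = seq(0, 10, length.out = 200), seed = 600 + i)
    hits_two[i] <- assess_lag(tr2)$lag_detected
    tr1 <- simulate_trace("single_exp", A0 = 1, k = 0.5, direction = "rise",
                          sigma = 0.01, times = seq(0, 10, length.out = 200),
                          seed = 700 + i)
    hits_one[i] <- assess_lag(tr1)$lag_detected
  }
  expect_gte(mean(hits_two), 0.95)
  expect_lte(mean(hits_one), 0.05)
  # canonical rate ordering
  la <- assess_lag(simulate_trace("two_step", A0 = 1, k1 = 0.5, k2 = 5,
                                  sigma = 0, times = seq(0, 10, length.out = 200)))
  expect_gte(la$two_step$k1, la$two_step$k2)
  expect_equal(la$two_step$k1, 5, tolerance = 1e-3)
})

test_that("binding lines recover slope and intercept exactly from exact points", {
  pts <- data.frame(conc = c(1, 2, 5, 10, 20), kobs = 2 * c(1, 2, 5, 10, 20) + 5)
  f <- fit_binding_line(pts)
  expect_equal(f$k1, 2, tolerance = 1e-10)
  expect_equal(f$k_minus1, 5, tolerance = 1e-10)
  expect_equal(f$Kd_kinetic, 2.5, tolerance = 1e-9)
  expect_true(f$intercept_reliable)
  expect_error(fit_binding_line(pts[1:2, ]), ">= 3")
  expect_error(fit_binding_line(data.frame(conc = c(2, 2, 2), kobs = 1:3)),
               "rank-deficient")
})

test_that("an unresolvable intercept suppresses the kinetic Kd", {
  set.seed(77)
  conc <- c(5, 10, 20, 40, 80)
  pts <- data.frame(conc = conc, kobs = 2 * conc + 0.01 + rnorm(5, 0, 3))
  f <- fit_binding_line(pts)
  expect_false(f$intercept_reliable)
  expect_true(is.na(f$Kd_kinetic))
})

test_that("binding-line CI coverage is near nominal under noise", {
  n <- 200
  hit <- logical(n)
  for (i in seq_len(n)) {
    set.seed(800 + i)
    conc <- c(1, 2, 5, 10, 20, 40)
    pts <- data.frame(conc = conc, kobs = 2 * conc + 5 + rnorm(6, 0, 2))
    f <- fit_binding_line(pts)
    hit[i] <- abs(f$k1 - 2) <= qt(0.975, 4) * f$k1_se
  }
  expect_gt(mean(hit), 0.90)
  expect_lt(mean(hit), 0.99)
})

test_that("Michaelis-Menten fits recover exact data to 1e-6 and flag missing curvature", {
  d <- simulate_mm(kcat = 10, Km = 100, enzyme_conc = 0.2)
  f <- fit_michaelis_menten(d, 0.2)
  expect_equal(f$kcat, 10, tolerance = 1e-6)
  expect_equal(f$Km, 100, tolerance = 1e-6)
  expect_equal(f$efficiency, 0.1, tolerance = 1e-6)
  expect_false(f$km_lower_bound_only)
  # substrate range far below Km: no curvature
  low <- simulate_mm(kcat = 10, Km = 1e4, enzyme_conc = 0.2,
                     s_grid = c(1, 2, 5, 10, 20, 50, 100))
  fl <- fit_michaelis_menten(low, 0.2)
  expect_true(fl$km_lower_bound_only)
  expect_error(fit_michaelis_menten(d[1:4, ], 0.2), ">= 5")
})

test_that("noisy Michaelis-Menten efficiency estimates are accurate and SE-calibrated", {
  n <- 100
  rel <- cov2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- simulate_mm(10, 100, 0.2, sigma_rel = 0.05, seed = 1200 + i)
    d$se <- NULL
    f <- fit_michaelis_menten(d, 0.2)
    rel[i] <- abs(f$efficiency - 0.1) / 0.1
    cov2[i] <- abs(f$efficiency - 0.1) <= 2 * f$efficiency_se
  }
  expect_lt(stats::median(rel), 0.10)
  expect_lt(mean(rel), 0.15)
  expect_gte(mean(cov2), 0.80)  # delta-method SE roughly calibrated
})

test_that("Lineweaver-Burk lines match the nonlinear fit on noiseless data", {
  d <- simulate_mm(10, 100, 0.2)
  lb <- lineweaver_burk(d)
  # slope = Km/Vmax, intercept = 1/Vmax
  expect_equal(lb$lines$slope, 100 / 2, tolerance = 1e-6)
  expect_equal(lb$lines$intercept, 1 / 2, tolerance = 1e-6)
  expect_error(lineweaver_burk(data.frame(conc = c(0, 1, 2), rate = c(1, 1, 1))),
               "exclude")
})

test_that("competitive inhibition shows shared intercepts and growing slopes", {
  sets <- lapply(c(0, 25, 50), function(I) {
    d <- simulate_mm(10, 100, 0.2, sigma_rel = 0.02, inhibitor_conc = I,
                     Ki = 25, seed = 50 + I)
    d
  })
  lb <- lineweaver_burk(do.call(rbind, sets))
  expect_true(lb$shared_intercept)
  expect_true(lb$slopes_increase)
  expect_true(lb$competitive_like)
  # a duplicated zero-inhibitor condition produces identical lines
  d0 <- simulate_mm(10, 100, 0.2)
  dup <- rbind(d0, transform(d0, inhibitor = 1e-12))
  lbd <- lineweaver_burk(dup)
  expect_equal(lbd$lines$slope[1], lbd$lines$slope[2], tolerance = 1e-9)
  expect_equal(lbd$lines$intercept[1], lbd$lines$intercept[2], tolerance = 1e-9)
  # Ki = Inf: inhibited data identical to uninhibited
  dinf <- simulate_mm(10, 100, 0.2, inhibitor_conc = 100, Ki = Inf)
  expect_equal(dinf$rate, d0$rate, tolerance = 1e-12)
})

test_that("efficiency fold changes propagate uncertainty and handle identity", {
  fa <- fit_michaelis_menten(simulate_mm(10, 100, 0.2), 0.2)
  expect_equal(efficiency_fold_change(fa, fa)$fold_change, 1, tolerance = 1e-9)
  fb <- fit_michaelis_menten(simulate_mm(10, 560, 0.2), 0.2)
  fc <- efficiency_fold_change(fa, fb)
  expect_equal(fc$fold_change, 5.6, tolerance = 1e-6)
})

test_that("kinetic tables read back from delimited text", {
  tr <- simulate_trace("single_exp", A0 = 1, k = 1, sigma = 0,
                       times = seq(0, 5, length.out = 20))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = tr$time_s, signal = tr$signal), f,
                   row.names = FALSE)
  tr2 <- read_kinetic_table(f, "trace")
  expect_equal(tr2$signal, tr$signal, tolerance = 1e-12)
  d <- simulate_mm(10, 100, 0.2)
  utils::write.csv(d, f, row.names = FALSE)
  expect_equal(read_kinetic_table(f, "rates")$rate, d$rate, tolerance = 1e-12)
})
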