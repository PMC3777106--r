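# Calibration statistics: null simulation, Gumbel and exponential-tail
# fits, score -> P-value -> E-value conversion.

test_that("null target sampling honors composition and seed", {
  t1 <- sample_null_targets(c(1, 0, 0, 0), 2, 50, seed = 5)
  expect_true(all(grepl("^A+$", vapply(t1, `[[`, "", "residues"))))
  big <- sample_null_targets(rep(0.25, 4), 1, 1e5, seed = 6)[[1]]
  freq <- table(strsplit(big$residues, "")[[1]]) / 1e5
  # binomial 3 sigma around 0.25 at n = 1e5: +- 0.0041
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  t2 <- sample_null_targets(c(1, 1, 1, 1), 3, 40, seed = 9)
  t3 <- sample_null_targets(c(1, 1, 1, 1), 3, 40, seed = 9)
  expect_identical(vapply(t2, `[[`, "", "residues"),
                   vapply(t3, `[[`, "", "residues"))
})

test_that("Gumbel ML fit recovers parameters and behaves at closed forms", {
  withr::with_seed(51, {
    mu <- 5; lambda <- 0.7
    x <- mu - log(-log(runif(10000))) / lambda
    fit <- fit_gumbel(x)
    expect_lt(abs(fit$mu - mu) / mu, 0.02)
    expect_lt(abs(fit$lambda - lambda) / lambda, 0.02)
    # P(S >= mu) = 1 - exp(-1)
    expect_equal(profscan:::gumbel_pvalue(fit$mu, fit$mu, fit$lambda),
                 1 - exp(-1), tolerance = 1e-12)
    # translation equivariance
    fit2 <- fit_gumbel(x + 3)
    expect_equal(fit2$mu, fit$mu + 3, tolerance = 1e-6)
    expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-6)
  })
  expect_error(fit_gumbel(rep(1, 200)), "degenerate")
})

test_that("exponential tail fit pins the quantile and tail probabilities", {
  withr::with_seed(52, {
    x <- rexp(5000) / log(2)          # lambda = 1 per bit
    fit <- fit_exp_tail(x, 0.04)
    expect_equal(mean(x >= fit$tau), 0.04, tolerance = 1e-3)
    expect_equal(fit_exp_tail(x, 0.5)$tau, median(x))
    # recovered tail P-values at probe points within binomial 3 sigma
    for (probe in fit$tau + c(0.5, 1, 2)) {
      p_model <- 0.04 * 2^(-(probe - fit$tau))
      p_emp <- mean(x >= probe)
      expect_lt(abs(p_model - p_emp),
                3 * sqrt(p_model * (1 - p_model) / 5000) + 1e-3)
    }
  })
  expect_error(fit_exp_tail(rep(2, 500)), "degenerate")
})

test_that("calibration is deterministic per seed and well-formed", {
  sp <- cached_calibrated_sp()
  cal <- sp$calibration
  expect_gt(cal$ssv_lambda, 0)
  expect_gt(cal$vit_lambda, 0)
  expect_true(is.finite(cal$fwd_tau))
  expect_equal(cal$calib_N, 100L)
  cal2 <- calibrate(configure_local(sp$hmm), n = 100, L = 1000, seed = 77)
  expect_equal(cal2$ssv_mu, cal$ssv_mu)
  expect_equal(cal2$fwd_qx, cal$fwd_qx)
  # a small-n calibration records its own warning
  cal3 <- calibrate(configure_local(sp$hmm), n = 30, L = 500, seed = 1)
  expect_match(cal3$warning, "30")
})

test_that("E-values scale linearly with searched residues", {
  sp <- cached_calibrated_sp()
  cal <- sp$calibration
  pe <- score_to_evalue(cal$fwd_tau, "fwd", cal, cal$calib_L)
  expect_equal(pe$pvalue, cal$fwd_tailmass)         # by construction
  expect_equal(pe$evalue, pe$pvalue)                # unit scaling
  pe2 <- score_to_evalue(cal$fwd_tau, "fwd", cal, 2 * cal$calib_L)
  expect_equal(pe2$evalue, 2 * pe$evalue)
  expect_error(score_to_evalue(1, "nope", cal, 100), "unknown stage")
})

test_that("P-values are monotone decreasing in score for every stage", {
  sp <- cached_calibrated_sp()
  cal <- sp$calibration
  grid <- seq(cal$fwd_qx[1] - 5, cal$fwd_tau + 20, length.out = 200)
  for (stage in c("ssv", "vit", "fwd")) {
    p <- score_to_evalue(grid, stage, cal, 1000)$pvalue
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("the forward P-value is continuous across the tail join", {
  sp <- cached_calibrated_sp()
  cal <- sp$calibration
  eps <- 1e-9
  below <- score_to_evalue(cal$fwd_tau - eps, "fwd", cal, 1)$pvalue
  above <- score_to_evalue(cal$fwd_tau + eps, "fwd", cal, 1)$pvalue
  expect_equal(below, above, tolerance = 1e-6)
  expect_equal(above, cal$fwd_tailmass, tolerance = 1e-6)
})
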