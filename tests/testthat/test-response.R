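test_that("Gaussian-CDF fit recovers moments of seeded normal samples", {
  set.seed(101)
  z <- rnorm(1e4)
  fit <- fit_fluctuation(z)
  expect_equal(fit$mu, 0, tolerance = 0.03)
  expect_equal(fit$sigma, 1, tolerance = 0.03)
  expect_equal(fit$df_th, 1.96, tolerance = 0.06)
  # affine transform maps the fit accordingly
  fit2 <- fit_fluctuation(0.1 + 0.05 * z)
  expect_equal(fit2$mu, 0.1 + 0.05 * fit$mu, tolerance = 1e-4)
  expect_equal(fit2$sigma, 0.05 * fit$sigma, tolerance = 1e-4)
  expect_equal(fit2$df_th, 0.198, tolerance = 0.02)
})

test_that("degenerate and undersized fluctuation sets are handled", {
  expect_warning(fit <- fit_fluctuation(rep(0.3, 25)), "zero spread")
  expect_equal(fit$mu, 0.3)
  expect_equal(fit$sigma, 0)
  expect_equal(fit$df_th, 0.3)
  expect_error(fit_fluctuation(1:5), "at least 10")
})

test_that("the threshold rule is mu + 1.96 sigma, equivariant under scaling", {
  set.seed(7)
  v <- rnorm(400, 0.2, 0.04)
  f1 <- fit_fluctuation(v)
  expect_equal(threshold(f1), f1$mu + 1.96 * f1$sigma)
  a <- 3.5; b <- 0.7
  f2 <- fit_fluctuation(a * v + b)
  expect_equal(threshold(f2), a * threshold(f1) + b, tolerance = 1e-4)
  # spot values of the rule itself
  expect_equal(0 + 1.96 * 1, 1.96)
  expect_equal(with(list(m = 0.05, s = 0.1), m + 1.96 * s), 0.246)
})

test_that("responder classification is strict at the threshold", {
  expect_identical(classify_responders(c(0.5, 0.5 + 1e-12, 0.2), 0.5),
                   c(FALSE, TRUE, FALSE))
  expect_identical(classify_responders(numeric(0), 0.5), logical(0))
})

test_that("fluctuation model methods expose the fit", {
  set.seed(3)
  fit <- fit_fluctuation(rnorm(100, 0.1, 0.02))
  expect_named(coef(fit), c("mu", "sigma", "df_th"))
  expect_equal(predict(fit, fit$mu), 0.5, tolerance = 1e-9)
  expect_output(print(fit), "dF_th")
})

test_that("binned response curves report per-bin responder fractions", {
  dT <- c(1, 1.5, 2, 2.5, 4, 4.5, 5, 5.5)
  resp <- dT > 3
  rc <- response_curve(dT, resp, breaks = c(0, 3, 6))
  expect_equal(rc$p, c(0, 1))
  expect_equal(rc$n, c(4L, 4L))
  rc_all <- response_curve(dT, rep(TRUE, 8), breaks = c(0, 3, 6))
  expect_true(all(rc_all$p == 1))
  expect_error(response_curve(rep(1, 20), rep(c(TRUE, FALSE), 10),
                              breaks = c(0, 2)), "one bin")
})

test_that("a deterministic step is interpolated at its midpoint via the fallback", {
  dT <- c(1, 2, 4, 5)
  resp <- c(FALSE, FALSE, TRUE, TRUE)
  fit <- fit_dose_response(dT, resp, boot = 0, min_per_bin = 2)
  expect_identical(fit$method, "isotonic")
  expect_gt(fit$dtth, 2)
  expect_lt(fit$dtth, 4)
  expect_equal(fit$dtth, 3)
})

test_that("degenerate responder sets are rejected", {
  expect_error(fit_dose_response(1:10, rep(TRUE, 10), boot = 0), "outside")
  expect_error(fit_dose_response(1:10, rep(FALSE, 10), boot = 0), "outside")
})

test_that("logistic MLE recovers a generative midpoint from binary draws", {
  set.seed(42)
  dT <- runif(500, 0, 15)
  resp <- runif(500) < plogis((dT - 5.8) / 1)
  fit <- fit_dose_response(dT, resp, boot = 200, seed = 1)
  expect_identical(fit$method, "mle")
  expect_equal(fit$dtth, 5.8, tolerance = 0.5 / 5.8)
  expect_lt(fit$ci_low, fit$dtth)
  expect_gt(fit$ci_high, fit$dtth)
  # fitted curve crosses one half at the estimate (floor ~ 0)
  expect_equal(predict(fit, fit$dtth), 0.5, tolerance = 0.06)
  # fitted probability is non-decreasing
  p <- predict(fit, seq(0, 15, 0.1))
  expect_true(all(diff(p) >= -1e-12))
})

test_that("a fixed spontaneous floor is honoured by the fit", {
  set.seed(8)
  dT <- runif(600, 0, 12)
  resp <- runif(600) < (0.05 + 0.95 * plogis((dT - 6) / 1))
  fit <- fit_dose_response(dT, resp, boot = 0, floor = 0.05)
  expect_equal(fit$spont_floor, 0.05)
  expect_equal(fit$dtth, 6, tolerance = 0.5 / 6)
})

test_that("dose-response methods are consistent with the data", {
  set.seed(5)
  dT <- runif(300, 0, 10)
  resp <- runif(300) < plogis((dT - 4) / 1)
  fit <- fit_dose_response(dT, resp, boot = 0)
  expect_named(coef(fit), c("dtth", "logistic_width"))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_length(sims[[1]], 300)
  expect_equal(length(residuals(fit)), 300)
  expect_output(print(fit), "dT_th")
})

test_that("midpoint estimates are nearly unbiased across generative truths", {
  # full pipeline at n = 300 heated + 100 unheated, 36 degC conditions
  errs <- sapply(c(1.4, 4.3, 4.9, 5.8), function(truth) {
    mut <- mutant_params(name = "x", dtth_true = truth, resp_slope = 1,
                         burst_amp_mean = 2.5, burst_amp_sd = 0.8)
    # sample a range matched to the line's sensitivity, as in the experiments
    rng <- c(0, max(6, round(2.6 * truth)))
    sapply(1:20, function(s) {
      cfg <- sim_config(seed = 7000 + 37 * s, n_cells = 300, mutant = mut,
                        protocol = heat_protocol(T0 = 36))
      coh <- simulate_cohort(cfg, n_unheated = 100, deltaT_range = rng)
      rep <- run_pipeline(coh, cfg$protocol, boot = 0, seed = 1)
      rep$dose_response$dtth - truth
    })
  })
  expect_true(all(apply(abs(errs), 2, median) <= 0.3))
})

test_that("rank comparisons match convention on extreme cases", {
  set.seed(31)
  a <- rnorm(60)
  res <- compare_groups(a, a)
  expect_gt(res$p.value, 0.9)
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$U), 0)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("rank-test p-values match exhaustive enumeration for small samples", {
  # brute-force two-sided p by enumerating all group assignments
  exact_p <- function(a, b) {
    pooled <- c(a, b)
    n1 <- length(a)
    n <- length(pooled)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    m <- n1 * (n - n1) / 2
    mean(abs(us - m) >= abs(u_obs - m) - 1e-9)
  }
  set.seed(17)
  for (i in 1:8) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    a <- rnorm(n1)
    b <- rnorm(n2, 0.5)
    res <- compare_groups(a, b)
    expect_equal(res$p.value, exact_p(a, b), tolerance = 1e-12,
                 info = sprintf("case %d (n1=%d, n2=%d)", i, n1, n2))
  }
})
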