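make_scores <- function(n, T_, delta, noise = 0.3, seed = 1) {
  sim <- simulate_two_group_panel(n, 1, T_, delta = delta, f = 1,
                                  d = noise^2, seed = seed)
  df <- as.data.frame(sim$panel)
  data.frame(subject = df$subject, time = df$time, group = df$group,
             age = df$age, score = df$y1)
}

test_that("the slope contrast recovers the generating group difference", {
  # noiseless limit: random intercept/slope trajectories with a -0.12/year
  # group contrast and tiny residual noise
  set.seed(5)
  n <- 200
  subj <- sprintf("s%03d", 1:n)
  group <- rep(0:1, n / 2)
  age <- rnorm(n, 75, 7)
  sc <- do.call(rbind, lapply(1:n, function(i) {
    b0 <- rnorm(1, 0, 0.3)
    b1 <- -0.12 * group[i] + rnorm(1, 0, 0.05)
    data.frame(subject = subj[i], time = 0:3, group = group[i],
               age = age[i], score = b0 + b1 * (0:3) + rnorm(4, 0, 0.01))
  }))
  ans <- fit_slope_contrast(sc)
  expect_lt(abs(ans$estimate - (-0.12)), 0.025)
  expect_lt(ans$p_value, 1e-6)

  # scale equivariance: doubling every score leaves the test untouched
  sc2 <- sc
  sc2$score <- 2 * sc2$score
  ans2 <- fit_slope_contrast(sc2)
  expect_equal(ans2$estimate, 2 * ans$estimate, tolerance = 1e-6)
  expect_equal(ans2$p_value, ans$p_value, tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  sc <- make_scores(40, 3, delta = 0, seed = 6)
  expect_error(fit_slope_contrast(sc[sc$group == 1, ]), "both groups")
  one_visit <- sc[sc$time == 1, ]
  expect_error(fit_slope_contrast(one_visit), "two distinct visit times")
})

test_that("the interaction test holds its size under the null", {
  set.seed(7)
  B <- 250
  rej <- replicate(B, {
    sc <- make_scores(120, 4, delta = 0, noise = 0.5,
                      seed = sample.int(2^30, 1))
    fit_slope_contrast(sc)$p_value < 0.05
  })
  # 3 binomial SEs around alpha = 0.05 at B = 250: +/- 0.041
  expect_lt(abs(mean(rej) - 0.05), 0.042)
})

test_that("bootstrap power is calibrated at the null and ordered in n and model", {
  src <- simulate_two_group_panel(300, 4, 4, delta = -0.35, seed = 11)
  res <- bootstrap_power(src, sizes = c(60, 160), B = 60,
                         outcomes = c("dfm", "cfm"), seed = 12,
                         fit_args = list(tol = 1e-5, max_iter = 60L))
  expect_s3_class(res, "power_result")
  expect_true(all(res$power >= 0 & res$power <= 1))
  expect_equal(res$se, sqrt(res$power * (1 - res$power) / res$B))

  dfm_p <- res$power[res$outcome == "dfm"]
  # power grows with n (2 Monte-Carlo-SE slack)
  se2 <- 2 * sqrt(0.25 / 60)
  expect_gt(dfm_p[2], dfm_p[1] - se2)

  # null: rejection ~ alpha for the factor outcome
  src0 <- simulate_two_group_panel(200, 4, 4, delta = 0, seed = 13)
  res0 <- bootstrap_power(src0, sizes = 120, B = 80, outcomes = "dfm",
                          seed = 14,
                          fit_args = list(tol = 1e-5, max_iter = 60L))
  expect_lt(res0$power, 0.05 + 2 * sqrt(0.05 * 0.95 / 80) + 0.05)
})

test_that("factor outcomes outpower a single noisy indicator", {
  src <- simulate_two_group_panel(300, 4, 4, delta = -0.4, seed = 21)
  noisiest <- src$panel$variable_names[which.max(src$beta)]
  res <- bootstrap_power(src, sizes = 200, B = 50,
                         outcomes = c("dfm", noisiest), seed = 22,
                         fit_args = list(tol = 1e-5, max_iter = 60L))
  p_dfm <- res$power[res$outcome == "dfm"]
  p_raw <- res$power[res$outcome == noisiest]
  expect_gt(p_dfm, p_raw - 2 * sqrt(0.5 / 50))
})

test_that("sample-size inversion interpolates, flags boundaries, isotonises", {
  ans <- required_sample_size(c(100, 200), c(0.6, 1.0), target = 0.8)
  expect_equal(ans$n, 150)
  expect_false(ans$extrapolated)

  above <- required_sample_size(c(100, 200), c(0.85, 0.95), target = 0.8)
  expect_equal(above$n, 100)
  expect_true(above$at_boundary)

  # non-monotone curve: isotonic fit first, then invert
  iso <- required_sample_size(c(100, 150, 200), c(0.5, 0.45, 0.9),
                              target = 0.8)
  # brute-force oracle: PAVA pools the violating pair to 0.475, then the
  # crossing sits between 150 and 200 by linear interpolation
  expect_equal(iso$n, 150 + (0.8 - 0.475) / (0.9 - 0.475) * 50,
               tolerance = 1e-10)
  expect_true(iso$n > 150 && iso$n < 200)

  below <- required_sample_size(c(100, 200), c(0.3, 0.5), target = 0.8)
  expect_true(below$extrapolated)
  expect_equal(below$n, 350)
  expect_error(required_sample_size(100, 0.5), "two")
})
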