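params_for <- function(f, d) factor_model_params(f, d)

test_that("state innovation variances equal the raw visit gaps", {
  pr <- params_for(c(0.6, 0.4), c(0.3, 0.2))
  expect_equal(assemble_system(pr, c(0, 1, 2))$Q, c(1, 1))
  expect_equal(assemble_system(pr, c(0, 2))$Q, 2)
  expect_length(assemble_system(pr, 5)$Q, 0)
  expect_error(assemble_system(pr, c(1, 1)), "gap")
})

test_that("with vanishing noise the filtered and smoothed states track the data", {
  pr <- params_for(1, 1e-12)
  y <- matrix(c(0.3, -0.2, 1.1), ncol = 1)
  sys <- assemble_system(pr, c(1, 2, 3), init_policy("prior"))
  run <- kalman_filter(y, sys)
  expect_equal(run$filt_mean, as.numeric(y), tolerance = 1e-6)
  expect_equal(run$smooth_mean, as.numeric(y), tolerance = 1e-6)
})

test_that("filter log-likelihood equals the brute-force joint-Gaussian density", {
  # the fixed scalar case with unit gaps: Sigma_ts = min(t,s) + 1 + d 1{t=s}
  set.seed(21)
  y <- matrix(rnorm(3), ncol = 1)
  sys <- assemble_system(params_for(1, 0.5), c(1, 2, 3), init_policy("prior"))
  Sig <- outer(1:3, 1:3, pmin) + 1 + diag(0.5, 3)
  direct <- -0.5 * (3 * log(2 * pi) + determinant(Sig)$modulus[1] +
                      drop(t(y) %*% solve(Sig, y)))
  expect_equal(kalman_filter(y, sys)$loglik, direct, tolerance = 1e-10)

  # random instances with nTp <= 50, missing cells, unequal gaps
  for (case in 1:12) {
    set.seed(100 + case)
    n <- sample(1:3, 1); p <- sample(1:3, 1); T_ <- sample(1:4, 1)
    f <- runif(p, 0.2, 1); d <- runif(p, 0.05, 0.8)
    sim <- simulate_panel(n, p, T_, f = f, d = d,
                          spacing = "random")
    if (T_ * p >= 2) {
      v <- sim$panel$values[[1]]
      v[sample(length(v), 1)] <- NA
      sim$panel$values[[1]] <- v
    }
    got <- panel_loglik(params_for(f, d), sim$panel, init_policy("prior"))
    want <- mvn_loglik_panel(sim$panel, f, d)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("a gap of 2 inflates the one-step state variance by exactly 2", {
  pr <- params_for(1, 0.4)
  y <- matrix(c(0.5, 0.1), ncol = 1)
  run <- kalman_filter(y, assemble_system(pr, c(1, 3), init_policy("prior")))
  expect_equal(run$pred_var[2], run$filt_var[1] + 2)
})

test_that("missing cells are equivalent to deleting the variable at that visit", {
  set.seed(7)
  f <- c(0.5, 0.3, 0.2); d <- c(0.2, 0.4, 0.1)
  sim <- simulate_panel(1, 3, 4, f = f, d = d)
  y <- sim$panel$values[[1]]
  y[2, 3] <- NA
  run <- kalman_filter(y, assemble_system(params_for(f, d),
                                          sim$panel$times[[1]],
                                          init_policy("prior")))
  # oracle: same data with that row/column removed from f, d at that visit
  want <- mvn_loglik_subject(y, f, d, sim$panel$times[[1]])
  expect_equal(run$loglik, want, tolerance = 1e-10)
  # a fully missing visit contributes a time update only
  y2 <- y
  y2[2, ] <- NA
  run2 <- kalman_filter(y2, assemble_system(params_for(f, d),
                                            sim$panel$times[[1]],
                                            init_policy("prior")))
  expect_equal(run2$loglik,
               mvn_loglik_subject(y2, f, d, sim$panel$times[[1]]),
               tolerance = 1e-10)
  expect_equal(run2$pred_var[3], run2$filt_var[2] + diff(sim$panel$times[[1]])[2])
})

test_that("smoothed moments match the Gaussian-conditioning oracle", {
  set.seed(9)
  f <- c(0.7, 0.3); d <- c(0.3, 0.15)
  sim <- simulate_panel(1, 2, 3, f = f, d = d)
  y <- sim$panel$values[[1]]
  y[3, 1] <- NA
  sys <- assemble_system(params_for(f, d), sim$panel$times[[1]],
                         init_policy("prior"))
  run <- kalman_filter(y, sys)
  sm <- kalman_smoother(run, sys)
  want <- mvn_smooth_subject(y, f, d, sim$panel$times[[1]])
  expect_equal(sm$mean, want$mean, tolerance = 1e-8)
  expect_equal(sm$var, want$var, tolerance = 1e-8)
  # boundary identity and variance ordering
  expect_equal(sm$mean[3], run$filt_mean[3])
  expect_true(all(sm$var <= run$filt_var + 1e-12))
})

test_that("panel log-likelihood is additive over subjects and exchangeable", {
  sim <- random_small_panel(1, 2, 3, seed = 31)
  pr <- params_for(c(0.6, 0.4), c(0.25, 0.4))
  single <- panel_loglik(pr, sim$panel, init_policy("prior"))
  two <- panel_data(c("a", "b"), rep(sim$panel$times, 2),
                    rep(sim$panel$values, 2), sim$panel$variable_names)
  expect_equal(panel_loglik(pr, two, init_policy("prior")), 2 * single,
               tolerance = 1e-12)

  sim3 <- random_small_panel(3, 2, 3, seed = 32)
  perm <- panel_data(sim3$panel$subject_ids[c(3, 1, 2)],
                     sim3$panel$times[c(3, 1, 2)],
                     sim3$panel$values[c(3, 1, 2)],
                     sim3$panel$variable_names)
  expect_equal(panel_loglik(pr, sim3$panel, init_policy("prior")),
               panel_loglik(pr, perm, init_policy("prior")),
               tolerance = 1e-12)
})

test_that("the adjoint loading gradient matches central differences", {
  for (case in 1:6) {
    set.seed(800 + case)
    n <- sample(1:3, 1); p <- sample(1:4, 1); T_ <- sample(1:4, 1)
    sim <- simulate_panel(n, p, T_, spacing = "random")
    if (p * T_ >= 2) {
      v <- sim$panel$values[[1]]
      v[sample(length(v), 1)] <- NA
      sim$panel$values[[1]] <- v
    }
    f <- runif(p, 0.2, 1); d <- runif(p, 0.1, 0.8)
    st <- dfmpanel:::panel_stack(sim$panel, init_policy("prior"))
    got <- dfmpanel:::panel_loglik_grad_cpp(st$values, st$start0, st$len,
                                            st$tau, f, d, 0, 1)
    ll <- function(ff) dfmpanel:::panel_loglik_cpp(st$values, st$start0,
                                                   st$len, st$tau, ff, d,
                                                   0, 1)
    expect_equal(got$loglik, ll(f), tolerance = 1e-12)
    h <- 1e-6
    num <- vapply(seq_len(p), function(k) {
      e <- replace(numeric(p), k, h)
      (ll(f + e) - ll(f - e)) / (2 * h)
    }, 0)
    expect_equal(got$gradient, num, tolerance = 1e-5)
  }
})

test_that("rescaling the loadings alone changes the likelihood", {
  # the gap-pinned state innovation variance identifies the loading scale
  sim <- random_small_panel(3, 2, 4, seed = 41)
  f <- c(0.6, 0.4); d <- c(0.3, 0.2)
  l1 <- panel_loglik(params_for(f, d), sim$panel, init_policy("prior"))
  l2 <- panel_loglik(params_for(2 * f, d), sim$panel, init_policy("prior"))
  expect_gt(abs(l1 - l2), 1e-4)
})
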