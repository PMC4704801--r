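test_that("pooled second moments accumulate outer products and handle missingness", {
  panel <- panel_data("s1", list(c(1, 2)),
                      list(rbind(c(1, 0), c(0, 1))), c("y1", "y2"))
  psm <- pooled_second_moment(panel)
  expect_equal(psm$Cyy, diag(2), ignore_attr = TRUE)
  expect_equal(psm$N_obs, 2L)

  # law of large numbers against the generator: Cyy/N -> ff' + diag(d)
  f <- c(0.5, 0.3, 0.2); d <- c(0.3, 0.2, 0.4)
  sim <- simulate_panel(20000, 3, 1, f = f, d = d, seed = 77)
  psm <- pooled_second_moment(sim$panel)
  target <- tcrossprod(f) * 2 + diag(d)   # Var(u at visit 1) = 1 + 1 = 2
  # 3 Monte-Carlo SEs of a second-moment entry, roughly sqrt(Var(y_j y_k)/N)
  expect_lt(max(abs(psm$Cyy / psm$N_obs - target)), 3 * sqrt(8 / 20000))

  # all cells of one variable missing -> error naming the variable
  v <- sim$panel$values[1:5]
  v <- lapply(v, function(m) { m[, 2] <- NA; m })
  small <- panel_data(letters[1:5], sim$panel$times[1:5], v,
                      c("y1", "y2", "y3"))
  expect_error(pooled_second_moment(small), "y2")
})

test_that("cycle-1 update is stationary at an exactly factor-structured moment", {
  f <- c(0.6, 0.3, 0.4); d <- c(0.2, 0.5, 0.3)
  N <- 50
  st <- ecme_state(f, d, N * (tcrossprod(f) + diag(d)), N)
  up <- cycle1_update(st)
  expect_equal(up$loadings_half, f, tolerance = 1e-10)
  expect_equal(up$variances, d, tolerance = 1e-10)
})

test_that("cycle-1 handles the null-loading degenerate case", {
  Cyy <- matrix(c(3, 1, 1, 2), 2)
  st <- ecme_state(c(0, 0), c(1, 1), Cyy, 10)
  expect_equal(st$gamma, c(0, 0))
  expect_equal(st$omega, 1)
  up <- cycle1_update(st)
  expect_equal(up$loadings_half, c(0, 0))
  expect_equal(up$variances, diag(Cyy) / 10)
})

test_that("cycle-1 matches a line-by-line matrix-algebra oracle", {
  f <- c(0.6, 0.4); d <- c(0.3, 0.2)
  Cyy <- matrix(c(5.2, 2.1, 2.1, 3.4), 2)
  N <- 7
  # independent route: explicit matrix inverses, no Sherman-Morrison
  gam <- solve(tcrossprod(f) + diag(d)) %*% f
  ome <- diag(1) - t(gam) %*% f
  Bh <- Cyy %*% gam %*% solve(t(gam) %*% Cyy %*% gam + N * ome)
  Dn <- diag(Cyy - Cyy %*% gam %*% t(Bh)) / N
  st <- ecme_state(f, d, Cyy, N)
  expect_equal(st$gamma, drop(gam), tolerance = 1e-12)
  expect_equal(st$omega, drop(ome), tolerance = 1e-12)
  up <- cycle1_update(st)
  expect_equal(up$loadings_half, drop(Bh), tolerance = 1e-12)
  expect_equal(up$variances, pmax(Dn, 1e-6), tolerance = 1e-12)
})

test_that("cycle-2 matches a 1-D grid search and never degrades the likelihood", {
  sim <- random_small_panel(6, 1, 4, seed = 55)
  d_fix <- 0.3
  f_hat <- cycle2_update(sim$panel, d_fix, f_start = 0.5,
                         init = init_policy("prior"))
  ll <- function(f) panel_loglik(factor_model_params(f, d_fix), sim$panel,
                                 init_policy("prior"))
  # golden-section-style brute force on a fine grid
  grid <- seq(0.01, 3, by = 0.001)
  f_grid <- grid[which.max(vapply(grid, ll, 0))]
  expect_equal(f_hat, f_grid, tolerance = 2e-3)

  # monotonicity contract on a random battery
  for (k in 1:20) {
    set.seed(600 + k)
    simk <- simulate_panel(3, 2, 3)
    d0 <- runif(2, 0.1, 1); f0 <- runif(2, -0.5, 1)
    f1 <- cycle2_update(simk$panel, d0, f0, init_policy("prior"))
    l0 <- panel_loglik(factor_model_params(f0, d0), simk$panel,
                       init_policy("prior"))
    l1 <- panel_loglik(factor_model_params(f1, d0), simk$panel,
                       init_policy("prior"))
    expect_gte(l1, l0 - 1e-8)
  }
})

test_that("ECME recovers the generating loadings on a large panel", {
  sim <- simulate_panel(300, 5, 15, seed = 2024)
  fit <- suppressWarnings(fit_dfm(sim$panel, init_state = init_policy("prior")))
  f_hat <- fit$loadings * sign(sum(fit$loadings * sim$loadings))
  expect_lt(max(abs(f_hat - sim$loadings)), 0.05)
})

test_that("the ECME log-likelihood trace never decreases", {
  for (k in 1:50) {
    set.seed(7000 + k)
    n <- sample(3:8, 1); p <- sample(2:4, 1); T_ <- sample(2:5, 1)
    sim <- simulate_panel(n, p, T_)
    fit <- tryCatch(
      suppressWarnings(fit_dfm(sim$panel, init_state = init_policy("prior"),
                               max_iter = 40L)),
      error = function(e) NULL)
    if (!is.null(fit))
      expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("converged ECME matches direct maximisation of the exact likelihood", {
  sim <- random_small_panel(3, 2, 3, seed = 404)
  fit <- suppressWarnings(fit_dfm(sim$panel, init_state = init_policy("prior"),
                                  tol = 1e-10))
  # independent route: joint numeric maximisation of the brute-force stacked
  # Gaussian likelihood over (f, log d)
  obj <- function(th) {
    f <- th[1:2]; d <- exp(th[3:4])
    -mvn_loglik_panel(sim$panel, f, d)
  }
  direct <- optim(c(0.5, 0.5, log(0.5), log(0.5)), obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
  expect_lte(fit$loglik, -direct$value + 1e-4)
  expect_gte(fit$loglik, -direct$value - 1e-4)
})

test_that("identical subjects receive identical smoothed score series", {
  sim <- random_small_panel(1, 3, 4, seed = 17)
  two <- panel_data(c("a", "b"), rep(sim$panel$times, 2),
                    rep(sim$panel$values, 2), sim$panel$variable_names)
  fit <- suppressWarnings(fit_dfm(two, init_state = init_policy("prior")))
  sc <- split(fit$scores$score, fit$scores$subject)
  expect_equal(sc$a, sc$b, tolerance = 1e-12)
})

test_that("sign convention makes fits agree from different starts", {
  sim <- simulate_panel(40, 3, 5, seed = 88)
  f1 <- suppressWarnings(fit_dfm(sim$panel, init_state = init_policy("prior")))
  init2 <- factor_model_params(c(-0.8, -0.1, -0.4), c(0.5, 0.5, 0.5))
  f2 <- suppressWarnings(fit_dfm(sim$panel, init = init2,
                                 init_state = init_policy("prior")))
  expect_gt(sum(f1$loadings), 0)
  expect_gt(sum(f2$loadings), 0)
  expect_equal(f1$loadings, f2$loadings, tolerance = 0.02)
})

test_that("non-dynamic EM agrees with the dynamic fit when the factor is i.i.d.", {
  # data generated from the static model: u fresh N(0,1) at every visit
  set.seed(99)
  n <- 400; p <- 4; T_ <- 5
  f <- c(0.45, 0.3, 0.15, 0.35); d <- c(0.3, 0.25, 0.4, 0.2)
  values <- lapply(seq_len(n), function(i) {
    u <- rnorm(T_)
    tcrossprod(u, f) + matrix(rnorm(T_ * p, 0, rep(sqrt(d), each = T_)), T_, p)
  })
  panel <- panel_data(sprintf("s%03d", 1:n), rep(list(1:T_), n), values,
                      paste0("y", 1:p))
  cfm <- suppressWarnings(fit_cfm(panel))
  expect_equal(cfm$loadings, f, tolerance = 0.06)
  expect_equal(cfm$variances, d, tolerance = 0.08)
})

test_that("the variance floor guards Heywood collapse on rank-1 moments", {
  f <- c(1, 0.5)
  Cyy <- 20 * tcrossprod(f)       # singular: no idiosyncratic noise at all
  st <- ecme_state(f, c(0.2, 0.2), Cyy, 20)
  up <- cycle1_update(st)
  expect_true(all(up$variances >= 1e-6))
})

test_that("regression scores reduce to the perfect indicator in the noiseless limit", {
  sim <- random_small_panel(4, 3, 3, seed = 5)
  fit <- suppressWarnings(fit_cfm(sim$panel))
  fit$loadings <- c(1, 0, 0)
  fit$variances <- c(1e-10, 1, 1)
  sc <- extract_scores(fit, sim$panel)
  y1 <- do.call(rbind, sim$panel$values)[, 1]
  expect_equal(sc$score, y1, tolerance = 1e-6)
})

test_that("score tables align with the panel and reflect each model's information set", {
  sim <- random_small_panel(5, 3, 4, seed = 66)
  dfm <- suppressWarnings(fit_dfm(sim$panel, init_state = init_policy("prior")))
  cfm <- suppressWarnings(fit_cfm(sim$panel))
  long <- as.data.frame(sim$panel)
  expect_equal(nrow(dfm$scores), nrow(long))
  expect_equal(dfm$scores$subject, long$subject)
  expect_equal(cfm$scores$time, long$time)

  # perturb the last visit of subject 1: smoothed scores at earlier visits
  # move (they use the future), regression scores do not
  pert <- sim$panel
  pert$values[[1]][4, ] <- pert$values[[1]][4, ] + 5
  d2 <- extract_scores(dfm, pert)
  c2 <- extract_scores(cfm, pert)
  expect_gt(abs(d2$score[1] - dfm$scores$score[1]), 1e-8)
  expect_equal(c2$score[1:3], cfm$scores$score[1:3], tolerance = 1e-12)

  # conditioning on data cannot inflate variance above the prior state var
  ini <- init_policy("prior")
  st <- dfmpanel:::panel_stack(sim$panel, ini)
  run <- dfmpanel:::kalman_panel_cpp(st$values, st$start0, st$len, st$tau,
                                     dfm$loadings, dfm$variances, 0, 1)
  expect_true(all(dfm$scores$score_var <= run$pred_var + 1e-12))
})
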