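#' Pooled second-moment matrix of a panel
#'
#' Accumulates the outer products of the visit observation vectors over all
#' subjects and visits.  Missing cells are handled by pairwise-complete
#' accumulation: each entry is scaled by `N / n_jk`, where `n_jk` counts the
#' visits at which both variables were observed, so that every entry refers
#' to the common pooled count `N` (the total number of visit rows).  The
#' result is symmetrized.
#'
#' @param panel a [panel_data] object, standardized (mean approximately 0
#'   per variable) so that second moments approximate covariances.
#' @return A list with `Cyy` (p x p) and `N_obs` (the pooled visit count).
#' @export
pooled_second_moment <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  V <- do.call(rbind, panel$values)
  M <- !is.na(V)
  none <- colSums(M) == 0L
  if (any(none))
    stop("all cells missing for variable '",
         panel$variable_names[which(none)[1L]], "'")
  V0 <- V
  V0[!M] <- 0
  S <- crossprod(V0)
  cnt <- crossprod(M * 1)
  if (any(cnt == 0)) {
    ij <- which(cnt == 0, arr.ind = TRUE)[1L, ]
    stop("no joint observations for variables '",
         panel$variable_names[ij[1L]], "' and '",
         panel$variable_names[ij[2L]], "'")
  }
  N <- nrow(V)
  Cyy <- N * S / cnt
  list(Cyy = (Cyy + t(Cyy)) / 2, N_obs = N)
}

#' ECME parameter state
#'
#' Bundles the current parameter partition and the cycle-1 sufficient
#' statistics: the free elements of `D` (`variances`) and of `B`
#' (`loadings`), the regression-weight vector `gamma = (ff' + diag d)^{-1} f`
#' used to score the factor cross-sectionally, the residual factor variance
#' `omega = 1 - gamma' f`, and the pooled second-moment matrix.
#'
#' @param loadings,variances current parameter values (length `p`).
#' @param Cyy pooled second-moment matrix from [pooled_second_moment()].
#' @param N_obs pooled count of observation vectors.
#' @return A list of class `ecme_state`.
#' @export
ecme_state <- function(loadings, variances, Cyy, N_obs) {
  f <- as.numeric(loadings)
  d <- as.numeric(variances)
  stopifnot(length(f) == length(d), all(d > 0),
            is.matrix(Cyy), nrow(Cyy) == length(f))
  g <- (f / d) / (1 + sum(f^2 / d))   # Sherman-Morrison form of (ff'+D)^-1 f
  structure(list(loadings = f, variances = d, gamma = g,
                 omega = 1 - sum(g * f), Cyy = Cyy, N_obs = N_obs),
            class = "ecme_state")
}

variance_floor <- 1e-6

#' Cycle-1 closed-form EM update
#'
#' The Rubin–Thayer factor-analysis EM update of the loadings and
#' idiosyncratic variances from the pooled second moments, treating the
#' factor cross-sectionally as `N(0, 1)`: with `gamma` and `omega` from the
#' current parameter point,
#' `B_half = Cyy gamma (gamma' Cyy gamma + N omega)^{-1}` and
#' `D_new = N^{-1} diag(Cyy - Cyy gamma B_half')`, with the variance update
#' floored at a small positive bound to guard against Heywood cases.
#'
#' @param state an [ecme_state].
#' @return A list with `loadings_half` (intermediate loadings) and
#'   `variances` (updated `d`).
#' @export
cycle1_update <- function(state) {
  stopifnot(inherits(state, "ecme_state"))
  g <- state$gamma
  Cg <- drop(state$Cyy %*% g)
  denom <- sum(g * Cg) + state$N_obs * state$omega
  if (!is.finite(denom) || denom <= 0)
    stop("singular cycle-1 system (gamma' Cyy gamma + N omega = ",
         format(denom), ")")
  B_half <- Cg / denom
  D_new <- pmax((diag(state$Cyy) - Cg * B_half) / state$N_obs,
                variance_floor)
  list(loadings_half = B_half, variances = D_new)
}

#' Cycle-2 likelihood maximisation over the loadings
#'
#' Maximises the exact Kalman prediction-error log-likelihood of the panel
#' over the `p` shared loadings jointly, holding the idiosyncratic variances
#' fixed, by quasi-Newton (BFGS) search with numerical gradients started at
#' `f_start`.  The returned point never degrades the likelihood relative to
#' the start (beyond `1e-8`): if the search fails to improve, the start (or
#' the best point found) is returned; if the optimiser errors on a restart
#' as well, an error carrying the best point found is raised.
#'
#' @param panel a [panel_data] object.
#' @param d_fixed positive idiosyncratic variances (held fixed).
#' @param f_start starting loadings.
#' @param init an [init_policy] for the latent state prior.
#' @param maxit maximum BFGS iterations per call.
#' @return The maximising loading vector.
#' @export
cycle2_update <- function(panel, d_fixed, f_start, init = init_policy(),
                          maxit = 40L) {
  stopifnot(all(d_fixed > 0), all(is.finite(f_start)))
  st <- panel_stack(panel, init)
  negll <- function(f)
    -panel_loglik_cpp(st$values, st$start0, st$len, st$tau,
                      f, d_fixed, st$init_mean, st$init_var)
  neggr <- function(f)
    -panel_loglik_grad_cpp(st$values, st$start0, st$len, st$tau,
                           f, d_fixed, st$init_mean, st$init_var)$gradient
  v0 <- negll(f_start)
  best <- list(par = f_start, value = v0)
  run1 <- tryCatch(
    stats::optim(f_start, negll, neggr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) NULL)
  if (!is.null(run1) && is.finite(run1$value) && run1$value < best$value)
    best <- run1
  if (is.null(run1)) {
    # restart from a mildly perturbed point before giving up
    run2 <- tryCatch(
      stats::optim(0.9 * f_start + 0.01, negll, neggr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(run2)) {
      cond <- simpleError("cycle-2 optimiser failed after restart")
      cond$best <- best$par
      stop(cond)
    }
    if (is.finite(run2$value) && run2$value < best$value) best <- run2
  }
  best$par
}

# Principal-axis starting values.  The leading eigenvector is taken on the
# correlation scale and rescaled, so a noisy variable with a large marginal
# variance cannot hijack the starting direction.
principal_axis_start <- function(Cyy, N_obs) {
  S <- Cyy / N_obs
  sdev <- sqrt(pmax(diag(S), variance_floor))
  R <- stats::cov2cor(S + diag(variance_floor, nrow(S)))
  e <- eigen(R, symmetric = TRUE)
  f0 <- e$vectors[, 1L] * sqrt(max(e$values[1L], variance_floor)) * sdev
  if (sum(f0) < 0) f0 <- -f0
  d0 <- pmax(diag(S) - f0^2, 1e-3)
  list(loadings = f0, variances = d0)
}

# Conditional maximisation of the actual Kalman likelihood over the
# idiosyncratic variances (log scale), loadings fixed: the "either" move of
# the ECME family, used when the closed-form cycle-1 variance update stops
# increasing the dynamic likelihood.
cm_step_variances <- function(panel, f_fixed, d_start,
                              init = init_policy(), maxit = 40L) {
  st <- panel_stack(panel, init)
  negll <- function(ld)
    -panel_loglik_cpp(st$values, st$start0, st$len, st$tau,
                      f_fixed, pmax(exp(ld), variance_floor),
                      st$init_mean, st$init_var)
  run <- tryCatch(
    stats::optim(log(d_start), negll, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(run) || !is.finite(run$value) ||
      run$value > negll(log(d_start)))
    return(d_start)
  pmax(exp(run$par), variance_floor)
}

check_fit_pre <- function(panel) {
  if (n_subjects(panel) < 2L) stop("at least 2 subjects required")
  if (sum(n_visits(panel)) < n_variables(panel))
    stop("fewer total visits than variables")
}

new_dfm_fit <- function(model, f, d, panel, scores, ll, trace, iter,
                        converged, settings) {
  f <- unname(f)
  d <- unname(d)
  structure(list(model = model, loadings = f, variances = d,
                 variable_names = panel$variable_names, scores = scores,
                 loglik = ll, loglik_trace = trace, iterations = iter,
                 converged = converged, settings = settings),
            class = "dfm_fit")
}

#' @export
print.dfm_fit <- function(x, ...) {
  cat(toupper(x$model), " fit: p = ", length(x$loadings),
      ", log-likelihood = ", format(x$loglik, digits = 8),
      ", iterations = ", x$iterations,
      ", converged = ", x$converged, "\n", sep = "")
  cat("loadings: ", paste(signif(x$loadings, 4), collapse = " "), "\n")
  cat("variances:", paste(signif(x$variances, 4), collapse = " "), "\n")
  invisible(x)
}

#' Fit the dynamic factor model by the two-cycle ECME algorithm
#'
#' Each iteration runs the closed-form cycle-1 update ([cycle1_update]) of
#' the idiosyncratic variances (with an intermediate loading estimate) and
#' then the cycle-2 maximisation ([cycle2_update]) of the exact Kalman
#' likelihood over the shared loadings.  Cycle 2 is started from the better
#' of the previous loadings and the intermediate cycle-1 loadings under the
#' freshly updated variances, so the recorded panel log-likelihood ascends.
#' Iteration stops when the relative log-likelihood change falls below
#' `tol` or after `max_iter` iterations.  The sign convention `sum(f) > 0`
#' is applied to the final fit, and factor scores are the fixed-interval
#' smoothed state means at the final parameters.
#'
#' @param panel a standardized (or mean-zero) [panel_data] with at least two
#'   subjects and at least `p` total visits.
#' @param init optional [factor_model_params] starting point; by default a
#'   principal-axis start from the pooled second moments.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum ECME iterations.
#' @param init_state an [init_policy] for the latent state prior: diffuse by
#'   default; use `init_policy("prior")` when the data-generating prior
#'   `N(0, 1)` at time 0 is known, as in simulation studies.  Note that the
#'   proper diffuse proxy adds a per-subject `log(1 + kappa f' D^-1 f)`
#'   term at the first visit that shrinks the loadings of weakly
#'   informative panels; prefer the matched prior whenever the latent scale
#'   at entry is known.
#' @param cycle2_maxit BFGS iteration cap inside each cycle 2.
#' @return A `dfm_fit` object: final loadings and variances, per-visit
#'   smoothed factor scores with variances, log-likelihood trace, iteration
#'   count, convergence flag and settings.
#' @export
fit_dfm <- function(panel, init = NULL, tol = 1e-6, max_iter = 200L,
                    init_state = init_policy(), cycle2_maxit = 40L) {
  stopifnot(inherits(panel, "panel_data"))
  check_fit_pre(panel)
  psm <- pooled_second_moment(panel)
  if (is.null(init)) {
    start <- principal_axis_start(psm$Cyy, psm$N_obs)
  } else {
    stopifnot(inherits(init, "factor_model_params"))
    start <- list(loadings = init$loadings,
                  variances = pmax(init$variances, variance_floor))
  }
  f <- start$loadings
  d <- start$variances
  st <- panel_stack(panel, init_state)
  pl <- function(f, d)
    panel_loglik_cpp(st$values, st$start0, st$len, st$tau, f, d,
                     st$init_mean, st$init_var)
  ll <- pl(f, d)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    c1 <- cycle1_update(ecme_state(f, d, psm$Cyy, psm$N_obs))
    d_new <- c1$variances
    # start cycle 2 from the better of the two candidate loading vectors
    ll_prev_f <- pl(f, d_new)
    ll_half <- pl(c1$loadings_half, d_new)
    f_start <- if (ll_half > ll_prev_f) c1$loadings_half else f
    f_new <- cycle2_update(panel, d_new, f_start, init_state,
                           maxit = cycle2_maxit)
    ll_new <- pl(f_new, d_new)
    if (ll_new < ll) {
      # never step downhill: when the closed-form variance update costs
      # actual likelihood, keep the previous point and let the
      # convergence branch below decide how to proceed
      f_new <- f
      d_new <- d
      ll_new <- ll
    }
    rel <- abs(ll_new - ll) / (abs(ll) + .Machine$double.eps)
    if (rel < tol) {
      # apparent convergence of the two-cycle map; the closed-form
      # variance update targets the observation-equation likelihood, so it
      # can be stationary short of the dynamic MLE.  Take the "either"
      # move of the ECME family: conditionally maximise the actual
      # likelihood over the variances, then re-fit the loadings.
      d_alt <- cm_step_variances(panel, f_new, d_new, init_state)
      f_alt <- cycle2_update(panel, d_alt, f_new, init_state,
                             maxit = cycle2_maxit)
      ll_alt <- pl(f_alt, d_alt)
      if (ll_alt > ll_new &&
          (ll_alt - ll_new) / (abs(ll_new) + .Machine$double.eps) >= tol) {
        f <- f_alt
        d <- d_alt
        ll <- ll_alt
        trace <- c(trace, ll)
        next
      }
      if (ll_alt >= ll_new) {
        f_new <- f_alt
        d_new <- d_alt
        ll_new <- ll_alt
      }
      f <- f_new
      d <- d_new
      ll <- ll_new
      trace <- c(trace, ll)
      converged <- TRUE
      break
    }
    f <- f_new
    d <- d_new
    ll <- ll_new
    trace <- c(trace, ll)
  }
  if (!converged)
    warning("ECME did not converge in ", max_iter, " iterations")
  if (sum(f) < 0) f <- -f
  sm <- kalman_panel_cpp(st$values, st$start0, st$len, st$tau, f, d,
                         st$init_mean, st$init_var)
  long <- as.data.frame(panel)[c("subject", "time")]
  scores <- cbind(long, score = sm$smooth_mean, score_var = sm$smooth_var)
  settings <- list(tol = tol, max_iter = max_iter,
                   init_state = unclass(init_state),
                   cycle2_maxit = cycle2_maxit)
  new_dfm_fit("dfm", f, d, panel, scores, ll, trace, iter, converged,
              settings)
}

#' Fit the non-dynamic (confirmatory) factor model
#'
#' The comparator defined solely by the observation equation: the factor is
#' treated as i.i.d. `N(0, 1)` across visits, so only the closed-form
#' cycle-1 updates are iterated, to convergence of the implied-covariance
#' Gaussian likelihood (classical factor-analysis EM).  Factor scores are
#' cross-sectional regression scores `gamma' y`, computed visit by visit on
#' the observed components.
#'
#' @inheritParams fit_dfm
#' @return A `dfm_fit` object with `model = "cfm"`.
#' @export
fit_cfm <- function(panel, init = NULL, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(panel, "panel_data"))
  check_fit_pre(panel)
  psm <- pooled_second_moment(panel)
  if (is.null(init)) {
    start <- principal_axis_start(psm$Cyy, psm$N_obs)
  } else {
    stopifnot(inherits(init, "factor_model_params"))
    start <- list(loadings = init$loadings,
                  variances = pmax(init$variances, variance_floor))
  }
  f <- start$loadings
  d <- start$variances
  V <- do.call(rbind, panel$values)
  ll <- cfm_loglik_cpp(V, f, d)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    c1 <- cycle1_update(ecme_state(f, d, psm$Cyy, psm$N_obs))
    f <- c1$loadings_half
    d <- c1$variances
    ll_new <- cfm_loglik_cpp(V, f, d)
    rel <- abs(ll_new - ll) / (abs(ll) + .Machine$double.eps)
    ll <- ll_new
    trace <- c(trace, ll)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("factor-analysis EM did not converge in ", max_iter,
            " iterations")
  if (sum(f) < 0) f <- -f
  sc <- cfm_scores_cpp(V, f, d)
  long <- as.data.frame(panel)[c("subject", "time")]
  scores <- cbind(long, score = sc[, 1L], score_var = sc[, 2L])
  settings <- list(tol = tol, max_iter = max_iter)
  new_dfm_fit("cfm", f, d, panel, scores, ll, trace, iter, converged,
              settings)
}

#' Extract factor scores aligned with a panel
#'
#' Returns one row per observed subject-visit.  For a dynamic fit the scores
#' are fixed-interval smoothed state means (they condition on the whole
#' series, including future visits); for the non-dynamic fit they are
#' cross-sectional regression scores that use the concurrent visit only.
#'
#' @param fit a `dfm_fit`.
#' @param panel optionally, a [panel_data] to score with the fitted
#'   parameters (defaults to the scores stored at fit time).
#' @return A data frame with columns `subject`, `time`, `score`,
#'   `score_var`.
#' @export
extract_scores <- function(fit, panel = NULL) {
  stopifnot(inherits(fit, "dfm_fit"))
  if (is.null(panel)) return(fit$scores)
  stopifnot(inherits(panel, "panel_data"))
  long <- as.data.frame(panel)[c("subject", "time")]
  if (fit$model == "dfm") {
    ini <- do.call(init_policy, fit$settings$init_state[
      intersect(names(fit$settings$init_state),
                c("type", "mean", "var", "time", "kappa"))])
    st <- panel_stack(panel, ini)
    sm <- kalman_panel_cpp(st$values, st$start0, st$len, st$tau,
                           fit$loadings, fit$variances,
                           st$init_mean, st$init_var)
    cbind(long, score = sm$smooth_mean, score_var = sm$smooth_var)
  } else {
    V <- do.call(rbind, panel$values)
    sc <- cfm_scores_cpp(V, fit$loadings, fit$variances)
    cbind(long, score = sc[, 1L], score_var = sc[, 2L])
  }
}
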