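#' Shared-loading one-factor model parameters
#'
#' Parameters of the random-walk dynamic factor model: a loading vector of
#' length `p` shared by every subject (so factor scores are comparable across
#' subjects) and strictly positive idiosyncratic variances, one per measure.
#' A single latent factor per subject (`q = 1`) is assumed throughout.
#'
#' @param loadings numeric vector `f` of length `p`.
#' @param variances numeric vector `d` of length `p`, all `> 0`.
#' @return An object of class `factor_model_params`.
#' @export
factor_model_params <- function(loadings, variances) {
  loadings <- as.numeric(loadings)
  variances <- as.numeric(variances)
  if (length(loadings) != length(variances))
    stop("'loadings' and 'variances' must have the same length")
  if (any(!is.finite(loadings))) stop("non-finite loading")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("idiosyncratic variances must be strictly positive")
  structure(list(loadings = loadings, variances = variances, q = 1L),
            class = "factor_model_params")
}

#' @export
print.factor_model_params <- function(x, ...) {
  cat("factor_model_params (q = 1, p = ", length(x$loadings), ")\n",
      sep = "")
  cat("loadings: ", paste(signif(x$loadings, 4), collapse = " "), "\n")
  cat("variances:", paste(signif(x$variances, 4), collapse = " "), "\n")
  invisible(x)
}

#' Initial-state policy for the latent random walk
#'
#' The likelihood needs a prior for the latent state.  Two policies are
#' supported: `"diffuse"` (the default for data analysis) places a
#' large-variance proper prior `N(0, kappa)` directly at the first visit;
#' `"prior"` places a proper `N(mean, var)` prior at a stated time origin,
#' so the state variance at the first visit is `var + (t1 - time)` by
#' random-walk accumulation.  The latter matches simulation designs in which
#' the latent path starts as `N(0, 1)` at time 0.
#'
#' @param type `"diffuse"` or `"prior"`.
#' @param mean prior state mean (default 0).
#' @param var prior state variance at the origin (default 1; ignored for
#'   `"diffuse"`).
#' @param time time point at which the prior applies (default 0; ignored for
#'   `"diffuse"`).
#' @param kappa variance of the diffuse proxy prior (default `1e7`).
#' @return A list of class `init_policy`.
#' @export
init_policy <- function(type = c("diffuse", "prior"), mean = 0, var = 1,
                        time = 0, kappa = 1e7) {
  type <- match.arg(type)
  structure(list(type = type, mean = mean, var = var, time = time,
                 kappa = kappa),
            class = "init_policy")
}

# initial gap (prior -> first visit) and prior variance for one subject
init_for_times <- function(init, times) {
  if (init$type == "diffuse")
    list(tau0 = 0, mean = init$mean, var = init$kappa)
  else {
    tau0 <- times[1L] - init$time
    if (tau0 < 0)
      stop("first visit time ", times[1L],
           " precedes the prior time origin ", init$time)
    list(tau0 = tau0, mean = init$mean, var = init$var)
  }
}

#' Assemble the per-subject state-space system
#'
#' Builds the scalar-state system for one subject: observation equation
#' `y_t = f u_t + e_t`, `e_t ~ N(0, diag(d))`; transition `u_{t+tau} = u_t +
#' eta`, `eta ~ N(0, tau)` with `tau` the raw elapsed time between visits
#' (state innovation variance is pinned to the visit gap, which is what
#' identifies the scale of the loadings).
#'
#' @param params a [factor_model_params] object.
#' @param times strictly increasing numeric visit times for the subject.
#' @param init an [init_policy] (default diffuse).
#' @return A list of class `subject_system` with elements `f`, `d`, `Q` (the
#'   between-visit gaps, length `length(times) - 1`), `tau` (initial gap plus
#'   `Q`), `init_mean`, `init_var`, `times`.
#' @export
assemble_system <- function(params, times, init = init_policy()) {
  stopifnot(inherits(params, "factor_model_params"))
  times <- as.numeric(times)
  if (length(times) < 1L) stop("at least one visit required")
  gaps <- diff(times)
  if (any(gaps <= 0)) stop("nonpositive gap between visits")
  ini <- init_for_times(init, times)
  structure(list(f = params$loadings, d = params$variances,
                 Q = gaps, tau = c(ini$tau0, gaps),
                 init_mean = ini$mean, init_var = ini$var,
                 times = times),
            class = "subject_system")
}

#' Kalman filter for one subject
#'
#' Runs the forward recursions for a single subject under the random-walk
#' one-factor model, restricting each measurement update to the non-missing
#' components of the visit (a fully missing visit contributes a time update
#' only), and returns the innovations, their covariances, the
#' filtered/smoothed state moments and the exact Gaussian log-likelihood of
#' the observed components by prediction-error decomposition.
#'
#' @param y numeric matrix (visits x p) of observations, `NA` = missing.
#' @param system a `subject_system` from [assemble_system()].
#' @return A list of class `kalman_run` with elements `loglik`,
#'   `innovations` (visits x p, `NA` at missing cells), `F` (list of
#'   innovation covariance matrices on the observed subspace),
#'   `std_innovations` (innovations scaled by `sqrt(diag(F_t))`),
#'   `pred_mean`, `pred_var`, `filt_mean`, `filt_var`, `smooth_mean`,
#'   `smooth_var`, `times`.
#' @export
kalman_filter <- function(y, system) {
  stopifnot(inherits(system, "subject_system"))
  y <- rbind(y)
  T_ <- nrow(y)
  if (T_ != length(system$times))
    stop("observation matrix has ", T_, " rows but the system has ",
         length(system$times), " visits")
  if (ncol(y) != length(system$f))
    stop("observation matrix has ", ncol(y), " columns but p = ",
         length(system$f))
  res <- kalman_panel_cpp(y, 0L, T_, system$tau, system$f, system$d,
                          system$init_mean, system$init_var)
  if (!is.finite(res$loglik))
    stop("non-finite log-likelihood in the Kalman filter")
  innov <- y - tcrossprod(res$pred_mean, system$f)
  Fts <- lapply(seq_len(T_), function(t) {
    obs <- which(!is.na(y[t, ]))
    fo <- system$f[obs]
    res$pred_var[t] * tcrossprod(fo) + diag(system$d[obs],
                                            nrow = length(obs))
  })
  structure(list(loglik = res$loglik, innovations = innov, F = Fts,
                 std_innovations = res$std_innov,
                 pred_mean = res$pred_mean, pred_var = res$pred_var,
                 filt_mean = res$filt_mean, filt_var = res$filt_var,
                 smooth_mean = res$smooth_mean, smooth_var = res$smooth_var,
                 times = system$times),
            class = "kalman_run")
}

#' Fixed-interval smoother
#'
#' Returns the Rauch–Tung–Striebel smoothed state means and variances from a
#' completed filter pass.  The smoothed variance never exceeds the filtered
#' variance, and at the last visit the two coincide.
#'
#' @param run a `kalman_run` from [kalman_filter()].
#' @param system the matching `subject_system` (unused; kept for a uniform
#'   signature).
#' @return A data frame with columns `time`, `mean`, `var`.
#' @export
kalman_smoother <- function(run, system = NULL) {
  stopifnot(inherits(run, "kalman_run"))
  data.frame(time = run$times, mean = run$smooth_mean,
             var = run$smooth_var)
}

# stack a panel into the flat arrays the C++ recursions consume
panel_stack <- function(panel, init = init_policy()) {
  nv <- vapply(panel$times, length, 0L)
  values <- do.call(rbind, panel$values)
  tau <- numeric(sum(nv))
  start0 <- cumsum(c(0L, nv[-length(nv)]))
  init_var <- NA_real_
  for (i in seq_along(panel$times)) {
    ti <- panel$times[[i]]
    ini <- init_for_times(init, ti)
    tau[(start0[i] + 1L):(start0[i] + nv[i])] <- c(ini$tau0, diff(ti))
    init_var <- ini$var  # same variance for every subject under both policies
  }
  list(values = values, start0 = as.integer(start0), len = as.integer(nv),
       tau = tau, init_mean = init$mean %||% 0, init_var = init_var)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Panel log-likelihood
#'
#' Exact Gaussian log-likelihood of a whole panel under the random-walk
#' one-factor model: subjects are independent, so the value is the sum of the
#' per-subject Kalman prediction-error decompositions.
#'
#' @param params a [factor_model_params] object.
#' @param panel a [panel_data] object.
#' @param init an [init_policy].
#' @return A single finite number.
#' @export
panel_loglik <- function(params, panel, init = init_policy()) {
  stopifnot(inherits(params, "factor_model_params"),
            inherits(panel, "panel_data"))
  st <- panel_stack(panel, init)
  ll <- panel_loglik_cpp(st$values, st$start0, st$len, st$tau,
                         params$loadings, params$variances,
                         st$init_mean, st$init_var)
  if (!is.finite(ll)) {
    bad <- which(!is.finite(vapply(seq_along(st$start0), function(i)
      panel_loglik_cpp(st$values,
                       st$start0[i], st$len[i], st$tau,
                       params$loadings, params$variances,
                       st$init_mean, st$init_var), 0)))
    stop("non-finite log-likelihood for subject ",
         paste(panel$subject_ids[bad], collapse = ", "))
  }
  ll
}
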