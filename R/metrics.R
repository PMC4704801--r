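#' Trace statistic for latent-path recovery
#'
#' The multivariate R-squared of the regression of the true latent paths on
#' the estimated ones.  With a single factor per subject the true and
#' estimated paths are stacked over all subjects and visits into vectors
#' `u` and `uh`, and the statistic reduces to the squared uncentred
#' correlation `(u' uh)^2 / ((uh' uh)(u' u))`.  It lies in `[0, 1]`, equals
#' 1 when `uh` is any non-zero multiple of `u`, and is invariant to the
#' sign/scale indeterminacy of factor estimates.  By convention the value
#' is 0 when `uh` is identically zero.
#'
#' @param u_true numeric vector of true latent values (stacked
#'   subject-visits).
#' @param u_hat numeric vector of estimated latent values on the same
#'   support.
#' @return A single number in `[0, 1]`.
#' @export
trace_statistic <- function(u_true, u_hat) {
  u <- as.numeric(u_true)
  uh <- as.numeric(u_hat)
  if (length(u) != length(uh))
    stop("true and estimated paths differ in length")
  uu <- sum(u^2)
  if (uu == 0) stop("true latent path has zero norm")
  hh <- sum(uh^2)
  if (hh == 0) return(0)
  sum(u * uh)^2 / (hh * uu)
}

#' Ratio of two trace statistics
#'
#' Comparison measure of the dynamic versus the non-dynamic estimator:
#' values above 1 mean the dynamic model recovers the latent paths better.
#'
#' @param tr_dfm trace statistic of the dynamic factor model.
#' @param tr_cfm trace statistic of the non-dynamic comparator (`> 0`).
#' @return `tr_dfm / tr_cfm`.
#' @export
trace_ratio <- function(tr_dfm, tr_cfm) {
  if (any(tr_cfm <= 0)) stop("non-positive comparator trace statistic")
  tr_dfm / tr_cfm
}

#' Residual diagnostics of one-step prediction errors
#'
#' Computes, on filter-standardised innovations, a skewness/kurtosis
#' normality statistic (Bowman–Shenton, chi-squared with 2 df) and a lag-1
#' portmanteau autocorrelation statistic (Box–Ljung, chi-squared with 1
#' df), with p-values.  The input is either one pooled series or a list of
#' series (e.g. one per subject); lag-1 products are then accumulated
#' within series only, so subject boundaries do not contaminate the
#' autocorrelation.
#'
#' @param innovations numeric vector, or list of numeric vectors, of
#'   standardised one-step prediction errors (`NA`s dropped); at least 8
#'   values in total.
#' @return A list with elements `normality` and `autocorrelation`, each a
#'   list `(statistic, df, p_value)`, plus `n`, the pooled count.
#' @export
residual_diagnostics <- function(innovations) {
  if (!is.list(innovations)) innovations <- list(innovations)
  series <- lapply(innovations, function(x) as.numeric(x[!is.na(x)]))
  x <- unlist(series, use.names = FALSE)
  n <- length(x)
  if (n < 8L) stop("need at least 8 standardised innovations, got ", n)
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  skew <- mean(xc^3) / m2^1.5
  kurt <- mean(xc^4) / m2^2
  bs <- n * (skew^2 / 6 + (kurt - 3)^2 / 24)
  # lag-1 autocorrelation accumulated within series
  num <- sum(vapply(series, function(s) {
    if (length(s) < 2L) return(0)
    sum((s[-length(s)] - m) * (s[-1L] - m))
  }, 0))
  r1 <- num / sum(xc^2)
  bl <- n * (n + 2) * r1^2 / (n - 1)
  list(normality = list(statistic = bs, df = 2L,
                        p_value = stats::pchisq(bs, 2L, lower.tail = FALSE)),
       autocorrelation = list(statistic = bl, df = 1L, r1 = r1,
                              p_value = stats::pchisq(bl, 1L,
                                                      lower.tail = FALSE)),
       n = n)
}

#' Residual diagnostics for a fitted factor model
#'
#' Extracts standardised one-step prediction errors from a fit (for the
#' dynamic model, Kalman innovations divided by the square root of the
#' diagonal of their covariance; for the non-dynamic model, observations
#' standardised by the implied marginal standard deviation) and applies
#' [residual_diagnostics()] per variable and pooled.
#'
#' @param fit a `dfm_fit`.
#' @param panel the [panel_data] the fit refers to.
#' @return A data frame with one row per variable plus a pooled `"all"`
#'   row: normality and lag-1 portmanteau statistics and p-values.
#' @export
diagnose_fit <- function(fit, panel) {
  stopifnot(inherits(fit, "dfm_fit"), inherits(panel, "panel_data"))
  p <- length(fit$loadings)
  if (fit$model == "dfm") {
    ini <- do.call(init_policy, fit$settings$init_state[
      intersect(names(fit$settings$init_state),
                c("type", "mean", "var", "time", "kappa"))])
    st <- panel_stack(panel, ini)
    run <- kalman_panel_cpp(st$values, st$start0, st$len, st$tau,
                            fit$loadings, fit$variances,
                            st$init_mean, st$init_var)
    E <- run$std_innov
  } else {
    V <- do.call(rbind, panel$values)
    E <- sweep(V, 2L, sqrt(fit$loadings^2 + fit$variances), "/")
  }
  nv <- n_visits(panel)
  split_series <- function(col) {
    lapply(split(col, rep(seq_along(nv), nv)), identity)
  }
  one <- function(series, label) {
    dg <- residual_diagnostics(series)
    data.frame(variable = label, n = dg$n,
               normality_stat = dg$normality$statistic,
               normality_p = dg$normality$p_value,
               portmanteau_stat = dg$autocorrelation$statistic,
               portmanteau_p = dg$autocorrelation$p_value)
  }
  rows <- lapply(seq_len(p), function(k)
    one(split_series(E[, k]), fit$variable_names[k]))
  pooled <- one(unlist(lapply(seq_len(p), function(k)
    split_series(E[, k])), recursive = FALSE), "all")
  out <- do.call(rbind, c(rows, list(pooled)))
  rownames(out) <- NULL
  out
}
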