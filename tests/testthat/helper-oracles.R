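# Brute-force oracles, independent of the package's Kalman recursions.

# Joint covariance of the stacked observation vector of ONE subject under the
# random-walk one-factor model with prior N(mean, var) at `init_time`:
# cov(u_t, u_s) = init_var + min(t, s) - init_time, and
# Sigma = K (x) f f' + I_T (x) diag(d), stacked visit-major.
subject_joint_cov <- function(f, d, times, init_var = 1, init_time = 0) {
  K <- outer(times, times, pmin) - init_time + init_var
  D <- rep(d, length(times))
  kronecker(K, tcrossprod(f)) + diag(D, nrow = length(D))
}

# Direct multivariate-normal log-density of one subject's observations
# (NA cells dropped), via base linear algebra only.
mvn_loglik_subject <- function(y, f, d, times, init_var = 1, init_time = 0) {
  Sig <- subject_joint_cov(f, d, times, init_var, init_time)
  yv <- as.vector(t(y))     # visit-major stacking to match the kronecker
  obs <- !is.na(yv)
  S <- Sig[obs, obs, drop = FALSE]
  yo <- yv[obs]
  ch <- chol(S)
  -0.5 * (length(yo) * log(2 * pi)) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, yo, transpose = TRUE)^2)
}

# Conditional mean/variance of the latent path given the observations, by
# Gaussian conditioning on the joint covariance.
mvn_smooth_subject <- function(y, f, d, times, init_var = 1, init_time = 0) {
  K <- outer(times, times, pmin) - init_time + init_var
  Sig_uy <- kronecker(K, t(f))
  Sig_y <- subject_joint_cov(f, d, times, init_var, init_time)
  yv <- as.vector(t(y))
  obs <- !is.na(yv)
  A <- solve(Sig_y[obs, obs, drop = FALSE])
  mean <- drop(Sig_uy[, obs, drop = FALSE] %*% (A %*% yv[obs]))
  V <- K - Sig_uy[, obs, drop = FALSE] %*% A %*% t(Sig_uy[, obs, drop = FALSE])
  list(mean = mean, var = diag(V))
}

# Panel log-likelihood by summing per-subject brute-force densities.
mvn_loglik_panel <- function(panel, f, d, init_var = 1, init_time = 0) {
  sum(vapply(seq_along(panel$subject_ids), function(i)
    mvn_loglik_subject(panel$values[[i]], f, d, panel$times[[i]],
                       init_var, init_time), 0))
}

# Small long-format panel data frame -> temporary CSV file.
write_temp_panel_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

random_small_panel <- function(n, p, T_, seed, missing_frac = 0) {
  sim <- simulate_panel(n, p, T_, seed = seed)
  if (missing_frac > 0) {
    for (i in seq_len(n)) {
      v <- sim$panel$values[[i]]
      drop <- stats::runif(length(v)) < missing_frac
      # never blank out a subject's entire first visit row in tiny cases
      v[drop] <- NA
      if (all(is.na(v[1, ]))) v[1, 1] <- sim$panel$values[[i]][1, 1]
      sim$panel$values[[i]] <- v
    }
  }
  sim
}
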