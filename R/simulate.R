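#' Draw a shared loading vector
#'
#' Loadings are drawn i.i.d. `U(0, 1)` and rescaled to sum exactly to 1,
#' the normalisation under which estimated factors are comparable across
#' replicates of the Monte Carlo design.
#'
#' @param p number of observed variables.
#' @return A numeric vector of length `p`, all entries positive, summing
#'   to 1.
#' @export
draw_loadings <- function(p) {
  stopifnot(p >= 1L)
  f <- stats::runif(p)
  f / sum(f)
}

#' Draw idiosyncratic variances tied to noise fractions
#'
#' For each variable the noise fraction `beta_k` — the ratio of the
#' idiosyncratic variance to the total variance of the observed variable —
#' is drawn `Uniform(0.1, 0.9)` (the interval avoids the boundary of the
#' parameter space) and the idiosyncratic variance is set to
#' `d_k = f_k * beta_k / (1 - beta_k)`.
#'
#' @param f loading vector from [draw_loadings()].
#' @return A list with `variances` (`d`) and `beta`.
#' @export
draw_idio_variances <- function(f) {
  stopifnot(all(f > 0))
  beta <- stats::runif(length(f), 0.1, 0.9)
  list(variances = f * beta / (1 - beta), beta = beta)
}

sim_gaps <- function(T_, spacing, gaps) {
  switch(spacing,
         unit = rep(1, T_),
         fixed = {
           stopifnot(length(gaps) == T_, all(gaps > 0))
           gaps
         },
         random = sample(c(0.5, 1, 1.5, 2), T_, replace = TRUE))
}

#' Simulate a panel from the random-walk one-factor design
#'
#' Per subject: `u_0 ~ N(0, 1)` at time 0, `u_{j} = u_{j-1} + N(delta *
#' tau_j, tau_j)` over each visit gap `tau_j`, and `y_j = f u_j +
#' N(0, diag(d))`.  Defaults draw `f` and `d` fresh from [draw_loadings()]
#' and [draw_idio_variances()]; pass them explicitly to fix the truth
#' (including `d = 0` for noiseless checks).
#'
#' @param n number of subjects (>= 2).
#' @param p number of observed variables.
#' @param T_ number of visits per subject (>= 2 in the grid designs; 1 is
#'   permitted).
#' @param f,d optional true loadings and idiosyncratic variances (`d >= 0`
#'   allowed here; estimation requires `d > 0`).
#' @param spacing `"unit"` (annual visits at times 1..T), `"fixed"` (supply
#'   `gaps`), or `"random"` (gaps drawn from \{0.5, 1, 1.5, 2\}, per subject).
#' @param gaps gap vector for `spacing = "fixed"`, length `T_` (first entry
#'   is the time of the first visit).
#' @param drift deterministic latent drift per year (default 0).
#' @param seed optional integer seed; the panel is deterministic given it.
#' @return An object of class `simulated_panel`: a list with `panel`
#'   ([panel_data]), true `loadings`, `variances`, `beta` (or `NULL` when
#'   `d` was supplied), `latent` (long data frame `subject`, `time`, `u`),
#'   and `seed`.
#' @export
simulate_panel <- function(n, p, T_, f = NULL, d = NULL,
                           spacing = c("unit", "fixed", "random"),
                           gaps = NULL, drift = 0, seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(n >= 1L, p >= 1L, T_ >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(f)) f <- draw_loadings(p)
  beta <- NULL
  if (is.null(d)) {
    dv <- draw_idio_variances(f)
    d <- dv$variances
    beta <- dv$beta
  }
  stopifnot(length(f) == p, length(d) == p, all(d >= 0))
  ids <- sprintf("s%0*d", nchar(n), seq_len(n))
  times <- vector("list", n)
  values <- vector("list", n)
  u_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- sim_gaps(T_, spacing, gaps)
    ti <- cumsum(g)
    u <- cumsum(c(stats::rnorm(1), stats::rnorm(T_, drift * g, sqrt(g))))[-1L]
    e <- matrix(stats::rnorm(T_ * p, 0, rep(sqrt(d), each = T_)), T_, p)
    times[[i]] <- ti
    values[[i]] <- tcrossprod(u, f) + e
    u_list[[i]] <- u
  }
  panel <- panel_data(ids, times, values, paste0("y", seq_len(p)))
  latent <- data.frame(subject = rep(ids, each = T_),
                       time = unlist(times),
                       u = unlist(u_list))
  structure(list(panel = panel, loadings = f, variances = d, beta = beta,
                 latent = latent, seed = seed),
            class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat("simulated_panel (seed ", x$seed %||% "unset", ")\n", sep = "")
  print(x$panel)
  invisible(x)
}

#' Simulate a two-group matched panel with a latent slope contrast
#'
#' A synthetic stand-in for matched case-control cognitive-decline cohorts:
#' `n/2` matched pairs, each pair sharing a baseline age draw, with one
#' member per group.  Group-1 subjects receive a deterministic drift
#' `delta` per year on their latent increments, so `delta` is the true
#' group difference in the annual rate of latent change; groups are
#' otherwise identically distributed.
#'
#' @param n total number of subjects (even).
#' @param p,T_,f,d,spacing,gaps,seed as in [simulate_panel()].
#' @param delta latent slope difference (group 1 minus group 0), per year.
#' @param age_mean,age_sd distribution of the matched baseline-age
#'   covariate (defaults reflect an elderly cohort).
#' @return A `simulated_panel` whose panel carries `group` (0/1), a `pair`
#'   covariate identifying the matched pairs, and baseline `age`.
#' @export
simulate_two_group_panel <- function(n, p, T_, delta, f = NULL, d = NULL,
                                     spacing = c("unit", "fixed", "random"),
                                     gaps = NULL, seed = NULL,
                                     age_mean = 75.7, age_sd = 7.5) {
  spacing <- match.arg(spacing)
  if (n %% 2L != 0L) stop("'n' must be even for matched pairs")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(f)) f <- draw_loadings(p)
  beta <- NULL
  if (is.null(d)) {
    dv <- draw_idio_variances(f)
    d <- dv$variances
    beta <- dv$beta
  }
  npair <- n %/% 2L
  age_pair <- stats::rnorm(npair, age_mean, age_sd)
  ids <- character(n)
  times <- vector("list", n)
  values <- vector("list", n)
  u_list <- vector("list", n)
  group <- integer(n)
  pair <- integer(n)
  age <- numeric(n)
  i <- 0L
  for (k in seq_len(npair)) {
    for (g in 0:1) {
      i <- i + 1L
      gp <- sim_gaps(T_, spacing, gaps)
      ti <- cumsum(gp)
      dr <- if (g == 1L) delta else 0
      u <- cumsum(c(stats::rnorm(1),
                    stats::rnorm(T_, dr * gp, sqrt(gp))))[-1L]
      e <- matrix(stats::rnorm(T_ * p, 0, rep(sqrt(d), each = T_)), T_, p)
      ids[i] <- sprintf("pair%0*d_g%d", nchar(npair), k, g)
      times[[i]] <- ti
      values[[i]] <- tcrossprod(u, f) + e
      u_list[[i]] <- u
      group[i] <- g
      pair[i] <- k
      age[i] <- age_pair[k]
    }
  }
  panel <- panel_data(ids, times, values, paste0("y", seq_len(p)),
                      group = group,
                      covariates = data.frame(age = age, pair = pair))
  latent <- data.frame(subject = rep(ids, vapply(times, length, 0L)),
                       time = unlist(times),
                       u = unlist(u_list))
  structure(list(panel = panel, loadings = f, variances = d, beta = beta,
                 latent = latent, delta = delta, seed = seed),
            class = "simulated_panel")
}
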