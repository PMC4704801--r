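#' Mixed-model slope contrast between groups
#'
#' Fits a linear mixed model to longitudinal scores with fixed effects for
#' time since first visit, group, their interaction and baseline age, and
#' correlated random intercepts and slopes per subject.  The quantity of
#' interest is the time-by-group interaction: the group difference in
#' annual rate of change.  Its p-value uses the normal reference for the
#' Wald statistic.  If the correlated-random-effects fit fails to converge
#' or is singular, a documented fallback with independent random effects is
#' used.
#'
#' @param scores data frame with columns `subject`, `time`, `group` (0/1),
#'   `age`, and `score`.
#' @return A list with `estimate`, `se`, `p_value`, `statistic` and
#'   `random_effects` (`"correlated"` or `"independent"`).
#' @export
fit_slope_contrast <- function(scores) {
  need <- c("subject", "time", "group", "age", "score")
  if (!all(need %in% names(scores)))
    stop("'scores' must have columns ", paste(need, collapse = ", "))
  df <- scores
  if (length(unique(df$group)) < 2L)
    stop("both groups must be present")
  if (length(unique(df$time)) < 2L)
    stop("at least two distinct visit times required")
  # time since first visit, per subject
  t0 <- tapply(df$time, df$subject, min)
  df$time <- df$time - t0[as.character(df$subject)]
  df$group <- as.numeric(df$group)

  fit_one <- function(formula) {
    withCallingHandlers(
      lme4::lmer(formula, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4))),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
  }
  used <- "correlated"
  fit <- tryCatch(fit_one(score ~ time * group + age + (1 + time | subject)),
                  error = function(e) NULL)
  bad <- is.null(fit) ||
    length(fit@optinfo$conv$lme4$messages) > 0 || lme4::isSingular(fit)
  if (bad) {
    used <- "independent"
    fit2 <- tryCatch(
      fit_one(score ~ time * group + age + (1 + time || subject)),
      error = function(e) NULL)
    if (!is.null(fit2)) fit <- fit2
    if (is.null(fit)) stop("mixed-model fit failed for both random-effects ",
                           "structures")
  }
  cf <- summary(fit)$coefficients
  if (!"time:group" %in% rownames(cf))
    stop("degenerate design: interaction not estimable")
  est <- cf["time:group", "Estimate"]
  se <- cf["time:group", "Std. Error"]
  z <- est / se
  list(estimate = est, se = se, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)), random_effects = used)
}

# resample n/2 pairs with replacement from a matched two-group source panel
resample_pairs <- function(source_panel, n_half) {
  panel <- source_panel$panel
  pair <- panel$covariates$pair
  if (is.null(pair)) stop("source panel has no 'pair' covariate")
  pick <- sample(unique(pair), n_half, replace = TRUE)
  idx <- unlist(lapply(seq_along(pick), function(j) which(pair == pick[j])))
  copy <- rep(seq_along(pick), each = 2L)
  # every bootstrap copy of a pair is its own matched pair
  panel_data(sprintf("b%04d_%s", copy, panel$subject_ids[idx]),
             panel$times[idx], panel$values[idx], panel$variable_names,
             group = panel$group[idx],
             covariates = data.frame(age = panel$covariates$age[idx],
                                     pair = copy))
}

#' Bootstrap power analysis on a matched two-group panel
#'
#' Implements the matched-pair bootstrap: for each candidate total sample
#' size `n`, repeat `B` times \{resample `n/2` matched pairs with
#' replacement; re-estimate the factor models on the resampled panel;
#' extract factor scores; fit the mixed-model slope contrast for each
#' outcome; record whether the time-by-group interaction is significant at
#' level `alpha`\}.  Power is the rejection proportion.  Factor models are
#' refit on every resample; resamples on which a fit fails count as
#' non-rejections (conservative) and are tallied.
#'
#' @param source a `simulated_panel` from [simulate_two_group_panel()] (or
#'   any panel carrying `group`, `age` and `pair`).
#' @param sizes integer vector of total sample sizes (each even).
#' @param B bootstrap replicates per size (default 1000).
#' @param alpha significance level (default 0.05).
#' @param outcomes character vector drawn from `"dfm"`, `"cfm"` and raw
#'   variable names.
#' @param seed optional integer seed.
#' @param fit_args list of extra arguments passed to [fit_dfm()] /
#'   [fit_cfm()] (e.g. `tol`).
#' @return A data frame of class `power_result`: one row per outcome and
#'   size, with `power`, Monte Carlo `se = sqrt(p(1-p)/B)`, `B` and the
#'   count of fit `failures`.
#' @export
bootstrap_power <- function(source, sizes, B = 1000L, alpha = 0.05,
                            outcomes = c("dfm", "cfm"), seed = NULL,
                            fit_args = list()) {
  stopifnot(inherits(source, "simulated_panel"), all(sizes %% 2L == 0L),
            alpha > 0, alpha < 1, B >= 1L)
  vars <- source$panel$variable_names
  unknown <- setdiff(outcomes, c("dfm", "cfm", vars))
  if (length(unknown))
    stop("unknown outcomes: ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  # the resampled panels come from the random-walk generator, so the
  # dynamic fits use the generator-matching latent prior by default; a
  # large proper diffuse proxy would shrink the loadings of weakly
  # informative resamples toward zero
  if (is.null(fit_args$init_state))
    fit_args$init_state <- init_policy("prior")
  res <- list()
  for (n in sizes) {
    rej <- stats::setNames(numeric(length(outcomes)), outcomes)
    fails <- stats::setNames(integer(length(outcomes)), outcomes)
    for (b in seq_len(B)) {
      bp <- resample_pairs(source, n %/% 2L)
      meta <- as.data.frame(bp)[c("subject", "time", "group", "age")]
      std <- standardize_panel(bp)$panel
      score_tabs <- list()
      for (oc in outcomes) {
        tab <- tryCatch({
          if (oc == "dfm") {
            fit <- do.call(fit_dfm, c(list(std), fit_args))
            cbind(meta, score = fit$scores$score)
          } else if (oc == "cfm") {
            fit <- do.call(fit_cfm, c(list(std),
                                      fit_args[intersect(names(fit_args),
                                        c("tol", "max_iter", "init"))]))
            cbind(meta, score = fit$scores$score)
          } else {
            v <- do.call(rbind, std$values)[, oc]
            cbind(meta, score = v)
          }
        }, error = function(e) NULL, warning = function(w) NULL)
        if (is.null(tab)) {
          fails[oc] <- fails[oc] + 1L
          next
        }
        ans <- tryCatch(fit_slope_contrast(tab), error = function(e) NULL)
        if (is.null(ans) || !is.finite(ans$p_value)) {
          fails[oc] <- fails[oc] + 1L
        } else if (ans$p_value < alpha) {
          rej[oc] <- rej[oc] + 1
        }
      }
    }
    for (oc in outcomes) {
      ph <- rej[oc] / B
      res[[length(res) + 1L]] <-
        data.frame(outcome = oc, n = n, power = ph,
                   se = sqrt(ph * (1 - ph) / B), B = B,
                   failures = fails[oc])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("power_result", class(out))
  out
}

#' Required sample size from a power curve
#'
#' Inverts a power curve at a target power.  The curve is first
#' regularised to be non-decreasing by isotonic regression (pool-adjacent
#' violators) and then inverted by linear interpolation; values beyond the
#' grid are linearly extrapolated from the last two distinct points and
#' flagged.
#'
#' @param sizes sample sizes of the grid (>= 2 points).
#' @param power estimated power at each size.
#' @param target target power (default 0.8).
#' @return A list with `n` (the required size, possibly fractional),
#'   `extrapolated` (logical), `at_boundary` (logical: every grid point
#'   already meets the target) and `curve` (the isotonic-regularised
#'   curve).
#' @export
required_sample_size <- function(sizes, power, target = 0.8) {
  if (length(sizes) < 2L || length(sizes) != length(power))
    stop("need at least two (size, power) points")
  o <- order(sizes)
  sizes <- sizes[o]
  power <- power[o]
  iso <- stats::isoreg(sizes, power)$yf
  curve <- data.frame(n = sizes, power = iso)
  if (iso[1L] >= target)
    return(list(n = sizes[1L], extrapolated = FALSE, at_boundary = TRUE,
                curve = curve))
  if (max(iso) < target) {
    keep <- !duplicated(iso, fromLast = TRUE)
    xs <- sizes[keep]
    ys <- iso[keep]
    if (length(xs) < 2L || ys[length(ys)] <= ys[length(ys) - 1L])
      return(list(n = Inf, extrapolated = TRUE, at_boundary = FALSE,
                  curve = curve))
    k <- length(xs)
    slope <- (ys[k] - ys[k - 1L]) / (xs[k] - xs[k - 1L])
    return(list(n = xs[k] + (target - ys[k]) / slope, extrapolated = TRUE,
                at_boundary = FALSE, curve = curve))
  }
  j <- which(iso >= target)[1L]
  n_star <- if (iso[j] == target || j == 1L) sizes[j] else
    sizes[j - 1L] + (target - iso[j - 1L]) / (iso[j] - iso[j - 1L]) *
      (sizes[j] - sizes[j - 1L])
  list(n = n_star, extrapolated = FALSE, at_boundary = FALSE, curve = curve)
}
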