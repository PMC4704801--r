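#' Replicate sub-seed derivation
#'
#' Deterministic sub-seed for replicate `r` of grid cell `cell` under a
#' master seed, so that any cell/replicate is independently reproducible.
#' Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param cell integer cell index.
#' @param r replicate index.
#' @return An integer seed.
#' @export
sub_seed <- function(seed, cell, r) {
  as.integer((as.numeric(seed) * 1000003 + cell * 10007 + r * 97) %%
               2147483629 + 1)
}

run_one_replicate <- function(n, p, T_, subseed, tol, max_iter) {
  sim <- simulate_panel(n, p, T_, seed = subseed)
  # simulated panels are mean-zero by construction, so they are fitted on
  # their raw scale; centring by the sample grand mean would shift the
  # estimated latent paths and bias the uncentred trace statistic at small n
  dfm <- fit_dfm(sim$panel, tol = tol, max_iter = max_iter,
                 init_state = init_policy("prior"))
  cfm <- fit_cfm(sim$panel, tol = tol, max_iter = max_iter)
  tr_d <- trace_statistic(sim$latent$u, dfm$scores$score)
  tr_c <- trace_statistic(sim$latent$u, cfm$scores$score)
  c(tr_dfm = tr_d, tr_cfm = tr_c, ratio = trace_ratio(tr_d, tr_c))
}

#' Run the Monte Carlo recovery grid
#'
#' For each `(n, p, T)` cell, generates `replicates` fresh panels (fresh
#' loadings and noise fractions each replicate), fits the dynamic and the
#' non-dynamic factor model on the same draws (paired design), computes
#' both trace statistics and their per-replicate ratio, and averages
#' across replicates.  The whole run is deterministic given `seed` (see
#' [sub_seed()]).  Replicates on which a fit fails are dropped and
#' counted, never imputed.
#'
#' @param cells data frame with columns `n`, `p`, `T` (one row per cell).
#' @param replicates Monte Carlo replicates per cell.
#' @param seed master seed.
#' @param tol,max_iter estimation settings passed to the fitters.
#' @param verbose print one line per finished cell.
#' @return A data frame of class `grid_result` with, per cell: replicate
#'   and failure counts, mean and Monte Carlo SE of the dynamic and
#'   non-dynamic trace statistics, the mean per-replicate ratio with SE,
#'   and the ratio of means (both averaging conventions are reported).
#' @export
run_grid <- function(cells, replicates = 200L, seed = 1L, tol = 1e-6,
                     max_iter = 200L, verbose = FALSE) {
  cells <- as.data.frame(cells)
  names(cells)[names(cells) == "T_"] <- "T"
  stopifnot(all(c("n", "p", "T") %in% names(cells)), replicates >= 1L)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; p <- cells$p[ci]; T_ <- cells$T[ci]
    vals <- matrix(NA_real_, replicates, 3L)
    fails <- 0L
    for (r in seq_len(replicates)) {
      rec <- tryCatch(
        suppressWarnings(run_one_replicate(n, p, T_, sub_seed(seed, ci, r),
                                           tol, max_iter)),
        error = function(e) NULL)
      if (is.null(rec)) fails <- fails + 1L else vals[r, ] <- rec
    }
    ok <- stats::complete.cases(vals)
    m <- colMeans(vals[ok, , drop = FALSE])
    se <- apply(vals[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
    out[[ci]] <- data.frame(
      n = n, p = p, T = T_, replicates = sum(ok), failures = fails,
      mean_tr_dfm = m[1L], se_tr_dfm = se[1L],
      mean_tr_cfm = m[2L], se_tr_cfm = se[2L],
      mean_ratio = m[3L], se_ratio = se[3L],
      ratio_of_means = m[1L] / m[2L])
    if (verbose)
      message(sprintf("cell n=%d p=%d T=%d: TR_DFM=%.3f ratio=%.3f (%d ok)",
                      n, p, T_, m[1L], m[3L], sum(ok)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("grid_result", class(res))
  res
}

#' Render grid results in the classic layout
#'
#' Lays out a [run_grid()] result with one row per `(n, p)` combination
#' and, for each `T`, a pair of columns: the mean dynamic trace statistic
#' and the mean dynamic/non-dynamic ratio, formatted to two decimals.
#'
#' @param results a `grid_result` data frame.
#' @return A character data frame (the formatted table); its `"text"`
#'   attribute holds a printable text rendering.
#' @export
render_table <- function(results) {
  stopifnot(nrow(results) >= 1L)
  Ts <- sort(unique(results$T))
  combos <- unique(results[c("n", "p")])
  combos <- combos[order(combos$n, combos$p), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    row <- data.frame(n = combos$n[i], p = combos$p[i])
    for (tt in Ts) {
      hit <- results[results$n == combos$n[i] & results$p == combos$p[i] &
                       results$T == tt, ]
      row[[paste0("TR_DFM.T", tt)]] <-
        fmt(if (nrow(hit)) hit$mean_tr_dfm[1L] else NA)
      row[[paste0("ratio.T", tt)]] <-
        fmt(if (nrow(hit)) hit$mean_ratio[1L] else NA)
    }
    row
  })
  tab <- do.call(rbind, rows)
  attr(tab, "text") <- paste(utils::capture.output(print(tab,
                                                         row.names = FALSE)),
                             collapse = "\n")
  tab
}
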