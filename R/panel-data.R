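#' Longitudinal panel data
#'
#' A `panel_data` object stores a multivariate longitudinal panel: for each
#' subject, a strictly increasing sequence of visit times (in years) and a
#' visit-by-variable matrix of continuous measures in which any cell may be
#' missing (`NA`).  Storage is per subject (ragged), which matches unequal
#' visit counts naturally; the stacked form used in state-space notation is
#' recovered on demand.
#'
#' @param subject_ids character vector of unique subject labels.
#' @param times list (one element per subject) of strictly increasing numeric
#'   visit times.
#' @param values list of numeric matrices, one per subject, with one row per
#'   visit and one column per measured variable; `NA` marks a missing cell.
#' @param variable_names character vector naming the `p` measures.
#' @param group optional vector (one element per subject) of binary group
#'   labels (0/1).
#' @param covariates optional data frame of per-subject scalars (e.g. baseline
#'   age), one row per subject.
#'
#' @return An object of class `panel_data`.
#' @seealso [read_panel()], [standardize_panel()], [as.data.frame.panel_data()]
#' @export
panel_data <- function(subject_ids, times, values, variable_names,
                       group = NULL, covariates = NULL) {
  subject_ids <- as.character(subject_ids)
  stopifnot(is.list(times), is.list(values))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (length(times) != length(subject_ids) ||
      length(values) != length(subject_ids))
    stop("'times' and 'values' must have one element per subject")
  p <- length(variable_names)
  for (i in seq_along(subject_ids)) {
    ti <- times[[i]]
    vi <- values[[i]]
    if (length(ti) < 1L)
      stop("subject ", subject_ids[i], " has no visits")
    if (any(!is.finite(ti)))
      stop("subject ", subject_ids[i], " has non-finite visit times")
    if (length(ti) > 1L && any(diff(ti) <= 0))
      stop("visit times not strictly increasing for subject ",
           subject_ids[i])
    if (!is.matrix(vi) || nrow(vi) != length(ti) || ncol(vi) != p)
      stop("value matrix for subject ", subject_ids[i],
           " must be ", length(ti), " x ", p)
    values[[i]] <- matrix(as.numeric(vi), nrow = nrow(vi),
                          dimnames = list(NULL, variable_names))
  }
  if (!is.null(group)) {
    if (length(group) != length(subject_ids))
      stop("'group' must have one element per subject")
    group <- as.integer(group)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(subject_ids))
      stop("'covariates' must have one row per subject")
  }
  structure(list(subject_ids = subject_ids,
                 times = times,
                 values = values,
                 variable_names = as.character(variable_names),
                 group = group,
                 covariates = covariates),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  nv <- vapply(x$times, length, 0L)
  cat("panel_data: ", length(x$subject_ids), " subjects, ",
      length(x$variable_names), " variables, ",
      sum(nv), " visits (", min(nv), "-", max(nv), " per subject)\n",
      sep = "")
  miss <- sum(vapply(x$values, function(v) sum(is.na(v)), 0))
  cat("missing cells: ", miss, "\n", sep = "")
  if (!is.null(x$group))
    cat("groups: ", paste(names(table(x$group)), table(x$group),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of subjects / variables / visits in a panel
#' @param panel a [panel_data] object.
#' @return `n_subjects`: integer; `n_variables`: integer; `n_visits`: integer
#'   vector per subject.
#' @export
n_subjects <- function(panel) length(panel$subject_ids)

#' @rdname n_subjects
#' @export
n_variables <- function(panel) length(panel$variable_names)

#' @rdname n_subjects
#' @export
n_visits <- function(panel) vapply(panel$times, length, 0L)

#' Convert a panel to long format
#'
#' @param x a [panel_data] object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame with columns `subject`, `time`, optional `group` and
#'   covariates, and one column per measure; missing cells are `NA`.
#' @export
as.data.frame.panel_data <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  nv <- vapply(x$times, length, 0L)
  df <- data.frame(subject = rep(x$subject_ids, nv),
                   time = unlist(x$times, use.names = FALSE),
                   stringsAsFactors = FALSE)
  if (!is.null(x$group)) df$group <- rep(x$group, nv)
  if (!is.null(x$covariates))
    for (cn in names(x$covariates)) df[[cn]] <- rep(x$covariates[[cn]], nv)
  vals <- do.call(rbind, x$values)
  df <- cbind(df, as.data.frame(vals))
  rownames(df) <- NULL
  df
}

#' Build a panel from a long-format data frame
#'
#' @param df data frame with columns `subject`, `time`, optionally `group`
#'   and covariates, plus one numeric column per measure.
#' @param measure_cols names of the measure columns; by default every column
#'   other than `subject`, `time`, `group` and `covariate_cols`.
#' @param covariate_cols names of per-subject covariate columns (default:
#'   `"age"` when present).
#' @return A [panel_data] object with subjects in order of first appearance.
#' @export
panel_from_df <- function(df, measure_cols = NULL, covariate_cols = NULL) {
  stopifnot(all(c("subject", "time") %in% names(df)))
  if (is.null(covariate_cols))
    covariate_cols <- intersect(c("age", "pair"), names(df))
  reserved <- c("subject", "time", "group", covariate_cols)
  if (is.null(measure_cols))
    measure_cols <- setdiff(names(df), reserved)
  if (length(measure_cols) == 0L) stop("no measure columns found")
  df$subject <- as.character(df$subject)
  if (anyDuplicated(df[c("subject", "time")]))
    stop("duplicate (subject, time) rows in input")

  # measures must parse as numbers; name the first offending cell
  for (cn in measure_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      raw <- trimws(as.character(col))
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & raw != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value '", raw[bad[1L]], "' in column '", cn,
             "', row ", bad[1L])
      num[raw == ""] <- NA_real_
      df[[cn]] <- num
    }
  }
  df$time <- as.numeric(df$time)

  ids <- unique(df$subject)
  idx <- split(seq_len(nrow(df)), factor(df$subject, levels = ids))
  times <- lapply(idx, function(j) df$time[j])
  values <- lapply(idx, function(j)
    as.matrix(df[j, measure_cols, drop = FALSE]))
  group <- NULL
  if ("group" %in% names(df)) {
    g <- vapply(idx, function(j) df$group[j][1L], df$group[1L])
    if (any(vapply(idx, function(j) length(unique(df$group[j])), 0L) > 1L))
      stop("group label varies within a subject")
    group <- g
  }
  covariates <- NULL
  if (length(covariate_cols)) {
    covariates <- as.data.frame(lapply(covariate_cols, function(cn)
      vapply(idx, function(j) df[[cn]][j][1L], df[[cn]][1L])))
    names(covariates) <- covariate_cols
  }
  panel_data(ids, times, values, measure_cols, group, covariates)
}

#' Read a long-format panel CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a header row
#' `subject,time[,group][,age],<var1>,...,<varp>`; an empty field marks a
#' missing measure cell.  Visit rows must appear in increasing time order
#' within each subject; duplicate `(subject, time)` rows are rejected.
#'
#' @param path path to the CSV file.
#' @inheritParams panel_from_df
#' @return A [panel_data] object.
#' @export
read_panel <- function(path, measure_cols = NULL, covariate_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$time <- as.numeric(df$time)
  if ("group" %in% names(df)) df$group <- as.integer(df$group)
  if (is.null(covariate_cols))
    covariate_cols <- intersect(c("age", "pair"), names(df))
  for (cn in covariate_cols) df[[cn]] <- as.numeric(df[[cn]])
  panel_from_df(df, measure_cols, covariate_cols)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: writes the long-format dialect with empty
#' fields for missing cells.
#'
#' @param panel a [panel_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Standardize panel variables
#'
#' Centres and scales each variable to mean 0 and (sample) standard
#' deviation 1 over its non-missing cells, pooling all subjects and visits.
#' The returned specification allows an exact inverse transform and records
#' that standardization was applied.
#'
#' @param panel a [panel_data] object; each variable needs at least two
#'   non-missing values and positive variance.
#' @param spec optionally, an existing specification (per-variable `mean` and
#'   `sd`) to apply instead of estimating one, e.g. reference statistics from
#'   a normative sample.
#' @return A list with elements `panel` (the transformed [panel_data]) and
#'   `spec` (a `standardization_spec`: per-variable `mean`, `sd`, `applied`).
#' @export
standardize_panel <- function(panel, spec = NULL) {
  vals <- do.call(rbind, panel$values)
  if (is.null(spec)) {
    nn <- colSums(!is.na(vals))
    if (any(nn < 2L))
      stop("variable '", panel$variable_names[which(nn < 2L)[1L]],
           "' has fewer than 2 non-missing values")
    mu <- colMeans(vals, na.rm = TRUE)
    sg <- apply(vals, 2L, stats::sd, na.rm = TRUE)
    if (any(sg <= 0))
      stop("variable '", panel$variable_names[which(sg <= 0)[1L]],
           "' has zero variance")
    spec <- structure(list(mean = mu, sd = sg, applied = TRUE),
                      class = "standardization_spec")
  } else {
    stopifnot(inherits(spec, "standardization_spec"), all(spec$sd > 0))
  }
  out <- panel
  out$values <- lapply(panel$values, function(v)
    sweep(sweep(v, 2L, spec$mean, "-"), 2L, spec$sd, "/"))
  list(panel = out, spec = spec)
}

#' Invert a standardization
#'
#' @param panel a standardized [panel_data] object.
#' @param spec the `standardization_spec` returned by [standardize_panel()].
#' @return The [panel_data] on the original scale.
#' @export
unstandardize_panel <- function(panel, spec) {
  stopifnot(inherits(spec, "standardization_spec"))
  out <- panel
  out$values <- lapply(panel$values, function(v)
    sweep(sweep(v, 2L, spec$sd, "*"), 2L, spec$mean, "+"))
  out
}

#' Write fitted results or result tables to disk
#'
#' A fitted model ([dfm_fit]) is written as JSON carrying the loadings,
#' idiosyncratic variances, per-visit factor scores, log-likelihood trace and
#' run metadata (settings, seed, package version); a data frame (e.g. a
#' Monte Carlo grid result) is written as CSV with one row per cell.
#'
#' @param x a `dfm_fit` or a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(x, path) {
  if (inherits(x, "dfm_fit")) {
    obj <- list(model = x$model,
                loadings = as.numeric(x$loadings),
                variances = as.numeric(x$variances),
                variable_names = x$variable_names,
                scores = x$scores,
                loglik = x$loglik,
                loglik_trace = x$loglik_trace,
                iterations = x$iterations,
                converged = x$converged,
                settings = x$settings,
                package_version = as.character(utils::packageVersion("dfmpanel")))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
  } else if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE, na = "")
  } else {
    stop("don't know how to write an object of class ", class(x)[1L])
  }
  invisible(path)
}

#' Read results written by [write_results()]
#' @param path file path (JSON for fits, CSV for tables).
#' @return A list (JSON) or data frame (CSV).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
}
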