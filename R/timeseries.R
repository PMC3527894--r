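#' ROI time-series container
#'
#' Holds one subject-session matrix of region-averaged BOLD-like signals:
#' rows are timepoints, columns are atlas regions.
#'
#' @param values numeric matrix, T timepoints x R regions, no missing values.
#' @param region_labels character vector of R unique region names. Defaults
#'   to the column names of `values`, or `roi_labels(ncol(values))`.
#' @param tr repetition time in seconds (sampling interval of the rows).
#' @param subject_id,session_id identifiers carried through the pipeline.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, region_labels = NULL, tr = 2,
                           subject_id = "subject", session_id = "1") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric")
  if (anyNA(values)) stop("time-series values must not contain missing values")
  if (nrow(values) < 2) stop("a time series needs at least 2 timepoints")
  if (is.null(region_labels)) {
    region_labels <- colnames(values)
    if (is.null(region_labels)) region_labels <- roi_labels(ncol(values))
  }
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(values)) {
    stop("need one region label per column")
  }
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  colnames(values) <- region_labels
  structure(
    list(values = values, region_labels = region_labels, tr = tr,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s session %s: %d timepoints x %d regions, TR = %g s\n",
              x$subject_id, x$session_id, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Canonical region labels
#'
#' Stable default node names (`ROI001`, `ROI002`, ...) used when the caller
#' supplies no atlas manifest. Padding keeps lexicographic and numeric order
#' identical, so feature names sort stably across runs.
#'
#' @param n number of regions.
#' @return character vector of length `n`.
#' @export
roi_labels <- function(n) {
  sprintf("ROI%03d", seq_len(n))
}

#' Zero-phase band-pass filter for ROI time series
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (zero phase) to each region's series. Columns are demeaned first, so a
#' constant series maps exactly to zero. Defaults match the standard
#' resting-state band of 0.009-0.08 Hz.
#'
#' @param ts `roi_timeseries`.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < 1/(2 tr).
#' @param order Butterworth order of the underlying design (per pass).
#' @return filtered `roi_timeseries`.
#' @export
bandpass_filter <- function(ts, low = 0.009, high = 0.08, order = 2) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high && high < nyquist)) {
    stop(sprintf("band (%g, %g) Hz must lie strictly inside (0, %g) Hz for tr = %g s",
                 low, high, nyquist, ts$tr))
  }
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  filtered <- apply(ts$values, 2, function(col) {
    signal::filtfilt(bf, col - mean(col))
  })
  out <- ts
  out$values <- matrix(filtered, nrow = nrow(ts$values),
                       dimnames = dimnames(ts$values))
  out
}

#' Concatenate repeated sessions of one subject
#'
#' Row-binds sessions in the given order; all sessions must share the same
#' subject and region labels.
#'
#' @param sessions list of `roi_timeseries`.
#' @return one `roi_timeseries` with the summed number of timepoints.
#' @export
concatenate_sessions <- function(sessions) {
  if (inherits(sessions, "roi_timeseries")) return(sessions)
  stopifnot(is.list(sessions), length(sessions) >= 1)
  if (length(sessions) == 1) return(sessions[[1]])
  ref <- sessions[[1]]
  for (s in sessions[-1]) {
    if (!identical(s$region_labels, ref$region_labels)) {
      stop("cannot concatenate sessions with different region labels")
    }
    if (!identical(s$subject_id, ref$subject_id)) {
      stop("cannot concatenate sessions from different subjects")
    }
  }
  out <- ref
  out$values <- do.call(rbind, lapply(sessions, `[[`, "values"))
  out$session_id <- paste(vapply(sessions, `[[`, "", "session_id"),
                          collapse = "+")
  out
}

#' Effective sample size of a correlated series pair
#'
#' Bartlett-style correction for temporal autocorrelation:
#' `T_eff = T / (1 + 2 * sum_k rho_x(k) rho_y(k))`, with sample
#' autocorrelations up to lag `K = min(floor(T/4), 50)`. The result is
#' clipped to `[4, T]` so the Fisher-transform scaling `sqrt(T_eff - 3)`
#' stays defined.
#'
#' @param x,y numeric series of equal length, T >= 8.
#' @return effective number of independent samples (scalar).
#' @export
effective_df <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 8) stop("need at least 8 timepoints for an autocorrelation estimate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("effective_df is undefined for a zero-variance series")
  }
  lag_max <- min(floor(n / 4), 50)
  rx <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  ry <- stats::acf(y, lag.max = lag_max, plot = FALSE)$acf[-1]
  correction <- 1 + 2 * sum(rx * ry)
  t_eff <- n / max(correction, .Machine$double.eps)
  min(max(t_eff, 4), n)
}
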