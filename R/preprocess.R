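# Feature extraction: mean-absolute-value windows, optional band-pass,
# channel z-normalization, and accelerometer change summaries.

#' Mean-absolute-value feature stream
#'
#' Reduces raw sampled signals to MAV features: for channel `j`, instance `k`
#' is the mean of `|f_j|` over a window of width `2N` samples centred at time
#' `kT`, i.e. samples `kT + i*T1` for `i = -N+1, ..., N`, with `T = step_s`
#' (default 1/20 s) and `T1 = 1/rate`. Windows at the end of the record that
#' would run past the last sample are truncated and averaged over the samples
#' actually present, so a 120 s run at 2 kHz yields exactly 2400 instances.
#'
#' @param x An `emg_run` (its EMG block is used) or a numeric matrix/vector of
#'   samples (rows = samples, columns = channels).
#' @param rate Sampling rate in Hz (taken from the run when `x` is one).
#' @param step_s Window step `T` in seconds (default 0.05: 20 instances/s).
#' @param half_width Window half-width `N` in samples (default 100, i.e. a
#'   100 ms window at 2 kHz).
#' @return An object of class `mav_stream`: list with `time` (seconds, `kT`),
#'   `values` (instances x channels matrix), `step`, and source metadata
#'   (`group`, `group_no`, `run_seed` when available).
#' @export
#' @examples
#' run <- generate_run(make_schedule("hammer"), noiseless_profile(), seed = 1)
#' mav <- compute_mav(run)
#' nrow(mav$values)  # 2400
compute_mav <- function(x, rate = NULL, step_s = 0.05, half_width = 100) {
  meta <- list()
  if (inherits(x, "emg_run")) {
    meta <- list(group = x$group, group_no = x$group_no, run_seed = x$seed)
    rate <- x$emg_rate
    x <- x$emg
  }
  if (is.null(rate)) stop("rate must be supplied for matrix input",
                          call. = FALSE)
  x <- as.matrix(x)
  n <- nrow(x)
  dur <- n / rate
  if (dur < 2 * step_s)
    stop("record too short: duration ", signif(dur, 4), " s < 2 * step (",
         2 * step_s, " s)", call. = FALSE)
  m <- floor(dur / step_s)
  step_samples <- rate * step_s
  if (abs(step_samples - round(step_samples)) > 1e-9)
    stop("step_s must be an integer number of samples at this rate",
         call. = FALSE)
  step_samples <- round(step_samples)
  N <- as.integer(half_width)

  cs <- apply(abs(x), 2, cumsum)
  cs <- rbind(0, cs)
  k <- seq_len(m)
  centre <- k * step_samples
  lo <- pmax(centre - N + 1L, 1L)
  hi <- pmin(centre + N, n)
  vals <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dimnames(vals) <- list(NULL, colnames(x))

  structure(
    c(list(time = k * step_s, values = vals, step = step_s), meta),
    class = "mav_stream"
  )
}

#' @export
print.mav_stream <- function(x, ...) {
  cat("<mav_stream> ", nrow(x$values), " instances x ", ncol(x$values),
      " channels, step ", x$step, " s", sep = "")
  if (!is.null(x$group)) cat(", group ", x$group, sep = "")
  if (!is.null(x$label)) cat(", labeled", sep = "")
  cat("\n")
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Flat-passband filtering matching the 20-450 Hz analogue conditioning
#' applied by typical sEMG acquisition hardware. Applied forward and backward
#' (`signal::filtfilt`) so phase is preserved. Synthetic runs from
#' [generate_run()] model already-conditioned output, so filtering them is
#' optional and off by default in the pipeline.
#'
#' @param x Numeric vector or matrix of samples (columns = channels).
#' @param rate Sampling rate, Hz; must exceed `2 * high`.
#' @param low,high Passband edges, Hz.
#' @param order Butterworth order (per pass).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, rate, low = 20, high = 450, order = 4) {
  if (rate <= 2 * high)
    stop("sampling rate ", rate, " Hz must exceed twice the upper edge (",
         2 * high, " Hz)", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
    dimnames(out) <- dimnames(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Channel normalization statistics from training data
#'
#' Per-channel mean and (population, divide-by-n) standard deviation of the
#' training MAV values. Held-out data must be normalized with *training*
#' statistics, so the fit and the transform are separate steps.
#'
#' @param x A `mav_stream`, a list of them, or an instances x channels matrix.
#' @return Object of class `channel_stats`: list with `mean` and `sd` vectors.
#' @export
fit_channel_stats <- function(x) {
  vals <- gather_values(x)
  if (nrow(vals) < 2L)
    stop("need at least 2 instances to fit channel statistics", call. = FALSE)
  mu <- colMeans(vals)
  sd_pop <- sqrt(colMeans(sweep(vals, 2, mu)^2))
  if (any(sd_pop == 0))
    stop("degenerate channel(s) with zero standard deviation: ",
         paste(which(sd_pop == 0), collapse = ", "), call. = FALSE)
  structure(list(mean = mu, sd = sd_pop), class = "channel_stats")
}

# Internal: extract a single values matrix from stream(s) or matrix input.
gather_values <- function(x) {
  if (inherits(x, "mav_stream")) return(x$values)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "mav_stream")))
    return(do.call(rbind, lapply(x, function(s) s$values)))
  as.matrix(x)
}

#' Apply (or invert) a channel z-score transform
#'
#' @param x A `mav_stream` or matrix.
#' @param stats A [fit_channel_stats()] object.
#' @param invert If `TRUE`, undo the transform.
#' @return Same type as `x`, transformed.
#' @export
apply_zscore <- function(x, stats, invert = FALSE) {
  stopifnot(inherits(stats, "channel_stats"))
  tf <- function(v) {
    if (invert) sweep(sweep(v, 2, stats$sd, "*"), 2, stats$mean, "+")
    else sweep(sweep(v, 2, stats$mean), 2, stats$sd, "/")
  }
  if (inherits(x, "mav_stream")) {
    x$values <- tf(x$values)
    x
  } else {
    tf(as.matrix(x))
  }
}

#' Accelerometer change summary of a run
#'
#' The movement-evidence statistic used for labeling: on a decimated grid
#' (every `stride`-th ACC sample, default 7, about 21.1 steps/s at 148.1 Hz),
#' the sum over the six hand-accelerometer channels of the absolute change in
#' value between consecutive grid points. The run-wide median of the
#' statistic is recorded as the reference for onset thresholding.
#'
#' @param x An `emg_run` or an ACC sample matrix.
#' @param rate ACC sampling rate (taken from the run when `x` is one).
#' @param stride Grid decimation in samples.
#' @return Object of class `acc_summary`: list with `time` (seconds, the
#'   later grid point of each pair, i.e. the right edge of the difference
#'   interval), `stat` (summed absolute differences, g), `median`, and `dt`
#'   (grid spacing, s).
#' @export
summarize_acc <- function(x, rate = NULL, stride = 7) {
  if (inherits(x, "emg_run")) {
    rate <- x$acc_rate
    x <- x$acc
  }
  if (is.null(rate)) stop("rate must be supplied for matrix input",
                          call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) < stride + 1L)
    stop("need at least ", stride + 1L, " ACC samples", call. = FALSE)
  idx <- seq(1L, nrow(x), by = stride)
  if (length(idx) < 2L) stop("too few ACC samples for the grid", call. = FALSE)
  g <- x[idx, , drop = FALSE]
  d <- abs(g[-1L, , drop = FALSE] - g[-nrow(g), , drop = FALSE])
  stat <- rowSums(d)
  t_grid <- idx / rate
  structure(
    list(time = t_grid[-1L], stat = stat,
         median = stats::median(stat), dt = stride / rate),
    class = "acc_summary"
  )
}
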