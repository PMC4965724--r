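#' Synthetic subject profile
#'
#' Bundles every tunable of the recording simulator: per-class, per-channel
#' MAV-scale activation amplitudes and the noise/timing parameters of one
#' synthetic "subject". Amplitudes are on the mV scale typical of surface-EMG
#' mean absolute values; accelerometer quantities are in g.
#'
#' @param amplitudes 25 x 8 numeric matrix (rows = activity codes in
#'   [activity_codes()] order, columns = the 8 EMG channels) of nonnegative
#'   activation amplitudes in mV. Distinct classes within a group must not
#'   share an identical row.
#' @param emg_noise_sd Additive zero-mean EMG noise standard deviation, mV.
#' @param amp_cv Coefficient of variation of the multiplicative envelope
#'   modulation applied in 50 ms blocks (instance-scale force variability).
#' @param rep_cv Coefficient of variation of the per-repetition effort scale.
#' @param rise_ms,fall_ms Envelope ramp times at activity onsets/offsets, ms.
#' @param acc_transient_g Peak amplitude of the hand-accelerometer transient
#'   at a movement onset, g; grip onsets get half this amplitude.
#' @param acc_noise_sd Accelerometer noise standard deviation, g.
#' @param jitter_ms Bound on uniform timing jitter applied to every scheduled
#'   onset, ms. Must be at most 500 (the protocol's timings are stated to be
#'   approximate only to within a few hundred milliseconds).
#' @param modes Optional 25 x 8 matrix of temporal activation peak positions
#'   in `(0, 1)` (fraction of the activity interval at which the channel's
#'   activation peaks). Rows with `NA` keep a flat plateau envelope (grips,
#'   rest); non-`NA` rows get a Gaussian-bump time course, emulating the
#'   sequential muscle firing of dynamic movements. `NULL` = all flat.
#' @param shape_sd Width (in interval fractions) of the activation bump.
#' @param shape_floor Envelope floor of shaped intervals, as a fraction of
#'   the peak amplitude.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(amplitudes,
                            emg_noise_sd = 0.02,
                            amp_cv = 0.35,
                            rep_cv = 0.2,
                            rise_ms = 200,
                            fall_ms = 200,
                            acc_transient_g = 1.0,
                            acc_noise_sd = 0.02,
                            jitter_ms = 300,
                            modes = NULL,
                            shape_sd = 0.25,
                            shape_floor = 0.55) {
  codes <- activity_codes()
  amplitudes <- as.matrix(amplitudes)
  if (!identical(dim(amplitudes), c(25L, 8L)))
    stop("amplitudes must be a 25 x 8 matrix (classes x EMG channels)",
         call. = FALSE)
  if (is.null(rownames(amplitudes))) rownames(amplitudes) <- codes
  if (!identical(rownames(amplitudes), codes))
    stop("amplitude rows must be the 25 activity codes in canonical order",
         call. = FALSE)
  if (any(amplitudes < 0) || any(!is.finite(amplitudes)))
    stop("amplitudes must be finite and nonnegative", call. = FALSE)
  if (jitter_ms > 500)
    stop("jitter_ms must be <= 500 ms", call. = FALSE)
  stopifnot(emg_noise_sd >= 0, amp_cv >= 0, rep_cv >= 0,
            rise_ms >= 0, fall_ms >= 0, acc_transient_g >= 0,
            acc_noise_sd >= 0, jitter_ms >= 0)
  # within a group, classes must be distinguishable at all
  tab <- activity_table()
  for (g in unique(tab$group_no[!is.na(tab$group_no)])) {
    rows <- tab$code[which(tab$group_no == g)]
    if (length(rows) > 1L) {
      m <- amplitudes[rows, , drop = FALSE]
      if (anyDuplicated(as.data.frame(m)) > 0L)
        stop("classes within group ", g,
             " have identical activation vectors", call. = FALSE)
    }
  }
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    if (!identical(dim(modes), c(25L, 8L)))
      stop("modes must be a 25 x 8 matrix or NULL", call. = FALSE)
    if (is.null(rownames(modes))) rownames(modes) <- codes
    rng <- range(modes, na.rm = TRUE)
    if (!all(is.na(modes)) && (rng[1] <= 0 || rng[2] >= 1))
      stop("modes must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(shape_sd > 0, shape_floor >= 0, shape_floor <= 1)
  structure(
    list(amplitudes = amplitudes, emg_noise_sd = emg_noise_sd,
         amp_cv = amp_cv, rep_cv = rep_cv, rise_ms = rise_ms,
         fall_ms = fall_ms, acc_transient_g = acc_transient_g,
         acc_noise_sd = acc_noise_sd, jitter_ms = jitter_ms,
         modes = modes, shape_sd = shape_sd, shape_floor = shape_floor),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> 25 classes x 8 channels\n",
      "  amplitude range [", signif(min(x$amplitudes), 3), ", ",
      signif(max(x$amplitudes), 3), "] mV; emg_noise_sd ", x$emg_noise_sd,
      " mV; amp_cv ", x$amp_cv, "; rep_cv ", x$rep_cv, "\n",
      "  acc transient ", x$acc_transient_g, " g (noise sd ", x$acc_noise_sd,
      " g); jitter <= ", x$jitter_ms, " ms\n", sep = "")
  invisible(x)
}

# Internal: deterministic amplitude and activation-timing matrices for a
# numbered synthetic subject. Classes of one action group share a group-level
# base activation pattern (the grip posture recruits the same muscles)
# modulated only mildly per class, so within-group classes overlap heavily in
# instantaneous amplitude -- the structure that makes within-group confusion
# the dominant instance-level error mode. What separates them is timing:
# each movement class gets its own per-channel activation peak times
# (sequential muscle firing), carried in `modes`.
subject_structure <- function(subject = 1) {
  tab <- activity_table()
  codes <- tab$code
  amp <- matrix(0, 25, 8, dimnames = list(codes, NULL))
  modes <- matrix(NA_real_, 25, 8, dimnames = list(codes, NULL))
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(77000L + as.integer(subject))
    base <- matrix(stats::runif(8 * 8, 0.10, 0.60), 8, 8)
    # movement-specific recruitment: each movement adds extra drive on its
    # own few dominant channels on top of the sustained grip pattern
    delta_w <- array(stats::runif(8 * 4 * 8), c(8, 4, 8))
    delta_a <- array(stats::runif(8 * 4 * 8, 0.20, 0.45), c(8, 4, 8))
    mds <- array(stats::runif(8 * 4 * 8, 0.2, 0.8), c(8, 4, 8))
    list(base = base, delta_w = delta_w, delta_a = delta_a, modes = mds)
  })
  for (i in seq_len(25)) {
    g <- tab$group_no[i]
    if (is.na(g)) { amp[i, ] <- 0.02; next }  # NR: quiescent floor
    k <- i - min(which(tab$group_no == g)) + 1L  # class index within group
    if (tab$is_grip[i]) {
      amp[i, ] <- rng$base[g, ]
    } else {
      # movement peak = 90 % of the held grip plus bursts on the movement's
      # top-3 recruitment channels
      extra <- rng$delta_a[g, k, ]
      extra[rank(-rng$delta_w[g, k, ]) > 3] <- 0
      amp[i, ] <- 0.9 * rng$base[g, ] + extra
      modes[i, ] <- rng$modes[g, k, ]
    }
  }
  list(amplitudes = amp, modes = modes)
}

# Internal: amplitude matrix only (used by configuration loading).
subject_amplitudes <- function(subject = 1) {
  subject_structure(subject)$amplitudes
}

#' Default synthetic subjects
#'
#' Three stock profiles mirror the three-subject reporting structure of the
#' collection protocol: same noise and timing characteristics, different
#' activation patterns. Amplitude structure is group-based (classes of one
#' grip family share a base pattern), which reproduces the qualitative error
#' structure of real recordings: confusions concentrate within action groups.
#'
#' @param subject Integer 1, 2 or 3 (any integer is accepted and yields a
#'   deterministic profile).
#' @return A [subject_profile()].
#' @export
#' @examples
#' default_profile(1)
default_profile <- function(subject = 1) {
  s <- subject_structure(subject)
  subject_profile(s$amplitudes, modes = s$modes)
}

#' A nearly noise-free, well-separated profile
#'
#' Used to verify that the pipeline recovers its inputs when classes are
#' cleanly separable: near-orthogonal activation patterns, minimal envelope
#' variability, little noise, no more than 100 ms timing jitter.
#'
#' @param jitter_ms Timing jitter bound, ms.
#' @return A [subject_profile()].
#' @export
separable_profile <- function(jitter_ms = 100) {
  tab <- activity_table()
  amp <- matrix(0.02, 25, 8, dimnames = list(tab$code, NULL))
  pairs <- t(utils::combn(8L, 2L))  # 28 distinct channel pairs for 24 classes
  for (i in seq_len(24)) {
    amp[i, pairs[i, 1L]] <- 0.8
    amp[i, pairs[i, 2L]] <- 0.45
    amp[i, ] <- amp[i, ] + 0.01 * i / 24
  }
  subject_profile(amp, emg_noise_sd = 0.005, amp_cv = 0.05, rep_cv = 0.05,
                  acc_noise_sd = 0.01, jitter_ms = jitter_ms)
}

#' A degenerate noiseless profile for exact recovery checks
#'
#' All stochastic elements off: zero noise, zero envelope variability, zero
#' timing jitter, instantaneous ramps. Mean-absolute values inside an
#' activity interval then equal the class amplitude exactly, and every onset
#' falls exactly on its scheduled second.
#'
#' @param rise_ms,fall_ms Envelope ramp times, ms (default 0).
#' @return A [subject_profile()].
#' @export
noiseless_profile <- function(rise_ms = 0, fall_ms = 0) {
  subject_profile(subject_amplitudes(1), emg_noise_sd = 0, amp_cv = 0,
                  rep_cv = 0, rise_ms = rise_ms, fall_ms = fall_ms,
                  acc_noise_sd = 0, jitter_ms = 0)
}
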