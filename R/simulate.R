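# Protocol simulator: synthetic raw sEMG + ACC runs with known ground truth.
#
# Signal model (chosen so that downstream features have closed forms):
#   emg_j(t) = envelope_j(t) * carrier(t) * mod_j(t) + noise,
# where envelope_j ramps between per-class activation amplitudes, carrier is a
# +1/-1 square wave alternating every sample (so |emg| recovers the envelope
# and the MAV of a constant-envelope stretch equals the class amplitude
# exactly when noise is off), mod_j is a 50 ms-blockwise lognormal force
# modulation, and noise is white Gaussian. Hand accelerometers carry a 300 ms
# raised-cosine transient at every movement onset; grips get a half-amplitude
# transient in the 300 ms *before* the grip onset, emulating the reach toward
# the object that ends when the grip is established.

EMG_RATE <- 2000
ACC_RATE <- 148.1
ACC_TRANSIENT_S <- 0.3

# Internal: evaluate a function under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Internal: jitter interior truth boundaries by U(-j, j), preserving order.
jitter_truth <- function(truth, jitter_s) {
  if (jitter_s <= 0 || nrow(truth) < 2L) return(truth)
  n <- nrow(truth)
  shifts <- stats::runif(n - 1L, -jitter_s, jitter_s)
  bounds <- c(truth$onset[1L], truth$onset[-1L] + shifts,
              truth$offset[n])
  bounds <- cummax(bounds)  # guard: never reorder (cannot fire for jitter<=0.5s)
  truth$onset <- bounds[seq_len(n)]
  truth$offset <- bounds[seq_len(n) + 1L]
  truth
}

# Internal: piecewise-linear envelope through per-interval target amplitudes.
build_envelope <- function(t, truth, targets, rise_s, fall_s) {
  n <- nrow(truth)
  xs <- 0
  ys <- targets[1L]
  if (n > 1L) {
    for (i in 2:n) {
      b <- truth$onset[i]
      ramp <- if (targets[i] >= targets[i - 1L]) rise_s else fall_s
      ramp <- max(ramp, 1e-9)  # approx() needs strictly increasing knots
      xs <- c(xs, b, b + ramp)
      ys <- c(ys, targets[i - 1L], targets[i])
    }
  }
  xs <- c(xs, truth$offset[n] + 1)
  ys <- c(ys, targets[n])
  stats::approx(xs, ys, xout = t, rule = 2, ties = "ordered")$y
}

#' Generate one synthetic two-minute collection run
#'
#' Produces raw 8-channel sEMG at 2 kHz and 6-channel hand accelerometer data
#' at 148.1 Hz following one action group's timed script, with the ground-truth
#' label track returned alongside. All randomness (timing jitter, repetition
#' effort scales, envelope modulation, additive noise) is driven by `seed`, so
#' the same call is bit-reproducible.
#'
#' @param schedule A [make_schedule()] object.
#' @param profile A [subject_profile()].
#' @param seed Integer seed for this run.
#' @param hybrid How hybrid protocol slots are performed: `"activity"`
#'   (default) or `"nr"`.
#' @return An object of class `emg_run`: list with `emg` (240000 x 8 matrix,
#'   mV), `acc` (17772 x 6 matrix, g), `emg_rate`, `acc_rate`, `duration`,
#'   `group`, `group_no`, `truth` (data frame `code`, `onset`, `offset`,
#'   `rep`) and `seed`.
#' @export
#' @examples
#' run <- generate_run(make_schedule("ball"), noiseless_profile(), seed = 1)
#' head(run$truth)
generate_run <- function(schedule, profile, seed,
                         hybrid = c("activity", "nr")) {
  stopifnot(inherits(schedule, "grip_schedule"),
            inherits(profile, "subject_profile"))
  hybrid <- match.arg(hybrid)
  with_seed(seed, {
    dur <- schedule$run_duration
    n_emg <- floor(dur * EMG_RATE)
    n_acc <- floor(dur * ACC_RATE)
    t_emg <- seq_len(n_emg) / EMG_RATE
    t_acc <- seq_len(n_acc) / ACC_RATE

    truth <- jitter_truth(schedule_truth(schedule, hybrid),
                          profile$jitter_ms / 1000)

    # per-repetition effort scale (lognormal, mean 1)
    s_rep <- sqrt(log1p(profile$rep_cv^2))
    rep_scale <- exp(stats::rnorm(schedule$rep_count, -s_rep^2 / 2, s_rep))
    scale_of <- ifelse(is.na(truth$rep), 1, rep_scale[truth$rep])

    # 50 ms blockwise force modulation shared grid
    n_blk <- ceiling(n_emg / 100)
    s_mod <- sqrt(log1p(profile$amp_cv^2))

    emg <- matrix(0, n_emg, 8)
    carrier <- rep_len(c(1, -1), n_emg)
    for (ch in 1:8) {
      targets <- profile$amplitudes[truth$code, ch] * scale_of
      env <- build_envelope(t_emg, truth, targets,
                            profile$rise_ms / 1000, profile$fall_ms / 1000)
      if (!is.null(profile$modes)) {
        # dynamic activities: Gaussian-bump time course peaking at the
        # class/channel-specific fraction of the interval
        for (i in seq_len(nrow(truth))) {
          m <- profile$modes[truth$code[i], ch]
          if (is.na(m)) next
          sel <- which(t_emg >= truth$onset[i] & t_emg < truth$offset[i])
          if (length(sel) == 0L) next
          u <- (t_emg[sel] - truth$onset[i]) /
            (truth$offset[i] - truth$onset[i])
          shape <- profile$shape_floor + (1 - profile$shape_floor) *
            exp(-(u - m)^2 / (2 * profile$shape_sd^2))
          env[sel] <- env[sel] * shape
        }
      }
      if (profile$amp_cv > 0) {
        mod <- exp(stats::rnorm(n_blk, -s_mod^2 / 2, s_mod))
        env <- env * rep(mod, each = 100)[seq_len(n_emg)]
      }
      noise <- if (profile$emg_noise_sd > 0)
        stats::rnorm(n_emg, 0, profile$emg_noise_sd) else 0
      emg[, ch] <- env * carrier + noise
    }
    colnames(emg) <- sensor_table()$abbrev[1:8]

    acc <- matrix(if (profile$acc_noise_sd > 0)
      stats::rnorm(n_acc * 6, 0, profile$acc_noise_sd) else 0, n_acc, 6)
    grips <- activity_table()$code[activity_table()$is_grip]
    for (i in seq_len(nrow(truth))) {
      code <- truth$code[i]
      if (code == "NR") next
      if (code %in% grips) {
        t0 <- truth$onset[i] - ACC_TRANSIENT_S
        a <- 0.5 * profile$acc_transient_g
      } else {
        t0 <- truth$onset[i]
        a <- profile$acc_transient_g
      }
      sel <- which(t_acc >= t0 & t_acc <= t0 + ACC_TRANSIENT_S)
      if (length(sel) > 0L) {
        bump <- a * 0.5 * (1 - cos(2 * pi * (t_acc[sel] - t0) / ACC_TRANSIENT_S))
        acc[sel, ] <- acc[sel, ] + bump
      }
    }
    colnames(acc) <- paste0(rep(c("thumb", "little"), each = 3), "_",
                            rep(c("x", "y", "z"), 2))

    structure(
      list(emg = emg, acc = acc, emg_rate = EMG_RATE, acc_rate = ACC_RATE,
           duration = dur, group = schedule$group,
           group_no = schedule$group_no, truth = truth, seed = seed),
      class = "emg_run"
    )
  })
}

#' @export
print.emg_run <- function(x, ...) {
  cat("<emg_run> group ", x$group_no, " (", x$group, "): ",
      nrow(x$emg), " EMG samples x 8 ch @ ", x$emg_rate, " Hz, ",
      nrow(x$acc), " ACC samples x 6 ch @ ", x$acc_rate, " Hz\n", sep = "")
  cat("  truth: ", nrow(x$truth), " intervals over [0, ", x$duration,
      "] s (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate the full eight-run collection session for one subject
#'
#' One run per action group, in protocol order. Per-run seeds are derived
#' deterministically from the master seed (`seed + group number`).
#'
#' @param profile A [subject_profile()].
#' @param seed Master integer seed.
#' @param hybrid Passed to [generate_run()].
#' @return List of 8 `emg_run` objects, named by group.
#' @export
generate_dataset <- function(profile, seed, hybrid = c("activity", "nr")) {
  hybrid <- match.arg(hybrid)
  runs <- lapply(seq_along(action_groups()), function(g)
    generate_run(make_schedule(g), profile, seed + g, hybrid = hybrid))
  names(runs) <- action_groups()
  runs
}
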