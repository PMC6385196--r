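# Tachogram simulation: integral-pulse-frequency-modulation style generator.
# Beat k+1 occurs RR(t_k)/1000 seconds after beat k, where RR(t) is an
# instantaneous RR function with band-limited sinusoidal modulation in the
# VLF/LF/HF bands plus white Gaussian noise.

#' Define an RR-modulation profile for tachogram simulation
#'
#' A modulation profile describes the instantaneous RR-interval function
#' used by [generate_tachogram()]: a baseline RR plus one sinusoid per
#' autonomic band (VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.40 Hz)
#' and additive white Gaussian noise. Per-band amplitude trajectories
#' (early, middle, late multipliers, interpolated piecewise-linearly over
#' the session) let a profile mimic the rise-then-fall phase patterns seen
#' during hemodialysis.
#'
#' @param base_rr baseline RR interval, ms.
#' @param amp_vlf,amp_lf,amp_hf sinusoid amplitudes per band, ms.
#' @param freq_vlf,freq_lf,freq_hf sinusoid frequencies, Hz; each must lie
#'   inside its band (half-open intervals `[0.003, 0.04)`, `[0.04, 0.15)`,
#'   `[0.15, 0.40)`).
#' @param noise_sd standard deviation of additive white noise, ms.
#' @param base_trajectory,traj_vlf,traj_lf,traj_hf length-3 numeric
#'   multipliers (early, middle, late) applied to the baseline and to each
#'   band amplitude respectively.
#' @param phase phase offsets (radians) for the three sinusoids, recycled.
#' @return an object of class `"modulation_profile"`.
#' @examples
#' p <- modulation_profile(base_rr = 900, amp_hf = 40, noise_sd = 3)
#' ts <- generate_tachogram(p, duration = 900, seed = 1)
#' @export
modulation_profile <- function(base_rr = 1000,
                               amp_vlf = 20, amp_lf = 30, amp_hf = 25,
                               freq_vlf = 0.03, freq_lf = 0.10, freq_hf = 0.25,
                               noise_sd = 5,
                               base_trajectory = c(1, 1, 1),
                               traj_vlf = c(1, 1, 1),
                               traj_lf = c(1, 1, 1),
                               traj_hf = c(1, 1, 1),
                               phase = c(0, 0, 0)) {
  stopifnot(is.numeric(base_rr), length(base_rr) == 1L, base_rr > 0)
  amps <- c(vlf = amp_vlf, lf = amp_lf, hf = amp_hf)
  if (any(amps < 0)) stop("band amplitudes must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  in_band <- function(f, band) f >= band[1] && f < band[2]
  if (!in_band(freq_vlf, .hrv_bands$vlf))
    stop("freq_vlf must lie in [0.003, 0.04) Hz")
  if (!in_band(freq_lf, .hrv_bands$lf))
    stop("freq_lf must lie in [0.04, 0.15) Hz")
  if (!in_band(freq_hf, .hrv_bands$hf))
    stop("freq_hf must lie in [0.15, 0.40) Hz")
  trajs <- list(base = base_trajectory, vlf = traj_vlf, lf = traj_lf,
                hf = traj_hf)
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    if (length(tr) != 3L || any(!is.finite(tr)) || any(tr < 0))
      stop("trajectory '", nm, "' must be 3 nonnegative multipliers")
  }
  structure(list(base_rr = base_rr,
                 amp = amps,
                 freq = c(vlf = freq_vlf, lf = freq_lf, hf = freq_hf),
                 noise_sd = noise_sd,
                 base_trajectory = base_trajectory,
                 traj = list(vlf = traj_vlf, lf = traj_lf, hf = traj_hf),
                 phase = rep_len(phase, 3L)),
            class = "modulation_profile")
}

# Evaluate a (early, middle, late) multiplier triple at time t by
# piecewise-linear interpolation between anchor times; constant outside.
.traj_eval <- function(mult, t, anchors) {
  if (t <= anchors[1]) return(mult[1])
  if (t >= anchors[3]) return(mult[3])
  if (t <= anchors[2]) {
    w <- (t - anchors[1]) / (anchors[2] - anchors[1])
    mult[1] + w * (mult[2] - mult[1])
  } else {
    w <- (t - anchors[2]) / (anchors[3] - anchors[2])
    mult[2] + w * (mult[3] - mult[2])
  }
}

#' Simulate a tachogram from a modulation profile
#'
#' Iterates beat times through the instantaneous RR function: beat `k+1`
#' occurs `RR(t_k)/1000` seconds after beat `k`, with the first beat at
#' `t = 0`. Amplitude trajectories are anchored at the temporal midpoints
#' of the early, middle and late phases (`phase_anchors`) and interpolated
#' linearly between them.
#'
#' @param profile a [modulation_profile()].
#' @param duration recording length, s; at least 600 unless
#'   `allow_short = TRUE` (used internally by examples/tests).
#' @param phase_anchors times (s) at which the early/middle/late trajectory
#'   multipliers apply exactly; defaults to the midpoints of segments 1-2,
#'   24-25 and 47-48 of a 240-minute session.
#' @param seed integer seed; identical seeds give identical series.
#' @param allow_short permit durations below 600 s.
#' @return a `beat_series`: data frame with columns `time_s` (strictly
#'   increasing beat times starting at 0) and `rr_ms`.
#' @export
generate_tachogram <- function(profile, duration = 14400,
                               phase_anchors = c(300, 7200, 14100),
                               seed = NULL, allow_short = FALSE) {
  stopifnot(inherits(profile, "modulation_profile"))
  if (!allow_short && duration < 600)
    stop("duration must be >= 600 s")
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))

  # generous preallocation: shortest plausible RR ~ base_rr/3
  n_max <- ceiling(duration / (profile$base_rr / 3000)) + 16L
  times <- numeric(n_max)
  rrs <- numeric(n_max)
  amp <- profile$amp
  frq <- 2 * pi * profile$freq
  ph <- profile$phase
  noise <- profile$noise_sd
  base_rr <- profile$base_rr
  tr_base <- profile$base_trajectory
  tr <- profile$traj
  anch <- phase_anchors

  t <- 0
  k <- 0L
  while (t < duration) {
    rr <- base_rr * .traj_eval(tr_base, t, anch) +
      amp[[1L]] * .traj_eval(tr$vlf, t, anch) * sin(frq[[1L]] * t + ph[1L]) +
      amp[[2L]] * .traj_eval(tr$lf, t, anch) * sin(frq[[2L]] * t + ph[2L]) +
      amp[[3L]] * .traj_eval(tr$hf, t, anch) * sin(frq[[3L]] * t + ph[3L])
    if (noise > 0) rr <- rr + rnorm(1L, 0, noise)
    # reject at 1 ms, not 0: near a zero crossing the beat step rr/1000
    # shrinks geometrically and a strict rr <= 0 check would never trigger
    if (rr < 1)
      stop("modulation profile generated a non-positive RR interval at t = ",
           signif(t, 6), " s; reduce amplitudes or noise_sd")
    k <- k + 1L
    if (k > n_max)
      stop("beat count exceeded the physiologic bound; invalid profile")
    times[k] <- t
    rrs[k] <- rr
    t <- t + rr / 1000
  }
  beat_series(times[seq_len(k)], rrs[seq_len(k)])
}

#' Construct a beat series (tachogram)
#'
#' @param time_s beat times in seconds, strictly increasing.
#' @param rr_ms RR intervals in milliseconds, all positive.
#' @return data frame of class `beat_series` with columns `time_s`, `rr_ms`.
#' @export
beat_series <- function(time_s, rr_ms) {
  stopifnot(length(time_s) == length(rr_ms))
  if (any(rr_ms <= 0)) stop("all RR intervals must be positive")
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("beat times must be strictly increasing")
  structure(data.frame(time_s = as.numeric(time_s),
                       rr_ms = as.numeric(rr_ms)),
            class = c("beat_series", "data.frame"))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats over %.1f s (mean RR %.1f ms)\n",
              nrow(x), if (nrow(x)) max(x$time_s) else 0,
              mean(x$rr_ms)))
  invisible(x)
}

#' Inject artificial ectopic beats into a tachogram
#'
#' Randomly flags beats (never the first) with per-beat probability `rate`
#' and shifts each flagged RR by `+/- magnitude` (fractional), emulating
#' ectopic beats that the 20%-difference preprocessing rule should remove.
#' The ground-truth flagged indices are attached as attribute
#' `"ectopic_idx"` so tests can compare removed versus injected sets.
#'
#' @param series a `beat_series`.
#' @param rate per-beat flag probability in `[0, 0.2)`.
#' @param magnitude fractional RR shift; must exceed 0.2, otherwise the
#'   injected beats would not be removable by the 20% rule.
#' @param seed integer seed.
#' @param at optional explicit beat indices to flag (overrides `rate`).
#' @return a `beat_series` with attribute `ectopic_idx` (integer indices
#'   into the input series, possibly empty).
#' @export
inject_ectopics <- function(series, rate = 0.05, magnitude = 0.3,
                            seed = NULL, at = NULL) {
  stopifnot(inherits(series, "beat_series"))
  if (magnitude <= 0.2)
    stop("magnitude must exceed 0.2 (the ectopic-removal threshold)")
  if (is.null(at)) {
    if (rate < 0 || rate >= 0.2) stop("rate must lie in [0, 0.2)")
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- nrow(series)
    idx <- which(rbinom(n, 1L, rate) == 1L)
    idx <- idx[idx > 1L]
  } else {
    idx <- sort(unique(as.integer(at)))
    if (any(idx < 2L | idx > nrow(series)))
      stop("'at' indices must lie in 2..n")
    if (!is.null(seed)) set.seed(as.integer(seed))
  }
  rr <- series$rr_ms
  if (length(idx)) {
    sign <- ifelse(runif(length(idx)) < 0.5, -1, 1)
    rr[idx] <- rr[idx] * (1 + sign * magnitude)
  }
  out <- beat_series(series$time_s, rr)
  attr(out, "ectopic_idx") <- as.integer(idx)
  out
}

#' Write / read a tachogram as two-column CSV
#'
#' The on-disk format is a plain CSV with header `time_s, rr_ms`.
#'
#' @param series a `beat_series`.
#' @param path file path.
#' @return `read_tachogram` returns a `beat_series`; `write_tachogram`
#'   returns `path` invisibly.
#' @export
write_tachogram <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tachogram
#' @export
read_tachogram <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "rr_ms") %in% names(df))) {
    # beat-times-only format: one timestamp (s) per line, RR by differencing
    tt <- as.numeric(readLines(path))
    if (any(is.na(tt))) stop("unrecognized tachogram format: ", path)
    return(beat_series(tt[-1L], diff(tt) * 1000))
  }
  beat_series(df$time_s, df$rr_ms)
}
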