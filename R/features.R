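# HRV feature extraction: nine parameters per 5-minute segment
# (HR, RRI, SDNN, RMSSD, VLF, LF, HF, TP, LF/HF), averaged over the two
# segments of each phase, plus middle-minus-early delta features.

.hrv_par_names <- c("hr", "rri", "sdnn", "rmssd",
                    "vlf", "lf", "hf", "tp", "lf_hf")

#' Time-domain HRV features of one segment
#'
#' @param rr_ms RR intervals (ms) of the beats in the segment; at least 3.
#' @return named list: `hr` (beats/min, 60000 / mean RR), `rri` (mean RR,
#'   ms), `sdnn` (sample SD, ms), `rmssd` (root mean square of successive
#'   differences, ms).
#' @export
time_domain_features <- function(rr_ms) {
  if (length(rr_ms) < 3L)
    stop("need at least 3 beats for time-domain features")
  rri <- mean(rr_ms)
  list(hr = 60000 / rri,
       rri = rri,
       sdnn = sd(rr_ms),
       rmssd = sqrt(mean(diff(rr_ms)^2)))
}

#' Resample a tachogram to an even 4 Hz grid
#'
#' RR as a function of beat time is linearly interpolated onto a regular
#' grid of spacing `1/fs` across the window `[from, to)`; samples outside
#' the beat span are held at the nearest beat's RR.
#'
#' @param series a `beat_series` (all beats available for interpolation,
#'   not just those inside the window).
#' @param from,to window bounds in seconds (half-open).
#' @param fs sampling frequency, Hz (default 4).
#' @return numeric vector of `(to - from) * fs` samples (ms).
#' @export
resample_tachogram <- function(series, from, to, fs = 4) {
  stopifnot(inherits(series, "beat_series"), to > from)
  if (nrow(series) < 2L) stop("need at least 2 beats to resample")
  n <- round((to - from) * fs)
  grid <- from + (seq_len(n) - 1L) / fs
  approx(series$time_s, series$rr_ms, xout = grid, rule = 2)$y
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann-tapered 64-second windows
#' (256 samples at 4 Hz) and 75% overlap. Each window is mean-removed
#' before tapering, and the taper's power loss is corrected so that the
#' one-sided PSD integrates (over 0 to Nyquist) to the mean-removed
#' signal variance.
#'
#' @param x evenly sampled series (ms), length at least `nwin`.
#' @param fs sampling frequency, Hz.
#' @param nwin window length in samples (default 256, i.e. 64 s at 4 Hz).
#' @param overlap fractional window overlap (default 0.75).
#' @return list of class `"welch_psd"`: `freq` (Hz, 0..fs/2), `psd`
#'   (ms^2/Hz), `df` (bin width, Hz), `n_windows`.
#' @export
welch_psd <- function(x, fs = 4, nwin = 256, overlap = 0.75) {
  n <- length(x)
  if (n < nwin)
    stop("series has ", n, " samples but one Welch window needs ", nwin)
  hop <- round(nwin * (1 - overlap))
  k <- floor((n - nwin) / hop) + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1)) / nwin))  # periodic Hann
  U <- mean(w^2)                                        # taper power correction
  nf <- nwin %/% 2L
  acc <- numeric(nf + 1L)
  for (j in seq_len(k)) {
    seg <- x[((j - 1L) * hop + 1L):((j - 1L) * hop + nwin)]
    seg <- (seg - mean(seg)) * w
    Y <- fft(seg)
    P <- (Mod(Y[1:(nf + 1L)])^2) / (fs * nwin * U)
    P[2:nf] <- 2 * P[2:nf]  # one-sided, DC and Nyquist not doubled
    acc <- acc + P
  }
  structure(list(freq = (0:nf) * fs / nwin,
                 psd = acc / k,
                 df = fs / nwin,
                 n_windows = k),
            class = "welch_psd")
}

#' Band powers from a Welch PSD
#'
#' Integrates the PSD over the VLF (0.003-0.04 Hz), LF (0.04-0.15 Hz) and
#' HF (0.15-0.40 Hz) bands; a frequency bin belongs to a band when its
#' center lies in the half-open interval `[low, high)`, so no bin is
#' double-counted at the shared edges. Total power is the integral over
#' the union of the three bands, making `vlf + lf + hf == tp` exact on
#' the bin grid. With 64-second windows the lowest nonzero bin is
#' 1/64 Hz, so the 0.003-0.0156 Hz part of the VLF band is unobservable;
#' the integral covers what the grid provides (recorded in attribute
#' `"vlf_resolution_limited"`).
#'
#' @param psd a `"welch_psd"` object.
#' @return named list: `vlf`, `lf`, `hf`, `tp` (ms^2) and `lf_hf`
#'   (dimensionless; `NA` with a warning when `hf` is zero).
#' @export
band_powers <- function(psd) {
  stopifnot(inherits(psd, "welch_psd"))
  f <- psd$freq
  bp <- function(band) sum(psd$psd[f >= band[1] & f < band[2]]) * psd$df
  vlf <- bp(.hrv_bands$vlf)
  lf <- bp(.hrv_bands$lf)
  hf <- bp(.hrv_bands$hf)
  lf_hf <- if (hf == 0) {
    warning("HF power is zero; LF/HF ratio reported as NA")
    NA_real_
  } else lf / hf
  structure(list(vlf = vlf, lf = lf, hf = hf, tp = vlf + lf + hf,
                 lf_hf = lf_hf),
            vlf_resolution_limited = psd$df > .hrv_bands$vlf[1],
            class = "band_powers")
}

#' All nine HRV parameters of one segment
#'
#' @param series the cleaned `beat_series` the grid was built on.
#' @param grid a `segment_grid`.
#' @param k segment index (1-based).
#' @param fs resampling frequency, Hz.
#' @return named list with the nine parameters
#'   `hr, rri, sdnn, rmssd, vlf, lf, hf, tp, lf_hf`.
#' @export
segment_features <- function(series, grid, k, fs = 4) {
  stopifnot(inherits(grid, "segment_grid"), k >= 1, k <= grid$n_segments)
  idx <- grid$beats[[k]]
  if (length(idx) < 3L)
    stop("segment ", k, " contains only ", length(idx), " beats")
  td <- time_domain_features(series$rr_ms[idx])
  from <- (k - 1) * grid$segment_length
  x <- resample_tachogram(series, from, from + grid$segment_length, fs = fs)
  sp <- band_powers(welch_psd(x, fs = fs))
  c(td, sp[c("vlf", "lf", "hf", "tp", "lf_hf")])
}

#' Phase-averaged HRV features
#'
#' Computes the nine parameters for each of the phase's two segments and
#' averages them arithmetically (the LF/HF ratio is averaged as a ratio,
#' not recomputed from the averaged LF and HF).
#'
#' @param series cleaned `beat_series`.
#' @param grid a `segment_grid`.
#' @param phase `"early"`, `"middle"` or `"late"` (or explicit pair, see
#'   [select_phase_segments()]).
#' @param fs resampling frequency, Hz.
#' @return named list of the nine phase-averaged parameters, with the
#'   phase name as attribute `"phase"`.
#' @export
phase_features <- function(series, grid, phase, fs = 4) {
  idx <- select_phase_segments(grid, phase)
  f1 <- tryCatch(segment_features(series, grid, idx[1], fs = fs),
                 error = function(e) stop("phase '", phase, "', segment ",
                                          idx[1], ": ", conditionMessage(e)))
  f2 <- tryCatch(segment_features(series, grid, idx[2], fs = fs),
                 error = function(e) stop("phase '", phase, "', segment ",
                                          idx[2], ": ", conditionMessage(e)))
  out <- mapply(function(a, b) (a + b) / 2, f1, f2, SIMPLIFY = FALSE)
  attr(out, "phase") <- if (is.character(phase)) phase else
    paste(idx, collapse = ",")
  out
}

#' Middle-minus-early delta features
#'
#' The change of each HRV parameter between the early and middle phases
#' of the session, `delta = middle - early`. Positive values mean the
#' parameter rose from the early to the middle phase.
#'
#' @param early,middle phase feature lists from [phase_features()].
#' @return named list `d_hr, d_rri, ..., d_lf_hf`; a parameter missing in
#'   either phase yields `NA`.
#' @export
delta_features <- function(early, middle) {
  out <- lapply(.hrv_par_names, function(nm) {
    a <- early[[nm]]; b <- middle[[nm]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) NA_real_ else b - a
  })
  names(out) <- paste0("d_", .hrv_par_names)
  out
}

#' Full per-session HRV feature extraction
#'
#' Convenience wrapper: ectopic filtering, segmentation, per-phase feature
#' averaging and delta features for one tachogram.
#'
#' @param series a raw `beat_series`.
#' @param segment_length,n_segments segmentation parameters (defaults 300 s
#'   and 48).
#' @param phases phases to extract (default early/middle/late).
#' @param fs resampling frequency, Hz.
#' @return one-row data frame with columns `<phase>_<par>` for each phase
#'   and parameter, plus `d_<par>` deltas and `n_removed` (ectopic beats
#'   removed).
#' @export
session_features <- function(series, segment_length = 300, n_segments = 48,
                             phases = c("early", "middle", "late"), fs = 4) {
  clean <- filter_ectopic(series)
  grid <- segment_series(clean, segment_length, n_segments)
  pf <- lapply(phases, function(p) phase_features(clean, grid, p, fs = fs))
  names(pf) <- phases
  row <- list(n_removed = length(attr(clean, "removed_idx")))
  for (p in phases)
    for (nm in .hrv_par_names)
      row[[paste0(p, "_", nm)]] <- pf[[p]][[nm]]
  if (all(c("early", "middle") %in% phases)) {
    d <- delta_features(pf$early, pf$middle)
    row <- c(row, d)
  }
  as.data.frame(row)
}

# Default divisors taking raw delta features to the count-model reporting
# scales: band powers per 100 ms^2, RRI per 0.1 s (see vignette for the
# unit discussion), HR / SDNN / RMSSD / LF-HF ratio unscaled.
.delta_scale_defaults <- c(d_hr = 1, d_rri = 100, d_sdnn = 1, d_rmssd = 1,
                           d_vlf = 100, d_lf = 100, d_hf = 100, d_tp = 100,
                           d_lf_hf = 1)

#' Scale delta features to count-model reporting units
#'
#' @param features data frame containing `d_*` columns (e.g. from
#'   [session_features()]).
#' @param divisors named divisors per column; defaults divide band-power
#'   deltas by 100 (per 100 ms^2) and the RRI delta by 100 ms (per 0.1 s).
#' @return the data frame with the scaled columns.
#' @export
scale_delta_features <- function(features, divisors = .delta_scale_defaults) {
  for (nm in intersect(names(divisors), names(features)))
    features[[nm]] <- features[[nm]] / divisors[[nm]]
  features
}
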