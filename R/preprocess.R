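# RR-interval preprocessing: ectopic-beat removal by the 20% rule and
# segmentation of the session into 5-minute wall-clock windows with
# early/middle/late phase selection.

#' Remove ectopic beats by the 20% rule
#'
#' Scans the tachogram in order and removes every beat whose RR interval
#' differs by more than 20% from the reference RR. The reference is the
#' most recent *retained* beat (not the raw predecessor), so a single
#' ectopic beat cannot cascade into removals of the normal beats that
#' follow it; this also makes the filter idempotent. The first beat is
#' always retained.
#'
#' @param series a [beat_series()] with at least 2 beats.
#' @param threshold fractional difference above which a beat is removed
#'   (default 0.20).
#' @return a `clean_series`: a `beat_series` of retained beats with
#'   attribute `removed_idx` (1-based indices into the input).
#' @examples
#' s <- beat_series(c(0, 0.8, 1.61, 2.63), c(800, 810, 1020, 805))
#' filter_ectopic(s)  # removes the 1020 ms beat (index 3)
#' @export
filter_ectopic <- function(series, threshold = 0.20) {
  stopifnot(inherits(series, "beat_series"))
  n <- nrow(series)
  if (n < 2L) stop("need at least 2 beats to apply the ectopic rule")
  rr <- series$rr_ms
  keep <- logical(n)
  keep[1L] <- TRUE
  ref <- rr[1L]
  for (i in 2:n) {
    if (abs(rr[i] - ref) / ref <= threshold) {
      keep[i] <- TRUE
      ref <- rr[i]
    }
  }
  out <- beat_series(series$time_s[keep], rr[keep])
  attr(out, "removed_idx") <- which(!keep)
  class(out) <- c("clean_series", class(out))
  out
}

#' Report removed beats as a data frame
#'
#' @param clean a `clean_series` from [filter_ectopic()].
#' @param original the original `beat_series` it was filtered from.
#' @return data frame with columns `index`, `time_s`, `rr_ms`, `reason`.
#' @export
removal_report <- function(clean, original) {
  idx <- attr(clean, "removed_idx")
  data.frame(index = idx,
             time_s = original$time_s[idx],
             rr_ms = original$rr_ms[idx],
             reason = rep("ectopic>20%", length(idx)))
}

#' Divide a session into 5-minute segments
#'
#' Segments are defined on wall-clock beat time, 1-based and half-open:
#' segment `k` covers `[(k-1)*segment_length, k*segment_length)` seconds.
#' A beat falling exactly on a boundary belongs to the later segment.
#'
#' @param series a `beat_series` (typically a `clean_series`).
#' @param segment_length segment length in seconds (default 300).
#' @param n_segments number of segments in a full grid (default 48, i.e.
#'   a 240-minute session).
#' @param partial if `FALSE` (default), a recording shorter than
#'   `n_segments * segment_length` is an error; if `TRUE`, a partial grid
#'   with the actually covered segments is returned with a message.
#' @return a `segment_grid`: list with `segment_length`, `n_segments`,
#'   and `beats`, a list of integer index vectors (one per segment,
#'   indices into `series`).
#' @export
segment_series <- function(series, segment_length = 300, n_segments = 48,
                           partial = FALSE) {
  stopifnot(inherits(series, "beat_series"),
            segment_length > 0, n_segments >= 1)
  span <- max(series$time_s)
  full_span <- n_segments * segment_length
  if (span < full_span - segment_length) {
    # last beat may legitimately fall just short of the final boundary;
    # anything more than one segment short is a truncated recording
    if (!partial)
      stop("recording spans ", round(span), " s but ", full_span,
           " s are needed for ", n_segments,
           " segments; use partial = TRUE for a partial grid")
    n_segments <- max(1L, ceiling((span + .Machine$double.eps) /
                                    segment_length))
    message("partial grid: ", n_segments, " segment(s) available")
  }
  seg_of <- floor(series$time_s / segment_length) + 1L
  beats <- lapply(seq_len(n_segments), function(k) which(seg_of == k))
  structure(list(segment_length = segment_length,
                 n_segments = as.integer(n_segments),
                 beats = beats),
            class = "segment_grid")
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("Segment grid: %d x %g s segments (%d beats)\n",
              x$n_segments, x$segment_length,
              sum(lengths(x$beats))))
  invisible(x)
}

#' Select the two segments of a dialysis phase
#'
#' The early phase uses segments 1 and 2, the middle phase segments 24 and
#' 25, and the late phase segments 47 and 48 of the standard 48-segment
#' grid (10 minutes per phase).
#'
#' @param grid a `segment_grid` from [segment_series()].
#' @param phase `"early"`, `"middle"` or `"late"`, or a length-2 integer
#'   vector of explicit segment indices.
#' @return integer vector of the two segment indices, with the per-segment
#'   beat indices as attribute `"beats"`.
#' @export
select_phase_segments <- function(grid, phase) {
  stopifnot(inherits(grid, "segment_grid"))
  if (is.character(phase)) {
    phase <- match.arg(phase, names(.phase_segments))
    idx <- .phase_segments[[phase]]
  } else {
    idx <- as.integer(phase)
    phase <- paste(idx, collapse = ",")
    stopifnot(length(idx) == 2L, all(idx >= 1L))
  }
  if (any(idx > grid$n_segments))
    stop("phase '", phase, "' needs segment ", max(idx),
         " but the grid has only ", grid$n_segments, " segments")
  structure(idx, beats = grid$beats[idx])
}
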