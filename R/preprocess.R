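#' Segment a beat series into overlapping 10-minute windows
#'
#' Windows are 600 000 ms long, stepped by 300 000 ms (50 % overlap),
#' anchored at time 0 and kept while fully contained in the recording. An RR
#' interval belongs to the window containing its terminating beat, so a pair
#' split at a boundary is assigned to the window of the second beat.
#'
#' @param beat_times Strictly increasing ventricular beat times (ms from
#'   recording start).
#' @param duration Recording duration in ms; defaults to the last beat time.
#' @param window_ms,step_ms Window length and step (ms).
#' @return List of segments; each is a list with \code{index}, \code{start},
#'   \code{end}, \code{rr} (intervals terminating inside the window),
#'   \code{beat_times} (beats inside the window), \code{included} (logical,
#'   TRUE until a filter excludes it), \code{reason}, and \code{lambda_hat}
#'   (NA until attached).
#' @export
segment_series <- function(beat_times, duration = NULL,
                           window_ms = 600000, step_ms = 300000) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) >= 2L && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing")
  if (is.null(duration))
    duration <- if (length(beat_times)) beat_times[length(beat_times)] else 0
  starts <- if (duration >= window_ms)
    seq(0, duration - window_ms, by = step_ms) else numeric(0)
  rr <- diff(beat_times)
  term <- beat_times[-1L] # terminating beat of each interval
  lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- s + window_ms
    list(index = i, start = s, end = e,
         rr = rr[term >= s & term < e],
         beat_times = beat_times[beat_times >= s & beat_times < e],
         included = TRUE, reason = "",
         lambda_hat = NA_real_)
  })
}

#' Exclude segments containing a low-beat minute
#'
#' Each 10-min segment is divided into ten non-overlapping minutes anchored
#' at the window start; the whole segment is excluded when any minute holds
#' fewer than 20 detected beats, since excessive noise shows up as missing
#' beats and an unrealistically low heart rate.
#'
#' @param segment One segment from [segment_series()].
#' @param min_beats_per_min Threshold (default 20).
#' @return The segment, possibly with \code{included = FALSE} and reason
#'   \code{"low-beat-minute"}.
#' @export
apply_beat_count_filter <- function(segment, min_beats_per_min = 20L) {
  mins <- floor((segment$beat_times - segment$start) / 60000)
  counts <- tabulate(mins + 1L, nbins = (segment$end - segment$start) / 60000)
  if (any(counts < min_beats_per_min)) {
    segment$included <- FALSE
    segment$reason <- "low-beat-minute"
  }
  segment
}

#' Patient-level duration filter
#'
#' A patient is excluded when the union of the included segments' coverage is
#' shorter than 12 h ("shorter than" is strict, so exactly 12 h passes).
#'
#' @param segments List of segments after the beat-count filter.
#' @param min_hours Minimum usable duration in hours (default 12).
#' @return Logical: keep the patient.
#' @export
apply_duration_filter <- function(segments, min_hours = 12) {
  inc <- Filter(function(s) s$included, segments)
  if (!length(inc)) return(FALSE)
  iv <- cbind(vapply(inc, `[[`, 0, "start"), vapply(inc, `[[`, 0, "end"))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  covered <- 0; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_e) cur_e <- max(cur_e, iv[i, 2])
    else { covered <- covered + cur_e - cur_s; cur_s <- iv[i, 1]; cur_e <- iv[i, 2] }
  }
  covered <- covered + cur_e - cur_s
  covered / 3600000 >= min_hours
}

#' Read an atrial-fibrillatory-rate trend CSV
#'
#' Columns \code{minute} (0-based index from recording start) and
#' \code{afr_per_min} (fibrillations per minute); blank values are missing
#' minutes.
#'
#' @param path File path.
#' @return Data frame with \code{minute} and \code{afr} (NA = missing).
#' @export
read_afr_csv <- function(path) {
  d <- read.csv(path)
  data.frame(minute = as.integer(d$minute), afr = as.numeric(d$afr_per_min))
}

#' @rdname read_afr_csv
#' @param afr Data frame as returned by \code{read_afr_csv}.
#' @export
write_afr_csv <- function(afr, path) {
  write.csv(data.frame(minute = afr$minute, afr_per_min = afr$afr),
            path, row.names = FALSE)
  invisible(path)
}

#' Mean atrial impulse rate for a segment
#'
#' The Poisson arrival rate of a segment is the mean of the ten AFR minutes
#' overlapping its window, converted from fibrillations per minute to
#' impulses per second. Missing minutes are filled with the nearest observed
#' minute (ties broken toward the earlier one).
#'
#' @param afr AFR trend data frame (\code{minute}, \code{afr}).
#' @param segment One segment from [segment_series()].
#' @return Estimated rate in impulses per second.
#' @export
lambda_for_segment <- function(afr, segment) {
  obs <- afr$minute[!is.na(afr$afr)]
  if (!length(obs)) stop("AFR trend has no observed minutes")
  mins <- seq(floor(segment$start / 60000),
              length.out = round((segment$end - segment$start) / 60000))
  vals <- vapply(mins, function(m) {
    v <- afr$afr[match(m, afr$minute)]
    if (!is.na(v)) return(v)
    nearest <- obs[which.min(abs(obs - m))] # which.min takes the earlier tie
    afr$afr[match(nearest, afr$minute)]
  }, 0)
  mean(vals) / 60
}

#' Full preprocessing of one recording
#'
#' Segments the beat series, applies the beat-count filter, attaches the
#' per-segment Poisson rate, and evaluates the 12-h duration rule.
#'
#' @param beat_times Beat times (ms).
#' @param afr AFR trend data frame.
#' @param duration Recording duration (ms), defaulting to the last beat.
#' @return List with \code{segments} (filtered, rates attached) and
#'   \code{patient_included}.
#' @export
preprocess_recording <- function(beat_times, afr, duration = NULL) {
  segs <- segment_series(beat_times, duration)
  segs <- lapply(segs, apply_beat_count_filter)
  segs <- lapply(segs, function(s) {
    if (s$included) s$lambda_hat <- lambda_for_segment(afr, s)
    s
  })
  list(segments = segs, patient_included = apply_duration_filter(segs))
}

#' Segment table for reporting
#'
#' @param segments List of segments.
#' @return Data frame with one row per segment (index, start, end, n_beats,
#'   included, reason, lambda_hat).
#' @export
segment_table <- function(segments) {
  data.frame(
    index = vapply(segments, `[[`, 0, "index"),
    start_ms = vapply(segments, `[[`, 0, "start"),
    end_ms = vapply(segments, `[[`, 0, "end"),
    n_beats = vapply(segments, function(s) length(s$beat_times), 0L),
    included = vapply(segments, `[[`, TRUE, "included"),
    reason = vapply(segments, `[[`, "", "reason"),
    lambda_hat = vapply(segments, `[[`, 0, "lambda_hat"))
}

#' Relative 24-h heart-rate change between two recordings
#'
#' \code{100 * (HR_base - HR_drug) / HR_base}, with HR the average heart rate
#' over the recording computed as \code{60000 * n / sum(rr)}. Positive values
#' mean the drug reduced the heart rate.
#'
#' @param rr_baseline,rr_drug RR-interval vectors (ms).
#' @return Percent change.
#' @export
delta_hr <- function(rr_baseline, rr_drug) {
  if (!length(rr_baseline) || !length(rr_drug))
    stop("both RR series must be non-empty")
  hr <- function(rr) 60000 * length(rr) / sum(rr)
  100 * (hr(rr_baseline) - hr(rr_drug)) / hr(rr_baseline)
}
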