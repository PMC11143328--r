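#' Detect calcium events on a smoothed dF/F trace
#'
#' Finds local maxima whose height and topographic prominence both reach
#' their thresholds (default 0.09 dF/F each, roughly one SD of the
#' pre-stimulus baseline at these recording conditions). Prominence of a
#' peak is its height minus the higher of the two saddle minima found by
#' walking from the peak towards higher ground (or the trace end) on each
#' side. Plateau maxima are reported at their earliest frame; trace
#' endpoints are never peaks.
#'
#' @param trace A `dff_trace` (from [compute_dff()] / [smooth_dff()]) or a
#'   numeric dF/F vector.
#' @param frame_rate Frames per second; required when `trace` is a bare
#'   numeric vector.
#' @param threshold Minimum peak height (dF/F).
#' @param prominence Minimum topographic prominence (dF/F).
#' @return data.frame with one row per event: `frame` (1-based), `time`
#'   (s from trace start), `amplitude` (dF/F at the peak sample) and
#'   `prominence`. Zero rows when nothing crosses threshold.
#' @export
detect_events <- function(trace, frame_rate = NULL,
                          threshold = 0.09, prominence = 0.09) {
  if (inherits(trace, "dff_trace")) {
    v <- trace$values
    frame_rate <- trace$frame_rate
  } else v <- trace
  stopifnot(is.numeric(v), !is.null(frame_rate))
  if (threshold <= 0 || prominence <= 0)
    stop("threshold and prominence must be > 0")
  pk <- local_maxima(v)
  pk <- pk[v[pk] >= threshold]
  if (length(pk) == 0L)
    return(data.frame(frame = integer(), time = numeric(),
                      amplitude = numeric(), prominence = numeric()))
  prom <- vapply(pk, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= prominence
  pk <- pk[keep]; prom <- prom[keep]
  data.frame(frame = pk, time = (pk - 1) / frame_rate,
             amplitude = v[pk], prominence = prom)
}

# Indices of strict local maxima; a plateau counts once, at its first
# sample. Boundary runs are excluded.
local_maxima <- function(v) {
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-nr]))
  j <- 2:(nr - 1L)
  is_peak <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  starts[j][is_peak]
}

# Topographic prominence of the peak at index i: on each side walk until a
# strictly higher sample (or the trace end) and take the minimum over the
# stretch; prominence = height minus the larger of the two minima.
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i == 1L) h else {
    higher <- which(v[seq_len(i - 1L)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(v[lo:(i - 1L)])
  }
  n <- length(v)
  right <- if (i == n) h else {
    seg <- v[(i + 1L):n]
    higher <- which(seg > h)
    hi <- if (length(higher)) min(higher) - 1L else length(seg)
    min(seg[seq_len(hi)])
  }
  h - max(left, right)
}

#' Classify one trial against the response window
#'
#' A trial is responsive when at least one detected event peak falls inside
#' the half-open response window `[stim_time, stim_time + window_len)`
#' (default 200 ms, which covers the 70 ms PF stimulus train and leaves
#' time for the response to build). The maximum dF/F inside the window is
#' recorded from the trace regardless of detection, for analyses that use
#' max-in-window amplitudes.
#'
#' @param trace A `dff_trace` or numeric dF/F vector.
#' @param stim_time Stimulus onset in seconds from trace start.
#' @param window_len Response window length in seconds (default 0.2).
#' @param frame_rate Required for bare numeric traces.
#' @param events Optional pre-computed [detect_events()] table; detection
#'   is run with default parameters when omitted.
#' @param params Optional list overriding `threshold` / `prominence`.
#' @return A list of class `trial_record`: `stim_time`, `window`, `events`
#'   (all detected events), `window_events` (those inside the window),
#'   `responsive`, `max_in_window`.
#' @export
classify_trial <- function(trace, stim_time, window_len = 0.2,
                           frame_rate = NULL, events = NULL,
                           params = list()) {
  if (inherits(trace, "dff_trace")) {
    v <- trace$values
    frame_rate <- trace$frame_rate
  } else v <- trace
  stopifnot(!is.null(frame_rate))
  trial_len <- length(v) / frame_rate
  if (stim_time < 0 || stim_time >= trial_len)
    stop("stim_time lies outside the trial bounds [0, ", trial_len, ")")
  if (is.null(events)) {
    events <- detect_events(v, frame_rate,
                            threshold = params$threshold %||% 0.09,
                            prominence = params$prominence %||% 0.09)
  }
  in_win <- events$time >= stim_time & events$time < stim_time + window_len
  ft <- (seq_along(v) - 1) / frame_rate
  widx <- which(ft >= stim_time & ft < stim_time + window_len)
  structure(list(
    stim_time = stim_time,
    window = c(stim_time, stim_time + window_len),
    events = events,
    window_events = events[in_win, , drop = FALSE],
    responsive = any(in_win),
    max_in_window = if (length(widx)) max(v[widx]) else NA_real_
  ), class = "trial_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shuffled-window null for spontaneous events
#'
#' Estimates the spontaneous event probability by drawing `n_windows`
#' windows of `window_len` seconds (with replacement) uniformly from the
#' pre-stimulus period, by default -4.5 to -0.5 s relative to stimulus
#' onset, and counting the fraction that contain at least one detected
#' event peak. This is the null against which evoked response probabilities
#' are compared.
#'
#' @param traces List of dF/F traces (numeric vectors or `dff_trace`s), one
#'   per trial.
#' @param frame_rate Frames per second (ignored for `dff_trace` input).
#' @param stim_time Stimulus onset (s) the sampling range is anchored to.
#' @param n_windows Number of windows; defaults to the number of trials,
#'   matching one shuffled window per stimulus trial.
#' @param window_len Window length in seconds (default 0.2).
#' @param sample_range Two-element range, seconds relative to stimulus
#'   onset, from which window *contents* are drawn (default `c(-4.5, -0.5)`;
#'   window starts are drawn so the whole window stays inside the range).
#' @param seed Integer seed; fixed seed gives bit-identical draws.
#' @param threshold,prominence Detection parameters.
#' @return A list of class `event_stats` with `probability`, `n_trials`
#'   (= `n_windows`), `amplitude_mean = NA`, `mode = "shuffled"`.
#' @export
shuffled_null <- function(traces, frame_rate = NULL, stim_time,
                          n_windows = NULL, window_len = 0.2,
                          sample_range = c(-4.5, -0.5), seed = 1L,
                          threshold = 0.09, prominence = 0.09) {
  vals <- lapply(traces, function(tr)
    if (inherits(tr, "dff_trace")) tr$values else tr)
  if (is.null(frame_rate)) {
    fr <- traces[[1]]
    stopifnot(inherits(fr, "dff_trace"))
    frame_rate <- fr$frame_rate
  }
  lo <- stim_time + sample_range[1]
  hi <- stim_time + sample_range[2] - window_len
  trial_len <- length(vals[[1]]) / frame_rate
  if (lo < 0 || stim_time + sample_range[2] > trial_len)
    stop("sampling range extends outside the trial")
  if (hi < lo) stop("sampling range shorter than the window")
  if (is.null(n_windows)) n_windows <- length(vals)
  peaks <- lapply(vals, function(v)
    detect_events(v, frame_rate, threshold, prominence)$time)
  set.seed(seed)
  trial_idx <- sample.int(length(vals), n_windows, replace = TRUE)
  starts <- stats::runif(n_windows, lo, hi)
  hit <- vapply(seq_len(n_windows), function(k) {
    p <- peaks[[trial_idx[k]]]
    any(p >= starts[k] & p < starts[k] + window_len)
  }, logical(1))
  structure(list(probability = mean(hit), amplitude_mean = NA_real_,
                 n_trials = n_windows, mode = "shuffled"),
            class = "event_stats")
}

#' Summarise trials into per-condition event statistics
#'
#' Probability is the number of responsive trials divided by the total
#' number of trials. Amplitude is summarised in one of two conventions:
#' `"peak_amplitude"` (PF and climbing-fibre analyses) averages the
#' detected peak amplitude over responsive trials only, taking the largest
#' detected peak inside the window when a spontaneous event also falls
#' there; `"max_in_window"` (tactile and compartment analyses, where
#' slow low-amplitude responses defeat peak detection) averages the maximum
#' dF/F inside the window over all trials. Amplitudes of individual trials
#' are averaged — never the peak of a trial-averaged trace.
#'
#' @param records List of `trial_record`s from [classify_trial()].
#' @param mode `"peak_amplitude"` or `"max_in_window"`.
#' @return A list of class `event_stats`: `probability`, `amplitude_mean`,
#'   `n_trials`, `mode`.
#' @export
summarize_trials <- function(records,
                             mode = c("peak_amplitude", "max_in_window")) {
  mode <- match.arg(mode)
  if (length(records) == 0L) stop("at least one trial is required")
  resp <- vapply(records, `[[`, logical(1), "responsive")
  amp <- switch(mode,
    peak_amplitude = {
      a <- vapply(records, function(r)
        if (r$responsive) max(r$window_events$amplitude) else NA_real_,
        numeric(1))
      if (any(resp)) mean(a[resp]) else NA_real_
    },
    max_in_window = mean(vapply(records, `[[`, numeric(1), "max_in_window"))
  )
  structure(list(probability = mean(resp), amplitude_mean = amp,
                 n_trials = length(records), mode = mode),
            class = "event_stats")
}

#' Classify every trial of a synthetic or loaded session
#'
#' Convenience wrapper: runs [classify_trial()] over all traces of an
#' `rf_session` (or a plain list of traces plus a trials table).
#'
#' @param session An `rf_session` from [generate_trial_session()].
#' @param window_len Response window (s).
#' @param smooth_window Moving-mean width applied before detection (frames);
#'   `NULL` skips smoothing.
#' @param threshold,prominence Detection parameters.
#' @return List of `trial_record`s, in trial order.
#' @export
classify_session <- function(session, window_len = 0.2, smooth_window = 5L,
                             threshold = 0.09, prominence = 0.09) {
  stopifnot(inherits(session, "rf_session"))
  fr <- session$config$frame_rate
  lapply(seq_along(session$traces), function(i) {
    v <- session$traces[[i]]
    if (!is.null(smooth_window)) v <- smooth_dff(v, smooth_window)
    classify_trial(v, session$trials$stim_time[i], window_len,
                   frame_rate = fr,
                   params = list(threshold = threshold,
                                 prominence = prominence))
  })
}
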