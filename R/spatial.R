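#' Extract a linescan response profile
#'
#' Reduces a pixels-by-frames linescan dF/F map to one response value per
#' pixel: the maximum dF/F inside the response window of each trial,
#' averaged across trials.
#'
#' @param linescan Numeric matrix, pixels (rows) by frames (columns), of
#'   dF/F values for a session.
#' @param frame_rate Frames per second.
#' @param stim_times Stimulus onsets in seconds of session time, one per
#'   trial.
#' @param window_len Response window length (s), default 0.2.
#' @param pixel_len Pixel spacing in micrometres, attached to the result.
#' @return Numeric per-pixel profile with attribute `pixel_len`.
#' @export
extract_profile <- function(linescan, frame_rate, stim_times,
                            window_len = 0.2, pixel_len = 15) {
  stopifnot(is.matrix(linescan))
  if (length(stim_times) == 0L) stop("at least one trial is required")
  ft <- (seq_len(ncol(linescan)) - 1) / frame_rate
  per_trial <- vapply(stim_times, function(s) {
    idx <- which(ft >= s & ft < s + window_len)
    if (!length(idx)) stop("response window outside the recording")
    apply(linescan[, idx, drop = FALSE], 1, max)
  }, numeric(nrow(linescan)))
  prof <- rowMeans(as.matrix(per_trial))
  attr(prof, "pixel_len") <- pixel_len
  prof
}

#' Normalise a pre/post profile pair to the pre-tetanus maximum
#'
#' Both profiles are divided by the maximum of the pre-tetanus profile, so
#' the pre maximum equals 1 by construction and post-tetanus potentiation
#' can exceed 1.
#'
#' @param pre,post Numeric linescan profiles (same length).
#' @return List with normalised `pre`, `post`, and the `scale` used.
#' @export
normalize_pair <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  m <- max(pre)
  if (!isTRUE(m > 0)) stop("pre-tetanus profile maximum must be positive")
  out <- list(pre = pre / m, post = post / m, scale = m)
  attr(out$pre, "pixel_len") <- attr(pre, "pixel_len")
  attr(out$post, "pixel_len") <- attr(post, "pixel_len")
  out
}

#' Cumulative dendritic length above each fluorescence level
#'
#' For each level `f` of the grid, `CL(f)` is the total dendritic length
#' (pixel count times pixel spacing) whose normalised response is at least
#' `f` — pixels are sorted by intensity and summed, disregarding their
#' position along the dendrite. `CL` is non-increasing in `f`, equals the
#' full profile length at `f = 0`, and is 0 above the profile maximum.
#'
#' @param profile Normalised per-pixel profile.
#' @param levels Fluorescence level grid; default 0 to the profile maximum
#'   in steps of 0.01.
#' @param pixel_len Pixel spacing in micrometres; taken from the profile
#'   attribute when present.
#' @return data.frame of class `cumulative_curve` with `level` and
#'   `length_um`.
#' @export
cumulative_length <- function(profile, levels = NULL, pixel_len = NULL) {
  if (length(profile) == 0L) stop("empty profile")
  if (is.null(pixel_len)) pixel_len <- attr(profile, "pixel_len") %||% 1
  if (is.null(levels)) levels <- seq(0, max(profile), by = 0.01)
  cl <- vapply(levels, function(f) pixel_len * sum(profile >= f), numeric(1))
  structure(data.frame(level = levels, length_um = cl),
            class = c("cumulative_curve", "data.frame"))
}

#' Tetanus-induced change in cumulative length
#'
#' Pointwise `post - pre` over a shared level grid, so expansion of the
#' responsive area appears as positive delta-length.
#'
#' @param pre_curve,post_curve `cumulative_curve`s on the same level grid
#'   (extend the shorter grid with zeros via `levels` when building them).
#' @param sign Either `"post_minus_pre"` (default; expansion positive) or
#'   `"pre_minus_post"` for the opposite orientation.
#' @return data.frame of class `delta_length_curve` with `level` and
#'   `delta_um`.
#' @export
delta_length <- function(pre_curve, post_curve,
                         sign = c("post_minus_pre", "pre_minus_post")) {
  sign <- match.arg(sign)
  if (nrow(pre_curve) != nrow(post_curve) ||
      any(abs(pre_curve$level - post_curve$level) > 1e-12))
    stop("pre and post curves must share the same level grid")
  d <- post_curve$length_um - pre_curve$length_um
  if (sign == "pre_minus_post") d <- -d
  structure(data.frame(level = pre_curve$level, delta_um = d),
            class = c("delta_length_curve", "data.frame"))
}

#' Hotspot and off-hotspot band summaries of a delta-length curve
#'
#' Averages delta-length over the grid levels falling in each band: the
#' hotspot band covers normalised levels strictly above 0.9 (up to 1), the
#' off-hotspot band 0.3 to 0.67 — the intermediate-fluorescence flank used
#' to quantify spread of potentiation beyond the stimulated hotspot.
#'
#' @param curve A `delta_length_curve`.
#' @param hotspot Two-element band; levels `> hotspot[1]` and
#'   `<= hotspot[2]` are included (strict lower bound).
#' @param offhotspot Two-element band, inclusive on both ends.
#' @return Named list `hotspot` / `offhotspot` of mean delta-lengths (um).
#' @export
band_metrics <- function(curve, hotspot = c(0.9, 1.0),
                         offhotspot = c(0.3, 0.67)) {
  hs <- curve$level > hotspot[1] & curve$level <= hotspot[2]
  os <- curve$level >= offhotspot[1] & curve$level <= offhotspot[2]
  if (!any(hs) || !any(os)) stop("a band contains no grid levels")
  list(hotspot = mean(curve$delta_um[hs]),
       offhotspot = mean(curve$delta_um[os]))
}

#' Exclude cells responding across the whole dendritic cross-section
#'
#' Cells whose response covers (nearly) the entire linescan cannot be split
#' into hotspot and off-hotspot regions and are removed before spatial
#' analysis. A cell is excluded when the fraction of its pixels above
#' `level` is strictly greater than `coverage`.
#'
#' @param profiles List of normalised profiles.
#' @param level Normalised fluorescence level defining "responding" pixels
#'   (default 0.9, the hotspot level).
#' @param coverage Coverage cutoff (default 0.9); cells at exactly the
#'   cutoff are retained.
#' @return Logical vector marking retained cells.
#' @export
exclude_global_responders <- function(profiles, level = 0.9,
                                      coverage = 0.9) {
  vapply(profiles, function(p) mean(p > level) <= coverage, logical(1))
}

#' Full linescan delta-length analysis for one cell
#'
#' Chains the spatial pipeline: normalise the pre/post profile pair to the
#' pre-tetanus maximum, build both cumulative-length curves on a shared
#' level grid (0 to the larger normalised maximum, step `by`), subtract
#' them, and summarise the hotspot and off-hotspot bands.
#'
#' @param pre,post Per-pixel response profiles (same length); `pixel_len`
#'   is read from the profile attribute or the argument.
#' @param pixel_len Pixel spacing in micrometres.
#' @param by Level grid step (default 0.01).
#' @param ... Passed to [band_metrics()].
#' @return List with `pre_curve`, `post_curve`, `delta` and `bands`.
#' @export
linescan_delta <- function(pre, post, pixel_len = NULL, by = 0.01, ...) {
  if (is.null(pixel_len)) pixel_len <- attr(pre, "pixel_len") %||% 1
  np <- normalize_pair(pre, post)
  levels <- seq(0, max(np$pre, np$post), by = by)
  pre_c <- cumulative_length(np$pre, levels, pixel_len)
  post_c <- cumulative_length(np$post, levels, pixel_len)
  d <- delta_length(pre_c, post_c)
  list(pre_curve = pre_c, post_curve = post_c, delta = d,
       bands = band_metrics(d, ...))
}
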