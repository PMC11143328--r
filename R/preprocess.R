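#' Circularly translate a matrix
#'
#' Moves the image down by `dy` rows and right by `dx` columns, wrapping at
#' the edges. Used both to build motion fixtures and to undo estimated
#' shifts.
#'
#' @param m Numeric matrix.
#' @param dy,dx Integer displacements (rows, columns).
#' @return The translated matrix.
#' @export
roll_matrix <- function(m, dy, dx) {
  d <- dim(m)
  ri <- ((seq_len(d[1]) - 1 - dy) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - dx) %% d[2]) + 1
  m[ri, ci, drop = FALSE]
}

#' Rigid motion correction by whole-frame cross-correlation
#'
#' Estimates an integer `(dy, dx)` displacement for every frame as the
#' argmax of its circular cross-correlation with a reference image (means
#' removed before correlating), then translates each frame back by the
#' estimated shift. This is whole-frame rigid registration: no sub-pixel
#' interpolation and no non-rigid warping.
#'
#' Frames with zero variance carry no registration signal; they are left in
#' place with shift `(0, 0)` and an `NA` correlation score.
#'
#' @param stack Numeric array `rows x cols x frames`.
#' @param reference Reference image (matrix of the same frame shape). If
#'   `NULL`, the mean of the frames in `ref_frames` is used.
#' @param ref_frames Frame indices averaged into the default reference
#'   (default: all frames; pass the first trial's frames to reproduce a
#'   baseline-anchored reference).
#' @return List with `corrected` (array like `stack`), and `shifts` — a
#'   data.frame with per-frame `dy`, `dx` and the normalised peak
#'   correlation `score`.
#' @export
motion_correct <- function(stack, reference = NULL, ref_frames = NULL) {
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  if (is.null(reference)) {
    if (is.null(ref_frames)) ref_frames <- seq_len(d[3])
    reference <- apply(stack[, , ref_frames, drop = FALSE], c(1, 2), mean)
  }
  stopifnot(all(dim(reference) == d[1:2]))
  ref0 <- reference - mean(reference)
  fr_ref <- stats::fft(ref0)
  corrected <- array(0, d)
  dy <- dx <- integer(d[3])
  score <- numeric(d[3])
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  for (k in seq_len(d[3])) {
    fr <- stack[, , k]
    if (stats::sd(fr) == 0) {
      corrected[, , k] <- fr
      dy[k] <- 0L; dx[k] <- 0L; score[k] <- NA_real_
      next
    }
    f0 <- fr - mean(fr)
    cc <- Re(stats::fft(Conj(fr_ref) * stats::fft(f0), inverse = TRUE))
    ij <- arrayInd(which.max(cc), d[1:2])
    sy <- wrap(ij[1] - 1L, d[1])
    sx <- wrap(ij[2] - 1L, d[2])
    dy[k] <- sy; dx[k] <- sx
    # unnormalised inverse FFT: divide by the pixel count to get the true
    # circular correlation sum, then scale to a correlation coefficient
    score[k] <- max(cc) / prod(d[1:2]) /
      (sqrt(sum(ref0^2)) * sqrt(sum(f0^2)))
    corrected[, , k] <- roll_matrix(fr, -sy, -sx)
  }
  list(corrected = corrected,
       shifts = data.frame(frame = seq_len(d[3]), dy = dy, dx = dx,
                           score = score))
}

#' Compute dF/F from a raw fluorescence trace
#'
#' Baseline-normalises a raw trace as `(F_t - F0) / F0` with `F0` the 20th
#' percentile of the whole trace (linear interpolation between order
#' statistics). Intended to be applied to the concatenated-session trace of
#' each ROI so that a single baseline serves all trials; pass a per-trial
#' slice for a per-trial baseline instead.
#'
#' @param values Raw fluorescence per frame (finite, positive baseline).
#' @param frame_rate Acquisition rate in Hz (carried as metadata).
#' @param percentile Baseline percentile, default 0.20.
#' @return A list of class `dff_trace` with `values` (dF/F per frame),
#'   `f0`, and `frame_rate`.
#' @examples
#' compute_dff(c(10, 10, 10, 10, 20), frame_rate = 31)$f0
#' @export
compute_dff <- function(values, frame_rate, percentile = 0.20) {
  if (inherits(values, "dff_trace")) stop("trace is already dF/F")
  stopifnot(is.numeric(values), length(values) > 0, all(is.finite(values)))
  f0 <- unname(stats::quantile(values, percentile, type = 7))
  if (f0 <= 0) stop("baseline F0 (", percentile * 100,
                    "th percentile) must be positive")
  structure(list(values = (values - f0) / f0, f0 = f0,
                 frame_rate = frame_rate),
            class = "dff_trace")
}

#' Moving-window smoothing of a dF/F trace
#'
#' Centred moving mean of odd width `window` (default five frames, the
#' low-pass step applied before event detection). At the boundaries the
#' window shrinks to the available frames, so the trace length is preserved
#' without padding with invented data.
#'
#' @param trace A `dff_trace` or numeric vector.
#' @param window Odd window width in frames, >= 1 and <= trace length.
#' @return Same type as the input, smoothed.
#' @export
smooth_dff <- function(trace, window = 5L) {
  vals <- if (inherits(trace, "dff_trace")) trace$values else trace
  n <- length(vals)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > n) stop("window exceeds trace length")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, vals))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(trace, "dff_trace")) {
    trace$values <- sm
    trace
  } else sm
}
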