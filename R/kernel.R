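#' Unit-peak calcium indicator impulse response
#'
#' Difference-of-exponentials kernel used to render synthetic calcium events,
#' normalised so its maximum equals 1. Defaults (50 ms rise, 400 ms decay)
#' approximate a fast genetically encoded indicator such as GCaMP6f.
#'
#' @param t Time in seconds relative to event onset (vectorised). Values
#'   before onset return 0.
#' @param rise Rise time constant in seconds; must be positive and smaller
#'   than `decay`.
#' @param decay Decay time constant in seconds.
#' @return Numeric vector of kernel values with unit peak.
#' @examples
#' tt <- seq(0, 2, by = 1 / 31)
#' max(calcium_kernel(tt)) # close to 1
#' @export
calcium_kernel <- function(t, rise = 0.05, decay = 0.4) {
  stopifnot(is.numeric(rise), is.numeric(decay), rise > 0, decay > rise)
  raw <- function(x) ifelse(x < 0, 0, exp(-x / decay) - exp(-x / rise))
  peak <- raw(kernel_peak_time(rise, decay))
  raw(t) / peak
}

#' Time of the kernel maximum
#'
#' @inheritParams calcium_kernel
#' @return Peak time in seconds after event onset (closed form).
#' @export
kernel_peak_time <- function(rise = 0.05, decay = 0.4) {
  stopifnot(rise > 0, decay > rise)
  rise * decay / (decay - rise) * log(decay / rise)
}

# Render a set of events as a sampled dF/F trace. times are onsets in s,
# amps the unit-peak scaling, so the continuous-time maximum of an isolated
# event equals its amplitude (the sampled maximum is within one frame of it).
render_events <- function(times, amps, n_frames, frame_rate,
                          rise = 0.05, decay = 0.4) {
  tr <- numeric(n_frames)
  if (length(times) == 0L) return(tr)
  frame_t <- (seq_len(n_frames) - 1) / frame_rate
  for (k in seq_along(times)) {
    tr <- tr + amps[k] * calcium_kernel(frame_t - times[k], rise, decay)
  }
  tr
}
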