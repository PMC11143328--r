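#' Classify a cell as stimulus-intensity dependent or independent
#'
#' Computes the Pearson correlation between a cell's five response values
#' (spontaneous plus four ascending stimulus intensities) and the condition
#' rank 0..4, then labels the cell `dependent` when `r > r_cutoff` and the
#' correlation-test p-value is below `p_cutoff`. Ranks rather than physical
#' intensities are used on the x-axis so that current (uA) and pressure
#' (psi) designs are treated identically; Pearson `r` is invariant to any
#' affine rescaling of the responses, so raw and normalised response values
#' give the same label.
#'
#' The conventional `p_cutoff` default is 0.05; the permissive 0.5 used in
#' the original classification is available by argument.
#'
#' @param responses Numeric length-5 vector: spontaneous followed by the
#'   four intensities in ascending order (probability or amplitude).
#' @param r_cutoff Correlation threshold (default 0.5).
#' @param p_cutoff Significance threshold (default 0.05).
#' @return A list of class `dependence_label`: `r`, `p`, `label`, and
#'   `degenerate` (TRUE when the responses had zero variance, in which case
#'   the cell is labelled independent).
#' @export
classify_dependence <- function(responses, r_cutoff = 0.5, p_cutoff = 0.05) {
  if (length(responses) != 5L)
    stop("exactly five points required: spontaneous + four intensities")
  x <- 0:4
  if (stats::sd(responses) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, label = "independent",
                          degenerate = TRUE), class = "dependence_label"))
  }
  ct <- stats::cor.test(x, responses, method = "pearson")
  r <- unname(ct$estimate)
  structure(list(
    r = r, p = ct$p.value,
    label = if (r > r_cutoff && ct$p.value < p_cutoff) "dependent"
            else "independent",
    degenerate = FALSE
  ), class = "dependence_label")
}

#' Normalise post-tetanus responses to the pre-tetanus baseline
#'
#' Divides each post-tetanus amplitude and probability by the pre-tetanus
#' value, so the baseline maps to 1 and potentiation appears as values
#' above 1.
#'
#' @param pre,early_post,late_post `event_stats` objects (see
#'   [summarize_trials()]), all with the same amplitude mode.
#' @return A list of class `plasticity_result` with `normalized` — a
#'   data.frame of `condition`, `amplitude`, `probability` — plus the raw
#'   `pre_amplitude` and `pre_probability`.
#' @export
normalize_to_baseline <- function(pre, early_post, late_post) {
  for (s in list(pre, early_post, late_post))
    stopifnot(inherits(s, "event_stats"))
  if (!isTRUE(pre$amplitude_mean > 0) || !isTRUE(pre$probability > 0))
    stop("pre-tetanus amplitude and probability must be positive; ",
         "cell excluded from normalized analyses")
  norm <- data.frame(
    condition = c("pre", "early_post", "late_post"),
    amplitude = c(1, early_post$amplitude_mean / pre$amplitude_mean,
                  late_post$amplitude_mean / pre$amplitude_mean),
    probability = c(1, early_post$probability / pre$probability,
                    late_post$probability / pre$probability)
  )
  structure(list(normalized = norm,
                 pre_amplitude = pre$amplitude_mean,
                 pre_probability = pre$probability),
            class = "plasticity_result")
}

#' Convert a window probability to an event rate
#'
#' Linear conversion `rate = P / window`: the spontaneous window
#' probability of 0.22 in a 200 ms window corresponds to 1.1 Hz, and evoked
#' probabilities of 0.25-0.37 to 1.25-1.85 Hz.
#'
#' @param p Probability in \[0, 1\].
#' @param window Window length in seconds (> 0), default 0.2.
#' @return Rate in Hz.
#' @examples
#' rate_from_probability(0.22) # 1.1 Hz
#' @export
rate_from_probability <- function(p, window = 0.2) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (window <= 0) stop("window must be > 0")
  p / window
}

#' Select weak tactile responders
#'
#' Keeps cells whose pre-tetanus mean max-in-window amplitude is strictly
#' below `factor * inclusion_criterion` (default 2 x 0.9 = 1.8 dF/F) —
#' cells with no reliable tactile response at baseline, the population in
#' which de-novo receptive-field recruitment is assessed.
#'
#' @param amplitudes Named or plain numeric vector of per-cell pre-tetanus
#'   mean max-in-window amplitudes (dF/F).
#' @param inclusion_criterion Calcium-event inclusion criterion (dF/F),
#'   default 0.9.
#' @param factor Multiplier on the criterion, default 2.
#' @return Logical vector marking retained (weak-responder) cells.
#' @export
weak_responder_filter <- function(amplitudes, inclusion_criterion = 0.9,
                                  factor = 2) {
  stopifnot(is.numeric(amplitudes))
  amplitudes < factor * inclusion_criterion
}
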