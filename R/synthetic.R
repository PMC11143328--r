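#' Configuration for a synthetic imaging session
#'
#' Bundles the trial structure and statistical parameters used by the
#' session generators. The defaults reproduce the electrical parallel-fibre
#' (PF) protocol: 10 s trials imaged at 31 Hz with the stimulus at the 5 s
#' mark; the tactile protocol uses 20 s trials at 62 Hz with the stimulus at
#' 10 s (see [tactile_config()]). Spontaneous dendritic events occur as a
#' homogeneous Poisson process at 1.1 Hz; evoked events occur on each trial
#' as an at-most-one Bernoulli draw whose probability and peak amplitude
#' rise with stimulus intensity.
#'
#' @param n_trials Trials per stimulus intensity (default 12, the upper end
#'   of the 10-12 trials per 20 min block used in vivo).
#' @param frame_rate Imaging frame rate in Hz.
#' @param trial_len Trial duration in seconds.
#' @param stim_time Stimulus onset in seconds from trial start.
#' @param spont_rate Spontaneous event rate lambda in Hz.
#' @param intensities Stimulus intensities (uA for PF, psi for tactile);
#'   labels only, responses are read from the two maps below.
#' @param evoked_prob Probability of an evoked response per trial, one value
#'   per intensity, each in \[0, 1\].
#' @param evoked_amp Peak dF/F of the evoked event, one value per intensity.
#' @param kernel_rise,kernel_decay Event kernel time constants in seconds.
#' @param latency Mean evoked-response latency after stimulus onset (s).
#' @param latency_jitter_sd SD of the Gaussian latency jitter (s). Set to 0
#'   for frame-locked responses.
#' @param spont_amp_mean,spont_amp_sd Mean and SD of spontaneous event
#'   amplitudes (dF/F); draws are truncated below at 0.2 so every rendered
#'   event clears the 0.09 detection threshold.
#' @param noise_sd SD of the additive Gaussian noise, in dF/F units.
#' @param seed Integer seed; a fixed seed gives bit-identical sessions.
#' @return A list of class `sim_config`.
#' @seealso [generate_trial_session()], [generate_plasticity_session()]
#' @export
sim_config <- function(n_trials = 12,
                       frame_rate = 31,
                       trial_len = 10,
                       stim_time = 5,
                       spont_rate = 1.1,
                       intensities = c(10, 20, 30, 50),
                       evoked_prob = c(0.25, 0.29, 0.33, 0.37),
                       evoked_amp = c(1.0, 1.15, 1.3, 1.45),
                       kernel_rise = 0.05,
                       kernel_decay = 0.4,
                       latency = 0.03,
                       latency_jitter_sd = 0.01,
                       spont_amp_mean = 1.0,
                       spont_amp_sd = 0.3,
                       noise_sd = 0.05,
                       seed = 1L) {
  if (!is.finite(spont_rate) || spont_rate < 0)
    stop("spont_rate must be finite and >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be finite and >= 0")
  if (any(!is.finite(evoked_prob)) || any(evoked_prob < 0) || any(evoked_prob > 1))
    stop("evoked_prob values must lie in [0, 1]")
  if (length(evoked_prob) != length(intensities) ||
      length(evoked_amp) != length(intensities))
    stop("evoked_prob and evoked_amp must have one value per intensity")
  if (!(stim_time < trial_len) || stim_time < 0)
    stop("stim_time must lie within [0, trial_len)")
  if (frame_rate <= 0 || trial_len <= 0) stop("frame_rate and trial_len must be > 0")
  if (latency < 0 || latency_jitter_sd < 0) stop("latency parameters must be >= 0")
  cfg <- list(
    n_trials = as.integer(n_trials), frame_rate = frame_rate,
    trial_len = trial_len, stim_time = stim_time, spont_rate = spont_rate,
    intensities = intensities, evoked_prob = evoked_prob,
    evoked_amp = evoked_amp, kernel_rise = kernel_rise,
    kernel_decay = kernel_decay, latency = latency,
    latency_jitter_sd = latency_jitter_sd,
    spont_amp_mean = spont_amp_mean, spont_amp_sd = spont_amp_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Tactile (airpuff) protocol configuration
#'
#' Convenience wrapper around [sim_config()] with the tactile trial
#' structure: 20 s trials at 62 Hz, a 30 ms airpuff at the 10 s mark, and
#' pressures of 4-10 psi whose response probability rises linearly from
#' 0.25 to 0.37 (spontaneous window probability ~0.22).
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
tactile_config <- function(...) {
  defaults <- list(
    frame_rate = 62, trial_len = 20, stim_time = 10,
    intensities = c(4, 6, 8, 10),
    evoked_prob = c(0.25, 0.29, 0.33, 0.37),
    evoked_amp = c(0.9, 1.0, 1.1, 1.2)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Plasticity regime specification
#'
#' Encodes which potentiation mechanisms a synthetic cell expresses, as
#' multiplicative gains applied to the post-tetanus sessions. `hotspot_gain`
#' scales the response inside the stimulated-input hotspot (synaptic
#' potentiation), `offhotspot_gain` scales the rest of the dendritic
#' cross-section (the widespread amplification attributed to intrinsic
#' excitability), and `probability_gain` scales the per-trial evoked
#' response probability.
#'
#' Presets mimic the study's three mechanistic pictures: `"both"`
#' (wild-type-like: local plus widespread potentiation), `"local_only"`
#' (synaptic mechanism intact, no spread), `"global_only"` (modest hotspot
#' change, widespread gain) and `"control"` (no tetanus effect).
#'
#' @param name One of `"both"`, `"local_only"`, `"global_only"`, `"control"`.
#' @param hotspot_gain,offhotspot_gain,probability_gain Optional numeric
#'   overrides of the preset gains.
#' @return A list of class `regime_spec`.
#' @export
regime_spec <- function(name = c("both", "local_only", "global_only", "control"),
                        hotspot_gain = NULL, offhotspot_gain = NULL,
                        probability_gain = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    both        = list(hotspot_gain = 1.5, offhotspot_gain = 1.3, probability_gain = 1.2),
    local_only  = list(hotspot_gain = 1.5, offhotspot_gain = 1.0, probability_gain = 1.1),
    global_only = list(hotspot_gain = 1.1, offhotspot_gain = 1.3, probability_gain = 1.2),
    control     = list(hotspot_gain = 1.0, offhotspot_gain = 1.0, probability_gain = 1.0)
  )
  if (!is.null(hotspot_gain)) preset$hotspot_gain <- hotspot_gain
  if (!is.null(offhotspot_gain)) preset$offhotspot_gain <- offhotspot_gain
  if (!is.null(probability_gain)) preset$probability_gain <- probability_gain
  if (name == "control" &&
      any(unlist(preset) != 1)) stop("control regime must have all gains = 1")
  if (name == "local_only" && preset$offhotspot_gain != 1)
    stop("local_only regime requires offhotspot_gain = 1")
  if (any(unlist(preset) < 0)) stop("gains must be >= 0")
  structure(c(list(name = name), preset), class = "regime_spec")
}

# Draw one trial's worth of ground-truth events.
draw_trial_events <- function(cfg, prob, amp) {
  n_spont <- stats::rpois(1, cfg$spont_rate * cfg$trial_len)
  times <- sort(stats::runif(n_spont, 0, cfg$trial_len))
  amps <- pmax(0.2, stats::rnorm(n_spont, cfg$spont_amp_mean, cfg$spont_amp_sd))
  kind <- rep("spontaneous", n_spont)
  evoked <- stats::runif(1) < prob
  if (evoked) {
    t_ev <- cfg$stim_time + cfg$latency +
      stats::rnorm(1, 0, cfg$latency_jitter_sd)
    t_ev <- min(max(t_ev, cfg$stim_time), cfg$trial_len - 1 / cfg$frame_rate)
    times <- c(times, t_ev)
    amps <- c(amps, amp)
    kind <- c(kind, "evoked")
  }
  data.frame(time = times, amplitude = amps, kind = kind,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic trial session with ground truth
#'
#' Simulates `n_trials` trials per stimulus intensity. Each trial contains
#' homogeneous-Poisson spontaneous events at `spont_rate` plus, with the
#' intensity's evoked probability, a single time-locked evoked event at
#' `stim_time + latency`. Events are rendered as unit-peak
#' difference-of-exponentials kernels scaled by their amplitude, and
#' Gaussian noise of SD `noise_sd` is added. Traces are emitted directly on
#' the dF/F scale (they model the post-preprocessing signal).
#'
#' @param config A [sim_config()].
#' @param intensities Optional subset of `config$intensities` to simulate.
#' @return A list of class `rf_session` with elements
#'   \describe{
#'     \item{traces}{list of numeric dF/F traces, one per trial}
#'     \item{trials}{data.frame with `trial`, `intensity`, `stim_time`,
#'       and the ground-truth `evoked` flag}
#'     \item{ground_truth}{data.frame of true event times (onsets, s),
#'       amplitudes and kinds, keyed by trial}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' s <- generate_trial_session(sim_config(n_trials = 2, seed = 7))
#' length(s$traces)
#' @export
generate_trial_session <- function(config, intensities = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(intensities)) intensities <- config$intensities
  idx <- match(intensities, config$intensities)
  if (anyNA(idx)) stop("unknown intensity requested")
  set.seed(config$seed)
  n_frames <- round(config$trial_len * config$frame_rate)
  traces <- list()
  trials <- list()
  events <- list()
  trial_id <- 0L
  for (i in idx) {
    for (k in seq_len(config$n_trials)) {
      trial_id <- trial_id + 1L
      ev <- draw_trial_events(config, config$evoked_prob[i], config$evoked_amp[i])
      tr <- render_events(ev$time, ev$amplitude, n_frames, config$frame_rate,
                          config$kernel_rise, config$kernel_decay)
      if (config$noise_sd > 0)
        tr <- tr + stats::rnorm(n_frames, 0, config$noise_sd)
      traces[[trial_id]] <- tr
      trials[[trial_id]] <- data.frame(
        trial = trial_id, intensity = config$intensities[i],
        stim_time = config$stim_time, evoked = any(ev$kind == "evoked")
      )
      if (nrow(ev) > 0) events[[trial_id]] <- cbind(trial = trial_id, ev)
    }
  }
  out <- list(
    traces = traces,
    trials = do.call(rbind, trials),
    ground_truth = if (length(events)) do.call(rbind, events) else
      data.frame(trial = integer(), time = numeric(),
                 amplitude = numeric(), kind = character()),
    config = config
  )
  class(out) <- "rf_session"
  out
}

#' Generate a pre / early-post / late-post plasticity experiment
#'
#' Mirrors the tetanisation protocol: a baseline block followed by two
#' post-tetanus blocks. Post-tetanus sessions have their evoked amplitude
#' multiplied by the regime's `hotspot_gain` (the dendritic ROI signal is
#' dominated by the stimulated hotspot) and their evoked probability
#' multiplied by `probability_gain` (capped at 1). The pre session always
#' uses unit gains. Each session draws from its own reproducible stream
#' keyed by `(seed, session index)`.
#'
#' @param config A [sim_config()]; its first intensity is used as the test
#'   stimulus (the protocol tests a single intermediate intensity).
#' @param regime A [regime_spec()].
#' @return List with `pre`, `early_post`, `late_post` (each an
#'   `rf_session`) and `ground_truth` holding the regime and the applied
#'   amplitude/probability gains.
#' @export
generate_plasticity_session <- function(config, regime) {
  stopifnot(inherits(config, "sim_config"), inherits(regime, "regime_spec"))
  test_int <- config$intensities[1]
  amp_gain <- regime$hotspot_gain
  prob_gain <- regime$probability_gain
  session_cfg <- function(gain_a, gain_p, offset) {
    cfg <- config
    cfg$intensities <- test_int
    cfg$evoked_amp <- config$evoked_amp[1] * gain_a
    cfg$evoked_prob <- min(1, config$evoked_prob[1] * gain_p)
    cfg$seed <- config$seed + offset
    class(cfg) <- "sim_config"
    cfg
  }
  pre <- generate_trial_session(session_cfg(1, 1, 0L))
  early <- generate_trial_session(session_cfg(amp_gain, prob_gain, 1L))
  late <- generate_trial_session(session_cfg(amp_gain, prob_gain, 2L))
  list(
    pre = pre, early_post = early, late_post = late,
    ground_truth = list(regime = regime, amplitude_gain = amp_gain,
                        probability_gain = prob_gain,
                        pre_amp = config$evoked_amp[1],
                        pre_prob = config$evoked_prob[1])
  )
}

#' Generate a pre/post linescan profile pair with a localised hotspot
#'
#' Builds a dendritic cross-section fluorescence profile: a flat baseline
#' plus a Gaussian bump whose peak defines the stimulated-input hotspot.
#' The post-tetanus profile multiplies hotspot pixels (those above 0.9 of
#' the pre-tetanus maximum, the same rule the spatial analysis uses) by
#' `hotspot_gain` and all remaining pixels by `offhotspot_gain`, then adds
#' Gaussian noise.
#'
#' @param n_pixels Number of linescan pixels.
#' @param pixel_len Pixel spacing in micrometres (default 15, the reslice
#'   output spacing used for Purkinje cell cross-sections).
#' @param hotspot_center Bump centre, 0-based pixel index.
#' @param hotspot_width Bump SD in pixels; must be > 0.
#' @param regime A [regime_spec()].
#' @param seed Integer seed.
#' @param baseline Baseline dF/F far from the hotspot.
#' @param peak Pre-tetanus bump peak dF/F.
#' @param noise_sd Additive noise SD (dF/F).
#' @return List with `pre`, `post` (numeric profiles), `pixel_len`, and
#'   `ground_truth` (hotspot mask and gains).
#' @export
generate_linescan_pair <- function(n_pixels = 40, pixel_len = 15,
                                   hotspot_center = floor(n_pixels / 2),
                                   hotspot_width = 2, regime,
                                   seed = 1L, baseline = 0.2, peak = 1.0,
                                   noise_sd = 0.02) {
  stopifnot(inherits(regime, "regime_spec"))
  if (hotspot_width <= 0) stop("hotspot_width must be > 0")
  if (hotspot_center < 0 || hotspot_center >= n_pixels)
    stop("hotspot_center must lie in [0, n_pixels)")
  set.seed(seed)
  x <- seq_len(n_pixels) - 1
  pre <- baseline + (peak - baseline) *
    exp(-((x - hotspot_center)^2) / (2 * hotspot_width^2))
  hot <- pre > 0.9 * max(pre)
  post <- pre * ifelse(hot, regime$hotspot_gain, regime$offhotspot_gain)
  if (noise_sd > 0) post <- post + stats::rnorm(n_pixels, 0, noise_sd)
  list(pre = pre, post = post, pixel_len = pixel_len,
       ground_truth = list(hotspot = hot, regime = regime))
}

#' Generate a rigidly shifted movie with known per-frame shifts
#'
#' Each frame is the base image circularly translated by the requested
#' integer `(dy, dx)` shift, plus optional Gaussian noise — the fixture for
#' motion-correction round-trip tests.
#'
#' @param base_image Numeric matrix.
#' @param shifts Integer matrix or 2-column data.frame of `(dy, dx)` per
#'   frame; each must be within a quarter of the image extent.
#' @param noise_sd Additive noise SD, in image intensity units.
#' @param seed Integer seed.
#' @return List with `stack` (rows x cols x frames array) and `true_shifts`.
#' @export
generate_movie <- function(base_image, shifts, noise_sd = 0, seed = 1L) {
  shifts <- as.matrix(shifts)
  stopifnot(is.matrix(base_image), ncol(shifts) == 2)
  d <- dim(base_image)
  if (any(abs(shifts[, 1]) > d[1] / 4) || any(abs(shifts[, 2]) > d[2] / 4))
    stop("shifts must be within a quarter of the image extent")
  set.seed(seed)
  n <- nrow(shifts)
  stack <- array(0, c(d[1], d[2], n))
  for (k in seq_len(n)) {
    fr <- roll_matrix(base_image, shifts[k, 1], shifts[k, 2])
    if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(prod(d), 0, noise_sd), d[1], d[2])
    stack[, , k] <- fr
  }
  list(stack = stack, true_shifts = shifts)
}

#' Generate correlated dendrite / soma / AIS amplitude sets
#'
#' Draws per-cell maximum response amplitudes for the three compartments.
#' Soma and axon-initial-segment (AIS) amplitudes share a latent component
#' with the dendrite so that each pair has population Pearson correlation
#' `target_r`.
#'
#' @param n_cells Number of cells.
#' @param target_r Target Pearson correlation, in \[-1, 1\].
#' @param seed Integer seed.
#' @param mean_amp,sd_amp Marginal mean and SD of each compartment (dF/F).
#' @return data.frame with columns `cell`, `dendrite`, `soma`, `ais`, and
#'   attribute `target_r`.
#' @export
generate_compartment_data <- function(n_cells, target_r, seed = 1L,
                                      mean_amp = 2, sd_amp = 0.6) {
  if (!is.finite(target_r) || abs(target_r) > 1)
    stop("target_r must lie in [-1, 1]")
  set.seed(seed)
  zd <- stats::rnorm(n_cells)
  mix <- function(z) target_r * zd + sqrt(1 - target_r^2) * z
  out <- data.frame(
    cell = seq_len(n_cells),
    dendrite = mean_amp + sd_amp * zd,
    soma = mean_amp + sd_amp * mix(stats::rnorm(n_cells)),
    ais = mean_amp + sd_amp * mix(stats::rnorm(n_cells))
  )
  attr(out, "target_r") <- target_r
  out
}

#' Duration spanned by a stimulus pulse train
#'
#' For a train of `n_pulses` delivered at `freq_hz`, the first and last
#' pulse onsets are `(n_pulses - 1) / freq_hz` seconds apart. The PF test
#' stimulus — eight pulses at 100 Hz — spans 70 ms.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param freq_hz Pulse rate in Hz.
#' @return Span in seconds.
#' @examples
#' stim_train_span(8, 100) # 0.07 s
#' @export
stim_train_span <- function(n_pulses, freq_hz) {
  stopifnot(n_pulses >= 1, freq_hz > 0)
  (n_pulses - 1) / freq_hz
}
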