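test_that("degenerate limits give exactly one time-locked event per trial", {
  cfg <- sim_config(n_trials = 8, spont_rate = 0, noise_sd = 0,
                    latency_jitter_sd = 0, intensities = 30,
                    evoked_prob = 1, evoked_amp = 1, seed = 3)
  s <- generate_trial_session(cfg)
  counts <- table(factor(s$ground_truth$trial, levels = 1:8))
  expect_true(all(counts == 1))
  expect_true(all(s$ground_truth$kind == "evoked"))
  expect_equal(unique(s$ground_truth$time), cfg$stim_time + cfg$latency)
})

test_that("fixed seed gives bit-identical sessions", {
  cfg <- sim_config(n_trials = 3, seed = 42)
  expect_identical(generate_trial_session(cfg), generate_trial_session(cfg))
  r <- regime_spec("both")
  expect_identical(generate_plasticity_session(cfg, r),
                   generate_plasticity_session(cfg, r))
  expect_identical(generate_linescan_pair(regime = r, seed = 9),
                   generate_linescan_pair(regime = r, seed = 9))
})

test_that("pre-stimulus window occupancy matches the Poisson closed form", {
  # P(>= 1 event in a 200 ms window) = 1 - exp(-0.2 * lambda), checked on
  # ground-truth event times over many sampled windows
  lambda <- 1.1
  cfg <- sim_config(n_trials = 250, spont_rate = lambda, noise_sd = 0,
                    intensities = 30, evoked_prob = 0, evoked_amp = 1,
                    seed = 7)
  s <- generate_trial_session(cfg)
  set.seed(101)
  n_win <- 10000
  tr <- sample.int(250, n_win, replace = TRUE)
  st <- stats::runif(n_win, 0.5, 4.3)
  ev_by_trial <- split(s$ground_truth$time, s$ground_truth$trial)
  hit <- vapply(seq_len(n_win), function(k) {
    tt <- ev_by_trial[[as.character(tr[k])]]
    !is.null(tt) && any(tt >= st[k] & tt < st[k] + 0.2)
  }, logical(1))
  expected <- 1 - exp(-0.2 * lambda)
  se <- sqrt(expected * (1 - expected) / n_win)
  expect_lt(abs(mean(hit) - expected), 3 * se)
})

test_that("spontaneous event counts are Poisson (dispersion index near 1)", {
  cfg <- sim_config(n_trials = 10000, frame_rate = 2, spont_rate = 1.1,
                    trial_len = 10, stim_time = 5, noise_sd = 0,
                    intensities = 30, evoked_prob = 0, evoked_amp = 1,
                    seed = 21)
  s <- generate_trial_session(cfg)
  counts <- tabulate(s$ground_truth$trial, nbins = 10000)
  disp <- stats::var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / (10000 - 1)))
  expect_lt(abs(mean(counts) - 11), 3 * sqrt(11 / 10000))
})

test_that("rendered events are recovered by detection within one frame", {
  a <- 0.8
  tr <- calciumRF:::render_events(2.0, a, 310, 31)
  ev <- detect_events(tr, 31)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time - (2.0 + kernel_peak_time())), 1 / 31)
  # sampled peak undershoots the continuous amplitude by < one frame's
  # worth of kernel curvature
  expect_lt(a - ev$amplitude, a - a * calcium_kernel(kernel_peak_time() + 1 / 31))
  expect_gt(ev$amplitude, 0.95 * a)
})

test_that("evoked probability gain is respected in post-tetanus sessions", {
  base_p <- 0.3
  gain <- 1.2
  cfg <- sim_config(n_trials = 10000, frame_rate = 2, trial_len = 10,
                    stim_time = 5, spont_rate = 0, noise_sd = 0,
                    intensities = 30, evoked_prob = base_p, evoked_amp = 1,
                    seed = 13)
  ps <- generate_plasticity_session(cfg, regime_spec("both",
                                                     probability_gain = gain))
  p_emp <- mean(ps$early_post$trials$evoked)
  p_true <- min(1, gain * base_p)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / 10000))
  expect_true(all(vapply(
    list(ps$pre, ps$early_post, ps$late_post),
    function(x) inherits(x, "rf_session"), logical(1))))
})

test_that("control regime leaves pre and post generator parameters equal", {
  cfg <- sim_config(n_trials = 4, seed = 5, intensities = 30,
                    evoked_prob = 0.4, evoked_amp = 1.2)
  ps <- generate_plasticity_session(cfg, regime_spec("control"))
  expect_equal(ps$early_post$config$evoked_amp, cfg$evoked_amp[1])
  expect_equal(ps$early_post$config$evoked_prob, cfg$evoked_prob[1])
  expect_equal(ps$ground_truth$amplitude_gain, 1)
})

test_that("linescan pair construction matches its gains", {
  ctrl <- generate_linescan_pair(regime = regime_spec("control"),
                                 seed = 2, noise_sd = 0)
  expect_identical(ctrl$pre, ctrl$post)
  g <- generate_linescan_pair(regime = regime_spec("global_only"),
                              seed = 2, noise_sd = 0)
  off <- !g$ground_truth$hotspot
  expect_equal(g$post[off] / g$pre[off],
               rep(regime_spec("global_only")$offhotspot_gain, sum(off)))
  expect_error(generate_linescan_pair(hotspot_width = 0,
                                      regime = regime_spec("both")),
               "width")
})

test_that("movie generator honours shifts and bounds", {
  base <- matrix(seq_len(36), 6, 6)
  mv <- generate_movie(base, rbind(c(0, 0), c(0, 0)), noise_sd = 0)
  expect_equal(mv$stack[, , 1], base)
  expect_equal(mv$stack[, , 2], base)
  expect_error(generate_movie(base, rbind(c(4, 0))), "quarter")
})

test_that("compartment generator hits its target correlation", {
  # noise-free coupling
  d1 <- generate_compartment_data(50, 1, seed = 1)
  expect_equal(stats::cor(d1$dendrite, d1$soma), 1)
  # independence bound
  d0 <- generate_compartment_data(10000, 0, seed = 2)
  expect_lt(abs(stats::cor(d0$dendrite, d0$ais)), 3 / sqrt(10000))
  # Fisher-z 99% interval around r = 0.6 at n = 1000
  d6 <- generate_compartment_data(1000, 0.6, seed = 3)
  z <- atanh(stats::cor(d6$dendrite, d6$soma))
  expect_lt(abs(z - atanh(0.6)), stats::qnorm(0.995) / sqrt(1000 - 3))
  expect_error(generate_compartment_data(10, 1.2), "target_r")
})

test_that("invalid configurations are rejected with messages", {
  expect_error(sim_config(spont_rate = -1), "spont_rate")
  expect_error(sim_config(noise_sd = NaN), "noise_sd")
  expect_error(sim_config(evoked_prob = c(0.5, 1.2, 0.1, 0.1)), "0, 1")
  expect_error(sim_config(stim_time = 10, trial_len = 10), "stim_time")
  expect_error(regime_spec("local_only", offhotspot_gain = 1.4),
               "local_only")
})
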