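test_that("config invariants are enforced", {
  expect_error(sim_config(alpha_amp = -1), "amplitude")
  expect_error(sim_config(lateralization_fraction = 1.2), "lateralization")
  expect_error(sim_config(sampling_rate = 80), "sampling_rate")
  expect_error(sim_config(trial_latency = c(1.0, 0.5),
                          attention_lead = c(1.5, 0.4)), "latency")
})

test_that("attended sides are unbiased fair draws without lag-1 structure", {
  cfg <- desk_config(n_trials = 10000, seed = 42)
  truth <- sample_behavior(cfg)
  frac_left <- mean(truth$side == "left")
  expect_lt(abs(frac_left - 0.5), 0.015)  # 3 sigma binomial envelope
  fit <- sequential_dependence_test(truth$side)
  expect_lt(abs(fit$slope), 0.1)
})

test_that("trial timing invariants hold on every row", {
  truth <- sample_behavior(desk_config(n_trials = 500, seed = 7))
  expect_true(all(truth$array_onset_s < truth$attention_onset_s))
  expect_true(all(truth$attention_onset_s < truth$press_s))
  lat <- truth$press_s - truth$array_onset_s
  expect_true(all(lat >= 1.2 & lat <= 20))
  gaps <- truth$array_onset_s[-1] - truth$press_s[-nrow(truth)]
  expect_true(all(gaps >= 0.5 - 1e-9))
  # attention is sustained for at least one ~1 s expansion cycle
  expect_true(all(truth$press_s - truth$attention_onset_s >=
                    pmin(1.0, lat - 0.05) - 1e-9))
})

test_that("identical config and seed give bit-identical truth and recording", {
  cfg <- desk_config(n_trials = 20, seed = 11)
  t1 <- sample_behavior(cfg); t2 <- sample_behavior(cfg)
  expect_identical(t1, t2)
  s1 <- synthesize_session(cfg, the_montage, t1)
  s2 <- synthesize_session(cfg, the_montage, t2)
  expect_identical(s1$raw$samples, s2$raw$samples)
  expect_identical(s1$events, s2$events)
})

test_that("events sit at exact sample indices with press codes matching sides", {
  cfg <- desk_config(n_trials = 15, seed = 3)
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  ev <- ses$events
  expect_true(all(diff(ev$sample_index) > 0))
  press <- ev[grepl("press", ev$code), ]
  expect_equal(nrow(press), 15)
  expect_equal(press$code, ifelse(truth$side == "left", "press_left",
                                  "press_right"))
  expect_equal(press$sample_index,
               as.integer(round(truth$press_s * cfg$sampling_rate)) + 1L)
})

test_that("with only the 1/f background the spectrum is a pure power law", {
  for (beta in c(0.8, 1.3)) {
    cfg <- desk_config(n_trials = 20, seed = 5,
                       alpha_amp = 0, mu_amp = 0, ssvep_amps = c(0, 0))
    cfg$one_over_f_exponent <- beta
    truth <- sample_behavior(cfg)
    ses <- synthesize_session(cfg, the_montage, truth)
    x <- ses$raw$samples[match("POz", ses$raw$channel_names), ]
    psd <- willdecode:::welch_psd(x, cfg$sampling_rate)
    sel <- psd$freq >= 2 & psd$freq <= 40
    slope <- unname(coef(lm(log10(psd$psd[sel]) ~ log10(psd$freq[sel])))[2])
    expect_lt(abs(slope + beta), 0.15)
  }
})

test_that("flicker components peak at 4 and 6 Hz but not inside the alpha band", {
  cfg <- desk_config(n_trials = 30, seed = 9, alpha_amp = 0, mu_amp = 0,
                     noise_amp = 1)
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  x <- ses$raw$samples[match("Oz", ses$raw$channel_names), ]
  psd <- willdecode:::welch_psd(x, cfg$sampling_rate)
  peak_at <- function(f0) {
    i <- which.min(abs(psd$freq - f0))
    psd$psd[i] > 2 * max(psd$psd[abs(psd$freq - f0) >= 0.75 &
                                   abs(psd$freq - f0) <= 1.5])
  }
  expect_true(peak_at(4))
  expect_true(peak_at(6))
  band <- psd$psd[psd$freq >= 9 & psd$freq <= 11]
  flank <- psd$psd[psd$freq >= 12 & psd$freq <= 14]
  expect_lt(max(band), 3 * max(flank))  # no alpha peak when alpha_amp = 0
})

test_that("doubling the alpha amplitude quadruples alpha-band power", {
  mk <- function(a) {
    cfg <- desk_config(n_trials = 10, seed = 13, mu_amp = 0,
                       ssvep_amps = c(0, 0))
    cfg$noise_amp <- 0
    cfg$alpha_amp <- a
    truth <- sample_behavior(cfg)
    ses <- synthesize_session(cfg, the_montage, truth)
    ep <- epoch_events(ses$raw, ses$events, lock = "response",
                       window_ms = c(-1000, 0))
    al <- tf_alpha_power(ep, channels = "PO7")
    mean(al$power, na.rm = TRUE)
  }
  expect_equal(mk(10) / mk(5), 4, tolerance = 0.01)
})

test_that("zero lateralization leaves PO7 and PO8 alpha power symmetric", {
  cfg <- desk_config(n_trials = 200, seed = 17, lateralization_fraction = 0,
                     mu_amp = 0, ssvep_amps = c(0, 0))
  cfg$noise_amp <- 0
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  ep <- epoch_events(ses$raw, ses$events, lock = "response",
                     window_ms = c(-1000, 0))
  al <- tf_alpha_power(ep, channels = c("PO7", "PO8"))
  p7 <- mean(al$power[, 1, ], na.rm = TRUE)
  p8 <- mean(al$power[, 2, ], na.rm = TRUE)
  expect_lt(abs(p7 - p8) / p7, 0.02)
})

test_that("blink transients trip the 100 uV rejector when enabled", {
  cfg <- desk_config(n_trials = 40, seed = 19)
  cfg$blink_rate <- 30  # frequent, so some epochs surely contain one
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  ep <- epoch_events(ses$raw, ses$events, lock = "response",
                     window_ms = c(-1000, 200))
  ep <- reject_artifacts_p2p(ep)
  expect_gt(sum(!ep$kept), 0)
})

test_that("montage/config mismatch is an error", {
  cfg <- desk_config(n_trials = 5, seed = 1)
  truth <- sample_behavior(cfg)
  expect_error(synthesize_session(cfg, the_montage, truth[1:3, ]), "trials")
})
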