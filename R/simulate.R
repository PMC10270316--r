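#' Simulation configuration for synthetic willed-attention sessions
#'
#' Defaults describe a full-scale uncued willed-attention experiment: 20 subjects,
#' ~479 self-paced trials each, 1000 samples/s recordings, trial latencies
#' with mean 3.9 s and a broad right-skewed spread, covert-attention onset
#' preceding the button press by at least one ~1 s stimulus expansion cycle,
#' posterior 10 Hz alpha lateralized by attended side, central mu activity
#' tied to the press, 4/6 Hz flicker-driven components, a 1/f background and
#' frontal blink transients.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject.
#' @param sampling_rate Sampling rate in Hz (> 100).
#' @param alpha_freq Alpha frequency in Hz, inside `[9, 11]`.
#' @param alpha_amp Occipital alpha source amplitude, uV.
#' @param lateralization_fraction Relative suppression of the alpha source
#'   contralateral to the attended hemifield while attention is deployed,
#'   in `[0, 1]`.
#' @param attention_lead Mean and sd (seconds) of the interval by which
#'   attention onset precedes the press; draws are floored at one expansion
#'   cycle (1 s).
#' @param trial_latency Mean and sd (seconds) of the array-onset-to-press
#'   latency (truncated lognormal, see Details).
#' @param mu_amp Central mu source amplitude, uV (non-informative about the
#'   attended side by construction: responses are always right-handed).
#' @param ssvep_amps Amplitudes (uV) of the 4 Hz and 6 Hz flicker components.
#' @param one_over_f_exponent Spectral exponent of the 1/f background
#'   (power ~ f^-exponent).
#' @param noise_amp Average sensor-level standard deviation (uV) of the
#'   mixed 1/f background.
#' @param blink_rate Blink events per minute (0 disables blinks).
#' @param intertrial_gap Seconds between a press and the next array onset.
#' @param seed Integer seed for all randomness in the simulator.
#'
#' @details The latency distribution is a lognormal moment-matched to the
#' configured mean/sd and truncated to `[1.2, 20]` s by redrawing: a
#' positive, right-skewed stand-in for the empirical latency spread, which
#' is constrained only through its mean and spread. The attention lead is normal,
#' floored at 1 s (one expansion cycle of sustained attention) and clipped
#' so attention onset always falls strictly inside the trial.
#'
#' @return A list of class `wd_sim_config`.
#' @export
sim_config <- function(n_subjects = 20,
                       n_trials = 479,
                       sampling_rate = 1000,
                       alpha_freq = 10,
                       alpha_amp = 10,
                       lateralization_fraction = 0.4,
                       attention_lead = c(mean = 1.5, sd = 0.4),
                       trial_latency = c(mean = 3.9, sd = 3.7),
                       mu_amp = 5,
                       ssvep_amps = c(2, 2),
                       one_over_f_exponent = 1,
                       noise_amp = 8,
                       blink_rate = 4,
                       intertrial_gap = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    sampling_rate = sampling_rate, alpha_freq = alpha_freq,
    alpha_amp = alpha_amp, lateralization_fraction = lateralization_fraction,
    attention_lead = unname(attention_lead), trial_latency = unname(trial_latency),
    mu_amp = mu_amp, ssvep_amps = unname(ssvep_amps),
    one_over_f_exponent = one_over_f_exponent, noise_amp = noise_amp,
    blink_rate = blink_rate, intertrial_gap = intertrial_gap,
    seed = as.integer(seed)
  )
  class(cfg) <- "wd_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  amps <- c(cfg$alpha_amp, cfg$mu_amp, cfg$ssvep_amps, cfg$noise_amp)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (cfg$lateralization_fraction < 0 || cfg$lateralization_fraction > 1) {
    stop("lateralization_fraction must lie in [0, 1]")
  }
  if (cfg$sampling_rate <= 100) stop("sampling_rate must exceed 100 Hz (2 x 50 Hz)")
  if (cfg$alpha_freq < 9 || cfg$alpha_freq > 11) stop("alpha_freq must lie in [9, 11]")
  if (cfg$trial_latency[1] <= cfg$attention_lead[1]) {
    stop("mean trial latency must exceed mean attention lead")
  }
  if (cfg$n_trials < 1 || cfg$n_subjects < 1) stop("counts must be positive")
  invisible(cfg)
}

#' Sample per-trial ground truth for one session
#'
#' Draws attended sides (i.i.d. fair Bernoulli, so there is no sequential
#' dependence to decode from behavior), trial latencies (truncated lognormal)
#' and attention onsets (press time minus a floored normal lead), then lays
#' trials end to end with the configured intertrial gap.
#'
#' @param config A `wd_sim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble of class `wd_truth` with columns `trial`, `side`
#'   (`"left"`/`"right"`), `array_onset_s`, `attention_onset_s`, `press_s`,
#'   `target_rt_s`. Every row satisfies
#'   `array_onset_s < attention_onset_s < press_s`.
#' @export
sample_behavior <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_trials
  side <- ifelse(runif(n) < 0.5, "left", "right")

  lm_mean <- config$trial_latency[1]
  lm_sd <- config$trial_latency[2]
  sdlog <- sqrt(log(1 + (lm_sd / lm_mean)^2))
  meanlog <- log(lm_mean) - sdlog^2 / 2
  draw_latency <- function(k) {
    out <- numeric(0)
    while (length(out) < k) {
      x <- rlnorm(k - length(out), meanlog, sdlog)
      out <- c(out, x[x >= 1.2 & x <= 20])
    }
    out
  }
  latency <- draw_latency(n)

  lead <- pmax(rnorm(n, config$attention_lead[1], config$attention_lead[2]), 1.0)
  lead <- pmin(lead, latency - 0.05)  # attention onset strictly after array onset

  array_onset <- numeric(n)
  array_onset[1] <- 1.0
  if (n > 1) {
    for (i in 2:n) {
      array_onset[i] <- array_onset[i - 1] + latency[i - 1] + config$intertrial_gap
    }
  }
  press <- array_onset + latency
  attention_onset <- press - lead
  target_rt <- rnorm(n, 0.19, 0.21)

  out <- tibble::tibble(
    trial = seq_len(n), side = side,
    array_onset_s = array_onset, attention_onset_s = attention_onset,
    press_s = press, target_rt_s = target_rt
  )
  stopifnot(all(out$array_onset_s < out$attention_onset_s),
            all(out$attention_onset_s < out$press_s))
  class(out) <- c("wd_truth", class(out))
  out
}

#' Spectrally shaped (1/f) Gaussian noise
#'
#' Shapes white Gaussian noise in the frequency domain so the power spectral
#' density falls as `f^-exponent`, then rescales to the requested standard
#' deviation. The DC component is zeroed.
#'
#' @param n Number of samples.
#' @param exponent Spectral exponent (power ~ f^-exponent).
#' @param sampling_rate Sampling rate in Hz.
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, exponent, sampling_rate, sd = 1) {
  one_over_f_noise_matrix(n, 1L, exponent, sampling_rate, sd)[, 1]
}

# k independent columns of 1/f noise, batched through one column-wise FFT.
one_over_f_noise_matrix <- function(n, k, exponent, sampling_rate, sd = 1) {
  np <- stats::nextn(n, c(2, 3))  # 3-smooth FFT length, then truncate
  w <- matrix(rnorm(np * k), nrow = np)
  W <- stats::mvfft(w)
  f <- seq(0, np - 1) * (sampling_rate / np)
  f[f > sampling_rate / 2] <- sampling_rate - f[f > sampling_rate / 2]
  scale <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(W * scale, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2, sd / s, "*")
}

# Multiply env by `factor` over [i0, i1] with raised-cosine ramps of length
# L at both edges (avoids broadband clicks at envelope transitions).
# Windows from different trials never overlap.
ramp_mult <- function(env, i0, i1, factor, L) {
  n <- length(env)
  i0 <- max(1L, i0); i1 <- min(n, i1)
  if (i1 <= i0) return(env)
  L <- min(L, (i1 - i0) %/% 2L)
  if (L >= 2) {
    blend <- 0.5 - 0.5 * cos(pi * seq_len(L) / (L + 1))
    env[i0:(i0 + L - 1)] <- env[i0:(i0 + L - 1)] * (1 + (factor - 1) * blend)
    env[(i1 - L + 1):i1] <- env[(i1 - L + 1):i1] * (1 + (factor - 1) * rev(blend))
    if (i0 + L <= i1 - L) {
      env[(i0 + L):(i1 - L)] <- env[(i0 + L):(i1 - L)] * factor
    }
  } else {
    env[i0:i1] <- env[i0:i1] * factor
  }
  env
}

new_raw <- function(samples, sampling_rate, channel_names, check = TRUE) {
  stopifnot(nrow(samples) == length(channel_names))
  if (check && anyNA(samples)) stop("recording contains non-finite samples")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_names = channel_names),
            class = "wd_raw")
}

#' Restrict a recording to a channel subset
#'
#' @param raw A `wd_raw`.
#' @param channels Channel labels to keep (montage order preserved as given).
#' @return A `wd_raw` with only those channels.
#' @export
subset_channels <- function(raw, channels) {
  idx <- match(channels, raw$channel_names)
  if (anyNA(idx)) {
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  }
  new_raw(raw$samples[idx, , drop = FALSE], raw$sampling_rate, channels)
}

#' @export
print.wd_raw <- function(x, ...) {
  cat(sprintf("<wd_raw> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Synthesize one continuous willed-attention EEG session
#'
#' Builds a multichannel recording as a sum of sources mixed through smooth
#' scalp topographies:
#'
#' * 1/f background: independent spectrally shaped noise sources spread over
#'   the scalp (exponent `one_over_f_exponent`, sd `noise_amp` each);
#' * bilateral occipital alpha at `alpha_freq` (foci PO7/PO8) whose source
#'   contralateral to the attended hemifield is attenuated by
#'   `lateralization_fraction` from attention onset to the press;
#' * a central mu source (focus C3, the right-hand motor region) ramping up
#'   over the 500 ms before every press, identically for both attended
#'   sides;
#' * 4 and 6 Hz flicker components plus first harmonics over occipital
#'   channels (foci O1/O2) while the array is on, with the 4/6 Hz
#'   side-assignment randomized per trial;
#' * optional stereotyped 300 ms biphasic blink transients, ~120 uV peak at
#'   Fp1/Fp2, decaying posteriorly.
#'
#' Events are recorded at exact sample indices; the press code matches the
#' attended side. The session length is padded to a whole number of seconds.
#'
#' @param config A `wd_sim_config`.
#' @param montage A `wd_montage`.
#' @param truth A `wd_truth` from [sample_behavior()] under the same config.
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return List with elements `raw` (a `wd_raw`, channels x time in uV) and
#'   `events` (tibble of class `wd_events` with columns `sample_index`,
#'   `code` in `{"array_onset", "press_left", "press_right"}`).
#' @export
synthesize_session <- function(config, montage, truth, seed = config$seed + 1L) {
  validate_sim_config(config)
  if (!inherits(montage, "wd_montage")) stop("montage must be a wd_montage")
  if (nrow(truth) != config$n_trials) {
    stop("truth has ", nrow(truth), " trials but config expects ", config$n_trials)
  }
  set.seed(seed)
  fs <- config$sampling_rate
  nch <- nrow(montage)
  dur <- max(truth$press_s) + 1.0
  n_samp <- as.integer(ceiling(dur) * fs)  # whole seconds (clean EDF records)
  tt <- (seq_len(n_samp) - 1) / fs

  # sources are collected as (topography, waveform) pairs and mixed with a
  # single matrix product at the end
  W_cols <- list()
  S_rows <- list()
  add_source <- function(weights, waveform) {
    W_cols[[length(W_cols) + 1]] <<- weights
    S_rows[[length(S_rows) + 1]] <<- waveform
  }

  ## 1/f background: independent sources on a fixed spread of focus
  ## channels; the mixed field is scaled so noise_amp is the average
  ## sensor-level standard deviation.
  n_bg <- 12
  bg_foci <- montage$name[round(seq(1, nch, length.out = n_bg))]
  if (config$noise_amp > 0) {
    Wbg <- vapply(bg_foci, function(fc)
      build_topography(montage, fc, spread = 0.8), numeric(nch))
    # the eye-proxy and mastoid-adjacent reference sites at the cap edge
    # carry little cortical background (the references are chosen for their
    # electrical quietness); keeping them quiet lets the 20 uV eye-movement
    # criterion respond to ocular transients rather than ongoing EEG, and
    # keeps re-referencing from injecting background into every channel
    edge_idx <- match(c("FT9", "FT10", "TP9", "TP10"), montage$name)
    edge_idx <- edge_idx[!is.na(edge_idx)]
    Wbg[edge_idx, ] <- 0.15 * Wbg[edge_idx, ]
    bg_scale <- config$noise_amp / mean(sqrt(rowSums(Wbg^2)))
    S_bg <- one_over_f_noise_matrix(n_samp, n_bg,
                                    config$one_over_f_exponent, fs)
    for (k in seq_len(n_bg)) {
      add_source(bg_scale * Wbg[, k], S_bg[, k])
    }
  }

  smp <- function(t_s) pmin(n_samp, pmax(1L, as.integer(round(t_s * fs)) + 1L))
  ramp_len <- max(3L, as.integer(round(0.1 * fs)))

  ## bilateral occipital alpha with attention-dependent asymmetry
  if (config$alpha_amp > 0) {
    env_l <- rep(1, n_samp)
    env_r <- rep(1, n_samp)
    supp <- 1 - config$lateralization_fraction
    for (i in seq_len(nrow(truth))) {
      i0 <- smp(truth$attention_onset_s[i])
      i1 <- smp(truth$press_s[i])
      if (truth$side[i] == "left") {
        env_r <- ramp_mult(env_r, i0, i1, supp, ramp_len)
      } else {
        env_l <- ramp_mult(env_l, i0, i1, supp, ramp_len)
      }
    }
    ph <- runif(2, 0, 2 * pi)
    add_source(build_topography(montage, "PO7", spread = 0.7),
               config$alpha_amp * env_l *
                 sin(2 * pi * config$alpha_freq * tt + ph[1]))
    add_source(build_topography(montage, "PO8", spread = 0.7),
               config$alpha_amp * env_r *
                 sin(2 * pi * config$alpha_freq * tt + ph[2]))
  }

  ## central mu: ramps up in the 500 ms before each press (side-invariant)
  if (config$mu_amp > 0) {
    env_mu <- rep(0, n_samp)
    for (i in seq_len(nrow(truth))) {
      i0 <- smp(truth$press_s[i] - 0.5)
      i1 <- smp(truth$press_s[i])
      i2 <- smp(truth$press_s[i] + 0.2)
      env_mu[i0:i1] <- pmax(env_mu[i0:i1], seq(0, 1, length.out = i1 - i0 + 1))
      if (i2 > i1) env_mu[i1:i2] <- pmax(env_mu[i1:i2],
                                         seq(1, 0, length.out = i2 - i1 + 1))
    }
    add_source(build_topography(montage, "C3", spread = 0.5),
               config$mu_amp * env_mu * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)))
  }

  ## flicker-driven 4/6 Hz components (+ first harmonics) while the array is
  ## on; the 4 Hz / 6 Hz side assignment is randomized per trial
  if (any(config$ssvep_amps > 0)) {
    env4l <- rep(0, n_samp); env4r <- rep(0, n_samp)
    env6l <- rep(0, n_samp); env6r <- rep(0, n_samp)
    # unit window with raised-cosine on/off edges (windows are disjoint)
    set_window <- function(env, i0, i1) {
      len <- i1 - i0 + 1L
      L <- min(ramp_len, len %/% 2L)
      w <- rep(1, len)
      if (L >= 2) {
        blend <- 0.5 - 0.5 * cos(pi * seq_len(L) / (L + 1))
        w[seq_len(L)] <- blend
        w[(len - L + 1):len] <- rev(blend)
      }
      env[i0:i1] <- w
      env
    }
    four_on_left <- runif(nrow(truth)) < 0.5
    for (i in seq_len(nrow(truth))) {
      i0 <- smp(truth$array_onset_s[i])
      i1 <- smp(truth$press_s[i])
      if (four_on_left[i]) {
        env4l <- set_window(env4l, i0, i1)
        env6r <- set_window(env6r, i0, i1)
      } else {
        env4r <- set_window(env4r, i0, i1)
        env6l <- set_window(env6l, i0, i1)
      }
    }
    flick <- function(freq, amp) {
      amp * (sin(2 * pi * freq * tt) + 0.5 * sin(2 * pi * 2 * freq * tt))
    }
    w_l <- build_topography(montage, "O1", spread = 0.5)
    w_r <- build_topography(montage, "O2", spread = 0.5)
    add_source(w_l, env4l * flick(4, config$ssvep_amps[1]))
    add_source(w_r, env4r * flick(4, config$ssvep_amps[1]))
    add_source(w_l, env6l * flick(6, config$ssvep_amps[2]))
    add_source(w_r, env6r * flick(6, config$ssvep_amps[2]))
  }

  ## blinks: biphasic 300 ms transients on frontal channels
  if (config$blink_rate > 0) {
    n_blinks <- rpois(1, config$blink_rate * dur / 60)
    if (n_blinks > 0) {
      t_blink <- runif(n_blinks, 0, dur - 0.4)
      blink_len <- as.integer(round(0.3 * fs))
      shape <- sin(2 * pi * seq_len(blink_len) / blink_len) *
        sin(pi * seq_len(blink_len) / blink_len)
      shape <- 120 * shape / max(abs(shape))
      w_blink <- (build_topography(montage, "Fp1", spread = 0.45) +
                    build_topography(montage, "Fp2", spread = 0.45))
      w_blink <- w_blink / max(w_blink)
      blink_tr <- rep(0, n_samp)
      for (tb in t_blink) {
        i0 <- smp(tb)
        idx <- i0:(i0 + blink_len - 1)
        blink_tr[idx] <- blink_tr[idx] + shape
      }
      add_source(w_blink, blink_tr)
    }
  }

  X <- if (length(W_cols) > 0) {
    do.call(cbind, W_cols) %*% do.call(rbind, S_rows)
  } else {
    matrix(0, nrow = nch, ncol = n_samp)
  }
  storage.mode(X) <- "double"

  events <- tibble::tibble(
    sample_index = c(smp(truth$array_onset_s), smp(truth$press_s)),
    code = c(rep("array_onset", nrow(truth)),
             ifelse(truth$side == "left", "press_left", "press_right"))
  )
  events <- events[order(events$sample_index), ]
  class(events) <- c("wd_events", class(events))

  list(raw = new_raw(X, fs, montage$name, check = FALSE), events = events)
}
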