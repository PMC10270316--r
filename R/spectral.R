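#' Alpha-band power with an adaptive three-cycle Hann taper
#'
#' At each timepoint of a 20 ms grid aligned to the lock event and at each
#' integer frequency in `freqs`, the signal is windowed with a Hann taper of
#' length `cycles / f` centred on the timepoint, the Fourier coefficient at
#' `f` is taken directly (no FFT grid), its squared magnitude is the power,
#' and powers are averaged over the frequencies. The coefficient is
#' normalized so a unit-amplitude sinusoid at `f` yields power 1 (amplitude
#' squared scaling is exact). Timepoints whose widest window (lowest
#' frequency) would exceed the epoch are marked `NA`, not zero.
#'
#' The 9-11 Hz band deliberately excludes the 4 and 6 Hz stimulus flicker
#' frequencies and their first harmonics (8, 12 Hz).
#'
#' @param epochs A `wd_epochs`.
#' @param freqs Integer frequencies in Hz (default `9:11`).
#' @param cycles Cycles per window (default 3).
#' @param step_ms Timepoint grid step in ms (default 20); must be a multiple
#'   of the sample period.
#' @param channels Channel labels to keep (default: all).
#' @return A list of class `wd_alpha`: `power` (trials x channels x
#'   timepoints, uV^2), `time_ms`, `band`, `lock`, `labels`, `kept`,
#'   `channel_names`.
#' @export
tf_alpha_power <- function(epochs, freqs = 9:11, cycles = 3, step_ms = 20,
                           channels = NULL) {
  fs <- epochs$sampling_rate
  if (is.null(channels)) channels <- epochs$channel_names
  ch_idx <- match(channels, epochs$channel_names)
  if (anyNA(ch_idx)) stop("unknown channels requested")
  step_samp <- step_ms * fs / 1000
  if (abs(step_samp - round(step_samp)) > 1e-9) {
    stop("step_ms must be a whole number of samples")
  }
  time_ms <- epochs$time_ms
  grid_idx <- which(abs(time_ms %% step_ms) < 1e-9 |
                      abs(time_ms %% step_ms - step_ms) < 1e-9)
  if (length(grid_idx) == 0) stop("no grid timepoints inside the epoch")

  n_samp <- dim(epochs$data)[3]
  half <- vapply(freqs, function(f) as.integer(floor(floor(cycles / f * fs) / 2)),
                 integer(1))
  widest <- max(half)
  if (2 * widest + 1 > n_samp) {
    stop("epoch shorter than the widest analysis window (",
         round((2 * widest + 1) / fs * 1000), " ms)")
  }
  valid <- grid_idx - widest >= 1 & grid_idx + widest <= n_samp

  nt <- dim(epochs$data)[1]
  nch <- length(ch_idx)
  data_sub <- epochs$data[, ch_idx, , drop = FALSE]
  power <- array(NA_real_, dim = c(nt, nch, length(grid_idx)))
  acc <- array(0, dim = c(nt, nch, sum(valid)))
  for (fi in seq_along(freqs)) {
    h <- half[fi]
    L <- 2L * h + 1L
    k <- seq_len(L) - 1
    taper <- 0.5 - 0.5 * cos(2 * pi * k / (L - 1))
    phase <- -2 * pi * freqs[fi] * (k - h) / fs
    # normalized so a unit sinusoid at f gives |coef| = 1
    v_re <- taper * cos(phase) * 2 / sum(taper)
    v_im <- taper * sin(phase) * 2 / sum(taper)
    acc <- acc + tf_band_power_cpp(data_sub, as.integer(grid_idx[valid]),
                                   h, v_re, v_im)
  }
  power[, , valid] <- acc / length(freqs)

  structure(list(power = power, time_ms = time_ms[grid_idx],
                 band = range(freqs), lock = epochs$lock,
                 labels = epochs$labels, kept = epochs$kept,
                 channel_names = channels, subject_id = epochs$subject_id),
            class = "wd_alpha")
}

#' @export
print.wd_alpha <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<wd_alpha> %g-%g Hz power: %d trials x %d channels x %d timepoints (%s lock)\n",
              x$band[1], x$band[2], d[1], d[2], d[3], x$lock))
  invisible(x)
}

# Legendre polynomials P_1..P_n evaluated at x (vector), via recurrence.
legendre_table <- function(x, n) {
  P <- matrix(0, nrow = length(x), ncol = n)
  P[, 1] <- x
  if (n >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (n >= 3) {
    for (k in 3:n) {
      P[, k] <- ((2 * k - 1) * x * P[, k - 1] - (k - 1) * P[, k - 2]) / k
    }
  }
  P
}

# Spherical-spline interpolation (g) and surface-Laplacian (h) kernels.
spline_gh <- function(cosang, m, n_terms) {
  x <- pmin(1, pmax(-1, as.vector(cosang)))
  P <- legendre_table(x, n_terms)
  n <- seq_len(n_terms)
  gw <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  hw <- (2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)
  list(g = matrix(P %*% gw, nrow = nrow(cosang)),
       h = matrix(P %*% hw, nrow = nrow(cosang)))
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Fits a spherical spline to the scalp potential at every sample and
#' evaluates its surface Laplacian at the electrode sites, yielding the
#' current source density (CSD) in spline units per steradian on the unit
#' sphere (a fixed positive scale relative to uV/cm^2 for a given head
#' radius). The transform is linear, independent of the global reference
#' (adding a constant to all channels changes nothing), and sharpens
#' topographies by attenuating volume conduction.
#'
#' @param epochs A `wd_epochs`.
#' @param montage A `wd_montage` supplying positions for the epoch channels.
#' @param m Spline order (default 4).
#' @param n_terms Legendre series terms (default 50).
#' @param lambda Regularization added to the spline system (default 1e-5).
#' @return A `wd_epochs` whose `data` holds CSD values; field `csd = TRUE`.
#' @export
surface_laplacian <- function(epochs, montage, m = 4, n_terms = 50,
                              lambda = 1e-5) {
  idx <- match(epochs$channel_names, montage$name)
  if (anyNA(idx)) stop("montage lacks positions for some epoch channels")
  P <- cbind(montage$x, montage$y, montage$z)[idx, , drop = FALSE]
  if (nrow(P) < 8) stop("surface Laplacian needs at least 8 channels")
  CC <- P %*% t(P)
  if (any(CC[upper.tri(CC)] > 1 - 1e-12)) stop("duplicate electrode positions")
  gh <- spline_gh(CC, m, n_terms)
  Gs <- gh$g + diag(lambda, nrow(P))
  Gi <- solve(Gs)
  gi1 <- rowSums(Gi)
  # CSD transform: fit v = c0 + G c with sum(c) = 0, output -Laplacian = H c
  Tm <- gh$h %*% (Gi - outer(gi1, gi1) / sum(gi1))

  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    out$data[i, , ] <- Tm %*% epochs$data[i, , ]
  }
  out$csd <- TRUE
  out
}

# Welch PSD: Hann taper, half-overlapping segments, mean periodogram.
welch_psd <- function(x, fs, nfft = min(length(x), round(4 * fs))) {
  step <- floor(nfft / 2)
  starts <- seq(1, length(x) - nfft + 1, by = step)
  k <- seq_len(nfft) - 1
  taper <- 0.5 - 0.5 * cos(2 * pi * k / (nfft - 1))
  norm <- sum(taper^2) * fs
  nf <- floor(nfft / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)]
    seg <- (seg - mean(seg)) * taper
    sp <- abs(fft(seg)[seq_len(nf)])^2 / norm
    acc <- acc + sp
  }
  list(freq = (seq_len(nf) - 1) * fs / nfft, psd = acc / length(starts))
}

#' Irregular-resampling separation of fractal and oscillatory spectra
#'
#' For every factor `h` in `resampling_set` the signal is resampled by `h`
#' and by `1/h`, the Welch PSDs of the two resampled series are computed on
#' the original frequency grid, and their geometric mean is taken: genuine
#' oscillatory peaks are displaced in opposite directions and cancelled,
#' while the self-similar 1/f (fractal) background is preserved. The median
#' across factors is the fractal component; the oscillatory component is
#' `total - fractal` exactly.
#'
#' @param x Single-channel signal segment (>= 4 s recommended).
#' @param fs Sampling rate in Hz.
#' @param resampling_set Resampling factors, all > 1 (default 1.1 to 1.9 in
#'   steps of 0.05).
#' @param nfft Welch segment length in samples (default 4 s).
#' @return A list of class `wd_irasa`: `freq`, `total`, `fractal`,
#'   `oscillatory`, `resampling_set`.
#' @export
irasa_decompose <- function(x, fs, resampling_set = seq(1.1, 1.9, by = 0.05),
                            nfft = min(length(x), round(4 * fs))) {
  if (any(resampling_set <= 1)) stop("all resampling factors must exceed 1")
  if (length(x) < 4 * fs) stop("segment must be at least 4 s long")
  total <- welch_psd(x, fs, nfft)
  gm <- matrix(NA_real_, nrow = length(total$freq),
               ncol = length(resampling_set))
  for (i in seq_along(resampling_set)) {
    h <- resampling_set[i]
    p <- round(h * 20)
    q <- 20L
    g <- gcd_int(p, q)
    up <- as.numeric(signal::resample(x, p %/% g, q %/% g))
    dn <- as.numeric(signal::resample(x, q %/% g, p %/% g))
    psd_up <- welch_psd(up, fs, nfft)$psd
    psd_dn <- welch_psd(dn, fs, nfft)$psd
    gm[, i] <- sqrt(psd_up * psd_dn)
  }
  fractal <- apply(gm, 1, stats::median)
  structure(list(freq = total$freq, total = total$psd, fractal = fractal,
                 oscillatory = total$psd - fractal,
                 resampling_set = resampling_set),
            class = "wd_irasa")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Fit the spectral exponent of the fractal component
#'
#' Ordinary least squares on log power vs log frequency over `fit_range`.
#'
#' @param irasa A `wd_irasa`.
#' @param fit_range Frequency range in Hz (default `c(2, 30)`).
#' @return Named numeric: `exponent` (positive beta of f^-beta) and
#'   `intercept` (log10 power at 1 Hz).
#' @export
irasa_exponent <- function(irasa, fit_range = c(2, 30)) {
  sel <- irasa$freq >= fit_range[1] & irasa$freq <= fit_range[2] &
    irasa$fractal > 0
  fit <- stats::lm(log10(irasa$fractal[sel]) ~ log10(irasa$freq[sel]))
  c(exponent = -unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]))
}

#' Channelwise alpha-power lateralization topography
#'
#' Mean alpha power difference (attend-left minus attend-right) per channel,
#' averaged over kept trials and over the timepoints inside `window_ms`.
#' Swapping the label assignment flips the sign of every value.
#'
#' @param alpha A `wd_alpha`.
#' @param window_ms Two-element window in ms on the alpha time grid.
#' @return Tibble with columns `channel` and `value` (uV^2), in the alpha
#'   object's channel order.
#' @export
lateralization_topography <- function(alpha, window_ms) {
  tsel <- alpha$time_ms >= window_ms[1] & alpha$time_ms <= window_ms[2]
  keep_l <- alpha$kept & alpha$labels == "left"
  keep_r <- alpha$kept & alpha$labels == "right"
  if (!any(keep_l) || !any(keep_r)) stop("both attend sides must have kept trials")
  mean_map <- function(sel) {
    apply(alpha$power[sel, , tsel, drop = FALSE], 2, mean, na.rm = TRUE)
  }
  tibble::tibble(channel = alpha$channel_names,
                 value = mean_map(keep_l) - mean_map(keep_r))
}
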