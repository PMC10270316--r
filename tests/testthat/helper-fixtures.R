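# Shared fixture builders. Everything is generated in code; no data files.

the_montage <- default_montage()

# Bare epochs container around a given trials x channels x samples array.
make_epochs <- function(data, channel_names, sampling_rate = 250,
                        time_ms = NULL, labels = NULL,
                        lock = "response") {
  d <- dim(data)
  if (is.null(time_ms)) time_ms <- (seq_len(d[3]) - 1 - (d[3] %/% 2)) /
      sampling_rate * 1000
  if (is.null(labels)) labels <- rep(c("left", "right"), length.out = d[1])
  structure(list(data = data, time_ms = time_ms, lock = lock,
                 labels = labels, kept = rep(TRUE, d[1]),
                 sampling_rate = sampling_rate,
                 channel_names = channel_names, subject_id = "S1",
                 n_dropped_bounds = 0L),
            class = "wd_epochs")
}

# Bare alpha-power container around a trials x channels x timepoints array.
make_alpha <- function(power, channel_names, time_ms = NULL, labels = NULL,
                       kept = NULL, lock = "response") {
  d <- dim(power)
  if (is.null(time_ms)) time_ms <- seq(0, by = 20, length.out = d[3])
  if (is.null(labels)) labels <- rep(c("left", "right"), length.out = d[1])
  if (is.null(kept)) kept <- rep(TRUE, d[1])
  structure(list(power = power, time_ms = time_ms, band = c(9, 11),
                 lock = lock, labels = labels, kept = kept,
                 channel_names = channel_names, subject_id = "S1"),
            class = "wd_alpha")
}

# A constant-zero recording over the full montage.
zero_raw <- function(n_samp = 5000, sampling_rate = 250,
                     montage = the_montage) {
  willdecode:::new_raw(matrix(0, nrow(montage), n_samp), sampling_rate,
                       montage$name)
}

# Sinusoidal recording with the same signal on all scalp channels and
# silent TP9/TP10 references.
sine_raw <- function(freq, n_sec = 20, sampling_rate = 1000,
                     montage = the_montage) {
  tt <- seq(0, n_sec, by = 1 / sampling_rate)[seq_len(n_sec * sampling_rate)]
  X <- matrix(rep(sin(2 * pi * freq * tt), nrow(montage)),
              nrow = nrow(montage), byrow = TRUE)
  X[match(c("TP9", "TP10"), montage$name), ] <- 0
  willdecode:::new_raw(X, sampling_rate, montage$name)
}

# Brute-force peak-to-peak rejection oracle: every window placement at step
# offsets plus the flushed final window, independent of the C++ scan.
p2p_oracle <- function(data, ch_idx, w, s, threshold) {
  ns <- dim(data)[3]
  starts <- seq(1, ns - w + 1, by = s)
  if (utils::tail(starts, 1) != ns - w + 1) starts <- c(starts, ns - w + 1)
  vapply(seq_len(dim(data)[1]), function(t) {
    for (c in ch_idx) {
      for (p in starts) {
        seg <- data[t, c, p:(p + w - 1)]
        if (max(seg) - min(seg) > threshold) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

# Run-scanner oracle for supra-threshold clusters.
cluster_oracle <- function(t_curve, tcrit) {
  out <- list()
  i <- 1
  n <- length(t_curve)
  while (i <= n) {
    if (!is.na(t_curve[i]) && t_curve[i] > tcrit) {
      j <- i
      while (j < n && !is.na(t_curve[j + 1]) && t_curve[j + 1] > tcrit) j <- j + 1
      out[[length(out) + 1]] <- c(start = i, end = j,
                                  mass = sum(t_curve[i:j]))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

# Log-likelihood grid-search oracle for the lag-1 logistic regression.
logistic_grid_oracle <- function(sides, b0_range = c(-3, 3),
                                 b1_range = c(-3, 3)) {
  y <- as.integer(sides[-1] == "left")
  x <- as.integer(sides[-length(sides)] == "left")
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta)))
  }
  best <- c(0, 0)
  for (step in c(0.1, 0.01, 0.001, 1e-4)) {
    g0 <- seq(best[1] - 10 * step, best[1] + 10 * step, by = step)
    g1 <- seq(best[2] - 10 * step, best[2] + 10 * step, by = step)
    ll <- outer(g0, g1, Vectorize(loglik))
    ix <- arrayInd(which.max(ll), dim(ll))
    best <- c(g0[ix[1]], g1[ix[2]])
  }
  best
}
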