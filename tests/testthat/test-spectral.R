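test_that("zero signal gives zero alpha power everywhere valid", {
  ep <- make_epochs(array(0, c(3, 2, 400)), c("Oz", "POz"))
  al <- tf_alpha_power(ep)
  expect_true(all(al$power[!is.na(al$power)] == 0))
})

test_that("a unit 10 Hz sinusoid matches the windowed-DFT oracle to 1e-8", {
  fs <- 250
  ns <- 751
  tt <- ((0:(ns - 1)) - (ns - 1) / 2) / fs
  sig <- sin(2 * pi * 10 * tt + 0.7)
  data <- array(rep(sig, each = 2), c(2, 1, ns))
  ep <- make_epochs(data, "Oz", time_ms = tt * 1000)
  al <- tf_alpha_power(ep, freqs = 10)

  # independent oracle: direct Hann-windowed DFT coefficient at 10 Hz
  h <- floor(floor(3 / 10 * fs) / 2)
  L <- 2 * h + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  for (g in c(10, 40, 70)) {
    cen <- which(abs(ep$time_ms - al$time_ms[g]) < 1e-9)
    seg <- sig[(cen - h):(cen + h)]
    coef <- sum(seg * w * exp(-1i * 2 * pi * 10 * ((0:(L - 1)) - h) / fs)) *
      2 / sum(w)
    expect_equal(al$power[1, 1, g], abs(coef)^2, tolerance = 1e-8)
  }
  # interior power is constant and ~1 for a unit sinusoid
  v <- al$power[1, 1, !is.na(al$power[1, 1, ])]
  expect_lt(diff(range(v)), 0.01)
})

test_that("edge timepoints without a full window are NA, not zero", {
  ep <- make_epochs(array(1, c(1, 1, 200)), "Oz")
  al <- tf_alpha_power(ep)
  expect_true(anyNA(al$power))
  first_valid <- which(!is.na(al$power[1, 1, ]))[1]
  expect_gt(first_valid, 1)
})

test_that("the 4 Hz flicker leaks under 2% of equal-amplitude alpha power", {
  fs <- 250
  ns <- 751
  tt <- (0:(ns - 1)) / fs
  mk <- function(f) {
    ep <- make_epochs(array(sin(2 * pi * f * tt), c(1, 1, ns)), "Oz")
    al <- tf_alpha_power(ep)
    max(al$power, na.rm = TRUE)
  }
  expect_lt(mk(4) / mk(10), 0.02)
})

test_that("alpha power scales as amplitude squared", {
  set.seed(5)
  data <- array(rnorm(2 * 2 * 400), c(2, 2, 400))
  ep1 <- make_epochs(data, c("Oz", "POz"))
  ep2 <- make_epochs(data * 3, c("Oz", "POz"))
  a1 <- tf_alpha_power(ep1)$power
  a2 <- tf_alpha_power(ep2)$power
  expect_equal(a2, 9 * a1, tolerance = 1e-10)
})

test_that("the epoch must fit the widest analysis window", {
  ep <- make_epochs(array(0, c(1, 1, 50)), "Oz")
  expect_error(tf_alpha_power(ep), "widest")
})

test_that("the surface Laplacian kills constants and is linear", {
  ep <- make_epochs(array(7.3, c(2, 64, 5)), the_montage$name)
  csd <- surface_laplacian(ep, the_montage)
  expect_lt(max(abs(csd$data)), 1e-10)

  set.seed(6)
  dat <- array(rnorm(2 * 64 * 5), c(2, 64, 5))
  e1 <- make_epochs(dat, the_montage$name)
  e2 <- make_epochs(2 * dat, the_montage$name)
  c1 <- surface_laplacian(e1, the_montage)
  c2 <- surface_laplacian(e2, the_montage)
  expect_equal(c2$data, 2 * c1$data, tolerance = 1e-12)
  # offset invariance
  e3 <- make_epochs(dat + 100, the_montage$name)
  c3 <- surface_laplacian(e3, the_montage)
  expect_equal(c3$data, c1$data, tolerance = 1e-8)
  # commutes with trial averaging by linearity
  avg_then <- surface_laplacian(
    make_epochs(array((dat[1, , ] + dat[2, , ]) / 2, c(1, 64, 5)),
                the_montage$name), the_montage)
  expect_equal(avg_then$data[1, , ], (c1$data[1, , ] + c1$data[2, , ]) / 2,
               tolerance = 1e-10)
})

test_that("the Laplacian of spherical harmonics matches the analytic eigenvalue", {
  # surface Laplacian of a degree-l spherical harmonic is -l(l+1) times it;
  # with the CSD sign convention the output is +l(l+1) Y at the electrodes
  m <- the_montage
  harmonics <- list(l1 = list(Y = m$z, l = 1),
                    l2a = list(Y = m$x * m$z, l = 2),
                    l2b = list(Y = m$x * m$y, l = 2))
  for (h in harmonics) {
    ep <- make_epochs(array(rep(h$Y, each = 1), c(1, 64, 1)), m$name,
                      time_ms = 0)
    csd <- surface_laplacian(ep, m)
    expect_gt(cor(csd$data[1, , 1], h$l * (h$l + 1) * h$Y), 0.99)
  }
})

test_that("duplicate electrode positions are refused", {
  m2 <- the_montage
  m2$x[2] <- m2$x[1]; m2$y[2] <- m2$y[1]; m2$z[2] <- m2$z[1]
  ep <- make_epochs(array(0, c(1, 64, 2)), m2$name)
  expect_error(surface_laplacian(ep, m2), "duplicate")
})

test_that("IRASA separates an oscillation from a 1/f background", {
  set.seed(7)
  fs <- 250
  n <- fs * 40
  x <- one_over_f_noise(n, 1.2, fs, sd = 5) +
    3 * sin(2 * pi * 10 * (0:(n - 1)) / fs)
  ir <- irasa_decompose(x, fs)
  expect_equal(ir$total, ir$fractal + ir$oscillatory)  # definitional
  sel <- ir$freq >= 2 & ir$freq <= 30
  expect_equal(ir$freq[sel][which.max(ir$oscillatory[sel])], 10,
               tolerance = 0.26)
  expect_lt(abs(irasa_exponent(ir)["exponent"] - 1.2), 0.1)
})

test_that("pure power-law input leaves a small oscillatory residue", {
  # averaged over realizations, the oscillatory component of pure 1/f noise
  # stays under 10% of the fractal component at every frequency in 2-30 Hz
  set.seed(8)
  fs <- 250
  n_real <- 20
  osc <- NULL; fra <- NULL; freq <- NULL
  for (r in seq_len(n_real)) {
    x <- one_over_f_noise(fs * 60, 1, fs, sd = 5)
    ir <- irasa_decompose(x, fs, nfft = fs)  # 1 s segments: many averages
    if (is.null(osc)) {
      osc <- ir$oscillatory; fra <- ir$fractal; freq <- ir$freq
    } else {
      osc <- osc + ir$oscillatory; fra <- fra + ir$fractal
    }
  }
  sel <- freq >= 2 & freq <= 30
  expect_true(all(abs(osc[sel]) / fra[sel] < 0.10))
})

test_that("IRASA grows its alpha peak monotonically with alpha amplitude", {
  fs <- 250
  peak <- vapply(c(2, 5, 10), function(a) {
    set.seed(10)
    n <- fs * 30
    x <- one_over_f_noise(n, 1, fs, sd = 5) +
      a * sin(2 * pi * 10 * (0:(n - 1)) / fs)
    ir <- irasa_decompose(x, fs)
    max(ir$oscillatory[ir$freq >= 9 & ir$freq <= 11])
  }, numeric(1))
  expect_true(all(diff(peak) > 0))
})

test_that("resampling factors at or below 1 are refused", {
  expect_error(irasa_decompose(rnorm(2000), 250, resampling_set = c(0.9, 1.1)),
               "exceed 1")
  expect_error(irasa_decompose(rnorm(100), 250), "4 s")
})

test_that("the lateralization topography is an antisymmetric label difference", {
  set.seed(11)
  pow <- array(rexp(40 * 3 * 6), c(40, 3, 6))
  al <- make_alpha(pow, c("PO7", "PO8", "Oz"),
                   labels = rep(c("left", "right"), 20))
  m1 <- lateralization_topography(al, c(0, 100))
  al2 <- al
  al2$labels <- ifelse(al$labels == "left", "right", "left")
  m2 <- lateralization_topography(al2, c(0, 100))
  expect_equal(m1$value, -m2$value)
  # identical left/right trial sets -> all-zero map
  pow3 <- pow
  pow3[al$labels == "right", , ] <- pow3[al$labels == "left", , ]
  al3 <- make_alpha(pow3, c("PO7", "PO8", "Oz"), labels = al$labels)
  expect_equal(lateralization_topography(al3, c(0, 100))$value, rep(0, 3))
  expect_error(lateralization_topography(make_alpha(pow, c("PO7", "PO8", "Oz"),
                                                    labels = rep("left", 40)),
                                         c(0, 100)), "both")
})

test_that("a simulated posterior effect shows up at posterior channels", {
  cfg <- desk_config(n_trials = 80, seed = 21, lateralization_fraction = 0.3)
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  pre <- preprocess_raw(ses$raw, ses$events, target_rate = 250)
  ep <- epoch_events(pre$raw, pre$events, lock = "response",
                     window_ms = c(-1500, 200))
  al <- tf_alpha_power(ep)
  map <- lateralization_topography(al, c(-1000, 0))
  top <- map$channel[order(-abs(map$value))][1:6]
  expect_true(all(top %in% montage_groups(the_montage)$posterior_19))
  # sign flips across hemispheres: attending left suppresses right-hemisphere
  # alpha, so the left-minus-right difference is negative over the right scalp
  v_po7 <- map$value[map$channel == "PO7"]
  v_po8 <- map$value[map$channel == "PO8"]
  expect_lt(v_po7 * v_po8, 0)
})
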