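test_that("the pointwise one-sample t matches hand computation", {
  # mean 0.7, sd 0.1, n 3 against 0.5: t = 0.2 / (0.1/sqrt(3)) = 3.4641
  res <- pointwise_onesample_t(matrix(c(0.6, 0.7, 0.8), 3, 1))
  expect_equal(res$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)

  expect_equal(pointwise_onesample_t(matrix(0.5, 4, 3))$t, rep(0, 3))

  # adding a constant shifts every t upward
  set.seed(21)
  acc <- matrix(runif(5 * 10, 0.4, 0.6), 5)
  t0 <- pointwise_onesample_t(acc)$t
  t1 <- pointwise_onesample_t(acc + 0.05)$t
  expect_true(all(t1 > t0))

  # zero variance -> signed infinite sentinel
  zv <- pointwise_onesample_t(matrix(c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2), 3, 2))
  expect_identical(zv$t, c(Inf, -Inf))
  expect_error(pointwise_onesample_t(matrix(0.5, 2, 3)), "3 subjects")
})

test_that("cluster extraction returns maximal runs with summed masses", {
  # threshold chosen so the critical value is exactly 2
  thr <- pt(2, 3, lower.tail = FALSE)
  cl <- cluster_mass(c(0, 3, 3, 0, 3, 0), df = 3, threshold_p = thr)
  expect_equal(cl$start, c(2, 5))
  expect_equal(cl$end, c(3, 5))
  expect_equal(cl$mass, c(6, 3))
  expect_equal(nrow(cluster_mass(rep(0.5, 10), df = 3)), 0)
})

test_that("cluster extraction agrees with a run-scanner oracle on 1000 curves", {
  set.seed(22)
  df <- 9
  tcrit <- qt(0.95, df)
  mism <- 0
  for (r in 1:1000) {
    tc <- rnorm(60, mean = 0.8)
    got <- cluster_mass(tc, df)
    want <- cluster_oracle(tc, tcrit)
    if (is.null(want)) {
      if (nrow(got) != 0) mism <- mism + 1
    } else if (nrow(got) != nrow(want) ||
               any(got$start != want[, "start"]) ||
               any(got$end != want[, "end"]) ||
               any(abs(got$mass - want[, "mass"]) > 1e-12)) {
      mism <- mism + 1
    }
  }
  expect_equal(mism, 0)
})

test_that("cluster Monte-Carlo p-values are floored, reproducible, and sane", {
  set.seed(23)
  alphas <- lapply(1:4, function(s) {
    pow <- array(rexp(40 * 3 * 12), c(40, 3, 12))
    pow[1:20, 1, 7:12] <- pow[1:20, 1, 7:12] + 4  # strong planted effect
    make_alpha(pow, c("P3", "P4", "Oz"),
               labels = rep(c("left", "right"), each = 20))
  })
  p <- decode_params(channel_set = c("P3", "P4", "Oz"), n_iterations = 2,
                     seed = 3)
  r1 <- cluster_monte_carlo(alphas, p, n_permutations = 60, seed = 41,
                            montage = the_montage)
  r2 <- cluster_monte_carlo(alphas, p, n_permutations = 60, seed = 41,
                            montage = the_montage)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max_mass, r2$null_max_mass)
  expect_true(all(r1$clusters$p >= 1 / 61))
  expect_true(all(r1$clusters$p <= 1))
  # the planted effect is found
  sig <- r1$clusters[r1$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$end_ms >= 120))
  expect_error(cluster_monte_carlo(alphas, p, n_permutations = 10),
               "coarse")
})

test_that("the asymmetry test flips sign exactly under label swap", {
  set.seed(24)
  chs <- montage_groups(the_montage)$posterior_19
  pow <- array(rexp(50 * 19 * 6), c(50, 19, 6))
  labs <- rep(c("left", "right"), 25)
  al <- make_alpha(pow, chs, labels = labs)
  al2 <- make_alpha(pow, chs, labels = ifelse(labs == "left", "right", "left"))
  t1 <- alpha_asymmetry_test(al, c(0, 100), the_montage)
  t2 <- alpha_asymmetry_test(al2, c(0, 100), the_montage)
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-12)
  expect_equal(t1$p.value, t2$p.value, tolerance = 1e-12)
  # Welch CI contains the estimate
  expect_true(t1$conf.int[1] <= t1$estimate && t1$estimate <= t1$conf.int[2])
})

test_that("asymmetry p-values are uniform under the null", {
  set.seed(25)
  chs <- montage_groups(the_montage)$posterior_19
  pvals <- replicate(200, {
    pow <- array(rexp(40 * 19 * 4), c(40, 19, 4))
    al <- make_alpha(pow, chs, labels = sample(rep(c("left", "right"), 20)))
    alpha_asymmetry_test(al, c(0, 60), the_montage)$p.value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a simulated lateralized session yields a significant asymmetry", {
  cfg <- desk_config(n_trials = 120, seed = 31, lateralization_fraction = 0.3)
  truth <- sample_behavior(cfg)
  ses <- synthesize_session(cfg, the_montage, truth)
  pre <- preprocess_raw(ses$raw, ses$events, target_rate = 250)
  ep <- epoch_events(pre$raw, pre$events, lock = "response",
                     window_ms = c(-1500, 200))
  al <- tf_alpha_power(ep, channels = montage_groups(the_montage)$posterior_19)
  tt <- alpha_asymmetry_test(al, c(-1000, 0), the_montage)
  expect_lt(tt$p.value, 0.01)
  # attending left suppresses right-hemisphere alpha, so the left-minus-right
  # index is larger on attend-left trials: positive t for left vs right
  expect_gt(tt$statistic, 0)
})

test_that("the latency side test uses Welch machinery over pooled truths", {
  truths <- lapply(1:3, function(s) sample_behavior(desk_config(n_trials = 50,
                                                                seed = s)))
  tt <- latency_side_test(truths)
  expect_s3_class(tt, "wd_ttest")
  expect_equal(tt$n, 150)
  expect_true(tt$df > 0 && tt$df < 149)
  td <- tidy(tt)
  expect_equal(td$statistic, tt$statistic)
})

test_that("the lag-1 logistic slope matches glm and a likelihood grid search", {
  set.seed(26)
  sides <- sample(c("left", "right"), 400, replace = TRUE,
                  prob = c(0.55, 0.45))
  fit <- sequential_dependence_test(sides)
  g <- stats::glm(I(sides[-1] == "left") ~ I(sides[-length(sides)] == "left"),
                  family = stats::binomial())
  expect_equal(fit$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(g)[1]), tolerance = 1e-6)

  set.seed(27)
  fifty <- sample(c("left", "right"), 50, replace = TRUE)
  fit50 <- sequential_dependence_test(fifty)
  grid <- logistic_grid_oracle(fifty)
  expect_equal(fit50$slope, grid[2], tolerance = 1e-3)
})

test_that("i.i.d. choices show no sequential dependence", {
  set.seed(28)
  ok <- replicate(20, {
    fit <- sequential_dependence_test(sample(c("left", "right"), 5000,
                                             replace = TRUE))
    abs(fit$slope) < 0.1 && fit$p.value > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("alternation gives a large negative slope; constancy errors", {
  fit <- sequential_dependence_test(rep(c("left", "right"), 30))
  expect_lt(fit$slope, -5)
  expect_error(sequential_dependence_test(rep("left", 30)), "separation")
  expect_error(sequential_dependence_test(c("left", "right")), "20 trials")
})
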