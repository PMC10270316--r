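test_that("trial equalization retains min(n_left, n_right) per class", {
  labs <- c(rep("left", 60), rep("right", 48))
  ret <- equalize_trial_counts(labs, seed = 1)
  expect_equal(sum(labs[ret] == "left"), 48)
  expect_equal(sum(labs[ret] == "right"), 48)

  # balanced input is untouched for any seed
  labs2 <- rep(c("left", "right"), 48)
  for (s in 1:3) {
    expect_identical(equalize_trial_counts(labs2, seed = s), seq_along(labs2))
  }

  # pooled full-scale counts
  labs3 <- c(rep("left", 4924), rep("right", 4653))
  ret3 <- equalize_trial_counts(labs3, seed = 2)
  expect_equal(as.integer(table(labs3[ret3])), c(4653L, 4653L))

  expect_error(equalize_trial_counts(c("left", "left", "right"), seed = 1),
               "excluded")
})

test_that("equalization respects the kept mask and never touches the smaller class", {
  labs <- c(rep("left", 10), rep("right", 6))
  kept <- rep(TRUE, 16); kept[1] <- FALSE
  ret <- equalize_trial_counts(labs, kept, seed = 3)
  expect_true(all(ret >= 2))
  expect_true(all(11:16 %in% ret))  # smaller class fully retained
})

test_that("well-separated classes decode perfectly; boundary ties are incorrect", {
  set.seed(12)
  X <- rbind(matrix(rnorm(30 * 4, 10), 30), matrix(rnorm(30 * 4, -10), 30))
  labs <- rep(c("left", "right"), each = 30)
  expect_equal(decode_timepoint(X, labs, decode_params(seed = 1)), 1.0)

  # all-constant features: every decision sits on the boundary -> defined
  # accuracy (0 under the conservative tie-break), not an error
  Xc <- matrix(1, 30, 4)
  acc <- decode_timepoint(Xc, rep(c("left", "right"), 15),
                          decode_params(seed = 1))
  expect_true(is.finite(acc))
  expect_equal(acc, 0)
})

test_that("permuted labels decode at chance on average", {
  set.seed(13)
  accs <- replicate(100, {
    decode_timepoint(matrix(rnorm(200 * 4), 200),
                     sample(rep(c("left", "right"), 100)),
                     decode_params(seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("label swap and channel permutation leave accuracies unchanged", {
  set.seed(14)
  nt <- 40; d <- 5; ntp <- 120
  cube <- array(rnorm(nt * d * ntp), c(nt, d, ntp))
  labs <- sample(rep(c("left", "right"), nt / 2))
  y <- as.integer(labs == "right")

  # exact on separable features
  sep <- cube
  sep[labs == "left", , ] <- sep[labs == "left", , ] + 10
  set.seed(1); a <- willdecode:::decode_cube_cpp(sep, y, 3L, 5L)
  set.seed(1); b <- willdecode:::decode_cube_cpp(sep, 1L - y, 3L, 5L)
  perm <- sample(d)
  set.seed(1); cc <- willdecode:::decode_cube_cpp(sep[, perm, ], y, 3L, 5L)
  expect_identical(a, b)
  expect_identical(a, cc)

  # statistical on noise features (floating-point branch flips only)
  set.seed(1); n1 <- willdecode:::decode_cube_cpp(cube, y, 3L, 5L)
  set.seed(1); n2 <- willdecode:::decode_cube_cpp(cube, 1L - y, 3L, 5L)
  set.seed(1); n3 <- willdecode:::decode_cube_cpp(cube[, perm, ], y, 3L, 5L)
  expect_lt(abs(mean(n1) - mean(n2)), 0.02)
  expect_lt(abs(mean(n1) - mean(n3)), 0.02)
})

test_that("the SMO solver agrees with libsvm predictions on tiny exemplar sets", {
  set.seed(15)
  agree <- 0
  total <- 0
  for (r in 1:100) {
    X <- matrix(rnorm(4 * 3), 4, 3)
    y <- c(-1, -1, 1, 1)
    Xs <- scale(X)
    fit <- willdecode:::svm_weights_cpp(Xs[, ], y)
    te <- matrix(rnorm(6 * 3), 6, 3)
    tes <- scale(te, attr(Xs, "scaled:center"), attr(Xs, "scaled:scale"))
    ours <- ifelse(as.numeric(tes %*% fit$w + fit$b) > 0, 1, -1)
    sv <- e1071::svm(Xs[, ], factor(y), kernel = "linear", cost = 1,
                     scale = FALSE)
    theirs <- as.numeric(as.character(predict(sv, tes)))
    agree <- agree + sum(ours == theirs)
    total <- total + length(ours)
  }
  expect_gte(agree / total, 0.98)
})

test_that("the decoding timecourse spans the alpha grid with NA edges only", {
  set.seed(16)
  al <- make_alpha(array(rexp(30 * 4 * 8), c(30, 4, 8)),
                   c("P3", "P4", "PO7", "PO8"))
  al$power[, , 1] <- NA  # simulated edge timepoint
  cv <- decode_timecourse(al, decode_params(channel_set = c("P3", "P4", "PO7", "PO8"),
                                            n_iterations = 2, seed = 5))
  expect_s3_class(cv, "wd_curve")
  expect_equal(nrow(cv), 8)
  expect_true(is.na(cv$accuracy[1]))
  expect_true(all(!is.na(cv$accuracy[-1])))
  expect_true(all(cv$accuracy[-1] >= 0 & cv$accuracy[-1] <= 1))
})

test_that("empirical chance curves are reproducible, bounded, and centred", {
  set.seed(17)
  al <- make_alpha(array(rexp(60 * 3 * 5), c(60, 3, 5)),
                   c("P3", "P4", "Oz"))
  p <- decode_params(channel_set = c("P3", "P4", "Oz"), n_iterations = 2,
                     seed = 9)
  n1 <- empirical_chance_curve(al, p, n_null_runs = 40, seed = 31,
                               montage = the_montage)
  n2 <- empirical_chance_curve(al, p, n_null_runs = 40, seed = 31,
                               montage = the_montage)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_lt(abs(mean(n1) - 0.5), 0.03)
})

test_that("display smoothing is a shrinking-window moving average", {
  x <- rep(0, 21); x[11] <- 1
  sm <- smooth_curve(x, 5)
  expect_equal(sm[9:13], rep(0.2, 5))
  expect_equal(sm[1:8], rep(0, 8))
  expect_equal(smooth_curve(rep(0.7, 10), 5), rep(0.7, 10))
  # interior mean preservation
  set.seed(18)
  y <- rnorm(50)
  expect_equal(mean(smooth_curve(y, 5)[10:40]), mean(y[10:40]),
               tolerance = 0.2)
  expect_error(smooth_curve(y, 4), "odd")
  expect_error(smooth_curve(y[1:3], 5), "exceeds")
})

test_that("weight maps localize a planted single-channel effect", {
  set.seed(19)
  chs <- montage_groups(the_montage)$all_nonreference
  nt <- 60
  pow <- array(rexp(nt * length(chs) * 5), c(nt, length(chs), 5))
  labs <- rep(c("left", "right"), each = nt / 2)
  pow[labs == "left", which(chs == "POz"), ] <-
    pow[labs == "left", which(chs == "POz"), ] + 3
  al <- make_alpha(pow, chs, labels = labs)
  wm <- suppressWarnings(
    corrected_weight_maps(al, decode_params(channel_set = "all_nonreference",
                                            seed = 4),
                          windows = list(c(0, 80)), montage = the_montage))
  expect_equal(wm$channel[which.max(abs(wm$value))], "POz")
  expect_true(all(is.finite(wm$value)))
})

test_that("class-identical features give near-zero patterns", {
  set.seed(20)
  chs <- c("P3", "P4", "PO7", "PO8", "Oz")
  base <- array(rexp(30 * 5 * 5), c(30, 5, 5))
  pow <- array(0, c(60, 5, 5))
  pow[1:30, , ] <- base
  pow[31:60, , ] <- base
  al <- make_alpha(pow, chs, labels = rep(c("left", "right"), each = 30))
  wm <- suppressWarnings(
    corrected_weight_maps(al, decode_params(channel_set = chs, seed = 4),
                          windows = list(c(0, 80)), montage = the_montage))
  # planted-effect patterns are an order of magnitude larger than this
  expect_lt(max(abs(wm$value)), 0.5)
})
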