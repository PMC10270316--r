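#' Decoding parameters
#'
#' @param n_folds Cross-validation folds (default 3).
#' @param n_iterations Repeats with re-randomized fold partitions
#'   (default 10).
#' @param channel_set `"posterior_19"`, `"central_19"`,
#'   `"all_nonreference"`, or a character vector of channel labels.
#' @param smoothing_width Display smoothing width in timepoints (odd,
#'   default 5). Never applied before statistics.
#' @param seed Integer seed controlling trial equalization and fold
#'   partitions.
#' @return A list of class `wd_decode_params`.
#' @export
decode_params <- function(n_folds = 3, n_iterations = 10,
                          channel_set = "posterior_19",
                          smoothing_width = 5, seed = 1L) {
  stopifnot(n_folds >= 2, smoothing_width %% 2 == 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 channel_set = channel_set,
                 smoothing_width = as.integer(smoothing_width),
                 seed = as.integer(seed)),
            class = "wd_decode_params")
}

#' Equalize trial counts between the two attend-side classes
#'
#' Randomly subsamples the larger class (seeded shuffle without
#' replacement) so both classes contribute `min(n_left, n_right)` trials;
#' the smaller class is untouched, absorbing the variable left/right
#' counts that self-generated choices produce.
#'
#' @param labels Character vector of `"left"`/`"right"` per trial.
#' @param kept Logical kept mask (default all `TRUE`).
#' @param seed Integer seed.
#' @param n_folds Minimum per-class count required (default 3).
#' @return Sorted integer indices of retained trials.
#' @export
equalize_trial_counts <- function(labels, kept = rep(TRUE, length(labels)),
                                  seed = 1L, n_folds = 3) {
  idx_l <- which(kept & labels == "left")
  idx_r <- which(kept & labels == "right")
  m <- min(length(idx_l), length(idx_r))
  if (m < n_folds) {
    stop("a class has fewer than n_folds (", n_folds, ") kept trials; ",
         "subject must be excluded")
  }
  set.seed(seed)
  if (length(idx_l) > m) idx_l <- sample(idx_l, m)
  if (length(idx_r) > m) idx_r <- sample(idx_r, m)
  sort(c(idx_l, idx_r))
}

#' Decode attend side from a single timepoint's features
#'
#' Trials of each class are partitioned into `n_folds` shuffled groups;
#' within every fold each class's trials are averaged into one exemplar; a
#' soft-margin linear SVM (cost 1, features standardized by training-fold
#' statistics) is trained on the exemplars of `n_folds - 1` folds and
#' tested on the held-out fold's two exemplars. Accuracy is the fraction of
#' correct test exemplars across folds, averaged over
#' `n_iterations` re-randomized partitions. A test exemplar exactly on the
#' decision boundary counts as incorrect (conservative, deterministic
#' tie-break), so all-constant features yield a defined accuracy rather
#' than an error.
#'
#' @param features Trials x channels matrix (classes already equalized).
#' @param labels `"left"`/`"right"` per trial.
#' @param params A `wd_decode_params`.
#' @param seed Seed (defaults to `params$seed`).
#' @return Accuracy in `[0, 1]`.
#' @export
decode_timepoint <- function(features, labels, params = decode_params(),
                             seed = params$seed) {
  set.seed(seed)
  cube <- array(as.matrix(features), dim = c(nrow(features), ncol(features), 1))
  y <- as.integer(labels == "right")
  as.numeric(decode_cube_cpp(cube, y, params$n_folds, params$n_iterations))
}

#' Per-timepoint decoding timecourse for one subject
#'
#' Equalizes trial counts once (seed-controlled), then applies
#' [decode_timepoint()] independently at every timepoint of the alpha-power
#' grid using the resolved channel set's power values as features. The
#' returned curve is unsmoothed; display smoothing is a separate,
#' explicitly flagged step.
#'
#' @param alpha A `wd_alpha`.
#' @param params A `wd_decode_params`.
#' @param montage A `wd_montage` used to resolve `params$channel_set`.
#' @return A tibble of class `wd_curve` with columns `time_ms` and
#'   `accuracy` (NA at edge timepoints without a full analysis window);
#'   attributes carry the params and trial counts.
#' @export
decode_timecourse <- function(alpha, params = decode_params(),
                              montage = default_montage()) {
  channels <- resolve_channel_set(montage, params$channel_set)
  ch_idx <- match(channels, alpha$channel_names)
  if (anyNA(ch_idx)) stop("alpha power lacks channels of the requested set")
  retained <- equalize_trial_counts(alpha$labels, alpha$kept,
                                    seed = params$seed,
                                    n_folds = params$n_folds)
  cube <- alpha$power[retained, ch_idx, , drop = FALSE]
  y <- as.integer(alpha$labels[retained] == "right")
  set.seed(params$seed + 1L)
  acc <- decode_cube_cpp(cube, y, params$n_folds, params$n_iterations)
  out <- tibble::tibble(time_ms = alpha$time_ms, accuracy = as.numeric(acc))
  attr(out, "params") <- params
  attr(out, "n_per_class") <- length(retained) %/% 2L
  attr(out, "subject_id") <- alpha$subject_id
  class(out) <- c("wd_curve", class(out))
  out
}

#' Empirical chance-level curves from random relabeling
#'
#' Re-runs the decoding timecourse with the attend-side labels replaced by
#' i.i.d. uniform draws over the two classes (the empirical chance-level
#' construction), `n_null_runs` times with distinct seeds derived from
#' `seed`. Equalization and fold averaging are applied to the random labels
#' exactly as to real ones.
#'
#' @param alpha A `wd_alpha`.
#' @param params A `wd_decode_params`.
#' @param n_null_runs Number of null curves.
#' @param seed Master seed for the ensemble.
#' @param montage A `wd_montage`.
#' @return Matrix `n_null_runs` x timepoints of null accuracies.
#' @export
empirical_chance_curve <- function(alpha, params = decode_params(),
                                   n_null_runs = 100, seed = params$seed,
                                   montage = default_montage()) {
  null_mat <- matrix(NA_real_, nrow = n_null_runs,
                     ncol = length(alpha$time_ms))
  shuffled <- alpha
  for (r in seq_len(n_null_runs)) {
    run_seed <- stage_seed(seed, paste0("null", r))
    set.seed(run_seed)
    shuffled$labels <- ifelse(runif(length(alpha$labels)) < 0.5,
                              "left", "right")
    p <- params
    p$seed <- run_seed
    null_mat[r, ] <- decode_timecourse(shuffled, p, montage)$accuracy
  }
  null_mat
}

#' Group decoding curve across subjects
#'
#' @param curves List of per-subject `wd_curve` tibbles on a common grid.
#' @param chance_level Chance reference (default 0.5).
#' @return A list of class `wd_decoding`: `per_subject` (subjects x
#'   timepoints), `time_ms`, `group_mean`, `group_se`, `chance_level`.
#' @export
group_decoding_curve <- function(curves, chance_level = 0.5) {
  time_ms <- curves[[1]]$time_ms
  per_subject <- do.call(rbind, lapply(curves, function(cv) cv$accuracy))
  structure(list(per_subject = per_subject, time_ms = time_ms,
                 group_mean = colMeans(per_subject),
                 group_se = apply(per_subject, 2, stats::sd) /
                   sqrt(nrow(per_subject)),
                 chance_level = chance_level,
                 params = attr(curves[[1]], "params")),
            class = "wd_decoding")
}

#' @export
print.wd_decoding <- function(x, ...) {
  cat(sprintf("<wd_decoding> %d subjects x %d timepoints, chance %.2f, peak mean %.3f\n",
              nrow(x$per_subject), ncol(x$per_subject), x$chance_level,
              max(x$group_mean, na.rm = TRUE)))
  invisible(x)
}

#' Centered moving-average smoothing (display only)
#'
#' Five-point (by default) centred moving average with shrinking windows at
#' the edges. Intended for plotting; statistics always run on the
#' unsmoothed curve.
#'
#' @param x Numeric vector (NAs allowed at edges).
#' @param width Odd window width, `<= length(x)`.
#' @return Smoothed vector of the same length.
#' @export
smooth_curve <- function(x, width = 5) {
  if (width %% 2 == 0) stop("smoothing width must be odd")
  if (width > length(x)) stop("smoothing width exceeds curve length")
  half <- width %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Covariance-corrected classifier patterns (weight maps)
#'
#' For each requested time window the alpha power is averaged over the
#' window's timepoints, the fold-averaged SVM is trained as in
#' [decode_timepoint()], and each fold's weight vector is transformed into
#' an activation pattern by multiplying with the trial-feature covariance
#' (with a small diagonal shrinkage when near-singular). Patterns are
#' averaged over folds and iterations; any deviation from zero indicates
#' the strength of a channel's contribution to the decoding.
#'
#' @param alpha A `wd_alpha` (typically over all non-reference channels).
#' @param params A `wd_decode_params`.
#' @param windows List of two-element ms windows.
#' @param montage A `wd_montage`.
#' @param shrinkage Diagonal covariance shrinkage fraction (default 1e-6).
#' @return Tibble of class `wd_weightmap` with columns `channel`,
#'   `window_start_ms`, `window_end_ms`, `value`.
#' @export
corrected_weight_maps <- function(alpha, params = decode_params(channel_set = "all_nonreference"),
                                  windows, montage = default_montage(),
                                  shrinkage = 1e-6) {
  channels <- resolve_channel_set(montage, params$channel_set)
  ch_idx <- match(channels, alpha$channel_names)
  if (anyNA(ch_idx)) stop("alpha power lacks channels of the requested set")
  retained <- equalize_trial_counts(alpha$labels, alpha$kept,
                                    seed = params$seed,
                                    n_folds = params$n_folds)
  labels <- alpha$labels[retained]
  n_folds <- params$n_folds
  out <- list()
  set.seed(params$seed + 2L)
  for (w in windows) {
    tsel <- which(alpha$time_ms >= w[1] & alpha$time_ms <= w[2])
    feats <- apply(alpha$power[retained, ch_idx, tsel, drop = FALSE],
                   c(1, 2), mean, na.rm = TRUE)
    if (anyNA(feats)) stop("window ", w[1], "..", w[2],
                           " ms has no trained classifier (edge timepoints)")
    covf <- stats::cov(feats)
    tr <- mean(diag(covf))
    if (rcond_safe(covf) < 1e-10) {
      warning("near-singular feature covariance; applying diagonal shrinkage")
    }
    covf <- covf + diag(shrinkage * max(tr, 1e-12), ncol(feats))
    pat_acc <- numeric(ncol(feats))
    n_pat <- 0L
    idx_l <- which(labels == "left")
    idx_r <- which(labels == "right")
    for (it in seq_len(params$n_iterations)) {
      il <- sample(idx_l)
      ir <- sample(idx_r)
      per_l <- length(il) %/% n_folds
      per_r <- length(ir) %/% n_folds
      ex <- lapply(seq_len(n_folds), function(f) {
        rbind(colMeans(feats[il[((f - 1) * per_l + 1):(f * per_l)], , drop = FALSE]),
              colMeans(feats[ir[((f - 1) * per_r + 1):(f * per_r)], , drop = FALSE]))
      })
      for (f in seq_len(n_folds)) {
        train <- do.call(rbind, ex[-f])
        ytr <- rep(c(-1, 1), n_folds - 1)
        mu <- colMeans(train)
        sdv <- apply(train, 2, stats::sd)
        sdv[sdv < 1e-12] <- 1
        train_std <- sweep(sweep(train, 2, mu), 2, sdv, "/")
        fit <- svm_weights_cpp(train_std, ytr)
        w_orig <- fit$w / sdv
        pat_acc <- pat_acc + as.numeric(covf %*% w_orig)
        n_pat <- n_pat + 1L
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(
      channel = channels, window_start_ms = w[1], window_end_ms = w[2],
      value = pat_acc / n_pat)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("wd_weightmap", class(res))
  res
}

rcond_safe <- function(m) {
  tryCatch(1 / kappa(m, exact = FALSE), error = function(e) 0)
}
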