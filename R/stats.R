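#' Pointwise one-sample t statistics against chance
#'
#' One-sample t of the per-subject decoding accuracies against the chance
#' level at every timepoint. Below-chance decoding is not of interest, so
#' cluster membership downstream uses the one-sided (above-chance) critical
#' value. Zero variance across subjects yields a `+Inf`/`-Inf` sentinel
#' according to the sign of the mean deviation.
#'
#' @param per_subject Subjects x timepoints accuracy matrix (>= 3 subjects).
#' @param chance Chance level (default 0.5).
#' @return List with `t` (per timepoint, NA where accuracies are NA) and
#'   `df` (subjects - 1).
#' @export
pointwise_onesample_t <- function(per_subject, chance = 0.5) {
  n <- nrow(per_subject)
  if (n < 3) stop("need at least 3 subjects")
  mns <- colMeans(per_subject)
  sds <- apply(per_subject, 2, stats::sd)
  tval <- (mns - chance) / (sds / sqrt(n))
  zero <- !is.na(sds) & sds == 0
  tval[zero & mns > chance] <- Inf
  tval[zero & mns < chance] <- -Inf
  tval[zero & mns == chance] <- 0
  list(t = tval, df = n - 1)
}

#' Contiguous supra-threshold clusters of a t curve
#'
#' Finds maximal runs of timepoints whose t value exceeds the one-sided
#' critical value at `threshold_p`, and sums the member t values into the
#' cluster mass.
#'
#' @param t_curve Numeric t values (NA allowed; NA breaks a run).
#' @param df Degrees of freedom for the critical value.
#' @param threshold_p Pointwise threshold (default 0.05, one-sided).
#' @return Tibble with columns `start`, `end` (indices into `t_curve`) and
#'   `mass`.
#' @export
cluster_mass <- function(t_curve, df, threshold_p = 0.05) {
  tcrit <- qt(1 - threshold_p, df)
  supra <- !is.na(t_curve) & t_curve > tcrit
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  tibble::tibble(
    start = starts[sel], end = ends[sel],
    mass = vapply(sel, function(i) sum(t_curve[starts[i]:ends[i]]), numeric(1))
  )
}

#' Cluster-based Monte-Carlo inference on group decoding curves
#'
#' Computes the observed pointwise t curve and its supra-threshold
#' clusters, then builds a null distribution of maximum cluster masses: in
#' each permutation every subject's curve is replaced by a decoding run on
#' i.i.d. random labels (the empirical chance construction), the pointwise
#' t curve is recomputed, and the largest cluster mass (0 when none) is
#' recorded. Each observed cluster's p-value is
#' `(1 + #(null >= mass)) / (1 + n_permutations)`, which controls the
#' family-wise type 1 error at the cluster level.
#'
#' @param alphas List of per-subject `wd_alpha` objects.
#' @param params A `wd_decode_params`.
#' @param n_permutations Monte-Carlo permutations (>= 20).
#' @param threshold_p Pointwise cluster-forming threshold (default 0.05).
#' @param seed Master seed for the permutation ensemble.
#' @param montage A `wd_montage`.
#' @param curves Optional precomputed list of observed per-subject
#'   `wd_curve`s (skips recomputation).
#' @param t_cap Finite cap applied to the infinite zero-variance t
#'   sentinels before cluster masses are formed (observed and null alike);
#'   it exceeds every achievable finite t, so capping only makes infinite
#'   masses comparable (default 100).
#' @return A list of class `wd_clusters`: `clusters` (tibble with
#'   `cluster_id`, `start_ms`, `end_ms`, `mass`, `p`), `pointwise_t`,
#'   `time_ms`, `null_max_mass`, `n_permutations`, `observed` (the
#'   `wd_decoding` group curve).
#' @export
cluster_monte_carlo <- function(alphas, params = decode_params(),
                                n_permutations = 1000, threshold_p = 0.05,
                                seed = params$seed,
                                montage = default_montage(),
                                curves = NULL, t_cap = 100) {
  if (n_permutations < 20) {
    stop("n_permutations below 20 gives too coarse a p-value resolution")
  }
  if (is.null(curves)) {
    curves <- lapply(alphas, decode_timecourse, params = params,
                     montage = montage)
  }
  observed <- group_decoding_curve(curves)
  tw <- pointwise_onesample_t(observed$per_subject)
  obs_clusters <- cluster_mass(pmin(tw$t, t_cap), tw$df, threshold_p)

  channels <- resolve_channel_set(montage, params$channel_set)
  cubes <- lapply(alphas, function(a) {
    ch_idx <- match(channels, a$channel_names)
    a$power[a$kept, ch_idx, , drop = FALSE]
  })
  set.seed(stage_seed(seed, "mcnull"))
  null_max <- as.numeric(mc_null_max_mass_cpp(
    cubes, n_permutations, params$n_folds, params$n_iterations,
    qt(1 - threshold_p, length(alphas) - 1), 0.5, t_cap))

  pvals <- vapply(obs_clusters$mass, function(m) {
    (1 + sum(null_max >= m)) / (1 + n_permutations)
  }, numeric(1))
  clusters <- tibble::tibble(
    cluster_id = seq_len(nrow(obs_clusters)),
    start_ms = observed$time_ms[obs_clusters$start],
    end_ms = observed$time_ms[obs_clusters$end],
    mass = obs_clusters$mass, p = pvals
  )
  structure(list(clusters = clusters, pointwise_t = tw$t, df = tw$df,
                 time_ms = observed$time_ms, null_max_mass = null_max,
                 n_permutations = n_permutations, threshold_p = threshold_p,
                 observed = observed),
            class = "wd_clusters")
}

#' @export
print.wd_clusters <- function(x, ...) {
  cat(sprintf("<wd_clusters> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_permutations))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Posterior alpha-power asymmetry test between attend sides
#'
#' Per trial, alpha power is averaged over the window and over the
#' left-hemisphere posterior channels minus the right-hemisphere posterior
#' channels (midline sites excluded), giving one asymmetry index per trial.
#' Attend-left and attend-right trials are compared with a two-sided
#' Welch two-sample t test, pooling trials across subjects when a list of
#' alpha objects is given.
#'
#' @param alpha A `wd_alpha` or list of them.
#' @param window_ms Two-element window in ms (e.g. `c(-1000, 0)` relative
#'   to the press).
#' @param montage A `wd_montage`.
#' @return A list of class `wd_ttest` (fields `statistic`, `df`, `p.value`,
#'   `conf.int`, `estimate`, `window_ms`, `n`), with [tidy()] support.
#' @export
alpha_asymmetry_test <- function(alpha, window_ms = c(-1000, 0),
                                 montage = default_montage()) {
  alphas <- if (inherits(alpha, "wd_alpha")) list(alpha) else alpha
  post <- montage_groups(montage)$posterior_19
  left_ch <- post[grepl("[13579]$", post) & !grepl("10$", post)]
  right_ch <- post[grepl("[02468]$", post) | grepl("10$", post)]
  idx_vals <- list()
  idx_labs <- list()
  for (a in alphas) {
    tsel <- a$time_ms >= window_ms[1] & a$time_ms <= window_ms[2]
    li <- match(left_ch, a$channel_names)
    ri <- match(right_ch, a$channel_names)
    if (anyNA(li) || anyNA(ri)) stop("alpha power lacks posterior channels")
    keep <- which(a$kept)
    lv <- apply(a$power[keep, li, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
    rv <- apply(a$power[keep, ri, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
    idx_vals[[length(idx_vals) + 1]] <- lv - rv
    idx_labs[[length(idx_labs) + 1]] <- a$labels[keep]
  }
  vals <- unlist(idx_vals)
  labs <- unlist(idx_labs)
  if (!any(labs == "left") || !any(labs == "right")) {
    stop("both attend sides must be present")
  }
  tt <- stats::t.test(vals[labs == "left"], vals[labs == "right"],
                      var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, conf.int = as.numeric(tt$conf.int),
                 estimate = unname(diff(rev(tt$estimate))),
                 window_ms = window_ms, n = length(vals),
                 test = "alpha asymmetry (Welch two-sample t)"),
            class = "wd_ttest")
}

#' Welch t test of trial latencies by attended side
#'
#' @param truth A `wd_truth` or list of them (pooled).
#' @return A `wd_ttest`.
#' @export
latency_side_test <- function(truth) {
  truths <- if (inherits(truth, "wd_truth")) list(truth) else truth
  lat <- unlist(lapply(truths, function(tr) tr$press_s - tr$array_onset_s))
  side <- unlist(lapply(truths, function(tr) tr$side))
  tt <- stats::t.test(lat[side == "left"], lat[side == "right"],
                      var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, conf.int = as.numeric(tt$conf.int),
                 estimate = unname(diff(rev(tt$estimate))),
                 window_ms = NULL, n = length(lat),
                 test = "trial latency by side (Welch two-sample t)"),
            class = "wd_ttest")
}

#' @export
print.wd_ttest <- function(x, ...) {
  cat(sprintf("<wd_ttest> %s: t = %.4f, df = %.1f, p = %.4g, CI [%.4f, %.4f]\n",
              x$test, x$statistic, x$df, x$p.value,
              x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

# In-package logistic regression via iteratively reweighted least squares.
irls_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    if (all(w < 1e-12)) break
    z <- eta + (y - p) / pmax(w, 1e-12)
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) stop(
                           "complete separation: logistic fit is degenerate"))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  W <- as.numeric(p * (1 - p))
  se <- tryCatch(sqrt(diag(solve(t(X * W) %*% X))),
                 error = function(e) rep(Inf, ncol(X)))
  list(coefficients = as.numeric(beta), se = se)
}

#' Sequential dependence of attend-side choices
#'
#' Logistic regression (in-package IRLS) of the current choice on the
#' previous choice; under the instruction to choose spontaneously, the slope
#' should be near zero. Returns the slope and its Wald p-value.
#'
#' @param sides Character vector of `"left"`/`"right"` choices in trial
#'   order (>= 20 trials).
#' @return A list of class `wd_seqdep`: `slope`, `se`, `z`, `p.value`,
#'   `intercept`, `n`.
#' @export
sequential_dependence_test <- function(sides) {
  if (length(sides) < 20) stop("need at least 20 trials")
  if (length(unique(sides)) < 2) {
    stop("complete separation: all choices identical")
  }
  y <- as.integer(sides[-1] == "left")
  prev <- as.integer(sides[-length(sides)] == "left")
  X <- cbind(1, prev)
  fit <- irls_logistic(X, y)
  z <- fit$coefficients[2] / fit$se[2]
  structure(list(slope = fit$coefficients[2], se = fit$se[2], z = z,
                 p.value = 2 * stats::pnorm(-abs(z)),
                 intercept = fit$coefficients[1], n = length(y)),
            class = "wd_seqdep")
}

#' @export
print.wd_seqdep <- function(x, ...) {
  cat(sprintf("<wd_seqdep> slope = %.4f (se %.4f), z = %.3f, p = %.4g, n = %d\n",
              x$slope, x$se, x$z, x$p.value, x$n))
  invisible(x)
}
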