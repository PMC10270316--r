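#' Tidy a group decoding curve
#'
#' @param x A `wd_decoding`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `mean_acc`, `se`, `acc_smoothed`,
#'   `chance`.
#' @export
tidy.wd_decoding <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, mean_acc = x$group_mean,
                 se = x$group_se, acc_smoothed = smooth_curve(x$group_mean),
                 chance = x$chance_level)
}

#' @export
glance.wd_decoding <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$per_subject),
                 n_timepoints = ncol(x$per_subject),
                 peak_acc = max(x$group_mean, na.rm = TRUE),
                 peak_time_ms = x$time_ms[which.max(x$group_mean)],
                 chance = x$chance_level)
}

#' Tidy a cluster inference result
#'
#' @param x A `wd_clusters`.
#' @param ... Unused.
#' @return The cluster table: `cluster_id`, `start_ms`, `end_ms`, `mass`,
#'   `p`.
#' @export
tidy.wd_clusters <- function(x, ...) x$clusters

#' @export
glance.wd_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p < 0.05),
                 min_p = if (nrow(x$clusters) == 0) NA_real_ else min(x$clusters$p),
                 n_permutations = x$n_permutations,
                 threshold_p = x$threshold_p)
}

#' Tidy a t-test result
#'
#' @param x A `wd_ttest`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `statistic`, `df`, `p.value`,
#'   `conf.low`, `conf.high`, `n`.
#' @export
tidy.wd_ttest <- function(x, ...) {
  tibble::tibble(test = x$test, estimate = x$estimate,
                 statistic = x$statistic, df = x$df, p.value = x$p.value,
                 conf.low = x$conf.int[1], conf.high = x$conf.int[2],
                 n = x$n)
}

#' Tidy a sequential-dependence fit
#'
#' @param x A `wd_seqdep`.
#' @param ... Unused.
#' @return One-row tibble with `slope`, `se`, `z`, `p.value`, `n`.
#' @export
tidy.wd_seqdep <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se, z = x$z, p.value = x$p.value,
                 intercept = x$intercept, n = x$n)
}

#' Tidy an IRASA decomposition into a long spectrum table
#'
#' @param x A `wd_irasa`.
#' @param ... Unused.
#' @return Tibble with `freq`, `component`
#'   (`total`/`fractal`/`oscillatory`), `psd`.
#' @export
tidy.wd_irasa <- function(x, ...) {
  tibble::tibble(freq = rep(x$freq, 3),
                 component = rep(c("total", "fractal", "oscillatory"),
                                 each = length(x$freq)),
                 psd = c(x$total, x$fractal, x$oscillatory))
}
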