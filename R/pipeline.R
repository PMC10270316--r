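#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end analysis
#' (simulate -> preprocess -> alpha power -> decode -> cluster statistics).
#' Every stochastic stage derives its seed deterministically from
#' `master_seed` and the stage name, so a run is reproducible from the
#' configuration alone.
#'
#' The default configuration is the package's reduced desk scale (4
#' subjects, 60 trials, 250 samples/s synthesis, 2.2 s mean latencies,
#' response-locked window -2500..500 ms, 2 decoding iterations, 200
#' permutations), sized so a full run completes in minutes; the full
#' experiment scale (20 subjects, ~479 trials, 1000 samples/s, 3.9 s latencies,
#' -4000..1400 ms, 10 iterations) is available by passing the corresponding
#' [sim_config()] and window values.
#'
#' @param sim A `wd_sim_config` (the `seed` field is overridden per subject
#'   from `master_seed`).
#' @param locks Epoch locks to analyse (`"response"`, `"stimulus"` or both).
#' @param window_response,window_stimulus Epoch windows in ms.
#' @param channel_sets Channel sets to decode.
#' @param n_iterations Decoding iterations per timepoint.
#' @param n_permutations Monte-Carlo permutations for cluster inference.
#' @param reject `TRUE` to run the 100 uV artifact and 20 uV eye-movement
#'   rejectors.
#' @param target_rate Preprocessing output rate in Hz.
#' @param master_seed Master seed for all stages.
#' @return A list of class `wd_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_subjects = 4, n_trials = 60,
                                             sampling_rate = 250,
                                             trial_latency = c(2.2, 0.6),
                                             attention_lead = c(1.5, 0.3),
                                             blink_rate = 0),
                            locks = c("response"),
                            window_response = c(-2500, 500),
                            window_stimulus = c(-1000, 4000),
                            channel_sets = c("posterior_19"),
                            n_iterations = 2,
                            n_permutations = 200,
                            reject = TRUE,
                            target_rate = 250,
                            master_seed = 1L) {
  structure(list(sim = sim, locks = locks,
                 window_response = window_response,
                 window_stimulus = window_stimulus,
                 channel_sets = channel_sets,
                 n_iterations = as.integer(n_iterations),
                 n_permutations = as.integer(n_permutations),
                 reject = reject, target_rate = target_rate,
                 master_seed = as.integer(master_seed)),
            class = "wd_pipeline_config")
}

# Simulate + preprocess + epoch + reject + alpha power for one subject.
process_subject <- function(config, montage, subject, channels) {
  sim <- config$sim
  sim$seed <- stage_seed(config$master_seed, paste0("subject", subject))
  truth <- sample_behavior(sim)
  session <- synthesize_session(sim, montage, truth)
  pre <- preprocess_raw(session$raw, session$events,
                        target_rate = config$target_rate)
  out <- list(truth = truth, alphas = list(), counts = list())
  for (lock in config$locks) {
    win <- if (lock == "response") config$window_response else config$window_stimulus
    ep <- epoch_events(pre$raw, pre$events, lock = lock, window_ms = win,
                       subject_id = paste0("S", subject))
    n_total <- dim(ep$data)[1]
    if (config$reject) {
      ep <- reject_artifacts_p2p(ep)
      ep <- reject_eye_movements(ep)
    }
    out$counts[[lock]] <- c(simulated = sim$n_trials,
                            epoched = n_total,
                            dropped_bounds = ep$n_dropped_bounds,
                            kept = sum(ep$kept),
                            rejected = n_total - sum(ep$kept))
    out$alphas[[lock]] <- tf_alpha_power(ep, channels = channels)
  }
  out
}

#' Run the full willed-attention analysis pipeline
#'
#' For every simulated subject: generate ground-truth behavior and the
#' synthetic session, preprocess, epoch at the configured locks, reject
#' artifacts, and extract alpha power; then decode every configured channel
#' set per subject, aggregate group curves, and run cluster-based
#' Monte-Carlo inference. Behavioral tests (latency by side, sequential
#' dependence) and the posterior asymmetry test are computed alongside.
#'
#' @param config A `wd_pipeline_config`.
#' @param out_dir Optional directory; when given, curves, clusters, truth
#'   tables, a stats summary (JSON) and a manifest (JSON) are written there.
#' @param montage A `wd_montage`.
#' @return A list of class `wd_run`: `truths`, `alphas` (per lock, per
#'   subject), `curves`, `decodings`, `clusters` (per lock x channel set),
#'   `asymmetry`, `latency_test`, `seqdep`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         montage = default_montage()) {
  channels <- unique(unlist(lapply(config$channel_sets, resolve_channel_set,
                                   montage = montage)))
  subjects <- seq_len(config$sim$n_subjects)
  per_subject <- lapply(subjects, function(s)
    process_subject(config, montage, s, channels))
  truths <- lapply(per_subject, `[[`, "truth")

  alphas <- list()
  for (lock in config$locks) {
    alphas[[lock]] <- lapply(per_subject, function(ps) ps$alphas[[lock]])
  }

  curves <- list()
  decodings <- list()
  clusters <- list()
  for (lock in config$locks) {
    for (set in config$channel_sets) {
      key <- paste(lock, set, sep = ".")
      params <- decode_params(n_iterations = config$n_iterations,
                              channel_set = set,
                              seed = stage_seed(config$master_seed,
                                                paste0("decode.", key)))
      cvs <- lapply(alphas[[lock]], decode_timecourse, params = params,
                    montage = montage)
      curves[[key]] <- cvs
      decodings[[key]] <- group_decoding_curve(cvs)
      clusters[[key]] <- cluster_monte_carlo(
        alphas[[lock]], params, n_permutations = config$n_permutations,
        seed = stage_seed(config$master_seed, paste0("mc.", key)),
        montage = montage, curves = cvs)
    }
  }

  resp_alphas <- if ("response" %in% config$locks) alphas[["response"]] else NULL
  asymmetry <- if (!is.null(resp_alphas)) {
    alpha_asymmetry_test(resp_alphas, window_ms = c(-1000, 0),
                         montage = montage)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("willdecode")),
    master_seed = config$master_seed,
    n_subjects = config$sim$n_subjects,
    subject_seeds = vapply(subjects, function(s)
      stage_seed(config$master_seed, paste0("subject", s)), numeric(1)),
    trial_counts = lapply(per_subject, `[[`, "counts"),
    locks = config$locks, channel_sets = config$channel_sets,
    n_permutations = config$n_permutations
  )
  run <- structure(list(config = config, truths = truths, alphas = alphas,
                        curves = curves, decodings = decodings,
                        clusters = clusters, asymmetry = asymmetry,
                        latency_test = latency_side_test(truths),
                        seqdep = sequential_dependence_test(
                          unlist(lapply(truths, `[[`, "side"))),
                        manifest = manifest),
                   class = "wd_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.wd_run <- function(x, ...) {
  cat(sprintf("<wd_run> %d subjects, locks: %s, channel sets: %s\n",
              x$config$sim$n_subjects, paste(x$config$locks, collapse = ", "),
              paste(x$config$channel_sets, collapse = ", ")))
  for (key in names(x$clusters)) {
    cl <- x$clusters[[key]]$clusters
    sig <- cl[cl$p < 0.05, ]
    cat(sprintf("  %s: %d cluster(s), %d significant\n", key, nrow(cl),
                nrow(sig)))
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(run$decodings)) {
    dec <- run$decodings[[key]]
    tab <- tibble::tibble(
      time_ms = dec$time_ms, mean_acc = dec$group_mean, se = dec$group_se,
      acc_smoothed = smooth_curve(dec$group_mean))
    readr::write_tsv(tab, file.path(out_dir, paste0("curve_", key, ".tsv")))
    readr::write_tsv(run$clusters[[key]]$clusters,
                     file.path(out_dir, paste0("clusters_", key, ".tsv")))
  }
  readr::write_tsv(dplyr::bind_rows(run$truths, .id = "subject"),
                   file.path(out_dir, "truth.tsv"))
  stats_summary <- list(
    asymmetry = if (!is.null(run$asymmetry)) tidy(run$asymmetry),
    latency = tidy(run$latency_test),
    sequential_dependence = tidy(run$seqdep)
  )
  jsonlite::write_json(stats_summary, file.path(out_dir, "stats_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(run, file.path(out_dir, "run.rds"))
  invisible(out_dir)
}

#' Render the figure set of a pipeline run
#'
#' Produces the analysis's standard figure set from a completed run: trial
#' latency and target reaction-time histograms, the alpha lateralization
#' topography in 500 ms sections, decoding curves with SE ribbons and
#' significant clusters marked, and (when available) an IRASA spectrum
#' panel. Figures are written as PDF, plus PNG when the device supports it.
#'
#' @param run A `wd_run`.
#' @param out_dir Output directory for figures.
#' @param montage A `wd_montage`.
#' @return Invisible character vector of files written.
#' @export
render_report <- function(run, out_dir, montage = default_montage()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_fig <- function(plot, name, width = 7, height = 5) {
    pdf_path <- file.path(out_dir, paste0(name, ".pdf"))
    ggplot2::ggsave(pdf_path, plot, width = width, height = height)
    written <<- c(written, pdf_path)
    if (capabilities("png")) {
      png_path <- file.path(out_dir, paste0(name, ".png"))
      ggplot2::ggsave(png_path, plot, width = width, height = height, dpi = 120)
      written <<- c(written, png_path)
    }
  }
  truth_all <- dplyr::bind_rows(run$truths, .id = "subject")
  save_fig(plot_latency_histogram(truth_all), "latency_histogram")
  save_fig(plot_rt_histogram(truth_all), "rt_histogram")
  for (key in names(run$decodings)) {
    save_fig(autoplot(run$clusters[[key]]), paste0("decoding_", key))
  }
  if ("response" %in% run$config$locks) {
    a <- run$alphas[["response"]]
    sections <- list(c(-2000, -1500), c(-1500, -1000), c(-1000, -500),
                     c(-500, 0))
    t0 <- min(a[[1]]$time_ms)
    sections <- Filter(function(s) s[1] >= t0, sections)
    maps <- dplyr::bind_rows(lapply(sections, function(s) {
      m <- dplyr::bind_rows(lapply(a, lateralization_topography,
                                   window_ms = s))
      m <- dplyr::summarise(dplyr::group_by(m, .data$channel),
                            value = mean(.data$value), .groups = "drop")
      m$section <- sprintf("%d..%d ms", s[1], s[2])
      m
    }))
    if (nrow(maps) > 0) {
      save_fig(plot_topography(maps, montage, facet = "section"),
               "alpha_difference_topography", width = 9, height = 3.2)
    }
  }
  invisible(written)
}
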