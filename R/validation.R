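#' Validation harnesses for the synthetic study
#'
#' These functions rerun the pipeline on freshly generated synthetic
#' datasets with known ground truth and summarize how well it recovers
#' the generative structure: the chosen number of template maps, the
#' injected duration-model coefficients, and the calibration of the
#' topographic consistency test.
#'
#' @name validation
NULL

# merged, filtered grand-average ERP over the analysis window (>= 50 ms)
.grand_analysis_erp <- function(epochs, band = c(0.2, 30)) {
  gm <- merge_epoch_set(average_epochs(epochs, "grand"),
                        strict_gaps = FALSE)$merged
  gm <- filter_epochs(gm, band[1], band[2])
  erp <- gm$data[[1]]
  t_ms <- (seq_len(ncol(erp)) - 1L) * 1000 / gm$sampling_rate
  list(erp = erp[, t_ms >= 50], time_ms = t_ms[t_ms >= 50],
       sampling_rate = gm$sampling_rate)
}

#' Map-count selection rate over seeds
#'
#' Simulates a study per seed, computes the merged band-passed grand
#' average, segments it over the analysis window, and records the
#' KL/CV-selected number of template maps.
#'
#' @param config a \code{\link{synthetic_config}} (its seed is replaced
#'   per run).
#' @param seeds integer vector of seeds.
#' @param k_min,k_max candidate range (default 2-8).
#' @return integer vector of selected K, one per seed.
#' @export
k_selection_rate <- function(config, seeds, k_min = 2L, k_max = 8L) {
  vapply(seeds, function(s) {
    config$seed <- s
    sim <- simulate_dataset(config)
    g <- .grand_analysis_erp(sim$epochs)
    seg <- suppressWarnings(microstate_segment(g$erp, g$sampling_rate,
                                               k_min, k_max))
    seg$selected_k
  }, integer(1))
}

#' Duration-model coefficient recovery over seeds
#'
#' Per seed: simulate, merge, low-pass the single trials (30 Hz; the
#' 0.2 Hz high-pass stays on the averages, where it cannot bias
#' durations), segment the grand average at the generative number of
#' maps, backfit into single trials, and fit the crossed random-intercept
#' duration model per requested map (plus the latency model). The
#' backfitting windows place every state boundary strictly inside a
#' window that allows both neighboring maps (50-460 ms: maps A-D;
#' 460 ms to articulation - 100 ms: maps D-E), so that no boundary
#' variance is censored at a window edge — the measurement-validity
#' counterpart of the replication windows in
#' \code{\link{default_fitting_windows}}. Returns one row per seed x
#' model x fixed term with the estimate, its confidence interval
#' (Satterthwaite df), the generative coefficient, and significance at
#' \code{alpha}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seeds seeds to run.
#' @param maps template indices whose duration models to fit
#'   (default 2, 4, 5: the maps carrying injected effects).
#' @param alpha significance level for the duration models (default 0.01).
#' @param refit_outliers apply the 2.5-SD refit (default TRUE).
#' @return data frame with columns seed, model, term, beta, se, df, p,
#'   true, covered, significant.
#' @export
coefficient_recovery <- function(config, seeds, maps = c(2L, 4L, 5L),
                                 alpha = 0.01, refit_outliers = TRUE) {
  fixed <- default_fixed_terms("book")
  out <- list()
  for (s in seeds) {
    config$seed <- s
    sim <- simulate_dataset(config)
    g <- .grand_analysis_erp(sim$epochs)
    seg <- suppressWarnings(microstate_segment(
      g$erp, g$sampling_rate, force_k = config$n_states))
    # permissive merging: excluding trials whose RT exceeds the combined
    # epoch coverage would truncate the response-time distribution and
    # bias every RT-correlated coefficient
    merged <- filter_epochs(merge_epoch_set(sim$epochs,
                                            strict_gaps = FALSE)$merged,
                            NULL, 30)
    windows <- list(fitting_window(50, 460, seq_len(max(config$n_states - 1L, 2L)),
                                   "early"),
                    fitting_window(460, NA, c(config$n_states - 1L,
                                              config$n_states), "late"))
    ft <- backfit_set(merged, seg$templates, windows)
    dur <- merge(map_durations(ft), sim$norms, by = "item_id")
    # latency model on the full behavioral set (independent of merging)
    rt_rows <- merge(sim$ground_truth[, c("trial_id", "participant_id",
                                          "item_id", "rt_ms")],
                     sim$norms, by = "item_id")
    one <- function(rows, response, label, a) {
      m <- fit_mixed(rows, model_spec(response, fixed, alpha = a))
      if (refit_outliers) m <- suppressWarnings(refit_without_outliers(m))
      co <- m$coefficients[-1L, ]   # drop intercept
      tv <- stats::qt(0.975, co$df)
      true <- if (label == "rt") colSums(config$coefficients)[fixed]
              else config$coefficients[as.integer(sub("map", "", label)), fixed]
      true[is.na(true)] <- 0
      data.frame(seed = s, model = label, term = co$term, beta = co$beta,
                 se = co$se, df = co$df, p = co$p, true = unname(true),
                 covered = abs(co$beta - true) <= tv * co$se,
                 significant = co$p < a, row.names = NULL)
    }
    out[[length(out) + 1L]] <- one(rt_rows, "rt_ms", "rt", 0.05)
    for (k in maps)
      out[[length(out) + 1L]] <-
        one(dur[dur$template == k, ], "duration_ms", paste0("map", k), alpha)
  }
  do.call(rbind, out)
}

#' Type-I error calibration of the topographic consistency test
#'
#' Repeatedly draws frames of pure white-noise maps (no shared
#' topography) and records the rejection rate of
#' \code{\link{tct_at_frame}} at \code{alpha}.
#'
#' @param n_reps number of null repetitions (default 500).
#' @param n_trials trials per repetition (default 50).
#' @param n_channels channels (default 19).
#' @param n_perm permutations per test (default 99).
#' @param alpha nominal level (default 0.05).
#' @return list with \code{rejection_rate} and the vector of
#'   \code{p_values}.
#' @export
tct_type1 <- function(n_reps = 500L, n_trials = 50L, n_channels = 19L,
                      n_perm = 99L, alpha = 0.05) {
  p <- vapply(seq_len(n_reps), function(i) {
    maps <- matrix(stats::rnorm(n_channels * n_trials), n_channels)
    tct_at_frame(maps, n_perm)$p_value
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p)
}
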