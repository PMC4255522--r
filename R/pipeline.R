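#' Run the full trial-by-trial topographic analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or use of supplied
#' epochs), band-pass filtering, error/RT-based trial exclusion,
#' amplitude-based artifact rejection, bad-channel interpolation, merging
#' of stimulus- and response-aligned epochs, grand-average computation,
#' microstate segmentation of the grand average over the analysis window
#' (50 ms post onset to 100 ms before articulation), optional topographic
#' consistency testing on a subset of items, backfitting into single
#' trials and subject averages, and the crossed random-effects regression
#' suite. All stage outputs are returned; \code{\link{report}} writes
#' them as TSVs.
#'
#' @param config a \code{\link{synthetic_config}} (used when \code{epochs}
#'   is NULL; its \code{seed} seeds the whole run).
#' @param epochs optionally, a pre-existing \code{epoch_set} with
#'   \code{norms} supplied separately.
#' @param norms item predictor table (required with \code{epochs}).
#' @param band band-pass edges in Hz (default c(0.2, 30)).
#' @param amp_threshold_uv amplitude rejection threshold (default 100).
#' @param rt_window_ms RT exclusion window (default c(500, 1500)).
#' @param k_min,k_max candidate map counts for segmentation.
#' @param min_duration_ms minimum map duration (default 20).
#' @param force_k optional forced number of maps.
#' @param windows fitting windows; NULL for the defaults when K = 5.
#' @param tct_items number of randomly selected items to run the
#'   topographic consistency test on (0 = skip; default 0).
#' @param n_perm TCT permutations (default 999).
#' @param random_slopes initial by-participant random slopes for the
#'   regression suite.
#' @param variant regression variant policy (see
#'   \code{\link{run_analysis_suite}}).
#' @return object of class \code{erpmicro_run}: list with elements
#'   \code{config}, \code{reports} (rejection bookkeeping), \code{merged},
#'   \code{grand_erp}, \code{analysis_start_frame}, \code{segmentation},
#'   \code{tct}, \code{fit_trials}, \code{fit_subjects}, \code{suite},
#'   \code{norms}, \code{ground_truth}.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         epochs = NULL, norms = NULL,
                         band = c(0.2, 30), amp_threshold_uv = 100,
                         rt_window_ms = c(500, 1500),
                         k_min = 2L, k_max = 8L, min_duration_ms = 20,
                         force_k = NULL, windows = NULL,
                         tct_items = 0L, n_perm = 999L,
                         random_slopes = c("AoA", "IAgr", "NAgr_pct"),
                         variant = "ld_phonotactics") {
  ground_truth <- NULL
  if (is.null(epochs)) {
    sim <- simulate_dataset(config)
    epochs <- sim$epochs; norms <- sim$norms; ground_truth <- sim$ground_truth
  } else if (is.null(norms)) stop("norms must be supplied with epochs")
  reports <- list()

  beh <- exclude_by_rt_and_accuracy(epochs, rt_window_ms[1], rt_window_ms[2])
  reports$behavioral <- beh$report
  amp <- reject_amplitude(beh$kept, amp_threshold_uv)
  reports$amplitude <- amp$report
  set <- amp$kept
  if ("bad_channels" %in% names(set$trials)) {
    for (i in which(nzchar(set$trials$bad_channels))) {
      bad <- strsplit(set$trials$bad_channels[i], ",")[[1]]
      set$stim[[i]] <- interpolate_bad_channels(set$stim[[i]], bad, set$layout)
      set$resp[[i]] <- interpolate_bad_channels(set$resp[[i]], bad, set$layout)
    }
  }

  # merge first, then filter the continuous encoding-period ERP: one
  # filter transient per trial instead of two independently filtered
  # segments meeting at the junction. Single trials get the low-pass
  # only: on a sub-second epoch the 0.2 Hz high-pass amounts to removing
  # the trial's own mean topography, which biases backfit durations; the
  # full band is applied to the averages, where the removed mean is
  # common to all trials.
  mg <- merge_epoch_set(set, strict_gaps = TRUE)
  reports$merge <- mg$report
  merged <- filter_epochs(mg$merged, NULL, band[2])

  grand <- average_epochs(set, "grand")
  grand_merged <- filter_epochs(merge_epoch_set(grand, strict_gaps = FALSE)$merged,
                                band[1], band[2])
  fs <- set$sampling_rate
  erp <- grand_merged$data[[1]]
  t_ms <- (seq_len(ncol(erp)) - 1L) * 1000 / fs
  a0 <- which(t_ms >= 50)[1]
  seg <- microstate_segment(erp[, a0:ncol(erp)], fs, k_min, k_max,
                            min_duration_ms, force_k,
                            time_ms = t_ms[a0:ncol(erp)])

  tct <- NULL
  if (tct_items > 0L) {
    items <- sample(unique(merged$trials$item_id), tct_items)
    tct <- lapply(items, function(it)
      tct_scan(.subset_epochs(merged, merged$trials$item_id == it),
               n_perm = n_perm))
    names(tct) <- items
  }

  fit_trials <- predict(seg, merged, windows = windows)
  subj <- average_epochs(set, "participant")
  subj_merged <- filter_epochs(merge_epoch_set(subj, strict_gaps = FALSE)$merged,
                               NULL, band[2])
  subj_merged$trials$item_id <- "average"
  fit_subjects <- predict(seg, subj_merged, windows = windows)

  suite <- run_analysis_suite(fit_trials, norms,
                              random_slopes = random_slopes, variant = variant)

  structure(list(config = config, reports = reports, merged = merged,
                 grand_erp = erp, analysis_start_frame = a0,
                 segmentation = seg, tct = tct,
                 fit_trials = fit_trials, fit_subjects = fit_subjects,
                 suite = suite, norms = norms, ground_truth = ground_truth),
            class = "erpmicro_run")
}

#' @export
print.erpmicro_run <- function(x, ...) {
  cat("== erpmicro pipeline run ==\n")
  for (nm in names(x$reports)) { cat("\n[", nm, "]\n", sep = ""); print(x$reports[[nm]]) }
  cat("\n"); print(x$segmentation)
  cat("\nTrial-level map presence:\n")
  print(presence_and_gev_report(x$fit_trials), digits = 3)
  cat("\n"); print(x$suite)
  invisible(x)
}

#' Write a pipeline run to disk as TSV tables
#'
#' Writes template maps, segmentation labels, criterion curves, rejection
#' reports, trial- and subject-level fit tables and presence/GEV
#' summaries, model coefficient tables, a model summary table, and a run
#' manifest with parameters and output file hashes.
#'
#' @param run an \code{erpmicro_run}.
#' @param dir output directory.
#' @return \code{dir}, invisibly; the manifest lists every file written.
#' @export
report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  seg <- run$segmentation
  tm <- as.data.frame(seg$templates)
  names(tm) <- LETTERS[seq_len(ncol(tm))]
  wt(cbind(channel = seq_len(nrow(tm)), tm), "templates.tsv")
  wt(data.frame(frame = seq_along(seg$labels),
                time_ms = seg$time_ms,
                label = LETTERS[seg$labels]), "labels.tsv")
  wt(seg$criteria, "criteria.tsv")
  for (nm in names(run$reports))
    wt(as.data.frame(run$reports[[nm]]), paste0("rejection_", nm, ".tsv"))
  wt(run$fit_trials, "fit_trials.tsv")
  wt(run$fit_subjects, "fit_subjects.tsv")
  wt(presence_and_gev_report(run$fit_trials), "presence_trials.tsv")
  wt(presence_and_gev_report(run$fit_subjects), "presence_subjects.tsv")
  if (!is.null(run$tct))
    for (it in names(run$tct)) wt(run$tct[[it]], paste0("tct_", it, ".tsv"))
  models <- c(list(rt = run$suite$rt_model), run$suite$map_models)
  if (!is.null(run$suite$variant_model))
    models$variant <- run$suite$variant_model
  summ <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    wt(m$coefficients, paste0("model_", nm, ".tsv"))
    summ[[nm]] <- data.frame(
      model = nm, n_obs_initial = m$n_obs_initial, n_obs_refit = m$n_obs_refit,
      r2_marginal = m$r2_marginal, r2_conditional = m$r2_conditional,
      converged = m$converged, singular = m$singular,
      dropped_slopes = paste(m$dropped_slopes, collapse = ","))
  }
  wt(do.call(rbind, summ), "model_summary.tsv")
  wt(data.frame(tolerance = run$suite$tolerance,
                predictor = names(run$suite$tolerance)), "tolerance.tsv")
  files <- setdiff(list.files(dir), "run_manifest.tsv")
  cfg <- run$config
  pars <- vapply(cfg, function(v) paste(format(v), collapse = ","), character(1))
  manifest <- rbind(
    data.frame(key = paste0("config.", names(pars)), value = unname(pars)),
    data.frame(key = paste0("md5.", files),
               value = unname(tools::md5sum(file.path(dir, files)))))
  wt(manifest, "run_manifest.tsv")
  invisible(dir)
}
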