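#' Epoched EEG containers
#'
#' An \code{epoch_set} holds, per trial, a stimulus-aligned epoch (from
#' picture onset, default 450 ms) and a response-aligned epoch (default
#' -550 to +100 ms around articulation onset), both as channels x samples
#' matrices in layout row order, together with the trial manifest
#' (participant, item, reaction time, accuracy). A \code{merged_set} holds
#' one matrix per trial covering picture onset to 100 ms before
#' articulation (see \code{\link{merge_epochs}}).
#'
#' @param trials data frame with columns \code{trial_id},
#'   \code{participant_id}, \code{item_id}, \code{rt_ms}, \code{accuracy}
#'   (1 = correct, 0 = error).
#' @param stim,resp lists of channels x samples matrices, one per trial row.
#' @param layout an \code{\link{eeg_layout}}.
#' @param sampling_rate sampling rate in Hz (default 512).
#' @return an object of class \code{epoch_set}.
#' @export
epoch_set <- function(trials, stim, resp, layout, sampling_rate = 512) {
  need <- c("trial_id", "participant_id", "item_id", "rt_ms", "accuracy")
  if (!all(need %in% names(trials)))
    stop("trials must have columns ", paste(need, collapse = ", "))
  n <- nrow(trials)
  if (length(stim) != n || length(resp) != n)
    stop("stim and resp must have one matrix per trial")
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive")
  nc <- nrow(layout)
  ok <- vapply(seq_len(n), function(i)
    nrow(stim[[i]]) == nc && nrow(resp[[i]]) == nc, logical(1))
  if (!all(ok)) stop("epoch matrices must have one row per layout channel")
  structure(list(trials = trials, stim = stim, resp = resp,
                 layout = layout, sampling_rate = sampling_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials, %d channels @ %g Hz, %d participants, %d items\n",
              nrow(x$trials), nrow(x$layout), x$sampling_rate,
              length(unique(x$trials$participant_id)),
              length(unique(x$trials$item_id))))
  invisible(x)
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("<merged_set> %d merged trials, %d channels @ %g Hz (onset to rt - %g ms)\n",
              nrow(x$trials), nrow(x$layout), x$sampling_rate, x$cut_ms))
  invisible(x)
}

# number of samples spanned by `ms` milliseconds
n_samples <- function(ms, sampling_rate) as.integer(round(ms * sampling_rate / 1000))

.subset_epochs <- function(set, keep) {
  set$trials <- set$trials[keep, , drop = FALSE]
  rownames(set$trials) <- NULL
  for (f in intersect(c("stim", "resp", "data"), names(set)))
    set[[f]] <- set[[f]][keep]
  set
}

#' Rejection bookkeeping
#'
#' Accumulates exclusion counts and trial ids per reason; each trial is
#' attributed to the first criterion that rejected it, and percentages are
#' reported relative to the full initial trial count.
#'
#' @param n_total initial number of trials.
#' @return object of class \code{rejection_report}.
#' @keywords internal
rejection_report <- function(n_total) {
  structure(list(n_total = n_total, reasons = list()), class = "rejection_report")
}

.add_reason <- function(report, reason, trial_ids) {
  report$reasons[[reason]] <- trial_ids
  report
}

#' @export
as.data.frame.rejection_report <- function(x, ...) {
  if (!length(x$reasons))
    return(data.frame(reason = character(), n = integer(), pct = numeric()))
  data.frame(reason = names(x$reasons),
             n = vapply(x$reasons, length, integer(1)),
             pct = 100 * vapply(x$reasons, length, integer(1)) / x$n_total,
             row.names = NULL)
}

#' @export
print.rejection_report <- function(x, ...) {
  d <- as.data.frame(x)
  cat(sprintf("<rejection_report> %d trials in, %d excluded\n",
              x$n_total, sum(d$n)))
  if (nrow(d)) {
    d$pct <- sprintf("%.1f%%", d$pct)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Exclude error trials and reaction-time outliers
#'
#' Error responses (accuracy 0: no-responses, wrong responses, hesitations,
#' auto-corrections) are removed first; among the remaining trials, those
#' with a reaction time below \code{rt_min} or above \code{rt_max} ms are
#' removed. Bounds are strict: a trial at exactly 500 or 1500 ms is kept.
#' Percentages in the report are relative to the full initial count.
#'
#' @param x an \code{epoch_set} or a trials data frame.
#' @param rt_min,rt_max reaction-time window in ms (default 500, 1500).
#' @return list with \code{kept} (same class as \code{x}) and
#'   \code{report} (a \code{rejection_report}).
#' @export
exclude_by_rt_and_accuracy <- function(x, rt_min = 500, rt_max = 1500) {
  stopifnot(rt_min < rt_max)
  trials <- if (inherits(x, "epoch_set")) x$trials else x
  rep <- rejection_report(nrow(trials))
  err <- trials$accuracy == 0
  rep <- .add_reason(rep, "error_response", trials$trial_id[err])
  rt_bad <- !err & (trials$rt_ms < rt_min | trials$rt_ms > rt_max)
  rep <- .add_reason(rep, "rt_out_of_window", trials$trial_id[rt_bad])
  keep <- !err & !rt_bad
  kept <- if (inherits(x, "epoch_set")) .subset_epochs(x, keep)
          else { out <- trials[keep, , drop = FALSE]; rownames(out) <- NULL; out }
  list(kept = kept, report = rep)
}

#' Amplitude-based artifact rejection
#'
#' A trial is excluded iff any sample on any channel, in either the
#' stimulus-aligned or the response-aligned epoch, exceeds the threshold in
#' absolute value (strictly: a sample at exactly the threshold is kept).
#'
#' @param set an \code{epoch_set}.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return list with \code{kept} (an \code{epoch_set}) and \code{report}.
#' @export
reject_amplitude <- function(set, threshold_uv = 100) {
  stopifnot(inherits(set, "epoch_set"), threshold_uv > 0)
  bad <- vapply(seq_len(nrow(set$trials)), function(i) {
    max(abs(set$stim[[i]])) > threshold_uv || max(abs(set$resp[[i]])) > threshold_uv
  }, logical(1))
  rep <- rejection_report(nrow(set$trials))
  rep <- .add_reason(rep, "amplitude", set$trials$trial_id[bad])
  list(kept = .subset_epochs(set, !bad), report = rep)
}
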