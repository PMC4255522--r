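#' Merge stimulus- and response-aligned epochs into one encoding-period ERP
#'
#' Builds, per trial, an ERP covering the whole encoding window from
#' picture onset to \code{pre_articulation_cut_ms} (default 100) ms before
#' articulation onset. Samples up to the end of the stimulus-aligned window
#' (450 ms by construction of the epochs) are taken verbatim from the
#' stimulus-aligned epoch; the remainder is taken verbatim from the tail of
#' the response-aligned epoch, which ends 100 ms before articulation. Where
#' the two alignments overlap, the stimulus-aligned signal wins and the
#' overlapping response-aligned samples are dropped.
#'
#' For reaction times above 1000 ms the two windows (450 ms of stimulus
#' time + 450 ms of pre-articulation time) do not cover the full encoding
#' period; such trials carry a coverage gap. In strict mode (default) they
#' are excluded and logged; in permissive mode the gap is filled by a
#' linear cross-fade between the last stimulus-aligned and first
#' response-aligned sample and the trial is flagged.
#'
#' @param stim,resp channels x samples matrices (stimulus-aligned from
#'   onset; response-aligned ending 100 ms after articulation onset).
#' @param rt_ms the trial's reaction time in ms.
#' @param sampling_rate sampling rate in Hz.
#' @param stim_span_ms extent of the stimulus-aligned epoch (default 450).
#' @param resp_span_ms extent of the response-aligned epoch (default 650,
#'   i.e. -550 to +100 ms around articulation).
#' @param pre_articulation_cut_ms margin before articulation onset excluded
#'   from the merged ERP (default 100).
#' @return list with \code{data} (channels x samples),
#'   \code{junction_sample} (first sample index, 1-based, that came from
#'   the response-aligned epoch; \code{NA} if none did) and \code{gap_flag}.
#' @export
merge_epochs <- function(stim, resp, rt_ms, sampling_rate = 512,
                         stim_span_ms = 450, resp_span_ms = 650,
                         pre_articulation_cut_ms = 100) {
  if (rt_ms <= pre_articulation_cut_ms)
    stop("rt_ms must exceed the pre-articulation cut")
  fs <- sampling_rate
  n_total <- n_samples(rt_ms - pre_articulation_cut_ms, fs)
  n_stim <- min(n_samples(stim_span_ms, fs), ncol(stim))
  n_from_stim <- min(n_total, n_stim)
  out <- matrix(NA_real_, nrow(stim), n_total)
  out[, seq_len(n_from_stim)] <- stim[, seq_len(n_from_stim)]
  n_resp_needed <- n_total - n_from_stim
  gap_flag <- FALSE
  if (n_resp_needed > 0L) {
    # the response-aligned epoch ends 100 ms after articulation onset; its
    # usable tail ends at the pre-articulation cut
    resp_tail_end <- min(n_samples(resp_span_ms - 100 - pre_articulation_cut_ms, fs),
                         ncol(resp))
    n_use <- min(n_resp_needed, resp_tail_end)
    gap_flag <- n_use < n_resp_needed
    take <- seq(resp_tail_end - n_use + 1L, resp_tail_end)
    out[, seq(n_total - n_use + 1L, n_total)] <- resp[, take, drop = FALSE]
    if (gap_flag) {
      gap_cols <- seq(n_from_stim + 1L, n_total - n_use)
      a <- out[, n_from_stim]
      b <- out[, n_total - n_use + 1L]
      w <- seq_along(gap_cols) / (length(gap_cols) + 1L)
      out[, gap_cols] <- a %o% (1 - w) + b %o% w
    }
  }
  list(data = out,
       junction_sample = if (n_resp_needed > 0L) n_from_stim + 1L else NA_integer_,
       gap_flag = gap_flag)
}

#' Merge every trial of an epoch set
#'
#' @param set an \code{epoch_set} (already filtered / artifact-screened).
#' @param strict_gaps if TRUE (default), trials whose reaction time exceeds
#'   the combined coverage of the two alignments are excluded and reported;
#'   if FALSE they are cross-faded and flagged.
#' @inheritParams merge_epochs
#' @return list with \code{merged} (a \code{merged_set}) and \code{report}.
#' @export
merge_epoch_set <- function(set, stim_span_ms = 450, resp_span_ms = 650,
                            pre_articulation_cut_ms = 100, strict_gaps = TRUE) {
  stopifnot(inherits(set, "epoch_set"))
  n <- nrow(set$trials)
  data <- vector("list", n)
  junction <- integer(n); gap <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_epochs(set$stim[[i]], set$resp[[i]], set$trials$rt_ms[i],
                      set$sampling_rate, stim_span_ms, resp_span_ms,
                      pre_articulation_cut_ms)
    data[[i]] <- m$data; junction[i] <- m$junction_sample; gap[i] <- m$gap_flag
  }
  rep <- rejection_report(n)
  trials <- set$trials
  trials$junction_sample <- junction
  trials$gap_flag <- gap
  merged <- structure(list(trials = trials, data = data, layout = set$layout,
                           sampling_rate = set$sampling_rate,
                           cut_ms = pre_articulation_cut_ms),
                      class = "merged_set")
  if (strict_gaps && any(gap)) {
    rep <- .add_reason(rep, "coverage_gap", trials$trial_id[gap])
    merged <- .subset_epochs(merged, !gap)
  }
  list(merged = merged, report = rep)
}

#' Average epochs across trials
#'
#' Point-wise mean of the stimulus-aligned and response-aligned epochs,
#' separately, over all trials of a group (per participant or grand
#' average), with the group mean reaction time attached so that merging of
#' the averages uses the group mean RT.
#'
#' @param set an \code{epoch_set}.
#' @param group_by \code{"participant"} or \code{"grand"}.
#' @return an \code{epoch_set} with one row per group (trial_id =
#'   group label, rt_ms = group mean RT).
#' @export
average_epochs <- function(set, group_by = c("participant", "grand")) {
  stopifnot(inherits(set, "epoch_set"))
  group_by <- match.arg(group_by)
  if (nrow(set$trials) == 0L) stop("cannot average an empty epoch set")
  g <- if (group_by == "grand") rep("grand", nrow(set$trials))
       else as.character(set$trials$participant_id)
  groups <- unique(g)
  avg <- function(lst) Reduce(`+`, lst) / length(lst)
  stim <- lapply(groups, function(gr) avg(set$stim[g == gr]))
  resp <- lapply(groups, function(gr) avg(set$resp[g == gr]))
  trials <- data.frame(trial_id = groups,
                       participant_id = groups,
                       item_id = NA_character_,
                       rt_ms = vapply(groups, function(gr)
                         mean(set$trials$rt_ms[g == gr]), numeric(1)),
                       accuracy = 1L,
                       stringsAsFactors = FALSE)
  epoch_set(trials, stim, resp, set$layout, set$sampling_rate)
}
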