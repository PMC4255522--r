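#' Fitting windows
#'
#' A fitting window constrains which template maps compete for the frames
#' of a time range during backfitting. \code{end_ms = NA} marks a
#' response-relative end: it resolves to \code{rt_ms - cut_ms} (100 ms
#' before articulation) per trial. At least two templates must be allowed
#' per window.
#'
#' @param start_ms,end_ms window bounds in stimulus time (ms);
#'   \code{end_ms = NA} for "until 100 ms before articulation".
#' @param templates integer indices of the allowed template maps.
#' @param name optional window label.
#' @return a \code{fitting_window} list.
#' @export
fitting_window <- function(start_ms, end_ms, templates, name = NULL) {
  templates <- as.integer(templates)
  if (length(templates) < 2L)
    stop("a fitting window must allow at least two template maps")
  structure(list(start_ms = start_ms, end_ms = end_ms,
                 templates = templates,
                 name = if (is.null(name)) sprintf("%g-%s", start_ms,
                   if (is.na(end_ms)) "rt" else as.character(end_ms)) else name),
            class = "fitting_window")
}

#' Default encoding-period fitting windows
#'
#' The three-window scheme for a five-map solution over picture naming:
#' 50-180 ms (maps A, B), 180-460 ms (maps B, C, D) and 460 ms to 100 ms
#' before articulation (maps D, E). Maps crossing a border are entered in
#' both adjacent windows.
#'
#' @return list of \code{fitting_window}s.
#' @export
default_fitting_windows <- function() {
  list(fitting_window(50, 180, c(1L, 2L), "w1"),
       fitting_window(180, 460, c(2L, 3L, 4L), "w2"),
       fitting_window(460, NA, c(4L, 5L), "w3"))
}

#' Resolve fitting windows against a trial's reaction time
#'
#' Replaces response-relative end markers by \code{rt_ms - cut_ms}, clips
#' each window to the merged epoch, and returns the member frame indices.
#' Windows are half-open in time, \code{[start, end)}: the frame at exactly
#' the shared border belongs to the later window. Windows resolving to
#' fewer than \code{min_frames} frames are marked excluded.
#'
#' @param windows list of \code{\link{fitting_window}}s.
#' @param rt_ms trial reaction time (ms); must exceed \code{cut_ms}.
#' @param n_frames_epoch number of samples in the merged epoch.
#' @param sampling_rate sampling rate (Hz).
#' @param cut_ms pre-articulation margin (default 100).
#' @param min_frames minimum usable window length in frames (default 2).
#' @return list per window: \code{frames} (integer indices into the merged
#'   epoch, possibly empty), \code{templates}, \code{excluded}.
#' @export
resolve_windows <- function(windows, rt_ms, n_frames_epoch,
                            sampling_rate = 512, cut_ms = 100,
                            min_frames = 2L) {
  if (rt_ms <= cut_ms) stop("reaction time too short to resolve windows")
  t_ms <- (seq_len(n_frames_epoch) - 1L) * 1000 / sampling_rate
  lapply(windows, function(w) {
    end <- if (is.na(w$end_ms)) rt_ms - cut_ms else w$end_ms
    frames <- which(t_ms >= w$start_ms & t_ms < end)
    list(name = w$name, frames = frames, templates = w$templates,
         start_ms = w$start_ms, end_ms = end,
         excluded = length(frames) < min_frames)
  })
}

#' Backfit template maps into an epoch
#'
#' Labels each frame inside each resolved window with the allowed template
#' map it bears the highest signed spatial correlation with. No temporal
#' smoothing is applied; ties (including zero-GFP frames, which correlate
#' zero with every template) go to the lowest allowed template index.
#' Frames outside all windows stay unlabeled (NA).
#'
#' @param data channels x time matrix (a merged epoch).
#' @param templates channels x K template matrix.
#' @param resolved output of \code{\link{resolve_windows}}.
#' @return integer vector of per-frame labels (NA outside windows).
#' @export
backfit <- function(data, templates, resolved) {
  r <- .corr_frames_templates(data, templates)
  labels <- rep(NA_integer_, ncol(data))
  for (w in resolved) {
    if (w$excluded || !length(w$frames)) next
    rw <- r[w$templates, w$frames, drop = FALSE]
    labels[w$frames] <- w$templates[apply(rw, 2L, which.max)]
  }
  labels
}

#' Summarize a backfit labeling into fit-table rows
#'
#' One row per (window, allowed template): presence, frame count, duration
#' in ms, and the within-window GEV of the template.
#'
#' @param labels per-frame labels from \code{\link{backfit}}.
#' @param data the epoch the labels refer to.
#' @param templates channels x K templates.
#' @param resolved resolved windows.
#' @param sampling_rate sampling rate (Hz).
#' @param presence_min_frames minimum frames for a map to count as present
#'   (default 1).
#' @return data frame with columns window, template, present, n_frames,
#'   duration_ms, gev.
#' @export
summarize_fit <- function(labels, data, templates, resolved,
                          sampling_rate = 512, presence_min_frames = 1L) {
  out <- list()
  g2 <- colMeans(average_reference(data)^2)
  r <- .corr_frames_templates(data, templates)
  for (w in resolved) {
    if (w$excluded) next
    denom <- sum(g2[w$frames])
    for (k in w$templates) {
      sel <- w$frames[!is.na(labels[w$frames]) & labels[w$frames] == k]
      nf <- length(sel)
      gv <- if (denom > 0 && nf > 0) sum(g2[sel] * r[k, sel]^2) / denom else 0
      out[[length(out) + 1L]] <- data.frame(
        window = w$name, template = k,
        present = nf >= presence_min_frames,
        n_frames = nf, duration_ms = nf * 1000 / sampling_rate, gev = gv)
    }
  }
  do.call(rbind, out)
}

#' Backfit template maps into every trial of a merged set
#'
#' @param set a \code{merged_set}.
#' @param templates channels x K template matrix (e.g. from
#'   \code{\link{microstate_segment}}).
#' @param windows list of \code{\link{fitting_window}}s.
#' @param cut_ms pre-articulation margin used when the set was merged.
#' @param presence_min_frames see \code{\link{summarize_fit}}.
#' @return a \code{fit_table}: data frame with columns trial_id,
#'   participant_id, item_id, rt_ms, window, template, present, n_frames,
#'   duration_ms, gev. Attribute \code{excluded_windows} counts trial x
#'   window combinations dropped for being shorter than 2 frames.
#' @export
backfit_set <- function(set, templates, windows = default_fitting_windows(),
                        cut_ms = 100, presence_min_frames = 1L) {
  stopifnot(inherits(set, "merged_set"))
  rows <- vector("list", nrow(set$trials))
  n_excl <- 0L
  for (i in seq_len(nrow(set$trials))) {
    res <- resolve_windows(windows, set$trials$rt_ms[i],
                           ncol(set$data[[i]]), set$sampling_rate, cut_ms)
    n_excl <- n_excl + sum(vapply(res, `[[`, logical(1), "excluded"))
    labels <- backfit(set$data[[i]], templates, res)
    s <- summarize_fit(labels, set$data[[i]], templates, res,
                       set$sampling_rate, presence_min_frames)
    if (is.null(s)) next
    rows[[i]] <- cbind(data.frame(trial_id = set$trials$trial_id[i],
                                  participant_id = set$trials$participant_id[i],
                                  item_id = set$trials$item_id[i],
                                  rt_ms = set$trials$rt_ms[i]), s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_windows") <- n_excl
  class(out) <- c("fit_table", "data.frame")
  out
}

#' Per-map presence and GEV report
#'
#' Aggregates a fit table into, per window and template, the percentage of
#' units (trials or subject averages) in which the map was present and the
#' mean within-window GEV.
#'
#' @param fit_table a \code{fit_table} from \code{\link{backfit_set}}.
#' @return data frame with columns window, template, n_units, presence_pct,
#'   mean_gev.
#' @export
presence_and_gev_report <- function(fit_table) {
  if (!nrow(fit_table)) stop("empty fit table")
  key <- interaction(fit_table$window, fit_table$template, drop = TRUE)
  out <- do.call(rbind, lapply(split(fit_table, key), function(d)
    data.frame(window = d$window[1], template = d$template[1],
               n_units = nrow(d),
               presence_pct = 100 * mean(d$present),
               mean_gev = mean(d$gev))))
  out <- out[order(out$window, out$template), ]
  rownames(out) <- NULL
  out
}

#' Backfit as prediction from a fitted segmentation
#'
#' Applies the template maps of a \code{microstate_segmentation} to new
#' single-trial (or subject-average) merged epochs within fitting windows,
#' returning the per-trial fit table.
#'
#' @param object a \code{microstate_segmentation}.
#' @param newdata a \code{merged_set}.
#' @param windows fitting windows (default \code{default_fitting_windows()}
#'   when the segmentation has 5 maps, else a single full-epoch window over
#'   all maps).
#' @param ... passed to \code{\link{backfit_set}}.
#' @return a \code{fit_table}.
#' @export
predict.microstate_segmentation <- function(object, newdata, windows = NULL, ...) {
  if (is.null(windows)) {
    windows <- if (object$selected_k == 5L) default_fitting_windows()
      else list(fitting_window(0, NA, seq_len(object$selected_k), "all"))
  }
  backfit_set(newdata, object$templates, windows, ...)
}
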