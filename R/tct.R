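#' Topographic consistency test at one time frame
#'
#' Randomization test for the presence of a topography shared across
#' trials. The observed statistic is the global field power of the
#' across-trial mean map; the null distribution is built by independently
#' shuffling the channel values within each trial's map (which preserves
#' each trial's GFP but destroys any shared spatial structure) and
#' recomputing the statistic. The p-value uses the add-one rule,
#' \code{p = (1 + #(null >= observed)) / (n_perm + 1)}.
#'
#' @param maps channels x trials matrix: one topography per trial.
#' @param n_perm number of permutations (default 999, minimum 99).
#' @return list with \code{observed} (GFP of the mean map) and
#'   \code{p_value}.
#' @export
tct_at_frame <- function(maps, n_perm = 999L) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 2L) stop("the consistency test needs at least 2 trials")
  if (n_perm < 99L) stop("use at least 99 permutations")
  nc <- nrow(maps); nt <- ncol(maps)
  maps <- sweep(maps, 2L, colMeans(maps))
  observed <- gfp(rowMeans(maps))
  null_stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- matrix(sample.int(nc * nt), nc, nt)      # random keys
    ord <- matrix(order(col(idx) * (nc * nt + 1) + idx), nc, nt)
    null_stat[b] <- gfp(rowMeans(matrix(maps[ord], nc, nt)))
  }
  list(observed = observed,
       p_value = (1 + sum(null_stat >= observed)) / (n_perm + 1))
}

#' Topographic consistency scan over frames
#'
#' Runs \code{\link{tct_at_frame}} at every requested frame of a common
#' trial-by-frame grid and marks consistent periods: runs of
#' \code{p < alpha} lasting at least \code{min_consistent_ms}.
#'
#' @param set a \code{merged_set} (typically the trials of one item, which
#'   share stimulus-relative timing); frames beyond the shortest trial are
#'   skipped.
#' @param frames integer frame indices to test (default: all frames common
#'   to every trial).
#' @param n_perm permutations per frame (default 999).
#' @param alpha frame-wise significance level (default 0.05).
#' @param min_consistent_ms minimum duration of a consistent period
#'   (default 20 ms).
#' @param seed optional RNG seed for reproducibility.
#' @return data frame with columns frame, time_ms, observed_gfp, p_value,
#'   consistent.
#' @export
tct_scan <- function(set, frames = NULL, n_perm = 999L, alpha = 0.05,
                     min_consistent_ms = 20, seed = NULL) {
  stopifnot(inherits(set, "merged_set"))
  if (!is.null(seed)) set.seed(seed)
  n_common <- min(vapply(set$data, ncol, integer(1)))
  if (is.null(frames)) frames <- seq_len(n_common)
  frames <- frames[frames <= n_common]
  res <- lapply(frames, function(f) {
    maps <- vapply(set$data, function(m) m[, f], numeric(nrow(set$layout)))
    tct_at_frame(maps, n_perm)
  })
  out <- data.frame(frame = frames,
                    time_ms = (frames - 1L) * 1000 / set$sampling_rate,
                    observed_gfp = vapply(res, `[[`, numeric(1), "observed"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  sig <- out$p_value < alpha
  min_frames <- ceiling(min_consistent_ms * set$sampling_rate / 1000)
  runs <- rle(sig)
  keep <- rep(runs$values & runs$lengths >= min_frames, runs$lengths)
  out$consistent <- keep
  out
}
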