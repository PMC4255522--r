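#' Topographic atomize-and-agglomerate hierarchical clustering (TAAHC)
#'
#' Bottom-up clustering of the time frames of an average-referenced ERP by
#' their (GFP-normalized) scalp topography. Every frame starts as its own
#' cluster; at each step the cluster contributing least global explained
#' variance (GEV) is atomized and each of its member frames is reassigned
#' to the remaining cluster whose template it correlates best with
#' (signed spatial correlation; ties go to the lowest template index).
#' Cluster templates are the GFP-normalized means of their members'
#' normalized maps. The procedure is fully deterministic.
#'
#' Purely greedy atomization can leave a K-cluster solution far from the
#' best K-partition (a small genuine cluster contributes little GEV and is
#' dissolved before diffuse ones); at the recorded cluster numbers the
#' solution is therefore polished by Lloyd-type iterations (reassign every
#' frame to its best-correlated template, recompute templates, repeat
#' until stable). Set \code{refine = 0} for the raw greedy hierarchy, in
#' which each solution arises from the next by removing exactly one
#' cluster.
#'
#' @param erp numeric channels x time matrix (average-referenced; it is
#'   re-referenced if not).
#' @param k_min,k_max range of cluster numbers for which solutions are
#'   returned.
#' @param refine maximum Lloyd iterations applied to each recorded
#'   solution (default 25; 0 disables refinement).
#' @return list of solutions indexed by as.character(K); each solution has
#'   \code{templates} (channels x K, unit GFP), \code{labels} (per frame),
#'   \code{gev_per_map}, \code{gev_total} and \code{W} (within-cluster
#'   dispersion, summed squared topographic distance to the assigned
#'   template over GFP-normalized maps).
#' @export
taahc <- function(erp, k_min = 1L, k_max = 10L, refine = 25L) {
  erp <- average_reference(erp)
  nT <- ncol(erp); nC <- nrow(erp)
  if (nT < k_max) stop("fewer time frames than clusters requested")
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max")
  g <- sqrt(colMeans(erp^2))
  if (all(g == 0)) stop("all-zero ERP cannot be segmented")
  nz <- g > 0
  U <- sweep(erp, 2L, ifelse(nz, g, 1), "/")  # unit-GFP maps (zero frames stay 0)
  gfp2 <- g^2
  denom <- sum(gfp2)

  make_templates_of <- function(labels, ids) {
    tmpl <- vapply(ids, function(k) {
      v <- rowMeans(U[, labels == k, drop = FALSE])
      v <- v - mean(v)
      s <- sqrt(mean(v^2))
      if (s > 0) v / s else v
    }, numeric(nC))
    matrix(tmpl, nrow = nC)
  }

  labels <- seq_len(nT)
  solutions <- list()
  repeat {
    ids <- sort(unique(labels))
    K <- length(ids)
    tmpl <- make_templates_of(labels, ids)
    r <- .corr_frames_templates(erp, tmpl)           # K x T
    if (K <= k_max && refine > 0L) {
      for (it in seq_len(refine)) {
        new_lab <- ids[apply(r, 2L, which.max)]
        new_lab[!nz] <- labels[!nz]                  # zero-GFP frames stay put
        if (any(tabulate(match(new_lab, ids), K) == 0L)) break
        if (identical(new_lab, labels)) break
        labels <- new_lab
        tmpl <- make_templates_of(labels, ids)
        r <- .corr_frames_templates(erp, tmpl)
      }
    }
    lab_idx <- match(labels, ids)
    r_own <- r[cbind(lab_idx, seq_len(nT))]
    gev_k <- vapply(seq_len(K), function(k)
      sum((gfp2 * r_own^2)[lab_idx == k]) / denom, numeric(1))
    if (K <= k_max) {
      W <- sum(2 * (1 - r_own[nz]))
      solutions[[as.character(K)]] <- list(
        templates = tmpl, labels = lab_idx,
        gev_per_map = gev_k, gev_total = sum(gev_k), W = W)
    }
    if (K <= k_min) break
    worst <- ids[which.min(gev_k)]
    keep_ids <- setdiff(ids, worst)
    r_keep <- r[match(keep_ids, ids), , drop = FALSE]
    members <- which(labels == worst)
    best <- apply(r_keep[, members, drop = FALSE], 2L, which.max)
    labels[members] <- keep_ids[best]
  }
  solutions[order(as.integer(names(solutions)))]
}

#' Global explained variance of a labeling
#'
#' GEV of template map k is the GFP-weighted squared spatial correlation
#' between each frame assigned to k and the template, relative to the total
#' squared GFP of the data:
#' \deqn{GEV_k = \sum_{t: L(t)=k} (GFP_t \, r(u_t, T_k))^2 / \sum_t GFP_t^2.}
#' Frames with label \code{NA} (outside any window) or zero GFP contribute
#' zero to the numerator.
#'
#' @param erp channels x time matrix.
#' @param templates channels x K template matrix.
#' @param labels integer vector of per-frame template indices (NA allowed).
#' @return list with \code{gev_per_map} and \code{gev_total}.
#' @export
gev <- function(erp, templates, labels) {
  erp <- average_reference(erp)
  g2 <- colMeans(erp^2)
  if (all(g2 == 0)) stop("all-zero ERP: GEV undefined")
  K <- ncol(templates)
  r <- .corr_frames_templates(erp, templates)
  per <- vapply(seq_len(K), function(k) {
    sel <- !is.na(labels) & labels == k
    if (!any(sel)) return(0)
    sum(g2[sel] * r[k, sel]^2)
  }, numeric(1)) / sum(g2)
  list(gev_per_map = per, gev_total = sum(per))
}

#' Enforce a minimum microstate duration
#'
#' Dissolves contiguous label runs shorter than \code{min_duration_ms}:
#' each frame of a short run is relabeled to whichever flanking run's
#' template it correlates best with (signed spatial correlation, ties to
#' the lower template index). The pass is iterated until no run violates
#' the minimum or a fixpoint is reached.
#'
#' @param labels integer per-frame labels.
#' @param erp channels x time matrix the labels refer to.
#' @param templates channels x K template matrix.
#' @param min_duration_ms minimum duration (default 20 ms).
#' @param sampling_rate sampling rate in Hz.
#' @return relabeled integer vector.
#' @export
enforce_min_duration <- function(labels, erp, templates,
                                 min_duration_ms = 20, sampling_rate = 512) {
  min_frames <- as.integer(ceiling(min_duration_ms * sampling_rate / 1000))
  if (min_frames <= 1L) return(labels)
  r <- .corr_frames_templates(average_reference(erp), templates)
  # dissolve one offending run per pass (the shortest, earliest on ties);
  # processing singly lets absorbed runs merge with their neighbors instead
  # of oscillating, and iterates to a fixpoint
  for (iter in seq_len(4L * length(labels))) {
    runs <- rle(labels)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bad <- which(runs$lengths < min_frames)
    if (!length(bad)) break
    b <- bad[which.min(runs$lengths[bad])]
    left <- if (b > 1L) runs$values[b - 1L] else NA_integer_
    right <- if (b < length(runs$values)) runs$values[b + 1L] else NA_integer_
    if (is.na(left) && is.na(right)) break
    new_labels <- labels
    for (t in starts[b]:ends[b]) {
      if (is.na(left)) new_labels[t] <- right
      else if (is.na(right)) new_labels[t] <- left
      else {
        rl <- r[left, t]; rr <- r[right, t]
        new_labels[t] <- if (rr > rl) right else left  # tie -> left (earlier run)
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  labels
}

#' Krzanowski-Lai criterion
#'
#' Relative curvature of the within-cluster dispersion curve W(q):
#' \code{DIFF(q) = (q-1)^(2/p) W(q-1) - q^(2/p) W(q)} with p the data
#' dimensionality (number of channels), and
#' \code{KL(q) = |DIFF(q)| / |DIFF(q+1)|}. The KL curve typically peaks at
#' the optimal number of clusters. Undefined (NA) at the boundary q values.
#'
#' @param W numeric vector of dispersions for consecutive cluster numbers.
#' @param k_values the cluster numbers W refers to (consecutive integers).
#' @param n_channels dimensionality exponent p.
#' @return numeric vector of KL values aligned with \code{k_values}.
#' @export
krzanowski_lai <- function(W, k_values, n_channels) {
  if (length(W) < 3L) stop("KL needs at least 3 consecutive cluster numbers")
  if (any(diff(k_values) != 1L)) stop("k_values must be consecutive")
  p <- n_channels
  wq <- k_values^(2 / p) * W
  DIFF <- c(NA, wq[-length(wq)] - wq[-1L])   # DIFF(q) = w(q-1) - w(q)
  KL <- rep(NA_real_, length(W))
  for (i in seq_len(length(W) - 1L)[-1L])
    KL[i] <- abs(DIFF[i]) / abs(DIFF[i + 1L])
  KL
}

#' Cross-validation criterion for the number of template maps
#'
#' Predictive residual variance of the segmentation, penalized for the
#' number of maps: \code{CV(q) = sigma2_q * ((C-1)/(C-1-q))^2}, where
#' \code{sigma2_q} is the mean residual variance of the frames after
#' (polarity-sensitive) projection onto their assigned template and C the
#' number of channels. Lower is better.
#'
#' @param erp channels x time matrix.
#' @param templates channels x K templates.
#' @param labels per-frame assignment.
#' @return scalar CV value.
#' @export
cross_validation_criterion <- function(erp, templates, labels) {
  erp <- average_reference(erp)
  C <- nrow(erp); q <- ncol(templates)
  if (q >= C - 1L) stop("CV criterion requires fewer maps than channels - 1")
  tn <- sweep(templates, 2L, sqrt(colSums(templates^2)), "/")  # unit norm
  proj <- colSums(tn[, labels, drop = FALSE] * erp)
  sigma2 <- sum(colSums(erp^2) - proj^2) / (ncol(erp) * (C - 1L))
  sigma2 * ((C - 1L) / (C - 1L - q))^2
}

#' Combine KL and CV into a choice of K
#'
#' If the KL maximum and the CV minimum agree, that K is returned. On
#' disagreement the KL peak is returned with a warning (the combination
#' rule is a documented package choice); \code{force_k} overrides both.
#'
#' The KL ratio degenerates where the dispersion curve has flattened: as
#' \code{DIFF(q+1)} approaches zero the ratio blows up at cluster numbers
#' whose own dispersion drop is negligible. A candidate K is therefore
#' only eligible if its own drop \code{W(K-1) - W(K)} is at least
#' \code{min_drop_frac} of the total drop over the explored range.
#'
#' @param curve data frame with columns \code{k}, \code{W}, \code{KL},
#'   \code{CV}.
#' @param force_k optional forced K.
#' @param min_drop_frac eligibility floor for the per-K dispersion drop
#'   (default 0.05).
#' @return selected K (integer).
#' @export
select_optimal_k <- function(curve, force_k = NULL, min_drop_frac = 0.05) {
  if (!is.null(force_k)) return(as.integer(force_k))
  KL <- curve$KL
  if (!is.null(curve$W) && nrow(curve) > 2L) {
    drop <- c(NA, -diff(curve$W))
    eligible <- !is.na(drop) & drop >= min_drop_frac * (max(curve$W) - min(curve$W))
    KL[!eligible] <- NA
    if (all(is.na(KL))) KL <- curve$KL
  }
  k_kl <- curve$k[which.max(KL)]
  k_cv <- curve$k[which.min(curve$CV)]
  if (length(k_kl) && length(k_cv) && k_kl != k_cv)
    warning(sprintf("KL (K=%d) and CV (K=%d) disagree; using KL", k_kl, k_cv))
  as.integer(k_kl)
}

#' Spatio-temporal microstate segmentation of an ERP
#'
#' Runs TAAHC over a range of cluster numbers, computes the dispersion (W),
#' Krzanowski-Lai and cross-validation criterion curves, selects the number
#' of template maps, enforces the minimum map duration on the selected
#' labeling, and returns the result as a fitted-model-style object.
#'
#' @param erp channels x time matrix (e.g. a merged grand average over the
#'   analysis window).
#' @param sampling_rate sampling rate in Hz.
#' @param k_min,k_max candidate range for the number of maps (default 2-8;
#'   KL/CV need the interior of the range).
#' @param min_duration_ms minimum retained map duration (default 20 ms).
#' @param force_k optional override of the criterion-based selection.
#' @param time_ms optional per-frame time stamps for reporting.
#' @return object of class \code{microstate_segmentation} with elements
#'   \code{templates}, \code{labels}, \code{gev_per_map}, \code{gev_total},
#'   \code{criteria} (data frame k, W, KL, CV), \code{selected_k},
#'   \code{sampling_rate}, \code{time_ms}.
#' @seealso \code{\link{predict.microstate_segmentation}} for backfitting.
#' @export
microstate_segment <- function(erp, sampling_rate = 512, k_min = 2L,
                               k_max = 8L, min_duration_ms = 20,
                               force_k = NULL, time_ms = NULL) {
  erp <- average_reference(erp)
  sols <- taahc(erp, k_min = k_min, k_max = k_max)
  ks <- as.integer(names(sols))
  curve <- data.frame(k = ks,
                      W = vapply(sols, `[[`, numeric(1), "W"),
                      KL = NA_real_, CV = NA_real_)
  curve$KL <- krzanowski_lai(curve$W, curve$k, nrow(erp))
  curve$CV <- vapply(sols, function(s)
    cross_validation_criterion(erp, s$templates, s$labels), numeric(1))
  selected_k <- select_optimal_k(curve, force_k)
  sol <- sols[[as.character(selected_k)]]
  labels <- enforce_min_duration(sol$labels, erp, sol$templates,
                                 min_duration_ms, sampling_rate)
  # order templates by their median time of occurrence (map A = earliest)
  med <- vapply(seq_len(selected_k), function(k) {
    w <- which(labels == k)
    if (length(w)) stats::median(w) else Inf
  }, numeric(1))
  ord <- order(med)
  templates <- sol$templates[, ord, drop = FALSE]
  labels <- match(labels, ord)
  gv <- gev(erp, templates, labels)
  structure(list(templates = templates, labels = labels,
                 gev_per_map = gv$gev_per_map, gev_total = gv$gev_total,
                 criteria = curve, selected_k = selected_k,
                 sampling_rate = sampling_rate,
                 min_duration_ms = min_duration_ms,
                 time_ms = time_ms),
            class = "microstate_segmentation")
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf("Microstate segmentation: %d template maps (GEV %.2f%%)\n",
              x$selected_k, 100 * x$gev_total))
  cat("Per-map GEV (%):", paste(sprintf("%s=%.2f", LETTERS[seq_len(x$selected_k)],
                                        100 * x$gev_per_map), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.microstate_segmentation <- function(object, ...) {
  runs <- rle(object$labels)
  seg <- data.frame(map = LETTERS[runs$values],
                    n_frames = runs$lengths,
                    duration_ms = runs$lengths * 1000 / object$sampling_rate)
  out <- list(selected_k = object$selected_k, gev_total = object$gev_total,
              gev_per_map = object$gev_per_map, criteria = object$criteria,
              segments = seg)
  class(out) <- "summary.microstate_segmentation"
  out
}

#' @export
print.summary.microstate_segmentation <- function(x, ...) {
  cat(sprintf("Selected K = %d, total GEV = %.4f\n", x$selected_k, x$gev_total))
  cat("\nCriterion curves:\n"); print(x$criteria, row.names = FALSE)
  cat("\nSegments (after minimum-duration enforcement):\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Plot a microstate segmentation
#'
#' Shows the GFP trace of the segmented ERP colored by the assigned
#' template map, plus the KL/CV criterion curves.
#'
#' @param x a \code{microstate_segmentation}; \code{erp}: the segmented
#'   channels x time matrix (needed for the GFP trace).
#' @param erp the data matrix the segmentation was fitted to.
#' @param ... ignored.
#' @export
plot.microstate_segmentation <- function(x, erp = NULL, ...) {
  op <- graphics::par(mfrow = c(if (is.null(erp)) 1 else 2, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(erp)) {
    g <- gfp(erp)
    tt <- if (!is.null(x$time_ms)) x$time_ms else seq_along(g)
    graphics::plot(tt, g, type = "h", col = x$labels + 1L,
                   xlab = if (!is.null(x$time_ms)) "time (ms)" else "frame",
                   ylab = "GFP (µV)", main = "GFP by assigned map")
    graphics::legend("topright", legend = LETTERS[seq_len(x$selected_k)],
                     col = seq_len(x$selected_k) + 1L, lty = 1, bty = "n")
  }
  graphics::plot(x$criteria$k, x$criteria$KL, type = "b", xlab = "K",
                 ylab = "KL", main = "Model-order criteria")
  graphics::abline(v = x$selected_k, lty = 2)
  invisible(x)
}
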