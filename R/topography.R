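#' Reference-free topographic primitives
#'
#' Scalp topographies are treated as average-referenced potential vectors
#' over the electrode montage; all topographic quantities used in the
#' package (global field power, spatial correlation, dissimilarity, global
#' explained variance) are computed on average-referenced data and are
#' therefore independent of the recording reference.
#'
#' @name topography
NULL

#' Re-reference a channel-by-time matrix to the average reference
#'
#' Subtracts, at each time frame, the mean potential over channels, so that
#' every column sums to zero. Between-channel differences are unchanged;
#' the operation is idempotent.
#'
#' @param x numeric matrix or vector, channels x time (a vector is treated
#'   as a single time frame).
#' @return matrix (or vector) of the same shape with zero column means.
#' @export
#' @examples
#' average_reference(c(1, 2, 6))   # -2 -1 3
average_reference <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) < 2L) stop("average reference requires at least 2 channels")
    return(x - mean(x))
  }
  if (nrow(x) < 2L) stop("average reference requires at least 2 channels")
  sweep(x, 2L, colMeans(x))
}

#' Global field power
#'
#' The spatial standard deviation of an average-referenced topography:
#' \code{sqrt(mean(u^2))} over the N channels (population normalization,
#' 1/N). A reference-free measure of momentary response strength.
#'
#' @param u numeric vector (one topography) or channels x time matrix
#'   (GFP returned per column). Inputs that are not average-referenced are
#'   re-referenced first.
#' @return non-negative scalar, or vector of length \code{ncol(u)}.
#' @export
gfp <- function(u) {
  if (is.null(dim(u))) {
    u <- u - mean(u)
    return(sqrt(mean(u^2)))
  }
  u <- average_reference(u)
  sqrt(colMeans(u^2))
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation of the two average-referenced potential vectors.
#' Polarity is respected (signed correlation): evoked-potential maps of
#' opposite polarity correlate at -1.
#'
#' @param a,b numeric vectors of equal length (same montage).
#' @return scalar in [-1, 1].
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("topographies live on different montages")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("spatial correlation undefined for a zero-GFP topography")
  sum(a * b) / (na * nb)
}

#' Topographic dissimilarity
#'
#' Global map dissimilarity between two topographies,
#' \code{sqrt(2 * (1 - r))} with r the spatial correlation; equals the GFP
#' of the difference of the two GFP-normalized maps. Ranges over [0, 2].
#'
#' @inheritParams spatial_correlation
#' @return scalar in [0, 2].
#' @export
dissimilarity <- function(a, b) {
  r <- spatial_correlation(a, b)
  sqrt(max(0, 2 * (1 - r)))
}

# column-wise correlations of average-referenced, possibly zero, frames
# against a matrix of unit-norm templates; returns K x T matrix.
# Zero-GFP frames get correlation 0 against every template.
.corr_frames_templates <- function(frames, templates) {
  frames <- sweep(frames, 2L, colMeans(frames))
  nrm <- sqrt(colSums(frames^2))
  nrm[nrm == 0] <- Inf
  fr <- sweep(frames, 2L, nrm, "/")
  tn <- sweep(templates, 2L, sqrt(colSums(templates^2)), "/")
  crossprod(tn, fr)
}
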