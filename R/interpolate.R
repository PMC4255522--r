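#' Spherical-spline interpolation of bad channels
#'
#' Replaces the rows of an epoch belonging to bad channels with spherical
#' spline estimates computed from the good channels (Perrin-style splines
#' of order \code{m = 4}, with a small ridge regularization on the spline
#' system). Good channels are returned unchanged.
#'
#' @param epoch numeric channels x time matrix in layout row order.
#' @param bad_channels character vector of channel ids (or integer indices)
#'   to interpolate.
#' @param layout the \code{\link{eeg_layout}} giving electrode positions.
#' @param m spline order (default 4).
#' @param n_legendre number of Legendre terms in the spline kernel
#'   (default 20).
#' @param lambda ridge regularization of the spline system (default 1e-5).
#' @return the epoch with bad rows replaced.
#' @export
interpolate_bad_channels <- function(epoch, bad_channels, layout,
                                     m = 4, n_legendre = 20L, lambda = 1e-5) {
  if (length(bad_channels) == 0L) return(epoch)
  if (is.character(bad_channels)) {
    bad <- match(bad_channels, layout$channel_id)
    if (anyNA(bad)) stop("unknown channel id: ",
                         paste(bad_channels[is.na(bad)], collapse = ", "))
  } else bad <- as.integer(bad_channels)
  n <- nrow(layout)
  if (nrow(epoch) != n) stop("epoch rows must match layout channels")
  good <- setdiff(seq_len(n), bad)
  if (length(good) < 4L) stop("at least 4 good channels are required")
  pos <- as.matrix(layout[, c("x", "y", "z")])
  g_gg <- .spline_g(tcrossprod(pos[good, , drop = FALSE]), m, n_legendre)
  g_bg <- .spline_g(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                    m, n_legendre)
  k <- length(good)
  # augmented system enforcing the zero-sum constraint on spline weights
  A <- rbind(cbind(g_gg + diag(lambda, k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(epoch[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(k), , drop = FALSE]
  c0 <- sol[k + 1L, ]
  est <- g_bg %*% w + matrix(c0, length(bad), ncol(epoch), byrow = TRUE)
  epoch[bad, ] <- est
  epoch
}

# spline kernel g(cos angle) = sum_n (2n+1) / (n (n+1))^m P_n(x) / (4 pi)
.spline_g <- function(x, m, n_legendre) {
  x <- pmin(pmax(x, -1), 1)
  p_prev <- array(1, dim = dim(as.matrix(x)))  # P_0
  p_cur <- as.matrix(x)                        # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_legendre) {
    p_next <- ((2 * n - 1) * as.matrix(x) * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}
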