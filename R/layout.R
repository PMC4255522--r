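#' Electrode layouts
#'
#' A layout is a data frame with columns \code{channel_id}, \code{x},
#' \code{y}, \code{z}: electrode positions on (or near) the unit sphere.
#' Positions are normalized to unit radius on construction; they are used
#' by the spherical-spline interpolation and by the synthetic template
#' generator, which builds smooth maps from low-order functions of position.
#'
#' @param channel_id character vector of unique channel names.
#' @param pos numeric matrix, one row per channel, columns x, y, z.
#' @return object of class \code{eeg_layout} (a data frame).
#' @export
eeg_layout <- function(channel_id, pos) {
  channel_id <- as.character(channel_id)
  pos <- as.matrix(pos)
  if (length(channel_id) < 2L) stop("a layout needs at least 2 channels")
  if (anyDuplicated(channel_id)) stop("channel_id values must be unique")
  if (nrow(pos) != length(channel_id) || ncol(pos) != 3L)
    stop("pos must be a length(channel_id) x 3 matrix")
  r <- sqrt(rowSums(pos^2))
  if (any(r == 0)) stop("electrode positions must have nonzero norm")
  pos <- pos / r
  out <- data.frame(channel_id = channel_id,
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_layout", "data.frame")
  out
}

#' Evenly distributed spherical montage
#'
#' Generates \code{n} electrode positions spread quasi-uniformly over the
#' upper portion of the unit sphere by the Fibonacci-lattice construction,
#' as a stand-in for a high-density geodesic montage (default 128 channels).
#'
#' @param n number of channels (default 128).
#' @param coverage fraction of the sphere covered from the vertex down
#'   (default 0.75: electrodes stop short of the neck/face).
#' @return an \code{eeg_layout}.
#' @export
make_spherical_layout <- function(n = 128L, coverage = 0.75) {
  stopifnot(n >= 2L, coverage > 0, coverage <= 1)
  i <- seq_len(n) - 0.5
  # z descends from the vertex over the covered cap
  z <- 1 - 2 * coverage * i / n
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(rho * cos(phi), rho * sin(phi), z)
  eeg_layout(sprintf("E%03d", seq_len(n)), pos)
}

#' Read / write a layout TSV
#'
#' Plain tab-separated file with columns \code{channel_id}, \code{x},
#' \code{y}, \code{z}.
#'
#' @param path file path.
#' @rdname layout_io
#' @export
read_layout <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "x", "y", "z")
  if (!all(need %in% names(d))) stop("layout file must have columns ", paste(need, collapse = ", "))
  eeg_layout(d$channel_id, as.matrix(d[, c("x", "y", "z")]))
}

#' @param layout an \code{eeg_layout}.
#' @rdname layout_io
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
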