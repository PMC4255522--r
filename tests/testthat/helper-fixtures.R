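# shared fixtures: small montages, template sets and epoch containers
# built in code at test time

tiny_layout <- function(n = 16L) make_spherical_layout(n)

# a deterministic pair of orthogonal smooth maps on a montage
two_maps <- function(layout) {
  pos <- as.matrix(layout[, c("x", "y", "z")])
  a <- average_reference(pos[, 3])
  b <- average_reference(pos[, 1])
  b <- b - a * sum(a * b) / sum(a * a)
  cbind(a / sqrt(mean(a^2)), b / sqrt(mean(b^2)))
}

# epoch_set with given per-trial rt and flat signals (for bookkeeping tests)
flat_epoch_set <- function(rt_ms, accuracy = rep(1L, length(rt_ms)),
                           n_channels = 8L, fs = 256) {
  lay <- tiny_layout(n_channels)
  n_stim <- round(450 * fs / 1000); n_resp <- round(650 * fs / 1000)
  n <- length(rt_ms)
  trials <- data.frame(trial_id = sprintf("t%03d", seq_len(n)),
                       participant_id = "p1", item_id = sprintf("i%03d", seq_len(n)),
                       rt_ms = rt_ms, accuracy = accuracy,
                       stringsAsFactors = FALSE)
  epoch_set(trials,
            stim = replicate(n, matrix(0, n_channels, n_stim), simplify = FALSE),
            resp = replicate(n, matrix(0, n_channels, n_resp), simplify = FALSE),
            lay, fs)
}

# reference implementation of edit distance: plain recursion (exponential),
# independent of utils::adist
lev_recursive <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
        rec(i - 1L, j - 1L) + (A[i] != B[j]))
  }
  rec(length(A), length(B))
}

random_string <- function(max_len = 5L, alphabet = letters[1:4]) {
  paste(sample(alphabet, sample(0:max_len, 1), replace = TRUE), collapse = "")
}

quiet_segment <- function(...) suppressWarnings(microstate_segment(...))
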