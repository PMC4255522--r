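test_that("band-pass keeps the pass band and rejects DC and high frequencies", {
  fs <- 512
  t <- seq(0, 2, by = 1 / fs)
  s10 <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(s10, 0.2, 30, fs)
  mid <- seq(round(0.25 * fs), round(1.75 * fs))    # past edge transients
  expect_lt(abs(sqrt(mean(y[mid]^2)) / sqrt(mean(s10[mid]^2)) - 1), 0.05)

  dc <- rep(50, length(t))
  expect_lt(max(abs(bandpass_filter(dc, 0.2, 30, fs)[mid])), 0.05 * 50)

  s100 <- sin(2 * pi * 100 * t)
  atten <- sqrt(mean(bandpass_filter(s100, 0.2, 30, fs)[mid]^2)) /
    sqrt(mean(s100[mid]^2))
  expect_lt(20 * log10(atten), -20)

  expect_error(bandpass_filter(s10, 40, 30, fs), "band edges")
  expect_error(bandpass_filter(s10, 0.2, 300, fs), "band edges")
})

test_that("matrix filtering matches the reference single-channel recursion", {
  # our multi-channel path against signal's own vector filter
  bt <- signal::butter(4, c(0.2, 30) / 128, type = "pass")
  x <- matrix(rnorm(600), 200, 3)
  ours <- erpmicro:::.iir_mat(x, bt$b, bt$a)
  ref <- vapply(1:3, function(j) as.numeric(signal::filter(bt, x[, j])),
                numeric(200))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("low-pass-only filtering is available for short epochs", {
  fs <- 256
  t <- seq(0, 1, by = 1 / fs)
  dc <- rep(10, length(t))
  y <- bandpass_filter(dc, NULL, 30, fs)
  expect_equal(y, dc, tolerance = 0.01)             # DC preserved without high-pass
  s100 <- sin(2 * pi * 100 * t)
  expect_lt(sqrt(mean(bandpass_filter(s100, NULL, 30, fs)^2)),
            0.01 * sqrt(mean(s100^2)))
})

test_that("amplitude rejection uses a strict threshold on both epochs", {
  set <- flat_epoch_set(rt_ms = c(700, 700, 700, 700))
  set$stim[[1]][3, 10] <- 99.9
  set$stim[[2]][3, 10] <- 101
  set$resp[[3]][1, 5] <- -101
  set$stim[[4]][2, 7] <- 100.0
  out <- reject_amplitude(set, 100)
  expect_equal(out$kept$trials$trial_id, c("t001", "t004"))
  rep <- as.data.frame(out$report)
  expect_equal(rep$n[rep$reason == "amplitude"], 2)
})

test_that("error and RT exclusion reproduces printed exclusion percentages", {
  n <- 3100                                          # 31 participants x 100 items
  rt <- rep(800, n); acc <- rep(1L, n)
  acc[seq_len(50)] <- 0L                             # 50 error responses
  rt[51:112] <- c(rep(450, 31), rep(1600, 31))       # 62 RT outliers
  trials <- data.frame(trial_id = seq_len(n), participant_id = 1,
                       item_id = 1, rt_ms = rt, accuracy = acc)
  out <- exclude_by_rt_and_accuracy(trials)
  rep <- as.data.frame(out$report)
  expect_equal(round(rep$pct[rep$reason == "error_response"], 1), 1.6)
  expect_equal(round(rep$pct[rep$reason == "rt_out_of_window"], 1), 2.0)
  expect_equal(nrow(out$kept), n - 112)
})

test_that("RT bounds are strict: values at the bound are kept", {
  trials <- data.frame(trial_id = 1:4, participant_id = 1, item_id = 1,
                       rt_ms = c(500, 1500, 499.9, 1500.1), accuracy = 1L)
  out <- exclude_by_rt_and_accuracy(trials)
  expect_equal(out$kept$trial_id, 1:2)
})

test_that("rejection is order-insensitive for disjoint criteria", {
  set.seed(8)
  set <- flat_epoch_set(rt_ms = runif(40, 300, 1700),
                        accuracy = rbinom(40, 1, 0.9))
  for (i in sample(40, 10)) set$stim[[i]][1, 1] <- 150
  a_then_b <- exclude_by_rt_and_accuracy(reject_amplitude(set)$kept)$kept
  b_then_a <- reject_amplitude(exclude_by_rt_and_accuracy(set)$kept)$kept
  keep_a <- vapply(seq_len(40), function(i) max(abs(set$stim[[i]])) <= 100, logical(1))
  keep_b <- set$trials$accuracy == 1 & set$trials$rt_ms >= 500 & set$trials$rt_ms <= 1500
  expect_equal(sort(a_then_b$trials$trial_id), sort(b_then_a$trials$trial_id))
  expect_equal(sort(a_then_b$trials$trial_id),
               sort(set$trials$trial_id[keep_a & keep_b]))
})

test_that("spherical-spline interpolation reconstructs smooth topographies", {
  lay <- make_spherical_layout(64)
  epoch <- matrix(rnorm(64 * 3), 64, 3)
  expect_identical(interpolate_bad_channels(epoch, character(0), lay), epoch)

  tpl <- two_maps(lay)                               # smooth low-order maps
  smooth <- tpl[, 1, drop = FALSE] %*% t(c(2, 1.5, 1))
  est <- interpolate_bad_channels(smooth, "E010", lay)
  rng <- diff(range(smooth))
  expect_lt(max(abs(est[10, ] - smooth[10, ])), 0.05 * rng)
  expect_equal(est[-10, ], smooth[-10, ])            # good channels untouched

  expect_error(interpolate_bad_channels(smooth, lay$channel_id, lay), "4 good")
  expect_error(interpolate_bad_channels(smooth, "nope", lay), "unknown channel")
})

test_that("merging spans onset to rt - 100 with stimulus data winning overlap", {
  fs <- 512
  n_stim <- round(450 * fs / 1000); n_resp <- round(650 * fs / 1000)
  stim <- matrix(rnorm(4 * n_stim), 4); resp <- matrix(rnorm(4 * n_resp), 4)

  m <- merge_epochs(stim, resp, 900, fs)
  expect_equal(ncol(m$data), round(800 * fs / 1000))
  expect_identical(m$data[, seq_len(n_stim)], stim)  # bit-identical stimulus part
  expect_false(m$gap_flag)
  n_use <- ncol(m$data) - n_stim
  tail_end <- round(450 * fs / 1000)
  expect_identical(m$data[, (n_stim + 1):ncol(m$data)],
                   resp[, (tail_end - n_use + 1):tail_end])

  m2 <- merge_epochs(stim, resp, 550, fs)            # degenerate: no response part
  expect_equal(ncol(m2$data), round(450 * fs / 1000))
  expect_true(is.na(m2$junction_sample))

  m3 <- merge_epochs(stim, resp, 1200, fs)           # coverage gap
  expect_true(m3$gap_flag)
  expect_false(anyNA(m3$data))                       # cross-faded, not missing

  expect_error(merge_epochs(stim, resp, 90, fs), "pre-articulation")
})

test_that("strict merging excludes coverage-gap trials and logs them", {
  set <- flat_epoch_set(rt_ms = c(700, 1200, 800))
  out <- merge_epoch_set(set, strict_gaps = TRUE)
  expect_equal(out$merged$trials$trial_id, c("t001", "t003"))
  expect_equal(as.data.frame(out$report)$n, 1)
  n_expect <- round((c(700, 800) - 100) * 256 / 1000)
  expect_equal(vapply(out$merged$data, ncol, integer(1)), n_expect)
})

test_that("averaging epochs is pointwise with group mean RT", {
  set <- flat_epoch_set(rt_ms = c(600, 800))
  set$stim[[1]][] <- 1; set$stim[[2]][] <- -1
  set$resp[[1]][] <- 2; set$resp[[2]][] <- -2
  g <- average_epochs(set, "grand")
  expect_equal(nrow(g$trials), 1)
  expect_true(all(g$stim[[1]] == 0) && all(g$resp[[1]] == 0))
  expect_equal(g$trials$rt_ms, 700)

  solo_set <- epoch_set(set$trials[1, ], set$stim[1], set$resp[1],
                        set$layout, set$sampling_rate)
  solo <- average_epochs(solo_set, "grand")          # single-epoch identity
  expect_equal(solo$stim[[1]], set$stim[[1]])

  # noise reduction ~ sigma/sqrt(n) on 10 noisy copies
  set.seed(9)
  lay <- tiny_layout(8); fs <- 256
  n_stim <- round(450 * fs / 1000); n_resp <- round(650 * fs / 1000)
  tmpl <- matrix(rnorm(8 * n_stim), 8)
  stim <- lapply(1:10, function(i) tmpl + rnorm(8 * n_stim, sd = 1))
  resp <- lapply(1:10, function(i) matrix(rnorm(8 * n_resp), 8))
  trials <- data.frame(trial_id = 1:10, participant_id = "p", item_id = 1:10,
                       rt_ms = 700, accuracy = 1L)
  avg <- average_epochs(epoch_set(trials, stim, resp, lay, fs), "grand")
  resid_rms <- sqrt(mean((avg$stim[[1]] - tmpl)^2))
  expect_lt(abs(resid_rms - 1 / sqrt(10)), 0.05)

  # averaging commutes with average referencing
  ar_then_avg <- Reduce(`+`, lapply(stim, average_reference)) / 10
  expect_equal(average_reference(avg$stim[[1]]), ar_then_avg)
})
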