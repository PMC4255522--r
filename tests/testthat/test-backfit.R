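test_that("windows resolve against reaction time with half-open borders", {
  fs <- 512
  w <- default_fitting_windows()
  res <- resolve_windows(w, 805, round(705 * fs / 1000), fs)
  t_ms <- (seq_len(round(705 * fs / 1000)) - 1) * 1000 / fs
  expect_equal(res[[3]]$end_ms, 705)                 # rt - 100
  expect_true(all(t_ms[res[[3]]$frames] >= 460 & t_ms[res[[3]]$frames] < 705))
  # frame at a shared border belongs to the later window
  expect_length(intersect(res[[1]]$frames, res[[2]]$frames), 0)
  expect_equal(max(res[[1]]$frames) + 1, min(res[[2]]$frames))

  res2 <- resolve_windows(w, 560, round(460 * fs / 1000), fs)
  expect_true(res2[[3]]$excluded)                    # zero-length third window

  res3 <- resolve_windows(w, 1000, round(900 * fs / 1000), fs)
  expect_equal(res3[[1]]$frames, res[[1]]$frames)    # stimulus windows RT-invariant
  expect_equal(res3[[2]]$frames, res[[2]]$frames)

  expect_error(resolve_windows(w, 90, 100, fs), "too short")
  expect_error(fitting_window(0, 100, 1L), "two template maps")
})

test_that("backfitting labels frames by best signed correlation", {
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  fs <- 512
  n <- round(705 * fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  data <- matrix(0, 16, n)
  data[, t_ms < 400] <- tpl[, 1] * 2
  data[, t_ms >= 400] <- tpl[, 2] * 2
  w <- list(fitting_window(50, NA, c(1L, 2L), "all"))
  res <- resolve_windows(w, 805, n, fs)
  labs <- backfit(data, tpl, res)
  expect_true(all(is.na(labs[t_ms < 50])))           # outside windows unlabeled
  inside <- !is.na(labs)
  expect_equal(labs[inside & t_ms < 400], rep(1L, sum(inside & t_ms < 400)))
  expect_equal(labs[inside & t_ms >= 400], rep(2L, sum(inside & t_ms >= 400)))
  expect_identical(backfit(3 * data, tpl, res), labs)  # scale invariance

  # zero-GFP frames correlate zero with every template: documented
  # tie-break to the lowest allowed index
  zero <- matrix(0, 16, n)
  expect_true(all(backfit(zero, tpl, res)[inside] == 1L))
})

test_that("fit summaries convert frames to ms and conserve window length", {
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  fs <- 512
  n <- round(705 * fs / 1000)
  set.seed(17)
  data <- tpl[, sample(1:2, n, replace = TRUE)] + rnorm(16 * n, sd = 0.1)
  w <- default_fitting_windows()[1:2]
  w[[1]]$templates <- c(1L, 2L); w[[2]]$templates <- c(1L, 2L)
  res <- resolve_windows(w, 805, n, fs)
  labs <- backfit(data, tpl, res)
  s <- summarize_fit(labs, data, tpl, res, fs)
  for (wn in unique(s$window)) {
    ss <- s[s$window == wn, ]
    wlen <- length(res[[which(vapply(res, `[[`, character(1), "name") == wn)]]$frames)
    expect_equal(sum(ss$n_frames), wlen)             # duration conservation
  }
  expect_equal(s$duration_ms, s$n_frames * 1000 / fs)
  expect_equal(s$duration_ms[s$n_frames == 10],
               rep(19.53125, sum(s$n_frames == 10)))

  # absent map: present FALSE, zero duration
  data1 <- matrix(tpl[, 1], 16, n) + 0.01
  labs1 <- backfit(data1, tpl, res)
  s1 <- summarize_fit(labs1, data1, tpl, res, fs)
  expect_false(any(s1$present[s1$template == 2]))
  expect_equal(s1$duration_ms[s1$template == 2], rep(0, 2))
})

test_that("set-level backfitting produces presence reports with ratios", {
  set.seed(18)
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  fs <- 256
  n_tr <- 20
  data <- lapply(seq_len(n_tr), function(i) {
    n <- round(600 * fs / 1000)
    m <- matrix(tpl[, 1], 16, n) * 2
    if (i <= 19) m[, (n - 20):n] <- tpl[, 2] * 2     # map 2 present in 19/20
    m + rnorm(16 * n, sd = 0.05)
  })
  trials <- data.frame(trial_id = sprintf("t%02d", 1:n_tr), participant_id = "p1",
                       item_id = "i1", rt_ms = 700, accuracy = 1L,
                       junction_sample = NA, gap_flag = FALSE)
  merged <- structure(list(trials = trials, data = data, layout = lay,
                           sampling_rate = fs, cut_ms = 100),
                      class = "merged_set")
  ft <- backfit_set(merged, tpl, list(fitting_window(50, NA, c(1L, 2L), "all")))
  rep <- presence_and_gev_report(ft)
  expect_equal(rep$presence_pct[rep$template == 1], 100)
  expect_equal(rep$presence_pct[rep$template == 2], 95)
  expect_equal(rep$n_units, c(20, 20))
})

test_that("noiseless generator round-trip recovers durations within a frame", {
  cfg <- synthetic_config(n_participants = 2L, n_items = 10L, n_channels = 16L,
                          sampling_rate = 256, noise_sd_uv = 0, seed = 31L)
  sim <- simulate_dataset(cfg)
  m <- merge_epoch_set(sim$epochs)$merged
  ft <- backfit_set(m, sim$templates,
                    list(fitting_window(50, NA, 1:5, "all")))
  dur <- map_durations(ft)
  gt <- sim$ground_truth
  tol <- 2 * 1000 / 256 + 1e-9                       # one frame per transition
  for (id in m$trials$trial_id) {
    g <- as.numeric(gt[gt$trial_id == id, paste0("duration_ms_", 1:5)])
    d <- dur[dur$trial_id == id, ]
    d <- d$duration_ms[order(d$template)]
    expect_true(all(abs(d - g) <= tol))
  }
})
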