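test_that("TAAHC recovers a noiseless two-map alternation exactly", {
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  labs_true <- rep(c(1L, 2L), each = 30)
  erp <- tpl[, labs_true] * 1.7
  sol <- taahc(erp, 2, 2)[["2"]]
  expect_equal(sol$gev_total, 1, tolerance = 1e-9)
  r <- abs(crossprod(sol$templates, tpl) / nrow(lay))
  expect_true(all(apply(r, 2, max) > 1 - 1e-9))      # templates match generators
  expect_equal(length(unique(sol$labels[1:30])), 1)  # exact partition
  expect_equal(length(unique(sol$labels[31:60])), 1)
})

test_that("a constant topography yields one cluster with full GEV", {
  lay <- tiny_layout(8)
  u <- average_reference(rnorm(8))
  erp <- matrix(u, 8, 25)
  sol <- taahc(erp, 1, 3)[["1"]]
  expect_equal(sol$gev_total, 1, tolerance = 1e-9)
})

test_that("TAAHC is deterministic and errors on too few frames", {
  set.seed(11)
  erp <- matrix(rnorm(16 * 40), 16)
  s1 <- taahc(erp, 2, 6); s2 <- taahc(erp, 2, 6)
  expect_identical(s1, s2)
  expect_error(taahc(erp, 2, 50), "fewer time frames")
})

test_that("the raw greedy hierarchy removes one cluster per step", {
  set.seed(12)
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  erp <- cbind(tpl[, rep(1, 20)], tpl[, rep(2, 20)],
               matrix(rnorm(16 * 20, sd = 0.5), 16))
  sols <- taahc(erp, 2, 6, refine = 0)
  for (K in 3:6) {
    hi <- sols[[as.character(K)]]$labels
    lo <- sols[[as.character(K - 1)]]$labels
    # exactly one cluster (the atomized one) is redistributed; all other
    # clusters survive intact into the K-1 solution
    split_up <- tapply(lo, hi, function(v) length(unique(v)) > 1)
    expect_lte(sum(split_up), 1)
    expect_equal(length(unique(lo)), K - 1)
  }
})

test_that("GEV follows its defining formula and bounds", {
  set.seed(13)
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  labs <- rep(c(1L, 2L), 15)
  erp <- sweep(tpl[, labs], 2, runif(30, 0.5, 2), "*")
  g <- gev(erp, tpl, labs)
  expect_equal(g$gev_total, 1, tolerance = 1e-9)     # generative labeling
  expect_equal(sum(g$gev_per_map), g$gev_total)

  set.seed(14)
  rand <- sample(labs)
  expect_lte(gev(erp, tpl, rand)$gev_total, g$gev_total + 1e-12)

  erp2 <- erp; erp2[, 3] <- 0                        # zero-GFP frame contributes 0
  g_zero <- gev(erp2, tpl, labs)
  labs_flip <- labs; labs_flip[3] <- 3 - labs_flip[3]
  expect_equal(gev(erp2, tpl, labs_flip)$gev_total, g_zero$gev_total)

  expect_equal(gev(5 * erp, tpl, labs)$gev_total, g$gev_total)  # scale invariance
  expect_error(gev(matrix(0, 16, 5), tpl, rep(1L, 5)), "all-zero")
})

test_that("minimum-duration enforcement dissolves short runs", {
  lay <- tiny_layout(16)
  tpl <- two_maps(lay)
  fs <- 512
  labs <- c(rep(1L, 40), rep(2L, 5), rep(1L, 40))    # 5 frames < 20 ms at 512 Hz
  erp <- tpl[, labs]
  out <- enforce_min_duration(labs, erp, tpl, 20, fs)
  expect_true(all(out == 1L))                        # short run absorbed

  long <- c(rep(1L, 40), rep(2L, 40))
  expect_identical(enforce_min_duration(long, tpl[, long], tpl, 20, fs), long)

  alt <- rep(c(1L, 2L), 20)                          # collapses to a fixpoint
  out2 <- enforce_min_duration(alt, tpl[, alt], tpl, 20, fs)
  runs <- rle(out2)$lengths
  expect_true(all(runs >= ceiling(20 * fs / 1000)))  # never creates short runs
})

test_that("Krzanowski-Lai peaks at a constructed elbow", {
  p <- 32
  q <- 2:8
  W <- ifelse(q <= 5, 100 - 18 * (q - 2), 100 - 18 * 3 - 0.5 * (q - 5))
  KL <- krzanowski_lai(W, q, p)
  expect_equal(q[which.max(KL)], 5)
  expect_true(all(is.na(KL[c(1, length(KL))])))

  # when q^(2/p) W(q) falls linearly in q, successive DIFFs are equal and
  # KL is exactly 1 everywhere (closed-form check of the ratio)
  W_lin <- (100 - 3 * q) * q^(-2 / p)
  KL_lin <- krzanowski_lai(W_lin, q, p)
  expect_equal(KL_lin[!is.na(KL_lin)], rep(1, sum(!is.na(KL_lin))),
               tolerance = 1e-9)
  expect_error(krzanowski_lai(c(1, 2), 2:3, p), "at least 3")
})

test_that("the cross-validation criterion is minimal at the true K", {
  set.seed(15)
  lay <- make_spherical_layout(24)
  tpl <- make_templates(3, lay)
  labs <- rep(1:3, each = 25)
  erp <- tpl[, labs] * 2
  sols <- taahc(erp, 2, 6)
  cv <- vapply(sols, function(s)
    cross_validation_criterion(erp, s$templates, s$labels), numeric(1))
  expect_equal(as.integer(names(which.min(cv))), 3)
  expect_true(all(cv >= 0))
  erp_noisy <- erp + matrix(rnorm(length(erp), sd = 0.8), nrow(erp))
  sols_n <- taahc(erp_noisy, 2, 6)
  cv_n <- vapply(names(sols), function(K)
    cross_validation_criterion(erp_noisy, sols_n[[K]]$templates,
                               sols_n[[K]]$labels), numeric(1))
  expect_true(all(cv_n > cv))                        # white noise raises CV
  expect_error(cross_validation_criterion(erp, tpl[, rep(1, 24)], rep(1L, 75)),
               "fewer maps")
})

test_that("K selection combines KL and CV with a documented rule", {
  curve <- data.frame(k = 2:6, W = c(50, 30, 12, 10, 9),
                      KL = c(NA, 2, 9, 1, NA), CV = c(5, 4, 2, 3, 4))
  expect_equal(select_optimal_k(curve), 4L)          # agreement
  curve2 <- curve; curve2$CV <- c(5, 4, 3, 2, 4)
  expect_warning(k <- select_optimal_k(curve2), "disagree")
  expect_equal(k, 4L)                                # KL wins
  expect_equal(select_optimal_k(curve2, force_k = 6), 6L)
  # KL peaks where the dispersion drop is negligible are ineligible
  curve3 <- data.frame(k = 2:6, W = c(50, 20, 19.8, 19.7, 19.69),
                       KL = c(NA, 3, 1, 40, NA), CV = c(5, 1, 2, 3, 4))
  expect_equal(select_optimal_k(curve3), 3L)
})

test_that("segmentation object carries time-ordered maps and methods work", {
  set.seed(16)
  lay <- make_spherical_layout(24)
  tpl <- make_templates(3, lay)
  labs <- rep(1:3, each = 30)
  erp <- tpl[, labs] * 2 + matrix(rnorm(24 * 90, sd = 0.1), 24)
  seg <- quiet_segment(erp, 256, k_min = 2, k_max = 5)
  expect_s3_class(seg, "microstate_segmentation")
  expect_equal(seg$selected_k, 3)
  # maps relabeled by time of occurrence: labels are non-decreasing in median
  med <- tapply(seq_along(seg$labels), seg$labels, median)
  expect_true(all(diff(med[order(as.integer(names(med)))]) > 0))
  expect_output(print(seg), "template maps")
  s <- summary(seg)
  expect_output(print(s), "Criterion curves")
})
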