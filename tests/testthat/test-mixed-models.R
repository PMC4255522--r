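# balanced crossed design with predictors at item level
sim_rows <- function(n_part = 6, n_item = 30, beta = c(x1 = 5, x2 = -2),
                     sd_part = 0, sd_item = 0, sd_res = 1, seed = 41) {
  set.seed(seed)
  items <- data.frame(item_id = sprintf("i%02d", 1:n_item),
                      x1 = rnorm(n_item), x2 = rnorm(n_item))
  d <- merge(expand.grid(participant_id = sprintf("p%02d", 1:n_part),
                         item_id = items$item_id), items, by = "item_id")
  u <- rnorm(n_part, 0, sd_part); names(u) <- sprintf("p%02d", 1:n_part)
  v <- rnorm(n_item, 0, sd_item); names(v) <- items$item_id
  d$y <- 100 + beta["x1"] * d$x1 + beta["x2"] * d$x2 +
    u[d$participant_id] + v[d$item_id] + rnorm(nrow(d), 0, sd_res)
  d
}

test_that("with zero random variance the fixed effects equal OLS", {
  d <- sim_rows(sd_part = 0, sd_item = 0)
  m <- fit_mixed(d, model_spec("y", c("x1", "x2")))
  ols <- coef(lm(y ~ x1 + x2, data = d))
  expect_equal(unname(coef(m)), unname(ols), tolerance = 1e-6)
  expect_true(m$singular)                            # variances estimated at zero
  expect_true(m$converged)
})

test_that("a balanced intercept-only fit returns the grand mean", {
  d <- sim_rows(beta = c(x1 = 0, x2 = 0), sd_part = 3, sd_item = 2)
  m <- fit_mixed(d, model_spec("y", character(0)))
  expect_equal(m$coefficients$beta[1], mean(d$y), tolerance = 1e-6)
})

test_that("coefficients are reported in specification order", {
  d <- sim_rows()
  m <- fit_mixed(d, model_spec("y", c("x2", "x1")))
  expect_equal(m$coefficients$term, c("(Intercept)", "x2", "x1"))
})

test_that("parameter recovery in a crossed design covers the truth", {
  d <- sim_rows(n_part = 10, n_item = 50, sd_part = 4, sd_item = 3,
                sd_res = 5, seed = 42)
  m <- fit_mixed(d, model_spec("y", c("x1", "x2")))
  co <- m$coefficients
  for (tm in c("x1", "x2")) {
    i <- co$term == tm
    truth <- c(x1 = 5, x2 = -2)[tm]
    expect_lt(abs(co$beta[i] - truth), qt(0.975, co$df[i]) * co$se[i])
  }
})

test_that("slope reduction drops slopes until the fit is stable", {
  d <- sim_rows(n_part = 8, n_item = 40, sd_part = 3, sd_item = 2, sd_res = 2,
                seed = 43)
  m <- slope_reduction(d, model_spec("y", c("x1", "x2")))
  expect_length(m$dropped_slopes, 0)                 # convergent model unchanged

  # no by-participant slope variance: the slope model is degenerate and
  # reduction must strip slopes (x2 first: reverse entry order)
  m2 <- slope_reduction(d, model_spec("y", c("x1", "x2"),
                                      random_slopes = c("x1", "x2")))
  expect_true(length(m2$dropped_slopes) >= 1)
  expect_equal(m2$dropped_slopes[1], "x2")
  expect_false(m2$singular && length(m2$spec$random_slopes) > 0)
})

test_that("the outlier refit removes only |resid| > 2.5 SD and is idempotent", {
  d <- sim_rows(n_part = 8, n_item = 30, sd_res = 2, seed = 44)
  spec <- model_spec("y", c("x1", "x2"))
  m <- fit_mixed(d, spec)
  r <- residuals(m)
  if (all(abs(r) <= 2.5 * sd(r))) {
    m_re <- refit_without_outliers(m)
    expect_equal(m_re$n_obs_refit, m_re$n_obs_initial)  # identical refit
    expect_equal(m_re$coefficients$beta, m$coefficients$beta)
  }

  d2 <- d; d2$y[1] <- d2$y[1] + 60                   # one gross outlier
  m2 <- fit_mixed(d2, spec)
  m2_re <- refit_without_outliers(m2)
  expect_equal(m2_re$n_obs_initial - m2_re$n_obs_refit, 1)
  truth <- c(5, -2)
  err_first <- abs(m2$coefficients$beta[2:3] - truth)
  err_refit <- abs(m2_re$coefficients$beta[2:3] - truth)
  expect_lt(sum(err_refit), sum(err_first) + 1e-9)   # refit closer to truth

  # a residual at exactly the threshold is retained
  res <- residuals(m2_re)
  keep <- abs(res) <= 2.5 * sd(res)
  expect_true(all(keep[abs(res) == 2.5 * sd(res)]))
})

test_that("variance-partition R2 matches the generative shares", {
  # fixed 20%, random 30%, residual 50% by construction
  set.seed(45)
  n_part <- 80; n_item <- 50
  items <- data.frame(item_id = sprintf("i%02d", 1:n_item),
                      x = rnorm(n_item, sd = 1))
  dd <- merge(expand.grid(participant_id = sprintf("p%02d", 1:n_part),
                          item_id = items$item_id), items, by = "item_id")
  u <- rnorm(n_part, 0, sqrt(30)); names(u) <- sprintf("p%02d", 1:n_part)
  dd$y <- sqrt(20) * dd$x + u[dd$participant_id] + rnorm(nrow(dd), 0, sqrt(50))
  m <- fit_mixed(dd, model_spec("y", "x"))
  expect_lt(abs(m$r2_marginal - 0.2), 0.07)
  expect_lt(abs(m$r2_conditional - 0.5), 0.07)
  expect_lte(m$r2_marginal, m$r2_conditional)
  expect_lte(m$r2_conditional, 1)

  # no fixed effects beyond the intercept: marginal R2 is zero
  m0 <- fit_mixed(dd, model_spec("y", character(0)))
  expect_lt(m0$r2_marginal, 1e-6)

  # zero random variance: conditional equals marginal
  d3 <- sim_rows(sd_part = 0, sd_item = 0)
  m3 <- fit_mixed(d3, model_spec("y", c("x1", "x2")))
  expect_equal(m3$r2_marginal, m3$r2_conditional, tolerance = 1e-4)
})

test_that("tolerance flags redundant predictors", {
  set.seed(46)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tol <- tolerance_check(d, c("a", "b", "c"))
  expect_true(all(tol > 0.9))                        # orthogonal -> near 1

  d$dup <- d$a
  tol2 <- tolerance_check(d, c("a", "dup", "b"))
  expect_lt(tol2["a"], 1e-9)
  expect_lt(tol2["dup"], 1e-9)

  # two predictors correlated at exactly 0.6, third orthogonal
  z <- rnorm(n)
  p <- scale(z)[, 1]
  q <- 0.6 * p + sqrt(1 - 0.36) * scale(resid(lm(rnorm(n) ~ p)))[, 1]
  dd <- data.frame(p = p, q = q, r = resid(lm(rnorm(n) ~ p + q)))
  tol3 <- tolerance_check(dd, c("p", "q", "r"))
  expect_equal(unname(tol3["p"]), 0.64, tolerance = 0.02)
  expect_equal(unname(tol3["q"]), 0.64, tolerance = 0.02)

  dd$const <- 1
  expect_warning(tol4 <- tolerance_check(dd, c("p", "const")), "constant")
  expect_true(is.na(tol4["const"]))
})
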