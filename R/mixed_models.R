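#' Model specification for crossed random-effects regression
#'
#' Fixes the response, the ordered fixed-effect terms (reported in entry
#' order), the by-participant random slopes requested initially, and the
#' significance level. Participants and items always enter as crossed
#' random intercepts.
#'
#' @param response name of the response column.
#' @param fixed_terms character vector of predictor columns, in entry
#'   order.
#' @param random_slopes subset of \code{fixed_terms} given by-participant
#'   random slopes in the initial fit (default none).
#' @param alpha significance level (0.05 for latencies; 0.01 for per-map
#'   duration models, Bonferroni over 5 maps).
#' @return a \code{model_spec}.
#' @export
model_spec <- function(response, fixed_terms, random_slopes = character(0),
                       alpha = 0.05) {
  stopifnot(all(random_slopes %in% fixed_terms))
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_slopes = random_slopes, alpha = alpha),
            class = "model_spec")
}

.spec_formula <- function(spec) {
  fe <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  re_p <- if (length(spec$random_slopes))
    sprintf("(1 + %s | participant_id)", paste(spec$random_slopes, collapse = " + "))
  else "(1 | participant_id)"
  stats::as.formula(paste(spec$response, "~", fe, "+", re_p, "+ (1 | item_id)"))
}

.fit_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  !any(grepl("failed to converge|convergence code", msgs, ignore.case = TRUE))
}

#' Fit a crossed random-effects linear mixed model
#'
#' REML fit with crossed random intercepts for participants and items and
#' any requested by-participant random slopes; t statistics use the
#' Satterthwaite degrees-of-freedom approximation (lmerTest). Coefficients
#' are reported in the entry order of the specification.
#'
#' @param data data frame with the response, the predictors, and
#'   \code{participant_id} / \code{item_id} columns.
#' @param spec a \code{\link{model_spec}}.
#' @return object of class \code{erpmicro_lmm}: list with \code{fit} (the
#'   lmerTest fit), \code{spec}, \code{coefficients} (term, beta, se, t, p,
#'   significant), \code{converged}, \code{singular}, \code{n_obs},
#'   \code{r2_marginal}, \code{r2_conditional}.
#' @export
fit_mixed <- function(data, spec) {
  if (length(unique(data$participant_id)) < 2L ||
      length(unique(data$item_id)) < 2L)
    stop("need at least 2 participants and 2 items")
  miss <- !stats::complete.cases(data[, c(spec$response, spec$fixed_terms),
                                       drop = FALSE])
  if (any(miss)) data <- data[!miss, , drop = FALSE]
  fit <- suppressMessages(lmerTest::lmer(.spec_formula(spec), data = data,
                                         REML = TRUE))
  co <- stats::coef(summary(fit))
  terms <- c("(Intercept)", spec$fixed_terms)
  co <- co[match(terms, rownames(co)), , drop = FALSE]
  r2 <- r2_nakagawa(fit)
  structure(list(
    fit = fit, spec = spec, data = data,
    coefficients = data.frame(
      term = terms, beta = co[, "Estimate"], se = co[, "Std. Error"],
      df = co[, "df"], t = co[, "t value"], p = co[, "Pr(>|t|)"],
      significant = co[, "Pr(>|t|)"] < spec$alpha, row.names = NULL),
    converged = .fit_converged(fit),
    singular = lme4::isSingular(fit),
    n_obs = nrow(data),
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]]),
    class = "erpmicro_lmm")
}

#' @export
print.erpmicro_lmm <- function(x, ...) {
  cat(sprintf("Crossed random-effects model: %s ~ %s\n", x$spec$response,
              paste(x$spec$fixed_terms, collapse = " + ")))
  if (length(x$spec$random_slopes))
    cat("  by-participant slopes:", paste(x$spec$random_slopes, collapse = ", "), "\n")
  cat(sprintf("  n = %d, R2m = %.3f, R2c = %.3f, alpha = %g%s%s\n", x$n_obs,
              x$r2_marginal, x$r2_conditional, x$spec$alpha,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular]" else ""))
  co <- x$coefficients
  co$beta <- signif(co$beta, 4); co$se <- signif(co$se, 3)
  co$t <- round(co$t, 2); co$p <- signif(co$p, 3)
  co$df <- round(co$df, 1)
  print(co, row.names = FALSE)
  invisible(x)
}

#' @export
summary.erpmicro_lmm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.erpmicro_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
residuals.erpmicro_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' Random-slope reduction on non-convergence
#'
#' Fits the full specification; while the optimizer fails to converge (or
#' the slope covariance is singular) and random slopes remain, removes the
#' by-participant slope whose term comes last in the fixed-effect entry
#' order and refits. A model that still fails with no slopes left is an
#' error; a singular intercepts-only fit (a variance estimated at zero) is
#' accepted and flagged.
#'
#' @param data model data frame.
#' @param spec initial \code{\link{model_spec}}.
#' @return an \code{erpmicro_lmm} with attribute-like element
#'   \code{dropped_slopes}.
#' @export
slope_reduction <- function(data, spec) {
  dropped <- character(0)
  repeat {
    m <- fit_mixed(data, spec)
    bad <- !m$converged || (m$singular && length(spec$random_slopes) > 0L)
    if (!bad) break
    if (!length(spec$random_slopes)) {
      if (!m$converged) stop("model failed to converge with no random slopes left")
      break
    }
    ord <- match(spec$random_slopes, spec$fixed_terms)
    drop <- spec$random_slopes[which.max(ord)]
    dropped <- c(dropped, drop)
    spec$random_slopes <- setdiff(spec$random_slopes, drop)
  }
  m$dropped_slopes <- dropped
  m
}

#' Refit after removing large standardized residuals
#'
#' Removes observations whose conditional residual exceeds
#' \code{threshold_sd} residual standard deviations in absolute value
#' (strictly) and refits the same specification. The refit is the model
#' whose coefficients are reported.
#'
#' @param model an \code{erpmicro_lmm} from \code{\link{fit_mixed}} or
#'   \code{\link{slope_reduction}}.
#' @param threshold_sd cutoff in residual SDs (default 2.5).
#' @return an \code{erpmicro_lmm} with elements \code{n_obs_initial} and
#'   \code{n_obs_refit}.
#' @export
refit_without_outliers <- function(model, threshold_sd = 2.5) {
  res <- stats::residuals(model$fit)
  keep <- abs(res) <= threshold_sd * stats::sd(res)
  if (mean(keep) < 0.8)
    warning(sprintf("outlier refit removes %.1f%% of rows; check model specification",
                    100 * mean(!keep)))
  out <- if (all(keep)) model else fit_mixed(model$data[keep, , drop = FALSE],
                                             model$spec)
  out$dropped_slopes <- model$dropped_slopes
  out$n_obs_initial <- model$n_obs
  out$n_obs_refit <- out$n_obs
  out
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R² for linear mixed models: the marginal R² is the
#' variance of the fixed-effect predictions over the total (fixed +
#' summed random + residual) variance; the conditional R² adds the random
#' variances to the numerator. Random-effect variance is the mean
#' per-observation variance implied by the fitted covariance (exact for
#' random-slope structures).
#'
#' @param fit a merMod / lmerModLmerTest fit (or an \code{erpmicro_lmm}).
#' @return named numeric vector \code{c(r2_marginal, r2_conditional)}.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "erpmicro_lmm")) fit <- fit$fit
  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  mu <- as.numeric(X %*% beta)
  var_f <- mean((mu - mean(mu))^2)
  lz <- lme4::getME(fit, "Lambdat") %*% lme4::getME(fit, "Zt")
  var_r <- mean(Matrix::colSums(lz^2)) * stats::sigma(fit)^2
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' Predictor tolerance (multicollinearity check)
#'
#' Tolerance of predictor j is \code{1 - R2} of the regression of j on all
#' other predictors; values below 0.5 indicate potentially harmful
#' redundancy. Constant predictors get NA with a warning.
#'
#' @param data data frame containing the predictors.
#' @param predictors character vector of column names (>= 2).
#' @return named numeric vector of tolerances.
#' @export
tolerance_check <- function(data, predictors) {
  stopifnot(length(predictors) >= 2L)
  out <- stats::setNames(numeric(length(predictors)), predictors)
  for (j in predictors) {
    x <- data[[j]]
    if (stats::var(x, na.rm = TRUE) == 0) {
      warning("constant predictor: ", j); out[j] <- NA_real_; next
    }
    f <- stats::as.formula(paste(j, "~", paste(setdiff(predictors, j),
                                               collapse = " + ")))
    out[j] <- 1 - summary(stats::lm(f, data = data))$r.squared
  }
  out
}
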