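#' Default fixed-effect entry order
#'
#' Phonological neighborhood density (LD20), positional segment and
#' diphone frequency, log lexical frequency, concept familiarity, visual
#' complexity, image agreement, name agreement (percent modal name) and
#' age of acquisition — always entered in this order.
#'
#' @param lexf which frequency measure to enter, \code{"book"} (written)
#'   or \code{"film"} (spoken).
#' @return character vector of predictor column names.
#' @export
default_fixed_terms <- function(lexf = c("book", "film")) {
  lexf <- match.arg(lexf)
  c("LD20", "PSF", "PDF", paste0("LexF_", lexf),
    "CFam", "VCom", "IAgr", "NAgr_pct", "AoA")
}

#' Per-trial map durations from a fit table
#'
#' Sums labeled time per trial and template over the fitting windows the
#' template is allowed in, giving one duration (ms) per trial x map.
#'
#' @param fit_table a \code{fit_table} from \code{\link{backfit_set}}.
#' @return data frame with columns trial_id, participant_id, item_id,
#'   rt_ms, template, duration_ms.
#' @export
map_durations <- function(fit_table) {
  key <- interaction(fit_table$trial_id, fit_table$template, drop = TRUE)
  out <- do.call(rbind, lapply(split(fit_table, key), function(d)
    data.frame(trial_id = d$trial_id[1], participant_id = d$participant_id[1],
               item_id = d$item_id[1], rt_ms = d$rt_ms[1],
               template = d$template[1],
               duration_ms = sum(d$duration_ms))))
  rownames(out) <- NULL
  out
}

#' Run the full regression suite
#'
#' Fits one production-latency model (alpha = 0.05) and one duration model
#' per template map (alpha = 0.01, Bonferroni over five maps), each with
#' crossed random intercepts for participants and items and by-participant
#' random slopes for the reported-effect terms (AoA, IAgr, NAgr), reduced
#' on non-convergence; each model is fitted twice, the second time without
#' observations whose residuals exceed 2.5 residual SDs, and reported from
#' the refit together with marginal/conditional R² and predictor
#' tolerances. An alternative variant replacing the neighborhood and
#' phonotactic measures by the number of syllables (which correlates with
#' them above 0.6) is fitted for the latency model when
#' \code{variant = "both"}.
#'
#' @param fit_table per-trial \code{fit_table} from \code{\link{backfit_set}}.
#' @param predictor_table item-level predictor table (column
#'   \code{item_id} plus the predictors).
#' @param alpha_rt,alpha_maps significance levels (defaults 0.05, 0.01).
#' @param lexf frequency measure entered (\code{"book"} or \code{"film"}).
#' @param random_slopes initial by-participant random slopes (default
#'   AoA, IAgr, NAgr_pct).
#' @param variant \code{"ld_phonotactics"} (default) or \code{"both"} to
#'   add the syllable-count variant of the latency model.
#' @param refit_outliers apply the 2.5-SD refit rule (default TRUE).
#' @return object of class \code{erpmicro_suite}: list with \code{rt_model},
#'   \code{map_models} (one per template), optional \code{variant_model},
#'   \code{tolerance}, and \code{skipped} (maps with no duration variance).
#' @export
run_analysis_suite <- function(fit_table, predictor_table,
                               alpha_rt = 0.05, alpha_maps = 0.01,
                               lexf = "book",
                               random_slopes = c("AoA", "IAgr", "NAgr_pct"),
                               variant = c("ld_phonotactics", "both"),
                               refit_outliers = TRUE) {
  variant <- match.arg(variant)
  fixed <- default_fixed_terms(lexf)
  miss <- setdiff(c("item_id", fixed), names(predictor_table))
  if (length(miss)) stop("predictor table lacks columns: ",
                         paste(miss, collapse = ", "))
  dur <- map_durations(fit_table)
  orphans <- setdiff(unique(dur$item_id), predictor_table$item_id)
  if (length(orphans)) stop("items missing from predictor table: ",
                            paste(utils::head(orphans, 5), collapse = ", "))
  dur <- merge(dur, predictor_table, by = "item_id")
  rt_rows <- dur[!duplicated(dur$trial_id), setdiff(names(dur), c("template", "duration_ms"))]

  run_one <- function(rows, spec) {
    m <- slope_reduction(rows, spec)
    if (refit_outliers) m <- refit_without_outliers(m) else {
      m$n_obs_initial <- m$n_obs; m$n_obs_refit <- m$n_obs
    }
    m
  }

  rt_model <- run_one(rt_rows, model_spec("rt_ms", fixed, random_slopes, alpha_rt))

  templates <- sort(unique(dur$template))
  map_models <- list(); skipped <- integer(0)
  for (k in templates) {
    rows <- dur[dur$template == k, ]
    if (!nrow(rows) || stats::var(rows$duration_ms) == 0) {
      skipped <- c(skipped, k)
      message("map ", k, ": no duration variance; model skipped")
      next
    }
    map_models[[LETTERS[k]]] <-
      run_one(rows, model_spec("duration_ms", fixed, random_slopes, alpha_maps))
  }

  variant_model <- NULL
  if (variant == "both") {
    v_fixed <- c("n_syllables", setdiff(fixed, c("LD20", "PSF", "PDF")))
    variant_model <- run_one(rt_rows,
                             model_spec("rt_ms", v_fixed, random_slopes, alpha_rt))
  }

  structure(list(rt_model = rt_model, map_models = map_models,
                 variant_model = variant_model,
                 tolerance = tolerance_check(predictor_table, fixed),
                 skipped = skipped),
            class = "erpmicro_suite")
}

#' @export
print.erpmicro_suite <- function(x, ...) {
  cat("== Production latencies ==\n"); print(x$rt_model)
  for (nm in names(x$map_models)) {
    cat(sprintf("\n== Map %s duration ==\n", nm)); print(x$map_models[[nm]])
  }
  if (!is.null(x$variant_model)) {
    cat("\n== Latency variant (syllable count) ==\n"); print(x$variant_model)
  }
  cat("\nPredictor tolerances:\n")
  print(round(x$tolerance, 3))
  if (any(x$tolerance < 0.5, na.rm = TRUE))
    cat("NOTE: tolerances below 0.5 indicate harmful collinearity\n")
  invisible(x)
}
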