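#' Configuration of the synthetic picture-naming dataset
#'
#' The generator emulates the statistical structure of a high-density EEG
#' picture-naming study: 31-ish participants naming ~100 items, a strictly
#' serial sequence of five quasi-stable scalp topographies (maps A-E)
#' between 50 ms post picture onset and 100 ms before articulation, map
#' durations depending linearly on item predictors, and reaction times
#' equal to an offset (50 ms pre-analysis + 100 ms pre-articulation
#' margin) plus the summed state durations.
#'
#' Default effect sizes (ms per predictor unit, predictors centered at
#' their scale midpoints): visual complexity -1.92 on map B; image
#' agreement -8.67, name agreement -1.08 and age of acquisition +9.92 on
#' map D; name agreement -0.67 and age of acquisition +7.6 on map E.
#' Trial-to-trial duration variability has a per-state residual, crossed
#' participant and item random intercepts, and a shared per-trial speed
#' component split over states by configurable weights (which ties map
#' durations to reaction time, as general processing speed does). The
#' variability defaults concentrate trial-to-trial variance on the later,
#' response-locked states: early visual maps are tightly stimulus-locked
#' while word-encoding durations carry most of the latency variance, which
#' is also what lets a grand average over stimulus- and response-aligned
#' segments retain all five topographies.
#'
#' @param n_participants,n_items,n_channels,sampling_rate,n_states study
#'   dimensions (defaults 30, 100, 128, 512 Hz, 5 states).
#' @param intercepts_ms mean state durations (ms); their sum plus
#'   \code{rt_offset_ms} is the mean reaction time.
#' @param coefficients n_states x predictor matrix of ms-per-unit effects
#'   (columns named after predictors); NULL for the defaults above.
#' @param resid_sd_ms,participant_sd_ms,item_sd_ms per-state SDs of the
#'   residual, participant-intercept and item-intercept components.
#' @param trial_speed_sd_ms SD of the shared per-trial speed component.
#' @param speed_weights how the speed component is split over states
#'   (normalized to sum to 1; default concentrates it on maps C-E).
#' @param amplitude_uv per-state GFP amplitude of the noiseless signal.
#' @param noise_sd_uv SD of white sensor noise added per channel/sample
#'   (before band-pass filtering).
#' @param rt_offset_ms offset between summed state durations and RT
#'   (default 150 = 50 ms pre-analysis + 100 ms pre-articulation).
#' @param rt_range_ms admissible RT range; trials outside are resampled.
#' @param min_duration_ms minimum admissible state duration; trials below
#'   are resampled.
#' @param seed RNG seed making all generated outputs reproducible.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_participants = 30L, n_items = 100L,
                             n_channels = 128L, sampling_rate = 512,
                             n_states = 5L,
                             intercepts_ms = c(90, 40, 200, 240, 85),
                             coefficients = NULL,
                             resid_sd_ms = c(5, 4, 30, 45, 15),
                             participant_sd_ms = c(5, 3, 25, 35, 12),
                             item_sd_ms = c(3, 2, 12, 18, 6),
                             trial_speed_sd_ms = 80,
                             speed_weights = c(0.05, 0.03, 0.25, 0.52, 0.15),
                             amplitude_uv = c(2.5, 3.0, 2.2, 1.8, 2.0),
                             envelope = c("halfsine", "plateau"),
                             envelope_floor = 0.3,
                             noise_sd_uv = 10,
                             rt_offset_ms = 150,
                             rt_range_ms = c(500, 1500),
                             min_duration_ms = 4,
                             seed = 1L) {
  if (is.null(coefficients)) {
    coefficients <- matrix(0, n_states, length(.predictor_centers()),
                           dimnames = list(NULL, names(.predictor_centers())))
    if (n_states >= 2L) coefficients[2L, "VCom"] <- -1.92
    if (n_states >= 4L) {
      coefficients[4L, "IAgr"] <- -8.67
      coefficients[4L, "NAgr_pct"] <- -1.08
      coefficients[4L, "AoA"] <- 9.92
    }
    if (n_states >= 5L) {
      coefficients[5L, "NAgr_pct"] <- -0.67
      coefficients[5L, "AoA"] <- 7.6
    }
  }
  envelope <- match.arg(envelope)
  stopifnot(length(intercepts_ms) == n_states,
            nrow(coefficients) == n_states,
            length(speed_weights) == n_states)
  speed_weights <- speed_weights / sum(speed_weights)
  structure(as.list(environment()), class = "synthetic_config")
}

# scale midpoints the generator centers predictors on
.predictor_centers <- function() {
  c(LD20 = 2, PSF = 0.5, PDF = 0.5, LexF_book = 1.2, LexF_film = 1.2,
    CFam = 3, VCom = 3, IAgr = 3, NAgr_pct = 65, AoA = 5.5, n_syllables = 2)
}

#' Generate smooth, mutually dissimilar template topographies
#'
#' Each template is a random linear combination of low-order polynomial
#' functions of electrode position (first- and second-order spherical
#' harmonics on the montage), giving smooth dipolar/quadrupolar-looking
#' maps; templates are average-referenced, normalized to unit GFP, and
#' regenerated until every pair is at least \code{min_dissimilarity}
#' apart in global map dissimilarity (|spatial correlation| <= 0.68 at
#' the 0.8 default).
#'
#' @param n_states number of maps.
#' @param layout an \code{\link{eeg_layout}}.
#' @param min_dissimilarity pairwise dissimilarity floor (default 0.8).
#' @param max_tries regeneration budget per map (default 500).
#' @return channels x n_states matrix of unit-GFP templates.
#' @export
make_templates <- function(n_states, layout, min_dissimilarity = 0.8,
                           max_tries = 500L) {
  pos <- as.matrix(layout[, c("x", "y", "z")])
  basis <- cbind(pos,
                 pos[, 1] * pos[, 2], pos[, 1] * pos[, 3], pos[, 2] * pos[, 3],
                 pos[, 1]^2 - pos[, 2]^2, 2 * pos[, 3]^2 - pos[, 1]^2 - pos[, 2]^2)
  if (n_states > ncol(basis))
    stop("at most ", ncol(basis), " mutually dissimilar smooth maps available")
  r_max <- 1 - min_dissimilarity^2 / 2
  # orthonormalize the (average-referenced) basis over electrodes, then mix
  # with a random rotation: maps from distinct stages are mutually orthogonal
  # scalp fields, comfortably above any admissible dissimilarity floor
  basis <- sweep(basis, 2L, colMeans(basis))
  for (try in seq_len(max_tries)) {
    B <- qr.Q(qr(basis))
    Q <- qr.Q(qr(matrix(stats::rnorm(ncol(basis)^2), ncol(basis))))
    out <- B %*% Q[, seq_len(n_states), drop = FALSE]
    out <- sweep(out, 2L, colMeans(out))            # numeric safety
    s <- sqrt(colMeans(out^2))
    if (any(s == 0)) next
    out <- sweep(out, 2L, s, "/")
    if (n_states == 1L) return(out)
    r <- crossprod(out) / nrow(out)
    if (max(abs(r[upper.tri(r)])) <= r_max) return(out)
  }
  stop("could not satisfy the dissimilarity constraint; lower it")
}

#' Simulate an item norms / predictor table
#'
#' Draws item predictors from a Gaussian copula whose targets reproduce
#' the reported predictor correlation structure: lexical frequency
#' correlates -0.366 with image agreement, 0.283 with concept familiarity
#' and -0.260 with age of acquisition; the number of syllables correlates
#' above 0.6 (in magnitude) with the neighborhood-density and phonotactic
#' measures (which triggers the syllable-count model variant); remaining
#' pairs are near zero. Marginals are mapped to each predictor's scale
#' (ratings 1-5, percent modal name 30-100, AoA 1-10, log10 frequency per
#' million, phonotactic scores in (0, 1)).
#'
#' @param n_items number of items (>= 10).
#' @return data frame with columns item_id, LD20, PSF, PDF, LexF_book,
#'   LexF_film, CFam, VCom, IAgr, NAgr_pct, H, AoA, n_syllables; the
#'   realized correlation matrix is attached as attribute
#'   \code{realized_correlations}.
#' @export
simulate_norms <- function(n_items = 100L) {
  if (n_items < 10L) stop("need at least 10 items")
  vars <- c("LD20", "PSF", "PDF", "LexF_book", "LexF_film",
            "CFam", "VCom", "IAgr", "NAgr_pct", "AoA", "n_syllables")
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set_r("LexF_book", "IAgr", -0.366)
  set_r("LexF_book", "CFam", 0.283)
  set_r("LexF_book", "AoA", -0.260)
  set_r("LexF_film", "IAgr", -0.366)
  set_r("LexF_film", "CFam", 0.283)
  set_r("LexF_film", "AoA", -0.260)
  set_r("LexF_book", "LexF_film", 0.85)
  set_r("n_syllables", "LD20", 0.65)
  set_r("n_syllables", "PSF", -0.62)
  set_r("n_syllables", "PDF", -0.62)
  set_r("PSF", "PDF", 0.50)
  set_r("LD20", "PSF", -0.40)
  set_r("LD20", "PDF", -0.40)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {            # nearest-PD repair by eigenvalue clipping
    ev$values <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    d <- sqrt(diag(R)); R <- R / tcrossprod(d)
    message("target correlation matrix repaired to nearest positive definite")
  }
  Z <- MASS::mvrnorm(n_items, mu = rep(0, length(vars)), Sigma = R)
  colnames(Z) <- vars
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- data.frame(
    item_id = sprintf("item%03d", seq_len(n_items)),
    LD20 = clip(2 + 0.4 * Z[, "LD20"], 0.5, 4),
    PSF = clip(0.5 + 0.15 * Z[, "PSF"], 0.02, 0.98),
    PDF = clip(0.5 + 0.15 * Z[, "PDF"], 0.02, 0.98),
    LexF_book = clip(1.2 + 0.6 * Z[, "LexF_book"], -0.5, 3.5),
    LexF_film = clip(1.2 + 0.6 * Z[, "LexF_film"], -0.5, 3.5),
    CFam = clip(3 + 0.8 * Z[, "CFam"], 1, 5),
    VCom = clip(3 + 0.8 * Z[, "VCom"], 1, 5),
    IAgr = clip(3 + 0.8 * Z[, "IAgr"], 1, 5),
    NAgr_pct = 30 + 70 * stats::pnorm(Z[, "NAgr_pct"]),
    AoA = clip(5.5 + 1.8 * Z[, "AoA"], 1, 10),
    n_syllables = pmin(pmax(round(2 + 0.8 * Z[, "n_syllables"]), 1), 5),
    stringsAsFactors = FALSE)
  out$H <- pmax(0, (100 - out$NAgr_pct) / 25 + stats::rnorm(n_items, 0, 0.1))
  attr(out, "realized_correlations") <- stats::cor(as.matrix(out[, vars]))
  out
}

#' Simulate raw stimulus- and response-aligned trials with ground truth
#'
#' For each participant x item trial, draws per-state durations from the
#' linear duration model of the configuration, builds the noiseless scalp
#' signal as the active state's template times a plateau amplitude
#' envelope with brief rise/fall tapers (so the global field power dips at
#' map transitions), adds white sensor noise, and cuts the stimulus-aligned
#' (0-450 ms) and response-aligned (-550 to +100 ms around articulation)
#' raw epochs so that rejection, merging and filtering can be exercised
#' end to end. Before 50 ms and after 100 ms before articulation the
#' signal is baseline (noise only).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param norms predictor table from \code{\link{simulate_norms}} (rows
#'   >= \code{config$n_items}).
#' @param templates channels x n_states matrix from
#'   \code{\link{make_templates}}.
#' @param layout the montage.
#' @return list with \code{epochs} (an \code{\link{epoch_set}}) and
#'   \code{ground_truth} (data frame: trial_id, participant_id, item_id,
#'   rt_ms, duration_ms_1..K; attribute \code{participant_intercepts}).
#' @export
simulate_trials <- function(config, norms, templates, layout) {
  cfg <- config
  K <- cfg$n_states
  fs <- cfg$sampling_rate
  stopifnot(nrow(norms) >= cfg$n_items, ncol(templates) == K)
  norms <- norms[seq_len(cfg$n_items), ]
  centers <- .predictor_centers()
  pred_cols <- colnames(cfg$coefficients)
  Xc <- sweep(as.matrix(norms[, pred_cols]), 2L, centers[pred_cols])
  item_fx <- Xc %*% t(cfg$coefficients)          # n_items x K, ms
  u_part <- matrix(stats::rnorm(cfg$n_participants * K), cfg$n_participants, K) *
    rep(cfg$participant_sd_ms, each = cfg$n_participants)
  v_item <- matrix(stats::rnorm(cfg$n_items * K), cfg$n_items, K) *
    rep(cfg$item_sd_ms, each = cfg$n_items)
  w_speed <- cfg$speed_weights

  n_trials <- cfg$n_participants * cfg$n_items
  grid <- expand.grid(item = seq_len(cfg$n_items),
                      participant = seq_len(cfg$n_participants))
  stim <- vector("list", n_trials); resp <- vector("list", n_trials)
  dur_all <- matrix(NA_real_, n_trials, K)
  rt_all <- numeric(n_trials)
  n_stim <- n_samples(450, fs); n_resp <- n_samples(650, fs)
  for (i in seq_len(n_trials)) {
    p <- grid$participant[i]; it <- grid$item[i]
    for (try in seq_len(100L)) {
      speed <- stats::rnorm(1, 0, cfg$trial_speed_sd_ms)
      dur <- cfg$intercepts_ms + item_fx[it, ] + u_part[p, ] + v_item[it, ] +
        w_speed * speed + stats::rnorm(K, 0, cfg$resid_sd_ms)
      rt <- cfg$rt_offset_ms + sum(dur)
      if (all(dur >= cfg$min_duration_ms) &&
          rt > cfg$rt_range_ms[1] && rt < cfg$rt_range_ms[2]) break
      if (try == 100L) stop("could not sample admissible durations; check config")
    }
    dur_all[i, ] <- dur; rt_all[i] <- rt
    # one continuous signal from min(0, rt-550) to rt+100 ms; for fast
    # responses the response-aligned epoch reaches back before picture
    # onset, where the signal is baseline (sensor noise only)
    resp_start_rel <- n_samples(rt - 550, fs) + 1L
    pre <- max(0L, 1L - resp_start_rel)
    L <- pre + max(n_samples(rt + 100, fs), resp_start_rel + n_resp - 1L)
    t_ms <- (seq_len(L) - 1L - pre) * 1000 / fs
    # state edges: analysis starts 50 ms post onset, ends at rt - 100 ms;
    # each state is an evoked-component amplitude bump (half-sine: field
    # waxes and wanes with GFP minima at transitions) or a tapered plateau;
    # before 50 ms and after articulation - 100 ms the signal is baseline
    edges <- cfg$rt_offset_ms - 100 + c(0, cumsum(dur))
    state <- pmin(pmax(findInterval(t_ms, edges), 0L), K)
    inside <- state >= 1L & t_ms < edges[K + 1L] & t_ms >= edges[1L]
    amp <- rep(0, L)
    ii <- which(inside)
    t_in <- t_ms[ii] - edges[state[ii]]
    d_s <- dur[state[ii]]
    fl <- cfg$envelope_floor
    amp[ii] <- cfg$amplitude_uv[state[ii]] *
      if (cfg$envelope == "halfsine") fl + (1 - fl) * sinpi(t_in / d_s) else {
        taper <- pmin(15, d_s / 3)
        pmin(1, t_in / taper, (d_s - t_in) / taper)
      }
    state[state < 1L] <- 1L
    sig <- templates[, state, drop = FALSE] * rep(amp, each = nrow(templates))
    sig <- sig + matrix(stats::rnorm(length(sig), 0, cfg$noise_sd_uv),
                        nrow(sig), ncol(sig))
    stim[[i]] <- sig[, pre + seq_len(n_stim), drop = FALSE]
    resp[[i]] <- sig[, pre + seq(resp_start_rel, resp_start_rel + n_resp - 1L),
                     drop = FALSE]
  }
  trials <- data.frame(
    trial_id = sprintf("t%05d", seq_len(n_trials)),
    participant_id = sprintf("p%02d", grid$participant),
    item_id = norms$item_id[grid$item],
    rt_ms = rt_all, accuracy = 1L, stringsAsFactors = FALSE)
  gt <- cbind(trials[, c("trial_id", "participant_id", "item_id", "rt_ms")],
              stats::setNames(as.data.frame(dur_all),
                              paste0("duration_ms_", seq_len(K))))
  attr(gt, "participant_intercepts") <- u_part
  list(epochs = epoch_set(trials, stim, resp, layout, fs), ground_truth = gt)
}

#' Inject amplitude artifacts and bad channels
#'
#' Adds a transient exceeding the rejection threshold to a random fraction
#' of trials (tagging them in the manifest) and replaces random channels
#' by high-variance noise on a fraction of trials, listing them in a
#' \code{bad_channels} manifest column.
#'
#' @param set an \code{epoch_set}.
#' @param fraction fraction of trials receiving an artifact transient.
#' @param amplitude_uv peak amplitude of the transient (default 150).
#' @param bad_channel_rate fraction of trials receiving one bad channel
#'   (default 0).
#' @return the modified \code{epoch_set}; manifest gains logical
#'   \code{artifact} and character \code{bad_channels} columns.
#' @export
inject_artifacts <- function(set, fraction, amplitude_uv = 150,
                             bad_channel_rate = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(set$trials)
  set$trials$artifact <- FALSE
  set$trials$bad_channels <- ""
  hit <- sample(n, round(fraction * n))
  for (i in hit) {
    ch <- sample(nrow(set$layout), 1L)
    at <- sample(ncol(set$stim[[i]]) - 3L, 1L)
    set$stim[[i]][ch, at:(at + 3L)] <- amplitude_uv * c(0.8, 1, 1, 0.8) *
      sign(stats::rnorm(1))
    set$trials$artifact[i] <- TRUE
  }
  if (bad_channel_rate > 0) {
    bad <- sample(n, round(bad_channel_rate * n))
    for (i in bad) {
      ch <- sample(nrow(set$layout), 1L)
      set$stim[[i]][ch, ] <- stats::rnorm(ncol(set$stim[[i]]), 0, 40)
      set$resp[[i]][ch, ] <- stats::rnorm(ncol(set$resp[[i]]), 0, 40)
      set$trials$bad_channels[i] <- set$layout$channel_id[ch]
    }
  }
  set
}

#' Simulate a complete synthetic study
#'
#' Layout, templates, norms and trials in one call, seeded for
#' reproducibility.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{layout}, \code{templates}, \code{norms},
#'   \code{epochs}, \code{ground_truth}, \code{config}.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  layout <- make_spherical_layout(config$n_channels)
  templates <- make_templates(config$n_states, layout)
  norms <- simulate_norms(config$n_items)
  sim <- simulate_trials(config, norms, templates, layout)
  list(layout = layout, templates = templates, norms = norms,
       epochs = sim$epochs, ground_truth = sim$ground_truth, config = config)
}

#' Random phonological lexicon
#'
#' Consonant-vowel forms with log10 frequencies, for exercising the
#' neighborhood-density and phonotactic measures.
#'
#' @param n_words lexicon size.
#' @return data frame with \code{phon_form}, \code{log_frequency}.
#' @export
make_lexicon <- function(n_words = 500L) {
  cons <- strsplit("ptkbdgmnlrsfvzj", "")[[1]]
  vows <- strsplit("aeiouy", "")[[1]]
  forms <- vapply(seq_len(n_words), function(i) {
    n_syl <- sample(1:4, 1, prob = c(0.3, 0.4, 0.2, 0.1))
    paste(vapply(seq_len(n_syl), function(s)
      paste0(sample(cons, 1), sample(vows, 1),
             if (stats::runif(1) < 0.25) sample(cons, 1) else ""),
      character(1)), collapse = "")
  }, character(1))
  data.frame(phon_form = forms,
             log_frequency = round(stats::rexp(n_words, 1) + 0.05, 3),
             stringsAsFactors = FALSE)
}
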