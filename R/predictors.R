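#' Phonological Levenshtein distance
#'
#' Minimum number of insertions, deletions or substitutions turning one
#' phonological form into the other, with one character per segment and
#' unit costs (computed via \code{utils::adist}).
#'
#' @param a,b segment strings (vectors recycle; elementwise distance).
#' @return integer vector of edit distances.
#' @export
levenshtein <- function(a, b) {
  if (length(a) == length(b)) {
    out <- integer(length(a))
    for (i in seq_along(a)) out[i] <- utils::adist(a[i], b[i])[1, 1]
    out
  } else as.integer(utils::adist(a, b))
}

#' Mean Levenshtein distance to the k closest neighbors (LD20)
#'
#' Phonological neighborhood density: the mean edit distance from a word
#' to its \code{k} (default 20) closest neighbors in the lexicon. The word
#' itself is excluded from its own neighbor set. Ties at the k-th smallest
#' distance do not affect the mean (all tied entries share the distance
#' value).
#'
#' @param word phonological form (segment string).
#' @param lexicon character vector of phonological forms, or a data frame
#'   with a \code{phon_form} column.
#' @param k number of neighbors (default 20).
#' @param exclude_self if TRUE (default), one exact-form occurrence is
#'   removed from the lexicon, on the assumption that it is the word's own
#'   entry; set FALSE when the lexicon is known not to contain the word
#'   (then identical forms are genuine homophone neighbors at distance 0).
#' @return mean distance (numeric scalar).
#' @export
ld20 <- function(word, lexicon, k = 20L, exclude_self = TRUE) {
  forms <- if (is.data.frame(lexicon)) lexicon$phon_form else lexicon
  if (exclude_self) {
    self <- match(word, forms)
    if (!is.na(self)) forms <- forms[-self]
  }
  if (length(forms) < k)
    stop(sprintf("lexicon has only %d entries besides the word; k = %d",
                 length(forms), k))
  d <- as.integer(utils::adist(word, forms))
  mean(sort(d)[seq_len(k)])
}

#' Positional phonotactic probability
#'
#' Frequency-weighted positional probability of a word's segments or
#' diphones. For each position i of the word, the ratio between the summed
#' log frequencies of the lexicon words carrying the same unit at position
#' i and the summed log frequencies of all lexicon words having any unit
#' at that position; the score is the arithmetic mean of the per-position
#' ratios. Diphones are indexed by the position of their first segment;
#' words shorter than two segments get a diphone score of 0.
#'
#' Log frequencies are shifted to be strictly positive
#' (\code{log10(freq_per_million + 1)} is the expected input scale) so
#' that the ratios lie in [0, 1].
#'
#' @param word segment string.
#' @param lexicon data frame with columns \code{phon_form} and
#'   \code{log_frequency} (positive).
#' @param unit \code{"segment"} or \code{"diphone"}.
#' @return scalar score in [0, 1] (when log frequencies are positive).
#' @export
positional_phonotactics <- function(word, lexicon,
                                    unit = c("segment", "diphone")) {
  unit <- match.arg(unit)
  units_of <- function(form) {
    seg <- strsplit(form, "")[[1]]
    if (unit == "segment") seg
    else if (length(seg) < 2L) character(0)
    else paste0(seg[-length(seg)], seg[-1L])
  }
  wu <- units_of(word)
  if (!length(wu)) return(0)
  lex_units <- lapply(lexicon$phon_form, units_of)
  lens <- lengths(lex_units)
  ratios <- vapply(seq_along(wu), function(i) {
    has <- lens >= i
    if (!any(has)) return(0)
    denom <- sum(lexicon$log_frequency[has])
    if (denom == 0) return(0)
    match_i <- has & vapply(seq_along(lex_units), function(j)
      lens[j] >= i && lex_units[[j]][i] == wu[i], logical(1))
    sum(lexicon$log_frequency[match_i]) / denom
  }, numeric(1))
  mean(ratios)
}

#' Name agreement from norming responses
#'
#' Percentage of raters producing the modal name, and the entropy (H, in
#' bits) of the response distribution: \code{H = sum p_i log2(1/p_i)}.
#' H is 0 when all raters agree and log2(n types) when responses are
#' uniform over the types.
#'
#' @param responses named integer vector of response counts (name -> count)
#'   or a character vector of raw responses.
#' @return list with \code{NAgr_pct} and \code{H}.
#' @export
name_agreement <- function(responses) {
  counts <- if (is.character(responses)) table(responses) else responses
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) < 1) stop("no norming responses")
  p <- as.numeric(counts) / sum(counts)
  list(NAgr_pct = 100 * max(p), H = -sum(p * log2(p)))
}

#' Assemble an item predictor table
#'
#' Joins rating norms with lexicon-derived measures (LD20, positional
#' segment and diphone frequency) for each item.
#'
#' @param norms data frame with columns \code{item_id}, \code{phon_form}
#'   and rating columns (e.g. VCom, CFam, IAgr, NAgr_pct, H, AoA,
#'   LexF_book, LexF_film, n_syllables).
#' @param lexicon data frame with \code{phon_form}, \code{log_frequency}.
#' @param k neighborhood size for LD (default 20).
#' @return the norms data frame with added columns \code{LD20},
#'   \code{PSF}, \code{PDF}.
#' @export
build_predictor_table <- function(norms, lexicon, k = 20L) {
  norms$LD20 <- vapply(norms$phon_form, ld20, numeric(1), lexicon = lexicon, k = k)
  norms$PSF <- vapply(norms$phon_form, positional_phonotactics, numeric(1),
                      lexicon = lexicon, unit = "segment")
  norms$PDF <- vapply(norms$phon_form, positional_phonotactics, numeric(1),
                      lexicon = lexicon, unit = "diphone")
  norms
}
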