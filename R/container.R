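#' Read and write epoch containers
#'
#' The on-disk epoch container is a directory holding \code{manifest.tsv}
#' (trial_id, participant_id, item_id, rt_ms, accuracy, plus file columns
#' and any bookkeeping columns such as junction_sample/gap_flag),
#' \code{layout.tsv}, \code{sampling_rate.tsv}, and one plain-text matrix
#' file per trial and alignment (tab-separated, channels x samples, row
#' order = layout order).
#'
#' @param set an \code{epoch_set} or \code{merged_set}.
#' @param dir target directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_epoch_container <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_layout(set$layout, file.path(dir, "layout.tsv"))
  writeLines(as.character(set$sampling_rate), file.path(dir, "sampling_rate.tsv"))
  man <- set$trials
  wm <- function(m, path) utils::write.table(
    m, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (inherits(set, "merged_set")) {
    man$data_file <- paste0(man$trial_id, "_merged.tsv")
    for (i in seq_len(nrow(man))) wm(set$data[[i]], file.path(dir, man$data_file[i]))
    man$cut_ms <- set$cut_ms
  } else {
    man$stim_file <- paste0(man$trial_id, "_stim.tsv")
    man$resp_file <- paste0(man$trial_id, "_resp.tsv")
    for (i in seq_len(nrow(man))) {
      wm(set$stim[[i]], file.path(dir, man$stim_file[i]))
      wm(set$resp[[i]], file.path(dir, man$resp_file[i]))
    }
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epoch_container
#' @export
read_epoch_container <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  layout <- read_layout(file.path(dir, "layout.tsv"))
  fs <- as.numeric(readLines(file.path(dir, "sampling_rate.tsv"))[1])
  rd <- function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
    dimnames(m) <- NULL
    m
  }
  if ("data_file" %in% names(man)) {
    data <- lapply(man$data_file, rd)
    cut_ms <- if ("cut_ms" %in% names(man)) man$cut_ms[1] else 100
    trials <- man[, setdiff(names(man), c("data_file", "cut_ms"))]
    structure(list(trials = trials, data = data, layout = layout,
                   sampling_rate = fs, cut_ms = cut_ms),
              class = "merged_set")
  } else {
    stim <- lapply(man$stim_file, rd)
    resp <- lapply(man$resp_file, rd)
    trials <- man[, setdiff(names(man), c("stim_file", "resp_file"))]
    epoch_set(trials, stim, resp, layout, fs)
  }
}
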