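# Breath-group segmentation: a breath group (BG) is the run of words between
# pauses long enough for breathing. A new BG starts whenever the silent gap
# between consecutive words reaches the pause threshold, or the speaker
# changes; BGs never span speakers.

#' Segment words into breath groups at speech pauses
#'
#' Rebuilds the breath-group level of a hierarchy from its word tokens. A new
#' breath group opens when the gap between consecutive words
#' (`next start - previous end`) is at least `pause_threshold`, or at a
#' speaker change. Each breath group spans exactly its words; every word is
#' assigned to exactly one breath group. The operation is idempotent for a
#' fixed threshold.
#'
#' @param h a `corpus_hierarchy`, or a data.frame of word tokens with columns
#'   `speaker`, `label`, `start`, `end` ordered by start time within speaker.
#' @param pause_threshold minimum pause duration in seconds (> 0) separating
#'   breath groups. The corpus under study fixes no canonical value; the
#'   default 0.1 s sits above typical annotation granularity (10 ms) and
#'   below breathing-pause durations.
#' @param tol tolerance in seconds for negative gaps (aligner rounding).
#' @return a `corpus_hierarchy` with the breath-group level replaced.
#' @export
segment_breath_groups <- function(h, pause_threshold = 0.1, tol = 1e-3) {
  if (!(is.numeric(pause_threshold) && length(pause_threshold) == 1L &&
        pause_threshold > 0))
    stop("pause_threshold must be a positive number")

  if (is.data.frame(h)) {
    words <- h
    words$level <- "word"
    return(corpus_hierarchy(words, pause_threshold = pause_threshold,
                            tol = tol))
  }
  stopifnot(inherits(h, "corpus_hierarchy"))
  tk <- h$tokens[h$tokens$level != "breath_group", , drop = FALSE]
  words <- tk[tk$level == "word", , drop = FALSE]
  if (nrow(words) == 0L) stop("hierarchy has no word tokens")

  next_id <- max(tk$id) + 1L
  bg_rows <- list()
  for (sp in unique(words$speaker)) {
    w <- words[words$speaker == sp, , drop = FALSE]
    if (is.unsorted(w$start)) stop("word tokens not ordered by start time")
    gap <- if (nrow(w) > 1L) w$start[-1L] - w$end[-nrow(w)] else numeric(0)
    if (any(gap < -tol))
      stop(sprintf("negative gap between words for speaker '%s'", sp))
    breaks <- c(TRUE, gap >= pause_threshold)
    grp <- cumsum(breaks)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      bg_rows[[length(bg_rows) + 1L]] <- data.frame(
        speaker = sp, level = "breath_group", label = "",
        start = w$start[idx[1L]], end = w$end[idx[length(idx)]],
        id = next_id, t = w$end[idx[length(idx)]] - w$start[idx[1L]],
        parent = NA_integer_, stringsAsFactors = FALSE
      )
      words_idx <- w$id[idx]
      tk$parent[match(words_idx, tk$id)] <- next_id
      next_id <- next_id + 1L
    }
  }
  tk2 <- rbind(tk, do.call(rbind, bg_rows))
  ord <- order(tk2$speaker, tk2$start, match(tk2$level, rev(.levels)))
  tk2 <- tk2[ord, , drop = FALSE]
  rownames(tk2) <- NULL
  structure(list(tokens = tk2), class = "corpus_hierarchy")
}
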