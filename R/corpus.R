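# Three-level corpus container: phonemes nested in words nested in breath
# groups. Tokens live in a single data.frame; nesting is carried by integer
# parent links (phoneme -> word id, word -> breath-group id).

#' Levels of the speech hierarchy
#' @keywords internal
.levels <- c("phoneme", "word", "breath_group")

# Labels treated as silence/pause markers: excluded from token lists but the
# gaps they leave drive breath-group segmentation.
.silence_labels <- c("", "sil", "sp", "pau", "pause", "#", "_", "<sil>", "<p>")

#' Construct a corpus hierarchy from a token table
#'
#' Builds the three-level containment structure (phonemes within words within
#' breath groups) from a flat table of time-aligned tokens. Phonemes are
#' attributed to words (and words to breath groups) by interval inclusion with
#' a small tolerance absorbing aligner rounding. If the table carries no
#' `breath_group` rows, breath groups are derived by pause segmentation via
#' [segment_breath_groups()].
#'
#' @param tokens data.frame with columns `speaker`, `level` (one of
#'   `"phoneme"`, `"word"`, `"breath_group"`), `label`, `start`, `end`
#'   (seconds). Silence/pause rows (empty label or a conventional marker such
#'   as `"sil"`) are dropped from the token lists; the temporal gaps they
#'   leave still separate breath groups.
#' @param pause_threshold minimum silent gap, in seconds, that starts a new
#'   breath group when breath groups have to be derived. Default 0.1 s.
#' @param tol containment tolerance in seconds (default 1 ms).
#' @return An object of class `corpus_hierarchy`: a list with element
#'   `tokens`, a data.frame with columns `id`, `speaker`, `level`, `label`,
#'   `start`, `end`, `t` (duration, `end - start`) and `parent` (id of the
#'   containing unit, `NA` for breath groups).
#' @export
corpus_hierarchy <- function(tokens, pause_threshold = 0.1, tol = 1e-3) {
  req <- c("speaker", "level", "label", "start", "end")
  miss <- setdiff(req, names(tokens))
  if (length(miss) > 0L)
    stop("token table lacks column(s): ", paste(miss, collapse = ", "))
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  tokens$speaker <- as.character(tokens$speaker)
  tokens$level <- as.character(tokens$level)
  tokens$label <- as.character(tokens$label)
  tokens$start <- as.numeric(tokens$start)
  tokens$end <- as.numeric(tokens$end)

  bad_level <- setdiff(unique(tokens$level), .levels)
  if (length(bad_level) > 0L)
    stop("unknown level(s): ", paste(bad_level, collapse = ", "))

  is_sil <- is.na(tokens$label) |
    tolower(trimws(tokens$label)) %in% .silence_labels
  is_sil <- is_sil & tokens$level != "breath_group"
  tokens <- tokens[!is_sil, , drop = FALSE]
  if (nrow(tokens) == 0L)
    stop("no non-silence tokens in input")
  if (any(!is.finite(tokens$start)) || any(!is.finite(tokens$end)))
    stop("non-finite start/end times")
  if (any(tokens$end < tokens$start - tol))
    stop("token(s) with end < start")
  if (any(tokens$label == "" & tokens$level != "breath_group"))
    stop("empty label on phoneme/word token")

  # order within speaker by start time, phonemes after their word
  ord <- order(tokens$speaker, tokens$start, match(tokens$level, rev(.levels)))
  tokens <- tokens[ord, , drop = FALSE]
  .check_overlap(tokens, tol)

  tokens$id <- seq_len(nrow(tokens))
  tokens$t <- tokens$end - tokens$start
  tokens$parent <- NA_integer_

  h <- structure(list(tokens = tokens), class = "corpus_hierarchy")
  if (!any(tokens$level == "breath_group")) {
    if (!any(tokens$level == "word")) {
      # phoneme-only (or word-only) corpora are allowed: nothing to nest
      return(h)
    }
    h <- segment_breath_groups(h, pause_threshold = pause_threshold, tol = tol)
  } else {
    h$tokens$parent[h$tokens$level == "word"] <-
      .assign_parents(h, "word", "breath_group", tol)
  }
  if (any(h$tokens$level == "phoneme") && any(h$tokens$level == "word"))
    h$tokens$parent[h$tokens$level == "phoneme"] <-
      .assign_parents(h, "phoneme", "word", tol)
  h
}

# same-tier overlap check (per speaker & level)
.check_overlap <- function(tokens, tol) {
  for (lv in unique(tokens$level)) {
    sub <- tokens[tokens$level == lv, , drop = FALSE]
    for (sp in unique(sub$speaker)) {
      s <- sub[sub$speaker == sp, , drop = FALSE]
      if (nrow(s) < 2L) next
      gap <- s$start[-1L] - s$end[-nrow(s)]
      if (any(gap < -tol))
        stop(sprintf(
          "overlapping %s intervals for speaker '%s' near t=%.3f s",
          lv, sp, s$start[which(gap < -tol)[1L] + 1L]))
    }
  }
  invisible(NULL)
}

# attribute each child interval to the unique parent interval containing it
.assign_parents <- function(h, child_level, parent_level, tol) {
  tk <- h$tokens
  ch <- tk[tk$level == child_level, , drop = FALSE]
  pa <- tk[tk$level == parent_level, , drop = FALSE]
  out <- rep(NA_integer_, nrow(ch))
  for (sp in unique(ch$speaker)) {
    ci <- which(ch$speaker == sp)
    p <- pa[pa$speaker == sp, , drop = FALSE]
    if (nrow(p) == 0L) next
    p <- p[order(p$start), , drop = FALSE]
    # candidate parent: last parent starting at or before child start (+tol)
    idx <- findInterval(ch$start[ci] + tol, p$start)
    ok <- idx >= 1L &
      ch$start[ci] >= p$start[pmax(idx, 1L)] - tol &
      ch$end[ci] <= p$end[pmax(idx, 1L)] + tol
    out[ci[ok]] <- p$id[idx[ok]]
  }
  if (anyNA(out)) {
    orphans <- ch[is.na(out), , drop = FALSE]
    stop(sprintf(
      "%d %s token(s) not contained in any %s interval; first orphan: '%s' [%.3f, %.3f] speaker '%s'",
      nrow(orphans), child_level, parent_level,
      orphans$label[1L], orphans$start[1L], orphans$end[1L],
      orphans$speaker[1L]))
  }
  out
}

#' Extract tokens at one level
#'
#' @param h a `corpus_hierarchy`
#' @param level `"phoneme"`, `"word"` or `"breath_group"`
#' @return data.frame of tokens at that level, ordered by speaker and time.
#' @export
tokens_at <- function(h, level = c("word", "phoneme", "breath_group")) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  level <- match.arg(level)
  h$tokens[h$tokens$level == level, , drop = FALSE]
}

#' Normalized type key of a label
#'
#' Case-folded exact match; no lemmatization.
#' @keywords internal
.type_key <- function(label) tolower(trimws(label))

#' Summarize a corpus hierarchy
#'
#' Token counts, type counts (types keyed by case-folded label) and median
#' durations per level. Median rather than mean, since unit duration
#' distributions are heavy tailed.
#'
#' @param object a `corpus_hierarchy`
#' @param ... unused
#' @return data.frame of class `corpus_summary` with one row per level
#'   present: `level`, `n_tokens`, `n_types`, `median_duration`. Breath
#'   groups are unlabeled so their type count is `NA`.
#' @export
summary.corpus_hierarchy <- function(object, ...) {
  tk <- object$tokens
  if (nrow(tk) == 0L) stop("empty hierarchy")
  lv <- intersect(.levels, unique(tk$level))
  out <- do.call(rbind, lapply(lv, function(l) {
    s <- tk[tk$level == l, , drop = FALSE]
    data.frame(
      level = l,
      n_tokens = nrow(s),
      n_types = if (l == "breath_group") NA_integer_
                else length(unique(.type_key(s$label))),
      median_duration = stats::median(s$t),
      stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("corpus_summary", "data.frame")
  out
}

#' @export
print.corpus_hierarchy <- function(x, ...) {
  tk <- x$tokens
  cat("<corpus_hierarchy>\n")
  for (l in intersect(.levels, unique(tk$level))) {
    n <- sum(tk$level == l)
    cat(sprintf("  %-13s %6d tokens\n", l, n))
  }
  cat(sprintf("  speakers: %d\n", length(unique(tk$speaker))))
  invisible(x)
}

#' Validate the containment partition of a hierarchy
#'
#' Checks that every phoneme has exactly one word parent, every word exactly
#' one breath-group parent, and that child intervals lie within their parents.
#'
#' @param h a `corpus_hierarchy`
#' @param tol tolerance in seconds
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_hierarchy <- function(h, tol = 1e-3) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  tk <- h$tokens
  for (pair in list(c("phoneme", "word"), c("word", "breath_group"))) {
    ch <- tk[tk$level == pair[1L], , drop = FALSE]
    pa <- tk[tk$level == pair[2L], , drop = FALSE]
    if (nrow(ch) == 0L || nrow(pa) == 0L) next
    if (anyNA(ch$parent))
      stop(sprintf("%s token(s) without %s parent", pair[1L], pair[2L]))
    if (!all(ch$parent %in% pa$id))
      stop(sprintf("dangling %s parent id(s)", pair[1L]))
    p <- pa[match(ch$parent, pa$id), ]
    if (any(ch$start < p$start - tol) || any(ch$end > p$end + tol))
      stop(sprintf("%s interval(s) outside parent %s", pair[1L], pair[2L]))
  }
  invisible(TRUE)
}
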