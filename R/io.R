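# Readers/writers for time-aligned annotations. Two dialects:
#  * canonical TSV: header `speaker level label start end`, UTF-8, times in
#    seconds with >= 3 decimals; the package's interchange format.
#  * Praat TextGrid (interval tiers, long or short text form), tier names
#    mapped to levels via `tier_map`.

#' Read a time-aligned annotation file
#'
#' @param path file path
#' @param dialect `"tsv"` (canonical dialect, see Details) or `"textgrid"`.
#' @param pause_threshold passed to [corpus_hierarchy()] when breath groups
#'   must be derived from pauses.
#' @param tier_map named character vector mapping levels to tier names for
#'   TextGrid input, e.g. `c(phoneme = "MAU", word = "ORT")`. Matching is
#'   case-insensitive. Default expects tiers named like the levels.
#' @param speaker speaker identifier for TextGrid input (one speaker per
#'   file); defaults to the file name without extension.
#' @param tol containment tolerance in seconds.
#'
#' @details The canonical TSV dialect has a header line
#' `speaker	level	label	start	end` with `level` one of `phoneme`,
#' `word`, `breath_group` and times in seconds. Silence rows (empty label or
#' a marker such as `sil`) may be present; they are dropped from token lists
#' but their gaps still drive breath-group segmentation.
#'
#' @return a `corpus_hierarchy`
#' @export
read_alignment <- function(path, dialect = c("tsv", "textgrid"),
                           pause_threshold = 0.1, tier_map = NULL,
                           speaker = NULL, tol = 1e-3) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tokens <- switch(dialect,
    tsv = .read_tsv_tokens(path),
    textgrid = .read_textgrid_tokens(path, tier_map = tier_map,
                                     speaker = speaker)
  )
  if (nrow(tokens) == 0L) stop("no tokens in ", path)
  if (!any(tokens$level == "phoneme") && !any(tokens$level == "word"))
    stop("no phoneme or word tier found in ", path)
  corpus_hierarchy(tokens, pause_threshold = pause_threshold, tol = tol)
}

.read_tsv_tokens <- function(path) {
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), "\t")[[1L]]
  req <- c("speaker", "level", "label", "start", "end")
  if (!all(req %in% header))
    stop("TSV parse error in ", path, ": header must contain ",
         paste(req, collapse = ", "), " (line 1)")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8", na.strings = NULL)
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("TSV parse error in %s: non-numeric '%s' at data line %d",
                   path, col, bad))
    }
    df[[col]] <- v
  }
  df[, req, drop = FALSE]
}

#' Write a hierarchy to the canonical TSV dialect
#'
#' All three levels are written; re-reading with [read_alignment()] restores
#' an identical hierarchy (times serialized with 6 decimals).
#'
#' @param h a `corpus_hierarchy`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_alignment <- function(h, path) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  tk <- h$tokens
  out <- data.frame(
    speaker = tk$speaker, level = tk$level, label = tk$label,
    start = sprintf("%.6f", tk$start), end = sprintf("%.6f", tk$end),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

# -- TextGrid ----------------------------------------------------------------

.read_textgrid_tokens <- function(path, tier_map = NULL, speaker = NULL) {
  if (is.null(speaker))
    speaker <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(tier_map))
    tier_map <- c(phoneme = "phoneme", word = "word",
                  breath_group = "breath_group")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 3L || !grepl("ooTextFile", lines[1L]))
    stop("TextGrid parse error in ", path, ": missing ooTextFile header (line 1)")
  long <- any(grepl("item\\s*\\[", lines))
  tiers <- if (long) .parse_textgrid_long(lines, path)
           else .parse_textgrid_short(lines, path)
  rows <- list()
  for (lv in names(tier_map)) {
    hit <- which(tolower(names(tiers)) == tolower(tier_map[[lv]]))
    if (length(hit) == 0L) next
    iv <- tiers[[hit[1L]]]
    if (nrow(iv) == 0L) next
    rows[[lv]] <- data.frame(speaker = speaker, level = lv, label = iv$text,
                             start = iv$xmin, end = iv$xmax,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("TextGrid parse error in ", path, ": no tier matches tier_map (",
         paste(tier_map, collapse = ", "), "); tiers present: ",
         paste(names(tiers), collapse = ", "))
  do.call(rbind, rows)
}

.tg_num <- function(line) as.numeric(sub(".*=\\s*", "", line))
.tg_str <- function(line) {
  m <- regmatches(line, regexpr('"[^"]*"', line))
  if (length(m) == 0L) "" else substr(m, 2L, nchar(m) - 1L)
}

.parse_textgrid_long <- function(lines, path) {
  tiers <- list()
  i <- 1L; n <- length(lines)
  while (i <= n && !grepl("^\\s*item\\s*\\[\\s*[0-9]+\\s*\\]", lines[i]))
    i <- i + 1L
  while (i <= n) {
    # at an `item [k]:` line
    j <- i + 1L
    cls <- NA_character_; name <- NA_character_
    iv <- list()
    while (j <= n && !grepl("^\\s*item\\s*\\[\\s*[0-9]+\\s*\\]", lines[j])) {
      ln <- lines[j]
      if (grepl("^\\s*class\\s*=", ln)) cls <- .tg_str(ln)
      if (grepl("^\\s*name\\s*=", ln)) name <- .tg_str(ln)
      if (grepl("^\\s*intervals\\s*\\[", ln)) {
        xmin <- xmax <- NA_real_; text <- ""
        k <- j + 1L
        while (k <= n && !grepl("^\\s*(intervals|item)\\s*\\[", lines[k])) {
          if (grepl("^\\s*xmin\\s*=", lines[k])) xmin <- .tg_num(lines[k])
          if (grepl("^\\s*xmax\\s*=", lines[k])) xmax <- .tg_num(lines[k])
          if (grepl("^\\s*text\\s*=", lines[k])) text <- .tg_str(lines[k])
          k <- k + 1L
        }
        if (is.na(xmin) || is.na(xmax))
          stop(sprintf("TextGrid parse error in %s: interval without xmin/xmax near line %d (tier '%s')",
                       path, j, name))
        iv[[length(iv) + 1L]] <- data.frame(xmin = xmin, xmax = xmax,
                                            text = text,
                                            stringsAsFactors = FALSE)
        j <- k - 1L
      }
      j <- j + 1L
    }
    if (!is.na(cls) && grepl("IntervalTier", cls)) {
      tiers[[if (is.na(name)) sprintf("tier%d", length(tiers) + 1L) else name]] <-
        if (length(iv)) do.call(rbind, iv)
        else data.frame(xmin = numeric(0), xmax = numeric(0),
                        text = character(0), stringsAsFactors = FALSE)
    }
    i <- j
  }
  if (length(tiers) == 0L)
    stop("TextGrid parse error in ", path, ": no IntervalTier found")
  tiers
}

.parse_textgrid_short <- function(lines, path) {
  # short form: bare values in fixed order
  vals <- lines[-(1:2)]
  vals <- vals[nzchar(trimws(vals))]
  p <- 3L  # skip global xmin, xmax; vals[3] is tiers? flag "<exists>"
  if (!grepl("exists", vals[p]))
    stop("TextGrid parse error in ", path, ": short form without tiers flag")
  ntier <- as.integer(vals[p + 1L]); p <- p + 2L
  tiers <- list()
  for (ti in seq_len(ntier)) {
    cls <- .tg_str(vals[p]); name <- .tg_str(vals[p + 1L])
    p <- p + 4L  # class, name, tier xmin, tier xmax
    nint <- as.integer(vals[p]); p <- p + 1L
    if (is.na(nint))
      stop(sprintf("TextGrid parse error in %s: bad interval count in tier '%s'",
                   path, name))
    iv <- data.frame(xmin = numeric(nint), xmax = numeric(nint),
                     text = character(nint), stringsAsFactors = FALSE)
    for (k in seq_len(nint)) {
      iv$xmin[k] <- as.numeric(vals[p])
      iv$xmax[k] <- as.numeric(vals[p + 1L])
      iv$text[k] <- .tg_str(vals[p + 2L])
      p <- p + 3L
    }
    if (grepl("IntervalTier", cls)) tiers[[name]] <- iv
  }
  tiers
}

#' Write a hierarchy as a Praat TextGrid (long form)
#'
#' One interval tier per level present, named after the level. Gaps between
#' tokens are filled with empty-label intervals so tiers tile the time axis,
#' as Praat expects. Intended for single-speaker hierarchies; multi-speaker
#' hierarchies are refused (write one file per speaker).
#'
#' @param h a `corpus_hierarchy`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_textgrid <- function(h, path) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  tk <- h$tokens
  if (length(unique(tk$speaker)) != 1L)
    stop("write_textgrid handles a single speaker per file")
  xmin <- min(tk$start); xmax <- max(tk$end)
  lvs <- intersect(.levels, unique(tk$level))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w('')
  w('xmin = %.6f', xmin)
  w('xmax = %.6f', xmax)
  w('tiers? <exists>')
  w('size = %d', length(lvs))
  w('item []:')
  for (ti in seq_along(lvs)) {
    s <- tk[tk$level == lvs[ti], , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # tile with silence fillers
    iv <- list(); cur <- xmin
    for (r in seq_len(nrow(s))) {
      if (s$start[r] > cur + 1e-9)
        iv[[length(iv) + 1L]] <- c(cur, s$start[r], "")
      iv[[length(iv) + 1L]] <- c(s$start[r], s$end[r], s$label[r])
      cur <- s$end[r]
    }
    if (cur < xmax - 1e-9) iv[[length(iv) + 1L]] <- c(cur, xmax, "")
    w('    item [%d]:', ti)
    w('        class = "IntervalTier"')
    w('        name = "%s"', lvs[ti])
    w('        xmin = %.6f', xmin)
    w('        xmax = %.6f', xmax)
    w('        intervals: size = %d', length(iv))
    for (k in seq_along(iv)) {
      w('        intervals [%d]:', k)
      w('            xmin = %s', iv[[k]][1L])
      w('            xmax = %s', iv[[k]][2L])
      w('            text = "%s"', iv[[k]][3L])
    }
  }
  invisible(path)
}
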