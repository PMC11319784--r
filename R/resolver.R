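# Offsets throughout are 0-based character positions with INCLUSIVE ends:
# a span [start, end] covers end - start + 1 characters.  This mirrors the
# postprocessing rule "tentative end = next section's start - 1" literally.

span_text <- function(note, start, end) substr(note, start + 1L, end + 1L)

# Regex for a minimum-format block start: literal "Section", whitespace, an
# integer, a colon.  Keywords are case-sensitive.
BLOCK_START_RE <- "Section[ \t]+[0-9]+[ \t]*:"
BLOCK_BODY_RE <-
  "(?s)^Section[ \t]+([0-9]+)[ \t]*:(.*?)Starts at:(.*?)Ends at:(.*)$"

#' Parse raw model output into raw sections
#'
#' Every block matching the minimum format
#' `Section <integer>: <name> Starts at: <text> Ends at: <text>` becomes one
#' raw section, in emission order; non-matching text (including malformed
#' blocks) is skipped. Text pieces run until the next keyword or block and
#' are trimmed of surrounding whitespace; a block whose trimmed name, start,
#' or end text is empty does not count.
#'
#' @param raw Raw response string.
#' @return A data frame with columns `index` (integer as emitted),
#'   `name_text`, `start_text`, `end_text`; zero rows when nothing parses.
#' @examples
#' parse_output("Section 1: Allergies\nStarts at: ALLERGIES:\nEnds at: rash.")
#' @export
parse_output <- function(raw) {
  empty <- data.frame(index = integer(0), name_text = character(0),
                      start_text = character(0), end_text = character(0),
                      stringsAsFactors = FALSE)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    return(empty)
  starts <- gregexpr(BLOCK_START_RE, raw)[[1]]
  if (starts[1] == -1L) return(empty)
  begins <- as.integer(starts)
  ends <- c(begins[-1] - 1L, nchar(raw))
  rows <- lapply(seq_along(begins), function(i) {
    block <- substr(raw, begins[i], ends[i])
    m <- regmatches(block, regexec(BLOCK_BODY_RE, block, perl = TRUE))[[1]]
    if (length(m) != 5L) return(NULL)
    fields <- trimws(m[3:5])
    if (any(!nzchar(fields))) return(NULL)
    data.frame(index = as.integer(m[2]), name_text = fields[1],
               start_text = fields[2], end_text = fields[3],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and
#' substitutions (unit cost) transforming `a` into `b`, computed by dynamic
#' programming.
#'
#' @param a,b Strings.
#' @return A non-negative integer.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L,
            is.character(b), length(b) == 1L)
  cpp_levenshtein(a, b)
}

#' Length-normalized Levenshtein similarity
#'
#' `100 * (1 - levenshtein(a, b) / max(nchar(a), nchar(b)))`, ranging 0-100.
#' Two empty strings have similarity 100.
#'
#' @param a,b Strings.
#' @return A number in \[0, 100\].
#' @examples
#' similarity("Admission Date", "Admision Date")  # ~92.86
#' @export
similarity <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L,
            is.character(b), length(b) == 1L)
  mx <- max(nchar(a), nchar(b))
  if (mx == 0L) return(100)
  100 * (1 - cpp_levenshtein(a, b) / mx)
}

#' Leftmost exact occurrence of a query in a note
#'
#' @param note Note text.
#' @param query Non-empty query string.
#' @param from_pos 0-based offset; the match must start at or after it.
#' @return A list `list(start, end)` (0-based inclusive), or `NULL` when
#'   the query does not occur.
#' @export
find_exact <- function(note, query, from_pos = 0L) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  from_pos <- max(0L, as.integer(from_pos))
  if (from_pos >= nchar(note)) return(NULL)
  m <- regexpr(query, substr(note, from_pos + 1L, nchar(note)), fixed = TRUE)
  if (m[1] == -1L) return(NULL)
  start <- from_pos + as.integer(m) - 1L
  list(start = start, end = start + nchar(query) - 1L)
}

# Rightmost exact occurrence fully inside [lo, hi] (0-based inclusive).
# Scans forward one position at a time so overlapping occurrences are seen.
find_exact_rightmost <- function(note, query, lo, hi) {
  best <- NULL
  pos <- lo
  repeat {
    m <- find_exact(note, query, pos)
    if (is.null(m) || m$end > hi) break
    best <- m
    pos <- m$start + 1L
  }
  best
}

#' Best fuzzy occurrence of a query in a note
#'
#' Considers every substring starting at or after `from_pos` with length in
#' `[ceil(0.8 q), floor(1.2 q) + 1]` (`q` = query length) and returns the
#' one with maximum [similarity()] provided that maximum reaches
#' `threshold`; ties are broken by smaller start offset, then shorter
#' length. The candidate-length window is sound because a similarity of 90
#' or more bounds the length difference by 10% of the longer string.
#' Threshold comparisons are made in exact rational arithmetic so boundary
#' scores (e.g. exactly 90) are accepted.
#'
#' @param note Note text.
#' @param query Non-empty query string.
#' @param from_pos 0-based offset; candidates must start at or after it.
#' @param threshold Minimum similarity in \[0, 100\] (default 90).
#' @return A list `list(start, end, score)` or `NULL` when the best score
#'   falls below `threshold`.
#' @export
find_fuzzy <- function(note, query, from_pos = 0L, threshold = 90) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            threshold >= 0, threshold <= 100)
  res <- cpp_fuzzy_best(note, query, as.integer(from_pos), -1L,
                        threshold, FALSE)
  if (!length(res)) return(NULL)
  list(start = as.integer(res[1]), end = as.integer(res[2]), score = res[3])
}

# Rightmost qualifying fuzzy match inside [lo, hi]; ties at the same end
# offset prefer the higher similarity.
find_fuzzy_rightmost <- function(note, query, lo, hi, threshold) {
  res <- cpp_fuzzy_best(note, query, as.integer(lo), as.integer(hi),
                        threshold, TRUE)
  if (!length(res)) return(NULL)
  list(start = as.integer(res[1]), end = as.integer(res[2]), score = res[3])
}

#' Resolution options
#'
#' The two matching variants of the span-resolution algorithm and the fuzzy
#' similarity threshold.
#'
#' @param case_insensitive_names Match section names ignoring case
#'   (resolving to the canonical casing) instead of exactly.
#' @param fuzzy_spans Locate start/end texts with [find_fuzzy()] instead of
#'   exact search.
#' @param fuzzy_threshold Minimum similarity in \[0, 100\] (default 90).
#' @return An object of class `resolve_options`.
#' @export
resolve_options <- function(case_insensitive_names = FALSE,
                            fuzzy_spans = FALSE, fuzzy_threshold = 90) {
  stopifnot(is.logical(case_insensitive_names),
            is.logical(fuzzy_spans),
            fuzzy_threshold >= 0, fuzzy_threshold <= 100)
  structure(list(case_insensitive_names = isTRUE(case_insensitive_names),
                 fuzzy_spans = isTRUE(fuzzy_spans),
                 fuzzy_threshold = fuzzy_threshold),
            class = "resolve_options")
}

#' Section spans
#'
#' Constructor for the labeled-span data frame used for resolved sections,
#' gold annotations, and evaluation. Offsets are 0-based with inclusive
#' ends.
#'
#' @param label Character vector of section labels.
#' @param start,end Integer vectors of 0-based inclusive offsets.
#' @return A data frame with columns `label`, `start`, `end`.
#' @export
section_spans <- function(label = character(), start = integer(),
                          end = integer()) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(end < start))
    stop("invalid spans: need 0 <= start <= end", call. = FALSE)
  data.frame(label = as.character(label), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Resolve raw sections to labeled character spans
#'
#' The span-resolution postprocessing algorithm, in order:
#' 1. Drop raw sections whose name does not equal a schema name (exactly,
#'    or ignoring case when `opts$case_insensitive_names`, in which case
#'    the canonical casing is assigned).
#' 2. Drop raw sections whose start text has no match in the note (exact
#'    search, or fuzzy when `opts$fuzzy_spans`).
#' 3. Locate each survivor's start offset, processing raws in emission
#'    order with a moving cursor: search from the cursor, retry from the
#'    beginning of the note on failure, and advance the cursor past each
#'    located start.
#' 4. Sort survivors by start offset; among sections sharing an identical
#'    start offset only the first is kept.
#' 5. Set each tentative end to the next section's start minus one; the
#'    last section's tentative end is the last character of the note.
#' 6. Search for the end text within `[start, tentative end]`; when found,
#'    the section's end becomes the final character offset of the rightmost
#'    qualifying match, otherwise the tentative end stands. A section whose
#'    span would be empty is dropped.
#'
#' A section therefore survives with a reasonable span even when its end
#' text was generated incorrectly, as long as its name and start text are
#' valid.
#'
#' @param note Note text.
#' @param raws Data frame from [parse_output()].
#' @param schema A [section_schema()].
#' @param opts A [resolve_options()].
#' @return A [section_spans()] data frame sorted by `start`, with an
#'   attribute `"log"` holding per-step counts: `n_raw`, `dropped_name`,
#'   `dropped_start`, `dropped_duplicate`, `dropped_empty`, `end_matched`,
#'   `n_resolved`.
#' @export
resolve_sections <- function(note, raws, schema,
                             opts = resolve_options()) {
  stopifnot(inherits(schema, "section_schema"),
            inherits(opts, "resolve_options"),
            is.character(note), length(note) == 1L)
  log <- list(n_raw = nrow(raws), dropped_name = 0L, dropped_start = 0L,
              dropped_duplicate = 0L, dropped_empty = 0L, end_matched = 0L,
              n_resolved = 0L)
  finish <- function(df) {
    log$n_resolved <- nrow(df)
    attr(df, "log") <- log
    df
  }
  empty <- section_spans()
  if (is.na(note) || !nzchar(note) || nrow(raws) == 0L) {
    log$dropped_name <- 0L
    return(finish(empty))
  }
  nms <- schema_names(schema)

  # step 1: valid section names
  if (opts$case_insensitive_names) {
    hit <- match(tolower(raws$name_text), tolower(nms))
  } else {
    hit <- match(raws$name_text, nms)
  }
  log$dropped_name <- sum(is.na(hit))
  raws <- raws[!is.na(hit), , drop = FALSE]
  labels <- nms[hit[!is.na(hit)]]  # canonical casing

  # steps 2-3: locate start texts with a moving cursor, emission order
  locate <- function(query, from) {
    if (opts$fuzzy_spans) find_fuzzy(note, query, from, opts$fuzzy_threshold)
    else find_exact(note, query, from)
  }
  starts <- rep(NA_integer_, nrow(raws))
  cursor <- 0L
  for (i in seq_len(nrow(raws))) {
    m <- locate(raws$start_text[i], cursor)
    if (is.null(m)) m <- locate(raws$start_text[i], 0L)
    if (is.null(m)) next
    starts[i] <- m$start
    cursor <- m$start + 1L
  }
  log$dropped_start <- sum(is.na(starts))
  keep <- !is.na(starts)
  raws <- raws[keep, , drop = FALSE]
  labels <- labels[keep]
  starts <- starts[keep]
  if (!length(starts)) return(finish(empty))

  # step 4: sort by start offset; drop later duplicates of an identical one
  ord <- order(starts, seq_along(starts))
  raws <- raws[ord, , drop = FALSE]
  labels <- labels[ord]
  starts <- starts[ord]
  dup <- duplicated(starts)
  log$dropped_duplicate <- sum(dup)
  raws <- raws[!dup, , drop = FALSE]
  labels <- labels[!dup]
  starts <- starts[!dup]

  # step 5: tentative ends
  n_note <- nchar(note)
  tentative <- c(starts[-1] - 1L, n_note - 1L)

  # step 6: end texts inside [start, tentative end]
  ends <- tentative
  for (i in seq_along(starts)) {
    if (tentative[i] < starts[i]) next
    m <- if (opts$fuzzy_spans) {
      find_fuzzy_rightmost(note, raws$end_text[i], starts[i], tentative[i],
                           opts$fuzzy_threshold)
    } else {
      find_exact_rightmost(note, raws$end_text[i], starts[i], tentative[i])
    }
    if (!is.null(m)) {
      ends[i] <- m$end
      log$end_matched <- log$end_matched + 1L
    }
  }
  nonempty <- ends >= starts
  log$dropped_empty <- sum(!nonempty)
  finish(section_spans(labels[nonempty], starts[nonempty], ends[nonempty]))
}
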