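# JSONL helpers.  One JSON object per line; section files open with a
# header record stating the offset convention (0-based, inclusive ends).

OFFSET_CONVENTION <- "0-based character offsets, inclusive end"

#' Read a JSONL file
#'
#' @param path File path.
#' @return A list of records (each parsed without vector simplification).
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}

#' Write a JSONL file
#'
#' @param records List of records; each is serialized onto one line.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write labeled section spans as JSONL
#'
#' Emits a header record naming the offset convention, then one
#' `{note_id, sections: [{label, start, end}, ...]}` record per note.
#'
#' @param sections Named list of [section_spans()] data frames, keyed by
#'   note id.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sections_jsonl <- function(sections, path) {
  header <- list(type = "header", offset_convention = OFFSET_CONVENTION)
  records <- lapply(names(sections), function(id) {
    df <- sections[[id]]
    list(note_id = id,
         sections = lapply(seq_len(nrow(df)), function(i)
           list(label = df$label[i], start = df$start[i], end = df$end[i])))
  })
  write_jsonl(c(list(header), records), path)
}

#' Read labeled section spans from JSONL
#'
#' Inverse of [write_sections_jsonl()]; the header record is skipped.
#'
#' @param path File path.
#' @return Named list of [section_spans()] data frames, keyed by note id.
#' @export
read_sections_jsonl <- function(path) {
  records <- read_jsonl(path)
  records <- Filter(function(r) !identical(r$type, "header"), records)
  out <- lapply(records, function(r) {
    secs <- r$sections
    if (!length(secs)) return(section_spans())
    section_spans(vapply(secs, `[[`, character(1), "label"),
                  vapply(secs, function(s) as.integer(s$start), integer(1)),
                  vapply(secs, function(s) as.integer(s$end), integer(1)))
  })
  names(out) <- vapply(records, `[[`, character(1), "note_id")
  out
}

write_generation_log <- function(records, path) {
  write_jsonl(lapply(names(records), function(id) {
    r <- records[[id]]
    list(note_id = id, fingerprint = r$fingerprint,
         n_attempts = length(r$attempts),
         n_retries_used = r$n_retries_used,
         accepted = !is.null(r$accepted))
  }), path)
}
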