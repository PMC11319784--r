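# Word bank for filler bodies: seeded pseudo-clinical word salad.  No PHI,
# no real note templates; what matters for testing is the structure
# (headings + bodies + spans that tile the note), not linguistic realism.
BODY_WORDS <- c(
  "patient", "stable", "denies", "reports", "mild", "moderate", "severe",
  "chronic", "acute", "bilateral", "daily", "oral", "dose", "improved",
  "afebrile", "tolerating", "ambulating", "continued", "monitor", "fluids",
  "pain", "nausea", "dizziness", "breathing", "appetite", "alert",
  "oriented", "examination", "unremarkable", "within", "normal", "limits",
  "followup", "scheduled", "clinic", "discussed", "reviewed", "started",
  "discontinued", "increased", "decreased", "tablet", "twice", "night",
  "morning", "symptoms", "resolved", "persistent", "intermittent", "without",
  "complication", "recommended", "advised", "rest", "hydration", "diet",
  "regular", "activity", "tolerated", "well")

#' Synthetic note recipe
#'
#' Parameters of the synthetic sectioned-note generator. The defaults
#' emulate mid-length discharge summaries: 4-8 sections per note with
#' filler bodies of 80-240 characters.
#'
#' @param n_sections Integer range `c(min, max)` of sections per note.
#' @param body_chars Integer range `c(min, max)` of filler-body length in
#'   characters.
#' @return An object of class `note_recipe`.
#' @export
note_recipe <- function(n_sections = c(4L, 8L), body_chars = c(80L, 240L)) {
  n_sections <- as.integer(n_sections)
  body_chars <- as.integer(body_chars)
  stopifnot(length(n_sections) == 2L, n_sections[1] >= 1L,
            n_sections[1] <= n_sections[2],
            length(body_chars) == 2L, body_chars[1] >= 10L,
            body_chars[1] <= body_chars[2])
  structure(list(n_sections = n_sections, body_chars = body_chars),
            class = "note_recipe")
}

#' Error-injection configuration
#'
#' Probabilities of the simulated response corruptions, modelling the
#' failure modes of real model output: invalid section names, wrong casing,
#' typos in the copied start/end anchor texts, dropped sections, shuffled
#' block order, and blocks violating the minimum output format. All
#' probabilities default to 0 (a faithful response).
#'
#' @param p_invalid_name Probability a block's name is replaced by a
#'   non-schema string.
#' @param p_case_flip Probability a (valid) name has its case flipped.
#' @param p_typo_start,p_typo_end Probability the start/end anchor text is
#'   corrupted by `typo_edits` random single-character edits.
#' @param typo_edits Number of edits per corrupted anchor (>= 1).
#' @param p_drop_section Probability a gold section is omitted entirely.
#' @param p_reorder Probability the emitted blocks are shuffled.
#' @param p_malformed_block Probability a block is rewritten to violate the
#'   minimum format.
#' @return An object of class `error_config`.
#' @export
error_config <- function(p_invalid_name = 0, p_case_flip = 0,
                         p_typo_start = 0, p_typo_end = 0, typo_edits = 1L,
                         p_drop_section = 0, p_reorder = 0,
                         p_malformed_block = 0) {
  probs <- c(p_invalid_name = p_invalid_name, p_case_flip = p_case_flip,
             p_typo_start = p_typo_start, p_typo_end = p_typo_end,
             p_drop_section = p_drop_section, p_reorder = p_reorder,
             p_malformed_block = p_malformed_block)
  if (any(probs < 0 | probs > 1))
    stop("all error probabilities must lie in [0, 1]", call. = FALSE)
  typo_edits <- as.integer(typo_edits)
  stopifnot(typo_edits >= 1L)
  structure(c(as.list(probs), list(typo_edits = typo_edits)),
            class = "error_config")
}

# sample() treats a length-1 vector as 1:n; guard degenerate ranges
sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
}

make_body <- function(target_len) {
  words <- character(0)
  len <- 0L
  while (len < target_len) {
    w <- BODY_WORDS[sample.int(length(BODY_WORDS), 1L)]
    words <- c(words, w)
    len <- len + nchar(w) + 1L
  }
  body <- substr(paste(words, collapse = " "), 1L, target_len)
  trimws(body, which = "right")
}

#' Generate one synthetic sectioned note with gold spans
#'
#' Samples section types (those with example headings) from the schema and
#' concatenates sections, each a heading line (one of the type's example
#' headings, original case, followed by a colon) plus a filler body ending
#' in a period. Sections tile the note exactly — each gold span ends
#' immediately before the next begins — with no whitespace at section
#' boundaries, so copied anchor texts survive the whitespace-trimming of
#' response parsing. Uses the current RNG state; seed with `set.seed()`
#' for reproducibility.
#'
#' @param schema A [section_schema()].
#' @param recipe A [note_recipe()].
#' @return A list with `text` (the note) and `gold` (a [section_spans()]
#'   data frame covering the note, sorted, non-overlapping).
#' @export
generate_note <- function(schema, recipe = note_recipe()) {
  stopifnot(inherits(schema, "section_schema"),
            inherits(recipe, "note_recipe"))
  eligible <- Filter(function(t) length(t$example_headings) > 0L,
                     schema$types)
  n <- sample_range(recipe$n_sections)
  if (length(eligible) < n)
    stop("schema has only ", length(eligible),
         " types with example headings; recipe needs up to ", n,
         call. = FALSE)
  picked <- eligible[sample.int(length(eligible), n)]
  texts <- vapply(picked, function(t) {
    heading <- t$example_headings[sample.int(length(t$example_headings), 1L)]
    body_len <- sample_range(recipe$body_chars)
    paste0(heading, ":\n", make_body(body_len), ".")
  }, character(1))
  lens <- nchar(texts)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  gold <- section_spans(vapply(picked, `[[`, character(1), "name"),
                        starts, starts + lens - 1L)
  list(text = paste(texts, collapse = ""), gold = gold)
}

flip_case <- function(x) {
  flipped <- toupper(x)
  if (identical(flipped, x)) flipped <- tolower(x)
  flipped
}

inject_typos <- function(x, n_edits) {
  for (k in seq_len(n_edits)) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    n <- length(chars)
    op <- sample(c("sub", "ins", "del"), 1L)
    if (n <= 1L && op == "del") op <- "sub"
    letter <- letters[sample.int(26L, 1L)]
    pos <- sample.int(n, 1L)
    chars <- switch(op,
      sub = { chars[pos] <- letter; chars },
      ins = append(chars, letter, after = pos),
      del = chars[-pos])
    x <- paste(chars, collapse = "")
  }
  x
}

#' Simulate a model response for a note
#'
#' Emits one block per gold section in the required output format
#' (`Section <i>: <name> / Starts at: <anchor> / Ends at: <anchor>`), the
#' anchors being the first and last `anchor_chars` characters of the
#' section (truncated at the section boundary), with corruptions injected
#' per the [error_config()]. With an all-zero config the response resolves
#' back to the gold spans exactly under all-exact resolution options. Uses
#' the current RNG state.
#'
#' @param note_text Note text the gold spans index into.
#' @param gold A [section_spans()] data frame.
#' @param schema A [section_schema()] (source of valid names; invalid-name
#'   corruptions are guaranteed to fall outside it).
#' @param err An [error_config()].
#' @param anchor_chars Length of the copied start/end anchor texts
#'   (default 30; with at most one or two edits this keeps similarity above
#'   the fuzzy threshold of 90).
#' @return The raw response string, with attribute `"tally"`: named integer
#'   counts of each injected corruption.
#' @export
simulate_response <- function(note_text, gold, schema,
                              err = error_config(), anchor_chars = 30L) {
  stopifnot(inherits(err, "error_config"), nrow(gold) >= 1L)
  tally <- c(invalid_name = 0L, case_flip = 0L, typo_start = 0L,
             typo_end = 0L, dropped = 0L, reordered = 0L, malformed = 0L)
  blocks <- character(0)
  for (i in seq_len(nrow(gold))) {
    if (runif(1) < err$p_drop_section) {
      tally[["dropped"]] <- tally[["dropped"]] + 1L
      next
    }
    name <- gold$label[i]
    if (runif(1) < err$p_invalid_name) {
      name <- paste0("Invented section ", i)
      tally[["invalid_name"]] <- tally[["invalid_name"]] + 1L
    } else if (runif(1) < err$p_case_flip) {
      name <- flip_case(name)
      tally[["case_flip"]] <- tally[["case_flip"]] + 1L
    }
    sect <- span_text(note_text, gold$start[i], gold$end[i])
    k <- min(anchor_chars, nchar(sect))
    start_anchor <- substr(sect, 1L, k)
    end_anchor <- substr(sect, nchar(sect) - k + 1L, nchar(sect))
    if (runif(1) < err$p_typo_start) {
      start_anchor <- inject_typos(start_anchor, err$typo_edits)
      tally[["typo_start"]] <- tally[["typo_start"]] + 1L
    }
    if (runif(1) < err$p_typo_end) {
      end_anchor <- inject_typos(end_anchor, err$typo_edits)
      tally[["typo_end"]] <- tally[["typo_end"]] + 1L
    }
    block <- sprintf("Section %d: %s\nStarts at: %s\nEnds at: %s",
                     i, name, start_anchor, end_anchor)
    if (runif(1) < err$p_malformed_block) {
      block <- sprintf("Section %d: %s\nBegins near: %s", i, name,
                       start_anchor)
      tally[["malformed"]] <- tally[["malformed"]] + 1L
    }
    blocks <- c(blocks, block)
  }
  if (length(blocks) > 1L && runif(1) < err$p_reorder) {
    blocks <- blocks[sample.int(length(blocks))]
    tally[["reordered"]] <- tally[["reordered"]] + 1L
  }
  structure(paste(blocks, collapse = "\n"), tally = tally)
}

note_seed <- function(seed, i) {
  ((as.double(seed) %% 59999) * 35317 + i * 7 + 13) %% 2147483647
}

#' Generate a synthetic corpus with simulated responses
#'
#' Produces `n_notes` aligned (note, gold, response) triples plus a
#' manifest recording the seed, the configs, and the total injected-error
#' tallies. Each note draws from an RNG stream derived from `(seed, note
#' index)`, so corpora are reproducible per note and in full.
#'
#' @param schema A [section_schema()].
#' @param recipe A [note_recipe()].
#' @param err An [error_config()].
#' @param n_notes Number of notes (>= 1).
#' @param seed Integer seed.
#' @param anchor_chars Anchor length passed to [simulate_response()].
#' @return A `note_corpus`: list with `notes` (data frame `id`, `text`),
#'   `gold` (named list of [section_spans()]), `responses` (named character
#'   vector of raw responses), and `manifest`.
#' @seealso [write_corpus()], [read_corpus()] for the on-disk bundle.
#' @export
generate_corpus <- function(schema, recipe = note_recipe(),
                            err = error_config(), n_notes, seed,
                            anchor_chars = 30L) {
  stopifnot(n_notes >= 1L)
  ids <- sprintf("note-%03d", seq_len(n_notes))
  texts <- character(n_notes)
  gold <- vector("list", n_notes)
  responses <- character(n_notes)
  tally <- NULL
  for (i in seq_len(n_notes)) {
    set.seed(note_seed(seed, i))
    ng <- generate_note(schema, recipe)
    resp <- simulate_response(ng$text, ng$gold, schema, err, anchor_chars)
    texts[i] <- ng$text
    gold[[i]] <- ng$gold
    responses[i] <- as.character(resp)
    t <- attr(resp, "tally")
    tally <- if (is.null(tally)) t else tally + t
  }
  names(gold) <- ids
  names(responses) <- ids
  structure(list(
    notes = data.frame(id = ids, text = texts, stringsAsFactors = FALSE),
    gold = gold,
    responses = responses,
    manifest = list(seed = seed, n_notes = n_notes,
                    recipe = unclass(recipe), errors = unclass(err),
                    anchor_chars = anchor_chars,
                    error_tally = as.list(tally))),
    class = "note_corpus")
}

#' Write a corpus bundle to a directory
#'
#' Writes `notes.jsonl` (`{id, text}` records), `gold.jsonl` (offset-
#' convention header plus `{note_id, sections}` records), `responses.jsonl`
#' (`{id, response}` records, the mock-backend script format), and
#' `manifest.json`.
#'
#' @param corpus A `note_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "note_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_jsonl(lapply(seq_len(nrow(corpus$notes)), function(i)
    list(id = corpus$notes$id[i], text = corpus$notes$text[i])),
    file.path(dir, "notes.jsonl"))
  write_sections_jsonl(corpus$gold, file.path(dir, "gold.jsonl"))
  write_jsonl(lapply(names(corpus$responses), function(id)
    list(id = id, response = unname(corpus$responses[[id]]))),
    file.path(dir, "responses.jsonl"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus bundle from a directory
#'
#' @param dir Directory written by [write_corpus()].
#' @return A `note_corpus`.
#' @export
read_corpus <- function(dir) {
  notes_recs <- read_jsonl(file.path(dir, "notes.jsonl"))
  notes <- data.frame(
    id = vapply(notes_recs, `[[`, character(1), "id"),
    text = vapply(notes_recs, `[[`, character(1), "text"),
    stringsAsFactors = FALSE)
  gold <- read_sections_jsonl(file.path(dir, "gold.jsonl"))
  resp_recs <- read_jsonl(file.path(dir, "responses.jsonl"))
  responses <- stats::setNames(
    vapply(resp_recs, `[[`, character(1), "response"),
    vapply(resp_recs, `[[`, character(1), "id"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(notes = notes, gold = gold, responses = responses,
                 manifest = manifest),
            class = "note_corpus")
}
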