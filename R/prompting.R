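DEFAULT_SYSTEM_MESSAGE <- paste(
  "You are a helpful assistant.",
  "You are an experienced clinician and you are familiar with writing and",
  "understanding clinical notes.")

DEFAULT_TASK_DESCRIPTION <- paste(
  "A clinical note contains multiple sections like family history,",
  "allergies and history of present illness. Given a clinical note as an",
  "input, please separate the notes into sections and output their section",
  "names. Also specify where the section starts and ends. Use section names",
  "from one of the following:")

# Synthetic exemplar blocks in the exact required output shape; not drawn
# from any real note.
DEFAULT_FORMAT_EXAMPLES <- c(
  "Section 1: Allergies\nStarts at: ALLERGIES: the patient is\nEnds at: rash with penicillin.",
  "Section 2: Social history\nStarts at: SOCIAL HISTORY:\nEnds at: denies tobacco use."
)

#' Prompt configuration
#'
#' Holds the fixed text blocks of the prompt: the system message, the task
#' description, the exemplar output blocks showing the required section
#' format, and the cue that signals the model to answer. Defaults follow the
#' framework's standard wording; the two default format examples are
#' synthetic blocks in the exact required output shape.
#'
#' @param system_message High-level instruction establishing the model's
#'   clinician persona.
#' @param task_description The section-identification task instruction.
#' @param format_examples Character vector of exemplar output blocks; each
#'   must pass [check_format()].
#' @param output_cue String appended after the note (default `"Output:"`).
#' @return An object of class `prompt_config`.
#' @export
prompt_config <- function(system_message = DEFAULT_SYSTEM_MESSAGE,
                          task_description = DEFAULT_TASK_DESCRIPTION,
                          format_examples = DEFAULT_FORMAT_EXAMPLES,
                          output_cue = "Output:") {
  stopifnot(is.character(system_message), length(system_message) == 1L,
            is.character(task_description), length(task_description) == 1L,
            is.character(format_examples),
            is.character(output_cue), length(output_cue) == 1L)
  bad <- !vapply(format_examples, check_format, logical(1))
  if (any(bad))
    stop("format_examples[", paste(which(bad), collapse = ", "),
         "] do not pass the minimum output format check", call. = FALSE)
  structure(list(system_message = system_message,
                 task_description = task_description,
                 format_examples = format_examples,
                 output_cue = output_cue),
            class = "prompt_config")
}

#' Render the section-definition block of the prompt
#'
#' One line per section type, in schema order:
#' `<name>: <definition>, example section headings include '<h1>', '<h2>'.`
#' Types without example headings omit the headings clause.
#'
#' @param schema A [section_schema()].
#' @return A single string (empty for an empty schema).
#' @examples
#' s <- section_schema(list(section_type(
#'   "Admit date", "the date of the patient's admit",
#'   c("admission date", "date of admission"))))
#' cat(render_section_definitions(s))
#' @export
render_section_definitions <- function(schema) {
  stopifnot(inherits(schema, "section_schema"))
  lines <- vapply(schema$types, function(t) {
    if (length(t$example_headings)) {
      sprintf("%s: %s, example section headings include %s.", t$name,
              t$definition,
              paste0("'", t$example_headings, "'", collapse = ", "))
    } else {
      sprintf("%s: %s.", t$name, t$definition)
    }
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Assemble the four-component prompt
#'
#' Builds the chat-style `(system, user)` message pair: the system message,
#' then a user message made of the task description, the rendered section
#' definitions, the exemplar output blocks, the clinical note (verbatim,
#' as the final content block), and the output cue, each block separated by
#' a blank line. Rendering is byte-deterministic for fixed inputs.
#'
#' @param schema A [section_schema()].
#' @param note_text The clinical note. Non-empty.
#' @param cfg A [prompt_config()].
#' @return A list with elements `system` and `user`.
#' @export
build_prompt <- function(schema, note_text, cfg = prompt_config()) {
  stopifnot(inherits(schema, "section_schema"),
            inherits(cfg, "prompt_config"))
  if (!is.character(note_text) || length(note_text) != 1L ||
      !nzchar(note_text))
    stop("note_text must be a non-empty string", call. = FALSE)
  blocks <- c(cfg$task_description,
              render_section_definitions(schema),
              cfg$format_examples,
              note_text,
              cfg$output_cue)
  blocks <- blocks[nzchar(blocks)]
  list(system = cfg$system_message,
       user = paste(blocks, collapse = "\n\n"))
}
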