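#' Section type
#'
#' One entry of a section schema: a canonical section label, its free-text
#' definition (shown to the language model inside the prompt), and example
#' headings under which the section appears in real notes.
#'
#' @param name Canonical section label, e.g. `"Admit date"`. Non-empty.
#' @param definition Free-text description of the section. Non-empty.
#' @param example_headings Character vector of example headings (may be empty).
#' @return An object of class `section_type`.
#' @examples
#' section_type("Admit date", "the date of the patient's admit",
#'              c("admission date", "date of admission"))
#' @export
section_type <- function(name, definition, example_headings = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("section type 'name' must be a non-empty string", call. = FALSE)
  if (!is.character(definition) || length(definition) != 1L ||
      !nzchar(trimws(definition)))
    stop("section type '", name, "': 'definition' must be a non-empty string",
         call. = FALSE)
  structure(
    list(name = name, definition = definition,
         example_headings = as.character(example_headings)),
    class = "section_type"
  )
}

#' Section schema
#'
#' An ordered collection of [section_type()] entries plus a many-to-one map
#' from raw annotation labels to canonical names. A schema may contain at
#' most one `"Unknown"` type, used as a catch-all for unmapped labels.
#'
#' @param types List of [section_type()] objects.
#' @param label_map Named character vector mapping raw labels to canonical
#'   names. Every target must be a canonical name in `types`.
#' @return An object of class `section_schema`.
#' @details No two types may share a name even ignoring case: the
#'   case-insensitive name-matching variant of the resolver would otherwise
#'   be ambiguous.
#' @export
section_schema <- function(types, label_map = character()) {
  if (!is.list(types) || !all(vapply(types, inherits, TRUE, "section_type")))
    stop("'types' must be a list of section_type objects", call. = FALSE)
  nms <- vapply(types, `[[`, character(1), "name")
  folded <- tolower(nms)
  if (anyDuplicated(folded)) {
    dups <- unique(nms[folded %in% folded[duplicated(folded)]])
    stop("duplicate section names (ignoring case): ",
         paste(sQuote(dups), collapse = ", "), call. = FALSE)
  }
  if (sum(nms == "Unknown") > 1L)
    stop("at most one 'Unknown' section type is allowed", call. = FALSE)
  label_map <- unlist(label_map)
  if (length(label_map)) {
    if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
      stop("'label_map' must be a named mapping raw label -> canonical name",
           call. = FALSE)
    label_map <- vapply(label_map, as.character, character(1))
    missing <- setdiff(unique(unname(label_map)), nms)
    if (length(missing))
      stop("label_map targets not present in types: ",
           paste(sQuote(missing), collapse = ", "), call. = FALSE)
  } else {
    label_map <- stats::setNames(character(0), character(0))
  }
  structure(list(types = types, label_map = label_map),
            class = "section_schema")
}

#' Canonical section names of a schema
#'
#' @param schema A [section_schema()].
#' @return Character vector of canonical names, in schema order.
#' @export
schema_names <- function(schema) {
  stopifnot(inherits(schema, "section_schema"))
  vapply(schema$types, `[[`, character(1), "name")
}

#' Load a section schema from a YAML config
#'
#' The config holds a `types` list (each entry: `name`, `definition`,
#' optional `example_headings`) and an optional `label_map` table of
#' raw-label to canonical-name pairs.
#'
#' @param path Path to a YAML schema config.
#' @return A validated [section_schema()].
#' @seealso [discharge_schema()], [progress_schema()] for the bundled
#'   configs; [write_schema()] for the inverse.
#' @export
load_schema <- function(path) {
  if (!file.exists(path))
    stop("schema config not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("schema config parse failure in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(raw$types))
    stop("schema config error: missing key 'types' in ", path, call. = FALSE)
  types <- lapply(seq_along(raw$types), function(i) {
    t <- raw$types[[i]]
    if (is.null(t$name))
      stop("schema config error: types[", i, "] missing key 'name'",
           call. = FALSE)
    if (is.null(t$definition))
      stop("schema config error: type ", sQuote(t$name),
           " missing key 'definition'", call. = FALSE)
    section_type(t$name, t$definition,
                 as.character(unlist(t$example_headings)))
  })
  section_schema(types, raw$label_map %||% character())
}

#' Write a section schema to a YAML config
#'
#' Inverse of [load_schema()]: `load_schema(write_schema(s, path))`
#' reproduces `s`.
#'
#' @param schema A [section_schema()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "section_schema"))
  doc <- list(
    types = lapply(schema$types, function(t) {
      out <- list(name = t$name, definition = t$definition)
      if (length(t$example_headings))
        out$example_headings <- as.list(t$example_headings)
      out
    })
  )
  if (length(schema$label_map))
    doc$label_map <- as.list(schema$label_map)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Map a raw annotation label to its canonical section name
#'
#' Resolution order: the explicit `label_map` entry; then identity if the
#' label is already canonical; then the schema's `"Unknown"` catch-all type
#' when one exists. A label that resolves by none of these is an error.
#'
#' @param schema A [section_schema()].
#' @param raw_label A raw label string.
#' @return The canonical section name.
#' @examples
#' s <- section_schema(list(
#'   section_type("Physical examination", "exam findings"),
#'   section_type("Unknown", "anything else")),
#'   label_map = c("Physical" = "Physical examination"))
#' map_label(s, "Physical")    # "Physical examination"
#' map_label(s, "Subsection")  # "Unknown"
#' @export
map_label <- function(schema, raw_label) {
  stopifnot(inherits(schema, "section_schema"),
            is.character(raw_label), length(raw_label) == 1L)
  if (raw_label %in% names(schema$label_map))
    return(unname(schema$label_map[[raw_label]]))
  nms <- schema_names(schema)
  if (raw_label %in% nms) return(raw_label)
  if ("Unknown" %in% nms) return("Unknown")
  stop("label ", sQuote(raw_label),
       " is not mappable and the schema has no 'Unknown' type", call. = FALSE)
}

#' Bundled discharge-summary schema (27 section types)
#'
#' The 27 canonical section-type names of the discharge-summary annotation
#' scheme, with authored free-text definitions and example headings, and a
#' raw-label map collapsing redundant categories (e.g. `"Subsection"` to
#' `"Unknown"`, `"Physical"` to `"Physical examination"`). Definitions,
#' headings and most map entries are editable reconstructions; override by
#' copying the YAML (see `system.file("extdata", "discharge_schema.yaml",
#' package = "notesect")`) and passing your copy to [load_schema()].
#'
#' @return A [section_schema()] with 27 types.
#' @export
discharge_schema <- function() {
  load_schema(system.file("extdata", "discharge_schema.yaml",
                          package = "notesect"))
}

#' Bundled progress-note schema (15 section types, synthetic reconstruction)
#'
#' A 15-type SOAP-style progress-note schema with an `"Unknown"` catch-all.
#' The original progress-note type list is not redistributable here, so this
#' schema is a synthetic reconstruction intended for simulation and as an
#' editable template (`system.file("extdata", "progress_schema.yaml",
#' package = "notesect")`).
#'
#' @return A [section_schema()] with 15 types.
#' @export
progress_schema <- function() {
  load_schema(system.file("extdata", "progress_schema.yaml",
                          package = "notesect"))
}

#' @export
print.section_schema <- function(x, ...) {
  cat("<section_schema> ", length(x$types), " types, ",
      length(x$label_map), " label-map entries\n", sep = "")
  nms <- schema_names(x)
  cat(strwrap(paste(nms, collapse = ", "), indent = 2, exdent = 2),
      sep = "\n")
  invisible(x)
}
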