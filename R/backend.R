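#' Backend configuration
#'
#' Uniform contract for querying a generative model. Two kinds are
#' supported: `"mock"`, a deterministic offline backend replaying a
#' programmed script of responses, and `"http_chat"`, a generic
#' chat-completion HTTP endpoint (model, messages, temperature). Credentials
#' for `http_chat` are read from the environment variable named by
#' `api_key_env`, never from config files.
#'
#' @param kind `"mock"` or `"http_chat"`.
#' @param endpoint Chat-completion URL (`http_chat` only).
#' @param model Model identifier sent to the endpoint (`http_chat` only).
#' @param temperature Sampling temperature; default 0 for reproducibility.
#' @param max_retries Maximum number of re-generations after a response
#'   fails the minimum format check (default 3).
#' @param seed Integer seed recorded for mock runs.
#' @param script Default programmed responses for the mock backend: a
#'   character vector of successive attempts (the last element is replayed
#'   if more attempts are requested than programmed).
#' @param api_key_env Name of the environment variable holding the API key.
#' @return An object of class `backend_config`.
#' @export
backend_config <- function(kind = c("mock", "http_chat"), endpoint = NULL,
                           model = NULL, temperature = 0,
                           max_retries = 3L, seed = 1L, script = NULL,
                           api_key_env = "NOTESECT_API_KEY") {
  kind <- match.arg(kind)
  max_retries <- as.integer(max_retries)
  if (is.na(max_retries) || max_retries < 0L)
    stop("max_retries must be an integer >= 0", call. = FALSE)
  if (kind == "http_chat" && (is.null(endpoint) || is.null(model)))
    stop("http_chat backend requires 'endpoint' and 'model'", call. = FALSE)
  structure(list(kind = kind, endpoint = endpoint, model = model,
                 temperature = temperature, max_retries = max_retries,
                 seed = as.integer(seed), script = script,
                 api_key_env = api_key_env),
            class = "backend_config")
}

#' Minimum output format check
#'
#' A raw model response passes when it contains at least one block of the
#' form `Section <integer>: <text> Starts at: <text> Ends at: <text>`, with
#' case-sensitive keywords and non-empty text pieces (which may span lines
#' until the next keyword or block).
#'
#' @param raw Raw response string.
#' @return `TRUE` or `FALSE`.
#' @examples
#' check_format("Section 1: Allergies\nStarts at: ALLERGIES\nEnds at: rash.")
#' check_format("Section one: Allergies Starts at: X Ends at: Y")  # FALSE
#' @export
check_format <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(FALSE)
  nrow(parse_output(raw)) > 0L
}

#' Fingerprint a prompt for audit logs
#'
#' Deterministic short hexadecimal digest of the `(system, user)` pair,
#' used to key generation records.
#'
#' @param prompt A list with elements `system` and `user`.
#' @return An 8-character hexadecimal string.
#' @export
prompt_fingerprint <- function(prompt) {
  txt <- paste(prompt$system, prompt$user, sep = "\x1f")
  h <- 0
  for (c in utf8ToInt(txt)) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Query a backend with format-checked retries
#'
#' Generates up to `1 + max_retries` responses; the first one passing
#' [check_format()] is accepted. When every attempt fails the check, the
#' record carries no accepted response — downstream, such a note simply
#' yields zero predicted sections (which counts against recall) rather than
#' aborting a corpus run.
#'
#' @param cfg A [backend_config()].
#' @param prompt A `(system, user)` list from [build_prompt()].
#' @param attempts_script For the mock backend, a character vector of
#'   programmed responses overriding `cfg$script` (e.g. the per-note entry
#'   of a response script file).
#' @return A `generation_record`: list with `fingerprint`, `attempts` (all
#'   raw responses generated), `accepted` (the accepted response or `NULL`),
#'   and `n_retries_used`.
#' @export
query_with_retry <- function(cfg, prompt, attempts_script = NULL) {
  stopifnot(inherits(cfg, "backend_config"))
  gen <- backend_generator(cfg, prompt, attempts_script)
  attempts <- character(0)
  accepted <- NULL
  n_retries_used <- 0L
  for (k in seq_len(1L + cfg$max_retries)) {
    raw <- gen(k)
    attempts <- c(attempts, raw)
    if (check_format(raw)) {
      accepted <- raw
      n_retries_used <- k - 1L
      break
    }
    n_retries_used <- k - 1L
  }
  if (!is.null(accepted)) stopifnot(check_format(accepted))
  structure(list(fingerprint = prompt_fingerprint(prompt),
                 attempts = attempts, accepted = accepted,
                 n_retries_used = n_retries_used),
            class = "generation_record")
}

# Returns a function(attempt_index) -> raw response string.
backend_generator <- function(cfg, prompt, attempts_script = NULL) {
  if (cfg$kind == "mock") {
    script <- attempts_script %||% cfg$script
    if (is.null(script) || !length(script))
      stop("mock backend requires a programmed response script",
           call. = FALSE)
    script <- as.character(script)
    function(k) script[[min(k, length(script))]]
  } else {
    function(k) http_chat_request(cfg, prompt, attempt = k)
  }
}

# Generic chat-completion request: POST {model, messages, temperature};
# expects choices[[1]]$message$content in the JSON reply.
http_chat_request <- function(cfg, prompt, attempt = 1L) {
  if (!requireNamespace("curl", quietly = TRUE))
    stop("the http_chat backend requires the 'curl' package", call. = FALSE)
  key <- Sys.getenv(cfg$api_key_env, unset = "")
  body <- jsonlite::toJSON(list(
    model = cfg$model,
    messages = list(
      list(role = "system", content = prompt$system),
      list(role = "user", content = prompt$user)
    ),
    temperature = cfg$temperature
  ), auto_unbox = TRUE)
  h <- curl::new_handle()
  headers <- c("Content-Type" = "application/json")
  if (nzchar(key)) headers <- c(headers, Authorization = paste("Bearer", key))
  curl::handle_setheaders(h, .list = as.list(headers))
  curl::handle_setopt(h, post = TRUE, postfields = body)
  res <- tryCatch(curl::curl_fetch_memory(cfg$endpoint, handle = h),
                  error = function(e)
                    stop("backend transport error on attempt ", attempt,
                         ": ", conditionMessage(e), call. = FALSE))
  if (res$status_code >= 300L)
    stop("backend HTTP error on attempt ", attempt, ": status ",
         res$status_code, call. = FALSE)
  parsed <- jsonlite::fromJSON(rawToChar(res$content),
                               simplifyVector = FALSE)
  content <- tryCatch(parsed$choices[[1]]$message$content,
                      error = function(e) NULL)
  if (is.null(content))
    stop("backend response on attempt ", attempt,
         " lacked choices[[1]]$message$content", call. = FALSE)
  as.character(content)
}

#' @export
print.generation_record <- function(x, ...) {
  cat("<generation_record> fingerprint ", x$fingerprint, ", ",
      length(x$attempts), " attempt(s), ",
      if (is.null(x$accepted)) "no accepted response"
      else paste0("accepted after ", x$n_retries_used, " retr",
                  if (x$n_retries_used == 1L) "y" else "ies"),
      "\n", sep = "")
  invisible(x)
}
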