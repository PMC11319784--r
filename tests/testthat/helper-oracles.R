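# Independent oracles and fixture builders.  The oracles deliberately avoid
# the package's own code paths: edit distance by memoized recursion on the
# definition (cross-checked against utils::adist), evaluation by an explicit
# double loop, fuzzy search by enumerating every substring with
# utils::adist similarities.

# Edit distance straight from the recursive definition.
oracle_lev <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# Directional evaluation by explicit double loop with explicit argmax.
oracle_evaluate <- function(L1, L2) {
  n1 <- nrow(L1)
  if (n1 == 0L)
    return(list(n_correct = 0L, ratios = numeric(0), accuracy = 0,
                match_ratio = 0))
  ratios <- numeric(n1)
  nc <- 0L
  for (i in seq_len(n1)) {
    best_ov <- -1L
    bj <- NA_integer_
    for (j in seq_len(nrow(L2))) {
      ov <- max(0L, min(L1$end[i], L2$end[j]) -
                      max(L1$start[i], L2$start[j]) + 1L)
      if (ov > best_ov ||
          (ov == best_ov && L2$start[j] < L2$start[bj])) {
        best_ov <- ov
        bj <- j
      }
    }
    if (!is.na(bj)) {
      ratios[i] <- best_ov / (L1$end[i] - L1$start[i] + 1L)
      if (best_ov > 0L && L2$label[bj] == L1$label[i]) nc <- nc + 1L
    }
  }
  list(n_correct = nc, ratios = ratios, accuracy = nc / n1,
       match_ratio = mean(ratios))
}

# Best fuzzy occurrence over ALL substrings (no candidate-length window),
# similarities via utils::adist.  Exact integer arithmetic for the
# threshold test and for similarity comparisons; ties broken by smaller
# start, then shorter length, like the implementation contract.
oracle_fuzzy_best <- function(note, query, threshold = 90) {
  n <- nchar(note)
  q <- nchar(query)
  best <- NULL
  better <- function(d1, m1, d2, m2) (m1 - d1) * m2 > (m2 - d2) * m1
  equal_sim <- function(d1, m1, d2, m2) (m1 - d1) * m2 == (m2 - d2) * m1
  for (L in seq_len(n)) {
    starts <- seq_len(n - L + 1L)
    cands <- substring(note, starts, starts + L - 1L)
    ds <- as.integer(utils::adist(query, cands))
    mx <- max(q, L)
    ok <- which(100 * (mx - ds) >= threshold * mx)
    for (k in ok) {
      d <- ds[k]
      s <- starts[k]
      if (is.null(best) || better(d, mx, best$d, best$mx) ||
          (equal_sim(d, mx, best$d, best$mx) &&
           (s < best$s || (s == best$s && L < best$L)))) {
        best <- list(s = s, L = L, d = d, mx = mx)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$s - 1L, end = best$s + best$L - 2L,
       score = 100 * (best$mx - best$d) / best$mx)
}

# Independent single-character corruption (sub/ins/del with letters).
corrupt_string <- function(x, n_edits = 1L) {
  for (k in seq_len(n_edits)) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    n <- length(chars)
    op <- sample(c("sub", "ins", "del"), 1L)
    if (n <= 1L && op == "del") op <- "sub"
    pos <- sample.int(n, 1L)
    letter <- letters[sample.int(26L, 1L)]
    chars <- switch(op,
      sub = { chars[pos] <- letter; chars },
      ins = append(chars, letter, after = pos),
      del = chars[-pos])
    x <- paste(chars, collapse = "")
  }
  x
}

# Small fixed schema used across tests.
tiny_schema <- function() {
  section_schema(list(
    section_type("Allergies", "substances the patient reacts to",
                 c("ALLERGIES", "allergies")),
    section_type("Social history", "lifestyle and habits",
                 "SOCIAL HISTORY"),
    section_type("Admit date", "the date of the patient's admit",
                 c("admission date", "date of admission")),
    section_type("Hospital course", "events during the stay",
                 "HOSPITAL COURSE"),
    section_type("Unknown", "anything else", "MISC")),
    label_map = c(Subsection = "Unknown"))
}

# Random (possibly overlapping) labeled spans for evaluation tests.
random_sections <- function(n, note_len, labels = c("A", "B", "C")) {
  if (n == 0L) return(section_spans())
  start <- sort(sample.int(note_len, n)) - 1L
  end <- pmin(start + sample.int(40L, n, replace = TRUE), note_len - 1L)
  section_spans(sample(labels, n, replace = TRUE), start, end)
}

wellformed_block <- function(i = 1L) {
  sprintf("Section %d: Allergies\nStarts at: ALLERGIES:\nEnds at: rash.", i)
}
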