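test_that("parse_output extracts well-formed blocks and skips the rest", {
  raws <- parse_output(
    "Section 1: Allergies\nStarts at: ALLERGIES:\nEnds at: to penicillin.")
  expect_identical(nrow(raws), 1L)
  expect_identical(raws$index, 1L)
  expect_identical(raws$name_text, "Allergies")
  expect_identical(raws$start_text, "ALLERGIES:")
  expect_identical(raws$end_text, "to penicillin.")

  expect_identical(nrow(parse_output("")), 0L)
  expect_identical(nrow(parse_output("no sections here")), 0L)

  two <- paste0(
    "Some preamble the model chatted.\n",
    "Section 1: Allergies\nStarts at: AAA\nEnds at: BBB\n",
    "random garbage in between\n",
    "Section 3: Social history\nStarts at: CCC\nEnds at: DDD")
  raws <- parse_output(two)
  expect_identical(raws$index, c(1L, 3L))
  expect_identical(raws$name_text, c("Allergies", "Social history"))
  # the garbage after the first end text is absorbed into that field's tail
  expect_match(raws$end_text[1], "^BBB")

  # multi-line anchor texts survive with internal newlines intact
  ml <- parse_output(
    "Section 2: Allergies\nStarts at: HEAD:\nline two\nEnds at: tail")
  expect_identical(ml$start_text, "HEAD:\nline two")
})

test_that("levenshtein matches the recursive definition", {
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  set.seed(42)
  alphabet <- c("a", "b", "c")
  for (k in 1:30) {
    a <- paste(sample(alphabet, sample.int(8L, 1L), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample.int(8L, 1L), TRUE), collapse = "")
    expect_identical(levenshtein(a, b), oracle_lev(a, b))
    expect_identical(levenshtein(a, b), as.integer(utils::adist(a, b)))
  }
})

test_that("similarity is the length-normalized edit distance on 0-100", {
  expect_equal(similarity("abc", "abc"), 100)
  expect_equal(similarity("Admission Date", "Admision Date"),
               100 * (1 - 1 / 14))
  expect_equal(similarity("kitten", "sitting"), 100 * (1 - 3 / 7))
  expect_equal(similarity("", ""), 100)
  expect_equal(similarity("", "abc"), 0)
})

test_that("find_exact returns the leftmost occurrence at or after from_pos", {
  expect_equal(find_exact("AB AB", "AB", 0), list(start = 0L, end = 1L))
  expect_equal(find_exact("AB AB", "AB", 1), list(start = 3L, end = 4L))
  expect_null(find_exact("AB AB", "ZZ", 0))
  expect_null(find_exact("AB", "AB", 2))
})

test_that("find_fuzzy finds exact matches with score 100", {
  m <- find_fuzzy("xx ALLERGIES: yy", "ALLERGIES:", 0, 90)
  expect_equal(m$start, 3L)
  expect_equal(m$end, 12L)
  expect_equal(m$score, 100)
})

test_that("the similarity threshold boundary is honored exactly", {
  # 1 deletion on a length-10 query: 100*(1 - 1/10) = 90, accepted at 90
  m <- find_fuzzy("xxABCDEFGHJyy", "ABCDEFGHIJ", 0, 90)
  expect_equal(m$score, 90)
  expect_equal(m$start, 2L)
  expect_equal(m$end, 10L)
  # best possible score 89: rejected at 90, accepted at 89
  note <- strrep("a", 100)
  query <- paste0(strrep("a", 89), strrep("b", 11))
  expect_null(find_fuzzy(note, query, 0, 90))
  expect_equal(find_fuzzy(note, query, 0, 89)$score, 89)
})

test_that("find_fuzzy at threshold 100 accepts exactly what find_exact does", {
  set.seed(11)
  for (k in 1:25) {
    note <- paste(sample(c("ab", "ba", "ca", " "), 30, TRUE), collapse = "")
    from <- sample.int(20L, 1L) - 1L
    q_len <- sample(2:6, 1L)
    query <- if (k %% 2 == 0) substr(note, 8, 7 + q_len) else
      paste(sample(c("z", "q"), q_len, TRUE), collapse = "")
    ex <- find_exact(note, query, from)
    fz <- find_fuzzy(note, query, from, 100)
    if (is.null(ex)) {
      expect_null(fz)
    } else {
      expect_equal(fz[c("start", "end")], ex)
      expect_equal(fz$score, 100)
    }
  }
})

test_that("section names must match exactly unless case folding is on", {
  s <- tiny_schema()
  note <- "ALLERGIES:\npenicillin causes rash."
  raws <- data.frame(index = 1L, name_text = "allergies",
                     start_text = "ALLERGIES:", end_text = "rash.",
                     stringsAsFactors = FALSE)
  strict <- resolve_sections(note, raws, s, resolve_options())
  expect_identical(nrow(strict), 0L)
  expect_identical(attr(strict, "log")$dropped_name, 1L)

  folded <- resolve_sections(note, raws, s,
                             resolve_options(case_insensitive_names = TRUE))
  expect_identical(folded$label, "Allergies")  # canonical casing restored
  expect_identical(folded$start, 0L)
  expect_identical(folded$end, nchar(note) - 1L)
})

test_that("a corrupted end text falls back to the tentative end", {
  s <- tiny_schema()
  note <- paste0("ALLERGIES:\npenicillin causes rash.",
                 "SOCIAL HISTORY:\ndenies tobacco and alcohol use.")
  raws <- data.frame(
    index = 1:2, name_text = c("Allergies", "Social history"),
    start_text = c("ALLERGIES:", "SOCIAL HISTORY:"),
    end_text = c("zzzzqqqqzzzzqqqq", "alcohol use."),
    stringsAsFactors = FALSE)
  res <- resolve_sections(note, raws, s,
                          resolve_options(fuzzy_spans = TRUE))
  expect_identical(nrow(res), 2L)
  expect_identical(res$end[1], res$start[2] - 1L)  # tentative end stands
  expect_identical(res$end[2], nchar(note) - 1L)
})

test_that("repeated start texts are located with a moving cursor", {
  s <- tiny_schema()
  note <- "ALLERGIES:\nnone.ALLERGIES:\nmore detail here today."
  raws <- data.frame(
    index = 1:2, name_text = c("Allergies", "Unknown"),
    start_text = c("ALLERGIES:", "ALLERGIES:"),
    end_text = c("none.", "today."), stringsAsFactors = FALSE)
  res <- resolve_sections(note, raws, s, resolve_options())
  expect_identical(res$start, c(0L, 16L))
  expect_identical(res$end, c(15L, nchar(note) - 1L))
})

test_that("resolved spans are always sorted, disjoint, and in bounds", {
  s <- tiny_schema()
  err <- error_config(p_invalid_name = 0.2, p_case_flip = 0.3,
                      p_typo_start = 0.4, p_typo_end = 0.4,
                      typo_edits = 2L, p_drop_section = 0.1,
                      p_reorder = 0.5, p_malformed_block = 0.2)
  for (seed in 1:8) {
    set.seed(seed)
    ng <- generate_note(s, note_recipe(c(2L, 4L), c(40L, 90L)))
    resp <- simulate_response(ng$text, ng$gold, s, err)
    for (opts in list(resolve_options(),
                      resolve_options(TRUE, TRUE, 90),
                      resolve_options(TRUE, TRUE, 70))) {
      res <- resolve_sections(ng$text, parse_output(resp), s, opts)
      if (nrow(res) == 0L) next
      expect_true(all(res$start <= res$end))
      expect_true(all(res$start >= 0L) &&
                    all(res$end <= nchar(ng$text) - 1L))
      if (nrow(res) > 1L) {
        expect_true(all(diff(res$start) > 0L))
        expect_true(all(res$end[-nrow(res)] < res$start[-1]))
      }
    }
  }
})

test_that("raising the fuzzy threshold never adds resolved sections", {
  s <- tiny_schema()
  err <- error_config(p_typo_start = 0.7, p_typo_end = 0.5, typo_edits = 3L)
  for (seed in 1:5) {
    set.seed(seed)
    ng <- generate_note(s, note_recipe(c(3L, 4L), c(40L, 80L)))
    resp <- simulate_response(ng$text, ng$gold, s, err, anchor_chars = 12L)
    raws <- parse_output(resp)
    counts <- vapply(c(60, 75, 90, 100), function(thr)
      nrow(resolve_sections(ng$text, raws, s,
                            resolve_options(fuzzy_spans = TRUE,
                                            fuzzy_threshold = thr))),
      integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})
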