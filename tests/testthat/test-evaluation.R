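test_that("span_overlap counts shared character positions", {
  expect_identical(span_overlap(list(start = 0, end = 9),
                                list(start = 5, end = 14)), 5L)
  expect_identical(span_overlap(list(start = 0, end = 9),
                                list(start = 0, end = 9)), 10L)
  expect_identical(span_overlap(list(start = 0, end = 4),
                                list(start = 10, end = 12)), 0L)
})

test_that("evaluate_directional scores accuracy and match ratio", {
  L <- section_spans(c("A", "B"), c(0, 10), c(9, 19))
  self <- evaluate_directional(L, L)
  expect_equal(self$accuracy, 1)
  expect_equal(self$match_ratio, 1)

  half <- evaluate_directional(section_spans("A", 0, 9),
                               section_spans("A", 5, 14))
  expect_equal(half$accuracy, 1)
  expect_equal(half$match_ratio, 0.5)

  wrong <- evaluate_directional(section_spans("A", 0, 9),
                                section_spans("B", 0, 9))
  expect_equal(wrong$accuracy, 0)
  expect_equal(wrong$match_ratio, 1)

  none <- evaluate_directional(section_spans(), L)
  expect_true(none$degenerate)
  expect_equal(none$accuracy, 0)
  expect_equal(none$match_ratio, 0)

  empty_l2 <- evaluate_directional(L, section_spans())
  expect_equal(empty_l2$ratios, c(0, 0))
})

test_that("a zero-overlap best match never counts as correct", {
  # same label but disjoint spans: argmax overlap is 0, not correct
  out <- evaluate_directional(section_spans("A", 0, 4),
                              section_spans("A", 50, 60))
  expect_identical(out$n_correct, 0L)
  expect_equal(out$ratios, 0)
})

test_that("compute_metrics combines the two directions", {
  L <- section_spans(c("A", "B"), c(0, 10), c(9, 19))
  m <- compute_metrics(L, L)
  expect_equal(unlist(m[c("precision", "recall", "f1", "match_ratio")]),
               c(precision = 1, recall = 1, f1 = 1, match_ratio = 1))

  # one of two predictions correct, both golds found: p = 0.5, r = 1
  pred <- section_spans(c("A", "B"), c(0, 10), c(9, 19))
  gold <- section_spans(c("A", "A"), c(0, 10), c(9, 19))
  m <- compute_metrics(pred, gold)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)  # gold B-span matched by wrong label
  m2 <- compute_metrics(section_spans("A", 0, 9),
                        section_spans(c("A", "A"), c(0, 5), c(4, 9)))
  expect_equal(m2$f1,
               2 * m2$precision * m2$recall / (m2$precision + m2$recall))

  degen <- compute_metrics(section_spans(), gold)
  expect_equal(c(degen$precision, degen$recall, degen$f1), c(0, 0, 0))
})

test_that("precision and recall swap under argument exchange", {
  set.seed(5)
  for (k in 1:20) {
    a <- random_sections(sample(0:6, 1), 150)
    b <- random_sections(sample(0:6, 1), 150)
    mab <- compute_metrics(a, b)
    mba <- compute_metrics(b, a)
    expect_equal(mab$precision, mba$recall)
    expect_equal(mab$prediction_match_ratio, mba$target_match_ratio)
  }
})

test_that("consistent label permutation leaves metrics unchanged", {
  set.seed(9)
  perm <- c(A = "B", B = "C", C = "A")
  for (k in 1:10) {
    pred <- random_sections(sample(1:6, 1), 120)
    gold <- random_sections(sample(1:6, 1), 120)
    m1 <- compute_metrics(pred, gold)
    pred2 <- pred; pred2$label <- unname(perm[pred$label])
    gold2 <- gold; gold2$label <- unname(perm[gold$label])
    m2 <- compute_metrics(pred2, gold2)
    expect_equal(m1[c("precision", "recall", "f1", "match_ratio")],
                 m2[c("precision", "recall", "f1", "match_ratio")])
  }
})

test_that("micro aggregation pools counts and ratio lists", {
  # note A: 1 of 2 preds correct; note B: 1 of 2 preds correct;
  # 4 golds total, 2 matched -> pooled precision 0.5
  noteA <- list(pred = section_spans(c("A", "B"), c(0, 10), c(9, 19)),
                gold = section_spans(c("A", "A"), c(0, 10), c(9, 19)))
  noteB <- list(pred = section_spans(c("B", "A"), c(0, 10), c(9, 19)),
                gold = section_spans(c("B", "B"), c(0, 10), c(9, 19)))
  m <- micro_aggregate(list(noteA, noteB))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$n_pred, 4L)
  expect_equal(m$n_gold, 4L)

  # single-note corpus reduces to per-note metrics
  single <- micro_aggregate(list(noteA))
  direct <- compute_metrics(noteA$pred, noteA$gold)
  expect_equal(single[c("precision", "recall", "f1", "match_ratio")],
               direct[c("precision", "recall", "f1", "match_ratio")])

  # two perfect notes -> micro-F1 1
  perfect <- list(pred = noteA$gold, gold = noteA$gold)
  expect_equal(micro_aggregate(list(perfect, perfect))$f1, 1)

  expect_error(micro_aggregate(list()), "non-empty")
})

test_that("per-type rows break the evaluation down by section type", {
  gold <- section_spans(c("A", "A", "B"), c(0, 20, 40), c(9, 29, 49))
  rows <- per_type_report(gold, gold)
  expect_identical(rows$label, c("A", "B"))
  expect_equal(rows$precision, c(1, 1))
  expect_equal(rows$prediction_count, c(2L, 1L))

  # a type with golds but no predictions: precision 0 by convention, f1 0
  pred <- section_spans("A", 0, 9)
  rows <- per_type_report(pred, gold)
  b <- rows[rows$label == "B", ]
  expect_equal(c(b$precision, b$recall, b$f1), c(0, 0, 0))
  expect_identical(b$prediction_count, 0L)
  expect_identical(b$target_count, 1L)

  # hand-computed confusion: pred B over gold A's span
  pred2 <- section_spans(c("A", "B"), c(0, 20), c(9, 29))
  rows2 <- per_type_report(pred2, gold)
  a <- rows2[rows2$label == "A", ]
  expect_equal(a$precision, 1)        # 1 of 1 A-pred correct
  expect_equal(a$recall, 0.5)         # 1 of 2 A-golds matched by an A
  b2 <- rows2[rows2$label == "B", ]
  expect_equal(b2$precision, 0)       # the B-pred overlaps an A-gold
  expect_equal(b2$recall, 0)
  # rows sorted by F1, descending
  expect_true(!is.unsorted(rev(rows2$f1)))
})
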