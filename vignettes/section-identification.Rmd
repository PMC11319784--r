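---
title: "Methods: grounding LLM output for clinical note section identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grounding LLM output for clinical note section identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notesect)
```

## The procedure and its assumptions

`notesect` frames section identification as question answering: the model
receives a system message establishing a clinician persona, a task
description, one definition line per section type (name, free-text
definition, example headings), two exemplar output blocks fixing the
required format, and finally the note itself with an `Output:` cue. The
model answers with a list of blocks, each naming a section and copying
the text where it starts and where it ends.

The central assumption is that generative models copy text verbatim far
more reliably than they compute character offsets. Everything downstream
leans on that: the copied anchors are searched for in the note, and the
section's character span is reconstructed from the match positions. Two
secondary assumptions: sections are contiguous and non-overlapping (the
resolver enforces both), and the schema's names are unambiguous even
ignoring case (validated when a schema is built).

A response that lacks even one minimally well-formed block is regenerated,
up to `max_retries` times (default 3 — a small budget is enough because a
model that can follow the format usually does so by the second attempt).
A note whose attempts all fail contributes zero predicted sections; it
penalizes recall rather than aborting a corpus run.

## The span-resolution algorithm

`resolve_sections()` proceeds in six steps: (1) drop blocks whose name is
not a schema name; (2) drop blocks whose start anchor cannot be found;
(3) assign start offsets; (4) sort by start, deduplicating identical
starts; (5) set each tentative end to the next start minus one, the last
section's to the last character of the note; (6) look for the end anchor
inside `[start, tentative end]` and, if found, move the end to the final
character of that match. A section with a valid name and start anchor
therefore survives even when its end anchor is garbage — the tentative
end simply stands.

Several points are underdetermined by that outline; the package's
choices, all exercised by tests:

- **Offsets** are 0-based with inclusive ends, so "next start minus one"
  is literal arithmetic. Serialized section files state the convention in
  a header record.
- **Repeated start anchors.** Anchors are located in emission order with
  a moving cursor: search from just past the previous located start,
  retry from the beginning of the note on failure. This preserves note
  order when the same heading text occurs twice and falls back gracefully
  when the model emits sections out of order. (A pure leftmost search was
  the alternative; it collapses duplicate headings onto one position,
  which the cursor avoids.) Survivors that still share a start offset are
  deduplicated keeping the first, preventing zero-length sections.
- **End anchor position.** Within the window the *rightmost* qualifying
  match wins — an end marker later in the window dominates, because the
  window already caps the section at the next section's start and a later
  match explains more of the window.

### Fuzzy matching

Two optional variants absorb the most common copying errors. With
`case_insensitive_names`, step 1 matches names ignoring case and restores
canonical casing. With `fuzzy_spans`, steps 2 and 6 replace exact search
by a fuzzy search under the length-normalized Levenshtein similarity

\[ \mathrm{sim}(a, b) = 100 \left(1 - \frac{d(a,b)}{\max(|a|, |b|)}\right), \]

accepting a match when the similarity is at least `fuzzy_threshold`
(default 90). The normalization by the longer string is one concrete
reading of "length-normalized"; it is symmetric, keeps scores in
\[0, 100\], and makes the 90 threshold equivalent to "at most one edit
per ten characters of the longer string".

Implementation notes, each guarded by a test:

- Candidate substrings range over lengths
  \([\lceil 0.8q \rceil, \lfloor 1.2q \rfloor + 1]\) for a query of
  length \(q\): similarity ≥ 90 already forces the length difference
  below 10% of the longer string, so the window is sound with margin. A
  brute-force all-substrings oracle confirms the windowed search returns
  identical results whenever the oracle's best score reaches the
  threshold.
- One dynamic-programming pass per start position yields the distances to
  *all* candidate lengths at that start (the final DP row), so the search
  costs \(O(nq \cdot 1.2q)\) rather than a full DP per candidate. The
  kernels are C++.
- Threshold and tie comparisons use exact rational arithmetic
  (`100(m-d) \ge t\,m` on integers). In floating point, a one-deletion
  match on a ten-character query evaluates to 89.999…, silently rejecting
  a score that is exactly 90 — the boundary the default threshold is
  defined by.
- Ties in the leftmost search break toward the smaller start offset, then
  the shorter candidate; the rightmost (end-anchor) search maximizes the
  end offset, then similarity. With threshold 100, the fuzzy search
  accepts exactly the matches exact search does.

## Evaluation conventions

The metric is span-based and partial-credit: each section in one list is
matched to the section in the other list with the largest character
overlap, and scored by label agreement (accuracy direction) and by
overlap as a fraction of its own length (match-ratio direction). Running
the evaluation in both directions gives precision/prediction match ratio
and recall/target match ratio; F1 is their harmonic mean.

Degenerate cases are made total so corpus runs never fail: an empty
prediction list yields precision 0 (flagged `degenerate`), `F1 = 0` when
precision and recall are both 0, and a best match with *zero* overlap is
never "correct" regardless of label — label agreement on disjoint spans
is vacuous. Ties for the largest overlap break toward the
earliest-starting competitor, then list order. Corpus aggregation is
micro: correct-match and section counts are pooled across notes, and the
per-section match ratios are pooled into one list per direction before
averaging. Per-type rows restrict one side to a single label at a time,
so a correct match must carry that label; rows are sorted by F1
descending.

## What the synthetic corpus does and does not emulate

`generate_note()` produces notes with the structural features the
pipeline cares about: a sampled number of sections (default 4–8), each a
heading drawn from the type's example headings plus a filler body of
pseudo-clinical word salad (default 80–240 characters), with gold spans
that exactly tile the note. `simulate_response()` then plays the model:
it copies 30-character anchors from each gold section and injects
failures at configurable rates — invalid names, case flips, anchor
typos, dropped sections, shuffled blocks, malformed blocks — keeping a
tally so tests can reconcile resolver drop counts against injected
errors.

Two deliberate generator choices:

- **No whitespace at section boundaries.** The output format delimits
  anchors by newlines, so leading/trailing whitespace in a copied anchor
  cannot survive parsing. Sections end with a period and the next heading
  starts immediately; interior newlines (after each heading) are
  preserved and exercised. This is what makes exact round-trip — zero
  error injection resolving to gold spans *exactly* — achievable and
  testable.
- **30-character anchors.** With one edit, similarity is at least
  \(100(1 - 1/30) \approx 96.7\); with two, ≈ 93.3 — comfortably above
  the 90 threshold, so typo-injection experiments isolate the fuzzy
  variant's contribution rather than the anchor length.

What passing these tests shows is that the *machinery* — prompting,
format checking, parsing, resolution, scoring — is correct and that the
postprocessing variants repair exactly the error classes they target.
What it does not show is performance on real notes: real models produce
paraphrased rather than edit-corrupted anchors, real schemas have
genuinely ambiguous boundaries and annotator disagreement (especially
around catch-all types), and real notes contain duplicated headings,
tables, and boilerplate the word-salad bodies do not imitate. Absolute
scores on synthetic corpora are therefore not comparable to scores on
clinical data.

## Parameters at a glance

| Parameter | Default | Why |
|---|---|---|
| `max_retries` | 3 | small budget; format failures are rare after a retry |
| `temperature` | 0 | reproducibility of hosted-model runs |
| `fuzzy_threshold` | 90 | one edit per ten characters of the longer string |
| candidate window | ±20% of query length | sound for threshold ≥ 90, with margin |
| `anchor_chars` | 30 | keeps 1–2 edits above the threshold |
| `n_sections` | 4–8 | mid-length discharge summaries |
| `body_chars` | 80–240 | section bodies long enough for distinct anchors |

## Problem sizes in the test suite

The suite validates against independent oracles at sizes chosen to make
brute force exact: memoized-recursive edit distance on strings up to
length 8 (100 pairs), a double-loop evaluation oracle on 200 random
instances of up to 8 sections, an all-substrings fuzzy-search oracle on
50 notes of at most 500 characters, and end-to-end corpus runs of 50
notes. Round-trip, ablation-direction, and bookkeeping properties are
asserted exactly rather than approximately.

## Known limitations

- ASCII/single-byte text is assumed for offset arithmetic in the C++
  kernels; the synthetic generator only emits ASCII.
- The resolver cannot represent nested or overlapping sections, and a
  model that reorders sections heavily can still confuse the
  moving-cursor start location (the global-retry fallback recovers the
  common cases).
- The bundled discharge definitions and the entire progress schema are
  editable reconstructions, not the original annotation guidelines; the
  HTTP backend is deliberately generic (chat-completion contract) and
  carries no provider-specific authentication or rate-limit logic.
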