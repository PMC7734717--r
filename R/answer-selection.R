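# Answer selection: threshold/rank filtering, numeric-content filtering for
# quantity questions, the class-assertion cross-check, and verbalization.

order_scored <- function(scored) {
  scored[order(-scored$combined, scored$domain, scored$property,
               scored$range), , drop = FALSE]
}

triple_key <- function(df) {
  paste(df$domain, df$property, df$range, sep = "\r")
}

#' Candidate filtering by gate, rank, and threshold
#'
#' Let `m` be the highest combined score among object-property assertions.
#' If `m > top_gate` (0.50), the top `ceiling(top_fraction * N)` object and
#' data assertions by combined score are kept, with boundary ties included.
#' Otherwise every object/data assertion with combined score above
#' `fallback_threshold` (0.45) is kept.
#'
#' @param scored Scored object/data assertion table (rows with
#'   `kind %in% c("object", "data")`; other rows are ignored).
#' @param cfg Configuration from [qa_config()].
#' @return The surviving rows, ordered by decreasing combined score.
#' @export
select_candidates <- function(scored, cfg = qa_config()) {
  od <- scored[scored$kind %in% c("object", "data"), , drop = FALSE]
  if (!nrow(od)) return(od)
  obj <- od$combined[od$kind == "object"]
  m <- if (length(obj)) max(obj) else 0
  if (m > cfg$top_gate) {
    k <- ceiling(cfg$top_fraction * nrow(od))
    cutoff <- sort(od$combined, decreasing = TRUE)[k]
    keep <- od$combined >= cutoff
  } else {
    keep <- od$combined > cfg$fallback_threshold
  }
  out <- order_scored(od[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Keep candidates with numeric content
#'
#' For COUNT/MAX/MIN (and NUMERIC) questions, a candidate survives when the
#' rendered label of any of its positions contains a digit or a number word
#' ("zero" through "ten" by default).
#'
#' @param candidates Scored candidate rows.
#' @param kb The `cooqa_kb` (label rendering).
#' @param cfg Configuration from [qa_config()].
#' @return The surviving rows.
#' @export
numeric_filter <- function(candidates, kb, cfg = qa_config()) {
  if (!nrow(candidates)) return(candidates)
  labels <- paste(
    kb_label(kb, candidates$domain),
    kb_label(kb, candidates$property),
    kb_label(kb, candidates$range, is_literal = candidates$range_is_literal)
  )
  word_pat <- paste0("\\b(", paste(cfg$number_words, collapse = "|"), ")\\b")
  keep <- grepl("[0-9]", labels) | grepl(word_pat, tolower(labels))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-assertion cross-check
#'
#' The top `ceiling(top_fraction * N)` scored class assertions (boundary
#' ties included) form the reference set `T`; an object/data candidate
#' survives when at least one of the class assertions it instantiates
#' ([tbox_assertions_of()]) is in `T`. With an empty class-assertion list
#' the strict default drops every candidate (the no-answer path);
#' `class_filter_permissive = TRUE` passes all instead.
#'
#' @param candidates Scored candidate rows (object/data).
#' @param class_scored Scored class-assertion rows.
#' @param kb The `cooqa_kb`.
#' @param cfg Configuration from [qa_config()].
#' @return The surviving rows.
#' @export
class_assertion_filter <- function(candidates, class_scored, kb,
                                   cfg = qa_config()) {
  if (!nrow(candidates)) return(candidates)
  if (!nrow(class_scored)) {
    if (isTRUE(cfg$class_filter_permissive)) return(candidates)
    out <- candidates[0, , drop = FALSE]
    return(out)
  }
  k <- ceiling(cfg$top_fraction * nrow(class_scored))
  cutoff <- sort(class_scored$combined, decreasing = TRUE)[k]
  top_keys <- triple_key(class_scored[class_scored$combined >= cutoff, ,
                                      drop = FALSE])
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    tb <- tbox_assertions_of(kb, candidates[i, ])
    nrow(tb) > 0L && any(triple_key(tb) %in% top_keys)
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verbalize selected triples
#'
#' Each triple is rendered as "domain-label property-label range-label";
#' clauses are joined with "; also, ", the sentence is capitalized and
#' terminated with a period. An empty selection yields the fixed no-answer
#' line.
#'
#' @param selected Assertion rows (possibly zero rows).
#' @param kb The `cooqa_kb`.
#' @param cfg Configuration from [qa_config()].
#' @return A single answer string.
#' @export
render_answer <- function(selected, kb, cfg = qa_config()) {
  if (is.null(selected) || !nrow(selected)) return(cfg$no_answer_line)
  clauses <- paste(
    kb_label(kb, selected$domain),
    kb_label(kb, selected$property),
    kb_label(kb, selected$range, is_literal = selected$range_is_literal)
  )
  text <- paste(clauses, collapse = "; also, ")
  text <- paste0(toupper(substr(text, 1L, 1L)), substr(text, 2L, nchar(text)), ".")
  text
}

#' Answer a natural-language question against a knowledge base
#'
#' Full pipeline: parse the question, score every object, data, and class
#' assertion against it, gate and filter the object/data candidates, apply
#' the question-type-dependent filter (numeric content for COUNT/MAX/MIN/
#' NUMERIC, class-assertion cross-check otherwise), and verbalize the top
#' survivors (at most `max_triples`, except ALL questions which keep every
#' survivor).
#'
#' @param question Question string.
#' @param kb A `cooqa_kb`.
#' @param backend `"string"` (Monge-Elkan over Smith-Waterman-Gotoh) or
#'   `"vector"` (embedding cosine).
#' @param lex Lexical-relation table.
#' @param embeddings Embedding matrix (vector backend only).
#' @param cfg Configuration from [qa_config()].
#' @return An object of class `cooqa_answer`: list with `question`, `qtype`,
#'   `selected` (assertion rows), `text`, `answered`, `backend`, and
#'   `scores` (the full scored table with a `stage` column: "scored",
#'   "candidate", or "selected").
#' @examples
#' kb <- load_ontology(generate_toy_kb(file.path(tempdir(), "kb.owl")))
#' answer_question("how does hpv affect males", kb)$text
#' @export
answer_question <- function(question, kb, backend = c("string", "vector"),
                            lex = load_lexical_table(), embeddings = NULL,
                            cfg = qa_config()) {
  backend <- match.arg(backend)
  sim <- similarity_backend(backend, embeddings = embeddings, swg = cfg$swg)
  q <- parse_question(question)
  scored <- score_assertions(kb, q, sim, lex, cfg)
  od <- scored[scored$kind %in% c("object", "data"), , drop = FALSE]
  cl <- scored[scored$kind == "class", , drop = FALSE]
  cand <- select_candidates(od, cfg)
  if (q$qtype %in% c("COUNT", "MAX", "MIN", "NUMERIC")) {
    cand <- numeric_filter(cand, kb, cfg)
  } else {
    cand <- class_assertion_filter(cand, cl, kb, cfg)
  }
  cand <- order_scored(cand)
  selected <- if (q$qtype == "ALL") cand else utils::head(cand, cfg$max_triples)
  rownames(selected) <- NULL
  scored$stage <- "scored"
  scored$stage[triple_key(scored) %in% triple_key(cand)] <- "candidate"
  scored$stage[triple_key(scored) %in% triple_key(selected)] <- "selected"
  out <- list(question = question, qtype = q$qtype, parsed = q,
              selected = selected, text = render_answer(selected, kb, cfg),
              answered = nrow(selected) > 0L, backend = backend,
              scores = scored)
  class(out) <- "cooqa_answer"
  out
}

#' @export
print.cooqa_answer <- function(x, ...) {
  cat("<cooqa_answer> [", x$qtype, "/", x$backend, "] ", x$question,
      "\n  answered: ", x$answered, "\n  ", x$text, "\n", sep = "")
  invisible(x)
}
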