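# Score Keeper: token-level string similarity (Monge-Elkan with a normalized
# Smith-Waterman-Gotoh inner metric), embedding cosine similarity, the
# lexical-relation score adjustment, and per-triple score assembly.

#' Normalized Smith-Waterman-Gotoh character similarity
#'
#' Local alignment over characters with match +1, mismatch -1, and a linear
#' gap penalty of -0.5 per gap character (affine with open = extend). The
#' best local alignment score is divided by the length of the longer string
#' and clamped to `[0, 1]`. Empty strings score 0.
#'
#' @param a,b Token strings.
#' @param match,mismatch,gap Alignment parameters.
#' @return Similarity in `[0, 1]`.
#' @examples
#' swg_similarity("vaccine", "vaccine")
#' swg_similarity("cover", "covers")
#' @export
swg_similarity <- function(a, b, match = 1, mismatch = -1, gap = -0.5) {
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) return(0)
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  n <- length(x)
  m <- length(y)
  prev <- numeric(m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      cur[j + 1L] <- max(0, prev[j] + s, prev[j + 1L] + gap, cur[j] + gap)
    }
    if (max(cur) > best) best <- max(cur)
    prev <- cur
  }
  min(1, max(0, best / max(n, m)))
}

#' Monge-Elkan token-set similarity
#'
#' For each token of `tokens_a`, the best inner-metric match among
#' `tokens_b` is found; the mean of these maxima is returned. The measure is
#' deliberately asymmetric. Either side empty scores 0.
#'
#' @param tokens_a,tokens_b Character vectors of tokens.
#' @param inner Token-level similarity function (default [swg_similarity()]).
#' @return Similarity in `[0, 1]`.
#' @examples
#' monge_elkan(c("hpv"), c("hpv", "vaccine"))
#' @export
monge_elkan <- function(tokens_a, tokens_b, inner = swg_similarity) {
  if (!length(tokens_a) || !length(tokens_b)) return(0)
  per_a <- vapply(tokens_a, function(a) {
    max(vapply(tokens_b, function(b) inner(a, b), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  mean(per_a)
}

#' Load a term-embedding table
#'
#' Text format: one term per line, `term v1 v2 ... vd`, whitespace-separated.
#' All rows must share one dimension.
#'
#' @param path Path to the table; defaults to the toy table shipped with the
#'   package.
#' @return Numeric matrix with terms as row names.
#' @export
load_embeddings <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toy_embeddings.txt", package = "cooqa")
    if (path == "") path <- file.path("inst", "extdata", "toy_embeddings.txt")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "\\s+")
  dims <- unique(vapply(parts, length, integer(1))) - 1L
  if (length(dims) != 1L || dims < 1L) {
    stop("embedding table '", path, "' has inconsistent dimensions: ",
         paste(dims, collapse = ", "))
  }
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims)))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1L)
  mat
}

#' Embedding cosine similarity between two term lists
#'
#' Each side is represented by the mean vector of its in-vocabulary terms;
#' the cosine of the two means is clamped to `[0, 1]`. A side with no
#' in-vocabulary term scores 0.
#'
#' @param terms_a,terms_b Character vectors of cleaned terms.
#' @param embeddings Matrix from [load_embeddings()].
#' @return Similarity in `[0, 1]`.
#' @export
vector_similarity <- function(terms_a, terms_b, embeddings) {
  mean_vec <- function(terms) {
    hit <- terms[terms %in% rownames(embeddings)]
    if (!length(hit)) return(NULL)
    colMeans(embeddings[hit, , drop = FALSE])
  }
  va <- mean_vec(terms_a)
  vb <- mean_vec(terms_b)
  if (is.null(va) || is.null(vb)) return(0)
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(va * vb) / (na * nb)))
}

#' Load a lexical-relation table
#'
#' Tab-separated lines `term<TAB>relation<TAB>related_term<TAB>depth` with
#' relation in `syn`, `hyper` (related_term is a hypernym of term), `hypo`.
#'
#' @param path Path; defaults to the table shipped with the package.
#' @return An object of class `cooqa_lexicon` (a data.frame).
#' @export
load_lexical_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexical_relations.tsv", package = "cooqa")
    if (path == "") path <- file.path("inst", "extdata", "lexical_relations.tsv")
  }
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("term", "relation", "related", "depth"))
  if (!all(df$relation %in% c("syn", "hyper", "hypo"))) {
    stop("lexical table '", path, "' contains unknown relations")
  }
  class(df) <- c("cooqa_lexicon", class(df))
  df
}

# Relations between two single terms: symmetric synonymy; hyper/hypo checked
# in both directions (an entry `a hyper b` also means `b hypo a`).
pair_relations <- function(lex, a, b) {
  hit <- (lex$term == a & lex$related == b) | (lex$term == b & lex$related == a)
  lex[hit, , drop = FALSE]
}

cross_pairs_syn <- function(lex, terms_a, terms_b, depth, identity_synonym) {
  for (a in terms_a) for (b in terms_b) {
    if (identity_synonym && a == b) return(TRUE)
    rel <- pair_relations(lex, a, b)
    if (any(rel$relation == "syn" & rel$depth <= depth)) return(TRUE)
  }
  FALSE
}

cross_pairs_any <- function(lex, terms_a, terms_b, identity_synonym) {
  for (a in terms_a) for (b in terms_b) {
    if (identity_synonym && a == b) return(TRUE)
    if (nrow(pair_relations(lex, a, b))) return(TRUE)
  }
  FALSE
}

#' Lexical-relation score adjustment
#'
#' If any cross-pair of terms is synonymous within the depth bound, the
#' score is boosted by 25% (capped at 1). If no cross-pair has any synonym,
#' hypernym, or hyponym relation, the score is zeroed. Otherwise the score
#' is unchanged. Identical terms count as synonyms (depth 0) unless
#' `identity_synonym = FALSE`.
#'
#' @param score Backend similarity in `[0, 1]`.
#' @param terms_a,terms_b Cleaned term vectors being compared.
#' @param lex Lexical table from [load_lexical_table()].
#' @param boost Synonym multiplier (default 1.25).
#' @param synonym_depth Depth bound for synonymy (default 3).
#' @param identity_synonym Treat identical terms as synonyms.
#' @return Adjusted score in `[0, 1]`.
#' @export
lexical_adjust <- function(score, terms_a, terms_b, lex, boost = 1.25,
                           synonym_depth = 3, identity_synonym = TRUE) {
  if (!length(terms_a) || !length(terms_b)) return(0)
  if (cross_pairs_syn(lex, terms_a, terms_b, synonym_depth, identity_synonym)) {
    return(min(1, boost * score))
  }
  if (!cross_pairs_any(lex, terms_a, terms_b, identity_synonym)) {
    return(0)
  }
  score
}

# Resolve a similarity backend name to a function over two term vectors.
similarity_backend <- function(backend = c("string", "vector"),
                               embeddings = NULL, swg = list()) {
  backend <- match.arg(backend)
  if (backend == "string") {
    inner <- function(a, b) {
      swg_similarity(a, b,
                     match = swg$match %||% 1,
                     mismatch = swg$mismatch %||% -1,
                     gap = swg$gap %||% -0.5)
    }
    function(terms_a, terms_b) monge_elkan(terms_a, terms_b, inner)
  } else {
    if (is.null(embeddings)) embeddings <- load_embeddings()
    function(terms_a, terms_b) vector_similarity(terms_a, terms_b, embeddings)
  }
}

#' Score one assertion triple against a parsed question
#'
#' The predicate label is compared with the question's verb phrases and the
#' domain/range labels with its noun phrases, each comparison passing through
#' [lexical_adjust()]. The entity score is the maximum over (entity, noun
#' phrase) pairs; the predicate score is the maximum over verb phrases, and
#' is absent (`NA`) when the question has no verb phrase. The combined score
#' is the mean of the two when both exist, else the entity score alone.
#'
#' @param triple One-row assertion data.frame (see [kb_assertions()]).
#' @param question A `cooqa_question` from [parse_question()].
#' @param kb The `cooqa_kb` the triple came from (label rendering).
#' @param sim Similarity function from `similarity_backend()`, or NULL for
#'   the string backend.
#' @param lex Lexical table.
#' @param cfg Configuration list (see [qa_config()]).
#' @return A one-row data.frame: the triple columns plus `predicate_score`,
#'   `entity_score`, `combined`.
#' @export
score_triple <- function(triple, question, kb, sim = NULL,
                         lex = load_lexical_table(), cfg = qa_config()) {
  if (is.null(sim)) sim <- similarity_backend("string", swg = cfg$swg)
  triple <- as.list(triple)
  adj <- function(s, ta, tb) {
    lexical_adjust(s, ta, tb, lex, boost = cfg$boost,
                   synonym_depth = cfg$synonym_depth,
                   identity_synonym = cfg$identity_synonym)
  }
  pred_terms <- clean_terms(kb_label(kb, triple$property))
  dom_terms  <- clean_terms(kb_label(kb, triple$domain))
  rng_terms  <- clean_terms(kb_label(kb, triple$range,
                                     is_literal = isTRUE(triple$range_is_literal)))
  pred_score <- NA_real_
  if (length(question$verb_phrases)) {
    pred_score <- max(0, vapply(question$verb_phrases, function(vp) {
      adj(sim(pred_terms, vp), pred_terms, vp)
    }, numeric(1)))
  }
  ent_score <- 0
  for (ent in list(dom_terms, rng_terms)) {
    for (np in question$noun_phrases) {
      s <- adj(sim(ent, np), ent, np)
      if (s > ent_score) ent_score <- s
    }
  }
  combined <- if (is.na(pred_score)) ent_score else mean(c(pred_score, ent_score))
  out <- data.frame(domain = triple$domain, property = triple$property,
                    range = triple$range,
                    range_is_literal = isTRUE(triple$range_is_literal),
                    kind = triple$kind, predicate_score = pred_score,
                    entity_score = ent_score, combined = combined,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Score every assertion of the given kinds; returns one combined table.
score_assertions <- function(kb, question, sim, lex, cfg,
                             kinds = c("object", "data", "class")) {
  rows <- kb$assertions[kb$assertions$kind %in% kinds, , drop = FALSE]
  if (!nrow(rows)) {
    return(cbind(rows, predicate_score = numeric(0),
                 entity_score = numeric(0), combined = numeric(0)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    score_triple(rows[i, ], question, kb, sim = sim, lex = lex, cfg = cfg)
  }))
  rownames(out) <- NULL
  out
}
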