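# Shared fixtures: generated once per test session into tempdir and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_path <- function(name) {
  d <- file.path(tempdir(), "cooqa-test-fixtures")
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  f <- file.path(d, name)
  if (!file.exists(f)) {
    switch(name,
      "dialogue.owl" = generate_dialogue_ontology(f),
      "dialogue.ttl" = generate_dialogue_ontology(f, format = "turtle"),
      "kb.owl" = generate_toy_kb(f),
      "kb.ttl" = generate_toy_kb(f, format = "turtle"),
      "kb_empty.owl" = generate_toy_kb(f, n_diseases = 0L,
                                       include_worked_example = FALSE),
      stop("unknown fixture: ", name))
  }
  f
}

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, make(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

dialogue_fixture_kb <- function() {
  cached("dialogue_kb", function() load_ontology(fixture_path("dialogue.owl")))
}

toy_fixture_kb <- function() {
  cached("toy_kb", function() load_ontology(fixture_path("kb.owl")))
}

empty_fixture_kb <- function() {
  cached("empty_kb", function() load_ontology(fixture_path("kb_empty.owl")))
}

fixture_lex <- function() cached("lex", load_lexical_table)
fixture_emb <- function() cached("emb", load_embeddings)

KB_NS <- "http://example.org/vaxkb#"
DLG_NS <- "http://example.org/counsel#"
kbiri <- function(x) paste0(KB_NS, x)
dlgiri <- function(x) paste0(DLG_NS, x)
local_names <- function(iris) sub("^.*[#/]", "", iris)

# Hand-built scored-triple table for filter tests.
scored_rows <- function(combined, kind = "object", domain = NULL) {
  n <- length(combined)
  if (is.null(domain)) domain <- sprintf("urn:t%02d", seq_len(n))
  data.frame(domain = domain, property = rep("urn:p", n),
             range = sprintf("urn:r%02d", seq_len(n)),
             range_is_literal = FALSE, kind = rep_len(kind, n),
             predicate_score = NA_real_, entity_score = combined,
             combined = combined, stringsAsFactors = FALSE)
}

# Independent brute-force re-statement of the gate/rank/threshold filter.
brute_filter <- function(scored, cfg = qa_config()) {
  od <- scored[scored$kind %in% c("object", "data"), , drop = FALSE]
  obj <- od$combined[od$kind == "object"]
  m <- if (length(obj)) max(obj) else 0
  if (m > cfg$top_gate) {
    k <- ceiling(cfg$top_fraction * nrow(od))
    cutoff <- sort(od$combined, decreasing = TRUE)[k]
    od[od$combined >= cutoff, , drop = FALSE]
  } else {
    od[od$combined > cfg$fallback_threshold, , drop = FALSE]
  }
}

# Independent Monge-Elkan oracle: plain double loop over the definition.
brute_monge_elkan <- function(A, B, inner = swg_similarity) {
  if (!length(A) || !length(B)) return(0)
  tot <- 0
  for (a in A) {
    best <- 0
    for (b in B) {
      v <- inner(a, b)
      if (v > best) best <- v
    }
    tot <- tot + best
  }
  tot / length(A)
}

# Independent local-alignment oracle via Biostrings (affine gaps with
# open = extend = 0.5, +1/-1 substitution), normalized like the package.
swg_oracle_many <- function(patterns, subject, alphabet = c("a", "b", "c")) {
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  sc <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0.5, scoreOnly = TRUE)
  pmin(1, pmax(0, sc / pmax(nchar(patterns), nchar(subject))))
}

run_session <- function(name, backend = "string",
                        kb = toy_fixture_kb(), dkb = dialogue_fixture_kb()) {
  s <- scripted_sessions()[[name]]
  st <- dialogue_initialize(dkb)
  qa <- make_qa_callback(kb, backend)
  dialogue_run(st, s$inputs, qa)
}
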