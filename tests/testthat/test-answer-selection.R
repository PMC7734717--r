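test_that("candidate selection applies the gate, rank, and fallback rules", {
  # gate open: 10 triples, top object score 0.55 -> top ceil(0.2*10) = 2 kept
  sc <- scored_rows(c(0.55, 0.50, 0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10,
                      0.05))
  out <- select_candidates(sc)
  expect_equal(nrow(out), 2L)
  expect_equal(out$combined, c(0.55, 0.50))
  # gate closed: top object 0.40 -> all above 0.45 kept
  sc2 <- scored_rows(c(0.40, 0.48, 0.46, 0.30))
  sc2$kind <- c("object", "data", "data", "data")
  out2 <- select_candidates(sc2)
  expect_equal(sort(out2$combined, decreasing = TRUE), c(0.48, 0.46))
  # all zero -> empty
  expect_equal(nrow(select_candidates(scored_rows(rep(0, 5)))), 0L)
  # boundary ties at the rank cutoff are all included
  sc3 <- scored_rows(c(0.9, 0.6, 0.6, 0.6, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  out3 <- select_candidates(sc3)
  expect_equal(nrow(out3), 4L)
})

test_that("candidate selection equals the brute-force filter on random sets", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(c(5L, 10L, 50L), 1)
    sc <- scored_rows(round(stats::runif(n), 3),
                      kind = sample(c("object", "data"), n, replace = TRUE))
    got <- select_candidates(sc)
    want <- brute_filter(sc)
    expect_setequal(paste(got$domain, got$combined),
                    paste(want$domain, want$combined))
    # fallback never passes a score at or below the threshold
    obj <- sc$combined[sc$kind == "object"]
    if (!length(obj) || max(obj) <= qa_config()$top_gate) {
      expect_true(all(got$combined > qa_config()$fallback_threshold))
    }
  }
})

test_that("the numeric filter keeps digits and number words only", {
  kb <- toy_fixture_kb()
  cand <- scored_rows(c(0.9, 0.8, 0.7),
                      domain = c("urn:aa", "urn:bb", "urn:cc"))
  cand$range <- c("one", "none at all", "3 doses")
  cand$range_is_literal <- TRUE
  out <- numeric_filter(cand, kb)
  expect_setequal(out$range, c("one", "3 doses"))
  # "none" must not match the number word "one"
  expect_false("none at all" %in% out$range)
})

test_that("the class-assertion cross-check keeps supported candidates", {
  kb <- toy_fixture_kb()
  lex <- fixture_lex()
  q <- parse_question("how does hpv affect males")
  sim <- cooqa:::similarity_backend("string")
  scored <- cooqa:::score_assertions(kb, q, sim, lex, qa_config())
  od <- scored[scored$kind %in% c("object", "data"), ]
  cl <- scored[scored$kind == "class", ]
  worked_key <- paste(kbiri("throat_cancer"), kbiri("affects"), kbiri("males"))
  kept <- class_assertion_filter(od, cl, kb)
  expect_true(worked_key %in% paste(kept$domain, kept$property, kept$range))
  # the prevention triple instantiates Vaccine->prevents->Virus, which is
  # outside the top class assertions for this question
  prev_key <- paste(kbiri("hpv_vaccine"), kbiri("prevents"), kbiri("hpv"))
  expect_false(prev_key %in% paste(kept$domain, kept$property, kept$range))
  # empty class list: strict default drops everything, permissive passes all
  none <- cl[0, ]
  expect_equal(nrow(class_assertion_filter(od, none, kb)), 0L)
  expect_equal(nrow(class_assertion_filter(od, none, kb,
                                           qa_config(class_filter_permissive = TRUE))),
               nrow(od))
})

test_that("answers verbalize triples and fall back to the no-answer line", {
  kb <- toy_fixture_kb()
  obj <- kb_assertions(kb, "object")
  worked <- obj[obj$domain == kbiri("throat_cancer") &
                  obj$range == kbiri("males"), ]
  expect_identical(render_answer(worked, kb), "Throat cancer affects males.")
  expect_identical(render_answer(obj[0, ], kb), qa_config()$no_answer_line)
  two <- rbind(worked, obj[obj$property == kbiri("covers"), ])
  txt <- render_answer(two, kb)
  expect_match(txt, "^Throat cancer affects males; also, ")
  expect_match(txt, "insurance plans covers hpv vaccine\\.$")
})

test_that("the QA pipeline answers, refuses, and counts as specified", {
  kb <- toy_fixture_kb()
  worked_key <- paste(kbiri("throat_cancer"), kbiri("affects"), kbiri("males"))
  for (backend in c("string", "vector")) {
    a <- answer_question("how does hpv affect males", kb, backend = backend)
    expect_true(a$answered)
    expect_true(worked_key %in%
                  paste(a$selected$domain, a$selected$property, a$selected$range),
                label = paste("worked example under", backend))
    miss <- answer_question("what is the weather like tomorrow", kb,
                            backend = backend)
    expect_false(miss$answered)
    expect_identical(miss$text, qa_config()$no_answer_line)
    cnt <- answer_question("how many doses of the hpv vaccine do i need", kb,
                           backend = backend)
    expect_identical(cnt$qtype, "COUNT")
    expect_true(cnt$answered)
    labs <- paste(kb_label(kb, cnt$selected$domain),
                  kb_label(kb, cnt$selected$property),
                  kb_label(kb, cnt$selected$range,
                           is_literal = cnt$selected$range_is_literal))
    expect_true(all(grepl("[0-9]|\\bone\\b|\\btwo\\b|\\bthree\\b", labs)))
  }
})

test_that("selection stages only remove candidates, never add", {
  kb <- toy_fixture_kb()
  a <- answer_question("how does hpv affect males", kb)
  key <- function(df) paste(df$domain, df$property, df$range)
  all_keys <- key(a$scores)
  expect_true(all(key(a$selected) %in% all_keys))
  cand_keys <- key(a$scores[a$scores$stage %in% c("candidate", "selected"), ])
  expect_true(all(key(a$selected) %in% cand_keys))
})

test_that("a knowledge base with no instance assertions never answers", {
  kb <- empty_fixture_kb()
  expect_equal(nrow(kb_assertions(kb, "object")), 0L)
  expect_equal(nrow(kb_assertions(kb, "data")), 0L)
  for (qtext in c("how does hpv affect males", "how many doses do i need",
                  "does insurance cover the vaccine")) {
    a <- answer_question(qtext, kb)
    expect_false(a$answered)
    expect_identical(a$text, qa_config()$no_answer_line)
  }
})

test_that("identical question, knowledge base, and config give one answer", {
  kb <- toy_fixture_kb()
  a <- answer_question("can you tell me if insurance covers the hpv vaccine", kb)
  b <- answer_question("can you tell me if insurance covers the hpv vaccine", kb)
  expect_identical(a$text, b$text)
  expect_identical(a$selected, b$selected)
  expect_identical(a$scores, b$scores)
})
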