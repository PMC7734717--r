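test_that("initialization places a single focus on the entry utterance", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  focused <- vapply(st$nodes, function(n) isTRUE(n$focus), logical(1))
  expect_equal(sum(focused), 1L)
  expect_identical(local_names(st$focused), "greeting")
  expect_equal(length(st$nodes), 19L)
  expect_error(dialogue_initialize(dialogue_fixture_kb(),
                                   start = dlgiri("not_here")),
               "not an utterance individual")
})

test_that("successors follow precedence links in IRI-sorted order", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  expect_identical(node_successors(st, dlgiri("health_info_1")),
                   dlgiri("confirm_info_1"))
  expect_length(node_successors(st, dlgiri("closing")), 0L)
  # oracle: brute-force edge scan, then sort
  succ <- node_successors(st, dlgiri("confirm_info_1"))
  scan <- sort(st$edges$to[st$edges$from == dlgiri("confirm_info_1")])
  expect_identical(succ, scan)
  expect_length(succ, 4L)
  expect_error(node_successors(st, "urn:nowhere"), "unknown node")
})

test_that("advancing focus preserves the single-focus invariant", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  st <- advance_focus(st, dlgiri("health_info_1"))
  focused <- names(st$nodes)[vapply(st$nodes, function(n) isTRUE(n$focus),
                                    logical(1))]
  expect_identical(focused, dlgiri("health_info_1"))
  expect_false(st$nodes[[dlgiri("greeting")]]$focus)
  # advancing to the focused node itself is a legal no-op on the flags
  st2 <- advance_focus(st, dlgiri("health_info_1"))
  expect_identical(st2$focused, dlgiri("health_info_1"))
  expect_equal(st2$focus_violations, 0L)
  expect_error(advance_focus(st, "urn:nowhere"), "unknown node")
})

test_that("user utterances classify onto the expected participant branches", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  cands <- st$nodes[node_successors(st, dlgiri("confirm_info_1"))]
  cases <- list(
    list("yes", "CONFIRMATION", "p_confirm_1"),
    list("not really", "DISCONFIRMATION", "p_disconfirm_1"),
    list("can you repeat that", "REQUEST_SYSTEM_REPEAT", "p_repeat_1"),
    list("can you tell me if insurance covers the hpv vaccine", "QUESTION",
         "p_question_1"),
    list("how does hpv affect males", "QUESTION", "p_question_1"))
  for (cs in cases) {
    res <- classify_user_utterance(cs[[1]], cands)
    expect_identical(res$category, cs[[2]])
    expect_identical(local_names(res$node$iri), cs[[3]])
    expect_true(res$node$iri %in% names(cands))  # branch soundness
  }
  res <- classify_user_utterance("blargh fizzle wump", cands)
  expect_identical(res$category, "UNINTELLIGIBLE")
  expect_null(res$node)
  expect_identical(classify_user_utterance("yes", list())$category,
                   "UNINTELLIGIBLE")
})

test_that("stepping speaks system utterances and routes questions to QA", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  no_input <- function() NULL
  st <- dialogue_step(st, no_input)          # greeting
  st <- dialogue_step(st, no_input)          # health info
  expect_identical(st$transcript$text[2],
                   utterance_texts()[["health_info_1"]])
  expect_identical(local_names(st$focused), "confirm_info_1")
  seen <- character()
  qa <- function(q) { seen <<- c(seen, q); "the answer." }
  inputs <- c("how does hpv affect males")
  i <- 0L
  provider <- function() { i <<- i + 1L; if (i > length(inputs)) NULL else inputs[i] }
  st <- dialogue_step(st, provider, qa)      # confirm prompt + question turn
  expect_identical(seen, "how does hpv affect males")
  expect_true("the answer." %in% st$transcript$text)
  expect_identical(local_names(st$focused), "p_question_1")
})

test_that("exhausted scripted input records a truncation marker", {
  st <- dialogue_initialize(dialogue_fixture_kb())
  st <- dialogue_run(st, character())
  expect_true(st$truncated)
  expect_false(st$complete)
  expect_identical(utils::tail(st$transcript$category, 1), "TRUNCATED")
})

test_that("all scripted sessions traverse their expected node sequences", {
  for (nm in names(scripted_sessions())) {
    st <- run_session(nm)
    expect_identical(local_names(st$history),
                     scripted_sessions()[[nm]]$expected_nodes,
                     label = paste("history of", nm))
    expect_true(st$complete, label = paste(nm, "completes"))
    expect_equal(st$focus_violations, 0L)
  }
})

test_that("a repeat request makes the agent speak the same line twice", {
  st <- run_session("repeat_request")
  info <- utterance_texts()[["health_info_1"]]
  expect_equal(sum(st$transcript$text == info), 2L)
})

test_that("disconfirmation without a question ends in a provider referral", {
  st <- run_session("disconfirm_no_question")
  expect_true(utterance_texts()[["provider_referral"]] %in% st$transcript$text)
})

test_that("an unanswerable question yields the apology line and continues", {
  st <- run_session("question_unanswered")
  expect_true(qa_config()$no_answer_line %in% st$transcript$text)
  expect_true(st$complete)
})

test_that("both questions of a multi-question session are answered in order", {
  st <- run_session("multi_question")
  ans <- st$transcript$text[st$transcript$category %in% "ANSWER"]
  expect_length(ans, 2L)
  expect_match(ans[1], "^Insurance plans covers")
  expect_match(ans[2], "Throat cancer affects males")
})

test_that("identical fixture and script produce byte-identical transcripts", {
  a <- run_session("qa_via_disconfirm")
  b <- run_session("qa_via_disconfirm")
  expect_identical(a$transcript, b$transcript)
  f1 <- file.path(tempdir(), "t1.jsonl"); f2 <- file.path(tempdir(), "t2.jsonl")
  write_transcript(a, f1); write_transcript(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})
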