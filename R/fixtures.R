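# Deterministic fixture generators: a replica counseling dialogue ontology
# (two health topics, full branch structure, 19 utterance individuals in the
# default preset), a toy vaccine knowledge base carrying the worked-example
# triple, and the scripted user sessions covering the canonical flows.

DIALOGUE_NS <- "http://example.org/counsel#"
KB_NS <- "http://example.org/vaxkb#"

# Pinned utterance texts (paraphrased counseling lines; fixed so transcripts
# are byte-stable in tests).
utterance_texts <- function() {
  c(
    greeting = "Hello. Let us talk about the HPV vaccine.",
    health_info_1 = "The HPV vaccine is available to you regardless of your insurance status.",
    health_info_2 = "Some people believe the HPV vaccine has long-term side effects, but there is no evidence for that misbelief.",
    confirm_info = "You following me so far?",
    ask_question = "Do you have a question I can help with?",
    provider_referral = "If you still have concerns, it is best to ask your health care provider. Let us move on.",
    ask_another = "Do you have another question?",
    closing = "That is all I have for today. Thank you for listening."
  )
}

utterance_examples <- function() {
  list(
    p_confirm = c("yes", "yeah", "ok", "i understand", "got it", "sure"),
    p_repeat = c("can you repeat that", "say that again", "repeat please"),
    p_disconfirm = c("not really", "no", "i do not agree", "i do not think so"),
    p_question = c("can you tell me if insurance covers the hpv vaccine",
                   "can you tell me about the vaccine"),
    p_no_question = c("nah", "no", "nope"),
    p_question_ask = c("can you tell me if insurance covers the hpv vaccine",
                       "i have a question"),
    p_no_more = c("nope no question", "no more questions", "nah"),
    p_question_more = c("can you tell me if insurance plans cover vaccination",
                        "i have another question")
  )
}

#' Generate the counseling dialogue ontology
#'
#' Writes a dialogue ontology whose utterance individuals realize the
#' two-topic counseling structure: each topic block opens with a health
#' information utterance and a confirmation prompt; configured branches add
#' the confirm, repeat, disconfirm (with question prompt, no-question,
#' question, and provider-referral utterances), and question (with
#' another-question prompt, no-more, and follow-up question utterances)
#' paths. A greeting and a closing utterance bridge the blocks. The default
#' preset (topic 1 with every branch, topic 2 with confirm and repeat)
#' yields exactly 19 utterance individuals. All focus flags are serialized
#' as "false"; generation is fully deterministic.
#'
#' @param path Output file (`.ttl` for Turtle, else RDF/XML).
#' @param branches List (one element per topic) of branch subsets drawn from
#'   `c("confirm", "repeat", "disconfirm", "question")`.
#' @param namespace Dialogue namespace IRI prefix.
#' @param format Serialization.
#' @return `path` invisibly, with attribute `n_utterances` (the instance
#'   count, which equals the topology formula: 2 bridges + per block 2 +
#'   |confirm| + |repeat| + 5*|disconfirm| + 4*|question|).
#' @examples
#' f <- generate_dialogue_ontology(file.path(tempdir(), "dialogue.owl"))
#' attr(f, "n_utterances")
#' @export
generate_dialogue_ontology <- function(path,
                                       branches = list(
                                         c("confirm", "repeat", "disconfirm",
                                           "question"),
                                         c("confirm", "repeat")),
                                       namespace = DIALOGUE_NS,
                                       format = c("auto", "rdfxml", "turtle")) {
  if (!grepl("^[a-z][a-z0-9+.-]*://", namespace)) {
    stop("namespace must be an absolute IRI prefix: ", namespace)
  }
  if (!length(branches)) stop("at least one topic block is required")
  ok <- c("confirm", "repeat", "disconfirm", "question")
  for (b in branches) {
    if (!all(b %in% ok)) stop("unknown branch: ", paste(setdiff(b, ok), collapse = ", "))
  }
  ns <- function(x) paste0(namespace, x)
  texts <- utterance_texts()
  exs <- utterance_examples()

  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- triple_df(...)
  classes <- c("Utterance", "System_Utterance", "Participant_Utterance",
               "Greeting_Utterance", "Health_Information_Utterance",
               "Confirm_Health_Information_Utterance", "Ask_Question_Utterance",
               "Ask_Another_Question_Utterance", "Provider_Referral_Utterance",
               "Closing_Utterance", "Confirmation_Utterance",
               "Disconfirmation_Utterance", "Question_Utterance",
               "Request_System_Repeat_Utterance")
  for (cl in classes) emit(ns(cl), IRI_TYPE, IRI_CLASS)
  sub <- rbind(
    c("System_Utterance", "Utterance"),
    c("Participant_Utterance", "Utterance"),
    c("Greeting_Utterance", "System_Utterance"),
    c("Health_Information_Utterance", "System_Utterance"),
    c("Confirm_Health_Information_Utterance", "System_Utterance"),
    c("Ask_Question_Utterance", "System_Utterance"),
    c("Ask_Another_Question_Utterance", "System_Utterance"),
    c("Provider_Referral_Utterance", "System_Utterance"),
    c("Closing_Utterance", "System_Utterance"),
    c("Confirmation_Utterance", "Participant_Utterance"),
    c("Disconfirmation_Utterance", "Participant_Utterance"),
    c("Question_Utterance", "Participant_Utterance"),
    c("Request_System_Repeat_Utterance", "Participant_Utterance"))
  for (k in seq_len(nrow(sub))) emit(ns(sub[k, 1]), IRI_SUBCLASS, ns(sub[k, 2]))
  emit(ns("precedes"), IRI_TYPE, IRI_OBJPROP)
  for (p in c("hasFocus", "hasUtteranceText", "hasUtteranceExample")) {
    emit(ns(p), IRI_TYPE, IRI_DATAPROP)
  }

  n_utt <- 0L
  system_node <- function(name, class, text) {
    n_utt <<- n_utt + 1L
    emit(ns(name), IRI_TYPE, ns(class))
    emit(ns(name), ns("hasFocus"), "false", is_literal = TRUE)
    emit(ns(name), ns("hasUtteranceText"), text, is_literal = TRUE)
    ns(name)
  }
  participant_node <- function(name, class, examples) {
    n_utt <<- n_utt + 1L
    emit(ns(name), IRI_TYPE, ns(class))
    emit(ns(name), ns("hasFocus"), "false", is_literal = TRUE)
    for (ex in examples) {
      emit(ns(name), ns("hasUtteranceExample"), ex, is_literal = TRUE)
    }
    ns(name)
  }
  link <- function(from, to) emit(from, ns("precedes"), to)

  greeting <- system_node("greeting", "Greeting_Utterance", texts[["greeting"]])
  closing_iri <- ns("closing")
  entries <- character(length(branches))
  blocks <- vector("list", length(branches))
  for (t in seq_along(branches)) {
    ti <- as.character(t)
    hi_text <- texts[[paste0("health_info_", min(t, 2L))]]
    hi <- system_node(paste0("health_info_", ti),
                      "Health_Information_Utterance", hi_text)
    ci <- system_node(paste0("confirm_info_", ti),
                      "Confirm_Health_Information_Utterance",
                      texts[["confirm_info"]])
    link(hi, ci)
    entries[t] <- hi
    blocks[[t]] <- list(hi = hi, ci = ci, branch = branches[[t]], ti = ti)
  }
  next_entry <- function(t) if (t < length(branches)) entries[t + 1L] else closing_iri
  for (t in seq_along(blocks)) {
    blk <- blocks[[t]]
    ti <- blk$ti
    if ("confirm" %in% blk$branch) {
      pc <- participant_node(paste0("p_confirm_", ti), "Confirmation_Utterance",
                             exs$p_confirm)
      link(blk$ci, pc); link(pc, next_entry(t))
    }
    if ("repeat" %in% blk$branch) {
      pr <- participant_node(paste0("p_repeat_", ti),
                             "Request_System_Repeat_Utterance", exs$p_repeat)
      link(blk$ci, pr); link(pr, blk$hi)
    }
    if ("disconfirm" %in% blk$branch) {
      pd <- participant_node(paste0("p_disconfirm_", ti),
                             "Disconfirmation_Utterance", exs$p_disconfirm)
      aq <- system_node(paste0("ask_question_", ti), "Ask_Question_Utterance",
                        texts[["ask_question"]])
      nq <- participant_node(paste0("p_no_question_", ti),
                             "Disconfirmation_Utterance", exs$p_no_question)
      qa <- participant_node(paste0("p_question_ask_", ti),
                             "Question_Utterance", exs$p_question_ask)
      pv <- system_node(paste0("provider_referral_", ti),
                        "Provider_Referral_Utterance",
                        texts[["provider_referral"]])
      link(blk$ci, pd); link(pd, aq); link(aq, nq); link(aq, qa)
      link(nq, pv); link(pv, next_entry(t))
    }
    if ("question" %in% blk$branch) {
      pq <- participant_node(paste0("p_question_", ti), "Question_Utterance",
                             exs$p_question)
      aa <- system_node(paste0("ask_another_", ti),
                        "Ask_Another_Question_Utterance", texts[["ask_another"]])
      nm <- participant_node(paste0("p_no_more_", ti),
                             "Disconfirmation_Utterance", exs$p_no_more)
      qm <- participant_node(paste0("p_question_more_", ti),
                             "Question_Utterance", exs$p_question_more)
      link(blk$ci, pq); link(pq, aa); link(aa, nm); link(aa, qm)
      link(nm, next_entry(t)); link(qm, aa)
      if ("disconfirm" %in% blk$branch) {
        link(ns(paste0("p_question_ask_", ti)), aa)
      }
    }
  }
  system_node("closing", "Closing_Utterance", texts[["closing"]])
  link(greeting, entries[1])

  triples <- do.call(rbind, rows)
  write_rdf(triples, path, format = match.arg(format))
  out <- path
  attr(out, "n_utterances") <- n_utt
  invisible(out)
}

#' Generate the toy vaccine knowledge base
#'
#' A small stand-in for a full vaccine ontology: insurance-coverage,
#' causation, prevention, dose-count, and minimum-age assertions, plus (when
#' `include_worked_example`) the triple throat_cancer -> affects -> males
#' with its TBox support (class assertion Disease -> affects -> People and
#' the subclass chain Males < People_of_Gender < People). `n_diseases` adds
#' extra disease-affects-group assertions drawn deterministically from a
#' fixed pool under the given seed.
#'
#' @param path Output file (`.ttl` for Turtle, else RDF/XML).
#' @param n_diseases Extra disease assertions (0-4).
#' @param include_worked_example Include the throat-cancer triple and its
#'   class-level support.
#' @param include_core Include the core instance assertions (insurance
#'   coverage, causation, prevention, dose count, minimum age); defaults to
#'   `include_worked_example`, so a KB generated with neither flag and
#'   `n_diseases = 0` carries zero instance assertions (the no-answer path).
#' @param seed Integer seed for the extra-disease draw.
#' @param namespace KB namespace IRI prefix.
#' @param format Serialization.
#' @return `path`, invisibly.
#' @export
generate_toy_kb <- function(path, n_diseases = 2L,
                            include_worked_example = TRUE,
                            include_core = include_worked_example, seed = 1L,
                            namespace = KB_NS,
                            format = c("auto", "rdfxml", "turtle")) {
  stopifnot(n_diseases >= 0L, n_diseases <= 4L)
  ns <- function(x) paste0(namespace, x)
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- triple_df(...)

  classes <- c("Disease", "Target", "Virus", "Vaccine", "Insurance_Plan",
               "People", "People_of_Gender", "Males", "Females", "Children")
  for (cl in classes) emit(ns(cl), IRI_TYPE, IRI_CLASS)
  emit(ns("Males"), IRI_SUBCLASS, ns("People_of_Gender"))
  emit(ns("Females"), IRI_SUBCLASS, ns("People_of_Gender"))
  emit(ns("People_of_Gender"), IRI_SUBCLASS, ns("People"))
  emit(ns("Children"), IRI_SUBCLASS, ns("People"))
  for (p in c("affects", "covers", "causes", "prevents")) {
    emit(ns(p), IRI_TYPE, IRI_OBJPROP)
  }
  for (p in c("hasDoseCount", "hasMinimumAge")) {
    emit(ns(p), IRI_TYPE, IRI_DATAPROP)
  }
  emit(ns("hasDoseCount"), IRI_LABEL, "has dose count", is_literal = TRUE)
  emit(ns("hasMinimumAge"), IRI_LABEL, "has minimum age", is_literal = TRUE)

  ind <- function(name, class) emit(ns(name), IRI_TYPE, ns(class))

  # class-level schema triples (the class-assertion family)
  emit(ns("Disease"), ns("affects"), ns("People"))
  emit(ns("Insurance_Plan"), ns("covers"), ns("Vaccine"))
  emit(ns("Virus"), ns("causes"), ns("Disease"))
  emit(ns("Vaccine"), ns("prevents"), ns("Virus"))

  if (include_core) {
    ind("hpv", "Virus")
    ind("hpv_vaccine", "Vaccine")
    ind("insurance_plans", "Insurance_Plan")
    ind("throat_cancer", "Disease")
    emit(ns("insurance_plans"), ns("covers"), ns("hpv_vaccine"))
    emit(ns("hpv"), ns("causes"), ns("throat_cancer"))
    emit(ns("hpv_vaccine"), ns("prevents"), ns("hpv"))
    emit(ns("hpv_vaccine"), ns("hasDoseCount"), "3", is_literal = TRUE)
    emit(ns("hpv_vaccine"), ns("hasMinimumAge"), "9", is_literal = TRUE)
  }
  if (include_worked_example) {
    ind("males", "Males")
    ind("throat_cancer", "Disease")
    ind("throat_cancer", "Target")
    emit(ns("throat_cancer"), ns("affects"), ns("males"))
  }
  if (n_diseases > 0L) {
    pool <- list(c("measles", "children"), c("polio", "children"),
                 c("cervical_cancer", "females"), c("flu", "people_group"))
    set.seed(seed)
    picks <- pool[sample.int(length(pool), n_diseases)]
    for (pk in picks) {
      ind(pk[1], "Disease")
      cls <- switch(pk[2], children = "Children", females = "Females",
                    people_group = "People")
      ind(pk[2], cls)
      emit(ns(pk[1]), ns("affects"), ns(pk[2]))
    }
  }
  triples <- do.call(rbind, rows)
  write_rdf(triples, path, format = match.arg(format))
  invisible(path)
}

#' Scripted user sessions for the counseling flows
#'
#' Nine named sessions, each with the ordered user inputs and the expected
#' focus-traversal sequence (utterance local names) over the default
#' dialogue fixture: plain confirmation; disconfirmation with no question;
#' repeat requests; unintelligible input ending in the segue; the two entry
#' paths into question answering; an answered and an unanswered question;
#' and two questions in sequence.
#'
#' @return Named list of sessions, each a list with `inputs` and
#'   `expected_nodes`.
#' @export
scripted_sessions <- function() {
  q_insurance <- "can you tell me if insurance covers the hpv vaccine"
  q_plans <- "can you tell me if insurance plans cover vaccination"
  q_males <- "how does hpv affect males"
  q_offtopic <- "what is the weather like tomorrow"
  topic2_tail <- c("health_info_2", "confirm_info_2", "p_confirm_2", "closing")
  list(
    confirm = list(
      inputs = c("yes", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_confirm_1", topic2_tail)),
    disconfirm_no_question = list(
      inputs = c("not really", "nah", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_disconfirm_1", "ask_question_1", "p_no_question_1",
                         "provider_referral_1", topic2_tail)),
    repeat_request = list(
      inputs = c("can you repeat that", "yes", "say that again", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_repeat_1", "health_info_1", "confirm_info_1",
                         "p_confirm_1", "health_info_2", "confirm_info_2",
                         "p_repeat_2", "health_info_2", "confirm_info_2",
                         "p_confirm_2", "closing")),
    unintelligible = list(
      inputs = c("blargh fizzle wump", "snorf gleeb", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         topic2_tail)),
    qa_via_disconfirm = list(
      inputs = c("not really", q_insurance, "nope no question", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_disconfirm_1", "ask_question_1", "p_question_ask_1",
                         "ask_another_1", "p_no_more_1", topic2_tail)),
    qa_direct_question = list(
      inputs = c(q_insurance, "nope no question", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_question_1", "ask_another_1", "p_no_more_1",
                         topic2_tail)),
    question_answered = list(
      inputs = c(q_males, "nope no question", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_question_1", "ask_another_1", "p_no_more_1",
                         topic2_tail)),
    question_unanswered = list(
      inputs = c(q_offtopic, "nope no question", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_question_1", "ask_another_1", "p_no_more_1",
                         topic2_tail)),
    multi_question = list(
      inputs = c(q_plans, q_males, "nope no question", "yes"),
      expected_nodes = c("greeting", "health_info_1", "confirm_info_1",
                         "p_question_1", "ask_another_1", "p_question_more_1",
                         "ask_another_1", "p_no_more_1", topic2_tail))
  )
}

#' Write the complete fixture set to a directory
#'
#' Dialogue ontology, toy knowledge base, embedding table, lexical table,
#' and one script file per session.
#'
#' @param dir Output directory (created if needed).
#' @param format Ontology serialization.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dir, format = c("rdfxml", "turtle")) {
  format <- match.arg(format)
  ext <- if (format == "turtle") "ttl" else "owl"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  generate_dialogue_ontology(file.path(dir, paste0("dialogue.", ext)),
                             format = format)
  generate_toy_kb(file.path(dir, paste0("kb.", ext)), format = format)
  file.copy(system.file("extdata", "toy_embeddings.txt", package = "cooqa"),
            file.path(dir, "toy_embeddings.txt"), overwrite = TRUE)
  file.copy(system.file("extdata", "lexical_relations.tsv", package = "cooqa"),
            file.path(dir, "lexical_relations.tsv"), overwrite = TRUE)
  sessions <- scripted_sessions()
  for (nm in names(sessions)) {
    writeLines(sessions[[nm]]$inputs,
               file.path(dir, paste0("session_", nm, ".txt")),
               useBytes = TRUE)
  }
  invisible(dir)
}
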