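# The dialogue loop: query the focused utterance, speak system utterances,
# classify participant utterances against their expected examples, hand
# questions to the QA callback, and advance the focus flag along precedence
# links.

#' Dialogue ontology vocabulary
#'
#' IRIs of the properties and classes the engine reads from a dialogue
#' ontology. Defaults match the fixture namespace produced by
#' [generate_dialogue_ontology()].
#'
#' @param namespace IRI prefix of the dialogue vocabulary.
#' @return Named list of IRIs and class local names.
#' @export
dialogue_vocab <- function(namespace = "http://example.org/counsel#") {
  list(
    namespace = namespace,
    precedes = paste0(namespace, "precedes"),
    has_focus = paste0(namespace, "hasFocus"),
    has_text = paste0(namespace, "hasUtteranceText"),
    has_example = paste0(namespace, "hasUtteranceExample"),
    utterance_class = paste0(namespace, "Utterance"),
    system_class = paste0(namespace, "System_Utterance"),
    participant_class = paste0(namespace, "Participant_Utterance"),
    category_classes = c(
      Confirmation_Utterance = "CONFIRMATION",
      Disconfirmation_Utterance = "DISCONFIRMATION",
      Question_Utterance = "QUESTION",
      Request_System_Repeat_Utterance = "REQUEST_SYSTEM_REPEAT"
    )
  )
}

empty_transcript <- function() {
  data.frame(speaker = character(), text = character(), node = character(),
             category = character(), stringsAsFactors = FALSE)
}

add_turn <- function(state, speaker, text, node = NA_character_,
                     category = NA_character_) {
  state$transcript <- rbind(state$transcript, data.frame(
    speaker = speaker, text = text, node = node, category = category,
    stringsAsFactors = FALSE))
  state
}

# Build one utterance node from the loaded ontology.
build_node <- function(kb, iri, vocab) {
  classes <- infer_classes(kb, iri)
  is_sys <- vocab$system_class %in% classes
  is_part <- vocab$participant_class %in% classes
  if (is_sys && is_part) {
    stop("utterance ", iri, " is typed both System and Participant")
  }
  if (!is_sys && !is_part) {
    stop("utterance ", iri, " is neither System nor Participant")
  }
  dat <- kb$assertions[kb$assertions$domain == iri, , drop = FALSE]
  text <- dat$range[dat$property == vocab$has_text]
  examples <- dat$range[dat$property == vocab$has_example]
  locals <- iri_local(classes)
  pcat <- NA_character_
  if (is_part) {
    hits <- vocab$category_classes[names(vocab$category_classes) %in% locals]
    pcat <- if (length(hits)) unname(hits[[1]]) else "UNINTELLIGIBLE"
  }
  asserted <- kb$types$class[kb$types$individual == iri]
  list(iri = iri, label = kb_label(kb, iri),
       text = if (length(text)) text[[1]] else "",
       examples = examples, classes = classes,
       primary_class = iri_local(asserted[[1]]),
       category = if (is_sys) "system" else "participant",
       pcat = pcat, focus = FALSE)
}

#' Initialize a dialogue from a loaded dialogue ontology
#'
#' Collects every individual typed (via the subclass closure) under the
#' utterance class, builds the precedence graph, and places the focus flag
#' on the start node.
#'
#' @param kb A `cooqa_kb` holding the dialogue ontology.
#' @param start IRI of the starting utterance; defaults to the unique node
#'   with no incoming precedence edge.
#' @param vocab Vocabulary from [dialogue_vocab()].
#' @param config Engine configuration from [dialogue_config()].
#' @return An object of class `cooqa_dialogue`: list with `nodes` (named
#'   list of utterance nodes), `edges` (data.frame `from`, `to`), `focused`
#'   (IRI), `transcript`, `history`, and bookkeeping flags.
#' @export
dialogue_initialize <- function(kb, start = NULL, vocab = dialogue_vocab(),
                                config = dialogue_config()) {
  utt_iris <- unique(kb$types$individual[vapply(
    kb$types$individual,
    function(i) vocab$utterance_class %in% infer_classes(kb, i),
    logical(1))])
  utt_iris <- sort(utt_iris)
  if (!length(utt_iris)) stop("no utterance individuals found in ontology")
  nodes <- lapply(utt_iris, build_node, kb = kb, vocab = vocab)
  names(nodes) <- utt_iris
  edges <- kb$assertions[kb$assertions$property == vocab$precedes,
                         c("domain", "range")]
  names(edges) <- c("from", "to")
  bad <- setdiff(unique(c(edges$from, edges$to)), utt_iris)
  if (length(bad)) {
    stop("precedence edges reference non-utterance nodes: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(start)) {
    entry <- setdiff(utt_iris, edges$to)
    if (length(entry) != 1L) {
      stop("cannot determine a unique entry utterance; pass `start`")
    }
    start <- entry
  }
  if (!start %in% utt_iris) {
    stop("start node is not an utterance individual: ", start)
  }
  nodes[[start]]$focus <- TRUE
  state <- list(nodes = nodes, edges = edges, focused = start,
                transcript = empty_transcript(), history = start,
                n_transitions = 0L, unintelligible_streak = 0L,
                complete = FALSE, truncated = FALSE,
                config = config, vocab = vocab,
                focus_violations = 0L)
  class(state) <- "cooqa_dialogue"
  state
}

#' @export
print.cooqa_dialogue <- function(x, ...) {
  cat("<cooqa_dialogue> ", length(x$nodes), " utterances | focus: ",
      iri_local(x$focused), " | ", nrow(x$transcript), " turns",
      if (x$complete) " | complete", "\n", sep = "")
  invisible(x)
}

#' Successor utterances of a node
#'
#' All nodes linked from `node` by the precedence property, in deterministic
#' IRI-sorted order.
#'
#' @param state A `cooqa_dialogue`.
#' @param node Node IRI.
#' @return Character vector of successor IRIs (possibly empty).
#' @export
node_successors <- function(state, node) {
  if (!node %in% names(state$nodes)) stop("unknown node: ", node)
  sort(state$edges$to[state$edges$from == node])
}

#' Move the focus flag to another node
#'
#' Sets `next_node` focused and clears the previous focus, preserving the
#' single-focus invariant (checked after every move).
#'
#' @param state A `cooqa_dialogue`.
#' @param next_node IRI of the node receiving focus.
#' @return The updated state.
#' @export
advance_focus <- function(state, next_node) {
  if (!next_node %in% names(state$nodes)) {
    stop("cannot advance to unknown node: ", next_node)
  }
  state$nodes[[state$focused]]$focus <- FALSE
  state$nodes[[next_node]]$focus <- TRUE
  state$focused <- next_node
  state$n_transitions <- state$n_transitions + 1L
  state$history <- c(state$history, next_node)
  nfoc <- sum(vapply(state$nodes, function(n) isTRUE(n$focus), logical(1)))
  if (nfoc != 1L) state$focus_violations <- state$focus_violations + 1L
  state
}

#' Classify a user utterance against participant candidates
#'
#' Each candidate is scored as the maximum over its expected-utterance
#' examples of the Monge-Elkan similarity between the example tokens and
#' the input tokens. A candidate reaching the strong-match threshold wins
#' outright (ties broken toward the lowest IRI, with a warning). Otherwise
#' an input carrying an interrogative cue (terminal "?" or a leading
#' interrogative keyword) is routed to a Question candidate when one exists
#' — transcribed speech rarely matches canned question examples closely.
#' Otherwise the best candidate wins if it reaches the match threshold;
#' failing all of these the input is unintelligible.
#'
#' @param text User utterance.
#' @param candidates List of participant utterance nodes.
#' @param config Engine configuration from [dialogue_config()].
#' @return List with `node` (the matched node or NULL), `category` (a
#'   participant category, or `"UNINTELLIGIBLE"`), and `scores`.
#' @export
classify_user_utterance <- function(text, candidates,
                                    config = dialogue_config()) {
  if (!length(candidates) || !nzchar(trimws(text))) {
    return(list(node = NULL, category = "UNINTELLIGIBLE", scores = numeric()))
  }
  toks <- function(x) {
    t <- strsplit(trimws(gsub("[^a-z0-9]+", " ", tolower(x))), "\\s+")[[1]]
    t[nzchar(t)]
  }
  input <- toks(text)
  scores <- vapply(candidates, function(nd) {
    if (!length(nd$examples)) return(0)
    max(vapply(nd$examples, function(ex) {
      monge_elkan(toks(ex), input)
    }, numeric(1)))
  }, numeric(1))
  best <- max(scores)
  pick_best <- function() {
    hits <- which(scores == best)
    if (length(hits) > 1L) {
      iris <- vapply(candidates[hits], `[[`, character(1), "iri")
      hits <- hits[order(iris)][1]
      warning("tie between participant branches; lowest IRI wins")
    }
    nd <- candidates[[hits[[1]]]]
    list(node = nd, category = nd$pcat, scores = scores)
  }
  if (best >= config$strong_match_threshold) return(pick_best())
  q_idx <- which(vapply(candidates, function(nd) {
    identical(nd$pcat, "QUESTION")
  }, logical(1)))
  if (length(q_idx)) {
    cue <- grepl("\\?\\s*$", text) ||
      (length(input) && input[1] %in% config$interrogatives)
    if (cue) {
      return(list(node = candidates[[q_idx[[1]]]], category = "QUESTION",
                  scores = scores))
    }
  }
  if (best >= config$match_threshold) return(pick_best())
  list(node = NULL, category = "UNINTELLIGIBLE", scores = scores)
}

# Target node for the segue after repeated unintelligible input: the
# successor of the Confirmation branch when present, else of the
# Disconfirmation branch.
segue_target <- function(state, candidates) {
  for (cat in c("CONFIRMATION", "DISCONFIRMATION")) {
    for (nd in candidates) {
      if (identical(nd$pcat, cat)) {
        succ <- node_successors(state, nd$iri)
        if (length(succ)) return(succ[[1]])
      }
    }
  }
  NULL
}

#' Execute one dialogue step
#'
#' A focused system utterance is spoken and the focus advances: directly
#' along a single system successor, or — when the successors are
#' participant branches — by obtaining user input, classifying it, and
#' advancing to the matched branch. A classified question is forwarded to
#' `qa_callback` and the answer spoken before continuing. Repeated
#' unintelligible input triggers the segue to the next topic. A focused
#' system utterance with no successor marks the dialogue complete.
#'
#' @param state A `cooqa_dialogue`.
#' @param input_provider Zero-argument function returning the next user
#'   line, or NULL when input is exhausted.
#' @param qa_callback Function of one argument (the question string)
#'   returning the answer text (or a `cooqa_answer`); NULL for a fixed
#'   no-answer reply.
#' @return The updated state.
#' @export
dialogue_step <- function(state, input_provider, qa_callback = NULL) {
  if (state$complete || state$truncated) return(state)
  cfg <- state$config
  node <- state$nodes[[state$focused]]

  if (node$category == "participant") {
    succ <- node_successors(state, node$iri)
    if (!length(succ)) {
      state$complete <- TRUE
      return(state)
    }
    if (length(succ) > 1L) {
      stop("participant utterance with multiple successors: ", node$iri)
    }
    return(advance_focus(state, succ[[1]]))
  }

  state <- add_turn(state, "agent", node$text, node$iri, node$primary_class)
  succ <- node_successors(state, node$iri)
  if (!length(succ)) {
    state$complete <- TRUE
    return(state)
  }
  cats <- vapply(succ, function(s) state$nodes[[s]]$category, character(1))
  if (all(cats == "system")) {
    if (length(succ) > 1L) {
      stop("system utterance with multiple system successors: ", node$iri)
    }
    return(advance_focus(state, succ[[1]]))
  }
  if (any(cats == "system")) {
    stop("mixed system/participant successors of ", node$iri)
  }

  candidates <- state$nodes[succ]
  repeat {
    input <- input_provider()
    if (is.null(input)) {
      state <- add_turn(state, "engine", cfg$truncation_marker,
                        category = "TRUNCATED")
      state$truncated <- TRUE
      return(state)
    }
    res <- classify_user_utterance(input, candidates, cfg)
    if (identical(res$category, "UNINTELLIGIBLE")) {
      state <- add_turn(state, "user", input, category = "UNINTELLIGIBLE")
      state$unintelligible_streak <- state$unintelligible_streak + 1L
      if (state$unintelligible_streak >= cfg$max_unintelligible) {
        state$unintelligible_streak <- 0L
        target <- segue_target(state, candidates)
        state <- add_turn(state, "agent", cfg$segue_line)
        if (is.null(target)) {
          state$complete <- TRUE
          return(state)
        }
        return(advance_focus(state, target))
      }
      state <- add_turn(state, "agent", cfg$retry_line)
      next
    }
    state$unintelligible_streak <- 0L
    state <- add_turn(state, "user", input, res$node$iri, res$category)
    state <- advance_focus(state, res$node$iri)
    if (identical(res$category, "QUESTION")) {
      ans <- if (is.null(qa_callback)) {
        qa_config()$no_answer_line
      } else {
        qa_callback(input)
      }
      if (inherits(ans, "cooqa_answer")) ans <- ans$text
      state <- add_turn(state, "agent", ans, category = "ANSWER")
    }
    return(state)
  }
}

#' Run a dialogue over scripted user inputs
#'
#' Loops [dialogue_step()] until the dialogue completes or the scripted
#' inputs are exhausted while a participant turn is pending (recorded as a
#' truncation row in the transcript).
#'
#' @param state A `cooqa_dialogue` from [dialogue_initialize()].
#' @param inputs Character vector of scripted user lines.
#' @param qa_callback Question callback, as in [dialogue_step()].
#' @param max_steps Safety bound on engine steps.
#' @return The final state; the transcript is in `$transcript` and the
#'   visited focus sequence in `$history`.
#' @export
dialogue_run <- function(state, inputs, qa_callback = NULL, max_steps = 500L) {
  i <- 0L
  provider <- function() {
    i <<- i + 1L
    if (i > length(inputs)) NULL else inputs[[i]]
  }
  steps <- 0L
  while (!state$complete && !state$truncated && steps < max_steps) {
    state <- dialogue_step(state, provider, qa_callback)
    steps <- steps + 1L
  }
  if (steps >= max_steps) warning("dialogue stopped at max_steps")
  state
}

#' Build a QA callback bound to a knowledge base
#'
#' @param kb A `cooqa_kb`.
#' @param backend `"string"` or `"vector"`.
#' @param lex,embeddings,cfg Passed to [answer_question()].
#' @return A function of one argument suitable for [dialogue_run()].
#' @export
make_qa_callback <- function(kb, backend = "string",
                             lex = load_lexical_table(), embeddings = NULL,
                             cfg = qa_config()) {
  force(kb); force(backend); force(lex); force(embeddings); force(cfg)
  function(question) {
    answer_question(question, kb, backend = backend, lex = lex,
                    embeddings = embeddings, cfg = cfg)$text
  }
}

#' Write a transcript as JSON lines
#'
#' One JSON object per turn with fields `speaker`, `text`, `node_iri`,
#' `category`.
#'
#' @param state A `cooqa_dialogue`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(state, path) {
  tr <- state$transcript
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(list(speaker = tr$speaker[i], text = tr$text[i],
                          node_iri = tr$node[i], category = tr$category[i]),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
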