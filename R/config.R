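# Tunable configuration for the QA pipeline and the dialogue engine.

#' QA pipeline configuration
#'
#' Defaults implement the published filtering rules: candidates are gated on
#' the top object-assertion score exceeding 0.50, in which case the top 20%
#' of object+data assertions by rank are kept (boundary ties included);
#' otherwise all object+data assertions scoring above 0.45 are kept.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
qa_config <- function(...) {
  cfg <- list(
    top_gate = 0.50,            # gate on the best object-assertion score
    top_fraction = 0.20,        # rank fraction kept when the gate opens
    fallback_threshold = 0.45,  # absolute cutoff otherwise
    boost = 1.25,               # synonym multiplier
    synonym_depth = 3,          # lexical graph depth for synonymy
    identity_synonym = TRUE,
    entity_aggregate = "max",
    max_triples = 3L,           # spoken answers stay short
    class_filter_permissive = FALSE,
    number_words = c("zero", "one", "two", "three", "four", "five", "six",
                     "seven", "eight", "nine", "ten"),
    no_answer_line = "I am sorry, I do not have an answer for that.",
    swg = list(match = 1, mismatch = -1, gap = -0.5)
  )
  utils::modifyList(cfg, list(...))
}

#' Dialogue engine configuration
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
dialogue_config <- function(...) {
  cfg <- list(
    match_threshold = 0.5,      # participant-utterance match cutoff
    strong_match_threshold = 0.75,  # outranks the interrogative cue
    max_unintelligible = 2L,    # consecutive failures before the segue
    interrogatives = c("who", "what", "when", "where", "why", "how", "can",
                       "does", "is", "are", "do", "could", "would", "will",
                       "should"),
    retry_line = "I am sorry, I did not catch that. Could you say that again?",
    segue_line = "Let us move on to the next topic.",
    truncation_marker = "<input exhausted>"
  )
  utils::modifyList(cfg, list(...))
}

#' Load configuration overrides from a YAML file
#'
#' Top-level keys `qa` and `dialogue` are merged over [qa_config()] and
#' [dialogue_config()].
#'
#' @param path YAML file.
#' @return List with elements `qa` and `dialogue`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  list(qa = do.call(qa_config, as.list(raw$qa %||% list())),
       dialogue = do.call(dialogue_config, as.list(raw$dialogue %||% list())))
}
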