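# Question analysis: term cleaning, keyword question typing, and a
# lexicon-driven noun/verb phrase chunker.

QUESTION_TYPES <- c("UNKNOWN", "ALL", "COUNT", "MAX", "MIN", "NUMERIC")

# Keyword table. Only the COUNT cues are fixed by the classification scheme
# this follows; the remaining rows are package defaults and can be overridden
# via the `keywords` argument. Precedence: COUNT > MAX > MIN > NUMERIC > ALL.
default_type_keywords <- function() {
  list(
    COUNT   = c("how many", "the number of"),
    MAX     = c("most", "maximum", "highest", "largest"),
    MIN     = c("least", "minimum", "lowest", "smallest"),
    NUMERIC = c("how much", "how old", "what age", "what number"),
    ALL     = c("list all", "what are all", "give me all")
  )
}

#' Classify the question type
#'
#' Six-way keyword classification: `COUNT` ("how many", "the number of"),
#' `MAX`, `MIN`, `NUMERIC`, `ALL`, and `UNKNOWN` when no cue fires.
#' Multi-word cues match as substrings, single-word cues at word boundaries,
#' in precedence order COUNT > MAX > MIN > NUMERIC > ALL.
#'
#' @param text Question string.
#' @param keywords Cue table (named list of character vectors), defaults to
#'   [default_type_keywords()].
#' @return One of `"UNKNOWN"`, `"ALL"`, `"COUNT"`, `"MAX"`, `"MIN"`,
#'   `"NUMERIC"`.
#' @examples
#' classify_question_type("how many cancers does hpv cause")
#' @export
classify_question_type <- function(text, keywords = default_type_keywords()) {
  stopifnot(is.character(text), length(text) == 1L)
  low <- tolower(text)
  for (ty in c("COUNT", "MAX", "MIN", "NUMERIC", "ALL")) {
    for (kw in keywords[[ty]]) {
      pat <- if (grepl(" ", kw, fixed = TRUE)) {
        kw
      } else {
        paste0("\\b", kw, "\\b")
      }
      if (grepl(pat, low, fixed = !grepl("\\\\b", pat))) return(ty)
    }
  }
  "UNKNOWN"
}

# Irregular inflection table for the rule lemmatizer.
IRREGULAR_LEMMAS <- c(
  does = "do", did = "do", done = "do", is = "be", are = "be", was = "be",
  were = "be", been = "be", am = "be", has = "have", had = "have",
  goes = "go", went = "go", gone = "go", said = "say", took = "take",
  taken = "take", gave = "give", given = "give", got = "get",
  gotten = "get", made = "make", men = "man", women = "woman",
  children = "child", feet = "foot", better = "good", worse = "bad"
)

ends_with <- function(x, suffix) {
  nx <- nchar(x); ns <- nchar(suffix)
  nx >= ns && substr(x, nx - ns + 1L, nx) == suffix
}

drop_suffix <- function(x, n) substr(x, 1L, nchar(x) - n)

# Map one lowercased word to its dictionary root: irregulars, then plural
# stripping, then -ing/-ed verb endings (restoring a final "e" or undoubling
# a final consonant when that recovers a known verb).
lemmatize_word <- function(word, verbs = verb_lexicon()) {
  if (word %in% names(IRREGULAR_LEMMAS)) return(IRREGULAR_LEMMAS[[word]])
  w <- word
  n <- nchar(w)
  if (ends_with(w, "ies") && n > 4L) {
    w <- paste0(drop_suffix(w, 3L), "y")
  } else if (ends_with(w, "sses")) {
    w <- drop_suffix(w, 2L)
  } else if ((ends_with(w, "xes") || ends_with(w, "ches") ||
              ends_with(w, "shes") || ends_with(w, "zes")) && n > 4L) {
    w <- drop_suffix(w, 2L)
  } else if (ends_with(w, "s") && !ends_with(w, "ss") &&
             !ends_with(w, "us") && !ends_with(w, "is") && n > 3L) {
    w <- drop_suffix(w, 1L)
  }
  for (suf in c("ing", "ed")) {
    if (ends_with(w, suf) && nchar(w) > nchar(suf) + 2L) {
      stem <- drop_suffix(w, nchar(suf))
      if (stem %in% verbs) return(stem)
      if (paste0(stem, "e") %in% verbs) return(paste0(stem, "e"))
      undoubled <- drop_suffix(stem, 1L)
      if (nchar(stem) >= 2L &&
          substr(stem, nchar(stem), nchar(stem)) ==
            substr(stem, nchar(stem) - 1L, nchar(stem) - 1L) &&
          undoubled %in% verbs) {
        return(undoubled)
      }
    }
  }
  w
}

pkg_wordlist <- function(file) {
  path <- system.file("extdata", file, package = "cooqa")
  if (path == "") path <- file.path("inst", "extdata", file)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

the_stopwords <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pkg_wordlist("stopwords_top100.txt")
    cache
  }
})

verb_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pkg_wordlist("verb_lexicon.txt")
    cache
  }
})

#' Clean a phrase into root-form terms
#'
#' Lowercases, strips underscores and other special characters, tokenizes,
#' removes common words (a fixed 100-entry function-word list shipped with
#' the package), lemmatizes each token to its dictionary root, and removes
#' duplicates while preserving order.
#'
#' @param phrase A string (may contain underscores, punctuation, digits).
#' @param stopwords Common-word list; defaults to the shipped list.
#' @return Character vector of cleaned terms (possibly empty).
#' @examples
#' clean_terms("insurance_plans plans")
#' @export
clean_terms <- function(phrase, stopwords = the_stopwords()) {
  if (is.na(phrase) || !nzchar(phrase)) return(character())
  low <- tolower(phrase)
  low <- gsub("[^a-z0-9]+", " ", low)
  toks <- strsplit(trimws(low), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% stopwords)]
  if (!length(toks)) return(character())
  toks <- vapply(toks, lemmatize_word, character(1), USE.NAMES = FALSE)
  toks <- toks[!(toks %in% stopwords)]
  unique(toks)
}

WH_WORDS <- c("who", "what", "when", "where", "why", "how", "which", "whom",
              "whose")
AUX_WORDS <- c("do", "does", "did", "is", "are", "was", "were", "be", "been",
               "am", "can", "could", "will", "would", "should", "shall",
               "may", "might", "must", "have", "has", "had")
EXTRA_FUNCTION_WORDS <- c("please", "ok", "okay", "hi", "hello", "yes",
                          "really")

#' Extract noun and verb phrases from a question
#'
#' A lexicon-driven chunker: tokens are tagged as wh-words, auxiliaries,
#' function words (the shipped common-word list), verbs (tokens whose lemma
#' is in the shipped verb lexicon), or nouns; maximal runs of noun tokens
#' become noun phrases and maximal runs of verb tokens become verb phrases.
#' If no noun phrase is found, all content tokens are returned as a single
#' noun phrase so the question remains processable.
#'
#' @param text Question string.
#' @return A list with character vectors `noun_phrases` and `verb_phrases`
#'   (raw, uncleaned phrase strings).
#' @examples
#' extract_phrases("insurance covers the hpv vaccine")
#' @export
extract_phrases <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  low <- gsub("[^a-z0-9]+", " ", tolower(text))
  toks <- strsplit(trimws(low), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list(noun_phrases = character(),
                                 verb_phrases = character()))
  funcwords <- unique(c(the_stopwords(), EXTRA_FUNCTION_WORDS))
  tag <- vapply(toks, function(tk) {
    if (tk %in% WH_WORDS) return("WH")
    if (tk %in% AUX_WORDS) return("AUX")
    if (lemmatize_word(tk) %in% verb_lexicon()) return("VERB")
    if (tk %in% funcwords) return("STOP")
    "NOUN"
  }, character(1), USE.NAMES = FALSE)
  runs <- function(which_tag) {
    r <- rle(tag == which_tag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    vapply(keep, function(k) paste(toks[starts[k]:ends[k]], collapse = " "),
           character(1))
  }
  nps <- runs("NOUN")
  vps <- runs("VERB")
  if (!length(nps)) {
    content <- toks[!(tag %in% c("STOP", "AUX", "WH"))]
    if (length(content)) nps <- paste(content, collapse = " ")
  }
  list(noun_phrases = nps, verb_phrases = vps)
}

#' Parse a user question
#'
#' Runs phrase extraction, term cleaning, and question typing, producing the
#' structure the scoring stage consumes.
#'
#' @param text Question string.
#' @param keywords Question-type cue table.
#' @return An object of class `cooqa_question`: list with `raw`, `qtype`,
#'   `noun_phrases` and `verb_phrases` (lists of cleaned term vectors;
#'   phrases whose terms all clean away are dropped).
#' @examples
#' parse_question("how does hpv affect males")
#' @export
parse_question <- function(text, keywords = default_type_keywords()) {
  phrases <- extract_phrases(text)
  np <- lapply(phrases$noun_phrases, clean_terms)
  vp <- lapply(phrases$verb_phrases, clean_terms)
  np <- np[vapply(np, length, integer(1)) > 0L]
  vp <- vp[vapply(vp, length, integer(1)) > 0L]
  out <- list(raw = text, qtype = classify_question_type(text, keywords),
              noun_phrases = np, verb_phrases = vp)
  class(out) <- "cooqa_question"
  out
}

#' @export
print.cooqa_question <- function(x, ...) {
  cat("<cooqa_question> [", x$qtype, "] ", x$raw, "\n  noun terms: ",
      paste(vapply(x$noun_phrases, paste, character(1), collapse = " "),
            collapse = " | "),
      "\n  verb terms: ",
      paste(vapply(x$verb_phrases, paste, character(1), collapse = " "),
            collapse = " | "), "\n", sep = "")
  invisible(x)
}
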