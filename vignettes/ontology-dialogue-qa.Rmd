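---
title: "Ontology-driven counseling dialogue and ontology question answering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven counseling dialogue and ontology question answering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooqa)
```

## The model

`cooqa` implements two cooperating engines for spoken health counseling.

The **dialogue engine** treats a conversation as a walk over an utterance
graph stored in an OWL ontology. Every turn — machine or human — is an
individual of an `Utterance` class hierarchy, split into `System_Utterance`
(what the agent says, carried in a `hasUtteranceText` data property) and
`Participant_Utterance` (what a user is expected to say, carried as example
strings in `hasUtteranceExample`). A boolean data property `hasFocus` marks
the single utterance where the conversation currently stands, and the object
property `precedes` links each utterance to its possible successors. One
engine step reads the focused node: a system utterance is spoken and the
focus moves along its single outgoing link; when the successors are
participant branches, the user's line is classified against the branches'
example strings and the focus moves to the matched branch. An utterance
classified as a question is handed to the QA subsystem and its answer is
spoken before the walk continues. Class membership (system vs participant,
and the participant categories confirmation / disconfirmation / question /
repeat-request) is derived structurally: asserted types plus the transitive
closure of `rdfs:subClassOf`. A full description-logic reasoner would
subsume this; the structural closure is deterministic, dependency-free, and
covers every behavior the utterance ontologies exercise, since their class
axioms are plain named-class hierarchies.

The **QA subsystem** answers a free-text question from a domain knowledge
base in four stages:

1. *Extraction.* Three assertion families are mined from the ontology:
   object-property assertions (instance → instance), data-property
   assertions (instance → literal), and class assertions (schema-level
   triples whose subject and object are both declared classes). Each is
   parsed into (domain, property, range).
2. *Question analysis.* Noun and verb phrases are chunked out of the
   question, terms are cleaned (lowercasing, underscore and punctuation
   stripping, removal of a fixed 100-entry common-word list, rule-based
   lemmatization to dictionary roots, de-duplication), and the question is
   typed by keyword: COUNT ("how many", "the number of"), MAX, MIN,
   NUMERIC, ALL, else UNKNOWN.
3. *Scoring.* Every triple is scored against the question under one of two
   pluggable backends: **string** — Monge-Elkan token-set similarity whose
   inner metric is a normalized Smith-Waterman-Gotoh character alignment —
   or **vector** — cosine similarity of mean term embeddings. The triple's
   predicate label is compared with the verb phrases and its domain/range
   labels with the noun phrases (the best-matching entity wins). Each
   comparison then passes a lexical-relation adjustment: a synonym pair
   within graph depth 3 boosts the score by 25% (capped at 1); the complete
   absence of any synonym/hypernym/hyponym relation zeroes it; any other
   relation leaves it unchanged. The triple's combined score is the mean of
   predicate and entity scores, or the entity score alone when the question
   has no verb phrase.
4. *Filtering.* If the best object-assertion score exceeds 0.50, the top
   20% of object+data assertions by rank are kept (boundary ties included);
   otherwise every object+data assertion above 0.45 is kept. COUNT/MAX/MIN
   (and NUMERIC) questions then keep only candidates whose labels carry
   numeric content (digits or the words "zero" … "ten"); all other
   questions pass a class-assertion cross-check — a candidate survives only
   if one of the class assertions it instantiates (via the type closure of
   its domain and range) sits in the top 20% of scored class assertions.
   Survivors are verbalized ("Throat cancer affects males.") or, when none
   survive, a fixed no-answer line is returned.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_gate` | 0.50 | gate on the best object-assertion score |
| `top_fraction` | 0.20 | rank fraction kept when the gate opens |
| `fallback_threshold` | 0.45 | absolute cutoff when it does not |
| `boost` | 1.25 | synonym multiplier |
| `synonym_depth` | 3 | lexical graph depth bounding synonymy |
| `max_triples` | 3 | answer cardinality cap (spoken answers stay short) |
| `swg` (match/mismatch/gap) | +1 / −1 / −0.5 | alignment scores, linear gaps |
| `match_threshold` | 0.5 | participant-branch match cutoff |
| `strong_match_threshold` | 0.75 | outranks the interrogative cue |
| `max_unintelligible` | 2 | consecutive failures before the segue |

The gate, fraction, fallback, boost, zeroing rule, depth bound, and the
COUNT keywords are the published filtering calibration and are not tuned
here. The alignment parameterization (match +1, mismatch −1, gap −0.5 with
open = extend, normalization by the longer string, clamped to [0, 1]) is a
package choice — any consistent parameterization satisfies the method's
description, and pinning one makes every test exact. The keyword rows for
MAX/MIN/NUMERIC/ALL are package defaults (only the COUNT cues are fixed by
the classification scheme this follows); both tables are overridable.

## Design choices where the design was open

- **Top 20% by rank, not by score.** "Top 20%" is read as the top
  `ceiling(0.2 N)` triples by rank; ties at the boundary are all included so
  no triple is dropped arbitrarily. The >0.45 fallback is not further
  trimmed.
- **Entity aggregation is max.** The best-matching entity (domain or range)
  against the best-matching noun phrase determines the entity score — the
  most selective reading of "entities are compared with the noun phrases".
- **The adjustment applies per comparison**, not to the combined score:
  predicate and entity comparisons are adjusted independently, so an
  unrelated predicate zeroes only the predicate half.
- **Identical terms count as synonyms** (a word trivially shares its own
  synset, depth 0), so exact lexical matches receive the 25% boost before
  clamping. Switchable via `identity_synonym`.
- **Monge-Elkan direction.** For triple scoring, each triple-label term
  seeks its best match among the question-phrase terms. For participant
  classification the direction is reversed — each *example* token seeks its
  match in the *input* — so a short canonical example ("yes") matches a
  longer actual reply ("yes i understand").
- **Question routing is tiered.** A participant branch matching at ≥ 0.75
  wins outright; otherwise an interrogative cue (terminal "?" or a leading
  who/what/when/where/why/how/can/does/is/are…) routes to a Question branch
  when one exists; otherwise the best branch ≥ 0.5 wins; otherwise the
  input is unintelligible. Cue-first alone misroutes "can you repeat that";
  best-match-first alone lets chance character alignments of short function
  words ("yes" vs "does" aligns "es" for exactly 0.5) capture real
  questions. Transcribed speech rarely matches canned question examples, so
  robust question capture needs the cue tier.
- **Unintelligible handling.** After two consecutive unclassifiable inputs
  the agent emits a segue line and the focus jumps to the successor of the
  confirmation branch (else the disconfirmation branch) — the conversation
  moves on to the next health topic rather than stalling.
- **Data-property triples in the class cross-check** match on domain class
  and property only: their ranges are literals and carry no type closure, so
  a range requirement would make every data assertion unanswerable outside
  the numeric path.
- **Class assertions are plain class-to-class triples.** The fixture
  ontologies assert schema triples such as `Disease affects People`
  directly between declared classes; the loader classifies any such triple
  as a class assertion. This stands in for reasoner-derived TBox queries
  over a production ontology and supports the same downstream filtering.

## What the fixtures emulate — and what they do not

`generate_dialogue_ontology()` reproduces a two-topic counseling structure:
greeting; a first health-information block with the full branch set
(confirm, repeat, disconfirm → question prompt → provider referral, and the
direct-question path with an "another question?" loop); a second block with
confirm and repeat; and a closing — 19 utterance individuals in total, all
`hasFocus` flags serialized false. `generate_toy_kb()` builds a small
vaccine knowledge base containing insurance-coverage, causation,
prevention, dose-count, and minimum-age assertions, the worked-example
triple `throat_cancer → affects → males` with its class-level support
(`Disease → affects → People`; `Males ⊑ People_of_Gender ⊑ People`), and a
deterministic draw of extra disease–population assertions. The shipped
embedding table (33 terms, 8 dimensions, hand-constructed so related terms
share directions) and lexical-relation table (19 entries with explicit
depths) pin both similarity backends without any corpus or model download.
`scripted_sessions()` provides nine user scripts with their expected focus
traversals, covering every reachable participant branch.

Passing tests on these fixtures demonstrate the *mechanics* — traversal,
classification, scoring, filtering, verbalization — under controlled
vocabulary. They do not demonstrate robustness to a production-scale
ontology (thousands of assertions with noisy labels), to a full WordNet and
embedding vocabulary, or to genuinely unconstrained speech transcription;
answer quality on such inputs is an empirical question the package does not
measure.

## Numerical choices and degenerate inputs

Similarity scores are clamped to [0, 1] after normalization; empty strings
and empty term lists score 0 by contract rather than raising. Branch-score
ties are broken toward the lowest IRI with a warning; successor lists are
IRI-sorted so every traversal is deterministic. Chunker failure (a question
with no recognizable noun phrase) falls back to treating all content tokens
as a single noun phrase. Every QA failure mode degrades to the explicit
no-answer marker, never an error. Problem sizes in the test suite are
chosen so the whole suite runs in well under a minute: the Monge-Elkan
brute-force comparison enumerates all ordered pairs of token lists of size
≤ 2 over a 6-token alphabet exhaustively plus thousands of seeded random
larger pairs, and the alignment comparison enumerates all ordered string
pairs of length ≤ 3 over a 3-letter alphabet exhaustively plus seeded
random pairs up to length 8, against an independent local-alignment oracle.

## Known limitations

- No multi-hop reasoning: answers are single triples, not chains.
- MAX/MIN questions filter for numeric content but do not compare
  magnitudes.
- The rule lemmatizer and lexicon-driven chunker cover the counseling
  vocabulary; they are not general-purpose NLP components.
- The structural type inference ignores OWL constructs beyond named-class
  subsumption (no property chains, disjointness, or cardinality).
- Dialogue policies are fixed by the ontology; there is no learning, no
  barge-in, and no timeout on user input.
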