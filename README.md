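# cooqa

Ontology-driven health-counseling dialogue management and ontology question
answering in R.

## The problem

Health-counseling agents (for example, an HPV-vaccine counseling assistant)
need two capabilities: a **dialogue manager** that delivers pieces of health
information in order, confirms understanding, repeats on request, and copes
with misunderstanding; and a **question-answering subsystem** that, when the
user interjects a question, finds an answer in a domain knowledge base and
speaks it. `cooqa` implements both, driving the conversation entirely from
an OWL ontology so the counseling script is data, not code. It is aimed at
consumer-health-informatics researchers prototyping ontology-based
conversational agents.

## The method

**Dialogue.** A conversation is a walk over utterance individuals in an
ontology. A boolean data property `hasFocus` marks the current turn; the
object property `precedes` defines the possible successors; system
utterances carry their spoken text, participant utterances carry example
strings (`hasUtteranceExample`) of what the user is expected to say. Each
engine step speaks the focused system utterance and advances the focus —
directly, or by classifying the user's reply against the participant
branches with Monge-Elkan string similarity. Replies classified as
questions are delegated to the QA subsystem.

**Question answering.** Object-property, data-property, and class
assertions `(domain, property, range)` are extracted from a knowledge-base
ontology. A question is chunked into noun and verb phrases, cleaned
(stop-listing, lemmatization), and keyword-typed (COUNT / MAX / MIN /
NUMERIC / ALL / UNKNOWN). Each triple is scored against the question —

    predicate vs verb phrases,  entities (domain, range) vs noun phrases

under a string backend (Monge-Elkan over a normalized Smith-Waterman-Gotoh
character alignment: match +1, mismatch −1, gap −0.5) or a vector backend
(cosine of mean term embeddings). Scores are adjusted by lexical relations:
synonyms within graph depth 3 boost a score by 25% (capped at 1); the
absence of any synonym/hypernym/hyponym relation zeroes it. The combined
score is the mean of the predicate and entity scores. Filtering: if the
best object-assertion score exceeds 0.50 the top 20% of object+data
assertions by rank are kept, otherwise all above 0.45; quantity-type
questions then require numeric content in the labels, and all other
questions require the candidate to instantiate one of the top 20% scored
class assertions (for example, `throat_cancer → affects → males` survives
because `Disease → affects → People` ranks at the top of the class
assertions). Survivors are verbalized; an empty selection yields an
explicit no-answer line.

## Worked example

```r
library(cooqa)

dir <- tempfile(); dir.create(dir)
dlg <- generate_dialogue_ontology(file.path(dir, "dialogue.owl"))
kb  <- load_ontology(generate_toy_kb(file.path(dir, "kb.owl")))
kb
#> <cooqa_kb> 31 entities | assertions: 6 object, 2 data, 4 class | 4 subclass edges

answer_question("how does hpv affect males", kb, backend = "string")
#> <cooqa_answer> [UNKNOWN/string] how does hpv affect males
#>   answered: TRUE
#>   Throat cancer affects males; also, cervical cancer affects females; also, measles affects children.

state <- dialogue_initialize(load_ontology(dlg))
state <- dialogue_run(state, scripted_sessions()$question_answered$inputs,
                      make_qa_callback(kb, "string"))
state$transcript[, c("speaker", "text")]
```

The transcript shows the full counseling flow — the agent greets, states a
health fact, asks for confirmation, answers the interjected question from
the knowledge base, offers another question, and on "nope no question"
segues to the next health topic and closes:

```
agent> Hello. Let us talk about the HPV vaccine.
agent> The HPV vaccine is available to you regardless of your insurance status.
agent> You following me so far?
user>  how does hpv affect males
agent> Throat cancer affects males; also, cervical cancer affects females; also, measles affects children.
agent> Do you have another question?
user>  nope no question
agent> Some people believe the HPV vaccine has long-term side effects, but there is no evidence for that misbelief.
agent> You following me so far?
user>  yes
agent> That is all I have for today. Thank you for listening.
```

The `answered: TRUE` line reflects that the worked-example triple
`throat_cancer → affects → males` scored 1.0 (predicate "affects" matches
the verb "affect" after lemmatization; entity "males" matches the noun
"males"), opened the 0.50 gate, and passed the class-assertion cross-check.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/coo.R fixtures --out fixtures/
Rscript inst/cli/coo.R run --dialogue fixtures/dialogue.owl --kb fixtures/kb.owl \
        --script fixtures/session_confirm.txt
Rscript inst/cli/foqus.R ask --kb fixtures/kb.owl \
        --question "how many doses of the hpv vaccine do i need" --explain
```

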