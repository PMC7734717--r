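Package: cooqa
Title: Ontology-Driven Health Counseling Dialogue and Ontology Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dialogue manager that conducts health-counseling conversations by
    walking an utterance graph stored in an OWL ontology (a focus flag marks the
    current turn, precedence links define the flow), together with a question
    answering subsystem that extracts object-, data-, and class-assertion triples
    from a domain knowledge base, scores them against the noun and verb phrases of
    a natural-language question with Monge-Elkan / Smith-Waterman-Gotoh string
    similarity or embedding cosine similarity, adjusts scores with lexical
    (synonym/hypernym/hyponym) relations, and filters candidates by threshold,
    rank, numeric content, and a class-assertion cross-check before verbalizing
    the answer. Includes deterministic generators for a replica counseling
    dialogue ontology and a toy vaccine knowledge base, plus scripted user
    sessions covering the canonical counseling flows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
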