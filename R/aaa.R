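# Shared constants and small utilities.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

IRI_TYPE       <- paste0(RDF_NS, "type")
IRI_SUBCLASS   <- paste0(RDFS_NS, "subClassOf")
IRI_LABEL      <- paste0(RDFS_NS, "label")
IRI_CLASS      <- paste0(OWL_NS, "Class")
IRI_OBJPROP    <- paste0(OWL_NS, "ObjectProperty")
IRI_DATAPROP   <- paste0(OWL_NS, "DatatypeProperty")
IRI_NAMED_IND  <- paste0(OWL_NS, "NamedIndividual")
IRI_ONTOLOGY   <- paste0(OWL_NS, "Ontology")
IRI_ANNPROP    <- paste0(OWL_NS, "AnnotationProperty")

`%||%` <- function(a, b) if (is.null(a)) b else a
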