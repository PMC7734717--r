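# Minimal RDF triple I/O: RDF/XML via xml2, plus a constrained line-oriented
# Turtle dialect (the subset the fixture generators emit: @prefix headers and
# one triple per statement, `a` shorthand, plain or ^^-typed quoted literals).


empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), is_literal = logical(),
             stringsAsFactors = FALSE)
}

triple_df <- function(subject, predicate, object, is_literal = FALSE) {
  data.frame(subject = subject, predicate = predicate, object = object,
             is_literal = is_literal, stringsAsFactors = FALSE)
}

iri_local <- function(iri) {
  sub("^.*[#/]", "", iri)
}

iri_namespace <- function(iri) {
  sub("[^#/]*$", "", iri)
}

#' Read an RDF graph from disk
#'
#' Parses an RDF/XML (`.owl`, `.rdf`, `.xml`) or constrained Turtle (`.ttl`)
#' file into a flat triple table.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"rdfxml"`, or `"turtle"`.
#' @return A data.frame with columns `subject`, `predicate`, `object`,
#'   `is_literal`.
#' @export
read_rdf <- function(path, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read ontology file (no such file): ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ttl", "nt")) "turtle" else "rdfxml"
  }
  if (format == "rdfxml") read_rdfxml(path) else read_turtle(path)
}

read_rdfxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse RDF/XML in '", path, "': ", conditionMessage(e))
  })
  ns <- xml2::xml_ns(doc)
  nsmap <- as.character(ns)
  names(nsmap) <- names(ns)
  expand <- function(qname) {
    parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(nsmap)) {
      paste0(nsmap[[parts[1]]], parts[2])
    } else {
      qname
    }
  }
  rows <- list()
  for (node in xml2::xml_children(doc)) {
    subj <- xml2::xml_attr(node, "about")
    if (is.na(subj)) {
      warning("skipping blank-node subject in ", path)
      next
    }
    el <- expand(xml2::xml_name(node, ns))
    if (el != paste0(RDF_NS, "Description")) {
      rows[[length(rows) + 1L]] <- triple_df(subj, IRI_TYPE, el)
    }
    for (prop in xml2::xml_children(node)) {
      pred <- expand(xml2::xml_name(prop, ns))
      res <- xml2::xml_attr(prop, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- triple_df(subj, pred, res)
      } else {
        rows[[length(rows) + 1L]] <-
          triple_df(subj, pred, xml2::xml_text(prop), is_literal = TRUE)
      }
    }
  }
  if (!length(rows)) return(empty_triples())
  do.call(rbind, rows)
}

read_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prefixes <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (grepl("^@prefix", line)) {
      m <- regmatches(line,
        regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*)?:\\s*<([^>]*)>\\s*\\.\\s*$", line))[[1]]
      if (length(m) < 3L) {
        stop("cannot parse Turtle prefix at ", path, ":", i, ": ", line)
      }
      prefixes[[if (m[2] == "") "" else m[2]]] <- m[3]
      next
    }
    if (!grepl("\\.\\s*$", line)) {
      stop("cannot parse Turtle statement at ", path, ":", i,
           " (expected one `s p o .` triple per line): ", line)
    }
    body <- sub("\\.\\s*$", "", line)
    toks <- turtle_tokens(body, path, i)
    if (length(toks) != 3L) {
      stop("cannot parse Turtle statement at ", path, ":", i, ": ", line)
    }
    subj <- turtle_term(toks[[1]], prefixes, path, i)
    pred <- if (identical(toks[[2]], "a")) {
      list(value = IRI_TYPE, literal = FALSE)
    } else {
      turtle_term(toks[[2]], prefixes, path, i)
    }
    obj <- turtle_term(toks[[3]], prefixes, path, i)
    rows[[length(rows) + 1L]] <-
      triple_df(subj$value, pred$value, obj$value, obj$literal)
  }
  if (!length(rows)) return(empty_triples())
  do.call(rbind, rows)
}

# Split a Turtle statement body into three terms, honoring quoted literals.
turtle_tokens <- function(body, path, lineno) {
  toks <- list()
  rest <- trimws(body)
  while (nzchar(rest)) {
    if (startsWith(rest, "\"")) {
      m <- regexpr('^"(\\\\.|[^"\\\\])*"(\\^\\^\\S+)?', rest)
      if (m == -1L) stop("unterminated literal at ", path, ":", lineno)
      tok <- substr(rest, 1L, attr(m, "match.length"))
    } else {
      tok <- sub("\\s.*$", "", rest)
    }
    toks[[length(toks) + 1L]] <- tok
    rest <- trimws(substr(rest, nchar(tok) + 1L, nchar(rest)))
  }
  toks
}

turtle_term <- function(tok, prefixes, path, lineno) {
  if (startsWith(tok, "<")) {
    return(list(value = sub("^<|>$", "", gsub("^<(.*)>$", "\\1", tok)),
                literal = FALSE))
  }
  if (startsWith(tok, "\"")) {
    lit <- sub('\\^\\^\\S+$', "", tok)
    lit <- substr(lit, 2L, nchar(lit) - 1L)
    lit <- gsub('\\\\"', '"', lit, fixed = FALSE)
    lit <- gsub("\\\\\\\\", "\\\\", lit)
    return(list(value = lit, literal = TRUE))
  }
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c("", parts)
  if (!parts[1] %in% names(prefixes) &&
      !("" %in% names(prefixes) && parts[1] == "")) {
    stop("undeclared Turtle prefix '", parts[1], "' at ", path, ":", lineno)
  }
  list(value = paste0(prefixes[[parts[1]]], parts[2]), literal = FALSE)
}

#' Write a triple table to disk
#'
#' @param triples Triple data.frame as returned by [read_rdf()].
#' @param path Output file path.
#' @param format `"rdfxml"` or `"turtle"` (default: by extension, RDF/XML
#'   unless the extension is `.ttl`).
#' @return `path`, invisibly.
#' @export
write_rdf <- function(triples, path, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "ttl") "turtle" else "rdfxml"
  }
  if (format == "rdfxml") write_rdfxml(triples, path) else write_turtle(triples, path)
  invisible(path)
}

rdf_prefix_map <- function(triples) {
  iris <- c(triples$subject, triples$predicate,
            triples$object[!triples$is_literal])
  nss <- unique(iri_namespace(iris))
  nss <- nss[nzchar(nss)]
  known <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS)
  map <- known
  extra <- setdiff(nss, known)
  if (length(extra)) {
    names(extra) <- paste0("ns", seq_along(extra))
    map <- c(map, extra)
  }
  map
}

rdf_qname <- function(iri, map) {
  ns <- iri_namespace(iri)
  hit <- match(ns, map)
  if (is.na(hit)) stop("cannot abbreviate IRI: ", iri)
  paste0(names(map)[hit], ":", iri_local(iri))
}

write_rdfxml <- function(triples, path) {
  map <- rdf_prefix_map(triples)
  attrs <- stats::setNames(as.list(unname(map)), paste0("xmlns:", names(map)))
  doc <- xml2::xml_new_root("rdf:RDF", .encoding = "UTF-8")
  for (nm in names(attrs)) xml2::xml_set_attr(doc, nm, attrs[[nm]])
  for (subj in unique(triples$subject)) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = subj)
    rows <- triples[triples$subject == subj, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      qn <- rdf_qname(rows$predicate[k], map)
      if (rows$is_literal[k]) {
        xml2::xml_add_child(node, qn, rows$object[k])
      } else {
        xml2::xml_add_child(node, qn, "rdf:resource" = rows$object[k])
      }
    }
  }
  xml2::write_xml(doc, path)
}

write_turtle <- function(triples, path) {
  map <- rdf_prefix_map(triples)
  out <- sprintf("@prefix %s: <%s> .", names(map), unname(map))
  term <- function(iri) rdf_qname(iri, map)
  lit <- function(x) paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
  for (k in seq_len(nrow(triples))) {
    o <- if (triples$is_literal[k]) lit(triples$object[k]) else term(triples$object[k])
    out <- c(out, paste(term(triples$subject[k]), term(triples$predicate[k]), o, "."))
  }
  writeLines(out, path, useBytes = TRUE)
}
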