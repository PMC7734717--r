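test_that("loader counts assertions of a minimal hand-written ontology", {
  ttl <- file.path(tempdir(), "mini.ttl")
  writeLines(c(
    "@prefix ex: <http://example.org/mini#> .",
    "ex:a ex:rel ex:b .",
    "ex:b ex:rel ex:c .",
    "ex:c ex:rel ex:a ."
  ), ttl)
  kb <- load_ontology(ttl)
  expect_equal(nrow(kb_assertions(kb, "object")), 3L)
  expect_equal(nrow(kb_assertions(kb, "data")), 0L)
  expect_equal(nrow(kb_assertions(kb, "class")), 0L)
})

test_that("toy knowledge base carries the worked-example triple", {
  kb <- toy_fixture_kb()
  obj <- kb_assertions(kb, "object")
  hit <- obj$domain == kbiri("throat_cancer") &
    obj$property == kbiri("affects") & obj$range == kbiri("males")
  expect_true(any(hit))
  expect_true(all(obj$kind == "object"))
})

test_that("unreadable and unparseable files raise informative errors", {
  expect_error(load_ontology(file.path(tempdir(), "nope-missing.owl")),
               "no such file")
  bad <- file.path(tempdir(), "bad.ttl")
  writeLines("ex:a ex:b", bad)
  expect_error(load_ontology(bad), "Turtle")
  badxml <- file.path(tempdir(), "bad.owl")
  writeLines("<rdf:RDF", badxml)
  expect_error(suppressWarnings(load_ontology(badxml)), "parse")
})

test_that("reloading and round-tripping preserve the assertion multiset", {
  key <- function(kb) {
    a <- kb$assertions
    sort(paste(a$domain, a$property, a$range, a$kind, sep = "|"))
  }
  kb1 <- load_ontology(fixture_path("kb.owl"))
  kb2 <- load_ontology(fixture_path("kb.owl"))
  expect_identical(key(kb1), key(kb2))
  for (fmt in c("rdfxml", "turtle")) {
    out <- file.path(tempdir(), paste0("roundtrip.",
                                       if (fmt == "turtle") "ttl" else "owl"))
    write_ontology(kb1, out, format = fmt)
    expect_identical(key(load_ontology(out)), key(kb1))
  }
})

test_that("labels prefer explicit annotations and never contain underscores", {
  kb <- toy_fixture_kb()
  expect_identical(kb_label(kb, kbiri("throat_cancer")), "throat cancer")
  expect_identical(kb_label(kb, kbiri("hasDoseCount")), "has dose count")
  labs <- kb_label(kb, kb$entities)
  expect_true(all(nzchar(labs)))
  expect_false(any(grepl("_", labs, fixed = TRUE)))
})

test_that("infer_classes returns the transitive superclass closure", {
  kb <- dialogue_fixture_kb()
  got <- infer_classes(kb, dlgiri("p_repeat_1"))
  expect_setequal(local_names(got),
                  c("Request_System_Repeat_Utterance", "Participant_Utterance",
                    "Utterance"))
  # a root-typed individual closes to exactly its type
  kbm <- toy_fixture_kb()
  expect_setequal(local_names(infer_classes(kbm, kbiri("hpv"))), "Virus")
  expect_error(infer_classes(kbm, kbiri("not_an_individual")), "unknown")
})

test_that("closure equals graph reachability on random subclass DAGs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 8L
    # random DAG: edges only from lower to higher index
    from <- sample(1:(n - 1), 10, replace = TRUE)
    to <- pmin(n, from + sample(1:3, 10, replace = TRUE))
    edges <- unique(data.frame(subclass = paste0("urn:c", from),
                               superclass = paste0("urn:c", to)))
    edges <- edges[edges$subclass != edges$superclass, ]
    kb <- list(subclass = edges,
               types = data.frame(individual = "urn:x",
                                  class = "urn:c1"))
    class(kb) <- "cooqa_kb"
    got <- sort(infer_classes(kb, "urn:x"))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    expected <- if ("urn:c1" %in% igraph::V(g)$name) {
      names(igraph::subcomponent(g, "urn:c1", mode = "out"))
    } else {
      "urn:c1"
    }
    expect_identical(got, sort(expected))
  }
})

test_that("closures are monotone under added subclass edges", {
  kb <- dialogue_fixture_kb()
  base <- infer_classes(kb, dlgiri("p_confirm_1"))
  kb2 <- kb
  kb2$subclass <- rbind(kb2$subclass,
                        data.frame(subclass = dlgiri("Utterance"),
                                   superclass = "urn:Thing"))
  grown <- infer_classes(kb2, dlgiri("p_confirm_1"))
  expect_true(all(base %in% grown))
})

test_that("tbox_assertions_of matches the worked example and its contracts", {
  kb <- toy_fixture_kb()
  triple <- kb_assertions(kb, "object")
  triple <- triple[triple$domain == kbiri("throat_cancer") &
                     triple$range == kbiri("males"), ]
  tb <- tbox_assertions_of(kb, triple)
  expect_true(any(tb$domain == kbiri("Disease") &
                    tb$property == kbiri("affects") &
                    tb$range == kbiri("People")))
  # a domain individual with no asserted types matches nothing
  orphan <- triple
  orphan$domain <- kbiri("never_typed")
  expect_equal(nrow(tbox_assertions_of(kb, orphan)), 0L)
  cls <- kb_assertions(kb, "class")[1, ]
  expect_error(tbox_assertions_of(kb, cls), "object- or data-property")
})

test_that("tbox_assertions_of equals the exhaustive cross-product oracle", {
  kb <- toy_fixture_kb()
  cls <- kb_assertions(kb, "class")
  closure_of <- function(ind) {
    types <- kb$types$class[kb$types$individual == ind]
    if (!length(types)) return(character())
    seen <- types
    repeat {
      nxt <- kb$subclass$superclass[kb$subclass$subclass %in% seen]
      add <- setdiff(nxt, seen)
      if (!length(add)) break
      seen <- c(seen, add)
    }
    seen
  }
  key <- function(df) paste(df$domain, df$property, df$range)
  for (kind in c("object", "data")) {
    rows <- kb_assertions(kb, kind)
    for (i in seq_len(nrow(rows))) {
      tr <- rows[i, ]
      dom <- closure_of(tr$domain)
      keep <- cls$domain %in% dom & cls$property == tr$property
      if (kind == "object") keep <- keep & cls$range %in% closure_of(tr$range)
      expected <- cls[keep, ]
      got <- tbox_assertions_of(kb, tr)
      expect_setequal(key(got), key(expected))
      expect_true(all(key(got) %in% key(cls)))
    }
  }
})
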