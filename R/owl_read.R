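# Reader for the OWL 2 Functional Syntax subset emitted by write_ontology():
# Declarations (Class / ObjectProperty / AnnotationProperty), rdfs:label
# AnnotationAssertions, SubClassOf and EquivalentClasses over
# ObjectSomeValuesFrom / ObjectIntersectionOf, with optional axiom
# annotations.  Any other construct raises an unsupported-construct error —
# nothing is ever silently dropped.

#' Read an ontology from OWL 2 Functional Syntax
#'
#' Inverse of [write_ontology()] for the `"functional"` format; a
#' write-then-read round trip is a structural identity
#' ([ontology_equal()]).  Unsupported constructs (e.g. `DisjointClasses`,
#' complex class expressions outside the EL subset used here) raise an
#' error naming the construct.  Class kinds are recovered from the IRI local
#' name: all-digit names are SNOMED concept classes, everything else is an
#' ICD category class.
#'
#' @param path file produced by [write_ontology()] (or an equivalent OWL 2
#'   Functional Syntax document restricted to the same subset).
#' @return An `el_ontology`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) {
    stop_elicd("file not found: ", path, class = "elicd_io_error")
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*@prefix", text)) {
    stop_elicd("this looks like Turtle; reading is supported for OWL ",
               "Functional Syntax only", class = "elicd_unsupported_error")
  }
  toks <- fs_tokenize(text)
  prefixes <- c(owl = OWL_NS, rdf = RDF_NS, rdfs = RDFS_NS, xsd = XSD_NS)

  # Parse into nested (name, children) nodes.
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) stop_elicd("unexpected end of file in ", path,
                             class = "elicd_parse_error")
    pos <<- pos + 1L
    t
  }
  parse_node <- function() {
    t <- advance()
    if (t %in% c("(", ")")) {
      stop_elicd("syntax error near token ", pos - 1L, " ('", t, "') in ",
                 path, class = "elicd_parse_error")
    }
    if (!is.na(peek()) && peek() == "(") {
      advance()
      children <- list()
      while (!is.na(peek()) && peek() != ")") {
        children[[length(children) + 1L]] <- parse_node()
      }
      if (is.na(peek())) {
        stop_elicd("unbalanced parentheses in ", path,
                   class = "elicd_parse_error")
      }
      advance()  # ")"
      list(kind = "node", name = t, children = children)
    } else {
      list(kind = "leaf", value = t)
    }
  }

  nodes <- list()
  while (!is.na(peek())) nodes[[length(nodes) + 1L]] <- parse_node()

  # Prefix(p:=<iri>) declarations, then the Ontology(...) wrapper.
  body <- NULL
  for (node in nodes) {
    if (node$kind == "leaf") {
      stop_elicd("unexpected token '", node$value, "' at document level in ",
                 path, class = "elicd_parse_error")
    }
    if (node$name == "Prefix") {
      pieces <- vapply(node$children, `[[`, character(1), "value")
      decl <- paste(pieces, collapse = "")
      m <- regmatches(decl, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:=<(.*)>$",
                                    decl))[[1L]]
      if (length(m) != 3L) {
        stop_elicd("malformed Prefix declaration in ", path,
                   class = "elicd_parse_error")
      }
      prefixes[[if (nzchar(m[[2L]])) m[[2L]] else ""]] <- m[[3L]]
    } else if (node$name == "Ontology") {
      body <- node$children
    } else {
      stop_elicd("unsupported document-level construct '", node$name, "' in ",
                 path, class = "elicd_unsupported_error")
    }
  }
  if (is.null(body)) {
    stop_elicd("no Ontology(...) block found in ", path,
               class = "elicd_parse_error")
  }

  # Leading leaves are the ontology IRI (and optional version IRI).
  axioms <- Filter(function(n) n$kind == "node", body)
  fs_interpret(axioms, prefixes, path)
}

fs_tokenize <- function(text) {
  pat <- paste0(
    "<[^>]*>",                                        # IRI
    "|\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z][A-Za-z0-9-]*)?",  # literal
    "(?:\\^\\^[^\\s()]+)?",
    "|:=|[()=]",
    "|[A-Za-z][A-Za-z0-9_.:-]*"
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  # Anything outside tokens must be whitespace.
  rest <- text
  regmatches(rest, list(m)) <- list(rep("", length(toks)))
  if (grepl("[^\\s]", rest, perl = TRUE)) {
    bad <- regmatches(rest, regexpr("[^\\s]+", rest, perl = TRUE))
    stop_elicd("unrecognized input '", substr(bad, 1, 40),
               "' in OWL functional syntax", class = "elicd_parse_error")
  }
  as.list(toks)
}

fs_resolve_iri <- function(leaf, prefixes) {
  v <- leaf$value
  if (startsWith(v, "<")) return(substr(v, 2L, nchar(v) - 1L))
  if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:", v)) {
    p <- sub(":.*$", "", v)
    local <- sub("^[^:]*:", "", v)
    if (!is.null(prefixes[[p]]) && !is.na(prefixes[[p]])) {
      return(paste0(prefixes[[p]], local))
    }
  }
  NA_character_
}

fs_literal <- function(leaf) {
  v <- leaf$value
  if (!startsWith(v, "\"")) return(NULL)
  body <- sub("(@[A-Za-z][A-Za-z0-9-]*)?$", "", v)
  body <- substr(body, 2L, nchar(body) - 1L)
  body <- gsub("\\\\\"", "\"", body)
  gsub("\\\\\\\\", "\\\\", body)
}

fs_interpret <- function(axioms, prefixes, path) {
  label_iri <- paste0(RDFS_NS, "label")
  class_iris <- character()
  prop_iris <- character()
  ann_prop_iris <- character()
  labels <- list()       # iri -> text
  sub_rows <- list()     # list of c(sub, super, prov)
  equiv <- list()        # list of list(iri, conjuncts(prop_iri, filler_iri), prov)

  get_iri <- function(n, ctx) {
    if (n$kind != "leaf") {
      stop_elicd("unsupported construct '", n$name, "' inside ", ctx,
                 " in ", path, class = "elicd_unsupported_error")
    }
    iri <- fs_resolve_iri(n, prefixes)
    if (is.na(iri)) {
      stop_elicd("cannot resolve entity '", n$value, "' inside ", ctx,
                 " in ", path, class = "elicd_parse_error")
    }
    iri
  }

  # Split leading Annotation(...) nodes from an axiom's children; returns
  # list(provenance, rest).
  split_annotations <- function(children, ctx) {
    prov <- NA_character_
    rest <- list()
    for (ch in children) {
      if (ch$kind == "node" && ch$name == "Annotation") {
        if (length(ch$children) != 2L) {
          stop_elicd("malformed Annotation in ", ctx, " in ", path,
                     class = "elicd_parse_error")
        }
        p <- get_iri(ch$children[[1L]], ctx)
        v <- fs_literal(ch$children[[2L]])
        if (identical(sub("^.*[#/]", "", p), PROVENANCE_LOCAL) &&
            !is.null(v)) {
          prov <- v
        }
        # Other axiom annotations carry no model content; retaining only the
        # provenance tag keeps the supported subset closed.
      } else {
        rest[[length(rest) + 1L]] <- ch
      }
    }
    list(provenance = prov, rest = rest)
  }

  parse_restriction <- function(n, ctx) {
    if (n$kind != "node" || n$name != "ObjectSomeValuesFrom") {
      nm <- if (n$kind == "node") n$name else n$value
      stop_elicd("unsupported class expression '", nm, "' inside ", ctx,
                 " in ", path, class = "elicd_unsupported_error")
    }
    if (length(n$children) != 2L) {
      stop_elicd("malformed ObjectSomeValuesFrom in ", path,
                 class = "elicd_parse_error")
    }
    c(property = get_iri(n$children[[1L]], "ObjectSomeValuesFrom"),
      filler = get_iri(n$children[[2L]], "ObjectSomeValuesFrom"))
  }

  for (ax in axioms) {
    name <- ax$name
    if (name == "Declaration") {
      if (length(ax$children) != 1L || ax$children[[1L]]$kind != "node") {
        stop_elicd("malformed Declaration in ", path,
                   class = "elicd_parse_error")
      }
      inner <- ax$children[[1L]]
      iri <- get_iri(inner$children[[1L]], "Declaration")
      if (inner$name == "Class") class_iris <- c(class_iris, iri)
      else if (inner$name == "ObjectProperty") prop_iris <- c(prop_iris, iri)
      else if (inner$name == "AnnotationProperty") {
        ann_prop_iris <- c(ann_prop_iris, iri)
      } else {
        stop_elicd("unsupported construct 'Declaration(", inner$name,
                   ")' in ", path, class = "elicd_unsupported_error")
      }
    } else if (name == "AnnotationAssertion") {
      sp <- split_annotations(ax$children, "AnnotationAssertion")
      ch <- sp$rest
      if (length(ch) != 3L) {
        stop_elicd("malformed AnnotationAssertion in ", path,
                   class = "elicd_parse_error")
      }
      p <- get_iri(ch[[1L]], "AnnotationAssertion")
      if (p != label_iri) {
        stop_elicd("unsupported construct 'AnnotationAssertion(<", p,
                   ">)': only rdfs:label annotations are supported (", path,
                   ")", class = "elicd_unsupported_error")
      }
      subject <- get_iri(ch[[2L]], "AnnotationAssertion")
      value <- fs_literal(ch[[3L]])
      if (is.null(value)) {
        stop_elicd("rdfs:label value must be a literal in ", path,
                   class = "elicd_parse_error")
      }
      labels[[subject]] <- value
    } else if (name == "SubClassOf") {
      sp <- split_annotations(ax$children, "SubClassOf")
      if (length(sp$rest) != 2L) {
        stop_elicd("malformed SubClassOf in ", path,
                   class = "elicd_parse_error")
      }
      sub_rows[[length(sub_rows) + 1L]] <-
        c(get_iri(sp$rest[[1L]], "SubClassOf"),
          get_iri(sp$rest[[2L]], "SubClassOf"),
          sp$provenance)
    } else if (name == "EquivalentClasses") {
      sp <- split_annotations(ax$children, "EquivalentClasses")
      if (length(sp$rest) != 2L) {
        stop_elicd("unsupported construct: EquivalentClasses with ",
                   length(sp$rest), " expressions in ", path,
                   class = "elicd_unsupported_error")
      }
      subject <- get_iri(sp$rest[[1L]], "EquivalentClasses")
      expr <- sp$rest[[2L]]
      if (expr$kind == "node" && expr$name == "ObjectIntersectionOf") {
        conj <- lapply(expr$children, parse_restriction,
                       ctx = "ObjectIntersectionOf")
      } else {
        conj <- list(parse_restriction(expr, "EquivalentClasses"))
      }
      equiv[[length(equiv) + 1L]] <-
        list(iri = subject,
             conjuncts = do.call(rbind, lapply(conj, function(x) {
               data.frame(property = x[["property"]], filler = x[["filler"]],
                          stringsAsFactors = FALSE)
             })),
             provenance = sp$provenance)
    } else {
      stop_elicd("unsupported construct '", name, "' in ", path,
                 class = "elicd_unsupported_error")
    }
  }

  # Derive the namespace from the declared class IRIs.
  split_local <- function(iri) sub("^.*[#/]", "", iri)
  split_ns <- function(iri) sub("[^#/]*$", "", iri)
  namespace <- if (length(class_iris) > 0L) split_ns(class_iris[[1L]])
               else default_namespace()

  ontology <- new_ontology(namespace)
  for (iri in class_iris) {
    local <- split_local(iri)
    kind <- if (is_digit_string(local)) "sct" else "icd"
    ontology <- ont_declare_class(ontology, local, kind)
  }
  wl <- default_property_whitelist()
  uncamel <- function(local) {
    hit <- wl$property[match(local, camel_property(wl$property))]
    ifelse(is.na(hit), local, hit)
  }
  for (iri in prop_iris) {
    ontology <- ont_declare_property(ontology, uncamel(split_local(iri)))
  }
  for (iri in names(labels)) {
    local <- split_local(iri)
    if (!ont_has_class(ontology, local)) {
      stop_elicd("label on undeclared entity <", iri, "> in ", path,
                 class = "elicd_invariant_error")
    }
    ontology$labels[[local]] <- labels[[iri]]
  }
  for (row in sub_rows) {
    ontology <- ont_add_subclass(ontology, split_local(row[[1L]]),
                                 split_local(row[[2L]]),
                                 if (is.na(row[[3L]])) "unspecified"
                                 else row[[3L]])
  }
  for (e in equiv) {
    conj <- data.frame(property = uncamel(split_local(e$conjuncts$property)),
                       filler = split_local(e$conjuncts$filler),
                       stringsAsFactors = FALSE)
    ontology <- ont_set_definition(ontology, split_local(e$iri), conj,
                                   if (is.na(e$provenance)) "unspecified"
                                   else e$provenance)
  }
  validate_ontology(ontology)
  ontology
}
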