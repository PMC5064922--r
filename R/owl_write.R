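# Deterministic OWL 2 serialization of the supported axiom subset:
# Declarations, rdfs:label annotation assertions, SubClassOf and
# EquivalentClasses over ObjectSomeValuesFrom / ObjectIntersectionOf.
#
# Functional Syntax is the canonical, lossless format: axiom provenance tags
# travel as axiom annotations on a dedicated annotation property.  Turtle is
# provided as an export format for interoperability (RDF toolchains); it does
# not carry axiom provenance.

OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"
PROVENANCE_LOCAL <- "axiomProvenance"

iri_of <- function(ontology, local) paste0(ontology$namespace, local)

check_iri_legal <- function(iri, what) {
  bad <- grepl('[\\x00-\\x20<>"{}|^`\\\\]', iri, perl = TRUE)
  if (any(bad)) {
    stop_elicd("IRI contains characters illegal in OWL serialization: ",
               what, " '", iri[bad][[1L]], "'",
               class = "elicd_serialization_error")
  }
  invisible(TRUE)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

# Serialized form of one existential restriction, functional syntax.
fs_restriction <- function(ontology, property, filler) {
  sprintf("ObjectSomeValuesFrom(<%s> <%s>)",
          iri_of(ontology, camel_property(property)),
          iri_of(ontology, filler))
}

fs_annotation <- function(ontology, provenance) {
  if (is.null(provenance) || is.na(provenance) || !nzchar(provenance)) ""
  else sprintf("Annotation(<%s> \"%s\") ",
               iri_of(ontology, PROVENANCE_LOCAL), escape_literal(provenance))
}

#' Write an ontology to OWL 2
#'
#' Axioms are emitted in a total deterministic order (declarations by IRI,
#' then labels, then SubClassOf by sub/super IRI, then EquivalentClasses by
#' class IRI with conjuncts in lexicographic order of their serialized
#' form), so re-running a build produces byte-identical output.
#'
#' In Functional Syntax (the default) every SubClassOf/EquivalentClasses
#' axiom carries its provenance tag as an axiom annotation, and
#' [read_ontology()] restores it.  The Turtle export is provided for RDF
#' toolchains and omits provenance.
#'
#' @param ontology an `el_ontology` (must pass [validate_ontology()]).
#' @param path output file path.
#' @param format `"functional"` or `"turtle"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path, format = c("functional", "turtle")) {
  format <- match.arg(format)
  validate_ontology(ontology)
  if (any(ontology$classes$kind == "auxiliary")) {
    stop_elicd("auxiliary classes are internal to reasoning and cannot be ",
               "serialized", class = "elicd_serialization_error")
  }
  ontology <- canonical_ontology(ontology)
  check_iri_legal(ontology$namespace, "namespace")
  check_iri_legal(iri_of(ontology, ontology$classes$id), "class")
  check_iri_legal(iri_of(ontology, camel_property(ontology$properties)),
                  "object property")
  lines <- switch(format,
                  functional = fs_serialize(ontology),
                  turtle = ttl_serialize(ontology))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

fs_serialize <- function(ontology) {
  ont_iri <- sub("[#/]$", "", ontology$namespace)
  out <- c(
    sprintf("Prefix(owl:=<%s>)", OWL_NS),
    sprintf("Prefix(rdf:=<%s>)", RDF_NS),
    sprintf("Prefix(rdfs:=<%s>)", RDFS_NS),
    sprintf("Prefix(xsd:=<%s>)", XSD_NS),
    sprintf("Ontology(<%s>", ont_iri))

  out <- c(out, sprintf("Declaration(Class(<%s>))",
                        iri_of(ontology, ontology$classes$id)))
  out <- c(out, sprintf("Declaration(ObjectProperty(<%s>))",
                        iri_of(ontology, camel_property(ontology$properties))))
  out <- c(out, sprintf("Declaration(AnnotationProperty(<%s>))",
                        iri_of(ontology, PROVENANCE_LOCAL)))

  if (length(ontology$labels) > 0L) {
    out <- c(out, sprintf('AnnotationAssertion(rdfs:label <%s> "%s"@en)',
                          iri_of(ontology, names(ontology$labels)),
                          escape_literal(unname(ontology$labels))))
  }

  sub <- ontology$subclass
  if (nrow(sub) > 0L) {
    ann <- vapply(sub$provenance, function(p) fs_annotation(ontology, p),
                  character(1), USE.NAMES = FALSE)
    out <- c(out, sprintf("SubClassOf(%s<%s> <%s>)", ann,
                          iri_of(ontology, sub$sub),
                          iri_of(ontology, sub$super)))
  }

  for (id in names(ontology$equivalence)) {
    def <- ontology$equivalence[[id]]
    parts <- sort_c(vapply(seq_len(nrow(def$conjuncts)), function(i) {
      fs_restriction(ontology, def$conjuncts$property[[i]],
                     def$conjuncts$filler[[i]])
    }, character(1)))
    expr <- if (length(parts) == 1L) parts else
      sprintf("ObjectIntersectionOf(%s)", paste(parts, collapse = " "))
    out <- c(out, sprintf("EquivalentClasses(%s<%s> %s)",
                          fs_annotation(ontology, def$provenance),
                          iri_of(ontology, id), expr))
  }

  c(out, ")")
}

ttl_restriction <- function(ontology, property, filler) {
  sprintf("[ a owl:Restriction ; owl:onProperty <%s> ; owl:someValuesFrom <%s> ]",
          iri_of(ontology, camel_property(property)),
          iri_of(ontology, filler))
}

ttl_serialize <- function(ontology) {
  out <- c(
    sprintf("@prefix owl: <%s> .", OWL_NS),
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    sprintf("@prefix rdfs: <%s> .", RDFS_NS),
    "",
    sprintf("<%s> a owl:Ontology .", sub("[#/]$", "", ontology$namespace)),
    "")
  for (p in ontology$properties) {
    out <- c(out, sprintf("<%s> a owl:ObjectProperty .",
                          iri_of(ontology, camel_property(p))))
  }
  sup_of <- split(ontology$subclass$super, ontology$subclass$sub)
  for (id in ontology$classes$id) {
    stanza <- sprintf("<%s> a owl:Class", iri_of(ontology, id))
    if (!is.null(ontology$labels[[id]])) {
      stanza <- c(stanza, sprintf('    rdfs:label "%s"@en',
                                  escape_literal(ontology$labels[[id]])))
    }
    for (super in sort_c(sup_of[[id]] %||% character())) {
      stanza <- c(stanza, sprintf("    rdfs:subClassOf <%s>",
                                  iri_of(ontology, super)))
    }
    def <- ontology$equivalence[[id]]
    if (!is.null(def)) {
      parts <- sort_c(vapply(seq_len(nrow(def$conjuncts)), function(i) {
        ttl_restriction(ontology, def$conjuncts$property[[i]],
                        def$conjuncts$filler[[i]])
      }, character(1)))
      expr <- if (length(parts) == 1L) parts else
        sprintf("[ a owl:Class ; owl:intersectionOf ( %s ) ]",
                paste(parts, collapse = " "))
      stanza <- c(stanza, sprintf("    owl:equivalentClass %s", expr))
    }
    out <- c(out, paste0(paste(stanza, collapse = " ;\n"), " ."), "")
  }
  out
}
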