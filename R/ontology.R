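#' Create an empty EL ontology container
#'
#' The ontology is the package's central data structure: a set of named
#' classes (tagged `icd`, `sct` or `auxiliary`), `rdfs:label` annotations,
#' SubClassOf axioms, EquivalentClasses axioms whose right-hand sides are
#' conjunctions of existential restrictions (`ObjectSomeValuesFrom`), and the
#' object properties those restrictions use.  Every axiom carries a provenance
#' tag recording which pipeline stage produced it (`hierarchy`,
#' `mapping-primary`, `mapping-secondary`, `inherited`, `lifted`, `imported`).
#'
#' Class identifiers are IRI local names (e.g. `"A00_0"`, `"62275004"`); the
#' full IRI is `paste0(namespace, id)` and only materializes at serialization
#' time.
#'
#' @param namespace IRI prefix used for every entity in the ontology.
#' @return An object of class `el_ontology`.
#' @seealso [build_ontology()], [write_ontology()], [el_saturate()]
#' @export
new_ontology <- function(namespace = default_namespace()) {
  stopifnot(is.character(namespace), length(namespace) == 1L,
            nzchar(namespace))
  structure(
    list(
      namespace = namespace,
      classes = data.frame(id = character(), kind = character(),
                           stringsAsFactors = FALSE),
      labels = character(),       # named character: id -> label text
      properties = character(),   # canonical (hyphenated) property names
      subclass = data.frame(sub = character(), super = character(),
                            provenance = character(),
                            stringsAsFactors = FALSE),
      equivalence = list()        # named list: id -> el_definition
    ),
    class = "el_ontology"
  )
}

#' Default ontology namespace
#'
#' @return The IRI prefix used when none is supplied.
#' @export
default_namespace <- function() "http://www.khaos.uma.es/dione#"

#' Build a set of existential restrictions
#'
#' An existential restriction pairs an object property with a SNOMED CT
#' filler concept: the `somevaluesfrom p.C` building block of every class
#' definition.  Sets have no duplicates and a canonical order, so equality
#' of definitions is order-insensitive.
#'
#' @param property character vector of canonical (hyphenated) property names.
#' @param filler character vector of filler concept ids (digit strings).
#' @return A data frame with columns `property` and `filler`, deduplicated
#'   and canonically ordered.
#' @export
restriction_set <- function(property = character(), filler = character()) {
  stopifnot(length(property) == length(filler))
  df <- data.frame(property = as.character(property),
                   filler = as.character(filler),
                   stringsAsFactors = FALSE)
  canonicalize_restrictions(df)
}

canonicalize_restrictions <- function(df) {
  df <- unique(df[, c("property", "filler"), drop = FALSE])
  df <- df[order_c(df$property, nchar(df$filler), df$filler), , drop = FALSE]
  rownames(df) <- NULL
  df
}

restriction_keys <- function(df) paste(df$property, df$filler, sep = "\r")

restriction_union <- function(a, b) {
  canonicalize_restrictions(rbind(a, b))
}

restriction_intersect <- function(a, b) {
  canonicalize_restrictions(a[restriction_keys(a) %in% restriction_keys(b), ,
                              drop = FALSE])
}

restriction_setdiff <- function(a, b) {
  canonicalize_restrictions(a[!(restriction_keys(a) %in% restriction_keys(b)), ,
                              drop = FALSE])
}

#' Set equality of two restriction sets
#'
#' @param a,b restriction data frames ([restriction_set()]).
#' @return `TRUE` when both denote the same set of existential
#'   restrictions, irrespective of row order or duplicates.
#' @export
restriction_equal <- function(a, b) {
  identical(restriction_keys(canonicalize_restrictions(a)),
            restriction_keys(canonicalize_restrictions(b)))
}

new_definition <- function(conjuncts, provenance) {
  conjuncts <- canonicalize_restrictions(conjuncts)
  if (nrow(conjuncts) == 0L) {
    stop_elicd("a class definition needs at least one restriction",
               class = "elicd_invariant_error")
  }
  structure(list(conjuncts = conjuncts, provenance = provenance),
            class = "el_definition")
}

# ---- mutation helpers -------------------------------------------------------

ont_has_class <- function(ontology, id) id %in% ontology$classes$id

ont_declare_class <- function(ontology, id, kind, label = NULL) {
  stopifnot(kind %in% c("icd", "sct", "auxiliary"))
  if (!ont_has_class(ontology, id)) {
    ontology$classes <- rbind(
      ontology$classes,
      data.frame(id = id, kind = kind, stringsAsFactors = FALSE))
  } else {
    existing <- ontology$classes$kind[ontology$classes$id == id]
    if (!identical(existing, kind)) {
      stop_elicd("class ", id, " already declared with kind ", existing,
                 class = "elicd_invariant_error")
    }
  }
  if (!is.null(label)) ontology$labels[[id]] <- label
  ontology
}

ont_class_kind <- function(ontology, id) {
  ontology$classes$kind[match(id, ontology$classes$id)]
}

ont_declare_property <- function(ontology, property) {
  ontology$properties <- sort_c(union(ontology$properties, property))
  ontology
}

ont_add_subclass <- function(ontology, sub, super, provenance) {
  for (x in c(sub, super)) {
    if (!ont_has_class(ontology, x)) {
      stop_elicd("subclass axiom references undeclared class ", x,
                 class = "elicd_invariant_error")
    }
  }
  key <- paste(ontology$subclass$sub, ontology$subclass$super, sep = "\r")
  if (!(paste(sub, super, sep = "\r") %in% key)) {
    ontology$subclass <- rbind(
      ontology$subclass,
      data.frame(sub = sub, super = super, provenance = provenance,
                 stringsAsFactors = FALSE))
  }
  ontology
}

#' Does a class have its own equivalence-axiom definition?
#'
#' @param ontology an `el_ontology`.
#' @param id class id.
#' @return `TRUE` or `FALSE`.
#' @export
ont_has_definition <- function(ontology, id) id %in% names(ontology$equivalence)

#' A class's own definition
#'
#' @param ontology an `el_ontology`.
#' @param id class id.
#' @return An `el_definition` (list with `conjuncts` and `provenance`), or
#'   `NULL` when the class has none.
#' @export
ont_definition <- function(ontology, id) ontology$equivalence[[id]]

ont_set_definition <- function(ontology, id, conjuncts, provenance,
                               force = FALSE) {
  if (!ont_has_class(ontology, id)) {
    stop_elicd("equivalence axiom references undeclared class ", id,
               class = "elicd_invariant_error")
  }
  if (!identical(ont_class_kind(ontology, id), "icd")) {
    stop_elicd("equivalence axioms may only define ICD-kind classes (", id, ")",
               class = "elicd_invariant_error")
  }
  if (ont_has_definition(ontology, id) && !force) {
    stop_elicd("class ", id, " already has a definition; ",
               "use force = TRUE to replace it",
               class = "elicd_conflict_error")
  }
  ontology$equivalence[[id]] <- new_definition(conjuncts, provenance)
  ontology
}

# Fillers used by any equivalence axiom.
ont_used_fillers <- function(ontology) {
  sort_digit_strings(unique(unlist(
    lapply(ontology$equivalence, function(d) d$conjuncts$filler),
    use.names = FALSE)))
}

ont_icd_classes <- function(ontology) {
  ontology$classes$id[ontology$classes$kind == "icd"]
}

ont_sct_classes <- function(ontology) {
  ontology$classes$id[ontology$classes$kind == "sct"]
}

# Direct ICD-hierarchy children/parents: subclass edges between icd classes.
ont_icd_edges <- function(ontology) {
  icd <- ont_icd_classes(ontology)
  edges <- ontology$subclass
  edges[edges$sub %in% icd & edges$super %in% icd, , drop = FALSE]
}

# ---- validation -------------------------------------------------------------

#' Validate ontology invariants
#'
#' Checks that every axiom references declared classes, that equivalence
#' axioms only define ICD-kind classes, and that the subclass graph is
#' acyclic.
#'
#' @param ontology an `el_ontology`.
#' @return The ontology, invisibly; errors on violation.
#' @export
validate_ontology <- function(ontology) {
  stopifnot(inherits(ontology, "el_ontology"))
  declared <- ontology$classes$id
  if (anyDuplicated(declared)) {
    stop_elicd("duplicate class declarations: ",
               paste(unique(declared[duplicated(declared)]), collapse = ", "),
               class = "elicd_invariant_error")
  }
  refs <- unique(c(ontology$subclass$sub, ontology$subclass$super,
                   names(ontology$equivalence), names(ontology$labels),
                   unlist(lapply(ontology$equivalence,
                                 function(d) d$conjuncts$filler),
                          use.names = FALSE)))
  undeclared <- setdiff(refs, declared)
  if (length(undeclared) > 0L) {
    stop_elicd("axioms reference undeclared class(es): ",
               paste(sort_c(undeclared), collapse = ", "),
               class = "elicd_invariant_error")
  }
  for (id in names(ontology$equivalence)) {
    if (!identical(ont_class_kind(ontology, id), "icd")) {
      stop_elicd("equivalence axiom on non-ICD class ", id,
                 class = "elicd_invariant_error")
    }
  }
  cycle <- find_cycle(ontology$subclass$sub, ontology$subclass$super)
  if (!is.null(cycle)) {
    stop_elicd("subclass graph contains a cycle: ",
               paste(cycle, collapse = " -> "),
               class = "elicd_cycle_error")
  }
  invisible(ontology)
}

# Returns a cycle (vector of node ids) in the directed edge list, or NULL.
find_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  path <- character()
  visit <- function(v) {
    st <- state[[v]] %||% 0L
    if (st == 1L) {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    if (st == 2L) return(NULL)
    state[[v]] <- 1L
    path[[length(path) + 1L]] <<- v
    for (w in adj[[v]] %||% character()) {
      res <- visit(w)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[v]] <- 2L
    NULL
  }
  for (v in nodes) {
    res <- visit(v)
    if (!is.null(res)) return(res)
  }
  NULL
}

# ---- equality and printing --------------------------------------------------

canonical_ontology <- function(ontology) {
  o <- ontology
  o$classes <- o$classes[order_c(o$classes$id), , drop = FALSE]
  rownames(o$classes) <- NULL
  o$labels <- o$labels[sort_c(names(o$labels))]
  o$properties <- sort_c(o$properties)
  o$subclass <- o$subclass[order_c(o$subclass$sub, o$subclass$super), ,
                           drop = FALSE]
  rownames(o$subclass) <- NULL
  o$equivalence <- o$equivalence[sort_c(names(o$equivalence))]
  o$equivalence <- lapply(o$equivalence, function(d) {
    d$conjuncts <- canonicalize_restrictions(d$conjuncts)
    d
  })
  o
}

#' Structural equality of two ontologies
#'
#' Compares namespaces, declarations, labels, properties, subclass axioms and
#' equivalence axioms after canonical ordering; conjunct order never matters.
#'
#' @param a,b `el_ontology` objects.
#' @param ignore_provenance if `TRUE`, axiom provenance tags are not compared
#'   (useful for formats that do not carry them).
#' @return `TRUE` or `FALSE`.
#' @export
ontology_equal <- function(a, b, ignore_provenance = FALSE) {
  ca <- canonical_ontology(a)
  cb <- canonical_ontology(b)
  if (ignore_provenance) {
    ca$subclass$provenance <- cb$subclass$provenance <- NULL
    ca$equivalence <- lapply(ca$equivalence, function(d) d["conjuncts"])
    cb$equivalence <- lapply(cb$equivalence, function(d) d["conjuncts"])
  }
  isTRUE(all.equal(unclass(ca), unclass(cb), check.attributes = FALSE))
}

#' @export
print.el_ontology <- function(x, ...) {
  kinds <- table(factor(x$classes$kind, levels = c("icd", "sct", "auxiliary")))
  cat("<el_ontology> namespace:", x$namespace, "\n")
  cat(sprintf("  classes: %d (icd %d, sct %d), object properties: %d\n",
              nrow(x$classes), kinds[["icd"]], kinds[["sct"]],
              length(x$properties)))
  cat(sprintf("  subclass axioms: %d, equivalence axioms: %d, labels: %d\n",
              nrow(x$subclass), length(x$equivalence), length(x$labels)))
  invisible(x)
}

#' @export
summary.el_ontology <- function(object, ...) {
  report_stats(object)
}
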