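# Independent brute-force subsumption oracle for validating the saturation
# reasoner on small, acyclic-definitional ontologies.
#
# In the fragment the pipeline generates, every definition is a flat
# conjunction of existential restrictions whose fillers are primitive
# (SNOMED) classes — description trees have depth one.  The oracle decides
# B subClassOf A by unfolding definitions and exhaustively searching for a
# homomorphism from A's description tree into B's, honoring told (primitive)
# ancestors; it shares no code or data structures with the saturation
# engine.

# Reflexive-transitive closure over told subclass edges.
oracle_prim_closure <- function(ontology) {
  edges <- ontology$subclass
  up <- split(edges$super, edges$sub)
  memo <- new.env(parent = emptyenv())
  closure <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    memo[[id]] <- id  # cycle guard; hierarchy is validated acyclic
    out <- id
    for (p in up[[id]] %||% character()) out <- union(out, closure(p))
    memo[[id]] <- out
    out
  }
  vapply(ontology$classes$id, function(id) {
    closure(id)
    0L
  }, integer(1))
  memo
}

#' Brute-force subsumption oracle
#'
#' Decides whether `sub` is subsumed by `super` by a per-class fixpoint
#' over description-tree matching: a defined class `B` subsumes `sub` when
#' every restriction `some r.C` in `B`'s definition is matched by a
#' restriction `some r.E` entailed by `sub` (from the definitions of any of
#' its subsumers) with `C` among `E`'s primitive ancestors.  Intended for
#' small fixtures (at most a few dozen classes); fillers with definitions of
#' their own (cyclic-definitional input) are rejected.
#'
#' @param ontology an `el_ontology`.
#' @param sub,super declared class ids.
#' @return `TRUE` or `FALSE`.
#' @seealso [oracle_all_subsumers()], [is_subsumed_by()]
#' @export
oracle_subsumption <- function(ontology, sub, super) {
  super %in% oracle_all_subsumers(ontology, sub)
}

#' All subsumers of a class, by the brute-force oracle
#'
#' @param ontology an `el_ontology`.
#' @param class a declared class id.
#' @param prim optional precomputed primitive closure (internal reuse when
#'   called for every class of the same ontology).
#' @return Character vector of subsumers (including `class`).
#' @export
oracle_all_subsumers <- function(ontology, class,
                                 prim = oracle_prim_closure(ontology)) {
  if (!ont_has_class(ontology, class)) {
    stop_elicd("undeclared class: ", class,
               class = "elicd_unknown_class_error")
  }
  defs <- ontology$equivalence
  for (id in names(defs)) {
    if (any(defs[[id]]$conjuncts$filler %in% names(defs))) {
      stop_elicd("cyclic-definitional input: filler ",
                 intersect(defs[[id]]$conjuncts$filler, names(defs))[[1L]],
                 " has a definition of its own",
                 class = "elicd_unsupported_error")
    }
  }
  defined <- names(defs)

  anc <- prim[[class]]
  repeat {
    # Existential restrictions entailed by `class`: everything asserted by
    # the definition of any current subsumer.
    entailed <- do.call(rbind, c(
      list(data.frame(property = character(), filler = character(),
                      stringsAsFactors = FALSE)),
      lapply(intersect(anc, defined), function(d) defs[[d]]$conjuncts)))
    matched <- vapply(setdiff(defined, anc), function(B) {
      conj <- defs[[B]]$conjuncts
      all(vapply(seq_len(nrow(conj)), function(i) {
        same_r <- entailed[entailed$property == conj$property[[i]], ,
                           drop = FALSE]
        any(vapply(same_r$filler,
                   function(E) conj$filler[[i]] %in% (prim[[E]] %||% E),
                   logical(1)))
      }, logical(1)))
    }, logical(1))
    new <- names(matched)[matched]
    if (length(new) == 0L) break
    anc <- union(anc, unique(c(new, unlist(lapply(new, function(n) prim[[n]]),
                                           use.names = FALSE))))
  }
  sort_c(anc)
}

#' Full subsumption matrix by the oracle
#'
#' @param ontology an `el_ontology`.
#' @return Named list: for each declared class, its oracle subsumer set.
#' @export
oracle_classification <- function(ontology) {
  prim <- oracle_prim_closure(ontology)
  ids <- sort_c(ontology$classes$id)
  stats::setNames(lapply(ids, function(id) {
    oracle_all_subsumers(ontology, id, prim = prim)
  }), ids)
}
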