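# Internal EL reasoner: normalization to the EL normal form followed by
# completion-rule saturation to a least fixpoint.  The supported fragment
# (conjunction + existential restriction, no bottom, no disjointness, no
# role axioms) is classifiable in polynomial time and can never be
# inconsistent.
#
# Normal forms over named classes A, B (original or fresh):
#   atomic_sub : A           subClassOf B
#   conj_sub   : A1 and A2   subClassOf B
#   exists_rhs : A           subClassOf some r.B
#   exists_lhs : some r.A    subClassOf B
#
# Completion rules maintained to fixpoint over subsumer sets S(A) and role
# links R(r):
#   CR1: A' in S(A), A' subClassOf B                         => B in S(A)
#   CR2: A1, A2 in S(A), A1 and A2 subClassOf B              => B in S(A)
#   CR3: A' in S(A), A' subClassOf some r.B                  => (A,B) in R(r)
#   CR4: (A,B) in R(r), B' in S(B), some r.B' subClassOf A'' => A'' in S(A)

#' Normalize an ontology TBox to EL normal form
#'
#' Equivalence axioms split into two inclusions; nested expressions flatten
#' through deterministically numbered fresh names (`_X:<class>:<i>` for the
#' conjunct existentials, `_C:<class>:<i>` for the binary conjunction
#' chain), so the output is identical across runs for a given ontology.
#'
#' @param ontology an `el_ontology`.
#' @param extra_definitions optional named list of restriction sets to
#'   normalize as additional defined classes (used for query realization;
#'   names may be fresh, non-declared ids).
#' @return A list with `axioms` (data frame `type`, `a1`, `a2`, `b`, `r`)
#'   and `classes` (all named classes incl. fresh ones, with the declared
#'   ones first).
#' @export
normalize_tbox <- function(ontology, extra_definitions = NULL) {
  declared <- sort_c(ontology$classes$id)
  fresh <- character()
  rows <- list()
  add <- function(type, a1, a2 = NA_character_, b, r = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(type = type, a1 = a1, a2 = a2,
                                             b = b, r = r,
                                             stringsAsFactors = FALSE)
  }

  sub <- ontology$subclass
  for (i in seq_len(nrow(sub))) add("atomic_sub", sub$sub[[i]],
                                    b = sub$super[[i]])

  normalize_definition <- function(id, conjuncts) {
    conjuncts <- canonicalize_restrictions(conjuncts)
    n <- nrow(conjuncts)
    # Right-to-left inclusions: the class implies each existential.
    for (i in seq_len(n)) {
      add("exists_rhs", id, b = conjuncts$filler[[i]],
          r = conjuncts$property[[i]])
    }
    # Left-to-right: the conjunction of the existentials implies the class.
    if (n == 1L) {
      add("exists_lhs", conjuncts$filler[[1L]], b = id,
          r = conjuncts$property[[1L]])
      return(invisible(NULL))
    }
    xs <- sprintf("_X:%s:%d", id, seq_len(n))
    fresh <<- c(fresh, xs)
    for (i in seq_len(n)) {
      add("exists_lhs", conjuncts$filler[[i]], b = xs[[i]],
          r = conjuncts$property[[i]])
    }
    cs <- sprintf("_C:%s:%d", id, seq_len(n - 1L))
    fresh <<- c(fresh, cs)
    add("conj_sub", xs[[1L]], xs[[2L]], cs[[1L]])
    for (i in seq_len(n - 2L)) {
      add("conj_sub", cs[[i]], xs[[i + 2L]], cs[[i + 1L]])
    }
    add("atomic_sub", cs[[n - 1L]], b = id)
    invisible(NULL)
  }

  for (id in sort_c(names(ontology$equivalence))) {
    normalize_definition(id, ontology$equivalence[[id]]$conjuncts)
  }
  for (id in names(extra_definitions %||% list())) {
    normalize_definition(id, extra_definitions[[id]])
  }

  axioms <- if (length(rows) == 0L) {
    data.frame(type = character(), a1 = character(), a2 = character(),
               b = character(), r = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  list(axioms = axioms,
       classes = c(declared, names(extra_definitions %||% list()), fresh))
}

#' Saturate a normalized axiom set
#'
#' Applies the EL completion rules to a least fixpoint.  Subsumption
#' `A subClassOf B` holds for named classes exactly when `B` is in `S(A)`
#' afterwards.
#'
#' @param normalized output of [normalize_tbox()].
#' @return A `saturation_state`: list with `S` (named list of subsumer
#'   vectors), `R` (named list of two-column matrices of role links) and
#'   `classes`.
#' @export
saturate <- function(normalized) {
  axioms <- normalized$axioms
  classes <- unique(normalized$classes)

  # Indexes keyed by left-hand entities.
  at <- axioms[axioms$type == "atomic_sub", , drop = FALSE]
  atomic_by_lhs <- split(at$b, at$a1)
  cj <- axioms[axioms$type == "conj_sub", , drop = FALSE]
  er <- axioms[axioms$type == "exists_rhs", , drop = FALSE]
  exrhs_by_lhs <- if (nrow(er) > 0L)
    split(seq_len(nrow(er)), er$a1) else list()
  el <- axioms[axioms$type == "exists_lhs", , drop = FALSE]
  exlhs_by_key <- if (nrow(el) > 0L)
    split(el$b, paste(el$r, el$a1, sep = "\r")) else list()

  S <- stats::setNames(as.list(classes), classes)
  links <- list()  # per property: 2-col matrix (source, filler)

  repeat {
    changed <- FALSE
    for (A in classes) {
      sA <- S[[A]]
      # CR1
      new <- setdiff(unique(unlist(atomic_by_lhs[sA], use.names = FALSE)), sA)
      # CR2
      if (nrow(cj) > 0L) {
        hit <- cj$a1 %in% sA & cj$a2 %in% sA
        new <- union(new, setdiff(cj$b[hit], sA))
      }
      if (length(new) > 0L) {
        S[[A]] <- c(sA, new)
        changed <- TRUE
        sA <- S[[A]]
      }
      # CR3
      idx <- unlist(exrhs_by_lhs[sA], use.names = FALSE)
      for (i in idx) {
        r <- er$r[[i]]
        tgt <- er$b[[i]]
        mat <- links[[r]]
        if (is.null(mat) ||
            !any(mat[, 1L] == A & mat[, 2L] == tgt)) {
          links[[r]] <- rbind(mat, c(A, tgt))
          changed <- TRUE
        }
      }
    }
    # CR4
    for (r in names(links)) {
      mat <- links[[r]]
      for (k in seq_len(nrow(mat))) {
        A <- mat[[k, 1L]]
        B <- mat[[k, 2L]]
        keys <- paste(r, S[[B]], sep = "\r")
        new <- setdiff(unique(unlist(exlhs_by_key[keys], use.names = FALSE)),
                       S[[A]])
        if (length(new) > 0L) {
          S[[A]] <- c(S[[A]], new)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  structure(list(S = lapply(S, sort_c), R = links, classes = classes),
            class = "saturation_state")
}

#' @export
print.saturation_state <- function(x, ...) {
  cat("<saturation_state>", length(x$classes), "classes,",
      sum(lengths(x$S)), "subsumption entries\n")
  invisible(x)
}

#' Saturate an ontology
#'
#' Convenience wrapper: [normalize_tbox()] then [saturate()].
#'
#' @param ontology an `el_ontology`.
#' @return A `saturation_state`.
#' @export
el_saturate <- function(ontology) saturate(normalize_tbox(ontology))

#' Decide a subsumption from a saturation state
#'
#' @param state a `saturation_state`.
#' @param sub,super named class ids; both must be declared.
#' @return `TRUE` iff `sub` is subsumed by `super`.
#' @export
is_subsumed_by <- function(state, sub, super) {
  for (x in c(sub, super)) {
    if (!(x %in% state$classes)) {
      stop_elicd("undeclared class: ", x, class = "elicd_unknown_class_error")
    }
  }
  super %in% state$S[[sub]]
}

#' Named subsumers of a class (fresh names removed)
#'
#' @param state a `saturation_state`.
#' @param class a declared class id.
#' @return Character vector of named subsumers, including `class` itself.
#' @export
subsumers <- function(state, class) {
  if (!(class %in% state$classes)) {
    stop_elicd("undeclared class: ", class,
               class = "elicd_unknown_class_error")
  }
  s <- state$S[[class]]
  sort_c(s[!startsWith(s, "_")])
}

#' Check ontology consistency
#'
#' The supported fragment has neither `owl:Nothing` nor disjointness, so no
#' contradiction is expressible: every ontology in the fragment is
#' consistent, and this check documents that as a fragment-level theorem
#' while validating the structural invariants.
#'
#' @param ontology an `el_ontology`.
#' @return `TRUE`, invisibly reported after validation.
#' @export
check_consistency <- function(ontology) {
  validate_ontology(ontology)
  TRUE
}

#' Realize a clinical-record query against the ontology
#'
#' The assertion list (property, SNOMED filler) is interpreted as a defined
#' query class `Q equiv some p1.C1 and ... and some pn.Cn`, added to a
#' working copy of the TBox, and saturated; the named ICD classes subsuming
#' `Q` are the categories the record is classified into.  The input
#' ontology is never modified.
#'
#' @param assertions data frame with columns `property` (canonical or
#'   camelCase name) and `filler_id` (declared SNOMED concept id), non-empty.
#' @param ontology an `el_ontology`.
#' @param whitelist whitelist used to resolve property spellings.
#' @return A `realization_result`: list with `all_subsumers` (ICD classes
#'   subsuming the query), `most_specific` (those without a strict
#'   descendant also in the set; for an equivalence group, its
#'   lexicographically least member), and `equivalents` (classes equivalent
#'   to the query expression).
#' @export
realize_query <- function(assertions, ontology,
                          whitelist = default_property_whitelist()) {
  stopifnot(is.data.frame(assertions),
            all(c("property", "filler_id") %in% names(assertions)))
  if (nrow(assertions) == 0L) {
    stop_elicd("a query needs at least one assertion",
               class = "elicd_parse_error")
  }
  offenders <- character()
  prop <- rep(NA_character_, nrow(assertions))
  known <- c(whitelist$property, whitelist$camel,
             ontology$properties, camel_property(ontology$properties))
  for (i in seq_len(nrow(assertions))) {
    p <- assertions$property[[i]]
    if (p %in% known) {
      prop[[i]] <- tryCatch(resolve_property(p, whitelist),
                            error = function(e) p)
    } else {
      offenders <- c(offenders, paste0("property '", p, "'"))
    }
  }
  fillers <- assertions$filler_id
  bad <- !vapply(fillers, ont_has_class, logical(1), ontology = ontology)
  if (any(bad)) {
    offenders <- c(offenders, paste0("filler '", fillers[bad], "'"))
  }
  if (length(offenders) > 0L) {
    stop_elicd("query references unknown entities: ",
               paste(unique(offenders), collapse = ", "),
               class = "elicd_unknown_entity_error")
  }

  qid <- "_Q"
  qdef <- restriction_set(prop, fillers)
  state <- saturate(normalize_tbox(ontology,
                                   extra_definitions = stats::setNames(
                                     list(qdef), qid)))
  icd <- ont_icd_classes(ontology)
  subs <- intersect(state$S[[qid]], icd)
  equivalents <- sort_c(subs[vapply(subs, function(c) qid %in% state$S[[c]],
                                    logical(1))])

  # Strict-descendant test inside the subsumer set, on the saturated
  # hierarchy; equivalence groups keep their lexicographically least member.
  is_most_specific <- vapply(subs, function(x) {
    for (y in setdiff(subs, x)) {
      y_below_x <- x %in% state$S[[y]]
      x_below_y <- y %in% state$S[[x]]
      if (y_below_x && !x_below_y) return(FALSE)          # strict descendant
      if (y_below_x && x_below_y && y < x) return(FALSE)  # equivalent, tie
    }
    TRUE
  }, logical(1))

  structure(list(all_subsumers = sort_c(subs),
                 most_specific = sort_c(subs[is_most_specific]),
                 equivalents = equivalents),
            class = "realization_result")
}

#' @export
print.realization_result <- function(x, ...) {
  cat("<realization_result>\n")
  cat("  most specific:", paste(x$most_specific, collapse = ", "), "\n")
  cat("  all subsumers:", paste(x$all_subsumers, collapse = ", "), "\n")
  if (length(x$equivalents) > 0L) {
    cat("  equivalent:   ", paste(x$equivalents, collapse = ", "), "\n")
  }
  invisible(x)
}
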