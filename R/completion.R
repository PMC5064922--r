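# Definition refinement: two sequential processes over the ICD hierarchy.
# First, downward inheritance copies every conjunct of a class's nearest
# defined ancestor into the class's own definition (a subclass is the parent
# disease plus distinguishing restrictions).  Second, sibling lift promotes
# any restriction shared by *all* direct subclasses into their parent's
# definition — the refinement that separates a parent from unrelated classes
# that happened to match its under-specified definition.

completion_report <- function(rows = NULL, pass_count = 1L) {
  if (is.null(rows) || length(rows) == 0L) {
    rows <- data.frame(class = character(), property = character(),
                       filler = character(), source = character(),
                       origin = character(), pass = integer(),
                       stringsAsFactors = FALSE)
  }
  structure(list(additions = rows, pass_count = pass_count),
            class = "completion_report")
}

#' @export
print.completion_report <- function(x, ...) {
  cat("<completion_report>", nrow(x$additions), "addition(s) in",
      x$pass_count, "pass(es)\n")
  if (nrow(x$additions) > 0L) print(utils::head(x$additions, 20L))
  invisible(x)
}

#' Write a completion report to TSV
#'
#' @param report a `completion_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_completion_report <- function(report, path) {
  df <- report$additions
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parent map over the ICD hierarchy edges of an ontology (hierarchy edges
# are single-parent by construction).
icd_parent_map <- function(ontology) {
  edges <- ont_icd_edges(ontology)
  stats::setNames(edges$super, edges$sub)
}

icd_depth_order <- function(ontology, decreasing = FALSE) {
  parent <- icd_parent_map(ontology)
  depth_of <- function(id) {
    d <- 0L
    while (!is.na(parent[id])) {
      id <- parent[[id]]
      d <- d + 1L
      if (d > 50L) stop_elicd("ICD parent chain too deep at ", id,
                              class = "elicd_cycle_error")
    }
    d
  }
  ids <- sort_c(ont_icd_classes(ontology))
  depths <- vapply(ids, depth_of, integer(1))
  ids[order(depths * (if (decreasing) -1L else 1L), ids, method = "radix")]
}

#' Inherit parent definitions downward
#'
#' Processing the ICD hierarchy top-down, every class that has its own
#' definition is augmented with all conjuncts of its nearest defined ICD
#' ancestor.  Classes without an own definition are left undefined
#' (augmentation only).  Applying the operation twice adds nothing.
#'
#' @param ontology an `el_ontology`.
#' @param pass pass number recorded in the report (used by the fixpoint
#'   driver).
#' @return A list with components `ontology` and `report`
#'   (a `completion_report` whose `origin` column names the ancestor each
#'   restriction came from).
#' @export
inherit_down <- function(ontology, pass = 1L) {
  parent <- icd_parent_map(ontology)
  additions <- list()
  for (id in icd_depth_order(ontology)) {
    if (!ont_has_definition(ontology, id)) next
    anc <- if (is.na(parent[id])) NA_character_ else parent[[id]]
    while (!is.na(anc) && !ont_has_definition(ontology, anc)) {
      anc <- if (is.na(parent[anc])) NA_character_ else parent[[anc]]
    }
    if (is.na(anc)) next
    own <- ont_definition(ontology, id)$conjuncts
    new <- restriction_setdiff(ont_definition(ontology, anc)$conjuncts, own)
    if (nrow(new) == 0L) next
    ontology$equivalence[[id]]$conjuncts <- restriction_union(own, new)
    additions[[length(additions) + 1L]] <-
      data.frame(class = id, property = new$property, filler = new$filler,
                 source = "inherited", origin = anc, pass = pass,
                 stringsAsFactors = FALSE)
  }
  list(ontology = ontology,
       report = completion_report(do.call(rbind, additions), pass))
}

#' Lift restrictions shared by all sibling subclasses
#'
#' Processing the ICD hierarchy bottom-up, for every class with at least two
#' direct subclasses, *all* of which have definitions, each restriction
#' present in every child's conjunct set is added to the parent's
#' definition.  A partial sibling set blocks lifting (it could wrongly
#' narrow the parent), and by default a parent without its own definition is
#' not given one; set `create_missing` to allow creation (tagged `lifted`).
#'
#' @param ontology an `el_ontology`, normally after [inherit_down()].
#' @param create_missing create definitions for definition-less parents.
#' @param pass pass number recorded in the report.
#' @return A list with components `ontology` and `report` (origin column is
#'   `"children"`).
#' @export
lift_shared <- function(ontology, create_missing = FALSE, pass = 1L) {
  parent <- icd_parent_map(ontology)
  children_of <- split(names(parent), unname(parent))
  additions <- list()
  for (id in icd_depth_order(ontology, decreasing = TRUE)) {
    kids <- children_of[[id]] %||% character()
    if (length(kids) < 2L) next
    if (!all(vapply(kids, ont_has_definition, logical(1),
                    ontology = ontology))) next
    shared <- ont_definition(ontology, kids[[1L]])$conjuncts
    for (k in kids[-1L]) {
      shared <- restriction_intersect(shared,
                                      ont_definition(ontology, k)$conjuncts)
    }
    if (nrow(shared) == 0L) next
    if (ont_has_definition(ontology, id)) {
      own <- ont_definition(ontology, id)$conjuncts
      new <- restriction_setdiff(shared, own)
      if (nrow(new) == 0L) next
      ontology$equivalence[[id]]$conjuncts <- restriction_union(own, new)
    } else {
      if (!create_missing) next
      new <- shared
      ontology <- ont_set_definition(ontology, id, shared, "lifted")
      ontology <- ont_declare_property(ontology, unique(shared$property))
    }
    additions[[length(additions) + 1L]] <-
      data.frame(class = id, property = new$property, filler = new$filler,
                 source = "lifted", origin = "children", pass = pass,
                 stringsAsFactors = FALSE)
  }
  list(ontology = ontology,
       report = completion_report(do.call(rbind, additions), pass))
}

#' Run the full completion pipeline
#'
#' [inherit_down()] followed by [lift_shared()], each a single pass by
#' default (the two processes are sequential); `fixpoint = TRUE` repeats
#' the pair until neither adds a restriction.
#'
#' @param ontology an `el_ontology`.
#' @param fixpoint iterate to stability instead of a single pass each.
#' @param create_missing passed to [lift_shared()].
#' @return A list with components `ontology` and `report` (all additions
#'   combined, with the pass number each was made in).
#' @export
complete_ontology <- function(ontology, fixpoint = FALSE,
                              create_missing = FALSE) {
  all_rows <- list()
  pass <- 1L
  repeat {
    st1 <- inherit_down(ontology, pass = pass)
    st2 <- lift_shared(st1$ontology, create_missing = create_missing,
                       pass = pass)
    ontology <- st2$ontology
    rows <- rbind(st1$report$additions, st2$report$additions)
    all_rows[[pass]] <- rows
    if (!fixpoint || nrow(rows) == 0L || pass >= 25L) break
    pass <- pass + 1L
  }
  list(ontology = ontology,
       report = completion_report(do.call(rbind, all_rows), pass))
}
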