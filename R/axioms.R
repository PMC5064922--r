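# Equivalence-axiom generation: turn SNOMED->ICD mappings plus whitelisted
# SNOMED relationships into class definitions (conjunctions of existential
# restrictions), import the SNOMED is-a closure of every filler, fill gaps
# from a secondary mapping source, and report completion statistics.

#' The default object-property whitelist
#'
#' Exactly twelve SNOMED CT attribute relationships provide information
#' about ICD inclusion terms and are admitted into class definitions; each
#' is paired with the ontology object-property name it is renamed to.
#' Historical attributes ("was a", "maybe a", "moved to"), "Is a" and
#' qualifier relationships are never harvested.
#'
#' @param path optional TSV with columns `property`, `sct_relationship`
#'   overriding the packaged table.
#' @return Data frame with columns `property` (canonical hyphenated name),
#'   `sct_relationship` (SNOMED relationship name) and `camel` (the
#'   serialized IRI local name).
#' @export
default_property_whitelist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "property_whitelist.tsv",
                        package = "elicd", mustWork = TRUE)
  }
  wl <- read_tsv_strict(path, c("property", "sct_relationship"))
  if (anyDuplicated(wl$property) || anyDuplicated(wl$sct_relationship)) {
    stop_elicd("whitelist names must be unique on both sides",
               class = "elicd_integrity_error")
  }
  wl$camel <- camel_property(wl$property)
  wl
}

#' Serialized (camelCase) form of a canonical property name
#'
#' Hyphenated names are canonical inside the package; IRI local names drop
#' the hyphens and lowercase the first letter
#' (`Has-Definitional-Manifestation` becomes
#' `hasDefinitionalManifestation`), avoiding gaps between words.
#'
#' @param property character vector of canonical property names.
#' @return Character vector of camelCase local names.
#' @export
camel_property <- function(property) {
  out <- gsub("-", "", property, fixed = TRUE)
  substr(out, 1, 1) <- tolower(substr(out, 1, 1))
  out
}

#' Resolve user-supplied property names to canonical form
#'
#' Accepts the canonical hyphenated spelling or the camelCase IRI spelling.
#'
#' @param x character vector of property names.
#' @param whitelist whitelist table ([default_property_whitelist()]).
#' @return Character vector of canonical names; errors listing offenders.
#' @export
resolve_property <- function(x, whitelist = default_property_whitelist()) {
  hit <- whitelist$property[match(x, whitelist$property)]
  hit2 <- whitelist$property[match(x, whitelist$camel)]
  out <- ifelse(!is.na(hit), hit, hit2)
  if (anyNA(out)) {
    stop_elicd("unknown object property name(s): ",
               paste(unique(x[is.na(out)]), collapse = ", "),
               class = "elicd_unknown_property_error")
  }
  out
}

#' Keep only whitelisted attribute relationships
#'
#' Retains relationship rows whose `type_name` exactly matches (after
#' trimming) a whitelisted SNOMED relationship name; "Is a", historical
#' attributes and every other type are dropped from attribute harvesting.
#' Inactive rows are dropped unless `include_inactive` is set.
#'
#' @param relationships relationship data frame
#'   (see [read_sct_tables()]).
#' @param whitelist whitelist table.
#' @param include_inactive keep rows flagged inactive.
#' @return The filtered relationship data frame.
#' @export
filter_whitelist <- function(relationships,
                             whitelist = default_property_whitelist(),
                             include_inactive = FALSE) {
  keep <- trimws(relationships$type_name) %in% whitelist$sct_relationship
  if (!include_inactive) keep <- keep & relationships$active
  out <- relationships[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concept ids mapped to an ICD category
#'
#' @param icd_code normalized or raw ICD code.
#' @param mappings deduplicated mapping data frame.
#' @return Concept ids whose mapping targets `icd_code`, in numeric order;
#'   empty when the category is unmapped.
#' @export
collect_mapped_concepts <- function(icd_code, mappings) {
  code <- normalize_code(icd_code)$code
  if (nrow(mappings) == 0L) return(character())
  hit <- normalize_codes(mappings$icd_code) == code
  sort_digit_strings(unique(mappings$sct_id[hit]))
}

#' Harvest existential restrictions for a set of mapped concepts
#'
#' Every whitelisted relationship row whose source is one of the mapped
#' concepts yields one restriction (property, destination); the union over
#' all mapped concepts is returned with set semantics.
#'
#' @param concepts character vector of concept ids.
#' @param relationships relationship rows already passed through
#'   [filter_whitelist()].
#' @param whitelist whitelist table.
#' @return A restriction set ([restriction_set()]).
#' @export
harvest_restrictions <- function(concepts, relationships,
                                 whitelist = default_property_whitelist()) {
  rows <- relationships[relationships$source_id %in% concepts, , drop = FALSE]
  if (nrow(rows) == 0L) return(restriction_set())
  prop <- whitelist$property[match(trimws(rows$type_name),
                                   whitelist$sct_relationship)]
  if (anyNA(prop)) {
    stop_elicd("harvest_restrictions received non-whitelisted relationship ",
               "type(s): ",
               paste(unique(rows$type_name[is.na(prop)]), collapse = ", "),
               class = "elicd_invariant_error")
  }
  restriction_set(prop, rows$destination_id)
}

#' Attach an equivalence axiom to an ICD class
#'
#' An empty restriction set leaves the ontology unchanged; one restriction
#' yields an equivalence to a single existential restriction (no unary
#' intersection wrapper); two or more yield an equivalence to their
#' intersection.  Re-defining a class that already has its own definition is
#' a conflict unless `force` is set.
#'
#' @param ontology an `el_ontology` with `icd_code` declared.
#' @param icd_code normalized ICD class id.
#' @param restrictions restriction set.
#' @param provenance `"mapping-primary"` or `"mapping-secondary"`.
#' @param force replace an existing definition instead of erroring.
#' @return The updated ontology.
#' @export
emit_equivalence <- function(ontology, icd_code, restrictions,
                             provenance = "mapping-primary", force = FALSE) {
  restrictions <- canonicalize_restrictions(restrictions)
  if (nrow(restrictions) == 0L) return(ontology)
  ontology <- ont_declare_property(ontology, unique(restrictions$property))
  ont_set_definition(ontology, icd_code, restrictions, provenance,
                     force = force)
}

#' Import the SNOMED is-a closure of all restriction fillers
#'
#' Declares every filler used by an equivalence axiom as a SNOMED-kind class
#' labelled with its fully specified name, walks the "Is a" relationship
#' table upward and declares every ancestor, linking each step with a
#' SubClassOf axiom tagged `imported`.  Concepts that are not ancestors of
#' any filler are never imported.
#'
#' @param ontology an `el_ontology`.
#' @param fillers concept ids to import; defaults to every filler used by an
#'   equivalence axiom in `ontology`.
#' @param relationships full relationship table (the "Is a" rows are used).
#' @param concepts concept table (for labels).
#' @param include_inactive also follow inactive "Is a" rows.
#' @return The updated ontology.
#' @export
import_sct_closure <- function(ontology, fillers = NULL, relationships,
                               concepts, include_inactive = FALSE) {
  if (is.null(fillers)) fillers <- ont_used_fillers(ontology)
  if (length(fillers) == 0L) return(ontology)
  isa <- relationships[trimws(relationships$type_name) == "Is a", ,
                       drop = FALSE]
  if (!include_inactive) isa <- isa[isa$active, , drop = FALSE]
  parents_of <- split(isa$destination_id, isa$source_id)

  todo <- sort_digit_strings(unique(fillers))
  seen <- character()
  edges <- list()
  while (length(todo) > 0L) {
    id <- todo[[1L]]
    todo <- todo[-1L]
    if (id %in% seen) next
    seen <- c(seen, id)
    for (p in sort_digit_strings(unique(parents_of[[id]] %||% character()))) {
      edges[[length(edges) + 1L]] <- c(id, p)
      if (!(p %in% seen)) todo <- c(todo, p)
    }
  }
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    cycle <- find_cycle(em[, 1L], em[, 2L])
    if (!is.null(cycle)) {
      stop_elicd("'Is a' cycle among imported concepts: ",
                 paste(cycle, collapse = " -> "),
                 class = "elicd_cycle_error")
    }
  }
  fsn_of <- concepts$fsn[match(seen, concepts$id)]
  for (i in seq_along(seen)) {
    if (ont_has_class(ontology, seen[[i]])) next
    ontology <- ont_declare_class(ontology, seen[[i]], "sct",
                                  if (is.na(fsn_of[[i]])) seen[[i]]
                                  else fsn_of[[i]])
  }
  for (e in edges) {
    ontology <- ont_add_subclass(ontology, e[[1L]], e[[2L]], "imported")
  }
  ontology
}

# ICD classes with neither an own definition nor one on any ICD ancestor
# (inheritance is judged through the ICD hierarchy only).
undefined_without_inherited <- function(ontology) {
  edges <- ont_icd_edges(ontology)
  parents_of <- split(edges$super, edges$sub)
  defined <- names(ontology$equivalence)
  has_cover <- function(id) {
    seen <- character()
    stack <- id
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v %in% defined) return(TRUE)
      stack <- c(stack, parents_of[[v]] %||% character())
    }
    FALSE
  }
  icd <- sort_c(ont_icd_classes(ontology))
  icd[!vapply(icd, has_cover, logical(1))]
}

#' Fill definition gaps from the secondary mapping source
#'
#' Candidates are ICD classes with no own definition and none inherited from
#' any ICD ancestor.  For each candidate, the collect/harvest/emit chain is
#' run over the secondary mapping rows; resulting axioms carry the
#' `mapping-secondary` provenance tag.
#'
#' @param ontology an `el_ontology` after primary generation.
#' @param secondary mapping rows tagged `secondary`.
#' @param relationships whitelist-filtered relationship rows.
#' @param whitelist whitelist table.
#' @return The updated ontology.
#' @export
fill_gaps_with_secondary <- function(ontology, secondary, relationships,
                                     whitelist = default_property_whitelist()) {
  secondary <- secondary[secondary$source_tag == "secondary", , drop = FALSE]
  for (code in undefined_without_inherited(ontology)) {
    if (code == "Diseases") next
    concepts <- collect_mapped_concepts(code, secondary)
    if (length(concepts) == 0L) next
    restr <- harvest_restrictions(concepts, relationships, whitelist)
    ontology <- emit_equivalence(ontology, code, restr,
                                 provenance = "mapping-secondary")
  }
  ontology
}

#' Completion statistics for an ontology
#'
#' @param ontology an `el_ontology`.
#' @return An `ontology_stats` list: class counts by kind, axiom counts,
#'   per-property restriction usage across own equivalence axioms,
#'   `pct_defined` (percentage of ICD classes with an own or inherited
#'   definition) and the mean number of conjuncts per defined class.
#' @export
report_stats <- function(ontology) {
  kinds <- table(factor(ontology$classes$kind,
                        levels = c("icd", "sct", "auxiliary")))
  n_icd <- as.integer(kinds[["icd"]])
  n_sct <- as.integer(kinds[["sct"]])
  defs <- ontology$equivalence
  usage <- table(unlist(lapply(defs, function(d) d$conjuncts$property),
                        use.names = FALSE))
  per_property <- stats::setNames(as.integer(usage), names(usage))
  per_property <- per_property[sort_c(names(per_property))]
  covered <- setdiff(ont_icd_classes(ontology),
                     undefined_without_inherited(ontology))
  pct <- if (n_icd == 0L) 0 else 100 * length(covered) / n_icd
  mean_conj <- if (length(defs) == 0L) NA_real_ else
    mean(vapply(defs, function(d) nrow(d$conjuncts), numeric(1)))
  structure(list(
    n_classes_total = nrow(ontology$classes),
    n_icd_classes = n_icd,
    n_sct_classes = n_sct,
    n_equivalence_axioms = length(defs),
    n_subclass_axioms = nrow(ontology$subclass),
    n_label_axioms = length(ontology$labels),
    per_property_usage = per_property,
    pct_defined = pct,
    mean_conjuncts_per_defined_class = mean_conj
  ), class = "ontology_stats")
}

#' @export
print.ontology_stats <- function(x, ...) {
  cat("Ontology statistics\n")
  cat(sprintf("  classes: %d total (%d ICD, %d SNOMED)\n",
              x$n_classes_total, x$n_icd_classes, x$n_sct_classes))
  cat(sprintf("  axioms: %d SubClassOf, %d EquivalentClasses, %d labels\n",
              x$n_subclass_axioms, x$n_equivalence_axioms, x$n_label_axioms))
  cat(sprintf("  ICD classes with own or inherited definition: %.1f%%\n",
              x$pct_defined))
  if (!is.na(x$mean_conjuncts_per_defined_class)) {
    cat(sprintf("  mean conjuncts per defined class: %.2f\n",
                x$mean_conjuncts_per_defined_class))
  }
  if (length(x$per_property_usage) > 0L) {
    cat("  restriction usage by property:\n")
    for (p in names(x$per_property_usage)) {
      cat(sprintf("    %-32s %d\n", p, x$per_property_usage[[p]]))
    }
  }
  invisible(x)
}
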