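# End-to-end construction: tables in, ontology out.

#' Build the ontology from terminology tables
#'
#' Runs the full construction pipeline: hierarchy building, whitelist
#' filtering, primary equivalence-axiom generation (one collect/harvest/emit
#' chain per ICD category), gap filling from the secondary mapping source,
#' and import of the SNOMED is-a closure of every filler.
#'
#' @param icd_rows ICD category rows ([read_icd_categories()]).
#' @param concepts,relationships SNOMED-style tables ([read_sct_tables()]).
#' @param mappings merged mapping table ([merge_mappings()]) or a single
#'   tagged table from [read_mappings()].
#' @param namespace ontology namespace.
#' @param whitelist property whitelist.
#' @param include_inactive use inactive concepts/relationship rows too.
#' @param chapter_blocks chapter block table, or `NULL` to use only blocks
#'   present in `icd_rows`.
#' @param all_chapters materialize every configured chapter block.
#' @param extra_fillers additional SNOMED concept ids whose is-a closure is
#'   imported alongside the restriction fillers — typically the concepts
#'   asserted by the clinical-record queries that will be classified
#'   against the ontology.
#' @return A validated `el_ontology`.
#' @export
build_ontology <- function(icd_rows, concepts, relationships, mappings,
                           namespace = default_namespace(),
                           whitelist = default_property_whitelist(),
                           include_inactive = FALSE,
                           chapter_blocks = icd_chapter_blocks(),
                           all_chapters = FALSE,
                           extra_fillers = character()) {
  hierarchy <- build_hierarchy(icd_rows, chapter_blocks = chapter_blocks,
                               all_chapters = all_chapters)
  ontology <- ontology_from_hierarchy(hierarchy, namespace)

  if (!include_inactive) {
    active_ids <- concepts$id[concepts$active]
    mappings <- mappings[mappings$sct_id %in% active_ids |
                           !(mappings$sct_id %in% concepts$id), ,
                         drop = FALSE]
  }
  filtered <- filter_whitelist(relationships, whitelist,
                               include_inactive = include_inactive)

  primary <- mappings[mappings$source_tag == "primary", , drop = FALSE]
  for (code in sort_c(hierarchy$nodes$code)) {
    ids <- collect_mapped_concepts(code, primary)
    if (length(ids) == 0L) next
    restr <- harvest_restrictions(ids, filtered, whitelist)
    ontology <- emit_equivalence(ontology, code, restr,
                                 provenance = "mapping-primary")
  }

  ontology <- fill_gaps_with_secondary(ontology, mappings, filtered,
                                       whitelist)
  fillers <- union(ont_used_fillers(ontology),
                   intersect(extra_fillers, concepts$id))
  ontology <- import_sct_closure(ontology, fillers, relationships, concepts,
                                 include_inactive = include_inactive)
  validate_ontology(ontology)
  ontology
}
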