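# Worked-example terminology bundles.  Each bundle is a self-contained,
# referentially closed set of tables (ICD categories, SNOMED-style concepts
# and relationships, mapping tables, queries) together with the outcomes the
# pipeline must reproduce on it.
#
# Concept ids that the source material prints (62275004, 24184005, 38341003,
# 449759005, 113257007, 51840005, 113276009, 71854001, 255399007) are used
# verbatim.  Ids it does not print are SYNTHETIC: they live in the 99xxxxx
# range, outside real SNOMED CT identifier ranges, and stand in for the real
# concepts only structurally.  The use-case fixtures likewise define their
# target ICD classes from the assertion sets the use cases print — they test
# the classification machinery, not any published axiom set.

bundle_names <- function() {
  c("i10", "cholera", "k58_e73", "k61_usecase2", "usecase1", "usecase3",
    "a93_8")
}

sct_concept_rows <- function(ids, fsns, active = TRUE) {
  data.frame(id = ids, fsn = fsns,
             active = rep_len(active, length(ids)),
             stringsAsFactors = FALSE)
}

sct_relationship_rows <- function(source, type, destination, active = TRUE) {
  data.frame(source_id = source, type_name = type,
             destination_id = destination,
             active = rep_len(active, length(source)),
             stringsAsFactors = FALSE)
}

mapping_rows <- function(sct_id, icd_code, source_tag) {
  if (length(sct_id) == 0L) {
    return(data.frame(sct_id = character(), icd_code = character(),
                      source_tag = character(), stringsAsFactors = FALSE))
  }
  data.frame(sct_id = sct_id, icd_code = icd_code, source_tag = source_tag,
             stringsAsFactors = FALSE)
}

icd_rows <- function(code, label) {
  data.frame(code = code, label = label, stringsAsFactors = FALSE)
}

new_bundle <- function(name, icd, concepts, relationships,
                       primary = mapping_rows(character(), character(),
                                              character()),
                       secondary = mapping_rows(character(), character(),
                                                character()),
                       queries = list(), expected = list(), extras = list(),
                       use_chapter_config = TRUE) {
  structure(list(name = name, icd_rows = icd, sct_concepts = concepts,
                 sct_relationships = relationships,
                 mappings_primary = primary, mappings_secondary = secondary,
                 queries = queries, expected = expected, extras = extras,
                 use_chapter_config = use_chapter_config),
            class = "terminology_bundle")
}

#' @export
print.terminology_bundle <- function(x, ...) {
  cat("<terminology_bundle>", x$name, "\n")
  cat(sprintf("  %d ICD rows, %d concepts, %d relationships, %d+%d mappings, %d queries\n",
              nrow(x$icd_rows), nrow(x$sct_concepts),
              nrow(x$sct_relationships), nrow(x$mappings_primary),
              nrow(x$mappings_secondary), length(x$queries)))
  invisible(x)
}

#' Worked-example terminology bundles
#'
#' Returns one of the built-in bundles reproducing the worked examples:
#' `i10` (essential hypertension inclusion terms and full definition),
#' `cholera` (the A00 subtree with inherited definitions), `k58_e73` (the
#' irritable-bowel/lactase-deficiency misclassification fixed by sibling
#' lift), `k61_usecase2` (anorectal abscess realization), `usecase1`
#' (thrombocytopenia realization), `usecase3` (secondary malignant
#' neoplasms realization) and `a93_8` (one-to-many secondary mappings).
#'
#' @param name one of [bundle_names()].
#' @return A `terminology_bundle`.
#' @export
paper_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% bundle_names())) {
    stop_elicd("unknown fixture '", paste(name, collapse = ","),
               "'; valid names: ", paste(bundle_names(), collapse = ", "),
               class = "elicd_unknown_fixture_error")
  }
  switch(name,
         i10 = bundle_i10(),
         cholera = bundle_cholera(),
         k58_e73 = bundle_k58_e73(),
         k61_usecase2 = bundle_k61_usecase2(),
         usecase1 = bundle_usecase1(),
         usecase3 = bundle_usecase3(),
         a93_8 = bundle_a93_8())
}

bundle_i10 <- function() {
  concepts <- sct_concept_rows(
    c("62275004", "449759005", "24184005", "38341003", "113257007",
      "51840005", "404684003", "123037004", "64572001"),
    c("Hypertensive episode (disorder)",
      "Complication of systemic hypertensive disorder (disorder)",
      "Finding of increased blood pressure (finding)",
      "Hypertensive disorder, systemic arterial (disorder)",
      "Structure of cardiovascular system (body structure)",
      "Systemic circulatory system structure (body structure)",
      "Clinical finding (finding)",
      "Body structure (body structure)",
      "Disease (disorder)"))
  inclusion <- sct_relationship_rows(
    c("62275004", "449759005"),
    c("Has definitional manifestation", "Associated with"),
    c("24184005", "38341003"))
  site <- sct_relationship_rows(
    c("62275004", "449759005"),
    c("Finding site", "Finding site"),
    c("113257007", "51840005"))
  noise <- sct_relationship_rows(
    c("62275004", "449759005", "62275004"),
    c("Is a", "Is a", "Was a"),
    c("64572001", "64572001", "64572001"))
  isa <- sct_relationship_rows(
    c("24184005", "38341003", "64572001", "113257007", "51840005"),
    "Is a",
    c("404684003", "64572001", "404684003", "123037004", "123037004"))
  relationships <- rbind(inclusion, site, noise, isa)
  new_bundle(
    "i10",
    icd_rows("I10", "Essential primary hypertension"),
    concepts, relationships,
    primary = mapping_rows(c("62275004", "449759005"), "I10", "primary"),
    extras = list(inclusion_relationships = rbind(inclusion, noise, isa)),
    expected = list(
      list(type = "mapped_count", code = "I10", source = "primary", n = 2L),
      list(type = "definition", stage = "build", class = "I10",
           conjuncts = restriction_set(
             c("Affects", "Affects", "Associated-With",
               "Has-Definitional-Manifestation"),
             c("113257007", "51840005", "38341003", "24184005"))),
      list(type = "subsumption", stage = "build", sub = "I10",
           super = "I00_I99", value = TRUE)))
}

bundle_cholera <- function() {
  concepts <- sct_concept_rows(
    c("9900011", "9900012", "9900013", "9900100", "9900101", "9900102",
      "9900103", "113276009", "123037004"),
    c("Cholera (disorder)",
      "Cholera due to Vibrio cholerae 01, biovar cholerae (disorder)",
      "Cholera due to Vibrio cholerae 01, biovar eltor (disorder)",
      "Genus Vibrio (organism)",
      "Vibrio cholerae (organism)",
      "Vibrio cholerae 01, biovar cholerae (organism)",
      "Vibrio cholerae 01, biovar eltor (organism)",
      "Intestinal structure (body structure)",
      "Body structure (body structure)"))
  relationships <- rbind(
    sct_relationship_rows(
      c("9900011", "9900011", "9900012", "9900013"),
      c("Causative agent", "Finding site", "Causative agent",
        "Causative agent"),
      c("9900101", "113276009", "9900102", "9900103")),
    sct_relationship_rows(
      c("9900102", "9900103", "9900101", "113276009"),
      "Is a",
      c("9900101", "9900101", "9900100", "123037004")))
  new_bundle(
    "cholera",
    icd_rows(c("A00-A09", "A00", "A00.0", "A00.1", "A00.9"),
             c("Intestinal infectious diseases", "Cholera",
               "Cholera due to Vibrio cholerae 01, biovar cholerae",
               "Cholera due to Vibrio cholerae 01, biovar eltor",
               "Cholera, unspecified")),
    concepts, relationships,
    primary = mapping_rows(c("9900011", "9900012", "9900013"),
                           c("A00", "A00.0", "A00.1"), "primary"),
    expected = list(
      list(type = "parent", code = "A00_0", parent = "A00"),
      list(type = "parent", code = "A00", parent = "A00_A09"),
      list(type = "parent", code = "A00_A09", parent = "A00_B99"),
      list(type = "parent", code = "A00_B99", parent = "Diseases"),
      list(type = "subsumption", stage = "build", sub = "A00_9",
           super = "A00_B99", value = TRUE),
      list(type = "subsumption", stage = "build", sub = "A00_0",
           super = "A00", value = TRUE),
      list(type = "definition", stage = "complete", class = "A00_0",
           conjuncts = restriction_set(
             c("Affects", "Caused-By-Agent", "Caused-By-Agent"),
             c("113276009", "9900101", "9900102")))))
}

bundle_k58_e73 <- function() {
  concepts <- sct_concept_rows(
    c("9900021", "9900022", "9900023", "9900024", "113276009", "71854001",
      "255399007", "123037004"),
    c("Irritable bowel syndrome (disorder)",
      "Congenital lactase deficiency (disorder)",
      "Irritable bowel syndrome with diarrhea (disorder)",
      "Irritable bowel syndrome without diarrhea (disorder)",
      "Intestinal structure (body structure)",
      "Colon structure (body structure)",
      "Congenital (qualifier value)",
      "Body structure (body structure)"))
  relationships <- rbind(
    sct_relationship_rows(
      c("9900021", "9900022", "9900022", "9900023", "9900023", "9900024",
        "9900024"),
      c("Finding site", "Finding site", "Occurrence", "Finding site",
        "Finding site", "Finding site", "Finding site"),
      c("113276009", "113276009", "255399007", "113276009", "71854001",
        "113276009", "71854001")),
    sct_relationship_rows(
      c("71854001", "113276009"), "Is a", c("113276009", "123037004")))
  new_bundle(
    "k58_e73",
    icd_rows(c("K58", "K58.0", "K58.9", "E73", "E73.0"),
             c("Irritable bowel syndrome",
               "Irritable bowel syndrome with diarrhea",
               "Irritable bowel syndrome without diarrhea",
               "Lactose intolerance",
               "Congenital lactase deficiency")),
    concepts, relationships,
    primary = mapping_rows(c("9900021", "9900023", "9900024", "9900022"),
                           c("K58", "K58.0", "K58.9", "E73.0"), "primary"),
    expected = list(
      list(type = "definition", stage = "build", class = "K58",
           conjuncts = restriction_set("Affects", "113276009")),
      list(type = "definition", stage = "build", class = "E73_0",
           conjuncts = restriction_set(c("Affects", "Has-Occurrence"),
                                       c("113276009", "255399007"))),
      list(type = "subsumption", stage = "build", sub = "E73_0",
           super = "K58", value = TRUE),
      list(type = "definition", stage = "complete", class = "K58",
           conjuncts = restriction_set(c("Affects", "Affects"),
                                       c("113276009", "71854001"))),
      list(type = "subsumption", stage = "complete", sub = "E73_0",
           super = "K58", value = FALSE),
      list(type = "subsumption", stage = "complete", sub = "K58_0",
           super = "K58", value = TRUE)))
}

bundle_k61_usecase2 <- function() {
  site <- c(K61_0 = "9900035", K61_1 = "9900036", K61_2 = "9900037",
            K61_3 = "9900034", K61_4 = "9900038")
  src <- c(K61 = "9900041", K61_0 = "9900042", K61_1 = "9900043",
           K61_2 = "9900044", K61_3 = "9900045", K61_4 = "9900046")
  concepts <- sct_concept_rows(
    c(unname(src), "9900031", "9900032", "9900033", unname(site),
      "123037004"),
    c("Abscess of anal and/or rectal region (disorder)",
      "Anal abscess (disorder)", "Rectal abscess (disorder)",
      "Anorectal abscess (disorder)", "Ischiorectal abscess (disorder)",
      "Intrasphincteric abscess (disorder)",
      "Anorectal structure (body structure)",
      "Abscess (morphologic abnormality)",
      "Infectious process (qualifier value)",
      "Anal structure (body structure)",
      "Rectal structure (body structure)",
      "Anorectal junction structure (body structure)",
      "Ischiorectal fossa structure (body structure)",
      "Anal sphincter structure (body structure)",
      "Body structure (body structure)"))
  base <- function(s, site_filler = "9900031") {
    sct_relationship_rows(
      rep(s, 3L),
      c("Finding site", "Associated morphology", "Pathological process"),
      c(site_filler, "9900032", "9900033"))
  }
  relationships <- rbind(
    base(src[["K61"]]),
    base(src[["K61_0"]], site[["K61_0"]]),
    base(src[["K61_1"]], site[["K61_1"]]),
    base(src[["K61_2"]], site[["K61_2"]]),
    base(src[["K61_3"]], site[["K61_3"]]),
    base(src[["K61_4"]], site[["K61_4"]]),
    sct_relationship_rows(c(unname(site), "9900031"), "Is a",
                          c(rep("9900031", 5L), "123037004")))
  queries <- list(
    abscess_main = data.frame(
      property = c("affects", "hasAssociatedMorphology",
                   "hasPathologicalProcess"),
      filler_id = c("9900031", "9900032", "9900033"),
      stringsAsFactors = FALSE),
    abscess_refined = data.frame(
      property = c("affects", "hasAssociatedMorphology",
                   "hasPathologicalProcess", "affects"),
      filler_id = c("9900031", "9900032", "9900033", site[["K61_3"]]),
      stringsAsFactors = FALSE))
  new_bundle(
    "k61_usecase2",
    icd_rows(c("K61", "K61.0", "K61.1", "K61.2", "K61.3", "K61.4"),
             c("Abscess of anal and rectal regions", "Anal abscess",
               "Rectal abscess", "Anorectal abscess",
               "Ischiorectal abscess", "Intrasphincteric abscess")),
    concepts, relationships,
    primary = mapping_rows(unname(src),
                           c("K61", "K61.0", "K61.1", "K61.2", "K61.3",
                             "K61.4"), "primary"),
    queries = queries,
    expected = list(
      list(type = "children_count", code = "K61", n = 5L),
      list(type = "realization", stage = "complete", query = "abscess_main",
           classes = "K61", where = "all_subsumers"),
      list(type = "realization", stage = "complete", query = "abscess_main",
           classes = "K61", where = "most_specific"),
      list(type = "realization", stage = "complete",
           query = "abscess_refined", classes = "K61_3",
           where = "most_specific")))
}

bundle_usecase1 <- function() {
  concepts <- sct_concept_rows(
    c("9900061", "9900051", "9900052", "9900053"),
    c("Thrombocytopenic disorder (disorder)",
      "Platelet count (procedure)",
      "Platelet count below reference range (finding)",
      "Hypersensitivity process (qualifier value)"))
  relationships <- sct_relationship_rows(
    rep("9900061", 3L),
    c("Interprets", "Has definitional manifestation",
      "Pathological process"),
    c("9900051", "9900052", "9900053"))
  queries <- list(
    hematology = data.frame(
      property = c("interprets", "hasDefinitionalManifestation",
                   "hasPathologicalProcess"),
      filler_id = c("9900051", "9900052", "9900053"),
      stringsAsFactors = FALSE))
  new_bundle(
    "usecase1",
    icd_rows(c("D69", "D69.6"),
             c("Purpura and other hemorrhagic conditions",
               "Thrombocytopenia, unspecified")),
    concepts, relationships,
    primary = mapping_rows("9900061", "D69.6", "primary"),
    queries = queries,
    expected = list(
      list(type = "realization", stage = "complete", query = "hematology",
           classes = "D69_6", where = "all_subsumers")))
}

bundle_usecase3 <- function() {
  concepts <- sct_concept_rows(
    c("9900081", "9900082", "9900083", "9900071", "9900072", "9900073",
      "9900074", "9900075", "9900076", "9900077", "9900079", "9900080",
      "123037004"),
    c("Secondary malignant neoplastic disease (disorder)",
      "Secondary malignant neoplasm of respiratory organ (disorder)",
      "Secondary malignant neoplasm of digestive organ (disorder)",
      "Neoplasm, metastatic (morphologic abnormality)",
      "Structure of retroperitoneal lymph node (body structure)",
      "Lung structure (body structure)",
      "Liver structure (body structure)",
      "Peritoneum (serous membrane) structure (body structure)",
      "Abdominal lymph node structure (body structure)",
      "Retroperitoneal structure (body structure)",
      "Respiratory system structure (body structure)",
      "Digestive system structure (body structure)",
      "Body structure (body structure)"))
  relationships <- rbind(
    sct_relationship_rows(
      c("9900081", "9900082", "9900082", "9900083", "9900083"),
      c("Associated morphology", "Associated morphology", "Finding site",
        "Associated morphology", "Finding site"),
      c("9900071", "9900071", "9900079", "9900071", "9900080")),
    sct_relationship_rows(
      c("9900073", "9900074", "9900079", "9900080"), "Is a",
      c("9900079", "9900080", "123037004", "123037004")))
  queries <- list(
    metastases = data.frame(
      property = c("hasAssociatedMorphology", rep("affects", 6L)),
      filler_id = c("9900071", "9900072", "9900073", "9900074", "9900075",
                    "9900076", "9900077"),
      stringsAsFactors = FALSE))
  new_bundle(
    "usecase3",
    icd_rows(c("C78", "C78.3", "C78.30", "C78.80"),
             c("Secondary malignant neoplasm of respiratory and digestive organs",
               "Secondary malignant neoplasm of other and unspecified respiratory organs",
               "Secondary malignant neoplasm of unspecified respiratory organ",
               "Secondary malignant neoplasm of unspecified digestive organ")),
    concepts, relationships,
    primary = mapping_rows(c("9900081", "9900082", "9900083"),
                           c("C78", "C78.30", "C78.80"), "primary"),
    queries = queries,
    expected = list(
      list(type = "parent", code = "C78_80", parent = "C78"),
      list(type = "parent", code = "C78_30", parent = "C78_3"),
      list(type = "realization", stage = "complete", query = "metastases",
           classes = c("C78", "C78_30", "C78_80"),
           where = "all_subsumers")))
}

bundle_a93_8 <- function() {
  concepts <- sct_concept_rows(
    c("9900091", "9900092", "9900093", "9900094", "9900095", "9900096"),
    c("[X]Other specified arthropod-borne viral fevers (disorder)",
      "Piry virus disease (disorder)",
      "[X]Other specified viral hemorrhagic fevers (disorder)",
      "Piry virus (organism)",
      "Arbovirus (organism)",
      "Virus (organism)"))
  relationships <- rbind(
    sct_relationship_rows(
      c("9900092", "9900091", "9900093"), "Causative agent",
      c("9900094", "9900095", "9900096")),
    sct_relationship_rows(
      c("9900094", "9900095"), "Is a", c("9900095", "9900096")))
  new_bundle(
    "a93_8",
    icd_rows(c("A93", "A93.8"),
             c("Other arthropod-borne viral fevers, not elsewhere classified",
               "Other specified arthropod-borne viral fevers")),
    concepts, relationships,
    secondary = mapping_rows(c("9900091", "9900092", "9900093"), "A93.8",
                             "secondary"),
    expected = list(
      list(type = "mapped_count", code = "A93.8", source = "secondary",
           n = 3L),
      list(type = "definition", stage = "build", class = "A93_8",
           provenance = "mapping-secondary",
           conjuncts = restriction_set(rep("Caused-By-Agent", 3L),
                                       c("9900094", "9900095",
                                         "9900096")))))
}

#' Build the ontology from a terminology bundle
#'
#' In-memory equivalent of writing the bundle to disk and running the build
#' command on it.
#'
#' @param bundle a `terminology_bundle`.
#' @param include_inactive passed through to [build_ontology()].
#' @param namespace ontology namespace.
#' @param relationships optional replacement relationship table (e.g. the
#'   `inclusion_relationships` subset some bundles carry in `extras`).
#' @return An `el_ontology`.
#' @export
build_from_bundle <- function(bundle, include_inactive = FALSE,
                              namespace = default_namespace(),
                              relationships = NULL) {
  stopifnot(inherits(bundle, "terminology_bundle"))
  query_fillers <- unique(unlist(lapply(bundle$queries,
                                        function(q) q$filler_id),
                                 use.names = FALSE))
  build_ontology(
    bundle$icd_rows, bundle$sct_concepts,
    relationships %||% bundle$sct_relationships,
    merge_mappings(bundle$mappings_primary, bundle$mappings_secondary),
    namespace = namespace,
    include_inactive = include_inactive,
    chapter_blocks = if (isTRUE(bundle$use_chapter_config))
      icd_chapter_blocks() else NULL,
    extra_fillers = query_fillers %||% character())
}

#' Write a bundle to a directory in the canonical TSV dialects
#'
#' Produces `icd_categories.tsv`, `sct_concepts.tsv`,
#' `sct_relationships.tsv`, `mappings_primary.tsv`,
#' `mappings_secondary.tsv` and, when the bundle has queries, `query.tsv`.
#'
#' @param bundle a `terminology_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file, cols) {
    utils::write.table(df[, cols, drop = FALSE], file.path(dir, file),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(bundle$icd_rows, "icd_categories.tsv", names(bundle$icd_rows))
  con <- bundle$sct_concepts
  con$active <- as.integer(con$active)
  w(con, "sct_concepts.tsv", c("id", "fsn", "active"))
  rel <- bundle$sct_relationships
  rel$active <- as.integer(rel$active)
  w(rel, "sct_relationships.tsv",
    c("source_id", "type_name", "destination_id", "active"))
  w(bundle$mappings_primary, "mappings_primary.tsv", c("sct_id", "icd_code"))
  w(bundle$mappings_secondary, "mappings_secondary.tsv",
    c("sct_id", "icd_code"))
  if (length(bundle$queries) > 0L) {
    write_queries(bundle$queries, file.path(dir, "query.tsv"))
  }
  invisible(dir)
}

#' Verify a bundle's packaged expectations end-to-end
#'
#' Runs build (and, where required, completion and realization) on the
#' bundle and evaluates every record in `bundle$expected`.
#'
#' @param bundle a `terminology_bundle`.
#' @return Named logical vector, one entry per expectation (all `TRUE` when
#'   the bundle reproduces its outcomes).
#' @export
check_bundle_expectations <- function(bundle) {
  built <- build_from_bundle(bundle)
  completed <- complete_ontology(built)$ontology
  hierarchy <- build_hierarchy(
    bundle$icd_rows,
    chapter_blocks = if (isTRUE(bundle$use_chapter_config))
      icd_chapter_blocks() else NULL)
  states <- list()
  state_of <- function(stage) {
    if (is.null(states[[stage]])) {
      states[[stage]] <<- el_saturate(if (stage == "build") built
                                      else completed)
    }
    states[[stage]]
  }
  ont_of <- function(stage) if (stage == "build") built else completed

  results <- vapply(bundle$expected, function(e) {
    switch(e$type,
      parent = identical(unname(hierarchy$parent[e$code]), e$parent),
      children_count =
        sum(hierarchy$parent == e$code, na.rm = TRUE) == e$n,
      mapped_count = {
        maps <- switch(e$source,
                       primary = bundle$mappings_primary,
                       secondary = bundle$mappings_secondary,
                       merged = merge_mappings(bundle$mappings_primary,
                                               bundle$mappings_secondary))
        length(collect_mapped_concepts(e$code, maps)) == e$n
      },
      definition = {
        ont <- ont_of(e$stage)
        ont_has_definition(ont, e$class) &&
          restriction_equal(ont_definition(ont, e$class)$conjuncts,
                            e$conjuncts) &&
          (is.null(e$provenance) ||
             identical(ont_definition(ont, e$class)$provenance,
                       e$provenance))
      },
      subsumption =
        is_subsumed_by(state_of(e$stage), e$sub, e$super) == e$value,
      realization = {
        res <- realize_query(bundle$queries[[e$query]], ont_of(e$stage))
        all(e$classes %in% res[[e$where]])
      },
      stop_elicd("unknown expectation type ", e$type,
                 class = "elicd_invariant_error"))
  }, logical(1))
  names(results) <- vapply(bundle$expected, function(e) {
    paste(c(e$type, e$class %||% e$code %||% e$query, e$stage %||% NULL),
          collapse = ":")
  }, character(1))
  results
}
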