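test_that("the default whitelist holds the twelve admitted relationships", {
  wl <- default_property_whitelist()
  expect_equal(nrow(wl), 12L)
  expect_setequal(wl$sct_relationship,
                  c("Finding site", "After", "Associated with",
                    "Causative agent", "Due to", "Associated finding",
                    "Associated morphology",
                    "Has definitional manifestation", "Occurrence",
                    "Pathological process", "Interprets", "Part of"))
  expect_equal(wl$property[wl$sct_relationship == "Causative agent"],
               "Caused-By-Agent")
  expect_equal(camel_property("Has-Definitional-Manifestation"),
               "hasDefinitionalManifestation")
  expect_equal(camel_property(c("Affects", "IsPartOf", "Associated-With")),
               c("affects", "isPartOf", "associatedWith"))
  # both spellings resolve to the canonical name
  expect_equal(resolve_property(c("affects", "Has-Occurrence")),
               c("Affects", "Has-Occurrence"))
  expect_error(resolve_property("frobnicates"),
               class = "elicd_unknown_property_error")
})

test_that("whitelist filtering keeps admitted types and drops the rest", {
  rel <- data.frame(
    source_id = rep("100", 4L),
    type_name = c("Causative agent", "Was a", "Is a", "Episodicity"),
    destination_id = c("201", "202", "203", "204"),
    active = TRUE, stringsAsFactors = FALSE)
  kept <- filter_whitelist(rel)
  expect_equal(kept$type_name, "Causative agent")
  expect_equal(nrow(filter_whitelist(rel[0, ])), 0L)
  # inactive rows are excluded unless requested
  rel$active[[1]] <- FALSE
  expect_equal(nrow(filter_whitelist(rel)), 0L)
  expect_equal(nrow(filter_whitelist(rel, include_inactive = TRUE)), 1L)
})

test_that("mapped-concept collection matches the worked examples", {
  i10 <- paper_fixture("i10")
  expect_equal(collect_mapped_concepts("I10", i10$mappings_primary),
               c("62275004", "449759005"))
  expect_equal(collect_mapped_concepts("J45", i10$mappings_primary),
               character())
  a93 <- paper_fixture("a93_8")
  expect_length(collect_mapped_concepts("A93.8", a93$mappings_secondary), 3L)
})

test_that("harvesting reproduces the hypertension inclusion and full definitions", {
  b <- paper_fixture("i10")
  wl <- default_property_whitelist()
  concepts <- collect_mapped_concepts("I10", b$mappings_primary)

  inclusion <- harvest_restrictions(
    concepts, filter_whitelist(b$extras$inclusion_relationships, wl), wl)
  expect_true(restriction_equal(inclusion, restriction_set(
    c("Has-Definitional-Manifestation", "Associated-With"),
    c("24184005", "38341003"))))

  full <- harvest_restrictions(
    concepts, filter_whitelist(b$sct_relationships, wl), wl)
  expect_true(restriction_equal(full, restriction_set(
    c("Has-Definitional-Manifestation", "Associated-With", "Affects",
      "Affects"),
    c("24184005", "38341003", "113257007", "51840005"))))

  expect_equal(nrow(harvest_restrictions("424242",
                                         filter_whitelist(b$sct_relationships,
                                                          wl), wl)), 0L)
})

test_that("equivalence emission collapses duplicates and guards re-definition", {
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = "I10", label = "hyp", stringsAsFactors = FALSE)))
  ont <- elicd:::ont_declare_class(ont, "24184005", "sct", "f")

  # empty restriction set leaves the ontology unchanged
  same <- emit_equivalence(ont, "I10", restriction_set())
  expect_true(ontology_equal(ont, same))

  # duplicates collapse: a single-conjunct definition results
  dup <- restriction_set(c("Has-Definitional-Manifestation",
                           "Has-Definitional-Manifestation"),
                         c("24184005", "24184005"))
  ont <- emit_equivalence(ont, "I10", dup)
  expect_equal(nrow(ont_definition(ont, "I10")$conjuncts), 1L)
  # the single conjunct serializes without an intersection wrapper
  f <- tempfile(fileext = ".ofn")
  write_ontology(ont, f)
  eq <- grep("^EquivalentClasses", readLines(f), value = TRUE)
  expect_length(eq, 1L)
  expect_false(grepl("ObjectIntersectionOf", eq))

  expect_error(emit_equivalence(ont, "I10",
                                restriction_set("Affects", "24184005")),
               class = "elicd_conflict_error")
  forced <- emit_equivalence(ont, "I10",
                             restriction_set("Affects", "24184005"),
                             force = TRUE)
  expect_equal(ont_definition(forced, "I10")$conjuncts$property, "Affects")
})

test_that("SNOMED import declares exactly the filler ancestors", {
  # chain of length 3: filler -> p1 -> p2 -> p3
  con <- data.frame(id = as.character(9000001:9000005),
                    fsn = paste("c", 9000001:9000005),
                    active = TRUE, stringsAsFactors = FALSE)
  rel <- data.frame(source_id = c("9000001", "9000002", "9000003",
                                  "9000005"),
                    type_name = "Is a",
                    destination_id = c("9000002", "9000003", "9000004",
                                       "9000004"),
                    active = TRUE, stringsAsFactors = FALSE)
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = "A00", label = "x", stringsAsFactors = FALSE)))
  ont <- elicd:::ont_declare_class(ont, "9000001", "sct", "seed filler")
  ont <- emit_equivalence(ont, "A00", restriction_set("Affects", "9000001"))

  before <- ont
  out <- import_sct_closure(ont, relationships = rel, concepts = con)
  added_edges <- out$subclass[out$subclass$provenance == "imported", ]
  expect_equal(nrow(added_edges), 3L)  # brute-force closure of the chain
  # 9000005 is not an ancestor of the filler and must not be imported
  expect_false("9000005" %in% out$classes$id)
  expect_true(all(c("9000002", "9000003", "9000004") %in% out$classes$id))
  # labels carry the fully specified names
  expect_equal(out$labels[["9000003"]], "c 9000003")

  # no fillers -> unchanged
  expect_true(ontology_equal(before,
                             import_sct_closure(before,
                                                fillers = character(),
                                                relationships = rel,
                                                concepts = con)))

  # an is-a cycle is an error
  cyc <- rbind(rel, data.frame(source_id = "9000004", type_name = "Is a",
                               destination_id = "9000001", active = TRUE,
                               stringsAsFactors = FALSE))
  expect_error(import_sct_closure(ont, relationships = cyc, concepts = con),
               class = "elicd_cycle_error")
})

test_that("gap filling defines only classes with no own or inherited axiom", {
  # three-class fixture: parent defined, child1 inherits, child2's branch
  # (separate tree) is truly undefined and has a secondary mapping
  rows <- data.frame(code = c("A00", "A00.0", "B99"),
                     label = c("parent", "child", "gap"),
                     stringsAsFactors = FALSE)
  ont <- ontology_from_hierarchy(build_hierarchy(rows))
  ont <- elicd:::ont_declare_class(ont, "9000010", "sct", "f")
  ont <- emit_equivalence(ont, "A00", restriction_set("Affects", "9000010"))

  secondary <- data.frame(sct_id = c("9000021", "9000022"),
                          icd_code = c("A00.0", "B99"),
                          source_tag = "secondary", stringsAsFactors = FALSE)
  rel <- data.frame(source_id = c("9000021", "9000022"),
                    type_name = "Causative agent",
                    destination_id = c("9000031", "9000032"),
                    active = TRUE, stringsAsFactors = FALSE)
  wl <- default_property_whitelist()
  out <- fill_gaps_with_secondary(ont, secondary, filter_whitelist(rel, wl),
                                  wl)
  # A00 keeps its primary definition, A00_0 inherits (stays undefined)
  expect_equal(ont_definition(out, "A00")$provenance, "mapping-primary")
  expect_false(ont_has_definition(out, "A00_0"))
  # B99 gains a one-conjunct secondary definition
  expect_true(ont_has_definition(out, "B99"))
  expect_equal(ont_definition(out, "B99")$provenance, "mapping-secondary")
  expect_equal(nrow(ont_definition(out, "B99")$conjuncts), 1L)
})

test_that("statistics count classes, per-property usage and coverage", {
  stats <- report_stats(built_fixture("i10"))
  expect_equal(stats$n_classes_total,
               stats$n_icd_classes + stats$n_sct_classes)
  expect_equal(stats$per_property_usage[["Affects"]], 2L)
  expect_equal(stats$per_property_usage[["Associated-With"]], 1L)
  expect_equal(stats$per_property_usage[["Has-Definitional-Manifestation"]],
               1L)
  expect_equal(stats$n_equivalence_axioms, 1L)

  hier_only <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("A00", "A01", "A02"), label = c("a", "b", "c"),
               stringsAsFactors = FALSE)))
  hstats <- report_stats(hier_only)
  expect_equal(hstats$n_equivalence_axioms, 0L)
  expect_equal(hstats$pct_defined, 0)
})

test_that("coverage percentage is the defined-or-inheriting share of ICD classes", {
  rows <- data.frame(code = c("A00", "A01", "A02"),
                     label = c("a", "b", "c"), stringsAsFactors = FALSE)
  ont <- ontology_from_hierarchy(build_hierarchy(rows))
  ont <- elicd:::ont_declare_class(ont, "9000010", "sct", "f")
  ont <- emit_equivalence(ont, "A00", restriction_set("Affects", "9000010"))
  ont <- emit_equivalence(ont, "A01", restriction_set("Affects", "9000010"))
  st <- report_stats(ont)
  # ICD classes: Diseases, A00_B99, A00, A01, A02 -> 2 of 5 covered
  expect_equal(st$n_icd_classes, 5L)
  expect_equal(st$pct_defined, 100 * 2 / 5)
  expect_equal(st$mean_conjuncts_per_defined_class, 1)
})

test_that("harvesting is monotone in added relationship rows", {
  wl <- default_property_whitelist()
  b <- random_terminology(seed = 21)
  rel <- filter_whitelist(b$sct_relationships, wl)
  concepts <- unique(b$mappings_primary$sct_id)
  half <- rel[seq_len(floor(nrow(rel) / 2)), , drop = FALSE]
  r_half <- harvest_restrictions(concepts, half, wl)
  r_full <- harvest_restrictions(concepts, rel, wl)
  keys <- function(df) paste(df$property, df$filler)
  expect_true(all(keys(r_half) %in% keys(r_full)))
})
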