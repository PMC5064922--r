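test_that("normalization splits equivalences with deterministic fresh names", {
  # hierarchy-only ontology: one atomic inclusion per subclass axiom
  hier <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("A00", "A00.0"), label = c("a", "b"),
               stringsAsFactors = FALSE)))
  nm <- normalize_tbox(hier)
  expect_equal(nrow(nm$axioms), nrow(hier$subclass))
  expect_true(all(nm$axioms$type == "atomic_sub"))
  expect_length(grep("^_", nm$classes), 0L)

  # the four-conjunct hypertension definition flattens to a chain of three
  # fresh conjunction names (binary conjunctions) plus one fresh name per
  # existential conjunct
  ont <- built_fixture("i10")
  nm2 <- normalize_tbox(ont)
  expect_equal(sum(startsWith(nm2$classes, "_C:I10")), 3L)
  expect_equal(sum(startsWith(nm2$classes, "_X:I10")), 4L)
  # both directions present
  expect_equal(sum(nm2$axioms$type == "exists_rhs"), 4L)
  expect_equal(sum(nm2$axioms$type == "exists_lhs"), 4L)
  # deterministic
  expect_identical(nm2, normalize_tbox(ont))

  # a single-conjunct definition needs no fresh names
  single <- built_fixture("k58_e73")
  nm3 <- normalize_tbox(single)
  expect_length(grep("^_[XC]:K58:", nm3$classes), 0L)
})

test_that("saturation classifies the block hierarchy transitively", {
  ont <- built_fixture("cholera")
  st <- el_saturate(ont)
  expect_true(is_subsumed_by(st, "A00_9", "A00_A09"))
  expect_true(is_subsumed_by(st, "A00_9", "A00_B99"))
  expect_true(is_subsumed_by(st, "A00_9", "Diseases"))
  expect_false(is_subsumed_by(st, "A00_A09", "A00_9"))
  # reflexivity for every declared class
  for (id in ont$classes$id) expect_true(is_subsumed_by(st, id, id))
  expect_error(is_subsumed_by(st, "A00_9", "Z99"),
               class = "elicd_unknown_class_error")
})

test_that("an empty axiom set saturates to reflexive subsumer sets", {
  ont <- new_ontology()
  ont <- elicd:::ont_declare_class(ont, "A00", "icd", "a")
  ont <- elicd:::ont_declare_class(ont, "B00", "icd", "b")
  st <- el_saturate(ont)
  expect_equal(st$S[["A00"]], "A00")
  expect_equal(st$S[["B00"]], "B00")
})

test_that("the sibling lift flips the lactase-deficiency misclassification", {
  before <- built_fixture("k58_e73")
  after <- complete_ontology(before)$ontology
  st_before <- el_saturate(before)
  st_after <- el_saturate(after)
  expect_true(is_subsumed_by(st_before, "E73_0", "K58"))
  expect_false(is_subsumed_by(st_before, "K58", "E73_0"))
  expect_false(is_subsumed_by(st_after, "E73_0", "K58"))
  # genuine subclasses keep their place
  expect_true(is_subsumed_by(st_after, "K58_0", "K58"))
  # and agree with the independent oracle on the flip
  expect_true(oracle_subsumption(before, "E73_0", "K58"))
  expect_false(oracle_subsumption(after, "E73_0", "K58"))
})

test_that("definition matching respects the imported filler hierarchy", {
  # A00_0's causative agent is a subtype of A00's: A00_0 is subsumed by A00
  # through its definition even before any completion runs
  ont <- built_fixture("cholera")
  st <- el_saturate(ont)
  expect_true(is_subsumed_by(st, "A00_0", "A00"))
  expect_true(is_subsumed_by(st, "A00_1", "A00"))
  expect_false(is_subsumed_by(st, "A00_0", "A00_1"))
})

test_that("realization returns the use-case categories", {
  # thrombocytopenia: the printed assertions reach D69_6
  b1 <- paper_fixture("usecase1")
  ont1 <- complete_ontology(build_from_bundle(b1))$ontology
  r1 <- realize_query(b1$queries$hematology, ont1)
  expect_true("D69_6" %in% r1$all_subsumers)
  expect_true("D69_6" %in% r1$most_specific)

  # anorectal abscess: K61, and K61 is the most specific hit
  b2 <- paper_fixture("k61_usecase2")
  ont2 <- complete_ontology(build_from_bundle(b2))$ontology
  r2 <- realize_query(b2$queries$abscess_main, ont2)
  expect_true("K61" %in% r2$all_subsumers)
  expect_equal(r2$most_specific, "K61")
  # the extra ischiorectal-fossa annotation refines the result to K61_3
  r2b <- realize_query(b2$queries$abscess_refined, ont2)
  expect_true("K61_3" %in% r2b$most_specific)

  # metastatic neoplasms: C78 plus both printed subcategories
  b3 <- paper_fixture("usecase3")
  ont3 <- complete_ontology(build_from_bundle(b3))$ontology
  r3 <- realize_query(b3$queries$metastases, ont3)
  expect_true(all(c("C78", "C78_30", "C78_80") %in% r3$all_subsumers))
  expect_setequal(r3$most_specific, c("C78_30", "C78_80"))
})

test_that("realization validates properties and fillers, leaves input untouched", {
  b <- paper_fixture("usecase1")
  ont <- build_from_bundle(b)
  snapshot <- ont
  expect_error(realize_query(
    data.frame(property = "frobnicates", filler_id = "9900051",
               stringsAsFactors = FALSE), ont),
    "frobnicates", class = "elicd_unknown_entity_error")
  expect_error(realize_query(
    data.frame(property = "interprets", filler_id = "123",
               stringsAsFactors = FALSE), ont),
    "123", class = "elicd_unknown_entity_error")
  r <- realize_query(b$queries$hematology, ont)
  expect_true(ontology_equal(snapshot, ont))
})

test_that("realization is monotone in added assertions", {
  for (seed in c(5, 6, 7)) {
    b <- random_terminology(seed = seed, mapping_coverage = 1)
    ont <- complete_ontology(build_from_bundle(b))$ontology
    defined <- names(ont$equivalence)
    if (length(defined) == 0L) next
    target <- ont_definition(ont, defined[[1]])$conjuncts
    pool <- setdiff(elicd:::ont_sct_classes(ont), target$filler)
    prev <- NULL
    q <- data.frame(property = character(), filler_id = character(),
                    stringsAsFactors = FALSE)
    for (i in seq_len(nrow(target))) {
      q <- rbind(q, data.frame(property = target$property[[i]],
                               filler_id = target$filler[[i]],
                               stringsAsFactors = FALSE))
      res <- realize_query(q, ont)
      if (!is.null(prev)) expect_true(all(prev %in% res$all_subsumers))
      prev <- res$all_subsumers
    }
  }
})

test_that("equivalent classes report as a group with one canonical pick", {
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("A00", "A01"), label = c("a", "b"),
               stringsAsFactors = FALSE)))
  ont <- elicd:::ont_declare_class(ont, "9000401", "sct", "f")
  def <- restriction_set("Affects", "9000401")
  ont <- emit_equivalence(ont, "A00", def)
  ont <- emit_equivalence(ont, "A01", def)
  r <- realize_query(data.frame(property = "Affects", filler_id = "9000401",
                                stringsAsFactors = FALSE), ont)
  expect_setequal(r$equivalents, c("A00", "A01"))
  expect_equal(r$most_specific, "A00")  # lexicographically least of the tie
})

test_that("consistency holds across the supported fragment", {
  expect_true(check_consistency(new_ontology()))
  for (name in bundle_names()) {
    expect_true(check_consistency(built_fixture(name)))
  }
})

test_that("saturation agrees with the tree-homomorphism oracle on fixtures", {
  for (name in c("i10", "cholera", "k58_e73", "usecase3")) {
    ont <- built_fixture(name, complete = TRUE)
    st <- el_saturate(ont)
    orc <- oracle_classification(ont)
    ids <- ont$classes$id
    for (a in ids) {
      expect_identical(sort(intersect(st$S[[a]], ids)), sort(orc[[a]]),
                       label = paste(name, a))
    }
  }
})
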