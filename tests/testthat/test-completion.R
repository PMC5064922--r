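test_that("downward inheritance augments children with ancestor conjuncts", {
  res <- inherit_down(chain_ontology())
  ont <- res$ontology
  # three-level chain, one conjunct each: the leaf ends with all three
  expect_equal(nrow(ont_definition(ont, "B00_B09")$conjuncts), 1L)
  expect_equal(nrow(ont_definition(ont, "B00")$conjuncts), 2L)
  expect_equal(nrow(ont_definition(ont, "B00_0")$conjuncts), 3L)
  expect_true(restriction_equal(
    ont_definition(ont, "B00_0")$conjuncts,
    restriction_set(rep("Affects", 3), c("9000101", "9000102", "9000103"))))
  # every child's conjunct set contains its parent's
  keys <- function(df) paste(df$property, df$filler)
  expect_true(all(keys(ont_definition(ont, "B00")$conjuncts) %in%
                    keys(ont_definition(ont, "B00_0")$conjuncts)))

  # idempotence: a second application adds nothing
  res2 <- inherit_down(ont)
  expect_equal(nrow(res2$report$additions), 0L)
  expect_true(ontology_equal(ont, res2$ontology))

  # classes with no own definition are never given one
  expect_false(ont_has_definition(ont, "Diseases"))
})

test_that("inheritance preserves child-under-ancestor classification", {
  base <- chain_ontology()
  inherited <- inherit_down(base)$ontology
  st0 <- el_saturate(base)
  st1 <- el_saturate(inherited)
  for (pair in list(c("B00_0", "B00"), c("B00", "B00_B09"),
                    c("B00_0", "B00_B09"))) {
    expect_true(is_subsumed_by(st0, pair[[1]], pair[[2]]))
    expect_true(is_subsumed_by(st1, pair[[1]], pair[[2]]))
  }
})

test_that("sibling lift promotes exactly the shared restrictions", {
  ont <- built_fixture("k58_e73")
  expect_true(restriction_equal(ont_definition(ont, "K58")$conjuncts,
                                restriction_set("Affects", "113276009")))
  res <- lift_shared(inherit_down(ont)$ontology)
  lifted <- res$ontology
  expect_true(restriction_equal(
    ont_definition(lifted, "K58")$conjuncts,
    restriction_set(c("Affects", "Affects"), c("113276009", "71854001"))))
  add <- res$report$additions
  expect_equal(add$class[add$source == "lifted"], "K58")
  expect_equal(add$filler[add$source == "lifted"], "71854001")

  # second application is empty
  res2 <- lift_shared(lifted)
  expect_equal(nrow(res2$report$additions), 0L)
})

test_that("children sharing nothing, or a partial sibling set, block lifting", {
  mk <- function(child2_def) {
    ont <- ontology_from_hierarchy(build_hierarchy(
      data.frame(code = c("A00", "A00.0", "A00.1"),
                 label = c("p", "c1", "c2"), stringsAsFactors = FALSE)))
    for (f in c("9000201", "9000202", "9000203")) {
      ont <- elicd:::ont_declare_class(ont, f, "sct", f)
    }
    ont <- emit_equivalence(ont, "A00", restriction_set("Affects", "9000201"))
    ont <- emit_equivalence(ont, "A00_0",
                            restriction_set("Affects", "9000202"))
    if (!is.null(child2_def)) {
      ont <- emit_equivalence(ont, "A00_1", child2_def)
    }
    ont
  }
  # disjoint child definitions: nothing shared, parent unchanged
  out <- lift_shared(mk(restriction_set("Affects", "9000203")))
  expect_equal(nrow(out$report$additions), 0L)
  # one child undefined: lifting is blocked even though the other shares
  out2 <- lift_shared(mk(NULL))
  expect_equal(nrow(out2$report$additions), 0L)
  expect_true(restriction_equal(
    ont_definition(out2$ontology, "A00")$conjuncts,
    restriction_set("Affects", "9000201")))
})

test_that("lift creates parent definitions only behind the flag", {
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("A00", "A00.0", "A00.1"),
               label = c("p", "c1", "c2"), stringsAsFactors = FALSE)))
  ont <- elicd:::ont_declare_class(ont, "9000301", "sct", "shared")
  ont <- emit_equivalence(ont, "A00_0", restriction_set("Affects", "9000301"))
  ont <- emit_equivalence(ont, "A00_1", restriction_set("Affects", "9000301"))
  default_run <- lift_shared(ont)
  expect_false(ont_has_definition(default_run$ontology, "A00"))
  created <- lift_shared(ont, create_missing = TRUE)
  expect_true(ont_has_definition(created$ontology, "A00"))
  expect_equal(ont_definition(created$ontology, "A00")$provenance, "lifted")
})

test_that("lifted additions equal a brute-force children-intersection oracle", {
  for (seed in 1:10) {
    b <- random_terminology(seed = seed, depth = 2L, branching = 3L,
                            mapping_coverage = 1)
    ont <- inherit_down(build_from_bundle(b))$ontology
    res <- lift_shared(ont)
    # independent recomputation: per parent with >= 2 all-defined children,
    # the intersection of the children's conjunct sets minus the parent's own
    parent <- elicd:::icd_parent_map(ont)
    expected <- list()
    for (p in unique(unname(parent))) {
      kids <- names(parent)[parent == p]
      if (length(kids) < 2L) next
      defs <- lapply(kids, function(k) ont_definition(ont, k))
      if (any(vapply(defs, is.null, logical(1)))) next
      keysets <- lapply(defs, function(d) paste(d$conjuncts$property,
                                                d$conjuncts$filler))
      shared <- Reduce(intersect, keysets)
      if (!ont_has_definition(ont, p)) next
      own <- ont_definition(ont, p)$conjuncts
      shared <- setdiff(shared, paste(own$property, own$filler))
      if (length(shared) > 0L) expected[[p]] <- sort(shared)
    }
    add <- res$report$additions
    got <- lapply(split(paste(add$property, add$filler), add$class), sort)
    norm <- function(l) if (length(l) == 0L) list() else l[order(names(l))]
    expect_identical(norm(got), norm(expected))
  }
})

test_that("the full completion pipeline is idempotent, fixpoint agrees on chains", {
  first <- complete_ontology(chain_ontology())
  second <- complete_ontology(first$ontology)
  expect_equal(nrow(second$report$additions), 0L)
  # single pass already stable on a chain: fixpoint result is identical
  fix <- complete_ontology(chain_ontology(), fixpoint = TRUE)
  expect_true(ontology_equal(first$ontology, fix$ontology))
})

test_that("completion reports serialize to TSV", {
  res <- complete_ontology(built_fixture("k58_e73"))
  f <- tempfile(fileext = ".tsv")
  write_completion_report(res$report, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(res$report$additions))
  expect_true(all(c("class", "property", "filler", "source", "pass") %in%
                    names(back)))
})
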