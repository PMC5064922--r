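test_that("ICD category reader validates codes and rejects duplicates", {
  f <- write_tsv(c("code\tlabel",
                   "I10\tEssential primary hypertension",
                   "A00-A09\tIntestinal infectious diseases",
                   "A00.0\tCholera due to Vibrio cholerae 01, biovar cholerae"))
  rows <- read_icd_categories(f)
  expect_equal(rows$code, c("I10", "A00-A09", "A00.0"))
  expect_equal(rows$label[[1]], "Essential primary hypertension")

  empty <- read_icd_categories(write_tsv("code\tlabel"))
  expect_equal(nrow(empty), 0L)

  bad <- write_tsv(c("code\tlabel", "A0X\tbad"))
  expect_error(read_icd_categories(bad), "A0X", class = "elicd_parse_error")
  dup <- write_tsv(c("code\tlabel", "I10\ta", "I10\tb"))
  expect_error(read_icd_categories(dup), "duplicate",
               class = "elicd_integrity_error")
})

test_that("SNOMED table reader flags inactive rows and reports dangling ids", {
  cf <- write_tsv(c("id\tfsn\tactive",
                    "62275004\tHypertensive episode (disorder)\t1",
                    "24184005\tFinding of increased blood pressure (finding)\t1",
                    "11111111\tRetired concept (disorder)\t0"))
  rf <- write_tsv(c("source_id\ttype_name\tdestination_id\tactive",
                    "62275004\tHas definitional manifestation\t24184005\t1",
                    "62275004\tIs a\t99999999\t1"))
  expect_warning(sct <- read_sct_tables(cf, rf), "unknown concept ids")
  expect_equal(nrow(sct$concepts), 3L)
  expect_false(sct$concepts$active[[3]])
  expect_equal(nrow(sct$relationships), 2L)  # dangling rows still loaded
  expect_equal(sct$dangling$destination_id, "99999999")
  expect_equal(sct$dangling$missing, "destination")

  badc <- write_tsv(c("id\tfsn\tactive", "abc\tBad\t1"))
  expect_error(read_sct_tables(badc, rf), "non-numeric",
               class = "elicd_parse_error")
})

test_that("mapping reader deduplicates and skips unclassifiable rows", {
  f <- write_tsv(c("sct_id\ticd_code",
                   "62275004\tI10",
                   "449759005\tI10",
                   "449759005\tI10",      # exact duplicate collapses
                   "12345678\t"))         # awaiting editorial review
  expect_warning(m <- read_mappings(f, "primary"), "skipped")
  expect_equal(nrow(m), 2L)
  expect_setequal(m$sct_id, c("62275004", "449759005"))
  expect_true(all(m$source_tag == "primary"))
})

test_that("merge_mappings is a union with primary precedence, deterministic order", {
  p <- data.frame(sct_id = "101", icd_code = "A00", source_tag = "primary",
                  stringsAsFactors = FALSE)
  s <- data.frame(sct_id = c("101", "102"), icd_code = "A00",
                  source_tag = "secondary", stringsAsFactors = FALSE)
  m <- merge_mappings(p, s)
  expect_equal(nrow(m), 2L)
  expect_equal(m$source_tag[m$sct_id == "101"], "primary")
  expect_equal(m$source_tag[m$sct_id == "102"], "secondary")

  # secondary empty -> identity
  empty <- s[0, ]
  expect_equal(merge_mappings(p, empty)[, 1:3], p)

  # disjoint sets of sizes 2 and 3 merge to 5 (plain set union)
  p2 <- data.frame(sct_id = c("1", "2"), icd_code = "B00",
                   source_tag = "primary", stringsAsFactors = FALSE)
  s2 <- data.frame(sct_id = c("3", "4", "5"), icd_code = "B01",
                   source_tag = "secondary", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_mappings(p2, s2)),
               length(union(paste(p2$sct_id, p2$icd_code),
                            paste(s2$sct_id, s2$icd_code))))

  # idempotent and commutative up to provenance tags
  expect_equal(merge_mappings(m, m), m)
  m_rev <- merge_mappings(s, p)
  expect_equal(m_rev[, c("sct_id", "icd_code")],
               m[, c("sct_id", "icd_code")])
})

test_that("query files round-trip through blank-line-separated blocks", {
  qs <- list(alpha = data.frame(property = c("affects", "interprets"),
                                filler_id = c("11", "12"),
                                stringsAsFactors = FALSE),
             beta = data.frame(property = "dueTo", filler_id = "13",
                               stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".tsv")
  write_queries(qs, f)
  back <- read_queries(f)
  expect_equal(names(back), c("alpha", "beta"))
  expect_equal(back$alpha$filler_id, c("11", "12"))

  noheader <- write_tsv(c("affects\t11"))
  expect_error(read_queries(noheader), "header", class = "elicd_parse_error")
})

test_that("write/read round trip is a structural identity and byte-deterministic", {
  for (name in c("i10", "cholera", "a93_8")) {
    ont <- built_fixture(name)
    f1 <- tempfile(fileext = ".ofn")
    f2 <- tempfile(fileext = ".ofn")
    write_ontology(ont, f1)
    write_ontology(ont, f2)
    expect_identical(readLines(f1), readLines(f2))
    back <- read_ontology(f1)
    expect_true(ontology_equal(ont, back))
    f3 <- tempfile(fileext = ".ofn")
    write_ontology(back, f3)
    expect_identical(readLines(f1), readLines(f3))
  }
})

test_that("hierarchy-only ontologies serialize with no equivalence axioms", {
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("A00", "A00.0"), label = c("a", "b"),
               stringsAsFactors = FALSE)))
  f <- tempfile(fileext = ".ofn")
  write_ontology(ont, f)
  text <- readLines(f)
  expect_length(grep("^EquivalentClasses", text), 0L)
  # one SubClassOf per parent link: A00_0->A00->A00_A09? no A00_A09 here:
  # A00 -> chapter block -> Diseases, A00_0 -> A00
  expect_length(grep("^SubClassOf", text), nrow(ont$subclass))
})

test_that("unsupported constructs error instead of silently dropping", {
  ont <- built_fixture("i10")
  f <- tempfile(fileext = ".ofn")
  write_ontology(ont, f)
  lines <- readLines(f)
  ns <- default_namespace()
  extra <- sprintf("DisjointClasses(<%sI10> <%sDiseases>)", ns, ns)
  writeLines(append(lines, extra, after = length(lines) - 1L), f)
  expect_error(read_ontology(f), "DisjointClasses",
               class = "elicd_unsupported_error")

  # empty but valid document
  f2 <- tempfile(fileext = ".ofn")
  writeLines(c("Ontology(<http://example.org/x>", ")"), f2)
  empty <- read_ontology(f2)
  expect_equal(nrow(empty$classes), 0L)

  expect_error(read_ontology(write_tsv("@prefix owl: <x> .")),
               class = "elicd_unsupported_error")
})

test_that("serialization rejects IRIs with illegal characters", {
  ont <- new_ontology("http://example.org/bad space#")
  ont <- elicd:::ont_declare_class(ont, "A00", "icd", "x")
  expect_error(write_ontology(ont, tempfile()), "illegal",
               class = "elicd_serialization_error")
})

test_that("Turtle export parses as RDF with the expected shape", {
  ont <- built_fixture("k58_e73", complete = TRUE)
  f <- tempfile(fileext = ".ttl")
  write_ontology(ont, f, format = "turtle")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "from rdflib.namespace import OWL, RDF, RDFS",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "named = [s for s in g.subjects(RDF.type, OWL.Class)",
    "         if isinstance(s, rdflib.URIRef)]",
    "print(len(named))",
    "print(len(list(g.subject_objects(OWL.equivalentClass))))",
    "print(len(list(g.subject_objects(RDFS.subClassOf))))"), script)
  out <- system2("python", c(script, f), stdout = TRUE)
  expect_equal(as.integer(out),
               c(nrow(ont$classes), length(ont$equivalence),
                 nrow(ont$subclass)))
})
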