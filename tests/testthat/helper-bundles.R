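# Shared helpers: write small TSV inputs programmatically and run common
# pipeline stages on bundles.

write_tsv <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

built_fixture <- local({
  cache <- list()
  function(name, complete = FALSE) {
    key <- paste0(name, if (complete) ":c")
    if (is.null(cache[[key]])) {
      ont <- build_from_bundle(paper_fixture(name))
      if (complete) ont <- complete_ontology(ont)$ontology
      cache[[key]] <<- ont
    }
    cache[[key]]
  }
})

# A tiny three-node chain ontology (block > parent > child), each level
# defined with one extra conjunct, used by completion tests.
chain_ontology <- function() {
  ont <- ontology_from_hierarchy(build_hierarchy(
    data.frame(code = c("B00-B09", "B00", "B00.0"),
               label = c("chain block", "chain parent", "chain child"),
               stringsAsFactors = FALSE)))
  for (f in c("9000101", "9000102", "9000103")) {
    ont <- elicd:::ont_declare_class(ont, f, "sct", paste("filler", f))
  }
  ont <- emit_equivalence(ont, "B00_B09", restriction_set("Affects", "9000101"))
  ont <- emit_equivalence(ont, "B00", restriction_set("Affects", "9000102"))
  ont <- emit_equivalence(ont, "B00_0", restriction_set("Affects", "9000103"))
  ont
}
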