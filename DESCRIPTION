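Package: elicd
Title: Compile ICD-10-CM/SNOMED CT Crossmaps into an OWL EL Ontology and
    Classify Clinical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an OWL (EL profile) representation of an ICD-10-CM-style
    disease hierarchy in which inclusion terms are equivalence axioms over
    existential restrictions harvested from SNOMED CT-style relationship and
    crossmap tables. Two refinement algorithms complete the class definitions
    (downward inheritance of parent definitions and upward lifting of
    restrictions shared by all sibling subclasses), and a built-in EL
    completion-rule saturation reasoner classifies the ontology and realizes
    SNOMED-annotated clinical-record queries into ICD categories. Includes
    deterministic OWL 2 Functional Syntax and Turtle writers, a reader for the
    supported axiom subset, worked-example and random terminology generators,
    and a brute-force subsumption oracle for validating the reasoner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
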