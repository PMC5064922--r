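# elicd

Compile an ICD-10-CM-style disease hierarchy plus SNOMED CT-style
relationship and crossmap tables into an OWL (EL profile) ontology whose
inclusion terms are equivalence axioms over existential restrictions,
complete it with two definition-refinement algorithms, and classify
SNOMED-annotated clinical-record queries into ICD categories with a
built-in EL saturation reasoner.

The intended users are clinical-terminology and ontology engineers who want
a logic-based bridge between the two coding systems: EHR annotations use
SNOMED CT concepts, while reporting and reimbursement run on ICD-10-CM
categories, and the published crossmaps between them are many-to-many
tables rather than reasoned artifacts.

## The method

For an ICD category *C* mapped to SNOMED concepts *s₁…s_k*, every
whitelisted attribute relationship *(sᵢ, r, d)* — twelve relationship types
are admitted, e.g. finding site, causative agent, associated morphology —
becomes an existential restriction, and *C* is defined by

    C ≡ ∃r₁.d₁ ⊓ … ⊓ ∃r_m.d_m

(`owl:equivalentClass` over `owl:intersectionOf` of `owl:someValuesFrom`).
The ICD categories form a `subClassOf` hierarchy under a `Diseases` root;
the "Is a" ancestor closure of every restriction filler is imported as a
SNOMED class branch. Definition gaps are filled from a secondary mapping
source, then two refinements run: **downward inheritance** (each defined
class absorbs the conjuncts of its nearest defined ancestor) and **sibling
lift** (a restriction shared by *all* direct subclasses is promoted into
the parent's definition). Everything stays inside OWL 2 EL, so a
completion-rule saturation reasoner classifies the result in polynomial
time; clinical records enter as conjunctive query classes and are realized
against the TBox.

## Worked example

The packaged `k58_e73` bundle reproduces the irritable-bowel-syndrome
refinement. Built from the raw tables, K58 is under-defined and wrongly
subsumes a congenital lactase deficiency class from another chapter;
sibling lift fixes it:

```r
library(elicd)

b   <- paper_fixture("k58_e73")
ont <- build_from_bundle(b)

ont_definition(ont, "K58")$conjuncts
#>   property    filler
#> 1  Affects 113276009

is_subsumed_by(el_saturate(ont), "E73_0", "K58")
#> [1] TRUE                      # lactase deficiency classified under IBS

res <- complete_ontology(ont)   # inherit_down, then lift_shared
res$report
#> <completion_report> 1 addition(s) in 1 pass(es)
#>   class property   filler source   origin pass
#> 1   K58  Affects 71854001 lifted children    1

is_subsumed_by(el_saturate(res$ontology), "E73_0", "K58")
#> [1] FALSE                     # the spurious subsumption is gone
```

K58 gained `∃affects.71854001` (*Colon structure*), shared by both of its
subclasses, so only genuine irritable-bowel records still classify there.

Realizing a clinical record (the anorectal-abscess use case: three SNOMED
assertions) returns the ICD categories that subsume it:

```r
b2   <- paper_fixture("k61_usecase2")
ont2 <- complete_ontology(build_from_bundle(b2))$ontology
realize_query(b2$queries$abscess_main, ont2)
#> <realization_result>
#>   most specific: K61
#>   all subsumers: Diseases, K00_K95, K61
#>   equivalent:    K61
```

`report_stats()` summarizes completion level (share of ICD classes with an
own or inherited definition, restriction usage per property), and
`write_ontology()` serializes to deterministic OWL 2 Functional Syntax or
Turtle. A command-line wrapper lives at `inst/cli/elicd.R`
(`build`, `complete`, `classify`, `stats`, `fixtures` subcommands).

## Package layout

- `R/` — readers/writers for the TSV table dialects and OWL subset
  (`terminology_io`), code normalization and hierarchy building
  (`hierarchy`), axiom generation and statistics (`axioms`), the two
  completion algorithms (`completion`), the EL reasoner (`reasoner`), the
  brute-force oracle (`oracle`), fixture and random-terminology generators
  (`fixtures`, `random_terminology`), pipeline and command functions.
- `inst/extdata/` — the packaged property whitelist and chapter-block
  tables.
- `vignettes/ontology-construction-and-reasoning.Rmd` — the methods
  vignette: model, parameters, design decisions, limitations.
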