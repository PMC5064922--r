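---
title: "Building and reasoning over an EL representation of ICD-10-CM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and reasoning over an EL representation of ICD-10-CM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicd)
```

## The problem

Electronic health records are increasingly annotated with SNOMED CT concept
codes, while billing, epidemiology and resource allocation run on ICD-10-CM
category codes. Assigning the ICD category for a record is traditionally a
manual expert task. `elicd` implements a construction method that turns the
published many-to-many SNOMED CT/ICD-10-CM crossmaps into a *logic-based*
bridge: every ICD category becomes an OWL class whose inclusion terms are
formalized as an equivalence axiom over existential restrictions, so that a
record described by SNOMED-coded property assertions can be *classified* into
ICD categories by a description-logic reasoner rather than matched by string
rules.

## The model

Three hierarchies and one axiom family make up the ontology:

1. **The disease hierarchy.** ICD-10-CM categories (three-character codes
   such as `I10`, their four/five-character subdivisions, and the block
   ranges such as `A00-A09`) are classes under a single `Diseases` root,
   linked by `owl:subClassOf`. Separators are replaced by underscores for
   IRI local names (`A00.0` becomes `A00_0`). Block membership is decided
   lexicographically on the (letter, digits) pair.

2. **Class definitions.** For a category *C* mapped to SNOMED concepts
   $s_1, \dots, s_k$, every whitelisted attribute relationship
   $(s_i, r, d)$ contributes one existential restriction, and the category
   is defined as

   $$C \equiv \exists r_1.d_1 \sqcap \cdots \sqcap \exists r_m.d_m$$

   via `owl:equivalentClass`, `owl:intersectionOf` and
   `owl:someValuesFrom`. Twelve SNOMED relationship types are admitted
   (finding site, causative agent, associated morphology, definitional
   manifestation, occurrence, pathological process, interprets, part of,
   after, due to, associated with, associated finding); historical
   attributes ("was a", "maybe a", "moved to"), "Is a" and qualifier
   relationships are never harvested. Relationship names are camel-cased
   for IRI local names (`Has definitional manifestation` →
   `hasDefinitionalManifestation`).

3. **The imported SNOMED branch.** Every concept used as a restriction
   filler is declared as a class, together with its full "Is a" ancestor
   closure — and nothing else — so that filler subsumption (e.g. *Colon
   structure* under *Intestinal structure*) participates in
   classification.

Everything stays inside the EL profile of OWL 2: conjunction and existential
restriction only, no negation, no disjointness, no role axioms. That choice
is what makes classification tractable at terminology scale, and it has a
useful corollary: the fragment cannot express a contradiction, so
`check_consistency()` is a fragment-level theorem rather than a search.

## The two completion processes

Crossmaps are incomplete, and under-specified definitions over-classify: a
category defined by a single restriction absorbs every record that happens
to satisfy it. Two sequential refinements address this.

**Downward inheritance** (`inherit_down()`): processing top-down, every
defined class absorbs all conjuncts of its nearest defined ICD ancestor. A
subclass *is* the parent disease plus distinguishing restrictions, so the
parent's conjuncts belong in the child's definition. Classes without a
definition are never given one here — augmentation only.

**Sibling lift** (`lift_shared()`): processing bottom-up, when a class has
at least two direct subclasses and *all* of them are defined, every
restriction present in every child's conjunct set is promoted into the
parent's definition. The packaged `k58_e73` bundle shows why this matters:
an irritable-bowel class defined only by `∃affects.IntestinalStructure`
wrongly subsumes a congenital lactase deficiency class from a different
chapter; after lifting the shared `∃affects.ColonStructure` from its two
subclasses, the spurious subsumption disappears while genuine subclasses
stay in place.

Two design points here were genuinely open and are resolved as follows.
Lifting from a *partial* sibling set is blocked: a restriction shared by
only the defined children could narrow the parent incorrectly once the
missing children are defined. And lifting does not create a definition for
a definition-less parent by default (`create_missing = TRUE` enables it):
the documented behaviour starts from a defined parent, and inventing
definitions changes the meaning of "coverage" silently. Both operations are
idempotent; the pipeline runs each once, in the order inheritance-then-lift
(they are sequential processes, not a joint fixpoint), with
`fixpoint = TRUE` available for experimentation.

## The reasoner

Classification and query realization use an internal EL saturation engine
(`normalize_tbox()`, `saturate()`). The TBox is normalized into the four EL
normal forms (atomic inclusion, binary conjunction inclusion, existential
on either side) using deterministically numbered fresh names, and four
completion rules are applied to a least fixpoint over subsumer sets
$S(A)$ and role-link sets $R(r)$. Subsumption $A \sqsubseteq B$ holds
exactly when $B \in S(A)$ at the fixpoint; since the rules only ever add
facts, the fixpoint is unique and rule order is irrelevant.

A clinical record — a list of (property, SNOMED filler) assertions — is
realized by defining a fresh query class $Q$ equivalent to the conjunction
of its assertions, saturating a working copy, and reading off the named ICD
classes in $S(Q)$. This "query as defined class" treatment matches EL
individual semantics for assertion-only instances without a separate ABox
engine. `most_specific` removes every subsumer with a strict descendant
also in the answer; equivalence ties keep the lexicographically least class
and report the whole group in `equivalents`.

### Validating the reasoner

Because the reasoner replaces an external system, the package carries an
independent oracle (`oracle_subsumption()`): in the generated fragment all
fillers are primitive SNOMED classes, so description trees have depth one,
and subsumption can be decided by exhaustively matching each conjunct of
the candidate subsumer's unfolded definition against the restrictions
entailed by the candidate subsumee, honoring told ancestors. The oracle
shares no code with the saturation engine, and the test suite and the
acceptance script compare the two on every ordered class pair of hundreds
of seeded random terminologies.

## Parameters that matter

* `namespace` (IRI prefix, default `http://www.khaos.uma.es/dione#`):
  every class and property IRI is namespace + local name; overridable
  everywhere.
* The **property whitelist** (`default_property_whitelist()`, packaged
  TSV): exactly twelve rows; replaceable by file for other attribute
  selections.
* `include_inactive` (default `FALSE`): inactive SNOMED rows are loaded and
  flagged but excluded from axiom generation. The source material is silent
  on the active flag; excluding retired content is the conservative default
  and a flag keeps the alternative one keystroke away.
* **Chapter blocks** (`icd_chapter_blocks()`, packaged TSV): the fourteen
  disease chapters `A00-B99` … `N00-N99` sit directly under `Diseases`;
  only chapters anchoring an input code are materialized unless
  `all_chapters = TRUE`. The table is configuration, so other ranges can be
  supplied.
* `force` on `emit_equivalence()`: re-defining an already-defined class is
  a conflict by default.

### Hierarchy placement rules

Four/five-character codes attach to their *longest proper prefix* present
in the input, falling back to the containing three-character category and
then to the containing block. Release files do omit intermediates (a
`C78.80` without a `C78.8`); fabricating the missing category would invent
terminology, so the longest-prefix rule skips it instead. Three-character
codes attach to the smallest containing block, blocks to the smallest
strictly containing block, and an uncovered three-character code is an
error rather than a silent root attachment.

## Serialization

`write_ontology()` emits OWL 2 Functional Syntax (default) or Turtle, with
a total deterministic axiom order — declarations by IRI, labels, subclass
axioms by (sub, super), equivalence axioms by class IRI with conjuncts in
lexicographic order of their serialized form — so identical inputs give
byte-identical files. Functional Syntax is lossless: per-axiom provenance
tags (`hierarchy`, `mapping-primary`, `mapping-secondary`, `imported`,
`inherited`, `lifted`) travel as axiom annotations and survive the
write/read round trip. The Turtle export targets RDF toolchains and drops
axiom provenance; it is write-only. `read_ontology()` accepts exactly the
supported construct set and raises an explicit unsupported-construct error
for anything else (`DisjointClasses`, non-label annotations, complex class
expressions outside the EL subset) — nothing is silently dropped.

## What the generators emulate — and what they do not

`paper_fixture()` reproduces the worked examples as self-contained bundles:
the hypertension inclusion terms and full definition, the cholera subtree,
the irritable-bowel/lactase-deficiency flip, the anorectal-abscess and
metastatic-neoplasm realizations, and the one-to-many secondary mapping of
`A93.8`. Where the source material prints concept ids they are used
verbatim; ids it does not print are synthetic (99xxxxx, outside real
SNOMED ranges) and stand in only structurally. In particular, the use-case
bundles define their target ICD classes *from the printed assertion sets*:
they validate the classification machinery, not any published axiom set.

`random_terminology()` generates seed-deterministic bundles with the
structural features the pipeline relies on: a block/category tree, an
acyclic concept forest, whitelisted relationships (Poisson counts per
mapped concept, uniform property choice), and leaf-level mapping coverage.
The default shape (2 blocks, two levels, 15 concepts, 80% coverage, mean
1.5 extra relationships per mapped concept) keeps bundles at a few dozen
classes — the scale at which the brute-force oracle is exhaustive; the test
suite sweeps four tree shapes over 200 seeds and the acceptance script over
50. What the generator does **not** emulate: real crossmap error modes
(wrong rather than missing mappings), SNOMED role groups (deliberately
flattened, as the construction method does), mapping rules/advice from the
curated crossmap, inactive-concept churn, and terminology-scale volume.
Passing tests therefore certify the algorithms and their invariants, not
coding accuracy on real records.

## Numerical and degenerate-input choices

* All identifier sorts are radix (byte) sorts, never locale collation;
  concept-id order is numeric via (length, lexicographic).
* Restriction sets are canonical (deduplicated, sorted); definition
  equality is order-insensitive; a single-conjunct equivalence is emitted
  without a unary intersection wrapper.
* Empty restriction sets emit no axiom; unmapped categories simply stay
  undefined (they still inherit placement from the hierarchy).
* Duplicate mapping pairs collapse; on a primary/secondary collision the
  primary tag wins; merge output order is (ICD code, numeric concept id).
* Fresh names in normalization are derived from the defining class and the
  canonical conjunct order, so normalization is reproducible.
* Gap filling considers inheritance through the ICD hierarchy only, and
  harvesting uses the mapped concepts' *direct* relationship rows —
  ancestors of mapped concepts are not harvested (the conservative reading
  where the source is silent).

## Known limitations

* The EL fragment cannot represent ICD exclusion notes as disjointness —
  by design, since the crossmaps are taken to handle exclusions; no
  `owl:disjointWith` is ever generated or read.
* No RF2 release semantics (effective time, module ids), no map
  rules/advice, no 6/7-character ICD extension codes or laterality.
* Realization covers assertion-only instances; there is no general ABox.
* The oracle requires acyclic, depth-one definitions and small ontologies;
  it is a validation instrument, not a second reasoner.
* Under-specified classes still over-classify when neither completion
  process can distinguish them — the same inherent incompleteness the
  completion statistics (`report_stats()`) are there to quantify.
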