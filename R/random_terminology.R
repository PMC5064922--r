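# Parametrized random terminologies with the structure the pipeline
# assumes: a block/category tree of ICD codes, an acyclic SNOMED-style
# concept forest, whitelisted attribute relationships drawn per concept,
# and mappings covering a chosen fraction of the leaf categories.
# Identical seed + parameters always produce the identical bundle.

#' Generate a random terminology bundle
#'
#' The ICD side is `n_blocks` top-level blocks (one letter each, `A00-A99`,
#' `B00-B99`, ...) holding `branching` three-character categories, each
#' subdivided `branching`-fold down to `depth` levels (1 = three-character
#' only, 2 = four-character, 3 = five-character).  The SNOMED side is a
#' pool of `n_sct_concepts` synthetic concepts (ids in the 9000000+ range,
#' outside real SNOMED CT ranges) wired into a random acyclic "Is a"
#' forest.  A fraction `mapping_coverage` of the leaf categories is mapped
#' to 1-2 source concepts each, and every mapped concept carries at least
#' `min_relationships` whitelisted relationship rows plus a Poisson
#' (`relationships_per_concept`) number of further ones with uniformly
#' drawn whitelist properties and uniform filler targets.
#'
#' @param n_blocks,branching,depth tree-shape parameters (positive; depth
#'   at most 3).
#' @param n_sct_concepts size of the concept pool.
#' @param mapping_coverage fraction of leaf categories mapped, in `[0, 1]`.
#' @param relationships_per_concept Poisson mean for extra relationship
#'   rows per mapped concept; either a scalar or a named vector with one
#'   mean per whitelist property.
#' @param min_relationships guaranteed whitelisted rows per mapped concept.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param whitelist property whitelist to draw relationship types from.
#' @return A `terminology_bundle` (with `use_chapter_config = FALSE`: the
#'   generated blocks are the top level).
#' @export
random_terminology <- function(n_blocks = 2L, depth = 2L, branching = 2L,
                               n_sct_concepts = 15L, mapping_coverage = 0.8,
                               relationships_per_concept = 1.5,
                               min_relationships = 1L, seed = 1L,
                               whitelist = default_property_whitelist()) {
  stopifnot(n_blocks >= 1L, n_blocks <= 26L, depth >= 1L, depth <= 3L,
            branching >= 1L, branching <= 9L, n_sct_concepts >= 2L,
            mapping_coverage >= 0, mapping_coverage <= 1,
            all(relationships_per_concept >= 0), min_relationships >= 0L)
  with_private_seed(seed, {
    codes <- character()
    labels <- character()
    add <- function(code, label) {
      codes[[length(codes) + 1L]] <<- code
      labels[[length(labels) + 1L]] <<- label
    }
    leaves <- character()
    for (b in seq_len(n_blocks)) {
      letter <- LETTERS[[b]]
      add(paste0(letter, "00-", letter, "99"),
          paste("Synthetic block", letter))
      for (i in seq_len(branching)) {
        c3 <- sprintf("%s%02d", letter, i - 1L)
        add(c3, paste("Synthetic category", c3))
        if (depth == 1L) leaves <- c(leaves, c3)
        if (depth >= 2L) {
          for (j in seq_len(branching)) {
            c4 <- sprintf("%s.%d", c3, j - 1L)
            add(c4, paste("Synthetic category", c4))
            if (depth == 2L) leaves <- c(leaves, c4)
            if (depth >= 3L) {
              for (k in seq_len(branching)) {
                c5 <- sprintf("%s%d", c4, k - 1L)
                add(c5, paste("Synthetic category", c5))
                leaves <- c(leaves, c5)
              }
            }
          }
        }
      }
    }
    icd <- icd_rows(codes, labels)

    pool <- as.character(9000000L + seq_len(n_sct_concepts))
    concepts <- sct_concept_rows(pool,
                                 paste0("Synthetic concept ", pool,
                                        " (finding)"))
    # Acyclic "Is a" forest: parents always have a smaller index.
    isa_src <- character()
    isa_dst <- character()
    for (i in seq_along(pool)[-1L]) {
      if (stats::runif(1) < 0.75) {
        isa_src <- c(isa_src, pool[[i]])
        isa_dst <- c(isa_dst, pool[[sample.int(i - 1L, 1L)]])
      }
    }

    n_mapped <- round(mapping_coverage * length(leaves))
    if (n_mapped > length(leaves)) {
      stop_elicd("infeasible parameters: coverage exceeds available leaves",
                 class = "elicd_parse_error")
    }
    mapped_leaves <- sort_c(leaves)[sample.int(length(leaves), n_mapped)]
    map_sct <- character()
    map_icd <- character()
    for (leaf in mapped_leaves) {
      k <- sample(1:2, 1L)
      ids <- pool[sample.int(length(pool), min(k, length(pool)))]
      map_sct <- c(map_sct, ids)
      map_icd <- c(map_icd, rep(leaf, length(ids)))
    }

    props <- whitelist$property
    lambda <- relationships_per_concept
    rel_src <- character()
    rel_type <- character()
    rel_dst <- character()
    pick_target <- function(src) {
      cand <- setdiff(pool, src)
      cand[[sample.int(length(cand), 1L)]]
    }
    for (src in sort_digit_strings(unique(map_sct))) {
      drawn <- character()
      if (length(lambda) > 1L) {
        for (p in props) {
          n <- stats::rpois(1L, if (p %in% names(lambda)) lambda[[p]] else 0)
          drawn <- c(drawn, rep(p, n))
        }
      } else {
        drawn <- props[sample.int(length(props), stats::rpois(1L, lambda),
                                  replace = TRUE)]
      }
      need <- min_relationships - length(drawn)
      if (need > 0L) {
        drawn <- c(drawn, props[sample.int(length(props), need,
                                           replace = TRUE)])
      }
      for (p in drawn) {
        rel_src <- c(rel_src, src)
        rel_type <- c(rel_type,
                      whitelist$sct_relationship[[match(p, props)]])
        rel_dst <- c(rel_dst, pick_target(src))
      }
    }

    relationships <- rbind(
      sct_relationship_rows(rel_src, rel_type, rel_dst),
      sct_relationship_rows(isa_src, rep("Is a", length(isa_src)), isa_dst))

    new_bundle(paste0("random-", seed), icd, concepts, relationships,
               primary = mapping_rows(map_sct, map_icd,
                                      rep("primary", length(map_sct))),
               extras = list(leaves = sort_c(leaves),
                             mapped_leaves = sort_c(mapped_leaves),
                             params = list(n_blocks = n_blocks,
                                           depth = depth,
                                           branching = branching,
                                           n_sct_concepts = n_sct_concepts,
                                           mapping_coverage = mapping_coverage,
                                           seed = seed)),
               use_chapter_config = FALSE)
  })
}
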