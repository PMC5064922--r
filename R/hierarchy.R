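# ICD code normalization and hierarchy construction.
#
# ICD-10-CM categories are a capital letter plus two digits (three-character
# categories), subdivided into four- and five-character categories, and
# grouped into blocks such as A00-A09.  For use as IRI local names, "." and
# "-" are replaced by "_" (A00.0 -> A00_0, A00-A09 -> A00_A09).  The whole
# disease classification hangs under a single root class, Diseases.

RE_RAW_3 <- "^[A-Z][0-9]{2}$"
RE_RAW_45 <- "^[A-Z][0-9]{2}\\.[0-9]{1,2}$"
RE_RAW_BLOCK <- "^[A-Z][0-9]{2}-[A-Z][0-9]{2}$"
RE_NORM_45 <- "^[A-Z][0-9]{2}_[0-9]{1,2}$"
RE_NORM_BLOCK <- "^[A-Z][0-9]{2}_[A-Z][0-9]{2}$"

is_valid_raw_code <- function(raw) {
  grepl(RE_RAW_3, raw) | grepl(RE_RAW_45, raw) | grepl(RE_RAW_BLOCK, raw) |
    raw == "Diseases"
}

#' Normalize an ICD code for use as an IRI local name
#'
#' Replaces `.` and `-` by `_` and assigns the structural level of the code.
#' Already-normalized codes are accepted unchanged.
#'
#' @param raw a single code such as `"A00.0"`, `"I10"`, `"A00-B99"` or
#'   `"Diseases"`.
#' @return A list with elements `code` (the normalized string) and `level`
#'   (one of `"root"`, `"block"`, `"three_char"`, `"four_char"`,
#'   `"five_char"`).
#' @examples
#' normalize_code("A00.0")$code    # "A00_0"
#' normalize_code("A00-B99")$level # "block"
#' @export
normalize_code <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  norm <- chartr(".-", "__", raw)
  level <- code_level(norm)
  if (is.na(level)) {
    stop_elicd("invalid ICD code: '", raw, "'", class = "elicd_parse_error")
  }
  list(code = norm, level = level)
}

# Level from the normalized shape; NA if the shape is invalid.
code_level <- function(norm) {
  ifelse(norm == "Diseases", "root",
  ifelse(grepl(RE_NORM_BLOCK, norm), "block",
  ifelse(grepl(RE_RAW_3, norm), "three_char",
  ifelse(grepl("^[A-Z][0-9]{2}_[0-9]$", norm), "four_char",
  ifelse(grepl("^[A-Z][0-9]{2}_[0-9]{2}$", norm), "five_char",
         NA_character_)))))
}

#' Vectorized code normalization
#'
#' @param raw character vector of raw or normalized codes.
#' @return Character vector of normalized codes.
#' @export
normalize_codes <- function(raw) vapply(raw, function(r) normalize_code(r)$code,
                                        character(1), USE.NAMES = FALSE)

# Integer key for a three-character code, ordered as (letter, digits).
code3_key <- function(code3) {
  (match(substr(code3, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(code3, 2, 3))
}

# Block table from normalized block codes: code, start, end, width.
block_table <- function(block_codes) {
  start <- substr(block_codes, 1, 3)
  end <- substr(block_codes, 5, 7)
  bad <- code3_key(start) > code3_key(end)
  if (any(bad)) {
    stop_elicd("block range start exceeds end: ",
               paste(block_codes[bad], collapse = ", "),
               class = "elicd_parse_error")
  }
  data.frame(code = block_codes, start = start, end = end,
             skey = code3_key(start), ekey = code3_key(end),
             width = code3_key(end) - code3_key(start),
             stringsAsFactors = FALSE)
}

#' Default chapter block table (Chapters I to XIV)
#'
#' The disease chapters shipped as package configuration: fourteen block
#' ranges from A00-B99 (certain infectious and parasitic diseases) to
#' N00-N99 (diseases of the genitourinary system), placed directly under the
#' Diseases root.  Other ranges can be supplied to [build_hierarchy()].
#'
#' @param path optional TSV with columns `start`, `end`, `label`.
#' @return Data frame with columns `code` (normalized), `start`, `end`,
#'   `label`.
#' @export
icd_chapter_blocks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chapter_blocks.tsv", package = "elicd",
                        mustWork = TRUE)
  }
  df <- read_tsv_strict(path, c("start", "end", "label"))
  data.frame(code = paste0(df$start, "_", df$end),
             start = df$start, end = df$end, label = df$label,
             stringsAsFactors = FALSE)
}

#' Infer the parent of a normalized ICD code
#'
#' Four/five-character codes attach to their longest proper prefix present
#' among the known codes, falling back to the containing three-character
#' category and then to the containing block (so C78_80 attaches to C78 when
#' C78_8 is absent, rather than fabricating it).  Three-character codes
#' attach to the smallest block containing them; blocks attach to the
#' smallest strictly containing block, or to the Diseases root.
#'
#' @param code normalized code (not the root).
#' @param all_codes character vector of normalized codes present in the
#'   hierarchy (categories and blocks).
#' @param blocks block table as produced by [block_table()] covering all
#'   three-character codes present.
#' @return The normalized parent code.
#' @export
infer_parent <- function(code, all_codes, blocks) {
  level <- code_level(code)
  if (is.na(level) || level == "root") {
    stop_elicd("cannot infer a parent for '", code, "'",
               class = "elicd_parse_error")
  }
  if (level %in% c("four_char", "five_char")) {
    prefixes <- substring(code, 1, seq_len(nchar(code) - 1L))
    prefixes <- prefixes[!endsWith(prefixes, "_")]
    prefixes <- prefixes[nchar(prefixes) >= 3L & prefixes != code]
    prefixes <- prefixes[order(-nchar(prefixes))]
    hit <- prefixes[prefixes %in% all_codes]
    if (length(hit) > 0L) return(hit[[1L]])
    return(smallest_containing_block(substr(code, 1, 3), blocks, code))
  }
  if (level == "three_char") {
    return(smallest_containing_block(code, blocks, code))
  }
  # block: smallest strictly containing block, else the root
  skey <- code3_key(substr(code, 1, 3))
  ekey <- code3_key(substr(code, 5, 7))
  cand <- blocks[blocks$skey <= skey & blocks$ekey >= ekey &
                   blocks$code != code, , drop = FALSE]
  if (nrow(cand) == 0L) return("Diseases")
  cand <- cand[order(cand$width, cand$skey), , drop = FALSE]
  cand$code[[1L]]
}

smallest_containing_block <- function(code3, blocks, orig) {
  key <- code3_key(code3)
  cand <- blocks[blocks$skey <= key & blocks$ekey >= key, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop_elicd("orphan category: ", orig, " is contained in no block",
               class = "elicd_orphan_error")
  }
  cand <- cand[order(cand$width, cand$skey), , drop = FALSE]
  cand$code[[1L]]
}

#' Build the Diseases-rooted ICD hierarchy
#'
#' Normalizes every input code, derives each category's parent (an explicit
#' `parent` column overrides inference), pulls in the chapter blocks needed
#' to anchor the input codes, and roots everything at the Diseases class.
#'
#' @param rows data frame with columns `code`, `label` and optionally
#'   `parent` (raw codes, as read by [read_icd_categories()]).
#' @param chapter_blocks chapter block table ([icd_chapter_blocks()] by
#'   default); pass `NULL` to use only blocks present in `rows`.
#' @param all_chapters if `TRUE`, every configured chapter block becomes a
#'   node even when empty; by default only chapters containing input codes
#'   are materialized.
#' @return An object of class `icd_hierarchy`: a list with `nodes`
#'   (data frame `code`, `level`, `label`), `parent` (named character map)
#'   and `root`.
#' @export
build_hierarchy <- function(rows, chapter_blocks = icd_chapter_blocks(),
                            all_chapters = FALSE) {
  stopifnot(is.data.frame(rows), all(c("code", "label") %in% names(rows)))
  codes <- character(nrow(rows))
  levels <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    nc <- normalize_code(rows$code[[i]])
    codes[[i]] <- nc$code
    levels[[i]] <- nc$level
  }
  dup <- duplicated(codes)
  if (any(dup)) {
    stop_elicd("duplicate ICD code(s): ",
               paste(unique(codes[dup]), collapse = ", "),
               class = "elicd_integrity_error")
  }

  nodes <- data.frame(code = codes, level = levels, label = rows$label,
                      stringsAsFactors = FALSE)
  nodes <- nodes[nodes$level != "root", , drop = FALSE]

  # Chapter blocks that anchor at least one input code (or all, on request).
  if (!is.null(chapter_blocks)) {
    keys <- unlist(lapply(seq_len(nrow(nodes)), function(i) {
      if (nodes$level[[i]] == "block") {
        c(code3_key(substr(nodes$code[[i]], 1, 3)),
          code3_key(substr(nodes$code[[i]], 5, 7)))
      } else {
        code3_key(substr(nodes$code[[i]], 1, 3))
      }
    }))
    need <- vapply(seq_len(nrow(chapter_blocks)), function(j) {
      all_chapters || any(keys >= code3_key(chapter_blocks$start[[j]]) &
                            keys <= code3_key(chapter_blocks$end[[j]]))
    }, logical(1))
    add <- chapter_blocks[need, , drop = FALSE]
    add <- add[!(add$code %in% nodes$code), , drop = FALSE]
    if (nrow(add) > 0L) {
      nodes <- rbind(nodes,
                     data.frame(code = add$code, level = "block",
                                label = add$label, stringsAsFactors = FALSE))
    }
  }

  all_codes <- nodes$code
  blocks <- block_table(nodes$code[nodes$level == "block"])

  explicit <- rep(NA_character_, nrow(nodes))
  if ("parent" %in% names(rows)) {
    m <- match(nodes$code, codes)
    raw_parent <- ifelse(is.na(m), NA_character_, rows$parent[m])
    has <- !is.na(raw_parent) & nzchar(raw_parent)
    explicit[has] <- normalize_codes(raw_parent[has])
    bad <- has & !(explicit %in% c(all_codes, "Diseases"))
    if (any(bad)) {
      stop_elicd("explicit parent(s) not present in the hierarchy: ",
                 paste(unique(explicit[bad]), collapse = ", "),
                 class = "elicd_integrity_error")
    }
  }

  parent <- character(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    parent[[i]] <- if (!is.na(explicit[[i]])) explicit[[i]] else
      infer_parent(nodes$code[[i]], all_codes, blocks)
  }
  names(parent) <- nodes$code

  cycle <- find_cycle(nodes$code, parent)
  if (!is.null(cycle)) {
    stop_elicd("parent links form a cycle: ", paste(cycle, collapse = " -> "),
               class = "elicd_cycle_error")
  }

  ord <- order_c(nodes$code)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, parent = parent[nodes$code],
                 root = "Diseases"),
            class = "icd_hierarchy")
}

#' @export
print.icd_hierarchy <- function(x, ...) {
  cat("<icd_hierarchy>", nrow(x$nodes), "categories under", x$root, "\n")
  tab <- table(x$nodes$level)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

# Depth of a node (root = 0), following parent links.
hierarchy_depth <- function(hierarchy, code) {
  d <- 0L
  while (code != hierarchy$root) {
    code <- hierarchy$parent[[code]]
    d <- d + 1L
    if (d > 10L) stop_elicd("parent chain too deep at ", code,
                            class = "elicd_cycle_error")
  }
  d
}

#' Seed an ontology from an ICD hierarchy
#'
#' Declares one ICD-kind class per category (plus the Diseases root), adds
#' its label, and one SubClassOf axiom per parent link, provenance-tagged
#' `hierarchy`.
#'
#' @param hierarchy an `icd_hierarchy`.
#' @param namespace ontology namespace IRI prefix.
#' @return An `el_ontology`.
#' @export
ontology_from_hierarchy <- function(hierarchy,
                                    namespace = default_namespace()) {
  stopifnot(inherits(hierarchy, "icd_hierarchy"))
  ontology <- new_ontology(namespace)
  ontology <- ont_declare_class(ontology, hierarchy$root, "icd", "Diseases")
  for (i in seq_len(nrow(hierarchy$nodes))) {
    ontology <- ont_declare_class(ontology, hierarchy$nodes$code[[i]], "icd",
                                  hierarchy$nodes$label[[i]])
  }
  for (code in names(hierarchy$parent)) {
    ontology <- ont_add_subclass(ontology, code, hierarchy$parent[[code]],
                                 "hierarchy")
  }
  validate_ontology(ontology)
  ontology
}
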