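# Readers for the terminology table families: ICD categories, SNOMED-style
# concept/relationship tables (RF2-like columns), SNOMED->ICD mapping tables,
# and clinical-record query files.  All canonical inputs are plain TSV.

#' Read an ICD category table
#'
#' TSV with header `code`, `label` and optionally `parent`.  Codes must be
#' three-character categories (letter + two digits), four/five-character
#' categories (a dot plus one or two more digits) or blocks (`A00-A09`).
#'
#' @param path TSV file path.
#' @return Data frame with columns `code`, `label` (and `parent` when
#'   present), in file order.
#' @export
read_icd_categories <- function(path) {
  df <- read_tsv_strict(path, c("code", "label"), optional = "parent")
  df$code <- trimws(df$code)
  df$label <- trimws(df$label)
  bad <- !is_valid_raw_code(df$code) | !nzchar(df$code)
  if (any(bad)) {
    stop_elicd("malformed ICD code '", df$code[bad][[1L]], "' at data line ",
               which(bad)[[1L]], " of ", path, class = "elicd_parse_error")
  }
  dup <- duplicated(df$code)
  if (any(dup)) {
    stop_elicd("duplicate ICD code '", df$code[dup][[1L]], "' in ", path,
               class = "elicd_integrity_error")
  }
  rownames(df) <- NULL
  df
}

#' Read SNOMED-style concept and relationship tables
#'
#' The concept table has columns `id`, `fsn` (fully specified name) and
#' `active`; the relationship table has `source_id`, `type_name`,
#' `destination_id`, `active`.  Inactive rows are retained but flagged;
#' relationships whose source or destination id does not appear in the
#' concept table are loaded and reported in the `dangling` component.
#'
#' @param concepts_path,relationships_path TSV file paths.
#' @return A list with components `concepts` (data frame `id`, `fsn`,
#'   `active`), `relationships` (data frame `source_id`, `type_name`,
#'   `destination_id`, `active`) and `dangling` (data frame of relationship
#'   rows with unresolved ids and a `missing` column).
#' @export
read_sct_tables <- function(concepts_path, relationships_path) {
  con <- read_tsv_strict(concepts_path, c("id", "fsn", "active"))
  con$id <- trimws(con$id)
  con$fsn <- trimws(con$fsn)
  bad <- !is_digit_string(con$id)
  if (any(bad)) {
    stop_elicd("non-numeric concept id '", con$id[bad][[1L]],
               "' at data line ", which(bad)[[1L]], " of ", concepts_path,
               class = "elicd_parse_error")
  }
  dup <- duplicated(con$id)
  if (any(dup)) {
    stop_elicd("duplicate concept id '", con$id[dup][[1L]], "' in ",
               concepts_path, class = "elicd_integrity_error")
  }
  con$active <- parse_active(con$active, concepts_path)

  rel <- read_tsv_strict(relationships_path,
                         c("source_id", "type_name", "destination_id",
                           "active"))
  rel$source_id <- trimws(rel$source_id)
  rel$destination_id <- trimws(rel$destination_id)
  rel$type_name <- trimws(rel$type_name)
  bad <- !is_digit_string(rel$source_id) | !is_digit_string(rel$destination_id)
  if (any(bad)) {
    stop_elicd("non-numeric concept id at data line ", which(bad)[[1L]],
               " of ", relationships_path, class = "elicd_parse_error")
  }
  if (any(!nzchar(rel$type_name))) {
    stop_elicd("empty relationship type at data line ",
               which(!nzchar(rel$type_name))[[1L]], " of ",
               relationships_path, class = "elicd_parse_error")
  }
  rel$active <- parse_active(rel$active, relationships_path)

  known <- con$id
  miss_src <- !(rel$source_id %in% known)
  miss_dst <- !(rel$destination_id %in% known)
  dangling <- rel[miss_src | miss_dst, , drop = FALSE]
  if (nrow(dangling) > 0L) {
    dangling$missing <- ifelse(miss_src[miss_src | miss_dst] &
                                 miss_dst[miss_src | miss_dst], "both",
                               ifelse(miss_src[miss_src | miss_dst],
                                      "source", "destination"))
    warning(nrow(dangling),
            " relationship row(s) reference unknown concept ids",
            call. = FALSE)
  } else {
    dangling$missing <- character(0)
  }
  rownames(con) <- rownames(rel) <- rownames(dangling) <- NULL
  list(concepts = con, relationships = rel, dangling = dangling)
}

parse_active <- function(x, path) {
  x <- trimws(x)
  out <- ifelse(x %in% c("1", "true", "TRUE"), TRUE,
                ifelse(x %in% c("0", "false", "FALSE"), FALSE, NA))
  if (anyNA(out)) {
    stop_elicd("unparseable active flag '", x[is.na(out)][[1L]], "' in ",
               path, class = "elicd_parse_error")
  }
  out
}

#' Read a SNOMED-to-ICD mapping table
#'
#' TSV with columns `sct_id` and `icd_code`.  Rows with an empty ICD code
#' are skipped with a warning (the concept is not classifiable or awaiting
#' editorial review); exact duplicate pairs collapse to one row.
#'
#' @param path TSV file path.
#' @param source_tag `"primary"` (the curated crossmap) or `"secondary"`
#'   (community/inferred mappings used for gap filling).
#' @return Data frame with columns `sct_id`, `icd_code`, `source_tag`.
#' @export
read_mappings <- function(path, source_tag = c("primary", "secondary")) {
  source_tag <- match.arg(source_tag)
  df <- read_tsv_strict(path, c("sct_id", "icd_code"))
  df$sct_id <- trimws(df$sct_id)
  df$icd_code <- trimws(df$icd_code)
  empty <- !nzchar(df$icd_code)
  if (any(empty)) {
    warning(sum(empty), " mapping row(s) with empty ICD code skipped",
            call. = FALSE)
    df <- df[!empty, , drop = FALSE]
  }
  bad <- !is_digit_string(df$sct_id)
  if (any(bad)) {
    stop_elicd("non-numeric sct_id '", df$sct_id[bad][[1L]], "' in ", path,
               class = "elicd_parse_error")
  }
  bad <- !is_valid_raw_code(df$icd_code)
  if (any(bad)) {
    stop_elicd("malformed ICD code '", df$icd_code[bad][[1L]], "' in ", path,
               class = "elicd_parse_error")
  }
  df <- df[!duplicated(paste(df$sct_id, df$icd_code, sep = "\r")), ,
           drop = FALSE]
  df$source_tag <- rep(source_tag, nrow(df))
  rownames(df) <- NULL
  df
}

#' Merge primary and secondary mapping tables
#'
#' Union keyed on (`sct_id`, `icd_code`); when a pair occurs in both tables
#' the `primary` tag wins.  Output order is deterministic: by ICD code, then
#' by concept id in numeric order.
#'
#' @param primary,secondary mapping data frames from [read_mappings()].
#' @return Merged mapping data frame.
#' @export
merge_mappings <- function(primary, secondary) {
  all_rows <- rbind(primary[, c("sct_id", "icd_code", "source_tag")],
                    secondary[, c("sct_id", "icd_code", "source_tag")])
  key <- paste(all_rows$sct_id, all_rows$icd_code, sep = "\r")
  tag <- vapply(split(all_rows$source_tag, key), function(tags) {
    if ("primary" %in% tags) "primary" else "secondary"
  }, character(1))
  first <- !duplicated(key)
  out <- all_rows[first, , drop = FALSE]
  out$source_tag <- unname(tag[key[first]])
  out <- out[order_c(out$icd_code, nchar(out$sct_id), out$sct_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read clinical-record query files
#'
#' A query file holds one clinical-record instance per block of
#' (`property`, `filler_id`) assertion pairs; blocks are separated by blank
#' lines.  The first non-comment line must be the header
#' `property<TAB>filler_id`.  A comment line `# query: NAME` immediately
#' before a block names it; unnamed blocks are `q1`, `q2`, ...
#'
#' @param path query TSV file path.
#' @return Named list of data frames with columns `property`, `filler_id`.
#' @export
read_queries <- function(path) {
  if (!file.exists(path)) {
    stop_elicd("file not found: ", path, class = "elicd_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  queries <- list()
  current <- NULL
  current_name <- NULL
  counter <- 0L
  header_seen <- FALSE
  flush <- function() {
    if (!is.null(current) && nrow(current) > 0L) {
      counter <<- counter + 1L
      nm <- current_name %||% paste0("q", counter)
      queries[[nm]] <<- current
    }
    current <<- NULL
    current_name <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec("^#\\s*query:\\s*(\\S+)", line))[[1L]]
      if (length(m) == 2L) current_name <- m[[2L]]
      next
    }
    if (!nzchar(trimws(line))) {
      flush()
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (!header_seen) {
      if (length(parts) < 2L || parts[[1L]] != "property" ||
          parts[[2L]] != "filler_id") {
        stop_elicd("query file must start with header 'property\tfiller_id' (",
                   path, ")", class = "elicd_parse_error")
      }
      header_seen <- TRUE
      next
    }
    if (length(parts) < 2L) {
      stop_elicd("malformed query line ", i, " in ", path,
                 class = "elicd_parse_error")
    }
    row <- data.frame(property = trimws(parts[[1L]]),
                      filler_id = trimws(parts[[2L]]),
                      stringsAsFactors = FALSE)
    current <- if (is.null(current)) row else rbind(current, row)
  }
  flush()
  queries
}

#' Write a query list to a TSV file
#'
#' Inverse of [read_queries()]: blocks separated by blank lines, each block
#' preceded by a `# query: NAME` comment.
#'
#' @param queries named list of data frames (`property`, `filler_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  out <- c("property\tfiller_id")
  for (nm in names(queries)) {
    q <- queries[[nm]]
    out <- c(out, "", paste0("# query: ", nm),
             paste(q$property, q$filler_id, sep = "\t"))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
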