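# Internal helpers shared across modules.

# Locale-independent sort: all identifiers here are ASCII, radix sort gives
# a stable byte order so serialization is reproducible across platforms.
sort_c <- function(x) {
  if (length(x) == 0L) return(x)
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# Numeric-style order for digit-string identifiers of arbitrary length:
# shorter strings first, then lexicographic (equivalent to numeric order
# for non-negative integers without leading zeros).
order_digit_strings <- function(x) order_c(nchar(x), x)

sort_digit_strings <- function(x) {
  x <- as.character(x %||% character())
  if (length(x) == 0L) return(x)
  x[order_digit_strings(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_digit_string <- function(x) grepl("^[0-9]+$", x)

# Evaluate an expression with a private RNG stream, leaving the caller's
# .Random.seed untouched.
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stop_elicd <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "elicd_error")))
}

read_tsv_strict <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    stop_elicd("file not found: ", path, class = "elicd_io_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, blank.lines.skip = TRUE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_elicd("file ", path, " is missing required column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "elicd_parse_error")
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}
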