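#' Construct a set of n-gram count records
#'
#' An `ngram_set` holds fixed-length token sequences with non-negative
#' occurrence counts, the raw material for co-occurrence counting.
#'
#' @param tokens Character matrix, one n-gram per row, one token per column.
#' @param count Numeric vector of non-negative counts, one per row.
#' @return An object of class `ngram_set`.
#' @seealso [read_ngram_counts()], [count_cooccurrences()]
#' @export
ngram_set <- function(tokens, count) {
  if (is.character(tokens) && is.null(dim(tokens))) tokens <- matrix(tokens, nrow = 1L)
  stopifnot(is.matrix(tokens), is.character(tokens))
  count <- as.numeric(count)
  if (length(count) != nrow(tokens))
    stop("`count` must have one entry per n-gram row")
  if (anyNA(tokens) || any(!nzchar(tokens)))
    stop("tokens must be non-empty strings")
  if (anyNA(count) || any(count < 0))
    stop("counts must be non-negative")
  structure(list(tokens = tokens, count = count, n = ncol(tokens)),
            class = "ngram_set")
}

#' Read n-gram count records from a text file
#'
#' Each line holds `n` whitespace-separated tokens, a tab, and an integer
#' count (the dialect of large public n-gram count releases). Lines are
#' yielded in file order.
#'
#' @param path Path to a UTF-8 text file.
#' @param n Expected tokens per record (default 5, i.e. 5-grams).
#' @param lowercase Fold tokens to lower case (default `TRUE`).
#' @return An [ngram_set()].
#' @export
read_ngram_counts <- function(path, n = 5L, lowercase = TRUE) {
  stopifnot(is_count(n))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(ngram_set(matrix(character(0), 0L, n), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed n-gram record at line %d: expected 'tokens<TAB>count'", bad[1L]))
  count <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(count) | count < 0 | count != round(count))
  if (length(bad))
    stop(sprintf("invalid count at line %d: must be a non-negative integer", bad[1L]))
  toks <- strsplit(trimws(vapply(parts, `[[`, "", 1L)), "[[:space:]]+")
  bad <- which(lengths(toks) != n)
  if (length(bad))
    stop(sprintf("line %d has %d tokens; expected %d", bad[1L], lengths(toks)[bad[1L]], n))
  tokens <- matrix(unlist(toks), ncol = n, byrow = TRUE)
  if (lowercase) tokens[] <- tolower(tokens)
  ngram_set(tokens, count)
}

#' Write n-gram count records to a text file
#'
#' Inverse of [read_ngram_counts()]: one `"tok1 ... tokN<TAB>count"` line per
#' record, UTF-8.
#'
#' @param x An [ngram_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ngram_counts <- function(x, path) {
  stopifnot(inherits(x, "ngram_set"))
  lines <- paste0(apply(x$tokens, 1L, paste, collapse = " "), "\t",
                  format(x$count, scientific = FALSE, trim = TRUE))
  if (nrow(x$tokens) == 0L) lines <- character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.ngram_set <- function(x, ...) {
  cat(sprintf("<ngram_set> %d records of %d-grams, total count %s\n",
              nrow(x$tokens), x$n,
              format(sum(x$count), scientific = FALSE)))
  invisible(x)
}
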