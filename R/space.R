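#' Configuration of an LSA semantic space
#'
#' Holds the parameters of co-occurrence counting and truncated SVD. The
#' defaults mirror the configuration used for large public n-gram corpora:
#' a +/-4 token co-occurrence window inside 5-grams, the 120,000 most
#' frequent words on the rows, 50,000 on the columns, and 512 retained
#' dimensions. Desk-scale synthetic corpora use far smaller values; every
#' vocabulary is truncated to the words actually present.
#'
#' @param window Integer half-width of the co-occurrence window; token pairs
#'   at ordered positions (i, j), i != j, |i - j| <= window within a single
#'   n-gram are counted (both directions).
#' @param n_row_words,n_col_words Maximum row/column vocabulary sizes, taken
#'   as the most frequent words in the corpus (ties broken lexicographically).
#' @param n_dims Number of SVD dimensions retained.
#' @param log_base Base of the log(count + 1) normalization: `"natural"`
#'   (default) or `"base10"`.
#' @param lowercase Fold words to lower case throughout.
#' @return An object of class `space_config`.
#' @export
space_config <- function(window = 4L, n_row_words = 120000L, n_col_words = 50000L,
                         n_dims = 512L, log_base = c("natural", "base10"),
                         lowercase = TRUE) {
  log_base <- match.arg(log_base)
  for (v in list(window, n_row_words, n_col_words, n_dims))
    if (!is_count(v)) stop("all space_config sizes must be positive integers")
  if (n_dims > min(n_row_words, n_col_words))
    stop("n_dims cannot exceed min(n_row_words, n_col_words)")
  structure(list(window = as.integer(window),
                 n_row_words = as.integer(n_row_words),
                 n_col_words = as.integer(n_col_words),
                 n_dims = as.integer(n_dims),
                 log_base = log_base,
                 lowercase = isTRUE(lowercase)),
            class = "space_config")
}

# corpus word frequencies (count-weighted), ordered by decreasing frequency
# with lexicographic tie-break for determinism
corpus_frequencies <- function(ngrams) {
  words <- as.vector(ngrams$tokens)
  w <- rep(ngrams$count, times = ncol(ngrams$tokens))
  f <- vapply(split(w, words), sum, 0.0)
  f[order(-f, names(f), method = "radix")]
}

#' Count word-by-word co-occurrences in an n-gram corpus
#'
#' Builds the word-by-word co-occurrence matrix: `cell(r, c)` is the number
#' of times row word `r` and column word `c` occupy distinct positions at
#' distance at most `config$window` within an n-gram, summed over ordered
#' position pairs and weighted by each n-gram's corpus count. Counting is
#' symmetric in direction and confined to single n-grams.
#'
#' @param ngrams An [ngram_set()].
#' @param config A [space_config()].
#' @param row_vocab,col_vocab Optional explicit vocabularies (character
#'   vectors). By default the top `n_row_words` / `n_col_words` corpus words
#'   by descending frequency are used, truncated to words present.
#' @return An object of class `cooc_matrix` with elements `cells` (dense
#'   numeric matrix with word dimnames), `row_vocab`, `col_vocab`, and
#'   `normalized = FALSE`.
#' @export
count_cooccurrences <- function(ngrams, config = space_config(),
                                row_vocab = NULL, col_vocab = NULL) {
  stopifnot(inherits(ngrams, "ngram_set"), inherits(config, "space_config"))
  n <- ngrams$n
  if (nrow(ngrams$tokens) == 0L || sum(ngrams$count) == 0)
    stop("empty corpus: no n-grams with positive count")
  if (config$window < 1L || config$window > n - 1L)
    stop(sprintf("window must lie in [1, %d] for %d-grams", n - 1L, n))
  toks <- ngrams$tokens
  if (config$lowercase) toks[] <- tolower(toks)
  if (is.null(row_vocab) || is.null(col_vocab)) {
    freq <- corpus_frequencies(ngram_set(toks, ngrams$count))
    row_vocab <- row_vocab %||% utils::head(names(freq), config$n_row_words)
    col_vocab <- col_vocab %||% utils::head(names(freq), config$n_col_words)
  }
  ri <- matrix(match(toks, row_vocab), nrow(toks))
  ci <- matrix(match(toks, col_vocab), nrow(toks))
  ii <- vector("list", n * n); jj <- ii; xx <- ii; p <- 0L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || abs(a - b) > config$window) next
      keep <- !is.na(ri[, a]) & !is.na(ci[, b])
      p <- p + 1L
      ii[[p]] <- ri[keep, a]; jj[[p]] <- ci[keep, b]; xx[[p]] <- ngrams$count[keep]
    }
  }
  cells <- as.matrix(Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(row_vocab), length(col_vocab))))
  dimnames(cells) <- list(row_vocab, col_vocab)
  structure(list(cells = cells, row_vocab = row_vocab, col_vocab = col_vocab,
                 normalized = FALSE),
            class = "cooc_matrix")
}

#' Log-normalize a co-occurrence matrix
#'
#' Replaces every cell by `log(cell + 1)` (base per `config$log_base`),
#' attenuating raw frequency artifacts before the SVD. Refuses to transform
#' an already-normalized matrix.
#'
#' @param matrix A raw [count_cooccurrences()] result.
#' @param config A [space_config()].
#' @return The matrix with transformed `cells` and `normalized = TRUE`.
#' @export
normalize_counts <- function(matrix, config = space_config()) {
  stopifnot(inherits(matrix, "cooc_matrix"))
  if (isTRUE(matrix$normalized))
    stop("matrix is already normalized; refusing to apply log(x + 1) twice")
  matrix$cells <- switch(config$log_base,
                         natural = log1p(matrix$cells),
                         base10  = log10(matrix$cells + 1))
  matrix$normalized <- TRUE
  matrix
}

#' Build a semantic space by truncated SVD
#'
#' Decomposes the log-normalized co-occurrence matrix with singular value
#' decomposition, retains the first `n_dims` dimensions (the ones carrying
#' the most information), scales the left singular vectors by their singular
#' values, and normalizes every word vector to unit Euclidean length. The
#' sign of each dimension is fixed deterministically by forcing its
#' largest-magnitude loading to be positive.
#'
#' @param matrix A normalized [cooc_matrix][count_cooccurrences()].
#' @param config A [space_config()]; `config$n_dims` dimensions are retained
#'   and must not exceed the numerical rank of the matrix.
#' @return An object of class `semantic_space`: `vocab`, unit-row-norm
#'   `embeddings` (|vocab| x d), non-increasing `singular_values`, `d`, the
#'   `config`, and the Frobenius reconstruction error of the rank-d
#'   truncation of the normalized matrix.
#' @export
build_space <- function(matrix, config = space_config()) {
  stopifnot(inherits(matrix, "cooc_matrix"))
  if (!isTRUE(matrix$normalized))
    stop("build_space() expects a log-normalized matrix; call normalize_counts() first")
  k <- config$n_dims
  if (k > min(dim(matrix$cells)))
    stop(sprintf("n_dims = %d exceeds matrix dimension %d", k, min(dim(matrix$cells))))
  sv <- svd(matrix$cells)
  tol <- max(dim(matrix$cells)) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  if (k > rank)
    stop(sprintf("n_dims = %d exceeds the achievable rank %d of the normalized matrix", k, rank))
  u <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  emb <- sweep(u, 2L, sv$d[seq_len(k)], `*`)
  nrm <- sqrt(rowSums(emb^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    warning(sprintf("%d word(s) had zero-norm embeddings and were dropped: %s",
                    sum(zero), paste(utils::head(matrix$row_vocab[zero], 5L), collapse = ", ")))
    emb <- emb[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
  }
  vocab <- matrix$row_vocab[!zero]
  emb <- emb / nrm
  rownames(emb) <- vocab
  recon_err <- sqrt(sum(sv$d[-seq_len(k)]^2))
  semantic_space(vocab, emb, singular_values = sv$d[seq_len(k)],
                 config = config, reconstruction_error = recon_err)
}

#' Construct a semantic space from a vocabulary and embedding matrix
#'
#' Low-level constructor (also used by [build_space()]); validates that word
#' vectors have unit norm and that singular values are non-increasing.
#'
#' @param vocab Character vector of words.
#' @param embeddings Numeric matrix, one unit-norm row per word.
#' @param singular_values Non-increasing, non-negative numeric vector of
#'   length `ncol(embeddings)`; defaults to all ones.
#' @param config Optional [space_config()] recorded with the space.
#' @param reconstruction_error Optional Frobenius truncation error.
#' @return An object of class `semantic_space`.
#' @export
semantic_space <- function(vocab, embeddings, singular_values = NULL,
                           config = NULL, reconstruction_error = NA_real_) {
  embeddings <- as.matrix(embeddings)
  stopifnot(is.character(vocab), length(vocab) == nrow(embeddings))
  if (anyDuplicated(vocab)) stop("vocabulary contains duplicated words")
  d <- ncol(embeddings)
  singular_values <- singular_values %||% rep(1, d)
  if (length(singular_values) != d || any(diff(singular_values) > 1e-12) ||
      any(singular_values < 0))
    stop("singular_values must be non-negative, non-increasing, length d")
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("every embedding row must have unit Euclidean norm (within 1e-9)")
  rownames(embeddings) <- vocab
  structure(list(vocab = vocab, embeddings = embeddings,
                 singular_values = as.numeric(singular_values), d = d,
                 config = config, reconstruction_error = reconstruction_error),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space> %d words x %d dimensions\n", length(x$vocab), x$d))
  cat(sprintf("  leading singular values: %s\n",
              paste(signif(utils::head(x$singular_values, 4L), 4L), collapse = ", ")))
  invisible(x)
}

#' Persist a semantic space to a directory
#'
#' Writes plain-text artifacts: `vocab.txt` (one word per line),
#' `embeddings.tsv` (tab-separated, 17 significant digits),
#' `singular_values.txt`, and `config.json`. [load_space()] round-trips them.
#'
#' @param space A `semantic_space`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_space <- function(space, dir) {
  stopifnot(inherits(space, "semantic_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(space$vocab, file.path(dir, "vocab.txt"), useBytes = TRUE)
  emb <- apply(space$embeddings, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(emb, file.path(dir, "embeddings.tsv"))
  writeLines(formatC(space$singular_values, digits = 17, format = "g"),
             file.path(dir, "singular_values.txt"))
  cfg <- space$config %||% list()
  jsonlite::write_json(list(config = unclass(cfg), d = space$d,
                            reconstruction_error = space$reconstruction_error),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a semantic space saved with [save_space()]
#'
#' @param dir Directory written by [save_space()].
#' @return A `semantic_space`.
#' @export
load_space <- function(dir) {
  vocab <- readLines(file.path(dir, "vocab.txt"), encoding = "UTF-8")
  emb <- do.call(rbind, lapply(strsplit(readLines(file.path(dir, "embeddings.tsv")), "\t"),
                               as.numeric))
  sv <- as.numeric(readLines(file.path(dir, "singular_values.txt")))
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- NULL
  if (length(meta$config))
    cfg <- space_config(window = meta$config$window,
                        n_row_words = meta$config$n_row_words,
                        n_col_words = meta$config$n_col_words,
                        n_dims = meta$config$n_dims,
                        log_base = meta$config$log_base,
                        lowercase = meta$config$lowercase)
  # renormalize rows: text serialization perturbs norms at ~1e-17
  emb <- emb / sqrt(rowSums(emb^2))
  semantic_space(vocab, emb, singular_values = sv, config = cfg,
                 reconstruction_error = meta$reconstruction_error %||% NA_real_)
}
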