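#' Embed a keyword response as a unit-norm text vector
#'
#' A text (here, a participant's descriptive keywords) is represented by the
#' sum of its words' embeddings, renormalized to unit Euclidean length.
#' Word order is irrelevant; duplicated words contribute multiply.
#' Out-of-vocabulary words are skipped with a warning; a response with no
#' in-vocabulary words is an error, never a silent zero vector.
#'
#' @param words Character vector of words (case-folded against the space's
#'   vocabulary when the space was built with `lowercase = TRUE`).
#' @param space A [semantic_space()].
#' @return An object of class `text_embedding`: `vector` (length `space$d`,
#'   unit norm), `n_known_words`, and `oov` (the skipped words).
#' @export
embed_keywords <- function(words, space) {
  stopifnot(inherits(space, "semantic_space"), is.character(words))
  words <- words[!is.na(words) & nzchar(words)]
  if (length(words) == 0L) stop("no words to embed")
  if (isTRUE(space$config$lowercase) || is.null(space$config)) words <- tolower(words)
  idx <- match(words, space$vocab)
  oov <- unique(words[is.na(idx)])
  if (all(is.na(idx)))
    stop(sprintf("all %d words are out of vocabulary: %s",
                 length(words), paste(utils::head(oov, 5L), collapse = ", ")))
  if (length(oov))
    warning(sprintf("skipping %d out-of-vocabulary word(s): %s",
                    length(oov), paste(utils::head(oov, 5L), collapse = ", ")))
  v <- colSums(space$embeddings[idx[!is.na(idx)], , drop = FALSE])
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12)
    stop("degenerate embedding: word vectors cancel to a zero-norm sum")
  structure(list(vector = v / nrm, n_known_words = sum(!is.na(idx)), oov = oov),
            class = "text_embedding")
}

#' Embed a set of keyword responses
#'
#' Applies the additive unit-norm text embedding to each response,
#' preserving order. Responses whose words are all out of vocabulary are
#' flagged and skipped (rows of `NA`) with a summary warning rather than
#' aborting the batch.
#'
#' @param words A character matrix (one response per row) or a list of
#'   character vectors.
#' @param space A [semantic_space()].
#' @param on_oov `"skip"` (default) flags all-OOV responses and continues;
#'   `"error"` aborts on the first such response.
#' @return A list: `embeddings` (n x d matrix, `NA` rows for skipped
#'   responses), `n_known` (in-vocabulary words per response), and `skipped`
#'   (logical).
#' @export
embed_dataset <- function(words, space, on_oov = c("skip", "error")) {
  on_oov <- match.arg(on_oov)
  stopifnot(inherits(space, "semantic_space"))
  if (is.list(words) && !is.data.frame(words)) {
    if (length(words) == 0L) stop("no responses to embed")
    if (any(lengths(words) == 0L)) stop("responses with empty word lists must be filtered upstream")
    k <- max(lengths(words))
    words <- t(vapply(words, function(w) c(w, rep(NA_character_, k - length(w))), character(k)))
  }
  words <- as.matrix(words)
  if (nrow(words) == 0L) stop("no responses to embed")
  w <- words
  if (isTRUE(space$config$lowercase) || is.null(space$config)) w[] <- tolower(w)
  w[!is.na(w) & !nzchar(w)] <- NA_character_
  if (any(rowSums(!is.na(w)) == 0L))
    stop("responses with empty word lists must be filtered upstream")
  idx <- matrix(match(w, space$vocab), nrow(w))
  known <- !is.na(idx) & !is.na(w)
  n_known <- rowSums(known)
  rec <- row(idx)[known]
  sums <- rowsum(space$embeddings[idx[known], , drop = FALSE], rec)
  out <- matrix(NA_real_, nrow(w), space$d)
  out[as.integer(rownames(sums)), ] <- sums
  nrm <- sqrt(rowSums(out^2))
  skipped <- n_known == 0L | (!is.na(nrm) & nrm < 1e-12)
  if (any(skipped)) {
    if (on_oov == "error")
      stop(sprintf("response %d has no in-vocabulary words", which(skipped)[1L]))
    warning(sprintf("%d of %d responses had no usable in-vocabulary words and were skipped",
                    sum(skipped), nrow(w)))
    out[skipped, ] <- NA_real_
  }
  ok <- !skipped
  out[ok, ] <- out[ok, , drop = FALSE] / nrm[ok]
  n_oov <- sum(!is.na(w) & is.na(idx))
  if (n_oov > 0 && !any(skipped))
    warning(sprintf("skipped %d out-of-vocabulary word occurrence(s) across responses", n_oov))
  list(embeddings = out, n_known = n_known, skipped = skipped)
}
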