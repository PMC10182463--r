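#' Train the physical-vs-psychological condition scale
#'
#' Logistic semantic scale on a binary outcome coding texts describing
#' physical violence as 1 and psychological violence as 0, used to score
#' words for the condition word cloud.
#'
#' @param x Embedding matrix of the responses.
#' @param condition Character/factor vector of `"physical"` /
#'   `"psychological"` labels.
#' @param k Dimensions to use; `NULL` selects via [select_dimensions()].
#' @param grid,method,inner_folds,seed Passed to [select_dimensions()] when
#'   `k` is `NULL`.
#' @return A logistic [semantic_scale][train_scale()] with attribute
#'   `scale_name = "condition"`.
#' @export
train_condition_scale <- function(x, condition, k = NULL, grid = NULL,
                                  method = "inner-cv", inner_folds = 5L,
                                  seed = NULL) {
  condition <- as.character(condition)
  if (!all(condition %in% c("physical", "psychological")))
    stop("condition labels must be 'physical' or 'psychological'")
  y <- as.numeric(condition == "physical")
  if (length(unique(y)) < 2L) stop("both conditions must be present")
  if (is.null(k))
    k <- select_dimensions(x, y, grid = grid, family = "logistic",
                           method = method, inner_folds = inner_folds,
                           seed = seed)$k
  m <- train_scale(x, y, k, family = "logistic")
  attr(m, "scale_name") <- "condition"
  m
}

#' Per-record calibration bias (P2 rating minus the event's P1 rating)
#'
#' @param dataset A [study_dataset][generate_study()].
#' @return Numeric vector aligned with `dataset$p2` rows.
#' @export
per_record_bias <- function(dataset) {
  m <- match(dataset$p2$event, dataset$p1$event)
  if (anyNA(m)) {
    missing <- unique(dataset$p2$event[is.na(m)])
    stop(sprintf("no P1 record for event(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  dataset$p2$severity - dataset$p1$severity[m]
}

#' Train the calibration-bias scale
#'
#' Linear semantic scale predicting the per-record calibration bias (the
#' P2 rating minus the same event's P1 rating) from the response embedding,
#' used to score words for the bias word cloud.
#'
#' @param x Embedding matrix of the P2 responses.
#' @param bias Per-record biases, e.g. from [per_record_bias()].
#' @inheritParams train_condition_scale
#' @return A linear `semantic_scale` with attribute `scale_name = "bias"`.
#' @export
train_bias_scale <- function(x, bias, k = NULL, grid = NULL,
                             method = "inner-cv", inner_folds = 5L, seed = NULL) {
  bias <- as.numeric(bias)
  stopifnot(nrow(x) == length(bias))
  if (stats::sd(bias) == 0) {
    warning("all biases identical: fitting a zero-slope model; fit r is undefined")
    k <- k %||% min(ncol(x), max(1L, nrow(x) - 2L), 2L)
  } else if (is.null(k)) {
    k <- select_dimensions(x, bias, grid = grid, family = "linear",
                           method = method, inner_folds = inner_folds, seed = seed)$k
  }
  m <- train_scale(x, bias, k, family = "linear")
  attr(m, "scale_name") <- "bias"
  m
}

#' Score words on a trained semantic scale
#'
#' Backs the word-cloud figures: every distinct in-vocabulary word occurring
#' in the response corpus is embedded on its own (its unit-norm word vector)
#' and scored with the scale; scores are standardized to z values over the
#' distinct scored words (mean 0, SD 1), and the word's corpus frequency is
#' attached (color = z, font size = frequency in a renderer). Rows are
#' sorted by decreasing |z|.
#'
#' @param model A [train_scale()] result.
#' @param space The [semantic_space()] the model was trained in.
#' @param words Character vector of word occurrences (with repeats), e.g.
#'   from [dataset_words()].
#' @return A data frame `word`, `scale`, `score`, `z`, `frequency`.
#' @export
score_words <- function(model, space, words) {
  stopifnot(inherits(model, "semantic_scale"), inherits(space, "semantic_space"))
  words <- words[!is.na(words) & nzchar(words)]
  if (isTRUE(space$config$lowercase) || is.null(space$config)) words <- tolower(words)
  tab <- table(words)
  known <- intersect(names(tab), space$vocab)
  if (length(known) < 2L)
    stop("need at least 2 distinct in-vocabulary words to standardize scores")
  scores <- predict_scale(model, space$embeddings[known, , drop = FALSE])
  sdv <- stats::sd(scores)
  if (sdv == 0) {
    warning("all word scores identical; z values set to 0")
    z <- rep(0, length(scores))
  } else {
    z <- (scores - mean(scores)) / sdv
  }
  out <- data.frame(word = known,
                    scale = attr(model, "scale_name") %||% model$family,
                    score = scores, z = z,
                    frequency = as.integer(tab[known]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$z), out$word), ]
  rownames(out) <- NULL
  out
}

#' Collect the keyword occurrences of a study dataset
#'
#' @param dataset A [study_dataset][generate_study()].
#' @param phase `"p2"` (default), `"p1"`, or `"both"`.
#' @return Character vector of word occurrences (with repeats).
#' @export
dataset_words <- function(dataset, phase = c("p2", "p1", "both")) {
  phase <- match.arg(phase)
  pull <- function(df) {
    cols <- grep("^word[0-9]+$", names(df), value = TRUE)
    w <- unlist(df[cols], use.names = FALSE)
    w[!is.na(w) & nzchar(w)]
  }
  switch(phase, p1 = pull(dataset$p1), p2 = pull(dataset$p2),
         both = c(pull(dataset$p1), pull(dataset$p2)))
}

#' Write a word-score table
#'
#' Tab-separated `word`, `scale`, `score`, `z`, `frequency`, suitable as
#' input to any word-cloud renderer.
#'
#' @param scores A [score_words()] data frame (or several row-bound).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_word_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
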