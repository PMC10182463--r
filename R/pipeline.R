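#' Validate a study dataset before analysis
#'
#' Structural checks on the two-phase tables: severity range (fatal),
#' condition labels (fatal), every P2 event having a P1 record (fatal),
#' keyword counts (warning), and raters spanning more than one condition
#' (warning).
#'
#' @param dataset A [study_dataset][generate_study()] (or [read_study()]
#'   result).
#' @param keywords_per_response Expected keyword count per response.
#' @return A data frame of diagnostics (`level` = `"fatal"`/`"warning"`,
#'   `message`); zero rows means a clean dataset.
#' @export
validate_inputs <- function(dataset, keywords_per_response = 5L) {
  p1 <- dataset$p1; p2 <- dataset$p2
  diag <- list()
  note <- function(level, msg) diag[[length(diag) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  for (nm in c("p1", "p2")) {
    sev <- get(nm)$severity
    bad <- which(is.na(sev) | sev < 0 | sev > 10)
    if (length(bad))
      note("fatal", sprintf("%s: %d severity value(s) outside [0, 10] (first at row %d)",
                            toupper(nm), length(bad), bad[1L]))
  }
  badc <- setdiff(unique(c(p1$condition, p2$condition)),
                  c("psychological", "physical"))
  if (length(badc))
    note("fatal", sprintf("unknown condition label(s): %s", paste(badc, collapse = ", ")))
  orphan <- setdiff(unique(p2$event), p1$event)
  if (length(orphan))
    note("fatal", sprintf("%d P2 event(s) have no P1 record (e.g. %s)",
                          length(orphan), orphan[1L]))
  wcols <- grep("^word[0-9]+$", names(p2), value = TRUE)
  if (length(wcols)) {
    for (nm in c("p1", "p2")) {
      df <- get(nm)
      nkw <- rowSums(!is.na(as.matrix(df[wcols])) & nzchar(as.matrix(df[wcols])))
      short <- sum(nkw < keywords_per_response)
      if (short > 0)
        note("warning", sprintf("%s: %d response(s) have fewer than %d keywords",
                                toupper(nm), short, keywords_per_response))
    }
  }
  spread <- vapply(split(p2$condition, p2$rater),
                   function(x) length(unique(x)), 0L)
  if (any(spread > 1L))
    note("warning", sprintf("%d rater(s) rated events of more than one condition",
                            sum(spread > 1L)))
  if (length(diag) == 0L)
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, diag)
}

default_synthetic_space_config <- function() {
  # sized for the synthetic vocabulary (~hundreds of words), not the
  # paper-scale 120k x 50k corpus space
  space_config(n_dims = 64L, n_row_words = 5000L, n_col_words = 5000L)
}

#' Run the end-to-end severity-assessment pipeline
#'
#' Orchestrates the full analysis in order: synthetic vocabulary and n-gram
#' corpus (or user-supplied inputs), semantic space by truncated SVD,
#' keyword embeddings, grouped cross-validated severity scale on the P2
#' responses (out-of-fold predictions = MP2), a final full-data scale
#' applied to the P1 responses (MP1), the condition-level bias report, and
#' word scores for the severity, condition, and calibration-bias scales.
#' Every artifact is written as plain text under `out_dir` together with a
#' run manifest recording config and seed; identical config + seed gives
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param study_config A [study_config()] for synthetic generation (its own
#'   seed is overridden by `seed`), ignored when `study` is given together
#'   with `ngram_path`.
#' @param space_config A [space_config()]; defaults to a synthetic-scale
#'   space (64 dimensions).
#' @param study Optional existing dataset: a `study_dataset` or a path for
#'   [read_study()]. Requires `ngram_path`.
#' @param ngram_path Optional n-gram count file for [read_ngram_counts()]
#'   (otherwise a synthetic corpus is generated).
#' @param n_grams,mixing Synthetic corpus size and cluster escape
#'   probability ([generate_corpus()]).
#' @param grid,n_folds,inner_folds,method Cross-validation settings
#'   ([cross_validated_fit()]).
#' @return Invisibly, a list with the in-memory artifacts (`dataset`,
#'   `space`, `cv`, `final_model`, `mp1`, `mp2`, `report`, `word_scores`)
#'   and `paths` of everything written.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         study_config = NULL, space_config = NULL,
                         study = NULL, ngram_path = NULL,
                         n_grams = 4000L, mixing = 0.05,
                         grid = NULL, n_folds = 10L, inner_folds = 5L,
                         method = c("inner-cv", "train-fit")) {
  method <- match.arg(method)
  synthetic <- is.null(study)
  if (!synthetic && is.null(ngram_path))
    stop("a user-supplied study needs `ngram_path` for the corpus; ",
         "omit `study` to run fully synthetic")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  # the argument shadows the constructor, so qualify the default explicitly
  scfg <- study_config %||% semscale::study_config()
  scfg$seed <- as.integer(seed)

  # corpus
  if (is.null(ngram_path)) {
    vocab <- build_vocabulary(scfg)
    corpus <- generate_corpus(vocab, scfg, n_grams = n_grams, mixing = mixing)
    paths$ngrams <- file.path(out_dir, "ngrams.tsv")
    write_ngram_counts(corpus, paths$ngrams)
  } else {
    corpus <- read_ngram_counts(ngram_path)
  }

  # study
  dataset <- if (synthetic) generate_study(scfg) else
    if (is.character(study)) read_study(study) else study
  diagnostics <- validate_inputs(dataset, scfg$keywords_per_response)
  if (any(diagnostics$level == "fatal"))
    stop("input validation failed: ",
         paste(diagnostics$message[diagnostics$level == "fatal"], collapse = "; "))
  for (msg in diagnostics$message[diagnostics$level == "warning"]) warning(msg)
  paths$study <- file.path(out_dir, "study.tsv")
  write_study(dataset, paths$study)

  # space
  pcfg <- space_config %||% default_synthetic_space_config()
  mat <- count_cooccurrences(corpus, pcfg)
  space <- build_space(normalize_counts(mat, pcfg), pcfg)
  paths$space <- file.path(out_dir, "space")
  save_space(space, paths$space)

  # embeddings
  wcols <- grep("^word[0-9]+$", names(dataset$p2), value = TRUE)
  if (!length(wcols)) stop("study dataset has no keyword columns")
  e2 <- embed_dataset(as.matrix(dataset$p2[wcols]), space)
  e1 <- embed_dataset(as.matrix(dataset$p1[wcols]), space)
  if (any(e2$skipped) || any(e1$skipped))
    stop(sprintf("%d response(s) could not be embedded (all words out of vocabulary)",
                 sum(e2$skipped) + sum(e1$skipped)))

  # cross-validated severity scale on P2 (out-of-fold predictions = MP2)
  cv <- cross_validated_fit(e2$embeddings, dataset$p2$severity,
                            groups = dataset$p2$event, n_folds = n_folds,
                            grid = grid, family = "linear", method = method,
                            inner_folds = inner_folds,
                            seed = derive_seed(seed, 11L))
  mp2 <- cv$predictions$predicted
  paths$predictions <- file.path(out_dir, "cv_predictions.tsv")
  utils::write.table(cv$predictions, paths$predictions, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # final full-data scale, applied to P1 (MP1)
  sel <- select_dimensions(e2$embeddings, dataset$p2$severity, grid = grid,
                           groups = dataset$p2$event, family = "linear",
                           method = method, inner_folds = inner_folds,
                           seed = derive_seed(seed, 12L))
  severity_model <- train_scale(e2$embeddings, dataset$p2$severity, sel$k)
  attr(severity_model, "scale_name") <- "severity"
  mp1 <- predict_scale(severity_model, e1$embeddings)
  paths$model <- file.path(out_dir, "severity_scale.json")
  write_scale(severity_model, paths$model)

  # bias report
  report <- build_bias_report(dataset, mp1 = mp1, mp2 = mp2)
  paths$report <- file.path(out_dir, "bias_report.tsv")
  paths$tests <- file.path(out_dir, "bias_tests.json")
  write_bias_report(report, paths$report, paths$tests)

  # word scores on the three scales
  words <- dataset_words(dataset, "p2")
  condition_model <- train_condition_scale(e2$embeddings, dataset$p2$condition,
                                           grid = grid, method = method,
                                           inner_folds = inner_folds,
                                           seed = derive_seed(seed, 13L))
  bias_model <- train_bias_scale(e2$embeddings, per_record_bias(dataset),
                                 grid = grid, method = method,
                                 inner_folds = inner_folds,
                                 seed = derive_seed(seed, 14L))
  word_scores <- rbind(score_words(severity_model, space, words),
                       score_words(condition_model, space, words),
                       score_words(bias_model, space, words))
  paths$word_scores <- file.path(out_dir, "word_scores.tsv")
  write_word_scores(word_scores, paths$word_scores)

  # manifest (no timestamps: outputs must be reproducible byte for byte)
  manifest <- list(package = "semscale",
                   version = as.character(utils::packageVersion("semscale")),
                   seed = as.integer(seed),
                   synthetic = synthetic,
                   study_config = unclass(scfg),
                   space_config = unclass(pcfg),
                   cv = list(n_folds = n_folds, inner_folds = inner_folds,
                             method = method,
                             k_per_fold = cv$k_per_fold,
                             k_mean = cv$k_mean, k_sd = cv$k_sd,
                             r = cv$r),
                   final_k = sel$k,
                   files = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(dataset = dataset, space = space, cv = cv,
                 final_model = severity_model, mp1 = mp1, mp2 = mp2,
                 report = report, word_scores = word_scores,
                 diagnostics = diagnostics, paths = paths))
}
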