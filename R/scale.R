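#' Create a grouped cross-validation plan
#'
#' Partitions the distinct groups (here, the phase-1 source texts) into
#' `n_folds` folds of as-equal-as-possible size, so that all records sharing
#' a source text are assigned to the same fold and models are never tested
#' on texts they trained on. The partition is created once and is
#' deterministic given `seed`.
#'
#' @param groups Per-record group identifiers (character or factor).
#' @param n_folds Number of folds (default 10, i.e. train on 90%, test on
#'   the left-out 10%).
#' @param seed Integer seed for the group shuffle; `NULL` uses the current
#'   RNG state.
#' @return An object of class `cv_plan` with an `assignment` data frame
#'   (`group`, `fold`).
#' @export
make_folds <- function(groups, n_folds = 10L, seed = NULL) {
  stopifnot(is_count(n_folds))
  ug <- sort(unique(as.character(groups)), method = "radix")
  if (length(ug) < n_folds)
    stop(sprintf("need at least %d distinct groups for %d folds; got %d",
                 n_folds, n_folds, length(ug)))
  perm <- with_seed(seed, sample.int(length(ug)))
  assignment <- data.frame(group = ug[perm],
                           fold = rep_len(seq_len(n_folds), length(ug)),
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, n_folds = as.integer(n_folds), seed = seed),
            class = "cv_plan")
}

fold_of <- function(plan, groups) {
  f <- plan$assignment$fold[match(as.character(groups), plan$assignment$group)]
  if (anyNA(f)) stop("some records belong to groups absent from the cross-validation plan")
  f
}

default_dim_grid <- function(d, n_train) {
  grid <- c(2L, 4L, 8L, 16L, 32L, 64L, 96L, 128L, 192L, 256L, 384L, 512L)
  grid <- grid[grid <= min(d, n_train - 2L)]
  if (length(grid) == 0L) grid <- max(1L, min(d, n_train - 2L))
  grid
}

#' Train a semantic scale on the first k embedding dimensions
#'
#' Fits the regression mapping text embeddings to an outcome: ordinary
#' (unregularized) least squares with intercept for `family = "linear"`, or
#' a maximum-likelihood logit for `family = "logistic"` (binary outcomes
#' coded 0/1). Only the first `k` embedding dimensions are used, exploiting
#' the SVD property that leading dimensions carry the most information.
#'
#' @param x Embedding matrix (records x dimensions).
#' @param y Numeric outcome (ratings, or 0/1 labels for logistic).
#' @param k Number of leading dimensions used.
#' @param family `"linear"` or `"logistic"`.
#' @return An object of class `semantic_scale`: `family`, `intercept`,
#'   `coefficients` (length `k`), `k_dims`, `n_train`, and for logistic fits
#'   `converged` and a `separation` flag.
#' @export
train_scale <- function(x, y, k, family = c("linear", "logistic")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  stopifnot(is_count(k), k <= ncol(x), nrow(x) == length(y))
  xk <- x[, seq_len(k), drop = FALSE]
  a <- cbind(1, xk)
  colnames(a) <- c("(intercept)", paste0("dim_", seq_len(k)))
  separation <- FALSE
  if (family == "linear") {
    if (nrow(a) <= k) stop(sprintf("need more than k = %d training records; got %d", k, nrow(a)))
    dec <- qr(a)
    if (dec$rank < ncol(a)) {
      bad <- colnames(a)[dec$pivot[(dec$rank + 1L):ncol(a)]]
      stop(sprintf("rank-deficient design: dimension(s) %s are linearly dependent",
                   paste(bad, collapse = ", ")))
    }
    coef <- qr.coef(dec, y)
  } else {
    if (length(unique(y)) < 2L) stop("logistic scale needs both classes present")
    if (!all(y %in% c(0, 1))) stop("logistic outcomes must be coded 0/1")
    fit <- suppressWarnings(stats::glm.fit(a, y, family = stats::binomial()))
    if (!fit$converged)
      stop(sprintf("logistic fit did not converge within %d iterations", fit$iter))
    coef <- fit$coefficients
    if (anyNA(coef)) {
      bad <- colnames(a)[is.na(coef)]
      stop(sprintf("rank-deficient design: dimension(s) %s are linearly dependent",
                   paste(bad, collapse = ", ")))
    }
    mu <- fit$fitted.values
    if (all(abs(mu - y) < 1e-6)) {
      separation <- TRUE
      warning("perfect separation detected: logistic coefficients are unstable")
    }
  }
  structure(list(family = family,
                 intercept = unname(coef[1L]),
                 coefficients = unname(coef[-1L]),
                 k_dims = as.integer(k),
                 n_train = nrow(a),
                 separation = separation),
            class = "semantic_scale")
}

#' Predict from a semantic scale
#'
#' Linear scales return `intercept + <coefficients, first k dimensions>`;
#' logistic scales return probabilities in \[0, 1\].
#'
#' @param model A [train_scale()] result.
#' @param x A `text_embedding`, a numeric vector of length >= `k_dims`, or a
#'   matrix with at least `k_dims` columns.
#' @return Numeric vector of predictions.
#' @export
predict_scale <- function(model, x) {
  stopifnot(inherits(model, "semantic_scale"))
  if (inherits(x, "text_embedding")) x <- x$vector
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  k <- model$k_dims
  if (ncol(x) < k)
    stop(sprintf("embedding has %d dimensions; the scale uses the first %d", ncol(x), k))
  eta <- drop(x[, seq_len(k), drop = FALSE] %*% model$coefficients) + model$intercept
  if (model$family == "logistic") stats::plogis(eta) else eta
}

#' Select the number of leading dimensions for a semantic scale
#'
#' Searches a candidate grid for the dimension count giving the highest fit
#' (Pearson r between predictions and outcomes) on the training partition.
#' By default the fit is scored by inner grouped cross-validation, which
#' guards against the overfitting that plain training fit invites; the
#' `"train-fit"` method scores the in-sample fit instead. Ties are broken
#' toward the smallest k.
#'
#' @param x,y Training embeddings and outcomes.
#' @param grid Candidate dimension counts (default: powers-of-two style grid
#'   clipped to the data).
#' @param groups Group ids for the inner folds (defaults to one group per
#'   record).
#' @param family `"linear"` or `"logistic"`.
#' @param method `"inner-cv"` (default) or `"train-fit"`.
#' @param inner_folds Number of inner folds (default 5).
#' @param seed Seed for the inner fold shuffle.
#' @return A list: `k` (selected), and `trace` (data frame of `k`, `score`).
#' @export
select_dimensions <- function(x, y, grid = NULL, groups = NULL,
                              family = c("linear", "logistic"),
                              method = c("inner-cv", "train-fit"),
                              inner_folds = 5L, seed = NULL) {
  family <- match.arg(family); method <- match.arg(method)
  x <- as.matrix(x)
  grid <- sort(unique(as.integer(grid %||% default_dim_grid(ncol(x), nrow(x)))))
  stopifnot(all(grid >= 1L), all(grid <= ncol(x)))
  score_one <- function(k) {
    r <- tryCatch({
      if (method == "train-fit") {
        m <- train_scale(x, y, k, family)
        suppressWarnings(stats::cor(predict_scale(m, x), y))
      } else {
        g <- groups %||% as.character(seq_along(y))
        plan <- make_folds(g, inner_folds, seed)
        f <- fold_of(plan, g)
        pred <- rep(NA_real_, length(y))
        for (fi in seq_len(inner_folds)) {
          m <- train_scale(x[f != fi, , drop = FALSE], y[f != fi], k, family)
          pred[f == fi] <- predict_scale(m, x[f == fi, , drop = FALSE])
        }
        suppressWarnings(stats::cor(pred, y))
      }
    }, error = function(e) NA_real_)
    if (!is.na(r) && !is.finite(r)) r <- NA_real_
    r
  }
  scores <- vapply(grid, score_one, 0.0)
  if (all(is.na(scores)))
    stop("dimension selection failed: fit undefined for every candidate (constant outcome?)")
  best <- max(scores, na.rm = TRUE)
  k <- grid[which(!is.na(scores) & scores >= best - 1e-10)][1L]
  list(k = k, trace = data.frame(k = grid, score = scores))
}

#' Grouped leave-out cross-validation of a semantic scale
#'
#' The canonical evaluation loop: one fixed grouped partition; per fold, the
#' dimension count is optimized on the training 90% ([select_dimensions()]),
#' the scale is fit there, and the left-out 10% is predicted. Every record
#' receives exactly one out-of-fold prediction, and overall fit is the
#' Pearson r between predicted and observed values across all of them.
#'
#' @param x Embedding matrix.
#' @param y Outcomes.
#' @param groups Per-record source-text ids (leakage control).
#' @param n_folds Number of folds (default 10).
#' @param plan Optional pre-built [make_folds()] plan.
#' @param grid,family,method,inner_folds Passed to [select_dimensions()] /
#'   [train_scale()].
#' @param seed Seed controlling the fold shuffles.
#' @return An object of class `cv_fit`: `predictions` (data frame `index`,
#'   `group`, `fold`, `k_dims`, `predicted`, `observed`), overall `r`,
#'   `k_per_fold`, `k_mean`, `k_sd`, and the `plan`.
#' @export
cross_validated_fit <- function(x, y, groups, n_folds = 10L, plan = NULL,
                                grid = NULL, family = c("linear", "logistic"),
                                method = c("inner-cv", "train-fit"),
                                inner_folds = 5L, seed = NULL) {
  family <- match.arg(family); method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(groups) == length(y))
  plan <- plan %||% make_folds(groups, n_folds, seed)
  f <- fold_of(plan, groups)
  pred <- rep(NA_real_, length(y))
  kf <- integer(plan$n_folds)
  for (fi in seq_len(plan$n_folds)) {
    res <- tryCatch({
      tr <- f != fi
      sel <- select_dimensions(x[tr, , drop = FALSE], y[tr], grid = grid,
                               groups = groups[tr], family = family,
                               method = method, inner_folds = inner_folds,
                               seed = derive_seed(seed, fi))
      m <- train_scale(x[tr, , drop = FALSE], y[tr], sel$k, family)
      list(k = sel$k, p = predict_scale(m, x[!tr, , drop = FALSE]))
    }, error = function(e) stop(sprintf("fold %d failed: %s", fi, conditionMessage(e)),
                                call. = FALSE))
    kf[fi] <- res$k
    pred[f == fi] <- res$p
  }
  r <- tryCatch(pearson_r(pred, y), error = function(e) {
    warning("overall fit undefined: ", conditionMessage(e)); NA_real_
  })
  predictions <- data.frame(index = seq_along(y), group = as.character(groups),
                            fold = f, k_dims = kf[f], predicted = pred,
                            observed = y, stringsAsFactors = FALSE)
  structure(list(predictions = predictions, r = r,
                 k_per_fold = kf, k_mean = mean(kf), k_sd = stats::sd(kf),
                 plan = plan, family = family),
            class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat(sprintf("<cv_fit> %d-fold grouped cross-validation (%s scale)\n",
              x$plan$n_folds, x$family))
  cat(sprintf("  out-of-fold Pearson r = %.3f (r^2 = %.3f)\n", x$r, x$r^2))
  cat(sprintf("  dimensions retained per fold: mean %.1f (SD %.1f)\n", x$k_mean, x$k_sd))
  invisible(x)
}

#' @export
print.semantic_scale <- function(x, ...) {
  cat(sprintf("<semantic_scale> %s model on the first %d dimensions (n = %d)\n",
              x$family, x$k_dims, x$n_train))
  invisible(x)
}

#' Write a semantic scale to a plain-text file
#'
#' JSON persistence of `family`, `k_dims`, `intercept` and `coefficients`;
#' [read_scale()] round-trips it.
#'
#' @param model A `semantic_scale`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scale <- function(model, path) {
  stopifnot(inherits(model, "semantic_scale"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family = m$family, intercept = m$intercept,
                 coefficients = as.numeric(m$coefficients),
                 k_dims = as.integer(m$k_dims), n_train = m$n_train,
                 separation = isTRUE(m$separation)),
            class = "semantic_scale")
}
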