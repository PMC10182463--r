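# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (explicit loops, closed forms, direct optimization)
# so they share no code with the implementation paths they check.

# brute-force co-occurrence counting: iterate every (gram, i, j) triple
brute_cooccurrence <- function(tokens, count, row_vocab, col_vocab, window) {
  m <- matrix(0, length(row_vocab), length(col_vocab),
              dimnames = list(row_vocab, col_vocab))
  n <- ncol(tokens)
  for (g in seq_along(count)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || abs(i - j) > window) next
        w1 <- tokens[g, i]; w2 <- tokens[g, j]
        if (w1 %in% row_vocab && w2 %in% col_vocab)
          m[w1, w2] <- m[w1, w2] + count[g]
      }
    }
  }
  m
}

# closed-form least squares via the normal equations
ols_normal_equations <- function(x, y) {
  a <- cbind(1, x)
  drop(solve(t(a) %*% a, t(a) %*% y))
}

# maximum-likelihood logistic coefficients by direct optimization
logistic_ml_oracle <- function(x, y) {
  a <- cbind(1, x)
  nll <- function(b) {
    eta <- drop(a %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  stats::optim(rep(0, ncol(a)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# direct covariance-formula Pearson correlation
pearson_formula_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# a tiny deterministic semantic space with orthonormal word vectors
toy_space <- function(words = c("alpha", "beta", "gamma", "delta")) {
  semantic_space(words, diag(length(words)))
}

# small random n-gram corpus over a letter vocabulary
random_corpus <- function(n_grams, n = 5L, vocab = letters[1:8], max_count = 3L) {
  tokens <- matrix(sample(vocab, n_grams * n, replace = TRUE), n_grams, n)
  ngram_set(tokens, sample.int(max_count, n_grams, replace = TRUE))
}

# corpus -> space -> embeddings -> grouped CV, the spine shared by the
# simulation-based checks; sizes chosen for desk-scale runs
run_core <- function(cfg, n_dims = 64L, n_grams = 4000L,
                     grid = c(2L, 4L, 8L, 16L, 32L, 64L),
                     n_folds = 10L, inner_folds = 5L, with_report = TRUE) {
  vocab <- build_vocabulary(cfg)
  corpus <- generate_corpus(vocab, cfg, n_grams = n_grams)
  spcfg <- space_config(n_dims = n_dims, n_row_words = 5000L, n_col_words = 5000L)
  space <- build_space(normalize_counts(count_cooccurrences(corpus, spcfg), spcfg), spcfg)
  ds <- generate_study(cfg)
  wcols <- grep("^word[0-9]+$", names(ds$p2), value = TRUE)
  grid <- grid[grid <= space$d]
  e2 <- embed_dataset(as.matrix(ds$p2[wcols]), space)
  e1 <- embed_dataset(as.matrix(ds$p1[wcols]), space)
  cv <- cross_validated_fit(e2$embeddings, ds$p2$severity, groups = ds$p2$event,
                            n_folds = n_folds, grid = grid,
                            inner_folds = inner_folds, seed = cfg$seed)
  out <- list(dataset = ds, space = space, e1 = e1, e2 = e2, cv = cv,
              eta2 = signal_variance_fraction(ds))
  if (with_report) {
    sel <- select_dimensions(e2$embeddings, ds$p2$severity, grid = grid,
                             groups = ds$p2$event, inner_folds = inner_folds,
                             seed = cfg$seed + 1L)
    model <- train_scale(e2$embeddings, ds$p2$severity, sel$k)
    out$final_model <- model
    out$mp1 <- predict_scale(model, e1$embeddings)
    out$report <- build_bias_report(ds, mp1 = out$mp1,
                                    mp2 = cv$predictions$predicted)
  }
  out
}

# shared cache so several acceptance checks reuse one 20-seed simulation
.sim_cache <- new.env(parent = emptyenv())

default_sim_runs <- function(seeds = 1303L + seq_len(20L)) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- lapply(seeds, function(s) {
      run <- run_core(study_config(seed = s))
      both <- run$report$tests$both
      list(r2 = run$cv$r^2, eta2 = run$eta2,
           human_r = both$mean_human_r, model_r = both$mean_model_r)
    })
  }
  .sim_cache[[key]]
}
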