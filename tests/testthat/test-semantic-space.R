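test_that("n-gram count files parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a b c d e\t3", "B c d e f\t1"), f)
  ng <- read_ngram_counts(f, n = 5)
  expect_equal(ng$tokens[1, ], c("a", "b", "c", "d", "e"))
  expect_equal(ng$count, c(3, 1))
  expect_equal(ng$tokens[2, 1], "b") # lowercased

  writeLines(character(0), f)
  expect_equal(nrow(read_ngram_counts(f, n = 5)$tokens), 0L)

  writeLines("a b c d\t2", f)
  expect_error(read_ngram_counts(f, n = 5), "line 1")
  writeLines("a b c d e\t-2", f)
  expect_error(read_ngram_counts(f, n = 5), "non-negative")
  writeLines("a b c d e 7", f)
  expect_error(read_ngram_counts(f, n = 5), "malformed")

  writeLines(c("x y z w v\t2", "v w x y z\t5"), f)
  ng <- read_ngram_counts(f, n = 5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ngram_counts(ng, f2)
  expect_identical(read_ngram_counts(f2, n = 5), ng)
})

test_that("window geometry of co-occurrence counting is honoured", {
  ng <- ngram_set(matrix(c("a", "b", "c", "d", "e"), 1), 1)
  cfg <- space_config(window = 4, n_row_words = 10, n_col_words = 10, n_dims = 2)
  m <- count_cooccurrences(ng, cfg)
  expect_equal(m$cells["a", "b"], 1)
  expect_equal(m$cells["a", "e"], 1)
  expect_equal(m$cells["a", "a"], 0)
  expect_false(m$normalized)

  cfg1 <- space_config(window = 1, n_row_words = 10, n_col_words = 10, n_dims = 2)
  m1 <- count_cooccurrences(ng, cfg1)
  expect_equal(m1$cells["a", "c"], 0)
  expect_equal(m1$cells["a", "b"], 1)

  # repeated word at distinct positions counts into the diagonal
  ng2 <- ngram_set(matrix(c("a", "b", "a", "c", "d"), 1), 2)
  m2 <- count_cooccurrences(ng2, cfg)
  expect_equal(m2$cells["a", "a"], 4) # two ordered position pairs x count 2

  expect_error(count_cooccurrences(ngram_set(matrix(character(0), 0, 5), numeric(0)), cfg),
               "empty corpus")
})

test_that("counting matches the brute-force position-pair oracle", {
  set.seed(11)
  for (rep in 1:8) {
    ng <- random_corpus(sample(3:50, 1))
    w <- sample(1:4, 1)
    cfg <- space_config(window = w, n_row_words = 50, n_col_words = 50, n_dims = 2)
    got <- count_cooccurrences(ng, cfg)
    oracle <- brute_cooccurrence(ng$tokens, ng$count, got$row_vocab, got$col_vocab, w)
    expect_equal(got$cells, oracle)
  }
})

test_that("co-occurrence counting is additive over corpora", {
  set.seed(12)
  a <- random_corpus(20); b <- random_corpus(15)
  cfg <- space_config(window = 3, n_row_words = 50, n_col_words = 50, n_dims = 2)
  vocab <- letters[1:8]
  ca <- count_cooccurrences(a, cfg, row_vocab = vocab, col_vocab = vocab)
  cb <- count_cooccurrences(b, cfg, row_vocab = vocab, col_vocab = vocab)
  ab <- ngram_set(rbind(a$tokens, b$tokens), c(a$count, b$count))
  cab <- count_cooccurrences(ab, cfg, row_vocab = vocab, col_vocab = vocab)
  expect_equal(cab$cells, ca$cells + cb$cells)
})

test_that("log normalization matches the elementwise oracle and refuses re-application", {
  set.seed(13)
  ng <- random_corpus(10, vocab = letters[1:4])
  cfg <- space_config(window = 2, n_row_words = 4, n_col_words = 4, n_dims = 2)
  raw <- count_cooccurrences(ng, cfg)
  nm <- normalize_counts(raw, cfg)
  expect_true(nm$normalized)
  expect_equal(nm$cells, log(raw$cells + 1))
  expect_error(normalize_counts(nm, cfg), "already normalized")

  # closed forms: log(0 + 1) = 0 and log(e - 1 + 1) = 1
  raw$cells[1, 1] <- 0; raw$cells[1, 2] <- exp(1) - 1
  nm <- normalize_counts(raw, cfg)
  expect_equal(nm$cells[1, 1], 0)
  expect_equal(nm$cells[1, 2], 1)

  cfg10 <- space_config(window = 2, n_row_words = 4, n_col_words = 4, n_dims = 2,
                        log_base = "base10")
  raw2 <- count_cooccurrences(ng, cfg10)
  expect_equal(normalize_counts(raw2, cfg10)$cells, log10(raw2$cells + 1))
})

make_cooc <- function(cells, normalized = TRUE) {
  rv <- paste0("r", seq_len(nrow(cells))); cv <- paste0("c", seq_len(ncol(cells)))
  dimnames(cells) <- list(rv, cv)
  structure(list(cells = cells, row_vocab = rv, col_vocab = cv,
                 normalized = normalized), class = "cooc_matrix")
}

test_that("SVD truncation behaves like the dense decomposition oracle", {
  # identity input: embeddings are orthonormal
  cfg <- space_config(window = 4, n_row_words = 6, n_col_words = 6, n_dims = 6)
  sp <- build_space(make_cooc(diag(6)), cfg)
  expect_equal(sp$embeddings %*% t(sp$embeddings), diag(6), ignore_attr = TRUE)

  # rank-2 truncation error of a 6x4 toy equals the best rank-2 error
  set.seed(14)
  m <- matrix(rexp(24), 6, 4)
  full <- svd(m)
  best2 <- full$u[, 1:2] %*% diag(full$d[1:2]) %*% t(full$v[, 1:2])
  oracle_err <- sqrt(sum((m - best2)^2))
  cfg2 <- space_config(window = 4, n_row_words = 6, n_col_words = 4, n_dims = 2)
  sp2 <- build_space(make_cooc(m), cfg2)
  expect_equal(sp2$reconstruction_error, oracle_err, tolerance = 1e-10)

  # truncation error is non-increasing in the retained dimension count
  errs <- vapply(1:4, function(k)
    build_space(make_cooc(m), space_config(window = 4, n_row_words = 6,
                                           n_col_words = 4, n_dims = k))$reconstruction_error,
    0.0)
  expect_true(all(diff(errs) <= 1e-12))

  # requesting more dimensions than the rank fails loudly
  low <- matrix(1, 4, 4) # rank 1
  expect_error(build_space(make_cooc(low),
                           space_config(window = 4, n_row_words = 4,
                                        n_col_words = 4, n_dims = 3)),
               "rank 1")
  expect_error(build_space(make_cooc(diag(4), normalized = FALSE),
                           space_config(window = 4, n_row_words = 4,
                                        n_col_words = 4, n_dims = 2)),
               "normalize_counts")
})

test_that("built spaces have unit-norm rows, sorted singular values, fixed signs", {
  set.seed(15)
  ng <- random_corpus(40)
  cfg <- space_config(window = 4, n_row_words = 8, n_col_words = 8, n_dims = 5)
  sp <- build_space(normalize_counts(count_cooccurrences(ng, cfg), cfg), cfg)
  expect_true(all(abs(sqrt(rowSums(sp$embeddings^2)) - 1) < 1e-9))
  expect_true(all(diff(sp$singular_values) <= 1e-12))
  expect_equal(sp$d, 5L)
  sp2 <- build_space(normalize_counts(count_cooccurrences(ng, cfg), cfg), cfg)
  expect_identical(sp$embeddings, sp2$embeddings)
})

test_that("the full-corpus configuration retains 512 dimensions by default", {
  cfg <- space_config()
  expect_equal(cfg$n_dims, 512L)
  expect_equal(cfg$window, 4L)
  expect_equal(cfg$n_row_words, 120000L)
  expect_equal(cfg$n_col_words, 50000L)
  expect_error(space_config(n_dims = 600, n_row_words = 100, n_col_words = 500),
               "n_dims")
})

test_that("semantic spaces survive a save/load round trip", {
  set.seed(16)
  ng <- random_corpus(40)
  cfg <- space_config(window = 3, n_row_words = 8, n_col_words = 8, n_dims = 4,
                      log_base = "base10")
  sp <- build_space(normalize_counts(count_cooccurrences(ng, cfg), cfg), cfg)
  dir <- withr::local_tempdir()
  save_space(sp, dir)
  sp2 <- load_space(dir)
  expect_identical(sp2$vocab, sp$vocab)
  expect_equal(sp2$embeddings, sp$embeddings, tolerance = 1e-12)
  expect_equal(sp2$singular_values, sp$singular_values, tolerance = 1e-12)
  expect_identical(unclass(sp2$config), unclass(sp$config))
})
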