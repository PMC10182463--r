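test_that("grouped folds are balanced, exclusive, and deterministic", {
  g10 <- rep(paste0("t", 1:10), each = 3)
  plan <- make_folds(g10, 10, seed = 1)
  expect_equal(sort(plan$assignment$fold), 1:10) # one group per fold

  g68 <- paste0("text", 1:68)
  plan68 <- make_folds(g68, 10, seed = 2)
  sizes <- as.vector(table(plan68$assignment$fold))
  expect_equal(sort(sizes), c(6, 6, rep(7, 8))) # 68 = 10*6 + 8

  # records sharing a source text are always co-assigned
  recs <- sample(g68, 200, replace = TRUE)
  f <- plan68$assignment$fold[match(recs, plan68$assignment$group)]
  expect_true(all(tapply(f, recs, function(x) length(unique(x))) == 1))

  expect_identical(make_folds(g68, 10, seed = 9), make_folds(g68, 10, seed = 9))
  expect_error(make_folds(paste0("t", 1:5), 10), "at least 10")
})

test_that("a noiseless one-dimensional outcome selects k = 1", {
  set.seed(31)
  x <- matrix(rnorm(200), 40, 5)
  y <- x[, 1]
  for (m in c("train-fit", "inner-cv")) {
    sel <- select_dimensions(x, y, grid = 1:5, method = m, seed = 3)
    expect_equal(sel$k, 1L)
  }
})

test_that("dimension selection recovers a planted 8-dimensional signal", {
  set.seed(32)
  n <- 200; d <- 30
  x <- matrix(rnorm(n * d), n, d)
  b <- c(3, -2, 1.5, 1, -1, 0.8, -0.6, 0.5)
  y <- drop(x[, 1:8] %*% b) + rnorm(n, 0, 0.5)
  sel <- select_dimensions(x, y, grid = c(2, 4, 8, 16, 30), seed = 4)
  expect_gte(sel$k, 8L)
  # fit at the selected k is within 0.05 of the k = 8 oracle fit
  oracle <- stats::cor(drop(cbind(1, x[, 1:8]) %*% ols_normal_equations(x[, 1:8], y)), y)
  fit <- stats::cor(predict_scale(train_scale(x, y, sel$k), x), y)
  expect_lt(abs(fit - oracle), 0.05)
  expect_error(select_dimensions(x, rep(1, n), grid = c(2, 4)),
               "constant outcome")
})

test_that("linear scales match the normal-equations oracle", {
  # exact recovery of y = 2 x1 - 1
  set.seed(33)
  x <- matrix(rnorm(36), 12, 3)
  m <- train_scale(x, 2 * x[, 1] - 1, k = 1)
  expect_equal(m$coefficients, 2, tolerance = 1e-10)
  expect_equal(m$intercept, -1, tolerance = 1e-10)
  expect_equal(stats::cor(predict_scale(m, x), 2 * x[, 1] - 1), 1, tolerance = 1e-12)

  # 12-point design against the closed form
  y <- rnorm(12)
  m3 <- train_scale(x, y, k = 3)
  oracle <- ols_normal_equations(x[, 1:3], y)
  expect_equal(c(m3$intercept, m3$coefficients), unname(oracle), tolerance = 1e-8)
  # and against lm's fitted values
  expect_equal(predict_scale(m3, x), unname(stats::lm.fit(cbind(1, x), y)$fitted.values),
               tolerance = 1e-10)

  xdup <- cbind(x[, 1], x[, 1], x[, 2])
  expect_error(train_scale(xdup, y, k = 3), "dim_2")
  expect_error(train_scale(x[1:3, ], y[1:3], k = 3), "more than k")
})

test_that("logistic scales match the likelihood oracle and flag separation", {
  set.seed(34)
  x <- matrix(rnorm(20), 10, 2)
  eta <- 1.2 * x[, 1] - 0.5
  y <- as.numeric(runif(10) < plogis(eta))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  m <- train_scale(x, y, k = 2, family = "logistic")
  oracle <- logistic_ml_oracle(x, y)
  expect_equal(c(m$intercept, m$coefficients), oracle, tolerance = 1e-3)
  expect_false(m$separation)

  # perfectly separated labels along dimension 1
  xs <- matrix(c(seq(-2, -0.5, length.out = 6), seq(0.5, 2, length.out = 6),
                 rnorm(12)), 12, 2)
  ys <- rep(c(0, 1), each = 6)
  expect_warning(ms <- train_scale(xs, ys, k = 1, family = "logistic"), "separation")
  expect_true(all((predict_scale(ms, xs) > 0.5) == (ys == 1)))
  expect_error(train_scale(xs, rep(1, 12), k = 1, family = "logistic"), "both classes")
})

test_that("prediction is the documented affine map", {
  m <- structure(list(family = "linear", intercept = 0.7,
                      coefficients = c(1.5, -2, 0.25), k_dims = 3L,
                      n_train = 10L, separation = FALSE),
                 class = "semantic_scale")
  expect_equal(predict_scale(m, rep(0, 3)), 0.7)
  v <- c(0.2, -0.4, 1)
  expect_equal(predict_scale(m, v), 0.7 + sum(c(1.5, -2, 0.25) * v), tolerance = 1e-12)
  # extra dimensions beyond k are ignored; too few are an error
  expect_equal(predict_scale(m, c(v, 9, 9)), predict_scale(m, v))
  expect_error(predict_scale(m, c(1, 2)), "dimensions")
})

test_that("scale persistence round-trips through plain text", {
  set.seed(35)
  x <- matrix(rnorm(60), 20, 3)
  m <- train_scale(x, rnorm(20), k = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_scale(m, f)
  m2 <- read_scale(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(predict_scale(m2, x), predict_scale(m, x))
})

test_that("cross-validation predicts every record once without text leakage", {
  set.seed(36)
  n <- 80; d <- 10
  x <- matrix(rnorm(n * d), n, d)
  groups <- rep(paste0("t", 1:20), each = 4)
  y <- drop(x[, 1:3] %*% c(2, -1, 0.5))
  cv <- cross_validated_fit(x, y, groups, n_folds = 10, grid = c(2, 3, 5), seed = 5)
  expect_gte(cv$r, 0.999) # noiseless planted signal
  expect_equal(sort(cv$predictions$index), 1:n)
  # leakage check: a record's fold equals its group's planned fold
  planned <- cv$plan$assignment$fold[match(groups, cv$plan$assignment$group)]
  expect_equal(cv$predictions$fold, planned)
  expect_true(all(tapply(cv$predictions$fold, cv$predictions$group,
                         function(f) length(unique(f))) == 1))
})

test_that("out-of-fold predictions are invariant to record order", {
  set.seed(37)
  n <- 60
  x <- matrix(rnorm(n * 6), n, 6)
  groups <- rep(paste0("t", 1:15), each = 4)
  y <- drop(x[, 1:2] %*% c(1, -1)) + rnorm(n, 0, 0.3)
  cv1 <- cross_validated_fit(x, y, groups, n_folds = 5, grid = c(2, 4), seed = 6)
  perm <- sample(n)
  cv2 <- cross_validated_fit(x[perm, ], y[perm], groups[perm], n_folds = 5,
                             grid = c(2, 4), seed = 6)
  expect_equal(cv2$predictions$predicted[order(perm)], cv1$predictions$predicted,
               tolerance = 1e-10)
  expect_equal(cv2$r, cv1$r, tolerance = 1e-10)
})

test_that("cross-validated fit improves monotonically as noise vanishes", {
  set.seed(38)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8)
  groups <- rep(paste0("t", 1:30), each = 4)
  signal <- drop(x[, 1:3] %*% c(2, -1.5, 1))
  rs <- vapply(c(4, 1, 0.1), function(sd_noise) {
    y <- signal + rnorm(n, 0, sd_noise)
    cross_validated_fit(x, y, groups, n_folds = 5, grid = c(2, 4, 8), seed = 7)$r
  }, 0.0)
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.99)
})
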