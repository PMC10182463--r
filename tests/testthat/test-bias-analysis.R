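test_that("calibration bias is an antisymmetric mean difference", {
  x <- c(2, 5, 7, 9)
  expect_equal(calibration_bias(x, x), 0)
  y <- c(1, 4, 6, 6)
  expect_equal(calibration_bias(x, y), -calibration_bias(y, x))
  expect_equal(calibration_bias(x, y), mean(y) - mean(x))
  a <- severity_series(x, "P1", "psychological")
  b <- severity_series(y, "P2", "physical")
  expect_error(calibration_bias(a, b), "condition mismatch")
})

test_that("calibration bias reproduces the reference summary arithmetic", {
  ref <- reference_summary()
  human <- round(mapply(calibration_bias, ref$mean_p1, ref$mean_p2), 2)
  expect_equal(unname(human), c(0.17, -0.61, 0.95))
  comp_both <- round(calibration_bias(ref$mean_p1[1], ref$mean_mp2[1]), 2)
  expect_equal(comp_both, 0.36)
})

test_that("the calibration t test matches the textbook pooled oracle", {
  # equal means, equal spread: no evidence of a shift
  t0 <- calibration_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # mean diff +1, pooled SD 1, se sqrt(2/3); statistic signed other - P1
  tt <- calibration_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, 1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(abs(tt$statistic), 1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$estimate, 1)
  expect_equal(tt$p_value, 2 * stats::pt(-sqrt(3 / 2), df = 4), tolerance = 1e-12)

  # degenerate inputs
  z <- calibration_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$statistic, 0); expect_equal(z$p_value, 1)
  expect_warning(zi <- calibration_test(c(2, 2, 2), c(3, 3, 3)), "zero variance")
  expect_equal(zi$statistic, Inf)
  expect_error(calibration_test(1, c(1, 2)), "at least 2")

  # Welch mode reports fractional df
  tw <- calibration_test(c(1, 2, 3, 7), c(2.2, 2.4, 2.3), var_equal = FALSE)
  expect_false(tw$df == 5)
})

test_that("per-rater accuracy equals the covariance-formula oracle", {
  p1 <- data.frame(event = paste0("e", 1:5), severity = c(2, 4, 5, 7, 9))
  echo <- data.frame(event = paste0("e", 1:5), severity = c(2, 4, 5, 7, 9))
  expect_equal(accuracy_per_rater(echo, p1), 1)
  # a rater outputting a reversed linear series of the P1 ratings
  rev <- data.frame(event = paste0("e", 1:5), severity = 10 - c(2, 4, 5, 7, 9))
  expect_equal(accuracy_per_rater(rev, p1), -1)

  hand <- data.frame(event = paste0("e", 1:5), severity = c(3, 3, 6, 8, 7))
  expect_equal(accuracy_per_rater(hand, p1),
               pearson_formula_oracle(p1$severity, hand$severity),
               tolerance = 1e-12)

  # matching is by event id, not row order
  shuf <- hand[c(4, 1, 5, 2, 3), ]
  expect_equal(accuracy_per_rater(shuf, p1), accuracy_per_rater(hand, p1))

  expect_error(accuracy_per_rater(hand[1:2, ], p1), "at least 3")
  flat <- data.frame(event = paste0("e", 1:5), severity = rep(5, 5))
  expect_error(accuracy_per_rater(flat, p1), "zero variance")
})

test_that("Pearson accuracy is invariant under positive affine transforms", {
  set.seed(41)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10, 0, 0.4)
  r0 <- pearson_r(x, y)
  expect_equal(pearson_r(2.5 * x + 3, y), r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 7), r0, tolerance = 1e-12)
})

test_that("accuracy comparison between humans and the model is a signed t test", {
  rs <- c(0.2, 0.3, 0.25, 0.4)
  same <- accuracy_compare(rs, rs)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 6)

  set.seed(42)
  human <- rep(0.3, 20) + rnorm(20, 0, 1e-3)
  model <- rep(0.4, 20) + rnorm(20, 0, 1e-3)
  cmp <- accuracy_compare(human, model)
  expect_lt(cmp$statistic, 0) # humans worse -> negative t
  expect_equal(cmp$df, 38)
  cmpz <- accuracy_compare(human, model, fisher_z = TRUE)
  expect_lt(cmpz$statistic, 0)
})

test_that("a dataset where P2 echoes P1 yields zero bias and perfect correlation", {
  cfg <- study_config(n_events_per_condition = 12, n_p2_raters = 6,
                      sigma_p1 = 0, sigma_p2 = c(0, 0), rater_sd = 0,
                      delta = c(0, 0), sensitivity = c(1, 1), seed = 11)
  ds <- generate_study(cfg, keywords = FALSE)
  mp2 <- ds$p1$severity[match(ds$p2$event, ds$p1$event)]
  mp1 <- ds$p1$severity
  rep <- build_bias_report(ds, mp1 = mp1, mp2 = mp2)
  expect_equal(rep$table$human_bias, rep(0, 3))
  expect_equal(rep$table$computational_bias, rep(0, 3))
  expect_equal(rep$table$r_p1_p2, rep(1, 3))
  expect_equal(rep$table$r_p1_mp1, rep(1, 3))
  expect_equal(rep$table$r_p1_mp2, rep(1, 3))
})

test_that("the report reproduces the study's degrees-of-freedom pattern", {
  cfg <- study_config(seed = 12)
  ds <- generate_study(cfg, keywords = FALSE)
  set.seed(43)
  mp2 <- ds$p1$severity[match(ds$p2$event, ds$p1$event)] + rnorm(nrow(ds$p2), 0, 1)
  mp1 <- ds$p1$severity + rnorm(nrow(ds$p1), 0, 1)
  rep <- build_bias_report(ds, mp1 = mp1, mp2 = mp2)
  tt <- rep$tests$psychological
  expect_equal(tt$human_calibration$df, 86)  # 68 events + 20 rater means - 2
  expect_equal(tt$model_calibration$df, 134) # 68 events + 68 event means - 2
  expect_equal(tt$accuracy$df, 38)           # 20 human + 20 model r values - 2
  expect_equal(rep$table$n_points, c(2720L, 1360L, 1360L))

  # partial report: missing model predictions leave explicit gaps
  partial <- build_bias_report(ds)
  expect_true(all(is.na(partial$table$r_p1_mp2)))
  expect_true(all(is.na(partial$table$computational_bias)))
  expect_null(partial$tests$psychological$accuracy)
})

test_that("low-noise planted shifts are recovered in the report", {
  cfg <- study_config(n_events_per_condition = 68, n_p2_raters = 40,
                      sigma_p1 = 0.1, sigma_p2 = c(0.3, 0.3), rater_sd = 0.1,
                      sensitivity = c(1, 1), seed = 13)
  ds <- generate_study(cfg, keywords = FALSE)
  rep <- build_bias_report(ds)
  got <- rep$table$human_bias[match(c("psychological", "physical"),
                                    rep$table$condition)]
  expect_lt(abs(got[1] - (-0.61)), 0.15)
  expect_lt(abs(got[2] - 0.95), 0.15)
})

test_that("bias report files are written in both delimited and structured form", {
  cfg <- study_config(n_events_per_condition = 10, n_p2_raters = 4, seed = 14)
  ds <- generate_study(cfg, keywords = FALSE)
  rep <- build_bias_report(ds)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_bias_report(rep, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$condition, c("both", "psychological", "physical"))
  tests <- jsonlite::read_json(js)
  expect_equal(tests$psychological$human_calibration$df,
               rep$tests$psychological$human_calibration$df)
})
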