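#' Severity rating series
#'
#' A light container for a set of 0--10 severity ratings with their role
#' (`P1` experiencers, `P2` readers, `MP1`/`MP2` model predictions for the
#' respective phases) and violence condition. Most bias functions also
#' accept bare numeric vectors.
#'
#' @param values Numeric severities on the 0--10 scale (model predictions
#'   may fall slightly outside after regression; they are accepted).
#' @param role One of `"P1"`, `"P2"`, `"MP1"`, `"MP2"`.
#' @param condition `"psychological"`, `"physical"`, or `"both"`.
#' @param event,rater Optional per-value identifiers.
#' @return An object of class `severity_series`.
#' @export
severity_series <- function(values, role = c("P1", "P2", "MP1", "MP2"),
                            condition = c("both", "psychological", "physical"),
                            event = NULL, rater = NULL) {
  role <- match.arg(role); condition <- match.arg(condition)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty severity series")
  if (role %in% c("P1", "P2") && (any(values < 0) || any(values > 10)))
    stop("human severity ratings must lie in [0, 10]")
  structure(list(values = values, role = role, condition = condition,
                 event = event, rater = rater),
            class = "severity_series")
}

series_values <- function(x) if (inherits(x, "severity_series")) x$values else as.numeric(x)

check_conditions <- function(a, b) {
  if (inherits(a, "severity_series") && inherits(b, "severity_series") &&
      a$condition != b$condition && a$condition != "both" && b$condition != "both")
    stop(sprintf("condition mismatch: %s vs %s", a$condition, b$condition))
}

#' Calibration bias between phases
#'
#' The calibration bias is the mean severity assigned by the receiving side
#' (P2 readers, or the model's predictions) minus the mean severity assigned
#' by the experiencers (P1): `mean(other) - mean(p1)`. A negative value
#' means readers under-rate the events relative to those who lived them.
#'
#' @param p1 P1 severities (numeric or [severity_series()]).
#' @param other P2 severities or model predictions for the same condition.
#' @return The mean difference, a single number.
#' @examples
#' ref <- reference_summary()
#' calibration_bias(ref$mean_p1[1], ref$mean_p2[1]) # combined human bias
#' @export
calibration_bias <- function(p1, other) {
  check_conditions(p1, other)
  mean(series_values(other)) - mean(series_values(p1))
}

new_bias_test <- function(statistic, df, p_value, estimate, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), estimate = unname(estimate),
                 method = method),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("%s: t(%s) = %.3f, p = %.3f, estimate = %.3f\n",
              x$method, format(round(x$df, 1)), x$statistic, x$p_value, x$estimate))
  invisible(x)
}

#' Two-sample t test of a calibration bias
#'
#' Two-sided independent two-sample t test of `other` against `p1`, with the
#' statistic signed like the bias (`mean(other) - mean(p1)`), so a negative
#' t means the receiving side rated lower. Pooled variance is the default,
#' matching the degrees of freedom convention of classic between-phase
#' comparisons; `var_equal = FALSE` gives the variance-robust Welch test,
#' appropriate when the two sides are aggregated at different levels (e.g.
#' per-event P1 ratings against per-rater P2 means) and so have unequal
#' variances by construction.
#'
#' Aggregation is the caller's choice: pass raw values, per-rater means, or
#' per-event means as the series.
#'
#' @param p1 Experiencer-side severities.
#' @param other Receiver-side severities (ratings or model predictions).
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#' @return A `bias_test`: `statistic`, `df`, `p_value` (two-sided),
#'   `estimate` (mean difference, other minus P1).
#' @export
calibration_test <- function(p1, other, var_equal = TRUE) {
  check_conditions(p1, other)
  x <- series_values(p1); y <- series_values(other)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 values on each side after aggregation")
  est <- mean(y) - mean(x)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (est == 0)
      return(new_bias_test(0, length(x) + length(y) - 2L, 1, 0, "calibration t test"))
    warning("zero variance on both sides with unequal means; t is infinite")
    return(new_bias_test(sign(est) * Inf, length(x) + length(y) - 2L, 0, est,
                         "calibration t test"))
  }
  tt <- safe_t_test(y, x, var_equal)
  if (is.null(tt)) {
    if (abs(est) < 1e-12)
      return(new_bias_test(0, length(x) + length(y) - 2L, 1, est, "calibration t test"))
    warning("near-zero variance on both sides with unequal means; t is infinite")
    return(new_bias_test(sign(est) * Inf, length(x) + length(y) - 2L, 0, est,
                         "calibration t test"))
  }
  new_bias_test(tt$statistic, tt$parameter, tt$p.value, est,
                if (var_equal) "calibration t test (pooled)" else "calibration t test (Welch)")
}

# t.test refuses essentially-constant data; return NULL so callers can
# resolve the degenerate case explicitly
safe_t_test <- function(a, b, var_equal) {
  tryCatch(stats::t.test(a, b, var.equal = var_equal), error = function(e) NULL)
}

#' Accuracy of one rater against the experiencers
#'
#' The accuracy bias is measured per rater as the Pearson correlation
#' between that rater's severity ratings and the P1 ratings of the same
#' events (lower r = larger bias). The same computation applies with the
#' model's predictions substituted for the rater's values.
#'
#' @param p2 The rater's severities: a numeric vector aligned with `p1`, or
#'   a data frame with columns `event` and `severity`.
#' @param p1 P1 severities, aligned vector or `event`/`severity` data frame
#'   (matched by event id).
#' @return The Pearson r over the rater's events.
#' @export
accuracy_per_rater <- function(p2, p1) {
  if (is.data.frame(p2) && is.data.frame(p1)) {
    m <- match(p2$event, p1$event)
    if (anyNA(m)) stop("some rated events have no P1 record")
    x <- p1$severity[m]; y <- p2$severity
  } else {
    x <- series_values(p1); y <- series_values(p2)
    if (length(x) != length(y)) stop("aligned numeric inputs must have equal length")
  }
  if (length(x) < 3L) stop("need at least 3 shared events to compute a correlation")
  pearson_r(x, y)
}

#' Per-rater accuracy correlations for a set of raters
#'
#' Splits the P2 records by rater and computes [accuracy_per_rater()] for
#' each; `values` substitutes model predictions (aligned with `p2_records`
#' rows) for the human ratings. Raters with a degenerate (zero-variance)
#' series are dropped with a warning.
#'
#' @param p2_records Data frame with columns `rater`, `event`, `severity`.
#' @param p1_records Data frame with columns `event`, `severity`.
#' @param values Optional replacement severities (e.g. MP2 predictions).
#' @return Named numeric vector of per-rater r values.
#' @export
accuracy_by_rater <- function(p2_records, p1_records, values = NULL) {
  stopifnot(all(c("rater", "event", "severity") %in% names(p2_records)))
  sev <- if (is.null(values)) p2_records$severity else as.numeric(values)
  stopifnot(length(sev) == nrow(p2_records))
  out <- vapply(split(seq_len(nrow(p2_records)), p2_records$rater), function(i) {
    tryCatch(accuracy_per_rater(
      data.frame(event = p2_records$event[i], severity = sev[i]),
      p1_records),
      error = function(e) NA_real_)
  }, 0.0)
  if (anyNA(out)) {
    warning(sprintf("%d rater(s) dropped: correlation undefined", sum(is.na(out))))
    out <- out[!is.na(out)]
  }
  out
}

#' Compare human and model accuracy correlations
#'
#' Two-sided independent two-sample t test on the per-rater correlation
#' values, statistic signed `mean(human) - mean(model)` (negative t: the
#' model ranks events more accurately than the raters). Raw r values are
#' compared by default; `fisher_z = TRUE` applies the variance-stabilizing
#' `atanh` transform first.
#'
#' @param human_rs,model_rs Numeric vectors of per-rater r values.
#' @param fisher_z Compare on the Fisher-z scale (default `FALSE`).
#' @param var_equal Pooled variance (default) or Welch.
#' @return A `bias_test`.
#' @export
accuracy_compare <- function(human_rs, model_rs, fisher_z = FALSE, var_equal = TRUE) {
  x <- as.numeric(human_rs); y <- as.numeric(model_rs)
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 r values per side")
  if (fisher_z) { x <- atanh(x); y <- atanh(y) }
  est <- mean(x) - mean(y)
  tt <- safe_t_test(x, y, var_equal)
  if (is.null(tt)) {
    if (abs(est) < 1e-12)
      return(new_bias_test(0, length(x) + length(y) - 2L, 1, est, "accuracy t test"))
    warning("near-zero variance on both sides with unequal means; t is infinite")
    return(new_bias_test(sign(est) * Inf, length(x) + length(y) - 2L, 0, est, "accuracy t test"))
  }
  new_bias_test(tt$statistic, tt$parameter, tt$p.value, est, "accuracy t test")
}

#' Build the condition-by-condition bias report
#'
#' The machine twin of the study's summary table: for the combined,
#' psychological, and physical conditions it reports the number of rated
#' texts, the correlations r(P1, P2), r(P1, MP1), r(P1, MP2), means (SDs)
#' of P1, P2 and MP2 severities, the human calibration bias (mean P2 minus
#' mean P1) and the computational bias (mean MP2 minus mean P1), plus three
#' significance tests per condition: the human calibration test (per-event
#' P1 ratings vs per-rater P2 means, pooled t), the model calibration test
#' (per-event P1 ratings vs per-event mean MP2 predictions), and the
#' accuracy comparison (per-rater human r vs per-rater model r).
#'
#' @param dataset A [study_dataset][generate_study()] (or a list with `p1`
#'   and `p2` data frames of the same shape).
#' @param mp1 Model-predicted severities for the P1 records (aligned with
#'   `dataset$p1` rows), or `NULL` for a partial report.
#' @param mp2 Model-predicted severities for the P2 records (aligned with
#'   `dataset$p2` rows; typically out-of-fold predictions), or `NULL`.
#' @param var_equal Pooled (default) or Welch calibration tests.
#' @return An object of class `bias_report`: `table` (one row per
#'   condition) and `tests` (per-condition list of `bias_test`s). Missing
#'   model predictions leave explicit `NA` gaps.
#' @export
build_bias_report <- function(dataset, mp1 = NULL, mp2 = NULL, var_equal = TRUE) {
  p1 <- dataset$p1; p2 <- dataset$p2
  stopifnot(all(c("event", "condition", "severity") %in% names(p1)),
            all(c("rater", "event", "condition", "severity") %in% names(p2)))
  if (!is.null(mp1)) stopifnot(length(mp1) == nrow(p1))
  if (!is.null(mp2)) stopifnot(length(mp2) == nrow(p2))
  conditions <- c("both", "psychological", "physical")
  rows <- list(); tests <- list()
  for (cond in conditions) {
    i1 <- if (cond == "both") seq_len(nrow(p1)) else which(p1$condition == cond)
    i2 <- if (cond == "both") seq_len(nrow(p2)) else which(p2$condition == cond)
    p1c <- p1[i1, ]; p2c <- p2[i2, ]
    m <- match(p2c$event, p1c$event)
    if (anyNA(m)) stop(sprintf("P2 events without a P1 record in condition %s", cond))
    x <- p1c$severity[m]
    mp1c <- if (is.null(mp1)) NULL else mp1[i1]
    mp2c <- if (is.null(mp2)) NULL else mp2[i2]
    row <- data.frame(
      condition = cond,
      n_points = nrow(p2c),
      r_p1_p2 = stats::cor(x, p2c$severity),
      r_p1_mp1 = if (is.null(mp1c)) NA_real_ else stats::cor(p1c$severity, mp1c),
      r_p1_mp2 = if (is.null(mp2c)) NA_real_ else stats::cor(x, mp2c),
      mean_p1 = mean(p1c$severity), sd_p1 = stats::sd(p1c$severity),
      mean_p2 = mean(p2c$severity), sd_p2 = stats::sd(p2c$severity),
      mean_mp2 = if (is.null(mp2c)) NA_real_ else mean(mp2c),
      sd_mp2 = if (is.null(mp2c)) NA_real_ else stats::sd(mp2c),
      stringsAsFactors = FALSE)
    row$human_bias <- row$mean_p2 - row$mean_p1
    row$computational_bias <- row$mean_mp2 - row$mean_p1
    rater_means <- vapply(split(p2c$severity, p2c$rater), mean, 0.0)
    ctests <- list(human_calibration = calibration_test(p1c$severity, rater_means,
                                                        var_equal = var_equal))
    if (!is.null(mp2c)) {
      event_mp2 <- vapply(split(mp2c, p2c$event), mean, 0.0)
      ctests$model_calibration <- calibration_test(p1c$severity, event_mp2,
                                                   var_equal = var_equal)
      human_rs <- accuracy_by_rater(p2c, p1c)
      model_rs <- accuracy_by_rater(p2c, p1c, values = mp2c)
      ctests$accuracy <- accuracy_compare(human_rs, model_rs)
      ctests$mean_human_r <- mean(human_rs)
      ctests$mean_model_r <- mean(model_rs)
    }
    for (nm in c("human_calibration", "model_calibration", "accuracy")) {
      tst <- ctests[[nm]]
      pre <- c(human_calibration = "human", model_calibration = "model",
               accuracy = "accuracy")[[nm]]
      row[[paste0(pre, "_t")]] <- if (is.null(tst)) NA_real_ else tst$statistic
      row[[paste0(pre, "_df")]] <- if (is.null(tst)) NA_real_ else tst$df
      row[[paste0(pre, "_p")]] <- if (is.null(tst)) NA_real_ else tst$p_value
    }
    rows[[cond]] <- row
    tests[[cond]] <- ctests
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 tests = tests),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, digits = 2, ...) {
  cat("<bias_report> severity of violence: humans vs the computational model\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab[, c("condition", "n_points", "r_p1_p2", "r_p1_mp1", "r_p1_mp2",
                "mean_p1", "mean_p2", "mean_mp2", "human_bias", "computational_bias")],
        row.names = FALSE)
  invisible(x)
}

#' Write a bias report to delimited and structured files
#'
#' @param report A [build_bias_report()] result.
#' @param table_path Tab-separated output mirroring the summary table.
#' @param tests_path Optional JSON file with the full test results.
#' @return `table_path`, invisibly.
#' @export
write_bias_report <- function(report, table_path, tests_path = NULL) {
  stopifnot(inherits(report, "bias_report"))
  utils::write.table(report$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tests_path)) {
    flat <- lapply(report$tests, function(ct) lapply(ct, function(t)
      if (inherits(t, "bias_test")) unclass(t) else t))
    jsonlite::write_json(flat, tests_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(table_path)
}
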