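#' Configuration of the synthetic two-phase severity study
#'
#' Defines the generative model that stands in for the (non-deposited)
#' two-phase IPV study data. Per condition `c`, each event carries a latent
#' severity `s_e ~ Normal(mu_c, sigma_c)`. Phase-1 experiencers rate
#' `round(clip(s_e + Normal(0, sigma_p1)))` on the 0--10 instrument. Phase-2
#' readers receive the event through text only; their rating is
#' `round(clip(mu_c + delta_c + sensitivity_c * (s_e - mu_c) + gamma_r +
#' Normal(0, sigma_p2_c)))`, where `delta_c` is the condition's calibration
#' shift, `gamma_r ~ Normal(0, rater_sd)` a per-rater offset, and
#' `sensitivity_c <= 1` the regression of communicated severity toward the
#' scale mean (sensitivity 1 recovers a purely additive reader model).
#' Keywords are drawn from disjoint severity-binned, condition-specific
#' vocabularies at the *perceived* severity `s_e + Normal(0, channel
#' noise)`, which is what makes severity linearly decodable from embeddings.
#'
#' Latent means/SDs and calibration shifts default to the reference
#' condition summaries ([reference_summary()]): psychological 6.46 (1.69)
#' with shift -0.61, physical 6.59 (1.81) with shift +0.95. The noise and
#' sensitivity defaults are fixed analytic choices that place per-rater
#' human accuracy near r^2 of 0.05 (psychological) and 0.2 (physical), the
#' regime the package is designed to study; the derivation is in the
#' methods vignette.
#'
#' @param n_events_per_condition Events (source texts) per condition.
#' @param n_p2_raters Phase-2 raters, split evenly between conditions
#'   (must be even); each rates every event of one condition.
#' @param keywords_per_response Keywords per response (default 5).
#' @param conditions Condition labels (fixed order).
#' @param mu,sigma Latent severity mean/SD per condition.
#' @param delta Calibration shift per condition (P2 minus P1 scale).
#' @param sensitivity Reader sensitivity (slope on centered latent
#'   severity) per condition.
#' @param sigma_p2 Reader rating noise SD per condition.
#' @param sigma_p1 Experiencer rating noise SD.
#' @param rater_sd SD of per-rater offsets.
#' @param channel_noise_p1,channel_noise_p2 SD of the keyword-channel
#'   perception noise for P1 / P2 keyword selection.
#' @param filler_prob Probability that a keyword slot is a shared filler
#'   word instead of a severity-bin word.
#' @param n_severity_bins Number of severity bins spanning the 0--10 scale.
#' @param words_per_bin Vocabulary words per (condition, bin) set.
#' @param n_filler_words Shared filler vocabulary size.
#' @param rating_min,rating_max Bounds of the rating instrument.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_events_per_condition = 68L,
                         n_p2_raters = 40L,
                         keywords_per_response = 5L,
                         conditions = c("psychological", "physical"),
                         mu = c(6.46, 6.59),
                         sigma = c(1.69, 1.81),
                         delta = c(-0.61, 0.95),
                         sensitivity = c(0.32, 0.50),
                         sigma_p2 = c(2.2, 1.6),
                         sigma_p1 = 0.5,
                         rater_sd = 0.5,
                         channel_noise_p1 = 0.4,
                         channel_noise_p2 = 0.8,
                         filler_prob = 0.2,
                         n_severity_bins = 11L,
                         words_per_bin = 8L,
                         n_filler_words = 40L,
                         rating_min = 0, rating_max = 10,
                         seed = 1L) {
  nc <- length(conditions)
  stopifnot(nc >= 1L, !anyDuplicated(conditions),
            length(mu) == nc, length(sigma) == nc, length(delta) == nc,
            length(sensitivity) == nc, length(sigma_p2) == nc)
  if (!is_count(n_events_per_condition) || !is_count(n_p2_raters) ||
      !is_count(keywords_per_response) || !is_count(words_per_bin) ||
      !(is_count(n_filler_words) || n_filler_words == 0))
    stop("counts in study_config must be positive integers")
  if (n_p2_raters %% nc != 0L)
    stop("n_p2_raters must split evenly across conditions")
  if (any(c(sigma, sigma_p2, sigma_p1, rater_sd,
            channel_noise_p1, channel_noise_p2) < 0))
    stop("all SDs must be non-negative")
  if (any(sensitivity <= 0)) stop("sensitivity must be positive")
  if (filler_prob < 0 || filler_prob >= 1) stop("filler_prob must lie in [0, 1)")
  if (!is_count(n_severity_bins) || n_severity_bins < 2L)
    stop("n_severity_bins must be an integer >= 2")
  if (rating_max <= rating_min) stop("rating_max must exceed rating_min")
  structure(list(n_events_per_condition = as.integer(n_events_per_condition),
                 n_p2_raters = as.integer(n_p2_raters),
                 keywords_per_response = as.integer(keywords_per_response),
                 conditions = as.character(conditions),
                 mu = mu, sigma = sigma, delta = delta,
                 sensitivity = sensitivity, sigma_p2 = sigma_p2,
                 sigma_p1 = sigma_p1, rater_sd = rater_sd,
                 channel_noise_p1 = channel_noise_p1,
                 channel_noise_p2 = channel_noise_p2,
                 filler_prob = filler_prob,
                 n_severity_bins = as.integer(n_severity_bins),
                 words_per_bin = as.integer(words_per_bin),
                 n_filler_words = as.integer(n_filler_words),
                 rating_min = rating_min, rating_max = rating_max,
                 seed = as.integer(seed)),
            class = "study_config")
}

# severity (on the rating scale) -> bin index in 0..(n_bins-1)
severity_bin <- function(config, severity) {
  s <- clip(severity, config$rating_min, config$rating_max)
  frac <- (s - config$rating_min) / (config$rating_max - config$rating_min)
  as.integer(round(frac * (config$n_severity_bins - 1L)))
}

#' Build the severity-tagged synthetic vocabulary
#'
#' Constructs disjoint word sets for every (condition, severity bin) pair
#' plus a shared filler set. Word strings encode their tags, so bin
#' membership is recoverable by construction; the vocabulary is
#' deterministic given the config.
#'
#' @param config A [study_config()].
#' @return A data frame `word`, `condition` (`"shared"` for fillers), `bin`
#'   (0-based bin index, `NA` for fillers), of class `study_vocabulary`.
#' @export
build_vocabulary <- function(config) {
  stopifnot(inherits(config, "study_config"))
  nb <- config$n_severity_bins
  rows <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    tag <- substr(cond, 1L, 4L)
    for (b in seq_len(nb) - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        word = sprintf("%s_s%02d_w%02d", tag, b, seq_len(config$words_per_bin)),
        condition = cond, bin = b, stringsAsFactors = FALSE)
    }
  }
  if (config$n_filler_words > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      word = sprintf("shared_w%02d", seq_len(config$n_filler_words)),
      condition = "shared", bin = NA_integer_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_vocabulary", "data.frame")
  out
}

#' Generate a synthetic n-gram corpus over the study vocabulary
#'
#' Emits 5-grams in which words of the same (condition, severity bin) set
#' co-occur preferentially, so that the semantic space built from the
#' corpus places same-bin words close together. Each gram is assigned to a
#' cluster (a bin set, or the filler set); each token slot draws from that
#' cluster with probability `1 - mixing` and from the full vocabulary
#' otherwise. Deterministic given the config seed.
#'
#' @param vocabulary A [build_vocabulary()] table.
#' @param config A [study_config()].
#' @param n_grams Number of 5-grams to draw (duplicates are aggregated into
#'   counts).
#' @param mixing Probability a slot escapes its cluster (default 0.05;
#'   0 gives bin-pure grams).
#' @param n Tokens per gram (default 5).
#' @return An [ngram_set()].
#' @export
generate_corpus <- function(vocabulary, config, n_grams = 4000L, mixing = 0.05,
                            n = 5L) {
  stopifnot(inherits(config, "study_config"), is_count(n_grams), is_count(n))
  if (mixing < 0 || mixing > 1) stop("mixing must lie in [0, 1]")
  key <- ifelse(is.na(vocabulary$bin), "shared",
                paste(vocabulary$condition, vocabulary$bin, sep = ":"))
  clusters <- split(vocabulary$word, key)
  all_words <- vocabulary$word
  with_seed(derive_seed(config$seed, 101L), {
    cl <- sample.int(length(clusters), n_grams, replace = TRUE)
    toks <- matrix(NA_character_, n_grams, n)
    for (g in seq_along(clusters)) {
      rows <- which(cl == g)
      if (!length(rows)) next
      pool <- clusters[[g]]
      toks[rows, ] <- pool[sample.int(length(pool), length(rows) * n, replace = TRUE)]
    }
    esc <- matrix(stats::runif(n_grams * n) < mixing, n_grams, n)
    if (any(esc))
      toks[esc] <- all_words[sample.int(length(all_words), sum(esc), replace = TRUE)]
  })
  key <- apply(toks, 1L, paste, collapse = " ")
  agg <- table(key)
  tokens <- matrix(unlist(strsplit(names(agg), " ", fixed = TRUE)),
                   ncol = n, byrow = TRUE)
  ngram_set(tokens, as.numeric(agg))
}

draw_keywords <- function(config, vocab_by, condition, perceived, k) {
  n <- length(perceived)
  bins <- severity_bin(config, perceived)
  pools <- vocab_by[[condition]] # matrix: n_bins x words_per_bin
  idx <- matrix(sample.int(config$words_per_bin, n * k, replace = TRUE), n, k)
  words <- matrix(pools[cbind(rep(bins + 1L, k), as.vector(idx))], n, k)
  if (config$filler_prob > 0 && config$n_filler_words > 0L) {
    fill <- matrix(stats::runif(n * k) < config$filler_prob, n, k)
    if (any(fill))
      words[fill] <- sprintf("shared_w%02d",
                             sample.int(config$n_filler_words, sum(fill), replace = TRUE))
  }
  colnames(words) <- paste0("word", seq_len(k))
  list(words = words, bins = bins)
}

#' Generate a synthetic two-phase study dataset
#'
#' Draws the full study described in [study_config()]: latent per-event
#' severities, phase-1 ratings and keywords by the experiencers, and
#' phase-2 ratings and keywords by readers who each rate every event of
#' exactly one condition. All ratings are drawn before any keywords, so
#' `keywords = FALSE` (a fast ratings-only study) yields bit-identical
#' ratings. The generating truth (latent severities, perceived severity
#' bins, planted shifts) is retained for oracle checks.
#'
#' @param config A [study_config()].
#' @param keywords Draw keyword responses (default `TRUE`).
#' @param vocabulary Optional pre-built [build_vocabulary()] table.
#' @return An object of class `study_dataset`: `p1` (event, condition,
#'   participant, severity, word1..wordK), `p2` (rater, event, condition,
#'   severity, word1..wordK), and `truth` (events with latent severities,
#'   per-record perceived bins, planted `delta`, the config).
#' @export
generate_study <- function(config = study_config(), keywords = TRUE,
                           vocabulary = NULL) {
  stopifnot(inherits(config, "study_config"))
  nc <- length(config$conditions)
  ne <- config$n_events_per_condition
  rpc <- config$n_p2_raters %/% nc
  vocab_by <- NULL
  if (keywords) {
    vocabulary <- vocabulary %||% build_vocabulary(config)
    vocab_by <- lapply(stats::setNames(nm = config$conditions), function(cond) {
      v <- vocabulary[vocabulary$condition == cond & !is.na(vocabulary$bin), ]
      v <- v[order(v$bin, v$word, method = "radix"), ]
      matrix(v$word, nrow = config$n_severity_bins, byrow = TRUE)
    })
  }
  rate <- function(x) round(clip(x, config$rating_min, config$rating_max))
  with_seed(config$seed, {
    # --- ratings first (keyword draws must not perturb them) ---
    latent <- p1sev <- vector("list", nc)
    for (ci in seq_len(nc)) {
      latent[[ci]] <- stats::rnorm(ne, config$mu[ci], config$sigma[ci])
      p1sev[[ci]] <- rate(latent[[ci]] + stats::rnorm(ne, 0, config$sigma_p1))
    }
    gamma <- stats::rnorm(config$n_p2_raters, 0, config$rater_sd)
    p2sev <- vector("list", nc)
    for (ci in seq_len(nc)) {
      raters <- (ci - 1L) * rpc + seq_len(rpc)
      base <- config$mu[ci] + config$delta[ci] +
        config$sensitivity[ci] * (latent[[ci]] - config$mu[ci])
      # one row per (rater, event)
      m <- outer(gamma[raters], base, `+`) +
        matrix(stats::rnorm(rpc * ne, 0, config$sigma_p2[ci]), rpc, ne)
      p2sev[[ci]] <- rate(m)
    }
    # --- keywords second ---
    p1_kw <- p2_kw <- vector("list", nc)
    if (keywords) {
      k <- config$keywords_per_response
      for (ci in seq_len(nc)) {
        perceived <- latent[[ci]] + stats::rnorm(ne, 0, config$channel_noise_p1)
        p1_kw[[ci]] <- draw_keywords(config, vocab_by, config$conditions[ci],
                                     perceived, k)
      }
      for (ci in seq_len(nc)) {
        nrec <- rpc * ne
        perceived <- rep(latent[[ci]], each = rpc) +
          stats::rnorm(nrec, 0, config$channel_noise_p2)
        p2_kw[[ci]] <- draw_keywords(config, vocab_by, config$conditions[ci],
                                     perceived, k)
      }
    }
  })
  # --- assemble tables ---
  p1 <- p2 <- events <- vector("list", nc)
  p2_bins <- vector("list", nc)
  for (ci in seq_len(nc)) {
    cond <- config$conditions[ci]
    ev <- sprintf("%s_%03d", cond, seq_len(ne))
    events[[ci]] <- data.frame(event = ev, condition = cond,
                               latent = latent[[ci]], stringsAsFactors = FALSE)
    p1df <- data.frame(event = ev, condition = cond,
                       participant = sprintf("p1_%03d", seq_len(ne)),
                       severity = p1sev[[ci]], stringsAsFactors = FALSE)
    raters <- (ci - 1L) * rpc + seq_len(rpc)
    p2df <- data.frame(rater = sprintf("p2_r%02d", rep(raters, times = ne)),
                       event = rep(ev, each = rpc),
                       condition = cond,
                       severity = as.vector(p2sev[[ci]]),
                       stringsAsFactors = FALSE)
    if (keywords) {
      p1df <- cbind(p1df, as.data.frame(p1_kw[[ci]]$words, stringsAsFactors = FALSE))
      # p2_kw rows are event-major with rater fastest, matching p2df
      p2df <- cbind(p2df, as.data.frame(p2_kw[[ci]]$words, stringsAsFactors = FALSE))
      p2_bins[[ci]] <- p2_kw[[ci]]$bins
    }
    p1[[ci]] <- p1df; p2[[ci]] <- p2df
  }
  truth <- list(events = do.call(rbind, events),
                delta = stats::setNames(config$delta, config$conditions),
                p1_bins = if (keywords) unlist(lapply(p1_kw, `[[`, "bins")) else NULL,
                p2_bins = if (keywords) unlist(p2_bins) else NULL,
                config = config)
  structure(list(p1 = do.call(rbind, p1), p2 = do.call(rbind, p2), truth = truth),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d P1 events, %d P2 ratings by %d raters (%s)\n",
              nrow(x$p1), nrow(x$p2), length(unique(x$p2$rater)),
              paste(unique(x$p1$condition), collapse = " + ")))
  invisible(x)
}

#' Decodable signal fraction of a generated study
#'
#' The fraction of P2 rating variance explained by the true (condition,
#' perceived severity bin) cell of each response -- the between-cell eta
#' squared. Since keyword sets are determined by exactly that cell, this is
#' the ceiling any embedding-based predictor of P2 ratings can reach, and
#' the benchmark the cross-validated r^2 is compared against.
#'
#' @param dataset A [generate_study()] result with keywords.
#' @return A single number in \[0, 1\].
#' @export
signal_variance_fraction <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(dataset$truth$p2_bins))
    stop("dataset was generated without keywords; no perceived bins retained")
  y <- dataset$p2$severity
  g <- paste(dataset$p2$condition, dataset$truth$p2_bins)
  gm <- stats::ave(y, g)
  sum((gm - mean(y))^2) / sum((y - mean(y))^2)
}

#' Write / read a study dataset as a delimited keyword table
#'
#' One combined tab-separated table with columns `phase`, `participant_id`,
#' `event_id`, `condition`, `word1..wordK`, `severity`. `read_study()`
#' reconstructs the dataset (without generating truth).
#'
#' @param dataset A `study_dataset`.
#' @param path Output file.
#' @return `path` invisibly, or for `read_study()` a `study_dataset` with
#'   `truth = NULL`.
#' @export
write_study <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  wcols <- grep("^word[0-9]+$", names(dataset$p1), value = TRUE)
  mk <- function(df, phase, idcol) {
    out <- data.frame(phase = phase, participant_id = df[[idcol]],
                      event_id = df$event, condition = df$condition,
                      stringsAsFactors = FALSE)
    for (w in wcols) out[[w]] <- df[[w]]
    out$severity <- df$severity
    out
  }
  combined <- rbind(mk(dataset$p1, "P1", "participant"),
                    mk(dataset$p2, "P2", "rater"))
  utils::write.table(combined, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phase", "participant_id", "event_id", "condition", "severity")
  if (!all(need %in% names(tab)))
    stop("study table must have columns phase, participant_id, event_id, condition, word*, severity")
  wcols <- grep("^word[0-9]+$", names(tab), value = TRUE)
  mk <- function(df, idcol) {
    out <- data.frame(event = df$event_id, condition = df$condition,
                      severity = df$severity, stringsAsFactors = FALSE)
    out[[idcol]] <- df$participant_id
    for (w in wcols) out[[w]] <- as.character(df[[w]])
    out
  }
  p1 <- mk(tab[tab$phase == "P1", ], "participant")
  p2 <- mk(tab[tab$phase == "P2", ], "rater")
  structure(list(p1 = p1, p2 = p2, truth = NULL), class = "study_dataset")
}
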