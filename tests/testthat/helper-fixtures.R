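# Shared helpers: fixture loaders, a minimal corpus builder that goes
# through the CSV layer, and the definitional step-up oracle.

fixture_corpus <- function(name, ...) {
  read_corpus(nhanesaudit_example(name), ...)
}

fixture_calendar <- function() {
  read_calendar(nhanesaudit_example("nhanes_calendar.csv"))
}

corpus_csv_cols <- c(
  "study_id", "pub_year", "predictor", "outcome",
  "p_reported", "or", "ci_low", "ci_high",
  "window_start", "window_end", "variable_key",
  "cohort", "journal", "affiliation_country"
)

# Build a corpus by writing a schema-complete CSV and reading it back,
# so tests exercise the same path users do.
toy_corpus <- function(..., schema_strict = TRUE) {
  rows <- list(...)
  tbl <- do.call(rbind, lapply(rows, function(r) {
    full <- stats::setNames(as.list(rep(NA, length(corpus_csv_cols))), corpus_csv_cols)
    full[names(r)] <- r
    as.data.frame(full, stringsAsFactors = FALSE)
  }))
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  read_corpus(path, schema_strict = schema_strict)
}

toy_row <- function(study_id, predictor, outcome, p_reported = "0.01", ...) {
  c(
    list(
      study_id = study_id, pub_year = 2024, predictor = predictor,
      outcome = outcome, p_reported = p_reported
    ),
    list(...)
  )
}

# Definitional step-up oracle: adjusted p at rank k is the minimum over
# ranks j >= k of m * c(m) * p(j) / j, capped at 1, mapped to input order.
oracle_stepup <- function(p, method = "BY", m = length(p)) {
  c_m <- if (method == "BY") sum(1 / seq_len(m)) else 1
  ord <- order(p)
  ps <- p[ord]
  n <- length(p)
  adj_sorted <- numeric(n)
  for (k in seq_len(n)) {
    adj_sorted[k] <- min(1, min(m * c_m * ps[k:n] / (k:n)))
  }
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}
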