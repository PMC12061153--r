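#' Corpus data model and CSV input/output
#'
#' A corpus is one row per published association study. The CSV schema has
#' exactly these columns: `study_id`, `pub_year`, `predictor`, `outcome`,
#' `p_reported`, `or`, `ci_low`, `ci_high`, `window_start`, `window_end`,
#' `variable_key`, `cohort`, `journal`, `affiliation_country`.
#'
#' Significance evidence is carried in one of two forms: a reported
#' p-value in `p_reported` (either a plain number such as `"0.039"` or a
#' censored bound such as `"<0.001"`), or an odds ratio with a confidence
#' interval in `or`/`ci_low`/`ci_high`. A record may carry at most one
#' form; records with neither (e.g., studies catalogued only for their
#' analyzed window) are accepted and flagged via [has_evidence()].
#'
#' @name corpus
NULL

corpus_columns <- c(
  "study_id", "pub_year", "predictor", "outcome",
  "p_reported", "or", "ci_low", "ci_high",
  "window_start", "window_end", "variable_key",
  "cohort", "journal", "affiliation_country"
)

corpus_col_types <- readr::cols(
  study_id = readr::col_character(),
  pub_year = readr::col_integer(),
  predictor = readr::col_character(),
  outcome = readr::col_character(),
  p_reported = readr::col_character(),
  or = readr::col_double(),
  ci_low = readr::col_double(),
  ci_high = readr::col_double(),
  window_start = readr::col_integer(),
  window_end = readr::col_integer(),
  variable_key = readr::col_character(),
  cohort = readr::col_character(),
  journal = readr::col_character(),
  affiliation_country = readr::col_character()
)

new_corpus <- function(tbl, provenance = NA_character_) {
  stopifnot(is.data.frame(tbl))
  tbl <- tibble::as_tibble(tbl)
  structure(tbl,
    provenance = provenance,
    class = c("corpus", class(tbl))
  )
}

#' @rdname corpus
#' @param x Object to test.
#' @export
is_corpus <- function(x) inherits(x, "corpus")

#' Parse a printed p-value field
#'
#' Accepts `"0.039"` or a censored form `"<0.001"`. Returns the numeric
#' value and whether it is an upper bound.
#'
#' @param x Character vector as printed in the source table.
#' @return A tibble with columns `value` and `is_upper_bound`.
#' @export
parse_reported_p <- function(x) {
  x <- trimws(as.character(x))
  bound <- startsWith(x, "<")
  num <- suppressWarnings(as.numeric(ifelse(bound, substring(x, 2), x)))
  bad <- !is.na(x) & x != "" & is.na(num)
  if (any(bad)) {
    stop("unparseable p-value(s): ", paste(unique(x[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  ok <- !is.na(num)
  if (any(ok & (num <= 0 | num > 1))) {
    stop("reported p-values must lie in (0, 1]", call. = FALSE)
  }
  tibble::tibble(value = num, is_upper_bound = bound & ok)
}

# Per-row validation. Returns a tibble of problems (row, study_id, message);
# zero rows means the corpus is valid.
corpus_problems <- function(tbl, synonyms = NULL) {
  probs <- list()
  note <- function(rows, msg) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = rows, study_id = tbl$study_id[rows], message = msg
      )
    }
  }

  note(which(is.na(tbl$study_id) | tbl$study_id == ""), "missing study_id")
  note(which(duplicated(tbl$study_id) & !is.na(tbl$study_id)), "duplicate study_id")

  has_p <- !is.na(tbl$p_reported) & tbl$p_reported != ""
  has_or <- !is.na(tbl$or) | !is.na(tbl$ci_low) | !is.na(tbl$ci_high)
  or_complete <- !is.na(tbl$or) & !is.na(tbl$ci_low) & !is.na(tbl$ci_high)
  note(which(has_p & has_or), "both evidence forms populated")
  note(which(has_or & !or_complete), "incomplete or/ci_low/ci_high group")

  p_bad <- rep(FALSE, nrow(tbl))
  for (i in which(has_p)) {
    res <- tryCatch(parse_reported_p(tbl$p_reported[i]), error = function(e) NULL)
    if (is.null(res)) p_bad[i] <- TRUE
  }
  note(which(p_bad), "unparseable p_reported (expect a number or '<number')")

  ok_or <- which(or_complete & !has_p)
  bad_dom <- ok_or[tbl$or[ok_or] <= 0 | tbl$ci_low[ok_or] <= 0 | tbl$ci_high[ok_or] <= 0]
  note(bad_dom, "odds ratio and CI bounds must be positive")
  bad_ord <- setdiff(ok_or, bad_dom)
  bad_ord <- bad_ord[!(tbl$ci_low[bad_ord] <= tbl$or[bad_ord] &
    tbl$or[bad_ord] <= tbl$ci_high[bad_ord])]
  note(bad_ord, "CI does not bracket the odds ratio (need ci_low <= or <= ci_high)")

  note(which(is.na(tbl$predictor) | trimws(tbl$predictor) == ""), "missing predictor")
  note(which(is.na(tbl$outcome) | trimws(tbl$outcome) == ""), "missing outcome")
  lab_ok <- !is.na(tbl$predictor) & trimws(tbl$predictor) != "" &
    !is.na(tbl$outcome) & trimws(tbl$outcome) != ""
  same <- which(lab_ok &
    normalize_label(ifelse(lab_ok, tbl$predictor, "x"), synonyms) ==
      normalize_label(ifelse(lab_ok, tbl$outcome, "y"), synonyms))
  note(same, "predictor and outcome are the same label after normalization")

  half_win <- xor(is.na(tbl$window_start), is.na(tbl$window_end))
  note(which(half_win), "window_start/window_end must both be present or both absent")
  win <- which(!is.na(tbl$window_start) & !is.na(tbl$window_end))
  note(win[tbl$window_start[win] > tbl$window_end[win]], "window_start > window_end")

  if (length(probs)) dplyr::arrange(dplyr::bind_rows(probs), .data$row) else {
    tibble::tibble(row = integer(), study_id = character(), message = character())
  }
}

#' Read a study corpus from CSV
#'
#' Reads and validates a corpus table. In strict mode (the default) any
#' invalid row aborts with row-number diagnostics; in lenient mode invalid
#' rows are dropped with a warning and the number skipped is recorded in
#' the `n_skipped` attribute.
#'
#' @param path Path to a corpus CSV with the documented schema.
#' @param schema_strict If `TRUE`, invalid rows are an error; if `FALSE`,
#'   they are skipped with a warning.
#' @param synonyms Optional named character vector mapping normalized
#'   labels to canonical labels, used during validation (see
#'   [normalize_label()]).
#' @return A `corpus`: a tibble with one row per study and a `provenance`
#'   attribute recording the source path.
#' @examples
#' tab2 <- read_corpus(nhanesaudit_example("table2_depression.csv"))
#' nrow(tab2)
#' @export
read_corpus <- function(path, schema_strict = TRUE, synonyms = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
    show_col_types = FALSE
  ))
  missing <- setdiff(corpus_columns, hdr)
  if (length(missing)) {
    stop("corpus schema error; missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- readr::read_csv(path, col_types = corpus_col_types, show_col_types = FALSE)
  tbl <- tbl[corpus_columns]

  probs <- corpus_problems(tbl, synonyms)
  n_skipped <- 0L
  if (nrow(probs)) {
    msg <- paste0("  row ", probs$row, " [", probs$study_id, "]: ", probs$message)
    if (schema_strict) {
      stop("invalid corpus rows:\n", paste(msg, collapse = "\n"), call. = FALSE)
    }
    drop <- unique(probs$row)
    warning(length(drop), " invalid row(s) skipped:\n",
      paste(msg, collapse = "\n"),
      call. = FALSE
    )
    n_skipped <- length(drop)
    tbl <- tbl[-drop, ]
  }
  out <- new_corpus(tbl, provenance = path)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a corpus back to CSV
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` is the
#' identity field-for-field on a valid corpus.
#'
#' @param corpus A `corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is_corpus(corpus))
  readr::write_csv(tibble::as_tibble(corpus)[corpus_columns], path, na = "")
  invisible(path)
}

#' Which records carry significance evidence?
#'
#' @param corpus A `corpus`.
#' @return Logical vector, `TRUE` where the record has either a reported
#'   p-value or a complete OR/CI triple.
#' @export
has_evidence <- function(corpus) {
  (!is.na(corpus$p_reported) & corpus$p_reported != "") |
    (!is.na(corpus$or) & !is.na(corpus$ci_low) & !is.na(corpus$ci_high))
}

#' Canonicalize a free-text variable label
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs
#' to single spaces, and case-folds to lower case; a user-supplied synonym
#' map is applied afterwards. The result is idempotent provided the
#' synonym map's values are themselves canonical.
#'
#' @param raw Character vector of labels.
#' @param synonyms Optional named character vector; names are matched
#'   against the normalized label and replaced by the corresponding value.
#' @return Character vector of canonical labels.
#' @examples
#' normalize_label("  Physical Activity ")
#' normalize_label("SII", synonyms = c(sii = "systemic immune-inflammation index"))
#' @export
normalize_label <- function(raw, synonyms = NULL) {
  if (any(is.na(raw) | trimws(raw) == "")) {
    stop("labels must be non-empty", call. = FALSE)
  }
  out <- tolower(gsub("\\s+", " ", trimws(raw)))
  if (!is.null(synonyms)) {
    if (is.null(names(synonyms)) || any(names(synonyms) == "")) {
      stop("synonym map must be a named character vector", call. = FALSE)
    }
    key <- tolower(gsub("\\s+", " ", trimws(names(synonyms))))
    hit <- match(out, key)
    out[!is.na(hit)] <- tolower(gsub("\\s+", " ", trimws(synonyms[hit[!is.na(hit)]])))
  }
  out
}
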