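#' Read a survey-cycle availability calendar
#'
#' The calendar maps each variable key to the survey-cycle spans in which
#' the variable was collected, together with the calendar year each span
#' was released to the public. Columns: `variable_key`, `span_start`,
#' `span_end`, `release_year`. Spans for a variable must be non-overlapping;
#' they are sorted on read. The packaged default
#' (`nhanesaudit_example("nhanes_calendar.csv")`) encodes one row per
#' released NHANES cycle (biennial 1999-2000 through 2015-2016, then the
#' combined pre-pandemic 2017-2020 release) and omits the 2021-2023 cycle,
#' which was released only in September 2024.
#'
#' @param path Calendar CSV path.
#' @return A `cycle_calendar` tibble.
#' @export
read_calendar <- function(path) {
  if (!file.exists(path)) stop("calendar file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path,
    col_types = readr::cols(
      variable_key = readr::col_character(),
      span_start = readr::col_integer(),
      span_end = readr::col_integer(),
      release_year = readr::col_integer()
    ), show_col_types = FALSE
  )
  need <- c("variable_key", "span_start", "span_end", "release_year")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop("calendar schema error; missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(tbl$variable_key) | is.na(tbl$span_start) | is.na(tbl$span_end))) {
    stop("calendar rows must have variable_key, span_start, span_end", call. = FALSE)
  }
  if (any(tbl$span_start > tbl$span_end)) {
    stop("calendar span_start > span_end", call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$variable_key, .data$span_start)
  overlap <- dplyr::group_by(tbl, .data$variable_key)
  overlap <- dplyr::summarise(overlap,
    bad = dplyr::n() > 1 && any(.data$span_start[-1] <= head(.data$span_end, -1))
  )
  if (any(overlap$bad)) {
    stop(
      "overlapping availability spans for: ",
      paste(overlap$variable_key[overlap$bad], collapse = ", "),
      call. = FALSE
    )
  }
  structure(tbl, class = c("cycle_calendar", class(tbl)))
}

#' Years of data available for a variable at publication time
#'
#' Returns the union of years in spans released strictly before the
#' publication year (`release_year < pub_year`): data released in the
#' same calendar year as publication are not assumed usable.
#'
#' @param calendar A `cycle_calendar`.
#' @param variable_key Variable key to look up.
#' @param pub_year Publication year used for truncation.
#' @return Sorted integer vector of available years (possibly empty).
#' @examples
#' cal <- read_calendar(nhanesaudit_example("nhanes_calendar.csv"))
#' range(available_years(cal, "DIQ", 2024))
#' @export
available_years <- function(calendar, variable_key, pub_year) {
  stopifnot(inherits(calendar, "cycle_calendar"))
  rows <- calendar[calendar$variable_key == variable_key, ]
  if (nrow(rows) == 0) {
    stop("unknown variable_key '", variable_key, "'; known keys: ",
      paste(sort(unique(calendar$variable_key)), collapse = ", "),
      call. = FALSE
    )
  }
  rows <- rows[!is.na(rows$release_year) & rows$release_year < pub_year, ]
  if (nrow(rows) == 0) {
    return(integer())
  }
  sort(unique(unlist(Map(seq.int, rows$span_start, rows$span_end))))
}

audit_one <- function(study_id, window_start, window_end, variable_key,
                      pub_year, calendar) {
  analyzed <- seq.int(window_start, window_end)
  available <- available_years(calendar, variable_key, pub_year)
  out_of_range <- setdiff(analyzed, available)
  missed <- setdiff(available, analyzed)
  coverage <- if (length(available)) {
    length(intersect(analyzed, available)) / length(available)
  } else {
    NA_real_
  }
  verdict <- if (length(out_of_range)) {
    "mismatch"
  } else if (length(missed) == 0) {
    "full"
  } else {
    "selective"
  }
  tibble::tibble(
    study_id = study_id, verdict = verdict, coverage = coverage,
    n_analyzed = length(analyzed), n_available = length(available),
    missed_years = paste(missed, collapse = ";"),
    out_of_range_years = paste(out_of_range, collapse = ";")
  )
}

#' Audit analyzed year windows against the availability calendar
#'
#' Classifies each study's analyzed window relative to the data available
#' for its variable at publication time: `full` when every available year
#' was analyzed, `selective` when a strict subset was (the pattern that,
#' absent stated justification, is suggestive of data dredging), and
#' `mismatch` when analyzed years fall outside availability altogether.
#' A `justified_subset` logical column in the corpus, if present, is
#' carried through as `justified` so flagged-but-justified records can be
#' reported separately.
#'
#' @param corpus A `corpus` whose records have `variable_key` and windows.
#' @param calendar A `cycle_calendar`.
#' @return A tibble with one row per record (corpus order): `study_id`,
#'   `verdict`, `coverage` (analyzed-and-available over available),
#'   `n_analyzed`, `n_available`, semicolon-joined `missed_years` and
#'   `out_of_range_years`, and `justified` if supplied.
#' @examples
#' sii <- read_corpus(nhanesaudit_example("table3_sii.csv"))
#' cal <- read_calendar(nhanesaudit_example("nhanes_calendar.csv"))
#' table(audit_windows(sii, cal)$verdict)
#' @export
audit_windows <- function(corpus, calendar) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0) {
    return(tibble::tibble(
      study_id = character(), verdict = character(), coverage = double(),
      n_analyzed = integer(), n_available = integer(),
      missed_years = character(), out_of_range_years = character()
    ))
  }
  ok <- !is.na(corpus$variable_key) & corpus$variable_key != "" &
    !is.na(corpus$window_start) & !is.na(corpus$window_end)
  if (!all(ok)) {
    stop("record(s) lacking variable_key or window: ",
      paste(corpus$study_id[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(corpus)), function(i) {
    audit_one(
      corpus$study_id[i], corpus$window_start[i], corpus$window_end[i],
      corpus$variable_key[i], corpus$pub_year[i], calendar
    )
  }))
  if ("justified_subset" %in% names(corpus)) {
    out$justified <- as.logical(corpus$justified_subset)
  }
  out
}

#' Tally of exact analyzed windows
#'
#' @param corpus A `corpus` with windows on every record.
#' @return Tibble `window_start`, `window_end`, `n`, sorted by count
#'   descending with deterministic (start, end) tie-break.
#' @export
window_popularity <- function(corpus) {
  stopifnot(is_corpus(corpus))
  if (any(is.na(corpus$window_start) | is.na(corpus$window_end))) {
    stop("all records must carry analyzed windows", call. = FALSE)
  }
  tbl <- dplyr::count(
    tibble::as_tibble(corpus)[c("window_start", "window_end")],
    .data$window_start, .data$window_end,
    name = "n"
  )
  dplyr::arrange(tbl, dplyr::desc(.data$n), .data$window_start, .data$window_end)
}

#' Median analyzed span, in years
#'
#' Span is inclusive: a 2013-2014 window is 2 years. Even-count medians
#' are the mean of the middle two.
#'
#' @param corpus A non-empty `corpus` with windows.
#' @return Median span in years.
#' @export
median_span <- function(corpus) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0) stop("empty corpus has no median span", call. = FALSE)
  if (any(is.na(corpus$window_start) | is.na(corpus$window_end))) {
    stop("all records must carry analyzed windows", call. = FALSE)
  }
  median(corpus$window_end - corpus$window_start + 1)
}

#' Paper-by-year membership matrix (UpSet input)
#'
#' @param corpus A `corpus` with windows.
#' @param years Column range of calendar years, default `1999:2020`.
#' @return Integer 0/1 matrix, rows in corpus order (rownames =
#'   `study_id`), one column per year; entry 1 iff the year lies in the
#'   record's analyzed window. Suitable as input to UpSet plotting tools.
#' @export
upset_membership <- function(corpus, years = 1999:2020) {
  stopifnot(is_corpus(corpus))
  mat <- matrix(0L, nrow(corpus), length(years),
    dimnames = list(corpus$study_id, as.character(years))
  )
  if (nrow(corpus)) {
    if (any(is.na(corpus$window_start) | is.na(corpus$window_end))) {
      stop("all records must carry analyzed windows", call. = FALSE)
    }
    for (i in seq_len(nrow(corpus))) {
      mat[i, years >= corpus$window_start[i] & years <= corpus$window_end[i]] <- 1L
    }
  }
  mat
}

#' Publication counts per calendar year
#'
#' @param corpus A `corpus`.
#' @return Tibble `year`, `n`, zero-filled over the min-max publication
#'   year range; zero rows for an empty corpus.
#' @export
annual_counts <- function(corpus) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0) {
    return(tibble::tibble(year = integer(), n = integer()))
  }
  yrs <- seq.int(min(corpus$pub_year), max(corpus$pub_year))
  tibble::tibble(
    year = yrs,
    n = vapply(yrs, function(y) sum(corpus$pub_year == y), integer(1))
  )
}

#' Share of publications from one affiliation country in a period
#'
#' @param corpus A `corpus` with `affiliation_country` populated.
#' @param country Country to match (normalized, case-insensitive).
#' @param period_start,period_end Inclusive publication-year range.
#' @return Named integer vector `c(numerator, denominator)`: matching
#'   records over all records published in the period.
#' @export
affiliation_period_share <- function(corpus, country, period_start, period_end) {
  stopifnot(is_corpus(corpus))
  in_period <- !is.na(corpus$pub_year) &
    corpus$pub_year >= period_start & corpus$pub_year <= period_end
  denom <- sum(in_period)
  aff <- corpus$affiliation_country[in_period]
  hit <- !is.na(aff) & aff != "" &
    normalize_label(ifelse(is.na(aff) | aff == "", "x", aff)) ==
      normalize_label(country)
  c(numerator = sum(hit), denominator = denom)
}
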