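#' Derive a two-sided p-value from an odds ratio and confidence interval
#'
#' Published odds ratios are converted to p-values on the log scale: the
#' standard error of the log odds ratio is recovered from the CI width,
#' \deqn{SE = (\ln U - \ln L) / (2 q),}{SE = (ln U - ln L) / (2 q),}
#' where \eqn{q} is the standard normal quantile at
#' \eqn{1 - (1 - \mathrm{level})/2} (1.959964 for a 95% CI); the z-score
#' is \eqn{z = \ln(OR)/SE} and the two-sided p-value
#' \eqn{p = 2 (1 - \Phi(|z|))}. Underflow is clamped to the smallest
#' positive double rather than returned as exact zero.
#'
#' @param odds_ratio Positive odds ratio(s).
#' @param ci_low,ci_high Positive confidence bounds with
#'   `ci_low <= odds_ratio <= ci_high` and `ci_low < ci_high` strictly.
#' @param ci_level Confidence level of the interval, default `0.95`.
#' @return A tibble with columns `log_or`, `se`, `z`, `p`.
#' @examples
#' p_from_or_ci(2.0, 1.5, 2.6667)
#' p_from_or_ci(1.0, 0.5, 2.0)$p # exactly 1
#' @export
p_from_or_ci <- function(odds_ratio, ci_low, ci_high, ci_level = 0.95) {
  n <- max(length(odds_ratio), length(ci_low), length(ci_high))
  odds_ratio <- rep_len(odds_ratio, n)
  ci_low <- rep_len(ci_low, n)
  ci_high <- rep_len(ci_high, n)
  if (length(ci_level) != 1 || is.na(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be a single value in (0, 1)", call. = FALSE)
  }
  if (any(is.na(odds_ratio) | is.na(ci_low) | is.na(ci_high))) {
    stop("odds_ratio, ci_low, ci_high must be non-missing", call. = FALSE)
  }
  if (any(odds_ratio <= 0 | ci_low <= 0 | ci_high <= 0)) {
    stop("odds_ratio and CI bounds must be positive", call. = FALSE)
  }
  if (any(ci_low == ci_high)) {
    stop("zero-width confidence interval; cannot recover a standard error",
      call. = FALSE
    )
  }
  if (any(ci_low > odds_ratio | odds_ratio > ci_high)) {
    stop("CI must bracket the odds ratio (ci_low <= or <= ci_high)", call. = FALSE)
  }
  q <- qnorm(1 - (1 - ci_level) / 2)
  log_or <- log(odds_ratio)
  se <- (log(ci_high) - log(ci_low)) / (2 * q)
  z <- log_or / se
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  tibble::tibble(log_or = log_or, se = se, z = z, p = p)
}

#' Resolve a reported (possibly censored) p-value to a number
#'
#' Plain values pass through unchanged. Censored entries printed as
#' `"<x"` are substituted under a stated convention: `at_bound` uses the
#' bound `x` itself (conservative for downstream survivor counts),
#' `half_bound` uses `x/2`.
#'
#' @param value Numeric p-value(s) in (0, 1].
#' @param is_upper_bound Logical; `TRUE` for entries printed as `"<value"`.
#' @param convention `"at_bound"` (default) or `"half_bound"`.
#' @return Numeric vector of resolved p-values.
#' @examples
#' resolve_p(0.039)
#' resolve_p(0.001, is_upper_bound = TRUE) # 0.001
#' resolve_p(0.001, is_upper_bound = TRUE, convention = "half_bound") # 5e-04
#' @export
resolve_p <- function(value, is_upper_bound = FALSE,
                      convention = c("at_bound", "half_bound")) {
  convention <- match.arg(convention)
  if (any(is.na(value) | value <= 0 | value > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  is_upper_bound <- rep_len(as.logical(is_upper_bound), length(value))
  ifelse(is_upper_bound & convention == "half_bound", value / 2, value)
}

#' Harmonize a corpus's evidence into one p-value per study
#'
#' Each record's evidence is converted to a single two-sided p-value:
#' reported p-values are taken as presented (censored entries resolved
#' under `convention`); OR/CI records go through [p_from_or_ci()]. Corpus
#' order is preserved and the `source` column records which path was
#' taken.
#'
#' @param corpus A `corpus` whose records all carry evidence
#'   (see [has_evidence()]).
#' @inheritParams resolve_p
#' @return A tibble with columns `study_id`, `p`, `source`
#'   (`"reported"` or `"derived_from_or_ci"`), `convention_applied`
#'   (`TRUE` where a censored bound was substituted), and `log_or`, `se`,
#'   `z` (`NA` for reported-p rows).
#' @examples
#' tab2 <- read_corpus(nhanesaudit_example("table2_depression.csv"))
#' h <- harmonize(tab2)
#' sum(h$p == 0.001) # the rows printed "<0.001"
#' @export
harmonize <- function(corpus, convention = c("at_bound", "half_bound")) {
  stopifnot(is_corpus(corpus))
  convention <- match.arg(convention)
  n <- nrow(corpus)
  if (n == 0) {
    return(tibble::tibble(
      study_id = character(), p = double(), source = character(),
      convention_applied = logical(), log_or = double(), se = double(),
      z = double()
    ))
  }
  ev <- has_evidence(corpus)
  if (!all(ev)) {
    stop("record(s) without evidence cannot be harmonized: ",
      paste(corpus$study_id[!ev], collapse = ", "),
      call. = FALSE
    )
  }
  has_p <- !is.na(corpus$p_reported) & corpus$p_reported != ""

  out <- tibble::tibble(
    study_id = corpus$study_id, p = NA_real_,
    source = ifelse(has_p, "reported", "derived_from_or_ci"),
    convention_applied = FALSE,
    log_or = NA_real_, se = NA_real_, z = NA_real_
  )
  if (any(has_p)) {
    parsed <- parse_reported_p(corpus$p_reported[has_p])
    out$p[has_p] <- withCallingHandlers(
      resolve_p(parsed$value, parsed$is_upper_bound, convention),
      error = function(e) {
        stop("while harmonizing reported p-values: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    out$convention_applied[has_p] <- parsed$is_upper_bound
  }
  if (any(!has_p)) {
    i <- which(!has_p)
    d <- tryCatch(
      p_from_or_ci(corpus$or[i], corpus$ci_low[i], corpus$ci_high[i]),
      error = function(e) {
        stop("while deriving p from OR/CI (studies ",
          paste(corpus$study_id[i], collapse = ", "), "): ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
    out$p[i] <- d$p
    out$log_or[i] <- d$log_or
    out$se[i] <- d$se
    out$z[i] <- d$z
  }
  out
}
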