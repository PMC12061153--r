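#' Harmonic partial sum
#'
#' \eqn{c(m) = \sum_{i=1}^m 1/i}, the correction constant that inflates
#' the Benjamini-Hochberg threshold in the Benjamini-Yekutieli procedure
#' (valid under arbitrary dependence among the test statistics).
#'
#' @param m Positive integer.
#' @return The harmonic sum, by direct summation.
#' @examples
#' harmonic_sum(2) # 1.5
#' @export
harmonic_sum <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != floor(m)) {
    stop("m must be a single integer >= 1", call. = FALSE)
  }
  sum(1 / seq_len(m))
}

#' Step-up false discovery rate adjustment
#'
#' From-first-principles implementation of the step-up FDR procedures:
#' p-values are sorted ascending (ties keep input order), candidate
#' adjusted values \eqn{m \, c(m) \, p_{(k)} / k} are formed at each rank
#' \eqn{k}, a cumulative minimum is taken from the largest rank downward,
#' and results are capped at 1 and mapped back to input order. `method =
#' "BY"` (Benjamini-Yekutieli) uses the harmonic constant
#' \eqn{c(m) = \sum_{i \le m} 1/i}; `"BH"` (Benjamini-Hochberg) is the
#' special case \eqn{c(m) = 1}.
#'
#' The number of hypotheses `m` defaults to the number of p-values
#' supplied, mirroring the choice of correcting a corpus of single-factor
#' studies jointly; it can be overridden when the true hypothesis count
#' is judged to be larger.
#'
#' @param p Numeric p-values in (0, 1].
#' @param method `"BY"` (default) or `"BH"`.
#' @param alpha Significance level; entries with adjusted p strictly
#'   below `alpha` are flagged significant.
#' @param ids Optional identifiers (default `"p1"`, `"p2"`, ...).
#' @param m Optional hypothesis-count override, `>= length(p)`.
#' @return An `adjustment_result`: a tibble in input order with columns
#'   `study_id`, `raw_p`, `rank`, `adjusted_p`, `significant`, and
#'   attributes `method`, `m`, `c_m`, `alpha`.
#' @examples
#' r <- fdr_adjust(c(0.001, 0.002, 0.03), method = "BY")
#' r$adjusted_p
#' count_significant(r)
#' @export
fdr_adjust <- function(p, method = c("BY", "BH"), alpha = 0.05, ids = NULL,
                       m = NULL) {
  method <- match.arg(method)
  if (length(p) < 1) stop("at least one p-value is required", call. = FALSE)
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  n <- length(p)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  if (length(ids) != n) stop("ids must match p in length", call. = FALSE)
  if (is.null(m)) m <- n
  if (m < n) stop("m override must be >= the number of p-values", call. = FALSE)

  c_m <- if (method == "BY") harmonic_sum(m) else 1
  ord <- order(p) # stable in base R: ties keep input order
  k <- seq_len(n)
  candidate <- m * c_m * p[ord] / k
  adjusted_sorted <- pmin(rev(cummin(rev(candidate))), 1)
  adjusted <- numeric(n)
  adjusted[ord] <- adjusted_sorted
  rank_of <- integer(n)
  rank_of[ord] <- k

  structure(
    tibble::tibble(
      study_id = as.character(ids), raw_p = p, rank = rank_of,
      adjusted_p = adjusted, significant = adjusted < alpha
    ),
    method = method, m = m, c_m = c_m, alpha = alpha,
    class = c("adjustment_result", class(tibble::tibble()))
  )
}

#' Count surviving associations
#'
#' @param result An `adjustment_result` from [fdr_adjust()].
#' @return Number of entries flagged significant after adjustment.
#' @export
count_significant <- function(result) {
  stopifnot(inherits(result, "adjustment_result"))
  sum(result$significant)
}

#' Group-wise FDR re-correction over a corpus
#'
#' Partitions a corpus by normalized outcome (or predictor) label and
#' applies [fdr_adjust()] within each group with `m` equal to the group
#' size — the joint correction a single research group investigating all
#' the group's predictors together would have applied. `group_key =
#' "none"` pools the whole corpus into one family.
#'
#' @param corpus A `corpus`.
#' @param harmonized Output of [harmonize()] for the same corpus.
#' @param group_key `"outcome"` (default), `"predictor"`, or `"none"`.
#' @param method,alpha Passed to [fdr_adjust()].
#' @param synonyms Optional synonym map for label normalization.
#' @return Named list of `adjustment_result`, one per group, names sorted;
#'   the pooled case uses the single name `"all"`.
#' @examples
#' tab2 <- read_corpus(nhanesaudit_example("table2_depression.csv"))
#' res <- group_adjust(tab2, harmonize(tab2))
#' count_significant(res$depression)
#' @export
group_adjust <- function(corpus, harmonized, group_key = c("outcome", "predictor", "none"),
                         method = c("BY", "BH"), alpha = 0.05, synonyms = NULL) {
  stopifnot(is_corpus(corpus))
  group_key <- match.arg(group_key)
  method <- match.arg(method)
  if (!identical(corpus$study_id, harmonized$study_id)) {
    stop("harmonized p-values do not match the corpus (study_id order)",
      call. = FALSE
    )
  }
  if (nrow(corpus) == 0) {
    return(stats::setNames(list(), character()))
  }
  key <- switch(group_key,
    outcome = normalize_label(corpus$outcome, synonyms),
    predictor = normalize_label(corpus$predictor, synonyms),
    none = rep("all", nrow(corpus))
  )
  groups <- split(seq_len(nrow(corpus)), key)
  lapply(groups[sort(names(groups))], function(i) {
    fdr_adjust(harmonized$p[i],
      method = method, alpha = alpha,
      ids = corpus$study_id[i]
    )
  })
}
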