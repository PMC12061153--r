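#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the study-generating process the audit assumes:
#' a bipartite corpus in which a few hub conditions attract many
#' single-factor studies, a null/alternative p-value mixture (a
#' proportion `pi0` of true nulls with uniform p; alternatives with
#' normally distributed true log odds ratios), published evidence that is
#' either a rounded/censored reported p-value or a rounded OR with 95%
#' CI, and analyzed windows drawn from a survey-cycle availability
#' calendar with a stated probability of being a strict (selective)
#' sub-window.
#'
#' Defaults mirror the audited corpus: 341 studies over 138 conditions
#' and 169 predictors, publication years drawn with the 2022/2023/2024
#' surge weights 33/82/190, `selective_prob = 10/14` (the observed
#' full-versus-selective split in the windows case study), a 50/50 split
#' between reported-p and OR/CI evidence, censoring below 0.001, and
#' odds ratios rounded to 2 decimals.
#'
#' @param n_conditions,n_predictors,n_studies Corpus dimensions.
#' @param pi0 Proportion of true-null studies in `[0, 1]`.
#' @param effect_logor_mean,effect_logor_sd Normal distribution of true
#'   log odds ratios under the alternative.
#' @param se_min,se_max Uniform range of per-study standard errors of the
#'   log odds ratio.
#' @param censor_threshold Reported p-values below this are printed as
#'   `"<threshold"`.
#' @param round_digits_or Decimals for reported OR and CI bounds.
#' @param hub_concentration Zipf exponent skewing study-to-condition
#'   assignment (0 = uniform; larger = more hub-concentrated).
#' @param selective_prob Probability a study analyzes a strict sub-window
#'   of its variable's availability.
#' @param p_report_prob Probability evidence is a reported p-value rather
#'   than OR/CI.
#' @param seed Integer seed; the same seed reproduces the corpus bit for
#'   bit.
#' @param calendar Optional `cycle_calendar`; defaults to the packaged
#'   calendar. Only variables whose availability forms one contiguous
#'   year run are sampled, so a contiguous analyzed window can realize
#'   the `full` verdict.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_conditions = 138, n_predictors = 169,
                             n_studies = 341, pi0 = 0.8,
                             effect_logor_mean = 0.5, effect_logor_sd = 0.2,
                             se_min = 0.1, se_max = 0.3,
                             censor_threshold = 0.001, round_digits_or = 2,
                             hub_concentration = 1.0, selective_prob = 10 / 14,
                             p_report_prob = 0.5, seed = 1L, calendar = NULL) {
  cfg <- list(
    n_conditions = n_conditions, n_predictors = n_predictors,
    n_studies = n_studies, pi0 = pi0,
    effect_logor_mean = effect_logor_mean, effect_logor_sd = effect_logor_sd,
    se_min = se_min, se_max = se_max, censor_threshold = censor_threshold,
    round_digits_or = round_digits_or, hub_concentration = hub_concentration,
    selective_prob = selective_prob, p_report_prob = p_report_prob,
    seed = seed, calendar = calendar
  )
  check <- function(field, ok) {
    if (!isTRUE(ok)) stop("invalid synthetic_config field: ", field, call. = FALSE)
  }
  for (f in c("n_conditions", "n_predictors", "n_studies")) {
    check(f, length(cfg[[f]]) == 1 && !is.na(cfg[[f]]) && cfg[[f]] >= 1 &&
      cfg[[f]] == floor(cfg[[f]]))
  }
  for (f in c("pi0", "selective_prob", "p_report_prob")) {
    check(f, length(cfg[[f]]) == 1 && !is.na(cfg[[f]]) &&
      cfg[[f]] >= 0 && cfg[[f]] <= 1)
  }
  check("se_min", is.numeric(se_min) && se_min > 0)
  check("se_max", is.numeric(se_max) && se_max >= se_min)
  check("effect_logor_sd", is.numeric(effect_logor_sd) && effect_logor_sd >= 0)
  check("censor_threshold", censor_threshold > 0 && censor_threshold < 1)
  check("round_digits_or", round_digits_or >= 0 &&
    round_digits_or == floor(round_digits_or))
  check("hub_concentration", is.numeric(hub_concentration) && hub_concentration >= 0)
  check("seed", length(seed) == 1 && !is.na(seed) && seed == floor(seed))
  structure(cfg, class = "synthetic_config")
}

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# variables whose availability union is one contiguous year run
contiguous_variables <- function(calendar) {
  spans <- split(calendar, calendar$variable_key)
  keep <- vapply(spans, function(s) {
    yrs <- sort(unique(unlist(Map(seq.int, s$span_start, s$span_end))))
    # need >= 2 years so a strict sub-window exists
    length(yrs) == max(yrs) - min(yrs) + 1 && length(yrs) >= 2
  }, logical(1))
  tibble::tibble(
    variable_key = names(spans)[keep],
    avail_start = vapply(spans[keep], function(s) min(s$span_start), integer(1)),
    avail_end = vapply(spans[keep], function(s) max(s$span_end), integer(1))
  )
}

# uniform draw of a strict contiguous sub-window of [start, end]
draw_subwindow <- function(start, end) {
  len <- end - start + 1
  pairs <- which(upper.tri(matrix(0, len, len), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[!(pairs[, "row"] == 1 & pairs[, "col"] == len), , drop = FALSE]
  k <- sample.int(nrow(pairs), 1)
  c(start + pairs[k, "row"] - 1L, start + pairs[k, "col"] - 1L)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws a corpus under the process described in [synthetic_config()] and
#' returns it together with the per-study ground truth needed for
#' parameter-recovery and calibration tests. Reported confidence
#' intervals always bracket the reported odds ratio after rounding: the
#' observation noise of any record violating that invariant is redrawn.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `corpus` (a valid `corpus`) and `truth`
#'   (a tibble keyed by `study_id` with `is_null`, `true_log_or`,
#'   `true_se`, `true_z` (the realized z statistic), `exact_p`,
#'   `condition_idx`, `predictor_idx`, `window_start`, `window_end`,
#'   `selective`, `source`).
#' @examples
#' sim <- generate_corpus(synthetic_config(n_studies = 50, seed = 7))
#' table(sim$truth$is_null)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  calendar <- config$calendar
  if (is.null(calendar)) {
    calendar <- read_calendar(nhanesaudit_example("nhanes_calendar.csv"))
  }
  vars <- contiguous_variables(calendar)
  if (nrow(vars) == 0) stop("calendar has no contiguous-availability variable", call. = FALSE)
  n <- config$n_studies
  q <- qnorm(0.975)

  local_seed(config$seed, {
    cond_w <- seq_len(config$n_conditions)^(-config$hub_concentration)
    condition_idx <- sample.int(config$n_conditions, n, TRUE, prob = cond_w)
    predictor_idx <- sample.int(config$n_predictors, n, TRUE)
    is_null <- runif(n) < config$pi0
    true_log_or <- ifelse(is_null, 0,
      rnorm(n, config$effect_logor_mean, config$effect_logor_sd)
    )
    true_se <- runif(n, config$se_min, config$se_max)
    obs_logor <- rnorm(n, true_log_or, true_se)
    report_p <- runif(n) < config$p_report_prob

    # round OR/CI; redraw observation noise where rounding breaks bracketing
    dg <- config$round_digits_or
    for (iter in seq_len(100)) {
      or_r <- round(exp(obs_logor), dg)
      lo_r <- round(exp(obs_logor - q * true_se), dg)
      hi_r <- round(exp(obs_logor + q * true_se), dg)
      bad <- !report_p &
        !(lo_r > 0 & lo_r < hi_r & lo_r <= or_r & or_r <= hi_r)
      if (!any(bad)) break
      obs_logor[bad] <- rnorm(sum(bad), true_log_or[bad], true_se[bad])
    }
    if (any(bad)) stop("could not draw valid rounded OR/CI records", call. = FALSE)

    true_z <- obs_logor / true_se
    exact_p <- pmax(2 * pnorm(abs(true_z), lower.tail = FALSE), .Machine$double.xmin)

    thr <- config$censor_threshold
    p_round <- round(exact_p, 3)
    censored <- exact_p < thr | p_round < thr
    p_chr <- ifelse(censored,
      paste0("<", format(thr, scientific = FALSE, trim = TRUE)),
      format(p_round, scientific = FALSE, trim = TRUE)
    )

    vi <- sample.int(nrow(vars), n, TRUE)
    selective <- runif(n) < config$selective_prob
    w_start <- vars$avail_start[vi]
    w_end <- vars$avail_end[vi]
    for (i in which(selective)) {
      w <- draw_subwindow(w_start[i], w_end[i])
      w_start[i] <- w[1]
      w_end[i] <- w[2]
    }

    pub_year <- sample(c(2022L, 2023L, 2024L), n, TRUE, prob = c(33, 82, 190))
    journal <- sample(sprintf("journal_%02d", 1:30), n, TRUE,
      prob = (1:30)^(-1)
    )
    country <- ifelse(runif(n) < 0.9, "China", "Other")
    study_id <- sprintf("S%05d", seq_len(n))

    corpus <- tibble::tibble(
      study_id = study_id,
      pub_year = pub_year,
      predictor = sprintf("predictor_%03d", predictor_idx),
      outcome = sprintf("condition_%03d", condition_idx),
      p_reported = ifelse(report_p, p_chr, NA_character_),
      or = ifelse(report_p, NA_real_, or_r),
      ci_low = ifelse(report_p, NA_real_, lo_r),
      ci_high = ifelse(report_p, NA_real_, hi_r),
      window_start = as.integer(w_start),
      window_end = as.integer(w_end),
      variable_key = vars$variable_key[vi],
      cohort = "general population",
      journal = journal,
      affiliation_country = country
    )
    probs <- corpus_problems(corpus)
    if (nrow(probs)) {
      stop("internal error: generator emitted invalid records", call. = FALSE)
    }
    corpus <- new_corpus(corpus,
      provenance = paste0("synthetic corpus, seed=", config$seed)
    )
    truth <- tibble::tibble(
      study_id = study_id, is_null = is_null, true_log_or = true_log_or,
      true_se = true_se, true_z = true_z, exact_p = exact_p,
      condition_idx = condition_idx, predictor_idx = predictor_idx,
      window_start = as.integer(w_start), window_end = as.integer(w_end),
      selective = selective,
      source = ifelse(report_p, "reported", "or_ci")
    )
    list(corpus = corpus, truth = truth)
  })
}

#' Dredging simulation: uncorrected versus jointly corrected analysis
#'
#' Repeatedly generates a synthetic corpus, harmonizes its evidence, and
#' contrasts the uncorrected single-factor reading (each study judged at
#' `alpha` on its own p-value) with joint group-wise FDR correction by
#' outcome, measuring realized error rates against the generator's ground
#' truth. This quantifies the central concern the audit addresses: many
#' independent single-factor studies of the same condition collectively
#' perform an uncorrected multiple-testing sweep.
#'
#' @param config A `synthetic_config` (its `seed` is ignored; replicate
#'   seeds derive from `seed`).
#' @param alpha Significance level.
#' @param n_replicates Number of simulation replicates.
#' @param seed Base seed for the replicate stream.
#' @return List with `replicates` (one row per replicate:
#'   `uncorrected_null_rejection_rate`; `by_fdp` and `bh_fdp`, each the
#'   mean over outcome groups of the realized within-group false
#'   discovery proportion, 0 for groups rejecting nothing, matching the
#'   per-family scope of the FDR guarantee; `by_power`, pooled over all
#'   non-null studies) and `pooled` (per metric: mean across replicates
#'   and its Monte-Carlo standard error).
#' @examples
#' cfg <- synthetic_config(n_studies = 100, pi0 = 1)
#' dredging_experiment(cfg, n_replicates = 5, seed = 1)$pooled
#' @export
dredging_experiment <- function(config, alpha = 0.05, n_replicates = 20,
                                seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  one <- function(r) {
    cfg <- config
    cfg$seed <- (seed + 131071 * r) %% 2147483647L
    sim <- generate_corpus(cfg)
    h <- harmonize(sim$corpus, convention = "at_bound")
    truth <- sim$truth

    null_i <- truth$is_null
    uncorrected <- if (any(null_i)) mean(h$p[null_i] < alpha) else NA_real_

    # FDR is controlled per family (per outcome group), so the realized
    # FDP is computed within each group (0 when the group rejects nothing)
    # and averaged over groups; power is pooled over all non-null studies.
    rates <- function(method) {
      res <- group_adjust(sim$corpus, h,
        group_key = "outcome",
        method = method, alpha = alpha
      )
      is_null_of <- stats::setNames(truth$is_null, truth$study_id)
      fdp_g <- vapply(res, function(g) {
        sig <- g$study_id[g$significant]
        if (length(sig)) sum(is_null_of[sig]) / length(sig) else 0
      }, double(1))
      sig_ids <- unlist(lapply(res, function(g) g$study_id[g$significant]),
        use.names = FALSE
      )
      power <- if (any(!null_i)) {
        sum(!is_null_of[sig_ids]) / sum(!null_i)
      } else {
        NA_real_
      }
      c(fdp = mean(fdp_g), power = power)
    }
    by <- rates("BY")
    bh <- rates("BH")
    tibble::tibble(
      replicate = r,
      uncorrected_null_rejection_rate = uncorrected,
      by_fdp = by[["fdp"]], by_power = by[["power"]], bh_fdp = bh[["fdp"]]
    )
  }
  reps <- dplyr::bind_rows(lapply(seq_len(n_replicates), one))
  metrics <- c("uncorrected_null_rejection_rate", "by_fdp", "by_power", "bh_fdp")
  pooled <- dplyr::bind_rows(lapply(metrics, function(mname) {
    x <- reps[[mname]]
    x <- x[!is.na(x)]
    tibble::tibble(
      metric = mname,
      mean = if (length(x)) mean(x) else NA_real_,
      mc_se = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    )
  }))
  list(replicates = reps, pooled = pooled)
}
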