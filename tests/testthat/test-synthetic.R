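test_that("the same seed reproduces the corpus bit for bit", {
  cfg <- synthetic_config(n_studies = 100, seed = 555)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(tibble::as_tibble(a$corpus), tibble::as_tibble(b$corpus))
  expect_identical(a$truth, b$truth)

  c2 <- generate_corpus(synthetic_config(n_studies = 100, seed = 556))
  expect_false(identical(a$truth$exact_p, c2$truth$exact_p))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_corpus(synthetic_config(n_studies = 20, seed = 9)))
  expect_identical(runif(1), before)
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(pi0 = 1.5), "pi0")
  expect_error(synthetic_config(se_min = 0.5, se_max = 0.1), "se_max")
  expect_error(synthetic_config(n_studies = 0), "n_studies")
  expect_error(synthetic_config(censor_threshold = 0), "censor_threshold")
})

test_that("under a pure null the exact p-values are uniform", {
  cfg <- synthetic_config(n_studies = 10000, pi0 = 1, seed = 2024)
  sim <- generate_corpus(cfg)
  expect_true(all(sim$truth$is_null))
  expect_true(all(sim$truth$true_log_or == 0))
  frac <- mean(sim$truth$exact_p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), tol)
  # ground-truth identity: exact_p = two-sided tail of the realized z
  expect_equal(sim$truth$exact_p,
    2 * pnorm(abs(sim$truth$true_z), lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("generated records always satisfy the corpus invariants", {
  sim <- generate_corpus(synthetic_config(n_studies = 400, seed = 77))
  corp <- sim$corpus
  orci <- !is.na(corp$or)
  expect_true(all(corp$ci_low[orci] > 0))
  expect_true(all(corp$ci_low[orci] <= corp$or[orci]))
  expect_true(all(corp$or[orci] <= corp$ci_high[orci]))
  # censoring contract on the reported-p side
  rep_p <- !is.na(corp$p_reported)
  parsed <- parse_reported_p(corp$p_reported[rep_p])
  expect_true(all(parsed$value[parsed$is_upper_bound] == 0.001))
  expect_true(all(sim$truth$exact_p[rep_p][parsed$is_upper_bound] < 0.001 + 5e-4))
  # round-trip through the CSV layer revalidates cleanly
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, path)
  expect_equal(nrow(read_corpus(path)), 400)
})

test_that("the selective-window fraction recovers selective_prob", {
  cfg <- synthetic_config(n_studies = 2000, selective_prob = 0.6, seed = 404)
  sim <- generate_corpus(cfg)
  aud <- audit_windows(sim$corpus, fixture_calendar())
  expect_true(all(aud$verdict %in% c("full", "selective")))
  expect_equal(aud$verdict == "selective", sim$truth$selective)
  frac <- mean(aud$verdict == "selective")
  tol <- 3 * sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(frac - 0.6), tol)
})

test_that("condition-degree skew grows with hub concentration", {
  top_share <- function(hub, seed) {
    sim <- generate_corpus(synthetic_config(
      n_studies = 400, hub_concentration = hub, seed = seed
    ))
    max(table(sim$truth$condition_idx)) / 400
  }
  for (seed in c(1, 2, 3)) {
    expect_lt(top_share(0, seed), top_share(2.5, seed))
  }
})

test_that("the dredging experiment returns pooled rates with MC errors", {
  cfg <- synthetic_config(n_studies = 150, pi0 = 0.6, seed = 1)
  res <- dredging_experiment(cfg, alpha = 0.05, n_replicates = 6, seed = 10)
  expect_equal(nrow(res$replicates), 6)
  expect_named(
    res$replicates,
    c(
      "replicate", "uncorrected_null_rejection_rate", "by_fdp",
      "by_power", "bh_fdp"
    )
  )
  expect_true(all(res$pooled$mean[!is.na(res$pooled$mean)] >= 0))
  expect_true(all(res$pooled$mean[!is.na(res$pooled$mean)] <= 1))
})

test_that("BY rejections are a subset of BH rejections in every group", {
  sim <- generate_corpus(synthetic_config(n_studies = 300, pi0 = 0.5, seed = 61))
  h <- harmonize(sim$corpus)
  by <- group_adjust(sim$corpus, h, method = "BY")
  bh <- group_adjust(sim$corpus, h, method = "BH")
  for (g in names(by)) {
    expect_true(all(
      by[[g]]$study_id[by[[g]]$significant] %in%
        bh[[g]]$study_id[bh[[g]]$significant]
    ))
  }
})

test_that("strong effects at moderate standard error are nearly always detected", {
  # |log OR| = 1 at se ~ 0.15: the normal-tail power at z = 1/0.15 = 6.7
  # is essentially 1 even after joint BY correction
  cfg <- synthetic_config(
    n_studies = 200, pi0 = 0.2, effect_logor_mean = 1,
    effect_logor_sd = 0.05, se_min = 0.14, se_max = 0.16, seed = 5
  )
  res <- dredging_experiment(cfg, alpha = 0.05, n_replicates = 5, seed = 50)
  pooled <- res$pooled
  expect_gt(pooled$mean[pooled$metric == "by_power"], 0.9)
})
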