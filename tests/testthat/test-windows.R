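test_that("available_years unions released spans, truncated at publication", {
  cal <- fixture_calendar()
  expect_equal(available_years(cal, "DIQ", 2024), 1999:2020)
  expect_equal(
    available_years(cal, "LBXFER", 2023),
    c(1999:2002, 2005:2010, 2015:2020)
  )
  # truncation: a 2003 publication sees only cycles released before 2003
  # (the 2001-2002 cycle is released in 2003 itself, so it is excluded)
  expect_equal(available_years(cal, "DIQ", 2003), 1999:2000)
  # the combined 2017-2020 release (2021) is invisible until 2022
  expect_equal(max(available_years(cal, "DIQ", 2021)), 2016)
  expect_equal(max(available_years(cal, "DIQ", 2022)), 2020)
  expect_error(available_years(cal, "NOPE", 2024), "known keys")
})

test_that("calendar validation rejects overlapping or inverted spans", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "variable_key,span_start,span_end,release_year",
    "X,1999,2002,2003", "X,2001,2004,2005"
  ), path)
  expect_error(read_calendar(path), "overlapping")
  writeLines(c(
    "variable_key,span_start,span_end,release_year",
    "X,2005,2003,2006"
  ), path)
  expect_error(read_calendar(path), "span_start > span_end")
})

test_that("window audit classifies the SII case-study fixture", {
  sii <- fixture_corpus("table3_sii.csv")
  aud <- audit_windows(sii, fixture_calendar())
  expect_equal(nrow(aud), 14)
  verdict <- setNames(aud$verdict, aud$study_id)

  # full users of the available series
  expect_equal(verdict[["39076553"]], "full") # stroke 1999-2020
  expect_equal(verdict[["39239395"]], "full") # serum NfL 2013-2014
  expect_equal(verdict[["39267962"]], "full") # atopic dermatitis 2001-2006
  # the two diabetes windows against availability 1999-2020
  expect_equal(verdict[["38974989"]], "selective") # 2003-2018
  expect_equal(verdict[["38027115"]], "selective") # 2017-2020
  # strict-rule tally over the whole table
  expect_equal(sum(aud$verdict == "full"), 3)
  expect_equal(sum(aud$verdict == "selective"), 11)

  diab <- aud[aud$study_id == "38974989", ]
  missed <- as.integer(strsplit(diab$missed_years, ";")[[1]])
  expect_true(all(c(1999, 2000, 2001, 2002, 2019, 2020) %in% missed))
  expect_equal(diab$coverage, 16 / 22)
  expect_true(all(aud$coverage >= 0 & aud$coverage <= 1))
  expect_true(all(aud$missed_years[aud$verdict == "full"] == ""))
})

test_that("analyzed years outside availability yield a mismatch verdict", {
  corp <- toy_corpus(toy_row("m1", "SII", "stroke",
    p_reported = NA,
    window_start = 2005, window_end = 2016, variable_key = "SSSNFL"
  ))
  aud <- audit_windows(corp, fixture_calendar())
  expect_equal(aud$verdict, "mismatch")
  expect_true(nzchar(aud$out_of_range_years))
})

test_that("widening a window never decreases coverage", {
  cal <- fixture_calendar()
  covs <- vapply(2018:2007, function(s) {
    corp <- toy_corpus(toy_row("w", "SII", "diabetes",
      p_reported = NA,
      window_start = s, window_end = 2018, variable_key = "DIQ"
    ))
    audit_windows(corp, cal)$coverage
  }, double(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("window popularity and median span summarize the fixture", {
  sii <- fixture_corpus("table3_sii.csv")
  pop <- window_popularity(sii)
  expect_equal(sum(pop$n), 14)
  expect_true(all(diff(pop$n) <= 0))
  top <- pop[pop$n == max(pop$n), ]
  expect_equal(top$window_start[1], 2005) # 2005-2018 appears twice

  expect_equal(median_span(sii), 8)
  one <- toy_corpus(toy_row("a", "x", "y", window_start = 2013, window_end = 2014))
  expect_equal(median_span(one), 2)
  two <- toy_corpus(
    toy_row("a", "x", "y", window_start = 2001, window_end = 2002),
    toy_row("b", "x", "z", window_start = 2001, window_end = 2006)
  )
  expect_equal(median_span(two), 4) # even count: mean of spans 2 and 6
})

test_that("upset membership matrix marks exactly the analyzed years", {
  one <- toy_corpus(toy_row("a", "x", "y", window_start = 2007, window_end = 2018))
  m <- upset_membership(one)
  expect_equal(dim(m), c(1, 22))
  expect_equal(sum(m), 12)
  expect_true(all(m[1, as.character(2007:2018)] == 1))

  sii <- fixture_corpus("table3_sii.csv")
  ms <- upset_membership(sii)
  expect_equal(dim(ms), c(14, 22))
  expect_equal(unname(rowSums(ms)), sii$window_end - sii$window_start + 1)
  # column sums agree with per-year usage derived from the window tally
  pop <- window_popularity(sii)
  per_year <- vapply(1999:2020, function(y) {
    sum(pop$n[pop$window_start <= y & y <= pop$window_end])
  }, double(1))
  expect_equal(unname(colSums(ms)), per_year)

  expect_equal(nrow(upset_membership(sii[0, ])), 0)
})

test_that("annual counts and affiliation shares tally the corpus", {
  tab2 <- fixture_corpus("table2_depression.csv")
  ac <- annual_counts(tab2)
  expect_equal(ac$n[ac$year == 2024], 16)
  expect_equal(ac$n[ac$year == 2021], 0) # zero-filled interior year
  expect_equal(sum(ac$n), 28)

  corp <- toy_corpus(
    toy_row("c1", "x", "y", pub_year = 2015, affiliation_country = "China"),
    toy_row("c2", "x", "z", pub_year = 2016, affiliation_country = "USA"),
    toy_row("c3", "w", "y", pub_year = 2023, affiliation_country = "china "),
    toy_row("c4", "w", "z", pub_year = 2024, affiliation_country = "China")
  )
  expect_equal(
    affiliation_period_share(corp, "China", 2014, 2020),
    c(numerator = 1, denominator = 2)
  )
  expect_equal(
    affiliation_period_share(corp, "China", 2021, 2024),
    c(numerator = 2, denominator = 2)
  )
  expect_equal(
    affiliation_period_share(corp, "Absentland", 2014, 2024),
    c(numerator = 0, denominator = 4)
  )
})
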