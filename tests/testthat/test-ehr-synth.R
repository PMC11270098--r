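test_that("degenerate cohorts behave: empty spec, forced prevalence", {
  cat1 <- codeCatalogue("DX1", base_prevalence = 1)
  sp0 <- cohortSpec(0, cat1)
  expect_length(patients(sampleCohort(sp0, seed = 1)), 0)

  sp <- cohortSpec(10, cat1, visitsMean = 1, visitsDispersion = 100,
                   baselineLogodds = -20)
  co <- sampleCohort(sp, seed = 1)
  expect_length(patients(co), 10)
  for (p in patients(co))
    for (v in p$visits) expect_true("DX1" %in% v$dx_codes)
})

test_that("identical (spec, seed) gives byte-identical serialized cohorts", {
  fx <- makeFixture("tiny_linear")
  f1 <- tempfile(); f2 <- tempfile()
  writeCohortJSONL(sampleCohort(fx$spec, seed = 7), f1)
  writeCohortJSONL(sampleCohort(fx$spec, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile()
  writeCohortJSONL(sampleCohort(fx$spec, seed = 8), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("visits are truncated at death and sequences stay well-formed", {
  fx <- makeFixture("tiny_linear", nPatients = 200)
  co <- sampleCohort(fx$spec, seed = 3)
  for (p in patients(co)) {
    offs <- vapply(p$visits, function(v) v$day_offset, numeric(1))
    idx <- vapply(p$visits, function(v) v$visit_index, numeric(1))
    expect_identical(as.integer(idx), seq_along(idx) - 1L)
    expect_false(is.unsorted(offs))
    if (!is.na(p$death_day_offset))
      expect_true(all(offs <= p$death_day_offset))
  }
})

test_that("null-effect death model matches its configured per-visit rate", {
  p0 <- 0.07
  cat_ <- codeCatalogue("DX1", base_prevalence = 0.5, mortality_logodds = 0)
  sp <- cohortSpec(10000, cat_, visitsMean = 1, visitsDispersion = 100,
                   baselineLogodds = qlogis(p0))
  co <- sampleCohort(sp, seed = 5)
  rate <- mean(vapply(patients(co), function(p) !is.na(p$death_day_offset),
                      logical(1)))
  mcErr <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(rate - p0), 3 * mcErr)
})

test_that("a +10 log-odds code saturates the per-visit death probability", {
  cat_ <- codeCatalogue("DX1", base_prevalence = 1, mortality_logodds = 10)
  sp <- cohortSpec(500, cat_, visitsMean = 1, visitsDispersion = 100,
                   baselineLogodds = -3)
  co <- sampleCohort(sp, seed = 2)
  rate <- mean(vapply(patients(co), function(p) !is.na(p$death_day_offset),
                      logical(1)))
  expect_gt(rate, 0.99)
})

test_that("mixed-catalogue mortality matches an independent enumeration oracle", {
  # single-visit patients, 3 independent codes: expected death probability is
  # the sum over the 8 code configurations of P(config) * plogis(eta(config))
  prev <- c(0.3, 0.5, 0.2); lo <- c(1.2, -0.8, 0.5); base <- -2
  expected <- 0
  for (mask in 0:7) {
    on <- bitwAnd(mask, c(1L, 2L, 4L)) > 0
    expected <- expected + prod(ifelse(on, prev, 1 - prev)) *
      plogis(base + sum(lo[on]))
  }
  cat_ <- codeCatalogue(paste0("DX", 1:3), base_prevalence = prev,
                        mortality_logodds = lo)
  sp <- cohortSpec(10000, cat_, visitsMean = 1, visitsDispersion = 100,
                   baselineLogodds = base)
  co <- sampleCohort(sp, seed = 11)
  rate <- mean(vapply(patients(co), function(p) !is.na(p$death_day_offset),
                      logical(1)))
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("30-day mortality label is inclusive at the boundary", {
  v <- mkVisit(0, 100)
  expect_true(label30DayMortality(mkPatient("P1", list(v), death = 130L), v))
  expect_false(label30DayMortality(mkPatient("P1", list(v), death = 131L), v))
  expect_false(label30DayMortality(mkPatient("P1", list(v)), v))
  # death before the visit does not label it
  expect_false(label30DayMortality(mkPatient("P1", list(v), death = 99L), v))
})

test_that("IHCA subset selects exactly the patients with a resuscitation code", {
  pNo <- mkPatient("A", list(mkVisit(0, 0, "DX1")))
  pYes <- mkPatient("B", list(mkVisit(0, 0, "DX1"),
                              mkVisit(1, 10, "DX1", proc = "99.63")))
  co <- new("EHRCohort", patients = list(pNo, pYes), spec = NULL,
            seed = NA_integer_)
  sub <- buildIHCASubset(co)
  expect_length(patients(sub), 1)
  expect_identical(patients(sub)[[1]]$patient_id, "B")
  expect_length(patients(buildIHCASubset(
    new("EHRCohort", patients = list(pNo), spec = NULL, seed = NA_integer_))), 0)
})

test_that("IHCA patient share tracks the generating per-visit probability", {
  cat_ <- codeCatalogue("DX1", base_prevalence = 0.2)
  sp <- cohortSpec(4000, cat_, visitsMean = 1, visitsDispersion = 100,
                   pIHCAVisit = 0.4, baselineLogodds = -20)
  co <- sampleCohort(sp, seed = 4)
  share <- length(patients(buildIHCASubset(co))) / 4000
  expect_lt(abs(share - 0.4), 3 * sqrt(0.4 * 0.6 / 4000))
})

test_that("within-visit co-occurrence hits the configured conditional", {
  # P(PNEU | UTI in same visit) configured to 23.36%
  cat_ <- codeCatalogue(c("UTI", "PNEU"), base_prevalence = c(0.5, 0.045))
  co_tab <- data.frame(code = "PNEU", given = "UTI", boost = 0.2336 / 0.045)
  sp <- cohortSpec(5000, cat_, visitsMean = 4, visitsDispersion = 100,
                   cooccur = co_tab, baselineLogodds = -20)
  co <- sampleCohort(sp, seed = 6)
  visits <- unlist(lapply(patients(co), function(p)
    lapply(p$visits, function(v) v$dx_codes)), recursive = FALSE)
  utiVisits <- visits[vapply(visits, function(d) "UTI" %in% d, logical(1))]
  expect_gt(length(utiVisits), 8000)
  pc <- mean(vapply(utiVisits, function(d) "PNEU" %in% d, logical(1)))
  mcErr <- sqrt(0.2336 * (1 - 0.2336) / length(utiVisits))
  expect_lt(abs(pc - 0.2336), 3 * mcErr)
})

test_that("observed mention shares converge to the analytic expectation", {
  fx <- makeFixture("paper_like", nPatients = 800)
  exp_share <- attr(expectedCodeShares(fx$spec), "mention_share")
  obs <- observedCodeShares(sampleCohort(fx$spec, seed = 9))
  common <- intersect(names(obs), names(exp_share))
  expect_lt(max(abs(obs[common] - exp_share[common])), 0.01)
})

test_that("paper-like catalogue reproduces the published top-4 rank order in expectation", {
  fx <- makeFixture("paper_like")
  sh <- attr(expectedCodeShares(fx$spec), "mention_share")
  expect_true(all(diff(sh[c("DM", "ARF", "PNEU", "UTI")]) < 0))
  expect_equal(unname(100 * sh[["DM"]]), 4.93, tolerance = 1e-6)
})

test_that("cohort readers and writers round-trip", {
  fx <- makeFixture("tiny_linear")
  co <- sampleCohort(fx$spec, seed = 12)
  f <- tempfile(fileext = ".jsonl")
  writeCohortJSONL(co, f)
  co2 <- readCohortJSONL(f)
  expect_identical(lapply(patients(co), function(p) p$visits),
                   lapply(patients(co2), function(p) p$visits))
  expect_identical(vapply(patients(co), function(p) p$death_day_offset, integer(1)),
                   vapply(patients(co2), function(p) p$death_day_offset, integer(1)))
  g <- tempfile(fileext = ".csv")
  writeCohortCSV(co, g)
  co3 <- readCohortCSV(g)
  expect_identical(lapply(patients(co), function(p)
    lapply(p$visits, function(v) v$dx_codes)),
    lapply(patients(co3), function(p) lapply(p$visits, function(v) v$dx_codes)))
})

test_that("spec files round-trip and parse errors name the line", {
  fx <- makeFixture("uti_confounder")
  f <- tempfile(fileext = ".txt")
  writeCohortSpecFile(fx$spec, f)
  sp2 <- readCohortSpecFile(f)
  expect_equal(sp2@catalogue$code, fx$spec@catalogue$code)
  expect_equal(sp2@catalogue$base_prevalence, fx$spec@catalogue$base_prevalence,
               tolerance = 1e-6)
  expect_equal(sp2@cooccur$boost, fx$spec@cooccur$boost, tolerance = 1e-6)
  expect_equal(sp2@baselineLogodds, fx$spec@baselineLogodds)

  bad <- tempfile()
  writeLines(c("n_patients = 5", "nonsense line without equals"), bad)
  expect_error(readCohortSpecFile(bad), "line 2")
  bad2 <- tempfile()
  writeLines(c("n_patients = 5", "codes:", "DX1 label notanumber 0"), bad2)
  expect_error(readCohortSpecFile(bad2), "base_prevalence")
})

test_that("invalid generator configuration names the offending field", {
  cat_ <- codeCatalogue("DX1", base_prevalence = 0.5)
  expect_error(cohortSpec(10, cat_, visitsMean = 0), "visitsMean")
  expect_error(cohortSpec(10, cat_, pIHCAVisit = 2), "pIHCAVisit")
  expect_error(codeCatalogue(c("A", "A"), base_prevalence = 0.1), "duplicated")
  expect_error(codeCatalogue("A", base_prevalence = 1.5), "base_prevalence")
})

test_that("cohortArithmetic recomputes derived statistics and flags missing counts", {
  out <- cohortArithmetic(list(total_records = 100, analyzed_records = 60,
                               n_patients = 10, ihca_records = 12, deaths = 5,
                               first_arrest_deaths = 4,
                               single_arrest_patients = 9))
  expect_equal(out$excluded_records, 40)
  expect_equal(out$mean_records_per_patient, 6)
  expect_equal(out$ihca_record_pct, 20)
  expect_equal(out$mortality_pct, 50)
  expect_equal(out$first_arrest_death_pct, 80)
  expect_equal(out$single_arrest_pct, 90)
  expect_error(cohortArithmetic(list(total_records = 1)), "missing counts")
})
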