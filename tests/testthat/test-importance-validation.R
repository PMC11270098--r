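test_that("eligible patients get 5 current and 4 historical decision points", {
  p <- eligiblePatient(nPrior = 6L)
  dp <- buildDecisionPoints(p)
  expect_equal(nrow(dp), 9)
  expect_equal(sum(dp$mode == "current"), 5)
  expect_equal(sum(dp$mode == "historical"), 4)
  # the 5 current records are the fatal IHCA record and its 4 predecessors
  expect_setequal(dp$visit_index[dp$mode == "current"], 2:6)
  expect_setequal(dp$visit_index[dp$mode == "historical"], 3:6)

  short <- eligiblePatient(nPrior = 3L)
  dpS <- buildDecisionPoints(short)
  expect_equal(nrow(dpS), 0)
  expect_match(attr(dpS, "excluded"), "prior records")

  alive <- mkPatient("P9", list(mkVisit(0, 0, "C1", proc = "99.60")))
  dpA <- buildDecisionPoints(alive)
  expect_equal(nrow(dpA), 0)
  expect_match(attr(dpA, "excluded"), "no IHCA record")
})

test_that("noise-free annotators bin risks deterministically on the 1-4 scale", {
  ann <- simulateAnnotators(c(0.99, 0.001, 0.5, 0.21, 0.05, 0.049),
                            noiseScale = 0, seed = 1)
  expect_equal(ann$scale_a, c(1L, 4L, 1L, 2L, 3L, 4L))
  expect_equal(ann$scale_b, ann$scale_a)
  expect_error(simulateAnnotators(0.5, cutpoints = c(0.2, 0.5, 0.05)),
               "decreasing")
  expect_error(simulateAnnotators(1.2), "\\[0,1\\]")
})

test_that("inter-annotator agreement decreases monotonically with noise", {
  set.seed(3)
  risks <- runif(3000)
  agree <- vapply(c(0.1, 0.4, 1.0), function(ns) {
    ann <- simulateAnnotators(risks, noiseScale = ns, seed = 7)
    mean(ann$scale_a == ann$scale_b)
  }, numeric(1))
  expect_true(all(diff(agree) < 0))
})

test_that("adjudication keeps the severe scale and refers large disagreements", {
  expect_equal(adjudicate(2, 2), 2L)
  expect_equal(adjudicate(1, 2), 1L)
  expect_equal(adjudicate(3, 4), 3L)
  expect_equal(adjudicate(1, 3, tiebreakFn = function(a, b) 4L), 4L)
  expect_equal(adjudicate(c(2, 1, 4), c(2, 3, 1),
                          tiebreakFn = function(a, b) rep(2L, length(a))),
               c(2L, 2L, 2L))
  expect_equal(adjudicate(1, 2, combine = "mean_round"), 2L)
  expect_error(adjudicate(0, 2), "1..4")
})

test_that("impact segmentation thresholds are inclusive as printed", {
  labs <- segmentRecords(c(0.25, 0.10, 0.15, 0.30, 0.05, 0.2499))
  expect_equal(labs, c("high", "low", "neither", "high", "low", "neither"))
  expect_error(segmentRecords(0.2, thetaHigh = 0.1, thetaLow = 0.25), "thetaLow")
})

test_that("importance statistics reproduce the published pneumonia row", {
  # 105 of 334 scale-1 records and 29 of 453 scale-4 records
  labels <- c(rep("high", 334), rep("low", 453))
  codeSets <- c(lapply(1:334, function(i) if (i <= 105) "Pneumonia" else "Other"),
                lapply(1:453, function(i) if (i <= 29) "Pneumonia" else "Other"))
  tab <- importanceTable(labels, codeSets)
  row <- tab[tab$code == "Pneumonia", ]
  expect_equal(round(100 * row$high_ratio, 2), 31.44)
  expect_equal(round(100 * row$low_ratio, 2), 6.40)
  expect_equal(round(100 * row$importance, 2), 25.04)
})

test_that("importance ordering, zero rows and signs behave", {
  labels <- c("high", "high", "low", "neither")
  codeSets <- list(c("A", "B"), "A", c("B", "C"), "D")
  tab <- importanceTable(labels, codeSets, allCodes = c("A", "B", "C", "D", "E"))
  expect_equal(tab$code[1], "A")                       # 2/2 - 0
  expect_lt(tab$importance[tab$code == "C"], 0)        # only in low records
  expect_equal(tab$importance[tab$code == "D"], 0)     # neither stratum only
  expect_equal(tab$importance[tab$code == "E"], 0)     # never observed
  zeroRanks <- tab$rank[tab$importance == 0]
  expect_true(all(zeroRanks > max(tab$rank[tab$importance > 0])))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  # deterministic tie-break by code string
  ties <- tab$code[tab$importance == 0]
  expect_identical(ties, sort(ties))
  expect_error(importanceTable(c("neither", "neither"), list("A", "B")),
               "empty strata")
})

test_that("codes are counted at most once per record", {
  labels <- c("high", "high", "low")
  codeSets <- list(c("A", "A", "B"), "A", c("A", "A"))
  tab <- importanceTable(labels, codeSets)
  expect_equal(tab$count_high[tab$code == "A"], 2)
  expect_equal(tab$count_low[tab$code == "A"], 1)
  # de-duplication identity over the high stratum
  expect_equal(sum(tab$count_high),
               sum(vapply(codeSets[labels == "high"],
                          function(s) length(unique(s)), numeric(1))))
})

test_that("ratio bounds and the importance identity hold over random tables", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    labels <- sample(c("high", "low", "neither"), n, replace = TRUE)
    if (!any(labels != "neither")) labels[1] <- "high"
    codeSets <- lapply(seq_len(n), function(i)
      sample(LETTERS[1:8], sample(0:4, 1), replace = TRUE))
    tab <- importanceTable(labels, codeSets, allCodes = LETTERS[1:8])
    expect_true(all(tab$high_ratio >= 0 & tab$high_ratio <= 1))
    expect_true(all(tab$low_ratio >= 0 & tab$low_ratio <= 1))
    expect_equal(tab$importance, tab$high_ratio - tab$low_ratio)
    expect_true(all(tab$count_high <= sum(labels == "high")))
  }
})

test_that("stratum totals are recoverable from the published tables", {
  ref <- referenceSummaries()$tables
  smallest <- function(x) x[1]
  expect_equal(smallest(recoverStratumTotal(ref$physician_current$high_ratio_pct,
                                            ref$physician_current$count_high)), 334)
  expect_equal(smallest(recoverStratumTotal(ref$physician_current$low_ratio_pct,
                                            ref$physician_current$count_low)), 453)
  expect_equal(smallest(recoverStratumTotal(ref$physician_historical$high_ratio_pct,
                                            ref$physician_historical$count_high)), 483)
  expect_equal(smallest(recoverStratumTotal(ref$physician_historical$low_ratio_pct,
                                            ref$physician_historical$count_low)), 135)
  expect_equal(smallest(recoverStratumTotal(ref$dshap_current$high_ratio_pct)), 133)
  expect_equal(smallest(recoverStratumTotal(ref$dshap_current$low_ratio_pct)), 264)
  expect_equal(smallest(recoverStratumTotal(ref$dshap_historical$high_ratio_pct)), 88)
  expect_equal(smallest(recoverStratumTotal(ref$dshap_historical$low_ratio_pct)), 381)
})

test_that("rank comparisons report overlap and tie-corrected correlation", {
  tab <- data.frame(code = LETTERS[1:6], rank = 1:6)
  cmp <- compareRankings(tab, tab, k = 5)
  expect_equal(cmp$top_k_overlap, 5)
  expect_equal(cmp$rank_correlation, 1)
  rev_ <- data.frame(code = LETTERS[1:6], rank = 6:1)
  cmpR <- compareRankings(tab, rev_, k = 5)
  expect_equal(cmpR$rank_correlation, -1)
  expect_equal(cmpR$top_k_overlap, 4)   # B..E shared, A vs F differ
  # codes absent from one table rank last there
  tabS <- data.frame(code = LETTERS[1:4], rank = 1:4)
  cmpA <- compareRankings(tab, tabS, k = 6)
  expect_equal(cmpA$ranks$dshap_rank[cmpA$ranks$code %in% c("E", "F")],
               c(5L, 5L))
})

test_that("importance tables and annotations round-trip through TSV/CSV", {
  labels <- c("high", "low", "high")
  tab <- importanceTable(labels, list("A", c("A", "B"), "B"))
  f <- tempfile(fileext = ".tsv")
  writeImportanceTSV(tab, f, meta = c(seed = "1"))
  tab2 <- readImportanceTSV(f)
  expect_equal(tab$importance, tab2$importance, tolerance = 1e-8)
  expect_identical(tab$code, tab2$code)
  ann <- data.frame(patient_id = "P1", visit_index = 0L, mode = "current",
                    scale_a = 1L, scale_b = 2L, scale_final = 1L)
  g <- tempfile(fileext = ".csv")
  writeAnnotationCSV(ann, g)
  expect_equal(readAnnotationCSV(g), ann)
})
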