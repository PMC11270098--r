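# End-to-end benchmark-vs-attribution comparison on a synthetic cohort.
#
# The generator's logistic death model is the synthetic ground truth, so the
# simulated annotators can judge each decision point from its true risk --
# the stand-in for physician judgment -- while the attribution side sees only
# the trained model. Both sides are evaluated on the same decision-point
# record set.

#' True per-visit death risk under the generating spec
#'
#' @param spec a \code{CohortSpec}.
#' @param visit a visit list.
#' @return probability of death within 30 days following the visit.
#' @export
trueVisitRisk <- function(spec, visit) {
  lo <- spec@catalogue$mortality_logodds
  names(lo) <- spec@catalogue$code
  plogis(spec@baselineLogodds + sum(lo[visit$dx_codes]))
}

trueWindowRisk <- function(spec, window) {
  vs <- c(list(window$current), window$history)
  1 - prod(vapply(vs, function(v) 1 - trueVisitRisk(spec, v), numeric(1)))
}

#' Run the annotation-benchmark validation of attribution-based importance
#'
#' Builds the decision-point set (5 current + 4 historical points per eligible
#' patient), simulates two ordinal annotators on the generator's true risks
#' with noise-free adjudication of large disagreements, attributes every
#' decision-point record with \code{\link{deepSHAP}}, aggregates code-level
#' impacts, segments records by the chosen basis at the high/low thresholds,
#' and produces four ranked importance tables (benchmark and attribution,
#' current and historical) plus rank comparisons.
#'
#' @param cohort an \code{EHRCohort} generated from a \code{CohortSpec} (the
#'   spec supplies the annotators' ground truth).
#' @param model a trained \code{RiskModel}.
#' @param thetaHigh,thetaLow impact segmentation thresholds (0.25 / 0.10).
#' @param noiseScale annotator noise scale.
#' @param seed seed for the annotator simulation.
#' @param basisMode record-segmentation basis: "max_code_impact" (default) or
#'   "predicted_probability".
#' @param k top-k size for rank comparisons.
#' @param allCodes code universe for the tables (default: model vocabulary).
#' @return list with \code{benchmark_current}, \code{benchmark_historical},
#'   \code{dshap_current}, \code{dshap_historical} (importance tables),
#'   \code{comparison_current}, \code{comparison_historical}, plus the
#'   decision points, annotations, impacts and attribution set.
#' @export
runValidation <- function(cohort, model, thetaHigh = 0.25, thetaLow = 0.10,
                          noiseScale = 0.3, seed = 1L,
                          basisMode = c("max_code_impact", "predicted_probability"),
                          k = 5L, allCodes = NULL) {
  basisMode <- match.arg(basisMode)
  spec <- cohort@spec
  if (!is(spec, "CohortSpec"))
    stop("runValidation: cohort must carry its generating CohortSpec ",
         "(the annotators' ground truth)")
  mspec <- model@spec
  if (is.null(allCodes)) allCodes <- mspec$vocabulary
  dp <- cohortDecisionPoints(cohort, H = mspec$H)
  if (!nrow(dp)) stop("runValidation: no eligible decision points in cohort")
  pats <- patients(cohort)
  names(pats) <- vapply(pats, function(p) p$patient_id, character(1))

  windows <- lapply(seq_len(nrow(dp)), function(i)
    recordWindow(pats[[dp$patient_id[i]]], dp$visit_index[i], mspec$H))

  # --- annotation benchmark -------------------------------------------------
  risks <- vapply(seq_len(nrow(dp)), function(i) {
    if (dp$mode[i] == "current") trueVisitRisk(spec, windows[[i]]$current)
    else trueWindowRisk(spec, windows[[i]])
  }, numeric(1))
  ann <- simulateAnnotators(risks, noiseScale = noiseScale, seed = seed)
  ann$scale_final <- adjudicate(ann$scale_a, ann$scale_b,
                                tiebreakFn = function(a, b)
                                  binRisk(risks[abs(ann$scale_a - ann$scale_b) > 1L]))
  annotations <- cbind(dp, ann)

  codeSetOf <- function(i) {
    w <- windows[[i]]
    if (dp$mode[i] == "current") unique(w$current$dx_codes)
    else unique(unlist(lapply(w$history, function(v) v$dx_codes)))
  }
  codeSets <- lapply(seq_len(nrow(dp)), codeSetOf)
  benchLabel <- ifelse(ann$scale_final == 1L, "high",
                       ifelse(ann$scale_final == 4L, "low", "neither"))
  isCur <- dp$mode == "current"
  benchmarkCurrent <- importanceTable(benchLabel[isCur], codeSets[isCur],
                                      allCodes = allCodes)
  benchmarkHistorical <- importanceTable(benchLabel[!isCur], codeSets[!isCur],
                                         allCodes = allCodes)

  # --- attribution side -----------------------------------------------------
  aset <- attributionBatch(model, windows)
  impacts <- codeImpactTable(aset, windows, mspec)
  preds <- aset@fX
  basis <- vapply(seq_len(nrow(dp)), function(i) {
    rows <- impacts[impacts$patient_id == dp$patient_id[i] &
                      impacts$visit_index == dp$visit_index[i], , drop = FALSE]
    recordBasis(rows, prediction = preds[i], mode = basisMode,
                which = if (isCur[i]) "current" else "historical")
  }, numeric(1))
  dshapLabel <- segmentRecords(basis, thetaHigh, thetaLow)
  dshapCurrent <- importanceTable(dshapLabel[isCur], codeSets[isCur],
                                  allCodes = allCodes)
  dshapHistorical <- importanceTable(dshapLabel[!isCur], codeSets[!isCur],
                                     allCodes = allCodes)

  list(benchmark_current = benchmarkCurrent,
       benchmark_historical = benchmarkHistorical,
       dshap_current = dshapCurrent,
       dshap_historical = dshapHistorical,
       comparison_current = compareRankings(benchmarkCurrent, dshapCurrent, k),
       comparison_historical = compareRankings(benchmarkHistorical,
                                               dshapHistorical, k),
       decision_points = dp, annotations = annotations,
       impacts = impacts, attribution = aset, basis = basis,
       settings = list(thetaHigh = thetaHigh, thetaLow = thetaLow,
                       noiseScale = noiseScale, seed = seed,
                       basisMode = basisMode,
                       record_set = "decision-point records only"))
}
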