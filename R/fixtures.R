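# Registered study fixtures. Each returns a fully parameterised CohortSpec
# (and can write it plus a drawn cohort to disk), so tests and worked examples
# construct their inputs in code rather than shipping data.
#
# Design notes:
# * paper_like emulates the published validation-cohort conditions: mean 9.3
#   scheduled records per patient, IHCA procedure codes 99.60/99.63 on about
#   11% of records, top-10 diagnosis marginals matching the published
#   frequency table (diabetes 4.93% of mentions > acute respiratory failure
#   4.81 > pneumonia 4.54 > urinary tract infection 4.19 ...), and urinary
#   tract infection co-occurrence boosts calibrated analytically so the
#   within-visit conditionals hit the published values (pneumonia 23.36%,
#   diabetes 20.72%, acute respiratory failure 19.41%, sepsis 11.51%,
#   hypertension 8.55%).
# * planted_top5 plants 5 strongly lethal codes (log-odds 2.5) among 40 null
#   background codes for the recovery test.
# * uti_confounder gives a mortality-neutral, prevalent code the published
#   co-occurrence profile with lethal comorbidities, among 50 background codes
#   with small-to-moderate real effects, to reproduce the confounding
#   discrepancy between attribution-based and annotation-based rank.

utiCooccur <- function(baseOf) {
  # boost = target conditional / base prevalence, so that
  # P(code | UTI in same visit) = min(1, base * boost) = target
  targets <- c(PNEU = 0.2336, DM = 0.2072, ARF = 0.1941, SEP = 0.1151,
               HTN = 0.0855)
  data.frame(code = names(targets), given = "UTI",
             boost = as.numeric(targets / baseOf[names(targets)]),
             stringsAsFactors = FALSE)
}

paperLikeCatalogue <- function() {
  # published mention shares (% of all diagnosis mentions), top 10
  shares <- c(DM = 4.93, ARF = 4.81, PNEU = 4.54, UTI = 4.19, SEP = 2.59,
              CHF = 2.52, HTN = 2.40, CRD = 2.01, SHOCK = 1.50, CLD = 1.50)
  labels <- c(DM = "Diabetes mellitus", ARF = "Acute respiratory failure",
              PNEU = "Pneumonia", UTI = "Urinary tract infection",
              SEP = "Sepsis", CHF = "Congestive heart failure",
              HTN = "Hypertension", CRD = "Chronic renal disease",
              SHOCK = "Shock, unspecified", CLD = "Chronic lung disease")
  logodds <- c(DM = 0.1, ARF = 1.6, PNEU = 1.0, UTI = 0, SEP = 1.4,
               CHF = 0.5, HTN = -0.2, CRD = 0.3, SHOCK = 1.5, CLD = 0.2)
  mentionsPerVisit <- 3                       # expected diagnoses per visit
  m <- shares / 100 * mentionsPerVisit        # target per-visit marginals
  q <- m[["UTI"]]
  cond <- c(PNEU = 0.2336, DM = 0.2072, ARF = 0.1941, SEP = 0.1151,
            HTN = 0.0855)
  base <- m
  base[names(cond)] <- (m[names(cond)] - cond * q) / (1 - q)
  nFill <- 30L
  fillShare <- (mentionsPerVisit - sum(m)) / nFill
  ord <- c("UTI", setdiff(names(shares), "UTI"))   # boosting code drawn first
  fill <- sprintf("DX%03d", seq_len(nFill) + 10L)
  cat_ <- codeCatalogue(
    code = c(ord, fill),
    label = c(labels[ord], paste("Background diagnosis", seq_len(nFill))),
    base_prevalence = c(base[ord], rep(fillShare, nFill)),
    mortality_logodds = c(logodds[ord], rep(0, nFill)))
  co <- data.frame(code = names(cond), given = "UTI",
                   boost = as.numeric(cond / base[names(cond)]),
                   stringsAsFactors = FALSE)
  list(catalogue = cat_, cooccur = co)
}

fixtureRegistry <- function() c("tiny_linear", "planted_top5",
                                "uti_confounder", "paper_like")

#' Construct a registered study fixture
#'
#' Registered fixtures: \describe{
#'   \item{tiny_linear}{20 patients, 3 codes, short sequences; a cohort whose
#'     death model an affine predictor can recover; fast smoke fixture.}
#'   \item{planted_top5}{5,000 patients; 5 planted strongly lethal codes
#'     (log-odds 2.5) among 40 null background codes; used by the
#'     importance-recovery check.}
#'   \item{uti_confounder}{4,000 patients; a mortality-neutral, prevalent
#'     urinary-tract-infection code whose within-visit comorbidity profile
#'     matches the published conditionals (pneumonia 23.36% etc.), among 50
#'     background codes with small-to-moderate true effects; used by the
#'     confounder-reproduction check.}
#'   \item{paper_like}{validation-cohort emulation: mean 9.3 scheduled
#'     records/patient, ~11% IHCA records, top-10 diagnosis marginals and
#'     urinary-tract-infection co-occurrence calibrated to the published
#'     tables.}}
#'
#' @param name fixture name (see above).
#' @param dir if non-NULL, write \code{<name>_spec.txt} and
#'   \code{<name>_cohort.jsonl} (drawn with \code{seed}) into this directory.
#' @param nPatients override the fixture's default cohort size.
#' @param seed override the fixture's default seed.
#' @return list with \code{spec} (a \code{CohortSpec}), \code{planted}
#'   (character vector of planted lethal codes, where applicable),
#'   \code{confounder} (the neutral co-occurring code, where applicable), and
#'   \code{files} (paths, when \code{dir} was given).
#' @export
makeFixture <- function(name, dir = NULL, nPatients = NULL, seed = NULL) {
  if (!name %in% fixtureRegistry())
    stop("makeFixture: unknown fixture '", name, "'; registered: ",
         paste(fixtureRegistry(), collapse = ", "))
  out <- switch(name,
    tiny_linear = {
      cat_ <- codeCatalogue(c("DX1", "DX2", "DX3"),
                            c("Lethal code", "Protective code", "Neutral code"),
                            base_prevalence = c(0.5, 0.4, 0.3),
                            mortality_logodds = c(2, -1, 0))
      list(spec = cohortSpec(20, cat_, visitsMean = 2, visitsDispersion = 2,
                             pIHCAVisit = 0.3, baselineLogodds = -1,
                             interVisitMeanDays = 20, seed = 11L),
           planted = "DX1")
    },
    planted_top5 = {
      lethal <- sprintf("L%02d", 1:5)
      bg <- sprintf("B%02d", 1:40)
      cat_ <- codeCatalogue(c(lethal, bg),
                            c(paste("Planted lethal", 1:5),
                              paste("Background diagnosis", 1:40)),
                            base_prevalence = c(rep(0.06, 5), rep(0.05, 40)),
                            mortality_logodds = c(rep(2.5, 5), rep(0, 40)))
      list(spec = cohortSpec(5000, cat_, visitsMean = 5, visitsDispersion = 2,
                             pIHCAVisit = 0.15, baselineLogodds = -3.5,
                             interVisitMeanDays = 30, seed = 21L),
           planted = lethal,
           study = list(hiddenDims = 16L, epochs = 30L, H = 4L,
                        initSeed = 7L, trainSeed = 5L,
                        annotatorSeed = 9L, noiseScale = 0.3))
    },
    uti_confounder = {
      named <- c(UTI = 0.12, PNEU = 0.12, ARF = 0.11, SEP = 0.06,
                 DM = 0.14, HTN = 0.056)
      logodds <- c(UTI = 0, PNEU = 1.4, ARF = 1.8, SEP = 1.8, DM = 0.1,
                   HTN = -0.1)
      labels <- c(UTI = "Urinary tract infection", PNEU = "Pneumonia",
                  ARF = "Acute respiratory failure", SEP = "Sepsis",
                  DM = "Diabetes mellitus", HTN = "Hypertension")
      bg <- sprintf("BG%02d", 1:80)
      cat_ <- codeCatalogue(c(names(named), bg),
                            c(labels, paste("Background comorbidity", 1:80)),
                            base_prevalence = c(named, rep(0.0375, 80)),
                            mortality_logodds = c(logodds,
                                                  seq(0.3, 1.2, length.out = 80)))
      list(spec = cohortSpec(8000, cat_, visitsMean = 6, visitsDispersion = 2,
                             cooccur = utiCooccur(named),
                             pIHCAVisit = 0.2, baselineLogodds = -3.8,
                             interVisitMeanDays = 30, seed = 31L),
           confounder = "UTI",
           lethal = c("PNEU", "ARF", "SEP"),
           study = list(hiddenDims = 4L, epochs = 12L, H = 4L,
                        initSeed = 7L, trainSeed = 5L,
                        annotatorSeed = 9L, noiseScale = 0.3))
    },
    paper_like = {
      pc <- paperLikeCatalogue()
      list(spec = cohortSpec(400, pc$catalogue, visitsMean = 9.3,
                             visitsDispersion = 1.5, cooccur = pc$cooccur,
                             pIHCAVisit = 0.11, baselineLogodds = -3.6,
                             interVisitMeanDays = 30, seed = 41L),
           confounder = "UTI")
    })
  if (!is.null(nPatients)) out$spec@nPatients <- as.integer(nPatients)
  if (!is.null(seed)) out$spec@seed <- as.integer(seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    specPath <- file.path(dir, paste0(name, "_spec.txt"))
    cohortPath <- file.path(dir, paste0(name, "_cohort.jsonl"))
    writeCohortSpecFile(out$spec, specPath)
    writeCohortJSONL(sampleCohort(out$spec), cohortPath)
    out$files <- c(spec = specPath, cohort = cohortPath)
  }
  out
}
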