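#' @import methods
#' @importFrom stats plogis qlogis rnorm runif rpois rnbinom rlogis cor setNames
NULL

#' Diagnosis-code catalogue constructor
#'
#' A catalogue row defines one synthetic diagnosis code: its identifier, a
#' human-readable label, the per-visit base prevalence, and an additive effect
#' on the 30-day-death log-odds. Within-visit comorbidity co-occurrence is
#' described separately (see \code{\link{cohortSpec}}).
#'
#' @param code character vector of unique ICD-9-like identifiers.
#' @param label human-readable diagnosis names (defaults to \code{code}).
#' @param base_prevalence per-visit probability of carrying the code, in [0,1].
#' @param mortality_logodds additive effect on the per-visit death log-odds.
#' @return data.frame with one row per code.
#' @examples
#' codeCatalogue(c("DX1", "DX2"), c("Pneumonia", "Sepsis"), c(0.1, 0.05), c(1.2, 1.8))
#' @export
codeCatalogue <- function(code, label = code, base_prevalence, mortality_logodds = 0) {
  code <- as.character(code)
  if (anyDuplicated(code))
    stop("codeCatalogue: duplicated code identifiers: ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  base_prevalence <- rep_len(as.numeric(base_prevalence), length(code))
  mortality_logodds <- rep_len(as.numeric(mortality_logodds), length(code))
  if (any(!is.finite(base_prevalence)) ||
      any(base_prevalence < 0) || any(base_prevalence > 1))
    stop("codeCatalogue: base_prevalence must lie in [0,1]")
  if (any(!is.finite(mortality_logodds)))
    stop("codeCatalogue: mortality_logodds must be finite")
  data.frame(code = code, label = as.character(label),
             base_prevalence = base_prevalence,
             mortality_logodds = mortality_logodds,
             stringsAsFactors = FALSE)
}

#' Class "CohortSpec": parameters of the synthetic IHCA-like cohort generator
#'
#' Encapsulates everything needed to draw a reproducible synthetic cohort:
#' the diagnosis-code catalogue with prevalences and mortality effects,
#' within-visit co-occurrence boosts, the visit-count and inter-visit-gap
#' distributions, the resuscitation procedure codes that mark an in-hospital
#' cardiac arrest (IHCA) record, and the intercept of the per-visit logistic
#' death model.
#'
#' @slot nPatients number of patients to simulate.
#' @slot visitsMean mean visits per patient (>= 1).
#' @slot visitsDispersion negative-binomial size parameter for the visit count.
#' @slot catalogue data.frame from \code{\link{codeCatalogue}}.
#' @slot cooccur data.frame (code, given, boost): multiplicative prevalence
#'   boost applied to \code{code} when \code{given} has already been drawn in
#'   the same visit (catalogue order).
#' @slot ihcaProcCodes procedure codes identifying an IHCA record.
#' @slot pIHCAVisit per-visit probability of an IHCA procedure code.
#' @slot baselineLogodds intercept of the per-visit death model.
#' @slot interVisitMeanDays mean gap between consecutive visits, days (>= 1).
#' @slot pInpatient probability a visit is inpatient (cosmetic metadata).
#' @slot seed default random seed for \code{\link{sampleCohort}}.
#' @seealso \code{\link{cohortSpec}}, \code{\link{sampleCohort}}
#' @export
setClass("CohortSpec", representation(
  nPatients = "integer",
  visitsMean = "numeric",
  visitsDispersion = "numeric",
  catalogue = "data.frame",
  cooccur = "data.frame",
  ihcaProcCodes = "character",
  pIHCAVisit = "numeric",
  baselineLogodds = "numeric",
  interVisitMeanDays = "numeric",
  pInpatient = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(length(object@nPatients) == 1 && !is.na(object@nPatients) &&
        object@nPatients >= 0L, "nPatients: must be a single integer >= 0")
  chk(length(object@visitsMean) == 1 && is.finite(object@visitsMean) &&
        object@visitsMean >= 1, "visitsMean: must be >= 1")
  chk(length(object@visitsDispersion) == 1 && is.finite(object@visitsDispersion) &&
        object@visitsDispersion > 0, "visitsDispersion: must be > 0")
  chk(all(c("code", "label", "base_prevalence", "mortality_logodds") %in%
            names(object@catalogue)),
      "catalogue: must have columns code, label, base_prevalence, mortality_logodds")
  if (nrow(object@catalogue)) {
    chk(!anyDuplicated(object@catalogue$code), "catalogue: code identifiers must be unique")
    chk(all(object@catalogue$base_prevalence >= 0 &
              object@catalogue$base_prevalence <= 1),
        "catalogue: base_prevalence must lie in [0,1]")
  }
  if (nrow(object@cooccur)) {
    chk(all(c("code", "given", "boost") %in% names(object@cooccur)),
        "cooccur: must have columns code, given, boost")
    chk(all(object@cooccur$boost >= 0), "cooccur: boost must be >= 0")
    chk(all(object@cooccur$code %in% object@catalogue$code) &&
          all(object@cooccur$given %in% object@catalogue$code),
        "cooccur: code and given must appear in the catalogue")
  }
  chk(length(object@pIHCAVisit) == 1 && object@pIHCAVisit >= 0 &&
        object@pIHCAVisit <= 1, "pIHCAVisit: must lie in [0,1]")
  chk(length(object@baselineLogodds) == 1 && is.finite(object@baselineLogodds),
      "baselineLogodds: must be finite")
  chk(length(object@interVisitMeanDays) == 1 && object@interVisitMeanDays >= 1,
      "interVisitMeanDays: must be >= 1")
  chk(length(object@pInpatient) == 1 && object@pInpatient >= 0 &&
        object@pInpatient <= 1, "pInpatient: must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Create a CohortSpec
#'
#' @param nPatients number of patients.
#' @param catalogue diagnosis-code catalogue (see \code{\link{codeCatalogue}}).
#' @param visitsMean,visitsDispersion visit-count distribution: a patient gets
#'   \code{1 + NegBin(mu = visitsMean - 1, size = visitsDispersion)} visits.
#' @param cooccur data.frame (code, given, boost) of within-visit prevalence
#'   boosts; empty by default.
#' @param ihcaProcCodes procedure codes marking an IHCA record.
#' @param pIHCAVisit per-visit probability of carrying an IHCA procedure code.
#' @param baselineLogodds intercept of the per-visit logistic death model.
#' @param interVisitMeanDays mean days between consecutive visits.
#' @param pInpatient probability a visit is flagged inpatient.
#' @param seed default seed used by \code{\link{sampleCohort}}.
#' @return a validated \code{CohortSpec} object.
#' @examples
#' sp <- cohortSpec(10, codeCatalogue("DX1", base_prevalence = 0.5))
#' @export
cohortSpec <- function(nPatients, catalogue,
                       visitsMean = 9.3, visitsDispersion = 1.5,
                       cooccur = data.frame(code = character(0),
                                            given = character(0),
                                            boost = numeric(0)),
                       ihcaProcCodes = c("99.60", "99.63"),
                       pIHCAVisit = 0.11,
                       baselineLogodds = -3.5,
                       interVisitMeanDays = 30,
                       pInpatient = 0.5,
                       seed = 1L) {
  new("CohortSpec",
      nPatients = as.integer(nPatients),
      visitsMean = as.numeric(visitsMean),
      visitsDispersion = as.numeric(visitsDispersion),
      catalogue = catalogue,
      cooccur = cooccur,
      ihcaProcCodes = as.character(ihcaProcCodes),
      pIHCAVisit = as.numeric(pIHCAVisit),
      baselineLogodds = as.numeric(baselineLogodds),
      interVisitMeanDays = as.numeric(interVisitMeanDays),
      pInpatient = as.numeric(pInpatient),
      seed = as.integer(seed))
}

#' Class "EHRCohort": a simulated (or loaded) patient cohort
#'
#' Holds an ordered list of patients, each an ordered, dated visit sequence
#' with diagnosis and procedure code sets and an optional death-day offset.
#'
#' @slot patients list of patient records (see \code{\link{patients}}).
#' @slot spec the generating \code{CohortSpec}, or NULL for loaded cohorts.
#' @slot seed the seed the cohort was drawn with (NA for loaded cohorts).
#' @export
setClass("EHRCohort", representation(
  patients = "list",
  spec = "ANY",
  seed = "integer"
))

setValidity("EHRCohort", function(object) {
  for (p in object@patients) {
    if (!all(c("patient_id", "visits") %in% names(p)))
      return("each patient needs at least patient_id and visits")
    if (!length(p$visits))
      return(sprintf("patient %s: included patients must have >= 1 visit", p$patient_id))
    offs <- vapply(p$visits, function(v) v$day_offset, numeric(1))
    idx <- vapply(p$visits, function(v) v$visit_index, numeric(1))
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      return(sprintf("patient %s: visit_index must be contiguous from 0", p$patient_id))
    if (is.unsorted(offs))
      return(sprintf("patient %s: day_offset must be non-decreasing", p$patient_id))
    dd <- p$death_day_offset
    if (!is.null(dd) && !is.na(dd) && any(offs > dd))
      return(sprintf("patient %s: visits after death", p$patient_id))
  }
  TRUE
})

#' @describeIn EHRCohort number of patients in the cohort
#' @param x,object an \code{EHRCohort}
#' @export
setMethod("length", "EHRCohort", function(x) length(x@patients))

#' Access the patient list of a cohort
#' @param x an \code{EHRCohort}
#' @return list of patients; each patient is a list with \code{patient_id},
#'   \code{sex}, \code{age_at_first_visit}, \code{visits} (list of visits with
#'   \code{visit_index}, \code{day_offset}, \code{setting}, \code{dx_codes},
#'   \code{proc_codes}) and \code{death_day_offset} (NA if alive).
#' @export
patients <- function(x) x@patients

#' Access the generating spec of a cohort (NULL for loaded cohorts)
#' @param x an \code{EHRCohort}
#' @export
cohortSpecOf <- function(x) x@spec

setMethod("show", "EHRCohort", function(object) {
  nv <- sum(vapply(object@patients, function(p) length(p$visits), numeric(1)))
  nd <- sum(vapply(object@patients, function(p)
    !is.null(p$death_day_offset) && !is.na(p$death_day_offset), logical(1)))
  cat(sprintf("EHRCohort: %d patients, %d visits, %d deaths (%.1f%%)\n",
              length(object@patients), nv, nd,
              if (length(object@patients)) 100 * nd / length(object@patients) else 0))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d patients, %d codes, %d co-occurrence boosts\n",
                     "  visits/patient ~ 1 + NB(mu=%.2f, size=%.2f); ",
                     "baseline log-odds %.2f; P(IHCA visit)=%.3f\n"),
              object@nPatients, nrow(object@catalogue), nrow(object@cooccur),
              object@visitsMean - 1, object@visitsDispersion,
              object@baselineLogodds, object@pIHCAVisit))
})
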