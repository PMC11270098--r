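# Synthetic IHCA-like cohort generation.
#
# Each patient gets an independent RNG substream derived deterministically from
# (master seed, patient index), so cohorts are reproducible and insensitive to
# the order in which patients are materialised.

patientSeed <- function(seed, i) {
  # deterministic substream; stays inside 32-bit integer range
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629)
}

drawVisitCodes <- function(cat, cooccur, u = NULL) {
  n <- nrow(cat)
  if (!n) return(character(0))
  if (is.null(u)) u <- runif(n)
  p <- cat$base_prevalence
  if (!nrow(cooccur)) return(cat$code[u < p])
  present <- logical(n)
  rownames_idx <- match(cooccur$code, cat$code)
  given_idx <- match(cooccur$given, cat$code)
  boosted <- unique(rownames_idx)
  # codes without incoming boosts are independent draws
  plain <- setdiff(seq_len(n), boosted)
  present[plain] <- u[plain] < p[plain]
  # boosted codes drawn in catalogue order, conditioning on codes already drawn
  for (j in sort(boosted)) {
    pj <- p[j]
    rows <- which(rownames_idx == j)
    for (r in rows) {
      g <- given_idx[r]
      if (g < j && present[g]) pj <- pj * cooccur$boost[r]
    }
    present[j] <- u[j] < min(1, max(0, pj))
  }
  cat$code[present]
}

#' Draw a synthetic cohort
#'
#' Samples \code{spec@nPatients} patients. Visit counts are
#' \code{1 + NegBin(mu = visitsMean - 1, size = visitsDispersion)}; diagnosis
#' codes are drawn per visit in catalogue order with co-occurrence boosts
#' applied conditionally on codes already drawn in the same visit; each visit
#' independently carries an IHCA procedure code with probability
#' \code{pIHCAVisit}. Death is planted by the per-visit logistic model of
#' \code{\link{plantMortality}} and visits after death are truncated.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param seed master seed; defaults to \code{spec@seed}. Identical
#'   \code{(spec, seed)} pairs give identical cohorts.
#' @return an \code{\link{EHRCohort}}.
#' @examples
#' sp <- cohortSpec(5, codeCatalogue("DX1", base_prevalence = 1), visitsMean = 2)
#' sampleCohort(sp, seed = 1)
#' @export
sampleCohort <- function(spec, seed = spec@seed) {
  validObject(spec)
  n <- spec@nPatients
  cat_ <- spec@catalogue
  pats <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patientSeed(seed, i))
    nv <- 1L + rnbinom(1, size = spec@visitsDispersion, mu = spec@visitsMean - 1)
    gaps <- if (nv > 1) 1L + rpois(nv - 1, max(0, spec@interVisitMeanDays - 1)) else integer(0)
    offs <- cumsum(c(0L, gaps))
    sex <- if (runif(1) < 0.5) "F" else "M"
    age <- min(118, max(0, round(rnorm(1, 69, 17))))
    visits <- vector("list", nv)
    for (k in seq_len(nv)) {
      dx <- drawVisitCodes(cat_, spec@cooccur)
      proc <- character(0)
      if (spec@pIHCAVisit > 0 && runif(1) < spec@pIHCAVisit)
        proc <- spec@ihcaProcCodes[1L + (runif(1) < 0.5)]
      visits[[k]] <- list(visit_index = k - 1L,
                          day_offset = as.integer(offs[k]),
                          setting = if (runif(1) < spec@pInpatient) "inpatient" else "outpatient",
                          dx_codes = dx, proc_codes = proc)
    }
    pat <- list(patient_id = sprintf("P%06d", i), sex = sex,
                age_at_first_visit = age, visits = visits,
                death_day_offset = NA_integer_)
    pat$death_day_offset <- plantMortality(spec, pat)
    if (!is.na(pat$death_day_offset)) {
      keep <- vapply(pat$visits, function(v) v$day_offset <= pat$death_day_offset,
                     logical(1))
      pat$visits <- pat$visits[keep]
    }
    pats[[i]] <- pat
  }
  new("EHRCohort", patients = pats, spec = spec, seed = as.integer(seed))
}

#' Plant a death time on a generated visit sequence
#'
#' After each visit, death within the next 30 days occurs with probability
#' \code{plogis(baselineLogodds + sum of mortality_logodds of the visit's
#' codes)}; when triggered, the death day is uniform on
#' \code{(day_offset, day_offset + 30]} and later visits are ignored.
#'
#' Called by \code{\link{sampleCohort}} within the patient's RNG substream;
#' when used standalone, pass \code{seed} to make the draw reproducible.
#'
#' @param spec the \code{CohortSpec} supplying the death model.
#' @param patient a patient list with generated visits.
#' @param seed optional seed (the caller's RNG state is used if NULL).
#' @return integer death day offset, or NA if the patient survives all visits.
#' @export
plantMortality <- function(spec, patient, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- spec@catalogue$mortality_logodds
  names(lo) <- spec@catalogue$code
  for (v in patient$visits) {
    eta <- spec@baselineLogodds + sum(lo[v$dx_codes])
    if (runif(1) < plogis(eta))
      return(as.integer(v$day_offset + sample.int(30L, 1L)))
  }
  NA_integer_
}

#' 30-day mortality label for one visit
#'
#' TRUE iff the patient has a recorded death and it falls within 30 days of
#' the visit, boundary inclusive (a death exactly 30 days after the visit
#' counts), and not before the visit.
#'
#' @param patient patient list (needs \code{death_day_offset}).
#' @param visit one visit of that patient.
#' @return logical.
#' @export
label30DayMortality <- function(patient, visit) {
  dd <- patient$death_day_offset
  if (is.null(dd) || is.na(dd)) return(FALSE)
  delta <- dd - visit$day_offset
  delta >= 0 && delta <= 30
}

#' Restrict a cohort to patients with at least one IHCA record
#'
#' A record is an IHCA record when its procedure codes intersect the spec's
#' resuscitation codes (default 99.60, 99.63).
#'
#' @param cohort an \code{EHRCohort}.
#' @param ihcaProcCodes procedure codes defining IHCA; defaults to the
#'   cohort spec's codes (or 99.60/99.63 for loaded cohorts).
#' @return an \code{EHRCohort} containing exactly the qualifying patients.
#' @export
buildIHCASubset <- function(cohort, ihcaProcCodes = NULL) {
  if (is.null(ihcaProcCodes))
    ihcaProcCodes <- if (is(cohort@spec, "CohortSpec"))
      cohort@spec@ihcaProcCodes else c("99.60", "99.63")
  keep <- vapply(cohort@patients, function(p)
    any(vapply(p$visits, function(v) length(intersect(v$proc_codes, ihcaProcCodes)) > 0,
               logical(1))), logical(1))
  new("EHRCohort", patients = cohort@patients[keep],
      spec = cohort@spec, seed = cohort@seed)
}

isIHCAVisit <- function(visit, ihcaProcCodes) {
  length(intersect(visit$proc_codes, ihcaProcCodes)) > 0
}

#' Summary statistics of a cohort
#'
#' Computes the bookkeeping quantities used to describe an IHCA claims cohort:
#' record counts, IHCA-record share, patient mortality, the share of deaths
#' occurring within 30 days of the first IHCA record ("first arrest
#' hospitalization" deaths), and the share of patients with exactly one
#' IHCA record.
#'
#' @param cohort an \code{EHRCohort}.
#' @param ihcaProcCodes IHCA procedure codes (default from the spec).
#' @return named list of counts and percentages.
#' @export
summarizeCohort <- function(cohort, ihcaProcCodes = NULL) {
  if (is.null(ihcaProcCodes))
    ihcaProcCodes <- if (is(cohort@spec, "CohortSpec"))
      cohort@spec@ihcaProcCodes else c("99.60", "99.63")
  np <- length(cohort@patients)
  nrec <- 0L; nihca <- 0L; deaths <- 0L; firstArrestDeaths <- 0L
  once <- 0L
  for (p in cohort@patients) {
    nrec <- nrec + length(p$visits)
    iv <- vapply(p$visits, isIHCAVisit, logical(1), ihcaProcCodes = ihcaProcCodes)
    nihca <- nihca + sum(iv)
    if (sum(iv) == 1L) once <- once + 1L
    dead <- !is.null(p$death_day_offset) && !is.na(p$death_day_offset)
    if (dead) {
      deaths <- deaths + 1L
      if (any(iv)) {
        firstIhcaDay <- p$visits[[which(iv)[1]]]$day_offset
        if (p$death_day_offset - firstIhcaDay <= 30 &&
            p$death_day_offset - firstIhcaDay >= 0)
          firstArrestDeaths <- firstArrestDeaths + 1L
      }
    }
  }
  list(n_patients = np, n_records = nrec, n_ihca_records = nihca,
       ihca_record_pct = if (nrec) 100 * nihca / nrec else 0,
       mean_records_per_patient = if (np) nrec / np else 0,
       n_deaths = deaths,
       mortality_pct = if (np) 100 * deaths / np else 0,
       first_arrest_death_pct = if (deaths) 100 * firstArrestDeaths / deaths else 0,
       single_arrest_pct = if (np) 100 * once / np else 0)
}

#' Cohort arithmetic from published summary counts
#'
#' Recomputes the derived cohort statistics from raw bookkeeping counts, as
#' used when checking a published cohort description: records excluded by the
#' dental/traditional-medicine/local-clinic filter, mean analyzed records per
#' patient, the IHCA share of analyzed records, patient mortality, the share
#' of deaths during the first arrest hospitalization, and the share of
#' single-arrest patients.
#'
#' @param counts named list/vector with \code{total_records},
#'   \code{analyzed_records}, \code{n_patients}, \code{ihca_records},
#'   \code{deaths}, \code{first_arrest_deaths}, \code{single_arrest_patients}.
#' @return named list of derived quantities (percentages on the 0-100 scale).
#' @examples
#' cohortArithmetic(list(total_records = 100, analyzed_records = 60,
#'   n_patients = 10, ihca_records = 12, deaths = 5,
#'   first_arrest_deaths = 4, single_arrest_patients = 9))
#' @export
cohortArithmetic <- function(counts) {
  counts <- as.list(counts)
  need <- c("total_records", "analyzed_records", "n_patients", "ihca_records",
            "deaths", "first_arrest_deaths", "single_arrest_patients")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("cohortArithmetic: missing counts: ", paste(miss, collapse = ", "))
  with(counts, list(
    excluded_records = total_records - analyzed_records,
    mean_records_per_patient = analyzed_records / n_patients,
    ihca_record_pct = 100 * ihca_records / analyzed_records,
    mortality_pct = 100 * deaths / n_patients,
    first_arrest_death_pct = 100 * first_arrest_deaths / deaths,
    single_arrest_pct = 100 * single_arrest_patients / n_patients))
}

#' Expected marginal code probabilities under a spec
#'
#' Computes, in catalogue order, the expected per-visit presence probability of
#' each code, accounting for co-occurrence boosts by enumerating presence
#' patterns of each code's boosting predecessors (predecessors are treated as
#' independent, which is exact when boosting codes are not themselves boosted
#' by one another).
#'
#' @param spec a \code{CohortSpec}.
#' @return named numeric vector of per-visit presence probabilities; the
#'   attribute \code{"mention_share"} carries each code's expected share of
#'   all diagnosis mentions.
#' @export
expectedCodeShares <- function(spec) {
  cat_ <- spec@catalogue
  co <- spec@cooccur
  n <- nrow(cat_)
  marg <- numeric(n)
  names(marg) <- cat_$code
  for (j in seq_len(n)) {
    rows <- co[match(co$code, cat_$code) == j & match(co$given, cat_$code) < j, ,
               drop = FALSE]
    base <- cat_$base_prevalence[j]
    if (!nrow(rows)) { marg[j] <- base; next }
    g <- match(rows$given, cat_$code)
    m <- nrow(rows)
    p <- 0
    for (mask in 0:(2^m - 1)) {
      on <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
      w <- prod(ifelse(on, marg[g], 1 - marg[g]))
      p <- p + w * min(1, base * prod(rows$boost[on]))
    }
    marg[j] <- p
  }
  share <- if (sum(marg) > 0) marg / sum(marg) else marg
  attr(marg, "mention_share") <- share
  marg
}

#' Observed diagnosis-mention shares in a cohort
#'
#' @param cohort an \code{EHRCohort}.
#' @return named numeric vector: each code's share of all diagnosis mentions
#'   (sums to 1), with attribute \code{"n_mentions"}.
#' @export
observedCodeShares <- function(cohort) {
  all_dx <- unlist(lapply(cohort@patients, function(p)
    unlist(lapply(p$visits, function(v) v$dx_codes))))
  tab <- table(all_dx)
  share <- as.numeric(tab) / sum(tab)
  names(share) <- names(tab)
  attr(share, "n_mentions") <- length(all_dx)
  share
}
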