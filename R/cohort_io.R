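# Cohort readers/writers: patient-per-line JSONL and flat visit-level CSV,
# plus the plain-text generator spec format. All outputs are UTF-8 text.

patientToList <- function(p) {
  list(patient_id = p$patient_id,
       sex = p$sex,
       age_at_first_visit = p$age_at_first_visit,
       death_day_offset = if (is.null(p$death_day_offset) || is.na(p$death_day_offset))
         NULL else as.integer(p$death_day_offset),
       visits = lapply(p$visits, function(v)
         list(visit_index = as.integer(v$visit_index),
              day_offset = as.integer(v$day_offset),
              setting = v$setting,
              dx_codes = as.list(as.character(v$dx_codes)),
              proc_codes = as.list(as.character(v$proc_codes)))))
}

#' Write a cohort as patient-per-line JSONL
#'
#' @param cohort an \code{EHRCohort}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCohortJSONL <- function(cohort, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in cohort@patients)
    writeLines(jsonlite::toJSON(patientToList(p), auto_unbox = TRUE, null = "null"),
               con)
  invisible(path)
}

#' Read a JSONL cohort written by \code{\link{writeCohortJSONL}}
#'
#' @param path input file.
#' @return an \code{EHRCohort} (spec slot NULL, seed NA).
#' @export
readCohortJSONL <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  pats <- lapply(seq_along(lines), function(i) {
    p <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("readCohortJSONL: line %d: %s", i, conditionMessage(e))))
    list(patient_id = p$patient_id,
         sex = p$sex,
         age_at_first_visit = p$age_at_first_visit,
         visits = lapply(p$visits, function(v)
           list(visit_index = as.integer(v$visit_index),
                day_offset = as.integer(v$day_offset),
                setting = v$setting,
                dx_codes = as.character(unlist(v$dx_codes)),
                proc_codes = as.character(unlist(v$proc_codes)))),
         death_day_offset = if (is.null(p$death_day_offset)) NA_integer_
                            else as.integer(p$death_day_offset))
  })
  new("EHRCohort", patients = pats, spec = NULL, seed = NA_integer_)
}

#' Write a cohort as a flat visit-level CSV
#'
#' One row per visit; code sets are pipe-delimited. Columns: patient_id,
#' visit_index, day_offset, setting, dx_codes, proc_codes, death_day_offset.
#'
#' @param cohort an \code{EHRCohort}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort@patients, function(p) {
    dd <- if (is.null(p$death_day_offset) || is.na(p$death_day_offset)) ""
          else as.character(p$death_day_offset)
    do.call(rbind, lapply(p$visits, function(v)
      data.frame(patient_id = p$patient_id,
                 visit_index = v$visit_index,
                 day_offset = v$day_offset,
                 setting = v$setting,
                 dx_codes = paste(v$dx_codes, collapse = "|"),
                 proc_codes = paste(v$proc_codes, collapse = "|"),
                 death_day_offset = dd,
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(rows))
    rows <- data.frame(patient_id = character(0), visit_index = integer(0),
                       day_offset = integer(0), setting = character(0),
                       dx_codes = character(0), proc_codes = character(0),
                       death_day_offset = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a visit-level CSV cohort
#'
#' @param path file written by \code{\link{writeCohortCSV}}.
#' @return an \code{EHRCohort}.
#' @export
readCohortCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(death_day_offset = "character",
                                       dx_codes = "character",
                                       proc_codes = "character",
                                       patient_id = "character"))
  splitCodes <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  }
  pats <- lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
                 function(d) {
    d <- d[order(d$visit_index), , drop = FALSE]
    dd <- d$death_day_offset[1]
    list(patient_id = d$patient_id[1], sex = NA_character_,
         age_at_first_visit = NA_real_,
         visits = lapply(seq_len(nrow(d)), function(k)
           list(visit_index = as.integer(d$visit_index[k]),
                day_offset = as.integer(d$day_offset[k]),
                setting = d$setting[k],
                dx_codes = splitCodes(d$dx_codes[k]),
                proc_codes = splitCodes(d$proc_codes[k]))),
         death_day_offset = if (is.na(dd) || !nzchar(dd)) NA_integer_ else as.integer(dd))
  })
  names(pats) <- NULL
  new("EHRCohort", patients = pats, spec = NULL, seed = NA_integer_)
}

# ---- generator spec file -----------------------------------------------------
# Flat `key = value` lines, then a `codes:` section (TSV: code label
# base_prevalence mortality_logodds) and an optional `cooccur:` section
# (TSV: code given boost). '#' starts a comment. Parse errors name the line.

specFileFields <- c("n_patients", "visits_mean", "visits_dispersion",
                    "ihca_proc_codes", "p_ihca_visit", "baseline_logodds",
                    "inter_visit_mean_days", "p_inpatient", "seed")

#' Read a cohort generator spec from its plain-text format
#'
#' The format is flat \code{key = value} pairs followed by a \code{codes:}
#' table (tab- or multi-space-separated: code, label, base_prevalence,
#' mortality_logodds) and an optional \code{cooccur:} table (code, given,
#' boost). Parse errors name the offending line and field.
#'
#' @param path spec file.
#' @return a \code{\link{CohortSpec}}.
#' @export
readCohortSpecFile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  strip <- function(s) sub("\\s+$", "", sub("^\\s+", "", sub("#.*$", "", s)))
  kv <- list(); codes <- list(); co <- list()
  section <- "kv"
  bad <- function(i, msg) stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
  for (i in seq_along(lines)) {
    s <- strip(lines[[i]])
    if (!nzchar(s)) next
    if (identical(s, "codes:")) { section <- "codes"; next }
    if (identical(s, "cooccur:")) { section <- "cooccur"; next }
    if (section == "kv") {
      if (!grepl("=", s, fixed = TRUE)) bad(i, "expected `key = value`")
      key <- strip(sub("=.*$", "", s)); val <- strip(sub("^[^=]*=", "", s))
      if (!key %in% specFileFields)
        bad(i, sprintf("unknown field '%s'", key))
      kv[[key]] <- val
    } else {
      parts <- strsplit(s, "[\t ]+")[[1]]
      if (section == "codes") {
        if (identical(tolower(parts[1]), "code")) next  # header row
        if (length(parts) < 4)
          bad(i, "codes row needs: code label base_prevalence mortality_logodds")
        pv <- suppressWarnings(as.numeric(parts[length(parts) - 1]))
        lo <- suppressWarnings(as.numeric(parts[length(parts)]))
        if (is.na(pv)) bad(i, "field base_prevalence: not a number")
        if (is.na(lo)) bad(i, "field mortality_logodds: not a number")
        codes[[length(codes) + 1]] <- list(
          code = parts[1],
          label = paste(parts[2:(length(parts) - 2)], collapse = " "),
          base_prevalence = pv, mortality_logodds = lo)
      } else {
        if (identical(tolower(parts[1]), "code")) next
        if (length(parts) != 3) bad(i, "cooccur row needs: code given boost")
        b <- suppressWarnings(as.numeric(parts[3]))
        if (is.na(b)) bad(i, "field boost: not a number")
        co[[length(co) + 1]] <- list(code = parts[1], given = parts[2], boost = b)
      }
    }
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop(sprintf("%s: field %s: not a number", path, key), call. = FALSE)
    v
  }
  if (!length(codes)) stop(path, ": missing codes: section", call. = FALSE)
  cataframe <- do.call(rbind, lapply(codes, as.data.frame, stringsAsFactors = FALSE))
  coframe <- if (length(co))
    do.call(rbind, lapply(co, as.data.frame, stringsAsFactors = FALSE))
  else data.frame(code = character(0), given = character(0), boost = numeric(0))
  cohortSpec(nPatients = num("n_patients", 100),
             catalogue = codeCatalogue(cataframe$code, cataframe$label,
                                       cataframe$base_prevalence,
                                       cataframe$mortality_logodds),
             visitsMean = num("visits_mean", 9.3),
             visitsDispersion = num("visits_dispersion", 1.5),
             cooccur = coframe,
             ihcaProcCodes = if (is.null(kv$ihca_proc_codes)) c("99.60", "99.63")
                             else strsplit(kv$ihca_proc_codes, ",")[[1]],
             pIHCAVisit = num("p_ihca_visit", 0.11),
             baselineLogodds = num("baseline_logodds", -3.5),
             interVisitMeanDays = num("inter_visit_mean_days", 30),
             pInpatient = num("p_inpatient", 0.5),
             seed = num("seed", 1))
}

#' Write a cohort generator spec in the plain-text format
#'
#' @param spec a \code{CohortSpec}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCohortSpecFile <- function(spec, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("n_patients = %d", spec@nPatients)
  w("visits_mean = %.6g", spec@visitsMean)
  w("visits_dispersion = %.6g", spec@visitsDispersion)
  w("ihca_proc_codes = %s", paste(spec@ihcaProcCodes, collapse = ","))
  w("p_ihca_visit = %.6g", spec@pIHCAVisit)
  w("baseline_logodds = %.6g", spec@baselineLogodds)
  w("inter_visit_mean_days = %.6g", spec@interVisitMeanDays)
  w("p_inpatient = %.6g", spec@pInpatient)
  w("seed = %d", spec@seed)
  w("codes:")
  ct <- spec@catalogue
  for (j in seq_len(nrow(ct)))
    w("%s\t%s\t%.8g\t%.8g", ct$code[j], gsub("[\t ]+", "_", ct$label[j]),
      ct$base_prevalence[j], ct$mortality_logodds[j])
  if (nrow(spec@cooccur)) {
    w("cooccur:")
    for (j in seq_len(nrow(spec@cooccur)))
      w("%s\t%s\t%.8g", spec@cooccur$code[j], spec@cooccur$given[j],
        spec@cooccur$boost[j])
  }
  invisible(path)
}
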