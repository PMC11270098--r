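# Expert-annotation protocol and importance statistics.
#
# Validation patients contribute 9 judgment units ("decision points"): the
# fatal IHCA record plus its 4 predecessors judged on their own codes (5
# current points), and the last 4 of those records judged together with their
# preceding window (4 historical points). Annotations are ordinal 1-4
# (1 = high probability of 30-day mortality ... 4 = very low). Per-code
# statistics over the high (scale-1 / high-impact) and low (scale-4 /
# low-impact) strata: count-high, count-low, high-ratio, low-ratio, and
# importance = high-ratio - low-ratio, used for ranking.

#' Decision points for one validation patient
#'
#' A patient qualifies when some IHCA record carries a positive 30-day
#' mortality label and has at least 4 prior records; patients with fewer prior
#' records are excluded (recorded in the \code{"excluded"} attribute). The
#' qualifying record and its 4 predecessors give 5 current points; the last 4
#' of those records give historical points (each judged with its own preceding
#' window).
#'
#' @param patient a patient list.
#' @param H history depth (4).
#' @param ihcaProcCodes procedure codes defining an IHCA record.
#' @return data.frame (patient_id, visit_index, mode) with 9 rows for an
#'   eligible patient, else 0 rows; attribute \code{"excluded"} holds an
#'   exclusion reason or NA.
#' @export
buildDecisionPoints <- function(patient, H = 4L,
                                ihcaProcCodes = c("99.60", "99.63")) {
  empty <- data.frame(patient_id = character(0), visit_index = integer(0),
                      mode = character(0), stringsAsFactors = FALSE)
  qual <- NA_integer_
  reason <- NA_character_
  for (k in seq_along(patient$visits)) {
    v <- patient$visits[[k]]
    if (isIHCAVisit(v, ihcaProcCodes) && label30DayMortality(patient, v)) {
      if (k - 1L >= H) { qual <- k; break }
      reason <- sprintf("IHCA mortality record at visit %d has only %d prior records (<%d)",
                        k - 1L, k - 1L, H)
    }
  }
  if (is.na(qual)) {
    if (is.na(reason)) reason <- "no IHCA record with positive 30-day mortality label"
    attr(empty, "excluded") <- reason
    return(empty)
  }
  idx <- (qual - H):qual - 1L            # 0-based indices of the 5 records
  out <- rbind(
    data.frame(patient_id = patient$patient_id, visit_index = idx,
               mode = "current", stringsAsFactors = FALSE),
    data.frame(patient_id = patient$patient_id, visit_index = idx[-1],
               mode = "historical", stringsAsFactors = FALSE))
  attr(out, "excluded") <- NA_character_
  out
}

#' Decision points for every eligible patient of a cohort
#'
#' @param cohort an \code{EHRCohort}.
#' @param H history depth.
#' @param ihcaProcCodes IHCA procedure codes (default from the spec).
#' @return data.frame of decision points; attribute \code{"n_excluded"} counts
#'   patients with a qualifying record but insufficient history.
#' @export
cohortDecisionPoints <- function(cohort, H = 4L, ihcaProcCodes = NULL) {
  if (is.null(ihcaProcCodes))
    ihcaProcCodes <- if (is(cohort@spec, "CohortSpec"))
      cohort@spec@ihcaProcCodes else c("99.60", "99.63")
  parts <- lapply(cohort@patients, buildDecisionPoints, H = H,
                  ihcaProcCodes = ihcaProcCodes)
  nExcl <- sum(vapply(parts, function(d)
    !nrow(d) && grepl("prior records", attr(d, "excluded") %||% ""), logical(1)))
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(patient_id = character(0), visit_index = integer(0),
                      mode = character(0))
  attr(out, "n_excluded") <- nExcl
  out
}

#' Simulated ordinal annotators
#'
#' Two independent annotators judge a record's true mortality risk on the 1-4
#' scale. Each annotator perturbs the risk on the log-odds scale with logistic
#' noise, then bins with fixed cut-points on the risk scale: risk >= 0.5 ->
#' scale 1, >= 0.2 -> 2, >= 0.05 -> 3, else 4.
#'
#' @param pointTruthRisk true risk(s) in [0,1] (vectorised).
#' @param noiseScale scale of the logistic perturbation (0 = deterministic).
#' @param seed RNG seed.
#' @param cutpoints strictly decreasing risk cut-points for scales 1/2/3.
#' @return data.frame (scale_a, scale_b), one row per risk.
#' @export
simulateAnnotators <- function(pointTruthRisk, noiseScale = 0.3, seed = 1L,
                               cutpoints = c(0.5, 0.2, 0.05)) {
  if (any(pointTruthRisk < 0 | pointTruthRisk > 1))
    stop("simulateAnnotators: risks must lie in [0,1]")
  if (length(cutpoints) != 3 || any(diff(cutpoints) >= 0))
    stop("simulateAnnotators: cutpoints must be 3 strictly decreasing values")
  set.seed(seed)
  n <- length(pointTruthRisk)
  draw <- function() {
    r <- pointTruthRisk
    if (noiseScale > 0) {
      eta <- qlogis(pmin(pmax(r, 1e-12), 1 - 1e-12)) + rlogis(n, 0, noiseScale)
      r <- plogis(eta)
    }
    binRisk(r, cutpoints)
  }
  data.frame(scale_a = draw(), scale_b = draw())
}

binRisk <- function(r, cutpoints = c(0.5, 0.2, 0.05)) {
  ifelse(r >= cutpoints[1], 1L,
         ifelse(r >= cutpoints[2], 2L, ifelse(r >= cutpoints[3], 3L, 4L)))
}

#' Adjudicate two ordinal annotations
#'
#' When the two scales differ by at most 1 the more severe (numerically lower)
#' is kept; a larger disagreement is referred to \code{tiebreakFn} (a simulated
#' senior adjudicator, e.g. binning the true risk noise-free).
#'
#' @param scaleA,scaleB annotations in 1..4 (vectorised).
#' @param tiebreakFn function(a, b) returning the final scale(s) for the
#'   referred cases; default takes the rounded midpoint.
#' @param combine for the |a-b| <= 1 case: "severe" (default, min) or
#'   "mean_round".
#' @return integer vector of final scales.
#' @export
adjudicate <- function(scaleA, scaleB,
                       tiebreakFn = function(a, b) as.integer(round((a + b) / 2)),
                       combine = c("severe", "mean_round")) {
  combine <- match.arg(combine)
  scaleA <- as.integer(scaleA); scaleB <- as.integer(scaleB)
  if (any(c(scaleA, scaleB) < 1L) || any(c(scaleA, scaleB) > 4L))
    stop("adjudicate: scales must lie in 1..4")
  out <- if (combine == "severe") pmin(scaleA, scaleB)
         else as.integer(round((scaleA + scaleB) / 2))
  far <- abs(scaleA - scaleB) > 1L
  if (any(far)) out[far] <- as.integer(tiebreakFn(scaleA[far], scaleB[far]))
  out
}

#' Segment records into high / low / neither impact strata
#'
#' Thresholds are inclusive exactly as stated: value >= thetaHigh -> "high",
#' value <= thetaLow -> "low", otherwise "neither".
#'
#' @param basisValues numeric record-basis values (see \code{\link{recordBasis}}).
#' @param thetaHigh high-impact threshold (default 0.25).
#' @param thetaLow low-impact threshold (default 0.10).
#' @return character vector of labels.
#' @export
segmentRecords <- function(basisValues, thetaHigh = 0.25, thetaLow = 0.10) {
  if (!(thetaLow < thetaHigh))
    stop("segmentRecords: thetaLow must be < thetaHigh")
  ifelse(basisValues >= thetaHigh, "high",
         ifelse(basisValues <= thetaLow, "low", "neither"))
}

#' Per-code importance table over labelled records
#'
#' Each record carries a stratum label (high / low / neither) and a code set;
#' a code counts at most once per record. count-high (count-low) is the number
#' of high (low) records containing the code; high-ratio and low-ratio divide
#' by the total number of high and low records; importance = high-ratio -
#' low-ratio. Rows are sorted by importance descending, ties broken by code
#' ascending; ranks are 1-based.
#'
#' @param labels character vector of record labels ("high"/"low"/"neither").
#' @param codeSets list of character vectors, one per record.
#' @param allCodes optional universe of codes to include as zero rows.
#' @return data.frame (code, count_high, count_low, high_ratio, low_ratio,
#'   importance, rank) with attributes \code{"total_high"}, \code{"total_low"}.
#' @export
importanceTable <- function(labels, codeSets, allCodes = NULL) {
  if (length(labels) != length(codeSets))
    stop("importanceTable: labels and codeSets differ in length")
  totalHigh <- sum(labels == "high")
  totalLow <- sum(labels == "low")
  if (totalHigh == 0 && totalLow == 0)
    stop("importanceTable: empty strata: no high and no low records")
  codes <- sort(unique(c(unlist(codeSets), allCodes)))
  countIn <- function(lab) {
    sets <- codeSets[labels == lab]
    if (!length(sets)) return(setNames(integer(length(codes)), codes))
    tab <- table(factor(unlist(lapply(sets, unique)), levels = codes))
    setNames(as.integer(tab), codes)
  }
  ch <- countIn("high"); cl <- countIn("low")
  hr <- if (totalHigh > 0) ch / totalHigh else ch * 0
  lr <- if (totalLow > 0) cl / totalLow else cl * 0
  df <- data.frame(code = codes, count_high = ch, count_low = cl,
                   high_ratio = as.numeric(hr), low_ratio = as.numeric(lr),
                   importance = as.numeric(hr - lr),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$importance, df$code), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "total_high") <- totalHigh
  attr(df, "total_low") <- totalLow
  df
}

#' Compare two importance rankings
#'
#' @param benchmark,dshap ranked importance tables (from
#'   \code{\link{importanceTable}} or equivalent, with columns code and rank).
#' @param k size of the top-k overlap.
#' @return list: \code{top_k_overlap}, \code{k}, \code{rank_correlation}
#'   (tie-corrected Kendall rank correlation over the code union, absent codes
#'   ranked last) and the merged per-code rank table.
#' @export
compareRankings <- function(benchmark, dshap, k = 5L) {
  topk <- function(df) df$code[order(df$rank)][seq_len(min(k, nrow(df)))]
  overlap <- length(intersect(topk(benchmark), topk(dshap)))
  codes <- union(benchmark$code, dshap$code)
  rb <- benchmark$rank[match(codes, benchmark$code)]
  rd <- dshap$rank[match(codes, dshap$code)]
  rb[is.na(rb)] <- nrow(benchmark) + 1L
  rd[is.na(rd)] <- nrow(dshap) + 1L
  rho <- if (length(codes) > 1) cor(rb, rd, method = "kendall") else 1
  list(top_k_overlap = overlap, k = as.integer(k), rank_correlation = rho,
       ranks = data.frame(code = codes, benchmark_rank = rb, dshap_rank = rd,
                          stringsAsFactors = FALSE))
}

#' Recover an integer stratum total from printed percentages
#'
#' Published importance tables print high/low ratios to two decimals but not
#' always the stratum sizes. A candidate total T is feasible when every
#' printed percentage is attainable as \code{100 * k / T} for some integer
#' \code{0 <= k <= T} within half a unit of the last printed digit (and, when
#' counts are printed, when \code{100 * count / T} rounds to the printed
#' percentage).
#'
#' @param ratiosPct printed percentages (0-100 scale, 2 decimals).
#' @param counts optional printed integer counts aligned with ratiosPct.
#' @param searchMax largest total to consider.
#' @param tol half-width of the rounding interval (default 0.005 percentage
#'   points, i.e. round-to-two-decimals).
#' @return integer vector of all feasible totals, smallest first.
#' @export
recoverStratumTotal <- function(ratiosPct, counts = NULL, searchMax = 2000L,
                                tol = 0.005) {
  tol <- tol + 1e-9
  feasible <- integer(0)
  for (T in seq_len(searchMax)) {
    ok <- if (!is.null(counts)) {
      all(abs(100 * counts / T - ratiosPct) <= tol)
    } else {
      all(vapply(ratiosPct, function(r) {
        kk <- round(r * T / 100)
        any(abs(100 * pmax(0, pmin(T, kk + (-1:1))) / T - r) <= tol)
      }, logical(1)))
    }
    if (ok) feasible <- c(feasible, T)
  }
  feasible
}

#' Importance identity from printed ratios
#'
#' @param highRatioPct,lowRatioPct printed percentages.
#' @return importance on the percentage scale (high minus low).
#' @export
importanceFromRatios <- function(highRatioPct, lowRatioPct)
  highRatioPct - lowRatioPct

#' Write / read an importance table as TSV
#'
#' Header \code{diagnosis, count_high, count_low, high_ratio, low_ratio,
#' importance, rank}; ratios and importance are written as fractions.
#'
#' @param tab importance table.
#' @param path file path.
#' @param meta optional named metadata vector (\code{#}-prefixed header).
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
writeImportanceTSV <- function(tab, path, meta = NULL) {
  out <- data.frame(diagnosis = tab$code, count_high = tab$count_high,
                    count_low = tab$count_low, high_ratio = tab$high_ratio,
                    low_ratio = tab$low_ratio, importance = tab$importance,
                    rank = tab$rank)
  writeTableWithMeta(out, path, meta, sep = "\t")
}

#' @rdname writeImportanceTSV
#' @export
readImportanceTSV <- function(path) {
  df <- readTableWithMeta(path, sep = "\t")
  names(df)[names(df) == "diagnosis"] <- "code"
  df
}

#' Write / read an annotation file
#'
#' CSV columns: patient_id, visit_index, mode, scale_a, scale_b, scale_final.
#'
#' @param ann annotations data.frame.
#' @param path file path.
#' @param meta optional metadata header.
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
writeAnnotationCSV <- function(ann, path, meta = NULL)
  writeTableWithMeta(ann, path, meta, sep = ",")

#' @rdname writeAnnotationCSV
#' @export
readAnnotationCSV <- function(path) readTableWithMeta(path, sep = ",")
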