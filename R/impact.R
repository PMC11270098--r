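# Aggregation of unit-level attributions into diagnosis-code-level impacts.
#
# With one input unit per (visit slot, code), the "linear combination"
# aggregating a code's attribution is the unweighted sum over its positions:
# current impact = phi at (block 0, code); historical impact = sum of phi over
# the code's positions in history blocks 1..H. With the all-zeros reference a
# code absent from a slot has x_i = ref_i, hence phi_i = 0 exactly, so absent
# codes receive exactly zero impact.

#' Diagnosis-level current and historical impacts for one record
#'
#' @param attribution an \code{AttributionSet} row (a single-record set) or a
#'   numeric phi vector laid out per \code{\link{layoutIndex}}.
#' @param window the record window the attribution was computed for.
#' @param spec the \code{ModelSpec} (layout).
#' @return data.frame with one row per code present anywhere in the window:
#'   patient_id, visit_index, code, current_impact, historical_impact.
#' @export
aggregateCodeImpacts <- function(attribution, window, spec) {
  phi <- if (is(attribution, "AttributionSet")) {
    if (nrow(attribution@phi) != 1)
      stop("aggregateCodeImpacts: expected a single-record AttributionSet")
    attribution@phi[1, ]
  } else as.numeric(attribution)
  V <- length(spec$vocabulary)
  if (length(phi) != (spec$H + 1L) * V)
    stop(sprintf("aggregateCodeImpacts: attribution length %d does not match layout %d",
                 length(phi), (spec$H + 1L) * V))
  curCodes <- unique(window$current$dx_codes)
  histCodes <- unique(unlist(lapply(window$history, function(v) v$dx_codes)))
  codes <- sort(unique(c(curCodes, histCodes)))
  if (!length(codes))
    return(data.frame(patient_id = character(0), visit_index = integer(0),
                      code = character(0), current_impact = numeric(0),
                      historical_impact = numeric(0)))
  cur <- vapply(codes, function(cd)
    if (cd %in% curCodes) phi[layoutIndex(spec, 0L, cd)] else 0, numeric(1))
  hist <- vapply(codes, function(cd) {
    s <- 0
    for (b in seq_along(window$history))
      if (cd %in% window$history[[b]]$dx_codes)
        s <- s + phi[layoutIndex(spec, b, cd)]
    s
  }, numeric(1))
  data.frame(patient_id = window$patient_id %||% NA_character_,
             visit_index = as.integer(window$visit_index %||% NA),
             code = codes, current_impact = unname(cur),
             historical_impact = unname(hist),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Code-impact table for a batch of attributed records
#'
#' @param aset an \code{AttributionSet} from \code{\link{attributionBatch}}.
#' @param windows the record windows the set was computed for (same order).
#' @param spec the \code{ModelSpec}.
#' @return data.frame of per-record \code{\link{aggregateCodeImpacts}} rows.
#' @export
codeImpactTable <- function(aset, windows, spec) {
  if (nrow(aset@phi) != length(windows))
    stop("codeImpactTable: attribution rows and windows differ in length")
  out <- lapply(seq_along(windows), function(i)
    aggregateCodeImpacts(aset@phi[i, ], windows[[i]], spec))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Record-segmentation basis value
#'
#' The scalar against which the high/low impact thresholds are applied for one
#' record: either the maximum code-level impact of the record (default; record
#' status driven by its strongest diagnosis code) or the model's predicted
#' probability.
#'
#' @param rows the record's code-impact rows (data.frame from
#'   \code{\link{aggregateCodeImpacts}}).
#' @param prediction the model's predicted probability for the record.
#' @param mode "max_code_impact" or "predicted_probability".
#' @param which for max mode, use "current" or "historical" impacts.
#' @return a single numeric value.
#' @export
recordBasis <- function(rows, prediction = NA_real_,
                        mode = c("max_code_impact", "predicted_probability"),
                        which = c("current", "historical")) {
  mode <- match.arg(mode)
  if (mode == "predicted_probability") return(as.numeric(prediction))
  which <- match.arg(which)
  col <- if (which == "current") rows$current_impact else rows$historical_impact
  if (!length(col)) {
    warning("recordBasis: no code-impact rows; returning 0")
    return(0)
  }
  max(col)
}

#' Write / read a code-impact table
#'
#' CSV columns: patient_id, visit_index, code, current_impact,
#' historical_impact, with optional \code{#}-prefixed metadata header.
#'
#' @param impacts data.frame from \code{\link{codeImpactTable}}.
#' @param path file path.
#' @param meta optional named character vector of metadata header fields.
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
writeImpactCSV <- function(impacts, path, meta = NULL) {
  writeTableWithMeta(impacts, path, meta, sep = ",")
}

#' @rdname writeImpactCSV
#' @export
readImpactCSV <- function(path) readTableWithMeta(path, sep = ",")
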