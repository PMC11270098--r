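# Deep attribution engine.
#
# Attributions are computed by back-propagating multipliers through the
# network: linear layers contribute their weight transpose, nonlinear units the
# rescale ratio (difference of activations over difference of pre-activations
# between the input and the reference). For an input x and reference r the
# per-unit contribution is phi_i = m_i * (x_i - r_i), and the multiplier
# composition guarantees the completeness identity sum(phi) = f(x) - f(r) up to
# floating-point error. The rescale rule is exact for linear layers and for any
# single nonlinearity; an exact Shapley enumeration oracle (exactShapley) is
# provided as the independent test surface for small n.

RESCALE_EPS <- 1e-9
COMPLETENESS_TOL <- 1e-6

#' Rescale multiplier of a scalar nonlinearity
#'
#' Returns \code{(sigma(preX) - sigma(preRef)) / (preX - preRef)}. When the two
#' pre-activations are within \code{1e-9} of each other the ratio degenerates
#' and the derivative at \code{preRef} is used instead (for the rectifier the
#' subgradient at the kink is taken as 0, i.e. the derivative on the inactive
#' side; away from the kink the derivative of the reference's side).
#'
#' @param unitNonlinearity one of "relu", "identity", "sigmoid".
#' @param preX pre-activation at the input (vectorised).
#' @param preRef pre-activation at the reference (vectorised, recycled).
#' @return numeric multiplier(s).
#' @examples
#' rescaleMultiplier("relu", 2, 0)   # 1
#' rescaleMultiplier("relu", -1, 0)  # 0
#' @export
rescaleMultiplier <- function(unitNonlinearity, preX, preRef) {
  if (!unitNonlinearity %in% c("relu", "identity", "sigmoid"))
    stop("rescaleMultiplier: unsupported nonlinearity: ", unitNonlinearity)
  delta <- preX - preRef
  near <- abs(delta) < RESCALE_EPS
  out <- numeric(length(delta))
  if (any(!near)) {
    sX <- applyActivation(unitNonlinearity, preX)
    sR <- applyActivation(unitNonlinearity, preRef)
    out[!near] <- ((sX - sR) / delta)[!near]
  }
  if (any(near))
    out[near] <- activationDeriv(unitNonlinearity, preRef + delta * 0)[near]
  dim(out) <- dim(delta)
  out
}

#' Class "AttributionSet": per-record additive attributions
#'
#' @slot phi matrix of contributions, one row per record, one column per input
#'   unit (named \code{cur_<code>}, \code{h1_<code>}, ...).
#' @slot fX model output at each input.
#' @slot fRef model output at the reference.
#' @slot residual completeness residual \code{fX - fRef - rowSums(phi)}.
#' @slot keys data.frame (patient_id, visit_index) or zero-row placeholder.
#' @slot ref the reference vector.
#' @export
setClass("AttributionSet", representation(
  phi = "matrix", fX = "numeric", fRef = "numeric",
  residual = "numeric", keys = "data.frame", ref = "numeric"))

setValidity("AttributionSet", function(object) {
  if (nrow(object@phi) != length(object@fX)) return("phi/fX length mismatch")
  if (any(!is.finite(object@phi))) return("phi must be finite")
  if (any(abs(object@residual) > COMPLETENESS_TOL))
    return(sprintf("completeness violated: max |residual| = %.3g",
                   max(abs(object@residual))))
  TRUE
})

setMethod("show", "AttributionSet", function(object) {
  cat(sprintf("AttributionSet: %d record(s) x %d input units; max |residual| %.2g\n",
              nrow(object@phi), ncol(object@phi),
              if (length(object@residual)) max(abs(object@residual)) else 0))
})

#' Contribution matrix, outputs and residuals of an AttributionSet
#' @param x an \code{AttributionSet}
#' @return \code{attributions}: the phi matrix; \code{outputValues}: data.frame
#'   with f_x, f_ref, residual and the record keys.
#' @export
attributions <- function(x) x@phi

#' @rdname attributions
#' @export
outputValues <- function(x) {
  cbind(x@keys[seq_along(x@fX), , drop = FALSE],
        data.frame(f_x = x@fX, f_ref = x@fRef, residual = x@residual))
}

attributionSet <- function(phi, fX, fRef, keys = NULL, ref = numeric(0)) {
  if (is.null(keys))
    keys <- data.frame(patient_id = character(0), visit_index = integer(0))
  new("AttributionSet", phi = phi, fX = as.numeric(fX),
      fRef = as.numeric(rep_len(fRef, length(fX))),
      residual = as.numeric(fX) - as.numeric(rep_len(fRef, length(fX))) - rowSums(phi),
      keys = keys, ref = as.numeric(ref))
}

#' Deep attribution of model outputs against a reference input
#'
#' Back-propagates multipliers through the layer stack (weight transpose for
#' the linear parts, \code{\link{rescaleMultiplier}} for each nonlinear unit)
#' and returns \code{phi = m * (x - ref)} per input unit. Satisfies the
#' completeness identity \code{sum(phi) = f(x) - f(ref)} to within \code{1e-6}
#' (enforced by the class validity), and \code{phi = 0} when \code{x = ref}.
#'
#' @param model a \code{RiskModel}.
#' @param x input vector, or matrix of inputs (one row per record).
#' @param ref reference input; default all-zeros ("no diagnoses recorded").
#' @param keys optional data.frame of record keys, one row per input row.
#' @return an \code{\link{AttributionSet}} (one row per input record).
#' @examples
#' sp <- modelSpec("DX1", H = 0, hiddenDims = integer(0))
#' m <- handSetModel(sp, list(list(W = matrix(2, 1, 1), b = 0, activation = "identity")))
#' attributions(deepSHAP(m, 1))  # phi = 2
#' @export
deepSHAP <- function(model, x, ref = NULL, keys = NULL) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  d <- ncol(x)
  if (d != inputDim(model@spec))
    stop(sprintf("deepSHAP: input has %d units, model expects %d", d,
                 inputDim(model@spec)))
  if (is.null(ref)) ref <- numeric(d)
  if (length(ref) != d) stop("deepSHAP: reference length mismatch")
  n <- nrow(x)
  fw <- forwardPass(model, x)
  fr <- forwardPass(model, matrix(ref, nrow = 1))
  nl <- length(model@layers)
  # multipliers from each layer's output back to the input, batched over rows:
  # M starts as the (n x 1) multiplier at the output unit
  M <- matrix(1, n, 1)
  for (l in rev(seq_len(nl))) {
    L <- model@layers[[l]]
    preR <- matrix(fr$pre[[l]], n, ncol(fw$pre[[l]]), byrow = TRUE)
    r <- rescaleMultiplier(L$activation, fw$pre[[l]], preR)
    M <- (M * r) %*% L$W
  }
  phi <- M * (x - matrix(ref, n, d, byrow = TRUE))
  colnames(phi) <- colnames(x) %||% unitNames0(model)
  attributionSet(phi, fw$out, fr$out, keys = keys, ref = ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unitNames0 <- function(model) {
  tryCatch(unitNames(model@spec), error = function(e) NULL)
}

#' Exact Shapley values by subset enumeration (test oracle)
#'
#' Computes, for a black-box function and a pair (input, reference), the exact
#' Shapley attribution \code{phi_i = sum over S not containing i of
#' |S|!(n-|S|-1)!/n! * (f(x_{S + i}) - f(x_S))}, where \code{x_S} takes the
#' input's value on S and the reference elsewhere. Enumeration is over all
#' \code{2^n} coalitions, so \code{n} is capped at 12.
#'
#' @param blackBoxFn function mapping a numeric vector to a scalar.
#' @param x input vector (n <= 12).
#' @param ref reference vector.
#' @return an \code{AttributionSet} with one row; completeness holds by
#'   construction.
#' @export
exactShapley <- function(blackBoxFn, x, ref = numeric(length(x))) {
  n <- length(x)
  if (n > 12) stop("exactShapley: n = ", n, " too large for 2^n enumeration (max 12)")
  if (length(ref) != n) stop("exactShapley: reference length mismatch")
  nMask <- 2^n
  vals <- numeric(nMask)
  bits <- 2^(seq_len(n) - 1)
  for (mask in 0:(nMask - 1)) {
    on <- bitwAnd(mask, bits) > 0
    vals[mask + 1] <- blackBoxFn(ifelse(on, x, ref))
  }
  sizes <- vapply(0:(nMask - 1), function(m) sum(bitwAnd(m, bits) > 0), numeric(1))
  wt <- factorial(0:(n - 1)) * factorial(n - 1 - (0:(n - 1))) / factorial(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    without <- which(bitwAnd(0:(nMask - 1), bits[i]) == 0)
    phi[i] <- sum(wt[sizes[without] + 1] *
                    (vals[without + bits[i]] - vals[without]))
  }
  attributionSet(matrix(phi, 1, n, dimnames = list(NULL, names(x))),
                 fX = vals[nMask], fRef = vals[1], ref = ref)
}

#' Attribute a batch of record windows
#'
#' Featurizes each window and applies \code{\link{deepSHAP}}; rows keep the
#' input order and are keyed by (patient_id, visit_index).
#'
#' @param model a \code{RiskModel}.
#' @param windows list of record windows.
#' @param ref reference vector (default all-zeros).
#' @return an \code{AttributionSet}.
#' @export
attributionBatch <- function(model, windows, ref = NULL) {
  if (!length(windows)) {
    d <- inputDim(model@spec)
    return(attributionSet(matrix(numeric(0), 0, d,
                                 dimnames = list(NULL, unitNames(model@spec))),
                          numeric(0), numeric(0)))
  }
  X <- tryCatch(featurizeWindows(windows, model@spec), error = function(e)
    stop("attributionBatch: ", conditionMessage(e)))
  keys <- data.frame(
    patient_id = vapply(windows, function(w) w$patient_id %||% NA_character_,
                        character(1)),
    visit_index = vapply(windows, function(w) as.integer(w$visit_index %||% NA),
                         integer(1)),
    stringsAsFactors = FALSE)
  deepSHAP(model, X, ref = ref, keys = keys)
}

#' Write an attribution table as CSV
#'
#' Columns: patient_id, visit_index, f_x, f_ref, then one column per input
#' unit (block_code naming, e.g. \code{h2_DX042}).
#'
#' @param aset an \code{AttributionSet}.
#' @param path output file.
#' @param meta optional named character vector written as \code{#}-prefixed
#'   header lines.
#' @return \code{path}, invisibly.
#' @export
writeAttributionCSV <- function(aset, path, meta = NULL) {
  df <- cbind(outputValues(aset)[c("patient_id", "visit_index", "f_x", "f_ref")],
              as.data.frame(aset@phi))
  writeTableWithMeta(df, path, meta, sep = ",")
}

#' Read an attribution table CSV
#'
#' @param path file from \code{\link{writeAttributionCSV}}.
#' @return an \code{AttributionSet}.
#' @export
readAttributionCSV <- function(path) {
  df <- readTableWithMeta(path, sep = ",")
  unitCols <- setdiff(names(df), c("patient_id", "visit_index", "f_x", "f_ref"))
  phi <- as.matrix(df[unitCols])
  attributionSet(phi, df$f_x, df$f_ref,
                 keys = df[c("patient_id", "visit_index")])
}

writeTableWithMeta <- function(df, path, meta = NULL, sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

readTableWithMeta <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
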