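# Visit-sequence mortality model. A small multilayer perceptron over a
# visit-addressable multi-hot layout: (H+1) contiguous blocks of length
# |vocabulary| -- block 0 is the current visit, blocks 1..H the H most recent
# prior visits (most recent first), absent slots all-zero. Hidden units are
# rectifiers; the output unit is a logistic probability. Restricting the body
# to piecewise-linear units keeps the attribution engine's multiplier rules
# exact per layer.

#' Model specification
#'
#' @param vocabulary ordered character vector of diagnosis codes.
#' @param H number of prior visits encoded (history window), default 4.
#' @param hiddenDims integer vector of hidden-layer widths (rectifier units);
#'   \code{integer(0)} gives a plain logistic model.
#' @param initSeed seed for parameter initialisation.
#' @return a list of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(vocabulary, H = 4L, hiddenDims = 16L, initSeed = 1L) {
  vocabulary <- as.character(vocabulary)
  if (anyDuplicated(vocabulary)) stop("modelSpec: duplicated vocabulary codes")
  H <- as.integer(H)
  if (H < 0) stop("modelSpec: H must be >= 0")
  hiddenDims <- as.integer(hiddenDims)
  if (any(hiddenDims < 1)) stop("modelSpec: all layer widths must be >= 1")
  structure(list(vocabulary = vocabulary, H = H, hiddenDims = hiddenDims,
                 initSeed = as.integer(initSeed), activation = "relu"),
            class = "ModelSpec")
}

inputDim <- function(spec) (spec$H + 1L) * length(spec$vocabulary)

#' Position of (block, code) in the input layout
#'
#' Block 0 is the current visit; blocks 1..H are history slots, most recent
#' first. Positions are 1-based: \code{block * |vocab| + match(code, vocab)}.
#'
#' @param spec a \code{ModelSpec}.
#' @param block integer block index in 0..H.
#' @param code diagnosis code.
#' @return integer index into the input vector.
#' @export
layoutIndex <- function(spec, block, code) {
  j <- match(code, spec$vocabulary)
  if (anyNA(j)) stop("layoutIndex: unknown code: ",
                     paste(code[is.na(j)], collapse = ", "))
  as.integer(block) * length(spec$vocabulary) + j
}

#' Build a record window (current visit + up to H prior visits)
#'
#' @param patient a patient list.
#' @param visitIndex 0-based index of the current visit.
#' @param H history depth.
#' @return list with \code{current}, \code{history} (most recent first),
#'   \code{patient_id}, \code{visit_index}.
#' @export
recordWindow <- function(patient, visitIndex, H = 4L) {
  k <- visitIndex + 1L
  if (k < 1 || k > length(patient$visits))
    stop("recordWindow: visit_index out of range for patient ", patient$patient_id)
  hist_idx <- rev(seq_len(k - 1L))
  hist_idx <- hist_idx[seq_len(min(H, length(hist_idx)))]
  list(current = patient$visits[[k]],
       history = patient$visits[hist_idx],
       patient_id = patient$patient_id,
       visit_index = as.integer(visitIndex))
}

#' Multi-hot featurization of a record window
#'
#' @param window a \code{\link{recordWindow}}.
#' @param spec a \code{ModelSpec}.
#' @return numeric vector of length \code{(H+1) * |vocabulary|} with entries
#'   in \{0,1\}; absent history slots stay all-zero (the reference encoding).
#' @export
featurize <- function(window, spec) {
  V <- length(spec$vocabulary)
  x <- numeric((spec$H + 1L) * V)
  fill <- function(block, codes) {
    if (!length(codes)) return()
    j <- match(unique(codes), spec$vocabulary)
    if (anyNA(j))
      stop("featurize: unknown code(s): ",
           paste(unique(codes)[is.na(j)], collapse = ", "))
    x[block * V + j] <<- 1
  }
  fill(0L, window$current$dx_codes)
  if (length(window$history) > spec$H)
    stop("featurize: window history longer than H")
  for (b in seq_along(window$history))
    fill(b, window$history[[b]]$dx_codes)
  x
}

#' All record windows of a cohort, with 30-day mortality labels
#'
#' @param cohort an \code{EHRCohort}.
#' @param spec a \code{ModelSpec} (supplies H).
#' @return list with \code{windows} (list), \code{labels} (0/1 vector) and
#'   \code{keys} (data.frame patient_id, visit_index).
#' @export
cohortWindows <- function(cohort, spec) {
  windows <- list(); labels <- integer(0)
  pid <- character(0); vix <- integer(0)
  for (p in cohort@patients) {
    for (k in seq_along(p$visits)) {
      w <- recordWindow(p, k - 1L, spec$H)
      windows[[length(windows) + 1]] <- w
      labels <- c(labels, as.integer(label30DayMortality(p, p$visits[[k]])))
      pid <- c(pid, p$patient_id); vix <- c(vix, k - 1L)
    }
  }
  list(windows = windows, labels = labels,
       keys = data.frame(patient_id = pid, visit_index = vix,
                         stringsAsFactors = FALSE))
}

#' Featurize a list of windows into a dense matrix
#'
#' @param windows list of record windows.
#' @param spec a \code{ModelSpec}.
#' @return numeric matrix, one row per window.
#' @export
featurizeWindows <- function(windows, spec) {
  X <- matrix(0, nrow = length(windows), ncol = inputDim(spec))
  for (i in seq_along(windows)) X[i, ] <- featurize(windows[[i]], spec)
  colnames(X) <- unitNames(spec)
  X
}

unitNames <- function(spec) {
  blocks <- c("cur", if (spec$H > 0) paste0("h", seq_len(spec$H)))
  as.vector(vapply(blocks, function(b) paste0(b, "_", spec$vocabulary),
                   character(length(spec$vocabulary))))
}

#' Class "RiskModel": piecewise-linear visit-sequence mortality model
#'
#' @slot spec the \code{ModelSpec} list.
#' @slot layers list of layers, each \code{list(W, b, activation)}; activations
#'   are "relu" for hidden layers and "sigmoid" for the output unit.
#' @slot trained logical.
#' @slot meta list (training history, held-out discrimination).
#' @export
setClass("RiskModel", representation(
  spec = "list", layers = "list", trained = "logical", meta = "list"))

setValidity("RiskModel", function(object) {
  d <- inputDim(object@spec)
  for (L in object@layers) {
    if (!all(c("W", "b", "activation") %in% names(L))) return("layer needs W, b, activation")
    if (ncol(L$W) != d) return("layer width mismatch")
    if (!L$activation %in% c("relu", "identity", "sigmoid"))
      return(paste0("unsupported activation: ", L$activation))
    d <- nrow(L$W)
  }
  if (d != 1) return("output layer must have a single unit")
  TRUE
})

setMethod("show", "RiskModel", function(object) {
  dims <- c(inputDim(object@spec),
            vapply(object@layers, function(L) nrow(L$W), numeric(1)))
  cat(sprintf("RiskModel: %s; H=%d, |vocab|=%d; %strained\n",
              paste(dims, collapse = " -> "), object@spec$H,
              length(object@spec$vocabulary),
              if (object@trained) "" else "un"))
  if (!is.null(object@meta$auroc))
    cat(sprintf("  held-out AUROC %.3f\n", object@meta$auroc))
})

#' Build an (untrained) risk model
#'
#' He-style Gaussian initialisation of the weights, seeded by
#' \code{spec$initSeed}; same spec gives identical parameters.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @return a \code{RiskModel}.
#' @export
buildModel <- function(spec) {
  if (!inherits(spec, "ModelSpec")) stop("buildModel: need a ModelSpec")
  set.seed(spec$initSeed)
  dims <- c(inputDim(spec), spec$hiddenDims, 1L)
  if (any(dims < 1)) stop("buildModel: zero-width layer")
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fanin <- dims[l]
    layers[[l]] <- list(
      W = matrix(rnorm(dims[l + 1] * fanin, sd = sqrt(2 / fanin)),
                 nrow = dims[l + 1], ncol = fanin),
      b = numeric(dims[l + 1]),
      activation = if (l == length(layers)) "sigmoid" else "relu")
  }
  new("RiskModel", spec = unclass(spec), layers = layers,
      trained = FALSE, meta = list())
}

#' Construct a risk model with hand-set parameters
#'
#' Convenience for tests and worked examples: builds a model from explicit
#' layer matrices rather than random initialisation.
#'
#' @param spec a \code{ModelSpec}.
#' @param layers list of \code{list(W, b, activation)}.
#' @return a \code{RiskModel}.
#' @export
handSetModel <- function(spec, layers) {
  new("RiskModel", spec = unclass(spec), layers = layers,
      trained = FALSE, meta = list())
}

# forward pass; returns list(pre = list of pre-activation matrices (n x units),
# act = list of post-activation), final prob vector
forwardPass <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  A <- X
  pre <- vector("list", length(model@layers))
  act <- vector("list", length(model@layers))
  for (l in seq_along(model@layers)) {
    L <- model@layers[[l]]
    Z <- A %*% t(L$W) + matrix(L$b, nrow(A), length(L$b), byrow = TRUE)
    A <- applyActivation(L$activation, Z)
    pre[[l]] <- Z; act[[l]] <- A
  }
  list(pre = pre, act = act, out = as.numeric(A))
}

applyActivation <- function(name, Z) {
  switch(name,
         relu = pmax(Z, 0),
         identity = Z,
         sigmoid = plogis(Z),
         stop("unsupported activation: ", name))
}

activationDeriv <- function(name, Z) {
  switch(name,
         relu = (Z > 0) * 1,      # subgradient 0 at the kink
         identity = Z * 0 + 1,
         sigmoid = plogis(Z) * (1 - plogis(Z)),
         stop("unsupported activation: ", name))
}

#' Predict the 30-day mortality probability for record windows
#'
#' @param model a \code{RiskModel}.
#' @param x a single window (from \code{\link{recordWindow}}), a numeric
#'   feature vector, or a feature matrix.
#' @return numeric vector of probabilities in [0,1].
#' @export
predictRisk <- function(model, x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$current))
    x <- featurize(x, model@spec)
  forwardPass(model, x)$out
}

#' Rank-statistic AUROC
#'
#' Area under the receiver-operating curve computed from the Wilcoxon rank-sum
#' identity (ties handled by midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUROC in [0,1].
#' @export
aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("aucRank: need both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a risk model by seeded mini-batch gradient descent
#'
#' Plain stochastic gradient descent with momentum on the logistic
#' cross-entropy, a fixed number of epochs and no early stopping (determinism
#' first). A held-out fraction is split off before training and its AUROC is
#' reported in \code{model@meta}.
#'
#' @param model an (untrained) \code{RiskModel}.
#' @param X feature matrix (rows = records) or an \code{EHRCohort}.
#' @param y 0/1 labels (ignored when \code{X} is a cohort).
#' @param epochs number of passes over the data.
#' @param lr learning rate.
#' @param batchSize mini-batch size.
#' @param momentum momentum coefficient.
#' @param holdout held-out fraction for the discrimination summary.
#' @param seed seed for shuffling and the holdout split.
#' @return the trained \code{RiskModel}; \code{meta} carries \code{auroc},
#'   \code{loss} and the training dimensions.
#' @export
trainModel <- function(model, X, y = NULL, epochs = 30L, lr = 0.3,
                       batchSize = 256L, momentum = 0.9, holdout = 0.2,
                       seed = 1L) {
  if (is(X, "EHRCohort")) {
    cw <- cohortWindows(X, model@spec)
    y <- cw$labels
    X <- featurizeWindows(cw$windows, model@spec)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("trainModel: degenerate data: labels contain a single class")
  set.seed(seed)
  n <- nrow(X)
  idxHold <- if (holdout > 0) sort(sample.int(n, max(1L, round(holdout * n)))) else integer(0)
  idxTrain <- setdiff(seq_len(n), idxHold)
  Xt <- X[idxTrain, , drop = FALSE]; yt <- y[idxTrain]
  layers <- model@layers
  vel <- lapply(layers, function(L) list(W = L$W * 0, b = L$b * 0))
  nt <- nrow(Xt)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nt)
    for (start in seq(1, nt, by = batchSize)) {
      ib <- ord[start:min(start + batchSize - 1, nt)]
      Xb <- Xt[ib, , drop = FALSE]; yb <- yt[ib]
      # forward
      A <- Xb; acts <- list(A); pres <- list()
      for (l in seq_along(layers)) {
        L <- layers[[l]]
        Z <- A %*% t(L$W) + matrix(L$b, nrow(A), length(L$b), byrow = TRUE)
        A <- applyActivation(L$activation, Z)
        pres[[l]] <- Z; acts[[l + 1]] <- A
      }
      # backward: d loss/d z_out = p - y for sigmoid + cross-entropy
      delta <- matrix(acts[[length(layers) + 1]] - yb, ncol = 1)
      for (l in rev(seq_along(layers))) {
        if (l < length(layers))
          delta <- delta * activationDeriv(layers[[l]]$activation, pres[[l]])
        gW <- t(delta) %*% acts[[l]] / length(ib)
        gb <- colMeans(delta)
        if (l > 1) deltaPrev <- delta %*% layers[[l]]$W
        vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW
        vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb
        layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
        layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
        if (l > 1) delta <- deltaPrev
      }
    }
    tmpModel <- new("RiskModel", spec = model@spec, layers = layers,
                    trained = TRUE, meta = list())
    p <- forwardPass(tmpModel, Xt)$out
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    losses[ep] <- -mean(yt * log(p) + (1 - yt) * log(1 - p))
  }
  out <- new("RiskModel", spec = model@spec, layers = layers,
             trained = TRUE, meta = list(loss = losses))
  if (length(idxHold)) {
    yh <- y[idxHold]
    if (length(unique(yh)) == 2)
      out@meta$auroc <- aucRank(forwardPass(out, X[idxHold, , drop = FALSE])$out, yh)
  }
  out@meta$n_train <- length(idxTrain); out@meta$n_holdout <- length(idxHold)
  out
}

#' Save a risk model as a versioned single-file JSON archive
#'
#' @param model a \code{RiskModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
saveRiskModel <- function(model, path) {
  obj <- list(format = "dshapr-riskmodel", version = 1L,
              spec = model@spec,
              layers = lapply(model@layers, function(L)
                list(W = as.vector(L$W), dim = dim(L$W), b = L$b,
                     activation = L$activation)),
              trained = model@trained, meta = model@meta)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a risk model archive
#'
#' @param path file from \code{\link{saveRiskModel}}.
#' @return a \code{RiskModel}.
#' @export
loadRiskModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "dshapr-riskmodel"))
    stop("loadRiskModel: not a risk-model archive: ", path)
  if (obj$version != 1) stop("loadRiskModel: unsupported version ", obj$version)
  spec <- obj$spec
  spec$vocabulary <- as.character(unlist(spec$vocabulary))
  spec$H <- as.integer(spec$H)
  spec$hiddenDims <- as.integer(unlist(spec$hiddenDims))
  layers <- lapply(obj$layers, function(L)
    list(W = matrix(unlist(L$W), nrow = unlist(L$dim)[1], ncol = unlist(L$dim)[2]),
         b = as.numeric(unlist(L$b)), activation = L$activation))
  new("RiskModel", spec = spec, layers = layers,
      trained = isTRUE(obj$trained),
      meta = if (is.null(obj$meta)) list() else obj$meta)
}
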