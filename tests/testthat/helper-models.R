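# Shared builders for tiny models, windows and specs used across the suite.

affineModel <- function(w, b = 0, H = 0L) {
  sp <- modelSpec(paste0("C", seq_along(w)), H = H, hiddenDims = integer(0),
                  initSeed = 1L)
  handSetModel(sp, list(list(W = matrix(w, 1, length(w)), b = b,
                             activation = "identity")))
}

# logistic-output affine model over an (H+1)-block layout; weights per block
logisticModel <- function(wBlocks, b = 0) {
  V <- length(wBlocks[[1]])
  sp <- modelSpec(paste0("C", seq_len(V)), H = length(wBlocks) - 1L,
                  hiddenDims = integer(0), initSeed = 1L)
  handSetModel(sp, list(list(W = matrix(unlist(wBlocks), 1), b = b,
                             activation = "sigmoid")))
}

randomReluNet <- function(nIn, hidden, seed) {
  sp <- modelSpec(paste0("C", seq_len(nIn)), H = 0L, hiddenDims = hidden,
                  initSeed = seed)
  buildModel(sp)
}

mkVisit <- function(idx, day, dx = character(0), proc = character(0),
                    setting = "inpatient") {
  list(visit_index = as.integer(idx), day_offset = as.integer(day),
       setting = setting, dx_codes = dx, proc_codes = proc)
}

mkPatient <- function(id, visits, death = NA_integer_) {
  list(patient_id = id, sex = "F", age_at_first_visit = 70,
       visits = visits, death_day_offset = death)
}

# a patient eligible for decision points: IHCA at visit H with death soon after
eligiblePatient <- function(id = "P1", nPrior = 4L, dxList = NULL) {
  visits <- lapply(seq_len(nPrior + 1L), function(k)
    mkVisit(k - 1L, (k - 1L) * 10L,
            dx = if (is.null(dxList)) paste0("C", k) else dxList[[k]],
            proc = if (k == nPrior + 1L) "99.63" else character(0)))
  mkPatient(id, visits, death = as.integer(nPrior * 10L + 5L))
}
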