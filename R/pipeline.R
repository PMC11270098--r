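# Top-level pipeline: synth -> train -> attribute -> impacts -> validate ->
# report, reproducible from one master seed. Each stage derives its own
# sub-seed by stable hashing of the stage name, so stages can be re-run in
# isolation with identical results.

stableHash <- function(s) {
  # 31-bit polynomial string hash, stable across platforms and sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

stageSeed <- function(masterSeed, stage)
  as.integer((as.double(masterSeed) * 2654435761 + stableHash(stage)) %% 2147483629)

pipelineVersion <- function()
  as.character(utils::packageVersion("dshapr"))

configHash <- function(config) {
  # hash the scientific configuration only, so reruns into a different
  # directory still produce byte-identical tables
  sci <- config[setdiff(names(config), c("out_dir", "verbose"))]
  stableHash(paste(deparse(sci[order(names(sci))]), collapse = ""))
}

defaultConfig <- function() {
  list(fixture = NULL, spec_file = NULL, cohort_file = NULL,
       out_dir = NULL, seed = 1L, H = 4L, hidden_dims = 16L,
       epochs = 30L, lr = 0.3, theta_high = 0.25, theta_low = 0.10,
       annotator_noise = 0.3, basis = "max_code_impact", k = 5L,
       n_patients = NULL, verbose = TRUE)
}

#' Run the full pipeline
#'
#' Executes synth, train, attribute, impacts, validate and report in sequence.
#' Every artifact file carries a \code{#}-prefixed metadata header (tool
#' version, master seed, config hash), so a rerun with the same config
#' reproduces byte-identical tables.
#'
#' @param config named list; recognised fields: \code{fixture} (a registered
#'   fixture name) or \code{spec_file} (generator spec path), \code{out_dir}
#'   (required), \code{seed}, \code{H}, \code{hidden_dims}, \code{epochs},
#'   \code{lr}, \code{theta_high}, \code{theta_low}, \code{annotator_noise},
#'   \code{basis}, \code{k}, \code{n_patients}, \code{verbose}.
#' @return invisible list: the \code{\link{runValidation}} result plus cohort
#'   and model summaries and the paths written.
#' @export
runPipeline <- function(config) {
  cfg <- utils::modifyList(defaultConfig(), as.list(config))
  unknown <- setdiff(names(config), names(defaultConfig()))
  if (length(unknown))
    stop("runPipeline: unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("runPipeline: config field out_dir is required")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  meta <- c(tool = paste0("dshapr ", pipelineVersion()),
            seed = as.character(cfg$seed),
            config_hash = as.character(configHash(cfg)))
  paths <- c()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # synth
  spec <- stage("synth", {
    if (!is.null(cfg$fixture)) {
      fx <- makeFixture(cfg$fixture, nPatients = cfg$n_patients)
      fx$spec
    } else if (!is.null(cfg$spec_file)) {
      if (!file.exists(cfg$spec_file))
        stop("config field spec_file: no such file: ", cfg$spec_file)
      sp <- readCohortSpecFile(cfg$spec_file)
      if (!is.null(cfg$n_patients)) sp@nPatients <- as.integer(cfg$n_patients)
      sp
    } else stop("config needs either fixture or spec_file")
  })
  cohort <- stage("synth", {
    if (!is.null(cfg$cohort_file)) {
      if (!file.exists(cfg$cohort_file))
        stop("config field cohort_file: no such file: ", cfg$cohort_file)
      co <- readCohortJSONL(cfg$cohort_file)
      co@spec <- spec
      co
    } else sampleCohort(spec, seed = stageSeed(cfg$seed, "synth"))
  })
  say("synth: %d patients", length(cohort))
  paths["cohort"] <- file.path(cfg$out_dir, "cohort.jsonl")
  writeCohortJSONL(cohort, paths["cohort"])

  # train
  model <- stage("train", {
    ms <- modelSpec(spec@catalogue$code, H = cfg$H, hiddenDims = cfg$hidden_dims,
                    initSeed = stageSeed(cfg$seed, "init"))
    trainModel(buildModel(ms), cohort, epochs = cfg$epochs, lr = cfg$lr,
               seed = stageSeed(cfg$seed, "train"))
  })
  say("train: held-out AUROC %.3f", model@meta$auroc %||% NA)
  paths["model"] <- file.path(cfg$out_dir, "model.json")
  saveRiskModel(model, paths["model"])

  # attribute + impacts + validate
  val <- stage("validate",
    runValidation(cohort, model, thetaHigh = cfg$theta_high,
                  thetaLow = cfg$theta_low, noiseScale = cfg$annotator_noise,
                  seed = stageSeed(cfg$seed, "annotate"),
                  basisMode = cfg$basis, k = cfg$k))
  paths["attributions"] <- file.path(cfg$out_dir, "attributions.csv")
  writeAttributionCSV(val$attribution, paths["attributions"], meta)
  paths["impacts"] <- file.path(cfg$out_dir, "impacts.csv")
  writeImpactCSV(val$impacts, paths["impacts"], meta)
  paths["annotations"] <- file.path(cfg$out_dir, "annotations.csv")
  writeAnnotationCSV(val$annotations, paths["annotations"], meta)
  tabs <- c("benchmark_current", "benchmark_historical",
            "dshap_current", "dshap_historical")
  for (tb in tabs) {
    paths[tb] <- file.path(cfg$out_dir, paste0(tb, ".tsv"))
    writeImportanceTSV(val[[tb]], paths[tb],
                       c(meta, stratum_totals = paste(
                         attr(val[[tb]], "total_high"),
                         attr(val[[tb]], "total_low"), sep = "/"),
                         record_set = val$settings$record_set))
  }

  # report
  paths["report"] <- file.path(cfg$out_dir, "report.txt")
  rep <- c(sprintf("# %s: %s", names(meta), meta),
           sprintf("patients: %d", length(cohort)),
           sprintf("decision points: %d", nrow(val$decision_points)),
           sprintf("held-out AUROC: %.4f", model@meta$auroc %||% NA),
           sprintf("top-%d overlap (current): %d", cfg$k,
                   val$comparison_current$top_k_overlap),
           sprintf("top-%d overlap (historical): %d", cfg$k,
                   val$comparison_historical$top_k_overlap),
           sprintf("rank correlation (current): %.4f",
                   val$comparison_current$rank_correlation),
           sprintf("rank correlation (historical): %.4f",
                   val$comparison_historical$rank_correlation))
  writeLines(rep, paths["report"])
  say("report: %s", paths["report"])
  invisible(c(val, list(cohort = cohort, model = model, paths = paths,
                        config = cfg)))
}

#' Published reference summaries shipped with the package
#'
#' Loads the plain-text reference inputs under \code{inst/extdata}: the cohort
#' bookkeeping counts of a published IHCA claims cohort and its four
#' importance tables (physician benchmark and attribution-based, current and
#' historical). These are inputs for arithmetic cross-checks; the package
#' never claims to reproduce them from simulation.
#'
#' @return list with \code{counts} (named numeric) and \code{tables} (named
#'   list of data.frames; ratio columns on the percentage scale).
#' @export
referenceSummaries <- function() {
  path <- function(f) system.file("extdata", f, package = "dshapr", mustWork = TRUE)
  counts_df <- utils::read.delim(path("ref_cohort_counts.tsv"), comment.char = "#",
                                 stringsAsFactors = FALSE)
  counts <- setNames(as.numeric(counts_df$value), counts_df$count)
  tables <- list(
    physician_current = utils::read.delim(path("ref_physician_current.tsv"),
                                          comment.char = "#", stringsAsFactors = FALSE),
    physician_historical = utils::read.delim(path("ref_physician_historical.tsv"),
                                             comment.char = "#", stringsAsFactors = FALSE),
    dshap_current = utils::read.delim(path("ref_dshap_current.tsv"),
                                      comment.char = "#", stringsAsFactors = FALSE),
    dshap_historical = utils::read.delim(path("ref_dshap_historical.tsv"),
                                         comment.char = "#", stringsAsFactors = FALSE))
  list(counts = counts, tables = tables)
}
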