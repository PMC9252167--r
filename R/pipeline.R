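#' Run the full analysis pipeline on a synthetic study
#'
#' End-to-end workflow: simulate the study, normalize VAFs, summarize
#' LIP/sLIP, compare the NM and LM groups, correlate sLIP with the
#' tumor-to-paracancer purity change, run the driver/resister cascade
#' on the external case-control cohorts, build the risk panel from the
#' surviving candidates (LIP weights from the discovery cohort), fit
#' and cross-validate the LIP-weighted logistic model, and evaluate it
#' leave-one-cohort-out. All outputs are written atomically to
#' \code{outDir} together with a run manifest (configuration, seed,
#' package version, file checksums). Identical configurations produce
#' byte-identical outputs.
#'
#' @param config a \code{\link{generatorConfig}}
#' @param outDir output directory; created if needed. \code{NULL}
#'   skips writing.
#' @param normalizePolicy VAF normalization policy
#'   (see \code{\link{normalizeVafs}})
#' @param cascade a \code{\link{cascadeConfig}}
#' @param quiet suppress progress messages (written to standard error)
#' @return list with \code{study}, \code{lip} (LipSummary),
#'   \code{groupTest}, \code{purityCorrelation}, \code{cascade}
#'   (CascadeResult), \code{model} (RiskModel), \code{loocv},
#'   \code{groupedEval}, \code{recovery} (driver/resister recovery
#'   against the ground truth) and \code{files}
#' @export
runPipeline <- function(config = generatorConfig(), outDir = NULL,
                        normalizePolicy = c("library_size", "none"),
                        cascade = cascadeConfig(), quiet = FALSE) {
  normalizePolicy <- match.arg(normalizePolicy)
  say <- function(...) if (!quiet) message("[metalip] ", ...)

  say("simulating study (seed ", config$seed, ")")
  study <- simulateStudy(config)

  say("normalizing VAFs (policy = ", normalizePolicy, ")")
  cohort <- normalizeVafs(study$discovery$cohort, policy = normalizePolicy)

  say("computing LIP statistics")
  lip <- summarizeLip(cohort)
  groupTest <- compareGroups(lip)
  purityCor <- correlateSlipPurity(lip, purities(cohort))
  say(sprintf("NM vs LM sLIP rank-sum p = %.4g; sLIP-purity r = %.3f",
              groupTest$p.value, purityCor$r))

  say("running driver/resister cascade on external cohorts")
  val <- study$validation
  ext <- val$cohorts != "discovery"
  casc <- runCascade(lip,
                     carriers = val$carriers[ext, , drop = FALSE],
                     labels = val$labels[ext],
                     expression = study$exprsurv$expression,
                     survivalTables = study$exprsurv$survival,
                     config = cascade,
                     horizon = config$censorHorizon)
  say("cascade funnel: ",
      paste(sprintf("%s=%d", names(funnel(casc)), funnel(casc)),
            collapse = " "))

  truth <- study$truth
  plantedIds <- truth$variant_id[truth$role != "background"]
  found <- candidates(casc)$variant_id
  recovery <- list(
    n_candidates = length(found),
    drivers_recovered = sum(found %in%
      truth$variant_id[truth$role == "driver"]),
    resisters_recovered = sum(found %in%
      truth$variant_id[truth$role == "resister"]),
    background_in_candidates = sum(!found %in% plantedIds),
    contamination = if (length(found))
      sum(!found %in% plantedIds) / length(found) else 0)

  if (nrow(candidates(casc)) < 2)
    stop("cascade produced fewer than two candidates; no risk panel",
         call. = FALSE)
  panel <- candidates(casc)$variant_id
  pvar <- perVariant(lip)
  L <- stats::setNames(pvar$mean_LIP[match(panel, pvar$variant_id)], panel)

  say("fitting risk model on ", length(panel), "-variant panel")
  y <- stats::setNames(as.integer(val$labels == "metastasis"),
                       names(val$labels))
  X <- val$carriers[, panel, drop = FALSE]
  model <- fitRiskModel(X, y, L)
  loo <- loocv(X, y, L)
  ge <- groupedEval(X, y, val$cohorts, L)
  say(sprintf("LOOCV pooled AUC = %.3f, accuracy = %.3f",
              loo$pooled@auc, loo$pooled@accuracy))

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      writeVariantTable(cohort, file.path(outDir, "discovery_variants.tsv")),
      writeLipTables(lip, outDir),
      writeCandidates(casc, file.path(outDir, "candidates.tsv")),
      writeRiskModel(model, file.path(outDir, "risk_model.json")))
    metrics <- list(
      group_test = groupTest,
      purity_correlation = purityCor,
      funnel = as.list(funnel(casc)),
      recovery = recovery,
      loocv = c(reportAsList(loo$pooled),
                list(per_fold_accuracy = loo$perFoldAccuracy)),
      grouped_eval = ge$average)
    mp <- file.path(outDir, "metrics.json")
    .writeAtomic(function(tmp) jsonlite::write_json(
      metrics, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE), mp)
    files <- c(files, mp)
    pp <- file.path(outDir, "predictions.tsv")
    .writeAtomic(function(tmp) utils::write.table(
      loo$predictions, tmp, sep = "\t", quote = FALSE,
      row.names = FALSE), pp)
    files <- c(files, pp)
    manifest <- list(
      tool = "metalip",
      version = as.character(utils::packageVersion("metalip")),
      seed = config$seed,
      config = unclass(config),
      normalize_policy = normalizePolicy,
      cascade_config = unclass(cascade),
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))))
    mf <- file.path(outDir, "manifest.json")
    .writeAtomic(function(tmp) jsonlite::write_json(
      manifest, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE), mf)
    files <- c(files, mf)
  }

  list(study = study, lip = lip, groupTest = groupTest,
       purityCorrelation = purityCor, cascade = casc, model = model,
       loocv = loo, groupedEval = ge, recovery = recovery,
       files = files)
}

#' Command-line entry point
#'
#' Thin argument-vector interface over the package functions, used by
#' the \code{inst/cli/metalip} wrapper script. Subcommands:
#' \describe{
#'   \item{simulate}{\code{--seed <int> --out <dir>}: write the
#'     synthetic study inputs (variant table, carrier table, truth
#'     manifest).}
#'   \item{run-all}{\code{--seed <int> --out <dir>}: full pipeline;
#'     writes candidate TSV, model JSON, metrics JSON and manifest.}
#'   \item{predict}{\code{--model <json> --status yes,no,...}: score
#'     one subject from the carrier status of the panel variants and
#'     print the probability and risk tier.}
#' }
#' All other stages are exported functions
#' (\code{\link{summarizeLip}}, \code{\link{runCascade}},
#' \code{\link{fitRiskModel}}, \code{\link{loocv}},
#' \code{\link{groupedEval}}, ...).
#'
#' @param args character vector of command-line arguments
#' @return integer exit status, invisibly (0 on success, 2 on usage
#'   error)
#' @export
lipCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: metalip <simulate|run-all|predict> [options]\n",
            "  simulate --seed <int> --out <dir>\n",
            "  run-all  --seed <int> --out <dir>\n",
            "  predict  --model <model.json> --status yes,no,...")
    invisible(2L)
  }
  getOpt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (length(args) == 0) return(usage())
  cmd <- args[1]
  known <- c("simulate", "run-all", "predict")
  if (!cmd %in% known) return(usage())
  extra <- args[-1]
  flags <- extra[startsWith(extra, "--")]
  if (!all(flags %in% c("--seed", "--out", "--model", "--status")))
    return(usage())
  status <- tryCatch({
    if (cmd == "predict") {
      modelPath <- getOpt("--model")
      statusStr <- getOpt("--status")
      if (is.null(modelPath) || is.null(statusStr)) return(usage())
      model <- readRiskModel(modelPath)
      toks <- tolower(strsplit(statusStr, ",", fixed = TRUE)[[1]])
      if (!all(toks %in% c("yes", "no", "1", "0")))
        stop("status must be a comma list of yes/no", call. = FALSE)
      V <- as.integer(toks %in% c("yes", "1"))
      if (length(V) != length(model@panel))
        stop("expected ", length(model@panel), " status entries",
             call. = FALSE)
      p <- predictRisk(model, V)
      cat(sprintf("probability\t%.6f\ntier\t%s\n", p, categorizeRisk(p)))
      0L
    } else {
      seed <- as.integer(getOpt("--seed", "42"))
      out <- getOpt("--out")
      if (is.null(out) || is.na(seed)) return(usage())
      config <- generatorConfig(seed = seed)
      if (cmd == "simulate") {
        study <- simulateStudy(config)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        writeVariantTable(study$discovery$cohort,
                          file.path(out, "discovery_variants.tsv"))
        car <- data.frame(subject = rownames(study$validation$carriers),
                          label = unname(study$validation$labels),
                          cohort = unname(study$validation$cohorts),
                          study$validation$carriers, check.names = FALSE)
        .writeAtomic(function(tmp) utils::write.table(
          car, tmp, sep = "\t", quote = FALSE, row.names = FALSE),
          file.path(out, "carriers.tsv"))
        .writeAtomic(function(tmp) jsonlite::write_json(
          study$truth, tmp, auto_unbox = TRUE, digits = NA,
          pretty = TRUE), file.path(out, "truth.json"))
        message("[metalip] simulated study written to ", out)
      } else {
        runPipeline(config, outDir = out)
      }
      0L
    }
  }, error = function(e) {
    message("[metalip] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
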