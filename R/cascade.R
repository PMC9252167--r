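#' Cascade configuration
#'
#' Thresholds of the three-step driver/resister identification:
#' (1) per-variant mean LIP above the promoter threshold (or below the
#' resister threshold for the resister arm); (2) case-control odds
#' ratio strictly above the OR threshold; (3) significant eQTL effect
#' on the host gene and a significant survival contrast between its
#' high and low expression strata.
#'
#' @param lipPromoterThreshold mean-LIP gate of the promoter arm
#'   (default 1, strict)
#' @param lipResisterThreshold mean-LIP gate of the resister arm
#'   (default -1, strict, values below pass)
#' @param orThreshold odds-ratio gate (default 5, strict; \code{Inf}
#'   passes)
#' @param eqtlAlpha eQTL significance level (default 0.01)
#' @param survivalAlpha log-rank significance level (default 0.01)
#' @return a validated list of class \code{cascadeConfig}
#' @export
cascadeConfig <- function(lipPromoterThreshold = 1,
                          lipResisterThreshold = -1,
                          orThreshold = 5,
                          eqtlAlpha = 0.01,
                          survivalAlpha = 0.01) {
  for (thr in list(lipPromoterThreshold = lipPromoterThreshold,
                   lipResisterThreshold = lipResisterThreshold,
                   orThreshold = orThreshold))
    if (!is.numeric(thr) || length(thr) != 1 || is.na(thr))
      stop("thresholds must be single finite numbers (or infinite to ",
           "disable an arm)", call. = FALSE)
  .assertScalarNumber(eqtlAlpha, "eqtlAlpha")
  .assertScalarNumber(survivalAlpha, "survivalAlpha")
  if (eqtlAlpha <= 0 || eqtlAlpha >= 1 ||
      survivalAlpha <= 0 || survivalAlpha >= 1)
    stop("alphas must lie in (0, 1)", call. = FALSE)
  structure(list(lipPromoterThreshold = lipPromoterThreshold,
                 lipResisterThreshold = lipResisterThreshold,
                 orThreshold = orThreshold,
                 eqtlAlpha = eqtlAlpha,
                 survivalAlpha = survivalAlpha),
            class = "cascadeConfig")
}

#' Run the three-step driver/resister identification cascade
#'
#' Pure intersection of three filters over the candidate variants of a
#' cohort LIP summary: the mean-LIP gate (promoter and resister arms),
#' the case-control odds-ratio gate, and the expression/survival
#' penetrance gate with MP/MR classification. Every input variant is
#' accounted for: it either survives or appears in the exclusion log
#' with the stage and reason (including missing carrier, expression or
#' survival data, which conservatively exclude a variant).
#'
#' @param summary a \code{\link[=LipSummary-class]{LipSummary}} from the
#'   discovery cohort
#' @param carriers subjects x variants binary carrier matrix of the
#'   case-control cohorts (row/col names required)
#' @param labels named \code{"metastasis"} / \code{"non-metastasis"}
#'   vector over the carrier-matrix subjects
#' @param expression named list (by variant id) of data.frames with
#'   columns \code{dosage}, \code{expression}; ignored for variants
#'   covered by \code{eqtl}
#' @param survivalTables named list (by variant id) of data.frames with
#'   columns \code{time}, \code{event}, \code{expression}
#' @param config a \code{\link{cascadeConfig}}
#' @param eqtl optional precomputed eQTL table (data.frame:
#'   \code{variant_id}, \code{p}, \code{direction}) standing in for the
#'   genotype-expression tables
#' @param horizon administrative censoring horizon in months for the
#'   survival contrast
#' @return a \code{\link[=CascadeResult-class]{CascadeResult}};
#'   candidates are sorted by survival p-value
#' @export
runCascade <- function(summary, carriers, labels,
                       expression = list(), survivalTables = list(),
                       config = cascadeConfig(), eqtl = NULL,
                       horizon = 120) {
  stopifnot(is(summary, "LipSummary"), inherits(config, "cascadeConfig"))
  pv <- summary@perVariant
  ids <- pv$variant_id
  meanLip <- stats::setNames(pv$mean_LIP, ids)
  log <- list()
  note <- function(id, stage, reason)
    log[[length(log) + 1]] <<- data.frame(variant_id = id, stage = stage,
                                          reason = reason,
                                          stringsAsFactors = FALSE)

  # step 1: mean-LIP gates (the LIP > 0 list is kept as an intermediate)
  lipPos <- ids[meanLip > 0]
  promoters <- ids[meanLip > config$lipPromoterThreshold]
  resisters <- ids[meanLip < config$lipResisterThreshold]
  arm <- c(stats::setNames(rep("promoter", length(promoters)), promoters),
           stats::setNames(rep("resister", length(resisters)), resisters))
  dropped1 <- setdiff(ids, names(arm))
  if (length(dropped1))
    note(dropped1, "lip", sprintf("mean LIP within (%g, %g]",
                                  config$lipResisterThreshold,
                                  config$lipPromoterThreshold))
  step1 <- names(arm)

  # step 2: odds-ratio gate on the case-control carrier matrix
  inCarrier <- step1[step1 %in% colnames(carriers)]
  missingCar <- setdiff(step1, inCarrier)
  if (length(missingCar))
    note(missingCar, "odds_ratio", "absent from carrier matrix")
  screen <- if (length(inCarrier))
    oddsRatioScreen(carriers[, inCarrier, drop = FALSE], labels)
  else
    data.frame(variant_id = character(), Mm = numeric(), Mn = numeric(),
               Nm = numeric(), Nn = numeric(), OR = numeric())
  orMap <- stats::setNames(screen$OR, screen$variant_id)
  step2 <- filterByOr(orMap, config$orThreshold)
  failedOr <- setdiff(inCarrier, step2)
  if (length(failedOr))
    note(failedOr, "odds_ratio",
         sprintf("OR <= %g or undefined", config$orThreshold))

  # step 3: eQTL direction + survival penetrance, then MP/MR class
  precomp <- if (!is.null(eqtl))
    stats::setNames(seq_len(nrow(eqtl)), eqtl$variant_id) else integer()
  cand <- list()
  for (id in step2) {
    if (id %in% names(precomp)) {
      row <- eqtl[precomp[[id]], ]
      ep <- row$p
      dir <- row$direction
    } else if (id %in% names(expression)) {
      tab <- expression[[id]]
      et <- eqtlTest(tab$dosage, tab$expression)
      ep <- et$p.value
      dir <- et$direction
    } else {
      note(id, "eqtl", "no expression data")
      next
    }
    if (is.na(dir) || !(ep < config$eqtlAlpha)) {
      note(id, "eqtl", sprintf("p = %.3g >= %g or undefined direction",
                               ep, config$eqtlAlpha))
      next
    }
    if (!id %in% names(survivalTables)) {
      note(id, "survival", "no survival data")
      next
    }
    st <- survivalTables[[id]]
    sv <- survivalByExpression(st$time, st$event, st$expression,
                               horizon = horizon)
    if (is.na(sv$worse) || !(sv$p.value < config$survivalAlpha)) {
      note(id, "survival", sprintf("log-rank p = %.3g >= %g",
                                   sv$p.value, config$survivalAlpha))
      next
    }
    i <- match(id, pv$variant_id)
    cand[[id]] <- data.frame(
      variant_id = id, rsid = pv$rsid[i], ref = pv$ref[i], alt = pv$alt[i],
      arm = unname(arm[id]),
      class = classifyVariant(dir, sv$worse),
      mean_LIP = meanLip[[id]], OR = orMap[[id]],
      eqtl_p = ep, eqtl_direction = dir,
      survival_p = sv$p.value, worse_stratum = sv$worse,
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(variant_id = character(), rsid = character(),
               ref = character(), alt = character(), arm = character(),
               class = character(), mean_LIP = numeric(), OR = numeric(),
               eqtl_p = numeric(), eqtl_direction = character(),
               survival_p = numeric(), worse_stratum = character(),
               stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$survival_p,
                                 candidates$variant_id), , drop = FALSE]
  rownames(candidates) <- NULL
  logDf <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  funnel <- c(input = length(ids),
              lip_positive = length(lipPos),
              promoter = length(promoters),
              resister = length(resisters),
              or_pass = length(step2),
              survived = nrow(candidates))
  new("CascadeResult", candidates = candidates,
      funnel = vapply(funnel, as.integer, integer(1)),
      log = logDf, config = unclass(config))
}

#' Write the cascade candidate table
#'
#' Tab-delimited candidate output (rsid, ref, alt, class, OR, eQTL p,
#' survival p, ...) with \code{"+inf"} for infinite odds ratios.
#'
#' @param result a \code{CascadeResult}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCandidates <- function(result, path) {
  stopifnot(is(result, "CascadeResult"))
  out <- result@candidates
  if (nrow(out)) {
    out$OR <- ifelse(is.infinite(out$OR), "+inf", sprintf("%.6g", out$OR))
    out$rsid[is.na(out$rsid)] <- "."
  }
  .writeAtomic(function(tmp) utils::write.table(
    out, tmp, sep = "\t", quote = FALSE, row.names = FALSE), path)
}
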