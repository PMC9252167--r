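#' Generator configuration for the synthetic study
#'
#' Defines the synthetic study conditions: a small discovery cohort
#' with tri-tissue whole-exome-like allele depths (4 non-metastasis
#' and 4 lymphatic-metastasis subjects at about 197x mean coverage),
#' external case-control validation cohorts for the odds-ratio screen
#' and the risk model, and genotype-expression / survival tables for
#' the penetrance filter. Planted driver variants raise the paracancer
#' VAF and deplete the tumor VAF of their carriers in the metastasis
#' group (net positive LIP); the planted resister acts in the opposite
#' direction. All background variants carry a small negative paracancer
#' drift so a neutral mutation profile accumulates a negative sLIP.
#'
#' @param seed master seed; all stage seeds derive from it
#' @param nNM,nLM discovery subjects per group
#' @param nBackground,nDriver,nResister variant counts
#' @param depthMean mean per-locus sequencing depth (reads)
#' @param driverBoost multiplicative paracancer-VAF effect of a planted
#'   driver in LM carriers (capped at VAF 1); the tumor VAF is divided
#'   by the same factor, representing edge-ward migration of the
#'   variant-carrying clone
#' @param backgroundDrift global multiplicative paracancer drift of
#'   non-driver variants (slightly below 1)
#' @param orEffect target case/control carrier odds ratio of planted
#'   variants in the validation cohorts. With the default near-zero
#'   control carriage the empirical odds ratio is frequently infinite
#'   (control-carrier cell 0), the regime the candidate tables of
#'   tri-tissue CRC studies actually report.
#' @param ctrlCarrierProb carrier probability of planted variants among
#'   non-metastasis controls; 0 makes every planted odds ratio
#'   structurally infinite (case carrier probability then fixed at 0.5)
#' @param eqtlSlope expression change per allele dosage of planted
#'   variants
#' @param hazardRatio hazard of the worse expression stratum relative
#'   to the other for planted variants
#' @param nDriverUp how many drivers up-regulate their host gene (the
#'   rest down-regulate)
#' @param cohortSizes named validation-cohort sizes (subjects)
#' @param caseFraction metastasis fraction within each validation
#'   cohort
#' @param purityTumor,puritySdTumor mean/sd of tumor purity
#' @param purityGapNM,purityGapLM mean tumor-minus-paracancer purity
#'   gap per group (sd \code{purityGapSd}); the smaller LM gap encodes
#'   heavier tumor-cell infiltration of LM paracancer tissue
#' @param purityGapSd sd of the purity gap
#' @param nExprSamples,nSurvSamples samples per genotype-expression and
#'   survival table
#' @param baseMedianSurvival median survival (months) of the
#'   better-faring stratum
#' @param censorHorizon administrative censoring horizon (months)
#' @param exprBackground also emit (null) expression/survival tables
#'   for background variants, so the penetrance filter is exercised on
#'   true negatives as well
#' @return list of class \code{generatorConfig}
#' @export
generatorConfig <- function(seed = 42L,
                            nNM = 4L, nLM = 4L,
                            nBackground = 1000L, nDriver = 10L,
                            nResister = 1L,
                            depthMean = 197,
                            driverBoost = 3,
                            backgroundDrift = 0.98,
                            orEffect = 50,
                            ctrlCarrierProb = 0.02,
                            eqtlSlope = 1.5,
                            hazardRatio = 3,
                            nDriverUp = 6L,
                            cohortSizes = c(cohortA = 10L, cohortB = 24L,
                                            cohortC = 19L),
                            caseFraction = 28 / 53,
                            purityTumor = 0.52, puritySdTumor = 0.08,
                            purityGapNM = 0.28, purityGapLM = 0.10,
                            purityGapSd = 0.03,
                            nExprSamples = 300L, nSurvSamples = 300L,
                            baseMedianSurvival = 40,
                            censorHorizon = 120,
                            exprBackground = TRUE) {
  nDriverUp <- min(as.integer(nDriverUp), as.integer(nDriver))
  cfg <- list(seed = as.integer(seed), nNM = as.integer(nNM),
              nLM = as.integer(nLM),
              nBackground = as.integer(nBackground),
              nDriver = as.integer(nDriver),
              nResister = as.integer(nResister),
              depthMean = depthMean, driverBoost = driverBoost,
              backgroundDrift = backgroundDrift, orEffect = orEffect,
              ctrlCarrierProb = ctrlCarrierProb, eqtlSlope = eqtlSlope,
              hazardRatio = hazardRatio, nDriverUp = nDriverUp,
              cohortSizes = cohortSizes, caseFraction = caseFraction,
              purityTumor = purityTumor, puritySdTumor = puritySdTumor,
              purityGapNM = purityGapNM, purityGapLM = purityGapLM,
              purityGapSd = purityGapSd,
              nExprSamples = as.integer(nExprSamples),
              nSurvSamples = as.integer(nSurvSamples),
              baseMedianSurvival = baseMedianSurvival,
              censorHorizon = censorHorizon,
              exprBackground = isTRUE(exprBackground))
  with(cfg, {
    stopifnot(nNM > 0, nLM > 0, nBackground > 0, nDriver >= 0,
              nResister >= 0, depthMean > 0, driverBoost >= 1,
              backgroundDrift > 0, backgroundDrift <= 1,
              ctrlCarrierProb >= 0, ctrlCarrierProb < 1,
              hazardRatio > 0, nDriverUp <= nDriver,
              caseFraction > 0, caseFraction < 1,
              all(cohortSizes > 0), censorHorizon > 0)
    if (orEffect < 1)
      stop("orEffect must be >= 1; model resistance through the ",
           "resister pathway, not an inverted odds ratio", call. = FALSE)
  })
  structure(cfg, class = "generatorConfig")
}

# the shared variant catalog: identities, roles, population frequencies
# and planted effect directions. Uses its own derived seed so that every
# simulator sees the same catalog.
.variantCatalog <- function(config) {
  set.seed(.deriveSeed(config$seed, 1L))
  n <- config$nBackground + config$nDriver + config$nResister
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  role <- c(rep("background", config$nBackground),
            rep("driver", config$nDriver),
            rep("resister", config$nResister))
  planted <- role != "background"
  id <- sprintf("%s%04d", ifelse(planted, "pl", "bg"), seq_len(n))
  cat <- data.frame(
    variant_id = variantId(chrom, pos, ref, alt),
    label = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    rsid = ifelse(planted, sprintf("rs9%06d", seq_len(n)), NA_character_),
    gene = ifelse(planted, sprintf("GENE%03d", seq_len(n)), NA_character_),
    role = role,
    popFreq = stats::runif(n, 0.1, 0.9),
    stringsAsFactors = FALSE)
  # planted effect orientation: drivers confer the worse-survival
  # stratum (MP); the resister confers the better one (MR)
  cat$eqtl_direction <- NA_character_
  cat$worse_stratum <- NA_character_
  cat$class <- NA_character_
  drv <- which(cat$role == "driver")
  if (length(drv)) {
    up <- drv[seq_len(min(config$nDriverUp, length(drv)))]
    dn <- setdiff(drv, up)
    cat$eqtl_direction[up] <- "up";   cat$worse_stratum[up] <- "high"
    cat$eqtl_direction[dn] <- "down"; cat$worse_stratum[dn] <- "low"
    cat$class[drv] <- "MP"
  }
  res <- which(cat$role == "resister")
  if (length(res)) {
    cat$eqtl_direction[res] <- "up"
    cat$worse_stratum[res] <- "low"
    cat$class[res] <- "MR"
  }
  if (anyDuplicated(cat$variant_id))
    cat <- cat[!duplicated(cat$variant_id), , drop = FALSE]
  cat
}

#' Simulate the tri-tissue discovery cohort
#'
#' Germline genotypes are drawn at each variant's population frequency
#' (dosage ~ Binomial(2, f)); carried variants have true VAF 0.5
#' (heterozygous) or 1 (homozygous) in every tissue, read depths are
#' Poisson with the configured mean, and alt reads are Binomial(depth,
#' tissue VAF). Background variants receive the global paracancer
#' drift. Planted drivers are carried heterozygously by every subject;
#' in LM subjects their paracancer VAF is multiplied by the driver
#' boost (capped at 1) and their tumor VAF divided by it, yielding a
#' strongly positive LIP; the resister applies the inverse. Tumor and
#' paracancer purities are drawn with a smaller tumor-to-paracancer gap
#' in LM subjects. The ground-truth manifest always accompanies the
#' data.
#'
#' @param config a \code{\link{generatorConfig}}
#' @return list with \code{cohort} (a raw \code{VariantCohort} with
#'   library sizes and purities), \code{truth} (the variant catalog)
#'   and \code{config}
#' @export
simulateDiscoveryCohort <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  cat <- .variantCatalog(config)
  set.seed(.deriveSeed(config$seed, 2L))
  subj <- c(paste0("N", seq_len(config$nNM)),
            paste0("L", seq_len(config$nLM)))
  grp <- c(rep("NM", config$nNM), rep("LM", config$nLM))
  nv <- nrow(cat)
  planted <- cat$role != "background"
  rows <- vector("list", length(subj))
  for (s in seq_along(subj)) {
    dosage <- stats::rbinom(nv, 2, cat$popFreq)
    dosage[planted] <- 1L # planted variants: heterozygous in all subjects
    keep <- dosage > 0
    base <- dosage[keep] / 2
    role <- cat$role[keep]
    vN <- base
    vP <- base * config$backgroundDrift
    vT <- base
    if (grp[s] == "LM") {
      isD <- role == "driver"
      isR <- role == "resister"
      vP[isD] <- pmin(1, base[isD] * config$driverBoost)
      vT[isD] <- base[isD] / config$driverBoost
      vP[isR] <- base[isR] / config$driverBoost
      vT[isR] <- pmin(1, base[isR] * config$driverBoost)
    }
    nk <- sum(keep)
    depthN <- stats::rpois(nk, config$depthMean)
    depthP <- stats::rpois(nk, config$depthMean)
    depthT <- stats::rpois(nk, config$depthMean)
    rows[[s]] <- data.frame(
      subject = subj[s], group = grp[s],
      chrom = cat$chrom[keep], pos = cat$pos[keep],
      ref = cat$ref[keep], alt = cat$alt[keep], rsid = cat$rsid[keep],
      normal_alt = stats::rbinom(nk, depthN, vN),
      normal_total = depthN,
      paracancer_alt = stats::rbinom(nk, depthP, vP),
      paracancer_total = depthP,
      tumor_alt = stats::rbinom(nk, depthT, vT),
      tumor_total = depthT,
      stringsAsFactors = FALSE)
  }
  # one sequencing effort per subject, shared by the three tissues: the
  # binomial read model already places all tissues on a common scale, so
  # per-tissue library rescaling must be a no-op on simulated data
  effort <- round(stats::rlnorm(length(subj), log(6e7), 0.15))
  libs <- data.frame(subject = subj, normal = effort,
                     paracancer = effort, tumor = effort)
  tum <- pmin(0.95, pmax(0.05, stats::rnorm(length(subj),
                                            config$purityTumor,
                                            config$puritySdTumor)))
  gap <- stats::rnorm(length(subj),
                      ifelse(grp == "LM", config$purityGapLM,
                             config$purityGapNM),
                      config$purityGapSd)
  par <- pmin(tum, pmax(0.02, tum - gap))
  pur <- data.frame(subject = subj, tumor = tum, paracancer = par)
  cohort <- VariantCohort(do.call(rbind, rows), librarySizes = libs,
                          purities = pur)
  list(cohort = cohort, truth = cat, config = config)
}

#' Simulate case-control validation cohorts
#'
#' Named cohorts of carrier profiles with metastasis labels. Planted
#' variants are carried with control probability
#' \code{ctrlCarrierProb} and a case probability chosen so the
#' expected carrier odds ratio equals \code{orEffect}; background
#' variants share one carrier probability in both groups. A
#' \code{discovery}-named cohort of the discovery-cohort size is
#' included so leave-one-cohort-out evaluation covers four datasets.
#'
#' @param config a \code{\link{generatorConfig}}
#' @return list with \code{carriers} (subjects x variants 0/1 matrix),
#'   \code{labels} (named metastasis / non-metastasis), \code{cohorts}
#'   (named cohort of each subject), \code{truth}, \code{config}
#' @export
simulateValidationCohorts <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  cat <- .variantCatalog(config)
  set.seed(.deriveSeed(config$seed, 3L))
  sizes <- c(config$cohortSizes,
             discovery = config$nNM + config$nLM)
  cohort <- rep(names(sizes), sizes)
  nSub <- length(cohort)
  subj <- sprintf("V%03d", seq_len(nSub))
  case <- unlist(lapply(sizes, function(k) {
    nc <- round(k * config$caseFraction)
    sample(c(rep(TRUE, nc), rep(FALSE, k - nc)))
  }), use.names = FALSE)
  labels <- stats::setNames(ifelse(case, "metastasis", "non-metastasis"),
                            subj)
  if (config$ctrlCarrierProb > 0) {
    oddsCtrl <- config$ctrlCarrierProb / (1 - config$ctrlCarrierProb)
    oddsCase <- oddsCtrl * config$orEffect
    pCase <- oddsCase / (1 + oddsCase)
  } else {
    pCase <- 0.5 # structural +Inf odds ratio: carriers confined to cases
  }
  planted <- cat$role != "background"
  pMat <- matrix(rep(cat$popFreq, each = nSub), nrow = nSub)
  pMat[, planted] <- ifelse(case, pCase, config$ctrlCarrierProb)
  # background carrier probability: subject-level carrier frequency
  pMat[, !planted] <- 1 - (1 - pMat[, !planted])^2
  carriers <- matrix(stats::rbinom(length(pMat), 1, pMat), nrow = nSub,
                     dimnames = list(subj, cat$variant_id))
  list(carriers = carriers, labels = labels,
       cohorts = stats::setNames(cohort, subj),
       truth = cat, config = config)
}

#' Simulate genotype-expression and survival tables
#'
#' For every planted variant (and, optionally, every background
#' variant as a true-negative control): a genotype-expression table
#' with expression = baseline + slope * dosage + Gaussian noise (slope
#' signed per the planted eQTL direction, 0 for background), and a
#' survival table whose high/low expression strata differ by the
#' configured hazard ratio (exponential times, administratively
#' censored at the horizon). Which stratum fares worse follows the
#' planted MP/MR orientation; background hazards are equal.
#'
#' @param config a \code{\link{generatorConfig}}
#' @return list with \code{expression} (named list of data.frames
#'   \code{dosage}/\code{expression}), \code{survival} (named list of
#'   data.frames \code{time}/\code{event}/\code{expression}),
#'   \code{truth}, \code{config}
#' @export
simulateExpressionSurvival <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  cat <- .variantCatalog(config)
  set.seed(.deriveSeed(config$seed, 4L))
  which_ <- if (config$exprBackground) seq_len(nrow(cat)) else
    which(cat$role != "background")
  baseRate <- log(2) / config$baseMedianSurvival
  expr <- list()
  surv <- list()
  for (i in which_) {
    id <- cat$variant_id[i]
    slope <- if (is.na(cat$eqtl_direction[i])) 0 else
      ifelse(cat$eqtl_direction[i] == "up", 1, -1) * config$eqtlSlope
    dosage <- stats::rbinom(config$nExprSamples, 2, cat$popFreq[i])
    expr[[id]] <- data.frame(
      dosage = dosage,
      expression = 10 + slope * dosage +
        stats::rnorm(config$nExprSamples))
    e <- stats::rnorm(config$nSurvSamples)
    stratum <- dichotomizeExpression(e)
    hr <- rep(1, config$nSurvSamples)
    if (!is.na(cat$worse_stratum[i]))
      hr[stratum == cat$worse_stratum[i]] <- config$hazardRatio
    t0 <- stats::rexp(config$nSurvSamples, rate = baseRate * hr)
    surv[[id]] <- data.frame(
      time = pmin(t0, config$censorHorizon),
      event = as.integer(t0 <= config$censorHorizon),
      expression = e)
  }
  list(expression = expr, survival = surv, truth = cat, config = config)
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper generating the discovery cohort, the validation
#' cohorts and the expression/survival tables from one configuration
#' (one shared variant catalog and ground-truth manifest).
#'
#' @param config a \code{\link{generatorConfig}}
#' @return list with \code{discovery}, \code{validation},
#'   \code{exprsurv}, \code{truth}, \code{config}
#' @export
simulateStudy <- function(config = generatorConfig()) {
  disc <- simulateDiscoveryCohort(config)
  val <- simulateValidationCohorts(config)
  es <- simulateExpressionSurvival(config)
  list(discovery = disc, validation = val, exprsurv = es,
       truth = disc$truth, config = config)
}
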