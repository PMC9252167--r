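#' @import methods
NULL

.TISSUES <- c("normal", "paracancer", "tumor")

.DEPTH_COLS <- c("normal_alt", "normal_total",
                 "paracancer_alt", "paracancer_total",
                 "tumor_alt", "tumor_total")

.VARIANT_COLS <- c("subject", "group", "chrom", "pos", "ref", "alt", "rsid",
                   .DEPTH_COLS)

#' VariantCohort: tri-tissue variant profiles for a cohort
#'
#' Container for per-subject variant calls with allele depths in three
#' matched tissues (normal, paracancer, tumor). Each row of the variant
#' table is one variant in one subject; normalized variant allele
#' fractions (columns \code{vN}, \code{vP}, \code{vT}) are added by
#' \code{\link{normalizeVafs}} and are required by the LIP statistics.
#'
#' @slot variants data.frame with columns \code{subject}, \code{group}
#'   (one of \code{NM}, \code{LM}, \code{unknown}), \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt} (\code{"-"} marks a
#'   pure insertion/deletion allele), \code{rsid} (\code{NA} if absent),
#'   the six per-tissue depth columns \code{<tissue>_alt} /
#'   \code{<tissue>_total}, and, after normalization, \code{vN},
#'   \code{vP}, \code{vT}.
#' @slot librarySizes data.frame with columns \code{subject},
#'   \code{normal}, \code{paracancer}, \code{tumor}: total aligned read
#'   counts per tissue, used by the library-size VAF normalization.
#'   May have zero rows.
#' @slot purities data.frame with columns \code{subject}, \code{tumor},
#'   \code{paracancer}: tumor-cell fractions in [0, 1]. May have zero
#'   rows.
#' @slot normalized character flag: \code{"raw"} (depths only),
#'   \code{"none"} (plain alt/total VAFs) or \code{"library_size"}.
#'
#' @seealso \code{\link{VariantCohort}}, \code{\link{normalizeVafs}},
#'   \code{\link{summarizeLip}}
#' @exportClass VariantCohort
setClass("VariantCohort",
  representation(
    variants     = "data.frame",
    librarySizes = "data.frame",
    purities     = "data.frame",
    normalized   = "character"
  ),
  prototype(
    variants     = data.frame(),
    librarySizes = data.frame(subject = character(), normal = numeric(),
                              paracancer = numeric(), tumor = numeric()),
    purities     = data.frame(subject = character(), tumor = numeric(),
                              paracancer = numeric()),
    normalized   = "raw"
  )
)

setValidity("VariantCohort", function(object) {
  v <- object@variants
  msg <- character()
  if (nrow(v) > 0) {
    miss <- setdiff(.VARIANT_COLS, names(v))
    if (length(miss))
      return(paste("missing variant columns:", paste(miss, collapse = ", ")))
    if (!all(v$group %in% c("NM", "LM", "unknown")))
      msg <- c(msg, "group must be one of NM, LM, unknown")
    if (any(v$pos < 1))
      msg <- c(msg, "pos must be >= 1")
    if (any(v$ref == v$alt))
      msg <- c(msg, "ref and alt must differ")
    if (any(v$ref == "-" & v$alt == "-"))
      msg <- c(msg, "at most one of ref/alt may be '-'")
    for (t in .TISSUES) {
      a <- v[[paste0(t, "_alt")]]
      d <- v[[paste0(t, "_total")]]
      if (any(a < 0) || any(d < 0) || any(a > d))
        msg <- c(msg, sprintf("%s depths invalid (need 0 <= alt <= total)", t))
    }
    key <- paste(v$subject, v$chrom, v$pos, v$ref, v$alt, sep = ":")
    if (anyDuplicated(key))
      msg <- c(msg, paste("duplicate (subject, variant) rows:",
                          paste(unique(key[duplicated(key)]), collapse = ", ")))
    if (object@normalized != "raw") {
      if (!all(c("vN", "vP", "vT") %in% names(v)))
        msg <- c(msg, "normalized cohort must carry vN, vP, vT")
      else if (any(!is.finite(c(v$vN, v$vP, v$vT))) ||
               any(c(v$vN, v$vP, v$vT) < 0))
        msg <- c(msg, "normalized VAFs must be finite and >= 0")
    }
  }
  ls <- object@librarySizes
  if (nrow(ls) > 0 && any(as.matrix(ls[.TISSUES]) <= 0))
    msg <- c(msg, "library sizes must be positive")
  pu <- object@purities
  if (nrow(pu) > 0 &&
      any(pu$tumor < 0 | pu$tumor > 1 | pu$paracancer < 0 | pu$paracancer > 1))
    msg <- c(msg, "purities must lie in [0, 1]")
  if (!object@normalized %in% c("raw", "none", "library_size"))
    msg <- c(msg, "normalized must be raw, none or library_size")
  if (length(msg)) msg else TRUE
})

#' LipSummary: per-variant and per-subject LIP statistics
#'
#' Result of \code{\link{summarizeLip}}: one LIP record per (subject,
#' variant), the per-variant mean LIP over subjects that carry the
#' variant with a finite LIP, and the per-subject sLIP (sum of that
#' subject's finite LIPs).
#'
#' @slot lipRecords data.frame: \code{subject}, \code{group},
#'   \code{variant_id}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{rsid}, \code{R} (invasion promotion rate), \code{Rbar}
#'   (invasion resistance rate), \code{LIP} (bits).
#' @slot perVariant data.frame: \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{rsid},
#'   \code{n_subjects}, \code{mean_LIP}.
#' @slot perSubject data.frame: \code{subject}, \code{group},
#'   \code{n_variants}, \code{sLIP}.
#'
#' @exportClass LipSummary
setClass("LipSummary",
  representation(
    lipRecords = "data.frame",
    perVariant = "data.frame",
    perSubject = "data.frame"
  )
)

setValidity("LipSummary", function(object) {
  ps <- object@perSubject
  lr <- object@lipRecords
  if (nrow(ps) > 0 && nrow(lr) > 0) {
    s <- vapply(split(lr$LIP, lr$subject), sum, numeric(1))
    got <- ps$sLIP[match(names(s), ps$subject)]
    if (any(abs(got - s) > 1e-8 * pmax(1, abs(s))))
      return("per-subject sLIP does not equal the sum of finite LIPs")
    n <- vapply(split(lr$LIP, lr$subject), length, integer(1))
    if (any(ps$n_variants[match(names(n), ps$subject)] != n))
      return("n_variants does not match the LIP record count")
  }
  TRUE
})

#' ContingencyTable: 2x2 carrier counts for one variant
#'
#' Carrier/non-carrier counts split by metastasis status, the input of
#' the cross-product odds ratio.
#'
#' @slot Mm metastasis-group carriers
#' @slot Mn metastasis-group non-carriers
#' @slot Nm non-metastasis-group carriers
#' @slot Nn non-metastasis-group non-carriers
#'
#' @seealso \code{\link{buildContingency}}, \code{\link{oddsRatio}}
#' @exportClass ContingencyTable
setClass("ContingencyTable",
  representation(Mm = "numeric", Mn = "numeric", Nm = "numeric", Nn = "numeric")
)

setValidity("ContingencyTable", function(object) {
  cells <- c(object@Mm, object@Mn, object@Nm, object@Nn)
  if (length(cells) != 4 || any(!is.finite(cells)))
    return("all four cells must be single finite numbers")
  if (any(cells < 0))
    return("cells must be non-negative")
  if (any(cells != round(cells)))
    return("cells must be whole counts")
  TRUE
})

#' CascadeResult: outcome of the driver/resister identification cascade
#'
#' @slot candidates data.frame of surviving candidate variants, sorted
#'   by survival p-value: \code{variant_id}, \code{rsid}, \code{ref},
#'   \code{alt}, \code{gene}, \code{arm} (promoter/resister),
#'   \code{class} (MP/MR), \code{mean_LIP}, \code{OR}, \code{eqtl_p},
#'   \code{eqtl_direction}, \code{survival_p}, \code{worse_stratum}.
#' @slot funnel named integer vector of per-step variant counts
#'   (input, lip_positive, promoter, resister, or_pass, eqtl_pass,
#'   survival_pass).
#' @slot log data.frame accounting for every excluded variant:
#'   \code{variant_id}, \code{stage}, \code{reason}.
#' @slot config the \code{CascadeConfig} used.
#'
#' @exportClass CascadeResult
setClass("CascadeResult",
  representation(
    candidates = "data.frame",
    funnel     = "integer",
    log        = "data.frame",
    config     = "list"
  )
)

#' RiskModel: LIP-weighted logistic classifier of early metastatic risk
#'
#' The classifier scores a subject by the dot product of the binary
#' carrier vector V over a fixed variant panel with the panel's average
#' LIP weights L, passed through a logistic regression fitted by maximum
#' likelihood (with a small L2 ridge fallback under complete
#' separation).
#'
#' @slot panel character vector of variant identifiers (ordered).
#' @slot L numeric LIP weight per panel variant (bits), estimated as the
#'   training-cohort average LIP.
#' @slot w numeric regression coefficients, one per panel variant.
#' @slot b numeric(1) intercept.
#' @slot penalty numeric(1) L2 penalty actually used (0 for plain MLE).
#' @slot meta list of fitting metadata (method, convergence, n, classes).
#'
#' @seealso \code{\link{fitRiskModel}}, \code{\link{predictRisk}}
#' @exportClass RiskModel
setClass("RiskModel",
  representation(
    panel   = "character",
    L       = "numeric",
    w       = "numeric",
    b       = "numeric",
    penalty = "numeric",
    meta    = "list"
  )
)

setValidity("RiskModel", function(object) {
  k <- length(object@panel)
  if (length(object@L) != k || length(object@w) != k)
    return("panel, L and w must have equal length")
  if (length(object@b) != 1 || !is.finite(object@b))
    return("b must be a single finite number")
  if (any(!is.finite(object@L)) || any(!is.finite(object@w)))
    return("L and w must be finite")
  TRUE
})

#' EvalReport: confusion-matrix metrics and AUC of a binary classifier
#'
#' @slot TP,TN,FP,FN confusion-matrix cells at the decision threshold.
#' @slot accuracy (TP+TN)/n.
#' @slot sensitivity TP/(TP+FN).
#' @slot specificity TN/(TN+FP).
#' @slot auc area under the ROC curve (rank statistic, ties counted 1/2).
#' @slot threshold decision threshold on the predicted probability.
#'
#' @seealso \code{\link{evaluateModel}}
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    TP = "integer", TN = "integer", FP = "integer", FN = "integer",
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    auc = "numeric", threshold = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  cells <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(cells < 0)) return("confusion cells must be non-negative")
  n <- sum(cells)
  if (n > 0 && abs(object@accuracy - (object@TP + object@TN) / n) > 1e-12)
    return("accuracy inconsistent with confusion cells")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    return("auc must lie in [0, 1]")
  TRUE
})
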