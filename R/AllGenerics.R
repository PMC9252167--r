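#' Accessors and generics
#'
#' @name metalip-generics
#' @keywords internal
NULL

#' Variant table of a cohort
#' @param x a \code{VariantCohort}
#' @return data.frame of per-subject, per-variant rows
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname variantCalls
#' @export
setMethod("variantCalls", "VariantCohort", function(x) x@variants)

#' Subjects of a cohort
#' @param x a \code{VariantCohort} or \code{LipSummary}
#' @return character vector of subject identifiers
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname subjects
#' @export
setMethod("subjects", "VariantCohort",
          function(x) unique(x@variants$subject))

#' @rdname subjects
#' @export
setMethod("subjects", "LipSummary", function(x) x@perSubject$subject)

#' Library sizes of a cohort
#' @param x a \code{VariantCohort}
#' @return data.frame (subject, normal, paracancer, tumor)
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "VariantCohort", function(x) x@librarySizes)

#' Tissue purities of a cohort
#' @param x a \code{VariantCohort}
#' @return data.frame (subject, tumor, paracancer)
#' @export
setGeneric("purities", function(x) standardGeneric("purities"))

#' @rdname purities
#' @export
setMethod("purities", "VariantCohort", function(x) x@purities)

#' Normalization state of a cohort
#' @param x a \code{VariantCohort}
#' @return one of \code{"raw"}, \code{"none"}, \code{"library_size"}
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname normalization
#' @export
setMethod("normalization", "VariantCohort", function(x) x@normalized)

#' Per-variant LIP summary
#' @param x a \code{LipSummary}
#' @return data.frame with mean LIP per variant over finite-LIP carriers
#' @export
setGeneric("perVariant", function(x) standardGeneric("perVariant"))

#' @rdname perVariant
#' @export
setMethod("perVariant", "LipSummary", function(x) x@perVariant)

#' Per-subject sLIP summary
#' @param x a \code{LipSummary}
#' @return data.frame with sLIP and variant count per subject
#' @export
setGeneric("perSubject", function(x) standardGeneric("perSubject"))

#' @rdname perSubject
#' @export
setMethod("perSubject", "LipSummary", function(x) x@perSubject)

#' Per-(subject, variant) LIP records
#' @param x a \code{LipSummary}
#' @return data.frame with R, Rbar and LIP per subject and variant
#' @export
setGeneric("lipRecords", function(x) standardGeneric("lipRecords"))

#' @rdname lipRecords
#' @export
setMethod("lipRecords", "LipSummary", function(x) x@lipRecords)

#' Odds ratio of a 2x2 carrier table
#'
#' Cross-product ratio (Mm * Nn) / (Mn * Nm). A zero denominator with a
#' positive numerator yields \code{Inf}; a zero numerator and zero
#' denominator is undefined and yields \code{NA}.
#'
#' @param x a \code{ContingencyTable}
#' @return a single extended-real odds ratio
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' Candidate variants emitted by the cascade
#' @param x a \code{CascadeResult}
#' @return data.frame of candidates sorted by survival p-value
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname candidates
#' @export
setMethod("candidates", "CascadeResult", function(x) x@candidates)

#' Per-step variant counts of the cascade
#' @param x a \code{CascadeResult}
#' @return named integer vector
#' @export
setGeneric("funnel", function(x) standardGeneric("funnel"))

#' @rdname funnel
#' @export
setMethod("funnel", "CascadeResult", function(x) x@funnel)

#' Exclusion log of the cascade
#' @param x a \code{CascadeResult}
#' @return data.frame (variant_id, stage, reason)
#' @export
setGeneric("cascadeLog", function(x) standardGeneric("cascadeLog"))

#' @rdname cascadeLog
#' @export
setMethod("cascadeLog", "CascadeResult", function(x) x@log)

#' Variant panel of a risk model
#' @param x a \code{RiskModel}
#' @return character vector of panel variant identifiers
#' @export
setGeneric("panelVariants", function(x) standardGeneric("panelVariants"))

#' @rdname panelVariants
#' @export
setMethod("panelVariants", "RiskModel", function(x) x@panel)

#' LIP weights of a risk model
#' @param x a \code{RiskModel}
#' @return numeric vector of average training LIPs (bits)
#' @export
setGeneric("lipWeights", function(x) standardGeneric("lipWeights"))

#' @rdname lipWeights
#' @export
setMethod("lipWeights", "RiskModel", function(x) x@L)

#' Coefficients of a risk model
#' @param object a \code{RiskModel}
#' @param ... unused
#' @return named numeric vector: intercept \code{b} then one coefficient
#'   per panel variant
#' @export
setMethod("coef", "RiskModel", function(object, ...) {
  c(b = object@b, stats::setNames(object@w, object@panel))
})

setMethod("show", "VariantCohort", function(object) {
  v <- object@variants
  cat("VariantCohort with", length(unique(v$subject)), "subject(s),",
      nrow(v), "variant call(s)\n")
  if (nrow(v)) {
    cat("  groups:", paste(sprintf("%s=%d", names(table(unique(
      v[c("subject", "group")])$group)),
      table(unique(v[c("subject", "group")])$group)), collapse = ", "), "\n")
  }
  cat("  normalization:", object@normalized, "\n")
  cat("  library sizes:", if (nrow(object@librarySizes)) "present" else "absent",
      "| purities:", if (nrow(object@purities)) "present" else "absent", "\n")
})

setMethod("show", "LipSummary", function(object) {
  cat("LipSummary:", nrow(object@lipRecords), "LIP record(s),",
      nrow(object@perVariant), "variant(s),",
      nrow(object@perSubject), "subject(s)\n")
  if (nrow(object@perSubject)) {
    cat("  sLIP range: [",
        sprintf("%.3f", min(object@perSubject$sLIP)), ", ",
        sprintf("%.3f", max(object@perSubject$sLIP)), "]\n", sep = "")
  }
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable (carriers / non-carriers)\n")
  cat(sprintf("  metastasis:     %d / %d\n", object@Mm, object@Mn))
  cat(sprintf("  non-metastasis: %d / %d\n", object@Nm, object@Nn))
  cat("  odds ratio:", format(oddsRatio(object)), "\n")
})

setMethod("show", "CascadeResult", function(object) {
  cat("CascadeResult:", nrow(object@candidates), "candidate variant(s)\n")
  cat("  funnel:", paste(sprintf("%s=%d", names(object@funnel), object@funnel),
                         collapse = " -> "), "\n")
  if (nrow(object@candidates)) {
    cat("  classes:", paste(sprintf("%s=%d",
        names(table(object@candidates$class)),
        table(object@candidates$class)), collapse = ", "), "\n")
  }
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel over", length(object@panel), "panel variant(s)\n")
  cat("  fit:", if (object@penalty > 0)
        sprintf("L2-penalized likelihood (lambda = %g)", object@penalty)
      else "maximum likelihood", "\n")
  cat("  intercept b =", sprintf("%.4f", object@b), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport (threshold %.2f): TP=%d TN=%d FP=%d FN=%d\n",
    object@threshold, object@TP, object@TN, object@FP, object@FN))
  cat(sprintf("  accuracy=%.4f sensitivity=%.4f specificity=%.4f auc=%s\n",
              object@accuracy, object@sensitivity, object@specificity,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
})
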