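#' Build a 2x2 carrier contingency table
#'
#' Counts subjects (dominant carrier model: a subject carrying the
#' variant on at least one allele scores 1) split by metastasis status.
#'
#' @param carrierStatus named 0/1 vector (or logical), one entry per
#'   subject
#' @param labels named character vector over the same subjects, values
#'   \code{"metastasis"} or \code{"non-metastasis"}
#' @return a \code{\link[=ContingencyTable-class]{ContingencyTable}}
#' @examples
#' status <- c(s1 = 1, s2 = 0, s3 = 1, s4 = 0)
#' labels <- c(s1 = "metastasis", s2 = "metastasis",
#'             s3 = "non-metastasis", s4 = "non-metastasis")
#' buildContingency(status, labels)
#' @export
buildContingency <- function(carrierStatus, labels) {
  carrierStatus <- stats::setNames(as.integer(carrierStatus),
                                   names(carrierStatus))
  if (!all(carrierStatus %in% c(0L, 1L)))
    stop("carrier status must be binary 0/1", call. = FALSE)
  if (is.null(names(carrierStatus)) || is.null(names(labels)))
    stop("carrierStatus and labels must be named by subject", call. = FALSE)
  unl <- setdiff(names(carrierStatus), names(labels))
  if (length(unl))
    stop("subject(s) with carrier status but no label: ",
         paste(unl, collapse = ", "), call. = FALSE)
  if (!all(labels %in% c("metastasis", "non-metastasis")))
    stop("labels must be 'metastasis' or 'non-metastasis'", call. = FALSE)
  lab <- labels[names(carrierStatus)]
  new("ContingencyTable",
      Mm = sum(carrierStatus == 1 & lab == "metastasis"),
      Mn = sum(carrierStatus == 0 & lab == "metastasis"),
      Nm = sum(carrierStatus == 1 & lab == "non-metastasis"),
      Nn = sum(carrierStatus == 0 & lab == "non-metastasis"))
}

#' @rdname oddsRatio
#' @export
setMethod("oddsRatio", "ContingencyTable", function(x) {
  .oddsRatioCells(x@Mm, x@Mn, x@Nm, x@Nn)
})

# vectorized cross-product ratio with the extended-real conventions
.oddsRatioCells <- function(Mm, Mn, Nm, Nn) {
  num <- Mm * Nn
  den <- Mn * Nm
  out <- num / den
  out[den == 0 & num > 0] <- Inf
  out[den == 0 & num == 0] <- NA_real_
  out
}

#' Odds-ratio screen over a carrier matrix
#'
#' Builds the per-variant 2x2 carrier table against the metastasis
#' labels and computes the cross-product odds ratio for every variant.
#' No continuity correction is applied by default: infinite odds ratios
#' from an empty control-carrier cell are reported as \code{Inf} and
#' deliberately retained (they indicate carriers confined to the
#' metastasis group). The counting unit is the subject; set
#' \code{unit = "allele"} to count alleles from a 0/1/2 dosage matrix
#' instead (sensitivity analysis).
#'
#' @param carriers subjects x variants matrix: binary carrier status
#'   (or dosages 0/1/2 under \code{unit = "allele"}); must have row and
#'   column names
#' @param labels named character vector (\code{"metastasis"} /
#'   \code{"non-metastasis"}) over the subjects
#' @param unit counting unit, \code{"subject"} (default) or
#'   \code{"allele"}
#' @param haldane if \code{TRUE}, add 0.5 to every cell
#'   (Haldane-Anscombe correction; off by default so that structural
#'   \code{Inf} odds ratios are preserved)
#' @return data.frame: \code{variant_id}, \code{Mm}, \code{Mn},
#'   \code{Nm}, \code{Nn}, \code{OR}
#' @export
oddsRatioScreen <- function(carriers, labels, unit = c("subject", "allele"),
                            haldane = FALSE) {
  unit <- match.arg(unit)
  carriers <- as.matrix(carriers)
  if (is.null(rownames(carriers)) || is.null(colnames(carriers)))
    stop("carriers must have subject rownames and variant colnames",
         call. = FALSE)
  unl <- setdiff(rownames(carriers), names(labels))
  if (length(unl))
    stop("subject(s) without a label: ", paste(unl, collapse = ", "),
         call. = FALSE)
  lab <- labels[rownames(carriers)]
  met <- lab == "metastasis"
  if (unit == "subject") {
    carriers <- (carriers > 0) + 0
    Mm <- colSums(carriers[met, , drop = FALSE])
    Nm <- colSums(carriers[!met, , drop = FALSE])
    Mn <- sum(met) - Mm
    Nn <- sum(!met) - Nm
  } else {
    if (any(!carriers %in% 0:2))
      stop("allele unit requires a 0/1/2 dosage matrix", call. = FALSE)
    Mm <- colSums(carriers[met, , drop = FALSE])
    Nm <- colSums(carriers[!met, , drop = FALSE])
    Mn <- 2 * sum(met) - Mm
    Nn <- 2 * sum(!met) - Nm
  }
  if (haldane) {
    Mm <- Mm + 0.5; Mn <- Mn + 0.5; Nm <- Nm + 0.5; Nn <- Nn + 0.5
  }
  data.frame(variant_id = colnames(carriers),
             Mm = unname(Mm), Mn = unname(Mn),
             Nm = unname(Nm), Nn = unname(Nn),
             OR = unname(.oddsRatioCells(Mm, Mn, Nm, Nn)),
             stringsAsFactors = FALSE)
}

#' Filter variants by odds ratio
#'
#' Retains variants with OR strictly above the threshold. \code{Inf}
#' always passes; an undefined OR (\code{NA}, from an all-zero
#' cross-product) never passes.
#'
#' @param or named numeric vector of odds ratios (names = variant ids)
#' @param threshold strict lower bound (default 5)
#' @return character vector of retained variant ids
#' @export
filterByOr <- function(or, threshold = 5) {
  .assertScalarNumber(threshold, "threshold")
  if (length(or) == 0) return(character())
  if (is.null(names(or)))
    stop("or must be named by variant id", call. = FALSE)
  names(or)[!is.na(or) & or > threshold]
}

#' Write an odds-ratio screen table
#'
#' Tab-delimited output with fixed tokens \code{"+inf"} for infinite and
#' \code{"NA"} for undefined odds ratios.
#'
#' @param screen data.frame from \code{\link{oddsRatioScreen}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeOrTable <- function(screen, path) {
  out <- screen
  out$OR <- ifelse(is.na(out$OR), "NA",
                   ifelse(is.infinite(out$OR), "+inf",
                          sprintf("%.17g", out$OR)))
  .writeAtomic(function(tmp) utils::write.table(
    out, tmp, sep = "\t", quote = FALSE, row.names = FALSE), path)
}
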