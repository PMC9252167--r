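#' Invasion promotion rate
#'
#' Ratio of the paracancer VAF to the tumor VAF of a variant. Values
#' above 1 mean the variant allele is relatively enriched in the
#' paracancer tissue, the substrate of local invasion.
#'
#' @param vP paracancer VAF (>= 0)
#' @param vT tumor VAF (> 0; zero VAFs must be resolved upstream by the
#'   zero policy of \code{\link{normalizeVafs}})
#' @return vP / vT, vectorized
#' @export
promotionRate <- function(vP, vT) {
  if (any(!is.finite(vP)) || any(!is.finite(vT)))
    stop("non-finite VAF input", call. = FALSE)
  if (any(vP < 0)) stop("paracancer VAF must be >= 0", call. = FALSE)
  if (any(vT <= 0))
    stop("tumor VAF must be > 0; apply a zero policy in normalizeVafs()",
         call. = FALSE)
  vP / vT
}

#' Invasion resistance rate
#'
#' Ratio of the tumor VAF to the normal-tissue VAF of a variant.
#'
#' @param vT tumor VAF (>= 0)
#' @param vN normal-tissue VAF (> 0)
#' @return vT / vN, vectorized
#' @export
resistanceRate <- function(vT, vN) {
  if (any(!is.finite(vT)) || any(!is.finite(vN)))
    stop("non-finite VAF input", call. = FALSE)
  if (any(vT < 0)) stop("tumor VAF must be >= 0", call. = FALSE)
  if (any(vN <= 0))
    stop("normal VAF must be > 0; apply a zero policy in normalizeVafs()",
         call. = FALSE)
  vT / vN
}

#' Local invasion power of a variant
#'
#' LIP is the base-2 log of the ratio of the invasion promotion rate
#' R = vP / vT to the invasion resistance rate Rbar = vT / vN, i.e.
#' log2(vP * vN / vT^2). LIP > 0 marks a variant prone to promoting
#' local invasion; LIP < 0 marks resistance. Doubling the paracancer
#' VAF raises LIP by exactly one bit.
#'
#' @param vN,vP,vT normalized VAFs in normal, paracancer and tumor
#'   tissue (all positive; vectorized)
#' @return data.frame with columns \code{R}, \code{Rbar}, \code{LIP}
#' @examples
#' lipScore(vN = 0.25, vP = 0.5, vT = 0.25) # R = 2, Rbar = 1, LIP = 1
#' @export
lipScore <- function(vN, vP, vT) {
  for (nm in c("vN", "vP", "vT")) {
    x <- get(nm)
    if (any(!is.finite(x)))
      stop("non-finite ", c(vN = "normal", vP = "paracancer",
                            vT = "tumor")[[nm]], "-tissue VAF", call. = FALSE)
  }
  R <- promotionRate(vP, vT)
  Rbar <- resistanceRate(vT, vN)
  data.frame(R = R, Rbar = Rbar, LIP = log2(R / Rbar))
}

#' Sum of LIPs (sLIP)
#'
#' Per-subject accumulated invasion potential, under the working
#' assumption that variant effects on local invasion add linearly.
#'
#' @param lips numeric vector of finite LIP values; an empty vector
#'   sums to 0
#' @return the sum
#' @export
slip <- function(lips) {
  if (length(lips) == 0) return(0)
  if (any(!is.finite(lips)))
    stop("sLIP requires finite LIP values", call. = FALSE)
  sum(lips)
}

#' Cohort-level LIP summary
#'
#' Computes R, Rbar and LIP for every (subject, variant) call in a
#' normalized cohort, the per-variant mean LIP across the subjects in
#' which the variant was called with a finite LIP (absence is treated as
#' absence, not as LIP 0), and the per-subject sLIP over that subject's
#' finite LIPs. Calls whose LIP is non-finite even after the zero policy
#' are dropped with a warning, never silently.
#'
#' @param cohort a normalized \code{VariantCohort}
#'   (see \code{\link{normalizeVafs}})
#' @return a \code{\link[=LipSummary-class]{LipSummary}}
#' @export
summarizeLip <- function(cohort) {
  stopifnot(is(cohort, "VariantCohort"))
  if (cohort@normalized == "raw")
    stop("cohort must be normalized first (see normalizeVafs)",
         call. = FALSE)
  v <- cohort@variants
  if (nrow(v) == 0) stop("empty cohort", call. = FALSE)
  lr <- cbind(
    v[c("subject", "group", "chrom", "pos", "ref", "alt", "rsid")],
    lipScore(v$vN, v$vP, v$vT))
  lr$variant_id <- variantId(lr$chrom, lr$pos, lr$ref, lr$alt)
  bad <- !is.finite(lr$LIP)
  if (any(bad)) {
    warning(sum(bad), " variant call(s) dropped with non-finite LIP: ",
            paste(utils::head(paste(lr$subject[bad], lr$variant_id[bad]), 5),
                  collapse = "; "), call. = FALSE)
    lr <- lr[!bad, , drop = FALSE]
  }
  lr <- lr[c("subject", "group", "variant_id", "chrom", "pos", "ref",
             "alt", "rsid", "R", "Rbar", "LIP")]
  rownames(lr) <- NULL

  pv <- do.call(rbind, lapply(split(lr, lr$variant_id), function(x) {
    data.frame(variant_id = x$variant_id[1], chrom = x$chrom[1],
               pos = x$pos[1], ref = x$ref[1], alt = x$alt[1],
               rsid = x$rsid[1], n_subjects = nrow(x),
               mean_LIP = mean(x$LIP), stringsAsFactors = FALSE)
  }))
  pv <- pv[order(pv$chrom, pv$pos, pv$alt, method = "radix"), , drop = FALSE]
  rownames(pv) <- NULL

  subj <- unique(v[c("subject", "group")])
  spl <- split(lr$LIP, lr$subject)
  ps <- data.frame(
    subject = subj$subject, group = subj$group,
    n_variants = vapply(subj$subject, function(s)
      length(spl[[s]]), integer(1)),
    sLIP = vapply(subj$subject, function(s)
      slip(spl[[s]]), numeric(1)),
    stringsAsFactors = FALSE)
  ps <- ps[order(ps$subject, method = "radix"), , drop = FALSE]
  rownames(ps) <- NULL

  new("LipSummary", lipRecords = lr, perVariant = pv, perSubject = ps)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum test, used to compare per-subject sLIPs
#' (or per-call LIP distributions) between the non-metastasis (NM) and
#' lymphatic-metastasis (LM) groups. The exact null distribution is
#' enumerated when the combined sample size is at most 20 and there are
#' no ties; otherwise the tie-corrected normal approximation is used.
#'
#' @param x either a numeric vector (with \code{g} giving the group of
#'   each element) or a \code{LipSummary}, in which case per-subject
#'   sLIPs are compared between the NM and LM groups.
#' @param g group labels (two levels), required for the vector form
#' @param ... unused
#' @return list with \code{statistic} (rank-sum W of the first group),
#'   \code{p.value}, \code{method}
#' @export
compareGroups <- function(x, g = NULL, ...) {
  if (is(x, "LipSummary")) {
    ps <- x@perSubject
    keep <- ps$group %in% c("NM", "LM")
    g <- factor(ps$group[keep], levels = c("NM", "LM"))
    x <- ps$sLIP[keep]
  }
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2)
    stop("exactly two non-empty groups are required", call. = FALSE)
  g <- droplevels(g)
  a <- x[g == levels(g)[1]]
  b <- x[g == levels(g)[2]]
  n <- length(a) + length(b)
  ties <- anyDuplicated(x) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic) + length(a) * (length(a) + 1) / 2,
       p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Pearson correlation between sLIP and tumor-to-paracancer purity change
#'
#' @param x a \code{LipSummary} (paired with \code{purities}, the
#'   cohort's purity table) or a numeric vector of sLIPs (paired with a
#'   numeric vector of purity changes).
#' @param purities data.frame (subject, tumor, paracancer) or numeric
#'   vector of per-subject purity changes (tumor minus paracancer),
#'   aligned with \code{x}.
#' @return list with \code{r}, \code{p.value}, \code{n}
#' @export
correlateSlipPurity <- function(x, purities) {
  if (is(x, "LipSummary")) {
    ps <- x@perSubject
    stopifnot(is.data.frame(purities))
    m <- match(ps$subject, purities$subject)
    if (any(is.na(m)))
      stop("purities missing for subject(s): ",
           paste(ps$subject[is.na(m)], collapse = ", "), call. = FALSE)
    delta <- purities$tumor[m] - purities$paracancer[m]
    x <- ps$sLIP
  } else {
    delta <- as.numeric(purities)
  }
  if (length(x) != length(delta) || length(x) < 3)
    stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(delta) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, delta, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Write LIP tables
#'
#' Emits the per-call LIP records, the per-variant mean-LIP table and
#' the per-subject sLIP table as tab-delimited files.
#'
#' @param summary a \code{LipSummary}
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return character vector of the three paths written, invisibly
#' @export
writeLipTables <- function(summary, dir, prefix = "lip") {
  stopifnot(is(summary, "LipSummary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("records", "per_variant", "per_subject"),
                                 ".tsv"))
  tabs <- list(summary@lipRecords, summary@perVariant, summary@perSubject)
  for (i in seq_along(paths)) {
    tab <- tabs[[i]]
    if ("rsid" %in% names(tab)) tab$rsid[is.na(tab$rsid)] <- "."
    .writeAtomic(function(tmp) utils::write.table(
      tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE), paths[i])
  }
  invisible(paths)
}
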