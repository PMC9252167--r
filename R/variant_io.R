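#' Construct a VariantCohort from a variant table
#'
#' @param variants data.frame with columns \code{subject}, \code{group},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{rsid} and
#'   the six depth columns \code{normal_alt}, \code{normal_total},
#'   \code{paracancer_alt}, \code{paracancer_total}, \code{tumor_alt},
#'   \code{tumor_total}. Optional \code{vN}, \code{vP}, \code{vT}
#'   columns carry already-normalized VAFs.
#' @param librarySizes optional data.frame (subject, normal, paracancer,
#'   tumor) of per-tissue total aligned read counts.
#' @param purities optional data.frame (subject, tumor, paracancer) of
#'   tumor-cell fractions.
#' @param normalized normalization state; leave at \code{"raw"} unless
#'   the table already carries normalized VAF columns.
#' @return a validated \code{\link[=VariantCohort-class]{VariantCohort}};
#'   rows are placed in the canonical (subject, chrom, pos, alt) order.
#' @export
VariantCohort <- function(variants, librarySizes = NULL, purities = NULL,
                          normalized = "raw") {
  v <- as.data.frame(variants)
  if (nrow(v) > 0) {
    v$subject <- as.character(v$subject)
    v$group <- as.character(v$group)
    v$chrom <- as.character(v$chrom)
    v$pos <- as.integer(v$pos)
    v$ref <- .canonicalAllele(v$ref)
    v$alt <- .canonicalAllele(v$alt)
    v$rsid <- as.character(v$rsid)
    v$rsid[!is.na(v$rsid) & v$rsid == "."] <- NA_character_
    for (col in .DEPTH_COLS) v[[col]] <- as.integer(v[[col]])
    v <- .orderVariants(v)
    rownames(v) <- NULL
  }
  if (is.null(librarySizes))
    librarySizes <- data.frame(subject = character(), normal = numeric(),
                               paracancer = numeric(), tumor = numeric())
  if (is.null(purities))
    purities <- data.frame(subject = character(), tumor = numeric(),
                           paracancer = numeric())
  new("VariantCohort", variants = v,
      librarySizes = as.data.frame(librarySizes),
      purities = as.data.frame(purities),
      normalized = normalized)
}

.TABLE_COLS <- .VARIANT_COLS
.VAF_COLS <- c("vN", "vP", "vT")

#' Read a tab-delimited variant table
#'
#' The table holds one row per (subject, variant) with tri-tissue
#' allele depths; it is the flat-file twin of the VCF reader and
#' round-trips bit-exactly with \code{\link{writeVariantTable}}.
#' Missing rsids are written as \code{"."}; empty indel alleles as
#' \code{"-"}.
#'
#' @param path path to a UTF-8, tab-delimited file whose header names
#'   the columns listed under \code{\link{VariantCohort}}.
#' @param librarySizes,purities optional companion data.frames forwarded
#'   to the constructor.
#' @return a \code{VariantCohort} (normalization state \code{"raw"}, or
#'   the state recorded in a \code{#normalized=} header comment when the
#'   table carries vN/vP/vT columns).
#' @export
readVariantTable <- function(path, librarySizes = NULL, purities = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  normalized <- "raw"
  skip <- 0L
  if (startsWith(first, "#normalized=")) {
    normalized <- sub("^#normalized=", "", first)
    skip <- 1L
  }
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, skip = skip)
  miss <- setdiff(.TABLE_COLS, names(tab))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0)
    return(VariantCohort(
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.TABLE_COLS))),
                      .TABLE_COLS),
      librarySizes, purities, normalized = normalized))
  numCols <- c("pos", .DEPTH_COLS)
  for (col in numCols) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad))
      stop(sprintf("malformed value '%s' in column %s at line %d of %s",
                   tab[[col]][bad[1]], col, bad[1] + 1L + skip, path),
           call. = FALSE)
    tab[[col]] <- parsed
  }
  for (col in intersect(.VAF_COLS, names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  VariantCohort(tab, librarySizes, purities, normalized = normalized)
}

#' Write a variant table
#'
#' Deterministic column order and canonical (subject, chrom, pos, alt)
#' row order; VAF columns, when present, are printed with full binary
#' round-trip precision.
#'
#' @param cohort a \code{VariantCohort}
#' @param path output path (tab-delimited, UTF-8)
#' @return \code{path}, invisibly
#' @export
writeVariantTable <- function(cohort, path) {
  stopifnot(is(cohort, "VariantCohort"))
  v <- cohort@variants
  cols <- .TABLE_COLS
  hasVaf <- all(.VAF_COLS %in% names(v)) && cohort@normalized != "raw"
  if (hasVaf) cols <- c(cols, .VAF_COLS)
  out <- v[, intersect(cols, names(v)), drop = FALSE]
  if (nrow(out)) {
    out$rsid[is.na(out$rsid)] <- "."
    if (hasVaf)
      for (col in .VAF_COLS) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  .writeAtomic(function(tmp) {
    con <- file(tmp, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (cohort@normalized != "raw")
      writeLines(paste0("#normalized=", cohort@normalized), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

# parse one tissue's VCF-derived AD strings into per-alt-allele depth rows
.vcfTissueTable <- function(vcf, sample) {
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) # single-record VCF: restore the matrix shape
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      rsid = character(), alt_reads = integer(),
                      total = integer()))
  formats <- vcf@gt[, "FORMAT"]
  if (!any(vapply(strsplit(formats, ":"), function(f) "AD" %in% f, logical(1))))
    stop("format error: VCF lacks the per-sample AD (allele depth) field",
         call. = FALSE)
  if (!sample %in% colnames(vcf@gt))
    stop("configuration error: sample '", sample,
         "' not present in VCF (have: ",
         paste(setdiff(colnames(vcf@gt), "FORMAT"), collapse = ", "), ")",
         call. = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample]
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, sample],
                 error = function(e) rep(NA_real_, nrow(fix)))
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adi <- ad[i]
    if (is.na(adi) || adi == ".") {
      total <- if (is.finite(dp[i])) as.integer(dp[i]) else 0L
      altReads <- rep(0L, length(alts))
      totReads <- rep(total, length(alts))
    } else {
      parts <- suppressWarnings(as.integer(strsplit(adi, ",", fixed = TRUE)[[1]]))
      parts[is.na(parts)] <- 0L
      total <- sum(parts)
      altReads <- vapply(seq_along(alts), function(k) {
        if (length(parts) >= k + 1) parts[k + 1] else 0L
      }, integer(1))
      totReads <- rep(total, length(alts))
    }
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      rsid = ifelse(is.na(fix$ID[i]) || fix$ID[i] == ".",
                    NA_character_, fix$ID[i]),
      alt_reads = altReads, total = totReads,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read one subject's tri-tissue variant calls from VCF
#'
#' Accepts either three per-tissue VCF files (named \code{normal},
#' \code{paracancer}, \code{tumor}) or a single multi-sample VCF plus a
#' map from tissue to sample name. Requires the per-sample \code{AD}
#' (allele depth) FORMAT field; multi-allelic records are split into one
#' variant per alternate allele, with that allele's AD entry as the alt
#' read count and the summed AD entries as the locus total. A variant
#' absent from a tissue receives alt reads 0 and, where a locus depth is
#' recoverable (same record, DP present), that depth as the total;
#' otherwise total 0 (a zero-depth placeholder resolved later by the
#' zero policy of \code{\link{normalizeVafs}}).
#'
#' @param paths character vector of VCF path(s): either length 3 named
#'   by tissue, or length 1 (multi-sample).
#' @param tissueMap for the multi-sample form, a named character vector
#'   mapping tissue (\code{normal}, \code{paracancer}, \code{tumor}) to
#'   the VCF sample name.
#' @param subjectId subject identifier stored in the profile.
#' @param group cohort group label: \code{NM}, \code{LM} or
#'   \code{unknown}.
#' @return a single-subject \code{VariantCohort} (state \code{"raw"})
#' @export
readSubjectVcf <- function(paths, tissueMap = NULL, subjectId = "subject1",
                           group = "unknown") {
  tabs <- list()
  if (length(paths) == 3) {
    if (!setequal(names(paths), .TISSUES))
      stop("configuration error: three paths must be named ",
           paste(.TISSUES, collapse = ", "), call. = FALSE)
    for (t in .TISSUES) {
      vcf <- vcfR::read.vcfR(paths[[t]], verbose = FALSE)
      sample <- setdiff(colnames(vcf@gt), "FORMAT")[1]
      tabs[[t]] <- .vcfTissueTable(vcf, sample)
    }
  } else if (length(paths) == 1) {
    if (is.null(tissueMap) || !setequal(names(tissueMap), .TISSUES))
      stop("configuration error: tissueMap must map normal, paracancer ",
           "and tumor to sample names", call. = FALSE)
    vcf <- vcfR::read.vcfR(paths[[1]], verbose = FALSE)
    for (t in .TISSUES) tabs[[t]] <- .vcfTissueTable(vcf, tissueMap[[t]])
  } else {
    stop("configuration error: supply one multi-sample VCF or three ",
         "per-tissue VCFs", call. = FALSE)
  }
  keys <- unique(do.call(rbind, lapply(tabs, function(x)
    x[c("chrom", "pos", "ref", "alt", "rsid")])))
  keys <- keys[!duplicated(keys[c("chrom", "pos", "ref", "alt")]), ,
               drop = FALSE]
  id <- variantId(keys$chrom, keys$pos, keys$ref, keys$alt)
  out <- data.frame(subject = subjectId, group = group, keys,
                    stringsAsFactors = FALSE)
  for (t in .TISSUES) {
    tid <- variantId(tabs[[t]]$chrom, tabs[[t]]$pos, tabs[[t]]$ref,
                     tabs[[t]]$alt)
    m <- match(id, tid)
    out[[paste0(t, "_alt")]] <- ifelse(is.na(m), 0L, tabs[[t]]$alt_reads[m])
    out[[paste0(t, "_total")]] <- ifelse(is.na(m), 0L, tabs[[t]]$total[m])
  }
  VariantCohort(out)
}

#' Derive normalized VAFs from allele depths
#'
#' The raw VAF is alt reads / total reads per tissue. Under
#' \code{policy = "library_size"} (the default) each tissue's raw VAF is
#' additionally divided by that tissue's library size relative to the
#' subject's three-tissue mean, so that only relative sequencing effort
#' across the matched tissues rescales the cross-tissue VAF ratios that
#' enter the LIP. Zero raw VAFs are replaced so every LIP stays finite:
#' with \code{zeroPolicy = "half_read"} a locus with positive depth but
#' no alt reads gets 0.5 / (total + 1); a zero-depth locus always falls
#' back to \code{epsilon}.
#'
#' @param cohort a raw \code{VariantCohort}
#' @param policy \code{"library_size"} or \code{"none"}
#' @param zeroPolicy \code{"half_read"} or \code{"epsilon"}
#' @param epsilon replacement VAF for zero-depth loci (and for all zero
#'   raw VAFs under \code{zeroPolicy = "epsilon"})
#' @return the cohort with \code{vN}, \code{vP}, \code{vT} columns and
#'   its normalization flag set; re-normalizing a library-size
#'   normalized cohort is rejected.
#' @examples
#' tab <- data.frame(subject = "s1", group = "NM", chrom = "chr1",
#'   pos = 100, ref = "A", alt = "G", rsid = NA,
#'   normal_alt = 50, normal_total = 100, paracancer_alt = 60,
#'   paracancer_total = 100, tumor_alt = 40, tumor_total = 100)
#' normalizeVafs(VariantCohort(tab), policy = "none")
#' @export
normalizeVafs <- function(cohort,
                          policy = c("library_size", "none"),
                          zeroPolicy = c("half_read", "epsilon"),
                          epsilon = 1e-4) {
  stopifnot(is(cohort, "VariantCohort"))
  policy <- match.arg(policy)
  zeroPolicy <- match.arg(zeroPolicy)
  .assertScalarNumber(epsilon, "epsilon")
  if (cohort@normalized == "library_size")
    stop("cohort is already library-size normalized; ",
         "start again from the raw profile", call. = FALSE)
  v <- cohort@variants
  if (nrow(v) == 0) {
    cohort@normalized <- policy
    return(cohort)
  }
  ls <- cohort@librarySizes
  if (policy == "library_size") {
    missing <- setdiff(unique(v$subject), ls$subject)
    if (nrow(ls) == 0 || length(missing))
      stop("configuration error: library_size normalization requires ",
           "library sizes for every subject (missing: ",
           paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  vafCols <- stats::setNames(.VAF_COLS, .TISSUES)
  for (t in .TISSUES) {
    a <- v[[paste0(t, "_alt")]]
    d <- v[[paste0(t, "_total")]]
    raw <- ifelse(d > 0, a / d, 0)
    if (zeroPolicy == "half_read") {
      raw[d > 0 & a == 0] <- 0.5 / (d[d > 0 & a == 0] + 1)
    } else {
      raw[d > 0 & a == 0] <- epsilon
    }
    raw[d == 0] <- epsilon
    if (policy == "library_size") {
      m <- match(v$subject, ls$subject)
      subjMean <- rowMeans(as.matrix(ls[m, .TISSUES, drop = FALSE]))
      raw <- raw / (ls[[t]][m] / subjMean)
    }
    v[[vafCols[[t]]]] <- raw
  }
  cohort@variants <- v
  cohort@normalized <- policy
  validObject(cohort)
  cohort
}
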