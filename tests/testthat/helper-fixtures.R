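# shared fixtures: all built in code, no stored data

# hand-sized variant table: depths chosen so raw VAFs are simple fractions
toyVariantTable <- function() {
  data.frame(
    subject = rep(c("s1", "s2"), each = 3),
    group = rep(c("NM", "LM"), each = 3),
    chrom = rep(c("chr1", "chr2", "chr3"), 2),
    pos = rep(c(100L, 200L, 300L), 2),
    ref = rep(c("A", "C", "G"), 2),
    alt = rep(c("G", "T", "-"), 2),
    rsid = rep(c("rs1", NA, NA), 2),
    normal_alt = c(25L, 50L, 10L, 25L, 50L, 10L),
    normal_total = c(100L, 100L, 100L, 100L, 100L, 100L),
    paracancer_alt = c(50L, 50L, 40L, 50L, 50L, 40L),
    paracancer_total = c(100L, 100L, 100L, 100L, 100L, 100L),
    tumor_alt = c(25L, 50L, 20L, 25L, 50L, 20L),
    tumor_total = c(100L, 100L, 100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE)
}

toyCohort <- function(...) VariantCohort(toyVariantTable(), ...)

# minimal 3-sample VCF 4.2 with per-sample AD (ref reads first, per the
# VCF spec) written to a temp file
writeToyVcf <- function(path = tempfile(fileext = ".vcf"),
                        samples = c("NORM", "PARA", "TUM"),
                        records = NULL) {
  if (is.null(records)) {
    # one biallelic SNV: raw VAFs 0.0 (zero depth), 0.1, 0.4
    records <- c("chr1\t100\trs1\tA\tG\t50\tPASS\t.\tGT:AD:DP\t0/0:0,0:0\t0/1:45,5:50\t0/1:30,20:50")
  }
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# exact two-sided rank-sum p by enumeration of all group assignments
enumWilcoxP <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# estimated coefficient standard errors of a fitted logistic model
# (inverse observed information at the estimate)
logisticSe <- function(X, beta) {
  X1 <- cbind(1, X)
  p <- stats::plogis(drop(X1 %*% beta))
  w <- p * (1 - p)
  sqrt(diag(solve(crossprod(X1 * w, X1))))
}

# one small, fully planted cascade input set with known pass/fail
# pattern, used by the cascade unit tests
toyCascadeInputs <- function() {
  pv <- data.frame(
    variant_id = paste0("v", 1:6),
    chrom = "chr1", pos = 1:6 * 100L, ref = "A", alt = "G",
    rsid = NA_character_, n_subjects = 4L,
    mean_LIP = c(2.5, 1.5, -2, 0.5, 3, 2.2),
    stringsAsFactors = FALSE)
  lr <- data.frame(subject = "s1", group = "LM",
                   variant_id = pv$variant_id, chrom = pv$chrom,
                   pos = pv$pos, ref = pv$ref, alt = pv$alt,
                   rsid = pv$rsid, R = 1, Rbar = 1, LIP = pv$mean_LIP,
                   stringsAsFactors = FALSE)
  ps <- data.frame(subject = "s1", group = "LM", n_variants = 6L,
                   sLIP = sum(pv$mean_LIP), stringsAsFactors = FALSE)
  summary <- new("LipSummary", lipRecords = lr, perVariant = pv,
                 perSubject = ps)
  subj <- paste0("p", 1:40)
  labels <- stats::setNames(rep(c("metastasis", "non-metastasis"),
                                each = 20), subj)
  carriers <- matrix(0L, 40, 6, dimnames = list(subj, pv$variant_id))
  carriers[1:16, c("v1", "v3", "v5", "v6")] <- 1L   # OR = +Inf
  carriers[c(1:10, 21:30), "v2"] <- 1L              # OR = 1
  set.seed(7)
  strongExpr <- function(sign) {
    dos <- rep(0:2, each = 40)
    data.frame(dosage = dos,
               expression = 10 + sign * 2 * dos + rnorm(120, sd = 0.5))
  }
  nullExpr <- function() {
    data.frame(dosage = rep(0:2, each = 40),
               expression = 10 + rnorm(120, sd = 0.5))
  }
  strongSurv <- function(worse) {
    e <- rnorm(200)
    hi <- e > median(e)
    rate <- ifelse(hi == (worse == "high"), 0.08, 0.01)
    t0 <- rexp(200, rate)
    data.frame(time = pmin(t0, 120), event = as.integer(t0 <= 120),
               expression = e)
  }
  expression <- list(v1 = strongExpr(+1), v3 = strongExpr(+1),
                     v5 = nullExpr(), v6 = strongExpr(-1))
  survivalT <- list(v1 = strongSurv("high"), v3 = strongSurv("low"),
                    v5 = strongSurv("high"), v6 = strongSurv("low"))
  list(summary = summary, carriers = carriers, labels = labels,
       expression = expression, survival = survivalT)
}
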