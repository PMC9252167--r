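test_that("a 3-sample VCF yields the expected tri-tissue raw VAFs", {
  vcf <- writeToyVcf()
  co <- readSubjectVcf(vcf, tissueMap = c(normal = "NORM", para = "x",
                                          paracancer = "PARA",
                                          tumor = "TUM")[c("normal",
                                                           "paracancer",
                                                           "tumor")],
                       subjectId = "s1", group = "LM")
  v <- variantCalls(co)
  expect_equal(nrow(v), 1)
  expect_equal(v$normal_alt, 0L)
  expect_equal(v$normal_total, 0L)    # zero-depth placeholder
  expect_equal(v$paracancer_alt / v$paracancer_total, 0.1)
  expect_equal(v$tumor_alt / v$tumor_total, 0.4)
  expect_equal(v$rsid, "rs1")
})

test_that("multi-allelic records split into one variant per alt allele", {
  rec <- "chr2\t500\t.\tA\tG,T\t50\tPASS\t.\tGT:AD\t1/2:10,5,5\t1/2:10,5,5\t1/2:10,5,5"
  vcf <- writeToyVcf(records = rec)
  co <- readSubjectVcf(vcf, tissueMap = c(normal = "NORM",
                                          paracancer = "PARA",
                                          tumor = "TUM"))
  v <- variantCalls(co)
  expect_equal(nrow(v), 2)
  expect_setequal(v$alt, c("G", "T"))
  expect_true(all(v$ref == "A" & v$pos == 500))
  # each alt gets its own AD entry over the shared locus total
  expect_equal(v$tumor_alt, c(5L, 5L))
  expect_equal(v$tumor_total, c(20L, 20L))
})

test_that("VCFs without AD are a format error; unmapped samples a configuration error", {
  rec <- "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:10\t0/1:10\t0/1:10"
  vcf <- writeToyVcf(records = rec)
  expect_error(readSubjectVcf(vcf, tissueMap = c(normal = "NORM",
                                                 paracancer = "PARA",
                                                 tumor = "TUM")),
               "format error")
  vcf2 <- writeToyVcf()
  expect_error(readSubjectVcf(vcf2, tissueMap = c(normal = "NOPE",
                                                  paracancer = "PARA",
                                                  tumor = "TUM")),
               "configuration error")
})

test_that("per-tissue VCFs fill tissues lacking a record with zero depths", {
  n <- writeToyVcf(samples = "S",
    records = "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/0:50,0")
  p <- writeToyVcf(samples = "S",
    records = c("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:45,5",
                "chr9\t900\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:30,10"))
  t <- writeToyVcf(samples = "S",
    records = "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:30,20")
  co <- readSubjectVcf(c(normal = n, paracancer = p, tumor = t))
  v <- variantCalls(co)
  expect_equal(nrow(v), 2) # union over tissues
  v9 <- v[v$chrom == "chr9", ]
  expect_equal(v9$normal_alt, 0L)
  expect_equal(v9$normal_total, 0L)
  expect_equal(v9$tumor_total, 0L)
  expect_equal(v9$paracancer_alt, 10L)
})

test_that("variant tables round-trip bit-exactly, raw and normalized", {
  co <- toyCohort()
  path <- tempfile(fileext = ".tsv")
  writeVariantTable(co, path)
  back <- readVariantTable(path)
  expect_identical(variantCalls(back), variantCalls(co))
  expect_identical(normalization(back), "raw")

  non <- normalizeVafs(co, policy = "none")
  path2 <- tempfile(fileext = ".tsv")
  writeVariantTable(non, path2)
  back2 <- readVariantTable(path2)
  expect_identical(normalization(back2), "none")
  expect_identical(variantCalls(back2)$vN, variantCalls(non)$vN)
  expect_identical(variantCalls(back2)$vT, variantCalls(non)$vT)
})

test_that("table reader groups subjects, rejects duplicates and malformed rows", {
  co <- readVariantTable({
    p <- tempfile(); writeVariantTable(toyCohort(), p); p
  })
  expect_setequal(subjects(co), c("s1", "s2"))
  expect_equal(sum(variantCalls(co)$subject == "s1"), 3)

  tab <- toyVariantTable()
  expect_error(VariantCohort(rbind(tab, tab[1, ])), "duplicate")

  p <- tempfile()
  writeVariantTable(toyCohort(), p)
  lines <- readLines(p)
  lines[3] <- sub("\t100\t", "\tnot_a_number\t", lines[3])
  writeLines(lines, p)
  expect_error(readVariantTable(p), "line 3")

  # header-only file: empty cohort
  writeLines(readLines(p)[1], p)
  expect_equal(nrow(variantCalls(readVariantTable(p))), 0)
})

test_that("em-dash and dot tokens canonicalize; invariants enforced", {
  tab <- toyVariantTable()[1, ]
  tab$ref <- "–"  # en dash as printed in candidate tables
  tab$alt <- "CTC"
  co <- VariantCohort(tab)
  expect_identical(variantCalls(co)$ref, "-")
  tab$alt <- "–"
  expect_error(VariantCohort(tab), "'-'")
  bad <- toyVariantTable()
  bad$normal_alt[1] <- 200L # alt > total
  expect_error(VariantCohort(bad), "normal")
})

test_that("normalizeVafs applies the stated policies and zero rules", {
  co <- toyCohort()
  non <- normalizeVafs(co, policy = "none")
  v <- variantCalls(non)
  expect_equal(v$vN[v$subject == "s1" & v$chrom == "chr1"], 0.25)
  expect_equal(v$vP[v$subject == "s1" & v$chrom == "chr1"], 0.5)
  expect_true(all(v$vN >= 0 & v$vN <= 1 & v$vT <= 1))

  # half-read correction: alt 0 over 99 reads -> 0.5/100
  tab <- toyVariantTable()[1, ]
  tab$tumor_alt <- 0L; tab$tumor_total <- 99L
  hz <- variantCalls(normalizeVafs(VariantCohort(tab), policy = "none"))
  expect_equal(hz$vT, 0.005)
  ez <- variantCalls(normalizeVafs(VariantCohort(tab), policy = "none",
                                   zeroPolicy = "epsilon"))
  expect_equal(ez$vT, 1e-4)
  # zero total reads -> epsilon under either zero policy
  tab$tumor_total <- 0L
  zz <- variantCalls(normalizeVafs(VariantCohort(tab), policy = "none"))
  expect_equal(zz$vT, 1e-4)
})

test_that("library-size normalization needs sizes, is identity for equal sizes, and refuses reapplication", {
  co <- toyCohort()
  expect_error(normalizeVafs(co), "library sizes")

  libs <- data.frame(subject = c("s1", "s2"), normal = 1e6,
                     paracancer = 1e6, tumor = 1e6)
  eq <- normalizeVafs(toyCohort(librarySizes = libs))
  non <- normalizeVafs(co, policy = "none")
  expect_equal(variantCalls(eq)$vN, variantCalls(non)$vN)
  expect_equal(variantCalls(eq)$vT, variantCalls(non)$vT)
  expect_error(normalizeVafs(eq), "already")

  # unequal sizes rescale by tissue effort relative to the subject mean
  libs2 <- data.frame(subject = c("s1", "s2"), normal = 2e6,
                      paracancer = 1e6, tumor = 1e6)
  un <- variantCalls(normalizeVafs(toyCohort(librarySizes = libs2)))
  f <- 2e6 / mean(c(2e6, 1e6, 1e6))
  expect_equal(un$vN[1], variantCalls(non)$vN[1] / f)
  expect_equal(un$vP[1], variantCalls(non)$vP[1] / (1e6 / mean(c(2e6, 1e6, 1e6))))
})
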