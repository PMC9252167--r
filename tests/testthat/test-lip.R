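test_that("promotion and resistance rates follow their VAF ratios", {
  expect_equal(promotionRate(0.5, 0.25), 2)
  expect_equal(promotionRate(0.3, 0.3), 1)
  expect_equal(promotionRate(0.1, 0.4), 0.25)
  expect_equal(resistanceRate(0.25, 0.25), 1)
  expect_equal(resistanceRate(0.5, 0.25), 2)
  expect_equal(resistanceRate(0.05, 0.5), 0.1)
  expect_error(promotionRate(0.5, 0), "zero")
  expect_error(resistanceRate(0.5, 0), "zero")
})

test_that("lipScore is log2 of promotion over resistance", {
  s <- lipScore(vN = 0.25, vP = 0.5, vT = 0.25)
  expect_equal(s$R, 2)
  expect_equal(s$Rbar, 1)
  expect_equal(s$LIP, 1)
  expect_equal(lipScore(0.3, 0.3, 0.3)$LIP, 0)
  # vT^2 = vP * vN => LIP exactly 0
  expect_equal(lipScore(vN = 0.1, vP = 0.4, vT = 0.2)$LIP, 0)
  expect_error(lipScore(NaN, 0.5, 0.5), "normal")
  expect_error(lipScore(0.5, Inf, 0.5), "paracancer")
})

test_that("LIP responds monotonically: doubling vP adds exactly one bit", {
  set.seed(11)
  for (i in 1:50) {
    v <- runif(3, 0.01, 0.5)
    base <- lipScore(v[1], v[2], v[3])$LIP
    expect_equal(lipScore(v[1], 2 * v[2], v[3])$LIP, base + 1)
    expect_lt(lipScore(v[1], v[2], v[3] * 1.5)$LIP, base)
    expect_gt(lipScore(v[1] * 1.5, v[2], v[3])$LIP, base)
  }
})

test_that("slip sums finite LIPs, is linear over disjoint lists", {
  expect_equal(slip(c(1, -0.5, 0.25)), 0.75)
  expect_equal(slip(numeric(0)), 0)
  expect_equal(slip(3.7), 3.7)
  expect_error(slip(c(1, NA)), "finite")
  set.seed(12)
  a <- rnorm(40); b <- rnorm(17)
  expect_equal(slip(c(a, b)), slip(a) + slip(b))
})

test_that("summarizeLip averages over carriers and sums per subject", {
  # 3 subjects share chr1 variant with LIPs 1, 2, 3; one subject has a
  # private variant whose LIP cancels its first
  mk <- function(s, g, vP1, extra = FALSE) {
    rows <- data.frame(subject = s, group = g, chrom = "chr1", pos = 100L,
                       ref = "A", alt = "G", rsid = NA,
                       normal_alt = 25L, normal_total = 100L,
                       paracancer_alt = as.integer(vP1 * 100),
                       paracancer_total = 100L,
                       tumor_alt = 25L, tumor_total = 100L)
    if (extra)
      rows <- rbind(rows, data.frame(subject = s, group = g,
        chrom = "chr2", pos = 200L, ref = "C", alt = "T", rsid = NA,
        normal_alt = 50L, normal_total = 100L, paracancer_alt = 25L,
        paracancer_total = 100L, tumor_alt = 50L, tumor_total = 100L))
    rows
  }
  # vN = vT = 0.25: LIP = log2(vP/0.25); vP 0.5, 1.0 -> LIP 1, 2
  tab <- rbind(mk("a", "NM", 0.50, extra = TRUE), # LIP 1, extra LIP -1
               mk("b", "NM", 1.00),               # LIP 2
               mk("c", "LM", 2.00))               # capped input: vP=2 invalid
  tab$paracancer_alt[tab$subject == "c"] <- 100L  # vP 1 -> LIP 2... use 8x
  co <- normalizeVafs(VariantCohort(tab), policy = "none")
  ls <- summarizeLip(co)
  pv <- perVariant(ls)
  shared <- pv[pv$chrom == "chr1", ]
  expect_equal(shared$n_subjects, 3)
  expect_equal(shared$mean_LIP, mean(c(1, 2, 2)))
  ps <- perSubject(ls)
  expect_equal(ps$sLIP[ps$subject == "a"], 0)  # 1 + (-1)
  expect_equal(ps$n_variants[ps$subject == "a"], 2)
  # absent variants do not contribute a zero
  expect_equal(ps$n_variants[ps$subject == "b"], 1)
  # determinism
  expect_identical(perSubject(summarizeLip(co)), ps)
  expect_error(summarizeLip(toyCohort()), "normalized")
})

test_that("rank-sum comparison is exact for small groups and matches enumeration", {
  expect_equal(compareGroups(c(1, 2, 3, 4, 5, 6),
                             rep(c("a", "b"), each = 3))$p.value,
               enumWilcoxP(1:3, 4:6))
  r <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$p.value, 0.1)
  expect_equal(r$statistic, 6) # extreme rank-sum of the first group
  expect_equal(r$method, "exact")
  # identical groups: no shift, p = 1 (tie-corrected path)
  expect_equal(compareGroups(c(1, 2, 3, 1, 2, 3),
                             rep(1:2, each = 3))$p.value, 1)
  # symmetric tie-free ranks, exact path
  x <- c(1, 4, 5, 8); y <- c(2, 3, 6, 7)
  expect_equal(compareGroups(c(x, y), rep(1:2, each = 4))$p.value, 1)
  # shift invariance
  set.seed(3)
  a <- rnorm(5); b <- rnorm(6)
  p1 <- compareGroups(c(a, b), rep(1:2, c(5, 6)))$p.value
  p2 <- compareGroups(c(a, b) + 17.3, rep(1:2, c(5, 6)))$p.value
  expect_equal(p1, p2)
  expect_error(compareGroups(a, rep("x", 5)), "two")
})

test_that("sLIP-purity correlation matches the textbook formula", {
  expect_equal(correlateSlipPurity(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(correlateSlipPurity(1:5, -(1:5))$r, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- correlateSlipPurity(x, y)
  expect_equal(got$r, r)
  tt <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(got$p.value, 2 * pt(abs(tt), 3, lower.tail = FALSE))
  expect_error(correlateSlipPurity(1:5, rep(1, 5)), "variance")
  expect_error(correlateSlipPurity(1:2, 1:2), "3")
})

test_that("LIP tables are written with stable columns", {
  co <- normalizeVafs(toyCohort(), policy = "none")
  ls <- summarizeLip(co)
  dir <- tempfile()
  paths <- writeLipTables(ls, dir)
  expect_true(all(file.exists(paths)))
  rec <- read.delim(paths[1])
  expect_true(all(c("subject", "variant_id", "R", "Rbar", "LIP") %in%
                  names(rec)))
  expect_equal(nrow(rec), nrow(lipRecords(ls)))
})
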