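test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- generatorConfig(seed = 7, nBackground = 60, nDriver = 3,
                         nResister = 1)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(variantCalls(a$discovery$cohort),
                   variantCalls(b$discovery$cohort))
  expect_identical(a$validation$carriers, b$validation$carriers)
  expect_identical(a$exprsurv$survival, b$exprsurv$survival)
  expect_identical(a$truth, b$truth)
  # and sensitive to the seed
  c <- simulateStudy(generatorConfig(seed = 8, nBackground = 60,
                                     nDriver = 3, nResister = 1))
  expect_false(identical(variantCalls(a$discovery$cohort),
                         variantCalls(c$discovery$cohort)))
})

test_that("the truth manifest labels every variant and planted effects", {
  cfg <- generatorConfig(seed = 9, nBackground = 50, nDriver = 4,
                         nResister = 1, nDriverUp = 2)
  tr <- simulateDiscoveryCohort(cfg)$truth
  expect_equal(sum(tr$role == "driver"), 4)
  expect_equal(sum(tr$role == "resister"), 1)
  expect_true(all(tr$class[tr$role == "driver"] == "MP"))
  expect_true(all(tr$class[tr$role == "resister"] == "MR"))
  drv <- tr[tr$role == "driver", ]
  expect_equal(sum(drv$eqtl_direction == "up"), 2)
  # orientation consistent with the MP/MR rule
  for (i in seq_len(nrow(tr))) {
    if (!is.na(tr$class[i]))
      expect_equal(classifyVariant(tr$eqtl_direction[i],
                                   tr$worse_stratum[i]), tr$class[i])
  }
})

test_that("discovery defaults separate the groups by sLIP sign", {
  d <- simulateDiscoveryCohort(generatorConfig())
  ls <- summarizeLip(normalizeVafs(d$cohort))
  ps <- perSubject(ls)
  expect_true(all(ps$sLIP[ps$group == "LM"] > 0))
  expect_true(all(ps$sLIP[ps$group == "NM"] < 0))
  # planted driver/resister mean LIPs clear their gates
  pv <- perVariant(ls)
  dm <- pv$mean_LIP[match(d$truth$variant_id[d$truth$role == "driver"],
                          pv$variant_id)]
  expect_true(all(dm > 1))
  rm_ <- pv$mean_LIP[match(d$truth$variant_id[d$truth$role == "resister"],
                           pv$variant_id)]
  expect_true(all(rm_ < -1))
})

test_that("a unit driver boost is a true null for the group contrast", {
  pvals <- vapply(1:40, function(s) {
    cfg <- generatorConfig(seed = 100 + s, nBackground = 150,
                           nDriver = 5, nResister = 1, driverBoost = 1)
    d <- simulateDiscoveryCohort(cfg)
    compareGroups(summarizeLip(normalizeVafs(d$cohort)))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("validation cohorts realize the planted odds-ratio structure", {
  # large-n sampling check of the carrier odds ratio around its target
  cfg <- generatorConfig(seed = 10, nBackground = 40, nDriver = 20,
                         nResister = 0, orEffect = 10,
                         ctrlCarrierProb = 0.2,
                         cohortSizes = c(big = 4000))
  val <- simulateValidationCohorts(cfg)
  ext <- val$cohorts != "discovery"
  screen <- oddsRatioScreen(val$carriers[ext, , drop = FALSE],
                            val$labels[ext])
  planted <- val$truth$variant_id[val$truth$role == "driver"]
  ors <- screen$OR[match(planted, screen$variant_id)]
  expect_gte(mean(ors > 5 & ors < 20), 0.95)
  # background variants carry no association
  bg <- screen$OR[match(val$truth$variant_id[val$truth$role == "background"],
                        screen$variant_id)]
  expect_lt(mean(bg > 5, na.rm = TRUE), 0.05)
})

test_that("zero control carriage makes every planted odds ratio infinite", {
  cfg <- generatorConfig(seed = 11, nBackground = 20, nDriver = 5,
                         nResister = 1, ctrlCarrierProb = 0)
  val <- simulateValidationCohorts(cfg)
  screen <- oddsRatioScreen(val$carriers, val$labels)
  planted <- val$truth$variant_id[val$truth$role != "background"]
  ors <- screen$OR[match(planted, screen$variant_id)]
  expect_true(all(is.infinite(ors)))
  expect_error(generatorConfig(orEffect = 0.5), "resister pathway")
})

test_that("planted eQTL and survival effects are detectable; nulls are null", {
  cfg <- generatorConfig(seed = 12, nBackground = 40, nDriver = 8,
                         nResister = 1)
  es <- simulateExpressionSurvival(cfg)
  tr <- es$truth
  planted <- tr$variant_id[tr$role != "background"]
  eq <- vapply(planted, function(id) {
    tab <- es$expression[[id]]
    t <- eqtlTest(tab$dosage, tab$expression)
    t$p.value < 0.01 &&
      t$direction == tr$eqtl_direction[tr$variant_id == id]
  }, logical(1))
  expect_gte(mean(eq), 0.95)
  sv <- vapply(planted, function(id) {
    tab <- es$survival[[id]]
    s <- survivalByExpression(tab$time, tab$event, tab$expression)
    s$p.value < 0.01 && s$worse == tr$worse_stratum[tr$variant_id == id]
  }, logical(1))
  expect_gte(mean(sv), 0.95)
  # background tables are generated under the null
  bg <- tr$variant_id[tr$role == "background"]
  bgP <- vapply(bg, function(id) {
    tab <- es$expression[[id]]
    eqtlTest(tab$dosage, tab$expression)$p.value
  }, numeric(1))
  expect_lt(mean(bgP < 0.05), 0.2)
  # hazard-ratio 1 gives a calibrated log-rank null
  cfg1 <- generatorConfig(seed = 13, nBackground = 5, nDriver = 40,
                          nResister = 0, hazardRatio = 1)
  es1 <- simulateExpressionSurvival(cfg1)
  p1 <- vapply(es1$truth$variant_id[es1$truth$role == "driver"],
               function(id) {
    tab <- es1$survival[[id]]
    survivalByExpression(tab$time, tab$event, tab$expression)$p.value
  }, numeric(1))
  expect_gt(mean(p1), 0.3)
  expect_lt(mean(p1 < 0.05), 0.2)
})
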