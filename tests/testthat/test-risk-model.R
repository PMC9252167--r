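test_that("featurize is the elementwise carrier-weight product", {
  expect_equal(featurize(c(1, 0, 1), c(2, -1, 0.5)), c(2, 0, 0.5))
  expect_equal(featurize(rep(0, 4), 1:4), rep(0, 4))
  L <- c(1.5, -2, 0.25)
  expect_equal(featurize(rep(1, 3), L), L)
  m <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  expect_equal(featurize(m, L), sweep(m, 2, L, `*`))
  expect_error(featurize(c(1, 0), 1:3), "length")
})

test_that("predictRisk follows the logistic closed form and its symmetry", {
  m <- new("RiskModel", panel = "v1", L = 2, w = 1, b = 0, penalty = 0,
           meta = list())
  expect_equal(predictRisk(m, 1), 1 / (1 + exp(-2)))
  expect_equal(predictRisk(m, 0), 0.5)
  flip <- new("RiskModel", panel = "v1", L = 2, w = -1, b = 0,
              penalty = 0, meta = list())
  expect_equal(predictRisk(flip, 1), 1 - predictRisk(m, 1))
  # strict monotonicity in the weighted sum
  m3 <- new("RiskModel", panel = paste0("v", 1:3), L = c(2, 1, 0.5),
            w = c(1, 1, 1), b = -1, penalty = 0, meta = list())
  V <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(1, 1, 1))
  p <- predictRisk(m3, V)
  expect_true(all(diff(p) > 0))
})

test_that("fit recovers generating parameters and honours duplication invariance", {
  set.seed(41)
  L <- c(2, -1, 0.5)
  wStar <- c(0.8, -0.6, 1.4); bStar <- -0.4
  V <- matrix(rbinom(1500, 1, 0.5), 500, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  eta <- featurize(V, L) %*% wStar + bStar
  y <- rbinom(500, 1, plogis(eta))
  m <- fitRiskModel(V, y, L)
  se <- logisticSe(featurize(V, L), c(m@b, m@w))
  expect_true(all(abs(c(m@b, m@w) - c(bStar, wStar)) < 3 * se))
  expect_equal(m@penalty, 0) # plain MLE at this n

  dup <- fitRiskModel(rbind(V, V), c(y, y), L)
  expect_equal(dup@w, m@w, tolerance = 1e-6)
  expect_equal(dup@b, m@b, tolerance = 1e-6)

  expect_error(fitRiskModel(V, rep(1, 500), L), "single class")
})

test_that("null data give near-zero slopes and a prevalence intercept", {
  set.seed(42)
  L <- c(1, 1, 1)
  V <- matrix(rbinom(3000, 1, 0.5), 1000, 3)
  y <- rbinom(1000, 1, 0.3)
  m <- fitRiskModel(V, y, L)
  se <- logisticSe(featurize(V, L), c(m@b, m@w))
  expect_true(all(abs(m@w) < 3 * se[-1]))
  expect_lt(abs(m@b - qlogis(mean(y))), 3 * se[1])
})

test_that("complete separation falls back to the penalized fit", {
  V <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "v1"))
  y <- c(rep(1, 10), rep(0, 10))
  m <- fitRiskModel(V, y, L = 2)
  expect_equal(m@meta$method, "ridge")
  expect_gt(m@penalty, 0)
  expect_true(all(is.finite(c(m@w, m@b))))
  expect_gt(predictRisk(m, 1), 0.9)
  expect_lt(predictRisk(m, 0), 0.1)
})

test_that("risk tiers split at 0.5 and 0.75 with closed-left boundaries", {
  expect_equal(categorizeRisk(c(0.8, 0.75, 0.74, 0.5, 0.49, 0.3, 0, 1)),
               c("high", "high", "moderate", "moderate", "mild", "mild",
                 "mild", "high"))
  expect_error(categorizeRisk(1.2), "\\[0, 1\\]")
  expect_error(categorizeRisk(-0.1), "\\[0, 1\\]")
})

test_that("evaluateModel reproduces the confusion-matrix identities", {
  # TP=3 FN=1 TN=4 FP=2
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.2, 0.3, 0.4, 0.8, 0.6)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  ev <- evaluateModel(prob, lab)
  expect_equal(c(ev@TP, ev@FN, ev@TN, ev@FP), c(3, 1, 4, 2))
  expect_equal(ev@sensitivity, 0.75)
  expect_equal(ev@specificity, 2 / 3)
  expect_equal(ev@accuracy, 0.7)
})

test_that("the rank AUC matches perfect, tied and library-computed cases", {
  expect_equal(evaluateModel(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))@auc, 1)
  expect_equal(evaluateModel(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))@auc, 0.5)
  set.seed(43)
  prob <- round(runif(60), 2) # induce ties
  lab <- rbinom(60, 1, 0.5)
  ev <- evaluateModel(prob, lab)
  # Mann-Whitney normalization oracle
  U <- unname(wilcox.test(prob[lab == 1], prob[lab == 0],
                          exact = FALSE)$statistic)
  expect_equal(ev@auc, U / (sum(lab) * sum(1 - lab)))
  skip_if_not_installed("pROC")
  expect_equal(ev@auc,
               as.numeric(pROC::auc(pROC::roc(lab, prob, quiet = TRUE))))
  expect_error(evaluateModel(prob, rep(1, 60)), "both classes")
})

test_that("LOOCV predicts every subject once and is order-invariant", {
  set.seed(44)
  L <- c(2, 1.5, -1)
  V <- matrix(rbinom(90, 1, 0.5), 30, 3,
              dimnames = list(sprintf("s%02d", 1:30), paste0("v", 1:3)))
  y <- rbinom(30, 1, plogis(featurize(V, L) %*% c(1, 1, 1) - 1))
  res <- loocv(V, y, L)
  expect_equal(nrow(res$predictions), 30)
  expect_equal(res$skipped, 0)
  perm <- sample(30)
  res2 <- loocv(V[perm, ], y[perm], L)
  expect_equal(res2$pooled@accuracy, res$pooled@accuracy)
  expect_equal(res2$pooled@auc, res$pooled@auc)
  expect_error(loocv(V[1:3, ], y[1:3], L), ">= 4")
})

test_that("grouped evaluation holds out each cohort once, isolated", {
  set.seed(45)
  L <- c(2, 1.5, -1, 1)
  n <- 80
  V <- matrix(rbinom(n * 4, 1, 0.4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("v", 1:4)))
  y <- rbinom(n, 1, plogis(featurize(V, L) %*% rep(1, 4) - 1))
  cohorts <- rep(c("w", "x", "y", "z"), each = 20)
  ge <- groupedEval(V, y, cohorts, L)
  expect_equal(length(ge$combinations), 4)
  expect_setequal(names(ge$combinations), c("w", "x", "y", "z"))
  # internal result ignores the held-out cohort's contents entirely
  V2 <- V; V2[cohorts == "z", ] <- 1 - V2[cohorts == "z", ]
  ge2 <- groupedEval(V2, y, cohorts, L)
  expect_equal(ge2$combinations$z$internal$pooled@accuracy,
               ge$combinations$z$internal$pooled@accuracy)
  expect_equal(ge2$combinations$z$internal$pooled@auc,
               ge$combinations$z$internal$pooled@auc)
  expect_error(groupedEval(V, y, rep("one", n), L), ">= 2")
})

test_that("risk models serialize to JSON and back without loss", {
  m <- new("RiskModel", panel = paste0("v", 1:3),
           L = c(2.123456789012345, -1.5, 0.25),
           w = c(0.87654321, -0.1, 3.3), b = -0.987654321,
           penalty = 1e-4, meta = list(method = "ridge", n = 60L))
  p <- tempfile(fileext = ".json")
  writeRiskModel(m, p)
  back <- readRiskModel(p)
  expect_identical(back@panel, m@panel)
  expect_identical(back@L, m@L)
  expect_identical(back@w, m@w)
  expect_identical(back@b, m@b)
  expect_equal(back@meta$method, "ridge")
  expect_error(readRiskModel({
    q <- tempfile(); jsonlite::write_json(list(a = 1), q); q
  }), "risk-model")
})
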