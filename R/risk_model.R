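#' LIP-weighted feature vector
#'
#' Elementwise product of the binary carrier vector V over the variant
#' panel with the panel's average-LIP weights L: the contribution of
#' each carried variant to the accumulated invasion driving force.
#'
#' @param V binary carrier vector of length k, or a subjects x k matrix
#' @param L numeric LIP weights of length k
#' @return vector or matrix of features x with x_i = V_i * L_i
#' @export
featurize <- function(V, L) {
  if (is.matrix(V)) {
    if (ncol(V) != length(L))
      stop("carrier matrix has ", ncol(V), " columns but L has length ",
           length(L), call. = FALSE)
    return(sweep(V, 2, L, `*`))
  }
  if (length(V) != length(L))
    stop("V and L must have equal length", call. = FALSE)
  V * L
}

# L2-penalized logistic regression by Newton-Raphson; penalty on the
# slopes only, never the intercept. Keeps estimates finite under
# complete separation while staying numerically close to the MLE.
.ridgeLogistic <- function(X, y, lambda, tol = 1e-8, maxit = 200) {
  X1 <- cbind(1, X)
  k <- ncol(X1)
  beta <- numeric(k)
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X1, y - p)) - drop(pen %*% beta)
    if (sqrt(sum(grad^2)) < tol)
      return(list(beta = beta, converged = TRUE, iter = it))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X1 * w, X1) + pen
    beta <- beta + solve(H, grad)
  }
  list(beta = beta, converged = FALSE, iter = maxit)
}

#' Fit the LIP-weighted logistic risk model
#'
#' Logistic regression of the metastasis label on the LIP-weighted
#' carrier features x_i = V_i * L_i, fitted by maximum likelihood
#' (\code{glm}). Under complete separation -- likely with a small
#' cohort and an 11-variant panel -- the fit falls back to an
#' L2-penalized likelihood with a small ridge penalty, recorded in the
#' model metadata.
#'
#' @param carriers subjects x k binary carrier matrix over the panel
#'   (column names become the panel)
#' @param labels 0/1 vector (1 = metastasis) aligned with the rows
#' @param L numeric LIP weight per panel variant, fixed from the
#'   training data (discovery-cohort average LIPs)
#' @param penalty ridge penalty used by the separation fallback
#' @return a \code{\link[=RiskModel-class]{RiskModel}}
#' @export
fitRiskModel <- function(carriers, labels, L, penalty = 1e-4) {
  carriers <- as.matrix(carriers)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need >= 2 subjects per class", call. = FALSE)
  if (ncol(carriers) != length(L))
    stop("carriers and L disagree on the panel size", call. = FALSE)
  panel <- colnames(carriers)
  if (is.null(panel)) panel <- paste0("v", seq_along(L))
  X <- featurize(carriers, L)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), labels,
                   family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  if (sep || any(abs(beta) > 15) || !fit$converged) {
    rf <- .ridgeLogistic(X, labels, lambda = penalty)
    new("RiskModel", panel = panel, L = unname(L),
        w = unname(rf$beta[-1]), b = unname(rf$beta[1]), penalty = penalty,
        meta = list(method = "ridge", converged = rf$converged,
                    iterations = rf$iter, n = nrow(X),
                    n_case = sum(labels), n_control = sum(1 - labels)))
  } else {
    new("RiskModel", panel = panel, L = unname(L),
        w = unname(beta[-1]), b = unname(beta[1]), penalty = 0,
        meta = list(method = "mle", converged = fit$converged,
                    n = nrow(X),
                    n_case = sum(labels), n_control = sum(1 - labels)))
  }
}

#' Predict metastatic risk probabilities
#'
#' P(y = 1) = 1 / (1 + exp(-(sum_i w_i V_i L_i + b))).
#'
#' @param model a \code{RiskModel}
#' @param carriers binary carrier vector of panel length, or a
#'   subjects x k matrix (columns matched to the panel by name when
#'   named)
#' @return numeric probabilities in (0, 1)
#' @export
predictRisk <- function(model, carriers) {
  stopifnot(is(model, "RiskModel"))
  if (!is.matrix(carriers))
    carriers <- matrix(carriers, nrow = 1,
                       dimnames = list(NULL, names(carriers)))
  if (!is.null(colnames(carriers))) {
    miss <- setdiff(model@panel, colnames(carriers))
    if (length(miss))
      stop("carriers lack panel variant(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    carriers <- carriers[, model@panel, drop = FALSE]
  } else if (ncol(carriers) != length(model@panel)) {
    stop("carrier vector length must equal the panel size", call. = FALSE)
  }
  X <- featurize(carriers, model@L)
  drop(stats::plogis(X %*% model@w + model@b))
}

#' Risk tier of a predicted probability
#'
#' High risk for p in [0.75, 1], moderate for [0.5, 0.75), mild below
#' 0.5 (closed-left boundaries).
#'
#' @param p probabilities in [0, 1]
#' @return character vector \code{"high"} / \code{"moderate"} /
#'   \code{"mild"}
#' @export
categorizeRisk <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  ifelse(p >= 0.75, "high", ifelse(p >= 0.5, "moderate", "mild"))
}

# rank-statistic AUC with ties counted 1/2 (Mann-Whitney normalization)
.aucRank <- function(scores, labels) {
  nP <- sum(labels == 1)
  nN <- sum(labels == 0)
  if (nP == 0 || nN == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Evaluate predicted probabilities against labels
#'
#' Confusion matrix at the decision threshold (predicted positive when
#' p >= threshold), accuracy (TP+TN)/(P+N), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), and the rank-statistic AUC with ties
#' counted 1/2.
#'
#' @param probabilities predicted P(metastasis)
#' @param labels 0/1 truth, aligned
#' @param threshold decision threshold (default 0.5, the mild/moderate
#'   tier boundary)
#' @return an \code{\link[=EvalReport-class]{EvalReport}}
#' @export
evaluateModel <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must be paired", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  new("EvalReport", TP = TP, TN = TN, FP = FP, FN = FN,
      accuracy = (TP + TN) / n,
      sensitivity = if (TP + FN > 0) TP / (TP + FN) else NaN,
      specificity = if (TN + FP > 0) TN / (TN + FP) else NaN,
      auc = .aucRank(probabilities, labels),
      threshold = threshold)
}

#' Leave-one-out cross-validation of the risk model
#'
#' Each subject is held out once and predicted by a model trained on
#' the remaining subjects (L stays fixed: it is panel metadata, not
#' refitted per fold). Metrics are computed on the pooled held-out
#' predictions; the mean per-fold accuracy is reported alongside. A
#' fold whose training labels collapse to one class is skipped with a
#' warning and counted.
#'
#' @param carriers subjects x k binary carrier matrix
#' @param labels 0/1 vector
#' @param L panel LIP weights
#' @param threshold decision threshold for the pooled confusion matrix
#' @param penalty ridge penalty of the separation fallback
#' @return list with \code{pooled} (an \code{EvalReport} over held-out
#'   predictions), \code{perFoldAccuracy}, \code{predictions}
#'   (data.frame subject/probability/label/tier), \code{skipped}
#' @export
loocv <- function(carriers, labels, L, threshold = 0.5, penalty = 1e-4) {
  carriers <- as.matrix(carriers)
  labels <- as.integer(labels)
  n <- nrow(carriers)
  if (n < 4 || length(unique(labels)) < 2)
    stop("need >= 4 subjects with both classes", call. = FALSE)
  prob <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2 || min(table(ytr)) < 2) {
      skipped <- skipped + 1L
      next
    }
    m <- fitRiskModel(carriers[-i, , drop = FALSE], ytr, L,
                      penalty = penalty)
    prob[i] <- predictRisk(m, carriers[i, , drop = FALSE])
  }
  if (skipped > 0)
    warning(skipped, " fold(s) skipped: single-class training set",
            call. = FALSE)
  keep <- !is.na(prob)
  pooled <- evaluateModel(prob[keep], labels[keep], threshold)
  foldAcc <- mean((prob[keep] >= threshold) == (labels[keep] == 1))
  subj <- rownames(carriers)
  if (is.null(subj)) subj <- paste0("s", seq_len(n))
  list(pooled = pooled,
       perFoldAccuracy = foldAcc,
       predictions = data.frame(subject = subj[keep],
                                probability = prob[keep],
                                label = labels[keep],
                                tier = categorizeRisk(prob[keep]),
                                stringsAsFactors = FALSE),
       skipped = skipped)
}

#' Leave-one-cohort-out evaluation
#'
#' For every named cohort: fit on the union of the other cohorts,
#' report the internal LOOCV metrics of that training union, and
#' evaluate the fitted model once on the held-out cohort (external).
#' Averages across the combinations are returned.
#'
#' @param carriers subjects x k binary carrier matrix
#' @param labels 0/1 vector
#' @param cohorts character vector naming each subject's cohort
#' @param L panel LIP weights
#' @param threshold decision threshold
#' @param penalty ridge penalty of the separation fallback
#' @return list with \code{combinations} (per held-out cohort: internal
#'   LOOCV result and external \code{EvalReport}, or \code{NULL}
#'   external report flagged when the held-out cohort is single-class)
#'   and \code{average} (internal/external mean AUC and accuracy)
#' @export
groupedEval <- function(carriers, labels, cohorts, L, threshold = 0.5,
                        penalty = 1e-4) {
  carriers <- as.matrix(carriers)
  labels <- as.integer(labels)
  cohorts <- as.character(cohorts)
  if (length(unique(cohorts)) < 2)
    stop("need >= 2 named cohorts", call. = FALSE)
  combos <- list()
  for (held in sort(unique(cohorts))) {
    test <- cohorts == held
    m <- fitRiskModel(carriers[!test, , drop = FALSE], labels[!test], L,
                      penalty = penalty)
    internal <- loocv(carriers[!test, , drop = FALSE], labels[!test], L,
                      threshold = threshold, penalty = penalty)
    external <- if (length(unique(labels[test])) < 2) NULL else
      evaluateModel(predictRisk(m, carriers[test, , drop = FALSE]),
                    labels[test], threshold)
    combos[[held]] <- list(held_out = held, model = m,
                           internal = internal, external = external)
  }
  intAuc <- vapply(combos, function(cb) cb$internal$pooled@auc, numeric(1))
  intAcc <- vapply(combos, function(cb) cb$internal$pooled@accuracy,
                   numeric(1))
  extAuc <- vapply(combos, function(cb)
    if (is.null(cb$external)) NA_real_ else cb$external@auc, numeric(1))
  extAcc <- vapply(combos, function(cb)
    if (is.null(cb$external)) NA_real_ else cb$external@accuracy,
    numeric(1))
  list(combinations = combos,
       average = list(internal_auc = mean(intAuc),
                      internal_accuracy = mean(intAcc),
                      external_auc = mean(extAuc, na.rm = TRUE),
                      external_accuracy = mean(extAcc, na.rm = TRUE)))
}

#' Serialize a risk model to versioned JSON
#'
#' @param model a \code{RiskModel}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeRiskModel <- function(model, path) {
  stopifnot(is(model, "RiskModel"))
  obj <- list(format = "metalip-risk-model", version = 1L,
              panel = model@panel, L = model@L, w = model@w, b = model@b,
              penalty = model@penalty, meta = model@meta)
  .writeAtomic(function(tmp) jsonlite::write_json(
    obj, tmp, auto_unbox = TRUE, digits = I(17), pretty = TRUE), path)
}

#' Read a risk model from JSON
#'
#' @param path path written by \code{\link{writeRiskModel}}
#' @return a \code{RiskModel}
#' @export
readRiskModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "metalip-risk-model"))
    stop("not a risk-model file: ", path, call. = FALSE)
  new("RiskModel", panel = obj$panel, L = as.numeric(obj$L),
      w = as.numeric(obj$w), b = as.numeric(obj$b),
      penalty = as.numeric(obj$penalty),
      meta = as.list(obj$meta))
}

#' Convert an EvalReport to a plain list
#'
#' @param report an \code{EvalReport}
#' @return named list of the confusion cells and metrics
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "EvalReport"))
  list(TP = report@TP, TN = report@TN, FP = report@FP, FN = report@FN,
       accuracy = report@accuracy, sensitivity = report@sensitivity,
       specificity = report@specificity, auc = report@auc,
       threshold = report@threshold)
}
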