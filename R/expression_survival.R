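#' Linear trend test of expression on genotype dosage
#'
#' Regresses normalized host-gene expression on allele dosage (0/1/2)
#' and tests the slope (two-sided t-test). The slope sign gives the
#' direction of the expression change conferred by the variant. This is
#' the internal stand-in for a cis-eQTL lookup: any user-supplied
#' genotype-expression table plugs in.
#'
#' @param dosage integer vector in {0, 1, 2}
#' @param expression numeric expression values, same length
#' @return list with \code{direction} (\code{"up"}, \code{"down"} or
#'   \code{NA} when the slope is undefined), \code{slope},
#'   \code{p.value}; constant expression yields p = 1 and an undefined
#'   direction, which fails the cascade filter downstream.
#' @export
eqtlTest <- function(dosage, expression) {
  if (length(dosage) != length(expression))
    stop("dosage and expression must be paired", call. = FALSE)
  if (!all(dosage %in% 0:2))
    stop("dosage must be 0, 1 or 2", call. = FALSE)
  if (length(dosage) < 3 || length(unique(dosage)) < 2)
    stop("need >= 3 samples and >= 2 dosage groups", call. = FALSE)
  if (stats::sd(expression) == 0)
    return(list(direction = NA_character_, slope = 0, p.value = 1))
  fit <- stats::lm(expression ~ dosage)
  co <- summary(fit)$coefficients
  slope <- co["dosage", "Estimate"]
  p <- co["dosage", "Pr(>|t|)"]
  list(direction = if (slope > 0) "up" else if (slope < 0) "down"
                   else NA_character_,
       slope = unname(slope), p.value = unname(p))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times (months)
#' @param event 0 = right-censored, 1 = death
#' @return list with the event-time grid (\code{time}), survival
#'   estimates (\code{surv}), counts (\code{n.risk}, \code{n.event}) and
#'   a right-continuous step function \code{fn} with \code{fn(0) = 1}
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$fn(2.5) # 0.5
#' @export
kmEstimate <- function(time, event) {
  if (length(time) == 0) stop("empty stratum", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  fn <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(time = fit$time, surv = fit$surv, n.risk = fit$n.risk,
       n.event = fit$n.event, fn = fn)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square between two survival strata. When
#' neither stratum has any event the statistic is 0 and p = 1. The
#' \code{worse} element names the stratum with more observed than
#' expected deaths (the stratum faring worse), used by the MP/MR
#' classification.
#'
#' @param time,event survival data over both strata
#' @param stratum two-level factor/character (e.g. \code{"high"} /
#'   \code{"low"} expression)
#' @return list with \code{statistic}, \code{p.value}, \code{worse}
#' @export
logrankTest <- function(time, event, stratum) {
  stratum <- as.factor(stratum)
  if (nlevels(droplevels(stratum)) != 2)
    stop("exactly two non-empty strata are required", call. = FALSE)
  stratum <- droplevels(stratum)
  if (sum(event) == 0)
    return(list(statistic = 0, p.value = 1, worse = NA_character_))
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum)
  stat <- unname(sd$chisq)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  diffOE <- sd$obs - sd$exp
  lev <- sub("^stratum=", "", names(sd$n))
  worse <- if (all(diffOE == 0)) NA_character_ else lev[which.max(diffOE)]
  list(statistic = stat, p.value = p, worse = worse)
}

#' Median split of expression into high/low strata
#'
#' Ties at the median are assigned to the low stratum.
#'
#' @param expression numeric vector
#' @return character vector \code{"high"} / \code{"low"}
#' @export
dichotomizeExpression <- function(expression) {
  med <- stats::median(expression)
  ifelse(expression > med, "high", "low")
}

#' Survival contrast between high and low expression
#'
#' Median-splits expression, administratively censors follow-up at the
#' analysis horizon (120 months by default, a 10-year window), and runs
#' the log-rank test between the high- and low-expression strata.
#'
#' @param time,event survival data (months; event 1 = death)
#' @param expression per-sample host-gene expression
#' @param horizon administrative censoring time in months
#' @return list with \code{p.value}, \code{statistic}, \code{worse}
#'   (stratum faring worse), \code{n_high}, \code{n_low}
#' @export
survivalByExpression <- function(time, event, expression, horizon = 120) {
  if (!(length(time) == length(event) &&
        length(event) == length(expression)))
    stop("time, event and expression must be aligned", call. = FALSE)
  over <- time > horizon
  event[over] <- 0
  time[over] <- horizon
  stratum <- dichotomizeExpression(expression)
  if (length(unique(stratum)) < 2)
    return(list(p.value = 1, statistic = 0, worse = NA_character_,
                n_high = sum(stratum == "high"),
                n_low = sum(stratum == "low")))
  lr <- logrankTest(time, event, stratum)
  list(p.value = lr$p.value, statistic = lr$statistic, worse = lr$worse,
       n_high = sum(stratum == "high"), n_low = sum(stratum == "low"))
}

#' Classify a candidate as metastasis promoter or resister
#'
#' A variant is a metastasis promoter (MP) when the expression level it
#' confers (up- or down-regulation of the host gene, from the eQTL
#' slope) is the expression stratum with the worse survival; otherwise
#' it is a metastasis resister (MR).
#'
#' @param eqtlDirection \code{"up"} or \code{"down"}
#' @param worseStratum \code{"high"} or \code{"low"}: the expression
#'   stratum with worse survival
#' @return \code{"MP"} or \code{"MR"}; an undefined direction or
#'   stratum is an error (such variants are excluded upstream)
#' @export
classifyVariant <- function(eqtlDirection, worseStratum) {
  if (is.na(eqtlDirection) || is.na(worseStratum) ||
      !eqtlDirection %in% c("up", "down") ||
      !worseStratum %in% c("high", "low"))
    stop("unclassifiable: direction and worse stratum must be defined",
         call. = FALSE)
  conferred <- if (eqtlDirection == "up") "high" else "low"
  if (conferred == worseStratum) "MP" else "MR"
}
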