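#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney form: the fraction of (event, non-event)
#' pairs where the event's score is higher, with ties counting one half.
#'
#' @param probs numeric predicted scores/probabilities.
#' @param labels binary outcomes (0/1).
#' @return numeric(1) AUC
#' @export
rocAuc <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both outcome classes")
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each observation, its placement value
# against the opposite class. psi = 1[x > y] + 0.5 * 1[x == y].
delongComponents <- function(probs, labels) {
  x <- probs[labels == 1L]
  y <- probs[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same records using the
#' DeLong structural-components estimator of the variance of the AUC
#' difference for correlated ROC curves. The z statistic is the AUC
#' difference divided by its estimated standard error; the p-value is
#' two-sided from the standard normal. When the two score vectors are
#' identical (zero estimated variance) the convention z = 0, p = 1 applies.
#'
#' @param probsA,probsB paired per-record scores for the two models.
#' @param labels binary outcomes (0/1), shared by both models.
#' @return list with \code{z}, \code{p}, \code{aucA}, \code{aucB},
#'   \code{varDiff}
#' @export
delongTest <- function(probsA, probsB, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probsA) == length(labels),
            length(probsB) == length(labels))
  if (length(unique(labels)) != 2L)
    stop("DeLong test requires both outcome classes")
  ca <- delongComponents(probsA, labels)
  cb <- delongComponents(probsB, labels)
  m <- length(ca$v10)
  n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  dAuc <- ca$auc - cb$auc
  if (varDiff <= 0 || (dAuc == 0 && varDiff < 1e-24)) {
    z <- 0; p <- 1
  } else {
    z <- dAuc / sqrt(varDiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, aucA = ca$auc, aucB = cb$auc, varDiff = varDiff)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' lower is better.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary outcomes (0/1).
#' @return numeric(1)
#' @export
brierScore <- function(probs, labels) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs - as.numeric(labels))^2)
}

#' Decision curve analysis: net benefit across treatment thresholds
#'
#' At threshold t a record is "treated" when its predicted probability
#' reaches t; net benefit is TP/N - FP/N * t/(1-t). The treat-all policy
#' treats everyone, treat-none has net benefit 0 by definition.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param thresholds threshold grid in (0, 1); t = 1 is excluded.
#' @return data.frame with columns \code{threshold}, \code{model},
#'   \code{treatAll}, \code{treatNone}
#' @export
decisionCurve <- function(probs, labels, thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds >= 1 | thresholds <= 0))
    stop("thresholds must lie strictly inside (0, 1)")
  if (length(unique(labels)) != 2L) stop("both outcome classes required")
  N <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(t) {
    treated <- probs >= t
    tp <- sum(treated & labels == 1L)
    fp <- sum(treated & labels == 0L)
    tp / N - fp / N * t / (1 - t)
  }, numeric(1))
  all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, model = nb, treatAll = all,
             treatNone = 0)
}

#' Baseline characteristics and between-group tests for cohorts
#'
#' Summarizes each cohort's covariates by LNM status and tests each
#' variable's distribution between cohorts against the first (reference)
#' cohort: chi-square without continuity correction for categorical
#' variables, Welch's unequal-variance t-test for the TIL score.
#'
#' @param cohorts named list (>= 2) of clinical data.frames with columns
#'   \code{age_cat}, \code{t_stage}, \code{stilc}, \code{til_score},
#'   \code{lnm}.
#' @return list with \code{byLNM} (per-cohort summaries) and
#'   \code{betweenCohorts} (data.frame of variable, cohort, statistic, p)
#' @export
summarizeCohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 2L, !is.null(names(cohorts)))
  for (nm in names(cohorts))
    if (nrow(cohorts[[nm]]) == 0L) stop("cohort ", nm, " is empty")
  catVars <- c("age_cat", "t_stage", "stilc")
  byLNM <- lapply(cohorts, function(d) {
    cnt <- lapply(catVars, function(v) table(d[[v]], lnm = d$lnm))
    names(cnt) <- catVars
    c(cnt, list(til_score = tapply(d$til_score, d$lnm, mean),
                n = nrow(d), events = sum(d$lnm)))
  })
  ref <- cohorts[[1L]]
  rows <- list()
  for (nm in names(cohorts)[-1L]) {
    d <- cohorts[[nm]]
    for (v in catVars) {
      tab <- table(factor(c(rep("ref", nrow(ref)), rep("cmp", nrow(d))),
                          levels = c("ref", "cmp")),
                   c(ref[[v]], d[[v]]))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, cohort = nm,
        statistic = unname(ct$statistic), p = ct$p.value)
    }
    tt <- tryCatch(stats::t.test(ref$til_score, d$til_score,
                                 var.equal = FALSE),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "til_score", cohort = nm,
      statistic = unname(tt$statistic), p = tt$p.value)
  }
  list(byLNM = byLNM, betweenCohorts = do.call(rbind, rows))
}
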