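# Feature sets for the two lymph-node-metastasis models: M1 adds the TIL
# features (patient TIL score + spatial TIL cluster) to the clinical pair.
M1_FEATURES <- c("age_cat", "t_stage", "til_score", "stilc")
M2_FEATURES <- c("age_cat", "t_stage")

#' Stratified 8:2 split of a clinical cohort
#'
#' Splits records into training and validation sets at the given validation
#' fraction, stratified on the LNM outcome so both sets keep the event rate.
#' Deterministic per seed; disjoint and exhaustive.
#'
#' @param records clinical data.frame with an \code{lnm} column (0/1).
#' @param validationFraction share held out, default 0.2 (an 8:2 split).
#' @param seed integer seed.
#' @return list with \code{training} and \code{validation} data.frames
#' @export
splitCohort <- function(records, validationFraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) >= 10L)
  if (length(unique(records$lnm)) != 2L)
    stop("cohort must contain both outcome classes")
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must lie in (0, 1)")
  withSeed(seed, {
    val <- unlist(lapply(split(seq_len(nrow(records)), records$lnm),
                         function(ix) {
      nv <- round(length(ix) * validationFraction)
      if (nv < 1L || nv >= length(ix))
        stop("split leaves an empty stratum; adjust validationFraction")
      sample(ix, nv)
    }), use.names = FALSE)
    list(training = records[-val, , drop = FALSE],
         validation = records[sort(val), , drop = FALSE])
  })
}

# stratified fold ids for cross-validation
stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(nFolds), length(ix))
  }
  fold
}

rangerFit <- function(data, features, hp, seed) {
  df <- data[, c(features, "lnm"), drop = FALSE]
  df$lnm <- factor(df$lnm, levels = c(0, 1))
  ranger::ranger(
    lnm ~ ., data = df, probability = TRUE,
    num.trees = hp$numTrees,
    max.depth = hp$maxDepth,           # 0 = unbounded
    min.node.size = hp$minNode,
    seed = seed, num.threads = 1L)
}

rangerProb <- function(fit, data) {
  p <- stats::predict(fit, data = data, num.threads = 1L)$predictions
  unname(p[, "1"])
}

#' Train an LNM random-forest model with cross-validated hyperparameters
#'
#' Fits a bagged ensemble of randomized decision trees (a probability random
#' forest) predicting lymph-node metastasis. Hyperparameters are chosen by
#' stratified 5-fold cross-validated AUC over a small grid: tree count in
#' \{100, 300, 500\}, maximum depth in \{3, 5, unbounded\}, minimum leaf
#' size in \{1, 5, 10\}. Ordinal covariates stay integer-coded (trees split
#' ordinals natively; no one-hot expansion). Deterministic per seed.
#'
#' @param training clinical data.frame with the feature columns and
#'   \code{lnm}.
#' @param features character vector of feature columns; use
#'   \code{m1Features()} (age, T stage, TIL score, sTILC) or
#'   \code{m2Features()} (age, T stage).
#' @param seed integer seed for fold assignment and forest growth.
#' @param nFolds cross-validation folds, default 5.
#' @return object of class \code{lnmModel}: list with \code{fit},
#'   \code{features}, \code{hyperparameters}, \code{cvAuc}, \code{seed}
#' @export
trainLNMModel <- function(training, features = m1Features(), seed = 1L,
                          nFolds = 5L) {
  miss <- setdiff(features, names(training))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (length(unique(training$lnm)) != 2L)
    stop("training cohort must contain both outcome classes")
  grid <- expand.grid(numTrees = c(100L, 300L, 500L),
                      maxDepth = c(3L, 5L, 0L),
                      minNode = c(1L, 5L, 10L))
  withSeed(seed, {
    fold <- stratifiedFolds(training$lnm, nFolds)
    cvAuc <- vapply(seq_len(nrow(grid)), function(g) {
      hp <- as.list(grid[g, ])
      aucs <- vapply(seq_len(nFolds), function(f) {
        tr <- training[fold != f, , drop = FALSE]
        te <- training[fold == f, , drop = FALSE]
        if (length(unique(te$lnm)) != 2L || length(unique(tr$lnm)) != 2L)
          return(NA_real_)
        fit <- rangerFit(tr, features, hp, seed = deriveSeed(seed, g * 100L + f))
        rocAuc(rangerProb(fit, te), te$lnm)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cvAuc)
    hp <- as.list(grid[best, ])
    fit <- rangerFit(training, features, hp, seed = deriveSeed(seed, 7L))
    structure(list(fit = fit, features = features, hyperparameters = hp,
                   cvAuc = cvAuc[best], seed = seed),
              class = "lnmModel")
  })
}

#' @rdname trainLNMModel
#' @export
m1Features <- function() M1_FEATURES

#' @rdname trainLNMModel
#' @export
m2Features <- function() M2_FEATURES

#' Predict event probabilities from an LNM model
#'
#' @param object an \code{lnmModel} from [trainLNMModel()].
#' @param newdata data.frame containing the model's feature columns.
#' @param ... ignored.
#' @return numeric vector of predicted LNM probabilities
#' @export
predict.lnmModel <- function(object, newdata, ...) {
  rangerProb(object$fit, newdata[, object$features, drop = FALSE])
}

#' @export
print.lnmModel <- function(x, ...) {
  cat("LNM random-forest model on features:",
      paste(x$features, collapse = ", "), "\n  hyperparameters:",
      sprintf("trees=%d depth=%s minLeaf=%d", x$hyperparameters$numTrees,
              if (x$hyperparameters$maxDepth == 0L) "unbounded"
              else x$hyperparameters$maxDepth,
              x$hyperparameters$minNode),
      sprintf("\n  cross-validated AUC: %.3f\n", x$cvAuc))
  invisible(x)
}

#' Compare the TIL-augmented (M1) and clinical-only (M2) LNM models
#'
#' Trains both models on the training cohort and evaluates them on every
#' supplied cohort: AUC, DeLong test of the AUC difference, Brier scores,
#' exact Shapley attributions for M1 (background = training cohort), and
#' decision-curve net benefit.
#'
#' @param training training cohort data.frame.
#' @param evalCohorts named list of cohorts to evaluate on (typically
#'   training / validation / test).
#' @param seed integer seed controlling both model fits.
#' @param shapley logical, compute exact Shapley attributions (default TRUE).
#' @param configHashValue optional provenance hash stored on the report.
#' @return a [ModelComparisonReport-class]
#' @export
compareLNMModels <- function(training, evalCohorts, seed = 1L,
                             shapley = TRUE, configHashValue = "") {
  m1 <- trainLNMModel(training, m1Features(), seed = seed)
  m2 <- trainLNMModel(training, m2Features(), seed = deriveSeed(seed, 2L))
  cohorts <- lapply(evalCohorts, function(d) {
    p1 <- predict(m1, d)
    p2 <- predict(m2, d)
    dl <- delongTest(p1, p2, d$lnm)
    res <- list(aucM1 = dl$aucA, aucM2 = dl$aucB,
                delongZ = dl$z, delongP = dl$p,
                brierM1 = brierScore(p1, d$lnm),
                brierM2 = brierScore(p2, d$lnm),
                netBenefit = list(m1 = decisionCurve(p1, d$lnm),
                                  m2 = decisionCurve(p2, d$lnm)),
                probsM1 = p1, probsM2 = p2)
    if (shapley) res$shapley <- exactShapley(m1, d, background = training)
    res
  })
  new("ModelComparisonReport", cohorts = cohorts,
      seeds = c(model = as.integer(seed)),
      configHash = configHashValue)
}

#' Ablation scenarios for the TIL feature representation
#'
#' Refits the TIL-augmented model with the spatial TIL cluster label
#' replaced by (a) all per-patient principal components, (b) only PC1 and
#' PC2, against (c) the primary sTILC-based model, and reports AUC on the
#' training, validation and test cohorts for each. The comparison exposes
#' how richer but higher-dimensional spatial representations overfit.
#'
#' @param training,validation,test clinical data.frames; each must carry the
#'   per-patient PCA columns.
#' @param pcaCols character vector naming the PCA feature columns.
#' @param seed integer seed shared by all fits.
#' @return data.frame with columns \code{scenario}, \code{cohort},
#'   \code{auc}
#' @export
runAblationScenarios <- function(training, validation, test, pcaCols,
                                 seed = 1L) {
  miss <- setdiff(pcaCols, names(training))
  if (length(miss))
    stop("missing PCA feature columns: ", paste(miss, collapse = ", "))
  base <- c("age_cat", "t_stage", "til_score")
  scen <- list(allPCs = c(base, pcaCols),
               pc1pc2 = c(base, pcaCols[1:2]),
               stilc = m1Features())
  cohorts <- list(training = training, validation = validation, test = test)
  out <- list()
  for (s in names(scen)) {
    fit <- trainLNMModel(training, scen[[s]], seed = seed)
    for (co in names(cohorts)) {
      out[[length(out) + 1L]] <- data.frame(
        scenario = s, cohort = co,
        auc = rocAuc(predict(fit, cohorts[[co]]), cohorts[[co]]$lnm))
    }
  }
  do.call(rbind, out)
}
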