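#' Exact interventional Shapley attributions
#'
#' Computes exact Shapley values for each record and feature of a fitted
#' model by enumerating all feature coalitions (feasible at the 4 features
#' of the TIL-augmented model: 16 coalitions). The value of a coalition S
#' for record x is the interventional expectation: the model's mean output
#' over the background rows with the features in S replaced by x's values.
#' Per-feature importance is the mean absolute attribution across records.
#'
#' The classical axioms hold by construction: attributions per record sum to
#' f(x) minus the mean background output (efficiency), a feature the model
#' never uses gets 0 everywhere (dummy), and exchangeable features receive
#' equal credit (symmetry).
#'
#' @param model an \code{lnmModel} (or any object with a \code{predict}
#'   method returning probabilities and a \code{features} element).
#' @param records data.frame of records to explain.
#' @param background non-empty data.frame of reference records (typically
#'   the training cohort).
#' @return list with \code{values} (records x features attribution matrix),
#'   \code{importance} (named mean |attribution| per feature),
#'   \code{baseline} (mean background prediction)
#' @export
exactShapley <- function(model, records, background) {
  feats <- model$features
  p <- length(feats)
  if (p > 12L) stop("exact enumeration is limited to <= 12 features")
  if (is.null(background) || nrow(background) == 0L)
    stop("background cohort must be non-empty")
  nB <- nrow(background)
  coalitions <- lapply(0:(2^p - 1L), function(m) which(bitwAnd(m, 2^(0:(p - 1L))) > 0))
  sizes <- lengths(coalitions)
  # Shapley kernel weight for adding feature i to coalition S: |S|!(p-|S|-1)!/p!
  wAdd <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) / factorial(p)
  bg <- background[, feats, drop = FALSE]
  vals <- matrix(0, nrow(records), p, dimnames = list(NULL, feats))
  for (r in seq_len(nrow(records))) {
    # one batched prediction over all coalitions for this record
    big <- bg[rep(seq_len(nB), length(coalitions)), , drop = FALSE]
    for (ci in seq_along(coalitions)) {
      S <- coalitions[[ci]]
      if (length(S))
        big[(ci - 1L) * nB + seq_len(nB), S] <-
          records[rep(r, nB), feats[S], drop = FALSE]
    }
    pred <- predict(model, big)
    v <- vapply(seq_along(coalitions), function(ci)
      mean(pred[(ci - 1L) * nB + seq_len(nB)]), numeric(1))
    mask <- vapply(coalitions, function(S) sum(2^(S - 1L)), numeric(1))
    vIdx <- structure(seq_along(coalitions), names = mask)
    for (i in seq_len(p)) {
      bit <- 2^(i - 1L)
      without <- which(bitwAnd(mask, bit) == 0)
      phi <- 0
      for (ci in without) {
        withI <- vIdx[[as.character(mask[ci] + bit)]]
        phi <- phi + wAdd[sizes[ci] + 1L] * (v[withI] - v[ci])
      }
      vals[r, i] <- phi
    }
  }
  list(values = vals,
       importance = colMeans(abs(vals)),
       baseline = mean(predict(model, background)))
}
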