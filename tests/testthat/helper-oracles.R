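# Independent oracle implementations used to cross-check the package's
# vectorized paths. These are deliberately naive (double loops, literal
# formulas) and share no code with the package internals.

# Naive per-patch evaluation of the local Gi* z-score formula on a
# neighbor-list weight structure. Denominator-zero patches get z = 0,
# matching the analytic convention for neighborhoods spanning the lattice.
naiveGiStar <- function(x, neighbors, weights) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  if (S == 0) return(z)
  for (i in seq_len(n)) {
    lag <- 0; Wi <- 0; Ui <- 0
    for (k in seq_along(neighbors[[i]])) {
      j <- neighbors[[i]][k]
      w <- weights[[i]][k]
      lag <- lag + w * x[j]
      Wi <- Wi + w
      Ui <- Ui + w^2
    }
    denom <- S * sqrt((n * Ui - Wi^2) / (n - 1))
    z[i] <- if (denom == 0) 0 else (lag - xbar * Wi) / denom
  }
  z
}

# Random masked lattice PatchGrid: Bernoulli tissue mask, Bernoulli labels.
randomMaskedGrid <- function(nr, nc, pTissue = 0.7, pPos = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    keep <- which(runif(nr * nc) < pTissue)
    if (length(keep) >= 5) break
  }
  row <- (keep - 1L) %/% nc
  col <- (keep - 1L) %% nc
  lab <- ifelse(runif(length(keep)) < pPos, "TIL_POS", "TIL_NEG")
  PatchGrid(sprintf("rnd_%d", seed), "p", row, col, lab,
            nRows = nr, nCols = nc)
}

# Brute-force mean silhouette width from the definitional formula.
bruteSilhouette <- function(X, lab) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    a <- if (length(own) > 1) mean(D[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(D[i, lab == cl]), numeric(1)))
    s[i] <- if (length(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Brute-force Davies-Bouldin index.
bruteDaviesBouldin <- function(X, lab) {
  ks <- sort(unique(lab))
  cent <- lapply(ks, function(k) colMeans(X[lab == k, , drop = FALSE]))
  s <- vapply(seq_along(ks), function(a) {
    rows <- X[lab == ks[a], , drop = FALSE]
    mean(apply(rows, 1, function(r) sqrt(sum((r - cent[[a]])^2))))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(a) {
    max(vapply(seq_along(ks)[-a], function(b) {
      (s[a] + s[b]) / sqrt(sum((cent[[a]] - cent[[b]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Brute-force Calinski-Harabasz index.
bruteCalinskiHarabasz <- function(X, lab) {
  ks <- sort(unique(lab))
  g <- colMeans(X)
  B <- 0; W <- 0
  for (k in ks) {
    rows <- X[lab == k, , drop = FALSE]
    ck <- colMeans(rows)
    B <- B + nrow(rows) * sum((ck - g)^2)
    W <- W + sum(sweep(rows, 2, ck)^2)
  }
  (B / (length(ks) - 1)) / (W / (nrow(X) - length(ks)))
}

# Brute-force AUC: exhaustive concordance over all (event, non-event) pairs.
bruteAuc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Join-count of like-labeled rook neighbors on a full lattice.
joinCountLike <- function(field) {
  nr <- nrow(field); nc <- ncol(field)
  cnt <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) cnt <- cnt + (field[i, j] == field[i + 1, j])
    if (j < nc) cnt <- cnt + (field[i, j] == field[i, j + 1])
  }
  cnt
}

# Tiny synthetic clinical cohort without the image path (fast model tests).
syntheticClinical <- function(n = 120, seed = 1, betaS = -3, betaC = 0.7) {
  set.seed(seed)
  arch <- sample(c("cold", "hot"), n, replace = TRUE)
  til <- ifelse(arch == "cold", rnorm(n, 0.08, 0.03), rnorm(n, 0.45, 0.08))
  til <- pmin(pmax(til, 0), 1)
  age <- sample(0:2, n, TRUE, prob = c(0.05, 0.47, 0.48))
  tst <- sample(0:3, n, TRUE, prob = c(0.35, 0.45, 0.13, 0.07))
  lp <- -1 + 0.6 * tst + 0.1 * age + betaS * til + betaC * (arch == "cold")
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age_cat = age, t_stage = tst, til_score = til,
             stilc = ifelse(arch == "cold", 1L, 2L),
             lnm = as.integer(runif(n) < plogis(lp)))
}
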