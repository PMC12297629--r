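#' Encoder configuration for hot spot map feature extraction
#'
#' The encoder is a fixed bank of random convolutional filters: four 3x3
#' convolution stages (stride 1, zero-padded "same", rectified-linear
#' activation), each followed by 2x2 max pooling with stride 2. Starting
#' from a 1024 x 1024 x 3 image the spatial side halves four times to
#' 64 x 64; with the default channel widths (16, 8, 8, 4) the flattened
#' output has 64 * 64 * 4 = 16,384 dimensions.
#'
#' The filters are never trained: weights are drawn once per seed from a
#' variance-scaled (He) normal distribution with zero biases and then frozen,
#' so the encoder acts as a deterministic random-projection feature
#' extractor. Identical seeds give identical features bit-for-bit.
#'
#' @param inputSize spatial side of the (square) input, default 1024.
#' @param channels integer vector of per-stage output channels,
#'   default \code{c(16, 8, 8, 4)}.
#' @param weightSeed integer seed for the filter draw.
#' @return list of class \code{encoderConfig}
#' @export
encoderConfig <- function(inputSize = 1024L, channels = c(16L, 8L, 8L, 4L),
                          weightSeed = 1L) {
  stopifnot(length(channels) >= 1L, all(channels >= 1L),
            inputSize %% 2^length(channels) == 0L)
  outSide <- inputSize / 2^length(channels)
  structure(list(inputSize = as.integer(inputSize),
                 channels = as.integer(channels),
                 kernel = 3L, weightSeed = as.integer(weightSeed),
                 outputLength = as.integer(outSide^2 * channels[length(channels)])),
            class = "encoderConfig")
}

# Draw the frozen filter bank for a config. He initialization:
# sd = sqrt(2 / fan_in) with fan_in = kh * kw * inChannels; biases zero.
encoderWeights <- function(cfg) {
  withSeed(cfg$weightSeed, {
    inC <- 3L
    lapply(cfg$channels, function(outC) {
      k <- cfg$kernel
      fanIn <- k * k * inC
      w <- array(stats::rnorm(k * k * inC * outC, sd = sqrt(2 / fanIn)),
                 dim = c(k, k, inC, outC))
      res <- list(w = w, b = rep(0, outC))
      inC <<- outC
      res
    })
  })
}

#' Preprocess a rendered map image for the encoder
#'
#' Pads the image to a square with the background color (white by default, or
#' anisotropic stretch with \code{resizeMode = "stretch"}), bilinearly
#' resizes it to \code{side} x \code{side}, and scales channel values to
#' [0, 1]. Padding before resizing preserves the lattice's aspect geometry.
#'
#' @param image numeric array H x W x 3 (values in [0, 1] or [0, 255]).
#' @param side target spatial side, default 1024.
#' @param resizeMode "pad" (default) or "stretch".
#' @param background padding color, default 1 (white).
#' @return numeric array side x side x 3 with values in [0, 1]
#' @export
preprocessMapImage <- function(image, side = 1024L,
                               resizeMode = c("pad", "stretch"),
                               background = 1) {
  resizeMode <- match.arg(resizeMode)
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop("image must be a non-empty H x W x 3 array")
  if (max(image) > 1) image <- image / 255
  if (resizeMode == "pad" && d[1] != d[2]) {
    s <- max(d[1], d[2])
    sq <- array(background, dim = c(s, s, 3))
    r0 <- (s - d[1]) %/% 2
    c0 <- (s - d[2]) %/% 2
    sq[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- image
    image <- sq
  }
  if (!all(dim(image)[1:2] == side))
    image <- resizeBilinear(image, as.integer(side))
  pmin(pmax(image, 0), 1)
}

#' Encode a preprocessed hot spot map into a feature vector
#'
#' Runs the fixed random-filter convolutional stack of [encoderConfig()] on
#' a preprocessed image and returns the flattened final feature maps
#' (length 16,384 at the defaults).
#'
#' @param image numeric array side x side x 3 from [preprocessMapImage()].
#' @param cfg an [encoderConfig()].
#' @param weights optional precomputed filter bank (from one seed); pass it
#'   when encoding many maps to avoid re-drawing.
#' @return numeric feature vector of length \code{cfg$outputLength}
#' @export
encodeHotspotMap <- function(image, cfg = encoderConfig(), weights = NULL) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] != cfg$inputSize ||
      d[2] != cfg$inputSize || d[3] != 3L)
    stop("image shape ", paste(d, collapse = "x"),
         " does not match encoder input ", cfg$inputSize)
  if (is.null(weights)) weights <- encoderWeights(cfg)
  x <- image
  for (layer in weights) {
    x <- conv2dSameRelu(x, layer$w, layer$b)
    x <- maxPool2(x)
  }
  as.numeric(x)
}

#' Fit PCA on encoder features
#'
#' Centers the slide x feature matrix on its column means and keeps the
#' smallest number of principal components whose cumulative explained
#' variance reaches \code{varianceTarget} (capped at \code{kCap} and at the
#' matrix rank). A fixed \code{kCap} with \code{varianceTarget = 1} pins the
#' component count instead.
#'
#' @param features numeric matrix, slides x features (>= 2 distinct rows).
#' @param varianceTarget cumulative explained-variance goal, default 0.95.
#' @param kCap optional hard cap on the number of components.
#' @return list with \code{scores} (slides x kPca), \code{center},
#'   \code{rotation}, \code{varShare} (all components), \code{kPca}.
#' @export
fitPCA <- function(features, varianceTarget = 0.95, kCap = NULL) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 1e-24) stop("rank zero: feature matrix is constant")
  rank <- sum(ev > max(ev) * 1e-12)
  varShare <- ev / tot
  k <- which(cumsum(varShare) >= varianceTarget - 1e-12)[1L]
  if (is.na(k)) k <- rank
  k <- min(k, rank, if (is.null(kCap)) Inf else kCap)
  k <- as.integer(k)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       center = pc$center,
       rotation = pc$rotation,
       varShare = varShare,
       kPca = k)
}

# project new feature rows onto a fitted PCA model
projectPCA <- function(model, features, k = model$kPca) {
  sweep(features, 2L, model$center) %*% model$rotation[, seq_len(k), drop = FALSE]
}

# ---- K-means with k-means++ seeding -----------------------------------

# Squared Euclidean distances from rows of X to rows of C.
sqDistToCenters <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

# One k-means++ initialization.
kppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (k > 1L) {
    d2 <- sqDistToCenters(X, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, sqDistToCenters(X, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

#' K-means clustering with k-means++ seeding
#'
#' Lloyd iterations from k-means++ starts: assignments to the nearest
#' center, centers to cluster means, stopping when the summed squared center
#' movement drops below \code{tol} or after \code{iterMax} sweeps. The best
#' of \code{nStart} restarts (lowest within-cluster sum of squares) is kept.
#' An emptied cluster is reseeded at the point farthest from its center.
#'
#' @param X numeric matrix, observations x dimensions.
#' @param k number of clusters (2 <= k < nrow(X)).
#' @param nStart restarts, default 10.
#' @param iterMax Lloyd iteration cap, default 300.
#' @param tol convergence tolerance on center movement, default 1e-4.
#' @param seed integer RNG seed for the restarts.
#' @return list with \code{cluster} (1-based labels), \code{centers},
#'   \code{totWithinSS}.
#' @export
kmeansPP <- function(X, k, nStart = 10L, iterMax = 300L, tol = 1e-4,
                     seed = 1L) {
  stopifnot(is.matrix(X), k >= 1L, k < nrow(X))
  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nStart)) {
      centers <- kppInit(X, k)
      for (it in seq_len(iterMax)) {
        d2 <- sqDistToCenters(X, centers)
        lab <- max.col(-d2, ties.method = "first")
        newC <- centers
        for (j in seq_len(k)) {
          rows <- lab == j
          if (!any(rows)) {
            far <- which.max(d2[cbind(seq_len(nrow(X)), lab)])
            newC[j, ] <- X[far, ]
            lab[far] <- j
          } else {
            newC[j, ] <- colMeans(X[rows, , drop = FALSE])
          }
        }
        shift <- sum((newC - centers)^2)
        centers <- newC
        if (shift < tol) break
      }
      d2 <- sqDistToCenters(X, centers)
      lab <- max.col(-d2, ties.method = "first")
      wss <- sum(d2[cbind(seq_len(nrow(X)), lab)])
      if (is.null(best) || wss < best$totWithinSS)
        best <- list(cluster = lab, centers = centers, totWithinSS = wss)
    }
    best
  })
}

# ---- internal cluster-quality indices ---------------------------------

#' Internal cluster-quality indices
#'
#' Mean silhouette width (via \pkg{cluster}), Davies-Bouldin index
#' (average over clusters of the worst ratio of summed mean within-cluster
#' centroid distances to the centroid separation) and Calinski-Harabasz
#' index (between/within variance ratio scaled by degrees of freedom).
#' Higher silhouette and Calinski-Harabasz are better; lower Davies-Bouldin
#' is better.
#'
#' @param X numeric matrix, observations x dimensions.
#' @param labels integer cluster labels (>= 2 distinct).
#' @return named numeric(3): \code{silhouette}, \code{daviesBouldin},
#'   \code{calinskiHarabasz}
#' @export
clusterIndices <- function(X, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  stopifnot(k >= 2L, k < nrow(X))
  sil <- mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  centers <- t(vapply(seq_len(k), function(j)
    colMeans(X[labels == j, , drop = FALSE]), numeric(ncol(X))))
  # Davies-Bouldin: s_j = mean distance to own centroid
  s <- vapply(seq_len(k), function(j) {
    rows <- X[labels == j, , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2L, centers[j, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centers))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / cd[i, j], numeric(1)))
  }, numeric(1)))
  # Calinski-Harabasz
  n <- nrow(X)
  grand <- colMeans(X)
  nj <- tabulate(labels, k)
  B <- sum(nj * rowSums(sweep(centers, 2L, grand)^2))
  W <- sum(vapply(seq_len(k), function(j)
    sum(sweep(X[labels == j, , drop = FALSE], 2L, centers[j, ])^2),
    numeric(1)))
  ch <- (B / (k - 1)) / (W / (n - k))
  c(silhouette = sil, daviesBouldin = db, calinskiHarabasz = ch)
}

#' Select the number of spatial TIL clusters by consensus voting
#'
#' For each candidate k, K-means ([kmeansPP()]) partitions the reduced
#' feature matrix and the three indices of [clusterIndices()] are computed.
#' Each metric votes for its best k (silhouette and Calinski-Harabasz
#' maximize, Davies-Bouldin minimizes); the consensus is the majority vote,
#' with a three-way tie resolved in favor of the silhouette's winner.
#'
#' @param reduced numeric matrix, slides x components.
#' @param candidateKs integer vector of cluster numbers, default 2:6.
#' @param seed integer seed for the K-means restarts.
#' @param ... passed to [kmeansPP()].
#' @return a [ConsensusVote-class]
#' @export
consensusKSelection <- function(reduced, candidateKs = 2:6, seed = 1L, ...) {
  candidateKs <- as.integer(candidateKs)
  vals <- matrix(NA_real_, length(candidateKs), 3,
                 dimnames = list(candidateKs,
                                 c("silhouette", "daviesBouldin",
                                   "calinskiHarabasz")))
  labelsByK <- vector("list", length(candidateKs))
  for (i in seq_along(candidateKs)) {
    k <- candidateKs[i]
    if (k >= nrow(reduced)) {
      warning("skipping k = ", k, ": needs more than k observations")
      next
    }
    km <- kmeansPP(reduced, k, seed = deriveSeed(seed, k), ...)
    labelsByK[[i]] <- km$cluster
    vals[i, ] <- clusterIndices(reduced, km$cluster)
  }
  ok <- !is.na(vals[, 1])
  if (!any(ok)) stop("no candidate k could be evaluated")
  ks <- candidateKs[ok]
  winners <- c(
    silhouette = ks[which.max(vals[ok, "silhouette"])],
    daviesBouldin = ks[which.min(vals[ok, "daviesBouldin"])],
    calinskiHarabasz = ks[which.max(vals[ok, "calinskiHarabasz"])]
  )
  tab <- table(winners)
  selected <- if (max(tab) >= 2L) as.integer(names(tab)[which.max(tab)])
              else winners[["silhouette"]]
  new("ConsensusVote", candidateKs = candidateKs,
      silhouette = vals[, "silhouette"],
      daviesBouldin = vals[, "daviesBouldin"],
      calinskiHarabasz = vals[, "calinskiHarabasz"],
      winners = winners, selectedK = as.integer(selected))
}

#' Name two spatial TIL clusters by their hot spot content
#'
#' The cluster whose members have the lower mean hot fraction (share of
#' patches with Gi* z at or above the hot threshold) is the TIL-cold cluster
#' sTILC1; the other is the TIL-hot cluster sTILC2. Naming is invariant to
#' the integer ids of the clusters and to slide order. An exact tie is
#' broken deterministically toward labeling the first-indexed cluster
#' sTILC1, with a warning.
#'
#' @param clusterLabels integer vector of cluster ids per slide (exactly 2
#'   distinct values).
#' @param hotspotMaps list of [HotspotMap-class] aligned with
#'   \code{clusterLabels} (or a numeric vector of hot fractions).
#' @return character vector of "sTILC1"/"sTILC2" per slide
#' @export
assignStilcNames <- function(clusterLabels, hotspotMaps) {
  ids <- sort(unique(clusterLabels))
  if (length(ids) != 2L)
    stop("sTILC naming is defined for exactly 2 clusters, got ", length(ids))
  hf <- if (is.numeric(hotspotMaps)) hotspotMaps
        else vapply(hotspotMaps, hotFraction, numeric(1))
  stopifnot(length(hf) == length(clusterLabels))
  m <- vapply(ids, function(id) mean(hf[clusterLabels == id]), numeric(1))
  if (m[1] == m[2]) {
    warning("clusters have equal mean hot fractions; ",
            "labeling first-indexed cluster sTILC1")
    cold <- ids[1]
  } else cold <- ids[which.min(m)]
  ifelse(clusterLabels == cold, "sTILC1", "sTILC2")
}

#' Derive spatial TIL clusters from hot spot maps
#'
#' End-to-end spatial feature derivation for a cohort of slides: render each
#' hot spot map, preprocess and encode it with the fixed random-filter
#' encoder, reduce the feature matrix with PCA, select the cluster number by
#' consensus voting, partition with K-means at the selected k, and (when two
#' clusters emerge) name them sTILC1/sTILC2 by hot spot content. Identical
#' seeds reproduce the full path bit-for-bit.
#'
#' @param hmaps named list of [HotspotMap-class] (names = slide ids).
#' @param cfg an [encoderConfig()].
#' @param varianceTarget,kCap PCA truncation, see [fitPCA()].
#' @param candidateKs candidate cluster numbers, default 2:6.
#' @param kmeansSeed seed for consensus and final K-means.
#' @param blockPx rendering block size, see [renderHotspotMap()].
#' @param k optional fixed cluster number; overrides the consensus choice
#'   for the final partition (the vote is still computed and stored).
#' @return a [SpatialFeatureSet-class]
#' @export
deriveSpatialClusters <- function(hmaps, cfg = encoderConfig(),
                                  varianceTarget = 0.95, kCap = NULL,
                                  candidateKs = 2:6, kmeansSeed = 1L,
                                  blockPx = 8L, k = NULL) {
  ids <- names(hmaps)
  if (is.null(ids)) ids <- vapply(hmaps, slideId, character(1))
  w <- encoderWeights(cfg)
  feats <- t(vapply(hmaps, function(h) {
    img <- preprocessMapImage(renderHotspotMap(h, blockPx = blockPx),
                              side = cfg$inputSize)
    encodeHotspotMap(img, cfg, weights = w)
  }, numeric(cfg$outputLength)))
  rownames(feats) <- ids
  pca <- fitPCA(feats, varianceTarget = varianceTarget, kCap = kCap)
  vote <- consensusKSelection(pca$scores, candidateKs, seed = kmeansSeed)
  kFinal <- if (is.null(k)) vote@selectedK else as.integer(k)
  km <- kmeansPP(pca$scores, kFinal,
                 seed = deriveSeed(kmeansSeed, 1000L + kFinal))
  stilc <- if (kFinal == 2L)
    assignStilcNames(km$cluster, hmaps) else character(0)
  new("SpatialFeatureSet", slideIds = ids, rawFeatures = feats,
      pcaScores = pca$scores,
      pcaModel = pca[c("center", "rotation", "varShare", "kPca")],
      clusterLabels = as.integer(km$cluster), stilcLabels = stilc,
      vote = vote)
}
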