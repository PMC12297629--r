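test_that("image preprocessing pads, resizes and scales to [0, 1]", {
  # square input only gets value-scaled
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  out <- preprocessMapImage(img, side = 64)
  expect_equal(out, img, tolerance = 1e-12)
  # non-square input is padded to square first, preserving tissue geometry
  img2 <- array(0.5, dim = c(32, 16, 3))
  out2 <- preprocessMapImage(img2, side = 32)
  expect_equal(dim(out2), c(32L, 32L, 3L))
  # padded margins carry the background color
  expect_equal(out2[1, 1, 1], 1)
  expect_equal(out2[16, 16, 2], 0.5)
  out3 <- preprocessMapImage(array(runif(50 * 70 * 3) * 255,
                                   dim = c(50, 70, 3)), side = 128)
  expect_gte(min(out3), 0)
  expect_lte(max(out3), 1)
  expect_error(preprocessMapImage(array(0, dim = c(0, 4, 3))), "non-empty")
})

test_that("encoder output has the configured dimensionality and determinism", {
  cfg <- encoderConfig(inputSize = 64L)
  expect_equal(cfg$outputLength, (64 / 16)^2 * 4)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  v1 <- encodeHotspotMap(img, cfg)
  v2 <- encodeHotspotMap(img, cfg)
  expect_identical(v1, v2)
  expect_length(v1, cfg$outputLength)
  # different weight seeds give different projections
  v3 <- encodeHotspotMap(img, encoderConfig(inputSize = 64L, weightSeed = 2L))
  expect_false(identical(v1, v3))
  # zero image maps to zero features (zero-bias convolutions + ReLU)
  expect_equal(encodeHotspotMap(array(0, dim = c(64, 64, 3)), cfg),
               rep(0, cfg$outputLength))
  expect_error(encodeHotspotMap(array(0, dim = c(32, 32, 3)), cfg),
               "does not match")
})

test_that("convolution and pooling match direct small-array evaluation", {
  # 4x4 single-channel image, one 3x3 filter: check one interior output
  set.seed(31)
  x <- array(seq_len(16) / 16, dim = c(4, 4, 1))
  wt <- array(rnorm(9), dim = c(3, 3, 1, 1))
  out <- spatialTIL:::conv2dSameRelu(x, wt, 0)
  # single-precision accumulation: compare at absolute float tolerance
  ref <- sum(wt[, , 1, 1] * x[1:3, 1:3, 1])
  expect_lt(abs(out[2, 2, 1] - max(ref, 0)), 1e-6)
  # border handling: top-left output only sees the valid 2x2 window
  ref00 <- sum(wt[2:3, 2:3, 1, 1] * x[1:2, 1:2, 1])
  expect_lt(abs(out[1, 1, 1] - max(ref00, 0)), 1e-6)
  p <- spatialTIL:::maxPool2(out)
  expect_equal(p[1, 1, 1], max(out[1:2, 1:2, 1]))
  expect_equal(dim(p), c(2L, 2L, 1L))
})

test_that("PCA truncates at the cumulative variance target", {
  set.seed(13)
  base <- matrix(rnorm(20), 20, 1) %*% matrix(rnorm(50), 1, 50)
  X <- base + matrix(rnorm(20 * 50, sd = 1e-4), 20, 50)
  p <- fitPCA(X, varianceTarget = 0.95)
  expect_equal(p$kPca, 1L)
  # completeness: full reconstruction reproduces centered data
  Xc <- sweep(X, 2, colMeans(X))
  full <- Xc %*% p$rotation %*% t(p$rotation)
  expect_lt(max(abs(full - Xc)), 1e-6)
  expect_true(all(diff(p$varShare) <= 1e-12))
  expect_lte(sum(p$varShare), 1 + 1e-9)
  # orthonormal loadings
  G <- unname(crossprod(p$rotation[, 1:5]))
  expect_equal(G, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fitPCA(matrix(1, 5, 4)), "rank zero")
  # kCap override pins the component count
  expect_equal(fitPCA(matrix(rnorm(200), 20), kCap = 3)$kPca, 3L)
})

test_that("cluster indices match brute-force definitional formulas", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), n, 3) +
      matrix(rnorm(k * 3, sd = 3), k, 3)[sample(k, n, TRUE), ]
    lab <- kmeansPP(X, k, seed = rep)$cluster
    ci <- clusterIndices(X, lab)
    expect_equal(ci[["silhouette"]], bruteSilhouette(X, lab), tolerance = 1e-8)
    expect_equal(ci[["daviesBouldin"]], bruteDaviesBouldin(X, lab),
                 tolerance = 1e-8)
    expect_equal(ci[["calinskiHarabasz"]], bruteCalinskiHarabasz(X, lab),
                 tolerance = 1e-8)
  }
})

test_that("k-means finds partitions at least as good as the stats reference", {
  set.seed(19)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
  mine <- kmeansPP(X, 3, seed = 1)
  ref <- stats::kmeans(X, 3, nstart = 10)
  expect_lte(mine$totWithinSS, ref$tot.withinss * 1.0001)
  expect_error(kmeansPP(X, 60, seed = 1))
})

test_that("consensus voting selects k on separated blobs and breaks ties", {
  set.seed(23)
  two <- rbind(matrix(rnorm(80, 0, 0.3), 40), matrix(rnorm(80, 5, 0.3), 40))
  v2 <- consensusKSelection(two, 2:6, seed = 1)
  expect_equal(v2@winners[["silhouette"]], 2L)
  expect_equal(v2@winners[["daviesBouldin"]], 2L)
  expect_equal(v2@winners[["calinskiHarabasz"]], 2L)
  expect_equal(selectedK(v2), 2L)
  three <- rbind(matrix(rnorm(60, 0, 0.3), 30),
                 matrix(rnorm(60, 6, 0.3), 30),
                 cbind(rnorm(30, 3, 0.3), rnorm(30, 5.2, 0.3)))
  expect_equal(selectedK(consensusKSelection(three, 2:6, seed = 1)), 3L)
  # too-large k values are skipped with a warning
  small <- matrix(rnorm(10), 5, 2)
  expect_warning(v <- consensusKSelection(small, c(2, 6), seed = 1),
                 "skipping k = 6")
  expect_equal(v@candidateKs, c(2L, 6L))
  expect_true(is.na(v@silhouette[2]))
})

test_that("three-way vote splits resolve toward the silhouette winner", {
  # exercise the tie-break rule directly on a crafted vote
  v <- new("ConsensusVote", candidateKs = 2:4,
           silhouette = c(0.5, 0.4, 0.3),
           daviesBouldin = c(1, 0.5, 2),
           calinskiHarabasz = c(5, 6, 9),
           winners = c(silhouette = 2L, daviesBouldin = 3L,
                       calinskiHarabasz = 4L),
           selectedK = 2L)
  expect_equal(selectedK(v), 2L)
  # and through the code path: three metrics disagreeing on crafted data is
  # hard to stage deterministically, so validate the majority rule instead
  set.seed(29)
  blobs <- rbind(matrix(rnorm(40, 0, 0.2), 20), matrix(rnorm(40, 4, 0.2), 20))
  vv <- consensusKSelection(blobs, 2:4, seed = 2)
  tab <- table(vv@winners)
  expect_equal(selectedK(vv),
               if (max(tab) >= 2) as.integer(names(tab)[which.max(tab)])
               else vv@winners[["silhouette"]])
})

test_that("sTILC naming follows hot spot content, not cluster ids", {
  hf <- c(0.05, 0.06, 0.40, 0.42, 0.04)
  lab <- c(1L, 1L, 2L, 2L, 1L)
  nm <- assignStilcNames(lab, hf)
  expect_equal(nm, c("sTILC1", "sTILC1", "sTILC2", "sTILC2", "sTILC1"))
  # swapping ids leaves names unchanged
  nm2 <- assignStilcNames(3L - lab, hf)
  expect_equal(nm2, nm)
  # slide-order invariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(assignStilcNames(lab[perm], hf[perm]), nm[perm])
  # ties break deterministically with a warning
  expect_warning(tied <- assignStilcNames(c(1L, 2L), c(0.2, 0.2)),
                 "equal mean hot fractions")
  expect_equal(tied, c("sTILC1", "sTILC2"))
  expect_error(assignStilcNames(c(1L, 2L, 3L), c(0.1, 0.2, 0.3)),
               "exactly 2 clusters")
})
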