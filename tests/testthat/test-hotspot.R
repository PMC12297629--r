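test_that("binarization maps TIL-positive to 1 and everything else to 0", {
  g <- PatchGrid("s", "p",
                 row = rep(0:1, each = 5), col = rep(0:4, 2),
                 label = c(rep("TIL_POS", 3), rep("TIL_NEG", 5),
                           rep("NECROTIC_OTHER", 2)))
  x <- binarizeTILMap(g)
  expect_equal(sum(x == 1), 3)
  expect_equal(sum(x == 0), 7)
  gAll <- PatchGrid("s", "p", 0:2, rep(0L, 3), rep("TIL_POS", 3))
  expect_equal(binarizeTILMap(gAll), rep(1L, 3))
  gNec <- PatchGrid("s", "p", 0:2, rep(0L, 3), rep("NECROTIC_OTHER", 3))
  expect_equal(binarizeTILMap(gNec), rep(0L, 3))
})

test_that("contiguity weights respect scheme, mask and self-inclusion", {
  full <- PatchGrid("s", "p", rep(0:2, each = 3), rep(0:2, 3),
                    rep("TIL_NEG", 9))
  wq <- buildLatticeWeights(full, "queen")
  # center patch (row 1, col 1) has 8 neighbors + self
  center <- which(patches(full)$row == 1 & patches(full)$col == 1)
  expect_length(wq@neighbors[[center]], 9L)
  wr <- buildLatticeWeights(full, "rook")
  corner <- which(patches(full)$row == 0 & patches(full)$col == 0)
  expect_length(wr@neighbors[[corner]], 3L)  # 2 neighbors + self
  # isolated patch keeps only itself
  iso <- PatchGrid("s", "p", c(0L, 5L), c(0L, 5L), rep("TIL_NEG", 2),
                   nRows = 6, nCols = 6)
  wi <- buildLatticeWeights(iso, "queen")
  expect_equal(wi@neighbors[[1L]], 1L)
  # neighbor relation (excluding self) is symmetric
  g <- randomMaskedGrid(7, 7, seed = 42)
  w <- buildLatticeWeights(g, "queen")
  for (i in seq_len(w@n)) {
    for (j in setdiff(w@neighbors[[i]], i)) {
      expect_true(i %in% w@neighbors[[j]])
    }
  }
})

test_that("Gi* matches the naive definitional oracle on random masked lattices", {
  for (seed in 1:20) {
    nr <- sample(5:30, 1)
    nc <- sample(5:30, 1)
    g <- randomMaskedGrid(nr, nc, pTissue = runif(1, 0.4, 1),
                          pPos = runif(1, 0.1, 0.6), seed = seed)
    w <- buildLatticeWeights(g, "queen")
    h <- localGiStar(g, w)
    oracle <- naiveGiStar(binarizeTILMap(g), w@neighbors, w@weights)
    expect_lt(max(abs(zScores(h) - oracle)), 1e-8)
  }
})

test_that("constant fields are degenerate with all-zero z", {
  g1 <- PatchGrid("s", "p", rep(0:2, each = 3), rep(0:2, 3),
                  rep("TIL_POS", 9))
  h1 <- localGiStar(g1)
  expect_true(isDegenerate(h1))
  expect_equal(zScores(h1), rep(0, 9))
  g0 <- PatchGrid("s", "p", rep(0:2, each = 3), rep(0:2, 3),
                  rep("NECROTIC_OTHER", 9))
  h0 <- localGiStar(g0)
  expect_true(isDegenerate(h0))
  expect_equal(hotFraction(h0), 0)
})

test_that("complementing the field negates every z exactly", {
  g <- randomMaskedGrid(12, 15, seed = 9)
  w <- buildLatticeWeights(g)
  x <- binarizeTILMap(g)
  z1 <- zScores(localGiStar(g, w, x = x))
  z2 <- zScores(localGiStar(g, w, x = 1 - x))
  expect_equal(z2, -z1)
})

test_that("Gi* z-scores are approximately standard normal on an iid lattice", {
  # 50x50 full lattice, iid Bernoulli(0.3), averaged over 10 seeds
  mu <- sdv <- numeric(10)
  for (s in 1:10) {
    set.seed(1000 + s)
    lab <- ifelse(runif(2500) < 0.3, "TIL_POS", "TIL_NEG")
    g <- PatchGrid("null", "p", rep(0:49, each = 50), rep(0:49, 50), lab)
    z <- zScores(localGiStar(g))
    mu[s] <- mean(z)
    sdv[s] <- sd(z)
  }
  expect_gt(mean(mu), -0.05)
  expect_lt(mean(mu), 0.05)
  expect_gt(mean(sdv), 0.85)
  expect_lt(mean(sdv), 1.15)
})

test_that("neighbor sums depend only on adjacency (mask locality)", {
  g <- PatchGrid("s", "p", rep(0:2, each = 3), rep(0:2, 3),
                 c(rep("TIL_POS", 4), rep("TIL_NEG", 5)), nRows = 20, nCols = 20)
  w1 <- buildLatticeWeights(g)
  lagOf <- function(w, x, i) sum(w@weights[[i]] * x[w@neighbors[[i]]])
  x1 <- binarizeTILMap(g)
  # add distant tissue beyond the contiguity radius
  p <- patches(g)
  g2 <- PatchGrid("s", "p", c(p$row, 15L, 16L), c(p$col, 15L, 16L),
                  c(as.character(p$label), "TIL_POS", "TIL_POS"),
                  nRows = 20, nCols = 20)
  w2 <- buildLatticeWeights(g2)
  x2 <- binarizeTILMap(g2)
  for (i in seq_len(9)) expect_equal(lagOf(w2, x2, i), lagOf(w1, x1, i))
})

test_that("Gi* requires at least two patches", {
  g <- PatchGrid("s", "p", 0L, 0L, "TIL_POS")
  expect_error(localGiStar(g), "at least 2")
})

test_that("hot spot rendering is deterministic with correct colormap polarity", {
  g <- randomMaskedGrid(10, 10, seed = 3)
  h <- localGiStar(g)
  img1 <- renderHotspotMap(h)
  img2 <- renderHotspotMap(h)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(80L, 80L, 3L))
  # strongest positive patch: red strictly exceeds blue in its block
  i <- which.max(zScores(h))
  rr <- h@coords[i, "row"] * 8 + 1
  cc <- h@coords[i, "col"] * 8 + 1
  expect_gt(img1[rr, cc, 1], img1[rr, cc, 3])
  # degenerate map renders uniformly
  gd <- PatchGrid("s", "p", rep(0:2, each = 3), rep(0:2, 3), rep("TIL_NEG", 9))
  imgd <- renderHotspotMap(localGiStar(gd))
  expect_equal(length(unique(as.vector(imgd))), 1L)
  # PNG round trip preserves the 8-bit image
  path <- withr::local_tempfile(fileext = ".png")
  writeHotspotPNG(img1, path)
  back <- png::readPNG(path)
  expect_equal(back, img1, tolerance = 1 / 254)
})
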