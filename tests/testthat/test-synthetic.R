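test_that("tissue masks are connected, near-target fill, and seeded", {
  expect_true(all(generateTissueMask(c(10L, 10L), 1.0, seed = 1)))
  m1 <- generateTissueMask(c(48L, 48L), 0.6, seed = 5)
  m2 <- generateTissueMask(c(48L, 48L), 0.6, seed = 5)
  expect_identical(m1, m2)
  # realized fill stays within +/- 0.15 of target across seeds
  fills <- vapply(1:20, function(s)
    mean(generateTissueMask(c(48L, 48L), 0.6, seed = s)), numeric(1))
  expect_true(all(abs(fills - 0.6) <= 0.15))
  # single connected component
  lab <- EBImage::bwlabel(m1)
  expect_equal(max(lab), 1)
  expect_error(generateTissueMask(c(48L, 48L), 0, seed = 1), "maskFill")
  expect_error(generateTissueMask(c(48L, 48L), 1.2, seed = 1), "maskFill")
})

test_that("lattices hit the archetype's density among scoreable patches", {
  scores <- vapply(1:20, function(s) {
    m <- generateTissueMask(seed = s)
    g <- generateTILLattice(m, archetypeSpec("hot"), seed = 100 + s)
    scoreValue(computeTILScore(g))
  }, numeric(1))
  expect_true(all(abs(scores - 0.45) <= 0.05))
  coldScores <- vapply(1:10, function(s) {
    m <- generateTissueMask(seed = s)
    scoreValue(computeTILScore(
      generateTILLattice(m, archetypeSpec("cold"), seed = 200 + s)))
  }, numeric(1))
  expect_true(all(abs(coldScores - 0.08) <= 0.05))
})

test_that("cold lattices have fewer Gi* hot patches than paired hot lattices", {
  for (s in 1:20) {
    m <- generateTissueMask(seed = s)
    hfCold <- hotFraction(localGiStar(
      generateTILLattice(m, archetypeSpec("cold"), seed = 300 + s)))
    hfHot <- hotFraction(localGiStar(
      generateTILLattice(m, archetypeSpec("hot"), seed = 300 + s)))
    expect_lt(hfCold, hfHot)
  }
})

test_that("correlation length 1 at density 1/2 behaves like an iid field", {
  # join counts of like rook neighbors match the iid expectation:
  # E[like] = J * (p^2 + (1-p)^2) with p = 1/2 -> J/2
  mask <- matrix(TRUE, 30, 30)
  spec1 <- archetypeSpec("cold", targetPosFraction = 0.5,
                         correlationLength = 1, necroticRate = 0)
  J <- 2 * 30 * 29
  jc <- vapply(1:10, function(s) {
    g <- generateTILLattice(mask, spec1, seed = s)
    f <- matrix(0L, 30, 30)
    f[cbind(patches(g)$row + 1, patches(g)$col + 1)] <- binarizeTILMap(g)
    joinCountLike(f)
  }, numeric(1))
  # binomial-ish fluctuation around J/2
  expect_lt(abs(mean(jc) - J / 2), 3 * sqrt(J / 4) / sqrt(10) + 20)
  expect_error(generateTILLattice(matrix(c(TRUE, rep(FALSE, 99)), 10, 10),
                                  archetypeSpec("cold")), "unreachable")
})

test_that("cohorts are deterministic with plausible event prevalence", {
  co <- generateCohort(cohortSpec(nPatients = 60, seed = 42))
  co2 <- generateCohort(cohortSpec(nPatients = 60, seed = 42))
  expect_identical(co$clinical, co2$clinical)
  expect_identical(patches(co$grids[[1]]), patches(co2$grids[[1]]))
  expect_equal(nrow(co$clinical), 60)
  # til_score in clinical equals the score recomputed from the lattice
  recomputed <- vapply(co$grids, function(g)
    scoreValue(computeTILScore(g)), numeric(1))
  expect_equal(unname(co$clinical$til_score), unname(recomputed))
  # archetype-coded stilc matches the truth table
  expect_equal(co$clinical$stilc,
               ifelse(co$truth$archetype == "cold", 1L, 2L))
  expect_error(generateCohort(cohortSpec(nPatients = 10)), ">= 20")
})

test_that("default cohorts have prevalence in the plausible clinical band", {
  co <- generateCohort(cohortSpec(nPatients = 500, seed = 9))
  prev <- mean(co$clinical$lnm)
  expect_gte(prev, 0.2)
  expect_lte(prev, 0.5)
})

test_that("cohort CSVs round-trip through the pipeline readers", {
  co <- generateCohort(cohortSpec(nPatients = 20, seed = 77))
  dir <- withr::local_tempdir()
  paths <- writeCohortCSV(co, dir)
  expect_no_warning(grids <- readPatchTable(paths[["patches"]]))
  expect_length(grids, 20)
  clin <- utils::read.csv(paths[["clinical"]])
  expect_equal(names(clin),
               c("patient_id", "age_cat", "t_stage", "til_score", "stilc",
                 "lnm", "cohort"))
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(names(truth),
               c("patient_id", "archetype", "linear_predictor",
                 "true_til_score"))
  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  writeCohortCSV(generateCohort(cohortSpec(nPatients = 20, seed = 77)), dir2)
  expect_identical(readLines(paths[["patches"]]),
                   readLines(file.path(dir2, "patch_table.csv")))
  expect_identical(readLines(paths[["clinical"]]),
                   readLines(file.path(dir2, "clinical.csv")))
})

test_that("removing the TIL effect removes the M1 advantage", {
  co <- generateCohort(cohortSpec(nPatients = 1000, betaS = 0, betaC = 0,
                                  seed = 31))
  sc <- splitCohort(co$clinical, 0.3, seed = 1)
  m1 <- trainLNMModel(sc$training, m1Features(), seed = 2)
  m2 <- trainLNMModel(sc$training, m2Features(), seed = 3)
  a1 <- rocAuc(predict(m1, sc$validation), sc$validation$lnm)
  a2 <- rocAuc(predict(m2, sc$validation), sc$validation$lnm)
  expect_lt(abs(a1 - a2), 0.05)
})
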