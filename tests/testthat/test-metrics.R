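test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               bruteAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    probs <- round(runif(n), 2)  # rounding forces ties
    expect_equal(rocAuc(probs, labels), bruteAuc(probs, labels))
  }
  # null scores give AUC near 1/2 at large n
  set.seed(5)
  labels <- rbinom(4000, 1, 0.5)
  expect_equal(rocAuc(runif(4000), labels), 0.5, tolerance = 0.05)
  expect_error(rocAuc(c(0.3, 0.4), c(1, 1)), "both outcome classes")
})

test_that("DeLong test has the identity convention and antisymmetry", {
  set.seed(21)
  labels <- rbinom(60, 1, 0.4)
  pa <- runif(60)
  r <- delongTest(pa, pa, labels)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  pb <- runif(60)
  r1 <- delongTest(pa, pb, labels)
  r2 <- delongTest(pb, pa, labels)
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$aucA, rocAuc(pa, labels))
})

test_that("DeLong variance agrees with a paired-bootstrap oracle", {
  set.seed(31)
  n <- 100
  labels <- rbinom(n, 1, 0.4)
  signal <- rnorm(n, labels)
  pa <- plogis(signal + rnorm(n, sd = 0.8))
  pb <- plogis(signal + rnorm(n, sd = 1.6))
  vd <- delongTest(pa, pb, labels)$varDiff
  boots <- replicate(2000, {
    ix <- sample.int(n, replace = TRUE)
    if (length(unique(labels[ix])) < 2) return(NA_real_)
    rocAuc(pa[ix], labels[ix]) - rocAuc(pb[ix], labels[ix])
  })
  expect_lt(abs(vd - var(boots, na.rm = TRUE)) / var(boots, na.rm = TRUE), 0.15)
})

test_that("DeLong agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  labels <- rbinom(80, 1, 0.35)
  pa <- plogis(rnorm(80, labels))
  pb <- plogis(rnorm(80, 0.5 * labels))
  mine <- delongTest(pa, pb, labels)
  ref <- pROC::roc.test(pROC::roc(labels, pa, quiet = TRUE),
                        pROC::roc(labels, pb, quiet = TRUE),
                        method = "delong")
  expect_equal(abs(mine$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brierScore(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brierScore(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  expect_equal(brierScore(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_error(brierScore(c(1.2, 0.4), c(1, 0)), "\\[0, 1\\]")
})

test_that("net benefit matches closed forms and hand enumeration", {
  set.seed(51)
  labels <- rbinom(200, 1, 0.3)
  probs <- runif(200)
  dc <- decisionCurve(probs, labels)
  prev <- mean(labels)
  expect_equal(dc$treatNone, rep(0, nrow(dc)))
  expect_equal(dc$treatAll,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold),
               tolerance = 1e-12)
  # perfect probabilities: NB(t) = prevalence at every threshold
  expect_equal(decisionCurve(as.numeric(labels), labels)$model,
               rep(prev, 99), tolerance = 1e-12)
  # 10-record hand enumeration at t = 0.5
  lab10 <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)
  p10 <- c(0.9, 0.6, 0.3, 0.7, 0.2, 0.1, 0.55, 0.5, 0.4, 0.05)
  # treated: p >= 0.5 -> records 1,2,4,7,8: TP = 3, FP = 2
  nb <- decisionCurve(p10, lab10, thresholds = 0.5)$model
  expect_equal(nb, 3 / 10 - 2 / 10 * 0.5 / 0.5, tolerance = 1e-12)
  expect_error(decisionCurve(probs, labels, thresholds = c(0.5, 1)),
               "strictly inside")
})

test_that("cohort summaries use chi-square and Welch t-test", {
  d <- syntheticClinical(80, seed = 3)
  s <- summarizeCohorts(list(a = d, b = d))
  # identical cohorts: chi-square statistic 0, p = 1
  expect_equal(s$betweenCohorts$statistic[s$betweenCohorts$variable == "t_stage"],
               0, tolerance = 1e-12)
  expect_equal(s$betweenCohorts$p[s$betweenCohorts$variable == "age_cat"], 1)
  # hand-computed 2x2 chi-square without continuity correction
  d1 <- data.frame(patient_id = 1:30, age_cat = rep(c(0, 1), c(10, 20)),
                   t_stage = 0, stilc = 1,
                   til_score = seq(0.1, 0.3, length.out = 30),
                   lnm = rep(c(0, 1), 15))
  d2 <- data.frame(patient_id = 1:30, age_cat = rep(c(0, 1), c(20, 10)),
                   t_stage = 0, stilc = 1,
                   til_score = seq(0.15, 0.35, length.out = 30),
                   lnm = rep(c(0, 1), 15))
  s2 <- summarizeCohorts(list(a = d1, b = d2))
  o <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(s2$betweenCohorts$statistic[
    s2$betweenCohorts$variable == "age_cat"], sum((o - e)^2 / e))
  expect_error(summarizeCohorts(list(a = d1, b = d1[0, ])), "empty")
})
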