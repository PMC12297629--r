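#' Archetype specification for synthetic TIL lattices
#'
#' Two archetypes emulate the dichotomy seen in real hot spot maps: a
#' TIL-cold pattern (sparse positives, short-range clumping) and a TIL-hot
#' pattern (dense positives concentrated in large patches). Density and
#' clustering are controlled independently: \code{targetPosFraction} fixes
#' the share of TIL-positive tissue patches, \code{correlationLength} the
#' spatial scale (in patches) of the latent field that places them
#' (1 = independent patches).
#'
#' @param name "cold" or "hot".
#' @param targetPosFraction share of tissue patches that are TIL-positive
#'   (defaults: 0.08 cold, 0.45 hot).
#' @param correlationLength latent-field correlation scale in patches
#'   (defaults: 2 cold, 8 hot).
#' @param necroticRate share of tissue patches relabeled necrotic/other,
#'   default 0.05.
#' @return list of class \code{archetypeSpec}
#' @export
archetypeSpec <- function(name = c("cold", "hot"),
                          targetPosFraction = NULL,
                          correlationLength = NULL,
                          necroticRate = 0.05) {
  name <- match.arg(name)
  if (is.null(targetPosFraction))
    targetPosFraction <- if (name == "cold") 0.08 else 0.45
  if (is.null(correlationLength))
    correlationLength <- if (name == "cold") 2 else 8
  stopifnot(targetPosFraction > 0, targetPosFraction < 1,
            correlationLength >= 1, necroticRate >= 0, necroticRate < 1)
  structure(list(name = name, targetPosFraction = targetPosFraction,
                 correlationLength = correlationLength,
                 necroticRate = necroticRate),
            class = "archetypeSpec")
}

#' Generate a connected blob-like tissue mask
#'
#' Grows a union of discs — each new disc centered on a point already inside
#' the mask, so the blob stays connected — until the target fill is reached,
#' then keeps the largest connected component. Deterministic per seed.
#'
#' @param gridSize integer(2), lattice rows x cols (>= 8 each).
#' @param maskFill target fraction of the grid covered, in (0, 1];
#'   1 gives the full rectangle.
#' @param seed integer seed.
#' @return logical matrix gridSize[1] x gridSize[2]
#' @export
generateTissueMask <- function(gridSize = c(48L, 48L), maskFill = 0.6,
                               seed = 1L) {
  stopifnot(length(gridSize) == 2L, all(gridSize >= 8L))
  if (maskFill <= 0 || maskFill > 1)
    stop("maskFill must lie in (0, 1]")
  nr <- gridSize[1]; nc <- gridSize[2]
  if (maskFill >= 0.999) return(matrix(TRUE, nr, nc))
  withSeed(seed, {
    mask <- matrix(FALSE, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    disc <- function(cr, cc, rad) (rows - cr)^2 + (cols - cc)^2 <= rad^2
    rmax <- max(3, min(nr, nc) / 5)
    mask <- mask | disc(nr / 2 + stats::runif(1, -nr / 8, nr / 8),
                        nc / 2 + stats::runif(1, -nc / 8, nc / 8),
                        stats::runif(1, rmax / 2, rmax))
    while (mean(mask) < maskFill) {
      inside <- which(mask)
      pick <- inside[sample.int(length(inside), 1L)]
      mask <- mask | disc(((pick - 1L) %% nr) + 1L,
                          ((pick - 1L) %/% nr) + 1L,
                          stats::runif(1, 2, rmax))
    }
    lab <- EBImage::bwlabel(mask)
    keep <- which.max(tabulate(lab[lab > 0]))
    mask & (lab == keep)
  })
}

# Separable Gaussian smoothing of a matrix with reflection padding.
smoothField <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  g <- stats::dnorm(-half:half, sd = sd)
  g <- g / sum(g)
  reflectIdx <- function(n) {
    ix <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    pmin(pmax(ix, 1L), n)
  }
  convAlong <- function(x) {       # smooth each column of x
    n <- nrow(x)
    xp <- x[reflectIdx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (k in seq_along(g))
      out <- out + g[k] * xp[(k - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(convAlong(t(convAlong(m))))
}

#' Generate a spatially autocorrelated TIL lattice
#'
#' A smooth latent Gaussian field (white noise smoothed at the archetype's
#' correlation length; no smoothing at length 1) is thresholded at the
#' quantile that yields the archetype's target TIL-positive fraction among
#' tissue patches. A uniformly random share of tissue patches is then
#' relabeled necrotic/other; the remainder is TIL-negative. Because necrosis
#' is uniform, the TIL score of the result concentrates on the target
#' fraction.
#'
#' @param mask logical tissue mask from [generateTissueMask()].
#' @param archetype an [archetypeSpec()].
#' @param seed integer seed.
#' @param slideId,patientId identifiers for the resulting grid.
#' @return a [PatchGrid-class]
#' @export
generateTILLattice <- function(mask, archetype = archetypeSpec("cold"),
                               seed = 1L, slideId = "synthetic",
                               patientId = slideId) {
  nTissue <- sum(mask)
  if (nTissue == 0L) stop("tissue mask is empty")
  if (nTissue * archetype$targetPosFraction < 1)
    stop("target TIL-positive fraction unreachable: mask too small")
  withSeed(seed, {
    latent <- matrix(stats::rnorm(length(mask)), nrow(mask), ncol(mask))
    # kernel sd = len/3 makes the field autocorrelation ~0.1 at lag len:
    # patches within the correlation length are related, beyond it not
    if (archetype$correlationLength > 1)
      latent <- smoothField(latent, sd = archetype$correlationLength / 3)
    vals <- latent[mask]
    thr <- stats::quantile(vals, 1 - archetype$targetPosFraction,
                           type = 7, names = FALSE)
    lab <- ifelse(vals > thr, "TIL_POS", "TIL_NEG")
    nNec <- round(archetype$necroticRate * nTissue)
    if (nNec > 0L)
      lab[sample.int(nTissue, nNec)] <- "NECROTIC_OTHER"
    pos <- which(mask, arr.ind = TRUE)
    PatchGrid(slideId, patientId,
              row = pos[, 1] - 1L, col = pos[, 2] - 1L, label = lab,
              nRows = nrow(mask), nCols = ncol(mask))
  })
}

#' Cohort specification for the synthetic study population
#'
#' Defines a cohort whose lymph-node-metastasis outcome depends
#' logistically on T stage, age category, TIL score and spatial archetype:
#' \deqn{logit P(LNM) = \beta_0 + \beta_T T + \beta_{age} A +
#'   \beta_s \cdot tilScore + \beta_c \cdot 1[cold]}
#' The default coefficients (-1.0, 0.6, 0.1, -3.0, 0.7) make low TIL scores
#' and the cold archetype risk factors — a detectable but unsaturated
#' advantage for the TIL-augmented model. Covariate marginals default to
#' age (<45, 45-65, >65) = (0.05, 0.47, 0.48) and T stage (T1..T4) =
#' (0.35, 0.45, 0.13, 0.07).
#'
#' @param nPatients cohort size (>= 20).
#' @param archetypeMixture named numeric(2) cold/hot probabilities
#'   summing to 1, default 0.5/0.5.
#' @param gridSize lattice dimensions, default 48 x 48.
#' @param maskFill tissue fill of the mask, default 0.6.
#' @param beta0,betaT,betaAge,betaS,betaC outcome coefficients.
#' @param ageMarginals,tMarginals covariate category probabilities.
#' @param necroticRate necrotic share of tissue patches, default 0.05.
#' @param seed integer master seed.
#' @return list of class \code{cohortSpec}
#' @export
cohortSpec <- function(nPatients = 500L,
                       archetypeMixture = c(cold = 0.5, hot = 0.5),
                       gridSize = c(48L, 48L), maskFill = 0.6,
                       beta0 = -1.0, betaT = 0.6, betaAge = 0.1,
                       betaS = -3.0, betaC = 0.7,
                       ageMarginals = c(0.05, 0.47, 0.48),
                       tMarginals = c(0.35, 0.45, 0.13, 0.07),
                       necroticRate = 0.05, seed = 1L) {
  stopifnot(abs(sum(archetypeMixture) - 1) < 1e-9,
            abs(sum(ageMarginals) - 1) < 1e-9,
            abs(sum(tMarginals) - 1) < 1e-9)
  if (nPatients < 20L)
    stop("nPatients must be >= 20 (downstream splits undefined below that)")
  structure(as.list(environment()), class = "cohortSpec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each patient: an archetype is drawn from the mixture, a tissue mask
#' and TIL lattice are generated, the true TIL score is computed from the
#' lattice, age and T stage are drawn from their marginals, and the LNM
#' outcome is drawn from the logistic model of [cohortSpec()]. The clinical
#' table carries the ground-truth spatial class as \code{stilc}
#' (cold = 1, hot = 2); the pipeline's clustering stage recomputes it from
#' the images. Fully deterministic per seed.
#'
#' @param spec a [cohortSpec()].
#' @return list with \code{grids} (named list of [PatchGrid-class]),
#'   \code{clinical} (data.frame \code{patient_id, age_cat, t_stage,
#'   til_score, stilc, lnm}), \code{truth} (data.frame \code{patient_id,
#'   archetype, linear_predictor, true_til_score})
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  arch <- list(cold = archetypeSpec("cold", necroticRate = spec$necroticRate),
               hot = archetypeSpec("hot", necroticRate = spec$necroticRate))
  withSeed(spec$seed, {
    archetypes <- sample(names(spec$archetypeMixture), spec$nPatients,
                         replace = TRUE, prob = spec$archetypeMixture)
    age <- sample(0:2, spec$nPatients, replace = TRUE, prob = spec$ageMarginals)
    tstage <- sample(0:3, spec$nPatients, replace = TRUE, prob = spec$tMarginals)
    u <- stats::runif(spec$nPatients)
    grids <- vector("list", spec$nPatients)
    til <- numeric(spec$nPatients)
    for (i in seq_len(spec$nPatients)) {
      pid <- sprintf("P%04d", i)
      mask <- generateTissueMask(spec$gridSize, spec$maskFill,
                                 seed = deriveSeed(spec$seed, 2L * i))
      grids[[i]] <- generateTILLattice(mask, arch[[archetypes[i]]],
                                       seed = deriveSeed(spec$seed, 2L * i + 1L),
                                       slideId = pid, patientId = pid)
      til[i] <- scoreValue(computeTILScore(grids[[i]]))
    }
    lp <- spec$beta0 + spec$betaT * tstage + spec$betaAge * age +
      spec$betaS * til + spec$betaC * (archetypes == "cold")
    lnm <- as.integer(u < stats::plogis(lp))
    ids <- sprintf("P%04d", seq_len(spec$nPatients))
    names(grids) <- ids
    list(grids = grids,
         clinical = data.frame(
           patient_id = ids, age_cat = age, t_stage = tstage,
           til_score = til,
           stilc = ifelse(archetypes == "cold", 1L, 2L),
           lnm = lnm),
         truth = data.frame(
           patient_id = ids, archetype = archetypes,
           linear_predictor = lp, true_til_score = til))
  })
}

#' Write a synthetic cohort to the pipeline's CSV formats
#'
#' Emits the patch table (parseable by [readPatchTable()]), the clinical
#' cohort table and the ground-truth table.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if missing).
#' @param cohortName value of the \code{cohort} column in the clinical CSV.
#' @return named character vector of the three file paths, invisibly
#' @export
writeCohortCSV <- function(cohort, dir, cohortName = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patches = file.path(dir, "patch_table.csv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.csv"))
  writePatchTable(cohort$grids, paths[["patches"]])
  cl <- cohort$clinical
  cl$cohort <- cohortName
  utils::write.csv(cl, paths[["clinical"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
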