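#' Binarize a TIL map for hot spot analysis
#'
#' TIL-positive patches get value 1; TIL-negative and necrotic/other patches
#' get 0. Background (absent coordinates) stays absent — the binary field is
#' defined over tissue patches only.
#'
#' @param grid a [PatchGrid-class]
#' @return integer vector of 0/1 values aligned with \code{patches(grid)}
#' @export
binarizeTILMap <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  as.integer(grid@patches$label == "TIL_POS")
}

#' Build binary contiguity weights on a masked patch lattice
#'
#' Neighbors are taken among the tissue patches present in the grid only:
#' background never contributes a weight. Queen contiguity uses the 8
#' surrounding lattice cells, rook the 4 orthogonal ones. With
#' \code{includeSelf = TRUE} (the default) each patch is its own neighbor
#' with weight 1, which is what turns the Getis-Ord Gi statistic into Gi*.
#'
#' @param grid a [PatchGrid-class]
#' @param scheme "queen" (default) or "rook"
#' @param includeSelf logical, add w_ii = 1 (default TRUE)
#' @return a [SpatialWeights-class]
#' @export
buildLatticeWeights <- function(grid, scheme = c("queen", "rook"),
                                includeSelf = TRUE) {
  stopifnot(is(grid, "PatchGrid"))
  scheme <- match.arg(scheme)
  p <- grid@patches
  n <- nrow(p)
  # index lookup on the full lattice; 0 = background
  idx <- matrix(0L, grid@nRows, grid@nCols)
  idx[cbind(p$row + 1L, p$col + 1L)] <- seq_len(n)
  offs <- if (scheme == "queen") {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  nbrMat <- matrix(0L, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r <- p$row + 1L + offs[k, "dr"]
    c <- p$col + 1L + offs[k, "dc"]
    ok <- r >= 1L & r <= grid@nRows & c >= 1L & c <= grid@nCols
    nbrMat[ok, k] <- idx[cbind(r[ok], c[ok])]
  }
  neighbors <- lapply(seq_len(n), function(i) {
    nb <- nbrMat[i, ]
    nb <- nb[nb > 0L]
    if (includeSelf) nb <- c(i, nb)
    nb
  })
  new("SpatialWeights", n = n, neighbors = neighbors,
      weights = lapply(neighbors, function(nb) rep(1, length(nb))),
      scheme = scheme, includeSelf = includeSelf)
}

#' Local Getis-Ord Gi* statistics on a masked lattice
#'
#' For each tissue patch i the statistic compares the weighted sum of the
#' binary TIL field over i's neighborhood (including i itself under the
#' starred convention) with what a spatially random field of the same mean
#' would give:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{x} W_i}
#'   {S \sqrt{(n U_i - W_i^2)/(n - 1)}}}
#' with \eqn{W_i = \sum_j w_{ij}}, \eqn{U_i = \sum_j w_{ij}^2},
#' \eqn{\bar{x}} the mean and \eqn{S} the population standard deviation of
#' the field over the n tissue patches. Positive z marks local enrichment in
#' TIL-positive patches (a hot spot), negative z depletion (a cold spot).
#'
#' A constant field (S = 0) has no spatial signal: all z are set to 0 and
#' the map is flagged degenerate rather than erroring, so cohort pipelines
#' survive rare all-negative slides. A patch whose individual denominator
#' vanishes (e.g. its neighborhood is the whole lattice) also gets z = 0.
#'
#' @param grid a [PatchGrid-class] (the binary field is taken via
#'   [binarizeTILMap()]), or \code{NULL} when \code{x} and \code{weights}
#'   are supplied directly.
#' @param weights a [SpatialWeights-class]; built with defaults
#'   (queen, self-inclusive) from \code{grid} when missing.
#' @param x optional binary/numeric field overriding the grid's.
#' @param hotThreshold z cutoff stored on the map (default 1.96, the
#'   two-sided 5\% point of the normal approximation).
#' @return a [HotspotMap-class]
#' @export
localGiStar <- function(grid, weights = NULL, x = NULL, hotThreshold = 1.96) {
  if (is.null(weights)) weights <- buildLatticeWeights(grid)
  if (is.null(x)) x <- binarizeTILMap(grid)
  n <- weights@n
  if (length(x) != n) stop("field length must equal the number of patches")
  if (n < 2L) stop("Gi* requires at least 2 tissue patches")
  x <- as.numeric(x)
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)
  lag <- vapply(seq_len(n), function(i)
    sum(weights@weights[[i]] * x[weights@neighbors[[i]]]), numeric(1))
  Wi <- vapply(weights@weights, sum, numeric(1))
  Ui <- vapply(weights@weights, function(w) sum(w^2), numeric(1))
  degenerate <- S == 0
  if (degenerate) {
    z <- rep(0, n)
  } else {
    denom <- S * sqrt(pmax(n * Ui - Wi^2, 0) / (n - 1))
    z <- ifelse(denom == 0, 0, (lag - xbar * Wi) / denom)
  }
  co <- as.matrix(grid@patches[, c("row", "col")])
  colnames(co) <- c("row", "col")
  new("HotspotMap", slideId = grid@slideId,
      nRows = grid@nRows, nCols = grid@nCols,
      coords = co, z = z, hotThreshold = hotThreshold,
      degenerate = degenerate)
}

#' Write a Gi* z-score table
#'
#' @param hmap a [HotspotMap-class]
#' @param path output CSV path with columns \code{slide_id,row,col,z,hot}
#'   (\code{hot} is 1 when z reaches the map's hot threshold).
#' @return the table, invisibly.
#' @export
writeGiTable <- function(hmap, path) {
  tab <- data.frame(slide_id = hmap@slideId,
                    row = hmap@coords[, "row"], col = hmap@coords[, "col"],
                    z = hmap@z,
                    hot = as.integer(hmap@z >= hmap@hotThreshold))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Render a hot spot map as an RGB image
#'
#' Each tissue patch is drawn as a \code{blockPx} x \code{blockPx} square
#' colored on a diverging blue-white-red scale: z is clipped to
#' \code{[-clip, clip]}, z = 0 maps to white, positive z shades toward red
#' (hot), negative toward blue (cold). Background is white. Rendering is
#' deterministic, so identical z fields give byte-identical images.
#'
#' @param hmap a [HotspotMap-class]
#' @param blockPx pixels per patch edge (default 8)
#' @param clip absolute z at which the color saturates (default 4)
#' @return numeric array height x width x 3 with values in [0, 1]
#' @export
renderHotspotMap <- function(hmap, blockPx = 8L, clip = 4) {
  stopifnot(is(hmap, "HotspotMap"), blockPx >= 1L, clip > 0)
  H <- hmap@nRows * blockPx
  W <- hmap@nCols * blockPx
  img <- array(1, dim = c(H, W, 3))
  t <- pmin(pmax(hmap@z, -clip), clip) / clip
  # white -> red for t > 0, white -> blue for t < 0
  rc <- ifelse(t >= 0, 1, 1 + t)
  gc <- 1 - abs(t)
  bc <- ifelse(t >= 0, 1 - t, 1)
  for (i in seq_along(t)) {
    rr <- hmap@coords[i, "row"] * blockPx + seq_len(blockPx)
    cc <- hmap@coords[i, "col"] * blockPx + seq_len(blockPx)
    img[rr, cc, 1] <- rc[i]
    img[rr, cc, 2] <- gc[i]
    img[rr, cc, 3] <- bc[i]
  }
  img
}

#' Write a rendered hot spot map to a PNG file
#'
#' @param img array from [renderHotspotMap()]
#' @param path output PNG path (8-bit RGB)
#' @return \code{path}, invisibly
#' @export
writeHotspotPNG <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
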