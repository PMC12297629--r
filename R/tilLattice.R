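#' Construct a PatchGrid from patch coordinates and labels
#'
#' @param slideId,patientId identifiers for the slide and its patient.
#' @param row,col integer vectors of 0-based patch coordinates.
#' @param label character vector of labels; case and surrounding whitespace
#'   are ignored, but anything other than \code{TIL_POS}, \code{TIL_NEG} or
#'   \code{NECROTIC_OTHER} is an error (background tissue is encoded by
#'   absence, never by a label).
#' @param nRows,nCols lattice dimensions; inferred as max coordinate + 1
#'   when \code{NULL}. Declaring them larger preserves empty margins for
#'   rendering.
#' @param patchSizePx,magnification metadata carried through to outputs.
#' @return a [PatchGrid-class]
#' @examples
#' g <- PatchGrid("s1", "p1", row = c(0, 0, 1), col = c(0, 1, 0),
#'                label = c("TIL_POS", "TIL_NEG", "NECROTIC_OTHER"))
#' computeTILScore(g)
#' @export
PatchGrid <- function(slideId, patientId, row, col, label,
                      nRows = NULL, nCols = NULL,
                      patchSizePx = 150L, magnification = "20x") {
  if (length(row) == 0L)
    stop("empty grids are not allowed: at least one patch required")
  lab <- canonicalLabel(label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1L]
    stop("unknown patch label '", label[bad], "' at patch ", bad,
         " of slide ", slideId)
  }
  if (is.null(nRows)) nRows <- max(row) + 1L
  if (is.null(nCols)) nCols <- max(col) + 1L
  new("PatchGrid",
      slideId = as.character(slideId), patientId = as.character(patientId),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      patches = data.frame(row = as.integer(row), col = as.integer(col),
                           label = factor(lab, levels = TIL_LABELS)),
      patchSizePx = as.integer(patchSizePx),
      magnification = as.character(magnification))
}

#' Read a patch-label table into PatchGrid objects
#'
#' The table is the output contract of an upstream patch classifier: a CSV
#' with header \code{slide_id,patient_id,row,col,label}, one row per tissue
#' patch. Non-tissue background never appears in the table. One
#' \code{PatchGrid} is returned per distinct \code{slide_id}.
#'
#' @param path path to the CSV file.
#' @param dims optional named list \code{slide_id -> c(nRows, nCols)}
#'   overriding the max-coordinate + 1 inference.
#' @return named list of [PatchGrid-class] objects, keyed by slide id.
#' @details Labels are matched case-insensitively after trimming whitespace;
#'   an unknown label or a duplicated \code{(slide_id, row, col)} triple
#'   aborts with the offending row number.
#' @export
readPatchTable <- function(path, dims = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "patient_id", "row", "col", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("patch table is missing columns: ", paste(miss, collapse = ", "))
  lab <- canonicalLabel(tab$label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1L]
    stop("unknown label '", tab$label[bad], "' in row ", bad, " of ", path)
  }
  dup <- duplicated(tab[, c("slide_id", "row", "col")])
  if (any(dup))
    stop("duplicate (slide_id, row, col) in row ", which(dup)[1L], " of ", path)
  tab$label <- lab
  out <- lapply(split(tab, tab$slide_id), function(s) {
    d <- dims[[s$slide_id[1L]]]
    PatchGrid(s$slide_id[1L], s$patient_id[1L], s$row, s$col, s$label,
              nRows = d[1L], nCols = d[2L])
  })
  out[unique(tab$slide_id)]
}

#' Write PatchGrid objects back to the patch-table CSV format
#'
#' Round-trips with [readPatchTable()] bit-identically for canonical label
#' spellings.
#'
#' @param grids list of [PatchGrid-class] objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePatchTable <- function(grids, path) {
  if (is(grids, "PatchGrid")) grids <- list(grids)
  tab <- do.call(rbind, lapply(grids, function(g) {
    data.frame(slide_id = g@slideId, patient_id = g@patientId,
               row = g@patches$row, col = g@patches$col,
               label = as.character(g@patches$label))
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute the TIL score of a slide
#'
#' The TIL score divides the number of TIL-positive patches by the number of
#' non-necrotic tissue patches (TIL-positive + TIL-negative). Necrotic/other
#' patches are excluded from both numerator and denominator, so adding or
#' removing them never moves the score.
#'
#' @param grid a [PatchGrid-class]
#' @return a [TILScore-class]
#' @export
computeTILScore <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  tab <- table(grid@patches$label)
  nPos <- as.integer(tab[["TIL_POS"]])
  nTissue <- nPos + as.integer(tab[["TIL_NEG"]])
  if (nTissue < 1L)
    stop("no scoreable tissue: slide ", grid@slideId,
         " has only NECROTIC_OTHER patches")
  new("TILScore", value = nPos / nTissue, nPos = nPos, nTissue = nTissue)
}

#' Aggregate per-slide TIL scores to a patient-level score
#'
#' When a patient has several slides, the patient score is the unweighted
#' arithmetic mean of the per-slide score values.
#'
#' @param scores a non-empty list of [TILScore-class] objects (or a numeric
#'   vector of score values).
#' @return numeric(1)
#' @export
aggregatePatientScore <- function(scores) {
  if (length(scores) == 0L) stop("no slide scores to aggregate")
  vals <- if (is.numeric(scores)) scores
          else vapply(scores, scoreValue, numeric(1))
  mean(vals)
}

#' Write a per-slide TIL score table
#'
#' @param grids list of [PatchGrid-class] objects.
#' @param path output CSV path with columns
#'   \code{patient_id,slide_id,til_score,n_pos,n_tissue}.
#' @return the score table data.frame, invisibly.
#' @export
writeScoreTable <- function(grids, path) {
  if (is(grids, "PatchGrid")) grids <- list(grids)
  rows <- lapply(grids, function(g) {
    s <- computeTILScore(g)
    data.frame(patient_id = g@patientId, slide_id = g@slideId,
               til_score = s@value, n_pos = s@nPos, n_tissue = s@nTissue)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
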