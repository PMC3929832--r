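#' @include AllClasses.R
NULL

# 1-based linear index of voxel coordinates in column-major storage
linearIndex <- function(coords, dims) {
  (coords[, 3L] - 1L) * dims[1L] * dims[2L] +
    (coords[, 2L] - 1L) * dims[1L] + coords[, 1L]
}

# Evaluate expr with a fixed RNG state, restoring the caller's stream after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed, kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% .Machine$integer.max)
}

#' Number of voxel-as-feature entries of a volume grid
#'
#' The voxel-as-feature representation assigns one feature per voxel before
#' any tissue masking, so a grid of dims (nx, ny, nz) contributes
#' nx * ny * nz features (2,122,945 for the standard 121 x 145 x 121
#' normalized-space grid at 1.5 mm).
#'
#' @param x a [SegmentedVolume-class] or an integer length-3 dims vector.
#' @return integer feature count.
#' @examples
#' vafFeatureCount(c(121L, 145L, 121L))
#' @export
vafFeatureCount <- function(x) {
  d <- if (is(x, "SegmentedVolume")) dim(x@data) else as.integer(x)
  stopifnot(length(d) == 3L, all(d >= 1L))
  as.integer(prod(d))
}

#' Dice overlap between two voxel masks
#'
#' Dice coefficient 2|A n B| / (|A| + |B|), used to score recovered ROI
#' masks against a planted truth mask.
#'
#' @param a,b logical arrays of identical dims, or [SelectionMask-class]
#'   objects (rendered through their voxel maps).
#' @return numeric in \[0, 1\]; `NaN` when both masks are empty.
#' @export
diceOverlap <- function(a, b) {
  if (is(a, "SelectionMask")) a <- maskAsVolume(a)
  if (is(b, "SelectionMask")) b <- maskAsVolume(b)
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Render a SelectionMask as a boolean volume
#'
#' @param mask a [SelectionMask-class].
#' @return logical 3-D array with `TRUE` at the selected voxels.
#' @export
maskAsVolume <- function(mask) {
  stopifnot(is(mask, "SelectionMask"))
  vol <- array(FALSE, mask@dims)
  if (length(mask@featureIndices)) {
    sel <- mask@voxelMap[mask@featureIndices, , drop = FALSE]
    vol[linearIndex(sel, mask@dims)] <- TRUE
  }
  vol
}
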