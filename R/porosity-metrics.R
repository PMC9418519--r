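# Scalar and distributional porosity quantities: global porosity, pore
# volume distribution Prob(v), equivalent sizes, axial profiles.

#' Porosity (pore volume fraction)
#'
#' Exact ratio between pore voxels and total voxels, optionally within a
#' mask.
#'
#' @param binary a [BinaryVolume-class]
#' @param mask optional logical array of the same shape restricting the
#'   computation; must contain at least one voxel
#' @return fraction between 0 and 1
#' @export
porosityFraction <- function(binary, mask = NULL) {
  stopifnot(is(binary, "BinaryVolume"))
  a <- voxelData(binary)
  if (is.null(mask)) return(mean(a))
  if (!identical(dim(mask), dim(a)))
    stop("mask shape does not match volume", call. = FALSE)
  n <- sum(mask)
  if (n == 0) stop("mask is empty", call. = FALSE)
  sum(a & mask) / n
}

#' PoreVolumeDistribution: per-pore volumes and their density Prob(v)
#'
#' @slot volumes per-pore volumes (nm^3), one per label
#' @slot breaks logarithmic bin edges (nm^3), 10 bins per decade
#' @slot density probability density over the bins (1/nm^3)
#' @slot counts pores per bin
#' @export
setClass("PoreVolumeDistribution",
  representation(volumes = "numeric", breaks = "numeric",
                 density = "numeric", counts = "integer")
)

setMethod("show", "PoreVolumeDistribution", function(object) {
  n <- length(object@volumes)
  cat(sprintf("PoreVolumeDistribution: %d pores, v in [%.3g, %.3g] nm^3\n",
              n, if (n) min(object@volumes) else NA,
              if (n) max(object@volumes) else NA))
})

#' Pore volume distribution Prob(v)
#'
#' Per-pore volumes v = voxel count x voxelSize^3, with a probability
#' density over logarithmic bins (10 per decade), making no assumption on
#' pore shapes. The density integrates to 1 over its support.
#'
#' @param labels a [LabeledVolume-class] with K >= 1 (K = 0 gives an empty
#'   distribution with a warning)
#' @return a [PoreVolumeDistribution-class]
#' @export
poreVolumeDistribution <- function(labels) {
  stopifnot(is(labels, "LabeledVolume"))
  K <- nLabels(labels)
  h <- voxelSize(labels)
  if (K == 0L) {
    warning("no labels: empty pore volume distribution")
    return(new("PoreVolumeDistribution", volumes = numeric(0),
               breaks = numeric(0), density = numeric(0),
               counts = integer(0)))
  }
  cnt <- tabulate(voxelData(labels), K)
  v <- cnt * h^3
  lo <- floor(log10(min(v)) * 10) / 10
  hi <- ceiling(log10(max(v)) * 10) / 10
  if (hi <= lo) hi <- lo + 0.1
  breaks <- 10^seq(lo, hi, by = 0.1)  # 10 bins per decade
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     length(breaks) - 1L)
  widths <- diff(breaks)
  density <- counts / (sum(counts) * widths)
  new("PoreVolumeDistribution", volumes = v, breaks = breaks,
      density = density, counts = as.integer(counts))
}

#' Equivalent pore size from volume
#'
#' Characteristic size of a pore of volume v, defined as v^(1/3).
#'
#' @param v pore volume(s), nm^3, > 0
#' @return length(s) in nm
#' @examples
#' equivalentSize(1000)  # 10 nm
#' @export
equivalentSize <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop("pore volume must be positive", call. = FALSE)
  v^(1 / 3)
}

#' Per-slice solid fraction along an axis
#'
#' One value per slice, the fraction of solid (non-pore) voxels; the
#' substrate for layer-boundary detection.
#'
#' @param binary a [BinaryVolume-class]
#' @param axis slicing axis ("y", "x" or "z")
#' @return numeric vector, one value between 0 and 1 per slice
#' @export
solidFractionProfile <- function(binary, axis = "z") {
  stopifnot(is(binary, "BinaryVolume"))
  a <- voxelData(binary)
  d <- dim(a)
  ai <- axisIndex(axis)
  poreMean <- switch(ai,
    rowMeans(matrix(a, d[1], d[2] * d[3])),
    colMeans(matrix(aperm(a, c(1, 3, 2)), d[1] * d[3], d[2])),
    colMeans(matrix(a, d[1] * d[2], d[3]))
  )
  1 - poreMean
}
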