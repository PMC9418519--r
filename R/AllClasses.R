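#' GridSpec: physical sampling grid of a voxel volume
#'
#' Describes the discrete sampling of a 3D volume: array extents, the
#' physical voxel edge length in nanometres, and the (0-based) voxel offset
#' of the lower corner relative to the original acquisition, used to track
#' provenance through crops.
#'
#' Volumes are stored as R arrays with `dim = c(y, x, z)`: a slice
#' `[, , k]` is an image matrix and `z` (the third dimension) is the
#' slicing/projection axis by default. All operations that depend on a
#' direction take an explicit `axis` argument (`"y"`, `"x"` or `"z"`).
#'
#' @slot shape integer(3), array extents (y, x, z); all >= 1
#' @slot voxelSize numeric(1), voxel edge length in nm; > 0
#' @slot origin integer(3), 0-based voxel offset of the lower corner
#' @export
setClass("GridSpec",
  representation(shape = "integer", voxelSize = "numeric", origin = "integer"),
  prototype(shape = c(1L, 1L, 1L), voxelSize = 1, origin = c(0L, 0L, 0L))
)

setValidity("GridSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three extents >= 1")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number (nm)")
  if (length(object@origin) != 3L)
    return("origin must be an integer triple")
  TRUE
})

#' @rdname GridSpec-class
#' @param shape integer(3) array extents (y, x, z)
#' @param voxelSize voxel edge length in nm
#' @param origin 0-based offset of the lower corner (provenance)
#' @return a `GridSpec`
#' @examples
#' gridSpec(c(64, 64, 64), voxelSize = 1)
#' @export
gridSpec <- function(shape, voxelSize, origin = c(0L, 0L, 0L)) {
  new("GridSpec", shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
      origin = as.integer(origin))
}

#' VoxelVolume: a 3D scalar grid with physical metadata
#'
#' The common container for raw grayscale reconstructions, segmented binary
#' volumes and labelled volumes. The `semantics` flag records how voxel
#' values are to be read: `"grayscale"` (arbitrary intensities),
#' `"binary"` (`TRUE` = pore/void, following the convention that black
#' voxels are void), or `"labels"` (0 = solid, k >= 1 = pore object k).
#'
#' @slot data 3D array of voxel values
#' @slot grid [GridSpec-class] physical sampling
#' @slot semantics one of "grayscale", "binary", "labels"
#' @export
setClass("VoxelVolume",
  representation(data = "array", grid = "GridSpec", semantics = "character")
)

setValidity("VoxelVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (!identical(as.integer(dim(object@data)), object@grid@shape))
    return("grid shape does not match data dimensions")
  if (!object@semantics %in% c("grayscale", "binary", "labels"))
    return("semantics must be grayscale, binary or labels")
  TRUE
})

#' BinaryVolume: phase-segmented volume (TRUE = pore/void)
#'
#' @export
setClass("BinaryVolume", contains = "VoxelVolume")

setValidity("BinaryVolume", function(object) {
  if (!is.logical(object@data)) return("binary data must be logical")
  if (anyNA(object@data)) return("binary data must not contain NA")
  TRUE
})

#' LabeledVolume: watershed/component-labelled pore objects
#'
#' Voxel value 0 marks solid; values 1..K mark pore objects. The label set
#' is contiguous and the union of all labels equals the pore phase of the
#' binary volume the labelling was derived from.
#'
#' @slot nLabels number of labels K
#' @export
setClass("LabeledVolume", contains = "VoxelVolume",
  representation(nLabels = "integer")
)

setValidity("LabeledVolume", function(object) {
  if (!is.integer(object@data)) return("label data must be integer")
  if (length(object@nLabels) != 1L || object@nLabels < 0L)
    return("nLabels must be a single non-negative integer")
  TRUE
})

#' @rdname VoxelVolume-class
#' @param data 3D array
#' @param voxelSize voxel edge length (nm)
#' @param semantics value semantics flag
#' @param origin 0-based lower-corner offset
#' @export
VoxelVolume <- function(data, voxelSize, semantics = "grayscale",
                        origin = c(0L, 0L, 0L)) {
  new("VoxelVolume", data = data,
      grid = gridSpec(dim(data), voxelSize, origin), semantics = semantics)
}

#' @rdname BinaryVolume-class
#' @param data 3D logical array, TRUE = pore
#' @param voxelSize voxel edge length (nm)
#' @param origin 0-based lower-corner offset
#' @export
BinaryVolume <- function(data, voxelSize, origin = c(0L, 0L, 0L)) {
  storage.mode(data) <- "logical"
  new("BinaryVolume", data = data,
      grid = gridSpec(dim(data), voxelSize, origin), semantics = "binary")
}

#' @rdname LabeledVolume-class
#' @param data 3D integer array, 0 = solid
#' @param voxelSize voxel edge length (nm)
#' @param nLabels number of labels (defaults to max(data))
#' @param origin 0-based lower-corner offset
#' @export
LabeledVolume <- function(data, voxelSize, nLabels = NULL,
                          origin = c(0L, 0L, 0L)) {
  storage.mode(data) <- "integer"
  if (is.null(nLabels)) nLabels <- max(0L, data)
  new("LabeledVolume", data = data,
      grid = gridSpec(dim(data), voxelSize, origin), semantics = "labels",
      nLabels = as.integer(nLabels))
}

#' ChordDistribution: chord-length statistics of one phase
#'
#' Maximal same-phase runs along a set of rays. `lengths` holds the raw
#' chord lengths (nm); the histogram is a probability density over length
#' bins; the first moment is the mean of the raw lengths, not of bin
#' midpoints.
#'
#' @slot phase "pore" or "solid"
#' @slot directions description of the ray set used
#' @slot lengths raw chord lengths (nm)
#' @slot breaks histogram bin edges (nm)
#' @slot density probability density per bin (1/nm)
#' @slot counts chords per bin
#' @export
setClass("ChordDistribution",
  representation(phase = "character", directions = "character",
                 lengths = "numeric", breaks = "numeric",
                 density = "numeric", counts = "integer")
)

#' Projection: 2D pore-count projection of a volume
#'
#' @slot data 2D grid of pore-voxel counts along the projection axis
#' @slot pixelSize pixel edge (nm)
#' @slot axis projection axis ("y", "x" or "z")
#' @slot depth number of voxels integrated along the axis
#' @export
setClass("Projection",
  representation(data = "matrix", pixelSize = "numeric", axis = "character",
                 depth = "integer")
)

#' SpectralDensity2D: 2D power spectrum of a projection
#'
#' `I(qx, qy)` with the convention q = 2 pi times spatial frequency; the
#' grid is centred (zero frequency in the middle).
#'
#' @slot I 2D intensity grid (rows = qy, columns = qx)
#' @slot qy,qx frequency axes (nm^-1)
#' @slot meanSubtracted,windowed preprocessing flags
#' @export
setClass("SpectralDensity2D",
  representation(I = "matrix", qy = "numeric", qx = "numeric",
                 meanSubtracted = "logical", windowed = "logical")
)

#' AzimuthalProfile: sector-averaged 1D scattering curve
#'
#' @slot direction "qx" or "qy"
#' @slot halfAngle sector half-angle (degrees)
#' @slot q radial bin centres (nm^-1)
#' @slot I mean intensity per bin (NA where the sector bin is empty)
#' @slot n pixels per bin
#' @export
setClass("AzimuthalProfile",
  representation(direction = "character", halfAngle = "numeric",
                 q = "numeric", I = "numeric", n = "integer")
)

#' LayerModel: axial layering of a three-layer valve unit
#'
#' Boundaries are fractional slice positions along the layer axis
#' (0-based, so a boundary at b separates slices floor(b) and floor(b)+1);
#' thicknesses in nm; porosity per layer from exact voxel counts.
#'
#' @slot axis layer axis
#' @slot boundaries strictly increasing fractional slice positions
#' @slot names layer names, bottom to top
#' @slot thickness per-layer thickness (nm)
#' @slot porosity per-layer pore fraction
#' @slot profile the solid-fraction profile the model was fitted to
#' @export
setClass("LayerModel",
  representation(axis = "character", boundaries = "numeric",
                 names = "character", thickness = "numeric",
                 porosity = "numeric", profile = "numeric")
)

setValidity("LayerModel", function(object) {
  if (is.unsorted(object@boundaries, strictly = TRUE))
    return("boundaries must be strictly increasing")
  if (length(object@names) != length(object@boundaries) + 1L)
    return("need one more layer name than boundaries")
  TRUE
})
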