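#' @describeIn frustule3d-generics raw voxel array of a volume
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' @describeIn frustule3d-generics voxel edge length (nm)
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@grid@voxelSize)

#' @describeIn frustule3d-generics voxel size stored in a GridSpec
#' @export
setMethod("voxelSize", "GridSpec", function(x) x@voxelSize)

#' @describeIn frustule3d-generics array extents (y, x, z)
#' @export
setMethod("gridShape", "VoxelVolume", function(x) x@grid@shape)

#' @describeIn frustule3d-generics extents of a GridSpec
#' @export
setMethod("gridShape", "GridSpec", function(x) x@shape)

#' @describeIn frustule3d-generics value semantics flag
#' @export
setMethod("semantics", "VoxelVolume", function(x) x@semantics)

#' @describeIn frustule3d-generics number of labels K
#' @export
setMethod("nLabels", "LabeledVolume", function(x) x@nLabels)

#' @describeIn frustule3d-generics boundary positions of a LayerModel
#' @export
setMethod("layerBoundaries", "LayerModel", function(x) x@boundaries)

#' @describeIn frustule3d-generics per-layer summary table of a LayerModel
#' @export
setMethod("layerTable", "LayerModel", function(x)
  data.frame(layer = x@names, thickness_nm = x@thickness,
             porosity = x@porosity))

#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d voxels (y,x,z), voxel %.4g nm, origin (%s)\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@voxelSize, paste(object@origin, collapse = ",")))
})

setMethod("show", "VoxelVolume", function(object) {
  cat(sprintf("%s [%s]: %d x %d x %d voxels (y,x,z), voxel %.4g nm\n",
              class(object), object@semantics,
              dim(object@data)[1], dim(object@data)[2], dim(object@data)[3],
              object@grid@voxelSize))
  if (is(object, "BinaryVolume")) {
    cat(sprintf("  pore fraction %.4g (TRUE = pore/void)\n",
                mean(object@data)))
  } else if (is(object, "LabeledVolume")) {
    cat(sprintf("  %d labels, %.4g%% of voxels labelled\n",
                object@nLabels, 100 * mean(object@data > 0L)))
  } else {
    r <- range(object@data)
    cat(sprintf("  intensity range [%.4g, %.4g]\n", r[1], r[2]))
  }
})

setMethod("show", "ChordDistribution", function(object) {
  cat(sprintf("ChordDistribution (%s phase, %s): %d chords, <l> = %.4g nm\n",
              object@phase, object@directions, length(object@lengths),
              if (length(object@lengths)) mean(object@lengths) else NA_real_))
})

setMethod("show", "Projection", function(object) {
  cat(sprintf("Projection along %s: %d x %d pixels (%.4g nm), depth %d voxels\n",
              object@axis, nrow(object@data), ncol(object@data),
              object@pixelSize, object@depth))
})

setMethod("show", "SpectralDensity2D", function(object) {
  cat(sprintf("SpectralDensity2D: %d x %d, q up to (%.3g, %.3g) nm^-1 (q = 2 pi nu)\n",
              nrow(object@I), ncol(object@I), max(abs(object@qx)),
              max(abs(object@qy))))
})

setMethod("show", "AzimuthalProfile", function(object) {
  cat(sprintf("AzimuthalProfile along %s (+/- %g deg): %d q-bins, q in [%.3g, %.3g] nm^-1\n",
              object@direction, object@halfAngle, length(object@q),
              min(object@q), max(object@q)))
})

setMethod("show", "LayerModel", function(object) {
  cat(sprintf("LayerModel along %s: %d layers\n", object@axis,
              length(object@names)))
  print(layerTable(object))
})

#' Profile of an azimuthal average as a data.frame
#'
#' @param x an `AzimuthalProfile`
#' @param ... unused
#' @return data.frame with columns `q_nm_inv`, `I`, `n_pixels`
#' @export
as.data.frame.AzimuthalProfile <- function(x, ...) {
  data.frame(q_nm_inv = x@q, I = x@I, n_pixels = x@n)
}
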