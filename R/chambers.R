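# Areola chamber metrology and the chamber connectivity graph.

#' Per-chamber metrology
#'
#' For each watershed label: the mid-plane equivalent diameter (diameter
#' of the circle with the same area as the chamber's cross-section at the
#' plane halfway between the two layer boundaries), the chamber height
#' (axial extent) and the chamber volume. When a [LayerModel-class] is
#' given, height and volume are measured within the areola slab, so the
#' foramen and cribrum pores a chamber label may extend into do not bias
#' the chamber dimensions; the mid-plane is then the midpoint of the two
#' boundaries, otherwise the mid-slice of the volume.
#'
#' Labels that do not intersect the mid-plane (e.g. small non-chamber
#' objects) are flagged `midplane = FALSE` and should be excluded from
#' diameter statistics.
#'
#' @param chambers a [LabeledVolume-class] from [watershedSeparate()]
#' @param layers optional [LayerModel-class] with two boundaries
#' @param axis layer axis
#' @return data.frame: `label`, `mid_diameter_nm`, `height_nm`,
#'   `volume_nm3`, `midplane`
#' @export
chamberMetrics <- function(chambers, layers = NULL, axis = "z") {
  stopifnot(is(chambers, "LabeledVolume"))
  lab <- voxelData(chambers)
  d <- dim(lab)
  h <- voxelSize(chambers)
  K <- nLabels(chambers)
  ai <- axisIndex(axis)
  if (K == 0L)
    return(data.frame(label = integer(), mid_diameter_nm = numeric(),
                      height_nm = numeric(), volume_nm3 = numeric(),
                      midplane = logical()))
  if (ai != 3L) {  # rotate the layer axis into third position
    perm <- switch(ai, c(2, 3, 1), c(1, 3, 2))
    lab <- aperm(lab, perm)
    d <- dim(lab)
  }
  if (!is.null(layers)) {
    b <- layerBoundaries(layers)
    if (length(b) < 2L)
      stop("layer model must have at least two boundaries", call. = FALSE)
    slab <- (floor(b[1]) + 1L):round(b[2])
    midPos <- (b[1] + b[2]) / 2
  } else {
    slab <- seq_len(d[3])
    midPos <- d[3] / 2
  }
  kMid <- min(d[3], max(1L, floor(midPos) + 1L))

  midCounts <- tabulate(lab[, , kMid], K)
  area <- midCounts * h^2
  midDiam <- ifelse(midCounts > 0, 2 * sqrt(area / pi), NA_real_)

  sub <- lab[, , slab, drop = FALSE]
  vol <- tabulate(sub, K) * h^3
  # axial extent within the slab
  zmin <- rep(NA_integer_, K); zmax <- rep(NA_integer_, K)
  for (k in seq_along(slab)) {
    present <- unique(as.vector(sub[, , k]))
    present <- present[present > 0L]
    zmin[present][is.na(zmin[present])] <- k
    zmax[present] <- k
  }
  height <- (zmax - zmin + 1L) * h
  data.frame(label = seq_len(K), mid_diameter_nm = midDiam,
             height_nm = height, volume_nm3 = vol,
             midplane = midCounts > 0)
}

#' Chamber connectivity graph
#'
#' Edges between watershed labels whose pore voxels touch across the
#' watershed boundary (6-connectivity face adjacency). The throat
#' equivalent diameter is that of the disc with the same area as the
#' contact surface, where the contact area uses the Cauchy projection of
#' the per-normal face counts (sqrt(ny^2 + nx^2 + nz^2) face units),
#' which is exact for flat cuts of any orientation and removes the
#' staircase inflation a raw face count suffers on oblique throats; the
#' throat axial position is the mean position of the contact faces.
#'
#' @param chambers a [LabeledVolume-class] produced by
#'   [watershedSeparate()] on the binary volume of interest
#' @param minFaces drop contacts smaller than this many faces (spurious
#'   one-voxel touches); default 1 keeps everything
#' @return data.frame: `i`, `j`, `throat_diameter_nm`, `y_nm`, `x_nm`,
#'   `z_nm`, `n_faces`; zero rows when all labels are isolated
#' @export
connectivityGraph <- function(chambers, minFaces = 1L) {
  stopifnot(is(chambers, "LabeledVolume"))
  lab <- voxelData(chambers)
  h <- voxelSize(chambers)
  ct <- .contact_table(as.vector(lab), dim(lab))
  ct <- ct[ct$n_faces >= minFaces, , drop = FALSE]
  data.frame(i = ct$i, j = ct$j,
             throat_diameter_nm = 2 * sqrt(ct$area_faces * h^2 / pi),
             y_nm = (ct$y - 0.5) * h, x_nm = (ct$x - 0.5) * h,
             z_nm = (ct$z - 0.5) * h, n_faces = ct$n_faces)
}
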