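# Synthetic test volumes: geometric primitives with analytic ground truth.
#
# Voxelization rule (used by every generator): a voxel belongs to the pore
# phase iff its centre lies inside the continuous shape. Voxel centres sit
# at (i - 0.5) * voxelSize along each dimension, i = 1..n. This gives an
# unbiased volume estimator and a simple analytic oracle.

# full voxel-centre coordinate arrays (nm), dim order (y, x, z)
coordArrays <- function(shape, h) {
  yc <- voxelCenters(shape[1], h)
  xc <- voxelCenters(shape[2], h)
  zc <- voxelCenters(shape[3], h)
  list(
    Y = array(yc, shape),
    X = array(rep(xc, each = shape[1]), shape),
    Z = array(rep(zc, each = shape[1] * shape[2]), shape),
    yc = yc, xc = xc, zc = zc
  )
}

# orthonormal basis whose third column is the unit vector e
rotationToAxis <- function(e) {
  e <- e / sqrt(sum(e^2))
  ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * e) * e
  u <- u / sqrt(sum(u^2))
  v <- c(e[2] * u[3] - e[3] * u[2],
         e[3] * u[1] - e[1] * u[3],
         e[1] * u[2] - e[2] * u[1])
  cbind(u, v, e)
}

#' Generate a binary test volume containing one geometric primitive
#'
#' Digitizes a single shape onto a grid by centre-sampling and returns the
#' binary volume together with an exact ground-truth record (analytic
#' volume, digitized voxel count, geometry parameters). These are the
#' oracle fixtures for the porosity, Minkowski, chord and scattering
#' estimators.
#'
#' @param kind one of `"ball"`, `"ellipsoid"`, `"cylinder"`, `"slab"`,
#'   `"hollow_shell"`, `"torus"`
#' @param grid a [GridSpec-class]
#' @param center shape centre in nm (y, x, z); defaults to the grid centre.
#'   For `slab`, only the component along `axis` is used.
#' @param radius ball / cylinder radius (nm)
#' @param semiAxes ellipsoid semi-axes (nm), third one along `direction`
#' @param direction unit vector (y, x, z) for the ellipsoid long axis
#' @param height cylinder length along its axis (nm)
#' @param axis cylinder / slab / torus axis ("y", "x" or "z")
#' @param thickness slab thickness (nm); the slab spans the grid laterally
#' @param innerRadius,outerRadius hollow shell radii (nm)
#' @param majorRadius,minorRadius torus radii (nm); `axis` is the torus
#'   symmetry axis
#' @return list with elements `volume` ([BinaryVolume-class], TRUE = pore)
#'   and `truth` (list with an `objects` data.frame and the analytic volume)
#' @examples
#' g <- gridSpec(c(48, 48, 48), voxelSize = 1)
#' ball <- generatePrimitive("ball", g, radius = 15)
#' ball$truth$objects$voxel_count / (4 / 3 * pi * 15^3)
#' @export
generatePrimitive <- function(kind, grid, center = NULL,
                              radius = NULL, semiAxes = NULL,
                              direction = c(0, 0, 1), height = NULL,
                              axis = "z", thickness = NULL,
                              innerRadius = NULL, outerRadius = NULL,
                              majorRadius = NULL, minorRadius = NULL) {
  kind <- checkFlag(kind, c("ball", "ellipsoid", "cylinder", "slab",
                            "hollow_shell", "torus"), "kind")
  shape <- gridShape(grid)
  h <- voxelSize(grid)
  ext <- shape * h
  if (is.null(center)) center <- ext / 2
  margin <- 2 * h

  checkFit <- function(lo, hi) {
    if (any(lo < margin) || any(hi > ext - margin))
      stop(sprintf("%s does not fit inside the grid with a 2-voxel margin",
                   kind), call. = FALSE)
  }

  co <- coordArrays(shape, h)
  params <- c(NA_real_, NA_real_, NA_real_)

  if (kind == "ball") {
    stopifnot(is.numeric(radius), radius > 0)
    checkFit(center - radius, center + radius)
    d2 <- outer(outer((co$yc - center[1])^2, (co$xc - center[2])^2, "+"),
                (co$zc - center[3])^2, "+")
    mask <- d2 <= radius^2
    analytic <- 4 / 3 * pi * radius^3
    params[1] <- radius
  } else if (kind == "ellipsoid") {
    stopifnot(is.numeric(semiAxes), length(semiAxes) == 3, all(semiAxes > 0))
    R <- rotationToAxis(direction)
    # tight axis-aligned bounding half-extents of the rotated ellipsoid
    halfExt <- sqrt((R^2) %*% (semiAxes^2))[, 1]
    checkFit(center - halfExt, center + halfExt)
    dy <- co$Y - center[1]; dx <- co$X - center[2]; dz <- co$Z - center[3]
    u1 <- dy * R[1, 1] + dx * R[2, 1] + dz * R[3, 1]
    u2 <- dy * R[1, 2] + dx * R[2, 2] + dz * R[3, 2]
    u3 <- dy * R[1, 3] + dx * R[2, 3] + dz * R[3, 3]
    mask <- (u1 / semiAxes[1])^2 + (u2 / semiAxes[2])^2 +
      (u3 / semiAxes[3])^2 <= 1
    analytic <- 4 / 3 * pi * prod(semiAxes)
    params <- semiAxes
  } else if (kind == "cylinder") {
    stopifnot(is.numeric(radius), radius > 0, is.numeric(height), height > 0)
    ai <- axisIndex(axis)
    lo <- center - radius; hi <- center + radius
    lo[ai] <- center[ai] - height / 2; hi[ai] <- center[ai] + height / 2
    checkFit(lo, hi)
    coords <- list(co$Y, co$X, co$Z)
    lat <- setdiff(1:3, ai)
    d2 <- (coords[[lat[1]]] - center[lat[1]])^2 +
      (coords[[lat[2]]] - center[lat[2]])^2
    mask <- d2 <= radius^2 &
      abs(coords[[ai]] - center[ai]) <= height / 2
    analytic <- pi * radius^2 * height
    params <- c(radius, height, NA)
  } else if (kind == "slab") {
    stopifnot(is.numeric(thickness), thickness > 0)
    ai <- axisIndex(axis)
    if (center[ai] - thickness / 2 < 0 || center[ai] + thickness / 2 > ext[ai])
      stop("slab does not fit inside the grid", call. = FALSE)
    coords <- list(co$Y, co$X, co$Z)
    mask <- abs(coords[[ai]] - center[ai]) <= thickness / 2
    analytic <- thickness * prod(ext[setdiff(1:3, ai)])
    params <- c(thickness, NA, NA)
  } else if (kind == "hollow_shell") {
    stopifnot(is.numeric(innerRadius), is.numeric(outerRadius),
              0 < innerRadius, innerRadius < outerRadius)
    checkFit(center - outerRadius, center + outerRadius)
    d2 <- outer(outer((co$yc - center[1])^2, (co$xc - center[2])^2, "+"),
                (co$zc - center[3])^2, "+")
    mask <- d2 <= outerRadius^2 & d2 > innerRadius^2
    analytic <- 4 / 3 * pi * (outerRadius^3 - innerRadius^3)
    params <- c(innerRadius, outerRadius, NA)
  } else {  # torus
    stopifnot(is.numeric(majorRadius), is.numeric(minorRadius),
              0 < minorRadius, minorRadius < majorRadius)
    r <- majorRadius + minorRadius
    checkFit(center - r, center + r)
    ai <- axisIndex(axis)
    coords <- list(co$Y, co$X, co$Z)
    lat <- setdiff(1:3, ai)
    rho <- sqrt((coords[[lat[1]]] - center[lat[1]])^2 +
                  (coords[[lat[2]]] - center[lat[2]])^2)
    mask <- (rho - majorRadius)^2 +
      (coords[[ai]] - center[ai])^2 <= minorRadius^2
    analytic <- 2 * pi^2 * majorRadius * minorRadius^2
    params <- c(majorRadius, minorRadius, NA)
  }

  vol <- BinaryVolume(mask, voxelSize = h)
  truth <- list(
    objects = data.frame(
      id = 1L, kind = kind,
      cy = center[1], cx = center[2], cz = center[3],
      p1 = params[1], p2 = params[2], p3 = params[3],
      analytic_volume_nm3 = analytic,
      voxel_count = sum(mask)
    ),
    analyticVolume = analytic
  )
  list(volume = vol, truth = truth)
}

#' Overlay two-level acquisition noise on a binary volume
#'
#' Emulates a segmented-before/after pair: solid and pore voxels receive
#' distinct mean intensities plus Gaussian noise, producing a grayscale
#' volume whose histogram is a two-Gaussian mixture. Used to exercise the
#' bimodal threshold stage against known ground truth.
#'
#' @param volume a [BinaryVolume-class]
#' @param solidLevel,poreLevel mean intensities of the two phases (must
#'   differ)
#' @param noiseSd Gaussian noise standard deviation (>= 0)
#' @param seed integer seed; the function is a pure function of
#'   (volume, levels, noiseSd, seed)
#' @return a grayscale [VoxelVolume-class]
#' @export
addAcquisitionNoise <- function(volume, solidLevel = 200, poreLevel = 50,
                                noiseSd = 20, seed = 1) {
  stopifnot(is(volume, "BinaryVolume"))
  if (solidLevel == poreLevel)
    stop("solidLevel and poreLevel must differ", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  mask <- voxelData(volume)
  g <- array(ifelse(mask, poreLevel, solidLevel), dim(mask))
  if (noiseSd > 0) {
    g <- g + withSeed(seed, array(rnorm(length(mask), sd = noiseSd),
                                  dim(mask)))
  }
  VoxelVolume(g, voxelSize = voxelSize(volume), semantics = "grayscale",
              origin = volume@grid@origin)
}
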