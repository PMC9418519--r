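# Sparse fields of elongated ellipsoidal nanopores with exact ground truth.

#' NanoporeFieldSpec: parameters of a sparse ellipsoidal nanopore field
#'
#' The field emulates the nanoporosity found in the silica walls of the
#' frustule: isolated elongated ellipsoids at a volume fraction around
#' 2e-3, with individual pore volumes spanning 10-1000 nm^3 and a
#' preferred long-axis orientation.
#'
#' Pore sizes are drawn by volume: v log-uniform over `volumeRange`, an
#' aspect ratio rho uniform over `aspectRatioRange`, then semi-axes
#' a = b = (3 v / (4 pi rho))^(1/3) and c = rho * a. Parameterizing by the
#' volume envelope (rather than by raw semi-axis ranges) pins the generator
#' to the measured quantity and guarantees every ground-truth volume lies
#' inside the envelope.
#'
#' Orientation is a one-parameter axial (Watson-type) distribution about
#' `orientationAxis` with density proportional to exp(kappa * cos^2 theta);
#' `orientationConcentration` kappa = 0 gives isotropy.
#'
#' @slot targetVolumeFraction pore volume fraction to reach, in [0, 0.5)
#' @slot volumeRange per-pore volume envelope (nm^3)
#' @slot aspectRatioRange long/short semi-axis ratio range
#' @slot orientationAxis "y", "x" or "z"
#' @slot orientationConcentration Watson concentration kappa >= 0
#' @slot minSeparation minimum surface-to-surface gap between pores (nm);
#'   NA means two voxels at generation time
#' @slot seed integer seed
#' @export
setClass("NanoporeFieldSpec",
  representation(targetVolumeFraction = "numeric", volumeRange = "numeric",
                 aspectRatioRange = "numeric", orientationAxis = "character",
                 orientationConcentration = "numeric",
                 minSeparation = "numeric", seed = "integer")
)

setValidity("NanoporeFieldSpec", function(object) {
  if (object@targetVolumeFraction < 0 || object@targetVolumeFraction >= 0.5)
    return("targetVolumeFraction must lie in [0, 0.5)")
  if (length(object@volumeRange) != 2L || any(object@volumeRange <= 0) ||
      diff(object@volumeRange) < 0)
    return("volumeRange must be a positive increasing pair (nm^3)")
  if (any(object@aspectRatioRange < 1))
    return("aspect ratios must be >= 1")
  if (object@orientationConcentration < 0)
    return("orientationConcentration must be >= 0")
  TRUE
})

#' @rdname NanoporeFieldSpec-class
#' @param targetVolumeFraction pore volume fraction in [0, 0.5)
#' @param volumeRange per-pore volume envelope (nm^3)
#' @param aspectRatioRange elongation range (long / short semi-axis)
#' @param orientationAxis preferred long-axis direction
#' @param orientationConcentration Watson kappa (0 = isotropic)
#' @param minSeparation minimum gap between pores (nm); NA = 2 voxels
#' @param seed integer seed
#' @export
nanoporeFieldSpec <- function(targetVolumeFraction = 1.922e-3,
                              volumeRange = c(10, 1000),
                              aspectRatioRange = c(2, 4),
                              orientationAxis = "z",
                              orientationConcentration = 8,
                              minSeparation = NA_real_,
                              seed = 1L) {
  new("NanoporeFieldSpec",
      targetVolumeFraction = targetVolumeFraction,
      volumeRange = as.numeric(volumeRange),
      aspectRatioRange = as.numeric(aspectRatioRange),
      orientationAxis = checkFlag(orientationAxis, c("y", "x", "z"),
                                  "orientationAxis"),
      orientationConcentration = orientationConcentration,
      minSeparation = as.numeric(minSeparation), seed = as.integer(seed))
}

# Watson-type axial direction: density ~ exp(kappa cos^2 theta) about `e`
sampleAxialDirection <- function(e, kappa) {
  repeat {
    u <- runif(1, -1, 1)
    if (runif(1) < exp(kappa * (u * u - 1))) break
  }
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - u * u))
  R <- rotationToAxis(e)
  as.numeric(R %*% c(s * cos(phi), s * sin(phi), u))
}

#' Generate a sparse field of elongated ellipsoidal nanopores
#'
#' Draws pore volumes log-uniformly over the spec's envelope until the
#' cumulative analytic volume reaches the target fraction, then places the
#' digitized ellipsoids by rejection sampling so that no two pores come
#' closer than the minimum separation. Every accepted pore is digitized by
#' centre-sampling, required to be a single 26-connected component, and
#' recorded in the ground-truth table with its exact voxel count.
#'
#' @param spec a [NanoporeFieldSpec-class]
#' @param grid a [GridSpec-class]
#' @param maxAttemptsPerPore rejection-sampling budget; generation fails
#'   with an explicit error (reporting the achieved fraction) if the total
#'   budget `maxAttemptsPerPore * nPores` is exhausted
#' @return list with `volume` ([BinaryVolume-class]) and `truth`: a list
#'   holding the per-pore table (centre, semi-axes, direction, analytic
#'   volume, voxel count) and the achieved volume fraction
#' @export
generateNanoporeField <- function(spec, grid, maxAttemptsPerPore = 100) {
  stopifnot(is(spec, "NanoporeFieldSpec"), is(grid, "GridSpec"))
  shape <- gridShape(grid)
  h <- voxelSize(grid)
  ext <- shape * h
  occ <- array(FALSE, shape)
  sep <- if (is.na(spec@minSeparation)) 2L else
    max(0L, as.integer(ceiling(spec@minSeparation / h)))
  e <- c(y = 0, x = 0, z = 0)
  e[axisIndex(spec@orientationAxis)] <- 1

  empty <- data.frame(id = integer(), cy = numeric(), cx = numeric(),
                      cz = numeric(), a = numeric(), b = numeric(),
                      c = numeric(), dy = numeric(), dx = numeric(),
                      dz = numeric(), analytic_volume_nm3 = numeric(),
                      voxel_count = integer())
  if (spec@targetVolumeFraction == 0) {
    return(list(volume = BinaryVolume(occ, h),
                truth = list(pores = empty, achievedFraction = 0,
                             targetFraction = 0)))
  }

  res <- withSeed(spec@seed, {
    targetVol <- spec@targetVolumeFraction * prod(ext)
    # draw sizes up front until the analytic volumes reach the target;
    # the last pore absorbs the remainder when it fits the envelope, so
    # the achieved fraction is not at the mercy of one large overshoot
    vs <- numeric(0); rhos <- numeric(0)
    while (sum(vs) < targetVol) {
      vs <- c(vs, exp(runif(1, log(spec@volumeRange[1]),
                            log(spec@volumeRange[2]))))
      rhos <- c(rhos, runif(1, spec@aspectRatioRange[1],
                            spec@aspectRatioRange[2]))
    }
    n <- length(vs)
    if (n > 1) {
      rem <- targetVol - sum(vs[-n])
      if (rem >= spec@volumeRange[1] && rem <= spec@volumeRange[2]) {
        vs[n] <- rem
      } else if (abs(sum(vs[-n]) - targetVol) < abs(sum(vs) - targetVol)) {
        vs <- vs[-n]; rhos <- rhos[-n]; n <- n - 1L
      }
    }
    budget <- maxAttemptsPerPore * n
    rows <- vector("list", n)
    placed <- 0L
    for (i in seq_len(n)) {
      a <- (3 * vs[i] / (4 * pi * rhos[i]))^(1 / 3)
      cc <- rhos[i] * a
      ok <- FALSE
      while (budget > 0) {
        budget <- budget - 1
        dir <- sampleAxialDirection(e, spec@orientationConcentration)
        ctr <- runif(3, min = cc + (sep + 2) * h,
                     max = ext - cc - (sep + 2) * h)
        # digitize inside the bounding box only
        lo <- pmax(1L, as.integer(floor((ctr - cc) / h)) - sep)
        hi <- pmin(shape, as.integer(ceiling((ctr + cc) / h)) + 1L + sep)
        bd <- hi - lo + 1L
        yc <- (lo[1] - 1 + seq_len(bd[1]) - 0.5) * h
        xc <- (lo[2] - 1 + seq_len(bd[2]) - 0.5) * h
        zc <- (lo[3] - 1 + seq_len(bd[3]) - 0.5) * h
        R <- rotationToAxis(dir)
        Y <- array(yc - ctr[1], bd)
        X <- array(rep(xc - ctr[2], each = bd[1]), bd)
        Z <- array(rep(zc - ctr[3], each = bd[1] * bd[2]), bd)
        u1 <- Y * R[1, 1] + X * R[2, 1] + Z * R[3, 1]
        u2 <- Y * R[1, 2] + X * R[2, 2] + Z * R[3, 2]
        u3 <- Y * R[1, 3] + X * R[2, 3] + Z * R[3, 3]
        m <- (u1 / a)^2 + (u2 / a)^2 + (u3 / cc)^2 <= 1
        if (!any(m)) next
        lab <- .cc_label3(as.vector(m), dim(m), 26L)
        if (attr(lab, "K") != 1L) next  # must digitize to one component
        # separation check: grow the pore by `sep` voxels (26-neighbourhood)
        grown <- m
        if (sep > 0) {
          for (s in seq_len(sep)) grown <- dilate26(grown)
        }
        if (any(occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] & grown)) next
        occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | m
        rows[[i]] <- data.frame(
          id = i, cy = ctr[1], cx = ctr[2], cz = ctr[3],
          a = a, b = a, c = cc, dy = dir[1], dx = dir[2], dz = dir[3],
          analytic_volume_nm3 = vs[i], voxel_count = sum(m))
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          paste0("nanopore packing failed after the attempt budget: ",
                 "placed %d of %d pores, achieved fraction %.3g ",
                 "(target %.3g)"),
          placed, n, sum(occ) / prod(as.numeric(shape)),
          spec@targetVolumeFraction), call. = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  achieved <- sum(occ) / prod(as.numeric(shape))
  list(volume = BinaryVolume(occ, h),
       truth = list(pores = res, achievedFraction = achieved,
                    targetFraction = spec@targetVolumeFraction))
}

# one 26-neighbourhood (Chebyshev) dilation step of a logical array
dilate26 <- function(a) {
  d <- dim(a)
  out <- a
  for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    s <- shiftPair(out, v)
    acc <- array(FALSE, d)
    ix <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
    i1 <- ix(d[1], v[1]); j1 <- ix(d[2], v[2]); k1 <- ix(d[3], v[3])
    acc[i1, j1, k1] <- acc[i1, j1, k1] | s$B
    acc[i1 + v[1], j1 + v[2], k1 + v[3]] <-
      acc[i1 + v[1], j1 + v[2], k1 + v[3]] | s$A
    out <- out | acc
  }
  out
}
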