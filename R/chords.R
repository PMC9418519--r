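# Chord-length distributions and specific-surface estimation.
#
# A chord is a maximal same-phase run along a ray with both ends on the
# phase interface. The default ray set is the three lattice axes pooled
# (runs are exact there); uniformly sampled orientations are available
# for anisotropic media. Chords that touch the volume boundary are
# discarded by default because truncation biases the mean downwards.

#' Chord-length distribution of one phase
#'
#' @param binary a [BinaryVolume-class]
#' @param phase "pore" or "solid"
#' @param directions `"axes"` (the three lattice axes pooled; exact
#'   run-length chords) or a list `list(n = <count>, seed = <int>)` for
#'   uniformly sampled ray orientations traced at half-voxel steps with
#'   trilinear phase lookup (thresholded at 0.5)
#' @param boundary `"discard"` (default) drops chords touching the volume
#'   boundary; `"truncate"` keeps them at their truncated length
#' @param binWidthVoxels histogram bin width in voxel units
#' @return a [ChordDistribution-class]; an absent phase yields an empty
#'   distribution with a warning
#' @examples
#' g <- gridSpec(c(24, 24, 24), 1)
#' slab <- generatePrimitive("slab", g, thickness = 10, axis = "z")
#' cd <- chordLengths(slab$volume, "pore")
#' firstMoment(cd)  # 10
#' @export
chordLengths <- function(binary, phase = c("pore", "solid"),
                         directions = "axes",
                         boundary = c("discard", "truncate"),
                         binWidthVoxels = 1) {
  stopifnot(is(binary, "BinaryVolume"))
  phase <- match.arg(phase)
  boundary <- match.arg(boundary)
  h <- voxelSize(binary)
  a <- voxelData(binary)
  if (phase == "solid") a <- !a
  if (!any(a)) {
    warning("phase '", phase, "' is absent: empty chord distribution")
    return(new("ChordDistribution", phase = phase,
               directions = "axes", lengths = numeric(0),
               breaks = numeric(0), density = numeric(0),
               counts = integer(0)))
  }

  if (identical(directions, "axes")) {
    lengths <- c(axisChords(a, 3L, boundary),
                 axisChords(a, 1L, boundary),
                 axisChords(a, 2L, boundary)) * h
    dirlab <- "axes"
    step <- h
  } else {
    stopifnot(is.list(directions), !is.null(directions$n))
    lengths <- sampledChords(a, h, directions$n,
                             directions$seed %||% 1L, boundary)
    dirlab <- sprintf("random:%d", directions$n)
    step <- h / 2
  }

  bw <- binWidthVoxels * h
  if (length(lengths) == 0) {
    warning("no interior chords found")
    return(new("ChordDistribution", phase = phase, directions = dirlab,
               lengths = numeric(0), breaks = numeric(0),
               density = numeric(0), counts = integer(0)))
  }
  breaks <- seq(0, (ceiling(max(lengths) / bw) + 1) * bw, by = bw)
  counts <- tabulate(findInterval(lengths, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     length(breaks) - 1L)
  density <- counts / (sum(counts) * bw)
  new("ChordDistribution", phase = phase, directions = dirlab,
      lengths = lengths, breaks = breaks, density = density,
      counts = as.integer(counts))
}

# exact run-length chords along one lattice axis; returns lengths in voxels
axisChords <- function(a, ai, boundary) {
  d <- dim(a)
  m <- switch(ai,
    matrix(aperm(a, c(1, 2, 3)), d[1], d[2] * d[3]),
    matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
    matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2])
  )
  L <- nrow(m)
  # sentinel row of NA separates rays in the flattened vector
  v <- rbind(matrix(as.integer(m), L, ncol(m)), -1L)
  r <- rle(as.vector(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isPhase <- r$values == 1L
  # a chord is interior iff bounded by the opposite phase on both sides
  nR <- length(r$values)
  prevSolid <- c(FALSE, r$values[-nR] == 0L)
  nextSolid <- c(r$values[-1] == 0L, FALSE)
  if (boundary == "discard") {
    keep <- isPhase & prevSolid & nextSolid
  } else {
    keep <- isPhase
  }
  r$lengths[keep]
}

# chords along uniformly sampled orientations, with trilinear phase
# lookup at sub-voxel steps (thresholded at 0.5); trilinear smoothing of
# the digitized boundary avoids the speckle chords that a nearest-voxel
# lookup produces on rays grazing a staircase surface
sampledChords <- function(a, h, nDir, seed, boundary) {
  d <- dim(a)
  num <- array(as.numeric(a), d)
  trilinear <- function(py, px, pz) {
    # positions in voxel-index coordinates (voxel i centred at i)
    py <- pmin(pmax(py, 1), d[1]); px <- pmin(pmax(px, 1), d[2])
    pz <- pmin(pmax(pz, 1), d[3])
    i0 <- pmin(floor(py), d[1] - 1L); fy <- py - i0
    j0 <- pmin(floor(px), d[2] - 1L); fx <- px - j0
    k0 <- pmin(floor(pz), d[3] - 1L); fz <- pz - k0
    v <- 0
    for (oy in 0:1) for (ox in 0:1) for (oz in 0:1) {
      w <- (if (oy) fy else 1 - fy) * (if (ox) fx else 1 - fx) *
        (if (oz) fz else 1 - fz)
      v <- v + w * num[cbind(i0 + oy, j0 + ox, k0 + oz)]
    }
    v
  }
  withSeed(seed, {
    out <- vector("list", nDir)
    step <- 0.5  # voxels
    for (i in seq_len(nDir)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      nRays <- 64L
      o <- cbind(runif(nRays, 1, d[1]), runif(nRays, 1, d[2]),
                 runif(nRays, 1, d[3]))
      res <- numeric(0)
      for (rix in seq_len(nRays)) {
        # march both directions from the seed point to the volume edge
        tmax <- sum(d)  # generous bound
        ts <- seq(-tmax, tmax, by = step)
        py <- o[rix, 1] + ts * u[1]
        px <- o[rix, 2] + ts * u[2]
        pz <- o[rix, 3] + ts * u[3]
        inside <- py >= 1 & py <= d[1] & px >= 1 & px <= d[2] &
          pz >= 1 & pz <= d[3]
        if (!any(inside)) next
        sel <- which(inside)
        vals <- trilinear(py[sel], px[sel], pz[sel]) >= 0.5
        r <- rle(vals)
        nr <- length(r$values)
        phaseRuns <- which(r$values)
        if (boundary == "discard") {
          # runs at either ray end touch the volume boundary
          phaseRuns <- phaseRuns[phaseRuns != 1L & phaseRuns != nr]
        }
        res <- c(res, r$lengths[phaseRuns] * step)
      }
      out[[i]] <- res
    }
    unlist(out) * h
  })
}

#' First moment of a chord distribution
#'
#' Mean of the raw chord lengths (not of bin midpoints).
#'
#' @param dist a [ChordDistribution-class] with at least one chord
#' @return mean chord length (nm)
#' @export
firstMoment <- function(dist) {
  stopifnot(is(dist, "ChordDistribution"))
  if (length(dist@lengths) == 0)
    stop("empty chord distribution has no first moment", call. = FALSE)
  mean(dist@lengths)
}

#' Specific surface from the mean pore chord
#'
#' For a two-phase medium the pore-phase surface-to-volume ratio is
#' related to the mean pore chord length by S/V = 4 / <l_p>. The value is
#' returned in nm^-1 and in the conventional m^2 cm^-3
#' (1 nm^-1 = 1000 m^2 cm^-3).
#'
#' @param lp mean pore chord length (nm), > 0
#' @return list with `nm_inv` and `m2_cm3`
#' @examples
#' specificSurfaceFromChords(4.41)$m2_cm3  # ~907
#' @export
specificSurfaceFromChords <- function(lp) {
  if (!is.finite(lp) || lp <= 0)
    stop("mean chord length must be positive", call. = FALSE)
  sv <- 4 / lp
  list(nm_inv = sv, m2_cm3 = sv * 1000)
}
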