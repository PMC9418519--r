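# Layer-boundary detection along the valve axis and per-layer porosity.

#' Detect layer boundaries from the solid-fraction profile
#'
#' Layer boundaries are placed at the inflection points of the (smoothed)
#' solid-fraction profile: positions where the derivative magnitude has a
#' local maximum above `minSlope` times the global maximum. When more
#' candidates than `nLayers - 1` are found, the strongest ones are kept.
#' Boundary positions are fractional 0-based slice indices (a boundary at
#' b separates slices floor(b) and floor(b)+1 in 0-based counting);
#' sub-slice refinement uses the derivative-weighted centroid around each
#' peak.
#'
#' @param x a [BinaryVolume-class] (profile computed internally, per-layer
#'   porosities filled in) or a numeric solid-fraction profile
#' @param axis slicing axis when `x` is a volume
#' @param voxelSizeNm voxel size when `x` is a plain profile (for
#'   thicknesses and the smoothing window)
#' @param smoothingNm moving-average window (nm) applied before
#'   differentiation
#' @param nLayers expected number of layers (boundaries kept =
#'   `nLayers - 1`); `NULL` keeps every detected inflection
#' @param layerNames names, bottom to top; defaults to the three-layer
#'   valve naming when the count matches, generic names otherwise
#' @param minSlope inflection acceptance threshold, as a fraction of the
#'   maximum derivative magnitude (weak but genuine inflections pass; the
#'   sustained-step ranking and `nLayers` cap guard against noise)
#' @return a [LayerModel-class]
#' @export
detectLayerBoundaries <- function(x, axis = "z", voxelSizeNm = NULL,
                                  smoothingNm = 50, nLayers = 3L,
                                  layerNames = NULL, minSlope = 0.02) {
  if (is(x, "BinaryVolume")) {
    profile <- solidFractionProfile(x, axis)
    h <- voxelSize(x)
  } else {
    profile <- as.numeric(x)
    h <- voxelSizeNm %||% 1
  }
  n <- length(profile)
  if (n < 5) stop("profile too short for boundary detection", call. = FALSE)

  w <- max(1L, as.integer(round(smoothingNm / h)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n - 2L) w <- max(1L, (n - 2L) - (n - 1L) %% 2L)  # keep odd, < n
  s <- as.numeric(stats::filter(profile, rep(1 / w, w), sides = 2))
  # pad the smoothing ends with the nearest valid value
  first <- which(!is.na(s))[1]; last <- max(which(!is.na(s)))
  s[seq_len(first - 1)] <- s[first]
  if (last < n) s[(last + 1):n] <- s[last]

  drv <- c(s[2] - s[1], (s[-(1:2)] - s[seq_len(n - 2)]) / 2,
           s[n] - s[n - 1])
  mag <- abs(drv)
  thr <- minSlope * max(mag)
  if (max(mag) == 0)
    stop("no layering detected: profile is flat", call. = FALSE)

  # local maxima of |derivative| above threshold; the first/last w
  # slices are excluded (smoothing end effects, partial top slices)
  cand <- which(mag > thr &
                  mag >= c(-Inf, mag[-n]) & mag >= c(mag[-1], -Inf))
  cand <- cand[cand > w & cand <= n - w]
  # merge contiguous candidates (plateaus) keeping the strongest
  if (length(cand) > 1) {
    keep <- c(TRUE, diff(cand) > w)
    grp <- cumsum(keep)
    cand <- vapply(split(cand, grp), function(g) g[which.max(mag[g])], 0L)
  }
  if (length(cand) == 0)
    stop("no layering detected: no inflection point found", call. = FALSE)
  # rank candidates by the detrended level step across the inflection:
  # fit a line to the profile on each side and extrapolate both to the
  # candidate position; the gap between the two predictions measures a
  # genuine step, while a smooth ramp (both fits extrapolate to the same
  # value) and transient features (e.g. a band of connecting pores)
  # score near zero
  sustained <- vapply(cand, function(i) {
    sideFit <- function(ks) {
      ks <- ks[ks >= 1L & ks <= n]
      if (length(ks) < 2L) return(s[ks[length(ks) %/% 2L + 1L]])
      fit <- lm(s[ks] ~ ks)
      unname(coef(fit)[1] + coef(fit)[2] * i)
    }
    # side windows stop short of neighbouring candidates, so the step of
    # an adjacent boundary does not leak into this candidate's score
    lo <- max(c(0L, cand[cand < i] + w))
    hi <- min(c(n + 1L, cand[cand > i] - w))
    aEnd <- max(i + w, min(i + 3L * w, hi - 1L))
    bStart <- min(i - w, max(i - 3L * w, lo + 1L))
    abs(sideFit((i + w):aEnd) - sideFit(bStart:(i - w)))
  }, 0)
  if (!is.null(nLayers) && length(cand) > nLayers - 1L)
    cand <- sort(cand[order(sustained, decreasing = TRUE)][seq_len(nLayers - 1L)])

  # sub-slice position: |derivative|-weighted centroid around each peak
  half <- max(1L, w %/% 2L)
  boundaries <- vapply(cand, function(i) {
    win <- max(1L, i - half):min(n, i + half)
    sum((win - 0.5) * mag[win]) / sum(mag[win])
  }, 0)

  nb <- length(boundaries)
  if (is.null(layerNames)) {
    layerNames <- if (nb == 2L) c("foramen", "areola", "cribrum")
      else paste0("layer", seq_len(nb + 1L))
  }
  edges <- c(0, boundaries, n)
  thickness <- diff(edges) * h
  # per-layer porosity: exact voxel-count ratio over the boundary slabs
  porosity <- rep(NA_real_, nb + 1L)
  slabOf <- function(lo, hi) (floor(lo) + 1L):max(floor(lo) + 1L, round(hi))
  for (L in seq_len(nb + 1L)) {
    ks <- slabOf(edges[L], edges[L + 1L])
    ks <- ks[ks >= 1L & ks <= n]
    porosity[L] <- 1 - mean(profile[ks])
  }
  new("LayerModel", axis = axis, boundaries = as.numeric(boundaries),
      names = layerNames, thickness = thickness, porosity = porosity,
      profile = profile)
}

#' Combine per-layer porosities into a total porosity
#'
#' Thickness-weighted mean of the layer porosities: the porosity the
#' stacked layers have as a whole when the layers tile the axis.
#'
#' @param layers a [LayerModel-class], or a numeric vector of layer
#'   thicknesses (then `porosity` must be given)
#' @param porosity per-layer porosities when `layers` is a plain vector
#' @return total porosity fraction
#' @examples
#' combineTotalPorosity(c(180, 200, 2500), c(0.33, 0.27, 0.78))
#' @export
combineTotalPorosity <- function(layers, porosity = NULL) {
  if (is(layers, "LayerModel")) {
    th <- layers@thickness
    po <- layers@porosity
  } else {
    th <- as.numeric(layers)
    po <- as.numeric(porosity)
  }
  if (length(th) != length(po) || length(th) < 1L)
    stop("need matching thickness and porosity vectors", call. = FALSE)
  if (sum(th) <= 0) stop("total thickness must be positive", call. = FALSE)
  sum(th * po) / sum(th)
}
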