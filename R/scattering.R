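# Projection-based 2D spectral (small-angle-scattering-like) analysis.
#
# The 2D Fourier transform of a projection of the pore phase is the
# central slice of the 3D spectrum, so its squared modulus can be read as
# a 2D small-angle scattering pattern I(qx, qy). Conventions: q = 2 pi x
# spatial frequency, so a cutoff at q corresponds to a characteristic
# distance r = pi / q (half a spatial period); the projection mean is
# subtracted before the transform (removes the q = 0 spike), and no
# window is applied by default so Parseval's identity holds exactly.

#' Project the pore phase along an axis
#'
#' Pixel value = number of pore voxels along the ray.
#'
#' @param binary a [BinaryVolume-class]
#' @param axis projection axis ("y", "x" or "z"); the output rows/columns
#'   are the remaining two axes in (y, x, z) order
#' @return a [Projection-class]
#' @export
projectVolume <- function(binary, axis = "z") {
  stopifnot(is(binary, "BinaryVolume"))
  a <- voxelData(binary)
  d <- dim(a)
  ai <- axisIndex(axis)
  m <- switch(ai,
    colSums(a),                                  # along y -> (x, z)
    apply(a, c(1, 3), sum),                      # along x -> (y, z)
    rowSums(a, dims = 2)                         # along z -> (y, x)
  )
  new("Projection", data = m, pixelSize = voxelSize(binary), axis = axis,
      depth = as.integer(d[ai]))
}

fftshift1 <- function(n) {
  # index permutation that moves the zero-frequency bin to the centre
  c((floor(n / 2) + 1):n, 1:floor(n / 2))
}

#' 2D power spectrum (spectral density) of a projection
#'
#' Subtracts the projection mean, applies an optional Hann window, and
#' returns the centred squared-modulus FFT with physical q axes
#' (q = 2 pi k / (N * pixel)).
#'
#' @param projection a [Projection-class] of at least 4 x 4 pixels
#' @param window "none" (default; keeps Parseval exact) or "hann"
#' @return a [SpectralDensity2D-class]
#' @export
powerSpectrum2D <- function(projection, window = c("none", "hann")) {
  stopifnot(is(projection, "Projection"))
  window <- match.arg(window)
  p <- projection@data
  if (nrow(p) < 4 || ncol(p) < 4)
    stop("projection must be at least 4 x 4 pixels", call. = FALSE)
  x <- p - mean(p)
  if (window == "hann") {
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * outer(hann(nrow(x)), hann(ncol(x)))
  }
  F <- stats::fft(x)
  I <- Mod(F)^2
  n1 <- nrow(I); n2 <- ncol(I)
  I <- I[fftshift1(n1), fftshift1(n2)]
  h <- projection@pixelSize
  qOf <- function(n) 2 * pi * ((seq_len(n) - 1) - floor(n / 2)) / (n * h)
  new("SpectralDensity2D", I = I, qy = qOf(n1), qx = qOf(n2),
      meanSubtracted = TRUE, windowed = window == "hann")
}

#' Azimuthal sector average of a 2D spectral density
#'
#' Mean intensity over pixels whose q-vector lies within `halfAngle`
#' degrees of the chosen axis (both half-axes pooled), binned radially in
#' |q| with bin width equal to one q-grid step of the finer axis. Bins
#' with no pixels are reported as NA, not zero.
#'
#' @param spec a [SpectralDensity2D-class]
#' @param direction "qx" or "qy"
#' @param halfAngle sector half-angle in degrees, in (0, 90)
#' @return an [AzimuthalProfile-class]
#' @export
azimuthalAverage <- function(spec, direction = c("qx", "qy"),
                             halfAngle = 15) {
  stopifnot(is(spec, "SpectralDensity2D"))
  direction <- match.arg(direction)
  if (halfAngle <= 0 || halfAngle >= 90)
    stop("halfAngle must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  QY <- matrix(spec@qy, length(spec@qy), length(spec@qx))
  QX <- matrix(spec@qx, length(spec@qy), length(spec@qx), byrow = TRUE)
  Q <- sqrt(QY^2 + QX^2)
  along <- if (direction == "qx") abs(QX) else abs(QY)
  inSector <- Q > 0 & along / Q >= cos(halfAngle * pi / 180)
  dq <- min(diff(sort(unique(spec@qx)))[1], diff(sort(unique(spec@qy)))[1])
  qmax <- max(Q[inSector])
  breaks <- seq(0, qmax + dq, by = dq)
  bin <- findInterval(Q[inSector], breaks, rightmost.closed = TRUE)
  vals <- spec@I[inSector]
  nb <- length(breaks) - 1L
  n <- tabulate(bin, nb)
  s <- vapply(seq_len(nb), function(b) sum(vals[bin == b]), 0)
  I <- ifelse(n > 0, s / pmax(n, 1L), NA_real_)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- centers <= qmax
  new("AzimuthalProfile", direction = direction, halfAngle = halfAngle,
      q = centers[keep], I = I[keep], n = as.integer(n[keep]))
}

#' Porod fit: log-log slope of an azimuthal profile
#'
#' Least-squares fit of log10(I) against log10(q) over a q range; for a
#' smooth two-phase interface the high-q slope is -4 (Porod regime).
#'
#' @param profile an [AzimuthalProfile-class]
#' @param qRange numeric(2), fit band in nm^-1; needs >= 5 populated bins
#' @return list with `slope`, `intercept` (log10 units), `qRange`, `nBins`
#' @export
porodFit <- function(profile, qRange) {
  stopifnot(is(profile, "AzimuthalProfile"), length(qRange) == 2)
  sel <- profile@q >= qRange[1] & profile@q <= qRange[2] &
    is.finite(profile@I) & profile@I > 0
  if (sum(sel) < 5)
    stop("need at least 5 populated bins in the fit band", call. = FALSE)
  fit <- lm(log10(profile@I[sel]) ~ log10(profile@q[sel]))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       qRange = qRange, nBins = sum(sel))
}

#' Porod cutoff: where the profile leaves the fitted q^-4 line
#'
#' Scanning downward in q from the lower edge of the fit band, the cutoff
#' is the largest q at which log10(I) departs from the fitted straight
#' line by more than `tolerance` (in log10 units). A profile that follows
#' the fit over its whole range has no cutoff (NA, reported not invented).
#' The associated characteristic distance is r = pi / q_cutoff.
#'
#' @param profile an [AzimuthalProfile-class]
#' @param fit result of `porodFit()` on this profile
#' @param tolerance allowed departure in log10 intensity
#' @return list with `q_cutoff` (nm^-1, NA if none) and `r_nm`
#' @export
porodCutoff <- function(profile, fit, tolerance = 0.15) {
  stopifnot(is(profile, "AzimuthalProfile"))
  below <- which(profile@q < fit$qRange[1] & is.finite(profile@I) &
                   profile@I > 0)
  if (length(below) == 0) return(list(q_cutoff = NA_real_, r_nm = NA_real_))
  below <- rev(below)  # scan downward from the fit band
  for (i in below) {
    pred <- fit$intercept + fit$slope * log10(profile@q[i])
    if (abs(log10(profile@I[i]) - pred) > tolerance) {
      return(list(q_cutoff = profile@q[i],
                  r_nm = pi / profile@q[i]))
    }
  }
  list(q_cutoff = NA_real_, r_nm = NA_real_)
}

#' Characteristic distance from a spectral cutoff
#'
#' r = pi / q: the half-period associated with wavevector q.
#'
#' @param qCutoff cutoff wavevector (nm^-1), > 0
#' @return distance in nm
#' @examples
#' characteristicDistance(0.6)  # ~5 nm
#' characteristicDistance(0.3)  # ~10 nm
#' @export
characteristicDistance <- function(qCutoff) {
  if (any(!is.finite(qCutoff)) || any(qCutoff <= 0))
    stop("cutoff wavevector must be positive", call. = FALSE)
  pi / qCutoff
}
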