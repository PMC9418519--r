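# Segmentation: bimodal thresholding, morphological cleanup, watershed
# pore separation and connected-component labelling.

#' Threshold a grayscale volume at the valley of its bimodal histogram
#'
#' The intensity histogram of a well-behaved tomographic reconstruction is
#' bimodal, with one mode for the silica and one for the pores/free space.
#' The threshold is chosen by between-class variance maximization (Otsu)
#' on the 256-bin histogram of the whole volume; voxels at or below the
#' threshold become pore (black = void convention) when the pore mode is
#' the darker one, as set by `poreIs`.
#'
#' The selector requires a genuinely bimodal histogram: volumes with a
#' single mode (including constant volumes, or mixtures in which one phase
#' is too rare to show as a mode) are rejected with an error suggesting a
#' manual threshold via `threshold=`.
#'
#' @param volume a grayscale [VoxelVolume-class]
#' @param poreIs which side of the threshold is pore: "dark" (default) or
#'   "bright"
#' @param threshold optional manual threshold overriding the automatic
#'   selection (no bimodality check is applied then)
#' @param nBins histogram bins for the automatic selector
#' @return list with `threshold` (intensity value) and `volume`
#'   ([BinaryVolume-class], TRUE = pore)
#' @export
bimodalThreshold <- function(volume, poreIs = c("dark", "bright"),
                             threshold = NULL, nBins = 256L) {
  stopifnot(is(volume, "VoxelVolume"))
  poreIs <- match.arg(poreIs)
  a <- voxelData(volume)
  r <- range(a)
  if (is.null(threshold)) {
    if (r[1] == r[2])
      stop(paste0("volume has a single intensity value; automatic ",
                  "thresholding needs a bimodal histogram - supply a ",
                  "manual threshold"), call. = FALSE)
    br <- seq(r[1], r[2], length.out = nBins + 1L)
    counts <- tabulate(findInterval(a, br, rightmost.closed = TRUE,
                                    all.inside = TRUE), nBins)
    mids <- (br[-1] + br[-length(br)]) / 2
    if (countHistModes(counts) < 2L)
      stop(paste0("intensity histogram is not bimodal; automatic ",
                  "thresholding is unreliable - supply a manual threshold"),
           call. = FALSE)
    threshold <- otsuThreshold(counts, mids)
  }
  pore <- if (poreIs == "dark") a <= threshold else a > threshold
  list(threshold = threshold,
       volume = BinaryVolume(pore, voxelSize(volume),
                             origin = volume@grid@origin))
}

# Otsu: maximize between-class variance over histogram split points
otsuThreshold <- function(counts, mids) {
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  om <- cumsum(w)
  muT <- mu[length(mu)]
  sb <- (muT * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-length(sb)])
  # threshold between bin k and k+1
  (mids[k] + mids[k + 1]) / 2
}

# count genuine modes of a histogram: smooth, find local maxima, then
# keep a peak only if it is tall enough (>= 5% of the global maximum)
# and separated from the global maximum by a valley dropping below half
# the peak's own height (a prominence rule, so histogram noise on the
# flank of a single mode is not counted)
countHistModes <- function(counts, smooth = 11L) {
  kern <- rep(1 / smooth, smooth)
  s <- as.numeric(stats::filter(counts, kern, sides = 2))
  s[is.na(s)] <- 0
  n <- length(s)
  isPeak <- s > 0 & s >= c(-Inf, s[-n]) & s >= c(s[-1], -Inf)
  peaks <- which(isPeak)
  if (length(peaks) == 0) return(0L)
  main <- peaks[which.max(s[peaks])]
  genuine <- 1L
  for (p in setdiff(peaks, main)) {
    if (s[p] < 0.05 * s[main]) next
    valley <- min(s[min(p, main):max(p, main)])
    if (valley < 0.5 * s[p]) genuine <- genuine + 1L
  }
  genuine
}

#' Morphological opening passes on the pore phase
#'
#' Applies `nPairs` erosion/dilation dual operations (each pair is one
#' opening) with the 6-connected (face-neighbour) structuring element,
#' removing speckle noise smaller than the element. `nPairs = 0` is the
#' identity. The volume border is treated as solid.
#'
#' @param binary a [BinaryVolume-class]
#' @param nPairs number of opening passes (>= 0)
#' @return a [BinaryVolume-class]
#' @export
morphologicalCleanup <- function(binary, nPairs = 1L) {
  stopifnot(is(binary, "BinaryVolume"))
  nPairs <- as.integer(nPairs)
  if (nPairs < 0L) stop("nPairs must be >= 0", call. = FALSE)
  a <- voxelData(binary)
  for (p in seq_len(nPairs)) {
    a <- erode6(a)
    a <- dilate6(a)
  }
  BinaryVolume(a, voxelSize(binary), origin = binary@grid@origin)
}

offsets6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))

shiftFill <- function(a, v, fill) {
  d <- dim(a)
  out <- array(fill, d)
  ix <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
  i1 <- ix(d[1], v[1]); j1 <- ix(d[2], v[2]); k1 <- ix(d[3], v[3])
  out[i1, j1, k1] <- a[i1 + v[1], j1 + v[2], k1 + v[3]]
  out
}

erode6 <- function(a) {
  out <- a
  for (v in offsets6) out <- out & shiftFill(a, v, FALSE)
  out
}

dilate6 <- function(a) {
  out <- a
  for (v in offsets6) out <- out | shiftFill(a, v, FALSE)
  out
}

#' Label connected pore components
#'
#' Plain connected-component labelling of the pore phase under 6- or
#' 26-connectivity (pore phase default 26, complementary to 6-connected
#' solid). Labels are assigned in deterministic scan order and are
#' contiguous 1..K.
#'
#' @param binary a [BinaryVolume-class]
#' @param connectivity 6 or 26
#' @return a [LabeledVolume-class]
#' @export
labelComponents <- function(binary, connectivity = 26L) {
  stopifnot(is(binary, "BinaryVolume"))
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  a <- voxelData(binary)
  lab <- .cc_label3(as.vector(a), dim(a), as.integer(connectivity))
  K <- attr(lab, "K")
  LabeledVolume(array(as.integer(lab), dim(a)), voxelSize(binary),
                nLabels = K, origin = binary@grid@origin)
}

#' Separate touching pores by distance-transform watershed
#'
#' Splits pore objects that touch through narrow throats: the Euclidean
#' distance transform of the pore phase is computed, shallow maxima are
#' suppressed with an h-maxima transform (`hMin`, in nm, the minimum depth
#' of the constriction that counts as a split), the surviving regional
#' maxima become markers, and the pore phase is flooded from the markers
#' in decreasing-distance order. Ties in the flooding order are broken by
#' queue insertion order, which is itself deterministic, so labellings are
#' bit-reproducible. The union of all labels is exactly the pore phase.
#'
#' @param binary a [BinaryVolume-class]
#' @param hMin h-maxima suppression depth in nm; maxima whose dynamics
#'   (height above the saddle towards a deeper basin) are below `hMin`
#'   do not seed a separate object. `hMin = 0` splits at every regional
#'   maximum.
#' @return a [LabeledVolume-class]; an empty pore phase yields K = 0
#' @export
watershedSeparate <- function(binary, hMin = 0) {
  stopifnot(is(binary, "BinaryVolume"))
  if (hMin < 0) stop("hMin must be >= 0", call. = FALSE)
  a <- voxelData(binary)
  if (!any(a)) {
    return(LabeledVolume(array(0L, dim(a)), voxelSize(binary), nLabels = 0L,
                         origin = binary@grid@origin))
  }
  hVox <- hMin / voxelSize(binary)
  lab <- .watershed3(as.vector(a), dim(a), hVox)
  LabeledVolume(array(as.integer(lab), dim(a)), voxelSize(binary),
                nLabels = attr(lab, "K"), origin = binary@grid@origin)
}
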