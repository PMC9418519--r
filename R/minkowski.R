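# Minkowski functionals of labelled pore objects and the
# planarity/filamentarity shape finder.
#
# Discrete estimators (all linear functionals of the 2x2x2 local
# configuration statistics of the padded object mask):
#
#  * V0: exact voxel count x voxelSize^3.
#  * S (surface): Crofton line counts along the 13 lattice directions
#    (3 axis, 6 face-diagonal, 4 body-diagonal), weighted by the spherical
#    Voronoi measure of each direction class (0.045778 / 0.036981 /
#    0.035196, summing to 1/2 over the 13 unoriented directions):
#      S = 4 h^2 sum_r w_r C_r / |v_r|,
#    with C_r the number of phase changes along lattice offset v_r.
#  * H (integral of mean curvature): Crofton plane formula
#      H = 2 pi <integral over parallel sections of chi_2D>
#    averaged over 9 lattice plane normals (3 axis, 6 face-diagonal) with
#    the spherical Voronoi weights of the 9-direction set (0.093566 and
#    (1 - 3*0.093566)/6); 2D Euler characteristics by inclusion-exclusion
#    cell counting on each section lattice.
#  * chi (Euler characteristic): inclusion-exclusion cell counting of the
#    union of closed voxel cubes (vertices - edges + faces - cubes),
#    which is the 26-connected foreground convention.

W13_AXIS <- 0.045778
W13_FACE <- 0.036981
W13_BODY <- 0.035196
W9_AXIS <- 0.093566
W9_FACE <- (1 - 3 * W9_AXIS) / 6

OFFS_AXIS <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
OFFS_FACE <- list(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                  c(0, 1, 1), c(0, 1, -1))
OFFS_BODY <- list(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# the 9 section-plane families for H: in-plane lattice directions (u, w)
# and the plane spacing in voxel units
PLANE_FAMILIES <- list(
  list(u = c(0, 1, 0), w = c(0, 0, 1), spacing = 1, weight = "axis"),
  list(u = c(1, 0, 0), w = c(0, 0, 1), spacing = 1, weight = "axis"),
  list(u = c(1, 0, 0), w = c(0, 1, 0), spacing = 1, weight = "axis"),
  list(u = c(1, -1, 0), w = c(0, 0, 1), spacing = 1 / sqrt(2), weight = "face"),
  list(u = c(1, 1, 0), w = c(0, 0, 1), spacing = 1 / sqrt(2), weight = "face"),
  list(u = c(1, 0, -1), w = c(0, 1, 0), spacing = 1 / sqrt(2), weight = "face"),
  list(u = c(1, 0, 1), w = c(0, 1, 0), spacing = 1 / sqrt(2), weight = "face"),
  list(u = c(0, 1, -1), w = c(1, 0, 0), spacing = 1 / sqrt(2), weight = "face"),
  list(u = c(0, 1, 1), w = c(1, 0, 0), spacing = 1 / sqrt(2), weight = "face")
)

# core estimator on a padded logical mask (object strictly interior)
minkowskiCore <- function(mask, h) {
  p <- pad3(mask, 1L, FALSE)
  nvox <- sum(p)
  V0 <- nvox * h^3

  crofton <- function(offs) vapply(offs, function(v) countDiff(p, v), 0)
  S <- 4 * h^2 * (W13_AXIS * sum(crofton(OFFS_AXIS)) +
                  W13_FACE * sum(crofton(OFFS_FACE)) / sqrt(2) +
                  W13_BODY * sum(crofton(OFFS_BODY)) / sqrt(3))

  # chi: vertices - edges + faces - cubes of the union of closed cubes
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); e3 <- c(0, 0, 1)
  z <- c(0, 0, 0)
  n0 <- countAnyOf(p, list(z, e1, e2, e3, e1 + e2, e1 + e3, e2 + e3,
                           e1 + e2 + e3))
  n1 <- countAnyOf(p, list(z, e2, e3, e2 + e3)) +
    countAnyOf(p, list(z, e1, e3, e1 + e3)) +
    countAnyOf(p, list(z, e1, e2, e1 + e2))
  n2 <- countAnyOf(p, list(z, e1)) + countAnyOf(p, list(z, e2)) +
    countAnyOf(p, list(z, e3))
  chi <- n0 - n1 + n2 - nvox

  # H: weighted Crofton plane integrals of sectional 2D Euler counts
  Hsum <- 0
  for (fam in PLANE_FAMILIES) {
    u <- fam$u; w <- fam$w
    chi2sum <- countAnyOf(p, list(z, u, w, u + w)) -
      countAnyOf(p, list(z, u)) - countAnyOf(p, list(z, w)) + nvox
    wgt <- if (fam$weight == "axis") W9_AXIS else W9_FACE
    Hsum <- Hsum + wgt * chi2sum * fam$spacing * h
  }
  H <- 2 * pi * Hsum

  list(V0 = V0, V1 = S / 6, V2 = H / (3 * pi), V3 = chi,
       S = S, H = H, chi = chi, voxelCount = nvox)
}

#' Minkowski functionals of one labelled pore
#'
#' The four 3D Minkowski functionals in the normalization
#' V0 = V (volume, nm^3), V1 = S/6 (nm^2), V2 = H/(3 pi) (nm) and
#' V3 = chi (Euler characteristic), where S is the external surface and H
#' the integral of mean curvature. V0 is exact from the voxel count; S, H
#' and chi come from local-configuration (Crofton / cell-counting)
#' estimators on the object's padded bounding box (see the package
#' vignette for the exact weights).
#'
#' @param labels a [LabeledVolume-class] (or a [BinaryVolume-class],
#'   treated as one object)
#' @param label which label to measure (ignored for a binary volume)
#' @return list with `V0`, `V1`, `V2`, `V3`, `S`, `H`, `chi`,
#'   `voxelCount`, `touchesBoundary`
#' @examples
#' g <- gridSpec(c(32, 32, 32), 1)
#' ball <- generatePrimitive("ball", g, radius = 10)
#' m <- minkowskiFunctionals(ball$volume)
#' c(m$chi, m$S / (4 * pi * 100))  # 1 and ~1
#' @export
minkowskiFunctionals <- function(labels, label = 1L) {
  h <- voxelSize(labels)
  if (is(labels, "BinaryVolume")) {
    mask <- voxelData(labels)
    if (!any(mask)) stop("empty object", call. = FALSE)
    d <- dim(mask)
    ii <- which(mask, arr.ind = TRUE)
    touches <- any(ii == 1L) || any(t(ii) == d)
  } else if (is(labels, "LabeledVolume")) {
    if (label < 1L || label > nLabels(labels))
      stop("label ", label, " does not exist (K = ", nLabels(labels), ")",
           call. = FALSE)
    a <- voxelData(labels)
    d <- dim(a)
    bb <- .label_bbox(as.vector(a), d, nLabels(labels))[label, ]
    if (bb[7] == 0L) stop("label ", label, " is empty", call. = FALSE)
    mask <- a[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE] == label
    touches <- bb[1] == 1L || bb[3] == 1L || bb[5] == 1L ||
      bb[2] == d[1] || bb[4] == d[2] || bb[6] == d[3]
  } else {
    stop("labels must be a LabeledVolume or BinaryVolume", call. = FALSE)
  }
  out <- minkowskiCore(mask, h)
  out$touchesBoundary <- touches
  out
}

#' Planarity/filamentarity shape finder
#'
#' From the Minkowski functionals, the two dimensionless factors
#' `x = pi V0 V2 / (4 V1^2)` and `y = 8 V1 V3 / (3 pi V2^2)` give the
#' planarity `P = (1 - x) / (1 + x)` and filamentarity
#' `F = (1 - y) / (1 + y)`. Both vanish for a ball; F grows for elongated
#' bodies, P for flattened ones. Because only flattening and elongation
#' of isolated pores are of interest, the Euler characteristic entering
#' `y` is taken as 1 by default (`forceEuler`); the measured chi stays
#' available separately.
#'
#' @param m a list with components `V0`, `V1`, `V2`, `V3` (as returned by
#'   [minkowskiFunctionals()])
#' @param forceEuler use V3 = 1 in the `y` factor (default), as
#'   appropriate for isolated handle-free pores
#' @return list with `x`, `y`, `P`, `F`
#' @examples
#' R <- 10
#' sphere <- list(V0 = 4 / 3 * pi * R^3, V1 = 4 * pi * R^2 / 6,
#'                V2 = 4 * R / 3, V3 = 1)
#' shapeFinder(sphere)  # x = y = 1, P = F = 0
#' @export
shapeFinder <- function(m, forceEuler = TRUE) {
  V0 <- m$V0; V1 <- m$V1; V2 <- m$V2
  V3 <- if (forceEuler) 1 else m$V3
  if (!is.finite(V1) || V1 <= 0 || !is.finite(V2) || V2 <= 0)
    stop("shape finder undefined: V1 and V2 must be positive", call. = FALSE)
  x <- pi * V0 * V2 / (4 * V1^2)
  y <- 8 * V1 * V3 / (3 * pi * V2^2)
  list(x = x, y = y, P = (1 - x) / (1 + x), F = (1 - y) / (1 + y))
}

#' Shape-finder (F-P) diagram of all labelled pores
#'
#' One row per label with the pore volume, the four Minkowski functionals,
#' S, H, the measured Euler characteristic and the shape-finder factors.
#' Labels touching the volume boundary are flagged and, by default,
#' excluded from the summary centroid (their functionals are truncated);
#' labels whose curvature functional is non-positive get `valid = FALSE`
#' and NA shape factors rather than being dropped silently.
#'
#' @param labels a [LabeledVolume-class] with K >= 1
#' @param forceEuler see [shapeFinder()]
#' @param excludeBoundary exclude boundary-touching pores from the summary
#' @return list with `table` (data.frame) and `summary` (centroid and
#'   spread of the (F, P) cloud over valid pores)
#' @export
fpDiagram <- function(labels, forceEuler = TRUE, excludeBoundary = TRUE) {
  stopifnot(is(labels, "LabeledVolume"))
  K <- nLabels(labels)
  if (K < 1L) stop("no labels", call. = FALSE)
  a <- voxelData(labels)
  d <- dim(a)
  h <- voxelSize(labels)
  bbAll <- .label_bbox(as.vector(a), d, K)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    bb <- bbAll[k, ]
    if (bb[7] == 0L) stop("label ", k, " is empty", call. = FALSE)
    mask <- a[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE] == k
    mk <- minkowskiCore(mask, h)
    mk$touchesBoundary <- bb[1] == 1L || bb[3] == 1L || bb[5] == 1L ||
      bb[2] == d[1] || bb[4] == d[2] || bb[6] == d[3]
    sf <- tryCatch(shapeFinder(mk, forceEuler = forceEuler),
                   error = function(e) NULL)
    rows[[k]] <- data.frame(
      label = k, v_nm3 = mk$V0, V0 = mk$V0, V1 = mk$V1, V2 = mk$V2,
      V3 = if (forceEuler) 1 else mk$chi, S_nm2 = mk$S, H_nm = mk$H,
      chi = mk$chi,
      x = if (is.null(sf)) NA_real_ else sf$x,
      y = if (is.null(sf)) NA_real_ else sf$y,
      P = if (is.null(sf)) NA_real_ else sf$P,
      F = if (is.null(sf)) NA_real_ else sf$F,
      boundary = mk$touchesBoundary, valid = !is.null(sf))
  }
  tab <- do.call(rbind, rows)
  use <- tab$valid & (!excludeBoundary | !tab$boundary)
  summary <- list(
    n = sum(use),
    centroidF = mean(tab$F[use]), centroidP = mean(tab$P[use]),
    sdF = sd(tab$F[use]), sdP = sd(tab$P[use]),
    nBoundary = sum(tab$boundary), nInvalid = sum(!tab$valid))
  list(table = tab, summary = summary)
}
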