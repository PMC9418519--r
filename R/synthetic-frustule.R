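# Three-layer frustule valve units (foramen / areola / cribrum) on a
# hexagonal lattice, with exact layer, chamber and throat ground truth.

#' FrustuleSpec: geometry of a synthetic three-layer valve unit
#'
#' Defaults reproduce the measured dimensions of the *Coscinodiscus* sp.
#' valve: a 180 nm foramen layer with one 1.2 um central pore per hexagon
#' and 230 nm low dividing walls above it, 2.5 um high areola chambers
#' with a trapezoidal vertical section, a 200 nm cribrum layer perforated
#' by 300 nm circular macropores, and 140 nm connecting pores linking
#' neighbouring chambers close to the foramen. Chamber mid-plane
#' equivalent diameters are drawn from the two observed modes
#' (1.2 um minor, 1.5 um major).
#'
#' The hexagon lattice parameter (centre-to-centre spacing) is not a
#' measured quantity; the 2 um default makes the foramen porosity of the
#' emitted unit close to the measured 33% (pore area pi * 600^2 over a
#' 2 um hexagonal cell is 32.7%).
#'
#' @slot latticeParameter centre-to-centre hexagon spacing (nm)
#' @slot foramenThickness,foramenPoreDiameter foramen layer geometry (nm)
#' @slot dividingWallHeight height over which the chamber keeps its
#'   narrow bottom width before widening (nm)
#' @slot cribrumThickness,cribrumPoreDiameter cribrum layer geometry (nm)
#' @slot areolaHeight chamber height (nm)
#' @slot chamberMidDiameters either the two mode positions (sampled with
#'   `chamberModeWeights` and jitter) or one explicit diameter per chamber
#' @slot chamberModeWeights sampling weights of the diameter modes
#' @slot chamberDiameterJitter Gaussian jitter of sampled diameters (nm)
#' @slot connectingPoreDiameter throat diameter between chambers (nm)
#' @slot nRings hexagonal rings around the central chamber (0 = 1 chamber,
#'   1 = 7, 2 = 19)
#' @slot seed integer seed (used only for stochastic diameter sampling)
#' @export
setClass("FrustuleSpec",
  representation(latticeParameter = "numeric", foramenThickness = "numeric",
                 foramenPoreDiameter = "numeric",
                 dividingWallHeight = "numeric",
                 cribrumThickness = "numeric",
                 cribrumPoreDiameter = "numeric", areolaHeight = "numeric",
                 chamberMidDiameters = "numeric",
                 chamberModeWeights = "numeric",
                 chamberDiameterJitter = "numeric",
                 connectingPoreDiameter = "numeric", nRings = "integer",
                 seed = "integer")
)

setValidity("FrustuleSpec", function(object) {
  lens <- c(object@latticeParameter, object@foramenThickness,
            object@foramenPoreDiameter, object@dividingWallHeight,
            object@cribrumThickness, object@cribrumPoreDiameter,
            object@areolaHeight, object@chamberMidDiameters,
            object@connectingPoreDiameter)
  if (any(!is.finite(lens)) || any(lens <= 0))
    return("all lengths must be positive")
  if (object@areolaHeight <= object@foramenThickness)
    return("areolaHeight must exceed foramenThickness")
  if (object@foramenPoreDiameter >= object@latticeParameter)
    return("foramen pore diameter must be smaller than the lattice parameter")
  if (max(object@chamberMidDiameters) * 1.26 >= object@latticeParameter * 1.05)
    return("chamber diameters too large for the lattice parameter")
  if (object@dividingWallHeight >= object@areolaHeight)
    return("dividing wall height must be smaller than the areola height")
  TRUE
})

#' @rdname FrustuleSpec-class
#' @param latticeParameter hexagon spacing (nm)
#' @param foramenThickness,foramenPoreDiameter,dividingWallHeight,cribrumThickness,cribrumPoreDiameter,areolaHeight,connectingPoreDiameter layer dimensions (nm)
#' @param chamberMidDiameters mode positions (length 2) or per-chamber values
#' @param chamberModeWeights weights of the two modes
#' @param chamberDiameterJitter jitter sd (nm) for sampled diameters
#' @param nRings hexagonal rings around the central chamber
#' @param seed integer seed
#' @export
frustuleSpec <- function(latticeParameter = 2000, foramenThickness = 180,
                         foramenPoreDiameter = 1200,
                         dividingWallHeight = 230, cribrumThickness = 200,
                         cribrumPoreDiameter = 300, areolaHeight = 2500,
                         chamberMidDiameters = c(1200, 1500),
                         chamberModeWeights = c(0.3, 0.7),
                         chamberDiameterJitter = 30,
                         connectingPoreDiameter = 140, nRings = 1L,
                         seed = 1L) {
  new("FrustuleSpec", latticeParameter = latticeParameter,
      foramenThickness = foramenThickness,
      foramenPoreDiameter = foramenPoreDiameter,
      dividingWallHeight = dividingWallHeight,
      cribrumThickness = cribrumThickness,
      cribrumPoreDiameter = cribrumPoreDiameter,
      areolaHeight = areolaHeight,
      chamberMidDiameters = as.numeric(chamberMidDiameters),
      chamberModeWeights = as.numeric(chamberModeWeights),
      chamberDiameterJitter = chamberDiameterJitter,
      connectingPoreDiameter = connectingPoreDiameter,
      nRings = as.integer(nRings), seed = as.integer(seed))
}

# hexagonal patch centres (lateral, nm, relative to patch centre)
hexPatchCenters <- function(a, nRings) {
  pts <- matrix(0, nrow = 1, ncol = 2)
  if (nRings >= 1) {
    for (ring in seq_len(nRings)) {
      for (s in 0:5) {
        ang0 <- s * pi / 3
        ang1 <- (s + 2) * pi / 3  # step direction along the ring edge
        for (t in 0:(ring - 1)) {
          p <- ring * a * c(cos(ang0), sin(ang0)) +
            t * a * c(cos(ang1), sin(ang1))
          pts <- rbind(pts, p)
        }
      }
    }
  }
  colnames(pts) <- c("px", "py")
  pts
}

# point-in-hexagon (flat sides facing the six lattice neighbours),
# across-flats width W; dy/dx are offsets from the hexagon centre
hexInside <- function(dy, dx, W) {
  ap <- W / 2
  a1 <- abs(dx)
  a2 <- abs(dx * 0.5 + dy * (sqrt(3) / 2))
  a3 <- abs(dx * 0.5 - dy * (sqrt(3) / 2))
  pmax(a1, pmax(a2, a3)) <= ap
}

#' Generate a three-layer frustule valve unit
#'
#' Emits the layered binary volume (TRUE = pore) of a hexagonal patch of
#' areola chambers between a foramen and a cribrum layer, with connecting
#' pores between neighbouring chambers in the bottom third of the chamber
#' height, plus exact ground truth: layer boundary slices, exact per-layer
#' porosities of the emitted volume, the per-chamber table and the chamber
#' adjacency list with throat diameters.
#'
#' Chamber cross-sections are regular hexagons whose across-flats width is
#' constant over the dividing-wall band at the bottom and then widens
#' linearly towards the cribrum (trapezoidal vertical section); the width
#' profile is scaled so that the area-equivalent diameter at the chamber
#' mid-plane equals the requested mid diameter.
#'
#' The grid must be large enough to hold the patch with a margin; z
#' should cover foramen + areola + cribrum to within one slice
#' (`frustuleGridFor()` sizes it so the stack is never over-covered,
#' since a trailing all-solid slice would read as a fourth layer).
#'
#' @param spec a [FrustuleSpec-class]
#' @param grid a [GridSpec-class]; voxel sizes of 20-25 nm resolve all
#'   features (the finest is the 140 nm throat)
#' @return list with `volume` ([BinaryVolume-class]) and `truth` (layer
#'   boundaries in fractional slice units, per-layer porosity, chamber
#'   table, adjacency list, patch metadata)
#' @export
generateFrustule <- function(spec, grid) {
  stopifnot(is(spec, "FrustuleSpec"), is(grid, "GridSpec"))
  shape <- gridShape(grid)
  h <- voxelSize(grid)
  a <- spec@latticeParameter
  tf <- spec@foramenThickness
  ha <- spec@areolaHeight
  tc <- spec@cribrumThickness
  total <- tf + ha + tc
  if (shape[3] * h < total - h)  # may stop short of the top by < 1 slice
    stop("grid too shallow for foramen + areola + cribrum", call. = FALSE)

  ctr <- hexPatchCenters(a, spec@nRings)
  nCh <- nrow(ctr)
  # patch must fit laterally with a wall margin
  lateralNeed <- (max(abs(ctr)) + 0.7 * a) * 2
  if (shape[1] * h < lateralNeed || shape[2] * h < lateralNeed)
    stop("grid too small laterally for the requested hexagonal patch",
         call. = FALSE)
  cy0 <- shape[1] * h / 2
  cx0 <- shape[2] * h / 2

  # per-chamber mid diameters: explicit per chamber, or sampled from modes
  D <- withSeed(spec@seed, {
    if (length(spec@chamberMidDiameters) == nCh) {
      spec@chamberMidDiameters
    } else {
      md <- sample(spec@chamberMidDiameters, nCh, replace = TRUE,
                   prob = spec@chamberModeWeights)
      if (spec@chamberDiameterJitter > 0)
        md <- md + rnorm(nCh, sd = spec@chamberDiameterJitter)
      pmin(pmax(md, min(spec@chamberMidDiameters) * 0.95),
           max(spec@chamberMidDiameters) * 1.05)
    }
  })

  # across-flats width profile: W_bot up to the dividing-wall band, then
  # linear to W_top; scaled so width at mid-height gives the equivalent
  # area diameter D (hexagon area = pi (D/2)^2  <=>  W = 0.9523 D)
  Wmid <- D * sqrt(pi / (2 * sqrt(3)))
  Wbot <- 0.9 * Wmid
  wallH <- spec@dividingWallHeight
  fmid <- (ha / 2 - wallH) / (ha - wallH)
  Wtop <- Wbot + (Wmid - Wbot) / fmid
  widthAt <- function(zrel) {
    # zrel in [0, ha] measured from the top of the foramen
    f <- pmin(1, pmax(0, (zrel - wallH) / (ha - wallH)))
    list(f = f)
  }

  yc <- voxelCenters(shape[1], h)
  xc <- voxelCenters(shape[2], h)
  zc <- voxelCenters(shape[3], h)
  YY <- matrix(yc, shape[1], shape[2])
  XX <- matrix(xc, shape[1], shape[2], byrow = TRUE)

  # chamber adjacency: centre pairs one lattice constant apart
  pairs <- which(as.matrix(dist(ctr)) < a * 1.05 & upper.tri(diag(nCh)),
                 arr.ind = TRUE)
  rThroat <- spec@connectingPoreDiameter / 2
  # throat heights spread deterministically over the bottom third of the
  # chamber height, so the porosity profile shows no sharp throat band
  nP <- nrow(pairs)
  zThroat <- if (nP > 1) {
    tf + (0.10 + 0.20 * (seq_len(nP) - 1) / (nP - 1)) * ha
  } else if (nP == 1) tf + 0.15 * ha else numeric(0)

  rf <- spec@foramenPoreDiameter / 2
  rc <- spec@cribrumPoreDiameter / 2
  # cribrum macropore pattern per hexagon: centre + ring of six, kept
  # inside the narrowest chamber top so every macropore opens into a
  # chamber rather than ending blind on a wall
  ringR <- min(0.27 * a, min(Wtop) / 2 - rc - h)
  cribOff <- rbind(c(0, 0),
                   cbind(ringR * cos(seq(0, 5) * pi / 3),
                         ringR * sin(seq(0, 5) * pi / 3)))

  pore <- array(FALSE, shape)
  for (k in seq_len(shape[3])) {
    z <- zc[k]
    if (z > total) break
    sl <- matrix(FALSE, shape[1], shape[2])
    if (z <= tf) {
      # foramen: solid slab with one central circular pore per hexagon
      for (i in seq_len(nCh)) {
        dy <- YY - (cy0 + ctr[i, "py"]); dx <- XX - (cx0 + ctr[i, "px"])
        sl <- sl | (dy * dy + dx * dx <= rf * rf)
      }
    } else if (z <= tf + ha) {
      zrel <- z - tf
      f <- min(1, max(0, (zrel - wallH) / (ha - wallH)))
      for (i in seq_len(nCh)) {
        W <- Wbot[i] + f * (Wtop[i] - Wbot[i])
        dy <- YY - (cy0 + ctr[i, "py"]); dx <- XX - (cx0 + ctr[i, "px"])
        sl <- sl | hexInside(dy, dx, W)
      }
      # connecting pores: horizontal cylinders between neighbour centres
      for (p in seq_len(nP)) {
        if (abs(z - zThroat[p]) > rThroat) next
        rz <- sqrt(rThroat^2 - (z - zThroat[p])^2)
        p1 <- ctr[pairs[p, 1], ]; p2 <- ctr[pairs[p, 2], ]
        vy <- p2["py"] - p1["py"]; vx <- p2["px"] - p1["px"]
        L2 <- vy * vy + vx * vx
        dy <- YY - (cy0 + p1["py"]); dx <- XX - (cx0 + p1["px"])
        t <- pmin(1, pmax(0, (dy * vy + dx * vx) / L2))
        d2 <- (dy - t * vy)^2 + (dx - t * vx)^2
        sl <- sl | (d2 <= rz * rz)
      }
    } else {
      # cribrum: solid slab with the macropore pattern per hexagon
      for (i in seq_len(nCh)) {
        for (o in seq_len(nrow(cribOff))) {
          dy <- YY - (cy0 + ctr[i, "py"] + cribOff[o, 2])
          dx <- XX - (cx0 + ctr[i, "px"] + cribOff[o, 1])
          sl <- sl | (dy * dy + dx * dx <= rc * rc)
        }
      }
    }
    pore[, , k] <- sl
  }

  # exact ground truth from the emitted volume
  b1 <- tf / h; b2 <- (tf + ha) / h  # fractional slice boundaries (0-based)
  lay <- function(z0, z1) {
    ks <- which(zc > z0 & zc <= z1)
    mean(pore[, , ks])
  }
  kTop <- max(which(zc <= total))
  truthLayers <- data.frame(
    layer = c("foramen", "areola", "cribrum"),
    z0_nm = c(0, tf, tf + ha), z1_nm = c(tf, tf + ha, total),
    thickness_nm = c(tf, ha, tc),
    porosity = c(lay(0, tf), lay(tf, tf + ha), lay(tf + ha, total))
  )

  chamberTable <- data.frame(
    id = seq_len(nCh),
    cy_nm = cy0 + ctr[, "py"], cx_nm = cx0 + ctr[, "px"],
    mid_diameter_nm = D, height_nm = ha
  )
  adjacency <- if (nP > 0) {
    data.frame(i = pairs[, 1], j = pairs[, 2],
               throat_diameter_nm = spec@connectingPoreDiameter,
               z_nm = zThroat)
  } else {
    data.frame(i = integer(), j = integer(),
               throat_diameter_nm = numeric(), z_nm = numeric())
  }

  list(volume = BinaryVolume(pore, h),
       truth = list(boundaries = c(b1, b2), layers = truthLayers,
                    chambers = chamberTable, adjacency = adjacency,
                    nChambers = nCh, zTop_slice = kTop,
                    totalThickness_nm = total))
}
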