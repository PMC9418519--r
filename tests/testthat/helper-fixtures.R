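# Shared fixtures (computed once per test run) and independent oracles.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# digitized ball of radius R on an n^3 unit grid
ballFixture <- function(R = 20, n = 2 * R + 8) {
  generatePrimitive("ball", gridSpec(c(n, n, n), 1), radius = R)
}

# the default three-layer valve unit plus its derived analyses
frustuleFixture <- function() {
  cached("frustule", {
    sp <- frustuleSpec(seed = 1)
    g <- frustuleGridFor(sp, voxelSize = 20)
    fr <- generateFrustule(sp, g)
    fr$layerModel <- detectLayerBoundaries(fr$volume)
    fr$chambers <- watershedSeparate(fr$volume, hMin = 200)
    fr$metrics <- chamberMetrics(fr$chambers, fr$layerModel)
    fr$graph <- connectivityGraph(fr$chambers, minFaces = 4)
    fr
  })
}

# the study-condition nanopore field at 256^3, 1 nm voxels
nanoporeFixture <- function() {
  cached("nanopores", {
    g <- gridSpec(c(256, 256, 256), 1)
    spec <- nanoporeFieldSpec(orientationAxis = "y", seed = 42)
    nf <- generateNanoporeField(spec, g)
    nf$labels <- labelComponents(nf$volume, 26)
    nf
  })
}

# polydisperse smooth-ball field (for the Porod q^-4 regime)
ballFieldFixture <- function(seed = 3, n = 192, nball = 60,
                             rlo = 5, rhi = 10) {
  cached(paste0("ballfield", seed), {
    set.seed(seed)
    a <- array(FALSE, c(n, n, n))
    yc <- (1:n) - 0.5
    ctr <- cbind(runif(nball, rhi + 4, n - rhi - 4),
                 runif(nball, rhi + 4, n - rhi - 4),
                 runif(nball, rhi + 4, n - rhi - 4))
    R <- runif(nball, rlo, rhi)
    for (i in seq_len(nball)) {
      lo <- pmax(1, floor(ctr[i, ] - R[i] - 1))
      hi <- pmin(n, ceiling(ctr[i, ] + R[i] + 1))
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      d2 <- outer(outer((yc[ii] - ctr[i, 1])^2, (yc[jj] - ctr[i, 2])^2,
                        "+"), (yc[kk] - ctr[i, 3])^2, "+")
      a[ii, jj, kk] <- a[ii, jj, kk] | (d2 <= R[i]^2)
    }
    BinaryVolume(a, 1)
  })
}

# ---- independent oracles ----

# closed-form surface area of a prolate spheroid, semi-axes (b, b, a), a > b
spheroidSurfaceOracle <- function(b, a) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

# integral of mean curvature of the same spheroid by 1D quadrature over
# the profile curve (surface of revolution); exact for a sphere (4 pi R)
spheroidMeanCurvatureOracle <- function(b, a) {
  f <- function(z) {
    rho2 <- b^2 * (1 - z^2 / a^2)
    b^2 * (a^2 * rho2 + b^2 * z^2) / (a^4 * rho2 + b^4 * z^2)
  }
  # kappa_n part contributes exactly 2*pi*a; kappa_m part is pi * int(f)
  2 * pi * a + pi * stats::integrate(f, -a, a)$value
}

# brute-force run-length chord oracle along the three axes (lengths in
# voxels); boundary chords discarded
bruteForceChords <- function(a) {
  d <- dim(a)
  res <- integer(0)
  scan1 <- function(v) {
    out <- integer(0)
    run <- 0L
    start <- 0L
    for (i in seq_along(v)) {
      if (v[i]) {
        if (run == 0L) start <- i
        run <- run + 1L
      } else if (run > 0L) {
        if (start > 1L) out <- c(out, run)  # interior on both sides
        run <- 0L
      }
    }
    # run still open at the ray end -> boundary chord, discarded
    out
  }
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    res <- c(res, scan1(a[, j, k]))
  for (k in seq_len(d[3])) for (i in seq_len(d[1]))
    res <- c(res, scan1(a[i, , k]))
  for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    res <- c(res, scan1(a[i, j, ]))
  res
}
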