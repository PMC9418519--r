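# Projections, 2D spectra, azimuthal averages, Porod fits and cutoffs.

test_that("projections conserve mass and map single voxels to pixels", {
  a <- array(FALSE, c(16, 16, 16))
  a[5, 9, 3] <- TRUE
  vol <- BinaryVolume(a, 1)
  pr <- projectVolume(vol, "z")
  expect_identical(sum(pr@data), 1)
  expect_identical(pr@data[5, 9], 1)

  nf <- nanoporeFixture()
  for (ax in c("y", "x", "z")) {
    p <- projectVolume(nf$volume, ax)
    expect_equal(sum(p@data), sum(voxelData(nf$volume)))
  }
})

test_that("an axis-aligned cylinder projects to a constant disc", {
  g <- gridSpec(c(32, 32, 32), 1)
  cyl <- generatePrimitive("cylinder", g, radius = 8, height = 20,
                           axis = "z")
  pr <- projectVolume(cyl$volume, "z")
  vals <- pr@data[pr@data > 0]
  expect_true(all(vals == 20))
})

test_that("power spectrum satisfies Hermitian symmetry and Parseval", {
  set.seed(41)
  x <- matrix(runif(36 * 36), 36, 36)
  pr <- new("Projection", data = x, pixelSize = 1, axis = "z", depth = 1L)
  sp <- powerSpectrum2D(pr)
  # even grid: the symmetric part excludes the unpaired Nyquist row/col
  I <- sp@I[-1, -1]
  expect_equal(I, I[rev(seq_len(nrow(I))), rev(seq_len(ncol(I)))],
               tolerance = 1e-9)
  expect_equal(sum(sp@I) / length(x), sum((x - mean(x))^2),
               tolerance = 1e-8)
})

test_that("spectrum is invariant under projection translation", {
  nf <- nanoporeFixture()
  sub <- cropSubvolume(nf$volume, c(0, 0, 0), c(128, 128, 128))
  pr <- projectVolume(sub, "z")
  shifted <- new("Projection",
                 data = pr@data[c(41:128, 1:40), c(91:128, 1:90)],
                 pixelSize = 1, axis = "z", depth = pr@depth)
  expect_equal(powerSpectrum2D(pr)@I, powerSpectrum2D(shifted)@I,
               tolerance = 1e-6)
})

test_that("radial patterns give identical qx and qy azimuthal profiles", {
  n <- 64
  q <- 2 * pi * (((1:n) - 1) - n / 2) / n
  # construct a spectral density directly from a radial function
  QY <- matrix(q, n, n); QX <- t(QY)
  I <- exp(-(QX^2 + QY^2) / 0.5)
  sp <- new("SpectralDensity2D", I = I, qy = q, qx = q,
            meanSubtracted = TRUE, windowed = FALSE)
  ax <- azimuthalAverage(sp, "qx", 15)
  ay <- azimuthalAverage(sp, "qy", 15)
  expect_equal(ax@I, ay@I, tolerance = 1e-10)
})

test_that("isotropic fields superimpose; anisotropic fields do not", {
  # isotropic ball field: the two sector profiles agree
  bin <- ballFieldFixture()
  sp <- powerSpectrum2D(projectVolume(bin, "z"))
  ax <- azimuthalAverage(sp, "qx", 15)
  ay <- azimuthalAverage(sp, "qy", 15)
  band <- ax@q > 0.2 & ax@q < 1.0
  # speckle noise is large in single bins; the median log-ratio over the
  # band is the robust summary of sector agreement
  lr <- log10(ax@I[band] / ay@I[band])
  expect_lt(abs(median(lr, na.rm = TRUE)), 0.2)

  # y-elongated pores, projected along z: the qy profile is shifted to
  # low q (faster decay along the elongation axis)
  nf <- nanoporeFixture()
  spn <- powerSpectrum2D(projectVolume(nf$volume, "z"))
  axn <- azimuthalAverage(spn, "qx", 15)
  ayn <- azimuthalAverage(spn, "qy", 15)
  bandn <- axn@q > 0.3 & axn@q < 1.2
  expect_gt(mean(axn@I[bandn], na.rm = TRUE),
            2 * mean(ayn@I[bandn], na.rm = TRUE))
})

test_that("rotating the volume about the projection axis swaps sectors", {
  nf <- nanoporeFixture()
  sub <- cropSubvolume(nf$volume, c(0, 0, 0), c(96, 96, 96))
  rot <- BinaryVolume(aperm(voxelData(sub), c(2, 1, 3)), 1)
  s1 <- powerSpectrum2D(projectVolume(sub, "z"))
  s2 <- powerSpectrum2D(projectVolume(rot, "z"))
  a1 <- azimuthalAverage(s1, "qx", 15)
  a2 <- azimuthalAverage(s2, "qy", 15)
  expect_equal(a1@I, a2@I, tolerance = 1e-9)
})

test_that("Porod fits recover constructed and physical slopes", {
  qs <- seq(0.1, 3, by = 0.1)
  prof <- new("AzimuthalProfile", direction = "qx", halfAngle = 15,
              q = qs, I = 7 * qs^-4, n = rep(10L, length(qs)))
  expect_equal(porodFit(prof, c(0.5, 3))$slope, -4, tolerance = 1e-10)

  # smooth polydisperse ball field: q^-4 regime in the high-q band
  bin <- ballFieldFixture()
  sp <- powerSpectrum2D(projectVolume(bin, "z"))
  sl <- mean(c(porodFit(azimuthalAverage(sp, "qx", 15), c(0.6, 1.5))$slope,
               porodFit(azimuthalAverage(sp, "qy", 15), c(0.6, 1.5))$slope))
  expect_lt(abs(sl + 4), 0.3)

  # white noise has a flat spectrum
  set.seed(44)
  wn <- new("Projection", data = matrix(rnorm(256^2), 256, 256),
            pixelSize = 1, axis = "z", depth = 1L)
  wsl <- porodFit(azimuthalAverage(powerSpectrum2D(wn), "qx", 15),
                  c(0.3, 3))$slope
  expect_lt(abs(wsl), 0.2)

  expect_error(porodFit(prof, c(2.9, 3)), "5 populated bins")
})

test_that("Porod cutoff finds constructed breakpoints and reports absence", {
  qs <- seq(0.1, 3, by = 0.1)
  pure <- new("AzimuthalProfile", direction = "qx", halfAngle = 15,
              q = qs, I = 7 * qs^-4, n = rep(10L, length(qs)))
  ft <- porodFit(pure, c(1, 3))
  expect_true(is.na(porodCutoff(pure, ft)$q_cutoff))

  piece <- new("AzimuthalProfile", direction = "qx", halfAngle = 15,
               q = qs, I = ifelse(qs < 1, 7, 7 * qs^-4),
               n = rep(10L, length(qs)))
  ftp <- porodFit(piece, c(1.5, 3))
  co <- porodCutoff(piece, ftp, 0.15)
  expect_lt(abs(co$q_cutoff - 1), 0.1 + 1e-9)  # within one bin
  expect_equal(co$r_nm, pi / co$q_cutoff)
})

test_that("anisotropic pores cut off at lower q along their long axis", {
  nf <- nanoporeFixture()
  sp <- powerSpectrum2D(projectVolume(nf$volume, "z"))
  # each direction has its own Porod window: the transverse sector (qx)
  # between the ~4 nm cross-section scale and the voxel scale, the
  # elongation sector (qy) between the ~13 nm length scale and where the
  # weaker signal meets the spectral floor
  az <- list(qx = azimuthalAverage(sp, "qx", 15),
             qy = azimuthalAverage(sp, "qy", 15))
  res <- list(
    qx = porodCutoff(az$qx, porodFit(az$qx, c(1.6, 2.6))),
    qy = porodCutoff(az$qy, porodFit(az$qy, c(0.7, 1.4))))
  # qy is the elongation axis: its Porod regime ends at lower q
  expect_true(is.finite(res$qx$q_cutoff) && is.finite(res$qy$q_cutoff))
  expect_lt(res$qy$q_cutoff, res$qx$q_cutoff)
  # characteristic distances bracket the generator semi-axes (factor 2)
  rShort <- res$qx$r_nm
  rLong <- res$qy$r_nm
  expect_gt(rShort, mean(nf$truth$pores$a) / 2)
  expect_lt(rShort, mean(nf$truth$pores$a) * 4)
  expect_gt(rLong, mean(nf$truth$pores$c) / 2)
  expect_lt(rLong, mean(nf$truth$pores$c) * 2)
  expect_gt(rLong, rShort)
})

test_that("characteristic distances follow r = pi/q", {
  expect_identical(round(characteristicDistance(0.6)), 5)
  expect_identical(round(characteristicDistance(0.3)), 10)
  expect_equal(characteristicDistance(pi), 1)
  expect_error(characteristicDistance(0), "positive")
})
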