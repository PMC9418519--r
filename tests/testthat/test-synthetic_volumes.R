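# Synthetic generators: voxelization accuracy, determinism, conservation.

test_that("primitive voxel counts match analytic volumes", {
  g <- gridSpec(c(64, 64, 64), 1)
  ball <- generatePrimitive("ball", g, radius = 20)
  expect_lt(abs(ball$truth$objects$voxel_count /
                  (4 / 3 * pi * 20^3) - 1), 0.01)

  # axis-aligned slab: exactly thickness x cross-section
  slab <- generatePrimitive("slab", g, thickness = 10, axis = "z")
  expect_identical(slab$truth$objects$voxel_count, as.integer(10 * 64 * 64))

  cyl <- generatePrimitive("cylinder", g, radius = 12, height = 30)
  expect_lt(abs(cyl$truth$objects$voxel_count /
                  (pi * 144 * 30) - 1), 0.03)
  tor <- generatePrimitive("torus", g, majorRadius = 18, minorRadius = 7)
  expect_lt(abs(tor$truth$objects$voxel_count /
                  (2 * pi^2 * 18 * 49) - 1), 0.03)
})

test_that("primitive ground truth equals the emitted pore voxel count", {
  g <- gridSpec(c(48, 48, 48), 2)
  for (kind in c("ball", "hollow_shell")) {
    obj <- if (kind == "ball")
      generatePrimitive(kind, g, radius = 30)
    else generatePrimitive(kind, g, innerRadius = 18, outerRadius = 30)
    expect_identical(obj$truth$objects$voxel_count,
                     sum(voxelData(obj$volume)))
  }
})

test_that("shapes exceeding the grid are rejected with a clear message", {
  g <- gridSpec(c(32, 32, 32), 1)
  expect_error(generatePrimitive("ball", g, radius = 20), "does not fit")
  expect_error(generatePrimitive("ball", g, center = c(4, 16, 16),
                                 radius = 6), "does not fit")
})

test_that("nanopore field hits its target fraction with exact bookkeeping", {
  g <- gridSpec(c(128, 128, 128), 1)
  spec <- nanoporeFieldSpec(targetVolumeFraction = 1.9e-3, seed = 7)
  nf <- generateNanoporeField(spec, g)
  tr <- nf$truth
  # achieved fraction within 10% relative of target
  expect_lt(abs(tr$achievedFraction / 1.9e-3 - 1), 0.10)
  # conservation: ground-truth voxel counts sum to the pore-phase count
  expect_identical(sum(tr$pores$voxel_count), sum(voxelData(nf$volume)))
  # every pore volume inside the generator envelope
  expect_true(all(tr$pores$analytic_volume_nm3 >= 10 &
                    tr$pores$analytic_volume_nm3 <= 1000))
  # no two pores touch: component count equals the table rows
  cc <- labelComponents(nf$volume, 26)
  expect_identical(nLabels(cc), nrow(tr$pores))
})

test_that("generators are pure functions of (spec, grid, seed)", {
  g <- gridSpec(c(96, 96, 96), 1)
  a <- generateNanoporeField(nanoporeFieldSpec(seed = 5), g)
  b <- generateNanoporeField(nanoporeFieldSpec(seed = 5), g)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(a$truth$pores, b$truth$pores)
  c <- generateNanoporeField(nanoporeFieldSpec(seed = 6), g)
  expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
})

test_that("zero requested fraction yields an all-solid volume", {
  g <- gridSpec(c(32, 32, 32), 1)
  nf <- generateNanoporeField(nanoporeFieldSpec(targetVolumeFraction = 0), g)
  expect_false(any(voxelData(nf$volume)))
  expect_identical(nrow(nf$truth$pores), 0L)
})

test_that("isotropic orientation sampling is uniform over octants", {
  set.seed(11)
  n <- 2000
  dirs <- t(vapply(seq_len(n), function(i)
    frustule3d:::sampleAxialDirection(c(0, 0, 1), 0), numeric(3)))
  octant <- 1 + (dirs[, 1] > 0) + 2 * (dirs[, 2] > 0) + 4 * (dirs[, 3] > 0)
  p <- chisq.test(tabulate(octant, 8), p = rep(1 / 8, 8))$p.value
  expect_gt(p, 0.01)
})

test_that("concentrated orientations align with the requested axis", {
  set.seed(12)
  dirs <- t(vapply(seq_len(500), function(i)
    frustule3d:::sampleAxialDirection(c(0, 1, 0), 8), numeric(3)))
  expect_gt(mean(dirs[, 2]^2), 0.7)  # most mass near the x-axis (dim 2)
})

test_that("frustule unit has the requested chambers and throat placement", {
  fr <- frustuleFixture()
  expect_identical(fr$truth$nChambers, 7L)
  # connecting pores in the bottom third of the chamber height
  sp <- frustuleSpec()
  zlo <- sp@foramenThickness
  zhi <- sp@foramenThickness + sp@areolaHeight / 3
  expect_true(all(fr$truth$adjacency$z_nm > zlo &
                    fr$truth$adjacency$z_nm < zhi))
  # 7-chamber hexagonal patch: 6 centre-ring + 6 ring-ring adjacencies
  expect_identical(nrow(fr$truth$adjacency), 12L)
})

test_that("frustule geometry is deterministic given explicit diameters", {
  sp <- frustuleSpec(chamberMidDiameters = rep(1400, 7), seed = 1)
  sp2 <- frustuleSpec(chamberMidDiameters = rep(1400, 7), seed = 99)
  g <- frustuleGridFor(sp, voxelSize = 40)
  expect_identical(voxelData(generateFrustule(sp, g)$volume),
                   voxelData(generateFrustule(sp2, g)$volume))
})

test_that("equal chamber diameters give equal chamber volumes", {
  sp <- frustuleSpec(chamberMidDiameters = rep(1400, 7), seed = 1)
  g <- frustuleGridFor(sp, voxelSize = 40)
  fr <- generateFrustule(sp, g)
  ws <- watershedSeparate(fr$volume, hMin = 200)
  cm <- chamberMetrics(ws, detectLayerBoundaries(fr$volume))
  expect_identical(nrow(cm), 7L)
  expect_lt(diff(range(cm$volume_nm3)) / median(cm$volume_nm3), 0.02)
})

test_that("geometrically inconsistent frustule specs are rejected", {
  expect_error(frustuleSpec(foramenPoreDiameter = 2500),
               "lattice parameter")
  expect_error(frustuleSpec(areolaHeight = 100), "areolaHeight")
})

test_that("acquisition noise is a reproducible two-Gaussian overlay", {
  ball <- ballFixture(R = 12, n = 40)
  clean <- addAcquisitionNoise(ball$volume, 200, 50, noiseSd = 0, seed = 1)
  expect_identical(sort(unique(as.vector(voxelData(clean)))), c(50, 200))
  g1 <- addAcquisitionNoise(ball$volume, 200, 50, 20, seed = 4)
  g2 <- addAcquisitionNoise(ball$volume, 200, 50, 20, seed = 4)
  expect_identical(voxelData(g1), voxelData(g2))
  expect_error(addAcquisitionNoise(ball$volume, 100, 100, 10), "differ")
  expect_error(addAcquisitionNoise(ball$volume, 200, 50, -1), "noiseSd")
})
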