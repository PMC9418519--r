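# Segmentation: threshold selection, opening, watershed, components.

test_that("bimodal threshold recovers phases from noisy two-level data", {
  ball <- ballFixture(R = 20, n = 56)
  noisy <- addAcquisitionNoise(ball$volume, solidLevel = 200,
                               poreLevel = 50, noiseSd = 20, seed = 2)
  seg <- bimodalThreshold(noisy)
  expect_gt(seg$threshold, 50)
  expect_lt(seg$threshold, 200)
  mis <- mean(voxelData(seg$volume) != voxelData(ball$volume))
  expect_lt(mis, 0.01)
})

test_that("noise-free two-level volumes are recovered exactly", {
  ball <- ballFixture(R = 10, n = 32)
  clean <- addAcquisitionNoise(ball$volume, 255, 0, noiseSd = 0, seed = 1)
  seg <- bimodalThreshold(clean)
  expect_identical(voxelData(seg$volume), voxelData(ball$volume))
})

test_that("constant and unimodal volumes are rejected with advice", {
  flat <- VoxelVolume(array(7, c(8, 8, 8)), 1)
  expect_error(bimodalThreshold(flat), "manual threshold")
  set.seed(6)
  uni <- VoxelVolume(array(rnorm(16^3, 100, 5), c(16, 16, 16)), 1)
  expect_error(bimodalThreshold(uni), "not bimodal")
  # manual override always works
  seg <- bimodalThreshold(flat, threshold = 10)
  expect_true(all(voxelData(seg$volume)))
})

test_that("threshold is equivariant under affine intensity rescaling", {
  ball <- ballFixture(R = 16, n = 48)
  noisy <- addAcquisitionNoise(ball$volume, 200, 50, 20, seed = 3)
  t1 <- bimodalThreshold(noisy)$threshold
  scaled <- VoxelVolume(3 * voxelData(noisy) + 11, 1)
  t2 <- bimodalThreshold(scaled)$threshold
  expect_equal(t2, 3 * t1 + 11, tolerance = 1e-10)
})

test_that("morphological opening removes speckle and keeps bodies", {
  a <- array(FALSE, c(24, 24, 24))
  a[12, 12, 12] <- TRUE  # isolated voxel
  speck <- BinaryVolume(a, 1)
  expect_false(any(voxelData(morphologicalCleanup(speck, 1))))

  ball <- ballFixture(R = 20, n = 48)
  opened <- morphologicalCleanup(ball$volume, 1)
  expect_lt(abs(sum(voxelData(opened)) / sum(voxelData(ball$volume)) - 1),
            0.02)

  # n = 0 is the identity
  expect_identical(voxelData(morphologicalCleanup(ball$volume, 0)),
                   voxelData(ball$volume))
  expect_error(morphologicalCleanup(ball$volume, -1), ">= 0")
})

test_that("watershed splits touching balls and leaves single bodies whole", {
  g <- gridSpec(c(48, 48, 48), 1)
  a <- generatePrimitive("ball", g, center = c(24, 24, 16), radius = 10)
  b <- generatePrimitive("ball", g, center = c(24, 24, 32), radius = 10)
  pair <- BinaryVolume(voxelData(a$volume) | voxelData(b$volume), 1)
  ws <- watershedSeparate(pair, hMin = 1)
  expect_identical(nLabels(ws), 2L)
  # merging all labels reproduces the binary volume exactly
  expect_identical(voxelData(ws) > 0L, voxelData(pair))

  single <- watershedSeparate(a$volume, hMin = 1)
  expect_identical(nLabels(single), 1L)
})

test_that("watershed on an empty pore phase returns K = 0, not an error", {
  empty <- BinaryVolume(array(FALSE, c(8, 8, 8)), 1)
  ws <- watershedSeparate(empty)
  expect_identical(nLabels(ws), 0L)
  expect_true(all(voxelData(ws) == 0L))
})

test_that("watershed labelling is bit-reproducible", {
  fr <- frustuleFixture()
  again <- watershedSeparate(fr$volume, hMin = 200)
  expect_identical(voxelData(again), voxelData(fr$chambers))
})

test_that("connectivity semantics of component labelling", {
  a <- array(FALSE, c(8, 8, 8))
  a[2, 2, 2] <- TRUE
  a[3, 3, 3] <- TRUE  # diagonal neighbour
  vol <- BinaryVolume(a, 1)
  expect_identical(nLabels(labelComponents(vol, 26)), 1L)
  expect_identical(nLabels(labelComponents(vol, 6)), 2L)
  expect_error(labelComponents(vol, 18), "connectivity")

  empty <- BinaryVolume(array(FALSE, c(4, 4, 4)), 1)
  expect_identical(nLabels(labelComponents(empty)), 0L)
})

test_that("labelling is a partition of the pore phase", {
  nf <- nanoporeFixture()
  lab <- voxelData(nf$labels)
  expect_identical(lab > 0L, voxelData(nf$volume))
  expect_identical(sort(unique(as.vector(lab[lab > 0]))),
                   seq_len(nLabels(nf$labels)))
})

test_that("a dense field of isolated pores is counted exactly", {
  # population-scale pore count in a small volume: ~2000 single-voxel pores
  # on a lattice with 2-voxel pitch
  a <- array(FALSE, c(26, 26, 26))
  a[seq(2, 26, by = 2), seq(2, 26, by = 2), seq(2, 26, by = 2)] <- TRUE
  vol <- BinaryVolume(a, 1)
  expect_identical(nLabels(labelComponents(vol, 26)), 2197L)
})
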