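# Porosity metrics: fractions, Prob(v), layers, chambers, connectivity.

test_that("porosity fraction is an exact voxel-count ratio", {
  allVoid <- BinaryVolume(array(TRUE, c(6, 6, 6)), 1)
  expect_identical(porosityFraction(allVoid), 1)

  idx <- as.matrix(expand.grid(1:8, 1:8, 1:8))
  checker <- array((rowSums(idx) %% 2) == 0, c(8, 8, 8))
  expect_identical(porosityFraction(BinaryVolume(checker, 1)), 0.5)

  nf <- nanoporeFixture()
  expect_lt(abs(porosityFraction(nf$volume) / 1.9e-3 - 1), 0.10)

  expect_error(porosityFraction(allVoid, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("Prob(v) has exact support and normalized density", {
  a <- array(0L, c(24, 24, 24))
  a[2:3, 2:3, 2:3] <- 1L      # 8 voxels
  a[8:10, 8:10, 8:10] <- 2L   # 27
  a[14:17, 14:17, 14:17] <- 3L  # 64
  lv <- LabeledVolume(a, 1)
  pvd <- poreVolumeDistribution(lv)
  expect_setequal(pvd@volumes, c(8, 27, 64))
  # density integrates to one over its bins
  expect_equal(sum(pvd@density * diff(pvd@breaks)), 1, tolerance = 1e-12)

  # duplicating the volume doubles the count, leaves the density unchanged
  a2 <- array(0L, c(24, 24, 48))
  a2[, , 1:24] <- a
  a2[, , 25:48] <- ifelse(a > 0L, a + 3L, 0L)
  pvd2 <- poreVolumeDistribution(LabeledVolume(a2, 1))
  expect_identical(length(pvd2@volumes), 6L)
  expect_equal(pvd2@density, pvd@density)
})

test_that("Prob(v) is invariant under translation and axis permutation", {
  nf <- nanoporeFixture()
  sub <- cropSubvolume(nf$volume, c(0, 0, 0), c(128, 128, 128))
  lab <- labelComponents(sub, 26)
  base <- sort(poreVolumeDistribution(lab)@volumes)
  perm <- BinaryVolume(aperm(voxelData(sub), c(3, 1, 2)), 1)
  labp <- labelComponents(perm, 26)
  expect_equal(sort(poreVolumeDistribution(labp)@volumes), base)
})

test_that("pore volumes of the study field stay inside the envelope", {
  nf <- nanoporeFixture()
  pvd <- poreVolumeDistribution(nf$labels)
  # voxelized volumes may sit slightly outside the analytic envelope
  expect_true(all(pvd@volumes >= 5 & pvd@volumes <= 1100))
  expect_true(all(nf$truth$pores$analytic_volume_nm3 >= 10 &
                    nf$truth$pores$analytic_volume_nm3 <= 1000))
})

test_that("equivalent size is the cube root with guarded domain", {
  expect_equal(equivalentSize(1000), 10)
  expect_equal(equivalentSize(1), 1)
  expect_equal(equivalentSize(27), 3)
  expect_error(equivalentSize(0), "positive")
  expect_error(equivalentSize(-5), "positive")
})

test_that("solid-fraction profiles behave on uniform and empty volumes", {
  g <- gridSpec(c(16, 16, 32), 1)
  slab <- generatePrimitive("slab", g, thickness = 8, axis = "z")
  profY <- solidFractionProfile(slab$volume, "y")
  expect_true(all(abs(profY - profY[1]) < 1e-12))  # uniform laterally

  void <- BinaryVolume(array(TRUE, c(4, 4, 4)), 1)
  expect_identical(solidFractionProfile(void, "z"), rep(0, 4))
})

test_that("a two-porosity slab stack yields one boundary at the interface", {
  # bottom half: dense (20% porosity), top half: open (70% porosity)
  set.seed(8)
  a <- array(FALSE, c(32, 32, 40))
  a[, , 1:20] <- array(runif(32 * 32 * 20) < 0.2, c(32, 32, 20))
  a[, , 21:40] <- array(runif(32 * 32 * 20) < 0.7, c(32, 32, 20))
  vol <- BinaryVolume(a, 10)
  lm <- detectLayerBoundaries(vol, nLayers = 2, smoothingNm = 30)
  expect_identical(length(layerBoundaries(lm)), 1L)
  expect_lt(abs(layerBoundaries(lm) - 20), 1.5)
  expect_lt(abs(lm@porosity[1] - 0.2), 0.05)
  expect_lt(abs(lm@porosity[2] - 0.7), 0.05)
})

test_that("uniform volumes report no layering", {
  solid <- BinaryVolume(array(FALSE, c(8, 8, 30)), 1)
  expect_error(detectLayerBoundaries(solid), "no layering")
})

test_that("frustule layer boundaries and porosities are recovered", {
  fr <- frustuleFixture()
  b <- layerBoundaries(fr$layerModel)
  expect_identical(length(b), 2L)
  expect_lt(max(abs(b - fr$truth$boundaries)), 2)
  expect_lt(max(abs(fr$layerModel@porosity - fr$truth$layers$porosity)),
            0.03)
})

test_that("total porosity is the thickness-weighted layer mean", {
  expect_identical(combineTotalPorosity(c(100, 100), c(0, 1)), 0.5)
  expect_identical(combineTotalPorosity(250, 0.33), 0.33)
  # printed layer triples of the three-layer valve: the coherent
  # thickness-weighted reading gives 71.6%
  expect_equal(combineTotalPorosity(c(180, 200, 2500), c(0.33, 0.27, 0.78)),
               0.7159, tolerance = 1e-3)
  expect_error(combineTotalPorosity(c(0, 0), c(0.5, 0.5)), "thickness")
  # conservation: weighted layer porosities reproduce the global porosity
  fr <- frustuleFixture()
  prof <- solidFractionProfile(fr$volume, "z")
  b <- c(0, layerBoundaries(fr$layerModel), length(prof))
  expect_equal(combineTotalPorosity(fr$layerModel),
               porosityFraction(fr$volume), tolerance = 1e-3)
})

test_that("cylindrical chamber dimensions are recovered within a voxel", {
  g <- gridSpec(c(64, 64, 48), 1)
  cyl <- generatePrimitive("cylinder", g, radius = 20, height = 30,
                           axis = "z")
  ws <- watershedSeparate(cyl$volume, hMin = 1)
  cm <- chamberMetrics(ws)
  expect_identical(nrow(cm), 1L)
  expect_lt(abs(cm$mid_diameter_nm - 40), 1)
  expect_lt(abs(cm$height_nm - 30), 1)
  # prismatic consistency: volume = mid-plane area x height
  expect_lt(abs(cm$volume_nm3 / (pi * 400 * 30) - 1), 0.05)
})

test_that("chamber volume scales quadratically with mid diameter", {
  fr <- frustuleFixture()
  cm <- fr$metrics[fr$metrics$midplane, ]
  fit <- lm(log(volume_nm3) ~ log(mid_diameter_nm), data = cm)
  expect_lt(abs(coef(fit)[2] - 2), 0.1)
})

test_that("chamber diameters reproduce the two-mode size distribution", {
  sp <- frustuleSpec(nRings = 2L, seed = 3)  # 19 chambers
  g <- frustuleGridFor(sp, voxelSize = 25)
  fr <- generateFrustule(sp, g)
  lm <- detectLayerBoundaries(fr$volume)
  ws <- watershedSeparate(fr$volume, hMin = 200)
  cm <- chamberMetrics(ws, lm)
  cm <- cm[cm$midplane, ]
  expect_identical(nrow(cm), 19L)
  # histogram with 100 nm bins: modes at the generator's 1200/1500 nm
  br <- seq(1000, 1800, by = 100)
  hh <- hist(cm$mid_diameter_nm, breaks = br, plot = FALSE)
  loc <- br[which(diff(sign(diff(c(-1, hh$counts, -1)))) == -2)] + 50
  expect_true(any(abs(loc - 1250) <= 100))
  expect_true(any(abs(loc - 1550) <= 100))
})

test_that("connectivity graph finds exactly the generated throats", {
  g <- gridSpec(c(40, 40, 72), 1)
  a <- generatePrimitive("ball", g, center = c(20, 20, 20), radius = 12)
  b <- generatePrimitive("ball", g, center = c(20, 20, 52), radius = 12)
  th <- generatePrimitive("cylinder", g, center = c(20, 20, 36),
                          radius = 5, height = 18, axis = "z")
  joined <- BinaryVolume(voxelData(a$volume) | voxelData(b$volume) |
                           voxelData(th$volume), 1)
  ws <- watershedSeparate(joined, hMin = 2)
  expect_identical(nLabels(ws), 2L)
  cg <- connectivityGraph(ws)
  expect_identical(nrow(cg), 1L)
  expect_lt(abs(cg$throat_diameter_nm - 10), 1.2)

  # isolated chambers: no edges
  iso <- BinaryVolume(voxelData(a$volume) | voxelData(b$volume), 1)
  cgi <- connectivityGraph(watershedSeparate(iso, hMin = 2))
  expect_identical(nrow(cgi), 0L)
})

test_that("frustule throat diameters match the generated 140 nm pores", {
  fr <- frustuleFixture()
  expect_identical(nrow(fr$graph), nrow(fr$truth$adjacency))
  expect_lt(abs(mean(fr$graph$throat_diameter_nm) - 140) / 140, 0.15)
})
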