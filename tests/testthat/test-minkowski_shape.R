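# Minkowski functionals and the planarity/filamentarity shape finder.

test_that("digitized ball matches analytic sphere functionals", {
  ball <- ballFixture(R = 20)
  m <- minkowskiFunctionals(ball$volume)
  expect_lt(abs(m$V0 / (4 / 3 * pi * 20^3) - 1), 0.01)
  expect_lt(abs(m$S / (4 * pi * 20^2) - 1), 0.03)
  expect_lt(abs(m$H / (4 * pi * 20) - 1), 0.03)
  expect_identical(m$chi, 1L)
  expect_equal(m$V0, sum(voxelData(ball$volume)) * 1)  # exact conservation
})

test_that("Euler characteristic is exact on toy topologies", {
  g <- gridSpec(c(64, 64, 64), 1)
  shell <- generatePrimitive("hollow_shell", g, innerRadius = 12,
                             outerRadius = 20)
  expect_identical(minkowskiFunctionals(shell$volume)$chi, 2L)
  torus <- generatePrimitive("torus", g, majorRadius = 18, minorRadius = 7)
  expect_identical(minkowskiFunctionals(torus$volume)$chi, 0L)
})

test_that("surface estimate converges for growing balls", {
  for (R in c(15, 20, 28)) {
    m <- minkowskiFunctionals(ballFixture(R = R)$volume)
    expect_lt(abs(m$S / (4 * pi * R^2) - 1), 0.03)
  }
})

test_that("functionals are invariant under translation and 90-degree turns", {
  g <- gridSpec(c(48, 48, 48), 1)
  e1 <- generatePrimitive("ellipsoid", g, center = c(20, 24, 24),
                          semiAxes = c(6, 9, 14),
                          direction = c(0, 0, 1))
  e2 <- generatePrimitive("ellipsoid", g, center = c(28, 24, 24),
                          semiAxes = c(6, 9, 14),
                          direction = c(0, 0, 1))
  m1 <- minkowskiFunctionals(e1$volume)
  m2 <- minkowskiFunctionals(e2$volume)
  expect_equal(m1[c("V0", "S", "H", "chi")], m2[c("V0", "S", "H", "chi")])

  rot <- BinaryVolume(aperm(voxelData(e1$volume), c(3, 1, 2)), 1)
  m3 <- minkowskiFunctionals(rot)
  expect_equal(m3[c("V0", "S", "H", "chi")], m1[c("V0", "S", "H", "chi")])
})

test_that("shape finder reproduces hand-computed values", {
  R <- 10
  sphere <- list(V0 = 4 / 3 * pi * R^3, V1 = 4 * pi * R^2 / 6,
                 V2 = 4 * R / 3, V3 = 1)
  sf <- shapeFinder(sphere)
  expect_equal(sf$x, 1, tolerance = 1e-12)
  expect_equal(sf$y, 1, tolerance = 1e-12)
  expect_equal(sf$P, 0, tolerance = 1e-12)
  expect_equal(sf$F, 0, tolerance = 1e-12)

  unit <- list(V0 = 1, V1 = 1, V2 = 1, V3 = 1)
  sfu <- shapeFinder(unit)
  expect_equal(sfu$x, pi / 4, tolerance = 1e-12)
  expect_equal(sfu$P, (1 - pi / 4) / (1 + pi / 4), tolerance = 1e-12)
  expect_equal(sfu$y, 8 / (3 * pi), tolerance = 1e-12)
  expect_equal(sfu$F, (1 - 8 / (3 * pi)) / (1 + 8 / (3 * pi)),
               tolerance = 1e-12)

  expect_error(shapeFinder(list(V0 = 1, V1 = 0, V2 = 1, V3 = 1)),
               "positive")
  expect_error(shapeFinder(list(V0 = 1, V1 = 1, V2 = -2, V3 = 1)),
               "positive")
})

test_that("prolate spheroid matches closed-form S and H, with F > P", {
  b <- 5; a <- 50
  g <- gridSpec(c(40, 40, 112), 1)
  sp <- generatePrimitive("ellipsoid", g, semiAxes = c(b, b, a),
                          direction = c(0, 0, 1))
  m <- minkowskiFunctionals(sp$volume)
  expect_lt(abs(m$S / spheroidSurfaceOracle(b, a) - 1), 0.07)
  # axis-aligned elongated bodies are the worst case for the 9-direction
  # plane sampling of H (known orientation bias)
  expect_lt(abs(m$H / spheroidMeanCurvatureOracle(b, a) - 1), 0.10)
  sf <- shapeFinder(m)
  expect_gt(sf$F, sf$P)
  # the analytic spheroid functionals give the same ordering
  sfa <- shapeFinder(list(V0 = 4 / 3 * pi * b * b * a,
                          V1 = spheroidSurfaceOracle(b, a) / 6,
                          V2 = spheroidMeanCurvatureOracle(b, a) / (3 * pi),
                          V3 = 1))
  expect_gt(sfa$F, sfa$P)
  expect_lt(abs(sf$F - sfa$F), 0.1)
})

test_that("F-P diagram of a ball field sits at the spherical origin", {
  set.seed(21)
  a <- array(FALSE, c(96, 96, 96))
  yc <- (1:96) - 0.5
  ctr <- 12 + 24 * (as.matrix(expand.grid(0:2, 0:2, 0:2)))
  for (i in seq_len(nrow(ctr))) {
    R <- runif(1, 7, 10)
    d2 <- outer(outer((yc - ctr[i, 1])^2, (yc - ctr[i, 2])^2, "+"),
                (yc - ctr[i, 3])^2, "+")
    a <- a | (d2 <= R^2)
  }
  lv <- labelComponents(BinaryVolume(a, 1), 26)
  expect_identical(nLabels(lv), 27L)
  fp <- fpDiagram(lv)
  expect_lt(abs(fp$summary$centroidF), 0.05)
  expect_lt(abs(fp$summary$centroidP), 0.05)
})

test_that("elongated pore fields score filamentarity over planarity", {
  nf <- nanoporeFixture()
  fp <- fpDiagram(nf$labels)
  expect_gt(fp$summary$centroidF, fp$summary$centroidP)
  expect_gt(fp$summary$centroidF, 0.05)
})

test_that("single label yields a one-row table; missing labels error", {
  ball <- ballFixture(R = 8, n = 24)
  lv <- labelComponents(ball$volume, 26)
  fp <- fpDiagram(lv)
  expect_identical(nrow(fp$table), 1L)
  expect_error(minkowskiFunctionals(lv, 2), "does not exist")
})
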