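test_that("occupancy-versus-force patterns classify by sign signature", {
  cls <- function(v) classifyResponse(v)@pattern
  # the four canonical panel behaviours at the 0.025 tolerance
  expect_equal(cls(c(0.44, 0.37, 0.24, 0.19)), "slip")
  expect_equal(cls(c(0.44, 0.67, 0.83, 0.39)), "catch-slip")
  expect_equal(cls(c(0.77, 0.61, 0.66, 0.58)), "slip-catch-slip")
  expect_equal(cls(c(0.23, 0.48, 0.25, 0.33)), "catch-slip-catch")
  expect_equal(cls(c(0.50, 0.50, 0.50, 0.50)), "insensitive")
  # sub-tolerance wobbles are flat: (+0.04, -0.01, -0.18) -> catch-slip
  expect_equal(cls(c(0.54, 0.58, 0.57, 0.39)), "catch-slip")
  # pure monotone increase has no named class
  expect_equal(cls(c(0.1, 0.3, 0.5, 0.7)), "other")
  expect_error(classifyResponse(c(0.1, 0.2)), ">= 3")
  expect_error(classifyResponse(c(0.1, 0.2, 0.3), forces = c(0, 50, 25)),
               "increasing")
})

test_that("classification of the printed force panel recovers four groups", {
  fp <- readOccupancyTable(tableFixture("force_panel_hbond_occupancy.tsv"))
  cls <- classifyOccupancyTable(fp, epsilon = 0.025)
  expect_equal(nrow(cls), 11)
  memb <- split(paste0(cls$ligand_residue, "-", cls$receptor_residue),
                cls$pattern)
  expect_setequal(memb[["slip"]], c("E243-K19", "E282-K19"))
  expect_setequal(memb[["catch-slip"]],
                  c("E252-K37", "E252-S39", "E252-R64", "E261-K237",
                    "K278-E40", "S288-D235"))
  expect_setequal(memb[["slip-catch-slip"]], c("K244-D18", "Y251-R64"))
  expect_setequal(memb[["catch-slip-catch"]], c("D259-K231"))
})

test_that("transition force finds extremes with low-force tie breaking", {
  f <- c(0, 25, 50, 75)
  expect_equal(transitionForce(f, c(1, 0.06, 0.11, 1.98), "min")$force, 25)
  expect_equal(transitionForce(f, c(4.44, 5.83, 5.53, 4.22), "max")$force, 25)
  # strictly increasing series: minimum at the first force
  expect_equal(transitionForce(f, c(1, 2, 3, 4), "min")$force, 0)
  tie <- transitionForce(f, c(0.2, 0.1, 0.1, 0.5), "min")
  expect_equal(tie$force, 25)
  expect_true(tie$tied)
  # invariance under monotone rescaling
  v <- c(3, 1, 2, 5)
  expect_equal(transitionForce(f, v, "min")$force,
               transitionForce(f, exp(v), "min")$force)
  expect_error(transitionForce(c(0, 25), c(1, 2), "min"), ">= 3")
  expect_error(transitionForce(c(0, 0, 25), c(1, 2, 3), "min"), "distinct")
})

test_that("segmented Pearson matches the direct formula and flags degeneracy", {
  f <- c(0, 10, 20, 30, 40, 50)
  v <- 2 * f + 3
  sp <- segmentedPearson(f, v, 20)
  expect_equal(sp$r, c(1, 1))
  spd <- segmentedPearson(f, -v, 20)
  expect_equal(spd$r, c(-1, -1))
  # seeded noisy linear data against the direct formula
  set.seed(77)
  vv <- 0.5 * f + rnorm(6)
  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  sp2 <- segmentedPearson(f, vv, 20)
  expect_equal(sp2$r[1], direct(f[f <= 20], vv[f <= 20]), tolerance = 1e-12)
  expect_equal(sp2$r[2], direct(f[f > 20], vv[f > 20]), tolerance = 1e-12)
  # two-point segments are +/-1 by construction and flagged
  sp3 <- segmentedPearson(c(0, 25, 50, 75), c(1, 2, 1.5, 3), 25)
  expect_equal(sp3$flag, c("two-point", "two-point"))
  # constant segment yields a flag, not a crash
  sp4 <- segmentedPearson(f, c(1, 1, 1, 2, 3, 4), 20)
  expect_equal(sp4$flag[1], "constant")
  expect_true(is.na(sp4$r[1]))
})

test_that("Gaussian histogram fit recovers seeded normal counts", {
  set.seed(40)
  x <- round(rnorm(10000, 6.9, 1.4))
  g <- fitGaussianHist(x)
  expect_equal(g@mean, 6.9, tolerance = 0.1)
  expect_equal(g@sigma, 1.4, tolerance = 0.15)
  # symmetric two-point histogram is degenerate (2 distinct values)
  expect_error(fitGaussianHist(rep(c(5L, 7L), 50)), ">= 3 distinct")
  # residual decreases with sample size
  set.seed(41)
  gSmall <- fitGaussianHist(round(rnorm(200, 6.9, 1.4)))
  expect_lt(g@residualNorm, gSmall@residualNorm)
})

test_that("rupture force reads the ramp peak", {
  # noiseless triangular ramp: peak at k*v*t_rupture
  tr <- genRampClampTrace(velocity = 3, duration = 10, ruptureTime = 7.2)
  rf <- ruptureForce(tr)
  expect_equal(rf$force, 13.89 * 3 * 7.2, tolerance = 1e-9)
  expect_equal(rf$time, 7.2, tolerance = 0.02)
  # seeded noise sigma = 5 pN: peak within 3 sigma
  trN <- genRampClampTrace(velocity = 3, duration = 10, ruptureTime = 7.2,
                           noiseSd = 5, seed = 13)
  expect_lt(abs(ruptureForce(trN)$force - 300), 3 * 5 + 5)
  # monotone ramp: last sample
  mono <- genRampClampTrace(velocity = 2, duration = 5)
  expect_equal(ruptureForce(mono)$force, 13.89 * 2 * 5, tolerance = 1e-9)
  expect_error(ruptureForce(new("ForceTrace", time = numeric(0),
                                force = numeric(0))), "empty")
})

test_that("force traces round-trip through TSV", {
  tr <- genRampClampTrace(velocity = 3, duration = 2, clampForce = 40)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeForceTrace(tr, f)
  tr2 <- readForceTrace(f)
  expect_equal(tr2@time, tr@time)
  expect_equal(tr2@force, tr@force)
  expect_equal(tr2@phase, tr@phase)
})
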