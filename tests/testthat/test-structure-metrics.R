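test_that("Kabsch superposition recovers rigid motions and closed forms", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(kabschSuperpose(ref, ref)@rmsd, 0, tolerance = 1e-12)
  R <- randomRotation()
  mob <- sweep(ref %*% R, 2, c(5, -2, 9), `+`)
  sup <- kabschSuperpose(mob, ref)
  expect_lt(sup@rmsd, 1e-6)
  expect_equal(det(sup@rotation), 1, tolerance = 1e-9)
  expect_equal(applySuperposition(sup, mob), ref, tolerance = 1e-8)
  # closed form: two points displaced +/-1 A among N total, arranged so
  # the optimal rotation and translation stay the identity
  cloud <- matrix(rnorm(24, sd = 4), 8, 3)
  cloud <- sweep(cloud, 2, colMeans(cloud))
  refN <- rbind(cloud, c(0, 0, 0), c(0, 0, 0))
  mobN <- rbind(cloud, c(1, 0, 0), c(-1, 0, 0))
  N <- nrow(refN)
  expect_equal(kabschSuperpose(mobN, refN)@rmsd, sqrt(2 / N),
               tolerance = 1e-9)
  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ]), ">= 3")
  expect_error(kabschSuperpose(ref, ref[1:5, ]), "identical dimensions")
})

test_that("RMSD series is zero for static input and matches bio3d on jitter", {
  gen <- genInterfaceTrajectory(list(bondSpec(1)), nFrames = 5, seed = 2)
  tr <- gen$trajectory  # omega*=1: geometry never moves
  ca <- selectAtoms(tr, "name CA N O")
  r <- caRmsdSeries(tr, ca)
  expect_equal(r, rep(0, 5), tolerance = 1e-10)
  expect_equal(r[1], 0)
  # jittered copies: cross-check every frame against the bio3d oracle
  set.seed(31)
  base <- matrix(rnorm(45, sd = 6), 15, 3)
  nfr <- 6
  coords <- array(NA_real_, c(15, 3, nfr))
  coords[, , 1] <- base
  for (f in 2:nfr) coords[, , f] <- base + rnorm(45, sd = 0.4)
  topo <- data.frame(eleno = 1:15, elety = "CA", resid = "GLY",
                     resno = 1:15, chain = "A", stringsAsFactors = FALSE)
  trj <- Trajectory(topo, coords)
  mine <- caRmsdSeries(trj, selectAtoms(trj, "name CA"))
  oracle <- vapply(seq_len(nfr), function(f) suppressWarnings({
    fit <- bio3d::fit.xyz(fixed = as.vector(t(base)),
                          mobile = as.vector(t(coords[, , f])))
    bio3d::rmsd(as.vector(t(base)), fit)
  }), numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-3)  # bio3d prints 3 decimals
})

test_that("RMSD under pure rigid motion vanishes after superposition", {
  set.seed(4)
  gen <- genInterfaceTrajectory(list(bondSpec(1), bondSpec(1)),
                                nFrames = 4, seed = 9)
  tr <- rigidMove(gen$trajectory, randomRotation(), c(3, 4, 5))
  # every frame differs from frame 1 only by the (same) rigid move applied
  # to identical geometry, so superposed RMSD is ~0 but raw RMSD of a
  # differently-moved copy is not
  moved <- gen$trajectory@coords
  R <- randomRotation()
  for (f in 2:4) moved[, , f] <- sweep(moved[, , f] %*% R, 2, c(8, 0, -3), `+`)
  trj <- Trajectory(gen$trajectory@topology, moved)
  sel <- selectAtoms(trj, "all")
  sup <- caRmsdSeries(trj, sel)
  expect_lt(max(sup), 1e-6)
  raw <- caRmsdSeries(trj, sel, superpose = FALSE)
  expect_gt(max(raw), 1)
})

test_that("SASA of isolated and disjoint spheres matches closed forms", {
  tr <- atomCloud("C", c(0, 0, 0))
  s <- shrakeRupleySASA(tr, selectAll(tr))
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s$total, exact, tolerance = 0.01)
  # two far-apart identical spheres: additivity
  tr2 <- atomCloud(c("C", "C"), rbind(c(0, 0, 0), c(50, 0, 0)))
  s2 <- shrakeRupleySASA(tr2, selectAll(tr2))
  expect_equal(s2$total, 2 * exact, tolerance = 0.02)
  expect_equal(s2$perAtom[1], s2$perAtom[2])
  expect_error(shrakeRupleySASA(atomCloud("XX", c(0, 0, 0)),
                                selectAll(atomCloud("XX", c(0, 0, 0)))),
               "unknown element")
})

test_that("overlapping-sphere SASA matches the spherical-cap oracle", {
  for (d in c(2.0, 3.5, 5.0)) {
    tr <- atomCloud(c("C", "N"), rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- shrakeRupleySASA(tr, selectAll(tr))
    oracle <- twoSphereAccessible(1.7, 1.55, d) +
              twoSphereAccessible(1.55, 1.7, d)
    expect_equal(s$total, oracle, tolerance = 0.02)
  }
})

test_that("SASA decreases monotonically as context atoms are added", {
  set.seed(19)
  pos <- matrix(rnorm(30, sd = 2.5), 10, 3)
  tr <- atomCloud(rep("C", 10), pos)
  partial <- shrakeRupleySASA(tr, selectAtoms(tr, "resid 1-5"))
  full <- shrakeRupleySASA(tr, selectAll(tr))
  expect_lte(sum(full$perAtom[1:5]), partial$total + 1e-9)
})

test_that("buried SASA is symmetric, non-negative and zero when separated", {
  gen <- genInterfaceTrajectory(list(bondSpec(1)), nFrames = 1, seed = 1)
  tr <- gen$trajectory
  A <- selectAtoms(tr, "chain A"); B <- selectAtoms(tr, "chain B")
  bAB <- buriedSASA(tr, A, B)
  bBA <- buriedSASA(tr, B, A)
  expect_equal(bAB, bBA, tolerance = 1e-9)
  expect_gt(bAB, 0)
  # separate the chains far beyond reach
  far <- tr@coords
  bIdx <- B@indices
  far[bIdx, 1, 1] <- far[bIdx, 1, 1] + 100
  trFar <- Trajectory(tr@topology, far)
  expect_equal(buriedSASA(trFar, selectAtoms(trFar, "chain A"),
                          selectAtoms(trFar, "chain B")), 0,
               tolerance = 1e-9)
  expect_error(buriedSASA(tr, A, A), "overlap")
})

test_that("helix axis recovery, orientation and equivariance", {
  ca <- genHelix(20)
  ax <- helixAxis(ca)
  expect_lt(acos(min(1, abs(ax@direction[3]))) * 180 / pi, 2)
  expect_gt(ax@direction[3], 0)  # oriented N -> C (+z here)
  # reversing residue order flips the direction
  axRev <- helixAxis(ca[20:1, ])
  expect_equal(axRev@direction, -ax@direction, tolerance = 1e-9)
  # collinear points: exact direction
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  expect_equal(helixAxis(line)@direction, c(0, 0, 1), tolerance = 1e-12)
  expect_error(helixAxis(ca[1:3, ]), ">= 4")
  # equivariance: rotating the generation rotates the recovered axis
  set.seed(23)
  R <- randomRotation()
  axR <- helixAxis(ca %*% t(R))
  expect_equal(axR@direction, as.numeric(R %*% ax@direction),
               tolerance = 1e-6)
  # minimal 4-residue helix is accepted
  expect_s4_class(helixAxis(genHelix(4)), "HelixAxis")
})

test_that("inter-helix angles cover parallel, orthogonal and antiparallel", {
  mk <- function(v) new("HelixAxis", origin = c(0, 0, 0),
                        direction = v / sqrt(sum(v^2)))
  expect_equal(interhelixAngle(mk(c(0, 0, 1)), mk(c(0, 0, 1))), 0)
  expect_equal(interhelixAngle(mk(c(1, 0, 0)), mk(c(0, 1, 0))), 90)
  expect_equal(interhelixAngle(mk(c(0, 0, 1)), mk(c(0, 0, -1))), 180)
})

test_that("centroid and atom-pair distances obey their contracts", {
  # unit-mass two-atom body at +/-1 on x; point at (3,0,0) -> 3 A
  topo <- data.frame(eleno = 1:3, elety = c("CA", "CA", "CA"),
                     resid = "GLY", resno = 1:3, chain = c("A", "A", "B"),
                     stringsAsFactors = FALSE)
  xyz <- rbind(c(-1, 0, 0), c(1, 0, 0), c(3, 0, 0))
  tr <- Trajectory(topo, xyz)
  body <- selectAtoms(tr, "chain A")
  pt <- selectAtoms(tr, "chain B")
  expect_equal(centroidDistance(tr, body, pt), 3.0)
  # translation invariance
  trT <- rigidMove(tr, diag(3), c(7, -2, 4))
  expect_equal(centroidDistance(trT, selectAtoms(trT, "chain A"),
                                selectAtoms(trT, "chain B")), 3.0,
               tolerance = 1e-9)
  # atom at the centre of mass
  one <- selectAtoms(tr, "resid 1")
  xyz0 <- rbind(c(2, 2, 2), c(2, 2, 2), c(9, 9, 9))
  tr0 <- Trajectory(topo, xyz0)
  expect_equal(centroidDistance(tr0, selectAtoms(tr0, "resid 1"),
                                selectAtoms(tr0, "resid 2")), 0)
  # atom-pair distance basics and rotation invariance
  a <- selectAtoms(tr, "resid 1"); b <- selectAtoms(tr, "resid 2")
  expect_equal(atomPairDistance(tr, a, b), 2.0)
  set.seed(3)
  trR <- rigidMove(tr, randomRotation(), c(1, 2, 3))
  expect_equal(atomPairDistance(trR, selectAtoms(trR, "resid 1"),
                                selectAtoms(trR, "resid 2")), 2.0,
               tolerance = 1e-9)
  expect_error(centroidDistance(tr, body, selectAtoms(tr, "chain A")),
               "exactly one")
})
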