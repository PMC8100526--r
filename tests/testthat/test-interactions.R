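test_that("hydrogen-bond criteria are strict at both cutoffs", {
  present <- function(tr) {
    nrow(detectHBonds(tr, selectAtoms(tr, "chain A"),
                      selectAtoms(tr, "chain B")))
  }
  expect_equal(present(hbondToyFrame(3.0, 10)), 1)  # inside both cutoffs
  expect_equal(present(hbondToyFrame(3.6, 0)), 0)   # distance fail
  expect_equal(present(hbondToyFrame(3.5, 0)), 0)   # boundary: strict <
  expect_equal(present(hbondToyFrame(3.0, 35)), 0)  # angle fail
  # just inside the boundary
  expect_equal(present(hbondToyFrame(3.4999, 0)), 1)
})

test_that("hydrogen-free fallback is opt-in and uses the heavy-atom angle", {
  # same toy without the hydrogen: default criteria find nothing
  topo <- data.frame(
    eleno = 1:3, elety = c("CA", "N", "O"),
    resid = c("GLY", "GLY", "GLY"), resno = c(1L, 1L, 2L),
    chain = c("A", "A", "B"), stringsAsFactors = FALSE)
  xyz <- rbind(c(-1.45, 0, 0), c(0, 0, 0), c(3.0, 0, 0))
  tr <- Trajectory(topo, xyz)
  A <- selectAtoms(tr, "chain A"); B <- selectAtoms(tr, "chain B")
  expect_equal(nrow(detectHBonds(tr, A, B)), 0)
  expect_equal(nrow(detectHBonds(tr, A, B, useHeavyAtomFallback = TRUE)), 1)
  # acceptor on the antecedent side (angle < 90): rejected by the fallback
  xyz2 <- xyz; xyz2[3, ] <- c(-1.2, 2.8, 0)
  tr2 <- Trajectory(topo, xyz2)
  expect_equal(nrow(detectHBonds(tr2, A, B, useHeavyAtomFallback = TRUE)), 0)
})

test_that("salt bridges use side-chain atoms with an inclusive 4 A cutoff", {
  present <- function(tr) {
    nrow(detectSaltBridges(tr, selectAtoms(tr, "chain A"),
                           selectAtoms(tr, "chain B")))
  }
  expect_equal(present(saltToyFrame(3.8)), 1)
  expect_equal(present(saltToyFrame(4.0)), 1)   # "within 4 A": inclusive
  expect_equal(present(saltToyFrame(4.2)), 0)
  # backbone O of Asp near Lys NZ does not count
  topo <- data.frame(
    eleno = 1:2, elety = c("O", "NZ"), resid = c("ASP", "LYS"),
    resno = c(10L, 20L), chain = c("A", "B"), stringsAsFactors = FALSE)
  tr <- Trajectory(topo, rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_equal(present(tr), 0)
})

test_that("empty selections warn and return no bonds", {
  tr <- hbondToyFrame(3.0, 10)
  empty <- selectAtoms(tr, "resid 99")
  expect_warning(k <- detectHBonds(tr, empty, selectAtoms(tr, "chain B")),
                 "empty")
  expect_equal(nrow(k), 0)
})

test_that("detection is invariant under rigid motion and monotone in cutoffs", {
  gen <- genInterfaceTrajectory(list(bondSpec(0.5), bondSpec(0.3)),
                                nFrames = 30, seed = 5)
  tr <- gen$trajectory
  A <- selectAtoms(tr, "chain A"); B <- selectAtoms(tr, "chain B")
  bp <- bondPresence(tr, A, B)
  set.seed(42)
  trR <- rigidMove(tr, randomRotation(), c(12.3, -4.5, 6.7))
  bpR <- bondPresence(trR, selectAtoms(trR, "chain A"),
                      selectAtoms(trR, "chain B"))
  expect_equal(bpR@presence, bp@presence)
  expect_equal(bpR@keys, bp@keys)
  # loosening criteria never removes a detected bond
  loose <- bondPresence(tr, A, B, hbond = hbondCriteria(4.5, 45))
  ksTight <- do.call(paste, bp@keys)
  ksLoose <- do.call(paste, loose@keys)
  expect_true(all(ksTight %in% ksLoose))
  m <- match(ksTight, ksLoose)
  expect_true(all(loose@presence[m, ][bp@presence]))
})

test_that("presence equals the generator's hidden state sequence", {
  gen <- genInterfaceTrajectory(
    list(bondSpec(0.2), bondSpec(0.6), bondSpec(0.9)),
    nFrames = 150, seed = 21)
  tr <- gen$trajectory
  bp <- bondPresence(tr, selectAtoms(tr, "chain A"),
                     selectAtoms(tr, "chain B"))
  expect_equal(nrow(bp@keys), 3)
  # generator order is by residue number, matching the key sort
  expect_equal(bp@presence, gen$presence)
})

test_that("occupancy is the presence fraction with sane edge cases", {
  expect_equal(bondOccupancy(rep(c(TRUE, FALSE), c(40, 60))), 0.40)
  expect_equal(bondOccupancy(rep(FALSE, 10)), 0)
  expect_equal(bondOccupancy(rep(TRUE, 10)), 1)
  expect_error(bondOccupancy(logical(0)), "zero frames")
})

test_that("mean N_HB equals the sum of occupancies (exact identity)", {
  gen <- genInterfaceTrajectory(
    list(bondSpec(0.25), bondSpec(0.5), bondSpec(0.75), bondSpec(1),
         bondSpec(0)),
    nFrames = 120, seed = 8)
  tr <- gen$trajectory
  A <- selectAtoms(tr, "chain A"); B <- selectAtoms(tr, "chain B")
  nhb <- hbondCountSeries(tr, A, B)
  bp <- bondPresence(tr, A, B)
  tab <- occupancyFromPresence(bp, "t")
  expect_equal(nhb$mean, sum(occupancyRecords(tab)$occupancy),
               tolerance = 1e-12)
  # frame with a known count
  expect_equal(nhb$counts[1], sum(gen$presence[, 1]))
})

test_that("two bonds between one residue pair stay distinct keys", {
  # one ligand residue with two donors (N and OG) to two receptor acceptors
  topo <- data.frame(
    eleno = 1:6, elety = c("N", "H", "OG", "HG", "O", "OD1"),
    resid = c("SER", "SER", "SER", "SER", "ASP", "ASP"),
    resno = c(1L, 1L, 1L, 1L, 2L, 2L),
    chain = c("A", "A", "A", "A", "B", "B"), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(0, 3, 0), c(1.01, 3, 0),
               c(2.9, 0, 0), c(2.9, 3, 0))
  tr <- Trajectory(topo, xyz)
  k <- detectHBonds(tr, selectAtoms(tr, "chain A"),
                    selectAtoms(tr, "chain B"))
  expect_equal(nrow(k), 2)
  expect_setequal(k$donor_atom, c("N", "OG"))
  expect_equal(unique(paste(k$ligand_resid, k$receptor_resid)), "1 2")
})
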