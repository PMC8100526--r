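modelTable <- function() readOccupancyTable(
  tableFixture("model_hbond_occupancy.tsv"))

test_that("pair probability follows the independence product", {
  expect_equal(pairProbability(0.5), 0.5)
  expect_equal(pairProbability(c(0.2, 0.5)), 0.6)
  expect_equal(pairProbability(c(1.0, 0.3)), 1.0)
  expect_equal(pairProbability(c(0, 0, 0)), 0)
  expect_error(pairProbability(numeric(0)), ">= 1")
  expect_error(pairProbability(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("residue-level binding probability multiplies over partners", {
  tab <- modelTable()
  # K278 pairs with E40 (0.32), Q66 (0.27), R64 (0.16) under model II:
  # P = 1 - 0.68 * 0.73 * 0.84 = 0.583024
  expect_equal(residueProbability(tab, "K278", "ligand", "model_II"),
               0.583024, tolerance = 1e-12)
  # single-partner, single-bond residue: P equals its omega
  expect_equal(residueProbability(tab, "D18", "receptor", "model_II"), 0.77)
  # all-zero partners give P = 0
  expect_equal(residueProbability(tab, "R216", "ligand", "model_I"), 0)
  expect_error(residueProbability(tab, "K999", "ligand", "model_II"),
               "not found")
})

test_that("complex dissociation reproduces the printed model values", {
  tab <- modelTable()
  dI <- complexDissociation(tab, "model_I")
  # independent arithmetic oracle: direct product over the 7 occupancies
  wI <- c(0.39, 0.62, 0.23, 0.35, 0.31, 0.17, 0.67)
  expect_equal(dI@PD, prod(1 - wI), tolerance = 1e-12)
  expect_equal(dI@PD, 0.0219, tolerance = 5e-3)
  dII <- complexDissociation(tab, "model_II")
  wII <- c(0.77, 0.66, 0.52, 0.44, 0.44, 0.34, 0.32, 0.54, 0.31, 0.27,
           0.23, 0.16, 0.16, 0.16)
  expect_equal(dII@PD, prod(1 - wII), tolerance = 1e-12)
  expect_true(dII@PD > 4.5e-4 && dII@PD < 6.5e-4)
})

test_that("degenerate dissociation cases behave as defined", {
  rec <- data.frame(
    condition = "c", ligand_chain = "L", ligand_resid = 1L,
    ligand_resname = "GLU", receptor_chain = "R", receptor_resid = 2L,
    receptor_resname = "LYS", donor_atom = NA_character_,
    acceptor_atom = NA_character_, kind = "hbond", occupancy = 0.77,
    stringsAsFactors = FALSE)
  tab <- new("OccupancyTable", records = rec)
  expect_equal(complexDissociation(tab, "c")@PD, 1 - 0.77)
  # all-zero occupancies: no bond ever survives, P_D = 1
  rec0 <- rec; rec0$occupancy <- 0
  expect_equal(complexDissociation(new("OccupancyTable", records = rec0),
                                   "c")@PD, 1)
  # an always-formed bond pins P_D at 0
  rec1 <- rec; rec1$occupancy <- 1
  expect_equal(complexDissociation(new("OccupancyTable", records = rec1),
                                   "c")@PD, 0)
  # compatibility flag returns the complement of the product
  expect_equal(complexDissociation(tab, "c", complement = TRUE)@PD, 0.77)
})

test_that("side products agree with the all-bond product on random tables", {
  set.seed(101)
  for (i in 1:60) {
    tab <- randomOccupancyTable(nPairs = sample(2:8, 1))
    d <- complexDissociation(tab, "c1")
    r <- occupancyRecords(tab)
    direct <- prod(1 - r$occupancy)
    expect_equal(d@PD, direct, tolerance = 1e-12)
    lig <- d@perResidue[d@perResidue$side == "ligand", ]
    rcp <- d@perResidue[d@perResidue$side == "receptor", ]
    expect_equal(prod(1 - lig$P), direct, tolerance = 1e-12)
    expect_equal(prod(1 - rcp$P), direct, tolerance = 1e-12)
    expect_equal(prod(1 - d@perPair$p), direct, tolerance = 1e-12)
    expect_true(all(d@perResidue$P >= 0 & d@perResidue$P <= 1))
  }
})

test_that("increasing any occupancy strictly decreases P_D", {
  set.seed(7)
  tab <- randomOccupancyTable(nPairs = 4)
  base <- complexDissociation(tab, "c1")@PD
  r <- occupancyRecords(tab)
  i <- sample(nrow(r), 1)
  r$occupancy[i] <- min(0.999, r$occupancy[i] + 0.05)
  up <- complexDissociation(new("OccupancyTable", records = r), "c1")@PD
  expect_lt(up, base)
})

test_that("log-space products survive large tables without underflow", {
  rec <- do.call(rbind, lapply(1:500, function(i) data.frame(
    condition = "c", ligand_chain = "L", ligand_resid = i,
    ligand_resname = "GLU", receptor_chain = "R", receptor_resid = i,
    receptor_resname = "LYS", donor_atom = NA_character_,
    acceptor_atom = NA_character_, kind = "hbond", occupancy = 0.9,
    stringsAsFactors = FALSE)))
  d <- complexDissociation(new("OccupancyTable", records = rec), "c")
  # PD itself underflows double precision; the log-scale result is exact
  expect_equal(d@logPD, 500 * log(0.1), tolerance = 1e-9)
  # and f_D between two such conditions is still well-defined
  rec2 <- rec; rec2$condition <- "c2"; rec2$occupancy <- 0.89
  tab2 <- new("OccupancyTable", records = rbind(rec, rec2))
  fd <- normalizedDissociation(tab2, "c2", "c")@fD
  expect_equal(log(fd), 500 * (log(0.11) - log(0.1)), tolerance = 1e-9)
})

test_that("normalised dissociation and expected bond count track the panel", {
  fp <- readOccupancyTable(tableFixture("force_panel_hbond_occupancy.tsv"))
  # f_D at the reference force is identically 1
  expect_equal(normalizedDissociation(fp, 0, 0)@fD, 1.0)
  # independent oracle: direct products over the printed columns
  w0 <- c(0.08, 0.44, 0.10, 0.54, 0.32, 0.52, 0.77, 0.34, 0.23, 0.44, 0.66)
  w25 <- c(0.19, 0.67, 0.74, 0.58, 0.62, 0.79, 0.61, 0.14, 0.48, 0.37, 0.64)
  w75 <- c(0.03, 0.39, 0.49, 0.39, 0.56, 0.62, 0.58, 0.16, 0.33, 0.19, 0.48)
  expect_equal(normalizedDissociation(fp, 25)@fD,
               prod(1 - w25) / prod(1 - w0), tolerance = 1e-12)
  expect_equal(normalizedDissociation(fp, 75)@fD,
               prod(1 - w75) / prod(1 - w0), tolerance = 1e-12)
  expect_equal(normalizedDissociation(fp, 25)@fD, 0.059, tolerance = 2e-2)
  expect_equal(normalizedDissociation(fp, 75)@fD, 1.98, tolerance = 2e-2)
  expect_equal(expectedBondCount(fp, 25), 5.83, tolerance = 1e-12)
  expect_equal(expectedBondCount(fp, 75), 4.22, tolerance = 1e-12)
  # undefined ratio when the reference P_D is 0
  r <- occupancyRecords(fp)
  r$occupancy[r$condition == "0"][1] <- 1
  pinned <- new("OccupancyTable", records = r)
  expect_error(normalizedDissociation(pinned, 25), "undefined")
})

test_that("composition through pair and residue stages matches direct product", {
  set.seed(55)
  tab <- randomOccupancyTable(nPairs = 6)
  r <- occupancyRecords(tab)
  d <- complexDissociation(tab, "c1")
  # rebuild P_D from the per-pair stage only
  expect_equal(prod(1 - d@perPair$p), prod(1 - r$occupancy),
               tolerance = 1e-12)
  # and each pair's p recomputed from its own bond occupancies
  key <- paste(r$ligand_resid, r$receptor_resid)
  pByPair <- vapply(split(r$occupancy, key), pairProbability, 0)
  expect_equal(prod(1 - pByPair), d@PD, tolerance = 1e-12)
})
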