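# Shared fixture builders. Everything is generated in code; no files.

# Minimal one-donor/one-acceptor frame: amide N-H on chain A, carbonyl O on
# chain B placed at donor-acceptor distance `da` with angular deviation
# `dev` (degrees) from the N->H direction.
hbondToyFrame <- function(da, dev = 0) {
  topo <- data.frame(
    eleno = 1:3, elety = c("N", "H", "O"),
    resid = c("GLY", "GLY", "GLY"), resno = c(1L, 1L, 2L),
    chain = c("A", "A", "B"), stringsAsFactors = FALSE)
  th <- dev * pi / 180
  xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(da * cos(th), da * sin(th), 0))
  Trajectory(topo, xyz)
}

# Asp/Lys side-chain pair with the O-N distance `don`.
saltToyFrame <- function(don) {
  topo <- data.frame(
    eleno = 1:4, elety = c("OD1", "CB", "NZ", "CE"),
    resid = c("ASP", "ASP", "LYS", "LYS"), resno = c(10L, 10L, 20L, 20L),
    chain = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(-1.5, 0, 0), c(don, 0, 0), c(don + 1.4, 0, 0))
  Trajectory(topo, xyz)
}

# Single-atom "trajectory" of one element at given coordinates per frame.
atomCloud <- function(elements, xyz, nframes = 1) {
  n <- length(elements)
  topo <- data.frame(
    eleno = seq_len(n), elety = elements, resid = "GLY",
    resno = seq_len(n), chain = "A", stringsAsFactors = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  coords <- array(rep(xyz, nframes), dim = c(n, 3, nframes))
  Trajectory(topo, coords)
}

# Random occupancy table: nPairs residue pairs x conditions, with a random
# number of bonds (1-3) per pair.
randomOccupancyTable <- function(nPairs, conds = "c1") {
  recs <- list()
  b <- 0L
  for (i in seq_len(nPairs)) {
    nb <- sample(1:3, 1)
    for (l in seq_len(nb)) {
      b <- b + 1L
      for (cc in conds) {
        recs[[length(recs) + 1L]] <- data.frame(
          condition = cc,
          ligand_chain = "L", ligand_resid = 100L + i,
          ligand_resname = "GLU",
          receptor_chain = "R",
          receptor_resid = 10L + sample(1:max(2, nPairs %/% 2), 1),
          receptor_resname = "LYS",
          donor_atom = paste0("b", b), acceptor_atom = "O",
          kind = "hbond", occupancy = runif(1, 0, 0.95),
          stringsAsFactors = FALSE)
      }
    }
  }
  r <- do.call(rbind, recs)
  key <- paste(r$condition, r$ligand_resid, r$receptor_resid,
               r$donor_atom)
  new("OccupancyTable", records = r[!duplicated(key), ])
}

# Rigid rotation matrix about a random axis (seeded by caller).
randomRotation <- function() {
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

# Apply a rigid motion to every frame of a trajectory.
rigidMove <- function(traj, R, t) {
  coords <- traj@coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- sweep(coords[, , f] %*% R, 2, t, `+`)
  Trajectory(traj@topology, coords, traj@time, traj@frameInterval)
}

# Accessible area of sphere 1 (radius r1, probe-expanded) partially buried
# by sphere 2 (radius r2) at centre distance d: exact spherical-cap formula,
# used as the independent oracle for the point-sampled SASA.
twoSphereAccessible <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)  # buried cap height on sphere 1
  4 * pi * R1^2 - 2 * pi * R1 * h
}

tableFixture <- function(name) {
  p <- system.file("extdata", name, package = "MechanoBond")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", name)
  p
}
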