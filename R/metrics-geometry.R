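#' @include AllClasses.R
NULL

## Standard atomic masses (u) for common protein elements.
.atomicMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

.atomMass <- function(elesy, elety = elesy) {
  key <- toupper(elesy)
  miss <- !(key %in% names(.atomicMasses))
  if (any(miss))
    stop("unknown element '", key[miss][1], "' for atom '",
         elety[miss][1], "': no atomic mass")
  unname(.atomicMasses[key])
}

#' Helix axis from ordered C-alpha coordinates
#'
#' The axis direction is the principal component (largest singular vector)
#' of the centred coordinates, with its sign fixed to have positive
#' projection onto the vector from the first to the last C-alpha, i.e.
#' oriented N-terminus to C-terminus.
#'
#' @param caCoords n x 3 matrix of C-alpha positions in N-to-C order,
#'   n >= 4.
#' @return a \linkS4class{HelixAxis}
#' @export
helixAxis <- function(caCoords) {
  caCoords <- as.matrix(caCoords)
  if (nrow(caCoords) < 4) stop("need >= 4 C-alpha positions for a helix axis")
  ctr <- colMeans(caCoords)
  X <- sweep(caCoords, 2, ctr)
  sv <- svd(X)
  dir <- sv$v[, 1]
  nc <- caCoords[nrow(caCoords), ] - caCoords[1, ]
  if (sum(dir * nc) < 0) dir <- -dir
  new("HelixAxis", origin = ctr, direction = dir / sqrt(sum(dir^2)))
}

#' Angle between two oriented helix axes
#'
#' @param a,b \linkS4class{HelixAxis} objects.
#' @return degrees in [0, 180] (oriented axes: antiparallel is 180).
#' @export
interhelixAngle <- function(a, b) {
  stopifnot(is(a, "HelixAxis"), is(b, "HelixAxis"))
  d <- sum(a@direction * b@direction)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Inter-helix angle time series
#'
#' Fits both helix axes per frame from the C-alpha atoms of two residue
#' intervals and returns their oriented angle.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param helixA,helixB \linkS4class{AtomSelection}s of the two helices'
#'   C-alpha atoms (ordered N to C by the topology).
#' @return numeric vector of degrees per frame.
#' @export
interhelixAngleSeries <- function(traj, helixA, helixB) {
  vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- frameCoords(traj, f)
    interhelixAngle(helixAxis(xyz[helixA@indices, , drop = FALSE]),
                    helixAxis(xyz[helixB@indices, , drop = FALSE]))
  }, numeric(1))
}

#' Distance from a body's centre of mass to a single atom
#'
#' Centre of mass is mass-weighted with standard atomic masses (hydrogens
#' included when present). Used e.g. to track the displacement of a loop
#' reference atom from the molecular body (L_MB).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param body non-empty \linkS4class{AtomSelection}.
#' @param pointAtom an \linkS4class{AtomSelection} resolving to exactly one
#'   atom.
#' @param frame frame index (default 1).
#' @return distance, Angstrom.
#' @export
centroidDistance <- function(traj, body, pointAtom, frame = 1L) {
  stopifnot(is(traj, "Trajectory"))
  if (length(body@indices) == 0) stop("empty body selection")
  if (length(pointAtom@indices) != 1)
    stop("pointAtom must resolve to exactly one atom (got ",
         length(pointAtom@indices), ")")
  topo <- traj@topology
  xyz <- frameCoords(traj, frame)
  m <- .atomMass(topo$elesy[body@indices], topo$elety[body@indices])
  com <- colSums(xyz[body@indices, , drop = FALSE] * m) / sum(m)
  sqrt(sum((xyz[pointAtom@indices, ] - com)^2))
}

#' Centroid-to-atom distance time series
#' @inheritParams centroidDistance
#' @return numeric vector, Angstrom per frame.
#' @export
centroidDistanceSeries <- function(traj, body, pointAtom) {
  vapply(seq_len(nFrames(traj)), function(f)
    centroidDistance(traj, body, pointAtom, frame = f), numeric(1))
}

#' Distance between two single atoms
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param a,b \linkS4class{AtomSelection}s resolving to one atom each.
#' @param frame frame index (default 1).
#' @return distance, Angstrom.
#' @export
atomPairDistance <- function(traj, a, b, frame = 1L) {
  if (length(a@indices) != 1 || length(b@indices) != 1)
    stop("both selections must resolve to exactly one atom")
  xyz <- frameCoords(traj, frame)
  sqrt(sum((xyz[a@indices, ] - xyz[b@indices, ])^2))
}

#' Pulled-to-fixed atom distance time series
#' @inheritParams atomPairDistance
#' @return numeric vector, Angstrom per frame.
#' @export
atomPairDistanceSeries <- function(traj, a, b) {
  vapply(seq_len(nFrames(traj)), function(f)
    atomPairDistance(traj, a, b, frame = f), numeric(1))
}
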