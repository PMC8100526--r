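#' @include AllClasses.R
NULL

## Bondi van der Waals radii (Angstrom).
.bondiRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                 SE = 1.90)

.vdwRadius <- function(elesy, elety = elesy) {
  key <- toupper(elesy)
  miss <- !(key %in% names(.bondiRadii))
  if (any(miss))
    stop("unknown element '", key[miss][1], "' for atom '",
         elety[miss][1], "': no van der Waals radius")
  unname(.bondiRadii[key])
}

## Deterministic quasi-uniform unit-sphere points (golden-section spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's solvent-expanded sphere (van der Waals radius plus
#' probe radius) with a deterministic quasi-uniform point set; a point is
#' accessible when outside every neighbouring atom's expanded sphere. The
#' per-atom area is the accessible fraction of 4 pi (r + probe)^2.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection an \linkS4class{AtomSelection}; only these atoms are
#'   considered (both as surfaces and as occluders).
#' @param frame frame index (default 1).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param nPoints sphere sample points per atom (default 960; precision /
#'   speed knob).
#' @return list with \code{total} (Angstrom^2), \code{perAtom} (numeric,
#'   one entry per selected atom), \code{probe}, \code{nPoints}.
#' @export
shrakeRupleySASA <- function(traj, selection, frame = 1L, probe = 1.4,
                             nPoints = 960L) {
  stopifnot(is(traj, "Trajectory"), is(selection, "AtomSelection"))
  idx <- selection@indices
  if (length(idx) == 0)
    return(list(total = 0, perAtom = numeric(0), probe = probe,
                nPoints = nPoints))
  topo <- traj@topology
  xyz <- frameCoords(traj, frame)[idx, , drop = FALSE]
  rad <- .vdwRadius(topo$elesy[idx], topo$elety[idx]) + probe
  pts <- .spherePoints(nPoints)
  n <- length(idx)
  perAtom <- numeric(n)
  ## pairwise distances once; only spheres that can intersect matter
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    area <- 4 * pi * rad[i]^2
    if (length(neigh) == 0) { perAtom[i] <- area; next }
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nPoints)
    for (j in neigh) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
             (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= rad[j]^2
    }
    perAtom[i] <- area * sum(acc) / nPoints
  }
  list(total = sum(perAtom), perAtom = perAtom, probe = probe,
       nPoints = nPoints)
}

#' Buried interface surface area
#'
#' SASA(A alone) + SASA(B alone) - SASA(A and B together), not divided by
#' two. Zero when the chains are farther apart than any expanded spheres
#' can reach.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param chainA,chainB disjoint \linkS4class{AtomSelection}s.
#' @param frame frame index (default 1).
#' @param probe probe radius, Angstrom.
#' @param nPoints sphere sample points per atom.
#' @return numeric, Angstrom^2.
#' @export
buriedSASA <- function(traj, chainA, chainB, frame = 1L, probe = 1.4,
                       nPoints = 960L) {
  if (length(intersect(chainA@indices, chainB@indices)))
    stop("chainA and chainB selections overlap")
  both <- new("AtomSelection",
              expression = paste0("(", chainA@expression, ") or (",
                                  chainB@expression, ")"),
              indices = sort(union(chainA@indices, chainB@indices)))
  sA <- shrakeRupleySASA(traj, chainA, frame, probe, nPoints)$total
  sB <- shrakeRupleySASA(traj, chainB, frame, probe, nPoints)$total
  sAB <- shrakeRupleySASA(traj, both, frame, probe, nPoints)$total
  sA + sB - sAB
}

#' Buried interface SASA time series
#'
#' @inheritParams buriedSASA
#' @return numeric vector, Angstrom^2 per frame.
#' @export
buriedSASASeries <- function(traj, chainA, chainB, probe = 1.4,
                             nPoints = 960L) {
  vapply(seq_len(nFrames(traj)), function(f)
    buriedSASA(traj, chainA, chainB, frame = f, probe = probe,
               nPoints = nPoints), numeric(1))
}
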