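#' @include AllClasses.R traj-io.R selections.R
NULL

.bondKeyCols <- c("ligand_chain", "ligand_resid", "ligand_resname",
                  "receptor_chain", "receptor_resid", "receptor_resname",
                  "donor_atom", "acceptor_atom", "donor_side", "kind")

.emptyKeys <- function() {
  df <- data.frame(
    ligand_chain = character(0), ligand_resid = integer(0),
    ligand_resname = character(0),
    receptor_chain = character(0), receptor_resid = integer(0),
    receptor_resname = character(0),
    donor_atom = character(0), acceptor_atom = character(0),
    donor_side = character(0), kind = character(0),
    stringsAsFactors = FALSE
  )
  df
}

.keyString <- function(keys) {
  do.call(paste, c(keys[.bondKeyCols[.bondKeyCols %in% names(keys)]],
                   list(sep = "|")))
}

## Static donor/acceptor chemistry resolved from the topology.
## Donors: N/O heavy atoms carrying at least one covalent hydrogen
## (attachment judged geometrically, same residue, < 1.3 A in refFrame).
## Acceptors: all N/O heavy atoms (His accepted in both tautomers since the
## unprotonated ring nitrogen is simply an N without attached H).
.hbondChemistry <- function(traj, refFrame = 1L) {
  topo <- traj@topology
  xyz <- frameCoords(traj, refFrame)
  heavyNO <- which(topo$elesy %in% c("N", "O"))
  hyd <- which(topo$elesy == "H")
  donorH <- vector("list", nrow(topo))
  if (length(hyd)) {
    for (d in heavyNO) {
      sameRes <- hyd[topo$chain[hyd] == topo$chain[d] &
                     topo$resno[hyd] == topo$resno[d]]
      if (!length(sameRes)) next
      dd <- sqrt(colSums((t(xyz[sameRes, , drop = FALSE]) - xyz[d, ])^2))
      att <- sameRes[dd < 1.3]
      if (length(att)) donorH[[d]] <- att
    }
  }
  ## heavy-atom antecedents (for the hydrogen-free fallback criterion)
  antecedent <- rep(NA_integer_, nrow(topo))
  heavy <- which(topo$elesy != "H")
  for (d in heavyNO) {
    cand <- heavy[heavy != d & topo$chain[heavy] == topo$chain[d]]
    if (!length(cand)) next
    dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[d, ])^2))
    ok <- which(dd < 1.8)
    if (length(ok)) antecedent[d] <- cand[ok[which.min(dd[ok])]]
  }
  list(heavyNO = heavyNO, donorH = donorH, antecedent = antecedent)
}

.angleDeg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  c1 <- min(1, max(-1, c1))
  acos(c1) * 180 / pi
}

## Directional scan: donors on side `from`, acceptors on side `to`.
.scanHBonds <- function(topo, xyz, chem, fromIdx, toIdx, criteria,
                        fallback) {
  donors <- intersect(chem$heavyNO, fromIdx)
  if (!fallback)
    donors <- donors[vapply(chem$donorH[donors],
                            function(h) length(h) > 0, logical(1))]
  acceptors <- intersect(chem$heavyNO, toIdx)
  out <- list()
  for (d in donors) {
    dvec <- t(xyz[acceptors, , drop = FALSE]) - xyz[d, ]
    dist <- sqrt(colSums(dvec^2))
    near <- which(dist < criteria@maxDaDistance)
    for (k in near) {
      a <- acceptors[k]
      ok <- FALSE
      if (!fallback) {
        for (h in chem$donorH[[d]]) {
          dev <- .angleDeg(xyz[h, ] - xyz[d, ], xyz[a, ] - xyz[h, ])
          if (dev < criteria@maxDhaAngle) { ok <- TRUE; break }
        }
      } else {
        ant <- chem$antecedent[d]
        if (!is.na(ant)) {
          ang <- .angleDeg(xyz[a, ] - xyz[d, ], xyz[ant, ] - xyz[d, ])
          ok <- ang > 90
        }
      }
      if (ok) out[[length(out) + 1L]] <- c(d = d, a = a)
    }
  }
  out
}

.pairsToKeys <- function(topo, pairs, ligandIdx, kind) {
  if (!length(pairs)) return(.emptyKeys())
  rows <- lapply(pairs, function(p) {
    d <- p[["d"]]; a <- p[["a"]]
    donorIsLigand <- d %in% ligandIdx
    li <- if (donorIsLigand) d else a
    ri <- if (donorIsLigand) a else d
    data.frame(
      ligand_chain = topo$chain[li], ligand_resid = topo$resno[li],
      ligand_resname = topo$resid[li],
      receptor_chain = topo$chain[ri], receptor_resid = topo$resno[ri],
      receptor_resname = topo$resid[ri],
      donor_atom = topo$elety[d], acceptor_atom = topo$elety[a],
      donor_side = if (donorIsLigand) "ligand" else "receptor",
      kind = kind, stringsAsFactors = FALSE
    )
  })
  keys <- do.call(rbind, rows)
  keys <- keys[!duplicated(.keyString(keys)), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

#' Detect interface hydrogen bonds in one frame
#'
#' A hydrogen bond is formed when the donor-acceptor distance is strictly
#' less than the distance cutoff and the donor-hydrogen-acceptor deviation
#' angle is strictly less than the angle cutoff, for some hydrogen bound to
#' the donor. Both inter-chain directions (ligand donor to receptor
#' acceptor and vice versa) are scanned. With
#' \code{useHeavyAtomFallback = TRUE} (for hydrogen-free crystal inputs) the
#' criterion becomes donor-acceptor distance below cutoff plus an
#' acceptor-donor-antecedent angle above 90 degrees.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ligand,receptor \linkS4class{AtomSelection}s on different chains.
#' @param criteria an \linkS4class{HBondCriteria}.
#' @param frame frame index (default 1).
#' @param useHeavyAtomFallback logical; default FALSE requires explicit
#'   hydrogens.
#' @return data.frame of canonical bond keys (ligand residue first); zero
#'   rows when none found.
#' @export
detectHBonds <- function(traj, ligand, receptor, criteria = hbondCriteria(),
                         frame = 1L, useHeavyAtomFallback = FALSE) {
  stopifnot(is(traj, "Trajectory"), is(criteria, "HBondCriteria"))
  li <- ligand@indices; ri <- receptor@indices
  if (!length(li) || !length(ri)) {
    warning("empty ligand or receptor selection; no bonds detectable")
    return(.emptyKeys())
  }
  chem <- .hbondChemistry(traj, frame)
  xyz <- frameCoords(traj, frame)
  topo <- traj@topology
  pairs <- c(
    .scanHBonds(topo, xyz, chem, li, ri, criteria, useHeavyAtomFallback),
    .scanHBonds(topo, xyz, chem, ri, li, criteria, useHeavyAtomFallback)
  )
  .pairsToKeys(topo, pairs, li, "hbond")
}

.acidicO <- function(topo)
  which((topo$resid == "ASP" & topo$elety %in% c("OD1", "OD2")) |
        (topo$resid == "GLU" & topo$elety %in% c("OE1", "OE2")))

.basicN <- function(topo)
  which((topo$resid == "LYS" & topo$elety == "NZ") |
        (topo$resid == "ARG" & topo$elety %in% c("NE", "NH1", "NH2")))

#' Detect interface salt bridges in one frame
#'
#' A salt bridge is scored at residue-pair level: present when any
#' side-chain carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2) lies within the
#' cutoff (inclusive) of any basic side-chain nitrogen (Lys NZ,
#' Arg NE/NH1/NH2) across the interface. Atom-name fields in the key are NA
#' because membership of the contact can migrate among equivalent
#' side-chain atoms frame to frame.
#'
#' @inheritParams detectHBonds
#' @param criteria a \linkS4class{SaltBridgeCriteria}.
#' @return data.frame of canonical bond keys, \code{kind = "saltbridge"}.
#' @export
detectSaltBridges <- function(traj, ligand, receptor,
                              criteria = saltBridgeCriteria(), frame = 1L) {
  stopifnot(is(traj, "Trajectory"), is(criteria, "SaltBridgeCriteria"))
  li <- ligand@indices; ri <- receptor@indices
  if (!length(li) || !length(ri)) {
    warning("empty ligand or receptor selection; no bonds detectable")
    return(.emptyKeys())
  }
  topo <- traj@topology
  xyz <- frameCoords(traj, frame)
  oAll <- .acidicO(topo); nAll <- .basicN(topo)
  out <- list()
  for (dir in 1:2) {
    oIdx <- intersect(oAll, if (dir == 1) li else ri)
    nIdx <- intersect(nAll, if (dir == 1) ri else li)
    for (o in oIdx) {
      if (!length(nIdx)) next
      dd <- sqrt(colSums((t(xyz[nIdx, , drop = FALSE]) - xyz[o, ])^2))
      for (n in nIdx[dd <= criteria@maxOnDistance]) {
        lig <- if (o %in% li) o else n
        rec <- if (lig == o) n else o
        out[[length(out) + 1L]] <- data.frame(
          ligand_chain = topo$chain[lig], ligand_resid = topo$resno[lig],
          ligand_resname = topo$resid[lig],
          receptor_chain = topo$chain[rec], receptor_resid = topo$resno[rec],
          receptor_resname = topo$resid[rec],
          donor_atom = NA_character_, acceptor_atom = NA_character_,
          donor_side = if (lig == n) "ligand" else "receptor",
          kind = "saltbridge", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(.emptyKeys())
  keys <- do.call(rbind, out)
  keys <- keys[!duplicated(.keyString(keys)), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

#' Per-frame bond presence across a trajectory
#'
#' Evaluates the geometric criteria independently in every frame and
#' returns, for the union of all bond keys ever observed, a logical
#' presence matrix (bonds x frames).
#'
#' @inheritParams detectHBonds
#' @param hbond an \linkS4class{HBondCriteria}, or NULL to skip H-bonds.
#' @param saltBridge a \linkS4class{SaltBridgeCriteria}, or NULL (default)
#'   to skip salt bridges.
#' @return a \linkS4class{BondPresence}
#' @export
bondPresence <- function(traj, ligand, receptor, hbond = hbondCriteria(),
                         saltBridge = NULL, useHeavyAtomFallback = FALSE) {
  stopifnot(is(traj, "Trajectory"))
  nfr <- nFrames(traj)
  topo <- traj@topology
  li <- ligand@indices; ri <- receptor@indices
  ## donor/acceptor chemistry is topological: resolve it once (frame 1)
  chem <- if (!is.null(hbond)) .hbondChemistry(traj, 1L) else NULL
  perFrame <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    keys <- .emptyKeys()
    if (!is.null(hbond) && length(li) && length(ri)) {
      xyz <- frameCoords(traj, f)
      pairs <- c(
        .scanHBonds(topo, xyz, chem, li, ri, hbond, useHeavyAtomFallback),
        .scanHBonds(topo, xyz, chem, ri, li, hbond, useHeavyAtomFallback))
      keys <- rbind(keys, .pairsToKeys(topo, pairs, li, "hbond"))
    }
    if (!is.null(saltBridge))
      keys <- rbind(keys, detectSaltBridges(traj, ligand, receptor,
                                            saltBridge, frame = f))
    perFrame[[f]] <- keys
  }
  allKeys <- do.call(rbind, perFrame)
  if (nrow(allKeys) == 0) {
    return(new("BondPresence", keys = .emptyKeys(),
               presence = matrix(logical(0), nrow = 0, ncol = nfr)))
  }
  uniq <- allKeys[!duplicated(.keyString(allKeys)), , drop = FALSE]
  ## deterministic order: ligand residue, receptor residue, atoms
  ord <- order(uniq$ligand_chain, uniq$ligand_resid, uniq$receptor_chain,
               uniq$receptor_resid, uniq$donor_atom, uniq$acceptor_atom,
               uniq$kind, method = "radix")
  uniq <- uniq[ord, , drop = FALSE]
  rownames(uniq) <- NULL
  ks <- .keyString(uniq)
  pres <- matrix(FALSE, nrow = nrow(uniq), ncol = nfr)
  for (f in seq_len(nfr))
    pres[, f] <- ks %in% .keyString(perFrame[[f]])
  new("BondPresence", keys = uniq, presence = pres)
}

#' Occupancy (survival ratio) of one presence series
#'
#' @param present logical vector, one entry per frame.
#' @return fraction of frames present, in [0, 1].
#' @export
bondOccupancy <- function(present) {
  if (length(present) == 0) stop("occupancy undefined for zero frames")
  mean(as.logical(present))
}

#' Occupancies of all bonds in a presence object
#'
#' @param bp a \linkS4class{BondPresence}.
#' @param condition label for the resulting table column (model id or
#'   force in pN).
#' @return an \linkS4class{OccupancyTable} (empty-bond input gives a
#'   zero-bond table is not representable; an error is raised instead).
#' @export
occupancyFromPresence <- function(bp, condition = "trajectory") {
  stopifnot(is(bp, "BondPresence"))
  if (ncol(bp@presence) == 0) stop("occupancy undefined for zero frames")
  if (nrow(bp@keys) == 0)
    stop("no bonds observed; an OccupancyTable needs >= 1 record")
  rec <- bp@keys
  rec$occupancy <- rowMeans(bp@presence)
  rec$condition <- as.character(condition)
  rec$donor_side <- NULL
  new("OccupancyTable", records = rec[, occupancyRecordCols])
}

#' Interface hydrogen-bond count per frame (N_HB)
#'
#' Counts distinct inter-chain H-bond keys per frame. The mean over frames
#' equals the sum of per-bond occupancies over the same key set (an exact
#' identity).
#'
#' @inheritParams detectHBonds
#' @return list with \code{counts} (integer per frame) and \code{mean}.
#' @export
hbondCountSeries <- function(traj, ligand, receptor,
                             criteria = hbondCriteria(),
                             useHeavyAtomFallback = FALSE) {
  bp <- bondPresence(traj, ligand, receptor, hbond = criteria,
                     saltBridge = NULL,
                     useHeavyAtomFallback = useHeavyAtomFallback)
  counts <- if (nrow(bp@presence) == 0) rep(0L, ncol(bp@presence))
            else as.integer(colSums(bp@presence))
  list(counts = counts, mean = mean(counts))
}
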