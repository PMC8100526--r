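#' @include AllClasses.R occupancy-io.R
NULL

## log Prod(1 - w), short-circuiting w == 1, robust for P_D << 1.
.logProdOneMinus <- function(omega) {
  if (any(omega >= 1)) return(-Inf)
  sum(log1p(-omega))
}

#' Residue-pair binding probability from its bond occupancies
#'
#' Under the assumption that each interface hydrogen bond forms and breaks
#' independently of the others, the probability that residue i of the
#' ligand binds residue j of the receptor through at least one of its
#' M_ij bonds is p_ij = 1 - prod_l (1 - omega_l).
#'
#' @param omega numeric vector of bond occupancies for one residue pair,
#'   each in [0, 1], non-empty.
#' @return probability in [0, 1].
#' @export
pairProbability <- function(omega) {
  if (length(omega) == 0) stop("need >= 1 bond occupancy")
  if (any(!is.finite(omega)) || any(omega < 0 | omega > 1))
    stop("occupancies must lie in [0, 1]")
  -expm1(.logProdOneMinus(omega))
}

## per-pair probabilities for one condition; returns data.frame
.pairTable <- function(rec) {
  lig <- paste(rec$ligand_chain, rec$ligand_resid, rec$ligand_resname,
               sep = "/")
  recp <- paste(rec$receptor_chain, rec$receptor_resid,
                rec$receptor_resname, sep = "/")
  sp <- split(seq_len(nrow(rec)), paste(lig, recp, sep = "~"))
  out <- lapply(sp, function(ii) {
    data.frame(
      ligand_residue = .residueLabel(rec$ligand_resname[ii[1]],
                                     rec$ligand_resid[ii[1]]),
      receptor_residue = .residueLabel(rec$receptor_resname[ii[1]],
                                       rec$receptor_resid[ii[1]]),
      ligand_id = lig[ii[1]], receptor_id = recp[ii[1]],
      n_bonds = length(ii),
      p = pairProbability(rec$occupancy[ii]),
      log_q = .logProdOneMinus(rec$occupancy[ii]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$ligand_id, res$receptor_id), , drop = FALSE]
}

#' Residue-level binding probability
#'
#' P_{j,L} (resp. P_{j,R}): the probability that a given ligand (receptor)
#' residue binds the opposite chain through at least one of its partners,
#' 1 - prod over partner residues of (1 - p_pair).
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param residue residue label such as \code{"K278"} (one- or
#'   three-letter code plus author residue number).
#' @param side \code{"ligand"} or \code{"receptor"}: which side the residue
#'   belongs to.
#' @param condition condition label.
#' @return probability in [0, 1].
#' @export
residueProbability <- function(table, residue, side = c("ligand", "receptor"),
                               condition) {
  side <- match.arg(side)
  rec <- conditionRecords(table, condition)
  pairs <- .pairTable(rec)
  lab <- .parseResidueLabel(residue)
  want <- .residueLabel(lab$resname, lab$resid)
  col <- if (side == "ligand") "ligand_residue" else "receptor_residue"
  hit <- pairs[[col]] == want
  if (!any(hit))
    stop("residue ", want, " not found on ", side, " side for condition '",
         condition, "'; known: ",
         paste(sort(unique(pairs[[col]])), collapse = ", "))
  -expm1(sum(pairs$log_q[hit]))
}

#' Complex dissociation probability for one condition
#'
#' Under bond independence, the probability that the ligand is dissociated
#' from the receptor is the probability that no interface bond survives:
#' P_D = prod over all bonds of (1 - omega), which factorises identically
#' through residue pairs (prod (1 - p_ij)) and through either side's
#' residues (prod_j (1 - P_j,L) = prod_j (1 - P_j,R)). The product is
#' evaluated as an exponentiated sum of log(1 - omega) so that very small
#' P_D values do not underflow. \code{complement = TRUE} instead returns
#' 1 minus that product (the complement), exposed for compatibility only.
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param condition condition label.
#' @param complement logical, default FALSE.
#' @return a \linkS4class{DissociationResult}
#' @export
complexDissociation <- function(table, condition, complement = FALSE) {
  rec <- conditionRecords(table, condition)
  rec <- rec[rec$occupancy > 0, , drop = FALSE]
  condition <- as.character(condition)
  if (nrow(rec) == 0) {
    return(new("DissociationResult", condition = condition, PD = 1,
               logPD = 0,
               perResidue = data.frame(residue = character(0),
                                       side = character(0), P = numeric(0)),
               perPair = data.frame()))
  }
  pairs <- .pairTable(rec)
  ## residue-level breakdowns, evaluated independently per side
  bySide <- function(col, side) {
    sp <- split(pairs$log_q, pairs[[col]])
    data.frame(residue = names(sp), side = side,
               P = vapply(sp, function(lq) -expm1(sum(lq)), 0),
               log_q = vapply(sp, sum, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  ligP <- bySide("ligand_residue", "ligand")
  recP <- bySide("receptor_residue", "receptor")
  logPD_L <- sum(ligP$log_q)
  logPD_R <- sum(recP$log_q)
  logPD_bonds <- .logProdOneMinus(rec$occupancy)
  if (is.finite(logPD_bonds) &&
      (abs(logPD_L - logPD_bonds) > 1e-9 || abs(logPD_R - logPD_bonds) > 1e-9))
    stop("internal inconsistency: side products disagree with bond product")
  PD <- exp(logPD_bonds)
  logPD <- logPD_bonds
  if (complement) {
    PD <- -expm1(logPD_bonds)
    logPD <- log(PD)
  }
  perResidue <- rbind(ligP[, c("residue", "side", "P")],
                      recP[, c("residue", "side", "P")])
  perPair <- pairs[, c("ligand_residue", "receptor_residue", "n_bonds", "p")]
  new("DissociationResult", condition = condition, PD = PD, logPD = logPD,
      perResidue = perResidue, perPair = perPair)
}

#' Normalised (mechano-regulation) dissociation ratio
#'
#' f_D = P_D at the given force divided by P_D at a reference force
#' (default 0). f_D at the reference is identically 1; values below 1
#' indicate force-strengthened (catch) binding, above 1 force-weakened
#' (slip) binding.
#'
#' @param table an \linkS4class{OccupancyTable} whose condition labels are
#'   forces in pN.
#' @param force force level of interest (label or number).
#' @param referenceForce zero-force reference condition (default 0).
#' @param complement passed to \code{\link{complexDissociation}}.
#' @return a \linkS4class{DissociationResult} with the \code{fD} slot set.
#' @export
normalizedDissociation <- function(table, force, referenceForce = 0,
                                   complement = FALSE) {
  num <- complexDissociation(table, force, complement = complement)
  den <- complexDissociation(table, referenceForce, complement = complement)
  if (den@PD == 0 && !is.finite(den@logPD))
    stop("f_D undefined: P_D at the reference force is 0")
  num@fD <- exp(num@logPD - den@logPD)  # ratio robust to PD underflow
  num
}

#' Expected interface bond count for one condition
#'
#' The expectation of the per-frame bond count equals the sum of the
#' per-bond occupancies (linearity), so Sigma omega estimates the mean
#' N_HB over the condition.
#'
#' @inheritParams conditionRecords
#' @return numeric, sum of occupancies.
#' @export
expectedBondCount <- function(table, condition) {
  sum(conditionRecords(table, condition)$occupancy)
}

#' Dissociation report across all conditions of a table
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param referenceForce optional reference condition for f_D; when given
#'   and present in the table, f_D columns are populated.
#' @return data.frame: condition, n_bonds (nonzero), P_D, f_D, sum_omega.
#' @export
dissociationReport <- function(table, referenceForce = NULL) {
  conds <- conditions(table)
  ref <- if (!is.null(referenceForce) &&
             as.character(referenceForce) %in% conds)
    complexDissociation(table, referenceForce)@PD else NA_real_
  rows <- lapply(conds, function(cc) {
    d <- complexDissociation(table, cc)
    data.frame(condition = cc, n_bonds = bondCensus(table, cc),
               P_D = d@PD,
               f_D = if (!is.na(ref) && ref > 0) d@PD / ref else NA_real_,
               sum_omega = expectedBondCount(table, cc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
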