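#' @import methods
NULL

#' Trajectory of a two-chain complex
#'
#' Ordered frames of typed atoms. The topology (atom metadata) is static
#' across frames; coordinates are stored as an natoms x 3 x nframes array in
#' Angstrom. Time, when known, is in nanoseconds.
#'
#' @slot topology data.frame with columns \code{eleno}, \code{elety}
#'   (PDB atom name), \code{elesy} (element symbol), \code{resid}
#'   (3-letter residue name), \code{resno} (author residue number),
#'   \code{chain} (single-character chain id).
#' @slot coords numeric array, dim \code{c(natoms, 3, nframes)}, Angstrom.
#' @slot time numeric vector of frame times in ns (length nframes, or
#'   length 0 when unknown).
#' @slot frameInterval numeric scalar, ns between saved frames (NA when
#'   unknown).
#'
#' @export
setClass("Trajectory",
  representation(
    topology = "data.frame",
    coords = "array",
    time = "numeric",
    frameInterval = "numeric"
  ),
  prototype(time = numeric(0), frameInterval = NA_real_)
)

setValidity("Trajectory", function(object) {
  msg <- character(0)
  need <- c("eleno", "elety", "elesy", "resid", "resno", "chain")
  if (!all(need %in% names(object@topology)))
    msg <- c(msg, paste("topology must have columns:", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an natoms x 3 x nframes array")
  else {
    if (d[3] < 1) msg <- c(msg, "trajectory must have >= 1 frame")
    if (d[1] != nrow(object@topology))
      msg <- c(msg, "coords atom count differs from topology")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(msg) == 0 && nrow(object@topology) > 0) {
    key <- paste(object@topology$chain, object@topology$resno,
                 object@topology$elety)
    if (anyDuplicated(key))
      msg <- c(msg, "(chain, resno, atom name) must be unique within a frame")
  }
  if (length(object@time) > 0 && length(object@time) != dim(object@coords)[3])
    msg <- c(msg, "time must have one entry per frame (or length 0)")
  if (length(msg)) msg else TRUE
})

#' Resolved atom selection
#'
#' A selection expression together with the sorted atom indices it resolves
#' to on a particular trajectory. Empty selections are valid.
#'
#' @slot expression character, the selection string.
#' @slot indices integer, sorted 1-based atom indices.
#'
#' @export
setClass("AtomSelection",
  representation(expression = "character", indices = "integer")
)

setValidity("AtomSelection", function(object) {
  if (is.unsorted(object@indices, strictly = TRUE) && length(object@indices) > 1)
    return("indices must be sorted and unique")
  if (length(object@indices) && any(object@indices < 1))
    return("indices must be positive")
  TRUE
})

#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair forms a hydrogen bond in a frame when the
#' donor-acceptor distance is strictly below \code{maxDaDistance} and the
#' deviation of the H->A direction from the D->H direction is strictly
#' below \code{maxDhaAngle} for some hydrogen covalently bound to the donor.
#'
#' @slot maxDaDistance numeric, Angstrom (default 3.5).
#' @slot maxDhaAngle numeric, degrees (default 30).
#' @export
setClass("HBondCriteria",
  representation(maxDaDistance = "numeric", maxDhaAngle = "numeric"),
  prototype(maxDaDistance = 3.5, maxDhaAngle = 30)
)

setValidity("HBondCriteria", function(object) {
  if (object@maxDaDistance <= 0 || object@maxDhaAngle <= 0)
    return("criteria must be strictly positive")
  TRUE
})

#' Salt-bridge criterion
#'
#' Side-chain carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2) within
#' \code{maxOnDistance} (inclusive) of a basic side-chain nitrogen
#' (Lys NZ, Arg NE/NH1/NH2).
#'
#' @slot maxOnDistance numeric, Angstrom (default 4.0).
#' @export
setClass("SaltBridgeCriteria",
  representation(maxOnDistance = "numeric"),
  prototype(maxOnDistance = 4.0)
)

setValidity("SaltBridgeCriteria", function(object) {
  if (object@maxOnDistance <= 0) return("maxOnDistance must be positive")
  TRUE
})

#' Per-bond presence across a trajectory
#'
#' For each interface bond ever observed, a logical presence value per
#' frame. Row i of \code{keys} describes bond i; \code{presence[i, t]} says
#' whether it satisfied the criteria in frame t.
#'
#' @slot keys data.frame of canonical bond keys (ligand-first): columns
#'   \code{ligand_chain}, \code{ligand_resid}, \code{ligand_resname},
#'   \code{receptor_chain}, \code{receptor_resid}, \code{receptor_resname},
#'   \code{donor_atom}, \code{acceptor_atom}, \code{kind}.
#' @slot presence logical matrix, bonds x frames.
#' @export
setClass("BondPresence",
  representation(keys = "data.frame", presence = "matrix")
)

setValidity("BondPresence", function(object) {
  if (nrow(object@keys) != nrow(object@presence))
    return("one presence row per bond key required")
  if (nrow(object@presence) > 0 && !is.logical(object@presence))
    return("presence must be logical")
  TRUE
})

#' Table of bond occupancies by condition
#'
#' One record per (bond key, condition). The occupancy (survival ratio
#' omega) is the fraction of frames in which the bond satisfied its
#' geometric criteria. Conditions label either structural models or
#' tensile-force levels (pN).
#'
#' @slot records data.frame with columns \code{condition},
#'   \code{ligand_chain}, \code{ligand_resid}, \code{ligand_resname},
#'   \code{receptor_chain}, \code{receptor_resid}, \code{receptor_resname},
#'   \code{donor_atom}, \code{acceptor_atom}, \code{kind}, \code{occupancy}.
#'   Atom-level columns may be NA in the reduced (residue-pair) dialect.
#' @export
setClass("OccupancyTable", representation(records = "data.frame"))

occupancyRecordCols <- c(
  "condition", "ligand_chain", "ligand_resid", "ligand_resname",
  "receptor_chain", "receptor_resid", "receptor_resname",
  "donor_atom", "acceptor_atom", "kind", "occupancy"
)

setValidity("OccupancyTable", function(object) {
  r <- object@records
  if (!all(occupancyRecordCols %in% names(r)))
    return(paste("records must have columns:",
                 paste(occupancyRecordCols, collapse = ", ")))
  if (nrow(r) == 0) return("conditions must be non-empty")
  if (any(!is.finite(r$occupancy)) || any(r$occupancy < 0 | r$occupancy > 1))
    return("occupancy must lie in [0, 1]")
  key <- paste(r$condition, r$ligand_chain, r$ligand_resid, r$ligand_resname,
               r$receptor_chain, r$receptor_resid, r$receptor_resname,
               r$donor_atom, r$acceptor_atom, r$kind)
  if (anyDuplicated(key))
    return("one record per (bond key, condition) required")
  TRUE
})

#' Complex dissociation result for one condition
#'
#' Under the bond-independence assumption, \code{PD} is the probability
#' that no interface bond survives: the product over all bonds of
#' (1 - omega). \code{fD} is the ratio of PD at the condition's force to PD
#' at a zero-force reference; it is NA unless computed by
#' \code{\link{normalizedDissociation}}.
#'
#' @slot condition character condition label.
#' @slot PD numeric in [0, 1].
#' @slot logPD numeric, log of PD (kept alongside so tables large enough to
#'   underflow PD remain usable).
#' @slot fD numeric (NA unless a zero-force reference was used).
#' @slot perResidue data.frame: \code{residue}, \code{side}, \code{P}.
#' @slot perPair data.frame: \code{ligand_residue}, \code{receptor_residue},
#'   \code{n_bonds}, \code{p}.
#' @export
setClass("DissociationResult",
  representation(condition = "character", PD = "numeric", logPD = "numeric",
                 fD = "numeric", perResidue = "data.frame",
                 perPair = "data.frame"),
  prototype(fD = NA_real_, logPD = NA_real_)
)

setValidity("DissociationResult", function(object) {
  if (!is.finite(object@PD) || object@PD < 0 || object@PD > 1)
    return("PD must lie in [0, 1]")
  TRUE
})

#' Force-time trace from a pulling experiment or simulation
#'
#' @slot time numeric, ns, strictly increasing.
#' @slot force numeric, pN, same length as time.
#' @slot phase character per-sample phase label ("ramp"/"clamp"), or
#'   length 0 when unlabeled.
#' @export
setClass("ForceTrace",
  representation(time = "numeric", force = "numeric", phase = "character"),
  prototype(phase = character(0))
)

setValidity("ForceTrace", function(object) {
  if (length(object@time) != length(object@force))
    return("time and force must have equal length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (length(object@phase) > 0 && length(object@phase) != length(object@time))
    return("phase labels must match trace length (or be absent)")
  TRUE
})

#' Force-response classification of a single bond (or metric)
#'
#' @slot label character, bond key or metric label.
#' @slot pattern character, one of "slip", "catch-slip", "slip-catch-slip",
#'   "catch-slip-catch", "insensitive", "other".
#' @slot signature character vector of merged significant change signs
#'   ("+"/"-").
#' @slot epsilon numeric, the flatness tolerance used.
#' @export
setClass("ResponsePattern",
  representation(label = "character", pattern = "character",
                 signature = "character", epsilon = "numeric")
)

#' Two-pathway (catch-slip) off-rate parameters
#'
#' Off-rate k(f) = k_c exp(-x_c f / kBT) + k_s exp(x_s f / kBT); the mean
#' bond lifetime is 1/k(f). The catch pathway (k_c, x_c) is suppressed by
#' force, the slip pathway (k_s, x_s) accelerated.
#'
#' @slot kc numeric, 1/s. @slot xc numeric, nm.
#' @slot ks numeric, 1/s. @slot xs numeric, nm.
#' @slot kBT numeric, pN nm (default 4.28, body temperature 310 K).
#' @export
setClass("TwoPathwayParams",
  representation(kc = "numeric", xc = "numeric", ks = "numeric",
                 xs = "numeric", kBT = "numeric"),
  prototype(kBT = 4.28)
)

setValidity("TwoPathwayParams", function(object) {
  v <- c(object@kc, object@xc, object@ks, object@xs, object@kBT)
  if (any(!is.finite(v)) || any(v < 0))
    return("rates and distances must be non-negative and finite")
  if (object@kBT <= 0) return("kBT must be positive")
  TRUE
})

#' Gaussian fit of an integer-count histogram
#'
#' @slot mean,numeric sigma numeric, amplitude numeric fitted parameters.
#' @slot sigma numeric, fitted width (> 0).
#' @slot amplitude numeric, fitted peak height (relative frequency).
#' @slot residualNorm numeric, root of the residual sum of squares.
#' @export
setClass("GaussianFit",
  representation(mean = "numeric", sigma = "numeric", amplitude = "numeric",
                 residualNorm = "numeric")
)

setValidity("GaussianFit", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' Result of a least-squares rigid superposition
#'
#' Apply as x_new = (x - centroidMobile) %*% rotation + centroidReference
#' (row-vector convention).
#'
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation numeric 3-vector: centroidReference - centroidMobile
#'   after rotation of the mobile centroid frame.
#' @slot centroidMobile,centroidReference numeric 3-vectors.
#' @slot rmsd numeric, Angstrom, after superposition.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 centroidMobile = "numeric", centroidReference = "numeric",
                 rmsd = "numeric")
)

setValidity("SuperpositionResult", function(object) {
  if (!all(dim(object@rotation) == c(3, 3)))
    return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-6)
    return("rotation must be proper (det +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' Helix axis
#'
#' @slot origin numeric 3-vector, centroid of the fitted C-alpha set.
#' @slot direction numeric unit 3-vector, oriented N-terminus to C-terminus.
#' @export
setClass("HelixAxis",
  representation(origin = "numeric", direction = "numeric")
)

setValidity("HelixAxis", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit vector")
  TRUE
})
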