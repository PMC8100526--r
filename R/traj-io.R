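#' @include AllClasses.R
NULL

## Element inference for PDB atom names that bio3d cannot map; falls back to
## the leading alphabetic character of the atom name.
.guessElement <- function(elety) {
  ele <- suppressWarnings(try(bio3d::atom2ele(elety, rescue = TRUE),
                              silent = TRUE))
  if (inherits(ele, "try-error") || length(ele) != length(elety)) {
    ele <- toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
  }
  ele <- toupper(ele)
  ## protein atom names starting with (digit+)H are hydrogens (HG, HD21,
  ## 1HB, ...), never metals such as mercury
  ele[grepl("^[0-9]*H", toupper(elety))] <- "H"
  ele
}

.makeTrajectory <- function(topology, coords, time = numeric(0),
                            frameInterval = NA_real_) {
  new("Trajectory", topology = topology, coords = coords, time = time,
      frameInterval = frameInterval)
}

#' Construct a trajectory from raw parts
#'
#' @param topology data.frame with columns \code{eleno}, \code{elety},
#'   \code{resid}, \code{resno}, \code{chain} and optionally \code{elesy}
#'   (inferred from atom names when absent).
#' @param coords natoms x 3 x nframes array (or natoms x 3 matrix for a
#'   single frame), Angstrom.
#' @param time optional numeric frame times, ns.
#' @param frameInterval optional ns between frames.
#' @return a \linkS4class{Trajectory}
#' @export
Trajectory <- function(topology, coords, time = numeric(0),
                       frameInterval = NA_real_) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.null(topology$elesy)) topology$elesy <- .guessElement(topology$elety)
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  .makeTrajectory(topology, coords, as.numeric(time), frameInterval)
}

#' Hydrogen-bond criteria constructor
#' @param maxDaDistance donor-acceptor cutoff, Angstrom (strict less-than).
#' @param maxDhaAngle donor-hydrogen-acceptor deviation cutoff, degrees
#'   (strict less-than).
#' @return an \linkS4class{HBondCriteria}
#' @export
hbondCriteria <- function(maxDaDistance = 3.5, maxDhaAngle = 30) {
  new("HBondCriteria", maxDaDistance = maxDaDistance,
      maxDhaAngle = maxDhaAngle)
}

#' Salt-bridge criteria constructor
#' @param maxOnDistance O-N cutoff, Angstrom (inclusive).
#' @return a \linkS4class{SaltBridgeCriteria}
#' @export
saltBridgeCriteria <- function(maxOnDistance = 4.0) {
  new("SaltBridgeCriteria", maxOnDistance = maxOnDistance)
}

#' Read a (multi-model) PDB structure as a trajectory
#'
#' Each MODEL becomes one frame; a plain ATOM-record file yields a
#' single-frame trajectory. Chain, author residue numbering, and atom-name
#' metadata are preserved verbatim; coordinates are Angstrom. Alternate
#' locations other than ' '/'A' are dropped for deterministic geometry.
#'
#' @param path PDB file path.
#' @param format only \code{"pdb"} is supported.
#' @param frameInterval optional ns between models.
#' @return a \linkS4class{Trajectory}
#' @export
readStructure <- function(path, format = c("pdb"), frameInterval = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  .checkAtomRecords(path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  if (!all(keep)) at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  natoms <- nrow(at)
  nframes <- nrow(xyz)
  if (ncol(xyz) != 3 * natoms)
    stop("parse error in ", path,
         ": models differ in atom count (coordinates for ", ncol(xyz) / 3,
         " atoms vs ", natoms, " ATOM records)")
  chain <- at$chain
  chain[is.na(chain)] <- " "
  topo <- data.frame(
    eleno = at$eleno, elety = at$elety,
    elesy = .guessElement(at$elety),
    resid = at$resid, resno = at$resno, chain = chain,
    stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, dim = c(natoms, 3, nframes))
  for (f in seq_len(nframes))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  time <- if (!is.na(frameInterval)) (seq_len(nframes) - 1) * frameInterval
          else numeric(0)
  .makeTrajectory(topo, coords, time, frameInterval)
}

## Light structural validation so malformed ATOM records fail with a line
## number instead of silently degrading inside the reader.
.checkAtomRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(atom)) stop("parse error in ", path, ": no ATOM/HETATM records")
  idx <- which(atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error in ", path, " at line ", i,
           ": ATOM record shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("parse error in ", path, " at line ", i,
           ": non-numeric coordinate field")
  }
  ## per-model atom counts must agree
  model <- cumsum(grepl("^MODEL", lines))
  if (max(model) >= 1) {
    counts <- table(model[atom])
    counts <- counts[names(counts) != "0"]
    if (length(unique(as.integer(counts))) > 1)
      stop("parse error in ", path,
           ": models differ in atom count (",
           paste(as.integer(counts), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  topo <- traj@topology
  nfr <- nFrames(traj)
  xyz <- matrix(NA_real_, nrow = nfr, ncol = 3 * nAtoms(traj))
  for (f in seq_len(nfr))
    xyz[f, ] <- as.vector(t(frameCoords(traj, f)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topo$resno, resid = topo$resid,
                   eleno = topo$eleno, elety = topo$elety,
                   chain = topo$chain, elesy = topo$elesy)
  invisible(path)
}

#' Read a binary trajectory (DCD) against a PDB/PSF-derived topology
#'
#' @param topologyPath PDB file providing atom metadata.
#' @param coordsPath DCD trajectory file.
#' @param format only \code{"dcd"} is supported.
#' @param frameInterval optional ns between frames.
#' @return a \linkS4class{Trajectory} with frames in file order, Angstrom.
#' @export
readTrajectory <- function(topologyPath, coordsPath, format = c("dcd"),
                           frameInterval = NA_real_) {
  format <- match.arg(format)
  topo <- readStructure(topologyPath)
  xyz <- bio3d::read.dcd(coordsPath, verbose = FALSE)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nAtoms(topo))
    stop("atom-count mismatch: topology has ", nAtoms(topo),
         " atoms but trajectory frames have ", ncol(xyz) / 3)
  nfr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nAtoms(topo), 3, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  time <- if (!is.na(frameInterval)) (seq_len(nfr) - 1) * frameInterval
          else numeric(0)
  .makeTrajectory(topo@topology, coords, time, frameInterval)
}
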