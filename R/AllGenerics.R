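#' @include AllClasses.R
NULL

#' Number of frames in a trajectory
#' @param x a \linkS4class{Trajectory}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a \linkS4class{Trajectory}
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom metadata table
#' @param x a \linkS4class{Trajectory}
#' @return data.frame of per-atom static fields
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinates of one frame
#' @param x a \linkS4class{Trajectory}
#' @param frame integer frame index (default 1)
#' @return natoms x 3 numeric matrix, Angstrom
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' Occupancy records of a table
#' @param x an \linkS4class{OccupancyTable}
#' @return data.frame of records
#' @export
setGeneric("occupancyRecords", function(x) standardGeneric("occupancyRecords"))

#' Condition labels of a table
#' @param x an \linkS4class{OccupancyTable} or \linkS4class{BondPresence}
#' @return character vector of unique condition labels, input order
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x))
    stop("frame index ", frame, " out of range [1, ", nFrames(x), "]")
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

#' @rdname occupancyRecords
#' @export
setMethod("occupancyRecords", "OccupancyTable", function(x) x@records)

#' @rdname conditions
#' @export
setMethod("conditions", "OccupancyTable", function(x) unique(x@records$condition))

setMethod("show", "Trajectory", function(object) {
  ch <- unique(object@topology$chain)
  cat("Trajectory:", nAtoms(object), "atoms,", nFrames(object), "frames\n")
  cat("  chains:", paste(ch, collapse = " "), "\n")
  if (!is.na(object@frameInterval))
    cat("  frame interval:", object@frameInterval, "ns\n")
  invisible(object)
})

setMethod("show", "AtomSelection", function(object) {
  cat("AtomSelection:", length(object@indices), "atoms  [",
      object@expression, "]\n")
  invisible(object)
})

setMethod("show", "OccupancyTable", function(object) {
  r <- object@records
  cat("OccupancyTable:", nrow(r), "records,",
      length(unique(r$condition)), "condition(s)\n")
  cat("  conditions:", paste(unique(r$condition), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "BondPresence", function(object) {
  cat("BondPresence:", nrow(object@keys), "bonds x",
      ncol(object@presence), "frames\n")
  invisible(object)
})

setMethod("show", "DissociationResult", function(object) {
  cat("DissociationResult [", object@condition, "]\n", sep = "")
  cat("  P_D =", format(object@PD, digits = 4))
  if (!is.na(object@fD)) cat("   f_D =", format(object@fD, digits = 4))
  cat("\n")
  invisible(object)
})

setMethod("show", "ResponsePattern", function(object) {
  cat("ResponsePattern [", object@label, "]: ", object@pattern,
      "  signature (", paste(object@signature, collapse = ","),
      ")  epsilon ", object@epsilon, "\n", sep = "")
  invisible(object)
})

setMethod("show", "ForceTrace", function(object) {
  cat("ForceTrace:", length(object@time), "samples")
  if (length(object@time))
    cat(", t in [", min(object@time), ",", max(object@time), "] ns, peak",
        format(max(object@force), digits = 4), "pN")
  cat("\n")
  invisible(object)
})

setMethod("show", "TwoPathwayParams", function(object) {
  cat("TwoPathwayParams: k_c=", object@kc, "/s x_c=", object@xc,
      " nm | k_s=", object@ks, "/s x_s=", object@xs,
      " nm (kBT=", object@kBT, " pN nm)\n", sep = "")
  invisible(object)
})
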