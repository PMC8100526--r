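#' @include AllClasses.R
NULL

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa3to1 <- stats::setNames(names(.aa1to3), .aa1to3)

## "K244" or "LYS244" -> list(resname = "LYS", resid = 244L)
.parseResidueLabel <- function(label) {
  label <- trimws(label)
  m <- regmatches(label, regexec("^([A-Za-z]{1,3})([0-9]+)$", label))[[1]]
  if (length(m) != 3)
    stop("cannot parse residue label '", label,
         "': expected e.g. K244 or LYS244")
  code <- toupper(m[2])
  resname <- if (nchar(code) == 1) {
    if (!code %in% names(.aa1to3))
      stop("unknown one-letter residue code '", code, "' in '", label, "'")
    .aa1to3[[code]]
  } else code
  list(resname = resname, resid = as.integer(m[3]))
}

## "LYS", 244 -> "K244"
.residueLabel <- function(resname, resid) {
  one <- ifelse(resname %in% names(.aa3to1), .aa3to1[resname], resname)
  paste0(one, resid)
}

#' Write an occupancy table as TSV
#'
#' Full dialect: columns \code{condition, ligand_chain, ligand_resid,
#' ligand_resname, receptor_chain, receptor_resid, receptor_resname,
#' donor_atom, acceptor_atom, kind, occupancy}.
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOccupancyTable <- function(table, path) {
  stopifnot(is(table, "OccupancyTable"))
  utils::write.table(table@records[, occupancyRecordCols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy table from TSV/CSV
#'
#' Accepts the full dialect written by \code{\link{writeOccupancyTable}} or
#' a reduced residue-pair dialect mirroring printed occupancy tables:
#' columns \code{ligand_residue} and \code{receptor_residue} (labels such
#' as \code{K244}) followed by one column per condition, whose header is
#' the condition label (a model id or a force in pN). Zero-occupancy
#' entries are retained as records so bond censuses can distinguish
#' absent-under-this-condition from never-reported.
#'
#' @param path input file.
#' @param dialect \code{"auto"} (default), \code{"full"} or
#'   \code{"reduced"}.
#' @param sep field separator; default tab.
#' @return an \linkS4class{OccupancyTable}
#' @export
readOccupancyTable <- function(path, dialect = c("auto", "full", "reduced"),
                               sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read occupancy table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  full <- all(occupancyRecordCols %in% names(df))
  if (dialect == "full" && !full)
    stop("file lacks full-dialect columns: ", path)
  if (dialect == "auto") dialect <- if (full) "full" else "reduced"
  if (dialect == "full") {
    return(new("OccupancyTable",
               records = df[, occupancyRecordCols, drop = FALSE]))
  }
  pairCols <- c("ligand_residue", "receptor_residue")
  if (!all(pairCols %in% names(df)))
    stop("reduced dialect needs columns ligand_residue, receptor_residue ",
         "plus one column per condition: ", path)
  condCols <- setdiff(names(df), pairCols)
  if (!length(condCols)) stop("no condition columns found in ", path)
  recs <- list()
  for (cc in condCols) {
    lig <- lapply(df$ligand_residue, .parseResidueLabel)
    rec <- lapply(df$receptor_residue, .parseResidueLabel)
    recs[[cc]] <- data.frame(
      condition = cc,
      ligand_chain = "L", ligand_resid = vapply(lig, `[[`, 1L, "resid"),
      ligand_resname = vapply(lig, `[[`, "", "resname"),
      receptor_chain = "R", receptor_resid = vapply(rec, `[[`, 1L, "resid"),
      receptor_resname = vapply(rec, `[[`, "", "resname"),
      donor_atom = NA_character_, acceptor_atom = NA_character_,
      kind = "hbond", occupancy = as.numeric(df[[cc]]),
      stringsAsFactors = FALSE
    )
    ## distinguish multiple bonds of one residue pair within a condition
    dup <- duplicated(paste(recs[[cc]]$ligand_resid, recs[[cc]]$ligand_resname,
                            recs[[cc]]$receptor_resid,
                            recs[[cc]]$receptor_resname))
    if (any(dup))
      recs[[cc]]$donor_atom <- make.unique(
        rep("bond", nrow(recs[[cc]])), sep = "_")
  }
  new("OccupancyTable", records = do.call(rbind, recs))
}

#' Subset an occupancy table to one condition
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param condition condition label (coerced to character).
#' @return data.frame of that condition's records.
#' @export
conditionRecords <- function(table, condition) {
  stopifnot(is(table, "OccupancyTable"))
  condition <- as.character(condition)
  r <- table@records[table@records$condition == condition, , drop = FALSE]
  if (nrow(r) == 0)
    stop("condition '", condition, "' not in table; known: ",
         paste(unique(table@records$condition), collapse = ", "))
  r
}

#' Bond census for one condition
#'
#' Number of interface bonds with strictly positive occupancy under the
#' condition.
#'
#' @inheritParams conditionRecords
#' @return integer count
#' @export
bondCensus <- function(table, condition) {
  sum(conditionRecords(table, condition)$occupancy > 0)
}
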