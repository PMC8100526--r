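#' @include AllClasses.R
NULL

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD of the
#' mobile point set onto the reference, via singular value decomposition of
#' the cross-covariance matrix with the determinant sign corrected so the
#' rotation is never a reflection.
#'
#' @param mobile N x 3 coordinate matrix (Angstrom).
#' @param reference N x 3 coordinate matrix, same N >= 3.
#' @return a \linkS4class{SuperpositionResult}
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (nrow(mobile) < 3) stop("need >= 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- crossprod(X, Y)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1                        # degenerate planar/collinear set
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cr - cm %*% R),
      centroidMobile = cm, centroidReference = cr, rmsd = rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param sup a \linkS4class{SuperpositionResult}.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
applySuperposition <- function(sup, coords) {
  sweep(sweep(as.matrix(coords), 2, sup@centroidMobile) %*% sup@rotation,
        2, sup@centroidReference, `+`)
}

#' C-alpha RMSD time series against a reference frame
#'
#' By default each frame is optimally superposed onto the reference before
#' the RMSD is taken, so the series reflects conformational change rather
#' than the rigid drift of a pulled complex; \code{superpose = FALSE} gives
#' the raw coordinate RMSD.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection an \linkS4class{AtomSelection} (e.g. the C-alpha set);
#'   must be non-empty.
#' @param referenceFrame frame index of the reference (default 1).
#' @param superpose logical, default TRUE.
#' @return numeric vector, Angstrom per frame.
#' @export
caRmsdSeries <- function(traj, selection, referenceFrame = 1L,
                         superpose = TRUE) {
  stopifnot(is(traj, "Trajectory"), is(selection, "AtomSelection"))
  idx <- selection@indices
  if (length(idx) == 0) stop("empty selection")
  ref <- frameCoords(traj, referenceFrame)[idx, , drop = FALSE]
  vapply(seq_len(nFrames(traj)), function(f) {
    mob <- frameCoords(traj, f)[idx, , drop = FALSE]
    if (superpose) kabschSuperpose(mob, ref)@rmsd
    else sqrt(mean(rowSums((mob - ref)^2)))
  }, numeric(1))
}
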