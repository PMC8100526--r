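#' @include AllClasses.R occupancy-io.R
NULL

#' Classify a bond's occupancy-versus-force pattern
#'
#' Consecutive differences of the values along increasing force are reduced
#' to a sign signature: steps with |delta| <= epsilon are flat and dropped,
#' adjacent equal signs are merged. The signature maps to a pattern:
#' ("-") slip, ("+","-") catch-slip, ("-","+","-") slip-catch-slip,
#' ("+","-","+") catch-slip-catch, empty signature insensitive; a pure
#' monotone increase and any other signature are reported as "other" (the
#' signature is preserved in the result).
#'
#' @param values occupancies (or lifetimes) per force level.
#' @param forces strictly increasing force levels, same length (default:
#'   the value order is taken as the force order).
#' @param epsilon change tolerance (default 0.025).
#' @param label optional label carried into the result.
#' @return a \linkS4class{ResponsePattern}
#' @export
classifyResponse <- function(values, forces = seq_along(values),
                             epsilon = 0.025, label = "") {
  if (length(values) < 3) stop("need >= 3 force levels to classify")
  if (length(forces) != length(values))
    stop("forces and values must have equal length")
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  d <- diff(values)
  signs <- ifelse(d > 0, "+", "-")[abs(d) > epsilon]
  if (length(signs) > 1)
    signs <- signs[c(TRUE, signs[-1] != signs[-length(signs)])]
  sig <- paste(signs, collapse = ",")
  pattern <- if (length(signs) == 0) "insensitive"
    else switch(sig,
      "-" = "slip",
      "+,-" = "catch-slip",
      "-,+,-" = "slip-catch-slip",
      "+,-,+" = "catch-slip-catch",
      "other")
  new("ResponsePattern", label = label, pattern = pattern,
      signature = signs, epsilon = epsilon)
}

#' Classify every bond of a force-panel occupancy table
#'
#' Conditions must be numeric force labels; each bond present under every
#' force is classified by \code{\link{classifyResponse}}.
#'
#' @param table an \linkS4class{OccupancyTable} with force conditions.
#' @param epsilon change tolerance (default 0.025).
#' @return data.frame: ligand_residue, receptor_residue, one occupancy
#'   column per force, signature, pattern, epsilon.
#' @export
classifyOccupancyTable <- function(table, epsilon = 0.025) {
  stopifnot(is(table, "OccupancyTable"))
  r <- table@records
  forces <- suppressWarnings(as.numeric(unique(r$condition)))
  if (any(is.na(forces)))
    stop("conditions must be numeric force labels; got: ",
         paste(unique(r$condition), collapse = ", "))
  forces <- sort(forces)
  key <- paste(r$ligand_chain, r$ligand_resid, r$ligand_resname,
               r$receptor_chain, r$receptor_resid, r$receptor_resname,
               r$donor_atom, r$acceptor_atom, r$kind)
  sp <- split(seq_len(nrow(r)), key)
  rows <- lapply(sp, function(ii) {
    sub <- r[ii, , drop = FALSE]
    f <- as.numeric(sub$condition)
    if (!setequal(f, forces)) return(NULL)  # bond absent under some force
    sub <- sub[order(f), , drop = FALSE]
    lab <- paste0(.residueLabel(sub$ligand_resname[1], sub$ligand_resid[1]),
                  "-", .residueLabel(sub$receptor_resname[1],
                                     sub$receptor_resid[1]))
    cls <- classifyResponse(sub$occupancy, sort(f), epsilon, lab)
    occ <- as.list(sub$occupancy)
    names(occ) <- paste0("occ_", sort(f))
    c(list(ligand_residue = .residueLabel(sub$ligand_resname[1],
                                          sub$ligand_resid[1]),
           receptor_residue = .residueLabel(sub$receptor_resname[1],
                                            sub$receptor_resid[1])),
      occ,
      list(signature = paste(cls@signature, collapse = ","),
           pattern = cls@pattern, epsilon = epsilon))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$ligand_residue, out$receptor_residue), , drop = FALSE]
}

#' Transition force of a force-dependent series
#'
#' Returns the force at which the series attains its extreme value. Ties
#' are broken toward the lowest force and reported.
#'
#' @param forces numeric, distinct forces, >= 3 points.
#' @param values numeric, same length.
#' @param mode \code{"min"} or \code{"max"}.
#' @return list with \code{force}, \code{value}, \code{tied} (logical).
#' @export
transitionForce <- function(forces, values, mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (length(forces) < 3) stop("need >= 3 points to locate a transition")
  if (length(values) != length(forces)) stop("length mismatch")
  if (anyDuplicated(forces)) stop("forces must be distinct")
  ord <- order(forces)
  forces <- forces[ord]; values <- values[ord]
  ext <- if (mode == "min") min(values) else max(values)
  hits <- which(values == ext)
  list(force = forces[hits[1]], value = ext, tied = length(hits) > 1)
}

#' Pearson correlation on two force segments
#'
#' Splits the data at \code{splitForce} into [min, split] and (split, max]
#' and reports the Pearson r per segment. Degenerate segments are flagged:
#' fewer than 2 points or constant values give \code{r = NA} with a
#' reason, and exactly 2 points give r = +/-1 by construction
#' (\code{flag = "two-point"}).
#'
#' @param forces,values numeric vectors.
#' @param splitForce the split point (included in the lower segment).
#' @return data.frame: segment, n, r, flag.
#' @export
segmentedPearson <- function(forces, values, splitForce) {
  if (length(forces) != length(values)) stop("length mismatch")
  seg <- list(lower = forces <= splitForce, upper = forces > splitForce)
  rows <- lapply(names(seg), function(nm) {
    f <- forces[seg[[nm]]]; v <- values[seg[[nm]]]
    flag <- "ok"; r <- NA_real_
    if (length(f) < 2) flag <- "too-few-points"
    else if (stats::sd(f) == 0 || stats::sd(v) == 0) flag <- "constant"
    else {
      r <- stats::cor(f, v)
      if (length(f) == 2) flag <- "two-point"
    }
    data.frame(segment = nm, n = length(f), r = r, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gaussian fit of an integer-count histogram
#'
#' Builds the relative-frequency histogram of the observed integer counts
#' and fits A exp(-(x - mu)^2 / (2 sigma^2)) by nonlinear least squares,
#' started from the sample moments.
#'
#' @param counts integer observations (e.g. per-frame H-bond numbers), with
#'   >= 3 distinct values.
#' @return a \linkS4class{GaussianFit}
#' @export
fitGaussianHist <- function(counts) {
  counts <- as.integer(counts)
  tab <- table(counts)
  if (length(tab) < 3)
    stop("need >= 3 distinct observed values for a Gaussian fit")
  x <- as.numeric(names(tab))
  y <- as.numeric(tab) / length(counts)
  st <- list(mu = mean(counts), sigma = max(stats::sd(counts), 0.5),
             A = max(y))
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
    start = st, data = data.frame(x = x, y = y),
    lower = c(mu = min(x) - diff(range(x)), sigma = 1e-3, A = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  new("GaussianFit", mean = unname(cf["mu"]),
      sigma = abs(unname(cf["sigma"])), amplitude = unname(cf["A"]),
      residualNorm = sqrt(sum(stats::resid(fit)^2)))
}

#' Rupture force from a pulling trace
#'
#' The rupture force is the maximum of the force-time pattern over the
#' ramp phase (the whole trace when phases are unlabeled).
#'
#' @param trace a \linkS4class{ForceTrace}.
#' @return list with \code{force} (pN) and \code{time} (ns) of the peak.
#' @export
ruptureForce <- function(trace) {
  stopifnot(is(trace, "ForceTrace"))
  if (length(trace@time) == 0) stop("empty force trace")
  keep <- if (length(trace@phase)) trace@phase == "ramp"
          else rep(TRUE, length(trace@time))
  if (!any(keep)) keep <- rep(TRUE, length(trace@time))
  f <- trace@force[keep]; t <- trace@time[keep]
  i <- which.max(f)
  list(force = f[i], time = t[i])
}

#' Read a two-column force trace (time_ns, force_pN) from TSV
#'
#' Tolerant of comment lines starting with '#'. A third column, when
#' present, is taken as the phase label.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return a \linkS4class{ForceTrace}
#' @export
readForceTrace <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("force trace needs columns time_ns, force_pN")
  phase <- if (ncol(df) >= 3) as.character(df[[3]]) else character(0)
  new("ForceTrace", time = as.numeric(df[[1]]), force = as.numeric(df[[2]]),
      phase = phase)
}

#' Write a force trace as TSV
#' @param trace a \linkS4class{ForceTrace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeForceTrace <- function(trace, path) {
  df <- data.frame(time_ns = trace@time, force_pN = trace@force)
  if (length(trace@phase)) df$phase <- trace@phase
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
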