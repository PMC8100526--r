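#' @include AllClasses.R
NULL

#' Two-pathway parameters constructor
#' @param kc,xc catch-pathway zero-force rate (1/s) and distance (nm).
#' @param ks,xs slip-pathway zero-force rate (1/s) and distance (nm).
#' @param kBT thermal energy, pN nm (default 4.28, 310 K).
#' @return a \linkS4class{TwoPathwayParams}
#' @export
twoPathwayParams <- function(kc, xc, ks, xs, kBT = 4.28) {
  new("TwoPathwayParams", kc = kc, xc = xc, ks = ks, xs = xs, kBT = kBT)
}

#' Mean bond lifetime under the two-pathway (catch-slip) off-rate
#'
#' k(f) = k_c exp(-x_c f / kBT) + k_s exp(x_s f / kBT); the mean lifetime
#' is 1/k(f). At zero force this reduces to 1/(k_c + k_s).
#'
#' @param force force, pN (vectorised).
#' @param params a \linkS4class{TwoPathwayParams}.
#' @return mean lifetime, s.
#' @export
twoPathwayLifetime <- function(force, params) {
  stopifnot(is(params, "TwoPathwayParams"))
  1 / (params@kc * exp(-params@xc * force / params@kBT) +
       params@ks * exp(params@xs * force / params@kBT))
}

#' Force of maximal lifetime under the two-pathway model (closed form)
#'
#' Setting dk/df = 0 gives
#' f* = kBT / (x_c + x_s) * log(k_c x_c / (k_s x_s)); a lifetime maximum
#' at positive force exists only when k_c x_c > k_s x_s.
#'
#' @param params a \linkS4class{TwoPathwayParams}.
#' @return force, pN (NA when no interior maximum exists).
#' @export
twoPathwayOptimumForce <- function(params) {
  stopifnot(is(params, "TwoPathwayParams"))
  num <- params@kc * params@xc
  den <- params@ks * params@xs
  if (num <= 0 || den <= 0) return(NA_real_)
  f <- params@kBT / (params@xc + params@xs) * log(num / den)
  if (f <= 0) NA_real_ else f
}

#' Bin single-bond lifetimes by clamp force
#'
#' Left-closed right-open bins anchored at 0 pN (a record at a bin edge
#' goes to the right bin). Empty bins are omitted.
#'
#' @param records data.frame with columns \code{clamp_force} (pN) and
#'   \code{lifetime} (s), both >= 0.
#' @param binWidth bin width, pN (default 7.5).
#' @return data.frame: force_mid, mean_lifetime, sem, n.
#' @export
binLifetimes <- function(records, binWidth = 7.5) {
  if (binWidth <= 0) stop("binWidth must be positive")
  stopifnot(all(c("clamp_force", "lifetime") %in% names(records)))
  if (nrow(records) == 0)
    return(data.frame(force_mid = numeric(0), mean_lifetime = numeric(0),
                      sem = numeric(0), n = integer(0)))
  if (any(records$clamp_force < 0) || any(records$lifetime < 0))
    stop("forces and lifetimes must be >= 0")
  bin <- floor(records$clamp_force / binWidth)
  sp <- split(records$lifetime, bin)
  out <- data.frame(
    force_mid = (as.numeric(names(sp)) + 0.5) * binWidth,
    mean_lifetime = vapply(sp, mean, 0),
    sem = vapply(sp, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, 0),
    n = vapply(sp, length, 0L)
  )
  rownames(out) <- NULL
  out[order(out$force_mid), , drop = FALSE]
}

#' Fit the two-pathway model to binned lifetimes
#'
#' Nonlinear least squares on the log mean lifetime, with rates and
#' distances log-parameterised for positivity. Non-convergence or a
#' boundary fit is flagged rather than raised.
#'
#' @param binned data.frame from \code{\link{binLifetimes}} (>= 4 bins).
#' @param kBT thermal energy, pN nm.
#' @param start optional \linkS4class{TwoPathwayParams} starting point.
#' @return list with \code{params} (\linkS4class{TwoPathwayParams}),
#'   \code{optimumForce} (pN, NA if monotone slip), \code{converged},
#'   \code{residuals}.
#' @export
fitTwoPathway <- function(binned, kBT = 4.28, start = NULL) {
  if (nrow(binned) < 4) stop("need >= 4 bins to fit the two-pathway model")
  f <- binned$force_mid
  ly <- log(binned$mean_lifetime)
  if (is.null(start)) {
    ## slip tail from the two highest-force bins; catch from the intercept
    n <- length(f)
    slope <- (ly[n] - ly[n - 1]) / (f[n] - f[n - 1])
    xs0 <- max(min(-slope * kBT, 2), 0.05)
    ks0 <- max(exp(-(ly[n] + xs0 * f[n] / kBT)), 1e-6)
    kc0 <- max(exp(-ly[1]) - ks0, 1e-4)
    start <- twoPathwayParams(kc0, 0.5, ks0, xs0, kBT)
  }
  df <- data.frame(f = f, ly = ly)
  fit <- try(minpack.lm::nlsLM(
    ly ~ -log(exp(lkc - exp(lxc) * f / kBT) + exp(lks + exp(lxs) * f / kBT)),
    start = list(lkc = log(start@kc), lxc = log(start@xc),
                 lks = log(start@ks), lxs = log(start@xs)),
    data = df,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    params <- twoPathwayParams(exp(cf[["lkc"]]), exp(cf[["lxc"]]),
                               exp(cf[["lks"]]), exp(cf[["lxs"]]), kBT)
    return(list(params = params,
                optimumForce = twoPathwayOptimumForce(params),
                converged = TRUE,
                residuals = as.numeric(stats::resid(fit))))
  }
  ## the catch amplitude is degenerate for monotone-slip data; refit the
  ## single slip pathway and report the catch term as zero
  fit2 <- try(minpack.lm::nlsLM(
    ly ~ -(lks + exp(lxs) * f / kBT),
    start = list(lks = log(start@ks), lxs = log(start@xs)), data = df,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit2, "try-error"))
    return(list(params = start, optimumForce = NA_real_, converged = FALSE,
                residuals = rep(NA_real_, nrow(binned))))
  cf <- stats::coef(fit2)
  params <- twoPathwayParams(0, start@xc, exp(cf[["lks"]]),
                             exp(cf[["lxs"]]), kBT)
  list(params = params, optimumForce = NA_real_, converged = TRUE,
       catchDegenerate = TRUE,
       residuals = as.numeric(stats::resid(fit2)))
}
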