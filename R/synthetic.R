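#' @include AllClasses.R traj-io.R
NULL

## Run expr with a private, seeded RNG; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specification of one synthetic interface bond
#'
#' Bound-state geometry (donor-acceptor 2.9 Angstrom, 10-degree deviation)
#' satisfies the default hydrogen-bond criteria; the unbound state
#' (5.5 Angstrom) violates them, so detection recovers the hidden state
#' sequence exactly.
#'
#' @param targetOccupancy stationary occupancy omega* in [0, 1].
#' @param switchRate per-frame switching intensity r in (0, 1]: the
#'   transition probabilities are r * omega* (unbound to bound) and
#'   r * (1 - omega*) (bound to unbound), giving stationary probability
#'   omega* and first-lag autocorrelation 1 - r.
#' @return list of class parameters for \code{\link{genInterfaceTrajectory}}.
#' @export
bondSpec <- function(targetOccupancy, switchRate = 0.5) {
  if (targetOccupancy < 0 || targetOccupancy > 1)
    stop("targetOccupancy must lie in [0, 1]")
  if (switchRate <= 0 || switchRate > 1)
    stop("switchRate must lie in (0, 1]")
  list(omega = targetOccupancy, rate = switchRate,
       dBound = 2.9, devBound = 10, dUnbound = 5.5)
}

#' Effective independent sample count of a two-state Markov occupancy
#'
#' For a chain with switching intensity r the lag-1 autocorrelation is
#' 1 - r and the variance of the occupancy estimator over n frames is
#' inflated by (1 + lambda) / (1 - lambda); the effective count is
#' n r / (2 - r).
#'
#' @param n number of frames.
#' @param switchRate r in (0, 1].
#' @return effective independent sample count.
#' @export
markovEffectiveSamples <- function(n, switchRate) {
  n * switchRate / (2 - switchRate)
}

.simulateTwoState <- function(omega, rate, n) {
  if (omega <= 0) return(rep(FALSE, n))
  if (omega >= 1) return(rep(TRUE, n))
  s <- logical(n)
  s[1] <- stats::runif(1) < omega
  p01 <- rate * omega        # unbound -> bound
  p10 <- rate * (1 - omega)  # bound -> unbound
  u <- stats::runif(n)
  for (t in seq_len(n - 1)) {
    s[t + 1] <- if (s[t]) u[t] >= p10 else u[t] < p01
  }
  s
}

## Rigid atom layout of one donor/acceptor module. Ligand residue (chain A)
## carries the amide donor N-H; receptor residue (chain B) carries the
## carbonyl acceptor O. Unbound frames translate the receptor residue along
## +x so the donor-acceptor distance fails the criterion.
.bondModule <- function(resno, yOffset, spec) {
  th <- spec$devBound * pi / 180
  acc <- c(spec$dBound * cos(th), spec$dBound * sin(th) + yOffset, 0)
  lig <- rbind(
    N  = c(0, yOffset, 0),
    H  = c(1.01, yOffset, 0),
    CA = c(-0.85, yOffset + 1.2, 0),
    C  = c(-2.3, yOffset + 1.0, 0),
    O  = c(-3.0, yOffset + 1.9, 0)
  )
  rec <- rbind(
    O  = acc,
    C  = acc + c(1.05, 0.65, 0),
    CA = acc + c(2.55, 0.70, 0),
    N  = acc + c(3.3, 1.85, 0)
  )
  shift <- c(spec$dUnbound - spec$dBound, 0, 0)
  list(lig = lig, rec = rec, recShift = shift)
}

#' Generate a synthetic two-chain interface trajectory
#'
#' Two chains of glycine-like residues host one designed donor-H-acceptor
#' triple per bond; each bond's per-frame bound/unbound state follows a
#' seeded two-state Markov chain with the prescribed stationary occupancy.
#' All non-bond geometry is rigid; modules are spaced far enough apart that
#' bonds cannot interfere. Deterministic given (parameters, seed).
#'
#' @param bonds list of \code{\link{bondSpec}} objects.
#' @param nFrames number of frames (>= 1).
#' @param seed integer RNG seed.
#' @param frameInterval ns between frames (metadata only).
#' @return list: \code{trajectory} (\linkS4class{Trajectory}),
#'   \code{presence} (logical bonds x frames ground-truth matrix),
#'   \code{ligandChain}, \code{receptorChain}, \code{bondResidues}
#'   (ligand/receptor residue number per bond).
#' @export
genInterfaceTrajectory <- function(bonds, nFrames, seed,
                                   frameInterval = 0.1) {
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (!length(bonds)) stop("need >= 1 bond spec")
  spacing <- 15
  nb <- length(bonds)
  modules <- lapply(seq_len(nb), function(k)
    .bondModule(k, (k - 1) * spacing, bonds[[k]]))
  topo <- list(); base <- list()
  eleno <- 0L
  recAtomIdx <- vector("list", nb)
  for (k in seq_len(nb)) {
    m <- modules[[k]]
    for (a in rownames(m$lig)) {
      eleno <- eleno + 1L
      topo[[eleno]] <- data.frame(
        eleno = eleno, elety = a,
        elesy = substr(a, 1, 1), resid = "GLY", resno = k, chain = "A",
        stringsAsFactors = FALSE)
      base[[eleno]] <- m$lig[a, ]
    }
    idx0 <- eleno
    for (a in rownames(m$rec)) {
      eleno <- eleno + 1L
      topo[[eleno]] <- data.frame(
        eleno = eleno, elety = a,
        elesy = substr(a, 1, 1), resid = "GLY", resno = k, chain = "B",
        stringsAsFactors = FALSE)
      base[[eleno]] <- m$rec[a, ]
    }
    recAtomIdx[[k]] <- (idx0 + 1L):eleno
  }
  topo <- do.call(rbind, topo)
  base <- do.call(rbind, base)
  presence <- .withSeed(seed, {
    m <- matrix(FALSE, nrow = nb, ncol = nFrames)
    for (k in seq_len(nb))
      m[k, ] <- .simulateTwoState(bonds[[k]]$omega, bonds[[k]]$rate, nFrames)
    m
  })
  coords <- array(rep(base, nFrames), dim = c(nrow(base), 3, nFrames))
  for (k in seq_len(nb)) {
    off <- which(!presence[k, ])
    if (length(off))
      for (f in off)
        coords[recAtomIdx[[k]], , f] <-
          sweep(coords[recAtomIdx[[k]], , f], 2, modules[[k]]$recShift, `+`)
  }
  traj <- Trajectory(topo, coords,
                     time = (seq_len(nFrames) - 1) * frameInterval,
                     frameInterval = frameInterval)
  list(trajectory = traj, presence = presence,
       ligandChain = "A", receptorChain = "B",
       bondResidues = data.frame(ligand_resid = seq_len(nb),
                                 receptor_resid = seq_len(nb)))
}

.defaultAnchors <- list(
  "slip" = c(0.60, 0.45, 0.30, 0.20),
  "catch-slip" = c(0.30, 0.60, 0.45, 0.30),
  "slip-catch-slip" = c(0.70, 0.50, 0.60, 0.40),
  "catch-slip-catch" = c(0.25, 0.50, 0.30, 0.45)
)

#' Specification of one bond's occupancy-versus-force law
#'
#' @param pattern one of \code{"slip"}, \code{"catch-slip"},
#'   \code{"slip-catch-slip"}, \code{"catch-slip-catch"}.
#' @param anchors occupancies per force level (default: a canonical set
#'   for the pattern). Noise-free anchors must classify to the declared
#'   pattern at epsilon = 0; this is validated.
#' @param noiseSd replicate noise standard deviation (default 0).
#' @return list of class parameters for \code{\link{genOccupancyTable}}.
#' @export
responseLawSpec <- function(pattern, anchors = NULL, noiseSd = 0) {
  pattern <- match.arg(pattern, names(.defaultAnchors))
  if (is.null(anchors)) anchors <- .defaultAnchors[[pattern]]
  got <- classifyResponse(anchors, epsilon = 0)@pattern
  if (got != pattern)
    stop("anchors classify as '", got, "', not the declared '", pattern, "'")
  list(pattern = pattern, anchors = anchors, noiseSd = noiseSd)
}

#' Generate a force-panel occupancy table with known response classes
#'
#' @param laws list of \code{\link{responseLawSpec}} objects.
#' @param forces strictly increasing force levels, pN; must match the
#'   anchor length (default 0, 25, 50, 75).
#' @param replicates bonds generated per law (default 1).
#' @param seed integer RNG seed.
#' @return list: \code{table} (\linkS4class{OccupancyTable}),
#'   \code{truth} (data.frame ligand_residue, receptor_residue, pattern).
#' @export
genOccupancyTable <- function(laws, forces = c(0, 25, 50, 75),
                              replicates = 1, seed = 1) {
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  for (l in laws)
    if (length(l$anchors) != length(forces))
      stop("anchor count must equal the number of force levels")
  .withSeed(seed, {
    recs <- list(); truth <- list(); b <- 0L
    for (i in seq_along(laws)) {
      for (rep in seq_len(replicates)) {
        b <- b + 1L
        occ <- laws[[i]]$anchors
        if (laws[[i]]$noiseSd > 0)
          occ <- pmin(0.999, pmax(0.001,
                 occ + stats::rnorm(length(occ), 0, laws[[i]]$noiseSd)))
        recs[[b]] <- data.frame(
          condition = as.character(forces),
          ligand_chain = "L", ligand_resid = 200L + b,
          ligand_resname = "GLU",
          receptor_chain = "R", receptor_resid = 10L + b,
          receptor_resname = "LYS",
          donor_atom = NA_character_, acceptor_atom = NA_character_,
          kind = "hbond", occupancy = occ, stringsAsFactors = FALSE)
        truth[[b]] <- data.frame(
          ligand_residue = .residueLabel("GLU", 200L + b),
          receptor_residue = .residueLabel("LYS", 10L + b),
          pattern = laws[[i]]$pattern, stringsAsFactors = FALSE)
      }
    }
    list(table = new("OccupancyTable", records = do.call(rbind, recs)),
         truth = do.call(rbind, truth))
  })
}

#' Generate a ramp-then-clamp force trace
#'
#' Force rises linearly at springConstant * velocity until either the
#' clamp threshold (then held constant) or rupture (then a short linear
#' fall to zero, producing the triangular rupture peak read by
#' \code{\link{ruptureForce}}).
#'
#' @param springConstant pN/Angstrom (default 13.89).
#' @param velocity pulling velocity, Angstrom/ns.
#' @param duration total trace length, ns.
#' @param dt sampling interval, ns.
#' @param ruptureTime ns at which the complex ruptures (NULL for none).
#' @param clampForce clamp threshold, pN (NULL for pure ramp).
#' @param noiseSd Gaussian force noise, pN.
#' @param seed integer RNG seed (only used when noiseSd > 0).
#' @return a \linkS4class{ForceTrace} with phase labels.
#' @export
genRampClampTrace <- function(springConstant = 13.89, velocity,
                              duration, dt = 0.01, ruptureTime = NULL,
                              clampForce = NULL, noiseSd = 0, seed = 1) {
  tt <- seq(0, duration, by = dt)
  slope <- springConstant * velocity
  f <- slope * tt
  phase <- rep("ramp", length(tt))
  if (!is.null(clampForce)) {
    tc <- clampForce / slope
    if (is.null(ruptureTime) || ruptureTime > tc) {
      cl <- tt >= tc
      f[cl] <- clampForce
      phase[cl] <- "clamp"
    }
  }
  if (!is.null(ruptureTime)) {
    inRamp <- is.null(clampForce) || ruptureTime <= clampForce / slope
    if (inRamp) {
      peak <- slope * ruptureTime
      fall <- max(ruptureTime * 0.05, 2 * dt)
      post <- tt > ruptureTime
      f[post] <- pmax(0, peak * (1 - (tt[post] - ruptureTime) / fall))
    }
  }
  if (noiseSd > 0)
    f <- .withSeed(seed, f + stats::rnorm(length(f), 0, noiseSd))
  new("ForceTrace", time = tt, force = f, phase = phase)
}

#' Generate single-bond AFM lifetimes under a two-pathway off-rate
#'
#' Lifetimes at each clamp force are exponential with rate
#' k(f) = k_c exp(-x_c f/kBT) + k_s exp(x_s f/kBT).
#'
#' @param params a \linkS4class{TwoPathwayParams}.
#' @param forces clamp forces, pN.
#' @param nPerForce records per force (vectorised over forces).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{clamp_force}, \code{lifetime}.
#' @export
genAfmLifetimes <- function(params, forces, nPerForce, seed = 1) {
  stopifnot(is(params, "TwoPathwayParams"))
  nPerForce <- rep_len(nPerForce, length(forces))
  .withSeed(seed, {
    rows <- lapply(seq_along(forces), function(i) {
      if (nPerForce[i] == 0)
        return(data.frame(clamp_force = numeric(0), lifetime = numeric(0)))
      rate <- 1 / twoPathwayLifetime(forces[i], params)
      data.frame(clamp_force = forces[i],
                 lifetime = stats::rexp(nPerForce[i], rate))
    })
    do.call(rbind, rows)
  })
}

## Rotation taking +z onto a given unit axis (Rodrigues).
.rotationFromZ <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c0 <- sum(z * axis)
  if (abs(c0 + 1) < 1e-12) return(diag(c(1, -1, -1)))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c0)
}

#' Generate ideal alpha-helix C-alpha coordinates
#'
#' @param nRes number of residues (>= 4).
#' @param rise rise per residue along the axis, Angstrom (default 1.5).
#' @param twist turn per residue, degrees (default 100).
#' @param radius helix radius, Angstrom (default 2.3).
#' @param axis axis direction (default +z).
#' @param origin first-residue axis origin.
#' @return nRes x 3 matrix of C-alpha coordinates, N to C.
#' @export
genHelix <- function(nRes, rise = 1.5, twist = 100, radius = 2.3,
                     axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (nRes < 4) stop("need >= 4 residues")
  i <- seq_len(nRes) - 1
  th <- i * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), i * rise)
  R <- .rotationFromZ(axis)
  sweep(xyz %*% t(R), 2, origin, `+`)
}
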