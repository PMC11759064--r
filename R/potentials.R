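# Closed-form interaction terms. These are the reference implementations used
# in documentation and tests; the integrator evaluates the same expressions in
# compiled code.

#' FENE bond potential
#'
#' Finitely extensible nonlinear elastic spring,
#' U(r) = -1/2 k R0^2 log(1 - r^2/R0^2), the backbone bond of the bead-spring
#' chains. The returned force magnitude k r / (1 - r^2/R0^2) is directed so
#' as to restore the bond.
#'
#' @param r bond length (sigma units), must satisfy 0 <= r < R0
#' @param k spring coefficient (eps/sigma^2); default 30
#' @param R0 maximum extensibility (sigma); default 1.5
#' @return list with vectors `energy` and `force`
#' @export
fene_bond <- function(r, k = 30, R0 = 1.5) {
  stopifnot(all(r >= 0))
  if (any(r >= R0)) {
    i <- which(r >= R0)[1]
    stop(sprintf("FENE bond overstretched: r = %.4f >= R0 = %.4f (element %d)",
                 r[i], R0, i))
  }
  q <- 1 - r^2 / R0^2
  list(energy = -0.5 * k * R0^2 * log(q), force = k * r / q)
}

#' Lennard-Jones pair potential
#'
#' U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) truncated at `rc`. With
#' `shifted_force = TRUE` a linear term is added so that both the energy and
#' the force go continuously to zero at the cutoff; with `FALSE` the
#' potential is plainly truncated. `rc = 2^(1/6) sigma` gives the purely
#' repulsive (WCA) branch used for spacer and solvent beads; attractive
#' interactions typically use `rc = 4 sigma`.
#'
#' @param r pair distance, > 0
#' @param eps well depth
#' @param sigma bead diameter
#' @param rc cutoff radius
#' @param shifted_force force-shifted truncation flag
#' @return list with vectors `energy` and `force` (force = -dU/dr, positive
#'   when repulsive)
#' @export
lj_pair <- function(r, eps = 1, sigma = 1, rc = 2^(1/6) * sigma,
                    shifted_force = FALSE) {
  if (any(r <= 0)) stop("lj_pair: r must be positive")
  sr6 <- (sigma / r)^6
  u <- 4 * eps * sr6 * (sr6 - 1)
  f <- 24 * eps * sr6 * (2 * sr6 - 1) / r
  if (shifted_force) {
    src6 <- (sigma / rc)^6
    urc <- 4 * eps * src6 * (src6 - 1)
    frc <- 24 * eps * src6 * (2 * src6 - 1) / rc
    u <- u - urc + (r - rc) * frc
    f <- f - frc
  }
  u[r > rc] <- 0
  f[r > rc] <- 0
  list(energy = u, force = f)
}

#' Harmonic angle potential
#'
#' U(theta) = K (theta - theta0)^2 between three consecutive beads. The
#' returned torque magnitude is |dU/dtheta| = 2 K |theta - theta0|; in the
#' engine the corresponding forces are distributed over the three beads so
#' that net force and net torque vanish.
#'
#' @param theta angle in radians, in (0, pi]
#' @param k stiffness K (energy/rad^2)
#' @param theta0 equilibrium angle in radians
#' @return list with vectors `energy` and `torque`
#' @export
angle_term <- function(theta, k, theta0) {
  stopifnot(all(theta > 0), all(theta <= pi + 1e-12))
  list(energy = k * (theta - theta0)^2, torque = 2 * k * abs(theta - theta0))
}

#' Hydropathy-scaled (Ashbaugh-Hatch) pair potential
#'
#' The lambda-scaled Lennard-Jones form used by one-bead-per-residue chain
#' models: inside the LJ minimum the full repulsion acts shifted up by
#' (1 - lambda) eps, outside it the attraction is scaled by lambda, and the
#' whole potential is energy-shifted to vanish at `rc`. lambda = 1 recovers
#' the plain LJ potential, lambda = 0 is purely repulsive.
#'
#' @param r pair distance, > 0
#' @param lambda hydropathy weight of the pair (arithmetic mean of the two
#'   residues' lambdas), in [0, 1.2]
#' @param eps well depth
#' @param sigma pair diameter (arithmetic mean of the two residues' sigmas)
#' @param rc cutoff radius (> 2^(1/6) sigma)
#' @return list with vectors `energy` and `force`
#' @export
hps_pair <- function(r, lambda, eps = 1, sigma = 1, rc = 4 * sigma) {
  if (any(r <= 0)) stop("hps_pair: r must be positive")
  stopifnot(lambda >= 0, lambda <= 1.2)
  rmin <- 2^(1/6) * sigma
  lj <- function(x) {
    s6 <- (sigma / x)^6
    4 * eps * s6 * (s6 - 1)
  }
  flj <- function(x) {
    s6 <- (sigma / x)^6
    24 * eps * s6 * (2 * s6 - 1) / x
  }
  ushift <- if (rc > rmin) lambda * lj(rc) else 0
  u <- ifelse(r <= rmin, lj(r) + (1 - lambda) * eps - ushift,
              lambda * lj(r) - ushift)
  f <- ifelse(r <= rmin, flj(r), lambda * flj(r))
  u[r > rc] <- 0
  f[r > rc] <- 0
  list(energy = u, force = f)
}

#' Nonbonded force-field parameter set
#'
#' Per-type-pair matrices of Lennard-Jones parameters plus the global pair
#' style. Type ids are small integers; by convention the builders use
#' 1 = spacer/polymer, 2 = solvent, 3 = sticker. A `lambda` entry of `NA`
#' selects the plain LJ form for that pair; a finite value selects the
#' hydropathy-scaled form of [hps_pair()].
#'
#' @param n_types number of bead types
#' @param eps,sigma,rc scalars or `n_types` x `n_types` matrices
#' @param lambda scalar or matrix; `NA` = plain LJ
#' @param shift_force use force-shifted truncation for plain-LJ pairs
#' @param style `"lj"` for production, `"soft"` for the cosine push-off
#'   potential used during initial-state relaxation (then `eps` is the
#'   amplitude and `rc` the range)
#' @param fene named vector `c(k =, R0 =)` used for FENE backbone bonds
#' @return object of class `forcefield`
#' @export
forcefield <- function(n_types = 1, eps = 1, sigma = 1, rc = 2^(1/6),
                       lambda = NA_real_, shift_force = FALSE,
                       style = c("lj", "soft"), fene = c(k = 30, R0 = 1.5)) {
  style <- match.arg(style)
  as_mat <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n_types, ncol(x) == n_types)
      x
    } else matrix(x, n_types, n_types)
  }
  ff <- structure(list(
    n_types = as.integer(n_types),
    eps = as_mat(eps), sigma = as_mat(sigma), rc = as_mat(rc),
    lambda = as_mat(lambda),
    shift_force = isTRUE(shift_force),
    style = style,
    fene = fene
  ), class = "forcefield")
  stopifnot(all(ff$eps >= 0), all(ff$sigma > 0), all(ff$rc > 0))
  ff
}

#' Set the parameters of one type pair
#'
#' @param ff a [forcefield()]
#' @param i,j type ids (symmetrised automatically)
#' @param eps,rc,sigma,lambda values to set; omitted fields are untouched
#' @return the modified forcefield
#' @export
set_pair <- function(ff, i, j, eps = NULL, rc = NULL, sigma = NULL,
                     lambda = NULL) {
  stopifnot(inherits(ff, "forcefield"), i <= ff$n_types, j <= ff$n_types)
  for (field in c("eps", "rc", "sigma", "lambda")) {
    v <- get(field)
    if (!is.null(v)) {
      ff[[field]][i, j] <- v
      ff[[field]][j, i] <- v
    }
  }
  ff
}

# engine-facing representation
ff_to_pairlist <- function(ff) {
  list(eps = ff$eps, sigma = ff$sigma, rc = ff$rc, lambda = ff$lambda,
       style = if (ff$style == "soft") 1L else 0L,
       shift_force = ff$shift_force)
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield> %d type(s), style = %s%s\n", x$n_types, x$style,
              if (x$shift_force) ", force-shifted" else ""))
  cat(sprintf("  FENE: k = %g, R0 = %g\n", x$fene["k"], x$fene["R0"]))
  cat("  eps:\n"); print(x$eps)
  cat("  rc:\n"); print(x$rc)
  invisible(x)
}
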