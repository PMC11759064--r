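# Liquid-vapor coexistence from slab simulations and the critical point by
# rectilinear diameters plus the universal order-parameter scaling.

#' Coexistence densities from a density profile
#'
#' Fits the folded slab profile to the hyperbolic-tangent interface form
#' rho(x) = rho_v + (rho_l - rho_v)/2 * (1 - tanh((|x - x0| - xi)/w)),
#' returning the liquid and vapor plateaus and the interface width. A
#' profile without two-phase structure returns a `supercritical` flag.
#'
#' @param x positions along the profile axis
#' @param rho number densities at `x`
#' @param temperature optional temperature label carried into the result
#' @param periodic treat `x` as periodic and center the dense phase by the
#'   density-weighted circular mean before folding (default TRUE)
#' @return object of class `coexistence_point`: list with `temperature`,
#'   `rho_l`, `rho_v`, `width`, `supercritical`
#' @export
coexistence_from_profile <- function(x, rho, temperature = NA_real_,
                                     periodic = TRUE) {
  stopifnot(length(x) == length(rho), length(x) >= 8)
  L <- max(x) - min(x) + (x[2] - x[1])
  if (periodic) {
    # density-weighted circular mean locates the slab center
    ang <- 2 * pi * (x - min(x)) / L
    cx <- sum(rho * cos(ang)); sx <- sum(rho * sin(ang))
    center <- min(x) + (atan2(sx, cx) %% (2 * pi)) * L / (2 * pi)
    xi <- abs(((x - center + L / 2) %% L) - L / 2)
  } else {
    center <- x[which.max(rho)]
    xi <- abs(x - center)
  }
  hi <- quantile(rho, 0.9); lo <- quantile(rho, 0.1)
  if (hi - lo < 0.05 * max(hi, 1e-12) || hi <= 0) {
    return(structure(list(temperature = temperature, rho_l = mean(rho),
                          rho_v = mean(rho), width = NA_real_,
                          supercritical = TRUE),
                     class = "coexistence_point"))
  }
  par0 <- c(rho_l = unname(hi), rho_v = unname(lo),
            x0 = unname(quantile(xi, 0.5)), w = L / 20)
  fn <- function(p) {
    pred <- p[2] + (p[1] - p[2]) / 2 * (1 - tanh((xi - p[3]) / abs(p[4])))
    pred - rho
  }
  fit <- minpack.lm::nls.lm(par0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  rho_l <- max(p[1], p[2]); rho_v <- max(min(p[1], p[2]), 0)
  structure(list(temperature = temperature, rho_l = unname(rho_l),
                 rho_v = unname(rho_v), width = abs(unname(p[4])),
                 supercritical = FALSE),
            class = "coexistence_point")
}

#' Coexistence densities from a slab trajectory
#'
#' Time-averages the density profile of the selected species over the
#' frames, then extracts the coexistence point with
#' [coexistence_from_profile()].
#'
#' @param frames list of wrapped N x 3 coordinate frames
#' @param box a [simulation_box()]
#' @param axis slab normal (default 1 = x)
#' @param n_bins profile bins
#' @param type,species optional species selection as in [density_profile()]
#' @param temperature temperature label for the result
#' @return a `coexistence_point`
#' @export
coexistence_from_slab <- function(frames, box, axis = 1, n_bins = 60,
                                  type = NULL, species = NULL,
                                  temperature = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  profs <- lapply(frames, function(fr) {
    fr <- fr
    for (ax in 1:3) if (box$periodic[ax]) fr[, ax] <- fr[, ax] %% box$L[ax]
    density_profile(fr, box, axis = axis, n_bins = n_bins, type = type,
                    species = species)
  })
  rho <- rowMeans(vapply(profs, function(p) p$rho, numeric(n_bins)))
  coexistence_from_profile(profs[[1]]$x, rho, temperature = temperature,
                           periodic = box$periodic[axis])
}

#' @export
print.coexistence_point <- function(x, ...) {
  if (x$supercritical)
    cat(sprintf("<coexistence_point> T = %.4g: supercritical (single plateau)\n",
                x$temperature))
  else
    cat(sprintf("<coexistence_point> T = %.4g: rho_l = %.4g, rho_v = %.4g, width = %.3g\n",
                x$temperature, x$rho_l, x$rho_v, x$width))
  invisible(x)
}

#' Fit the critical point by rectilinear diameters
#'
#' Simultaneous least squares of
#' (rho_l + rho_v)/2 = rho_c + A (Tc - T) and
#' rho_l - rho_v = Drho0 (1 - T/Tc)^beta
#' with the order-parameter exponent fixed at the 3D Ising value
#' beta = 0.325 (overridable). Tc is parameterised as
#' max(T) + exp(u) so the fit cannot cross the data.
#'
#' @param points data.frame with columns `T`, `rho_l`, `rho_v` (>= 3 rows,
#'   all subcritical), or a list of `coexistence_point`s
#' @param beta order-parameter exponent (default 0.325)
#' @return object of class `critical_fit`: `Tc`, `rho_c`, `A`, `drho0`,
#'   `beta`, `residual`
#' @export
fit_critical_point <- function(points, beta = 0.325) {
  if (is.list(points) && inherits(points[[1]], "coexistence_point"))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(T = p$temperature, rho_l = p$rho_l, rho_v = p$rho_v)))
  stopifnot(all(c("T", "rho_l", "rho_v") %in% names(points)))
  if (nrow(points) < 3)
    stop("fit error: need at least 3 coexistence points")
  stopifnot(all(points$rho_l > points$rho_v))
  Tmax <- max(points$T)
  dia <- (points$rho_l + points$rho_v) / 2
  dif <- points$rho_l - points$rho_v
  fn <- function(p) {
    Tc <- Tmax + exp(p[1]); rho_c <- p[2]; A <- p[3]; d0 <- exp(p[4])
    c(dia - (rho_c + A * (Tc - points$T)),
      dif - d0 * (1 - points$T / Tc)^beta)
  }
  # init: linear diameter extrapolated to the vanishing of dif^( 1/beta )
  lfit <- lm(dif^(1 / beta) ~ points$T)
  Tc0 <- unname(-coef(lfit)[1] / coef(lfit)[2])
  if (!is.finite(Tc0) || Tc0 <= Tmax) Tc0 <- Tmax * 1.1
  p0 <- c(log(Tc0 - Tmax), mean(dia), 0.1,
          log(max(dif) / max(1e-6, (1 - min(points$T) / Tc0)^beta)))
  fit <- minpack.lm::nls.lm(p0, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0, 9))
    stop("fit error: critical-point fit did not converge")
  p <- unname(fit$par)
  structure(list(Tc = Tmax + exp(p[1]), rho_c = p[2], A = p[3],
                 drho0 = exp(p[4]), beta = beta,
                 residual = sqrt(sum(fit$fvec^2) / length(fit$fvec))),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("<critical_fit> Tc = %.4g eps/kB, rho_c = %.4g sigma^-3 (A = %.3g, drho0 = %.3g, beta = %g fixed)\n",
              x$Tc, x$rho_c, x$A, x$drho0, x$beta))
  invisible(x)
}

#' @export
coef.critical_fit <- function(object, ...) {
  c(Tc = object$Tc, rho_c = object$rho_c, A = object$A,
    drho0 = object$drho0, beta = object$beta)
}
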