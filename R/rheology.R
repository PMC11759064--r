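# Viscoelastic analysis: multi-tau autocorrelation, the Green-Kubo
# relaxation-modulus estimator, oscillatory-shear moduli, generalized
# Maxwell fits, viscosity, crossovers and response classification.

#' Multi-tau autocorrelation
#'
#' Hierarchical block-averaging autocorrelation with logarithmically spaced
#' lags: level 0 holds the first `p` lags at the native stride, every
#' higher level averages pairs of samples of the level below and covers
#' lags p/2 ... p-1 at twice the coarser stride. Returns the unnormalized
#' autocorrelation <x(0) x(t)>.
#'
#' @param x numeric sample series on a uniform stride
#' @param dt time stride between samples; must be a scalar (a vector of
#'   per-sample times is rejected unless uniform)
#' @param p lags per level (>= 4, even); series must hold at least 2p
#'   samples
#' @return data.frame with columns `lag` (time) and `acf`
#' @export
multitau_correlate <- function(x, dt, p = 16) {
  if (length(dt) > 1) {
    dd <- diff(dt)
    if (max(abs(dd - dd[1])) > 1e-8 * max(abs(dd), 1e-300))
      stop("non-uniform time stride")
    dt <- dd[1]
  }
  stopifnot(p >= 4, p %% 2 == 0, length(x) >= 2 * p, dt > 0)
  acf_at <- function(v, k) {
    n <- length(v)
    if (k >= n) return(NA_real_)
    mean(v[1:(n - k)] * v[(1 + k):n])
  }
  lags <- 0:(p - 1)
  vals <- vapply(lags, function(k) acf_at(x, k), numeric(1))
  out_lag <- lags * dt
  out_val <- vals
  level <- 1
  v <- x
  repeat {
    n2 <- floor(length(v) / 2)
    if (n2 < p) break
    v <- (v[seq(1, 2 * n2, 2)] + v[seq(2, 2 * n2, 2)]) / 2
    stride <- dt * 2^level
    ks <- (p / 2):(p - 1)
    vals <- vapply(ks, function(k) acf_at(v, k), numeric(1))
    keep <- !is.na(vals)
    out_lag <- c(out_lag, ks[keep] * stride)
    out_val <- c(out_val, vals[keep])
    level <- level + 1
  }
  data.frame(lag = out_lag, acf = out_val)
}

#' Green-Kubo relaxation modulus G*(t)
#'
#' Equilibrium stress-autocorrelation estimator for an isotropic system:
#' \deqn{G^*(t) = \frac{V}{5 k_B T}\Big[\sum_{ab \in \{xy,xz,yz\}} C_{ab}(t)
#'   + \frac{1}{6}\sum C_{N_{ab}}(t)\Big]}
#' where C_ab are the off-diagonal stress autocorrelations and C_N the
#' autocorrelations of the normal-stress differences N_ab = S_aa - S_bb,
#' each computed with [multitau_correlate()]. If the diagonal components
#' are missing the estimator falls back to the off-diagonal-only average
#' with prefactor V/(3 kB T) and flags the result (attribute
#' `"offdiag_only"`).
#'
#' @param stress a [stress_series()] from an equilibrium run (no applied
#'   strain)
#' @param p lags per multi-tau level
#' @return object of class `complex_modulus`: data.frame `t`, `G`
#' @export
gk_complex_modulus <- function(stress, p = 16) {
  stopifnot(inherits(stress, "stress_series"))
  if ("strain" %in% names(stress) && any(abs(stress$strain) > 1e-12))
    stop("Green-Kubo estimator needs an equilibrium series (no applied strain)")
  V <- attr(stress, "volume")
  Temp <- attr(stress, "temperature")
  dt <- stress$t[2] - stress$t[1]
  cxy <- multitau_correlate(stress$sxy, dt, p)
  cxz <- multitau_correlate(stress$sxz, dt, p)
  cyz <- multitau_correlate(stress$syz, dt, p)
  nd <- normal_diffs(stress)
  offdiag_only <- is.null(nd)
  if (offdiag_only) {
    G <- V / (3 * Temp) * (cxy$acf + cxz$acf + cyz$acf)
  } else {
    cnxy <- multitau_correlate(nd$nxy, dt, p)
    cnxz <- multitau_correlate(nd$nxz, dt, p)
    cnyz <- multitau_correlate(nd$nyz, dt, p)
    G <- V / (5 * Temp) * (cxy$acf + cxz$acf + cyz$acf +
                           (cnxy$acf + cnxz$acf + cnyz$acf) / 6)
  }
  structure(data.frame(t = cxy$lag, G = G),
            offdiag_only = offdiag_only,
            class = c("complex_modulus", "data.frame"))
}

#' Storage and loss moduli from an oscillatory-shear record
#'
#' Least-squares fit of the stress response to
#' A sin(wt) + B cos(wt) after discarding the first cycle:
#' G' = A/gamma0, G'' = B/gamma0, Sigma0 = sqrt(A^2+B^2),
#' delta = atan2(B, A).
#'
#' @param stress a [stress_series()] with the applied `strain` column, or a
#'   data.frame with columns `t`, `strain`, `sxy`
#' @param omega drive frequency (rad/tau)
#' @param gamma0 strain amplitude; inferred from the strain column if
#'   omitted
#' @param discard_cycles initial cycles dropped as transient (default 1)
#' @param max_residual error if the fit residual exceeds this fraction of
#'   Sigma0 (nonlinearity / noise guard)
#' @return one-row data.frame: `omega`, `Gp`, `Gpp`, `sigma0`, `delta`,
#'   `residual`
#' @export
os_moduli <- function(stress, omega, gamma0 = NULL, discard_cycles = 1,
                      max_residual = 0.5) {
  t <- stress$t
  period <- 2 * pi / omega
  if ((max(t) - min(t)) < (discard_cycles + 3) * period)
    stop("need at least ", discard_cycles + 3, " full cycles of data")
  keep <- t >= min(t) + discard_cycles * period
  t <- t[keep]
  y <- stress$sxy[keep]
  if (is.null(gamma0)) {
    if (!"strain" %in% names(stress) || all(stress$strain == 0))
      stop("gamma0 not given and no strain column present")
    g <- stress$strain[keep]
    # strain is gamma0 sin(wt): amplitude by quadrature fit
    gs <- sin(omega * t); gc <- cos(omega * t)
    cf <- coef(lm(g ~ 0 + gs + gc))
    gamma0 <- sqrt(sum(cf^2))
  }
  s <- sin(omega * t); co <- cos(omega * t)
  fit <- lm(y ~ s + co)
  A <- coef(fit)[["s"]]; B <- coef(fit)[["co"]]
  sigma0 <- sqrt(A^2 + B^2)
  # nonlinearity / noise guard on the cycle-averaged waveform: folding the
  # response onto one period averages away thermal noise, so the residual
  # measures systematic distortion of the sinusoid
  phase_bin <- floor(((omega * t) %% (2 * pi)) / (2 * pi) * 24)
  ybar <- tapply(residuals(fit), phase_bin, mean)
  resid <- sqrt(mean(ybar^2))
  if (sigma0 > 0 && resid > max_residual * sigma0)
    stop(sprintf(
      "stress fit residual %.3g exceeds %.0f%% of the stress amplitude %.3g (nonlinear or too noisy)",
      resid, 100 * max_residual, sigma0))
  data.frame(omega = omega, Gp = A / gamma0, Gpp = B / gamma0,
             sigma0 = sigma0, delta = atan2(B, A), residual = resid)
}

#' @importFrom stats residuals
NULL

#' Linear-regime check over a strain-amplitude sweep
#'
#' Returns the largest strain amplitude whose storage and loss moduli stay
#' within `tol` (default 10%) of the smallest-amplitude values.
#'
#' @param sweep data.frame with columns `gamma0`, `Gp`, `Gpp` at a fixed
#'   frequency (>= 3 amplitudes)
#' @param tol relative deviation defining the linear window
#' @return the largest linear gamma0; attribute `"window"` holds the
#'   accepted amplitudes. If no amplitude beyond the smallest qualifies the
#'   result carries attribute `"flagged" = TRUE`.
#' @export
linear_regime_check <- function(sweep, tol = 0.1) {
  stopifnot(all(c("gamma0", "Gp", "Gpp") %in% names(sweep)),
            nrow(sweep) >= 3)
  sweep <- sweep[order(sweep$gamma0), ]
  ref <- sweep[1, ]
  rel <- pmax(abs(sweep$Gp - ref$Gp) / max(abs(ref$Gp), 1e-300),
              abs(sweep$Gpp - ref$Gpp) / max(abs(ref$Gpp), 1e-300))
  ok <- rel <= tol
  window <- sweep$gamma0[ok]
  out <- max(window)
  attr(out, "window") <- window
  if (length(window) <= 1) attr(out, "flagged") <- TRUE
  out
}

maxwell_Gt <- function(G, tau, t) {
  drop(exp(-outer(t, tau, "/")) %*% G)
}
maxwell_Gp <- function(G, tau, w) {
  drop(sapply(w, function(wi) sum(G * (wi * tau)^2 / (1 + (wi * tau)^2))))
}
maxwell_Gpp <- function(G, tau, w) {
  drop(sapply(w, function(wi) sum(G * wi * tau / (1 + (wi * tau)^2))))
}

#' Fit a generalized Maxwell model
#'
#' Nonlinear least squares of either a relaxation modulus
#' G(t) = sum_i G_i exp(-t/tau_i) (input of class `complex_modulus`) or a
#' modulus spectrum G'(w) = sum_i G_i w^2 tau_i^2/(1 + w^2 tau_i^2),
#' G''(w) = sum_i G_i w tau_i/(1 + w^2 tau_i^2) (input with columns
#' `omega`, `Gp`, `Gpp`). Modes are parameterised as exponentials of free
#' log-parameters, so G_i, tau_i > 0 by construction and the low-frequency
#' asymptotics obey G' ~ w^2, G'' ~ w. When `n_modes` is omitted the count
#' is grown until the residual improves by less than 5%.
#'
#' @param x a `complex_modulus` data.frame (`t`, `G`) or a spectrum
#'   (`omega`, `Gp`, `Gpp`)
#' @param n_modes number of Maxwell modes, or NULL to choose by residual
#'   plateau
#' @param t_min,t_max optional fit window for time-domain input (the tail
#'   cut beyond which G*(t) is noise is exposed here)
#' @param max_modes mode-count ceiling for automatic selection
#' @return object of class `maxwell_fit` with elements `modes`
#'   (data.frame `G`, `tau`, tau ascending), `eta_star` = sum G_i tau_i,
#'   `residual` (relative), `n_modes`
#' @export
fit_maxwell <- function(x, n_modes = NULL, t_min = NULL, t_max = NULL,
                        max_modes = 6) {
  time_domain <- inherits(x, "complex_modulus") ||
    all(c("t", "G") %in% names(x))
  if (time_domain) {
    d <- x[is.finite(x$G), ]
    if (is.null(t_min)) {
      # default short-time cut: the microscopic (bond-vibration) regime rings
      # through zero; start after the last sign change in the first percent
      # of the lag range
      ring <- which(d$G < 0 & d$t < max(d$t) / 100)
      if (length(ring) && max(ring) + 8 <= nrow(d)) t_min <- d$t[max(ring) + 1]
    }
    if (!is.null(t_min)) d <- d[d$t >= t_min, ]
    if (!is.null(t_max)) d <- d[d$t <= t_max, ]
    d <- d[d$t > 0, ]
    # tail cut: stop at the first clearly negative excursion in the noise
    # tail (never inside the first few resolved lags)
    neg <- which(d$G < -0.05 * max(d$G))
    neg <- neg[neg > 8]
    if (length(neg)) d <- d[seq_len(neg[1] - 1), ]
    if (nrow(d) < 4 || max(d$G) <= 0) stop("not enough positive G(t) data to fit")
    tgrid <- d$t; y <- d$G
    scale <- max(abs(y))
    resid_fn <- function(par, nm) {
      G <- exp(par[1:nm]); tau <- exp(par[nm + 1:nm])
      (maxwell_Gt(G, tau, tgrid) - y) / scale
    }
    span <- range(tgrid)
  } else {
    stopifnot(all(c("omega", "Gp", "Gpp") %in% names(x)))
    d <- x[is.finite(x$Gp) & is.finite(x$Gpp) & x$Gp > 0 & x$Gpp > 0, ]
    if (nrow(d) < 3) stop("not enough positive spectrum data to fit")
    w <- d$omega
    scale <- max(d$Gp, d$Gpp)
    resid_fn <- function(par, nm) {
      G <- exp(par[1:nm]); tau <- exp(par[nm + 1:nm])
      c(maxwell_Gp(G, tau, w) - d$Gp, maxwell_Gpp(G, tau, w) - d$Gpp) / scale
    }
    span <- rev(1 / range(w))
  }
  fit_n <- function(nm) {
    tau0 <- exp(seq(log(max(span[1], 1e-12)), log(span[2]), length.out = nm + 2))
    tau0 <- tau0[2:(nm + 1)]
    G0 <- if (time_domain) {
      pmax(approx(tgrid, y, xout = pmin(tau0, max(tgrid)), rule = 2)$y,
           1e-8 * scale)
    } else rep(scale / nm, nm)
    par0 <- c(log(G0), log(tau0))
    res <- minpack.lm::nls.lm(par0, fn = resid_fn, nm = nm,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ptol = 1e-12, ftol = 1e-14))
    res
  }
  pick <- NULL
  if (is.null(n_modes)) {
    best <- NULL
    for (nm in seq_len(max_modes)) {
      res <- tryCatch(fit_n(nm), error = function(e) NULL)
      if (is.null(res)) next
      rn <- sqrt(sum(res$fvec^2))
      if (!is.null(best) && rn > best$rn * 0.95) break
      best <- list(res = res, nm = nm, rn = rn)
    }
    if (is.null(best)) stop("Maxwell fit failed to converge for any mode count")
    pick <- best
  } else {
    res <- fit_n(n_modes)
    pick <- list(res = res, nm = n_modes, rn = sqrt(sum(res$fvec^2)))
  }
  nm <- pick$nm
  par <- pick$res$par
  G <- exp(par[1:nm]); tau <- exp(par[nm + 1:nm])
  ord <- order(tau)
  G <- G[ord]; tau <- tau[ord]
  # prune duplicate / vanishing modes
  keep <- G > 1e-8 * sum(G)
  G <- G[keep]; tau <- tau[keep]
  ynorm <- if (time_domain) sqrt(sum((y / scale)^2)) else
    sqrt(sum((c(d$Gp, d$Gpp) / scale)^2))
  structure(list(modes = data.frame(G = G, tau = tau),
                 n_modes = length(G),
                 eta_star = sum(G * tau),
                 residual = pick$rn / ynorm,
                 fit_window = if (time_domain) range(tgrid) else NULL,
                 domain = if (time_domain) "time" else "frequency"),
            class = "maxwell_fit")
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("<maxwell_fit> %d mode(s) (%s-domain fit), eta* = %.4g, rel. residual = %.3g\n",
              x$n_modes, x$domain, x$eta_star, x$residual))
  print(x$modes, digits = 4)
  invisible(x)
}

#' @export
summary.maxwell_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  slowest mode tau_max = %.4g tau; terminal crossover near %.3g rad/tau\n",
              max(object$modes$tau), 1 / max(object$modes$tau)))
  invisible(object)
}

#' @export
coef.maxwell_fit <- function(object, ...) {
  m <- object$modes
  setNames(c(m$G, m$tau),
           c(paste0("G", seq_len(nrow(m))), paste0("tau", seq_len(nrow(m)))))
}

#' Predict moduli from a Maxwell fit
#'
#' @param object a `maxwell_fit`
#' @param omega frequencies at which to evaluate G'(w), G''(w)
#' @param t lag times at which to evaluate G(t) (alternative to `omega`)
#' @param ... unused
#' @return a [modulus_spectrum()] (for `omega`) or a data.frame `t`, `G`
#' @export
predict.maxwell_fit <- function(object, omega = NULL, t = NULL, ...) {
  m <- object$modes
  if (!is.null(t))
    return(data.frame(t = t, G = maxwell_Gt(m$G, m$tau, t)))
  if (is.null(omega))
    omega <- 10^seq(log10(0.01 / max(m$tau)), log10(10 / min(m$tau)),
                    length.out = 60)
  modulus_spectrum(omega, maxwell_Gp(m$G, m$tau, omega),
                   maxwell_Gpp(m$G, m$tau, omega))
}

#' @export
plot.maxwell_fit <- function(x, ...) {
  sp <- predict(x)
  plot(sp$omega, sp$Gp, log = "xy", type = "l", col = "firebrick",
       xlab = expression(omega ~ "(rad/" * tau * ")"),
       ylab = "modulus (eps/sigma^3)", ...)
  graphics::lines(sp$omega, sp$Gpp, col = "steelblue")
  graphics::legend("topleft", c("G'", "G''"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Modulus spectrum container
#'
#' @param omega frequencies (rad/tau), ascending
#' @param Gp storage modulus G'
#' @param Gpp loss modulus G''
#' @return classed data.frame `modulus_spectrum`
#' @export
modulus_spectrum <- function(omega, Gp, Gpp) {
  ord <- order(omega)
  structure(data.frame(omega = omega[ord], Gp = Gp[ord], Gpp = Gpp[ord]),
            class = c("modulus_spectrum", "data.frame"))
}

#' Dynamic viscosity eta* = integral of G*(t)
#'
#' From a [fit_maxwell()] result the integral is exact: eta* = sum G_i
#' tau_i. From a raw `complex_modulus` series it is the trapezoidal
#' integral plus a single-exponential tail extrapolation; a series that has
#' not decayed (a gel) returns `Inf` with attribute `"gel" = TRUE`.
#'
#' @param x a `maxwell_fit` or a `complex_modulus` data.frame
#' @param plateau_tol plateau detection: flag as gel when the mean of the
#'   last decade of lags exceeds this fraction of G(0)
#' @return eta* (eps tau / sigma^3)
#' @export
dynamic_viscosity <- function(x, plateau_tol = 0.05) {
  if (inherits(x, "maxwell_fit")) return(sum(x$modes$G * x$modes$tau))
  stopifnot(all(c("t", "G") %in% names(x)))
  d <- x[x$t >= 0 & is.finite(x$G), ]
  G0 <- max(d$G)
  tail_win <- d$t >= max(d$t) / 10
  tail_mean <- mean(d$G[tail_win])
  if (tail_mean > plateau_tol * G0) {
    out <- Inf
    attr(out, "gel") <- TRUE
    return(out)
  }
  eta <- sum(diff(d$t) * (head(d$G, -1) + tail(d$G, -1)) / 2)
  # exponential tail beyond the data
  tl <- d[tail_win & d$G > 0, ]
  if (nrow(tl) >= 3) {
    cf <- coef(lm(log(tl$G) ~ tl$t))
    tau_tail <- -1 / unname(cf[2])
    if (is.finite(tau_tail) && tau_tail > 0)
      eta <- eta + tail(tl$G, 1) * tau_tail
  }
  eta
}

#' Crossover frequencies where G' = G''
#'
#' Locates sign changes of log G' - log G'' by linear interpolation in
#' log-log space; each crossover is tagged with which modulus dominates on
#' either side. Tangencies (zero-width sign changes) are reported with a
#' `tangent` flag.
#'
#' @param spectrum a [modulus_spectrum()] sorted by omega
#' @return data.frame `omega`, `below`, `above` (dominant modulus on each
#'   side); zero rows when the spectrum never crosses
#' @export
crossover_frequencies <- function(spectrum) {
  stopifnot(all(c("omega", "Gp", "Gpp") %in% names(spectrum)))
  sp <- spectrum[spectrum$Gp > 0 & spectrum$Gpp > 0, ]
  d <- log(sp$Gp) - log(sp$Gpp)
  out <- data.frame(omega = numeric(), below = character(),
                    above = character(), tangent = logical())
  if (nrow(sp) < 2) return(out)
  for (i in seq_len(nrow(sp) - 1)) {
    if (d[i] == 0) next
    if (sign(d[i]) != sign(d[i + 1]) && d[i + 1] != 0) {
      lw <- log(sp$omega[i]) + (0 - d[i]) / (d[i + 1] - d[i]) *
        (log(sp$omega[i + 1]) - log(sp$omega[i]))
      out <- rbind(out, data.frame(
        omega = exp(lw),
        below = if (d[i] > 0) "elastic" else "viscous",
        above = if (d[i + 1] > 0) "elastic" else "viscous",
        tangent = FALSE))
    } else if (d[i + 1] == 0 && i + 1 < nrow(sp) &&
               sign(d[i]) == sign(d[i + 2])) {
      out <- rbind(out, data.frame(
        omega = sp$omega[i + 1],
        below = if (d[i] > 0) "elastic" else "viscous",
        above = if (d[i] > 0) "elastic" else "viscous",
        tangent = TRUE))
    }
  }
  out
}

#' Log-log slope of G' over the lowest frequency decade
#'
#' @param spectrum a [modulus_spectrum()]
#' @param decades width of the low-frequency window in decades
#' @param component `"Gp"` or `"Gpp"`
#' @return fitted slope
#' @export
terminal_slope <- function(spectrum, decades = 1, component = c("Gp", "Gpp")) {
  component <- match.arg(component)
  sp <- spectrum[spectrum[[component]] > 0, ]
  wmin <- min(sp$omega)
  win <- sp$omega <= wmin * 10^decades
  if (sum(win) < 3) stop("fewer than 3 points in the terminal window")
  unname(coef(lm(log10(sp[[component]][win]) ~ log10(sp$omega[win])))[2])
}

#' Classify the low-frequency viscoelastic response
#'
#' Maxwell fluid: terminal G' ~ w^2 with G'' > G' at the lowest
#' frequencies but an elastic (G' > G'') window somewhere. Kelvin-Voigt
#' solid: G' plateaus (slope ~ 0) and dominates at low frequency. Viscous
#' fluid: G'' > G' everywhere with no elastic window.
#'
#' @param spectrum a [modulus_spectrum()] covering at least one decade at
#'   the low end
#' @return object of class `response_class`: list with `classification`
#'   (one of `"maxwell_fluid"`, `"kelvin_voigt_solid"`, `"viscous_fluid"`,
#'   `"indeterminate"`), `terminal_slope_Gp`, `elastic_window`
#' @export
classify_response <- function(spectrum) {
  sp <- spectrum[spectrum$Gp > 0 & spectrum$Gpp > 0, ]
  if (nrow(sp) < 4 || max(sp$omega) / min(sp$omega) < 10)
    return(structure(list(classification = "indeterminate",
                          terminal_slope_Gp = NA_real_,
                          elastic_window = NA),
                     class = "response_class"))
  sl <- terminal_slope(sp, decades = 1, component = "Gp")
  low <- sp[which.min(sp$omega), ]
  elastic_anywhere <- any(sp$Gp > sp$Gpp)
  cls <- if (low$Gp > low$Gpp && sl < 0.5) "kelvin_voigt_solid"
  else if (elastic_anywhere) "maxwell_fluid"
  else "viscous_fluid"
  structure(list(classification = cls, terminal_slope_Gp = sl,
                 elastic_window = elastic_anywhere),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("<response_class> %s (terminal G' slope %.2f, elastic window: %s)\n",
              x$classification, x$terminal_slope_Gp,
              ifelse(isTRUE(x$elastic_window), "yes", "no")))
  invisible(x)
}
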