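# Structural and dynamical chain metrics: persistence length (tangent and
# equilibrium-angle estimators), radius of gyration, mean-squared
# displacement with subdiffusion exponent, and density profiles.

chain_groups <- function(chain) {
  g <- split(seq_along(chain), chain)
  g[names(g) != "0"]
}

#' Persistence length from tangent-tangent correlations
#'
#' Computes <t(s) . t(s + ds)> along the contour, averaged over chains and
#' frames, and fits the initial decay to exp(-ds b / lp) (b = mean bond
#' length). The fit window runs to the first decay below 1/e^2. A
#' correlation that never decays below 1/e over the available contour is a
#' rigid rod at this chain length: the result then carries attribute
#' `"lower_bound" = TRUE`.
#'
#' @param frames list of unwrapped N x 3 coordinate frames (or one matrix)
#' @param chain integer chain id per bead; chains need >= 10 bonds
#' @return persistence length in sigma; attributes `"bond_length"` and the
#'   correlation curve `"correlation"`
#' @export
persistence_length_tangent <- function(frames, chain) {
  if (is.matrix(frames)) frames <- list(frames)
  groups <- chain_groups(chain)
  nb_min <- min(lengths(groups)) - 1
  if (nb_min < 10) stop("chains need at least 10 bonds")
  max_ds <- nb_min - 1
  num <- rep(0, max_ds + 1); den <- rep(0, max_ds + 1)
  blen <- 0; nbl <- 0
  for (fr in frames) {
    for (idx in groups) {
      bv <- diff(fr[idx, , drop = FALSE])
      bn <- sqrt(rowSums(bv^2))
      blen <- blen + sum(bn); nbl <- nbl + length(bn)
      t_hat <- bv / bn
      nb <- nrow(t_hat)
      for (ds in 0:min(max_ds, nb - 1)) {
        dots <- rowSums(t_hat[1:(nb - ds), , drop = FALSE] *
                        t_hat[(1 + ds):nb, , drop = FALSE])
        num[ds + 1] <- num[ds + 1] + sum(dots)
        den[ds + 1] <- den[ds + 1] + length(dots)
      }
    }
  }
  corr <- num / den
  b <- blen / nbl
  below <- which(corr < exp(-2))
  lower_bound <- FALSE
  if (!length(below)) {
    if (min(corr, na.rm = TRUE) > exp(-1)) lower_bound <- TRUE
    win <- seq_along(corr)
  } else win <- seq_len(below[1])
  win <- win[corr[win] > 0]
  ds <- (win - 1) * b
  # exponential decay through C(0) = 1: slope of log C vs contour distance,
  # weighted by C^2 (the log of a noisy correlation has error ~ 1/C)
  lp <- if (length(win) >= 2)
    -1 / unname(coef(lm(log(corr[win]) ~ 0 + ds,
                        weights = corr[win]^2))[1])
  else Inf
  if (lower_bound || !is.finite(lp) || lp <= 0) {
    lp <- max(ds)
    lower_bound <- TRUE
  }
  structure(lp, bond_length = b, lower_bound = lower_bound,
            correlation = data.frame(ds = (seq_along(corr) - 1) * b,
                                     corr = corr))
}

#' Persistence length from the equilibrium backbone angle
#'
#' Converts the mean interior backbone angle theta_i to the bond-deflection
#' angle theta_m = 180 - theta_i and returns lp = -1/ln(cos theta_m) in
#' bond-length units (natural log). The interior angle 111.6 degrees gives
#' lp close to one bond length - the fully flexible limit; as theta_i
#' approaches 180 degrees the chain straightens and lp diverges (returned
#' as a large finite value with attribute `"straight_limit"`).
#'
#' @param theta_interior mean interior angle in degrees, in (90, 180]
#' @return persistence length in bond-length units
#' @export
persistence_length_angle <- function(theta_interior) {
  stopifnot(length(theta_interior) == 1)
  if (theta_interior <= 90 || theta_interior > 180)
    stop("domain error: interior angle must lie in (90, 180] degrees ",
         "(deflection below 90)")
  theta_m <- (180 - theta_interior) * pi / 180
  cm <- cos(theta_m)
  if (cm >= 1 - 1e-12)
    return(structure(1e12, straight_limit = TRUE))
  -1 / log(cm)
}

#' Radius of gyration
#'
#' Rg^2 = mean squared distance of the beads from the chain centroid,
#' computed on unwrapped coordinates.
#'
#' @param pos unwrapped N x 3 coordinates of one frame
#' @param chain integer chain id per bead
#' @return named list: `per_chain` vector and `mean`; single-bead chains
#'   give Rg = 0 and set attribute `"flagged"`
#' @export
radius_of_gyration <- function(pos, chain) {
  groups <- chain_groups(chain)
  if (!length(groups)) stop("no chains present")
  rg <- vapply(groups, function(idx) {
    p <- pos[idx, , drop = FALSE]
    if (nrow(p) == 1) return(0)
    c0 <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, c0)^2)))
  }, numeric(1))
  out <- list(per_chain = rg, mean = mean(rg))
  if (any(lengths(groups) == 1)) attr(out, "flagged") <- "single-bead chain"
  out
}

#' Mean-squared displacement and subdiffusion exponent
#'
#' Monomer (or chain-centroid) MSD averaged over beads and multiple time
#' origins on a logarithmically spaced lag grid; the exponent alpha is the
#' log-log slope over the requested lag window. A dense melt shows the
#' subdiffusive intermediate regime <dr^2> ~ t^(1/2).
#'
#' @param frames list of unwrapped N x 3 frames at a uniform frame stride
#' @param times frame times (tau)
#' @param window lag window `c(tmin, tmax)` over which to fit alpha
#' @param chain chain ids; required for `mode = "chain"`
#' @param mode `"monomer"` (default) or `"chain"` (centroid MSD)
#' @param n_lags number of log-spaced lags
#' @param max_origins subsample time origins to at most this many
#' @return list with `msd` (data.frame `lag`, `msd`) and `alpha`
#' @export
msd_exponent <- function(frames, times, window = NULL, chain = NULL,
                         mode = c("monomer", "chain"), n_lags = 30,
                         max_origins = 50) {
  mode <- match.arg(mode)
  stopifnot(length(frames) == length(times), length(frames) >= 4)
  if (mode == "chain") {
    stopifnot(!is.null(chain))
    groups <- chain_groups(chain)
    frames <- lapply(frames, function(fr)
      t(vapply(groups, function(idx) colMeans(fr[idx, , drop = FALSE]),
               numeric(3))))
  }
  nf <- length(frames)
  dtf <- times[2] - times[1]
  lag_idx <- unique(round(10^seq(0, log10(nf - 1), length.out = n_lags)))
  msd <- vapply(lag_idx, function(k) {
    origins <- seq(1, nf - k)
    if (length(origins) > max_origins)
      origins <- unique(round(seq(1, nf - k, length.out = max_origins)))
    mean(vapply(origins, function(o)
      mean(rowSums((frames[[o + k]] - frames[[o]])^2)), numeric(1)))
  }, numeric(1))
  curve <- data.frame(lag = lag_idx * dtf, msd = msd)
  if (is.null(window)) window <- range(curve$lag)
  win <- curve$lag >= window[1] & curve$lag <= window[2] & curve$msd > 0
  if (sum(win) < 3) stop("MSD window outside the available lag range")
  alpha <- unname(coef(lm(log10(curve$msd[win]) ~ log10(curve$lag[win])))[2])
  list(msd = curve, alpha = alpha)
}

#' Number-density profile along an axis
#'
#' Counts per bin divided by bin volume, optionally restricted to one
#' species (e.g. the polymer density rho_poly or solvent density rho_sol).
#'
#' @param pos wrapped N x 3 coordinates
#' @param box a [simulation_box()]
#' @param axis 1 (x), 2 (y) or 3 (z)
#' @param n_bins number of bins (>= 4)
#' @param type per-bead types; needed when `species` is given
#' @param species type id(s) to include (NULL = all beads)
#' @param range profile range along the axis; defaults to the wall extent
#'   (walled axis) or `[0, L]`
#' @return data.frame `x` (bin centers), `rho`; attribute `"flagged"` when
#'   the selection is empty
#' @export
density_profile <- function(pos, box, axis = 1, n_bins = 40, type = NULL,
                            species = NULL, range = NULL) {
  stopifnot(n_bins >= 4)
  if (is.null(range)) {
    range <- if (axis == 1 && !is.null(box$xwalls)) box$xwalls
    else c(0, box$L[axis])
  }
  sel <- rep(TRUE, nrow(pos))
  if (!is.null(species)) {
    stopifnot(!is.null(type))
    sel <- type %in% species
  }
  x <- pos[sel, axis]
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  bin_vol <- diff(edges) * prod(box$L[-axis])
  out <- data.frame(x = (head(edges, -1) + tail(edges, -1)) / 2,
                    rho = counts / bin_vol)
  if (!any(sel)) attr(out, "flagged") <- "empty selection"
  out
}
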