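# Residue-level coarse-grained chains (one bead per residue) with
# hydropathy-scaled pair interactions and explicit weak-attraction solvent.
# The residue parameter table is user-supplied; everything is reduced to
# engine units through one declared (length, energy, mass) scale so the
# same integrator drives both model families.

#' Read a protein sequence from a FASTA file
#'
#' Returns the first record's sequence as an upper-case character string;
#' a multi-record file is accepted with a warning.
#'
#' @param path FASTA file
#' @param alphabet optional vector of allowed residue codes (e.g. the
#'   parameter table's codes); an unknown residue errors, naming the code
#'   and position
#' @return single character string
#' @export
read_sequence <- function(path, alphabet = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    recs <- Biostrings::readAAStringSet(path)
    if (length(recs) == 0) stop("FASTA file holds no records")
    if (length(recs) > 1)
      warning("multi-record FASTA: using the first record")
    seqstr <- toupper(as.character(recs[[1]]))
  } else {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    if (!length(heads)) stop("FASTA file holds no records")
    if (length(heads) > 1)
      warning("multi-record FASTA: using the first record")
    end <- if (length(heads) > 1) heads[2] - 1 else length(lines)
    seqstr <- toupper(gsub("\\s", "", paste(lines[(heads[1] + 1):end],
                                            collapse = "")))
  }
  if (!nzchar(seqstr)) stop("first FASTA record has an empty sequence")
  if (!is.null(alphabet)) {
    codes <- strsplit(seqstr, "")[[1]]
    bad <- which(!codes %in% alphabet)
    if (length(bad))
      stop(sprintf("unknown residue code '%s' at position %d",
                   codes[bad[1]], bad[1]))
  }
  seqstr
}

#' Load a per-residue parameter table
#'
#' CSV columns: `code` (single letter), `lambda` (hydropathy weight in
#' [0, 1.2]), `sigma` (residue diameter, same length unit throughout the
#' table), `mass`. Values are converted to reduced engine units by
#' dividing lengths by `length_scale` (default: the table's mean sigma)
#' and masses by `mass_scale` (default: the mean mass).
#'
#' @param path CSV file (or a data.frame with the same columns)
#' @param length_scale,mass_scale declared reduction scales
#' @return data.frame of class `residue_params` with reduced `sigma_red`,
#'   `mass_red` columns; attributes record the scales
#' @export
load_residue_params <- function(path, length_scale = NULL, mass_scale = NULL) {
  tab <- if (is.data.frame(path)) path else read.csv(path,
                                                     stringsAsFactors = FALSE)
  need <- c("code", "lambda", "sigma", "mass")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop("format error: duplicate residue code(s) ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "))
  stopifnot(all(tab$lambda >= 0), all(tab$lambda <= 1.2),
            all(tab$sigma > 0), all(tab$mass > 0))
  if (is.null(length_scale)) length_scale <- mean(tab$sigma)
  if (is.null(mass_scale)) mass_scale <- mean(tab$mass)
  tab$sigma_red <- tab$sigma / length_scale
  tab$mass_red <- tab$mass / mass_scale
  structure(tab, length_scale = length_scale, mass_scale = mass_scale,
            class = c("residue_params", "data.frame"))
}

#' Residue-level system specification
#'
#' @param sequence residue string (e.g. from [read_sequence()])
#' @param n_chains number of chains
#' @param solvent_fraction solvent volume fraction phi_s in [0, 1)
#' @param solvent_attraction depth (eps units) of the weak solvent-residue
#'   LJ attraction that keeps the mixture colocalized; 0 is accepted but
#'   flagged, since purely repulsive solvent demixes from the protein
#' @param angle optional `list(k =, theta0 =)` backbone angle model
#'   (theta0 in degrees); rigidity raises the persistence length and opens
#'   an elastic-dominated frequency window
#' @param eps_hps residue-residue interaction scale (reduced units)
#' @param target_density total bead density for the builder
#' @param seed integer seed
#' @return object of class `hps_system_spec`
#' @export
hps_system_spec <- function(sequence, n_chains = 1, solvent_fraction = 0,
                            solvent_attraction = 0.2, angle = NULL,
                            eps_hps = 1, target_density = 0.7, seed = 1) {
  stopifnot(nzchar(sequence), n_chains >= 1,
            solvent_fraction >= 0, solvent_fraction < 1,
            solvent_attraction >= 0, eps_hps > 0)
  structure(list(sequence = toupper(sequence), n_chains = as.integer(n_chains),
                 solvent_fraction = solvent_fraction,
                 solvent_attraction = solvent_attraction, angle = angle,
                 eps_hps = eps_hps, target_density = target_density,
                 seed = as.integer(seed)),
            class = "hps_system_spec")
}

#' Build a residue-level condensate with explicit solvent
#'
#' One bead per residue, harmonic backbone bonds, optional backbone angle
#' terms, hydropathy-scaled (Ashbaugh-Hatch) residue-residue pair
#' interactions with lambda_ij the arithmetic mean of the residues'
#' lambdas, and free solvent beads with a weak plain-LJ attraction to every
#' residue. Returns the system, topology and the matching forcefield.
#'
#' @param spec an [hps_system_spec()]
#' @param params a [load_residue_params()] table covering the sequence's
#'   alphabet
#' @param bond_r0 backbone bond length in reduced units (default 0.8 of
#'   the mean residue diameter)
#' @param bond_k harmonic bond stiffness (reduced units)
#' @return list with `system`, `topology`, `ff`; when
#'   `solvent_attraction = 0` the result carries attribute
#'   `"demixing_expected"`
#' @export
build_hps_condensate <- function(spec, params, bond_r0 = 0.8, bond_k = 75) {
  stopifnot(inherits(spec, "hps_system_spec"),
            inherits(params, "residue_params"))
  codes <- strsplit(spec$sequence, "")[[1]]
  bad <- which(!codes %in% params$code)
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d",
                 codes[bad[1]], bad[1]))
  np <- length(codes)
  res_codes <- sort(unique(codes))
  n_rtypes <- length(res_codes)
  type_of <- match(codes, res_codes)
  solvent_type <- n_rtypes + 1L
  prm <- params[match(res_codes, params$code), ]

  n_res <- spec$n_chains * np
  phi_s <- spec$solvent_fraction
  n_solv <- if (phi_s > 0) round(phi_s / (1 - phi_s) * n_res) else 0L
  n <- n_res + n_solv
  L <- (n / spec$target_density)^(1 / 3)
  box <- simulation_box(L)

  # pair matrices over residue types + solvent
  nt <- solvent_type
  sig <- matrix(1, nt, nt); epsm <- matrix(0, nt, nt)
  rcm <- matrix(2^(1/6), nt, nt); lam <- matrix(NA_real_, nt, nt)
  for (i in seq_len(n_rtypes)) for (j in seq_len(n_rtypes)) {
    sij <- (prm$sigma_red[i] + prm$sigma_red[j]) / 2
    sig[i, j] <- sij
    epsm[i, j] <- spec$eps_hps
    rcm[i, j] <- 4 * sij
    lam[i, j] <- (prm$lambda[i] + prm$lambda[j]) / 2
  }
  # solvent: weak plain-LJ attraction to residues, WCA to itself
  for (i in seq_len(n_rtypes)) {
    sij <- (prm$sigma_red[i] + 1) / 2
    sig[i, nt] <- sig[nt, i] <- sij
    epsm[i, nt] <- epsm[nt, i] <- max(spec$solvent_attraction, 1e-12)
    rcm[i, nt] <- rcm[nt, i] <- if (spec$solvent_attraction > 0) 2.5 * sij
    else 2^(1/6) * sij
  }
  sig[nt, nt] <- 1; epsm[nt, nt] <- 1; rcm[nt, nt] <- 2^(1/6)
  ff <- forcefield(nt, eps = epsm, sigma = sig, rc = rcm, lambda = lam)

  # topology: harmonic backbone bonds, optional angles
  bonds <- NULL; angles <- NULL
  types <- integer(0)
  for (c in seq_len(spec$n_chains)) {
    off <- (c - 1) * np
    if (np >= 2) bonds <- rbind(bonds, cbind(off + 1:(np - 1), off + 2:np))
    if (!is.null(spec$angle) && np >= 3)
      angles <- rbind(angles, cbind(off + 1:(np - 2), off + 2:(np - 1),
                                    off + 3:np))
    types <- c(types, type_of)
  }
  types <- c(types, rep(solvent_type, n_solv))
  nb <- if (is.null(bonds)) 0 else nrow(bonds)
  na <- if (is.null(angles)) 0 else nrow(angles)
  topo <- cg_topology(
    n_atoms = n, bonds = bonds, bond_type = rep(2L, nb),
    bond_k = rep(bond_k, nb), bond_r0 = rep(bond_r0, nb),
    angles = angles,
    angle_k = rep(if (is.null(spec$angle)) 0 else spec$angle$k, na),
    angle_theta0 = rep(if (is.null(spec$angle)) pi
                       else spec$angle$theta0 * pi / 180, na),
    types = types)

  with_seed(spec$seed, {
    pos <- NULL
    for (c in seq_len(spec$n_chains)) {
      start <- runif(3, 0, L)
      pos <- rbind(pos, grow_chain(np, bond_r0, start, angle = spec$angle))
    }
    if (n_solv > 0)
      pos <- rbind(pos, matrix(runif(3 * n_solv, 0, L), n_solv, 3))
    sys <- particle_system(pos, type = types,
                           chain = c(rep(seq_len(spec$n_chains), each = np),
                                     rep(0L, n_solv)),
                           box = box)
    sys <- init_velocities(sys, temp = 1)
    # bonded residues sit at bond_r0 < sigma, so the packing target is set
    # below the backbone bond length rather than the LJ-unit default
    sys <- relax_pushoff(sys, topo, ff, min_dist = 0.7 * bond_r0)
  })
  out <- list(system = sys, topology = topo, ff = ff)
  if (spec$solvent_attraction == 0 && n_solv > 0)
    attr(out, "demixing_expected") <-
      "purely repulsive solvent phase-separates from the protein"
  out
}
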