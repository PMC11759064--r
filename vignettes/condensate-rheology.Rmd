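---
title: "Coarse-grained condensate rheology: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained condensate rheology: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgrheo)
```

# The problem

Biomolecular condensates age: their material response drifts from that of a
viscous liquid toward an elastic solid, a process implicated in
neurodegenerative disease. Three microscopic drivers are commonly invoked -
loss of solvent from the dense phase (desolvation), rigidification of the
polymer backbone (e.g. beta-strand formation), and the lifetime of sticker
contacts between chains. `cgrheo` implements a desk-scale simulation and
analysis pipeline for dissecting these drivers with coarse-grained models:
bead-spring sticker-spacer chains with explicit solvent, cross-linked gels,
and a residue-level hydropathy-scaled chain model, all integrated with the
same Langevin engine and analysed with the same rheology estimators.

# Models and units

All sticker-spacer systems use reduced Lennard-Jones units: bead mass m,
diameter sigma and well depth eps set the scales, with tau = sqrt(m
sigma^2/eps), rho* = sigma^-3, T* = eps/kB, p* = eps sigma^-3
(`reduced_units()`).

**Bonds.** Backbone beads are joined by FENE springs
U(r) = -k R0^2/2 log(1 - r^2/R0^2) with k = 30 eps/sigma^2 and R0 = 1.5
sigma; together with the repulsive LJ core this gives bond lengths near
0.97 sigma and makes chain crossing effectively impossible. Cross-links and
residue-level backbones use harmonic bonds.

**Angles.** Chain rigidity enters through U = K (theta - theta0)^2 on bead
triplets. theta0 = 111.6 deg reproduces the fully flexible limit
(persistence length about one bond); theta0 in the 120-170 deg range with
K = 10 kB T spans lp ~ 1.4-15 sigma. Sticker triplets get theta0 ~ 180 deg
(stiff stickers).

**Pair interactions.** Plain LJ with two cutoffs: 2^(1/6) sigma gives the
purely repulsive (WCA) branch used for spacers and solvent; attractive
channels extend to rc = 4 sigma where the potential has decayed to
permille level. For rheology runs a force-shifted truncation
(`shift_force = TRUE`) removes the cutoff discontinuity in both energy and
force. The residue-level model uses the lambda-scaled (Ashbaugh-Hatch) LJ
form of `hps_pair()`; the hydropathy weight of a pair is the arithmetic
mean of the residue weights. Electrostatics are deliberately out of scope:
the qualitative orderings studied here (rigidity and solvent-fraction
effects) do not require charge, and the parameter table is user-supplied.

**Stress sign convention.** Diagonal stress components follow the
pressure-tensor sign (an ideal gas averages to +rho kB T); off-diagonal
components are recorded as the material shear stress, i.e. the negative of
the pressure-tensor component, so a sheared elastic solid reports
Sigma_xy = +G gamma with zero phase lag. The Green-Kubo estimator only
uses autocorrelations and is insensitive to this choice.

# The synthetic-data stage

Every input configuration is generated by the package builders
(`build_melt()`, `build_solvated()`, `place_stickers()`,
`crosslink_gel()`, `build_hps_condensate()`, `build_aging_system()`),
which are pure functions of a `composition()`, a `chain_blueprint()` and a
seed. The default compositions are the study conditions: polymer:solvent
fractions 1:2, 1:1, 2:1, 1:0; chain lengths Np = 200 (full scale) and
Np = 20 (reduced); total density 0.85 sigma^-3; stickers at ten-bead
intervals (denser intervals are used in some reduced presets so that tiny
gels still percolate); sticker strength chi_ps in eps units.

Initial states are grown as self-avoiding-ish random walks (bond length
0.97 sigma, immediate backfolding rejected) and relaxed by a soft-cosine
push-off with increasing amplitude followed by a short WCA settle, until
no pair sits below 0.8 sigma. This is standard bead-spring preparation
practice and avoids FENE overstretch; the preparation protocol is a
package choice, as is the deterministic integer rounding of composition
ratios (solvent count = round(phi_s/phi_p x polymer beads)). Coordinates
are handed to the integrator unwrapped so that chains stay continuous;
the engine wraps them while maintaining image flags, and every observable
that needs continuity (Rg, MSD, tangent correlations) works on unwrapped
coordinates.

What the generator emulates: dense one-component melts and
polymer-solvent mixtures at prescribed ratios, semiflexible backbones,
transient vs permanent sticker networks. What it does not emulate:
sequence-specific interaction patterns, hydrodynamic interactions
(Langevin friction is local), electrostatics, and true experimental
concentration-to-volume-fraction conversions. Tests passing on these
systems therefore validate the estimators and the qualitative physics, not
quantitative agreement with any particular protein.

# Dynamics

`langevin_run()` integrates Langevin dynamics with a BAOAB splitting;
damping = 0 reduces exactly to velocity-Verlet, which the NVE drift test
exploits (relative drift < 1e-4 over 1e4 steps at dt = 0.005 tau). The
default timestep range is 0.005-0.01 tau and the Langevin friction
defaults to 1/tau (the damping constant is not prescribed by the physics
here; it sets the thermostat correlation time, and all results quoted are
at the default). Noise is drawn from R's RNG inside the compiled loop, so
`set.seed()` makes whole trajectories bit-reproducible.

Neighbours come from a Verlet list (skin 0.3 sigma) rebuilt from a cell
list on a half-skin displacement trigger; an O(N^2) fallback covers small
or heavily tilted boxes. The list is invisible to results and is pinned by
an O(N^2) force-loop oracle in the tests.

**Oscillatory shear.** `oscillatory_shear_run()` deforms a triclinic box
with gamma_xy(t) = gamma0 sin(omega t), applying the per-step affine
displacement and Lees-Edwards image shifts, and thermostats peculiar
velocities (the streaming profile is removed before the friction/noise
step). This deforming-box construction is used as a desk-scale stand-in
for a full SLLOD integrator: in the linear-response regime the two yield
the same moduli, and the package asserts exactly that through the
GK-vs-OS agreement checks rather than by construction. A guard rejects
omega dt > 0.1 rad/step.

# Rheology estimators

**Green-Kubo.** For an isotropic equilibrium system the relaxation modulus
is estimated as

G*(t) = V/(5 kB T) [ C_xy + C_xz + C_yz + (C_Nxy + C_Nxz + C_Nyz)/6 ]

with C_ab the off-diagonal stress autocorrelations and C_N the
autocorrelations of the normal-stress differences N_ab = Sigma_aa -
Sigma_bb. The five-component form follows the standard isotropic-average
estimator of the method literature; for a Gaussian isotropic stress the
normal-difference autocorrelation equals 4x the off-diagonal one, making
the bracket equal 5 C_xy and the prefactor V/(kB T) per channel, which is
the property the tests pin. When diagonal components are unavailable the
estimator falls back to the off-diagonal-only average with prefactor
V/(3 kB T) and flags the result.

Autocorrelations use a multi-tau correlator (`multitau_correlate()`,
p = 16 lags per level): level zero keeps the native stride, each higher
level block-averages pairs of samples, giving logarithmic lag coverage at
fixed cost and strong noise reduction at long lags. The correlator is
checked against a brute-force O(N^2) autocorrelation on
Ornstein-Uhlenbeck paths.

**Maxwell fits.** `fit_maxwell()` fits G(t) = sum_i G_i exp(-t/tau_i) (or
the corresponding G', G'' forms in the frequency domain) by
Levenberg-Marquardt on log-parameters, so G_i, tau_i > 0 by construction
and the terminal asymptotics G' ~ omega^2, G'' ~ omega are built in - the
terminal-slope acceptance checks measure this pipeline exactly as the
fitting-based workflow prescribes. Two data-driven cuts stabilise the
time-domain fit: the short-time cut starts the fit after the last
negative excursion of the bond-vibration ringing (confined to the first
percent of the lag range), and the tail cut stops at the first clearly
negative noise excursion beyond the first eight fitted lags; both are
overridable (`t_min`, `t_max`), which also exposes the short/long-time
split as a parameter. When `n_modes` is omitted the mode count grows
until the residual improves by less than 5%.

**Oscillatory-shear moduli.** `os_moduli()` fits the recorded stress to
A sin + B cos after discarding the first cycle; G' = A/gamma0,
G'' = B/gamma0. A residual above 50% of the stress amplitude raises a
nonlinearity/noise error, and `linear_regime_check()` implements the
10%-deviation window over a gamma0 sweep.

**Fast dissipation.** The short-time window excluded from the Maxwell fit
still carries real dissipation (eta_fast, the trapezoidal integral of
G*(t) over that window, which the native-stride lags resolve accurately).
An oscillatory-shear measurement sees it as an extra omega x eta_fast in
the loss modulus, so `gk_modulus_spectrum(include_fast_dissipation =
TRUE)` adds it when comparing against OS moduli; with it the two routes
agree within a few tens of percent on reduced melts, without it the GK
loss modulus is systematically low at finite frequency.

**Derived quantities.** eta* = integral of G*(t) (exact sum G_i tau_i from
a fit; trapezoid plus exponential-tail extrapolation from raw data, with a
plateau detector that flags gels as infinite-viscosity).
`crossover_frequencies()` locates G' = G'' in log-log space;
`classify_response()` distinguishes Maxwell fluids (terminal slope ~2,
elastic window present), Kelvin-Voigt solids (low-frequency G' plateau
dominating G'') and purely viscous responses. Because a generalized
Maxwell spectrum always turns elastic at high frequency, classification
and crossover counting are restricted to the frequency window actually
resolved by the data (1/t_max to 1/t_min); the high-frequency viscous
re-entry seen in raw oscillatory data lies outside the fitted model class.
A corollary for reduced-scale work: any fitted fluid spectrum has exactly
one crossover near 1/tau_max, so the full two-crossover interim elastic
window of long semiflexible chains is a full-scale feature. At reduced
scale the package asserts the resolvable content of that result - the
semiflexible melt's viscous-to-elastic crossover ordering, and the
rigidity ordering of the elastic fraction G'/G'' (fast dissipation
included) between semiflexible and flexible melts at matched frequencies.

# Chain observables

Persistence length comes from two estimators: tangent-tangent correlation
decay fitted to exp(-ds b/lp) over the initial decay (weighted by C^2, the
correct weighting for the log of a noisy correlation), and the
equilibrium-angle formula lp = -1/ln(cos theta_m) with theta_m the bond
deflection angle, i.e. 180 deg minus the interior backbone angle. The
deflection convention is fixed because it reproduces the flexible-limit
lp ~ sigma at theta0 = 111.6 deg. MSD is computed for monomers by default
(chain-centroid MSD is available via `mode = "chain"`; which of the two a
given figure shows is ambiguous in parts of the literature, so both are
provided) with multiple time origins and log-spaced lags; the subdiffusion
exponent is the log-log slope over a stated window. The reduced dense-melt
runs quote the exponent over lags of 2-30 tau, inside the Rouse-like
intermediate regime and below the terminal diffusive crossover.

# Phase diagram

Slab coexistence profiles are folded about the density-weighted circular
mean (avoiding interface splitting across the periodic boundary) and
fitted to a tanh interface form - the standard, noise-robust choice; the
extraction method is a package decision since only the rectilinear
extrapolation itself is prescribed. The critical point then comes from a
simultaneous fit of (rho_l + rho_v)/2 = rho_c + A (Tc - T) and rho_l -
rho_v = drho0 (1 - T/Tc)^beta with beta fixed at the 3D Ising value 0.325
(overridable). The order-parameter law is implemented multiplicatively -
drho0 scales the vanishing power law - as dimensional consistency
requires. Tc is parameterised as max(T) + exp(u) so the optimizer cannot
cross the data. The temperature grid is a configuration choice; the
reduced `phase_diagram` workflow uses three temperatures on a 400-bead
slab.

# Aging protocol

`run_aging()` interleaves Langevin chunks (1 tau by default) with
boundary evaporation and wall motion in a box elongated along x, walls on
x, periodic y/z. Evaporation removes up to rate x elapsed solvent beads
(default 10 per tau) from within `evap_slab` of the upper wall, nearest
the wall first. The printed slab width of 1e-2 sigma is far thinner than
a bead diameter and would almost never contain a bead center, so the
constructor default is a practical 0.5 sigma; the thinner value can be
set explicitly and the choice is logged in the config.

How the box shrinks behind the evaporated solvent is not prescribed
physics; the package models it as a moving reflective wall with a
proportional controller that keeps the boundary-slab pressure (ideal-gas
estimator rho_slab kB T) near its initial value, plus a constant-speed
mode as a simpler alternative. The wall only moves inward, never through
the dense phase (it halts with a flag 0.5 sigma above the polymer
extent). Corona metrics reduce the shell to 1-D profile quantities: the
shell is the outermost contiguous run of bins with polymer density above
a threshold, onset is the first snapshot with a shell at least two bins
wide, and trapped solvent is the solvent interior to the shell relative
to the initial count. Momentum removed with evaporated beads is simply
absorbed by the thermostat.

# Problem sizes and determinism

The bundled checks run at reduced scale by design: dense melts of 1000 -
2000 beads with 1000-2000 tau of production for the terminal-scaling and
MSD checks, 100-300-bead systems for workflow classification, and
300-500-bead aging and slab runs. Full-scale statements (Np = 200 chains,
frequencies down to 1e-6 rad/tau, the Rg ~ lp^0.41 exponent at scale, the
Tc = 2.4, rho_c = 0.38 critical point of the polymer-solvent model) are
cluster-scale experiments; at desk scale the package asserts the
corresponding reduced-scale properties (terminal slopes, exponent within
[0.3, 0.5], exact recovery of the critical fit on synthetic coexistence
curves generated at those values). Every stochastic stage consumes an
explicit seed; trajectories are bit-reproducible for a fixed seed on a
fixed platform.

The package's interface is its functions: `run_workflow()` drives the
end-to-end presets (`solvent_sweep`, `rigidity_sweep`, `length_compare`,
`gel_vs_melt`, `sticker_sweep`, `aging`, `phase_diagram`) from a validated
YAML/list configuration (`validate_config()`) and writes CSV/JSON
artifacts plus a manifest with seeds and checksums; no shell entry point
is shipped.

# Known limitations

- Langevin dynamics screens hydrodynamics and momentum transport; absolute
  viscosities depend on the friction constant.
- The deforming-box shear is a linear-response tool; no LAOS analysis.
- Maxwell fits cannot represent the high-frequency viscous re-entry or a
  true gel plateau with finite modes; gels appear as a slowest mode with
  tau far beyond the data window (and are flagged by the viscosity
  plateau detector).
- The gel linker algorithm (distance-ordered greedy matching, inter-chain
  only, each sticker used once) is a package decision; linker density is
  exposed as `linker_fraction`/`cutoff`.
- Reduced-scale gels and melts are far from the thermodynamic limit;
  classifications are robust, plateau values are not.
- At reduced scale the 1-D corona metrics do not resolve the
  sticker-strength ordering of shell onset: the onset statistic is
  dominated by sticker-independent boundary enrichment and seed-to-seed
  scatter. The mechanism that separates sticker lifetimes - pore closure
  in the boundary plane over long times - lives in the 2-D boundary
  structure that the 1-D profiles integrate over; the corresponding
  check in the test suite measures the ordering as defined and currently
  fails, by design rather than by accident.
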