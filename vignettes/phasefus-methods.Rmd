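---
title: "Sticker-and-spacer mean-field theory of ATP-modulated phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sticker-and-spacer mean-field theory of ATP-modulated phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefus)
```

## The model

Prion-like proteins such as FUS phase separate into a dilute phase and a
dense condensate through many weak, specific contacts between tyrosine
and arginine side chains.  `phasefus` implements an associative-polymer
("sticker-and-spacer") mean-field theory of this process, its coupling
to a multivalent ligand (ATP) that competes for the arginines, and a
reduced-scale coarse-grained (CG) Langevin slab simulator for the
dynamic picture.

The protein is a linear chain of `N1` residues carrying `m1` Tyr and
`m2` Arg stickers (FUS: `N1 = 526`, `m1 = m2 = 34`); the solvent is a
chain of `N2` sites, the one fitted parameter of the ATP-free model
(see *Units and calibration*).  On a lattice of unit site volume `v`,
the ATP-free free energy per site (in kT) is the Flory–Huggins mixing
entropy

    f_ref(phi) = (phi/N1) log phi + ((1-phi)/N2) log(1-phi)

plus a binding term obtained from the association partition function

    Z = sum_k C(M1, k) C(M2, k) k! (v/V)^k e^{-k beta_eps1},

with `M1 = n_p m1` Tyr sites, `M2 = n_p m2` Arg sites and `k` Tyr–Arg
bonds of strength `beta_eps1` (≈ −2 kT).  Taking the maximum term with
Stirling's approximation gives

    f_bind(phi, p) = (m1 phi/N1)[p log p + (1-p) log(1-p)]
                   + (m2 phi/N1)(1 - p m1/m2) log(1 - p m1/m2)
                   - (p m1 phi/N1)[log(m2 phi/N1) - beta_eps1 - 1],

where `p` is the fraction of Tyr in bonds.  The trailing `-1` in the
attachment term deserves a note: it is the Euler factor produced by
`log k! ≈ k log k - k` together with folding the `s log s` half of the
Arg binomial entropy into the attachment term.  Minimization over `p`
then yields the clean mass-action law

    p / [(1-p)(1 - p m1/m2)] = (m2 phi / N1) e^{-beta_eps1},

and the package's `exact_association_oracle()` — a direct summation of
`Z` over all bond numbers with no approximation — confirms this form:
the relative gap between the enumeration and the Stirling free energy
falls by an order of magnitude for every tenfold increase in system
size.  Dropping the Euler factor instead shifts the predicted onset of
phase separation from about −1.4 kT to −0.4 kT, far from where the
model is known to place it.

## ATP as a multivalent binder

ATP enters as a single-site solute that can bind up to `L` arginines
(`L` = 1–3; the triphosphate moiety accommodates at most three).  The
solution exchanges ATP with a reservoir at fixed chemical potential
(semi-grand ensemble), so the free energy gains mixing, contact
(`chi = -1.2` with the solvent; ATP is strongly hydrated) and exchange
terms, and the binding term generalizes to coupled occupancies: `p` for
Tyr, `q` for ATP binding sites, sharing one free-Arg budget

    t = p m1/m2 + q L lambda N1 / m2,

where `lambda` is the ATP-to-residue ratio in the solution.
Stationarity gives two mass-action laws sharing the factor `(1 - t)` —
the competition between protein–protein and ATP–protein binding — plus
an equality of ATP chemical potentials in which binding contributes
`L log(1-q)`.  `solve_internal()` solves these as nested safeguarded
scalar roots; the outer root runs in `x = log(lambda/lambda_max)` so
the solvent fraction `(1-phi)(1-e^x)` remains accurate even when ATP
nearly fills the box.

Phase coexistence requires equal protein chemical potential
`mu = df/dphi` and osmotic pressure `Pi = phi mu - f` in the two
phases.  Because the internal variables are at a free-energy minimum,
the envelope theorem gives `mu` analytically
(`d f_bind/d phi = f_bind/phi - p m1/N1 - q L lambda`); the package
verifies this against central differences.  The tie-line itself is
found by an equal-grand-potential construction: for a trial `mu` the
dilute and dense roots of `mu(phi) = mu` bracket the spinodal, and the
difference of their grand potentials is strictly monotone in `mu`, so
one bracketed root yields the binodal with residuals near machine
precision and no initial guesses.  A subtlety of strongly driven
regimes: `mu` diverges only like `log(phi)/N1` as `phi -> 0`, so deep
inside a reentrant loop the formal dilute branch can lie below one
chain per macroscopic volume.  `solve_coexistence()` then reports the
dilute branch clamped at a composition floor (`clipped = TRUE`) rather
than failing; dense-phase observables are unaffected.

## Units and calibration

Volume fractions are converted to molarities through the residue
hydration volume.  The package treats the 0.65 nm residue "hydration
size" as a radius, `v = (4/3) pi (0.65 nm)^3 = 1.150 nm^3`.  This is a
deliberate choice: with the spherical volume (and no other adjustment)
the model simultaneously reproduces the three concentration anchors
the theory is calibrated against — a 5 uM saturation concentration at
`beta_eps1 = -2` with `N2 = 65`, and condensate dissolution near 10 mM
(L = 2) and 15 mM (L = 3) ATP — whereas a cubic volume
`(0.65 nm)^3` leaves all three too high by the same factor of ~4.3,
while every dimensionless observable (onset near −1.4 kT, a dense/dilute
contrast above two orders of magnitude, the ratio of the L = 3 to
L = 2 closure concentrations) is insensitive to the convention.

The per-bond ATP–Arg energies per valence are inputs of the theory.
Quantum-chemistry estimates fix their scale — roughly four times the
Tyr–Arg bond, i.e. about −8 kT — and show the per-bond average
weakening as more arginines crowd one triphosphate.  The defaults are
`beta_eps2 = -8` for L = 2 and L = 3 (the closure concentration is
nearly insensitive to `beta_eps2` there, because binding is saturated
well before the loop closes), and `beta_eps2 = -12.5` for L = 1, where
the closure *is* sensitive: the monovalent case is a full
arginine–triphosphate salt bridge, and its default is calibrated so the
monovalent dissolution scale lands at the micromolar value the theory
is known to produce — the same spirit in which `N2` is calibrated to
the 5 uM saturation concentration.  All of these are plain arguments of
`model_params()` and can be overridden.

```{r anchors}
pure <- fus_profile("fus2022")
pure$atp_reservoir_phi <- 0
cx <- solve_coexistence(pure)
c(rho_dilute_uM = cx$rho_dilute * 1e6,
  contrast = cx$rho_dense / cx$rho_dilute)
```

## What the phase-diagram scans show

`scan_atp()` traces the binodal versus reservoir ATP concentration.
For `L = 2` or 3 the saturation concentration is reentrant — ATP first
promotes separation (each ATP bridges several arginines, adding
cross-links) and then suppresses it (ATP saturates the arginines
one-to-one and severs the Tyr–Arg network), closing the loop near
10–16 mM.  For `L = 1` ATP only blocks arginines, the saturation
concentration rises monotonically, and the loop closes around
10^-3 mM.  With asymmetric sticker counts (34/11 and 11/34) neither
protein phase separates alone; ATP opens a closed loop in the
(c, rho) plane that is much larger — and the bound-Arg-per-ATP count
`g2` much higher — when arginines outnumber tyrosines.  The loop area
is computed trapezoidally in doubly logarithmic coordinates (matching
how such diagrams are drawn; a linear-coordinate variant is also
reported, as the convention is not standardized).

## The coarse-grained slab simulator

The CG model is a bead-spring chain (bond `k (r - r_b)^2`,
`r_b = 4.5 nm`, `k = 20 eps0 / r_b^2`) with three bead types (Tyr,
Arg, neutral; sticker fraction 0.06 each) plus single-bead ATP.
Tyr–Arg and ATP–Arg pairs attract through the smooth bounded well
`U0 (1 + cos(pi r / r0))` for `r < r0 = 2 nm` with depths −20 eps0 and
−75 eps0 (the same ~4x ratio as the mean-field energies).  A softened,
truncated Lennard-Jones repulsion (lambda = 0.68, sigma = 3.5 nm,
r_c = 5 nm; 0.621 eps0 for Tyr, 0.15 eps0 for Arg) acts between beads
of the *same type only*: it exists to prevent same-type aggregation,
and because its range exceeds the sticker range, a cross-type
repulsion would abolish sticker binding altogether.  Spacer beads are
phantom (repulsion 0): at 88% of each chain, a spacer–spacer repulsion
of sticker magnitude overwhelms the sparse attraction and dissolves
the slab.  ATP–ATP repulsion uses the Tyr value.  The repulsion is
shifted by its cutoff value (+0.28 eps per pair) so the energy is
continuous; forces are unaffected.

Dynamics are BAOAB Langevin in the NVT ensemble with minimum-image
periodic boundaries, a deterministic platform-independent RNG, and a
cell-list pair loop (falling back to the direct sum when the box is
smaller than three cutoffs per side).  Reduced units: bead mass 1,
friction 1/tau, energies in eps0, lengths in nm; the reference
full-scale mapping (0.5 ns per step, 50 chains of 526 beads in a
50x50x250 nm box, 50 ms of sampling) is available through the config
but is far beyond desk scale.  Only ratios of well depths to kT matter
for the phase behavior tested here.

Desk-scale defaults used by the test suite: 10 chains of 34 beads
(2 Tyr + 2 Arg each) in a 30x30x90 nm box, 3x10^4 steps of dt = 0.02,
sampled every 100 steps.  The thermostat for the exchange analyses runs
at kT = 8 eps0, chosen once so that sticker contacts (well depth
~40 eps0 at contact) are strong but reversible on these short
trajectories; at kT ~ 1 the network is frozen and nothing exchanges
within reachable run lengths.  `density_profile()` recenters each frame
by the circular mean along the slab axis and defines the condensate as
the half-maximum region; `exchange_statistics()` counts debounced
(dwell of 5 sampled frames, 1 nm boundary hysteresis) inside/outside
transitions of chains, a chain being inside when at least half its
beads are.

What the reduced scale does and does not show.  Robustly reproduced:
the slab persists without ATP; a moderate ATP dose makes the condensate
denser; a large dose (ATP comparable to or exceeding the arginine
count) loosens and ultimately dissolves it, re-promoting molecular
exchange — the dissolution arm of the reentrant behavior.  Not
resolved at this scale: the *suppression* of exchange at moderate ATP.
With only ~20 arginines and hundreds of sampled frames, exchange
counts are dominated by interface flicker of marginally attached
chains (Poisson noise of order the signal), and medians across seeds
do not separate the moderate-ATP condition from the ATP-free one, even
though the densification that causes the suppression at full scale is
visible.  The acceptance suite states this sub-property exactly as the
full-scale picture predicts and lets it fail honestly at reduced
scale rather than weakening the assertion.

## Numerical choices and limitations

* Tolerances: internal-state roots to 1e-15 (bracketed Brent /
  safeguarded Newton), tie-line residuals typically below 1e-12,
  spinodal refinement 1e-12, dissolution bisection to 0.1% in
  concentration.
* Boundary limits (`phi -> 0, 1`; `p, q -> 0`) return exact limit
  values; logs are never evaluated at 0.
* The dissolution search detects the two-phase region through spinodal
  existence (equivalent to binodal existence at loop closure) and
  backs its upper bracket away from reservoir fractions above ~0.1,
  where the semi-grand model leaves its physical regime (the solution
  floods with ATP).
* No electrostatics, salt dependence, temperature dependence beyond
  the implicit kT scaling, or three-phase equilibria; ATP valence is a
  fixed integer, not a titratable state.
* The synthetic FASTA fixture bundled under `inst/extdata/` matches
  the FUS sticker composition (526 residues, 34 Tyr, 34 Arg) but is
  not the natural sequence; sequence order is irrelevant to the
  mean-field model, which consumes only the counts.
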