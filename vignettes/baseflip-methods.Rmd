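---
title: "Methods: the eversion coordinate, WHAM free energies and glycosylase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eversion coordinate, WHAM free energies and glycosylase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseflip)
```

## Scope

`baseflip` implements the analysis layer of a base-eversion study of the
bacterial 8-oxoguanine (oxoG) glycosylase Fpg/MutM: a pseudodihedral
reaction coordinate for base flipping, umbrella-sampling free-energy
estimation by the weighted histogram analysis method (WHAM) with two-run
error bars, eversion-angle-binned structural and energetic observables,
and steady-state Michaelis–Menten kinetics of wild-type and mutant
enzymes. It deliberately does *not* run molecular dynamics: trajectories
enter as multi-model PDB files, reaction-coordinate time series as plain
two-column text, and the package ships seeded synthetic generators that
emulate those inputs so every estimator can be validated end to end at
desk scale.

## The eversion-angle coordinate

Base eversion is tracked by a center-of-mass (COM) pseudodihedral over
four points: P1, the COM of the four bases flanking the target pair; P2,
the COM of the 5′ phosphate group; P3, the COM of the 3′ phosphate
group; and P4, the COM of the Watson–Crick edge of the everting base.
COMs are mass-weighted (the standard convention for COM pseudodihedrals),
and the dihedral sign follows the IUPAC right-handed convention with the
two-argument arctangent branch (−180°, 180°].

Because a full eversion sweeps through roughly 280°, the raw branch is
unwrapped: whenever the raw dihedral falls below the intrahelical
reference minus 90°, 360° is added. The intrahelical state then sits near
0° and eversion proceeds continuously toward ~280° with no wrap inside
the sampled range.

Atom-set choices that the coordinate definition leaves open are
configurable with these defaults:

* Watson–Crick edge of G/oxoG: the heavy pairing-edge atoms O6, N1, N2.
* Phosphate groups: P, OP1, OP2, O5′ of the named nucleotide.
* P1 uses base-moiety atoms only (no sugars or phosphates), since the
  flanking-base COM is meant to track the helical frame, not backbone
  breathing.

The phosphate indexing convention used throughout: p⁰ is the phosphate
5′ of the everting nucleotide, p¹ the next phosphate 5′ of that, and
p⁻¹ the phosphate 3′ of the everting nucleotide.

Ancillary per-frame observables use equally standard conventions: a
hydrogen bond is counted when the donor–acceptor distance is ≤ 3.5 Å
*and* the donor–H–acceptor angle is ≥ 135° (common MD practice; both
cutoffs configurable); the base-pair step twist is the signed angle
between the two inter-strand C1′→C1′ vectors after projection onto the
plane perpendicular to the local step axis. This simplified C1′
convention is not the full CEHS/3DNA frame construction; it is adequate
because only relative twist differences are interpreted.

## Pairwise nonbonded energies

Group–group interaction energies are decomposed into an electrostatic
term, $\sum_{ij} k_e q_i q_j / r_{ij}$ with
$k_e = 332.0522$ kcal·Å·mol⁻¹·e⁻², and a 12-6 Lennard-Jones term in the
Amber $R_{min}/\epsilon$ convention with Lorentz–Berthelot combination,
$\epsilon_{ij}\left[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^6\right]$.
The decomposition is a post-hoc analysis of raw pairwise interactions,
so no cutoff and no dielectric screening are applied (an MD engine's
nonbonded cutoff belongs to the dynamics, not to this bookkeeping), and
bonded/1–4 exclusions are not modeled because the operators are defined
only between atoms of different residues or groups. Parameters come from
a plain columnar table keyed by (residue name, atom name); an
unparameterized atom is an error, never a silent zero charge.

## Umbrella sampling and WHAM

The free-energy protocol mirrors the study design: 64 windows evenly
spaced at 4° along the eversion angle, each restrained by a harmonic
bias of 0.183 kcal·mol⁻¹·deg⁻² in the engine's restraint convention
$U = k\,\Delta\theta^2$ (no ½ prefactor; a flag switches to ½k if
needed), at 330 K ($k_B = 0.0019872041$ kcal·mol⁻¹·K⁻¹). The coordinate
is treated as non-periodic over the unwrapped 0→~280° range.

WHAM solves the usual self-consistent equations

$$P(b) \propto \frac{\sum_i n_i(b)}{\sum_i N_i e^{-\beta (U_i(b) - f_i)}},
\qquad f_i = -k_BT \ln \sum_b P(b)\, e^{-\beta U_i(b)},$$

iterated from $f_i = 0$ until the largest change in any $f_i$ is below
10⁻⁷ kcal/mol (at most 100 000 iterations, an error otherwise).
$G(b) = -k_BT\ln P(b)$ is anchored so the intrahelical endpoint is
0 kcal/mol. Bins with no samples are masked, never extrapolated, and
windows whose sampled supports do not connect raise a coverage error.

One numerical point matters at this protocol's geometry. The restrained
window distributions are narrow — standard deviation
$\sqrt{k_BT/2k} \approx 1.3°$ — so a histogram cell of the conventional
1° reporting width is *not* small compared to the window. Evaluating the
bias only at cell centers then biases the window-to-window matching by
$O(w^2)$; on the steep normal-base landscape this accumulates to several
kcal/mol across 64 windows. The implementation therefore solves the
self-consistent equations on an internal fine grid (`grid_refine`
subdivisions per reporting bin, default 8, with the bias Boltzmann
factor averaged within each fine cell) and pools probabilities back into
the 1° reporting bins. This keeps the discretization bias negligible
while retaining the low counting noise of the coarser reporting bins.

Uncertainty follows the study's two-run convention: every window is
sampled in two completely independent runs; each run is WHAM-solved and
anchored separately on a shared bin grid, the reported profile is the
per-bin mean and the error bar is half the absolute run difference. No
autocorrelation-based estimator is provided, deliberately.

## Angle-binned observables

Any per-frame observable is aggregated into eversion-angle bins of 5°
(the reporting convention for such curves). Within a run the bin value
is the arithmetic mean of the member frames; across the two runs the
reported value is the mean of the per-run means and the error is half
their difference — the same construction as the PMF error bars, which is
why the per-run means are averaged rather than pooling frames. A bin is
reported only when both runs contribute at least `min_count` frames
(default 10), a safeguard against sparsely visited angle ranges.

## Steady-state kinetics

Initial velocities $v_0$ at substrate concentrations $[S]$ are fitted to
$v_0 = k_{cat} [E]_{active} [S] / (K_M + [S])$ by nonlinear least
squares (Levenberg–Marquardt), separately per replicate, matching a
design of 3–5 independent experiments; the reported $K_M$ and $k_{cat}$
are replicate means ± sd. A pooled fit is available behind a flag. The
enzyme concentration is always the *active* concentration
$\varphi\,[E]_{total}$, with the active fraction $\varphi \in (0,1]$
measured externally (borohydride trapping) and supplied as an input.
Fit initialization is $k_{cat,0} = \max(v_0)/[E]_{active}$,
$K_{M,0} = \mathrm{median}([S])$, which is robust for Michaelis–Menten
curvature over the 2–100 nM design range.

The specificity constant is $k_{sp} = k_{cat}/K_M$ (ratio of the
reported means; its sd follows first-order error propagation). For
enzymes too impaired to resolve $K_M$ and $k_{cat}$ separately, $k_{sp}$
comes from the slope of the linear part of $v_0$ vs $[S]$ (ordinary
least squares through the origin, divided by $[E]_{active}$); such rows
render $K_M$ and $k_{cat}$ as "n/d".

Report formatting reproduces the conventions of published kinetics
tables: $K_M$, $k_{cat}$ and $k_{sp}$ at 2 significant figures, relative
activity as $100\,k_{sp}^{mut}/k_{sp}^{wt}$ at 1 decimal. The relative
activity is computed from the *rounded* $k_{sp}$ values — the published
percent column is only reproduced exactly under that convention, so it
is adopted as the reporting rule (a `round_inputs = FALSE` escape hatch
exists).

Not modeled, by design: product inhibition, burst kinetics, substrate
depletion. $v_0$ is taken at face value as a measured initial rate.

## The synthetic-data generators

The generators produce every input the pipeline reads, under a single
seed per invocation (run 1 and run 2 of a campaign use caller-supplied
distinct seeds; per-window seeds are derived deterministically).

**Landscapes** are sums of Gaussians plus a constant, offset so
G(0°) = 0. Two presets emulate the published eversion phenomenology and
were constructed once to match the printed feature values, then frozen:

* `oxoG_like`: metastable minima near 40° (−3.5 kcal/mol) and 88°
  (−4.5), overall barrier 6.9 kcal/mol near 140°, extrahelical endpoint
  7.5 kcal/mol *below* the intrahelical state.
* `G_like`: shallow minimum at 37°, mid-path crest ~11.5 kcal/mol,
  overall barrier 22.0 kcal/mol, endpoint ~19 kcal/mol *above* the
  intrahelical state.

`flat` and `double_well` support null and construction tests.

**Window sampling** is Metropolis Monte Carlo targeting
$e^{-\beta(G + U_{bias})}$ — the simplest kernel that targets the
distribution exactly and is fully deterministic under a seed. Proposal
sd is 2°, burn-in 1000 updates, and one recorded sample per 10 updates
(`stride`). The stride deserves a comment: the study records the
coordinate at every MD timestep, about 10⁶ points per window, while the
desk-scale stand-in keeps 5000 samples per window. Recording every 10th
Metropolis update makes those 5000 samples effectively independent, so
their information content is commensurate with what the estimator sees
in the full-length records; without it the window-matching noise of the
random-walk chain dominates the recovered profiles. Note also that an
*unbiased* chain has a proper stationary law only on a confining
landscape; sum-of-Gaussian landscapes are flat at infinity, so unbiased
validation runs should include wall terms.

**Toy trajectories** realize the coordinate geometrically: a
mass-realistic but chemically meaningless scaffold in which the two
phosphate-group COMs sit exactly on the rotation axis, the flanking-base
COM has azimuth exactly zero, and the Watson–Crick-edge group is rotated
about the axis by the scheduled angle — so the analytic pseudodihedral
equals the schedule to machine precision, giving an exact forward/inverse
identity for the coordinate code. Probe atoms (one pair co-rotating, one
static) support observable-pipeline tests. Frames can additionally be
tumbled by random rigid motions, which must not change any internal
observable.

**Kinetics data** follow
$v_0 = k_{cat}\varphi E_{tot} S/(K_M+S)\,(1+\varepsilon)$ with
$\varepsilon \sim N(0, \sigma)$, the multiplicative noise model matching
gel-quantified velocity errors that scale with signal.

## What the synthetic tests do and do not show

Passing the closure tests (campaign → WHAM → two-run errors recovers the
generating landscape to ≤ 0.25 kcal/mol RMS; WHAM agrees with direct
Boltzmann inversion of a long unbiased run to ≤ 0.15 kcal/mol RMS;
coordinate forward/inverse identity to 10⁻⁶ degrees; Michaelis–Menten
recovery to 10⁻⁶ relative noiseless and median-within-15% at 5% noise)
demonstrates that the *estimators* are correct and unbiased at the
study's protocol scale. They do not demonstrate anything about real
molecular systems: the synthetic landscapes are smooth 1-D caricatures
with no orthogonal slow degrees of freedom, no hysteresis between runs
started from different paths, and no force-field error — the dominant
uncertainties in the real calculation. Problem sizes used throughout
(64 windows × 5000 recorded samples × 2 runs; 200 seeded kinetics
repetitions) were chosen as the smallest sets at which the estimator
noise floors sit comfortably below the tolerances being checked.

## Numerical choices and degenerate inputs

* Dihedral/COM operators reject coincident points, collinear bond
  vectors and zero total mass rather than returning NaN.
* WHAM masks empty reporting bins; a dominant contiguous coverage block
  is required, stray far-tail bins are masked, and two substantial
  disconnected blocks raise an error (the run is unusable, not fixable).
* Endpoint/barrier statistics refuse masked bins inside the segment
  unless linear interpolation is explicitly enabled.
* Saturable fits error on non-convergence or non-physical (≤ 0)
  parameters; the linear-slope route errors on a non-positive slope;
  a saturable fit whose largest $[S]$ does not exceed $K_M/2$ warns that
  saturation is poorly constrained.
* Ties in anchor/endpoint lookup resolve to the nearest bin center.

## Known limitations

* The twist angle is a simplified C1′ construction, not a full base-pair
  step frame; absolute values can differ from 3DNA-style definitions.
* Trajectories are multi-model PDB only; binary MD formats are out of
  scope.
* Two-run differences are the only uncertainty estimate, faithful to the
  protocol but known to understate error when the two runs share
  initialization pathologies.
* The 2-D free-energy analysis of earlier work is intentionally not
  supported; the coordinate here is the 1-D modified COM pseudodihedral.
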