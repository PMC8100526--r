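---
title: "MechanoBond: models, parameters and design choices"
author: "MechanoBond authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MechanoBond: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MechanoBond)
```

MechanoBond analyses how a two-chain receptor–ligand interface responds to
tensile force: which hydrogen bonds and salt bridges hold the interface
together, how often each is formed, how the complex-level dissociation
probability follows from the bond statistics, and how individual bonds
and the whole complex behave as force increases (slip, catch–slip, and
higher-order patterns). This vignette explains the underlying models,
their assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Bond detection

A hydrogen bond is scored per frame from pure geometry:

* donor–acceptor distance **strictly less than** 3.5 Å
  (`hbondCriteria(maxDaDistance=)`), and
* deviation of the H→A direction from the D→H direction **strictly less
  than** 30° (`maxDhaAngle=`), for at least one hydrogen covalently
  attached to the donor (attachment is judged geometrically: same
  residue, < 1.3 Å).

Donors are N/O heavy atoms carrying a hydrogen; acceptors are all N/O
heavy atoms. This deliberately broad chemistry covers backbone and side
chain alike, and both histidine tautomers fall out naturally: the
unprotonated ring nitrogen is simply an N without an attached H and so
acts only as an acceptor. Both inter-chain directions are scanned each
frame.

Strictness at the cutoffs is a convention; with measured coordinates the
boundary set has measure zero, but the tests pin the behaviour so it
cannot drift silently. Salt bridges instead use an **inclusive** 4.0 Å
cutoff ("within 4 Å") between side-chain carboxylate oxygens (Asp
OD1/OD2, Glu OE1/OE2) and basic side-chain nitrogens (Lys NZ, Arg
NE/NH1/NH2). Salt bridges are scored at residue-pair level — the
participating atom pair may migrate among the chemically equivalent
side-chain atoms from frame to frame without breaking the contact — so
their keys carry no atom names. Hydrogen bonds, in contrast, are keyed at
atom level (donor and acceptor names), because two distinct bonds between
the same residue pair are statistically distinct events; residue-level
aggregation happens only inside the dissociation model.

Crystal structures usually lack hydrogens. Detection then finds nothing
by default; an explicit `useHeavyAtomFallback = TRUE` switches to a
heavy-atom criterion (D–A < 3.5 Å plus acceptor–donor–antecedent angle
> 90°). The fallback is opt-in rather than automatic so that a
trajectory accidentally stripped of hydrogens fails loudly instead of
silently changing criteria.

Occupancy is the fraction of frames in which a bond satisfies its
criteria. Frames are weighted equally regardless of time stamps — the
occupancy is a "percentage of survival time" under a uniform saving
stride, and the stride itself is a user decision, never inferred from
the file.

## The dissociation probability model

Each bond is assumed to form and break **independently** of every other
bond. Writing $\omega_{ij,l}$ for the occupancy of the $l$-th bond
between ligand residue $i$ and receptor residue $j$:

$$p_{ij} = 1 - \prod_l (1 - \omega_{ij,l})$$

is the probability that the pair is connected by at least one bond, and

$$P_{j,L} = 1 - \prod_i (1 - p_{ji}), \qquad
  P_{j,R} = 1 - \prod_i (1 - p_{ij})$$

are the residue-level binding probabilities on the two sides. The
complex-level dissociation probability is the probability that **no**
interface bond survives,

$$P_D = \prod_{j}(1 - P_{j,L}) = \prod_{j}(1 - P_{j,R})
      = \prod_{\text{bonds}} (1 - \omega),$$

an algebraic identity under independence that the implementation verifies
internally on every call (the two side evaluations must agree to
$10^{-9}$ in log space, and property tests push this to $10^{-12}$ on
random tables). The complementary quantity $1 - \prod_j (1 - P_{j,L})$ —
the probability that at least one residue-level contact is engaged — is
available behind `complement = TRUE` for comparison with conventions that
define a "dissociation" score that way, but it is not the default: for a
healthy interface it saturates near 1 and does not discriminate between
models, whereas the no-bond-survives product spans orders of magnitude.

The normalized dissociation $f_D(f) = P_D(f)/P_D(0)$ compares a loaded
condition to the zero-force reference; $f_D < 1$ means force-strengthened
binding (catch), $f_D > 1$ force-weakened (slip). Both quantities are
computed as exponentiated sums of $\log(1-\omega)$ with $\omega = 1$
short-circuited: with tens of bonds $P_D$ can be far below $10^{-3}$, and
the `logPD` slot remains exact even where $P_D$ itself would underflow a
double. The f_D ratio is always formed in log space.

What the model does **not** do: no correlation between bonds (cooperative
breaking is real but unidentifiable from occupancies alone), no kinetic
(off-rate) interpretation of $P_D$, and no geometric or timescale
correction. It is an equilibrium-statistics summary of a sampled ensemble.

## Force-response classification

A bond's occupancies across increasing force levels are reduced to a sign
signature: consecutive differences with $|\Delta| \le \varepsilon$ are
flat and dropped; adjacent equal signs merge. The surviving signature
maps to a named class — $(-)$ slip, $(+,-)$ catch–slip, $(-,+,-)$
slip–catch–slip, $(+,-,+)$ catch–slip–catch, empty = insensitive. A pure
monotone increase has no conventional name in the slip/catch taxonomy
(over a finite force window it is the rising limb of a catch–slip bond
whose maximum lies beyond the window), so it is reported as `"other"`
with the signature preserved.

The default tolerance $\varepsilon = 0.025$ reflects the occupancy
estimation noise of typical clamped-MD sampling windows (tens of ns,
occupancy SEs of 0.01–0.02 across replicate runs): wobbles at that scale
are flat, not pattern reversals. It is exposed in the configuration and
in every classifying function. Flat steps are dropped rather than
interpolated because the classification is a qualitative trend over a
handful of force levels, not a fitted curve.

Transition forces are located as the extreme value of a force-indexed
series (minimum for $f_D$, maximum for the expected bond count
$\sum\omega$), with ties broken toward the lowest force and reported.
Segmented Pearson correlations around a split force use the standard
product-moment formula; segments with fewer than 3 points are flagged
(`"two-point"` segments give $r = \pm 1$ by construction and should not
be over-read) and constant segments return `NA` with a reason instead of
propagating `NaN`.

## Structural metrics

* **Superposition/RMSD** — Kabsch least-squares rotation via SVD with the
  determinant sign corrected (never a reflection). Cα-RMSD time courses
  superpose each frame onto the reference by default: a pulled complex
  drifts rigidly, and the conformational signal is what remains after
  that drift is removed. `superpose = FALSE` gives the raw displacement
  when the drift itself is of interest.
* **SASA** — Shrake–Rupley point sampling with Bondi van der Waals radii,
  a 1.4 Å water probe, and 960 deterministic golden-spiral points per
  atom (~1% accuracy on a sphere; `nPoints` is the precision/speed knob).
  Buried interface area is $SASA_A + SASA_B - SASA_{AB}$, **not divided
  by two**; the convention is stated here and in the output metadata
  because both halved and unhalved conventions circulate.
* **Helix axis** — principal component of the centred Cα coordinates,
  oriented N→C by its projection on (last − first) Cα. For ideal
  geometry the recovered axis is within ~2° of truth once the helix
  spans about three full turns (≥ 12–20 residues); shorter stretches are
  accepted down to 4 residues but the lateral helix radius then competes
  with the axial spread, so short-helix angles should be read
  qualitatively. Helix ranges are user-specified residue intervals — the
  package does no secondary-structure assignment.
* **Centroid distances** use mass-weighted centres with standard atomic
  masses, hydrogens included when present.

All metrics are invariant under global rigid motion (tested), and SASA is
monotone under adding context atoms.

## Force traces and lifetimes

Rupture force is the maximum of the force–time pattern over the ramp
phase (whole trace when unlabeled), with the peak time reported.
Lifetimes are binned into left-closed, right-open bins anchored at 0 pN
(default width 7.5 pN; a record exactly at an edge goes right), with
per-bin mean, SEM and count.

The two-pathway off-rate

$$k(f) = k_c e^{-x_c f / k_BT} + k_s e^{x_s f / k_BT}$$

(mean lifetime $1/k(f)$; $k_BT$ defaults to 4.28 pN·nm at 310 K) is the
standard minimal model for catch–slip lifetimes. It is fitted to binned
mean lifetimes by nonlinear least squares on the log lifetime with all
four parameters log-parameterised for positivity. The optimum force has
the closed form $f^* = \frac{k_BT}{x_c + x_s}\ln\frac{k_c x_c}{k_s x_s}$.
For monotone-slip data the catch amplitude is unidentifiable; instead of
failing, the fitter falls back to the single slip pathway, reports
$k_c = 0$ with a `catchDegenerate` flag, and returns no interior optimum.

## Synthetic generators: what they emulate, and what they do not

The generators exist so that every analysis stage can be tested against
known ground truth without external data.

* `genInterfaceTrajectory()` builds two chains of glycine-like residues,
  each hosting one designed donor–H–acceptor triple. The bound geometry
  (2.9 Å, 10° deviation) satisfies the default criteria; the unbound
  geometry (5.5 Å) violates them, so detection recovers the hidden state
  sequence exactly. Per-bond states follow a **two-state Markov chain**
  with prescribed stationary occupancy $\omega^*$ and switching intensity
  $r$ (transition probabilities $r\omega^*$ up, $r(1-\omega^*)$ down) —
  deliberately *not* i.i.d. frames, so occupancy estimators face the
  autocorrelation real trajectories have. The effective sample count is
  $n_\mathrm{eff} = nr/(2-r)$, and recovery tests use a
  $4\sqrt{\omega(1-\omega)/n_\mathrm{eff}}$ band. Default test problem
  sizes are 1500–2000 frames and $r = 0.5$.
* `genOccupancyTable()` produces force panels from anchor occupancies per
  response class (validated to classify correctly at $\varepsilon = 0$)
  plus optional Gaussian replicate noise, over the canonical force grid
  0/25/50/75 pN.
* `genRampClampTrace()` uses the spring constant 13.89 pN/Å and a
  constant-velocity ramp (slope $k v$), then either clamps at the target
  force or ruptures with a short triangular fall; phases are labeled.
* `genAfmLifetimes()` draws exponential lifetimes with rate $k(f)$ from
  the two-pathway model. Recovery tests use 500 lifetimes per 7.5 pN bin
  (with a 50/bin consistency check).

What passing these tests shows: the detectors, estimators, model algebra
and fitters are correct on inputs whose truth is known, including under
realistic estimator autocorrelation and noise. What it does not show:
anything about force-field accuracy, sampling convergence of real MD,
solvent effects, or instrument artefacts in real AFM data — the
generators are kinematic puppetry, with no physical mechanics. Real
trajectories also exhibit correlated bond dynamics, which the
independence model ignores by construction.

## Degenerate inputs and numerical conventions

* Empty interface: $P_D = 1$ (no bond ever survives) and the pipeline
  exits cleanly with an empty classification.
* $\omega = 1$ anywhere pins $P_D = 0$ (and makes $f_D$ against that
  reference undefined — an error, not `Inf`).
* Zero frames, empty selections, unknown elements, overlapping chain
  selections, non-increasing forces, and sub-3-level panels are all
  rejected with specific errors; empty *selections* during detection are
  a warning plus an empty result, since "no atoms matched" is a
  legitimate query outcome.
* All randomness is behind a single integer seed per generator; the
  caller's RNG stream is saved and restored, so generators are
  bit-reproducible and side-effect-free.
* Re-running a pipeline with the same configuration and seed reproduces
  byte-identical TSV outputs (the manifest's timestamp line aside).

## Known limitations

Only multi-model PDB and PDB+DCD inputs are read (no mmCIF); no
π-stacking, cation–π, hydrophobic or water-mediated contacts; no
Bell/Dudko rupture-force distribution analysis; no docking or MD
execution — the package starts where the simulation engine stops. The
equilibrium occupancy tables shipped in `inst/extdata` are means; where a
source reports per-run spreads, only the means enter the model, which is
consistent with the model's use of long-run survival fractions.
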