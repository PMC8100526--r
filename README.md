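# MechanoBond

Mechano-regulation analysis of receptor–ligand interface bonds from
molecular dynamics trajectories and single-molecule force spectroscopy.

Adhesive receptor–ligand complexes — integrin–glycoprotein pairs such as
Mac-1/GPIbα, selectins with PSGL-1, VWF-A1 with GPIbα — are loaded by
tensile force in flowing blood, and their interfaces respond to that force
bond by bond: some hydrogen bonds weaken monotonically (slip bonds), some
strengthen before weakening (catch–slip bonds), and the complex-level
dissociation probability inherits a biphasic force dependence from this
mix. MechanoBond provides the post-processing side of that analysis for
structural biologists and biophysicists who already have trajectories
(from steered/clamped MD) or force-spectroscopy records (from AFM), and
want the bond-level statistics, the probability model, and the
classification machinery in one tested toolchain.

## What it computes

**Interface bond detection and occupancy.** A hydrogen bond is scored in a
frame when the donor–acceptor distance is < 3.5 Å and the
donor–hydrogen–acceptor deviation is < 30°; a salt bridge when a
side-chain carboxylate oxygen (Asp/Glu) is within 4 Å of a basic
side-chain nitrogen (Lys/Arg). The occupancy (survival ratio) of bond *l*
between ligand residue *i* and receptor residue *j* is

    ω_ij,l = (frames in which the bond is formed) / (total frames)

**Independence-based dissociation model.** Treating each bond's
formation/breakage as independent,

    p_ij   = 1 − Π_l (1 − ω_ij,l)          (residue-pair binding)
    P_j,L  = 1 − Π_i (1 − p_ji)            (ligand-residue binding)
    P_j,R  = 1 − Π_i (1 − p_ij)            (receptor-residue binding)
    P_D    = Π_j (1 − P_j,L) = Π_j (1 − P_j,R) = Π_bonds (1 − ω)
    f_D    = P_D(f) / P_D(0)               (normalized dissociation)

P_D is the probability that *no* interface bond survives; products are
evaluated in log space so many-bond interfaces do not underflow. f_D < 1
indicates force-strengthened (catch) binding, f_D > 1 force-weakened
(slip) binding.

**Force-response classification.** Per-bond occupancy-versus-force series
are reduced to a sign signature (changes below a tolerance ε, default
0.025, count as flat) and mapped to slip, catch–slip, slip–catch–slip,
catch–slip–catch, insensitive, or other.

**Structural mechano-metrics.** Kabsch-superposed Cα-RMSD time courses,
Shrake–Rupley SASA and buried interface SASA (SASA_A + SASA_B − SASA_AB),
inter-helix angle from principal-axis fits of Cα coordinates,
centre-of-mass–to-atom distances, and pulled–fixed atom distances.

**Force traces and lifetimes.** Rupture-force extraction from ramp
pulling traces, lifetime binning (7.5 pN default bins) and a two-pathway
catch–slip off-rate fit, k(f) = k_c·e^(−x_c f/kBT) + k_s·e^(x_s f/kBT),
with the closed-form lifetime-optimum force.

**Synthetic generators.** Every input the pipeline consumes can be
generated with known ground truth: Markov-switching interface
trajectories with prescribed stationary occupancies, force-panel
occupancy tables per response class, ramp-clamp force traces, exponential
AFM lifetimes, and ideal helices.

## Worked example

The package ships the interface H-bond occupancy tables of a docked
integrin I-domain/GPIbα complex: `model_hbond_occupancy.tsv` compares
three structural models at equilibrium, and
`force_panel_hbond_occupancy.tsv` holds the top 11 interface bonds under
0, 25, 50 and 75 pN clamped tension.

```r
library(MechanoBond)
tab <- readOccupancyTable(system.file("extdata",
  "model_hbond_occupancy.tsv", package = "MechanoBond"))
complexDissociation(tab, "model_I")
#> DissociationResult [model_I]
#>   P_D = 0.02193
complexDissociation(tab, "model_II")
#> DissociationResult [model_II]
#>   P_D = 0.0005586
```

The force-optimized model II (14 interface bonds vs 7) is ~40-fold less
likely to let go: a per-frame probability of 5.6×10⁻⁴ that no interface
bond is formed, versus 2.2×10⁻² for the raw docking pose.

```r
panel <- readOccupancyTable(system.file("extdata",
  "force_panel_hbond_occupancy.tsv", package = "MechanoBond"))
dissociationReport(panel, referenceForce = 0)
#>   condition n_bonds      P_D    f_D sum_omega
#> 1         0      11 1.55e-03 1.0000      4.44
#> 2        25      11 9.21e-05 0.0595      5.83
#> 3        50      11 1.66e-04 0.1070      5.53
#> 4        75      11 3.06e-03 1.9778      4.22
```

f_D dips to 0.06 at 25 pN — the complex is ~17× *less* likely to
dissociate under moderate load than unloaded — then rises past 1 at
75 pN: a catch–slip transition with its turning point at 25 pN, where the
expected interface bond count (Σω) also peaks at 5.83.

```r
cls <- classifyOccupancyTable(panel, epsilon = 0.025)
table(cls$pattern)
#>       catch-slip catch-slip-catch             slip  slip-catch-slip
#>                6                1                2                2
```

Six of the eleven bonds are individually catch–slip (e.g. S288–D235,
K278–E40), two are pure slip (both partners of K19), and the remainder
show higher-order patterns — the complex-level catch bond emerges from
this cooperative mix.

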