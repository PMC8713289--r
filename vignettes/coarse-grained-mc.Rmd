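---
title: "Coarse-grained constant-pH Monte Carlo of protein self-association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained constant-pH Monte Carlo of protein self-association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadmc)
```

## The model

`beadmc` studies the solution behaviour of a globular protein —
oligomerisation, net pairwise attraction or repulsion, and how both depend
on pH and added salt — with a rigid one-bead-per-residue model sampled by
Metropolis Monte Carlo. Each residue of an all-atom structure is replaced
by a spherical bead at the residue's element-mass-weighted centre of mass.
The bead mass is the average residue mass $M_{w,i}$ and the bead diameter
is that of the volume-equivalent sphere,

$$\sigma_{ii} = 2\left(\frac{3 M_{w,i}}{4\pi\rho}\right)^{1/3},
\qquad \rho = 1\ \mathrm{g\,mol^{-1}\,\text{Å}^{-3}},$$

which puts all twenty residue types between about 4.4 and 7.1 Å. The
potential energy is a sum over inter-protein residue pairs of

* **screened Coulomb electrostatics**,
  $u_{el} = \lambda_B z_i z_j e^{-r/\lambda} / r$ in units of $k_BT$, with
  the Bjerrum length $\lambda_B = e^2/(4\pi\varepsilon_0\varepsilon_r k_B T)
  \approx 7.0$ Å for $\varepsilon_r = 80$ at 298.15 K, and the Debye length
  of a 1:1 electrolyte $\lambda/\text{Å} = 3.04/\sqrt{I(\mathrm{M})}$
  (unscreened at $I = 0$);
* **van der Waals attraction and excluded volume** as a single
  Lennard-Jones term $4\varepsilon_{ij}[(\sigma_{ij}/r)^{12} -
  (\sigma_{ij}/r)^6]$ with Lorentz–Berthelot mixing
  ($\sigma_{ij}$ arithmetic, $\varepsilon_{ij}$ geometric mean) and a
  uniform $\varepsilon_{ij} = 0.05\,k_BT$ baseline;
* a **titration term**: the nine reactions $HA \rightleftharpoons H + A$
  (C-terminus 3.67, Asp 3.67, Glu 4.25, His 6.54, N-terminus 8.0, Cys 8.55,
  Tyr 9.84, Lys 10.4, Arg 12.0) sampled by reactive Monte Carlo. A flip of
  one site is accepted with probability
  $\min\{1, \exp(-\Delta U_{el} \mp \ln 10\,( \mathrm{pH} - \mathrm{p}K_a))\}$,
  the sign chosen so that deprotonation is favoured above the p$K_a$; the
  proton bath is implicit, which leaves the stationary distribution of a
  fixed-pH ensemble unchanged. Acid sites carry $0/-1$, base sites $+1/0$;
  the two terminal sites attach to the first and last bead on top of any
  side-chain site there. Sites sharing a bead are coincident and do not
  interact with each other.

All energies are carried in $k_BT$ at the configured temperature, all
lengths in ångström, charges in units of $e$.

## Two-body cell: force, PMF and $B_2^*$

Two copies of the protein sit in a spherical cell of radius 120 Å: one
rotates about its centre of mass at the origin, the other rotates at a
centre-of-mass separation $z$ on the $z$-axis. Both proteins titrate
during the run. The package supports two ways of covering $z$: Monte Carlo
translation moves, or (default) a ladder of fixed-$z$ windows swept from
the cell edge inwards, each window's chain seeded from the final state of
its outer neighbour. The windowed mode gives even coverage of every
separation; the inward seeding keeps the pair on the physically connected
branch of configurations rather than letting an isolated window relax into
an interlocked overlap state it could never reach quasi-statically.

For every recorded state a virtual displacement $dL = 0.2$ Å of the second
protein gives an energy perturbation $du$, and the mean force is estimated
per window by free-energy perturbation,

$$F(z) = \frac{1}{dL}\,\ln\left\langle e^{-\beta\,du}\right\rangle,$$

whose first-order expansion $-\langle du\rangle/dL$ is reported alongside
as a consistency check. Trapezoidal integration from the outer edge
($U(z_{max}) = 0$) gives the potential of mean force, and

$$B_2 = \frac{2\pi\sigma^3}{3}
 - 2\pi\int_\sigma^{z_{max}}\left(e^{-\beta U(z)} - 1\right) z^2\,dz,
\qquad B_2^{hs} = \frac{2\pi (2R_h)^3}{3},
\qquad B_2^* = B_2/B_2^{hs},$$

with $R_h = 22.71$ Å. The contact distance $\sigma$ is not imposed: it is
the innermost separation just outside the outermost bin whose Boltzmann
factor falls below $e^{-10}$ (both the integrated PMF and the directly
sampled mean energy must clear the floor). Because $B_2$ depends
exponentially on the deepest PMF values, single finite chains have heavy-
tailed errors; `twobody_virial()` therefore reports per-replica values
*and* a pooled estimate in which the perturbation samples of all replicas
are combined per window before the force estimate. The pooled value is the
headline number.

## Multipole decomposition

Treating each protein as a monopole $Q$, dipole $\boldsymbol{\mu}$ and
traceless quadrupole $\Theta$ about its centre of mass, the pair energy is
expanded through order $r^{-3}$: ion–ion, ion–dipole, dipole–dipole and
ion–quadrupole terms (higher cross terms are omitted). With the separation
vector defined from protein 2 to protein 1 the ion–dipole term is
$[Q_1(\boldsymbol{\mu}_2\cdot\hat r) - Q_2(\boldsymbol{\mu}_1\cdot\hat
r)]/r^2$; the convention is fixed by requiring the series to converge to
the exact Coulomb sum, which the test suite verifies against a brute-force
oracle. Ensemble averages of each term are taken over the recorded
two-body samples; the decomposition is evaluated unscreened (it is
analysed at zero added salt), with an optional screened variant multiplying
each term by $e^{-r/\lambda}$. For single-number summaries the samples are
weighted by the configurational weight $e^{-\beta u} z^2$ of their
separation shell, and the average is restricted to separations beyond
about twice the maximal bead radius: at contact the expansion is
evaluated inside the charge distribution and does not converge, so
including those states would let an invalid series dominate the summary.

## Many-body box: clusters, shapes, tempering

$N$ proteins (30 by default) move in a periodic cube sized to a target
mass concentration, $L = (N M_w / N_A c)^{1/3}$ — about 986, 458 and
317 Å for 1, 10 and 30 mg/mL with a 19.24 kDa monomer. Charges are fixed
at the per-site mean occupancies from a constant-pH equilibration (rounded
to three decimals); electrostatics use molecule-based minimum image with a
half-box truncation (at zero added salt the unscreened Coulomb tail is
truncated likewise — an approximation noted here once and accepted, as no
Ewald treatment is attempted). The Lennard-Jones part uses a $4.5\sigma$
pair cutoff, beyond which the discarded tail is below
$5\times10^{-4}\,\varepsilon$ per pair.

Moves are single-protein translations and rotations plus a cluster move: a
single-linkage cluster (centre-of-mass distance threshold, default
$2R_h = 45.4$ Å — the same threshold used for the analysis) is translated
or rotated as one object, and the proposal is rejected outright if the
move would change cluster membership, preserving detailed balance. A toy
test confirms that pair statistics with and without cluster moves agree.

Hamiltonian parallel tempering runs replicas along a ladder of
$\varepsilon_{ij}$ values (default ten rungs from 0.05 by 0.01 $k_BT$;
increasing $\varepsilon_{ij}$ acts like cooling). Because
$\varepsilon_{ij}$ is uniform, the Lennard-Jones energy is linear in it
and cross-ladder energies follow by rescaling the stored vdW component;
adjacent swaps are accepted with the standard two-state criterion. The
running pair-energy bookkeeping is checked against a from-scratch
recomputation at the end of every run.

Cluster analysis reports, per frame, the single-linkage partition, the
number-average cluster size $\langle N\rangle$ (total proteins divided by
number of clusters; the mass-average is emitted alongside), and the
relative shape anisotropy

$$k^2 = 1 - 3\,\frac{\lambda_1\lambda_2 + \lambda_1\lambda_3 +
\lambda_2\lambda_3}{(\lambda_1+\lambda_2+\lambda_3)^2}$$

from the sorted eigenvalues of the gyration tensor of the member
centres of mass, unwrapped to a common periodic image by minimum-image
growth. $k^2$ is 0 for spherically symmetric arrangements and 1 for a
collinear chain; a dimer is identically 1, so shapes are reported for
trimers and larger.

## The synthetic reference structure

The package's reference protein is human interferon alpha-2a: 165
residues, 19.24 kDa, pI near 6, a five-helix-bundle cytokine whose
solution behaviour (attraction and oligomer formation near the pI at low
salt, uniform screening by 140 mM NaCl) is the package's motivating use
case. The experimental coordinates are an external download, so the
package ships `ifn_alpha2a_model()`, a SYNTHETIC stand-in built entirely
in code: the true mature sequence threaded onto an idealized five-helix
bundle (ideal helix geometry on five axes, loops interpolated along the
bundle surface, termini wrapped against the bundle, each bead displaced
~1.9 Å outward toward the residue centroid, plus a small fixed-seed
irregularity because a perfectly periodic bundle lets two copies dock in
an unphysically complementary register).

What this stand-in preserves exactly: residue count, molecular weight,
titratable-site composition, and hence the full charge-versus-pH
behaviour and the isoelectric point. What it only approximates: the
three-dimensional arrangement of charges, hence dipole and quadrupole
magnitudes, surface complementarity and contact geometry. Consequences
observed with the defaults: the equilibrium dipole magnitude at pH 6.5
comes out near 100 eÅ rather than the ~122 eÅ of the experimental fold,
and the synthetic surface is stickier than the real one — the two-body
$B_2^*$ shows the correct qualitative pH dependence at zero salt
(repulsion at high pH, strongest attraction near the pI) but
over-predicts attraction at low pH and under 140 mM NaCl, where locked
contact configurations with favourable charge pairing dominate the
Boltzmann integral. Passing tests on the synthetic structure therefore
validate the machinery and the sequence-derived physics, not the
experimental fold's contact map.

## Numerical choices and defaults

* Two-body: cell radius 120 Å; separations 26–115 Å in ~3 Å windows;
  $10^5$ equilibration plus $10^6$ production moves and 5 replicas at full
  scale (tests and examples run scaled-down versions: $2\times10^5$
  production moves and 3 replicas per condition, which keeps a full
  pH × salt screen to a couple of minutes);
* rotation step sizes adapt during equilibration toward 30–50 %
  acceptance and are frozen for production;
* titration equilibration: $10^5$ flip attempts by default; fractional
  charges rounded to 3 decimals before many-body runs;
* many-body: 30 proteins and ten ladder rungs at full scale; the scaled
  demonstrations use 10 proteins, three rungs and $6\times10^3$ production sweeps;
  cluster moves take 10 % of move attempts;
* all samplers draw from their own explicitly seeded generator, so every
  result is bitwise reproducible from its recorded seed and independent of
  R's global RNG state;
* degenerate inputs: overlapping beads yield an immediate move rejection
  inside samplers and an error in direct energy evaluations; empty
  separation bins are flagged and excluded from the force profile;
  non-contiguous force grids are an error, not silently bridged.

## Limitations

No explicit ions, dielectric boundaries or polarizability; no Ewald
summation; no titration during many-body production (charges are fixed
averages); rigid proteins only; and the reference structure is synthetic
as described above — conclusions about the real protein's contact
geometry require the experimental coordinates, which can be supplied as
ordinary PDB input to `parse_structure()`/`coarsen()`.
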