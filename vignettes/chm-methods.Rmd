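---
title: "Fitting potential energy surfaces with a PIP-parameterized charge density matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting potential energy surfaces with a PIP-parameterized charge density matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chmpes)
```

## The model

A molecular potential energy surface (PES) is a function of the nuclear
configuration that is exactly invariant under permutations of identical
nuclei.  The conventional way to build that invariance into a linear fit
is a basis of permutationally invariant polynomials (PIPs): monomials in
Morse-transformed internuclear distances, $y_{ab} = e^{-d_{ab}/d_0}$,
symmetrized over the like-atom permutation group.  For a maximal total
power $M$ this gives $L$ basis functions and the baseline model

$$E_\mathrm{PIP}(\mathbf R) \;=\; \sum_{i=1}^{L} c_i\, u_i(\mathbf R).$$

`chmpes` additionally implements a physically structured alternative, the
core-Hamiltonian model (CHM).  Its ansatz is the closed-shell
Hartree–Fock trace expression with the two-electron matrix dropped
($\mathbf G = 0$), one normalized $s$-type Gaussian per atom:

$$E_\mathrm{CHM}(\mathbf R) = E_\mathrm{nuc}
 + \sum_a P_{aa} H^\mathrm{core}_{aa}
 + 2\sum_{a<b} P_{ab} H^\mathrm{core}_{ab}
 + \Delta E(\mathbf R),$$

where $H^\mathrm{core}$ (electron kinetic energy plus electron–nucleus
attraction) and the overlap $S$ have closed forms in terms of Gaussian
and error functions (the Boys function $F_0$), $E_\mathrm{nuc}$ is the
exact point-charge repulsion, and the density matrix elements are fitted
functions of geometry:

* diagonal: $P_{aa} = n_a + \sigma_a(\mathbf R)\sum_i c^{\mathrm{class}(a)}_i
  u_{a,i}(\mathbf R)$ with $n_a$ the permanent electron population of the
  atom's class (e.g. $n_\mathrm{H} = 2/3$ for H$_3^+$, $n_\mathrm{C} = 6$,
  $n_\mathrm{H} = 4/5$ for CH$_5^+$) chosen so that
  $\sum_a n_a + q = \sum_a Z_a$;
* off-diagonal: $P_{ab} = \tau(d_{ab})\sum_i c^{\mathrm{pair}(ab)}_i
  v_{ab,i}(\mathbf R)$ built on an independently scaled variable set
  $t_{ab} = e^{-d_{ab}/t_0}$;
* correction: $\Delta E = \sum_i c^\mathrm{corr}_i u_i(\mathbf R)$,
  formally the correlation energy, fitted with the same invariant PIPs.

All coefficients enter linearly, so a weighted least-squares problem (QR
decomposition, SVD minimum-norm fallback on rank deficiency) determines
them in one shot.  Charge conservation,
$n(\mathbf R) = \sum_{ab} P_{ab} S_{ab}$, can be imposed softly as extra
residual-zero rows with a small weight (default 0.01, the published
protocol for the larger systems).

## Covariant PIPs: the coset-sum construction

Site quantities must *relabel*, not stay fixed, under like-atom
permutations: swapping hydrogens 1 and 2 must exchange $P_{11}$ and
$P_{22}$ and map $P_{1c} \leftrightarrow P_{2c}$, leaving the total
energy invariant.  `chmpes` builds the covariant function attached to
anchor $a$ (or pair $\{a,b\}$) as the sum of a generator monomial's
images over the *coset* of group elements that map the class reference
anchor onto $a$:

$$u_{a,i}(\mathbf R) \;=\; \sum_{g:\,g(a_0)=a} (g\cdot m_i)(\mathbf R),$$

one function for each of the $L-1$ non-constant invariant orbits $i$.
Covariance holds exactly because the coset for $g(a)$ is $g$ times the
coset for $a$; the tests verify it to $10^{-12}$ for every group element.

The source literature instead symmetrizes with binary phase factors
$b = \pm 1$ whose exact definition lives in an unavailable reference.
The two constructions coincide: any consistent (covariant) sign
assignment has the form $b_{a,J} = f(J^{-1}(a))$ for some sign pattern
$f$ over sites, and every such signed full-group sum equals a linear
combination of coset sums plus a multiple of the invariant PIP of the
same orbit.  Since the correction term $\Delta E$ already spans all
invariants, the fitted model space is identical.  The package therefore
keeps the all-plus coset sums (simplest, manifestly covariant) with no
loss of expressivity.

Orbit sums run over *distinct* orbit members without multiplicity;
within one coset every distinct image occurs equally often, so dropping
multiplicities is a per-function constant absorbed by the linear
coefficients.

## Counting conventions

Density-class expansions exclude the constant term and the correction
keeps it, giving
$L' = (n_\mathrm{atom\,classes} + n_\mathrm{pair\,classes})(L-1) + L$
coefficients.  This reproduces the published dimensions for methanium
($L' = 5(L-1)+1$: classes $P_\mathrm{H}, P_\mathrm{C}, P_\mathrm{HH},
P_\mathrm{CH}$ plus $\Delta E$) and formamide ($L' = 12(L-1)+1$: four
atom and seven pair classes).  The two-electron systems are printed with
a per-class-$L$ convention ($4L$ for HeH$^+$, $3L$ for H$_3^+$);
`chm_basis_set(..., convention = "per_class")` exposes exactly that
variant, and the H$_3^+$ reproduction below uses it.

Atom classes are **declared, not detected**: formamide treats all three
hydrogens as one class even though they are chemically inequivalent,
because that is the convention behind the printed $L = 8, 46, 220, 905,
3292$.  Atom indices are 1-based throughout (R convention); pair slots
are ordered lexicographically $(i<j)$.

Augmented bases add all orbits of monomial *shape patterns* placed on
distinct distance slots with no restriction on shared atoms — e.g.
patterns $\{[3],[2,1]\}$ on the formamide $M=2$ basis give the published
$L = 111$, and $\{[4],[3,1],[2,2],[2,1,1]\}$ on $M=3$ give $L = 611$,
which settles the pattern-interpretation question in favor of the
unrestricted reading.

## Tunable parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `M` | maximal total PIP power | — | – |
| `d0` | Morse range of atom/correction PIPs | 2 | Angstrom |
| `t0` | Morse range of pair PIPs | 2 | Angstrom |
| `alpha` (per class) | $s$-Gaussian exponent | 1 | bohr$^{-2}$ |
| `tau_rs` | short-range damping scale of $\tau(d) = 1 - e^{-(d/r_s)^2}$ | 0.05 | Angstrom |
| `charge_weight` | weight of the total-charge rows | 0.01 | – |

`d0`, `t0`, `alpha` (and optionally `tau_rs`) are genuine nonlinear
parameters; `optimize_nonlinear()` searches them by coordinate descent
over bounded grids ($d_0, t_0 \in [1,5]$ Å on 9-point log grids,
$\alpha \in [0.2, 2]$ bohr$^{-2}$ on 7-point grids by default) followed
by Nelder–Mead refinement with a bounded evaluation budget.  The
landscape is multi-modal; the grid stage is what makes the refinement
land reliably.

The damping functions are configurable stand-ins: the source defines
$\sigma_a$ (long-range) and a short-range factor only in unavailable
supplementary material.  Here $\sigma_a \equiv 1$ — the Morse variables
already vanish at dissociation, so $P_{aa} \to n_a$ regardless — and
$\tau$ is the smooth switch above, which kills the off-diagonal density
at the united-atom limit.  Both are stored in the model and pluggable.

## Units and numerics

Coordinates are Angstrom at every user-facing boundary; integrals work
in atomic units (1 bohr = 0.529177210903 Å) and energies are reported in
cm$^{-1}$ via 219474.6313632 cm$^{-1}$/hartree.  The Boys function uses
a Taylor branch below $t = 10^{-6}$.  Fits are performed on energies
relative to the dataset minimum; the offset is stored in the model.
Rank-deficient designs (routine with near-duplicate sampled frames)
return the SVD minimum-norm solution with a warning, never a hard
failure.  Monomial orbits are deduplicated by an order-isomorphic
numeric key (falling back to strings when the encoding would overflow),
and a raw-monomial cap (default $5\times10^6$) guards the factorial
blow-up.

## The data generators, and what a green test establishes

`chm_surrogate_pes()` provides analytic stand-ins (per-pair-class Morse
wells, an optional three-body product term, an optional Coulomb tail)
with analytic gradients; `run_nve()`/`run_restrained()` propagate
velocity-Verlet trajectories with seed-deterministic initial velocities
(random directions, center-of-mass motion and angular momentum removed,
scaled to the target kinetic energy).  Restraint presets carry the
published basin-II/III and proton-transfer-saddle parameters.
`prune_select()` substitutes an energy-stratified greedy farthest-point
rule for the externally documented pruning method — it reproduces the
*purpose* (coverage without redundancy), not the exact published
selection.

These surrogates emulate smooth, single-minimum (or harmonically
restrained) sampling.  They do not emulate electronic-structure error,
multireference character, or basin-hopping fragmentation dynamics; a
green test on surrogate data establishes the correctness of the
machinery (invariance, covariance, nestedness, recovery), not the
published accuracy numbers.

For the two-electron benchmark systems the package carries its own small
electronic-structure engine (`qc_energy()`): McMurchie–Davidson
integrals over contracted $s/p$ Gaussians (cc-pVDZ embedded), restricted
Hartree–Fock, and full CI for two electrons — where full CI coincides
with CCSD, so "CCSD/cc-pVDZ" energies for HeH$^+$, H$_3^+$, H$_2$ and He
are exact within the basis.  The engine reproduces the standard
He HF/cc-pVDZ energy ($-2.855160$ hartree) and the published HeH$^+$
binding energy (16,094 cm$^{-1}$) to 0.02%.

The H$_3^+$ reproduction (`h3p_reference_dataset()`) samples an NVE
trajectory at a total energy of 7335 cm$^{-1}$ above the minimum.
Because full-CI gradients would make direct dynamics impractical here,
sampling is two-staged: a Morse surrogate calibrated on the full-CI
equilateral curve seeds a short batch, whose full-CI labels train a
PIP(6) surface; the production trajectory then runs on that
few-cm$^{-1}$-accurate surface with analytic gradients, so the stated
total energy genuinely bounds the sampled region.  The energies that are
fitted are full-CI values at the sampled frames.  Fitting follows the
two-electron-system protocol as printed: per-class-$L$ coefficient
space ($3L$) and no charge rows (the 1/0.01 weight scheme is stated for
the larger systems only); `d0`, `t0`, `alpha`, `tau_rs` are optimized
variationally.  The resulting CHM(2) training RMSE lands below the
published 2.8 cm$^{-1}$, consistent with a sampler that is slightly
smoother than true ab initio dynamics.

## Design choices that were genuinely open

* **Initial velocities** of NVE runs are unspecified in the source;
  class-uniform random directions with rigid-body components projected
  out are used, seeded for determinism.
* **Midpoint splits** return the $n-1$ interior midpoints (no
  extrapolated test points).
* **HeH$^+$ grid upper bound** is not printed; the generator defaults to
  3.0 Å (covers the binding tail) and is configurable.
* **Energy-unit policy**: datasets declare their unit (`hartree` or
  `cm-1`) in the extended-XYZ comment line; everything is converted to
  hartree on load and reported in cm$^{-1}$.
* **Charge-row targets** are residual-zero (populations already sum to
  the electron count), matching either reading of the constraint.

## Known limitations

Only $s$-type densities (one Gaussian per atom); no two-electron matrix
$\mathbf G$; no analytic gradients of the fitted models except the
conventional PIP baseline; the built-in engine is limited to
two-electron correlated calculations, so the many-electron DFT
benchmarks (formamide tautomer gap and barrier) require an external
engine plugged in via `register_qc_engine()`; the exact supplementary
damping functions and pruning rule of the source are replaced by the
documented configurable forms.

## A worked example

```{r example}
typing <- chm_typing(classes = list(H = 1:3), populations = c(H = 2/3),
                     formal_charge = 1L, exponents = c(H = 1))
pes <- chm_surrogate_pes(typing,
                         pair = list(HH = list(De = 0.15, a = 1.8, re = 0.9)))
eq <- chm_config(c("H", "H", "H"),
                 rbind(c(0.5196, 0, 0), c(-0.2598, 0.45, 0),
                       c(-0.2598, -0.45, 0)))
spec <- chm_trajectory_spec(eq, ekin = 3000, timestep = 0.2, steps = 2000,
                            stride = 10, seed = 1)
run <- run_nve(pes, spec)
ds <- chm_dataset(run$configs, run$energies)

fit_pip <- fit_pip_baseline(ds, typing, M = 2, d0 = 2)
fit_chm <- fit_chm(ds, typing, M = 2,
                   chm_nlparams(d0 = 2, t0 = 2, alpha = c(H = 1)),
                   charge_weight = 0)
c(PIP2 = fit_pip$rmse_train, CHM2 = fit_chm$rmse_train)
```

The CHM(2) training RMSE is far below PIP(2) on the same 200 frames —
the "run-ahead" behavior that motivates the model.
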