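# chmpes

Potential energy surface (PES) fitting with permutationally invariant
polynomials (PIPs) and a core-Hamiltonian charge-density model (CHM),
for people who fit analytic molecular surfaces to electronic-structure
energies: small fluxional ions (H3+, CH5+), isomerizing molecules
(formamide), and desk-scale method studies.

## The model

A PES must be exactly invariant under permutations of identical nuclei.
The conventional linear ansatz is a PIP expansion in Morse variables
`y_ab = exp(-d_ab / d0)`,

    E_PIP(R) = sum_i c_i u_i(R),        i = 1..L,

where each `u_i` is a symmetrized monomial orbit of total power `<= M`.
The CHM alternative keeps the Hartree-Fock trace structure with the
two-electron matrix set to zero and one s-type Gaussian per atom:

    E_CHM(R) = Enuc + sum_a P_aa Hcore_aa + 2 sum_{a<b} P_ab Hcore_ab + dE(R)

    P_aa = n_a + sigma_a(R) sum_i c_i^class(a) u_{a,i}(R)
    P_ab = tau(d_ab)        sum_i c_i^pair(ab)  v_{ab,i}(R)
    dE   = sum_i c_i^corr u_i(R)

`Hcore` (kinetic + electron-nucleus attraction) and the overlap `S` are
analytic in the Gaussian exponents `alpha`; `u_{a,i}` / `v_{ab,i}` are
*covariant* PIPs (coset sums over the like-atom permutation group) so
that site quantities relabel consistently — permuting two hydrogens
exchanges `P_11` and `P_22` while the energy is invariant to 1e-10
hartree.  All coefficients are linear; `d0`, `t0`, `alpha` and the
damping scale are nonlinear parameters searched on grids plus
Nelder-Mead.  Soft charge-conservation rows
(`n(R) = sum_ab P_ab S_ab`, weight 0.01) are optional.

The point of the exercise: CHM(M) matches conventional PIP(M+2) accuracy
with 10-20% of the basis, e.g. CH5+ needs L' = 501 CHM coefficients at
M = 4 to approach a PIP(6) fit with 849 terms.

The package also ships a small electronic-structure engine (contracted
Gaussian s/p integrals, restricted Hartree-Fock, full CI for two
electrons == CCSD there, cc-pVDZ embedded) used by the desk-scale
ab initio checks, plus a velocity-Verlet sampler with harmonic
restraints, energy-stratified pruning, extended-XYZ I/O and a CLI
(`genbasis`, `fit`, `predict`, `sample`, `report`).

## Worked example

Fit the same 200 trajectory frames of an H3+-like Morse surface with
PIP(2) and CHM(2):

```r
library(chmpes)
typing <- chm_typing(classes = list(H = 1:3), populations = c(H = 2/3),
                     formal_charge = 1L, exponents = c(H = 1))
pes <- chm_surrogate_pes(typing,
                         pair = list(HH = list(De = 0.15, a = 1.8, re = 0.9)))
eq <- chm_config(c("H", "H", "H"),
                 rbind(c(0.5196, 0, 0), c(-0.2598, 0.45, 0),
                       c(-0.2598, -0.45, 0)))
run <- run_nve(pes, chm_trajectory_spec(eq, ekin = 3000, timestep = 0.2,
                                        steps = 2000, stride = 10, seed = 1))
ds <- chm_dataset(run$configs, run$energies)
fit_pip <- fit_pip_baseline(ds, typing, M = 2, d0 = 2)
fit_chm <- fit_chm(ds, typing, M = 2,
                   chm_nlparams(d0 = 2, t0 = 2, alpha = c(H = 1)),
                   charge_weight = 0)
round(c(PIP2 = fit_pip$rmse_train, CHM2 = fit_chm$rmse_train), 4)
#>     PIP2     CHM2
#> 138.2154   0.0393
```

Both models use the same L = 4 invariant PIP basis (M = 2); the CHM
rearrangement of the same polynomial budget is ~3500x more accurate
here (RMSE in cm^-1) because the `P_ab Hcore_ab` products supply the
multi-body structure PIP(2) lacks.

Basis sizes come from `enumerate_invariant_basis()` /
`chm_basis_set()`:

```r
basis_size(enumerate_invariant_basis(typing, 2))   # L = 4
chm_coef_count(chm_basis_set(typing, 2))           # 10 = 2(L-1) + L
```

## CLI

```sh
inst/exec/chmpes genbasis --config run.json
inst/exec/chmpes fit      --config run.json train.xyz test.xyz --seed 1
inst/exec/chmpes sample   --config run.json --seed 4
```

The JSON run configuration declares the system block (classes,
populations, formal charge), the basis block (`M`, augmentation
patterns, counting convention), the fit block (weights, nonlinear
parameters or `"optimize": true`) and output paths; unknown keys are
rejected with their location.  Datasets are extended XYZ with
`energy=... unit=hartree|cm-1` comment-line tags.

See `vignettes/chm-methods.Rmd` for the model assumptions, counting
conventions, damping/pruning stand-ins, and what the synthetic
generators do and do not emulate.
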