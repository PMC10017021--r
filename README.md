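# qcembed

Projection-based wavefunction-in-DFT embedding with a two-site DMRG
solver, in R.

## What problem it solves, and for whom

Molecules whose chemistry is driven by a *strongly correlated fragment*
— a stretching triple bond, a metal center with a noninnocent ligand —
need multireference wavefunction treatment exactly where single-
reference coupled cluster and plain Kohn–Sham DFT fail. Treating the
whole molecule that way is exponentially expensive. `qcembed` is for
computational chemists who want to study such systems at desk scale:
it partitions a molecule into an active subsystem solved by a
matrix-product-state (DMRG) or determinant-FCI solver and an
environment treated by HF or DFT, glued together by projection-based
embedding.

The pipeline:

1. **Full-system mean field** — restricted HF or KS-DFT (LDA, PBE,
   PBE0, B3LYP with a VWN3/VWN5 switch) on a self-contained
   McMurchie–Davidson Gaussian integral engine (s/p/d shells; STO-3G
   and cc-pVDZ built in).
2. **SPADE partition** — SVD of the fragment-AO block of the
   orthogonalized occupied orbitals; the subsystem split sits at the
   largest singular-value gap, `gamma = gamma_A + gamma_B`.
3. **Concentric localization** — the correlated virtual space is
   truncated to shells concentrated on the fragment: shell 1 is the
   projection of the virtuals onto the fragment AOs, later shells are
   Fock-connected images in the remaining virtual complement.
4. **Projection-based embedding** — embedding potential
   `v_emb = g[gamma_A + gamma_B] − g[gamma_A]` and level-shift
   projector `mu * S gamma_B S` (`mu = 1e6`) form the effective core
   `h_tilde`; an embedded HF (HF-in-DFT) relaxes the subsystem-A
   density under it. With the same functional on both layers the
   assembled energy equals the full-system calculation exactly — the
   test-suite enforces this identity at 1e-6 Hartree.
5. **Correlated solver** — the subsystem Hamiltonian (FCIDUMP
   serializable) is solved by determinant FCI (the oracle) or by
   two-site DMRG: exact `O(norb^2)` sparse MPO, Davidson local solver,
   dynamical block state selection against a preset truncation error,
   CI-inspired warm-up, Fiedler orbital ordering from the
   mutual-information graph, single-orbital entropies and 1-RDMs.

## Worked example

The flagship setup: the nitrile group of propionitrile
(CH3CH2CN) as active subsystem in cc-pVDZ.

```r
library(qcembed)

geom <- fixture("propionitrile")          # standard equilibrium frame
sys  <- build_system(geom, "cc-pvdz")     # 81 AOs
mf   <- run_mean_field(sys, "hf")         # E = -170.96825005 Eh
part <- build_partition(mf, sys, active_atoms = c(3, 4), n_shells = 2)
print(part)
#> <qc_partition: 14 active electrons in 63 orbitals (k = 7 occ + shells 28+28)>
round(part$sigma, 4)
#>  [1] 1.0000 1.0000 0.9992 0.9927 0.9924 0.9913 0.7109 0.1844 0.1772
#> [10] 0.1745 0.0406 0.0270 0.0071 0.0061 0.0028
```

The SPADE spectrum separates cleanly after the seventh singular value
(0.7109 → 0.1844): seven occupied orbitals — two cores, the C≡N sigma
and two pi bonds, the nitrogen lone pair and the C–C bond — belong to
the fragment, giving the 14-electron, 63-orbital active space (7
occupied + 28 + 28 concentric virtuals) used by reference embedded-DMRG
studies of this molecule.

A complete embedded-DMRG calculation at desk scale (minimal basis,
stretched nitrile bond):

```r
g   <- fixture("propionitrile", r_cn = 2.05)
run <- embed_system(g, "sto-3g", active_atoms = c(3, 4),
                    env_level = "b3lyp", wf_solver = "dmrg",
                    sweep = sweep_config(tre_target = 1e-4, m_max = 16,
                                         max_sweeps = 3, warmup = "entropy",
                                         ordering = "fiedler", m_min = 8,
                                         noise = 1e-3, seed = 11))
run$E_total
#> [1] -169.2224            # assembled DMRG-in-B3LYP total energy (Eh)
run$E_A_hf_span - run$E_A_elec
#> [1] 0.356                # correlation recovered inside the span (Eh)
run$assembly$components$level_shift   # mu * tr(Gamma_A P_B), ~1e-9 au
run$solver$entropies                  # single-orbital entanglement entropies
```

(about two minutes on one core; the stretched nitrile bond is strongly
multireference, and the embedded DMRG energy sits 0.36 Hartree below
the embedded HF in the same space)

The same pipeline is scriptable from the command line
(`exec/qcembed run config.txt` with a plain `key: value` file; see
`?read_run_config`).

## Scope

Closed-shell references only. No DMRG-SCF orbital relaxation, no
post-DMRG dynamical correlation, no CCSD solver (the FCIDUMP handoff
is the extension point). The iron-complex benchmark of the original
study needs externally published geometries and an iron basis set, which
are not shipped; the package reproduces the method, the printed
nitrile active-space counts, and the qualitative stretch physics at
desk scale. See `vignettes/embedding-methods.Rmd` for the model, the
parameter choices and their rationale, and known limitations.
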