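---
title: "Projection-based DMRG-in-DFT embedding: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-based DMRG-in-DFT embedding: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Molecules with a strongly correlated fragment — a stretching triple
bond, a transition-metal center with a noninnocent ligand — defeat both
single-reference wavefunction methods (coupled cluster develops
unphysical features along bond breaking) and semilocal DFT (single
determinant, approximate exchange–correlation). Full CI handles the
correlation but scales exponentially; DMRG pushes the tractable active
space to a few dozen orbitals but cannot treat a whole molecule in a
real basis. Quantum embedding reconciles the two scales: a small
strongly correlated subsystem A is solved at the wavefunction level
inside a mean-field description of its environment B.

`qcembed` implements the projection-based flavor of this idea
end-to-end in R: full-system restricted HF or Kohn–Sham DFT, SPADE
partitioning of the occupied space, concentric localization of the
virtual space, a level-shift-projected embedded mean field, and a
two-site DMRG solver (with a determinant FCI oracle) for the embedded
subsystem Hamiltonian.

## The model

**Partition.** A converged full-system calculation gives an AO density
`γ`. The occupied orbitals are rotated by SPADE: the symmetrically
orthogonalized occupied block is restricted to the AO rows of the
active atoms, an SVD of that block rotates the occupied space, and the
split `γ = γ_A + γ_B` is placed at the largest gap of consecutive
singular values. The gap position is a property of the electronic
structure, not a tunable: for the nitrile fragment of propionitrile in
cc-pVDZ the gap sits after seven orbitals, giving the 14-electron
active subsystem.

**Virtual truncation.** The correlated step cannot afford the full
virtual space. Concentric localization keeps, first, the projection of
the virtual space onto the fragment AO block (the rank of the
fragment-AO × virtual overlap — 28 functions for the cc-pVDZ nitrile
fragment), then grows one further shell by applying the full-system
Fock matrix to the previous shell and SVD-selecting its image in the
remaining virtual complement. Two shells give the 63-orbital active
space quoted for propionitrile. Shells are semicanonicalized so
orbital-energy-based diagnostics and preconditioners exist.

**Embedding operators.** The environment acts on subsystem A through

* the embedding potential `v_emb = g[γ_A + γ_B] − g[γ_A]`, where `g`
  collects Coulomb, the functional's exact-exchange fraction, and the
  exchange–correlation potential at the environment level;
* the level-shift projector `μ P_B`, `P_B = S γ_B S`, which pushes
  environment-occupied character out of the variational space. `μ`
  defaults to `1e6`; in the `μ → ∞` limit the subsystems are exactly
  orthogonal. When the embedded density is allowed to explore the full
  AO basis, the finite-`μ` leakage `tr(γ̃_A P_B)` scales as `1/μ²`
  (the second-order penalty-method result) and the energy term
  `μ·tr(γ̃_A P_B)` as `1/μ`.

Both enter the effective core Hamiltonian `h̃ = h + v_emb + μ P_B`.
The embedded mean field (HF-in-DFT) self-consistently optimizes
`γ̃_A` under `F̃ = h̃ + g_HF[γ̃_A]`. In the production pipeline it
relaxes *within the truncated active span* (SPADE occupieds plus
concentric shells): environment-occupied directions are excluded
outright, so the reported level-shift term `μ·tr(γ̃_A P_B)` is pure
numerical residue at the 1e-9 Hartree scale — the magnitude reference
implementations of this method report along dissociation curves. A
full-AO-basis mode is also provided (`embedded_scf(span = NULL)`), in
which the projector actively penalizes environment character and the
`1/μ²` leakage law is observable; on a covalently cut fragment that
leakage puts `μ·tr` at ~1e-7, which is why the span mode is the
default. The embedded wavefunction step uses the second-quantized
Hamiltonian with one-electron part `h̃`, transformed into the embedded
canonical orbitals of the span.

**Energy assembly.** The total energy is assembled as

```
E = E_A[h̃; Ψ_A] + E_DFT[γ_A + γ_B] − E_DFT^elec[γ_A] − tr(γ_A v_emb)
```

with nuclear repulsion carried once (inside the full-density term, so
the subtracted subsystem functional value is electronic-only), and the
level-shift contribution reported separately. The algebraic
bookkeeping left open by this folded form is pinned by an exactness
identity: with the same functional on both sides and the mean-field
path, the assembled energy equals the full-system single-calculation
energy. The test-suite enforces this identity to 1e-6 Hartree for HF,
PBE and B3LYP; the residual (~1e-9) is the finite-`μ` leakage.

**DMRG.** The FCI expansion over orbital occupations
`{|0⟩, |↓⟩, |↑⟩, |↓↑⟩}` is factorized into a matrix product state;
the two-site algorithm optimizes adjacent site pairs with a Davidson
solver against exact sparse-MPO environments, truncating each
decimation by dynamical block state selection: the smallest bond
dimension within `[m_min, m_max]` whose discarded Schmidt weight stays
below the preset truncation error (TRE); an unattainable target keeps
`m_max` and records the overrun as data. The Hamiltonian MPO is
compiled exactly (no compression) in a normal/complementary-operator
form with bond dimension `O(norb²)`, with Jordan–Wigner parities
carried by channel-parity pass-through operators. Orbital orderings
come from the Fiedler vector of the mutual-information graph
Laplacian, produced by a cheap low-`m` pre-run (two-stage pipeline).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mu` | `1e6` | level shift (Hartree-scale penalty); results change `< 1e-6 Eh` over `1e5..1e7` |
| `n_shells` | `2` | concentric virtual shells retained |
| `tre_target` | `1e-6` | preset truncation error per DBSS decimation (the literature setting for embedded runs; full-molecule benchmarks commonly use `1e-5`) |
| `m_min`, `m_max` | `2`, `64` | bond-dimension bounds for DBSS |
| `e_conv` | `1e-8` Eh | sweep-to-sweep energy convergence |
| `noise` | `1e-5` | initial perturbative noise, decaying ×0.1 per sweep, zeroed below `1e-8` |
| SCF convergence | `1e-9` Eh | both full-system and embedded mean fields |

The local Davidson residual tolerance (`davidson_tol`, default `1e-5`)
exploits the quadratic relation between residual norm and eigenvalue
error; criteria at the 1e-7 Hartree level tighten it to `1e-7`.

## What the fixture generator emulates — and what it does not

The built-in geometries (H chains, N₂, water, a water dimer, and
propionitrile with an exactly adjustable C≡N distance) are constructed
from standard equilibrium internal coordinates. They reproduce the
*structure* of the benchmark problems of this field — SPADE splits across a
covalent bond, triple-bond stretching with strong static correlation,
truncated virtual spaces — at desk scale. They do not reproduce
absolute literature numbers that depend on externally published
equilibrium geometries (for propionitrile or for the iron-nitrosyl
complex), which are not shipped here; a green test therefore establishes
method-level correctness (exactness identities, oracle equivalence,
printed active-space counts, level-shift magnitudes, qualitative
stretch behavior), not agreement with the iron-complex reaction
energies, which additionally need an iron basis and cluster-scale
DMRG.

The propionitrile equilibrium frame was chosen once from standard
bond lengths (C–C 1.540 Å, C–CN 1.458 Å, C≡N 1.157 Å, C–H 1.091 Å,
tetrahedral hydrogens, C–C–C 111.5°); the nitrile axis is a coordinate
axis so a requested C–N distance is exact by construction. With this
frame, RHF/cc-pVDZ + SPADE + two-shell concentric localization
reproduces the reference 14-electron/63-orbital active space exactly
(7 occupied at the singular-value gap, 28 + 28 virtuals).

## Numerical choices

* **Integrals.** A self-contained McMurchie–Davidson engine (s, p,
  spherical d; Boys function by downward-stable series plus asymptotic
  branch; Schwarz screening). Validated against quadrature oracles in
  the test-suite; agreement with an independent engine is at ~1e-14
  for S/T/V/ERI elements.
* **DFT.** LDA (VWN5), PBE, PBE0, B3LYP (VWN3 variant by default, the
  Gaussian-style convention; `b3lyp5` selects the VWN5 flavor — codes
  differ here and reference data rarely state the variant, so it is
  a switch rather than a guess). XC energy densities
  are analytic; potentials are obtained by central differences of the
  energy density, which is variationally safe (second-order in the
  converged energy) and keeps every embedding identity exact because
  all code paths share the same functions. The quadrature grid
  (Becke partition, Gauss–Chebyshev radial map, Gauss–Legendre ×
  uniform-φ angular product) is fixed by the geometry alone, so
  embedded and full-system functional evaluations are grid-consistent
  by construction.
* **Degenerate SPADE gaps** raise an error demanding an explicit `k`
  override rather than silently picking a side.
* **Tie-breaks.** Fiedler ordering breaks ties by orbital index and
  fixes the eigenvector sign by its first nonzero component;
  disconnected graphs are ordered per component, concatenated largest
  first. All stochastic elements (warm-up mixing, sweep noise) sit
  behind one integer seed.
* **Warm-up.** The determinant strategy mixes the aufbau determinant
  of the chain with a few seeded particle-conserving double swaps; the
  entropy-guided variant weights frontier-orbital swaps by the inverse
  diagonal gap, standing in for configuration-interaction-based
  entropy estimates, whose production implementations are not publicly
  specified in full. Both reach the same variational fixed point on the
  test fixtures.
* **FCI.** Determinant strings as bitmasks, Slater–Condon rules,
  dense diagonalization. The dense oracle refuses spaces beyond
  ~6000 determinants with a size report — within the oracle's remit
  (every oracle-checked fixture is far smaller), a deliberate
  narrowing of the looser size bound a production CI would have.

## Design decisions that were genuinely open

* The embedded mean field relaxes in the **truncated span** by
  default; the full-AO-basis mode exists for studying the level-shift
  penalty itself. Both reproduce the same-level exactness identity;
  only the span mode yields the reference ~1e-9 magnitude of the
  level-shift term on covalently cut fragments.
* Virtual shells are generated from the **full-system Fock matrix**
  (the cited construction); the correlated step uses the embedded
  canonical orbitals of the span.
* The level-shift report uses the **correlated 1-RDM** back-transformed
  to the AO basis (switchable to the mean-field density), since this
  convention choice is genuinely open in the method definition.
* `e_core` of the active Hamiltonian is zero in the folded assembly;
  nuclear repulsion lives in the full-density DFT term. Any
  convention passing the same-level exactness identity at 1e-6
  Hartree is conformant; this one is the simplest.

## Known limitations

* Closed-shell restricted references only; no open-shell embedding.
* No DMRG-SCF orbital optimization, no post-DMRG dynamical
  correlation, no CCSD solver (the FCIDUMP writer is the extension
  point).
* The dense MPS/MPO machinery carries abelian quantum numbers as
  measured labels, not as block structure; production-scale spaces
  (the 38e/102o iron-complex space) are out of desk reach.
* DFT energies carry ~1e-5 Hartree grid error at default settings;
  all embedding identities are grid-consistent and unaffected.
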