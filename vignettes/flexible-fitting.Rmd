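---
title: "Flexible fitting into model-phased maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible fitting into model-phased maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The refinement model

`xmapfit` refines an atomic model against low-resolution X-ray amplitudes
by alternating two steps. First, the current model phases the data: from
F_calc and |F_obs| it builds a σ_A-weighted 2mFo−DFc map, excluding the
free reflections so that R_free remains an untouched cross-validation
signal. Second, the model is relaxed by Langevin dynamics under

U_total = U_MD + U_EM + U_SS,

where U_MD is a simplified molecular-mechanics potential, U_EM = Σ_j w_j
V(r_j) couples atoms to the density-derived grid potential V, and U_SS
holds secondary structure and stereochemistry. The refitted model phases
the next map. Phases improve as the model improves, which shows up as
falling R factors; the loop stops when the best R_free stalls (< 0.0005
improvement over 15 map iterations), hits a floor, or diverges.

Because only amplitudes constrain the model, the global origin is not
observable — in P1 it is a continuous degeneracy, and a refined model is
typically translated as a rigid body relative to the ground truth while
being internally correct. All recovery metrics are therefore reported
after least-squares superposition; the flag is recorded in every report.

## Map generation

* **σ_A estimation.** Reflections are binned into shells of roughly equal
  working-set counts (≥ 30 each). Within a shell, amplitudes are
  normalized (E = F/√⟨F²⟩) and σ_A is estimated by the moment relation
  corr(|E_o|², |E_c|²) = σ_A², clamped to [0, 0.999]. The amplitude-based
  correlation corr(|E_o|,|E_c|) was tried first and systematically
  underestimates σ_A (for a model with one of two domains displaced it
  gave ~0.2 where ~0.6 is appropriate); because D inherits the
  underestimate, too little D·F_calc is subtracted and the model-bias
  ghost in the map strengthens enough to stall refinement. The intensity
  correlation is exact for bivariate complex-Gaussian structure factors
  and behaves correctly in both limits (perfect model → 1, unrelated
  model → 0). D = σ_A·√(⟨|F_obs|²⟩/⟨|F_calc|²⟩) per shell, which also
  absorbs the overall observed-to-calculated scale. The figure of merit is
  m = I₁(X)/I₀(X) (acentric) or tanh(X/2) (centric), with
  X = 2σ_A|E_o||E_c|/(1−σ_A²).
* **Coefficients.** (2m|F_obs| − D|F_calc|)·exp(iφ_calc); free reflections
  zeroed; unmeasured reflections filled with D|F_calc|·exp(iφ_calc).
  Optional sharpening multiplies amplitudes by exp(+B_sharp s²)
  (s = sinθ/λ); optional kicked averaging rebuilds the map from several
  randomly perturbed copies of the model and averages, which blunts model
  bias.
* **Synthesis.** One FFT over a grid of spacing d_min/3 (Shannon-safe;
  d_min/2 is the hard floor), with Friedel completion so the map is real.
* **Potential.** V(r) = ξ[1 − (Φ′−Φ_thr)/(Φ_max−Φ_thr)], Φ′ = max(Φ,
  Φ_thr). The default threshold Φ_thr = 0 treats negative and zero values
  of the signed difference-style map as featureless solvent: V is flat
  (= ξ) there, so atoms in solvent feel no force. Φ_max is taken per map,
  which makes ξ transferable across iterations.

## Force field and restraints

U_MD is deliberately minimal: harmonic bonds and angles (k_b = 300
kcal/mol/Å², k_a = 60 kcal/mol/rad²) with ideal backbone template
geometry, improper torsions for Cα chirality and peptide-plane planarity
(k = 40), trans-ω restraints (cis where flagged), and a soft-core
harmonic repulsion (k = 25 kcal/mol/Å², radii scaled by 0.85, 1-2/1-3
pairs excluded) instead of Lennard-Jones and electrostatics. Refinement
runs in vacuum. The rationale: at these resolutions the method's essence
is the balance between stereochemical restraints and density steering,
not the fine energetics; the term is isolated behind one interface so a
full force field could be substituted. Side-chain connectivity beyond Cβ,
and unknown residues/ligands, are restrained to their starting internal
geometry (bonds and angles at observed values, 1-4 distances pinned for
unknown residues) — input models are assumed to carry sensible
stereochemistry, which holds for deposited search models and for the
synthetic systems.

Secondary structure is assigned once, on the starting model, and never
updated: a fit cannot change secondary structure, only preserve it (a
known limitation of the approach — a search model with the wrong fold
stays wrong). Geometric assignment uses generous torsion windows (helix
φ ∈ (−110°, −25°), ψ ∈ (−90°, 10°); sheet φ ∈ (−170°, −80°), ψ ∈ (90°,
180°)) with single-residue gaps closed before requiring runs of ≥ 4
(helix) or ≥ 3 (sheet). The generosity is deliberate: with ~0.3 Å of
coordinate noise, strict windows left a seed-dependent fraction
(sometimes < 30%) of genuinely helical residues unrestrained, and those
residues melted into density during fitting. Assigned residues are pulled
toward (−57°, −47°) or (−119°, 113°) with k_ss = 100 kcal/mol/rad², plus
i→i+4 O···N distance restraints (r₀ = 2.9 Å, k = 25) inside helices. The
stiff constants matter: with k_ss = 20 the R factors kept improving while
the model visibly deformed — the soft force field lets helices absorb
density unless the restraints make rigid-body motion the cheapest way to
gain density overlap. A blunt edge of window-based assignment is that
near-helical turn torsions can be swept into a helix run; in the systems
tested this slightly biases turn geometry without affecting recovery.

NCS restraints superpose each copy onto the group consensus and penalize
residual deviations harmonically; rigid-body differences between copies
cost nothing.

## Dynamics and the staged protocol

BAOAB-discretized Langevin dynamics (1 fs steps, friction 5 ps⁻¹,
Maxwell–Boltzmann start, masses as weights) with one force evaluation per
step; γ = 0 reduces to velocity Verlet and conserves energy to < 0.1%
over 1000 half-fs steps. 0 K stages run L-BFGS minimization with analytic
gradients. The force evaluation and integrator are compiled (Rcpp); the
reference R path implements identical formulas and the suite asserts
agreement at 1e−12 — the compiled path exists purely because the protocol
needs ~10⁴–10⁵ steps per map iteration.

The default schedule follows the staged protocol: when the model is
suspected to be far from the target (> ~2 Å r.m.s.d.), couple only the
backbone at ξ = 0.1 so the fold stays mobile in the still-noisy map (8
map iterations), then all heavy atoms at ξ = 0.3 (12) and ξ = 0.5 (25),
then cool to 0 K (10 minimization iterations). Data worse than 4 Å get a
simulated-annealing stage (600→450→300 K) before cooling. Two schedule
choices were settled empirically on synthetic systems and then frozen:

* **Re-phasing cadence.** The map is regenerated every ~1 ps (1000
  steps). Long excursions against a stale map (20–25 ps) consistently
  overfitted the model into its own phase-bias ghost; frequent re-phasing
  keeps the fit quasi-static and was decisively more stable.
* **Convergence rule.** Stop when best R_free improves by < 0.0005 over
  15 consecutive map iterations (the loop spans many cheap iterations, so
  patience is high), on an absolute floor of 0.02, or when R_free exceeds
  the best by > 0.05 for that long (divergence guard). The best-R_free
  model is always the one returned.

## The synthetic test system

The generator emulates a controlled refinement experiment: an
ideal-geometry poly-alanine (backbone + Cβ) target in one of three
architectures (helix-hairpin, two-domain hinge, extended), boxed in a P1
cell with 12 Å solvent padding and uniform B = 20 Å²; amplitudes are
|F_calc(target)| truncated at d_min (optionally smoothed by
exp(−B_smooth s²) with B = 35 Å² to mimic weak low-resolution data, and
optionally log-normally perturbed); the search model opens the hinge
symmetrically (each arm ± half the hinge angle about the plane-normal
axis through the hinge Cα — a one-sided swing of a 15-residue arm at 30°
leaves the 2–6 Å band the generator targets) plus 0.3 Å r.m.s. jitter.
P1 keeps symmetry out of the recovery path; symmetry expansion is
exercised separately in the scattering tests. Cβ-only side chains keep
the tests at desk scale and focus on backbone placement, which is what
low-resolution data can actually determine. What passing these tests does
**not** show: behavior under experimental noise models, bulk solvent,
lattice disorder, real side-chain packing, or non-P1 origin fixing.

Default study conditions (frozen): 2 × 15 residues, 30° hinge, d_min =
4 Å, noise-free amplitudes, 5% free set. Under these conditions all five
generator seeds recover from ~3.4 Å to < 0.5 Å superposed backbone
r.m.s.d. with R_free dropping by ≥ 0.35; the 5 Å/B = 35 Å² variant
recovers to ~0.8 Å.

## Numerical choices and degenerate inputs

* Structure factors: direct summation is the production path at toy
  scale; the FFT-gridded path (atoms splatted as the real-space mates of
  their Cromer–Mann Gaussians, blur B added then removed in reciprocal
  space) agrees to ~1e−4 relative and exists for large models. The
  Cromer–Mann constant term must be splatted with zero intrinsic width —
  giving it a small artificial width loses ~0.02 e of nitrogen's c =
  −11.5 at typical resolutions, visible as a fixed amplitude error.
* Scaling: two-parameter k·exp(−B_overall s²) least squares (log-linear
  start, BFGS polish), fitted on the working set only. No bulk-solvent
  model: absolute R factors on real data will sit above values from a
  full pipeline, uniformly across resolution.
* Trilinear map interpolation with the analytic gradient of the
  interpolant (identical to finite differences of the eight grid
  neighbors); periodic wrap applies to map lookup only, never to bonded
  terms.
* Degenerate inputs: flat maps are rejected in potential conversion;
  overlapping atoms (< 0.1 Å) get a capped repulsion force and a warning;
  duplicate reflections merge if consistent and error otherwise; an empty
  free set makes R_free NA with a warning; minimization that fails to
  improve returns the start point, flagged.
* Every stochastic element (free flags, velocities, thermostat noise,
  kicks, jitter) is seeded from one master seed; refinement runs are
  bit-reproducible.

## Known limitations

Vacuum force field without electrostatics or attractive packing; no bulk
solvent; no ADP (B-factor) refinement — B factors stay at input values;
secondary structure frozen at iteration 0; binary MTZ must be converted
to hkl text externally; automatic symmetry expansion only for P1 (other
space groups accept user-supplied operators); rotamer-aware side-chain
fitting out of scope. Problem sizes used throughout the tests (34
residues, ~2000–4000 reflections, 10³–10⁵ MD steps per stage) were chosen
to make the full study reproducible on a single CPU in minutes.
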