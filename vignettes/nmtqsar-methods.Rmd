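---
title: "GA-MLR QSAR modeling of Hs-NMT inhibition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-MLR QSAR modeling of Hs-NMT inhibition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

Human *N*-myristoyltransferase (Hs-NMT) attaches a myristoyl group to the
N-terminal glycine of substrate proteins and is a drug target in oncology and
anti-parasitic programs. Large series of nitrogen heterocycles (mostly
sulfonamide-linked pyrazoles, pyridines and quinolines) have been screened
against it, with IC50 values spanning eight orders of magnitude. `nmtqsar`
implements a complete quantitative structure–activity relationship (QSAR)
workflow for such data: from SMILES to charged 3D conformers, to a pool of
interpretable 3D descriptors, through objective and genetic-algorithm feature
selection, to multiple-linear-regression (MLR) models validated with the full
internal/external statistics battery and an applicability domain.

Activities are modeled as pIC50 = −log10(IC50 in mol/L); an IC50 of 1 µM is
pIC50 6. The final models are ordinary least squares fits

pIC50 = b0 + Σ bi · di

on five descriptors chosen by a genetic algorithm, and the package ships the
two published five-descriptor models (`published_model("model1")`,
`published_model("model2")`) for prediction.

## Conformer preparation

`prepare_3d()` builds one conformer per molecule:

1. distance-geometry embedding (ETKDG, via the shipped Python/RDKit helper)
   with explicit hydrogens, seeded by `embed_seed` — the whole chain is
   bit-for-bit reproducible for a fixed seed;
2. largest-fragment selection for salt/multi-fragment SMILES (logged);
3. MMFF94 steepest-descent minimization, at most `max_steps` steps
   (default 1000), through OpenBabel;
4. MMFF94 partial charges, which sum to the net formal charge.

A single low-energy conformer is a modeling choice, not a claim that the
molecule is rigid: the frequency descriptors below are either purely
topological (bond counts) or use short-range geometric shells that are stable
across low-energy conformers of these scaffolds. Protonation states are taken
as written in the SMILES (neutral amines stay neutral); we do not enumerate
tautomers or charge states.

## Descriptors

`per_atom_sasa()` implements Shrake–Rupley solvent-accessible surface area:
each atom's Bondi van der Waals sphere is inflated by the probe radius
(1.4 Å, water) and covered with a deterministic Fibonacci-lattice point set;
the accessible fraction of points times the sphere area is the atom's SASA.
`n_points = 960` per atom is the package's mapping of the "dot density 4"
accuracy level of molecular-surface tools. One quadrature cell at this
density is ~1.5% of a buried carbon's exposed area, so *per-atom* values at
the default density are accurate to a few percent (molecular totals are far
tighter, as cell errors cancel); validation tests therefore compare per-atom
values against an independent dense point-rejection grid at
`n_points = 10000`, where agreement is within 1%.

The five published model descriptors:

* `all_HASA2` — SASA summed over atoms with MMFF94 partial charge in
  [+0.10, +0.20] (Å²): exposed mildly positive surface.
* `C_AbSA` — SASA summed over carbon atoms (Å²). The descriptor's source
  description is ambiguous (it is also glossed as a SASA-minus-molecular-
  surface difference); this package implements the carbon-sum reading, which
  matches the descriptor's name and its interpretation as "surface area due
  to carbon atoms".
* `fringNH2A` — number of H atoms whose nearest ring nitrogen lies in the
  spatial shell [1.0, 2.0) Å. A hydrogen with a ring N closer than 1 Å is
  excluded; the min-distance formulation enforces the exclusion
  automatically. An N–H hydrogen on an azole ring (≈1.01 Å) qualifies.
* `flipoH3B` — number of H atoms whose nearest lipophilic atom is exactly
  3 bonds away (shortest topological path; hydrogens at 1–2 bonds from any
  lipophilic atom are excluded by the same minimum rule).
* `fNH4B` — number of H atoms whose nearest nitrogen is exactly 4 bonds away.

Distance shells are half-open, [lo, hi), so adjacent bins never double-count;
"exactly k bonds" is the shortest path in the bond graph with orders ignored.
Lipophilic atoms (the source never defines them) follow standard
pharmacophoric typing: carbons not bonded to N, O or a formally charged atom,
halogens, and divalent sulfur — configurable via `lipophilic_atoms()`.

`generate_descriptor_pool()` embeds these five in parametric families with a
documented name grammar (charge-binned SASA over 0.1-wide windows spanning
[−0.5, +0.5]; per-element SASA; H-frequency shells over elements/classes in
bond and Euclidean space; atom counts), yielding a realistic pool of >100
columns for selection experiments. The full commercial descriptor catalogues
(tens of thousands of columns) are out of scope.

## Feature selection

`ofs_filter()` performs objective (unsupervised) selection in three passes:
exact constants; near-constants whose modal value covers ≥95% of molecules;
then greedy pruning of pairs with |Pearson R| > 0.90. In a correlated pair
the column less correlated with the response is dropped (when a response is
given); exact ties — duplicated columns — fall back to dropping the later
column of the pair, a deterministic, locale-independent rule.

`ga_mlr_search()` performs subjective selection: a fixed-cardinality subset
genetic algorithm (tournament selection of size 2, uniform crossover repaired
to the model size, point mutation swapping one member, elitism of 1) whose
fitness is leave-one-out Q². Q² rather than R² penalizes overfitted subsets.
Fitness values are cached per subset, so on small pools a long run approaches
complete enumeration; `exhaustive_mlr_search()` provides that enumeration
both as a user tool and as the test oracle. Defaults (population 200, 10,000
generations) mirror the published workflow's settings; the validation suite
uses smaller, planted problems (pools ≤ 20, subsets of 3, n = 60–120) where
the GA provably matches enumeration.

The model size itself comes from `breaking_point()`: run the search at sizes
1, 2, 3, … and find the elbow of the best-Q² curve — the smallest size after
which the marginal gain drops below 25% (configurable) of the preceding gain.
On the full published dataset this elbow sits at five descriptors.

## Validation statistics

`validation_report()` assembles, for one training/external split:

* fitting: R²tr, R²adj, RMSEtr, MAEtr, RSStr, s, F, Lin's CCC, Friedman
  lack-of-fit (smoothing parameter d = 0.5 by default; the exact d used by
  the original modeling tool is unpublished, so LOF is reported but not used
  as an acceptance rule), and Todeschini's multivariate K correlation (Kxx
  of the descriptor block, ΔK = Kxy − Kxx; a single-descriptor block has
  Kxx = 0 by convention);
* leave-one-out CV via the hat-matrix identity e_loo = e/(1−h) (an explicit
  refit loop backs any unit-leverage point, and serves as the test oracle);
* leave-many-out CV: 30% excluded per repetition, 2000 repetitions by
  default, per-repetition Q² referenced to the training-half mean of that
  repetition;
* Y-randomization: refits on permuted responses (default 2000, seeded);
  a sound model shows mean scrambled R² near p/(n−1) and negative scrambled
  Q²;
* external statistics: RMSEex, MAEex, PRESSext, R²ex (squared Pearson),
  Q²F1 (training-mean reference), Q²F2 (external-mean reference), Q²F3
  (per-observation MSE against training variance), CCCex, and the
  Golbraikh–Tropsha block (origin-regression slopes k, k′, the constrained
  R²o and R′²o, and r²m = r²(1 − √|r² − R²o|));
* the Williams applicability domain: leverages against the training design,
  h* = 3(p+1)/n, residuals standardized by s with a ±3 outlier cutoff.

`acceptance_check()` evaluates the complete published rule set (R²tr ≥ 0.6,
Q²loo ≥ 0.5, Q²LMO ≥ 0.6, R² > Q², R²ex ≥ 0.6, RMSEtr < RMSEcv, ΔK ≥ 0.05,
CCCex ≥ 0.80, all Q²-Fn ≥ 0.60, r²m ≥ 0.5, the k/k′ origin-regression
conditions and |R²o − R′²o| < 0.3) and reports per-rule verdicts.

## The exchange workflow

`run_exchange_workflow()` encodes the 50/50 exchange strategy: split the
dataset into two equal halves (default: sort by activity, assign alternately,
so both halves span the full 0.97–8.70 pIC50 range; a seeded random split is
available), select and fit on half A, validate externally on half B, then
exchange the halves and repeat. Agreement of the two arms — ideally identical
descriptor sets, reported as `consensus` — is the workflow's internal
replication check. The two shipped models are the two arms of that strategy
on the full 309-compound dataset (155/154 molecules); which arm produced
which model is not asserted.

## What the synthetic generator emulates — and what it does not

`gen_descriptor_dataset()` produces the statistical situation the selection
machinery faces after descriptor calculation: standard-normal descriptor
columns, a sparse linear signal y = X[, planted]·β + N(0, σ²), and the
degeneracies objective selection must remove (constants, 95%-modal
near-constants, exact or jittered collinear copies). Ground truth is carried
alongside so selection accuracy and coefficient recovery can be scored
directly. It does **not** emulate real descriptor pools' heavy tails,
block-correlation structure, or integer-valued frequency columns, nor any
structure–activity nonlinearity; passing the planted-recovery tests shows the
search and validation machinery is correct, not that five descriptors suffice
for any particular assay. The hand-enumerable fixtures (`toy_molecules()`:
methane, water, ammonia, cyclohexane, pyrrole, n-propylamine, a hand-built
Cl–O–O–H chain, and the ten published example compounds with their IC50s)
pin the descriptor semantics where counts can be derived by hand.

## Numerical choices and degenerate inputs

* OLS uses a Cholesky solve of the normal equations with an explicit
  singularity guard; rank-deficient subsets raise an error in `fit_ols()`
  and receive fitness −∞ in the GA (never ranked above finite candidates).
* LOO leverage numerically at 1 triggers an explicit refit for that point.
* Coefficient uncertainties are two-sided 95% t-interval half-widths, the
  "(± …)" convention of the published equations.
* Quadrature: SASA points are deterministic; per-atom SASA is exactly
  invariant under atom reindexing and invariant under rigid rotation up to
  the quadrature resolution (tests allow 0.5% at 10k points).
* Breaking-point analysis warns (rather than fails) when Q² dips between
  sizes, and returns the largest size with a warning when no elbow exists.
* Degenerate GA cases: a model size equal to the pool returns the single
  full subset; `choose(pool, size)` above the enumeration budget is an error
  in the exhaustive search.
* Sub-seeds for all resampling (LMO, scrambling, GA, splits) are taken from
  explicit `seed` arguments; no global RNG state is consumed silently.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run the statistical guarantees
at desk scale, chosen to exercise the machinery decisively: 50 planted
selection instances (n = 60–120, pools of 20, subsets of 3) for
GA-vs-enumeration agreement; 20 instances (30 × 3) for the LOO identity; 500
replicates (100 × 5) for coefficient-recovery calibration; n = 200, p = 5
pure-noise data for the Y-scrambling floor; and a 120-molecule planted
dataset for the end-to-end exchange workflow. The published full-dataset
statistics (R²tr = 0.788 etc.) require the complete 309-compound appendix
and the original descriptor software, so they are audited instead through
their internal identities (e.g. RMSEtr = √(RSStr/155), s, R²adj, RMSEcv,
RMSEex) and through `acceptance_check()` on the published statistic blocks.

## Known limitations

* One conformer per molecule; conformer-ensemble descriptors are out of
  scope.
* The lipophilic typing and the C_AbSA reading are declared conventions
  where the source is silent or self-contradictory.
* Friedman LOF depends on an unpublished smoothing parameter; comparisons
  across tools should use the sums of squares, not LOF.
* The GA's operator set reproduces the published search's *role*
  (Q²-fitness subset selection), not the original tool's exact operators,
  which are unpublished.
* Pharmacophore modeling and any use of crystal structures are outside this
  package's scope.
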