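---
title: "Methods: descriptors, model cascade and synthetic libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, model cascade and synthetic libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`benzoqsar` predicts benzodiazepine activity at the GABA-A receptor
(log 1/c, c the molar IC50 for displacing [3H]-diazepam) from five
two-dimensional molecular descriptors, and re-builds such models from data
with a partial-least-squares cascade.  This vignette is the package's
account of the science: what is computed, which conventions were fixed
where several were defensible, and what the synthetic test data can and
cannot show.

## Molecular graphs

SMILES strings are parsed and canonicalised by Open Babel (via ChemmineOB);
the package builds its own heavy-atom graph from the returned molblock.
Counter-ions and solvates are removed by keeping the largest covalent
fragment, stereochemistry is discarded (every descriptor is 2D), and
implicit hydrogens are assigned from standard valences adjusted by formal
charge.  Open Babel returns kekulised bonds, so aromaticity is re-perceived
with an explicit rule applied uniformly to every molecule: a 5- or 6-ring
is aromatic when every ring atom offers a p-orbital (a ring double bond
contributes one π electron; N, O or S with only single bonds contributes a
lone pair, two electrons; an exocyclic double bond or a saturated carbon
disqualifies the ring) and the π count satisfies Hückel's 4n+2.  This
covers the chemistry of the benzodiazepine space — benzo, pyridine,
pyrrole, imidazole, triazole and thiophene rings — and deliberately does
not attempt exotic cases (azulenes, mesoionics).

## The five descriptors

**π-bond-order sum (`h_log_pbo`).**  Conjugated subsystems are the
connected sets of atoms carrying double/triple bonds plus adjacent
lone-pair donor heteroatoms.  Each subsystem gets a simple Hückel matrix
(α = 0, β = 1 for C–C; heteroatom h and k parameters after the standard
van-Catledge-style tables, with a documented 0.7 fallback for
unparameterised pairs); the lowest orbitals are filled with the subsystem's
π electrons (degenerate frontier shells fractionally, with an open-shell
warning) and the bond order is p_uv = Σ_k n_k c_uk c_vk.  An isolated
double bond therefore gets exactly p = 1 and benzene's ring bonds 2/3 —
both are frozen test oracles.  The descriptor is Σ_bonds log(1 + p) under
the **natural-log convention**; the printed description of the descriptor
does not identify the base, so it is fixed here, documented, and exposed as
`log_base` (the ethylene value is ln 2 ≈ 0.693 rather than 0.301).
Absolute agreement with closed-source implementations is not claimed.

**Kier flexibility (`kier_flex`).**  κ₁ = (A+α)(A+α−1)²/(P₁+α)²,
κ₂ = (A+α−1)(A+α−2)²/(P₂+α)², flexibility = κ₁κ₂/A, with A the heavy-atom
count, P₁ the bond count, P₂ the two-bond path count and α the sum of
r_i/r(Csp3) − 1 over Kier's hybridisation-dependent covalent radii
(aromatic atoms treated as sp2; halogens tabulated as sp3).  Propane gives
exactly 2 and cyclohexane 150/36 · 80/36 / 6 ≈ 1.5432; molecules with
A < 3 or P₂ = 0 return 0 with a warning.

**Surface-area partitions.**  Per-atom approximate van der Waals surface
areas follow Labute's connection-table construction: each heavy atom is a
sphere of its vdW radius minus one spherical cap per neighbour, the cap
height computed from an ideal bond length clamped to the admissible range
[|R_i−R_j|, R_i+R_j]; implicit hydrogens contribute capped spheres folded
into their heavy atom.  Radii are Labute's published values (so that
magnitudes are on the scale the activity equation's coefficients expect —
roughly 300 Å² total for a drug-sized molecule); ideal bond lengths come
from a standard table by element pair and bond order, with a
covalent-radius-sum fallback.  Three partitions of this common VSA are
descriptors:

* `q_vsa_hyd` — VSA of *hydrophobic* atoms, |q| ≤ 0.2 elementary charges,
  where q is the Gasteiger–Marsili PEOE partial charge (8 damped iterations,
  damping ½ per cycle, implicit-hydrogen charges folded into the heavy
  atom).  The 0.2 threshold is the conventional hydrophobic/polarised split
  and is exposed as `hyd_threshold`.
* `slogp_vsa7` — VSA of atoms whose Wildman–Crippen atomic logP
  contribution falls in (0.25, 0.30].  Atom classes are assigned
  first-match-wins over the published ordered class table (values taken
  verbatim from the published parameterisation); hydrogens fold their class
  value into the carrying atom.  The full ten-bin family is implemented;
  its sum equals the total VSA exactly, which the tests assert at 1e-6
  together with the hydrophobic/polarised partition identity.  Bin
  *boundaries*, not bin names, are normative — other toolkits number the
  same intervals differently.
* `vsa_pol` — VSA of *polar* atoms, defined as atoms that are
  simultaneously hydrogen-bond donor and acceptor (hydroxyl O, amine N–H);
  amide and nitro nitrogens, pyrrole-type ring N–H and pure acceptors are
  excluded.  "Polar atom" is ambiguous in isolation; the donor-and-acceptor
  reading is the pharmacophore-typing convention and is fixed here.

## The published activity equation

`predict_published()` evaluates, exactly as printed,

log 1/c = 9.45416 + 0.77505·h_log_pbo + 1.24990·kier_flex −
0.03382·q_vsa_hyd − 0.01507·slogp_vsa7 − 0.03849·vsa_pol.

Predictions are binned low [5.80, 7.00), medium [7.00, 8.00), high
[8.00, ∞).  The printed bin edges are two-decimal labels ("5.80–6.99");
half-open real intervals make unrounded predictions bin unambiguously, and
the run report additionally shows predictions rounded to 2 dp to match the
conventional presentation.  Values below 5.80 lie outside the span of the
underlying training activities and are reported `out_of_range` with a
warning rather than silently extrapolated.

## Model-building cascade

1. **Curation.**  Hashed linear-path fingerprints (all simple paths up to 7
   bonds, canonical direction, 2048 bits — parameters exposed) feed
   Tanimoto similarities; a molecule whose *average* similarity to the rest
   of the dataset falls below 0.3 is removed.  Two empty fingerprints
   compare as 0 with a warning.
2. **Split.**  "Similarity and activity sampling" is implemented as joint
   quantile stratification — activity quartiles crossed with a median split
   on average similarity — each stratum contributing ≈ 20% to the test set
   under a fixed seed.  Strata with fewer than two members trigger a
   documented fallback to activity-only stratification.  The activity
   extremes are pinned to the training set so the test range is interpolative.
3. **Selection.**  Keep descriptors with |Pearson r| ≥ 0.5 to the activity;
   then repeatedly drop, from the worst-correlated surviving pair with
   mutual |r| > 0.7, the member with the weaker activity correlation.  The
   report lists every candidate with its correlation and fate.
4. **PLS fit.**  PLS1 by NIPALS on centred, unit-variance-scaled
   descriptors, coefficients back-transformed to the original units.  The
   latent-variable count is not specified by the source procedure; the
   default chooses the count maximising leave-one-out xr², capped at the
   descriptor count.  With full rank the fit coincides with least squares,
   which gives the exact-recovery guarantee used in testing.  An
   independent PLS implementation (mixOmics) serves as a cross-check oracle
   in the test suite, never as the implementation.
5. **Validation.**  Training and test r² are reported as the squared
   Pearson correlation of predicted vs observed (the correlation-plot
   convention); because PLS predictions are not guaranteed to make this
   coincide with explained variance, 1 − SS_res/SS_tot is reported
   alongside.  RMSE is √mean(squared error).  LOO xr² refits the model
   without each sample.  Outliers are molecules deviating by strictly more
   than 2.5 log units; the published rule reads "higher than", but an
   under-predicted compound is as suspect as an over-predicted one, so the
   default uses absolute deviation with `direction = "over"` available for
   the literal reading.
6. **Applicability domain.**  A prediction is in-domain when the molecule's
   average Tanimoto similarity to the whole modelling dataset is ≥ 0.5.
   Curation (0.3) and domain (0.5) thresholds are deliberately distinct,
   separately configurable parameters.  Because the fingerprint is not the
   (unnamed) one used by closed-source tools, absolute similarity values
   are implementation-relative; the workflow's comparisons are internal and
   self-consistent.

## Synthetic libraries

No public benzodiazepine activity table accompanies the workflow, so the
generator builds one.  Molecules are assembled from four scaffold families
— classic 1,4-benzodiazepin-2-one, triazolo-, imidazo- and
thieno-triazolo-fused — with substituents at the potency-determining
positions: C7/C8 (H, F, Cl, Br, NO2, CF3, NH2, OMe), the pendant phenyl's
ortho position C2′ (H, F, Cl, Br, NO2, CH3, OMe), N1 (H, methyl, ethyl,
n-propyl, 2-hydroxyethyl, diethylaminoethyl) and C3 (H, OH, CH3).  All are
features of real classic or designer benzodiazepines (3-OH metabolites,
7-amino metabolites, flurazepam's N1 chain, 2-ethyl thienodiazepines).
Planted activities are the published equation evaluated on each molecule's
own computed descriptors, plus N(0, σ²) noise; the default σ = 0.3 puts
fitted training r² in the commonly reported 0.7–0.95 regime and is a
configuration choice, not a literature value.  Libraries are pure functions
of (n, seed, mode, parameters); the manifest written next to every dataset
suffices to regenerate it exactly.  Noisy activities leaving the 6.0–9.0
span are redrawn (default), clipped or kept, per configuration; redrawing
keeps the span literal without skewing residuals elsewhere.

Two modes emulate the two dataset shapes of the workflow:

* **`train`** emulates a curated literature SAR series confined to the
  classic scaffold.  A uniform draw from the combinatorial space would be
  scientifically wrong here in an instructive way: when the activity is an
  exact linear function of all five descriptors and is confined to a
  three-log-unit window, a uniform draw leaves each descriptor's
  *marginal* correlation with activity far below the 0.5 selection
  threshold (the range restriction even induces compensating, negatively
  aligned contributions), and the cascade would reject the very descriptors
  that generate the data.  Real curated series do not look like uniform
  draws — decades of analogue synthesis produce datasets in which each
  reported descriptor carries standalone signal, which is precisely why a
  univariate contingency filter is usable at all.  The train mode therefore
  selects its n molecules by a seeded simulated-annealing subset search
  over the enumerated space (~3000 combinations, of which ~1600 have
  noiseless activity inside 6.0–9.0), maximising the weakest
  sign-aligned descriptor–activity correlation while penalising any mutual
  descriptor correlation above 0.65 — the documented correlation structure
  of such series (each descriptor |r| ≥ 0.5, mutual ≤ 0.7, with 0.65 the
  largest mutual value reported).  The search runs on precomputed
  descriptor matrices with incrementally updated sufficient statistics
  (200,000 proposals by default, ~20 s) and is a pure function of the seed.
* **`screen`** emulates a diverse monitoring set of designer
  benzodiazepines: a plain seeded uniform draw across all four scaffold
  families, used for prediction, binning, census and applicability-domain
  demonstrations.

What passing tests on these libraries show — and what they do not: the
pipeline provably recovers a five-descriptor linear ground truth from its
own descriptors under realistic noise, the selection cascade's guarantees
hold on adversarially collinear inputs, and every conservation identity of
the descriptor code holds across the generated chemistry.  They do not
show that real [3H]-diazepam displacement data is linear in these five
descriptors, nor that the descriptor values match any proprietary
implementation numerically; synthetic structures are surrogates and are
never claimed to match any study's compounds.

## Problem sizes and numerics

The shipped tests and the acceptance script run the pipeline at the study
scale (libraries of 67–100 molecules; 76 with an 80/20 split; 50 noise
seeds for the acceptability-threshold simulation, one annealed molecule set
with independent noise draws, since the molecular library and the noise
process are separate sources of randomness).  Catalog featurisation (~2
minutes for ~3000 molecules, memoised per session) dominates the cost of
the first train-mode library.  Key numeric conventions: path-hash modulus
below 2^26 so all hash arithmetic is exact in doubles; cap heights and bond
lengths clamped to geometric admissibility; PEOE damping ½ per cycle for 8
cycles (geometric tail < 1e-2 of the first transfer); Hückel occupation
tolerance 1e-9 for degeneracy detection; selection ties broken toward the
descriptor with the stronger activity correlation; zero-variance
descriptors dropped with a warning before PLS; the split's extreme pinning
takes precedence over exact 80/20 counts (±1 molecule).

## Known limitations

* Descriptor absolute values are conventions-dependent (log base, radii,
  charge model, polar typing); cross-software comparisons should be made at
  the level of workflow behaviour, not raw descriptor values.
* The aromaticity model is scoped to the benzodiazepine chemical space.
* The Wildman–Crippen typer implements the classes reachable by C, N, O, S,
  halogen and H chemistry; atoms outside the tables fall to the published
  element wildcard class with a warning.
* Hückel parameters for heteroatom pairs outside the tabulated set use a
  neutral fallback; triple bonds contribute their orthogonal π bond as a
  localised p = 1.
* The train-mode generator's correlation shaping means its libraries are
  not independent draws from the scaffold space; screen mode provides those.
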