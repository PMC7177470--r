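---
title: "Enrichment-factor-optimized consensus scoring over monomers and frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment-factor-optimized consensus scoring over monomers and frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsensemble)
```

# Scope and model

`vsensemble` analyzes the score matrices produced by ensemble docking
against an oligomeric target: one row per ligand of a binary-labelled
screening library, one column per (scoring function, monomer chain, MD
frame, normalization) combination. The package's central object is the
**consensus model**, a linear equation

$$c(\ell) = s_1(\ell) + w_2\, s_2(\ell) + \dots + w_k\, s_k(\ell), \qquad k \le 4,$$

over *oriented* score columns (every column negated as needed so that
larger always means better), whose free coefficients are chosen to
maximize the **enrichment factor** at a fixed top fraction $f$:

$$\mathrm{EF}_f = \frac{a / \lceil fN \rceil}{A / N},$$

with $a$ the actives among the $\lceil fN \rceil$ top-ranked ligands,
$A$ the total actives, and $N$ the library size. The default is
$f = 0.01$ (EF 1%), the fraction a prospective screen would actually
purchase and assay. EF 1 is chance; $\min(1/f,\ N/\lceil fN\rceil)$ is
the ceiling, which a 5300-ligand, 53-active library reaches at exactly
100.

The leading coefficient is fixed at $+1.0$: orientation absorbs the
sign, every model is identifiable up to overall scale (EF is invariant
under strictly increasing transforms of the consensus values), and the
reported equations read like the consensus equations conventionally
printed in screening papers.

## Tie handling and missing scores

EF counts actives inside a sharp cutoff, so ties at the cutoff value
matter. All rankings here are **pessimistic**: at equal consensus value
inactives precede actives, then ties break by lexicographic ligand id.
Reported enrichment therefore never benefits from arbitrary tie order,
and the reported EF is a lower bound over all tie resolutions. A ligand
missing any score used by a model (a docking failure) is ranked last.

# The EFO optimizer

EF is piecewise constant in the coefficients — gradients are useless
and plateaus are everywhere — so coefficients are fitted by a
gradient-free cyclic coordinate search:

- Each free coefficient is scanned over $\tan\theta$ for $\theta$ on a
  uniform 177-point grid in $(-88^\circ, 88^\circ)$, scaled by the
  ratio of the leading and scanned columns' standard deviations. The
  tangent parameterization covers the whole real line with resolution
  concentrated where the scanned column's contribution is comparable to
  the leader's; the sd scaling makes the grid meaningful for columns on
  arbitrary units.
- Coefficients are swept cyclically until a full sweep leaves EF
  unchanged, at most 10 sweeps, from 5 starts: all-zero, equal
  per-column contribution, and 3 seeded random draws. (With a single
  free coefficient one full scan already is the global grid optimum, so
  multi-starts are skipped.)
- On EF plateaus two deterministic secondary criteria order the tied
  candidates: higher **mean reciprocal rank of the actives**, then
  lower coefficient L1 norm. This makes the whole fit reproducible to
  the byte for a fixed seed.

Constant columns are rejected before any search; they cannot change a
ranking and would make the sd scaling degenerate.

One property of this objective is worth stating plainly: near its
optimum, EF 1% is *flat*. On synthetic campaigns with a planted
complementary pair (below), the fitted coefficient recovers the
generative ratio without bias, but its seed-to-seed spread is set by
the width of the top EF plateau, not by the grid resolution — an
independent dense-grid scan of the same tie-broken objective scatters
exactly as much. Point estimates of individual coefficients should be
read with that in mind; the selected column subset is far more stable.

## Combination search

`search_combinations()` enumerates subsets of sizes 1 and 2
exhaustively and grows sizes 3 and 4 by beam search (default width 50)
from the best smaller subsets. Admissibility constraints — minimum
distinct chains, minimum distinct frames, maximum size — implement the
protocol's model rules. Subsets that cannot reach the constraint even
after growing to the size cap are discarded before any coefficient
fitting; subsets that merely do not *yet* satisfy it are fitted so the
beam can grow through them, but only satisfying models are returned.
This keeps the beam well-seeded (a strong same-chain pair may be the
route to the best three-column, two-chain model) while guaranteeing
constraint soundness of everything reported.

## Validation

`validate_model()` repeats, five times by default: a stratified 70/30
split (preserving the ~1% active fraction — an unstratified 30% test of
a 53-active library too often contains too few actives for EF 1% to
mean anything), a coefficient refit on the training part with the same
column subset, and an EF evaluation on the held-out part. The headline
coefficients are refit on the full set (`ef_full`), with the per-repeat
and mean test EFs always attached — training, full-set and held-out
numbers are all exposed rather than collapsed into one figure. A test
split drawn without actives is redrawn with the next seed offset and
logged.

# The progressive protocol

Three stages, each a pure function of (pools, config, seed):

1. **Per monomer, per frame** — best single-column EF and best EFO
   model inside every (program, frame, chain) cell, with per-chain,
   per-frame, per-program and global unweighted means recomputable
   exactly from the cells. Empty cells are excluded from means and
   logged.
2. **Per frame** — EFO search over the union of a frame's chains,
   admitting only models spanning ≥ 2 distinct monomers. This is the
   stage that captures inter-monomer cross-talk: conformationally
   distinct copies of the same site contribute complementary signal.
3. **All frames** — per program, EFO search over every column with
   models spanning ≥ 2 distinct frames; the best model per size in
   2–4 is reported next to the best single column for reference.

Programs are analyzed as separate pools and never mixed inside one
model: scores from different docking engines live on incommensurable
scales and their hybrid equations would not be portable to a rescreen
with either engine alone. Stage-2 and stage-3 searches run fresh
rather than seeded by stage-1 beams; with exhaustive size-1/2
enumeration the smaller optima are rediscovered anyway, and fresh runs
keep each stage independently reproducible.

# The synthetic generator

Real campaign data of this kind (thousands of ligands docked by
commercial engines into many receptor conformations) is rarely
shareable, so the generator emulates the *statistical structure* the
analysis relies on:

- inactive scores $\mathcal{N}(0,1)$, active scores
  $\mathcal{N}(\delta_{jcf}, 1)$ with
  $\delta_{jcf} = \delta_{\max}\, s_j\, q_c\, q_f$ — per-function
  signal, per-chain quality, per-frame quality;
- a shared per-ligand latent factor with loading $\sqrt{\rho}$
  correlating all columns (rescoring functions of the same poses are
  far from independent);
- heavy-atom counts uniform on 10–60 and molecular weight
  $13.5 \times \text{heavy atoms} + \mathcal{N}(0, 15)$ Da, supporting
  the per-heavy-atom and per-weight normalized score variants;
- optionally, a **planted complementary pair**: two columns replaced
  by $u+v$ and $u-v$, where $u$ carries the activity signal
  ($\delta_u = 2$ by default) and $v$ is high-variance nuisance noise
  ($\sigma_v = 3$). Each column alone is weak; the equal-weight sum
  reconstructs $2u$. This is the minimal mechanism by which a
  multi-monomer consensus can beat every single monomer, and it gives
  the optimizer a known ground truth to recover.

Defaults are fixed once to mirror a well-behaved tetramer campaign:
5300 ligands with 53 actives; chain qualities A = 1.0, B = 0.3,
C = D = 0.6 (one monomer equilibrates quickly and docks well, one
never stabilizes); frame qualities 0.7/0.7/1.0 (one clearly best
frame); $\rho = 0.3$; $\delta_{\max} = 3$, which puts a typical single
column's EF 1% in the tens — though the best of all 48 default columns,
being a maximum over many correlated draws, lands higher (around 50).

What the generator does **not** emulate: real score distributions are
skewed and heavy-tailed, docking failures cluster by chemotype rather
than at random, actives are structurally related to each other, and
library/assay biases correlate activity with size. Passing tests on
this generator show the machinery is correct and the protocol's
qualitative orderings follow from the assumed structure — not that any
particular real campaign will enrich.

# Structural statistics

- **Superposition** pairs atoms by (chain, residue number, atom name)
  and computes the optimal proper rotation from the SVD of the
  covariance matrix, with the reflection branch corrected, so mirror
  images are never silently matched. Binding-site RMSD fits on the
  binding-site backbone by default (the fit region is configurable);
  `select_frames()` reports, per chain × reference × criterion
  (binding-site backbone; all heavy atoms of the binding-site
  residues), the frame minimizing RMSD — the standard layout for
  picking docking-ready MD frames against crystal structures.
  Ligand-pose RMSD (`pose_rmsd()`) pairs by atom order in a shared
  frame with no symmetry correction, as in a raw re-docking comparison.
- **SASA** is Shrake–Rupley with a 1.4 Å probe, Bondi radii (fully
  overridable, per atom if needed) and 960 deterministic golden-spiral
  test points per atom: the isolated-sphere error is below 0.5% and
  halving the quadrature step moves totals by less than 0.5%. Because
  the point lattice is fixed in the laboratory frame, surface areas are
  rigid-motion invariant only to quadrature accuracy (< 0.5% at the
  default resolution), unlike the RMSD and energy routines which are
  invariant to machine precision. The contact surface
  $\sigma(t) = (S_\text{monomer} + S_\text{trimer} -
  S_\text{tetramer})/2$ is the buried interface between one subunit
  and the rest of the assembly; it is non-negative up to quadrature
  tolerance and decreases monotonically as subunits separate.
- **Interaction energies** between two atom groups sum
  $332.0716\, q_i q_j / (\varepsilon_0 r_{ij}^2)$ kcal/mol — the $1/r^2$
  form arising from the distance-dependent dielectric
  $\varepsilon(r) = \varepsilon_0 r$, the standard implicit-screening
  choice when no explicit solvent is present — and a CHARMM-form 12-6
  Lennard-Jones with Lorentz/geometric combining, within a cutoff.
  Parameters are user-supplied per atom name; the package does no
  force-field typing. Atoms closer than 0.1 Å across groups are an
  error rather than an astronomically large term.

Residue presets (binding-site residues 745, 746, 778, 782, 785, 799,
802, 838, 841, 844, 1003, 1004, 1012; transmembrane segments S1–S4 at
736–757, 769–788, 797–816, 824–851; TRP box 992–1008) use the channel's
author numbering; all selections accept explicit residue and atom-name
lists, and terminal-domain segment boundaries, which vary between
constructs, are deliberately config-only with no shipped default.

# Numerical choices and degenerate inputs

- `top_size = ceiling(f * N)`: fixes the ambiguity between "top 50"
  and "top 1% = 53" readings of a 5300-ligand library; the ceiling
  convention keeps perfect-ranking EF at exactly 100 there.
- Comparisons of fitted models use a $10^{-12}$ tolerance on EF and
  MRR before falling through to the next criterion.
- Multi-model PDB files are frame sequences; coordinates round-trip
  through `bio3d` at PDB precision (3 decimals, so ~$10^{-3}$ Å).
- Duplicate ligand ids, non-binary labels, dimension mismatches,
  unparseable headers, unknown score directions, unpaired fit atoms,
  collinear fit selections, empty selections and unsatisfiable search
  constraints are all hard errors naming the offender, never silent
  repairs.

# Problem sizes in the shipped tests

The test suite exercises the full pipeline at sizes chosen to keep a
complete run in a few minutes while leaving each statistical check
adequately powered: oracle comparisons on libraries of up to 200
ligands (500 instances), EF extremes on the full 5300-ligand shape,
planted-pair recovery and protocol-ordering checks on 2000-ligand
campaigns over 20 seeds, and combination-search-vs-brute-force
equivalence on 100-ligand, 5-column pools over 50 seeds. The
acceptance script reruns the same analyses from scratch at the same
sizes.

# Known limitations

- Only linear consensus models; no rank fusion, no nonlinear learners,
  and no objectives other than EF at one fixed fraction (mean
  reciprocal rank appears only as a tie-breaker).
- Beam search for sizes 3–4 is heuristic; the shipped tests verify it
  against exhaustive search only on small pools.
- Coefficient point estimates sit on flat EF plateaus (see above);
  compare models by subset and validated EF, not by coefficient
  decimals.
- No docking, rescoring, or descriptor computation: score matrices are
  consumed as given. Trajectory input is multi-model PDB only.
- SASA is quadrature-based; areas carry ~0.5% resolution error at the
  default 960 points.
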