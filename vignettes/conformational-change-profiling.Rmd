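---
title: "Conformational change profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational change profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccprofiler)
```

## The problem

Many proteins change shape when they bind a partner — a ligand, an ion,
a nucleic acid or another protein. A single global RMSD between the free
(apo) and bound (holo) crystal structures hides where that change happens.
`ccprofiler` computes a *conformational change profile* (CCP): a per-residue
track of local superposition RMSD, so that hinge points, switch regions and
disorder-to-order transitions become visible position by position, and lines
that track up with companion profiles (binding contacts, secondary
structure, conservation, hydropathy) on the same ruler.

## The reference ruler

Crystal structures are fragments: SEQRES covers only the crystallised
construct, and ATOM records cover only the residues that diffracted. All
profiles are therefore indexed on a full-length *reference sequence* (for
real data, typically the UniProt entry of the protein). Each structure's
SEQRES sequence is placed on the reference by a **gapless offset scan**: the
validity conditions — the fragment must embed end-to-end, without insertions
or deletions, at identity ≥ 95% and Karlin–Altschul e-value < 0.001, and the
two placements must overlap — reduce the alignment problem to trying every
offset and counting matches. We deliberately implement exactly that rather
than wrapping a general aligner: it is the semantics the validity conditions
define, and it is trivially checkable against an exhaustive oracle. Ties on
identity go to the smallest offset and are flagged `"ambiguous"`.

The e-value uses the standard ungapped BLOSUM62 Karlin–Altschul constants
(λ = 0.318, K = 0.13, natural-log units) with search space m·n. The fragment
length is the identity denominator; since valid placements are gapless and
end-to-end, fragment length and alignment length coincide.

Every reference position then gets one of three statuses per structure:

* **observed** — a residue with coordinates maps here;
* **disordered** — the position is inside the crystallised fragment
  (in SEQRES) but has no coordinates;
* **null** — the position is outside the fragment entirely.

These statuses are pure set differences (reference \ SEQRES, SEQRES \ ATOM);
no geometry is involved, and the tests enforce that.

## The conformational change profile

A window of 21 residues (10 on each side of the current position) slides
along the reference. At position *i* the C-alpha coordinates of the window
residues observed in *both* structures are rigidly superposed and the
unweighted RMSD becomes the profile value at *i*. Each window is fitted
independently — a hinge then shows up as a localized peak rather than
contaminating the whole profile the way a single global superposition
would. Positions not observed in both structures are null, and a window
with fewer than `min_common = 3` doubly observed residues (the rigid-fit
minimum) is null rather than zero, so sparse regions cannot masquerade as
stable ones. Terminal windows are truncated, never wrapped.

Two estimators are available:

* `least_squares` — the exact Kabsch fit (SVD with determinant correction,
  so reflections are never returned, even for planar or collinear inputs);
* `reweighted` (default) — iterate a weighted Kabsch fit with weights
  $w_i = 1/(d_i^2 + c)$, $c = \max(0.01\,\overline{d^2}, 10^{-6})$, until
  the unweighted RMSD moves less than $10^{-6}$ Å. This stands in for full
  maximum-likelihood superposition: it down-weights the variable region so
  the fit anchors on the stable core, which is the property that matters
  here. It is an approximation — no hierarchical covariance model is
  estimated — and is documented as such.

Whatever the estimator, the *reported* RMSD is the plain unweighted RMSD
under the final transform, so profiles from the two estimators are directly
comparable, and the reweighted value can never undercut the least-squares
optimum (a property the test suite asserts on random pairings).

The global RMSD is the same computation over all doubly observed positions
in one fit.

## Pair enumeration and binding targets

Two chains in two different files form a before/after pair when both map
validly onto the reference with overlapping intervals, and the after-file
contains every molecule of the before-file plus at least one extra.
Molecule identity across files is not defined by the data model of the PDB,
so we pin it down: polymer chains compare by exact SEQRES string (chain ids
ignored), het groups by component-id multiset. The paired chain itself is
the pivot of the comparison and is exempt from the identity requirement.
Waters (`HOH`, `DOD`, `WAT`) and the configurable pseudo-ligand list
(defaults: LA, LU, MSE, OS, PT, RE, SM, SR, WO4, XE, YB — crystallisation
artifacts) never count, either as inventory or as targets.

Extras within 5 Å (heavy atom to heavy atom) of the paired chain become the
*binding targets*, categorised as protein (amino-acid polymer), nucleic
acid (nucleotide polymer), ion (single heavy atom, or a small curated
polyatomic set) or ligand (everything else). When the after-file has more
copies of a component than the before-file, the later instances in file
order are taken as the extras; which physical copy is "the extra one" is
genuinely unidentifiable from inventories alone.

The binding-site profile flags position *i* when any heavy atom of the
residue observed at *i* in the bound structure lies within 5 Å of any heavy
atom of a target; names attach at 3 Å. Hydrogens are ignored on both sides
(the rule speaks of heavy atoms for the residue; we assume the same for the
target). Positions with no observed residue in the bound structure are null
— the alternative of falling back to the free structure would measure a
contact in the wrong conformation.

## Secondary structure

The assigner follows the classic hydrogen-bond dictionary: the amide
hydrogen is placed 1 Å from N along the previous peptide's C→O direction;
the bond energy is

$$E = 0.084 \cdot 332 \cdot \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right) \ \text{kcal/mol},$$

assigned when E < −0.5 kcal/mol; two consecutive n-turns seed 3/10-, α- or
π-helices (G/H/I); bridge patterns seed strands (E) and isolated bridges
(B); remaining turn positions are T; a κ angle above 70° is a bend (S);
priority H > E > G > I > T > S. Chain breaks (consecutive C-alpha distance
above 4.5 Å, or a SEQRES gap) terminate all patterns. The eight classes
merge to three: G,I → H and T,B,S → C — note B joins *coil* in this
merging, strand-like or not; that is the convention this profile follows.
Two overlay classes complete the profile: D (disordered)
and N (null), taken verbatim from the residue map. A classic `.dssp` file
can be ingested instead of the internal assigner.

The loop/coil percentage is 100·|C| / (|H|+|E|+|C|); D and N are excluded
from the denominator.

## Conservation

The conservation track is an entropy over weighted amino-acid frequencies
of each alignment column, with an *independent count* weighting: for each
residue type at a column, the rows carrying it are single-linkage clustered
at 80% full-row identity, and each cluster counts once. Redundant homologs
therefore cannot inflate a frequency. Published descriptions of
independent-count weighting leave implementation details open; the
per-column cluster count used here is this package's chosen realisation
(PSIC-flavoured), with the threshold configurable and an unweighted
fallback (`theta > 1`).

The raw score $\sum_a f_a \ln f_a$ lies in $[-\ln 20, 0] \approx
[-2.996, 0]$ and is mapped linearly to $[0, 1]$: raw 0 (a single-type
column) is most conserved and scores 1, raw $-\ln 20$ (uniform over the 20
types) is most random and scores 0. Gaps are excluded and frequencies
renormalised; an all-gap column is null; a column with a single surviving
row scores 1.

Pairwise row identity for clustering is matches over columns where at least
one of the two rows has a residue — a denominator choice the source leaves
open; it penalises indels symmetrically.

## Hydropathy

The hydropathy track is the *sum* — deliberately not the mean — of
Kyte–Doolittle scale values over a 15-residue window centred on each
position, truncated at the termini. `X` contributes nothing.

## The synthetic world

The fixture generator builds full backbones (N, CA, C, O) from ideal
internal coordinates (bond lengths 1.458/1.525/1.329/1.231 Å, standard
angles) by NeRF chain extension at fixed torsions: α-helix (−57°, −47°),
extended (−139°, 135°), or custom. A hinge pair rotates everything past a
chosen residue about an axis through the hinge C-alpha and plants a small
ligand at an exact minimum heavy-atom distance from an anchor residue
(found by bisection along the local outward radial direction — exactness
matters because the acceptance scans probe the 5 Å and 3 Å boundaries at
±0.01 Å). Deleted coordinate ranges create disorder. The antiparallel
sheet fixture places a second strand by a 180° rotation after aligning the
strand axis; its spacing (4.2 Å separation, −2.5 Å shift) was calibrated
once so the H-bond ladder actually forms, verified against an external
DSSP implementation, and frozen.

Synthetic MSAs plant fully conserved columns and optional two-family
structure (per-family consensus plus 5% within-family noise) for
independent-count tests.

What the synthetic world does *not* emulate: side chains (binding contacts
run through backbone + planted ligand atoms only), B-factors/occupancy
pathologies beyond simple altloc cases, crystal contacts, real sequence
composition, and real MSA gap structure. A green test therefore establishes
the correctness of the *computation* under the stated geometry, not
robustness to every PDB idiosyncrasy.

## Numerical choices and degenerate inputs

* Superposition needs ≥ 3 point pairs; fewer is an error, not a zero.
* Proper rotations are enforced via the SVD determinant correction;
  mirror-degenerate inputs still yield det(+1).
* Reweighted fits stop at ΔRMSD < 1e−6 Å or 100 iterations.
* Altloc resolution: highest occupancy, ties to first occurrence.
* Multi-model files: MODEL 1 only (inputs are X-ray biological units).
* Modified residues translate through a built-in table (MSE→M, …) plus
  MODRES records; unknown polymer components become X.
* Observed-to-SEQRES mapping tries a uniform author-numbering offset first
  (smallest |offset| wins), then falls back to leftmost gapless subsequence
  embedding; un-embeddable chains are an error.
* Serialisation is deterministic: fixed float widths (4 decimals for Å,
  3 for conservation/hydropathy), nulls as `NA` in TSV and native nulls in
  JSON.

## Open choices we fixed

* Whether window RMSDs use a per-window fit or a single global fit: the
  windowed definition reads as independent local alignments, and that is
  what makes a hinge a *local* signal — implemented per-window.
* The atom set entering superposition: C-alpha only, the standard
  backbone-change convention; the window definition names residues, not
  atoms.
* The 11-character pair-id separator is not printed anywhere we can check;
  underscore chosen (`1G7RA_1G7TA`).
* Oligomeric context of the paired chains is not enforced.

## Known limitations

* The reweighted estimator is a heuristic stand-in for maximum-likelihood
  superposition; profiles are comparable across estimators only because
  the reported RMSD is always unweighted.
* Contact detection is geometric only; no energy model.
* No mmCIF input, no symmetry-generated assemblies, no NMR ensembles.
* Conservation depends entirely on the user-supplied MSA; the package
  neither builds alignments nor fetches homologs.
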