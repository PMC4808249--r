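# ccprofiler

Per-residue conformational change profiling of apo/holo protein structure
pairs.

## What it is for

When the free (apo) and bound (holo) crystal structures of a protein are
compared with a single global RMSD, local rearrangements — hinge bending,
switch-loop ordering, binding-site closure — are averaged away. `ccprofiler`
computes a **conformational change profile (CCP)**: a sliding 21-residue
window moves along a full-length reference sequence, the C-alpha atoms
observed in *both* states inside the window are rigidly superposed
(least-squares Kabsch, or an iteratively reweighted fit that anchors on the
stable core), and the unweighted local RMSD becomes the profile value at
that position:

$$\mathrm{CCP}(i) = \min_{R,\,t}\ \mathrm{RMSD}\big(
  \{r_1(i-10..i+10)\},\ R\,\{r_2(i-10..i+10)\} + t\big)$$

Positions lacking coordinates in either state are null, so disorder is
visible rather than silently interpolated.

Around the CCP the package computes the companion per-position tracks on
the same reference ruler, enumerates valid before/after pairs from a set of
PDB files, and extracts the bound file's extra molecules as binding
targets:

| track | definition |
|---|---|
| `ccp` | windowed superposition RMSD (Å), null where unobserved |
| `binding_flag` | any residue heavy atom within 5 Å of a target heavy atom |
| `binding_names` | target names attached at 3 Å |
| `ss_before` / `ss_after` | Kabsch–Sander assignment merged to H/E/C, plus D (in SEQRES, no coordinates) and N (outside the crystallised fragment) |
| `conservation` | column entropy with independent-count sequence weighting, normalised from [−ln 20, 0] to [0, 1] |
| `hydropathy` | Kyte–Doolittle sum over a 15-residue window |

It is aimed at structural bioinformaticians studying binding-induced
conformational change, disorder-to-order transitions and switch regions.
Everything is testable offline: a deterministic fixture module generates
ideal backbones, hinge-rotated pairs with planted ligands, and synthetic
alignments.

## Worked example

```r
library(ccprofiler)

# a 60-residue helix whose C-terminal half rotates 30 degrees at residue 30,
# with a GNP ligand planted 4 A from residue 45 in the bound copy
pair <- make_hinge_pair(length = 60, hinge = 30, angle = 30, seed = 1)
ref  <- reference_sequence("ref", pair$free$protein_chains[["A"]]$seqres)
map  <- build_residue_map(pair$bound$protein_chains[["A"]],
                          pair$free$protein_chains[["A"]], ref)

ccp <- compute_ccp(map)
which.max(ccp$values)               # 30      <- the hinge position
max(ccp$values, na.rm = TRUE)       # 2.819   <- local RMSD peak, Angstrom
global_rmsd(map)                    # 7.282   <- the global view overstates
                                    #            the locality of the change

targets <- extract_binding_targets(pair$bound, pair$free, "A", "A")
targets[[1]]$name                   # "GNP"
targets[[1]]$category               # "ligand"
which(binding_site_profile(map, targets)$values)   # 45  <- the planted site
```

The CCP values fall off symmetrically around the hinge
(`ccp$values[25:35]`):

```
1.372 1.600 1.843 2.232 2.591 2.819 2.582 2.226 1.836 1.592 1.367
```

meaning: residues whose 21-residue window straddles the hinge see part of
the rotated segment and pick up RMSD proportional to how much of it they
cover; ten residues away the window no longer reaches the hinge and the
profile returns to zero.

The full profile set (TSV/JSON/superposed two-model PDB/metadata) comes
from one call:

```r
ps <- assemble(pair$free$protein_chains[["A"]],
               pair$bound$protein_chains[["A"]], ref, targets = targets,
               before_meta = pair$free$metadata,
               after_meta  = pair$bound$metadata)
ps$metadata$pair_id                 # "SYNFA_SYNBA"
write_tsv(ps, "profiles.tsv")
```

```
position  ref_aa  ccp     binding_flag  binding_names  ss_before  ss_after  conservation  hydropathy
30        I       2.8195  false                        H          H         NA            -2.000
```

Or from the command line:

```sh
Rscript inst/exec/ccprofiler profile \
  --before free.pdb --before-chain A --after bound.pdb --after-chain A \
  --ref ref.fasta --out myprofile
Rscript inst/exec/ccprofiler pair --pdb-dir structures/ --ref ref.fasta \
  --out pairs.tsv
```

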