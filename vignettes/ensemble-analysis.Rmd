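---
title: "Analysing protein-ligand structural ensembles with plens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein-ligand structural ensembles with plens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plens)
```

## The problem

Structure-based and fragment-based drug-discovery programmes routinely
accumulate tens of liganded crystal structures of one target. Generic
viewers show such an ensemble as an uninterpretable superposition: it is
hard to see which waters are conserved, which ligand displaces which water,
which residues flip between conformations, and which pharmacophoric
features recur across the bound ligands -- and even harder to trace any of
those observations back to individual ligands. `plens` automates exactly
that bookkeeping. Its input is deliberately minimal: a CSV manifest (one
row per ligand-bound chain, giving a PDB path and the ligand SMILES with
tautomer and charge state assigned) plus the PDB files, pre-superposed onto
a common template chain with consistent residue numbering. Alignment is an
input requirement, not something the package attempts.

## The clustering model

Every analysis reduces to one primitive: hard clustering where the number
of clusters is unknown but a physically interpretable distance is known.
Two H-bond acceptors 0.5 Å apart are "the same" feature; two 8 Å apart
are not. The package therefore uses DP-means with a single penalty
$\lambda$, read as the maximum distance allowed between a cluster member
and its cluster centre:

* points are scanned in a deterministic input order; a point farther than
  $\lambda$ from every current centre spawns a new singleton cluster at its
  own position, otherwise it joins its nearest centre (ties to the lowest
  cluster index);
* after each full pass, centres are recomputed as unweighted coordinate
  means and empty clusters are dropped;
* passes repeat until an assignment pass changes nothing. At that fixed
  point every member provably lies within $\lambda$ of its centre.

This is the distance-threshold reading of the penalty, not the
$\lambda^2$-penalised k-means objective of the original derivation of
DP-means from a Dirichlet-process mixture: the threshold semantics is what
makes $\lambda$ interpretable in Angstrom and is what the analyses below
rely on. Initialisation is the first point (equivalently, zero clusters, so
the first point always spawns); a global-mean seed would violate the
$\lambda$ contract on the first pass for spread data. A convergence cap of
100 passes guards against pathological oscillation; in practice the fixed
point arrives within a handful of passes.

Residue conformations have no coordinates to average -- only pairwise
heavy-atom RMSDs -- so the residue analysis uses a medoid variant: the same
pass structure, with the cluster centre being the member minimising the
within-cluster dissimilarity sum (ties to the lowest index).

Distances between residue conformations are heavy-atom RMSDs over atoms
paired by PDB atom name, computed **without** re-superposition, since the
ensemble is pre-aligned. Atoms present in only one conformation (truncated
side chains, alternate completeness) are excluded from the pairing;
conformations are compared over the atom-name intersection.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\lambda$ water | 1.5 | Å | water-site clustering penalty |
| $\lambda$ pharmacophore | 2.0 | Å | per-kind pharmacophore clustering |
| $\lambda$ fragment | 2.0 | Å | fragment-centroid clustering |
| $\lambda$ residue | 2.5 | Å (RMSD) | residue conformational clustering |
| $\lambda$ ligand | 5.0 | Å | binding-site assignment from ligand centroids |
| water contact | 1.5 | Å | a water cluster is "ligand-proximal" when its centre is within this distance of any site ligand heavy atom |
| residue contact | 5.0 | Å | a residue is "binding-site" when any heavy atom comes within this distance of any site ligand heavy atom, in any model |
| min. water conservation | 0 | fraction | strict lower bound on reported site waters; presentation thresholds such as 0.85 belong to the report layer |
| Butina cutoff | 0.4 | Tanimoto distance | compound-ordering chemotype clustering |

The $\lambda$ defaults are the values that have proven broadly appropriate
for liganded-ensemble analysis of diverse targets; they are deliberate
compromises (a tighter water $\lambda$ fragments genuinely conserved sites,
a looser one merges distinct ones) and every one of them is exposed in
`runConfig()` rather than hard-coded.

## From ligands to features

Each manifest row contributes one `StructureModel`: the stated chain's
residues (hydrogens and deuteriums dropped, alternate locations resolved to
the highest-occupancy record, ties to the alphabetically first altloc),
the chain's waters (oxygen positions only), and exactly one ligand. The
ligand is found by composition: the hetero group whose heavy-atom element
multiset matches the template SMILES. Crystallographic connectivity is
inferred from interatomic distances (covalent radii + 0.45 Å, since PDB
files frequently lack CONECT records) and matched to the template graph by
element-coloured VF2 isomorphism; bond orders, formal charges and
aromaticity are transferred from the template onto the crystallographic
atoms, whose coordinates are preserved bit-exactly.

Pharmacophore typing applies six rules to the annotated graph, the
graph-predicate form of the standard SMARTS definitions, extended with the
two medicinal-chemistry kinds (halogen and ring-methyl):

* **Donor** -- N--H (neutral trivalent or protonated quaternary), neutral
  O--H/S--H, aromatic N--H;
* **Acceptor** -- neutral divalent O/S (hydroxyls excluded when attached to
  an atom double-bonded to O/N/P/S, i.e. acid hydroxyls), anionic O/S,
  trivalent N not adjacent to such a double bond (amide N excluded),
  aromatic N without hydrogen, aromatic O/S not adjacent (or ortho through
  carbon) to aromatic N;
* **Aromatic** -- one point per smallest aromatic ring, at the unweighted
  ring centroid;
* **Hydrophobe** -- a methyl carbon with exactly one heavy neighbour, that
  neighbour being carbon ("singly substituted non-polar carbon");
* **Halogen** -- F, Cl, Br, I;
* **RingMethyl** -- a methyl on a ring atom. Whether "ring" means any ring
  or aromatic rings only is genuinely open; the package defaults to any
  ring and exposes the choice (`ringMethylAnyRing`).

Matches on identical atom sets are de-duplicated within a kind; an atom may
carry several kinds (a toluene methyl is both Hydrophobe and RingMethyl).
The behaviour of the six rules is pinned by a ten-molecule panel whose
expected counts were derived by hand before the implementation existed.

Fragmentation enumerates all single cuts of acyclic single bonds between
heavy atoms (each cut yields the two complementary fragments) and all
unordered pairs of such cuts, each yielding the core fragment incident to
both cut bonds. Depth stops at double cuts: fragments feed only spatial
clustering, and double cuts suffice to localise cores. For n-butane this
enumeration gives six single-cut fragments and three double-cut cores
(the two terminal CH2 cores and the central C2 core); the count follows
directly from brute-force enumeration of bond subsets of size at most two.
Fragment positions are unweighted centroids of the member atoms in the
bound pose.

## The summary products

* **Sites** -- DP-means over ligand centroids at $\lambda$ = 5 Å. The most
  populated cluster is the *main site* (ties to the site containing the
  lexicographically smallest model id); all other analyses default to it,
  and `analyseSite()` recomputes everything restricted to any other site.
* **Waters** -- DP-means over all water oxygens at $\lambda$ = 1.5 Å.
  *Conservation* is the fraction of ensemble models contributing at least
  one water to the cluster (distinct models, not water count). Clusters are
  ranked by conservation; the site-water table keeps those whose centre is
  within the water contact of any site-ligand heavy atom and whose
  conservation strictly exceeds the configured minimum.
* **Displacement** -- for each site water (row) and each site ligand
  (column), a cell is marked displaced exactly when that model contributes
  no water to the cluster. Displacement is pure non-contribution: the
  contact filter has already localised the clusters to the ligand envelope,
  so no additional ligand-overlap test is applied.
* **Pharmacophore presence** -- per-kind DP-means at $\lambda$ = 2 Å (kinds
  never co-cluster, even at identical coordinates). Conservation is counted
  over the site's ligands -- by distinct ligands, not points, so a ligand
  contributing two acceptors to one cluster counts once. Rows are ranked by
  cluster size; the grid cell is green when the ligand contributes a point.
* **Residues** -- residues within the residue contact of any site ligand
  (union over models, so a residue pushed out of range by one ligand still
  counts), clustered by the medoid DP-means on pairwise RMSD at $\lambda$ =
  2.5 Å and ranked by maximum pairwise RMSD, descending. Residues missing
  from more than half the models are excluded with a note.
* **Compound order** -- Morgan (radius-2) fingerprints, folded to 2048
  bits, Butina-clustered at Tanimoto distance 0.4; columns list clusters by
  size and members by model id, which groups chemotypes in every grid.

## The synthetic-ensemble generator

Real ensembles with known ground truth do not exist, so the package ships
a seeded generator (`generateEnsemble()`) that *plants* the truth: water
sites with chosen conservation fractions and Gaussian positional jitter,
far-field decoy waters, a bi-rotameric pocket residue with a chosen
state split, and ligands built from template chemotypes, rigidly placed
with small random rotations and translations on a rigid shared protein
scaffold (so the "alignment" of the synthetic ensemble is exact). The
default demonstration spec (`defaultDemoSpec()`) has 20 models, two
chemotypes (phenol-like and chlorobenzene-like, ten each, one binding
site), five planted water sites -- four ligand-proximal at conservations
1.00, 0.95, 0.90, 0.60 and one distal at 0.30 -- and a rotamer split of
6/14 with an inter-rotamer RMSD of 6.69 Å. The 0.95 site is missing from
exactly one designated model: the "unique displacement" the summary
should single out, the classic signature of one ligand binding deeper
than the rest of the series.

Two generator details make exact recovery a theorem rather than a hope:

* the Gaussian jitter ($\sigma$ = 0.3 Å) is resampled until its norm is at
  most $2\sigma$. Then any two same-site waters are at most $4\sigma$ =
  1.2 Å apart, below $\lambda$ = 1.5 Å, so the first site member reached in
  a pass absorbs the rest; and with planted sites separated by more than
  $\lambda + 4\sigma$ = 2.7 Å no point can come within $\lambda$ of another
  site's members. Recovery of the planted partition is therefore guaranteed
  for *every* seed, which is what lets the test suite assert conservations
  to three decimals rather than approximately;
* decoy waters are drawn uniformly in a far-field box, rejected when closer
  than $2\lambda$ to a planted site or to another decoy -- each decoy is
  provably its own singleton cluster.

The generator emulates geometry, not crystallography: occupancies are
constant, B-factors are placeholders, there is no coordinate noise model
beyond the water jitter, no missing side chains, no alternate ligand
conformers, and the scaffold is not a real protein fold. Passing the
planted-recovery tests demonstrates that the analysis machinery is exact
under its stated separability conditions; it does not demonstrate
robustness to refinement artefacts, borderline-separated water networks or
inconsistent residue numbering in real data, where the $\lambda$ defaults,
not theorems, do the work.

## Numerical choices and degenerate inputs

* Ties everywhere resolve to the lowest index (nearest-centre ties, medoid
  ties, Butina centroid ties); cluster output order is size-descending with
  first-member input order as the tiebreak. Together with the deterministic
  scan order this makes every run reproducible.
* An empty ensemble, a model without waters, a ligand with no cuttable
  bond, and an empty site after filtering are all valid inputs with empty
  (not failing) outputs.
* Residue conformations sharing no atom names cannot be compared and raise
  a data error; the conservative atom-name-intersection RMSD otherwise
  keeps partially modelled residues in the analysis.
* `summary.json` carries the full provenance (every $\lambda$, both
  contacts, tool version, input checksums), and reruns with the same seed
  are byte-identical -- the determinism contract is tested, not assumed.

## Problem sizes used in validation

The shipped validation uses ensembles of 20 models (the demonstration
spec), random point sets of up to 500 points for the clustering fixed-point
property at each default $\lambda$, 100 random instances for equivalence
against an independently transcribed reference implementation, and
brute-force partition search over all set partitions for the medoid variant
at up to 8 items -- sizes chosen so the whole suite exercises every
contract in a few minutes on one core.

## Known limitations

* One ligand per manifest row; multi-ligand chains must be disambiguated
  with `lig_resno`.
* Waters are taken from the model's chain when the file assigns them chain
  ids, otherwise from the whole file; ion/buffer hetero groups are ignored
  entirely rather than analysed.
* Aromaticity and SMILES interpretation follow Open Babel's perception;
  exotic tautomers should be pre-assigned in the manifest SMILES, as the
  input contract requires.
* No occupancy weighting: the highest-occupancy altloc wins outright.
* Donor/acceptor points carry no directionality, and there is no scoring or
  virtual-screening layer on the pharmacophores -- the package summarises
  observed structures; it does not predict.
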