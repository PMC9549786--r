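---
title: "Detecting ligand binding sites with ligand-environment sphere templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ligand binding sites with ligand-environment sphere templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligsphere)
```

## The model

ligsphere is a strictly structure-template-based binding-site detector.  Its
premise is that the repertoire of binding-pocket shapes is far smaller than
the repertoire of protein sequences, so the local environment of a ligand
observed in one solved complex is a reusable template for finding the same
pocket — possibly in a protein with very low sequence identity, or in an apo
conformation that has never been seen with a ligand.

The template unit is the **sphere**: for a ligand bound in a complex, every
polymer residue with at least one heavy atom within 12.0 Å of any ligand
heavy atom (waters excluded), carried together with the ligand's own
coordinates.  Twelve ångströms is large enough to constrain the local fold
around the pocket while staying local; residues within 4.5 Å form the
*interface* set, the residues in direct contact.  Ligands are hetero
compounds, metals/ions (single-heavy-atom hetero groups), and bound peptide
chains of at most 25 residues; waters are never ligands.

Detection proceeds in two stages:

1. **Shape detection.**  The sphere is aligned onto the query with a
   sequence-independent local structural alignment on residue
   representative points (Cα by default; Cβ with Cα fallback for glycine).
   The alignment quality is summarised by a 0–100 score combining a
   global-distance-test (GDT) component — the maximal fraction of aligned
   residues superposable within each of the thresholds {1, 2, 4, 8} Å,
   averaged — and a longest-continuous-segment (LCS) component — the
   longest contiguous aligned segment fitting under each RMSD cutoff of
   {1, 2, 5} Å, as a fraction, averaged — weighted 3:1 in favour of GDT.
2. **Conformation assessment.**  Residue pairs within 4.0 Å under the final
   transform are *conserved* (their count is Nc); over the conserved pairs
   an all-atom score **GDC** matches heavy atoms by identical atom name and
   averages the fractions within 0.5 Å, 1.0 Å, …, 5.0 Å with linearly
   decreasing weights (10, 9, …, 1), so agreement in side-chain placement
   is credited and atoms missing on either side count against the score.

The template ligand is then transplanted into the query frame by the rigid
alignment transform — its internal conformation untouched; no docking,
minimisation or relaxation — and the prediction is characterised by N4, the
number of query residues with a heavy atom within 4.5 Å of the inserted
ligand, and cl, the number of query residues with an atom closer than 1.0 Å
(steric clashes, counted per residue, so several clashing atoms inside one
residue count once).

A match is **accepted** when Nc ≥ 10, GDC ≥ 55.0, N4 ≥ 1 and cl ≤ 2, and is
flagged **high confidence** when additionally Nc ≥ 25, GDC ≥ 65 and cl ≤ 1.
All bounds are inclusive except the clash distance, which is strict.

Accepted matches that describe the same pocket are merged: two matches are
linked when more than 80% of their predicted contact residues coincide or
their inserted-ligand centroids lie within 2.0 Å, and clusters are the
connected components of this graph.  A cluster is the package's *consensus
pocket*, summarised by Nm (members), Nlig (distinct ligands) and Nres (the
union of contact residues).

## Scoring predictions

Predicted binding residues are scored against a *unified binding site*
(UBS): the union of residues contacted by any ligand across a protein
family, mapped into a common residue frame by global sequence alignment.
With residues labelled TP/FP/TN/FN against the UBS,

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},\qquad
F = \frac{2\,TP}{2\,TP+FP+FN}.$$

A zero denominator is reported as 0 with an `undefined` flag.  The TN
universe is all polymer residues of the scored structure.

For pocket-vs-pocket studies, each complex is reduced to the 16 Å region
around its ligand, all-against-all similarities are computed by aligning
each sphere onto each region, and pockets are grouped by *exclusive*
clustering: single-linkage components over pairs with GDC at or above a
threshold (default 70 — deliberately prominent as a configuration item,
since it is study-dependent).  Affinity concordance across similar pocket
pairs (default constraints GDC ≥ 95 and centroids within 0.5 Å; relaxed,
GDC ≥ 90 and 1.0 Å) is summarised by R² and Spearman rank correlation on
log-scale affinities, with Kd and Ki populations never mixed.

## The alignment search

The published engines in this scoring family are iterative superposition
searches; ligsphere implements its own, with these choices:

* **Seeding.**  Least-squares (Kabsch) superpositions of all gapless
  single-chain fragment pairs of length 7, with stride 2 on the query to
  bound cost; the 48 seeds with lowest fragment RMSD are refined.
* **Refinement.**  Alternate (a) assigning residue pairs as
  chain-consistent, sequence-order-monotone mutual nearest neighbours
  within 6.0 Å (monotonicity enforced per chain pair by longest increasing
  subsequence), and (b) re-superposing on the current pairs; stop at
  convergence or 20 rounds.
* **Selection.**  Candidates are ranked cheaply by their unrefined GDT
  fraction; the best six receive the full GDT/LCS score, and the winner is
  the highest score, ties broken by larger Nc, then lower RMSD.  GDT and
  LCS fractions are normalised by the maximal alignable length
  min(sphere size, query size), so a short spurious alignment cannot
  saturate the score.
* **LCS floor.**  Segments shorter than three residues superpose trivially
  and are not counted; with nothing else alignable the score is exactly 0.
* **Conserved-pair cutoff.**  4.0 Å on representative points.  The cutoff
  is a declared default of this implementation, configurable in
  `default_config()`, not a claim about any published binary.

Floating-point comparisons use 1e-6 absolute tolerance throughout; the
final transform is re-fit on the conserved pairs when there are at least
three.

## Synthetic study conditions

Because real template libraries derive from large structure archives, the
package ships a deterministic generator so every stage is testable offline:

* `make_toy_complex()` builds four ideal α-helices (CA radius 2.3 Å, rise
  1.5 Å, 100°/residue; backbone N, CA, C, O and a CB side-chain
  representative) as a bundle with a central channel, 64 residues by
  default, and plants a rigid 12-atom pseudo-ligand (component `LIG`) in
  the channel.  Glycine is excluded from the generated sequences so every
  residue carries a CB.  Ground-truth 4.5 Å contacts are emitted alongside.
* `perturb_structure()` emulates apo and homolog conformations: i.i.d.
  Gaussian coordinate noise (0.3 Å for the standard apo condition),
  optional residue-type substitution, ligand removal.
* `make_decoy()` draws a self-avoiding random-walk backbone (CA spacing
  3.8 Å, non-adjacent CA ≥ 4.0 Å) with no concave site, as a negative
  control.

What the fixtures do *not* emulate: full side chains beyond CB (so GDC on
fixtures exercises backbone + CB atom matching only), realistic packing
densities, crystallographic artefacts (altloc disorder, missing atoms,
insertion codes) beyond what the parser tests construct directly, and true
conformational change beyond isotropic noise.  Passing the desk-scale suite
therefore demonstrates correctness of the machinery, not benchmark-level
accuracy on real proteins.

Desk-scale problem sizes were chosen to keep the full suite fast while
leaving no stage untested: 10 toy complexes of 64 residues, 20 decoys of 60
residues, and a 3-template library for the clustering run.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `shell_radius` | 12.0 | Å | sphere shell around the ligand |
| `interface_radius` | 4.5 | Å | interface residue distance |
| `contact_cutoff` | 4.5 | Å | N4 contact distance (inclusive) |
| `clash_cutoff` | 1.0 | Å | clash distance (strict) |
| `nc_min`, `gdc_min`, `n4_min`, `cl_max` | 10, 55.0, 1, 2 | — | acceptance filter |
| `hc_nc_min`, `hc_gdc_min`, `hc_cl_max` | 25, 65, 1 | — | high-confidence tier |
| `overlap_frac` | 0.80 | — | contact-overlap merge rule (strict >) |
| `centroid_cutoff` | 2.0 | Å | centroid merge rule (inclusive) |
| `region_radius` | 16.0 | Å | pocket region for all-vs-all studies |
| `conserved_cutoff` | 4.0 | Å | conserved-pair distance |
| `burial_min_neighbors`, `burial_radius` | 10, 5.0 | —, Å | ligand-core burial rule |

## Design decisions in open territory

* **Contact-overlap denominator.**  ">80% of predicted contact residues the
  same" is read as the overlap coefficient |A∩B| / min(|A|,|B|); Jaccard is
  available via `overlap_method = "jaccard"`.  The overlap coefficient
  merges a small contact set into a larger superset pocket, which matches
  how differently sized ligands of one pocket behave.
* **Merge rule combination.**  The two merge criteria act jointly as edges
  of one graph with transitive (single-linkage) closure, rather than
  sequentially; sequential application would make the result depend on
  processing order.
* **Centroids for merging** use all heavy atoms.  Core (buried-part)
  centroids — a ligand atom is buried when ≥ 10 protein heavy atoms lie
  within 5.0 Å — are reported for interpretation but not used in merging,
  since exposed ligand parts are exactly what the core centroid is meant to
  discount, not a merge criterion.
* **Sequence identity** (library preselection) is Smith–Waterman local
  alignment with BLOSUM62, gap open 11 / extend 1, identity over aligned
  columns; identical to common `ssearch`-style reporting.
* **Altloc resolution** keeps the highest-occupancy conformer, ties broken
  by file order.  Modified amino acids inside polymer chains stay polymer
  residues.  Hydrogens are parsed but ignored in every distance
  computation.
* **Ranking of reported matches** is GDC desc, Nc desc, RMSD asc — GDC is
  the confidence metric, so it leads.

## Known limitations

* The alignment search is a heuristic; symmetry of A→B vs B→A holds only
  approximately (asserted within 1 LGA unit on fixtures), and pathological
  topologies could in principle trap the refinement in a local optimum.
* GDC depends on atom-name matching, so chemically equivalent but
  differently named atoms (e.g. ring-flip ambiguous side-chain atoms) are
  scored as mismatches.
* The library scales linearly in templates with no spatial indexing; the
  intended scale for this implementation is thousands, not millions, of
  spheres.
* Chemical-fingerprint (Tanimoto/Tversky) preselection is exposed only as
  a no-op hook (`preselect()` filters by name, size and sequence identity).

## A short worked example

```{r example, eval = FALSE}
tc  <- make_toy_complex(fixture_spec(seed = 1))
sp  <- build_sphere(tc$holo, tc$truth$ligand)
apo <- perturb_structure(tc$holo, noise_sigma = 0.3, seed = 1001)
al  <- structural_align(sp, apo)
m   <- evaluate_match(sp, apo, al)
match_table(list(m))
eval_scores(m$contact_keys, tc$truth$contact_keys,
            residue_table(apo)$key)
```
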