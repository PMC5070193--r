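---
title: "Classifying tandem double-AAA ATPases: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tandem double-AAA ATPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cdc48-family proteins (Type-II AAA ATPases: Cdc48/p97, NSF, Pex1, Pex6,
Spaf, Spaf-like, NVL, Yta7 in eukaryotes, and the archaeal Cdc48/VAT) carry
two consecutive AAA domains, D1 and D2, preceded in most members by an
N-domain and followed in several by a short C-terminal tail helix with a
conserved central tyrosine; Cdc48 and VAT additionally end with the
proteasome-docking HbYX tripeptide. Because the two domains of one protein
are themselves ancient paralogs, a sequence-level classification has to
operate at the level of *D-domain subgroups* — one subgroup per family per
domain — and a family assignment for a protein is derived from the
assignments of its domains.

`tandemaaa` implements that pipeline end to end: per-subgroup profile HMMs
with E-value calibration, a glocal domain scanner and architecture caller,
AAA+ motif diagnostics (Walker A/B, Sensor 1/2, arginine finger, pore
loop), a similarity-graph clustering reconciled against phylogenetic
clades into a unified subgroup classification, and Dollo ancestral
repertoire inference (root/LECA set, lineage-specific losses,
duplications). A synthetic-data generator with machine-readable planted
truth makes every stage testable without any external database.

## Profile HMMs and scoring

Each subgroup model is a plan7-style profile over the 20 amino acids:
every alignment column of the (gap-filtered) training alignment becomes a
match state; insert emissions equal the background, so inserted residues
are score-neutral. Match emissions are Henikoff position-weighted counts
plus background-proportional pseudocounts (total strength 20, i.e. 20
times each residue's background frequency), floored at 1e-6 and
renormalized; the effective sample size is the number of distinct rows, so
duplicated rows never sharpen a model. Transitions are weighted observed
match/delete moves plus Laplace pseudocounts (insert moves are unobserved
in a column-complete alignment and come from the pseudocounts alone).

Scoring is *glocal*: global in the model, local in the sequence, with free
background flanks; the score is the log2 odds of the best path (Viterbi)
or of all paths (forward) against the background model. Ties in the
dynamic programming break M > D > I, making envelopes deterministic.
Alignment filtering removes columns with more than 50 % gaps and then rows
with more than 50 % gaps over the kept columns; both thresholds are strict
inequalities, so a 4-row column with exactly two gaps is kept.

## E-value calibration

Each model is calibrated by scoring 5000 i.i.d. background sequences
(default fixed length 400, overridable with an empirical length law) and
fitting a Gumbel by maximum likelihood. The E-value of a score `S` against
a database of `N` sequences is `N * (1 - exp(-exp(-lambda * (S - mu))))`.
Two bounds drive assignment status: a strict bound (default 1e-5) for firm
calls and a soft bound (default 1e-3) for provisional ones; the published
per-family bounds are not machine-readable, so the defaults are properties
of the synthetic calibration, not copied values. Because glocal null
scores of a length-200 model are far below zero, fitted locations are
strongly negative and true-domain E-values are many orders of magnitude
below the strict bound; classification therefore leans on the *bit-score
margin* (default 10 bits between the best and second-best model) rather
than on the absolute E-value alone. Calibration is performed once per
subgroup at the first build and reused across retraining iterations: the
null distribution depends on model length and background composition,
which the added training rows barely move.

## The classification loop

`iterate()` builds and calibrates one model per seed alignment, scans
every database protein (per model, iteratively masking each accepted
envelope so tandem repeats yield one hit per repeat), groups hits whose
envelopes overlap reciprocally by more than 50 %, and assigns each
envelope group: *firm* (strict bound and margin), *provisional* (soft
bound only), *ambiguous* (two models under the soft bound within the
margin; `resolve_ambiguous()` then compares mean exemplar bit scores and
keeps the segment ambiguous unless one subgroup leads by 2 bits), or
*unclassified*. Firm segments are re-aligned to their model and added to
the training alignment *cumulatively* — members are never removed, seeds
are always kept — and the loop repeats until no label or status changes
(typically 3-5 iterations on the default synthetic data), with oscillation
detection as a guard. Only firm members ever train; provisional hits never
feed back into the models.

## Reconciling clusters with clades

Firm tandem proteins are split into their D1 and D2 segments. All segment
pairs are locally aligned (Smith-Waterman, BLOSUM62, affine 11/1 gaps, in
compiled code) and converted to Karlin-Altschul-style E-values with fixed
`K = 0.1`; only the ordering matters. Connected components are extracted
at a ladder of cutoffs (defaults 1e-40, 1e-28, 1e-16, 1e-8, chosen from
the observed score scale of the generator: within-subgroup single-linkage
bottlenecks sit below 1e-30 while the strongest between-subgroup pair sits
near 1e-24, so the 1e-28 rung separates subgroups with several orders of
magnitude of slack on both sides). Components nest across cutoffs, giving
the cluster hierarchy.

The phylogenetic side builds a "general AAA domain alignment": the
filtered seed alignments are progressively profile-profile aligned
(column-frequency scores under BLOSUM62), which yields a map from every
subgroup's columns to the joined columns; each segment is then
Viterbi-aligned to its own subgroup model and its match-state residues are
placed through that map. Within-subgroup homology thus comes from the
subgroup model and between-subgroup homology from the profile join — an
important design point: anchoring all segments to a single averaged master
model scrambles within-subgroup columns and destroys clade structure.
Distances are gamma-corrected (shape 1) with near-saturated pairs capped,
trees are neighbor joining, and supports come from nonparametric column
bootstrap (50 replicates in the pipeline default).

`reconcile()` accepts a set as a unified subgroup iff it is a connected
cluster at some cutoff *and* a clade of the domain tree with bootstrap
support of at least 70 %. Walking the component forest from the loosest
cutoff down, the first valid set on each path becomes a subgroup;
singletons, the universal set and — on unrooted trees — the larger side of
a split never qualify. A component that is not a supported clade is first
decomposed into its stricter-cutoff children; only if that yields nothing
is it repaired from the tree (the best supported clade with Jaccard
similarity at least 0.7, provenance `"clade-only"`), and uncovered
segments whose addition keeps a subgroup a supported clade are re-homed by
the tree. This operationalizes "reconciling the two hierarchies" with the
tree as the default arbiter.

## Repertoires and ancestral states

Protein-level family calls (majority family over firm segments, tandem
flag requiring a firm D1 before a firm D2) feed a species-by-family
presence/absence matrix with copy numbers. Ancestral repertoires follow
Dollo parsimony: one gain at the MRCA of the possessing leaves, losses on
every maximal branch below the gain whose subtree lacks the family — the
loss-minimal single-gain history, verified in the tests against exhaustive
search on small trees. The root repertoire of a user-rooted eukaryote tree
is the LECA set; the intersection of all rows is the minimal core. An
"uncertain absence" list excludes cells from loss calls without asserting
presence, for incompletely sequenced genomes. The shipped example table
(`cdc48_repertoire_example()`) encodes the published repertoires of
parasitic lineages plus a full-repertoire Homo sapiens row on a consensus
eukaryote tree rooted between the opisthokont and SAR/excavate sides; on
it the minimal core is {Cdc48, NSF, NVL} and the Dollo LECA set has all
eight eukaryotic families.

## The synthetic generator

`synth_dataset()` draws a root AAA domain with canonical motifs planted at
fixed coordinates (Walker A `GPPGTGKT`, Walker B `ILFIDE`, Sensor 2 `GAD`,
an `R..R` arginine finger, pore loop, Sensor 1), derives one D1 and one D2
profile per family at 1.0 expected substitutions/site from the root
(non-motif sites only), applies the planted modifications — Pex1/Pex6 D1
Walker A/B and arginine finger scrambled away from the canonical residues,
NSF D2 Sensor 2 aspartate replaced by lysine, the ~50-residue NVL D1
insert before the terminal helix, a 40-residue Pex1 D2 insert, loss of the
tail helix in NSF and Yta7, HbYX on Cdc48 and VAT — and assembles
N-linker-D1-linker-D2(-tail)(-HbYX) constructs. Constructs evolve along a
40-leaf eukaryote tree (plus a 6-leaf archaeal subtree for VAT) scaled to
0.8 expected substitutions/site root-to-tip, under a BLOSUM62-biased
replacement process with Poisson event counts and rare indels (0.005 per
site per unit length) outside motif sites; motif sites are protected from
both indels and substitutions, modelling strong purifying selection and
keeping motif-coordinate truth exact. A 5-leaf "parasite" clade loses all
families except {Cdc48, NSF, NVL}; a 6-leaf clade carries a planted Yta7
duplication re-evolved independently from the clade ancestor. Fractional
positions thread every coordinate through the indel history, so domain and
motif boundaries in the truth tables are exact for every leaf.

What the generator does *not* emulate: rate heterogeneity across sites and
lineages beyond the branch lengths, domain shuffling, compositional bias,
alignment uncertainty from honest misalignment (seed alignments are cut
from the planted homology), and realistic family-specific divergence
levels. Passing the recovery tests therefore demonstrates the pipeline's
internal consistency at a realistic divergence, not its performance on
real proteomes.

## Problem sizes and numerical choices

The default study design is 40 eukaryotes + 6 archaea and 8 + 1 families
(about 300 proteins, about 600 D-domains). The package's own experiment
sizes are: 5000 calibration sequences per model, 50 bootstrap replicates
for the domain tree, 10 bootstrap seeds when reporting the modal subgroup
count, and 10 seed rows per subgroup alignment. Unit tests run the same
machinery on a 12 + 4 species configuration. Degenerate inputs are handled
explicitly: all-gap logo columns are flagged rather than NaN, saturated
distances (p >= 1) error under correction unless capping is requested,
negative NJ branch lengths are clamped to zero and flagged, and zero-score
calibration distributions are rejected.

## Known limitations

Full maximum-likelihood tree inference, AU tests and multi-program support
values are out of scope; NJ + bootstrap and a least-squares quartet
surrogate stand in for them, which is adequate for clade membership
questions but not for deep-branching order. The HbYX rule is strict
(tyrosine only) by default; phenylalanine acceptance is a flag. Ambiguity
resolution uses exemplar bit scores, not profile-profile comparison. The
similarity-graph E-values use a fixed Karlin-Altschul `K`; their absolute
scale is nominal.
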