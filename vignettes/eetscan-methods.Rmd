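---
title: "Screening metagenomes for putative extracellular electron transfer genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metagenomes for putative extracellular electron transfer genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetscan)
```

## The screening procedure

Microbes that respire insoluble or high-molecular-weight electron acceptors
— Fe(III) minerals, Fe(II) as a donor, and the quinone moieties of humic
substances — must move electrons across the cell envelope, a process called
extracellular electron transfer (EET). In genomes and metagenomes the
genetic potential for EET is visible through a small set of protein
signatures, and `eetscan` operationalizes that screen over annotated
assemblies:

1. **Multiheme c-type cytochromes (MHCs).** Heme c attaches covalently at
   the CXXCH motif, so counting motif occurrences estimates the heme number
   of a protein. A protein with at least `mhcMin = 5` motifs is treated as
   an MHC; abundances are reported in the two bins `5-10` and `>10` hemes
   (`binSplit = 10`), and a stricter `emphMin = 8` flag marks high-heme
   proteins, the candidates for electron-conducting "molecular wires".
2. **Porin–cytochrome conduits (PCCs).** A PCC couples an outer-membrane
   porin to a periplasmic (and sometimes an additional
   extracellular/outer-membrane) MHC. Known families — MtrABC, MtoAB,
   PioAB, and OmbB-OmaB-OmcB — are found by homology. Because independent
   PCC systems evolved without sequence homology to one another, the caller
   also searches for the *gene organization* alone: a porin-coding gene
   within `maxGeneGap = 1` intervening genes of a signal-peptide-bearing
   MHC on the same contig is reported as a `novel_organization` cluster.
3. **Outer-surface MHCs.** MHCs localized to the outer membrane,
   extracellular space, or (in monoderm organisms) the cell wall that are
   not members of any PCC cluster are reported separately; exemplars are
   OmcE/OmcS/OmcZ-type cytochromes.
4. **Cyc2-like genes.** Cyc2 is a monoheme outer-membrane cytochrome with
   one N-terminal heme motif and a C-terminal porin fold, associated with
   Fe(II) oxidation. The caller requires exactly one motif within the first
   `nTermWindow = 60` residues, an admissible length (`150–800` residues),
   and a Cyc2-family alignment covering at least `ctermCov = 0.40` of the
   C-terminal half of the protein.

### Quantification

Reads are assumed to have been mapped to contigs upstream, so each gene
inherits its contig's mean read depth $c_g$. The normalized abundance of a
gene is

$$A_g = \frac{c_g}{\overline{c}_{hk}},\qquad
\overline{c}_{hk} = \frac{1}{|H|}\sum_{h \in H} c_h,$$

where $H$ is the set of single-copy conserved housekeeping genes of the
same metagenome. $A_g$ is dimensionless, roughly the abundance of the gene
relative to an average genome, and invariant under global rescaling of all
coverages. Metagenome-level panel values are **sums** of member genes'
$A_g$ (per heme bin for MHCs, total for Cyc2); per-MAG values are the
**mean** over that MAG's EET genes, the statistic used for occurrence
reporting. Sums at the metagenome level are the only aggregation under
which the metagenome totals decompose exactly into per-MAG contributions
plus an unbinned remainder, a property the test suite checks. The
housekeeping average uses the arithmetic mean because that is what the
normalization is defined against; a median option
(`denominator = "median"`) exists for outlier-heavy contigs but is not the
default. Denominators are metagenome-wide, not MAG-specific: normalization
is against the average genome of the community, so values are comparable
across MAGs of one metagenome.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `motifSpacers` | `2` | residues | spacer lengths *k* in C-X{k}-C-H; `2` is the canonical CXXCH |
| `mhcMin` | 5 | motifs | minimum heme count for MHC status |
| `emphMin` | 8 | motifs | high-heme emphasis flag |
| `binSplit` | 10 | motifs | boundary between the `5-10` and `>10` bins |
| `minIdentity` | 0.30 | fraction | minimum alignment identity for a family hit |
| `minCov` | 0.50 | fraction | minimum query coverage for a family hit |
| `gapOpening`, `gapExtension` | 11, 1 | score | affine gap costs under BLOSUM62 |
| `hMin` | 7 | residues | hydrophobic run length in the signal-peptide heuristic |
| `nRegionLen` | 45 | residues | N-terminal window searched for the signal |
| `maxGeneGap` | 1 | genes | intervening genes allowed inside a PCC cluster |
| `pccMhcMin` | 5 | motifs | minimum hemes of the periplasmic PCC member |
| `strandRequired` | `FALSE` | — | require porin and MHC on one strand |
| `nTermWindow` | 60 | residues | window for the single Cyc2 motif |
| `ctermCov` | 0.40 | fraction | required C-terminal-half coverage of the Cyc2 hit |
| `cyc2LenMin`, `cyc2LenMax` | 150, 800 | residues | admissible Cyc2 length |

The motif set defaults to the canonical CXXCH only. CX3CH/CX4CH variants
occur in some cytochrome families, and the scanner accepts them through
`motifSpacers`, but they stay off by default because the conservative
motif is the community standard for heme counting; enlarging the set can
only increase counts (a monotonicity the tests assert). Overlapping
matches at distinct start indices are all counted — this is deterministic
and order-independent, so reported heme counts are reproducible
irrespective of scanning order. The three count thresholds (5, 8, 10) are
exposed as first-class configuration because all downstream summaries are
defined in terms of them.

The homology thresholds (30% identity, 50% query coverage) are package
defaults in the twilight-zone tradition of protein homology searching; the
screen gives no thresholds of its own, so these are stated in the
configuration embedded in every report. Users with a profile-based search
stack can bypass the built-in aligner entirely by supplying a precomputed
hit table (`readHitsTable()`), which replaces `searchReferences()`
verbatim.

## The bundled reference panel is synthetic

Pairwise search needs reference sequences for MtrA/B/C, MtoA/B, PioA/B,
OmaB/OmbB/OmcB, OmcE/S/Z, Cyc2, and a generic porin. The panel shipped in
`inst/extdata/eet_references_synthetic.fasta` is **synthetic**: each entry
is a constructed sequence that mimics the documented length, heme-motif
content, and signal-peptide architecture of its family (for example, the
OmaB entry is a 300-residue octaheme with an N-terminal signal region; the
Cyc2 entry carries one motif at residue 23 and a motif-free C-terminal
region). The `source_tag` column records which protein each entry is
modeled on. This keeps the package fully self-contained and makes the
synthetic benchmarks exact, but it means **real-data analyses should
substitute curated sequences** via the `fasta`/`meta` arguments of
`eetReferences()` or the hit-table bypass; the detection logic is
unchanged by the substitution.

The family-to-role map follows the characterized architectures:
MtrB/MtoB/PioB/OmbB are porins; MtrA/MtoA/PioA/OmaB are periplasmic MHCs;
MtrC/OmcB are the extracellular/outer-membrane conduit members;
OmcE/OmcS/OmcZ are outer-surface MHCs; Cyc2 is its own role.

## Localization

Real subcellular-localization predictors are deliberately not
re-implemented. Instead there are two paths, resolved by strict
precedence:

1. an **annotation path** — a TSV of `protein_id, compartment` labels from
   any external predictor, which always wins;
2. a **homology implication** — porin or outer-surface family hits imply
   the outer membrane, extracellular-MHC hits the extracellular space;
3. a **transparent heuristic** — a deterministic signal-peptide rule (a
   basic residue followed by a run of at least `hMin` hydrophobics within
   the first `nRegionLen` residues) mapping to periplasmic, else
   cytoplasmic.

The `evidence` column records which branch fired for every protein, so a
reported compartment is always traceable. For MAGs flagged monoderm
(Gram-positive), secreted MHCs resolved by branches 2–3 are re-mapped to
`cell_wall`, since those cells have no outer membrane; this is how
cell-wall MHC clusters of Gram-positive lineages surface in the reports.

## Numerical and tie-breaking choices

* **Coordinates** are 0-based half-open internally; GFF3 I/O is 1-based
  inclusive. Gene `rank` (ordinal position on the contig by ascending
  start) drives the cluster window arithmetic, making "within one
  intervening gene" unambiguous.
* **Cluster assembly is greedy leftmost**: porins are visited in rank
  order, each pairs with the nearest unused qualifying MHC (ties broken by
  smaller start coordinate), and each gene joins at most one cluster. On
  tandem arrays this gives a deterministic, order-independent partition.
* **Local alignment** uses Smith–Waterman under BLOSUM62 with affine gaps
  (a gap of length $L$ costs $11 + L$). When nothing scores above zero the
  hit is empty with score 0. Identity is identical residues over alignment
  columns including gaps. Co-optimal alignments exist; the reported
  statistics are defined against the reported traceback.
* **Strandedness** is not required within clusters by default
  (`strandRequired` exists): the organization signature is described at
  the operon level, but gene callers and assemblies disagree often enough
  about strand context that the permissive default loses fewer true
  conduits than it admits false ones, and decoy-based precision is
  testable either way.
* **Determinism**: identical inputs and configuration produce
  byte-identical report files; every report embeds the resolved
  configuration and input checksums.

## What the synthetic generator emulates — and what it does not

`generateSyntheticMetagenome()` builds multi-contig assemblies with planted
ground truth: MHCs with exact heme counts on motif-free backgrounds
(rejection-sampled from a C/H-depleted residue distribution, then certified
by an independent re-scan), known-family PCC operons planted as mutated
reference homologs with motif positions frozen (target identity 0.75),
novel-organization operons from non-homologous porin-like/MHC pairs,
Cyc2-like genes, four decoy types (4-heme near-MHCs, lone porins, lone
MHCs without signal peptides, cysteine-rich motif-free proteins),
housekeeping genes, and filler genes. Contig coverage is lognormal
(meanlog 1.0, sdlog 0.5) with MAG-level multipliers (sdlog 0.3), giving
the normalization and additivity tests realistic spread. Certification is
by construction plus verification: planted counts are re-scanned, and
planted proteins that must not match the panel are aligned against it with
offenders resampled — so precision = recall = 1.0 is a hard expectation on
generator output, not an approximation.

`simulateStudy()` arranges three such metagenomes with EET-content
multipliers 1:2:4 (ME-, TE-, TH-like), emulating an oxic clear-water
epilimnion, a humic-bog epilimnion, and a humic-bog hypolimnion. The base
per-metagenome content (5 outer-surface MHCs, 2 known and 2 novel PCC
operons, 5 Cyc2 genes, 24 housekeeping genes) was chosen once so that,
under the coverage noise above, the expected separation between adjacent
density levels exceeds two standard deviations even for the smallest panel
— which makes a correct three-way ranking on all three panels the typical
outcome while leaving genuine stochasticity in play.

The generator does **not** emulate: real phylogenetic sequence divergence
(mutants are i.i.d. point substitutions), compositional biases of real
proteomes, sequencing error or assembly artifacts (inputs are perfect gene
calls), chimeric contigs or binning errors, variable gene density, or
real signal-peptide diversity. Consequently, passing the planted-truth
benchmarks demonstrates that the *logic* of the callers is exact under the
stated rules — it does not estimate sensitivity or specificity on real
metagenomes, where remote homology and localization prediction dominate
the error budget.

## Problem sizes used by the test suite

The shipped tests exercise: motif-scanner/oracle equivalence on 1,000
random proteins of up to 1,000 residues; alignment/oracle equivalence on
200 pairs of up to 60 residues (the quadratic-time oracle is the
bottleneck, so pairs stay short); the full default benchmark metagenome
(~350 proteins, 50 planted MHCs including the 5/8/10/11/51 heme counts,
five operons of each PCC type, five Cyc2 genes, 32 decoys); and ten
replicate three-metagenome gradient studies. These sizes are the package's
own trade-off between coverage and a test suite that stays pleasant to run
interactively.

## Known limitations

* Heme counting treats every CXXCH as a heme site; active-site variants
  (e.g. CXXCK) and spacing constraints beyond the configured set are not
  modeled.
* The Cyc2 porin-fold requirement is operationalized as C-terminal
  homology coverage, not de novo beta-barrel prediction; distant Cyc2-like
  proteins with diverged C-termini will be missed unless supplied through
  the hit table.
* Conductive pilins (e-pilins), archaeal EET systems, and Gram-positive
  conduit complexes beyond cell-wall MHC flagging are out of scope.
* Per-gene read coverage is inherited from contigs; genuinely per-gene
  coverage tables can be supplied but are not computed here, and read
  mapping, assembly, and binning are upstream of this package.
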