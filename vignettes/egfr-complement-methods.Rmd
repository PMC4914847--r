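---
title: "Methods: rule-based EGFR-pathway complement inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based EGFR-pathway complement inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EGFRcomplement)
```

## The model

This package re-implements, as a tested pipeline, a comparative survey of the
epidermal growth factor receptor (EGFR) pathway across animals. The survey has
three computational layers:

1. **Domain-architecture classification.** A protein is an *EGFR* when it has
   a cytoplasmic tyrosine-kinase (TK) domain, at least one transmembrane (TM)
   segment, and at least one cysteine-rich cluster N-terminal of the first TM
   (the ligand-binding ectodomain). A protein is an *EGF ligand* when it is
   full length, carries exactly one EGF motif, and has at most two TM
   segments; ligands with an immunoglobulin I-set domain plus a TM are
   *NRG-type* (neuregulin-like), the rest *EGF-type*. Everything else is
   rejected with a machine-readable reason.
2. **Similarity clustering of the ligands.** All-vs-all Smith–Waterman scores
   form a threshold graph whose connected components test the claim that
   NRG-type ligands form one coherent cluster while EGF-type ligands disperse.
3. **Ancestral-state reconstruction.** Presence/absence characters are
   reconstructed by Dollo parsimony (single gain, minimal losses); copy-number
   characters by Sankoff parsimony with a linear cost, yielding the ancestral
   complement at the metazoan and bilaterian roots plus per-edge gains,
   losses, expansions and contractions.

The original survey's database searches against dozens of genome and
transcriptome resources are not reproducible at desk scale. Instead, the
package bundles the survey's published species-by-complement tables
(`combineComplements()`) and a fixed 35-species tree
(`bundledSpeciesTree()`), and a **deterministic synthetic-proteome
generator** that instantiates each table row as sequences with the stated
domain architecture. The end-to-end claim is a round trip: generate →
scan → classify must reproduce every printed per-species count exactly.

## What the generator emulates — and what it does not

`generateProtein()` concatenates sequence *templates* for each declared
element (signal peptide, cysteine-rich cluster, EGF motif, Ig I-set tag, TM
segment, TK domain), separated by random linkers. The design goal is
*scanner-exact planting*: every scanner fires exactly on the planted elements
and never on background. This is achieved by construction, not by tuning:

- linkers draw from a 14-letter alphabet without cysteine or strongly
  hydrophobic residues, and are resampled until they contain no glycine-loop
  pattern and no hydrophobic window that could fake a TM or signal peptide.
  The alphabet is deliberately wide: a narrow alphabet would manufacture
  low-complexity similarity between unrelated proteins that real sequences do
  not share, distorting the clustering layer;
- template-internal spacers additionally exclude glycine (no spurious kinase
  glycine loop) and arginine (no spurious HR[DN] catalytic motif);
- consecutive cysteine-rich clusters are separated by 90 residues so windowed
  cluster detection cannot merge them;
- the Ig I-set element is one fixed 90-residue tag recognized by mismatch
  counting (at most 10%), standing in for profile-based domain detection,
  which is out of scope. Because every NRG-type fixture carries the identical
  tag, NRG-type ligands are guaranteed to exceed the clustering threshold
  pairwise — the synthetic analogue of their conserved Ig domain.

These are synthetic study conditions, not biology: real proteomes contain
divergent domain instances, compositional bias, and fragments. The fixtures
only claim that *if* a proteome contains proteins with the published
architectures, the rules recover the published complement.

## Scanners and their parameters

All scanners use 1-based inclusive residue coordinates.

| Parameter | Default | Rationale |
|---|---|---|
| EGF motif spacing | `C-x(3,14)-C-x(3,7)-C-x(1,16)-C-x(1,2)-C-x(4,15)-C` | the canonical six-cysteine spacing envelope of EGF modules |
| TM window / threshold / min length | 19 / 1.6 / 15 | classical Kyte–Doolittle windowed hydropathy for membrane spans |
| SP stretch / threshold / latest start / search window | 8 / 2.0 / 11 / 35 | signal peptides are short N-terminal hydrophobic cores |
| Cys-rich window / min cysteines | 60 / 6 | elevated cysteine density outside EGF/TK hits |
| TK motifs | `G-x-G-x-x-G`, `[LIVMF]A[IV][KR]`, `HR[DN]`, `[DN]FG`, span 200–350 | glycine loop plus the three catalytic positions in kinase order |
| Ig tag mismatches | ≤ 9 of 90 | 10% divergence tolerance on the fixed tag |

The EGF scanner is greedy left-to-right with a shortest-match tie-break; the
kinase audit reports, per catalytic position (VAIK lysine, HRD aspartate, DFG
aspartate), whether the canonical residue is present — any substitution marks
the domain `INACTIVE` (a pseudokinase, as in human ErbB3). Threshold
comparisons carry a `1e-9` tolerance so windows whose true mean equals the
threshold are not dropped by floating-point rounding (achievable means differ
by at least 0.1/window, orders of magnitude more).

## Clustering

`pairwiseScores()` computes Smith–Waterman local alignments (BLOSUM62, gap
open 11, extension 1). Because BLOSUM62 is a half-bit matrix, the default
`BITS_PER_SHORTER` normalization is `(raw / 2) / length(shorter sequence)`,
and the default threshold is **0.5 bits per residue**. This replaces the
original P-value cutoff of a PSI-BLAST/CLANS analysis, whose statistics are
out of scope; it preserves the qualitative contrast (one NRG component,
dispersed EGF-type components) without reimplementing them. The threshold is
exposed in the API and CLI. Component numbering is deterministic
(lexicographically smallest member), invariant to input order, and raising
the threshold can only refine the partition.

## Parsimony

`dolloReconstruct()` places the single gain at the most recent common
ancestor of all possessing taxa and one loss on the root edge of every
maximal character-free subtree below it — the unique minimal-loss solution
under the single-gain constraint. `sankoffCounts()` runs the standard
dynamic program over states `0..maxCount` with cost `|parent − child|`
(configurable via `costMatrix`), breaking ties toward the smaller ancestral
count — a conservative-ancestor convention that must be kept in mind when
reading borderline nodes. Polytomies are handled natively; the bundled tree
keeps published uncertainties (for example within Xenacoelomorpha and
Platyhelminthes) as polytomies rather than inventing a resolution.

Both algorithms are validated against brute-force oracles in the test suite:
Dollo against exhaustive minimal-loss search over every rooted topology on
4–5 tips plus random 6–8-tip trees, Sankoff against exhaustive assignment
enumeration on trees up to 6 tips — problem sizes chosen so the oracles stay
exact yet fast.

## Data notes

Two judgment calls in the bundled data deserve flagging. First, one surveyed
species appears in the receptor table but not in the ligand table; its ligand
counts are recorded as zero in the combined matrix so that the character
matrix stays complete. Second, receptor rows with unknown per-gene details
(`?` entries) take clade-typical values (one TM, signal peptide present,
three cysteine-rich clusters); these defaults affect only fixture
architecture, never the published counts being reproduced.

## Worked example

```{r example}
fx <- speciesFixtures("S. mediterranea")[[1]]
records <- generateSpeciesSet(fx, seed = 1)
calls <- classifyProteins(records)
table(calls$category)
```

```{r ancestral}
tree <- bundledSpeciesTree()
chm <- characterMatrixFromComplements(combineComplements())
scen <- scenarioReport(tree, chm)
scen$rootComplement
```

## Limitations

- Scanners are rule-based stand-ins for InterProScan/SignalP-class tools;
  they are exact on the synthetic fixtures and have no claimed sensitivity or
  specificity on real proteomes.
- The Ig I-set detector matches one fixed tag; it cannot find real I-set
  domains.
- Clustering uses normalized alignment scores, not alignment statistics;
  thresholds are not comparable to BLAST E-values or P-values.
- Parsimony reconstructions inherit the fixed topology; alternative published
  topologies (for example a different placement of Xenacoelomorpha) would
  change node assignments.
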