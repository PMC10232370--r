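---
title: "From RNA-binding landscapes to RIBOTAC degrader candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RNA-binding landscapes to RIBOTAC degrader candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotriage)
```

## The problem this package addresses

Most small molecules that bind a structured RNA do nothing to it: occupancy
alone rarely perturbs function unless the binding site happens to be a
functional element such as a Drosha or Dicer processing site in a miRNA
hairpin. A ribonuclease-targeting chimera (RIBOTAC) converts such a
biologically silent binder into a degrader by conjugating it to a
heterocycle that recruits and locally activates RNase L, which cleaves RNA
preferentially at UNN trinucleotides whose leading U is unpaired. Whether a
silent binding site is convertible therefore becomes a geometric question:
is there a suitable cleavage site close enough along the hairpin stem?

`ribotriage` implements that computational triage as a pipeline of five
stages, each usable on its own:

1. **Motif model** — parsing, classification and canonical identity of
   two-strand RNA structural motifs (internal loops, bulges), and their
   extraction from dot-bracket hairpins.
2. **Selection library** — enumeration of the 3+3 randomized internal-loop
   cassette (4,096 folds) and per-member motif-class profiling.
3. **Selection statistics** — the pooled two-proportion enrichment
   statistic `Z_obs` on selected-versus-input read counts, bound-motif
   calls, LOGO matrices and motif-class enrichment tests.
4. **Mapping and triage** — bound motifs located in a hairpin structure
   database, annotated functional or silent, and silent sites paired with
   RNase L sites under a stem-distance rule.
5. **Chemistry** — Tanimoto novelty against reference binder sets,
   physicochemical descriptors and scaffold classes.

A synthetic-data module generates every input with planted ground truth, so
the whole pipeline is testable end to end without any external resource.

## The motif model

A structural motif is written in the field's two-strand loop notation: the
top strand 5'→3', the bottom strand 3'→5', aligned column by column, with
`_` marking a gap. The two terminal columns must be closing base pairs;
everything between them is loop. GU wobble counts as paired everywhere —
the motifs of interest themselves require it (a U·G closing pair is
perfectly ordinary).

```{r motifs}
parse_motif("5'GAU/3'C_A")    # an A bulge: the archetypal silent site
parse_motif("5'UUCG/3'ACCC")  # a 2x2 internal loop
parse_motif("5'UUU/3'GUCA")   # asymmetric loop written without gaps
```

Design choices worth making explicit:

* **Unpairedness is structural, not typographic.** Print conventions mark
  loop nucleotides in bold; plain text cannot. Here the terminal columns
  are closing pairs and every interior position is loop, which is
  unambiguous and testable.
* **Canonical orientation.** Which strand is "top" is arbitrary on a
  transcript, so each motif is reduced to a canonical reading before
  comparison: interior nucleotides are left-aligned within the interior
  (gaps pushed right), and of the two strand-swap readings the one with
  fewer gaps on the top strand wins, ties broken lexicographically. The
  gap-minimal rule keeps the conventional bulge writing (`5'GAU/3'C_A`
  rather than `5'A_C/3'UAG`) canonical. `motifs_equivalent()` is exactly
  equality of canonical keys, which makes it an equivalence relation by
  construction.
* **Class labels** report internal loops as `min x max` (a `1×2 internal
  loop`, not `2×1`), matching how asymmetric loops are described in the
  literature.
* **Coordinates** are 0-based half-open internally and 1-based inclusive in
  every report and file, the conventional split between code and
  biologist-facing output.
* **Asymmetric notation without gaps** (`5'UUU/3'GUCA`) is accepted by
  padding the shorter interior; `pad = FALSE` restores strict equal-length
  parsing.

Extraction (`extract_motifs()`) walks a single hairpin's stem outermost-in:
every non-stacked step between consecutive base pairs becomes an internal
loop or bulge carrying its nearest closing pairs, and the apical loop is
reported once. Pseudoknots and multibranch junctions are out of scope, as
is thermodynamic folding — structures arrive as dot-bracket input (e.g.
from an external folding or structure-scanning tool).

## The selection library

The library cassette displays a 3+3 randomized region between fixed closing
pairs; full enumeration gives $4^6 = 4096$ members, and crossing them with
a 15,000-compound collection gives the 61,440,000 candidate interactions a
library-versus-library screen probes. The exact scaffold sequence of the
original cassette is not public, so the default here is a documented
synthetic scaffold (G·C and C·G closings); the scaffold only matters for
the optional folding backend.

How a member's randomized region folds decides which motif it displays.
The default classifier is a deterministic, dependency-free pairing rule:
aligned columns pair outermost-in while they are WC/GU; a symmetric
leftover whose single-register shift pairs completely is a bulge-containing
member; an asymmetric leftover that pairs after skipping a contiguous block
is a bulge of that size. A thermodynamic backend can be plugged in as any
`function(sequence) -> dot-bracket`. **Class percentages are therefore
backend-dependent**: the rule-based default emits all the expected classes
(1×1, 2×2, 3×3 loops, bulges, fully paired) but its percentages are not
comparable to ones computed under a free-energy model, and the package
deliberately asserts none.

## Selection statistics

Enrichment of motif $i$ is quantified by the pooled two-proportion
statistic

$$Z = \frac{\varphi_\mathrm{sel} - \varphi_\mathrm{in}}
{\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_\mathrm{sel}} +
\tfrac1{n_\mathrm{in}}\right)}},\qquad
\hat p = \frac{k_\mathrm{sel}+k_\mathrm{in}}{n_\mathrm{sel}+n_\mathrm{in}},$$

with $\varphi = k/n$ the motif's read fraction in each pool. The pooled
form is the standard reading of a "pooled population comparison"; the
unpooled variant differs only in the variance term and users who need it
can compare against the permutation null directly. There is no continuity
correction and no pseudocount by default (a +0.5 option exists); depths in
practice are large enough that neither matters. The statistic returns 0
when the pooled proportion is degenerate and is antisymmetric under pool
swap.

A motif is **bound** when $Z_{obs}$ strictly exceeds the threshold
(default 8) — one-sided by design: depletion is not binding. No
multiple-testing correction is applied across motifs; the fixed high
threshold plays that role, and the null simulations below show it is
conservative (no null exceedances of 8 across thousands of simulated
motifs at realistic depth).

LOGO matrices take the top fraction (default 0.5%) of motifs ranked by
$Z_{obs}$, ties broken by lexicographic motif order for determinism, and
tally per-column nucleotide frequencies; the retained count is
`ceiling(top_fraction * n)` and the ranking is per selection (per
compound), not global. Motif-class enrichment uses a two-tailed one-sample
t-test of the per-compound bound-class fractions against the library
background fraction — the compounds are the replicates
($df = n_\mathrm{compounds} - 1$), a choice recorded in the output because
the alternative (resampling motifs) answers a different question.

## Mapping, functional annotation and triage

`build_motif_index()` keys every extracted non-canonically paired motif by
canonical identity, so a library motif matches a transcript motif no matter
which strand was written on top. Mapping a compound→motif table over the
index yields one target site per (compound, location); summaries
deduplicate locations and report both site-level and transcript-level
denominators, since published counts mix the two conventions.

A site is **functional** when its motif span lies within ±2 nt (the
`functional_window`, configurable) of an annotated Drosha or Dicer scissile
position. The window is a design choice — no published definition exists —
reflecting that a motif must effectively occlude the scissile position to
block processing; the planted-window tests pin its semantics (distances 0
and 2 functional, 3 silent).

RNase L substrate scanning reports every UNN whose leading U is unpaired;
`strict = TRUE` additionally requires any other U inside the trinucleotide
to be unpaired. The default is the lenient reading; both are exposed
because the substrate literature emphasizes "unpaired Us" without fixing a
count.

**Stem distance** is counted in base pairs, not nucleotides: loops along a
single hairpin stem are totally ordered by nesting depth, and the distance
between a binding motif and a cleavage site is the number of base-paired
columns strictly between them, *not counting the motif's own closing pair*
(`max(0, |depth difference| - 1)`). A cleavage loop immediately inside the
motif's closing pair is at distance 0; the worked geometry with seven
intervening pairs — mirroring the arrangement in the miR-155 precursor —
measures 7. A silent site is **RIBOTAC-eligible** when its nearest cleavage
site (minimal stem distance, ties to the 5'-most) is at most 10 bp away,
inclusive. Functional sites pass through flagged `bioactive-by-binding`:
their effect does not depend on recruitment of a nuclease. Alternative
(suboptimal) structures are out of scope — one structure per transcript.

## Chemistry

Similarity uses binary structural fingerprints with the Tanimoto
coefficient $|A \cap B|/|A \cup B|$ (defined as 1 when both empty); a
compound is **dissimilar** from a reference set when its maximum similarity
is strictly below 0.7. The fingerprint is OpenBabel's FP2 (1024-bit,
path-based), computed through ChemmineOB and recorded in output metadata;
the similarity logic is fingerprint-agnostic, so any equal-length bitsets
can be supplied. Descriptors are TPSA (standard atom-contribution method),
hydrogen-bond donors and acceptors, with the acceptor definition recorded
(`openbabel-HBA2`).

Scaffolds are ring-system frameworks: iteratively removing terminal atoms
leaves rings plus linkers. Frameworks are compared by graph isomorphism
with atoms coloured by element and saturation (whether the atom carries a
multiple bond), which is invariant to Kekulé phase; bond orders are not
otherwise compared. The coarser *class* level compares the bare skeleton
(all atoms equivalent), merging frameworks of the same shape. Both
groupings are emitted because published scaffold/class counts never specify
their merging procedure; the implementation is deliberately swappable.
Reference binder sets are user-supplied SMILES files — curated databases of
known RNA binders are license-restricted and are not bundled.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
exercised and tested:

* `gen_selection()` draws both pools from multinomials — the input pool
  over uniform motif weights, the selected pool over weights multiplied by
  the planted fold-enrichments — matching fixed sequencing depth per pool.
  Defaults are a 4,096-motif universe at depth $10^5$ per pool with
  10-fold planted enrichments; null calibrations use depth $10^4$ over
  2,500 motifs.
* `gen_structure_db()` builds hairpins from the outside in: random
  Watson-Crick stem pairs, planted binding motifs (interiors restricted to
  A/C/G), planted UNN cleavage loops (whose top interior U is the only
  unpaired U the construction allows) and a U-free apical loop — so the
  extractors and scanners provably find exactly what was planted, and
  planted stem distances are exact by construction. The default plan mirrors
  the miRNA mapping counts of the motivating analysis: 13 motifs placed 114
  times in 111 hairpins, 33 placements functional, 55 silent placements
  eligible at planted distances cycling over {3, 5, 7, 10} bp, 15 at 12 bp
  (beyond the rule) and 11 with no cleavage site.
* `gen_compounds()` decorates ring-system templates with acyclic
  substituents, making template membership the scaffold ground truth.

Everything is deterministic under a fixed seed (R's Mersenne-Twister; the
generator identifier and seed are recorded in each ground-truth object, and
the session RNG state is left untouched). What the synthetic data does
*not* emulate: sequencing error, PCR amplification bias, read-level data,
folding ambiguity (each transcript has one structure), motif co-occurrence
biology, or realistic miRNA sequence composition. Passing tests therefore
demonstrate the correctness of the triage logic and the calibration of the
statistic under the stated sampling model — not performance on real
sequencing data.

## Numerical choices and degenerate inputs

* Percentages in reports are rounded half-up at the displayed precision
  (`round_half_up()`), the convention consistent with printed figures like
  28.9% and 0.22%; R's default half-to-even would differ on ties.
* `Z_obs` returns 0 (not NaN) for degenerate pooled proportions; empty
  inputs yield empty, well-formed outputs throughout (empty report, all-zero
  summary, no division errors).
* Ties are always broken deterministically: lexicographic motif order in
  LOGO retention, 5'-most cleavage site in triage.
* Problem sizes in the test-suite simulations (2,500-motif null panels,
  100 replicate seeds for recovery, 111-hairpin databases) were chosen so
  binomial sampling error is small relative to the tested tolerances while
  the whole suite runs in well under a minute.

## Known limitations

* Single hairpins only: no pseudoknots, multibranch junctions or tertiary
  interactions; no folding is performed in-package.
* The ladder classifier is a structural rule, not a free-energy model;
  library class percentages are backend-dependent by design.
* The pooled z approximation degrades at very low depth; the permutation
  null (hypergeometric under fixed margins) is the reference in that
  regime.
* Scaffold grouping ignores bond-order detail beyond saturation and treats
  stereochemistry as absent.
* Database-version-dependent quantities (how many real miRNAs carry a given
  motif, etc.) require the real structure databases and are deliberately
  not asserted anywhere.
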