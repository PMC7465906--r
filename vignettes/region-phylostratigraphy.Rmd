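---
title: "Dating mutation-hotspot regions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating mutation-hotspot regions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionstrat)
```

`regionstrat` dates protein regions, not just genes. This vignette
explains the model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The age model

Ages are discrete strata on a nested taxonomy ladder, youngest first:
Mammalia ⊂ Vertebrata ⊂ Eumetazoa ⊂ Opisthokonta. Raw node labels on
gene trees ("Amniota", "Bilateria", "Sarcopterygii", …) are resolved to
a stratum through an extensible label map; an unknown label is a hard
error rather than a silent guess, because a mis-binned label corrupts
every downstream age.

*Gene age* is the stratum of the root of the reconciled gene tree — the
most ancient node of the family, paralogs included. *Region age* is the
stratum of the deepest (closest-to-root) lowest common ancestor of the
reference leaf with any homolog in which the region is conserved. This
"deepest-LCA" operationalisation is what makes paralog evidence work
uniformly: a conserved region in a paralog that split off at Eumetazoa
dates the region to Eumetazoa even if all orthologs outside vertebrates
have lost it. The region is effectively treated as the founder of its
own family. Two consequences are asserted as invariants in the test
suite: the region stratum can never exceed the gene stratum, and adding
a conserved homolog can never make a region younger.

Two edge cases get explicit flags instead of numbers: a region conserved
in no other homolog is assigned the youngest stratum with flag
`reference-only`, and a stratum supported by exactly one leaf is flagged
`single-witness`, so users can emulate manual scrutiny of weakly
supported ancient calls.

## The conservation statistic

Within a risk region some positions are much more heavily mutated than
others, and those positions are the ones that matter functionally. The
per-homolog conservation call therefore weights positions by their
missense counts: with reference residue $r_i$, homolog residue $h_i$ and
missense count $m_i$ at region position $i$,

$$f_h = \frac{\sum_{i\,:\,s(r_i,h_i)\ \ge\ 0} m_i}{\sum_i m_i},$$

where $s$ is the BLOSUM62 score and gap columns never count as similar.
The region is conserved in homolog $h$ iff $f_h > 0.5$ — strictly, so an
exact 50/50 split is *not* conserved. A region with zero missense weight
in the table gets $f_h = 0$, not-conserved, and a `no_weight` flag
rather than a division by zero; such regions are normally removed
upstream by the dataset filter (total missense < 15, or in-frame indel
total strictly exceeding the missense total). `X` and other ambiguity
codes score as non-similar, the conservative choice.

For cohort-level summaries the package also computes region-average
per-position conservation: the fraction of homolog rows similar
(BLOSUM62 mode) or identical (identity mode) to the reference, averaged
over positions whose missense count reaches a tier (1, 15 or 25 by
default). Positions are *thresholded* by the tier, not weighted —
weighting is available behind `weight_by_mutations = TRUE` but is not
the default, because the tiers themselves already select the heavily
mutated positions. Since the BLOSUM62 diagonal is strictly positive,
identity implies similarity, and the identity-mode average can never
exceed the similarity-mode average; this is a property test over 1,000
random alignments.

## Alignment and projection

The built-in aligner is a progressive Needleman–Wunsch–Gotoh: global
pairwise/profile alignment with affine gaps, sum-of-pairs column
scoring, profiles merged in post-order of a guide tree. Defaults are
BLOSUM62 with gap open 11 and extend 1 (the canonical pairing for that
matrix); a gap run of length $k$ costs $11 + k$ per sequence pair, and
profile-level gap penalties are scaled by the product of the row counts
to stay commensurate with sum-of-pairs column scores. The guide tree
defaults to the gene tree's topology — it is always available in this
pipeline and removes a stochastic guide-estimation stage. Dynamic-program
ties are broken deterministically (match > delete > insert), so
alignments are byte-stable across runs. The pairwise score is verified
in the tests against an exhaustive-recursion oracle on short pairs and
against Biostrings' independent dynamic program on longer ones.

No attempt is made to reproduce MAFFT's heuristics; externally computed
alignments can be imported (`import_alignment()`) and take precedence
when supplied. Region projection reads homolog residues off the
reference region's alignment columns, records gaps explicitly (never
skips them), and is inverse-consistent: projecting the homolog interval
back recovers at least the original non-gap columns.

Single-residue hotspots are widened before projection: explicit
functional-unit bounds override; otherwise a symmetric flank of 7
residues (a minimal linear-motif-sized neighbourhood) is used, clamped
to the protein.

## Profile corroboration

Disordered flanks are hard to align, so a second, alignment-free line of
evidence guards against false projections: a gapless log-odds profile
(PSSM) built from the region instances of conserved vertebrate homologs,
scanned exhaustively over each homolog sequence. A PSSM rather than a
full profile HMM is a deliberate simplification: the scanned unit is a
short fixed-length region, so match-state emissions carry essentially
all the signal, and the corroborative role does not warrant indel
states. Columns gapped in more than half the training instances are
dropped; minority gaps reduce the column's effective count. Scores are
$\log_2$ odds against a Robinson–Robinson background with a total
pseudocount of 1.

There is no principled published cutoff for a "hit" in this setting, so
the threshold is calibrated per profile from the training data: 60 % of
the minimum training self-score (configurable). In the tests, training
sequences embedded in random flanks are recovered at the true offset,
while pure background sequences stay below threshold in at least 95 % of
seeded trials. When the alignment-based call and the scan disagree the
verdict is `conflict` — the deterministic stand-in for manual curation —
which age assignment treats as not conserved but which stays visible in
the verdict table and reports.

## Emergence mechanism and fate

Classification relates the region's emergence node $E$ (the defining
node of the region age) to the duplication nodes of the tree, using leaf
verdicts only — presence at internal nodes is never imputed, and no
Fitch-style ancestral reconstruction is attempted.

* No duplication anywhere in the family → **singleton**.
* Nearest duplication $D$ strictly above $E$, presence confined to one
  child clade of $D$: **neofunctionalization** if no speciation
  intervenes between $D$ and $E$, otherwise **de novo /
  post-duplication**. "Directly after a duplication" needs a window; we
  operationalise it as *zero intervening speciation nodes*, and report
  the intervening count so users can loosen the rule post hoc.
* No duplication above $E$ but at least one at or below it → **de novo /
  pre-duplication** (the region predates those duplications).
* Duplications only in sister clades → **de novo / no duplication
  context**.
* Presence patterns that contradict a single birth at $E$ (carriers in
  both clades of the ancestral duplication, or outside $E$'s clade) →
  **ambiguous**. Under the single-birth parsimony assumption such
  patterns would require two independent births, and resolving them
  automatically would be guesswork.

Fate looks at duplications at or below $E$ whose subtree contains a
carrier: none → `not_duplicated`; all paralog leaves under them carry
the region → `spread_all`; a mix → `partial_loss`. The `partial_loss`
definition is checked in the tests against a brute-force leaf-set
enumeration.

## The synthetic-data generator

`simulate_family()` is first-class, tested code, not a fixture. It
builds a ladder-shaped species tree (defaults: human, mouse, dog /
chicken, zebrafish / fly, hydra / yeast), optionally duplicates a
stratum clade (recorded as an NHX duplication node), and evolves
sequences from the root by i.i.d. per-site substitution: a site mutates
with the per-edge probability of its context and the replacement residue
is drawn proportional to $e^{s(a,b)}$ under BLOSUM62 — biased toward
chemically similar residues, which stresses the similar-vs-identical
distinction downstream. Defaults: 20-residue region, 90-residue flanks,
per-edge substitution probability 0.15 in flanks vs 0.02 in the region
(the region is the conserved island), and a 0.02 per-flank chance of a
short 1–3 residue indel per edge. Indels never enter the region, so the
planted coordinates stay exact while the flanks still stress the
aligner. Before its birth node the region's columns hold
background-composition residues evolved like flanks — unrelated to the
planted region but mutually homologous, giving profile scans a clean
negative class. Loss branches re-randomise the region and evolve it at
the flank rate thereafter.

The four scenario presets place one duplication and the birth node so
that each emergence mechanism arises by construction; the reference
mutation table carries three exact hotspots (30/22/16 missense at region
offsets 3/9/15) over a Poisson(0.3) background, comfortably above the
15-missense retention floor. Rates are deliberately config-exposed
rather than claimed realistic: real disordered regions evolve with
length variation, compositional bias and alignment ambiguity that the
generator does not model, so passing recovery tests demonstrates that
the *inference machinery* is correct under its stated model, not that
real regions are this easy. One RNG stream per family, keyed by
`(seed, family_id)`, makes every family independently reproducible and
whole cohorts byte-identical across runs.

## Problem sizes and numerical choices

The test suite runs the oracle-backed property suites at 1,000 random
instances for the conservation statistics, 120 + 5 short pairs against
the exhaustive alignment recursion (lengths up to 6, plus spot checks at
7–8, over a reduced 4-letter alphabet — full enumeration beyond that is
combinatorially pointless) plus 50 longer pairs against Biostrings, and
the parameter-recovery surface at 50 families per scenario (200
families end to end); the cohort sizes in the unit tests are smaller.
Coordinates are 1-based inclusive everywhere a user sees them;
conversion to other conventions happens only inside alignment
internals. All tie-breaks (alignment traceback, equal-scoring scan
windows, equal-depth LCAs) resolve to the first/smallest candidate, so
every pipeline output is a pure function of inputs and seed.

## Known limitations

* Events are taken from the NHX annotations as given; no gene-tree /
  species-tree reconciliation is performed, and mis-annotated
  duplications propagate into mechanism calls.
* The built-in aligner is quadratic per merge and intended for
  family-sized inputs (tens of sequences), not proteome scale.
* The PSSM stage has no E-value statistics; its threshold is a
  documented calibration, not a reconstruction of any published cutoff.
* Selection evidence is only mapped, never computed: branch-site
  posteriors and MK flags must come from upstream tools.
* Composite regions with internally heterogeneous conservation (a
  conserved motif plus a lineage-specific linker) receive one average
  and one verdict per homolog; the per-position verdict table is the
  place to look when that average hides structure.
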