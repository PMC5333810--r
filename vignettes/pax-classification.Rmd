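---
title: "Identifying and classifying lophotrochozoan Pax proteins"
author: "lophopax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying lophotrochozoan Pax proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lophopax)
```

## The problem

Pax transcription factors are defined by a 128-residue DNA-binding paired
domain (PRD), composed of an N-terminal PAI subdomain (model columns 0–63)
and a C-terminal RED subdomain (columns 64–127). Two further landmarks may
follow the PRD: an eight-residue octapeptide motif (OM) and a ~60-residue
paired-type homeodomain (HD). In Lophotrochozoa (molluscs, annelids,
platyhelminths, nemerteans, brachiopods) six Pax subfamilies are
distinguishable by which of these landmarks are present and by short
family-diagnostic sequence motifs:

| family   | composition                                                   |
|----------|---------------------------------------------------------------|
| Pax1/9   | PRD + H-type OM (`H[ST]V[ST][DN][IL]LG`), no HD               |
| Pax2/5/8 | PRD + Y-type OM (`Y[TS]IX2ILG`) + quadribasic/diacid signal, no HD |
| Pax3/7   | PRD + HD, OM present only in some lineages                    |
| Pax4/6   | PRD + MDKL linker + HD, no OM                                 |
| Paxβ     | PRD + long variable region carrying three conserved motifs    |
| PoxNeuro | PRD with tribasic first-helix signal and a KPKQVAT insertion at the PAI/RED junction, a post-PRD `[VI]PGLSYP[KR][IL]V` motif, no OM, no HD |

Database entries for these proteins are frequently unannotated or
mis-annotated (e.g. Paxβ sequences submitted as "Pax-2-A" or "mucin-5AC"),
and many are fragments lacking part of the PRD. This package mechanises the
identification procedure — locate the domains, check the diagnostics,
assign a family with an explicit confidence tier — and adds the two
downstream steps used to corroborate assignments: Gblocks-style alignment
curation and neighbor-joining trees with bootstrap support and family
monophyly reports. A seventh, divergent class (eyegone) is only ever
*flagged* (`eyg?`), never auto-assigned, because its status cannot be
settled by architecture alone.

## Domain detection

Domains are found by ungapped position-profile scanning. A
`PositionProfile` holds per-column residue frequencies built from a
reference alignment with a pseudocount (default 1): for a column holding
`A,A,C` among three sequences the frequency of `A` is `(2+1)/(3+20)`.
Windows are scored as the mean log-odds per covered column against a
uniform background (1/20); `X`, gaps and unknown letters contribute zero.
Placements may run off either terminus so that database fragments with a
truncated PRD are still found; a placement must cover at least 25% of the
model, and only full-length placements count as `complete`. An HD hit
covering less than half the model is reported as a *partial* HD, which the
classifier distinguishes from an absent one.

The acceptance threshold is data-driven rather than a hand-picked constant:
the mean self-score of the reference sequences minus three standard
deviations. For this rule to be meaningful the reference set must span the
within-family divergence the detector is expected to accept; the bundled
reference alignments therefore include, for every family consensus, three
seeded variants diverged by 8% — comparable to the divergence between
congeneric database entries. With near-identical references the standard
deviation collapses and the threshold degenerates to "only exact copies".

Ungapped scanning (no affine gaps) is a deliberate simplification: the PRD
is strongly conserved, and downstream analyses discard indel-ambiguous
regions anyway. The cost is that insertion-bearing PRDs (e.g. the
Crassostrea Pax6 RED insertion) score lower; the data-driven threshold
absorbs moderate cases.

## The motif language

Diagnostic motifs are written in the bracket notation used in the
literature: literals (`M`), residue classes (`[ST]`), and counted wildcards
(`X2`, equivalently `X_2_`). Scanning counts mismatches per pattern
*element* — a failed class counts one regardless of repeat — and wildcards
never fail. An `X` in the sequence fails literals and classes but matches
wildcards; whether a printed `X` should also match a sequence `X` is not
specified anywhere we know of, and letting wildcards match everything is
the permissive choice. Short motifs (under 10 elements) are matched
exactly (0 mismatches); the 31-element Paxβ motif allows 2, since long
motifs were historically matched by similarity rather than identity. No
published mismatch tolerance exists for these motifs; these defaults are
the package's own and are stored per-motif in the editable registry
(`inst/extdata/pax_motifs.tsv`).

The "quadribasic/diacid" signal of Pax2/5/8 (and the related
quadribasic/quadriacid signal near Paxβ PRDs) is operationalised as a
4-residue run containing at least 3 of K/R — so the KRKH-type run is
accepted — followed by at least two acidic residues within 8 positions of
the run start. Chance basic runs in linkers without the acidic tail are
skipped, not treated as failures. The PoxNeuro "tribasic signal in the
first helix" is searched within the first 20 PRD columns, since helix
boundaries are not printed but the first helix lies in the PAI N-terminus.
The KPKQVAT junction heptapeptide is accepted within ±10 columns of the
PAI/RED boundary (column 64), reflecting that the exon-junction position
is only known approximately.

## Classification semantics

`classifyFamily()` is deterministic: the family whose required evidence is
fully satisfied with no forbidden evidence wins. Several fully satisfied
families are resolved by diagnostic score; when the winner's evidence
contains the runner-up's (Pax4/6 ⊃ Pax3/7) the call is clean, otherwise it
is decorated with `?`. Forbidden evidence is interpreted conservatively:
only accepted hits veto (a chance low-scoring window cannot), and for
Pax2/5/8 both complete and partial HDs veto. A paired domain with no
winning family yields the indeterminate call `"Pax"`; fragments win with
confidence `weak` and a `(f)` decoration, matching the reporting
conventions of curated reclassification tables.

Paxβ requires only 2 of its 3 motifs: sequences genuinely in the subfamily
can lack one motif, and the published examples include a tree-supported
member lacking all three — which architecture alone cannot and should not
confirm. Conversely, a sequence carrying at least two β motifs but *no*
PRD is reported as `"Paxβlike"` (the Biomphalaria case). Duplicated PRD
configurations (a second, possibly partial, high-scoring PRD copy) raise
the `eyg?` flag for manual or tree-based review.

## Alignment curation

`filterAlignment()` reimplements the published block-filtering parameters:
minimum block length 10, no gap positions in the final alignment, rejection
of segments with more than 8 contiguous non-conserved positions, and an 85%
flank threshold. Columns are classified by modal residue frequency:
`gap` (any `-`), `highly_conserved` (≥ 0.85), `conserved` (> 0.5, the
canonical "more than half" rule, exposed as `conservedFraction`), else
`nonconserved`. Rules apply in a fixed order: gap columns and adjacent
non-conserved columns are dropped; long non-conserved runs are rejected;
candidate blocks are trimmed to begin and end on highly conserved flank
columns; short blocks are discarded. This order makes the filter idempotent
(curating a curated alignment is a no-op), which the test suite checks on
randomized alignments alongside equivalence with an independently written
rule-by-rule oracle. Identity-based conservation only — similarity groups
and the "with half" gap mode are out of scope, so bit-for-bit agreement
with any particular Gblocks binary is not claimed, only the stated
parameters.

## Trees, supports, monophyly

The tree stage substitutes distance methods for maximum-likelihood
inference: p-distances with pairwise deletion (gaps and `X` excluded), an
optional gamma correction `d = α((1−p)^{−1/α} − 1)` using the reference
shape α = 0.716 estimated on comparable curated data (an invariant-sites
proportion of 0.088 is carried as a documentation constant only), and
neighbor joining with two tidy-ups: negative branch lengths are clamped to
zero with the deficit moved to the sister edge, and zero-length internal
edges become polytomies (an all-zero matrix yields a star tree). Supports
come from 100 seeded column-resampling replicates; branches below 50% are
collapsed. Reports label these values "bootstrap (NJ)" — they are not
comparable to likelihood-based aLRT values. Family monophyly is a split
test on the unrooted tree (members form a clade on *some* rooting);
indeterminate leaves are excluded before testing, singleton families are
skipped, and intruding taxa are listed for non-monophyletic families.

## The synthetic benchmark

Because the original database snapshots cannot be redistributed, every
stage is exercised on generated Pax-like proteins with planted, labelled
architectures. The per-family PRD consensus sequences are synthetic
stand-ins: one master 128-mer diverged independently per family (~8%
substitutions each, hence ~15% between families — enough to separate
families while keeping the PRD recognisable as one domain), with the
PoxNeuro landmarks written into its consensus. The KPKQVAT junction is
written across columns 62–68 as a substitution rather than an insertion,
preserving the fixed 128-column model that ungapped scanning relies on.
Real reference alignments can be dropped in via the `profiles` arguments.

Generator defaults emulate a curated lophotrochozoan collection: all six
families, 5% point mutations (within-family divergence), 20% fragments
(truncated at a uniform position inside the PRD — database fragment rates
are in fact higher still), uniform-composition linkers of 10–40 residues,
and a single seed from which all randomness flows (identical
configurations give byte-identical FASTA). Mutations spare a 2-residue
guard at the ends of each planted element so that planted coordinates stay
well-defined for recovery tests; interior positions of motifs do mutate,
so diagnostic evidence degrades realistically with the mutation rate.

What passing these benchmarks shows — and what it does not: the synthetic
data have no indels, no composition bias, no alternative-splicing isoforms
and no genuinely ambiguous architectures, so perfect recovery at zero
noise and high recovery at 5% establishes the correctness of the
machinery, not the field performance of the thresholds on real databases.
Problem sizes in the shipped tests and acceptance script (30–54 records,
100 bootstrap replicates, ≤15×60 random alignments) were chosen as the
smallest sets that exercise every rule; all scale linearly if increased.

## Known limitations

* No affine-gap profile alignment; strongly insertion-bearing PRDs can
  fall below threshold and surface only as fragments or indeterminate
  calls.
* The percent-identity convention (both-gap columns excluded, single-gap
  columns count as mismatches, `X` never matches, half-up rounding) is one
  concrete choice among several; published identity values computed under
  unknown conventions may differ by a point.
* eyegone is detected only as a flag; confirming it requires trees and
  manual review.
* Chordate-specific architectures (partial-HD Pax2/5/8, OM-bearing
  PoxNeuro) are documented but deliberately outside the rule set, which
  targets lophotrochozoan sequences.
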