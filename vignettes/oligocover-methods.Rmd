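---
title: "Methods: in-silico oligo coverage evaluation for EBPR taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico oligo coverage evaluation for EBPR taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocover)
```

## The problem

FISH probes and universal PCR primers are the instruments through which
EBPR communities are observed, and each instrument has a transfer
function: the set of 16S rRNA reference sequences it actually matches.
`oligocover` computes that transfer function against annotated reference
databases and summarizes it as coverage (fraction of a target taxon
matched), specificity (out-group sequences matched, by taxon), probe-mix
union coverage and Venn partitions, and blind-spot lists.

## Matching model

All matching is ungapped, full-length window scanning on the deposited
(gene-sense) strand, with per-position semantics chosen to mirror a
TestProbe-style "0 mismatches, 0 N's" evaluation:

* a subject symbol **matches** an oligo symbol iff the subject's IUPAC
  expansion set is a subset of the oligo's. Oligo-side degeneracy always
  expands (515F's `Y` accepts `C` or `T`); subject-side ambiguity only
  matches when every base it could be is acceptable (`Y` in the subject
  matches `Y` or `N` in the oligo, not `C`);
* a literal subject `N` is never a match. It is counted separately and
  consumed by the subject-N allowance (`max_subject_n`, default 0), not by
  the mismatch budget (`max_mismatches`, default 0). This keeps
  low-quality, N-rich deposits from passing as binders while still letting
  the user admit them explicitly;
* every other non-match consumes the mismatch budget.

FISH probes hybridize to the rRNA, so they are complementary to the
deposited sequence; the default orientation therefore scans
`reverse_complement(probe)` against the subject. Because the convention of
the original web tools is not documented, `as_is` and `both` orientations
exist behind `scan_policy()`, but the default follows the biochemistry.
Coordinates are 0-based half-open throughout; a sequence with multiple
binding sites counts once in every statistic.

The scanner deliberately replaces a BLASTn-short route: for full-length,
ungapped, 0-mismatch hits the exhaustive window scan is equivalent, and
gapped or partial hits are intentionally out of scope. Equivalence with a
position-by-position brute-force matcher (an independent implementation
from the expansion-set definition) is asserted over tens of thousands of
randomized cases in the test suite, and agreement with
`Biostrings::matchPattern` is checked on concrete-base patterns.

## In-silico PCR and the 27F rule

A primer pair amplifies a sequence iff the forward primer matches the
sense strand, the reverse primer's reverse complement matches strictly
downstream without overlap, and the spanned interval is inside the pair's
amplicon length bounds. The default bounds `[50, 2500]` only suppress
pathological distant pairings; the shipped pair table carries tighter
per-region brackets (e.g. 250–600 nt for V4–V5).

Reference databases contain 5'-truncated deposits that lack the 27F primer
region entirely. Counting those as amplification failures would conflate
database artifacts with primer blind spots, so 27F-containing sets support
three modes: `apply_rule` (the default) detects the primer region within
the first 25 nt at a budget relaxed by +2 mismatches and removes
non-evaluable sequences from the denominator (logging the count);
`skip_27f_sets` marks the sets `not_evaluated`, the right convention for
databases whose deposits are uniformly primer-clipped; `ignore` applies no
correction. The 25 nt window and +2 relaxation are this package's
operationalization of an otherwise informal omission rule — they are
arguments, not constants, and the relaxed budget exists so that the region
is recognized even in sequences the strict scan would fail.

## Coverage statistics

Coverage is `100 * n_hit / n_total` rounded **half-up** to one decimal;
half-up is fixed (rather than banker's rounding) so that published-table
arithmetic is bit-reproducible. An empty target group yields an undefined
(`NA`) coverage, never 0, to avoid fabricating coverage for absent taxa.
Non-target hits are aggregated by the out-group sequence's lowest
available rank label, matching how such results are narrated (genus where
present, placeholder labels like `midas_g_94` otherwise). Venn partitions
are exact subset partitions (all 2^k regions, including "none") and are
refused above six oligos, where a pairwise co-coverage matrix is the
honest summary.

The copy-number correction divides relative abundances by per-taxon 16S
gene copy numbers and renormalizes; it preserves the simplex and is
invariant to uniform scaling of the copy numbers, and a missing copy
number is a hard error rather than a silently assumed default.

## Taxonomy refinement

Pairwise identity is defined on the optimal global alignment under fixed
scoring — match +1, mismatch −1, linear gap −2, traceback ties resolved
toward the upper-left (diagonal, then up, then left) — with the identical
aligned positions divided by the shorter sequence's length. The
denominator convention follows CD-HIT, since the clustering it feeds is
CD-HIT-style: sort by descending length (ties lexicographic by id), take
the longest unassigned sequence as centroid, absorb every unassigned
sequence at identity ≥ cutoff, repeat. This makes clustering deterministic
and lets a brute-force re-derivation from the full identity matrix serve
as an oracle in the tests. 98.7% (species boundary) and 94.5% (genus
boundary) are defaults, not constants.

Where the original workflow confirmed taxonomy by building
maximum-likelihood trees and inspecting them, this package substitutes
nearest-reference assignment: a query takes the label of its
highest-identity confirmed reference if that identity reaches the genus
cutoff, and is `unassigned` otherwise (ties break to the
lexicographically smaller reference id; abstention is monotone in the
threshold). This is a deliberate simplification — sufficient to build
explicit-id target groups for coverage runs, and honest about not being a
phylogeny. Clade-level curation that required externally derived reference
sequences is accepted as an input table, not bundled.

## The synthetic generator

`generate_synthetic_db()` emulates what the downstream statistics need
from a reference database, with exact planted truth:

* several taxa diverged ~10% from a common root (well past the genus
  boundary), members within 1.3% of their taxon ancestor (inside the
  98.7% species boundary), lengths 1200–1500 nt — the shape of a
  full-length 16S reference set;
* probe sites planted as the reverse complement of the probe with
  degenerate positions resolved uniformly at random, so subject-side
  realizations exercise the expansion semantics; primer-pair sites planted
  at distances inside the amplicon bounds, 27F-type forward sites at the
  5' terminus;
* optional subject-`N` injection (outside planted windows) and an exact
  fraction of 5'-truncated records (probe sites are placed downstream of
  the truncation point, so truncation destroys exactly the 5'-anchored
  primer sites — which is the phenomenon the 27F rule exists for);
* a post-hoc self-check re-scans every emitted sequence with the package's
  own scanner and rejection-resamples any sequence carrying an accidental
  site, so the planted binder and amplifiable sets are exact rather than
  probabilistic.

What the generator does **not** emulate: 16S secondary structure and
conserved-region architecture, chimeras, taxon-specific GC skew (uniform
base composition by default), or realistic taxonomy depth (paths are
root + taxon). Consequently, passing planted-truth tests demonstrates the
correctness of the counting machinery, not the biological coverage values
of any real probe; real-database numbers come only from running the real
databases (see `analysis/07_full_silva_reproduction.R`).

One interaction worth knowing: planted sites sit at independent random
positions per sequence, so heavy planting adds apparent divergence between
same-taxon members. Refinement analyses therefore use site-free synthetic
databases; site planting and clade-structure evaluation are separate
concerns.

## Problem sizes and determinism

The shipped tests run entirely on synthetic data: scanner-oracle
equivalence on 10,000+ randomized cases (oligos 15–25 nt, subjects up to
a few hundred nt, budgets 0–2), planted-truth recovery on 50 seeded
databases of 25 full-length sequences across three taxa, clustering
oracles on sets of 80–100 sequences of 300–450 nt, and 100 reference-
assignment queries at 2% divergence — sizes chosen to exercise every code
path while keeping the default suite in the low minutes. All randomness
flows from explicit seeds; two runs with identical config produce
byte-identical outputs (reports are sorted, files written in binary mode,
and the run manifest records config and database checksums).

## Known limitations

* No thermodynamics: formamide percentages are carried as metadata only;
  a 0-mismatch match is not a hybridization guarantee.
* No gapped or partial matching; an oligo longer than its subject simply
  does not bind.
* Nearest-reference assignment is not a phylogeny and inherits the
  quality of the supplied confirmed references.
* The published table this package's fixtures derive from contains four
  internally inconsistent rows (GAO431, GAO989, Actino-658, Bet135 on
  SILVA); the package follows the hits/group-size definition and flags
  the discrepancy rather than matching both numbers.
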