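---
title: "Switch-junction breakpoint calling and classification: methods"
author: "switchjunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-junction breakpoint calling and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchjunc)
```

## The problem

During immunoglobulin class switch recombination (CSR), AID-initiated
double-strand breaks in the donor switch region (Sμ, the *bait*) are joined to
breaks in an acceptor switch region (Sγ1, the *prey*). The structure of the
junction records which repair pathway formed it: classical non-homologous end
joining favours *blunt* joins, while alternative end joining leaves
*microhomology* (MH, an uninterrupted stretch of sequence shared by both
flanks) or templated/untemplated *insertions*, often with flank *deletions*
and point *mutations*. In LAM-HTGTS-style junction sequencing, every read
begins at a fixed nested primer in Sμ and crosses one junction into Sγ1.

Two complications shape the analysis. First, hybrid mouse strains carry two
switch-region haplotypes (C57BL/6 and S129) whose fixed sequence differences
must never be scored as mutations; the pipeline therefore aligns the two
haplotypes once into a *dual reference* and matches reads against per-column
allele sets ("100 % identity with either background is not a mutation").
Second, non-recombined germline amplification products contaminate the
library; they are recognised in silico by bait-contiguity and by the AflII
site that lies between the primer and the break zone (germline products
retain it; recombined junctions have deleted it).

## The decomposition model

Each read is decomposed as

    bait-supported prefix [1..e]  (+ optional insertion)  prey-supported suffix [sp..L]

over candidate prey alignment diagonals (found by exact 12-mer seeding on
both strands; minus-strand hits are flagged as inversions and excluded from
summaries). The objective maximised is the **support score**: match +1,
mismatch −1 against the per-column allele sets, every read position counted
at most once, minus an affine penalty (open 5, extend 1) for at most one
reference gap per side (a flank deletion). Overlapping supports
(`sp ≤ e`) are microhomology; the overlap must match **both** references
base-for-base and contributes its length once. Ties break towards longer MH
(the field's "longest uninterrupted stretch of donor/acceptor identity"
convention), then the smaller bait end column, then the smaller prey read
start and prey column, so calls are exactly reproducible.

Two details of this objective are deliberate design choices:

* *Mismatch penalty and single counting.* Scoring matched bases alone (or
  counting the MH tract once per flank) makes the optimum degenerate:
  junction-adjacent chance matches would systematically inflate MH or eat
  insertions. With ±1 scoring and the overlap counted once, a decomposition
  only beats the true one if chance matches outnumber mismatches in the
  re-attributed stretch — which the generator additionally excludes (below).
* *Window-limited analysis, full-prefix scoring.* The 50 bp windows on each
  side of the junction delimit where deletions and mutations are *scored*,
  matching the assay's definition; the decomposition itself is scored over
  the full supported segments, because a window-limited objective is blind to
  how much of the read each decomposition explains.

An exhaustive oracle (`enumerate_decompositions()`, pure R, independent of
the C++ engine) scores every `(e, sp)` pair over every prey offset with the
same objective and tie-breaks; caller-vs-oracle agreement on planted
junctions is part of the test suite.

The per-read calling steps are: primer check (≤ 1 mismatch, else unmapped);
germline test (≥ 90 % of the read matching bait contiguously, or the AflII
site found within the bait-matching span beyond the primer); seeding and
decomposition; then, on the chosen decomposition, flank-gap recording,
per-side background assignment (fewer alterations over the 50 bp window wins,
ties to B6; discordant sides raise `cross_background`, reported but kept) and
mutation calling (window bases outside the allele set at unambiguous
columns, classified `ref>alt` on the top strand of the assigned background).
Junctions with fewer than 20 support-score points on either side are
unmapped.

## Event classes and counting

The junction-point classes partition every call set: `blunt` iff `mh_len = 0`
and no insertion; exactly one of blunt / MH / insertion per junction.
Deletion and mutation are independent booleans, so a junction with MH and a
deletion counts in both classes — the *at-least-one-event* counting rule used
for all class frequencies. A stricter `blunt_perfect` column additionally
requires clean flanks (no deletion, no mutation); it is reported alongside
because the literature sometimes uses "blunt" in that stricter sense, but the
partition definition is what the counting rule and the count invariants
(`n_blunt + n_mh + n_insertion = n_junctions`) rely on.

Insertion lengths are binned 1 / 2 / 3 / ≥4 bp; mutation spectra use the 12
`ref>alt` classes on the top strand, keeping C>T and G>A distinct.

## Statistics

Replicate class percentages are compared with the classical equal-variance
(pooled) Student t-test, two-sided, untransformed (Welch is available behind
a flag). When both groups are constant the degenerate case is handled
explicitly: equal means give statistic 0 and p = 1; different means give an
infinite statistic and p = 0. Cloned-junction MH/insertion counts are tested
with a Pearson chi-square goodness-of-fit (`Σ(O−E)²/E`, `df = k−1`,
upper-tail p); the expected proportions for a mutant come from the baseline's
observed MH/insertion frequencies applied to the mutant's total — the
conventional reading where no expected model is stated. C>T and G>A rates are
summarised as per-junction rates with fold changes versus baseline. All
p-values are reported raw; no multiplicity correction is applied to junction
statistics.

## What the generator simulates

`synthetic_locus_layout()` builds a bait and a prey locus (2 kb each by
default) with the assay's structure:

* the Sμ nested primer (`CACACAAAGACTCTGGACCTC`) planted once near the bait
  5′ end;
* one AflII site (`CTTAAG`) planted downstream of the break zone — so
  germline reads contain it and junction reads cannot — and scrubbed from
  everywhere else a read can reach;
* strain variants shared by both loci, with inter-variant gaps drawn from
  18–34 bp and hard-capped at 45 bp so **every** 50 bp analysis window
  contains at least one variant. This keeps per-side background assignment
  informative for every read, mirroring data in which every junction could be
  assigned to a single allele. (A sparser catalogue would leave a fraction
  of windows uninformative and per-side assignment would fall back to the B6
  tie rule.)
* planted microhomology sites: for each MH length m = 1…12, a bait tract
  copied into the prey locus at two positions with mismatch-enforced
  boundaries. Sharing planted sites across reads keeps a single, consistent
  reference for the whole library (per-read editing of a shared reference
  would let later reads contradict earlier ones). MH lengths are therefore
  supported up to the planted maximum; requesting more raises a simulation
  error.

`simulate_library()` draws, per read: germline status; one strain background
for both sides of the junction (no read mixes backgrounds, matching the
single-allele switching observation); the junction-point class from the
normalised blunt : MH : insertion triple; event lengths; at most one flank
deletion (probability `p_deletion`); window mutations with an explicit
per-class rate model (the per-base probability of class R>b is
`4·mut_rate·w(R>b)`, so doubling a class weight doubles that class's realised
rate); and iid sequencing errors. Reads are single-end 300 bp from the
primer, always spanning the junction with both full windows; fragment length
is carried as an annotation only. FASTQ qualities are constant Q30 and the
same seed reproduces byte-identical outputs.

### Identifiability by construction

The generator's central guarantee is that every emitted truth is the
*unique optimum* of the caller's objective:

* junction boundaries are rejection-sampled so the flanking bases fail
  allele-set matching on the opposite reference (no accidental MH extension,
  insertions pinned at both ends);
* each drawn junction is verified by a local scan that scores every
  alternative breakpoint decomposition on the true diagonals under the exact
  objective and tie-breaks, and is redrawn if any alternative ties or wins;
* flank-deletion placements are verified by a gap-aware version of the same
  scan that replays the caller's one-gap support DP on both sides (all
  shifts, splits and endpoints, including pure downstream diagonals), so a
  gap can be neither absorbed into the junction insertion, nor dodged by
  staying on a frame-shifted diagonal, nor re-attributed across sides;
  placements are also kept clear of variant columns (gap-placement ambiguity
  must not shift content across a variant) and must leave at least one
  variant in the affected window;
* mutations are excluded from the MH tract, the junction-adjacent four
  columns of each flank, and gap-adjacent regions.

These constraints are what make "100 % exact recovery on error-free
libraries" a meaningful, checkable contract rather than a statistical
accident; the price is that the generator slightly under-samples
configurations that would be intrinsically ambiguous for any caller (e.g. a
deletion immediately beside the junction, which is indistinguishable from a
different breakpoint). What passing the round-trip shows about real data is
therefore calibrated: the caller resolves every *resolvable* junction
exactly; on intrinsically ambiguous real junctions it returns the
deterministic tie-break choice.

Features of real libraries the generator deliberately does not model: PCR
duplicates and chimeras, base-quality-dependent errors, paired-end reads,
translocations outside the configured prey locus, and background indel
differences between the strains (columns where one haplotype has a gap are
flagged ambiguous and excluded from mutation calling rather than simulated).

## Default parameters

| parameter | default | rationale |
|---|---|---|
| junction-point rates | WT 27.3 / 50 / 21.1 %; Setx 25 / 45.5 / 29.5 %; Rnaseh2b 26 / 49 / 25 %; DKO 17.7 / 45 / 37.7 % (blunt/MH/ins) | published LAM-HTGTS frequencies where printed; the triple is renormalised at draw time (stored values are kept verbatim); Setx blunt/MH and the Rnaseh2b profile are not printed anywhere and are filled with WT-like values chosen once |
| `p_deletion` | 0.3 | deletion-class frequency is not printed; free parameter, documented |
| `mh_len_dist` | geometric (ratio 0.6) on 1–12 bp | short MH dominates CSR junctions; 12 bp is the planted maximum |
| `ins_len_dist` | mass 0.42/0.27/0.13/… on 1–12 bp (WT); shifted towards 3 and ≥4 bp for DKO, intermediate for Setx | reproduces the reported increase of 3 bp and ≥4 bp insertions in the double mutant |
| `mut_rate` | 0.004 /bp (WT, Setx, Rnaseh2b), 0.006 (DKO) | with the spectrum weights below this doubles the DKO C>T per-base rate (2×) and raises G>A 1.5× |
| `spectrum_weights` | WT: C>T 0.30, G>A 0.30, others 0.04; DKO: 0.40/0.30/0.03 | AID-footprint-weighted spectrum |
| `germline_fraction` | 0.2 | in-silico stand-in for incomplete enzymatic removal |
| `seq_error` | 0.001 /bp | typical post-filter short-read substitution rate |
| `analysis_window` | 50 bp | the assay's junction window |
| `min_flank` | 20 | support-score floor per side; uniqueness at switch-region repeat density |
| `seed_k` | 12 | exact-seed length for prey candidates |
| `max_del` | 15 bp | largest flank gap searched per side |
| `germline_identity` | 0.90 | bait-contiguity threshold; junction reads reach at most ≈ 0.81 under the default geometry |

## Numerical and coordinate conventions

Coordinates are 1-based inclusive column indices of the dual reference
(R/Bioconductor convention); a fixed per-haplotype offset maps to genomic
coordinates. The MH read interval uses the leftmost placement. The
two-haplotype consensus alignment is a global pairwise alignment (match +1,
mismatch −1, gap −2 per base, via Biostrings); background indel columns are
flagged ambiguous and never yield mutation calls. Degenerate statistic inputs
(zero variance, zero expected counts) are handled explicitly as described
above rather than through silent epsilons.

## Problem sizes used by the tests

The shipped test-suite and acceptance analyses use one 2 kb/2 kb synthetic
layout; 500 planted random junctions for oracle agreement; 2,000 reads per
genotype for exact-recovery and class-rate checks; 1,000 + 1,000 reads for
the germline filter; 500 pure-S129 reads for background neutrality; and
20 seeded replicates of 5,000 reads per genotype for the WT-vs-DKO direction
check — sizes at which every binomial check has comfortable power while the
whole analysis stays desk-scale.

## Known limitations

* The caller models at most one reference gap per flank; multi-gap junctions
  would be reported as a single gap plus mutations.
* Real GenBank references are supported through `read_reference_fasta()` and
  `build_dual_reference()`, but gapped (indel-containing) dual references
  degrade gracefully rather than being modelled fully: reads from the
  background with the indel lose diagonal support at those columns.
* Background assignment needs at least one variant in the 50 bp window; with
  sparse natural variant catalogues, uninformative windows fall back to B6
  by the documented tie rule.
* The paper-scale class percentages recovered here are recoveries of the
  simulator's own configured rates (which default to the published
  frequencies); they are not a re-analysis of the original sequencing data.
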