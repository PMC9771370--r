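# switchjunc

Breakpoint calling and classification for immunoglobulin **class switch
recombination (CSR) junction sequencing** reads, with a ground-truth
simulator that makes every stage verifiable.

In LAM-HTGTS-style libraries each read starts at a fixed nested primer in
the donor switch region (Sμ, the *bait*) and crosses one junction into the
acceptor region (Sγ1, the *prey*). The structure of the junction reports the
repair pathway that formed it: blunt joins (classical NHEJ) versus
microhomology (MH) and insertions (alternative end joining), plus flank
deletions and point mutations. `switchjunc`:

* builds a **dual strain-background reference** (C57BL/6 / S129 haplotypes
  aligned once into per-column allele sets) so fixed strain variants are
  never miscalled as mutations;
* decomposes each read into bait segment + junction + prey segment by
  maximising the support score *S* = (matches − mismatches against the
  allele sets, each read position counted once) − (5 + length) per flank
  gap, with the MH tract required to match **both** flanks exactly and ties
  broken towards the longest uninterrupted donor/acceptor identity;
* removes non-recombined **germline products** in silico (bait-contiguity
  or the retained AflII site), flags inversions and cross-background
  junctions, and assigns a strain background per side ("fewest alterations"
  over each 50 bp window);
* aggregates calls into genotype-level **class frequencies** (at-least-one-
  event counting; blunt/MH/insertion partition the junctions),
  insertion-length bins (1/2/3/≥4 bp), top-strand mutation spectra, pooled
  Student *t*-tests on replicate percentages and chi-square
  goodness-of-fit tests on MH/insertion counts;
* simulates FASTQ libraries with exact per-read truth (junction columns,
  MH length, insertion sequence, deletions, mutations) from genotype
  profiles whose default class rates equal published LAM-HTGTS
  frequencies, with every emitted truth verified to be the unique optimum of
  the caller's objective.

The decomposition engine is C++ (Rcpp); an exhaustive pure-R oracle
(`enumerate_decompositions()`) provides an independent check of every call.

## Worked example

```r
library(switchjunc)

layout <- synthetic_locus_layout(seed = 1)
layout
#> <locus_layout: bait 2000 cols, prey 2000 cols, primer 21bp@31, window 50, synthetic>

profiles <- default_profiles()          # WT, Setx, Rnaseh2b, DKO
lib <- simulate_library(profiles$WT, layout, n = 1000, seed = 42)
lib
#> <sim_library: 1000 reads, 194 germline>

calls <- call_reads(lib$reads, layout)
attr(calls, "filter_counts")
#>        ok  unmapped  germline inversion 
#>       806         0       194       0

wt1 <- aggregate_calls(calls[calls$status == "ok", ], "WT", "rep1")
wt1
#> <junction_summary WT/rep1: 806 junctions; blunt 25.2% | MH 53.2% | ins 21.6% (del 28.2%, mut 35.4%)>
```

806 of 1,000 reads are genuine junctions (194 simulated germline
contaminants were filtered); of those, 25.2 % are blunt joins, 53.2 % use
microhomology and 21.6 % carry insertions — the WT profile's configured
rates recovered within sampling error. Comparing genotypes (two replicates
each of WT and the Setx/Rnaseh2b double mutant, 1,000 reads per library):

```r
report <- compare_genotypes(list(wt1, wt2, dko1, dko2), baseline = "WT")
report$class_counts[, c("genotype", "replicate_id", "pct_blunt", "pct_insertion")]
#>   genotype replicate_id pct_blunt pct_insertion
#> 1 WT       rep1              25.2          21.6
#> 2 WT       rep2              25.8          23.2
#> 3 DKO      rep1              16.4          39.5
#> 4 DKO      rep2              17.0          33.5

generics::tidy(report)        # t-tests and GOF tests, broom-style
#>   genotype        class test_name  statistic df      p_value
#> 1      DKO        blunt student_t  20.158719  2 2.451741e-03
#> 2      DKO    insertion student_t  -4.577888  2 4.455203e-02
#> 3      DKO mh,insertion chisq_gof 119.933500  1 6.541731e-28
```

The double mutant shows fewer blunt joins (25.5 % → 16.7 %, pooled *t*,
p = 0.0025) and more insertions (22.4 % → 36.5 %, p = 0.045), and its
MH/insertion junction counts depart strongly from WT-derived expected
proportions (χ² = 119.9, df = 1). `autoplot(report)`,
`plot_insertion_lengths(report)` and `plot_mutation_spectrum(report)` draw
the corresponding figures, and `write_report(report, dir)` emits a versioned
JSON report plus TSV tables.

A command-line wrapper (`inst/scripts/switchjunc`) exposes `simulate`,
`call`, `summarize` and `run-all` subcommands over the same functions.

## Package layout

* `R/refmodel.R` — dual reference, allele sets, locus layout, synthetic
  reference generator
* `R/simulate.R` — genotype profiles, junction truth sampling, read
  synthesis, library writer
* `R/caller.R` + `src/caller_core.cpp` — anchoring, seeding, decomposition,
  germline filter, background assignment, classification, exhaustive oracle
* `R/summarize.R` — aggregation, tests, fold changes, report IO, plots
* `R/cli.R` — subcommand entry point
* `vignettes/switch-junction-analysis.Rmd` — the methods vignette (model,
  assumptions, parameter rationale, limitations)
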