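# m7Gtrac

Analysis toolkit for **TRAC-seq** (tRNA reduction and cleavage
sequencing) profiling of **N7-methylguanosine (m7G)** tRNA modification,
and for the downstream question such experiments ask: does reshaping the
tRNA m7G methylome change which mRNAs are efficiently translated?

The assay chemistry reduces m7G — deposited by the METTL1–WDR4 complex,
canonically at position 46 of the tRNA variable loop — and cleaves the
backbone at the modified base, so read 5′ ends pile up immediately 3′ of
each site. m7Gtrac provides the full computational chain for users of
this assay:

* a **synthetic-data generator** with truth tables (cleavage libraries
  with planted sites, and paired RNC-seq/RNA-seq count matrices with
  planted translation-efficiency shifts plus codon-controlled CDS), so
  every stage is testable without external downloads;
* **alignment and pileup**: ungapped forward-strand alignment to mature
  tRNA references (or SAM import), reduced to per-position `starts`,
  `coverage`, `readthrough` and the **stop fraction**
  `starts / (starts + readthrough)` — the site-level cleavage signal;
* **site calling**: at stop position *j* (site = *j* − 1), a one-sided
  binomial tail against a per-tRNA background (median stop fraction,
  floor 0.001), BH-corrected per library, gated by coverage ≥ 50 and
  stop fraction ≥ 0.10; per-site score = stop fraction, cross-condition
  effect = `log2((s_b + ε)/(s_a + ε))`, ε = 0.001;
* replicate merging, exact condition set algebra (common / unique
  sites), and per-tRNA roll-ups;
* a **PFM motif consensus** of 7-nt windows centred on called sites
  (MEME minimal format out);
* **translation efficiency**: per replicate
  `log2 TE = log2((cpm_RNC + 0.5)/(cpm_RNA + 0.5))`, a variance-moderated
  two-sample test (prior weight d0 = 4), and the conventional
  |log2FC| > 1 & p < 0.05 classification into TE-up / TE-down / other;
* **codon decoding**: anticodon→codon maps (strict Watson–Crick by
  default, wobble opt-in), per-CDS frame-0 counts of codons decoded by
  the m7G-modified tRNA set, rank-sum comparison across TE classes, and
  per-gene codon position tracks (BED);
* a **2^(−ΔΔCt)** qPCR relative-quantification screen;
* a deterministic end-to-end **pipeline driver** with a flat config, JSON
  run manifest and text report (`inst/scripts/tracseq.R` is a thin CLI).

## Worked example

```r
library(m7Gtrac)
res <- runPipeline(defaultConfig(), "demo_out")
cat(readLines(res$results$report_file), sep = "\n")
```

prints (demo scale: 12 tRNAs — 5 modified in both conditions, 2 only
under WDR4 overexpression — 4 × 8,000 reads, 600-gene TE experiment):

```
m7G TRAC-seq pipeline summary
===============================

Sites (venn): common 5 | unique to vector 0 | unique to WDR4_OE 2
Unique tRNA isodecoders in WDR4_OE: 2
Modified tRNAs (any condition): 7
Motif consensus (7 windows): TGAACCN
Differential TE: 30 up, 63 down, 93 changed of 600 tested
m7G-decoded codon set: AAG, TGC
  TE-up    n=  30  median decoded-codon freq 0.2986
  TE-down  n=  63  median decoded-codon freq 0.1442
  other    n= 507  median decoded-codon freq 0.1502
  rank-sum TE-up vs other: p = 4.91e-12
```

Reading this: all 5 sites planted in both conditions are recovered as
common; the 2 overexpression-only sites (planted on tRNA-Cys-GCA and
tRNA-Lys-CTT) appear only in the overexpression condition, and their
anticodons map to the codon set {TGC, AAG}; the consensus around the
called sites recovers the planted degenerate context `TGAACCN`; and genes
whose CDS are enriched for the decoded codons show markedly higher
decoded-codon frequency in the TE-up class (0.299 vs 0.150 median) with a
vanishing rank-sum p — the qualitative coupling between the tRNA
modification layer and translational regulation that the analysis is
built to detect. Reruns with the same config are byte-identical.

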