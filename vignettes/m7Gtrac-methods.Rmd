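---
title: "Methods: TRAC-seq m7G site calling and translation-efficiency analysis"
author: "m7Gtrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRAC-seq m7G site calling and translation-efficiency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m7Gtrac)
```

# Scope and model

m7Gtrac implements the computational chain of a chemical-cleavage tRNA
sequencing (TRAC-seq) experiment: N7-methylguanosine (m7G) residues —
deposited by the METTL1–WDR4 methyltransferase complex, canonically at
position 46 of the tRNA variable loop — are chemically reduced and the
backbone cleaved at the modified base, so that in the sequencing library
the 5' ends of reads accumulate immediately 3' of each modified site.
The package calls these sites from read pileups, summarises the sequence
context around them as a position-frequency-matrix motif, quantifies
per-gene translation efficiency (TE) from paired ribosome-associated
(RNC-seq) and total RNA-seq counts, and links the two layers by counting,
per mRNA, the codons decoded by the m7G-modified tRNA set. A
`2^(-ΔΔCt)` qPCR screen rounds out the toolkit.

Because raw TRAC-seq libraries are bulky and external, every input can be
generated synthetically with known ground truth; the generator is
first-class, tested code, and all recovery claims in the test-suite are
made against its truth tables, never against hard-coded numbers.

## Cleavage geometry and the stop fraction

Chemical scission 3' of a reduced m7G at position $s$ yields a downstream
fragment whose 5' end sits at $s + 1$. After ungapped alignment of reads
to the mature tRNA reference, each tRNA position $j$ receives

* `starts[j]` — reads whose 5' end is at $j$,
* `readthrough[j]` — reads covering $j$ that started before it,
* the **stop fraction** `starts / (starts + readthrough)`,

which estimates the fraction of molecules covering $j$ that were cleaved
immediately 5' of it — the site-level modification signal. A stop
position $j$ is attributed to an m7G at $j - 1$. Stop positions 1 and 2
are never callable: position-1 starts are indistinguishable from intact
5' ends, and are counted as starts at 1 but excluded from testing.

## Site calling

For each library, every stop position $j \in [3, L]$ with coverage at
least `min_coverage` (default 50 reads) is tested with a one-sided
binomial tail
$P(X \ge \mathrm{starts}_j \mid n = \mathrm{starts}_j +
\mathrm{readthrough}_j,\ p = \mathrm{background})$.
The background is estimated per tRNA as the median stop fraction over its
testable positions, floored at 0.001; a per-tRNA background protects
against structure-induced stops that are tRNA-specific, and the floor
avoids degenerate $p = 0$ nulls. Benjamini–Hochberg correction is applied
across all tested positions of the library — at 50,000 reads per library,
uncorrected per-position tests would inflate calls. A site is reported
when additionally its stop fraction reaches `min_stop_fraction` (default
0.10) and the adjusted p-value is below `alpha` (default 0.01). The
per-site **cleavage score** is defined as the stop fraction itself — the
only site-level frequency the assay measures — and the cross-condition
effect as `log2((s_b + 0.001) / (s_a + 0.001))`.

Replicate handling is intersection-by-default: a condition-level site must
be called in all replicates (`min_support` configurable), with scores
averaged over the supporting replicates. Condition comparison is exact set
algebra on `(trna_id, position)`. Because "38 unique modification sites"
and "9 modified tRNAs" are different roll-ups of the same calls, both are
reported: per-site sets and a per-tRNA harbouring table.

An optional mock mode replaces the estimated background with a
no-chemistry control library's stop fraction at the same position; the
default is background-only because treated-only designs are the common
case.

## Alignment

Reads are placed by exhaustive ungapped forward-strand search over every
reference offset (mature tRNAs are 60–120 nt, so genome-scale indexing is
unnecessary); the best placement is the one with the fewest mismatches,
bounded by `max_mismatches` (default 1). Ties across references — common
among isodecoders — are resolved deterministically to the
lexicographically smallest tRNA id and logged, or discarded on request;
ties between offsets on one reference go to the smallest start.
Coordinates are 1-based, fully closed, tRNA-local, forward strand. A
minimal SAM importer (header `@SQ`, columns 1–9, CIGAR M/S; reverse,
secondary and indel records skipped with logged counts) interoperates
with external aligners, and alignments round-trip through the package's
SAM writer to identical pileups.

Positions are plain 1-based sequence indices throughout. Whether a
published coordinate refers to Sprinzl canonical numbering cannot be
resolved without secondary-structure annotation, which is out of scope;
users comparing across tRNA families should keep this in mind.

## Motif

Fixed-width windows (default 7 nt) are extracted around called sites with
the site centred (offset −3, m7G in column 4); the window anchoring is a
convention, exposed as a flag, and the simulator plants its context under
the same convention so round-trips are exact. The motif model is a
pseudocounted (0.25 per cell) position frequency matrix with per-column
information content `2 + Σ p log2 p` bits; the consensus letter is the
column argmax when its probability reaches 0.8, else `N`. For aligned
fixed-width windows a PFM consensus is sufficient and keeps the package
self-contained; no de novo motif discovery is attempted. Output includes
MEME minimal motif format.

## Translation efficiency

Counts are scaled to counts-per-million within each sample, and per
(condition, replicate) pair
`log2 TE = log2((cpm_RNC + 0.5) / (cpm_RNA + 0.5))`. The pseudocount
(0.5 on the CPM scale) keeps low-expression ratios finite and maps
all-zero genes to exactly 0. Genes with mean RNA CPM below 1 are excluded
before testing and reported separately.

Differential TE between conditions uses a transparent moderated
two-sample test: the per-gene pooled variance is shrunk toward the mean
of all per-gene pooled variances with prior weight `d0 = 4`, and the t
statistic gains `d0` degrees of freedom. At `d0 = 0` this reduces exactly
to the pooled two-sample t-test (verified numerically against
`stats::t.test`); moderation prevents tiny-variance artifacts at n = 3.
Classification uses the conventional gate |log2FC| > 1 with raw p < 0.05;
a BH-adjusted column is emitted alongside for users who prefer FDR
control.

## Codon decoding

Decoding maps translate anticodons to codons in the DNA alphabet. The
default is strict Watson–Crick pairing (anticodon → reverse complement;
e.g. Cys-GCA → TGC, Lys-CTT → AAG), because the decoded-codon analyses
are defined on exact partners; wobble mode additionally expands codon
position 3 by the pairing of anticodon position 34
(G → {C, T}, T → {A, G}, A → {T}, C → {G}). Distinct anticodons are
collapsed, so isodecoders of one isoacceptor contribute once.

Per CDS, frame-0 triplets are counted (`ATG` start enforced with a
warning, internal stops warned but counted, the trailing stop excluded
from the total), and the decoded-codon frequency is compared across
TE classes with two-sided rank-sum tests (normal approximation with tie
correction). Frequencies rather than raw counts are compared because CDS
lengths differ by construction; raw counts are also emitted.

# The synthetic-data generator

The TRAC-seq generator emulates: per-molecule cleavage at the planted
site with a per-(tRNA, condition) efficiency; uniform background breakage
per internucleotide bond (default 0.002); emission of both the upstream
(5' end at 1) and downstream (5' end at site + 1) fragments, size-selected
at 15 nt as in small-RNA library preparation; per-base substitution
errors (default 0.001) applied after fragmentation; and a planted 7-nt
IUPAC context (default `TGAACCN`) centred on every site. Under this model
the expected stop fraction at site + 1 equals the cleavage efficiency,
which the truth table records. Fragments are truncated to the requested
library size in molecule order, so truncation never biases the
cleaved/uncleaved ratio. Defaults describe a two-condition
overexpression design: 20 tRNAs, 9 modified in both conditions and 5 only
under overexpression at efficiency 0.5, two replicates of 50,000 reads
per library. Replicate counts and library sizes for such experiments are
rarely reported; these values are fixed, realistic desk-scale choices.

It does **not** model adapter ligation artifacts, PCR duplication,
reverse-transcription stuttering, demethylation side effects, or quality
scores (qualities are constant `'I'`; no stage consumes them). Passing
recovery tests on this generator therefore demonstrates correctness of
the calling chain under the stated noise model, not robustness to every
artifact of real libraries.

The TE generator draws per-gene lognormal baselines (sdlog 1), scales
expected totals to the library depth (default 1e6), and samples negative
binomial counts with dispersion 0.02 — the regime of cell-line replicates,
where gene-wise dispersions typically run 0.01–0.05; under it the
|log2FC| > 1 gate dominates null-gene classification, which is the
intended operating point of the classifier. RNC counts share the baseline
and are multiplied by `2^shift` in the second condition, so the planted
shift is the true log2 TE fold change (defaults: 2% of genes at +2, 10%
at −2, 3 replicates). Each gene receives an in-frame CDS (100–300 codons)
whose usage of a designated codon set (default {AAG, TGC}, the strict
partners of Lys-CTT and Cys-GCA) is 0.30 for TE-up genes versus 0.15
otherwise, planting the codon-enrichment signal the group comparison is
designed to detect. Tissue-level overdispersion, batch effects, length
bias and isoform structure are not modelled.

# Numerical and reproducibility choices

* All randomness flows from one root seed; per-stage and per-library
  seeds are derived deterministically (`seed * 1103 + offset * 7919`
  mod 2^31 − 1), so stages are independently reproducible and pipeline
  reruns are byte-identical.
* Binomial tails via `stats::pbinom`, BH via `stats::p.adjust`; tests
  cross-check the tails against direct pmf summation to 1e-9.
* Degenerate inputs: zero-read libraries produce empty FASTQ with a
  warning; empty site sets propagate to empty tables and a "no sites
  called" report line; one-gene groups report medians with an NA p-value;
  zero-total samples are an error naming the sample.
* U/lowercase in reference FASTA are normalised to uppercase DNA with a
  logged note; non-ACGTU characters are an error naming the record; a
  reference not ending in CCA warns (references are assumed mature — no
  intron removal or tail handling is performed).

## Problem sizes

The shipped demonstration configuration uses 12 tRNAs (5 modified in both
conditions, 2 overexpression-only), 2 × 2 libraries of 8,000 reads, and a
600-gene TE experiment at depth 2e5 — small enough to run in seconds
while exercising every stage. The test-suite recovery checks use the full
default conditions (4 × 50,000 reads; 10 × 2,000-gene TE simulations),
chosen as representative desk-scale sizes for this assay.

# Worked demonstration

```{r demo, eval = FALSE}
res <- runPipeline(defaultConfig(), "demo_out")
cat(readLines(res$results$report_file), sep = "\n")
```

The demo report shows the condition venn (5 common, 2
overexpression-unique sites), the `TGAACCN` consensus recovered from the
planted contexts, the TE class counts, the decoded-codon set {TGC, AAG}
derived from the overexpression-unique tRNAs, and the elevated
decoded-codon frequency of TE-up genes.

# Known limitations

* Ungapped alignment only; indel-containing reads are unalignable (and
  indel CIGARs are skipped on SAM import).
* The site caller estimates modification stoichiometry only as the stop
  fraction; cleavage efficiency below the stop-fraction threshold is
  invisible by design.
* Strict decoding ignores inosine wobble (A34 anticodons); wobble mode
  covers the standard expansion table only.
* The TE test assumes log-scale replicate exchangeability; it is not a
  count-model test and does not borrow the mean-variance trend.
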