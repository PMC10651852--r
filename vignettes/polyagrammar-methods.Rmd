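---
title: "Models and methods behind polyagrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyagrammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyagrammar identifies cleavage and polyadenylation (polyA) sites at
nucleotide resolution, scores their strength, and dissects the sequence
grammar that drives both.  This vignette explains the models, the choices
behind their implementation, and what the bundled synthetic benchmark can
and cannot establish.

## From 3' end reads to expressed polyA sites

3' end sequencing reads carry a stretch of untemplated adenosines
downstream of the alignment: reads with **at least 2 non-genomic As** are
polyA-site-supporting (PASS) reads, and their 3' ends mark cleavage
positions.  `extract_pass_reads()` subtracts reference As immediately
downstream of the alignment end (those could be templated), and when the
cleavage lands in a genomic A-run it assigns the read to the **first A of
the run** — terminal genomic As cannot be distinguished from the polyA
tail, and cleavage preferentially happens after CA dinucleotides and
within A-rich stretches, so the convention keeps those positions callable.
Minus-strand reads are mirrored (tails are leading reference Ts).

Cleavage is imprecise, so `cluster_sites()` groups positions **within
24 nt** by a greedy rule: the position with most PASS reads seeds a
cluster and becomes its representative.  The clustering rule is stated
only as "within 24 nt" in the literature this follows; we chose
highest-count-first greedy absorption with ties broken to the 5'-most
position (strand-aware) because it is deterministic and conserves every
read.  `filter_sites()` keeps sites with **>= 10 reads** whose within-gene
expression exceeds **2%** in at least one lineage; `extend_terminal_exon()`
extends gene 3' ends by at most 5 kb without crossing the next same-strand
transcription start site.

Coordinates are 1-based inclusive internally — the native convention of
the R/Bioconductor containers this package interoperates with — and are
converted to 0-based half-open only at the BED boundary.

## PolyaID and PolyaStrength

Both models read a one-hot encoded (4 x 240) window: 120 nt of nascent
sequence either side of an anchor.  The trunk is a convolutional layer
(window 8) followed by a bidirectional LSTM.  PolyaID has two heads: a
sigmoid **classification probability** trained with binary cross-entropy,
and a 50-way softmax **cleavage probability vector** over offsets -25..+24
trained with the Kullback-Leibler divergence against the observed PASS-read
distribution (negatives use a constant background vector of 0.02, which
sums to 1 exactly).  The two losses are equally weighted.  PolyaStrength
shares the trunk shape and regresses the log2-odds relative usage
\(o_i = \log_2(u_i/(1-u_i))\), \(u_i = n_i/(n_{top}+n_{second})\), under
mean squared error.  Optimisation uses Nadam (the Nesterov variant of
Adam) with learning rate 0.001 and batch size 100; weights from the epoch
with minimum validation loss are kept.

The engine is implemented in RcppArmadillo (forward and full
backpropagation through time, Nadam, inverted dropout, global-norm
gradient clipping at 5) so training runs on a single CPU with no
framework dependency.  Numerical guards: probabilities are clipped at
1e-7 before logs; `0·log 0 := 0`; training aborts with a diagnostic on
non-finite loss.

Two trunk read-outs are available.  `trunk = "flatten"` feeds the full
per-position biLSTM output to the dense layer — position-sensitive, which
the cleavage head needs (PolyaID default).  `trunk = "pool"` summarises the
biLSTM output by global mean+max pooling — translation-invariant, fewer
parameters.  In the desk-scale experiments the strength regression was
dominated by motif *identity and count* rather than exact position, and
the flatten trunk trained on shift-augmented windows generalised best, so
the fitted toy models use flatten for both tasks; the pooled trunk remains
available as a configuration choice.

Exact layer widths of the published models are not public; defaults are
64 filters, 32 LSTM units per direction, a 64-unit dense trunk and 0.3
dropout, all configurable.  Training labels for positives are the 51
windows shifted -25..+25 around each site, with the read distribution
re-centred per shift; the 50-length vector covers offsets -25..+24 (the
anchor sits at index 26).  Splits are **site-level** (all shifts of a site
travel together) so shifted near-duplicates cannot leak across the
train/validation/test boundary; splitting is stratified by class.
Degenerate usage ratios receive a 0.5-read pseudocount before the
log-odds.  Windows with more than 10% N are excluded; N columns one-hot to
zero.

## Scanning and consolidation

`scan_region()` applies PolyaID at every nucleotide.  Anchors with
classification probability > 0.5 **and** central cleavage probability
> 0.05 are retained; maximal runs of retained anchors (gap 0 by default)
form positive clusters.  Within a cluster every vector is
background-subtracted (0.02, floored at zero — flooring is our choice, as
renormalising a signed vector is not meaningful), renormalised, projected
onto genomic coordinates and averaged position-wise; the maximum of the
averaged profile is the putative site (ties 5'-most).  Subtract-then-
average is the implemented order; `subtract_first = FALSE` averages raw
vectors for comparison.  The mean cleavage position is the dot product
\(m = \sum_i p_i i\) over the 50 indices, and cleavage heterogeneity is
the Shannon entropy \(E = -\sum_i p_i \log p_i\) (natural log, 0 to
log 50).

## Motif importance and grammar

`hexamer_importance()` replaces each overlapping hexamer with 100 random
hexamers (the same draws reused at every position, a variance-reduction
choice) and records the median change in log-odds output.
`positional_profile()` aggregates over well-expressed sites into summed
and per-occurrence importance per (hexamer, start offset -120..+114).
Positions beyond +/-40 nt are treated as a null: the 99.99th percentile of
their summed scores is the significance threshold, exceeded strictly, with
PolyaID and PolyaStrength profiles combined by OR.  Motif families follow
the published definitions (U-rich: >= 5 Us with U first; G-rich: >= 5 Gs
with G first; GU/CU-rich: contains GUGU/UGUG/GUCU/UGUC/CUGU/UCUG; UGUA;
canonical PAS and a packaged, editable table of single-nucleotide PAS
variants), with precedence PAS > UGUA > GU/CU-rich > U-rich > G-rich for
hexamers matching several rules.  Entropy-group analyses intersect the
top/bottom 20% of sites under both the observed and predicted entropy and
compare motif occurrence across the four closed subregions -120..-31,
-30..0, 1..30, 31..120 with chi-squared and two-proportion tests.
`motif_distance_perturbation()` slides one motif through unchanged context
(displaced nucleotides refill the vacated span, length stays 240) to probe
the distance dependence of predicted cleavage heterogeneity.

## Genomic context models

Intronic sites are `composite` (no splicing between the upstream 5' splice
site and the site) or `skipped` (a used 3' splice site intervenes).
Features feeding the logistic usage classifiers: site strength, sense
distances to the flanking splice sites, donor/acceptor strengths, exon and
intron sizes, last-intron status; for terminal-exon pairs, pair distance,
last-intron size, distance to the nearest downstream antisense gene, and
the proximal-minus-distal strength difference (a difference, not a ratio —
the scores are already log-odds).  Splice-site strength uses an
annotation-trained position-weight-matrix log-odds score (9-nt donor
window -3..+6, 23-nt acceptor window -20..+3, 0.5 pseudocount, genome
background); the scorer is pluggable so a maximum-entropy model can be
substituted.  Distances are log10(x+1)-transformed before standardisation
(they act multiplicatively), features with Wald p >= 0.05 are dropped and
the model refit, and perfect separation falls back to a ridge-penalised
fit.  Strength confounding is removed by quantile matching (sampling
equal used/unused counts per strength bin); the default of 20 bins was
chosen because coarser strata (e.g. 10) leave a residual standardised
mean difference of about 0.1 between groups when the raw distributions
are well separated.  Tissue-level
APA regulation uses a Fisher exact test of proximal/distal counts in each
condition against all others, Benjamini-Hochberg adjustment, and an
absolute usage change >= 0.1 relative to the across-condition mean.

## Variant effects

A variant is evaluated only when it changes a significant hexamer (either
allele, either orientation).  Both alleles are scanned at 1-nt steps over
identical anchors within +/-120 nt, consolidated, and scored: strengths
are evaluated for both alleles **at one common representative anchor**
(the most confident positive cluster within 50 nt of the variant — the
span of PAS-to-cleavage geometries — from the allele with the stronger
call) so the delta isolates the variant rather than anchor drift.  Significance requires classification
probability >= 0.9 (either allele), strength >= -9, and |delta| >= 1;
sites in extended terminal regions must lie within 1 kb of the annotated
3' end, and intronic sites can additionally be gated on a usage-classifier
expression probability >= 0.9.

## The synthetic benchmark: what it emulates

`generate_genome()` + `plant_polya_sites()` build genomes whose terminal
exons carry sites with an explicit grammar: a PAS hexamer ending 21 nt
upstream of cleavage (a mix of AATAAA, ATTAAA and the broken signal
AATAAT), a CA dinucleotide at the cleavage site, a mandatory GU-rich CstF
motif 5-35 nt downstream, and optional UGUA / upstream U-rich / second
CstF / G-rich elements at their field-standard windows.  Planted strength
is `-4 + bonus(PAS) + 0.8 x (optional motifs)` with bonuses 3 / 1.5 / 0 —
the AATAAA-to-ATTAAA gap mirrors the roughly threefold usage drop reported
for that substitution (about 1.5 on the log2 scale).  Cleavage dispersion
grows with the PAS-CstF distance (`sd = 0.3 + 0.25 x max(0, d - 8)` nt),
encoding the distance-heterogeneity mechanism so that a model trained on
the reads can rediscover it.  `simulate_pass_reads()` draws Poisson read
counts (usage x depth), Gaussian 3' ends truncated at +/-25, non-genomic
tails of 2-10 As, emulated aligner extension through genomic A-runs, and a
small fraction of low-quality/secondary alignments.  `simulate_variants()`
emits PAS-destroying (AATAAA to AACAAA), PAS-creating (AATAAT to AATAAA)
and neutral records.  `scrub_background()` rewrites signal hexamers that
arise by chance in background sequence: in a planted-motif benchmark such
accidents make the truth set ambiguous, since calling them is not an
error of the scanner.

What the benchmark does **not** emulate: real nucleotide composition and
repeat structure, internal-priming artifacts, expression heterogeneity
across tissues, splicing dynamics, or sequencing error.  Passing the
bundled tests therefore demonstrates that the algorithms are implemented
correctly and can recover a known grammar at desk scale — not that the
toy weights match the published genome-scale models, whose headline
numbers require the full read corpus.

## Desk-scale study conditions

The test-suite and the acceptance script train reduced models on fixed
seeds.  A single-signal world (25 genes, 50 sites, read depth 400, all
AATAAA with the CstF motif at +10) supports the 4-epoch, ~5000-example
classifier check.  A full-grammar world (300 genes, ~580 sites, depth
300) trains the scanning PolyaID (200 training sites, 12 epochs,
negatives 1:1) and hosts the importance profiles and the 120-site
heterogeneity sweeps.  PolyaStrength trains on a larger 450-gene
plant-only panel (~870 distinct sites, 11 jittered windows each, 40
epochs at learning rate 0.003, dropout 0.2) — the number of *distinct*
sites, more than the number of windows, drives strength generalisation —
and is evaluated site-level by averaging the held-out windows of each
site.  Variant effects are checked on a further held-out 450-gene panel,
with variants planted only at isolated (>= 250 nt from the next site) and
crisp (cleavage sd <= 2 nt) sites so the intended effect is unambiguous;
destroying variants break AATAAA to the grammar's weak class AATAAT, the
exact inverse of a creating variant.  Scanning recovery uses a 16-gene,
~50-kb single-signal genome with scrubbed background.  These sizes are
the package's chosen desk-scale study conditions and are stated here so
every number the tests print is reproducible from the seeds alone.

## Known limitations

The toy models inherit the synthetic grammar's simplicity; their absolute
probabilities are not calibrated for real genomes.  The splice-site scorer
is a PWM, not a maximum-entropy model.  The intronic expression gate for
variants requires a fitted context classifier and host-gene annotation,
and is otherwise skipped.  Greedy clustering is order-deterministic but,
like any greedy rule, not globally optimal for pathological read
distributions.
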