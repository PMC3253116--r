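---
title: "Strand-specific tiling-array analysis of antisense transcription: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific tiling-array analysis of antisense transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astiler)
```

# The problem

In vegetatively growing fission yeast, a group of meiotic genes —
especially the mid-meiotic, forkhead-regulated ones — is kept tightly
silent while long polyadenylated antisense RNAs run across their entire
coding regions. On a two-strand 25-nt tiling microarray this shows up as
a distinctive signature: low signal on a gene's coding strand together
with high signal on the opposite strand. During meiosis the pattern
inverts (sense up, antisense down), and in a forkhead-repressor deletion
a subset of these genes is derepressed in vegetative cells.

`astiler` implements the complete analysis that turns raw two-channel
probe intensities into that picture: probe-effect normalization against
a genomic-DNA hybridization, change-point segmentation of each strand,
segment classification and antisense calling, per-gene strand-specific
expression, group selection and differential statistics, and motif
proximity analysis. A seeded simulator generates data with known truth
so every stage can be validated end to end.

# Data model and conventions

All genomic coordinates are **1-based, closed**, the native convention of
IRanges/GenomicRanges on which the package is built; GFF3 uses it
directly, and BED export converts. A probe assigned strand *s* reports
RNA transcribed *from* strand *s* — i.e. sense signal for genes on *s*.
Array vendors are not consistent about whether a "strand" label denotes
the probe sequence or its RNA target; the package fixes this convention
once and applies it identically in mapping, simulation and
quantification, which is all the downstream analysis requires. Only
probes that map to the genome exactly once are used in any intensity
computation.

# Normalization against the gDNA channel

Every probe hybridizes the same DNA copy number in a genomic-DNA
hybridization, so the gDNA channel measures each probe's
sequence-dependent efficiency (the probe effect). For unique probe $p$
and RNA sample $c$:

$$ r_{p,c} = \log_2\!\frac{\mathrm{rna}_{p,c}}{\mathrm{gdna}_p}, \qquad
   y_{p,c} = r_{p,c} - b_c, $$

where the background offset $b_c$ is the **median** of $r_{p,c}$ over
unique probes whose footprint overlaps no annotated CDS on either
strand. The median (not the mean) is used for robustness to residual
transcription in unannotated regions. The output is exactly invariant
to a global rescaling of any RNA sample, and in a multiplicative noise
regime the ratio removes probe effects exactly (verified in the tests
by planting known affinities). Whether background subtraction should
precede or follow the ratio is not determined by the two-step
description the method follows; the ratio-first order is this package's
choice, stated rather than asserted as the original's. No cross-sample
quantile step is applied — comparability across samples rests on the
shared gDNA reference, a documented divergence risk on real
scanner-derived data.

# Change-point segmentation

Each (chromosome, strand) vector of normalized probe values is modelled
as piecewise constant with Gaussian residuals. For every candidate
number of segments $k \le S$, boundaries minimizing the residual sum of
squares are found by exact dynamic programming over prefix sums
(quadratic, not greedy), and $k$ is chosen to maximize

$$ -\tfrac{n}{2}\log\!\frac{\mathrm{RSS}_k}{n} -
   \tfrac{\lambda}{2}\,k\log n, $$

with $\lambda = 2$ (the BIC rate) by default; the original study names
its segmentation model but not its settings, so the penalty is exposed
as a parameter. Numerical choices: the RSS is floored at $10^{-12} n$
before the logarithm so exactly-fitting segmentations remain comparable;
ties prefer fewer segments, then leftmost boundaries (determinism);
segments must span at least `min_probes = 4` probes (about 100 nt at
25-nt pitch), suppressing single-probe artifacts. On pure noise the
default penalty returns a single segment in about 95% of cases.

Because exact DP is quadratic, chromosomes longer than 3000 probes are
processed in overlapping chunks (300-probe overlap); change points are
accepted only inside each chunk's core, the cores partition the vector
exactly, and any sub-minimum segment created at a seam is merged into
the nearer-mean neighbor. Results carry an `exact` attribute saying
whether chunking was used. The tests compare chunked against exact
boundaries on multi-level signals.

# Segment taxonomy, antisense calls and origins

A segment is classified against the gene whose CDS it overlaps the most
(at least 50 nt, suppressing boundary-probe bleed): same strand means
*sense*, opposite strand *antisense*, no qualifying overlap
*non-annotated*. The full (segment, gene) pair table is kept as well,
because one probe — and one segment — can legitimately be sense for one
gene and antisense for an overlapping opposite-strand gene; antisense
calling therefore emits one call per (gene, segment) pair whose mean
exceeds the threshold of **1.0** log2 units in vegetative cells.

Called antisense RNAs fall into two architectures. A **3'UTR
extension** is continuous expressed signal flowing out of a convergent
same-strand neighbor's 3' end across the silent gene; operationally,
the call's segment sits in a run of expressed segments (mean > 0.5,
gaps at most 100 nt) that also covers the CDS of a same-strand gene
lying upstream in the direction of transcription. A **discrete unit**
is flanked by low signal on both sides: its expressed run touches no
same-strand CDS. Anything else is left unclassified. The 100-nt gap
tolerance quantifies the continuity that the underlying data show only
qualitatively; at the simulator's noise levels the rule recovers 100 of
100 planted architectures.

# Per-gene strand expression and the splicing index

`gene_strand_expression()` averages, for each gene, the unique probes
lying fully within the CDS span — ATG through stop codon, introns
included — on the gene's strand (`sense_avg`) and on the opposite
strand (`antisense_avg`). Genes with no probe on a strand are flagged
missing (`NA`), never zero, and drop out of medians. Intron probes can
be excluded (`include_introns = FALSE`) since it is not documented
whether the original averages did so; the default includes them, which
matters for the splicing interplay below.

The splicing index $SI = \overline{\text{intron probes}} -
\overline{\text{exon probes}}$ (sense strand, log2) is strongly
negative for spliced transcripts and near zero for unspliced ones. A
near-zero SI is ambiguous on its own: a covering antisense RNA raises
intron and exon probes alike on the *opposite* strand and, summed into
a non-strand-aware view, can mimic an unspliced sense transcript. The
report therefore emits the gene's `antisense_avg` alongside SI, which
resolves the two cases.

# Gene-level statistics

All thresholds sit in `analysis_config()` and are strict inequalities,
matching how they are printed in the study design: the
high-antisense/low-sense group is `sense_avg < 1` and
`antisense_avg > 0.5`; differential derepression is
`sense(mutant) - sense(wild type) > 1`; newly appearing antisense RNAs
satisfy `antisense(6 h)/antisense(veg) > 2` on the stored values, with
denominators at or below zero (possible on a background-anchored log
scale) floored at 0.05 — the floor is exposed because the source
analysis is silent on the case. A gene counts as meiotically induced
when its sense delta is strictly positive at either time point, with no
magnitude threshold. Whether "new" antisense genes should exclude
already-meiotic genes before or after the ratio is ambiguous in the
source; the `exclude` argument supports both readings. Enrichment of an
annotated set within a selection uses the upper-tail hypergeometric
probability computed in log space (`stats::phyper(log.p = TRUE)`),
which the tests pin against full enumeration; no multiple-testing
correction is applied to single enrichment values, and a
Benjamini–Hochberg option exists for users testing many sets.

`delta_correlation()` is the Pearson correlation between per-gene sense
changes and antisense changes across two samples. On identical tables
the deltas have zero variance and the result is flagged `NA` with a
warning — never silently 0.

# Motif analysis

`scan_iupac()` matches degenerate patterns (the forkhead core motif
`GTAAAYA`, with Y = C/T) via `Biostrings::matchPattern(fixed = FALSE)`;
minus-strand hits come from the reverse-complement pattern and report
their 5' base through the `five_prime` column. Proximity of antisense
5' origins to motif hits is reported at a 500-nt window by default —
the biological statement is only "close" — together with a sensitivity
report over 200/500/1000 nt. On a random genome a 7-mer with one
two-fold degenerate position matches about $2 \cdot 2/4^7$ per position
across both strands, so a 1-kb proximity window picks up a chance hit
with probability ~0.2; recovery validation against planted truth
therefore measures at the 200-nt planting distance, where the chance
contribution is ~2%.

`find_common_kmer()` answers the internal-promoter question — is there
a word shared by all input windows? — by exhaustive enumeration: count
the sequences containing each k-mer and score containment in at least
$n$ of $m$ sequences as a Poisson-binomial upper tail over per-sequence
containment probabilities $q_i$. Two backgrounds are provided. The
window-independence approximation $q = 1-(1-4^{-k})^{L-k+1}$ is simple
but measurably biased at small $k$ (for 2-mers in 10-mers it is off by
~0.02, beyond Monte-Carlo resolution at $10^5$ draws, and worse for
self-overlapping words, which cluster). The default therefore computes
$q_i$ exactly by propagating the word's KMP prefix-automaton state
distribution along the sequence; the tests verify it against
Monte-Carlo. At the scale this search is actually used (hexamers in
400-nt windows) the two agree to within a few percent. Both-strand
containment has no single-word automaton and always uses the windows
approximation. The upstream study quotes a motif-discovery p-value from
an EM-based tool whose objective this transparent statistic does not
reproduce, intentionally.

# The simulator: what it emulates

`sim_config()` + `generate_genome_and_annotation()` +
`simulate_intensities()` build a complete synthetic study. Genes are
placed left to right on a random genome with 600–1000-nt gaps and
900–2100-nt CDSs, and each carries one architecture:

* **mid-meiotic, discrete antisense** — sense nearly silent in veg
  (abundance 0.1), induced through meiosis (3 at 4 h, 8 at 6 h);
  a covering antisense unit at 3 in veg decaying to 0.7 at 6 h;
  a GTAAAYA motif 30–200 nt upstream of the meiotic promoter;
* **mid-meiotic, 3'UTR-extension antisense** — the same program, but
  the antisense is the convergent neighbor's transcript extended across
  the whole gene (one transcription unit, abundance 5 → 1);
* **forkhead-responsive subset** — 5 of the 8 mid-meiotic genes gain
  vegetative sense expression (3) in the repressor-deletion condition;
* **new antisense** — non-meiotic genes whose antisense rises from
  0.15 to 3 by 6 h while sense falls from 8 to 3.5; 80% get an
  upstream forkhead motif at the antisense start;
* **internal bidirectional promoter** (three genes, matching the three
  worked examples that motivated the hexamer search) — an ACGCTC
  hexamer at an internal site emitting a truncated sense RNA (4) and a
  divergent antisense RNA (2.5) in veg, replaced by the full-length
  meiotic transcript in meiosis;
* **fold change** — sense doubling 24 → 48 between veg and 4 h, the
  calibration class for log2-recovery checks;
* **correlated change** — per-gene bivariate normal log2 deltas
  (sd 1, correlation −0.4) between veg and 6 h on both strands, used to
  validate correlation recovery at scale;
* **normal genes** — constant sense around 8 (lognormal gene-to-gene
  spread, sdlog 0.4) with background antisense 0.2; a subset carries
  1–2 introns of 100–250 nt, either spliced (per-exon transcripts, so
  intron probes see no sense signal) or unspliced.

Raw intensities follow a **multiplicative** model: probe affinity
$a_p$ is lognormal with mean 1 (sdlog `affinity_sigma`, default 0.5),
and for an RNA condition

$$ \mathrm{raw}_{p,c} = a_p\,(A_{p,c} + \beta)\,\varepsilon, \qquad
   \mathrm{gdna}_p = a_p\,(G + \beta)\,\varepsilon, $$

with $A$ the summed abundance of same-strand transcripts overlapping
the probe footprint by at least 1 nt (no fractional weighting — the
segmentation tolerance absorbs edge probes), $\beta$ the background
(default 1), $G$ the gDNA copy level (20) and $\varepsilon$ lognormal
mean-1 noise with CV `noise_cv` (default 0.25). The background sits
*inside* the affinity term: nonspecific signal scales with probe
efficiency the way specific signal does. This is the regime in which
the gDNA ratio removes probe effects exactly — which is precisely what
makes normalization testable — and it keeps the clean mapping

$$ \mathbb{E}\,y \approx \log_2\!\left(1 + A/\beta\right), $$

so the abundance defaults land expressed sense averages near 3,
background antisense near 0.3, and planted antisense RNAs at 1.5–2 —
putting the genome-wide medians and the 0.5 / 1.0 thresholds in the
same regime as the study's value range. With zero planted abundance the
expected raw value is exactly $\beta$, because the affinities are drawn
with mean 1. None of the noise magnitudes are documented in the
original work; the defaults are calibrated only to reproduce the
qualitative structure, and that is all passing tests certify.

What the simulator deliberately does **not** emulate:
sequence-composition-dependent affinities (affinity is independent of
probe sequence), optical or spatial array artifacts, cross-hybridization
of near-matching probes, scanner saturation, and biological replicate
variance. Pipeline accuracy on this generator therefore demonstrates
algorithmic correctness, not robustness to every failure mode of real
arrays.

The seed fully determines all outputs; setting `structure_seed`
separately lets the noise be re-drawn on a fixed genome and truth.

# Validation scales

The test suite and the acceptance script exercise three problem sizes,
chosen to keep a full run in the minutes range on one core: the default
study scale (100-kb genome, 30 genes, 8000 probes, all four
conditions), an origin-classification study (420 kb, 100 antisense
architectures, vegetative sample only), and a correlation-recovery run
(5.6 Mb, 2000 correlated-change genes, two conditions, quantification
without segmentation). At the default scale the pipeline recovers
per-probe segment categories at ≥ 99.9%, planted origin classes at
100/100, planted 2-fold changes within 0.05 log2 units, and the planted
−0.4 delta correlation within ±0.03.

# Known limitations

* The segmentation chunk reconciliation is an approximation for inputs
  beyond 3000 probes per strand; boundaries within half an overlap of a
  seam can differ from the exact optimum (flagged via `exact`).
* Supplementary per-gene tables are ingested as TSV with the
  `sense_<sample>` / `antisense_<sample>` schema; spreadsheet formats
  must be exported to TSV first.
* Boundary-calling on real arrays depends on normalization details
  (scanner background, saturation) that the gDNA-ratio model does not
  capture; thresholds tuned here transfer to real data only to the
  extent that the value scale matches.
* `classify_antisense_origin()` assumes the annotation is complete
  enough that an expressed same-strand run into a neighbor's CDS means
  a shared transcript; unannotated genes upstream would masquerade as
  3'UTR extensions.
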