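---
title: "Pangenome-aware small-variant calling with haplotype-augmented pileups"
author: "pangecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome-aware small-variant calling with haplotype-augmented pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short-read variant callers that work against a single linear reference
suffer from *reference bias*: wherever the sampled genome diverges enough
from the reference — most acutely inside high-identity segmental
duplications (SDs) — reads mismap or lose their distinguishing markers,
and downstream genotyping mistakes alignment noise for variation (false
positives) or discards true variant signal as noise (false negatives).
A pangenome — here, a panel of reference-quality haplotypes from many
individuals, each aligned to the linear reference — carries exactly the
population context needed to tell these apart: an apparent variant that
no panel haplotype carries, at a locus where panel haplotypes *do*
explain the read mismatches as paralogous sequence, is probably an
artifact; a weakly supported variant that segregates in the panel is
probably real.

pangecall implements this idea at desk scale: candidate variants are
discovered from read alignments, each candidate is rendered as a
fixed-width multi-channel pileup tensor in which a block of panel
haplotype rows is stacked on top of the read rows, and a small
convolutional network classifies the candidate's genotype as REF (0/0),
HET (0/1) or HOM_ALT (1/1). Calls are emitted in linear-reference
coordinates as ordinary VCF.

## Candidate discovery

Candidates are reference positions where at least `min_support = 2`
reads assert the same mismatch or the same indel. Indels are anchored at
the preceding reference base and left-aligned against the reference
before tallying, so a deletion placed at different offsets of a
homopolymer run by different reads counts as one allele. Soft-clipped
bases assert no reference position and never create candidates. The
default applies no mapping-quality or base-quality floor — reads with
MAPQ 0–2 are retained deliberately, because they carry the mismapping
signal the classifier is supposed to see through; both floors exist as
configuration for other uses. One alternate per site is kept (the
most-supported one), which keeps the label space of the classifier
exactly {REF, HET, HOM_ALT}; multiallelic resolution is out of scope.

## The pileup tensor

Each candidate becomes a tensor of shape `(2 × height, width, 6)` with
`width = 221` columns centered on the candidate and `height = 100` rows
per block: rows 1–100 are panel haplotypes (in stable panel order), rows
101–200 are reads sorted by start position then name. Values lie in
[0, 1]:

| channel | encoding |
|---|---|
| BASE | A = 0.25, C = 0.50, G = 0.75, T = 1.00, deletion gap = 0.10, N = 0.05, empty = 0 |
| BASE_QUAL | min(q, 40) / 40 |
| MAP_QUAL | min(q, 60) / 60 |
| STRAND | forward = 0.5, reverse = 1.0 |
| SUPPORTS_ALT | row carries the candidate alternate = 1.0, carries the reference allele = 0.5, anything else = 0.25 |
| DIFFERS_FROM_REF | column differs from the reference = 1.0, matches = 0.3 |

The exact values are conventions of this package (bounded, monotone,
mutually distinct); they are configuration, not science. Insertions are
flagged at their anchor column rather than by column expansion, keeping
the tensor width fixed in reference coordinates. Base quality, mapping
quality and strand are identically zero in haplotype rows — a haplotype
panel defines none of them — while SUPPORTS_ALT and DIFFERS_FROM_REF
*are* populated for haplotypes, because they are computable from the
haplotype-to-reference alignment alone and they are precisely the
population signal the model needs.

Odd width gives a unique center column; near contig edges the window is
kept centered and out-of-contig columns stay blank. When more reads
overlap the window than there are rows, a uniform subsample of exactly
`height` reads is drawn from a seed derived from `row_overflow_seed` and
the candidate position, so re-runs are identical. More panel haplotypes
than rows is an error by default — the intended remedy is a personalized
panel via haplotype sampling, not silent truncation — with an explicit
seeded-subsample opt-in.

## The genotype classifier

The classifier is intentionally small: three 3×3 convolution blocks
(16/32/64 filters) with stride-2 downsampling and ReLU, a dense ReLU
layer of width 64 with dropout 0.2, and a softmax over the three
genotype classes, trained with class-weighted cross-entropy (inverse
class frequency by default) and Adam (learning rate 1e-3, batch 32, up
to 10 epochs, early stopping on holdout loss with patience 3). Stride-2
convolution replaces a stride-1 convolution plus pooling pair: the same
receptive-field growth at about a third of the arithmetic, which matters
for single-CPU training. Validation follows the held-out-chromosome
convention: examples on the holdout contigs contribute no gradients and
drive early stopping and reported accuracy.

All stochastic elements — He initialization, epoch shuffling, dropout
masks — derive from one integer seed, so a seed fixes the final weights
bit for bit. Checkpoints store weights at their native float32
precision, which is why save → load → predict is bitwise identical to
predicting before the save. The implementation (im2col + BLAS GEMM,
analytic backprop verified in the test suite against central finite
differences) lives in the package's C++ code; no external deep-learning
runtime is involved.

## Calls and VCF

The called genotype is the argmax class; within a tie margin of 1e-9
the order REF > HET > HOM_ALT wins, which is the conservative choice
(prefer no call over a variant call on ties). Genotype quality is
`min(99, round(-10·log10(1 − p_max)))` with `p_max` capped at
1 − 1e-10, QUAL is set equal to GQ, DP/AD come from the candidate's
support counts, and 0/0 calls are marked `RefCall` and omitted from the
VCF unless requested. Coordinates are 0-based half-open everywhere
inside the package and become 1-based only at the VCF/SAM boundary.

## Personalized panels by k-mer scoring

Haplotype sampling scores each panel haplotype against the sample's
reads without alignment: reads are reduced to their canonical (strand
neutral) 29-mers, k-mers seen fewer than twice are discarded as likely
sequencing errors, each haplotype is split into non-overlapping 10 kb
segments, and a segment's score is the fraction of its distinct
canonical k-mers present in the read set (a containment index). A
haplotype's aggregate score is the mean over its segments *weighted by
each segment's distinct k-mer count*: a haplotype whose net insertions
push its length just past the last full segment acquires a remainder
segment shorter than k with zero k-mers, and an unweighted mean would
charge it a full 1/nseg for that artifact — enough to out-rank the true
donors. With k-mer-count weighting the degenerate segment simply carries
no evidence. The top-N haplotypes are returned (presets 16/32/64), with
ties broken by panel order so that selections nest. Segmenting tolerates recombination
between segments but not within one; recombination-aware mosaic
selection is a declared non-goal.

## The synthetic diploid generator

The generator is the package's study design, not a test convenience,
and its defaults are fixed:

* **Reference**: i.i.d. uniform A/C/G/T contigs (2 × 500 kb in the
  `small` preset), each containing one segmental duplication — a 20 kb
  block copied to a second locus at 99% identity. Divergence positions
  between the copies are the "paralogous sequence variants" that
  mismapped reads later present as phantom candidates.
* **Panel**: polymorphic sites occur at 3 × 10⁻³ per bp (chosen to give
  the ~1 het/kb heterozygosity typical of human genomes once carrier
  fractions are accounted for); 90% SNVs, 10% indels of 1–5 bp
  (mirroring the SNP-dominance of short-read callable variation). Each
  site's carrier count i among the n = 20 haplotypes is drawn with
  probability ∝ 1/i — the neutral site-frequency spectrum — which
  produces the monotonically decreasing allele-frequency histogram the
  evaluation bins assume. Sites are placed with ≥ 8 bp spacing and
  retained only if already left-align-stable, so truth, panel and
  discovery agree on coordinates with no normalization ambiguity.
* **Sample**: two donor haplotypes copied from the panel plus private
  variants at 5 × 10⁻⁵ per bp per haplotype (variation absent from the
  panel, which keeps the classifier honest: panel absence must not be
  sufficient grounds to refuse a call).
* **Reads**: single-end 150 bp at 30× diploid coverage, per-base error
  rate 10⁻³ with reduced base quality at error positions. Reads
  contained in a duplication copy are re-addressed to the homologous
  copy with probability 0.25 (0.5 in the `biased` preset), *keeping
  their true sequence* — the mismapped read then shows a dense cluster
  of mismatches at the wrong locus, which is the reference-bias
  signature. Every duplication-contained read carries mapping quality 2
  whether or not its placement is correct, because a short read inside a
  high-identity SD is ambiguous either way; modelling low MAPQ only for
  the truly mismapped reads would hand the classifier an oracle channel
  that real mappers do not provide.

What the generator does not emulate: paired-end structure (pairing adds
no behavior this pipeline exercises), instrument-specific error
profiles, coalescent genealogies, overlapping/nested variants, and real
SD architecture beyond a single two-copy duplication. Consequently,
green tests here demonstrate the mechanics and the direction of the
pangenome benefit under controlled reference bias — not real-data parity
with production callers or hap.py.

The `biased` preset (2 × 150 kb, mismap 0.5) is sized so that paralog
divergence sites present read evidence indistinguishable from a
heterozygous variant (alt fraction ≈ 0.5 at MAPQ 2); only the haplotype
block separates them from true variants, making it the ablation
scenario for the method's central claim. Every byte of a bundle is a
deterministic function of the master seed; the JSON manifest carries no
timestamps, so regeneration from the manifest's seed is byte-identical.

## Evaluation and error transitions

Benchmarking matches calls to truth by exact normalized key
(contig, position, ref, alt) *plus genotype*; an allele match with the
wrong genotype counts as one FP and one FN, as in hap.py's accounting.
The synthetic truth is non-overlapping and left-aligned by
construction, so exact matching is lossless here; haplotype-aware
(vcfeval-style) equivalence matching on real data is a non-goal. Only
PASS calls inside the confident regions are evaluated.

Given baseline and pangenome-aware comparisons against the same truth,
the four transition sets are plain set differences of the error sets —
removed FP, rescued FN (fixed), induced FP, induced FN (new) — pairwise
disjoint by construction and exactly swapped when the two call sets are
exchanged. Transition counts are stratified by a labelled region
partition (the simulator emits its duplication BED directly; SD-identity
computation from self-alignment is out of scope), reported as counts
per Mb of class size and per 100 kb window, and binned by panel allele
frequency in width-0.2 bins with the last bin closed at 1.0.

## Numerical and degenerate-input choices

* Tie-breaks: genotype ties prefer REF (margin 1e-9); candidate-allele
  ties at a site prefer the lexicographically smaller alternate;
  haplotype-score ties keep panel order.
* Probability clipping: log-loss uses max(p, 1e-12); GQ caps p_max at
  1 − 1e-10 and GQ at 99.
* Empty inputs: a window with no overlapping reads still yields an
  example (all-zero read block); an empty region query returns an empty
  panel that remembers its declared haplotype count; an absent allele
  has panel frequency exactly 0.
* CIGAR dialect: `=`/`X` normalize to M, hard clips are dropped,
  anything outside M/I/D/S is rejected loudly.
* float32 vs double: tensors and weights are float32 end to end; tests
  compare encoded constants at 1e-6 tolerance, while checkpoint and
  prediction round-trips are exact because no re-quantization occurs.

## Problem sizes used by the test suite

The shipped suite trains and evaluates on the `small` preset (2 × 500 kb
contigs, panel of 20, 30×, ≈ 2,300 candidate examples) and runs the
ablation on five seeds of the `biased` preset (2 × 150 kb); haplotype
sampling is validated on 20-haplotype/60 kb and 100-haplotype/30 kb
panels. These sizes are the package's chosen study scale: large enough
for stable behavior (hundreds of labelled examples per class, clear
donor-score separation), small enough that the whole suite runs on one
CPU in well under half an hour.

## Known limitations

* Exact-key matching understates parity with haplotype-aware matchers
  on real data with complex representation differences.
* The classifier is a deliberately small CNN; no claim is made that its
  accuracy transfers to real sequencing data or that it approximates
  any production model's behavior.
* Single-sample calling only; no gVCF, no phasing, no multiallelic
  genotypes (1/2), no CRAM, and mates are treated independently.
* The k-mer similarity score is a containment fraction at 10 kb
  granularity; it recovers donors under the study conditions but does
  not model within-segment recombination or k-mer copy number.
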