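# pangecall

Pangenome-aware small-variant calling from haplotype-augmented pileups,
at desk scale.

Short-read variant callers that see only reads mapped to a linear
reference suffer from *reference bias*: inside high-identity segmental
duplications and other low-mappability regions, mismapped reads mimic
heterozygous variants (false positives) and dilute the support of real
ones (false negatives). `pangecall` injects population context directly
into the genotyping step. A *pangenome* — here, a panel of haplotypes
aligned to the linear reference, ingestible from haplotype-to-reference
SAM/BAM or from a phased multi-sample VCF — is rendered into the same
pileup image the classifier sees for the reads.

The pipeline:

1. **Candidate discovery** — positions where ≥ 2 reads assert the same
   mismatch or indel (anchored, left-aligned alleles).
2. **Pileup encoding** — per candidate, a float32 tensor of shape
   `(2×100, 221, 6)`: a 221-column window centered on the candidate,
   100 haplotype rows stacked on top of 100 read rows, with channels
   BASE, BASE_QUAL, MAP_QUAL, STRAND, SUPPORTS_ALT, DIFFERS_FROM_REF
   (quality/strand channels are blank in haplotype rows).
3. **CNN genotyping** — a small convolutional classifier
   (conv 16/32/64 → dense 64 → softmax) maps each tensor to
   probabilities over {REF (0/0), HET (0/1), HOM_ALT (1/1)}; genotype
   quality is `min(99, round(−10·log₁₀(1 − p_max)))`.
4. **VCF output** — PASS/RefCall records with GT:GQ:DP:AD in linear
   reference coordinates.
5. **Haplotype sampling** — personalized panels: reads are reduced to
   canonical 29-mers, haplotypes are scored per 10 kb segment by k-mer
   containment, and the top-N (16/32/64) most similar haplotypes form a
   smaller panel.
6. **Benchmarking** — comparison to a truth set inside confident
   regions, and classification of call-set differences between a
   baseline and a pangenome-aware run into removed FP / rescued FN
   (fixed) and induced FP / induced FN, stratified by region class,
   100 kb window and panel allele frequency (0.2-wide bins).

A seeded synthetic-data module generates the study conditions end to
end: a reference with a high-identity (99%) duplicated segment, a
20-haplotype panel with a neutral 1/i allele-frequency spectrum, a
diploid sample built from two panel donors plus private variants, and
error-bearing reads of which a fraction inside the duplication is
mismapped to the homologous copy — with a truth VCF, confident-region
and region-partition BEDs, and a JSON manifest from which the bundle
regenerates byte-identically.

## Worked example

```r
library(pangecall)

# a complete simulated experiment: reference, panel, diploid truth, reads
bundle <- simulate_scenario("small", seed = 1)

# discover candidates, encode pangenome-augmented tensors, label by truth
examples <- make_pileup_examples(bundle$reads, bundle$reference,
                                 bundle$panel, truth = bundle$truth)

# train on chrA, call and benchmark chrB
res <- run_end_to_end(bundle, holdout_contig = "chrB",
                      model = model_config(seed = 1), examples = examples)
res$comparison
#> <pg_comparison> TP 637  FP 22  FN 16  precision 0.9666  recall 0.9755  F1 0.9710

# how much of that is the pangenome? zero the haplotype block and retrain
base <- run_end_to_end(bundle, holdout_contig = "chrB",
                       model = model_config(seed = 1), examples = examples,
                       use_panel = FALSE)
base$comparison
#> <pg_comparison> TP 613  FP 20  FN 40  precision 0.9684  recall 0.9387  F1 0.9533
classify_error_transitions(base$comparison, res$comparison)
#> <pg_transitions> removed FP 8  rescued FN 28  induced FP 9  induced FN 6  (SNPs only)
```

The comparison line reads: of the truth variants on the held-out
contig, 637 were called with the correct genotype, 22 calls had no
matching truth record (or the wrong genotype) and 16 truth records went
uncalled. The transition lines compare the reads-only ablation with the
pangenome-aware run against the same truth: 36 SNP errors fixed versus
15 induced, with the recall gap (0.9387 → 0.9755) concentrated at the
simulated segmental duplication — the pangenome pays for itself
precisely where read evidence alone is ambiguous.

Calls are written with `write_vcf(res$calls, bundle$reference, "S1",
"calls.vcf")`. A thin CLI over the same functions is installed at
`inst/cli/pangecall` (subcommands `simulate`, `make-examples`, `train`,
`call`, `sample-haplotypes`, `error-transitions`).

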