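#' Discover candidates and build labelled pileup examples
#'
#' @param reads Alignment `data.table` of reads.
#' @param reference A `pg_reference`.
#' @param panel A `haplotype_panel` or `NULL` (reads-only ablation).
#' @param region Optional [genomic_interval].
#' @param discovery A [discovery_config].
#' @param pileup A [pileup_config].
#' @param truth Optional truth table for labelling.
#' @return A `pg_examples` object.
#' @export
make_pileup_examples <- function(reads, reference, panel, region = NULL,
                                 discovery = discovery_config(),
                                 pileup = pileup_config(), truth = NULL) {
  cands <- discover_candidates(reads, reference, region, discovery)
  build_examples(cands, reads, panel, reference, pileup, truth)
}

#' Classify examples and assemble calls
#'
#' @param examples A `pg_examples` object.
#' @param model A `pg_genotyper`.
#' @param tie_epsilon Tie margin for genotype assignment.
#' @return Call `data.table` (see [make_calls]).
#' @export
call_variants <- function(examples, model, tie_epsilon = 1e-9) {
  probs <- predict_genotypes(model, examples)
  make_calls(examples$meta, probs, tie_epsilon)
}

#' Subset a `pg_examples` object by example index
#' @param examples A `pg_examples` object.
#' @param idx Integer or logical index.
#' @return A `pg_examples` object with the selected examples.
#' @export
subset_examples <- function(examples, idx) {
  structure(list(tensors = examples$tensors[idx],
                 meta = examples$meta[idx],
                 width = examples$width, height = examples$height,
                 channels = examples$channels),
            class = "pg_examples")
}

#' Variant-level macro F1 over the HET and HOM_ALT classes
#'
#' For each non-reference genotype class, truth records of that class
#' count as true positives when a PASS call matches key and genotype,
#' as false negatives otherwise; PASS calls of that class without a
#' matching truth record are false positives. Macro-F1 averages the two
#' class F1 scores.
#'
#' @param calls Call `data.table`.
#' @param truth Truth `data.table`.
#' @param confident Optional confident-region BED.
#' @return List with `f1_het`, `f1_hom`, `macro_f1`.
#' @export
genotype_macro_f1 <- function(calls, truth, confident = NULL) {
  calls <- as.data.table(calls)[filter == "PASS"]
  calls <- calls[in_regions(contig, pos, confident)]
  truth <- as.data.table(truth)[in_regions(contig, pos, confident)]
  call_gt <- match(calls$genotype, c("0/1", "1/1"))
  per_class <- vapply(1:2, function(cl) {
    t_rec <- truth[gt == cl, key]
    c_rec <- calls[which(call_gt == cl), key]
    tp <- length(intersect(t_rec, c_rec))
    fp <- length(setdiff(c_rec, t_rec))
    fn <- length(setdiff(t_rec, c_rec))
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  list(f1_het = per_class[1], f1_hom = per_class[2],
       macro_f1 = mean(per_class))
}

#' Train on one contig, call and benchmark another
#'
#' The full pipeline on a simulated scenario bundle: candidate
#' discovery, pileup encoding (optionally with the haplotype block
#' zeroed), CNN training with the evaluation contig held out, calling
#' on the held-out contig, and benchmarking against the truth set
#' inside the confident regions.
#'
#' @param bundle Scenario bundle from [simulate_scenario].
#' @param holdout_contig Contig reserved for calling/evaluation.
#' @param model A [model_config].
#' @param pileup A [pileup_config].
#' @param use_panel `FALSE` zeroes the haplotype block (reads-only
#'   baseline).
#' @param examples Optional precomputed `pg_examples` (with panel); when
#'   given, discovery/encoding is skipped and the haplotype block is
#'   zeroed here if `use_panel = FALSE`.
#' @return List with `model`, `calls`, `comparison`, `f1` (from
#'   [genotype_macro_f1]), `errors` (FP+FN) and `examples`.
#' @export
run_end_to_end <- function(bundle, holdout_contig = "chrB",
                           model = model_config(), pileup = pileup_config(),
                           use_panel = TRUE, examples = NULL) {
  if (is.null(examples)) {
    examples <- make_pileup_examples(
      bundle$reads, bundle$reference,
      if (use_panel) bundle$panel else NULL,
      pileup = pileup, truth = bundle$truth)
  } else if (!use_panel) {
    examples <- zero_haplotype_block(examples)
  }
  fit <- train_genotyper(examples, model, holdout_contigs = holdout_contig)
  ho <- which(examples$meta$contig == holdout_contig)
  ex_ho <- subset_examples(examples, ho)
  calls <- call_variants(ex_ho, fit)
  truth_ho <- bundle$truth[contig == holdout_contig]
  conf <- bundle$confident
  cmp <- compare_to_truth(calls, truth_ho, conf)
  f1 <- genotype_macro_f1(calls, truth_ho, conf)
  list(model = fit, calls = calls, comparison = cmp, f1 = f1,
       errors = cmp$n_fp + cmp$n_fn, examples = examples)
}

#' Pangenome-benefit experiment on the reference-bias scenario
#'
#' Trains two identically configured models on the same examples — one
#' seeing the haplotype block, one with it zeroed — and compares their
#' total errors (FP + FN) on the held-out contig. The expectation under
#' reference bias is that the pangenome-aware model makes no more, and
#' typically fewer, errors.
#'
#' @param seed Scenario seed.
#' @param model A [model_config] (the same for both arms).
#' @param holdout_contig Contig held out for evaluation.
#' @param preset Scenario preset; default `"biased"`.
#' @return List with `errors_pangenome`, `errors_baseline`,
#'   `comparison_pangenome`, `comparison_baseline`, `transitions`,
#'   `bundle`.
#' @export
pangenome_benefit_run <- function(seed, model = model_config(),
                                  holdout_contig = "chrB",
                                  preset = "biased") {
  bundle <- simulate_scenario(preset, seed)
  examples <- make_pileup_examples(bundle$reads, bundle$reference,
                                   bundle$panel, truth = bundle$truth)
  pg <- run_end_to_end(bundle, holdout_contig, model, use_panel = TRUE,
                       examples = examples)
  base <- run_end_to_end(bundle, holdout_contig, model, use_panel = FALSE,
                         examples = examples)
  trans <- classify_error_transitions(base$comparison, pg$comparison,
                                      snp_only = TRUE)
  list(errors_pangenome = pg$errors, errors_baseline = base$errors,
       comparison_pangenome = pg$comparison,
       comparison_baseline = base$comparison,
       transitions = trans, bundle = bundle)
}
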