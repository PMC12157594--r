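# toy truth/call construction helpers
toy_truth <- function(keys, gt) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  dt <- data.table(contig = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   ref = vapply(parts, `[`, "", 3L),
                   alt = vapply(parts, `[`, "", 4L),
                   gt = gt)
  dt[, key := keys]
  dt[]
}

toy_calls <- function(keys, genotype) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  dt <- data.table(contig = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   ref = vapply(parts, `[`, "", 3L),
                   alt = vapply(parts, `[`, "", 4L),
                   genotype = genotype)
  dt[, `:=`(filter = "PASS", key = keys)]
  dt[]
}

test_that("perfect calls give precision = recall = 1 with empty error sets", {
  truth <- toy_truth(c("c:10:A:T", "c:20:C:G"), c(1L, 2L))
  calls <- toy_calls(c("c:10:A:T", "c:20:C:G"), c("0/1", "1/1"))
  cmp <- compare_to_truth(calls, truth)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 1)
  expect_equal(length(cmp$fp), 0L)
  expect_equal(length(cmp$fn), 0L)
})

test_that("an extra PASS call is one FP; genotype mismatches count FP and FN", {
  truth <- toy_truth(c("c:10:A:T"), 1L)
  calls <- toy_calls(c("c:10:A:T", "c:30:G:C"), c("0/1", "0/1"))
  cmp <- compare_to_truth(calls, truth)
  expect_equal(cmp$n_fp, 1L)
  expect_equal(cmp$n_fn, 0L)

  calls2 <- toy_calls("c:10:A:T", "1/1")      # allele right, genotype wrong
  cmp2 <- compare_to_truth(calls2, truth)
  expect_equal(cmp2$n_fp, 1L)
  expect_equal(cmp2$n_fn, 1L)
  expect_equal(cmp2$n_tp, 0L)
})

test_that("non-PASS calls and records outside confident regions are ignored", {
  truth <- toy_truth(c("c:10:A:T", "c:500:A:T"), c(1L, 1L))
  calls <- toy_calls(c("c:10:A:T", "c:40:C:G"), c("0/1", "0/1"))
  calls[key == "c:40:C:G", filter := "RefCall"]
  conf <- data.table(contig = "c", start = 0L, end = 100L)
  cmp <- compare_to_truth(calls, truth, conf)
  expect_equal(cmp$n_tp, 1L)
  expect_equal(cmp$n_fp, 0L)    # RefCall ignored
  expect_equal(cmp$n_fn, 0L)    # truth at 500 outside confident bed
})

test_that("transition sets match hand enumeration on the toy example", {
  # truth: y (het at c:20); baseline calls FP x and misses y;
  # pangenome calls y correctly plus FP z
  truth <- toy_truth("c:20:C:G", 1L)
  base_calls <- toy_calls("c:10:A:T", "0/1")
  pg_calls <- toy_calls(c("c:20:C:G", "c:30:G:A"), c("0/1", "0/1"))
  base <- compare_to_truth(base_calls, truth)
  pg <- compare_to_truth(pg_calls, truth)
  tr <- classify_error_transitions(base, pg)
  expect_equal(tr$removed_fp, "c:10:A:T:1")
  expect_equal(tr$rescued_fn, "c:20:C:G:1")
  expect_equal(tr$induced_fp, "c:30:G:A:1")
  expect_equal(length(tr$induced_fn), 0L)

  # identical comparisons produce four empty sets
  tr0 <- classify_error_transitions(pg, pg)
  expect_true(all(lengths(tr0[1:4]) == 0L))
})

test_that("comparisons against different truth inputs are refused", {
  t1 <- toy_truth("c:20:C:G", 1L)
  t2 <- toy_truth(c("c:20:C:G", "c:40:A:T"), c(1L, 1L))
  calls <- toy_calls("c:20:C:G", "0/1")
  expect_error(
    classify_error_transitions(compare_to_truth(calls, t1),
                               compare_to_truth(calls, t2)),
    "different truth")
})

test_that("transitions are disjoint and swap-symmetric on random comparison pairs", {
  set.seed(91)
  for (rep in 1:100) {
    keys <- pg_key("c", sample(1000L, 30L), "A", "T")
    truth <- toy_truth(keys[1:20], sample(1:2, 20L, TRUE))
    mk <- function() {
      pick <- sample(keys, 15L)
      toy_calls(pick, sample(c("0/1", "1/1"), 15L, TRUE))
    }
    a <- compare_to_truth(mk(), truth)
    b <- compare_to_truth(mk(), truth)
    tr <- classify_error_transitions(a, b, snp_only = FALSE)
    sets <- tr[c("removed_fp", "rescued_fn", "induced_fp", "induced_fn")]
    all_rec <- unlist(sets)
    expect_equal(length(all_rec), length(unique(all_rec)))  # disjoint
    sw <- classify_error_transitions(b, a, snp_only = FALSE)
    expect_setequal(sw$removed_fp, tr$induced_fp)
    expect_setequal(sw$rescued_fn, tr$induced_fn)
    expect_setequal(sw$induced_fp, tr$removed_fp)
    expect_setequal(sw$induced_fn, tr$rescued_fn)
  }
})

test_that("stratified rates are count per Mb with exhaustive window assignment", {
  truth <- toy_truth("c:1500000:A:T", 1L)
  base <- compare_to_truth(toy_calls(character(), character()), truth)
  pg <- compare_to_truth(toy_calls("c:1500000:A:T", "0/1"), truth)
  tr <- classify_error_transitions(base, pg)
  part <- data.table(contig = "c", start = c(0L, 1000000L),
                     end = c(1000000L, 3000000L),
                     label = c("outside_sd", "sd99"))
  st <- stratify_counts(tr, part)
  expect_equal(st$by_class[category == "rescued_fn" & label == "sd99", rate],
               0.5)                                # 1 SNP in a 2 Mb class
  expect_equal(st$by_window$window, 15L)

  tr0 <- classify_error_transitions(base, base)
  st0 <- stratify_counts(tr0, part)
  expect_true(all(st0$by_class$count == 0L))
})

test_that("region-class assignment matches a brute-force membership oracle", {
  set.seed(93)
  part <- data.table(contig = "c",
                     start = c(0L, 40000L, 100000L),
                     end = c(40000L, 100000L, 500000L),
                     label = c("p1", "p2", "p3"))
  pos <- sample(0:600000, 500L)
  truth <- toy_truth(pg_key("c", pos, "A", "T"), rep(1L, 500L))
  base <- compare_to_truth(toy_calls(character(), character()), truth)
  pg <- compare_to_truth(toy_calls(truth$key, "0/1"), truth)
  tr <- classify_error_transitions(base, pg)
  st <- stratify_counts(tr, part)
  oracle <- vapply(pos, function(p) {
    hit <- which(p >= part$start & p < part$end)
    if (length(hit)) part$label[hit] else "outside"
  }, "")
  want <- table(factor(oracle, levels = c("p1", "p2", "p3")))
  got <- st$by_class[category == "rescued_fn"]
  expect_equal(got[match(names(want), label), count], as.integer(want))
})

test_that("allele-frequency bins are half-open with a closed last bin and sum to totals", {
  cfg <- sim_config(contig_lengths = c(chrA = 40000L), duplication = list(),
                    panel_size = 10L, panel_site_rate = 0.004, seed = 95L)
  sim <- simulate_panel(cfg)
  sites <- sim$sites[nchar(ref) == 1L & nchar(alt) == 1L]
  keys <- pg_key(sites$contig, sites$pos, sites$ref, sites$alt)
  n <- min(100L, length(keys))
  truth <- toy_truth(keys[seq_len(n)], rep(1L, n))
  base <- compare_to_truth(toy_calls(character(), character()), truth)
  pg <- compare_to_truth(toy_calls(truth$key, "0/1"), truth)
  tr <- classify_error_transitions(base, pg)
  hist <- bin_by_allele_frequency(tr, sim$panel, sim$reference)
  expect_equal(hist[category == "rescued_fn", sum(count)],
               length(tr$rescued_fn))
  # brute-force binning oracle from the generator's carrier sets
  f <- vapply(sites$carriers[seq_len(n)], length, 1L) / 10
  want <- table(cut(f, seq(0, 1, 0.2), right = FALSE))
  # the closed last bin collects frequency 1.0 (never produced here; i < n)
  got <- hist[category == "rescued_fn", count]
  expect_equal(got, as.integer(want))

  expect_error(bin_by_allele_frequency(tr, sim$panel, sim$reference,
                                       bin_width = 0.3), "divide")
})

test_that("boundary frequencies land in the documented bins", {
  # frequency 0.1 -> first bin; carriers = all -> frequency 1 -> last bin
  refseq <- rand_seq(400)
  ref <- tiny_reference(c(chrT = refseq))
  b1 <- substr(refseq, 101, 101); b2 <- substr(refseq, 201, 201)
  a1 <- setdiff(c("A", "C", "G", "T"), b1)[1]
  a2 <- setdiff(c("A", "C", "G", "T"), b2)[1]
  hap_seq <- vapply(1:10, function(h) {
    s <- refseq
    if (h == 1L) substr(s, 101, 101) <- a1     # carrier fraction 0.1
    substr(s, 201, 201) <- a2                  # carrier fraction 1.0
    s
  }, "")
  panel <- new_panel(new_alignments(sprintf("h%02d", 1:10), "chrT", 0L,
                                    "400M", hap_seq, NA, NA, "*",
                                    "haplotype"), 10L)
  truth <- toy_truth(c(pg_key("chrT", 100L, b1, a1),
                       pg_key("chrT", 200L, b2, a2)), c(1L, 1L))
  base <- compare_to_truth(toy_calls(character(), character()), truth)
  pg <- compare_to_truth(toy_calls(truth$key, "0/1"), truth)
  tr <- classify_error_transitions(base, pg)
  hist <- bin_by_allele_frequency(tr, panel, ref)
  got <- hist[category == "rescued_fn"]
  expect_equal(got[bin == "[0.0,0.2)", count], 1L)
  expect_equal(got[bin == "[0.8,1.0]", count], 1L)
})
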