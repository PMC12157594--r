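chan <- function() setNames(seq_along(pg_channels()), pg_channels())

# a small deterministic pileup scene: reference, 6 reads, 2-hap panel,
# one SNP candidate at the center
pileup_scene <- function(seed = 21L, width = 21L, height = 8L) {
  set.seed(seed)
  refseq <- rand_seq(200)
  ref <- tiny_reference(c(chrT = refseq))
  pos <- 100L
  b <- substr(refseq, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  mk <- function(name, s, alt_read) {
    bases <- substr(refseq, s + 1L, s + 40L)
    if (alt_read) substr(bases, pos - s + 1L, pos - s + 1L) <- alt
    data.table(name = name, s = s, bases = bases)
  }
  rows <- rbindlist(list(mk("r1", 80L, FALSE), mk("r2", 85L, TRUE),
                         mk("r3", 90L, TRUE), mk("r4", 95L, FALSE),
                         mk("r5", 70L, FALSE), mk("r6", 99L, TRUE)))
  reads <- new_alignments(rows$name, "chrT", rows$s, "40M", rows$bases,
                          strrep("F", 40L), 60L, "+", "read")
  hap_bases <- c(substr(refseq, 1, 200),
                 { h <- substr(refseq, 1, 200)
                   substr(h, pos + 1L, pos + 1L) <- alt; h })
  panel <- new_panel(new_alignments(c("hapA", "hapB"), "chrT", 0L, "200M",
                                    hap_bases, NA, NA, "*", "haplotype"), 2L)
  cands <- discover_candidates(reads, ref)
  cfg <- pileup_config(width = width, height_per_block = height)
  list(ref = ref, reads = reads, panel = panel, cands = cands, cfg = cfg,
       pos = pos, alt = alt, refb = b)
}

test_that("candidate windows are centered with odd width", {
  cfg <- pileup_config(width = 221L)
  w <- candidate_window(list(contig = "c", pos = 10000L), cfg)
  expect_equal(w$start, 10000L - 110L)
  expect_equal(w$end, 10000L + 111L)
  expect_equal(w$end - w$start, 221L)

  near0 <- candidate_window(list(contig = "c", pos = 50L), cfg)
  expect_equal(near0$start, -60L)

  small <- pileup_config(width = 5L, height_per_block = 4L)
  w5 <- candidate_window(list(contig = "c", pos = 2L), small)
  expect_equal(c(w5$start, w5$end), c(0L, 5L))

  expect_error(pileup_config(width = 220L), "odd")
})

test_that("tensors satisfy shape, range, blankness and center invariants", {
  sc <- pileup_scene()
  ex <- build_examples(sc$cands, sc$reads, sc$panel, sc$ref, sc$cfg)
  expect_equal(length(ex$tensors), 1L)
  a <- example_tensor(ex, 1L)
  expect_equal(dim(a), c(16L, 21L, 6L))
  expect_true(all(a >= 0 & a <= 1))
  ch <- chan()
  # haplotype block rows 1..height: BASE_QUAL, MAP_QUAL, STRAND all zero
  expect_true(all(a[1:8, , ch[c("BASE_QUAL", "MAP_QUAL", "STRAND")]] == 0))
  # haplotype BASE is populated for the two panel rows
  expect_true(any(a[1:2, , ch["BASE"]] > 0))
  # read rows carry strand and mapping quality
  expect_true(all(a[9:14, 11, ch["MAP_QUAL"]] == 1))
  # center column: reads r2, r3, r6 support the alt
  center <- 11L
  read_rows <- 8L + seq_len(6L)
  sup <- a[read_rows, center, ch["SUPPORTS_ALT"]]
  names(sup) <- sort(c("r1", "r2", "r3", "r4", "r5", "r6"))  # start-sorted = r5,r1,r2,r3,r4,r6
  expect_equal(unname(sup), c(0.5, 0.5, 1.0, 1.0, 0.5, 1.0))
  # haplotype carrying the alt scores 1.0, the other 0.5
  expect_equal(unname(a[1:2, center, ch["SUPPORTS_ALT"]]), c(0.5, 1.0))
  # DIFFERS_FROM_REF: matching read base encodes 0.3, the alt encodes 1.0
  expect_equal(unname(a[9, center, ch["DIFFERS_FROM_REF"]]), 0.3,
               tolerance = 1e-6)
  expect_equal(unname(a[11, center, ch["DIFFERS_FROM_REF"]]), 1.0)
})

test_that("tensor is invariant to read input permutation", {
  sc <- pileup_scene()
  ex1 <- build_examples(sc$cands, sc$reads, sc$panel, sc$ref, sc$cfg)
  set.seed(9)
  shuffled <- sc$reads[sample(nrow(sc$reads))]
  ex2 <- build_examples(sc$cands, shuffled, sc$panel, sc$ref, sc$cfg)
  expect_identical(ex1$tensors, ex2$tensors)
})

test_that("read overflow subsamples deterministically to the block height", {
  set.seed(31)
  refseq <- rand_seq(300)
  ref <- tiny_reference(c(chrT = refseq))
  reads <- random_reads(refseq, 60, len = 50L, p_snp = 0, p_indel = 0,
                        p_clip = 0)
  cand <- data.table(contig = "chrT", pos = 150L,
                     ref = substr(refseq, 151, 151),
                     alt = "A", alt_support = 2L, total_depth = 60L,
                     kind = "SNP")
  cfg <- pileup_config(width = 21L, height_per_block = 10L,
                       row_overflow_seed = 7L)
  ex1 <- build_examples(cand, reads, NULL, ref, cfg)
  ex2 <- build_examples(cand, reads, NULL, ref, cfg)
  expect_identical(ex1$tensors, ex2$tensors)
  a <- example_tensor(ex1, 1L)
  filled <- sum(rowSums(a[11:20, , chan()["BASE"]]) > 0)
  expect_equal(filled, 10L)                     # exactly height read rows
  cfg2 <- pileup_config(width = 21L, height_per_block = 10L,
                        row_overflow_seed = 8L)
  ex3 <- build_examples(cand, reads, NULL, ref, cfg2)
  expect_false(identical(ex1$tensors, ex3$tensors))  # seed governs the draw
})

test_that("haplotype overflow errors by default, advising sampling", {
  set.seed(33)
  refseq <- rand_seq(120)
  ref <- tiny_reference(c(chrT = refseq))
  panel <- new_panel(new_alignments(sprintf("h%02d", 1:12), "chrT", 0L,
                                    "120M", refseq, NA, NA, "*", "haplotype"),
                     12L)
  reads <- random_reads(refseq, 5, len = 40L)
  cand <- data.table(contig = "chrT", pos = 60L,
                     ref = substr(refseq, 61, 61), alt = "A",
                     alt_support = 2L, total_depth = 5L, kind = "SNP")
  cfg <- pileup_config(width = 11L, height_per_block = 8L)
  expect_error(build_examples(cand, reads, panel, ref, cfg),
               "select_haplotypes")
  cfg2 <- pileup_config(width = 11L, height_per_block = 8L,
                        hap_overflow = "subsample")
  ex <- build_examples(cand, reads, panel, ref, cfg2)
  expect_equal(dim(example_tensor(ex, 1L))[1], 16L)
})

test_that("an 88-haplotype panel fills rows 1-88 of a height-100 block", {
  set.seed(37)
  refseq <- rand_seq(200)
  ref <- tiny_reference(c(chrT = refseq))
  panel <- new_panel(new_alignments(sprintf("hap%03d", 1:88), "chrT", 0L,
                                    "200M", refseq, NA, NA, "*", "haplotype"),
                     88L)
  expect_equal(panel$haplotype_count, 88L)
  reads <- random_reads(refseq, 6, len = 40L)
  cand <- data.table(contig = "chrT", pos = 100L,
                     ref = substr(refseq, 101, 101), alt = "A",
                     alt_support = 2L, total_depth = 6L, kind = "SNP")
  ex <- build_examples(cand, reads, panel, ref,
                       pileup_config(width = 21L, height_per_block = 100L))
  a <- example_tensor(ex, 1L)
  filled <- rowSums(a[1:100, , 1L]) > 0
  expect_true(all(filled[1:88]))
  expect_true(all(!filled[89:100]))
})

test_that("an example with no overlapping reads still encodes", {
  refseq <- rand_seq(100)
  ref <- tiny_reference(c(chrT = refseq))
  reads <- new_alignments(character(), character(), integer(), character(),
                          character())
  cand <- data.table(contig = "chrT", pos = 50L,
                     ref = substr(refseq, 51, 51), alt = "A",
                     alt_support = 2L, total_depth = 0L, kind = "SNP")
  ex <- build_examples(cand, reads, NULL, ref,
                       pileup_config(width = 11L, height_per_block = 4L))
  a <- example_tensor(ex, 1L)
  expect_true(all(a == 0))
})

test_that("BASE channel equals an alignment-expansion oracle on random reads", {
  set.seed(35)
  refseq <- rand_seq(240)
  ref <- tiny_reference(c(chrT = refseq))
  reads <- random_reads(refseq, 12, len = 40L, p_clip = 0)
  cand <- data.table(contig = "chrT", pos = 120L,
                     ref = substr(refseq, 121, 121), alt = "A",
                     alt_support = 2L, total_depth = 12L, kind = "SNP")
  cfg <- pileup_config(width = 41L, height_per_block = 15L)
  ex <- build_examples(cand, reads, NULL, ref, cfg)
  a <- example_tensor(ex, 1L)
  enc <- c(A = 0.25, C = 0.5, G = 0.75, T = 1.0, N = 0.05, `-` = 0.10)
  win <- c(100L, 141L)   # [start, end) of the window
  ord <- order(reads$start, reads$name)
  sorted <- reads[ord]
  spans <- pangecall:::alignment_span(sorted)
  keep <- which(sorted$start < win[2] & sorted$start + spans > win[1])
  for (r in seq_along(keep)) {
    rd <- sorted[keep[r]]
    # expand the alignment into per-column characters
    cols <- rep(NA_character_, 41L)
    ops <- regmatches(rd$cigar, gregexpr("[0-9]+[A-Z]", rd$cigar))[[1]]
    lens <- as.integer(sub("[A-Z]", "", ops)); opc <- sub("[0-9]+", "", ops)
    p <- rd$start; q <- 0L
    bch <- strsplit(rd$bases, "")[[1]]
    for (k in seq_along(opc)) {
      if (opc[k] == "S") q <- q + lens[k]
      else if (opc[k] == "M") {
        for (t in seq_len(lens[k])) {
          col <- p + t - 1L - win[1] + 1L
          if (col >= 1L && col <= 41L) cols[col] <- bch[q + t]
        }
        p <- p + lens[k]; q <- q + lens[k]
      } else if (opc[k] == "I") q <- q + lens[k]
      else if (opc[k] == "D") {
        for (t in seq_len(lens[k])) {
          col <- p + t - 1L - win[1] + 1L
          if (col >= 1L && col <= 41L) cols[col] <- "-"
        }
        p <- p + lens[k]
      }
    }
    want <- ifelse(is.na(cols), 0, enc[cols])
    expect_equal(unname(a[15L + r, , chan()["BASE"]]), unname(want),
                 info = paste("read row", r))
  }
})

test_that("zeroing the haplotype block only clears haplotype rows", {
  sc <- pileup_scene()
  ex <- build_examples(sc$cands, sc$reads, sc$panel, sc$ref, sc$cfg)
  z <- zero_haplotype_block(ex)
  a <- example_tensor(ex, 1L); az <- example_tensor(z, 1L)
  expect_true(all(az[1:8, , ] == 0))
  expect_identical(az[9:16, , ], a[9:16, , ])
  expect_false(all(a[1:8, , ] == 0))   # original untouched
})

test_that("labels join candidates to truth by normalized key", {
  truth <- data.table(contig = "chrT", pos = c(10L, 20L, 30L),
                      ref = c("A", "C", "G"), alt = c("T", "CTT", "G"),
                      gt = c(1L, 2L, 1L))
  truth[, key := pg_key(contig, pos, ref, alt)]
  cands <- data.table(contig = "chrT", pos = c(10L, 20L, 40L, 10L),
                      ref = c("A", "C", "A", "A"),
                      alt = c("T", "CTT", "G", "G"))
  labs <- label_candidates(cands, truth, NULL)
  expect_equal(labs, c(1L, 2L, 0L, 0L))
})

test_that("examples serialize and reload identically", {
  sc <- pileup_scene()
  ex <- build_examples(sc$cands, sc$reads, sc$panel, sc$ref, sc$cfg)
  ex$meta$label <- 1L
  path <- tempfile(fileext = ".bin.gz")
  save_examples(ex, path)
  back <- load_examples(path)
  expect_identical(back$tensors, ex$tensors)
  expect_equal(back$meta$label, ex$meta$label)
  expect_equal(back$width, ex$width)
})
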