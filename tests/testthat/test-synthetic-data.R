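tiny_cfg <- function(seed = 1L, ...) {
  args <- list(contig_lengths = c(chrA = 30000L, chrB = 30000L),
               duplication = list(chrA = c(src = 5000L, len = 4000L,
                                           dest = 20000L),
                                  chrB = c(src = 5000L, len = 4000L,
                                           dest = 20000L)),
               coverage = 12, panel_size = 10L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("mutation rate zero produces reference-identical haplotypes", {
  cfg <- tiny_cfg(panel_site_rate = 0)
  sim <- simulate_panel(cfg)
  expect_equal(nrow(sim$sites), 0L)
  expect_true(all(sim$panel$haplotypes$bases ==
                    sim$reference$seq[sim$panel$haplotypes$contig]))
  expect_true(all(sim$panel$haplotypes$cigar == "30000M"))
})

test_that("the same seed reproduces the panel exactly", {
  a <- simulate_panel(tiny_cfg(seed = 5L))
  b <- simulate_panel(tiny_cfg(seed = 5L))
  expect_identical(a$reference$seq, b$reference$seq)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$sites$pos, b$sites$pos)
})

test_that("panel site and carrier counts follow the generative law", {
  cfg <- sim_config(contig_lengths = c(chrA = 300000L), duplication = list(),
                    panel_size = 20L, panel_site_rate = 0.001, seed = 31L)
  sim <- simulate_panel(cfg)
  n_sites <- nrow(sim$sites)
  expected <- 300000 * 0.001
  sd3 <- 3 * sqrt(expected)
  # spacing and left-align-stability filters remove a few percent
  expect_lt(n_sites, expected + sd3)
  expect_gt(n_sites, 0.75 * expected - sd3)

  # per-haplotype carrier fraction: E[i]/n with P(i) proportional to 1/i
  i <- 1:19
  p_carry <- sum(i * (1 / i) / sum(1 / i)) / 20
  per_hap <- vapply(1:20, function(h)
    sum(vapply(sim$sites$carriers, function(x) h %in% x, TRUE)), 1L)
  sigma <- sqrt(n_sites * p_carry * (1 - p_carry))
  expect_true(all(abs(per_hap - n_sites * p_carry) < 4 * sigma))
})

test_that("panel allele frequencies are monotone decreasing over 0.2 bins", {
  cfg <- sim_config(contig_lengths = c(chrA = 400000L), duplication = list(),
                    panel_size = 20L, panel_site_rate = 0.002, seed = 33L)
  sim <- simulate_panel(cfg)
  f <- vapply(sim$sites$carriers, length, 1L) / 20
  bins <- table(cut(f, breaks = seq(0, 1, by = 0.2), right = FALSE))
  counts <- as.integer(bins)
  expect_true(all(diff(counts) <= 0))
})

test_that("with no private variants truth equals the union of donor variants", {
  cfg <- tiny_cfg(private_rate = 0, donors = c(2L, 7L))
  sim <- simulate_panel(cfg)
  dip <- simulate_diploid(sim, cfg)
  expect_equal(dip$donors, c(2L, 7L))
  want <- sim$sites[vapply(carriers, function(x) any(c(2L, 7L) %in% x), TRUE)]
  expect_setequal(dip$truth$key, pg_key(want$contig, want$pos, want$ref,
                                        want$alt))
  hom <- sim$sites[vapply(carriers, function(x) all(c(2L, 7L) %in% x), TRUE)]
  expect_setequal(dip$truth[gt == 2L, key],
                  pg_key(hom$contig, hom$pos, hom$ref, hom$alt))
})

test_that("identical donors give an all-homozygous truth set", {
  cfg <- tiny_cfg(private_rate = 0, donors = c(4L, 4L))
  sim <- simulate_panel(cfg)
  dip <- simulate_diploid(sim, cfg)
  expect_true(all(dip$truth$gt == 2L))
})

test_that("applying the truth phases to the reference rebuilds both haplotypes", {
  cfg <- tiny_cfg(seed = 9L)
  sim <- simulate_panel(cfg)
  dip <- simulate_diploid(sim, cfg)
  for (ci in names(cfg$contig_lengths)) {
    for (h in 1:2) {
      tv <- dip$truth[contig == ci &
                        substr(phase, 2L * h - 1L, 2L * h - 1L) == "1"]
      rebuilt <- apply_variants(sim$reference$seq[[ci]], tv$pos, tv$ref,
                                tv$alt)$seq
      expect_identical(rebuilt, dip$sample_seqs[[ci]][h])
    }
  }
})

test_that("error-free, mismap-free reads assert only truth alleles", {
  cfg <- tiny_cfg(error_rate = 0, mismap_prob = 0, seed = 11L)
  b <- simulate_scenario(config = cfg)
  cands <- discover_candidates(b$reads, b$reference,
                               config = discovery_config(min_support = 1L))
  keys <- pg_key(cands$contig, cands$pos, cands$ref, cands$alt)
  expect_true(all(keys %in% b$truth$key))
  # outside the duplication placement is unambiguous
  d <- cfg$duplication$chrA
  spans <- pangecall:::alignment_span(b$reads)
  in_dup <- (b$reads$start >= d["src"] &
               b$reads$start + spans <= d["src"] + d["len"]) |
    (b$reads$start >= d["dest"] & b$reads$start + spans <= d["dest"] + d["len"])
  expect_true(all(b$reads$mapq[!in_dup] == 60L))
  expect_true(all(b$reads$mapq[in_dup] == 2L))
})

test_that("mean depth holds the target coverage within 10%", {
  cfg <- tiny_cfg(seed = 13L, coverage = 30)
  b <- simulate_scenario(config = cfg)
  reads <- b$reads[contig == "chrA"]
  spans <- pangecall:::alignment_span(reads)
  lo <- 10000L; hi <- 18000L   # clear of the duplication blocks
  ov <- pmin(reads$start + spans, hi) - pmax(reads$start, lo)
  depth <- sum(pmax(ov, 0L)) / (hi - lo)
  expect_lt(abs(depth - 30) / 30, 0.1)
})

test_that("read simulation is byte-reproducible through SAM", {
  cfg <- tiny_cfg(seed = 17L)
  b1 <- simulate_scenario(config = cfg)
  b2 <- simulate_scenario(config = cfg)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(b1$reads, b1$reference, f1)
  write_sam(b2$reads, b2$reference, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("mismapped duplication reads carry low mapping quality and true sequence", {
  cfg <- tiny_cfg(seed = 19L, mismap_prob = 0.5, error_rate = 0)
  b <- simulate_scenario(config = cfg)
  mm <- b$reads[mapq == 2L]
  expect_gt(nrow(mm), 0L)
  d <- cfg$duplication$chrA
  spans <- pangecall:::alignment_span(mm)
  in_dup <- (mm$start >= d["src"] & mm$start + spans <= d["src"] + d["len"]) |
    (mm$start >= d["dest"] & mm$start + spans <= d["dest"] + d["len"])
  expect_true(all(in_dup[mm$contig == "chrA"]))
  # mismapped reads create non-truth candidates (the reference-bias signal)
  cands <- discover_candidates(b$reads, b$reference)
  keys <- pg_key(cands$contig, cands$pos, cands$ref, cands$alt)
  expect_gt(sum(!keys %in% b$truth$key), 0L)
})

test_that("duplication must not overlap its destination", {
  expect_error(
    sim_config(contig_lengths = c(chrA = 30000L),
               duplication = list(chrA = c(src = 5000L, len = 4000L,
                                           dest = 7000L))),
    "overlap")
})

test_that("scenario bundles regenerate byte-identically from the manifest seed", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- tiny_cfg(seed = 23L)
  b1 <- simulate_scenario(config = cfg, out_dir = dir1)
  regen_seed <- jsonlite::read_json(file.path(dir1, "manifest.json"))$seed
  cfg2 <- tiny_cfg(seed = regen_seed)
  simulate_scenario(config = cfg2, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
  expect_equal(jsonlite::read_json(file.path(dir1, "manifest.json"))$donors,
               as.list(b1$donors))
})
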