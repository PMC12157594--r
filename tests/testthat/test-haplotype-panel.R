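make_phased_vcf <- function(ref, sites, gt, samples, path) {
  write_sites_vcf(sites, gt, samples, ref, path)
  path
}

test_that("phased VCF ingest reconstructs haplotypes exactly", {
  set.seed(3)
  refseq <- rand_seq(300)
  ref <- tiny_reference(c(chrT = refseq))
  vcf <- tempfile(fileext = ".vcf")
  b <- substr(refseq, 51, 51)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  make_phased_vcf(ref, data.table(contig = "chrT", pos = 50L, ref = b,
                                  alt = alt),
                  matrix("0|1", 1, 1), "S1", vcf)
  panel <- panel_from_phased_vcf(vcf, ref)
  expect_equal(panel$haplotype_count, 2L)
  expect_equal(nrow(panel$haplotypes), 2L)
  expect_equal(panel$haplotypes[name == "S1_h1", bases], refseq)
  h2 <- panel$haplotypes[name == "S1_h2", bases]
  expect_equal(substr(h2, 51, 51), alt)
  expect_equal(sum(strsplit(h2, "")[[1]] != strsplit(refseq, "")[[1]]), 1L)
})

test_that("a VCF without variant records yields reference haplotypes, all-M", {
  ref <- tiny_reference(c(chrT = rand_seq(120)))
  vcf <- tempfile(fileext = ".vcf")
  make_phased_vcf(ref, data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character()),
                  matrix(character(), 0, 2), c("S1", "S2"), vcf)
  panel <- panel_from_phased_vcf(vcf, ref)
  expect_equal(panel$haplotype_count, 4L)
  expect_true(all(panel$haplotypes$bases == ref$seq[["chrT"]]))
  expect_true(all(panel$haplotypes$cigar == "120M"))
})

test_that("unphased genotypes are rejected with the offending record", {
  ref <- tiny_reference(c(chrT = rand_seq(100)))
  vcf <- tempfile(fileext = ".vcf")
  b <- substr(ref$seq[["chrT"]], 11, 11)
  make_phased_vcf(ref, data.table(contig = "chrT", pos = 10L, ref = b,
                                  alt = setdiff(c("A", "C", "G", "T"), b)[1]),
                  matrix("0/1", 1, 1), "S1", vcf)
  expect_error(panel_from_phased_vcf(vcf, ref), "unphased")
})

test_that("random phased VCF matches an independent string-edit oracle and round-trips", {
  set.seed(17)
  refseq <- rand_seq(2000)
  ref <- tiny_reference(c(chrT = refseq))
  # seeded random phased SNPs and indels, spaced and left-align-stable
  pos <- sort(sample(seq(20L, 1960L, by = 18L), 20L))
  sites <- rbindlist(lapply(pos, function(p) {
    b <- substr(refseq, p + 1L, p + 1L)
    kind <- sample(c("snp", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
    if (kind == "snp") {
      data.table(contig = "chrT", pos = p, ref = b,
                 alt = sample(setdiff(c("A", "C", "G", "T"), b), 1L))
    } else if (kind == "ins") {
      data.table(contig = "chrT", pos = p, ref = b,
                 alt = paste0(b, rand_seq(2L)))
    } else {
      data.table(contig = "chrT", pos = p,
                 ref = substr(refseq, p + 1L, p + 3L), alt = b)
    }
  }))
  nv <- cpp_normalize_variants(sites$pos, sites$ref, sites$alt, refseq)
  sites <- sites[nv$pos == sites$pos & nv$ref == sites$ref & nv$alt == sites$alt]
  nhap <- 10L
  carry <- matrix(runif(nrow(sites) * nhap) < 0.4, nrow(sites), nhap)
  gt <- matrix("", nrow(sites), nhap / 2L)
  for (j in seq_len(nhap / 2L)) {
    gt[, j] <- paste0(carry[, 2L * j - 1L] + 0L, "|", carry[, 2L * j] + 0L)
  }
  vcf <- tempfile(fileext = ".vcf")
  make_phased_vcf(ref, sites, gt, sprintf("S%d", 1:(nhap / 2L)), vcf)
  panel <- panel_from_phased_vcf(vcf, ref)

  # oracle: edit the reference string per haplotype, applying right to left
  oracle_seq <- function(v) {
    s <- refseq
    for (i in rev(seq_len(nrow(v)))) {
      s <- paste0(substr(s, 1L, v$pos[i]), v$alt[i],
                  substr(s, v$pos[i] + nchar(v$ref[i]) + 1L, nchar(s)))
    }
    s
  }
  for (j in seq_len(nhap)) {
    sample_id <- sprintf("S%d_h%d", (j + 1L) %/% 2L, 2L - (j %% 2L))
    got <- panel$haplotypes[name == sample_id, bases]
    expect_identical(got, oracle_seq(sites[carry[, j]]))
  }

  # round trip: diffing haplotypes against the reference recovers the input
  pv <- panel_variants(panel, ref)
  carried_keys <- sort(unique(pv$key))
  want_keys <- sort(unique(pg_key("chrT", sites$pos, sites$ref,
                                  sites$alt)[rowSums(carry) > 0]))
  expect_identical(carried_keys, want_keys)
})

test_that("panel allele frequency is carriers over haplotype count", {
  set.seed(5)
  refseq <- rand_seq(500)
  ref <- tiny_reference(c(chrT = refseq))
  cfg <- sim_config(contig_lengths = c(chrT = 4000L), duplication = list(),
                    panel_size = 8L, panel_site_rate = 0.01, seed = 9L)
  sim <- simulate_panel(cfg)
  pv <- panel_variants(sim$panel, sim$reference)

  # brute-force carrier count per site from the generator's own carrier sets
  for (i in sample(nrow(sim$sites), min(30L, nrow(sim$sites)))) {
    s <- sim$sites[i]
    af <- panel_allele_frequency(sim$panel, sim$reference, s$contig, s$pos,
                                 s$ref, s$alt)
    expect_equal(af$frequency, length(s$carriers[[1]]) / 8)
  }

  # an allele absent from the panel has frequency 0
  af0 <- panel_allele_frequency(sim$panel, sim$reference, "chrT", 17L,
                                substr(sim$reference$seq[["chrT"]], 18, 18),
                                "N")
  expect_equal(af0$frequency, 0)

  # alt carriers + reference carriers partition a biallelic site
  s <- sim$sites[1]
  af <- panel_allele_frequency(sim$panel, sim$reference, s$contig, s$pos,
                               s$ref, s$alt)
  expect_equal(af$frequency + (8 - af$n_carriers) / 8, 1)
})

test_that("panels load from haplotype alignments with declared counts", {
  cfg <- sim_config(contig_lengths = c(chrA = 5000L), duplication = list(),
                    panel_size = 12L, seed = 2L)
  sim <- simulate_panel(cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$panel$haplotypes, sim$reference, sam)
  panel <- load_panel_from_alignments(sam, reference = sim$reference)
  expect_equal(panel$haplotype_count, 12L)
  expect_equal(nrow(panel$haplotypes), 12L)

  # per-haplotype aligned intervals match an independent text parse
  oracle <- oracle_parse_sam(sam)
  expect_equal(panel$haplotypes$start, oracle$start)
  expect_equal(panel$haplotypes$cigar, oracle$cigar)

  # empty region keeps the declared count
  p2 <- load_panel_from_alignments(sam, region = genomic_interval("chrZ", 0, 10))
  expect_equal(p2$haplotype_count, 12L)
  expect_equal(nrow(p2$haplotypes), 0L)

  # haplotypes aligned to contigs missing from the reference are an error
  ref2 <- tiny_reference(c(other = rand_seq(100)))
  expect_error(load_panel_from_alignments(sam, reference = ref2),
               "linear reference")
})
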