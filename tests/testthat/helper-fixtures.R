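suppressMessages(library(data.table))

# ---- small deterministic building blocks ------------------------------

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

tiny_reference <- function(seqs) new_reference(seqs)

# generate random reads as perturbed copies of a reference window,
# expressed directly as alignment rows (optionally with indels/softclips)
random_reads <- function(refseq, n, len = 30L, contig = "chrT",
                         p_snp = 0.3, p_indel = 0.15, p_clip = 0.1,
                         prefix = "rd") {
  L <- nchar(refseq)
  rows <- lapply(seq_len(n), function(i) {
    s <- sample.int(L - len - 10L, 1L) - 1L
    bases <- substr(refseq, s + 1L, s + len)
    cigar <- paste0(len, "M")
    if (runif(1) < p_indel) {
      at <- sample.int(len - 10L, 1L) + 4L   # interior offset
      if (runif(1) < 0.5) {
        ilen <- sample.int(3L, 1L)
        ins <- rand_seq(ilen)
        bases <- paste0(substr(bases, 1L, at), ins,
                        substr(bases, at + 1L, len - ilen))
        cigar <- paste0(at, "M", ilen, "I", len - at - ilen, "M")
      } else {
        dlen <- sample.int(3L, 1L)
        bases <- paste0(substr(bases, 1L, at),
                        substr(refseq, s + at + dlen + 1L,
                               s + len + dlen))
        cigar <- paste0(at, "M", dlen, "D", len - at, "M")
      }
    } else if (runif(1) < p_snp) {
      at <- sample.int(len, 1L)
      old <- substr(bases, at, at)
      substr(bases, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
    if (runif(1) < p_clip) {
      clip <- rand_seq(3L)
      bases <- paste0(clip, bases)
      cigar <- paste0("3S", cigar)
    }
    qlen <- nchar(bases)
    data.table(name = sprintf("%s%04d", prefix, i), contig = contig,
               start = s, cigar = cigar, bases = bases,
               qual = strrep("F", qlen), mapq = 60L,
               strand = sample(c("+", "-"), 1L), origin = "read")
  })
  dt <- rbindlist(rows)
  new_alignments(dt$name, dt$contig, dt$start, dt$cigar, dt$bases,
                 dt$qual, dt$mapq, dt$strand, dt$origin)
}

# ---- independent oracles ----------------------------------------------

# line-by-line SAM text parser, independent of Rsamtools
oracle_parse_sam <- function(path) {
  lines <- readLines(path)
  recs <- lines[!startsWith(lines, "@")]
  if (!length(recs)) {
    return(data.table(name = character(), contig = character(),
                      start = integer(), cigar = character(),
                      bases = character(), qual = character(),
                      mapq = integer(), strand = character()))
  }
  f <- strsplit(recs, "\t", fixed = TRUE)
  dt <- data.table(
    name = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    contig = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = vapply(f, `[`, "", 6L),
    bases = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L))
  dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  dt[qual == "*", qual := NA_character_]
  dt[mapq == 255L, mapq := NA_integer_]
  dt[, flag := NULL]
  setorder(dt, contig, start, name)
  dt[]
}

# R-only left-alignment of a pure indel (shared convention, written
# independently of the C++ code)
oracle_leftalign <- function(refseq, pos, ref, alt) {
  rch <- strsplit(refseq, "")[[1]]
  if (nchar(ref) == 1L && nchar(alt) > 1L) {       # insertion
    ins <- strsplit(substr(alt, 2L, nchar(alt)), "")[[1]]
    p <- pos + 1L                                  # insertion point
    while (p > 0L && rch[p] == ins[length(ins)]) {
      ins <- c(rch[p], ins[-length(ins)])
      p <- p - 1L
    }
    a <- p                                          # 1-based anchor
    if (a == 0L) return(NULL)
    list(pos = a - 1L, ref = rch[a],
         alt = paste(c(rch[a], ins), collapse = ""))
  } else if (nchar(alt) == 1L && nchar(ref) > 1L) { # deletion
    dlen <- nchar(ref) - 1L
    p <- pos + 1L                                   # first deleted (0-based)
    while (p > 0L && rch[p] == rch[p + dlen]) p <- p - 1L
    a <- p
    if (a == 0L) return(NULL)
    list(pos = a - 1L,
         ref = paste(rch[a:(a + dlen)], collapse = ""),
         alt = rch[a])
  } else list(pos = pos, ref = ref, alt = alt)
}

# brute-force candidate oracle: expand every alignment into per-column
# allele assertions, tally multisets per column, apply the support rule
oracle_candidates <- function(reads, refseq, min_support = 2L) {
  rch <- strsplit(refseq, "")[[1]]
  events <- list()
  depth <- integer(nchar(refseq))
  for (i in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[i],
                      gregexpr("[0-9]+[A-Z]", reads$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z]", "", ops))
    opc <- sub("[0-9]+", "", ops)
    p <- reads$start[i]; q <- 0L
    bch <- strsplit(reads$bases[i], "")[[1]]
    for (k in seq_along(opc)) {
      if (opc[k] == "S") { q <- q + lens[k] }
      else if (opc[k] == "M") {
        for (t in seq_len(lens[k])) {
          rp <- p + t - 1L
          depth[rp + 1L] <- depth[rp + 1L] + 1L
          rb <- rch[rp + 1L]; qb <- bch[q + t]
          if (rb != qb && rb != "N" && qb != "N") {
            events[[length(events) + 1L]] <-
              list(read = i, pos = rp, ref = rb, alt = qb, kind = "SNP")
          }
        }
        p <- p + lens[k]; q <- q + lens[k]
      } else if (opc[k] == "I") {
        ins <- paste(bch[(q + 1L):(q + lens[k])], collapse = "")
        la <- oracle_leftalign(refseq, p - 1L,
                               rch[p], paste0(rch[p], ins))
        if (!is.null(la) && !grepl("N", ins)) {
          events[[length(events) + 1L]] <-
            c(la, list(read = i, kind = "insertion"))
        }
        q <- q + lens[k]
      } else if (opc[k] == "D") {
        del <- paste(rch[(p + 1L):(p + lens[k])], collapse = "")
        la <- oracle_leftalign(refseq, p - 1L,
                               paste0(rch[p], del), rch[p])
        if (!is.null(la) && !grepl("N", paste0(del, rch[p]))) {
          events[[length(events) + 1L]] <-
            c(la, list(read = i, kind = "deletion"))
        }
        p <- p + lens[k]
      }
    }
  }
  if (!length(events)) {
    return(data.table(pos = integer(), ref = character(), alt = character(),
                      alt_support = integer(), total_depth = integer(),
                      kind = character()))
  }
  ev <- rbindlist(lapply(events, as.data.table), use.names = TRUE)
  tal <- ev[, .(alt_support = length(unique(read))),
            by = .(pos, ref, alt, kind)]
  tal[, total_depth := depth[pos + 1L]]
  tal <- tal[alt_support >= min_support]
  # biallelic rule: strongest alternate, ties by allele string
  setorder(tal, pos, -alt_support, alt)
  tal <- tal[, head(.SD, 1L), by = pos]
  setorder(tal, pos, alt)
  tal[, .(pos, ref, alt, alt_support, total_depth, kind)]
}

# random mini-pileup for oracle equivalence tests
random_mini_pileup <- function(seed) {
  set.seed(seed)
  L <- sample(120:300, 1L)
  refseq <- rand_seq(L)
  n <- sample(3:20, 1L)
  reads <- random_reads(refseq, n, len = sample(c(25L, 30L, 40L), 1L),
                        p_snp = 0.6, p_indel = 0.25, p_clip = 0.15)
  list(reference = tiny_reference(c(chrT = refseq)), reads = reads,
       refseq = refseq)
}

# synthetic, linearly separable pg_examples for genotyper tests: class
# k has mean intensity ~ (k+1)/4 in the read block of channel BASE
toy_examples <- function(n_per_class = 30L, height = 6L, width = 9L,
                         seed = 1L, contigs = c("c1", "c2")) {
  set.seed(seed)
  nch <- 6L
  nfl <- 2L * height * width * nch
  tensors <- list(); labs <- integer(); ctg <- character()
  for (k in 0:2) {
    for (i in seq_len(n_per_class)) {
      x <- numeric(nfl)
      base_idx <- seq(1L, nfl, by = nch)                  # channel 1
      read_rows <- base_idx > nfl / 2                     # read block
      x[base_idx[read_rows]] <- pmin(1, pmax(0,
        (k + 1) / 4 + rnorm(sum(read_rows), 0, 0.03)))
      tensors[[length(tensors) + 1L]] <- writeBin(x, raw(), size = 4L)
      labs <- c(labs, k)
      ctg <- c(ctg, contigs[1L + (i %% length(contigs))])
    }
  }
  meta <- data.table(contig = ctg, pos = seq_along(labs) * 10L,
                     ref = "A", alt = "C", alt_support = 5L,
                     total_depth = 10L, kind = "SNP", label = labs)
  structure(list(tensors = tensors, meta = meta, width = width,
                 height = height, channels = pg_channels()),
            class = "pg_examples")
}

# a pileup with n reads of which n_alt share one substitution
support_pileup_boundary <- function(n, n_alt, L = 120L) {
  refseq <- rand_seq(L)
  b <- substr(refseq, 61, 61)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  bases <- vapply(seq_len(n), function(i) {
    s <- substr(refseq, 41, 80)
    if (i <= n_alt) substr(s, 21, 21) <- alt
    s
  }, "")
  reads <- new_alignments(sprintf("r%02d", seq_len(n)), "chrT", 40L, "40M",
                          bases, strrep("F", 40L), 60L, "+", "read")
  list(ref = tiny_reference(c(chrT = refseq)), reads = reads,
       pos = 60L, alt = alt)
}

# truth/call tables from key strings (evaluation fixtures)
acc_truth <- function(keys, gt) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  dt <- data.table(contig = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   ref = vapply(parts, `[`, "", 3L),
                   alt = vapply(parts, `[`, "", 4L),
                   gt = gt)
  dt[, key := keys]
  dt[]
}

acc_calls <- function(keys, genotype) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  dt <- data.table(contig = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   ref = vapply(parts, `[`, "", 3L),
                   alt = vapply(parts, `[`, "", 4L),
                   genotype = genotype)
  dt[, `:=`(filter = "PASS", key = keys)]
  dt[]
}

# memoized expensive fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_scenario("small", seed = 20260920L)
  }
  .fixture_env$small
}

small_examples <- function() {
  if (is.null(.fixture_env$small_ex)) {
    b <- small_bundle()
    cands <- discover_candidates(b$reads, b$reference)
    .fixture_env$small_ex <- build_examples(cands, b$reads, b$panel,
                                            b$reference, pileup_config(),
                                            truth = b$truth)
  }
  .fixture_env$small_ex
}
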