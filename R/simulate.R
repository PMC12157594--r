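`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Defines the generative conditions for a synthetic diploid experiment:
#' a random reference with one high-identity duplicated block per contig,
#' a panel of phased haplotypes whose allele carrier counts follow a
#' neutral 1/i site-frequency law, a diploid sample copying two panel
#' donors plus private variants, and error-bearing single-end reads of
#' which a fraction originating inside the duplication is mismapped to
#' the homologous copy (with low mapping quality and unchanged sequence —
#' the reference-bias signature the haplotype block is meant to resolve).
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param panel_size Number of panel haplotypes (even, so haplotypes pair
#'   into pseudo-diploid VCF samples).
#' @param panel_site_rate Per-bp probability of a polymorphic panel site.
#' @param indel_fraction Fraction of simulated variants that are indels
#'   (split evenly between insertions and deletions, lengths 1 to
#'   `indel_max`); the remainder are SNVs.
#' @param indel_max Maximum indel length.
#' @param private_rate Per-bp, per-haplotype rate of sample-private
#'   variants absent from the panel.
#' @param read_length Read length (bp).
#' @param coverage Mean diploid coverage.
#' @param error_rate Per-base sequencing error rate.
#' @param duplication Named list (per contig) of `c(src, len, dest)`:
#'   a segmental duplication copying `[src, src+len)` to
#'   `[dest, dest+len)`, or `NULL` for none.
#' @param dup_identity Sequence identity of the duplicated copy, in
#'   `[0.95, 1)`.
#' @param mismap_prob Probability that a read lying fully inside the
#'   duplication is re-addressed to the homologous copy (mapping quality
#'   set to 2).
#' @param donors Optional fixed donor haplotype indices (length 2).
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(contig_lengths = c(chrA = 500000L, chrB = 500000L),
                       panel_size = 20L, panel_site_rate = 0.003,
                       indel_fraction = 0.1, indel_max = 5L,
                       private_rate = 5e-5, read_length = 150L,
                       coverage = 30, error_rate = 0.001,
                       duplication = list(chrA = c(src = 100000L, len = 20000L,
                                                   dest = 300000L),
                                          chrB = c(src = 100000L, len = 20000L,
                                                   dest = 300000L)),
                       dup_identity = 0.99, mismap_prob = 0.25,
                       donors = NULL, seed = 1L) {
  stopifnot(all(contig_lengths > 1000L), panel_size >= 2L,
            panel_size %% 2L == 0L,
            panel_site_rate >= 0, panel_site_rate <= 1,
            private_rate >= 0, private_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            mismap_prob >= 0, mismap_prob <= 1,
            dup_identity >= 0.95, dup_identity < 1, coverage > 0)
  for (ci in names(duplication)) {
    d <- duplication[[ci]]
    if (is.null(d)) next
    if (intervals_overlap(d["src"], d["src"] + d["len"],
                          d["dest"], d["dest"] + d["len"])) {
      stop("duplication source and destination overlap on ", ci)
    }
    stopifnot(d["src"] >= 0, d["dest"] + d["len"] <= contig_lengths[[ci]])
  }
  structure(list(contig_lengths = contig_lengths,
                 panel_size = as.integer(panel_size),
                 panel_site_rate = panel_site_rate,
                 indel_fraction = indel_fraction,
                 indel_max = as.integer(indel_max),
                 private_rate = private_rate,
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 duplication = duplication, dup_identity = dup_identity,
                 mismap_prob = mismap_prob, donors = donors,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation conditions
#'
#' `"small"`: 2 contigs x 500 kb, panel of 20, 30x coverage, 0.1% error,
#' one 20 kb duplication at 99% identity per contig with mismap
#' probability 0.25 — the end-to-end training/calling fixture.
#' `"biased"`: 2 contigs x 150 kb with mismap probability 0.5, making
#' read evidence at paralog-divergence sites mimic heterozygous support —
#' the reference-bias scenario where the haplotype block is informative.
#'
#' @param preset `"small"` or `"biased"`.
#' @param seed Master seed.
#' @return A [sim_config].
#' @export
sim_preset <- function(preset = c("small", "biased"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "small") {
    sim_config(seed = seed)
  } else {
    sim_config(contig_lengths = c(chrA = 150000L, chrB = 150000L),
               duplication = list(chrA = c(src = 30000L, len = 15000L,
                                           dest = 90000L),
                                  chrB = c(src = 30000L, len = 15000L,
                                           dest = 90000L)),
               mismap_prob = 0.5, seed = seed)
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, positions) {
  # substitute a random different base at each (1-based) position
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# greedy spacing filter on sorted positions
space_positions <- function(pos, min_gap) {
  if (length(pos) <= 1L) return(pos)
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= min_gap) { keep[i] <- TRUE; last <- pos[i] }
  }
  pos[keep]
}

# draw variant alleles at given 0-based positions on refseq; returns a
# data.table, keeping only variants whose normalized (left-aligned)
# representation equals the drawn one, so truth and discovery agree on
# coordinates without ambiguity
draw_variants <- function(refseq, pos, indel_fraction, indel_max) {
  if (length(pos) == 0L) {
    return(data.table(pos = integer(), ref = character(), alt = character()))
  }
  refb <- substring(refseq, pos + 1L, pos + 1L)
  is_indel <- runif(length(pos)) < indel_fraction
  is_ins <- is_indel & runif(length(pos)) < 0.5
  is_del <- is_indel & !is_ins
  ref <- refb
  alt <- refb
  snp <- !is_indel
  alt[snp] <- vapply(refb[snp], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  if (any(is_ins)) {
    lens <- sample.int(indel_max, sum(is_ins), replace = TRUE)
    alt[is_ins] <- paste0(refb[is_ins], vapply(lens, random_dna, ""))
  }
  if (any(is_del)) {
    lens <- sample.int(indel_max, sum(is_del), replace = TRUE)
    ref[is_del] <- substring(refseq, pos[is_del] + 1L, pos[is_del] + 1L + lens)
  }
  dt <- data.table(pos = pos, ref = ref, alt = alt)
  dt <- dt[!grepl("N", paste0(ref, alt))]
  nv <- cpp_normalize_variants(dt$pos, dt$ref, dt$alt, refseq)
  dt[nv$pos == dt$pos & nv$ref == dt$ref & nv$alt == dt$alt]
}

#' Simulate a reference and haplotype panel
#'
#' @param config A [sim_config].
#' @return List with `reference` (`pg_reference`), `panel`
#'   (`haplotype_panel`), `sites` (panel site table with carrier lists)
#'   and `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$panel_size
  seqs <- character(0)
  site_list <- list()
  min_gap <- config$indel_max + 3L
  for (ci in names(config$contig_lengths)) {
    L <- config$contig_lengths[[ci]]
    s <- random_dna(L)
    d <- config$duplication[[ci]]
    if (!is.null(d)) {
      src_seq <- substr(s, d["src"] + 1L, d["src"] + d["len"])
      ndiv <- rbinom(1L, d["len"], 1 - config$dup_identity)
      divpos <- sort(sample.int(d["len"], ndiv))
      dest_seq <- mutate_bases(src_seq, divpos)
      s <- paste0(substr(s, 1L, d["dest"]), dest_seq,
                  substr(s, d["dest"] + d["len"] + 1L, L))
    }
    seqs[ci] <- s
    nsite <- rbinom(1L, L, config$panel_site_rate)
    pos <- sort(sample.int(L - 2L * min_gap, min(nsite, L %/% (2L * min_gap))) +
                  min_gap - 1L)
    pos <- space_positions(pos, min_gap)
    vars <- draw_variants(s, pos, config$indel_fraction, config$indel_max)
    if (nrow(vars)) {
      cc <- seq_len(n - 1L)
      ncar <- sample(cc, nrow(vars), replace = TRUE, prob = 1 / cc)
      vars[, carriers := lapply(ncar, function(k) sort(sample.int(n, k)))]
      vars[, contig := ci]
      site_list[[ci]] <- vars
    }
  }
  reference <- new_reference(seqs)
  sites <- if (length(site_list)) rbindlist(site_list) else
    data.table(pos = integer(), ref = character(), alt = character(),
               carriers = list(), contig = character())
  hap_rows <- list()
  for (ci in names(config$contig_lengths)) {
    sc <- sites[contig == ci]
    for (h in seq_len(n)) {
      hv <- if (nrow(sc)) sc[vapply(carriers, function(x) h %in% x, TRUE)] else sc
      ap <- apply_variants(reference$seq[[ci]], hv$pos, hv$ref, hv$alt)
      hap_rows[[length(hap_rows) + 1L]] <- data.table(
        name = sprintf("hap%02d", h), contig = ci, start = 0L,
        cigar = ap$cigar, bases = ap$seq, qual = NA_character_,
        mapq = NA_integer_, strand = "*", origin = "haplotype")
    }
  }
  haps <- rbindlist(hap_rows)
  validate_alignments(haps)
  list(reference = reference,
       panel = new_panel(haps, n, "alignments"),
       sites = sites, config = config)
}

#' Simulate a diploid sample from a panel
#'
#' Two donor haplotypes are copied from the panel and private variants
#' are added at `private_rate`; the truth set is the exact diff of the
#' sample haplotypes against the reference, phased and genotyped.
#'
#' @param sim Output of [simulate_panel].
#' @param config The same [sim_config].
#' @return List with `donors`, `truth` (phased truth table), `confident`
#'   (BED table), `hap_variants` (per-haplotype variant table) and
#'   `sample_seqs` (list contig -> 2 haplotype sequences).
#' @export
simulate_diploid <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  n <- config$panel_size
  donors <- config$donors %||% sort(sample.int(n, 2L))
  stopifnot(length(donors) == 2L, all(donors >= 1L & donors <= n))
  min_gap <- config$indel_max + 3L
  hv_list <- list()
  for (ci in names(config$contig_lengths)) {
    L <- config$contig_lengths[[ci]]
    refseq <- sim$reference$seq[[ci]]
    sc <- sim$sites[contig == ci]
    for (h in 1:2) {
      dv <- if (nrow(sc)) {
        sc[vapply(carriers, function(x) donors[h] %in% x, TRUE),
           .(pos, ref, alt)]
      } else data.table(pos = integer(), ref = character(), alt = character())
      npriv <- rbinom(1L, L, config$private_rate)
      priv <- data.table(pos = integer(), ref = character(), alt = character())
      if (npriv > 0L) {
        cand <- sort(sample.int(L - 2L * min_gap, npriv) + min_gap - 1L)
        # keep private positions clear of panel sites and of each other
        occupied <- sort(c(sc$pos, hv_list_pos(hv_list, ci)))
        ok <- vapply(cand, function(p)
          !any(abs(occupied - p) < min_gap), TRUE)
        cand <- space_positions(cand[ok], min_gap)
        priv <- draw_variants(refseq, cand, config$indel_fraction,
                              config$indel_max)
      }
      hv <- rbind(dv, priv)
      setorder(hv, pos)
      check_variant_overlap(cbind(hv, contig = ci),
                            sprintf("sample haplotype %d (%s)", h, ci))
      hv[, `:=`(contig = ci, hap = h)]
      hv_list[[paste(ci, h)]] <- hv
    }
  }
  hap_variants <- rbindlist(hv_list)
  truth <- hap_variants[, .(phase1 = any(hap == 1L), phase2 = any(hap == 2L)),
                        by = .(contig, pos, ref, alt)]
  truth[, phase := paste0(as.integer(phase1), "|", as.integer(phase2))]
  truth[, gt := as.integer(phase1) + as.integer(phase2)]
  truth[, c("phase1", "phase2") := NULL]
  truth[, key := pg_key(contig, pos, ref, alt)]
  setorder(truth, contig, pos)
  confident <- data.table(
    contig = names(config$contig_lengths),
    start = 200L,
    end = as.integer(config$contig_lengths) - 200L)
  sample_seqs <- lapply(names(config$contig_lengths), function(ci) {
    vapply(1:2, function(h) {
      hv <- hap_variants[contig == ci & hap == h]
      apply_variants(sim$reference$seq[[ci]], hv$pos, hv$ref, hv$alt)$seq
    }, "")
  })
  names(sample_seqs) <- names(config$contig_lengths)
  list(donors = donors, truth = truth[], confident = confident,
       hap_variants = hap_variants, sample_seqs = sample_seqs)
}

hv_list_pos <- function(hv_list, ci) {
  ps <- lapply(hv_list, function(x) x[contig == ci, pos])
  if (length(ps)) unlist(ps) else integer()
}

# alignment segment table of one sample haplotype against the reference:
# M segments (hap_start, ref_start, len) broken at indels, with the
# inter-segment event ("I"/"D" and its length)
hap_segments <- function(L, variants) {
  ind <- variants[nchar(ref) != nchar(alt)]
  setorder(ind, pos)
  nseg <- nrow(ind) + 1L
  seg <- data.table(h = integer(nseg), r = integer(nseg), len = integer(nseg),
                    ev = character(nseg), evlen = integer(nseg))
  hcur <- 0L; rcur <- 0L
  for (i in seq_len(nrow(ind))) {
    p <- ind$pos[i]
    mlen <- p + 1L - rcur
    ins <- nchar(ind$alt[i]) > nchar(ind$ref[i])
    evl <- abs(nchar(ind$alt[i]) - nchar(ind$ref[i]))
    seg[i, `:=`(h = hcur, r = rcur, len = mlen,
                ev = ifelse(ins, "I", "D"), evlen = evl)]
    hcur <- hcur + mlen + if (ins) evl else 0L
    rcur <- p + 1L + if (ins) 0L else evl
  }
  seg[nseg, `:=`(h = hcur, r = rcur, len = L - rcur, ev = "", evlen = 0L)]
  seg
}

# CIGAR and reference start of a read covering hap positions [hs, e]
read_cigar_from_segments <- function(seg, i, hs, e) {
  ref_start <- seg$r[i] + (hs - seg$h[i])
  pieces <- character()
  cur <- hs
  t <- i
  repeat {
    seg_end <- seg$h[t] + seg$len[t] - 1L
    take <- min(e, seg_end) - cur + 1L
    if (take > 0L) pieces <- c(pieces, paste0(take, "M"))
    if (e <= seg_end) break
    if (seg$ev[t] == "I") {
      cov <- min(e, seg_end + seg$evlen[t]) - seg_end
      pieces <- c(pieces, paste0(cov, "I"))
      if (e <= seg_end + seg$evlen[t]) break
    } else {
      pieces <- c(pieces, paste0(seg$evlen[t], "D"))
    }
    t <- t + 1L
    cur <- seg$h[t]
  }
  list(ref_start = ref_start, cigar = paste(pieces, collapse = ""))
}

#' Simulate aligned reads from the diploid sample
#'
#' Single-end reads are drawn uniformly from both haplotypes to the
#' target mean coverage; sequencing errors are injected per base with
#' reduced base quality at error positions; reads lying fully inside a
#' duplication block are re-addressed to the homologous copy with
#' `mismap_prob`, keeping their true sequence. Every read contained in a
#' duplication copy carries mapping quality 2 — placement there is
#' ambiguous whether or not it is correct — while reads outside are
#' placed at their true coordinates with mapping quality 60.
#'
#' @param sim Output of [simulate_panel].
#' @param dip Output of [simulate_diploid].
#' @param config The same [sim_config].
#' @return Alignment `data.table` of reads, coordinate sorted.
#' @export
simulate_reads <- function(sim, dip, config = sim$config) {
  set.seed(config$seed + 2L)
  rl <- config$read_length
  out <- list()
  for (ci in names(config$contig_lengths)) {
    L <- config$contig_lengths[[ci]]
    if (rl > L) stop("read length exceeds contig ", ci)
    d <- config$duplication[[ci]]
    for (h in 1:2) {
      hseq <- dip$sample_seqs[[ci]][h]
      hlen <- nchar(hseq)
      hv <- dip$hap_variants[contig == ci & hap == h]
      seg <- hap_segments(L, hv)
      nreads <- round(L * config$coverage / 2 / rl)
      hs <- sample.int(hlen - rl + 1L, nreads, replace = TRUE) - 1L
      i <- findInterval(hs, seg$h)
      # a start inside an insertion gap snaps to the next M segment
      in_gap <- hs >= seg$h[i] + seg$len[i]
      if (any(in_gap)) {
        i[in_gap] <- pmin(i[in_gap] + 1L, nrow(seg))
        hs[in_gap] <- seg$h[i[in_gap]]
        hs <- pmin(hs, hlen - rl)
      }
      e <- hs + rl - 1L
      j <- findInterval(e, seg$h)
      simple <- i == j & e < seg$h[i] + seg$len[i]
      ref_start <- integer(nreads)
      cigar <- character(nreads)
      ref_start[simple] <- seg$r[i[simple]] + (hs[simple] - seg$h[i[simple]])
      cigar[simple] <- paste0(rl, "M")
      for (k in which(!simple)) {
        rc <- read_cigar_from_segments(seg, i[k], hs[k], e[k])
        ref_start[k] <- rc$ref_start
        cigar[k] <- rc$cigar
      }
      bases <- substring(hseq, hs + 1L, hs + rl)
      qual <- rep(strrep("F", rl), nreads)
      nerr <- rbinom(nreads, rl, config$error_rate)
      for (k in which(nerr > 0L)) {
        ep <- sample.int(rl, nerr[k])
        b <- strsplit(bases[k], "")[[1]]
        q <- strsplit(qual[k], "")[[1]]
        for (p in ep) {
          b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
          q[p] <- "-"
        }
        bases[k] <- paste(b, collapse = "")
        qual[k] <- paste(q, collapse = "")
      }
      span <- cpp_cigar_info(cigar)$rspan
      mapq <- rep(60L, nreads)
      if (!is.null(d)) {
        off <- as.integer(d["dest"] - d["src"])
        in_src <- ref_start >= d["src"] & ref_start + span <= d["src"] + d["len"]
        in_dest <- ref_start >= d["dest"] & ref_start + span <= d["dest"] + d["len"]
        flip <- runif(nreads) < config$mismap_prob
        ref_start[in_src & flip] <- ref_start[in_src & flip] + off
        ref_start[in_dest & flip] <- ref_start[in_dest & flip] - off
        # placement inside a high-identity duplication is ambiguous for a
        # short read whether or not it ends up at the right copy, so every
        # duplication-contained read gets a low mapping quality
        mapq[in_src | in_dest] <- 2L
      }
      strand <- sample(c("+", "-"), nreads, replace = TRUE)
      out[[paste(ci, h)]] <- data.table(
        name = sprintf("r_%s_h%d_%06d", ci, h, seq_len(nreads)),
        contig = ci, start = ref_start, cigar = cigar, bases = bases,
        qual = qual, mapq = mapq, strand = strand, origin = "read")
    }
  }
  dt <- rbindlist(out)
  validate_alignments(dt)
  setorder(dt, contig, start, name)
  dt[]
}

#' Region partition of a simulated scenario
#'
#' Labels the duplication blocks (`"SD<identity>"`) and the remainder of
#' each contig (`"rest"`), mirroring the segmental-duplication identity
#' partitions used in stratified evaluation.
#'
#' @param config A [sim_config].
#' @return BED `data.table` with `contig`, `start`, `end`, `label`.
#' @export
sim_partition <- function(config) {
  rows <- list()
  sd_label <- paste0("SD", round(config$dup_identity * 100))
  for (ci in names(config$contig_lengths)) {
    L <- as.integer(config$contig_lengths[[ci]])
    d <- config$duplication[[ci]]
    if (is.null(d)) {
      rows[[ci]] <- data.table(contig = ci, start = 0L, end = L,
                               label = "rest")
      next
    }
    ivs <- data.table(start = as.integer(c(d["src"], d["dest"])),
                      end = as.integer(c(d["src"] + d["len"],
                                         d["dest"] + d["len"])))
    setorder(ivs, start)
    sd <- data.table(contig = ci, start = ivs$start, end = ivs$end,
                     label = sd_label)
    gaps <- data.table(
      contig = ci,
      start = c(0L, ivs$end),
      end = c(ivs$start, L))
    gaps <- gaps[start < end]
    gaps[, label := "rest"]
    rows[[ci]] <- rbind(sd, gaps)
  }
  out <- rbindlist(rows)
  setorder(out, contig, start)
  out[]
}

#' Simulate a complete scenario bundle
#'
#' Composes [simulate_panel], [simulate_diploid] and [simulate_reads]
#' under a preset, optionally writing the bundle to a directory as
#' standard files (FASTA, SAM, FASTQ, VCF, BED) plus a JSON manifest
#' holding the seed, preset and donor choices; regenerating from the
#' manifest's seed reproduces the bundle byte for byte.
#'
#' @param preset `"small"` or `"biased"` (see [sim_preset]).
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @param config Optional explicit [sim_config] overriding the preset.
#' @return List with `config`, `reference`, `panel`, `sites`, `donors`,
#'   `truth`, `confident`, `partition`, `reads`, `sample_seqs`,
#'   `manifest`.
#' @export
simulate_scenario <- function(preset = "small", seed = 1L, out_dir = NULL,
                              config = NULL) {
  cfg <- config %||% sim_preset(preset, seed)
  sim <- simulate_panel(cfg)
  dip <- simulate_diploid(sim, cfg)
  reads <- simulate_reads(sim, dip, cfg)
  manifest <- list(package = "pangecall", preset = preset,
                   seed = cfg$seed, donors = dip$donors,
                   contigs = as.list(cfg$contig_lengths),
                   panel_size = cfg$panel_size,
                   n_truth_variants = nrow(dip$truth),
                   n_reads = nrow(reads))
  bundle <- list(config = cfg, reference = sim$reference, panel = sim$panel,
                 sites = sim$sites, donors = dip$donors, truth = dip$truth,
                 confident = dip$confident, partition = sim_partition(cfg),
                 reads = reads, sample_seqs = dip$sample_seqs,
                 manifest = manifest)
  if (!is.null(out_dir)) write_scenario(bundle, out_dir)
  invisible(bundle)
}

#' Desk-scale reference-bias scenario
#'
#' The `"biased"` preset of [simulate_scenario]: inside the segmental
#' duplication, mismapped reads make paralog-divergence sites look like
#' heterozygous variants from read evidence alone, so the haplotype
#' block carries the distinguishing signal.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A scenario bundle (see [simulate_scenario]).
#' @export
simulate_biased_scenario <- function(seed = 1L, out_dir = NULL) {
  simulate_scenario("biased", seed, out_dir)
}

#' Write a scenario bundle to standard files
#'
#' @param bundle Output of [simulate_scenario].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_reference(bundle$reference, fp("ref.fa"))
  write_sam(bundle$panel$haplotypes, bundle$reference, fp("panel.sam"))
  write_panel_vcf(bundle, fp("panel.vcf"))
  write_sam(bundle$reads, bundle$reference, fp("reads.sam"))
  write_fastq(bundle$reads, fp("reads.fastq"))
  write_sites_vcf(bundle$truth[, .(contig, pos, ref, alt)],
                  matrix(bundle$truth$phase, ncol = 1L), "SAMPLE",
                  bundle$reference, fp("truth.vcf"))
  write_bed(bundle$confident, fp("confident.bed"))
  write_bed(bundle$partition, fp("partition.bed"))
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write the panel as a phased multi-sample VCF
#'
#' Panel haplotypes are paired in order into pseudo-diploid samples
#' (hap01/hap02 -> S01, ...), preserving phase.
#'
#' @param bundle Output of [simulate_scenario] or [simulate_panel]
#'   (needs `sites`, `reference`, `config`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(bundle, path) {
  n <- bundle$config$panel_size
  sites <- bundle$sites
  ns <- n %/% 2L
  gt <- matrix("", nrow = nrow(sites), ncol = ns)
  for (j in seq_len(ns)) {
    h1 <- 2L * j - 1L; h2 <- 2L * j
    gt[, j] <- paste0(
      as.integer(vapply(sites$carriers, function(x) h1 %in% x, TRUE)), "|",
      as.integer(vapply(sites$carriers, function(x) h2 %in% x, TRUE)))
  }
  write_sites_vcf(sites[, .(contig, pos, ref, alt)], gt,
                  sprintf("S%02d", seq_len(ns)), bundle$reference, path)
}
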