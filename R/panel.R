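#' Haplotype panels
#'
#' A pangenome is represented as an ordered set of haplotypes aligned to
#' the linear reference (one aligned record per haplotype per covered
#' region), mirroring how haplotype alignments are extracted from a
#' pangenome graph that embeds the reference. Haplotype order is the file
#' order and is stable, which keeps pileup row assignment deterministic.
#'
#' @param haplotypes Alignment `data.table` with `origin == "haplotype"`.
#' @param haplotype_count Declared number of haplotypes in the panel (may
#'   exceed the number of records when a region query returned few).
#' @param source `"alignments"` or `"phased_vcf"`.
#' @return A `haplotype_panel` object.
#' @export
new_panel <- function(haplotypes, haplotype_count, source = "alignments") {
  haplotype_count <- as.integer(haplotype_count)
  stopifnot(haplotype_count >= 1L)
  structure(list(haplotypes = haplotypes,
                 haplotype_count = haplotype_count,
                 source = source,
                 cache = new.env(parent = emptyenv())),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", x$haplotype_count, " haplotypes (",
      nrow(x$haplotypes), " aligned records, source: ", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' Load a haplotype panel from haplotype-to-reference alignments
#'
#' @param path SAM/BAM of haplotype contigs aligned to the same reference
#'   the reads were mapped to.
#' @param region Optional [genomic_interval] restriction. The declared
#'   `haplotype_count` always reflects the whole file, so an empty region
#'   yields a panel with zero records but the full count.
#' @param reference Optional `pg_reference`; when given, every haplotype
#'   must be aligned to a contig of this reference (the pangenome must
#'   include the linear reference).
#' @return A `haplotype_panel`.
#' @export
load_panel_from_alignments <- function(path, region = NULL, reference = NULL) {
  all_aln <- load_alignments(path, region = NULL, origin = "haplotype")
  if (!is.null(reference)) {
    missing <- setdiff(unique(all_aln$contig), names(reference$lengths))
    if (length(missing)) {
      stop("panel haplotypes aligned to contig(s) absent from the reference: ",
           paste(missing, collapse = ", "),
           "; the pangenome must include the linear reference")
    }
  }
  n_hap <- length(unique(all_aln$name))
  aln <- if (is.null(region)) all_aln else {
    spans <- alignment_span(all_aln)
    all_aln[contig == region$contig &
              intervals_overlap(start, start + spans, region$start, region$end)]
  }
  new_panel(aln, max(n_hap, 1L), "alignments")
}

#' Build a haplotype panel from a phased multi-sample VCF
#'
#' Each diploid sample contributes two haplotypes; each haplotype sequence
#' is the reference with that haplotype's alleles applied, and its CIGAR
#' is constructed directly from the applied variants (no realignment).
#'
#' @param vcf_path Phased multi-sample VCF (biallelic records).
#' @param reference A `pg_reference`.
#' @param region Optional [genomic_interval]; restricts both the variants
#'   applied and the contigs reconstructed.
#' @return A `haplotype_panel` with `source = "phased_vcf"`.
#' @export
panel_from_phased_vcf <- function(vcf_path, reference, region = NULL) {
  v <- read_vcf_table(vcf_path, genotypes = "all")
  samples <- attr(v, "samples")
  if (length(samples) == 0L) stop("VCF has no sample columns: ", vcf_path)
  if (nrow(v)) {
    unphased <- Reduce(`|`, lapply(samples, function(s)
      grepl("/", v[[s]], fixed = TRUE)))
    if (any(unphased)) {
      bad <- which(unphased)[1]
      stop("unphased genotype in record ", v$contig[bad], ":", v$pos[bad] + 1L,
           "; panel reconstruction requires '|'-phased GT")
    }
  }
  contigs <- if (is.null(region)) names(reference$seq) else region$contig
  haps <- vector("list", 2L * length(samples) * length(contigs))
  k <- 0L
  for (ci in contigs) {
    refseq <- reference$seq[[ci]]
    vc <- v[contig == ci]
    if (!is.null(region)) vc <- vc[pos >= region$start & pos < region$end]
    setorder(vc, pos)
    for (si in seq_along(samples)) {
      gts <- strsplit(vc[[samples[si]]], "|", fixed = TRUE)
      for (phase in 1:2) {
        allele <- if (nrow(vc)) as.integer(vapply(gts, `[`, "", phase)) else integer()
        sel <- which(allele == 1L)
        vv <- vc[sel]
        check_variant_overlap(vv, sprintf("sample %s haplotype %d", samples[si], phase))
        ap <- apply_variants(refseq, vv$pos, vv$ref, vv$alt)
        k <- k + 1L
        haps[[k]] <- data.table(
          name = sprintf("%s_h%d", samples[si], phase), contig = ci,
          start = 0L, cigar = ap$cigar, bases = ap$seq,
          qual = NA_character_, mapq = NA_integer_, strand = "*",
          origin = "haplotype")
      }
    }
  }
  dt <- rbindlist(haps[seq_len(k)])
  validate_alignments(dt)
  new_panel(dt, 2L * length(samples), "phased_vcf")
}

check_variant_overlap <- function(v, what) {
  if (nrow(v) < 2L) return(invisible())
  ends <- v$pos + nchar(v$ref)
  bad <- which(ends[-length(ends)] > v$pos[-1])
  if (length(bad)) {
    stop("overlapping variants on ", what, " at ", v$contig[bad[1]], ":",
         v$pos[bad[1]] + 1L, " and ", v$pos[bad[1] + 1L] + 1L)
  }
  invisible()
}

#' Apply variants to a reference sequence
#'
#' Variants must be non-overlapping, anchored (indels share their first
#' base with the reference allele) and sorted by position. Returns the
#' edited sequence together with the alignment CIGAR of the edited
#' sequence against the original.
#'
#' @param refseq Reference contig sequence (character scalar).
#' @param pos 0-based variant positions.
#' @param ref,alt Reference/alternate alleles.
#' @return List with `seq` and `cigar`.
#' @export
apply_variants <- function(refseq, pos, ref, alt) {
  if (length(pos) == 0L) {
    return(list(seq = refseq, cigar = paste0(nchar(refseq), "M")))
  }
  o <- order(pos)
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  n <- length(pos)
  L <- nchar(refseq)
  pieces <- character(2L * n + 1L)
  cig <- character(0)
  prev <- 0L
  for (i in seq_len(n)) {
    p <- pos[i]; r <- ref[i]; a <- alt[i]
    if (p < prev) stop("variants overlap or are unsorted at position ", p)
    gap <- p - prev
    pieces[2L * i - 1L] <- substr(refseq, prev + 1L, p)
    pieces[2L * i] <- a
    rl <- nchar(r); al <- nchar(a)
    if (rl == al) {
      cig <- c(cig, paste0(gap + rl, "M"))
    } else if (rl == 1L && al > 1L) {        # insertion (anchored)
      cig <- c(cig, paste0(gap + 1L, "M"), paste0(al - 1L, "I"))
    } else if (al == 1L && rl > 1L) {        # deletion (anchored)
      cig <- c(cig, paste0(gap + 1L, "M"), paste0(rl - 1L, "D"))
    } else stop("unsupported allele pair ", r, ">", a)
    prev <- p + rl
  }
  pieces[2L * n + 1L] <- substr(refseq, prev + 1L, L)
  if (L - prev > 0L) cig <- c(cig, paste0(L - prev, "M"))
  list(seq = paste(pieces, collapse = ""),
       cigar = cpp_normalize_cigars(paste(cig, collapse = "")))
}

#' Per-haplotype variant keys of a panel
#'
#' Diffs every haplotype record against the reference (walking its CIGAR)
#' and returns one row per (haplotype, variant) with normalized,
#' left-aligned alleles. Results are cached on the panel.
#'
#' @param panel A `haplotype_panel`.
#' @param reference A `pg_reference`.
#' @return `data.table` with `name` (haplotype), `contig`, `pos`, `ref`,
#'   `alt`, `key`.
#' @export
panel_variants <- function(panel, reference) {
  if (!is.null(panel$cache$variants)) return(panel$cache$variants)
  out <- list()
  haps <- panel$haplotypes
  for (ci in unique(haps$contig)) {
    sub <- haps[contig == ci]
    ev <- cpp_candidate_events(sub$start, sub$cigar, sub$bases,
                               rep(NA_character_, nrow(sub)),
                               reference$seq[[ci]], 0L)
    if (length(ev$pos) == 0L) next
    out[[ci]] <- data.table(name = sub$name[ev$read], contig = ci,
                            pos = ev$pos, ref = ev$ref, alt = ev$alt)
  }
  v <- if (length(out)) rbindlist(out) else
    data.table(name = character(), contig = character(), pos = integer(),
               ref = character(), alt = character())
  v[, key := pg_key(contig, pos, ref, alt)]
  panel$cache$variants <- v
  v
}

#' Panel allele frequency of a variant
#'
#' The fraction of panel haplotypes carrying exactly this (normalized)
#' alternate allele. Alleles absent from the panel have frequency 0.
#'
#' @param panel A `haplotype_panel`.
#' @param reference A `pg_reference` (used for normalization and for
#'   diffing the haplotypes).
#' @param contig,pos,ref,alt Variant key (vectors recycled to common
#'   length; `pos` 0-based).
#' @return `data.table` with the normalized key, `n_carriers` and
#'   `frequency`.
#' @export
panel_allele_frequency <- function(panel, reference, contig, pos, ref, alt) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  dt <- data.table(contig = rep_len(as.character(contig), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n))
  norm <- lapply(seq_len(n), function(i) {
    nv <- cpp_normalize_variants(dt$pos[i], dt$ref[i], dt$alt[i],
                                 reference$seq[[dt$contig[i]]])
    list(pos = nv$pos, ref = nv$ref, alt = nv$alt)
  })
  dt[, pos := vapply(norm, function(x) as.integer(x$pos), 1L)]
  dt[, ref := vapply(norm, function(x) as.character(x$ref), "")]
  dt[, alt := vapply(norm, function(x) as.character(x$alt), "")]
  dt[, key := pg_key(contig, pos, ref, alt)]
  pv <- panel_variants(panel, reference)
  carriers <- pv[, .(n_carriers = length(unique(name))), by = key]
  out <- carriers[dt, on = "key"]
  out[is.na(n_carriers), n_carriers := 0L]
  out[, frequency := n_carriers / panel$haplotype_count]
  out[]
}

#' Variant key strings
#' @param contig,pos,ref,alt Variant fields (`pos` 0-based).
#' @return `"contig:pos:ref:alt"` strings.
#' @export
pg_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}
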