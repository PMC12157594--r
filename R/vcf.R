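#' Read a VCF into a flat table
#'
#' Thin wrapper over `VariantAnnotation::readVcf` converting to the
#' package's 0-based coordinates. Records must be biallelic (split
#' multiallelics upstream).
#'
#' @param path VCF path (plain or bgzipped).
#' @param genotypes `"all"` to keep one GT column per sample, `"none"` to
#'   drop genotypes.
#' @return `data.table` with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `filter` and one character GT column per sample; sample names in
#'   `attr(, "samples")`.
#' @export
read_vcf_table <- function(path, genotypes = "all") {
  vcf <- VariantAnnotation::readVcf(path, genome = "pg")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  if (any(n_alt != 1L)) {
    stop("VCF record ", which(n_alt != 1L)[1], " in ", path,
         " is not biallelic; split multiallelic records first")
  }
  dt <- data.table(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_list)),
    filter = as.character(rr$FILTER)
  )
  samples <- character()
  if (identical(genotypes, "all")) {
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (!is.null(gt)) {
      samples <- colnames(gt)
      for (s in samples) dt[, (s) := as.character(gt[, s])]
    }
  }
  setattr(dt, "samples", samples)
  dt[]
}

vcf_header_lines <- function(reference, sample_names, extra = character()) {
  c("##fileformat=VCFv4.2",
    "##source=pangecall",
    sprintf("##contig=<ID=%s,length=%d>", names(reference$lengths),
            as.integer(reference$lengths)),
    "##FILTER=<ID=PASS,Description=\"Passing genotype call\">",
    "##FILTER=<ID=RefCall,Description=\"Genotype call is reference\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (Phred)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref, alt)\">",
    extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a phased multi-sample site VCF
#'
#' Used for simulated truth sets (one sample) and simulated panel VCFs
#' (haplotypes paired into pseudo-diploid samples). `gt` is a matrix of
#' phased GT strings, one column per sample.
#'
#' @param sites `data.table` with `contig`, `pos` (0-based), `ref`, `alt`.
#' @param gt Character matrix, `nrow(sites)` x `length(sample_names)`.
#' @param sample_names Sample column names.
#' @param reference A `pg_reference` for the header.
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, gt, sample_names, reference, path) {
  body <- character()
  if (nrow(sites)) {
    gt <- matrix(as.character(gt), nrow = nrow(sites))
    stopifnot(ncol(gt) == length(sample_names))
    o <- order(match(sites$contig, names(reference$lengths)), sites$pos)
    sites <- sites[o]
    gt <- gt[o, , drop = FALSE]
    body <- paste(sites$contig, sites$pos + 1L, ".", sites$ref, sites$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  writeLines(c(vcf_header_lines(reference, sample_names), body), con)
  invisible(path)
}

#' Load a truth VCF
#'
#' @param path VCF with one phased sample.
#' @param reference `pg_reference` used to normalize alleles.
#' @return `data.table` with `contig`, `pos`, `ref`, `alt`, `gt`
#'   (genotype class: 1 = heterozygous, 2 = homozygous alternate),
#'   `phase` (the raw GT string) and `key`.
#' @export
load_truth_vcf <- function(path, reference) {
  v <- read_vcf_table(path)
  samples <- attr(v, "samples")
  if (length(samples) != 1L) stop("truth VCF must contain exactly one sample")
  truth_table(v$contig, v$pos, v$ref, v$alt, v[[samples[1]]], reference)
}

truth_table <- function(contig, pos, ref, alt, phase, reference) {
  dt <- data.table(contig = contig, pos = as.integer(pos), ref = ref,
                   alt = alt, phase = phase)
  alleles <- strsplit(gsub("|", "/", dt$phase, fixed = TRUE), "/", fixed = TRUE)
  nalt <- vapply(alleles, function(a) sum(a == "1"), 1L)
  if (any(is.na(nalt) | nalt < 1L | nalt > 2L)) {
    bad <- which(is.na(nalt) | nalt < 1L | nalt > 2L)[1]
    stop("malformed truth genotype '", dt$phase[bad], "' at ",
         dt$contig[bad], ":", dt$pos[bad] + 1L)
  }
  dt[, gt := nalt]
  for (ci in unique(dt$contig)) {
    idx <- which(dt$contig == ci)
    nv <- cpp_normalize_variants(dt$pos[idx], dt$ref[idx], dt$alt[idx],
                                 reference$seq[[ci]])
    dt[idx, `:=`(pos = nv$pos, ref = nv$ref, alt = nv$alt)]
  }
  dt[, key := pg_key(contig, pos, ref, alt)]
  setorder(dt, contig, pos)
  dt[]
}
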