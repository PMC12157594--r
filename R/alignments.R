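#' Aligned-sequence tables
#'
#' Reads and haplotype contigs share one tabular representation: a
#' `data.table` with columns
#' \describe{
#'   \item{name}{record name}
#'   \item{contig}{reference contig}
#'   \item{start}{0-based leftmost reference position}
#'   \item{cigar}{CIGAR over the ops M, I, D, S (`=`/`X` are normalized to
#'     M on ingest, hard clips are dropped)}
#'   \item{bases}{query sequence}
#'   \item{qual}{per-base Phred qualities as a Phred+33 string, or NA}
#'   \item{mapq}{mapping quality, or NA}
#'   \item{strand}{"+", "-" or "*"}
#'   \item{origin}{"read" or "haplotype"}
#' }
#' Base and mapping qualities and strand may be absent (`NA`/`"*"`) for
#' haplotype records; for reads they are carried through from the input.
#'
#' @param name,contig,start,cigar,bases,qual,mapq,strand,origin Column
#'   vectors, recycled to a common length.
#' @return A `data.table` of aligned sequences, coordinate sorted.
#' @export
new_alignments <- function(name, contig, start, cigar, bases,
                           qual = NA_character_, mapq = NA_integer_,
                           strand = "*", origin = "read") {
  dt <- data.table(
    name = as.character(name), contig = as.character(contig),
    start = as.integer(start), cigar = as.character(cigar),
    bases = as.character(bases), qual = as.character(qual),
    mapq = as.integer(mapq), strand = as.character(strand),
    origin = as.character(origin)
  )
  validate_alignments(dt)
  setorder(dt, contig, start, name)
  dt[]
}

validate_alignments <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  info <- cpp_cigar_info(dt$cigar)
  bad <- which(info$qlen != nchar(dt$bases))
  if (length(bad)) {
    stop("CIGAR/sequence length mismatch for record '", dt$name[bad[1]],
         "': CIGAR consumes ", info$qlen[bad[1]], " bases but sequence has ",
         nchar(dt$bases[bad[1]]))
  }
  qbad <- which(!is.na(dt$qual) & nchar(dt$qual) != nchar(dt$bases))
  if (length(qbad)) {
    stop("quality/sequence length mismatch for record '", dt$name[qbad[1]], "'")
  }
  invisible(dt)
}

# reference span of each alignment (bases of reference consumed)
alignment_span <- function(dt) cpp_cigar_info(dt$cigar)$rspan

#' Load read or haplotype alignments from SAM/BAM
#'
#' Unmapped, secondary and supplementary records are excluded. SAM input is
#' converted, sorted and indexed through Rsamtools behind the scenes; BAM
#' input used with a `region` must already be coordinate-sorted and have a
#' `.bai` index next to it. `=`/`X` CIGAR ops are normalized to M and hard
#' clips are dropped. Reads with mapping quality 0 are retained: in
#' segmental duplications they carry exactly the mismapping signal the
#' caller is designed to see through.
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file.
#' @param region Optional [genomic_interval]; only records overlapping it
#'   are returned.
#' @param origin `"read"` or `"haplotype"`, stored in the `origin` column.
#' @return Alignment `data.table` (see [new_alignments]), coordinate sorted.
#' @export
load_alignments <- function(path, region = NULL, origin = "read") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    dest <- tempfile(fileext = ".bam")
    bam0 <- suppressMessages(Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                                              overwrite = TRUE,
                                              indexDestination = FALSE))
    bam <- Rsamtools::sortBam(bam0, tempfile())
    Rsamtools::indexBam(bam)
    on.exit(unlink(c(bam0, bam, paste0(bam, ".bai"))), add = TRUE)
  } else {
    bam <- path
    if (!is.null(region) && !file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("regional fetch from '", path, "' requires a .bai index; ",
           "sort and index the BAM first")
    }
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "rname", "pos", "cigar", "seq", "qual", "mapq", "strand")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flags, what = what)
  } else {
    which <- GenomicRanges::GRanges(region$contig,
                                    IRanges::IRanges(region$start + 1L, region$end))
    Rsamtools::ScanBamParam(flag = flags, what = what, which = which)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  fields <- lapply(what, function(w)
    do.call(c, unname(lapply(res, `[[`, w))))
  names(fields) <- what
  n <- length(fields$qname)
  if (n == 0L) {
    return(new_alignments(character(), character(), integer(), character(),
                          character()))
  }
  qual <- as.character(fields$qual)
  qual[qual == "*" | nchar(qual) == 0L] <- NA_character_
  mapq <- as.integer(fields$mapq)
  mapq[!is.na(mapq) & mapq == 255L] <- NA_integer_
  strand <- as.character(fields$strand)
  strand[!strand %in% c("+", "-")] <- "*"
  norm <- cpp_normalize_cigars(as.character(fields$cigar))
  new_alignments(
    name = fields$qname, contig = as.character(fields$rname),
    start = fields$pos - 1L, cigar = norm,
    bases = as.character(fields$seq), qual = qual, mapq = mapq,
    strand = strand, origin = origin
  )
}

#' Write alignments to SAM
#'
#' @param aln Alignment `data.table`.
#' @param reference A `pg_reference` providing the `@SQ` header lines.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, reference, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference$lengths),
                      as.integer(reference$lengths)))
  aln <- as.data.table(aln)
  if (nrow(aln)) {
    setorder(aln, contig, start, name)
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    recs <- paste(aln$name, flag, aln$contig, aln$start + 1L,
                  ifelse(is.na(aln$mapq), 255L, aln$mapq), aln$cigar,
                  "*", 0L, 0L, aln$bases,
                  ifelse(is.na(aln$qual), "*", aln$qual),
                  sep = "\t")
  } else recs <- character()
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Load a BED3/BED4 file of genomic intervals
#'
#' BED coordinates are already 0-based half-open and are returned as
#' parsed. Overlapping intervals are permitted. An optional 4th column is
#' kept as `label` (used for region-partition BEDs).
#'
#' @param path BED file path.
#' @return `data.table` with columns `contig`, `start`, `end` and, when a
#'   4th column is present, `label`.
#' @export
load_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(track|browser|#)", lines))
  if (length(keep) == 0L) {
    return(data.table(contig = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) stop("BED line ", keep[i], " has fewer than 3 columns")
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", keep[i], " has non-integer coordinates")
    if (s >= e) stop("BED line ", keep[i], ": start (", s, ") >= end (", e, ")")
  }
  dt <- data.table(
    contig = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L))
  )
  if (all(lengths(parts) >= 4L)) dt[, label := vapply(parts, `[`, "", 4L)]
  dt[]
}

#' Write intervals to BED
#' @param bed `data.table` with `contig`, `start`, `end` and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("contig", "start", "end", "label"), names(bed))
  fwrite(as.data.table(bed)[, cols, with = FALSE], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Reverse-strand alignments are reverse-complemented back to read
#' orientation, so the FASTQ mirrors what the instrument produced.
#'
#' @param aln Alignment `data.table`.
#' @param path Output `.fastq` path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(aln, path) {
  seqs <- aln$bases
  quals <- ifelse(is.na(aln$qual), strrep("I", nchar(seqs)), aln$qual)
  rev <- which(aln$strand == "-")
  if (length(rev)) {
    seqs[rev] <- revcomp(seqs[rev])
    quals[rev] <- vapply(quals[rev], function(q)
      paste(rev(strsplit(q, "")[[1]]), collapse = ""), "")
  }
  out <- character(4L * nrow(aln))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", aln$name)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seqs
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from a FASTQ file
#' @param path FASTQ path.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
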