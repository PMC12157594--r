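#' Count canonical read k-mers
#'
#' Builds the strand-neutral (canonical) k-mer membership set of a read
#' collection. K-mers seen fewer than `min_count` times are dropped,
#' which suppresses k-mers created by sequencing errors. The default
#' k = 29 matches common practice for read/haplotype similarity scoring.
#'
#' @param reads Character vector of read sequences, an alignment
#'   `data.table` (its `bases` are used), or a path to a FASTQ file.
#' @param k Odd k-mer size, at least 11 (32 max).
#' @param min_count Minimum multiplicity for membership.
#' @return A `kmer_set`: list with the membership handle, `k`,
#'   `min_count` and `n_reads`.
#' @export
count_read_kmers <- function(reads, k = 29L, min_count = 2L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L) stop("k must be odd and >= 11")
  seqs <- if (is.character(reads) && length(reads) == 1L &&
              file.exists(reads)) {
    read_fastq_seqs(reads)
  } else if (is.data.frame(reads)) {
    reads$bases
  } else {
    as.character(reads)
  }
  if (length(seqs) == 0L) stop("no reads supplied")
  if (k > max(nchar(seqs))) {
    stop("k = ", k, " exceeds the longest read (", max(nchar(seqs)), " bp)")
  }
  ptr <- cpp_kmer_build(seqs, k, as.integer(min_count))
  structure(list(ptr = ptr, k = k, min_count = as.integer(min_count),
                 n_reads = length(seqs)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("<kmer_set> k=", x$k, ", ", format(cpp_kmer_size(x$ptr), big.mark = ","),
      " canonical k-mers from ", x$n_reads, " reads (min_count=",
      x$min_count, ")\n", sep = "")
  invisible(x)
}

#' Number of k-mers in a set
#' @param kmers A `kmer_set`.
#' @return Count of canonical k-mers.
#' @export
kmer_set_size <- function(kmers) cpp_kmer_size(kmers$ptr)

#' List the canonical k-mers of a set (small sets; for inspection)
#' @param kmers A `kmer_set`.
#' @return Sorted character vector of canonical k-mers.
#' @export
kmer_set_members <- function(kmers) cpp_kmer_dump(kmers$ptr, kmers$k)

#' Score haplotype segments against read k-mers
#'
#' Each haplotype sequence is split into non-overlapping segments of
#' `segment_size` bases (the last segment may be shorter); a segment's
#' score is the fraction of its distinct canonical k-mers present in the
#' read set — a containment proxy for similarity between the haplotype
#' segment and the sample's genome. Segmentation makes the score robust
#' to recombination between (but not within) segments.
#'
#' @param panel A `haplotype_panel`.
#' @param kmers A `kmer_set` from [count_read_kmers].
#' @param segment_size Segment length in bp; default 10000.
#' @return `data.table` with `name`, `contig`, `segment_index`,
#'   `seg_start`, `seg_len`, `n_kmers` (distinct segment k-mers) and
#'   `score`.
#' @export
score_haplotype_segments <- function(panel, kmers, segment_size = 10000L) {
  segment_size <- as.integer(segment_size)
  if (segment_size < kmers$k) {
    stop("segment_size (", segment_size, ") must be at least k (", kmers$k, ")")
  }
  haps <- panel$haplotypes
  sc <- cpp_segment_scores(kmers$ptr, haps$bases, kmers$k, segment_size)
  sc <- as.data.table(sc)
  sc[, name := haps$name[haplotype]]
  sc[, contig := haps$contig[haplotype]]
  sc[, .(name, contig, segment_index, seg_start, seg_len, n_kmers, score)]
}

#' Select the haplotypes most similar to the sample
#'
#' Aggregates segment scores per haplotype as the mean segment score
#' weighted by each segment's distinct k-mer count (when available), so
#' a degenerate trailing segment shorter than k — which exists exactly
#' for haplotypes whose net indel length spills over the last full
#' segment — carries no weight. Without the weighting such remainder
#' segments score 0 and systematically push down haplotypes with net
#' insertions. The `n` top-scoring haplotypes are kept; ties break by
#' panel order, so selections nest: top-16 is a subset of top-32 is a
#' subset of top-64 for fixed scores. Preset panel sizes of 16, 32 and
#' 64 haplotypes are typical.
#'
#' @param panel A `haplotype_panel`.
#' @param scores Segment scores from [score_haplotype_segments].
#' @param n Number of haplotypes to keep (1 to panel size).
#' @return A personalized `haplotype_panel` with `haplotype_count = n`;
#'   the selection with aggregate scores is in
#'   `attr(, "selection")`.
#' @export
select_haplotypes <- function(panel, scores, n) {
  n <- as.integer(n)
  hap_names <- unique(panel$haplotypes$name)
  if (n < 1L || n > length(hap_names)) {
    stop("n = ", n, " outside 1..", length(hap_names), " (panel size)")
  }
  scores <- as.data.table(scores)
  agg <- if ("n_kmers" %in% names(scores)) {
    scores[, .(score = if (sum(n_kmers) > 0)
      sum(score * n_kmers) / sum(n_kmers) else 0), by = name]
  } else {
    scores[, .(score = mean(score)), by = name]
  }
  agg <- agg[match(hap_names, name)]       # panel order; stable ties
  agg[, name := hap_names]
  agg[is.na(score), score := 0]
  sel <- agg[order(-score)][seq_len(n)]
  sub <- panel$haplotypes[name %in% sel$name]
  out <- new_panel(sub, n, panel$source)
  setattr(out, "selection", sel)
  out
}
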