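#' Candidate discovery configuration
#'
#' The normative rule is the two-read threshold: a position becomes a
#' candidate when at least `min_support` reads assert the same mismatch
#' or indel. `min_fraction` is an optional fraction-of-depth gate, off by
#' default; `max_alts_per_site` keeps the genotype label space biallelic
#' (the most-supported alternate wins). `min_base_quality` optionally
#' excludes low-quality mismatches from support counting (default: none).
#'
#' @param min_support Minimum supporting reads per (position, allele);
#'   default 2.
#' @param min_fraction Minimum fraction of aligned depth; default 0
#'   (disabled).
#' @param max_alts_per_site Maximum alternates kept per position.
#' @param min_base_quality Minimum base quality for a mismatch to count.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(min_support = 2L, min_fraction = 0,
                             max_alts_per_site = 1L, min_base_quality = 0L) {
  stopifnot(min_support >= 1L, min_fraction >= 0, min_fraction <= 1,
            max_alts_per_site >= 1L)
  structure(list(min_support = as.integer(min_support),
                 min_fraction = min_fraction,
                 max_alts_per_site = as.integer(max_alts_per_site),
                 min_base_quality = as.integer(min_base_quality)),
            class = "discovery_config")
}

#' Discover candidate small variants from read pileups
#'
#' Walks every read alignment, collecting left-aligned, anchored mismatch
#' and indel events, and emits one candidate per (position, alternate
#' allele) with enough support. Soft-clipped bases assert no reference
#' position and never generate candidates; positions where the reference
#' is N are skipped.
#'
#' @param reads Alignment `data.table` of reads.
#' @param reference A `pg_reference`.
#' @param region Optional [genomic_interval] restriction (candidate
#'   positions inside the region; supporting reads may start outside).
#' @param config A [discovery_config].
#' @return `data.table` of candidates: `contig`, `pos` (0-based), `ref`,
#'   `alt`, `alt_support`, `total_depth`, `kind` ("SNP", "insertion",
#'   "deletion"), sorted by position.
#' @export
discover_candidates <- function(reads, reference, region = NULL,
                                config = discovery_config()) {
  contigs <- if (is.null(region)) unique(reads$contig) else region$contig
  out <- list()
  for (ci in contigs) {
    sub <- reads[contig == ci]
    if (!is.null(region)) {
      spans <- alignment_span(sub)
      sub <- sub[intervals_overlap(start, start + spans,
                                   region$start, region$end)]
    }
    if (nrow(sub) == 0L) next
    ev <- cpp_candidate_events(sub$start, sub$cigar, sub$bases, sub$qual,
                               reference$seq[[ci]], config$min_base_quality)
    if (length(ev$pos) == 0L) next
    events <- data.table(read = ev$read, pos = ev$pos, ref = ev$ref,
                         alt = ev$alt, kind = ev$kind)
    tall <- events[, .(alt_support = uniqueN(read)),
                   by = .(pos, ref, alt, kind)]
    tall[, total_depth := ev$depth[pos + 1L]]
    tall <- tall[alt_support >= config$min_support &
                   alt_support >= config$min_fraction * total_depth]
    if (!is.null(region)) {
      tall <- tall[pos >= region$start & pos < region$end]
    }
    if (nrow(tall) == 0L) next
    # most-supported alternate per site; ties resolved lexicographically
    setorder(tall, pos, -alt_support, alt)
    tall <- tall[, head(.SD, config$max_alts_per_site), by = pos]
    tall[, contig := ci]
    out[[ci]] <- tall
  }
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      alt_support = integer(), total_depth = integer(),
                      kind = character())
  if (!length(out)) return(empty)
  res <- rbindlist(out)
  res[, kind := c("SNP", "insertion", "deletion")[kind + 1L]]
  setorder(res, contig, pos, alt)
  res[, .(contig, pos, ref, alt, alt_support, total_depth, kind)]
}

#' Write candidates as a TSV (1-based positions, for inspection)
#' @param candidates Candidate `data.table` from [discover_candidates].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  out <- copy(candidates)
  out[, pos := pos + 1L]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
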