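#' Load a FASTA reference
#'
#' Reads all contigs of a FASTA file into memory as uppercase character
#' strings. Contig names are taken up to the first whitespace, matching the
#' SAM/VCF convention. Only the nucleotides A, C, G, T, N are accepted.
#'
#' @param path Path to a FASTA file (a `.fai` index is not required).
#' @return A `pg_reference`: list with `seq` (named character vector of
#'   uppercase sequences) and `lengths` (named integer vector).
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA at line 1 of ", path, ": expected a '>' header line")
  }
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("reference contig '", names(seqs)[bad][1],
         "' contains characters outside A,C,G,T,N")
  }
  new_reference(seqs)
}

#' Construct a reference from named sequences
#' @param seqs Named character vector of uppercase contig sequences.
#' @return A `pg_reference`.
#' @export
new_reference <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "pg_reference")
}

#' @export
print.pg_reference <- function(x, ...) {
  cat("<pg_reference> ", length(x$seq), " contig(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Extract reference sequence over an interval
#'
#' @param reference A `pg_reference`.
#' @param interval A [genomic_interval]; must be in bounds.
#' @return Character string of length `end - start`.
#' @export
ref_slice <- function(reference, interval) {
  check_interval(interval, reference)
  substr(reference$seq[[interval$contig]], interval$start + 1L, interval$end)
}

#' Write a reference to FASTA
#'
#' @param reference A `pg_reference`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(reference$seq)) {
    writeLines(paste0(">", nm), con)
    s <- reference$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
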