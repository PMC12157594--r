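#' Genomic intervals (0-based, half-open)
#'
#' All coordinates inside pangecall are 0-based and half-open: an interval
#' covers positions `start, start+1, ..., end-1`. Conversion to the 1-based
#' conventions of SAM/VCF and of `contig:start-end` region strings happens
#' only at file boundaries.
#'
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @return An object of class `genomic_interval`.
#' @export
#' @examples
#' genomic_interval("chrT", 100, 200)
genomic_interval <- function(contig, start, end) {
  stopifnot(is.character(contig), length(contig) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(contig = contig, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d> (0-based, half-open, width %d)\n",
              x$contig, x$start, x$end, x$end - x$start))
  invisible(x)
}

#' Parse a 1-based inclusive region string
#'
#' Accepts the CLI convention `contig:start-end` (1-based, inclusive, as
#' printed by samtools) and converts it to the internal 0-based half-open
#' representation.
#'
#' @param text Region string such as `"chrT:101-200"`.
#' @return A [genomic_interval].
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", text, "'; expected contig:start-end")
  s1 <- as.integer(gsub(",", "", m[3])); e1 <- as.integer(gsub(",", "", m[4]))
  if (s1 < 1L || e1 < s1) stop("region '", text, "' is empty or starts before base 1")
  genomic_interval(m[2], s1 - 1L, e1)
}

interval_width <- function(x) x$end - x$start

intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & end1 > start2
}

#' Validate an interval against a reference
#' @noRd
check_interval <- function(interval, reference) {
  len <- reference$lengths[[interval$contig]]
  if (is.null(len)) stop("contig '", interval$contig, "' not present in the reference")
  if (interval$end > len) stop("interval end ", interval$end,
                               " exceeds length of ", interval$contig, " (", len, ")")
  invisible(interval)
}
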