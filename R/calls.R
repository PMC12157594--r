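#' Genotype, quality and filter from class probabilities
#'
#' The called genotype is the argmax class; within `tie_epsilon` the
#' conservative order REF > HET > HOM_ALT wins. Genotype quality is the
#' Phred-scaled probability that the argmax class is wrong,
#' `min(99, round(-10 log10(1 - p_max)))`, with `p_max` clipped to at
#' most `1 - 1e-10`. Reference calls are flagged `RefCall`, everything
#' else `PASS`.
#'
#' @param probs Numeric vector of 3 probabilities, or a matrix with one
#'   row per call (columns REF, HET, HOM_ALT).
#' @param tie_epsilon Probability margin treated as a tie.
#' @return `data.table` with `genotype` ("0/0", "0/1", "1/1"), `gq`
#'   (integer) and `filter` ("PASS"/"RefCall").
#' @export
genotype_from_probs <- function(probs, tie_epsilon = 1e-9) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 3L)
  bad <- abs(rowSums(probs) - 1) > 1e-6 | probs < -1e-9
  if (any(bad)) stop("probabilities of call ", which(bad)[1], " do not form a distribution")
  pmax_ <- apply(probs, 1L, max)
  cls <- apply(probs >= pmax_ - tie_epsilon, 1L, which.max) - 1L
  p_clip <- pmin(pmax_, 1 - 1e-10)
  gq <- pmin(99L, as.integer(round(-10 * log10(1 - p_clip))))
  data.table(genotype = c("0/0", "0/1", "1/1")[cls + 1L], gq = gq,
             filter = ifelse(cls == 0L, "RefCall", "PASS"))
}

#' Turn candidate probabilities into a call table
#'
#' @param candidates Candidate `data.table` (the `meta` of the examples
#'   that were classified).
#' @param probs Probability matrix from [predict_genotypes].
#' @param tie_epsilon Tie margin for [genotype_from_probs].
#' @return `data.table` of calls: candidate fields plus probabilities,
#'   `genotype`, `gq`, `filter` and `key`.
#' @export
make_calls <- function(candidates, probs, tie_epsilon = 1e-9) {
  candidates <- as.data.table(candidates)
  stopifnot(nrow(candidates) == nrow(probs))
  g <- genotype_from_probs(probs, tie_epsilon)
  calls <- cbind(candidates[, .(contig, pos, ref, alt, alt_support,
                                total_depth, kind)],
                 as.data.table(probs), g)
  calls[, key := pg_key(contig, pos, ref, alt)]
  setorder(calls, contig, pos, alt)
  calls[]
}

#' Write calls to VCF 4.2
#'
#' QUAL is set to the genotype quality of the called genotype. RefCall
#' records are dropped unless `emit_refcalls`. DP and AD come from the
#' candidate's support counts.
#'
#' @param calls Call `data.table` from [make_calls].
#' @param reference A `pg_reference` (contig header lines).
#' @param sample_name Sample column name.
#' @param path Output `.vcf` or `.vcf.gz`.
#' @param emit_refcalls Keep `RefCall` records.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, reference, sample_name, path,
                      emit_refcalls = FALSE) {
  out <- as.data.table(calls)
  if (!emit_refcalls) out <- out[filter != "RefCall"]
  setorder(out, contig, pos, alt)
  dup <- duplicated(out[, .(contig, pos, ref, alt)])
  if (any(dup)) {
    k <- pg_key(out$contig[dup], out$pos[dup], out$ref[dup], out$alt[dup])
    stop("duplicate call records: ", paste(unique(k), collapse = ", "))
  }
  body <- if (nrow(out)) {
    ad <- paste0(pmax(out$total_depth - out$alt_support, 0L), ",",
                 out$alt_support)
    paste(out$contig, out$pos + 1L, ".", out$ref, out$alt, out$gq,
          out$filter, ".", "GT:GQ:DP:AD",
          paste(out$genotype, out$gq, out$total_depth, ad, sep = ":"),
          sep = "\t")
  } else character()
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  writeLines(c(vcf_header_lines(reference, sample_name), body), con)
  invisible(path)
}

#' Load a call VCF written by this package (or an equivalent caller)
#'
#' @param path VCF path.
#' @param reference A `pg_reference` for allele normalization.
#' @return `data.table` with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `filter`, `genotype`, `gq`, `key`.
#' @export
load_calls_vcf <- function(path, reference) {
  v <- read_vcf_table(path)
  samples <- attr(v, "samples")
  if (length(samples) != 1L) stop("call VCF must contain exactly one sample")
  gt_field <- v[[samples[1]]]
  genotype <- sub(":.*$", "", gt_field)
  dt <- data.table(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                   filter = v$filter, genotype = gsub("|", "/", genotype,
                                                      fixed = TRUE))
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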