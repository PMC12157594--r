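#' Pileup tensor configuration
#'
#' Each candidate is rendered as a window of `width` reference columns
#' centered on the candidate position (odd width guarantees a unique
#' center column), with two stacked blocks of `height_per_block` rows:
#' the haplotype block on top, the read block below. Six channels encode
#' bases, base quality, mapping quality, strand, candidate support and
#' difference-from-reference; base quality, mapping quality and strand
#' are left at zero in haplotype rows because a haplotype panel defines
#' none of them.
#'
#' @param width Window width in reference columns; odd. Default 221.
#' @param height_per_block Rows per block. Default 100.
#' @param hap_overflow What to do when the panel has more haplotypes than
#'   rows: `"error"` (default; the remedy is haplotype sampling, see
#'   [select_haplotypes]) or `"subsample"` (seeded uniform subsample).
#' @param row_overflow_seed Seed governing read-row (and optional
#'   haplotype-row) subsampling.
#' @return A `pileup_config` list.
#' @export
pileup_config <- function(width = 221L, height_per_block = 100L,
                          hap_overflow = c("error", "subsample"),
                          row_overflow_seed = 0L) {
  width <- as.integer(width); height_per_block <- as.integer(height_per_block)
  if (width %% 2L == 0L) stop("pileup width must be odd so a unique center column exists")
  stopifnot(height_per_block >= 1L)
  structure(list(width = width, height_per_block = height_per_block,
                 channels = pg_channels(),
                 haplotype_blank_channels = c("BASE_QUAL", "MAP_QUAL", "STRAND"),
                 hap_overflow = match.arg(hap_overflow),
                 row_overflow_seed = as.integer(row_overflow_seed)),
            class = "pileup_config")
}

#' Channel names of the pileup tensor, in tensor order
#' @return Character vector of the six channel identifiers.
#' @export
pg_channels <- function() {
  c("BASE", "BASE_QUAL", "MAP_QUAL", "STRAND", "SUPPORTS_ALT",
    "DIFFERS_FROM_REF")
}

#' Genotype class labels in label order (0, 1, 2)
#' @return `c("REF", "HET", "HOM_ALT")`.
#' @export
pg_classes <- function() c("REF", "HET", "HOM_ALT")

#' Window of a candidate's pileup image
#'
#' The candidate position maps to the center column. Near contig edges
#' the interval may extend beyond the contig; out-of-contig columns are
#' left blank at encoding time rather than shifting the center.
#'
#' @param candidate List or one-row `data.table` with `contig` and `pos`.
#' @param config A [pileup_config].
#' @return A `genomic_interval` (possibly with negative `start`).
#' @export
candidate_window <- function(candidate, config = pileup_config()) {
  half <- (config$width - 1L) %/% 2L
  s <- as.integer(candidate$pos) - half
  structure(list(contig = as.character(candidate$contig), start = s,
                 end = s + config$width),
            class = "genomic_interval")
}

# run expr with a temporary RNG state seeded deterministically
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

strand_code <- function(strand) {
  c("*" = 0L, "+" = 1L, "-" = 2L)[strand]
}

block_args <- function(dt) {
  list(start = dt$start, cigar = dt$cigar, bases = dt$bases, qual = dt$qual,
       mapq = dt$mapq, strand = unname(strand_code(dt$strand)))
}

kind_code <- function(kind) {
  c(SNP = 0L, insertion = 1L, deletion = 2L)[kind]
}

#' Build pangenome-augmented pileup examples
#'
#' For every candidate, overlapping reads are collected (sorted by start
#' position then name, so the tensor is invariant to input read order),
#' subsampled to the block height with a seeded uniform draw when
#' necessary, and encoded together with the panel haplotypes into a
#' float32 tensor of shape `(2*height_per_block, width, 6)` with all
#' values in [0, 1].
#'
#' @param candidates Candidate `data.table` from [discover_candidates].
#' @param reads Alignment `data.table` of reads.
#' @param panel A `haplotype_panel`, or `NULL` for a blank haplotype
#'   block (the reads-only ablation).
#' @param reference A `pg_reference`.
#' @param config A [pileup_config].
#' @param truth Optional truth `data.table` (from [load_truth_vcf] or the
#'   simulator); when given, examples carry labels 0 = REF, 1 = HET,
#'   2 = HOM_ALT.
#' @return A `pg_examples` object: list with `tensors` (list of float32
#'   raw vectors), `meta` (candidates plus `label`), `width`, `height`,
#'   `channels`.
#' @export
build_examples <- function(candidates, reads, panel, reference,
                           config = pileup_config(), truth = NULL) {
  candidates <- as.data.table(candidates)
  h <- config$height_per_block
  labels <- if (is.null(truth)) rep(NA_integer_, nrow(candidates))
            else label_candidates(candidates, truth, reference)

  tensors <- vector("list", nrow(candidates))
  read_spans <- alignment_span(reads)
  hap_all <- if (is.null(panel)) NULL else panel$haplotypes
  empty_block <- block_args(new_alignments(character(), character(),
                                           integer(), character(), character()))
  slice_block <- function(bl, sel) {
    lapply(bl, `[`, sel)
  }
  half <- (config$width - 1L) %/% 2L
  for (ci in unique(candidates$contig)) {
    rsub <- reads[contig == ci]
    rspan <- read_spans[reads$contig == ci]
    ord <- order(rsub$start, rsub$name)
    rsub <- rsub[ord]; rspan <- rspan[ord]
    rend <- rsub$start + rspan
    rblock_full <- block_args(rsub)
    rstart <- rsub$start
    hsub <- if (is.null(hap_all)) NULL else hap_all[contig == ci]
    if (!is.null(hsub) && nrow(hsub) > h) {
      if (config$hap_overflow == "error") {
        stop(nrow(hsub), " panel haplotypes exceed the block height of ", h,
             "; increase height_per_block or build a personalized panel ",
             "with select_haplotypes()")
      }
      keep <- with_local_seed(config$row_overflow_seed,
                              sort(sample.int(nrow(hsub), h)))
      hsub <- hsub[keep]
    }
    hblock_full <- if (is.null(hsub)) empty_block else block_args(hsub)
    hstart <- if (is.null(hsub)) integer() else hsub$start
    hend <- if (is.null(hsub)) integer() else hsub$start + alignment_span(hsub)
    clen <- reference$lengths[[ci]]
    refseq <- reference$seq[[ci]]
    cidx <- which(candidates$contig == ci)
    cpos <- candidates$pos; cref <- candidates$ref; calt <- candidates$alt
    ckind <- unname(kind_code(candidates$kind))
    for (i in cidx) {
      ws <- cpos[i] - half
      we <- ws + config$width
      sel <- which(rstart < we & rend > ws)
      if (length(sel) > h) {
        sub_seed <- (config$row_overflow_seed * 1000003L +
                       cpos[i] %% 1000003L) %% .Machine$integer.max
        sel <- sel[with_local_seed(sub_seed, sort(sample.int(length(sel), h)))]
      }
      rblock <- if (length(sel) == length(rstart)) rblock_full
                else slice_block(rblock_full, sel)
      hb <- if (is.null(hsub)) empty_block else {
        hsel <- which(hstart < we & hend > ws)
        if (length(hsel) == length(hstart)) hblock_full
        else slice_block(hblock_full, hsel)
      }
      lo <- max(ws, 0L); hi <- min(we, clen)
      refwin <- strrep(".", config$width)
      if (hi > lo) {
        refwin <- paste0(strrep(".", lo - ws), substr(refseq, lo + 1L, hi),
                         strrep(".", we - hi))
      }
      tensors[[i]] <- cpp_encode_example(
        config$width, h, ws, refwin, cpos[i], cref[i], calt[i],
        ckind[i], hb, rblock)
    }
  }
  meta <- copy(candidates)
  meta[, label := labels]
  structure(list(tensors = tensors, meta = meta, width = config$width,
                 height = h, channels = config$channels),
            class = "pg_examples")
}

#' @export
print.pg_examples <- function(x, ...) {
  cat("<pg_examples> ", length(x$tensors), " examples, tensors (",
      2L * x$height, ", ", x$width, ", ", length(x$channels), ")\n", sep = "")
  invisible(x)
}

#' Extract one example tensor as a numeric array
#'
#' @param examples A `pg_examples` object.
#' @param i Example index.
#' @return Array of shape `(2*height, width, channels)`.
#' @export
example_tensor <- function(examples, i) {
  nfl <- 2L * examples$height * examples$width * length(examples$channels)
  v <- readBin(examples$tensors[[i]], "numeric", n = nfl, size = 4L)
  a <- array(v, dim = c(length(examples$channels), examples$width,
                        2L * examples$height))
  aperm(a, c(3L, 2L, 1L))
}

#' Label candidates against a truth set
#'
#' A candidate is HET (1) if the truth genotype carries its alternate
#' allele once, HOM_ALT (2) if twice, REF (0) if the candidate matches no
#' truth alternate at its position.
#'
#' @param candidates Candidate `data.table`.
#' @param truth Truth `data.table` with `key` and `gt` columns.
#' @param reference A `pg_reference` (candidates are already normalized;
#'   retained for interface symmetry).
#' @return Integer labels in `{0, 1, 2}`.
#' @export
label_candidates <- function(candidates, truth, reference) {
  keys <- pg_key(candidates$contig, candidates$pos, candidates$ref,
                 candidates$alt)
  m <- match(keys, truth$key)
  lab <- truth$gt[m]
  lab[is.na(lab)] <- 0L
  as.integer(lab)
}

#' Zero the haplotype block of encoded examples
#'
#' Returns a copy of the examples whose haplotype rows are identically
#' zero — the reads-only ablation used to measure the contribution of
#' the pangenome.
#'
#' @param examples A `pg_examples` object.
#' @return A new `pg_examples` object.
#' @export
zero_haplotype_block <- function(examples) {
  out <- examples
  out$tensors <- cpp_zero_hap_block(examples$tensors[seq_along(examples$tensors)],
                                    examples$height, examples$width)
  out
}

#' Serialize examples to disk
#'
#' Tensors are concatenated as float32 into a gzip stream with a JSON
#' sidecar (`<path>.json`) describing shape, channels and metadata.
#'
#' @param examples A `pg_examples` object.
#' @param path Output path for the binary tensor stream.
#' @return `path`, invisibly.
#' @export
save_examples <- function(examples, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  for (tr in examples$tensors) writeBin(tr, con)
  sidecar <- list(
    n = length(examples$tensors), width = examples$width,
    height = examples$height, channels = examples$channels,
    meta = examples$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load examples written by [save_examples]
#' @param path Path given to [save_examples].
#' @return A `pg_examples` object.
#' @export
load_examples <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nbytes <- 2L * sidecar$height * sidecar$width * length(sidecar$channels) * 4L
  con <- gzfile(path, "rb")
  on.exit(close(con))
  tensors <- vector("list", sidecar$n)
  for (i in seq_len(sidecar$n)) tensors[[i]] <- readBin(con, "raw", nbytes)
  meta <- as.data.table(sidecar$meta)
  meta[, label := as.integer(label)]
  structure(list(tensors = tensors, meta = meta, width = sidecar$width,
                 height = sidecar$height, channels = sidecar$channels),
            class = "pg_examples")
}
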