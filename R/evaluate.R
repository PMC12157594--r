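in_regions <- function(contig, pos, bed) {
  if (is.null(bed) || nrow(bed) == 0L) return(rep(TRUE, length(pos)))
  bed <- as.data.table(bed)
  res <- rep(FALSE, length(pos))
  for (ci in unique(contig)) {
    sub <- bed[contig == ci]
    idx <- which(contig == ci)
    if (nrow(sub) == 0L) next
    setorder(sub, start)
    iv <- findInterval(pos[idx], sub$start)
    hit <- iv >= 1L & pos[idx] < sub$end[pmax(iv, 1L)]
    res[idx] <- hit
  }
  res
}

truth_digest <- function(truth, confident) {
  paste(nrow(truth), sum(as.numeric(truth$pos)),
        if (is.null(confident)) 0 else nrow(confident),
        if (is.null(confident)) 0 else sum(as.numeric(confident$end)),
        sep = "-")
}

#' Compare a call set to a truth set
#'
#' Matching is by exact normalized key (contig, pos, ref, alt) plus
#' genotype. A call whose allele matches a truth record but whose
#' genotype differs counts as one false positive (the called record) and
#' one false negative (the truth record), so both precision and recall
#' register the error. Only PASS calls are considered and only records
#' inside the confident regions are evaluated.
#'
#' @param calls Call `data.table` with `key`, `genotype`, `filter`,
#'   `contig`, `pos` (from [make_calls] or [load_calls_vcf]).
#' @param truth Truth `data.table` with `key`, `gt`, `contig`, `pos`
#'   (from [load_truth_vcf] or the simulator).
#' @param confident Optional confident-region BED `data.table`.
#' @return A `pg_comparison`: list with `tp`, `fp`, `fn` (vectors of
#'   `key:GT` record identifiers), `precision`, `recall`, `f1`, counts
#'   and a digest of the truth provenance.
#' @export
compare_to_truth <- function(calls, truth, confident = NULL) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (!all(truth$gt %in% 1:2)) stop("malformed truth genotypes (gt must be 1 or 2)")
  calls <- calls[filter == "PASS"]
  calls <- calls[in_regions(contig, pos, confident)]
  truth <- truth[in_regions(contig, pos, confident)]
  call_gt <- match(calls$genotype, c("0/1", "1/1"))
  if (anyNA(call_gt)) {
    calls <- calls[!is.na(call_gt)]
    call_gt <- call_gt[!is.na(call_gt)]
  }
  call_rec <- if (nrow(calls)) paste0(calls$key, ":", call_gt) else character()
  truth_rec <- if (nrow(truth)) paste0(truth$key, ":", truth$gt) else character()
  tp <- intersect(call_rec, truth_rec)
  fp <- setdiff(call_rec, truth_rec)
  fn <- setdiff(truth_rec, call_rec)
  ntp <- length(tp); nfp <- length(fp); nfn <- length(fn)
  precision <- if (ntp + nfp > 0) ntp / (ntp + nfp) else NA_real_
  recall <- if (ntp + nfn > 0) ntp / (ntp + nfn) else NA_real_
  f1 <- if (ntp == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 n_tp = ntp, n_fp = nfp, n_fn = nfn,
                 digest = truth_digest(truth, confident)),
            class = "pg_comparison")
}

#' @export
print.pg_comparison <- function(x, ...) {
  cat(sprintf("<pg_comparison> TP %d  FP %d  FN %d  precision %.4f  recall %.4f  F1 %.4f\n",
              x$n_tp, x$n_fp, x$n_fn, x$precision, x$recall, x$f1))
  invisible(x)
}

rec_is_snp <- function(rec) {
  parts <- strsplit(rec, ":", fixed = TRUE)
  vapply(parts, function(p) nchar(p[3]) == 1L && nchar(p[4]) == 1L, TRUE)
}

rec_allele_key <- function(rec) {
  sub(":[0-9]+$", "", rec)
}

rec_pos <- function(rec) {
  parts <- strsplit(rec, ":", fixed = TRUE)
  list(contig = vapply(parts, `[`, "", 1L),
       pos = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Classify error transitions between two call sets
#'
#' Given comparisons of a baseline and a pangenome-aware call set
#' against the same truth, the four transition categories are set
#' differences of their error sets: errors the pangenome-aware set fixed
#' (removed FP, rescued FN) and errors it introduced (induced FP,
#' induced FN). The four sets are pairwise disjoint, and swapping the
#' two inputs exactly swaps removed with induced.
#'
#' @param baseline `pg_comparison` of the baseline call set.
#' @param pangenome `pg_comparison` of the pangenome-aware call set.
#' @param snp_only Restrict to SNPs (both alleles length 1), the class
#'   driving most pangenome gains. Default TRUE.
#' @return A `pg_transitions`: list of the four record-key sets.
#' @export
classify_error_transitions <- function(baseline, pangenome, snp_only = TRUE) {
  if (!identical(baseline$digest, pangenome$digest)) {
    stop("comparisons were made against different truth/confident inputs")
  }
  filt <- function(x) if (snp_only) x[rec_is_snp(x)] else x
  structure(list(
    removed_fp = filt(setdiff(baseline$fp, pangenome$fp)),
    rescued_fn = filt(setdiff(baseline$fn, pangenome$fn)),
    induced_fp = filt(setdiff(pangenome$fp, baseline$fp)),
    induced_fn = filt(setdiff(pangenome$fn, baseline$fn)),
    snp_only = snp_only), class = "pg_transitions")
}

#' @export
print.pg_transitions <- function(x, ...) {
  cat(sprintf("<pg_transitions> removed FP %d  rescued FN %d  induced FP %d  induced FN %d%s\n",
              length(x$removed_fp), length(x$rescued_fn),
              length(x$induced_fp), length(x$induced_fn),
              if (x$snp_only) "  (SNPs only)" else ""))
  invisible(x)
}

transition_table <- function(transitions) {
  cats <- c("removed_fp", "rescued_fn", "induced_fp", "induced_fn")
  rbindlist(lapply(cats, function(cat) {
    rec <- transitions[[cat]]
    if (!length(rec)) return(NULL)
    rp <- rec_pos(rec)
    data.table(category = cat, rec = rec, contig = rp$contig, pos = rp$pos)
  }))
}

#' Stratify transition counts by region class and genomic window
#'
#' Every transition record is assigned to exactly one partition class
#' (or `"outside"`) and one non-overlapping window. Class rates are
#' counts per Mb of class size.
#'
#' @param transitions A `pg_transitions`.
#' @param partition BED `data.table` with a `label` column of disjoint
#'   region classes.
#' @param window_size Window length in bp; default 100000.
#' @return List with `by_class` (category, label, count, size_mb, rate)
#'   and `by_window` (category, contig, window, count).
#' @export
stratify_counts <- function(transitions, partition, window_size = 100000L) {
  stopifnot(window_size > 0L)
  partition <- as.data.table(partition)
  tt <- transition_table(transitions)
  sizes <- partition[, .(size_mb = sum((end - start)) / 1e6), by = label]
  cats <- c("removed_fp", "rescued_fn", "induced_fp", "induced_fn")
  if (is.null(tt) || nrow(tt) == 0L) {
    by_class <- CJ(category = cats, label = sizes$label)[sizes, on = "label"]
    by_class[, `:=`(count = 0L, rate = 0)]
    return(list(by_class = by_class[, .(category, label, count, size_mb, rate)],
                by_window = data.table(category = character(),
                                       contig = character(),
                                       window = integer(), count = integer())))
  }
  tt[, label := "outside"]
  for (li in seq_len(nrow(partition))) {
    hit <- tt$contig == partition$contig[li] &
      tt$pos >= partition$start[li] & tt$pos < partition$end[li]
    tt[hit, label := partition$label[li]]
  }
  by_class <- CJ(category = cats, label = sizes$label)
  cnt <- tt[, .(count = .N), by = .(category, label)]
  by_class <- cnt[by_class, on = c("category", "label")]
  by_class[is.na(count), count := 0L]
  by_class <- sizes[by_class, on = "label"]
  by_class[, rate := count / size_mb]
  tt[, window := pos %/% as.integer(window_size)]
  by_window <- tt[, .(count = .N), by = .(category, contig, window)]
  list(by_class = by_class[, .(category, label, count, size_mb, rate)],
       by_window = by_window)
}

#' Plot per-window fixed and induced error counts
#'
#' A simple per-contig barplot of transition counts in non-overlapping
#' windows: fixed errors (removed FP + rescued FN) above the axis,
#' induced errors (induced FP + FN) below.
#'
#' @param stratified Output of [stratify_counts].
#' @param window_size The window size the counts were computed with.
#' @return Invisibly, the plotted per-window table.
#' @export
plot_transition_windows <- function(stratified, window_size = 100000L) {
  bw <- stratified$by_window
  if (nrow(bw) == 0L) {
    plot.new()
    title("no transition records")
    return(invisible(bw))
  }
  bw <- copy(bw)
  bw[, fixed := category %in% c("removed_fp", "rescued_fn")]
  agg <- bw[, .(count = sum(count)), by = .(contig, window, fixed)]
  contigs <- unique(agg$contig)
  op <- graphics::par(mfrow = c(length(contigs), 1),
                      mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ci in contigs) {
    sub <- agg[contig == ci]
    wmax <- max(sub$window)
    up <- sapply(0:wmax, function(w) sum(sub[window == w & fixed == TRUE, count]))
    dn <- sapply(0:wmax, function(w) sum(sub[window == w & fixed == FALSE, count]))
    graphics::barplot(up, col = "steelblue", border = NA,
                      ylim = c(-max(dn, 1), max(up, 1)),
                      names.arg = NULL, main = ci,
                      ylab = "fixed / induced per window")
    graphics::barplot(-dn, col = "firebrick", border = NA, add = TRUE,
                      names.arg = NULL)
  }
  invisible(agg)
}

#' Histogram of panel allele frequencies per transition category
#'
#' Each transition record's allele is looked up in the panel and counted
#' into frequency bins of `bin_width` (default 0.2; the last bin is
#' closed at 1). Alleles on contigs absent from the panel are assigned
#' frequency 0 and flagged.
#'
#' @param transitions A `pg_transitions`.
#' @param panel A `haplotype_panel`.
#' @param reference A `pg_reference`.
#' @param bin_width Bin width; must divide 1 evenly.
#' @return `data.table` with `category`, `bin` (label), `count`, plus a
#'   `flagged` attribute (number of unresolvable alleles).
#' @export
bin_by_allele_frequency <- function(transitions, panel, reference,
                                    bin_width = 0.2) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1 evenly")
  nb <- as.integer(round(nb))
  bin_labels <- sprintf("[%.1f,%.1f%s", bin_width * (seq_len(nb) - 1L),
                        bin_width * seq_len(nb),
                        c(rep(")", nb - 1L), "]"))
  tt <- transition_table(transitions)
  cats <- c("removed_fp", "rescued_fn", "induced_fp", "induced_fn")
  grid <- CJ(category = cats, bin = bin_labels)
  if (is.null(tt) || nrow(tt) == 0L) {
    grid[, count := 0L]
    setattr(grid, "flagged", 0L)
    return(grid[])
  }
  ak <- rec_allele_key(tt$rec)
  parts <- strsplit(ak, ":", fixed = TRUE)
  dt <- data.table(category = tt$category,
                   contig = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   ref = vapply(parts, `[`, "", 3L),
                   alt = vapply(parts, `[`, "", 4L))
  known <- dt$contig %in% unique(panel$haplotypes$contig)
  freq <- rep(0, nrow(dt))
  if (any(known)) {
    af <- panel_allele_frequency(panel, reference, dt$contig[known],
                                 dt$pos[known], dt$ref[known], dt$alt[known])
    freq[known] <- af$frequency
  }
  idx <- pmin(as.integer(freq %/% bin_width), nb - 1L) + 1L
  dt[, bin := bin_labels[idx]]
  cnt <- dt[, .(count = .N), by = .(category, bin)]
  out <- cnt[grid, on = c("category", "bin")]
  out[is.na(count), count := 0L]
  setorder(out, category, bin)
  setattr(out, "flagged", sum(!known))
  out[]
}
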