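# Copy-number-variation detection from bisulfite read depth: windowed
# ln coverage ratios between two samples, threshold-and-merge region
# calling, and annotation enrichment within called regions.

#' Windowed coverage and ln coverage ratio of two samples
#'
#' Per-base depth is averaged within fixed windows (default 100 kb; the
#' last window of each scaffold is truncated).  Depths are normalized by
#' each sample's total mapped bases so that a genome without copy-number
#' differences has ratios centered at 0; the reported ratio is the
#' natural log `ln(norm_depth_A / norm_depth_B)`.  Windows with zero
#' depth in either sample are flagged and excluded from calling.
#'
#' @param reads_A,reads_B read data.frames (read_id, scaffold, start,
#'   strand, seq); only coordinates and read lengths are used.
#' @param genome a `DNAStringSet` (for scaffold lengths), or a named
#'   integer vector of scaffold lengths.
#' @param window_size window width in bases (> 0).
#' @return data.frame: scaffold, start, end, depth_A, depth_B,
#'   norm_depth_A, norm_depth_B, ln_ratio, ok (both depths > 0).
#' @export
windowed_coverage <- function(reads_A, reads_B, genome,
                              window_size = 100000) {
  if (window_size <= 0) .stopf("'window_size' must be > 0")
  lens <- if (is.numeric(genome)) genome else .scaffold_lengths(genome)
  tot_A <- sum(nchar(reads_A$seq)); tot_B <- sum(nchar(reads_B$seq))
  out <- list()
  for (sc in names(lens)) {
    L <- lens[[sc]]
    nw <- ceiling(L / window_size)
    wstart <- (seq_len(nw) - 1L) * window_size
    wend <- pmin(L, wstart + window_size)
    ba <- .window_bases(reads_A, sc, L, window_size)
    bb <- .window_bases(reads_B, sc, L, window_size)
    out[[sc]] <- data.frame(scaffold = sc, start = wstart, end = wend,
                            depth_A = ba / (wend - wstart),
                            depth_B = bb / (wend - wstart))
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  if (tot_A <= 0 || tot_B <= 0) {
    w$norm_depth_A <- 0; w$norm_depth_B <- 0
    w$ln_ratio <- NA_real_; w$ok <- FALSE
    warning("empty read set: all windows flagged")
    return(w)
  }
  # scale-free normalization: per-base depth over mean genome depth
  w$norm_depth_A <- w$depth_A / (tot_A / sum(lens))
  w$norm_depth_B <- w$depth_B / (tot_B / sum(lens))
  w$ok <- w$norm_depth_A > 0 & w$norm_depth_B > 0
  w$ln_ratio <- ifelse(w$ok, log(w$norm_depth_A / w$norm_depth_B), NA_real_)
  w
}

.window_bases <- function(reads, sc, L, window_size) {
  rd <- reads[reads$scaffold == sc, , drop = FALSE]
  if (!nrow(rd)) return(numeric(ceiling(L / window_size)))
  cpp_window_bases(as.integer(rd$start), nchar(rd$seq), as.integer(L),
                   as.integer(window_size))
}

#' Call CNV regions from windowed coverage ratios
#'
#' Windows with `|ln_ratio| >= threshold` (default 0.3) are marked;
#' adjacent marked windows of equal sign on the same scaffold are merged
#' into maximal regions.  Reports the merged regions, the count of
#' significant windows, and the fraction of the genome covered by
#' regions.
#'
#' @param windows data.frame from [windowed_coverage()].
#' @param threshold |ln ratio| cut (> 0).
#' @return data.frame of class `fm_cnv`: scaffold, start, end, n_windows,
#'   mean_ln_ratio, direction ("amplified-in-A" / "amplified-in-B");
#'   attributes `genome_fraction`, `n_significant_windows`,
#'   `genome_length`.
#' @export
call_cnv_regions <- function(windows, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold <= 0)
    .stopf("'threshold' must be > 0")
  sig <- windows$ok & !is.na(windows$ln_ratio) &
    abs(windows$ln_ratio) >= threshold
  glen <- sum(tapply(windows$end, windows$scaffold, max))
  regs <- list()
  if (any(sig)) {
    w <- windows[sig, , drop = FALSE]
    widx <- which(sig)
    sign_w <- sign(w$ln_ratio)
    # runs of consecutive window indices, same scaffold, same sign
    new_run <- c(TRUE, diff(widx) != 1L |
                   w$scaffold[-1] != w$scaffold[-nrow(w)] |
                   sign_w[-1] != sign_w[-nrow(w)])
    run_id <- cumsum(new_run)
    regs <- lapply(split(seq_len(nrow(w)), run_id), function(i) {
      data.frame(scaffold = w$scaffold[i[1]], start = min(w$start[i]),
                 end = max(w$end[i]), n_windows = length(i),
                 mean_ln_ratio = mean(w$ln_ratio[i]),
                 direction = if (sign_w[i[1]] > 0) "amplified-in-A"
                             else "amplified-in-B")
    })
  }
  out <- if (length(regs)) do.call(rbind, regs) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               n_windows = integer(), mean_ln_ratio = numeric(),
               direction = character())
  rownames(out) <- NULL
  attr(out, "n_significant_windows") <- sum(sig)
  attr(out, "genome_fraction") <- sum(out$end - out$start) / glen
  attr(out, "genome_length") <- glen
  class(out) <- c("fm_cnv", class(out))
  out
}

#' @export
print.fm_cnv <- function(x, ...) {
  cat(sprintf("CNV regions: %d (%d significant windows, %.2f%% of genome)\n",
              nrow(x), attr(x, "n_significant_windows"),
              100 * attr(x, "genome_fraction")))
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Feature enrichment and methylation shift inside CNV regions
#'
#' Features are assigned to CNV vs non-CNV space by their midpoint.
#' Fold-enrichment is the feature density (count per Mb) inside CNV
#' regions over the density outside, for genes, TEs, expressed TEs and
#' each TE subclass; a two-sample Kolmogorov-Smirnov test compares the
#' CG methylation distribution of TEs inside vs outside CNV regions.
#'
#' @param regions data.frame from [call_cnv_regions()].
#' @param features feature data.frame.
#' @param feature_meth data.frame from [feature_methylation()] (needs
#'   `level_CG`).
#' @param expression data.frame with id and rpkm (optional; enables the
#'   expressed-TE row).
#' @param rpkm_cut expressed threshold.
#' @return list: `enrichment` (data.frame group, n_cnv, n_noncnv,
#'   fold_enrichment — NA with `infinite = TRUE` when the non-CNV density
#'   is 0), `ks` (htest or NULL), or NULL when there are no regions.
#' @export
cnv_enrichment <- function(regions, features, feature_meth,
                           expression = NULL, rpkm_cut = 1) {
  if (!nrow(regions)) return(NULL)
  glen <- attr(regions, "genome_length") %||%
    sum(tapply(features$end, features$scaffold, max))
  cnv_len <- sum(regions$end - regions$start)
  non_len <- glen - cnv_len
  mid <- (features$start + features$end) / 2
  in_cnv <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(regions)))
    in_cnv <- in_cnv | (features$scaffold == regions$scaffold[i] &
                          mid >= regions$start[i] & mid < regions$end[i])
  rpkm <- if (!is.null(expression))
    expression$rpkm[match(features$id, expression$id)] else
    rep(NA_real_, nrow(features))
  rpkm[is.na(rpkm)] <- 0
  is_te <- features$kind %in% c("TE", "other_repeat")
  sets <- list(gene = features$kind == "gene", TE = is_te,
               expressed_TE = is_te & rpkm >= rpkm_cut)
  for (cl in unique(features$te_class[is_te]))
    if (!is.na(cl)) sets[[paste0("TE_", cl)]] <- is_te &
      !is.na(features$te_class) & features$te_class == cl
  rows <- lapply(names(sets), function(nm) {
    sel <- sets[[nm]]
    n_in <- sum(sel & in_cnv); n_out <- sum(sel & !in_cnv)
    dens_in <- n_in / cnv_len; dens_out <- n_out / non_len
    inf <- dens_out == 0 & dens_in > 0
    data.frame(group = nm, n_cnv = n_in, n_noncnv = n_out,
               fold_enrichment = ifelse(inf | non_len == 0, NA_real_,
                                        dens_in / dens_out),
               infinite = inf | non_len == 0)
  })
  enr <- do.call(rbind, rows)
  rownames(enr) <- NULL
  ks <- NULL
  lvl <- feature_meth$level_CG[match(features$id, feature_meth$id)]
  m_in <- lvl[is_te & in_cnv & !is.na(lvl)]
  m_out <- lvl[is_te & !in_cnv & !is.na(lvl)]
  if (length(m_in) >= 2 && length(m_out) >= 2)
    ks <- suppressWarnings(stats::ks.test(m_in, m_out))
  list(enrichment = enr, ks = ks)
}
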