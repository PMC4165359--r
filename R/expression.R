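# RPKM quantification and methylation-expression association analyses,
# including the two-condition (demethylating-treatment) response binning.

#' Union of exon intervals per gene
#'
#' Effective transcribed length of a gene: the union length of all its
#' exons (overlapping exons counted once).
#'
#' @param exons data.frame: gene_id, start, end (0-based half-open).
#' @return named numeric vector of union lengths per gene_id.
#' @export
union_exon_length <- function(exons) {
  if (!nrow(exons)) return(stats::setNames(numeric(), character()))
  sp <- split(seq_len(nrow(exons)), exons$gene_id)
  vapply(sp, function(i) {
    ir <- IRanges::reduce(IRanges::IRanges(exons$start[i] + 1L,
                                           exons$end[i]))
    sum(IRanges::width(ir))
  }, numeric(1))
}

#' Compute RPKM expression records
#'
#' RPKM = raw_count * 1e9 / (effective_length * total_mapped).  Genes use
#' the union length of their exons as effective length; TEs use their
#' full feature length.  A feature is "expressed" when its RPKM reaches
#' `threshold` (default 1).
#'
#' @param counts data.frame: id, count (reads fully contained in the
#'   feature).
#' @param features feature data.frame.
#' @param exons exon data.frame (for gene union lengths); may be empty,
#'   genes then fall back to feature length.
#' @param total_mapped total mapped reads of the library (> 0); defaults
#'   to `sum(counts$count)`.
#' @param threshold expressed cutoff in RPKM.
#' @return data.frame: id, kind, raw_count, effective_length, rpkm,
#'   expressed.
#' @export
compute_rpkm <- function(counts, features, exons = NULL,
                         total_mapped = sum(counts$count), threshold = 1) {
  if (total_mapped <= 0) .stopf("'total_mapped' must be > 0")
  raw <- counts$count[match(features$id, counts$id)]
  raw[is.na(raw)] <- 0
  elen <- features$end - features$start
  if (!is.null(exons) && nrow(exons)) {
    ul <- union_exon_length(exons)
    m <- match(features$id, names(ul))
    elen[!is.na(m)] <- ul[m[!is.na(m)]]
  }
  if (any(elen <= 0))
    .stopf("zero-length feature: %s",
           features$id[which(elen <= 0)[1]])
  rpkm <- raw * 1e9 / (elen * total_mapped)
  data.frame(id = features$id, kind = features$kind, raw_count = raw,
             effective_length = elen, rpkm = rpkm,
             expressed = rpkm >= threshold)
}

#' Methylation-expression association analyses for TEs
#'
#' Produces (i) a per-subclass table of TE counts, expressed counts and
#' percentages with methylation and log2-RPKM quartiles, (ii) the
#' Spearman correlation between TE CG methylation and log2 RPKM among
#' TEs with RPKM > 0 (the negative association expected under
#' methylation-mediated silencing), (iii) Welch t-tests of per-TE log2
#' expression between two samples per subclass (when `expression_B` is
#' given), and (iv) a size comparison of expressed vs all TEs.
#'
#' @param feature_meth data.frame from [feature_methylation()] (TE rows,
#'   `level_CG` used).
#' @param expression data.frame from [compute_rpkm()] (sample A).
#' @param te_features TE feature data.frame.
#' @param expression_B optional second-sample expression for the
#'   between-sample tests.
#' @param rpkm_cut expressed threshold.
#' @param pseudocount added to RPKM before log2.
#' @return list with elements `subclass_table`, `correlation` (rho, p, n),
#'   `sample_tests` (or NULL), `size_comparison`.
#' @export
methylation_expression_association <- function(feature_meth, expression,
                                               te_features,
                                               expression_B = NULL,
                                               rpkm_cut = 1,
                                               pseudocount = 0.25) {
  te <- te_features[te_features$kind %in% c("TE", "other_repeat"), ,
                    drop = FALSE]
  meth <- feature_meth$level_CG[match(te$id, feature_meth$id)]
  rpkm <- expression$rpkm[match(te$id, expression$id)]
  rpkm[is.na(rpkm)] <- 0
  cls <- ifelse(is.na(te$te_class), "unclassified", te$te_class)
  expressed <- rpkm >= rpkm_cut

  rows <- lapply(unique(cls), function(k) {
    sel <- cls == k
    mq <- stats::quantile(meth[sel], c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
    eq <- stats::quantile(log2(rpkm[sel] + pseudocount),
                          c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(te_class = k, n = sum(sel), n_expressed = sum(expressed[sel]),
               pct_expressed = 100 * mean(expressed[sel]),
               meth_q25 = mq[1], meth_median = mq[2], meth_q75 = mq[3],
               log2rpkm_q25 = eq[1], log2rpkm_median = eq[2],
               log2rpkm_q75 = eq[3])
  })
  subclass_table <- do.call(rbind, rows)
  rownames(subclass_table) <- NULL

  correlation <- NULL
  pos <- rpkm > 0 & !is.na(meth)
  if (sum(pos) >= 4) {
    ct <- suppressWarnings(
      stats::cor.test(meth[pos], log2(rpkm[pos]), method = "spearman",
                      exact = FALSE))
    correlation <- list(rho = unname(ct$estimate), p = ct$p.value,
                        n = sum(pos))
  }

  sample_tests <- NULL
  if (!is.null(expression_B)) {
    rpkm_b <- expression_B$rpkm[match(te$id, expression_B$id)]
    rpkm_b[is.na(rpkm_b)] <- 0
    tr <- lapply(unique(cls), function(k) {
      sel <- cls == k & (expressed | rpkm_b >= rpkm_cut)
      if (sum(sel) < 2) return(NULL)
      a <- log2(rpkm[sel] + pseudocount); b <- log2(rpkm_b[sel] + pseudocount)
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NULL)
      tt <- stats::t.test(a, b)
      data.frame(te_class = k, n = sum(sel), t = unname(tt$statistic),
                 p = tt$p.value, mean_log2_A = mean(a), mean_log2_B = mean(b))
    })
    tr <- tr[!vapply(tr, is.null, logical(1))]
    if (length(tr)) {
      sample_tests <- do.call(rbind, tr)
      rownames(sample_tests) <- NULL
    }
  }

  size_comparison <- data.frame(
    group = c("all", "expressed"),
    n = c(nrow(te), sum(expressed)),
    median_size = c(stats::median(te$size),
                    if (any(expressed)) stats::median(te$size[expressed])
                    else NA_real_),
    mean_size = c(mean(te$size),
                  if (any(expressed)) mean(te$size[expressed]) else NA_real_))

  list(subclass_table = subclass_table, correlation = correlation,
       sample_tests = sample_tests, size_comparison = size_comparison)
}

#' Expression response binned by delta methylation between two conditions
#'
#' For each TE profiled in both conditions, the delta methylation in the
#' chosen context (condition A - condition B, e.g. untreated - treated)
#' is computed from feature-level methylation; TEs are split at
#' `delta_cut` (default 5 percentage points) or at arbitrary
#' `bin_edges`.  Expression response is log2((rpkm_B + pseudocount) /
#' (rpkm_A + pseudocount)) and bins are compared with Welch t-tests
#' against the lowest bin.
#'
#' @param meth_A,meth_B data.frames from [feature_methylation()].
#' @param expr_A,expr_B data.frames from [compute_rpkm()].
#' @param context "CG", "CHG", "CHH" or "nonCG" (column
#'   `level_<context>`).
#' @param delta_cut single threshold splitting low/high delta.
#' @param bin_edges optional full vector of bin edges overriding
#'   `delta_cut`.
#' @param pseudocount RPKM pseudocount (> 0).
#' @return list: `per_te` (id, delta, log2_fc, bin), `bins` (bin label,
#'   n, mean log2 fold-change), `tests` (bin vs first bin; NULL when any
#'   bin is empty or degenerate).
#' @export
treatment_response_bins <- function(meth_A, meth_B, expr_A, expr_B,
                                    context = "CHH", delta_cut = 0.05,
                                    bin_edges = NULL, pseudocount = 0.25) {
  if (pseudocount <= 0) .stopf("'pseudocount' must be > 0")
  col <- paste0("level_", context)
  if (!col %in% names(meth_A)) .stopf("no column '%s' in meth_A", col)
  ids <- intersect(meth_A$id, meth_B$id)
  la <- meth_A[[col]][match(ids, meth_A$id)]
  lb <- meth_B[[col]][match(ids, meth_B$id)]
  ra <- expr_A$rpkm[match(ids, expr_A$id)]
  rb <- expr_B$rpkm[match(ids, expr_B$id)]
  ok <- !is.na(la) & !is.na(lb) & !is.na(ra) & !is.na(rb)
  ids <- ids[ok]; la <- la[ok]; lb <- lb[ok]; ra <- ra[ok]; rb <- rb[ok]
  delta <- la - lb
  edges <- if (is.null(bin_edges)) c(-Inf, delta_cut, Inf) else bin_edges
  labs <- paste0("(", utils::head(edges, -1), ",", edges[-1], "]")
  bin <- cut(delta, breaks = edges, labels = labs, include.lowest = TRUE)
  log2_fc <- log2((rb + pseudocount) / (ra + pseudocount))
  per_te <- data.frame(id = ids, delta = delta, log2_fc = log2_fc,
                       bin = as.character(bin))
  bins <- do.call(rbind, lapply(labs, function(l) {
    sel <- per_te$bin == l
    data.frame(bin = l, n = sum(sel),
               mean_log2_fc = if (any(sel)) mean(log2_fc[sel]) else NA_real_,
               mean_delta = if (any(sel)) mean(delta[sel]) else NA_real_)
  }))
  tests <- NULL
  ref <- per_te$log2_fc[per_te$bin == labs[1]]
  if (length(ref) >= 2) {
    tr <- lapply(labs[-1], function(l) {
      x <- per_te$log2_fc[per_te$bin == l]
      if (length(x) < 2 || (stats::sd(x) == 0 && stats::sd(ref) == 0))
        return(NULL)
      tt <- stats::t.test(x, ref)
      data.frame(bin = l, vs = labs[1], t = unname(tt$statistic),
                 p = tt$p.value)
    })
    tr <- tr[!vapply(tr, is.null, logical(1))]
    if (length(tr)) { tests <- do.call(rbind, tr); rownames(tests) <- NULL }
  }
  list(per_te = per_te, bins = bins, tests = tests)
}
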