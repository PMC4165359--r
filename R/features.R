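# Feature-level methylation, metagene/meta-TE profiles, gene-proximity
# methylation and size-stratified TE summaries.

#' Per-feature methylation levels
#'
#' Summarizes site-level methylation within each feature, per context.
#' "site-mean" averages the per-site levels; "read-weighted" pools counts
#' (sum n_meth / sum coverage).  Features with no eligible site in a
#' context are reported NA for that context.
#'
#' @param records data.frame from [estimate_levels()].
#' @param features feature data.frame.
#' @param mode "site-mean" (default) or "read-weighted".
#' @param contexts contexts to summarize (default CG, CHG, CHH).
#' @return data.frame: id, kind, plus per context `level_<ctx>` and
#'   `n_sites_<ctx>` columns, and `level_nonCG` / `n_sites_nonCG` pooled
#'   over CHG+CHH.
#' @export
feature_methylation <- function(records, features,
                                mode = c("site-mean", "read-weighted"),
                                contexts = c("CG", "CHG", "CHH")) {
  mode <- match.arg(mode)
  lens <- NULL
  if (nrow(features) && any(features$start < 0))
    .stopf("feature with negative start")
  out <- data.frame(id = features$id, kind = features$kind)
  hits <- GenomicRanges::findOverlaps(.positions_granges(records),
                                      .features_granges(features))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  groups <- c(as.list(stats::setNames(contexts, contexts)),
              list(nonCG = c("CHG", "CHH")))
  for (g in names(groups)) {
    keep <- records$context[qh] %in% groups[[g]]
    q <- qh[keep]; s <- sh[keep]
    lvl <- rep(NA_real_, nrow(features))
    n <- rep(0L, nrow(features))
    if (length(q)) {
      if (mode == "site-mean") {
        agg <- tapply(records$level[q], s, mean)
      } else {
        num <- tapply(records$n_meth[q], s, sum)
        den <- tapply(records$n_meth[q] + records$n_unmeth[q], s, sum)
        agg <- num / den
      }
      idx <- as.integer(names(agg))
      lvl[idx] <- as.numeric(agg)
      cnt <- tapply(rep(1L, length(q)), s, sum)
      n[as.integer(names(cnt))] <- as.integer(cnt)
    }
    out[[paste0("level_", g)]] <- lvl
    out[[paste0("n_sites_", g)]] <- n
  }
  attr(out, "mode") <- mode
  out
}

#' Meta-plot of methylation across scaled feature bodies and flanks
#'
#' Each feature body is rescaled to `body_bins` relative bins; upstream
#' and downstream flanks of `flank` bases are cut into `flank_bins`
#' fixed-width bins.  Minus-strand features are reversed so bin 1 is
#' always the 5' end.  A site spanning several relative bins (features
#' shorter than `body_bins` bases) contributes to each overlapped bin
#' proportionally.  Bin values are per-feature means averaged across
#' features (unweighted).
#'
#' @param records data.frame from [estimate_levels()].
#' @param features feature data.frame.
#' @param flank flank length in bases (>= 0).
#' @param body_bins number of body bins (>= 1).
#' @param flank_bins number of bins per flank.
#' @param contexts contexts profiled separately.
#' @return data.frame: region (upstream-flank / body / downstream-flank),
#'   bin (1-based within region), context, mean_level, n_features,
#'   n_sites.
#' @export
metaplot <- function(records, features, flank = 1000, body_bins = 20,
                     flank_bins = 10, contexts = c("CG", "CHG", "CHH")) {
  if (flank < 0) .stopf("'flank' must be >= 0")
  if (body_bins < 1) .stopf("'body_bins' must be >= 1")
  nb_tot <- body_bins + 2L * flank_bins
  nf <- nrow(features)
  res <- list()
  ext <- features
  ext$start <- pmax(0L, features$start - as.integer(flank))
  ext$end <- features$end + as.integer(flank)
  for (cx in contexts) {
    rc <- records[records$context == cx, , drop = FALSE]
    sum_w <- matrix(0, nf, nb_tot)
    sum_wl <- matrix(0, nf, nb_tot)
    nsite <- matrix(0, nf, nb_tot)
    if (nrow(rc) && nf) {
      hits <- GenomicRanges::findOverlaps(.positions_granges(rc),
                                          .features_granges(ext))
      fi <- S4Vectors::subjectHits(hits)
      p <- rc$pos[S4Vectors::queryHits(hits)]
      lv <- rc$level[S4Vectors::queryHits(hits)]
      fs <- features$start[fi]; fe <- features$end[fi]
      minus <- features$strand[fi] == "-"
      L <- fe - fs
      acc <- function(fi, bin, w, lv, count = 1) {
        lin <- fi + (bin - 1L) * nf
        s1 <- rowsum(w, lin); s2 <- rowsum(w * lv, lin)
        s3 <- rowsum(rep(count, length(lin)), lin)
        idx <- as.integer(rownames(s1))
        sum_w[idx] <<- sum_w[idx] + s1
        sum_wl[idx] <<- sum_wl[idx] + s2
        nsite[idx] <<- nsite[idx] + s3
      }
      # --- body sites, rescaled to body_bins relative bins
      inb <- p >= fs & p < fe
      if (any(inb)) {
        r0 <- (p[inb] - fs[inb]) / L[inb] * body_bins
        r1 <- (p[inb] - fs[inb] + 1) / L[inb] * body_bins
        m <- minus[inb]
        t0 <- ifelse(m, body_bins - r1, r0)
        r1 <- ifelse(m, body_bins - r0, r1)
        r0 <- t0
        b0 <- floor(r0); b1 <- pmin(body_bins - 1, floor(r1 - 1e-9))
        simple <- b0 >= b1
        acc(fi[inb][simple], flank_bins + as.integer(b0[simple]) + 1L,
            rep(1, sum(simple)), lv[inb][simple])
        for (j in which(!simple)) {    # rare: site wider than one bin
          bins <- b0[j]:b1[j]
          w <- pmin(r1[j], bins + 1) - pmax(r0[j], bins)
          w <- w / sum(w)
          acc(rep(fi[inb][j], length(bins)), flank_bins + bins + 1L, w,
              rep(lv[inb][j], length(bins)), count = 1 / length(bins))
        }
      }
      # --- flank sites, fixed-width bins; minus-strand features mirrored
      if (flank_bins > 0 && flank > 0) {
        bw <- flank / flank_bins
        up <- p < fs & p >= fs - flank
        if (any(up)) {
          k <- pmin(flank_bins - 1, floor((fs[up] - 1 - p[up]) / bw))
          bin <- ifelse(minus[up], flank_bins + body_bins + k + 1,
                        flank_bins - k)
          acc(fi[up], as.integer(bin), rep(1, sum(up)), lv[up])
        }
        dn <- p >= fe & p < fe + flank
        if (any(dn)) {
          k <- pmin(flank_bins - 1, floor((p[dn] - fe[dn]) / bw))
          bin <- ifelse(minus[dn], flank_bins - k,
                        flank_bins + body_bins + k + 1)
          acc(fi[dn], as.integer(bin), rep(1, sum(dn)), lv[dn])
        }
      }
    }
    featmean <- sum_wl / sum_w  # NaN where a feature has no sites in a bin
    mean_level <- colMeans(featmean, na.rm = TRUE)
    mean_level[!is.finite(mean_level)] <- NA_real_
    region <- rep(c("upstream-flank", "body", "downstream-flank"),
                  c(flank_bins, body_bins, flank_bins))
    bin <- c(seq_len(flank_bins), seq_len(body_bins), seq_len(flank_bins))
    res[[cx]] <- data.frame(region = region, bin = bin, context = cx,
                            mean_level = mean_level,
                            n_features = colSums(sum_w > 0),
                            n_sites = round(colSums(nsite)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' TE methylation as a function of distance to expressed genes
#'
#' Genes are split at expression quartiles (top 25\% vs bottom 25\% RPKM,
#' quartiles over genes with RPKM > 0, nearest-rank ties).  Cytosines of
#' TEs lying within `max_dist` of a gene's 5' or 3' end (TEs overlapping
#' any gene are excluded, their distance being undefined) are assigned a
#' signed gene-relative distance (negative = upstream of the 5' end) and
#' averaged in tiled `window`-bp distance bins per gene class.  Welch
#' t-tests compare high- vs low-class TE site levels within the
#' 0-0.5 kb and 0.5-1 kb distance strata.
#'
#' @param te_features,gene_features feature data.frames.
#' @param expression data.frame with columns id and rpkm (genes).
#' @param records site-level methylation, filtered to `context` below.
#' @param max_dist maximum gene-TE distance in bases (> 0).
#' @param window tiled averaging window in bases.
#' @param context site context used (default CG).
#' @return list: `profile` (data.frame class, distance bin mid, mean
#'   level, n sites), `tests` (data.frame stratum, t, p, n_high, n_low;
#'   NULL when a class has < 2 genes or a stratum < 2 sites per class).
#' @export
proximity_profile <- function(te_features, gene_features, expression,
                              records, max_dist = 1000, window = 100,
                              context = "CG") {
  if (max_dist <= 0) .stopf("'max_dist' must be > 0")
  rp <- expression$rpkm[match(gene_features$id, expression$id)]
  pos_rp <- rp[!is.na(rp) & rp > 0]
  if (length(pos_rp) < 4)
    return(list(profile = .empty_proximity(), tests = NULL,
                sites = .empty_proximity_sites()))
  qs <- stats::quantile(pos_rp, c(0.25, 0.75), type = 1, names = FALSE)
  cls <- rep(NA_character_, nrow(gene_features))
  cls[!is.na(rp) & rp > 0 & rp >= qs[2]] <- "high"
  cls[!is.na(rp) & rp > 0 & rp <= qs[1]] <- "low"

  # TEs overlapping any gene are excluded
  ov <- GenomicRanges::findOverlaps(.features_granges(te_features),
                                    .features_granges(gene_features))
  te_ok <- te_features[setdiff(seq_len(nrow(te_features)),
                               unique(S4Vectors::queryHits(ov))), ,
                       drop = FALSE]
  rc <- records[records$context == context, , drop = FALSE]
  site_tab <- list()
  if (nrow(te_ok) && nrow(rc)) {
    # sites inside eligible TEs
    h <- GenomicRanges::findOverlaps(.positions_granges(rc),
                                     .features_granges(te_ok))
    te_sites <- rc[unique(S4Vectors::queryHits(h)), , drop = FALSE]
    for (side in c("upstream", "downstream")) {
      for (gi in which(!is.na(cls))) {
        g <- gene_features[gi, ]
        plus <- !identical(g$strand, "-")
        # gene-relative: negative distances flank the 5' (TSS) side
        if (side == "upstream") {
          iv <- if (plus) c(g$start - max_dist, g$start)
                else c(g$end, g$end + max_dist)
        } else {
          iv <- if (plus) c(g$end, g$end + max_dist)
                else c(g$start - max_dist, g$start)
        }
        sel <- te_sites$scaffold == g$scaffold &
          te_sites$pos >= iv[1] & te_sites$pos < iv[2]
        if (!any(sel)) next
        p <- te_sites$pos[sel]
        d <- if (plus) {
          if (side == "upstream") p - g$start else p - g$end + 1
        } else {
          if (side == "upstream") g$end - 1 - p else g$start - p
        }
        # upstream distances negative, downstream positive
        site_tab[[length(site_tab) + 1L]] <- data.frame(
          class = cls[gi], distance = as.numeric(d),
          level = te_sites$level[sel])
      }
    }
  }
  if (!length(site_tab))
    return(list(profile = .empty_proximity(), tests = NULL,
                sites = .empty_proximity_sites()))
  sites <- do.call(rbind, site_tab)
  bin <- floor(sites$distance / window)
  key <- paste(sites$class, bin)
  prof <- data.frame(
    class = tapply(sites$class, key, `[`, 1),
    bin_mid = tapply(bin, key, `[`, 1) * window + window / 2,
    mean_level = as.numeric(tapply(sites$level, key, mean)),
    n_sites = as.integer(tapply(sites$level, key, length)))
  prof <- prof[order(prof$class, prof$bin_mid), , drop = FALSE]
  rownames(prof) <- NULL

  n_genes <- table(cls)
  tests <- NULL
  if (all(c("high", "low") %in% names(n_genes)) &&
      all(n_genes[c("high", "low")] >= 2)) {
    strata <- list("<=0.5kb" = c(0, 500), "0.5-1kb" = c(500, 1000))
    rows <- list()
    for (snm in names(strata)) {
      rng <- strata[[snm]]
      ad <- abs(sites$distance)
      sel <- ad >= rng[1] & ad < rng[2]
      hi <- sites$level[sel & sites$class == "high"]
      lo <- sites$level[sel & sites$class == "low"]
      if (length(hi) >= 2 && length(lo) >= 2 &&
          (stats::sd(hi) > 0 || stats::sd(lo) > 0)) {
        tt <- stats::t.test(hi, lo)
        rows[[snm]] <- data.frame(stratum = snm, t = unname(tt$statistic),
                                  p = tt$p.value, mean_high = mean(hi),
                                  mean_low = mean(lo),
                                  n_high = length(hi), n_low = length(lo))
      }
    }
    if (length(rows)) { tests <- do.call(rbind, rows); rownames(tests) <- NULL }
  }
  list(profile = prof, tests = tests, sites = sites)
}

.empty_proximity <- function() {
  data.frame(class = character(), bin_mid = numeric(),
             mean_level = numeric(), n_sites = integer())
}
.empty_proximity_sites <- function() {
  data.frame(class = character(), distance = numeric(), level = numeric())
}

#' TE methylation and expression stratified by element size
#'
#' Cross-tabulates TEs by size (at `size_cut`, default 1.5 kb) and
#' expression status (RPKM >= `rpkm_cut`), reporting per-stratum counts,
#' methylation mean and quartiles, and the expressed fraction.  Large,
#' heavily methylated elements being almost never expressed is the
#' signature of methylation-directed repeat silencing.
#'
#' @param te_methylation data.frame from [feature_methylation()] (TEs),
#'   with a `level_CG` column.
#' @param te_features TE feature data.frame.
#' @param expression data.frame with id and rpkm.
#' @param size_cut size threshold in bases.
#' @param rpkm_cut expression threshold.
#' @return data.frame: one row per size stratum with n, n_expressed,
#'   expressed_fraction, meth mean/q25/median/q75.
#' @export
size_stratified_summary <- function(te_methylation, te_features, expression,
                                    size_cut = 1500, rpkm_cut = 1) {
  size <- te_features$size[match(te_methylation$id, te_features$id)]
  rpkm <- expression$rpkm[match(te_methylation$id, expression$id)]
  rpkm[is.na(rpkm)] <- 0
  stratum <- ifelse(size > size_cut,
                    sprintf(">%dbp", size_cut), sprintf("<=%dbp", size_cut))
  expressed <- rpkm >= rpkm_cut
  rows <- lapply(unique(stratum), function(s) {
    sel <- stratum == s
    lv <- te_methylation$level_CG[sel]
    qs <- stats::quantile(lv, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(stratum = s, n = sum(sel), n_expressed = sum(expressed[sel]),
               expressed_fraction = mean(expressed[sel]),
               meth_mean = mean(lv, na.rm = TRUE),
               meth_q25 = qs[1], meth_median = qs[2], meth_q75 = qs[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  out
}
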