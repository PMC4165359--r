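# Feature-level differential methylation between two samples: per-site
# delta methylation and a z-score over per-feature mean deltas.

#' Per-site delta methylation between two samples
#'
#' Delta m = level(A) - level(B), computed only at positions that carry a
#' valid level in both samples with matching context.  Antisymmetric:
#' swapping the samples negates every delta.
#'
#' @param records_A,records_B data.frames from [estimate_levels()].
#' @param contexts contexts retained (default all three).
#' @return data.frame: scaffold, pos, strand, context, level_A, level_B,
#'   delta; attribute `context_mismatches` counts skipped positions.
#' @export
site_deltas <- function(records_A, records_B,
                        contexts = c("CG", "CHG", "CHH")) {
  a <- records_A[records_A$context %in% contexts, , drop = FALSE]
  b <- records_B[records_B$context %in% contexts, , drop = FALSE]
  ka <- paste(a$scaffold, a$pos, a$strand)
  kb <- paste(b$scaffold, b$pos, b$strand)
  m <- match(ka, kb)
  keep <- !is.na(m)
  a <- a[keep, , drop = FALSE]; m <- m[keep]
  mismatch <- a$context != b$context[m]
  if (any(mismatch))
    warning(sprintf("%d position(s) with mismatching context skipped",
                    sum(mismatch)))
  a <- a[!mismatch, , drop = FALSE]; m <- m[!mismatch]
  out <- data.frame(scaffold = a$scaffold, pos = a$pos, strand = a$strand,
                    context = a$context, level_A = a$level,
                    level_B = b$level[m], delta = a$level - b$level[m])
  rownames(out) <- NULL
  attr(out, "context_mismatches") <- sum(mismatch)
  out
}

#' Call differentially methylated features
#'
#' For each feature with at least `min_sites` eligible sites (sites with a
#' delta) in a context class, the mean delta methylation is standardized
#' against the across-feature distribution of mean deltas of the same
#' feature kind and context class: z = (mean_delta - mu) / sigma.  A
#' feature is called differentially methylated when |z| exceeds
#' `z_threshold` (default 1.96) and its feature-level mean methylation
#' differs between the samples by at least `min_mean_diff` — 20
#' percentage points for TEs and 10 for genes by default, the reduced
#' gene cut reflecting their much weaker methylation.  CG and non-CG
#' (CHG+CHH) classes are analyzed separately.
#'
#' @param deltas data.frame from [site_deltas()].
#' @param features feature data.frame.
#' @param min_sites minimum eligible sites per feature and context class.
#' @param z_threshold |z| cut for a call.
#' @param min_mean_diff named vector: minimum absolute difference of
#'   feature mean levels per kind (defaults `c(TE = 0.20, gene = 0.10)`).
#' @param context_classes list of context groupings analyzed separately.
#' @param z_mode "across-features" (default: empirical mean/SD of mean
#'   deltas over same-kind features) or "within-feature" (mean delta over
#'   its standard error from per-site delta spread).
#' @return data.frame of class `fm_dmr`: id, kind, context_class,
#'   n_sites, mean_delta, mean_level_A, mean_level_B, z, is_dmr,
#'   direction ("A>B" / "B>A").
#' @export
call_differential_features <- function(deltas, features, min_sites = 4,
                                       z_threshold = 1.96,
                                       min_mean_diff = c(TE = 0.20,
                                                         gene = 0.10),
                                       context_classes = list(
                                         CG = "CG",
                                         nonCG = c("CHG", "CHH")),
                                       z_mode = c("across-features",
                                                  "within-feature")) {
  z_mode <- match.arg(z_mode)
  if (min_sites < 1) .stopf("'min_sites' must be >= 1")
  fgr <- .features_granges(features)
  out <- list()
  for (cl in names(context_classes)) {
    d <- deltas[deltas$context %in% context_classes[[cl]], , drop = FALSE]
    if (!nrow(d)) next
    hits <- GenomicRanges::findOverlaps(.positions_granges(d), fgr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (!length(qh)) next
    n_sites <- tapply(rep(1L, length(qh)), sh, sum)
    idx <- as.integer(names(n_sites))
    tab <- data.frame(
      id = features$id[idx], kind = features$kind[idx],
      context_class = cl, n_sites = as.integer(n_sites),
      mean_delta = as.numeric(tapply(d$delta[qh], sh, mean)),
      mean_level_A = as.numeric(tapply(d$level_A[qh], sh, mean)),
      mean_level_B = as.numeric(tapply(d$level_B[qh], sh, mean)),
      sd_delta = as.numeric(tapply(d$delta[qh], sh, stats::sd)))
    tab <- tab[tab$n_sites >= min_sites, , drop = FALSE]
    out[[cl]] <- tab
  }
  empty <- function() {
    res <- data.frame(id = character(), kind = character(),
                      context_class = character(), n_sites = integer(),
                      mean_delta = numeric(), mean_level_A = numeric(),
                      mean_level_B = numeric(), z = numeric(),
                      is_dmr = logical(), direction = character())
    class(res) <- c("fm_dmr", class(res))
    res
  }
  if (!length(out)) return(empty())
  tab <- do.call(rbind, out)
  if (!nrow(tab)) return(empty())
  tab$z <- NA_real_
  for (grp in split(seq_len(nrow(tab)),
                    paste(tab$kind, tab$context_class))) {
    if (length(grp) < 2) next
    if (z_mode == "across-features") {
      mu <- mean(tab$mean_delta[grp]); sg <- stats::sd(tab$mean_delta[grp])
      if (is.na(sg) || sg == 0) {
        warning("zero variance of mean deltas; z undefined for a group")
        next
      }
      tab$z[grp] <- (tab$mean_delta[grp] - mu) / sg
    } else {
      se <- tab$sd_delta[grp] / sqrt(tab$n_sites[grp])
      tab$z[grp] <- ifelse(se > 0, tab$mean_delta[grp] / se, NA_real_)
    }
  }
  cut <- min_mean_diff[tab$kind]
  cut[is.na(cut)] <- max(min_mean_diff)
  tab$is_dmr <- !is.na(tab$z) & abs(tab$z) > z_threshold &
    abs(tab$mean_level_A - tab$mean_level_B) >= cut
  tab$direction <- ifelse(tab$mean_delta > 0, "A>B", "B>A")
  tab$sd_delta <- NULL
  rownames(tab) <- NULL
  class(tab) <- c("fm_dmr", class(tab))
  tab
}

#' @export
print.fm_dmr <- function(x, ...) {
  cat(sprintf("Differential methylation: %d feature/context entries, %d called\n",
              nrow(x), sum(x$is_dmr)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
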