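# Strand-aware per-cytosine methylation calling: context classification,
# C/T vote counting, level estimation (#C / (#C + #T)), methylated-site
# calling and bulk summaries.

# ASCII byte codes used for base comparisons on integer-converted raw
# scaffold sequences (fast and vectorizable).
BYTE_A <- 65L; BYTE_C <- 67L; BYTE_G <- 71L; BYTE_T <- 84L

# Context of plus-strand cytosines at 0-based positions `pos`, given the
# scaffold as an integer byte vector: inspect the two downstream bases.
.classify_raw_plus <- function(ri, pos) {
  L <- length(ri)
  np <- length(pos)
  n1 <- rep(0L, np); n2 <- rep(0L, np)
  ok1 <- pos + 2L <= L; ok2 <- pos + 3L <= L
  n1[ok1] <- ri[pos[ok1] + 2L]
  n2[ok2] <- ri[pos[ok2] + 3L]
  .ctx_from_neighbors(n1, n2, g = BYTE_G)
}

# Minus-strand cytosines sit at plus-strand G positions; their downstream
# neighbors are the complements of the plus-strand bases at pos-1, pos-2.
# "Next base is G on the minus strand" <=> plus base at pos-1 is C.
.classify_raw_minus <- function(ri, pos) {
  np <- length(pos)
  n1 <- rep(0L, np); n2 <- rep(0L, np)
  ok1 <- pos >= 1L; ok2 <- pos >= 2L
  n1[ok1] <- ri[pos[ok1]]
  n2[ok2] <- ri[pos[ok2] - 1L]
  .ctx_from_neighbors(n1, n2, g = BYTE_C)
}

.ctx_from_neighbors <- function(n1, n2, g) {
  valid <- c(BYTE_A, BYTE_C, BYTE_G, BYTE_T)
  good1 <- n1 %in% valid
  good2 <- n2 %in% valid
  out <- rep("unknown", length(n1))
  out[good1 & n1 == g] <- "CG"
  chx <- good1 & n1 != g
  out[chx & good2 & n2 == g] <- "CHG"
  out[chx & good2 & n2 != g] <- "CHH"
  out
}

#' Classify the sequence context of cytosines
#'
#' Returns "CG", "CHG" or "CHH" (H = A, C or T) for each cytosine,
#' inspecting the two bases downstream on the cytosine's own strand;
#' "unknown" when a neighbor is off-contig or not A/C/G/T.  Symmetric CG
#' and CHG contexts pair across strands; CHH is asymmetric.
#'
#' @param genome a `DNAStringSet`.
#' @param scaffold scaffold name(s), recycled against `pos`.
#' @param pos 0-based position(s) of the cytosine (plus-strand coordinate
#'   also for minus-strand cytosines, which sit at plus-strand G).
#' @param strand "+" or "-" per position.
#' @return character vector of contexts.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "ACGTTGCA"))
#' classify_context(g, "chr", c(1, 6), c("+", "-"))
classify_context <- function(genome, scaffold, pos, strand) {
  n <- max(length(scaffold), length(pos), length(strand))
  scaffold <- rep_len(scaffold, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (sc in unique(scaffold)) {
    ri <- as.integer(charToRaw(.genome_char(genome, sc)))
    sel <- scaffold == sc
    p <- pos[sel]; s <- strand[sel]
    if (any(p < 0) || any(p >= length(ri)))
      .stopf("position out of range on scaffold '%s'", sc)
    base <- ri[p + 1L]
    bad <- (s == "+" & base != BYTE_C) | (s == "-" & base != BYTE_G)
    if (any(bad))
      .stopf("reference base at %s:%d (%s) is not a cytosine on that strand",
             sc, p[which(bad)[1]], s[which(bad)[1]])
    res <- character(length(p))
    res[s == "+"] <- .classify_raw_plus(ri, p[s == "+"])
    res[s == "-"] <- .classify_raw_minus(ri, p[s == "-"])
    out[sel] <- res
  }
  out
}

#' Tabulate methylated / unmethylated read votes per cytosine
#'
#' Watson-origin reads vote at plus-strand C positions (C = methylated,
#' T = unmethylated); Crick-origin reads vote at minus-strand C positions
#' through the complementary base on the plus-strand projection
#' (G = methylated, A = unmethylated).  Any other observed base is a
#' mismatch and casts no vote.  Reads overhanging a contig end are
#' rejected and counted.
#'
#' @param reads read data.frame (read_id, scaffold, start, strand, seq),
#'   as produced by [simulate_bisulfite_reads()] or [read_reads()].
#' @param genome a `DNAStringSet`.
#' @return data.frame (scaffold, pos, strand, n_meth, n_unmeth) for every
#'   cytosine with at least one vote; attributes `rejected_reads` and
#'   `mismatch_bases`.
#' @export
tabulate_counts <- function(reads, genome) {
  out <- vector("list", length(genome))
  rejected <- 0; mismatches <- 0
  for (k in seq_along(genome)) {
    sc <- names(genome)[k]
    rd <- reads[reads$scaffold == sc, , drop = FALSE]
    if (!nrow(rd)) { out[[k]] <- NULL; next }
    pl <- cpp_pileup(as.character(genome[[k]]), as.integer(rd$start),
                     rd$strand == "+", rd$seq)
    rejected <- rejected + pl$rejected
    mismatches <- mismatches + pl$mismatches
    pcov <- pl$plus_meth + pl$plus_unmeth
    mcov <- pl$minus_meth + pl$minus_unmeth
    ip <- which(pcov > 0); im <- which(mcov > 0)
    df <- data.frame(
      scaffold = rep(sc, length(ip) + length(im)),
      pos = c(ip, im) - 1L,
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      n_meth = c(pl$plus_meth[ip], pl$minus_meth[im]),
      n_unmeth = c(pl$plus_unmeth[ip], pl$minus_unmeth[im]))
    out[[k]] <- df[order(df$pos), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scaffold = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer())
  rownames(res) <- NULL
  if (rejected > 0)
    warning(sprintf("%d read(s) overhanging contig ends were rejected",
                    rejected))
  attr(res, "rejected_reads") <- rejected
  attr(res, "mismatch_bases") <- mismatches
  res
}

#' Estimate per-cytosine methylation levels
#'
#' The level of each cytosine is `n_meth / (n_meth + n_unmeth)` — the
#' fraction of unconverted (C) reads over all informative reads — and is
#' reported only at sites covered by at least `min_coverage` informative
#' reads.  Sequence context is attached from the genome.
#'
#' @param counts data.frame from [tabulate_counts()].
#' @param genome a `DNAStringSet`.
#' @param min_coverage minimum informative reads per site (default 4).
#' @return data.frame (scaffold, pos, strand, context, n_meth, n_unmeth,
#'   level); attribute `coverage_fraction` = included sites / all genomic
#'   cytosines.
#' @export
estimate_levels <- function(counts, genome, min_coverage = 4) {
  if (!is.numeric(min_coverage) || min_coverage < 1)
    .stopf("'min_coverage' must be >= 1")
  cov <- counts$n_meth + counts$n_unmeth
  rec <- counts[cov >= min_coverage, , drop = FALSE]
  rec$context <- if (nrow(rec))
    classify_context(genome, rec$scaffold, rec$pos, rec$strand)
  else character()
  rec$level <- ifelse(rec$n_meth + rec$n_unmeth > 0,
                      rec$n_meth / (rec$n_meth + rec$n_unmeth), NA_real_)
  rec <- rec[, c("scaffold", "pos", "strand", "context",
                 "n_meth", "n_unmeth", "level")]
  rownames(rec) <- NULL
  attr(rec, "coverage_fraction") <- nrow(rec) / .n_genomic_cytosines(genome)
  rec
}

#' Call methylated cytosines
#'
#' Default "binomial" mode tests each site's methylated count against the
#' bisulfite non-conversion error rate (one-sided binomial) and controls
#' the FDR across sites with Benjamini-Hochberg; "positive" mode simply
#' flags any site with level > 0.
#'
#' @param records data.frame from [estimate_levels()].
#' @param error_rate expected non-conversion (false-C) rate, in (0, 1).
#' @param fdr Benjamini-Hochberg false-discovery-rate level, in (0, 1).
#' @param method "binomial" (default) or "positive".
#' @return `records` with logical column `is_methylated` (and `p_value`,
#'   `q_value` in binomial mode).
#' @export
call_methylated_sites <- function(records, error_rate = 0.005, fdr = 0.05,
                                  method = c("binomial", "positive")) {
  method <- match.arg(method)
  if (method == "positive") {
    records$is_methylated <- records$level > 0
    return(records)
  }
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1)
    .stopf("'error_rate' must be in (0, 1)")
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1)
    .stopf("'fdr' must be in (0, 1)")
  n <- records$n_meth + records$n_unmeth
  # P(X >= n_meth) under X ~ Binom(n, error_rate)
  p <- stats::pbinom(records$n_meth - 1L, n, error_rate, lower.tail = FALSE)
  p[records$n_meth == 0L] <- 1
  q <- stats::p.adjust(p, method = "BH")
  records$p_value <- p
  records$q_value <- q
  records$is_methylated <- q < fdr & records$n_meth > 0L
  records
}

#' Bulk methylome summary
#'
#' Per-context (CG / CHG / CHH) unweighted means of site levels, the
#' fraction of covered cytosines called methylated, per-context level
#' histograms on fixed bin edges (including 0.10 and 0.80, so bimodality
#' of the CG landscape can be read off directly), and the genomic coverage
#' fraction.  Unknown-context sites are excluded from context-stratified
#' summaries; an absent context is reported as missing (NA), not zero.
#'
#' @param records data.frame from [estimate_levels()] (optionally after
#'   [call_methylated_sites()]).
#' @param breaks histogram bin edges on `[0, 1]`; must include 0.10 and
#'   0.80.
#' @return object of class `fm_bulk_summary`: list with `means`,
#'   `methylated_fraction`, `histograms` (per-context masses summing to
#'   1), `n_sites`, `covered_fraction`.
#' @export
summarize_bulk <- function(records, breaks = seq(0, 1, by = 0.05)) {
  if (!all(c(0.10, 0.80) %in% round(breaks, 10)))
    .stopf("'breaks' must include 0.10 and 0.80")
  ctxs <- c("CG", "CHG", "CHH")
  means <- stats::setNames(rep(NA_real_, 3), ctxs)
  nsites <- stats::setNames(rep(0L, 3), ctxs)
  hists <- stats::setNames(vector("list", 3), ctxs)
  for (cx in ctxs) {
    lv <- records$level[records$context == cx]
    nsites[cx] <- length(lv)
    if (length(lv)) {
      means[cx] <- mean(lv)
      h <- hist(lv, breaks = breaks, plot = FALSE, right = FALSE,
                include.lowest = TRUE)
      hists[[cx]] <- stats::setNames(h$counts / sum(h$counts),
                                     paste0("[", head(breaks, -1), ",",
                                            breaks[-1], ")"))
    }
  }
  mfrac <- if (!is.null(records$is_methylated) && nrow(records))
    mean(records$is_methylated) else NA_real_
  out <- list(means = means, methylated_fraction = mfrac,
              histograms = hists, n_sites = nsites,
              covered_fraction = attr(records, "coverage_fraction") %||%
                NA_real_)
  class(out) <- "fm_bulk_summary"
  out
}

#' @export
print.fm_bulk_summary <- function(x, ...) {
  cat("Bulk methylome summary\n")
  for (cx in names(x$means))
    cat(sprintf("  %-3s mean level %s over %d sites\n", cx,
                ifelse(is.na(x$means[cx]), "NA",
                       sprintf("%.4f", x$means[cx])), x$n_sites[cx]))
  if (!is.na(x$methylated_fraction))
    cat(sprintf("  methylated fraction of covered sites: %.4f\n",
                x$methylated_fraction))
  if (!is.na(x$covered_fraction))
    cat(sprintf("  fraction of genomic cytosines covered: %.4f\n",
                x$covered_fraction))
  invisible(x)
}

#' One-step methylation calling from reads
#'
#' Convenience wrapper: [tabulate_counts()] then [estimate_levels()].
#' @inheritParams tabulate_counts
#' @inheritParams estimate_levels
#' @return see [estimate_levels()].
#' @export
call_methylation <- function(reads, genome, min_coverage = 4) {
  estimate_levels(tabulate_counts(reads, genome), genome,
                  min_coverage = min_coverage)
}
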