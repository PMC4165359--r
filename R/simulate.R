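# Synthetic-data generator: genome layout, ground-truth methylome,
# bisulfite reads, expression counts and planted copy-number changes.

#' Generate a synthetic TE-rich genome with gene and TE annotations
#'
#' Lays out each scaffold as alternating gene blocks and TE islands: blocks
#' hold genes (with exon/intron structure) separated by short intergenic
#' gaps, islands are densely tiled with individual TE copies whose subclass
#' is sampled from `config$te_subclass_weights`.  Block length is derived
#' from `te_island_size` and `te_fraction` so that the cumulative TE length
#' matches `te_fraction` closely; a configurable minority of TEs
#' (`te_near_gene_frac`) is additionally placed inside gene blocks within
#' 1 kb of a gene.  Genes never overlap TEs.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed for this operation; defaults to `config$seed`.
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `features`
#'   (data.frame: id, scaffold, start, end, strand, kind, te_class, size;
#'   0-based half-open coordinates) and `exons` (data.frame: id, gene_id,
#'   scaffold, start, end, strand).
#' @export
build_genome <- function(config, seed = config$seed) {
  if (!inherits(config, "fm_sim_config")) config <- do.call(sim_config, config)
  set.seed(seed)
  lens <- .split_lengths(config$genome_length, config$n_scaffolds)
  scaff_names <- sprintf("scaffold_%02d", seq_along(lens))

  feats <- list(); exons <- list()
  seqs <- character(length(lens))
  gene_i <- 0L; te_i <- 0L
  for (k in seq_along(lens)) {
    L <- lens[k]
    sc <- scaff_names[k]
    seqs[k] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                            prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
    segs <- .layout_segments(L, config)
    for (si in seq_len(nrow(segs))) {
      s0 <- segs$start[si]; s1 <- segs$end[si]
      if (segs$type[si] == "island") {
        placed <- .fill_te_island(s0, s1, config)
        if (nrow(placed)) {
          placed$id <- sprintf("te_%05d", te_i + seq_len(nrow(placed)))
          te_i <- te_i + nrow(placed)
          placed$scaffold <- sc
          feats[[length(feats) + 1L]] <- placed
        }
      } else {
        gb <- .fill_gene_block(s0, s1, config)
        if (nrow(gb$genes)) {
          gb$genes$id <- sprintf("gene_%05d", gene_i + seq_len(nrow(gb$genes)))
          gb$exons$gene_id <- gb$genes$id[gb$exons$gene_idx]
          gene_i <- gene_i + nrow(gb$genes)
          gb$genes$scaffold <- sc
          gb$exons$scaffold <- sc
          feats[[length(feats) + 1L]] <- gb$genes
          exons[[length(exons) + 1L]] <- gb$exons
        }
        if (nrow(gb$near_tes)) {
          gb$near_tes$id <- sprintf("te_%05d", te_i + seq_len(nrow(gb$near_tes)))
          te_i <- te_i + nrow(gb$near_tes)
          gb$near_tes$scaffold <- sc
          feats[[length(feats) + 1L]] <- gb$near_tes
        }
      }
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(id = character(), scaffold = character(), start = integer(),
               end = integer(), strand = character(), kind = character(),
               te_class = character())
  features <- features[, c("id", "scaffold", "start", "end", "strand",
                           "kind", "te_class")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$size <- features$end - features$start
  rownames(features) <- NULL
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(id = character(), gene_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character())
  exons <- exons[, c("id", "gene_id", "scaffold", "start", "end", "strand")]
  rownames(exons) <- NULL
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, scaff_names))
  list(genome = genome, features = features, exons = exons)
}

.split_lengths <- function(total, n) {
  base <- total %/% n
  out <- rep(base, n)
  out[1] <- out[1] + total - sum(out)
  out
}

# Alternating block/island segmentation of one scaffold.  The gene-block
# target length is derived from the island size and the requested TE
# fraction (TEs tile ~95% of an island), so that the expected cumulative
# TE length tracks te_fraction.
.layout_segments <- function(L, config) {
  f <- config$te_fraction
  if (f <= 0)
    return(data.frame(type = "block", start = 0L, end = L))
  fill <- 0.95
  f <- min(f, 0.90)
  isl <- config$te_island_size
  blk <- max(500, isl * (fill - f) / f)
  pos <- 0L; type <- character(); start <- integer(); end <- integer()
  island_next <- FALSE
  while (pos < L) {
    target <- if (island_next) isl else blk
    len <- round(stats::rnorm(1, target, 0.15 * target))
    len <- max(round(0.3 * target), min(len, round(2 * target)))
    len <- min(len, L - pos)
    type <- c(type, if (island_next) "island" else "block")
    start <- c(start, pos); end <- c(end, pos + len)
    pos <- pos + len
    island_next <- !island_next
  }
  data.frame(type = type, start = as.integer(start), end = as.integer(end))
}

.fill_te_island <- function(s0, s1, config) {
  pos <- s0 + 40L
  starts <- integer(); ends <- integer()
  repeat {
    te_len <- round(stats::rlnorm(1, log(2000), 0.7))
    te_len <- max(200L, min(8000L, te_len))
    if (pos + te_len > s1 - 40L) {
      rem <- (s1 - 40L) - pos
      if (rem >= 300L) { starts <- c(starts, pos); ends <- c(ends, pos + rem) }
      break
    }
    starts <- c(starts, pos); ends <- c(ends, pos + te_len)
    pos <- pos + te_len + 80L
  }
  n <- length(starts)
  if (!n) return(data.frame())
  data.frame(start = as.integer(starts), end = as.integer(ends),
             strand = sample(c("+", "-"), n, replace = TRUE),
             kind = "TE",
             te_class = sample(names(config$te_subclass_weights), n,
                               replace = TRUE,
                               prob = config$te_subclass_weights))
}

.fill_gene_block <- function(s0, s1, config) {
  pos <- s0 + max(200L, round(stats::rnorm(1, 500, 100)))
  g_start <- integer(); g_end <- integer(); g_strand <- character()
  t_start <- integer(); t_end <- integer()
  ex <- list()
  gi <- 0L
  repeat {
    gl <- round(stats::rnorm(1, 1500, 400))
    gl <- max(600L, min(4000L, gl))
    if (pos + gl > s1 - 200L) break
    gi <- gi + 1L
    strand <- sample(c("+", "-"), 1)
    g_start <- c(g_start, pos); g_end <- c(g_end, pos + gl)
    g_strand <- c(g_strand, strand)
    ex[[gi]] <- cbind(gene_idx = gi, .make_exons(pos, pos + gl), strand = strand)
    pos <- pos + gl
    # occasionally drop a short TE into the intergenic gap, < 1 kb downstream
    if (stats::runif(1) < config$te_near_gene_frac) {
      tl <- max(150L, min(600L, round(stats::rnorm(1, 350, 80))))
      ts <- pos + 60L
      if (ts + tl < s1 - 200L) {
        t_start <- c(t_start, ts); t_end <- c(t_end, ts + tl)
        pos <- ts + tl
      }
    }
    gap <- max(200L, round(stats::rnorm(1, 800, 150)))
    pos <- pos + gap
  }
  genes <- if (gi) data.frame(start = g_start, end = g_end, strand = g_strand,
                              kind = "gene", te_class = NA_character_)
           else data.frame()
  exdf <- if (gi) {
    d <- as.data.frame(do.call(rbind, lapply(ex, function(m)
      m[, c("gene_idx", "start", "end"), drop = FALSE])))
    d$strand <- unlist(lapply(ex, function(m) m[, "strand"]))
    d$gene_idx <- as.integer(d$gene_idx)
    d$start <- as.integer(d$start); d$end <- as.integer(d$end)
    d$id <- sprintf("exon_%d", seq_len(nrow(d)))
    d
  } else data.frame()
  near <- if (length(t_start))
    data.frame(start = t_start, end = t_end,
               strand = sample(c("+", "-"), length(t_start), replace = TRUE),
               kind = "TE",
               te_class = sample(names(config$te_subclass_weights),
                                 length(t_start), replace = TRUE,
                                 prob = config$te_subclass_weights))
    else data.frame()
  list(genes = genes, exons = exdf, near_tes = near)
}

# 1-3 exons per gene separated by short introns.
.make_exons <- function(g0, g1) {
  len <- g1 - g0
  n <- 1L + stats::rbinom(1, 2, 0.6)
  if (len < n * 150 + (n - 1) * 250) n <- 1L
  if (n == 1L) return(cbind(start = g0, end = g1))
  introns <- round(stats::runif(n - 1, 80, 250))
  exlen_total <- len - sum(introns)
  w <- stats::runif(n, 0.3, 1); w <- w / sum(w)
  exlens <- pmax(100L, round(w * exlen_total))
  exlens[n] <- exlen_total - sum(exlens[-n])
  if (exlens[n] < 100) return(cbind(start = g0, end = g1))
  starts <- g0 + cumsum(c(0L, exlens[-n] + introns))
  cbind(start = as.integer(starts), end = as.integer(starts + exlens))
}

#' Assign a ground-truth methylome to every genomic cytosine
#'
#' Every cytosine (plus-strand C and minus-strand C, i.e. plus-strand G)
#' receives a true methylation level drawn from a context- and
#' annotation-dependent distribution: cytosines inside TE features draw
#' from a high mode (CG: a mixture concentrated above 0.8 with mean
#' `cg_meth_te`; non-CG: a broad beta with mean `noncg_meth_te`), all other
#' cytosines from a low background mode (means `cg_meth_gene` /
#' `noncg_meth_gene`), giving the bimodal CG landscape characteristic of
#' TE-silencing fungal methylomes.  Sites whose context cannot be
#' determined (contig edge or flanking N) get level 0 and are flagged.
#'
#' @param genome a `DNAStringSet`.
#' @param annotations feature data.frame as from [build_genome()] (may be
#'   empty or NULL: all sites then take the background distribution).
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return data.frame: scaffold, pos (0-based), strand, context, true_level,
#'   flagged.
#' @export
assign_true_methylome <- function(genome, annotations, config,
                                  seed = config$seed + 1L) {
  set.seed(seed)
  out <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    sc <- names(genome)[k]
    ri <- as.integer(charToRaw(as.character(genome[[k]])))
    plus_pos <- which(ri == BYTE_C) - 1L
    minus_pos <- which(ri == BYTE_G) - 1L
    df <- data.frame(
      scaffold = sc,
      pos = c(plus_pos, minus_pos),
      strand = rep(c("+", "-"), c(length(plus_pos), length(minus_pos))))
    df$context <- c(.classify_raw_plus(ri, plus_pos),
                    .classify_raw_minus(ri, minus_pos))
    df <- df[order(df$pos), , drop = FALSE]
    out[[k]] <- df
  }
  meth <- do.call(rbind, out)
  rownames(meth) <- NULL

  in_te <- rep(FALSE, nrow(meth))
  if (!is.null(annotations) && NROW(annotations) > 0) {
    te <- annotations[annotations$kind %in% c("TE", "other_repeat"), ,
                      drop = FALSE]
    if (nrow(te)) {
      hits <- GenomicRanges::findOverlaps(.positions_granges(meth),
                                          .features_granges(te))
      in_te[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  is_cg <- meth$context == "CG"
  unknown <- meth$context == "unknown"

  lv <- numeric(nrow(meth))
  lv[in_te & is_cg] <- .draw_bimodal_high(sum(in_te & is_cg), config$cg_meth_te)
  lv[in_te & !is_cg] <- .draw_beta_mean(sum(in_te & !is_cg),
                                        config$noncg_meth_te, conc = 8)
  lv[!in_te & is_cg] <- .draw_beta_mean(sum(!in_te & is_cg),
                                        config$cg_meth_gene, conc = 30)
  lv[!in_te & !is_cg] <- .draw_beta_mean(sum(!in_te & !is_cg),
                                         config$noncg_meth_gene, conc = 30)
  lv[unknown] <- 0
  meth$true_level <- lv
  meth$flagged <- unknown
  meth
}

.draw_beta_mean <- function(n, m, conc) {
  if (n == 0) return(numeric())
  if (m <= 0) return(rep(0, n))
  if (m >= 1) return(rep(1, n))
  stats::rbeta(n, m * conc, (1 - m) * conc)
}

# Spike-and-slab mixture: a high component near 0.92 and a low component
# near 0.03, mixed so the overall mean equals `m` while keeping CG levels
# out of the (0.1, 0.8) mid-zone (bimodality).
.draw_bimodal_high <- function(n, m) {
  if (n == 0) return(numeric())
  mh <- 0.92; ml <- 0.03
  if (m <= ml) return(.draw_beta_mean(n, m, conc = 30))
  if (m >= mh) return(.draw_beta_mean(n, m, conc = 40))
  p_hi <- (m - ml) / (mh - ml)
  hi <- stats::runif(n) < p_hi
  out <- numeric(n)
  out[hi] <- .draw_beta_mean(sum(hi), mh, conc = 60)
  out[!hi] <- .draw_beta_mean(sum(!hi), ml, conc = 60)
  out
}

#' Simulate bisulfite-converted, pre-aligned reads
#'
#' Reads are drawn uniformly from both strands at `config$coverage` mean
#' depth per strand.  For each read, every cytosine on the originating
#' strand is methylated with probability equal to its true level;
#' unmethylated cytosines convert to T (observed as A on the plus-strand
#' projection of Crick reads) unless conversion fails with probability
#' `conversion_failure`; uniform substitution errors are applied at
#' `sequencing_error`.  Reads carry true coordinates, standing in for
#' aligner output.
#'
#' @param genome a `DNAStringSet`.
#' @param methylome data.frame from [assign_true_methylome()].
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @param id_prefix prefix for read identifiers.
#' @return data.frame: read_id, scaffold, start (0-based), strand
#'   (`+` = Watson, `-` = Crick origin), seq.
#' @export
simulate_bisulfite_reads <- function(genome, methylome, config,
                                     seed = config$seed + 2L,
                                     id_prefix = "read") {
  if (config$coverage <= 0) .stopf("'coverage' must be positive")
  set.seed(seed)
  rl <- config$read_length
  out <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    sc <- names(genome)[k]
    L <- Biostrings::width(genome)[k]
    if (rl > L) .stopf("read_length %d exceeds scaffold '%s' length %d",
                       rl, sc, L)
    m <- methylome[methylome$scaffold == sc, , drop = FALSE]
    lp <- rep(NA_real_, L); lm <- rep(NA_real_, L)
    ip <- m$strand == "+"
    lp[m$pos[ip] + 1L] <- m$true_level[ip]
    lm[m$pos[!ip] + 1L] <- m$true_level[!ip]
    n_per_strand <- max(1L, round(config$coverage * L / rl))
    starts <- sample.int(L - rl + 1L, 2L * n_per_strand, replace = TRUE) - 1L
    watson <- rep(c(TRUE, FALSE), each = n_per_strand)
    seqs <- cpp_simulate_reads(as.character(genome[[k]]), starts, watson,
                               lp, lm, rl, config$conversion_failure,
                               config$sequencing_error)
    out[[k]] <- data.frame(
      read_id = sprintf("%s_%s_%07d", id_prefix, sc, seq_along(starts)),
      scaffold = sc, start = starts,
      strand = ifelse(watson, "+", "-"), seq = seqs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate expression counts with TE methylation repression
#'
#' Counts are negative-binomial.  Gene means are methylation-independent
#' (log-normal rate per kb); TE means decrease log-linearly with the TE's
#' mean true CG methylation at slope `config$expr_meth_slope`, emulating
#' methylation-mediated transposon silencing.
#'
#' @param features feature data.frame from [build_genome()].
#' @param methylome data.frame from [assign_true_methylome()].
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed + 3`.
#' @return data.frame: id, kind, size, meth_cg, mu (expected count), count;
#'   attribute `total_count` holds the library total for RPKM.
#' @export
simulate_expression <- function(features, methylome, config,
                                seed = config$seed + 3L) {
  set.seed(seed)
  n <- nrow(features)
  meth_cg <- feature_true_methylation(features, methylome, context = "CG")
  is_gene <- features$kind == "gene"
  rate <- numeric(n)
  rate[is_gene] <- stats::rlnorm(sum(is_gene), log(config$expr_rate_kb), 1)
  rate[!is_gene] <- config$expr_rate_kb *
    exp(-config$expr_meth_slope * meth_cg[!is_gene])
  mu <- rate * (features$end - features$start) / 1000
  count <- stats::rnbinom(n, mu = mu, size = config$nb_dispersion)
  if (config$zero_inflation > 0)
    count[stats::runif(n) < config$zero_inflation] <- 0L
  out <- data.frame(id = features$id, kind = features$kind,
                    size = features$end - features$start,
                    meth_cg = meth_cg, mu = mu, count = count)
  attr(out, "total_count") <- sum(out$count)
  out
}

#' Mean true methylation of each feature in a given context
#'
#' Site-mean of `true_level` over the cytosines of the chosen context that
#' fall inside each feature; NA-free (features without eligible sites get
#' 0, reflecting an unmethylated region).
#' @param features feature data.frame.
#' @param methylome true methylome data.frame.
#' @param context one of "CG", "CHG", "CHH", or "nonCG".
#' @return numeric vector aligned with `features` rows.
#' @export
feature_true_methylation <- function(features, methylome, context = "CG") {
  keep <- if (context == "nonCG") methylome$context %in% c("CHG", "CHH")
          else methylome$context == context
  m <- methylome[keep, , drop = FALSE]
  out <- numeric(nrow(features))
  if (!nrow(m) || !nrow(features)) return(out)
  hits <- GenomicRanges::findOverlaps(.positions_granges(m),
                                      .features_granges(features))
  if (!length(hits)) return(out)
  sums <- tapply(m$true_level[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), mean)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Plant copy-number amplifications or deletions into one of two read sets
#'
#' Within each region, sample A's depth is multiplied by `fold`: for
#' `fold > 1` extra reads are drawn from the same bisulfite model over the
#' region; for `fold < 1` reads whose midpoint falls in the region are
#' thinned.  Sample B is untouched.  Returns the modified read sets plus a
#' truth table with the expected natural-log coverage ratio `ln(fold)`.
#'
#' @param reads_A,reads_B read data.frames from
#'   [simulate_bisulfite_reads()].
#' @param regions data.frame: scaffold, start, end (0-based half-open) and
#'   optionally fold; regions must not overlap.
#' @param fold per-region depth multiplier (recycled); ignored when
#'   `regions$fold` exists.  Must be > 0.
#' @param genome,methylome,config the generator state used to draw extra
#'   reads.
#' @param seed integer seed; defaults to `config$seed + 4`.
#' @return list with `reads_A`, `reads_B`, `truth` (scaffold, start, end,
#'   fold, expected_ln_ratio).
#' @export
plant_cnv <- function(reads_A, reads_B, regions, fold = 2,
                      genome = NULL, methylome = NULL, config = NULL,
                      seed = if (is.null(config)) 99L else config$seed + 4L) {
  if (is.null(regions$fold)) regions$fold <- rep(fold, length.out = nrow(regions))
  if (any(regions$fold <= 0)) .stopf("'fold' must be > 0")
  lens <- .scaffold_lengths(genome)
  for (sc in unique(regions$scaffold)) {
    rr <- regions[regions$scaffold == sc, , drop = FALSE]
    if (any(rr$start < 0) || any(rr$end > lens[[sc]]))
      .stopf("planted region outside scaffold '%s'", sc)
    ir <- IRanges::IRanges(rr$start + 1L, rr$end)
    if (sum(IRanges::width(IRanges::reduce(ir))) < sum(IRanges::width(ir)))
      .stopf("planted regions overlap on scaffold '%s'", sc)
  }
  set.seed(seed)
  rl <- config$read_length
  keep <- rep(TRUE, nrow(reads_A))
  extra <- list()
  mid <- reads_A$start + rl / 2
  for (i in seq_len(nrow(regions))) {
    sc <- regions$scaffold[i]; rs <- regions$start[i]; re <- regions$end[i]
    f <- regions$fold[i]
    in_reg <- reads_A$scaffold == sc & mid >= rs & mid < re
    n_in <- sum(in_reg)
    if (f < 1) {
      keep[in_reg] <- stats::runif(n_in) < f
    } else if (f > 1) {
      n_extra <- round((f - 1) * n_in)
      if (n_extra > 0) {
        lo <- max(0L, rs - round(rl / 2))
        hi <- min(lens[[sc]] - rl, re - round(rl / 2))
        starts <- lo + sample.int(hi - lo + 1L, n_extra, replace = TRUE) - 1L
        watson <- stats::runif(n_extra) < 0.5
        m <- methylome[methylome$scaffold == sc, , drop = FALSE]
        L <- lens[[sc]]
        lp <- rep(NA_real_, L); lm <- rep(NA_real_, L)
        ip <- m$strand == "+"
        lp[m$pos[ip] + 1L] <- m$true_level[ip]
        lm[m$pos[!ip] + 1L] <- m$true_level[!ip]
        seqs <- cpp_simulate_reads(.genome_char(genome, sc), starts, watson,
                                   lp, lm, rl, config$conversion_failure,
                                   config$sequencing_error)
        extra[[length(extra) + 1L]] <- data.frame(
          read_id = sprintf("cnv_%s_%d_%07d", sc, i, seq_len(n_extra)),
          scaffold = sc, start = starts,
          strand = ifelse(watson, "+", "-"), seq = seqs)
      }
    }
  }
  reads_A <- reads_A[keep, , drop = FALSE]
  if (length(extra)) reads_A <- rbind(reads_A, do.call(rbind, extra))
  rownames(reads_A) <- NULL
  truth <- data.frame(scaffold = regions$scaffold, start = regions$start,
                      end = regions$end, fold = regions$fold,
                      expected_ln_ratio = log(regions$fold))
  list(reads_A = reads_A, reads_B = reads_B, truth = truth)
}
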