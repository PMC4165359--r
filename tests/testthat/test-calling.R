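# Vote counting, level estimation and methylated-site calling.

test_that("single reads cast the expected strand-aware votes", {
  g <- toy_genome(chr = "AACGTT")
  # Watson read showing C over the plus-strand C at pos 2
  cnt <- tabulate_counts(toy_reads("chr", 0, "+", "AACGTT"), g)
  expect_equal(cnt[cnt$pos == 2 & cnt$strand == "+", c("n_meth", "n_unmeth")],
               data.frame(n_meth = 1L, n_unmeth = 0L),
               ignore_attr = TRUE)
  # Watson read showing T (converted)
  cnt <- tabulate_counts(toy_reads("chr", 0, "+", "AATGTT"), g)
  expect_equal(cnt$n_unmeth[cnt$pos == 2], 1L)
  expect_equal(cnt$n_meth[cnt$pos == 2], 0L)
  # Crick read showing A at the minus-strand C (plus-strand G, pos 3)
  cnt <- tabulate_counts(toy_reads("chr", 0, "-", "AACATT"), g)
  expect_equal(cnt[cnt$strand == "-", c("pos", "n_meth", "n_unmeth")],
               data.frame(pos = 3L, n_meth = 0L, n_unmeth = 1L),
               ignore_attr = TRUE)
  # Crick read keeping G = methylated
  cnt <- tabulate_counts(toy_reads("chr", 0, "-", "AACGTT"), g)
  expect_equal(cnt$n_meth[cnt$strand == "-"], 1L)
})

test_that("mismatched bases are ignored, not counted unmethylated", {
  g <- toy_genome(chr = "AACGTT")
  cnt <- tabulate_counts(toy_reads("chr", 0, "+", "AAGGTT"), g)  # G over C
  expect_false(any(cnt$strand == "+" & cnt$pos == 2))
  expect_equal(attr(cnt, "mismatch_bases"), 1)
})

test_that("reads overhanging the contig end are rejected with a count", {
  g <- toy_genome(chr = "AACGTT")
  rd <- toy_reads("chr", c(0, 4), c("+", "+"), c("AACGTT", "AACGTT"))
  expect_warning(cnt <- tabulate_counts(rd, g), "rejected")
  expect_equal(attr(cnt, "rejected_reads"), 1)
})

test_that("counts equal an independent pileup recount on simulated data", {
  w <- small_world()
  set.seed(1)
  rd <- simulate_bisulfite_reads(w$genome, w$methylome, w$config)
  rd <- rd[rd$scaffold == "scaffold_01", ][1:400, ]
  cnt <- tabulate_counts(rd, w$genome)
  # naive oracle: walk every read base in R
  `%||%` <- function(a, b) if (is.null(a)) b else a
  sq <- as.character(w$genome[["scaffold_01"]])
  ref <- strsplit(sq, "")[[1]]
  meth <- list(); unmeth <- list()
  for (i in seq_len(nrow(rd))) {
    obs <- strsplit(rd$seq[i], "")[[1]]
    for (j in seq_along(obs)) {
      p <- rd$start[i] + j - 1
      key <- paste0(p, rd$strand[i])
      if (rd$strand[i] == "+" && ref[p + 1] == "C") {
        if (obs[j] == "C") meth[[key]] <- (meth[[key]] %||% 0) + 1
        if (obs[j] == "T") unmeth[[key]] <- (unmeth[[key]] %||% 0) + 1
      }
      if (rd$strand[i] == "-" && ref[p + 1] == "G") {
        if (obs[j] == "G") meth[[key]] <- (meth[[key]] %||% 0) + 1
        if (obs[j] == "A") unmeth[[key]] <- (unmeth[[key]] %||% 0) + 1
      }
    }
  }
  key <- paste0(cnt$pos, cnt$strand)
  expect_equal(cnt$n_meth,
               vapply(key, function(k) meth[[k]] %||% 0, numeric(1),
                      USE.NAMES = FALSE))
  expect_equal(cnt$n_unmeth,
               vapply(key, function(k) unmeth[[k]] %||% 0, numeric(1),
                      USE.NAMES = FALSE))
  expect_equal(nrow(cnt), length(unique(c(names(meth), names(unmeth)))))
})

test_that("levels are #C/(#C+#T) with the minimum-coverage filter", {
  g <- toy_genome(chr = "AACGTT")
  cnt <- data.frame(scaffold = "chr", pos = 2L, strand = "+",
                    n_meth = 3L, n_unmeth = 1L)
  rec <- estimate_levels(cnt, g, min_coverage = 4)
  expect_equal(rec$level, 0.75)
  expect_equal(rec$context, "CG")
  # (2,1) excluded at the default threshold of 4 reads
  cnt2 <- data.frame(scaffold = "chr", pos = 2L, strand = "+",
                     n_meth = 2L, n_unmeth = 1L)
  expect_equal(nrow(estimate_levels(cnt2, g, min_coverage = 4)), 0L)
  # bounds
  cnt3 <- data.frame(scaffold = "chr", pos = c(2L, 3L), strand = c("+", "-"),
                     n_meth = c(0L, 10L), n_unmeth = c(10L, 0L))
  rec3 <- estimate_levels(cnt3, g, min_coverage = 4)
  expect_equal(rec3$level, c(0, 1))
  expect_error(estimate_levels(cnt, g, min_coverage = 0), "min_coverage")
})

test_that("methylated-site calling behaves at the extremes", {
  g <- toy_genome(chr = "AACGTT")
  rec <- data.frame(scaffold = "chr", pos = c(2L, 2L), strand = c("+", "+"),
                    context = "CG", n_meth = c(0L, 30L),
                    n_unmeth = c(30L, 0L), level = c(0, 1))
  out <- call_methylated_sites(rec, error_rate = 0.005, fdr = 0.05)
  expect_false(out$is_methylated[1])   # n_meth = 0 never called
  expect_true(out$is_methylated[2])    # (30, 0) overwhelmingly non-null
  expect_error(call_methylated_sites(rec, fdr = 1.5), "fdr")
  out2 <- call_methylated_sites(rec, method = "positive")
  expect_equal(out2$is_methylated, c(FALSE, TRUE))
})

test_that("false-positive rate of calling respects the FDR on null sites", {
  set.seed(7)
  n <- 4000; depth <- 30; err <- 0.005
  n_meth <- rbinom(n, depth, err)   # unmethylated sites, conversion failure
  rec <- data.frame(scaffold = "chr", pos = seq_len(n), strand = "+",
                    context = "CG", n_meth = n_meth,
                    n_unmeth = depth - n_meth, level = n_meth / depth)
  out <- call_methylated_sites(rec, error_rate = err, fdr = 0.05)
  expect_lt(mean(out$is_methylated), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("strand symmetry: reverse-complementing the world preserves levels", {
  w <- small_world()
  g1 <- w$genome["scaffold_01"]
  set.seed(5)
  rd <- simulate_bisulfite_reads(g1, w$methylome[
    w$methylome$scaffold == "scaffold_01", ], w$config)
  rd <- rd[sample.int(nrow(rd), 4000), ]
  rec1 <- call_methylation(rd, g1, min_coverage = 1)
  L <- Biostrings::width(g1)[1]
  g2 <- Biostrings::DNAStringSet(
    stats::setNames(as.character(Biostrings::reverseComplement(g1[[1]])),
                    "scaffold_01"))
  rd2 <- rd
  rd2$start <- L - (rd$start + nchar(rd$seq))
  rd2$strand <- ifelse(rd$strand == "+", "-", "+")
  rd2$seq <- vapply(rd$seq, function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
  rec2 <- call_methylation(rd2, g2, min_coverage = 1)
  # remap rec2 coordinates back
  rec2$pos <- as.integer(L) - 1L - rec2$pos
  rec2$strand <- ifelse(rec2$strand == "+", "-", "+")
  k1 <- paste(rec1$pos, rec1$strand)
  k2 <- paste(rec2$pos, rec2$strand)
  expect_setequal(k1, k2)
  m <- match(k1, k2)
  expect_equal(rec1$level, rec2$level[m])
  expect_equal(rec1$n_meth, rec2$n_meth[m])
})

test_that("bulk summary reports means, histograms and missing contexts", {
  rec <- rbind(toy_records(c(0, 10), c(0.2, 0.4), context = "CG"),
               toy_records(20, 0.5, context = "CHG"))
  s <- summarize_bulk(rec)
  expect_equal(unname(s$means["CG"]), 0.3)
  expect_equal(unname(s$means["CHG"]), 0.5)
  expect_true(is.na(s$means["CHH"]))
  expect_equal(sum(s$histograms$CG), 1)
  expect_null(s$histograms$CHH)
  # empty record set: everything missing
  s0 <- summarize_bulk(rec[0, ])
  expect_true(all(is.na(s0$means)))
  expect_true(is.na(s0$methylated_fraction))
  expect_error(summarize_bulk(rec, breaks = c(0, 0.5, 1)), "0.1")
})
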