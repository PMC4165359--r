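# Synthetic-data generator: layout, methylome, reads, expression, CNV
# planting.

test_that("generator is byte-deterministic for a fixed seed", {
  cfg <- sim_config(genome_length = 5e4, n_scaffolds = 1,
                    te_island_size = 5000, coverage = 3, seed = 9)
  d <- withr::local_tempdir()
  for (run in 1:2) {
    g <- build_genome(cfg)
    m <- assign_true_methylome(g$genome, g$features, cfg)
    rd <- simulate_bisulfite_reads(g$genome, m, cfg)
    write_genome_fasta(g$genome, file.path(d, sprintf("g%d.fa", run)))
    write_annotations_gff3(g$features, g$exons,
                           file.path(d, sprintf("a%d.gff3", run)))
    write_reads(rd, file.path(d, sprintf("r%d.tsv", run)))
  }
  for (f in c("g", "a", "r")) {
    md5 <- tools::md5sum(file.path(d, sprintf("%s%d.%s", f, 1:2,
                                              switch(f, g = "fa",
                                                     a = "gff3",
                                                     r = "tsv"))))
    expect_equal(unname(md5[1]), unname(md5[2]))
  }
})

test_that("TE occupancy tracks the configured fraction and config is validated", {
  cfg <- sim_config(genome_length = 1e6, n_scaffolds = 2, seed = 1)
  g <- build_genome(cfg)
  occ <- sum(g$features$size[g$features$kind == "TE"]) /
    sum(Biostrings::width(g$genome))
  expect_lt(abs(occ - 0.58), 0.05)
  # genes never overlap TEs
  te <- g$features[g$features$kind == "TE", ]
  gn <- g$features[g$features$kind == "gene", ]
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(te$scaffold,
                           IRanges::IRanges(te$start + 1, te$end)),
    GenomicRanges::GRanges(gn$scaffold,
                           IRanges::IRanges(gn$start + 1, gn$end)))
  expect_equal(length(ov), 0L)
  # zero TE fraction: no TE features at all
  g0 <- build_genome(sim_config(genome_length = 5e4, n_scaffolds = 1,
                                te_fraction = 0, te_island_size = 5000,
                                seed = 2))
  expect_equal(sum(g0$features$kind == "TE"), 0L)
  # validation errors name the offending field
  expect_error(sim_config(te_fraction = 1.2), "te_fraction")
  expect_error(sim_config(genome_length = 5e4, te_island_size = 4e4),
               "te_island_size")
  expect_error(sim_config(te_subclass_weights = c(Gypsy = 0.5)),
               "te_subclass_weights")
})

test_that("true methylome matches configured means and is bimodal at CG", {
  w <- small_world()
  m <- w$methylome
  te <- w$features[w$features$kind == "TE", ]
  in_te <- rep(FALSE, nrow(m))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(m$scaffold, IRanges::IRanges(m$pos + 1, m$pos + 1)),
    GenomicRanges::GRanges(te$scaffold, IRanges::IRanges(te$start + 1, te$end)))
  in_te[S4Vectors::queryHits(hits)] <- TRUE
  gene_cg <- m$true_level[!in_te & m$context == "CG"]
  te_cg <- m$true_level[in_te & m$context == "CG"]
  expect_gt(length(gene_cg), 1e4)
  expect_lt(abs(mean(gene_cg) - w$config$cg_meth_gene), 0.005)
  expect_lt(abs(mean(te_cg) - w$config$cg_meth_te), 0.02)
  # bimodality: CG mass inside (0.1, 0.8) below mass outside
  cg <- m$true_level[m$context == "CG"]
  expect_lt(mean(cg > 0.1 & cg < 0.8), mean(cg <= 0.1 | cg >= 0.8))
  # every genomic cytosine has exactly one entry
  chars <- strsplit(as.character(w$genome[["scaffold_01"]]), "")[[1]]
  expect_equal(sum(m$scaffold == "scaffold_01"),
               sum(chars %in% c("C", "G")))
  expect_false(any(duplicated(paste(m$scaffold, m$pos))))
  # empty annotations: everything background
  cfg <- sim_config(genome_length = 2e4, n_scaffolds = 1,
                    te_island_size = 2000, seed = 3)
  g <- build_genome(cfg)
  m0 <- assign_true_methylome(g$genome, NULL, cfg)
  expect_lt(mean(m0$true_level[m0$context == "CG"]), 0.05)
})

test_that("read conversion follows true levels and the conversion model", {
  g <- toy_genome(chr = paste(rep("ACGTT", 12), collapse = ""))
  cfg <- sim_config(genome_length = 1e4, n_scaffolds = 1,
                    te_island_size = 1000, read_length = 30,
                    conversion_failure = 0, sequencing_error = 0, seed = 4)
  m <- assign_true_methylome(g, NULL, cfg)
  # fully methylated: every read base over a C site stays C
  m1 <- m; m1$true_level <- 1
  set.seed(1)
  rd <- simulate_bisulfite_reads(g, m1, cfg)
  cnt <- tabulate_counts(rd, g)
  expect_true(all(cnt$n_unmeth == 0))
  # fully unmethylated: everything converts
  m0 <- m; m0$true_level <- 0
  set.seed(1)
  rd0 <- simulate_bisulfite_reads(g, m0, cfg)
  cnt0 <- tabulate_counts(rd0, g)
  expect_true(all(cnt0$n_meth == 0))
  expect_error(simulate_bisulfite_reads(
    g, m, sim_config(genome_length = 1e4, n_scaffolds = 1,
                     te_island_size = 1000, read_length = 100, seed = 1)),
    "read_length")
})

test_that("site-level C fraction converges to level + (1-level)*failure", {
  # one genome position observed at depth ~1e4
  g <- toy_genome(chr = paste0(strrep("A", 25), "C", strrep("A", 24)))
  cfg <- sim_config(genome_length = 1e4, n_scaffolds = 1,
                    te_island_size = 1000, read_length = 25,
                    coverage = 5000, conversion_failure = 0.03,
                    sequencing_error = 0, seed = 8)
  m <- data.frame(scaffold = "chr", pos = 25L, strand = "+",
                  context = "CHH", true_level = 0.3, flagged = FALSE)
  set.seed(2)
  rd <- simulate_bisulfite_reads(g, m, cfg)
  cnt <- tabulate_counts(rd, g)
  site <- cnt[cnt$pos == 25 & cnt$strand == "+", ]
  depth <- site$n_meth + site$n_unmeth
  expect_gt(depth, 4000)
  apparent <- 0.3 + 0.7 * 0.03
  expect_lt(abs(site$n_meth / depth - apparent),
            3 * sqrt(apparent * (1 - apparent) / depth))
  # depth conservation: total bases ~ 2 * coverage * genome length
  expect_lt(abs(sum(nchar(rd$seq)) / (2 * 5000 * 50) - 1), 0.1)
})

test_that("expression means decrease with TE methylation", {
  w <- small_world()
  expr <- simulate_expression(w$features, w$methylome, w$config)
  # monotone mean function: expected count strictly smaller when methylated
  f2 <- w$features[w$features$kind == "TE", ][1:2, ]
  f2$end <- f2$start + 1000L  # same size
  mm <- rbind(
    data.frame(scaffold = f2$scaffold[1], pos = f2$start[1] + 1L,
               strand = "+", context = "CG", true_level = 0.9,
               flagged = FALSE),
    data.frame(scaffold = f2$scaffold[2], pos = f2$start[2] + 1L,
               strand = "+", context = "CG", true_level = 0.0,
               flagged = FALSE))
  e2 <- simulate_expression(f2, mm, w$config)
  expect_lt(e2$mu[1], e2$mu[2])
  # zero inflation 1 silences everything
  cfgz <- w$config; cfgz$zero_inflation <- 1
  ez <- simulate_expression(w$features, w$methylome, cfgz)
  expect_true(all(ez$count == 0))
  # negative methylation-expression correlation at scale
  set.seed(11)
  n <- 1000
  fts <- data.frame(id = sprintf("t%d", 1:n), scaffold = "chr",
                    start = (0:(n - 1)) * 2000L,
                    end = (0:(n - 1)) * 2000L + 1000L, strand = "+",
                    kind = "TE", te_class = "Gypsy", size = 1000L)
  mth <- data.frame(scaffold = "chr", pos = fts$start + 10L, strand = "+",
                    context = "CG", true_level = runif(n), flagged = FALSE)
  ee <- simulate_expression(fts, mth, w$config)
  expect_lt(suppressWarnings(
    cor(ee$meth_cg, ee$count, method = "spearman")), 0)
})

test_that("plant_cnv changes depth by the requested fold", {
  cfg <- sim_config(genome_length = 2e5, n_scaffolds = 1,
                    te_island_size = 2000, te_fraction = 0.1,
                    coverage = 10, seed = 21)
  g <- build_genome(cfg)
  m <- assign_true_methylome(g$genome, g$features, cfg)
  ra <- simulate_bisulfite_reads(g$genome, m, cfg, seed = 31)
  rb <- simulate_bisulfite_reads(g$genome, m, cfg, seed = 32)
  reg <- data.frame(scaffold = "scaffold_01", start = 50000, end = 150000)
  depth_in <- function(reads) {
    mid <- reads$start + nchar(reads$seq) / 2
    sum(reads$scaffold == "scaffold_01" & mid >= 50000 & mid < 150000)
  }
  base_n <- depth_in(ra)
  pl2 <- plant_cnv(ra, rb, reg, fold = 2, genome = g$genome, methylome = m,
                   config = cfg, seed = 41)
  expect_lt(abs(depth_in(pl2$reads_A) / base_n - 2), 0.1)
  expect_equal(pl2$truth$expected_ln_ratio, log(2))
  pl1 <- plant_cnv(ra, rb, reg, fold = 1, genome = g$genome, methylome = m,
                   config = cfg, seed = 41)
  expect_identical(pl1$reads_A, ra)
  expect_equal(pl1$truth$expected_ln_ratio, 0)
  ph <- plant_cnv(ra, rb, reg, fold = 0.5, genome = g$genome, methylome = m,
                  config = cfg, seed = 41)
  expect_lt(abs(depth_in(ph$reads_A) / base_n - 0.5), 0.1)
  # overlapping planted regions rejected
  reg2 <- data.frame(scaffold = "scaffold_01",
                     start = c(10000, 40000), end = c(60000, 80000))
  expect_error(plant_cnv(ra, rb, reg2, fold = 2, genome = g$genome,
                         methylome = m, config = cfg), "overlap")
})
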