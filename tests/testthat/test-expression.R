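# RPKM quantification and methylation-expression association.

test_that("RPKM closed form, thresholds and union-exon lengths", {
  f <- data.frame(id = "g1", scaffold = "chr", start = 0L, end = 1000L,
                  strand = "+", kind = "gene", te_class = NA_character_,
                  size = 1000L)
  cnts <- data.frame(id = "g1", count = 10L)
  rec <- compute_rpkm(cnts, f, total_mapped = 1e6)
  expect_equal(rec$rpkm, 10)
  expect_true(rec$expressed)
  # zero reads
  rec0 <- compute_rpkm(data.frame(id = "g1", count = 0L), f,
                       total_mapped = 1e6)
  expect_equal(rec0$rpkm, 0)
  expect_false(rec0$expressed)
  # overlapping exons [0,100) + [50,150): union is 150, not 200
  ex <- data.frame(id = c("e1", "e2"), gene_id = "g1", scaffold = "chr",
                   start = c(0L, 50L), end = c(100L, 150L), strand = "+")
  expect_equal(unname(union_exon_length(ex)), 150)
  # independent interval-union oracle over random exon sets
  set.seed(19)
  for (i in 1:20) {
    st <- sample.int(500, 8); en <- st + sample.int(80, 8)
    exr <- data.frame(id = sprintf("e%d", 1:8), gene_id = "g",
                      scaffold = "chr", start = st, end = en, strand = "+")
    covered <- logical(1000)
    for (j in 1:8) covered[(st[j] + 1):en[j]] <- TRUE
    expect_equal(unname(union_exon_length(exr)), sum(covered))
  }
  rec_u <- compute_rpkm(cnts, f, exons = ex, total_mapped = 1e6)
  expect_equal(rec_u$rpkm, 10 * 1000 / 150)
  # zero-length feature is an error naming the feature
  fz <- f; fz$end <- 0L
  expect_error(compute_rpkm(cnts, fz, total_mapped = 1e6), "g1")
  expect_error(compute_rpkm(cnts, f, total_mapped = 0), "total_mapped")
})

test_that("RPKM is invariant under deterministic halving", {
  f <- data.frame(id = c("a", "b"), scaffold = "chr", start = c(0L, 2000L),
                  end = c(1000L, 4000L), strand = "+", kind = "TE",
                  te_class = "Gypsy", size = c(1000L, 2000L))
  cnts <- data.frame(id = c("a", "b"), count = c(40L, 60L))
  r1 <- compute_rpkm(cnts, f, total_mapped = 1e6)
  cnts2 <- cnts; cnts2$count <- cnts2$count / 2
  r2 <- compute_rpkm(cnts2, f, total_mapped = 5e5)
  expect_equal(r1$rpkm, r2$rpkm)
})

test_that("association recovers a planted negative effect", {
  set.seed(20)
  n <- 300
  te <- data.frame(id = sprintf("t%d", 1:n), scaffold = "chr",
                   start = (0:(n - 1)) * 2000L,
                   end = (0:(n - 1)) * 2000L + 1000L, strand = "+",
                   kind = "TE",
                   te_class = sample(c("Gypsy", "LINE"), n, TRUE),
                   size = 1000L)
  meth <- runif(n)
  fm <- data.frame(id = te$id, kind = "TE", level_CG = meth,
                   n_sites_CG = 20L)
  counts <- data.frame(id = te$id,
                       count = rnbinom(n, mu = 200 * exp(-3 * meth),
                                       size = 2))
  expr <- compute_rpkm(counts, te, total_mapped = 1e6)
  assoc <- methylation_expression_association(fm, expr, te)
  expect_lt(assoc$correlation$rho, 0)
  expect_lt(assoc$correlation$p, 0.01)
  expect_equal(sum(assoc$subclass_table$n), n)
  expect_true(all(assoc$subclass_table$n_expressed <=
                    assoc$subclass_table$n))
  # single subclass: one row, consistent percentages
  te1 <- te; te1$te_class <- "Gypsy"
  a1 <- methylation_expression_association(fm, expr, te1)
  expect_equal(nrow(a1$subclass_table), 1L)
})

test_that("between-sample tests are well calibrated under the null", {
  set.seed(21)
  n <- 200
  te <- data.frame(id = sprintf("t%d", 1:n), scaffold = "chr",
                   start = (0:(n - 1)) * 2000L,
                   end = (0:(n - 1)) * 2000L + 1000L, strand = "+",
                   kind = "TE", te_class = "Gypsy", size = 1000L)
  fm <- data.frame(id = te$id, kind = "TE", level_CG = runif(n),
                   n_sites_CG = 20L)
  reject <- 0; n_rep <- 50
  for (i in seq_len(n_rep)) {
    ca <- data.frame(id = te$id, count = rnbinom(n, mu = 50, size = 2))
    cb <- data.frame(id = te$id, count = rnbinom(n, mu = 50, size = 2))
    ea <- compute_rpkm(ca, te, total_mapped = 1e5)
    eb <- compute_rpkm(cb, te, total_mapped = 1e5)
    a <- methylation_expression_association(fm, ea, te, expression_B = eb)
    if (!is.null(a$sample_tests) && a$sample_tests$p[1] < 0.05)
      reject <- reject + 1
  }
  expect_lt(reject / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("treatment response bins separate responders from the rest", {
  set.seed(22)
  n <- 120
  ids <- sprintf("t%d", 1:n)
  responder <- rep(c(TRUE, FALSE), each = n / 2)
  meth_A <- data.frame(id = ids, kind = "TE",
                       level_CHH = runif(n, 0.25, 0.35))
  meth_B <- meth_A
  meth_B$level_CHH <- meth_A$level_CHH - ifelse(responder,
                                                runif(n, 0.10, 0.20),
                                                runif(n, 0, 0.02))
  rpkm_A <- rlnorm(n, log(5), 0.3)
  expr_A <- data.frame(id = ids, rpkm = rpkm_A)
  expr_B <- data.frame(id = ids,
                       rpkm = rpkm_A * ifelse(responder, 2, 1) *
                         rlnorm(n, 0, 0.2))
  rb <- treatment_response_bins(meth_A, meth_B, expr_A, expr_B,
                                context = "CHH", delta_cut = 0.05)
  hi <- rb$bins[rb$bins$bin == "(0.05,Inf]", ]
  lo <- rb$bins[rb$bins$bin == "(-Inf,0.05]", ]
  expect_equal(hi$n + lo$n, n)
  expect_gt(hi$mean_log2_fc, lo$mean_log2_fc)
  expect_lt(rb$tests$p, 0.05)
  expect_gt(rb$tests$t, 0)
})

test_that("treatment response degenerate cases", {
  ids <- c("a", "b", "c")
  ma <- data.frame(id = ids, kind = "TE", level_CHH = c(0.3, 0.3, 0.3))
  ea <- data.frame(id = ids, rpkm = c(0, 1, 2))
  # identical conditions: all deltas zero, one populated bin, no test
  rb <- treatment_response_bins(ma, ma, ea, ea)
  expect_true(all(rb$per_te$delta == 0))
  expect_equal(sum(rb$bins$n > 0), 1L)
  expect_null(rb$tests)
  # both RPKM zero: fold-change 0 for any positive pseudocount
  ez <- data.frame(id = ids, rpkm = 0)
  rb2 <- treatment_response_bins(ma, ma, ez, ez, pseudocount = 0.1)
  expect_true(all(rb2$per_te$log2_fc == 0))
  expect_error(treatment_response_bins(ma, ma, ea, ea, pseudocount = 0),
               "pseudocount")
  expect_error(treatment_response_bins(ma, ma, ea, ea, context = "CG"),
               "level_CG")
})
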