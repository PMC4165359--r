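# Feature-level methylation, meta-plots, proximity profiles and size
# strata.

feat <- function(id, start, end, strand = "+", kind = "TE",
                 te_class = "Gypsy", scaffold = "chr") {
  data.frame(id = id, scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             te_class = ifelse(kind == "gene", NA_character_, te_class),
             size = as.integer(end - start))
}

test_that("feature methylation: site-mean and read-weighted arithmetic", {
  f <- feat("te1", 0, 100)
  rec <- toy_records(c(10, 20), c(0.8, 0.6))
  fm <- feature_methylation(rec, f)
  expect_equal(fm$level_CG, 0.7)
  expect_equal(fm$n_sites_CG, 2L)
  # read-weighted: (4,0) and (1,4) pool to 5/9
  rec2 <- data.frame(scaffold = "chr", pos = c(10L, 20L), strand = "+",
                     context = "CG", n_meth = c(4L, 1L),
                     n_unmeth = c(0L, 4L), level = c(1, 0.2))
  fw <- feature_methylation(rec2, f, mode = "read-weighted")
  expect_equal(fw$level_CG, 5 / 9)
  # single covered site: site-mean equals that site's level exactly
  fm1 <- feature_methylation(toy_records(50, 0.3), f)
  expect_equal(fm1$level_CG, 0.3)
  # no eligible sites: missing, not zero
  expect_true(is.na(feature_methylation(rec[0, ], f)$level_CG))
})

test_that("TE feature methylation recovers the configured mean on simulation", {
  w <- small_world()
  set.seed(3)
  rd <- simulate_bisulfite_reads(w$genome, w$methylome, w$config)
  rec <- call_methylation(rd, w$genome)
  te <- w$features[w$features$kind == "TE", ]
  fm <- feature_methylation(rec, te)
  truth <- feature_true_methylation(te, w$methylome, "CG")
  ok <- !is.na(fm$level_CG) & fm$n_sites_CG >= 10
  expect_gt(sum(ok), 10)
  expect_lt(abs(mean(fm$level_CG[ok] - truth[ok])), 0.02)
})

test_that("metaplot: uniform levels give flat body, minus strand mirrors", {
  f <- feat("te1", 1000, 2000)
  rec <- toy_records(seq(1000, 1995, by = 5), 0.5)
  mp <- metaplot(rec, f, flank = 500, body_bins = 10, flank_bins = 5)
  body <- mp[mp$region == "body" & mp$context == "CG", ]
  expect_equal(body$mean_level, rep(0.5, 10))
  # graded profile reverses on the minus strand
  lv <- seq(0.1, 0.9, length.out = 200)
  rec2 <- toy_records(seq(1000, 1995, by = 5), lv)
  mp_p <- metaplot(rec2, f, flank = 0, body_bins = 10, flank_bins = 0)
  f_m <- f; f_m$strand <- "-"
  mp_m <- metaplot(rec2, f_m, flank = 0, body_bins = 10, flank_bins = 0)
  sel <- function(mp) mp$region == "body" & mp$context == "CG"
  expect_equal(mp_m$mean_level[sel(mp_m)],
               rev(mp_p$mean_level[sel(mp_p)]), tolerance = 1e-9)
  # invariance to feature ordering
  f2 <- rbind(feat("a", 1000, 2000), feat("b", 3000, 3500))
  mp1 <- metaplot(rec, f2, flank = 100, body_bins = 5, flank_bins = 2)
  mp2 <- metaplot(rec, f2[2:1, ], flank = 100, body_bins = 5, flank_bins = 2)
  expect_equal(mp1, mp2)
})

test_that("metaplot separates a methylated body from unmethylated flanks", {
  f <- feat("te1", 1000, 3000)
  inside <- toy_records(seq(1000, 2995, by = 10), 0.8)
  out_up <- toy_records(seq(200, 995, by = 10), 0.05)
  out_dn <- toy_records(seq(3000, 3795, by = 10), 0.05)
  mp <- metaplot(rbind(inside, out_up, out_dn), f, flank = 800,
                 body_bins = 10, flank_bins = 4)
  cg <- mp[mp$context == "CG", ]
  expect_gt(min(cg$mean_level[cg$region == "body"]),
            max(cg$mean_level[cg$region != "body"]))
  # short feature: sites spread over all bins by proportional overlap
  fs <- feat("s", 100, 104)
  rs <- toy_records(c(100, 101, 102, 103), 0.4)
  mps <- metaplot(rs, fs, flank = 0, body_bins = 8, flank_bins = 0)
  expect_equal(mps$mean_level[mps$region == "body" & mps$context == "CG"],
               rep(0.4, 8))
})

test_that("proximity profile recovers a planted distance effect", {
  set.seed(13)
  n_genes <- 40
  gene_pos <- seq(0, by = 20000, length.out = n_genes)
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(i)
    feat(sprintf("g%d", i), gene_pos[i], gene_pos[i] + 2000,
         kind = "gene")))
  # one TE 200 bp downstream of each gene
  tes <- do.call(rbind, lapply(seq_len(n_genes), function(i)
    feat(sprintf("t%d", i), gene_pos[i] + 2200, gene_pos[i] + 2800)))
  rpkm <- c(rep(100, n_genes / 2), rep(0.5, n_genes / 2))
  expr <- data.frame(id = genes$id, rpkm = rpkm)
  # TEs near high-expression genes are hypomethylated by 0.2
  rec <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    m <- if (i <= n_genes / 2) 0.6 else 0.8
    sampled_records(seq(tes$start[i], tes$end[i] - 1, by = 30), m,
                    depth = 30)
  }))
  pr <- proximity_profile(tes, genes, expr, rec, max_dist = 1000)
  expect_false(is.null(pr$tests))
  st <- pr$tests[pr$tests$stratum == "<=0.5kb", ]
  expect_lt(st$mean_high, st$mean_low)
  expect_lt(st$p, 0.05)
  # t statistic equals a direct Welch computation on the site table
  hi <- pr$sites$level[pr$sites$class == "high" &
                         abs(pr$sites$distance) < 500]
  lo <- pr$sites$level[pr$sites$class == "low" &
                         abs(pr$sites$distance) < 500]
  tt <- t.test(hi, lo)
  expect_equal(st$t, unname(tt$statistic))
  expect_equal(st$p, tt$p.value)
})

test_that("proximity profile handles degenerate inputs", {
  genes <- rbind(feat("g1", 0, 2000, kind = "gene"),
                 feat("g2", 50000, 52000, kind = "gene"),
                 feat("g3", 100000, 102000, kind = "gene"),
                 feat("g4", 150000, 152000, kind = "gene"))
  expr <- data.frame(id = genes$id, rpkm = c(100, 50, 10, 1))
  tes <- feat("t1", 500000, 501000)  # far from every gene
  rec <- toy_records(seq(500000, 500990, by = 10), 0.5)
  pr <- proximity_profile(tes, genes, expr, rec)
  expect_equal(nrow(pr$profile), 0L)
  expect_null(pr$tests)
})

test_that("size strata count expression and methylation correctly", {
  tes <- rbind(feat("t1", 0, 1000), feat("t2", 2000, 4000),
               feat("t3", 5000, 8000))
  fm <- data.frame(id = tes$id, kind = "TE",
                   level_CG = c(0.2, 0.8, 0.9), n_sites_CG = 10L)
  expr <- data.frame(id = tes$id, rpkm = c(5, 0.2, 0))
  tab <- size_stratified_summary(fm, tes, expr, size_cut = 1500)
  small <- tab[tab$stratum == "<=1500bp", ]
  large <- tab[tab$stratum == ">1500bp", ]
  expect_equal(small$n, 1L); expect_equal(large$n, 2L)
  expect_equal(small$expressed_fraction, 1)
  expect_equal(large$expressed_fraction, 0)
  # all same size: a single stratum
  tes2 <- rbind(feat("t1", 0, 100), feat("t2", 200, 300))
  fm2 <- fm[1:2, ]; fm2$id <- tes2$id
  tab2 <- size_stratified_summary(fm2, tes2, expr[1:2, ])
  expect_equal(nrow(tab2), 1L)
  # infinite cutoff: nothing is expressed
  tab3 <- size_stratified_summary(fm, tes, expr, rpkm_cut = Inf)
  expect_true(all(tab3$expressed_fraction == 0))
})
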