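# End-to-end pipeline driver: simulate (or load) inputs, run every
# analysis stage in order, write all tables/tracks, and emit a
# machine-readable JSON run report.  Reruns with the same configuration
# are byte-identical.

#' Build and validate a pipeline configuration
#'
#' Either provide input paths (`genome_path`, `annotation_path`,
#' `reads_A_path`, `reads_B_path`, optionally `counts_A_path` /
#' `counts_B_path`) or leave them NULL to have the pipeline simulate its
#' inputs from `sim` (a [sim_config()]).  Stage parameters carry the
#' module defaults: >= 4 reads per cytosine, z threshold 1.96 with
#' 20\%/10\% mean-difference cuts, 100-kb CNV windows at |ln ratio| 0.3,
#' RPKM >= 1 expressed threshold, 5-percentage-point response binning.
#'
#' @param out_dir output directory (created if missing).
#' @param sim a [sim_config()] used when no input paths are given.
#' @param genome_path,annotation_path,reads_A_path,reads_B_path,counts_A_path,counts_B_path
#'   optional input files.
#' @param min_coverage,error_rate,fdr,z_threshold,min_mean_diff,window_size,cnv_threshold,rpkm_threshold,delta_cut,flank,body_bins,cri_window
#'   stage parameters; see the stage functions.
#' @param cnv_plant optional data.frame (scaffold, start, end, fold) of
#'   amplifications planted into simulated sample A.
#' @param seed master seed for the run; defaults to `sim$seed`.
#' @return validated list of class `fm_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            genome_path = NULL, annotation_path = NULL,
                            reads_A_path = NULL, reads_B_path = NULL,
                            counts_A_path = NULL, counts_B_path = NULL,
                            min_coverage = 4, error_rate = 0.005,
                            fdr = 0.05, z_threshold = 1.96,
                            min_mean_diff = c(TE = 0.20, gene = 0.10),
                            window_size = 100000, cnv_threshold = 0.3,
                            rpkm_threshold = 1, delta_cut = 0.05,
                            flank = 1000, body_bins = 20,
                            cri_window = 1000,
                            cnv_plant = NULL,
                            seed = sim$seed) {
  .check_count(min_coverage, "min_coverage", 1)
  .check_fraction(error_rate, "error_rate")
  .check_fraction(fdr, "fdr")
  if (z_threshold <= 0) .stopf("'z_threshold' must be > 0")
  if (window_size <= 0) .stopf("'window_size' must be > 0")
  if (cnv_threshold <= 0) .stopf("'cnv_threshold' must be > 0")
  cfg <- list(out_dir = out_dir, sim = sim,
              genome_path = genome_path, annotation_path = annotation_path,
              reads_A_path = reads_A_path, reads_B_path = reads_B_path,
              counts_A_path = counts_A_path, counts_B_path = counts_B_path,
              min_coverage = min_coverage, error_rate = error_rate,
              fdr = fdr, z_threshold = z_threshold,
              min_mean_diff = min_mean_diff, window_size = window_size,
              cnv_threshold = cnv_threshold,
              rpkm_threshold = rpkm_threshold, delta_cut = delta_cut,
              flank = flank, body_bins = body_bins,
              cri_window = cri_window, cnv_plant = cnv_plant,
              seed = as.integer(seed))
  class(cfg) <- "fm_pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `sim:` holds
#' [sim_config()] fields.  Values given in the file override defaults;
#' arguments passed here override the file.
#'
#' @param path YAML file.
#' @param ... overrides forwarded to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$te_subclass_weights))
    sim_args$te_subclass_weights <- unlist(sim_args$te_subclass_weights)
  y$sim <- do.call(sim_config, sim_args)
  if (!is.null(y$min_mean_diff)) y$min_mean_diff <- unlist(y$min_mean_diff)
  if (!is.null(y$cnv_plant)) y$cnv_plant <- as.data.frame(y$cnv_plant)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate/load inputs, methylation calling (both samples),
#' feature analysis, differential methylation, CNV, RIP index,
#' expression association.  Every stage writes its tables under
#' `config$out_dir`, and `report.json` records parameters, the seed,
#' input checksums and per-stage row counts.  A rerun with the same
#' configuration and inputs is byte-identical.  A stage failure aborts
#' the run naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage log lines on stderr.
#' @return invisibly, a list with the in-memory stage results plus
#'   `report`.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(stage, msg)
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  run_stage <- function(stage, expr) {
    say(stage, "start")
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  for (p in c(config$genome_path, config$annotation_path,
              config$reads_A_path, config$reads_B_path,
              config$counts_A_path, config$counts_B_path))
    if (!is.null(p) && !file.exists(p))
      .stopf("input path '%s' does not exist", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  rows <- list()
  checksums <- list()

  ## ---- inputs: simulate or load -------------------------------------
  sim <- config$sim
  simulate_inputs <- is.null(config$genome_path)
  inp <- run_stage("simulate", {
    if (simulate_inputs) {
      gen <- build_genome(sim, seed = config$seed)
      meth <- assign_true_methylome(gen$genome, gen$features, sim,
                                    seed = config$seed + 1L)
      reads_A <- simulate_bisulfite_reads(gen$genome, meth, sim,
                                          seed = config$seed + 2L,
                                          id_prefix = "A")
      reads_B <- simulate_bisulfite_reads(gen$genome, meth, sim,
                                          seed = config$seed + 3L,
                                          id_prefix = "B")
      truth <- NULL
      if (!is.null(config$cnv_plant) && nrow(config$cnv_plant)) {
        pl <- plant_cnv(reads_A, reads_B, config$cnv_plant,
                        genome = gen$genome, methylome = meth, config = sim,
                        seed = config$seed + 4L)
        reads_A <- pl$reads_A; truth <- pl$truth
      }
      counts_A <- simulate_expression(gen$features, meth, sim,
                                      seed = config$seed + 5L)
      counts_B <- simulate_expression(gen$features, meth, sim,
                                      seed = config$seed + 6L)
      write_genome_fasta(gen$genome, out("genome.fa"))
      write_annotations_gff3(gen$features, gen$exons, out("annotations.gff3"))
      write_reads(reads_A, out("reads_A.sam"), genome = gen$genome)
      write_reads(reads_B, out("reads_B.sam"), genome = gen$genome)
      .write_tsv(counts_A[, c("id", "count")], out("counts_A.tsv"))
      .write_tsv(counts_B[, c("id", "count")], out("counts_B.tsv"))
      .write_tsv(meth, out("true_methylome.tsv"))
      if (!is.null(truth)) .write_tsv(truth, out("cnv_truth.tsv"))
      list(genome = gen$genome, features = gen$features, exons = gen$exons,
           reads_A = reads_A, reads_B = reads_B,
           counts_A = counts_A[, c("id", "count")],
           counts_B = counts_B[, c("id", "count")])
    } else {
      ann <- load_annotations(config$annotation_path)
      list(genome = read_genome_fasta(config$genome_path),
           features = ann$features, exons = ann$exons,
           reads_A = read_reads(config$reads_A_path),
           reads_B = read_reads(config$reads_B_path),
           counts_A = if (!is.null(config$counts_A_path))
             utils::read.table(config$counts_A_path, header = TRUE,
                               sep = "\t") else NULL,
           counts_B = if (!is.null(config$counts_B_path))
             utils::read.table(config$counts_B_path, header = TRUE,
                               sep = "\t") else NULL)
    }
  })
  for (f in c("genome.fa", "annotations.gff3"))
    if (file.exists(out(f))) checksums[[f]] <- unname(tools::md5sum(out(f)))
  rows$features <- nrow(inp$features)
  rows$reads_A <- nrow(inp$reads_A); rows$reads_B <- nrow(inp$reads_B)

  ## ---- methylation calling ------------------------------------------
  calls <- run_stage("call", {
    lapply(stats::setNames(c("A", "B"), c("A", "B")), function(s) {
      rec <- call_methylation(inp[[paste0("reads_", s)]], inp$genome,
                              min_coverage = config$min_coverage)
      rec <- call_methylated_sites(rec, error_rate = config$error_rate,
                                   fdr = config$fdr)
      write_methylome_track(rec, out(sprintf("methylome_%s.tsv", s)),
                            bedgraph = TRUE)
      rec
    })
  })
  rows$sites_A <- nrow(calls$A); rows$sites_B <- nrow(calls$B)

  ## ---- feature analysis ---------------------------------------------
  feats <- run_stage("features", {
    fm <- lapply(calls, feature_methylation, features = inp$features)
    .write_tsv(fm$A, out("feature_methylation_A.tsv"))
    .write_tsv(fm$B, out("feature_methylation_B.tsv"))
    te <- inp$features[inp$features$kind == "TE", , drop = FALSE]
    genes <- inp$features[inp$features$kind == "gene", , drop = FALSE]
    mp <- rbind(
      cbind(feature_kind = "gene",
            metaplot(calls$A, genes, flank = config$flank,
                     body_bins = config$body_bins)),
      cbind(feature_kind = "TE",
            metaplot(calls$A, te, flank = config$flank,
                     body_bins = config$body_bins)))
    .write_tsv(mp, out("metaplot_A.tsv"))
    list(fm = fm, metaplot = mp, te = te, genes = genes)
  })
  rows$metaplot_bins <- nrow(feats$metaplot)

  ## ---- expression ----------------------------------------------------
  expr <- run_stage("expr", {
    ex <- list()
    for (s in c("A", "B")) {
      cnts <- inp[[paste0("counts_", s)]]
      if (is.null(cnts)) next
      ex[[s]] <- compute_rpkm(cnts, inp$features, inp$exons,
                              threshold = config$rpkm_threshold)
      .write_tsv(ex[[s]], out(sprintf("expression_%s.tsv", s)))
    }
    ex
  })

  ## ---- feature analyses needing expression ---------------------------
  run_stage("features", {
    if (!is.null(expr$A)) {
      prox <- proximity_profile(feats$te, feats$genes, expr$A, calls$A)
      .write_tsv(prox$profile, out("proximity_profile_A.tsv"))
      if (!is.null(prox$tests))
        .write_tsv(prox$tests, out("proximity_tests_A.tsv"))
      te_fm <- feats$fm$A[feats$fm$A$kind == "TE", , drop = FALSE]
      sss <- size_stratified_summary(te_fm, feats$te, expr$A,
                                     rpkm_cut = config$rpkm_threshold)
      .write_tsv(sss, out("size_strata_A.tsv"))
    }
  })

  ## ---- differential methylation --------------------------------------
  dmr <- run_stage("dmr", {
    d <- site_deltas(calls$A, calls$B)
    dm <- call_differential_features(
      d, inp$features, min_sites = 4, z_threshold = config$z_threshold,
      min_mean_diff = config$min_mean_diff)
    .write_tsv(as.data.frame(dm), out("dmr.tsv"))
    dm
  })
  rows$dmr_features <- nrow(dmr); rows$dmr_calls <- sum(dmr$is_dmr)

  ## ---- CNV ------------------------------------------------------------
  cnv <- run_stage("cnv", {
    w <- windowed_coverage(inp$reads_A, inp$reads_B, inp$genome,
                           window_size = config$window_size)
    regs <- call_cnv_regions(w, threshold = config$cnv_threshold)
    .write_tsv(w, out("cnv_windows.tsv"))
    .write_tsv(as.data.frame(regs), out("cnv_regions.tsv"))
    wb <- w[w$ok, , drop = FALSE]
    write_bed(data.frame(scaffold = wb$scaffold, start = wb$start,
                         end = wb$end,
                         name = ifelse(wb$ln_ratio >= 0, "A_up", "B_up"),
                         score = wb$ln_ratio * 1000),
              out("cnv_windows.bed"), track_name = "cnv_ln_ratio_x1000")
    enr <- if (nrow(regs))
      cnv_enrichment(regs, inp$features, feats$fm$A, expr$A) else NULL
    if (!is.null(enr)) .write_tsv(enr$enrichment, out("cnv_enrichment.tsv"))
    list(windows = w, regions = regs, enrichment = enr)
  })
  rows$cnv_windows <- nrow(cnv$windows)
  rows$cnv_regions <- nrow(cnv$regions)

  ## ---- RIP index ------------------------------------------------------
  cri <- run_stage("cri", {
    ct <- cri_features(inp$genome, feats$te, symmetrized = TRUE)
    .write_tsv(ct, out("cri_features.tsv"))
    con <- file(out("cri_windows.bedGraph"), "wt")
    writeLines("track type=bedGraph name=composite_rip_index", con)
    for (sc in names(inp$genome)) {
      cw <- cri_windows(.genome_char(inp$genome, sc),
                        size = config$cri_window)
      cw <- cw[cw$defined, , drop = FALSE]
      if (nrow(cw))
        utils::write.table(
          data.frame(sc, cw$start, cw$end, .fmt_num(cw$cri)), con,
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    close(con)
    ct
  })
  rows$cri_features <- nrow(cri)

  ## ---- expression association ----------------------------------------
  assoc <- run_stage("expr", {
    if (is.null(expr$A)) return(NULL)
    a <- methylation_expression_association(
      feats$fm$A, expr$A, feats$te, expression_B = expr$B,
      rpkm_cut = config$rpkm_threshold)
    .write_tsv(a$subclass_table, out("te_subclass_expression.tsv"))
    if (!is.null(a$sample_tests))
      .write_tsv(a$sample_tests, out("te_sample_tests.tsv"))
    if (!is.null(expr$B)) {
      rb <- treatment_response_bins(feats$fm$A, feats$fm$B, expr$A, expr$B,
                                    context = "CHH",
                                    delta_cut = config$delta_cut)
      .write_tsv(rb$bins, out("response_bins.tsv"))
    }
    a
  })

  ## ---- report ---------------------------------------------------------
  outputs <- sort(setdiff(list.files(config$out_dir), "report.json"))
  output_md5 <- lapply(stats::setNames(outputs, outputs), function(f)
    unname(tools::md5sum(out(f))))
  report <- list(
    package = "fungimeth",
    seed = config$seed,
    parameters = config[c("min_coverage", "error_rate", "fdr",
                          "z_threshold", "window_size", "cnv_threshold",
                          "rpkm_threshold", "delta_cut", "flank",
                          "body_bins", "cri_window")],
    min_mean_diff = as.list(config$min_mean_diff),
    simulated_inputs = simulate_inputs,
    input_checksums = checksums,
    row_counts = rows,
    output_checksums = output_md5)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done", sprintf("%d output files in %s (%.1f s)",
                      length(outputs) + 1L, config$out_dir,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(inputs = inp, calls = calls, features = feats,
                 expression = expr, dmr = dmr, cnv = cnv, cri = cri,
                 association = assoc, report = report))
}
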