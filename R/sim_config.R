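#' Configuration for the synthetic WGBS data generator
#'
#' Builds and validates the parameter set that drives [build_genome()],
#' [assign_true_methylome()], [simulate_bisulfite_reads()],
#' [simulate_expression()] and [plant_cnv()].  Defaults emulate a
#' transposon-rich fungal genome: repetitive elements occupy a majority of
#' the sequence (default 58\%), arranged as large TE islands separating
#' relatively small blocks of genes; CG methylation is bimodal (TEs near
#' 80\%, genes near 1\%), non-CG methylation on TEs is moderate (30\%), and
#' sequencing reaches roughly 30X combined over both strands.
#'
#' @param genome_length total genome length in bases.
#' @param n_scaffolds number of scaffolds; the genome length is split
#'   near-equally among them.
#' @param te_fraction target fraction of the genome covered by TE features,
#'   in `[0, 1]`.
#' @param gene_block_size nominal length in bases of a block of genes
#'   between TE islands (jittered per block).
#' @param te_island_size nominal length in bases of a TE island (jittered).
#'   Must satisfy `genome_length >= 10 * te_island_size`.
#' @param te_subclass_weights named numeric vector of TE subclass sampling
#'   weights; must sum to 1.  Default is dominated by Gypsy LTR
#'   retrotransposons, as in sequenced truffle-like genomes.
#' @param cg_meth_te,noncg_meth_te mean true methylation level of TE
#'   cytosines in CG and non-CG context.
#' @param cg_meth_gene,noncg_meth_gene mean true methylation level of
#'   cytosines outside TEs (genes and background) per context.
#' @param conversion_failure probability that an unmethylated cytosine
#'   escapes bisulfite conversion and still reads as C.
#' @param sequencing_error per-base probability of a uniform substitution
#'   error after conversion.
#' @param read_length simulated read length in bases.
#' @param coverage mean sequencing depth per strand (combined two-strand
#'   depth is twice this).
#' @param te_near_gene_frac fraction of TEs deliberately placed in gene
#'   blocks within 1 kb of a gene, exercising gene-proximity analyses.
#' @param expr_meth_slope log-scale decrease of expected TE expression per
#'   unit of CG methylation (negative association strength).
#' @param expr_rate_kb log-mean expected read count per kilobase for an
#'   unmethylated feature.
#' @param nb_dispersion negative-binomial size (dispersion) parameter of
#'   simulated counts.
#' @param zero_inflation probability that a feature's count is forced to
#'   zero regardless of its mean.
#' @param seed integer seed; every generator operation derives its random
#'   stream from it.
#'
#' @return a validated list of class `"fm_sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, te_island_size = 2e4)
#' cfg$te_fraction
sim_config <- function(genome_length = 1e6,
                       n_scaffolds = 2,
                       te_fraction = 0.58,
                       gene_block_size = 20000,
                       te_island_size = 30000,
                       te_subclass_weights = c(
                         "Gypsy" = 0.50, "non-Gypsy-LTR" = 0.15,
                         "LINE" = 0.10, "non-LTR-non-LINE" = 0.10,
                         "DNA-transposon" = 0.10, "unclassified" = 0.05),
                       cg_meth_te = 0.80,
                       noncg_meth_te = 0.30,
                       cg_meth_gene = 0.01,
                       noncg_meth_gene = 0.005,
                       conversion_failure = 0.005,
                       sequencing_error = 0.001,
                       read_length = 50,
                       coverage = 15,
                       te_near_gene_frac = 0.10,
                       expr_meth_slope = 4,
                       expr_rate_kb = 30,
                       nb_dispersion = 2,
                       zero_inflation = 0,
                       seed = 1) {
  .check_count(genome_length, "genome_length", min = 1000)
  .check_count(n_scaffolds, "n_scaffolds", min = 1)
  .check_fraction(te_fraction, "te_fraction")
  .check_count(gene_block_size, "gene_block_size", min = 1000)
  .check_count(te_island_size, "te_island_size", min = 1000)
  if (genome_length < 10 * te_island_size)
    .stopf("'genome_length' must be at least 10 * 'te_island_size'")
  if (is.null(names(te_subclass_weights)) || any(te_subclass_weights < 0))
    .stopf("'te_subclass_weights' must be a named non-negative vector")
  if (abs(sum(te_subclass_weights) - 1) > 1e-6)
    .stopf("'te_subclass_weights' must sum to 1 (got %s)",
           format(sum(te_subclass_weights)))
  for (f in c("cg_meth_te", "noncg_meth_te", "cg_meth_gene",
              "noncg_meth_gene", "conversion_failure", "sequencing_error",
              "te_near_gene_frac", "zero_inflation"))
    .check_fraction(get(f), f)
  .check_count(read_length, "read_length", min = 10)
  if (!is.numeric(coverage) || length(coverage) != 1L || coverage <= 0)
    .stopf("'coverage' must be a single positive number")
  .check_count(seed, "seed", min = 0)
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_scaffolds = as.integer(n_scaffolds),
    te_fraction = te_fraction,
    gene_block_size = as.integer(gene_block_size),
    te_island_size = as.integer(te_island_size),
    te_subclass_weights = te_subclass_weights,
    cg_meth_te = cg_meth_te, noncg_meth_te = noncg_meth_te,
    cg_meth_gene = cg_meth_gene, noncg_meth_gene = noncg_meth_gene,
    conversion_failure = conversion_failure,
    sequencing_error = sequencing_error,
    read_length = as.integer(read_length),
    coverage = coverage,
    te_near_gene_frac = te_near_gene_frac,
    expr_meth_slope = expr_meth_slope,
    expr_rate_kb = expr_rate_kb,
    nb_dispersion = nb_dispersion,
    zero_inflation = zero_inflation,
    seed = as.integer(seed)
  )
  class(cfg) <- "fm_sim_config"
  cfg
}

#' @export
print.fm_sim_config <- function(x, ...) {
  cat("Synthetic WGBS configuration\n")
  cat(sprintf("  genome: %s bp over %d scaffold(s), TE fraction %.2f\n",
              format(x$genome_length, big.mark = ","), x$n_scaffolds,
              x$te_fraction))
  cat(sprintf("  methylation: TE CG %.2f / non-CG %.2f; background CG %.2f\n",
              x$cg_meth_te, x$noncg_meth_te, x$cg_meth_gene))
  cat(sprintf("  reads: %d bp, %gX per strand, conv.failure %.3g, error %.3g\n",
              x$read_length, x$coverage, x$conversion_failure,
              x$sequencing_error))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
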