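# Shared fixtures, all built in code at test time.

# A small simulated world (genome + annotations + methylome), cached per
# test file run.
small_world <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cfg <- sim_config(genome_length = 2.5e5, n_scaffolds = 2,
                      te_island_size = 8000, gene_block_size = 6000,
                      coverage = 8, seed = seed)
    g <- build_genome(cfg)
    m <- assign_true_methylome(g$genome, g$features, cfg)
    cache <<- list(seed = seed, config = cfg, genome = g$genome,
                   features = g$features, exons = g$exons, methylome = m)
    cache
  }
})

# Hand-built genome from explicit scaffold strings.
toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# Hand-built read table.
toy_reads <- function(scaffold, start, strand, seq) {
  data.frame(read_id = sprintf("r%d", seq_along(start)),
             scaffold = scaffold, start = as.integer(start),
             strand = strand, seq = seq)
}

# Site records built directly (bypassing read simulation) for modules
# that consume estimate_levels() output.
toy_records <- function(pos, level, context = "CG", scaffold = "chr",
                        strand = "+", depth = 10) {
  n_meth <- as.integer(round(level * depth))
  data.frame(scaffold = scaffold, pos = as.integer(pos), strand = strand,
             context = context, n_meth = n_meth,
             n_unmeth = as.integer(depth - n_meth),
             level = n_meth / depth)
}

# Binomially sampled records at given true levels, one site per element.
sampled_records <- function(pos, m, depth = 30, context = "CG",
                            scaffold = "chr", strand = "+") {
  n_meth <- stats::rbinom(length(pos), depth, m)
  data.frame(scaffold = scaffold, pos = as.integer(pos), strand = strand,
             context = context, n_meth = n_meth,
             n_unmeth = as.integer(depth) - n_meth,
             level = n_meth / depth)
}
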