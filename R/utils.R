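# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single fraction in [0, 1] (got %s)",
           name, paste(format(x), collapse = ","))
  invisible(x)
}

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    .stopf("'%s' must be a single number >= %s (got %s)", name, min, format(x))
  invisible(x)
}

# Scaffold lengths of a genome held as a Biostrings::DNAStringSet.
.scaffold_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

.genome_char <- function(genome, scaffold) {
  if (!scaffold %in% names(genome))
    .stopf("scaffold '%s' not present in genome", scaffold)
  as.character(genome[[scaffold]])
}

# Total number of genomic cytosines (C on plus strand plus C on minus
# strand, i.e. G on plus) across all scaffolds.
.n_genomic_cytosines <- function(genome) {
  freq <- Biostrings::alphabetFrequency(genome)
  sum(freq[, "C"]) + sum(freq[, "G"])
}

# Feature data.frames use 0-based half-open [start, end) coordinates.
.features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$scaffold,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
}

.positions_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$pos + 1L, width = 1L)
  )
}

# Deterministic fixed-format number rendering for text outputs, so that
# reruns are byte-identical regardless of options(digits).
.fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
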