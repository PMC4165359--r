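# Readers and writers for the standard interchange formats: FASTA, GFF3,
# BED, bedGraph, a CGmap-style methylome TSV, and reads as minimal SAM or
# a 5-column TSV.  Internal coordinates are 0-based half-open everywhere;
# conversion happens only at these I/O boundaries (GFF3/SAM are 1-based
# inclusive, BED/bedGraph 0-based half-open).

#' Write a genome FASTA
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a `DNAStringSet` with names truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write features and exons as GFF3
#'
#' Feature types `gene`, `exon` (with `Parent`) and
#' `transposable_element` (with a `te_class` attribute).  GFF3 is 1-based
#' inclusive; internal coordinates are 0-based half-open, so start maps
#' to start+1.  Output ordering (scaffold, start, id) is deterministic.
#'
#' @param features,exons data.frames as from [build_genome()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotations_gff3 <- function(features, exons, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  f <- features[order(features$scaffold, features$start, features$id), ,
                drop = FALSE]
  for (i in seq_len(nrow(f))) {
    if (f$kind[i] == "gene") {
      writeLines(sprintf("%s\tfungimeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         f$scaffold[i], f$start[i] + 1L, f$end[i],
                         f$strand[i], f$id[i]), con)
      ex <- exons[exons$gene_id == f$id[i], , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (j in seq_len(nrow(ex)))
        writeLines(sprintf(
          "%s\tfungimeth\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
          ex$scaffold[j], ex$start[j] + 1L, ex$end[j], ex$strand[j],
          ex$id[j], ex$gene_id[j]), con)
    } else {
      cls <- if (is.na(f$te_class[i])) "unclassified" else f$te_class[i]
      writeLines(sprintf(
        "%s\tfungimeth\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;te_class=%s",
        f$scaffold[i], f$start[i] + 1L, f$end[i], f$strand[i], f$id[i],
        cls), con)
    }
  }
  invisible(path)
}

#' Load gene/TE annotations from GFF3 or BED
#'
#' GFF3 records of type `gene`, `exon` and `transposable_element` (or
#' `*_retrotransposon` / `repeat_region`) are recognized; exons attach to
#' their gene through the `Parent` attribute and the TE subclass is read
#' from the `te_class` attribute (default "unclassified").  Other types
#' are skipped with a warning.  BED entries become TE features unless
#' their name starts with "gene".  Coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param path annotation file; format from the extension
#'   (`.gff`/`.gff3` or `.bed`) unless given.
#' @param format "gff3" or "bed".
#' @return list with `features` and `exons` data.frames.
#' @export
load_annotations <- function(path,
                             format = if (grepl("\\.bed$", path)) "bed"
                                      else "gff3") {
  if (!file.exists(path)) .stopf("annotation file '%s' not found", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   .stopf("malformed %s file '%s': %s", format, path,
                          conditionMessage(e)))
  df <- as.data.frame(gr)
  if (format == "bed") {
    nm <- if (!is.null(df$name)) df$name else sprintf("feat_%d", seq_len(nrow(df)))
    features <- data.frame(
      id = nm, scaffold = as.character(df$seqnames),
      start = df$start - 1L, end = df$end,
      strand = ifelse(as.character(df$strand) == "-", "-", "+"),
      kind = ifelse(grepl("^gene", nm), "gene", "TE"),
      te_class = ifelse(grepl("^gene", nm), NA_character_, "unclassified"))
    features$size <- features$end - features$start
    return(list(features = features,
                exons = data.frame(id = character(), gene_id = character(),
                                   scaffold = character(), start = integer(),
                                   end = integer(), strand = character())))
  }
  type <- as.character(df$type)
  te_types <- c("transposable_element", "repeat_region",
                "LTR_retrotransposon", "non_LTR_retrotransposon")
  known <- type %in% c("gene", "exon", te_types)
  if (any(!known))
    warning(sprintf("skipped %d record(s) of unknown type: %s",
                    sum(!known),
                    paste(unique(type[!known]), collapse = ", ")))
  df <- df[known, , drop = FALSE]
  type <- type[known]
  id <- if (!is.null(df$ID)) as.character(df$ID) else
    sprintf("feat_%d", seq_len(nrow(df)))
  is_gene <- type == "gene"
  is_te <- type %in% te_types
  is_exon <- type == "exon"
  te_class <- if (!is.null(df$te_class)) as.character(df$te_class) else
    rep(NA_character_, nrow(df))
  features <- data.frame(
    id = id[is_gene | is_te],
    scaffold = as.character(df$seqnames)[is_gene | is_te],
    start = df$start[is_gene | is_te] - 1L,
    end = df$end[is_gene | is_te],
    strand = ifelse(as.character(df$strand)[is_gene | is_te] == "-",
                    "-", "+"),
    kind = ifelse(is_gene[is_gene | is_te], "gene", "TE"),
    te_class = ifelse(is_gene[is_gene | is_te], NA_character_,
                      ifelse(is.na(te_class[is_gene | is_te]),
                             "unclassified", te_class[is_gene | is_te])))
  features$size <- features$end - features$start
  parent <- if (!is.null(df$Parent)) {
    vapply(df$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  exons <- data.frame(
    id = id[is_exon], gene_id = unname(parent[is_exon]),
    scaffold = as.character(df$seqnames)[is_exon],
    start = df$start[is_exon] - 1L, end = df$end[is_exon],
    strand = ifelse(as.character(df$strand)[is_exon] == "-", "-", "+"))
  if (any(is.na(exons$gene_id)))
    warning("exon(s) without Parent attribute dropped")
  exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  rownames(features) <- rownames(exons) <- NULL
  list(features = features, exons = exons)
}

#' Write the methylome as a CGmap-style TSV (plus per-context bedGraph)
#'
#' Columns: scaffold, position (1-based), strand, context, level
#' (6 decimals), n_meth, coverage; rows ordered by scaffold then
#' position.  One bedGraph per context is written next to the TSV when
#' `bedgraph = TRUE`.
#'
#' @param records data.frame from [estimate_levels()].
#' @param path output TSV path.
#' @param bedgraph also write `<path>_<context>.bedGraph` tracks.
#' @return the TSV path, invisibly.
#' @export
write_methylome_track <- function(records, path, bedgraph = FALSE) {
  rec <- records[order(records$scaffold, records$pos), , drop = FALSE]
  df <- data.frame(scaffold = rec$scaffold, position = rec$pos + 1L,
                   strand = rec$strand, context = rec$context,
                   level = .fmt_num(rec$level), n_meth = rec$n_meth,
                   coverage = rec$n_meth + rec$n_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (bedgraph) {
    for (cx in intersect(c("CG", "CHG", "CHH"), unique(rec$context))) {
      sel <- rec$context == cx
      bg <- data.frame(rec$scaffold[sel], rec$pos[sel], rec$pos[sel] + 1L,
                       .fmt_num(rec$level[sel]))
      bgpath <- sprintf("%s_%s.bedGraph", sub("\\.tsv$", "", path), cx)
      con <- file(bgpath, "wt")
      writeLines(sprintf("track type=bedGraph name=methylation_%s", cx), con)
      utils::write.table(bg, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      close(con)
    }
  }
  invisible(path)
}

#' Read a CGmap-style methylome TSV back into records
#'
#' Counts are exact; the level is recomputed as n_meth / coverage, so a
#' write/read round trip reproduces the original records.
#'
#' @param path TSV from [write_methylome_track()].
#' @return data.frame (scaffold, pos, strand, context, n_meth, n_unmeth,
#'   level).
#' @export
read_methylome_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric", "integer",
                                         "integer"))
  out <- data.frame(scaffold = df$scaffold, pos = df$position - 1L,
                    strand = df$strand, context = df$context,
                    n_meth = df$n_meth, n_unmeth = df$coverage - df$n_meth)
  out$level <- ifelse(out$n_meth + out$n_unmeth > 0,
                      out$n_meth / (out$n_meth + out$n_unmeth), NA_real_)
  out
}

#' Write reads as a 5-column TSV or minimal SAM
#'
#' The SAM dialect is intentionally minimal: @HD/@SQ header plus the 11
#' mandatory columns; FLAG 0 marks Watson-origin and FLAG 16
#' Crick-origin reads.  SEQ always holds the plus-strand projection of
#' the read (the form aligners report), so the flag encodes the strand
#' of origin only.
#'
#' @param reads read data.frame.
#' @param path output path.
#' @param format "tsv" or "sam" (default from extension).
#' @param genome required for SAM @SQ header lines.
#' @return the path, invisibly.
#' @export
write_reads <- function(reads, path,
                        format = if (grepl("\\.sam$", path)) "sam" else "tsv",
                        genome = NULL) {
  if (format == "tsv") {
    utils::write.table(reads[, c("read_id", "scaffold", "start", "strand",
                                 "seq")],
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  if (is.null(genome)) .stopf("'genome' is required to write SAM headers")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  lens <- .scaffold_lengths(genome)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     reads$read_id, flag, reads$scaffold,
                     reads$start + 1L, nchar(reads$seq), reads$seq), con)
  invisible(path)
}

#' Read aligned reads from TSV or minimal SAM
#'
#' @param path input path.
#' @param format "tsv" or "sam" (default from extension).
#' @return read data.frame (read_id, scaffold, start, strand, seq).
#' @export
read_reads <- function(path,
                       format = if (grepl("\\.sam$", path)) "sam"
                                else "tsv") {
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "integer", "character",
                                           "character"))
    return(df)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), scaffold = character(),
                      start = integer(), strand = character(),
                      seq = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11)
  if (length(bad))
    .stopf("malformed SAM line %d: fewer than 11 fields", bad[1])
  m <- matrix(unlist(lapply(parts, `[`, 1:11)), ncol = 11, byrow = TRUE)
  data.frame(read_id = m[, 1], scaffold = m[, 3],
             start = as.integer(m[, 4]) - 1L,
             strand = ifelse(bitwAnd(as.integer(m[, 2]), 16L) > 0, "-", "+"),
             seq = m[, 10])
}

#' Write a BED track of intervals with a score
#'
#' @param df data.frame with scaffold, start, end (0-based half-open),
#'   plus optional name and score columns.
#' @param path output path.
#' @param track_name BED track name.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path, track_name = "fungimeth") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("track name=%s", track_name), con)
  name <- df$name %||% sprintf("region_%d", seq_len(nrow(df)))
  score <- df$score %||% rep(0L, nrow(df))
  utils::write.table(
    data.frame(df$scaffold, df$start, df$end, name, round(score)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
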