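# Dinucleotide statistics and the composite RIP index (CRI).
#
# RIP (repeat-induced point mutation) mutates CpA to TpA within repeats;
# its footprint is a skew in dinucleotide frequencies.  The composite
# index is
#   CRI = (TpA / ApT) - ((CpA + TpG) / (ApC + GpT))
# where the first term scores RIP products and the second the depletion
# of RIP targets and their reverse complements.  Positive values indicate
# a RIP-affected sequence.

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))

#' Count overlapping dinucleotides
#'
#' Counts all 16 dinucleotides in overlapping 2-base windows on the given
#' strand; pairs containing a non-ACGT character (e.g. N) are skipped.
#'
#' @param sequence a single DNA string (A/C/G/T/N alphabet).
#' @return named integer vector over the 16 dinucleotides.
#' @export
#' @examples
#' dinucleotide_counts("TATA")  # TA = 2, AT = 1
dinucleotide_counts <- function(sequence) {
  out <- stats::setNames(integer(16), DINUCS)
  n <- nchar(sequence)
  if (is.na(sequence) || n < 2) return(out)
  v <- strsplit(toupper(sequence), "")[[1]]
  d <- paste0(v[-n], v[-1])
  d <- d[v[-n] %in% c("A", "C", "G", "T") & v[-1] %in% c("A", "C", "G", "T")]
  tb <- table(factor(d, levels = DINUCS))
  out[] <- as.integer(tb)
  out
}

.cri_from_counts <- function(cnt) {
  product <- if (cnt[["AT"]] > 0) cnt[["TA"]] / cnt[["AT"]] else NA_real_
  den <- cnt[["AC"]] + cnt[["GT"]]
  substrate <- if (den > 0) (cnt[["CA"]] + cnt[["TG"]]) / den else NA_real_
  defined <- cnt[["AT"]] > 0 && den > 0
  list(product = product, substrate = substrate,
       cri = if (defined) product - substrate else NA_real_,
       defined = defined)
}

#' Composite RIP index of a sequence
#'
#' Computes the RIP product (TpA/ApT), RIP substrate
#' ((CpA+TpG)/(ApC+GpT)) and their difference, the CRI.  When a
#' denominator is zero the score is undefined (`defined = FALSE`, values
#' NA) rather than infinite.  With `symmetrized = TRUE` the mean of the
#' scores of both strands is also reported (the per-strand CRI is not
#' strand-symmetric).
#'
#' @param sequence a single DNA string.
#' @param symmetrized also compute the strand-symmetrized score.
#' @return one-row data.frame: TpA, ApT, CpA, TpG, ApC, GpT, product,
#'   substrate, cri, defined (and cri_symmetrized if requested).
#' @export
#' @examples
#' composite_rip_index("ACATGT")  # cri = -1
composite_rip_index <- function(sequence, symmetrized = FALSE) {
  cnt <- dinucleotide_counts(sequence)
  s <- .cri_from_counts(cnt)
  out <- data.frame(TpA = cnt[["TA"]], ApT = cnt[["AT"]], CpA = cnt[["CA"]],
                    TpG = cnt[["TG"]], ApC = cnt[["AC"]], GpT = cnt[["GT"]],
                    product = s$product, substrate = s$substrate,
                    cri = s$cri, defined = s$defined)
  if (symmetrized) {
    rc <- .revcomp(sequence)
    s2 <- .cri_from_counts(dinucleotide_counts(rc))
    out$cri_symmetrized <- if (s$defined && s2$defined)
      (s$cri + s2$cri) / 2 else NA_real_
  }
  out
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Composite RIP index in sliding windows
#'
#' One [composite_rip_index()] row per window of `size` bases advanced by
#' `step` along the sequence (the final partial window is scored if at
#' least 2 bases long).
#'
#' @param sequence a single DNA string.
#' @param size window size in bases (>= 2).
#' @param step step between window starts (default `size`, i.e. tiled).
#' @param symmetrized see [composite_rip_index()].
#' @return data.frame with start, end (0-based half-open) and the CRI
#'   columns.
#' @export
cri_windows <- function(sequence, size = 500, step = size,
                        symmetrized = FALSE) {
  if (size < 2) .stopf("window 'size' must be >= 2")
  if (step < 1) .stopf("'step' must be >= 1")
  L <- nchar(sequence)
  starts <- seq(0, max(0, L - 2), by = step)
  starts <- starts[starts < L - 1]
  rows <- lapply(starts, function(s) {
    e <- min(L, s + size)
    cbind(start = s, end = e,
          composite_rip_index(substr(sequence, s + 1, e),
                              symmetrized = symmetrized))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composite RIP index of annotated repeats
#'
#' Scores each feature's genomic sequence on the feature's own strand
#' (minus-strand features are reverse-complemented before counting).
#'
#' @param genome a `DNAStringSet`.
#' @param features feature data.frame (typically TEs).
#' @param symmetrized see [composite_rip_index()].
#' @return data.frame with id, kind, te_class and the CRI columns.
#' @export
cri_features <- function(genome, features, symmetrized = FALSE) {
  rows <- lapply(seq_len(nrow(features)), function(i) {
    sq <- substr(.genome_char(genome, features$scaffold[i]),
                 features$start[i] + 1L, features$end[i])
    if (identical(features$strand[i], "-")) sq <- .revcomp(sq)
    cbind(id = features$id[i], kind = features$kind[i],
          te_class = features$te_class[i],
          composite_rip_index(sq, symmetrized = symmetrized))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate RIP-like mutation on a sequence
#'
#' Mutates the C of each CpA to T with probability `p`, and the G of each
#' TpG to A with the same probability (the reverse-complement strand's
#' CpA), the dinucleotide footprint RIP leaves on double-stranded DNA.
#' Useful for validating that the CRI increases with mutation load.
#'
#' @param sequence a single DNA string.
#' @param p per-site mutation probability.
#' @return the mutated sequence.
#' @export
rip_mutate <- function(sequence, p = 0.5) {
  .check_fraction(p, "p")
  v <- strsplit(sequence, "")[[1]]
  n <- length(v)
  if (n < 2) return(sequence)
  ca <- which(v[-n] == "C" & v[-1] == "A")
  tg <- which(v[-n] == "T" & v[-1] == "G") + 1L
  hit_ca <- ca[stats::runif(length(ca)) < p]
  hit_tg <- tg[stats::runif(length(tg)) < p]
  v[hit_ca] <- "T"
  v[hit_tg] <- "A"
  paste(v, collapse = "")
}
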