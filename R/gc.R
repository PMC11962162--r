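#' GC content of hotspot windows vs the genome
#'
#' GC fraction is (G+C)/(A+C+G+T) — ambiguous bases are excluded from the
#' denominator; a window consisting entirely of ambiguous bases yields
#' \code{NA}. Hotspot windows are \code{window} bp centred on each peak bin
#' (default 10 kb), clipped at chromosome ends; the genome-wide reference
#' distribution uses non-overlapping windows of the same size tiling every
#' host chromosome, so the two are comparable.
#'
#' @param seqs a \code{Biostrings::DNAStringSet} (names matching the genome's
#'   chromosomes) or a FASTA file path.
#' @param peaks a \code{peak_set}.
#' @param window window size in bp.
#' @return list(hotspot_gc, genome_gc, hotspot_mean, genome_mean); fractions
#'   in [0, 1].
#' @export
gc_windows <- function(seqs, peaks, window = 10000) {
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  g <- attr(peaks, "genome")
  if (!all(peaks$chrom %in% names(seqs)))
    stop("FASTA lacks chromosome(s): ",
         paste(setdiff(peaks$chrom, names(seqs)), collapse = ", "))
  bs <- g$bin_size
  hotspot_gc <- vapply(seq_len(nrow(peaks)), function(k) {
    cn <- peaks$chrom[k]
    center <- peaks$start[k] + bs / 2
    lo <- max(0, floor(center - window / 2))
    hi <- min(length(seqs[[cn]]), ceiling(center + window / 2))
    gc_fraction(Biostrings::subseq(seqs[[cn]], lo + 1, hi))
  }, numeric(1))
  genome_gc <- unlist(lapply(intersect(host_chroms(g), names(seqs)), function(cn) {
    L <- length(seqs[[cn]])
    starts <- seq(1, L, by = window)
    starts <- starts[starts + window - 1 <= L | starts == 1]
    vapply(starts, function(s)
      gc_fraction(Biostrings::subseq(seqs[[cn]], s, min(s + window - 1, L))),
      numeric(1))
  }), use.names = FALSE)
  list(hotspot_gc = hotspot_gc, genome_gc = genome_gc,
       hotspot_mean = mean(hotspot_gc, na.rm = TRUE),
       genome_mean = mean(genome_gc, na.rm = TRUE))
}

gc_fraction <- function(dna) {
  f <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  f <- as.numeric(f)                      # XString gives a named vector
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  (f[3] + f[2]) / tot
}
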