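#' Subtelomeric intervals
#'
#' The terminal \code{flank} bp at each end of every host chromosome
#' (default 30 kb, the study's subtelomere definition). Chromosomes shorter
#' than \code{2 * flank} yield a single merged interval; plasmid contigs are
#' excluded.
#'
#' @param genome a \code{binned_genome}.
#' @param flank bp from each chromosome end (> 0).
#' @return a \code{feature_set} with class \code{"subtelomere"}.
#' @export
subtelomere_intervals <- function(genome, flank = 30000) {
  stopifnot(flank > 0)
  res <- lapply(host_chroms(genome), function(cn) {
    L <- unname(genome$length[cn])
    if (L <= 2 * flank)
      data.frame(chrom = cn, start = 0, end = L)
    else
      data.frame(chrom = cn, start = c(0, L - flank), end = c(flank, L))
  })
  df <- do.call(rbind, res)
  feature_set(df$chrom, df$start, df$end,
              name = sprintf("subtel%02d", seq_len(nrow(df))),
              class = "subtelomere")
}

#' Long-gene feature group
#'
#' Genes strictly longer than \code{min_length} bp (7 kb is the study's
#' threshold for budding yeast; 10 kb for the amoeba). A gene of exactly
#' \code{min_length} bp is excluded.
#'
#' @param genes a \code{feature_set} with a length column.
#' @param min_length strict length threshold in bp.
#' @return the subset \code{feature_set}.
#' @export
long_gene_group <- function(genes, min_length = 7000) {
  out <- genes[genes$length > min_length, , drop = FALSE]
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Count peak/feature overlaps
#'
#' A peak occupies its single bin interval
#' \code{[start, start + bin_size)}. Returns both directions of the overlap:
#' how many peaks land in a feature, and how many features are hit by at
#' least one peak (for statements like "15 of the 19 longest genes").
#'
#' @param peaks a \code{peak_set}.
#' @param features a \code{feature_set} on the same genome.
#' @param genome the \code{binned_genome} (defaults to the peak set's).
#' @return list(peak_overlap, features_hit).
#' @export
feature_hit_count <- function(peaks, features, genome = attr(peaks, "genome")) {
  if (!all(features$chrom %in% genome$chrom))
    stop("features refer to chromosomes absent from the peak set's genome")
  if (!nrow(peaks) || !nrow(features))
    return(list(peak_overlap = 0L, features_hit = 0L))
  bs <- genome$bin_size
  pk <- GenomicRanges::GRanges(factor(peaks$chrom, levels = genome$chrom),
          IRanges::IRanges(start = peaks$start + 1,
                           end = pmin(peaks$start + bs,
                                      unname(genome$length[peaks$chrom]))))
  ft <- GenomicRanges::GRanges(factor(features$chrom, levels = genome$chrom),
          IRanges::IRanges(start = features$start + 1, end = features$end))
  hits <- GenomicRanges::findOverlaps(pk, ft)
  list(peak_overlap = length(unique(S4Vectors::queryHits(hits))),
       features_hit = length(unique(S4Vectors::subjectHits(hits))))
}

#' Permutation test for hotspot/feature overlap enrichment
#'
#' Draws \code{n_permutations} realisations of \code{|peaks|} distinct host
#' bins uniformly at random (optionally stratified per chromosome to
#' preserve per-chromosome peak counts), counts how many random positions
#' overlap the feature group exactly as \code{\link{feature_hit_count}}
#' does, and reports
#' \code{p = #\{realisations with overlap >= observed\} / n_permutations}.
#' When that count is 0 the result records p = 0 and flags
#' \code{"p < 1/n_permutations"}.
#'
#' @param peaks a non-empty \code{peak_set}.
#' @param features a \code{feature_set}.
#' @param genome the \code{binned_genome}.
#' @param n_permutations number of random realisations (default 1000, the
#'   study's choice).
#' @param seed RNG seed (required for reproducibility).
#' @param stratify_by_chrom if TRUE, each realisation preserves the observed
#'   per-chromosome peak counts; default FALSE (genome-wide uniform).
#' @return an \code{enrichment_result} with the observed overlap, the full
#'   null distribution, the p-value and provenance.
#' @export
permutation_overlap_test <- function(peaks, features,
                                     genome = attr(peaks, "genome"),
                                     n_permutations = 1000, seed = 1L,
                                     stratify_by_chrom = FALSE,
                                     label = NULL) {
  stopifnot(n_permutations >= 1, nrow(peaks) >= 1)
  npk <- nrow(peaks)
  nh <- genome$n_host_bins
  if (npk > nh) stop("more peaks than host bins")
  hit <- feature_bin_mask(features, genome)
  observed <- feature_hit_count(peaks, features, genome)$peak_overlap
  set.seed(seed)
  if (stratify_by_chrom) {
    chrom_of <- host_bin_chrom(genome)
    counts <- table(factor(peaks$chrom, levels = levels(chrom_of)))
    pools <- split(seq_len(nh), chrom_of)
    null <- vapply(seq_len(n_permutations), function(k) {
      s <- unlist(lapply(names(counts)[counts > 0], function(cn)
        sample(pools[[cn]], counts[[cn]])), use.names = FALSE)
      sum(hit[s])
    }, numeric(1))
  } else {
    null <- vapply(seq_len(n_permutations), function(k)
      sum(hit[sample.int(nh, npk)]), numeric(1))
  }
  ge <- sum(null >= observed)
  structure(list(observed = observed, n_permutations = n_permutations,
                 n_ge_observed = ge, p_value = ge / n_permutations,
                 null = null, seed = seed,
                 label = if (is.null(label)) features$class[1] else label,
                 n_peaks = npk,
                 note = if (ge == 0) sprintf("p < 1/%d", n_permutations) else ""),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> '%s': observed %d/%d peaks; null mean %.2f (sd %.2f); p = %g%s\n",
    x$label, x$observed, x$n_peaks, mean(x$null), stats::sd(x$null),
    x$p_value, if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Write enrichment results as TSV
#' @param results list of \code{enrichment_result}s.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#tetherscan permutation overlap enrichment", con)
  writeLines("group\tn_peaks\tobserved\tnull_mean\tnull_sd\tp_value\tn_permutations\tseed\tnote", con)
  for (r in results)
    writeLines(sprintf("%s\t%d\t%d\t%.4f\t%.4f\t%g\t%d\t%d\t%s",
                       r$label, r$n_peaks, r$observed, mean(r$null),
                       stats::sd(r$null), r$p_value, r$n_permutations,
                       r$seed, r$note), con)
  invisible(path)
}
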