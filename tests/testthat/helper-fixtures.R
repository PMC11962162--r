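# Small fixtures built in code, shared across test files.

# one host chromosome (nbins bins) plus an optional 1-bin plasmid contig
toy_genome <- function(nbins = 4, bin_size = 2000, plasmid = TRUE) {
  if (plasmid)
    binned_genome(c("chrA", "pl"), c(nbins * bin_size, bin_size),
                  bin_size = bin_size, plasmids = "pl")
  else
    binned_genome("chrA", nbins * bin_size, bin_size = bin_size)
}

# dense symmetric brute-force accumulation of COO triplets (the oracle for
# sparse storage): returns an n x n matrix with each pair counted once per
# cell, mirrored
dense_accumulate <- function(n, i, j, x) {
  m <- matrix(0, n, n)
  for (k in seq_along(i)) {
    m[i[k], j[k]] <- m[i[k], j[k]] + x[k]
    if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + x[k]
  }
  m
}

# contact profile built directly from a hand-specified score vector
profile_from_scores <- function(genome, scores) {
  structure(list(genome = genome, score = scores, valid = !is.na(scores),
                 plasmid = plasmid_chroms(genome),
                 stats = library_stats(1, 10), denominator = "all",
                 interpolated = FALSE),
            class = "contact_profile")
}

# peak set at given 0-based bin ordinals of a single-chromosome genome
peaks_at <- function(genome, chrom, bins, scores = 1) {
  structure(data.frame(chrom = rep_len(chrom, length(bins)), bin = bins,
                       start = bins * genome$bin_size,
                       score = rep_len(scores, length(bins)),
                       stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"),
            height = 0.8, distance = 2L, genome = genome)
}

# the standard synthetic scenario, simulated once per session and memoised
standard_scenario <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      syn <- simulate_genome(seed = seed)
      truth <- synthetic_truth(syn$genome, syn$genes, seed = seed)
      sim <- simulate_contact_data(syn$genome, truth, depth = 5e6,
                                   seed = seed)
      prof <- compute_contact_profile(sim$matrix, sim$stats)
      peaks <- call_peaks(interpolate_profile(prof))
      cache[[key]] <<- list(syn = syn, truth = truth, sim = sim,
                            profile = prof, peaks = peaks)
    }
    cache[[key]]
  }
})

# sensitivity/precision of a peak set against truth sites, +/- tol bins
recovery_rates <- function(peaks, truth, genome, tol = 2) {
  pb <- host_bin_index(genome, peaks$chrom, peaks$start)
  d <- outer(pb, truth$host_bin, function(a, b) abs(a - b))
  list(sensitivity = mean(apply(d, 2, min) <= tol),
       precision = mean(apply(d, 1, min) <= tol))
}
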