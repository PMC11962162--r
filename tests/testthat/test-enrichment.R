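test_that("subtelomere intervals: two flanks per chromosome, merged when short", {
  g <- binned_genome(sprintf("c%02d", 1:16), rep(750000, 16), bin_size = 2000)
  st <- subtelomere_intervals(g, flank = 30000)
  expect_equal(nrow(st), 32)
  expect_equal(sum(st$length), 960000)
  # short chromosome merges into a single interval
  g2 <- binned_genome(c("c1", "c2"), c(50000, 100000), bin_size = 2000)
  st2 <- subtelomere_intervals(g2, flank = 30000)
  expect_equal(nrow(st2), 3)
  expect_equal(st2$end[1] - st2$start[1], 50000)
  # flank must be positive but can be tiny
  expect_error(subtelomere_intervals(g, flank = 0))
  expect_equal(unique(subtelomere_intervals(g, flank = 1)$length), 1)
  # plasmid contigs excluded
  g3 <- toy_genome(40)
  expect_false("pl" %in% subtelomere_intervals(g3)$chrom)
})

test_that("long-gene group uses a strict length threshold", {
  fs <- feature_set("c", c(0, 10000, 30000), c(2000, 18000, 42000))
  expect_equal(nrow(long_gene_group(fs, 7000)), 2)
  expect_equal(nrow(long_gene_group(feature_set("c", 0, 7000), 7000)), 0)
  # exactly 7000 bp is excluded
  fs2 <- feature_set("c", c(0, 10000), c(7000, 17001))
  expect_equal(long_gene_group(fs2, 7000)$length, 7001)
})

test_that("hit counts match brute-force pairwise interval intersection", {
  g <- binned_genome("chrA", 40000, bin_size = 2000)
  pk <- peaks_at(g, "chrA", c(1, 5, 15))           # bins at 2-4k, 10-12k, 30-32k
  fs <- feature_set("chrA", c(2000, 9000), c(4500, 12000))
  got <- feature_hit_count(pk, fs, g)
  # brute force: peak bin [s, s+2000) vs feature [start, end)
  overlap <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  pkiv <- cbind(pk$start, pk$start + 2000)
  fiv <- cbind(fs$start, fs$end)
  hits <- outer(1:3, 1:2, Vectorize(function(p, f)
    overlap(pkiv[p, 1], pkiv[p, 2], fiv[f, 1], fiv[f, 2])))
  expect_equal(got$peak_overlap, sum(rowSums(hits) > 0))
  expect_equal(got$features_hit, sum(colSums(hits) > 0))
  expect_equal(got, list(peak_overlap = 2L, features_hit = 2L))
  # trivial cases
  expect_equal(feature_hit_count(pk, feature_set(character(), numeric(),
                                                 numeric()), g)$peak_overlap, 0L)
  whole <- feature_set("chrA", 0, 40000)
  expect_equal(feature_hit_count(pk, whole, g),
               list(peak_overlap = 3L, features_hit = 1L))
})

test_that("permutation test: degenerate feature sets give p = 1", {
  g <- binned_genome("chrA", 100000, bin_size = 2000)
  pk <- peaks_at(g, "chrA", c(3, 10, 20))
  whole <- feature_set("chrA", 0, 100000)
  r <- permutation_overlap_test(pk, whole, g, n_permutations = 50, seed = 1)
  expect_equal(r$observed, 3L)
  expect_true(all(r$null == 3))
  expect_equal(r$p_value, 1)
  empty <- feature_set(character(), numeric(), numeric())
  r0 <- permutation_overlap_test(pk, empty, g, n_permutations = 50, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_true(all(r0$null == 0))
  expect_equal(r0$p_value, 1)
})

test_that("permutation null matches the closed-form binomial mean", {
  g <- binned_genome(c("c1", "c2"), c(300000, 300000), bin_size = 2000)
  # features covering a fraction f of bins; random peaks -> E[overlap] = f * n
  fs <- feature_set(rep("c1", 15), seq(0, 280000, by = 20000),
                    seq(0, 280000, by = 20000) + 10000)
  covered <- sum(tetherscan:::feature_bin_mask(fs, g))
  f <- covered / g$n_host_bins
  pk <- peaks_at(g, "c2", c(5, 25, 50, 75, 100, 125))
  r <- permutation_overlap_test(pk, fs, g, n_permutations = 2000, seed = 3)
  expect_lt(abs(mean(r$null) - f * 6), 3 * sd(r$null) / sqrt(2000) * 3 + 0.05)
  # determinism and internal consistency
  r2 <- permutation_overlap_test(pk, fs, g, n_permutations = 2000, seed = 3)
  expect_identical(r$null, r2$null)
  expect_equal(r$p_value, sum(r$null >= r$observed) / r$n_permutations)
  expect_equal(r$p_value, r$n_ge_observed / 2000)
})

test_that("zero exceedances are flagged as p below resolution", {
  g <- binned_genome("chrA", 400000, bin_size = 2000)
  fs <- feature_set("chrA", 0, 2000)     # single bin
  pk <- peaks_at(g, "chrA", 0:9)
  r <- permutation_overlap_test(pk, fs, g, n_permutations = 200, seed = 5)
  expect_equal(r$observed, 1L)
  expect_equal(r$p_value, sum(r$null >= 1) / 200)
  if (r$n_ge_observed == 0) expect_match(r$note, "p < 1/200")
})

test_that("stratified sampling preserves per-chromosome peak counts", {
  g <- binned_genome(c("c1", "c2"), c(100000, 100000), bin_size = 2000)
  pk <- peaks_at(g, "c1", c(2, 10, 20))
  fs <- feature_set("c2", 0, 100000)     # all of c2
  r <- permutation_overlap_test(pk, fs, g, n_permutations = 100, seed = 1,
                                stratify_by_chrom = TRUE)
  # all peaks on c1, feature on c2 -> stratified null overlap is always 0
  expect_true(all(r$null == 0))
  expect_equal(r$observed, 0L)
})

test_that("null p-values are uniform when overlap counts are well spread", {
  # 200 random peaks against features covering ~half the genome: the
  # discrete permutation p-value support is fine enough for a KS check
  g <- binned_genome(sprintf("c%02d", 1:4), rep(3e6, 4), bin_size = 2000)
  nh <- g$n_host_bins
  starts <- seq(0, 2.99e6, by = 8000)
  fs <- feature_set(rep(sprintf("c%02d", 1:4), each = length(starts)),
                    rep(starts, 4), rep(starts + 4000, 4))
  hit <- tetherscan:::feature_bin_mask(fs, g)
  set.seed(99)
  pvals <- replicate(200, {
    bins <- sample.int(nh, 200)
    loc <- tetherscan:::host_bin_locate(g, bins)
    pk <- structure(data.frame(chrom = loc$chrom, bin = loc$bin,
                               start = loc$start, score = 1),
                    class = c("peak_set", "data.frame"),
                    height = 0.8, distance = 2L, genome = g)
    permutation_overlap_test(pk, fs, g, n_permutations = 400,
                             seed = sample.int(1e6, 1))$p_value
  })
  ks <- max(abs(sort(pvals) - (1:200) / 200),
            abs(sort(pvals) - (0:199) / 200))
  expect_lt(ks, 0.1)
})
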