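test_that("simulated genomes are deterministic and meet the annotation targets", {
  a <- simulate_genome(seed = 4)
  b <- simulate_genome(seed = 4)
  expect_identical(a$genes, b$genes)
  expect_identical(unname(a$genome$length), unname(b$genome$length))
  # requested number of long genes, exactly
  expect_equal(sum(a$genes$length > 7000), 20)
  c30 <- simulate_genome(n_long_genes = 30, seed = 4)
  expect_equal(sum(c30$genes$length > 7000), 30)
  # ~1 kb median gene length
  expect_gt(median(a$genes$length), 800)
  expect_lt(median(a$genes$length), 1200)
  # genes do not overlap and stay inside chromosomes
  for (cn in unique(a$genes$chrom)) {
    gg <- a$genes[a$genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= head(gg$end, -1)))
    expect_true(all(gg$end <= a$genome$length[cn]))
  }
  # degenerate length distribution pins the median exactly
  d <- simulate_genome(n_chromosomes = 2, total_size = 2e6, n_long_genes = 0,
                       gene_params = list(sdlog = 1e-9), seed = 1)
  expect_equal(median(d$genes$length), 1000)
  # one centromere per chromosome
  expect_equal(nrow(a$centromeres), 16)
})

test_that("long genes are preferentially lowly expressed", {
  a <- simulate_genome(seed = 6)
  long <- a$genes$length > 7000
  expect_lt(median(a$genes$expression[long]),
            median(a$genes$expression[!long]))
})

test_that("truth sites land inside long lowly expressed genes, well separated", {
  syn <- simulate_genome(seed = 2)
  truth <- synthetic_truth(syn$genome, syn$genes, n_sites = 30, seed = 2)
  expect_equal(nrow(truth), 30)
  long <- long_gene_group(syn$genes, 7000)
  hit <- mapply(function(cn, p) any(long$chrom == cn & long$start <= p &
                                      long$end > p), truth$chrom, truth$pos)
  expect_true(all(hit))
  sep <- unlist(tapply(truth$host_bin, truth$chrom, function(b)
    if (length(b) > 1) diff(sort(b)) else NULL))
  if (length(sep)) expect_true(all(sep >= 3))
  expect_error(synthetic_truth(syn$genome, syn$genes, n_sites = 500),
               "cannot place")
})

test_that("simulated libraries verify against their truth", {
  sc <- standard_scenario(1)
  v <- verify_synthetic(sc$sim)
  expect_true(v$ok)
  expect_equal(v$plasmid_fraction, 0.02, tolerance = 0.05)
  expect_equal(v$site_fold, 3, tolerance = 0.3)
  # determinism of the full simulation path
  sim2 <- simulate_contact_data(sc$syn$genome, sc$truth, depth = 5e6,
                                seed = 1)
  expect_identical(as.matrix(sim2$matrix$upper[1:50, 1:50]),
                   as.matrix(sc$sim$matrix$upper[1:50, 1:50]))
})

test_that("with no implanted sites the peak caller stays near-silent", {
  fp <- sapply(1:3, function(s) {
    syn <- simulate_genome(n_chromosomes = 4, total_size = 3e6, seed = s)
    truth <- synthetic_truth(syn$genome, syn$genes, n_sites = 2, fold = 1,
                             seed = s)
    sim <- simulate_contact_data(syn$genome, truth, depth = 1.25e6, seed = s)
    prof <- compute_contact_profile(sim$matrix, sim$stats)
    nrow(call_peaks(interpolate_profile(prof)))
  })
  expect_lt(mean(fp), 2)
})

test_that("the top-scoring bin is the implanted site at high fold and depth", {
  syn <- simulate_genome(n_chromosomes = 4, total_size = 3e6, seed = 9)
  truth <- synthetic_truth(syn$genome, syn$genes, n_sites = 1, fold = 10,
                           seed = 9)
  sim <- simulate_contact_data(syn$genome, truth, depth = 4e6, seed = 9)
  prof <- compute_contact_profile(sim$matrix, sim$stats)
  expect_equal(which.max(prof$score), truth$host_bin[1])
})

test_that("doubling depth shrinks the profile noise", {
  syn <- simulate_genome(n_chromosomes = 4, total_size = 3e6, seed = 10)
  truth <- synthetic_truth(syn$genome, syn$genes, n_sites = 2, fold = 1,
                           seed = 10)
  dev <- sapply(c(1e6, 4e6), function(d) {
    sim <- simulate_contact_data(syn$genome, truth, depth = d, seed = 10)
    prof <- compute_contact_profile(sim$matrix, sim$stats)
    v <- prof$score[prof$valid]
    sd(v) / mean(v)
  })
  expect_lt(dev[2], dev[1])
})

test_that("RNA tracks follow gene bodies and CPM-normalize", {
  g <- binned_genome("chrA", 20000, bin_size = 2000)
  genes <- feature_set("chrA", 4000, 10000, name = "g1", class = "gene",
                       expression = 100)
  tr <- simulate_rna_track(g, genes, noise_sdlog = 0, seed = 1, cpm = FALSE)
  expect_equal(tr$values, c(0, 0, 100, 100, 100, 0, 0, 0, 0, 0))
  cpm <- simulate_rna_track(g, genes, noise_sdlog = 0, seed = 1)
  expect_equal(sum(cpm$values), 1e6)
})

test_that("screen tracks implant the requested multiplicative effect", {
  syn <- simulate_genome(n_chromosomes = 2, total_size = 1e6, seed = 11)
  truth <- synthetic_truth(syn$genome, syn$genes, n_sites = 4, seed = 11)
  tr <- simulate_screen_track(syn$genome, truth, effect = 4, noise_sd = 0,
                              seed = 11)
  expect_equal(tr$values[truth$host_bin], rep(4, 4))
  off_site <- setdiff(seq_along(tr$values),
                      as.vector(outer(truth$host_bin, -2:2, `+`)))
  expect_true(all(tr$values[off_site] == 1))
})

test_that("stability assays are binomial with the requested retention", {
  all_in <- simulate_stability_assay(5, 100, 1, seed = 1)
  expect_true(all(all_in$positive == 100))
  none <- simulate_stability_assay(5, 100, 0, seed = 1)
  expect_true(all(none$positive == 0))
  sim <- simulate_stability_assay(5, 200, 0.4, seed = 42)
  p <- retention_proportion(sim)
  expect_gt(p$upper, 0.4)
  expect_lt(p$lower, 0.4)
  expect_identical(simulate_stability_assay(5, 200, 0.4, seed = 42)$positive,
                   sim$positive)
})
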