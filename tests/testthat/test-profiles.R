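test_that("window stacks align the centre and pad chromosome ends with NA", {
  g <- binned_genome("chrA", 100000, bin_size = 2000)   # 50 bins
  tr <- signal_track(g, seq_len(50))
  # mid-chromosome locus: row is the raw slice
  st <- window_stack(tr, data.frame(chrom = "chrA", pos = 50000), flank = 8000)
  expect_equal(ncol(st), 9)
  expect_equal(as.numeric(st[1, ]), 22:30)
  expect_equal(attr(st, "offsets")[5], 0)
  expect_equal(as.numeric(st[1, 5]), 26)               # centre = locus bin
  # locus in bin 0: left flank missing, never wrapped
  st0 <- window_stack(tr, data.frame(chrom = "chrA", pos = 0), flank = 8000)
  expect_equal(as.numeric(st0[1, ]), c(NA, NA, NA, NA, 1, 2, 3, 4, 5))
  # unknown chromosome rejected
  expect_error(window_stack(tr, data.frame(chrom = "chrZ", pos = 0)),
               "unknown")
})

test_that("masked bins propagate into windows as NA", {
  g <- binned_genome("chrA", 20000, bin_size = 2000)
  tr <- signal_track(g, c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10))
  st <- window_stack(tr, data.frame(chrom = "chrA", pos = 8000), flank = 4000)
  expect_equal(as.numeric(st[1, ]), c(NA, 4, 5, 6, 7))
})

test_that("mean profile: constant track gives the constant with zero CI", {
  g <- binned_genome("chrA", 100000, bin_size = 2000)
  tr <- signal_track(g, rep(1, 50))
  st <- window_stack(tr, data.frame(chrom = "chrA", pos = c(40000, 60000)),
                     flank = 10000)
  mp <- mean_profile(st)
  expect_true(all(mp$mean == 1))
  expect_true(all(mp$ci == 0))
  expect_true(all(mp$n_valid == 2))
})

test_that("mean profile CI matches the hand SEM formula and NA columns stay NA", {
  st <- structure(rbind(c(0, NA), c(2, NA)),
                  class = c("locus_stack", "matrix"),
                  offsets = c(0, 2000), flank = 2000, bin_size = 2000)
  mp <- mean_profile(st)
  expect_equal(mp$mean[1], 1)
  expect_equal(mp$ci[1], 1.96 * sd(c(0, 2)) / sqrt(2))  # 1.96 * sqrt(2)/sqrt(2)
  expect_true(is.na(mp$mean[2]))
  expect_equal(mp$n_valid, c(2L, 0L))
})

test_that("heatmap sorting is by central mean, descending and stable", {
  g <- binned_genome("chrA", 200000, bin_size = 2000)
  v <- rep(0, 100); v[20 + -2:2] <- 1; v[50 + -2:2] <- 3; v[80 + -2:2] <- 2
  tr <- signal_track(g, v)
  loci <- data.frame(chrom = "chrA", pos = c(20, 50, 80) * 2000 - 2000)
  st <- window_stack(tr, loci, flank = 20000)
  sh <- sorted_heatmap(st, score_flank = 10000)
  # brute-force order of central means
  centr <- abs(attr(st, "offsets")) <= 10000
  oracle <- order(-rowMeans(st[, centr], na.rm = TRUE))
  expect_equal(sh$order, oracle)
  expect_equal(sh$order, c(2, 3, 1))
  # ties keep input order
  trc <- signal_track(g, rep(2, 100))
  stc <- window_stack(trc, loci, flank = 20000)
  expect_equal(sorted_heatmap(stc, 10000)$order, 1:3)
})

test_that("pileup over a uniform inter-chromosomal matrix is ~1 everywhere", {
  g <- binned_genome(c("c1", "c2"), c(60000, 60000), bin_size = 2000)
  n1 <- 30
  i <- rep(1:n1, each = n1); j <- rep(n1 + 1:n1, times = n1)
  cm <- contact_matrix(g, i, j, rep(4, length(i)))   # all inter cells = 4
  pk <- peaks_at(g, c("c1", "c2"), c(15, 15))
  pu <- pileup_pairs(cm, pk, mode = "inter", window = 5)
  expect_equal(attr(pu, "n_pairs"), 1L)
  expect_true(all(abs(pu - 1) < 1e-9))
})

test_that("pileup divides by the distance-decay expectation in intra mode", {
  g <- binned_genome("c1", 200000, bin_size = 2000)   # 100 bins
  # counts exactly equal to a decay model f(d) = 100 - d
  idx <- which(upper.tri(matrix(0, 100, 100), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  cm <- contact_matrix(g, idx[, 1], idx[, 2], 100 - d)
  pk <- peaks_at(g, "c1", c(20, 60))
  pu <- pileup_pairs(cm, pk, mode = "intra", window = 4)
  # all pair distances in the window are < 100 bins: exact expectation
  expect_true(all(abs(pu - 1) < 1e-6))
  # intra mode with peaks on different chromosomes -> empty with warning
  g2 <- binned_genome(c("c1", "c2"), c(60000, 60000), bin_size = 2000)
  cm2 <- contact_matrix(g2, 1, 31, 5)
  pk2 <- peaks_at(g2, c("c1", "c2"), c(10, 10))
  expect_warning(pu2 <- pileup_pairs(cm2, pk2, mode = "intra"), "no peak pair")
  expect_equal(length(pu2), 0)
})

test_that("a bright pixel at one of two pairs averages against the background", {
  g <- binned_genome(c("c1", "c2", "c3"), rep(60000, 3), bin_size = 2000)
  n <- 30
  # uniform inter background = 2 everywhere, one bright pixel at (c1:15, c2:15)
  ij <- expand.grid(a = 1:n, b = (n + 1):(3 * n))
  extra <- expand.grid(a = (n + 1):(2 * n), b = (2 * n + 1):(3 * n))
  i <- c(ij$a, extra$a); j <- c(ij$b, extra$b)
  x <- rep(2, length(i))
  bright <- which(i == 15 & j == n + 15)
  x[bright] <- 42
  cm <- contact_matrix(g, i, j, x)
  pk <- peaks_at(g, c("c1", "c2", "c3"), c(14, 14, 14))  # bins 15 (1-based)
  pu <- pileup_pairs(cm, pk, mode = "inter", window = 3)
  e <- tetherscan:::inter_expected(cm)
  centre <- 4
  # three pairs: (c1,c2) has the bright pixel, the others are background
  expect_equal(pu[centre, centre], (42 / e + 2 / e + 2 / e) / 3,
               tolerance = 1e-9)
  off <- pu[centre, centre + 1]
  expect_equal(off, 2 / e, tolerance = 1e-9)
})

test_that("gene contact stats reproduce brute-force Spearman ranks", {
  g <- binned_genome("chrA", 40000, bin_size = 2000)
  genes <- feature_set("chrA", c(0, 8000, 16000, 24000, 32000),
                       c(6000, 14000, 22000, 30000, 38000),
                       name = paste0("g", 1:5), class = "gene",
                       expression = c(5, 50, 2, 80, 20))
  # paint each gene body's bins with its intended score
  score <- rep(1, 20)
  vals <- c(2, 1, 4, 0.5, 3)
  for (k in 1:5) {
    ids <- (genes$start[k] %/% 2000):((genes$end[k] - 1) %/% 2000) + 1
    score[ids] <- vals[k]
  }
  prof <- profile_from_scores(g, score)
  gs <- gene_contact_stats(prof, genes)
  expect_equal(gs$table$score, c(2, 1, 4, 0.5, 3))
  # brute-force rank formula (no ties): rho = 1 - 6*sum(d^2)/(n(n^2-1))
  rho_oracle <- function(a, b) {
    d <- rank(a) - rank(b); 1 - 6 * sum(d^2) / (length(a) * (length(a)^2 - 1))
  }
  expect_equal(gs$correlations$rho[1],
               rho_oracle(gs$table$score, log1p(gs$table$expression)))
  # score == length -> Spearman(score, length) = 1
  genes2 <- genes; genes2$length <- c(2, 1, 4, 0.5, 3) * 1000
  gs2 <- gene_contact_stats(prof, genes2)
  expect_equal(gs2$correlations$rho[2], 1)
  # all-equal scores -> rho 0 by the tie convention
  profc <- profile_from_scores(g, rep(2, 20))
  gsc <- gene_contact_stats(profc, genes)
  expect_equal(gsc$correlations$rho, c(0, 0))
  expect_equal(gsc$correlations$p_value, c(1, 1))
})

test_that("genes without valid bins are excluded with a message", {
  g <- binned_genome("chrA", 20000, bin_size = 2000)
  genes <- feature_set("chrA", c(0, 10000), c(6000, 16000),
                       name = c("ok", "masked"), expression = c(1, 2))
  prof <- profile_from_scores(g, c(1, 1, 1, NA, NA, NA, NA, NA, 1, 1))
  expect_message(gs <- gene_contact_stats(prof, genes), "1 gene")
  expect_equal(gs$table$name, "ok")
})

test_that("GC fractions count bases exactly and ignore ambiguity codes", {
  g <- binned_genome("chrA", 40000, bin_size = 2000)
  seq_a <- paste(rep(c("G", "C"), 10000), collapse = "")     # all GC
  dna <- Biostrings::DNAStringSet(c(chrA = seq_a))
  pk <- peaks_at(g, "chrA", 10)
  r <- gc_windows(dna, pk, window = 4000)
  expect_equal(r$hotspot_gc, 1.0)
  expect_true(all(r$genome_gc == 1.0))
  # AT-only window -> 0; brute-force oracle on a mixed toy
  toy <- "ATGCNATGGC"
  counts <- table(strsplit(toy, "")[[1]])
  oracle <- (counts[["G"]] + counts[["C"]]) /
    (counts[["A"]] + counts[["T"]] + counts[["G"]] + counts[["C"]])
  expect_equal(tetherscan:::gc_fraction(Biostrings::DNAString(toy)),
               unname(oracle))
  expect_equal(tetherscan:::gc_fraction(Biostrings::DNAString("ATAT")), 0)
  expect_true(is.na(tetherscan:::gc_fraction(Biostrings::DNAString("NNN"))))
  # GC + AT = 1 on unambiguous windows
  set.seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  gc <- tetherscan:::gc_fraction(Biostrings::DNAString(rnd))
  at <- tetherscan:::gc_fraction(Biostrings::DNAString(chartr("ACGT", "GTAC",
                                                              rnd)))
  expect_equal(gc + at, 1)
})
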