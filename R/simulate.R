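# Synthetic data with known tether sites.
#
# The generator emulates the statistical structure the analysis assumes:
# a ~12 Mb host genome in 16 chromosomes binned at 2 kb carrying a small
# episomal contig; genes with a ~1 kb median length and a configurable
# number of long (>7 kb) genes that are preferentially lowly expressed;
# a contact library in which the plasmid's trans contacts are uniform over
# host coverage except at tether sites, where they are boosted by a
# triangular kernel; and plating assays with binomial retention. Every
# dataset carries its ground truth so recovery can be verified.

#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package's simulations flows from a single seed via
#' this splitting scheme, so any stage is independently reproducible.
#' @param seed master seed (integer).
#' @param k child index (integer >= 1), possibly a vector.
#' @return integer seed(s) < 2^31.
#' @export
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 1000003 * as.numeric(k)) %% 2147483629) + 1L
}

#' Simulate a host genome, gene annotation and expression levels
#'
#' Chromosome lengths are drawn from a gamma distribution and scaled to the
#' requested total. Non-overlapping genes are placed first-fit with
#' log-normal lengths calibrated to a ~1 kb median; exactly
#' \code{n_long_genes} genes longer than 7 kb are included, and each long
#' gene is assigned an expression value from the low tail of the expression
#' distribution with probability \code{p_long_low} (long genes at hotspots
#' of episome contact are observed to be lowly expressed). A centromere
#' position is drawn per chromosome, and a plasmid contig is appended.
#'
#' @param n_chromosomes number of host chromosomes (default 16).
#' @param total_size total host genome size in bp (default 12 Mb).
#' @param bin_size bin width in bp (default 2000).
#' @param n_long_genes number of genes strictly longer than 7 kb (default 20).
#' @param gene_params list overriding gene-model defaults:
#'   \code{median_length} (1000), \code{sdlog} (0.65), \code{long_range}
#'   (c(8000, 16000)), \code{occupancy} (0.55), \code{gap_mean} (400),
#'   \code{expr_meanlog} (log(50)), \code{expr_sdlog} (1.2),
#'   \code{p_long_low} (0.8), \code{low_quantile} (0.2).
#' @param plasmid_name,plasmid_size the episomal contig (6.3 kb default,
#'   the natural 2-micron size).
#' @param seed RNG seed.
#' @return list(genome, genes, centromeres); \code{genes} is a
#'   \code{feature_set} with expression and strand columns.
#' @export
simulate_genome <- function(n_chromosomes = 16, total_size = 12e6,
                            bin_size = 2000, n_long_genes = 20,
                            gene_params = list(),
                            plasmid_name = "plasmid_2u", plasmid_size = 6300,
                            seed = 1L) {
  stopifnot(total_size >= n_chromosomes * bin_size * 10)
  gp <- utils::modifyList(list(
    median_length = 1000, sdlog = 0.65, long_range = c(8000, 16000),
    occupancy = 0.55, gap_mean = 400, expr_meanlog = log(50),
    expr_sdlog = 1.2, p_long_low = 0.8, low_quantile = 0.2), gene_params)
  set.seed(split_seed(seed, 1))
  # chromosome lengths
  wl <- stats::rgamma(n_chromosomes, shape = 8, rate = 8)
  len <- pmax(round(total_size * wl / sum(wl)), 40 * bin_size)
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  genome <- binned_genome(c(chroms, plasmid_name), c(len, plasmid_size),
                          bin_size = bin_size, plasmids = plasmid_name)
  # gene length pool: short genes truncated below the long-gene threshold
  n_short <- max(0, round(gp$occupancy * sum(len) /
                            (gp$median_length * exp(gp$sdlog^2 / 2))) - n_long_genes)
  short <- stats::rlnorm(n_short, log(gp$median_length), gp$sdlog)
  while (any(short > 6900))
    short[short > 6900] <- stats::rlnorm(sum(short > 6900),
                                         log(gp$median_length), gp$sdlog)
  long <- stats::runif(n_long_genes, gp$long_range[1], gp$long_range[2])
  pool <- round(pmax(c(short, long), 100))
  is_long <- c(rep(FALSE, length(short)), rep(TRUE, n_long_genes))
  ord <- sample.int(length(pool))
  pool <- pool[ord]; is_long <- is_long[ord]
  # first-fit placement, per chromosome
  res_chrom <- character(); res_start <- numeric(); res_len <- numeric()
  res_long <- logical()
  placed <- rep(FALSE, length(pool))
  for (ci in seq_len(n_chromosomes)) {
    cursor <- round(stats::rexp(1, 1 / gp$gap_mean)) + 1000
    L <- len[ci]
    repeat {
      cand <- which(!placed & pool <= L - cursor - 1000)
      if (!length(cand)) break
      k <- cand[1]
      placed[k] <- TRUE
      res_chrom <- c(res_chrom, chroms[ci])
      res_start <- c(res_start, cursor)
      res_len <- c(res_len, pool[k])
      res_long <- c(res_long, is_long[k])
      cursor <- cursor + pool[k] + round(stats::rexp(1, 1 / gp$gap_mean)) + 50
    }
  }
  if (!all(placed[is_long]))
    stop("infeasible packing: not all long genes fit the genome")
  n <- length(res_start)
  expr <- stats::rlnorm(n, gp$expr_meanlog, gp$expr_sdlog)
  lowq <- stats::quantile(expr, gp$low_quantile)
  low_assign <- res_long & stats::runif(n) < gp$p_long_low
  expr[low_assign] <- stats::runif(sum(low_assign),
                                   stats::quantile(expr, 0.01), lowq)
  genes <- feature_set(res_chrom, res_start, res_start + res_len,
                       name = sprintf("gene%05d", seq_len(n)),
                       class = "gene", expression = expr,
                       strand = sample(c("+", "-"), n, TRUE),
                       genome = genome)
  cen_pos <- round(len * stats::runif(n_chromosomes, 0.4, 0.6))
  centromeres <- feature_set(chroms, cen_pos, cen_pos + 120,
                             name = sprintf("CEN%02d", seq_len(n_chromosomes)),
                             class = "centromere", genome = genome)
  list(genome = genome, genes = genes, centromeres = centromeres)
}

#' Define ground-truth tether sites
#'
#' Places \code{n_sites} tether sites inside the most lowly expressed long
#' (>7 kb) genes: one site mid-gene; when more sites are requested than
#' there are long genes, genes of >= 4.5 bins (9 kb at 2 kb bins) host two
#' sites at their one-sixth and five-sixth points, keeping implanted sites
#' >= 3 bins apart so each remains a separate local maximum. Records the
#' background model parameters used by
#' \code{\link{simulate_contact_data}}.
#'
#' @param genome a \code{binned_genome}.
#' @param genes the gene \code{feature_set}.
#' @param n_sites number of tether sites (default 30).
#' @param fold per-site fold enrichment of plasmid contact (>= 1, default 3).
#' @param plasmid_fraction plasmid share of library pair events (default
#'   0.02).
#' @param cis_fraction fraction of plasmid-involving pairs that are
#'   intra-plasmid (default 0.275).
#' @param coverage_shape gamma shape of per-bin coverage heterogeneity
#'   (default 20; larger = more uniform).
#' @param kernel_halfwidth half-width in bins of the triangular contact
#'   kernel around each site (default 2: weights 1, 1/2, 0).
#' @param min_length strict long-gene threshold in bp (default 7000).
#' @param seed RNG seed (site jitter only; placement is deterministic).
#' @return an object of class \code{synthetic_truth}: data.frame of sites
#'   (chrom, pos, host_bin, fold) plus a \code{params} attribute.
#' @export
synthetic_truth <- function(genome, genes, n_sites = 30, fold = 3,
                            plasmid_fraction = 0.02, cis_fraction = 0.275,
                            coverage_shape = 20, kernel_halfwidth = 2,
                            min_length = 7000, seed = 1L) {
  stopifnot(fold >= 1)
  long <- long_gene_group(genes, min_length)
  long <- long[order(long$expression), , drop = FALSE]
  bs <- genome$bin_size
  two_ok <- long$length >= 4.5 * bs
  capacity <- nrow(long) + sum(two_ok)
  if (n_sites > capacity)
    stop("cannot place ", n_sites, " sites in ", nrow(long), " long genes")
  n_two <- max(0, n_sites - nrow(long))
  two_genes <- which(two_ok)[seq_len(n_two)]
  pos <- numeric(); chrom <- character()
  for (k in seq_len(min(n_sites, nrow(long)))) {
    if (k %in% two_genes) {
      p <- long$start[k] + c(1, 5) / 6 * long$length[k]
    } else {
      p <- long$start[k] + 0.5 * long$length[k]
    }
    pos <- c(pos, p); chrom <- c(chrom, rep(long$chrom[k], length(p)))
  }
  pos <- pos[seq_len(n_sites)]; chrom <- chrom[seq_len(n_sites)]
  sites <- data.frame(chrom = chrom, pos = floor(pos),
                      host_bin = host_bin_index(genome, chrom, floor(pos)),
                      fold = fold, stringsAsFactors = FALSE)
  sites <- sites[order(match(sites$chrom, genome$chrom), sites$pos), ]
  rownames(sites) <- NULL
  structure(sites, class = c("synthetic_truth", "data.frame"),
            params = list(plasmid_fraction = plasmid_fraction,
                          cis_fraction = cis_fraction,
                          coverage_shape = coverage_shape,
                          kernel_halfwidth = kernel_halfwidth),
            seed = seed)
}

#' Simulate a contact library with implanted tether sites
#'
#' Pair events are drawn in three classes: intra-plasmid (cis), plasmid-host
#' (trans) and host-host. Per-bin host coverage weights are gamma-perturbed
#' uniform; both ends of host-host pairs are drawn independently from the
#' coverage weights, while the host end of each plasmid-host pair is drawn
#' from coverage times the tether kernel
#' \eqn{1 + (fold - 1) k(i)} (triangular \code{k} around each site). Counts
#' are Poisson by construction (multinomial thinning of a fixed depth); an
#' optional per-bin negative-binomial overdispersion multiplier is
#' available. The realized plasmid pair fraction matches
#' \code{plasmid_fraction} within binomial error, and the returned
#' \code{library_stats} are computed from the realized matrix.
#'
#' @param genome a \code{binned_genome} with one plasmid contig.
#' @param truth a \code{\link{synthetic_truth}} (its params set the
#'   background model).
#' @param depth total pair events (default 5e6).
#' @param seed RNG seed.
#' @param nb_size optional negative-binomial size for per-bin
#'   overdispersion (NULL = pure Poisson).
#' @return list(matrix, stats, truth, coverage_weights).
#' @export
simulate_contact_data <- function(genome, truth, depth = 5e6, seed = 1L,
                                  nb_size = NULL) {
  stopifnot(depth > 0)
  p <- attr(truth, "params")
  g <- genome
  nh <- g$n_host_bins
  if (nrow(truth) && any(truth$host_bin > nh))
    stop("tether site outside the host genome")
  set.seed(split_seed(seed, 2))
  w <- stats::rgamma(nh, shape = p$coverage_shape, rate = p$coverage_shape)
  if (!is.null(nb_size))
    w <- w * stats::rgamma(nh, shape = nb_size, rate = nb_size)
  m <- rep(1, nh)
  h <- p$kernel_halfwidth
  chrom_of <- host_bin_chrom(g)
  for (k in seq_len(nrow(truth))) {
    b <- truth$host_bin[k]
    off <- (-h):h
    tgt <- b + off
    ok <- tgt >= 1 & tgt <= nh & as.integer(chrom_of[pmax(pmin(tgt, nh), 1)]) ==
      as.integer(chrom_of[b])
    m[tgt[ok]] <- m[tgt[ok]] + (truth$fold[k] - 1) * (1 - abs(off[ok]) / h)
  }
  n_p <- stats::rbinom(1, depth, p$plasmid_fraction)
  Q <- stats::rbinom(1, n_p, p$cis_fraction)
  P <- n_p - Q
  H <- depth - n_p
  pb <- unlist(lapply(plasmid_chroms(g), function(cn)
    g$offset[cn] + seq_len(g$n_bins[cn])), use.names = FALSE)
  map <- host_to_flat(g)
  he <- sample.int(nh, P, replace = TRUE, prob = w * m)
  pe <- sample(pb, P, replace = TRUE)
  q1 <- sample(pb, Q, replace = TRUE)
  q2 <- sample(pb, Q, replace = TRUE)
  e1 <- sample.int(nh, H, replace = TRUE, prob = w)
  e2 <- sample.int(nh, H, replace = TRUE, prob = w)
  i <- c(map[he], q1, map[e1])
  j <- c(pe, q2, map[e2])
  cm <- contact_matrix(g, i, j, rep(1, length(i)))
  list(matrix = cm, stats = cm_library_stats(cm), truth = truth,
       coverage_weights = w)
}

#' Simulate an RNA coverage track from gene expression
#'
#' Per-bin value = length-weighted sum of the expression of covering genes
#' (zero between genes), optional multiplicative log-normal noise, then
#' CPM normalization.
#'
#' @param genome a \code{binned_genome}.
#' @param genes gene \code{feature_set} with expression.
#' @param noise_sdlog sdlog of multiplicative noise (0 = none).
#' @param seed RNG seed.
#' @param cpm CPM-normalize (default TRUE).
#' @return a \code{signal_track} (units CPM).
#' @export
simulate_rna_track <- function(genome, genes, noise_sdlog = 0.1, seed = 1L,
                               cpm = TRUE) {
  set.seed(split_seed(seed, 3))
  bs <- genome$bin_size
  vals <- numeric(genome$n_host_bins)
  for (k in seq_len(nrow(genes))) {
    cn <- genes$chrom[k]
    b0 <- genes$start[k] %/% bs; b1 <- (genes$end[k] - 1) %/% bs
    for (b in b0:b1) {
      cov <- min(genes$end[k], (b + 1) * bs) - max(genes$start[k], b * bs)
      id <- genome$host_offset[cn] + b + 1L
      vals[id] <- vals[id] + genes$expression[k] * cov / bs
    }
  }
  if (noise_sdlog > 0)
    vals <- vals * stats::rlnorm(length(vals), 0, noise_sdlog)
  tr <- signal_track(genome, vals, units = "CPM", name = "rna")
  if (cpm) cpm_normalize(tr) else tr
}

#' Simulate phased nucleosome and binding tracks around TSS
#'
#' On a fine-binned copy of the genome (default 5 bp), builds a nucleosome
#' occupancy signal with a damped cosine of the given period downstream of
#' every TSS, and a binding track that is the same oscillation shifted by
#' \code{phase_deg} degrees — emulating a protein positioned in register
#' with the nucleosomal array. Gaussian noise is added per bin.
#'
#' @param genome a \code{binned_genome} (its bin size is ignored here).
#' @param genes gene \code{feature_set} with strand; TSS = 5' end.
#' @param fine_bin fine bin size in bp (<= 50 recommended).
#' @param period nucleosome repeat length in bp (default 165).
#' @param phase_deg phase shift of the binding track (default 90).
#' @param decay_bp exponential damping length of the array (default 800).
#' @param reach_bp how far downstream of the TSS the array extends
#'   (default 1500).
#' @param noise_sd per-bin Gaussian noise sd (default 0.05).
#' @param seed RNG seed.
#' @return list(nucleosome, binding, tss, genome) where the tracks live on
#'   the fine-binned genome and \code{tss} is a data.frame(chrom, pos).
#' @export
simulate_phased_tracks <- function(genome, genes, fine_bin = 5, period = 165,
                                   phase_deg = 90, decay_bp = 800,
                                   reach_bp = 1500, noise_sd = 0.05,
                                   seed = 1L) {
  set.seed(split_seed(seed, 4))
  fg <- genome_rebin(genome, fine_bin)
  tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  dir <- ifelse(genes$strand == "+", 1, -1)
  nuc <- numeric(fg$n_host_bins)
  bind <- numeric(fg$n_host_bins)
  shift <- phase_deg / 360 * period
  for (k in seq_len(nrow(genes))) {
    cn <- genes$chrom[k]
    L <- unname(fg$length[cn])
    d <- seq(0, reach_bp, by = fine_bin)
    x <- tss_pos[k] + dir[k] * d
    ok <- x >= 0 & x < L
    id <- fg$host_offset[cn] + x[ok] %/% fine_bin + 1L
    damp <- exp(-d[ok] / decay_bp)
    nuc[id] <- nuc[id] + cos(2 * pi * d[ok] / period) * damp
    bind[id] <- bind[id] + cos(2 * pi * (d[ok] - shift) / period) * damp
  }
  nuc <- 1 + nuc + stats::rnorm(length(nuc), 0, noise_sd)
  bind <- 1 + bind + stats::rnorm(length(bind), 0, noise_sd)
  list(nucleosome = signal_track(fg, nuc, name = "nucleosome"),
       binding = signal_track(fg, bind, name = "binding"),
       tss = data.frame(chrom = genes$chrom, pos = tss_pos,
                        strand = genes$strand, stringsAsFactors = FALSE),
       genome = fg)
}

#' Simulate a screen track enriched or depleted at tether sites
#'
#' A homogeneous track (value ~ 1 plus Gaussian noise) multiplied by
#' \code{effect} over each site's kernel footprint; \code{effect > 1}
#' enriched, \code{< 1} depleted, \code{= 1} flat.
#'
#' @param genome a \code{binned_genome}.
#' @param truth a \code{synthetic_truth}.
#' @param effect multiplicative effect at site centres.
#' @param noise_sd Gaussian noise sd (default 0.05).
#' @param seed RNG seed.
#' @param name track name.
#' @return a \code{signal_track}.
#' @export
simulate_screen_track <- function(genome, truth, effect = 1, noise_sd = 0.05,
                                  seed = 1L, name = NULL) {
  set.seed(split_seed(seed, 5))
  nh <- genome$n_host_bins
  mult <- rep(1, nh)
  h <- attr(truth, "params")$kernel_halfwidth
  for (k in seq_len(nrow(truth))) {
    off <- (-h):h
    tgt <- truth$host_bin[k] + off
    ok <- tgt >= 1 & tgt <= nh
    kern <- 1 - abs(off[ok]) / h
    mult[tgt[ok]] <- mult[tgt[ok]] * (1 + (effect - 1) * kern)
  }
  vals <- pmax(stats::rnorm(nh, 1, noise_sd), 0) * mult
  signal_track(genome, vals, name = name)
}

#' Simulate a plating stability assay
#'
#' Per replicate, the number of plasmid-positive colonies is binomial with
#' the given retention probability.
#'
#' @param n_replicates number of replicates.
#' @param colonies_per_replicate colonies plated per replicate.
#' @param retention_prob probability a colony retains the plasmid, in [0,1].
#' @param seed RNG seed.
#' @param condition,timepoint labels.
#' @return a \code{stability_assay}.
#' @export
simulate_stability_assay <- function(n_replicates, colonies_per_replicate,
                                     retention_prob, seed = 1L,
                                     condition = "sim", timepoint = NA) {
  stopifnot(retention_prob >= 0, retention_prob <= 1)
  set.seed(split_seed(seed, 6))
  pos <- stats::rbinom(n_replicates, colonies_per_replicate, retention_prob)
  stability_assay(pos, rep(colonies_per_replicate, n_replicates),
                  condition = condition, timepoint = timepoint)
}

#' Verify a simulated contact library against its ground truth
#'
#' Re-derives the realized plasmid pair fraction and the per-site contact
#' enrichment (site score over the genome-wide median background) and
#' checks them against the truth parameters within the given tolerances.
#'
#' @param sim result of \code{\link{simulate_contact_data}}.
#' @param frac_tol relative tolerance on the plasmid fraction (default 0.1).
#' @param fold_tol relative tolerance on the median per-site realized fold
#'   (default 0.3).
#' @return list(ok, plasmid_fraction, target_fraction, site_fold,
#'   target_fold).
#' @export
verify_synthetic <- function(sim, frac_tol = 0.1, fold_tol = 0.3) {
  p <- attr(sim$truth, "params")
  frac <- sim$stats$n_plasmid / sim$stats$N_total
  prof <- compute_contact_profile(sim$matrix, sim$stats)
  bg <- stats::median(prof$score[prof$valid])
  site_fold <- stats::median(prof$score[sim$truth$host_bin] / bg, na.rm = TRUE)
  target_fold <- stats::median(sim$truth$fold)
  ok <- abs(frac - p$plasmid_fraction) <= frac_tol * p$plasmid_fraction &&
    abs(site_fold - target_fold) <= fold_tol * target_fold
  list(ok = ok, plasmid_fraction = frac,
       target_fraction = p$plasmid_fraction,
       site_fold = site_fold, target_fold = target_fold)
}
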