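#' Stack signal windows around loci
#'
#' Extracts the per-bin signal in windows of +/- \code{flank} bp centred on
#' each locus (default +/- 40 kb, the study's averaged-profile window). Where
#' a window crosses a chromosome end, or hits a masked bin, the cell is
#' \code{NA} — never wrapped or truncated. Extraction preserves locus order;
#' the centre column aligns to the locus bin.
#'
#' @param x a \code{signal_track} or \code{contact_profile}.
#' @param loci a \code{peak_set}, or a data.frame with columns \code{chrom}
#'   and \code{pos} (0-based bp).
#' @param flank half-window in bp.
#' @return a \code{locus_stack}: matrix (rows = loci, odd number of columns),
#'   with bp offsets as an attribute.
#' @export
window_stack <- function(x, loci, flank = 40000) {
  g <- x$genome
  vals <- if (inherits(x, "contact_profile")) x$score else x$values
  if (inherits(loci, "peak_set")) {
    chrom <- loci$chrom; pos <- loci$start
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(loci)))
    chrom <- loci$chrom; pos <- loci$pos
  }
  if (!all(chrom %in% host_chroms(g)))
    stop("locus on unknown or non-host chromosome: ",
         paste(setdiff(chrom, host_chroms(g)), collapse = ", "))
  w <- as.integer(round(flank / g$bin_size))
  center <- host_bin_index(g, chrom, pos)
  chrom_of <- host_bin_chrom(g)
  # per-host-bin chromosome bounds in host-bin ids
  lo_bound <- unname((g$host_offset[chrom]) + 1L)
  hi_bound <- unname(g$host_offset[chrom] + g$n_bins[chrom])
  m <- matrix(NA_real_, nrow = length(center), ncol = 2L * w + 1L)
  for (r in seq_along(center)) {
    idx <- (center[r] - w):(center[r] + w)
    ok <- idx >= lo_bound[r] & idx <= hi_bound[r]
    m[r, ok] <- vals[idx[ok]]
  }
  rownames(m) <- sprintf("%s:%d", chrom, as.integer(pos))
  structure(m, class = c("locus_stack", "matrix"),
            offsets = (-w:w) * g$bin_size, flank = flank,
            bin_size = g$bin_size)
}

#' Column-wise mean profile with confidence band
#'
#' Missing-ignoring column means with a 95% normal confidence half-width,
#' \code{1.96 * sd / sqrt(n_valid)}; columns with no valid value are
#' \code{NA}.
#'
#' @param stack a \code{locus_stack}.
#' @return data.frame(offset, mean, ci, n_valid).
#' @export
mean_profile <- function(stack) {
  stopifnot(nrow(stack) >= 1)
  n <- colSums(!is.na(stack))
  mu <- ifelse(n > 0, colMeans(stack, na.rm = TRUE), NA_real_)
  sdv <- apply(stack, 2, stats::sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sdv / sqrt(n), ifelse(n == 1, NA_real_, NA_real_))
  data.frame(offset = attr(stack, "offsets"), mean = mu, ci = ci, n_valid = n)
}

#' Sort stacked windows by central signal strength
#'
#' Rows are sorted in descending order of their mean signal over the central
#' +/- \code{score_flank} bp (default 20 kb, the study's heatmap ordering
#' window), ignoring missing values; the sort is stable so equal rows keep
#' their input order.
#'
#' @param stack a \code{locus_stack} with flank >= \code{score_flank}.
#' @param score_flank half-window (bp) used for the ordering score.
#' @return list(order, matrix, score): the row permutation, the reordered
#'   matrix, and the per-row ordering scores (input order).
#' @export
sorted_heatmap <- function(stack, score_flank = 20000) {
  stopifnot(attr(stack, "flank") >= score_flank)
  off <- attr(stack, "offsets")
  central <- abs(off) <= score_flank
  sc <- rowMeans(stack[, central, drop = FALSE], na.rm = TRUE)
  sc[is.nan(sc)] <- -Inf
  ord <- order(-sc)                      # radix sort: stable
  list(order = ord, matrix = stack[ord, , drop = FALSE], score = sc)
}

#' Observed/expected pile-up over peak pairs
#'
#' For every unordered pair of peaks in the requested configuration
#' (\code{intra}: same chromosome, \code{inter}: different chromosomes),
#' extracts the \code{(2*window+1)^2} contact submatrix centred on the pair,
#' divides it by its expected value and averages element-wise across pairs,
#' ignoring cells that fall outside either chromosome. Expected values:
#' \itemize{
#'   \item \code{inter}: the genome-wide mean inter-chromosomal count per
#'     host bin pair (zeros included);
#'   \item \code{intra}: the empirical distance-decay curve — the mean count
#'     at each genomic separation pooled over all host chromosomes, with
#'     geometric distance binning beyond 100 bins.
#' }
#' A matrix whose counts equal the expected model therefore piles up to 1
#' everywhere.
#'
#' @param cm a \code{contact_matrix}.
#' @param peaks a \code{peak_set} with >= 2 peaks.
#' @param mode "intra" or "inter".
#' @param window half-width of the window in bins (default 10).
#' @return matrix of averaged observed/expected ratios, with attributes
#'   \code{n_pairs} and \code{mode}; an empty (0 x 0) matrix with a warning
#'   if no pair exists in the requested mode.
#' @export
pileup_pairs <- function(cm, peaks, mode = c("inter", "intra"), window = 10L) {
  mode <- match.arg(mode)
  stopifnot(nrow(peaks) >= 2)
  g <- cm$genome
  w <- as.integer(window)
  flat <- host_to_flat(g)[peak_host_bins(peaks, g)]
  pr <- utils::combn(seq_along(flat), 2)
  same <- peaks$chrom[pr[1, ]] == peaks$chrom[pr[2, ]]
  pr <- pr[, if (mode == "intra") same else !same, drop = FALSE]
  if (!ncol(pr)) {
    warning("no peak pair in '", mode, "' configuration")
    return(structure(matrix(numeric(), 0, 0), n_pairs = 0L, mode = mode))
  }
  sym <- cm_sym(cm)
  Matrix::diag(sym) <- Matrix::diag(cm$upper)   # self-pairs count once
  loc <- bin_locate(g, flat)
  lo <- unname(g$offset[loc$chrom]) + 1L
  hi <- unname(g$offset[loc$chrom]) + unname(g$n_bins[loc$chrom])
  if (mode == "inter") {
    expected_fun <- local({
      e <- inter_expected(cm)
      function(d) rep(e, length(d))
    })
  } else {
    dd <- distance_decay(cm)
    expected_fun <- dd$expected
  }
  acc <- matrix(0, 2L * w + 1L, 2L * w + 1L)
  cnt <- matrix(0, 2L * w + 1L, 2L * w + 1L)
  for (k in seq_len(ncol(pr))) {
    a <- pr[1, k]; b <- pr[2, k]
    ia <- (flat[a] - w):(flat[a] + w)
    ib <- (flat[b] - w):(flat[b] + w)
    oka <- ia >= lo[a] & ia <= hi[a]
    okb <- ib >= lo[b] & ib <= hi[b]
    if (!any(oka) || !any(okb)) next
    sub <- as.matrix(sym[ia[oka], ib[okb], drop = FALSE])
    if (mode == "intra") {
      dmat <- abs(outer(ia[oka], ib[okb], `-`))
      emat <- matrix(expected_fun(as.vector(dmat)), nrow(sub), ncol(sub))
    } else {
      emat <- matrix(expected_fun(1), nrow(sub), ncol(sub))
    }
    ratio <- ifelse(emat > 0, sub / emat, NA_real_)
    cells <- which(oka) ; cellsb <- which(okb)
    ok_ratio <- !is.na(ratio)
    acc[cells, cellsb] <- acc[cells, cellsb] + ifelse(ok_ratio, ratio, 0)
    cnt[cells, cellsb] <- cnt[cells, cellsb] + ok_ratio
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(out, n_pairs = ncol(pr), mode = mode, window = w)
}

# genome-wide mean inter-chromosomal count per host bin pair (zeros included)
inter_expected <- function(cm) {
  g <- cm$genome
  u <- cm$upper
  hb <- host_to_flat(g)
  ti <- u@i + 1L
  tj <- rep.int(seq_len(ncol(u)), diff(u@p))
  host <- (ti %in% hb) & (tj %in% hb)
  chrom_i <- findInterval(ti - 1L, unname(g$offset))
  chrom_j <- findInterval(tj - 1L, unname(g$offset))
  inter <- host & chrom_i != chrom_j
  tot <- sum(u@x[inter])
  nb <- g$n_bins[host_chroms(g)]
  npairs <- (sum(nb)^2 - sum(nb^2)) / 2
  tot / npairs
}

#' Empirical distance-decay expectation for intra-chromosomal contacts
#'
#' Mean contact count per bin pair at each genomic separation (in bins),
#' pooled over all host chromosomes, zeros included. Separations beyond 100
#' bins are pooled in geometric bins (ratio 1.12) for stability in the
#' sparse tail.
#'
#' @param cm a \code{contact_matrix}.
#' @return list(table = data.frame(d_lo, d_hi, mean), expected = function(d)).
#' @export
distance_decay <- function(cm) {
  g <- cm$genome
  u <- cm$upper
  hb_chrom <- host_chroms(g)
  nb <- unname(g$n_bins[hb_chrom])
  maxd <- max(nb) - 1L
  breaks <- 0:min(100L, maxd)
  if (maxd > 100L) {
    b <- 100
    while (b < maxd) { b <- ceiling(b * 1.12); breaks <- c(breaks, min(b, maxd)) }
    breaks <- unique(breaks)
  }
  # number of intra pairs at each separation d, pooled over chromosomes
  npairs_at <- function(d) sum(pmax(nb - d, 0))
  bin_of_d <- function(d) findInterval(d, breaks)     # 1-based bin id
  nbin <- length(breaks)
  sums <- numeric(nbin); denom <- numeric(nbin)
  for (bi in seq_len(nbin)) {
    dlo <- breaks[bi]
    dhi <- if (bi < nbin) breaks[bi + 1L] - 1L else maxd
    denom[bi] <- sum(vapply(dlo:dhi, npairs_at, numeric(1)))
  }
  ti <- u@i + 1L
  tj <- rep.int(seq_len(ncol(u)), diff(u@p))
  chrom_i <- findInterval(ti - 1L, unname(g$offset))
  chrom_j <- findInterval(tj - 1L, unname(g$offset))
  intra <- chrom_i == chrom_j & !g$is_plasmid[g$chrom[chrom_i]]
  if (any(intra)) {
    d <- tj[intra] - ti[intra]
    bi <- bin_of_d(d)
    agg <- tapply(u@x[intra], bi, sum)
    sums[as.integer(names(agg))] <- agg
  }
  means <- ifelse(denom > 0, sums / denom, 0)
  list(table = data.frame(d_lo = breaks,
                          d_hi = c(breaks[-1L] - 1L, maxd),
                          mean = means),
       expected = function(d) means[pmin(pmax(findInterval(d, breaks), 1L), nbin)])
}

#' Per-gene contact score and its correlates
#'
#' For each gene, the contact score is the mean profile score over the bins
#' overlapping the gene body (missing-ignoring). Reports Spearman rank
#' correlations (average-rank ties) of score vs log(1 + expression) and
#' score vs gene length, with large-sample p-values. Genes with no valid
#' bin are excluded and counted in a message.
#'
#' @param profile a \code{contact_profile}.
#' @param genes a \code{feature_set} with length and expression columns (or
#'   pass \code{expression} separately, aligned by gene name).
#' @param expression optional named numeric vector of per-gene expression.
#' @return list(table, correlations) where correlations is a data.frame with
#'   rows "expression" and "length".
#' @export
gene_contact_stats <- function(profile, genes, expression = NULL) {
  g <- profile$genome
  if (!is.null(expression)) {
    genes$expression <- unname(expression[genes$name])
  }
  bins <- feature_host_bins(genes, g)
  score <- vapply(bins, function(b) {
    v <- profile$score[b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  drop <- is.na(score)
  if (any(drop))
    message("gene_contact_stats: ", sum(drop),
            " gene(s) with no valid bin excluded")
  tab <- data.frame(name = genes$name, chrom = genes$chrom,
                    length = genes$length, expression = genes$expression,
                    score = score, stringsAsFactors = FALSE)[!drop, ]
  cors <- rbind(
    spearman_row(tab$score, log1p(tab$expression), "expression"),
    spearman_row(tab$score, tab$length, "length"))
  list(table = tab, correlations = cors)
}

# Spearman with average-rank ties; rho := 0 (p := 1) when either side is
# constant, the tie convention for degenerate inputs
spearman_row <- function(x, y, label) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    return(data.frame(against = label, rho = 0, p_value = 1, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(against = label, rho = unname(ct$estimate),
             p_value = ct$p.value, n = length(x))
}
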