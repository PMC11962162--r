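#' Plasmid stability assay counts
#'
#' Per-replicate colony counts from a plating assay: colonies grown without
#' selection (\code{total}) and the subset scored plasmid-positive after
#' replica plating on selective medium (\code{positive}).
#'
#' @param positive,total integer vectors, one entry per replicate;
#'   \code{0 <= positive <= total}, \code{total > 0}.
#' @param condition condition label (e.g. "WT", "5toA").
#' @param timepoint optional time point label.
#' @return an object of class \code{stability_assay}.
#' @export
stability_assay <- function(positive, total, condition = "", timepoint = NA) {
  stopifnot(length(positive) == length(total), all(total > 0),
            all(positive >= 0), all(positive <= total))
  structure(list(positive = as.numeric(positive), total = as.numeric(total),
                 condition = condition, timepoint = timepoint),
            class = "stability_assay")
}

#' @export
print.stability_assay <- function(x, ...) {
  cat(sprintf("<stability_assay> '%s'%s: %d replicate(s), %g/%g positive (%.1f%%)\n",
              x$condition,
              if (!is.na(x$timepoint)) paste0(" @", x$timepoint) else "",
              length(x$total), sum(x$positive), sum(x$total),
              100 * sum(x$positive) / sum(x$total)))
  invisible(x)
}

#' Pooled plasmid retention proportion with Wilson CI
#'
#' Replicates are pooled: proportion = sum(positive) / sum(total), with a
#' 95% Wilson score interval.
#'
#' @param assay a \code{stability_assay}.
#' @return list(proportion, lower, upper, positive, total).
#' @export
retention_proportion <- function(assay) {
  pos <- sum(assay$positive); tot <- sum(assay$total)
  ci <- stats::prop.test(pos, tot, correct = FALSE)$conf.int
  list(proportion = pos / tot, lower = ci[1], upper = ci[2],
       positive = pos, total = tot)
}

#' Chi-square test comparing two stability assays
#'
#' Pearson chi-square (1 df, no continuity correction) on the pooled 2x2
#' table [positive, negative] x [condition a, condition b] of colony counts
#' — the counts themselves, not the per-replicate proportions. With
#' \code{per_replicate = TRUE} a Cochran-Mantel-Haenszel test stratified by
#' replicate is used instead.
#'
#' @param assay_a,assay_b \code{stability_assay}s.
#' @param per_replicate stratify by replicate (default FALSE: pooled).
#' @return list(statistic, df, p_value, table).
#' @export
stability_chi_square <- function(assay_a, assay_b, per_replicate = FALSE) {
  if (per_replicate) {
    stopifnot(length(assay_a$total) == length(assay_b$total))
    arr <- array(c(rbind(assay_a$positive, assay_a$total - assay_a$positive),
                   rbind(assay_b$positive, assay_b$total - assay_b$positive)),
                 dim = c(2, length(assay_a$total), 2))
    arr <- aperm(arr, c(1, 3, 2))
    mh <- stats::mantelhaen.test(arr, correct = FALSE)
    return(list(statistic = unname(mh$statistic), df = 1,
                p_value = mh$p.value, table = arr))
  }
  tab <- rbind(a = c(pos = sum(assay_a$positive),
                     neg = sum(assay_a$total) - sum(assay_a$positive)),
               b = c(pos = sum(assay_b$positive),
                     neg = sum(assay_b$total) - sum(assay_b$positive)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("degenerate 2x2 table: expected cell count 0")
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab)
}

#' Plasmid copy number per plasmid-positive cell
#'
#' From shotgun sequencing: the plasmid read proportion is compared with the
#' proportion expected if the plasmid were present at one copy per genome
#' (plasmid size / genome size; 6 kb / 12 Mb = 5e-4 for the yeast 2-micron
#' system), then divided by the fraction of cells that carry the plasmid:
#' \deqn{copies = \frac{read\_prop / (plasmid\_size/genome\_size)}{fraction\_positive}}
#'
#' @param read_prop plasmid read proportion, n_plasmid / N_total (>= 0).
#' @param plasmid_size,genome_size sizes in bp (> 0).
#' @param fraction_positive fraction of plasmid-carrying cells, in (0, 1].
#' @return an object of class \code{copy_number_estimate} with fields
#'   read_prop, expected_prop, fraction_positive, copies_per_positive_cell.
#' @export
copy_number_per_positive_cell <- function(read_prop, plasmid_size = 6000,
                                          genome_size = 12e6,
                                          fraction_positive = 1) {
  stopifnot(read_prop >= 0, plasmid_size > 0, genome_size > 0)
  if (fraction_positive <= 0 || fraction_positive > 1)
    stop("fraction_positive must be in (0, 1]")
  expected <- plasmid_size / genome_size
  structure(list(read_prop = read_prop, expected_prop = expected,
                 fraction_positive = fraction_positive,
                 copies_per_positive_cell =
                   (read_prop / expected) / fraction_positive),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_number_estimate> read prop %.4g / expected %.4g, %.0f%% cells positive -> %.2f copies/positive cell\n",
    x$read_prop, x$expected_prop, 100 * x$fraction_positive,
    x$copies_per_positive_cell))
  invisible(x)
}

#' Two-sample t-test on copy-number estimates
#'
#' Two-sided Student t-test with pooled variance (equal-variance form, the
#' default of the common reference implementations). Degenerate input with
#' zero pooled variance: equal means give t = 0, p = 1; different means are
#' an error.
#'
#' @param group_a,group_b numeric vectors of estimates (each length >= 2).
#' @return list(statistic, df, p_value).
#' @export
copy_number_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1))
    stop("zero variance with different means: t undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Read a stability-assay TSV
#'
#' Expected columns: condition, replicate, timepoint, positive, total
#' (tab-separated, \code{#} comments allowed). Returns one
#' \code{stability_assay} per (condition, timepoint).
#' @param path file path.
#' @return named list of \code{stability_assay}s.
#' @export
read_stability_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "positive", "total") %in% names(df)))
  if (!"timepoint" %in% names(df)) df$timepoint <- NA
  sp <- split(df, paste(df$condition, df$timepoint, sep = "@"))
  lapply(sp, function(d)
    stability_assay(d$positive, d$total, condition = d$condition[1],
                    timepoint = d$timepoint[1]))
}
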