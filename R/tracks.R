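#' Binned genomic signal track
#'
#' Per-host-bin real values (CPM, ratio, or dimensionless) with a validity
#' mask. The value vector has one entry per host bin; masked bins carry
#' \code{NA}, never a silent zero.
#'
#' @param genome a \code{binned_genome}.
#' @param values numeric vector of length \code{genome$n_host_bins};
#'   \code{NA} marks masked bins.
#' @param units free-text unit label (e.g. "CPM", "ratio").
#' @param name optional track name (used in messages).
#' @return An object of class \code{signal_track}.
#' @export
signal_track <- function(genome, values, units = "", name = NULL) {
  stopifnot(inherits(genome, "binned_genome"),
            length(values) == genome$n_host_bins)
  structure(list(genome = genome, values = as.numeric(values),
                 valid = !is.na(values), units = units, name = name),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track>%s %d host bins (%d masked)%s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              length(x$values), sum(!x$valid),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

#' Bin a bedGraph-style interval signal onto the genome
#'
#' Each bin's value is the length-weighted mean of the bedGraph values over
#' the bases of the bin that are covered; bins with no covering interval are
#' masked. Intervals extending past a chromosome end are truncated with a
#' warning; overlapping input intervals are rejected (the dialect is
#' ambiguous).
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open bp) and \code{value}, or a file path to a
#'   bedGraph file.
#' @param genome a \code{binned_genome}.
#' @param units,name passed to \code{\link{signal_track}}.
#' @return a \code{signal_track}.
#' @export
bin_track <- function(intervals, genome, units = "", name = NULL) {
  if (is.character(intervals)) intervals <- read_bedgraph(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  iv <- intervals[intervals$chrom %in% host_chroms(genome), , drop = FALSE]
  if (!all(is.finite(iv$value))) stop("bedGraph values must be finite")
  if (any(iv$start >= iv$end)) stop("bedGraph intervals must have start < end")
  over_end <- iv$end > unname(genome$length[iv$chrom])
  if (any(over_end)) {
    warning(sum(over_end), " interval(s) exceed chromosome end; truncated")
    iv$end[over_end] <- unname(genome$length[iv$chrom[over_end]])
    iv <- iv[iv$start < iv$end, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(start = iv$start + 1, end = iv$end))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("overlapping bedGraph intervals are not allowed")
  bs <- genome$bin_size
  num <- numeric(genome$n_host_bins)   # sum(value * covered bases)
  den <- numeric(genome$n_host_bins)   # covered bases
  for (k in seq_len(nrow(iv))) {
    cn <- iv$chrom[k]
    b0 <- iv$start[k] %/% bs
    b1 <- (iv$end[k] - 1) %/% bs
    for (b in b0:b1) {
      lo <- max(iv$start[k], b * bs)
      hi <- min(iv$end[k], (b + 1) * bs)
      id <- genome$host_offset[cn] + b + 1L
      num[id] <- num[id] + iv$value[k] * (hi - lo)
      den[id] <- den[id] + (hi - lo)
    }
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  signal_track(genome, vals, units = units, name = name)
}

#' Read a bedGraph file
#' @param path file path; \code{track} and \code{#} lines are skipped.
#' @return data.frame(chrom, start, end, value), coordinates 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  f <- strsplit(lines, "\t")
  data.frame(chrom = vapply(f, `[`, "", 1L),
             start = as.numeric(vapply(f, `[`, "", 2L)),
             end   = as.numeric(vapply(f, `[`, "", 3L)),
             value = as.numeric(vapply(f, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write a per-bin vector as bedGraph
#'
#' Masked (\code{NA}) bins are omitted from the output, matching bedGraph's
#' sparse convention.
#' @param x a \code{signal_track} or \code{contact_profile}.
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  g <- x$genome
  vals <- if (inherits(x, "contact_profile")) x$score else x$values
  loc <- host_bin_locate(g, seq_len(g$n_host_bins))
  keep <- !is.na(vals)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#tetherscan bedGraph, bin %d bp", g$bin_size), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", loc$chrom[keep], loc$start[keep],
                     loc$end[keep], vals[keep]), con)
  invisible(path)
}

#' CPM-normalize a track
#'
#' Rescales valid bin values so they sum to one million.
#' @param track a \code{signal_track}.
#' @export
cpm_normalize <- function(track) {
  s <- sum(track$values[track$valid])
  if (s <= 0) stop("cannot CPM-normalize a track with non-positive total")
  signal_track(track$genome, track$values / s * 1e6, units = "CPM",
               name = track$name)
}
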