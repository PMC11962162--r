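#' Binned genome description
#'
#' A \code{binned_genome} carries the chromosome names, lengths and a fixed
#' width binning that indexes every other structure in the package: contact
#' matrices, signal tracks, contact profiles and peak sets all refer to its
#' bins. Episomal contigs (plasmids) are part of the genome but flagged, so
#' host-genome quantities (\code{n_host_bins}, host bin indices) are always
#' derivable.
#'
#' Two indexings coexist:
#' \itemize{
#'   \item \emph{flat} bin ids: 1-based, contiguous over all contigs in the
#'     given order (plasmids included); this is the indexing of the contact
#'     matrix. The on-disk COO dialect writes these ids 0-based.
#'   \item \emph{host} bin ids: 1-based, contiguous over host chromosomes
#'     only; this is the indexing of tracks and contact profiles.
#' }
#' Base-pair coordinates are 0-based half-open throughout; bp position
#' \code{p} falls in bin ordinal \code{floor(p / bin_size)} (0-based within
#' its chromosome). Only the last bin of a chromosome may be shorter than
#' \code{bin_size}.
#'
#' @param chroms character vector of contig names, in order.
#' @param lengths integer vector of contig lengths in bp (same order).
#' @param bin_size bin width in bp (default 2000).
#' @param plasmids character vector naming the episomal contigs
#'   (must be a subset of \code{chroms}).
#' @return An object of class \code{binned_genome}.
#' @examples
#' g <- binned_genome(c("chrI", "plasmid"), c(10000, 6000),
#'                    bin_size = 2000, plasmids = "plasmid")
#' g$n_bins_total   # 8 = 5 + 3
#' @export
binned_genome <- function(chroms, lengths, bin_size = 2000L, plasmids = character()) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms),
            all(lengths >= 1), bin_size >= 1)
  if (!all(plasmids %in% chroms))
    stop("unknown plasmid contig(s): ", paste(setdiff(plasmids, chroms), collapse = ", "))
  lengths <- as.numeric(lengths)
  n_bins <- as.integer(ceiling(lengths / bin_size))
  offset <- c(0L, cumsum(n_bins))[seq_along(chroms)]
  is_plasmid <- chroms %in% plasmids
  host_n_bins <- ifelse(is_plasmid, 0L, n_bins)
  host_offset <- c(0L, cumsum(host_n_bins))[seq_along(chroms)]
  host_offset[is_plasmid] <- NA_integer_
  g <- structure(list(
    chrom       = chroms,
    length      = stats::setNames(lengths, chroms),
    bin_size    = as.integer(bin_size),
    is_plasmid  = stats::setNames(is_plasmid, chroms),
    n_bins      = stats::setNames(n_bins, chroms),
    offset      = stats::setNames(offset, chroms),
    host_offset = stats::setNames(host_offset, chroms),
    n_bins_total = sum(n_bins),
    n_host_bins  = sum(host_n_bins)
  ), class = "binned_genome")
  g
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("<binned_genome> %d contigs (%d host + %d plasmid), %s bp, bin %d bp, %d bins (%d host)\n",
              length(x$chrom), sum(!x$is_plasmid), sum(x$is_plasmid),
              format(sum(x$length), big.mark = ","), x$bin_size,
              x$n_bins_total, x$n_host_bins))
  invisible(x)
}

host_chroms <- function(genome) genome$chrom[!genome$is_plasmid]

plasmid_chroms <- function(genome) genome$chrom[genome$is_plasmid]

#' Flat bin id of a genomic position
#'
#' @param genome a \code{binned_genome}.
#' @param chrom chromosome name(s), recycled against \code{pos}.
#' @param pos 0-based bp position(s).
#' @return 1-based flat bin id(s) over all contigs.
#' @export
bin_index <- function(genome, chrom, pos) {
  stopifnot(all(chrom %in% genome$chrom))
  stopifnot(all(pos >= 0), all(pos < genome$length[chrom]))
  unname(genome$offset[chrom] + pos %/% genome$bin_size + 1L)
}

#' Host bin id of a genomic position on a host chromosome
#' @inheritParams bin_index
#' @return 1-based host bin id(s) (host chromosomes only).
#' @export
host_bin_index <- function(genome, chrom, pos) {
  if (any(genome$is_plasmid[chrom]))
    stop("position on a plasmid contig has no host bin id")
  stopifnot(all(pos >= 0), all(pos < genome$length[chrom]))
  unname(genome$host_offset[chrom] + pos %/% genome$bin_size + 1L)
}

#' Invert a flat bin id to (chromosome, bin start)
#' @param genome a \code{binned_genome}.
#' @param flat 1-based flat bin id(s).
#' @return data.frame with columns chrom, bin (0-based ordinal), start, end (bp).
#' @export
bin_locate <- function(genome, flat) {
  stopifnot(all(flat >= 1), all(flat <= genome$n_bins_total))
  ci <- findInterval(flat - 1L, unname(genome$offset))
  chrom <- genome$chrom[ci]
  ord <- flat - 1L - unname(genome$offset[ci])
  start <- ord * genome$bin_size
  end <- pmin(start + genome$bin_size, unname(genome$length[chrom]))
  data.frame(chrom = chrom, bin = ord, start = start, end = end,
             stringsAsFactors = FALSE)
}

# host bin id -> flat id and back; vectors over all host bins
host_to_flat <- function(genome) {
  idx <- unlist(lapply(host_chroms(genome), function(cn) {
    genome$offset[cn] + seq_len(genome$n_bins[cn])
  }), use.names = FALSE)
  as.integer(idx)
}

# locate host bin ids -> data.frame(chrom, bin, start, end)
host_bin_locate <- function(genome, host_id) {
  bin_locate(genome, host_to_flat(genome)[host_id])
}

# per-host-bin chromosome factor (in genome order), used for per-chromosome ops
host_bin_chrom <- function(genome) {
  hc <- host_chroms(genome)
  factor(rep(hc, genome$n_bins[hc]), levels = hc)
}

#' Rebin a genome at a different resolution
#'
#' Returns a new \code{binned_genome} over the same contigs with a different
#' bin size. Used for high-resolution operations such as TSS phase analysis.
#' @param genome a \code{binned_genome}.
#' @param bin_size new bin width in bp.
#' @export
genome_rebin <- function(genome, bin_size) {
  binned_genome(genome$chrom, unname(genome$length), bin_size,
                plasmids = plasmid_chroms(genome))
}
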