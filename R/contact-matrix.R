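#' Sparse symmetric contact matrix
#'
#' Stores binned proximity-ligation counts as an upper-triangular sparse
#' matrix over the flat bin indexing of a \code{\link{binned_genome}}
#' (plasmid contigs included). Querying (i, j) and (j, i) returns the same
#' value; counts are non-negative integers and duplicate triplets are summed.
#'
#' @param genome a \code{binned_genome}.
#' @param i,j 1-based flat bin ids of the two pair ends.
#' @param x counts (non-negative integers), same length as \code{i}.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(genome, i = integer(), j = integer(), x = numeric()) {
  stopifnot(inherits(genome, "binned_genome"),
            length(i) == length(j), length(j) == length(x))
  n <- genome$n_bins_total
  if (length(i)) {
    if (any(i < 1 | i > n | j < 1 | j > n))
      stop("bin index out of range (matrix has ", n, " bins)")
    if (any(x < 0) || any(x != round(x)))
      stop("counts must be non-negative integers")
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  m <- Matrix::sparseMatrix(i = lo, j = hi, x = as.numeric(x), dims = c(n, n))
  structure(list(genome = genome, upper = m), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d bins, %s pair events, %d non-zero cells\n",
              x$genome$n_bins_total, x$genome$n_bins_total,
              format(sum(x$upper@x), big.mark = ","), length(x$upper@x)))
  invisible(x)
}

#' Query contact counts
#' @param cm a \code{contact_matrix}.
#' @param i,j 1-based flat bin ids (vectors recycled to common length).
#' @return numeric vector of counts; symmetric in (i, j).
#' @export
cm_query <- function(cm, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  cm$upper[cbind(lo, hi)]
}

#' Total pair events in the matrix
#' @param cm a \code{contact_matrix}.
#' @export
cm_total <- function(cm) sum(cm$upper@x)

# full symmetric sparse matrix; diagonal entries are doubled (callers correct)
cm_sym <- function(cm) cm$upper + Matrix::t(cm$upper)

#' Per-bin total contacts
#'
#' Number of pair events involving each bin (each pair counted once per bin it
#' touches; a self-pair (i, i) counts once for bin i).
#' @param cm a \code{contact_matrix}.
#' @return numeric vector over all flat bins.
#' @export
bin_totals <- function(cm) {
  u <- cm$upper
  as.numeric(Matrix::rowSums(u) + Matrix::colSums(u) - Matrix::diag(u))
}

#' Library-level statistics
#'
#' \code{n_plasmid} is the number of pair events with at least one end on a
#' plasmid contig (intra-plasmid pairs count once); \code{N_total} is the
#' total number of informative pair events in the library. Both are in pair
#' units; see the methods vignette for the consequence of this convention on
#' the contact-score scale.
#'
#' @param n_plasmid,N_total pair counts, \code{0 <= n_plasmid <= N_total},
#'   \code{N_total > 0}.
#' @return An object of class \code{library_stats}.
#' @export
library_stats <- function(n_plasmid, N_total) {
  stopifnot(N_total > 0, n_plasmid >= 0, n_plasmid <= N_total)
  structure(list(n_plasmid = as.numeric(n_plasmid),
                 N_total = as.numeric(N_total)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats> n_plasmid = %s, N_total = %s (%.3f%%)\n",
              format(x$n_plasmid, big.mark = ","),
              format(x$N_total, big.mark = ","),
              100 * x$n_plasmid / x$N_total))
  invisible(x)
}

#' Derive library statistics from a contact matrix
#' @param cm a \code{contact_matrix}.
#' @param plasmid plasmid contig name(s); defaults to all contigs flagged
#'   episomal in the genome.
#' @export
cm_library_stats <- function(cm, plasmid = plasmid_chroms(cm$genome)) {
  g <- cm$genome
  if (!length(plasmid)) stop("genome has no plasmid contig")
  pb <- unlist(lapply(plasmid, function(cn) g$offset[cn] + seq_len(g$n_bins[cn])),
               use.names = FALSE)
  u <- cm$upper
  ti <- u@i + 1L
  tj <- rep.int(seq_len(ncol(u)), diff(u@p))
  touches <- (ti %in% pb) | (tj %in% pb)
  library_stats(sum(u@x[touches]), sum(u@x))
}

# ---- COO text dialect -------------------------------------------------------

#' Read a contact matrix from COO text
#'
#' The dialect is tab-separated with a comment header declaring the binning:
#' \preformatted{
#' #binsize: 2000
#' #chrom: chrI 230218
#' #chrom: plasmid_2u 6300 plasmid
#' idx1  idx2  count
#' }
#' Data rows are either \code{idx1 idx2 count} with 0-based flat bin ids, or
#' \code{chrom1 pos1 chrom2 pos2 count} with 0-based bp positions. Duplicate
#' triplets are summed; storage is normalized to upper-triangular.
#'
#' @param path file path.
#' @param genome optional \code{binned_genome}; if omitted it is built from
#'   the header.
#' @return list with elements \code{genome} and \code{matrix}.
#' @export
load_contact_matrix <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(genome)) {
    bs <- sub("^#binsize:\\s*", "", grep("^#binsize:", hdr, value = TRUE))
    if (!length(bs)) stop("COO header lacks '#binsize:' line")
    cl <- sub("^#chrom:\\s*", "", grep("^#chrom:", hdr, value = TRUE))
    if (!length(cl)) stop("COO header lacks '#chrom:' lines")
    parts <- strsplit(cl, "\\s+")
    genome <- binned_genome(
      chroms   = vapply(parts, `[`, "", 1L),
      lengths  = as.numeric(vapply(parts, `[`, "", 2L)),
      bin_size = as.integer(bs[1L]),
      plasmids = vapply(parts, `[`, "", 1L)[vapply(parts, function(p)
        length(p) > 2 && p[3] == "plasmid", FALSE)])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) && grepl("^(idx1|chrom1)\\b", body[1L])) body <- body[-1L]
  if (!length(body))
    return(list(genome = genome, matrix = contact_matrix(genome)))
  fields <- strsplit(body, "\t")
  nf <- lengths(fields)
  if (all(nf == 3L)) {
    i <- as.numeric(vapply(fields, `[`, "", 1L)) + 1
    j <- as.numeric(vapply(fields, `[`, "", 2L)) + 1
    x <- as.numeric(vapply(fields, `[`, "", 3L))
  } else if (all(nf == 5L)) {
    c1 <- vapply(fields, `[`, "", 1L); c2 <- vapply(fields, `[`, "", 3L)
    bad <- !(c1 %in% genome$chrom) | !(c2 %in% genome$chrom)
    if (any(bad))
      stop("unknown chromosome name(s) in COO records: ",
           paste(unique(c(c1[bad], c2[bad])[!c(c1[bad], c2[bad]) %in% genome$chrom]),
                 collapse = ", "))
    i <- bin_index(genome, c1, as.numeric(vapply(fields, `[`, "", 2L)))
    j <- bin_index(genome, c2, as.numeric(vapply(fields, `[`, "", 4L)))
    x <- as.numeric(vapply(fields, `[`, "", 5L))
  } else {
    stop("COO rows must have 3 (idx) or 5 (chrom/pos) fields")
  }
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  list(genome = genome, matrix = contact_matrix(genome, i, j, x))
}

#' Write a contact matrix in the COO text dialect
#' @param cm a \code{contact_matrix}.
#' @param path output file path.
#' @export
write_contact_matrix <- function(cm, path) {
  g <- cm$genome
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(coo_header(g), "idx1\tidx2\tcount"), con)
  u <- cm$upper
  if (length(u@x)) {
    ti <- u@i                           # already 0-based
    tj <- rep.int(seq_len(ncol(u)) - 1L, diff(u@p))
    keep <- u@x != 0
    writeLines(sprintf("%d\t%d\t%g", ti[keep], tj[keep], u@x[keep]), con)
  }
  invisible(path)
}

coo_header <- function(g) {
  c(sprintf("#tetherscan COO contact matrix v%s",
            as.character(utils::packageVersion("tetherscan"))),
    sprintf("#binsize: %d", g$bin_size),
    sprintf("#chrom: %s %g%s", g$chrom, unname(g$length),
            ifelse(g$is_plasmid, " plasmid", "")))
}
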