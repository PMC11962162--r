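#' Genomic feature set
#'
#' A data.frame-backed container of genomic intervals with attributes.
#' Coordinates are 0-based half-open; \code{length = end - start} always.
#' The \code{class} column is one of \code{"gene"}, \code{"subtelomere"},
#' \code{"centromere"}, \code{"other"}.
#'
#' @param chrom,start,end interval coordinates (0-based half-open bp).
#' @param name feature names (default generated).
#' @param class feature class label.
#' @param expression optional per-feature expression level (e.g. CPM).
#' @param strand optional strand ("+"/"-"), default "+".
#' @param genome optional \code{binned_genome} to validate intervals against.
#' @return a data.frame of class \code{feature_set}.
#' @export
feature_set <- function(chrom, start, end, name = NULL,
                        class = "other", expression = NA_real_,
                        strand = "+", genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    stopifnot(length(start) == n, length(end) == n)
  }
  if (n && any(start >= end)) stop("feature intervals must have start < end")
  if (is.null(name)) name <- if (n) sprintf("feat%04d", seq_len(n)) else character()
  fs <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = name,
                   class = rep_len(as.character(class), n),
                   length = as.numeric(end) - as.numeric(start),
                   expression = rep_len(as.numeric(expression), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    if (!all(fs$chrom %in% genome$chrom))
      stop("unknown chromosome(s): ",
           paste(setdiff(fs$chrom, genome$chrom), collapse = ", "))
    if (any(fs$end > unname(genome$length[fs$chrom])))
      stop("feature(s) extend past chromosome end")
  }
  class(fs) <- c("feature_set", "data.frame")
  fs
}

#' Load features from BED or GFF3
#'
#' BED (0-based half-open) is read record by record: malformed records
#' (\code{start >= end}, coordinates outside the chromosome when a genome is
#' given) are rejected with a message naming the line number while the
#' remainder loads. GFF3 (1-based closed) is read with
#' \code{rtracklayer::import} and converted to the internal 0-based half-open
#' convention.
#'
#' @param path file path; format guessed from the extension
#'   (\code{.bed} vs \code{.gff}/\code{.gff3}) unless \code{format} is given.
#' @param genome optional \code{binned_genome} used to validate intervals.
#' @param format "bed" or "gff".
#' @param class class label assigned to the loaded features.
#' @return a \code{feature_set}.
#' @export
load_features <- function(path, genome = NULL, format = NULL, class = "gene") {
  stopifnot(file.exists(path))
  if (is.null(format))
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "bed"
  if (format == "gff") {
    gr <- rtracklayer::import(path, format = "gff3")
    fs <- feature_set(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1L,
                      GenomicRanges::end(gr),
                      name = if (!is.null(gr$Name)) as.character(gr$Name) else
                        if (!is.null(gr$ID)) as.character(gr$ID) else NULL,
                      strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
                      class = class)
    return(validate_features(fs, genome))
  }
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lnum <- which(keep)
  f <- strsplit(lines[keep], "\t")
  chrom <- vapply(f, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  name <- vapply(f, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (!is.null(genome)) {
    known <- chrom %in% genome$chrom
    bad <- bad | !known | (known & end > ifelse(known, unname(genome$length[chrom]), Inf))
  }
  if (any(bad))
    message("load_features: rejected ", sum(bad), " record(s) at line(s) ",
            paste(lnum[bad], collapse = ", "))
  fs <- feature_set(chrom[!bad], start[!bad], end[!bad],
                    name = if (all(is.na(name[!bad]))) NULL else name[!bad],
                    class = class)
  fs
}

validate_features <- function(fs, genome) {
  if (is.null(genome)) return(fs)
  bad <- !(fs$chrom %in% genome$chrom)
  bad[!bad] <- fs$end[!bad] > unname(genome$length[fs$chrom[!bad]])
  if (any(bad))
    message("load_features: rejected ", sum(bad),
            " record(s) outside the genome")
  out <- fs[!bad, , drop = FALSE]
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Write a feature set as BED4 (+score column with the length)
#' @param fs a \code{feature_set}.
#' @param path output path.
#' @export
write_features <- function(fs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#tetherscan features (BED, 0-based half-open)", con)
  writeLines(sprintf("%s\t%d\t%d\t%s", fs$chrom, as.integer(fs$start),
                     as.integer(fs$end), fs$name), con)
  invisible(path)
}

# host bin ids covered by each feature row -> list of integer vectors
feature_host_bins <- function(fs, genome) {
  bs <- genome$bin_size
  lapply(seq_len(nrow(fs)), function(k) {
    cn <- fs$chrom[k]
    if (genome$is_plasmid[cn]) return(integer())
    b0 <- fs$start[k] %/% bs
    b1 <- (fs$end[k] - 1) %/% bs
    as.integer(genome$host_offset[cn] + b0:b1 + 1L)
  })
}

# logical over host bins: bin interval intersects >= 1 feature
feature_bin_mask <- function(fs, genome) {
  mask <- logical(genome$n_host_bins)
  for (b in feature_host_bins(fs, genome)) mask[b] <- TRUE
  mask
}
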