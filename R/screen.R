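#' Mean signal at contact hotspots vs the genome
#'
#' Averages a binned track over each peak's bin +/- \code{flank} bp
#' (default 2 kb: at 2 kb bins that is the peak bin plus one bin each side),
#' pooled across peaks and ignoring masked bins, and compares it with the
#' genome-wide mean over all valid host bins.
#'
#' @param track a \code{signal_track} binned at the genome's bin size.
#' @param peaks a non-empty \code{peak_set}.
#' @param flank half-window in bp around each peak bin.
#' @return list(hotspot_mean, genome_mean, ratio, n_peaks); ratio is
#'   hotspot/genome when the genome mean is > 0, else NA.
#' @export
hotspot_signal_score <- function(track, peaks, flank = 2000) {
  if (!nrow(peaks)) stop("empty peak set")
  stack <- window_stack(track, peaks, flank = flank)
  vals <- as.vector(stack)
  if (all(is.na(vals)))
    stop("all hotspot bins are masked in track ",
         if (!is.null(track$name)) sQuote(track$name) else "")
  hm <- mean(vals, na.rm = TRUE)
  gm <- mean(track$values[track$valid])
  list(hotspot_mean = hm, genome_mean = gm,
       ratio = if (gm > 0) hm / gm else NA_real_,
       n_peaks = nrow(peaks))
}

#' Screen many signal libraries for enrichment at hotspots
#'
#' One record per track: the raw hotspot mean (the quantity plotted in
#' ChIP-exo screens) and the genome-normalized enrichment ratio, which is
#' comparable across libraries of different depth. Output is sorted by
#' category, then descending ratio; a per-category median-ratio summary is
#' attached.
#'
#' @param tracks a list of entries \code{list(id=, category=, track=)} where
#'   \code{track} is a \code{signal_track}; ids must be unique.
#' @param peaks a \code{peak_set}.
#' @param flank half-window in bp (see \code{\link{hotspot_signal_score}}).
#' @return data.frame of class \code{screen_table} (id, category,
#'   hotspot_mean, genome_mean, ratio, n_peaks) with attribute
#'   \code{category_summary}.
#' @export
screen_libraries <- function(tracks, peaks, flank = 2000) {
  stopifnot(length(tracks) >= 1)
  ids <- vapply(tracks, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate library id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rec <- lapply(tracks, function(tr) {
    s <- hotspot_signal_score(tr$track, peaks, flank)
    data.frame(id = tr$id, category = tr$category,
               hotspot_mean = s$hotspot_mean, genome_mean = s$genome_mean,
               ratio = s$ratio, n_peaks = s$n_peaks,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rec)
  tab <- tab[order(tab$category, -tab$ratio), ]
  rownames(tab) <- NULL
  med <- stats::aggregate(ratio ~ category, tab, stats::median)
  names(med)[2] <- "median_ratio"
  structure(tab, class = c("screen_table", "data.frame"),
            category_summary = med, flank = flank)
}

#' Write a screen table as TSV
#' @param tab a \code{screen_table}.
#' @param path output path.
#' @export
write_screen_tsv <- function(tab, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#tetherscan hotspot signal screen, flank %g bp",
                     attr(tab, "flank")), con)
  writeLines("id\tcategory\thotspot_mean\tgenome_mean\tratio\tn_peaks", con)
  writeLines(sprintf("%s\t%s\t%.6g\t%.6g\t%.6g\t%d", tab$id, tab$category,
                     tab$hotspot_mean, tab$genome_mean, tab$ratio,
                     tab$n_peaks), con)
  invisible(path)
}
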