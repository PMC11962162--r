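#' Interpolate a contact profile over masked bins
#'
#' Masked interior bins are filled by per-chromosome linear interpolation
#' between the nearest valid neighbours; leading/trailing masked bins stay
#' masked (no extrapolation) and valid bins are unchanged. Chromosomes with
#' fewer than two valid bins are left fully masked with a message.
#'
#' @param profile a \code{contact_profile}.
#' @return a \code{contact_profile} with interior gaps filled and
#'   \code{interpolated = TRUE}.
#' @export
interpolate_profile <- function(profile) {
  g <- profile$genome
  chrom <- host_bin_chrom(g)
  score <- profile$score
  for (cn in levels(chrom)) {
    idx <- which(chrom == cn)
    v <- score[idx]
    ok <- which(!is.na(v))
    if (length(ok) < 2L) {
      if (any(is.na(v)))
        message("interpolate_profile: ", cn,
                " has < 2 valid bins; left masked")
      next
    }
    gap <- which(is.na(v))
    gap <- gap[gap > min(ok) & gap < max(ok)]      # no extrapolation
    if (length(gap))
      v[gap] <- stats::approx(x = ok, y = v[ok], xout = gap,
                              method = "linear")$y
    score[idx] <- v
  }
  out <- profile
  out$score <- score
  out$valid <- !is.na(score)
  out$interpolated <- TRUE
  out
}

#' Call contact hotspots as thresholded local maxima
#'
#' Per chromosome (never across chromosome boundaries), a candidate peak is a
#' strict local maximum: a bin (or the leftmost bin of a plateau of equal
#' values) whose flanking values are both strictly smaller. Chromosome
#' terminal bins and bins adjacent to masked bins are ineligible (no
#' two-sided neighbourhood). Candidates below \code{height} are dropped;
#' among the rest, peaks closer than \code{distance} bins are resolved
#' iteratively from the highest peak down (ties keep the leftmost), so any
#' two reported peaks are >= \code{distance} bins apart.
#'
#' The defaults (\code{height = 0.8}, \code{distance = 2}) are the study
#' parameters for 2 kb-binned profiles; \code{height} is in score units
#' (see \code{\link{compute_contact_profile}}).
#'
#' @param profile an interpolated \code{contact_profile} (see
#'   \code{\link{interpolate_profile}}), or any \code{signal_track}-like
#'   per-host-bin vector object.
#' @param height minimum peak score (> 0).
#' @param distance minimum separation between peaks, in bins (>= 1).
#' @return a \code{peak_set}: data.frame(chrom, bin, start, score) sorted by
#'   (chromosome order, position), with the detection parameters as
#'   attributes. \code{bin} is the 0-based bin ordinal within the
#'   chromosome, \code{start} its bp start.
#' @export
call_peaks <- function(profile, height = 0.8, distance = 2L) {
  if (height <= 0) stop("height must be > 0")
  if (distance < 1) stop("distance must be >= 1")
  g <- profile$genome
  vals <- if (inherits(profile, "contact_profile")) profile$score else profile$values
  chrom <- host_bin_chrom(g)
  res <- list()
  for (cn in levels(chrom)) {
    v <- vals[chrom == cn]
    cand <- local_maxima(v)
    cand <- cand[v[cand] >= height]
    if (!length(cand)) next
    keep <- suppress_by_distance(cand, v[cand], distance)
    res[[cn]] <- data.frame(chrom = cn, bin = keep - 1L,
                            start = (keep - 1L) * g$bin_size,
                            score = v[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), bin = integer(), start = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"),
            height = height, distance = as.integer(distance),
            genome = g)
}

# strict local maxima of a vector with NAs treated as ineligible neighbours;
# plateaus report their leftmost bin
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (is.na(v[i]) || is.na(v[i - 1L]) || v[i] <= v[i - 1L]) { i <- i + 1L; next }
    # v[i] > v[i-1]; extend plateau
    j <- i
    while (j < n && !is.na(v[j + 1L]) && v[j + 1L] == v[i]) j <- j + 1L
    if (j < n && !is.na(v[j + 1L]) && v[j + 1L] < v[i]) out <- c(out, i)
    i <- j + 1L
  }
  out
}

# greedy suppression: resolve from the highest down (ties leftmost); peaks
# closer than `distance` bins to an already-kept higher peak are removed
suppress_by_distance <- function(pos, val, distance) {
  ord <- order(-val, pos)
  kept <- integer()
  for (k in ord) {
    if (!length(kept) || all(abs(pos[kept] - pos[k]) >= distance))
      kept <- c(kept, k)
  }
  sort(pos[kept])
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (height >= %g, distance >= %d bins)\n",
              nrow(x), attr(x, "height"), attr(x, "distance")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# host bin ids of the peaks
peak_host_bins <- function(peaks, genome = attr(peaks, "genome")) {
  if (!nrow(peaks)) return(integer())
  host_bin_index(genome, peaks$chrom, peaks$start)
}

#' Write a peak set as BED with a score column
#' @param peaks a \code{peak_set}.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  g <- attr(peaks, "genome")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#tetherscan peaks: height=%g distance=%d binsize=%d",
                     attr(peaks, "height"), attr(peaks, "distance"),
                     g$bin_size), con)
  if (nrow(peaks)) {
    end <- pmin(peaks$start + g$bin_size, unname(g$length[peaks$chrom]))
    writeLines(sprintf("%s\t%d\t%d\tpeak%03d\t%.4f", peaks$chrom,
                       as.integer(peaks$start), as.integer(end),
                       seq_len(nrow(peaks)), peaks$score), con)
  }
  invisible(path)
}
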