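#' Per-bin normalized plasmid contact score
#'
#' For each host-genome bin i, the score is the proportion of the bin's
#' contacts that involve the plasmid, normalized by the plasmid's share of
#' the whole library:
#' \deqn{S_i = \frac{cp_i / T_i}{n_{plasmid} / N_{total}}}
#' where \eqn{cp_i} is the number of contacts between the plasmid contig and
#' host bin i, \eqn{T_i} the total number of contacts involving bin i, and
#' \eqn{n_{plasmid}/N_{total}} the plasmid fraction of the library. A score
#' of 1 means the bin contacts the plasmid exactly in proportion to the
#' plasmid's presence in the library; the score is invariant under
#' count-preserving rescaling of the library and self-normalizes per-bin
#' coverage, so it is computed on raw (unbalanced) counts.
#'
#' Bins with \eqn{T_i = 0} have an undefined score and are masked, never
#' dropped, so downstream window extraction keeps alignment.
#'
#' @param cm a \code{\link{contact_matrix}}.
#' @param stats a \code{\link{library_stats}}; defaults to statistics derived
#'   from the matrix itself (pair units).
#' @param plasmid plasmid contig name(s); must be flagged episomal in the
#'   genome. Defaults to all flagged contigs.
#' @param denominator \code{"all"} (default): \eqn{T_i} counts the bin's
#'   contacts with every contig, plasmid included; \code{"host"}: plasmid
#'   partners are excluded from the denominator.
#' @return An object of class \code{contact_profile}: per-host-bin
#'   \code{score}, \code{valid} mask, and provenance.
#' @export
compute_contact_profile <- function(cm, stats = NULL,
                                    plasmid = plasmid_chroms(cm$genome),
                                    denominator = c("all", "host")) {
  g <- cm$genome
  denominator <- match.arg(denominator)
  if (!length(plasmid)) stop("no plasmid contig given")
  if (!all(g$is_plasmid[plasmid]))
    stop("contig(s) not flagged episomal: ",
         paste(plasmid[!g$is_plasmid[plasmid]], collapse = ", "))
  if (is.null(stats)) stats <- cm_library_stats(cm, plasmid)
  if (stats$n_plasmid <= 0) stop("n_plasmid = 0: score undefined")
  pb <- unlist(lapply(plasmid, function(cn) g$offset[cn] + seq_len(g$n_bins[cn])),
               use.names = FALSE)
  hb <- host_to_flat(g)
  sym <- cm_sym(cm)                       # doubles the diagonal; corrected below
  cp <- as.numeric(Matrix::colSums(sym[pb, hb, drop = FALSE]))
  tot <- bin_totals(cm)[hb]
  if (denominator == "host") {
    tot <- tot - cp
  }
  valid <- tot > 0
  score <- rep(NA_real_, length(tot))
  score[valid] <- (cp[valid] / tot[valid]) / (stats$n_plasmid / stats$N_total)
  structure(list(genome = g, score = score, valid = valid,
                 plasmid = plasmid, stats = stats,
                 denominator = denominator, interpolated = FALSE),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  v <- x$score[x$valid]
  cat(sprintf("<contact_profile> plasmid %s over %d host bins (%d masked)%s\n",
              paste(x$plasmid, collapse = "+"), length(x$score),
              sum(!x$valid),
              if (x$interpolated) ", interpolated" else ""))
  if (length(v))
    cat(sprintf("  score: mean %.3f, median %.3f, max %.3f\n",
                mean(v), stats::median(v), max(v)))
  invisible(x)
}

#' Write a contact profile as TSV (score + mask flag per host bin)
#' @param profile a \code{contact_profile}.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  g <- profile$genome
  loc <- host_bin_locate(g, seq_len(g$n_host_bins))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(coo_header(g)[1:2],
               sprintf("#plasmid: %s", paste(profile$plasmid, collapse = ","))),
             con)
  writeLines("chrom\tstart\tend\tscore\tmasked", con)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", loc$chrom, loc$start, loc$end,
                     ifelse(is.na(profile$score), "NA",
                            sprintf("%.6g", profile$score)),
                     as.integer(!profile$valid)), con)
  invisible(path)
}
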