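#' Pipeline run configuration
#'
#' All defaults are the study's stated analysis parameters: 2 kb bins, peak
#' height 0.8 and distance 2, 30 kb subtelomeres, 7 kb long genes, 1000
#' permutations, +/- 40 kb averaged-profile windows, +/- 20 kb heatmap
#' ordering windows, +/- 2 kb screen flank.
#'
#' @param matrix_path COO contact matrix path (see
#'   \code{\link{load_contact_matrix}}).
#' @param genes_path optional BED/GFF gene annotation path.
#' @param plasmid plasmid contig name (NULL = all flagged contigs).
#' @param peak_height,peak_distance peak-calling parameters.
#' @param subtelomere_flank,long_gene_min bp definitions of the feature
#'   groups.
#' @param n_permutations,seed permutation-test parameters.
#' @param profile_flank,heatmap_score_flank,screen_flank window sizes in bp.
#' @param out_dir output directory.
#' @return a \code{run_config} list.
#' @export
run_config <- function(matrix_path = NULL, genes_path = NULL, plasmid = NULL,
                       peak_height = 0.8, peak_distance = 2,
                       subtelomere_flank = 30000, long_gene_min = 7000,
                       n_permutations = 1000, seed = 1L,
                       profile_flank = 40000, heatmap_score_flank = 20000,
                       screen_flank = 2000, out_dir = "tetherscan_out") {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{run_config}}; unknown keys are
#' an error, missing keys keep their defaults.
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. from CLI flags).
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  if (length(setdiff(names(y), known)))
    stop("unknown config key(s): ",
         paste(setdiff(names(y), known), collapse = ", "))
  cfg <- do.call(run_config, y)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full tethering analysis
#'
#' score -> peaks -> enrichment (subtelomeres, long genes) -> averaged
#' profile -> sorted heatmap, writing every stage's output to
#' \code{config$out_dir} together with a JSON manifest recording the
#' package version, parameters, seed and input checksums. Deterministic
#' given config + seed. A stage failure aborts with the stage name.
#'
#' @param config a \code{\link{run_config}}; alternatively pass
#'   pre-loaded objects through \code{matrix}, \code{genes}.
#' @param matrix optional pre-loaded \code{contact_matrix} (overrides
#'   \code{config$matrix_path}).
#' @param genes optional pre-loaded gene \code{feature_set}.
#' @return (invisibly) a list with profile, peaks, enrichment results,
#'   mean profile, heatmap and the manifest.
#' @export
run_pipeline <- function(config = run_config(), matrix = NULL, genes = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- list()
  if (is.null(matrix)) {
    matrix <- stage("load", load_contact_matrix(config$matrix_path)$matrix)
    inputs$matrix <- c(path = config$matrix_path,
                       md5 = unname(tools::md5sum(config$matrix_path)))
  }
  g <- matrix$genome
  if (is.null(genes) && !is.null(config$genes_path)) {
    genes <- stage("load", load_features(config$genes_path, genome = g))
    inputs$genes <- c(path = config$genes_path,
                      md5 = unname(tools::md5sum(config$genes_path)))
  }
  message("[score] computing contact profile")
  profile <- stage("score", {
    pl <- if (is.null(config$plasmid)) plasmid_chroms(g) else config$plasmid
    compute_contact_profile(matrix, plasmid = pl)
  })
  message(sprintf("[score] %d/%d host bins masked", sum(!profile$valid),
                  length(profile$valid)))
  write_bedgraph(profile, file.path(config$out_dir, "contact_score.bedgraph"))
  write_profile_tsv(profile, file.path(config$out_dir, "contact_score.tsv"))

  peaks <- stage("peaks", {
    call_peaks(interpolate_profile(profile),
               height = config$peak_height, distance = config$peak_distance)
  })
  message(sprintf("[peaks] yielded %d hotspots (height=%g, distance=%d)",
                  nrow(peaks), config$peak_height, config$peak_distance))
  write_peaks_bed(peaks, file.path(config$out_dir, "hotspots.bed"))

  enrich <- list()
  if (nrow(peaks)) {
    enrich$subtelomere <- stage("enrich", permutation_overlap_test(
      peaks, subtelomere_intervals(g, config$subtelomere_flank), g,
      n_permutations = config$n_permutations, seed = config$seed,
      label = "subtelomere"))
    if (!is.null(genes) && nrow(long_gene_group(genes, config$long_gene_min)))
      enrich$long_gene <- stage("enrich", permutation_overlap_test(
        peaks, long_gene_group(genes, config$long_gene_min), g,
        n_permutations = config$n_permutations,
        seed = split_seed(config$seed, 7), label = "long_gene"))
    for (e in enrich)
      message(sprintf("[enrich] %s: %d/%d peaks overlap, p = %g",
                      e$label, e$observed, e$n_peaks, e$p_value))
  }
  write_enrichment_tsv(enrich, file.path(config$out_dir, "enrichment.tsv"))

  mean_prof <- NULL; heat <- NULL
  if (nrow(peaks)) {
    stack <- stage("profile", window_stack(profile, peaks,
                                           flank = config$profile_flank))
    mean_prof <- mean_profile(stack)
    heat <- sorted_heatmap(stack, score_flank = config$heatmap_score_flank)
    utils::write.table(format(mean_prof, digits = 6), sep = "\t",
                       file = file.path(config$out_dir, "mean_profile.tsv"),
                       quote = FALSE, row.names = FALSE)
    utils::write.table(round(heat$matrix, 6), sep = "\t",
                       file = file.path(config$out_dir, "heatmap.tsv"),
                       quote = FALSE, col.names = FALSE)
  } else {
    writeLines("#empty: no peaks", file.path(config$out_dir, "mean_profile.tsv"))
    writeLines("#empty: no peaks", file.path(config$out_dir, "heatmap.tsv"))
  }

  manifest <- list(
    tool = "tetherscan",
    version = as.character(utils::packageVersion("tetherscan")),
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = inputs,
    stages = list(score = TRUE, peaks = nrow(peaks),
                  enrich = names(enrich),
                  profile = !is.null(mean_prof)),
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(profile = profile, peaks = peaks, enrichment = enrich,
                 mean_profile = mean_prof, heatmap = heat,
                 manifest = manifest))
}
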