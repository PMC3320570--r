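#' End-to-end analysis of a perturbation database
#'
#' Runs the full pipeline: normalization to within-study controls and the
#' inclusion filter, consensus orientation clustering, release-model unit
#' vectors, fixed-orientation regression with the error-reduction statistic
#' and its permutation null, entropy/RMS diagnostics, gene-level summaries,
#' the GOF/LOF weighted contingency randomization test (when annotations are
#' present), and the control-correlation screen (when wild-type reference
#' flags are present).
#'
#' @param db a `synclust_db` database (or path to one in the canonical
#'   delimited dialect).
#' @param K_values candidate cluster numbers for the consensus step.
#' @param restarts EM restarts per K.
#' @param seed master seed for every stochastic step.
#' @param n_perm permutations for the proportional-model null.
#' @param n_rand randomizations for the contingency test.
#' @param min_observed inclusion filter threshold (variables per
#'   perturbation).
#' @param K_star optional override of the chosen number of clusters.
#' @param soft use soft co-occurrence in the consensus step.
#' @param include_F include spontaneous frequency in the RMS diagnostic.
#' @param perm_scheme permutation scheme for the proportional-model null.
#' @param pooled_projections which projections enter the orientation fits and
#'   the error-reduction statistic: `"evoked"` (default) or `"all"` (adds the
#'   spontaneous-frequency projections).
#' @return object of class `"synclust_analysis"` collecting all results.
#' @examples
#' sim <- generate_database(paperlike_config(), seed = 7)
#' res <- analyze_perturbations(sim$database, K_values = 2:4, restarts = 4,
#'                              seed = 7, n_perm = 99, n_rand = 199)
#' res
#' @export
analyze_perturbations <- function(db, K_values = 2:6, restarts = 10, seed,
                                  n_perm = 1000, n_rand = 9999,
                                  min_observed = 2, K_star = NULL,
                                  soft = FALSE, include_F = FALSE,
                                  perm_scheme = "within_column",
                                  pooled_projections = c("evoked", "all")) {
  pooled_projections <- match.arg(pooled_projections)
  if (is.character(db)) db <- read_database(db)
  if (!inherits(db, "synclust_db")) db <- as_synclust_db(db)
  seeds <- derive_seeds(seed, 3L)

  vectors <- filter_min_variables(normalize_to_controls(db), min_observed)
  flags <- flag_large_effects(vectors)

  consensus <- consensus_cluster(vectors, K_values = K_values,
                                 restarts = restarts, seed = seeds[1],
                                 soft = soft, K_star = K_star)
  q <- consensus$responsibilities
  unit_vectors <- cluster_unit_vectors(consensus$model)

  proj <- if (pooled_projections == "all") c(EVOKED_PROJECTIONS, F_PROJECTIONS)
          else EVOKED_PROJECTIONS
  fits_evoked <- orientation_fit(vectors, q, projections = proj)
  gw <- gene_weights(vectors$gene_symbol)
  fits_F <- orientation_fit(vectors, q, projections = F_PROJECTIONS,
                            weights = gw)
  reduction <- error_reduction(fits_evoked)
  perm <- permutation_null(vectors, n_perm = n_perm, seed = seeds[2],
                           scheme = perm_scheme)

  diag_tab <- perturbation_diagnostics(vectors, q, include_F = include_F)
  genes <- gene_cluster_summary(q, vectors$gene_symbol)

  contingency <- NULL
  if (sum(vectors$gof_label %in% "GOF") >= 1 &&
      sum(vectors$gof_label %in% "LOF") >= 1) {
    contingency <- weighted_contingency_test(
      vectors$gof_label, q, genes = vectors$gene_symbol,
      n_rand = n_rand, seed = seeds[3])
  }
  correlations <- NULL
  if (sum(db$wt_reference %in% c(1, 2)) >= 3) {
    correlations <- control_correlations(db)
  }

  structure(list(
    db = db, vectors = vectors, large_effect_ids = flags,
    consensus = consensus, model = consensus$model,
    unit_vectors = unit_vectors,
    orientation = fits_evoked, orientation_F = fits_F,
    error_reduction = reduction, permutation = perm,
    diagnostics = diag_tab, gene_summary = genes,
    contingency = contingency, control_correlations = correlations,
    seed = seed, call = match.call()
  ), class = "synclust_analysis")
}

#' @export
print.synclust_analysis <- function(x, ...) {
  cat("Perturbation orientation-clustering analysis\n")
  cat(sprintf("  %d database rows -> %d perturbations after the >=2-variable filter (%d genes, %d studies)\n",
              nrow(x$db), nrow(x$vectors),
              length(unique(x$vectors$gene_symbol)),
              length(unique(x$db$study_id[x$vectors$db_row]))))
  cat(sprintf("  %d perturbations with >10-fold effects (kept in all analyses)\n",
              length(x$large_effect_ids)))
  cat(sprintf("  K* = %d, cluster sizes %s\n", x$consensus$K_star,
              paste(x$consensus$sizes, collapse = " / ")))
  cat("  cluster unit vectors (RRP, Pv, A):\n")
  print(round(x$unit_vectors$unit_vectors, 3))
  cat(sprintf("  error reduction from clustering: %.1f%%\n",
              100 * x$error_reduction))
  cat(sprintf("  proportional-model permutation p = %.4g (%d permutations)\n",
              x$permutation$p_value, x$permutation$n_perm))
  if (!is.null(x$contingency)) {
    cat(sprintf("  GOF/LOF contingency: chi-square %.3f, randomization p = %.4g\n",
                x$contingency$chisq, x$contingency$p_value))
  }
  if (!is.null(x$control_correlations)) {
    sig <- x$control_correlations$significant
    cat(sprintf("  control correlations: %d of %d pairs significant at Bonferroni %.4f\n",
                sum(sig, na.rm = TRUE), length(sig),
                attr(x$control_correlations, "bonferroni")))
  }
  invisible(x)
}

#' Write every pipeline report to a directory
#'
#' @param analysis a `synclust_analysis` object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sd <- analysis$seed
  write_perturbations(analysis$vectors, file.path(dir, "perturbations.tsv"), seed = sd)
  write_consensus(analysis$consensus, dir)
  write_orientation(analysis$orientation, file.path(dir, "orientation_evoked.tsv"), seed = sd)
  write_orientation(analysis$orientation_F, file.path(dir, "orientation_F.tsv"), seed = sd)
  write_tsv_prov(analysis$diagnostics, file.path(dir, "diagnostics.tsv"), seed = sd)
  write_tsv_prov(analysis$gene_summary, file.path(dir, "gene_summary.tsv"), seed = sd)
  if (!is.null(analysis$control_correlations)) {
    write_tsv_prov(analysis$control_correlations,
                   file.path(dir, "control_correlations.tsv"), seed = sd)
  }
  summary_json <- list(
    package_version = as.character(utils::packageVersion("synclust")),
    seed = sd,
    n_records = nrow(analysis$db),
    n_perturbations = nrow(analysis$vectors),
    n_large_effects = length(analysis$large_effect_ids),
    K_star = analysis$consensus$K_star,
    cluster_sizes = analysis$consensus$sizes,
    error_reduction = analysis$error_reduction,
    permutation_p = analysis$permutation$p_value
  )
  if (!is.null(analysis$contingency)) {
    summary_json$contingency <- list(
      chisq = analysis$contingency$chisq,
      p_value = analysis$contingency$p_value,
      gof_cluster_probability = as.vector(analysis$contingency$group_probability["GOF", ])
    )
  }
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
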