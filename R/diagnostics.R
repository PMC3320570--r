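#' Cluster-specificity entropy of assignment probabilities
#'
#' Shannon entropy (natural log) of each perturbation's cluster probability
#' vector: `E_j = -sum_k q_kj ln q_kj`, with `0 ln 0 = 0`. Zero for a
#' degenerate assignment, `ln K` for a uniform one.
#'
#' @param q a probability vector, or a J x K matrix (rowwise entropies).
#' @return numeric vector of entropies.
#' @export
cluster_entropy <- function(q) {
  ent <- function(p) {
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
      stop_synclust("q must be a probability vector", "synclust_validation_error")
    }
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (is.matrix(q)) apply(q, 1L, ent) else ent(q)
}

#' RMS log2 effect size
#'
#' Root-mean-square of the observed evoked log2 effects:
#' `RMS_j = sqrt(mean over observed v of x_v^2)`. Measures distance from the
#' control (no-effect) condition irrespective of direction.
#'
#' @param x numeric vector with `NA`s for unobserved entries, or a matrix
#'   (rowwise), or a `synclust_perturbations` (evoked variables used).
#' @param include_F for a `synclust_perturbations`, include the spontaneous
#'   frequency in the average.
#' @return numeric vector of RMS values.
#' @export
rms_effect <- function(x, include_F = FALSE) {
  if (inherits(x, "synclust_perturbations")) {
    vars <- if (include_F) c(EVOKED_VARS, "F") else EVOKED_VARS
    x <- as.matrix(as.data.frame(x)[paste0("x_", vars)])
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop_synclust("RMS undefined: no observed variables in some row(s)",
                  "synclust_undefined_error")
  }
  sqrt(rowMeans(x^2, na.rm = TRUE))
}

#' Gene-correction weights
#'
#' Weight `1 / n_g` for each perturbation, where `n_g` is the number of
#' perturbations of the same gene present in the analysis, so every gene
#' contributes total weight 1 regardless of how many of its perturbations were
#' curated.
#'
#' @param genes character vector of gene symbols (one per perturbation).
#' @return numeric vector of weights.
#' @export
gene_weights <- function(genes) {
  1 / as.vector(table(genes)[genes])
}

#' Average cluster probabilities per gene
#'
#' @param q J x K assignment probability matrix.
#' @param genes gene symbol per perturbation.
#' @return data.frame with one row per gene: `gene_symbol`,
#'   `n_perturbations`, and the per-cluster average probabilities (each row
#'   sums to 1).
#' @export
gene_cluster_summary <- function(q, genes) {
  ag <- stats::aggregate(q, by = list(gene_symbol = genes), FUN = mean)
  names(ag)[-1] <- paste0("q", seq_len(ncol(q)))
  ag$n_perturbations <- as.vector(table(genes)[ag$gene_symbol])
  ag[c("gene_symbol", "n_perturbations", paste0("q", seq_len(ncol(q))))]
}

#' Per-perturbation diagnostics table
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param q matching J x K assignment probability matrix.
#' @param include_F include spontaneous frequency in the RMS.
#' @return data.frame: id, gene, per-cluster probabilities, dominant cluster
#'   and probability, entropy, RMS.
#' @export
perturbation_diagnostics <- function(pv, q, include_F = FALSE) {
  stopifnot(nrow(pv) == nrow(q))
  out <- data.frame(
    perturbation_id = pv$perturbation_id,
    gene_symbol = pv$gene_symbol,
    stats::setNames(as.data.frame(q), paste0("q", seq_len(ncol(q)))),
    cluster = max.col(q, ties.method = "first"),
    max_probability = apply(q, 1L, max),
    entropy = cluster_entropy(q),
    rms = rms_effect(pv, include_F = include_F)
  )
  rownames(out) <- NULL
  out
}

#' Weighted contingency randomization test for GOF vs LOF enrichment
#'
#' Builds the weighted 2 x K contingency table with cell
#' `(g, k) = sum over perturbations j of group g of weight_j * q_kj`
#' (weights are gene-correction weights or 1), computes the Pearson
#' chi-square statistic on it, and assesses significance by randomly
#' permuting the group labels across the labelled perturbations. Because the
#' table is non-integer, the chi-square is used purely as a randomization
#' statistic, never with its asymptotic distribution. Also reports each
#' group's weighted average probability per cluster.
#'
#' @param labels character vector with values `"GOF"`, `"LOF"` or `NA`
#'   (unannotated perturbations are dropped).
#' @param q J x K assignment probability matrix (rows matching `labels`).
#' @param genes optional gene symbols enabling gene correction.
#' @param gene_correction divide each perturbation's weight by the number of
#'   labelled perturbations of its gene within its group.
#' @param n_rand number of label randomizations.
#' @param seed integer seed.
#' @return object of class `"synclust_contingency"`: `table` (weighted 2 x
#'   K), `group_probability` (row-normalized table), `chisq`, `p_value`,
#'   `n_rand`, `n` per group.
#' @export
weighted_contingency_test <- function(labels, q, genes = NULL,
                                      gene_correction = !is.null(genes),
                                      n_rand = 9999, seed) {
  keep <- which(!is.na(labels) & labels %in% c("GOF", "LOF"))
  labels <- labels[keep]
  q <- q[keep, , drop = FALSE]
  if (length(unique(labels)) < 2L) {
    stop_synclust("need at least one GOF and one LOF perturbation",
                  "synclust_validation_error")
  }
  if (gene_correction) {
    if (is.null(genes)) stop_synclust("genes required for gene correction",
                                      "synclust_parameter_error")
    genes <- genes[keep]
    w <- numeric(length(labels))
    for (g in c("GOF", "LOF")) {
      idx <- labels == g
      w[idx] <- gene_weights(genes[idx])
    }
  } else {
    w <- rep(1, length(labels))
  }

  tab_of <- function(lab) {
    t(vapply(c("GOF", "LOF"), function(g) {
      idx <- lab == g
      colSums(w[idx] * q[idx, , drop = FALSE])
    }, numeric(ncol(q))))
  }
  chisq_of <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  tab <- tab_of(labels)
  obs <- chisq_of(tab)
  set.seed(seed)
  null <- vapply(seq_len(n_rand), function(i) chisq_of(tab_of(sample(labels))),
                 numeric(1))
  structure(list(
    table = tab,
    group_probability = tab / rowSums(tab),
    chisq = obs,
    p_value = (1 + sum(null >= obs)) / (1 + n_rand),
    null = null, n_rand = n_rand,
    n = table(labels), gene_correction = gene_correction
  ), class = "synclust_contingency")
}

#' @export
print.synclust_contingency <- function(x, ...) {
  cat("Weighted contingency randomization test (GOF vs LOF)\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s n=%d", names(x$n), x$n), collapse = ", ")))
  cat("  weighted table:\n")
  print(round(x$table, 3))
  cat("  group average cluster probabilities:\n")
  print(round(x$group_probability, 3))
  cat(sprintf("  Pearson chi-square = %.4f, randomization p = %.4g (%d randomizations)\n",
              x$chisq, x$p_value, x$n_rand))
  invisible(x)
}

#' Pairwise correlations among control experiments
#'
#' For the wild-type reference controls, the pairwise Pearson correlations
#' among the four functional variables (pairwise-complete observations), with
#' p-values from the linear-regression F-test and a Bonferroni threshold of
#' 0.05 / 6 for the six comparisons. This is the screen for whether absolute
#' wild-type values are comparable across studies (they are not, hence the
#' within-study normalization).
#'
#' @param db a `synclust_db` database.
#' @param log_scale correlate log-transformed values.
#' @return data.frame with one row per variable pair: `var1`, `var2`, `n`,
#'   `r`, `p_value`, `significant`; attribute `"bonferroni"` holds the
#'   threshold and `"n_controls"` the number of reference controls.
#' @export
control_correlations <- function(db, log_scale = FALSE) {
  ctrl <- db[!is.na(db$wt_reference) & db$wt_reference %in% c(1, 2), , drop = FALSE]
  if (nrow(ctrl) < 3L) stop_synclust("need at least 3 reference control experiments",
                                     "synclust_validation_error")
  vals <- as.matrix(as.data.frame(ctrl)[paste0("mean_", ALL_VARS)])
  colnames(vals) <- ALL_VARS
  if (log_scale) vals <- log(vals)
  pairs <- utils::combn(ALL_VARS, 2, simplify = FALSE)
  thr <- 0.05 / length(pairs)
  rows <- lapply(pairs, function(pr) {
    ok <- stats::complete.cases(vals[, pr])
    n <- sum(ok)
    if (n < 3L || stats::sd(vals[ok, pr[1]]) == 0 || stats::sd(vals[ok, pr[2]]) == 0) {
      return(data.frame(var1 = pr[1], var2 = pr[2], n = n,
                        r = NA_real_, p_value = NA_real_, significant = NA))
    }
    ct <- stats::cor.test(vals[ok, pr[1]], vals[ok, pr[2]])
    data.frame(var1 = pr[1], var2 = pr[2], n = n,
               r = unname(ct$estimate), p_value = ct$p.value,
               significant = ct$p.value < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- thr
  attr(out, "n_controls") <- nrow(ctrl)
  out
}
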