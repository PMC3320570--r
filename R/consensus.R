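#' Co-occurrence matrix from hard cluster labels
#'
#' `M[i, j] = 1` when i and j carry the same label, else 0; diagonal 1.
#'
#' @param labels integer vector of cluster labels.
#' @return J x J binary matrix.
#' @export
cooccurrence_matrix <- function(labels) {
  m <- outer(labels, labels, "==") * 1
  diag(m) <- 1
  m
}

#' Soft co-occurrence from assignment probabilities
#' @noRd
soft_cooccurrence <- function(q) {
  m <- tcrossprod(q)
  diag(m) <- 1
  m
}

#' Consensus co-occurrence clustering over restarts and cluster numbers
#'
#' Runs [mppca()] `restarts` times for every K in `K_values`, records for each
#' run which perturbation pairs land in the same cluster (by maximum
#' assignment probability), averages the binary co-occurrence matrices per K,
#' and averages the per-K matrices into a grand consensus matrix. The
#' consensus matrix is ordered for display with optimal leaf ordering, the
#' number of clusters `K*` is chosen by a block-structure score (see
#' [choose_K()]), and a final best-of-restarts model is fitted at `K*` with
#' clusters renumbered in decreasing size.
#'
#' A failed fit is retried once with a fresh seed; if it fails again the run
#' is dropped from the average with a warning. Results are deterministic given
#' `seed`.
#'
#' @param x data matrix or `synclust_perturbations` (see [mppca()]).
#' @param K_values candidate cluster numbers.
#' @param restarts independent EM restarts per K (>= 2).
#' @param seed master seed; every run seed is derived from it.
#' @param soft use soft co-occurrence (`sum_k q_ki q_kj`) instead of hard
#'   labels.
#' @param K_star optional override of the chosen number of clusters.
#' @param ... passed on to [mppca()].
#' @return an object of class `"synclust_consensus"`: `per_K` (named list of
#'   averaged matrices), `grand` (consensus matrix), `leaf_order`, `scores`
#'   (block-structure score per candidate K), `K_star`, `model` (final
#'   [mppca()] fit at `K_star`, clusters sorted by decreasing size),
#'   `responsibilities`, `labels`, `sizes`, `runs` (per-run metadata),
#'   `K_values`, `seed`.
#' @examples
#' sim <- simulate_orientations(n_per = 30, angles_deg = c(0, 90),
#'                              noise_sd = 0.1, seed = 1)
#' cons <- consensus_cluster(sim$x, K_values = 2:3, restarts = 4, seed = 2)
#' cons$K_star
#' cons$sizes
#' @export
consensus_cluster <- function(x, K_values = 2:6, restarts = 10, seed,
                              soft = FALSE, K_star = NULL, ...) {
  if (inherits(x, "synclust_perturbations")) x <- evoked_matrix(x)
  x <- as.matrix(x)
  if (length(K_values) == 0L) stop_synclust("K_values must be non-empty",
                                            "synclust_parameter_error")
  if (restarts < 2) stop_synclust("restarts must be >= 2",
                                  "synclust_parameter_error")
  J <- nrow(x)
  n_runs <- length(K_values) * restarts
  seeds <- derive_seeds(seed, 2L * n_runs + 1L)
  run_seeds <- matrix(seeds[seq_len(n_runs)], nrow = restarts)
  retry_seeds <- matrix(seeds[n_runs + seq_len(n_runs)], nrow = restarts)
  final_seed <- seeds[2L * n_runs + 1L]

  per_K <- vector("list", length(K_values))
  names(per_K) <- as.character(K_values)
  runs <- list()
  for (ik in seq_along(K_values)) {
    K <- K_values[ik]
    acc <- matrix(0, J, J)
    n_ok <- 0L
    for (r in seq_len(restarts)) {
      fit <- tryCatch(
        mppca(x, K = K, seed = run_seeds[r, ik], nstart = 1, ...),
        error = function(e) e)
      if (inherits(fit, "error")) {
        fit <- tryCatch(
          mppca(x, K = K, seed = retry_seeds[r, ik], nstart = 1, ...),
          error = function(e) e)
      }
      if (inherits(fit, "error")) {
        warning(sprintf("run (K = %d, restart %d) failed twice and was excluded: %s",
                        K, r, conditionMessage(fit)))
        runs[[length(runs) + 1L]] <- list(K = K, restart = r,
                                          seed = run_seeds[r, ik], ok = FALSE)
        next
      }
      acc <- acc + if (soft) soft_cooccurrence(fit$responsibilities)
                   else cooccurrence_matrix(fit$labels)
      n_ok <- n_ok + 1L
      runs[[length(runs) + 1L]] <- list(K = K, restart = r,
                                        seed = run_seeds[r, ik], ok = TRUE,
                                        logLik = fit$logLik)
    }
    if (n_ok == 0L) stop_synclust(sprintf("all runs failed for K = %d", K),
                                  "synclust_fit_error")
    per_K[[ik]] <- acc / n_ok
  }
  grand <- Reduce(`+`, per_K) / length(per_K)
  dimnames(grand) <- list(rownames(x), rownames(x))

  leaf_order <- olo_order(grand)
  K_sel <- choose_K(grand, K_values)
  scores <- attr(K_sel, "scores")
  K_auto <- as.integer(K_sel)
  K_star <- K_star %||% K_auto

  fin <- final_assignment(x, K_star, restarts = restarts, seed = final_seed, ...)

  structure(list(
    per_K = per_K, grand = grand, leaf_order = leaf_order,
    scores = scores, K_star = K_star, K_auto = K_auto,
    model = fin$model, responsibilities = fin$responsibilities,
    labels = fin$labels, sizes = fin$sizes, runs = runs,
    K_values = K_values, restarts = restarts, seed = seed, soft = soft
  ), class = "synclust_consensus")
}

#' Block-structure score of a consensus matrix for each candidate K
#'
#' The consensus dendrogram (average linkage on `1 - M`) is cut into K blocks;
#' the score is the mean within-block co-occurrence minus the mean
#' between-block co-occurrence over off-diagonal pairs. Ties in the maximum go
#' to the smaller K (parsimony).
#'
#' Because shaving a handful of weakly attached items into their own block
#' always nudges the pooled within-block mean upward, the score typically
#' jumps at the true block count and then plateaus; [choose_K()] therefore
#' treats near-maximal scores as ties.
#'
#' @param M consensus matrix.
#' @param K_values candidate block counts.
#' @return named numeric vector of scores.
#' @export
block_scores <- function(M, K_values) {
  J <- nrow(M)
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  off <- upper.tri(M)
  vapply(K_values, function(K) {
    if (K >= J) return(-mean(M[off]))
    ct <- stats::cutree(hc, k = K)
    same <- outer(ct, ct, "==")
    within <- off & same
    between <- off & !same
    w <- if (any(within)) mean(M[within]) else 0
    b <- if (any(between)) mean(M[between]) else 0
    w - b
  }, numeric(1)) |> stats::setNames(as.character(K_values))
}

#' Choose the number of clusters from a consensus result
#'
#' Picks the smallest K whose block-structure score is within a small
#' parsimony tolerance of the best score. The tolerance (`tie_tol`, a
#' fraction of the observed score range across the candidates) generalizes
#' the exact-tie rule "smaller K wins": cutting additional near-singleton
#' blocks off a clean partition inflates the score by a sliver, and such
#' slivers should not overrule parsimony.
#'
#' @param consensus a `synclust_consensus` object or a consensus matrix.
#' @param K_values candidate K (defaults to the candidates stored in
#'   `consensus`).
#' @param tie_tol scores within `tie_tol * diff(range(scores))` of the
#'   maximum count as tied.
#' @return the chosen K; the full score vector is attached as attribute
#'   `"scores"`.
#' @export
choose_K <- function(consensus, K_values = NULL, tie_tol = 0.01) {
  M <- if (inherits(consensus, "synclust_consensus")) consensus$grand else consensus
  K_values <- K_values %||%
    (if (inherits(consensus, "synclust_consensus")) consensus$K_values
     else stop_synclust("K_values required when passing a bare matrix",
                        "synclust_parameter_error"))
  sc <- block_scores(M, K_values)
  tol <- tie_tol * diff(range(sc))
  out <- K_values[which(sc >= max(sc) - tol)[1L]]
  attr(out, "scores") <- sc
  out
}

#' Final best-of-restarts fit at the chosen K
#'
#' Fits `restarts` independent EM runs and keeps the highest log-likelihood
#' model; hard labels are the argmax responsibilities and clusters are
#' renumbered in decreasing size (ties broken by first occurrence).
#'
#' @param x data matrix.
#' @param K_star chosen number of clusters.
#' @param restarts number of restarts.
#' @param seed master seed.
#' @param ... passed to [mppca()].
#' @return list with `model`, `responsibilities`, `labels`, `sizes`.
#' @export
final_assignment <- function(x, K_star, restarts = 10, seed, ...) {
  model <- mppca(x, K = K_star, seed = seed, nstart = restarts, ...)
  q <- model$responsibilities
  labels <- max.col(q, ties.method = "first")
  sizes <- tabulate(labels, K_star)
  ord <- order(-sizes, seq_len(K_star))
  relab <- match(seq_len(K_star), ord)
  model$W <- model$W[, ord, drop = FALSE]
  model$sigma2 <- model$sigma2[ord]
  model$pi <- model$pi[ord]
  model$responsibilities <- q[, ord, drop = FALSE]
  model$labels <- relab[labels]
  list(model = model, responsibilities = model$responsibilities,
       labels = model$labels, sizes = sizes[ord])
}

#' Optimal leaf ordering of a consensus matrix
#'
#' Hierarchical clustering (average linkage) on dissimilarity `1 - M`,
#' followed by exact optimal leaf ordering: among the orderings consistent
#' with the dendrogram, the one minimizing the sum of adjacent
#' dissimilarities. Ties are broken toward the smaller leaf index; of the two
#' mirror-image optimal orders the one whose first element has the lower
#' original index is returned.
#'
#' @param M symmetric co-occurrence/consensus matrix (or a dissimilarity
#'   matrix if `dissimilarity = TRUE`).
#' @param linkage linkage method for the dendrogram.
#' @param dissimilarity interpret `M` directly as dissimilarities.
#' @return integer permutation of `1..nrow(M)`.
#' @export
olo_order <- function(M, linkage = "average", dissimilarity = FALSE) {
  D <- if (dissimilarity) M else 1 - M
  J <- nrow(D)
  if (J == 1L) return(1L)
  if (J == 2L) return(1:2)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  olo_from_hclust(hc, D)
}

#' Exact DP over subtree orientations (Bar-Joseph style)
#' @noRd
olo_from_hclust <- function(hc, D) {
  merge <- hc$merge
  n_nodes <- nrow(merge)
  leaves <- vector("list", n_nodes)
  costs <- vector("list", n_nodes)   # matrix over (left-end, right-end) leaves

  node_leaves <- function(id) if (id < 0) -id else leaves[[id]]
  node_cost <- function(id) {
    if (id < 0) return(matrix(0, 1, 1, dimnames = list(-id, -id)))
    costs[[id]]
  }
  minplus <- function(A, B) {
    # (i, k) -> min_m A[i, m] + B[m, k]
    R <- matrix(Inf, nrow(A), ncol(B))
    for (m in seq_len(ncol(A))) R <- pmin(R, outer(A[, m], B[m, ], "+"))
    R
  }

  for (v in seq_len(n_nodes)) {
    L <- node_leaves(merge[v, 1]); R <- node_leaves(merge[v, 2])
    CL <- node_cost(merge[v, 1]); CR <- node_cost(merge[v, 2])
    H <- minplus(CL, D[L, R, drop = FALSE])
    CV <- minplus(H, CR)                     # cost[u in L, w in R]
    full <- matrix(Inf, length(L) + length(R), length(L) + length(R))
    all_lv <- c(L, R)
    dimnames(full) <- list(all_lv, all_lv)
    iL <- seq_along(L); iR <- length(L) + seq_along(R)
    full[iL, iR] <- CV
    full[iR, iL] <- t(CV)
    leaves[[v]] <- all_lv
    costs[[v]] <- full
  }

  root <- n_nodes
  Cst <- costs[[root]]
  lv <- leaves[[root]]
  best <- which(Cst == min(Cst), arr.ind = TRUE)
  # deterministic tie-break: smallest (u, w) leaf-index pair
  key <- order(lv[best[, 1]], lv[best[, 2]])[1L]
  u <- lv[best[key, 1]]; w <- lv[best[key, 2]]

  expand <- function(id, u, w) {
    if (id < 0) return(-id)
    L <- node_leaves(merge[id, 1]); R <- node_leaves(merge[id, 2])
    if (u %in% R) {                 # mirrored arrangement
      return(rev(expand(id, w, u)))
    }
    CL <- node_cost(merge[id, 1]); CR <- node_cost(merge[id, 2])
    iu <- match(u, L); iw <- match(w, R)
    # argmin over junction leaves m (right end of left child), k (left end of right child)
    tot <- outer(CL[iu, ], rep(1, length(R))) + D[L, R, drop = FALSE] +
      outer(rep(1, length(L)), CR[, iw])
    bm <- which(tot == min(tot), arr.ind = TRUE)
    key <- order(L[bm[, 1]], R[bm[, 2]])[1L]
    m <- L[bm[key, 1]]; k <- R[bm[key, 2]]
    c(expand(merge[id, 1], u, m), expand(merge[id, 2], k, w))
  }
  ord <- expand(root, u, w)
  if (ord[1L] > ord[length(ord)]) ord <- rev(ord)
  ord
}

#' @export
print.synclust_consensus <- function(x, ...) {
  cat(sprintf("Consensus co-occurrence clustering (%d vectors; K in {%s}, %d restarts)\n",
              nrow(x$grand), paste(x$K_values, collapse = ", "), x$restarts))
  cat("Block-structure scores:\n")
  print(round(x$scores, 4))
  cat(sprintf("Chosen K* = %d%s\n", x$K_star,
              if (!identical(x$K_star, x$K_auto))
                sprintf(" (override; score-based choice was %d)", x$K_auto) else ""))
  cat("Final cluster sizes:", paste(x$sizes, collapse = " / "), "\n")
  invisible(x)
}

#' @export
plot.synclust_consensus <- function(x, ...) {
  ord <- x$leaf_order
  M <- x$grand[ord, ord]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M[, rev(seq_len(ncol(M)))],
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "perturbation (leaf order)", ylab = "",
                  main = "Consensus co-occurrence", ...)
  invisible(x)
}

#' Write consensus matrices and the assignment table to TSV
#'
#' @param consensus a `synclust_consensus` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_consensus <- function(consensus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- consensus$leaf_order
  ids <- rownames(consensus$grand) %||% as.character(seq_len(nrow(consensus$grand)))
  gm <- as.data.frame(consensus$grand[ord, ord])
  names(gm) <- ids[ord]
  gm <- cbind(id = ids[ord], gm)
  write_tsv_prov(gm, file.path(dir, "consensus_matrix.tsv"), seed = consensus$seed)
  for (k in names(consensus$per_K)) {
    m <- as.data.frame(consensus$per_K[[k]][ord, ord])
    names(m) <- ids[ord]
    write_tsv_prov(cbind(id = ids[ord], m),
                   file.path(dir, sprintf("cooccurrence_K%s.tsv", k)),
                   seed = consensus$seed)
  }
  q <- consensus$responsibilities
  at <- data.frame(id = ids, cluster = consensus$labels,
                   stats::setNames(as.data.frame(q),
                                   paste0("q", seq_len(ncol(q)))))
  write_tsv_prov(at, file.path(dir, "assignments.tsv"), seed = consensus$seed)
  invisible(dir)
}
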