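# Geometry of the quantal release model in log2 effect space.
#
# With quantal size unchanged, evoked amplitude factorizes as
# A = RRP * Pv * q, so log2 effects obey the plane x_A = x_RRP + x_Pv.
# In the (RRP, Pv, A) axis order used throughout, the plane has unit normal
# (1, 1, -1)/sqrt(3); its intersection with the unit sphere is the
# "release-model great circle" of admissible effect orientations.

release_plane_normal <- c(1, 1, -1) / sqrt(3)

# fixed orthonormal in-plane basis (so circle angles are reproducible)
release_basis <- cbind(c(1, 0, 1) / sqrt(2), c(1, -2, -1) / sqrt(6))

#' Points on the release-model great circle
#'
#' Parameterizes the intersection of the unit sphere with the plane
#' `x_A = x_RRP + x_Pv` (axis order RRP, Pv, A). Every returned point has unit
#' norm and satisfies the plane equation to machine precision.
#'
#' @param theta angles in radians.
#' @return length(theta) x 3 matrix with columns RRP, Pv, A.
#' @export
release_circle <- function(theta) {
  m <- cbind(cos(theta), sin(theta)) %*% t(release_basis)
  colnames(m) <- EVOKED_VARS
  m
}

#' Project a direction onto the release-model circle
#'
#' Nearest point on the great circle by Euclidean (equivalently angular)
#' distance: project onto the plane, then normalize. Idempotent for points
#' already on the circle.
#'
#' @param w 3-vector (need not be unit length) in (RRP, Pv, A) order.
#' @return unit 3-vector on the circle.
#' @export
project_to_release_circle <- function(w) {
  stopifnot(length(w) == 3L)
  if (sqrt(sum(w^2)) < 1e-12) {
    stop_synclust("degenerate (zero) direction cannot be projected",
                  "synclust_degenerate_error")
  }
  y <- w - sum(w * release_plane_normal) * release_plane_normal
  ny <- sqrt(sum(y^2))
  if (ny < 1e-12) {
    # direction normal to the plane: every circle point is equidistant;
    # return the angle-0 point by convention
    warning("direction is normal to the release plane; projection is arbitrary")
    return(stats::setNames(release_basis[, 1], EVOKED_VARS))
  }
  stats::setNames(y / ny, EVOKED_VARS)
}

#' Cluster unit vectors and their release-model projections
#'
#' Normalizes each component loading to a unit orientation vector, fixes the
#' sign so the largest-magnitude coordinate is positive, and projects each
#' onto the release-model circle.
#'
#' @param model a fitted [mppca()] object over the 3-D evoked space.
#' @return list with `unit_vectors` (3 x K, columns named by cluster),
#'   `projections` (3 x K points on the circle), `angles` (circle angle of
#'   each projection, radians), `plane_angle` (angular distance of each unit
#'   vector from the release plane, radians).
#' @export
cluster_unit_vectors <- function(model) {
  W <- model$W
  if (nrow(W) != 3L) stop_synclust("release-model geometry needs a 3-D model",
                                   "synclust_validation_error")
  nrm <- sqrt(colSums(W^2))
  if (any(nrm < 1e-12)) stop_synclust("degenerate component with zero loading",
                                      "synclust_degenerate_error")
  uv <- sweep(W, 2L, nrm, "/")
  for (k in seq_len(ncol(uv))) {
    i <- which.max(abs(uv[, k]))
    if (uv[i, k] < 0) uv[, k] <- -uv[, k]
  }
  rownames(uv) <- EVOKED_VARS
  proj <- apply(uv, 2L, project_to_release_circle)
  ang <- atan2(drop(release_basis[, 2] %*% proj), drop(release_basis[, 1] %*% proj))
  plane_ang <- asin(pmin(1, abs(drop(release_plane_normal %*% uv))))
  list(unit_vectors = uv, projections = proj, angles = ang,
       plane_angle = plane_ang)
}

FIXED_ANGLES <- c(0, 45, 90, 135)
# tie preference: proportionality first, then the axes, then anti-proportional
ANGLE_PREFERENCE <- c(45, 0, 135, 90)

#' Weighted orthogonal error to a fixed origin-line
#'
#' Sum of weighted squared perpendicular distances from 2-D points to the line
#' through the origin at the given angle (degrees, counter-clockwise from the
#' x-axis). Computed by rotation, so vertical (90 degree) lines need no
#' special-casing. Also returns the weight-corrected error (error divided by
#' the summed weights).
#'
#' @param points n x 2 matrix of complete observations.
#' @param weights non-negative weights in `[0, 1]` (default 1).
#' @param angle line angle in degrees.
#' @return list with `error`, `corrected`, `n`, `total_weight`.
#' @export
weighted_orthogonal_error <- function(points, weights = NULL, angle) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    stop_synclust("orthogonal error is undefined for an empty point set",
                  "synclust_undefined_error")
  }
  if (anyNA(points)) stop_synclust("points must be complete",
                                   "synclust_validation_error")
  weights <- weights %||% rep(1, nrow(points))
  th <- angle * pi / 180
  d <- points[, 1] * (-sin(th)) + points[, 2] * cos(th)   # signed distance
  err <- sum(weights * d^2)
  list(error = err, corrected = err / sum(weights),
       n = nrow(points), total_weight = sum(weights))
}

#' Best of the four fixed regression orientations
#'
#' Evaluates the weighted orthogonal error of the 0, 45, 90 and 135 degree
#' origin-lines and returns the minimizer. Exact ties are broken toward 45,
#' then 0, then 135, then 90 degrees (proportionality preferred).
#'
#' @inheritParams weighted_orthogonal_error
#' @return one-row data.frame: `error_0` .. `error_135`, `corrected_0` ..
#'   `corrected_135`, `best_angle`, `best_error`, `best_corrected`, `n`,
#'   `mean_weight`.
#' @export
fit_best_orientation <- function(points, weights = NULL) {
  errs <- lapply(FIXED_ANGLES, function(a)
    weighted_orthogonal_error(points, weights, a))
  names(errs) <- FIXED_ANGLES
  ev <- vapply(errs, `[[`, numeric(1), "error")
  pref <- as.character(ANGLE_PREFERENCE)
  best <- pref[which(ev[pref] == min(ev))[1L]]
  out <- data.frame(t(stats::setNames(ev, paste0("error_", FIXED_ANGLES))))
  for (a in FIXED_ANGLES) {
    out[[paste0("corrected_", a)]] <- errs[[as.character(a)]]$corrected
  }
  out$best_angle <- as.numeric(best)
  out$best_error <- ev[[best]]
  out$best_corrected <- errs[[best]]$corrected
  out$n <- errs[[1]]$n
  out$mean_weight <- errs[[1]]$total_weight / errs[[1]]$n
  out
}

EVOKED_PROJECTIONS <- list(c("RRP", "Pv"), c("A", "RRP"), c("A", "Pv"))
F_PROJECTIONS <- list(c("A", "F"), c("RRP", "F"), c("Pv", "F"))

#' Fixed-orientation fits per cluster and 2-D projection
#'
#' For every cluster (weights = that cluster's assignment probabilities) and
#' for the pooled non-clustered case (unit weights), fits the four fixed
#' orientations in each 2-D projection, using the rows where both coordinates
#' are observed. The first-named variable of a projection is its x-axis.
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param q J x K matrix of assignment probabilities (rows matching `pv`).
#' @param projections list of variable pairs; defaults to the three
#'   evoked-release projections.
#' @param weights optional J-vector multiplied into the cluster
#'   probabilities (e.g. gene-correction weights); also used, alone, for the
#'   pooled case when supplied.
#' @return data.frame of class `"synclust_orientation"`: one row per
#'   (cluster x projection) plus pooled rows (`cluster = "pooled"`).
#' @export
orientation_fit <- function(pv, q, projections = EVOKED_PROJECTIONS,
                            weights = NULL) {
  x <- as.matrix(as.data.frame(pv)[paste0("x_", ALL_VARS)])
  colnames(x) <- ALL_VARS
  K <- ncol(q)
  base_w <- weights %||% rep(1, nrow(x))
  rows <- list()
  for (pr in projections) {
    ok <- which(stats::complete.cases(x[, pr]))
    if (length(ok) == 0L) next
    pts <- x[ok, pr, drop = FALSE]
    for (k in seq_len(K)) {
      f <- fit_best_orientation(pts, (base_w * q[, k])[ok])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(cluster = as.character(k),
                         projection = paste(pr, collapse = "-")), f)
    }
    fp <- fit_best_orientation(pts, base_w[ok])
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(cluster = "pooled",
                       projection = paste(pr, collapse = "-")), fp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synclust_orientation", "data.frame")
  out
}

#' Error reduction achieved by clustering
#'
#' One minus the ratio of the summed best-orientation weighted errors of the
#' per-cluster fits to the summed best-orientation errors of the pooled
#' (unit-weight) fits, over the same projections.
#'
#' @param fits a `synclust_orientation` table from [orientation_fit()]
#'   containing both cluster and pooled rows.
#' @return scalar in `(-Inf, 1]`.
#' @export
error_reduction <- function(fits) {
  cl <- fits[fits$cluster != "pooled", ]
  po <- fits[fits$cluster == "pooled", ]
  denom <- sum(po$best_error)
  if (denom == 0) {
    stop_synclust("pooled error is zero; reduction statistic undefined",
                  "synclust_undefined_error")
  }
  1 - sum(cl$best_error) / denom
}

#' Permutation null for the proportional (45 degree) model
#'
#' The observed statistic is the pooled average orthogonal error of the
#' proportional model: total squared perpendicular distance to the 45-degree
#' line over the chosen projections, divided by the total number of
#' pairwise-complete points. Each permutation independently shuffles the
#' observed values within each variable column, leaving the missingness
#' pattern in place (`scheme = "within_column"`), or shuffles all observed
#' entries across the whole matrix (`scheme = "across_matrix"`). The p-value
#' is `(1 + #[null <= observed]) / (1 + n_perm)`: small when the observed
#' proportional structure is stronger than chance.
#'
#' @param x data matrix with `NA`s (variables in columns), or a
#'   `synclust_perturbations` (all four variables used).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param projections list of column-name pairs; defaults to the three
#'   evoked-release projections.
#' @param scheme permutation scheme.
#' @return list with `observed`, `null` (length `n_perm`), `p_value`,
#'   `n_perm`, `scheme`.
#' @export
permutation_null <- function(x, n_perm = 1000, seed,
                             projections = EVOKED_PROJECTIONS,
                             scheme = c("within_column", "across_matrix")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "synclust_perturbations")) {
    x <- as.matrix(as.data.frame(x)[paste0("x_", ALL_VARS)])
    colnames(x) <- ALL_VARS
  }
  if (n_perm < 1) stop_synclust("n_perm must be >= 1", "synclust_parameter_error")
  stat <- function(m) {
    tot <- 0; n <- 0L
    for (pr in projections) {
      ok <- stats::complete.cases(m[, pr])
      if (!any(ok)) next
      e <- weighted_orthogonal_error(m[ok, pr, drop = FALSE], angle = 45)
      tot <- tot + e$error
      n <- n + e$n
    }
    if (n == 0L) stop_synclust("no complete pairs in any projection",
                               "synclust_undefined_error")
    tot / n
  }
  observed <- stat(x)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    xp <- x
    if (scheme == "within_column") {
      for (cn in colnames(x)) {
        obs <- which(!is.na(x[, cn]))
        xp[obs, cn] <- x[sample(obs), cn]
      }
    } else {
      obs <- which(!is.na(x))
      xp[obs] <- x[sample(obs)]
    }
    stat(xp)
  }, numeric(1))
  list(observed = observed, null = null,
       p_value = (1 + sum(null <= observed)) / (1 + n_perm),
       n_perm = n_perm, scheme = scheme)
}

#' Write orientation fits to TSV
#'
#' @param fits a `synclust_orientation` table.
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_orientation <- function(fits, path, seed = NULL) {
  write_tsv_prov(as.data.frame(fits), path, seed = seed)
  invisible(path)
}
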