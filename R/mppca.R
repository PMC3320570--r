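#' Mixture of origin-anchored probabilistic principal component analyzers
#'
#' Fits a K-component mixture model to control-normalized log2 effect vectors
#' in the evoked-release space (RRP, Pv, A). Each component is a zero-mean
#' Gaussian with rank-1-plus-isotropic covariance
#' \deqn{C_k = w_k w_k' + \sigma^2_k I,}
#' i.e. a noisy line through the origin. The origin is the no-effect point, so
#' components capture *orientations* of perturbation effects irrespective of
#' effect size. Missing coordinates are handled exactly: a vector observed on
#' index set O contributes the Gaussian marginal with covariance `C_k[O, O]`
#' to the likelihood, and the M-step uses expected sufficient statistics with
#' the missing coordinates treated as additional latent variables.
#'
#' @param x numeric matrix (rows = perturbations, columns = variables, `NA`
#'   for unobserved entries) or a `synclust_perturbations` data.frame, from
#'   which the evoked-release matrix is taken.
#' @param K number of mixture components.
#' @param seed integer seed for the random initialization (required when
#'   `nstart > 0`).
#' @param nstart number of random restarts; the best final log-likelihood
#'   wins.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param min_observed vectors with fewer observed coordinates than this are
#'   excluded from the fit (they still receive responsibilities). Set to 1 to
#'   fit on every vector with at least one observed coordinate.
#' @param sigma2_floor lower bound on the isotropic noise variance.
#' @param init optional list of starting values with elements `W` (d x K),
#'   `sigma2`, `pi`; overrides random initialization.
#' @return an object of class `"mppca"` with elements `K`, `W` (d x K loading
#'   matrix), `sigma2`, `pi`, `logLik`, `loglik_trace`, `responsibilities`
#'   (all input rows with >= 1 observed coordinate), `labels` (argmax
#'   responsibility), `converged`, `n_iter`, `fitted_rows`, `data`, `seed`.
#' @examples
#' sim <- simulate_orientations(n_per = 50, angles_deg = c(0, 60, 120),
#'                              noise_sd = 0.1, seed = 1)
#' fit <- mppca(sim$x, K = 3, seed = 2, nstart = 5)
#' fit
#' table(sim$cluster, fit$labels)
#' @seealso [responsibilities()], [mppca_loglik()], [consensus_cluster()]
#' @export
mppca <- function(x, K, seed = NULL, nstart = 1, max_iter = 500, tol = 1e-8,
                  min_observed = 2, sigma2_floor = 1e-6, init = NULL) {
  if (inherits(x, "synclust_perturbations")) x <- evoked_matrix(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  J <- nrow(x)
  d <- ncol(x)
  if (K < 1) stop_synclust("K must be >= 1", "synclust_parameter_error")
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs == 0L)) {
    stop_synclust(sprintf("row(s) %s have no observed coordinates",
                          paste(which(n_obs == 0L), collapse = ", ")),
                  "synclust_validation_error")
  }
  fit_rows <- which(n_obs >= min_observed)
  if (K >= length(fit_rows)) {
    stop_synclust("K must be smaller than the number of fitted vectors",
                  "synclust_parameter_error")
  }

  xf <- x[fit_rows, , drop = FALSE]
  data_rms <- sqrt(mean(xf^2, na.rm = TRUE))
  data_var <- stats::var(as.vector(xf), na.rm = TRUE)

  if (!is.null(init)) {
    seeds <- NA_integer_
    nstart <- 1L
  } else {
    if (is.null(seed)) stop_synclust("seed is required for random initialization",
                                     "synclust_parameter_error")
    seeds <- derive_seeds(seed, nstart)
  }

  best <- NULL
  for (r in seq_len(nstart)) {
    theta <- if (!is.null(init)) {
      list(W = as.matrix(init$W), sigma2 = rep_len(init$sigma2, K),
           pi = rep_len(init$pi, K))
    } else {
      init_random(d, K, data_rms, data_var, seeds[r])
    }
    res <- em_mppca(xf, theta, max_iter = max_iter, tol = tol,
                    sigma2_floor = sigma2_floor, seed_reinit = seeds[r])
    if (is.null(best) || res$logLik > best$logLik) best <- res
  }

  q <- resp_matrix(x, best$W, best$sigma2, best$pi)
  obj <- structure(list(
    K = K, W = best$W, sigma2 = best$sigma2, pi = best$pi,
    logLik = best$logLik, loglik_trace = best$trace,
    responsibilities = q, labels = max.col(q, ties.method = "first"),
    converged = best$converged, n_iter = best$n_iter,
    fitted_rows = fit_rows, data = x, seed = seed,
    min_observed = min_observed, call = match.call()
  ), class = "mppca")
  if (!best$converged) {
    warning("EM did not converge within max_iter; results carry converged = FALSE")
  }
  obj
}

#' @noRd
init_random <- function(d, K, data_rms, data_var, seed) {
  set.seed(seed)
  W <- matrix(stats::rnorm(d * K), d, K)
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/") * data_rms
  list(W = W, sigma2 = rep(0.5 * data_var, K), pi = rep(1 / K, K))
}

#' Group rows of a masked matrix by observation pattern
#' @noRd
obs_patterns <- function(x) {
  obs <- !is.na(x)
  key <- apply(obs, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(x)), key), function(idx) {
    O <- which(obs[idx[1L], ])
    list(rows = idx, O = O, X = x[idx, O, drop = FALSE])
  })
}

#' Per-pattern component log-density and latent moments
#'
#' For a component (w, s2) and observed index set O:
#' C = w_O w_O' + s2 I; via the rank-1 Woodbury identity,
#' quadratic form and determinant are closed-form.
#' @noRd
pat_estep <- function(pat, w, s2) {
  wO <- w[pat$O]
  nO <- length(pat$O)
  g <- s2 + sum(wO^2)                      # 1 + w_O' w_O / s2, rescaled
  a <- drop(pat$X %*% wO)                  # x_O . w_O
  ss <- rowSums(pat$X^2)
  quad <- (ss - a^2 / g) / s2
  logdet <- (nO - 1) * log(s2) + log(g)
  list(
    logdens = -0.5 * (nO * log(2 * pi) + logdet + quad),
    m = a / g,                             # E[t | x_O]
    v = s2 / g,                            # Var[t | x_O]
    ss = ss
  )
}

#' One EM run (monotone in log-likelihood)
#' @noRd
em_mppca <- function(x, theta, max_iter, tol, sigma2_floor, seed_reinit) {
  J <- nrow(x)
  d <- ncol(x)
  K <- ncol(theta$W)
  W <- theta$W
  sigma2 <- pmax(theta$sigma2, sigma2_floor)
  piw <- theta$pi / sum(theta$pi)
  pats <- obs_patterns(x)
  trace <- numeric(0)
  reinit_used <- rep(FALSE, K)
  converged <- FALSE
  it <- 0L

  repeat {
    it <- it + 1L
    # E-step: log pi_k + log N(x_O; 0, C_k[O,O]) for every row, component
    lp <- matrix(NA_real_, J, K)
    est <- vector("list", K)
    for (k in seq_len(K)) {
      ek <- vector("list", length(pats))
      for (p in seq_along(pats)) {
        e <- pat_estep(pats[[p]], W[, k], sigma2[k])
        lp[pats[[p]]$rows, k] <- log(piw[k]) + e$logdens
        ek[[p]] <- e
      }
      est[[k]] <- ek
    }
    lse <- log_sum_exp(lp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    q <- exp(lp - lse)

    if (it > 1L) {
      rel <- abs(ll - trace[it - 1L]) / (abs(trace[it - 1L]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (it >= max_iter) break

    # M-step with expected sufficient statistics
    for (k in seq_len(K)) {
      S1 <- numeric(d)   # sum_j q E[x_j t_j]
      S2 <- 0            # sum_j q E[t_j^2]
      A1 <- 0            # sum_j q E[|x_j|^2]
      Nk <- 0
      for (p in seq_along(pats)) {
        pat <- pats[[p]]
        e <- est[[k]][[p]]
        qk <- q[pat$rows, k]
        M <- setdiff(seq_len(d), pat$O)
        Et2 <- e$v + e$m^2
        S1[pat$O] <- S1[pat$O] + colSums(pat$X * (qk * e$m))
        if (length(M) > 0L) S1[M] <- S1[M] + W[M, k] * sum(qk * Et2)
        S2 <- S2 + sum(qk * Et2)
        A1 <- A1 + sum(qk * e$ss) +
          sum(W[M, k]^2) * sum(qk * Et2) + length(M) * sigma2[k] * sum(qk)
        Nk <- Nk + sum(qk)
      }
      w_new <- S1 / S2
      s2_new <- (A1 - sum(S1^2) / S2) / (d * Nk)
      W[, k] <- w_new
      sigma2[k] <- max(s2_new, sigma2_floor)
      piw[k] <- Nk / J
    }
    piw <- piw / sum(piw)

    # collapsed component: one fresh re-initialization, then proceed
    collapsed <- which(piw < 1 / (10 * J) & !reinit_used)
    if (length(collapsed) > 0L) {
      set.seed(seed_reinit + it)
      for (k in collapsed) {
        wk <- stats::rnorm(d)
        W[, k] <- wk / sqrt(sum(wk^2)) * sqrt(mean(x^2, na.rm = TRUE))
        sigma2[k] <- max(0.5 * stats::var(as.vector(x), na.rm = TRUE), sigma2_floor)
        piw[k] <- 1 / K
        reinit_used[k] <- TRUE
      }
      piw <- piw / sum(piw)
    }
  }

  list(W = W, sigma2 = sigma2, pi = piw, logLik = trace[length(trace)],
       trace = trace, converged = converged, n_iter = it)
}

#' @noRd
resp_matrix <- function(x, W, sigma2, piw, sem = NULL) {
  J <- nrow(x)
  K <- ncol(W)
  lp <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) {
    O <- which(!is.na(x[j, ]))
    if (length(O) == 0L) {
      stop_synclust(sprintf("row %d has no observed coordinates", j),
                    "synclust_validation_error")
    }
    xo <- x[j, O]
    for (k in seq_len(K)) {
      wO <- W[O, k]
      C <- tcrossprod(wO) + diag(sigma2[k], length(O))
      if (!is.null(sem)) {
        s <- sem[j, O]
        s[is.na(s)] <- 0
        C <- C + diag(s^2, length(O))
      }
      lp[j, k] <- log(piw[k]) + dmvnorm0(xo, C)
    }
  }
  lse <- log_sum_exp(lp)
  attr(lse, "total") <- sum(lse)
  q <- exp(lp - lse)
  rownames(q) <- rownames(x)
  attr(q, "logLik") <- sum(lse)
  q
}

#' Zero-mean multivariate normal log-density
#' @noRd
dmvnorm0 <- function(x, C) {
  R <- chol(C)
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi)) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Posterior cluster assignment probabilities
#'
#' `q[j, k]` is proportional to `pi_k N(x_j[O_j]; 0, C_k[O_j, O_j])`,
#' normalized over components. Deterministic given the model and data.
#'
#' @param model a fitted [mppca()] object.
#' @param x data matrix in the model's variable space (`NA` = unobserved);
#'   defaults to the training data.
#' @param sem optional matrix of per-entry measurement SEMs; when given,
#'   `diag(sem^2)` is added to each component's observed-covariance block
#'   (evaluation-time measurement-error mode).
#' @return J x K matrix of probabilities with rows summing to 1; attribute
#'   `"logLik"` carries the total log-likelihood of `x` under the model.
#' @export
responsibilities <- function(model, x = NULL, sem = NULL) {
  stopifnot(inherits(model, "mppca"))
  if (is.null(x)) x <- model$data
  if (inherits(x, "synclust_perturbations")) x <- evoked_matrix(x)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$W)) {
    stop_synclust("dimension mismatch between model and data",
                  "synclust_validation_error")
  }
  resp_matrix(x, model$W, model$sigma2, model$pi, sem = sem)
}

#' Total log-likelihood of data under a fitted mixture
#'
#' @inheritParams responsibilities
#' @return scalar log-likelihood.
#' @export
mppca_loglik <- function(model, x = NULL, sem = NULL) {
  attr(responsibilities(model, x, sem = sem), "logLik")
}

#' @export
logLik.mppca <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- object$K * (nrow(object$W) + 2) - 1
  attr(val, "nobs") <- length(object$fitted_rows)
  class(val) <- "logLik"
  val
}

#' @export
print.mppca <- function(x, digits = 3, ...) {
  cat(sprintf("Mixture of probabilistic PCA orientations (K = %d, %d vectors fitted)\n",
              x$K, length(x$fitted_rows)))
  uv <- sweep(x$W, 2L, sqrt(colSums(x$W^2)), "/")
  for (k in seq_len(x$K)) {
    cat(sprintf("  component %d: pi = %.3f, sigma2 = %.4g, orientation = (%s)\n",
                k, x$pi[k], x$sigma2[k],
                paste(sprintf(paste0("%.", digits, "f"), uv[, k]), collapse = ", ")))
  }
  cat(sprintf("  log-likelihood: %.4f (%s after %d EM iterations)\n",
              x$logLik, if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.mppca <- function(object, ...) {
  uv <- sweep(object$W, 2L, sqrt(colSums(object$W^2)), "/")
  out <- list(
    K = object$K, unit_vectors = uv, sigma2 = object$sigma2, pi = object$pi,
    sizes = tabulate(object$labels, object$K), logLik = object$logLik,
    converged = object$converged, n_iter = object$n_iter,
    mean_max_prob = mean(apply(object$responsibilities, 1L, max))
  )
  class(out) <- "summary.mppca"
  out
}

#' @export
print.summary.mppca <- function(x, ...) {
  cat(sprintf("MPPCA with K = %d components\n", x$K))
  cat("Cluster sizes (argmax assignment):", paste(x$sizes, collapse = " / "), "\n")
  cat("Mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " / "), "\n")
  cat("Noise variances:", paste(sprintf("%.4g", x$sigma2), collapse = " / "), "\n")
  cat("Unit orientation vectors (columns):\n")
  print(round(x$unit_vectors, 3))
  cat(sprintf("Mean max assignment probability: %.3f\n", x$mean_max_prob))
  cat(sprintf("log-likelihood %.4f after %d iterations (%s)\n",
              x$logLik, x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.mppca <- function(object, ...) {
  list(W = object$W, sigma2 = object$sigma2, pi = object$pi)
}

#' @export
predict.mppca <- function(object, newdata = NULL, type = c("response", "class"),
                          sem = NULL, ...) {
  type <- match.arg(type)
  q <- responsibilities(object, newdata, sem = sem)
  if (type == "class") max.col(q, ties.method = "first") else q
}

#' @export
simulate.mppca <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(object$W)
  k <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
  t <- stats::rnorm(nsim)
  x <- t(object$W[, k, drop = FALSE]) * t +
    matrix(stats::rnorm(nsim * d, sd = rep(sqrt(object$sigma2[k]), each = d)),
           nsim, d, byrow = TRUE)
  colnames(x) <- rownames(object$W) %||% colnames(object$data)
  attr(x, "component") <- k
  x
}

#' @export
residuals.mppca <- function(object, ...) {
  # orthogonal distance (within the observed subspace) to the line of the
  # dominant component
  x <- object$data
  vapply(seq_len(nrow(x)), function(j) {
    O <- which(!is.na(x[j, ]))
    w <- object$W[O, object$labels[j]]
    xo <- x[j, O]
    proj <- sum(xo * w) / sum(w^2)
    sqrt(max(sum(xo^2) - proj^2 * sum(w^2), 0))
  }, numeric(1))
}

#' @export
plot.mppca <- function(x, pairs = NULL, ...) {
  d <- ncol(x$data)
  vars <- colnames(x$data) %||% paste0("V", seq_len(d))
  if (is.null(pairs)) pairs <- utils::combn(d, 2, simplify = FALSE)
  oldpar <- graphics::par(mfrow = c(1, length(pairs)))
  on.exit(graphics::par(oldpar))
  cols <- grDevices::hcl.colors(x$K, "Dark 3")
  for (pr in pairs) {
    ok <- stats::complete.cases(x$data[, pr])
    graphics::plot(x$data[ok, pr[1]], x$data[ok, pr[2]],
                   col = cols[x$labels[ok]],
                   cex = 0.5 + 1.5 * apply(x$responsibilities[ok, , drop = FALSE], 1, max),
                   xlab = vars[pr[1]], ylab = vars[pr[2]], pch = 19, ...)
    graphics::abline(h = 0, v = 0, col = "grey80")
    for (k in seq_len(x$K)) {
      w <- x$W[pr, k]
      if (abs(w[1]) > 1e-12) graphics::abline(0, w[2] / w[1], col = cols[k], lty = 2)
      else graphics::abline(v = 0, col = cols[k], lty = 2)
    }
  }
  invisible(x)
}

#' Serialize a fitted mixture to JSON
#'
#' @param model a fitted [mppca()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mppca_json <- function(model, path) {
  payload <- list(
    K = model$K,
    W = unname(apply(model$W, 2L, identity, simplify = FALSE)),
    sigma2 = model$sigma2, pi = model$pi,
    logLik = model$logLik, converged = model$converged,
    n_iter = model$n_iter, seed = model$seed,
    package_version = as.character(utils::packageVersion("synclust"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized mixture model
#'
#' @param path path written by [write_mppca_json()].
#' @return an `mppca` object without data/responsibilities.
#' @export
read_mppca_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    K = p$K, W = matrix(unlist(p$W), ncol = p$K),
    sigma2 = p$sigma2, pi = p$pi, logLik = p$logLik,
    converged = p$converged, n_iter = p$n_iter, seed = p$seed
  ), class = "mppca")
}
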