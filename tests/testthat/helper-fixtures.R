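# fixture builders shared across test files

# a minimal database row in the canonical column layout
db_row <- function(author = "smith", pubmed_id = 111, gene_symbol = "geneX",
                   description = "perturbation", control_offset = NA,
                   wt_reference = NA, gof_label = NA,
                   A = c(NA, NA, NA), RRP = c(NA, NA, NA),
                   Pv = c(NA, NA, NA), F = c(NA, NA, NA)) {
  row <- data.frame(author = author, pubmed_id = pubmed_id,
                    gene_symbol = gene_symbol, gene_family = NA,
                    description = description,
                    control_offset = control_offset,
                    wt_reference = wt_reference, gof_label = gof_label,
                    stringsAsFactors = FALSE)
  for (v in c("A", "RRP", "Pv", "F")) {
    val <- get(v)
    row[[paste0("mean_", v)]] <- val[1]
    row[[paste0("sem_", v)]] <- val[2]
    row[[paste0("n_", v)]] <- val[3]
  }
  row
}

# 3-row study block: one control + two perturbations linked by offset
make_linked_db <- function() {
  rbind(
    db_row(description = "control", gene_symbol = "control",
           A = c(1.0, 0.1, 10), RRP = c(100, 10, 10), Pv = c(30, 3, 10),
           F = c(2, 0.2, 10)),
    db_row(control_offset = 1, gene_symbol = "geneA",
           A = c(2.0, 0.2, 10), RRP = c(200, 20, 10), Pv = c(30, 3, 10)),
    db_row(control_offset = 2, gene_symbol = "geneB",
           A = c(0.5, 0.05, 10), Pv = c(15, 1.5, 10), F = c(1, 0.1, 10))
  )
}

# hand-constructed mppca model object (bypassing the fit) for method tests
make_mppca_model <- function(W, sigma2, piw, x = NULL) {
  obj <- structure(list(
    K = ncol(W), W = W, sigma2 = sigma2, pi = piw,
    logLik = NA_real_, loglik_trace = numeric(0),
    converged = TRUE, n_iter = 0L,
    fitted_rows = seq_len(if (is.null(x)) 0 else nrow(x)),
    data = x, seed = NA_integer_, min_observed = 1
  ), class = "mppca")
  if (!is.null(x)) {
    obj$responsibilities <- responsibilities(obj, x)
    obj$labels <- max.col(obj$responsibilities, ties.method = "first")
  }
  obj
}
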