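# internal helpers shared across modules

#' @noRd
log_sum_exp <- function(m) {
  # rowwise log(sum(exp(m))) for a matrix, guarded against -Inf rows
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Derive a stream of child seeds from one master seed
#'
#' Keeps every derived seed a valid 32-bit integer so nested calls to
#' `set.seed()` stay reproducible across platforms.
#' @noRd
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_synclust <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "synclust_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Write a table with a provenance header
#'
#' All file outputs carry `#`-prefixed header lines recording the package
#' version and the seed(s) consumed, so a result file is self-describing.
#' @noRd
write_tsv_prov <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("synclust"))
  writeLines(sprintf("# synclust %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", paste(seed, collapse = " ")), con)
  is_num <- vapply(x, is.numeric, logical(1))
  x[is_num] <- lapply(x[is_num], function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- NA_character_
    out
  })
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
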