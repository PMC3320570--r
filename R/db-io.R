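#' Read a perturbation database in the canonical delimited dialect
#'
#' The database is a UTF-8 tab-separated table with one row per experimental
#' group (a perturbation or a control). Each row carries study metadata and,
#' for each of the four synaptic variables -- evoked amplitude `A` (nA),
#' readily releasable pool `RRP` (pC), vesicular release probability `Pv` (%),
#' spontaneous event frequency `F` (Hz) -- a mean, an SEM and a cell count,
#' any of which may be absent. Absent cells are empty fields and are loaded as
#' `NA`, never as zero.
#'
#' Mandatory columns: `author`, `pubmed_id`, `gene_symbol`, `description`,
#' `control_offset`, `wt_reference`, and `mean_*`, `sem_*`, `n_*` for each
#' variable. Recognized optional columns: `gene_alias`, `gene_name`,
#' `gene_family`, `gof_label` (values `GOF`/`LOF` or empty),
#' `control_row` (explicit 1-based row id of the control, an alternative to
#' `control_offset`), `unit_A` .. `unit_F` (per-cell unit overrides), plus
#' free-form condition columns (`ca_mm`, `mg_mm`, `k_mm`, `na_mm`,
#' `ca_mg_ratio`, `compounds`, `div_mean`, `div_range`, `temperature_c`,
#' `source_A` .. `source_F`). Lines starting with `#` are provenance headers
#' and are skipped.
#'
#' Control linkage follows the rows-above convention: `control_offset = k`
#' means the control group sits `k` rows above the current row, within the
#' same study (same `author` + `pubmed_id`). Controls leave it empty.
#'
#' @param path path to the TSV file.
#' @param dialect only `"delimited"` is supported.
#' @return a `data.frame` of experiment records with a `study_id` column
#'   added; class `c("synclust_db", "data.frame")`.
#' @examples
#' db <- generate_database(paperlike_config(), seed = 1)$database
#' f <- tempfile(fileext = ".tsv")
#' write_database(db, f)
#' db2 <- read_database(f)
#' nrow(db2)
#' @export
read_database <- function(path, dialect = c("delimited")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), comment.char = "#",
                          fileEncoding = "UTF-8")
  as_synclust_db(df)
}

MANDATORY_COLS <- c("author", "pubmed_id", "gene_symbol", "description",
                    "control_offset", "wt_reference",
                    paste0("mean_", ALL_VARS), paste0("sem_", ALL_VARS),
                    paste0("n_", ALL_VARS))

#' Validate a data frame as a perturbation database
#'
#' Checks the canonical schema and the row-level invariants: means are strictly
#' positive magnitudes, an SEM requires its mean and is non-negative, and every
#' control link resolves to an existing row of the same study.
#'
#' @param df a data.frame in the canonical column layout.
#' @return the validated database with class `synclust_db`.
#' @export
as_synclust_db <- function(df) {
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop_synclust(sprintf("database schema error: missing mandatory column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "synclust_schema_error")
  }
  num_cols <- c(paste0("mean_", ALL_VARS), paste0("sem_", ALL_VARS),
                paste0("n_", ALL_VARS), "control_offset", "wt_reference")
  for (cl in intersect(c(num_cols, "control_row"), names(df))) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df$study_id <- paste(df$author, df$pubmed_id, sep = "_")

  bad <- integer(0)
  for (v in ALL_VARS) {
    m <- df[[paste0("mean_", v)]]
    s <- df[[paste0("sem_", v)]]
    bad <- union(bad, which(!is.na(m) & m <= 0))
    bad <- union(bad, which(!is.na(s) & (is.na(m) | s < 0)))
  }
  if (length(bad) > 0L) {
    stop_synclust(sprintf("database validation error in row(s) %s: means must be positive and SEMs require a non-negative mean",
                          paste(sort(bad), collapse = ", ")),
                  "synclust_validation_error")
  }

  ctrl <- resolve_control_rows(df)
  bad_link <- which(!is.na(df$control_offset) & is.na(ctrl))
  if ("control_row" %in% names(df)) {
    bad_link <- union(bad_link,
                      which(!is.na(df$control_row) & is.na(ctrl)))
  }
  if (length(bad_link) > 0L) {
    stop_synclust(sprintf("control linkage error in row(s) %s: referenced control row does not exist in the same study",
                          paste(sort(bad_link), collapse = ", ")),
                  "synclust_linkage_error")
  }
  class(df) <- c("synclust_db", "data.frame")
  df
}

#' Resolve the control row index for every database row
#'
#' Returns NA for controls (no link) and for unresolvable links.
#' @noRd
resolve_control_rows <- function(df) {
  n <- nrow(df)
  ctrl <- rep(NA_integer_, n)
  if ("control_row" %in% names(df)) {
    explicit <- !is.na(df$control_row)
    idx <- as.integer(df$control_row[explicit])
    ok <- idx >= 1L & idx <= n
    ctrl[explicit][ok] <- idx[ok]
  }
  off <- !is.na(df$control_offset) & is.na(ctrl)
  idx <- which(off) - as.integer(df$control_offset[off])
  ok <- idx >= 1L & idx <= n
  ok[ok] <- df$study_id[which(off)[ok]] == df$study_id[idx[ok]]
  ctrl[which(off)[ok]] <- idx[ok]
  ctrl
}

#' Write a perturbation database to the canonical delimited dialect
#'
#' Values round-trip exactly: numerics are written with 17 significant digits
#' and absent cells as empty fields.
#'
#' @param db a `synclust_db` (or compatible data.frame).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path, seed = NULL) {
  db$study_id <- NULL
  write_tsv_prov(as.data.frame(db), path, seed = seed)
  invisible(path)
}

#' Normalize perturbations to their within-study controls
#'
#' Every row with a resolvable control link becomes one perturbation vector:
#' for each variable reported by *both* the perturbation and its control,
#' the log2 fold-change `x_v = log2(mean_v^pert / mean_v^ctrl)` and, when both
#' SEMs are available, the first-order (delta-method) propagated SEM
#' `s_v = sqrt((sem_p/mean_p)^2 + (sem_c/mean_c)^2) / ln 2`. Because effects
#' are ratios, absolute units cancel; when unit-override columns are present,
#' a perturbation and its control must agree on the unit of any variable they
#' both report.
#'
#' @param db a validated `synclust_db`.
#' @return a data.frame of class `c("synclust_perturbations", "data.frame")`
#'   with columns `perturbation_id`, `gene_symbol`, `gene_family`,
#'   `gof_label`, `db_row`, `control_db_row`, and `x_v`/`s_v` for each of
#'   `A`, `RRP`, `Pv`, `F` (NA where undefined), plus `n_observed`.
#' @export
normalize_to_controls <- function(db) {
  if (!inherits(db, "synclust_db")) db <- as_synclust_db(db)
  ctrl <- resolve_control_rows(db)
  pert_rows <- which(!is.na(ctrl))
  out <- data.frame(
    perturbation_id = sprintf("%s_r%03d", db$gene_symbol[pert_rows], pert_rows),
    gene_symbol = db$gene_symbol[pert_rows],
    gene_family = if ("gene_family" %in% names(db)) db$gene_family[pert_rows] else NA_character_,
    gof_label = if ("gof_label" %in% names(db)) db$gof_label[pert_rows] else NA_character_,
    db_row = pert_rows,
    control_db_row = ctrl[pert_rows],
    stringsAsFactors = FALSE
  )
  for (v in ALL_VARS) {
    mp <- db[[paste0("mean_", v)]][pert_rows]
    mc <- db[[paste0("mean_", v)]][ctrl[pert_rows]]
    sp <- db[[paste0("sem_", v)]][pert_rows]
    sc <- db[[paste0("sem_", v)]][ctrl[pert_rows]]
    ucol <- paste0("unit_", v)
    if (ucol %in% names(db)) {
      up <- db[[ucol]][pert_rows]
      uc <- db[[ucol]][ctrl[pert_rows]]
      clash <- which(!is.na(mp) & !is.na(mc) & !is.na(up) & !is.na(uc) & up != uc)
      if (length(clash) > 0L) {
        stop_synclust(sprintf("unit mismatch between perturbation and control for %s in database row(s) %s",
                              v, paste(pert_rows[clash], collapse = ", ")),
                      "synclust_validation_error")
      }
    }
    out[[paste0("x_", v)]] <- log2(mp / mc)
    out[[paste0("s_", v)]] <- sqrt((sp / mp)^2 + (sc / mc)^2) / log(2)
  }
  out$n_observed <- rowSums(!is.na(as.matrix(out[paste0("x_", ALL_VARS)])))
  class(out) <- c("synclust_perturbations", "data.frame")
  out
}

#' Keep perturbations reporting at least a minimum number of variables
#'
#' The default inclusion rule keeps perturbations with two or more of the four
#' variables defined. Idempotent; input order preserved.
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param min_observed minimum number of defined log2 effects.
#' @return the filtered `synclust_perturbations`.
#' @export
filter_min_variables <- function(pv, min_observed = 2) {
  keep <- rowSums(!is.na(as.matrix(pv[paste0("x_", ALL_VARS)]))) >= min_observed
  out <- pv[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pv)
  out
}

#' Flag perturbations with very large effects
#'
#' Returns the ids of perturbations whose largest absolute log2 effect exceeds
#' `log2(threshold_fold)`. This mirrors a plotting exclusion only: flagged
#' perturbations remain in all analyses.
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param threshold_fold fold-change threshold (default 10).
#' @return character vector of `perturbation_id`s.
#' @export
flag_large_effects <- function(pv, threshold_fold = 10) {
  x <- abs(as.matrix(pv[paste0("x_", ALL_VARS)]))
  mx <- suppressWarnings(apply(x, 1L, max, na.rm = TRUE))
  pv$perturbation_id[is.finite(mx) & mx > log2(threshold_fold)]
}

#' Extract the evoked-release effect matrix
#'
#' The 3-D space used for orientation clustering, in variable order
#' (RRP, Pv, A). Rows are perturbations; missing entries are `NA`.
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param sem return the propagated SEMs instead of the effects.
#' @return a numeric matrix with rownames = perturbation ids.
#' @export
evoked_matrix <- function(pv, sem = FALSE) {
  pre <- if (sem) "s_" else "x_"
  m <- as.matrix(pv[paste0(pre, EVOKED_VARS)])
  colnames(m) <- EVOKED_VARS
  rownames(m) <- pv$perturbation_id
  m
}

#' Write normalized perturbations to TSV
#'
#' @param pv a `synclust_perturbations` data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_perturbations <- function(pv, path, seed = NULL) {
  write_tsv_prov(as.data.frame(pv), path, seed = seed)
  invisible(path)
}
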