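#' Assemble a cohort dataset
#'
#' Bundles a subject table and a long-format protein abundance table into a
#' single validated container used by every analysis stage. Subjects are
#' children assigned to one channel of one multiplexed (iTRAQ) experiment;
#' observations are per-(protein, child) abundance values tagged with the
#' child's experiment.
#'
#' @param subjects data.frame with columns `child_id`, `experiment_id`,
#'   `channel`, `pivka2_ugL`, optionally `below_detection` (logical) and any
#'   number of covariate columns. `(experiment_id, channel)` must be unique.
#' @param observations data.frame with columns `gene_symbol`, `gi_accession`,
#'   `child_id`, `experiment_id`, `value`. The protein key is `gi_accession`
#'   (gene symbols are not unique across isoforms). At most one observation
#'   per (protein, child).
#' @param normalized logical; `TRUE` once values are per-channel
#'   median-normalized log2 relative abundances, `FALSE` while they are raw
#'   reporter-ion intensities.
#' @param detection_limit assay detection limit in ug/L used to flag
#'   below-detection PIVKA-II values when `below_detection` is absent.
#'
#' @return An object of class `cohort_dataset`: a list with elements
#'   `subjects`, `observations`, `normalized`.
#' @export
cohort_dataset <- function(subjects, observations, normalized = FALSE,
                           detection_limit = 0.001) {
  subjects <- as.data.frame(subjects)
  observations <- as.data.frame(observations)
  req_s <- c("child_id", "experiment_id", "channel", "pivka2_ugL")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss))
    stop("subject table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  req_o <- c("gene_symbol", "gi_accession", "child_id", "experiment_id", "value")
  miss <- setdiff(req_o, names(observations))
  if (length(miss))
    stop("abundance table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  subjects$child_id <- as.character(subjects$child_id)
  subjects$experiment_id <- as.character(subjects$experiment_id)
  subjects$channel <- as.integer(subjects$channel)
  if (!("below_detection" %in% names(subjects)))
    subjects$below_detection <- !is.na(subjects$pivka2_ugL) &
      subjects$pivka2_ugL < detection_limit
  observations$child_id <- as.character(observations$child_id)
  observations$experiment_id <- as.character(observations$experiment_id)
  observations$gi_accession <- as.character(observations$gi_accession)
  observations$gene_symbol <- as.character(observations$gene_symbol)
  x <- structure(list(subjects = subjects, observations = observations,
                      normalized = isTRUE(normalized)),
                 class = "cohort_dataset")
  validate_cohort(x)
  x
}

#' Validate cohort invariants
#'
#' Checks referential integrity and uniqueness constraints: non-negative
#' PIVKA-II, channels in 1..8, unique (experiment, channel) slots, at most
#' one observation per (protein, child), and that every observation's child
#' and experiment resolve against the subject table.
#'
#' @param x a `cohort_dataset`.
#' @return `x`, invisibly. Errors describe the violated constraint.
#' @export
validate_cohort <- function(x) {
  s <- x$subjects; o <- x$observations
  if (anyDuplicated(s$child_id))
    stop("integrity error: duplicated child_id in subject table", call. = FALSE)
  if (any(!is.na(s$pivka2_ugL) & s$pivka2_ugL < 0))
    stop("pivka2_ugL must be non-negative", call. = FALSE)
  if (any(is.na(s$channel)) || any(s$channel < 1L) || any(s$channel > 8L))
    stop("channel must be an integer in 1..8", call. = FALSE)
  slot <- paste(s$experiment_id, s$channel, sep = "\r")
  if (anyDuplicated(slot)) {
    d <- slot[duplicated(slot)][1]
    stop("integrity error: duplicate (experiment, channel) slot: ",
         gsub("\r", ", channel ", d), call. = FALSE)
  }
  if (nrow(o)) {
    key <- paste(o$gi_accession, o$child_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
      stop("integrity error: duplicate observation for protein ", d[1],
           ", child ", d[2], call. = FALSE)
    }
    unknown <- !(o$child_id %in% s$child_id)
    if (any(unknown))
      stop("integrity error: observation references unknown child_id ",
           o$child_id[unknown][1], call. = FALSE)
    exp_of <- setNames(s$experiment_id, s$child_id)
    bad <- o$experiment_id != exp_of[o$child_id]
    if (any(bad))
      stop("integrity error: observation experiment_id does not match the ",
           "child's experiment for child ", o$child_id[bad][1], call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat("  subjects:    ", nrow(x$subjects), " children in ",
      length(unique(x$subjects$experiment_id)), " experiments\n", sep = "")
  cat("  observations:", nrow(x$observations), "values for",
      length(unique(x$observations$gi_accession)), "proteins\n")
  cat("  normalized:  ", x$normalized, "\n", sep = "")
  invisible(x)
}

.map_cols <- function(df, col_map, required, what) {
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df))
        stop("schema error in ", what, ": mapped column '", src,
             "' (for '", std, "') not found", call. = FALSE)
      names(df)[names(df) == src] <- std
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", what, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a subject table
#'
#' Reads the tab-delimited subject table (one row per child). Required
#' columns: `child_id`, `experiment_id`, `channel`, `pivka2_ugL`. Any other
#' column is preserved as a covariate. PIVKA-II values below the assay
#' detection limit are flagged, never dropped; downstream stages decide
#' inclusion. A column-mapping list allows reading exports whose headers use
#' other names (e.g. a flattened supplementary-dataset export).
#'
#' @param path path to a TSV file with a header row.
#' @param col_map optional named list mapping standard names to the file's
#'   column names, e.g. `list(child_id = "SubjectID")`.
#' @param detection_limit detection limit in ug/L (default 0.001).
#' @return data.frame of subjects with a logical `below_detection` column.
#' @export
read_subject_table <- function(path, col_map = NULL, detection_limit = 0.001) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  df <- .map_cols(df, col_map, c("child_id", "experiment_id", "channel",
                                 "pivka2_ugL"), "subject table")
  df$child_id <- as.character(df$child_id)
  df$experiment_id <- as.character(df$experiment_id)
  df$channel <- as.integer(df$channel)
  df$pivka2_ugL <- as.numeric(df$pivka2_ugL)
  slot <- paste(df$experiment_id, df$channel)
  if (anyDuplicated(slot))
    stop("integrity error: duplicate (experiment, channel) slot: ",
         slot[duplicated(slot)][1], call. = FALSE)
  if (!("below_detection" %in% names(df)))
    df$below_detection <- !is.na(df$pivka2_ugL) & df$pivka2_ugL < detection_limit
  else df$below_detection <- as.logical(df$below_detection)
  df
}

#' Read a long-format protein abundance table
#'
#' Reads the tab-delimited abundance table (one row per protein-by-child
#' measurement). Required columns: `protein_id` (gene symbol),
#' `gi_accession`, `child_id`, `experiment_id`, `value`.
#'
#' @inheritParams read_subject_table
#' @return data.frame of observations with columns `gene_symbol`,
#'   `gi_accession`, `child_id`, `experiment_id`, `value`.
#' @export
read_abundance_table <- function(path, col_map = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  df <- .map_cols(df, col_map, c("protein_id", "gi_accession", "child_id",
                                 "experiment_id", "value"), "abundance table")
  if (nrow(df) == 0L) {
    warning("abundance table ", path, " contains a header only; no observations")
    return(data.frame(gene_symbol = character(), gi_accession = character(),
                      child_id = character(), experiment_id = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !is.na(df$value) & df$value != "NA")
  if (length(bad))
    stop("parse error in abundance table: non-numeric value '",
         df$value[bad[1]], "' at row ", bad[1], call. = FALSE)
  out <- data.frame(gene_symbol = df$protein_id,
                    gi_accession = df$gi_accession,
                    child_id = df$child_id,
                    experiment_id = df$experiment_id,
                    value = val, stringsAsFactors = FALSE)
  key <- paste(out$gi_accession, out$child_id)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (protein, child) observation: ",
         key[duplicated(key)][1], call. = FALSE)
  out
}

#' Write subject or abundance tables
#'
#' Tab-delimited, UTF-8, header row; full numeric precision so a
#' write-then-read round trip reproduces values to well below 1e-9.
#'
#' @param subjects,observations data.frames as held by a [cohort_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
write_abundance_table <- function(observations, path) {
  out <- data.frame(protein_id = observations$gene_symbol,
                    gi_accession = observations$gi_accession,
                    child_id = observations$child_id,
                    experiment_id = observations$experiment_id,
                    value = sprintf("%.12g", observations$value),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fmt_pct_ci <- function(pct, lo, hi) {
  sprintf("%.1f (%.1f, %.1f)", pct, lo, hi)
}

#' Write a results table
#'
#' Renders association or group-difference results as a tab-delimited table
#' mirroring the published layouts: percent effect to one decimal with its
#' 95% CI as `"lo, hi"`, rows sorted by ascending p-value. `kind =
#' "correlation"` writes a numeric correlation matrix with protein ids.
#'
#' @param results for `"association"`/`"group_diff"`, a data.frame as
#'   returned by [associate_all()] / [group_diff_all()]; for
#'   `"correlation"`, an object from [averaged_correlation()] or a matrix.
#' @param path output file path.
#' @param kind one of `"association"`, `"group_diff"`, `"correlation"`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path,
                                kind = c("association", "group_diff",
                                         "correlation")) {
  kind <- match.arg(kind)
  if (kind == "correlation") {
    m <- if (inherits(results, "avg_cor")) results$r_matrix else as.matrix(results)
    out <- data.frame(gi_accession = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  pcol <- if (kind == "association") "percent_change" else "percent_difference"
  cols <- c("gene_symbol", "gi_accession", "n_obs", pcol, "ci_lo", "ci_hi",
            "p_value", "q_value", if (kind == "association") "r2")
  if (nrow(as.data.frame(results)) == 0L) {
    hdr <- c("gene_symbol", "gi_accession", "n",
             if (kind == "association") "percent_change" else "percent_difference",
             "p", "q", if (kind == "association") "r2")
    writeLines(paste(hdr, collapse = "\t"), path)
    return(invisible(path))
  }
  res <- as.data.frame(results)[, cols]
  res <- res[order(res$p_value), , drop = FALSE]
  out <- data.frame(
    gene_symbol = res$gene_symbol,
    gi_accession = res$gi_accession,
    n = res$n_obs,
    pct = .fmt_pct_ci(res[[pcol]], res$ci_lo, res$ci_hi),
    p = signif(res$p_value, 3),
    q = signif(res$q_value, 3),
    stringsAsFactors = FALSE)
  names(out)[4] <- if (kind == "association") "percent_change" else "percent_difference"
  if (kind == "association") out$r2 <- sprintf("%.2f", res$r2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
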