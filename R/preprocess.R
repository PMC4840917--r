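#' Log2-transform and median-normalize reporter intensities
#'
#' Converts raw reporter-ion intensities to log2 scale and centers them so
#' that, within each iTRAQ experiment, every channel (i.e. every child's
#' sample) has median zero. This makes channels comparable across the
#' labelling and loading differences of a multiplexed experiment. A
#' per-protein-within-experiment centering mode is available for sensitivity
#' analysis.
#'
#' @param dataset a non-normalized [cohort_dataset()] holding positive raw
#'   intensities.
#' @param center `"channel"` (default): subtract the per-child median of log2
#'   intensities within the child's experiment; `"protein"`: subtract the
#'   per-protein median within each experiment.
#' @return list with elements `dataset` (normalized `cohort_dataset`) and
#'   `report` (data.frame with one row per centering unit: ids, `n_obs`,
#'   `median_log2` subtracted).
#' @export
log2_median_normalize <- function(dataset, center = c("channel", "protein")) {
  center <- match.arg(center)
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (isTRUE(dataset$normalized))
    stop("dataset is already normalized", call. = FALSE)
  o <- dataset$observations
  bad <- which(!is.finite(o$value) | o$value <= 0)
  if (length(bad))
    stop("non-positive intensity for protein ", o$gi_accession[bad[1]],
         ", child ", o$child_id[bad[1]], call. = FALSE)
  v <- log2(o$value)
  key <- if (center == "channel") o$child_id
         else paste(o$experiment_id, o$gi_accession, sep = "\r")
  med <- ave(v, key, FUN = median)
  o$value <- v - med
  dataset$observations <- o
  dataset$normalized <- TRUE
  u <- !duplicated(key)
  report <- data.frame(experiment_id = o$experiment_id[u],
                       child_id = if (center == "channel") o$child_id[u] else NA,
                       gi_accession = if (center == "protein") o$gi_accession[u] else NA,
                       n_obs = as.vector(table(key)[key[u]]),
                       median_log2 = med[u],
                       stringsAsFactors = FALSE)
  if (center == "channel") {
    ch <- setNames(dataset$subjects$channel, dataset$subjects$child_id)
    report$channel <- as.integer(ch[report$child_id])
  }
  list(dataset = dataset, report = report)
}

#' Filter proteins by cohort coverage
#'
#' Retains proteins quantified in strictly more than `min_children` distinct
#' children (the ">10% of children" rule of the study design, i.e. n > 50 of
#' 500). Counts distinct children, not observations.
#'
#' @param dataset a [cohort_dataset()].
#' @param min_children strict lower bound on the number of distinct children
#'   (default 50).
#' @return the dataset with observations restricted to retained proteins.
#' @export
filter_proteins_by_coverage <- function(dataset, min_children = 50) {
  stopifnot(inherits(dataset, "cohort_dataset"), min_children >= 0)
  o <- dataset$observations
  n_child <- tapply(o$child_id, o$gi_accession,
                    function(x) length(unique(x)))
  keep <- names(n_child)[n_child > min_children]
  dataset$observations <- o[o$gi_accession %in% keep, , drop = FALSE]
  rownames(dataset$observations) <- NULL
  dataset
}

#' Dichotomize vitamin K status
#'
#' Classifies children as vitamin K deficient (PIVKA-II strictly above the
#' cutoff, default 2 ug/L) or sufficient (at or below). Below-detection
#' values are low and therefore classed sufficient; children missing
#' PIVKA-II get `NA` and are excluded downstream.
#'
#' @param subjects a subject data.frame with `pivka2_ugL`.
#' @param cutoff_ugL deficiency cutoff in ug/L (default 2.0, strict `>`).
#' @return `subjects` with a `vk_status` factor
#'   (`"deficient"`/`"sufficient"`).
#' @export
dichotomize_vk <- function(subjects, cutoff_ugL = 2.0) {
  status <- ifelse(is.na(subjects$pivka2_ugL), NA_character_,
                   ifelse(subjects$pivka2_ugL > cutoff_ugL,
                          "deficient", "sufficient"))
  subjects$vk_status <- factor(status, levels = c("deficient", "sufficient"))
  subjects
}

#' Continuous-outcome analysis subset
#'
#' Drops children whose PIVKA-II is below the assay detection limit (their
#' values cannot enter a log2 outcome) and attaches `log2_pivka`. In the
#' emulated study this reduces 500 children to 474.
#'
#' @param subjects a subject data.frame with `pivka2_ugL` and
#'   `below_detection`.
#' @param detection_limit detection limit in ug/L (default 0.001).
#' @return the retained subjects with a `log2_pivka` column.
#' @export
continuous_outcome_subset <- function(subjects, detection_limit = 0.001) {
  bd <- if ("below_detection" %in% names(subjects)) subjects$below_detection
        else rep(FALSE, nrow(subjects))
  drop <- is.na(subjects$pivka2_ugL) | bd | subjects$pivka2_ugL < detection_limit
  out <- subjects[!drop, , drop = FALSE]
  out$log2_pivka <- log2(out$pivka2_ugL)
  rownames(out) <- NULL
  out
}
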