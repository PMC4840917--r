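#' Within-experiment-averaged protein correlation matrix
#'
#' For each pair of selected proteins, Pearson correlation is computed
#' within each iTRAQ experiment over the children observed for both
#' proteins, and the per-experiment coefficients are averaged (unweighted)
#' across experiments. Computing correlations within experiments keeps batch
#' effects from inflating co-abundance. Experiments contributing fewer than
#' `min_pairs_per_experiment` complete pairs are skipped for that pair
#' (Pearson is undefined below 2 points and degenerates to +/-1 at 2);
#' pairs with no contributing experiment are `NA`.
#'
#' @param dataset a normalized [cohort_dataset()].
#' @param protein_ids character vector (>= 2) of `gi_accession` keys.
#' @param min_pairs_per_experiment minimum complete pairs per experiment
#'   (default 3).
#' @param average `"mean"` (default, the plain arithmetic average),
#'   `"weighted"` (weights by per-experiment pair count), or `"fisher"`
#'   (Fisher z-transform before averaging) for sensitivity analysis.
#' @return object of class `avg_cor`: list with `r_matrix` (symmetric,
#'   diagonal 1), `support_matrix` (experiments contributing per pair), and
#'   `protein_ids`.
#' @export
averaged_correlation <- function(dataset, protein_ids,
                                 min_pairs_per_experiment = 3,
                                 average = c("mean", "weighted", "fisher")) {
  average <- match.arg(average)
  stopifnot(inherits(dataset, "cohort_dataset"))
  protein_ids <- as.character(protein_ids)
  if (length(protein_ids) < 2L)
    stop("at least 2 proteins are required for a correlation matrix",
         call. = FALSE)
  if (min_pairs_per_experiment < 3)
    stop("min_pairs_per_experiment must be >= 3", call. = FALSE)
  obs <- dataset$observations
  obs <- obs[obs$gi_accession %in% protein_ids, , drop = FALSE]
  k <- length(protein_ids)
  acc <- matrix(0, k, k, dimnames = list(protein_ids, protein_ids))
  wsum <- matrix(0, k, k, dimnames = dimnames(acc))
  support <- matrix(0L, k, k, dimnames = dimnames(acc))
  for (ex in unique(obs$experiment_id)) {
    oe <- obs[obs$experiment_id == ex, , drop = FALSE]
    kids <- unique(oe$child_id)
    m <- matrix(NA_real_, length(kids), k,
                dimnames = list(kids, protein_ids))
    m[cbind(match(oe$child_id, kids), match(oe$gi_accession, protein_ids))] <-
      oe$value
    npair <- crossprod(!is.na(m))
    r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
    valid <- npair >= min_pairs_per_experiment & is.finite(r)
    diag(valid) <- FALSE
    if (!any(valid)) next
    contrib <- ifelse(valid,
                      switch(average,
                             mean = r,
                             weighted = r * npair,
                             fisher = atanh(pmin(pmax(r, -1 + 1e-12),
                                                 1 - 1e-12))),
                      0)
    w <- ifelse(valid, switch(average, weighted = npair, 1), 0)
    acc <- acc + contrib
    wsum <- wsum + w
    support <- support + valid
  }
  rmat <- acc / wsum
  rmat[wsum == 0] <- NA_real_
  if (average == "fisher") rmat <- tanh(rmat)
  diag(rmat) <- 1
  structure(list(r_matrix = rmat, support_matrix = support,
                 protein_ids = protein_ids, average = average),
            class = "avg_cor")
}

#' @export
print.avg_cor <- function(x, ...) {
  cat("<avg_cor> ", length(x$protein_ids), " proteins, ",
      "averaged within-experiment Pearson (", x$average, ")\n", sep = "")
  off <- x$r_matrix[upper.tri(x$r_matrix)]
  cat("  off-diagonal range: [", signif(min(off, na.rm = TRUE), 3), ", ",
      signif(max(off, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

#' Threshold small correlations for display
#'
#' Sets entries with `|r|` strictly below `eps` (default 0.01) to exactly
#' zero, leaving the diagonal untouched, matching the rendering convention
#' of the study's correlation heatmap.
#'
#' @param x an `avg_cor` object or a numeric matrix.
#' @param eps display threshold (strict `<`).
#' @return same type as `x`, thresholded.
#' @export
display_threshold <- function(x, eps = 0.01) {
  m <- if (inherits(x, "avg_cor")) x$r_matrix else x
  d <- diag(m)
  m[abs(m) < eps] <- 0
  diag(m) <- d
  if (inherits(x, "avg_cor")) { x$r_matrix <- m; x } else m
}

#' Select proteins for the correlation network
#'
#' The network covers proteins associated with the nutrient outcome or
#' differentially abundant by deficiency status under the relaxed FDR
#' threshold (q < `q_relaxed`, strict): the union of discoveries from the
#' two families, de-duplicated, ordered by each protein's minimum q across
#' families.
#'
#' @param association_results a `vk_assoc` data.frame.
#' @param group_results a `vk_groupdiff` data.frame.
#' @param q_relaxed relaxed FDR threshold (default 0.20).
#' @return character vector of `gi_accession` keys in ascending min-q order.
#' @export
select_network_proteins <- function(association_results, group_results,
                                    q_relaxed = 0.20) {
  fams <- rbind(
    data.frame(gi = association_results$gi_accession,
               q = association_results$q_value, stringsAsFactors = FALSE),
    data.frame(gi = group_results$gi_accession,
               q = group_results$q_value, stringsAsFactors = FALSE))
  minq <- tapply(fams$q, fams$gi, min)
  sel <- minq[minq < q_relaxed]
  if (!length(sel))
    stop("no protein passes q < ", q_relaxed,
         "; consider relaxing the threshold", call. = FALSE)
  names(sort(sel))
}

#' Heatmap of an averaged correlation matrix
#'
#' Base-graphics rendering: blue for positive, red for negative
#' correlations, darker for stronger; entries below the display threshold
#' shown as white.
#'
#' @param x an `avg_cor` object.
#' @param eps display threshold applied before rendering.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.avg_cor <- function(x, eps = 0.01, ...) {
  m <- display_threshold(x, eps)$r_matrix
  k <- ncol(m)
  pal <- colorRampPalette(c("#b2182b", "#f7f7f7", "#2166ac"))(101)
  image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
        zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  axis(1, at = seq_len(k), labels = colnames(m), las = 2, cex.axis = 0.6)
  axis(2, at = seq_len(k), labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  invisible(x)
}
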