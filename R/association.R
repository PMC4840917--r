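#' Analysis configuration
#'
#' Tunable thresholds of the association analysis, with the study defaults:
#' primary FDR threshold q < 0.10, relaxed network threshold q < 0.20,
#' deficiency cutoff PIVKA-II > 2 ug/L, coverage filter n > 50 children,
#' 95% confidence intervals.
#'
#' @param q_primary primary FDR threshold (strict `<`).
#' @param q_relaxed relaxed FDR threshold used for network selection.
#' @param vkd_cutoff_ugL vitamin K deficiency cutoff in ug/L (strict `>`).
#' @param min_children coverage filter bound (strict `>`).
#' @param ci_level confidence level for percent-effect intervals.
#' @param detection_limit PIVKA-II assay detection limit in ug/L.
#' @param chisq_correct continuity-correct 2x2 chi-square tests in the
#'   cohort descriptive table.
#' @param pi0_method `pi0` estimator passed to [storey_qvalues()].
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(q_primary = 0.10, q_relaxed = 0.20,
                            vkd_cutoff_ugL = 2.0, min_children = 50,
                            ci_level = 0.95, detection_limit = 0.001,
                            chisq_correct = TRUE, pi0_method = "smoother") {
  stopifnot(q_primary > 0, q_primary <= q_relaxed, q_relaxed < 1,
            vkd_cutoff_ugL > 0, min_children >= 0,
            ci_level > 0, ci_level < 1)
  structure(list(q_primary = q_primary, q_relaxed = q_relaxed,
                 vkd_cutoff_ugL = vkd_cutoff_ugL,
                 min_children = min_children, ci_level = ci_level,
                 detection_limit = detection_limit,
                 chisq_correct = chisq_correct, pi0_method = pi0_method),
            class = "analysis_config")
}

#' Percent change per doubling
#'
#' Converts a slope on the log2-log2 scale into the percent change in the
#' outcome associated with a doubling (100% increase) of the predictor:
#' \eqn{(2^\beta - 1) \times 100}. When a standard error is supplied, the
#' normal-quantile confidence bounds of \eqn{\beta} are transformed the same
#' (monotone) way.
#'
#' @param beta slope(s) on the log2 scale.
#' @param se optional standard error(s) of `beta`.
#' @param ci_level confidence level (default 0.95).
#' @return numeric vector of percents, or (with `se`) a data.frame with
#'   `percent_change`, `ci_lo`, `ci_hi`.
#' @examples
#' percent_change(1)    # +100: doubling maps to doubling
#' percent_change(-1)   # -50
#' @export
percent_change <- function(beta, se = NULL, ci_level = 0.95) {
  pc <- (2^beta - 1) * 100
  if (is.null(se)) return(pc)
  z <- qnorm(1 - (1 - ci_level) / 2)
  data.frame(percent_change = pc,
             ci_lo = (2^(beta - z * se) - 1) * 100,
             ci_hi = (2^(beta + z * se) - 1) * 100)
}

# Shared per-protein mixed-model loop. `direction` fixes which variable is
# the LME outcome so the two analyses can never be accidentally swapped.
.per_protein_lme <- function(obs, outcome_by_child, direction, min_n = 3L) {
  idx <- split(seq_len(nrow(obs)), obs$gi_accession)
  res <- vector("list", length(idx))
  skipped <- character(0)
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    child <- obs$child_id[rows]
    keep <- child %in% names(outcome_by_child)
    rows <- rows[keep]; child <- child[keep]
    if (length(rows) < min_n) { skipped <- c(skipped, names(idx)[k]); next }
    prot <- obs$value[rows]
    outc <- unname(outcome_by_child[child])
    grp <- obs$experiment_id[rows]
    if (direction == "nutrient_on_protein") {
      y <- outc; x <- prot
    } else {
      y <- prot; x <- outc
    }
    if (var(x) == 0 || var(y) == 0) {
      skipped <- c(skipped, names(idx)[k]); next
    }
    fit <- tryCatch(.fit_ri(y, cbind(`(Intercept)` = 1, x = x), grp),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$se["x"]) ||
        fit$se["x"] <= 0) {
      skipped <- c(skipped, names(idx)[k]); next
    }
    res[[k]] <- list(gi = names(idx)[k],
                     gene = obs$gene_symbol[rows[1L]],
                     n = length(rows),
                     beta = unname(fit$coefficients["x"]),
                     se = unname(fit$se["x"]),
                     p = wald_test(fit, "x"),
                     r2 = fitted_r2(fit))
  }
  list(results = res[!vapply(res, is.null, logical(1))], skipped = skipped)
}

#' Per-protein association with the continuous nutrient outcome
#'
#' For every protein passing the coverage filter, fits the random-intercept
#' mixed model with log2 PIVKA-II as the dependent variable and the protein's
#' normalized log2 relative abundance as the independent variable (random
#' intercept per iTRAQ experiment, REML). Children below the assay detection
#' limit are excluded (continuous-outcome subset). The slope is reported as
#' the percent change in PIVKA-II per doubling of protein abundance, with
#' Wald p-values, Storey q-values computed within this family, and the
#' proportion of outcome variance explained by the fitted values (BLUPs
#' included).
#'
#' @param dataset a normalized [cohort_dataset()].
#' @param config an [analysis_config()].
#' @return data.frame of class `vk_assoc`, ordered by ascending p, with
#'   columns `gene_symbol`, `gi_accession`, `n_obs`, `beta`, `se_beta`,
#'   `percent_change`, `ci_lo`, `ci_hi`, `p_value`, `q_value`, `r2`.
#'   Attributes: `pi0_hat`, `skipped` (proteins with degenerate fits).
#' @export
associate_all <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!isTRUE(dataset$normalized))
    stop("dataset must be normalized first (log2_median_normalize)",
         call. = FALSE)
  subj <- continuous_outcome_subset(dataset$subjects,
                                    detection_limit = config$detection_limit)
  ds <- filter_proteins_by_coverage(dataset, config$min_children)
  y_by_child <- setNames(subj$log2_pivka, subj$child_id)
  ans <- .per_protein_lme(ds$observations, y_by_child, "nutrient_on_protein")
  res <- ans$results
  # honor the coverage bound on the children actually contributing
  res <- Filter(function(r) r$n > config$min_children, res)
  if (length(ans$skipped))
    warning(length(ans$skipped), " protein(s) skipped (degenerate or ",
            "non-convergent fits)")
  if (!length(res)) {
    out <- data.frame(gene_symbol = character(), gi_accession = character(),
                      n_obs = integer(), beta = numeric(), se_beta = numeric(),
                      percent_change = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), p_value = numeric(),
                      q_value = numeric(), r2 = numeric())
    return(structure(out, class = c("vk_assoc", "data.frame"),
                     skipped = ans$skipped))
  }
  beta <- vapply(res, `[[`, numeric(1), "beta")
  se <- vapply(res, `[[`, numeric(1), "se")
  pc <- percent_change(beta, se, config$ci_level)
  p <- vapply(res, `[[`, numeric(1), "p")
  qv <- storey_qvalues(p, pi0_method = config$pi0_method)
  out <- data.frame(
    gene_symbol = vapply(res, `[[`, character(1), "gene"),
    gi_accession = vapply(res, `[[`, character(1), "gi"),
    n_obs = vapply(res, function(r) as.integer(r$n), integer(1)),
    beta = beta, se_beta = se,
    percent_change = pc$percent_change, ci_lo = pc$ci_lo, ci_hi = pc$ci_hi,
    p_value = p, q_value = qv$q_values,
    r2 = vapply(res, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("vk_assoc", "data.frame"),
            pi0_hat = qv$pi0_hat, skipped = ans$skipped)
}

#' Per-protein differential abundance by deficiency status
#'
#' For every protein passing the coverage filter, fits the random-intercept
#' mixed model with the protein's normalized log2 abundance as the dependent
#' variable and a deficiency indicator (deficient = 1, sufficient = 0) as
#' the fixed effect, random intercept per experiment. All children with a
#' vitamin K status are eligible, including below-detection children (they
#' are classed sufficient). The group contrast is reported as the percent
#' difference in protein abundance in deficient relative to sufficient
#' children; q-values are computed within this family, separately from the
#' association family.
#'
#' @inheritParams associate_all
#' @return data.frame of class `vk_groupdiff`, ordered by ascending p, with
#'   columns `gene_symbol`, `gi_accession`, `n_obs`, `beta_group`,
#'   `se_beta`, `percent_difference`, `ci_lo`, `ci_hi`, `p_value`,
#'   `q_value`.
#' @export
group_diff_all <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!isTRUE(dataset$normalized))
    stop("dataset must be normalized first (log2_median_normalize)",
         call. = FALSE)
  subj <- dataset$subjects
  if (!("vk_status" %in% names(subj)))
    subj <- dichotomize_vk(subj, config$vkd_cutoff_ugL)
  subj <- subj[!is.na(subj$vk_status), , drop = FALSE]
  ds <- filter_proteins_by_coverage(dataset, config$min_children)
  ind <- setNames(as.numeric(subj$vk_status == "deficient"), subj$child_id)
  obs <- ds$observations
  idx <- split(seq_len(nrow(obs)), obs$gi_accession)
  res <- list(); skipped <- character(0)
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    child <- obs$child_id[rows]
    keep <- child %in% names(ind)
    rows <- rows[keep]; child <- child[keep]
    x <- unname(ind[child])
    # require at least 2 observed children in each status group
    if (sum(x == 1) < 2 || sum(x == 0) < 2) {
      skipped <- c(skipped, names(idx)[k]); next
    }
    y <- obs$value[rows]
    if (var(y) == 0) { skipped <- c(skipped, names(idx)[k]); next }
    fit <- tryCatch(.fit_ri(y, cbind(`(Intercept)` = 1, x = x),
                            obs$experiment_id[rows]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$se["x"]) ||
        fit$se["x"] <= 0) {
      skipped <- c(skipped, names(idx)[k]); next
    }
    res[[length(res) + 1L]] <- list(
      gi = names(idx)[k], gene = obs$gene_symbol[rows[1L]],
      n = length(rows), beta = unname(fit$coefficients["x"]),
      se = unname(fit$se["x"]), p = wald_test(fit, "x"))
  }
  if (length(skipped))
    warning(length(skipped), " protein(s) skipped in the group analysis")
  if (!length(res)) {
    out <- data.frame(gene_symbol = character(), gi_accession = character(),
                      n_obs = integer(), beta_group = numeric(),
                      se_beta = numeric(), percent_difference = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      p_value = numeric(), q_value = numeric())
    return(structure(out, class = c("vk_groupdiff", "data.frame"),
                     skipped = skipped))
  }
  beta <- vapply(res, `[[`, numeric(1), "beta")
  se <- vapply(res, `[[`, numeric(1), "se")
  pc <- percent_change(beta, se, config$ci_level)
  p <- vapply(res, `[[`, numeric(1), "p")
  qv <- storey_qvalues(p, pi0_method = config$pi0_method)
  out <- data.frame(
    gene_symbol = vapply(res, `[[`, character(1), "gene"),
    gi_accession = vapply(res, `[[`, character(1), "gi"),
    n_obs = vapply(res, function(r) as.integer(r$n), integer(1)),
    beta_group = beta, se_beta = se,
    percent_difference = pc$percent_change, ci_lo = pc$ci_lo,
    ci_hi = pc$ci_hi, p_value = p, q_value = qv$q_values,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("vk_groupdiff", "data.frame"),
            pi0_hat = qv$pi0_hat, skipped = skipped)
}

#' Descriptive cohort comparison table
#'
#' Compares covariates between deficient and sufficient children: mean (SD)
#' with a t-test for continuous variables declared normal, median (IQR) with
#' a Mann-Whitney test for those declared skewed, and percent with a
#' chi-square test (continuity-corrected for 2x2 tables by default) for
#' categorical variables. The test routing is declared per covariate since
#' distributional shape is a property of the data, not a rule the analysis
#' can infer reliably.
#'
#' @param subjects subject data.frame with `vk_status` (see
#'   [dichotomize_vk()]) and the covariate columns.
#' @param covariates data.frame with columns `name` (column in `subjects`)
#'   and `type` (one of `"normal"`, `"skewed"`, `"categorical"`).
#' @param config an [analysis_config()] (controls chi-square continuity
#'   correction).
#' @return data.frame with columns `variable`, `deficient`, `sufficient`,
#'   `p_value`, `test`. All-missing covariates get `NA` p-values.
#' @export
build_cohort_table <- function(subjects, covariates,
                               config = analysis_config()) {
  if (!("vk_status" %in% names(subjects)))
    stop("subjects must carry vk_status; call dichotomize_vk() first",
         call. = FALSE)
  grp <- subjects$vk_status
  rows <- lapply(seq_len(nrow(covariates)), function(i) {
    nm <- as.character(covariates$name[i])
    ty <- as.character(covariates$type[i])
    if (!nm %in% names(subjects))
      stop("covariate column not found: ", nm, call. = FALSE)
    v <- subjects[[nm]]
    ok <- !is.na(v) & !is.na(grp)
    if (!any(ok))
      return(data.frame(variable = nm, deficient = NA, sufficient = NA,
                        p_value = NA_real_,
                        test = switch(ty, normal = "t-test",
                                      skewed = "Mann-Whitney",
                                      categorical = "chi-square", ty),
                        stringsAsFactors = FALSE))
    vd <- v[ok & grp == "deficient"]; vs <- v[ok & grp == "sufficient"]
    if (ty == "normal") {
      p <- tryCatch(t.test(vd, vs)$p.value, error = function(e) NA_real_)
      fmt <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
      data.frame(variable = nm, deficient = fmt(vd), sufficient = fmt(vs),
                 p_value = p, test = "t-test", stringsAsFactors = FALSE)
    } else if (ty == "skewed") {
      p <- tryCatch(wilcox.test(vd, vs)$p.value, error = function(e) NA_real_)
      fmt <- function(x) sprintf("%.2f (%.2f, %.2f)", median(x),
                                 quantile(x, 0.25), quantile(x, 0.75))
      data.frame(variable = nm, deficient = fmt(vd), sufficient = fmt(vs),
                 p_value = p, test = "Mann-Whitney", stringsAsFactors = FALSE)
    } else if (ty == "categorical") {
      tb <- table(factor(v[ok]), droplevels(grp[ok]))
      p <- tryCatch(suppressWarnings(
        chisq.test(tb, correct = config$chisq_correct)$p.value),
        error = function(e) NA_real_)
      pct <- function(col) paste(sprintf("%.1f", 100 * tb[, col] / sum(tb[, col])),
                                 collapse = "/")
      data.frame(variable = nm, deficient = pct("deficient"),
                 sufficient = pct("sufficient"), p_value = p,
                 test = "chi-square", stringsAsFactors = FALSE)
    } else stop("unknown covariate type: ", ty, call. = FALSE)
  })
  do.call(rbind, rows)
}
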