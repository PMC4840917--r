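#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: load (or simulate) the cohort, normalize,
#' build the descriptive cohort table, run the continuous association and
#' deficiency-group analyses with Storey q-values, select the relaxed-FDR
#' network proteins and build the averaged correlation matrix. Writes
#' `table1.tsv`, `table2.tsv` (association; full results plus a
#' `table2_significant.tsv` view at the primary threshold), `table3.tsv`
#' (group differences), `rmatrix.tsv`, and `manifest.json` (config
#' snapshot, input checksums, seed, package version, per-stage row counts
#' and timings, aggregated warnings) into `out_dir`.
#'
#' @param config either a path to a YAML file or a list, with elements:
#'   `input` (list with `subjects`, `abundance` file paths) or `simulate`
#'   (arguments for [sim_config()]); optional `analysis` (arguments for
#'   [analysis_config()]); optional `covariates` (data.frame or list for
#'   [build_cohort_table()]).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed controlling simulation.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_full_analysis <- function(config, out_dir, seed = 1) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acfg <- do.call(analysis_config, as.list(config$analysis))
  manifest <- list(package = "vkproteome",
                   version = as.character(packageVersion("vkproteome")),
                   seed = seed, config = config, stages = list(),
                   warnings = character(0))
  warn <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(force(expr), warning = function(w) {
      warn <<- c(warn, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      rows = if (is.data.frame(res)) nrow(res)
             else if (inherits(res, "cohort_dataset")) nrow(res$observations)
             else NA)
    res
  }

  truth <- NULL
  if (!is.null(config$input)) {
    subjects <- stage("read_subjects",
                      read_subject_table(config$input$subjects,
                                         col_map = config$input$subject_col_map,
                                         detection_limit = acfg$detection_limit))
    observations <- stage("read_abundance",
                          read_abundance_table(config$input$abundance,
                                               col_map = config$input$abundance_col_map))
    dataset <- cohort_dataset(subjects, observations,
                              normalized = isTRUE(config$input$normalized))
    manifest$inputs <- lapply(
      list(subjects = config$input$subjects,
           abundance = config$input$abundance),
      function(p) list(path = p, md5 = unname(tools::md5sum(p))))
  } else if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, as.list(config$simulate))
    sim <- stage("simulate", generate_cohort(scfg, seed = seed))
    dataset <- sim$dataset
    truth <- sim$truth
  } else {
    stop("config must provide either $input or $simulate", call. = FALSE)
  }

  if (!isTRUE(dataset$normalized)) {
    norm <- stage("normalize", log2_median_normalize(dataset))
    dataset <- norm$dataset
  }
  dataset$subjects <- dichotomize_vk(dataset$subjects, acfg$vkd_cutoff_ugL)

  covspec <- config$covariates
  if (!is.null(covspec)) covspec <- as.data.frame(covspec)
  table1 <- stage("cohort_table", {
    base <- data.frame(
      variable = c("n", "PIVKA-II median (IQR), ug/L"),
      deficient = c(sum(dataset$subjects$vk_status == "deficient",
                        na.rm = TRUE), NA),
      sufficient = c(sum(dataset$subjects$vk_status == "sufficient",
                         na.rm = TRUE), NA),
      p_value = NA_real_, test = "", stringsAsFactors = FALSE)
    fmt_piv <- function(g) {
      v <- dataset$subjects$pivka2_ugL[dataset$subjects$vk_status == g]
      sprintf("%.2f (%.2f, %.2f)", median(v, na.rm = TRUE),
              quantile(v, 0.25, na.rm = TRUE), quantile(v, 0.75, na.rm = TRUE))
    }
    base$deficient[2] <- fmt_piv("deficient")
    base$sufficient[2] <- fmt_piv("sufficient")
    if (!is.null(covspec))
      rbind(base, build_cohort_table(dataset$subjects, covspec, acfg))
    else base
  })
  write.table(table1, file.path(out_dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  assoc <- stage("associate", associate_all(dataset, acfg))
  write_results_table(assoc, file.path(out_dir, "table2.tsv"), "association")
  write_results_table(assoc[assoc$q_value < acfg$q_primary, , drop = FALSE],
                      file.path(out_dir, "table2_significant.tsv"),
                      "association")

  gdiff <- stage("diffabund", group_diff_all(dataset, acfg))
  write_results_table(gdiff, file.path(out_dir, "table3.tsv"), "group_diff")

  rmat <- stage("correlate", {
    sel <- select_network_proteins(assoc, gdiff, acfg$q_relaxed)
    averaged_correlation(dataset, sel)
  })
  write_results_table(rmat, file.path(out_dir, "rmatrix.tsv"), "correlation")

  manifest$warnings <- warn
  manifest$counts <- list(
    subjects = nrow(dataset$subjects),
    observations = nrow(dataset$observations),
    proteins_tested_association = nrow(assoc),
    proteins_tested_group = nrow(gdiff),
    discoveries_q_primary = sum(assoc$q_value < acfg$q_primary),
    group_discoveries_q_primary = sum(gdiff$q_value < acfg$q_primary),
    network_proteins = length(rmat$protein_ids))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(dataset = dataset, truth = truth, table1 = table1,
                 association = assoc, group_diff = gdiff, rmatrix = rmat,
                 manifest = manifest, out_dir = out_dir))
}
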