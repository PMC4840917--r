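#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the design
#' of the emulated study: 500 children allocated across 72 iTRAQ 8-plex
#' experiments, 4705 proteins with missing-by-experiment detection averaging
#' 589 proteins per experiment and ~978 proteins quantified in more than 50
#' children, a right-skewed PIVKA-II distribution (median 1.31 ug/L, ~20%
#' above the 2 ug/L deficiency cutoff, 26/500 below the 0.001 ug/L detection
#' limit) partially driven by a handful of driver proteins, experiment-level
#' batch effects, and one positively correlated protein block emulating the
#' hemoglobin / erythrocyte-enzyme cluster.
#'
#' The marginal latent log2 PIVKA-II is normal with mean `log2(pivka_median)`
#' and total standard deviation `pivka_log2_sd`; the residual outcome
#' variance is solved as the total variance minus the variance contributed
#' by the driver proteins (a calibration error is raised when the drivers
#' already exceed the target variance). `round(frac_below_detection *
#' n_children)` children are assigned to an assay-undetectable zero spike,
#' independently of the continuous latent.
#'
#' @param n_children number of children (default 500).
#' @param n_experiments number of iTRAQ experiments (default 72).
#' @param plex_size channels per experiment (default 8);
#'   `n_children <= n_experiments * plex_size`.
#' @param n_proteins_total total distinct proteins (default 4705).
#' @param mean_proteins_per_experiment target mean number of proteins
#'   detected per experiment (default scales 589 with `n_proteins_total`).
#' @param coverage_target target number of proteins observed in more than
#'   `min_children_covered` children (default scales 978).
#' @param min_children_covered coverage bound used for calibration
#'   (default 50, strict `>`).
#' @param n_driver_proteins number of proteins driving the outcome.
#' @param driver_slopes true slopes (log2 outcome per log2 abundance) of the
#'   drivers; defaults emulate the magnitudes of the study's top hits.
#' @param sigma2_u_protein experiment-level batch variance of log2 abundance.
#' @param sigma2_bio between-child biological variance of log2 abundance.
#' @param sigma2_e_outcome residual outcome variance; `NULL` (default)
#'   solves it from `pivka_log2_sd` and the driver contribution.
#' @param pivka_median,pivka_log2_sd location (ug/L) and scale (log2 units)
#'   of the latent outcome distribution.
#' @param frac_below_detection fraction of children censored below the
#'   0.001 ug/L detection limit (default 26/500).
#' @param block_size,block_rho size and within-block correlation of the
#'   correlated protein block (default 5 proteins at rho = 0.8).
#' @param special_detection per-experiment detection probability of driver
#'   and block proteins (abundant, near-ubiquitously quantified proteins).
#' @param base_log2_intensity,sigma_protein_mean,sigma_channel nuisance
#'   scales of the raw reporter intensities: grand log2 intensity, protein
#'   mean spread, and per-channel loading offset spread.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_children = 500, n_experiments = 72, plex_size = 8,
                       n_proteins_total = 4705,
                       mean_proteins_per_experiment = NULL,
                       coverage_target = NULL, min_children_covered = 50,
                       n_driver_proteins = 5, driver_slopes = NULL,
                       sigma2_u_protein = 0.04, sigma2_bio = 0.09,
                       sigma2_e_outcome = NULL,
                       pivka_median = 1.31, pivka_log2_sd = 0.79,
                       frac_below_detection = 26 / 500,
                       block_size = 5, block_rho = 0.8,
                       special_detection = 0.95,
                       base_log2_intensity = 10, sigma_protein_mean = 0.3,
                       sigma_channel = 0.3) {
  if (is.null(mean_proteins_per_experiment))
    mean_proteins_per_experiment <- 589 * n_proteins_total / 4705
  if (is.null(coverage_target))
    coverage_target <- round(978 * n_proteins_total / 4705)
  if (is.null(driver_slopes)) {
    defaults <- c(1.2, -0.8, 0.9, -0.7, 0.6)
    if (n_driver_proteins > length(defaults))
      stop("supply driver_slopes when n_driver_proteins > 5", call. = FALSE)
    driver_slopes <- defaults[seq_len(n_driver_proteins)]
  }
  if (length(driver_slopes) != n_driver_proteins)
    stop("driver_slopes must have length n_driver_proteins", call. = FALSE)
  stopifnot(plex_size >= 1, n_children >= 1, n_experiments >= 1,
            n_children <= n_experiments * plex_size,
            sigma2_u_protein >= 0, sigma2_bio >= 0,
            frac_below_detection >= 0, frac_below_detection <= 1,
            block_rho >= 0, block_rho < 1,
            n_proteins_total >= n_driver_proteins + block_size,
            special_detection > 0, special_detection <= 1)
  s_tot2 <- pivka_log2_sd^2
  var_s <- sum(driver_slopes^2) * (sigma2_u_protein + sigma2_bio)
  if (is.null(sigma2_e_outcome)) {
    sigma2_e_outcome <- s_tot2 - var_s
    if (sigma2_e_outcome <= 0)
      stop("calibration error: driver slopes contribute variance ",
           signif(var_s, 4), " >= target outcome variance ",
           signif(s_tot2, 4), call. = FALSE)
  }
  structure(list(
    n_children = n_children, n_experiments = n_experiments,
    plex_size = plex_size, n_proteins_total = n_proteins_total,
    mean_proteins_per_experiment = mean_proteins_per_experiment,
    coverage_target = coverage_target,
    min_children_covered = min_children_covered,
    n_driver_proteins = n_driver_proteins, driver_slopes = driver_slopes,
    sigma2_u_protein = sigma2_u_protein, sigma2_bio = sigma2_bio,
    sigma2_e_outcome = sigma2_e_outcome,
    pivka_median = pivka_median, pivka_log2_sd = pivka_log2_sd,
    frac_below_detection = frac_below_detection,
    block_size = block_size, block_rho = block_rho,
    special_detection = special_detection,
    base_log2_intensity = base_log2_intensity,
    sigma_protein_mean = sigma_protein_mean, sigma_channel = sigma_channel),
    class = "sim_config")
}

# Beta(a, b) detection-probability calibration for the "regular" proteins:
# fixes the mean detection probability (per-experiment detected count) and
# solves the shape so that the beta-binomial tail P(detected in >= k*
# experiments) matches the target fraction of well-covered proteins, where
# k* is the smallest number of experiments whose children exceed the
# coverage bound.
.calibrate_detection <- function(exp_sizes, mean_pi, tail_target,
                                 min_children) {
  E <- length(exp_sizes)
  ssort <- sort(exp_sizes)
  cum <- cumsum(ssort)
  k_star <- which(cum > min_children)[1L]
  if (is.na(k_star))
    stop("calibration error: coverage bound exceeds total children",
         call. = FALSE)
  if (mean_pi <= 0 || mean_pi >= 1)
    stop("calibration error: mean detection probability ", signif(mean_pi, 4),
         " outside (0, 1)", call. = FALSE)
  tail_bb <- function(log_a) {
    a <- exp(log_a)
    b <- a * (1 - mean_pi) / mean_pi
    k <- k_star:E
    sum(exp(lchoose(E, k) + lbeta(k + a, E - k + b) - lbeta(a, b)))
  }
  lo <- -8; hi <- 10
  flo <- tail_bb(lo) - tail_target
  fhi <- tail_bb(hi) - tail_target
  if (flo * fhi > 0)
    stop("calibration error: coverage target ", signif(tail_target, 4),
         " unreachable at mean detection ", signif(mean_pi, 4), call. = FALSE)
  root <- uniroot(function(x) tail_bb(x) - tail_target, c(lo, hi),
                  tol = 1e-10)
  a <- exp(root$root)
  list(shape1 = a, shape2 = a * (1 - mean_pi) / mean_pi, k_star = k_star)
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic study from a [sim_config()]: children are
#' shuffled and allocated round-robin to experiments (each holding at most
#' `plex_size` channels, assigned at random); protein log2 abundance is
#' protein mean + experiment batch effect + biological signal (the
#' correlated block shares a latent factor); protein-by-experiment
#' missingness uses protein-specific Beta-distributed detection
#' probabilities calibrated to the per-experiment mean and well-covered
#' counts; latent log2 PIVKA-II is the driver combination plus calibrated
#' residual noise; a fixed fraction of children form an assay-undetectable
#' zero spike below the detection limit. Raw reporter intensities are
#' emitted (`normalized = FALSE`) so the normalization stage is exercised.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the master seed fans out to per-stage
#'   substreams so identical configs and seeds give byte-identical output.
#' @return list with `dataset` (a [cohort_dataset()]) and `truth` (ground
#'   truth: driver/block ids and slopes, latent outcomes, detection
#'   probabilities, variance components, calibrated shapes, seed).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4L)

  n <- config$n_children; E <- config$n_experiments
  npt <- config$n_proteins_total
  nd <- config$n_driver_proteins; nb <- config$block_size
  n_special <- nd + nb

  ## stage 1: allocation ----------------------------------------------------
  set.seed(stage_seed[1L])
  child_id <- sprintf("C%04d", seq_len(n))
  ord <- sample.int(n)
  exp_idx <- ((seq_len(n) - 1L) %% E) + 1L
  exp_of_child <- integer(n)
  exp_of_child[ord] <- exp_idx
  experiment_id <- sprintf("E%02d", exp_of_child)
  channel <- integer(n)
  for (j in seq_len(E)) {
    kids <- which(exp_of_child == j)
    channel[kids] <- sample(config$plex_size, length(kids))
  }
  exp_sizes <- tabulate(exp_of_child, E)
  children_by_exp <- split(seq_len(n), exp_of_child)

  ## protein identities -----------------------------------------------------
  driver_idx <- seq_len(nd)
  block_idx <- nd + seq_len(nb)
  gene_symbol <- c(sprintf("DRV%02d", seq_len(nd)),
                   sprintf("BLK%02d", seq_len(nb)),
                   sprintf("SYN%04d", seq_len(npt - n_special)))
  gi_accession <- c(sprintf("9%06d", seq_len(nd)),
                    sprintf("8%06d", seq_len(nb)),
                    sprintf("1%06d", seq_len(npt - n_special)))

  ## stage 2: latent biology and outcome ------------------------------------
  set.seed(stage_seed[2L])
  su <- sqrt(config$sigma2_u_protein); sb <- sqrt(config$sigma2_bio)
  U <- matrix(rnorm(npt * E, 0, su), npt, E)
  bio_special <- matrix(0, n_special, n)
  if (nd > 0)
    bio_special[seq_len(nd), ] <- matrix(rnorm(nd * n, 0, sb), nd, n)
  if (nb > 0) {
    f <- rnorm(n)
    eps <- matrix(rnorm(nb * n), nb, n)
    bio_special[nd + seq_len(nb), ] <-
      sb * (sqrt(config$block_rho) * rep(f, each = nb) +
            sqrt(1 - config$block_rho) * eps)
  }
  alpha <- log2(config$pivka_median)
  S <- rep(0, n)
  if (nd > 0) {
    x_driver <- U[driver_idx, exp_of_child, drop = FALSE] +
      bio_special[seq_len(nd), , drop = FALSE]
    S <- drop(crossprod(x_driver, config$driver_slopes))
  }
  latent_log2 <- alpha + S + rnorm(n, 0, sqrt(config$sigma2_e_outcome))
  pivka <- 2^latent_log2
  # Undetectable children are a distinct zero spike (assay-undetectable),
  # drawn independently of the continuous latent: a continuous distribution
  # with median ~1.31 ug/L carries essentially no mass below 0.001 ug/L, so
  # the below-detection group cannot be its smooth lower tail.
  n_bd <- round(config$frac_below_detection * n)
  below <- rep(FALSE, n)
  if (n_bd > 0) {
    below[sample.int(n, n_bd)] <- TRUE
    pivka[below] <- 0
  }

  ## stage 3: detection -----------------------------------------------------
  set.seed(stage_seed[3L])
  n_regular <- npt - n_special
  mean_pi_reg <- (config$mean_proteins_per_experiment -
                  n_special * config$special_detection) / n_regular
  det_prob <- numeric(npt)
  det_prob[seq_len(n_special)] <- config$special_detection
  cal <- NULL
  if (n_regular > 0) {
    k_star <- which(cumsum(sort(exp_sizes)) > config$min_children_covered)[1L]
    spec_cov <- n_special *
      (1 - stats::pbinom(k_star - 1L, E, config$special_detection))
    tail_target <- (config$coverage_target - spec_cov) / n_regular
    cal <- .calibrate_detection(exp_sizes, mean_pi_reg, tail_target,
                                config$min_children_covered)
    det_prob[n_special + seq_len(n_regular)] <-
      rbeta(n_regular, cal$shape1, cal$shape2)
  }
  det <- matrix(runif(npt * E) < det_prob, npt, E)

  ## stage 4: observed intensities ------------------------------------------
  set.seed(stage_seed[4L])
  mu_p <- rnorm(npt, 0, config$sigma_protein_mean)
  chan_off <- rnorm(n, 0, config$sigma_channel)
  p_rows <- child_rows <- vector("list", E)
  for (j in seq_len(E)) {
    prot <- which(det[, j])
    kids <- children_by_exp[[j]]
    p_rows[[j]] <- rep(prot, each = length(kids))
    child_rows[[j]] <- rep(kids, times = length(prot))
  }
  pr <- unlist(p_rows, use.names = FALSE)
  cr <- unlist(child_rows, use.names = FALSE)
  er <- exp_of_child[cr]
  b <- rnorm(length(pr), 0, sb)
  is_spec <- pr <= n_special
  if (any(is_spec))
    b[is_spec] <- bio_special[cbind(pr[is_spec], cr[is_spec])]
  log2_int <- config$base_log2_intensity + mu_p[pr] + chan_off[cr] +
    U[cbind(pr, er)] + b
  observations <- data.frame(
    gene_symbol = gene_symbol[pr],
    gi_accession = gi_accession[pr],
    child_id = child_id[cr],
    experiment_id = experiment_id[cr],
    value = 2^log2_int,
    stringsAsFactors = FALSE)

  subjects <- data.frame(child_id = child_id, experiment_id = experiment_id,
                         channel = channel, pivka2_ugL = pivka,
                         below_detection = below, stringsAsFactors = FALSE)
  dataset <- cohort_dataset(subjects, observations, normalized = FALSE)
  truth <- structure(list(
    driver_gi = gi_accession[driver_idx],
    driver_gene = gene_symbol[driver_idx],
    driver_slopes = config$driver_slopes,
    block_gi = gi_accession[block_idx],
    block_rho = config$block_rho,
    latent_log2_pivka = setNames(latent_log2, child_id),
    detection_prob = setNames(det_prob, gi_accession),
    sigma2_u_protein = config$sigma2_u_protein,
    sigma2_bio = config$sigma2_bio,
    sigma2_e_outcome = config$sigma2_e_outcome,
    alpha = alpha,
    beta_shape = if (is.null(cal)) NULL else c(cal$shape1, cal$shape2),
    k_star = if (is.null(cal)) NULL else cal$k_star,
    seed = seed, config = config), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Permute the outcome to generate a null cohort
#'
#' Permutes PIVKA-II values (together with their below-detection flags)
#' across children within each iTRAQ experiment. This severs every
#' protein-outcome association while preserving the outcome's marginal
#' distribution and the experiment-level batch structure, giving an exact
#' null for error-calibration checks.
#'
#' @param dataset a [cohort_dataset()].
#' @param seed integer seed for the permutation.
#' @return the dataset with permuted outcomes.
#' @export
resample_null <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  set.seed(seed)
  s <- dataset$subjects
  for (ex in unique(s$experiment_id)) {
    rows <- which(s$experiment_id == ex)
    perm <- rows[sample.int(length(rows))]
    s$pivka2_ugL[rows] <- s$pivka2_ugL[perm]
    s$below_detection[rows] <- s$below_detection[perm]
    if ("vk_status" %in% names(s)) s$vk_status[rows] <- s$vk_status[perm]
  }
  dataset$subjects <- s
  dataset
}
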