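#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with the statistical structure the OPLS analysis assumes:
#' log-normal spot intensities whose latent structure is one y-predictive
#' direction per outcome plus one shared structured component orthogonal to
#' all outcomes, multiplicative technical noise calibrated to a target
#' coefficient of variation, and group-level fold changes on informative
#' spots. Defaults reproduce the study conditions of the emulated cohort:
#' 23 controls + 15 patients, 325 matched spots, technical CV 0.20 (below the
#' 25% bound typical of 2-DE quantification), and 20 informative spots per
#' outcome.
#'
#' @param n_con,n_cwp group sizes (defaults 23 and 15).
#' @param n_spots number of quantified spots (default 325).
#' @param n_informative_per_outcome informative spots planted per outcome
#'   (default 20; outcomes get disjoint sets).
#' @param latent_effect_size standardized slope (log-IOD per SD of the latent
#'   outcome factor) of informative spots (default 0.7, giving spot-outcome
#'   correlations around 0.9, in line with the very tight model fits such
#'   data shows).
#' @param orth_variance_fraction fraction of the non-informative log-scale
#'   variance carried by the shared y-orthogonal component (default 0.3).
#' @param technical_cv target coefficient of variation of replicate
#'   quantification (default 0.20). The log-scale noise SD is chosen via
#'   `CV^2 = exp(sigma^2) - 1` so the CV is an exact property of the noise
#'   model, not an approximation.
#' @param biological_sd per-spot between-subject log-scale SD unrelated to
#'   any outcome (default 0.2).
#' @param group_fold_changes named numeric vector mapping spot numbers to
#'   multiplicative CWP/CON offsets; `NULL` (default) draws a log-normal
#'   (sdlog 0.35) fold change for every informative spot, mimicking the
#'   up/down regulation quotients the report tables print.
#' @param outcome_noise_sd SD of the noise added to each outcome on its
#'   latent-factor scale (default 0.2).
#' @param seed random seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_con = 23L, n_cwp = 15L, n_spots = 325L,
                       n_informative_per_outcome = 20L,
                       latent_effect_size = 0.7,
                       orth_variance_fraction = 0.3,
                       technical_cv = 0.20,
                       biological_sd = 0.2,
                       group_fold_changes = NULL,
                       outcome_noise_sd = 0.2,
                       seed = 1L) {
  assert_number(n_con, "n_con", 1); assert_number(n_cwp, "n_cwp", 1)
  assert_number(n_spots, "n_spots", 1)
  assert_number(n_informative_per_outcome, "n_informative_per_outcome", 0, n_spots)
  assert_number(latent_effect_size, "latent_effect_size", 0)
  assert_number(orth_variance_fraction, "orth_variance_fraction", 0, 0.95)
  assert_number(technical_cv, "technical_cv", 0)
  if (technical_cv >= 1) stop_fmt("technical_cv must be below 1")
  assert_number(biological_sd, "biological_sd", 0)
  assert_number(outcome_noise_sd, "outcome_noise_sd", 0)
  assert_number(seed, "seed")
  if (4L * n_informative_per_outcome > n_spots) {
    stop_fmt("need n_spots >= 4 * n_informative_per_outcome for disjoint sets")
  }
  if (!is.null(group_fold_changes)) {
    if (is.null(names(group_fold_changes)) || any(group_fold_changes <= 0)) {
      stop_fmt("group_fold_changes must be a named vector of positive folds")
    }
  }
  structure(list(n_con = as.integer(n_con), n_cwp = as.integer(n_cwp),
                 n_spots = as.integer(n_spots),
                 n_informative_per_outcome = as.integer(n_informative_per_outcome),
                 latent_effect_size = latent_effect_size,
                 orth_variance_fraction = orth_variance_fraction,
                 technical_cv = technical_cv,
                 biological_sd = biological_sd,
                 group_fold_changes = group_fold_changes,
                 outcome_noise_sd = outcome_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_outcomes <- c("nrs", "hads_total", "bmi", "age")

# Log-scale technical noise SD giving the target CV on the natural scale.
technical_sigma <- function(cv) sqrt(log(1 + cv^2))

# Shared scaffolding: spot numbers, base means, informative sets, per-spot
# slopes, orthogonal loadings and fold changes. Called after set.seed().
sim_structure <- function(config) {
  nk <- config$n_spots
  spots <- sort(sample(100:9999, nk))
  mu <- stats::runif(nk, log(50), log(30000))
  ni <- config$n_informative_per_outcome
  idx <- sample(nk, 4L * ni)
  truth <- list()
  slopes <- matrix(0, nk, 4L, dimnames = list(NULL, sim_outcomes))
  for (o in seq_along(sim_outcomes)) {
    take <- idx[seq.int((o - 1L) * ni + 1L, o * ni)]
    truth[[sim_outcomes[o]]] <- spots[take]
    slopes[take, o] <- config$latent_effect_size *
      sample(c(-1, 1), ni, replace = TRUE)
  }
  sig_t <- technical_sigma(config$technical_cv)
  s_orth <- sqrt(config$orth_variance_fraction /
                   (1 - config$orth_variance_fraction) *
                   (config$biological_sd^2 + sig_t^2))
  p_orth <- stats::rnorm(nk, 0, s_orth)
  fold <- rep(1, nk)
  names(fold) <- as.character(spots)
  if (is.null(config$group_fold_changes)) {
    inf_all <- idx
    fold[inf_all] <- exp(stats::rnorm(length(inf_all), 0, 0.35))
  } else {
    hit <- match(names(config$group_fold_changes), names(fold))
    if (anyNA(hit)) stop_fmt("group_fold_changes names must be generated spot numbers")
    fold[hit] <- config$group_fold_changes
  }
  list(spots = spots, mu = mu, truth = truth, slopes = slopes,
       p_orth = p_orth, fold = fold, sigma_tech = sig_t)
}

clip <- function(v, lo, hi) pmin(hi, pmax(lo, v))

#' Simulate a two-group cohort with planted outcome associations
#'
#' Generates a spot-intensity table and a clinical table for `n_con` controls
#' and `n_cwp` patients. On the log scale each spot is
#' `base + sum_o(slope_o * t_o) + p_orth * t_orth + log(fold) * [CWP]
#' + biological + technical noise`, where `t_o` are per-sample standard
#' normal latent factors (one per outcome), `t_orth` is a latent factor
#' shared by all samples but uncorrelated with every outcome, and `fold` is
#' the multiplicative group offset. Each clinical outcome is an affine
#' function of its latent factor plus noise, clipped and rounded to its valid
#' range, with group-specific intercepts and spreads matching the emulated
#' cohort; NRS is 0 for every control (controls report no pain). The planted
#' informative spot numbers are returned as ground truth for recovery
#' testing.
#'
#' @param config a [sim_config].
#' @return List of class `sim_cohort` with elements `spots` (a
#'   [spot_table]), `clinical` (a [clinical_table]), `truth` (named list of
#'   informative spot numbers per outcome) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_fmt("config must be a sim_config")
  set.seed(config$seed)
  st <- sim_structure(config)
  n <- config$n_con + config$n_cwp
  nk <- config$n_spots
  group <- c(rep("CON", config$n_con), rep("CWP", config$n_cwp))
  ids <- c(sprintf("CON%02d", seq_len(config$n_con)),
           sprintf("CWP%02d", seq_len(config$n_cwp)))
  t_lat <- matrix(stats::rnorm(n * 4L), n, 4L, dimnames = list(NULL, sim_outcomes))
  t_orth <- stats::rnorm(n)
  logx <- matrix(st$mu, n, nk, byrow = TRUE) +
    t_lat %*% t(st$slopes) +
    tcrossprod(t_orth, st$p_orth) +
    matrix(log(st$fold), n, nk, byrow = TRUE) * (group == "CWP") +
    matrix(stats::rnorm(n * nk, 0, config$biological_sd), n, nk) +
    matrix(stats::rnorm(n * nk, 0, st$sigma_tech), n, nk)
  x <- exp(logx)
  dimnames(x) <- list(ids, as.character(st$spots))
  eps <- function() stats::rnorm(n, 0, config$outcome_noise_sd)
  cwp <- group == "CWP"
  nrs <- ifelse(cwp,
                clip(round(4.9 + 2.0 * (t_lat[, "nrs"] + eps())), 0, 10), 0)
  hads <- ifelse(cwp,
                 clip(round(14.0 + 5.3 * (t_lat[, "hads_total"] + eps())), 0, 42),
                 clip(round(3.3 + 2.8 * (t_lat[, "hads_total"] + eps())), 0, 42))
  bmi <- ifelse(cwp, 26.0 + 5.0 * (t_lat[, "bmi"] + eps()),
                     24.0 + 2.8 * (t_lat[, "bmi"] + eps()))
  bmi <- clip(bmi, 15, 50)
  age <- ifelse(cwp, round(49.2 + 8.9 * (t_lat[, "age"] + eps())),
                     round(41.0 + 10.2 * (t_lat[, "age"] + eps())))
  age <- clip(age, 20, 75)
  structure(list(spots = spot_table(x),
                 clinical = clinical_table(ids, group, nrs, hads, bmi, age),
                 truth = st$truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d CON + %d CWP, %d spots, %d informative per outcome (seed %d)\n",
              x$config$n_con, x$config$n_cwp, x$config$n_spots,
              x$config$n_informative_per_outcome, x$config$seed))
  invisible(x)
}

#' Simulate replicate quantifications of identical samples
#'
#' Draws one set of underlying true spot intensities (base means plus
#' biological variation, no technical noise) and quantifies each sample
#' `n_replicates` times with fresh multiplicative technical noise. Used to
#' validate that the technical-noise model meets its target coefficient of
#' variation.
#'
#' @param config a [sim_config]; `technical_cv` sets the noise level.
#' @param n_replicates replicates per underlying sample (>= 2).
#' @param n_samples number of underlying samples (default 20).
#' @return List of class `sim_replicates` with `spots` (a [spot_table] of
#'   `n_samples * n_replicates` rows, IDs `S<i>_r<j>`), `sample` and
#'   `replicate` index vectors, and `config`.
#' @export
simulate_replicates <- function(config = sim_config(), n_replicates = 2L,
                                n_samples = 20L) {
  if (!inherits(config, "sim_config")) stop_fmt("config must be a sim_config")
  if (n_replicates < 2L) stop_fmt("need at least 2 replicates")
  set.seed(config$seed)
  st <- sim_structure(config)
  nk <- config$n_spots
  true_log <- matrix(st$mu, n_samples, nk, byrow = TRUE) +
    matrix(stats::rnorm(n_samples * nk, 0, config$biological_sd), n_samples, nk)
  nrow_out <- n_samples * n_replicates
  sample_id <- rep(seq_len(n_samples), each = n_replicates)
  repl <- rep(seq_len(n_replicates), times = n_samples)
  logx <- true_log[sample_id, , drop = FALSE] +
    matrix(stats::rnorm(nrow_out * nk, 0, st$sigma_tech), nrow_out, nk)
  x <- exp(logx)
  dimnames(x) <- list(sprintf("S%02d_r%02d", sample_id, repl),
                      as.character(st$spots))
  structure(list(spots = spot_table(x), sample = sample_id, replicate = repl,
                 config = config),
            class = "sim_replicates")
}

#' Per-spot coefficient of variation across replicates
#'
#' For every spot, the CV (SD/mean across replicate quantifications) is
#' computed within each underlying sample and averaged over samples.
#'
#' @param reps a `sim_replicates` object from [simulate_replicates()].
#' @return Named numeric vector of per-spot mean CVs.
#' @export
replicate_cv <- function(reps) {
  if (!inherits(reps, "sim_replicates")) stop_fmt("expected a sim_replicates object")
  x <- unclass(reps$spots)
  groups <- split(seq_len(nrow(x)), reps$sample)
  cvs <- vapply(groups, function(rows) {
    xm <- x[rows, , drop = FALSE]
    apply(xm, 2L, function(v) stats::sd(v) / mean(v))
  }, numeric(ncol(x)))
  out <- rowMeans(cvs)
  names(out) <- colnames(x)
  out
}
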