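#' Fit a centering/unit-variance scaler with optional log transform
#'
#' Standard chemometric pretreatment: each variable is optionally
#' log-transformed, then mean centered and scaled to unit variance
#' (UV scaling). The log transform uses `log1p` so that zero IODs (a spot
#' absent from a gel) remain finite. Under `log_rule = "auto"` a variable is
#' flagged for transformation when its sample skewness exceeds
#' `skew_threshold`; `"always"` and `"never"` force the flag for all or no
#' variables.
#'
#' @param x numeric matrix, samples in rows.
#' @param log_rule `"never"` (default), `"always"` or `"auto"`.
#' @param skew_threshold skewness above which `"auto"` flags a variable
#'   (default 2).
#' @return An object of class `scaler`: per-variable means, standard
#'   deviations (computed after any log transform, with the n-1 denominator),
#'   log flags, and the indices of retained (non-constant) variables.
#'   Zero-variance variables are excluded with a warning.
#' @export
fit_scaler <- function(x, log_rule = c("never", "always", "auto"),
                       skew_threshold = 2) {
  log_rule <- match.arg(log_rule)
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop_fmt("cannot fit scaler on empty matrix")
  log_flag <- switch(log_rule,
    never  = rep(FALSE, ncol(x)),
    always = rep(TRUE, ncol(x)),
    auto   = apply(x, 2L, sample_skewness) > skew_threshold)
  log_flag[is.na(log_flag)] <- FALSE
  xt <- x
  if (any(log_flag)) xt[, log_flag] <- log1p(xt[, log_flag, drop = FALSE])
  mu <- colMeans(xt)
  sdev <- apply(xt, 2L, stats::sd)
  keep <- which(sdev > 0)
  if (length(keep) == 0L) stop_fmt("all variables are constant; nothing to scale")
  if (length(keep) < ncol(x)) {
    warn_fmt("excluding %d zero-variance variable(s): %s",
             ncol(x) - length(keep),
             paste(utils::head(colnames(x)[-keep] %||% (seq_len(ncol(x))[-keep]), 10L),
                   collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev, log = log_flag, keep = keep,
                 var_names = colnames(x)),
            class = "scaler")
}

# Adjusted Fisher-Pearson sample skewness (the g1 moment estimator).
sample_skewness <- function(v) {
  n <- length(v)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0 || n < 3L) return(0)
  mean((v - m)^3) / s^3
}

#' Apply a fitted scaler to a (possibly out-of-sample) matrix
#'
#' Out-of-sample rows are transformed with the training-set means and SDs; this
#' contract is what makes scaling inside cross-validation leakage-free.
#' Variables excluded at fit time (zero variance) are dropped.
#'
#' @param state a `scaler` from [fit_scaler()].
#' @param x numeric matrix with the same columns as the training matrix.
#' @return The scaled matrix (retained columns only).
#' @export
apply_scaler <- function(state, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(state$mean)) {
    stop_fmt("scaler was fitted on %d columns, got %d", length(state$mean), ncol(x))
  }
  if (any(state$log)) x[, state$log] <- log1p(x[, state$log, drop = FALSE])
  out <- sweep(x, 2L, state$mean, "-")
  out <- sweep(out, 2L, state$sd, "/")
  out[, state$keep, drop = FALSE]
}

#' Invert a fitted scaler
#'
#' Maps a scaled matrix (retained columns) back to the original measurement
#' scale, undoing UV scaling, centering and any log transform.
#'
#' @inheritParams apply_scaler
#' @param x_scaled scaled matrix with `length(state$keep)` columns.
#' @return Matrix on the original scale.
#' @export
invert_scaler <- function(state, x_scaled) {
  x_scaled <- as.matrix(x_scaled)
  if (ncol(x_scaled) != length(state$keep)) {
    stop_fmt("expected %d scaled columns, got %d", length(state$keep), ncol(x_scaled))
  }
  out <- sweep(x_scaled, 2L, state$sd[state$keep], "*")
  out <- sweep(out, 2L, state$mean[state$keep], "+")
  lf <- state$log[state$keep]
  if (any(lf)) out[, lf] <- expm1(out[, lf, drop = FALSE])
  colnames(out) <- (state$var_names %||% as.character(seq_along(state$mean)))[state$keep]
  out
}

#' PCA screen for multivariate outliers
#'
#' Unsupervised PCA run on the scaled X block before any OPLS regression, to
#' flag samples that do not belong to the multivariate normal bulk. Each
#' sample gets a Hotelling T-squared statistic from its normalized scores and
#' a residual distance-to-model (DModX-style, the RMS of its reconstruction
#' residual relative to the pooled residual). Samples beyond the 99% T-squared
#' limit are classed `strong`; samples beyond the 95% (but not the 99%)
#' T-squared limit, or beyond the 95% residual-distance limit, are `moderate`.
#'
#' @param x_scaled centered/UV-scaled matrix (samples in rows).
#' @param n_components number of principal components; `NULL` (default) picks
#'   the smallest number explaining at least `var_target` of the variance,
#'   capped at `max_components`.
#' @param var_target cumulative explained-variance target for the automatic
#'   component choice (default 0.6).
#' @param max_components cap for the automatic choice (default 5).
#' @return An object of class `outlier_screen` with per-sample `t2`, `dmodx`,
#'   `classification` (factor: none/moderate/strong), the T-squared limits
#'   `t2_crit95`/`t2_crit99`, the DModX limit `dmodx_crit95`, and the number
#'   of components used.
#' @export
pca_outlier_screen <- function(x_scaled, n_components = NULL,
                               var_target = 0.6, max_components = 5L) {
  x_scaled <- as.matrix(x_scaled)
  n <- nrow(x_scaled)
  k <- ncol(x_scaled)
  if (n < 3L) stop_fmt("need at least 3 samples for an outlier screen")
  pc <- stats::prcomp(x_scaled, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]
  if (length(ev) == 0L) stop_fmt("degenerate covariance: no non-zero components")
  if (is.null(n_components)) {
    cum <- cumsum(ev) / sum(ev)
    n_components <- min(which(cum >= var_target)[1L], max_components, length(ev))
  }
  a <- as.integer(n_components)
  if (a >= min(n, k)) stop_fmt("n_components must be below min(samples, variables)")
  if (a > length(ev)) stop_fmt("requested %d components but rank is %d", a, length(ev))
  scores <- pc$x[, seq_len(a), drop = FALSE]
  svar <- ev[seq_len(a)]
  t2 <- rowSums(sweep(scores^2, 2L, svar, "/"))
  # Hotelling T2 limit for PCA scores with A components and n observations.
  t2_lim <- function(alpha) {
    a * (n - 1) / (n - a) * stats::qf(alpha, a, n - a)
  }
  t2_95 <- t2_lim(0.95)
  t2_99 <- t2_lim(0.99)
  resid <- x_scaled - scores %*% t(pc$rotation[, seq_len(a), drop = FALSE])
  dof_row <- max(k - a, 1L)
  s_i <- sqrt(rowSums(resid^2) / dof_row)
  dof_pool <- max((n - a - 1) * (k - a), 1L)
  s0 <- sqrt(sum(resid^2) / dof_pool)
  if (sum(resid^2) > 1e-12 * sum(x_scaled^2)) {
    dmodx <- s_i / s0
    dmodx_95 <- sqrt(stats::qf(0.95, dof_row, dof_pool))
  } else {
    dmodx <- rep(0, n)      # exact low-rank case: no residual variation
    dmodx_95 <- Inf
  }
  cls <- rep("none", n)
  cls[t2 > t2_95 | dmodx > dmodx_95] <- "moderate"
  cls[t2 > t2_99] <- "strong"
  structure(list(n_components = a,
                 t2 = stats::setNames(t2, rownames(x_scaled)),
                 dmodx = stats::setNames(dmodx, rownames(x_scaled)),
                 t2_crit95 = t2_95, t2_crit99 = t2_99,
                 dmodx_crit95 = dmodx_95,
                 classification = factor(cls, levels = c("none", "moderate", "strong"))),
            class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  tab <- table(x$classification)
  cat(sprintf("PCA outlier screen (%d components): %d none, %d moderate, %d strong\n",
              x$n_components, tab[["none"]], tab[["moderate"]], tab[["strong"]]))
  invisible(x)
}
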