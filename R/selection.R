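#' Variable influence on projection (VIP)
#'
#' VIP summarizes each variable's contribution to the predictive projection:
#' `VIP_j = sqrt(K * sum_a(SSY_a * (w_aj/||w_a||)^2) / sum_a(SSY_a))` over the
#' predictive components. For the single-predictive-component models fitted
#' here this reduces to `sqrt(K) * |w_j|`, and the mean of squared VIPs is
#' exactly 1 — which is what makes the conventional VIP > 1.0 selection
#' threshold interpretable ("more important than the average variable").
#'
#' The `"total"` variant additionally folds in the orthogonal components,
#' weighting each component's squared normalized weight by the fraction of X
#' variance it captures (predictive component weighted by its explained
#' Y variance). It is provided for comparison with software that reports a
#' combined-variation VIP; the predictive-only variant is the default and the
#' one used by the selection procedure.
#'
#' @param model an `opls_fit` or [opls] object.
#' @param variant `"predictive"` (default) or `"total"`.
#' @return Named non-negative numeric vector, one entry per variable.
#' @export
vip_scores <- function(model, variant = c("predictive", "total")) {
  variant <- match.arg(variant)
  fit <- if (inherits(model, "opls")) model$fit else model
  if (!inherits(fit, "opls_fit")) stop_fmt("not a fitted OPLS model")
  K <- length(fit$w)
  if (variant == "predictive") {
    out <- sqrt(K) * abs(fit$w)
  } else {
    wts <- c(max(fit$r2y, 0), fit$ssx$orthogonal / fit$ssx$total)
    W <- cbind(fit$w, fit$w_ortho)
    out <- sqrt(K * drop(W^2 %*% wts) / sum(wts))
    names(out) <- names(fit$w)
  }
  out
}

#' Jack-knifed confidence intervals for OPLS coefficients
#'
#' Coefficient uncertainty is estimated from the perturbed sub-models of the
#' cross-validation rounds: with G folds,
#' `SE_j = sqrt((G-1)/G * sum_g (b_jg - mean_g(b_jg))^2)` and the interval is
#' `b_j +/- t(1-(1-level)/2, G-1) * SE_j` around the full-model coefficient.
#' A variable whose interval excludes zero has a coefficient estimated
#' consistently in sign and magnitude across the cross-validation rounds.
#'
#' @param cv_coefficients folds x variables matrix of per-fold coefficients
#'   (as stored on an [opls] object), or an [opls] object itself.
#' @param b full-model coefficient vector; taken from the model if
#'   `cv_coefficients` is an [opls] object.
#' @param level confidence level (default 0.95).
#' @return List with `lower`, `upper`, `se` (named vectors) and
#'   `excludes_zero` (logical).
#' @export
jackknife_ci <- function(cv_coefficients, b, level = 0.95) {
  if (inherits(cv_coefficients, "opls")) {
    if (missing(b)) b <- cv_coefficients$coefficients
    cv_coefficients <- cv_coefficients$cv_coefficients
  }
  cv_coefficients <- as.matrix(cv_coefficients)
  G <- nrow(cv_coefficients)
  if (G < 2L) stop_fmt("jack-knife needs at least 2 cross-validation folds")
  if (ncol(cv_coefficients) != length(b)) {
    stop_fmt("coefficient length mismatch: %d folds columns vs %d coefficients",
             ncol(cv_coefficients), length(b))
  }
  bbar <- colMeans(cv_coefficients)
  se <- sqrt((G - 1) / G * colSums(sweep(cv_coefficients, 2L, bbar, "-")^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = G - 1)
  lower <- b - tq * se
  upper <- b + tq * se
  names(lower) <- names(upper) <- names(se) <- names(b)
  list(lower = lower, upper = upper, se = se,
       excludes_zero = lower > 0 | upper < 0)
}

# Shared CV-ANOVA arithmetic on precomputed sums of squares.
cv_anova_press <- function(ss, press, n, n_pred, n_ortho, df_model = NULL) {
  df_model <- as.integer(df_model %||% (n_pred + n_ortho))
  df_total <- as.integer(n) - 1L
  df_resid <- df_total - df_model
  if (df_resid <= 0L) stop_fmt("CV-ANOVA needs n - 1 > number of components")
  ss_regr <- max(ss - press, 0)
  f <- (ss_regr / df_model) / (press / df_resid)
  if (!is.finite(f)) f <- Inf   # press == 0: perfect prediction
  p <- stats::pf(f, df_model, df_resid, lower.tail = FALSE)
  list(f = f, p = p, df_model = df_model, df_resid = df_resid,
       ss = ss, press = press)
}

#' CV-ANOVA model significance test
#'
#' Cross-validated analysis of variance: an F test comparing the variation
#' explained by cross-validated prediction (`SS - PRESS`) to the prediction
#' error (`PRESS`). Degrees of freedom follow the component-counting
#' convention: the model consumes one degree of freedom per fitted component
#' (predictive + orthogonal), the total is `n - 1`, and the residual the
#' difference. `F = ((SS - PRESS)/DF_model) / (PRESS/DF_resid)`, clipped at 0
#' when PRESS exceeds SS; p is the upper tail of the corresponding F
#' distribution. A model with `p <= 0.05` is conventionally called
#' significant.
#'
#' @param y_scaled the centered/scaled response vector, or an [opls] object
#'   (in which case the remaining arguments are taken from the model).
#' @param press prediction residual sum of squares from cross-validation.
#' @param n_pred,n_ortho numbers of predictive and orthogonal components.
#' @param df_model optional override of the model degrees of freedom, for
#'   software that counts components differently; default `n_pred + n_ortho`.
#' @return List with `f`, `p`, `df_model`, `df_resid`, `ss`, `press`.
#' @export
cv_anova <- function(y_scaled, press, n_pred = 1L, n_ortho = 1L,
                     df_model = NULL) {
  if (inherits(y_scaled, "opls")) {
    m <- y_scaled
    return(cv_anova_press(m$ss, m$press, length(m$y), m$n_pred, m$n_ortho,
                          df_model))
  }
  y_scaled <- as.numeric(y_scaled)
  if (press < 0) stop_fmt("press must be non-negative")
  ss <- sum(y_scaled^2)
  if (ss <= 0) stop_fmt("response has zero variance")
  cv_anova_press(ss, press, length(y_scaled), n_pred, n_ortho, df_model)
}

#' Two-step VIP-based variable selection with a validated refit
#'
#' The selection procedure used throughout the analysis: first an OPLS model
#' on all variables, from which variables with VIP above the threshold
#' (strictly greater than 1.0 by default) are carried forward; second, a
#' refit on the selected subset with VIP, jack-knifed confidence intervals,
#' p(corr) and CV-ANOVA recomputed. The final significant set contains the
#' variables with stage-2 VIP above the threshold whose stage-2 confidence
#' interval excludes zero. Both stages are retained for provenance.
#'
#' @inheritParams opls
#' @param vip_threshold VIP cut-off (strict inequality; default 1.0).
#' @param ci_level confidence level for the jack-knifed intervals.
#' @param stage1_require_ci also require the confidence-interval criterion at
#'   stage 1 (default `FALSE`: stage 1 selects on VIP alone).
#' @param vip_variant VIP variant, see [vip_scores()].
#' @return An object of class `opls_twostep`: `stage1` and `stage2` [opls]
#'   models, `selected_stage1` and `significant` (character vectors of
#'   variable names), stage-2 `vip`, `ci`, `pcorr`, `cvanova`, and `valid`
#'   (`FALSE` when no variable passes stage 1, in which case `stage2` is
#'   `NULL`).
#' @export
opls_two_step <- function(x, y, n_ortho = 1L, vip_threshold = 1,
                          ci_level = 0.95, stage1_require_ci = FALSE,
                          vip_variant = "predictive",
                          log_rule = "never", skew_threshold = 2,
                          cv_folds = 7L, cv_scaling = c("fixed", "refit")) {
  cv_scaling <- match.arg(cv_scaling)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  if (ncol(x) < 2L) stop_fmt("need at least 2 variables for the two-step procedure")
  stage1 <- opls(x, y, n_ortho = n_ortho, log_rule = log_rule,
                 skew_threshold = skew_threshold, cv_folds = cv_folds,
                 cv_scaling = cv_scaling)
  vip1 <- vip_scores(stage1, variant = vip_variant)
  ci1 <- jackknife_ci(stage1, level = ci_level)
  pass1 <- vip1 > vip_threshold
  if (stage1_require_ci) pass1 <- pass1 & ci1$excludes_zero
  selected <- names(vip1)[pass1]
  base <- list(stage1 = stage1, vip_stage1 = vip1, ci_stage1 = ci1,
               selected_stage1 = selected,
               settings = list(n_ortho = n_ortho, vip_threshold = vip_threshold,
                               ci_level = ci_level, vip_variant = vip_variant,
                               stage1_require_ci = stage1_require_ci,
                               log_rule = log_rule,
                               skew_threshold = skew_threshold,
                               cv_folds = cv_folds, cv_scaling = cv_scaling))
  if (length(selected) == 0L) {
    return(structure(c(base, list(stage2 = NULL, vip = NULL, ci = NULL,
                                  pcorr = NULL, cvanova = NULL,
                                  significant = character(0), valid = FALSE)),
                     class = "opls_twostep"))
  }
  st2 <- refit_subset(x, y, selected, base$settings)
  structure(c(base, st2, list(valid = TRUE)), class = "opls_twostep")
}

# Stage-2 refit on a named variable subset; shared with the confounder
# compensation workflow. Reduces n_ortho (with a warning) if the subset is
# too small to support the requested orthogonal components.
refit_subset <- function(x, y, vars, settings) {
  x2 <- as.matrix(x)[, vars, drop = FALSE]
  no <- settings$n_ortho
  stage2 <- NULL
  repeat {
    stage2 <- tryCatch(
      opls(x2, y, n_ortho = no, log_rule = settings$log_rule,
           skew_threshold = settings$skew_threshold,
           cv_folds = settings$cv_folds, cv_scaling = settings$cv_scaling),
      error = function(e) e)
    if (!inherits(stage2, "error") || no == 0L) break
    no <- no - 1L
    warn_fmt("stage-2 subset does not support %d orthogonal component(s); using %d",
             settings$n_ortho, no)
  }
  if (inherits(stage2, "error")) stop(stage2)
  vip2 <- vip_scores(stage2, variant = settings$vip_variant)
  ci2 <- jackknife_ci(stage2, level = settings$ci_level)
  sig <- names(vip2)[vip2 > settings$vip_threshold & ci2$excludes_zero]
  list(stage2 = stage2, vip = vip2, ci = ci2,
       pcorr = stage2$pcorr, cvanova = stage2$cvanova, significant = sig)
}

#' @export
print.opls_twostep <- function(x, ...) {
  cat(sprintf("Two-step OPLS selection: %d -> %d (stage 1, VIP > %g) -> %d significant\n",
              length(x$vip_stage1), length(x$selected_stage1),
              x$settings$vip_threshold, length(x$significant)))
  if (x$valid) {
    cat(sprintf("  stage 2: R2Y = %.3f, Q2 = %.3f, CV-ANOVA p = %.4g\n",
                x$stage2$r2y, x$stage2$q2, x$cvanova$p))
  } else {
    cat("  no variable passed stage 1; model not valid\n")
  }
  invisible(x)
}
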