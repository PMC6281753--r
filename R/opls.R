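#' Fit the OPLS algorithm on pretreated data
#'
#' Low-level single-response orthogonal projections to latent structures
#' (OPLS) fit on an already centered/UV-scaled X block and response. OPLS
#' splits the systematic variation of X into one component predictive of y
#' and `n_ortho` components orthogonal to y. The predictive weight vector is
#' `w = X'y / ||X'y||`; each orthogonal component is extracted from the
#' current loading as `w_o = p - (w'p) w` (normalized), scored as
#' `t_o = X w_o`, loaded as `p_o = X't_o / (t_o't_o)` and deflated from X;
#' the predictive component `t = X w`, `p = X't/(t't)`, `c = y't/(t't)` is
#' taken on the filtered matrix. All steps are closed form; no iteration is
#' required for a single response.
#'
#' @param x_scaled numeric matrix, centered and scaled, samples in rows.
#' @param y_scaled numeric vector, centered (and typically UV-scaled).
#' @param n_ortho number of orthogonal components (>= 0).
#' @return An object of class `opls_fit` with unit-norm weights `w` and
#'   `w_ortho`, scores `t`/`t_ortho`, loadings `p`/`p_ortho`, y-loading `c`,
#'   coefficient vector `coefficients` (scaled space, so that
#'   `x_scaled %*% coefficients` reproduces the fitted values), `fitted`,
#'   `r2y`, and the X-variance bookkeeping `ssx` (total, predictive,
#'   per-orthogonal-component, residual).
#' @export
fit_opls <- function(x_scaled, y_scaled, n_ortho = 1L) {
  X <- as.matrix(x_scaled)
  y <- as.numeric(y_scaled)
  n <- nrow(X)
  K <- ncol(X)
  if (length(y) != n) stop_fmt("length(y) = %d but X has %d rows", length(y), n)
  if (n_ortho < 0L) stop_fmt("n_ortho must be >= 0")
  ssy <- sum(y^2)
  if (ssy <= 0) stop_fmt("response has zero variance")
  wv <- crossprod(X, y)[, 1L]
  nw <- sqrt(sum(wv^2))
  if (nw < 1e-12) stop_fmt("response is orthogonal to every column of X")
  w <- wv / nw
  W_o <- matrix(0, K, n_ortho)
  T_o <- matrix(0, n, n_ortho)
  P_o <- matrix(0, K, n_ortho)
  ssx_total <- sum(X^2)
  ssx_orth <- numeric(n_ortho)
  Xd <- X
  for (j in seq_len(n_ortho)) {
    t_j <- drop(Xd %*% w)
    p_j <- crossprod(Xd, t_j)[, 1L] / sum(t_j^2)
    wo <- p_j - sum(w * p_j) * w
    nwo <- sqrt(sum(wo^2))
    if (!is.finite(nwo) || nwo < 1e-10 * max(1, sqrt(sum(p_j^2)))) {
      stop_fmt("matrix rank does not support %d orthogonal component(s)", n_ortho)
    }
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    tto <- sum(to^2)
    if (tto < 1e-20) {
      stop_fmt("matrix rank does not support %d orthogonal component(s)", n_ortho)
    }
    po <- crossprod(Xd, to)[, 1L] / tto
    Xd <- Xd - tcrossprod(to, po)
    W_o[, j] <- wo
    T_o[, j] <- to
    P_o[, j] <- po
    ssx_orth[j] <- tto * sum(po^2)
  }
  t_pred <- drop(Xd %*% w)
  tt <- sum(t_pred^2)
  if (tt < 1e-20) stop_fmt("predictive score collapsed; too many orthogonal components")
  c_load <- sum(y * t_pred) / tt
  p_pred <- crossprod(Xd, t_pred)[, 1L] / tt
  # Coefficients: back-propagate the predictive weight through the
  # orthogonal filters so that yhat = X b for raw (unfiltered) scaled rows.
  v <- w
  for (j in rev(seq_len(n_ortho))) v <- v - W_o[, j] * sum(P_o[, j] * v)
  b <- c_load * v
  fitted <- t_pred * c_load
  r2y <- 1 - sum((y - fitted)^2) / ssy
  vn <- colnames(X) %||% as.character(seq_len(K))
  names(w) <- names(p_pred) <- names(b) <- vn
  rownames(W_o) <- rownames(P_o) <- vn
  structure(list(w = w, t = t_pred, p = p_pred, c = c_load,
                 w_ortho = W_o, t_ortho = T_o, p_ortho = P_o,
                 coefficients = b, fitted = fitted, r2y = r2y,
                 n_pred = 1L, n_ortho = as.integer(n_ortho),
                 ssx = list(total = ssx_total,
                            predictive = tt * sum(p_pred^2),
                            orthogonal = ssx_orth,
                            residual = sum((Xd - tcrossprod(t_pred, p_pred))^2)),
                 var_names = vn),
            class = "opls_fit")
}

# Project new scaled rows through the orthogonal filters and the predictive
# component of a fitted model. Returns the filtered predictive scores and the
# predicted response in the scaled space.
opls_project <- function(fit, x_scaled_new) {
  Xn <- as.matrix(x_scaled_new)
  if (ncol(Xn) != length(fit$w)) {
    stop_fmt("model was fitted on %d variables, got %d", length(fit$w), ncol(Xn))
  }
  for (j in seq_len(fit$n_ortho)) {
    to_new <- drop(Xn %*% fit$w_ortho[, j])
    Xn <- Xn - tcrossprod(to_new, fit$p_ortho[, j])
  }
  t_new <- drop(Xn %*% fit$w)
  list(t = t_new, yhat = t_new * fit$c)
}

#' Per-variable loadings scaled as correlation coefficients
#'
#' p(corr) expresses the loading of each X variable as its Pearson
#' correlation with the predictive score, standardizing the range to
#' \[-1, 1\] so that loadings are comparable across models.
#'
#' @param model an `opls_fit` or [opls] object.
#' @param x_scaled the scaled X block the model was fitted on; may be omitted
#'   for an [opls] object, which stores it.
#' @return Named numeric vector in \[-1, 1\]; zero-variance columns get 0 with
#'   a warning.
#' @export
p_corr <- function(model, x_scaled) {
  fit <- if (inherits(model, "opls")) model$fit else model
  if (missing(x_scaled)) {
    if (inherits(model, "opls")) x_scaled <- model$x_scaled
    else stop_fmt("x_scaled is required for an opls_fit")
  }
  Xs <- as.matrix(x_scaled)
  t_pred <- fit$t
  sds <- apply(Xs, 2L, stats::sd)
  out <- rep(0, ncol(Xs))
  ok <- sds > 0
  if (!all(ok)) warn_fmt("%d zero-variance column(s); p(corr) set to 0", sum(!ok))
  if (any(ok)) out[ok] <- drop(stats::cor(Xs[, ok, drop = FALSE], t_pred))
  names(out) <- colnames(Xs) %||% as.character(seq_len(ncol(Xs)))
  out
}

#' Cross-validated Q2 for an OPLS model
#'
#' K-fold cross-validation with deterministic round-robin fold assignment
#' over the row order (rows are expected to be in the package's canonical
#' lexicographic sample order). Held-out predictions are accumulated in the
#' full-data scaled space, where `Q2 = 1 - PRESS / sum(y_scaled^2)`. The
#' per-fold coefficient vectors are retained for jack-knife confidence
#' intervals.
#'
#' Two pretreatment conventions are available. The default, `"fixed"`,
#' computes centering and UV scaling once on the full data and refits only
#' the latent-variable model per fold — the convention of the chemometrics
#' packages this workflow emulates, and the one under which the CV-ANOVA
#' F test is calibrated close to its nominal level. `"refit"` re-estimates
#' the scaling inside every training fold (strictly leakage-free; Q2 is
#' slightly lower and the CV-ANOVA test becomes conservative). See the
#' methods vignette for the calibration comparison.
#'
#' @param x raw (untransformed) X matrix, samples in rows.
#' @param y raw response vector.
#' @param n_ortho number of orthogonal components.
#' @param n_folds number of cross-validation folds (default 7).
#' @param log_rule,skew_threshold passed to [fit_scaler()]; log-transform
#'   flags are fixed from the full-data fit and reused inside every fold.
#' @param cv_scaling `"fixed"` (default) or `"refit"`, see above.
#' @param scaler optionally, a pre-fitted full-data `scaler` to reuse.
#' @return List with `q2`, `press`, `ss` (total sum of squares of the scaled
#'   response), `cv_coefficients` (folds x variables matrix of per-fold
#'   coefficients, aligned to the retained variables), and `folds` (the fold
#'   id of every sample).
#' @export
cross_validated_q2 <- function(x, y, n_ortho = 1L, n_folds = 7L,
                               log_rule = "never", skew_threshold = 2,
                               cv_scaling = c("fixed", "refit"),
                               scaler = NULL) {
  cv_scaling <- match.arg(cv_scaling)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n_folds < 2L) stop_fmt("need at least 2 folds")
  n_folds <- min(as.integer(n_folds), n)
  fold_id <- rep_len(seq_len(n_folds), n)
  if (min(n - tabulate(fold_id, n_folds)) < 3L) {
    stop_fmt("every fold must leave at least 3 training samples (n = %d, folds = %d)",
             n, n_folds)
  }
  if (is.null(scaler)) {
    scaler <- suppressWarnings(fit_scaler(x, log_rule = log_rule,
                                          skew_threshold = skew_threshold))
  }
  my <- mean(y)
  sy <- stats::sd(y)
  if (sy == 0) stop_fmt("response has zero variance")
  ys_full <- (y - my) / sy
  ss <- sum(ys_full^2)
  keep <- scaler$keep
  xt <- x
  if (any(scaler$log)) xt[, scaler$log] <- log1p(xt[, scaler$log, drop = FALSE])
  xt <- xt[, keep, drop = FALSE]
  K <- ncol(xt)
  Xs_full <- sweep(sweep(xt, 2L, scaler$mean[keep], "-"), 2L, scaler$sd[keep], "/")
  cv_coef <- matrix(0, n_folds, K,
                    dimnames = list(NULL, colnames(x)[keep] %||% as.character(keep)))
  press <- 0
  for (g in seq_len(n_folds)) {
    te <- which(fold_id == g)
    tr <- setdiff(seq_len(n), te)
    if (cv_scaling == "fixed") {
      fit <- fit_opls(Xs_full[tr, , drop = FALSE], ys_full[tr], n_ortho = n_ortho)
      yhat <- opls_project(fit, Xs_full[te, , drop = FALSE])$yhat
      press <- press + sum((ys_full[te] - yhat)^2)
      cv_coef[g, ] <- fit$coefficients
    } else {
      mtr <- colMeans(xt[tr, , drop = FALSE])
      str <- apply(xt[tr, , drop = FALSE], 2L, stats::sd)
      ok <- str > 0
      Xtr <- sweep(sweep(xt[tr, ok, drop = FALSE], 2L, mtr[ok], "-"), 2L, str[ok], "/")
      Xte <- sweep(sweep(xt[te, ok, drop = FALSE], 2L, mtr[ok], "-"), 2L, str[ok], "/")
      my_tr <- mean(y[tr])
      sy_tr <- stats::sd(y[tr])
      if (sy_tr == 0) stop_fmt("response is constant within training fold %d", g)
      ytr <- (y[tr] - my_tr) / sy_tr
      fit <- fit_opls(Xtr, ytr, n_ortho = n_ortho)
      yhat_raw <- opls_project(fit, Xte)$yhat * sy_tr + my_tr
      press <- press + sum((ys_full[te] - (yhat_raw - my) / sy)^2)
      cv_coef[g, ok] <- fit$coefficients
    }
  }
  list(q2 = 1 - press / ss, press = press, ss = ss,
       cv_coefficients = cv_coef, folds = fold_id)
}

#' Fit an OPLS regression model
#'
#' The main fitting function. Takes a raw spot-intensity (or any numeric)
#' matrix and a single clinical response, applies the standard chemometric
#' pretreatment (optional log transform, mean centering, UV scaling of both
#' blocks), fits a single-response OPLS model with one predictive and
#' `n_ortho` orthogonal components, and cross-validates it. The returned
#' object carries R2Y (goodness of fit), Q2 (goodness of prediction), VIP
#' scores, p(corr), the per-fold cross-validation coefficients used for
#' jack-knifed confidence intervals, and the PRESS statistic consumed by
#' [cv_anova()].
#'
#' @param x numeric matrix of predictors (e.g. a [spot_table]), samples in
#'   rows. Rows should be in the canonical sorted-sample order for
#'   reproducible fold assignment (see [join_cohort()]).
#' @param y numeric response vector with non-zero variance.
#' @param n_ortho number of orthogonal components (default 1, the model form
#'   used throughout 2-DE plasma analyses of this kind).
#' @param log_rule,skew_threshold variable-wise log-transform rule, see
#'   [fit_scaler()].
#' @param cv_folds number of cross-validation folds (default 7).
#' @param cv_scaling pretreatment convention inside cross-validation, see
#'   [cross_validated_q2()].
#' @return An object of class `opls`; see Details for components. Methods:
#'   [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()], [simulate()].
#' @details Components include `fit` (the `opls_fit`), `vip` (predictive-
#'   component VIP), `pcorr`, `r2y`, `q2`, `press`, `cv_coefficients`,
#'   `cvanova` (F and p from [cv_anova()]), the fitted `x_scaler` and the
#'   response centering/scale.
#' @seealso [fit_opls()] for the algorithm on pretreated data,
#'   [opls_two_step()] for the two-stage VIP selection procedure.
#' @export
opls <- function(x, y, n_ortho = 1L, log_rule = "never", skew_threshold = 2,
                 cv_folds = 7L, cv_scaling = c("fixed", "refit")) {
  cv_scaling <- match.arg(cv_scaling)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_fmt("nrow(x) != length(y)")
  sx <- fit_scaler(x, log_rule = log_rule, skew_threshold = skew_threshold)
  Xs <- apply_scaler(sx, x)
  my <- mean(y)
  sy <- stats::sd(y)
  if (sy == 0) stop_fmt("response has zero variance")
  ys <- (y - my) / sy
  fit <- fit_opls(Xs, ys, n_ortho = n_ortho)
  cv <- cross_validated_q2(x, y, n_ortho = n_ortho, n_folds = cv_folds,
                           cv_scaling = cv_scaling, scaler = sx)
  vip <- vip_scores(fit)
  pc <- p_corr(fit, Xs)
  av <- cv_anova_press(cv$ss, cv$press, length(y), fit$n_pred, fit$n_ortho)
  structure(list(fit = fit, x_scaler = sx, y_center = my, y_scale = sy,
                 x_scaled = Xs, y_scaled = ys, y = y,
                 coefficients = fit$coefficients,
                 r2y = fit$r2y, q2 = cv$q2, press = cv$press, ss = cv$ss,
                 cv_coefficients = cv$cv_coefficients, folds = cv$folds,
                 vip = vip, pcorr = pc, cvanova = av,
                 n_ortho = fit$n_ortho, n_pred = fit$n_pred,
                 call = match.call()),
            class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS model: 1 predictive + %d orthogonal component(s), %d samples, %d variables\n",
              x$n_ortho, length(x$y), length(x$coefficients)))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f, CV-ANOVA p = %.4g\n",
              x$r2y, x$q2, x$cvanova$p))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  f <- object$fit
  ssx <- f$ssx
  out <- list(n = length(object$y), k = length(object$coefficients),
              n_ortho = f$n_ortho, r2y = object$r2y, q2 = object$q2,
              cvanova = object$cvanova,
              r2x_pred = ssx$predictive / ssx$total,
              r2x_orth = ssx$orthogonal / ssx$total,
              n_vip_gt1 = sum(object$vip > 1))
  class(out) <- "summary.opls"
  out
}

#' @export
print.summary.opls <- function(x, ...) {
  cat(sprintf("OPLS: %d samples, %d variables, 1 + %d components\n",
              x$n, x$k, x$n_ortho))
  cat(sprintf("  R2Y = %.3f  Q2 = %.3f\n", x$r2y, x$q2))
  cat(sprintf("  R2X(pred) = %.3f  R2X(orth) = %s\n", x$r2x_pred,
              paste(sprintf("%.3f", x$r2x_orth), collapse = ", ")))
  cat(sprintf("  CV-ANOVA: F = %.3f on (%d, %d) df, p = %.4g\n",
              x$cvanova$f, x$cvanova$df_model, x$cvanova$df_resid, x$cvanova$p))
  cat(sprintf("  variables with VIP > 1: %d\n", x$n_vip_gt1))
  invisible(x)
}

#' @export
coef.opls <- function(object, ...) object$coefficients

#' Predict from a fitted OPLS model
#'
#' New rows are pretreated with the training scaler, filtered through the
#' stored orthogonal components, and projected onto the predictive component.
#'
#' @param object an [opls] model.
#' @param newdata raw predictor matrix with the training columns; defaults to
#'   the training data.
#' @param type `"response"` (original y units, default) or `"scaled"`.
#' @param ... unused.
#' @export
predict.opls <- function(object, newdata, type = c("response", "scaled"), ...) {
  type <- match.arg(type)
  Xs <- if (missing(newdata)) object$x_scaled
        else apply_scaler(object$x_scaler, as.matrix(newdata))
  yh <- opls_project(object$fit, Xs)$yhat
  if (type == "response") yh * object$y_scale + object$y_center else yh
}

#' @export
fitted.opls <- function(object, ...) {
  object$fit$fitted * object$y_scale + object$y_center
}

#' @export
residuals.opls <- function(object, ...) object$y - fitted(object)

#' @export
plot.opls <- function(x, ...) {
  to <- if (x$n_ortho > 0L) x$fit$t_ortho[, 1L] else rep(0, length(x$fit$t))
  graphics::plot(x$fit$t, to, xlab = "t[1] (predictive)",
                 ylab = if (x$n_ortho > 0L) "to[1] (orthogonal)" else "",
                 main = "OPLS score plot", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' @export
simulate.opls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdr <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
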