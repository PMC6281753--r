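#' Fit one outcome model on a cohort and assemble its report
#'
#' The per-model pipeline: subset the cohort to the requested group, run the
#' PCA outlier screen on the pretreated X block (advisory by default: outliers
#' are reported, not dropped, unless `drop_outliers = TRUE`), run the two-step
#' VIP selection ([opls_two_step()]), and assemble the report table. Group
#' means and SDs for the OD-quotient columns are always computed from the raw
#' (untransformed) IOD values over the full cohort — both groups — because the
#' quotient describes CWP-vs-CON regulation, however the model itself was
#' scaled.
#'
#' @param cohort a `cohort` from [join_cohort()] or a `sim_cohort`.
#' @param outcome one of `"nrs"`, `"hads_total"`, `"bmi"`, `"age"`.
#' @param group `"CWP"`, `"CON"` or `"all"`.
#' @inheritParams opls_two_step
#' @param drop_outliers drop samples classed `strong` by the screen before
#'   modelling (default `FALSE`).
#' @param name model name for reporting; defaults to `<OUTCOME>_<GROUP>`.
#' @return An object of class `model_report`: `model_name`, `group`,
#'   `outcome`, `n_samples`, `significant_spots` (data frame sorted by
#'   descending VIP with VIP, p(corr), per-group raw mean/SD, OD quotient and
#'   alteration direction), model statistics `r2`, `q2`, `cvanova_p`,
#'   `excluded_spots`, the outlier `screen`, and the full two-stage
#'   `selection` object for provenance.
#' @export
run_model <- function(cohort, outcome = c("nrs", "hads_total", "bmi", "age"),
                      group = c("CWP", "CON", "all"),
                      n_ortho = 1L, vip_threshold = 1, ci_level = 0.95,
                      stage1_require_ci = FALSE, vip_variant = "predictive",
                      log_rule = "never", skew_threshold = 2, cv_folds = 7L,
                      cv_scaling = c("fixed", "refit"),
                      drop_outliers = FALSE, name = NULL) {
  cv_scaling <- match.arg(cv_scaling)
  outcome <- match.arg(outcome)
  group <- match.arg(group)
  ch <- as_cohort(cohort)
  rows <- if (group == "all") seq_len(nrow(ch$x)) else which(ch$clinical$group == group)
  if (length(rows) == 0L) stop_fmt("no samples in group '%s'", group)
  y <- ch$clinical[[outcome]][rows]
  if (stats::sd(y) == 0) {
    stop_fmt("outcome '%s' is constant within group '%s' (value %s); no regression possible",
             outcome, group, format(y[1L]))
  }
  x_sub <- unclass(ch$x)[rows, , drop = FALSE]
  settings <- list(n_ortho = n_ortho, vip_threshold = vip_threshold,
                   ci_level = ci_level, stage1_require_ci = stage1_require_ci,
                   vip_variant = vip_variant, log_rule = log_rule,
                   skew_threshold = skew_threshold, cv_folds = cv_folds,
                   cv_scaling = cv_scaling)
  scr <- screen_subset(x_sub, log_rule, skew_threshold)
  if (!is.null(scr)) {
    n_strong <- sum(scr$classification == "strong")
    n_mod <- sum(scr$classification == "moderate")
    if (n_strong + n_mod > 0L) {
      warn_fmt("PCA screen: %d moderate and %d strong multivariate outlier(s) in group '%s'%s",
               n_mod, n_strong, group,
               if (drop_outliers && n_strong > 0L) " (strong outliers dropped)" else "")
    }
    if (drop_outliers && n_strong > 0L) {
      keep <- scr$classification != "strong"
      x_sub <- x_sub[keep, , drop = FALSE]
      y <- y[keep]
      rows <- rows[keep]
    }
  }
  ts <- opls_two_step(x_sub, y, n_ortho = n_ortho,
                      vip_threshold = vip_threshold, ci_level = ci_level,
                      stage1_require_ci = stage1_require_ci,
                      vip_variant = vip_variant, log_rule = log_rule,
                      skew_threshold = skew_threshold, cv_folds = cv_folds,
                      cv_scaling = cv_scaling)
  build_report(ch, ts,
               name = name %||% default_model_name(outcome, group),
               group = group, outcome = outcome, settings = settings,
               screen = scr,
               excluded = data.frame(spot_number = integer(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE))
}

default_model_name <- function(outcome, group) {
  paste0(switch(outcome, nrs = "NRS", hads_total = "HADS", bmi = "BMI", age = "Age"),
         "_", group)
}

as_cohort <- function(cohort) {
  if (inherits(cohort, "cohort")) return(cohort)
  if (inherits(cohort, "sim_cohort")) return(join_cohort(cohort$spots, cohort$clinical))
  stop_fmt("expected a cohort or sim_cohort object")
}

screen_subset <- function(x_sub, log_rule, skew_threshold) {
  if (nrow(x_sub) < 4L) return(NULL)
  sx <- suppressWarnings(fit_scaler(x_sub, log_rule = log_rule,
                                    skew_threshold = skew_threshold))
  pca_outlier_screen(apply_scaler(sx, x_sub))
}

#' Raw-scale group statistics and OD quotients for a set of spots
#'
#' For each requested spot, the mean and SD of the raw IOD values within each
#' group and the OD quotient `mean(CWP) / mean(CON)`, rounded half-up to two
#' decimals as printed in report tables. The alteration direction is `"up"`
#' when the unrounded quotient exceeds 1 (up-regulated in CWP) and `"down"`
#' when it is below 1; exact equality is reported as `"up"` with a logged
#' note (by convention; the rounded quotient then prints as 1.00).
#'
#' @param spots a [spot_table] (raw IOD values).
#' @param group factor/character of `"CWP"`/`"CON"` per row of `spots`.
#' @param spot_numbers spots to tabulate (default: all).
#' @return Data frame with `spot_number`, `mean_con`, `sd_con`, `mean_cwp`,
#'   `sd_cwp`, `quotient`, `alteration`.
#' @export
od_quotients <- function(spots, group, spot_numbers = NULL) {
  raw <- as.matrix(spots)
  group <- as.character(group)
  sel <- if (is.null(spot_numbers)) colnames(raw) else as.character(spot_numbers)
  bad <- setdiff(sel, colnames(raw))
  if (length(bad)) stop_fmt("unknown spot number(s): %s", paste(bad, collapse = ", "))
  m_con <- colMeans(raw[group == "CON", sel, drop = FALSE])
  s_con <- apply(raw[group == "CON", sel, drop = FALSE], 2L, stats::sd)
  m_cwp <- colMeans(raw[group == "CWP", sel, drop = FALSE])
  s_cwp <- apply(raw[group == "CWP", sel, drop = FALSE], 2L, stats::sd)
  quot_raw <- m_cwp / m_con
  if (any(quot_raw == 1)) {
    message(sprintf("%d spot(s) with identical group means; alteration reported as 'up'",
                    sum(quot_raw == 1)))
  }
  data.frame(spot_number = as.integer(sel),
             mean_con = unname(m_con), sd_con = unname(s_con),
             mean_cwp = unname(m_cwp), sd_cwp = unname(s_cwp),
             quotient = unname(round_half_up(quot_raw, 2L)),
             alteration = unname(ifelse(quot_raw >= 1, "up", "down")),
             stringsAsFactors = FALSE)
}

# Assemble the per-spot report from a finished two-step selection; raw-scale
# group statistics always come from the full cohort.
build_report <- function(cohort, twostep, name, group, outcome, settings,
                         screen, excluded) {
  sig <- twostep$significant
  if (length(sig)) {
    vip <- twostep$vip[sig]
    ord <- order(-vip)
    sig <- sig[ord]
    od <- od_quotients(cohort$x, cohort$clinical$group, sig)
    tab <- data.frame(spot_number = od$spot_number,
                      vip = unname(twostep$vip[sig]),
                      pcorr = unname(twostep$pcorr[sig]),
                      od[, c("mean_con", "sd_con", "mean_cwp", "sd_cwp",
                             "quotient", "alteration")],
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(spot_number = integer(0), vip = numeric(0),
                      pcorr = numeric(0), mean_con = numeric(0),
                      sd_con = numeric(0), mean_cwp = numeric(0),
                      sd_cwp = numeric(0), quotient = numeric(0),
                      alteration = character(0), stringsAsFactors = FALSE)
  }
  structure(list(model_name = name, group = group, outcome = outcome,
                 n_samples = length(twostep$stage1$y),
                 significant_spots = tab,
                 r2 = if (twostep$valid) twostep$stage2$r2y else NA_real_,
                 q2 = if (twostep$valid) twostep$stage2$q2 else NA_real_,
                 cvanova_p = if (twostep$valid) twostep$cvanova$p else NA_real_,
                 cvanova_f = if (twostep$valid) twostep$cvanova$f else NA_real_,
                 excluded_spots = excluded, screen = screen,
                 selection = twostep, settings = settings,
                 valid = twostep$valid),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model %s (%s ~ spots, group %s, n = %d)\n", x$model_name,
              x$outcome, x$group, x$n_samples))
  if (x$valid) {
    cat(sprintf("  R2 = %.3f, Q2 = %.3f, CV-ANOVA p = %.4g; %d significant spot(s)\n",
                x$r2, x$q2, x$cvanova_p, nrow(x$significant_spots)))
  } else {
    cat("  no variable passed stage-1 selection; model not valid\n")
  }
  if (nrow(x$excluded_spots)) {
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%d (%s)", x$excluded_spots$spot_number,
                              x$excluded_spots$reason), collapse = ", ")))
  }
  invisible(x)
}

#' Spots significant in both of two models
#'
#' The intersection of the significant spot sets of two model reports —
#' "shared proteoforms" in the 2-DE vocabulary, where the same spot loading
#' on two different outcomes flags a possible confounding relation.
#'
#' @param report_a,report_b `model_report` objects.
#' @return Sorted integer vector of shared spot numbers.
#' @export
shared_spots <- function(report_a, report_b) {
  sort(intersect(report_a$significant_spots$spot_number,
                 report_b$significant_spots$spot_number))
}

#' Recalculate a model after excluding spots shared with confounder models
#'
#' For every confounder report, the spots significant in both the target and
#' the confounder are collected; their union is removed from the target's
#' stage-2 variable set (the stage-1 VIP-selected set) and stage 2 is
#' refitted on the reduced set. The recalculated report records each removed
#' spot with a `shared_with:<model>` reason tag and keeps the original
#' model's statistics under `$previous` so before/after can be compared.
#'
#' @param target a `model_report` to recalculate.
#' @param confounder_reports list of `model_report`s whose significant spots
#'   define the exclusions.
#' @param cohort the cohort both were fitted on.
#' @param settings optional settings list; defaults to the target's own.
#' @return A recalculated `model_report`.
#' @export
compensate_confounders <- function(target, confounder_reports, cohort,
                                   settings = NULL) {
  ch <- as_cohort(cohort)
  settings <- settings %||% target$settings
  if (inherits(confounder_reports, "model_report")) {
    confounder_reports <- list(confounder_reports)
  }
  excl <- data.frame(spot_number = integer(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (cf in confounder_reports) {
    sh <- shared_spots(target, cf)
    if (length(sh)) {
      excl <- rbind(excl, data.frame(spot_number = sh,
                                     reason = paste0("shared_with:", cf$model_name),
                                     stringsAsFactors = FALSE))
    }
  }
  removed <- unique(excl$spot_number)
  old <- list(r2 = target$r2, q2 = target$q2, cvanova_p = target$cvanova_p,
              significant = target$significant_spots$spot_number)
  sel <- target$selection
  vars_new <- setdiff(sel$selected_stage1, as.character(removed))
  if (length(vars_new) == 0L) {
    stop_fmt("confounder exclusion removes every stage-1 variable of model %s",
             target$model_name)
  }
  rows <- if (target$group == "all") seq_len(nrow(ch$x))
          else which(ch$clinical$group == target$group)
  y <- ch$clinical[[target$outcome]][rows]
  x_sub <- unclass(ch$x)[rows, , drop = FALSE]
  st2 <- refit_subset(x_sub, y, vars_new, sel$settings)
  twostep2 <- structure(c(list(stage1 = sel$stage1, vip_stage1 = sel$vip_stage1,
                               ci_stage1 = sel$ci_stage1,
                               selected_stage1 = vars_new,
                               settings = sel$settings),
                          st2, list(valid = TRUE)),
                        class = "opls_twostep")
  out <- build_report(ch, twostep2, name = target$model_name,
                      group = target$group, outcome = target$outcome,
                      settings = settings, screen = target$screen,
                      excluded = excl)
  out$previous <- old
  out
}

#' Univariate two-group comparison with a normality gate
#'
#' Compares a clinical variable or a single spot's IOD between CWP and CON.
#' Normality is assessed per group with the Shapiro-Wilk test at alpha =
#' 0.05; if both groups look normal a two-sample Student's t-test is used,
#' otherwise the non-parametric Mann-Whitney U test.
#'
#' @param cohort a `cohort` or `sim_cohort`.
#' @param variable a clinical column name (`"nrs"`, `"hads_total"`, `"bmi"`,
#'   `"age"`) or a spot number.
#' @return List with `test` (`"t-test"` or `"mann-whitney"`), `statistic`,
#'   `p`, and the per-group Shapiro-Wilk p-values.
#' @export
univariate_group_stats <- function(cohort, variable) {
  ch <- as_cohort(cohort)
  if (is.character(variable) && variable %in% names(ch$clinical)) {
    v <- ch$clinical[[variable]]
  } else {
    key <- as.character(variable)
    if (!key %in% colnames(ch$x)) stop_fmt("unknown variable '%s'", key)
    v <- unclass(ch$x)[, key]
  }
  g <- ch$clinical$group
  if (min(table(g)) < 3L) stop_fmt("both groups need at least 3 samples")
  sw <- vapply(split(v, g), function(vv) {
    if (stats::sd(vv) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(vv)$p.value
  }, numeric(1L))
  if (all(sw > 0.05)) {
    ht <- stats::t.test(v ~ g, var.equal = TRUE)
    list(test = "t-test", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = sw)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(v ~ g))
    list(test = "mann-whitney", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = sw)
  }
}

#' Biological-process distribution of significant spots across models
#'
#' Aggregates the significant spots of a set of model reports by the cohort
#' group each model was fitted in, and tabulates the percentage of entries
#' per biological-process class. Counting is entry-level by default: a spot
#' significant in two models of the same group is counted once per model;
#' `dedupe = TRUE` counts each distinct spot once per group instead. Spots
#' without an annotation entry are counted as `"unknown"`.
#'
#' @param reports list of `model_report`s.
#' @param annotation a [spot_annotation].
#' @param dedupe logical, see above.
#' @return Data frame with one row per biological-process class and one
#'   percentage column per cohort group (whole percents; each column sums to
#'   100 up to rounding).
#' @export
biological_process_distribution <- function(reports, annotation, dedupe = FALSE) {
  if (inherits(reports, "model_report")) reports <- list(reports)
  levs <- biological_process_levels()
  groups <- unique(vapply(reports, function(r) r$group, character(1L)))
  out <- data.frame(biological_process = levs, stringsAsFactors = FALSE)
  for (g in groups) {
    spots <- unlist(lapply(reports[vapply(reports, function(r) r$group == g,
                                          logical(1L))],
                           function(r) r$significant_spots$spot_number))
    if (dedupe) spots <- unique(spots)
    proc <- annotation$biological_process[match(spots, annotation$spot_number)]
    miss <- is.na(proc)
    if (any(miss)) {
      message(sprintf("%d significant spot(s) without annotation counted as 'unknown'",
                      sum(miss)))
    }
    proc <- as.character(proc)
    proc[miss] <- "unknown"
    cnt <- table(factor(proc, levels = levs))
    pct <- if (sum(cnt) > 0) round_half_up(100 * as.numeric(cnt) / sum(cnt), 0L)
           else rep(0, length(levs))
    out[[g]] <- pct
  }
  out
}

#' Run the full multi-model study workflow
#'
#' Fits the standard set of seven outcome models (NRS in CWP; HADS-total,
#' BMI and age in both groups — NRS in controls is constant at 0 and admits
#' no model), then recalculates the patient NRS and HADS models after
#' excluding spots shared with the control-derived age/BMI models and with
#' each other, mirroring the confounder-compensation scheme of this study
#' design. The compensation map is configurable.
#'
#' @param cohort a `cohort` or `sim_cohort`.
#' @param annotation optional [spot_annotation] for the process distribution.
#' @param confounder_map named list mapping a target model name to the
#'   character vector of confounder model names; the default compensates
#'   `NRS_CWP` against `BMI_CON`, `Age_CON` and `HADS_CWP`, and `HADS_CWP`
#'   against `BMI_CON`, `Age_CON` and `NRS_CWP`.
#' @param ... settings forwarded to [run_model()].
#' @return An object of class `study`: `models` (named list of seven
#'   `model_report`s), `compensated` (named list of recalculated reports),
#'   and optionally `process_distribution`.
#' @export
run_study <- function(cohort, annotation = NULL,
                      confounder_map = list(
                        NRS_CWP = c("BMI_CON", "Age_CON", "HADS_CWP"),
                        HADS_CWP = c("BMI_CON", "Age_CON", "NRS_CWP")),
                      ...) {
  ch <- as_cohort(cohort)
  plan <- list(NRS_CWP = c("nrs", "CWP"),
               HADS_CWP = c("hads_total", "CWP"),
               HADS_CON = c("hads_total", "CON"),
               BMI_CWP = c("bmi", "CWP"),
               BMI_CON = c("bmi", "CON"),
               Age_CWP = c("age", "CWP"),
               Age_CON = c("age", "CON"))
  models <- lapply(names(plan), function(nm) {
    run_model(ch, outcome = plan[[nm]][1L], group = plan[[nm]][2L],
              name = nm, ...)
  })
  names(models) <- names(plan)
  compensated <- list()
  for (nm in names(confounder_map)) {
    if (!nm %in% names(models)) stop_fmt("unknown target model '%s'", nm)
    confs <- models[confounder_map[[nm]]]
    compensated[[nm]] <- compensate_confounders(models[[nm]], confs, ch)
  }
  pd <- if (!is.null(annotation)) {
    biological_process_distribution(models, annotation)
  }
  structure(list(models = models, compensated = compensated,
                 process_distribution = pd),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat("study:", length(x$models), "models\n")
  for (m in x$models) {
    cat(sprintf("  %-9s R2 = %.3f Q2 = %.3f p = %.4g  %d significant\n",
                m$model_name, m$r2, m$q2, m$cvanova_p,
                nrow(m$significant_spots)))
  }
  if (length(x$compensated)) {
    cat("compensated:\n")
    for (m in x$compensated) {
      cat(sprintf("  %-9s R2 = %.3f Q2 = %.3f p = %.4g  %d significant, %d excluded\n",
                  m$model_name, m$r2, m$q2, m$cvanova_p,
                  nrow(m$significant_spots), length(unique(m$excluded_spots$spot_number))))
    }
  }
  invisible(x)
}

#' Serialize a model report to text lines
#'
#' Full-precision textual form of a report (statistics, selections,
#' exclusions); two runs of the same deterministic workflow produce
#' byte-identical serializations.
#'
#' @param x a `model_report` (or a `study` for [format.study()]).
#' @param ... unused.
#' @export
format.model_report <- function(x, ...) {
  num <- function(v) sprintf("%.12g", v)
  lines <- c(sprintf("model: %s", x$model_name),
             sprintf("group: %s", x$group),
             sprintf("outcome: %s", x$outcome),
             sprintf("n_samples: %d", x$n_samples),
             sprintf("r2: %s", num(x$r2)),
             sprintf("q2: %s", num(x$q2)),
             sprintf("cvanova_f: %s", num(x$cvanova_f)),
             sprintf("cvanova_p: %s", num(x$cvanova_p)),
             sprintf("n_stage1_selected: %d", length(x$selection$selected_stage1)),
             sprintf("n_significant: %d", nrow(x$significant_spots)))
  if (nrow(x$significant_spots)) {
    s <- x$significant_spots
    lines <- c(lines, sprintf("spot %d vip=%s pcorr=%s quot=%.2f %s",
                              s$spot_number, num(s$vip), num(s$pcorr),
                              s$quotient, s$alteration))
  }
  if (nrow(x$excluded_spots)) {
    lines <- c(lines, sprintf("excluded %d %s", x$excluded_spots$spot_number,
                              x$excluded_spots$reason))
  }
  lines
}

#' @rdname format.model_report
#' @export
format.study <- function(x, ...) {
  unlist(c(lapply(x$models, format), lapply(x$compensated, format)))
}

#' Write a model report table as delimited text
#'
#' One row per significant spot, sorted by descending VIP, with the
#' annotation columns, VIP, p(corr), raw group means and SDs, the OD
#' quotient printed to two decimals, and the alteration direction. Spots
#' without an annotation entry get an `"unidentified"` placeholder (logged
#' via [message()]).
#'
#' @param report a `model_report`.
#' @param annotation a [spot_annotation] (may be empty).
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return The path, invisibly.
#' @export
write_model_report <- function(report, annotation, path, dialect = c("tsv", "csv")) {
  s <- report$significant_spots
  idx <- match(s$spot_number, annotation$spot_number)
  if (anyNA(idx) && nrow(s)) {
    message(sprintf("model %s: %d spot(s) without annotation reported as 'unidentified'",
                    report$model_name, sum(is.na(idx))))
  }
  pick <- function(col, default) {
    out <- rep(default, nrow(s))
    ok <- !is.na(idx)
    out[ok] <- as.character(annotation[[col]][idx[ok]])
    out
  }
  df <- data.frame(
    spot_number = s$spot_number,
    protein_name = pick("protein_name", "unidentified"),
    accession = pick("accession", ""),
    biological_process = pick("biological_process", "unknown"),
    mw_kda = pick("mw_kda", ""),
    pi = pick("pi", ""),
    vip = sprintf("%.2f", s$vip),
    pcorr = sprintf("%.2f", s$pcorr),
    od_con_mean = sprintf("%.6g", s$mean_con),
    od_con_sd = sprintf("%.6g", s$sd_con),
    od_cwp_mean = sprintf("%.6g", s$mean_cwp),
    od_cwp_sd = sprintf("%.6g", s$sd_cwp),
    od_quotient = sprintf("%.2f", s$quotient),
    alteration = s$alteration,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(dialect), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write model-level statistics as key-value text
#'
#' @param report a `model_report` or `study`.
#' @param path output path.
#' @export
write_model_summary <- function(report, path) {
  writeLines(format(report), path)
  invisible(path)
}
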