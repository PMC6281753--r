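test_that("the patient pain-intensity model recovers the planted spots", {
  co <- simulate_cohort(sim_config(seed = 2))
  rep <- suppressWarnings(run_model(co, outcome = "nrs", group = "CWP"))
  expect_s3_class(rep, "model_report")
  expect_true(rep$valid)
  sig <- rep$significant_spots$spot_number
  sens <- length(intersect(sig, co$truth$nrs)) / length(co$truth$nrs)
  expect_gte(sens, 0.8)
  expect_lte(rep$cvanova_p, 0.05)
  # report sorted by descending VIP, quotients rounded to 2 decimals
  expect_true(all(diff(rep$significant_spots$vip) <= 0))
  expect_equal(rep$significant_spots$quotient,
               round(rep$significant_spots$quotient, 2))
})

test_that("a constant outcome is refused with a clear message", {
  co <- simulate_cohort(sim_config(seed = 2))
  expect_error(run_model(co, outcome = "nrs", group = "CON"),
               "constant within group 'CON'")
})

test_that("duplicating one group leaves stage-1 selection unchanged", {
  co <- simulate_cohort(sim_config(n_con = 10, n_cwp = 10, n_spots = 60,
                                   n_informative_per_outcome = 8, seed = 5))
  x <- unclass(co$spots)
  cwp_rows <- which(co$clinical$group == "CWP")
  dup <- spot_table(rbind(x[cwp_rows, ], x[cwp_rows, ]),
                    sample_ids = c(sprintf("CON%02d", seq_along(cwp_rows)),
                                   sprintf("CWP%02d", seq_along(cwp_rows))),
                    spot_numbers = colnames(x))
  cl <- co$clinical[rep(cwp_rows, 2), ]
  cl$sample_id <- rownames(dup)
  cl$group <- factor(rep(c("CON", "CWP"), each = length(cwp_rows)),
                     levels = c("CON", "CWP"))
  dup_cl <- clinical_table(cl$sample_id, cl$group, cl$nrs, cl$hads_total,
                           cl$bmi, cl$age)
  both <- join_cohort(dup, dup_cl)
  r_all <- suppressWarnings(run_model(both, "bmi", "all"))
  r_cwp <- suppressWarnings(run_model(both, "bmi", "CWP"))
  expect_setequal(r_all$selection$selected_stage1,
                  r_cwp$selection$selected_stage1)
})

test_that("shared spots are the intersection of significant sets", {
  a <- stub_report("A", c(2116, 2903, 4316, 4809, 510))
  b <- stub_report("B", c(2116, 2903, 4316, 4809))
  expect_identical(shared_spots(a, b), c(2116L, 2903L, 4316L, 4809L))
  expect_identical(shared_spots(stub_report("C", 1:3), stub_report("D", 7:9)),
                   integer(0))
  expect_identical(shared_spots(a, a), sort(c(2116L, 2903L, 4316L, 4809L, 510L)))
})

test_that("confounder compensation removes exactly the shared spots", {
  co <- simulate_cohort(sim_config(seed = 2))
  target <- suppressWarnings(run_model(co, "nrs", "CWP"))
  sig <- target$significant_spots$spot_number
  planted <- sig[seq_len(min(4L, length(sig)))]
  conf <- stub_report("BMI_CON", planted)
  recal <- suppressWarnings(compensate_confounders(target, list(conf), co))
  expect_setequal(recal$excluded_spots$spot_number, planted)
  expect_true(all(recal$excluded_spots$reason == "shared_with:BMI_CON"))
  expect_false(any(planted %in% recal$significant_spots$spot_number))
  # never adds spots: subset of original stage-1 selection minus removals
  expect_true(all(recal$significant_spots$spot_number %in%
                    setdiff(as.integer(target$selection$selected_stage1), planted)))
  expect_identical(recal$previous$r2, target$r2)
})

test_that("compensation with no shared spots is a bitwise no-op", {
  co <- simulate_cohort(sim_config(seed = 2))
  target <- suppressWarnings(run_model(co, "nrs", "CWP"))
  conf <- stub_report("Age_CON", setdiff(1:50, target$significant_spots$spot_number))
  recal <- suppressWarnings(compensate_confounders(target, list(conf), co))
  expect_identical(format(recal), format(target))
})

test_that("removing noise spots barely moves Q2", {
  co <- simulate_cohort(sim_config(seed = 2))
  target <- suppressWarnings(run_model(co, "nrs", "CWP"))
  false_pos <- setdiff(target$significant_spots$spot_number, co$truth$nrs)
  expect_gt(length(false_pos), 0)
  conf <- stub_report("X", false_pos)
  recal <- suppressWarnings(compensate_confounders(target, list(conf), co))
  expect_lt(abs(recal$q2 - target$q2), 0.1)
})

test_that("univariate comparison gates on normality and detects shifts", {
  ids <- sprintf("s%02d", 1:40)
  grp <- rep(c("CON", "CWP"), each = 20)
  st <- spot_table(matrix(rexp(80, 1e-3), 40, 2), ids, c(11, 12))
  mk <- function(v) {
    cl <- clinical_table(ids, grp, nrs = ifelse(grp == "CWP", 5, 0),
                         hads_total = pmin(pmax(round(v), 0), 42),
                         bmi = pmax(v, 15), age = pmax(round(v + 40), 20))
    join_cohort(st, cl)
  }
  set.seed(102)
  shifted <- mk(c(rnorm(20, 20, 1), rnorm(20, 23, 1)))
  res <- univariate_group_stats(shifted, "bmi")
  expect_identical(res$test, "t-test")
  expect_lt(res$p, 0.001)

  same <- mk(rep(c(rnorm(20, 20, 1)), 2))
  res0 <- univariate_group_stats(same, "bmi")
  expect_gt(res0$p, 0.99)

  set.seed(103)
  skewed <- mk(16 + rexp(40, 1 / 4))
  ress <- univariate_group_stats(skewed, "bmi")
  expect_identical(ress$test, "mann-whitney")
})

test_that("biological-process percentages follow the counting convention", {
  ann <- spot_annotation(1:10, paste0("p", 1:10), paste0("P", 1:10),
                         c(rep("metabolic", 4), rep("immunity", 6)),
                         mw_kda = 1:10, pi = rep(5, 10))
  r1 <- stub_report("M1", 1:10, group = "CWP")
  pd <- biological_process_distribution(list(r1), ann)
  expect_equal(pd$CWP[pd$biological_process == "metabolic"], 40)
  expect_equal(sum(pd$CWP), 100)

  r_all_one <- stub_report("M2", 1:4, group = "CON")
  pd2 <- biological_process_distribution(list(r_all_one), ann)
  expect_equal(pd2$CON[pd2$biological_process == "metabolic"], 100)

  # entry-level counting: a spot shared by two models counts once per model
  rA <- stub_report("A", c(1, 5), group = "CWP")
  rB <- stub_report("B", c(1, 6), group = "CWP")
  pd3 <- biological_process_distribution(list(rA, rB), ann)
  expect_equal(pd3$CWP[pd3$biological_process == "metabolic"], 50)
  pd4 <- biological_process_distribution(list(rA, rB), ann, dedupe = TRUE)
  expect_equal(pd4$CWP[pd4$biological_process == "metabolic"],
               round(100 / 3))
})

test_that("the seven-model study runs end to end with compensation", {
  co <- simulate_cohort(sim_config(seed = 2))
  st <- suppressWarnings(run_study(co))
  expect_named(st$models, c("NRS_CWP", "HADS_CWP", "HADS_CON", "BMI_CWP",
                            "BMI_CON", "Age_CWP", "Age_CON"))
  expect_true(all(vapply(st$models, function(m) m$valid, logical(1))))
  expect_named(st$compensated, c("NRS_CWP", "HADS_CWP"))
  for (nm in names(st$compensated)) {
    cm <- st$compensated[[nm]]
    expect_true(all(cm$significant_spots$spot_number %in%
                      as.integer(st$models[[nm]]$selection$selected_stage1)))
    expect_false(any(cm$excluded_spots$spot_number %in%
                       cm$significant_spots$spot_number))
  }
})
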