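test_that("spot table construction validates and preserves values", {
  st <- spot_table(matrix(c(430, 570, 745, 763), 2, 2),
                   sample_ids = c("s1", "s2"), spot_numbers = c(8822, 9901))
  expect_identical(dim(st), c(2L, 2L))
  expect_identical(unname(unclass(st)[, "8822"]), c(430, 570))
  expect_error(spot_table(matrix(-1, 1, 1), "s1", 10), "negative IOD")
  expect_error(spot_table(matrix(1:4, 2, 2), c("a", "a"), c(1, 2)), "duplicate sample")
  expect_error(spot_table(matrix(1:4, 2, 2), c("a", "b"), c(7, 7)), "duplicate spot")
  expect_error(spot_table(matrix(NA_real_, 1, 1), "a", 1), "missing")
})

test_that("spot tables round-trip through delimited text bit-exactly", {
  st <- spot_table(matrix(c(430, 745, 570, 763), 2, 2, byrow = TRUE),
                   sample_ids = c("g1", "g2"), spot_numbers = c(8822, 9901))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(st, path)
  back <- read_spot_table(path)
  expect_identical(unclass(back), unclass(st))

  set.seed(5)
  dec <- spot_table(matrix(round(rexp(12, 1e-3), 4), 3, 4),
                    sample_ids = paste0("s", 1:3), spot_numbers = c(11, 12, 13, 14))
  write_spot_table(dec, path, dialect = "csv")
  expect_equal(unclass(read_spot_table(path, dialect = "csv")), unclass(dec),
               tolerance = 1e-12)
})

test_that("reader reports malformed input with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\t10\t10", "s1\t1\t2"), path)
  expect_error(read_spot_table(path), "duplicated spot column header: 10")
  writeLines(c("id\t10\t11", "s1\t1\tabc"), path)
  expect_error(read_spot_table(path), "non-numeric IOD value 'abc' at data row 1, spot column 11")
  writeLines(c("id\t10\t11", "s1\t1\t-4"), path)
  expect_error(read_spot_table(path), "negative IOD value at data row 1")
  writeLines("id\t10\t11", path)
  empty <- read_spot_table(path)
  expect_identical(nrow(empty), 0L)
  expect_identical(colnames(empty), c("10", "11"))
})

test_that("clinical and annotation tables validate ranges and vocabulary", {
  expect_error(clinical_table("a", "CWP", nrs = 11, hads_total = 1, bmi = 20, age = 30),
               "nrs")
  expect_error(clinical_table("a", "CWP", nrs = 1, hads_total = 50, bmi = 20, age = 30),
               "hads_total")
  expect_error(clinical_table("a", "PATIENT", nrs = 1, hads_total = 1, bmi = 20, age = 30),
               "group")
  expect_error(spot_annotation(1, "p", "P1", "cosmic rays", 10, 5), "biological process")
  ann <- spot_annotation(c(8822, 9901), c("Plasminogen", "Plasminogen"),
                         c("P00747", "P00747"), c("metabolic", "metabolic"),
                         c(143, 143), c(6.91, 7.11))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_spot_annotation(path)$accession, ann$accession)
})

test_that("join_cohort aligns by sample ID and is permutation invariant", {
  set.seed(1)
  ids <- sprintf("P%02d", 1:6)
  st <- spot_table(matrix(rexp(18, 1e-3), 6, 3), ids, c(101, 102, 103))
  cl <- clinical_table(ids, rep(c("CON", "CWP"), 3), nrs = c(0, 3, 0, 5, 0, 7),
                       hads_total = 1:6, bmi = 20 + 1:6, age = 30 + 1:6)
  shuffle <- sample(6)
  st2 <- spot_table(unclass(st)[shuffle, ])
  cl2 <- cl[rev(seq_len(6)), ]
  a <- join_cohort(st, cl)
  b <- join_cohort(st2, cl2)
  expect_identical(unclass(a$x), unclass(b$x))
  expect_identical(a$clinical, b$clinical)
  expect_identical(unclass(a$x)["P03", ], unclass(st)["P03", ])
  expect_error(join_cohort(st, cl[-2, ]), "P02")
})

test_that("default synthetic cohort joins with the study's group sizes", {
  co <- simulate_cohort()
  ch <- join_cohort(co$spots, co$clinical)
  tab <- table(ch$clinical$group)
  expect_identical(as.integer(tab[["CON"]]), 23L)
  expect_identical(as.integer(tab[["CWP"]]), 15L)
  expect_identical(ncol(ch$x), 325L)
})

test_that("report writer prints quotients to 2 decimals sorted by VIP with placeholders", {
  rep <- structure(list(
    model_name = "demo",
    significant_spots = data.frame(
      spot_number = c(510L, 8822L, 77L),
      vip = c(1.4, 1.15, 1.1), pcorr = c(0.5, 0.55, -0.2),
      mean_con = c(440, 430, 100), sd_con = c(560, 292, 10),
      mean_cwp = c(854, 745, 100), sd_cwp = c(725, 337, 12),
      quotient = c(1.94, 1.73, 1.00),
      alteration = c("up", "up", "up"), stringsAsFactors = FALSE),
    excluded_spots = data.frame()), class = "model_report")
  ann <- spot_annotation(8822, "Plasminogen", "P00747", "metabolic", 143, 6.91)
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_message(write_model_report(rep, ann, path), "unidentified")
  out <- utils::read.delim(path, colClasses = "character")
  expect_identical(out$od_quotient, c("1.94", "1.73", "1.00"))
  expect_identical(out$protein_name, c("unidentified", "Plasminogen", "unidentified"))
  expect_true(all(diff(as.numeric(out$vip)) <= 0))
})
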