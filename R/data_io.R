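#' Construct a spot-intensity table
#'
#' A `spot_table` holds the X block of the analysis: one row per sample, one
#' column per matched 2-DE spot, cell values being the background-corrected
#' integrated optical density (IOD) of the spot in that sample's gel. IOD is
#' dimensionless and non-negative (a spot absent from a gel quantifies as 0).
#'
#' @param values numeric matrix of IOD values, samples in rows.
#' @param sample_ids character vector of unique sample identifiers, one per row.
#' @param spot_numbers integer vector of unique positive spot labels, one per
#'   column. Spot numbers are opaque labels assigned by the gel-matching
#'   software; no ordering semantics are attached to them.
#' @return An object of class `spot_table`: the value matrix with sample IDs as
#'   row names and spot numbers as column names.
#' @export
spot_table <- function(values, sample_ids = rownames(values),
                       spot_numbers = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !(nrow(values) == 0L || ncol(values) == 0L)) {
    stop_fmt("spot table values must be numeric")
  }
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  spot_numbers <- as.integer(spot_numbers)
  if (length(sample_ids) != nrow(values)) {
    stop_fmt("%d sample ids for %d rows", length(sample_ids), nrow(values))
  }
  if (length(spot_numbers) != ncol(values)) {
    stop_fmt("%d spot numbers for %d columns", length(spot_numbers), ncol(values))
  }
  if (anyDuplicated(sample_ids)) {
    stop_fmt("duplicate sample id(s): %s",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(spot_numbers)) {
    stop_fmt("duplicate spot number(s): %s",
             paste(unique(spot_numbers[duplicated(spot_numbers)]), collapse = ", "))
  }
  if (anyNA(spot_numbers) || any(spot_numbers <= 0L)) {
    stop_fmt("spot numbers must be positive integers")
  }
  if (anyNA(values)) stop_fmt("spot table contains missing IOD values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_fmt("negative IOD at sample '%s', spot %d",
             sample_ids[bad[1L]], spot_numbers[bad[2L]])
  }
  dimnames(values) <- list(sample_ids, as.character(spot_numbers))
  structure(values, class = c("spot_table", "matrix", "array"))
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d samples x %d spots (IOD)\n", nrow(x), ncol(x)))
  if (nrow(x) > 0L && ncol(x) > 0L) {
    print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
    if (nrow(x) > 5L || ncol(x) > 6L) cat("...\n")
  }
  invisible(x)
}

spot_numbers <- function(x) as.integer(colnames(x))

#' Construct a clinical table
#'
#' Per-sample group membership and outcome variables: the Y block candidates.
#' `nrs` is pain intensity on the 11-grade numeric rating scale (0 = no pain,
#' 10 = worst possible pain); `hads_total` is the Hospital Anxiety and
#' Depression Scale total score (anxiety + depression subscales, 0-42), used as
#' a psychological-distress index; `bmi` in kg/m^2; `age` in years.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param group factor or character, one of `"CWP"` (chronic widespread pain
#'   patient) or `"CON"` (healthy control) per sample.
#' @param nrs,hads_total,bmi,age numeric outcome vectors.
#' @return A `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(sample_ids, group, nrs, hads_total, bmi, age) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop_fmt("duplicate sample id(s): %s",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  group <- as.character(group)
  if (!all(group %in% c("CWP", "CON"))) {
    stop_fmt("group labels must be 'CWP' or 'CON'")
  }
  n <- length(sample_ids)
  for (v in list(group = group, nrs = nrs, hads_total = hads_total,
                 bmi = bmi, age = age)) {
    if (length(v) != n) stop_fmt("all clinical columns must have length %d", n)
  }
  if (anyNA(nrs) || any(nrs < 0 | nrs > 10)) stop_fmt("nrs must lie in [0, 10]")
  if (anyNA(hads_total) || any(hads_total < 0 | hads_total > 42)) {
    stop_fmt("hads_total must lie in [0, 42]")
  }
  if (anyNA(bmi) || any(bmi <= 0)) stop_fmt("bmi must be positive")
  if (anyNA(age) || any(age <= 0)) stop_fmt("age must be positive")
  out <- data.frame(sample_id = sample_ids,
                    group = factor(group, levels = c("CON", "CWP")),
                    nrs = as.numeric(nrs),
                    hads_total = as.numeric(hads_total),
                    bmi = as.numeric(bmi),
                    age = as.numeric(age),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Construct a spot annotation table
#'
#' Spot-level metadata linking a spot number to the identified protein, its
#' UniProt accession, the biological-process class assigned from the UniProt
#' definition, and the experimental molecular weight (kDa) and isoelectric
#' point read off the gel.
#'
#' @param spot_number integer vector of unique positive spot labels.
#' @param protein_name,accession character vectors.
#' @param biological_process character; one of `"metabolic"`, `"immunity"`,
#'   `"iron ion homeostasis"`, `"inflammatory"`, `"lipid metabolism"`,
#'   `"unknown"`.
#' @param mw_kda,pi numeric experimental MW and pI.
#' @return A `data.frame` of class `spot_annotation`.
#' @export
spot_annotation <- function(spot_number, protein_name, accession,
                            biological_process, mw_kda, pi) {
  spot_number <- as.integer(spot_number)
  if (anyDuplicated(spot_number)) stop_fmt("duplicate spot number in annotation")
  biological_process <- as.character(biological_process)
  bad <- setdiff(unique(biological_process), biological_process_levels())
  if (length(bad)) {
    stop_fmt("unknown biological process class(es): %s", paste(bad, collapse = ", "))
  }
  out <- data.frame(spot_number = spot_number,
                    protein_name = as.character(protein_name),
                    accession = as.character(accession),
                    biological_process = factor(biological_process,
                                                levels = biological_process_levels()),
                    mw_kda = as.numeric(mw_kda),
                    pi = as.numeric(pi),
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_annotation", "data.frame")
  out
}

#' @rdname spot_annotation
#' @export
biological_process_levels <- function() {
  c("metabolic", "immunity", "iron ion homeostasis", "inflammatory",
    "lipid metabolism", "unknown")
}

delim_for <- function(dialect = c("tsv", "csv")) {
  switch(match.arg(dialect), tsv = "\t", csv = ",")
}

#' Read a spot-intensity table from delimited text
#'
#' Expects a header row of spot numbers and one row per sample whose first
#' field is the sample ID, remaining fields the IOD values.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [spot_table].
#' @export
read_spot_table <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  sep <- delim_for(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 1L) stop_fmt("%s: no columns", path)
  ids <- raw[[1L]]
  spot_cols <- names(raw)[-1L]
  spots <- suppressWarnings(as.integer(spot_cols))
  if (anyNA(spots)) {
    stop_fmt("%s: non-integer spot number in header: %s", path,
             paste(spot_cols[is.na(spots)], collapse = ", "))
  }
  if (anyDuplicated(spots)) {
    stop_fmt("%s: duplicated spot column header: %s", path,
             paste(unique(spots[duplicated(spots)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(spots))
  for (j in seq_along(spots)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      stop_fmt("%s: non-numeric IOD value '%s' at data row %d, spot column %d",
               path, col[i], i, spots[j])
    }
    if (any(num < 0)) {
      i <- which(num < 0)[1L]
      stop_fmt("%s: negative IOD value at data row %d, spot column %d",
               path, i, spots[j])
    }
    vals[, j] <- num
  }
  spot_table(vals, sample_ids = ids, spot_numbers = spots)
}

#' Write a spot-intensity table as delimited text
#'
#' Values are written with [format()] at full precision so that integer IODs
#' round-trip bit-exactly.
#'
#' @param x a [spot_table].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_spot_table <- function(x, path, dialect = c("tsv", "csv")) {
  sep <- delim_for(dialect)
  df <- data.frame(sample_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical table from delimited text
#'
#' Columns required: `sample_id`, `group`, `nrs`, `hads_total`, `bmi`, `age`.
#'
#' @inheritParams read_spot_table
#' @return A [clinical_table].
#' @export
read_clinical_table <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim_for(dialect),
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "nrs", "hads_total", "bmi", "age")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_fmt("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  clinical_table(raw$sample_id, raw$group, raw$nrs, raw$hads_total, raw$bmi, raw$age)
}

#' @rdname read_clinical_table
#' @param x a [clinical_table].
#' @export
write_clinical_table <- function(x, path, dialect = c("tsv", "csv")) {
  utils::write.table(as.data.frame(x), path, sep = delim_for(dialect),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spot annotation table from delimited text
#'
#' Columns required: `spot_number`, `protein_name`, `accession`,
#' `biological_process`, `mw_kda`, `pi`.
#'
#' @inheritParams read_spot_table
#' @return A [spot_annotation].
#' @export
read_spot_annotation <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim_for(dialect),
                           stringsAsFactors = FALSE)
  need <- c("spot_number", "protein_name", "accession", "biological_process",
            "mw_kda", "pi")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_fmt("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  spot_annotation(raw$spot_number, raw$protein_name, raw$accession,
                  raw$biological_process, raw$mw_kda, raw$pi)
}

#' Join a spot table and a clinical table into an analysis cohort
#'
#' Requires the two sample ID sets to be equal; rows of both blocks are
#' aligned and sorted lexicographically by sample ID, so every downstream
#' procedure (cross-validation fold assignment in particular) sees a
#' deterministic sample order regardless of input file ordering.
#'
#' @param spots a [spot_table].
#' @param clinical a [clinical_table].
#' @return An object of class `cohort`: a list with elements `x` (the aligned
#'   spot table), `clinical` (the aligned clinical table) and `sample_ids`.
#' @export
join_cohort <- function(spots, clinical) {
  sid_x <- rownames(spots)
  sid_c <- clinical$sample_id
  only_x <- setdiff(sid_x, sid_c)
  only_c <- setdiff(sid_c, sid_x)
  if (length(only_x) || length(only_c)) {
    stop_fmt("sample ID mismatch; only in spot table: {%s}; only in clinical: {%s}",
             paste(only_x, collapse = ", "), paste(only_c, collapse = ", "))
  }
  ord <- order_ids(sid_x)
  x <- spot_table(unclass(spots)[ord, , drop = FALSE])
  cl <- clinical[match(rownames(x), clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(x = x, clinical = cl, sample_ids = rownames(x)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$clinical$group)
  cat(sprintf("cohort: %d samples (%s), %d spots\n", nrow(x$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              ncol(x$x)))
  invisible(x)
}
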