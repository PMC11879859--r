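# Data model and table I/O. A trial dataset is a plain data.frame in a
# documented column schema; validation is centralised here so every reader
# and generator enforces the same invariants. Missing week-12 measurements
# (discontinued participants) are empty CSV cells / NA in R, never sentinels.

#' Trial table column schema
#'
#' Column names, in their stable on-disk order, of a participant table:
#' identity (`participant_id`, `arm`, `completed`, `age`), baseline and
#' week-12 clinical measurements (`*_glucose` mmol/l, `*_insulin` mIE/l,
#' `*_c_peptide` nmol/l, `*_hba1c` mmol/mol, `*_bmi` kg/m^2, `*_waist` cm,
#' `*_triglycerides` mmol/l, `*_ggt` ukat/l, `*_weight` kg plus baseline
#' `baseline_height` cm) and post-treatment `serum_sulforaphane` nmol/ml
#' (optional).
#'
#' @return Character vector of column names.
#' @export
trial_schema <- function() {
  vars <- c("glucose", "insulin", "c_peptide", "hba1c", "bmi", "waist",
            "triglycerides", "ggt", "weight")
  c("participant_id", "arm", "completed", "age",
    paste0("baseline_", c(vars, "height")),
    paste0("week12_", vars),
    "serum_sulforaphane")
}

#' Validate a trial dataset against the schema and invariants
#'
#' Checks: all schema columns present; `participant_id` unique; `arm` in
#' BSE/placebo; positive glucose and BMI wherever present; week-12 fields may
#' be missing only for participants with `completed = FALSE`. Violations
#' raise errors with row-level diagnostics.
#'
#' @param dataset A data.frame in the [trial_schema()] layout.
#' @return The dataset, invisibly, if valid.
#' @export
validate_trial_dataset <- function(dataset) {
  missing_cols <- setdiff(trial_schema(), names(dataset))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(dataset$participant_id)) {
    dup <- unique(dataset$participant_id[duplicated(dataset$participant_id)])
    stop("duplicated participant_id: ", paste(dup, collapse = ", "))
  }
  bad_arm <- !dataset$arm %in% c("BSE", "placebo")
  if (any(bad_arm))
    stop("invalid arm label in row(s): ",
         paste(which(bad_arm), collapse = ", "))
  check_pos <- function(col) {
    v <- dataset[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("non-positive ", col, " in row(s): ",
           paste(which(bad), collapse = ", "))
  }
  check_pos("baseline_glucose")
  check_pos("baseline_bmi")
  check_pos("week12_glucose")
  check_pos("week12_bmi")
  wk <- grep("^week12_", trial_schema(), value = TRUE)
  incomplete_wk <- rowSums(is.na(dataset[, wk, drop = FALSE])) > 0
  bad <- incomplete_wk & dataset$completed
  if (any(bad))
    stop("week-12 fields missing for completed participant(s), row(s): ",
         paste(which(bad), collapse = ", "))
  invisible(dataset)
}

#' Read a participant table
#'
#' Reads a CSV or TSV participant table in the [trial_schema()] layout,
#' coerces numeric columns (reporting the row index of any non-numeric
#' value), and validates all dataset invariants.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A validated data.frame.
#' @export
read_trial_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", check.names = FALSE,
                         na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_schema(), names(d))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  d <- d[, trial_schema(), drop = FALSE]
  num_cols <- setdiff(trial_schema(), c("participant_id", "arm", "completed"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "', row(s): ",
           paste(bad, collapse = ", "))
    d[[col]] <- v
  }
  d$completed <- as.logical(d$completed)
  validate_trial_dataset(d)
  d
}

#' Write a participant table
#'
#' Writes a validated dataset as CSV (or TSV) in the stable [trial_schema()]
#' column order. Numeric values are serialized with 17 significant digits so
#' that reading the file back reproduces every double exactly; missing values
#' become empty cells.
#'
#' @param dataset A data.frame in the [trial_schema()] layout.
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(dataset, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_trial_dataset(dataset)
  d <- dataset[, trial_schema(), drop = FALSE]
  num_cols <- setdiff(trial_schema(), c("participant_id", "arm", "completed"))
  for (col in num_cols) {
    v <- d[[col]]
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    d[[col]] <- out
  }
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a feature-by-sample abundance table
#'
#' Reads a TSV abundance table with features as rows (first column the
#' feature id) and samples as columns, returning the transposed
#' samples-by-features numeric matrix used throughout the package.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, samples x features.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  feats <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  m <- t(m)
  colnames(m) <- feats
  m
}

#' Write a feature-by-sample abundance table
#'
#' @param table Numeric matrix, samples x features.
#' @param path Output TSV path (features as rows, first column `feature_id`).
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  m <- t(as.matrix(table))
  d <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
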