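# Required numeric vitals and the bounds their invariants impose.
.required_cols <- c("age", "sex", "heart_rate", "sbp", "scr")
.flag_cols <- c("death", "stroke", "acute_heart_failure", "dialysis", "tvr",
                "ci_aki", "bleeding", "death_1y")
.optional_num_cols <- c("weight", "followup_days")

#' Default column-name mapping for cohort files
#'
#' Maps internal field names to the column headers expected in a delimited
#' cohort file. Override individual entries to read files with other headers,
#' e.g. `cohort_schema(sbp = "systolic_bp")`.
#'
#' @param ... named character overrides, `internal_name = "file column"`.
#' @return named character vector mapping internal names to file columns.
#' @export
cohort_schema <- function(...) {
  schema <- c(
    patient_id = "patient_id", age = "age", sex = "sex", weight = "weight",
    heart_rate = "heart_rate", sbp = "sbp", scr = "scr",
    death = "death", stroke = "stroke",
    acute_heart_failure = "acute_heart_failure", dialysis = "dialysis",
    tvr = "tvr", ci_aki = "ci_aki", bleeding = "bleeding",
    followup_days = "followup_days", death_1y = "death_1y",
    cohort_label = "cohort_label"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad))
      stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

# Parse a flag column accepting {0,1,true,false,yes,no} case-insensitively;
# empty cells and NA become NA (absent).
.parse_flag <- function(x, col) {
  x_chr <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true", "yes")] <- TRUE
  out[x_chr %in% c("0", "false", "no")] <- FALSE
  bad <- !is.na(x_chr) & x_chr != "" & is.na(out)
  if (any(bad))
    stop(sprintf("column '%s': unparseable flag value '%s' at row %d",
                 col, x_chr[which(bad)[1]], which(bad)[1]))
  out
}

.parse_num <- function(x, col) {
  x_chr <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- !is.na(x_chr) & x_chr != "" & is.na(out)
  if (any(bad))
    stop(sprintf("column '%s': unparseable numeric '%s' at row %d",
                 col, x_chr[which(bad)[1]], which(bad)[1]))
  out
}

#' Validate a cohort data frame
#'
#' Checks the record-level invariants: positive vitals and creatinine,
#' age in [18, 120), positive weight when present, non-negative follow-up,
#' follow-up present wherever the 1-year death indicator is, unique patient
#' ids, and a non-empty cohort.
#'
#' @param cohort a cohort data frame as returned by [read_cohort()].
#' @return the cohort, invisibly, if valid; otherwise an error naming the
#'   offending row and field.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data frame")
  miss <- setdiff(.required_cols, names(cohort))
  if (length(miss))
    stop("cohort lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id: ",
         cohort$patient_id[anyDuplicated(cohort$patient_id)])
  if (!all(cohort$sex %in% c("male", "female")))
    stop(sprintf("row %d: sex must be 'male' or 'female'",
                 which(!cohort$sex %in% c("male", "female"))[1]))
  .check_range <- function(col, ok, what) {
    v <- cohort[[col]]
    bad <- !is.na(v) & !ok(v)
    if (any(bad))
      stop(sprintf("row %d: field '%s' %s (value %g)",
                   which(bad)[1], col, what, v[which(bad)[1]]))
    if (col %in% .required_cols && anyNA(v))
      stop(sprintf("row %d: required field '%s' is missing",
                   which(is.na(v))[1], col))
  }
  .check_range("heart_rate", function(v) v > 0, "must be > 0")
  .check_range("sbp", function(v) v > 0, "must be > 0")
  .check_range("scr", function(v) v > 0, "must be > 0")
  .check_range("age", function(v) v >= 18 & v < 120, "must be in [18, 120)")
  if ("weight" %in% names(cohort))
    .check_range("weight", function(v) v > 0, "must be > 0 when present")
  if ("followup_days" %in% names(cohort))
    .check_range("followup_days", function(v) v >= 0, "must be >= 0")
  if ("death_1y" %in% names(cohort) && "followup_days" %in% names(cohort)) {
    bad <- !is.na(cohort$death_1y) & is.na(cohort$followup_days)
    if (any(bad))
      stop(sprintf("row %d: death_1y present without followup_days",
                   which(bad)[1]))
  }
  invisible(cohort)
}

#' Read a delimited cohort file
#'
#' Reads a comma- (default) or tab-delimited UTF-8 file with a header row into
#' a validated cohort data frame, one row per patient admission. Flags are
#' accepted as 0/1, true/false, or yes/no (case-insensitive); empty cells in
#' optional columns become `NA` (explicitly absent, never imputed).
#'
#' @param path file path.
#' @param schema column mapping from [cohort_schema()].
#' @param sep field separator, `","` or `"\t"`.
#' @return a `data.frame` of class `sic_cohort` with canonical column names.
#' @export
read_cohort <- function(path, schema = cohort_schema(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(schema[.required_cols], names(raw))
  if (length(miss))
    stop("schema error: required column(s) missing from file: ",
         paste(miss, collapse = ", "))
  out <- list()
  n <- nrow(raw)
  for (field in names(schema)) {
    col <- schema[[field]]
    if (!col %in% names(raw)) next
    v <- raw[[col]]
    out[[field]] <- if (field %in% c("age", "heart_rate", "sbp", "scr",
                                     .optional_num_cols)) {
      .parse_num(v, col)
    } else if (field %in% .flag_cols) {
      .parse_flag(v, col)
    } else if (field == "sex") {
      s <- trimws(tolower(v))
      s[s %in% c("m", "1")] <- "male"
      s[s %in% c("f", "0")] <- "female"
      s
    } else {
      as.character(v)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (is.null(out$patient_id)) out$patient_id <- sprintf("P%05d", seq_len(n))
  if (is.null(out$cohort_label)) out$cohort_label <- "unspecified"
  out$cohort_label[is.na(out$cohort_label) | out$cohort_label == ""] <-
    "unspecified"
  extra <- setdiff(names(raw), schema)
  for (col in extra) out[[col]] <- utils::type.convert(raw[[col]],
                                                       as.is = TRUE)
  validate_cohort(out)
  class(out) <- c("sic_cohort", "data.frame")
  out
}

#' Write a cohort to a delimited file
#'
#' Inverse of [read_cohort()]: one row per record, header row, absent optional
#' values serialized as empty cells. The output round-trips through
#' [read_cohort()] with the default schema, preserving floating-point values
#' to at least 15 significant digits.
#'
#' @param cohort validated cohort data frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)
  num_cols <- vapply(out, is.numeric, logical(1))
  for (col in names(out)[num_cols])
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  flag_here <- intersect(.flag_cols, names(out))
  for (col in flag_here)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(as.logical(out[[col]]), "1", "0"))
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write cohort to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' In-hospital MACE composite
#'
#' Major adverse clinical events during hospitalization: the composite is
#' positive if any of stroke, dialysis, acute heart failure, or target vessel
#' revascularization occurred. Death is accounted for separately and is not
#' part of the composite.
#'
#' @param cohort cohort data frame with the four component flags.
#' @return logical vector, one element per record.
#' @export
derive_mace <- function(cohort) {
  comp <- c("stroke", "dialysis", "acute_heart_failure", "tvr")
  miss <- setdiff(comp, names(cohort))
  if (length(miss))
    stop("MACE components missing: ", paste(miss, collapse = ", "))
  if (anyNA(cohort[comp]))
    stop("MACE components contain missing values")
  Reduce(`|`, lapply(comp, function(cl) as.logical(cohort[[cl]])))
}
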