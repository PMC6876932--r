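#' Construct a phonation database
#'
#' A phonation database is a data frame with one row per recording:
#' metadata columns `subject_id`, `label` (`PD`/`healthy`), `gender`
#' (`M`/`F`/`unknown`), `sample_type` (`vowel_a`, `vowel_o`, `vowel_u`,
#' `word`, `sentence`, `number`) followed by the feature columns in
#' schema order. The constructor validates per-subject consistency: all
#' rows of a subject must share one label and one gender.
#'
#' @param rows Data frame holding the metadata and feature columns.
#' @param schema A [pd_feature_schema()]-like schema (defaults to the
#'   canonical 26-feature schema).
#' @param role `"training"` or `"testing"`.
#' @return An object of class `phonation_db` (a validated data frame
#'   with `schema` and `role` attributes).
#' @export
phonation_database <- function(rows, schema = pd_feature_schema(),
                               role = c("training", "testing")) {
  role <- match.arg(role)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)

  missing <- setdiff(c(.metadata_cols, schema$name), names(rows))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  rows <- rows[, c(.metadata_cols, schema$name), drop = FALSE]

  rows$subject_id <- as.character(rows$subject_id)
  if (any(is.na(rows$subject_id) | !nzchar(rows$subject_id))) {
    stop("subject ids must be non-empty")
  }
  if (!all(rows$label %in% .labels)) {
    stop("labels must be one of: ", paste(.labels, collapse = ", "))
  }
  if (!all(rows$gender %in% .genders)) {
    stop("gender must be one of: ", paste(.genders, collapse = ", "))
  }
  if (!all(rows$sample_type %in% .sample_types)) {
    stop("sample_type must be one of: ",
         paste(.sample_types, collapse = ", "))
  }
  for (fc in schema$name) {
    v <- rows[[fc]]
    if (!is.numeric(v)) stop("feature column not numeric: ", fc)
    if (any(!is.finite(v))) {
      stop("non-finite value in feature column '", fc, "' at row ",
           which(!is.finite(v))[1L])
    }
  }
  # per-subject label/gender consistency
  for (meta in c("label", "gender")) {
    n_distinct <- tapply(rows[[meta]], rows$subject_id,
                         function(x) length(unique(x)))
    bad <- names(n_distinct)[n_distinct > 1L]
    if (length(bad) > 0L) {
      stop("subject(s) with conflicting ", meta, ": ",
           paste(bad, collapse = ", "))
    }
  }

  rownames(rows) <- NULL
  structure(rows, schema = schema, role = role,
            class = c("phonation_db", "data.frame"))
}

#' @export
print.phonation_db <- function(x, ...) {
  sch <- db_schema(x)
  cat(sprintf("Phonation database (%s): %d recordings, %d subjects, %d features\n",
              attr(x, "role"), nrow(x), length(unique(x$subject_id)),
              nrow(sch)))
  tab <- table(label = x$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  tt <- table(x$sample_type)
  cat("  sample types:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Schema and helpers of a phonation database
#'
#' `db_schema()` returns the schema attribute; `feature_matrix()` the
#' numeric feature block as a matrix (rows = recordings, columns in
#' schema order); `db_labels()` the per-row class labels; `db_subjects()`
#' the unique subject ids in order of first appearance.
#'
#' @param db A `phonation_db`.
#' @export
db_schema <- function(db) attr(db, "schema")

#' @rdname db_schema
#' @export
feature_matrix <- function(db) {
  as.matrix(as.data.frame(db)[, db_schema(db)$name, drop = FALSE])
}

#' @rdname db_schema
#' @export
db_labels <- function(db) db$label

#' @rdname db_schema
#' @export
db_subjects <- function(db) unique(db$subject_id)

#' Read a phonation database from CSV
#'
#' Reads the canonical CSV dialect: UTF-8, header row, comma separator,
#' decimal point; columns `subject_id,label,gender,sample_type` followed
#' by the 26 feature columns in schema order. Validation errors name the
#' offending columns, rows or subjects.
#'
#' @param path Path to a CSV file.
#' @param role Database role, `"training"` or `"testing"`.
#' @param schema Expected feature schema.
#' @return A validated [phonation_database()]; input row order preserved.
#' @export
load_database <- function(path, role = c("training", "testing"),
                          schema = pd_feature_schema()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  expected <- c(.metadata_cols, schema$name)
  missing <- setdiff(expected, names(raw))
  extra <- setdiff(names(raw), expected)
  if (length(missing) > 0L || length(extra) > 0L) {
    msg <- character(0)
    if (length(missing) > 0L) {
      msg <- c(msg, paste0("missing column(s): ",
                           paste(missing, collapse = ", ")))
    }
    if (length(extra) > 0L) {
      msg <- c(msg, paste0("unexpected column(s): ",
                           paste(extra, collapse = ", ")))
    }
    stop("schema mismatch in ", path, ": ", paste(msg, collapse = "; "))
  }
  for (fc in schema$name) {
    v <- suppressWarnings(as.numeric(raw[[fc]]))
    bad <- which(is.na(v) & !is.na(raw[[fc]]) & nzchar(raw[[fc]]))
    if (any(is.na(v))) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(v))[1L]
      stop("non-numeric value in column '", fc, "' at data row ", row)
    }
    raw[[fc]] <- v
  }
  phonation_database(raw, schema = schema, role = role)
}

#' Write a phonation database to CSV
#'
#' Emits the canonical dialect read by [load_database()]. Feature values
#' are written with 17 significant digits so that a write/load round
#' trip reproduces the database exactly; output is byte-deterministic
#' for a given database.
#'
#' @param db A `phonation_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  sch <- db_schema(db)
  out <- as.data.frame(db)[, .metadata_cols, drop = FALSE]
  for (fc in sch$name) out[[fc]] <- sprintf("%.17g", db[[fc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a database to one sustained vowel
#'
#' Builds the single-phonation-type dataset used by the per-vowel
#' experiments: only rows of the requested vowel are kept. Subjects
#' without any row of that vowel are dropped with a warning naming them.
#' Feature values are never modified; this is pure row selection.
#' Subjects contributing several phonations of the vowel (as in the
#' testing cohort) keep all of them — per-subject aggregation is the
#' validator's responsibility.
#'
#' @param db A `phonation_db`.
#' @param vowel One of `"vowel_a"`, `"vowel_o"`, `"vowel_u"`.
#' @return A `phonation_db` containing only the selected rows.
#' @export
build_vowel_dataset <- function(db, vowel) {
  if (length(vowel) != 1L || !vowel %in% .vowel_types) {
    stop("vowel must be one of: ", paste(.vowel_types, collapse = ", "))
  }
  keep <- db$sample_type == vowel
  dropped <- setdiff(db_subjects(db), unique(db$subject_id[keep]))
  if (length(dropped) > 0L) {
    warning("subject(s) without '", vowel, "' rows dropped: ",
            paste(dropped, collapse = ", "))
  }
  rows <- as.data.frame(db)[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(structure(rows, schema = db_schema(db), role = attr(db, "role"),
                     class = c("phonation_db", "data.frame")))
  }
  phonation_database(rows, schema = db_schema(db), role = attr(db, "role"))
}

#' Drop the gender-dependent acoustic features
#'
#' Removes the 11 features flagged `gender_dependent` in the schema —
#' jitter (local), shimmer (local), the four pulse/period measures and
#' the five pitch statistics — leaving the 15 features whose class
#' contrast is not confounded by the gender imbalance typical of
#' clinical voice cohorts. Survivor order is preserved; the operation is
#' idempotent.
#'
#' @param db A `phonation_db`.
#' @return A `phonation_db` with the reduced schema.
#' @export
remove_gender_dependent_features <- function(db) {
  sch <- db_schema(db)
  keep <- !sch$gender_dependent
  new_schema <- sch[keep, , drop = FALSE]
  rownames(new_schema) <- NULL
  class(new_schema) <- class(sch)
  rows <- as.data.frame(db)[, c(.metadata_cols, new_schema$name),
                            drop = FALSE]
  if (nrow(rows) == 0L) {
    return(structure(rows, schema = new_schema, role = attr(db, "role"),
                     class = c("phonation_db", "data.frame")))
  }
  phonation_database(rows, schema = new_schema, role = attr(db, "role"))
}
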