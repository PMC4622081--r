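#' Build a validated patient table
#'
#' Binds a patient-level data frame to a schema and a right-censored
#' outcome, checking the structural invariants every downstream module
#' relies on: positive follow-up times, a 0/1 event indicator, no missing
#' outcomes or predictors, and categorical values drawn from their declared
#' levels.
#'
#' @param data A data frame with one row per patient.
#' @param schema A schema tibble from [schema()] / [var_spec()]. Every
#'   schema variable must be a column of `data`.
#' @param time_col,event_col Names of the outcome columns: follow-up time in
#'   days (> 0) and the event indicator (1 = event observed, 0 =
#'   right-censored).
#' @param id_col Optional patient-identifier column; defaults to row order.
#' @return A `patient_table` object.
#' @examples
#' sch <- schema(var_spec("biomarker", "continuous", group = "proteomic"))
#' df <- tibble::tibble(time = c(100, 250, 400), event = c(1, 0, 1),
#'                      biomarker = c(1.2, -0.5, 0.3))
#' as_patient_table(df, sch)
#' @export
as_patient_table <- function(data, schema, time_col = "time",
                             event_col = "event", id_col = NULL) {
  validate_schema(schema)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(time_col, event_col, schema$name), names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  time <- as.numeric(data[[time_col]])
  event <- as.numeric(data[[event_col]])
  if (anyNA(time) || anyNA(event)) {
    stop("missing outcome values are not allowed", call. = FALSE)
  }
  bad_t <- which(time <= 0)
  if (length(bad_t)) {
    stop("non-positive follow-up time in row(s) ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  ids <- if (is.null(id_col)) {
    sprintf("P%04d", seq_len(nrow(data)))
  } else {
    as.character(data[[id_col]])
  }
  if (anyDuplicated(ids)) stop("patient identifiers must be unique",
                               call. = FALSE)

  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- data[[nm]]
    if (anyNA(v)) {
      stop("missing values in predictor '", nm, "'", call. = FALSE)
    }
    if (schema$kind[i] == "categorical") {
      lv <- schema$levels[[i]]
      v <- as.character(v)
      unknown <- setdiff(unique(v), lv)
      if (length(unknown)) {
        stop("variable '", nm, "' contains undeclared level(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      data[[nm]] <- v
    } else {
      v <- as.numeric(v)
      if (any(!is.finite(v))) {
        stop("non-finite values in continuous predictor '", nm, "'",
             call. = FALSE)
      }
      data[[nm]] <- v
    }
  }

  structure(
    list(
      data = data[, c(schema$name), drop = FALSE],
      schema = schema,
      patient_ids = ids,
      time = time,
      event = event,
      extra = data[, setdiff(names(data),
                             c(schema$name, time_col, event_col)),
                   drop = FALSE]
    ),
    class = "patient_table"
  )
}

#' @export
print.patient_table <- function(x, ...) {
  cat("<patient_table> ", n_patients(x), " patients, ",
      nrow(x$schema), " variables (",
      paste(sprintf("%s: %d", names(table(x$schema$group)),
                    as.integer(table(x$schema$group))), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  events: %d observed, %d censored (%.1f%% censoring)\n",
              sum(x$event == 1), sum(x$event == 0),
              100 * mean(x$event == 0)))
  print(utils::head(dplyr::bind_cols(
    tibble::tibble(time = x$time, event = x$event), x$data), 6))
  invisible(x)
}

#' Number of patients in a patient table
#' @param table A `patient_table`.
#' @return Integer count.
#' @export
n_patients <- function(table) length(table$time)

#' Variable names of one or more assemblage groups
#' @param table A `patient_table`.
#' @param groups Character vector of group labels; `NULL` means all.
#' @return Character vector of variable names.
#' @export
group_variables <- function(table, groups = NULL) {
  if (is.null(groups)) return(table$schema$name)
  unknown <- setdiff(groups, unique(table$schema$group))
  if (length(unknown)) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  table$schema$name[table$schema$group %in% groups]
}

#' Restrict a patient table to a subset of variables
#' @param table A `patient_table`.
#' @param variables Variable names to keep.
#' @return A `patient_table` with the reduced schema.
#' @export
subset_variables <- function(table, variables) {
  unknown <- setdiff(variables, table$schema$name)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table$schema <- table$schema[match(variables, table$schema$name), ]
  table$data <- table$data[, variables, drop = FALSE]
  table
}

#' Restrict a patient table to a subset of patients
#' @param table A `patient_table`.
#' @param idx Integer row indices.
#' @return A `patient_table` with those patients.
#' @export
subset_patients <- function(table, idx) {
  table$data <- table$data[idx, , drop = FALSE]
  table$patient_ids <- table$patient_ids[idx]
  table$time <- table$time[idx]
  table$event <- table$event[idx]
  if (ncol(table$extra)) table$extra <- table$extra[idx, , drop = FALSE]
  table
}

#' Convert a patient table back to a tibble
#' @param x A `patient_table`.
#' @param ... Unused.
#' @return A tibble with `patient_id`, `time`, `event` and all predictors.
#' @method as_tibble patient_table
#' @export
as_tibble.patient_table <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(patient_id = x$patient_ids, time = x$time,
                   event = x$event),
    x$data
  )
}

#' Read / write a patient table as CSV plus schema sidecar
#'
#' The on-disk format is a plain comma-separated file (UTF-8, header row,
#' `.` decimal separator) with columns `patient_id`, `time`, `event` and one
#' column per predictor, plus a YAML/JSON sidecar describing each variable
#' (see [write_schema()]).
#'
#' @param path CSV file path.
#' @param schema A schema tibble, or a path to a sidecar file.
#' @param time_col,event_col Outcome column names in the CSV.
#' @param table A `patient_table` to write.
#' @param schema_path Optional sidecar path for `write_patient_table()`
#'   (default: `path` with extension replaced by `.schema.yaml`).
#' @return `read_patient_table()` returns a `patient_table`;
#'   `write_patient_table()` returns `path` invisibly.
#' @export
read_patient_table <- function(path, schema, time_col = "time",
                               event_col = "event") {
  if (is.character(schema) && length(schema) == 1) {
    schema <- read_schema(schema)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  id_col <- if ("patient_id" %in% names(df)) "patient_id" else NULL
  as_patient_table(df, schema, time_col = time_col, event_col = event_col,
                   id_col = id_col)
}

#' @rdname read_patient_table
#' @export
write_patient_table <- function(table, path, schema_path = NULL) {
  stopifnot(inherits(table, "patient_table"))
  readr::write_csv(as_tibble(table), path, progress = FALSE)
  if (is.null(schema_path)) {
    schema_path <- paste0(sub("\\.csv$", "", path), ".schema.yaml")
  }
  write_schema(table$schema, schema_path)
  invisible(path)
}
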