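#' Encode a patient table as a numeric design matrix
#'
#' Continuous variables are copied unchanged; each categorical variable with
#' L declared levels expands to L - 1 treatment-coded indicator columns, the
#' first declared level serving as reference. Column order is deterministic:
#' schema order, then declared level order. A declared level absent from the
#' data yields an all-zero indicator column, reported in `degenerate`.
#'
#' @param table A `patient_table`.
#' @param variables Optional subset of variable names to encode (default:
#'   all, in schema order).
#' @return A `cox_design`: list with `x` (numeric matrix, patients x design
#'   columns), `mapping` (tibble: `column`, `variable`, `level`), and
#'   `degenerate` (names of all-zero or constant columns).
#' @examples
#' pt <- simulate_cohort(n = 20, seed = 1)
#' d <- encode(pt, variables = c("stage", "age"))
#' colnames(d$x)
#' @export
encode <- function(table, variables = NULL) {
  stopifnot(inherits(table, "patient_table"))
  sch <- table$schema
  if (!is.null(variables)) {
    sch <- sch[match(variables, sch$name), ]
    if (anyNA(sch$name)) stop("unknown variable in 'variables'", call. = FALSE)
  }
  n <- n_patients(table)
  cols <- list()
  map_var <- character()
  map_lev <- character()
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    v <- table$data[[nm]]
    if (sch$kind[i] == "continuous") {
      cols[[nm]] <- as.numeric(v)
      map_var <- c(map_var, nm)
      map_lev <- c(map_lev, NA_character_)
    } else {
      lv <- sch$levels[[i]]
      for (l in lv[-1]) {
        cn <- paste0(nm, "=", l)
        cols[[cn]] <- as.numeric(v == l)
        map_var <- c(map_var, nm)
        map_lev <- c(map_lev, l)
      }
    }
  }
  x <- if (length(cols)) {
    matrix(unlist(cols, use.names = FALSE), nrow = n,
           dimnames = list(NULL, names(cols)))
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  constant <- constant_columns(x)
  structure(
    list(
      x = x,
      mapping = tibble::new_tibble(
        list(column = colnames(x) %||% character(0), variable = map_var,
             level = map_lev),
        nrow = ncol(x)),
      degenerate = colnames(x)[constant]
    ),
    class = "cox_design"
  )
}

constant_columns <- function(x) {
  if (!ncol(x)) return(logical(0))
  apply(x, 2, function(col) col[1] == col[length(col)] &&
          all(col == col[1]))
}

#' @export
print.cox_design <- function(x, ...) {
  cat("<cox_design> ", nrow(x$x), " patients x ", ncol(x$x),
      " design columns\n", sep = "")
  if (length(x$degenerate)) {
    cat("  degenerate (constant) columns: ",
        paste(x$degenerate, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
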