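#' Declare a predictor variable
#'
#' A variable specification records how one predictor column is interpreted:
#' its measurement kind, the ordered category levels (categoricals only,
#' first level = reference), and the assemblage group it belongs to (e.g.
#' `"clinicopathological"` or `"proteomic"`).
#'
#' Optional generator hints (`mean`, `sd`, `lower`, `upper`, `probs`) are
#' carried alongside so [simulate_cohort()] can draw realistic values; they
#' play no role in model fitting.
#'
#' @param name Variable (column) name; unique within a schema.
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels Character vector of category labels (categorical only,
#'   length >= 2); the first label is the reference level.
#' @param group Free-form assemblage label.
#' @param mean,sd,lower,upper Generator hints for continuous variables
#'   (Gaussian location/scale, optional truncation bounds).
#' @param probs Generator hint: level probabilities for categorical
#'   variables (defaults to uniform).
#' @return A one-row tibble; rows from several calls bind into a schema.
#' @examples
#' var_spec("stage", "categorical",
#'          levels = paste("stage", 1:4), group = "clinicopathological")
#' @export
var_spec <- function(name, kind = c("continuous", "categorical"),
                     levels = NULL, group = "predictors",
                     mean = 0, sd = 1, lower = -Inf, upper = Inf,
                     probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2) {
      stop("categorical variable '", name, "' needs >= 2 levels", call. = FALSE)
    }
    if (anyDuplicated(levels)) {
      stop("duplicate levels for '", name, "'", call. = FALSE)
    }
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels) || any(probs < 0)) {
      stop("probs must be non-negative and match levels for '", name, "'",
           call. = FALSE)
    }
    probs <- probs / sum(probs)
  } else {
    if (!is.null(levels)) {
      stop("continuous variable '", name, "' must not declare levels",
           call. = FALSE)
    }
    probs <- NULL
  }
  tibble::tibble(
    name = as.character(name), kind = kind,
    levels = list(levels), group = as.character(group),
    mean = mean, sd = sd, lower = lower, upper = upper,
    probs = list(probs)
  )
}

#' Combine variable specifications into a schema
#'
#' @param ... One-row tibbles from [var_spec()], or schema tibbles.
#' @return A schema tibble with unique variable names.
#' @export
schema <- function(...) {
  sch <- dplyr::bind_rows(...)
  validate_schema(sch)
  sch
}

validate_schema <- function(sch) {
  stopifnot(is.data.frame(sch))
  needed <- c("name", "kind", "levels", "group")
  missing <- setdiff(needed, names(sch))
  if (length(missing)) {
    stop("schema lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sch$name)) {
    stop("duplicate variable names in schema: ",
         paste(unique(sch$name[duplicated(sch$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !sch$kind %in% c("continuous", "categorical")
  if (any(bad)) stop("unknown kind for: ", paste(sch$name[bad], collapse = ", "),
                     call. = FALSE)
  invisible(sch)
}

#' Schema of an ovarian-cancer proteogenomic cohort
#'
#' The default study design emulated by [simulate_cohort()]: five
#' clinicopathological inputs (age in days, both continuous and stratified
#' at 50 years; histopathology with six levels; FIGO stage with four;
#' chemotherapy regimen with two) and twenty proteomic AQUA immunofluorescence
#' intensities (scale 0-255) measured per subcellular compartment: thirteen
#' nuclear-only targets, three cytoplasm-only EMT markers, and the two
#' estrogen receptor beta isoforms measured in both compartments.
#'
#' @return A schema tibble with 25 variables (5 clinicopathological,
#'   20 proteomic).
#' @examples
#' dplyr::count(ovarian_schema(), group)
#' @export
ovarian_schema <- function() {
  nuclear <- c("pERK", "pbCatenin", "pSTAT3_Ser727", "pSTAT3_Ser705",
               "pNFkB", "pRB", "pH2AX", "pBRCA1", "p-p53", "Ki67",
               "pHH3", "cleaved_caspase3", "WT1")
  cytoplasm <- c("Snail", "Slug", "E-cadherin")
  both <- c("ERb1", "ERb2")
  prot_names <- c(paste0(nuclear, "_nuc"),
                  paste0(cytoplasm, "_cyt"),
                  paste0(rep(both, each = 2), c("_nuc", "_cyt")))
  prot <- purrr::map(prot_names, function(nm) {
    var_spec(nm, "continuous", group = "proteomic",
             mean = 100, sd = 40, lower = 0, upper = 255)
  })
  clin <- list(
    var_spec("age", "continuous", group = "clinicopathological",
             mean = 60 * 365.25, sd = 11 * 365.25, lower = 20 * 365.25,
             upper = 92 * 365.25),
    var_spec("age_over_50", "categorical", levels = c("<50", ">50"),
             group = "clinicopathological"),
    var_spec("histopathology", "categorical",
             levels = c("papillary serous", "clear cell", "endometrioid",
                        "mixed histology", "mucinous", "adenocarcinoma"),
             group = "clinicopathological",
             probs = c(0.60, 0.08, 0.12, 0.08, 0.05, 0.07)),
    var_spec("stage", "categorical",
             levels = paste("stage", 1:4),
             group = "clinicopathological",
             probs = c(0.15, 0.10, 0.55, 0.20)),
    var_spec("regimen", "categorical",
             levels = c("platinum", "platinum + taxane"),
             group = "clinicopathological",
             probs = c(0.45, 0.55))
  )
  dplyr::bind_rows(c(clin, prot))
}

# schema <-> plain-list form for YAML/JSON sidecar files
schema_to_list <- function(sch) {
  purrr::pmap(sch, function(name, kind, levels, group, mean, sd, lower,
                            upper, probs, ...) {
    out <- list(name = name, kind = kind, group = group)
    if (kind == "categorical") {
      out$levels <- as.list(levels)
      out$probs <- as.list(probs)
    } else {
      out$mean <- mean; out$sd <- sd
      if (is.finite(lower)) out$lower <- lower
      if (is.finite(upper)) out$upper <- upper
    }
    out
  })
}

schema_from_list <- function(lst) {
  rows <- purrr::map(lst, function(v) {
    var_spec(v$name, v$kind,
             levels = if (!is.null(v$levels)) unlist(v$levels),
             group = v$group %||% "predictors",
             mean = v$mean %||% 0, sd = v$sd %||% 1,
             lower = v$lower %||% -Inf, upper = v$upper %||% Inf,
             probs = if (!is.null(v$probs)) unlist(v$probs))
  })
  schema(!!!rows)
}

#' Read or write a schema sidecar file
#'
#' Schemas travel beside the patient CSV as a YAML (or JSON) document listing
#' each variable's name, kind, levels and group.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param sch A schema tibble.
#' @return `read_schema()` returns a schema tibble; `write_schema()` its
#'   path, invisibly.
#' @export
read_schema <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  schema_from_list(lst)
}

#' @rdname read_schema
#' @export
write_schema <- function(sch, path) {
  validate_schema(sch)
  lst <- schema_to_list(sch)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
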