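#' Construct a risk-index definition
#'
#' A risk-index definition is data, not code: the list of risk items counted
#' by the index, the protective items that subtract one point, the category
#' cap (scores of `cap` or more share the top category), and whether the
#' prior-utilization extension to a 0-12 scale is enabled.
#'
#' @param risk_items Character vector of risk item ids (non-empty).
#' @param protective_items Character vector of protective item ids, disjoint
#'   from `risk_items`.
#' @param cap Top category; default 6 ("six or more").
#' @param prior_use_extension Enable the extended 0-12 index (categories 0-6
#'   for persons without prior hospital/ED use, 7-12 with).
#' @return A list of class `hedri_index`.
#' @export
risk_index_definition <- function(risk_items, protective_items = character(),
                                  cap = 6L, prior_use_extension = TRUE) {
  risk_items <- as.character(risk_items)
  protective_items <- as.character(protective_items)
  if (length(risk_items) == 0) {
    stop_config("risk_items must be non-empty")
  }
  if (anyDuplicated(c(risk_items, protective_items))) {
    stop_config("risk_items and protective_items must be disjoint and unique")
  }
  if (!(length(cap) == 1 && cap >= 1 && cap == round(cap))) {
    stop_config("cap must be a positive integer")
  }
  structure(
    list(
      risk_items = risk_items,
      protective_items = protective_items,
      cap = as.integer(cap),
      prior_use_extension = isTRUE(prior_use_extension)
    ),
    class = "hedri_index"
  )
}

#' Turn a fitted model into a risk-index definition
#'
#' Covariates of the final multivariate model with an adjusted odds ratio
#' above 1 become the counted risk items; covariates with OR below 1 become
#' the protective items. A covariate with OR exactly 1 has an ambiguous role
#' and is rejected; an intercept-only model yields no index and is an error.
#'
#' @param model A fitted `hedri_logit` (typically a [stepwise_select()]
#'   result).
#' @param cap,prior_use_extension Passed to [risk_index_definition()].
#' @return A `hedri_index`.
#' @export
build_index_definition <- function(model, cap = 6L,
                                   prior_use_extension = TRUE) {
  ors <- odds_ratios(model)
  if (length(ors) == 0) {
    stop_data("model has no covariates: cannot build an empty index")
  }
  if (any(ors == 1)) {
    stop_data(paste0(
      "covariate(s) with odds ratio exactly 1 have an ambiguous role: ",
      paste(names(ors)[ors == 1], collapse = ", ")
    ))
  }
  risk_index_definition(
    risk_items = names(ors)[ors > 1],
    protective_items = names(ors)[ors < 1],
    cap = cap,
    prior_use_extension = prior_use_extension
  )
}

#' The canonical hospital-ED risk-index definition
#'
#' The shipped 16-item definition: fourteen named items (pneumonia, urinary
#' tract infection, stasis ulcers, unintended weight loss, major status
#' deterioration over the prior 90 days, falls, renal failure, emphysema,
#' cancer, wound care, IV infusion, medication by injection, daily nurse
#' monitoring, unscheduled physician visits) plus two configurable slots
#' (default: fever and nine-or-more medications), with Alzheimer's disease
#' and day-care participation as the protective pair. Loaded from the JSON
#' definition shipped in `inst/extdata/`.
#'
#' @param slots Character vector of length 2 filling the two configurable
#'   risk-item slots.
#' @return A `hedri_index`.
#' @export
default_index_definition <- function(slots = NULL) {
  path <- system.file("extdata", "hospital_ed_index.json", package = "hedri")
  def <- read_index_json(path)
  if (!is.null(slots)) {
    if (length(slots) != 2) {
      stop_config("slots must name exactly 2 items")
    }
    fixed <- setdiff(def$risk_items, attr(def, "slot_items"))
    def <- risk_index_definition(c(fixed, as.character(slots)),
                                 def$protective_items, def$cap,
                                 def$prior_use_extension)
  }
  def
}

#' Score a single assessment record
#'
#' Applies the index rules: the raw count of risk items present; minus one
#' (floored at zero) when one or both protective items are present; capped
#' at `cap` for the category; and, when the prior-use extension is enabled,
#' mapped to the 0-12 scale (category for persons without prior use,
#' `7 + min(adjusted, 5)` with prior use).
#'
#' @param record One-row data frame or named list containing 0/1 values for
#'   every definition item (and `prior_use` if the extension is enabled).
#' @param definition A `hedri_index`.
#' @return List of class `hedri_score`: `raw_count`, `adjusted`, `category`,
#'   `extended_category` (NA when the extension is off), `protective_present`.
#' @export
score <- function(record, definition) {
  record <- as.list(record)
  needed <- c(definition$risk_items, definition$protective_items)
  missing_items <- needed[!vapply(needed, function(it)
    !is.null(record[[it]]) && !is.na(record[[it]]), logical(1))]
  if (length(missing_items) > 0) {
    stop_data(paste0("record is missing item value(s): ",
                     paste(missing_items, collapse = ", ")))
  }
  raw <- sum(vapply(definition$risk_items,
                    function(it) as.integer(record[[it]]), integer(1)))
  prot <- any(vapply(definition$protective_items,
                     function(it) record[[it]] == 1, logical(1)))
  adjusted <- if (prot) max(0L, raw - 1L) else raw
  category <- min(adjusted, definition$cap)
  ext <- NA_integer_
  if (definition$prior_use_extension) {
    pu <- record[["prior_use"]]
    if (is.null(pu) || is.na(pu)) {
      stop_data("record is missing prior_use (required for the extended index)")
    }
    ext <- if (pu == 1) 7L + min(adjusted, 5L) else as.integer(category)
  }
  structure(
    list(raw_count = as.integer(raw), adjusted = as.integer(adjusted),
         category = as.integer(category), extended_category = ext,
         protective_present = prot),
    class = "hedri_score"
  )
}

#' @export
print.hedri_score <- function(x, ...) {
  cat(sprintf(
    "Risk score: raw %d, adjusted %d%s, category %d%s\n",
    x$raw_count, x$adjusted,
    if (x$protective_present) " (protective decrement applied)" else "",
    x$category,
    if (!is.na(x$extended_category))
      sprintf(", extended %d", x$extended_category) else ""
  ))
  invisible(x)
}

#' Score every record of a dataset
#'
#' Vectorized application of [score()]; order-preserving and deterministic.
#' Missing item columns or non-0/1 values are errors (no imputation).
#'
#' @param dataset Cohort data frame.
#' @param definition A `hedri_index`.
#' @return Data frame: `person_id`, `raw_count`, `adjusted`, `category`,
#'   `extended_category`, `protective_present`.
#' @export
score_dataset <- function(dataset, definition) {
  needed <- c(definition$risk_items, definition$protective_items)
  missing_cols <- setdiff(needed, names(dataset))
  if (length(missing_cols) > 0) {
    stop_data(paste0("dataset is missing definition item(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (nrow(dataset) == 0) {
    return(data.frame(person_id = character(), raw_count = integer(),
                      adjusted = integer(), category = integer(),
                      extended_category = integer(),
                      protective_present = logical(),
                      stringsAsFactors = FALSE))
  }
  for (col in needed) {
    if (!is_binary01(dataset[[col]])) {
      stop_data(paste0("item '", col, "' has missing or non-0/1 values"))
    }
  }
  rmat <- as.matrix(dataset[, definition$risk_items, drop = FALSE])
  raw <- as.integer(rowSums(rmat))
  prot <- if (length(definition$protective_items) > 0) {
    rowSums(dataset[, definition$protective_items, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(dataset))
  }
  adjusted <- ifelse(prot, pmax(0L, raw - 1L), raw)
  category <- pmin(adjusted, definition$cap)
  ext <- rep(NA_integer_, nrow(dataset))
  if (definition$prior_use_extension) {
    if (!"prior_use" %in% names(dataset) ||
        !is_binary01(dataset$prior_use)) {
      stop_data("dataset needs a 0/1 prior_use column for the extended index")
    }
    ext <- ifelse(dataset$prior_use == 1L, 7L + pmin(adjusted, 5L),
                  as.integer(category))
  }
  data.frame(
    person_id = as.character(dataset$person_id),
    raw_count = raw,
    adjusted = as.integer(adjusted),
    category = as.integer(category),
    extended_category = as.integer(ext),
    protective_present = prot,
    stringsAsFactors = FALSE
  )
}

#' Attach index scores to a cohort data frame
#'
#' Convenience wrapper around [score_dataset()] that binds the score columns
#' to the dataset, ready for the stratified-rate reports.
#'
#' @inheritParams score_dataset
#' @return The dataset with `raw_count`, `adjusted`, `category`,
#'   `extended_category`, `protective_present` columns appended.
#' @export
apply_index <- function(dataset, definition) {
  scores <- score_dataset(dataset, definition)
  stopifnot(identical(scores$person_id, as.character(dataset$person_id)))
  out <- cbind(dataset, scores[, -1, drop = FALSE])
  attr(out, "index_cap") <- definition$cap
  out
}

#' @export
print.hedri_index <- function(x, ...) {
  cat(sprintf(
    "Hospital-ED risk index: %d risk item(s), %d protective, cap %d+, extended index %s\n",
    length(x$risk_items), length(x$protective_items), x$cap,
    if (x$prior_use_extension) "on" else "off"
  ))
  cat("Risk items:", paste(x$risk_items, collapse = ", "), "\n")
  if (length(x$protective_items) > 0) {
    cat("Protective:", paste(x$protective_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a risk-index definition as JSON
#'
#' @param definition A `hedri_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_json <- function(definition, path) {
  out <- list(
    risk_items = definition$risk_items,
    protective_items = definition$protective_items,
    cap = definition$cap,
    prior_use_extension = definition$prior_use_extension
  )
  if (!is.null(attr(definition, "slot_items"))) {
    out$slot_items <- attr(definition, "slot_items")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a risk-index definition from JSON
#'
#' @param path JSON file path.
#' @return A `hedri_index`.
#' @export
read_index_json <- function(path) {
  if (!file.exists(path) || !nzchar(path)) {
    stop_data(paste0("no such index definition file: ", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, c("risk_items", "protective_items", "cap",
                    "prior_use_extension", "slot_items"), "index definition")
  def <- risk_index_definition(
    risk_items = raw$risk_items,
    protective_items = raw$protective_items %||% character(),
    cap = raw$cap %||% 6L,
    prior_use_extension = raw$prior_use_extension %||% TRUE
  )
  if (!is.null(raw$slot_items)) attr(def, "slot_items") <- raw$slot_items
  def
}

#' Write scores as TSV
#'
#' @param scores A [score_dataset()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
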