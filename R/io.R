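#' Write a cohort table to CSV
#'
#' Emits the canonical cohort schema: header
#' `person_id,cohort,age,prior_use,outcome,<item_id>...`, one row per person,
#' binary fields as 0/1, UTF-8, comma-delimited, newline-terminated. The
#' `split` column is working state, not data, and is not written.
#'
#' @param dataset Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(dataset, path) {
  cols <- c("person_id", "cohort", "age", "prior_use", "outcome",
            item_columns(dataset))
  missing_cols <- setdiff(cols, names(dataset))
  if (length(missing_cols) > 0) {
    stop_data(paste0("dataset is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  utils::write.csv(dataset[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Reads and validates the canonical cohort schema (see
#' [write_cohort_csv()]). Violations are reported with the offending data row
#' numbers. A `split` column of `"unassigned"` is added.
#'
#' @param path CSV file path.
#' @param catalog Optional catalog; if given, the file must contain exactly
#'   the catalog's items.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path, catalog = NULL) {
  if (!file.exists(path)) {
    stop_data(paste0("no such file: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("person_id", "cohort", "age", "prior_use", "outcome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_data(paste0("cohort CSV is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) {
    rows <- which(duplicated(df$person_id))
    stop_data(paste0("duplicated person_id at data row(s): ",
                     paste(utils::head(rows, 10), collapse = ", ")))
  }
  items <- setdiff(names(df), c(required, "split"))
  if (!is.null(catalog)) {
    missing_items <- setdiff(catalog$item_id, items)
    extra_items <- setdiff(items, catalog$item_id)
    if (length(missing_items) > 0 || length(extra_items) > 0) {
      stop_data(paste0(
        "cohort CSV items do not match catalog",
        if (length(missing_items) > 0)
          paste0("; missing: ", paste(missing_items, collapse = ", ")),
        if (length(extra_items) > 0)
          paste0("; unexpected: ", paste(extra_items, collapse = ", "))
      ))
    }
  }
  for (col in c("prior_use", "outcome", items)) {
    bad <- which(is.na(df[[col]]) | !(df[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_data(sprintf(
        "column '%s' must be 0/1; bad value(s) at data row(s): %s",
        col, paste(utils::head(bad, 10), collapse = ", ")
      ))
    }
    df[[col]] <- as.integer(df[[col]])
  }
  bad_age <- which(is.na(df$age) | df$age < 60)
  if (length(bad_age) > 0) {
    stop_data(paste0("age must be >= 60; bad value(s) at data row(s): ",
                     paste(utils::head(bad_age, 10), collapse = ", ")))
  }
  df$split <- "unassigned"
  # reorder: bookkeeping columns first
  df[c(required, "split", items)]
}

# Recursively reject unknown keys in a config section.
check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown key(s) in %s: %s",
                        where, paste(unknown, collapse = ", ")))
  }
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Accepts JSON (`.json`) or YAML (`.yml`/`.yaml`). The schema has four
#' optional sections: `simulation` (arguments of [sim_config()], plus
#' `split_fraction`; `catalog` may be the string `"default"` or a list of
#' item records), `screening` (arguments of [screening_config()]),
#' `selection` (arguments of [selection_config()]), and `log_level`. Unknown
#' keys anywhere are rejected.
#'
#' @param path Config file path.
#' @return A list of class `hedri_pipeline_config` with elements
#'   `simulation` (a `hedri_sim_config`), `split_fraction`, `screening`,
#'   `selection`, `log_level`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(paste0("no such config file: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop_config("config file must be .json, .yml or .yaml")
  }
  pipeline_config(raw)
}

#' Build a pipeline configuration from a plain list
#'
#' @param raw Nested list as produced by parsing a JSON/YAML config file; see
#'   [read_pipeline_config()] for the schema.
#' @return A list of class `hedri_pipeline_config`.
#' @export
pipeline_config <- function(raw = list()) {
  check_keys(raw, c("simulation", "screening", "selection", "log_level"),
             "config")
  sim_raw <- raw$simulation %||% list()
  check_keys(sim_raw, c("n_persons", "cohorts", "catalog", "beta_prior_use",
                        "prior_use_prevalence", "age_range",
                        "domain_correlation", "seed", "split_fraction"),
             "config$simulation")
  catalog <- sim_raw$catalog
  if (is.null(catalog) || identical(catalog, "default")) {
    catalog <- default_catalog()
  } else {
    catalog <- item_catalog(as.data.frame(catalog))
  }
  cohorts <- sim_raw$cohorts
  if (!is.null(cohorts)) cohorts <- as.data.frame(cohorts)
  sim <- sim_config(
    n_persons = sim_raw$n_persons %||% 10000L,
    catalog = catalog,
    cohorts = cohorts,
    beta_prior_use = sim_raw$beta_prior_use %||% log(4),
    prior_use_prevalence = sim_raw$prior_use_prevalence %||% 0.45,
    age_range = unlist(sim_raw$age_range %||% c(60L, 100L)),
    domain_correlation = sim_raw$domain_correlation %||% 0,
    seed = sim_raw$seed %||% 1L
  )

  scr_raw <- raw$screening %||% list()
  check_keys(scr_raw, c("risk_threshold", "protective_threshold",
                        "require_validation_confirmation",
                        "continuity_correction"), "config$screening")
  scr <- do.call(screening_config, scr_raw)

  sel_raw <- raw$selection %||% list()
  check_keys(sel_raw, c("stage1_domains", "stage2_domains",
                        "retention_or_threshold", "entry_alpha", "max_terms",
                        "tolerance", "max_iterations", "validation_rule"),
             "config$selection")
  sel_raw[c("stage1_domains", "stage2_domains")] <-
    lapply(sel_raw[c("stage1_domains", "stage2_domains")], unlist)
  sel_raw <- sel_raw[!vapply(sel_raw, is.null, logical(1))]
  sel <- do.call(selection_config, sel_raw)

  structure(
    list(
      simulation = sim,
      split_fraction = sim_raw$split_fraction %||% (2 / 3),
      screening = scr,
      selection = sel,
      log_level = raw$log_level %||% "info"
    ),
    class = "hedri_pipeline_config"
  )
}
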