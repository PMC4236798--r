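#' Derive a hospital-ED risk index from a split cohort
#'
#' The package's front door: runs the whole derivation procedure on a cohort
#' table — univariate odds-ratio screening with validation confirmation, the
#' cross-cohort poolability check, staged stepwise logistic selection with
#' the dual-sample retention rule, and construction of the count-based index
#' from the final model.
#'
#' @param dataset Cohort data frame. If its `split` column is unassigned it
#'   is split with [split_derivation_validation()] first.
#' @param catalog Item catalog describing the candidate items and domains.
#' @param screening A [screening_config()].
#' @param selection A [selection_config()].
#' @param split_fraction Derivation fraction used when the dataset arrives
#'   unsplit.
#' @param probe_items Poolability probe items; `NULL` skips the check (it is
#'   skipped anyway for single-cohort data).
#' @param seed Seed for the split when one is needed.
#' @return Object of class `hedri`: `screening` (the [screen_all()] table),
#'   `poolability`, `model` (the [stepwise_select()] fit), `definition` (the
#'   [build_index_definition()] result), `n_derivation`, `n_validation`.
#' @export
derive_risk_index <- function(dataset, catalog,
                              screening = screening_config(),
                              selection = selection_config(),
                              split_fraction = 2 / 3,
                              probe_items = default_probe_items(),
                              seed = 1L) {
  if (all(dataset$split == "unassigned")) {
    dataset <- split_derivation_validation(dataset, split_fraction, seed)
  }
  pool <- NULL
  if (!is.null(probe_items) && length(unique(dataset$cohort)) > 1 &&
      all(probe_items %in% item_columns(dataset))) {
    pool <- poolability_check(dataset, probe_items, screening)
  }
  scr <- screen_all(dataset, catalog, screening)
  model <- stepwise_select(dataset, scr, selection)
  definition <- build_index_definition(model)
  structure(
    list(
      screening = scr,
      poolability = pool,
      model = model,
      definition = definition,
      n_derivation = sum(dataset$split == "derivation"),
      n_validation = sum(dataset$split == "validation")
    ),
    class = "hedri"
  )
}

#' @export
print.hedri <- function(x, ...) {
  cat(sprintf(
    "Hospital-ED risk index derivation (n = %d derivation / %d validation)\n\n",
    x$n_derivation, x$n_validation
  ))
  if (!is.null(x$poolability)) {
    cat(sprintf("Poolability: %s\n",
                if (x$poolability$verdict) "poolable" else "NOT poolable"))
  }
  cat(sprintf(
    "Screening: %d risk / %d protective of %d items\n",
    sum(x$screening$classification == "risk"),
    sum(x$screening$classification == "protective"),
    nrow(x$screening)
  ))
  print(x$model)
  cat("\n")
  print(x$definition)
  invisible(x)
}

#' @export
summary.hedri <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.hedri <- function(object, ...) coef(object$model)

#' Predict risk scores or event probabilities from a derived index
#'
#' @param object A [derive_risk_index()] result.
#' @param newdata Cohort data frame.
#' @param type `"category"` (index categories via the derived definition),
#'   `"extended"` (the 0-12 extended categories), or `"response"` (fitted
#'   event probability from the final logistic model).
#' @param ... Unused.
#' @return Integer vector of categories, or numeric probabilities.
#' @export
predict.hedri <- function(object, newdata,
                          type = c("category", "extended", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") {
    return(predict(object$model, newdata, type = "response"))
  }
  scores <- score_dataset(newdata, object$definition)
  if (type == "category") scores$category else scores$extended_category
}

log_msg <- function(level, config_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[config_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

#' Simulate a cohort and write it as CSV
#'
#' @param config A `hedri_pipeline_config` (see [read_pipeline_config()]) or
#'   a `hedri_sim_config`.
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
run_simulate <- function(config, out_path) {
  sim <- if (inherits(config, "hedri_pipeline_config")) config$simulation
         else config
  if (!inherits(sim, "hedri_sim_config")) {
    stop_config("config must be a pipeline or simulation config")
  }
  dataset <- generate_cohort(sim)
  write_cohort_csv(dataset, out_path)
  invisible(out_path)
}

#' Run the derivation pipeline on a cohort CSV
#'
#' Reads (or accepts) a cohort table, splits it, screens all catalog items,
#' checks poolability across cohorts, runs the staged stepwise selection,
#' builds the index definition, and (when `out_dir` is given) writes
#' `screening.tsv`, `screening.json`, `model.json` and `index.json`.
#'
#' @param cohort Path to a cohort CSV, or a cohort data frame.
#' @param config A `hedri_pipeline_config`; its catalog must match the data.
#' @param out_dir Optional output directory (created if needed).
#' @return A `hedri` object, invisibly.
#' @export
run_derive <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  dataset <- if (is.character(cohort)) {
    read_cohort_csv(cohort, config$simulation$catalog)
  } else {
    cohort
  }
  result <- derive_risk_index(
    dataset, config$simulation$catalog,
    screening = config$screening,
    selection = config$selection,
    split_fraction = config$split_fraction,
    seed = config$simulation$seed
  )
  if (!is.null(result$poolability) && !result$poolability$verdict) {
    log_msg("warn", config$log_level,
            "poolability check failed: probe odds ratios are not directionally consistent across cohorts")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_screening_tsv(result$screening, file.path(out_dir, "screening.tsv"))
    write_screening_json(result$screening, file.path(out_dir, "screening.json"))
    write_model_json(result$model, file.path(out_dir, "model.json"))
    write_index_json(result$definition, file.path(out_dir, "index.json"))
    log_msg("info", config$log_level, "derivation artifacts written to ", out_dir)
  }
  invisible(result)
}

#' Score a cohort and write the stratified-rate reports
#'
#' Applies an index definition to a cohort, and (when `out_dir` is given)
#' writes `scores.tsv`, `rates_by_category.tsv`,
#' `rates_by_category_cohort.tsv`, `rates_by_prior_use.tsv` and
#' `reports.json` (rates, protective-effect summary, prior-use crossing).
#'
#' @param cohort Path to a cohort CSV, or a cohort data frame.
#' @param definition A `hedri_index`, or path to an index JSON.
#' @param out_dir Optional output directory.
#' @return List with `scores`, `rates_category`, `rates_category_cohort`,
#'   `prior_use`, `protective`, invisibly.
#' @export
run_score_evaluate <- function(cohort, definition, out_dir = NULL) {
  dataset <- if (is.character(cohort)) read_cohort_csv(cohort) else cohort
  if (is.character(definition)) definition <- read_index_json(definition)
  scored <- apply_index(dataset, definition)
  scores <- scored[c("person_id", "raw_count", "adjusted", "category",
                     "extended_category", "protective_present")]
  rates_category <- rates_by(scored, "category")
  rates_cc <- if (length(unique(scored$cohort)) > 1) {
    rates_by(scored, c("category", "cohort"))
  } else {
    NULL
  }
  prior <- if (length(unique(scored$prior_use)) > 1) {
    prior_use_comparison(scored)
  } else {
    NULL
  }
  protective <- protective_effect_summary(scored)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
    write_rates_tsv(rates_category, file.path(out_dir, "rates_by_category.tsv"))
    if (!is.null(rates_cc)) {
      write_rates_tsv(rates_cc, file.path(out_dir, "rates_by_category_cohort.tsv"))
    }
    if (!is.null(prior)) {
      write_rates_tsv(prior$grid, file.path(out_dir, "rates_by_prior_use.tsv"))
    }
    jsonlite::write_json(
      list(
        rates_by_category = as.data.frame(rates_category),
        prior_use_crossing = prior$crossing %||% NA,
        protective_overall_category_drop = protective$overall
      ),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA,
      na = "null"
    )
  }
  invisible(list(
    scores = scores,
    rates_category = rates_category,
    rates_category_cohort = rates_cc,
    prior_use = prior,
    protective = protective
  ))
}
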