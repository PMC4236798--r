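#' Screening configuration
#'
#' Thresholds for the univariate odds-ratio screen: an item is a candidate
#' risk factor when its OR equals or exceeds `risk_threshold` (default 1.30)
#' and a candidate protective factor when its OR is `protective_threshold`
#' (default 0.75) or lower. With `require_validation_confirmation` (the
#' default) the rule must hold in both the derivation and the validation
#' sample; otherwise the derivation OR alone decides.
#'
#' @param risk_threshold OR at or above which an item is flagged as risk.
#' @param protective_threshold OR at or below which an item is protective.
#' @param require_validation_confirmation Require the threshold rule to hold
#'   in both samples.
#' @param continuity_correction Amount added to all four cells of a 2x2
#'   table when any cell is zero (Haldane-Anscombe), default 0.5.
#' @return A list of class `hedri_screening_config`.
#' @export
screening_config <- function(risk_threshold = 1.30,
                             protective_threshold = 0.75,
                             require_validation_confirmation = TRUE,
                             continuity_correction = 0.5) {
  if (!(protective_threshold < 1 && 1 < risk_threshold)) {
    stop_config("need protective_threshold < 1 < risk_threshold")
  }
  if (continuity_correction < 0) {
    stop_config("continuity_correction must be >= 0")
  }
  structure(
    list(
      risk_threshold = risk_threshold,
      protective_threshold = protective_threshold,
      require_validation_confirmation = isTRUE(require_validation_confirmation),
      continuity_correction = continuity_correction
    ),
    class = "hedri_screening_config"
  )
}

#' Cross-tabulate one item against the outcome
#'
#' Builds the exposure-by-outcome 2x2 table for one item within one split:
#' `a` = exposed with event, `b` = exposed without, `c` = unexposed with
#' event, `d` = unexposed without.
#'
#' @param dataset Cohort data frame with a filled `split` column.
#' @param item_id Item column to tabulate.
#' @param split_label Which split to use (`"derivation"`, `"validation"`, or
#'   any label present; `"all"` uses every record).
#' @return Named integer vector `c(a, b, c, d)` of class `two_by_two`.
#' @export
build_table <- function(dataset, item_id, split_label = "derivation") {
  if (!item_id %in% item_columns(dataset)) {
    stop_data(paste0("unknown item: ", item_id))
  }
  sub <- if (identical(split_label, "all")) dataset
         else dataset[dataset$split == split_label, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_data(paste0("no records in split '", split_label, "'"))
  }
  x <- sub[[item_id]]
  y <- sub$outcome
  tab <- c(
    a = sum(x == 1 & y == 1),
    b = sum(x == 1 & y == 0),
    c = sum(x == 0 & y == 1),
    d = sum(x == 0 & y == 0)
  )
  structure(as.integer(tab), names = names(tab), class = "two_by_two")
}

#' Odds ratio of a 2x2 table
#'
#' Computes the cross-product odds ratio `(a d) / (b c)`. When any cell is
#' zero, the configured continuity correction is added to all four cells
#' first. A table of four zeros has no defined odds ratio and raises an
#' error, as does a table whose corrected off-diagonal product is zero.
#'
#' @param table Named vector/list with cells `a`, `b`, `c`, `d`.
#' @param config A [screening_config()].
#' @return The odds ratio (positive real).
#' @export
odds_ratio <- function(table, config = screening_config()) {
  cells <- unlist(table)[c("a", "b", "c", "d")]
  if (anyNA(cells) || any(cells < 0)) {
    stop_data("2x2 table must have non-negative cells a, b, c, d")
  }
  if (sum(cells) == 0) {
    stop_data("odds ratio undefined: all four cells are zero")
  }
  if (any(cells == 0)) {
    cells <- cells + config$continuity_correction
  }
  denom <- cells["b"] * cells["c"]
  if (denom == 0) {
    stop_data("odds ratio undefined: zero off-diagonal product after correction")
  }
  unname((cells["a"] * cells["d"]) / denom)
}

#' Classify one item from its derivation and validation odds ratios
#'
#' `risk` when both ORs meet or exceed the risk threshold, `protective` when
#' both are at or below the protective threshold, otherwise `neutral`. With
#' `require_validation_confirmation = FALSE` only the derivation OR is used.
#'
#' @param or_derivation,or_validation Odds ratios in the two samples.
#' @param config A [screening_config()].
#' @return One of `"risk"`, `"protective"`, `"neutral"`.
#' @export
classify_item <- function(or_derivation, or_validation,
                          config = screening_config()) {
  ors <- c(or_derivation, or_validation)
  if (!all(is.finite(ors)) || any(ors <= 0)) {
    stop_data("odds ratios must be positive and finite")
  }
  if (!config$require_validation_confirmation) {
    ors <- ors[1]
  }
  if (all(ors >= config$risk_threshold)) {
    "risk"
  } else if (all(ors <= config$protective_threshold)) {
    "protective"
  } else {
    "neutral"
  }
}

# Vectorized per-split odds ratios for all items at once. Returns NA for
# items whose OR is undefined (e.g. constant item with no events among the
# exposed and correction 0).
or_by_item <- function(dataset, items, split_label, config) {
  sub <- dataset[dataset$split == split_label, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_data(paste0("no records in split '", split_label, "'"))
  }
  x <- as.matrix(sub[items])
  y <- sub$outcome
  a <- as.vector(crossprod(x, y))
  exposed <- colSums(x)
  b <- exposed - a
  cc <- sum(y) - a
  dd <- nrow(sub) - exposed - cc
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  corr <- config$continuity_correction
  a[zero] <- a[zero] + corr
  b[zero] <- b[zero] + corr
  cc[zero] <- cc[zero] + corr
  dd[zero] <- dd[zero] + corr
  or <- (a * dd) / (b * cc)
  or[!is.finite(or) | (b * cc) == 0] <- NA_real_
  or
}

#' Screen every catalog item against the follow-up outcome
#'
#' Computes the univariate odds ratio of each item in the derivation and the
#' validation sample and classifies each item as risk, protective, or
#' neutral under the thresholds in `config`. Items whose OR is undefined in
#' either sample are recorded with `NA` and classified neutral rather than
#' raising an error.
#'
#' @param dataset Split cohort data frame.
#' @param catalog Item catalog (only `item_id`/`domain` are used).
#' @param config A [screening_config()].
#' @return Data frame of class `hedri_screening` with columns `item_id`,
#'   `domain`, `or_derivation`, `or_validation`, `classification`.
#' @export
screen_all <- function(dataset, catalog, config = screening_config()) {
  items <- catalog$item_id
  missing_items <- setdiff(items, item_columns(dataset))
  if (length(missing_items) > 0) {
    stop_data(paste0("dataset lacks catalog item(s): ",
                     paste(missing_items, collapse = ", ")))
  }
  or_d <- or_by_item(dataset, items, "derivation", config)
  or_v <- or_by_item(dataset, items, "validation", config)
  cls <- rep("neutral", length(items))
  ok <- is.finite(or_d) & is.finite(or_v)
  use_v <- config$require_validation_confirmation
  is_risk <- ok & or_d >= config$risk_threshold &
    (!use_v | or_v >= config$risk_threshold)
  is_prot <- ok & or_d <= config$protective_threshold &
    (!use_v | or_v <= config$protective_threshold)
  cls[is_risk] <- "risk"
  cls[is_prot] <- "protective"
  out <- data.frame(
    item_id = items,
    domain = catalog$domain,
    or_derivation = or_d,
    or_validation = or_v,
    classification = cls,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hedri_screening", "data.frame")
  out
}

#' @export
print.hedri_screening <- function(x, ...) {
  cat(sprintf(
    "Univariate OR screen: %d items (%d risk, %d protective, %d neutral)\n",
    nrow(x), sum(x$classification == "risk"),
    sum(x$classification == "protective"),
    sum(x$classification == "neutral")
  ))
  flagged <- x[x$classification != "neutral", ]
  if (nrow(flagged) > 0) {
    print.data.frame(flagged, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Default cross-cohort poolability probe items
#'
#' Five widely replicated predictors of hospital/ED use used to check that
#' the same risk forces operate in every cohort before pooling: pneumonia,
#' congestive heart failure, urinary tract infection, an Alzheimer's disease
#' diagnosis (expected protective, OR < 1), and taking nine or more
#' medications.
#'
#' @return Character vector of five item ids from the default catalog.
#' @export
default_probe_items <- function() {
  c("pneumonia", "congestive_heart_failure", "urinary_tract_infection",
    "alzheimers", "nine_plus_medications")
}

#' Cross-cohort poolability check
#'
#' For each probe item, computes the exposure-outcome odds ratio within each
#' cohort and asks whether the ORs lie on the same side of 1.0 in every
#' cohort (directional consistency). If every probe is directionally
#' consistent, the cohorts are judged poolable for the subsequent analyses.
#'
#' @param datasets A single cohort data frame with a `cohort` column, or a
#'   named list of per-cohort data frames.
#' @param probe_items Items to probe; default [default_probe_items()].
#' @param config A [screening_config()] (used for the continuity
#'   correction).
#' @return List of class `hedri_poolability`: `table` (long data frame of
#'   cohort, item_id, odds_ratio), `per_item` (named logical), `verdict`
#'   (single logical).
#' @export
poolability_check <- function(datasets, probe_items = default_probe_items(),
                              config = screening_config()) {
  if (is.data.frame(datasets)) {
    datasets <- split(datasets, datasets$cohort)
  }
  if (length(datasets) < 1) {
    stop_data("need at least one cohort")
  }
  rows <- list()
  for (label in names(datasets)) {
    d <- datasets[[label]]
    missing_items <- setdiff(probe_items, item_columns(d))
    if (length(missing_items) > 0) {
      stop_data(sprintf("cohort '%s' lacks probe item(s): %s",
                        label, paste(missing_items, collapse = ", ")))
    }
    d$split <- "all"
    for (it in probe_items) {
      or <- odds_ratio(build_table(d, it, "all"), config)
      rows[[length(rows) + 1L]] <-
        data.frame(cohort = label, item_id = it, odds_ratio = or,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  per_item <- vapply(probe_items, function(it) {
    ors <- tab$odds_ratio[tab$item_id == it]
    all(ors > 1) || all(ors < 1)
  }, logical(1))
  structure(
    list(table = tab, per_item = per_item, verdict = all(per_item)),
    class = "hedri_poolability"
  )
}

#' @export
print.hedri_poolability <- function(x, ...) {
  cat("Cross-cohort poolability check (directional consistency of probe ORs)\n")
  wide <- stats::reshape(x$table, idvar = "item_id", timevar = "cohort",
                         direction = "wide")
  names(wide) <- sub("^odds_ratio\\.", "", names(wide))
  print.data.frame(wide, digits = 3, row.names = FALSE)
  cat(sprintf("Verdict: %s\n",
              if (x$verdict) "poolable" else "NOT poolable"))
  invisible(x)
}

#' Write a screening result as TSV
#'
#' @param screening A `hedri_screening` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_tsv <- function(screening, path) {
  utils::write.table(screening, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a screening result as JSON
#'
#' @param screening A `hedri_screening` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_json <- function(screening, path) {
  jsonlite::write_json(as.data.frame(screening), path, digits = NA,
                       na = "null")
  invisible(path)
}
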