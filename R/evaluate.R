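# Declared level sets for the orderable stratifiers; item-id stratifiers are
# 0/1 subgroup indicators.
stratifier_levels <- function(scored, s) {
  switch(s,
    category = 0:max(6, scored$category, na.rm = TRUE),
    extended_category = 0:12,
    prior_use = 0:1,
    cohort = sort(unique(scored$cohort)),
    sort(unique(scored[[s]]))  # item-as-disease subgroup: observed values
  )
}

#' Stratified follow-up event rates
#'
#' Cross-tabulates the follow-up hospital/ED outcome over any combination of
#' stratifiers: index `category`, `extended_category`, `cohort`,
#' `prior_use`, or any item id (a disease-defined subgroup indicator). The
#' full crossing is reported, so empty strata appear with `n = 0` and an
#' undefined (`NA`) rate.
#'
#' @param scored A scored cohort, see [apply_index()].
#' @param by Non-empty character vector of stratifiers.
#' @return Data frame of class `hedri_rates`: one stratifier column per
#'   entry of `by`, plus `n`, `events`, `rate`.
#' @export
rates_by <- function(scored, by) {
  if (length(by) == 0) {
    stop_data("at least one stratifier is required")
  }
  known <- c("category", "extended_category", "cohort", "prior_use")
  bad <- setdiff(by, c(known, names(scored)))
  if (length(bad) > 0) {
    stop_data(paste0("unknown stratifier(s): ", paste(bad, collapse = ", ")))
  }
  missing_cols <- setdiff(by, names(scored))
  if (length(missing_cols) > 0) {
    stop_data(paste0("scored dataset lacks column(s): ",
                     paste(missing_cols, collapse = ", "),
                     " (apply_index() first?)"))
  }
  facs <- lapply(by, function(s)
    factor(scored[[s]], levels = stratifier_levels(scored, s)))
  names(facs) <- by
  n <- as.data.frame(table(facs), stringsAsFactors = FALSE)
  names(n)[ncol(n)] <- "n"
  ev <- as.data.frame(table(lapply(facs, function(f) f[scored$outcome == 1])),
                      stringsAsFactors = FALSE)
  names(ev)[ncol(ev)] <- "events"
  out <- merge(n, ev, by = by, sort = FALSE)
  # restore declared ordering of the crossing
  for (s in rev(by)) {
    out <- out[order(match(out[[s]], as.character(stratifier_levels(scored, s)))), ]
  }
  # coerce numeric-looking stratifiers back to integers
  for (s in by) {
    if (s != "cohort") out[[s]] <- as.integer(out[[s]])
  }
  out$rate <- ifelse(out$n > 0, out$events / out$n, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("hedri_rates", "data.frame")
  attr(out, "by") <- by
  attr(out, "total_n") <- nrow(scored)
  out
}

#' @export
print.hedri_rates <- function(x, ...) {
  cat("Follow-up hospital/ED event rates by",
      paste(attr(x, "by"), collapse = " x "), "\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot stratified rates
#'
#' Bar chart of the event rate across an ordered stratifier, one group of
#' bars per level of an optional second stratifier (e.g. rate by index
#' category, grouped by cohort).
#'
#' @param x A `hedri_rates` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hedri_rates <- function(x, ...) {
  by <- attr(x, "by")
  if (length(by) == 1) {
    graphics::barplot(x$rate, names.arg = x[[by]], xlab = by,
                      ylab = "event rate", ...)
  } else {
    m <- tapply(x$rate, x[by[c(2, 1)]], identity)
    graphics::barplot(as.matrix(m), beside = TRUE, xlab = by[1],
                      ylab = "event rate", legend.text = rownames(m), ...)
  }
  invisible(x)
}

#' Check that rates increase along an ordered stratifier
#'
#' Verifies the risk gradient: each successive stratum's rate must be at
#' least the previous rate minus a tolerance. The default tolerance for each
#' adjacent pair is twice the pooled binomial standard error of the
#' difference, so sampling noise in small strata does not flag spurious
#' reversals.
#'
#' @param rates A [rates_by()] result over a single ordered stratifier.
#' @param ordered_stratifier Column to order by (default: the stratifier the
#'   rates were built with).
#' @param tolerance Fixed tolerance overriding the SE-based default.
#' @return List: `ok` (logical verdict) and `violations` (data frame of
#'   adjacent pairs whose drop exceeds the tolerance).
#' @export
monotonicity_report <- function(rates, ordered_stratifier = NULL,
                                tolerance = NULL) {
  by <- attr(rates, "by") %||% names(rates)[1]
  ordered_stratifier <- ordered_stratifier %||% by[1]
  if (!ordered_stratifier %in% names(rates)) {
    stop_data(paste0("no such stratifier column: ", ordered_stratifier))
  }
  r <- rates[rates$n > 0, , drop = FALSE]
  if (nrow(r) < 2) {
    stop_data("need at least 2 non-empty strata")
  }
  r <- r[order(r[[ordered_stratifier]]), , drop = FALSE]
  viol <- list()
  for (i in seq_len(nrow(r) - 1)) {
    n1 <- r$n[i]; n2 <- r$n[i + 1]
    tol <- if (!is.null(tolerance)) tolerance else {
      p <- (r$events[i] + r$events[i + 1]) / (n1 + n2)
      2 * sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    }
    drop_size <- r$rate[i] - r$rate[i + 1]
    if (drop_size > tol) {
      viol[[length(viol) + 1L]] <- data.frame(
        from = r[[ordered_stratifier]][i],
        to = r[[ordered_stratifier]][i + 1],
        drop = drop_size, tolerance = tol
      )
    }
  }
  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(from = integer(), to = integer(), drop = numeric(),
               tolerance = numeric())
  list(ok = length(viol) == 0, violations = violations)
}

#' Average category drop attributable to the protective factors
#'
#' At each raw risk count, compares the mean index category of persons with
#' and without a protective factor; by construction of the subtract-one rule
#' the difference is one category whenever the raw count is at least one
#' (and zero at raw count zero, where the decrement floors). The overall
#' summary is the carrier-weighted mean difference across matched raw
#' counts.
#'
#' @param scored A scored cohort ([apply_index()]).
#' @return List: `by_raw_count` (data frame of raw_count, n_carriers,
#'   n_noncarriers, mean difference), `overall`, `partial` (TRUE when one
#'   group is empty and only a partial report is possible).
#' @export
protective_effect_summary <- function(scored) {
  needed <- c("raw_count", "category", "protective_present")
  if (!all(needed %in% names(scored))) {
    stop_data("scored dataset lacks score columns (apply_index() first?)")
  }
  carriers <- scored[scored$protective_present, , drop = FALSE]
  others <- scored[!scored$protective_present, , drop = FALSE]
  if (nrow(carriers) == 0 || nrow(others) == 0) {
    return(list(
      by_raw_count = data.frame(raw_count = integer(), n_carriers = integer(),
                                n_noncarriers = integer(),
                                mean_difference = numeric()),
      overall = NA_real_,
      partial = TRUE
    ))
  }
  shared <- sort(intersect(carriers$raw_count, others$raw_count))
  rows <- lapply(shared, function(r) {
    mc <- mean(carriers$category[carriers$raw_count == r])
    mo <- mean(others$category[others$raw_count == r])
    data.frame(raw_count = r,
               n_carriers = sum(carriers$raw_count == r),
               n_noncarriers = sum(others$raw_count == r),
               mean_difference = mo - mc)
  })
  by_raw <- do.call(rbind, rows)
  overall <- stats::weighted.mean(by_raw$mean_difference, by_raw$n_carriers)
  list(by_raw_count = by_raw, overall = overall, partial = FALSE)
}

#' Event rates by prior use and index category, with the crossing indicator
#'
#' Reports the full prior-use-by-category rate grid and whether the rate for
#' persons *with* prior hospital/ED use in the lowest risk category exceeds
#' the rate for persons *without* prior use in the top category — the
#' signature of prior utilization as a dominant driver in its own right.
#'
#' @param scored A scored cohort ([apply_index()]).
#' @return List: `grid` (a `hedri_rates` over prior_use x category) and
#'   `crossing` (logical; `NA` when either corner cell is empty).
#' @export
prior_use_comparison <- function(scored) {
  if (!"prior_use" %in% names(scored)) {
    stop_data("scored dataset lacks a prior_use column")
  }
  if (length(unique(scored$prior_use)) < 2) {
    stop_data("both prior-use groups must be non-empty")
  }
  grid <- rates_by(scored, c("prior_use", "category"))
  top <- max(grid$category)
  r_prior_cat0 <- grid$rate[grid$prior_use == 1 & grid$category == 0]
  r_noprior_top <- grid$rate[grid$prior_use == 0 & grid$category == top]
  crossing <- if (anyNA(c(r_prior_cat0, r_noprior_top))) NA else
    r_prior_cat0 > r_noprior_top
  list(grid = grid, crossing = crossing)
}

#' Write a stratified-rate report as TSV
#'
#' @param rates A `hedri_rates` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_tsv <- function(rates, path) {
  utils::write.table(as.data.frame(rates), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stratified-rate report as JSON
#'
#' @param rates A `hedri_rates` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_json <- function(rates, path) {
  jsonlite::write_json(as.data.frame(rates), path, digits = NA, na = "null")
  invisible(path)
}
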