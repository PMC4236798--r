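# Core IRLS (Newton-Raphson with step-halving) for logistic maximum
# likelihood on a dense model matrix. Authored here because the staged
# selection needs tight control over convergence, separation detection and
# repeated refits on column subsets.
irls_core <- function(X, y, tolerance = 1e-8, max_iterations = 100L,
                      separation_bound = 15, start = NULL) {
  n <- nrow(X)
  if (!is.null(start) && length(start) == ncol(X) && all(is.finite(start))) {
    beta <- start
  } else {
    beta <- numeric(ncol(X))
    beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-12), 1e-12))
  }
  loglik <- function(b) {
    eta <- as.vector(X %*% b)
    # numerically stable: log(1+exp(eta)) = max(eta,0) + log1p(exp(-|eta|))
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- as.vector(crossprod(X, y - mu))
    if (max(abs(grad)) <= tolerance) {
      converged <- TRUE
      break
    }
    if (iter >= max_iterations) break
    iter <- iter + 1L
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) {
      stop_degenerate("singular information matrix (collinear covariates?)")
    }
    # step-halving keeps the likelihood ascent monotone; the slack is
    # relative so rounding at large |logLik| cannot trigger futile halving
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10 * (1 + abs(ll))) break
      step <- step / 2
      if (step < 1e-10) {
        cand <- beta
        ll_new <- ll
        break
      }
    }
    beta <- cand
    ll <- ll_new
    if (any(abs(beta) > separation_bound)) {
      stop_separation(paste0(
        "coefficients diverging (|beta| > ", separation_bound,
        "): quasi-complete separation"
      ))
    }
  }
  # observed information at the solution, for standard errors
  mu <- stats::plogis(as.vector(X %*% beta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, log_likelihood = ll, converged = converged,
       n_iterations = iter, vcov = vcov)
}

# Build (X, y) from a cohort data frame for the given covariates/split.
design_matrix <- function(dataset, covariates, split = NULL) {
  sub <- if (is.null(split)) dataset
         else dataset[dataset$split == split, , drop = FALSE]
  if (nrow(sub) < 1) {
    stop_data(paste0("no records", if (!is.null(split))
      paste0(" in split '", split, "'")))
  }
  missing_cov <- setdiff(covariates, names(sub))
  if (length(missing_cov) > 0) {
    stop_data(paste0("unknown covariate(s): ",
                     paste(missing_cov, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sub[, covariates, drop = FALSE]))
  if (length(covariates) > 0) colnames(X) <- c("(Intercept)", covariates)
  list(X = X, y = sub$outcome)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of the follow-up hospital/ED
#' outcome on a set of dichotomous covariates, fitted by Newton-Raphson /
#' IRLS with step-halving. Degenerate designs (constant outcome or constant
#' covariate) and quasi-complete separation (any coefficient diverging past
#' 15 on the log-odds scale) are raised as classed errors.
#'
#' @param dataset Cohort data frame.
#' @param covariates Character vector of item columns (possibly empty for an
#'   intercept-only model).
#' @param split Optional split label to restrict the fit to.
#' @param tolerance Convergence tolerance on the max-norm of the score
#'   (gradient) vector.
#' @param max_iterations IRLS iteration cap.
#' @return An object of class `hedri_logit` with components `coefficients`,
#'   `covariates`, `converged`, `n_iterations`, `log_likelihood`, `n`,
#'   `vcov`.
#' @export
fit_logistic <- function(dataset, covariates = character(), split = NULL,
                         tolerance = 1e-8, max_iterations = 100L) {
  dm <- design_matrix(dataset, covariates, split)
  y <- dm$y
  if (length(unique(y)) < 2) {
    stop_degenerate("outcome is constant; logistic model is degenerate")
  }
  const <- covariates[vapply(covariates, function(v)
    length(unique(dm$X[, v])) < 2, logical(1))]
  if (length(const) > 0) {
    stop_degenerate(paste0("constant covariate(s): ",
                           paste(const, collapse = ", ")))
  }
  fit <- irls_core(dm$X, y, tolerance, max_iterations)
  coefs <- stats::setNames(fit$beta, colnames(dm$X))
  structure(
    list(
      coefficients = coefs,
      covariates = covariates,
      converged = fit$converged,
      n_iterations = fit$n_iterations,
      log_likelihood = fit$log_likelihood,
      n = length(y),
      vcov = structure(fit$vcov, dimnames = list(names(coefs), names(coefs)))
    ),
    class = "hedri_logit"
  )
}

#' @export
coef.hedri_logit <- function(object, ...) object$coefficients

#' @export
vcov.hedri_logit <- function(object, ...) object$vcov

#' @export
logLik.hedri_logit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), nobs = object$n,
            class = "logLik")
}

#' Adjusted odds ratios of a fitted logistic model
#'
#' @param model A `hedri_logit`.
#' @return Named vector `exp(beta)` over the covariates (intercept omitted).
#' @export
odds_ratios <- function(model) {
  exp(model$coefficients[setdiff(names(model$coefficients), "(Intercept)")])
}

#' @export
predict.hedri_logit <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  dm <- design_matrix(newdata, object$covariates)
  eta <- as.vector(dm$X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.hedri_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic model (IRLS): %d covariate(s), n = %d, logLik = %.3f%s\n",
    length(x$covariates), x$n, x$log_likelihood,
    if (x$converged) "" else "  [NOT converged]"
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.hedri_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- data.frame(
    estimate = object$coefficients,
    odds_ratio = exp(object$coefficients),
    std_error = se,
    z_value = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
  structure(list(coefficients = tab, model = object),
            class = "summary.hedri_logit")
}

#' @export
print.summary.hedri_logit <- function(x, ...) {
  print(x$model)
  cat("\nCoefficient table:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stepwise selection configuration
#'
#' Parameters of the staged forward selection: stage 1 considers only the
#' three clinically central domains (clinical complications, diseases,
#' specialized treatments); stage 2 offers the remaining six domains to the
#' surviving model. Covariate entry is by likelihood-ratio test at
#' `entry_alpha`; after every entry, any covariate whose adjusted odds ratio
#' falls below `retention_or_threshold` (or above its reciprocal, for
#' protective candidates) in the derivation model or in the same covariate
#' set refit on the validation sample is dropped.
#'
#' @param stage1_domains Domains eligible in stage 1.
#' @param stage2_domains Domains added in stage 2.
#' @param retention_or_threshold Multivariate OR a risk covariate must reach
#'   in both samples to stay in the model (default 1.2); protective
#'   covariates must stay at or below its reciprocal.
#' @param entry_alpha Likelihood-ratio entry significance level.
#' @param max_terms Cap on the number of covariates.
#' @param tolerance,max_iterations Passed to the IRLS fitter.
#' @param validation_rule `"refit"` re-estimates the current covariate set on
#'   the validation sample for the retention check; `"derivation_only"`
#'   checks the derivation fit alone.
#' @return A list of class `hedri_selection_config`.
#' @export
selection_config <- function(stage1_domains = c("clinical_complication",
                                                "disease", "treatment"),
                             stage2_domains = setdiff(ITEM_DOMAINS,
                                                      stage1_domains),
                             retention_or_threshold = 1.2,
                             entry_alpha = 0.05,
                             max_terms = Inf,
                             tolerance = 1e-8,
                             max_iterations = 100L,
                             validation_rule = c("refit", "derivation_only")) {
  if (!(retention_or_threshold > 1)) {
    stop_config("retention_or_threshold must exceed 1")
  }
  if (!(entry_alpha > 0 && entry_alpha < 1)) {
    stop_config("entry_alpha must lie strictly between 0 and 1")
  }
  structure(
    list(
      stage1_domains = stage1_domains,
      stage2_domains = stage2_domains,
      retention_or_threshold = retention_or_threshold,
      entry_alpha = entry_alpha,
      max_terms = max_terms,
      tolerance = tolerance,
      max_iterations = max_iterations,
      validation_rule = match.arg(validation_rule)
    ),
    class = "hedri_selection_config"
  )
}

#' Staged stepwise logistic selection with dual-sample retention
#'
#' Forward stepwise logistic regression over the screened candidate items,
#' run in two stages by domain, with the dual-sample retention rule: after
#' each entry, every covariate must hold a multivariate odds ratio of at
#' least `retention_or_threshold` (for risk candidates; at most its
#' reciprocal for protective candidates) in the derivation fit and in the
#' validation refit, or it is dropped and barred from re-entry. The selection
#' trace records every entry and drop.
#'
#' @param dataset Cohort data frame with non-empty derivation and validation
#'   splits.
#' @param candidates Data frame with columns `item_id`, `domain`,
#'   `classification` (`"risk"`/`"protective"`), typically the flagged rows
#'   of a [screen_all()] result. A `hedri_screening` object may be passed
#'   directly; its neutral rows are ignored.
#' @param config A [selection_config()].
#' @return Object of class `c("hedri_stepwise", "hedri_logit")`: the final
#'   model fit on the derivation sample, plus `validation` (the same
#'   covariate set refit on validation), `or_derivation`, `or_validation`,
#'   `trace` (data frame of selection events) and `empty_pool`.
#' @export
stepwise_select <- function(dataset, candidates,
                            config = selection_config()) {
  if (inherits(candidates, "hedri_screening")) {
    candidates <- candidates[candidates$classification != "neutral",
                             c("item_id", "domain", "classification")]
  }
  candidates <- as.data.frame(candidates)
  der <- dataset[dataset$split == "derivation", , drop = FALSE]
  val <- dataset[dataset$split == "validation", , drop = FALSE]
  if (nrow(der) == 0 || nrow(val) == 0) {
    stop_data("both derivation and validation splits must be non-empty")
  }
  if (length(unique(der$outcome)) < 2 || length(unique(val$outcome)) < 2) {
    stop_degenerate("outcome is constant within a split; design is degenerate")
  }
  role <- stats::setNames(candidates$classification, candidates$item_id)
  items <- candidates$item_id
  # drop candidates that are constant in either split (unfittable)
  usable <- vapply(items, function(it)
    length(unique(der[[it]])) > 1 && length(unique(val[[it]])) > 1,
    logical(1))
  items <- items[usable]

  y_der <- der$outcome
  y_val <- val$outcome
  X_der <- cbind(`(Intercept)` = 1, as.matrix(der[, items, drop = FALSE]))
  X_val <- cbind(`(Intercept)` = 1, as.matrix(val[, items, drop = FALSE]))
  if (length(items) > 0) {
    colnames(X_der) <- colnames(X_val) <- c("(Intercept)", items)
  }
  fit_on <- function(X, y, covs, start = NULL) {
    irls_core(X[, c("(Intercept)", covs), drop = FALSE], y,
              config$tolerance, config$max_iterations, start = start)
  }

  current <- character()
  excluded <- character()
  trace <- list()
  note <- function(stage, action, item, lr = NA_real_, p = NA_real_,
                   or_d = NA_real_, or_v = NA_real_, reason = "") {
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, action = action, item = item, lr_stat = lr,
      p_value = p, or_derivation = or_d, or_validation = or_v,
      reason = reason, stringsAsFactors = FALSE
    )
  }
  retained_or_ok <- function(or, item) {
    thr <- config$retention_or_threshold
    if (identical(role[[item]], "protective")) or <= 1 / thr else or >= thr
  }

  prune <- function(stage) {
    repeat {
      if (length(current) == 0) return(invisible(NULL))
      fd <- fit_on(X_der, y_der, current)
      or_d <- stats::setNames(exp(fd$beta[-1]), current)
      if (config$validation_rule == "refit") {
        fv <- tryCatch(fit_on(X_val, y_val, current),
                       error = function(e) NULL)
        or_v <- if (is.null(fv)) or_d else
          stats::setNames(exp(fv$beta[-1]), current)
      } else {
        or_v <- or_d
      }
      fails <- current[!vapply(current, function(it)
        retained_or_ok(or_d[[it]], it) && retained_or_ok(or_v[[it]], it),
        logical(1))]
      if (length(fails) == 0) return(invisible(NULL))
      for (it in fails) {
        note(stage, "drop", it, or_d = or_d[[it]], or_v = or_v[[it]],
             reason = sprintf(
               "multivariate OR outside retention rule (threshold %.3g)",
               config$retention_or_threshold))
      }
      current <<- setdiff(current, fails)
      excluded <<- union(excluded, fails)
    }
  }

  run_stage <- function(stage, domains) {
    pool <- items[candidates$domain[match(items, candidates$item_id)] %in% domains]
    repeat {
      avail <- setdiff(pool, c(current, excluded))
      if (length(avail) == 0 || length(current) >= config$max_terms) break
      base_fit <- fit_on(X_der, y_der, current)
      base_ll <- base_fit$log_likelihood
      lr <- vapply(avail, function(it) {
        f <- tryCatch(
          fit_on(X_der, y_der, c(current, it), start = c(base_fit$beta, 0)),
          error = function(e) NULL
        )
        if (is.null(f)) NA_real_ else 2 * (f$log_likelihood - base_ll)
      }, numeric(1))
      pv <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
      ok <- which(!is.na(pv) & pv < config$entry_alpha)
      if (length(ok) == 0) break
      best <- ok[which.max(lr[ok])]
      note(stage, "enter", avail[best], lr = lr[best], p = pv[best])
      current <<- c(current, avail[best])
      prune(stage)
    }
  }

  if (length(items) > 0) {
    run_stage("stage1", config$stage1_domains)
    run_stage("stage2", config$stage2_domains)
  }

  final <- fit_logistic(der, current, tolerance = config$tolerance,
                        max_iterations = config$max_iterations)
  or_d <- odds_ratios(final)
  if (length(current) > 0) {
    vfit <- fit_logistic(val, current, tolerance = config$tolerance,
                         max_iterations = config$max_iterations)
    or_v <- odds_ratios(vfit)
  } else {
    vfit <- NULL
    or_v <- stats::setNames(numeric(0), character(0))
  }
  final$classification <- role[current]
  final$validation <- vfit
  final$or_derivation <- or_d
  final$or_validation <- or_v
  final$trace <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(stage = character(), action = character(), item = character(),
               lr_stat = numeric(), p_value = numeric(),
               or_derivation = numeric(), or_validation = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  final$empty_pool <- length(items) == 0
  class(final) <- c("hedri_stepwise", class(final))
  final
}

#' @export
print.hedri_stepwise <- function(x, ...) {
  cat("Staged stepwise logistic selection (dual-sample retention)\n")
  if (length(x$covariates) == 0) {
    cat("Final model: intercept only",
        if (x$empty_pool) " (empty candidate pool)\n" else "\n", sep = "")
  } else {
    cat(sprintf("Final model: %d covariate(s), n = %d\n",
                length(x$covariates), x$n))
    tab <- data.frame(
      item = x$covariates,
      or_derivation = unname(x$or_derivation[x$covariates]),
      or_validation = unname(x$or_validation[x$covariates])
    )
    print.data.frame(tab, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a fitted (stepwise) model as JSON
#'
#' Writes covariates, intercept, log-odds coefficients, derivation and
#' validation odds ratios, convergence state, and (for stepwise fits) the
#' full selection trace.
#'
#' @param model A `hedri_logit` or `hedri_stepwise`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  out <- list(
    covariates = model$covariates,
    intercept = unname(model$coefficients["(Intercept)"]),
    betas = as.list(model$coefficients[model$covariates]),
    or_derivation = as.list(exp(model$coefficients[model$covariates])),
    converged = model$converged,
    n_iterations = model$n_iterations,
    log_likelihood = model$log_likelihood,
    n = model$n
  )
  if (!is.null(model$or_validation)) {
    out$or_validation <- as.list(model$or_validation)
  }
  if (!is.null(model$trace)) {
    out$selection_trace <- model$trace
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
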