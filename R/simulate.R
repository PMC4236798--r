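# Target follow-up hospital/ED event rates for the six default cohorts; the
# spread (not the individual values) is what the synthetic populations emulate.
DEFAULT_COHORT_RATES <- c(
  massachusetts = 0.27, michigan = 0.29, finland = 0.33,
  ontario = 0.35, manitoba = 0.39, georgia = 0.41
)

#' Simulation configuration for a synthetic multi-cohort home-care population
#'
#' Bundles everything the generator needs: the item catalog (with the planted
#' per-item effects), the cohort structure (each cohort has its own baseline
#' log-odds intercept, producing the cross-cohort spread of event rates), the
#' prior hospital/ED-use mechanism, and a master seed.
#'
#' When `cohorts` is omitted, six cohorts are built whose baseline intercepts
#' are calibrated (first-order, by subtracting the expected planted linear
#' predictor) so realized event rates spread over roughly 0.27-0.41.
#'
#' @param n_persons Number of persons to generate.
#' @param catalog An item catalog, see [item_catalog()].
#' @param cohorts Data frame with columns `label`, `alpha` (log-odds
#'   intercept) and `weight` (sampling proportions summing to 1), or `NULL`
#'   for the calibrated six-cohort default.
#' @param beta_prior_use Log-odds effect of prior hospital/ED use on the
#'   follow-up outcome. Default `log(4)`: prior utilization is by far the
#'   strongest single driver of subsequent use.
#' @param prior_use_prevalence Probability of the baseline prior-use flag.
#' @param age_range Integer range of ages; the lower bound must be at least
#'   60 (the population is home-care clients aged 60+).
#' @param domain_correlation Optional within-domain tetrachoric-style
#'   correlation, induced by a shared latent Gaussian factor per domain.
#'   0 (the default) generates items independently.
#' @param seed Master seed; all per-stage seeds are derived from it.
#' @return A list of class `hedri_sim_config`.
#' @export
sim_config <- function(n_persons,
                       catalog = default_catalog(),
                       cohorts = NULL,
                       beta_prior_use = log(4),
                       prior_use_prevalence = 0.45,
                       age_range = c(60L, 100L),
                       domain_correlation = 0,
                       seed = 1L) {
  if (length(n_persons) != 1 || is.na(n_persons) || n_persons < 1 ||
      n_persons != round(n_persons)) {
    stop_config("n_persons must be a positive integer")
  }
  if (!inherits(catalog, "hedri_catalog")) {
    catalog <- item_catalog(catalog)
  }
  if (!is.finite(beta_prior_use)) {
    stop_config("beta_prior_use must be finite")
  }
  if (!(prior_use_prevalence > 0 && prior_use_prevalence < 1)) {
    stop_config("prior_use_prevalence must lie strictly between 0 and 1")
  }
  if (length(age_range) != 2 || age_range[1] < 60 || age_range[2] < age_range[1]) {
    stop_config("age_range must be [lo, hi] with lo >= 60 and hi >= lo")
  }
  if (!(domain_correlation >= 0 && domain_correlation < 1)) {
    stop_config("domain_correlation must lie in [0, 1)")
  }
  if (is.null(cohorts)) {
    offset <- sum(catalog$true_beta * catalog$prevalence) +
      beta_prior_use * prior_use_prevalence
    cohorts <- data.frame(
      label = names(DEFAULT_COHORT_RATES),
      alpha = stats::qlogis(unname(DEFAULT_COHORT_RATES)) - offset,
      weight = rep(1 / length(DEFAULT_COHORT_RATES), length(DEFAULT_COHORT_RATES)),
      stringsAsFactors = FALSE
    )
  }
  cohorts <- as.data.frame(cohorts)
  if (!all(c("label", "alpha", "weight") %in% names(cohorts))) {
    stop_config("cohorts must have columns label, alpha, weight")
  }
  if (!all(is.finite(cohorts$alpha))) {
    stop_config("cohort alpha must be finite")
  }
  if (anyDuplicated(cohorts$label)) {
    stop_config("cohort labels must be unique")
  }
  if (abs(sum(cohorts$weight) - 1) > 1e-8 || any(cohorts$weight <= 0)) {
    stop_config("cohort weights must be positive and sum to 1")
  }
  structure(
    list(
      n_persons = as.integer(n_persons),
      catalog = catalog,
      cohorts = cohorts,
      beta_prior_use = beta_prior_use,
      prior_use_prevalence = prior_use_prevalence,
      age_range = as.integer(age_range),
      domain_correlation = domain_correlation,
      seed = as.integer(seed)
    ),
    class = "hedri_sim_config"
  )
}

#' Generate a synthetic multi-cohort home-care dataset
#'
#' Draws `n_persons` assessment records. Each dichotomous item is Bernoulli
#' with its catalog prevalence (optionally correlated within domain through a
#' shared latent Gaussian factor); the prior-use flag is an independent
#' Bernoulli; and the follow-up hospital/ED outcome is Bernoulli with
#' \deqn{logit P(Y=1) = \alpha_{cohort} + \sum_j \beta_j x_j +
#'   \beta_{prior} \cdot prior}
#' using the planted catalog effects. Generation is reproducible: every
#' stochastic stage uses a child seed derived deterministically from
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A data frame with columns `person_id`, `cohort`, `age`,
#'   `prior_use`, `outcome`, `split` (initially `"unassigned"`), followed by
#'   one 0/1 column per catalog item.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hedri_sim_config")) {
    stop_config("config must be a hedri_sim_config (see sim_config())")
  }
  n <- config$n_persons
  cat <- config$catalog
  p <- nrow(cat)

  set.seed(child_seed(config$seed, "cohort"))
  cohort <- sample(config$cohorts$label, n, replace = TRUE,
                   prob = config$cohorts$weight)

  set.seed(child_seed(config$seed, "age"))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)

  set.seed(child_seed(config$seed, "items"))
  rho <- config$domain_correlation
  if (rho == 0) {
    x <- matrix(runif(n * p), nrow = n) <
      matrix(cat$prevalence, nrow = n, ncol = p, byrow = TRUE)
    storage.mode(x) <- "integer"
  } else {
    # shared latent factor per domain: item latent = sqrt(rho) z_dom +
    # sqrt(1-rho) eps, thresholded at the normal quantile of the prevalence
    domains <- unique(cat$domain)
    z <- matrix(stats::rnorm(n * length(domains)), nrow = n,
                dimnames = list(NULL, domains))
    x <- matrix(0L, nrow = n, ncol = p)
    for (j in seq_len(p)) {
      latent <- sqrt(rho) * z[, cat$domain[j]] + sqrt(1 - rho) * stats::rnorm(n)
      x[, j] <- as.integer(latent < stats::qnorm(cat$prevalence[j]))
    }
  }
  colnames(x) <- cat$item_id

  set.seed(child_seed(config$seed, "prior"))
  prior_use <- as.integer(runif(n) < config$prior_use_prevalence)

  alpha <- config$cohorts$alpha[match(cohort, config$cohorts$label)]
  eta <- alpha + as.vector(x %*% cat$true_beta) +
    config$beta_prior_use * prior_use
  set.seed(child_seed(config$seed, "outcome"))
  outcome <- as.integer(runif(n) < stats::plogis(eta))

  out <- data.frame(
    person_id = sprintf("p%07d", seq_len(n)),
    cohort = cohort,
    age = age,
    prior_use = prior_use,
    outcome = outcome,
    split = "unassigned",
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(x))
}

#' Split a cohort into derivation and validation samples
#'
#' Randomly labels `round(fraction * n)` records as the derivation sample and
#' the remainder as validation, mirroring the two-thirds / one-third split
#' used to derive and then re-test the risk model. Assignment depends only on
#' the seed, never on outcomes or items.
#'
#' @param dataset Cohort data frame (any data frame with one row per person).
#' @param fraction Derivation fraction, strictly between 0 and 1.
#' @param seed Seed for the assignment.
#' @return The dataset with its `split` column filled with
#'   `"derivation"`/`"validation"`.
#' @export
split_derivation_validation <- function(dataset, fraction = 2 / 3, seed = 1L) {
  if (!(length(fraction) == 1 && fraction > 0 && fraction < 1)) {
    stop_config("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(dataset)
  if (n < 2) {
    stop_data("need at least 2 records to split")
  }
  n_der <- round(fraction * n)
  n_der <- min(max(n_der, 1L), n - 1L)  # both samples non-empty
  set.seed(child_seed(seed, "split"))
  idx <- sample.int(n, n_der)
  split <- rep("validation", n)
  split[idx] <- "derivation"
  dataset$split <- split
  dataset
}
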