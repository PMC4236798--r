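test_that("the univariate logistic MLE equals the 2x2 cross-product odds ratio", {
  d <- dataset_from_table(20, 10, 40, 80)
  fit <- fit_logistic(d, "x", split = "derivation")
  expect_true(fit$converged)
  expect_equal(unname(exp(coef(fit)["x"])), 4.0, tolerance = 1e-6)
})

test_that("the intercept-only fit is the logit of the outcome mean", {
  d <- make_dataset(data.frame(x = rep(0:1, 10)), rep(c(1, 0, 0, 0), 5))
  fit <- fit_logistic(d)
  expect_equal(unname(coef(fit)), qlogis(0.25), tolerance = 1e-8)
  expect_equal(fit$log_likelihood,
               20 * (0.25 * log(0.25) + 0.75 * log(0.75)),
               tolerance = 1e-8)
})

test_that("degenerate designs and perfect separation raise classed errors", {
  d <- make_dataset(data.frame(x = rep(0:1, 10)), rep(1L, 20))
  expect_error(fit_logistic(d, "x"), class = "hedri_degenerate_error")
  d2 <- make_dataset(data.frame(x = rep(1L, 20)), rep(0:1, 10))
  expect_error(fit_logistic(d2, "x"), class = "hedri_degenerate_error")
  # covariate identical to outcome: quasi-complete separation
  y <- rep(0:1, 15)
  d3 <- make_dataset(data.frame(x = y), y)
  expect_error(fit_logistic(d3, "x"), class = "hedri_separation_error")
})

test_that("IRLS matches direct likelihood maximization and glm on random data", {
  set.seed(202)
  for (k in 1:25) {
    n <- sample(30:200, 1)
    p <- sample(1:3, 1)
    d <- random_small_dataset(n, n_cov = p)
    covs <- paste0("x", seq_len(p))
    fit <- tryCatch(fit_logistic(d, covs),
                    hedri_data_error = function(e) NULL)
    if (is.null(fit)) next  # separated or collinear draw
    X <- cbind(1, as.matrix(d[covs]))
    expect_equal(unname(coef(fit)), oracle_logit(X, d$outcome),
                 tolerance = 1e-5)
    gfit <- glm(reformulate(covs, "outcome"), binomial(), data = d)
    expect_equal(unname(coef(fit)), unname(coef(gfit)), tolerance = 1e-6)
    expect_equal(fit$log_likelihood, as.numeric(logLik(gfit)),
                 tolerance = 1e-8)
  }
})

test_that("predict returns fitted probabilities consistent with coefficients", {
  set.seed(9)
  d <- random_small_dataset(80, n_cov = 2)
  fit <- fit_logistic(d, c("x1", "x2"))
  eta <- coef(fit)[1] + coef(fit)[2] * d$x1 + coef(fit)[3] * d$x2
  expect_equal(predict(fit, d, type = "link"), unname(eta))
  expect_equal(predict(fit, d, type = "response"), unname(plogis(eta)))
})

test_that("stepwise selection recovers planted items among null candidates", {
  cat23 <- tiny_catalog(n_risk = 3, n_protective = 0, n_null = 20,
                        risk_or = 2, prevalence = 0.25)
  cfg <- sim_config(20000, catalog = cat23,
                    cohorts = data.frame(label = "one", alpha = qlogis(0.25),
                                         weight = 1),
                    beta_prior_use = 0, seed = 11)
  d <- split_derivation_validation(generate_cohort(cfg), 1 / 2, seed = 11)
  candidates <- data.frame(
    item_id = cat23$item_id, domain = cat23$domain,
    classification = "risk", stringsAsFactors = FALSE
  )
  m <- stepwise_select(d, candidates)
  expect_setequal(m$covariates, cat23$item_id[1:3])
  # every forward entry strictly increased the derivation log-likelihood
  entries <- m$trace[m$trace$action == "enter", ]
  expect_true(all(entries$lr_stat > 0))
})

test_that("an empty candidate pool yields a flagged intercept-only model", {
  set.seed(12)
  d <- random_small_dataset(60, n_cov = 1)
  d$split[1:30] <- "validation"
  empty <- data.frame(item_id = character(), domain = character(),
                      classification = character(), stringsAsFactors = FALSE)
  m <- stepwise_select(d, empty)
  expect_true(m$empty_pool)
  expect_length(m$covariates, 0)
  expect_named(coef(m), "(Intercept)")
})

test_that("the dual-sample retention rule excludes split-inconsistent items", {
  # item planted with an effect only in the derivation half
  cat2 <- tiny_catalog(n_risk = 1, n_protective = 0, n_null = 1,
                       risk_or = 1.6, prevalence = 0.25)
  null_cat <- cat2
  null_cat$true_beta[1] <- 0
  cohorts <- data.frame(label = "one", alpha = qlogis(0.3), weight = 1)
  der <- generate_cohort(sim_config(20000, catalog = cat2, cohorts = cohorts,
                                    beta_prior_use = 0, seed = 21))
  val <- generate_cohort(sim_config(20000, catalog = null_cat,
                                    cohorts = cohorts, beta_prior_use = 0,
                                    seed = 22))
  der$split <- "derivation"
  val$split <- "validation"
  val$person_id <- paste0("v", val$person_id)
  d <- rbind(der, val)
  candidates <- data.frame(item_id = cat2$item_id[1],
                           domain = cat2$domain[1],
                           classification = "risk", stringsAsFactors = FALSE)
  m <- stepwise_select(d, candidates)
  expect_length(m$covariates, 0)
  drops <- m$trace[m$trace$action == "drop", ]
  expect_true(cat2$item_id[1] %in% drops$item)
})

test_that("protective candidates are retained through the reciprocal threshold", {
  cat3 <- tiny_catalog(n_risk = 1, n_protective = 1, n_null = 0,
                       risk_or = 2, protective_or = 0.6, prevalence = 0.25)
  cfg <- sim_config(30000, catalog = cat3,
                    cohorts = data.frame(label = "one", alpha = qlogis(0.35),
                                         weight = 1),
                    beta_prior_use = 0, seed = 31)
  d <- split_derivation_validation(generate_cohort(cfg), 1 / 2, seed = 31)
  candidates <- data.frame(
    item_id = cat3$item_id[1:2], domain = cat3$domain[1:2],
    classification = c("risk", "protective"), stringsAsFactors = FALSE
  )
  m <- stepwise_select(d, candidates)
  expect_setequal(m$covariates, cat3$item_id[1:2])
  expect_lt(m$or_derivation[[cat3$item_id[2]]], 1 / 1.2)
})

test_that("stage structure is respected: stage-2 domains enter after stage 1", {
  cat4 <- item_catalog(data.frame(
    item_id = c("s1a", "s1b", "s2a"),
    domain = c("clinical_complication", "disease", "services"),
    true_beta = log(c(1.8, 1.8, 0.55)),
    prevalence = 0.25
  ))
  cfg <- sim_config(30000, catalog = cat4,
                    cohorts = data.frame(label = "one", alpha = qlogis(0.35),
                                         weight = 1),
                    beta_prior_use = 0, seed = 41)
  d <- split_derivation_validation(generate_cohort(cfg), 1 / 2, seed = 41)
  candidates <- data.frame(
    item_id = cat4$item_id, domain = cat4$domain,
    classification = c("risk", "risk", "protective"),
    stringsAsFactors = FALSE
  )
  m <- stepwise_select(d, candidates)
  entries <- m$trace[m$trace$action == "enter", ]
  expect_setequal(m$covariates, cat4$item_id)
  s1 <- which(entries$stage == "stage1")
  s2 <- which(entries$stage == "stage2")
  expect_true(max(s1) < min(s2))
  expect_equal(entries$item[entries$stage == "stage2"], "s2a")
})

test_that("models serialize to JSON with the selection trace", {
  set.seed(13)
  items <- data.frame(x1 = rbinom(400, 1, 0.4), x2 = rbinom(400, 1, 0.3))
  y <- rbinom(400, 1, plogis(-1 + 1.3 * items$x1))
  d <- make_dataset(items, y)
  d$split[sample(400, 200)] <- "validation"
  candidates <- data.frame(item_id = c("x1", "x2"),
                           domain = "disease", classification = "risk",
                           stringsAsFactors = FALSE)
  m <- stepwise_select(d, candidates)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$covariates, m$covariates)
  expect_equal(back$intercept, unname(coef(m)["(Intercept)"]),
               tolerance = 1e-12)
  expect_true(is.data.frame(back$selection_trace) ||
                length(back$selection_trace) == 0)
})
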