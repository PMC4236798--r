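# Shared fixtures and independent oracles for the test suite. All fixtures
# are built in code; nothing is read from disk.

# A small catalog: n_risk elevated items, n_protective protective, n_null
# null, spread over the three stage-1 domains plus services.
tiny_catalog <- function(n_risk = 2, n_protective = 1, n_null = 3,
                         risk_or = 2, protective_or = 0.6,
                         prevalence = 0.2) {
  n <- n_risk + n_protective + n_null
  domains <- rep(c("clinical_complication", "disease", "treatment", "services"),
                 length.out = n)
  item_catalog(data.frame(
    item_id = sprintf("it%02d", seq_len(n)),
    domain = domains,
    true_beta = c(rep(log(risk_or), n_risk),
                  rep(log(protective_or), n_protective),
                  rep(0, n_null)),
    prevalence = prevalence,
    stringsAsFactors = FALSE
  ))
}

# Build a cohort data frame directly from item values and outcomes.
make_dataset <- function(items, outcome, prior_use = 0,
                         split = "derivation", cohort = "c1") {
  items <- as.data.frame(items)
  n <- nrow(items)
  cbind(
    data.frame(
      person_id = sprintf("p%04d", seq_len(n)),
      cohort = rep_len(cohort, n),
      age = 70L,
      prior_use = as.integer(rep_len(prior_use, n)),
      outcome = as.integer(outcome),
      split = rep_len(split, n),
      stringsAsFactors = FALSE
    ),
    items
  )
}

# Expand a 2x2 table (a, b, c, d) into person-level records.
dataset_from_table <- function(a, b, c, d, item = "x", split = "derivation") {
  x <- c(rep(1L, a + b), rep(0L, c + d))
  y <- c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d))
  items <- data.frame(x)
  names(items) <- item
  make_dataset(items, y, split = split)
}

# Independent odds-ratio oracle: enumerate records one by one, count the
# four cells, apply the same zero-cell rule by direct arithmetic.
oracle_or <- function(dataset, item, split_label, correction = 0.5) {
  sub <- dataset[dataset$split == split_label, ]
  a <- b <- cc <- d <- 0
  for (i in seq_len(nrow(sub))) {
    x <- sub[[item]][i]
    y <- sub$outcome[i]
    if (x == 1 && y == 1) a <- a + 1
    else if (x == 1 && y == 0) b <- b + 1
    else if (x == 0 && y == 1) cc <- cc + 1
    else d <- d + 1
  }
  if (a == 0 || b == 0 || cc == 0 || d == 0) {
    a <- a + correction; b <- b + correction
    cc <- cc + correction; d <- d + correction
  }
  if (b * cc == 0) return(NA_real_)
  (a * d) / (b * cc)
}

# Independent logistic MLE oracle: direct numerical maximization of the
# log-likelihood with optim(BFGS), no IRLS.
oracle_logit <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Random small dataset with a guaranteed non-degenerate design.
random_small_dataset <- function(n, n_cov = 1) {
  repeat {
    items <- as.data.frame(matrix(rbinom(n * n_cov, 1, runif(1, 0.2, 0.8)),
                                  nrow = n))
    names(items) <- paste0("x", seq_len(n_cov))
    y <- rbinom(n, 1, 0.4)
    ok <- length(unique(y)) == 2 &&
      all(vapply(items, function(v) length(unique(v)) == 2, logical(1)))
    if (ok) return(make_dataset(items, y))
  }
}
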