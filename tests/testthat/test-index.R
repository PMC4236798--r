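make_model <- function(betas) {
  structure(
    list(
      coefficients = c("(Intercept)" = -2, betas),
      covariates = names(betas),
      converged = TRUE, n_iterations = 5L, log_likelihood = -1, n = 100L,
      vcov = diag(length(betas) + 1)
    ),
    class = "hedri_logit"
  )
}

test_that("index definitions are built from model odds ratios", {
  betas <- c(setNames(log(seq(1.5, 2, length.out = 16)),
                      paste0("r", 1:16)),
             setNames(log(c(0.65, 0.7)), c("p1", "p2")))
  def <- build_index_definition(make_model(betas))
  expect_length(def$risk_items, 16)
  expect_setequal(def$protective_items, c("p1", "p2"))

  # no protective covariates -> empty protective list
  def2 <- build_index_definition(make_model(betas[1:3]))
  expect_length(def2$protective_items, 0)

  # OR exactly 1 is ambiguous; intercept-only model has no index
  expect_error(build_index_definition(make_model(c(r1 = 0))),
               class = "hedri_data_error")
  expect_error(build_index_definition(make_model(setNames(numeric(0), character(0)))),
               class = "hedri_data_error")
})

test_that("definition invariants are enforced", {
  expect_error(risk_index_definition(character()), class = "hedri_config_error")
  expect_error(risk_index_definition(c("a", "b"), "a"),
               class = "hedri_config_error")
  expect_error(risk_index_definition("a", "b", cap = 0),
               class = "hedri_config_error")
})

test_that("scoring rules are exact over the full raw/protective/prior grid", {
  def <- risk_index_definition(paste0("r", 1:16), c("p1", "p2"))
  rec <- function(raw, n_prot, prior) {
    r <- as.list(setNames(integer(18), c(paste0("r", 1:16), "p1", "p2")))
    if (raw > 0) r[paste0("r", seq_len(raw))] <- 1L
    if (n_prot > 0) r[paste0("p", seq_len(n_prot))] <- 1L
    r$prior_use <- prior
    r
  }
  for (raw in 0:16) {
    for (n_prot in 0:2) {
      for (prior in 0:1) {
        s <- score(rec(raw, n_prot, prior), def)
        expect_equal(s$raw_count, raw)
        adj <- if (n_prot > 0) max(0, raw - 1) else raw
        expect_equal(s$adjusted, adj)
        expect_equal(s$category, min(adj, 6))
        expect_equal(s$extended_category,
                     if (prior == 1) 7 + min(adj, 5) else min(adj, 6))
        # bounds
        expect_gte(s$adjusted, 0)
        expect_lte(s$adjusted, 16)
        expect_true(s$category %in% 0:6)
        expect_true(s$extended_category %in% 0:12)
      }
    }
  }
  # decrement is idempotent in the number of protective factors
  for (raw in 0:16) {
    for (prior in 0:1) {
      expect_identical(score(rec(raw, 1, prior), def),
                       score(rec(raw, 2, prior), def))
    }
  }
})

test_that("named scoring examples follow the published rules", {
  def <- risk_index_definition(paste0("r", 1:16), c("alz", "day"))
  base <- as.list(setNames(integer(18), c(paste0("r", 1:16), "alz", "day")))
  base$prior_use <- 0L

  r3 <- base; r3[paste0("r", 1:3)] <- 1L; r3$alz <- 1L
  s <- score(r3, def)
  expect_equal(s$raw_count, 3)
  expect_equal(s$adjusted, 2)

  r0 <- base; r0$day <- 1L
  expect_equal(score(r0, def)$adjusted, 0)  # floored, never negative

  r8 <- base; r8[paste0("r", 1:8)] <- 1L; r8$prior_use <- 1L
  s8 <- score(r8, def)
  expect_equal(s8$raw_count, 8)
  expect_equal(s8$category, 6)
  expect_equal(s8$extended_category, 12)
})

test_that("scores are monotone in risk items and antitone in protective items", {
  def <- risk_index_definition(paste0("r", 1:6), "p1", cap = 4)
  set.seed(303)
  fields <- function(s) unlist(s[c("raw_count", "adjusted", "category",
                                   "extended_category")])
  for (k in 1:50) {
    r <- as.list(setNames(rbinom(7, 1, 0.5), c(paste0("r", 1:6), "p1")))
    r$prior_use <- rbinom(1, 1, 0.5)
    s0 <- score(r, def)
    off <- names(which(unlist(r[paste0("r", 1:6)]) == 0))
    if (length(off) > 0) {
      r2 <- r; r2[[sample(off, 1)]] <- 1L
      expect_true(all(fields(score(r2, def)) >= fields(s0)))
    }
    if (r$p1 == 0) {
      r3 <- r; r3$p1 <- 1L
      expect_true(all(fields(score(r3, def)) <= fields(s0)))
    }
  }
})

test_that("score_dataset matches per-record scoring and validates input", {
  def <- risk_index_definition(c("r1", "r2"), "p1", cap = 2)
  items <- data.frame(
    r1 = c(1, 1, 0, 0, 1, 0), r2 = c(1, 0, 0, 1, 1, 0),
    p1 = c(0, 1, 1, 0, 1, 0)
  )
  d <- make_dataset(items, outcome = c(1, 0, 1, 0, 1, 0),
                    prior_use = c(0, 1, 0, 1, 0, 1))
  scores <- score_dataset(d, def)
  expect_equal(nrow(scores), 6)
  expect_equal(scores$person_id, d$person_id)
  for (i in seq_len(6)) {
    s <- score(d[i, ], def)
    expect_equal(scores$raw_count[i], s$raw_count)
    expect_equal(scores$adjusted[i], s$adjusted)
    expect_equal(scores$category[i], s$category)
    expect_equal(scores$extended_category[i], s$extended_category)
  }
  # saturation: all risk items, no protective -> top category everywhere
  d2 <- d
  d2$r1 <- 1L; d2$r2 <- 1L; d2$p1 <- 0L
  expect_true(all(score_dataset(d2, def)$category == 2))
  # empty dataset -> empty scores
  expect_equal(nrow(score_dataset(d[0, ], def)), 0)
  # missing item column and NA values are errors, no imputation
  expect_error(score_dataset(d[, setdiff(names(d), "r2")], def),
               class = "hedri_data_error")
  d3 <- d
  d3$r1[2] <- NA
  expect_error(score_dataset(d3, def), class = "hedri_data_error")
  expect_error(score(list(r1 = 1, p1 = 0, prior_use = 0), def),
               class = "hedri_data_error")
})

test_that("the shipped canonical definition round-trips through JSON", {
  def <- default_index_definition()
  expect_length(def$risk_items, 16)
  expect_setequal(def$protective_items, c("alzheimers", "day_care"))
  expect_equal(def$cap, 6L)
  expect_true(all(c("pneumonia", "urinary_tract_infection", "stasis_ulcer",
                    "falls", "renal_failure", "emphysema", "cancer",
                    "iv_infusion", "daily_nurse_monitoring") %in%
                    def$risk_items))
  # the two configurable slots can be swapped
  def2 <- default_index_definition(slots = c("chest_pain", "oxygen_therapy"))
  expect_true(all(c("chest_pain", "oxygen_therapy") %in% def2$risk_items))
  expect_length(def2$risk_items, 16)

  path <- tempfile(fileext = ".json")
  write_index_json(def, path)
  back <- read_index_json(path)
  expect_equal(back$risk_items, def$risk_items)
  expect_equal(back$protective_items, def$protective_items)
  expect_equal(back$cap, def$cap)
})
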