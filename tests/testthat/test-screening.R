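test_that("2x2 tables are exact cross-tabulations", {
  d <- dataset_from_table(2, 1, 1, 2)
  tab <- build_table(d, "x", "derivation")
  expect_equal(unclass(tab), c(a = 2L, b = 1L, c = 1L, d = 2L),
               ignore_attr = "class")
  expect_error(build_table(d, "nope", "derivation"), class = "hedri_data_error")
  expect_error(build_table(d, "x", "validation"), class = "hedri_data_error")
  # constant-zero item: no exposed persons at all
  d$x <- 0L
  tab0 <- build_table(d, "x", "derivation")
  expect_equal(tab0[["a"]] + tab0[["b"]], 0L)
})

test_that("odds ratios follow the cross-product formula with zero-cell correction", {
  expect_equal(odds_ratio(c(a = 20, b = 10, c = 40, d = 80)), 4.0)
  expect_equal(odds_ratio(c(a = 5, b = 5, c = 5, d = 5)), 1.0)
  # zero cell: 0.5 added to all four cells
  expect_equal(odds_ratio(c(a = 0, b = 10, c = 5, d = 85)),
               (0.5 * 85.5) / (10.5 * 5.5))
  expect_error(odds_ratio(c(a = 0, b = 0, c = 0, d = 0)),
               class = "hedri_data_error")
  # symmetric under simultaneous row and column swap
  expect_equal(odds_ratio(c(a = 7, b = 3, c = 2, d = 11)),
               odds_ratio(c(a = 11, b = 2, c = 3, d = 7)))
})

test_that("screening ORs equal brute-force enumeration on random small datasets", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(4:50, 1)
    d <- random_small_dataset(n)
    got <- odds_ratio(build_table(d, "x1", "derivation"))
    expect_identical(got, oracle_or(d, "x1", "derivation"))
  }
})

test_that("the odds ratio is invariant under record duplication", {
  set.seed(77)
  d <- random_small_dataset(30)
  or1 <- odds_ratio(build_table(d, "x1", "derivation"))
  for (k in c(2, 5)) {
    dk <- d[rep(seq_len(nrow(d)), k), ]
    expect_equal(odds_ratio(build_table(dk, "x1", "derivation")), or1)
  }
})

test_that("items classify by the dual-sample threshold rule", {
  expect_equal(classify_item(1.44, 1.58), "risk")
  expect_equal(classify_item(0.66, 0.67), "protective")
  expect_equal(classify_item(1.45, 1.10), "neutral")
  # thresholds are inclusive: "equaled or exceeded 1.30", ".75 or lower"
  expect_equal(classify_item(1.30, 1.30), "risk")
  expect_equal(classify_item(0.75, 0.75), "protective")
  expect_equal(classify_item(1.299999, 1.5), "neutral")
  expect_equal(classify_item(0.750001, 0.5), "neutral")
  expect_error(classify_item(Inf, 1.2), class = "hedri_data_error")
  # derivation-only switch
  cfg <- screening_config(require_validation_confirmation = FALSE)
  expect_equal(classify_item(1.45, 1.10, cfg), "risk")
})

test_that("screen_all recovers the planted truth at scale", {
  cfg <- sim_config(
    100000, catalog = default_catalog(),
    cohorts = data.frame(label = "pooled", alpha = -2.5, weight = 1),
    seed = 3
  )
  d <- split_derivation_validation(generate_cohort(cfg), 2 / 3, seed = 3)
  scr <- screen_all(d, cfg$catalog)
  truth_risk <- cfg$catalog$item_id[cfg$catalog$true_beta > 0]
  truth_prot <- cfg$catalog$item_id[cfg$catalog$true_beta < 0]
  found_risk <- scr$item_id[scr$classification == "risk"]
  found_prot <- scr$item_id[scr$classification == "protective"]
  expect_gte(sum(truth_risk %in% found_risk), 14)
  expect_setequal(intersect(found_prot, truth_prot), truth_prot)
  # determinism
  expect_identical(scr, screen_all(d, cfg$catalog))
})

test_that("an all-null catalog screens almost entirely neutral", {
  cat0 <- tiny_catalog(n_risk = 0, n_protective = 0, n_null = 40,
                       prevalence = 0.25)
  cfg <- sim_config(50000, catalog = cat0,
                    cohorts = data.frame(label = "one", alpha = qlogis(0.3),
                                         weight = 1),
                    beta_prior_use = 0, seed = 11)
  d <- split_derivation_validation(generate_cohort(cfg), 2 / 3, seed = 11)
  scr <- screen_all(d, cat0)
  expect_gte(mean(scr$classification == "neutral"), 0.95)
})

test_that("identical splits give identical derivation and validation ORs", {
  set.seed(55)
  half <- random_small_dataset(40, n_cov = 3)
  other <- half
  other$split <- "validation"
  other$person_id <- paste0("v", other$person_id)
  d <- rbind(half, other)
  cat3 <- item_catalog(data.frame(
    item_id = paste0("x", 1:3), domain = "disease",
    true_beta = 0, prevalence = 0.5
  ))
  scr <- screen_all(d, cat3)
  expect_equal(scr$or_derivation, scr$or_validation)
})

test_that("poolability verdict reflects planted homogeneity or its absence", {
  cat_probe <- tiny_catalog(n_risk = 2, n_protective = 1, n_null = 1,
                            risk_or = 2, protective_or = 0.5,
                            prevalence = 0.25)
  probe <- cat_probe$item_id[1:3]  # two risk, one protective
  make_cohorts <- function(catalog, seeds) {
    parts <- lapply(seq_along(seeds), function(i) {
      cfg <- sim_config(20000, catalog = catalog,
                        cohorts = data.frame(label = paste0("c", i),
                                             alpha = qlogis(0.3), weight = 1),
                        beta_prior_use = 0, seed = seeds[i])
      generate_cohort(cfg)
    })
    names(parts) <- paste0("c", seq_along(seeds))
    parts
  }
  # identical planted betas in all three cohorts -> poolable
  pool <- poolability_check(make_cohorts(cat_probe, 1:3), probe)
  expect_true(pool$verdict)
  expect_equal(nrow(pool$table), 3 * length(probe))

  # flip the sign of one probe's beta in one cohort -> not poolable
  flipped <- cat_probe
  flipped$true_beta[1] <- -flipped$true_beta[1]
  parts <- make_cohorts(cat_probe, 1:2)
  parts$c3 <- make_cohorts(flipped, 3)[[1]]
  parts$c3$cohort <- "c3"
  pool2 <- poolability_check(parts, probe)
  expect_false(pool2$verdict)
  expect_false(pool2$per_item[[probe[1]]])

  # single cohort is vacuously consistent
  pool3 <- poolability_check(make_cohorts(cat_probe, 1), probe)
  expect_true(pool3$verdict)

  # missing probe item is an error
  expect_error(poolability_check(make_cohorts(cat_probe, 1), "absent_item"),
               class = "hedri_data_error")
})

test_that("screening serializes to TSV and JSON", {
  cat3 <- tiny_catalog()
  cfg <- sim_config(2000, catalog = cat3,
                    cohorts = data.frame(label = "one", alpha = 0, weight = 1),
                    seed = 6)
  d <- split_derivation_validation(generate_cohort(cfg), 2 / 3, seed = 6)
  scr <- screen_all(d, cat3)
  tsv <- tempfile(fileext = ".tsv")
  json <- tempfile(fileext = ".json")
  write_screening_tsv(scr, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$item_id, scr$item_id)
  expect_equal(back$or_derivation, scr$or_derivation, tolerance = 1e-12)
  write_screening_json(scr, json)
  jback <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(jback$classification, scr$classification)
})
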