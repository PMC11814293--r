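make_records <- function(n, a = 1e-5, b = 3, sd = 0, lrange = c(2, 40),
                         seed = 1) {
  set.seed(seed)
  L <- runif(n, lrange[1], lrange[2])
  data.frame(length_mm = L, afdm_g = a * L^b * exp(rnorm(n, 0, sd)))
}

test_that("the noiseless power law is recovered within one percent", {
  mod <- fit_allometry(make_records(500))
  gr <- seq(5, 35, by = 0.5)
  rel <- abs(predict_allometry(mod, gr)$afdm / (1e-5 * gr^3) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("constant mass gives a flat curve and out-of-domain requests clamp", {
  rec <- make_records(100)
  rec$afdm_g <- 0.02
  mod <- fit_allometry(rec)
  p <- predict_allometry(mod, c(5, 20, 35))
  expect_equal(p$afdm, rep(0.02, 3))
  out <- predict_allometry(mod, c(1, 100))
  expect_true(all(out$extrapolated))
  expect_equal(out$afdm, rep(0.02, 2))  # clamped to the domain edges
})

test_that("too few records point the caller back to scale selection", {
  expect_error(fit_allometry(make_records(40)), "select_scale")
  small_taxon <- list(sibes_id = 9L, small_species = TRUE)
  expect_silent(fit_allometry(make_records(50), taxon = small_taxon))
})

test_that("outlier fences flag exactly the gross error and nothing else", {
  rec <- make_records(98, sd = 0)
  rec$afdm_g <- rec$afdm_g * exp(rep(c(-0.1, 0.1), 49))
  bad <- data.frame(length_mm = 20, afdm_g = 1e-5 * 20^3 * exp(10))
  rec <- rbind(rec, bad)
  mod <- fit_allometry(rec[-99, ], min_records = 10)
  flags <- detect_outliers(rec, mod)
  expect_identical(which(flags), 99L)
})

test_that("all-zero residuals flag nothing and tiny sets warn", {
  rec <- make_records(80)
  mod <- fit_allometry(rec)
  expect_false(any(detect_outliers(rec, mod)))
  expect_warning(f <- detect_outliers(rec[1:3, ], mod), "quartiles")
  expect_identical(f, rep(FALSE, 3))
})

test_that("clean Gaussian residuals are flagged at well under two percent", {
  rec <- make_records(10000, sd = 0.15, seed = 99)
  mod <- fit_allometry(rec)
  expect_lt(mean(detect_outliers(rec, mod)), 0.02)
})

test_that("one outlier pass removes gross errors before the final fit", {
  rec <- make_records(200, sd = 0.05, seed = 3)
  rec$afdm_g[1:5] <- rec$afdm_g[1:5] * exp(8)
  mod <- fit_allometry(rec)
  expect_identical(mod$n_outliers_removed, 5L)
  expect_identical(mod$n_records, 195L)
})

test_that("scale selection returns the finest level meeting its threshold", {
  expect_identical(
    select_scale(c(season = 1000, year = 200, region = 80, basin = 40)),
    "region")
  expect_identical(
    select_scale(c(season = 1000, year = 200, region = 80, basin = 50),
                 small_species = TRUE),
    "basin")
  expect_true(is.na(
    select_scale(c(season = 20, year = 10, region = 5, basin = 1),
                 purpose = "mean")))
  expect_identical(
    select_scale(c(season = 35, year = 35, region = 35, basin = 35),
                 purpose = "mean"),
    "basin")
})

test_that("raising the threshold never selects a finer scale", {
  set.seed(7)
  for (i in 1:200) {
    ladder <- sort(sample(0:120, 4), decreasing = TRUE)
    lvl_hi <- sibesim:::scale_from_counts(ladder, 75L)
    lvl_lo <- sibesim:::scale_from_counts(ladder, 45L)
    expect_lte(lvl_hi, lvl_lo)
  }
})

test_that("single-record imputation dispatches by availability and method", {
  pool <- make_records(120, sd = 0.1, seed = 5)
  pool$era <- rep(c(2014L, 2015L), 60)
  pool$region <- "west"; pool$tidal_basin_id <- 1L
  taxon <- list(sibes_id = 1L, small_species = FALSE,
                missing_afdm_method_id = 24L)

  rec <- list(length_mm = 20, afdm_g = NA_real_, era = 2015L,
              region = "west", tidal_basin_id = 1L)
  res <- impute_afdm(rec, taxon, pool)
  expect_identical(res$method, 24L)
  # 120 pooled records but only 60 in 2015: the season level qualifies
  expect_identical(res$level, "season")
  expect_gt(res$afdm_g, 0)
})

test_that("loess imputation stops at the finest stratum meeting its threshold", {
  pool <- make_records(160, sd = 0.1, seed = 6)
  pool$era <- 2015L
  pool$region <- rep(c("west", "east"), c(80, 80))
  pool$tidal_basin_id <- rep(1:4, each = 40)
  taxon <- list(sibes_id = 1L, small_species = FALSE,
                missing_afdm_method_id = 24L)
  rec <- list(length_mm = 20, afdm_g = NA_real_, era = 2015L,
              region = "west", tidal_basin_id = 1L)
  # ladder: season 160, year 160, region 80, basin 40 -> region (80 >= 75)
  res <- impute_afdm(rec, taxon, pool)
  expect_identical(res$method, 24L)
  expect_identical(res$level, "region")
})

test_that("records without length use the hierarchical year mean", {
  pool <- make_records(60, sd = 0.1, seed = 8)
  pool$era <- rep(c(2014L, 2015L), c(25, 35))
  pool$region <- rep(c("west", "east"), 30)
  pool$tidal_basin_id <- rep(1:2, 30)
  taxon <- list(sibes_id = 1L, small_species = FALSE,
                missing_afdm_method_id = 12L)
  rec <- list(length_mm = NA_real_, afdm_g = NA_real_, era = 2015L,
              region = "west", tidal_basin_id = 1L)
  res <- impute_afdm(rec, taxon, pool)
  expect_identical(res$method, 12L)
  expect_identical(res$level, "year")   # 35 >= 30, finer strata < 30
  expect_equal(res$afdm_g, mean(pool$afdm_g[pool$era == 2015L]))
})

test_that("the historical-average method pools prior years only", {
  pool <- make_records(80, sd = 0, seed = 9)
  pool$afdm_g <- rep(c(1, 9), each = 40)
  pool$era <- rep(c(2010L, 2015L), each = 40)
  pool$region <- "west"; pool$tidal_basin_id <- 1L
  taxon <- list(sibes_id = 1L, missing_afdm_method_id = 25L)
  rec <- list(length_mm = NA_real_, afdm_g = NA_real_, era = 2015L,
              region = "west", tidal_basin_id = 1L)
  res <- impute_afdm(rec, taxon, pool)
  expect_identical(res$method, 25L)
  expect_equal(res$afdm_g, 1)  # only the 2010 records qualify
})

test_that("imputation refuses measured records and reports dead ends", {
  taxon <- list(sibes_id = 1L, missing_afdm_method_id = 24L)
  pool <- make_records(10, seed = 10)
  pool$era <- 2015L; pool$region <- "west"; pool$tidal_basin_id <- 1L
  expect_error(
    impute_afdm(list(length_mm = 5, afdm_g = 0.1, era = 2015L,
                     region = "west", tidal_basin_id = 1L), taxon, pool),
    "already carries")
  res <- impute_afdm(list(length_mm = 5, afdm_g = NA_real_, era = 2015L,
                          region = "west", tidal_basin_id = 1L), taxon, pool)
  expect_true(is.na(res$afdm_g))
  expect_match(res$reason, "insufficient")
})

test_that("bulk imputation fills what it can and never goes negative", {
  fix <- campaign_with_missing(seed = 17, p_missing_afdm = 0.2)
  ind <- fix$campaign$individuals
  taxa <- species_template(list(fix$truth))
  out <- impute_missing_afdm(ind, fix$campaign$samples, taxa)
  expect_identical(nrow(out$audit), sum(is.na(ind$afdm_g)))
  filled <- out$individuals$afdm_g[out$audit$row]
  expect_true(all(is.na(filled) | filled >= 0))
  expect_true(all(out$audit$method %in% c(12L, 24L, 25L) |
                    is.na(out$audit$method)))
})
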