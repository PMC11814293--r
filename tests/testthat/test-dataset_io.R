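tiny_tables <- function() {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    sampling_station_id = 1:3, sampling_type = c("grid", "grid", "random"),
    date = c("2015-07-01", "2015-07-02", "2015-07-03"),
    platform = c("boat", "walk", "boat"),
    tidal_basin_name = "basin_1", tidal_flat_name = "flat_1",
    x = c(4.9, 4.91, 4.92), y = c(53.0, 53.01, 53.02),
    median_grain_size = c(150, 180, NA), percentage_mud = c(12, 35, NA),
    stringsAsFactors = FALSE)
  species <- species_template(list(species_truth(1L), species_truth(2L)))
  biota <- data.frame(
    sample_id = c("s1", "s2"), sibes_id = c(1L, 2L),
    abundance_m2 = c(57.8, 113), afdm_m2 = c(0.5, NA),
    stringsAsFactors = FALSE)
  list(samples = samples, species = species, biota = biota)
}

test_that("the printed annual counts reproduce the published averages row", {
  tab <- annual_station_counts()
  s <- summarize_campaign(tab, year_range = 2008:2019)
  expect_identical(s$averages$total, 4109L)
  expect_identical(s$averages$grid, 3565L)
  expect_identical(s$averages$random, 544L)
  expect_identical(s$averages$pct_random, 13L)
  expect_identical(s$averages$pct_boating, 92L)
  expect_identical(s$min_total, 2399L)
  expect_identical(s$max_total, 4471L)
})

test_that("every printed percent-random cell reproduces under half-up rounding", {
  tab <- annual_station_counts()
  s <- summarize_campaign(tab)
  expect_identical(s$yearly$pct_random,
                   as.integer(round_half_up(100 * tab$random / tab$total)))
  expect_identical(s$yearly$pct_random, tab$pct_random)
})

test_that("a single synthetic year averages to itself", {
  one <- data.frame(year = 2015L, total = 100L, grid = 80L, random = 20L,
                    boat = 90L)
  s <- summarize_campaign(one, year_range = 2015)
  expect_identical(s$averages$total, 100L)
  expect_identical(s$averages$pct_random, 20L)
  expect_identical(s$averages$pct_boating, 90L)
  expect_identical(s$min_total, s$max_total)
})

test_that("a samples table is tallied into per-year counts before summarising", {
  tt <- tiny_tables()
  tt$samples$year <- 2015L
  s <- summarize_campaign(tt$samples, year_range = 2015)
  expect_identical(s$yearly$total, 3L)
  expect_identical(s$yearly$grid, 2L)
  expect_identical(s$yearly$pct_random, 33L)
  expect_identical(s$yearly$pct_boating, 67L)
})

test_that("zero filling emits exactly samples x taxa rows and conserves totals", {
  tt <- tiny_tables()
  dense <- zero_fill(tt$samples, tt$species, tt$biota)
  expect_identical(nrow(dense), 6L)
  expect_identical(sum(dense$abundance_m2 == 0), 4L)
  expect_equal(sum(dense$abundance_m2), sum(tt$biota$abundance_m2))
  # nonzero values pass through unchanged
  expect_equal(
    dense$abundance_m2[dense$sample_id == "s1" & dense$sibes_id == 1L], 57.8)
  expect_error(zero_fill(tt$samples, tt$species, tt$biota, taxa = 99L), "absent")
  empty <- zero_fill(tt$samples, tt$species, tt$biota[0, ])
  expect_true(all(empty$abundance_m2 == 0))
})

test_that("validation is silent on clean tables and itemises violations", {
  tt <- tiny_tables()
  rep0 <- validate_tables(tt$samples, tt$species, tt$biota)
  expect_identical(nrow(rep0), 0L)

  bad_s <- rbind(tt$samples, tt$samples[1, ])
  bad_s$platform[2] <- "hovercraft"
  bad_s$percentage_mud[1] <- 101
  bad_b <- rbind(tt$biota, data.frame(sample_id = "ghost", sibes_id = 7L,
                                      abundance_m2 = -3, afdm_m2 = -1))
  rep1 <- validate_tables(bad_s, tt$species, bad_b)
  expect_identical(sum(rep1$rule == "duplicate key" & rep1$table == "samples"), 1L)
  get_n <- function(rule) rep1$n[rep1$rule == rule]
  expect_identical(get_n("unknown enum: platform"), 1L)
  expect_identical(get_n("range: percentage_mud"), 1L)
  expect_identical(get_n("referential: sample_id"), 1L)
  expect_identical(get_n("referential: sibes_id"), 1L)
  expect_identical(get_n("range: afdm_m2"), 1L)
})

test_that("the three tables round-trip through CSV value-identically", {
  tt <- tiny_tables()
  d <- withr::local_tempdir()
  write_samples(tt$samples, file.path(d, "samples.csv"))
  write_species(tt$species, file.path(d, "species.csv"))
  write_biota(tt$biota, file.path(d, "biota.csv"))
  expect_equal(read_samples(file.path(d, "samples.csv")), tt$samples)
  sp_back <- read_species(file.path(d, "species.csv"))
  expect_equal(sp_back[names(tt$species)], tt$species)
  expect_equal(read_biota(file.path(d, "biota.csv")), tt$biota)
  # NA markers written as empty fields survive the round trip
  raw <- readLines(file.path(d, "samples.csv"))
  expect_match(raw[4], ",,$")
  expect_error(read_biota(file.path(d, "samples.csv")), "required columns")
})

test_that("community summaries require a dense table and count richness", {
  tt <- tiny_tables()
  tt$samples$year <- 2015L
  expect_error(summarize_community(tt$biota, tt$samples), "zero_fill")
  dense <- zero_fill(tt$samples, tt$species, tt$biota)
  cs <- summarize_community(dense, tt$samples)
  expect_identical(cs$per_sample$richness[cs$per_sample$sample_id == "s1"], 1L)
  expect_identical(cs$per_sample$richness[cs$per_sample$sample_id == "s3"], 0L)
  expect_identical(cs$per_sample$total_afdm_m2[cs$per_sample$sample_id == "s3"], 0)
  expect_identical(unique(cs$yearly$n_samples), 3L)
})

test_that("richness of five is reported for a five-taxon station", {
  samples <- data.frame(sample_id = "s1", year = 2015L)
  species <- species_template(lapply(1:5, species_truth))
  biota <- data.frame(sample_id = "s1", sibes_id = 1:5,
                      abundance_m2 = 1:5, afdm_m2 = 0.1)
  dense <- zero_fill(samples, species, biota)
  cs <- summarize_community(dense, samples)
  expect_identical(cs$per_sample$richness, 5L)
})

test_that("simulated yearly means recover the generator's spatial mean density", {
  fix <- campaign_with_missing(seed = 23, p_missing_afdm = 0)
  camp <- fix$campaign
  biota <- as_biota_table(camp$individuals, camp$samples)
  species <- species_template(list(fix$truth))
  dense <- zero_fill(camp$samples, species, biota)
  cs <- summarize_community(dense, camp$samples)
  truth_mean <- mean(sibesim:::raster_value_at(
    fix$world$density[["1"]], camp$samples$x, camp$samples$y))
  dens <- dense$abundance_m2[dense$sibes_id == 1L]
  se <- stats::sd(dens) / sqrt(length(dens))
  expect_lt(abs(cs$yearly$mean_abundance_m2 - truth_mean), 3 * se)
})

test_that("campaign exports match the published schemas", {
  fix <- campaign_with_missing(seed = 29, p_missing_afdm = 0.1)
  st <- fix$stations
  st$sampling_type <- "grid"
  samples_tab <- as_samples_table(fix$campaign, st)
  expect_identical(names(samples_tab), sibesim:::samples_columns)
  expect_true(all(samples_tab$platform %in% c("boat", "walk")))
  biota <- as_biota_table(fix$campaign$individuals, fix$campaign$samples)
  expect_identical(names(biota), sibesim:::biota_columns)
  expect_true(all(biota$abundance_m2 > 0))
  expect_identical(anyDuplicated(biota[c("sample_id", "sibes_id")]), 0L)
  rep <- validate_tables(samples_tab, species_template(list(fix$truth)), biota)
  expect_identical(attr(rep, "n_violations"), 0L)
})
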