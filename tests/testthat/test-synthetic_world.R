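test_that("zero-sill species produce a spatially constant density surface", {
  sp <- species_truth(1L, mean_log_density = log(250), nugget = 0, sill = 0)
  w <- flat_world(species = list(sp))
  vals <- as.vector(w$density[["1"]]$values)
  expect_equal(vals, rep(exp(log(250)), length(vals)))
})

test_that("identical config and seed reproduce the world and campaign exactly", {
  cfg <- world_config(extent = c(0, 1500, 0, 1500), cell_size = 150,
                      intertidal_fraction = 0.8,
                      species = list(species_truth(1L), species_truth(
                        2L, small_species = TRUE, length_meanlog = log(5))),
                      seed = 42L)
  w1 <- build_world(cfg); w2 <- build_world(cfg)
  expect_identical(serialize(w1, NULL, version = 3),
                   serialize(w2, NULL, version = 3))
  st <- lattice_stations(5, 300)
  c1 <- simulate_campaign(w1, st, year = 2012, seed = 5)
  c2 <- simulate_campaign(w2, st, year = 2012, seed = 5)
  expect_identical(serialize(c1, NULL, version = 3),
                   serialize(c2, NULL, version = 3))
})

test_that("world rasters share geometry and densities are positive", {
  w <- flat_world(species = list(species_truth(1L), species_truth(2L)))
  geom <- function(r) r[c("xmin", "ymin", "cell", "nx", "ny")]
  expect_identical(geom(w$mask), geom(w$density[["1"]]))
  expect_identical(geom(w$mask), geom(w$sediment$mgs_um))
  expect_true(all(w$density[["1"]]$values > 0))
  expect_true(all(w$sediment$mud_fraction$values >= 0 &
                    w$sediment$mud_fraction$values <= 1))
})

test_that("intertidal fraction of the mask matches the configuration", {
  cfg <- world_config(extent = c(0, 3000, 0, 3000), cell_size = 100,
                      intertidal_fraction = 0.6, seed = 9L)
  w <- build_world(cfg)
  expect_equal(mean(w$mask$values), 0.6, tolerance = 0.01)
})

test_that("configuration errors are caught", {
  expect_error(world_config(extent = c(0, -10, 0, 10)), "extent")
  expect_error(world_config(cell_size = 0), "cell_size")
  expect_error(species_truth(1L, sill = -1), "sill")
  expect_error(species_truth(1L, p_broken = 1.5), "p_broken")
  w <- flat_world()
  st <- data.frame(station_id = 1L, x = 99999, y = 0, platform = "boat")
  expect_error(simulate_campaign(w, st), "inside the world extent")
  expect_error(simulate_campaign(w, lattice_stations(2), seed = -1), "seed")
})

test_that("a zero-density species yields no records and sub-mesh lengths are sieved out", {
  absent <- species_truth(1L, mean_log_density = -30, nugget = 0, sill = 0)
  tiny <- species_truth(2L, mean_log_density = log(500), nugget = 0, sill = 0,
                        length_meanlog = log(0.2), length_sdlog = 0.1)
  w <- flat_world(species = list(absent, tiny))
  camp <- simulate_campaign(w, lattice_stations(8, 250), year = 2019, seed = 3)
  expect_identical(nrow(camp$individuals), 0L)
})

test_that("retained counts match the Poisson-thinning expectation", {
  D <- 500
  sp <- species_truth(1L, mean_log_density = log(D), nugget = 0, sill = 0,
                      length_meanlog = log(3), length_sdlog = 0.6)
  w <- build_world(world_config(extent = c(0, 4000, 0, 4000), cell_size = 200,
                                intertidal_fraction = 1,
                                species = list(sp), seed = 21L))
  st <- lattice_stations(32, 125)  # 1024 stations, all boat
  camp <- simulate_campaign(w, st, year = 2018, seed = 22)
  p_keep <- stats::plnorm(1, log(3), 0.6, lower.tail = FALSE)
  lambda <- D * 0.0173 * p_keep
  per_station <- table(factor(camp$individuals$sample_id,
                              levels = camp$samples$sample_id))
  se <- sqrt(lambda / length(per_station))
  expect_lt(abs(mean(per_station) - lambda), 3 * se)
})

test_that("subsample correction leaves standardized density unbiased", {
  D <- 12000  # ~208 expected per core, above the subsampling trigger of 100
  sp <- species_truth(1L, mean_log_density = log(D), nugget = 0, sill = 0,
                      length_meanlog = log(12), length_sdlog = 0.2,
                      subsample_eligible = TRUE)
  w <- build_world(world_config(extent = c(0, 4000, 0, 4000), cell_size = 200,
                                intertidal_fraction = 1,
                                species = list(sp), seed = 31L))
  st <- lattice_stations(32, 125)
  camp <- simulate_campaign(w, st, year = 2018, seed = 32)
  expect_true(all(camp$individuals$subsample_fraction < 1))
  biota <- as_biota_table(camp$individuals, camp$samples)
  dens <- rep(0, nrow(camp$samples))
  dens[match(biota$sample_id, camp$samples$sample_id)] <- biota$abundance_m2
  se <- stats::sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - D), 3 * se)
})

test_that("generated sediment spectra are valid and reflect the mud field", {
  w <- flat_world(seed = 13)
  camp <- simulate_campaign(w, lattice_stations(6, 300), year = 2014, seed = 14)
  expect_true(all(abs(rowSums(camp$sediment) - 1) < 1e-9))
  expect_true(all(camp$samples$percentage_mud >= 0 &
                    camp$samples$percentage_mud <= 100))
  mudf <- sibesim:::raster_value_at(w$sediment$mud_fraction,
                                    camp$samples$x, camp$samples$y)
  expect_gt(cor(mudf, camp$samples$percentage_mud), 0.9)
})

test_that("variogram of a generated log-density field recovers the range", {
  # median over 50 world realisations at 40 x 40 cells of 100 m
  ests <- vapply(1:50, function(s) {
    w <- build_world(world_config(
      extent = c(0, 4000, 0, 4000), cell_size = 100, intertidal_fraction = 1,
      species = list(species_truth(1L, nugget = 0, sill = 1, range = 500)),
      seed = s))
    ctr <- sibesim:::raster_centers(w$log_density[["1"]])
    set.seed(s)
    idx <- sample(nrow(ctr), 400)
    cg <- estimate_correlogram(ctr$x[idx], ctr$y[idx],
                               as.vector(w$log_density[["1"]]$values)[idx],
                               spacing = 500)
    fit_variogram(cg)$range
  }, numeric(1))
  expect_lt(abs(median(ests) / 500 - 1), 0.30)
})
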