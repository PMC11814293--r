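# shared builders for small synthetic fixtures; everything is generated
# in code so tests carry no stored data

flat_world <- function(seed = 7, extent = c(0, 2000, 0, 2000), cell = 100,
                       species = list(species_truth(1L))) {
  build_world(world_config(extent = extent, cell_size = cell,
                           intertidal_fraction = 1, n_basins = 2L,
                           species = species, seed = seed))
}

full_mask <- function(side_m = 2000, cell = 100) {
  mud_raster(matrix(TRUE, side_m / cell, side_m / cell), 0, 0, cell)
}

# stations on a regular lattice (avoids design randomness where a test
# only needs "many stations")
lattice_stations <- function(n_side = 10, spacing = 200, platform = "boat") {
  g <- expand.grid(x = (seq_len(n_side) - 0.5) * spacing,
                   y = (seq_len(n_side) - 0.5) * spacing)
  data.frame(station_id = seq_len(nrow(g)), x = g$x, y = g$y,
             platform = platform)
}

# a small campaign with known allometry and controlled missingness
campaign_with_missing <- function(seed = 11, p_missing_afdm = 0.2,
                                  n_side = 14) {
  sp <- species_truth(1L, mean_log_density = log(400), nugget = 0.05,
                      sill = 0.3, range = 600,
                      allometry_a = 1e-5, allometry_b = 3,
                      allometry_sd = 0.15,
                      p_missing_afdm = p_missing_afdm)
  w <- build_world(world_config(extent = c(0, 2800, 0, 2800), cell_size = 200,
                                intertidal_fraction = 1, n_basins = 2L,
                                species = list(sp), seed = seed))
  st <- lattice_stations(n_side, 2800 / n_side)
  camp <- simulate_campaign(w, st, year = 2015, seed = seed + 1)
  list(world = w, stations = st, campaign = camp, truth = sp)
}
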