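#' Ground-truth parameters of one simulated species
#'
#' Describes how a species is laid over the virtual mudflat: its latent
#' log-density surface is a Gaussian random field (exponential
#' covariance) around `mean_log_density`; individual lengths follow a
#' lognormal law; individual ash-free dry mass follows the allometric
#' power law `AFDM = a * L^b` with multiplicative lognormal noise.
#' Probabilities control the measurement pathologies the laboratory
#' produces: missing lengths, missing mass, and broken shells recorded by
#' width only.
#'
#' @param sibes_id integer taxon identifier.
#' @param name scientific name (free text).
#' @param mean_log_density mean of the latent log density, log(ind m^-2).
#' @param nugget,sill,range GRF parameters of the latent log-density
#'   field: nugget and partial sill on the log scale, range in metres
#'   (e-folding distance of the exponential covariance).
#' @param allometry_a,allometry_b coefficients of `AFDM = a * L^b`
#'   (grams, millimetres).
#' @param allometry_sd sd of the lognormal mass noise (log scale). The
#'   default 0.15 matches the residual spread typical of the monitoring
#'   programme's species-level biomass-length fits.
#' @param length_meanlog,length_sdlog lognormal length law (log mm).
#' @param small_species logical; lengths predominantly under 11 mm
#'   (lowers the LOESS record-count threshold downstream).
#' @param p_missing_length,p_missing_afdm,p_broken probabilities of a
#'   measured individual lacking a length, lacking a mass, or being a
#'   broken razor-clam-style shell carrying only a width.
#' @param subsample_eligible logical; taxon is subsampled when abundant.
#' @param taxonomic_group one of the survey's group labels.
#' @return list of class `species_truth`.
#' @export
species_truth <- function(sibes_id, name = paste0("Taxon_", sibes_id),
                          mean_log_density = log(200),
                          nugget = 0.1, sill = 1, range = 500,
                          allometry_a = 1e-5, allometry_b = 3,
                          allometry_sd = 0.15,
                          length_meanlog = log(12), length_sdlog = 0.35,
                          small_species = FALSE,
                          p_missing_length = 0, p_missing_afdm = 0,
                          p_broken = 0, subsample_eligible = FALSE,
                          taxonomic_group = "bivalve") {
  if (sill < 0) stop("sill must be >= 0", call. = FALSE)
  if (nugget < 0) stop("nugget must be >= 0", call. = FALSE)
  stopifnot_positive(range, "range")
  stopifnot_positive(allometry_a, "allometry_a")
  stopifnot_prob(p_missing_length, "p_missing_length")
  stopifnot_prob(p_missing_afdm, "p_missing_afdm")
  stopifnot_prob(p_broken, "p_broken")
  structure(
    list(sibes_id = as.integer(sibes_id), name = name,
         mean_log_density = mean_log_density,
         nugget = nugget, sill = sill, range = range,
         allometry_a = allometry_a, allometry_b = allometry_b,
         allometry_sd = allometry_sd,
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         small_species = isTRUE(small_species),
         p_missing_length = p_missing_length,
         p_missing_afdm = p_missing_afdm, p_broken = p_broken,
         subsample_eligible = isTRUE(subsample_eligible),
         taxonomic_group = taxonomic_group),
    class = "species_truth")
}

#' Configuration of a virtual mudflat world
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size raster cell size (m).
#' @param intertidal_fraction proportion of cells that are intertidal
#'   mudflat (exposed at low tide and hence sampleable).
#' @param n_basins number of tidal basins (vertical bands).
#' @param species list of [species_truth()] objects.
#' @param sediment list with GRF parameters for `log10` median grain size
#'   (`mgs`: mean, sill, range) and logit mud fraction (`mud`).
#' @param seed integer seed; the whole world is reproducible from it.
#' @return list of class `world_config`.
#' @export
world_config <- function(extent = c(0, 4000, 0, 4000), cell_size = 100,
                         intertidal_fraction = 0.7, n_basins = 2L,
                         species = list(species_truth(1L)),
                         sediment = list(
                           mgs = list(mean = log10(150), sill = 0.01, range = 1000),
                           mud = list(mean = -1.5, sill = 0.5, range = 1000)),
                         seed = 1L) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans",
         call. = FALSE)
  }
  stopifnot_positive(cell_size, "cell_size")
  stopifnot_prob(intertidal_fraction, "intertidal_fraction")
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  if (seed < 0) stop("seed must be non-negative", call. = FALSE)
  structure(
    list(extent = extent, cell_size = cell_size,
         intertidal_fraction = intertidal_fraction,
         n_basins = as.integer(n_basins), species = species,
         sediment = sediment, seed = as.integer(seed)),
    class = "world_config")
}

#' Build a synthetic mudflat world
#'
#' Realises the latent surfaces a field campaign will sample: an
#' intertidal mask (thresholded smooth random field, so flats are
#' spatially coherent), tidal-basin membership, one exp-transformed
#' Gaussian-random-field density surface per species, and sediment
#' surfaces (log10 median grain size; mud fraction on the logit scale).
#' The full ground truth is embedded for parameter-recovery tests.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world` with elements `mask`,
#'   `basin_id`, `density` (list of rasters by taxon), `log_density`,
#'   `sediment` (rasters `mgs_um`, `mud_fraction`), `truth`, `config`.
#' @export
build_world <- function(config) {
  if (!inherits(config, "world_config")) stop("need a world_config", call. = FALSE)
  set.seed(child_seed(config$seed, "world"))
  ext <- config$extent
  nx <- max(1L, round((ext[2] - ext[1]) / config$cell_size))
  ny <- max(1L, round((ext[4] - ext[3]) / config$cell_size))
  template <- mud_raster(matrix(0, ny, nx), xmin = ext[1], ymin = ext[3],
                         cell = config$cell_size)
  ctr <- raster_centers(template)

  ## intertidal mask: threshold a smooth field at the quantile that gives
  ## the requested areal fraction exactly
  if (config$intertidal_fraction >= 1) {
    mask_vals <- rep(TRUE, nrow(ctr))
  } else if (config$intertidal_fraction <= 0) {
    mask_vals <- rep(FALSE, nrow(ctr))
  } else {
    relief <- sim_grf(ctr$x, ctr$y, nugget = 0, psill = 1,
                      range = max(ext[2] - ext[1], ext[4] - ext[3]) / 4)
    mask_vals <- relief <= stats::quantile(relief, config$intertidal_fraction)
  }
  mask <- mud_raster(matrix(mask_vals, ny, nx), ext[1], ext[3], config$cell_size)

  ## tidal basins: vertical bands of equal width
  band <- pmin(config$n_basins,
               floor((ctr$x - ext[1]) / ((ext[2] - ext[1]) / config$n_basins)) + 1L)
  basin <- mud_raster(matrix(as.integer(band), ny, nx), ext[1], ext[3],
                      config$cell_size)

  density <- list(); log_density <- list()
  for (sp in config$species) {
    set.seed(child_seed(config$seed, paste0("species", sp$sibes_id)))
    z <- sp$mean_log_density +
      sim_grf(ctr$x, ctr$y, nugget = sp$nugget, psill = sp$sill, range = sp$range)
    key <- as.character(sp$sibes_id)
    log_density[[key]] <- mud_raster(matrix(z, ny, nx), ext[1], ext[3],
                                     config$cell_size)
    density[[key]] <- mud_raster(matrix(exp(z), ny, nx), ext[1], ext[3],
                                 config$cell_size)
  }

  set.seed(child_seed(config$seed, "sediment"))
  sed <- config$sediment
  lmgs <- sed$mgs$mean + sim_grf(ctr$x, ctr$y, nugget = 0,
                                 psill = sed$mgs$sill, range = sed$mgs$range)
  lmud <- sed$mud$mean + sim_grf(ctr$x, ctr$y, nugget = 0,
                                 psill = sed$mud$sill, range = sed$mud$range)
  sediment <- list(
    mgs_um = mud_raster(matrix(10^lmgs, ny, nx), ext[1], ext[3], config$cell_size),
    mud_fraction = mud_raster(matrix(stats::plogis(lmud), ny, nx),
                              ext[1], ext[3], config$cell_size))

  structure(
    list(mask = mask, basin_id = basin, density = density,
         log_density = log_density, sediment = sediment,
         truth = list(species = config$species, sediment = sed),
         config = config),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d species, %d basins\n",
              x$mask$nx, x$mask$ny, length(x$density), x$config$n_basins))
  invisible(x)
}

## draw a synthetic 126-class grain-size spectrum: two lognormal modes
## (mud < 63 um, sand > 63 um) mixed by the local mud fraction
synth_sediment_spectrum <- function(mud_fraction, mgs_um, constants) {
  edges <- constants$grain_edges
  mud_mode <- diff(stats::pnorm(log(edges), mean = log(20), sd = 1))
  sand_mode <- diff(stats::pnorm(log(edges), mean = log(max(mgs_um, 70)), sd = 0.45))
  f <- mud_fraction * mud_mode / sum(mud_mode) +
    (1 - mud_fraction) * sand_mode / sum(sand_mode)
  f / sum(f)
}

#' Simulate one field campaign on a synthetic world
#'
#' Visits each station and applies the field protocol: a macrozoobenthos
#' core of the platform's area, per-species Poisson counts from the
#' latent density surface, lognormal individual lengths truncated at the
#' 1-mm sieve, allometric mass with noise, high-density subsampling for
#' eligible taxa (a binomial subsample targeting ~30 individuals, with
#' the fraction recorded), missing lengths/mass, broken width-only
#' records, and a sediment core whose grain-size spectrum reflects the
#' local mud and median-grain-size fields.
#'
#' @param world a [build_world()] result.
#' @param stations data.frame with `station_id`, `x`, `y` and optionally
#'   `platform` (otherwise assigned boat with probability `p_boat`).
#' @param year campaign year (drives sample identifiers and era rules).
#' @param constants a [protocol_constants()].
#' @param seed non-negative integer seed.
#' @param p_boat probability a station is sampled by boat when `stations`
#'   carries no platform column (the programme samples ~92% by boat).
#' @return list with data.frames `samples` (one row per visit: sample_id,
#'   station_id, year, platform, area_m2, x, y, basin, and the reduced
#'   sediment variables), `individuals` (one row per measured individual:
#'   sample_id, sibes_id, count_unit, length_mm, length_estimated,
#'   width_top_mm, width_bottom_mm, afdm_g, subsample_fraction, era), and
#'   `sediment` (matrix of per-sample spectra).
#' @export
simulate_campaign <- function(world, stations, year = 2020L,
                              constants = protocol_constants(), seed = 1L,
                              p_boat = 0.92) {
  if (!inherits(world, "synthetic_world")) stop("need a synthetic_world", call. = FALSE)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer", call. = FALSE)
  if (!all(raster_inside(world$mask, stations$x, stations$y))) {
    stop("all stations must lie inside the world extent", call. = FALSE)
  }
  set.seed(child_seed(seed, paste0("campaign", year)))
  ns <- nrow(stations)
  platform <- if ("platform" %in% names(stations)) stations$platform else
    ifelse(stats::runif(ns) < p_boat, "boat", "walk")
  area <- platform_area(platform, constants)
  sample_id <- sprintf("S%d_%s", year, stations$station_id)

  samples <- data.frame(
    sample_id = sample_id, sampling_station_id = stations$station_id,
    year = year,
    date = as.Date(sprintf("%d-07-01", year)) + sample.int(90L, ns, replace = TRUE) - 1L,
    platform = platform, area_m2 = area,
    x = stations$x, y = stations$y,
    tidal_basin_id = raster_value_at(world$basin_id, stations$x, stations$y),
    stringsAsFactors = FALSE)

  ## individuals
  ind <- vector("list", ns * length(world$truth$species))
  k <- 0L
  for (sp in world$truth$species) {
    dens <- raster_value_at(world$density[[as.character(sp$sibes_id)]],
                            stations$x, stations$y)
    counts <- stats::rpois(ns, dens * area)
    for (i in seq_len(ns)) {
      n <- counts[i]
      if (n == 0L) next
      len <- stats::rlnorm(n, sp$length_meanlog, sp$length_sdlog)
      len <- len[len >= constants$sieve_mesh]
      n <- length(len)
      if (n == 0L) next
      frac <- 1
      if (sp$subsample_eligible && n > constants$subsample_trigger) {
        frac <- constants$subsample_min / n
        keep <- stats::runif(n) < frac
        len <- len[keep]
        n <- length(len)
        if (n == 0L) next
      }
      afdm <- sp$allometry_a * len^sp$allometry_b *
        exp(stats::rnorm(n, 0, sp$allometry_sd))
      broken <- stats::runif(n) < sp$p_broken
      miss_len <- !broken & stats::runif(n) < sp$p_missing_length
      miss_afdm <- stats::runif(n) < sp$p_missing_afdm
      width_top <- ifelse(broken, len / constants$ensis_coef_top, NA_real_)
      len_out <- ifelse(broken | miss_len, NA_real_, len)
      afdm_out <- ifelse(miss_afdm, NA_real_, afdm)
      k <- k + 1L
      ind[[k]] <- data.frame(
        sample_id = sample_id[i], sibes_id = sp$sibes_id,
        count_unit = "whole", length_mm = len_out,
        length_estimated = FALSE,
        width_top_mm = width_top, width_bottom_mm = NA_real_,
        afdm_g = afdm_out, true_length_mm = len, true_afdm_g = afdm,
        subsample_fraction = frac, era = year, stringsAsFactors = FALSE)
    }
  }
  individuals <- if (k > 0L) do.call(rbind, ind[seq_len(k)]) else
    data.frame(sample_id = character(), sibes_id = integer(),
               count_unit = character(), length_mm = numeric(),
               length_estimated = logical(), width_top_mm = numeric(),
               width_bottom_mm = numeric(), afdm_g = numeric(),
               true_length_mm = numeric(), true_afdm_g = numeric(),
               subsample_fraction = numeric(), era = integer())

  ## sediment spectra + reduced variables
  mudf <- raster_value_at(world$sediment$mud_fraction, stations$x, stations$y)
  mgs <- raster_value_at(world$sediment$mgs_um, stations$x, stations$y)
  spectra <- t(vapply(seq_len(ns), function(i) {
    f <- synth_sediment_spectrum(mudf[i], mgs[i], constants)
    f * abs(stats::rnorm(length(f), 1, 0.02))
  }, numeric(constants$n_grain_classes)))
  spectra <- spectra / rowSums(spectra)
  rownames(spectra) <- sample_id
  red <- lapply(seq_len(ns), function(i) reduce_sediment_spectrum(spectra[i, ], constants))
  samples$median_grain_size <- vapply(red, `[[`, numeric(1), "median_grain_size")
  samples$percentage_mud <- vapply(red, `[[`, numeric(1), "percentage_mud")

  list(samples = samples, individuals = individuals, sediment = spectra)
}
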