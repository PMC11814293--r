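#' Protocol constants of the monitoring programme
#'
#' Bundles the fixed physical and procedural constants of the field and
#' laboratory protocol: core areas for the two sampling platforms, sieve
#' mesh, the 126-class laser-diffraction grain-size grid, the mud
#' threshold, subsampling target, the shell-width coefficients used to
#' estimate razor-clam (*Ensis*) lengths, the LOESS span and hierarchical
#' record-count thresholds of the biomass imputation, and the mapping
#' resolutions.
#'
#' @param area_boat sampled area (m^2) of the two combined boat cores.
#' @param area_walk sampled area (m^2) of the single by-foot core.
#' @param sieve_mesh sieve mesh (mm); individuals below it are not retained.
#' @param mud_threshold grain size (um) below which sediment counts as mud.
#' @param grain_range range (um) spanned by the grain-size classes.
#' @param n_grain_classes number of grain-size classes.
#' @param subsample_min target number of individuals in a subsample.
#' @param subsample_trigger count above which an eligible taxon is subsampled.
#' @param ensis_coef_top,ensis_coef_bottom length = coef x shell width (mm).
#' @param loess_span span of the species-specific biomass-length LOESS.
#' @param scale_threshold_standard,scale_threshold_small,scale_threshold_mean
#'   minimum record counts for fitting a LOESS (standard taxa / taxa under
#'   11 mm) and for using a hierarchical average.
#' @param map_resolution interpolation grid resolution (m).
#' @param grid_spacing systematic-grid inter-station distance (m).
#' @return a list of class `protocol_constants`; `grain_edges` holds the
#'   127 geometric class boundaries (um).
#' @export
protocol_constants <- function(area_boat = 0.0173,
                               area_walk = 0.0177,
                               sieve_mesh = 1,
                               mud_threshold = 63,
                               grain_range = c(0.04, 2000),
                               n_grain_classes = 126L,
                               subsample_min = 30L,
                               subsample_trigger = 100L,
                               ensis_coef_top = 6.5,
                               ensis_coef_bottom = 6.6,
                               loess_span = 0.6,
                               scale_threshold_standard = 75L,
                               scale_threshold_small = 45L,
                               scale_threshold_mean = 30L,
                               map_resolution = 25,
                               grid_spacing = 500) {
  for (nm in c("area_boat", "area_walk", "sieve_mesh", "mud_threshold",
               "subsample_min", "subsample_trigger", "ensis_coef_top",
               "ensis_coef_bottom", "loess_span", "scale_threshold_standard",
               "scale_threshold_small", "scale_threshold_mean",
               "map_resolution", "grid_spacing")) {
    stopifnot_positive(get(nm), nm)
  }
  if (area_boat == area_walk) {
    stop("boat and walk core areas must differ", call. = FALSE)
  }
  edges <- 10^seq(log10(grain_range[1]), log10(grain_range[2]),
                  length.out = n_grain_classes + 1L)
  if (any(diff(edges) <= 0)) stop("grain class edges must increase", call. = FALSE)
  structure(
    list(area_boat = area_boat, area_walk = area_walk,
         sieve_mesh = sieve_mesh, mud_threshold = mud_threshold,
         grain_edges = edges, n_grain_classes = as.integer(n_grain_classes),
         subsample_min = as.integer(subsample_min),
         subsample_trigger = as.integer(subsample_trigger),
         ensis_coef_top = ensis_coef_top, ensis_coef_bottom = ensis_coef_bottom,
         loess_span = loess_span,
         scale_threshold_standard = as.integer(scale_threshold_standard),
         scale_threshold_small = as.integer(scale_threshold_small),
         scale_threshold_mean = as.integer(scale_threshold_mean),
         map_resolution = map_resolution, grid_spacing = grid_spacing),
    class = "protocol_constants")
}

platform_area <- function(platform, constants) {
  area <- ifelse(platform == "boat", constants$area_boat,
                 ifelse(platform == "walk", constants$area_walk, NA_real_))
  if (anyNA(area)) stop("unknown platform; must be 'boat' or 'walk'", call. = FALSE)
  area
}

#' Count individuals from a fragment tally
#'
#' Applies the laboratory counting rules. Polychaetes fragment in the
#' sieve, so from 2011 onwards they are counted as the number of heads
#' (plus whole animals); before 2011 loose heads and tails were tallied
#' and the count is taken as max(heads, tails) plus wholes, which avoids
#' counting one fragmented animal twice. Sand-mason worms (*Lanice
#' conchilega*) leave abundant empty tubes and fragments, so only whole
#' individuals count. All other taxa are counted as whole individuals.
#'
#' @param tally named numeric vector or list with any of `whole`, `head`,
#'   `tail`, `fragment` (missing entries count as zero).
#' @param taxon a row of a species table (see [species_template()]); the
#'   fields used are `taxonomic_group` and `count_whole_only`.
#' @param year sampling year, which selects the counting era.
#' @return integer count.
#' @export
count_individuals <- function(tally, taxon, year) {
  tl <- c(whole = 0, head = 0, tail = 0, fragment = 0)
  tally <- unlist(tally)
  tl[names(tally)] <- tally
  if (any(tl < 0)) stop("fragment tallies must be non-negative", call. = FALSE)
  whole_only <- isTRUE(taxon$count_whole_only) ||
    identical(as.character(taxon$name), "Lanice conchilega")
  n <- if (whole_only) {
    tl[["whole"]]
  } else if (identical(as.character(taxon$taxonomic_group), "polychaete")) {
    if (year >= 2011) tl[["head"]] + tl[["whole"]]
    else max(tl[["head"]], tl[["tail"]]) + tl[["whole"]]
  } else {
    tl[["whole"]]
  }
  as.integer(n)
}

#' Standardize a sample count and biomass to per-square-metre densities
#'
#' Divides by the subsample fraction (counts from a subsample represent
#' `1/fraction` times as many animals) and by the sampled core area of
#' the platform.
#'
#' @param count individuals counted (possibly in a subsample).
#' @param afdm_total_g summed ash-free dry mass (g) of those individuals,
#'   or `NA` when not measured.
#' @param subsample_fraction fraction of the sample that was processed,
#'   in (0, 1]; 1 means no subsampling.
#' @param platform `"boat"` or `"walk"`.
#' @param constants a [protocol_constants()] object.
#' @return list with `abundance_m2` and `afdm_m2` (the latter `NA` if
#'   `afdm_total_g` is `NA`).
#' @examples
#' standardize(10, NA, 0.5, "boat")$abundance_m2  # 10 / 0.5 / 0.0173
#' @export
standardize <- function(count, afdm_total_g = NA_real_, subsample_fraction = 1,
                        platform = "boat", constants = protocol_constants()) {
  if (any(subsample_fraction <= 0 | subsample_fraction > 1)) {
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  area <- platform_area(platform, constants)
  list(abundance_m2 = count / subsample_fraction / area,
       afdm_m2 = afdm_total_g / subsample_fraction / area)
}

#' Estimate razor-clam length from shell width
#'
#' *Ensis leei* shells usually break during sampling; length (mm) is then
#' estimated from the width of the top or bottom shell fragment as
#' `6.5 * width_top` or `6.6 * width_bottom`.
#'
#' @param width_mm fragment width (mm), non-negative.
#' @param part `"top"` or `"bottom"`.
#' @param constants a [protocol_constants()] object.
#' @return list with `length_mm` and `length_estimated = TRUE`.
#' @export
estimate_ensis_length <- function(width_mm, part = c("top", "bottom"),
                                  constants = protocol_constants()) {
  part <- match.arg(part)
  if (any(width_mm < 0)) stop("width must be non-negative", call. = FALSE)
  coef <- if (part == "top") constants$ensis_coef_top else constants$ensis_coef_bottom
  list(length_mm = coef * width_mm, length_estimated = TRUE)
}

#' Reduce a grain-size spectrum to median grain size and mud content
#'
#' Takes the volume fractions over the 126 geometric grain-size classes
#' and extracts (i) the volume percentage of particles finer than the mud
#' threshold (63 um), splitting the straddling class log-linearly, and
#' (ii) the median grain size, interpolated log-linearly inside the class
#' where the cumulative volume curve crosses 0.5.
#'
#' @param fractions numeric vector of per-class volume fractions; must be
#'   non-negative and sum to 1 within 1e-6.
#' @param constants a [protocol_constants()] object (supplies the class
#'   edges and mud threshold).
#' @return list with `median_grain_size` (um) and `percentage_mud`.
#' @export
reduce_sediment_spectrum <- function(fractions, constants = protocol_constants()) {
  edges <- constants$grain_edges
  if (length(fractions) != length(edges) - 1L) {
    stop(sprintf("expected %d class fractions", length(edges) - 1L), call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  le <- log10(edges)
  lo <- le[-length(le)]; hi <- le[-1]

  ## mud: classes wholly below the threshold plus the log-linear share of
  ## the straddling class
  lt <- log10(constants$mud_threshold)
  below <- pmin(pmax((lt - lo) / (hi - lo), 0), 1)
  percentage_mud <- 100 * sum(fractions * below)

  ## median: first class where the cumulative curve reaches 0.5
  cum <- cumsum(fractions)
  k <- which(cum >= 0.5 - 1e-12)[1]
  cum_lo <- if (k == 1L) 0 else cum[k - 1L]
  mgs <- if (fractions[k] <= 0) {
    10^lo[k]
  } else {
    10^(lo[k] + (0.5 - cum_lo) / fractions[k] * (hi[k] - lo[k]))
  }
  list(median_grain_size = mgs, percentage_mud = percentage_mud)
}
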