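## The published three-file data model: samples.csv (station visits and
## sediment), species.csv (taxon metadata), biota.csv (per-sample,
## per-taxon densities; absences are not stored). Column names follow
## the published tables verbatim, including their spellings
## ("occurance", "taxonomic_indentification_level").

samples_columns <- c("sample_id", "sampling_station_id", "sampling_type",
                     "date", "platform", "tidal_basin_name",
                     "tidal_flat_name", "x", "y",
                     "median_grain_size", "percentage_mud")
species_columns <- c("sibes_id", "name", "short_name", "aphia_id",
                     "taxonomic_group", "taxonomic_indentification_level",
                     "year_added", "occurance", "occupancy",
                     "weight_is_measured", "length_measuring_method_id",
                     "min_shell_length_to_separate_flesh",
                     "missing_afdm_method_id", "remarks")
biota_columns <- c("sample_id", "sibes_id", "abundance_m2", "afdm_m2")

#' Printed annual station counts of the monitoring programme
#'
#' The published per-year campaign summary (2008-2021): stations sampled
#' in total, on the grid, and at random positions, the percentage of
#' random stations and of boat-based samples, and the number of samples
#' processed in the laboratory. Shipped as a package fixture for
#' summary-reproduction checks.
#'
#' @return data.frame with columns `year`, `total`, `grid`, `random`,
#'   `pct_random`, `pct_boating`, `processed`.
#' @export
annual_station_counts <- function() {
  utils::read.csv(system.file("extdata", "annual_station_counts.csv",
                              package = "sibesim"))
}

#' Species-table template
#'
#' Builds a `species.csv`-shaped table, optionally populated from the
#' ground-truth species of a synthetic world.
#'
#' @param truth list of [species_truth()] objects (or `NULL` for an
#'   empty table).
#' @return data.frame with the published species columns plus the
#'   working flags `small_species` and `count_whole_only`.
#' @export
species_template <- function(truth = NULL) {
  n <- length(truth)
  df <- data.frame(
    sibes_id = integer(n), name = character(n), short_name = character(n),
    aphia_id = NA_integer_, taxonomic_group = character(n),
    taxonomic_indentification_level = "species",
    year_added = 2008L, occurance = NA_integer_, occupancy = NA_real_,
    weight_is_measured = TRUE, length_measuring_method_id = 1L,
    min_shell_length_to_separate_flesh = NA_real_,
    missing_afdm_method_id = 24L, remarks = NA_character_,
    small_species = FALSE, count_whole_only = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- truth[[i]]
    df$sibes_id[i] <- sp$sibes_id
    df$name[i] <- sp$name
    df$short_name[i] <- abbreviate(sp$name, 8)
    df$taxonomic_group[i] <- sp$taxonomic_group
    df$small_species[i] <- sp$small_species
  }
  df
}

## ---- reading and writing ---------------------------------------------

## declared column types so empty (all-NA) columns keep their class
## across a write/read round trip
column_types <- c(
  sample_id = "character", sampling_station_id = "integer",
  sampling_type = "character", date = "character", platform = "character",
  tidal_basin_name = "character", tidal_flat_name = "character",
  x = "numeric", y = "numeric", median_grain_size = "numeric",
  percentage_mud = "numeric",
  sibes_id = "integer", name = "character", short_name = "character",
  aphia_id = "integer", taxonomic_group = "character",
  taxonomic_indentification_level = "character", year_added = "integer",
  occurance = "integer", occupancy = "numeric",
  weight_is_measured = "logical", length_measuring_method_id = "integer",
  min_shell_length_to_separate_flesh = "numeric",
  missing_afdm_method_id = "integer", remarks = "character",
  small_species = "logical", count_whole_only = "logical",
  abundance_m2 = "numeric", afdm_m2 = "numeric")

read_table_checked <- function(path, columns) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(sprintf("'%s' lacks required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in intersect(names(df), names(column_types))) {
    df[[nm]] <- switch(column_types[[nm]],
                       character = as.character(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]))
  }
  df
}

#' Read / write the published CSV files
#'
#' Thin, schema-checked wrappers around CSV input/output. Missing values
#' are written as empty fields by default (`na`), and dates are written
#' in ISO-8601. Reading checks the published column sets are present.
#'
#' @param path file path.
#' @param x table to write.
#' @param na missing-value token used on output.
#' @return the table (read) or `invisible(path)` (write).
#' @name dataset_files
#' @export
read_samples <- function(path) read_table_checked(path, samples_columns)

#' @rdname dataset_files
#' @export
read_species <- function(path) read_table_checked(path, species_columns)

#' @rdname dataset_files
#' @export
read_biota <- function(path) read_table_checked(path, biota_columns)

write_table <- function(x, path, na) {
  if ("date" %in% names(x)) x$date <- format(as.Date(x$date), "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, na = na)
  invisible(path)
}

#' @rdname dataset_files
#' @export
write_samples <- function(x, path, na = "") write_table(x, path, na)

#' @rdname dataset_files
#' @export
write_species <- function(x, path, na = "") write_table(x, path, na)

#' @rdname dataset_files
#' @export
write_biota <- function(x, path, na = "") write_table(x, path, na)

## ---- building the published tables from a simulated campaign ----------

#' Export a simulated campaign's station visits as a samples table
#'
#' @param campaign result of [simulate_campaign()].
#' @param stations the station data.frame the campaign was run on.
#' @return data.frame with the published `samples.csv` columns
#'   (coordinates in WGS84 decimal degrees).
#' @export
as_samples_table <- function(campaign, stations) {
  s <- campaign$samples
  idx <- match(s$sampling_station_id, stations$station_id)
  ll <- planar_to_wgs84(s$x, s$y)
  data.frame(
    sample_id = s$sample_id,
    sampling_station_id = s$sampling_station_id,
    sampling_type = stations$sampling_type[idx],
    date = format(s$date, "%Y-%m-%d"),
    platform = s$platform,
    tidal_basin_name = paste0("basin_", s$tidal_basin_id),
    tidal_flat_name = paste0("flat_", s$tidal_basin_id),
    x = ll$lon, y = ll$lat,
    median_grain_size = s$median_grain_size,
    percentage_mud = s$percentage_mud,
    stringsAsFactors = FALSE)
}

#' Aggregate individual records into a biota table
#'
#' Standardizes every measured individual to per-square-metre units
#' (dividing by its subsample fraction and by the platform's core area)
#' and sums per sample and taxon, exactly how the published `biota.csv`
#' is built. Samples where a taxon is absent yield no row.
#'
#' @param individuals individual-record table (see [simulate_campaign()]),
#'   ideally after [impute_missing_afdm()].
#' @param samples the campaign samples table (supplies the platform).
#' @param constants a [protocol_constants()].
#' @return data.frame with columns `sample_id`, `sibes_id`,
#'   `abundance_m2`, `afdm_m2`.
#' @export
as_biota_table <- function(individuals, samples,
                           constants = protocol_constants()) {
  if (nrow(individuals) == 0L) {
    return(data.frame(sample_id = character(), sibes_id = integer(),
                      abundance_m2 = numeric(), afdm_m2 = numeric()))
  }
  platform <- samples$platform[match(individuals$sample_id, samples$sample_id)]
  area <- platform_area(platform, constants)
  contrib_n <- 1 / individuals$subsample_fraction / area
  contrib_m <- individuals$afdm_g / individuals$subsample_fraction / area
  key <- interaction(individuals$sample_id, individuals$sibes_id, drop = TRUE)
  out <- data.frame(
    sample_id = tapply(individuals$sample_id, key, `[`, 1),
    sibes_id = as.integer(tapply(individuals$sibes_id, key, `[`, 1)),
    abundance_m2 = as.numeric(tapply(contrib_n, key, sum)),
    afdm_m2 = as.numeric(tapply(contrib_m, key, function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$sibes_id), ]
  rownames(out) <- NULL
  out
}

## ---- validation -------------------------------------------------------

#' Validate the three published tables
#'
#' Checks key uniqueness, enumerations, value ranges and referential
#' integrity (every biota row must point at an existing sample and
#' taxon).
#'
#' @param samples,species,biota the three tables.
#' @return data.frame of class `validation_report` with columns `table`,
#'   `rule`, `n`, `detail`; zero rows means a clean dataset. The
#'   attribute `n_violations` carries the total.
#' @export
validate_tables <- function(samples, species, biota) {
  v <- list()
  add <- function(tab, rule, n, detail) {
    if (n > 0) v[[length(v) + 1L]] <<- data.frame(
      table = tab, rule = rule, n = n, detail = detail,
      stringsAsFactors = FALSE)
  }
  dup <- duplicated(samples$sample_id)
  add("samples", "duplicate key", sum(dup),
      paste(utils::head(samples$sample_id[dup], 3), collapse = ", "))
  add("samples", "unknown enum: platform",
      sum(!samples$platform %in% c("boat", "walk")), "platform not boat/walk")
  add("samples", "unknown enum: sampling_type",
      sum(!samples$sampling_type %in% c("grid", "random")),
      "sampling_type not grid/random")
  mud <- samples$percentage_mud
  add("samples", "range: percentage_mud",
      sum(!is.na(mud) & (mud < 0 | mud > 100)), "percentage_mud outside [0,100]")
  add("samples", "range: coordinates",
      sum(!is.na(samples$x) & (samples$x < -180 | samples$x > 180)) +
        sum(!is.na(samples$y) & (samples$y < -90 | samples$y > 90)),
      "lon/lat outside plausible ranges")

  dup <- duplicated(species$sibes_id)
  add("species", "duplicate key", sum(dup),
      paste(utils::head(species$sibes_id[dup], 3), collapse = ", "))
  add("species", "range: occupancy",
      sum(!is.na(species$occupancy) &
            (species$occupancy < 0 | species$occupancy > 100)),
      "occupancy outside [0,100]")
  add("species", "range: aphia_id",
      sum(!is.na(species$aphia_id) & species$aphia_id <= 0),
      "aphia_id not a positive integer")

  dup <- duplicated(biota[c("sample_id", "sibes_id")])
  add("biota", "duplicate key", sum(dup), "(sample_id, sibes_id) repeated")
  add("biota", "referential: sample_id",
      sum(!biota$sample_id %in% samples$sample_id),
      "biota rows referencing absent samples")
  add("biota", "referential: sibes_id",
      sum(!biota$sibes_id %in% species$sibes_id),
      "biota rows referencing absent taxa")
  add("biota", "range: abundance_m2",
      sum(!is.na(biota$abundance_m2) & biota$abundance_m2 <= 0),
      "stored rows must have positive abundance")
  add("biota", "range: afdm_m2",
      sum(!is.na(biota$afdm_m2) & biota$afdm_m2 < 0), "negative biomass")

  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), rule = character(), n = integer(),
               detail = character())
  structure(rep, n_violations = sum(rep$n),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("validation: clean, no violations\n")
  else {
    cat(sprintf("validation: %d violation(s)\n", attr(x, "n_violations")))
    print.data.frame(x)
  }
  invisible(x)
}

## ---- zero filling and summaries ---------------------------------------

#' Densify the biota table with explicit zeros
#'
#' Absences are not stored in `biota.csv`; analyses of densities or
#' richness need them back. Crossing every sample with every requested
#' taxon yields exactly `|samples| x |taxa|` rows, with zeros where no
#' biota row exists.
#'
#' @param samples,species,biota the three tables.
#' @param taxa taxon ids to densify over (default: all of `species`).
#' @return data.frame `sample_id`, `sibes_id`, `abundance_m2`, `afdm_m2`
#'   with explicit zeros.
#' @export
zero_fill <- function(samples, species, biota, taxa = NULL) {
  if (is.null(taxa)) taxa <- species$sibes_id
  if (!all(taxa %in% species$sibes_id)) {
    stop("taxa subset contains ids absent from the species table", call. = FALSE)
  }
  dense <- expand.grid(sample_id = samples$sample_id, sibes_id = taxa,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(dense$sample_id, dense$sibes_id),
               paste(biota$sample_id, biota$sibes_id))
  dense$abundance_m2 <- ifelse(is.na(idx), 0, biota$abundance_m2[idx])
  dense$afdm_m2 <- ifelse(is.na(idx), 0, biota$afdm_m2[idx])
  dense$afdm_m2[is.na(dense$afdm_m2)] <- 0
  dense
}

#' Campaign summary in the style of the published per-year table
#'
#' Summarises per-year station counts (total, grid, random, percentage
#' random, percentage boat-based) and appends an averages row over an
#' explicit year range plus the min/max yearly totals. Percentages are
#' rounded half-up, matching the printed tables; the default averaging
#' range is 2008-2019 (the published means equal that range's
#' arithmetic means).
#'
#' @param counts either a per-year counts data.frame (columns `year`,
#'   `total`, `grid`, `random`, optionally `pct_boating` or `boat`,
#'   `processed`) such as [annual_station_counts()], or a samples table
#'   with `date`/`year`, `sampling_type` and `platform` columns to be
#'   tallied.
#' @param year_range years entering the averages row.
#' @return list of class `campaign_summary`: `yearly` (with derived
#'   `pct_random`), `averages` (one row), `min_total`, `max_total`,
#'   `year_range`.
#' @export
summarize_campaign <- function(counts, year_range = 2008:2019) {
  if (all(c("sample_id", "sampling_type") %in% names(counts))) {
    yr <- if ("year" %in% names(counts)) counts$year
    else as.integer(format(as.Date(counts$date), "%Y"))
    tab <- data.frame(year = sort(unique(yr)))
    tab$total <- as.integer(table(yr)[as.character(tab$year)])
    tab$grid <- vapply(tab$year, function(y)
      sum(yr == y & counts$sampling_type == "grid"), integer(1))
    tab$random <- tab$total - tab$grid
    if ("platform" %in% names(counts)) {
      tab$boat <- vapply(tab$year, function(y)
        sum(yr == y & counts$platform == "boat"), integer(1))
    }
    counts <- tab
  }
  if (nrow(counts) == 0L) {
    return(structure(list(yearly = counts, averages = counts,
                          min_total = NA, max_total = NA,
                          year_range = year_range),
                     class = "campaign_summary"))
  }
  yearly <- counts
  yearly$pct_random <- as.integer(round_half_up(100 * yearly$random / yearly$total))
  if (!("pct_boating" %in% names(yearly)) && "boat" %in% names(yearly)) {
    yearly$pct_boating <- as.integer(round_half_up(100 * yearly$boat / yearly$total))
  }
  in_range <- yearly$year %in% year_range
  avg_cols <- intersect(c("total", "grid", "random", "pct_random",
                          "pct_boating", "processed"), names(yearly))
  averages <- as.data.frame(lapply(yearly[in_range, avg_cols, drop = FALSE],
                                   function(v) as.integer(round_half_up(mean(v)))))
  structure(
    list(yearly = yearly, averages = averages,
         min_total = min(yearly$total), max_total = max(yearly$total),
         year_range = year_range),
    class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  print.data.frame(x$yearly)
  cat(sprintf("averages over %d-%d:\n", min(x$year_range), max(x$year_range)))
  print.data.frame(x$averages)
  cat(sprintf("yearly totals range: %d - %d\n", x$min_total, x$max_total))
  invisible(x)
}

#' Community summaries from a zero-filled table
#'
#' Computes per-sample species richness (taxa with positive abundance)
#' and total biomass, per-year per-taxon mean densities, and the
#' cross-year mean with its standard error among years (SD over yearly
#' means divided by the square root of the number of years).
#'
#' @param dense a [zero_fill()] result; a non-dense table is rejected
#'   because richness would be ill-defined.
#' @param samples the samples table (must map `sample_id` to a year via
#'   `date` or `year`).
#' @return list with `per_sample` (`sample_id`, `richness`,
#'   `total_afdm_m2`), `yearly` (`year`, `sibes_id`, `mean_abundance_m2`,
#'   `mean_afdm_m2`, `n_samples`) and `cross_year` (`sibes_id`, means
#'   and `se_*` among years, `n_years`).
#' @export
summarize_community <- function(dense, samples) {
  n_taxa <- length(unique(dense$sibes_id))
  if (nrow(dense) != nrow(samples) * n_taxa ||
      !all(samples$sample_id %in% dense$sample_id)) {
    stop("input is not a zero-filled sample x taxon table; run zero_fill()",
         call. = FALSE)
  }
  per_sample <- data.frame(
    sample_id = samples$sample_id,
    richness = as.integer(tapply(dense$abundance_m2 > 0, dense$sample_id,
                                 sum)[samples$sample_id]),
    total_afdm_m2 = as.numeric(tapply(dense$afdm_m2, dense$sample_id,
                                      sum)[samples$sample_id]))
  yr <- if ("year" %in% names(samples)) samples$year
  else as.integer(format(as.Date(samples$date), "%Y"))
  dense$year <- yr[match(dense$sample_id, samples$sample_id)]
  key <- interaction(dense$year, dense$sibes_id, drop = TRUE)
  yearly <- data.frame(
    year = as.integer(tapply(dense$year, key, `[`, 1)),
    sibes_id = as.integer(tapply(dense$sibes_id, key, `[`, 1)),
    mean_abundance_m2 = as.numeric(tapply(dense$abundance_m2, key, mean)),
    mean_afdm_m2 = as.numeric(tapply(dense$afdm_m2, key, mean)),
    n_samples = as.integer(tapply(dense$abundance_m2, key, length)))
  rownames(yearly) <- NULL
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  cross <- do.call(rbind, lapply(split(yearly, yearly$sibes_id), function(d)
    data.frame(sibes_id = d$sibes_id[1],
               mean_abundance_m2 = mean(d$mean_abundance_m2),
               se_abundance_m2 = se(d$mean_abundance_m2),
               mean_afdm_m2 = mean(d$mean_afdm_m2),
               se_afdm_m2 = se(d$mean_afdm_m2),
               n_years = nrow(d))))
  rownames(cross) <- NULL
  list(per_sample = per_sample, yearly = yearly, cross_year = cross)
}
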