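## Species-specific biomass-length modelling and hierarchical imputation.
##
## Missing ash-free dry mass (AFDM) is predicted from length with a LOESS
## of log(AFDM) on log(length) (span 0.6), fitted at the smallest spatial/
## temporal scale holding enough records: the data are filtered per
## season (all years pooled), then per year, then per region, then per
## tidal basin, and the finest level with at least 75 records (45 for
## taxa under 11 mm) is used. Records without length fall back to a
## hierarchical average with a 30-record minimum. Gross errors are
## fenced at the residual quartiles plus/minus twice the interquartile
## range before the final fit.

scale_levels <- c("season", "year", "region", "basin")

## vectorised core: counts matrix (one ladder per row, columns coarse to
## fine), returns 0 when no level qualifies, else the index of the
## finest qualifying level
scale_from_counts <- function(counts, threshold) {
  counts <- matrix(counts, ncol = length(scale_levels))
  res <- integer(nrow(counts))
  for (j in seq_along(scale_levels)) res[counts[, j] >= threshold] <- j
  res
}

#' Select the imputation scale from a record-count ladder
#'
#' @param counts named numeric vector (or matrix, one ladder per row)
#'   with record counts at the levels `season`, `year`, `region`,
#'   `basin`, ordered coarse to fine.
#' @param small_species logical; taxa under 11 mm need only 45 records
#'   for a LOESS fit instead of 75.
#' @param purpose `"loess"` (biomass-length model) or `"mean"`
#'   (hierarchical average, 30-record minimum).
#' @param constants a [protocol_constants()] (supplies the thresholds).
#' @return the finest qualifying level name (`NA` if none); a character
#'   vector when `counts` is a matrix.
#' @export
select_scale <- function(counts, small_species = FALSE,
                         purpose = c("loess", "mean"),
                         constants = protocol_constants()) {
  purpose <- match.arg(purpose)
  threshold <- if (purpose == "mean") constants$scale_threshold_mean
  else if (isTRUE(small_species)) constants$scale_threshold_small
  else constants$scale_threshold_standard
  idx <- scale_from_counts(counts, threshold)
  ifelse(idx == 0L, NA_character_, scale_levels[pmax(idx, 1L)])
}

#' Flag biomass-length outliers by the 2 x IQR rule
#'
#' Residuals are taken on the model's fitting scale (log mass); records
#' fall outside the fences `Q1 - 2 IQR` and `Q3 + 2 IQR` of the residual
#' distribution are flagged.
#'
#' @param records data.frame with `length_mm` and `afdm_g`.
#' @param model an [fit_allometry()] model for the same taxon.
#' @return logical vector of flags. With fewer than 4 records quartiles
#'   are undefined: all `FALSE`, with a warning.
#' @export
detect_outliers <- function(records, model) {
  if (nrow(records) < 4L) {
    warning("fewer than 4 records; quartiles undefined, no outliers flagged")
    return(rep(FALSE, nrow(records)))
  }
  r <- log(records$afdm_g) - predict_allometry(model, records$length_mm,
                                               log_scale = TRUE)$afdm
  q <- stats::quantile(r, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  ## absolute guard so numerically-zero residual spread (noiseless data)
  ## does not flag floating-point dust
  eps <- 1e-8
  flag <- r < q[1] - 2 * iqr - eps | r > q[2] + 2 * iqr + eps
  flag & !is.na(flag)
}

#' Share of flagged outliers, as printed in QC reports
#'
#' @param n_outliers,n_total counts of flagged and total records.
#' @param digits decimal places (half-up rounding).
#' @return percentage of records flagged.
#' @export
outlier_share <- function(n_outliers, n_total, digits = 1) {
  round_half_up(100 * n_outliers / n_total, digits)
}

#' Fit a species-specific LOESS biomass-length model
#'
#' Locally weighted regression of `log(AFDM)` on `log(length)` with span
#' 0.6 (the power-law allometry is locally linear on that scale, so the
#' smoother tracks it without small-length bias).
#' After a first fit, records outside the 2 x IQR residual fences are
#' removed and the model refitted once. Predictions are restricted to
#' the training length range (no extrapolation; requests outside the
#' domain are clamped to its edge and flagged).
#'
#' @param records data.frame with positive `length_mm` and `afdm_g`.
#' @param taxon optional species row (used for the record-count
#'   threshold: standard 75, small species 45) — a list with at least
#'   `small_species` or `sibes_id`; `NULL` applies the standard threshold.
#' @param level the hierarchical level the records come from (bookkeeping).
#' @param constants a [protocol_constants()].
#' @param min_records override of the applicable record-count threshold.
#' @return object of class `allometry_model`: the LOESS fit, `domain`
#'   (training length range), `n_records`, `n_outliers_removed`,
#'   `residual_se`, `span`, `taxon_id`, `level`.
#' @export
fit_allometry <- function(records, taxon = NULL, level = NA_character_,
                          constants = protocol_constants(),
                          min_records = NULL) {
  ok <- !is.na(records$length_mm) & !is.na(records$afdm_g) &
    records$length_mm > 0 & records$afdm_g > 0
  records <- records[ok, , drop = FALSE]
  small <- isTRUE(taxon$small_species)
  if (is.null(min_records)) {
    min_records <- if (small) constants$scale_threshold_small
    else constants$scale_threshold_standard
  }
  if (nrow(records) < min_records) {
    stop(sprintf(paste("insufficient records (%d < %d) at this scale;",
                       "use select_scale() to find a coarser level"),
                 nrow(records), min_records), call. = FALSE)
  }
  ## the power-law allometry is locally linear in log-log; fitting there
  ## keeps the span-0.6 smoother unbiased across the length range
  fit1 <- stats::loess(log(afdm_g) ~ log(length_mm), data = records,
                       span = constants$loess_span, degree = 2,
                       control = stats::loess.control(surface = "direct"))
  m <- structure(
    list(fit = fit1, domain = range(records$length_mm),
         span = constants$loess_span,
         taxon_id = if (is.null(taxon$sibes_id)) NA_integer_ else taxon$sibes_id,
         level = level, n_records = nrow(records), n_outliers_removed = 0L,
         residual_se = stats::sd(fit1$residuals)),
    class = "allometry_model")
  flags <- suppressWarnings(detect_outliers(records, m))
  if (any(flags) && sum(!flags) >= min_records) {
    kept <- records[!flags, , drop = FALSE]
    fit2 <- stats::loess(log(afdm_g) ~ log(length_mm), data = kept,
                         span = constants$loess_span, degree = 2,
                         control = stats::loess.control(surface = "direct"))
    m$fit <- fit2
    m$domain <- range(kept$length_mm)
    m$n_records <- nrow(kept)
    m$n_outliers_removed <- sum(flags)
    m$residual_se <- stats::sd(fit2$residuals)
  }
  m
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf(paste0("<allometry_model> taxon %s, level %s: n = %d",
                     " (%d outliers removed), span %.2f, domain %.1f-%.1f mm,",
                     " residual SE %.3f\n"),
              x$taxon_id, x$level, x$n_records, x$n_outliers_removed,
              x$span, x$domain[1], x$domain[2], x$residual_se))
  invisible(x)
}

#' Predict AFDM from length with an allometry model
#'
#' @param model an [fit_allometry()] model.
#' @param length_mm lengths (mm); values outside the training domain are
#'   clamped to its nearest edge.
#' @param log_scale return the prediction on the log scale.
#' @return list with `afdm` (g, or log g) and `extrapolated` flags.
#' @export
predict_allometry <- function(model, length_mm, log_scale = FALSE) {
  lo <- model$domain[1]; hi <- model$domain[2]
  extrapolated <- !is.na(length_mm) & (length_mm < lo | length_mm > hi)
  lcl <- pmin(pmax(length_mm, lo), hi)
  p <- unname(stats::predict(model$fit, data.frame(length_mm = lcl)))
  list(afdm = if (log_scale) p else exp(p), extrapolated = extrapolated)
}

## default region grouping: western vs eastern half of the basin ids
basin_region <- function(basin_id) {
  ids <- sort(unique(basin_id[!is.na(basin_id)]))
  if (length(ids) == 0L) return(rep(NA_character_, length(basin_id)))
  west <- ids[seq_len(ceiling(length(ids) / 2))]
  ifelse(is.na(basin_id), NA_character_,
         ifelse(basin_id %in% west, "west", "east"))
}

## ladder of nested record subsets for one target record
ladder_subsets <- function(pool, rec) {
  list(season = rep(TRUE, nrow(pool)),
       year = pool$era == rec$era,
       region = pool$era == rec$era & !is.na(pool$region) &
         pool$region %in% rec$region,
       basin = pool$era == rec$era & !is.na(pool$tidal_basin_id) &
         pool$tidal_basin_id %in% rec$tidal_basin_id)
}

#' Impute one record's missing AFDM
#'
#' Dispatch for a single individual lacking a measured mass: with a
#' length available and a qualifying biomass-length model, the LOESS
#' prediction is used (method 24); otherwise a qualifying hierarchical
#' average (method 12), or the average over prior years only for taxa
#' whose species-table method is 25. Returns the provenance alongside
#' the value.
#'
#' @param record one-row data.frame (or list) with `length_mm`, `era`,
#'   `region`, `tidal_basin_id` and missing `afdm_g`.
#' @param taxon the species row ([species_template()] fields).
#' @param pool data.frame of the taxon's complete records (`length_mm`,
#'   `afdm_g`, `era`, `region`, `tidal_basin_id`) the banks are built from.
#' @param constants a [protocol_constants()].
#' @param cache optional environment; LOESS fits are memoised in it by
#'   (taxon, level, stratum) so bulk imputation does not refit per record.
#' @return list with `afdm_g` (`NA` when nothing qualifies), `method`
#'   (24, 12, 25 or `NA`), `level`, `reason`.
#' @export
impute_afdm <- function(record, taxon, pool, constants = protocol_constants(),
                        cache = NULL) {
  if (!is.null(record$afdm_g) && !is.na(record$afdm_g)) {
    stop("record already carries a measured AFDM", call. = FALSE)
  }
  method_id <- if (is.null(taxon$missing_afdm_method_id) ||
                   is.na(taxon$missing_afdm_method_id)) 24L
  else as.integer(taxon$missing_afdm_method_id)
  historical <- identical(method_id, 25L)
  base_pool <- if (historical) pool[pool$era < record$era, , drop = FALSE] else pool
  subs <- ladder_subsets(base_pool, record)
  counts <- vapply(subs, sum, numeric(1))

  if (!historical && !is.na(record$length_mm)) {
    lvl <- select_scale(counts, small_species = isTRUE(taxon$small_species),
                        purpose = "loess", constants = constants)
    if (!is.na(lvl)) {
      stratum <- switch(lvl,
                        season = "",
                        year = record$era,
                        region = paste(record$era, record$region),
                        basin = paste(record$era, record$region,
                                      record$tidal_basin_id))
      key <- paste("loess", taxon$sibes_id, lvl, stratum, sep = "|")
      m <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else
        fit_allometry(base_pool[subs[[lvl]], , drop = FALSE], taxon = taxon,
                      level = lvl, constants = constants)
      if (!is.null(cache)) cache[[key]] <- m
      p <- predict_allometry(m, record$length_mm)
      return(list(afdm_g = p$afdm, method = 24L, level = lvl,
                  reason = if (p$extrapolated) "extrapolation clamped" else "ok"))
    }
  }
  lvl <- select_scale(counts, purpose = "mean", constants = constants)
  if (!is.na(lvl)) {
    val <- mean(base_pool$afdm_g[subs[[lvl]]])
    return(list(afdm_g = val, method = if (historical) 25L else 12L,
                level = lvl, reason = "ok"))
  }
  list(afdm_g = NA_real_, method = NA_integer_, level = NA_character_,
       reason = "insufficient records")
}

#' Impute all missing AFDM values in an individuals table
#'
#' Bulk driver around [impute_afdm()]: joins basin/region context from
#' the samples table, builds per-taxon pools of complete records, caches
#' LOESS fits per (taxon, level, stratum) and fills every record lacking
#' a mass. Provenance is returned as a separate audit table so the
#' published `biota.csv` stays schema-exact.
#'
#' @param individuals data.frame with `sample_id`, `sibes_id`,
#'   `length_mm`, `afdm_g`, `era`.
#' @param samples optional samples table supplying `tidal_basin_id` per
#'   `sample_id`.
#' @param taxa species table ([species_template()]), one row per taxon.
#' @param constants a [protocol_constants()].
#' @return list with `individuals` (AFDM filled where possible) and
#'   `audit` (row index, sample, taxon, method 24/12/25, level, value,
#'   reason for every record that needed imputation).
#' @export
impute_missing_afdm <- function(individuals, samples = NULL, taxa,
                                constants = protocol_constants()) {
  ind <- individuals
  if (!is.null(samples) && !("tidal_basin_id" %in% names(ind))) {
    ind$tidal_basin_id <-
      samples$tidal_basin_id[match(ind$sample_id, samples$sample_id)]
  }
  if (!("tidal_basin_id" %in% names(ind))) ind$tidal_basin_id <- NA_integer_
  if (!("region" %in% names(ind))) ind$region <- basin_region(ind$tidal_basin_id)
  if (!("era" %in% names(ind))) stop("individuals need an 'era' (year) column",
                                     call. = FALSE)
  complete <- !is.na(ind$length_mm) & !is.na(ind$afdm_g) &
    ind$length_mm > 0 & ind$afdm_g > 0
  todo <- which(is.na(ind$afdm_g))
  audit <- vector("list", length(todo))
  cache <- new.env(parent = emptyenv())
  pools <- split(ind[complete, , drop = FALSE], ind$sibes_id[complete])
  for (t in seq_along(todo)) {
    i <- todo[t]
    rec <- ind[i, ]
    taxon <- as.list(taxa[match(rec$sibes_id, taxa$sibes_id), ])
    pool <- pools[[as.character(rec$sibes_id)]]
    if (is.null(pool)) pool <- ind[0, , drop = FALSE]
    res <- impute_afdm(rec, taxon, pool, constants, cache = cache)
    ind$afdm_g[i] <- res$afdm_g
    audit[[t]] <- data.frame(
      row = i, sample_id = rec$sample_id, sibes_id = rec$sibes_id,
      method = res$method, level = res$level, imputed_afdm_g = res$afdm_g,
      reason = res$reason, stringsAsFactors = FALSE)
  }
  list(individuals = ind,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(row = integer(), sample_id = character(),
                    sibes_id = integer(), method = integer(),
                    level = character(), imputed_afdm_g = numeric(),
                    reason = character()))
}
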