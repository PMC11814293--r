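#' Specification of a grid-plus-random sampling design
#'
#' @param spacing inter-station distance of the systematic grid (m).
#' @param random_fraction target share of *all* stations that are random
#'   stations (random / total; the programme moved from ~10% to ~20%).
#' @param origin_offset `c(dx, dy)` of the grid origin within one cell,
#'   each in `[0, spacing)`; the "randomly selected starting position".
#' @param seed integer seed for random-station placement.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(spacing = 500, random_fraction = 0.20,
                        origin_offset = c(0, 0), seed = 1L) {
  stopifnot_positive(spacing, "spacing")
  if (random_fraction < 0 || random_fraction >= 1) {
    stop("random_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (any(origin_offset < 0) || any(origin_offset >= spacing)) {
    stop("origin_offset components must lie in [0, spacing)", call. = FALSE)
  }
  structure(list(spacing = spacing, random_fraction = random_fraction,
                 origin_offset = origin_offset, seed = as.integer(seed)),
            class = "design_spec")
}

## grid-node coordinates covering the raster extent
design_grid_nodes <- function(mask, spec) {
  ext <- raster_extent(mask)
  xs <- seq(ceiling((ext[["xmin"]] - spec$origin_offset[1]) / spec$spacing),
            floor((ext[["xmax"]] - spec$origin_offset[1] - 1e-9) / spec$spacing)) *
    spec$spacing + spec$origin_offset[1]
  ys <- seq(ceiling((ext[["ymin"]] - spec$origin_offset[2]) / spec$spacing),
            floor((ext[["ymax"]] - spec$origin_offset[2] - 1e-9) / spec$spacing)) *
    spec$spacing + spec$origin_offset[2]
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

## number of random stations solving n_r = round(f * (n_g + n_r))
n_random_for <- function(n_grid, fraction) {
  if (fraction <= 0 || n_grid == 0L) return(0L)
  cand <- 0:max(10L, ceiling(2 * fraction * n_grid / (1 - fraction)) + 10L)
  ok <- cand == round_half_up(fraction * (n_grid + cand))
  if (any(ok)) cand[ok][1] else
    cand[which.min(abs(cand - fraction * (n_grid + cand)))]
}

## in-mask gridline segments: one row per (cell, line) intersection, each
## of length = cell size; vertical and horizontal gridlines
gridline_segments <- function(mask, spec) {
  ext <- raster_extent(mask)
  nodes_x <- unique(design_grid_nodes(mask, spec)$x)
  nodes_y <- unique(design_grid_nodes(mask, spec)$y)
  segs <- list(); k <- 0L
  ## vertical lines x = const crossing each raster row
  ys0 <- mask$ymin + (seq_len(mask$ny) - 1L) * mask$cell
  for (xv in nodes_x) {
    cr <- raster_colrow(mask, rep(xv, mask$ny), ys0 + mask$cell / 2)
    ok <- !is.na(cr$col) & mask$values[cbind(cr$row, cr$col)]
    if (any(ok)) {
      k <- k + 1L
      segs[[k]] <- data.frame(orient = "v", at = xv, from = ys0[ok])
    }
  }
  xs0 <- mask$xmin + (seq_len(mask$nx) - 1L) * mask$cell
  for (yv in nodes_y) {
    cr <- raster_colrow(mask, xs0 + mask$cell / 2, rep(yv, mask$nx))
    ok <- !is.na(cr$col) & mask$values[cbind(cr$row, cr$col)]
    if (any(ok)) {
      k <- k + 1L
      segs[[k]] <- data.frame(orient = "h", at = yv, from = xs0[ok])
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, segs)
}

## draw n points uniformly over the total in-mask gridline length
sample_on_gridlines <- function(mask, spec, n) {
  segs <- gridline_segments(mask, spec)
  if (is.null(segs) || n == 0L) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  pick <- sample.int(nrow(segs), n, replace = TRUE)
  pos <- segs$from[pick] + stats::runif(n) * mask$cell
  x <- ifelse(segs$orient[pick] == "v", segs$at[pick], pos)
  y <- ifelse(segs$orient[pick] == "v", pos, segs$at[pick])
  data.frame(x = x, y = y)
}

station_frame <- function(station_id, sampling_type, x, y, basin_map,
                          first_year, active = TRUE) {
  n <- length(x)
  ll <- planar_to_wgs84(x, y)
  basin <- if (is.null(basin_map)) rep(NA_integer_, n)
  else raster_value_at(basin_map, x, y)
  sampling_type <- rep(sampling_type, length.out = n)
  first_year <- rep(as.integer(first_year), length.out = n)
  active <- rep(active, length.out = n)
  data.frame(station_id = station_id, sampling_type = sampling_type,
             x = x, y = y, lon = ll$lon, lat = ll$lat,
             tidal_basin_id = basin,
             tidal_basin_name = ifelse(is.na(basin), NA_character_,
                                       paste0("basin_", basin)),
             first_year = first_year, active = active,
             stringsAsFactors = FALSE)
}

#' Generate a grid-plus-random station design on a mudflat mask
#'
#' Overlays a systematic grid (nodes at `origin_offset` plus integer
#' multiples of `spacing`) on the intertidal mask, keeps the nodes that
#' fall on mudflat cells as grid stations, and then appends random
#' stations at uniform-random positions along the in-mask gridlines until
#' the random share of all stations reaches `random_fraction` (to the
#' nearest achievable count).
#'
#' @param mask a logical [mud_raster()]: `TRUE` where intertidal mudflat.
#' @param spec a [design_spec()].
#' @param basin_map optional integer [mud_raster()] of tidal-basin ids
#'   used to label stations.
#' @param first_year bookkeeping year recorded on the stations.
#' @return data.frame of stations (`station_id`, `sampling_type`, `x`,
#'   `y`, `lon`, `lat`, `tidal_basin_id`, `tidal_basin_name`,
#'   `first_year`, `active`); zero rows for an all-false mask.
#' @export
generate_design <- function(mask, spec = design_spec(), basin_map = NULL,
                            first_year = 2008L) {
  if (!inherits(mask, "mud_raster") || !is.logical(mask$values)) {
    stop("mask must be a logical mud_raster", call. = FALSE)
  }
  set.seed(child_seed(spec$seed, "design"))
  nodes <- design_grid_nodes(mask, spec)
  on_flat <- raster_value_at(mask, nodes$x, nodes$y)
  nodes <- nodes[!is.na(on_flat) & on_flat, , drop = FALSE]
  n_g <- nrow(nodes)
  n_r <- n_random_for(n_g, spec$random_fraction)
  rand <- sample_on_gridlines(mask, spec, n_r)
  n_r <- nrow(rand)
  if (n_g + n_r == 0L) {
    return(station_frame(integer(), character(), numeric(), numeric(),
                         basin_map, integer()))
  }
  station_frame(
    station_id = seq_len(n_g + n_r),
    sampling_type = rep(c("grid", "random"), c(n_g, n_r)),
    x = c(nodes$x, rand$x), y = c(nodes$y, rand$y),
    basin_map = basin_map, first_year = first_year)
}

#' Update a station design for a new year's mudflat configuration
#'
#' Mudflats erode and accrete, so the station set is maintained yearly:
#' stations whose cell is no longer mudflat are deactivated (identifiers
#' are retained and never reused), grid nodes on newly emerged mudflat
#' become new grid stations, and per tidal basin random stations are
#' added or deactivated until each basin's random share is within 2
#' percentage points of the target. Stations at unchanged locations keep
#' their identifiers.
#'
#' @param stations data.frame from [generate_design()] (same spacing and
#'   offset as `spec`).
#' @param new_mask logical [mud_raster()] for the new year.
#' @param spec the [design_spec()] the stations were generated with.
#' @param basin_map integer [mud_raster()] of tidal-basin ids.
#' @param year the new campaign year (recorded on added stations).
#' @return updated station data.frame.
#' @export
update_design <- function(stations, new_mask, spec, basin_map, year = NULL) {
  on_node <- function(v, off) abs((v - off) / spec$spacing -
                                    round((v - off) / spec$spacing)) < 1e-9
  grid_st <- stations$sampling_type == "grid"
  if (any(grid_st) && !all(on_node(stations$x[grid_st], spec$origin_offset[1]) &
                           on_node(stations$y[grid_st], spec$origin_offset[2]))) {
    stop("stations do not match the spec's spacing/offset", call. = FALSE)
  }
  set.seed(child_seed(spec$seed, paste0("update", year)))
  st <- stations
  on_flat <- raster_value_at(new_mask, st$x, st$y)
  st$active <- !is.na(on_flat) & on_flat

  ## new grid nodes
  nodes <- design_grid_nodes(new_mask, spec)
  nv <- raster_value_at(new_mask, nodes$x, nodes$y)
  nodes <- nodes[!is.na(nv) & nv, , drop = FALSE]
  occupied <- paste(st$x[grid_st], st$y[grid_st])
  fresh <- nodes[!(paste(nodes$x, nodes$y) %in% occupied), , drop = FALSE]
  next_id <- max(0L, st$station_id) + 1L
  if (nrow(fresh) > 0L) {
    st <- rbind(st, station_frame(
      station_id = seq.int(next_id, length.out = nrow(fresh)),
      sampling_type = "grid", x = fresh$x, y = fresh$y,
      basin_map = basin_map, first_year = if (is.null(year)) NA_integer_ else year))
    next_id <- next_id + nrow(fresh)
  }
  st$tidal_basin_id <- raster_value_at(basin_map, st$x, st$y)
  st$tidal_basin_name <- ifelse(is.na(st$tidal_basin_id), NA_character_,
                                paste0("basin_", st$tidal_basin_id))

  ## per-basin random-share maintenance (+/- 2 percentage points)
  target <- spec$random_fraction
  for (b in sort(unique(st$tidal_basin_id[st$active]))) {
    if (is.na(b)) next
    repeat {
      in_b <- st$active & !is.na(st$tidal_basin_id) & st$tidal_basin_id == b
      n_tot <- sum(in_b); n_rand <- sum(in_b & st$sampling_type == "random")
      share <- if (n_tot == 0L) target else n_rand / n_tot
      if (abs(share - target) <= 0.02) break
      if (share < target) {
        bmask <- new_mask
        bvals <- basin_map$values == b & new_mask$values
        bmask$values <- bvals
        pt <- sample_on_gridlines(bmask, spec, 1L)
        if (nrow(pt) == 0L) break
        st <- rbind(st, station_frame(
          station_id = next_id, sampling_type = "random",
          x = pt$x, y = pt$y, basin_map = basin_map,
          first_year = if (is.null(year)) NA_integer_ else year))
        next_id <- next_id + 1L
      } else {
        drop_id <- utils::tail(st$station_id[in_b & st$sampling_type == "random"], 1)
        st$active[st$station_id == drop_id] <- FALSE
      }
    }
  }
  rownames(st) <- NULL
  st
}

## ---- design evaluation -----------------------------------------------

## station layouts of equal size n for the five compared designs, on a
## rectangular extent; grid geometry is nx x ny nodes at `spacing`
design_points <- function(design, nx, ny, spacing, random_share = 0.2) {
  n <- nx * ny
  grid <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                      y = (seq_len(ny) - 1) * spacing, KEEP.OUT.ATTRS = FALSE)
  ext_x <- (nx - 1) * spacing; ext_y <- (ny - 1) * spacing
  switch(
    design,
    grid = grid,
    simple_random = data.frame(x = stats::runif(n, 0, ext_x),
                               y = stats::runif(n, 0, ext_y)),
    transect_A = , transect_B = {
      step <- if (design == "transect_A") spacing / 2 else spacing
      ## parallel vertical lines `spacing` apart, points every `step`;
      ## enough lines to reach n points, then truncated
      pts <- expand.grid(y = seq(0, ext_y, by = step),
                         x = (seq_len(nx) - 1) * spacing, KEEP.OUT.ATTRS = FALSE)
      pts <- pts[order(pts$x, pts$y), c("x", "y")]
      pts[seq_len(min(n, nrow(pts))), , drop = FALSE]
    },
    grid_plus_random = {
      n_r <- round(random_share * n)
      keep <- sort(sample.int(n, n - n_r))
      vertical <- stats::runif(n_r) < 0.5
      rx <- ifelse(vertical,
                   sample(grid$x[!duplicated(grid$x)], n_r, replace = TRUE),
                   stats::runif(n_r, 0, ext_x))
      ry <- ifelse(vertical,
                   stats::runif(n_r, 0, ext_y),
                   sample(grid$y[!duplicated(grid$y)], n_r, replace = TRUE))
      rbind(grid[keep, ], data.frame(x = rx, y = ry))
    },
    stop("unknown design: ", design, call. = FALSE))
}

#' Evaluate sampling designs by Monte-Carlo simulation
#'
#' Compares station layouts of equal size under spatially autocorrelated
#' fields, mirroring the simulation study that led to the grid-plus-
#' random design. Per replicate a zero-mean Gaussian field (exponential
#' covariance) is drawn jointly at every design's stations and at
#' hold-out points; per design it computes (1) the minimum detectable
#' difference between two periods/areas from the two-sample normal power
#' formula at alpha = 0.05 and power = 0.80, (2) the mean absolute
#' ordinary-kriging prediction error at the hold-out points, and (3) the
#' error of the fitted variogram range against the generating value.
#'
#' @param designs character subset of `c("simple_random", "grid",
#'   "transect_A", "transect_B", "grid_plus_random")`.
#' @param nx,ny grid nodes in x and y; every design gets `nx * ny`
#'   stations (the fairness contract).
#' @param spacing grid spacing (m).
#' @param field list with `nugget`, `sill` and the autocorrelation
#'   `range` (m); `range = 0` is the pure-nugget level.
#' @param n_reps Monte-Carlo replicates (>= 2).
#' @param n_holdout hold-out points per replicate for prediction error.
#' @param metrics which of `"mdd"`, `"prediction"`, `"range_bias"` to
#'   compute (dropping "prediction" skips the kriging step).
#' @param seed integer seed.
#' @return data.frame of class `design_evaluation`: one row per
#'   (design, metric) with columns `design`, `range_true`, `metric`,
#'   `value`, `n_reps`. `range_bias` is mean(fitted - true); `mdd` and
#'   `prediction_error` are means over replicates. An attribute
#'   `"per_rep"` carries the replicate-level values.
#' @export
evaluate_designs <- function(designs = c("simple_random", "grid", "transect_A",
                                         "transect_B", "grid_plus_random"),
                             nx = 10L, ny = 20L, spacing = 500,
                             field = list(nugget = 0.1, sill = 1, range = 500),
                             n_reps = 200L, n_holdout = 50L,
                             metrics = c("mdd", "prediction", "range_bias"),
                             seed = 1L) {
  designs <- match.arg(designs, several.ok = TRUE)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  n <- nx * ny
  set.seed(child_seed(seed, "evaluate"))
  ext_x <- (nx - 1) * spacing; ext_y <- (ny - 1) * spacing

  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pts <- lapply(designs, design_points, nx = nx, ny = ny, spacing = spacing)
    names(pts) <- designs
    sizes <- vapply(pts, nrow, integer(1))
    if (length(unique(sizes)) != 1L) {
      stop("designs yield unequal station counts; comparison would be unfair",
           call. = FALSE)
    }
    hold <- data.frame(x = stats::runif(n_holdout, 0, ext_x),
                       y = stats::runif(n_holdout, 0, ext_y))
    all_pts <- rbind(do.call(rbind, pts), hold)
    z <- as.vector(sim_grf(all_pts$x, all_pts$y, nugget = field$nugget,
                           psill = field$sill, range = field$range))
    idx <- split(seq_len(n * length(designs)),
                 rep(seq_along(designs), each = n))
    z_hold <- z[n * length(designs) + seq_len(n_holdout)]

    rows <- lapply(seq_along(designs), function(di) {
      zi <- z[idx[[di]]]; pi <- pts[[di]]
      out <- data.frame(design = designs[di], rep = r,
                        mean_est = mean(zi),
                        mdd = NA_real_, prediction_error = NA_real_,
                        range_est = NA_real_)
      if ("mdd" %in% metrics) {
        out$mdd <- (stats::qnorm(0.975) + stats::qnorm(0.80)) *
          stats::sd(zi) * sqrt(2 / n)
      }
      needs_fit <- any(c("prediction", "range_bias") %in% metrics) &&
        field$range > 0
      vg <- NULL
      if (needs_fit) {
        cg <- tryCatch(
          estimate_correlogram(pi$x, pi$y, zi, spacing = spacing),
          error = function(e) NULL)
        if (!is.null(cg)) {
          vg <- tryCatch(fit_variogram(cg), error = function(e) NULL)
        }
      }
      if ("range_bias" %in% metrics && !is.null(vg) && vg$converged &&
          !isTRUE(vg$unidentifiable)) {
        out$range_est <- vg$range
      }
      if ("prediction" %in% metrics) {
        model <- if (!is.null(vg) && vg$converged) vg else
          variogram_model(field$nugget, field$sill, max(field$range, spacing / 4))
        pred <- tryCatch(
          krige_points(pi$x, pi$y, zi, hold$x, hold$y, model),
          error = function(e) rep(mean(zi), n_holdout))
        out$prediction_error <- mean(abs(pred - z_hold))
      }
      out
    })
    per_rep[[r]] <- do.call(rbind, rows)
  }
  per_rep <- do.call(rbind, per_rep)

  agg <- do.call(rbind, lapply(designs, function(d) {
    pr <- per_rep[per_rep$design == d, ]
    data.frame(
      design = d, range_true = field$range,
      metric = c("mean_bias", "mdd", "prediction_error", "range_bias"),
      value = c(mean(pr$mean_est),
                mean(pr$mdd),
                mean(pr$prediction_error),
                mean(pr$range_est, na.rm = TRUE) - field$range),
      n_reps = n_reps)
  }))
  keep <- c("mean_bias",
            if ("mdd" %in% metrics) "mdd",
            if ("prediction" %in% metrics) "prediction_error",
            if ("range_bias" %in% metrics && field$range > 0) "range_bias")
  agg <- agg[agg$metric %in% keep, ]
  rownames(agg) <- NULL
  structure(agg, per_rep = per_rep, class = c("design_evaluation", "data.frame"))
}
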