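# Synthetic two-species camera-trap studies with exposed ground truth.
#
# The generator emulates the field design the pipeline targets: ~83 sites on
# a ~1.7 km grid surveyed for ~15 trap-days each, zero-inflated Poisson
# event counts driven by standardized site covariates through a log
# trap-day offset, diel event times from von Mises mixtures (diurnal
# unimodal vs crepuscular bimodal), and 3-photo bursts 1 min apart.

#' Default diel activity mixtures
#'
#' Serow: diurnal, 0.85 vM(noon, 2) + 0.15 uniform. Deer: crepuscular,
#' 0.45 vM(05:30, 4) + 0.45 vM(18:30, 4) + 0.10 uniform. The uniform
#' component keeps both densities strictly positive around the clock.
#'
#' @return named list of mixtures, each with weights, mu (radians), kappa.
#' @export
default_activity_mixtures <- function() {
  hr <- function(h) 2 * pi * h / 24
  list(
    serow = list(weights = c(0.85, 0.15), mu = c(hr(12), 0), kappa = c(2, 0)),
    deer = list(weights = c(0.45, 0.45, 0.10),
                mu = c(hr(5.5), hr(18.5), 0), kappa = c(4, 4, 0))
  )
}

#' Ground truth for a synthetic study
#'
#' Occurrence parameters are on the standardized covariate scale, slopes
#' ordered (slope, road, settlement, water, deciduous, coniferous,
#' other-species rate). The serow selects steep slopes and proximity to
#' water; the deer avoids settlements and also selects water. Neither
#' responds to the other's capture rate in generation.
#'
#' @param scenario "default", "separated" (species confined to opposite
#'   halves of the landscape) or "identical-activity" (deer given the
#'   serow's diel mixture).
#' @return list of class `synthetic_truth`.
#' @export
default_truth <- function(scenario = c("default", "separated",
                                       "identical-activity")) {
  scenario <- match.arg(scenario)
  mix <- default_activity_mixtures()
  if (scenario == "identical-activity") mix$deer <- mix$serow
  slopes <- function(v) stats::setNames(v, c("slope_mean_deg", "dist_road_km",
                                             "dist_settlement_km", "dist_water_km",
                                             "area_decid_km2", "area_conif_km2",
                                             "rate_other_species"))
  structure(list(
    scenario = scenario,
    n_sites = 83L,
    spacing_m = 1700,
    trap_days_mean = 15,
    serow = list(q = 0.7, beta0 = -1,
                 beta = slopes(c(0.5, 0, 0, -0.5, 0, 0, 0)),
                 mixture = mix$serow),
    deer = list(q = 0.55, beta0 = -1,
                beta = slopes(c(0, 0, 0.5, -0.5, 0, 0, 0)),
                mixture = mix$deer)
  ), class = "synthetic_truth")
}

.smooth_field <- function(x, y, phases, scale_m) {
  # superposed sinusoids with seeded random phases: smooth, bounded in [-3, 3]
  s <- 0
  for (k in seq_len(nrow(phases))) {
    s <- s + phases$amp[k] *
      sin(2 * pi * x / (scale_m * phases$fx[k]) + phases$px[k]) *
      cos(2 * pi * y / (scale_m * phases$fy[k]) + phases$py[k])
  }
  s
}

.random_phases <- function(k = 4) {
  data.frame(amp = stats::runif(k, 0.4, 1),
             fx = stats::runif(k, 0.8, 3), fy = stats::runif(k, 0.8, 3),
             px = stats::runif(k, 0, 2 * pi), py = stats::runif(k, 0, 2 * pi))
}

.random_polyline <- function(extent, n_vertices = 5) {
  x <- sort(stats::runif(n_vertices, 0, extent[1]))
  y <- stats::runif(1, 0, extent[2]) +
    cumsum(stats::rnorm(n_vertices, 0, extent[2] / 8))
  cbind(x = x, y = pmin(pmax(y, 0), extent[2]))
}

#' Generate a synthetic landscape and its site covariates
#'
#' Sites are jittered inside the cells of a regular grid with the given
#' spacing. The slope field is a superposition of seeded sinusoids sampled
#' on a regular 20 m point grid; settlements are random points, roads and
#' watercourses random polylines. Land cover within each 200 m buffer is
#' obtained by classifying the buffer's 20 m grid points with smooth cover
#' fields (forest extent plus a fine-scale forest-type split); grassland is
#' a noisy share of the open land and farmland tracks grassland, which
#' deliberately injects the collinearity the variance-inflation screen is
#' meant to catch. All covariates are computed through the package's own
#' geometry helpers.
#'
#' @param n_sites number of camera sites (>= 4; default 83).
#' @param spacing_m grid spacing in metres (default 1700).
#' @param seed integer seed.
#' @return list: `geometry` (sites, slope_raster, roads, settlements,
#'   water, landcover) and `covariates` (the covariates.csv schema).
#' @export
generate_landscape <- function(n_sites = 83, spacing_m = 1700, seed = 1) {
  if (n_sites < 4) stop("need at least 4 sites")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ncols <- ceiling(sqrt(n_sites))
  nrows <- ceiling(n_sites / ncols)
  extent <- c(ncols, nrows) * spacing_m
  idx <- seq_len(n_sites) - 1L
  site_x <- (idx %% ncols + stats::runif(n_sites, 0.2, 0.8)) * spacing_m
  site_y <- (idx %/% ncols + stats::runif(n_sites, 0.2, 0.8)) * spacing_m
  sites <- data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
                      x = site_x, y = site_y, stringsAsFactors = FALSE)

  slope_phases <- .random_phases(5)
  gx <- seq(0, extent[1], by = 20)
  gy <- seq(0, extent[2], by = 20)
  # restrict the raster to 220 m boxes around sites: identical values inside
  # every buffer, far smaller than rasterizing the whole landscape
  raster_pieces <- vector("list", n_sites)
  seen <- character(0)
  for (i in seq_len(n_sites)) {
    sx <- gx[abs(gx - site_x[i]) <= 220]
    sy <- gy[abs(gy - site_y[i]) <= 220]
    pts <- expand.grid(x = sx, y = sy, KEEP.OUT.ATTRS = FALSE)
    key <- paste(pts$x, pts$y)
    new <- !(key %in% seen)
    seen <- c(seen, key[new])
    raster_pieces[[i]] <- pts[new, , drop = FALSE]
  }
  raster <- do.call(rbind, raster_pieces)
  raster$slope_deg <- pmin(pmax(
    18 + 7 * .smooth_field(raster$x, raster$y, slope_phases, spacing_m * 2),
    0), 45)

  settlements <- list(points = cbind(x = stats::runif(8, 0, extent[1]),
                                     y = stats::runif(8, 0, extent[2])),
                      lines = list())
  roads <- list(points = NULL,
                lines = lapply(1:6, function(i) .random_polyline(extent)))
  water <- list(points = cbind(x = stats::runif(4, 0, extent[1]),
                               y = stats::runif(4, 0, extent[2])),
                lines = lapply(1:5, function(i) .random_polyline(extent)))

  # forest extent from one broad field, forest type (deciduous vs
  # coniferous) from a fine-scale field that varies within buffers: the two
  # forest areas share the extent signal but split it noisily
  cover_forest <- .random_phases(4); cover_type <- .random_phases(4)
  area_decid <- numeric(n_sites); area_conif <- numeric(n_sites)
  area_open <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    near <- abs(raster$x - site_x[i]) <= 200 & abs(raster$y - site_y[i]) <= 200
    sub <- raster[near, ]
    inside <- (sub$x - site_x[i])^2 + (sub$y - site_y[i])^2 <= 200^2
    sub <- sub[inside, ]
    forest <- .smooth_field(sub$x, sub$y, cover_forest, spacing_m * 1.5) > 0.2
    decid_type <- .smooth_field(sub$x, sub$y, cover_type, 600) > 0
    # class areas as exact fractions of the buffer area, so the land-cover
    # sum can never exceed it through grid discretization
    cell_km2 <- (pi * 200^2 / 1e6) / nrow(sub)
    area_decid[i] <- sum(forest & decid_type) * cell_km2
    area_conif[i] <- sum(forest & !decid_type) * cell_km2
    area_open[i] <- sum(!forest) * cell_km2
  }
  # injected collinearity: grassland is a noisy fixed share of the open
  # land -- and open land is the exact complement of the two forest areas,
  # so grassland is strongly collinear with them jointly -- while farmland
  # tracks grassland almost exactly. Iterative VIF screening therefore
  # strips exactly these two land-cover columns and leaves the rest clean.
  tau <- 0.45 * stats::sd(area_open) / 4
  area_grass <- pmin(pmax(0.45 * area_open + stats::rnorm(n_sites, 0, tau), 0),
                     0.62 * area_open)
  area_farm <- pmin(pmax(0.55 * area_grass + stats::rnorm(n_sites, 0, 1e-4), 0),
                    area_open - area_grass)

  geometry <- list(sites = sites, extent = extent, slope_raster = raster,
                   roads = roads, settlements = settlements, water = water,
                   landcover = data.frame(site_id = sites$site_id,
                                          area_decid_km2 = area_decid,
                                          area_conif_km2 = area_conif,
                                          area_grass_km2 = area_grass,
                                          area_farm_km2 = area_farm,
                                          stringsAsFactors = FALSE))
  covariates <- extract_site_covariates(geometry)
  list(geometry = geometry, covariates = covariates)
}

#' Draw diel event times from a von Mises mixture
#'
#' @param n number of draws.
#' @param mixture list with `weights` (summing to 1), `mu` (radians) and
#'   `kappa` (0 for a uniform component).
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @return radian times in `[0, 2*pi)`.
#' @export
generate_activity_times <- function(n, mixture, seed = NULL) {
  if (abs(sum(mixture$weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  out <- numeric(n)
  for (k in unique(comp)) {
    ii <- comp == k
    out[ii] <- rvonmises(sum(ii), mixture$mu[k], mixture$kappa[k])
  }
  out
}

.make_deployments <- function(n_sites, seed) {
  set.seed(seed)
  base <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC")
  batch <- (seq_len(n_sites) - 1L) %/% 20L
  start <- base + batch * 14 * 86400 + round(stats::runif(n_sites, 0, 6 * 3600))
  trap_days <- stats::runif(n_sites, 13.5, 16.5)
  data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
             start = start,
             end = start + round(trap_days * 86400),
             stringsAsFactors = FALSE) -> dep
  dep$trap_days <- as.numeric(difftime(dep$end, dep$start, units = "days"))
  dep
}

#' Generate detections for a synthetic study
#'
#' Per site and species: presence ~ Bernoulli(q); if present, the number of
#' independent events ~ Poisson(exp(beta0 + z beta + log T)) on the
#' standardized environmental covariates. Event clock times are drawn from
#' the species' diel mixture on a uniformly chosen deployment day; events
#' at a site are re-spaced so consecutive bursts are separated by more than
#' the 30-min window (the independence filter then recovers them exactly),
#' and each event expands to a 3-photo burst at 1-min spacing.
#'
#' @param truth a `synthetic_truth` from [default_truth()].
#' @param landscape result of [generate_landscape()].
#' @param seed integer seed.
#' @return list of class `synthetic_study`: detections, deployments,
#'   covariates, truth, realized (per site x species presence and event
#'   counts).
#' @export
generate_detections <- function(truth, landscape, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  covs <- landscape$covariates
  n <- nrow(covs)
  deployments <- .make_deployments(n, seed)
  set.seed(seed + 1L)
  env_cols <- c("slope_mean_deg", "dist_road_km", "dist_settlement_km",
                "dist_water_km", "area_decid_km2", "area_conif_km2")
  Z <- standardize_covariates(covs[, env_cols])
  west <- landscape$geometry$sites$x <
    stats::median(landscape$geometry$sites$x)

  all_det <- list()
  realized <- list()
  for (sp in CAMPART_SPECIES) {
    par <- truth[[sp]]
    eta <- par$beta0 + drop(Z %*% par$beta[env_cols]) + log(deployments$trap_days)
    lambda <- exp(eta)
    if (any(lambda > 1e5)) stop("expected count exceeds the 1e5 safety cap")
    present <- stats::rbinom(n, 1, par$q)
    if (truth$scenario == "separated") {
      present <- present * as.integer(if (sp == "serow") west else !west)
    }
    counts <- ifelse(present == 1, stats::rpois(n, lambda), 0L)
    for (i in which(counts > 0)) {
      times <- .draw_event_times(counts[i], par$mixture,
                                 deployments$start[i], deployments$trap_days[i])
      for (t0 in times) {
        all_det[[length(all_det) + 1L]] <- data.frame(
          site_id = deployments$site_id[i],
          species = sp,
          timestamp = as.POSIXct(t0 + c(0, 60, 120), origin = "1970-01-01",
                                 tz = "UTC"),
          stringsAsFactors = FALSE)
      }
    }
    realized[[sp]] <- data.frame(site_id = deployments$site_id, species = sp,
                                 present = present, n_events = as.integer(counts),
                                 stringsAsFactors = FALSE)
  }
  detections <- if (length(all_det)) do.call(rbind, all_det) else
    data.frame(site_id = character(), species = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"))
  detections <- detections[order(detections$site_id, detections$timestamp), ]
  rownames(detections) <- NULL
  structure(list(detections = detections, deployments = deployments,
                 covariates = covs, truth = truth,
                 realized = do.call(rbind, realized)),
            class = "synthetic_study")
}

# min_gap is between event *start* times; bursts span 2 min, so 33 min
# between starts leaves > 31 min between the last photo of one event and
# the first of the next — strictly more than the 30-min independence window.
.draw_event_times <- function(k, mixture, start, trap_days, min_gap = 33 * 60) {
  n_days <- floor(trap_days - 0.5)
  start_num <- as.numeric(start)
  start_clock <- start_num %% 86400
  draw_one <- function(m) {
    day <- sample.int(n_days, m, replace = TRUE) - 1L
    clock <- generate_activity_times(m, mixture) / (2 * pi) * 86400
    start_num + day * 86400 + (clock - start_clock) %% 86400
  }
  times <- sort(draw_one(k))
  for (iter in seq_len(1000)) {
    gaps <- diff(times)
    bad <- which(gaps < min_gap) + 1L
    if (!length(bad)) return(times)
    times[bad] <- draw_one(length(bad))
    times <- sort(times)
  }
  stop("could not space ", k, " events at least 31 min apart within the deployment")
}

#' Simulate a complete synthetic camera-trap study
#'
#' Builds the landscape and covariates, draws detections under the chosen
#' scenario's ground truth, and optionally writes the three input tables
#' plus the serialized truth to a directory.
#'
#' @param scenario see [default_truth()].
#' @param seed integer master seed (landscape uses `seed`, detections
#'   `seed + 1000`).
#' @param out_dir optional output directory for detections.csv,
#'   deployments.csv, covariates.csv and truth.json.
#' @param truth optional `synthetic_truth` overriding the scenario default.
#' @return a `synthetic_study` (with the landscape attached).
#' @export
simulate_study <- function(scenario = "default", seed = 1, out_dir = NULL,
                           truth = NULL) {
  if (is.null(truth)) truth <- default_truth(scenario)
  landscape <- generate_landscape(truth$n_sites, truth$spacing_m, seed = seed)
  study <- generate_detections(truth, landscape, seed = seed + 1000L)
  study$landscape <- landscape
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_detections(study$detections, file.path(out_dir, "detections.csv"))
    write_deployments(study$deployments, file.path(out_dir, "deployments.csv"))
    write_covariates(study$covariates, file.path(out_dir, "covariates.csv"))
    jsonlite::write_json(unclass(truth), file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}
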