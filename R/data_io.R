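# Input tables, timestamp handling, day-period labelling.
#
# All date-times are local civil time at second resolution, carried as
# POSIXct in a fixed "UTC" representation (no daylight-saving shifts are
# applied; the clock reading is the datum). CSV is the only dialect:
# comma-separated, UTF-8, header row, ISO 8601 date-times.

.TS_FORMATS <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")

#' Parse ISO 8601 local timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` (or with a space separator). The result is
#' POSIXct in a fixed representation with no daylight-saving handling: the
#' civil clock reading is taken at face value.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector; unparseable entries are `NA`.
#' @export
parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in .TS_FORMATS) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = fmt, tz = "UTC")
  }
  out
}

#' Format timestamps back to ISO 8601
#' @param x POSIXct vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SS`.
#' @export
format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

.seconds_of_day <- function(x) {
  as.numeric(x) %% 86400
}

#' Convert clock time to radians
#'
#' Maps a timestamp to its position on the 24 h clock circle:
#' `2 * pi * (seconds since local midnight) / 86400`, in `[0, 2*pi)`.
#'
#' @param x POSIXct vector (or character parseable by [parse_timestamp()]).
#' @return numeric vector of radian clock times.
#' @export
to_radians <- function(x) {
  if (is.character(x)) x <- parse_timestamp(x)
  if (anyNA(x)) stop("to_radians: unparseable or missing timestamp")
  2 * pi * .seconds_of_day(x) / 86400
}

.parse_clock <- function(x) {
  # "HH:MM" or "HH:MM:SS" or numeric hours -> seconds of day
  if (is.numeric(x)) return(x * 3600)
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || length(p) < 2 || length(p) > 3) {
      stop("invalid clock time; expected HH:MM[:SS]")
    }
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

#' Classify a time of day into dawn, daytime, dusk, or nighttime
#'
#' Dawn is the hour before and after sunrise, dusk the hour before and after
#' sunset, daytime the interval strictly between the twilight windows, and
#' nighttime the rest of the 24 h cycle. Boundary instants belong to the
#' twilight classes.
#'
#' @param time POSIXct, or clock time as "HH:MM[:SS]" or numeric hours.
#' @param sunrise,sunset clock times ("HH:MM[:SS]" or numeric hours),
#'   sunrise before sunset and at least 2 h apart.
#' @return factor with levels dawn, daytime, dusk, nighttime.
#' @export
day_period <- function(time, sunrise, sunset) {
  sr <- .parse_clock(sunrise)
  ss <- .parse_clock(sunset)
  if (length(sr) != 1L || length(ss) != 1L) stop("sunrise/sunset must be scalar")
  if (ss <= sr + 2 * 3600) stop("degenerate day: sunset must exceed sunrise by more than 2 h")
  s <- if (inherits(time, "POSIXct")) .seconds_of_day(time) else .parse_clock(time)
  h <- 3600
  period <- ifelse(s >= sr - h & s <= sr + h, "dawn",
            ifelse(s >= ss - h & s <= ss + h, "dusk",
            ifelse(s > sr + h & s < ss - h, "daytime", "nighttime")))
  factor(period, levels = c("dawn", "daytime", "dusk", "nighttime"))
}

.read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a detections table
#'
#' Expects columns `site_id,species,timestamp` (ISO 8601 local time).
#' Records are returned sorted by site then timestamp. Unknown species and
#' malformed timestamps raise an error naming the offending line (header is
#' line 1).
#'
#' @param path path to a CSV file.
#' @return data.frame with columns site_id (character), species (character,
#'   one of [CAMPART_SPECIES]), timestamp (POSIXct).
#' @export
read_detections <- function(path) {
  df <- .read_table_checked(path, c("site_id", "species", "timestamp"))
  bad_sp <- which(!df$species %in% CAMPART_SPECIES)
  if (length(bad_sp)) {
    stop(sprintf("line %d: unknown species '%s' in field 'species' (expected %s)",
                 bad_sp[1] + 1L, df$species[bad_sp[1]],
                 paste(CAMPART_SPECIES, collapse = "|")))
  }
  ts <- parse_timestamp(df$timestamp)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop(sprintf("line %d: malformed timestamp '%s' in field 'timestamp'",
                 bad_ts[1] + 1L, df$timestamp[bad_ts[1]]))
  }
  out <- data.frame(site_id = as.character(df$site_id),
                    species = df$species,
                    timestamp = ts,
                    stringsAsFactors = FALSE)
  out[order(out$site_id, out$timestamp), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write a detections table
#' @param detections data.frame as produced by [read_detections()].
#' @param path output CSV path.
#' @export
write_detections <- function(detections, path) {
  df <- data.frame(site_id = detections$site_id,
                   species = detections$species,
                   timestamp = format_timestamp(detections$timestamp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deployments table
#'
#' Expects columns `site_id,start,end`. Each site has exactly one
#' deployment interval (cameras were moved, not revisited); duplicates are
#' rejected. Trap-days are the exact interval length in days and must be
#' positive.
#'
#' @param path path to a CSV file.
#' @return data.frame with site_id, start, end (POSIXct), trap_days.
#' @export
read_deployments <- function(path) {
  df <- .read_table_checked(path, c("site_id", "start", "end"))
  dup <- duplicated(df$site_id)
  if (any(dup)) {
    stop("multiple deployment intervals for site(s): ",
         paste(unique(df$site_id[dup]), collapse = ", "))
  }
  start <- parse_timestamp(df$start)
  end <- parse_timestamp(df$end)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("line %d: malformed deployment date-time", bad[1] + 1L))
  trap_days <- as.numeric(difftime(end, start, units = "days"))
  if (any(trap_days <= 0)) {
    stop("deployment end must be after start for site(s): ",
         paste(df$site_id[trap_days <= 0], collapse = ", "))
  }
  out <- data.frame(site_id = as.character(df$site_id), start = start,
                    end = end, trap_days = trap_days,
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a deployments table
#' @param deployments data.frame as from [read_deployments()].
#' @param path output CSV path.
#' @export
write_deployments <- function(deployments, path) {
  df <- data.frame(site_id = deployments$site_id,
                   start = format_timestamp(deployments$start),
                   end = format_timestamp(deployments$end))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Buffer area implied by the covariate schema, in km^2
#' @keywords internal
.BUFFER_KM2 <- 0.1257

.COVARIATE_COLS <- c("slope_mean_deg", "dist_road_km", "dist_settlement_km",
                     "dist_water_km", "area_decid_km2", "area_conif_km2",
                     "area_grass_km2", "area_farm_km2")

#' Read a site covariate table
#'
#' Expects `site_id` plus the eight numeric covariate columns: mean slope in
#' degrees, distances (km) to the nearest road, settlement and water, and
#' land-cover areas (km^2) of deciduous broadleaved forest, coniferous
#' forest, grassland and farmland within the 200 m buffer. Distances and
#' areas must be non-negative and land-cover areas cannot exceed the buffer
#' area (0.1257 km^2) in total.
#'
#' @param path path to a CSV file.
#' @return data.frame with site_id and the eight covariates.
#' @export
read_covariates <- function(path) {
  df <- .read_table_checked(path, c("site_id", .COVARIATE_COLS))
  for (col in .COVARIATE_COLS) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("covariate column '", col, "' must be numeric with no missing values")
    }
  }
  nonneg <- setdiff(.COVARIATE_COLS, "slope_mean_deg")
  for (col in nonneg) {
    if (any(df[[col]] < 0)) stop("covariate column '", col, "' has negative values")
  }
  areas <- rowSums(df[, c("area_decid_km2", "area_conif_km2",
                          "area_grass_km2", "area_farm_km2")])
  if (any(areas > .BUFFER_KM2 + 1e-9)) {
    stop("land-cover areas exceed the 200 m buffer area (0.1257 km^2) at site(s): ",
         paste(df$site_id[areas > .BUFFER_KM2 + 1e-9], collapse = ", "))
  }
  out <- df[, c("site_id", .COVARIATE_COLS)]
  out$site_id <- as.character(out$site_id)
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a site covariate table
#' @param covariates data.frame as from [read_covariates()].
#' @param path output CSV path.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates[, c("site_id", .COVARIATE_COLS)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate detections against deployments
#'
#' Checks that every detection's site has a deployment and that its
#' timestamp falls inside the deployment interval.
#'
#' @param detections detections data.frame.
#' @param deployments deployments data.frame.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_detections <- function(detections, deployments) {
  unknown <- setdiff(unique(detections$site_id), deployments$site_id)
  if (length(unknown)) {
    stop("detections at site(s) with no deployment: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(detections$site_id, deployments$site_id)
  outside <- detections$timestamp < deployments$start[idx] |
    detections$timestamp > deployments$end[idx]
  if (any(outside)) {
    stop("detection timestamp outside deployment interval at site(s): ",
         paste(unique(detections$site_id[outside]), collapse = ", "))
  }
  invisible(TRUE)
}
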