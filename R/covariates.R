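# Planar geometry helpers emulating the GIS covariate extraction, plus
# standardization and variance-inflation-factor screening.

#' Area of a circular buffer, in hectares
#'
#' @param radius_m buffer radius in metres (the study design uses 200 m).
#' @return pi * r^2 in hectares, full precision.
#' @export
buffer_area <- function(radius_m) {
  if (any(radius_m <= 0)) stop("buffer radius must be positive")
  pi * radius_m^2 / 1e4
}

#' Area of the circle implied by a camera spacing, in km^2
#'
#' The circle whose diameter is the distance between two adjacent cameras;
#' its area is compared against home-range sizes when judging whether one
#' camera per grid cell samples independent animals.
#'
#' @param distance_m spacing between adjacent cameras in metres.
#' @return area of the circle with radius `distance_m / 2`, in km^2.
#' @export
circle_area_from_spacing <- function(distance_m) {
  if (any(distance_m <= 0)) stop("camera spacing must be positive")
  pi * (distance_m / 2)^2 / 1e6
}

#' Mean slope within a circular buffer
#'
#' Arithmetic mean of the slope raster over the regular 20 m grid points
#' whose Euclidean distance from the site is at most `radius_m`.
#'
#' @param geometry landscape geometry list with `slope_raster`, a data.frame
#'   of x, y (metres) and slope_deg.
#' @param site numeric length-2 (x, y) in metres, or a site_id present in
#'   `geometry$sites`.
#' @param radius_m buffer radius in metres.
#' @return mean slope in degrees.
#' @export
mean_slope_in_buffer <- function(geometry, site, radius_m = 200) {
  if (is.character(site)) {
    i <- match(site, geometry$sites$site_id)
    if (is.na(i)) stop("unknown site_id: ", site)
    site <- c(geometry$sites$x[i], geometry$sites$y[i])
  }
  r <- geometry$slope_raster
  near <- abs(r$x - site[1]) <= radius_m & abs(r$y - site[2]) <= radius_m
  r <- r[near, , drop = FALSE]
  d2 <- (r$x - site[1])^2 + (r$y - site[2])^2
  inside <- d2 <= radius_m^2
  if (!any(inside)) stop("no slope grid points inside the buffer")
  mean(r$slope_deg[inside])
}

.dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

#' Distance from a site to the nearest feature, in km
#'
#' Features are points (a 2-column matrix) and/or polylines (a list of
#' 2-column matrices of vertices); distances are planar Euclidean,
#' point-to-segment for polylines.
#'
#' @param site numeric length-2 (x, y) in metres.
#' @param feature_set list with optional elements `points` (matrix) and
#'   `lines` (list of vertex matrices), coordinates in metres.
#' @return minimum distance in kilometres.
#' @export
nearest_distance <- function(site, feature_set) {
  d <- Inf
  pts <- feature_set$points
  if (!is.null(pts) && nrow(pts) > 0) {
    d <- min(d, sqrt(min((pts[, 1] - site[1])^2 + (pts[, 2] - site[2])^2)))
  }
  for (line in feature_set$lines) {
    if (nrow(line) == 1L) {
      d <- min(d, sqrt(sum((line[1, ] - site)^2)))
      next
    }
    for (k in seq_len(nrow(line) - 1L)) {
      d <- min(d, .dist_point_segment(site, line[k, ], line[k + 1L, ]))
    }
  }
  if (!is.finite(d)) stop("empty feature set")
  d / 1000
}

#' Standardize a covariate matrix to mean 0, SD 1
#'
#' Column-wise z-scores using the sample standard deviation (n - 1
#' denominator). The original means and SDs are stored as attributes
#' `center` and `scale` for back-transformation, and `standardized = TRUE`
#' marks the result. Idempotent.
#'
#' @param x numeric matrix or data.frame of covariates (no site_id column).
#' @return standardized numeric matrix with attributes.
#' @export
standardize_covariates <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("covariate matrix has missing values")
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  zero <- sdev < .Machine$double.eps * 1e3
  if (any(zero)) {
    stop("zero-variance covariate column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdev
  attr(z, "standardized") <- TRUE
  z
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary least-squares
#' regression of column j on all other columns plus an intercept. Perfectly
#' collinear columns get `Inf` rather than an error.
#'
#' @param x numeric matrix with at least two columns and more rows than
#'   columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("VIF needs at least two columns")
  if (nrow(x) <= ncol(x)) stop("VIF needs more rows than columns")
  out <- vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Iterative VIF screening
#'
#' Repeatedly removes the column with the largest VIF until all remaining
#' VIFs are below the threshold. Ties are broken by column order (the
#' earlier column is removed). The exclusion log records each removal with
#' the VIF at removal time.
#'
#' @param x numeric covariate matrix with named columns.
#' @param threshold VIF threshold (default 5, the usual instability cutoff).
#' @return list with `retained` (matrix), `vif` (final VIFs) and
#'   `removed` (data.frame column, vif_at_removal).
#' @export
vif_screen <- function(x, threshold = 5) {
  x <- as.matrix(x)
  removed <- data.frame(column = character(), vif_at_removal = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    v <- vif(x)
    if (all(v < threshold)) break
    j <- which.max(v)
    removed <- rbind(removed,
                     data.frame(column = colnames(x)[j], vif_at_removal = v[j],
                                stringsAsFactors = FALSE))
    x <- x[, -j, drop = FALSE]
    if (ncol(x) < 2L) {
      stop("VIF screening removed all but one column; covariates are too collinear")
    }
  }
  rownames(removed) <- NULL
  list(retained = x, vif = vif(x), removed = removed)
}

#' Standardize and VIF-screen a site covariate table
#'
#' Convenience wrapper around [standardize_covariates()] and [vif_screen()]
#' for a covariates data.frame (site_id plus numeric columns): returns the
#' retained standardized matrix together with the standardization constants
#' and the screening log, ready for [write_screened_covariates()].
#'
#' @param covariates data.frame with a site_id column and numeric covariates.
#' @param threshold VIF threshold (default 5).
#' @return list: site_id, z (retained standardized matrix), center, scale,
#'   vif (final VIFs), removed (screening log).
#' @export
screen_covariates <- function(covariates, threshold = 5) {
  num <- covariates[, setdiff(names(covariates), "site_id"), drop = FALSE]
  z_full <- standardize_covariates(num)
  screen <- vif_screen(z_full, threshold)
  list(site_id = covariates$site_id,
       z = screen$retained,
       center = attr(z_full, "center"),
       scale = attr(z_full, "scale"),
       vif = screen$vif,
       removed = screen$removed)
}

#' Write screened covariates with a JSON audit sidecar
#'
#' Writes the retained standardized covariates as CSV and, next to it, a
#' `<path>.json` sidecar logging the standardization means and SDs, the
#' final VIFs, and each removal with its VIF at removal time — enough to
#' audit or invert the preprocessing.
#'
#' @param screened result of [screen_covariates()].
#' @param path output CSV path (sidecar gets `.json` appended).
#' @return invisibly the two paths written.
#' @export
write_screened_covariates <- function(screened, path) {
  df <- data.frame(site_id = screened$site_id, screened$z,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(center = as.list(screened$center),
                            scale = as.list(screened$scale),
                            vif = as.list(screened$vif),
                            removed = screened$removed,
                            sd_convention = "sample (n-1)"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' Extract covariates for a landscape's sites via the geometry helpers
#'
#' Computes the full eight-column site covariate table (mean slope in the
#' 200 m buffer, nearest-feature distances, land-cover areas) from a
#' landscape geometry as built by [generate_landscape()].
#'
#' @param geometry landscape geometry list.
#' @param radius_m buffer radius in metres.
#' @return covariates data.frame matching the covariates.csv schema.
#' @export
extract_site_covariates <- function(geometry, radius_m = 200) {
  sites <- geometry$sites
  n <- nrow(sites)
  slope <- numeric(n); droad <- numeric(n); dsettle <- numeric(n); dwater <- numeric(n)
  for (i in seq_len(n)) {
    p <- c(sites$x[i], sites$y[i])
    slope[i] <- mean_slope_in_buffer(geometry, p, radius_m)
    droad[i] <- nearest_distance(p, geometry$roads)
    dsettle[i] <- nearest_distance(p, geometry$settlements)
    dwater[i] <- nearest_distance(p, geometry$water)
  }
  data.frame(site_id = sites$site_id,
             slope_mean_deg = slope,
             dist_road_km = droad,
             dist_settlement_km = dsettle,
             dist_water_km = dwater,
             area_decid_km2 = geometry$landcover$area_decid_km2,
             area_conif_km2 = geometry$landcover$area_conif_km2,
             area_grass_km2 = geometry$landcover$area_grass_km2,
             area_farm_km2 = geometry$landcover$area_farm_km2,
             stringsAsFactors = FALSE)
}
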