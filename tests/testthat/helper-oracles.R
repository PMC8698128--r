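# Shared fixtures and independent oracles used across the test files.

ts <- function(x) parse_timestamp(x)

# small detections table from (site, species, clock-time) triples on one day
make_detections <- function(site, species, times, day = "2012-08-01") {
  data.frame(site_id = site, species = species,
             timestamp = parse_timestamp(paste0(day, "T", times)),
             stringsAsFactors = FALSE)
}

circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)

# trapezoidal integral of f over [0, 2*pi) from values on an equally
# spaced grid (periodic closure)
circ_trapz <- function(f) {
  n <- length(f)
  sum((f + f[c(2:n, 1)]) / 2) * (2 * pi / n)
}

# L1 distance between a fitted activity density and an analytic density
kde_l1_error <- function(dens, true_f) {
  mean(abs(dens$f - true_f(dens$grid))) * 2 * pi
}

# Brute-force Watson U2 from the textbook rank formula (no ties assumed):
# evaluate the cumulative-fraction difference at every pooled observation.
watson_u2_bruteforce <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- sort(c(x, y))
  d <- sapply(pooled, function(v) sum(x <= v) / n1 - sum(y <= v) / n2)
  (n1 * n2 / N^2) * (sum(d^2) - sum(d)^2 / N)
}

# exact von Mises density without the package's machinery
vm_pdf <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# minimal landscape geometry for the geometry-helper oracles
toy_geometry <- function(slope_df) {
  list(sites = data.frame(site_id = "S01", x = 0, y = 0),
       slope_raster = slope_df)
}
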