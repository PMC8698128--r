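# Geometry helpers, standardization and VIF screening.

test_that("buffer and spacing-circle areas match the survey geometry", {
  expect_equal(round(buffer_area(200), 1), 12.6)
  expect_equal(buffer_area(200), pi * 200^2 / 1e4)
  expect_equal(buffer_area(100), pi, tolerance = 1e-12)
  expect_error(buffer_area(0), "positive")

  expect_equal(round(circle_area_from_spacing(1241), 2), 1.21)
  expect_equal(circle_area_from_spacing(2000), pi, tolerance = 1e-12)
  expect_equal(circle_area_from_spacing(856), pi * 0.428^2, tolerance = 1e-12)
  expect_error(circle_area_from_spacing(-1), "positive")

  # unit consistency between the two helpers
  for (r in c(50, 200, 1000)) {
    expect_equal(buffer_area(r) / 100, circle_area_from_spacing(2 * r),
                 tolerance = 1e-12)
  }
})

test_that("mean slope in buffer averages the 20 m grid points inside", {
  grid <- expand.grid(x = seq(-300, 300, 20), y = seq(-300, 300, 20))
  grid$slope_deg <- 10
  geom <- toy_geometry(grid)
  expect_equal(mean_slope_in_buffer(geom, c(0, 0), 200), 10)

  two <- data.frame(x = c(10, -10), y = c(0, 0), slope_deg = c(0, 20))
  expect_equal(mean_slope_in_buffer(toy_geometry(two), c(0, 0), 200), 10)

  set.seed(31)
  grid$slope_deg <- runif(nrow(grid), 0, 45)
  inside <- grid$x^2 + grid$y^2 <= 200^2
  expect_equal(mean_slope_in_buffer(toy_geometry(grid), c(0, 0), 200),
               mean(grid$slope_deg[inside]))     # brute-force oracle

  far <- data.frame(x = 1e5, y = 1e5, slope_deg = 5)
  expect_error(mean_slope_in_buffer(toy_geometry(far), c(0, 0), 200),
               "no slope grid points")
})

test_that("nearest feature distance handles points and segments", {
  expect_equal(nearest_distance(c(0, 0),
                                list(points = cbind(0, 0), lines = list())), 0)
  # perpendicular foot onto a vertical segment 3 m away
  seg <- list(points = NULL, lines = list(cbind(c(3, 3), c(4, -4))))
  expect_equal(nearest_distance(c(0, 0), seg), 3 / 1000)
  expect_error(nearest_distance(c(0, 0), list(points = NULL, lines = list())),
               "empty feature set")

  # discretization oracle: min distance over densely sampled feature points
  set.seed(32)
  for (rep in 1:3) {
    verts <- matrix(runif(8, -500, 500), ncol = 2)
    fs <- list(points = matrix(runif(4, -500, 500), ncol = 2),
               lines = list(verts))
    site <- runif(2, -500, 500)
    dense <- do.call(rbind, lapply(seq_len(nrow(verts) - 1), function(k) {
      t <- seq(0, 1, by = 1e-4)
      cbind(verts[k, 1] + t * (verts[k + 1, 1] - verts[k, 1]),
            verts[k, 2] + t * (verts[k + 1, 2] - verts[k, 2]))
    }))
    dense <- rbind(dense, fs$points)
    oracle <- sqrt(min((dense[, 1] - site[1])^2 + (dense[, 2] - site[2])^2)) / 1000
    expect_equal(nearest_distance(site, fs), oracle, tolerance = 1e-4)
  }
})

test_that("standardization gives sample-SD z-scores and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_covariates(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(attr(z, "center")), c(2, 20))
  z2 <- standardize_covariates(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  m_bad <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(standardize_covariates(m_bad), "zero-variance.*b")
})

test_that("VIF matches the closed form and flags perfect collinearity", {
  set.seed(33)
  # orthonormal centred columns -> VIF exactly 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(30), 10, 3))))[, 2:4]
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-9)

  # correlation exactly 0.9 -> VIF = 1/(1 - 0.81) for both columns
  x1 <- q[, 1]; x2 <- 0.9 * q[, 1] + sqrt(1 - 0.81) * q[, 2]
  expect_equal(unname(vif(cbind(x1, x2))), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-9)

  x3 <- x1 + x2
  v <- vif(cbind(x1, x2, x3))
  expect_true(all(is.infinite(v)))

  # VIF is invariant under standardization of the input
  m <- matrix(rnorm(200), 50, 4) %*% diag(c(1, 10, 100, 0.1))
  m[, 2] <- m[, 2] + 0.7 * m[, 1]
  expect_equal(unname(vif(m)), unname(vif(standardize_covariates(m))),
               tolerance = 1e-9)
})

test_that("iterative VIF screening removes the worst column until clean", {
  set.seed(34)
  ok <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("c", 1:4)))
  sc <- vif_screen(ok)
  expect_equal(ncol(sc$retained), 4L)
  expect_equal(nrow(sc$removed), 0L)

  bad <- cbind(ok, c5 = ok[, 1] + ok[, 2] + rnorm(50, 0, 1e-4))
  sc2 <- vif_screen(bad)
  expect_true(all(sc2$vif < 5))           # postcondition replay
  expect_true(nrow(sc2$removed) >= 1L)
  expect_true(all(sc2$removed$vif_at_removal >= 5))
})

test_that("screened covariates round-trip with a complete audit sidecar", {
  lsc <- generate_landscape(n_sites = 30, seed = 3)
  sc <- screen_covariates(lsc$covariates)
  path <- withr::local_tempfile(fileext = ".csv")
  write_screened_covariates(sc, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$site_id, sc$site_id)
  expect_equal(as.matrix(back[, -1]), unclass(sc$z)[, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_setequal(names(meta$center), colnames(lsc$covariates)[-1])
  expect_setequal(meta$removed$column, c("area_grass_km2", "area_farm_km2"))
  expect_true(all(unlist(meta$vif) < 5))
  # the sidecar's constants invert the standardization of a retained column
  col <- colnames(sc$z)[1]
  expect_equal(back[[col]] * meta$scale[[col]] + meta$center[[col]],
               lsc$covariates[[col]], tolerance = 1e-9)
})

test_that("the default synthetic landscape loses exactly the grass and farm columns", {
  for (s in c(1, 7)) {
    lsc <- generate_landscape(seed = s)
    Z <- standardize_covariates(lsc$covariates[, -1])
    v <- vif(Z)
    expect_true(v[["area_grass_km2"]] > 5 || v[["area_farm_km2"]] > 5)
    sc <- vif_screen(Z)
    expect_setequal(sc$removed$column, c("area_grass_km2", "area_farm_km2"))
    expect_true(max(sc$vif) < 5)
  }
})
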