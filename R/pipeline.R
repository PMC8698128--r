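# End-to-end orchestration: three input tables -> machine-readable report.

#' Analysis configuration
#'
#' Defaults follow the study protocol: 30-min independence window, 4 MCMC
#' chains of 2000 iterations with 1000 burn-in (unthinned), 10,000
#' bootstrap replicates, VIF threshold 5, overlap classification bounds
#' (0.50, 0.75), 512-point density grid. The `fast` profile (2 chains x
#' 500 iterations, 500 bootstrap replicates, 199 permutations) is for quick
#' exploratory runs and is not the study protocol.
#'
#' @param independence_window_minutes event-independence window.
#' @param chains,iterations,warmup,thin MCMC settings.
#' @param bootstrap_reps smoothed-bootstrap replicates.
#' @param randomization_reps permutations for the randomization test.
#' @param vif_threshold collinearity exclusion threshold.
#' @param overlap_class_bounds strictly increasing bounds in (0, 1).
#' @param seed master seed; per-stage seeds are derived as documented in
#'   [run_full_analysis()].
#' @param grid_n circular density grid size.
#' @param kappa_policy bootstrap refit policy, "reselect" or "fixed".
#' @param fast use the fast (non-protocol) profile?
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(independence_window_minutes = 30,
                            chains = 4, iterations = 2000, warmup = 1000,
                            thin = 1, bootstrap_reps = 10000,
                            randomization_reps = 999, vif_threshold = 5,
                            overlap_class_bounds = c(0.50, 0.75),
                            seed = 1, grid_n = 512,
                            kappa_policy = c("reselect", "fixed"),
                            fast = FALSE) {
  kappa_policy <- match.arg(kappa_policy)
  if (fast) {
    chains <- 2; iterations <- 500; warmup <- 250
    bootstrap_reps <- 500; randomization_reps <- 199
  }
  cfg <- list(independence_window_minutes = independence_window_minutes,
              chains = chains, iterations = iterations, warmup = warmup,
              thin = thin, bootstrap_reps = bootstrap_reps,
              randomization_reps = randomization_reps,
              vif_threshold = vif_threshold,
              overlap_class_bounds = overlap_class_bounds,
              seed = seed, grid_n = grid_n, kappa_policy = kappa_policy,
              fast = fast)
  stopifnot(cfg$independence_window_minutes > 0, cfg$chains >= 1,
            cfg$iterations > 0, cfg$warmup < cfg$iterations, cfg$thin >= 1,
            cfg$bootstrap_reps >= 100, cfg$randomization_reps >= 99,
            cfg$vif_threshold > 0, length(cfg$overlap_class_bounds) == 2,
            cfg$overlap_class_bounds[1] > 0, cfg$overlap_class_bounds[2] < 1,
            cfg$overlap_class_bounds[1] < cfg$overlap_class_bounds[2],
            cfg$grid_n >= 32)
  structure(cfg, class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# Per-stage seeds derived from the master seed by fixed small offsets so
# any stage can be re-run in isolation. The two species' occurrence models
# and activity bootstraps share one seed each, which makes a species-label
# swap in the inputs mirror the fitted models exactly.
.stage_seeds <- function(seed) {
  list(mcmc = seed + 11L, boot_activity = seed + 21L,
       boot_delta4 = seed + 31L, randomization = seed + 41L)
}

#' Run the complete two-species partitioning analysis
#'
#' Stages, in order: validation; 30-min independent-event filtering;
#' capture rates and the site-occurrence summary; Pianka's spatial overlap
#' with classification; covariate assembly (the other species' capture rate
#' appended to the six environmental covariates), standardization and VIF
#' screening; one ZIP occurrence model per species by MCMC with effect
#' summaries; circular kernel activity densities; activity levels with
#' smoothed bootstrap and the Wald comparison; temporal overlap (Delta-4
#' point estimate, smoothed-bootstrap mean and 95% CI, randomization and
#' Watson tests) with classification. Fully deterministic given the inputs,
#' configuration and master seed.
#'
#' @param detections detections table (data.frame) or path to a CSV.
#' @param deployments deployments table or path.
#' @param covariates site covariate table or path.
#' @param config an [analysis_config()].
#' @return list of class `campart_result`.
#' @export
run_full_analysis <- function(detections, deployments, covariates,
                              config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(detections)) detections <- .stage("read", read_detections(detections))
  if (is.character(deployments)) deployments <- .stage("read", read_deployments(deployments))
  if (is.character(covariates)) covariates <- .stage("read", read_covariates(covariates))
  seeds <- .stage_seeds(config$seed)

  .stage("validate", validate_detections(detections, deployments))
  events <- .stage("filter_events",
                   filter_independent_events(detections,
                                             config$independence_window_minutes))
  rates <- .stage("capture_rates", capture_rates(events, deployments))
  occurrence <- .stage("occurrence_summary", site_occurrence_summary(rates))

  rate_wide <- .stage("rates_align", {
    lapply(stats::setNames(CAMPART_SPECIES, CAMPART_SPECIES), function(sp) {
      sub <- rates[rates$species == sp, ]
      sub[match(deployments$site_id, sub$site_id), ]
    })
  })
  pianka <- .stage("pianka",
                   pianka_alpha(rate_wide$serow$rate, rate_wide$deer$rate,
                                bounds = config$overlap_class_bounds))

  env_cols <- c("slope_mean_deg", "dist_road_km", "dist_settlement_km",
                "dist_water_km", "area_decid_km2", "area_conif_km2",
                "area_grass_km2", "area_farm_km2")
  covs <- covariates[match(deployments$site_id, covariates$site_id), ]
  if (anyNA(covs$site_id)) {
    stop("pipeline stage 'covariates' failed: covariate table is missing deployed sites")
  }

  models <- list()
  for (sp in CAMPART_SPECIES) {
    other <- setdiff(CAMPART_SPECIES, sp)
    X <- as.matrix(covs[, env_cols])
    X <- cbind(X, rate_other_species = rate_wide[[other]]$rate)
    Zfull <- .stage("standardize", standardize_covariates(X))
    screen <- .stage("vif_screen", vif_screen(Zfull, config$vif_threshold))
    y <- rate_wide[[sp]]$n_events
    post <- .stage("fit_zip_mcmc",
                   fit_zip_mcmc(y, deployments$trap_days, screen$retained,
                                chains = config$chains,
                                iterations = config$iterations,
                                warmup = config$warmup, thin = config$thin,
                                seed = seeds$mcmc))
    models[[sp]] <- list(effects = summarize_effects(post),
                         rhat = post$rhat, converged = post$converged,
                         vif = screen$vif, vif_removed = screen$removed,
                         posterior = post)
  }

  times <- lapply(stats::setNames(CAMPART_SPECIES, CAMPART_SPECIES), function(sp) {
    events$event_radians[events$species == sp]
  })
  densities <- .stage("circular_kde", lapply(times, function(tt) {
    if (length(tt) < 2) stop("need at least 2 events per species for the KDE")
    fit_circular_kde(tt, grid_n = config$grid_n)
  }))
  activity <- .stage("activity_levels", {
    out <- list()
    for (sp in CAMPART_SPECIES) {
      out[[sp]] <- smoothed_bootstrap_level(densities[[sp]],
                                            B = config$bootstrap_reps,
                                            seed = seeds$boot_activity,
                                            kappa_policy = config$kappa_policy)
    }
    out
  })
  wald <- .stage("wald", wald_compare(activity$serow, activity$deer))

  d4boot <- .stage("delta4",
                   delta4_bootstrap(times$serow, times$deer,
                                    densities$serow, densities$deer,
                                    B = config$bootstrap_reps,
                                    seed = seeds$boot_delta4,
                                    kappa_policy = config$kappa_policy,
                                    grid_n = config$grid_n))
  rand <- .stage("randomization",
                 randomization_compare(times$serow, times$deer,
                                       R = config$randomization_reps,
                                       seed = seeds$randomization,
                                       grid_n = config$grid_n))
  watson <- .stage("watson", watson_two_sample(times$serow, times$deer))

  temporal <- list(delta4 = d4boot$delta4, boot_mean = d4boot$boot_mean,
                   ci95 = d4boot$ci95, B = d4boot$B,
                   classification = classify_overlap(d4boot$delta4,
                                                     config$overlap_class_bounds),
                   watson_u2 = watson$u2, watson_p = watson$p,
                   randomization_p = rand$p)

  structure(list(events = events, rates = rates, occurrence = occurrence,
                 pianka = pianka, models = models,
                 densities = densities, activity = activity, wald = wald,
                 temporal = temporal,
                 config = unclass(config), seeds = seeds,
                 version = as.character(utils::packageVersion("campart"))),
            class = "campart_result")
}

#' @export
print.campart_result <- function(x, ...) {
  occ <- x$occurrence
  cat("Two-species camera-trap partitioning analysis\n")
  cat(sprintf("  events: %d serow, %d deer at %d sites\n",
              sum(x$rates$n_events[x$rates$species == "serow"]),
              sum(x$rates$n_events[x$rates$species == "deer"]), occ$n_sites))
  cat(sprintf("  sites: both %d | serow only %d | deer only %d | neither %d\n",
              occ$both, occ$only_serow, occ$only_deer, occ$neither))
  cat(sprintf("  spatial overlap: alpha = %.3f (%s)\n",
              x$pianka$alpha, x$pianka$classification))
  cat(sprintf("  activity levels: serow %.3f, deer %.3f (Wald W = %.3f, p = %.3f)\n",
              x$activity$serow$a, x$activity$deer$a, x$wald$W, x$wald$p))
  cat(sprintf("  temporal overlap: Delta4 = %.3f (%s), boot mean %.3f, 95%% CI %.3f-%.3f\n",
              x$temporal$delta4, x$temporal$classification,
              x$temporal$boot_mean, x$temporal$ci95[1], x$temporal$ci95[2]))
  cat(sprintf("  Watson U2 = %.3f (p = %.3g); randomization p = %.3g\n",
              x$temporal$watson_u2, x$temporal$watson_p,
              x$temporal$randomization_p))
  invisible(x)
}

.bundle_json <- function(bundle) {
  eff <- .effects_table(bundle)
  list(
    occurrence = bundle$occurrence,
    pianka = list(alpha = bundle$pianka$alpha,
                  classification = bundle$pianka$classification),
    models = lapply(bundle$models, function(m) {
      list(effects = m$effects, converged = m$converged,
           max_rhat = max(m$rhat), vif = as.list(m$vif),
           vif_removed = m$vif_removed)
    }),
    activity = lapply(bundle$activity, function(a) {
      list(a = a$a, se = a$se, lo95 = a$ci95[1], hi95 = a$ci95[2], B = a$B)
    }),
    wald = bundle$wald,
    temporal = bundle$temporal,
    kappa = lapply(bundle$densities, function(d) d$kappa),
    effects = eff,
    config = bundle$config,
    seeds = bundle$seeds,
    version = bundle$version
  )
}

.effects_table <- function(bundle) {
  do.call(rbind, lapply(names(bundle$models), function(sp) {
    cbind(model = sp, bundle$models[[sp]]$effects)
  }))
}

#' Write the analysis report to a directory
#'
#' Writes results.json (the full bundle, numerics at 6 significant digits),
#' events.csv, rates.csv, effects.csv, activity.csv and overlap.json.
#'
#' @param bundle a `campart_result`.
#' @param outdir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "campart_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  p <- file.path(outdir, "results.json")
  jsonlite::write_json(.bundle_json(bundle), p, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  add(p)

  p <- file.path(outdir, "events.csv"); write_events(bundle$events, p); add(p)
  p <- file.path(outdir, "rates.csv")
  utils::write.csv(bundle$rates, p, row.names = FALSE, quote = FALSE); add(p)
  p <- file.path(outdir, "effects.csv")
  utils::write.csv(.effects_table(bundle), p, row.names = FALSE, quote = FALSE)
  add(p)

  act <- do.call(rbind, lapply(names(bundle$activity), function(sp) {
    a <- bundle$activity[[sp]]
    data.frame(species = sp, n_events = bundle$densities[[sp]]$n,
               kappa = bundle$densities[[sp]]$kappa, activity_level = a$a,
               se = a$se, lo95 = a$ci95[1], hi95 = a$ci95[2],
               stringsAsFactors = FALSE)
  }))
  p <- file.path(outdir, "activity.csv")
  utils::write.csv(act, p, row.names = FALSE, quote = FALSE); add(p)

  p <- file.path(outdir, "overlap.json")
  jsonlite::write_json(list(pianka = list(alpha = bundle$pianka$alpha,
                                          class = bundle$pianka$classification),
                            temporal = bundle$temporal,
                            settings = bundle$config, seeds = bundle$seeds),
                       p, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  add(p)
  invisible(files)
}
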