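#' Default pipeline configuration
#'
#' One list drives the whole synthetic study: the landscape, the generating
#' truth per season, study sizes, candidate radii (the fixed study radii by
#' default, or `"computed"` to derive them from simulated daily movements),
#' the MCMC profile, validation thresholds and the availability ratio. The
#' global `seed` fans out to deterministic per-stage seeds, so a rerun with
#' the same config reproduces every output.
#'
#' Seasonal generating truths differ the way the seasonal models do: nesting
#' and brood rearing select shrub and (log) ruggedness at an 887 m radius
#' with strong release-site attraction; summer selects shrub at 1,503 m and
#' ruggedness at 767 m with the release effect nearly gone.
#'
#' @param seed global integer seed.
#' @param seasons subset of `c("nest", "brood", "summer")`.
#' @param model a [rsf_model_config()]; its seed is overridden per season.
#' @param landscape a [landscape_config()].
#' @param n_individuals tracked females for brood/summer simulation.
#' @param days_brood,days_summer daily locations per individual.
#' @param ratio availability points per used point.
#' @param radii_source `"fixed"` (study radii) or `"computed"` (from steps).
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1,
                                    seasons = c("nest", "brood", "summer"),
                                    model = rsf_model_config(),
                                    landscape = landscape_config(),
                                    n_individuals = 30,
                                    days_brood = 5, days_summer = 12,
                                    ratio = 5,
                                    radii_source = c("fixed", "computed")) {
  radii_source <- match.arg(radii_source)
  truth_breeding <- simulation_truth()
  truth_summer <- simulation_truth(
    beta = c(shrub = 0.8, ruggedness = -0.6, elevation = -0.4,
             northness = 0.2, road = -0.4, water = -0.3, mesic = 0.5,
             release = 0.1),
    true_scale = c(shrub = 1503, ruggedness = 767))
  structure(list(
    seed = as.integer(seed), seasons = seasons, model = model,
    landscape = landscape, n_individuals = n_individuals,
    days = list(brood = days_brood, summer = days_summer),
    ratio = ratio, radii_source = radii_source,
    radii_fixed = list(nest = c(60, 331, 887), brood = c(60, 331, 887),
                       summer = c(111, 767, 1503, 3005)),
    truth = list(nest = truth_breeding, brood = truth_breeding,
                 summer = truth_summer),
    thresholds = list(spearman = 0.75, r_squared = 0.75,
                      slope_range = c(0.8, 1.2)),
    shrub_loss = list(magnitude = 6, radius = 1000)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar entries under the `synthetic:`, `model:` and `validation:` blocks
#' override the defaults of [default_pipeline_config()]. A top-level `seed`
#' is required.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must provide a seed")
  cfg <- default_pipeline_config(seed = y$seed)
  syn <- y$synthetic
  if (!is.null(syn)) {
    for (nm in intersect(names(syn), c("n_individuals", "ratio", "radii_source")))
      cfg[[nm]] <- syn[[nm]]
    if (!is.null(syn$seasons)) cfg$seasons <- syn$seasons
    for (nm in intersect(names(syn), names(cfg$landscape)))
      cfg$landscape[[nm]] <- syn[[nm]]
    if (!is.null(syn$days_brood)) cfg$days$brood <- syn$days_brood
    if (!is.null(syn$days_summer)) cfg$days$summer <- syn$days_summer
  }
  if (!is.null(y$model)) {
    m <- y$model
    args <- m[intersect(names(m), names(formals(rsf_model_config)))]
    cfg$model <- do.call(rsf_model_config, args)
  }
  if (!is.null(y$validation)) {
    for (nm in intersect(names(y$validation), names(cfg$thresholds)))
      cfg$thresholds[[nm]] <- y$validation[[nm]]
  }
  cfg
}

season_seed <- function(cfg, season, stage) {
  offs <- c(nest = 100L, brood = 200L, summer = 300L)
  cfg$seed + offs[[season]] + stage
}

#' Run the full synthetic RSF study
#'
#' Executes the pipeline end to end on a simulated landscape: data
#' generation, thinning and minimum-location filters, MCP availability
#' sampling at the configured ratio, covariate assembly at all candidate
#' radii, unit-level train/test split, two-stage Bayesian fit with scale
#' selection, held-out calibration with quadratic escalation when it fails,
#' seasonal and composite habitat surfaces, epoch-difference change maps,
#' the nest resident/translocated contrast, and a study ledger. Reruns with
#' the same config are identical.
#'
#' @param config a `pipeline_config`.
#' @param outdir optional directory; when given, locations, designs,
#'   posterior and scale summaries, calibration tables, surfaces (`.asc`)
#'   and a run log are written there.
#' @param quiet suppress progress messages.
#' @return A `pipeline_result` list with per-season results, the composite
#'   surface, change summaries and the ledger.
#' @export
run_rsf_pipeline <- function(config = default_pipeline_config(),
                             outdir = NULL, quiet = FALSE) {
  cfg <- config
  say <- function(...) if (!quiet) message(...)
  say("generating landscape")
  land <- generate_landscape(cfg$landscape, seed = cfg$seed)
  epochs <- generate_shrub_epochs(land, loss_magnitude = cfg$shrub_loss$magnitude,
                                  loss_radius = cfg$shrub_loss$radius)
  land$shrub <- epochs$late  # "current" epoch drives the analysis

  # simulate every season first: movement-derived radii for nesting come
  # from the brood tracks
  all_locations <- list()
  for (season in cfg$seasons) {
    truth <- cfg$truth[[season]]
    if (season == "nest") {
      locs <- simulate_nests(land, truth, seed = season_seed(cfg, season, 1))
    } else {
      locs <- simulate_individuals(
        land, truth, n_individuals = cfg$n_individuals,
        days_per_individual = cfg$days[[season]],
        seed = season_seed(cfg, season, 1), life_stage = season)
      locs <- thin_one_per_day(locs, seed = season_seed(cfg, season, 2))
      locs <- filter_min_locations(locs, season)
    }
    all_locations[[season]] <- locs
  }

  results <- list()
  for (season in cfg$seasons) {
    say("season: ", season)
    locs <- all_locations[[season]]

    radii <- if (cfg$radii_source == "fixed") cfg$radii_fixed[[season]]
    else {
      src <- if (season == "nest") all_locations$brood %||%
        stop("computed radii for nesting need brood locations in the run")
      else locs
      compute_candidate_radii(step_distances(src), season)$radii
    }

    boundary <- mcp_boundary(locs)
    avail <- sample_available(boundary, nrow(locs), ratio = cfg$ratio,
                              seed = season_seed(cfg, season, 3))
    stack <- build_covariate_stack(land, radii = radii)
    design <- assemble_design(locs, avail, stack)
    design <- split_train_test(design, seed = season_seed(cfg, season, 4))
    design <- standardize_design(design)

    mcfg <- cfg$model
    mcfg$random_intercept <- season != "nest"
    mcfg$seed <- as.integer(season_seed(cfg, season, 5))
    ts <- two_stage_fit(design, mcfg)
    esc <- escalate_quadratic(ts$design, mcfg, fit = ts$fit,
                              thresholds = cfg$thresholds)

    stack_sel <- stack
    surf_w <- rsf_surface(esc$fit, stack_sel, selected_scales = ts$modal_scales)
    surf_p <- logistic_surface(surf_w)
    stack_early <- build_covariate_stack(land, radii = radii,
                                         shrub = epochs$early)
    delta <- change_surface(esc$fit, stack_sel, stack_early,
                            selected_scales = ts$modal_scales)
    results[[season]] <- list(
      locations = locs, boundary = boundary, radii = radii,
      design = esc$design, two_stage = ts, fit = esc$fit,
      calibration = esc$calibration, quadratic_terms = esc$quadratic_terms,
      surface_w = surf_w, surface_p = surf_p, change = delta,
      change_by_class = change_by_selection_class(delta, surf_p))
  }

  composite <- if (all(c("nest", "brood", "summer") %in% names(results)))
    annual_composite(results$nest$surface_p, results$brood$surface_p,
                     results$summer$surface_p) else NULL

  contrast <- NULL
  if ("nest" %in% names(results)) {
    say("resident/translocated contrast")
    contrast <- nest_group_contrast(results$nest, cfg)
  }

  ledger <- ledger_counts(do.call(rbind, lapply(all_locations, function(l)
    l[c("individual_id", "date", "life_stage", "year", "used")])),
    ratio = cfg$ratio)

  out <- structure(list(config = cfg, landscape = land, epochs = epochs,
                        seasons = results, composite = composite,
                        contrast = contrast, ledger = ledger),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# refit the nest model with the most influential coefficients varying by
# group and record P(beta_resident > beta_translocated)
nest_group_contrast <- function(nest_result, cfg) {
  fit <- nest_result$fit
  infl <- influence_flags(fit)
  vary <- setdiff(infl$parameter[infl$influential], "(Intercept)")
  vary <- grep("\\^2$", vary, invert = TRUE, value = TRUE)
  if (!length(vary)) return(NULL)
  d <- expand_group_columns(nest_result$design, vary)
  mcfg <- cfg$model
  mcfg$random_intercept <- FALSE
  mcfg$seed <- as.integer(season_seed(cfg, "nest", 6))
  refit <- fit_rsf(d, mcfg, sample_scales = FALSE)
  probs <- vapply(vary, function(cv)
    group_contrast(refit, paste0(cv, ":resident"), paste0(cv, ":translocated")),
    numeric(1))
  data.frame(covariate = vary, prob_resident_gt_translocated = unname(probs),
             strong_evidence = unname(probs > 0.95 | probs < 0.05))
}

write_pipeline_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_landscape(res$landscape, file.path(outdir, "landscape"))
  for (season in names(res$seasons)) {
    r <- res$seasons[[season]]
    sd <- file.path(outdir, season)
    if (!dir.exists(sd)) dir.create(sd)
    utils::write.csv(r$locations, file.path(sd, "locations.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(r$design), file.path(sd, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(parameter = rownames(posterior_summary(r$fit)),
                           posterior_summary(r$fit)),
                     file.path(sd, "posterior_summary.csv"), row.names = FALSE)
    utils::write.csv(r$two_stage$scale_posterior,
                     file.path(sd, "scale_probabilities.csv"), row.names = FALSE)
    utils::write.csv(r$calibration$bins, file.path(sd, "calibration_bins.csv"),
                     row.names = FALSE)
    utils::write.csv(r$fit$convergence$table, file.path(sd, "rhat.csv"),
                     row.names = FALSE)
    write_geojson(list(boundary = unclass(r$boundary)),
                  file.path(sd, "boundary.geojson"))
    write_ascii_grid(r$surface_p$w, file.path(sd, "surface_p.asc"))
    write_ascii_grid(r$change, file.path(sd, "change.asc"))
    utils::write.csv(r$change_by_class, file.path(sd, "change_by_class.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$composite))
    write_ascii_grid(res$composite$w, file.path(outdir, "composite.asc"))
  if (!is.null(res$contrast))
    utils::write.csv(res$contrast, file.path(outdir, "contrast.csv"),
                     row.names = FALSE)
  log <- list(seed = res$config$seed, seasons = names(res$seasons),
              model = unclass(res$config$model),
              selected_scales = lapply(res$seasons, function(r)
                as.list(r$two_stage$modal_scales)),
              quadratic_terms = lapply(res$seasons, `[[`, "quadratic_terms"))
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(outdir)
}

#' Study ledger of sample sizes
#'
#' Per-season and per-year bookkeeping of individuals, used locations and
#' (implied) availability counts, with the pooled nest total and the
#' translocation total. Accepts either a combined location table (rows are
#' locations with `individual_id`, `date`, `life_stage`, `year`) or a nest
#' count table (`year`, `n_nests`); release records are a table with `year`,
#' `season` (`"spring"` / `"brood"`) and `n_females`. Duplicate
#' (individual, date, life stage) rows are rejected.
#'
#' @param locations location table or nest count table.
#' @param releases optional release-record table.
#' @param ratio availability points per used point (bookkeeping only).
#' @return A `study_ledger` list.
#' @export
ledger_counts <- function(locations = NULL, releases = NULL, ratio = 5) {
  seasons <- NULL
  nest_by_year <- NULL
  nest_total <- NA_integer_
  if (!is.null(locations)) {
    if ("n_nests" %in% names(locations)) {
      nest_by_year <- locations
      nest_total <- sum(locations$n_nests)
    } else {
      key <- paste(locations$individual_id, locations$date, locations$life_stage)
      if (anyDuplicated(key))
        stop("duplicate (individual, date, life stage) rows in the location table")
      seasons <- do.call(rbind, lapply(split(locations, locations$life_stage),
        function(d) data.frame(
          life_stage = d$life_stage[1],
          individuals = length(unique(d$individual_id)),
          used = nrow(d), available = ratio * nrow(d))))
      rownames(seasons) <- NULL
      nests <- locations[locations$life_stage == "nest", , drop = FALSE]
      if (nrow(nests)) {
        tab <- table(nests$year)
        nest_by_year <- data.frame(year = as.integer(names(tab)),
                                   n_nests = as.integer(tab))
        nest_total <- nrow(nests)
      }
    }
  }
  translocated_total <- NA_integer_
  if (!is.null(releases)) {
    if (!all(c("year", "season", "n_females") %in% names(releases)))
      stop("release records need year, season and n_females columns")
    translocated_total <- sum(releases$n_females[releases$season == "spring"]) +
      sum(releases$n_females[releases$season == "brood"])
  }
  structure(list(seasons = seasons, nest_by_year = nest_by_year,
                 nest_total = nest_total, releases = releases,
                 translocated_total = translocated_total, ratio = ratio),
            class = "study_ledger")
}

#' @export
print.study_ledger <- function(x, ...) {
  cat("<study_ledger>\n")
  if (!is.null(x$seasons)) print(x$seasons)
  if (!is.na(x$nest_total)) cat("  pooled nests:", x$nest_total, "\n")
  if (!is.na(x$translocated_total))
    cat("  translocated females:", x$translocated_total, "\n")
  invisible(x)
}

#' Printed study counts
#'
#' The study's published per-year nest counts and release records, shipped
#' as plain-text tables; inputs to [ledger_counts()].
#'
#' @return List with `nests` (`year`, `group`, `n_nests`) and `releases`
#'   (`year`, `season`, `n_females`, `n_chicks`).
#' @export
study_counts <- function() {
  list(
    nests = utils::read.csv(system.file("extdata", "study_nest_counts.csv",
                                        package = "grouseRSF")),
    releases = utils::read.csv(system.file("extdata", "study_release_counts.csv",
                                           package = "grouseRSF")))
}

#' Benchmark study: two-stage fit and held-out calibration on synthetic data
#'
#' The package's standard end-to-end check: a seeded 120 x 120-cell
#' landscape, 30 individuals with 5 daily locations each (~150 used points,
#' 5:1 availability), a two-stage random-intercept fit on two thirds of the
#' individuals, and 10-bin calibration on the withheld individuals. Returns
#' the calibration statistics and the maximum Gelman-Rubin rhat across all
#' monitored parameters of both stages.
#'
#' @param seed global seed.
#' @param iterations,burn_in,chains,thin MCMC profile; the defaults are the
#'   full study protocol, `iterations = 5000, burn_in = 2500` is the reduced
#'   profile used in the test suite.
#' @return List: `calibration`, `max_rhat`, `rhat_table`, `two_stage`,
#'   `design`, `n_rows`.
#' @export
benchmark_calibration <- function(seed = 1, iterations = 30000,
                                  burn_in = 15000, chains = 3, thin = 5) {
  land <- generate_landscape(landscape_config(), seed = seed)
  truth <- simulation_truth()
  locs <- simulate_individuals(land, truth, n_individuals = 30,
                               days_per_individual = 5, seed = seed + 1)
  locs <- thin_one_per_day(locs, seed = seed + 2)
  locs <- filter_min_locations(locs, "brood")
  boundary <- mcp_boundary(locs)
  avail <- sample_available(boundary, nrow(locs), ratio = 5, seed = seed + 3)
  stack <- build_covariate_stack(land, radii = c(60, 331, 887))
  design <- assemble_design(locs, avail, stack)
  design <- split_train_test(design, seed = seed + 4)
  design <- standardize_design(design)
  cfg <- rsf_model_config(chains = chains, iterations = iterations,
                          burn_in = burn_in, thin = thin,
                          random_intercept = TRUE, seed = seed + 5)
  ts <- two_stage_fit(design, cfg)
  cal <- validate_holdout(ts$fit, ts$design)
  rhat <- rbind(cbind(stage = 1L, ts$stage1$convergence$table),
                cbind(stage = 2L, ts$fit$convergence$table))
  list(calibration = cal,
       max_rhat = max(rhat$rhat, na.rm = TRUE),
       rhat_table = rhat,
       two_stage = ts, design = ts$design, n_rows = nrow(design))
}
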