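#' Precision, bias, accuracy, and coverage of replicate estimates
#'
#' Given replicate abundance estimates against a known truth:
#' * precision: coefficient of variation, `cv = sd / mean` of the estimates
#'   (sample standard deviation);
#' * bias: scaled mean error, `sme = mean((n_hat - truth) / truth)`;
#' * accuracy: scaled root mean squared error,
#'   `srmse = sqrt(mean(((n_hat - truth) / truth)^2))`;
#' * coverage: fraction of replicates whose confidence interval contains the
#'   truth (when intervals are supplied).
#'
#' @param estimates A numeric vector of abundance estimates, or a data frame
#'   with `n_hat` and optionally `ci_low`/`ci_high`.
#' @param truth The true (positive) abundance.
#' @return A one-row tibble with `n_iter`, `cv`, `sme`, `srmse`, `coverage`.
#' @examples
#' compute_metrics(c(90, 110), truth = 100) # sme 0, srmse 0.10, cv ~0.1414
#' @export
compute_metrics <- function(estimates, truth) {
  if (!is.numeric(truth) || truth <= 0) abort("truth must be a positive count")
  if (is.data.frame(estimates)) {
    n_hat <- estimates$n_hat
    ci_low <- estimates$ci_low
    ci_high <- estimates$ci_high
  } else {
    n_hat <- as.numeric(estimates)
    ci_low <- NULL
  }
  if (length(n_hat) < 2) abort("need at least 2 estimates")
  err <- (n_hat - truth) / truth
  coverage <- if (!is.null(ci_low) && any(!is.na(ci_low))) {
    mean(ci_low <= truth & truth <= ci_high, na.rm = TRUE)
  } else {
    NA_real_
  }
  tibble(
    n_iter = length(n_hat),
    cv = sd(n_hat) / mean(n_hat),
    sme = mean(err),
    srmse = sqrt(mean(err^2)),
    coverage = coverage
  )
}

# Shared engine behind the three objectives: run `iterations` independent
# multi-year sampling histories on one simulated population, estimate
# abundance each year, and tabulate metrics. `scheme` picks the design;
# `levels` are sampling fractions (population) or cell counts (spatial).
run_sampling_experiment <- function(sim, scheme = c("population", "spatial"),
                                    levels, years = NULL, iterations = 50,
                                    n_boot = 2000, ci_level = 0.95,
                                    prior = beta_prior(),
                                    adult_age_threshold = 2, seed = 1L,
                                    layers = NULL, cells = NULL,
                                    truth_fun = NULL, mortality_known = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(years)) years <- (sim$years - 4):sim$years
  ped0 <- sim_pedigree(sim)
  inds <- sim$state$inds
  if (scheme == "spatial" && is.null(layers)) {
    layers <- lapply(years, function(t) spatial_layer(sim, t, cells = cells))
    names(layers) <- as.character(years)
  }
  if (is.null(truth_fun)) {
    truth_fun <- function(t) true_adults(sim, t, adult_age_threshold)
  }
  truths <- vapply(years, truth_fun, numeric(1))
  names(truths) <- as.character(years)

  rows <- vector("list", length(levels) * iterations * length(years))
  k <- 0L
  for (lev in levels) {
    for (it in seq_len(iterations)) {
      record <- new_sampling_record()
      ped <- ped0
      for (t in years) {
        eligible <- inds$id[alive_at(sim, t) & inds$in_area]
        pool <- length(setdiff(eligible, record$id))
        s <- derive_seed(seed, paste(scheme, lev, it, t))
        n_before <- nrow(record)
        record <- if (scheme == "population") {
          population_sample(sim, t, lev, record, seed = s)
        } else {
          spatial_sample(sim, t, lev,
            layer = layers[[as.character(t)]],
            record = record, seed = s
          )
        }
        new_rows <- record[record$year == t, ]
        ped <- apply_record(ped, new_rows)
        # mortality accounting: the practitioner is assumed to know which
        # pedigree members are no longer alive at this census, so dead
        # adults drop out of the segment counts (their genotypes still
        # establish matches)
        if (mortality_known) ped$known_dead <- !alive_at(sim, t)
        res <- tryCatch(
          {
            counts <- classify_adults(ped, t, adult_age_threshold)
            if (n_boot > 0) {
              bootstrap_interval(counts, prior, n_boot, ci_level,
                seed = derive_seed(seed, paste("boot", lev, it, t))
              )
            } else {
              estimate_abundance(counts)
            }
          },
          pedrecon_undefined = function(e) NULL
        )
        k <- k + 1L
        rows[[k]] <- tibble(
          level = lev, iteration = it, year = t,
          n_new = nrow(record) - n_before,
          n_pool = pool,
          n_cum = nrow(record),
          truth = truths[[as.character(t)]],
          failed = is.null(res),
          n_obs = if (is.null(res)) NA_integer_ else res$n_obs,
          n_hat = if (is.null(res)) NA_real_ else res$n_hat,
          ci_low = if (is.null(res)) NA_real_ else res$ci_low,
          ci_high = if (is.null(res)) NA_real_ else res$ci_high
        )
      }
    }
  }
  estimates <- bind_rows(rows)

  metrics <- estimates %>%
    group_by(.data$level, .data$year) %>%
    summarise(
      truth = .data$truth[1],
      n_iter = sum(!.data$failed),
      failure_rate = mean(.data$failed),
      mean_n_new = mean(.data$n_new),
      realized_fraction = mean(.data$n_new / pmax(.data$n_pool, 1)),
      cv = if (sum(!.data$failed) >= 2) {
        sd(.data$n_hat[!.data$failed]) / mean(.data$n_hat[!.data$failed])
      } else {
        NA_real_
      },
      sme = mean((.data$n_hat[!.data$failed] - .data$truth[1]) / .data$truth[1]),
      srmse = sqrt(mean(((.data$n_hat[!.data$failed] - .data$truth[1]) / .data$truth[1])^2)),
      coverage = mean(
        .data$ci_low[!.data$failed] <= .data$truth[1] &
          .data$truth[1] <= .data$ci_high[!.data$failed]
      ),
      .groups = "drop"
    )

  growth <- estimates %>%
    filter(!.data$failed) %>%
    arrange(.data$level, .data$iteration, .data$year) %>%
    group_by(.data$level, .data$iteration) %>%
    filter(n() >= 2) %>%
    dplyr::reframe(
      year_from = .data$year[-dplyr::n()],
      year_to = .data$year[-1],
      lambda_hat = .data$n_hat[-1] / .data$n_hat[-dplyr::n()],
      lambda_true = .data$truth[-1] / .data$truth[-dplyr::n()]
    )

  structure(
    list(
      scheme = scheme, estimates = estimates, metrics = metrics,
      growth = growth, years = years, iterations = iterations,
      n_boot = n_boot, ci_level = ci_level, seed = seed
    ),
    class = "pr_experiment"
  )
}

#' Objective 1: estimator accuracy under population-based sampling
#'
#' Runs replicate multi-year population-based sampling histories at a range
#' of sampling intensities on one simulated population, re-estimating adult
#' abundance each year, and reports precision (CV), bias (SME), accuracy
#' (SRMSE), confidence-interval coverage, and growth-rate estimates against
#' the true in-study-area adult count.
#'
#' @param sim A `pop_sim` (default configuration: 20 burn-in years plus 5
#'   sampling years).
#' @param intensities Sampling fractions to test (default 10-90% in 10%
#'   steps).
#' @param years Census years to sample (default: the last five).
#' @param iterations Replicate sampling histories per intensity.
#' @param n_boot Bootstrap trials per estimate (0 skips intervals).
#' @param ci_level Interval level.
#' @param prior Beta prior on the marginals.
#' @param adult_age_threshold Adult age cutoff.
#' @param seed Root seed.
#' @return A `pr_experiment` with `estimates`, `metrics`, and `growth`.
#' @export
run_objective1 <- function(sim, intensities = seq(0.1, 0.9, by = 0.1),
                           years = NULL, iterations = 50, n_boot = 2000,
                           ci_level = 0.95, prior = beta_prior(),
                           adult_age_threshold = 2, seed = 1L,
                           mortality_known = TRUE) {
  run_sampling_experiment(
    sim, "population", intensities, years, iterations, n_boot, ci_level,
    prior, adult_age_threshold, seed,
    mortality_known = mortality_known
  )
}

#' Objective 2: spatial sampling effort for accurate estimates
#'
#' As [run_objective1()] but with abundance-weighted grid-cell surveys and
#' utilization-scaled detection. The metrics table additionally reports the
#' realized fraction of previously unsampled individuals captured per effort
#' and year.
#'
#' @inheritParams run_objective1
#' @param efforts Numbers of 1 km^2 cells surveyed annually.
#' @export
run_objective2 <- function(sim, efforts = c(10, 50, 100, 150, 200),
                           years = NULL, iterations = 50, n_boot = 2000,
                           ci_level = 0.95, prior = beta_prior(),
                           adult_age_threshold = 2, seed = 1L,
                           mortality_known = TRUE) {
  run_sampling_experiment(
    sim, "spatial", efforts, years, iterations, n_boot, ci_level,
    prior, adult_age_threshold, seed,
    mortality_known = mortality_known
  )
}

#' Density zones spanning the simulated population
#'
#' Nine equal square zones (default 298 km^2 each) in a 3 x 3 layout
#' centred on the study area. Because dispersal carries animals beyond the
#' management-unit rectangle, the zone extent is larger than the study area
#' itself; only the grid cells inside the study area are surveyable.
#'
#' @param area A `study_area`.
#' @param zone_area_km2 Area of each zone.
#' @param n_side Zones per side.
#' @return A tibble with `zone`, `x0`, `x1`, `y0`, `y1`.
#' @export
zone_spec <- function(area, zone_area_km2 = 298, n_side = 3) {
  side <- sqrt(zone_area_km2)
  cx <- area$origin[1] + area$width / 2
  cy <- area$origin[2] + area$height / 2
  x0 <- cx - n_side * side / 2
  y0 <- cy - n_side * side / 2
  grid <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  zx0 <- x0 + (grid$ix - 1) * side
  zy0 <- y0 + (grid$iy - 1) * side
  tibble(
    zone = seq_len(n_side^2),
    x0 = zx0, x1 = zx0 + side,
    y0 = zy0, y1 = zy0 + side
  )
}

#' Objective 3: estimator performance across local densities
#'
#' Single-year, final-census experiment: the population extent is split
#' into nine equal-density zones, and each zone is surveyed at a range of
#' fractions of its available 1 km^2 grid cells with the stratified spatial
#' design. Zone truth is the number of alive adults whose home-range
#' centroid falls in the zone; outputs are per-zone density, bias, and
#' interval coverage by effort.
#'
#' @inheritParams run_objective1
#' @param fractions Fractions of each zone's grid cells to survey.
#' @param year Census year (default: the final one).
#' @param zones A [zone_spec()] tibble.
#' @return A list of class `pr_zone_experiment` with `zones` (per-zone truth
#'   and density) and `metrics` (per zone x effort).
#' @export
run_objective3 <- function(sim, fractions = c(0.01, 0.05, 0.10, 0.20),
                           year = NULL, zones = NULL, iterations = 30,
                           n_boot = 2000, ci_level = 0.95,
                           prior = beta_prior(), adult_age_threshold = 2,
                           seed = 1L) {
  if (is.null(year)) year <- sim$years
  if (is.null(zones)) zones <- zone_spec(sim$area)
  area <- sim$area
  inds <- sim$state$inds
  alive <- alive_at(sim, year)
  adult <- alive & (year - inds$birth_year) >= adult_age_threshold

  centers <- cell_center(area, seq_len(area$n_cells))
  layer_full <- spatial_layer(sim, year)
  zone_rows <- vector("list", nrow(zones))
  metric_rows <- list()
  for (z in seq_len(nrow(zones))) {
    zn <- zones[z, ]
    # clip the zone to the surveyable grid extent so truth, density, and
    # sampling effort all refer to the same frame (animals beyond the grid
    # cannot be surveyed and would contaminate the bias of edge zones)
    ox0 <- max(zn$x0, area$origin[1])
    ox1 <- min(zn$x1, area$origin[1] + area$width)
    oy0 <- max(zn$y0, area$origin[2])
    oy1 <- min(zn$y1, area$origin[2] + area$height)
    if (ox1 <= ox0 || oy1 <= oy0) next
    in_zone <- alive & inds$cx >= ox0 & inds$cx < ox1 &
      inds$cy >= oy0 & inds$cy < oy1
    truth <- sum(in_zone & adult)
    zcells <- which(centers[, 1] >= ox0 & centers[, 1] < ox1 &
      centers[, 2] >= oy0 & centers[, 2] < oy1)
    zone_rows[[z]] <- tibble(
      zone = zn$zone,
      n_alive = sum(in_zone),
      n_adults = truth,
      n_cells = length(zcells),
      surveyable_km2 = (ox1 - ox0) * (oy1 - oy0),
      density = population_density(sum(in_zone), (ox1 - ox0) * (oy1 - oy0))
    )
    if (truth == 0 || length(zcells) == 0) next
    layer <- restrict_layer(layer_full, zcells)
    for (f in fractions) {
      n_cells <- max(1, floor(f * length(zcells) + 0.5))
      exp_z <- run_sampling_experiment(
        sim, "spatial",
        levels = n_cells, years = year,
        iterations = iterations, n_boot = n_boot, ci_level = ci_level,
        prior = prior, adult_age_threshold = adult_age_threshold,
        seed = derive_seed(seed, paste("zone", zn$zone, f)),
        layers = setNames(list(layer), as.character(year)),
        truth_fun = function(t) truth
      )
      m <- exp_z$metrics
      m$zone <- zn$zone
      m$fraction <- f
      m$density <- zone_rows[[z]]$density
      metric_rows[[length(metric_rows) + 1]] <- m
    }
  }
  structure(
    list(
      zones = bind_rows(zone_rows),
      metrics = bind_rows(metric_rows),
      year = year, seed = seed
    ),
    class = "pr_zone_experiment"
  )
}

#' Population density over an area
#'
#' @param n Number of animals.
#' @param area A `study_area`, or a numeric area in km^2.
#' @return Animals per km^2.
#' @examples
#' population_density(872, make_study_area()) # 0.528 moose / km^2
#' @export
population_density <- function(n, area) {
  a <- if (inherits(area, "study_area")) area$area_km2 else as.numeric(area)
  if (a <= 0) abort("area must be positive")
  n / a
}

#' Genotyping cost of a sampling effort
#'
#' @param mean_sampled Mean number of animals sampled.
#' @param unit_cost Genotyping cost per sample (default 22 USD).
#' @return A tibble with the total cost.
#' @examples
#' cost_summary(c(769, 793)) # 16918, 17446 USD
#' @export
cost_summary <- function(mean_sampled, unit_cost = 22) {
  tibble(
    mean_sampled = mean_sampled,
    unit_cost = unit_cost,
    total = mean_sampled * unit_cost
  )
}

#' @export
print.pr_experiment <- function(x, ...) {
  cat(sprintf(
    "%s-based sampling experiment: %d levels x %d iterations x %d years\n",
    x$scheme, length(unique(x$metrics$level)), x$iterations, length(x$years)
  ))
  print(as_tibble(x$metrics), n = 20)
  invisible(x)
}

#' Metrics table of an experiment
#' @param x A `pr_experiment`.
#' @param ... Unused.
#' @export
tidy.pr_experiment <- function(x, ...) {
  as_tibble(x$metrics)
}

#' Plot bias by sampling effort and year
#' @param object A `pr_experiment`.
#' @param metric One of `"sme"`, `"cv"`, `"srmse"`, `"coverage"`.
#' @param ... Unused.
#' @export
autoplot.pr_experiment <- function(object, metric = "sme", ...) {
  m <- object$metrics
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$year, y = .data[[metric]],
    colour = factor(.data$level), group = .data$level
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "sampling year", y = metric,
      colour = if (object$scheme == "population") "fraction" else "cells"
    ) +
    ggplot2::theme_minimal()
}
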