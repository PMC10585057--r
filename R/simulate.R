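#' Initialize a simulated population
#'
#' Creates `n0` individuals at the stable age distribution shipped with the
#' vital-rate table (scaled proportionally when `n0` differs from the
#' table's total), assigns each a uniform-random home-range centroid inside
#' the study area, and generates synthetic winter/annual home ranges.
#' Founders have no recorded parents.
#'
#' @param rates A vital-rate table (see [moose_vital_rates()]).
#' @param n0 Starting population size (default 659).
#' @param area A `study_area`.
#' @param hr Home-range parameters ([hr_params()]).
#' @param seed Integer seed.
#' @param age_structure Optional explicit tibble with `sex`, `age`, `n`;
#'   must sum to `n0`.
#' @return A list of class `pop_state`: the census at year 0.
#' @export
initialize_population <- function(rates = moose_vital_rates(), n0 = 659,
                                  area = make_study_area(), hr = hr_params(),
                                  seed = 1L, age_structure = NULL) {
  if (!is.numeric(n0) || n0 < 1) abort("n0 must be at least 1")
  if (is.null(age_structure)) {
    struct <- starting_age_structure(rates)
    tot <- sum(struct$n)
    if (n0 != tot) {
      # proportional scaling with largest-remainder rounding
      raw <- struct$n * n0 / tot
      base <- floor(raw)
      rem <- n0 - sum(base)
      ord <- order(raw - base, decreasing = TRUE)
      add <- integer(nrow(struct))
      if (rem > 0) add[ord[seq_len(rem)]] <- 1L
      struct$n <- as.integer(base + add)
    }
  } else {
    struct <- as_tibble(age_structure)
    if (sum(struct$n) != n0) {
      abort("explicit age_structure must sum to n0")
    }
  }
  struct <- struct[struct$n > 0, ]
  sex <- rep(struct$sex, struct$n)
  age <- rep(struct$age, struct$n)
  n <- length(sex)
  with_seed(derive_seed(seed, "init"), {
    cx <- runif(n, area$origin[1], area$origin[1] + area$width)
    cy <- runif(n, area$origin[2], area$origin[2] + area$height)
    hrs <- vector("list", n)
    for (i in seq_len(n)) {
      hrs[[i]] <- generate_home_range(cx[i], cy[i], sex[i], hr)
    }
    inds <- tibble(
      id = seq_len(n),
      sex = sex,
      age = as.integer(age),
      mother_id = NA_integer_,
      father_id = NA_integer_,
      alive = TRUE,
      birth_year = as.integer(-age),
      death_year = NA_integer_,
      cx = cx, cy = cy,
      hull_a = purrr::map(hrs, "hull_annual"),
      r_a = purrr::map_dbl(hrs, "r_annual"),
      cloud_w = purrr::map(hrs, "cloud_winter"),
      hull_w = purrr::map(hrs, "hull_winter"),
      r_w = purrr::map_dbl(hrs, "r_winter"),
      in_area = purrr::map_lgl(hrs, function(h) {
        convex_intersects(h$hull_annual, area_polygon(area))
      })
    )
    structure(
      list(
        year = 0L, inds = inds, area = area, hr = hr,
        counts = census_row(inds, 0L, 0L, 0L, 0L, 0L)
      ),
      class = "pop_state"
    )
  })
}

census_row <- function(inds, year, births, winter_deaths, summer_deaths, no_father) {
  alive <- inds$alive
  adult <- alive & inds$age >= 2
  tibble(
    year = as.integer(year),
    n_alive = sum(alive),
    n_adults = sum(adult),
    n_alive_area = sum(alive & inds$in_area),
    n_adults_area = sum(adult & inds$in_area),
    births = as.integer(births),
    winter_deaths = as.integer(winter_deaths),
    summer_deaths = as.integer(summer_deaths),
    no_father_events = as.integer(no_father)
  )
}

#' Advance the population by one annual cycle
#'
#' Applies, in order: (1) Bernoulli winter survival at sex/age-specific
#' rates; (2) the May birth pulse — each surviving female with a positive
#' birth rate at her census age bears at most one calf (calf sex is a fair
#' coin flip), with the father drawn by [assign_mate()] among males older
#' than 3 that were alive at the previous December census and whose annual
#' MCP overlaps the mother's (no overlapping candidate cancels the birth and
#' is logged); (3) aging of all survivors by one year (newborns stay age 0);
#' (4) dispersal of new yearlings to a new centroid and freshly generated
#' home ranges; (5) Bernoulli summer survival at the new ages. Dead
#' individuals are retained with `alive = FALSE` and their `death_year` set
#' to the census they failed to reach.
#'
#' @param state A `pop_state`.
#' @param rates A vital-rate table.
#' @param seed Optional integer seed for this step (a deterministic child
#'   stream is derived from it and the step's year).
#' @return The `pop_state` at the next census.
#' @export
step_year <- function(state, rates, seed = NULL) {
  run <- function() {
    inds <- state$inds
    yr <- state$year + 1L
    alive0 <- which(inds$alive)

    # (1) winter survival
    p_w <- rate_at(rates, inds$sex[alive0], inds$age[alive0], "winter")
    surv_w <- rbinom(length(alive0), 1, p_w) == 1
    died_w <- alive0[!surv_w]
    inds$alive[died_w] <- FALSE
    inds$death_year[died_w] <- yr
    alive_w <- alive0[surv_w]

    # candidate fathers: alive at the previous December census, age > 3 there
    cand <- alive0[inds$sex[alive0] == "M" & inds$age[alive0] > 3]

    # (2) May birth pulse
    fem <- alive_w[inds$sex[alive_w] == "F"]
    b <- rate_at(rates, inds$sex[fem], inds$age[fem], "birth")
    bearing_calf <- fem[rbinom(length(fem), 1, b) == 1]
    no_father <- 0L
    mothers <- integer(0)
    fathers <- integer(0)
    if (length(bearing_calf) > 0) {
      cx_c <- inds$cx[cand]
      cy_c <- inds$cy[cand]
      r_c <- inds$r_a[cand]
      hulls <- inds$hull_a
      for (m in bearing_calf) {
        near <- cand[(cx_c - inds$cx[m])^2 + (cy_c - inds$cy[m])^2 <=
          (r_c + inds$r_a[m])^2]
        ok <- near[vapply(
          near,
          function(j) convex_intersects(hulls[[j]], hulls[[m]]),
          logical(1)
        )]
        if (length(ok) == 0) {
          no_father <- no_father + 1L
        } else {
          mothers <- c(mothers, m)
          fathers <- c(fathers, if (length(ok) == 1) ok else sample(ok, 1))
        }
      }
    }

    # (3) aging (newborns are added afterwards at age 0)
    inds$age[alive_w] <- inds$age[alive_w] + 1L

    # (4) yearling dispersal: new centroid, fresh home ranges
    yearlings <- alive_w[inds$age[alive_w] == 1L]
    if (length(yearlings) > 0) {
      dr <- rates[!is.na(rates$dispersal_mean_km), ]
      dmu <- setNames(dr$dispersal_mean_km, dr$sex)
      dsd <- setNames(dr$dispersal_sd_km, dr$sex)
      bear <- runif(length(yearlings), 0, 2 * pi)
      dist <- pmax(0, rnorm(
        length(yearlings),
        dmu[inds$sex[yearlings]], dsd[inds$sex[yearlings]]
      ))
      nx <- inds$cx[yearlings] + dist * sin(bear)
      ny <- inds$cy[yearlings] + dist * cos(bear)
      for (k in seq_along(yearlings)) {
        i <- yearlings[k]
        h <- generate_home_range(nx[k], ny[k], inds$sex[i], state$hr)
        inds$cx[i] <- nx[k]
        inds$cy[i] <- ny[k]
        inds$hull_a[[i]] <- h$hull_annual
        inds$r_a[i] <- h$r_annual
        inds$cloud_w[[i]] <- h$cloud_winter
        inds$hull_w[[i]] <- h$hull_winter
        inds$r_w[i] <- h$r_winter
        inds$in_area[i] <- convex_intersects(h$hull_annual, area_polygon(state$area))
      }
    }

    # append newborn calves (mother's home range until their own dispersal)
    n_born <- length(mothers)
    if (n_born > 0) {
      calves <- tibble(
        id = max(inds$id) + seq_len(n_born),
        sex = ifelse(rbinom(n_born, 1, 0.5) == 1, "F", "M"),
        age = 0L,
        mother_id = inds$id[mothers],
        father_id = inds$id[fathers],
        alive = TRUE,
        birth_year = yr,
        death_year = NA_integer_,
        cx = inds$cx[mothers], cy = inds$cy[mothers],
        hull_a = inds$hull_a[mothers],
        r_a = inds$r_a[mothers],
        cloud_w = inds$cloud_w[mothers],
        hull_w = inds$hull_w[mothers],
        r_w = inds$r_w[mothers],
        in_area = inds$in_area[mothers]
      )
      inds <- bind_rows(inds, calves)
    }

    # (5) summer survival at the new ages
    alive_s <- which(inds$alive)
    p_s <- rate_at(rates, inds$sex[alive_s], inds$age[alive_s], "summer")
    surv_s <- rbinom(length(alive_s), 1, p_s) == 1
    died_s <- alive_s[!surv_s]
    inds$alive[died_s] <- FALSE
    inds$death_year[died_s] <- yr

    state$inds <- inds
    state$year <- yr
    state$counts <- bind_rows(
      state$counts,
      census_row(inds, yr, n_born, length(died_w), length(died_s), no_father)
    )
    state
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, paste0("step", state$year + 1)), run())
}

#' Draw a mate for a reproducing female
#'
#' Uniform random choice among candidate fathers: males older than 3 years
#' at the state's census, alive, whose annual 100% MCP intersects the
#' mother's. Returns `NA` when no candidate overlaps (the simulator then
#' cancels the birth and logs the event).
#'
#' @param state A `pop_state`.
#' @param mother_id Id of the reproducing female.
#' @param seed Optional seed.
#' @return The chosen male's id, or `NA_integer_`.
#' @export
assign_mate <- function(state, mother_id, seed = NULL) {
  inds <- state$inds
  m <- match(mother_id, inds$id)
  if (is.na(m)) abort("mother_id not found")
  cand <- which(inds$alive & inds$sex == "M" & inds$age > 3)
  near <- cand[(inds$cx[cand] - inds$cx[m])^2 + (inds$cy[cand] - inds$cy[m])^2 <=
    (inds$r_a[cand] + inds$r_a[m])^2]
  ok <- near[vapply(
    near,
    function(j) convex_intersects(inds$hull_a[[j]], inds$hull_a[[m]]),
    logical(1)
  )]
  if (length(ok) == 0) {
    return(NA_integer_)
  }
  pick <- function() if (length(ok) == 1) ok else sample(ok, 1)
  j <- if (is.null(seed)) pick() else with_seed(seed, pick())
  inds$id[j]
}

#' Run the full multi-year simulation
#'
#' Initializes the population and advances it through `years` annual cycles,
#' recording a census row per year. All randomness derives deterministically
#' from the root seed; each year consumes an independent child stream, so
#' downstream consumers (e.g. the estimator bootstrap) are unaffected by
#' replay order.
#'
#' @inheritParams initialize_population
#' @param years Number of annual cycles (default 25: a 20-year burn-in that
#'   builds the pedigree plus 5 sampling years).
#' @return A list of class `pop_sim` with the final `state`, the per-census
#'   `counts` tibble, and the configuration used.
#' @examples
#' \donttest{
#' sim <- simulate_population(years = 5, n0 = 200, seed = 42)
#' tidy(sim)
#' }
#' @export
simulate_population <- function(rates = moose_vital_rates(), years = 25,
                                n0 = 659, area = make_study_area(),
                                hr = hr_params(), seed = 1L) {
  state <- initialize_population(rates, n0, area, hr, seed)
  for (y in seq_len(years)) {
    state <- step_year(state, rates, seed = seed)
  }
  structure(
    list(
      state = state, counts = state$counts, area = area, rates = rates,
      hr = hr, seed = seed, years = years
    ),
    class = "pop_sim"
  )
}

#' @export
print.pop_sim <- function(x, ...) {
  last <- x$counts[nrow(x$counts), ]
  cat(sprintf(
    "Simulated population: %d years, %d -> %d alive (%d adults, %d in study area)\n",
    x$years, x$counts$n_alive[1], last$n_alive, last$n_adults, last$n_adults_area
  ))
  invisible(x)
}

#' Per-census counts of a simulation
#' @param x A `pop_sim`.
#' @param ... Unused.
#' @return The census tibble: one row per year with alive/adult totals,
#'   in-study-area totals, births, seasonal deaths, and cancelled-birth
#'   events.
#' @export
tidy.pop_sim <- function(x, ...) {
  as_tibble(x$counts)
}

#' One-row summary of a simulation
#' @param x A `pop_sim`.
#' @param ... Unused.
#' @export
glance.pop_sim <- function(x, ...) {
  n0 <- x$counts$n_alive[1]
  nT <- x$counts$n_alive[nrow(x$counts)]
  tibble(
    years = x$years,
    n_start = n0,
    n_final = nT,
    lambda_realized = (nT / n0)^(1 / x$years),
    lambda_asymptotic = lambda_asymptotic(x$rates),
    seed = x$seed
  )
}

#' Plot the simulated trajectory
#' @param object A `pop_sim`.
#' @param ... Unused.
#' @export
autoplot.pop_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$counts[, c("year", "n_alive", "n_adults", "n_adults_area")],
    -"year",
    names_to = "series", values_to = "n"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$n, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "census year", y = "individuals", colour = NULL) +
    ggplot2::theme_minimal()
}

# Logical index over sim$state$inds: alive at census `year`.
alive_at <- function(sim, year) {
  inds <- sim$state$inds
  inds$birth_year <= year & (is.na(inds$death_year) | inds$death_year > year)
}

#' True adult count at a census
#'
#' Recomputes, from the raw individual table, the number of adults alive at
#' the given census — optionally restricted to animals whose annual MCP
#' intersects the study area. This is the denominator for bias and accuracy
#' metrics.
#'
#' @param sim A `pop_sim`.
#' @param year Census year.
#' @param adult_age_threshold Adult age cutoff (default 2).
#' @param in_area_only Restrict to study-area animals (default `TRUE`).
#' @return An integer count.
#' @export
true_adults <- function(sim, year, adult_age_threshold = 2, in_area_only = TRUE) {
  inds <- sim$state$inds
  keep <- alive_at(sim, year) & (year - inds$birth_year) >= adult_age_threshold
  if (in_area_only) keep <- keep & inds$in_area
  sum(keep)
}

# Annual or winter hulls of animals alive at a census (for cell weights /
# detection tables). Accepts a pop_sim or pop_state.
alive_hulls <- function(x, year = NULL, season = c("annual", "winter")) {
  season <- match.arg(season)
  if (inherits(x, "pop_sim")) {
    if (is.null(year)) year <- x$state$year
    keep <- alive_at(x, year)
    inds <- x$state$inds
  } else {
    inds <- x$inds
    keep <- inds$alive
  }
  col <- if (season == "annual") "hull_a" else "hull_w"
  inds[[col]][keep]
}

#' Export the true pedigree of a simulation
#'
#' Returns the simulation's individual table in the estimator's pedigree
#' layout (`id`, `sire`, `dam`, `sex`, `birth_year`, plus unsampled/alive
#' bookkeeping columns). The `sampled` flags are all `FALSE`; sampling
#' designs fill them in.
#'
#' @param sim A `pop_sim`.
#' @return A `pedigree` tibble.
#' @export
sim_pedigree <- function(sim) {
  inds <- sim$state$inds
  as_pedigree(tibble(
    id = inds$id,
    sire = inds$father_id,
    dam = inds$mother_id,
    sex = inds$sex,
    birth_year = inds$birth_year,
    sampled = FALSE,
    sample_year = NA_integer_,
    known_dead = FALSE
  ))
}
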