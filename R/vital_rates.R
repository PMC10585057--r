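#' Default moose vital-rate and age-structure table
#'
#' Sex- and age-specific winter survival, birth rate (calves per cow per
#' year), summer survival, yearling dispersal-distance parameters (km), and
#' the starting number of animals per class for the default simulated
#' population (659 animals at a stable age distribution). Rates come from
#' multiyear radio-collar studies of moose in northern New England, adjusted
#' for a stable, slightly growing population; senescence is embedded in the
#' declining survival of classes above age 9, and the terminal class pools
#' all ages of 13 and older.
#'
#' Age is the age in whole years at the December census. Birth rate is the
#' probability that a female of that census age produces a single calf at the
#' following May birth pulse (twinning is not modelled). `age_to = NA` marks
#' an open-ended terminal class whose rates apply to all older ages.
#'
#' @param path Optional path to a CSV in the same layout; defaults to the
#'   table shipped with the package.
#' @return A tibble of class `vital_rates` with columns `sex`, `age_from`,
#'   `age_to`, `winter_survival`, `birth_rate`, `summer_survival`,
#'   `dispersal_mean_km`, `dispersal_sd_km`, `n_start`.
#' @examples
#' rates <- moose_vital_rates()
#' sum(rates$n_start) # 659
#' @export
moose_vital_rates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vital_rates_moose.csv", package = "pedrecon")
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- as_tibble(out)
  class(out) <- c("vital_rates", class(out))
  validate_vital_rates(out)
  out
}

#' Validate a vital-rate table
#'
#' Checks that survival and birth probabilities lie in \[0, 1\], that males
#' carry no birth rate, that each sex has a contiguous age coverage starting
#' at 0 with exactly one open-ended terminal class, and that dispersal
#' parameters are present for age-1 animals.
#'
#' @param rates A vital-rate table as returned by [moose_vital_rates()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_vital_rates <- function(rates) {
  need <- c(
    "sex", "age_from", "age_to", "winter_survival", "birth_rate",
    "summer_survival"
  )
  miss <- setdiff(need, names(rates))
  if (length(miss) > 0) {
    abort(paste0("vital-rate table is missing columns: ", paste(miss, collapse = ", ")))
  }
  probs <- c(rates$winter_survival, rates$summer_survival, rates$birth_rate)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    abort("all survival and birth rates must be probabilities in [0, 1]")
  }
  if (any(rates$birth_rate[rates$sex == "M"] != 0)) {
    abort("males must have birth_rate 0")
  }
  for (s in unique(rates$sex)) {
    r <- rates[rates$sex == s, ]
    r <- r[order(r$age_from), ]
    if (r$age_from[1] != 0) abort(sprintf("sex %s: age coverage must start at 0", s))
    if (sum(is.na(r$age_to)) != 1 || !is.na(r$age_to[nrow(r)])) {
      abort(sprintf("sex %s: need exactly one open-ended terminal class (age_to = NA)", s))
    }
    closed <- r[-nrow(r), ]
    if (nrow(closed) > 0) {
      if (any(closed$age_to < closed$age_from)) {
        abort(sprintf("sex %s: age_to < age_from", s))
      }
      nxt <- c(closed$age_to + 1)
      if (any(nxt != r$age_from[-1])) {
        abort(sprintf("sex %s: age classes must be contiguous", s))
      }
    }
  }
  invisible(rates)
}

# Expand a class table into per-age vectors for one sex. Ages above the
# terminal class reuse its (constant) rates.
rate_vectors <- function(rates, sex, max_age = NULL) {
  r <- rates[rates$sex == sex, ]
  r <- r[order(r$age_from), ]
  terminal <- r$age_from[nrow(r)]
  if (is.null(max_age)) max_age <- terminal
  idx <- findInterval(0:max_age, r$age_from)
  list(
    age = 0:max_age,
    winter = r$winter_survival[idx],
    summer = r$summer_survival[idx],
    birth = r$birth_rate[idx],
    terminal_age = terminal
  )
}

# Per-individual rate lookup used by the simulator (vectorised over age).
rate_at <- function(rates, sex, age, what = c("winter", "summer", "birth")) {
  what <- match.arg(what)
  out <- numeric(length(age))
  for (s in unique(sex)) {
    v <- rate_vectors(rates, s)
    a <- pmin(age[sex == s], v$terminal_age)
    out[sex == s] <- switch(what,
      winter = v$winter[a + 1],
      summer = v$summer[a + 1],
      birth = v$birth[a + 1]
    )
  }
  out
}

#' Regenerate senescent survival rates by odds scaling
#'
#' Old-age survival can be derived from the prime-age rate by increasing the
#' odds of mortality by a constant factor for every year past a base age:
#' \deqn{s' = s / (s + (1 - s) \cdot f^{(a - a_0)})}
#' with default factor \eqn{f = 1.6} per year after \eqn{a_0 = 9} years. The
#' default table already embeds this schedule (to printed precision); this
#' utility exists to validate a table or extend one that lacks senescent
#' classes. Birth rates are untouched.
#'
#' @param rates A vital-rate table.
#' @param base_odds_age Last prime age; survival declines for ages above it.
#' @param odds_factor Yearly multiplicative increase in mortality odds.
#' @return A vital-rate table with winter and summer survival of classes
#'   above `base_odds_age` recomputed from the rate at `base_odds_age`.
#' @examples
#' s <- senescence_schedule(moose_vital_rates())
#' # age-10 female winter survival 0.93/(0.93 + 0.07*1.6) = 0.8925 ~ 0.89
#' @export
senescence_schedule <- function(rates, base_odds_age = 9, odds_factor = 1.6) {
  if (!is.numeric(odds_factor) || odds_factor <= 0) {
    abort("odds_factor must be a positive number")
  }
  scale_s <- function(s, age) {
    k <- pmax(age - base_odds_age, 0)
    ifelse(k == 0, s, s / (s + (1 - s) * odds_factor^k))
  }
  out <- rates
  for (i in seq_len(nrow(out))) {
    a <- out$age_from[i]
    if (a <= base_odds_age) next
    # prime rate = rate of the class containing base_odds_age
    prime <- out[out$sex == out$sex[i] &
      out$age_from <= base_odds_age &
      (!is.na(out$age_to) & out$age_to >= base_odds_age), , drop = FALSE]
    if (nrow(prime) == 0) next
    out$winter_survival[i] <- scale_s(prime$winter_survival[1], a)
    out$summer_survival[i] <- scale_s(prime$summer_survival[1], a)
  }
  out
}

#' Female annual projection matrix
#'
#' Builds the female-only Leslie matrix implied by the vital-rate table and
#' the simulator's annual event order (December census, winter survival, May
#' birth pulse at the mother's census age, aging, summer survival at the new
#' age). Survival transitions are therefore
#' `winter_survival(a) * summer_survival(a + 1)` with a terminal self-loop,
#' and fertilities are
#' `winter_survival(a) * birth_rate(a) * calf_sex_ratio * summer_survival(0)`
#' (the calf must survive its first summer to be counted at the next census).
#'
#' @param rates A vital-rate table.
#' @param calf_sex_ratio Proportion of calves that are female (default 0.5).
#' @return A square nonnegative matrix; rows/columns are census ages 0 up to
#'   the terminal pooled class.
#' @examples
#' A <- build_projection_matrix(moose_vital_rates())
#' lambda_asymptotic(A)
#' @export
build_projection_matrix <- function(rates, calf_sex_ratio = 0.5) {
  validate_vital_rates(rates)
  v <- rate_vectors(rates, "F")
  n <- v$terminal_age + 1
  if (length(v$winter) != n) abort("female rates must cover ages 0..terminal")
  A <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    A[a + 1, a] <- v$winter[a] * v$summer[a + 1]
  }
  A[n, n] <- v$winter[n] * v$summer[n]
  A[1, ] <- v$winter * v$birth * calf_sex_ratio * v$summer[1]
  dimnames(A) <- list(paste0("age", 0:(n - 1)), paste0("age", 0:(n - 1)))
  A
}

#' Asymptotic annual growth rate of a projection matrix
#'
#' @param A A projection matrix, or a vital-rate table (in which case the
#'   matrix is built first with [build_projection_matrix()]).
#' @return The dominant eigenvalue (a real number for a nonnegative matrix).
#' @export
lambda_asymptotic <- function(A) {
  if (is.data.frame(A)) A <- build_projection_matrix(A)
  ev <- eigen(A, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8 | Mod(ev) == max(Mod(ev))]))
}

#' Starting age structure of the default population
#'
#' Expands the `n_start` column of a vital-rate table into one row per
#' (sex, age) pair. Counts in pooled multi-age classes are spread across the
#' member ages as evenly as possible (largest-remainder rounding), youngest
#' ages first; the open-ended terminal class keeps all its animals at its
#' first age.
#'
#' @param rates A vital-rate table with an `n_start` column.
#' @return A tibble with columns `sex`, `age`, `n`.
#' @export
starting_age_structure <- function(rates) {
  if (!"n_start" %in% names(rates)) abort("rates table has no n_start column")
  rows <- purrr::pmap(
    list(rates$sex, rates$age_from, rates$age_to, rates$n_start),
    function(sex, a0, a1, n) {
      if (is.na(a1)) a1 <- a0 # terminal class: keep at first age
      ages <- a0:a1
      k <- length(ages)
      base <- floor(n / k)
      n_each <- rep(base, k)
      rem <- n - base * k
      if (rem > 0) n_each[seq_len(rem)] <- n_each[seq_len(rem)] + 1
      tibble(sex = sex, age = ages, n = n_each)
    }
  )
  bind_rows(rows)
}
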