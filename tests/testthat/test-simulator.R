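test_that("initialization reproduces the shipped age structure", {
  state <- initialize_population(seed = 2)
  inds <- state$inds
  expect_equal(nrow(inds), 659)
  expect_equal(sum(inds$sex == "F" & inds$age == 0), 72)
  expect_equal(sum(inds$sex == "M" & inds$age == 0), 72)
  expect_equal(sum(inds$sex == "F" & inds$age >= 3 & inds$age <= 9), 180)
  expect_equal(sum(inds$sex == "M" & inds$age >= 13), 1)
  expect_true(all(is.na(inds$mother_id)))
  # centroids inside the study area
  area <- state$area
  expect_true(all(inds$cx >= 0 & inds$cx <= area$width))
  expect_true(all(inds$cy >= 0 & inds$cy <= area$height))
})

test_that("initialization scales, errors, and reproduces deterministically", {
  s100 <- initialize_population(n0 = 100, seed = 1)
  expect_equal(nrow(s100$inds), 100)
  expect_error(initialize_population(n0 = 0), "at least 1")
  expect_error(
    initialize_population(
      n0 = 10,
      age_structure = tibble::tibble(sex = "F", age = 2, n = 5)
    ),
    "sum to n0"
  )
  a <- initialize_population(n0 = 50, seed = 9)
  b <- initialize_population(n0 = 50, seed = 9)
  expect_identical(a$inds$cx, b$inds$cx)
  expect_identical(a$inds$hull_a, b$inds$hull_a)
})

test_that("degenerate vital rates drive the step as expected", {
  rates <- moose_vital_rates()
  immortal <- rates
  immortal$winter_survival <- 1
  immortal$summer_survival <- 1
  immortal$birth_rate <- 0
  state <- initialize_population(immortal, n0 = 80, seed = 4)
  ages0 <- state$inds$age
  nxt <- step_year(state, immortal, seed = 4)
  expect_equal(sum(nxt$inds$alive), 80)
  expect_equal(nxt$inds$age, ages0 + 1L)

  doomed <- rates
  doomed$winter_survival <- 0
  nxt2 <- step_year(state, doomed, seed = 4)
  expect_equal(sum(nxt2$inds$alive), 0)
  expect_true(all(nxt2$inds$death_year == 1))
})

test_that("the annual cycle conserves individuals and ages monotonically", {
  sim <- small_sim()
  ct <- tidy(sim)
  for (i in 2:nrow(ct)) {
    expect_equal(
      ct$n_alive[i],
      ct$n_alive[i - 1] - ct$winter_deaths[i] - ct$summer_deaths[i] + ct$births[i]
    )
  }
  inds <- sim$state$inds
  # dead stay dead, and death never precedes birth
  expect_true(all(is.na(inds$death_year) | inds$death_year >= inds$birth_year))
  # every non-founder has both parents recorded
  nonf <- inds[inds$birth_year > 0, ]
  expect_true(all(!is.na(nonf$mother_id) & !is.na(nonf$father_id)))
  # the recorded pedigree is acyclic and sex-consistent
  expect_silent(validate_pedigree(sim_pedigree(sim)))
  # mothers are female and were old enough to breed at the birth pulse
  mo <- inds[match(nonf$mother_id, inds$id), ]
  expect_true(all(mo$sex == "F"))
  expect_true(all(nonf$birth_year - mo$birth_year >= 2))
  # fathers are male and older than 3 at the previous census
  fa <- inds[match(nonf$father_id, inds$id), ]
  expect_true(all(fa$sex == "M"))
  expect_true(all(nonf$birth_year - 1 - fa$birth_year > 3))
})

test_that("realized survival respects exact binomial envelopes", {
  rates <- moose_vital_rates()
  flat <- rates
  flat$winter_survival <- 0.8
  flat$summer_survival <- 1
  flat$birth_rate <- 0
  state <- initialize_population(flat, n0 = 300, seed = 6)
  inside <- 0
  n_steps <- 100
  lo <- qbinom(0.0005, 300, 0.8)
  hi <- qbinom(0.9995, 300, 0.8)
  for (r in seq_len(n_steps)) {
    nxt <- step_year(state, flat, seed = r)
    surv <- sum(nxt$inds$alive)
    inside <- inside + (surv >= lo && surv <= hi)
  }
  expect_gte(inside / n_steps, 0.97)
})

test_that("identical seeds give bit-identical trajectories", {
  a <- simulate_population(years = 4, n0 = 120, seed = 17)
  b <- simulate_population(years = 4, n0 = 120, seed = 17)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$state$inds$id, b$state$inds$id)
  expect_identical(a$state$inds$cx, b$state$inds$cx)
  c <- simulate_population(years = 4, n0 = 120, seed = 18)
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("the realized long-run growth rate matches the projection matrix", {
  lams <- vapply(1:6, function(s) {
    sim <- simulate_population(years = 12, n0 = 400, seed = 100 + s)
    glance(sim)$lambda_realized
  }, numeric(1))
  # asymptotic lambda of the default schedule is ~1.01; demographic
  # stochasticity and occasional cancelled births keep replicate means in a
  # band around it
  expect_gt(mean(lams), 0.985)
  expect_lt(mean(lams), 1.025)
})

test_that("mate assignment is uniform among overlapping candidates", {
  # hand-built state: one mother, two overlapping males, one far male
  p <- hr_params()
  mk <- function(id, sex, age, x, y, seed) {
    h <- generate_home_range(x, y, sex, p, seed = seed)
    tibble::tibble(
      id = id, sex = sex, age = age, mother_id = NA_integer_,
      father_id = NA_integer_, alive = TRUE, birth_year = -age,
      death_year = NA_integer_, cx = x, cy = y,
      hull_a = list(h$hull_annual), r_a = h$r_annual,
      cloud_w = list(h$cloud_winter), hull_w = list(h$hull_winter),
      r_w = h$r_winter, in_area = TRUE
    )
  }
  inds <- dplyr::bind_rows(
    mk(1L, "F", 5L, 10, 10, 1),
    mk(2L, "M", 6L, 11, 10, 2),
    mk(3L, "M", 7L, 9, 10, 3),
    mk(4L, "M", 9L, 45, 40, 4),
    mk(5L, "M", 2L, 10, 10, 5) # too young
  )
  state <- structure(
    list(year = 0L, inds = inds, area = make_study_area(), hr = p),
    class = "pop_state"
  )
  picks <- replicate(4000, assign_mate(state, 1L))
  expect_setequal(unique(picks), c(2L, 3L))
  expect_equal(mean(picks == 2L), 0.5, tolerance = 0.04)
  # exactly one candidate: always chosen
  solo <- structure(
    list(
      year = 0L, inds = inds[inds$id %in% c(1L, 2L), ],
      area = make_study_area(), hr = p
    ),
    class = "pop_state"
  )
  expect_equal(unique(replicate(20, assign_mate(solo, 1L))), 2L)
  # no candidate at all
  none <- structure(
    list(
      year = 0L, inds = inds[inds$id %in% c(1L, 4L), ],
      area = make_study_area(), hr = p
    ),
    class = "pop_state"
  )
  expect_true(is.na(assign_mate(none, 1L)))
})
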