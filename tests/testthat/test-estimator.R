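test_that("the six-adult worked example classifies into (2, 1, 1)", {
  counts <- classify_adults(toy_pedigree(), census_year = 10)
  expect_equal(counts$n_linked, 2L)
  expect_equal(counts$n_unlinked, 1L)
  expect_equal(counts$n_inferred, 1L)
})

test_that("degenerate sampling patterns classify as expected", {
  ped <- toy_pedigree()
  # everyone sampled: every adult with a sampled offspring (and sampled
  # mate) is linked; adults without offspring are unlinked
  all_s <- set_sampled(ped, ped$id)
  counts <- classify_adults(all_s, 10)
  expect_equal(counts$n_inferred, 0L)
  expect_equal(counts$n_linked, 3L) # both calves' parent pairs
  expect_equal(counts$n_unlinked, 3L)
  # nobody sampled
  none <- ped
  none$sampled <- FALSE
  none$sample_year <- NA_integer_
  counts0 <- classify_adults(none, 10)
  expect_equal(unlist(counts0[, 1:3], use.names = FALSE), c(0L, 0L, 0L))
})

test_that("classification matches the brute-force definition on enumerated populations", {
  ped <- toy_pedigree()
  ids <- ped$id
  for (pattern in 0:(2^length(ids) - 1)) {
    sel <- ids[bitwAnd(pattern, 2^(seq_along(ids) - 1)) > 0]
    p <- set_sampled(
      transform(ped, sampled = FALSE, sample_year = NA_integer_), sel
    )
    got <- classify_adults(p, 10)
    want <- brute_classify(p, 10)
    expect_equal(
      c(got$n_linked, got$n_unlinked, got$n_inferred),
      unname(want),
      info = paste("pattern", pattern)
    )
  }
})

test_that("classification matches brute force on random pedigrees", {
  set.seed(42)
  for (r in 1:60) {
    ped <- random_pedigree()
    sel <- sample(ped$id, sample(0:nrow(ped), 1))
    p <- set_sampled(ped, sel)
    # randomly mark some as known dead
    p$known_dead <- runif(nrow(p)) < 0.2
    got <- classify_adults(p, 10)
    want <- brute_classify(p, 10)
    expect_equal(c(got$n_linked, got$n_unlinked, got$n_inferred), unname(want))
  }
})

test_that("outputs are invariant to relabelling individual ids", {
  ped <- toy_pedigree()
  relab <- ped
  map <- setNames(c(105L, 3L, 99L, 42L, 7L, 88L, 12L, 54L), ped$id)
  relab$id <- unname(map[as.character(ped$id)])
  relab$sire <- unname(map[as.character(ped$sire)])
  relab$dam <- unname(map[as.character(ped$dam)])
  a <- classify_adults(ped, 10)
  b <- classify_adults(relab, 10)
  expect_equal(a$n_linked, b$n_linked)
  expect_equal(a$n_unlinked, b$n_unlinked)
  expect_equal(a$n_inferred, b$n_inferred)
})

test_that("marginal probabilities are conditional proportions", {
  m <- estimate_marginals(segment_counts(60, 20, 20))
  expect_equal(m$p_sampled, 0.75)
  expect_equal(m$p_matched, 0.75)
  m1 <- estimate_marginals(segment_counts(10, 0, 0))
  expect_equal(m1$p_sampled, 1)
  expect_equal(m1$p_matched, 1)
  expect_error(
    estimate_marginals(segment_counts(0, 5, 5)),
    class = "pedrecon_undefined"
  )
})

test_that("the joint-probability estimate matches hand arithmetic", {
  est <- estimate_abundance(segment_counts(60, 20, 20))
  expect_equal(est$n_hat, 100 / 0.9375, tolerance = 1e-12)
  expect_equal(est$n_invisible_hat, 100 / 0.9375 - 100, tolerance = 1e-12)
  # saturated sampling: estimate equals the observed count
  estL <- estimate_abundance(segment_counts(500, 0, 0))
  expect_equal(estL$n_hat, 500)
  expect_equal(estL$n_invisible_hat, 0)
  # the estimate can never fall below what was observed
  set.seed(7)
  for (r in 1:50) {
    cnt <- segment_counts(sample(1:50, 1), sample(0:30, 1), sample(0:30, 1))
    e <- estimate_abundance(cnt)
    expect_gte(e$n_hat, cnt$n_linked + cnt$n_unlinked + cnt$n_inferred)
  }
})

test_that("the estimator recovers truth under the independence model", {
  # Monte-Carlo oracle: N adults, independent Bernoulli sampling and
  # matching; the mean estimate must be within 1% of N.
  set.seed(123)
  N <- 500
  reps <- 2000
  n_hats <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- rbinom(N, 1, 0.6) == 1
    m <- rbinom(N, 1, 0.5) == 1
    est <- estimate_abundance(
      segment_counts(sum(s & m), sum(s & !m), sum(!s & m))
    )
    n_hats[r] <- est$n_hat
  }
  expect_lt(abs(mean(n_hats) - N) / N, 0.01)
})

test_that("bootstrap intervals are reproducible and self-consistent", {
  cnt <- segment_counts(60, 20, 20)
  b1 <- bootstrap_interval(cnt, n_boot = 2000, seed = 11)
  b2 <- bootstrap_interval(cnt, n_boot = 2000, seed = 11)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  b3 <- bootstrap_interval(cnt, n_boot = 2000, seed = 12)
  expect_false(identical(b1$ci_low, b3$ci_low))

  big <- bootstrap_interval(cnt, n_boot = 50000, seed = 5)
  expect_lt(abs(median(attr(big, "boot")) - big$n_hat) / big$n_hat, 0.01)
  expect_lt(big$ci_low, big$n_hat)
  expect_gt(big$ci_high, big$n_hat)

  # posterior concentration: relative width shrinks as the saturated
  # sample grows
  w <- vapply(c(50, 500), function(L) {
    b <- bootstrap_interval(segment_counts(L, 0, 0), n_boot = 2000, seed = 1)
    (b$ci_high - b$ci_low) / b$n_hat
  }, numeric(1))
  expect_lt(w[2], w[1])
  expect_lt(w[2], 0.01)

  expect_error(bootstrap_interval(cnt, prior = list(alpha0 = -1, beta0 = 1)))
  expect_error(bootstrap_interval(cnt, n_boot = 10))
})

test_that("bootstrap intervals attain near-nominal coverage under the independence model", {
  set.seed(99)
  N <- 500
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    s <- rbinom(N, 1, 0.6) == 1
    m <- rbinom(N, 1, 0.6) == 1
    cnt <- segment_counts(sum(s & m), sum(s & !m), sum(!s & m))
    b <- bootstrap_interval(cnt, n_boot = 2000, seed = r)
    hits <- hits + (b$ci_low <= N && N <= b$ci_high)
  }
  expect_gte(hits / reps, 0.93)
})

test_that("growth rates are ratios of successive estimates", {
  expect_equal(growth_rate(c(100, 103)), 1.03)
  expect_equal(growth_rate(rep(55, 4)), rep(1, 3))
  expect_equal(growth_rate(c(106.67, 96.0, 105.6)), c(0.9000, 1.1000),
    tolerance = 1e-4
  )
  expect_error(growth_rate(100), "two consecutive")
  expect_error(growth_rate(c(0, 10)), "zero")
  df <- tibble::tibble(census_year = c(2, 1), n_hat = c(103, 100))
  out <- growth_rate(df)
  expect_equal(out$lambda, 1.03)
  expect_equal(out$year_from, 1)
})

test_that("pedigree validation catches structural errors", {
  ped <- toy_pedigree()
  dup <- ped
  dup$id[2] <- dup$id[1]
  expect_error(as_pedigree(dup), "unique")
  cyc <- tibble::tibble(
    id = 1:2, sire = c(2, 1), dam = NA_integer_,
    sex = "M", birth_year = 0L, sampled = FALSE,
    sample_year = NA_integer_, known_dead = FALSE
  )
  expect_error(as_pedigree(cyc), "cycle|sire and dam|ancestor")
  bad_sex <- ped
  bad_sex$sex[1] <- "F" # id 1 is a sire
  expect_error(as_pedigree(bad_sex), "sex-of-parent")
  both <- ped
  both$sire[8] <- 2 # id 2 is a dam elsewhere
  expect_error(as_pedigree(both), "both sire and dam")
  missing_year <- ped
  missing_year$sample_year[1] <- NA
  expect_error(as_pedigree(missing_year), "sample_year")
})

test_that("tidy and glance return the estimate in broom shape", {
  b <- bootstrap_interval(segment_counts(60, 20, 20), n_boot = 2000, seed = 1)
  td <- tidy(b)
  expect_setequal(
    td$term,
    c("n_hat", "n_invisible_hat", "p_sampled", "p_matched")
  )
  expect_equal(td$estimate[td$term == "n_hat"], b$n_hat)
  gl <- glance(b)
  expect_equal(nrow(gl), 1)
  expect_false(inherits(gl, "abundance_estimate"))
})
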