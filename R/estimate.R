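#' Segment counts: the estimator's sufficient statistic
#'
#' An adult population seen through a reconstructed pedigree splits into four
#' segments: *linked* (sampled, matched by a parent-offspring relationship to
#' at least one sampled offspring), *unlinked* (sampled, no sampled
#' offspring), *inferred* (unsampled, but revealed because a mate and a
#' shared offspring were both sampled), and *invisible* (unsampled and
#' unmatched, estimable only probabilistically). The observed triple of
#' linked/unlinked/inferred counts is all the estimator needs.
#'
#' @param n_linked,n_unlinked,n_inferred Nonnegative counts of live adults in
#'   each observed segment.
#' @param census_year Optional census year the counts refer to.
#' @return A one-row tibble of class `segment_counts`.
#' @examples
#' segment_counts(60, 20, 20)
#' @export
segment_counts <- function(n_linked, n_unlinked, n_inferred, census_year = NA_integer_) {
  counts <- c(n_linked, n_unlinked, n_inferred)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("segment counts must be nonnegative integers")
  }
  out <- tibble(
    n_linked = as.integer(n_linked),
    n_unlinked = as.integer(n_unlinked),
    n_inferred = as.integer(n_inferred),
    census_year = as.integer(census_year)
  )
  class(out) <- c("segment_counts", class(out))
  out
}

#' Classify adults into pedigree segments
#'
#' Assigns every adult in a pedigree (age at census at or above the adult
#' threshold, and not known dead) to exactly one of the linked, unlinked, or
#' inferred segments; unsampled adults with no sampled offspring are
#' invisible and are never counted. Offspring of any age (including calves)
#' establish matches, but only adults enter the counts. Samples accumulate:
#' an individual counts as sampled at census year `t` if its sample year is
#' at most `t`. Individuals with an unknown birth year are treated as adults
#' when they are a recorded parent (a successful breeder is mature by
#' definition).
#'
#' @param pedigree A pedigree table (coerced with [as_pedigree()]).
#' @param census_year The census year at which adults are counted.
#' @param adult_age_threshold Minimum age in years, at the December census,
#'   for an individual to count as an adult (default 2).
#' @return A `segment_counts` row. The number of adults evaluated (observed
#'   or not) is not returned: the invisible segment is an estimate, not a
#'   count.
#' @examples
#' ped <- tibble::tibble(
#'   id = 1:4, sire = c(NA, NA, 1, NA), dam = c(NA, NA, 2, NA),
#'   sex = c("M", "F", "F", "M"), birth_year = c(1, 1, 9, 2),
#'   sampled = c(TRUE, FALSE, TRUE, FALSE),
#'   sample_year = c(10L, NA, 10L, NA)
#' )
#' classify_adults(ped, census_year = 10)
#' @export
classify_adults <- function(pedigree, census_year, adult_age_threshold = 2) {
  ped <- as_pedigree(pedigree)
  if (!is.na(census_year) && any(!is.na(ped$birth_year)) &&
    census_year < min(ped$birth_year, na.rm = TRUE)) {
    abort("census_year precedes every birth year in the pedigree")
  }
  sampled_now <- ped$sampled & !is.na(ped$sample_year) & ped$sample_year <= census_year
  sampled_ids <- ped$id[sampled_now]

  off <- ped[sampled_now, c("id", "sire", "dam")]
  matched <- unique(c(off$sire, off$dam))
  matched <- matched[!is.na(matched)]
  sire_sampled <- off$sire %in% sampled_ids
  dam_sampled <- off$dam %in% sampled_ids
  inferred_ids <- unique(c(
    off$sire[!is.na(off$sire) & dam_sampled],
    off$dam[!is.na(off$dam) & sire_sampled]
  ))

  age <- census_year - ped$birth_year
  is_parent <- ped$id %in% unique(c(ped$sire, ped$dam))
  adult <- !ped$known_dead &
    ((!is.na(age) & age >= adult_age_threshold) | (is.na(age) & is_parent))

  n_linked <- sum(adult & sampled_now & ped$id %in% matched)
  n_unlinked <- sum(adult & sampled_now & !(ped$id %in% matched))
  n_inferred <- sum(adult & !sampled_now & ped$id %in% inferred_ids)
  segment_counts(n_linked, n_unlinked, n_inferred, census_year)
}

#' Marginal sampling and matching probabilities
#'
#' Within the matched adults, the proportion that were sampled estimates the
#' marginal probability of being sampled; within the sampled adults, the
#' proportion that were matched estimates the marginal probability of being
#' matched:
#' \deqn{\hat p_{sampled} = L / (L + I), \qquad \hat p_{matched} = L / (L + U)}
#' with \eqn{L, U, I} the linked, unlinked, and inferred counts. Both rely on
#' the assumption that sampling and matching are independent.
#'
#' @param counts A `segment_counts` row (or anything accepted by
#'   [segment_counts()] column-wise).
#' @return A one-row tibble with `p_sampled` and `p_matched`.
#' @examples
#' estimate_marginals(segment_counts(60, 20, 20)) # 0.75, 0.75
#' @export
estimate_marginals <- function(counts) {
  L <- counts$n_linked
  U <- counts$n_unlinked
  I <- counts$n_inferred
  if (L == 0) {
    abort("marginals undefined: no linked adults in the pedigree",
      class = "pedrecon_undefined"
    )
  }
  if (L + I == 0) {
    abort("p_sampled undefined: no linked or inferred adults (matched segment empty)",
      class = "pedrecon_undefined"
    )
  }
  if (L + U == 0) {
    abort("p_matched undefined: no linked or unlinked adults (sampled segment empty)",
      class = "pedrecon_undefined"
    )
  }
  tibble(p_sampled = L / (L + I), p_matched = L / (L + U))
}

#' Point estimate of adult abundance
#'
#' An adult is observed by pedigree reconstruction if it is sampled, matched,
#' or both; under independence the probability of being observed is
#' \deqn{1 - (1 - p_{sampled})(1 - p_{matched}).}
#' Dividing the observed count \eqn{N_{obs} = L + U + I} by this joint
#' probability (the capture-probability logic of mark-recapture estimators)
#' yields the adult population estimate; the excess over \eqn{N_{obs}} is the
#' estimated invisible segment.
#'
#' @inheritParams estimate_marginals
#' @return A one-row tibble of class `abundance_estimate` with the segment
#'   counts, the marginals, `n_obs`, `n_hat`, and `n_invisible_hat`.
#'   Interval columns are `NA` until filled by [bootstrap_interval()].
#' @examples
#' estimate_abundance(segment_counts(60, 20, 20)) # n_hat = 106.67
#' @export
estimate_abundance <- function(counts) {
  m <- estimate_marginals(counts)
  n_obs <- counts$n_linked + counts$n_unlinked + counts$n_inferred
  p_joint <- 1 - (1 - m$p_sampled) * (1 - m$p_matched)
  n_hat <- n_obs / p_joint
  out <- tibble(
    census_year = counts$census_year,
    n_linked = counts$n_linked,
    n_unlinked = counts$n_unlinked,
    n_inferred = counts$n_inferred,
    n_obs = n_obs,
    p_sampled = m$p_sampled,
    p_matched = m$p_matched,
    n_hat = n_hat,
    n_invisible_hat = n_hat - n_obs,
    ci_low = NA_real_,
    ci_high = NA_real_,
    ci_level = NA_real_,
    n_boot = NA_integer_,
    seed = NA_integer_
  )
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' Beta prior on the marginal probabilities
#'
#' @param alpha0,beta0 Positive shape parameters; the default `(1, 1)` is the
#'   uniform (vague) prior.
#' @return A list of class `beta_prior`.
#' @export
beta_prior <- function(alpha0 = 1, beta0 = 1) {
  if (!is.numeric(alpha0) || !is.numeric(beta0) ||
    length(alpha0) != 1 || length(beta0) != 1 ||
    !is.finite(alpha0) || !is.finite(beta0) || alpha0 <= 0 || beta0 <= 0) {
    abort("beta prior parameters must be positive finite numbers")
  }
  structure(list(alpha0 = alpha0, beta0 = beta0), class = "beta_prior")
}

#' Beta-posterior bootstrap confidence interval for adult abundance
#'
#' The observed segment counts update a vague beta prior to posteriors on the
#' two marginal probabilities:
#' \deqn{p_{sampled} \sim Beta(\alpha_0 + L,\; \beta_0 + I), \qquad
#'       p_{matched} \sim Beta(\alpha_0 + L,\; \beta_0 + U).}
#' Each bootstrap trial draws the two marginals independently and multiplies
#' them into a joint observation probability. By default
#' (`resample_counts = TRUE`) the trial then replays the whole observation
#' process: the point-estimate population is partitioned by a multinomial
#' draw at the trial's marginals into linked/unlinked/inferred/invisible
#' segments, and the estimator is re-applied to the resampled counts. This
#' propagates both the uncertainty in the marginals and the sampling noise
#' of the observed count, and attains nominal frequentist coverage under the
#' independence model. `resample_counts = FALSE` gives the narrower
#' probability-scale-only interval (`n_obs` divided by each trial's joint
#' probability), which ignores observation noise and undercovers.
#' The percentile interval of the trials at `ci_level` is reported.
#'
#' @inheritParams estimate_marginals
#' @param prior A [beta_prior()]; default uniform.
#' @param n_boot Number of bootstrap trials (at least 1000; default 10000).
#' @param ci_level Interval coverage level (default 0.95, giving the 2.5 and
#'   97.5 percentiles).
#' @param seed Integer seed; the same seed reproduces the same interval.
#' @param resample_counts Replay the observation process in each trial
#'   (default `TRUE`); see Details.
#' @return An `abundance_estimate` row with interval columns filled. The
#'   bootstrap sample of population estimates is attached as attribute
#'   `"boot"`.
#' @examples
#' bootstrap_interval(segment_counts(60, 20, 20), seed = 1)
#' @export
bootstrap_interval <- function(counts, prior = beta_prior(), n_boot = 10000,
                               ci_level = 0.95, seed = 1L,
                               resample_counts = TRUE) {
  if (!inherits(prior, "beta_prior")) prior <- do.call(beta_prior, as.list(prior))
  if (n_boot < 1000) abort("n_boot must be at least 1000")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("ci_level must be in (0, 1)")
  }
  est <- estimate_abundance(counts)
  L <- counts$n_linked
  U <- counts$n_unlinked
  I <- counts$n_inferred
  n_obs <- L + U + I
  draws <- with_seed(seed, {
    ps <- rbeta(n_boot, prior$alpha0 + L, prior$beta0 + I)
    pm <- rbeta(n_boot, prior$alpha0 + L, prior$beta0 + U)
    if (!resample_counts) {
      n_obs / (1 - (1 - ps) * (1 - pm))
    } else {
      nh <- round(est$n_hat)
      # sequential binomial composition of the 4-cell multinomial
      p11 <- ps * pm
      p10 <- ps * (1 - pm)
      p01 <- (1 - ps) * pm
      Ls <- rbinom(n_boot, nh, p11)
      rem <- nh - Ls
      Us <- rbinom(n_boot, rem, pmin(1, p10 / pmax(1 - p11, 1e-12)))
      Is <- rbinom(n_boot, rem - Us, pmin(1, p01 / pmax(1 - p11 - p10, 1e-12)))
      # trials with no linked adults are undefined for the estimator,
      # exactly as in the real pipeline; they are dropped from the
      # percentile computation
      ok <- Ls > 0
      if (!any(ok)) {
        n_obs / (1 - (1 - ps) * (1 - pm))
      } else {
        ps2 <- Ls[ok] / (Ls[ok] + Is[ok])
        pm2 <- Ls[ok] / (Ls[ok] + Us[ok])
        (Ls[ok] + Us[ok] + Is[ok]) / (1 - (1 - ps2) * (1 - pm2))
      }
    }
  })
  alpha <- (1 - ci_level) / 2
  ci <- unname(quantile(draws, c(alpha, 1 - alpha)))
  est$ci_low <- ci[1]
  est$ci_high <- ci[2]
  est$ci_level <- ci_level
  est$n_boot <- as.integer(n_boot)
  est$seed <- as.integer(seed)
  attr(est, "boot") <- draws
  est
}

#' Annual growth rates from successive abundance estimates
#'
#' The estimated growth rate over each interval is the ratio of successive
#' abundance values, \eqn{\hat\lambda_t = \hat N_{t+1} / \hat N_t}.
#'
#' @param estimates Either a numeric vector of abundance values in year
#'   order, or a data frame with an `n_hat` column (ordered by `census_year`
#'   when present).
#' @return For numeric input, a numeric vector one shorter than the input;
#'   for a data frame, a tibble with `year_from`, `year_to`, `lambda`.
#' @examples
#' growth_rate(c(100, 103)) # 1.03
#' @export
growth_rate <- function(estimates) {
  if (is.data.frame(estimates)) {
    df <- estimates
    if (!"n_hat" %in% names(df)) abort("data frame input needs an n_hat column")
    if ("census_year" %in% names(df)) df <- df[order(df$census_year), ]
    lam <- growth_rate(df$n_hat)
    yr <- if ("census_year" %in% names(df)) df$census_year else seq_len(nrow(df))
    return(tibble(year_from = yr[-length(yr)], year_to = yr[-1], lambda = lam))
  }
  x <- as.numeric(estimates)
  if (length(x) < 2) abort("need at least two consecutive annual estimates")
  if (any(x[-length(x)] == 0)) abort("growth rate undefined: zero abundance in series")
  x[-1] / x[-length(x)]
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf(
    "Pedigree-reconstruction abundance estimate%s\n",
    if (!is.na(x$census_year)) sprintf(" (census year %d)", x$census_year) else ""
  ))
  cat(sprintf(
    "  segments: %d linked, %d unlinked, %d inferred (N_obs = %d)\n",
    x$n_linked, x$n_unlinked, x$n_inferred, x$n_obs
  ))
  cat(sprintf(
    "  p_sampled = %.3f, p_matched = %.3f\n", x$p_sampled, x$p_matched
  ))
  cat(sprintf(
    "  N_hat = %.1f (invisible: %.1f)\n", x$n_hat, x$n_invisible_hat
  ))
  if (!is.na(x$ci_level)) {
    cat(sprintf(
      "  %.0f%% bootstrap CI: [%.1f, %.1f] (%d trials, seed %d)\n",
      100 * x$ci_level, x$ci_low, x$ci_high, x$n_boot, x$seed
    ))
  }
  invisible(x)
}

#' Tidy an abundance estimate
#'
#' @param x An `abundance_estimate`.
#' @param ... Unused.
#' @return One row per estimated quantity with `term`, `estimate`, and (for
#'   `n_hat`, when a bootstrap interval is present) `conf.low`/`conf.high`.
#' @export
tidy.abundance_estimate <- function(x, ...) {
  tibble(
    term = c("n_hat", "n_invisible_hat", "p_sampled", "p_matched"),
    estimate = c(x$n_hat, x$n_invisible_hat, x$p_sampled, x$p_matched),
    conf.low = c(x$ci_low, NA, NA, NA),
    conf.high = c(x$ci_high, NA, NA, NA)
  )
}

#' One-row summary of an abundance estimate
#'
#' @param x An `abundance_estimate`.
#' @param ... Unused.
#' @return The underlying one-row tibble, without the bootstrap attribute.
#' @export
glance.abundance_estimate <- function(x, ...) {
  out <- x
  attr(out, "boot") <- NULL
  class(out) <- setdiff(class(out), "abundance_estimate")
  out
}

#' Plot the bootstrap distribution of an abundance estimate
#'
#' @param object An `abundance_estimate` produced by [bootstrap_interval()].
#' @param ... Unused.
#' @return A ggplot: histogram of bootstrap population estimates with the
#'   point estimate and percentile interval marked.
#' @export
autoplot.abundance_estimate <- function(object, ...) {
  draws <- attr(object, "boot")
  if (is.null(draws)) {
    abort("no bootstrap sample attached; run bootstrap_interval() first")
  }
  df <- tibble(n_hat = draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_hat)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$n_hat, colour = "black") +
    ggplot2::geom_vline(
      xintercept = c(object$ci_low, object$ci_high),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "bootstrap adult population estimate", y = "trials",
      title = sprintf(
        "N_hat = %.0f, %.0f%% CI [%.0f, %.0f]",
        object$n_hat, 100 * object$ci_level, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}
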