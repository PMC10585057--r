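#' Create an empty multi-year sampling record
#'
#' A sampling record accumulates, across years, which individuals have been
#' genetically sampled (each at most once — duplicate samples carry no new
#' pedigree information and are never recorded twice) and, for the spatial
#' design, in which grid cell. The set of grid cells already surveyed in
#' earlier years of the run is tracked so that new cells are sampled each
#' year.
#'
#' @return A tibble of class `sampling_record` with columns `id`, `year`,
#'   `cell` and an attribute `cells_drawn`.
#' @export
new_sampling_record <- function() {
  out <- tibble(id = integer(0), year = integer(0), cell = integer(0))
  attr(out, "cells_drawn") <- integer(0)
  class(out) <- c("sampling_record", class(out))
  out
}

record_add <- function(record, ids, year, cells = NA_integer_) {
  if (length(cells) == 1) cells <- rep(cells, length(ids))
  keep <- !(ids %in% record$id)
  ids <- ids[keep]
  cells <- cells[keep]
  if (length(ids) == 0) {
    return(record)
  }
  add <- tibble(
    id = as.integer(ids), year = as.integer(year), cell = as.integer(cells)
  )
  cd <- attr(record, "cells_drawn")
  out <- bind_rows(record, add)
  attr(out, "cells_drawn") <- cd
  class(out) <- unique(c("sampling_record", class(out)))
  out
}

#' Cow-calf joint sampling rule
#'
#' In winter scat surveys a cow and her dependent calf (under 1 year old)
#' travel together, so sampling either member of the pair samples both: for
#' every sampled female with an alive dependent calf the calf is added, and
#' for every sampled calf the alive mother is added.
#'
#' @param sampled_ids Integer ids drawn this year.
#' @param sim A `pop_sim` (or `pop_state`) giving mother-calf pairs.
#' @param year Census year (calves are animals born that year).
#' @return The augmented id vector.
#' @export
cow_calf_rule <- function(sampled_ids, sim, year) {
  inds <- if (inherits(sim, "pop_sim")) sim$state$inds else sim$inds
  alive <- if (inherits(sim, "pop_sim")) {
    alive_at(sim, year)
  } else {
    inds$alive
  }
  calf <- alive & inds$birth_year == year & !is.na(inds$mother_id)
  mother_alive <- inds$mother_id[calf] %in% inds$id[alive]
  pairs <- tibble(
    calf_id = inds$id[calf][mother_alive],
    mother_id = inds$mother_id[calf][mother_alive]
  )
  add_calves <- pairs$calf_id[pairs$mother_id %in% sampled_ids]
  add_mothers <- pairs$mother_id[pairs$calf_id %in% sampled_ids]
  unique(c(sampled_ids, add_calves, add_mothers))
}

#' Population-based annual sample
#'
#' Draws a simple random sample of a fixed fraction of the previously
#' unsampled animals alive in the study area at the December census
#' (demographic closure: sampling happens before the next winter's
#' mortality), then applies the cow-calf rule, which can push the realized
#' sample beyond the nominal fraction.
#'
#' @param sim A `pop_sim`.
#' @param year Census year to sample at.
#' @param fraction Fraction of previously unsampled eligible animals to draw
#'   (in (0, 1]); the nominal size rounds half-up.
#' @param record A `sampling_record` accumulated over earlier years.
#' @param seed Integer seed for this draw.
#' @return The updated `sampling_record`.
#' @export
population_sample <- function(sim, year, fraction, record = new_sampling_record(),
                              seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  inds <- sim$state$inds
  eligible <- inds$id[alive_at(sim, year) & inds$in_area]
  pool <- setdiff(eligible, record$id)
  n_draw <- min(length(pool), floor(fraction * length(pool) + 0.5))
  ids <- with_seed(derive_seed(seed, paste0("popsample", year)), {
    drawn <- if (n_draw > 0) sample(pool, n_draw) else integer(0)
    cow_calf_rule(drawn, sim, year)
  })
  record_add(record, ids, year)
}

#' Precompute the spatial sampling layer for a census
#'
#' For a given census the layer holds (a) the abundance-weighted cell map
#' (annual MCP counts scaled by the busiest cell) used to stratify cell
#' selection and (b) a detection table: for every alive animal, the grid
#' cells its *winter* MCP touches with the animal's scaled utilization
#' there, used as the per-cell Bernoulli detection probability.
#'
#' @param sim A `pop_sim`.
#' @param year Census year.
#' @param cells Optional restriction to a subset of grid cells (used by the
#'   density-zone experiment).
#' @return A list of class `spatial_layer` with `weights` and `detection`.
#' @export
spatial_layer <- function(sim, year, cells = NULL) {
  area <- sim$area
  inds <- sim$state$inds
  keep <- which(alive_at(sim, year))
  w <- cell_weights(inds$hull_a[keep], area)
  det <- purrr::map_dfr(keep, function(i) {
    u <- utilization(
      structure(
        list(
          cloud_winter = inds$cloud_w[[i]],
          hull_winter = inds$hull_w[[i]]
        ),
        class = "home_range"
      ),
      area
    )
    if (nrow(u) == 0) {
      return(NULL)
    }
    tibble(id = inds$id[i], cell = u$cell, u = u$u)
  })
  if (!is.null(cells)) {
    w <- w[w$cell %in% cells, ]
    det <- det[det$cell %in% cells, ]
  }
  structure(
    list(weights = w, detection = det, year = year, area = area),
    class = "spatial_layer"
  )
}

# Restrict a precomputed layer to a subset of grid cells (used by the
# density-zone experiment; selection probabilities are proportional, so no
# reweighting is needed).
restrict_layer <- function(layer, cells) {
  structure(
    list(
      weights = layer$weights[layer$weights$cell %in% cells, ],
      detection = layer$detection[layer$detection$cell %in% cells, ],
      year = layer$year, area = layer$area
    ),
    class = "spatial_layer"
  )
}

#' Spatially based annual sample
#'
#' Draws `n_cells` distinct grid cells without replacement with probability
#' proportional to the abundance weights (an all-zero weight map falls back
#' to a uniform draw, with a warning), excluding cells surveyed in earlier
#' years of the run. Every alive animal whose winter MCP touches a drawn
#' cell is then sampled by an independent Bernoulli trial with its scaled
#' utilization in that cell, unless already sampled. The cow-calf rule is
#' applied last.
#'
#' @param sim A `pop_sim`.
#' @param year Census year.
#' @param n_cells Number of 1 km^2 cells to survey.
#' @param layer A `spatial_layer` for this census (precompute once per year
#'   with [spatial_layer()]); built on the fly if missing.
#' @param record A `sampling_record`.
#' @param seed Integer seed.
#' @param exclude_prior_cells Exclude cells drawn in earlier years of this
#'   record (default `TRUE`).
#' @return The updated `sampling_record`.
#' @export
spatial_sample <- function(sim, year, n_cells, layer = NULL,
                           record = new_sampling_record(), seed = 1L,
                           exclude_prior_cells = TRUE) {
  if (is.null(layer)) layer <- spatial_layer(sim, year)
  w <- layer$weights
  if (exclude_prior_cells) {
    w <- w[!(w$cell %in% attr(record, "cells_drawn")), ]
  }
  if (n_cells > nrow(w)) n_cells <- nrow(w)
  if (n_cells == 0) {
    return(record)
  }
  res <- with_seed(derive_seed(seed, paste0("spatsample", year)), {
    prob <- w$weight
    if (all(prob == 0)) {
      warn("all cell weights are zero; falling back to a uniform cell draw")
      prob <- rep(1, nrow(w))
    }
    drawn <- sample(w$cell, n_cells, prob = prob)
    det <- layer$detection
    det <- det[det$cell %in% drawn & !(det$id %in% record$id), ]
    hit <- det[rbinom(nrow(det), 1, det$u) == 1, ]
    # an animal detected in several cells is recorded at its first cell
    hit <- hit[!duplicated(hit$id), ]
    ids <- cow_calf_rule(hit$id, sim, year)
    cells <- c(hit$cell, rep(NA_integer_, length(ids) - nrow(hit)))
    list(ids = ids, cells = cells, drawn = drawn)
  })
  out <- record_add(record, res$ids, year, res$cells)
  attr(out, "cells_drawn") <- union(attr(record, "cells_drawn"), res$drawn)
  out
}

#' Mark a sampling record on a pedigree
#'
#' Sets the `sampled`/`sample_year` columns of a pedigree from an
#' accumulated sampling record, producing the estimator's input.
#'
#' @param ped A `pedigree` (e.g. from [sim_pedigree()]).
#' @param record A `sampling_record`.
#' @return The pedigree with sampling flags applied.
#' @export
apply_record <- function(ped, record) {
  i <- match(record$id, ped$id)
  if (anyNA(i)) abort("sampling record refers to ids absent from the pedigree")
  ped$sampled[i] <- TRUE
  ped$sample_year[i] <- record$year
  ped
}
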