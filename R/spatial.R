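#' Rectangular study area with a 1 km^2 sampling grid
#'
#' The default emulates a 1650 km^2 management unit as a 50 x 33 km
#' rectangle in planar km coordinates with the origin at the lower-left
#' corner. Grid cells are half-open squares `[x, x+1) x [y, y+1)` indexed
#' row-major from the lower-left corner.
#'
#' @param width_km,height_km Rectangle dimensions in km.
#' @param cell_km Grid cell side length in km (default 1).
#' @param origin Lower-left corner coordinates.
#' @return A list of class `study_area` with the rectangle, the grid
#'   dimensions (`nx`, `ny`), and the total cell count.
#' @export
make_study_area <- function(width_km = 50, height_km = 33, cell_km = 1,
                            origin = c(0, 0)) {
  if (width_km <= 0 || height_km <= 0 || cell_km <= 0) {
    abort("study area dimensions and cell size must be positive")
  }
  nx <- ceiling(width_km / cell_km)
  ny <- ceiling(height_km / cell_km)
  structure(
    list(
      width = width_km, height = height_km, cell = cell_km,
      origin = origin, nx = nx, ny = ny, n_cells = nx * ny,
      area_km2 = width_km * height_km
    ),
    class = "study_area"
  )
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf(
    "Study area: %.0f x %.0f km (%.0f km^2), %d x %d grid of %.0f km^2 cells\n",
    x$width, x$height, x$area_km2, x$nx, x$ny, x$cell^2
  ))
  invisible(x)
}

# Cell index helpers: k = (row - 1) * nx + col, row-major from lower-left.
cell_center <- function(area, k) {
  row <- (k - 1) %/% area$nx + 1
  col <- (k - 1) %% area$nx + 1
  cbind(
    x = area$origin[1] + (col - 0.5) * area$cell,
    y = area$origin[2] + (row - 0.5) * area$cell
  )
}

cell_polygon <- function(area, k) {
  row <- (k - 1) %/% area$nx + 1
  col <- (k - 1) %% area$nx + 1
  x0 <- area$origin[1] + (col - 1) * area$cell
  y0 <- area$origin[2] + (row - 1) * area$cell
  cbind(x = c(x0, x0 + area$cell, x0 + area$cell, x0),
        y = c(y0, y0, y0 + area$cell, y0 + area$cell))
}

area_polygon <- function(area) {
  cbind(
    x = area$origin[1] + c(0, area$width, area$width, 0),
    y = area$origin[2] + c(0, 0, area$height, area$height)
  )
}

#' Synthetic home-range parameters
#'
#' Empirical GPS-collar location clouds are emulated by isotropic bivariate
#' normal point clouds around each animal's home-range centroid, with
#' sex-specific spreads (males range wider than females in moose). The
#' winter range is a tighter cloud around a centroid offset drawn within the
#' annual range. Spreads are free parameters of the synthetic layer; the
#' defaults put median annual 100% minimum-convex-polygon areas in the tens
#' of km^2, typical for moose in northern New England.
#'
#' @param annual_sd_f,annual_sd_m Spread (km) of annual location clouds.
#' @param winter_sd_f,winter_sd_m Spread (km) of winter location clouds.
#' @param winter_offset_sd Spread (km) of the winter-centroid offset.
#' @param n_annual,n_winter Locations per cloud.
#' @return A list of class `hr_params`.
#' @export
hr_params <- function(annual_sd_f = 1.3, annual_sd_m = 1.8,
                      winter_sd_f = 0.5, winter_sd_m = 0.6,
                      winter_offset_sd = 0.5,
                      n_annual = 60, n_winter = 40) {
  vals <- c(annual_sd_f, annual_sd_m, winter_sd_f, winter_sd_m)
  if (any(vals <= 0)) abort("home-range spreads must be positive")
  if (n_annual < 3 || n_winter < 3) abort("need at least 3 locations per cloud")
  structure(
    list(
      annual_sd = c(F = annual_sd_f, M = annual_sd_m),
      winter_sd = c(F = winter_sd_f, M = winter_sd_m),
      winter_offset_sd = winter_offset_sd,
      n_annual = n_annual, n_winter = n_winter
    ),
    class = "hr_params"
  )
}

# Convex hull of a 2-column point matrix, vertices in order.
hull_of <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) <= 2) {
    return(pts)
  }
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Max distance from a reference point to hull vertices (overlap prefilter).
hull_radius <- function(hull, centre) {
  max(sqrt((hull[, 1] - centre[1])^2 + (hull[, 2] - centre[2])^2))
}

# Separating-axis test for two convex polygons given as vertex matrices.
# Touching boundaries count as overlap. Degenerate hulls (points, segments)
# are handled by adding the centroid-difference axis.
convex_intersects <- function(a, b) {
  axes_of <- function(p) {
    n <- nrow(p)
    if (n < 2) {
      return(matrix(numeric(0), ncol = 2))
    }
    nxt <- c(2:n, 1)
    ex <- p[nxt, 1] - p[, 1]
    ey <- p[nxt, 2] - p[, 2]
    keep <- (ex != 0 | ey != 0)
    cbind(-ey[keep], ex[keep])
  }
  axes <- rbind(axes_of(a), axes_of(b))
  da <- c(mean(b[, 1]) - mean(a[, 1]), mean(b[, 2]) - mean(a[, 2]))
  if (any(da != 0)) axes <- rbind(axes, da)
  if (nrow(axes) == 0) {
    return(TRUE) # both single identical points
  }
  for (i in seq_len(nrow(axes))) {
    ax <- axes[i, ]
    pa <- a[, 1] * ax[1] + a[, 2] * ax[2]
    pb <- b[, 1] * ax[1] + b[, 2] * ax[2]
    if (max(pa) < min(pb) || max(pb) < min(pa)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic winter/annual home-range pair
#'
#' Draws an annual location cloud from an isotropic bivariate normal around
#' the centroid with the sex-specific spread, and a winter cloud with a
#' smaller spread around a winter centroid offset from the annual one. The
#' 100% minimum convex polygon (MCP) of each cloud and its circumscribing
#' radius are precomputed for fast overlap tests.
#'
#' @param x,y Home-range centroid (km).
#' @param sex `"F"` or `"M"`.
#' @param params An [hr_params()] list.
#' @param seed Optional integer seed for a reproducible cloud.
#' @return A list of class `home_range` with elements `centroid`,
#'   `winter_centroid`, `cloud_annual`, `cloud_winter`, `hull_annual`,
#'   `hull_winter`, `r_annual`, `r_winter`, `sex`.
#' @export
generate_home_range <- function(x, y, sex, params = hr_params(), seed = NULL) {
  gen <- function() {
    sa <- params$annual_sd[[sex]]
    sw <- params$winter_sd[[sex]]
    cloud_a <- cbind(
      rnorm(params$n_annual, x, sa),
      rnorm(params$n_annual, y, sa)
    )
    wc <- c(
      rnorm(1, x, params$winter_offset_sd),
      rnorm(1, y, params$winter_offset_sd)
    )
    cloud_w <- cbind(
      rnorm(params$n_winter, wc[1], sw),
      rnorm(params$n_winter, wc[2], sw)
    )
    ha <- hull_of(cloud_a)
    hw <- hull_of(cloud_w)
    structure(
      list(
        centroid = c(x, y), winter_centroid = wc, sex = sex,
        cloud_annual = cloud_a, cloud_winter = cloud_w,
        hull_annual = ha, hull_winter = hw,
        r_annual = hull_radius(ha, c(x, y)),
        r_winter = hull_radius(hw, c(x, y))
      ),
      class = "home_range"
    )
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Do two 100% minimum convex polygons overlap?
#'
#' Overlap is tested on the convex hulls of the two location clouds
#' (a shared boundary point counts as overlap), with a fast circumscribing-
#' radius prefilter.
#'
#' @param a,b `home_range` objects, or bare 2-column vertex matrices.
#' @param season Which hull to compare for `home_range` inputs.
#' @return `TRUE` if the hulls intersect.
#' @export
mcp_overlap <- function(a, b, season = c("annual", "winter")) {
  season <- match.arg(season)
  get_hull <- function(h) {
    if (inherits(h, "home_range")) {
      if (season == "annual") h$hull_annual else h$hull_winter
    } else {
      as.matrix(h)
    }
  }
  ha <- get_hull(a)
  hb <- get_hull(b)
  if (nrow(ha) == 0 || nrow(hb) == 0) abort("empty location cloud")
  if (inherits(a, "home_range") && inherits(b, "home_range") && season == "annual") {
    d <- sqrt(sum((a$centroid - b$centroid)^2))
    if (d > a$r_annual + b$r_annual) {
      return(FALSE)
    }
  }
  convex_intersects(ha, hb)
}

#' Dispersal of a yearling to a new home-range centroid
#'
#' Yearlings disperse at a uniform random bearing (0-360 degrees) and a
#' distance drawn from a sex-specific normal distribution (female mean
#' 2.3 km, male mean 9.3 km by default) truncated at zero.
#'
#' @param x,y Current centroid.
#' @param sex `"F"` or `"M"`.
#' @param rates A vital-rate table carrying `dispersal_mean_km` and
#'   `dispersal_sd_km` for age-1 animals.
#' @param seed Optional seed.
#' @return Numeric `c(x, y)`: the new centroid.
#' @export
disperse_yearling <- function(x, y, sex, rates = moose_vital_rates(), seed = NULL) {
  r <- rates[rates$sex == sex & !is.na(rates$dispersal_mean_km), ]
  if (nrow(r) == 0) abort(sprintf("no dispersal parameters for sex %s", sex))
  gen <- function() {
    bearing <- runif(1, 0, 2 * pi)
    dist <- max(0, rnorm(1, r$dispersal_mean_km[1], r$dispersal_sd_km[1]))
    c(x + dist * sin(bearing), y + dist * cos(bearing))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Grid cells whose squares intersect a convex hull. Quick bounding-box
# candidate set, cell-centre-inside fast accept, separating-axis test for
# boundary cells.
cells_touching_hull <- function(area, hull) {
  bx <- range(hull[, 1])
  by <- range(hull[, 2])
  col_lo <- max(1, floor((bx[1] - area$origin[1]) / area$cell) + 1)
  col_hi <- min(area$nx, floor((bx[2] - area$origin[1]) / area$cell) + 1)
  row_lo <- max(1, floor((by[1] - area$origin[2]) / area$cell) + 1)
  row_hi <- min(area$ny, floor((by[2] - area$origin[2]) / area$cell) + 1)
  if (col_hi < col_lo || row_hi < row_lo) {
    return(integer(0))
  }
  cand <- as.vector(outer(col_lo:col_hi, (row_lo:row_hi - 1) * area$nx, `+`))
  if (length(cand) == 0) {
    return(integer(0))
  }
  ctr <- cell_center(area, cand)
  inside <- points_in_convex(ctr, hull)
  boundary <- cand[!inside]
  hit <- cand[inside]
  if (length(boundary) > 0) {
    keep <- vapply(
      boundary,
      function(k) convex_intersects(cell_polygon(area, k), hull),
      logical(1)
    )
    hit <- c(hit, boundary[keep])
  }
  sort(hit)
}

# Vectorised point-in-convex-polygon (vertices in hull order, either
# orientation); boundary counts as inside.
points_in_convex <- function(pts, hull) {
  n <- nrow(hull)
  if (n < 3) {
    return(rep(FALSE, nrow(pts)))
  }
  nxt <- c(2:n, 1)
  # polygon orientation from twice the signed area
  area2 <- sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])
  s <- if (area2 >= 0) 1 else -1
  res <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    ex <- hull[nxt[i], 1] - hull[i, 1]
    ey <- hull[nxt[i], 2] - hull[i, 2]
    cr <- ex * (pts[, 2] - hull[i, 2]) - ey * (pts[, 1] - hull[i, 1])
    res <- res & (s * cr >= -1e-12)
  }
  res
}

#' Per-cell abundance weights from annual home ranges
#'
#' Counts, for every grid cell, the number of animals whose annual 100% MCP
#' intersects the cell, and scales the counts by the busiest cell so weights
#' lie in \[0, 1\]. These weights emulate the prior knowledge (habitat
#' suitability, occurrence data) a practitioner would use to stratify a
#' scat survey.
#'
#' @param hulls A list of annual hull matrices (one per alive animal), or a
#'   `pop_sim`/`pop_state` object (then `year` selects the census).
#' @param area A `study_area`.
#' @param year Census year when `hulls` is a simulation object.
#' @return A tibble of class `cell_weight_map` with `cell`, `count`,
#'   `weight`.
#' @export
cell_weights <- function(hulls, area, year = NULL) {
  if (!is.list(hulls) || inherits(hulls, "pop_state") || inherits(hulls, "pop_sim")) {
    hulls <- alive_hulls(hulls, year, season = "annual")
  }
  counts <- integer(area$n_cells)
  for (h in hulls) {
    k <- cells_touching_hull(area, h)
    counts[k] <- counts[k] + 1L
  }
  mx <- max(counts)
  out <- tibble(
    cell = seq_len(area$n_cells),
    count = counts,
    weight = if (mx > 0) counts / mx else rep(0, area$n_cells)
  )
  class(out) <- c("cell_weight_map", class(out))
  out
}

#' Utilization probabilities of one animal over grid cells
#'
#' Evaluates a bivariate normal-kernel density estimate of the animal's
#' winter location cloud at cell centres (normal-reference bandwidths, as in
#' the classical 2-D KDE), then scales per animal so the busiest cell has
#' utilization 1. These scaled values serve as the per-cell detection
#' probability in the spatial sampling design. Cells outside the evaluated
#' neighbourhood (by default, the cells the winter MCP touches) have
#' utilization 0.
#'
#' @param hr A `home_range`, or a bare 2-column matrix of winter locations.
#' @param area A `study_area`.
#' @param cells Optional integer cell indices to evaluate; defaults to the
#'   cells intersecting the winter MCP.
#' @return A tibble with `cell` and `u` (scaled utilization in \[0, 1\]); the
#'   maximum cell has `u = 1` (ties broken by lowest cell index).
#' @export
utilization <- function(hr, area, cells = NULL) {
  cloud <- if (inherits(hr, "home_range")) hr$cloud_winter else as.matrix(hr)
  if (nrow(cloud) == 0) abort("empty winter cloud")
  hull <- if (inherits(hr, "home_range")) hr$hull_winter else hull_of(cloud)
  hood <- cells_touching_hull(area, hull)
  if (is.null(cells)) cells <- hood
  if (length(cells) == 0) {
    return(tibble(cell = integer(0), u = numeric(0)))
  }
  ctr <- cell_center(area, cells)
  # Degenerate cloud: all mass in the containing cell.
  if (nrow(unique(cloud)) == 1 ||
    (stats::var(cloud[, 1]) + stats::var(cloud[, 2])) < 1e-12) {
    px <- cloud[1, 1]
    py <- cloud[1, 2]
    inside <- px >= ctr[, 1] - area$cell / 2 & px < ctr[, 1] + area$cell / 2 &
      py >= ctr[, 2] - area$cell / 2 & py < ctr[, 2] + area$cell / 2
    return(tibble(cell = cells, u = as.numeric(inside)))
  }
  hx <- MASS::bandwidth.nrd(cloud[, 1]) / 4
  hy <- MASS::bandwidth.nrd(cloud[, 2]) / 4
  if (hx <= 0) hx <- area$cell / 4
  if (hy <= 0) hy <- area$cell / 4
  kde_at <- function(ks) {
    ctr_k <- cell_center(area, ks)
    vapply(
      seq_along(ks),
      function(i) {
        mean(stats::dnorm((ctr_k[i, 1] - cloud[, 1]) / hx) *
          stats::dnorm((ctr_k[i, 2] - cloud[, 2]) / hy)) / (hx * hy)
      },
      numeric(1)
    )
  }
  # the per-animal scaling reference is the busiest cell of the animal's
  # own neighbourhood, whatever subset of cells is being evaluated
  ref_cells <- unique(c(hood, cells))
  ref_dens <- kde_at(ref_cells)
  dens <- ref_dens[match(cells, ref_cells)]
  u <- dens / max(ref_dens)
  # Exactly one cell at 1; break exact float ties toward the lowest index.
  top <- which(u == 1)
  if (length(top) > 1) u[top[-1]] <- u[top[-1]] - .Machine$double.eps
  tibble(cell = cells, u = u)
}
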