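# Independent brute-force oracles and shared fixtures. These deliberately
# re-derive results from first principles (loops over definitions, ray
# casting, segment intersection) so they share no code with the package
# implementations they check.

# Literal segment classifier: walks every (adult, offspring) pair and applies
# the linked/unlinked/inferred definitions verbatim.
brute_classify <- function(ped, census_year, adult_age = 2) {
  is_sampled <- function(row) {
    isTRUE(row$sampled) && !is.na(row$sample_year) && row$sample_year <= census_year
  }
  n_l <- n_u <- n_i <- 0L
  for (i in seq_len(nrow(ped))) {
    ind <- ped[i, ]
    age <- census_year - ind$birth_year
    is_parent_somewhere <- any(
      (!is.na(ped$sire) & ped$sire == ind$id) |
        (!is.na(ped$dam) & ped$dam == ind$id)
    )
    adult <- !isTRUE(ind$known_dead) &&
      ((!is.na(age) && age >= adult_age) || (is.na(age) && is_parent_somewhere))
    if (!adult) next
    has_sampled_off <- FALSE
    mate_and_off_sampled <- FALSE
    for (j in seq_len(nrow(ped))) {
      off <- ped[j, ]
      if (!is_sampled(off)) next
      parent_here <- (!is.na(off$sire) && off$sire == ind$id) ||
        (!is.na(off$dam) && off$dam == ind$id)
      if (!parent_here) next
      has_sampled_off <- TRUE
      other <- if (!is.na(off$sire) && off$sire == ind$id) off$dam else off$sire
      if (!is.na(other)) {
        k <- match(other, ped$id)
        if (!is.na(k) && is_sampled(ped[k, ])) mate_and_off_sampled <- TRUE
      }
    }
    if (is_sampled(ind)) {
      if (has_sampled_off) n_l <- n_l + 1L else n_u <- n_u + 1L
    } else if (mate_and_off_sampled) {
      n_i <- n_i + 1L
    }
  }
  c(n_linked = n_l, n_unlinked = n_u, n_inferred = n_i)
}

# Ray-casting point-in-polygon (boundary not guaranteed; used with interior
# points only).
ray_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
      px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

seg_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) || on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

# Brute-force convex polygon overlap: vertex containment + edge crossings.
brute_overlap <- function(a, b) {
  for (i in seq_len(nrow(a))) if (ray_in_poly(a[i, 1], a[i, 2], b)) return(TRUE)
  for (i in seq_len(nrow(b))) if (ray_in_poly(b[i, 1], b[i, 2], a)) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (seg_intersect(
        a[i, ], a[if (i == na) 1 else i + 1, ],
        b[j, ], b[if (j == nb) 1 else j + 1, ]
      )) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# The worked six-adult example: two sampled parents of a sampled calf, one
# sampled adult without offspring, one unsampled adult revealed by a sampled
# mate and calf, and two adults invisible to the method.
toy_pedigree <- function() {
  tibble::tibble(
    id = 1:8,
    sire = c(NA, NA, NA, NA, NA, NA, 1, 4),
    dam = c(NA, NA, NA, NA, NA, NA, 2, 2),
    sex = c("M", "F", "F", "M", "M", "F", "F", "M"),
    birth_year = c(0L, 0L, 0L, 0L, 0L, 0L, 10L, 10L),
    sampled = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    sample_year = c(10L, 10L, 10L, NA, NA, NA, 10L, 10L),
    known_dead = FALSE
  )
}

# A random small pedigree with founders, offspring, and arbitrary sampling
# flags, for the enumeration/property checks.
random_pedigree <- function(n_founders = 6, n_off = 4, census = 10) {
  sires <- seq_len(ceiling(n_founders / 2))
  dams <- setdiff(seq_len(n_founders), sires)
  off_id <- n_founders + seq_len(n_off)
  tibble::tibble(
    id = c(seq_len(n_founders), off_id),
    sire = c(rep(NA, n_founders), sample(sires, n_off, replace = TRUE)),
    dam = c(rep(NA, n_founders), sample(dams, n_off, replace = TRUE)),
    sex = c(
      ifelse(seq_len(n_founders) %in% sires, "M", "F"),
      sample(c("M", "F"), n_off, replace = TRUE)
    ),
    birth_year = c(
      rep(0L, n_founders),
      sample(c(census, census - 1L, census - 5L), n_off, replace = TRUE)
    ),
    sampled = FALSE,
    sample_year = NA_integer_,
    known_dead = FALSE
  )
}

set_sampled <- function(ped, ids, year = 10L) {
  ped$sampled[ped$id %in% ids] <- TRUE
  ped$sample_year[ped$id %in% ids] <- year
  ped
}

# Small cached simulation for unit tests (one per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(
        years = 8, n0 = 200,
        area = make_study_area(25, 16), seed = 3
      )
    }
    cache
  }
})
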