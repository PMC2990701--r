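# Shared fixtures built in code.

# Small synthetic country for fast tests.
tiny_config <- function(seed = 11L, ...) {
  synthetic_config(n_municipalities = 30L, n_regions = 3L, years = 2L,
                   seed = seed, ...)
}

# A hand-made municipality table with six deprivation variables derived
# deterministically from a single severity score (higher = more deprived).
toy_municipalities <- function(severity, population = NULL,
                               ids = sprintf("M%03d", seq_along(severity))) {
  n <- length(severity)
  if (is.null(population)) population <- rep(1e5, n)
  data.frame(
    municipality_id = ids,
    population = population,
    centroid_x = seq_len(n),
    centroid_y = rep(0, n),
    altitude_m = rep(100, n),
    precipitation_mm = rep(2000, n),
    pct_rural = pmin(100, pmax(0, 40 + severity)),
    pct_under15 = rep(37, n),
    pct_male_surplus = rep(1, n),
    dist_hospital_m = 1000 + 100 * severity,
    pct_households_gt5km_hc = pmin(100, pmax(0, 10 + severity)),
    pct_poverty = pmin(100, pmax(0, 30 + severity)),
    pct_illiterate = pmin(100, pmax(0, 20 + severity)),
    pct_area_gt1km_road = pmin(100, pmax(0, 15 + severity)),
    births_outside_hc_per_inhab = pmax(0, 0.01 + 0.001 * severity),
    stringsAsFactors = FALSE
  )
}

# Independent pairwise-counting oracle for oriented ordinal ranks: the rank
# of i is 1 + (# strictly worse) + (# tied with a larger id), so the best
# value gets rank n and ties go to the smaller id.
oracle_rank <- function(values, ids, higher_is_worse = TRUE) {
  goodness <- if (higher_is_worse) -values else values
  vapply(seq_along(values), function(i) {
    1L + sum(goodness < goodness[i]) +
      sum(goodness == goodness[i] & ids > ids[i])
  }, integer(1))
}

# Coarse-to-fine grid maximizer of the written-out Poisson log-likelihood
# sum(y * (off + b0 + b1 x) - exp(off + b0 + b1 x)). For any slope b1 the
# intercept maximizing the likelihood is log(sum(y) / sum(exp(off + b1 x)))
# (set the derivative in b0 to zero), so the slope is found by dense search
# over b1 alone, refined around the best cell.
oracle_grid_poisson <- function(y, x, off, passes = 5L, width = 0.1,
                                grid_n = 2001L) {
  profile_b0 <- function(b1) log(sum(y) / sum(exp(off + b1 * x)))
  profile_ll <- function(b1) {
    eta <- off + profile_b0(b1) + b1 * x
    sum(y * eta - exp(eta))
  }
  centre <- 0
  for (p in seq_len(passes)) {
    b1s <- seq(centre - width, centre + width, length.out = grid_n)
    ll <- vapply(b1s, profile_ll, numeric(1))
    centre <- b1s[which.max(ll)]
    width <- 4 * width / (grid_n - 1)  # shrink to a few cells around the best
  }
  c(profile_b0(centre), centre)
}

# Canonical form of a partition (for label-permutation invariance): the
# sorted list of sorted member-id groups.
partition_canonical <- function(assignment) {
  groups <- split(assignment$municipality_id, assignment$region)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}
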