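# Independent brute-force oracles and fixture builders used across tests.

# O(n^2) re-implementation of the communal-attendance rule with plain loops;
# deliberately independent of detect_attendance().
brute_force_attendance <- function(nights, radius = 300, min_others = 2,
                                   matching = "cross_night") {
  out <- NULL
  for (w in unique(nights$winter_id)) {
    for (b in unique(nights$interval_index[nights$winter_id == w])) {
      blk <- nights[nights$winter_id == w & nights$interval_index == b, ]
      for (bird in unique(blk$bird_id)) {
        own <- blk[blk$bird_id == bird, ]
        neigh <- character()
        for (other in setdiff(unique(blk$bird_id), bird)) {
          oth <- blk[blk$bird_id == other, ]
          found <- FALSE
          for (i in seq_len(nrow(own))) {
            for (j in seq_len(nrow(oth))) {
              if (matching == "same_night" &&
                  own$night_date[i] != oth$night_date[j]) next
              d <- sqrt((own$x[i] - oth$x[j])^2 + (own$y[i] - oth$y[j])^2)
              if (d <= radius) { found <- TRUE; break }
            }
            if (found) break
          }
          if (found) neigh <- c(neigh, other)
        }
        out <- rbind(out, data.frame(
          bird_id = bird, winter_id = w, interval_index = b,
          n_neighbours = length(neigh),
          attendance = as.integer(length(neigh) >= min_others)))
      }
    }
  }
  out[order(out$bird_id, out$winter_id, out$interval_index), ]
}

# random night-location fixtures: a mix of clustered (roost-like) and
# scattered birds over real winter dates
make_random_nights <- function(n_birds = 20, nights_per_bird = 10, seed = 1,
                               winter = 2019, cluster_frac = 0.5,
                               extent = 10000) {
  set.seed(seed)
  dates <- seq(as.Date(paste0(winter, "-11-01")), by = "day", length.out = 92)
  centres <- matrix(stats::runif(6, -extent, extent), ncol = 2)
  rows <- list()
  for (i in seq_len(n_birds)) {
    dd <- sort(sample(dates, nights_per_bird))
    clustered <- stats::runif(1) < cluster_frac
    if (clustered) {
      cc <- centres[sample(3, 1), ]
      x <- cc[1] + stats::rnorm(nights_per_bird, 0, 120)
      y <- cc[2] + stats::rnorm(nights_per_bird, 0, 120)
    } else {
      x <- stats::runif(nights_per_bird, -extent, extent)
      y <- stats::runif(nights_per_bird, -extent, extent)
    }
    rows[[i]] <- data.frame(bird_id = sprintf("B%02d", i), night_date = dd,
                            x = x, y = y, n_fixes = 3L)
  }
  assign_intervals(do.call(rbind, rows))
}

# independent per-night classification of co-roosting with labelled partners
brute_force_with_kin <- function(records, nights, registry, radius = 300) {
  vapply(seq_len(nrow(records)), function(k) {
    b <- records$bird_id[k]; d <- records$night_date[k]
    w <- records$winter_id[k]
    own <- nights[nights$bird_id == b & nights$night_date == d, ]
    others <- nights[nights$bird_id != b & nights$night_date == d, ]
    hit <- 0L
    for (j in seq_len(nrow(others))) {
      o <- others$bird_id[j]
      lab <- FALSE
      m <- registry$mates
      if (any(m$year == w & pmin(m$bird1, m$bird2) == pmin(b, o) &
                pmax(m$bird1, m$bird2) == pmax(b, o))) lab <- TRUE
      p <- registry$parent_offspring
      if (any((p$parent_id == b & p$chick_id == o) |
                (p$parent_id == o & p$chick_id == b))) lab <- TRUE
      s <- registry$siblings
      if (any(s$bird1 == pmin(b, o) & s$bird2 == pmax(b, o))) lab <- TRUE
      if (!lab) next
      if (sqrt((own$x - others$x[j])^2 + (own$y - others$y[j])^2) <= radius)
        hit <- 1L
    }
    hit
  }, 0L)
}

# small synthetic world reused by association tests
make_assoc_world <- function(seed = 5, n_juv = 40, n_ad = 16, n_winters = 2) {
  cfg <- population_config(n_juvenile_tagged = n_juv, n_adult_tagged = n_ad,
                           n_winters = n_winters, seed = seed)
  pop <- generate_population(cfg)
  sim <- simulate_winter_nights(pop)
  nights <- assign_intervals(extract_night_locations(sim$fixes))
  det <- detect_attendance(nights)
  registry <- build_relatedness_registry(pop$broods, pop$pairs, pop$individuals)
  list(pop = pop, sim = sim, nights = nights, det = det, registry = registry)
}
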