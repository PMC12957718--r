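# Synthetic tracked population: individuals, broods, pairs, roost sites and
# nightly GPS fixes with known generative parameters.
#
# The generator emulates the sampling situation of a duty-cycled GPS-tagged
# red-kite population on its wintering grounds: major and satellite roost
# sites, territory-anchored non-communal roosting, pair co-roosting at the
# nest, sex/age/breeding-dependent attendance, migration absences, mortality,
# and ~19 m within-night fix scatter.

# Shared projection origin for synthetic fixtures (western Switzerland).
.ROOST_LON0 <- 7.0
.ROOST_LAT0 <- 46.8

#' Default projection used by synthetic fixtures
#' @return A [local_projection()] centred on the synthetic study area.
#' @export
default_projection <- function() local_projection(.ROOST_LON0, .ROOST_LAT0)

#' Rectangular study-area polygon of a given area
#'
#' @param area_km2 Area in square kilometres (default 387).
#' @param aspect Width/height ratio (default 1.25).
#' @return Two-column matrix of planar vertices (metres), centred on origin.
#' @export
make_study_area <- function(area_km2 = 387, aspect = 1.25) {
  h <- sqrt(area_km2 * 1e6 / aspect)
  w <- aspect * h
  cbind(x = c(-w / 2, w / 2, w / 2, -w / 2), y = c(-h / 2, -h / 2, h / 2, h / 2))
}

#' Population configuration for the synthetic generator
#'
#' Defaults mirror the tracked study population: 148 juvenile-tagged and 68
#' adult-tagged birds, six winters from 2016, hourly fixes on a 07:00--21:00
#' duty cycle, a 387 km^2 study area, and within-night scatter calibrated so
#' the median distance between a night's fixes is about 18.9 m (for an
#' isotropic Gaussian the median pairwise distance is sigma * sqrt(2) *
#' sqrt(2 log 2) ~ 1.665 sigma, so sigma ~ 11.35 m).
#'
#' @param n_juvenile_tagged,n_adult_tagged Tagged-bird counts by tag class.
#' @param sex_ratio Proportion of males.
#' @param n_winters Number of consecutive winters.
#' @param start_year Calendar year of the first winter's 1 November.
#' @param study_area Polygon (planar metres) or NULL for the default.
#' @param n_major_roosts,n_satellite_roosts Communal roost-site counts;
#'   satellites lie within 2 km of a major site.
#' @param roost_size_mean_nov,roost_size_mean_jan Roost-size means used to
#'   set the seasonal attendance trend (counts; 54 and 40).
#' @param within_night_scatter_sd Per-coordinate fix scatter, metres.
#' @param fix_interval Fix spacing in minutes.
#' @param duty_window Local duty-cycle hours, default `c(7, 21)`.
#' @param migration_absence_prob Named list `f`/`m` of per-age-class
#'   whole-winter absence probabilities (last element reused for older ages
#'   and adult-tagged birds).
#' @param annual_mortality_prob Per-age-class annual death probabilities
#'   (last element reused for older ages and adults).
#' @param tagged_parent_prob Probability a juvenile brood descends from a
#'   tagged adult pair.
#' @param seed Integer seed stored with the config.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_juvenile_tagged = 148, n_adult_tagged = 68,
                              sex_ratio = 0.5, n_winters = 6, start_year = 2016,
                              study_area = NULL,
                              n_major_roosts = 3, n_satellite_roosts = 4,
                              roost_size_mean_nov = 54, roost_size_mean_jan = 40,
                              within_night_scatter_sd = 11.35,
                              fix_interval = 60, duty_window = c(7, 21),
                              migration_absence_prob = list(
                                f = c(0.75, 0.5, 0.35, 0.3),
                                m = c(0.65, 0.35, 0.2, 0.15)),
                              annual_mortality_prob = c(0.55, 0.25, 0.15),
                              tagged_parent_prob = 0.35,
                              seed = 1L) {
  if (is.null(study_area)) study_area <- make_study_area()
  cfg <- list(n_juvenile_tagged = n_juvenile_tagged,
              n_adult_tagged = n_adult_tagged, sex_ratio = sex_ratio,
              n_winters = as.integer(n_winters), start_year = as.integer(start_year),
              study_area = study_area,
              n_major_roosts = n_major_roosts,
              n_satellite_roosts = n_satellite_roosts,
              roost_size_mean_nov = roost_size_mean_nov,
              roost_size_mean_jan = roost_size_mean_jan,
              within_night_scatter_sd = within_night_scatter_sd,
              fix_interval = fix_interval, duty_window = duty_window,
              migration_absence_prob = migration_absence_prob,
              annual_mortality_prob = annual_mortality_prob,
              tagged_parent_prob = tagged_parent_prob,
              seed = as.integer(seed))
  probs <- c(sex_ratio, unlist(migration_absence_prob), annual_mortality_prob,
             tagged_parent_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_juvenile_tagged, n_adult_tagged, n_winters)
  if (any(counts <= 0)) stop("counts must be positive")
  if (n_major_roosts < 0 || n_satellite_roosts < 0)
    stop("roost counts must be non-negative")
  if (n_major_roosts == 0 && n_satellite_roosts > 0)
    stop("satellite roosts require at least one major roost")
  if (within_night_scatter_sd <= 0 || fix_interval <= 0)
    stop("scatter sd and fix interval must be positive")
  structure(cfg, class = "population_config")
}

#' Generative attendance parameters
#'
#' Log-odds coefficients and variance components of the latent attendance
#' model, on the standardised-age scale (`(age - 3.5) / 1.5`). Defaults are
#' the juvenile-cohort point estimates of the attendance model reported for
#' the study population, plus co-roosting propensities and a weak negative
#' seasonal trend reproducing larger November than January roosts.
#'
#' @param beta_intercept,beta_age,beta_age2,beta_sex_male,beta_breeding Fixed
#'   effects (log-odds).
#' @param sd_bird,sd_bird_winter,sd_slope,sd_winter Random-effect SDs.
#' @param cor_intercept_slope Correlation between the bird-winter intercept
#'   and its interval-sequence slope.
#' @param beta_season Common linear logit trend over the standardised
#'   interval sequence.
#' @param pair_coroost_prob Nightly probability that a breeding pair, both at
#'   home, roosts together at the nest.
#' @param kin_coroost_prob Nightly probability that a non-breeding bird joins
#'   a present relative's roosting spot.
#' @return A list of class `attendance_truth`.
#' @export
attendance_truth <- function(beta_intercept = -0.441, beta_age = -0.27,
                             beta_age2 = -0.453, beta_sex_male = 1.731,
                             beta_breeding = -1.296,
                             sd_bird = 1.624, sd_bird_winter = 1.852,
                             sd_slope = 1.394, sd_winter = 0.345,
                             cor_intercept_slope = -0.581,
                             beta_season = -0.1,
                             pair_coroost_prob = 0.8, kin_coroost_prob = 0.05) {
  if (any(c(sd_bird, sd_bird_winter, sd_slope, sd_winter) < 0))
    stop("random-effect SDs must be non-negative")
  if (abs(cor_intercept_slope) > 1) stop("correlation must lie in [-1, 1]")
  if (pair_coroost_prob < 0 || pair_coroost_prob > 1 ||
      kin_coroost_prob < 0 || kin_coroost_prob > 1)
    stop("co-roosting probabilities must lie in [0, 1]")
  structure(list(beta_intercept = beta_intercept, beta_age = beta_age,
                 beta_age2 = beta_age2, beta_sex_male = beta_sex_male,
                 beta_breeding = beta_breeding, sd_bird = sd_bird,
                 sd_bird_winter = sd_bird_winter, sd_slope = sd_slope,
                 sd_winter = sd_winter,
                 cor_intercept_slope = cor_intercept_slope,
                 beta_season = beta_season,
                 pair_coroost_prob = pair_coroost_prob,
                 kin_coroost_prob = kin_coroost_prob),
            class = "attendance_truth")
}

# standardisation constants shared by generator and models
.AGE_CENTER <- 3.5
.AGE_SCALE <- 1.5

.std_age <- function(age) (age - .AGE_CENTER) / .AGE_SCALE

.runif_disc <- function(n, r) {
  # uniform points in a disc of radius r
  a <- stats::runif(n, 0, 2 * pi)
  d <- r * sqrt(stats::runif(n))
  cbind(d * cos(a), d * sin(a))
}

.uniform_in_polygon <- function(n, polygon) {
  bb <- apply(polygon, 2, range)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    cand <- cbind(stats::runif(n, bb[1, 1], bb[2, 1]),
                  stats::runif(n, bb[1, 2], bb[2, 2]))
    out <- rbind(out, cand[point_in_polygon(cand, polygon), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic tagged population
#'
#' Creates individuals (sex, tag class, cohort, natal brood, mortality,
#' first breeding winter), broods of 1--3 tagged siblings, breeding pairs
#' with shared nests, and communal roost sites (satellites within 2 km of a
#' major site) inside the study area.
#'
#' @param config A [population_config()].
#' @param truth An [attendance_truth()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of class `roost_population` with elements `individuals`,
#'   `broods`, `pairs` (per active year), `roosts`, `territories`,
#'   `study_area`, `config`, `truth`.
#' @export
generate_population <- function(config = population_config(),
                                truth = attendance_truth(),
                                seed = config$seed) {
  stopifnot(inherits(config, "population_config"),
            inherits(truth, "attendance_truth"))
  set.seed(seed)
  winters <- config$start_year + seq_len(config$n_winters) - 1L
  area <- config$study_area

  ## roost sites ------------------------------------------------------------
  roosts <- NULL
  if (config$n_major_roosts > 0) {
    core <- area * 0.8  # keep roosts away from the margin
    maj <- .uniform_in_polygon(config$n_major_roosts, core)
    for (it in seq_len(200)) {  # push majors at least 5 km apart
      if (config$n_major_roosts < 2) break
      dm <- as.matrix(stats::dist(maj)); diag(dm) <- Inf
      if (min(dm) >= 5000) break
      i <- which(dm == min(dm), arr.ind = TRUE)[1, 1]
      maj[i, ] <- .uniform_in_polygon(1, core)
    }
    roosts <- data.frame(site_id = sprintf("R%02d", seq_len(config$n_major_roosts)),
                         x = maj[, 1], y = maj[, 2], type = "major",
                         site_weight = 3)
    if (config$n_satellite_roosts > 0) {
      host <- sample(config$n_major_roosts, config$n_satellite_roosts, replace = TRUE)
      a <- stats::runif(config$n_satellite_roosts, 0, 2 * pi)
      d <- stats::runif(config$n_satellite_roosts, 500, 2000)
      roosts <- rbind(roosts, data.frame(
        site_id = sprintf("S%02d", seq_len(config$n_satellite_roosts)),
        x = maj[host, 1] + d * cos(a), y = maj[host, 2] + d * sin(a),
        type = "satellite", site_weight = 1))
    }
  }

  ## individuals ------------------------------------------------------------
  nj <- config$n_juvenile_tagged; na <- config$n_adult_tagged
  n <- nj + na
  ind <- data.frame(
    bird_id = sprintf("B%03d", seq_len(n)),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "m", "f"),
    tag_class = rep(c("juvenile", "adult"), c(nj, na)),
    stringsAsFactors = FALSE)

  # juvenile cohorts: tagged as fledglings; a small early cohort lets the
  # oldest age classes appear within the study window
  cohort_years <- c(config$start_year - 1L, winters)
  cohort_w <- c(0.5, rep(1, length(winters)))
  ind$birth_year <- NA_integer_
  ind$birth_year[seq_len(nj)] <-
    sort(sample(cohort_years, nj, replace = TRUE, prob = cohort_w))
  ind$tag_start_winter <- pmax(ind$birth_year, config$start_year)
  ind$tag_start_winter[ind$tag_class == "adult"] <-
    sample(winters[seq_len(min(4, length(winters)))], na, replace = TRUE)

  ## broods of tagged siblings ----------------------------------------------
  broods <- NULL
  nest_counter <- 0L
  ind$natal_nest_id <- NA_character_
  for (y in unique(ind$birth_year[!is.na(ind$birth_year)])) {
    ids <- ind$bird_id[!is.na(ind$birth_year) & ind$birth_year == y]
    ids <- sample(ids)
    while (length(ids)) {
      size <- min(length(ids), sample(1:3, 1, prob = c(0.45, 0.35, 0.2)))
      nest_counter <- nest_counter + 1L
      nest <- sprintf("N%04d", nest_counter)
      xy <- .uniform_in_polygon(1, area)
      broods <- rbind(broods, data.frame(
        nest_id = nest, year = y, bird_id = ids[seq_len(size)],
        x = xy[1], y_ = xy[2], stringsAsFactors = FALSE))
      ind$natal_nest_id[match(ids[seq_len(size)], ind$bird_id)] <- nest
      ids <- ids[-seq_len(size)]
    }
  }
  names(broods)[names(broods) == "y_"] <- "y"

  ## mortality --------------------------------------------------------------
  mort <- config$annual_mortality_prob
  ind$death_date <- as.Date(NA)
  for (i in seq_len(n)) {
    first <- ind$tag_start_winter[i]
    age0 <- if (ind$tag_class[i] == "juvenile") first - ind$birth_year[i] + 1L
            else length(mort)
    for (k in 0:(config$n_winters + 2)) {
      yr <- first + k
      p <- mort[min(age0 + k, length(mort))]
      if (stats::runif(1) < p) {
        # death on a uniform day of that tracking year (from 1 Jul)
        ind$death_date[i] <- as.Date(paste0(yr, "-07-01")) +
          sample.int(365, 1) - 1L
        break
      }
    }
  }

  ## breeding onset and pairs ------------------------------------------------
  # adults breed from their first tracked winter; juvenile-tagged birds may
  # settle from age 3, with settlement probability rising to ~0.5 by age 4
  ind$first_breeding_winter <- NA_integer_
  ind$first_breeding_winter[ind$tag_class == "adult"] <-
    ind$tag_start_winter[ind$tag_class == "adult"]
  start_p <- c(0.25, 0.5, 0.6)  # hazard at ages 3, 4, 5+
  for (i in which(ind$tag_class == "juvenile")) {
    for (w in winters) {
      age <- w - ind$birth_year[i] + 1L
      if (age < 3) next
      if (!is.na(ind$death_date[i]) && ind$death_date[i] < as.Date(paste0(w, "-07-01")))
        break
      if (stats::runif(1) < start_p[min(age - 2, length(start_p))]) {
        ind$first_breeding_winter[i] <- w
        break
      }
    }
  }

  # pair tagged breeders of opposite sex; remaining breeders have untagged
  # mates (breeding status without a pair record)
  pair_rows <- NULL
  paired <- character()
  for (w in winters) {
    breeders <- ind$bird_id[!is.na(ind$first_breeding_winter) &
                              ind$first_breeding_winter == w]
    newly <- setdiff(breeders, paired)
    males <- sample(intersect(newly, ind$bird_id[ind$sex == "m"]))
    females <- sample(intersect(newly, ind$bird_id[ind$sex == "f"]))
    k <- floor(min(length(males), length(females)) * 0.5)
    if (k > 0) {
      xy <- .uniform_in_polygon(k, area)
      for (j in seq_len(k)) {
        nest_counter <- nest_counter + 1L
        pair_rows <- rbind(pair_rows, data.frame(
          male_id = males[j], female_id = females[j],
          nest_id = sprintf("N%04d", nest_counter),
          x = xy[j, 1], y = xy[j, 2], first_year = w,
          stringsAsFactors = FALSE))
        paired <- c(paired, males[j], females[j])
      }
    }
  }
  # expand pairs per active year (both alive at the start of the season)
  pairs <- NULL
  if (!is.null(pair_rows)) {
    for (j in seq_len(nrow(pair_rows))) {
      pr <- pair_rows[j, ]
      for (w in winters[winters >= pr$first_year]) {
        alive <- function(id) {
          dd <- ind$death_date[match(id, ind$bird_id)]
          is.na(dd) || dd >= as.Date(paste0(w, "-11-01"))
        }
        if (alive(pr$male_id) && alive(pr$female_id))
          pairs <- rbind(pairs, data.frame(
            year = w, male_id = pr$male_id, female_id = pr$female_id,
            nest_id = pr$nest_id, x = pr$x, y = pr$y,
            stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(year = integer(), male_id = character(),
                        female_id = character(), nest_id = character(),
                        x = numeric(), y = numeric())

  ## descend some broods from tagged pairs (parent-offspring links) ----------
  if (nrow(pairs) > 0) {
    used_nest_year <- character()
    for (nest in unique(broods$nest_id)) {
      rows <- broods$nest_id == nest
      y <- broods$year[rows][1]
      cand <- pairs[pairs$year == y &
                      !(paste(pairs$nest_id, y) %in% used_nest_year), ,
                    drop = FALSE]
      if (nrow(cand) && stats::runif(1) < config$tagged_parent_prob) {
        pk <- cand[sample.int(nrow(cand), 1), ]
        used_nest_year <- c(used_nest_year, paste(pk$nest_id, y))
        broods$nest_id[rows] <- pk$nest_id
        broods$x[rows] <- pk$x
        broods$y[rows] <- pk$y
        ind$natal_nest_id[match(broods$bird_id[rows], ind$bird_id)] <- pk$nest_id
      }
    }
  }

  ## territories (non-communal anchors) --------------------------------------
  # breeders anchor on their nest; other birds on a home range offset from
  # the natal nest (or a random point for adult-tagged birds never paired)
  terr <- data.frame(bird_id = ind$bird_id, x = NA_real_, y = NA_real_)
  off <- .runif_disc(n, 3000)
  off[, 1] <- off[, 1] + 500 * sign(off[, 1])  # keep anchors off the nest itself
  for (i in seq_len(n)) {
    nest <- ind$natal_nest_id[i]
    if (!is.na(nest) && nest %in% broods$nest_id) {
      k <- match(nest, broods$nest_id)
      terr$x[i] <- broods$x[k] + off[i, 1]
      terr$y[i] <- broods$y[k] + off[i, 2]
    } else {
      xy <- .uniform_in_polygon(1, area)
      terr$x[i] <- xy[1]; terr$y[i] <- xy[2]
    }
  }

  structure(list(individuals = ind, broods = broods, pairs = pairs,
                 roosts = roosts, territories = terr, study_area = area,
                 config = config, truth = truth),
            class = "roost_population")
}

#' @export
print.roost_population <- function(x, ...) {
  cat(sprintf("Synthetic roosting population: %d birds (%d juvenile-tagged, %d adult-tagged)\n",
              nrow(x$individuals), sum(x$individuals$tag_class == "juvenile"),
              sum(x$individuals$tag_class == "adult")))
  cat(sprintf("  %d broods, %d pair-years, %d roost sites, %d winters from %d\n",
              length(unique(x$broods$nest_id)), nrow(x$pairs),
              if (is.null(x$roosts)) 0L else nrow(x$roosts),
              x$config$n_winters, x$config$start_year))
  invisible(x)
}

# winter night dates: 1 Nov .. 31 Jan
.winter_nights <- function(winter_id) {
  seq(as.Date(paste0(winter_id, "-11-01")),
      as.Date(paste0(winter_id + 1, "-01-31")), by = "day")
}

# draw correlated bird-winter intercept/slope effects
.draw_bw_effects <- function(n, truth) {
  sig <- matrix(c(truth$sd_bird_winter^2,
                  truth$cor_intercept_slope * truth$sd_bird_winter * truth$sd_slope,
                  truth$cor_intercept_slope * truth$sd_bird_winter * truth$sd_slope,
                  truth$sd_slope^2), 2)
  if (all(sig == 0)) matrix(0, n, 2)
  else matrix(MASS::mvrnorm(n, c(0, 0), sig), ncol = 2)
}

#' Simulate winter nights and GPS fixes
#'
#' Draws latent communal-roost attendance for each bird and five-night
#' interval from the generative attendance model (fixed effects plus bird,
#' bird-winter intercept/slope and winter random effects), places attending
#' birds at a distance-weighted roost site and non-attending birds on their
#' territory (breeding pairs co-roost at the nest with probability
#' `pair_coroost_prob`), then emits duty-cycled fixes between civil dusk and
#' 21:00 plus the 07:00 fix before dawn, with Gaussian within-night scatter.
#' Migration absences and deaths remove nights.
#'
#' @param pop A [generate_population()] result.
#' @param seed Integer seed.
#' @return List with `fixes` (bird_id, timestamp UTC, lon, lat, x, y),
#'   `truth` (one row per simulated bird-night with the latent attendance
#'   state and placement), and `random_effects`.
#' @export
simulate_winter_nights <- function(pop, seed = pop$config$seed + 1L) {
  stopifnot(inherits(pop, "roost_population"))
  set.seed(seed)
  config <- pop$config; truth <- pop$truth
  ind <- pop$individuals
  winters <- config$start_year + seq_len(config$n_winters) - 1L
  n_int <- n_intervals_per_winter(5)
  t_std_all <- (seq_len(n_int) - mean(seq_len(n_int))) / stats::sd(seq_len(n_int))

  u_bird <- stats::rnorm(nrow(ind), 0, truth$sd_bird)
  names(u_bird) <- ind$bird_id
  w_winter <- stats::rnorm(length(winters), 0, truth$sd_winter)
  names(w_winter) <- winters

  mig <- config$migration_absence_prob
  truth_rows <- list(); re_rows <- list(); fix_rows <- list()

  for (wi in seq_along(winters)) {
    w <- winters[wi]
    nights <- .winter_nights(w)
    nov1 <- nights[1]
    ## which birds hold data this winter
    present <- ind$tag_start_winter <= w &
      (is.na(ind$death_date) | ind$death_date >= nov1)
    age <- ifelse(ind$tag_class == "juvenile", w - ind$birth_year + 1L, NA_integer_)
    present <- present & (is.na(age) | age >= 1)
    mig_p <- vapply(seq_len(nrow(ind)), function(i) {
      tab <- mig[[ind$sex[i]]]
      a <- if (is.na(age[i])) length(tab) else min(max(age[i], 1L), length(tab))
      tab[a]
    }, 0)
    present <- present & stats::runif(nrow(ind)) >= mig_p
    idx <- which(present)
    if (!length(idx)) next

    bw <- .draw_bw_effects(length(idx), truth)
    re_rows[[length(re_rows) + 1]] <- data.frame(
      bird_id = ind$bird_id[idx], winter_id = w,
      u_bird = u_bird[idx], v_intercept = bw[, 1], v_slope = bw[, 2],
      w_winter = w_winter[wi])

    breeding <- as.integer(!is.na(ind$first_breeding_winter[idx]) &
                             ind$first_breeding_winter[idx] <= w)
    age_std <- ifelse(is.na(age[idx]), 0, .std_age(age[idx]))
    male <- as.integer(ind$sex[idx] == "m")

    ## latent attendance per bird x interval
    eta0 <- truth$beta_intercept + truth$beta_age * age_std +
      truth$beta_age2 * age_std^2 + truth$beta_sex_male * male +
      truth$beta_breeding * breeding + u_bird[idx] + bw[, 1] + w_winter[wi]
    att <- matrix(0L, length(idx), n_int)
    site_choice <- matrix(NA_character_, length(idx), n_int)
    has_sites <- !is.null(pop$roosts) && nrow(pop$roosts) > 0
    for (tt in seq_len(n_int)) {
      eta <- eta0 + (truth$beta_season + bw[, 2]) * t_std_all[tt]
      att[, tt] <- stats::rbinom(length(idx), 1, stats::plogis(eta))
    }
    if (!has_sites) att[] <- 0L  # nowhere to aggregate
    if (has_sites) {
      ## site choice per bird-interval: weight by attractiveness and
      ## distance decay from the bird's anchor (5 km scale)
      tx <- pop$territories$x[idx]; ty <- pop$territories$y[idx]
      for (j in seq_along(idx)) {
        dsite <- sqrt((pop$roosts$x - tx[j])^2 + (pop$roosts$y - ty[j])^2)
        wgt <- pop$roosts$site_weight * exp(-dsite / 5000)
        site_choice[j, ] <- sample(pop$roosts$site_id, n_int, replace = TRUE,
                                   prob = wgt)
      }
    }

    ## nightly placements
    pres_id <- ind$bird_id[idx]
    pair_tab <- pop$pairs[pop$pairs$year == w &
                            pop$pairs$male_id %in% pres_id &
                            pop$pairs$female_id %in% pres_id, , drop = FALSE]
    nest_of <- stats::setNames(rep(NA_integer_, length(idx)), pres_id)
    # registry of sibling/parent partners for kin co-roosting
    sib_of <- .kin_partner_list(pop, pres_id)

    death <- ind$death_date[idx]
    for (dn in seq_along(nights)) {
      d <- nights[dn]
      tt <- (dn - 1L) %/% 5L + 1L
      alive <- is.na(death) | death > d
      if (!any(alive)) next
      a_now <- att[, tt] == 1L & alive
      cx <- rep(NA_real_, length(idx)); cy <- rep(NA_real_, length(idx))
      site_night <- rep(NA_character_, length(idx))
      ## attending birds: roost site + spread across the tree line
      if (any(a_now)) {
        k <- match(site_choice[cbind(which(a_now), tt)], pop$roosts$site_id)
        cx[a_now] <- pop$roosts$x[k] + stats::rnorm(sum(a_now), 0, 50)
        cy[a_now] <- pop$roosts$y[k] + stats::rnorm(sum(a_now), 0, 50)
        site_night[a_now] <- pop$roosts$site_id[k]
      }
      home <- !a_now & alive
      ## breeding pairs both at home: co-roost at the nest
      co_mate <- rep(FALSE, length(idx))
      if (nrow(pair_tab)) {
        im <- match(pair_tab$male_id, pres_id)
        if_ <- match(pair_tab$female_id, pres_id)
        both_home <- home[im] & home[if_]
        co <- both_home & stats::runif(nrow(pair_tab)) < truth$pair_coroost_prob
        if (any(co)) {
          for (p_ in which(co)) {
            for (b_ in c(im[p_], if_[p_])) {
              cx[b_] <- pair_tab$x[p_] + stats::rnorm(1, 0, 25)
              cy[b_] <- pair_tab$y[p_] + stats::rnorm(1, 0, 25)
              co_mate[b_] <- TRUE
            }
          }
        }
      }
      rest <- home & is.na(cx)
      if (any(rest)) {
        cx[rest] <- pop$territories$x[idx][rest] + stats::rnorm(sum(rest), 0, 150)
        cy[rest] <- pop$territories$y[idx][rest] + stats::rnorm(sum(rest), 0, 150)
      }
      ## kin co-roosting: a non-breeding home bird may join a relative
      co_kin <- rep(FALSE, length(idx))
      if (truth$kin_coroost_prob > 0) {
        cand <- which(home & breeding == 0L)
        base_x <- cx; base_y <- cy
        for (b_ in cand) {
          partners <- sib_of[[pres_id[b_]]]
          partners <- partners[partners %in% pres_id]
          pj <- match(partners, pres_id)
          pj <- pj[!is.na(pj) & home[pj]]
          if (length(pj) && stats::runif(1) < truth$kin_coroost_prob) {
            tgt <- pj[sample.int(length(pj), 1)]
            cx[b_] <- base_x[tgt] + stats::rnorm(1, 0, 25)
            cy[b_] <- base_y[tgt] + stats::rnorm(1, 0, 25)
            co_kin[b_] <- TRUE
          }
        }
      }
      keep <- alive
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        bird_id = pres_id[keep], winter_id = w, night_date = d,
        interval_index = tt, age = age[idx][keep], breeding = breeding[keep],
        attendance = as.integer(a_now[keep]), site_id = site_night[keep],
        x = cx[keep], y = cy[keep], co_mate = co_mate[keep],
        co_kin = co_kin[keep])
    }
  }

  truth_tab <- do.call(rbind, truth_rows)
  if (is.null(truth_tab))
    truth_tab <- data.frame(bird_id = character(), winter_id = integer(),
                            night_date = as.Date(character()),
                            interval_index = integer(), age = integer(),
                            breeding = integer(), attendance = integer(),
                            site_id = character(), x = numeric(), y = numeric(),
                            co_mate = logical(), co_kin = logical())
  rownames(truth_tab) <- NULL
  fixes <- .emit_fixes(truth_tab, config)
  list(fixes = fixes, truth = truth_tab,
       random_effects = do.call(rbind, re_rows))
}

# partners usable for kin co-roosting: intra-year siblings and tagged parents
.kin_partner_list <- function(pop, ids) {
  out <- stats::setNames(vector("list", length(ids)), ids)
  br <- pop$broods
  for (id in ids) {
    k <- which(br$bird_id == id)
    partners <- character()
    if (length(k)) {
      nest <- br$nest_id[k[1]]; yr <- br$year[k[1]]
      partners <- setdiff(br$bird_id[br$nest_id == nest & br$year == yr], id)
      pk <- pop$pairs[pop$pairs$nest_id == nest, , drop = FALSE]
      partners <- c(partners, pk$male_id, pk$female_id)
    }
    out[[id]] <- unique(partners)
  }
  out
}

# duty-cycled nocturnal fixes for each simulated bird-night
.emit_fixes <- function(truth_tab, config) {
  if (is.null(truth_tab) || nrow(truth_tab) == 0)
    return(data.frame(bird_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), x = numeric(), y = numeric()))
  prj <- default_projection()
  dates <- sort(unique(truth_tab$night_date))
  step <- config$fix_interval / 60
  grid <- seq(config$duty_window[1], config$duty_window[2], by = step)
  # evening schedule per date: duty-grid times from civil dusk to duty end,
  # plus next-morning grid times before civil dawn (local = UTC+1)
  sched <- lapply(dates, function(d) {
    dusk_h <- as.numeric(difftime(civil_dusk(d, .ROOST_LON0, .ROOST_LAT0),
                                  as.POSIXct(paste(d, "00:00:00"), tz = "Etc/GMT-1"),
                                  units = "hours"))
    dawn_h <- as.numeric(difftime(civil_dawn(d + 1, .ROOST_LON0, .ROOST_LAT0),
                                  as.POSIXct(paste(d + 1, "00:00:00"), tz = "Etc/GMT-1"),
                                  units = "hours"))
    c(grid[grid >= dusk_h & grid <= config$duty_window[2]],
      24 + grid[grid >= config$duty_window[1] & grid <= dawn_h])
  })
  names(sched) <- as.character(dates)
  nfix <- vapply(sched, length, 0L)[as.character(truth_tab$night_date)]
  n_total <- sum(nfix)
  rep_i <- rep(seq_len(nrow(truth_tab)), nfix)
  hours <- unlist(sched[as.character(truth_tab$night_date)], use.names = FALSE)
  t0 <- as.POSIXct(paste(truth_tab$night_date[rep_i], "00:00:00"),
                   tz = "Etc/GMT-1")
  ts <- t0 + hours * 3600
  attr(ts, "tzone") <- "UTC"
  x <- truth_tab$x[rep_i] + stats::rnorm(n_total, 0, config$within_night_scatter_sd)
  y <- truth_tab$y[rep_i] + stats::rnorm(n_total, 0, config$within_night_scatter_sd)
  ll <- unproject_xy(cbind(x, y), prj)
  fx <- data.frame(bird_id = truth_tab$bird_id[rep_i], timestamp = ts,
                   lon = ll[, 1], lat = ll[, 2], x = x, y = y)
  fx <- fx[order(fx$bird_id, fx$timestamp), , drop = FALSE]
  rownames(fx) <- NULL
  fx
}

#' Simulate a confirmed-mortality cohort under contrasting mechanisms
#'
#' Generates interval units for a cohort of birds that all die during the
#' study (longevity known), under one of two generative mechanisms:
#' `"plasticity"` — attendance declines within individuals with age (the
#' quadratic age effect of [attendance_truth()]) while longevity is
#' unrelated to roosting; `"selective_mortality"` — attendance is constant
#' within individuals but birds with high roosting propensity die young
#' (attendance depends on longevity, log-odds `beta_longevity` per SD, with
#' no age effect). Under both, death truncates observation at the longevity
#' age, so a population-level age decline appears in either case; only the
#' model suite can tell the mechanisms apart.
#'
#' @param mechanism `"plasticity"` or `"selective_mortality"`.
#' @param n_birds Number of confirmed-dead birds (default 43).
#' @param truth An [attendance_truth()] supplying the shared parameters.
#' @param beta_longevity Selective-mortality effect, log-odds per SD of
#'   longevity (default -1.5; ignored under `"plasticity"`).
#' @param max_longevity Longest longevity (winters, default 6).
#' @param seed Integer seed.
#' @return List with `units` (interval units for [plasticity_mortality_suite()])
#'   and `deaths` (`bird_id`, `longevity`).
#' @export
simulate_mortality_cohort <- function(mechanism = c("plasticity", "selective_mortality"),
                                      n_birds = 43, truth = attendance_truth(),
                                      beta_longevity = -1.5, max_longevity = 6,
                                      seed = 1) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  n_int <- n_intervals_per_winter(5)
  idx <- seq_len(n_int)
  t_std <- (idx - mean(idx)) / stats::sd(idx)
  longevity <- sample(2:max_longevity, n_birds, replace = TRUE)
  lon_std <- (longevity - mean(longevity)) / stats::sd(longevity)
  sex <- ifelse(stats::runif(n_birds) < 0.5, "m", "f")
  u <- stats::rnorm(n_birds, 0, truth$sd_bird)
  start_p <- c(0.25, 0.5, 0.6)
  units <- list(); k <- 0
  for (i in seq_len(n_birds)) {
    breeding <- 0L
    for (age in seq_len(longevity[i])) {
      if (breeding == 0L && age >= 3 &&
          stats::runif(1) < start_p[min(age - 2, length(start_p))])
        breeding <- 1L
      eta <- truth$beta_intercept + truth$beta_sex_male * (sex[i] == "m") +
        truth$beta_breeding * breeding + u[i]
      eta <- if (mechanism == "plasticity")
        eta + truth$beta_age * .std_age(age) + truth$beta_age2 * .std_age(age)^2
      else eta + beta_longevity * lon_std[i]
      k <- k + 1
      units[[k]] <- data.frame(
        bird_id = sprintf("D%03d", i), winter_id = 2016L + age - 1L,
        interval_index = idx, interval_t = t_std,
        attendance = stats::rbinom(n_int, 1, stats::plogis(eta)),
        weight = 1, sex = sex[i], tag_class = "juvenile", age = age,
        breeding_status = breeding, n_nights_observed = 5L)
    }
  }
  list(units = do.call(rbind, units),
       deaths = data.frame(bird_id = sprintf("D%03d", seq_len(n_birds)),
                           longevity = longevity))
}

#' Simulate interval units directly from the attendance model
#'
#' Draws bird x winter x five-night-interval attendance directly from the
#' generative mixed model (no spatial layer), for model validation at a
#' chosen population size. Breeding begins no earlier than age 3 and is
#' persistent; weights are 1.
#'
#' @param truth An [attendance_truth()].
#' @param n_birds Number of juvenile-tagged birds.
#' @param n_winters Number of winters.
#' @param start_age_range Inclusive range of first-winter ages.
#' @param seed Integer seed.
#' @return Data frame of interval units ready for [fit_attendance()], with
#'   attribute `random_effects`.
#' @export
simulate_interval_units <- function(truth = attendance_truth(), n_birds = 150,
                                    n_winters = 4, start_age_range = c(1, 4),
                                    seed = 1) {
  set.seed(seed)
  n_int <- n_intervals_per_winter(5)
  idx <- seq_len(n_int)
  t_std <- (idx - mean(idx)) / stats::sd(idx)
  birds <- sprintf("B%03d", seq_len(n_birds))
  sex <- ifelse(stats::runif(n_birds) < 0.5, "m", "f")
  age0 <- sample(start_age_range[1]:start_age_range[2], n_birds, replace = TRUE)
  u <- stats::rnorm(n_birds, 0, truth$sd_bird)
  w <- stats::rnorm(n_winters, 0, truth$sd_winter)
  start_p <- c(0.25, 0.5, 0.6)
  units <- vector("list", n_birds * n_winters)
  k <- 0
  for (i in seq_len(n_birds)) {
    breeding <- 0L
    for (wi in seq_len(n_winters)) {
      age <- age0[i] + wi - 1L
      if (breeding == 0L && age >= 3 &&
          stats::runif(1) < start_p[min(age - 2, length(start_p))])
        breeding <- 1L
      bw <- .draw_bw_effects(1, truth)
      eta <- truth$beta_intercept + truth$beta_age * .std_age(age) +
        truth$beta_age2 * .std_age(age)^2 +
        truth$beta_sex_male * (sex[i] == "m") +
        truth$beta_breeding * breeding +
        (truth$beta_season + bw[2]) * t_std + u[i] + bw[1] + w[wi]
      k <- k + 1
      units[[k]] <- data.frame(
        bird_id = birds[i], winter_id = 2016L + wi - 1L,
        interval_index = idx, interval_t = t_std,
        attendance = stats::rbinom(n_int, 1, stats::plogis(eta)),
        weight = 1, sex = sex[i], tag_class = "juvenile",
        age = age, breeding_status = breeding,
        n_nights_observed = 5L)
    }
  }
  out <- do.call(rbind, units)
  rownames(out) <- NULL
  out
}
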