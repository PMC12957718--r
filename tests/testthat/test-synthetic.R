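test_that("configuration validation catches impossible settings", {
  expect_error(population_config(sex_ratio = 1.2), "probabilities")
  expect_error(population_config(n_juvenile_tagged = 0), "positive")
  expect_error(population_config(n_major_roosts = 0, n_satellite_roosts = 2),
               "satellite")
  expect_error(attendance_truth(sd_bird = -1), "non-negative")
  expect_error(attendance_truth(cor_intercept_slope = 1.5), "correlation")
})

test_that("the default population has the study's tagged sample", {
  pop <- generate_population(population_config(seed = 3))
  expect_equal(nrow(pop$individuals), 216)
  expect_equal(sum(pop$individuals$tag_class == "juvenile"), 148)
  expect_equal(sum(pop$individuals$tag_class == "adult"), 68)
  # broods hold 1-3 tagged siblings
  sizes <- table(paste(pop$broods$nest_id, pop$broods$year))
  expect_true(all(sizes >= 1 & sizes <= 3))
  # pairs are male-female with a shared nest, satellites within 2 km of a major
  m_sex <- pop$individuals$sex[match(pop$pairs$male_id, pop$individuals$bird_id)]
  f_sex <- pop$individuals$sex[match(pop$pairs$female_id, pop$individuals$bird_id)]
  expect_true(all(m_sex == "m") && all(f_sex == "f"))
  sat <- pop$roosts[pop$roosts$type == "satellite", ]
  maj <- pop$roosts[pop$roosts$type == "major", ]
  for (i in seq_len(nrow(sat))) {
    d <- sqrt((maj$x - sat$x[i])^2 + (maj$y - sat$y[i])^2)
    expect_lte(min(d), 2000)
  }
  # earliest breeding is in the third winter of life
  juv <- pop$individuals[pop$individuals$tag_class == "juvenile" &
                           !is.na(pop$individuals$first_breeding_winter), ]
  expect_true(all(juv$first_breeding_winter - juv$birth_year + 1 >= 3))
})

test_that("generation and simulation are deterministic under a fixed seed", {
  cfg <- population_config(n_juvenile_tagged = 20, n_adult_tagged = 8,
                           n_winters = 2, seed = 11)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$individuals, p2$individuals)
  expect_identical(p1$broods, p2$broods)
  s1 <- simulate_winter_nights(p1)
  s2 <- simulate_winter_nights(p2)
  expect_identical(s1$fixes, s2$fixes)
  expect_identical(s1$truth, s2$truth)
})

test_that("within-night scatter reproduces the ~19 m median fix distance", {
  cfg <- population_config(n_juvenile_tagged = 25, n_adult_tagged = 10,
                           n_winters = 1, seed = 21)
  sim <- simulate_winter_nights(generate_population(cfg))
  fx <- sim$fixes
  key <- paste(fx$bird_id, as.Date(format(fx$timestamp - 12 * 3600,
                                          tz = "Etc/GMT-1")))
  dists <- unlist(tapply(seq_len(nrow(fx)), key, function(ii) {
    if (length(ii) < 2) return(NULL)
    as.numeric(dist(cbind(fx$x[ii], fx$y[ii])))
  }))
  expect_gt(length(dists), 1000)
  expect_lt(abs(median(dists) - 18.9), 18.9 * 0.2)
})

test_that("the male attendance advantage propagates to simulated nights", {
  cfg <- population_config(n_juvenile_tagged = 60, n_adult_tagged = 20,
                           n_winters = 2, seed = 31)
  pop <- generate_population(cfg)
  sim <- simulate_winter_nights(pop)
  sex <- pop$individuals$sex[match(sim$truth$bird_id, pop$individuals$bird_id)]
  expect_gt(mean(sim$truth$attendance[sex == "m"]),
            mean(sim$truth$attendance[sex == "f"]))
})

test_that("forced pair co-roosting places both mates at the shared nest", {
  cfg <- population_config(n_juvenile_tagged = 30, n_adult_tagged = 20,
                           n_winters = 2, seed = 41)
  # suppress attendance entirely so all pair-nights are at-home nights
  truth <- attendance_truth(beta_intercept = -30, beta_sex_male = 0,
                            sd_bird = 0, sd_bird_winter = 0, sd_slope = 0,
                            sd_winter = 0, pair_coroost_prob = 1)
  pop <- generate_population(cfg, truth)
  sim <- simulate_winter_nights(pop)
  expect_true(all(sim$truth$attendance == 0))
  co <- sim$truth[sim$truth$co_mate, ]
  expect_gt(nrow(co), 100)
  pr <- pop$pairs
  key <- c(paste(pr$male_id, pr$year), paste(pr$female_id, pr$year))
  nx <- rep(pr$x, 2); ny <- rep(pr$y, 2)
  m <- match(paste(co$bird_id, co$winter_id), key)
  expect_false(anyNA(m))
  d <- sqrt((co$x - nx[m])^2 + (co$y - ny[m])^2)
  # placement jitter is 25 m per coordinate; 4 sd covers the Rayleigh tail
  expect_lt(quantile(d, 0.99), 100)
  expect_lt(median(d), 50)
})

test_that("without roost sites no communal units arise on distinct territories", {
  cfg <- population_config(n_juvenile_tagged = 30, n_adult_tagged = 10,
                           n_winters = 1, n_major_roosts = 0,
                           n_satellite_roosts = 0, seed = 51)
  truth <- attendance_truth(pair_coroost_prob = 0, kin_coroost_prob = 0)
  sim <- simulate_winter_nights(generate_population(cfg, truth))
  expect_true(all(sim$truth$attendance == 0))
  nights <- assign_intervals(extract_night_locations(sim$fixes))
  det <- detect_attendance(nights)
  oracle <- brute_force_attendance(nights)
  expect_equal(det$units$attendance, oracle$attendance)
  expect_true(all(det$units$attendance == 0))
})

test_that("every emitted bird-night appears exactly once in the truth table", {
  cfg <- population_config(n_juvenile_tagged = 20, n_adult_tagged = 8,
                           n_winters = 2, seed = 61)
  sim <- simulate_winter_nights(generate_population(cfg))
  tkey <- paste(sim$truth$bird_id, sim$truth$night_date)
  expect_false(any(duplicated(tkey)))
  fx <- sim$fixes
  fkey <- unique(paste(fx$bird_id, as.Date(format(fx$timestamp - 12 * 3600,
                                                  tz = "Etc/GMT-1"))))
  expect_true(all(fkey %in% tkey))
})

test_that("unit-level attendance frequencies converge to the linear predictor", {
  truth <- attendance_truth(sd_bird = 0, sd_bird_winter = 0, sd_slope = 0,
                            sd_winter = 0, beta_season = 0)
  u <- simulate_interval_units(truth, n_birds = 400, n_winters = 2, seed = 71)
  for (sx in c("f", "m")) {
    cell <- u[u$sex == sx & u$age == 2 & u$breeding_status == 0, ]
    p_theory <- plogis(truth$beta_intercept + truth$beta_age * (2 - 3.5) / 1.5 +
                         truth$beta_age2 * ((2 - 3.5) / 1.5)^2 +
                         truth$beta_sex_male * (sx == "m"))
    mc_se <- sqrt(p_theory * (1 - p_theory) / nrow(cell))
    expect_lt(abs(mean(cell$attendance) - p_theory), 4 * mc_se)
  }
})

test_that("fixture files round-trip byte-identically", {
  cfg <- population_config(n_juvenile_tagged = 10, n_adult_tagged = 4,
                           n_winters = 2, seed = 81)
  pop <- generate_population(cfg)
  sim <- simulate_winter_nights(pop)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(pop, sim, d1)
  back <- read_fixture(d1)
  # re-write from the parsed data: fixes must be byte-identical
  sim2 <- sim
  sim2$fixes <- back$fixes
  write_fixture(pop, sim2, d2)
  for (f in c("fixes.csv", "individuals.csv", "broods.csv", "pairs.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # night medians recomputed from parsed WGS84 fixes match planar truth
  fx <- project_coordinates(back$fixes, back$projection)
  nl <- extract_night_locations(fx)
  expect_gt(nrow(nl), 0)
})

test_that("an empty fix table writes a headers-only file", {
  cfg <- population_config(n_juvenile_tagged = 2, n_adult_tagged = 2,
                           n_winters = 1, seed = 91)
  pop <- generate_population(cfg)
  sim <- simulate_winter_nights(pop)
  sim$fixes <- sim$fixes[0, ]
  sim$truth <- sim$truth[0, ]
  d <- withr::local_tempdir()
  write_fixture(pop, sim, d)
  expect_equal(readLines(file.path(d, "fixes.csv")), "bird_id,timestamp,lon,lat")
})
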