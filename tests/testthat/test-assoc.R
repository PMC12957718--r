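# Hand-built registry: pair P-Q raised chicks A and B at nest N1 in 2018;
# pair R-S nested at N2 the same season.
hand_broods <- data.frame(nest_id = "N1", year = 2018,
                          bird_id = c("A", "B"), x = 0, y = 0)
hand_pairs <- data.frame(year = 2018, male_id = c("P", "R"),
                         female_id = c("Q", "S"), nest_id = c("N1", "N2"),
                         x = c(0, 5000), y = c(0, 0))
hand_ind <- data.frame(bird_id = c("A", "B", "P", "Q", "R", "S"),
                       sex = c("m", "f", "m", "f", "m", "f"),
                       tag_class = c("juvenile", "juvenile", rep("adult", 4)))

test_that("the registry derives mates, siblings and parent-offspring links", {
  reg <- build_relatedness_registry(hand_broods, hand_pairs, hand_ind)
  expect_equal(nrow(reg$siblings), 1)
  expect_equal(c(reg$siblings$bird1, reg$siblings$bird2), c("A", "B"))
  expect_equal(nrow(reg$mates), 2)
  po <- reg$parent_offspring
  expect_equal(nrow(po), 4)
  expect_setequal(paste(po$parent_id, po$chick_id),
                  c("P A", "P B", "Q A", "Q B"))
})

test_that("inconsistent registries are rejected", {
  expect_error(build_relatedness_registry(
    rbind(hand_broods, data.frame(nest_id = "N9", year = 2018,
                                  bird_id = "A", x = 1, y = 1)),
    hand_pairs, hand_ind), "two broods")
  expect_error(build_relatedness_registry(
    hand_broods,
    rbind(hand_pairs, data.frame(year = 2018, male_id = "P", female_id = "S",
                                 nest_id = "N3", x = 1, y = 1)),
    hand_ind), "conflicting pair")
})

test_that("bird-nights are classified into the four association categories", {
  reg <- build_relatedness_registry(hand_broods, hand_pairs, hand_ind)
  d <- as.Date("2018-11-16")
  # R and S 50 m apart at their nest; A with sibling B inside a 12-bird roost
  crowd <- data.frame(bird_id = sprintf("X%02d", 1:10), night_date = d,
                      x = 20000 + runif(10, 0, 100), y = runif(10, 0, 100),
                      n_fixes = 1L)
  nights <- assign_intervals(rbind(
    data.frame(bird_id = c("R", "S"), night_date = d, x = c(5000, 5050),
               y = 0, n_fixes = 1L),
    data.frame(bird_id = c("A", "B"), night_date = d,
               x = c(20050, 20080), y = c(50, 20), n_fixes = 1L),
    crowd))
  det <- detect_attendance(nights)
  rec <- classify_association_nights(nights, det$units, reg)
  expect_setequal(rec$bird_id, c("R", "S", "A", "B"))
  r_rec <- rec[rec$bird_id == "R", ]
  expect_equal(r_rec$communal, 0L)          # only one other bird within 300 m
  expect_equal(r_rec$with_mate_or_kin, 1L)
  expect_equal(r_rec$partner_type, "mate")
  expect_equal(r_rec$nest_distance, 0)
  a_rec <- rec[rec$bird_id == "A", ]
  expect_equal(a_rec$communal, 1L)          # 11 others within the buffer
  expect_equal(a_rec$partner_type, "sibling")
})

test_that("classification matches the brute-force oracle on a synthetic world", {
  w <- make_assoc_world(seed = 17, n_juv = 30, n_ad = 12, n_winters = 2)
  rec <- classify_association_nights(w$nights, w$det$units, w$registry)
  oracle <- brute_force_with_kin(rec, w$nights, w$registry)
  expect_equal(rec$with_mate_or_kin, oracle)
  # the four categories partition the eligible records
  os <- observed_summaries(rec)
  pct <- os$value[grepl("^pct_", os$statistic)]
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("observed summaries reproduce planted counts exactly", {
  rec <- data.frame(
    bird_id = "Z", winter_id = 2018, interval_index = 1,
    night_date = as.Date("2018-11-01") + 0:9,
    communal = c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0),
    with_mate_or_kin = c(1, 1, 0, 1, 1, 1, 0, 0, 0, 0),
    partner_type = c("mate", "sibling", NA, "mate", "mate",
                     "parent_offspring", NA, NA, NA, NA),
    nest_distance = c(100, 200, 300, 10, 20, 30, 1000, 2000, 400, 3000))
  os <- observed_summaries(rec)
  val <- function(s) os$value[os$statistic == s]
  expect_equal(val("pct_cr_with"), 20)
  expect_equal(val("pct_ncr_with"), 30)
  expect_equal(val("pct_cr_without"), 20)
  expect_equal(val("pct_ncr_without"), 30)
  expect_equal(val("dist_ncr_with"), 20)
  expect_equal(val("type_cr_mate"), 100 * 1 / 5)
  expect_equal(val("type_ncr_mate"), 100 * 2 / 5)
  expect_equal(val("type_cr_sibling"), 100 * 1 / 5)
  expect_equal(val("type_ncr_parent_offspring"), 100 * 1 / 5)
  # degenerate single-category input
  rec2 <- rec[rec$communal == 0 & rec$with_mate_or_kin == 1, ]
  os2 <- observed_summaries(rec2)
  expect_equal(os2$value[os2$statistic == "pct_ncr_with"], 100)
  expect_equal(os2$value[os2$statistic == "pct_cr_with"], 0)
  expect_equal(os2$value[os2$statistic == "type_ncr_mate"], 100 * 2 / 3)
})

test_that("planted pair co-roosting is detected against the permutation null", {
  cfg <- population_config(n_juvenile_tagged = 40, n_adult_tagged = 20,
                           n_winters = 2, seed = 23)
  truth <- attendance_truth(pair_coroost_prob = 1)
  pop <- generate_population(cfg, truth)
  sim <- simulate_winter_nights(pop)
  nights <- assign_intervals(extract_night_locations(sim$fixes))
  det <- detect_attendance(nights)
  reg <- build_relatedness_registry(pop$broods, pop$pairs, pop$individuals)
  rec <- classify_association_nights(nights, det$units, reg)
  pr <- suppressMessages(permute_nests(rec, reg, nights, n_iter = 200, seed = 2))
  # category shares under the identity assignment match the plain summaries
  os <- observed_summaries(rec)
  for (s in c("pct_cr_with", "pct_ncr_with", "pct_cr_without", "pct_ncr_without"))
    expect_equal(pr$observed[pr$statistic == s], os$value[os$statistic == s])
  ncr_with <- pr[pr$statistic == "pct_ncr_with", ]
  expect_equal(ncr_with$direction, "greater")
  expect_gt(ncr_with$observed, ncr_with$null_mean)
  expect_lt(ncr_with$p_value, 0.01)
  d_ncr <- pr[pr$statistic == "dist_ncr_with", ]
  expect_equal(d_ncr$direction, "less")
  expect_lt(d_ncr$observed, d_ncr$null_mean)
  # boundary p-values are labelled as below the permutation resolution
  zero <- pr$p_value == 0 & !is.na(pr$p_value)
  expect_true(all(pr$p_label[zero] == paste0("< ", format(1 / 200))))
  expect_true(all(pr$p_value >= 0 & pr$p_value <= 1, na.rm = TRUE))
})

test_that("the seasonal trend model recovers a planted interval slope", {
  make_rec <- function(slope, seed) {
    set.seed(seed)
    grid <- expand.grid(bird_id = sprintf("B%02d", 1:40), interval_index = 1:19)
    t_std <- (grid$interval_index - 10) / sd(1:19)
    p <- plogis(-1 + slope * t_std)
    data.frame(bird_id = grid$bird_id, winter_id = 2018,
               interval_index = grid$interval_index,
               night_date = as.Date("2018-11-01") + (grid$interval_index - 1) * 5,
               communal = 0L, with_mate_or_kin = rbinom(nrow(grid), 1, p),
               partner_type = ifelse(rbinom(nrow(grid), 1, p) == 1, "mate", NA),
               nest_distance = 100)
  }
  tr <- suppressWarnings(seasonal_association_trend(make_rec(1.0, 31)))
  expect_gt(tr$mates$slope, 0)
  expect_gt(tr$mates$lower, 0)
  tr0 <- suppressWarnings(seasonal_association_trend(make_rec(0, 32)))
  expect_lt(tr0$mates$lower, 0)
  expect_gt(tr0$mates$upper, 0)
  # single bird reduces to ordinary logistic regression
  one <- make_rec(1.0, 33)
  one <- one[one$bird_id == "B01", ]
  one$with_mate_or_kin[1:5] <- 1L; one$partner_type[1:5] <- "mate"
  tr1 <- suppressWarnings(seasonal_association_trend(one))
  expect_s3_class(tr1$mates$model, "glm")
  # all-zero kin response is skipped with a warning
  expect_warning(seasonal_association_trend(make_rec(0.5, 34)), "kin")
})
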