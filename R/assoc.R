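# Assortative roosting with breeding mates and kin.
#
# Bird-nights of individuals that could have been observed with a tagged
# mate, parent, offspring or intra-year sibling are classified into the four
# cells of {communal, non-communal} x {with, without mate-or-kin}, and the
# observed cell shares, nest distances and association-type shares are
# compared with node-permutation nulls that randomise nest/brood identity
# while keeping the spatial data fixed.

#' Build the relatedness registry
#'
#' Derives mate, parent-offspring and sibling links and per-bird nest
#' coordinates from the brood and pair registries. Mates are year-specific
#' (two birds nesting together that season); parent-offspring and sibling
#' links are permanent. A dyad carrying several labels resolves with
#' precedence mate > parent-offspring > sibling.
#'
#' @param broods Data frame `nest_id`, `year`, `bird_id`, `x`, `y` (one row
#'   per tagged chick).
#' @param pairs Data frame `year`, `male_id`, `female_id`, `nest_id`, `x`,
#'   `y` (one row per pair-year).
#' @param individuals Individual table (used for tag class and natal nests).
#' @return Object of class `relatedness_registry`.
#' @export
build_relatedness_registry <- function(broods, pairs, individuals) {
  # consistency: a bird belongs to at most one brood per year, one mate per year
  if (nrow(broods)) {
    dup <- duplicated(broods[, c("bird_id", "year")])
    if (any(dup)) stop("bird in two broods of one year: ",
                       paste(unique(broods$bird_id[dup]), collapse = ", "))
  }
  if (nrow(pairs)) {
    long <- rbind(data.frame(bird = pairs$male_id, year = pairs$year),
                  data.frame(bird = pairs$female_id, year = pairs$year))
    dup <- duplicated(long)
    if (any(dup)) stop("conflicting pair records within a year for: ",
                       paste(unique(long$bird[dup]), collapse = ", "))
  }

  mates <- if (nrow(pairs)) data.frame(
    year = pairs$year, bird1 = pmin(pairs$male_id, pairs$female_id),
    bird2 = pmax(pairs$male_id, pairs$female_id)) else
    data.frame(year = integer(), bird1 = character(), bird2 = character())

  siblings <- NULL
  po <- NULL
  if (nrow(broods)) {
    for (key in unique(paste(broods$nest_id, broods$year))) {
      rows <- broods[paste(broods$nest_id, broods$year) == key, , drop = FALSE]
      ids <- rows$bird_id
      if (length(ids) > 1) {
        cmb <- utils::combn(sort(ids), 2)
        siblings <- rbind(siblings, data.frame(bird1 = cmb[1, ], bird2 = cmb[2, ]))
      }
      pr <- pairs[pairs$nest_id == rows$nest_id[1] & pairs$year == rows$year[1], ,
                  drop = FALSE]
      if (nrow(pr) == 1)
        po <- rbind(po, data.frame(
          parent_id = rep(c(pr$male_id, pr$female_id), each = length(ids)),
          chick_id = rep(ids, 2)))
    }
  }
  if (is.null(siblings)) siblings <- data.frame(bird1 = character(), bird2 = character())
  if (is.null(po)) po <- data.frame(parent_id = character(), chick_id = character())

  natal <- broods[!duplicated(broods$bird_id), c("bird_id", "nest_id", "x", "y")]
  structure(list(mates = mates, parent_offspring = po, siblings = siblings,
                 broods = broods, pairs = pairs, natal = natal,
                 individuals = individuals),
            class = "relatedness_registry")
}

#' @export
print.relatedness_registry <- function(x, ...) {
  cat(sprintf("Relatedness registry: %d pair-years, %d parent-offspring links, %d sibling dyads\n",
              nrow(x$mates), nrow(x$parent_offspring), nrow(x$siblings)))
  invisible(x)
}

# canonical dyad keys for fast membership tests
.relation_sets <- function(registry) {
  list(
    mate = paste(registry$mates$year, registry$mates$bird1, registry$mates$bird2),
    po = unique(paste(pmin(registry$parent_offspring$parent_id,
                           registry$parent_offspring$chick_id),
                      pmax(registry$parent_offspring$parent_id,
                           registry$parent_offspring$chick_id))),
    sib = unique(paste(registry$siblings$bird1, registry$siblings$bird2)))
}

# all relatives (any label) of each bird, with mate years
.relatives_of <- function(registry) {
  edges <- rbind(
    data.frame(a = registry$mates$bird1, b = registry$mates$bird2),
    data.frame(a = registry$parent_offspring$parent_id,
               b = registry$parent_offspring$chick_id),
    data.frame(a = registry$siblings$bird1, b = registry$siblings$bird2))
  edges <- rbind(edges, data.frame(a = edges$b, b = edges$a))
  split(edges$b, edges$a)
}

# nest coordinates per (bird, year): breeding nest that season if the bird
# nested, otherwise the natal nest; NA if neither is known
.bird_nest_xy <- function(registry, bird_id, year) {
  n <- length(bird_id)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  if (nrow(registry$pairs)) {
    pk <- c(paste(registry$pairs$male_id, registry$pairs$year),
            paste(registry$pairs$female_id, registry$pairs$year))
    px <- rep(registry$pairs$x, 2); py <- rep(registry$pairs$y, 2)
    m <- match(paste(bird_id, year), pk)
    x <- px[m]; y <- py[m]
  }
  miss <- is.na(x)
  if (any(miss) && nrow(registry$natal)) {
    m <- match(bird_id[miss], registry$natal$bird_id)
    x[miss] <- registry$natal$x[m]; y[miss] <- registry$natal$y[m]
  }
  cbind(x = x, y = y)
}

#' Classify bird-nights by association type
#'
#' For every night of every bird with at least one tagged mate or kin
#' holding night locations in the same five-night interval (the eligibility
#' rule), records whether the bird was at a communal roost (interval-level
#' attendance flag), whether a labelled partner's nightly median lay within
#' the co-roosting radius that night, which partner types were involved, and
#' the distance from the night location to the bird's nest.
#'
#' @param nights Night locations annotated by [assign_intervals()].
#' @param units Attendance units from [detect_attendance()] (same run).
#' @param registry A [build_relatedness_registry()].
#' @param config [detection_config()]; the co-roosting radius reuses the
#'   detection radius.
#' @param in_country Optional polygon (planar metres); when given, a
#'   relative only confers eligibility in intervals where it has night
#'   locations inside the polygon.
#' @return Data frame of association records (one row per eligible
#'   bird-night): `bird_id`, `night_date`, `winter_id`, `interval_index`,
#'   `communal`, `with_mate_or_kin`, `partner_type` (precedence-resolved),
#'   `partner_types`, `nest_distance`, `x`, `y`.
#' @export
classify_association_nights <- function(nights, units, registry,
                                        config = detection_config(),
                                        in_country = NULL) {
  att_key <- paste(units$bird_id, units$winter_id, units$interval_index)
  rel <- .relatives_of(registry)
  sets <- .relation_sets(registry)

  ## eligibility: relative present (night locations, optionally in-country)
  ## in the same winter x interval
  pres <- nights
  if (!is.null(in_country))
    pres <- pres[point_in_polygon(cbind(pres$x, pres$y), in_country), , drop = FALSE]
  pres_key <- unique(paste(pres$bird_id, pres$winter_id, pres$interval_index))

  has_rel <- vapply(seq_len(nrow(nights)), function(i) {
    r <- rel[[nights$bird_id[i]]]
    if (is.null(r)) return(FALSE)
    any(paste(r, nights$winter_id[i], nights$interval_index[i]) %in% pres_key)
  }, TRUE)
  rec <- nights[has_rel, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no eligible bird-nights (no tagged relatives co-occurring)")

  rec$communal <- units$attendance[match(
    paste(rec$bird_id, rec$winter_id, rec$interval_index), att_key)]

  ## proximity partners per night
  prox <- .proximity_pairs(nights, config$radius)
  rec_key <- paste(rec$bird_id, rec$night_date)
  prox <- prox[paste(prox$bird, prox$night_date) %in% rec_key, , drop = FALSE]
  ptype <- .pair_types(prox$bird, prox$partner, prox$winter_id, sets)
  prox <- prox[!is.na(ptype), , drop = FALSE]
  ptype <- ptype[!is.na(ptype)]

  pk <- paste(prox$bird, prox$night_date)
  rec$with_mate_or_kin <- as.integer(rec_key %in% pk)
  types_by_key <- split(ptype, pk)
  rec$partner_types <- vapply(types_by_key[rec_key], function(tt) {
    if (is.null(tt)) "" else paste(sort(unique(tt)), collapse = ",")
  }, "", USE.NAMES = FALSE)
  prec <- c("mate", "parent_offspring", "sibling")
  rec$partner_type <- vapply(strsplit(rec$partner_types, ","), function(tt) {
    hit <- prec[prec %in% tt]
    if (length(hit)) hit[1] else NA_character_
  }, "")

  nest <- .bird_nest_xy(registry, rec$bird_id, rec$winter_id)
  rec$nest_distance <- sqrt((rec$x - nest[, "x"])^2 + (rec$y - nest[, "y"])^2)
  rownames(rec) <- NULL
  attr(rec, "radius") <- config$radius
  rec
}

# bird-night pairs within radius (directed: one row per focal bird)
.proximity_pairs <- function(nights, radius) {
  out <- lapply(split(nights, nights$night_date), function(b) {
    m <- nrow(b)
    if (m < 2) return(NULL)
    dx <- outer(b$x, b$x, "-"); dy <- outer(b$y, b$y, "-")
    hit <- which((dx * dx + dy * dy) <= radius * radius &
                   outer(b$bird_id, b$bird_id, "!="), arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(bird = b$bird_id[hit[, 1]], partner = b$bird_id[hit[, 2]],
               night_date = b$night_date[1], winter_id = b$winter_id[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bird = character(), partner = character(),
                      night_date = as.Date(character()), winter_id = integer())
  out
}

# label of a (focal, partner) pair in a given winter, with precedence
.pair_types <- function(bird, partner, winter, sets) {
  k2 <- paste(pmin(bird, partner), pmax(bird, partner))
  ky <- paste(winter, pmin(bird, partner), pmax(bird, partner))
  type <- rep(NA_character_, length(bird))
  type[k2 %in% sets$sib] <- "sibling"
  type[k2 %in% sets$po] <- "parent_offspring"
  type[ky %in% sets$mate] <- "mate"
  type
}

.CATEGORIES <- c("cr_with", "ncr_with", "cr_without", "ncr_without")

.category_of <- function(communal, with) {
  ifelse(communal == 1,
         ifelse(with == 1, "cr_with", "cr_without"),
         ifelse(with == 1, "ncr_with", "ncr_without"))
}

#' Observed association summaries
#'
#' Cell percentages of eligible bird-nights over {communal, non-communal} x
#' {with, without mate-or-kin}, the mean nest distance per cell, and the
#' association-type shares (mate / parent-offspring / sibling, split by
#' communal context) among all with-mate-or-kin records.
#'
#' @param records Output of [classify_association_nights()].
#' @return Data frame `statistic`, `value` (percentages in 0--100, distances
#'   in metres).
#' @export
observed_summaries <- function(records) {
  if (nrow(records) == 0) stop("no records")
  cat_ <- .category_of(records$communal, records$with_mate_or_kin)
  n <- nrow(records)
  out <- data.frame(statistic = paste0("pct_", .CATEGORIES),
                    value = vapply(.CATEGORIES, function(cc)
                      100 * sum(cat_ == cc) / n, 0))
  dist <- vapply(.CATEGORIES, function(cc) {
    d <- records$nest_distance[cat_ == cc]
    if (all(is.na(d)) || !length(d)) NA_real_ else mean(d, na.rm = TRUE)
  }, 0)
  out <- rbind(out, data.frame(statistic = paste0("dist_", .CATEGORIES),
                               value = dist))
  nw <- sum(records$with_mate_or_kin == 1)
  for (ctx in c("cr", "ncr")) {
    comm <- if (ctx == "cr") 1L else 0L
    for (tp in c("mate", "parent_offspring", "sibling")) {
      cnt <- sum(records$with_mate_or_kin == 1 & records$communal == comm &
                   records$partner_type == tp, na.rm = TRUE)
      out <- rbind(out, data.frame(
        statistic = paste0("type_", ctx, "_", tp),
        value = if (nw) 100 * cnt / nw else NA_real_))
    }
  }
  rownames(out) <- NULL
  out
}

#' Nest-permutation null models for assortative roosting
#'
#' Keeps the spatial data (night locations, communal flags, record set)
#' fixed and randomises nest identity: within each cohort year the natal
#' brood assignment of juvenile-tagged birds is shuffled (re-deriving sibling
#' and parent-offspring links and natal nests), and within each breeding
#' season the male->nest and female->nest assignments are shuffled
#' independently (re-deriving mate links as co-assignment and breeding-nest
#' coordinates). Every statistic of [observed_summaries()] is re-evaluated
#' per iteration, with nest distances measured from the bird's average
#' roosting location that winter to its (permuted) nest. The observed values
#' are computed through the same evaluation path with the identity
#' assignment, so observed and null statistics are exchangeable under no
#' assortment; directional p-values are the proportion of null draws at
#' least as extreme as the observed value on the side where it lies. The
#' null draws are attached as attribute `"null"`.
#'
#' @param records Output of [classify_association_nights()].
#' @param registry The [build_relatedness_registry()] used to classify.
#' @param nights Annotated night locations (for average roosting locations).
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame of class `permutation_result`: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `direction`, `p_value`, `p_label`, `n_iter`.
#' @export
permute_nests <- function(records, registry, nights, n_iter = 1000, seed = 1) {
  set.seed(seed)
  stat_names <- observed_summaries(records)$statistic

  ## fixed per-record structures ------------------------------------------
  rec_key <- paste(records$bird_id, records$night_date)
  prox <- .proximity_pairs(nights, attr(records, "radius") %||% 300)
  prox <- prox[paste(prox$bird, prox$night_date) %in% rec_key, , drop = FALSE]
  prox$rec_idx <- match(paste(prox$bird, prox$night_date), rec_key)
  prox$k2 <- paste(pmin(prox$bird, prox$partner), pmax(prox$bird, prox$partner))

  # average roosting location per bird-winter
  bw_key <- paste(nights$bird_id, nights$winter_id)
  avg_x <- tapply(nights$x, bw_key, mean); avg_y <- tapply(nights$y, bw_key, mean)
  rec_bw <- paste(records$bird_id, records$winter_id)
  rx <- as.numeric(avg_x[rec_bw]); ry <- as.numeric(avg_y[rec_bw])

  ## permutable assignments ------------------------------------------------
  br <- registry$broods
  brood_tab <- br[!duplicated(paste(br$nest_id, br$year)), c("nest_id", "year", "x", "y")]
  chick <- data.frame(bird_id = br$bird_id, year = br$year,
                      brood = match(paste(br$nest_id, br$year),
                                    paste(brood_tab$nest_id, brood_tab$year)))
  pairs <- registry$pairs
  singleton_years <- c(
    names(which(tapply(chick$brood, chick$year, function(b) length(unique(b))) < 2)),
    names(which(table(pairs$year) < 2)))
  if (length(singleton_years))
    message("year(s) with a single brood/nest kept fixed: ",
            paste(unique(singleton_years), collapse = ", "))

  perm_relations <- function(chick_perm, male_nest, female_nest) {
    # chick_perm: brood index per chick row; male/female_nest: nest row per pair row
    sib <- character(0); po <- character(0); mate <- character(0)
    for (bidx in unique(chick_perm)) {
      ids <- chick$bird_id[chick_perm == bidx]
      if (length(ids) > 1) {
        cmb <- utils::combn(sort(ids), 2)
        sib <- c(sib, paste(cmb[1, ], cmb[2, ]))
      }
    }
    if (nrow(pairs)) {
      # mates: birds co-assigned to a nest row within a year
      m_at <- pairs$male_id[order(male_nest)]
      f_at <- pairs$female_id[order(female_nest)]
      mate <- paste(pairs$year, pmin(m_at, f_at), pmax(m_at, f_at))
      # parents of a brood: the pair row whose nest matches the brood nest-year
      pk <- paste(pairs$nest_id, pairs$year)
      for (i in seq_len(nrow(brood_tab))) {
        j <- match(paste(brood_tab$nest_id[i], brood_tab$year[i]), pk)
        if (is.na(j)) next
        par_ids <- c(pairs$male_id[which(male_nest == j)],
                     pairs$female_id[which(female_nest == j)])
        ids <- chick$bird_id[chick_perm == i]
        if (length(par_ids) && length(ids))
          po <- c(po, as.vector(outer(par_ids, ids, function(a, b)
            paste(pmin(a, b), pmax(a, b)))))
      }
    }
    list(mate = mate, po = unique(po), sib = unique(sib))
  }

  perm_nest_xy <- function(chick_perm, male_nest, female_nest) {
    # permuted nest per (bird, winter) for all record bird-winters
    ub <- unique(data.frame(bird_id = records$bird_id, winter = records$winter_id))
    x <- rep(NA_real_, nrow(ub)); y <- rep(NA_real_, nrow(ub))
    if (nrow(pairs)) {
      mk <- paste(pairs$male_id, pairs$year); fk <- paste(pairs$female_id, pairs$year)
      key <- paste(ub$bird_id, ub$winter)
      im <- match(key, mk); fi <- match(key, fk)
      x[!is.na(im)] <- pairs$x[male_nest[im[!is.na(im)]]]
      y[!is.na(im)] <- pairs$y[male_nest[im[!is.na(im)]]]
      x[!is.na(fi)] <- pairs$x[female_nest[fi[!is.na(fi)]]]
      y[!is.na(fi)] <- pairs$y[female_nest[fi[!is.na(fi)]]]
    }
    miss <- is.na(x)
    if (any(miss)) {
      m <- match(ub$bird_id[miss], chick$bird_id)
      ok <- !is.na(m)
      x[miss][ok] <- brood_tab$x[chick_perm[m[ok]]]
      y[miss][ok] <- brood_tab$y[chick_perm[m[ok]]]
    }
    ub$x <- x; ub$y <- y
    ub[match(rec_bw, paste(ub$bird_id, ub$winter)), c("x", "y")]
  }

  eval_stats <- function(sets, nest_xy) {
    type <- rep(NA_character_, nrow(prox))
    type[prox$k2 %in% sets$sib] <- "sibling"
    type[prox$k2 %in% sets$po] <- "parent_offspring"
    type[paste(prox$winter_id, prox$k2) %in% sets$mate] <- "mate"
    hit <- !is.na(type)
    with_ <- rep(0L, nrow(records))
    with_[unique(prox$rec_idx[hit])] <- 1L
    ptype <- rep(NA_character_, nrow(records))
    for (tp in c("sibling", "parent_offspring", "mate"))  # ascending precedence
      ptype[prox$rec_idx[hit & type == tp]] <- tp
    cat_ <- .category_of(records$communal, with_)
    n <- nrow(records)
    vals <- vapply(.CATEGORIES, function(cc) 100 * sum(cat_ == cc) / n, 0)
    d <- sqrt((rx - nest_xy$x)^2 + (ry - nest_xy$y)^2)
    dist <- vapply(.CATEGORIES, function(cc) {
      dd <- d[cat_ == cc]
      if (!length(dd) || all(is.na(dd))) NA_real_ else mean(dd, na.rm = TRUE)
    }, 0)
    nw <- sum(with_ == 1)
    types <- c()
    for (ctx in c("cr", "ncr")) {
      comm <- if (ctx == "cr") 1L else 0L
      for (tp in c("mate", "parent_offspring", "sibling"))
        types <- c(types, if (nw) 100 * sum(with_ == 1 & records$communal == comm &
                                              ptype == tp, na.rm = TRUE) / nw else NA_real_)
    }
    c(vals, dist, types)
  }

  ## observed values through the same evaluation path as the null draws
  ## (distance statistics use the bird-winter average roosting location on
  ## both sides, so observed and null are exchangeable under no assortment)
  obs <- data.frame(statistic = stat_names,
                    value = eval_stats(.relation_sets(registry),
                                       perm_nest_xy(chick$brood,
                                                    seq_len(nrow(pairs)),
                                                    seq_len(nrow(pairs)))))

  ## iterations -------------------------------------------------------------
  null <- matrix(NA_real_, n_iter, nrow(obs))
  for (it in seq_len(n_iter)) {
    chick_perm <- chick$brood
    for (y_ in unique(chick$year)) {
      rows <- which(chick$year == y_)
      if (length(unique(chick$brood[rows])) > 1)
        chick_perm[rows] <- sample(chick$brood[rows])
    }
    male_nest <- seq_len(nrow(pairs)); female_nest <- seq_len(nrow(pairs))
    for (y_ in unique(pairs$year)) {
      rows <- which(pairs$year == y_)
      if (length(rows) > 1) {
        male_nest[rows] <- sample(rows)
        female_nest[rows] <- sample(rows)
      }
    }
    sets <- perm_relations(chick_perm, male_nest, female_nest)
    null[it, ] <- eval_stats(sets, perm_nest_xy(chick_perm, male_nest, female_nest))
  }

  null_mean <- colMeans(null, na.rm = TRUE)
  null_sd <- apply(null, 2, stats::sd, na.rm = TRUE)
  direction <- ifelse(obs$value >= null_mean, "greater", "less")
  p <- vapply(seq_len(nrow(obs)), function(j) {
    nj <- null[, j]; nj <- nj[!is.na(nj)]
    if (!length(nj) || is.na(obs$value[j])) return(NA_real_)
    if (direction[j] == "greater") mean(nj >= obs$value[j]) else mean(nj <= obs$value[j])
  }, 0)
  out <- data.frame(statistic = obs$statistic, observed = obs$value,
                    null_mean = null_mean, null_sd = null_sd,
                    direction = direction, p_value = p,
                    p_label = ifelse(is.na(p), NA_character_,
                                     ifelse(p == 0, paste0("< ", format(1 / n_iter)),
                                            format(p))),
                    n_iter = n_iter)
  rownames(out) <- NULL
  colnames(null) <- obs$statistic
  attr(out, "null") <- null
  class(out) <- c("permutation_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Within-season trend in mate and kin co-roosting
#'
#' Aggregates eligible bird-nights to bird x interval (did the bird co-roost
#' with a breeding mate / with kin at least once in the interval) and fits
#' logistic mixed models with the standardised interval sequence as slope and
#' bird as random intercept. The kin model is skipped with a warning when kin
#' co-roosting never occurs; with a single bird the model reduces to an
#' ordinary logistic regression.
#'
#' @param records Output of [classify_association_nights()].
#' @return List with elements `mates` and `kin`, each either `NULL` or a
#'   list with `model`, `slope`, `se`, `lower`, `upper`.
#' @export
seasonal_association_trend <- function(records) {
  key <- paste(records$bird_id, records$winter_id, records$interval_index)
  agg <- data.frame(
    bird_id = tapply(records$bird_id, key, `[`, 1),
    interval_index = as.integer(tapply(records$interval_index, key, `[`, 1)),
    y_mate = as.integer(tapply(records$partner_type == "mate", key, any, na.rm = TRUE)),
    y_kin = as.integer(tapply(records$partner_type %in%
                                c("parent_offspring", "sibling"), key, any, na.rm = TRUE)),
    row.names = NULL)
  n_int <- n_intervals_per_winter(5)
  idx <- seq_len(n_int)
  agg$interval_t <- (agg$interval_index - mean(idx)) / stats::sd(idx)

  fit_one <- function(y, what) {
    if (length(unique(y)) < 2) {
      warning("constant ", what, " response; trend not estimable")
      return(NULL)
    }
    agg$y <- y
    if (length(unique(agg$bird_id)) < 2) {
      m <- stats::glm(y ~ interval_t, family = stats::binomial(), data = agg)
      est <- stats::coef(m)["interval_t"]
      se <- sqrt(diag(stats::vcov(m)))["interval_t"]
    } else {
      m <- suppressMessages(lme4::glmer(y ~ interval_t + (1 | bird_id),
                                        family = stats::binomial(), data = agg))
      est <- lme4::fixef(m)["interval_t"]
      se <- sqrt(diag(as.matrix(stats::vcov(m))))["interval_t"]
    }
    list(model = m, slope = unname(est), se = unname(se),
         lower = unname(est - 1.96 * se), upper = unname(est + 1.96 * se))
  }

  kin <- NULL
  if (all(agg$y_kin == 0)) {
    warning("no kin co-roosting events; kin trend not testable")
  } else kin <- fit_one(agg$y_kin, "kin")
  list(mates = fit_one(agg$y_mate, "mate"), kin = kin)
}
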