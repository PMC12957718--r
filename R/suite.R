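# Separating within-individual behavioural plasticity from selective
# mortality in the age trajectory of communal roosting.
#
# On the subset of birds with confirmed mortality (so longevity, the age at
# death, is known), four weighted binomial models are compared: (1) age only
# (no bird intercept), (2) age + bird intercept, (3) longevity + bird
# intercept, (4) age + longevity + bird intercept. All include sex, breeding
# status, Julian date (days from 1 November; temporal autocorrelation proxy
# suited to the reduced sample) and a winter intercept; age enters
# quadratically. If the age effect persists when longevity is in the model
# while longevity itself is indistinguishable from zero, the population age
# trend reflects within-individual change (plasticity); an effect of
# longevity indicates selective disappearance of birds with particular
# roosting propensities.

.suite_formulas <- function() list(
  age_fixed = attendance ~ age_std + age_std2 + male + breeding_status +
    julian_std + (1 | winter_f),
  age_bird = attendance ~ age_std + age_std2 + male + breeding_status +
    julian_std + (1 | winter_f) + (1 | bird_id),
  longevity_bird = attendance ~ longevity_std + male + breeding_status +
    julian_std + (1 | winter_f) + (1 | bird_id),
  age_longevity_bird = attendance ~ age_std + age_std2 + longevity_std +
    male + breeding_status + julian_std + (1 | winter_f) + (1 | bird_id))

.wald_table <- function(model) {
  est <- glmmTMB::fixef(model)$cond
  se <- sqrt(diag(stats::vcov(model)$cond))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             lower = unname(est - 1.96 * se), upper = unname(est + 1.96 * se))
}

#' Plasticity versus selective-mortality model suite
#'
#' @param units Juvenile-cohort interval units (see [fit_attendance()]).
#' @param deaths Data frame `bird_id`, `longevity` (age at confirmed death,
#'   in winters). Only these birds enter the suite.
#' @param vif_limit Variance-inflation threshold that triggers a
#'   collinearity flag (default 2).
#' @return Object of class `plasticity_suite`: the four fits with
#'   coefficient tables, the VIFs of the fullest fixed-effect design, and an
#'   interpretation label in `"plasticity"`, `"selective_mortality"`,
#'   `"both"`, `"neither"`.
#' @export
plasticity_mortality_suite <- function(units, deaths, vif_limit = 2) {
  if (!all(c("bird_id", "longevity") %in% names(deaths)))
    stop("deaths needs columns bird_id and longevity")
  d <- .prep_model_data(units, "juvenile")
  d <- d[as.character(d$bird_id) %in% deaths$bird_id, , drop = FALSE]
  if (nrow(d) == 0) stop("no units for confirmed-dead birds")
  d$bird_id <- droplevels(d$bird_id)
  d$longevity <- deaths$longevity[match(as.character(d$bird_id), deaths$bird_id)]
  last_age <- tapply(d$age, as.character(d$bird_id), max)
  bad <- names(last_age)[d$longevity[match(names(last_age), as.character(d$bird_id))] < last_age]
  if (length(bad))
    stop("longevity below last observed age for: ", paste(bad, collapse = ", "))
  # standardise age within this cohort: centring the quadratic on the
  # subset mean keeps age and age^2 near-orthogonal
  d$age_std <- as.numeric(scale(d$age))
  d$age_std2 <- d$age_std^2
  # Julian date of the interval midpoint, counted from 1 November
  d$julian <- (d$interval_index - 1) * 5 + 2
  d$julian_std <- as.numeric(scale(d$julian))
  d$longevity_std <- as.numeric(scale(d$longevity))

  forms <- .suite_formulas()
  have_longevity <- length(unique(d$longevity)) >= 2
  if (!have_longevity) {
    warning("fewer than 2 longevity levels; longevity models skipped")
    forms <- forms[c("age_fixed", "age_bird")]
  }
  # REML: longevity is a between-bird covariate and only a few dozen birds
  # have confirmed deaths; ML variance components make its Wald SE
  # anticonservative at this cluster count
  fits <- lapply(forms, function(f)
    .quiet_glmmTMB(glmmTMB::glmmTMB(f, data = d, family = stats::binomial(),
                                    weights = d$weight, REML = TRUE)))
  tables <- lapply(fits, .wald_table)

  vifs <- NULL
  if (have_longevity) {
    vf <- suppressWarnings(stats::glm(
      attendance ~ age_std + age_std2 + longevity_std + male +
        breeding_status + julian_std,
      family = stats::binomial(), data = d, weights = d$weight))
    vifs <- tryCatch(car::vif(vf), error = function(e) {
      warning("VIF not computable (", conditionMessage(e), ")")
      NULL
    })
  }

  label <- NA_character_
  if (have_longevity) {
    tb <- tables$age_longevity_bird
    excl0 <- function(term) {
      r <- tb[tb$term == term, ]
      nrow(r) == 1 && (isTRUE(r$lower > 0) || isTRUE(r$upper < 0))
    }
    age_eff <- excl0("age_std") || excl0("age_std2")
    lon_eff <- excl0("longevity_std")
    label <- if (age_eff && !lon_eff) "plasticity"
      else if (!age_eff && lon_eff) "selective_mortality"
      else if (age_eff && lon_eff) "both"
      else "neither"
  }

  comparison <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]; tb$model <- nm; tb
  }))
  structure(list(fits = fits, tables = tables, comparison = comparison,
                 vif = vifs, vif_flag = isTRUE(any(vifs >= vif_limit)),
                 label = label, n_birds = nlevels(d$bird_id),
                 data = d),
            class = "plasticity_suite")
}

#' @export
print.plasticity_suite <- function(x, ...) {
  cat(sprintf("Plasticity vs selective-mortality suite: %d confirmed-dead birds, %d models\n",
              x$n_birds, length(x$fits)))
  if (!is.na(x$label)) cat("  interpretation:", x$label, "\n")
  if (!is.null(x$vif)) {
    cat(sprintf("  max VIF %.2f%s\n", max(x$vif),
                if (x$vif_flag) " [!] collinearity flagged" else ""))
  }
  full <- x$tables[[length(x$tables)]]
  print(format(full, digits = 3), row.names = FALSE)
  invisible(x)
}
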