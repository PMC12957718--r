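# Weighted binomial mixed models of communal-roost attendance.
#
# The response is attendance (0/1) per bird x five-night interval. The
# juvenile-cohort model has fixed effects for standardised age, its square,
# sex and breeding status; the adult-cohort model has sex only (age unknown,
# all breeding). Both carry a bird random intercept, a correlated
# bird-within-winter random intercept + slope over the standardised interval
# sequence (temporal autocorrelation), a winter random intercept, and
# observation weights that multiply each unit's log-likelihood contribution.
# Estimation is marginal maximum likelihood via the Laplace approximation
# (glmmTMB).

.SEPARATION_LIMIT <- 15  # |logit coefficient| beyond which we flag separation

.prep_model_data <- function(units, cohort) {
  d <- units
  if (!is.null(d$tag_class)) d <- d[d$tag_class == cohort, , drop = FALSE]
  if (nrow(d) == 0) stop("no units for cohort ", cohort)
  if (is.null(d$weight)) d$weight <- 1
  if (any(d$weight < 0 | d$weight > 1)) stop("weights must lie in [0, 1]")
  if (is.null(d$interval_t)) {
    n_int <- n_intervals_per_winter(5)
    idx <- seq_len(n_int)
    d$interval_t <- (d$interval_index - mean(idx)) / stats::sd(idx)
  }
  d$male <- as.integer(d$sex == "m")
  d$bird_id <- factor(d$bird_id)
  d$winter_f <- factor(d$winter_id)
  d$bird_winter <- interaction(d$bird_id, d$winter_f, drop = TRUE)
  if (cohort == "juvenile") {
    if (anyNA(d$age)) stop("juvenile cohort requires known ages")
    d$age_std <- .std_age(d$age)
    d$age_std2 <- d$age_std^2
  }
  d
}

.fixef_terms <- function(cohort, quadratic = TRUE) {
  if (cohort == "juvenile") {
    c("age_std", if (quadratic) "age_std2", "male", "breeding_status")
  } else "male"
}

# glmmTMB warns about non-integer successes for fractional likelihood
# weights; that is exactly the intended weighting, so muffle just that one.
.quiet_glmmTMB <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit the communal-roost attendance model
#'
#' @param units Interval units: `bird_id`, `winter_id`, `interval_index`,
#'   `attendance`, `sex`, `weight` (optional, defaults to 1), and for the
#'   juvenile cohort `age` and `breeding_status`. A `tag_class` column, if
#'   present, subsets to the requested cohort.
#' @param cohort `"juvenile"` (age + age^2 + sex + breeding status) or
#'   `"adult"` (sex only).
#' @param quadratic Include the second-order age term (juvenile cohort;
#'   default TRUE). Setting it `FALSE` gives the linear-age rival for model
#'   selection with [compare_models()].
#' @param use_weights Set `FALSE` to ignore the weight column.
#' @param control Optional [glmmTMB::glmmTMBControl()].
#' @return Object of class `attendance_fit`: coefficient table with 95%
#'   Wald intervals, variance components, fitted probabilities, engine
#'   metadata and flags (`converged`, `separation`).
#' @seealso [predict.attendance_fit()], [adjusted_repeatability()],
#'   [binned_residuals()], [classification_accuracy()], [compare_models()]
#' @examples
#' units <- simulate_interval_units(n_birds = 25, n_winters = 2, seed = 1)
#' fit <- fit_attendance(units, "juvenile")
#' coef(fit)
#' @export
fit_attendance <- function(units, cohort = c("juvenile", "adult"),
                           quadratic = TRUE, use_weights = TRUE,
                           control = NULL) {
  cohort <- match.arg(cohort)
  d <- .prep_model_data(units, cohort)
  if (nlevels(d$bird_id) < 2 || length(unique(d$winter_id)) < 2)
    stop("need at least 2 birds and 2 winters")
  if (!use_weights) d$weight <- 1
  rhs <- paste(c(.fixef_terms(cohort, quadratic),
                 "(1 | bird_id)", "(1 + interval_t | bird_winter)",
                 "(1 | winter_f)"), collapse = " + ")
  form <- stats::as.formula(paste("attendance ~", rhs))
  args <- list(formula = form, data = d, family = stats::binomial(),
               weights = d$weight)
  if (!is.null(control)) args$control <- control
  model <- .quiet_glmmTMB(do.call(glmmTMB::glmmTMB, args))

  est <- glmmTMB::fixef(model)$cond
  se <- sqrt(diag(stats::vcov(model)$cond))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      lower = unname(est - 1.96 * se),
                      upper = unname(est + 1.96 * se))
  vc <- glmmTMB::VarCorr(model)$cond
  varcomp <- list(
    sd_bird = attr(vc$bird_id, "stddev")[[1]],
    sd_bird_winter = attr(vc$bird_winter, "stddev")[[1]],
    sd_slope = attr(vc$bird_winter, "stddev")[[2]],
    cor_intercept_slope = attr(vc$bird_winter, "correlation")[1, 2],
    sd_winter = attr(vc$winter_f, "stddev")[[1]])

  converged <- isTRUE(model$fit$convergence == 0) &&
    isTRUE(model$sdr$pdHess)
  separation <- any(abs(est) > .SEPARATION_LIMIT)
  if (!converged) warning("attendance model did not converge cleanly; ",
                          "inspect $model diagnostics")
  if (separation) warning("possible separation: |coefficient| > ",
                          .SEPARATION_LIMIT, " on the logit scale")
  structure(list(model = model, coefficients = coefs, varcomp = varcomp,
                 fitted = stats::fitted(model), data = d, cohort = cohort,
                 quadratic = quadratic,
                 converged = converged, separation = separation,
                 engine = list(method = "Laplace marginal ML (glmmTMB)",
                               use_weights = use_weights),
                 call = match.call()),
            class = "attendance_fit")
}

#' @export
print.attendance_fit <- function(x, ...) {
  cat(sprintf("Communal-roost attendance model (%s cohort)\n", x$cohort))
  cat(sprintf("  %d units, %d birds, %d winters; %s\n",
              nrow(x$data), nlevels(x$data$bird_id),
              length(unique(x$data$winter_id)), x$engine$method))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  if (!x$converged) cat("  [!] convergence flagged\n")
  if (x$separation) cat("  [!] separation flagged\n")
  invisible(x)
}

#' @export
summary.attendance_fit <- function(object, ...) {
  print(object)
  v <- object$varcomp
  cat(sprintf("Random effects (SD): bird %.3f | bird-winter %.3f, slope %.3f (cor %.2f) | winter %.3f\n",
              v$sd_bird, v$sd_bird_winter, v$sd_slope, v$cor_intercept_slope,
              v$sd_winter))
  cat(sprintf("Adjusted repeatability (latent scale): %.3f\n",
              latent_repeatability(v$sd_bird^2, v$sd_winter^2)))
  invisible(object)
}

#' @export
coef.attendance_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.attendance_fit <- function(object, ...) stats::vcov(object$model)$cond

#' @export
residuals.attendance_fit <- function(object, type = "response", ...) {
  object$data$attendance - object$fitted
}

.model_matrix_for <- function(fit, newdata) {
  terms <- .fixef_terms(fit$cohort, fit$quadratic %||% TRUE)
  nd <- newdata
  nd$male <- as.integer(nd$sex == "m")
  if (fit$cohort == "juvenile") {
    nd$age_std <- .std_age(nd$age)
    nd$age_std2 <- nd$age_std^2
  }
  X <- cbind(1, as.matrix(nd[, terms, drop = FALSE]))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Population-level attendance predictions
#'
#' Expected attendance probability for covariate profiles, marginalised over
#' the random effects by Monte Carlo: coefficient draws from the Wald
#' approximation propagate estimation uncertainty, and for each draw the
#' inverse-logit is averaged over random-effect draws (bird + bird-winter +
#' winter intercepts; the interval-sequence slope contributes nothing at the
#' average interval, where predictions are evaluated).
#'
#' @param object An `attendance_fit`.
#' @param newdata Data frame of covariate profiles (`age`, `sex`,
#'   `breeding_status` for the juvenile cohort; `sex` for the adult cohort).
#' @param n_draws Coefficient draws (default 1000).
#' @param n_re Random-effect draws per coefficient draw (default 400).
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return `newdata` with `fit` (median), `lower`, `upper` appended.
#' @export
predict.attendance_fit <- function(object, newdata, n_draws = 1000,
                                   n_re = 400, seed = 1, level = 0.95, ...) {
  if (object$cohort == "juvenile") {
    rng <- range(object$data$age)
    if (any(newdata$age < rng[1] | newdata$age > rng[2]))
      warning("age outside the fitted range ", rng[1], "-", rng[2],
              "; predictions are extrapolations")
  }
  set.seed(seed)
  X <- .model_matrix_for(object, newdata)
  est <- coef(object)
  V <- vcov(object)
  betas <- MASS::mvrnorm(n_draws, est, V)
  v <- object$varcomp
  s <- sqrt(v$sd_bird^2 + v$sd_bird_winter^2 + v$sd_winter^2)
  z <- stats::rnorm(n_re, 0, 1)
  qs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  out <- t(apply(X %*% t(betas), 1, function(eta_d) {
    p_d <- vapply(eta_d, function(e) mean(stats::plogis(e + s * z)), 0)
    stats::quantile(p_d, qs, names = FALSE)
  }))
  newdata$fit <- out[, 1]; newdata$lower <- out[, 2]; newdata$upper <- out[, 3]
  newdata
}

#' Simulate attendance from a fitted model
#'
#' Draws entirely new random effects from the fitted variance components and
#' a fresh Bernoulli response for every unit of the fitting data (parametric
#' simulation, used by the repeatability bootstrap).
#'
#' @param object An `attendance_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated 0/1 responses.
#' @export
simulate.attendance_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  X <- .model_matrix_for(object, d)
  eta_fix <- drop(X %*% coef(object))
  v <- object$varcomp
  sig_bw <- matrix(c(v$sd_bird_winter^2,
                     v$cor_intercept_slope * v$sd_bird_winter * v$sd_slope,
                     v$cor_intercept_slope * v$sd_bird_winter * v$sd_slope,
                     v$sd_slope^2), 2)
  out <- matrix(NA_integer_, nrow(d), nsim)
  for (s_ in seq_len(nsim)) {
    u <- stats::rnorm(nlevels(d$bird_id), 0, v$sd_bird)
    bw <- if (all(sig_bw == 0)) matrix(0, nlevels(d$bird_winter), 2)
          else MASS::mvrnorm(nlevels(d$bird_winter), c(0, 0), sig_bw)
    w <- stats::rnorm(nlevels(d$winter_f), 0, v$sd_winter)
    eta <- eta_fix + u[as.integer(d$bird_id)] +
      bw[as.integer(d$bird_winter), 1] +
      bw[as.integer(d$bird_winter), 2] * d$interval_t +
      w[as.integer(d$winter_f)]
    out[, s_] <- stats::rbinom(nrow(d), 1, stats::plogis(eta))
  }
  as.data.frame(out)
}

#' Event-rate classification accuracy
#'
#' Converts fitted probabilities to binary predictions with the threshold set
#' to the observed event rate (the proportion of ones in the data) and
#' returns the weight-weighted proportion of correct classifications.
#'
#' @param fit An `attendance_fit`.
#' @return Proportion correct in `[0, 1]`.
#' @export
classification_accuracy <- function(fit) {
  y <- fit$data$attendance
  w <- fit$data$weight
  threshold <- mean(y)
  pred <- as.integer(fit$fitted > threshold)
  sum(w * (pred == y)) / sum(w)
}

#' Binned residual diagnostics
#'
#' Units are sorted by fitted probability and cut into equal-count bins; per
#' bin the mean residual is compared to an approximate +/-2 SE band
#' (`2 * sqrt(mean(p (1 - p)) / n)`). Systematic excursions outside the band
#' indicate misspecification (for a binary response, raw residual plots are
#' uninformative).
#'
#' @param fit An `attendance_fit`.
#' @param n_bins Number of bins (default 20; must not exceed the unit count).
#' @return Data frame of class `binned_residuals`: `bin`, `n`, `mean_fitted`,
#'   `mean_resid`, `band`.
#' @export
binned_residuals <- function(fit, n_bins = 20) {
  n <- nrow(fit$data)
  if (n_bins > n) stop("n_bins exceeds the number of units")
  ord <- order(fit$fitted)
  bin <- ceiling(seq_along(ord) / (n / n_bins))
  p <- fit$fitted[ord]
  r <- (fit$data$attendance - fit$fitted)[ord]
  out <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(table(bin)),
    mean_fitted = as.numeric(tapply(p, bin, mean)),
    mean_resid = as.numeric(tapply(r, bin, mean)),
    band = as.numeric(tapply(p, bin, function(pp) 2 * sqrt(mean(pp * (1 - pp)) / length(pp)))))
  class(out) <- c("binned_residuals", "data.frame")
  out
}

#' @export
plot.binned_residuals <- function(x, ...) {
  graphics::plot(x$mean_fitted, x$mean_resid,
                 xlab = "mean fitted probability", ylab = "mean residual",
                 pch = 16, ylim = range(c(x$mean_resid, x$band, -x$band)), ...)
  graphics::lines(x$mean_fitted, x$band, lty = 2, col = "grey40")
  graphics::lines(x$mean_fitted, -x$band, lty = 2, col = "grey40")
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' @export
plot.attendance_fit <- function(x, n_bins = 20, ...) {
  plot(binned_residuals(x, n_bins), ...)
}

#' Latent-scale repeatability
#'
#' Adjusted repeatability of a binary trait on the link scale:
#' `R = var_bird / (var_bird + var_winter + pi^2 / 3)`, where `pi^2 / 3` is
#' the logit residual variance. Fixed-effect and random-slope variance are
#' excluded (the slope contributes nothing at the average interval).
#'
#' @param var_bird Among-individual variance (link scale).
#' @param var_winter Among-winter variance (link scale).
#' @return Repeatability in `[0, 1]`.
#' @export
latent_repeatability <- function(var_bird, var_winter = 0) {
  if (any(is.na(c(var_bird, var_winter))) || var_bird < 0 || var_winter < 0)
    stop("variances must be non-negative and finite")
  var_bird / (var_bird + var_winter + pi^2 / 3)
}

#' Adjusted repeatability of attendance with bootstrap CI
#'
#' Point estimate from the fitted variance components; optional parametric
#' bootstrap (simulate a new response from the fit, refit, recompute) for a
#' percentile confidence interval.
#'
#' @param fit An `attendance_fit`.
#' @param n_boot Bootstrap replicates (0 for point estimate only).
#' @param seed Integer seed for the bootstrap.
#' @param level CI coverage (default 0.95).
#' @return List with `R`, and when `n_boot > 0` also `ci` and `boot`.
#' @export
adjusted_repeatability <- function(fit, n_boot = 0, seed = 1, level = 0.95) {
  v <- fit$varcomp
  R <- latent_repeatability(v$sd_bird^2, v$sd_winter^2)
  out <- list(R = R)
  if (n_boot > 0) {
    sims <- simulate(fit, nsim = n_boot, seed = seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      d <- fit$data
      d$attendance <- sims[[b]]
      bf <- try(suppressWarnings(fit_attendance(d, fit$cohort,
                                                quadratic = fit$quadratic %||% TRUE,
                                                use_weights = fit$engine$use_weights)),
                silent = TRUE)
      if (inherits(bf, "try-error")) return(NA_real_)
      latent_repeatability(bf$varcomp$sd_bird^2, bf$varcomp$sd_winter^2)
    }, 0)
    boot <- boot[!is.na(boot)]
    out$ci <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                              names = FALSE)
    out$boot <- boot
  }
  out
}

#' Cramér's V between two categorical variables
#'
#' `V = sqrt(chi^2 / (n * (min(r, c) - 1)))` from the uncorrected chi-squared
#' statistic, with its p-value.
#'
#' @param a,b Vectors of equal length, each with at least two levels.
#' @return List with `v`, `chisq`, `df`, `p_value`, `n`.
#' @export
cramers_v <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  tab <- table(a, b)
  if (any(dim(tab) < 2)) stop("both variables need at least two levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  list(v = sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1))),
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n = n)
}

#' Compare attendance models by approximate predictive criterion
#'
#' An information-criterion approximation to out-of-sample predictive
#' density: the criterion is the penalised marginal log-likelihood
#' (-AIC / 2, Laplace-approximated with random effects integrated out), and
#' pairwise differences to the best model are reported. The difference SE is
#' a heuristic from the pointwise conditional log-likelihood differences,
#' analogous to the pointwise SE of cross-validated predictive density.
#'
#' @param ... Named `attendance_fit` objects on the same data.
#' @return Data frame: `model`, `criterion` (higher is better), `diff` to the
#'   best model, `se_diff`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  y0 <- fits[[1]]$data$attendance
  w0 <- fits[[1]]$data$weight
  ll <- lapply(fits, function(f) {
    if (!isTRUE(all.equal(f$data$attendance, y0)) ||
        !isTRUE(all.equal(f$data$weight, w0)))
      stop("models must share the same response and weights")
    k <- length(f$model$fit$par)
    w0 * stats::dbinom(y0, 1, f$fitted, log = TRUE) - k / length(y0)
  })
  crit <- vapply(fits, function(f) -stats::AIC(f$model) / 2, 0)
  best <- which.max(crit)
  out <- data.frame(model = names(fits), criterion = crit,
                    diff = crit - crit[best],
                    se_diff = vapply(ll, function(l) {
                      d <- l - ll[[best]]
                      sqrt(length(d) * stats::var(d))
                    }, 0))
  rownames(out) <- NULL
  out[order(-out$criterion), ]
}
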