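#' Demographic parameters for Rhagoletis cerasi females
#'
#' Bundles the calibrated constants governing adult survival, fecundity and
#' immature development.  Defaults follow the published life-history synthesis
#' for the species: a 59-day mean adult lifespan under optimal conditions with
#' a hard 95-day cap, 3\% daily extrinsic mortality from resident natural
#' enemies, 92\% combined mortality from egg to next-spring adult, maturation
#' between 5 and 14 days of age, 0--10 eggs/day with a 365-egg lifetime
#' potential, 20--23 days of in-fruit development and a 1:1 sex ratio.
#'
#' @param mean_lifespan_target mean adult lifespan (days) the intrinsic
#'   (Gompertz) hazard is calibrated to, in the absence of extrinsic risks.
#' @param max_lifespan hard cap on individual age (days); the daily hazard is
#'   forced to 1 at this age.
#' @param extrinsic_daily_risk constant daily mortality probability from the
#'   on-farm complex of predators and pathogens.
#' @param immature_generation_mortality combined mortality from egg until the
#'   adult emerging from the soil next spring.
#' @param maturation_onset,maturation_full age (days) at which egg laying can
#'   begin / is fully established.
#' @param daily_fecundity_cap maximum mean daily fecundity (eggs/female/day).
#' @param lifetime_fecundity potential lifetime fecundity (eggs/female) under
#'   optimal conditions.
#' @param egg_to_larva_days_range range (days) of in-fruit development from
#'   egg to the mature larva leaving the fruit.
#' @param sex_ratio female fraction among emerging adults.
#' @return An object of class \code{demog_params}: a list with the arguments
#'   above plus the calibrated Gompertz parameters \code{gompertz_a},
#'   \code{gompertz_b} and the calibrated fecundity curve (see
#'   \code{\link{fecundity_curve}}).
#' @seealso \code{\link{calibrate_gompertz}}, \code{\link{fecundity_curve}},
#'   \code{\link{intrinsic_daily_mortality}}
#' @export
demog_params <- function(mean_lifespan_target = 59,
                         max_lifespan = 95,
                         extrinsic_daily_risk = 0.03,
                         immature_generation_mortality = 0.92,
                         maturation_onset = 5,
                         maturation_full = 14,
                         daily_fecundity_cap = 10,
                         lifetime_fecundity = 365,
                         egg_to_larva_days_range = c(20, 23),
                         sex_ratio = 0.5) {
  stopifnot(mean_lifespan_target > 0, max_lifespan > mean_lifespan_target,
            extrinsic_daily_risk >= 0, extrinsic_daily_risk < 1,
            immature_generation_mortality >= 0, immature_generation_mortality <= 1,
            maturation_onset <= maturation_full,
            length(egg_to_larva_days_range) == 2L,
            sex_ratio > 0, sex_ratio <= 1)
  g <- calibrate_gompertz(mean_lifespan_target, max_lifespan)
  curve <- fecundity_curve(maturation_onset = maturation_onset,
                           max_lifespan = max_lifespan,
                           lifetime_fecundity = lifetime_fecundity,
                           daily_cap = daily_fecundity_cap)
  structure(list(
    gompertz_a = g[["a"]], gompertz_b = g[["b"]],
    max_lifespan = max_lifespan,
    mean_lifespan_target = mean_lifespan_target,
    extrinsic_daily_risk = extrinsic_daily_risk,
    immature_generation_mortality = immature_generation_mortality,
    maturation_onset = maturation_onset,
    maturation_full = maturation_full,
    daily_fecundity_cap = daily_fecundity_cap,
    lifetime_fecundity = lifetime_fecundity,
    egg_to_larva_days_range = as.integer(egg_to_larva_days_range),
    sex_ratio = sex_ratio,
    fecundity = curve
  ), class = "demog_params")
}

#' @export
print.demog_params <- function(x, ...) {
  cat("Rhagoletis cerasi demographic parameters\n")
  cat(sprintf("  Gompertz hazard: a = %.4g, b = %.4g (mean lifespan %.1f d, cap %d d)\n",
              x$gompertz_a, x$gompertz_b,
              truncated_gompertz_mean(x$gompertz_a, x$gompertz_b, x$max_lifespan),
              x$max_lifespan))
  cat(sprintf("  Extrinsic daily risk: %.2f; overwinter generation mortality: %.2f\n",
              x$extrinsic_daily_risk, x$immature_generation_mortality))
  cat(sprintf("  Fecundity: %.0f eggs lifetime, peak %.2f eggs/day at age %d d\n",
              sum(x$fecundity$mean), max(x$fecundity$mean),
              which.max(x$fecundity$mean)))
  invisible(x)
}

## Discrete survival bookkeeping for the truncated Gompertz process:
## an agent of age t dies during the day with probability h(t); the hazard is
## forced to 1 at max_lifespan so nobody outlives the cap.

gompertz_hazard <- function(age, a, b, max_lifespan) {
  h <- pmin(1, a * exp(b * age))
  h[age >= max_lifespan] <- 1
  h
}

truncated_gompertz_mean <- function(a, b, max_lifespan) {
  ages <- 0:max_lifespan
  h <- gompertz_hazard(ages, a, b, max_lifespan)
  surv <- cumprod(1 - h)               # P(survive day 0..t), i.e. P(T > t)
  # T = age at death; E[T] = sum_{t>=1} P(T >= t) = sum_{t>=0} P(T > t)
  sum(surv)
}

#' Calibrate the truncated Gompertz intrinsic mortality
#'
#' Finds daily-hazard parameters \code{a, b} of the Gompertz law
#' \code{h(t) = min(1, a exp(b t))}, with the hazard forced to 1 at
#' \code{max_lifespan}, such that the expected age at death of the truncated
#' process equals \code{mean_target}.  The two-parameter family is closed by
#' requiring the unforced hazard to reach 1 exactly at the cap
#' (\code{a = exp(-b * max_lifespan)}), leaving a one-dimensional root solved
#' by bisection on \code{b}.
#'
#' @param mean_target target mean lifespan (days), \code{0 < mean_target <
#'   max_lifespan}.
#' @param max_lifespan hard age cap (days).
#' @param tol calibration tolerance on the mean lifespan (days).
#' @return named numeric vector \code{c(a =, b =)}.
#' @export
calibrate_gompertz <- function(mean_target = 59, max_lifespan = 95, tol = 1e-6) {
  if (!is.finite(mean_target) || mean_target <= 0 || mean_target >= max_lifespan)
    stop("mean_target must lie strictly between 0 and max_lifespan")
  f <- function(b) {
    a <- exp(-b * max_lifespan)
    truncated_gompertz_mean(a, b, max_lifespan) - mean_target
  }
  lo <- 1e-4; hi <- 2
  if (f(lo) > 0 || f(hi) < 0) stop("Gompertz calibration failed to bracket the target mean")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  a <- exp(-root * max_lifespan)
  resid <- truncated_gompertz_mean(a, root, max_lifespan) - mean_target
  if (abs(resid) > 0.5)
    stop(sprintf("Gompertz calibration did not converge (residual %.3f d)", resid))
  c(a = a, b = root)
}

#' Intrinsic age-dependent daily mortality risk
#'
#' Gompertz daily hazard \code{min(1, a exp(b age))}, forced to exactly 1 at
#' and beyond the maximum modeled lifespan.
#'
#' @param age age in days (vectorized), \code{>= 0}.
#' @param params a \code{\link{demog_params}} object.
#' @return daily death probability in \code{[0, 1]}.
#' @export
intrinsic_daily_mortality <- function(age, params) {
  if (any(age < 0)) stop("age must be non-negative")
  gompertz_hazard(age, params$gompertz_a, params$gompertz_b, params$max_lifespan)
}

#' Age-dependent mean daily fecundity curve
#'
#' Asymmetric bell over female age: zero before the maturation onset, then a
#' gamma-kernel shape \code{c (age - onset)^alpha exp(-(age - onset)/beta)}
#' whose scale \code{c} is solved so the curve integrates to the lifetime
#' potential fecundity over ages 1..\code{max_lifespan}.  With the default
#' shape (\code{alpha = 2, beta = 12}) the peak falls at age
#' \code{onset + alpha beta = 29} days, inside the most damaging "mature"
#' age band, and stays below the 10 eggs/day cap.
#'
#' @param maturation_onset age (days) before which mean fecundity is zero.
#' @param max_lifespan horizon (days) over which the curve is normalized.
#' @param lifetime_fecundity total the mean curve must sum to over ages
#'   1..\code{max_lifespan}.
#' @param daily_cap upper bound on the mean daily fecundity; if the normalized
#'   peak exceeds it, \code{beta} is widened until it does not.
#' @param alpha,beta gamma-kernel shape and scale (days).
#' @return object of class \code{fecundity_curve}: list with \code{mean}
#'   (vector indexed by age 1..\code{max_lifespan}) and the shape parameters.
#' @export
fecundity_curve <- function(maturation_onset = 5, max_lifespan = 95,
                            lifetime_fecundity = 365, daily_cap = 10,
                            alpha = 2, beta = 12) {
  ages <- seq_len(max_lifespan)
  shape <- function(beta) {
    x <- pmax(0, ages - maturation_onset)
    u <- ifelse(x > 0, x^alpha * exp(-x / beta), 0)
    u * (lifetime_fecundity / sum(u))
  }
  m <- shape(beta)
  while (max(m) > daily_cap) {      # widen the bell until the cap holds
    beta <- beta * 1.1
    m <- shape(beta)
  }
  structure(list(mean = m, alpha = alpha, beta = beta,
                 maturation_onset = maturation_onset,
                 max_lifespan = max_lifespan,
                 lifetime_fecundity = lifetime_fecundity,
                 daily_cap = daily_cap),
            class = "fecundity_curve")
}

#' Mean daily fecundity at a given age
#'
#' @param age age in days (vectorized).
#' @param curve a \code{\link{fecundity_curve}}.
#' @return mean eggs/day at each age (0 outside 1..max_lifespan).
#' @export
mean_daily_fecundity <- function(age, curve) {
  out <- numeric(length(age))
  ok <- age >= 1 & age <= curve$max_lifespan
  out[ok] <- curve$mean[age[ok]]
  out
}

#' Draw an individual daily egg load
#'
#' Individual realizations around the age-specific mean: Normal(mean, mean/3)
#' truncated to \code{[0, daily_cap]} and rounded to an integer count.
#'
#' @param age ages in days (vectorized; one draw per element).
#' @param curve a \code{\link{fecundity_curve}}.
#' @return integer egg counts.
#' @export
draw_daily_eggs <- function(age, curve) {
  m <- mean_daily_fecundity(age, curve)
  draws <- stats::rnorm(length(m), mean = m, sd = m / 3)
  draws[m == 0] <- 0
  as.integer(round(pmin(curve$daily_cap, pmax(0, draws))))
}

#' Build a staggered spring emergence schedule
#'
#' Spring emergence is staggered over a 35--50 day window with 70--90\% of
#' individuals emerging during the peak 14 days.  The expected shape is a
#' symmetric truncated normal centered mid-window whose spread is solved so
#' that the best consecutive 14-day window carries \code{peak14_target} of the
#' mass; realized daily counts are a multinomial draw from those expected
#' fractions.
#'
#' @param total number of adults to emerge (conserved exactly).
#' @param window_days emergence window length (days), in \code{[35, 50]}.
#' @param peak14_target fraction of emergence in the peak 14 days, in
#'   \code{[0.70, 0.90]}.
#' @param start_day season day on which the window opens (day 1 = first
#'   simulated day).
#' @return object of class \code{emergence_schedule}: list with integer
#'   \code{daily_counts} (length \code{window_days}), \code{expected_fractions},
#'   \code{sigma}, \code{start_day} and \code{peak14_fraction} (expected mass
#'   of the best 14-day window).
#' @export
build_emergence_schedule <- function(total, window_days = 42,
                                     peak14_target = 0.8, start_day = 1) {
  if (window_days < 35 || window_days > 50)
    stop("window_days must lie in [35, 50]")
  if (peak14_target < 0.70 || peak14_target > 0.90)
    stop("peak14_target must lie in [0.70, 0.90]")
  frac <- emergence_fractions(window_days, peak14_target)
  counts <- if (total > 0) {
    as.integer(stats::rmultinom(1, size = total, prob = frac$fractions))
  } else integer(window_days)
  structure(list(daily_counts = counts,
                 expected_fractions = frac$fractions,
                 sigma = frac$sigma,
                 start_day = start_day,
                 window_days = window_days,
                 peak14_fraction = frac$peak14),
            class = "emergence_schedule")
}

# Expected (pre-sampling) daily emergence fractions: day-binned truncated
# normal centered mid-window; sigma solved so the best 14 consecutive days
# carry peak14_target of the mass.
emergence_fractions <- function(window_days, peak14_target) {
  mu <- (window_days + 1) / 2
  mass <- function(sigma) {
    p <- stats::pnorm(1:window_days + 0.5, mu, sigma) -
         stats::pnorm(1:window_days - 0.5, mu, sigma)
    p / sum(p)
  }
  best14 <- function(p) {
    if (window_days <= 14) return(1)
    max(vapply(1:(window_days - 13), function(i) sum(p[i:(i + 13)]), 0))
  }
  f <- function(sigma) best14(mass(sigma)) - peak14_target
  sigma <- stats::uniroot(f, c(1, 30), tol = 1e-8)$root
  p <- mass(sigma)
  list(fractions = p, sigma = sigma, peak14 = best14(p))
}

#' In-fruit immature development duration from mean season temperature
#'
#' Egg-to-larva development inside the fruit lasts 20--23 days depending on
#' locally prevailing temperatures; the map is linear through the anchors
#' (22.1 C, 20 d) and (19.1 C, 23 d), rounded to the nearest day and clamped
#' to \code{[20, 23]}.
#'
#' @param mean_season_temp mean temperature (C) over the development season.
#' @return integer number of days in \code{[20, 23]}.
#' @export
immature_duration <- function(mean_season_temp) {
  stopifnot(is.finite(mean_season_temp))
  d <- round(20 + (22.1 - mean_season_temp) * (23 - 20) / (22.1 - 19.1))
  as.integer(pmin(23, pmax(20, d)))
}

#' Expected next-spring adults from an overwintering pool
#'
#' Applies the combined egg-to-adult generation mortality (default 92\%) and,
#' optionally, the female fraction to a pool of immatures that entered the
#' soil.  The simulator tracks females only, so next-season emergence maps are
#' built with \code{female_only = TRUE}.
#'
#' @param pool immatures entering the overwinter pool (vectorized).
#' @param params a \code{\link{demog_params}}.
#' @param female_only multiply by the female sex ratio?
#' @return expected adults next spring (not rounded).
#' @export
overwinter_recruits <- function(pool, params, female_only = FALSE) {
  r <- pool * (1 - params$immature_generation_mortality)
  if (female_only) r <- r * params$sex_ratio
  r
}

#' Write a demographic calibration report
#'
#' Dumps the fitted Gompertz parameters, their residual against the target
#' mean lifespan, and the fecundity-curve constraint checks as JSON.
#'
#' @param params a \code{\link{demog_params}}.
#' @param path file to write.
#' @return (invisibly) the report list.
#' @export
write_calibration_report <- function(params, path) {
  mean_ls <- truncated_gompertz_mean(params$gompertz_a, params$gompertz_b,
                                     params$max_lifespan)
  rep <- list(
    gompertz = list(a = params$gompertz_a, b = params$gompertz_b,
                    mean_lifespan = mean_ls,
                    residual = mean_ls - params$mean_lifespan_target),
    fecundity = list(total = sum(params$fecundity$mean),
                     peak = max(params$fecundity$mean),
                     peak_age = which.max(params$fecundity$mean),
                     alpha = params$fecundity$alpha,
                     beta = params$fecundity$beta),
    checks = list(
      mean_within_half_day = abs(mean_ls - params$mean_lifespan_target) <= 0.5,
      total_within_half_egg =
        abs(sum(params$fecundity$mean) - params$lifetime_fecundity) <= 0.5,
      peak_below_cap = max(params$fecundity$mean) <= params$daily_fecundity_cap
    )
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
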