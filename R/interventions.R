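#' Rebel trap parameters
#'
#' A new Rebel trap imposes a 5\% daily trapping risk within its own 100 m2
#' sector, declining 1\% (relative) per day of field exposure as glue
#' efficiency is lost.  Female responsiveness to the trap is age dependent:
#' 80\% just after emergence, 100\% at the peak of reproductive activity and
#' a gradual decline to a 40\% floor at 4--6 weeks of age.
#'
#' @param base_daily_risk initial daily capture probability of a fresh trap.
#' @param daily_efficacy_decay relative daily decline in trap efficacy.
#' @param resp_knots,resp_values piecewise-linear responsiveness over age
#'   (days); constant beyond the end knots.
#' @return a \code{trap_params} list.
#' @export
trap_params <- function(base_daily_risk = 0.05, daily_efficacy_decay = 0.01,
                        resp_knots = c(0, 12, 22, 28),
                        resp_values = c(0.80, 1.00, 1.00, 0.40)) {
  stopifnot(base_daily_risk >= 0, base_daily_risk <= 1,
            daily_efficacy_decay >= 0, daily_efficacy_decay < 1,
            length(resp_knots) == length(resp_values))
  structure(list(base_daily_risk = base_daily_risk,
                 daily_efficacy_decay = daily_efficacy_decay,
                 resp_knots = resp_knots, resp_values = resp_values),
            class = "trap_params")
}

#' Age-dependent responsiveness to a Rebel trap
#'
#' @param age age in days (vectorized).
#' @param params a \code{\link{trap_params}}.
#' @return responsiveness fraction.
#' @export
trap_responsiveness <- function(age, params = trap_params()) {
  stats::approx(params$resp_knots, params$resp_values, xout = age, rule = 2)$y
}

#' Daily capture probability of a trap for a resident female
#'
#' \code{p = base_risk x (1 - decay)^(days deployed) x responsiveness(age)}.
#' Only flies resident in the trap's own sector are exposed; for flies
#' elsewhere the probability is zero (use \code{in_sector = FALSE}).
#'
#' @param days_deployed days since the trap was deployed (vectorized).
#' @param agent_age female age in days.
#' @param params a \code{\link{trap_params}}.
#' @param in_sector is the fly in the trap's sector?
#' @return capture probability, never above \code{base_daily_risk}.
#' @export
trap_capture_probability <- function(days_deployed, agent_age,
                                     params = trap_params(), in_sector = TRUE) {
  p <- params$base_daily_risk *
    (1 - params$daily_efficacy_decay)^pmax(0, days_deployed) *
    trap_responsiveness(agent_age, params)
  p * as.numeric(in_sector)
}

#' Define a pesticide application
#'
#' Three modes are provided.  \code{systemic} (acetamiprid-like cover spray):
#' weeks-long larvicidal action inside the fruit (plateau 0.9/day for 14
#' days, declining through 0.6/day at day 21, exponential tail with 7-day
#' half-life) plus a short-term adult knockdown (0.8 on the application day,
#' 2-day half-life, so the adult action is spent within about a week).  \code{knockdown}: a 1-day, 100\%-mortality contact
#' spray against adults, no larvicidal action.  \code{bait_spot}: bait +
#' pyrethroid spot spray, adults only, 50\% risk on the application day.
#' Custom risk profiles may be supplied to override the defaults.
#'
#' @param date application \code{Date}.
#' @param sectors sector indices of the treated zone.
#' @param mode \code{"systemic"}, \code{"knockdown"} or \code{"bait_spot"}.
#' @param adult_profile,larval_profile optional functions of days since
#'   application returning a daily mortality risk.
#' @param enemy_suppression_days recovery horizon of the local natural
#'   enemies after the application.
#' @param label free-text product label (metadata).
#' @return a \code{pesticide_application} list.
#' @export
pesticide_application <- function(date, sectors,
                                  mode = c("systemic", "knockdown", "bait_spot"),
                                  adult_profile = NULL, larval_profile = NULL,
                                  enemy_suppression_days = 21, label = mode) {
  mode <- match.arg(mode)
  if (is.null(adult_profile))
    adult_profile <- switch(mode,
      systemic = function(d) ifelse(d < 0, 0, 0.8 * 0.5^(d / 2)),
      knockdown = function(d) ifelse(d == 0, 1, 0),
      bait_spot = function(d) ifelse(d == 0, 0.5, 0))
  if (is.null(larval_profile))
    larval_profile <- switch(mode,
      systemic = function(d) {
        r <- numeric(length(d))
        r[d >= 0 & d <= 14] <- 0.9
        mid <- d > 14 & d <= 21
        r[mid] <- 0.9 * (0.6 / 0.9)^((d[mid] - 14) / 7)
        late <- d > 21
        r[late] <- 0.6 * 0.5^((d[late] - 21) / 7)
        r
      },
      knockdown = function(d) numeric(length(d)),
      bait_spot = function(d) numeric(length(d)))
  structure(list(date = as.Date(date), sectors = as.integer(sectors),
                 mode = mode, adult_profile = adult_profile,
                 larval_profile = larval_profile,
                 enemy_suppression_days = enemy_suppression_days,
                 label = label[1]),
            class = "pesticide_application")
}

#' Combined daily pesticide risks in a sector
#'
#' Overlapping applications combine as \code{1 - prod(1 - risk)}; sectors
#' outside all treated zones carry zero risk.
#'
#' @param applications list of \code{\link{pesticide_application}}s.
#' @param sector_idx sector index.
#' @param date a \code{Date}.
#' @return named numeric \code{c(adult =, larval =)}.
#' @export
daily_pesticide_risks <- function(applications, sector_idx, date) {
  a_surv <- 1; l_surv <- 1
  for (ap in applications) {
    if (!(sector_idx %in% ap$sectors)) next
    d <- as.integer(as.Date(date) - ap$date)
    if (d < 0) next
    a_surv <- a_surv * (1 - min(1, max(0, ap$adult_profile(d))))
    l_surv <- l_surv * (1 - min(1, max(0, ap$larval_profile(d))))
  }
  c(adult = 1 - a_surv, larval = 1 - l_surv)
}

#' Natural-enemy mortality risk with pesticide suppression and border effect
#'
#' The on-farm complex of resident predators and pathogens imposes a constant
#' 3\% daily adult mortality.  A pesticide application transiently suppresses
#' the local natural enemies: the risk drops to 0 on the application day in
#' the treated zone and recovers linearly over \code{enemy_suppression_days},
#' faster near the zone border -- per-sector recovery speed is multiplied by
#' \code{1 + 1/dist} with \code{dist} the distance (sectors) to the nearest
#' untreated sector, i.e. twice as fast at the zone edge.
#'
#' @param applications list of \code{\link{pesticide_application}}s.
#' @param sector_idx sector index.
#' @param date a \code{Date}.
#' @param farm a \code{farm_grid}.
#' @param baseline untreated daily risk.
#' @return daily mortality probability in \code{[0, baseline]}.
#' @export
natural_enemy_risk <- function(applications, sector_idx, date, farm,
                               baseline = 0.03) {
  risk <- baseline
  for (ap in applications) {
    if (!(sector_idx %in% ap$sectors)) next
    d <- as.integer(as.Date(date) - ap$date)
    if (d < 0 || d > ap$enemy_suppression_days) next
    untreated <- setdiff(seq_len(nrow(farm$sectors)), ap$sectors)
    speed <- if (!length(untreated)) 1 else {
      s <- farm$sectors
      dd <- sqrt((s$x[untreated] - s$x[sector_idx])^2 +
                 (s$y[untreated] - s$y[sector_idx])^2) / 10
      1 + 1 / max(1, min(dd))
    }
    frac <- min(1, d * speed / ap$enemy_suppression_days)
    risk <- min(risk, baseline * frac)
  }
  risk
}

#' Define a harvest event
#'
#' @param date harvest \code{Date}.
#' @param sectors sector indices of the harvested plot.
#' @param accuracy fraction of the fruit actually picked (usual practice ca.
#'   0.8; complete harvest 1.0).
#' @param assessment_sample number of harvested fruit dissected to assess
#'   infestation.
#' @return a \code{harvest_event} list.
#' @export
harvest_event <- function(date, sectors, accuracy = 0.80,
                          assessment_sample = 100) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  structure(list(date = as.Date(date), sectors = as.integer(sectors),
                 accuracy = accuracy, assessment_sample = assessment_sample),
            class = "harvest_event")
}
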