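#' Load and validate a daily weather series
#'
#' Reads a CSV with one row per day and columns
#' \code{date,tmin,tavg,tmax,rain_mm,wind_ms,radiation_wm2}.  The series must
#' be gap-free and satisfy \code{tmin <= tavg <= tmax} and non-negative rain,
#' wind and radiation on every day.
#'
#' @param path CSV file path.
#' @return a \code{weather_series}: data.frame with columns \code{date}
#'   (Date), \code{tmin}, \code{tavg}, \code{tmax}, \code{rain_mm},
#'   \code{wind_ms}, \code{radiation_wm2}.
#' @export
load_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "tmin", "tavg", "tmax", "rain_mm", "wind_ms", "radiation_wm2")
  missing <- setdiff(needed, names(w))
  if (length(missing))
    stop("weather file missing columns: ", paste(missing, collapse = ", "))
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("weather file contains unparseable dates")
  w <- w[order(w$date), , drop = FALSE]
  validate_weather(w)
}

validate_weather <- function(w) {
  if (nrow(w) == 0) stop("empty weather series")
  d <- diff(as.integer(w$date))
  if (any(d != 1)) {
    gap <- w$date[which(d != 1)[1]]
    stop("weather series has a gap or duplicate after ", format(gap))
  }
  bad <- which(!(w$tmin <= w$tavg & w$tavg <= w$tmax))
  if (length(bad))
    stop("temperature ordering violated on ", format(w$date[bad[1]]))
  neg <- which(w$rain_mm < 0 | w$wind_ms < 0 | w$radiation_wm2 < 0)
  if (length(neg))
    stop("negative rain/wind/radiation on ", format(w$date[neg[1]]))
  class(w) <- c("weather_series", "data.frame")
  w
}

#' Daily activity gate from weather
#'
#' Explorative activity requires no rain, average temperature above 13 C,
#' mid-day wind below 12 m/s and sunshine above 100 W/m2.  Mating additionally
#' requires temperature above 15 C and oviposition above 16 C.
#'
#' @param weather one row of a \code{weather_series} (or a list with the same
#'   fields).
#' @return list of logicals \code{explore}, \code{mate}, \code{oviposit}.
#' @export
activity_gate <- function(weather) {
  needed <- c("tavg", "rain_mm", "wind_ms", "radiation_wm2")
  if (any(vapply(needed, function(f) is.null(weather[[f]]) || is.na(weather[[f]]),
                 logical(1))))
    stop("incomplete weather record")
  explore <- weather$rain_mm == 0 && weather$tavg > 13 &&
    weather$wind_ms < 12 && weather$radiation_wm2 > 100
  list(explore = explore,
       mate = explore && weather$tavg > 15,
       oviposit = explore && weather$tavg > 16)
}

#' Weather-imposed daily mortality risk
#'
#' Bad-weather spells (severe rain, strong wind, or both) add a mortality
#' risk, moderated by the sheltering capacity of the local tree canopy.
#' Severity is scored \code{w_rain} for rain above \code{rain_threshold},
#' \code{w_wind} for wind above \code{wind_threshold}, plus \code{w_combined}
#' when both hold; the risk is \code{cap * score * (1 - shelter_coeff *
#' canopy_shelter)}, bounded above by \code{cap}.
#'
#' @param day one row of a \code{weather_series}.
#' @param canopy_shelter sheltering fraction in \code{[0, 1]} (the sector's
#'   canopy cover).
#' @param rain_threshold,wind_threshold severity thresholds (mm, m/s).
#' @param w_rain,w_wind,w_combined severity weights.
#' @param cap maximum daily weather mortality risk.
#' @param shelter_coeff fraction of the risk a full canopy removes.
#' @return daily death probability in \code{[0, cap]}.
#' @export
weather_mortality <- function(day, canopy_shelter,
                              rain_threshold = 10, wind_threshold = 8,
                              w_rain = 0.5, w_wind = 0.5, w_combined = 1,
                              cap = 0.10, shelter_coeff = 0.7) {
  stopifnot(all(canopy_shelter >= 0 & canopy_shelter <= 1))
  severe_rain <- day$rain_mm > rain_threshold
  severe_wind <- day$wind_ms > wind_threshold
  s <- w_rain * severe_rain + w_wind * severe_wind +
    w_combined * (severe_rain && severe_wind)
  pmin(cap, pmax(0, cap * s * (1 - shelter_coeff * canopy_shelter)))
}
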