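#' Generate a synthetic daily weather series
#'
#' Seeded generator emulating a central-European cherry-season weather
#' record: a seasonal temperature ramp plus day-to-day noise, occasional rain
#' days and rarer storm days (heavy rain with strong wind).  The output
#' passes \code{\link{load_weather}} validation.
#'
#' @param days series length.
#' @param start first date.
#' @param mean_temp season mean of the daily average temperature (C).
#' @param rain_prob probability a day carries rain.
#' @param storm_prob probability a rain day is a storm (severe rain + wind).
#' @param seed optional RNG seed (uses the current RNG state when NULL).
#' @return a \code{weather_series}.
#' @export
generate_weather <- function(days, start = as.Date("2015-05-15"),
                             mean_temp = 18, rain_prob = 0.2,
                             storm_prob = 0.05, seed = NULL) {
  stopifnot(days >= 1)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(days)
  # gentle seasonal ramp centred on the series, zero-mean over the season
  ramp <- 4 * sin(pi * (t - 1) / max(1, days - 1) - pi / 2)
  ramp <- ramp - mean(ramp)
  tavg <- mean_temp + ramp + stats::rnorm(days, 0, 1.5)
  spread <- stats::runif(days, 3, 6)
  rain <- ifelse(stats::runif(days) < rain_prob,
                 stats::rexp(days, rate = 1 / 4), 0)
  storm <- rain > 0 & stats::runif(days) < storm_prob / rain_prob
  rain[storm] <- 12 + stats::rexp(sum(storm), 1 / 8)
  wind <- stats::rgamma(days, shape = 2, scale = 1.5)
  wind[storm] <- 9 + stats::rexp(sum(storm), 1 / 3)
  rad <- ifelse(rain > 0, stats::runif(days, 40, 250),
                stats::runif(days, 150, 800))
  validate_weather(data.frame(
    date = start + t - 1,
    tmin = round(tavg - spread, 1), tavg = round(tavg, 1),
    tmax = round(tavg + spread, 1),
    rain_mm = round(rain, 1), wind_ms = round(wind, 1),
    radiation_wm2 = round(rad)))
}

#' Benign weather: warm, dry, calm and sunny every day
#'
#' Convenience series under which every day passes the exploration, mating
#' and oviposition gates and imposes no weather mortality; used for the
#' mark-recapture virtual experiment and for controlled tests.
#'
#' @inheritParams generate_weather
#' @param tavg constant daily average temperature (C).
#' @return a \code{weather_series}.
#' @export
benign_weather <- function(days, start = as.Date("2015-05-15"), tavg = 20) {
  validate_weather(data.frame(
    date = start + seq_len(days) - 1,
    tmin = tavg - 5, tavg = tavg, tmax = tavg + 5,
    rain_mm = 0, wind_ms = 2, radiation_wm2 = 500))
}

# blank sector table for an all-empty grid
empty_sector_table <- function(rows, cols) {
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  data.frame(row = g$row, col = g$col, cover_type = "empty",
             cultivar = NA_character_, canopy_cover = 0, canopy_diameter = 0,
             trap_id = NA_character_, initial_pupae = 0L, fruit_count = 0L,
             stringsAsFactors = FALSE)
}

set_block <- function(sec, rows, cols, grid_cols, ...) {
  idx <- which(sec$row %in% rows & sec$col %in% cols)
  vals <- list(...)
  for (nm in names(vals)) sec[[nm]][idx] <- vals[[nm]]
  sec
}

#' Generate a synthetic farm grid
#'
#' Seeded generator of a rectangular farm: rectangular host plots with
#' cultivars drawn from the requested phenology-group mix, an optional
#' non-host tree block, traps placed on a regular rule over host sectors and
#' negative-binomial initial pupae per host sector.  The result passes
#' \code{\link{farm_grid}} validation and round-trips through
#' \code{\link{write_farm_grid}} / \code{\link{load_farm_grid}}.
#'
#' @param rows,cols grid dimensions (10 m sectors).
#' @param host_plots list of plots, each a list with \code{rows}, \code{cols}
#'   (0-based index vectors) and \code{cultivar} (name in \code{cultivars}).
#' @param cultivars a \code{\link{cultivar_table}}.
#' @param nonhost_plots like \code{host_plots} but without cultivar.
#' @param traps_per_plot traps placed (evenly spaced) in each host plot.
#' @param pupae_mean,pupae_dispersion negative-binomial initial pupae per
#'   host sector (mean, size).
#' @param fruit_per_sector fruit count per host sector.
#' @param canopy_cover canopy cover of tree sectors.
#' @param seed optional RNG seed.
#' @return a \code{farm_grid}.
#' @export
generate_synthetic_farm <- function(rows = 20, cols = 20,
                                    host_plots, cultivars,
                                    nonhost_plots = list(),
                                    traps_per_plot = 1,
                                    pupae_mean = 2, pupae_dispersion = 1,
                                    fruit_per_sector = 400,
                                    canopy_cover = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sec <- empty_sector_table(rows, cols)
  for (p in host_plots) {
    if (max(p$rows) >= rows || max(p$cols) >= cols || min(p$rows) < 0 || min(p$cols) < 0)
      stop("host plot exceeds the grid")
    sec <- set_block(sec, p$rows, p$cols, cols, cover_type = "host",
                     cultivar = p$cultivar, canopy_cover = canopy_cover,
                     canopy_diameter = 4, fruit_count = fruit_per_sector)
  }
  for (p in nonhost_plots) {
    if (max(p$rows) >= rows || max(p$cols) >= cols || min(p$rows) < 0 || min(p$cols) < 0)
      stop("non-host plot exceeds the grid")
    sec <- set_block(sec, p$rows, p$cols, cols, cover_type = "non_host_tree",
                     canopy_cover = canopy_cover, canopy_diameter = 4)
  }
  host <- which(sec$cover_type == "host")
  if (length(host)) {
    sec$initial_pupae[host] <- stats::rnbinom(length(host),
                                              size = pupae_dispersion,
                                              mu = pupae_mean)
    k <- 0
    for (p in host_plots) {
      idx <- which(sec$row %in% p$rows & sec$col %in% p$cols)
      pick <- idx[round(seq(1, length(idx), length.out = traps_per_plot))]
      sec$trap_id[pick] <- paste0("T", k + seq_along(pick))
      k <- k + length(pick)
    }
  }
  farm_grid(sec, cultivars)
}

#' Mark-recapture farm layout
#'
#' A 30 x 30 sector (300 x 300 m) grid realizing the field layout of the
#' mark-recapture experiment the mobility module is calibrated against:
#' five re-capture zones of fruiting sweet cherries with 38 Rebel traps in
#' total.  Zone 1 (release) is a single elongated
#' cherry plot with 3 traps; zone 2 comprises parallel plots with 4 traps,
#' separated from the release zone by a ca. 20 m band of empty field; zone 3
#' is a large Regina plot with 12 traps, its closest edge ca. 90 m and its
#' centre ca. 140 m from the release point, behind a plot of apple trees;
#' zone 4 contains several cherry plots with 19 traps, centre ca. 190 m
#' away; zone 5 is two large wild cherry trees ca. 238 m away (no traps
#' listed for it).  Apple and plum plots and empty fields fill the
#' remainder.  Shapes not stated in the description are invented here.
#'
#' @param fruiting are the cherry plots carrying suitable fruit at release
#'   time?  (controls the cultivar phenology calendar relative to
#'   \code{release_date}).
#' @param release_date nominal release date used to anchor the phenology.
#' @return a \code{farm_grid} with a \code{zones} list (sector indices per
#'   zone) and \code{release_sector} set.
#' @export
build_jki_markrecapture_layout <- function(fruiting = TRUE,
                                           release_date = as.Date("2015-06-15")) {
  rows <- 30; cols <- 30
  sec <- empty_sector_table(rows, cols)
  # phenology: all plots in fruit around the release date when fruiting
  off <- if (fruiting) 0 else 90
  cvs <- cultivar_table(
    name = c("mixed_early", "Regina", "wild"),
    group = c("medium", "late", "late"),
    flowering = as.character(release_date - c(60, 70, 65) + off),
    hue_change = as.character(release_date - c(10, 20, 15) + off),
    harvest1 = as.character(release_date + c(20, 30, 25) + off))

  host <- function(sec, rows_, cols_, cultivar, canopy = 0.8)
    set_block(sec, rows_, cols_, cols, cover_type = "host", cultivar = cultivar,
              canopy_cover = canopy, canopy_diameter = 4, fruit_count = 500L)

  sec <- host(sec, 14:15, 0:5, "mixed_early")       # zone 1: elongated plot
  sec <- host(sec, 11, 0:9, "mixed_early")          # zone 2: two parallel rows
  sec <- host(sec, 9, 0:9, "mixed_early")
  sec <- host(sec, 12:19, 12:24, "Regina")          # zone 3: large plot
  sec <- host(sec, 2:6, 14:20, "mixed_early")       # zone 4: several plots
  sec <- host(sec, 2:6, 22:27, "mixed_early")
  sec <- host(sec, 8:10, 15:26, "mixed_early")
  sec <- host(sec, 15:16, 27, "wild", canopy = 0.9) # zone 5: two wild trees
  # non-host orchards: apples between release zone and zone 3, plums south
  sec <- set_block(sec, 13:17, 8:10, cols, cover_type = "non_host_tree",
                   canopy_cover = 0.7, canopy_diameter = 4)
  sec <- set_block(sec, 22:26, 4:10, cols, cover_type = "non_host_tree",
                   canopy_cover = 0.7, canopy_diameter = 4)

  place_traps <- function(sec, coords, prefix) {
    for (i in seq_len(nrow(coords))) {
      j <- which(sec$row == coords[i, 1] & sec$col == coords[i, 2])
      sec$trap_id[j] <- sprintf("%s%02d", prefix, i)
    }
    sec
  }
  sec <- place_traps(sec, rbind(c(14, 1), c(15, 4), c(14, 5)), "Z1_")
  sec <- place_traps(sec, cbind(c(11, 11, 9, 9), c(2, 8, 4, 8)), "Z2_")
  z3 <- cbind(rep(c(13, 15, 17), each = 4), rep(c(13, 16, 19, 23), 3))
  sec <- place_traps(sec, z3, "Z3_")
  z4 <- rbind(cbind(rep(c(3, 5), each = 3), rep(c(15, 17, 19), 2)),
              cbind(rep(c(3, 5), each = 3), rep(c(23, 25, 27), 2)),
              cbind(rep(c(8, 10), each = 3), rep(c(16, 20, 24), 2)),
              c(9, 18))
  sec <- place_traps(sec, z4, "Z4_")

  farm <- farm_grid(sec, cvs)
  s <- farm$sectors
  idx_of <- function(rows_, cols_) which(s$row %in% rows_ & s$col %in% cols_)
  zones <- list(
    release = idx_of(14:15, 0:5),
    zone2 = idx_of(c(9, 11), 0:9),
    zone3 = idx_of(12:19, 12:24),
    zone4 = c(idx_of(2:6, 14:20), idx_of(2:6, 22:27), idx_of(8:10, 15:26)),
    zone5 = idx_of(15:16, 27))
  farm$zones <- zones
  farm$release_sector <- which(s$row == 15 & s$col == 3)
  farm
}

#' Two-plot demo farm for IPM scenario experiments
#'
#' A compact synthetic farm with two mixed-cultivar sweet cherry plots, the
#' standard stage for the package's scenario experiments.  The "treated"
#' plot carries a medium (Kordia-like, harvested 2 July) and a late
#' (Regina-like, harvested 9 July) cultivar side by side, mirroring the
#' field layout in which a single plot with both cultivars received the
#' only pesticide treatment of the season (a systemic spray at the Kordia
#' hue change, 5 June).  The non-treated plot carries a medium
#' (Blaze-Star-like, harvested 18 June) and a very late (Sweetheart-like,
#' harvested 29 July) cultivar, the latter with most larvae leaving the
#' fruit before harvest -- the contrast needed for the harvest-accuracy
#' carry-over comparison.  Two monitoring traps per plot.
#'
#' @param pupae_mean mean initial pupae per host sector.
#' @param seed RNG seed for the pupae map.
#' @return a \code{farm_grid} with a \code{plots} attribute: sector index
#'   vectors \code{treated}, \code{untreated}, and per-cultivar
#'   \code{kordia}, \code{regina}, \code{blaze}, \code{sweetheart}.
#' @export
build_demo_farm <- function(pupae_mean = 4, seed = 1) {
  cvs <- cultivar_table(
    name = c("Kordia", "Regina", "BlazeStar", "Sweetheart"),
    group = c("medium", "late", "medium", "very_late"),
    flowering = c("2015-04-20", "2015-04-24", "2015-04-15", "2015-04-25"),
    hue_change = c("2015-06-05", "2015-06-10", "2015-06-01", "2015-06-22"),
    harvest1 = c("2015-07-02", "2015-07-09", "2015-06-18", "2015-07-29"))
  farm <- generate_synthetic_farm(
    rows = 16, cols = 22,
    host_plots = list(
      list(rows = 3:6, cols = 2:5, cultivar = "BlazeStar"),
      list(rows = 3:6, cols = 6:9, cultivar = "Sweetheart"),
      list(rows = 9:12, cols = 12:15, cultivar = "Kordia"),
      list(rows = 9:12, cols = 16:19, cultivar = "Regina")),
    cultivars = cvs, traps_per_plot = 1,
    pupae_mean = pupae_mean, pupae_dispersion = 2, seed = seed)
  s <- farm$sectors
  farm$plots <- list(
    treated = which(s$cultivar %in% c("Kordia", "Regina")),
    untreated = which(s$cultivar %in% c("BlazeStar", "Sweetheart")),
    kordia = which(s$cultivar %in% "Kordia"),
    regina = which(s$cultivar %in% "Regina"),
    blaze = which(s$cultivar %in% "BlazeStar"),
    sweetheart = which(s$cultivar %in% "Sweetheart"))
  farm
}
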