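#' Mobility parameters
#'
#' Age-dependent micro-migration rules.  A female either explores locally
#' (staying within her 100 m2 sector, the model's atomic unit) or, with an
#' age-dependent daily propensity, undertakes a micro-migration of 30--300 m.
#' Migration distances are drawn from a Normal with age-dependent mean and SD
#' and clamped to the 30--300 m range; propensity and mean distance both
#' increase with age, reflecting the enhanced propensity of older females for
#' longer explorative errands.  The numeric defaults are the package's
#' calibration against the mark-recapture experiment (see the methods
#' vignette).
#'
#' @param propensity_breaks,propensity_values daily micro-migration
#'   probability as a step function of age: \code{propensity_values[i]}
#'   applies to ages in \code{(propensity_breaks[i], propensity_breaks[i+1]]}.
#' @param distance_knots,distance_means piecewise-linear mean migration
#'   distance (m) over age (days); constant beyond the end knots.
#' @param distance_sd_factor SD of the distance draw as a fraction of the
#'   mean.
#' @param migration_min,migration_max clamp range for sampled distances (m).
#' @param in_out_balance ratio of immigration to emigration across the farm
#'   boundary (1 = balanced landscape).
#' @param canopy_gap_penalty weight multiplier per open (canopy-free) sector
#'   crossed en route to a destination: tree canopy macro-structure channels
#'   relocations, so transfers within contiguous canopy are preferred over
#'   flights across open ground (1 = no channeling).  Age dependent
#'   (piecewise linear over \code{gap_penalty_knots}): young females are
#'   tightly canopy-bound while old females undertake committed long errands
#'   across open ground.
#' @param gap_penalty_knots ages (days) anchoring the penalty values.
#' @param home_weight_factor weight of the current sector in the destination
#'   choice (times its attractiveness): when nothing in reach beats home the
#'   migration attempt is abandoned.
#' @return a \code{mobility_params} list.
#' @export
mobility_params <- function(propensity_breaks = c(0, 14, 28, Inf),
                            propensity_values = c(0.95, 0.95, 0.65),
                            distance_knots = c(10, 22, 30),
                            distance_means = c(32, 42, 150),
                            distance_sd_factor = 0.4,
                            migration_min = 30, migration_max = 300,
                            in_out_balance = 1,
                            canopy_gap_penalty = c(0.03, 0.08, 0.9),
                            gap_penalty_knots = c(10, 22, 30),
                            home_weight_factor = 1) {
  stopifnot(length(propensity_values) == length(propensity_breaks) - 1,
            all(propensity_values >= 0 & propensity_values <= 1),
            length(distance_knots) == length(distance_means),
            !is.unsorted(distance_means),
            migration_min < migration_max)
  structure(list(propensity_breaks = propensity_breaks,
                 propensity_values = propensity_values,
                 distance_knots = distance_knots,
                 distance_means = distance_means,
                 distance_sd_factor = distance_sd_factor,
                 migration_min = migration_min,
                 migration_max = migration_max,
                 in_out_balance = in_out_balance,
                 canopy_gap_penalty = canopy_gap_penalty,
                 gap_penalty_knots = gap_penalty_knots,
                 home_weight_factor = home_weight_factor),
            class = "mobility_params")
}

#' Mean migration distance at a given age
#'
#' @param age age in days (vectorized).
#' @param params a \code{\link{mobility_params}}.
#' @return mean distance in meters.
#' @export
mean_migration_distance <- function(age, params = mobility_params()) {
  stats::approx(params$distance_knots, params$distance_means, xout = age,
                rule = 2)$y
}

#' Daily micro-migration propensity at a given age
#'
#' @inheritParams mean_migration_distance
#' @return daily probability of undertaking a micro-migration.
#' @export
migration_propensity <- function(age, params = mobility_params()) {
  idx <- findInterval(age, params$propensity_breaks, left.open = TRUE,
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(params$propensity_values))
  params$propensity_values[idx]
}

#' Sample micro-migration distances
#'
#' Normal draw around the age-specific mean with SD =
#' \code{distance_sd_factor * mean}, clamped to the 30--300 m range.
#'
#' @param age ages in days (one draw per element).
#' @param params a \code{\link{mobility_params}}.
#' @return distances in meters, all within \code{[migration_min,
#'   migration_max]}.
#' @export
sample_migration_distance <- function(age, params = mobility_params()) {
  if (any(age < 0)) stop("age must be non-negative")
  m <- mean_migration_distance(age, params)
  d <- stats::rnorm(length(m), m, params$distance_sd_factor * m)
  pmin(params$migration_max, pmax(params$migration_min, d))
}

#' Niche modulation of oviposition and settling
#'
#' Oviposition propensity and destination attractiveness are modulated
#' downward by local niche exploitation: \code{(1 - I^2)(1 - (d/K)^2)}
#' (floored at 0) with \code{I} the sector's infested fruit fraction,
#' \code{d} the live females in the sector and \code{K} the density
#' capacity.  The quadratic form keeps the impact minor at low to moderate
#' infestation (multiplier >= 0.91 for I <= 0.3 at low density) and is 1 in
#' an empty, uninfested niche.
#'
#' @param infestation infested fruit fraction in \code{[0, 1]} (vectorized).
#' @param density live females in the sector.
#' @param capacity density normalization constant (females/sector).
#' @return multiplier in \code{[0, 1]}.
#' @export
niche_multiplier <- function(infestation, density, capacity = 20) {
  pmax(0, 1 - infestation^2) * pmax(0, 1 - (density / capacity)^2)
}

#' Leave multiplier: crowding and infestation enhance mobility
#'
#' The complementary modulation of \code{\link{niche_multiplier}}: mobility
#' is enhanced (factor >= 1) by decreased site attractiveness, excessive
#' local density or fruit infestation.
#'
#' @inheritParams niche_multiplier
#' @return factor \code{>= 1} multiplying the migration propensity.
#' @export
leave_multiplier <- function(infestation, density, capacity = 20) {
  1 + infestation^2 + (density / capacity)^2
}

#' Choose a micro-migration destination
#'
#' Candidate destinations are the sectors whose centre lies within
#' +/- 5 m (half a sector) of the sampled distance from the current sector's
#' centre.  Selection probability is proportional to sector attractiveness
#' plus a small floor \code{eps} so unattractive sectors remain reachable,
#' discounted by \code{canopy_gap_penalty} for every open sector the straight
#' path crosses (canopy macro-structure channels relocations along
#' contiguous tree cover).  Where the ring extends beyond the farm, the
#' out-of-grid arc competes with weight \code{mean candidate weight x
#' out-of-grid ring fraction x in_out_balance}; choosing it means
#' emigration.  An empty candidate ring (distance larger than the farm)
#' forces emigration.
#'
#' @param sector_idx current sector index (row-major).
#' @param farm a \code{farm_grid}.
#' @param distance sampled migration distance (m).
#' @param attractiveness per-sector attractiveness vector for the day.
#' @param params a \code{\link{mobility_params}}.
#' @param eps floor weight added to every candidate.
#' @param ring_halfwidth candidate ring half-width (m).
#' @param gap_crossings optional precomputed row of
#'   \code{\link{canopy_gap_matrix}} for the current sector (computed on the
#'   fly when NULL).
#' @param age female age (days), for the age-dependent gap penalty; NULL
#'   uses the youngest-age penalty.
#' @return destination sector index (the current one when the migration
#'   attempt is abandoned), or \code{NA} for emigration.
#' @export
choose_destination <- function(sector_idx, farm, distance, attractiveness,
                               params = mobility_params(), eps = 0.01,
                               ring_halfwidth = 5, gap_crossings = NULL,
                               age = NULL) {
  s <- farm$sectors
  dx <- s$x - s$x[sector_idx]
  dy <- s$y - s$y[sector_idx]
  dd <- sqrt(dx * dx + dy * dy)
  cand <- which(abs(dd - distance) <= ring_halfwidth)
  cand <- cand[cand != sector_idx]
  if (!length(cand)) return(NA_integer_)
  w <- attractiveness[cand] + eps
  pen <- gap_penalty_at(age, params)
  if (pen < 1) {
    if (is.null(gap_crossings))
      gap_crossings <- canopy_gap_matrix(farm, from = sector_idx)[1, ]
    w <- w * pen^gap_crossings[cand]
  }
  out_frac <- ring_outside_fraction(s$x[sector_idx], s$y[sector_idx],
                                    distance, farm$ncol * 10, farm$nrow * 10)
  w_out <- mean(w) * out_frac * params$in_out_balance
  # the current sector competes: an unattractive ring aborts the migration
  w_home <- params$home_weight_factor * (attractiveness[sector_idx] + eps)
  pick <- sample.int(length(cand) + 2L, 1L, prob = c(w, w_out, w_home))
  if (pick == length(cand) + 2L) sector_idx
  else if (pick == length(cand) + 1L) NA_integer_
  else cand[pick]
}

# age-dependent canopy-gap penalty (piecewise linear over the knots)
gap_penalty_at <- function(age, params) {
  v <- params$canopy_gap_penalty
  if (length(v) == 1L) return(v)
  if (is.null(age)) return(v[1])
  stats::approx(params$gap_penalty_knots, v, xout = age, rule = 2)$y
}

#' Open-ground crossings between sector pairs
#'
#' For every (origin, destination) pair, the expected number of open
#' (canopy-free) sectors the straight flight path crosses, estimated by
#' sampling points along the path: (fraction of sampled intermediate points
#' over open ground) x (path length in sectors).  A sector counts as open
#' when its canopy cover is below \code{open_threshold}.  Used by
#' \code{\link{choose_destination}} to channel relocations along contiguous
#' canopy.
#'
#' @param farm a \code{farm_grid}.
#' @param from origin sector indices (default: all).
#' @param n_points sample points per path.
#' @param open_threshold canopy cover below which a sector is open ground.
#' @return matrix \code{length(from) x n_sectors} of crossing counts.
#' @export
canopy_gap_matrix <- function(farm, from = seq_len(nrow(farm$sectors)),
                              n_points = 12, open_threshold = 0.2) {
  s <- farm$sectors
  open <- s$canopy_cover < open_threshold
  n <- nrow(s)
  out <- matrix(0, nrow = length(from), ncol = n)
  tt <- (seq_len(n_points) - 0.5) / n_points
  for (k in seq_along(from)) {
    i <- from[k]
    frac_open <- numeric(n)
    for (t in tt) {
      px <- s$x[i] + t * (s$x - s$x[i])
      py <- s$y[i] + t * (s$y - s$y[i])
      idx <- pmin(farm$nrow - 1, pmax(0, floor(py / 10))) * farm$ncol +
        pmin(farm$ncol - 1, pmax(0, floor(px / 10))) + 1
      frac_open <- frac_open + open[idx]
    }
    frac_open <- frac_open / n_points
    dist_sect <- sqrt((s$x - s$x[i])^2 + (s$y - s$y[i])^2) / 10
    out[k, ] <- frac_open * dist_sect
  }
  out
}

# Fraction of the circle of radius r centred at (x, y) lying outside the
# [0, width] x [0, height] farm rectangle; evaluated on 72 arc points.
ring_outside_fraction <- function(x, y, r, width, height) {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  px <- x + r * cos(th); py <- y + r * sin(th)
  mean(px < 0 | px > width | py < 0 | py > height)
}

#' One female's daily movement decision
#'
#' If the weather gates exploration off, the female stays put.  Otherwise she
#' undertakes a micro-migration with probability \code{migration_propensity
#' (age) x leave_multiplier(local infestation, density)} (capped at 1), with
#' the destination drawn by \code{\link{choose_destination}}; failing that
#' she performs a local exploration errand, which by construction stays
#' within her current 100 m2 sector.
#'
#' @param sector_idx current sector index.
#' @param age female age (days).
#' @param farm a \code{farm_grid}.
#' @param explore logical: does the day's weather allow explorative activity?
#' @param attractiveness per-sector attractiveness vector for the day.
#' @param local_infestation,local_density niche state of the current sector.
#' @param params a \code{\link{mobility_params}}.
#' @return list \code{(sector, emigrated)}: new sector index and emigration
#'   flag.
#' @export
daily_movement <- function(sector_idx, age, farm, explore, attractiveness,
                           local_infestation = 0, local_density = 0,
                           params = mobility_params()) {
  if (!explore) return(list(sector = sector_idx, emigrated = FALSE))
  p <- min(1, migration_propensity(age, params) *
             leave_multiplier(local_infestation, local_density))
  if (stats::runif(1) >= p) return(list(sector = sector_idx, emigrated = FALSE))
  d <- sample_migration_distance(age, params)
  dest <- choose_destination(sector_idx, farm, d, attractiveness, params,
                             age = age)
  if (is.na(dest)) list(sector = sector_idx, emigrated = TRUE)
  else list(sector = dest, emigrated = FALSE)
}

#' Attempt oviposition in a sector
#'
#' The intended egg load is an individual draw around the age-specific mean
#' fecundity, modulated by the niche multiplier; eggs are laid singly (one
#' egg per fruit, enforced by the oviposition-marking pheromone), so the
#' number placed is capped by the suitable, uninfested fruit available.
#'
#' @param age female age (days).
#' @param available_fruit suitable uninfested fruit in the sector.
#' @param curve a \code{\link{fecundity_curve}}.
#' @param oviposit logical: does the day's weather allow oviposition?
#' @param infestation,density,capacity niche state for the modulation.
#' @return integer number of eggs placed (each into a distinct fruit).
#' @export
oviposition_attempt <- function(age, available_fruit, curve, oviposit = TRUE,
                                infestation = 0, density = 0, capacity = 20) {
  if (!oviposit || available_fruit <= 0) return(0L)
  intended <- round(draw_daily_eggs(age, curve) *
                      niche_multiplier(infestation, density, capacity))
  as.integer(min(intended, available_fruit))
}
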