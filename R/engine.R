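## Simulation engine: daily loop over agents and sectors, fate ledger,
## replicate runs, mark-recapture virtual experiment.

FATES <- c("alive", "died_intrinsic", "died_extrinsic", "died_weather",
           "died_pesticide", "trapped", "emigrated")

#' Scenario configuration
#'
#' Bundles everything one simulation run needs: the farm, the weather, the
#' emergence settings, the parameter blocks and the treatment calendar.
#'
#' @param farm a \code{\link{farm_grid}}.
#' @param weather a \code{weather_series} covering at least
#'   \code{duration_days} from \code{start_date}.
#' @param start_date first simulated day (all seasons start 15 May by
#'   default).
#' @param duration_days season length in days; must cover the latest harvest.
#' @param emergence list with \code{window_days} (35--50), \code{peak14_target}
#'   (0.70--0.90) and \code{start_day} (season day the emergence window
#'   opens).
#' @param demography a \code{\link{demog_params}}.
#' @param mobility a \code{\link{mobility_params}}.
#' @param traps a \code{\link{trap_params}}; traps listed on the farm grid
#'   are deployed on \code{trap_deploy_day}.
#' @param applications list of \code{\link{pesticide_application}}s.
#' @param harvests list of \code{\link{harvest_event}}s; when \code{NULL},
#'   every host plot is harvested on its cultivar's harvest date(s) with
#'   \code{harvest_accuracy}.
#' @param harvest_accuracy default harvest accuracy for auto-generated
#'   harvest events.
#' @param trap_deploy_day season day the monitoring traps go out.
#' @param replicates number of replicate runs for
#'   \code{\link{run_replicates}}.
#' @param master_seed integer seed from which per-replicate streams are
#'   derived.
#' @param in_out_balance immigration:emigration ratio across the boundary.
#' @param nonhost_attraction baseline attraction of non-host tree sectors.
#' @param density_capacity niche crowding normalization (females/sector).
#' @param immature_temp mean season temperature used for the in-fruit
#'   development duration; computed from the weather series when NULL.
#' @param record_density record the day x sector female density matrix?
#' @return a \code{scenario_config} list.
#' @export
scenario_config <- function(farm, weather,
                            start_date = as.Date("2015-05-15"),
                            duration_days = 100,
                            emergence = list(window_days = 42,
                                             peak14_target = 0.8,
                                             start_day = 1),
                            demography = demog_params(),
                            mobility = mobility_params(),
                            traps = trap_params(),
                            applications = list(),
                            harvests = NULL,
                            harvest_accuracy = 0.8,
                            trap_deploy_day = 1,
                            replicates = 5,
                            master_seed = 1,
                            in_out_balance = 1,
                            nonhost_attraction = 0.10,
                            density_capacity = 20,
                            immature_temp = NULL,
                            record_density = FALSE) {
  stopifnot(inherits(farm, "farm_grid"), replicates >= 1, duration_days >= 1)
  start_date <- as.Date(start_date)
  if (nrow(weather) < duration_days)
    stop("weather series shorter than the simulation duration")
  if (!weather$date[1] == start_date)
    stop("weather series must start on the scenario start date")
  mobility$in_out_balance <- in_out_balance
  if (is.null(immature_temp))
    immature_temp <- mean(weather$tavg[seq_len(duration_days)])
  if (is.null(harvests)) {
    harvests <- auto_harvests(farm, harvest_accuracy)
  }
  for (h in harvests) {
    if (as.integer(h$date - start_date) + 1 > duration_days)
      stop("duration_days does not cover the harvest on ", format(h$date))
  }
  structure(list(farm = farm, weather = weather, start_date = start_date,
                 duration_days = duration_days, emergence = emergence,
                 demography = demography, mobility = mobility,
                 traps = traps, applications = applications,
                 harvests = harvests, trap_deploy_day = trap_deploy_day,
                 replicates = replicates, master_seed = master_seed,
                 nonhost_attraction = nonhost_attraction,
                 density_capacity = density_capacity,
                 immature_temp = immature_temp,
                 record_density = record_density),
            class = "scenario_config")
}

# one harvest event per (cultivar x harvest date), all that cultivar's sectors
auto_harvests <- function(farm, accuracy) {
  cv <- farm$cultivars
  if (is.null(cv)) return(list())
  out <- list()
  for (i in seq_len(nrow(cv))) {
    secs <- which(farm$sectors$cover_type == "host" &
                    farm$sectors$cultivar == cv$name[i])
    if (!length(secs)) next
    for (h in c(cv$harvest1[i], cv$harvest2[i])) {
      if (is.na(h)) next
      out[[length(out) + 1L]] <- harvest_event(h, secs, accuracy)
    }
  }
  out
}

# deterministic per-replicate seed from (master_seed, replicate_index)
replicate_seed <- function(master_seed, replicate_index) {
  as.integer((as.numeric(master_seed) * 7919 + replicate_index * 104729) %%
               2147483647)
}

#' Run one full-season simulation
#'
#' Executes the daily loop over the configured season.  The fixed daily
#' event order is: spring emergence (and queued immigration); intrinsic
#' (Gompertz) mortality; extrinsic natural-enemy mortality; weather
#' mortality; activity gating and movement (including boundary exchange);
#' adult pesticide risk at the end-of-day sector; oviposition; trap capture;
#' fruit-state update (larval mortality, fruit recovery, exits to the
#' overwinter pool); harvest events; ledger check.  Ages increment at day
#' end.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param replicate_index replicate number; the RNG stream is derived
#'   deterministically from \code{(master_seed, replicate_index)}.
#' @return a \code{cherry_sim} object; see \code{\link{summary.cherry_sim}}.
#' @export
run_simulation <- function(config, replicate_index = 1) {
  set.seed(replicate_seed(config$master_seed, replicate_index))
  st <- init_state(config)
  for (day in seq_len(config$duration_days)) st <- daily_step(st, day)
  finish_output(st, replicate_index)
}

init_state <- function(config) {
  farm <- config$farm
  s <- farm$sectors
  n_sec <- nrow(s)
  duration <- config$duration_days

  # emergence calendar: day x sector counts, one schedule per seeded sector
  emerge <- matrix(0L, nrow = duration, ncol = n_sec)
  for (j in which(s$initial_pupae > 0)) {
    sched <- build_emergence_schedule(s$initial_pupae[j],
                                      config$emergence$window_days,
                                      config$emergence$peak14_target,
                                      config$emergence$start_day)
    days <- sched$start_day + seq_along(sched$daily_counts) - 1L
    keep <- days <= duration
    emerge[days[keep], j] <- sched$daily_counts[keep]
  }

  trap_idx <- which(!is.na(s$trap_id))
  traps <- data.frame(trap_id = s$trap_id[trap_idx], sector = trap_idx,
                      deploy_day = config$trap_deploy_day,
                      stringsAsFactors = FALSE)

  # per-cultivar attractiveness bell and suitability flag per season day
  cv <- farm$cultivars
  bell <- NULL
  if (!is.null(cv) && nrow(cv)) {
    dates <- config$start_date + seq_len(duration) - 1
    bell <- sapply(seq_len(nrow(cv)), function(i)
      daily_fruit_attractiveness(cv[i, ], dates))
    if (is.null(dim(bell))) bell <- matrix(bell, nrow = duration)
    colnames(bell) <- cv$name
  }

  sector_cv <- match(s$cultivar, if (is.null(cv)) character() else cv$name)

  dur0 <- immature_duration(config$immature_temp)

  gapmat <- if (any(config$mobility$canopy_gap_penalty < 1))
    canopy_gap_matrix(farm) else NULL

  list(config = config, farm = farm, n_sec = n_sec,
       emerge = emerge, traps = traps, bell = bell, sector_cv = sector_cv,
       immature_dur = dur0, gapmat = gapmat,
       # agents (parallel vectors)
       age = integer(0), sector = integer(0), fate = integer(0),
       eggs = integer(0), natal = integer(0), cohort = character(0),
       # per-sector fruit state
       fruit_total = as.integer(s$fruit_count), damaged = integer(n_sec),
       recovering = integer(n_sec), pool = numeric(n_sec),
       harvested = logical(n_sec),
       # occupant records (active in-fruit immatures)
       occ_sector = integer(0), occ_day = integer(0), occ_dur = integer(0),
       # fruit recovery queue
       rec_sector = integer(0), rec_free = integer(0),
       # egg ledger
       eggs_laid = 0L, eggs_killed_fruit = 0L, eggs_killed_harvest = 0L,
       eggs_concealed = 0L, eggs_pooled = 0L, eggs_recovered = 0L,
       # flow ledger
       emerged = 0L, immigrated = 0L, pending_immigrants = integer(0),
       # outputs
       catch = matrix(0L, nrow = duration, ncol = nrow(traps),
                      dimnames = list(NULL, traps$trap_id)),
       age_structure = matrix(0L, nrow = duration, ncol = 4,
                              dimnames = list(NULL, c("immature", "mature",
                                                      "old", "senile"))),
       density = if (config$record_density)
         matrix(0L, nrow = duration, ncol = n_sec) else NULL,
       harvest_reports = list())
}

active_occupied <- function(st) {
  tabulate(st$occ_sector, st$n_sec)
}

sector_infestation <- function(st) {
  inf <- active_occupied(st) + st$damaged
  ifelse(st$fruit_total > 0, pmin(1, inf / st$fruit_total), 0)
}

available_fruit <- function(st, suitable) {
  av <- st$fruit_total - active_occupied(st) - st$damaged - st$recovering
  av[!suitable | st$harvested] <- 0L
  pmax(0L, av)
}

add_agents <- function(st, n, sectors, ages, cohort = NA_character_) {
  if (n == 0) return(st)
  st$age <- c(st$age, as.integer(ages))
  st$sector <- c(st$sector, as.integer(sectors))
  st$fate <- c(st$fate, integer(n))
  st$eggs <- c(st$eggs, integer(n))
  st$natal <- c(st$natal, as.integer(sectors))
  st$cohort <- c(st$cohort, rep(cohort, n))
  st
}

daily_step <- function(st, day) {
  cfg <- st$config
  farm <- st$farm
  date <- cfg$start_date + day - 1
  w <- cfg$weather[day, ]

  ## (1) emergence + queued immigration
  em <- st$emerge[day, ]
  for (j in which(em > 0)) {
    st <- add_agents(st, em[j], rep(j, em[j]), rep(0L, em[j]))
    st$emerged <- st$emerged + em[j]
  }
  if (length(st$pending_immigrants)) {
    border <- border_host_sectors(farm)
    n_im <- length(st$pending_immigrants)
    st <- add_agents(st, n_im,
                     sample(border, n_im, replace = TRUE),
                     st$pending_immigrants, cohort = "immigrant")
    st$immigrated <- st$immigrated + n_im
    st$pending_immigrants <- integer(0)
  }

  alive <- which(st$fate == 0L)

  ## (2) intrinsic mortality (hazard forced to 1 at the age cap)
  if (length(alive)) {
    h <- intrinsic_daily_mortality(st$age[alive], cfg$demography)
    dead <- alive[stats::runif(length(alive)) < h]
    st$fate[dead] <- 1L
    alive <- setdiff(alive, dead)
  }

  ## (3) extrinsic natural-enemy risk (with pesticide suppression)
  if (length(alive)) {
    enemy <- enemy_risk_vector(st, date)
    dead <- alive[stats::runif(length(alive)) < enemy[st$sector[alive]]]
    st$fate[dead] <- 2L
    alive <- setdiff(alive, dead)
  }

  ## (4) weather mortality, sheltered by the local canopy
  if (length(alive)) {
    shelter <- farm$sectors$canopy_cover[st$sector[alive]]
    wm <- weather_mortality(w, shelter)
    dead <- alive[stats::runif(length(alive)) < wm]
    st$fate[dead] <- 3L
    alive <- setdiff(alive, dead)
  }

  ## (5) activity gating + movement
  gate <- activity_gate(w)
  suitable <- sector_suitable(st, day)
  if (gate$explore && length(alive)) {
    dens <- tabulate(st$sector[alive], st$n_sec)
    infest <- sector_infestation(st)
    att <- attractiveness_vector(farm, st$bell[day, ], dens, infest,
                                 cfg$nonhost_attraction, cfg$density_capacity)
    p_mig <- pmin(1, migration_propensity(st$age[alive], cfg$mobility) *
                    leave_multiplier(infest[st$sector[alive]],
                                     dens[st$sector[alive]],
                                     cfg$density_capacity))
    movers <- alive[stats::runif(length(alive)) < p_mig]
    if (length(movers)) {
      dist <- sample_migration_distance(st$age[movers], cfg$mobility)
      for (k in seq_along(movers)) {
        i <- movers[k]
        dest <- choose_destination(st$sector[i], farm, dist[k], att,
                                   cfg$mobility,
                                   gap_crossings = if (is.null(st$gapmat))
                                     NULL else st$gapmat[st$sector[i], ],
                                   age = st$age[i])
        if (is.na(dest)) {
          st$fate[i] <- 6L
          # balanced boundary: an immigrant arrives (in expectation 1:1)
          if (stats::runif(1) < cfg$mobility$in_out_balance) {
            pool_ages <- st$age[st$fate == 0L]
            im_age <- if (length(pool_ages)) sample(pool_ages, 1) else st$age[i]
            st$pending_immigrants <- c(st$pending_immigrants, im_age)
          }
        } else {
          st$sector[i] <- dest
        }
      }
      alive <- which(st$fate == 0L)
    }
  }

  ## (6) adult pesticide risk at the end-of-day sector
  if (length(alive) && length(cfg$applications)) {
    arisk <- pesticide_risk_vector(st, date)$adult
    dead <- alive[stats::runif(length(alive)) < arisk[st$sector[alive]]]
    st$fate[dead] <- 4L
    alive <- setdiff(alive, dead)
  }

  ## (7) oviposition
  if (gate$oviposit && length(alive)) {
    avail <- available_fruit(st, suitable)
    dens <- tabulate(st$sector[alive], st$n_sec)
    infest <- sector_infestation(st)
    cand <- alive[avail[st$sector[alive]] > 0 &
                    st$age[alive] > cfg$demography$maturation_onset]
    for (i in cand) {
      sec <- st$sector[i]
      if (avail[sec] <= 0) next
      laid <- oviposition_attempt(st$age[i], avail[sec],
                                  cfg$demography$fecundity, TRUE,
                                  infest[sec], dens[sec],
                                  cfg$density_capacity)
      if (laid > 0) {
        st$eggs[i] <- st$eggs[i] + laid
        st$eggs_laid <- st$eggs_laid + laid
        durs <- st$immature_dur + sample(-1:1, laid, replace = TRUE)
        st$occ_sector <- c(st$occ_sector, rep(sec, laid))
        st$occ_day <- c(st$occ_day, rep(day, laid))
        st$occ_dur <- c(st$occ_dur, durs)
        avail[sec] <- avail[sec] - laid
      }
    }
  }

  ## (8) trap capture
  if (length(alive) && nrow(st$traps)) {
    tsec <- st$traps$sector
    in_trap <- alive[st$sector[alive] %in% tsec]
    for (i in in_trap) {
      t <- match(st$sector[i], tsec)
      if (day < st$traps$deploy_day[t]) next
      p <- trap_capture_probability(day - st$traps$deploy_day[t], st$age[i],
                                    cfg$traps)
      if (stats::runif(1) < p) {
        st$fate[i] <- 5L
        st$catch[day, t] <- st$catch[day, t] + 1L
      }
    }
    alive <- which(st$fate == 0L)
  }

  ## (9) fruit-state update
  st <- fruit_state_update(st, day, date)

  ## (10) harvest events dated today
  for (h in cfg$harvests) {
    if (as.integer(h$date - cfg$start_date) + 1L == day)
      st <- harvest_plot(st, h, day)
  }

  ## (11) ledger + logging
  st$age_structure[day, ] <- age_category_counts(st$age[st$fate == 0L])
  if (!is.null(st$density))
    st$density[day, ] <- tabulate(st$sector[st$fate == 0L], st$n_sec)
  created <- st$emerged + st$immigrated
  accounted <- length(st$fate)  # every agent row has exactly one fate/alive
  if (created != accounted)
    stop("fate ledger imbalance on day ", day, ": created ", created,
         " accounted ", accounted)

  st$age[st$fate == 0L] <- st$age[st$fate == 0L] + 1L
  st
}

# is each sector's fruit inside its cultivar's suitability window on `day`?
sector_suitable <- function(st, day) {
  if (is.null(st$bell)) return(logical(st$n_sec))
  b <- st$bell[day, ]
  out <- logical(st$n_sec)
  h <- !is.na(st$sector_cv)
  out[h] <- b[st$sector_cv[h]] > 0
  out
}

border_host_sectors <- function(farm) {
  s <- farm$sectors
  border <- s$row == 0 | s$row == farm$nrow - 1 |
    s$col == 0 | s$col == farm$ncol - 1
  idx <- which(border & s$cover_type == "host")
  if (!length(idx)) idx <- which(s$cover_type == "host")
  if (!length(idx)) idx <- which(border)
  idx
}

enemy_risk_vector <- function(st, date, baseline = 0.03) {
  risk <- rep(baseline, st$n_sec)
  for (ap in st$config$applications) {
    d <- as.integer(date - ap$date)
    if (d < 0 || d > ap$enemy_suppression_days) next
    for (j in ap$sectors)
      risk[j] <- min(risk[j],
                     natural_enemy_risk(list(ap), j, date, st$farm, baseline))
  }
  risk
}

pesticide_risk_vector <- function(st, date) {
  adult <- numeric(st$n_sec); larval <- numeric(st$n_sec)
  for (ap in st$config$applications) {
    d <- as.integer(date - ap$date)
    if (d < 0) next
    a <- min(1, max(0, ap$adult_profile(d)))
    l <- min(1, max(0, ap$larval_profile(d)))
    adult[ap$sectors] <- 1 - (1 - adult[ap$sectors]) * (1 - a)
    larval[ap$sectors] <- 1 - (1 - larval[ap$sectors]) * (1 - l)
  }
  list(adult = adult, larval = larval)
}

# daily occupant mortality, 5-day fruit recovery, exits to the overwinter pool
fruit_state_update <- function(st, day, date) {
  # release recovered fruit
  if (length(st$rec_free)) {
    due <- st$rec_free <= day
    if (any(due)) {
      st$recovering <- st$recovering - tabulate(st$rec_sector[due], st$n_sec)
      st$rec_sector <- st$rec_sector[!due]
      st$rec_free <- st$rec_free[!due]
    }
  }
  n_occ <- length(st$occ_sector)
  if (!n_occ) return(st)
  lrisk <- if (length(st$config$applications))
    pesticide_risk_vector(st, date)$larval else numeric(st$n_sec)
  r <- lrisk[st$occ_sector]
  dies <- stats::runif(n_occ) < r
  infruit_age <- day - st$occ_day
  matured <- !dies & infruit_age >= st$occ_dur
  if (any(dies)) {
    early <- dies & infruit_age < 5          # fruit heals, reusable on day 5
    late <- dies & !early
    st$eggs_killed_fruit <- st$eggs_killed_fruit + sum(dies)
    st$eggs_recovered <- st$eggs_recovered + sum(early)
    if (any(early)) {
      st$recovering <- st$recovering + tabulate(st$occ_sector[early], st$n_sec)
      st$rec_sector <- c(st$rec_sector, st$occ_sector[early])
      st$rec_free <- c(st$rec_free, st$occ_day[early] + 5L)
    }
    if (any(late))
      st$damaged <- st$damaged + tabulate(st$occ_sector[late], st$n_sec)
  }
  if (any(matured)) {
    st$pool <- st$pool + tabulate(st$occ_sector[matured], st$n_sec)
    st$damaged <- st$damaged + tabulate(st$occ_sector[matured], st$n_sec)
    st$eggs_pooled <- st$eggs_pooled + sum(matured)
  }
  keep <- !dies & !matured
  st$occ_sector <- st$occ_sector[keep]
  st$occ_day <- st$occ_day[keep]
  st$occ_dur <- st$occ_dur[keep]
  st
}

# harvest a plot: per-fruit picking at `accuracy`, occupant fates, assessment
harvest_plot <- function(st, event, day) {
  secs <- intersect(event$sectors, which(!st$harvested))
  if (!length(secs)) return(st)
  acc <- event$accuracy
  occ_idx <- which(st$occ_sector %in% secs)
  n_active <- length(occ_idx)
  dam <- sum(st$damaged[secs])
  total <- sum(st$fruit_total[secs])
  unin <- total - dam - n_active
  if (total == 0) {
    warning("harvest on a plot with no fruit")
    return(st)
  }
  picked_act <- occ_idx[stats::runif(n_active) < acc]
  left_act <- setdiff(occ_idx, picked_act)
  h_dam <- stats::rbinom(1, dam, acc)
  h_unin <- stats::rbinom(1, unin, acc)
  yield <- length(picked_act) + h_dam + h_unin

  concealed <- picked_act[day - st$occ_day[picked_act] <= 4]
  killed <- setdiff(picked_act, concealed)
  st$eggs_concealed <- st$eggs_concealed + length(concealed)
  st$eggs_killed_harvest <- st$eggs_killed_harvest + length(killed)
  # occupants of fruit left on the tree complete development into the pool
  if (length(left_act)) {
    st$pool <- st$pool + tabulate(st$occ_sector[left_act], st$n_sec)
    st$eggs_pooled <- st$eggs_pooled + length(left_act)
  }
  drop <- c(picked_act, left_act)
  keep <- setdiff(seq_along(st$occ_sector), drop)
  st$occ_sector <- st$occ_sector[keep]
  st$occ_day <- st$occ_day[keep]
  st$occ_dur <- st$occ_dur[keep]

  # infestation assessment on a random sample of the harvested fruit;
  # concealed (< 4 d old) infestations look unblemished and are not seen
  visible <- h_dam + length(killed)
  m <- min(event$assessment_sample, yield)
  assessed <- if (m > 0 && yield > 0)
    stats::rhyper(1, visible, yield - visible, m) / m else NA_real_

  st$harvested[secs] <- TRUE
  st$harvest_reports[[length(st$harvest_reports) + 1L]] <- list(
    day = day, date = event$date, sectors = secs,
    cultivar = unique(st$farm$sectors$cultivar[secs]),
    accuracy = acc, yield_fruit = yield,
    assessed_infestation = assessed,
    larvae_killed = length(killed), larvae_left = length(left_act),
    concealed = length(concealed))
  st
}

age_category_counts <- function(ages) {
  c(immature = sum(ages <= 10), mature = sum(ages >= 11 & ages <= 30),
    old = sum(ages >= 31 & ages <= 60), senile = sum(ages > 60))
}

finish_output <- function(st, replicate_index) {
  cfg <- st$config
  fate_counts <- tabulate(st$fate + 1L, length(FATES))
  names(fate_counts) <- FATES
  harvests <- if (length(st$harvest_reports)) {
    do.call(rbind, lapply(st$harvest_reports, function(h)
      data.frame(day = h$day, date = h$date,
                 cultivar = paste(h$cultivar, collapse = "+"),
                 accuracy = h$accuracy, yield_fruit = h$yield_fruit,
                 assessed_infestation = h$assessed_infestation,
                 larvae_killed = h$larvae_killed,
                 larvae_left = h$larvae_left, concealed = h$concealed)))
  } else NULL
  next_spring <- round(overwinter_recruits(st$pool, cfg$demography,
                                           female_only = TRUE))
  # realized fecundity by natal plot (cultivar of the natal sector)
  natal_cv <- st$farm$sectors$cultivar[st$natal]
  fec <- if (length(st$eggs) && any(!is.na(natal_cv)))
    stats::aggregate(list(eggs = st$eggs[!is.na(natal_cv)]),
                     by = list(cultivar = natal_cv[!is.na(natal_cv)]), mean)
  else NULL
  structure(list(
    replicate = replicate_index,
    catch = st$catch, age_structure = st$age_structure,
    density = st$density,
    harvests = harvests,
    fate_counts = fate_counts,
    emerged = st$emerged, immigrated = st$immigrated,
    egg_ledger = c(laid = st$eggs_laid, killed_in_fruit = st$eggs_killed_fruit,
                   killed_by_harvest = st$eggs_killed_harvest,
                   concealed = st$eggs_concealed, pooled = st$eggs_pooled),
    carryover_pool = st$pool,
    next_spring_map = next_spring,
    fecundity_by_plot = fec,
    agents = data.frame(age = st$age, sector = st$sector,
                        fate = FATES[st$fate + 1L], eggs = st$eggs,
                        natal = st$natal, cohort = st$cohort,
                        stringsAsFactors = FALSE),
    config_summary = list(duration = cfg$duration_days,
                          start = cfg$start_date,
                          master_seed = cfg$master_seed)),
    class = "cherry_sim")
}

#' @export
print.cherry_sim <- function(x, ...) {
  cat("cherry_sim: one replicate of a virtual-farm season\n")
  cat(sprintf("  %d days from %s; %d females emerged, %d immigrated\n",
              x$config_summary$duration, format(x$config_summary$start),
              x$emerged, x$immigrated))
  cat("  fates: ",
      paste(names(x$fate_counts), x$fate_counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  eggs laid: %d; carry-over pool: %d; trap catch total: %d\n",
              x$egg_ledger[["laid"]], sum(x$carryover_pool), sum(x$catch)))
  invisible(x)
}

#' @export
summary.cherry_sim <- function(object, ...) {
  h <- object$harvests
  out <- list(fates = object$fate_counts, eggs = object$egg_ledger,
              total_catch = sum(object$catch),
              carryover = sum(object$carryover_pool),
              next_spring = sum(object$next_spring_map),
              harvests = h)
  class(out) <- "summary.cherry_sim"
  out
}

#' @export
print.summary.cherry_sim <- function(x, ...) {
  cat("Season summary\n  fates: ",
      paste(names(x$fates), x$fates, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  egg ledger: ",
      paste(names(x$eggs), x$eggs, sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  total trap catch: %d; carry-over pool: %d; expected next-spring females: %d\n",
              x$total_catch, x$carryover, x$next_spring))
  if (!is.null(x$harvests)) {
    cat("  harvests:\n")
    print(x$harvests[, c("date", "cultivar", "accuracy", "yield_fruit",
                         "assessed_infestation")], row.names = FALSE)
  }
  invisible(x)
}

#' Plot daily trap catches of a simulated season
#'
#' @param x a \code{cherry_sim}.
#' @param ... passed to \code{matplot}.
#' @export
plot.cherry_sim <- function(x, ...) {
  graphics::matplot(x$catch, type = "l", lty = 1,
                    xlab = "season day", ylab = "daily catch", ...)
  graphics::legend("topright", colnames(x$catch), lty = 1,
                   col = seq_len(ncol(x$catch)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Run replicate simulations with a homogeneity check
#'
#' Runs \code{config$replicates} independent replicates (seeds derived from
#' the master seed), verifies the homogeneity of the replicate trap-catch
#' tables with a Monte-Carlo chi-square test, and assembles the per-point
#' mean and SD series needed for 3-sigma control charts.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param check_every trap-check interval (days) for the aggregated catch
#'   tables.
#' @return a \code{replicate_set}: list with \code{outputs} (list of
#'   \code{cherry_sim}), \code{catch_tables} (replicate x (trap x check)
#'   matrix), \code{mean}, \code{sd} and \code{homogeneity}
#'   (\code{\link{replicate_homogeneity}} result, or NULL for a single
#'   replicate).
#' @export
run_replicates <- function(config, check_every = 7) {
  outs <- lapply(seq_len(config$replicates),
                 function(k) run_simulation(config, k))
  tables <- lapply(outs, function(o) aggregate_catch(o$catch, check_every))
  flat <- t(vapply(tables, function(m) as.numeric(m),
                   numeric(length(tables[[1]]))))
  hom <- NULL
  if (config$replicates >= 2) {
    hom <- tryCatch(replicate_homogeneity(tables),
                    error = function(e) NULL)
  } else {
    warning("single replicate: homogeneity check skipped")
  }
  structure(list(outputs = outs, catch_tables = tables,
                 points = expand.grid(trap = colnames(tables[[1]]),
                                      check = rownames(tables[[1]])),
                 mean = colMeans(flat), sd = apply(flat, 2, stats::sd),
                 homogeneity = hom),
            class = "replicate_set")
}

# aggregate a day x trap catch matrix into check-interval x trap counts
aggregate_catch <- function(catch, check_every = 7) {
  breaks <- seq(0, nrow(catch) + check_every - 1, by = check_every)
  grp <- findInterval(seq_len(nrow(catch)) - 1, breaks)
  out <- rowsum(catch, grp)
  rownames(out) <- paste0("check", seq_len(nrow(out)))
  t(out)  # trap x check
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d replicates\n", length(x$outputs)))
  if (!is.null(x$homogeneity))
    cat(sprintf("  homogeneity chi-square = %.2f, MC p = %.3f\n",
                x$homogeneity$statistic, x$homogeneity$p_montecarlo))
  invisible(x)
}

#' Simulate the mark-recapture virtual experiment
#'
#' Releases marked female cohorts of known ages at the release sector of a
#' zoned farm layout (\code{\link{build_jki_markrecapture_layout}}) and
#' runs the daily loop -- mortality, movement, trapping; no oviposition
#' bookkeeping -- for the experiment duration, under benign weather.
#' Recaptures are aggregated by zone, day and cohort.
#'
#' @param layout a \code{farm_grid} with \code{zones} and
#'   \code{release_sector}.
#' @param cohorts list of \code{c(age, count)} pairs (or a 2-column matrix).
#' @param days experiment duration (days).
#' @param replicates number of replicate experiments.
#' @param seed master seed.
#' @param demography,mobility,traps parameter blocks.
#' @param trapping set FALSE to disable trapping (control runs).
#' @param natural_mortality apply intrinsic + extrinsic mortality to the
#'   released flies?
#' @return a \code{mark_recapture} object: recapture counts by replicate x
#'   cohort x zone and by day, plus per-cohort summary rates (percent).
#' @export
simulate_mark_recapture <- function(layout,
                                    cohorts = list(c(5, 300), c(14, 300),
                                                   c(28, 300)),
                                    days = 15, replicates = 5, seed = 1,
                                    demography = demog_params(),
                                    mobility = mobility_params(),
                                    traps = trap_params(),
                                    trapping = TRUE,
                                    natural_mortality = TRUE) {
  if (is.null(layout$zones) || is.null(layout$release_sector))
    stop("layout must carry zones and a release sector")
  zones <- layout$zones
  s <- layout$sectors
  trap_idx <- which(!is.na(s$trap_id))
  trap_zone <- vapply(trap_idx, function(j) {
    z <- names(zones)[vapply(zones, function(zz) j %in% zz, TRUE)]
    if (length(z)) z[1] else "outside"
  }, "")
  zone_names <- c(names(zones), "outside")
  cohorts <- lapply(cohorts, as.numeric)
  cohort_ages <- vapply(cohorts, `[`, 0, 1)
  cohort_names <- paste0("age", cohort_ages)

  # static phenology over the short experiment: evaluate at the release date
  bell <- cultivar_bell(layout, as.Date("2015-06-15"))
  gapmat <- if (any(mobility$canopy_gap_penalty < 1))
    canopy_gap_matrix(layout) else NULL

  rec <- array(0L, dim = c(replicates, length(cohorts), length(zone_names)),
               dimnames = list(NULL, cohort_names, zone_names))
  rec_day <- array(0L, dim = c(replicates, length(cohorts), days),
                   dimnames = list(NULL, cohort_names, NULL))
  released <- vapply(cohorts, `[`, 0, 2)

  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(seed, r))
    age <- rep(cohort_ages, released)
    coh <- rep(seq_along(cohorts), released)
    sec <- rep(layout$release_sector, length(age))
    alive <- rep(TRUE, length(age))
    for (day in seq_len(days)) {
      idx <- which(alive)
      if (!length(idx)) break
      if (natural_mortality) {
        h <- intrinsic_daily_mortality(age[idx], demography)
        h <- 1 - (1 - h) * (1 - demography$extrinsic_daily_risk)
        dead <- idx[stats::runif(length(idx)) < h]
        alive[dead] <- FALSE
        idx <- which(alive)
      }
      if (length(idx)) {
        dens <- tabulate(sec[idx], nrow(s))
        att <- attractiveness_vector(layout, bell, dens,
                                     numeric(nrow(s)))
        p_mig <- migration_propensity(age[idx], mobility)
        movers <- idx[stats::runif(length(idx)) < p_mig]
        if (length(movers)) {
          dist <- sample_migration_distance(age[movers], mobility)
          for (k in seq_along(movers)) {
            i <- movers[k]
            dest <- choose_destination(sec[i], layout, dist[k], att, mobility,
                                       gap_crossings = if (is.null(gapmat))
                                         NULL else gapmat[sec[i], ],
                                       age = age[i])
            if (is.na(dest)) alive[i] <- FALSE   # left the farm
            else sec[i] <- dest
          }
          idx <- which(alive)
        }
      }
      if (trapping && length(idx)) {
        here <- idx[sec[idx] %in% trap_idx]
        for (i in here) {
          t <- match(sec[i], trap_idx)
          p <- trap_capture_probability(day - 1, age[i], traps)
          if (stats::runif(1) < p) {
            alive[i] <- FALSE
            z <- match(trap_zone[t], zone_names)
            rec[r, coh[i], z] <- rec[r, coh[i], z] + 1L
            rec_day[r, coh[i], day] <- rec_day[r, coh[i], day] + 1L
          }
        }
      }
      age[alive] <- age[alive] + 1L
    }
  }

  tot <- apply(rec, 1:2, sum)                      # replicate x cohort
  rate <- sweep(tot, 2, released, "/") * 100
  share_release <- 100 * rec[, , "release"] /
    ifelse(tot > 0, tot, NA)
  structure(list(recaptures = rec, by_day = rec_day,
                 released = stats::setNames(released, cohort_names),
                 rate_pct = rate,
                 release_share_pct = share_release,
                 zone_names = zone_names, cohort_ages = cohort_ages),
            class = "mark_recapture")
}

#' @export
print.mark_recapture <- function(x, ...) {
  cat("mark_recapture:", dim(x$recaptures)[1], "replicates\n")
  cat("  mean recapture rate (%):\n")
  print(round(colMeans(x$rate_pct), 2))
  cat("  mean release-zone share of recaptures (%):\n")
  print(round(colMeans(x$release_share_pct, na.rm = TRUE), 1))
  cat("  mean recaptures by zone:\n")
  print(round(apply(x$recaptures, 2:3, mean), 2))
  invisible(x)
}
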