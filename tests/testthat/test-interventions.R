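test_that("trap capture probability follows risk, decay and responsiveness", {
  tp <- trap_params()
  # fresh trap, peak-age female
  expect_equal(trap_capture_probability(0, 14, tp), 0.05)
  # 30 days of field exposure
  expect_equal(trap_capture_probability(30, 14, tp), 0.05 * 0.99^30,
               tolerance = 1e-10)
  expect_equal(0.05 * 0.99^30, 0.037, tolerance = 1e-3)
  # a fly in a different sector is never exposed
  expect_equal(trap_capture_probability(0, 14, tp, in_sector = FALSE), 0)
  # responsiveness anchors: 80% at emergence, 100% at peak, 40% floor
  expect_equal(trap_responsiveness(0, tp), 0.8)
  expect_equal(trap_responsiveness(14, tp), 1.0)
  expect_equal(trap_responsiveness(40, tp), 0.4)
  # capture probability never exceeds the base risk
  for (a in c(0, 5, 14, 28, 60))
    expect_lte(trap_capture_probability(0, a, tp), 0.05)
})

test_that("pesticide risk profiles match their modes and combine multiplicatively", {
  apps <- list(pesticide_application("2015-06-05", 1:4, "knockdown"))
  expect_equal(daily_pesticide_risks(apps, 2, "2015-06-05")[["adult"]], 1.0)
  expect_equal(daily_pesticide_risks(apps, 2, "2015-06-07")[["adult"]], 0.0)
  expect_equal(daily_pesticide_risks(apps, 2, "2015-06-05")[["larval"]], 0.0)
  # untreated sector
  expect_equal(unname(daily_pesticide_risks(apps, 9, "2015-06-05")), c(0, 0))
  # systemic larval protection holds at or above 60%/day through day 21
  sy <- pesticide_application("2015-06-05", 1:4, "systemic")
  for (d in 0:21) expect_gte(sy$larval_profile(d), 0.6)
  expect_lt(sy$larval_profile(30), 0.6)
  # overlapping applications combine as complements
  two <- list(sy, pesticide_application("2015-06-10", 1:4, "systemic"))
  r <- daily_pesticide_risks(two, 1, "2015-06-12")
  expect_equal(r[["larval"]], 1 - (1 - 0.9)^2)
})

test_that("natural-enemy risk: 3% baseline, suppression, border-first recovery", {
  farm <- tiny_farm()
  host <- which(farm$sectors$cover_type == "host")
  ap <- list(pesticide_application("2015-06-05", host, "systemic"))
  expect_equal(natural_enemy_risk(list(), 1, "2015-06-05", farm), 0.03)
  # application day: full suppression in the zone
  expect_equal(natural_enemy_risk(ap, host[1], "2015-06-05", farm), 0)
  # beyond the recovery horizon the baseline returns
  expect_equal(natural_enemy_risk(ap, host[1], "2015-07-20", farm), 0.03)
  # border sectors recover no later than interior ones, on every day
  s <- farm$sectors
  interior <- host[s$row[host] == 3 & s$col[host] == 3]  # deepest in the plot
  border <- host[s$row[host] == 2 & s$col[host] == 2]
  for (d in 0:21) {
    day <- as.Date("2015-06-05") + d
    expect_gte(natural_enemy_risk(ap, border, day, farm),
               natural_enemy_risk(ap, interior, day, farm))
  }
})

test_that("harvest kills picked larvae, pools left ones, and conceals fresh eggs", {
  # controlled state via the engine: one plot, all eggs placed on known days
  farm <- tiny_farm(pupae = 0L, fruit = 100L)
  w <- benign_weather(80)
  cfg <- scenario_config(farm, w, duration_days = 80, master_seed = 1)
  # harvest with perfect accuracy: every in-fruit larva dies
  st <- cherryfarm:::init_state(cfg)
  host <- which(farm$sectors$cover_type == "host")
  # 20 occupants deposited 10 days before harvest day 56, 5 deposited 2 days before
  st$occ_sector <- c(rep(host[1], 20), rep(host[2], 5))
  st$occ_day <- c(rep(46L, 20), rep(54L, 5))
  st$occ_dur <- rep(21L, 25)
  st$eggs_laid <- 25L
  ev <- harvest_event(as.Date("2015-05-15") + 55, host, accuracy = 1.0,
                      assessment_sample = 1000)
  st2 <- cherryfarm:::harvest_plot(st, ev, 56L)
  rep <- st2$harvest_reports[[1]]
  expect_equal(rep$larvae_left, 0)
  expect_equal(rep$larvae_killed, 20)   # the 5 fresh ones are concealed
  expect_equal(rep$concealed, 5)
  # assessment sees exactly the 20 visible infestations out of 800 fruit
  expect_equal(rep$assessed_infestation, 20 / 800)

  # accuracy 0.8: about 20% of infested fruit stays and feeds the carry-over
  set.seed(33)
  left <- replicate(300, {
    st3 <- st
    ev2 <- harvest_event(as.Date("2015-05-15") + 55, host, accuracy = 0.8)
    cherryfarm:::harvest_plot(st3, ev2, 56L)$harvest_reports[[1]]$larvae_left
  })
  expect_equal(mean(left) / 25, 0.2, tolerance = 0.02)
})

test_that("fruit-state update: early kills recover the fruit, late kills damage it", {
  farm <- tiny_farm(fruit = 50L)
  w <- benign_weather(80)
  host <- which(farm$sectors$cover_type == "host")
  ap <- pesticide_application("2015-05-20", host, "systemic",
                              larval_profile = function(d) rep(1, length(d)))
  cfg <- scenario_config(farm, w, duration_days = 80, applications = list(ap),
                         master_seed = 1)
  st <- cherryfarm:::init_state(cfg)
  # egg deposited on day 10, killed immediately (risk 1): fruit recovers on day dep+5
  st$occ_sector <- host[1]; st$occ_day <- 10L; st$occ_dur <- 21L
  st2 <- cherryfarm:::fruit_state_update(st, 11L, as.Date("2015-05-15") + 10)
  expect_length(st2$occ_sector, 0)
  expect_equal(st2$recovering[host[1]], 1L)
  expect_equal(st2$damaged[host[1]], 0L)
  st3 <- cherryfarm:::fruit_state_update(st2, 15L, as.Date("2015-05-15") + 14)
  expect_equal(st3$recovering[host[1]], 0L)   # available again on day 5

  # occupant killed 10 days after deposition: fruit permanently damaged
  st$occ_sector <- host[1]; st$occ_day <- 1L; st$occ_dur <- 21L
  st4 <- cherryfarm:::fruit_state_update(st, 11L, as.Date("2015-05-15") + 10)
  expect_equal(st4$damaged[host[1]], 1L)
  expect_equal(st4$eggs_killed_fruit, 1L)

  # zero larval risk: occupant exits to the pool exactly at its duration
  cfg0 <- scenario_config(farm, w, duration_days = 80, master_seed = 1)
  st5 <- cherryfarm:::init_state(cfg0)
  st5$occ_sector <- host[1]; st5$occ_day <- 1L; st5$occ_dur <- 21L
  st6 <- cherryfarm:::fruit_state_update(st5, 21L, as.Date("2015-06-04"))
  expect_length(st6$occ_sector, 1)            # day 20 in fruit: still inside
  st7 <- cherryfarm:::fruit_state_update(st5, 22L, as.Date("2015-06-05"))
  expect_equal(st7$pool[host[1]], 1)
  expect_equal(st7$eggs_pooled, 1L)
})
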