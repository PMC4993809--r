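test_that("a farm with no initial pupae produces identically zero output", {
  farm <- tiny_farm(pupae = 0L)
  cfg <- scenario_config(farm, benign_weather(80), duration_days = 80,
                         master_seed = 1)
  out <- run_simulation(cfg, 1)
  expect_equal(sum(out$catch), 0)
  expect_equal(sum(out$age_structure), 0)
  expect_equal(sum(out$carryover_pool), 0)
  expect_equal(out$egg_ledger[["laid"]], 0L)
})

test_that("fixed seeds give bit-identical reruns; different replicates differ", {
  farm <- tiny_farm(pupae = 3L)
  cfg <- scenario_config(farm, benign_weather(80), duration_days = 80,
                         master_seed = 11)
  a <- run_simulation(cfg, 1)
  b <- run_simulation(cfg, 1)
  expect_identical(a$catch, b$catch)
  expect_identical(a$egg_ledger, b$egg_ledger)
  expect_identical(a$agents, b$agents)
  c2 <- run_simulation(cfg, 2)
  expect_false(identical(a$agents, c2$agents))
})

test_that("the fate ledger reconciles and age categories partition the living", {
  farm <- tiny_farm(pupae = 4L)
  cfg <- scenario_config(farm, generate_weather(90, seed = 2),
                         duration_days = 90, master_seed = 3)
  out <- run_simulation(cfg, 1)   # daily_step aborts on any daily imbalance
  expect_equal(out$emerged + out$immigrated, sum(out$fate_counts))
  alive_daily <- rowSums(out$age_structure)
  expect_true(all(alive_daily >= 0))
  expect_equal(unname(out$fate_counts["alive"]),
               unname(alive_daily[length(alive_daily)]))
  # every laid egg is accounted for: resolved fates never exceed eggs laid,
  # the remainder being occupants still inside fruit at season end
  el <- out$egg_ledger
  expect_gte(el[["laid"]] - el[["killed_in_fruit"]] - el[["killed_by_harvest"]] -
               el[["concealed"]] - el[["pooled"]], 0)
})

test_that("without recruitment or immigration the population only declines", {
  farm <- tiny_farm(pupae = 5L)
  cfg <- scenario_config(farm, benign_weather(100), duration_days = 100,
                         emergence = list(window_days = 35, peak14_target = 0.8,
                                          start_day = 1),
                         in_out_balance = 0, master_seed = 5)
  out <- run_simulation(cfg, 1)
  expect_equal(out$immigrated, 0)
  alive <- rowSums(out$age_structure)
  post <- alive[36:100]
  expect_true(all(diff(post) <= 0))
})

test_that("the next-spring map applies 92% generation mortality and the female fraction", {
  farm <- tiny_farm(pupae = 6L)
  cfg <- scenario_config(farm, benign_weather(85), duration_days = 85,
                         harvests = list(), master_seed = 9)
  out <- run_simulation(cfg, 1)
  expect_true(sum(out$carryover_pool) > 0)
  expect_equal(out$next_spring_map,
               round(out$carryover_pool * 0.08 * 0.5))
})

test_that("replicate runs are homogeneous and carry mean/SD series per point", {
  farm <- tiny_farm(pupae = 6L)
  cfg <- scenario_config(farm, benign_weather(80), duration_days = 80,
                         replicates = 5, master_seed = 21)
  rs <- run_replicates(cfg)
  expect_length(rs$outputs, 5)
  expect_equal(length(rs$mean), length(rs$sd))
  expect_equal(nrow(rs$points), length(rs$mean))
  if (!is.null(rs$homogeneity)) expect_gt(rs$homogeneity$p_montecarlo, 0.05)
  cfg1 <- scenario_config(farm, benign_weather(80), duration_days = 80,
                          replicates = 1, master_seed = 21)
  expect_warning(rs1 <- run_replicates(cfg1), "single replicate")
  expect_null(rs1$homogeneity)
})

test_that("out-trapping: with a fixed local population the expected catch declines", {
  # one trap amid a sedentary population, no recruitment after the window
  farm <- tiny_farm(pupae = 30L)
  cfg <- scenario_config(farm, benign_weather(90), duration_days = 90,
                         emergence = list(window_days = 35, peak14_target = 0.8,
                                          start_day = 1),
                         in_out_balance = 0, master_seed = 2, replicates = 8)
  rs <- run_replicates(cfg, check_every = 30)
  weekly <- Reduce(`+`, rs$catch_tables) / length(rs$catch_tables)
  expect_gt(weekly[1, 1], weekly[1, 3])
})

test_that("mark-recapture machinery: controls behave and age effects go the right way", {
  layout <- build_jki_markrecapture_layout()
  # trapping disabled: zero recaptures
  off <- simulate_mark_recapture(layout, cohorts = list(c(5, 50)), days = 5,
                                 replicates = 2, seed = 1, trapping = FALSE)
  expect_equal(sum(off$recaptures), 0)
  mr <- simulate_mark_recapture(layout, cohorts = list(c(5, 150), c(28, 150)),
                                days = 15, replicates = 12, seed = 2)
  r <- colMeans(mr$rate_pct)
  # old females are recaptured at a much lower rate than young ones
  expect_gt(r[["age5"]], r[["age28"]])
  # and a larger share of their recaptures falls beyond the release zone
  beyond5 <- 100 - mean(mr$release_share_pct[, "age5"], na.rm = TRUE)
  beyond28 <- 100 - mean(mr$release_share_pct[, "age28"], na.rm = TRUE)
  expect_gt(beyond28, beyond5)
})

test_that("scenario configuration validates coverage of weather and harvests", {
  farm <- tiny_farm(pupae = 1L)
  expect_error(scenario_config(farm, benign_weather(30), duration_days = 60),
               "shorter")
  expect_error(scenario_config(farm, benign_weather(120), duration_days = 40),
               "cover")
})
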