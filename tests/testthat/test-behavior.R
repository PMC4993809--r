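test_that("migration distances are clamped to 30-300 m and match the clamped-normal mean", {
  set.seed(5)
  mob <- mobility_params()
  d <- sample_migration_distance(rep(20, 100000), mob)
  expect_true(all(d >= 30 & d <= 300))
  mu <- mean_migration_distance(20, mob)
  oracle <- clamped_normal_mean(mu, 0.4 * mu, 30, 300)
  expect_equal(mean(d), oracle, tolerance = 1 / oracle)
  # mean distance grows with age
  expect_gt(mean_migration_distance(28, mob), mean_migration_distance(5, mob))
  expect_error(sample_migration_distance(-2), "age")
})

test_that("niche modulation is minor at low-to-moderate exploitation and neutral when empty", {
  expect_equal(niche_multiplier(0, 0), 1)
  expect_gte(niche_multiplier(0.3, 0), 0.9)
  expect_lt(niche_multiplier(0.8, 0), niche_multiplier(0.2, 0))
  expect_lt(niche_multiplier(0, 15), niche_multiplier(0, 2))
  expect_equal(niche_multiplier(1, 0), 0)
  expect_gte(leave_multiplier(0.5, 10), 1)
})

test_that("destination choice is uniform over a uniform ring and prefers attractive sectors", {
  # all-host farm with flat attractiveness: ring destinations are exchangeable
  sec <- expand.grid(col = 0:14, row = 0:14)
  sec <- data.frame(row = sec$row, col = sec$col, cover_type = "host",
                    cultivar = "Kordia", canopy_cover = 0.8,
                    canopy_diameter = 4, trap_id = NA_character_,
                    initial_pupae = 0L, fruit_count = 100L,
                    stringsAsFactors = FALSE)
  farm <- farm_grid(sec, two_cultivars())
  centre <- which(sec$row == 7 & sec$col == 7)
  att <- rep(0.5, nrow(sec))
  mob <- mobility_params()  # gap penalty irrelevant: no open sectors
  set.seed(9)
  draws <- replicate(20000, choose_destination(centre, farm, 40, att, mob))
  draws <- draws[!is.na(draws) & draws != centre]
  tab <- table(draws)
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)

  # a single high-attractiveness sector in the ring dominates the choice
  s <- farm$sectors
  ring <- which(abs(sqrt((s$x - s$x[centre])^2 + (s$y - s$y[centre])^2) - 40) <= 5)
  att2 <- rep(0.001, nrow(sec))
  att2[ring[1]] <- 1
  draws2 <- replicate(3000, choose_destination(centre, farm, 40, att2, mob,
                                               eps = 0.001))
  expect_equal(as.integer(names(which.max(table(draws2)))), ring[1])
})

test_that("an empty candidate ring forces emigration", {
  sec <- data.frame(row = 0, col = 0, cover_type = "host", cultivar = "Kordia",
                    canopy_cover = 1, canopy_diameter = 4,
                    trap_id = NA_character_, initial_pupae = 0L,
                    fruit_count = 10L, stringsAsFactors = FALSE)
  farm1 <- farm_grid(sec, two_cultivars())
  expect_true(is.na(choose_destination(1, farm1, 100, 0.5, mobility_params())))
})

test_that("daily movement respects the weather gate and the propensity knob", {
  farm <- tiny_farm()
  att <- rep(0.1, nrow(farm$sectors))
  host_idx <- which(farm$sectors$cover_type == "host")[1]
  # bad-weather day: no movement at all
  out <- daily_movement(host_idx, 20, farm, explore = FALSE, att)
  expect_equal(out$sector, host_idx)
  expect_false(out$emigrated)
  # zero propensity: never leaves the natal sector over a full season
  mob0 <- mobility_params(propensity_values = c(0, 0, 0))
  set.seed(4)
  for (i in 1:120) {
    out <- daily_movement(host_idx, i %% 90, farm, TRUE, att, params = mob0)
    expect_equal(out$sector, host_idx)
  }
})

test_that("the canopy-gap penalty channels relocations along contiguous cover", {
  # two host rows separated by open ground; crossing is discounted
  sec <- expand.grid(col = 0:9, row = 0:6)
  sec <- data.frame(row = sec$row, col = sec$col, cover_type = "empty",
                    cultivar = NA_character_, canopy_cover = 0,
                    canopy_diameter = 0, trap_id = NA_character_,
                    initial_pupae = 0L, fruit_count = 0L,
                    stringsAsFactors = FALSE)
  for (r in c(0, 3)) {
    idx <- sec$row == r
    sec$cover_type[idx] <- "host"; sec$cultivar[idx] <- "Kordia"
    sec$canopy_cover[idx] <- 0.8; sec$fruit_count[idx] <- 100L
  }
  farm <- farm_grid(sec, two_cultivars())
  G <- canopy_gap_matrix(farm)
  from <- which(sec$row == 3 & sec$col == 5)
  same_row <- which(sec$row == 3 & sec$col == 2)
  across <- which(sec$row == 0 & sec$col == 5)
  expect_lt(G[from, same_row], 0.2)
  expect_gt(G[from, across], 1.5)
  att <- rep(0.5, nrow(sec))
  mob <- mobility_params()  # young penalty 0.03
  set.seed(11)
  draws <- replicate(4000, choose_destination(from, farm, 30, att, mob, age = 5))
  draws <- draws[!is.na(draws) & draws != from]
  frac_across <- mean(farm$sectors$row[draws] <= 1)
  expect_lt(frac_across, 0.1)
  # old females cross far more readily
  draws_old <- replicate(4000, choose_destination(from, farm, 30, att, mob,
                                                  age = 40))
  draws_old <- draws_old[!is.na(draws_old) & draws_old != from]
  expect_gt(mean(farm$sectors$row[draws_old] <= 1), frac_across)
})

test_that("oviposition respects fruit limits, gating and niche modulation", {
  curve <- fecundity_curve()
  set.seed(8)
  # no suitable fruit: nothing laid
  expect_equal(oviposition_attempt(29, 0, curve), 0L)
  # weather gate off (e.g. 15.5 C day): nothing laid regardless of fruit
  expect_equal(oviposition_attempt(29, 100, curve, oviposit = FALSE), 0L)
  # one egg per fruit: never exceeds the available count
  laid <- replicate(500, oviposition_attempt(29, 3, curve))
  expect_true(all(laid <= 3))
  # saturated niche shuts oviposition down
  expect_equal(oviposition_attempt(29, 50, curve, infestation = 1), 0L)
})
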