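test_that("farm grid loading validates structure and cultivar references", {
  f <- tempfile(fileext = ".csv")
  writeLines("", f)
  expect_error(load_farm_grid(f))

  # 1 x 2 grid of empty sectors
  write.csv(data.frame(row = 0, col = 0:1, cover_type = "empty",
                       cultivar = NA, canopy_cover = 0, canopy_diameter = 0,
                       trap_id = NA, initial_pupae = 0, fruit_count = 0),
            f, row.names = FALSE)
  g <- load_farm_grid(f)
  expect_s3_class(g, "farm_grid")
  expect_equal(nrow(g$sectors), 2)
  expect_equal(sum(!is.na(g$sectors$trap_id)), 0)

  # dangling cultivar reference
  sec <- tiny_farm()$sectors
  sec$cultivar[sec$cover_type == "host"] <- "Nonexistent"
  expect_error(farm_grid(sec, two_cultivars()), "dangling")

  # non-rectangular grid
  expect_error(farm_grid(tiny_farm()$sectors[-1, ], two_cultivars()),
               "rectangle")
  # fruit on a non-host sector
  sec <- tiny_farm()$sectors
  sec$fruit_count[sec$cover_type == "empty"][1] <- 10
  expect_error(farm_grid(sec, two_cultivars()), "fruit")
})

test_that("fruit suitability windows follow hue dates or the 31/44% backward rule", {
  # Regina: hue-to-harvest 40 d ending 27 July
  reg <- cultivar_table("Regina", "late", "2015-05-04", "2015-06-17", "2015-07-27")
  w <- fruit_suitability_window(reg[1, ])
  expect_equal(w$start, as.Date("2015-06-17"))
  expect_equal(w$end, as.Date("2015-07-27"))
  expect_equal(w$length, 40L)

  # Kordia: hue-to-harvest 29 d ending 9 July
  kor <- cultivar_table("Kordia", "medium", "2015-05-20", "2015-06-10", "2015-07-09")
  w <- fruit_suitability_window(kor[1, ])
  expect_equal(w$start, as.Date("2015-06-10"))
  expect_equal(w$length, 29L)

  # early cultivar without hue record: last round(0.31 * 70) = 22 days
  early <- cultivar_table("E1", "early", "2015-04-20", NA, "2015-06-29")
  w <- fruit_suitability_window(early[1, ])
  expect_equal(w$length, 22L)
  expect_equal(w$start, as.Date("2015-06-29") - 22)

  # neither hue change nor flowering available
  bad <- cultivar_table("X", "early", NA, NA, "2015-07-01")
  expect_error(fruit_suitability_window(bad[1, ]), "neither")
})

test_that("default-rule windows never exceed the flowering-to-harvest span", {
  set.seed(2)
  for (i in 1:20) {
    span <- sample(50:90, 1)
    grp <- sample(c("early", "medium", "late", "very_late"), 1)
    cv <- cultivar_table("C", grp, as.Date("2015-04-15"), NA,
                         as.Date("2015-04-15") + span)
    expect_lte(fruit_suitability_window(cv[1, ])$length, span)
  }
})

test_that("windows recomputed from recorded hue dates match the printed season table", {
  # cultivar calendar with recorded flowering-to-hue and hue-to-harvest spans
  fsw <- c(Hertford = 23, Kordia = 29, Karina = 19, GraceStar = 26,
           Lapins = 30, Regina = 40, Sylvia = 44, Sweetheart = 45)
  fy <- c(59, 50, 62, 54, 61, 53, 50, 59)
  harvest <- as.Date(c("2015-07-07", "2015-07-09", "2015-07-10", "2015-07-10",
                       "2015-07-14", "2015-07-27", "2015-07-28", "2015-07-29"))
  cv <- cultivar_table(names(fsw), "late", harvest - fy - fsw,
                       harvest - fsw, harvest)
  for (i in seq_along(fsw))
    expect_equal(fruit_suitability_window(cv[i, ])$length, unname(fsw[i]))
})

test_that("daily fruit attractiveness is an asymmetric bell peaking at 1/3 of the window", {
  reg <- cultivar_table("Regina", "late", "2015-05-04", "2015-06-17",
                        "2015-07-27")[1, ]
  w <- fruit_suitability_window(reg)
  days <- seq(w$start - 10, w$end + 10, by = 1)
  vals <- daily_fruit_attractiveness(reg, days)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(vals[days < w$start], rep(0, sum(days < w$start)))
  expect_equal(vals[days > w$end], rep(0, sum(days > w$end)))
  peak_day <- w$start + w$length %/% 3
  expect_equal(daily_fruit_attractiveness(reg, peak_day), 1.0)
  # post-peak decline is monotone and ends below the peak
  post <- daily_fruit_attractiveness(reg, seq(peak_day, w$end, by = 1))
  expect_true(all(diff(post) <= 1e-12))
  expect_lt(daily_fruit_attractiveness(reg, w$end), 1.0)
})

test_that("sector attractiveness combines cover, canopy, phenology and niche state", {
  farm <- tiny_farm(fruit = 200L)
  s <- farm$sectors
  empty_idx <- which(s$cover_type == "empty")[1]
  host_idx <- which(s$cover_type == "host")[1]
  # empty sector attracts nothing on any date
  expect_equal(sector_attractiveness(empty_idx, as.Date("2015-06-20"),
                                     farm = farm), 0)
  # host sector outside the suitability window: 30% baseline times canopy
  expect_equal(sector_attractiveness(host_idx, as.Date("2015-05-20"),
                                     farm = farm), 0.3 * 0.8)
  # at the cultivar's peak, attractiveness equals the canopy factor
  kor <- farm$cultivars[1, ]
  w <- fruit_suitability_window(kor)
  peak_day <- w$start + w$length %/% 3
  expect_equal(sector_attractiveness(host_idx, peak_day, farm = farm), 0.8)
  # halving canopy halves it
  farm2 <- farm
  farm2$sectors$canopy_cover[host_idx] <- 0.4
  expect_equal(sector_attractiveness(host_idx, peak_day, farm = farm2), 0.4)
  # crowding and infestation modulate downward
  expect_lt(sector_attractiveness(host_idx, peak_day, local_density = 10,
                                  local_infestation = 0.5, farm = farm), 0.8)
  # full-season scan stays within [0, 1] for every sector
  for (d in seq(as.Date("2015-05-15"), by = 7, length.out = 12)) {
    a <- sapply(seq_len(nrow(s)), function(i)
      sector_attractiveness(i, as.Date(d, origin = "1970-01-01"), farm = farm))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("farm grids round-trip through CSV", {
  farm <- tiny_farm(pupae = 3L)
  f <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
  write_farm_grid(farm, f, cf)
  back <- load_farm_grid(f, cf)
  expect_equal(back$sectors[c("row", "col", "cover_type", "cultivar",
                              "initial_pupae", "fruit_count")],
               farm$sectors[c("row", "col", "cover_type", "cultivar",
                              "initial_pupae", "fruit_count")])
  expect_equal(back$cultivars$name, farm$cultivars$name)
})
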