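# shared fixtures, built in code at test time

two_cultivars <- function() {
  cultivar_table(
    name = c("Kordia", "Regina"), group = c("medium", "late"),
    flowering = c("2015-04-20", "2015-04-24"),
    hue_change = c("2015-06-10", "2015-06-17"),
    harvest1 = c("2015-07-09", "2015-07-27"))
}

# minimal one-plot farm: a 6 x 8 grid with a 2 x 4 Kordia plot and one trap
tiny_farm <- function(pupae = 0L, fruit = 200L) {
  sec <- expand.grid(col = 0:7, row = 0:5)
  sec <- data.frame(row = sec$row, col = sec$col, cover_type = "empty",
                    cultivar = NA_character_, canopy_cover = 0,
                    canopy_diameter = 0, trap_id = NA_character_,
                    initial_pupae = 0L, fruit_count = 0L,
                    stringsAsFactors = FALSE)
  plot <- sec$row %in% 2:3 & sec$col %in% 2:5
  sec$cover_type[plot] <- "host"
  sec$cultivar[plot] <- "Kordia"
  sec$canopy_cover[plot] <- 0.8
  sec$fruit_count[plot] <- fruit
  sec$initial_pupae[plot] <- pupae
  sec$trap_id[sec$row == 2 & sec$col == 3] <- "T1"
  farm_grid(sec, two_cultivars())
}

# closed-form mean of a Normal(mu, sigma) clamped to [a, b]
clamped_normal_mean <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  a * pnorm(al) + b * pnorm(be, lower.tail = FALSE) +
    mu * (pnorm(be) - pnorm(al)) - sigma * (dnorm(be) - dnorm(al))
}
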