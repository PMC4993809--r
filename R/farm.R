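#' Build a cultivar phenology table
#'
#' @param name cultivar labels.
#' @param group phenology group, one of \code{"early"}, \code{"medium"},
#'   \code{"late"}, \code{"very_late"}.
#' @param flowering flowering dates (30\% flowers open), \code{Date} or ISO
#'   strings; may be \code{NA} when a hue-change date is recorded.
#' @param hue_change date of fruit color change (green to yellowish-green),
#'   opening the fruit suitability window; \code{NA} when unrecorded.
#' @param harvest1,harvest2 harvest date(s); \code{harvest2} optional.
#' @return a \code{cultivar_table} data.frame.
#' @export
cultivar_table <- function(name, group, flowering = NA, hue_change = NA,
                           harvest1, harvest2 = NA) {
  groups <- c("early", "medium", "late", "very_late")
  if (!all(group %in% groups))
    stop("unknown phenology group; expected one of ", paste(groups, collapse = ", "))
  cv <- data.frame(name = as.character(name), group = as.character(group),
                   flowering = as.Date(flowering), hue_change = as.Date(hue_change),
                   harvest1 = as.Date(harvest1), harvest2 = as.Date(harvest2),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cv))) {
    h <- last_harvest(cv[i, ])
    if (is.na(h)) stop("cultivar ", cv$name[i], ": harvest date required")
    if (!is.na(cv$hue_change[i]) && !is.na(cv$flowering[i]) &&
        !(cv$flowering[i] < cv$hue_change[i] && cv$hue_change[i] < cv$harvest1[i]))
      stop("cultivar ", cv$name[i], ": expected flowering < hue change < harvest")
  }
  class(cv) <- c("cultivar_table", "data.frame")
  cv
}

last_harvest <- function(cultivar) {
  h <- c(cultivar$harvest1, cultivar$harvest2)
  h <- h[!is.na(h)]
  if (!length(h)) return(as.Date(NA))
  max(h)
}

#' Default fruit-suitability fraction of the flowering-to-harvest period
#'
#' When no hue-change date is recorded, the fruit suitability window is
#' estimated as 31\% (early/medium cultivars) or 44\% (late/very-late
#' cultivars) of the flowering-to-harvest period, counted backwards from
#' harvest.
#'
#' @param group phenology group label(s).
#' @return 0.31 or 0.44.
#' @export
suitability_fraction <- function(group) {
  ifelse(group %in% c("early", "medium"), 0.31, 0.44)
}

#' Fruit suitability window of a cultivar
#'
#' The period during which fruit can be infested: from the hue change (green
#' to yellowish-green) until the last harvest.  When the hue-change date is
#' unrecorded, the window start is estimated backwards from harvest as
#' \code{harvest - round(fraction * (harvest - flowering))} with the group
#' default fraction (\code{\link{suitability_fraction}}).
#'
#' @param cultivar one row of a \code{\link{cultivar_table}}.
#' @return list with \code{start}, \code{end} (Dates) and \code{length}
#'   (days, \code{end - start}).
#' @export
fruit_suitability_window <- function(cultivar) {
  end <- last_harvest(cultivar)
  if (is.na(end)) stop("cultivar ", cultivar$name, ": no harvest date")
  if (!is.na(cultivar$hue_change)) {
    start <- cultivar$hue_change
  } else if (!is.na(cultivar$flowering)) {
    span <- as.integer(end - cultivar$flowering)
    start <- end - round(suitability_fraction(cultivar$group) * span)
  } else {
    stop("cultivar ", cultivar$name,
         ": neither hue-change nor flowering date available")
  }
  if (start > end) stop("cultivar ", cultivar$name, ": window start after harvest")
  list(start = start, end = end, length = as.integer(end - start))
}

#' Daily fruit attractiveness of a cultivar
#'
#' Asymmetric bell over the fruit suitability window: zero outside the
#' window, rising to exactly 1 at one third of the window length past its
#' start, then declining monotonically to a low terminal value (0.2) at
#' harvest, when fully ripened dark fruit loses attractiveness.  The peak
#' height is the same for all cultivars.
#'
#' @param cultivar one row of a \code{\link{cultivar_table}}.
#' @param date a \code{Date} (vectorized).
#' @param terminal attractiveness at harvest.
#' @return attractiveness in \code{[0, 1]}.
#' @export
daily_fruit_attractiveness <- function(cultivar, date, terminal = 0.2) {
  w <- fruit_suitability_window(cultivar)
  d <- as.integer(as.Date(date) - w$start)    # day offset within window
  L <- w$length
  peak <- L %/% 3
  out <- numeric(length(d))
  rise <- d >= 0 & d <= peak
  out[rise] <- sin(pi / 2 * (d[rise] + 1) / (peak + 1))
  fall <- d > peak & d <= L
  out[fall] <- terminal + (1 - terminal) * ((L - d[fall]) / (L - peak))^1.5
  out
}

#' Load and validate a farm grid
#'
#' Reads the sector CSV (columns \code{row,col,cover_type,cultivar,
#' canopy_cover,canopy_diameter,trap_id,initial_pupae,fruit_count}; one row
#' per 10 x 10 m sector) and assembles a validated \code{farm_grid}.
#'
#' @param path sector CSV path.
#' @param cultivars a \code{\link{cultivar_table}}, or path to a cultivar CSV
#'   with columns \code{name,group,flowering,hue_change,harvest1[,harvest2]}
#'   (ISO dates; empty cells for unrecorded values).
#' @return a \code{farm_grid}.
#' @export
load_farm_grid <- function(path, cultivars = NULL) {
  sec <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read farm grid: ", conditionMessage(e)))
  if (nrow(sec) == 0) stop("farm grid file is empty")
  if (is.character(cultivars)) {
    cv <- utils::read.csv(cultivars, stringsAsFactors = FALSE)
    if (!"harvest2" %in% names(cv)) cv$harvest2 <- NA
    cultivars <- cultivar_table(cv$name, cv$group, cv$flowering,
                                cv$hue_change, cv$harvest1, cv$harvest2)
  }
  farm_grid(sec, cultivars)
}

#' Construct a farm grid from a sector table
#'
#' @param sectors data.frame with columns \code{row,col,cover_type,cultivar,
#'   canopy_cover,canopy_diameter,trap_id,initial_pupae,fruit_count};
#'   \code{row}/\code{col} 0-based.
#' @param cultivars a \code{\link{cultivar_table}} (required when any sector
#'   is a host), or \code{NULL}.
#' @param zones optional named list of sector index vectors (recapture zones).
#' @param release_sector optional sector index of a mark-recapture release
#'   point.
#' @return a \code{farm_grid}: list with the validated \code{sectors} table
#'   (ordered row-major, with sector centre coordinates \code{x},\code{y} in
#'   meters), the \code{cultivars} table and grid \code{nrow}/\code{ncol}.
#' @export
farm_grid <- function(sectors, cultivars = NULL, zones = NULL,
                      release_sector = NULL) {
  needed <- c("row", "col", "cover_type", "cultivar", "canopy_cover",
              "canopy_diameter", "trap_id", "initial_pupae", "fruit_count")
  missing <- setdiff(needed, names(sectors))
  if (length(missing))
    stop("farm grid missing columns: ", paste(missing, collapse = ", "))
  covers <- c("host", "non_host_tree", "empty")
  bad <- which(!sectors$cover_type %in% covers)
  if (length(bad))
    stop("row ", bad[1], ": unknown cover_type '", sectors$cover_type[bad[1]], "'")
  sectors$cultivar[sectors$cultivar %in% c("", "NA")] <- NA
  sectors$trap_id[sectors$trap_id %in% c("", "NA")] <- NA

  rows <- sort(unique(sectors$row)); cols <- sort(unique(sectors$col))
  if (nrow(sectors) != length(rows) * length(cols) ||
      !all(rows == seq(min(rows), max(rows))) ||
      length(rows) != max(rows) - min(rows) + 1 ||
      !all(cols == seq(min(cols), max(cols))) ||
      length(cols) != max(cols) - min(cols) + 1)
    stop("farm grid is not a complete rectangle of sectors")
  if (anyDuplicated(sectors[c("row", "col")]))
    stop("duplicated sector coordinates in farm grid")

  host <- sectors$cover_type == "host"
  bad <- which(host & is.na(sectors$cultivar))
  if (length(bad)) stop("row ", bad[1], ": host sector without cultivar")
  bad <- which(!host & !is.na(sectors$cultivar))
  if (length(bad)) stop("row ", bad[1], ": cultivar on a non-host sector")
  bad <- which(!host & sectors$fruit_count > 0)
  if (length(bad)) stop("row ", bad[1], ": fruit on a non-host sector")
  if (any(host)) {
    if (is.null(cultivars)) stop("host sectors present but no cultivar table given")
    dangling <- setdiff(unique(sectors$cultivar[host]), cultivars$name)
    if (length(dangling))
      stop("dangling cultivar reference: ", paste(dangling, collapse = ", "))
  }
  stopifnot(all(sectors$canopy_cover >= 0 & sectors$canopy_cover <= 1),
            all(sectors$initial_pupae >= 0), all(sectors$fruit_count >= 0))

  sectors <- sectors[order(sectors$row, sectors$col), , drop = FALSE]
  rownames(sectors) <- NULL
  # sector centres, meters; 0-based row-major grid of 10 m sectors
  sectors$x <- (sectors$col + 0.5) * 10
  sectors$y <- (sectors$row + 0.5) * 10
  structure(list(sectors = sectors, cultivars = cultivars,
                 nrow = length(rows), ncol = length(cols),
                 zones = zones, release_sector = release_sector),
            class = "farm_grid")
}

#' @export
print.farm_grid <- function(x, ...) {
  s <- x$sectors
  cat(sprintf("farm_grid: %d x %d sectors (%.1f ha)\n", x$nrow, x$ncol,
              nrow(s) * 100 / 1e4))
  cat(sprintf("  host: %d, non-host trees: %d, empty: %d; traps: %d; initial pupae: %d\n",
              sum(s$cover_type == "host"), sum(s$cover_type == "non_host_tree"),
              sum(s$cover_type == "empty"), sum(!is.na(s$trap_id)),
              sum(s$initial_pupae)))
  if (!is.null(x$zones))
    cat("  zones: ", paste(names(x$zones), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a farm grid back to its CSV representation
#'
#' @param farm a \code{farm_grid}.
#' @param path sector CSV to write.
#' @param cultivar_path optional cultivar CSV to write.
#' @export
write_farm_grid <- function(farm, path, cultivar_path = NULL) {
  cols <- c("row", "col", "cover_type", "cultivar", "canopy_cover",
            "canopy_diameter", "trap_id", "initial_pupae", "fruit_count")
  utils::write.csv(farm$sectors[cols], path, row.names = FALSE, na = "")
  if (!is.null(cultivar_path) && !is.null(farm$cultivars)) {
    cv <- farm$cultivars
    utils::write.csv(
      data.frame(name = cv$name, group = cv$group,
                 flowering = as.character(cv$flowering),
                 hue_change = as.character(cv$hue_change),
                 harvest1 = as.character(cv$harvest1),
                 harvest2 = as.character(cv$harvest2)),
      cultivar_path, row.names = FALSE, na = "")
  }
  invisible(farm)
}

#' Daily attractiveness of one sector
#'
#' Empty sectors are unattractive; non-host trees retain a low baseline
#' attraction from their chemical cues; host sectors are attractive in
#' proportion to their canopy cover, at a 30\% baseline outside the fruit
#' suitability window and up to the full fruit attractiveness inside it.
#' High local infestation or crowding modulates the value downward via the
#' niche rules (\code{\link{niche_multiplier}}).
#'
#' @param sector one row of \code{farm$sectors} (or its index given
#'   \code{farm}).
#' @param date a \code{Date}.
#' @param local_density live females currently in the sector.
#' @param local_infestation infested fraction of the sector's fruit.
#' @param farm the \code{farm_grid} (for cultivar lookup).
#' @param nonhost_attraction baseline attraction of non-host tree sectors.
#' @param density_capacity crowding normalization (females/sector).
#' @return attractiveness in \code{[0, 1]}.
#' @export
sector_attractiveness <- function(sector, date, local_density = 0,
                                  local_infestation = 0, farm,
                                  nonhost_attraction = 0.10,
                                  density_capacity = 20) {
  if (is.numeric(sector) && length(sector) == 1) sector <- farm$sectors[sector, ]
  base <- switch(sector$cover_type,
    empty = 0,
    non_host_tree = nonhost_attraction * sector$canopy_cover,
    host = {
      cv <- farm$cultivars[match(sector$cultivar, farm$cultivars$name), ]
      fr <- daily_fruit_attractiveness(cv, date)
      sector$canopy_cover * max(0.30, fr)
    })
  base * niche_multiplier(local_infestation, local_density, density_capacity)
}

# Vectorized attractiveness over all sectors of a farm for one date.
# `bell` is the per-cultivar attractiveness value for that date (named);
# precomputed by the engine to avoid repeated window arithmetic.
attractiveness_vector <- function(farm, bell, density, infestation,
                                  nonhost_attraction = 0.10,
                                  density_capacity = 20) {
  s <- farm$sectors
  att <- numeric(nrow(s))
  nh <- s$cover_type == "non_host_tree"
  att[nh] <- nonhost_attraction * s$canopy_cover[nh]
  h <- s$cover_type == "host"
  if (any(h)) {
    fr <- bell[s$cultivar[h]]
    att[h] <- s$canopy_cover[h] * pmax(0.30, fr)
  }
  att * niche_multiplier(infestation, density, density_capacity)
}

# Per-cultivar bell value for one date: named numeric vector.
cultivar_bell <- function(farm, date) {
  cv <- farm$cultivars
  if (is.null(cv)) return(numeric(0))
  vals <- vapply(seq_len(nrow(cv)),
                 function(i) daily_fruit_attractiveness(cv[i, ], date), 0)
  names(vals) <- cv$name
  vals
}
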