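# Data-structuring rules for the two survey streams: zero-filling and
# first-year observer flags for route counts; quality filters, hexagonal
# spatiotemporal subsampling and effort covariates for checklists.

#' Flag first-year observers
#'
#' The first-year indicator is 1 exactly when the record's year equals the
#' observer's first year anywhere in the full survey archive (which may
#' predate the study window), 0 otherwise.
#'
#' @param records Data frame with `observer_id` and `year`.
#' @param observers Observer-history data frame with `observer_id` and
#'   `first_year` (first year the observer ever surveyed).
#' @return Integer 0/1 vector aligned with `records`.
#' @export
flag_first_year <- function(records, observers) {
  fy <- observers$first_year[match(records$observer_id, observers$observer_id)]
  if (any(is.na(fy)))
    stop("observer(s) missing from the history: ",
         paste(unique(records$observer_id[is.na(fy)]), collapse = ", "))
  if (any(records$year < fy))
    stop("record year precedes the observer's first year in the archive")
  as.integer(records$year == fy)
}

#' Zero-fill route counts
#'
#' Adds a count-0 record for every surveyed route-year that has no detection
#' record, so non-detections inform the likelihood. Added records take their
#' observer (and any other columns, e.g. coordinates) from the surveyed-set
#' table.
#'
#' @param records Detection records: data frame with `route_id`, `year`,
#'   `species_count` (and usually `observer_id`).
#' @param surveyed The full set of surveyed route-years: data frame with
#'   `route_id`, `year`, `observer_id` and optionally other columns to carry
#'   into the filled records.
#' @return Data frame with exactly one record per surveyed route-year.
#' @export
zero_fill_bbs <- function(records, surveyed) {
  key <- function(d) paste(d$route_id, d$year, sep = "\r")
  if (anyDuplicated(key(surveyed)))
    stop("duplicate route-years in the surveyed set")
  if (nrow(records) > 0 && !all(key(records) %in% key(surveyed)))
    stop("detection record on a route-year not in the surveyed set")
  missing <- !(key(surveyed) %in% key(records))
  add <- surveyed[missing, , drop = FALSE]
  add$species_count <- rep(0L, nrow(add))
  cols <- union(names(records), names(add))
  for (cc in setdiff(cols, names(add))) add[[cc]] <- NA
  if (nrow(records) > 0) {
    for (cc in setdiff(cols, names(records))) records[[cc]] <- NA
    out <- rbind(records[cols], add[cols])
  } else out <- add[cols]
  rownames(out) <- NULL
  out
}

#' Filter checklists on completeness and effort
#'
#' Keeps only complete checklists (all species recorded) with duration
#' < 300 minutes (5 h), distance travelled < 5 km, and < 10 observers --
#' strict inequalities. Stationary counts are treated as distance 0. Records
#' with a missing effort field are rejected with reason `"missing"`; other
#' rejections are attributed to the first rule violated in the order
#' completeness, duration, distance, observers.
#'
#' @param checklists Data frame with `all_species_reported` (logical or 0/1),
#'   `duration_min`, `distance_km`, `n_observers`, and optionally `protocol`
#'   (`"stationary"` distances are zeroed).
#' @return A list: `kept` (the surviving data frame) and `counts`, a named
#'   integer vector of rejection counts per rule plus `kept`.
#' @export
filter_checklists <- function(checklists) {
  d <- checklists
  dist <- d$distance_km
  if (!is.null(d$protocol)) dist[d$protocol == "stationary"] <- 0
  miss <- is.na(d$all_species_reported) | is.na(d$duration_min) |
    is.na(dist) | is.na(d$n_observers)
  reason <- rep(NA_character_, nrow(d))
  reason[miss] <- "missing"
  ok <- !miss
  incomplete <- ok & !(as.logical(d$all_species_reported))
  reason[incomplete] <- "incomplete"
  ok <- ok & !incomplete
  dur <- ok & !(d$duration_min < 300)
  reason[dur] <- "duration"
  ok <- ok & !dur
  dst <- ok & !(dist < 5)
  reason[dst] <- "distance"
  ok <- ok & !dst
  obs <- ok & !(d$n_observers < 10)
  reason[obs] <- "observers"
  ok <- ok & !obs
  counts <- c(missing = sum(miss), incomplete = sum(incomplete),
              duration = sum(dur), distance = sum(dst),
              observers = sum(obs), kept = sum(ok))
  list(kept = d[ok, , drop = FALSE], counts = counts)
}

# Hexagonal lattice with center spacing `a` km: rows at a*sqrt(3)/2 apart,
# odd rows shifted a/2. Nearest-center assignment; candidate centers from the
# two nearest rows, ties to the lowest (row, col).
.hex_assign <- function(x, y, a) {
  dy <- a * sqrt(3) / 2
  n <- length(x)
  row <- integer(n); col <- integer(n)
  for (i in seq_len(n)) {
    r0 <- floor(y[i] / dy)
    best <- Inf; br <- 0L; bc <- 0L
    for (r in c(r0, r0 + 1)) {
      off <- (r %% 2) * a / 2
      c0 <- floor((x[i] - off) / a)
      for (cc in c(c0, c0 + 1)) {
        d2 <- (x[i] - (cc * a + off))^2 + (y[i] - r * dy)^2
        if (d2 < best - 1e-12 ||
            (abs(d2 - best) <= 1e-12 && (r < br || (r == br && cc < bc)))) {
          best <- d2; br <- as.integer(r); bc <- as.integer(cc)
        }
      }
    }
    row[i] <- br; col[i] <- bc
  }
  paste(row, col, sep = ":")
}

#' Assign checklists to hexagonal-grid cells and season weeks
#'
#' Assigns each checklist to the nearest center of a hexagonal lattice with
#' 5-km center spacing, and to a 7-day week block anchored at the season
#' start (June 1 by default; week 0 = June 1-7). Dates outside June-July are
#' flagged `in_season = FALSE` with `week_index = NA`.
#'
#' @param checklists Data frame with `x_km`, `y_km`, and `date`
#'   (`Date` or `"YYYY-MM-DD"` strings).
#' @param hex_spacing_km Center-to-center spacing of the hexagonal lattice.
#' @param season_start `"MM-DD"` anchor of week 0 (default `"06-01"`).
#' @param season_end `"MM-DD"` last in-season day (default `"07-31"`).
#' @return The data frame with `hex_id`, `week_index`, `in_season` columns.
#' @export
assign_hex_week <- function(checklists, hex_spacing_km = 5,
                            season_start = "06-01", season_end = "07-31") {
  d <- checklists
  dt <- as.Date(d$date)
  yr <- as.integer(format(dt, "%Y"))
  start <- as.Date(paste0(yr, "-", season_start))
  end <- as.Date(paste0(yr, "-", season_end))
  in_season <- !is.na(dt) & dt >= start & dt <= end
  wk <- as.integer(floor(as.numeric(dt - start) / 7))
  wk[!in_season] <- NA_integer_
  d$hex_id <- .hex_assign(d$x_km, d$y_km, hex_spacing_km)
  d$week_index <- wk
  d$in_season <- in_season
  d
}

#' Spatiotemporally subsample checklists
#'
#' Thins checklists within each hexagonal-grid cell x week (x year, if a
#' `year` column is present) stratum. In `"retain_detections"` mode (rare
#' species) every detection is kept and one uniformly random non-detection
#' is retained per stratum; in `"balanced"` mode (very frequently detected
#' species) at most one random detection and one random non-detection are
#' retained per stratum. Output is always a subset of the input.
#'
#' @param checklists Data frame with `hex_id`, `week_index`, `species_count`
#'   (see [assign_hex_week()]); rows with `NA` `week_index` are dropped.
#' @param mode `"retain_detections"` or `"balanced"`.
#' @param seed Integer RNG seed for the uniform draws.
#' @return The retained subset of `checklists`.
#' @export
subsample_checklists <- function(checklists,
                                 mode = c("retain_detections", "balanced"),
                                 seed = 1) {
  mode <- match.arg(mode)
  d <- checklists[!is.na(checklists$week_index), , drop = FALSE]
  yr <- if (!is.null(d$year)) d$year else 0L
  stratum <- paste(d$hex_id, d$week_index, yr, sep = "\r")
  det <- d$species_count > 0
  keep <- logical(nrow(d))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (s in unique(stratum)) {
    in_s <- which(stratum == s)
    ds <- in_s[det[in_s]]; ns <- in_s[!det[in_s]]
    if (mode == "retain_detections") keep[ds] <- TRUE
    else if (length(ds)) keep[ds[sample.int(length(ds), 1)]] <- TRUE
    if (length(ns)) keep[ns[sample.int(length(ns), 1)]] <- TRUE
  }
  d[keep, , drop = FALSE]
}

#' Solar-time-of-day covariates
#'
#' Maps a start time in solar seconds of day to the 24-h-period pair
#' `(cos(2*pi*s/86400), sin(2*pi*s/86400))`: the cosine is high at night and
#' low at midday, the sine high in the morning and low in the evening.
#'
#' @param start_seconds Seconds since solar midnight, in `[0, 86400)`.
#' @return Data frame with columns `costime` and `sintime`.
#' @examples
#' solar_time_covariates(c(0, 21600, 43200))
#' @export
solar_time_covariates <- function(start_seconds) {
  if (any(start_seconds < 0 | start_seconds >= 86400))
    stop("start_seconds must lie in [0, 86400)")
  ang <- 2 * pi * start_seconds / 86400
  data.frame(costime = cos(ang), sintime = sin(ang))
}

#' Approximate local solar seconds from clock time
#'
#' Clock time plus 240 seconds per degree of longitude east of the time
#' zone's reference meridian (an approximation sufficient for effort
#' covariates; the synthetic generator produces solar seconds directly).
#'
#' @param clock_seconds Seconds since local clock midnight.
#' @param lon Longitude in degrees (east positive).
#' @param tz_meridian Reference meridian of the local time zone (degrees).
#' @return Solar seconds of day in `[0, 86400)`.
#' @export
clock_to_solar_seconds <- function(clock_seconds, lon, tz_meridian) {
  (clock_seconds + 240 * (lon - tz_meridian)) %% 86400
}

#' Effort covariate matrix for the checklist observation model
#'
#' Builds the `TYPE, DIST, COSTIME, SINTIME, DURA, NOOB` design columns from
#' a checklist data frame: `TYPE` = 1 for stationary point counts and 0 for
#' travelling transects (whose distance enters as `DIST`; stationary
#' distances are zeroed), solar-time covariates from `start_seconds`,
#' duration in minutes and number of observers.
#'
#' @param checklists Data frame with `protocol`, `distance_km`,
#'   `start_seconds`, `duration_min`, `n_observers`.
#' @return Numeric matrix with columns `TYPE`, `DIST`, `COSTIME`, `SINTIME`,
#'   `DURA`, `NOOB`.
#' @export
effort_covariates <- function(checklists) {
  d <- checklists
  type <- as.numeric(d$protocol == "stationary")
  dist <- ifelse(type == 1, 0, d$distance_km)
  st <- solar_time_covariates(d$start_seconds)
  cbind(TYPE = type, DIST = dist, COSTIME = st$costime, SINTIME = st$sintime,
        DURA = d$duration_min, NOOB = d$n_observers)
}
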